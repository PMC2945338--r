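# Default book-keeping coefficients (Georgian parameterisation).
# Missing keys fall back to the package defaults; see ?carbon_coefficients.
slash_ratio_clearing   = 0.33
slash_ratio_harvest    = 0.09
slash_decay_rate       = 0.04
frac_1y_clearing       = 0.500
frac_10y_clearing      = 0.100
frac_100y_clearing     = 0.070
frac_1y_harvest        = 0.307
frac_10y_harvest       = 0.072
frac_100y_harvest      = 0.531
decay_rate_10y         = 0.10
decay_rate_100y        = 0.01
veg_c_mature           = 144
veg_c_min              = 5
veg_c_initial_recovery = 127
initial_recovery_time  = 80
full_recovery_time     = 100
soil_c_undisturbed     = 134
soil_c_disturbed       = 114
soil_c_min             = 107
soil_recovery_time     = 40
biomass_discount       = 1.0
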