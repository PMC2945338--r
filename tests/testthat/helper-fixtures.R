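# Shared fixtures, built in code at test time.

# the published Georgian stratified assessment (counts, sample sizes, areas)
table1_matrix <- function() {
  read_error_matrix(system.file("extdata", "georgia_error_matrix.csv",
                                package = "luccarbon"))
}

# truth spec whose per-stratum probabilities equal the observed Table-1
# reference proportions, with the same sample allocation and areas
table1_spec <- function() {
  em <- table1_matrix()
  truth_spec(sweep(em$counts, 1, em$n_h, "/"), em$A_h, em$n_h,
             em$strata_labels)
}

# random valid error matrix for property-style loops
random_error_matrix <- function(k = 3, seed = 1, n_max = 200) {
  set.seed(seed)
  n_h <- sample(2:n_max, k, replace = TRUE)
  probs <- matrix(stats::rgamma(k * k, 1), k)
  probs <- probs / rowSums(probs)
  counts <- t(vapply(seq_len(k),
                     function(h) stats::rmultinom(1, n_h[h], probs[h, ])[, 1],
                     numeric(k)))
  error_matrix(counts, stats::runif(k, 1e3, 1e6))
}
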