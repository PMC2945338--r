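#' Ground-truth specification for a synthetic accuracy assessment
#'
#' Defines the "true" confusion structure of a stratified accuracy
#' assessment: for each map stratum, its mapped area, its sample size and
#' the probability that a sampled unit's reference class is each of the
#' classes. From this spec, assessments can be simulated (stratified random
#' sampling: per-stratum multinomial counts with fixed \code{n_h}) and the
#' design-based estimators validated against the known truth.
#'
#' @param probs square matrix; row \code{h} is stratum \code{h}'s reference
#'   class probability vector (rows sum to 1).
#' @param mapped_area_ha positive mapped area per stratum, hectares.
#' @param n_h samples per stratum, each \eqn{\ge 2}.
#' @param strata_labels class names; default from \code{probs} row names.
#' @return An object of class \code{"truth_spec"}.
#' @seealso [simulate_assessment()], [coverage_experiment()]
#' @export
truth_spec <- function(probs, mapped_area_ha, n_h,
                       strata_labels = rownames(probs)) {
  probs <- as.matrix(probs)
  if (nrow(probs) != ncol(probs)) stop("'probs' must be square")
  k <- nrow(probs)
  if (is.null(strata_labels)) strata_labels <- paste0("class_", seq_len(k))
  if (any(probs < 0) || any(abs(rowSums(probs) - 1) > 1e-9))
    stop("each row of 'probs' must be a probability vector summing to 1")
  if (length(mapped_area_ha) != k || any(mapped_area_ha <= 0))
    stop("'mapped_area_ha' must be ", k, " positive areas")
  n_h <- as.integer(rep_len(n_h, k))
  if (any(n_h < 2)) stop("every 'n_h' must be at least 2")
  dimnames(probs) <- list(strata_labels, strata_labels)
  structure(list(probs = probs, A_h = mapped_area_ha, n_h = n_h,
                 strata_labels = as.character(strata_labels)),
            class = "truth_spec")
}

#' True class proportions implied by a truth spec
#'
#' The population value of the stratified estimator:
#' \eqn{\phi_c = \sum_h W_h \, P(\mathrm{ref} = c \mid h)}.
#'
#' @param spec a [truth_spec()].
#' @return Named vector of true proportions (sums to 1).
#' @export
true_class_proportions <- function(spec) {
  stopifnot(inherits(spec, "truth_spec"))
  W <- spec$A_h / sum(spec$A_h)
  colSums(W * spec$probs)
}

#' Simulate one stratified accuracy assessment
#'
#' Draws each stratum's reference-class counts from a multinomial with that
#' stratum's sample size and probability vector, and assembles the result
#' into an [error_matrix()].
#'
#' @param spec a [truth_spec()].
#' @param seed optional integer seed for reproducibility.
#' @return An [error_matrix()].
#' @export
simulate_assessment <- function(spec, seed = NULL) {
  stopifnot(inherits(spec, "truth_spec"))
  if (!is.null(seed)) set.seed(seed)
  k <- nrow(spec$probs)
  counts <- t(vapply(seq_len(k),
                     function(h) stats::rmultinom(1, spec$n_h[h],
                                                  spec$probs[h, ])[, 1],
                     numeric(k)))
  error_matrix(counts, spec$A_h, spec$strata_labels)
}

#' Monte-Carlo validation of the stratified estimator
#'
#' Repeatedly simulates assessments from a known truth, computes the
#' adjusted proportion and its \eqn{\pm m \cdot SE} interval for one class,
#' and summarises empirical coverage, bias, and the agreement between the
#' analytic standard error and the Monte-Carlo spread of the estimates.
#'
#' @param spec a [truth_spec()].
#' @param class class label (or index) whose proportion is tracked.
#' @param replicates number of simulated assessments, \eqn{\ge 100}.
#' @param seed optional integer seed.
#' @param ci_multiplier interval half-width multiplier (default 2, nominal
#'   coverage about 95.4% under the normal approximation).
#' @return List with \code{true_phi}, \code{coverage}, \code{bias},
#'   \code{bias_mc_se} (Monte-Carlo standard error of the bias),
#'   \code{mean_phi_hat}, \code{sd_phi_hat}, \code{mean_analytic_se},
#'   \code{mean_analytic_var} and \code{replicates}.
#' @export
coverage_experiment <- function(spec, class, replicates = 2000, seed = NULL,
                                ci_multiplier = 2) {
  stopifnot(inherits(spec, "truth_spec"))
  if (replicates < 100) stop("'replicates' must be at least 100")
  if (!is.null(seed)) set.seed(seed)
  k <- nrow(spec$probs)
  ci <- if (is.numeric(class)) as.integer(class) else
    match(class, spec$strata_labels)
  if (is.na(ci) || ci < 1 || ci > k) stop("unknown class: ", class)
  W <- spec$A_h / sum(spec$A_h)
  true_phi <- sum(W * spec$probs[, ci])

  # vectorised over replicates: one multinomial block per stratum
  p_hat <- v_term <- matrix(0, k, replicates)
  for (h in seq_len(k)) {
    draws <- stats::rmultinom(replicates, spec$n_h[h], spec$probs[h, ])
    ph <- draws[ci, ] / spec$n_h[h]
    p_hat[h, ] <- ph
    v_term[h, ] <- W[h]^2 * ph * (1 - ph) / (spec$n_h[h] - 1)
  }
  phi_hat <- colSums(W * p_hat)
  se_hat <- sqrt(colSums(v_term))
  covered <- abs(phi_hat - true_phi) <= ci_multiplier * se_hat
  list(true_phi = true_phi,
       coverage = mean(covered),
       bias = mean(phi_hat) - true_phi,
       bias_mc_se = stats::sd(phi_hat) / sqrt(replicates),
       mean_phi_hat = mean(phi_hat),
       sd_phi_hat = stats::sd(phi_hat),
       mean_analytic_se = mean(se_hat),
       mean_analytic_var = mean(se_hat^2),
       replicates = replicates)
}

#' Random land-use rate series
#'
#' Gamma-distributed annual rates around stated means, for fuzz-testing the
#' simulator's invariants (non-negativity, linearity, time-shift
#' equivariance). A zero mean yields an exactly zero stream.
#'
#' @param from,to inclusive year range.
#' @param mean_harvest,mean_clearing,mean_afforestation mean rates, ha/yr.
#' @param shape gamma shape (default 4; coefficient of variation 0.5).
#' @param seed optional integer seed.
#' @return A [rate_series()].
#' @export
random_rate_series <- function(from, to, mean_harvest = 0, mean_clearing = 0,
                               mean_afforestation = 0, shape = 4,
                               seed = NULL) {
  if (to < from) stop("inverted year range")
  if (any(c(mean_harvest, mean_clearing, mean_afforestation) < 0) ||
      shape <= 0)
    stop("intensity parameters must be non-negative (shape positive)")
  if (!is.null(seed)) set.seed(seed)
  n <- to - from + 1
  draw <- function(mu) if (mu == 0) numeric(n) else
    stats::rgamma(n, shape = shape, rate = shape / mu)
  rate_series(seq(from, to), draw(mean_harvest), draw(mean_clearing),
              draw(mean_afforestation))
}
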