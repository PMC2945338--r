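#' Stratum area weights
#'
#' Proportional mapped area of each stratum, \eqn{W_h = A_h / A_{tot}}.
#'
#' @param matrix an [error_matrix()].
#' @return Named numeric vector of weights summing to 1.
#' @export
stratum_weights <- function(matrix) {
  stopifnot(inherits(matrix, "error_matrix"))
  matrix$A_h / matrix$A_tot
}

# per-stratum reference proportions p_{h,c} = n[h,c] / n_h
reference_proportions <- function(matrix) {
  sweep(matrix$counts, 1, matrix$n_h, "/")
}

#' Stratified estimate of a class's true area proportion
#'
#' Design-based estimator of the true proportion of the assessed area that
#' belongs to a reference class, \eqn{\phi_c = \sum_h W_h \, p_{h,c}}, where
#' \eqn{p_{h,c} = n_{hc}/n_h} is the proportion of stratum \eqn{h}'s samples
#' whose reference class is \eqn{c} and \eqn{W_h} is the stratum's area
#' weight. Weighting by mapped area rather than sample count corrects for the
#' disproportionate allocation of samples to rare strata (e.g. a small
#' forest-loss class).
#'
#' @param matrix an [error_matrix()].
#' @param class a class label (or index), or \code{NULL} for all classes.
#' @return Proportion(s) in \eqn{[0, 1]}; across all classes they sum to 1.
#' @export
class_proportion <- function(matrix, class = NULL) {
  stopifnot(inherits(matrix, "error_matrix"))
  W <- stratum_weights(matrix)
  phi <- colSums(W * reference_proportions(matrix))
  if (is.null(class)) phi else phi[match_class(matrix, class)]
}

#' Adjusted (error-corrected) class area
#'
#' The area of a reference class after adjustment for map error:
#' \eqn{A_{c,a} = A_{tot} \times \phi_c}. Adjusted areas across all classes
#' sum to the total assessed area.
#'
#' @inheritParams class_proportion
#' @return Adjusted area(s) in hectares.
#' @export
adjusted_area <- function(matrix, class = NULL) {
  matrix$A_tot * class_proportion(matrix, class)
}

#' Variance and standard error of the adjusted proportion and area
#'
#' Stratified-sampling variance of the proportion estimator,
#' \deqn{V(\phi_c) = \sum_h W_h^2 \, \frac{p_{h,c}(1 - p_{h,c})}{n_h - 1},}
#' with \eqn{S(\phi_c) = \sqrt{V(\phi_c)}} and the area-scale standard error
#' \eqn{S(A_{c,a}) = A_{tot} \times S(\phi_c)}.
#'
#' @inheritParams class_proportion
#' @return For a single class, a list with \code{variance_phi},
#'   \code{se_phi} and \code{se_area_ha}; for \code{class = NULL} a data
#'   frame with one row per class.
#' @export
proportion_variance_se <- function(matrix, class = NULL) {
  stopifnot(inherits(matrix, "error_matrix"))
  W <- stratum_weights(matrix)
  p <- reference_proportions(matrix)
  v <- colSums(W^2 * p * (1 - p) / (matrix$n_h - 1))
  out <- data.frame(class = matrix$strata_labels,
                    variance_phi = unname(v),
                    se_phi = unname(sqrt(v)),
                    se_area_ha = unname(matrix$A_tot * sqrt(v)),
                    row.names = NULL)
  if (is.null(class)) return(out)
  i <- match_class(matrix, class)
  list(variance_phi = out$variance_phi[i], se_phi = out$se_phi[i],
       se_area_ha = out$se_area_ha[i])
}

#' Confidence interval for an adjusted class area
#'
#' Interval \eqn{A_{c,a} \pm m \, S(A_{c,a})}; the default multiplier
#' \eqn{m = 2} gives the conventional approximate 95% interval.
#'
#' @inheritParams class_proportion
#' @param multiplier positive half-width multiplier (default 2).
#' @return Numeric vector \code{c(lower_ha, upper_ha)} for one class, or a
#'   two-column matrix for all classes.
#' @export
confidence_interval <- function(matrix, class = NULL, multiplier = 2) {
  if (!is.numeric(multiplier) || length(multiplier) != 1 || multiplier <= 0)
    stop("'multiplier' must be a positive number")
  a <- adjusted_area(matrix, class)
  se <- if (is.null(class)) proportion_variance_se(matrix)$se_area_ha
        else proportion_variance_se(matrix, class)$se_area_ha
  if (is.null(class))
    cbind(lower_ha = a - multiplier * se, upper_ha = a + multiplier * se)
  else
    c(lower_ha = unname(a) - multiplier * se,
      upper_ha = unname(a) + multiplier * se)
}

#' Map accuracy summary
#'
#' Overall, area-weighted, user's and producer's accuracies from a stratified
#' error matrix. Overall accuracy is the fraction of correctly classified
#' samples; the area-weighted version weights each stratum's user's accuracy
#' by its mapped-area proportion instead of its sample share, which is the
#' appropriate summary when sampling is disproportionately stratified.
#'
#' @inheritParams class_proportion
#' @return An object of class \code{"accuracy_summary"}: list with
#'   \code{overall_pct}, \code{area_weighted_pct}, and per-class
#'   \code{users_pct} and \code{producers_pct} (all percentages). A producer's
#'   accuracy is \code{NA} when no assessed sample has that reference class.
#' @export
accuracy_summary <- function(matrix) {
  stopifnot(inherits(matrix, "error_matrix"))
  W <- stratum_weights(matrix)
  diag_n <- diag(matrix$counts)
  users <- diag_n / matrix$n_h
  col_tot <- colSums(matrix$counts)
  producers <- ifelse(col_tot > 0, diag_n / col_tot, NA_real_)
  structure(list(overall_pct = 100 * sum(diag_n) / sum(matrix$n_h),
                 area_weighted_pct = 100 * sum(W * users),
                 users_pct = 100 * users,
                 producers_pct = 100 * producers),
            class = "accuracy_summary")
}

#' @export
print.accuracy_summary <- function(x, digits = 0, ...) {
  cat(sprintf("Overall accuracy:       %s%%\n", round(x$overall_pct, digits)))
  cat(sprintf("Area-weighted accuracy: %s%%\n", round(x$area_weighted_pct, digits)))
  cat("Per class (user's / producer's %):\n")
  tab <- cbind(users = round(x$users_pct, digits),
               producers = round(x$producers_pct, digits))
  print(tab, ...)
  invisible(x)
}

#' Full adjusted-area report
#'
#' One row per class: adjusted proportion, adjusted area, standard error,
#' confidence bounds and class accuracies. Overall and area-weighted
#' accuracies are attached as attributes and shown by the print method.
#' Values are kept at full precision; rounding is a display concern.
#'
#' @inheritParams confidence_interval
#' @param ci_multiplier CI half-width multiplier, see [confidence_interval()].
#' @return A data frame of class \code{"area_report"} with columns
#'   \code{class}, \code{phi}, \code{adjusted_area_ha}, \code{se_area_ha},
#'   \code{ci_lower_ha}, \code{ci_upper_ha}, \code{users_pct},
#'   \code{producers_pct}.
#' @examples
#' path <- system.file("extdata", "georgia_error_matrix.csv", package = "luccarbon")
#' area_report(read_error_matrix(path))
#' @export
area_report <- function(matrix, ci_multiplier = 2) {
  phi <- class_proportion(matrix)
  se <- proportion_variance_se(matrix)
  ci <- confidence_interval(matrix, multiplier = ci_multiplier)
  acc <- accuracy_summary(matrix)
  out <- data.frame(class = matrix$strata_labels,
                    phi = unname(phi),
                    adjusted_area_ha = unname(matrix$A_tot * phi),
                    se_area_ha = se$se_area_ha,
                    ci_lower_ha = unname(ci[, "lower_ha"]),
                    ci_upper_ha = unname(ci[, "upper_ha"]),
                    users_pct = unname(acc$users_pct),
                    producers_pct = unname(acc$producers_pct),
                    row.names = NULL)
  attr(out, "overall_pct") <- acc$overall_pct
  attr(out, "area_weighted_pct") <- acc$area_weighted_pct
  attr(out, "ci_multiplier") <- ci_multiplier
  class(out) <- c("area_report", "data.frame")
  out
}

#' @export
print.area_report <- function(x, ...) {
  cat("Design-based adjusted area estimates\n")
  df <- data.frame(class = x$class,
                   phi = round(x$phi, 4),
                   adjusted_area_ha = round(x$adjusted_area_ha),
                   se_area_ha = round(x$se_area_ha),
                   ci_lower_ha = round(x$ci_lower_ha),
                   ci_upper_ha = round(x$ci_upper_ha),
                   users_pct = round(x$users_pct),
                   producers_pct = round(x$producers_pct))
  print(df, row.names = FALSE, ...)
  cat(sprintf("Overall accuracy %s%%, area-weighted %s%% (CI multiplier %s)\n",
              round(attr(x, "overall_pct")),
              round(attr(x, "area_weighted_pct")),
              attr(x, "ci_multiplier")))
  invisible(x)
}
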