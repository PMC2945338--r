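#' Stratified accuracy-assessment error matrix
#'
#' Container for a confusion (error) matrix from a stratified accuracy
#' assessment of a categorical map, together with the mapped area of each
#' stratum. Rows are map strata, columns are reference classes, in the same
#' order (the matrix is square; map classes excluded from the assessment are
#' simply absent and their mapped area does not enter \code{A_tot}).
#'
#' @param counts square matrix of non-negative integer sample counts;
#'   \code{counts[h, c]} is the number of samples mapped as stratum \code{h}
#'   whose reference class is \code{c}.
#' @param mapped_area_ha numeric vector of mapped area per stratum in
#'   hectares; strictly positive, one entry per row of \code{counts}.
#' @param strata_labels character vector of class names; defaults to the row
#'   names of \code{counts}.
#'
#' @return An object of class \code{"error_matrix"}: a list with elements
#'   \code{counts}, \code{strata_labels}, \code{n_h} (row sums), \code{A_h}
#'   and \code{A_tot} (sum of \code{A_h}).
#'
#' @details Every stratum must contain at least two samples, since the
#'   variance estimator divides by \code{n_h - 1}.
#'
#' @seealso [area_report()], [read_error_matrix()]
#' @examples
#' em <- error_matrix(rbind(c(51, 23, 13), c(0, 416, 15), c(1, 20, 410)),
#'                    mapped_area_ha = c(22044, 2694787, 4071576),
#'                    strata_labels = c("change", "stable_forest", "stable_nonforest"))
#' em
#' @export
error_matrix <- function(counts, mapped_area_ha, strata_labels = rownames(counts)) {
  counts <- as.matrix(counts)
  if (nrow(counts) != ncol(counts))
    stop("'counts' must be square: reference classes must match map strata")
  k <- nrow(counts)
  if (is.null(strata_labels)) strata_labels <- paste0("class_", seq_len(k))
  strata_labels <- as.character(strata_labels)
  if (length(strata_labels) != k || anyDuplicated(strata_labels))
    stop("'strata_labels' must be ", k, " unique class names")
  if (any(!is.finite(counts)) || any(counts < 0) || any(counts != round(counts)))
    stop("'counts' must be non-negative integers")
  storage.mode(counts) <- "double"
  dimnames(counts) <- list(strata_labels, strata_labels)
  mapped_area_ha <- as.numeric(mapped_area_ha)
  if (length(mapped_area_ha) != k)
    stop("'mapped_area_ha' must have one entry per stratum")
  bad <- which(!is.finite(mapped_area_ha) | mapped_area_ha <= 0)
  if (length(bad))
    stop("mapped area must be positive; offending stratum: ",
         paste(strata_labels[bad], collapse = ", "))
  n_h <- rowSums(counts)
  small <- which(n_h < 2)
  if (length(small))
    stop("every stratum needs at least 2 samples; offending stratum: ",
         paste(strata_labels[small], collapse = ", "))
  structure(list(counts = counts,
                 strata_labels = strata_labels,
                 n_h = stats::setNames(n_h, strata_labels),
                 A_h = stats::setNames(mapped_area_ha, strata_labels),
                 A_tot = sum(mapped_area_ha)),
            class = "error_matrix")
}

#' @export
print.error_matrix <- function(x, ...) {
  cat("Stratified accuracy-assessment error matrix\n")
  cat(sprintf("  %d strata, %d samples, %s ha assessed\n\n",
              length(x$strata_labels), sum(x$n_h),
              format(x$A_tot, big.mark = ",")))
  tab <- cbind(x$counts, n_h = x$n_h, A_h = x$A_h)
  print(tab, ...)
  invisible(x)
}

# resolve a class label (or index) against the matrix, with a clear error
match_class <- function(matrix, class) {
  if (is.numeric(class)) {
    if (any(class < 1 | class > length(matrix$strata_labels)))
      stop("class index out of range")
    return(as.integer(class))
  }
  idx <- match(class, matrix$strata_labels)
  if (anyNA(idx))
    stop("unknown class label: ", paste(class[is.na(idx)], collapse = ", "))
  idx
}
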