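#' Read a stratified error matrix from CSV
#'
#' Expected schema: header
#' \code{stratum,ref_<class_1>,...,ref_<class_k>,n,mapped_area_ha}, one row
#' per map stratum, comma-separated, no thousands separators. The
#' \code{ref_} column order defines the reference-class order and must match
#' the stratum rows; the \code{n} column must equal the row sum of counts.
#' All [error_matrix()] invariants are enforced at load.
#'
#' @param path path to the CSV file.
#' @return An [error_matrix()].
#' @examples
#' path <- system.file("extdata", "georgia_error_matrix.csv", package = "luccarbon")
#' read_error_matrix(path)
#' @export
read_error_matrix <- function(path) {
  df <- utils::read.csv(path, check.names = FALSE, strip.white = TRUE)
  if (!all(c("stratum", "n", "mapped_area_ha") %in% names(df)))
    stop("error-matrix CSV needs columns 'stratum', 'n', 'mapped_area_ha'")
  ref_cols <- grep("^ref_", names(df), value = TRUE)
  if (!length(ref_cols)) stop("no 'ref_<class>' count columns found")
  labels <- sub("^ref_", "", ref_cols)
  if (!identical(as.character(df$stratum), labels))
    stop("stratum rows (", paste(df$stratum, collapse = ", "),
         ") must match reference columns (", paste(labels, collapse = ", "), ")")
  counts <- as.matrix(df[ref_cols])
  if (any(counts != round(counts)))
    stop("non-integer count in column ",
         ref_cols[which(colSums(counts != round(counts)) > 0)[1]])
  bad <- which(rowSums(counts) != df$n)
  if (length(bad))
    stop("row sum of counts disagrees with 'n' for stratum: ",
         paste(df$stratum[bad], collapse = ", "))
  error_matrix(counts, df$mapped_area_ha, labels)
}

#' Write an error matrix to CSV
#'
#' Inverse of [read_error_matrix()]; the round trip is the identity.
#'
#' @param matrix an [error_matrix()].
#' @param path output CSV path.
#' @return The path, invisibly.
#' @export
write_error_matrix <- function(matrix, path) {
  stopifnot(inherits(matrix, "error_matrix"))
  df <- data.frame(stratum = matrix$strata_labels,
                   matrix$counts, check.names = FALSE)
  names(df)[-1] <- paste0("ref_", matrix$strata_labels)
  df$n <- unname(matrix$n_h)
  df$mapped_area_ha <- unname(matrix$A_h)
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read / write an annual rate series (CSV)
#'
#' Schema: \code{year,harvest_ha,clearing_ha,afforestation_ha}. Years must
#' be contiguous; gaps are an error naming the missing years.
#'
#' @param path CSV path.
#' @return [read_rate_series()] returns a [rate_series()];
#'   \code{write_rate_series} returns the path invisibly.
#' @export
read_rate_series <- function(path) {
  validate_rate_series(utils::read.csv(path))
}

#' @rdname read_rate_series
#' @param series a [rate_series()].
#' @export
write_rate_series <- function(series, path) {
  series <- validate_rate_series(series)
  utils::write.csv(as.data.frame(series), path, row.names = FALSE,
                   quote = FALSE)
  invisible(path)
}

#' Read / write an annual flux series (CSV)
#'
#' Schema:
#' \code{year,slash_release,product_release,soil_release,soil_uptake,regrowth_uptake,net},
#' Tg C/yr, release positive; numbers are serialised in full precision.
#'
#' @param path CSV path.
#' @return \code{read_flux_series} returns a \code{flux_series} data frame;
#'   \code{write_flux_series} returns the path invisibly.
#' @export
read_flux_series <- function(path) {
  df <- utils::read.csv(path)
  cols <- c("year", "slash_release", "product_release", "soil_release",
            "soil_uptake", "regrowth_uptake", "net")
  if (!all(cols %in% names(df)))
    stop("flux CSV needs columns: ", paste(cols, collapse = ", "))
  df <- df[cols]
  class(df) <- c("flux_series", "data.frame")
  df
}

#' @rdname read_flux_series
#' @param series a \code{flux_series} as returned by [run_simulation()].
#' @export
write_flux_series <- function(series, path) {
  stopifnot(inherits(series, "flux_series"))
  df <- as.data.frame(series)
  # full precision round trip
  for (col in names(df)[-1]) df[[col]] <- format(df[[col]], digits = 17)
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read model coefficients from a flat key-value file
#'
#' Lines of the form \code{key = value} (or \code{key: value}); blank lines
#' and \code{#} comments are ignored. Keys are the snake_case coefficient
#' names of [carbon_coefficients()]; missing keys keep their packaged
#' defaults.
#'
#' @param path path to the text file, or \code{NULL} for all defaults.
#' @return A [carbon_coefficients()] set.
#' @examples
#' path <- system.file("extdata", "default_coefficients.txt", package = "luccarbon")
#' read_coefficients(path)
#' @export
read_coefficients <- function(path = NULL) {
  if (is.null(path)) return(carbon_coefficients())
  lines <- readLines(path, warn = FALSE)
  lines <- sub("#.*$", "", lines)
  lines <- trimws(lines)
  lines <- lines[nzchar(lines)]
  kv <- strsplit(lines, "[=:]")
  bad <- lengths(kv) != 2
  if (any(bad)) stop("malformed coefficient line: ", lines[bad][1])
  keys <- trimws(vapply(kv, `[`, "", 1))
  vals <- suppressWarnings(as.numeric(trimws(vapply(kv, `[`, "", 2))))
  if (anyNA(vals)) stop("non-numeric value for key: ", keys[is.na(vals)][1])
  do.call(carbon_coefficients, as.list(stats::setNames(vals, keys)))
}

#' Write an adjusted-area report and accuracy summary
#'
#' Writes the per-class report as CSV (columns \code{class, phi,
#' adjusted_area_ha, se_area_ha, ci_lower_ha, ci_upper_ha, users_pct,
#' producers_pct}) and, if \code{summary_path} is given, a two-line
#' key-value file with the overall and area-weighted accuracies.
#'
#' @param report an [area_report()].
#' @param path output CSV path.
#' @param summary_path optional path for the accuracy summary.
#' @return \code{path}, invisibly.
#' @export
write_area_report <- function(report, path, summary_path = NULL) {
  stopifnot(inherits(report, "area_report"))
  utils::write.csv(as.data.frame(report), path, row.names = FALSE,
                   quote = FALSE)
  if (!is.null(summary_path))
    writeLines(c(sprintf("overall_pct = %.10g", attr(report, "overall_pct")),
                 sprintf("area_weighted_pct = %.10g",
                         attr(report, "area_weighted_pct"))),
               summary_path)
  invisible(path)
}
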