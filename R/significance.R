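# Data-driven significance thresholds for a CSP profile.
#
# The cutoffs are derived from the profile itself: take the subset of
# residues whose combined difference is below a trim cutoff (default
# 0.1 ppm), compute that subset's mean and standard deviation, and place
# thresholds at mean + k * SD for a ladder of multipliers (default 2.5 and
# 5). Residues are then classified as below / significant / pronounced by
# which thresholds their combined difference reaches. This is an outlier
# heuristic, not a hypothesis test.

CSP_CATEGORIES <- c("below", "significant", "pronounced", "incomplete")

#' Derive significance thresholds from a CSP profile
#'
#' @param profile a [csp_profile], or a bare numeric vector of combined
#'   differences (ppm) for worked examples.
#' @param trim_cutoff subset membership cutoff in ppm (strict `<`; default
#'   0.1).
#' @param k_values increasing SD multipliers defining the threshold ladder
#'   (default `c(2.5, 5)`, i.e. a "significant" and a "pronounced" level).
#' @param sd_type `"sample"` (default) or `"population"` standard deviation.
#' @param iterative if `TRUE`, re-trim against the current lower threshold
#'   until the subset stabilizes instead of the single pass on
#'   `trim_cutoff`. Off by default.
#' @return object of class `threshold_result`: `trim_cutoff`, `k_values`,
#'   `subset_mean`, `subset_sd`, `subset_n`, `thresholds` (ppm,
#'   `subset_mean + k * subset_sd`), and `classification`, a named character
#'   vector residue -> category (empty for bare numeric input without
#'   residue numbers, in which case categories are returned positionally).
#' @details At least 3 combined differences below `trim_cutoff` are
#'   required; otherwise an error suggests a larger cutoff. Category
#'   boundaries are floors: a residue exactly at a threshold belongs to the
#'   higher category.
#' @examples
#' derive_thresholds(c(0.02, 0.04, 0.06, 0.30))
#' @export
derive_thresholds <- function(profile, trim_cutoff = 0.1,
                              k_values = c(2.5, 5),
                              sd_type = c("sample", "population"),
                              iterative = FALSE) {
  sd_type <- match.arg(sd_type)
  stopifnot(is.numeric(trim_cutoff), trim_cutoff > 0,
            is.numeric(k_values), length(k_values) >= 1L,
            !is.unsorted(k_values, strictly = TRUE))
  if (inherits(profile, "csp_profile")) {
    rec <- profile$records
    delta <- rec$delta_combined
    residues <- rec$residue_number
    pair_label <- profile$pair_label
  } else {
    delta <- as.numeric(profile)
    residues <- seq_along(delta)
    pair_label <- NULL
  }
  complete <- !is.na(delta)

  subset_of <- function(cutoff) which(complete & delta < cutoff)
  sel <- subset_of(trim_cutoff)
  if (length(sel) < 3L) {
    stop("only ", length(sel), " combined differences below trim_cutoff = ",
         trim_cutoff, " ppm; increase trim_cutoff")
  }
  repeat {
    m <- mean(delta[sel])
    s <- .sd(delta[sel], sd_type)
    if (!iterative) break
    new_sel <- subset_of(m + k_values[1L] * s)
    if (length(new_sel) < 3L || identical(new_sel, sel)) break
    sel <- new_sel
  }
  thresholds <- m + k_values * s

  res <- structure(
    list(trim_cutoff = trim_cutoff,
         k_values = k_values,
         subset_mean = m,
         subset_sd = s,
         subset_n = length(sel),
         thresholds = thresholds,
         pair_label = pair_label,
         classification = NULL),
    class = "threshold_result"
  )
  res$classification <- classify(profile, res)
  res
}

#' Classify residues against derived thresholds
#'
#' Deterministic category per residue: `"incomplete"` when the combined
#' difference is absent; otherwise `"below"` under the first threshold,
#' `"significant"` from the first threshold (inclusive) up to the last, and
#' `"pronounced"` at or above the last. With more than two `k_values` the
#' intermediate levels all map to `"significant"`.
#'
#' @param profile a [csp_profile] or numeric vector of combined differences.
#' @param thresholds a `threshold_result` (from [derive_thresholds()]), or a
#'   bare increasing numeric vector of threshold levels in ppm.
#' @return named character vector residue_number -> category.
#' @export
classify <- function(profile, thresholds) {
  if (inherits(thresholds, "threshold_result")) {
    levels <- thresholds$thresholds
  } else {
    levels <- as.numeric(thresholds)
  }
  stopifnot(length(levels) >= 1L, !is.unsorted(levels))
  if (inherits(profile, "csp_profile")) {
    delta <- profile$records$delta_combined
    residues <- profile$records$residue_number
  } else {
    delta <- as.numeric(profile)
    residues <- seq_along(delta)
  }
  lo <- levels[1L]
  hi <- levels[length(levels)]
  cat <- ifelse(is.na(delta), "incomplete",
         ifelse(delta >= hi, "pronounced",
         ifelse(delta >= lo, "significant", "below")))
  stats::setNames(cat, residues)
}

#' @export
print.threshold_result <- function(x, ...) {
  cat("<threshold_result>\n")
  if (!is.null(x$pair_label)) {
    cat("  pair:", paste(x$pair_label, collapse = " vs "), "\n")
  }
  cat(sprintf("  trimmed subset (delta < %g ppm): n = %d, mean = %.4f, sd = %.4f ppm\n",
              x$trim_cutoff, x$subset_n, x$subset_mean, x$subset_sd))
  cat(sprintf("  thresholds: %s ppm (k = %s)\n",
              paste(sprintf("%.3f", x$thresholds), collapse = ", "),
              paste(x$k_values, collapse = ", ")))
  tb <- table(factor(x$classification, levels = CSP_CATEGORIES))
  cat("  classification:", paste(sprintf("%s %d", names(tb), tb), collapse = ", "),
      "\n")
  invisible(x)
}

#' Write classification results as CSV
#'
#' Columns `residue_number`, `delta_combined`, `category`, preceded by a
#' `#`-comment metadata block with the cutoff, multipliers, subset mean/SD
#' and thresholds.
#'
#' @param profile the [csp_profile] the thresholds were derived from.
#' @param thresholds a `threshold_result`.
#' @param path output CSV file.
#' @return `path`, invisibly.
#' @export
write_classification_csv <- function(profile, thresholds, path) {
  stopifnot(inherits(profile, "csp_profile"),
            inherits(thresholds, "threshold_result"))
  cls <- classify(profile, thresholds)
  rec <- profile$records
  df <- data.frame(residue_number = rec$residue_number,
                   delta_combined = rec$delta_combined,
                   category = unname(cls[as.character(rec$residue_number)]))
  hdr <- c(
    .provenance_lines(),
    sprintf("# pair: %s", paste(profile$pair_label, collapse = " vs ")),
    sprintf("# trim_cutoff_ppm: %g", thresholds$trim_cutoff),
    sprintf("# k_values: %s", paste(thresholds$k_values, collapse = ",")),
    sprintf("# subset: n=%d mean=%.6f sd=%.6f", thresholds$subset_n,
            thresholds$subset_mean, thresholds$subset_sd),
    sprintf("# thresholds_ppm: %s",
            paste(sprintf("%.6f", thresholds$thresholds), collapse = ","))
  )
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(hdr, con)
  utils::write.csv(df, con, row.names = FALSE, quote = FALSE)
  invisible(path)
}
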