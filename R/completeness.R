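# Assignment-completeness bookkeeping over a residue range and relative
# peak-intensity profiles.

#' Assignment completeness over a residue range
#'
#' Counts residues, prolines and assigned non-proline residues within an
#' inclusive author-numbered range. Prolines are excluded from both the
#' numerator and the denominator, since amide-detected experiments cannot
#' observe them.
#'
#' @param sequence one-letter amino-acid string.
#' @param range_start,range_end inclusive residue-number range; must lie
#'   within the sequence.
#' @param assigned integer vector of assigned residue numbers (e.g. from
#'   [assigned_residues()]); entries outside the range are ignored, prolines
#'   in the set are ignored.
#' @param first_residue author number of `sequence`'s first residue.
#' @return object of class `assignment_stats`: `range_start`, `range_end`,
#'   `n_residues`, `n_proline`, `n_non_proline`, `assigned` (the non-proline
#'   assigned set within range), `unassigned_non_proline`, `n_assigned`.
#' @examples
#' stats <- assignment_stats(h3_sequence(), 44, 132,
#'                           assigned = setdiff(44:132, c(66, 121, 78:81)))
#' stats
#' @export
assignment_stats <- function(sequence, range_start, range_end, assigned,
                             first_residue = 1L) {
  sequence <- toupper(sequence)
  range_start <- as.integer(range_start)
  range_end <- as.integer(range_end)
  first_residue <- as.integer(first_residue)
  stopifnot(range_start <= range_end)
  last_residue <- first_residue + nchar(sequence) - 1L
  if (range_start < first_residue || range_end > last_residue) {
    stop("range ", range_start, "-", range_end,
         " lies outside the sequence (", first_residue, "-", last_residue, ")")
  }
  residues <- range_start:range_end
  types <- substring(sequence,
                     residues - first_residue + 1L,
                     residues - first_residue + 1L)
  prolines <- residues[types == "P"]
  non_proline <- setdiff(residues, prolines)
  assigned <- unique(as.integer(assigned))
  assigned_in <- intersect(assigned, non_proline)
  structure(
    list(range_start = range_start,
         range_end = range_end,
         n_residues = length(residues),
         n_proline = length(prolines),
         n_non_proline = length(non_proline),
         assigned = sort(assigned_in),
         unassigned_non_proline = sort(setdiff(non_proline, assigned_in)),
         n_assigned = length(assigned_in)),
    class = "assignment_stats"
  )
}

#' @export
print.assignment_stats <- function(x, ...) {
  cat(sprintf("<assignment_stats> residues %d-%d\n", x$range_start, x$range_end))
  cat(sprintf("  %d residues, %d proline(s), %d non-proline\n",
              x$n_residues, x$n_proline, x$n_non_proline))
  cat(sprintf("  assigned: %d out of %d non-proline residues\n",
              x$n_assigned, x$n_non_proline))
  if (length(x$unassigned_non_proline)) {
    cat("  unassigned:", paste(x$unassigned_non_proline, collapse = ", "), "\n")
  }
  invisible(x)
}

#' Normalize a peak-intensity table to relative intensities
#'
#' Scales raw intensities so that the maximum is exactly 1 (the
#' normalization anchor); `anchor = "mean"` divides by the mean instead.
#' Input order is preserved.
#'
#' @param raw an `intensity_table` (see [intensity_table()]).
#' @param anchor `"max"` (default) or `"mean"`.
#' @return object of class `intensity_profile`: data.frame `records` with
#'   `residue_number` and `relative_intensity`, plus the condition label.
#' @export
intensity_profile <- function(raw, anchor = c("max", "mean")) {
  stopifnot(inherits(raw, "intensity_table"))
  anchor <- match.arg(anchor)
  i <- raw$intensities
  if (!nrow(i)) stop("empty intensity table")
  denom <- if (anchor == "max") max(i$raw_intensity) else mean(i$raw_intensity)
  structure(
    list(condition_label = raw$condition_label,
         anchor = anchor,
         records = data.frame(residue_number = i$residue_number,
                              relative_intensity = i$raw_intensity / denom)),
    class = "intensity_profile"
  )
}

#' Compare two relative-intensity profiles
#'
#' Root-mean-square deviation and Pearson correlation of relative
#' intensities over the residues shared by both profiles.
#'
#' @param a,b [intensity_profile()]s with at least 3 shared residues.
#' @return list with `shared_n`, `rmsd` and `correlation` (`NA` correlation
#'   when either profile is constant over the shared residues).
#' @export
compare_profiles <- function(a, b) {
  stopifnot(inherits(a, "intensity_profile"), inherits(b, "intensity_profile"))
  shared <- intersect(a$records$residue_number, b$records$residue_number)
  if (length(shared) < 3L) {
    stop("profiles share only ", length(shared),
         " residue(s); need at least 3")
  }
  va <- a$records$relative_intensity[match(shared, a$records$residue_number)]
  vb <- b$records$relative_intensity[match(shared, b$records$residue_number)]
  corr <- if (.sd(va) == 0 || .sd(vb) == 0) NA_real_ else stats::cor(va, vb)
  list(shared_n = length(shared),
       rmsd = sqrt(mean((va - vb)^2)),
       correlation = corr)
}
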