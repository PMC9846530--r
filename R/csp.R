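# Combined chemical-shift differences between two conditions.
#
# For each residue the amide 1H, 15N and 13Calpha shift differences between
# two conditions are merged into a single scalar by a weighted Euclidean
# norm,
#
#     delta = sqrt(dHN^2 + alpha * dN^2 + beta * dCA^2)
#
# with beta = 0.3 and alpha = 0.14 for all residue types except glycine,
# where alpha = 0.2. The weights rescale the 15N and 13C dispersions onto
# the amide-proton scale, following standard CSP practice.

#' Combined-shift weighting scheme
#'
#' @param alpha_default weight on the squared 15N difference for non-glycine
#'   residues (default 0.14).
#' @param alpha_glycine weight on the squared 15N difference for glycines
#'   (default 0.2, reflecting glycine's narrower 15N dispersion).
#' @param beta weight on the squared 13Calpha difference (default 0.3).
#' @return object of class `csp_weights`.
#' @examples
#' csp_weights()
#' @export
csp_weights <- function(alpha_default = 0.14, alpha_glycine = 0.2,
                        beta = 0.3) {
  stopifnot(alpha_default > 0, alpha_glycine > 0, beta > 0)
  structure(list(alpha_default = alpha_default,
                 alpha_glycine = alpha_glycine,
                 beta = beta),
            class = "csp_weights")
}

#' @export
print.csp_weights <- function(x, ...) {
  cat(sprintf("<csp_weights> alpha = %g (%g for Gly), beta = %g\n",
              x$alpha_default, x$alpha_glycine, x$beta))
  invisible(x)
}

#' Combined chemical-shift difference for one residue
#'
#' Computes `sqrt(d_hn^2 + alpha * d_n^2 + beta * d_ca^2)` where `alpha` is
#' the glycine weight when `residue_type == "G"` and the default weight
#' otherwise. Vectorized over all arguments.
#'
#' @param d_hn,d_n,d_ca pairwise shift differences (ppm) in amide 1H, 15N
#'   and 13Calpha.
#' @param residue_type one-letter residue code(s).
#' @param weights a [csp_weights].
#' @return combined difference(s) in ppm, always `>= 0`.
#' @examples
#' combined_delta(0.05, 0.2, 0.1, "A")
#' combined_delta(0, 0.2, 0, "G")  # glycine branch, alpha = 0.2
#' @export
combined_delta <- function(d_hn, d_n, d_ca, residue_type,
                           weights = csp_weights()) {
  stopifnot(inherits(weights, "csp_weights"),
            is.numeric(d_hn), is.numeric(d_n), is.numeric(d_ca))
  if (any(!is.finite(d_hn)) || any(!is.finite(d_n)) || any(!is.finite(d_ca))) {
    stop("shift differences must be finite")
  }
  residue_type <- toupper(residue_type)
  if (!all(residue_type %in% AA_131)) {
    stop("invalid residue type: ",
         residue_type[!(residue_type %in% AA_131)][1L])
  }
  alpha <- ifelse(residue_type == "G", weights$alpha_glycine,
                  weights$alpha_default)
  sqrt(d_hn^2 + alpha * d_n^2 + weights$beta * d_ca^2)
}

#' Per-residue CSP profile between two conditions
#'
#' Builds one record per residue present in either table. Nucleus-wise
#' differences are taken as `a - b` and populated only where the nucleus is
#' assigned in both conditions; the combined difference is computed only
#' when all of H, N and CA are present in both (`complete = TRUE`).
#' Prolines, lacking an amide proton, can never be complete and appear as
#' gaps in the profile.
#'
#' @param a,b [shift_table]s for the two conditions; their sequences must
#'   agree at every shared residue number.
#' @param weights a [csp_weights].
#' @return object of class `csp_profile`: list with `pair_label`, `weights`
#'   and `records`, a data.frame with columns `residue_number`,
#'   `residue_type`, `d_hn`, `d_n`, `d_ca`, `delta_combined`, `complete`,
#'   ordered by residue number.
#' @export
pairwise_profile <- function(a, b, weights = csp_weights()) {
  stopifnot(inherits(a, "shift_table"), inherits(b, "shift_table"))
  .check_sequence_agreement(a, b)
  la <- .shift_lookup(a)
  lb <- .shift_lookup(b)
  residues <- sort(union(unique(a$shifts$residue_number),
                         unique(b$shifts$residue_number)))
  rt <- residue_type_at(a, residues)
  rtb <- residue_type_at(b, residues)
  rt[is.na(rt) | rt == "X"] <- rtb[is.na(rt) | rt == "X"]

  diff_for <- function(nuc) {
    va <- la[paste(residues, nuc)]
    vb <- lb[paste(residues, nuc)]
    unname(va - vb)          # NA where either condition lacks the nucleus
  }
  d_hn <- diff_for("H")
  d_n <- diff_for("N")
  d_ca <- diff_for("CA")
  complete <- !is.na(d_hn) & !is.na(d_n) & !is.na(d_ca)
  delta <- rep(NA_real_, length(residues))
  if (any(complete)) {
    delta[complete] <- combined_delta(d_hn[complete], d_n[complete],
                                      d_ca[complete], rt[complete], weights)
  }
  records <- data.frame(residue_number = residues,
                        residue_type = rt,
                        d_hn = d_hn, d_n = d_n, d_ca = d_ca,
                        delta_combined = delta,
                        complete = complete,
                        stringsAsFactors = FALSE)
  rownames(records) <- NULL
  structure(
    list(pair_label = c(a$condition_label, b$condition_label),
         weights = weights,
         records = records),
    class = "csp_profile"
  )
}

#' @export
print.csp_profile <- function(x, digits = 2, ...) {
  cat("<csp_profile>", paste(x$pair_label, collapse = " vs "), "\n")
  r <- x$records
  cat("  ", nrow(r), " residues, ", sum(r$complete),
      " with combined delta\n", sep = "")
  if (any(r$complete)) {
    m <- mean_combined_delta(x)
    cat(sprintf("  mean combined delta = %.*f +/- %.*f ppm (n = %d)\n",
                digits, m$mean, digits, m$sd, m$n))
  }
  invisible(x)
}

#' Mean absolute shift difference for one nucleus
#'
#' Mean and sample standard deviation (n - 1 denominator; switchable) of
#' `|delta_a - delta_b|` over the residues carrying that nucleus in both
#' conditions.
#'
#' @param a,b [shift_table]s.
#' @param nucleus one of `"H"`, `"N"`, `"CA"`, `"CB"`, `"C"`.
#' @param sd_type `"sample"` (default) or `"population"`.
#' @return list with `mean`, `sd` and `n`; when no residue has the nucleus
#'   in both tables, `n = 0` and `mean`/`sd` are `NA`.
#' @export
mean_abs_nucleus_diff <- function(a, b, nucleus, sd_type = c("sample", "population")) {
  stopifnot(inherits(a, "shift_table"), inherits(b, "shift_table"))
  nucleus <- match.arg(toupper(nucleus), NUCLEI)
  sd_type <- match.arg(sd_type)
  .check_sequence_agreement(a, b)
  la <- .shift_lookup(a)
  lb <- .shift_lookup(b)
  residues <- intersect(a$shifts$residue_number[a$shifts$nucleus == nucleus],
                        b$shifts$residue_number[b$shifts$nucleus == nucleus])
  if (!length(residues)) {
    return(list(mean = NA_real_, sd = NA_real_, n = 0L))
  }
  d <- abs(la[paste(residues, nucleus)] - lb[paste(residues, nucleus)])
  list(mean = mean(d), sd = .sd(d, sd_type), n = length(residues))
}

.sd <- function(x, sd_type = "sample") {
  if (length(x) < 2L) return(0)
  if (sd_type == "population") {
    sqrt(mean((x - mean(x))^2))
  } else {
    stats::sd(x)
  }
}

#' Summary statistics of a CSP profile
#'
#' Mean and sample standard deviation of the combined differences over the
#' complete records of a profile.
#'
#' @param profile a [csp_profile] with at least one complete record.
#' @param sd_type `"sample"` (default) or `"population"`.
#' @return list with `mean`, `sd` and `n`.
#' @export
mean_combined_delta <- function(profile, sd_type = c("sample", "population")) {
  stopifnot(inherits(profile, "csp_profile"))
  sd_type <- match.arg(sd_type)
  d <- profile$records$delta_combined[profile$records$complete]
  if (!length(d)) stop("profile has no complete records")
  list(mean = mean(d), sd = .sd(d, sd_type), n = length(d))
}

#' Write a CSP profile as CSV
#'
#' Columns `residue_number`, `residue_type`, `d_hn`, `d_n`, `d_ca`,
#' `delta_combined`, `complete`, preceded by `#` provenance comment lines
#' recording the package version, the condition pair and the weights.
#'
#' @param profile a [csp_profile].
#' @param path output CSV file.
#' @return `path`, invisibly.
#' @export
write_profile_csv <- function(profile, path) {
  stopifnot(inherits(profile, "csp_profile"))
  w <- profile$weights
  hdr <- c(
    .provenance_lines(),
    sprintf("# pair: %s vs %s", profile$pair_label[1L], profile$pair_label[2L]),
    sprintf("# weights: alpha_default=%g alpha_glycine=%g beta=%g",
            w$alpha_default, w$alpha_glycine, w$beta)
  )
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(hdr, con)
  utils::write.csv(profile$records, con, row.names = FALSE, quote = FALSE)
  invisible(path)
}

.provenance_lines <- function() {
  sprintf("# nmrcsp %s", as.character(utils::packageVersion("nmrcsp")))
}
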