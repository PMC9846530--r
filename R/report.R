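# Run-level drivers: compare a set of conditions end-to-end, or write a
# synthetic condition set with its ground-truth manifest. These functions
# back the command-line wrapper in inst/cli/nmrcsp.R.

# internal: load a condition input (shift_table passthrough or file path)
.load_condition <- function(x, label = NULL) {
  if (inherits(x, "shift_table")) return(x)
  stopifnot(is.character(x), length(x) == 1L)
  if (grepl("\\.(str|star|nmrstar)$", x, ignore.case = TRUE)) {
    read_nmrstar(x, condition_label = label)
  } else {
    read_shift_tsv(x, condition_label = label)
  }
}

#' Run a full pairwise CSP comparison over a set of conditions
#'
#' For every pair of conditions this computes the per-residue combined-shift
#' profile, derives trimmed-subset significance thresholds, classifies
#' residues, and writes per-pair profile and classification CSVs plus a
#' run summary CSV (`summary.csv`: mean +/- SD combined difference and mean
#' +/- SD absolute 13Calpha difference per pair). When a coordinate file and
#' chains are given, a B-factor-mapped PDB is written per pair.
#'
#' @param conditions named list of [shift_table]s or file paths (NMR-STAR
#'   `.str`/`.star` or TSV); at least two.
#' @param out_dir output directory, created if needed.
#' @param weights a [csp_weights].
#' @param trim_cutoff,k_values threshold parameters, see
#'   [derive_thresholds()].
#' @param pdb_in optional coordinate file for B-factor maps.
#' @param chains chain identifiers used with `pdb_in`.
#' @param verbose print per-pair progress to stderr.
#' @return invisibly, a list with `profiles`, `thresholds` (per pair) and
#'   the `summary` data.frame.
#' @export
run_compare <- function(conditions, out_dir, weights = csp_weights(),
                        trim_cutoff = 0.1, k_values = c(2.5, 5),
                        pdb_in = NULL, chains = NULL, verbose = FALSE) {
  stopifnot(length(conditions) >= 2L)
  if (is.null(names(conditions)) || any(!nzchar(names(conditions)))) {
    stop("conditions must be a named list")
  }
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  tables <- Map(.load_condition, conditions, names(conditions))

  pairs <- utils::combn(names(tables), 2L, simplify = FALSE)
  profiles <- list()
  thresholds <- list()
  summary_rows <- list()
  for (p in pairs) {
    key <- paste0(p[1L], "_vs_", p[2L])
    if (verbose) message("comparing ", p[1L], " vs ", p[2L])
    prof <- pairwise_profile(tables[[p[1L]]], tables[[p[2L]]], weights)
    thr <- derive_thresholds(prof, trim_cutoff = trim_cutoff,
                             k_values = k_values)
    write_profile_csv(prof, file.path(out_dir, paste0("profile_", key, ".csv")))
    write_classification_csv(prof, thr,
                             file.path(out_dir, paste0("classification_", key, ".csv")))
    if (!is.null(pdb_in)) {
      if (is.null(chains)) stop("chains must be given with pdb_in")
      write_bfactor_map(prof, pdb_in,
                        file.path(out_dir, paste0("map_", key, ".pdb")),
                        chains = chains)
    }
    m <- mean_combined_delta(prof)
    ca <- mean_abs_nucleus_diff(tables[[p[1L]]], tables[[p[2L]]], "CA")
    summary_rows[[key]] <- data.frame(
      pair = key,
      n_complete = m$n,
      mean_delta = m$mean, sd_delta = m$sd,
      n_ca = ca$n,
      mean_abs_dca = ca$mean, sd_abs_dca = ca$sd,
      threshold_lo = thr$thresholds[1L],
      threshold_hi = thr$thresholds[length(thr$thresholds)],
      stringsAsFactors = FALSE
    )
    profiles[[key]] <- prof
    thresholds[[key]] <- thr
  }
  summary_df <- do.call(rbind, summary_rows)
  rownames(summary_df) <- NULL
  con <- file(file.path(out_dir, "summary.csv"), "w")
  writeLines(c(.provenance_lines(),
               sprintf("# trim_cutoff_ppm: %g", trim_cutoff),
               sprintf("# k_values: %s", paste(k_values, collapse = ","))), con)
  utils::write.csv(format(summary_df, digits = 6, trim = TRUE), con,
                   row.names = FALSE, quote = FALSE)
  close(con)
  invisible(list(profiles = profiles, thresholds = thresholds,
                 summary = summary_df))
}

#' Write a synthetic condition set and its ground-truth manifest
#'
#' Generates the spec's condition set, writes one shift table per condition
#' (TSV by default, NMR-STAR on request) and a `manifest.csv` listing every
#' planted perturbation site with its nucleus offsets and the combined
#' difference it implies, for downstream recovery checks.
#'
#' @param spec a [synthetic_spec].
#' @param out_dir output directory, created if needed.
#' @param format `"tsv"` or `"nmrstar"`.
#' @param weights weights used to report each planted site's implied
#'   combined difference.
#' @return invisibly, a list with the generated `tables` and the `manifest`
#'   data.frame.
#' @export
run_simulate <- function(spec, out_dir, format = c("tsv", "nmrstar"),
                         weights = csp_weights()) {
  stopifnot(inherits(spec, "synthetic_spec"))
  format <- match.arg(format)
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  tables <- generate_condition_set(spec)
  for (label in names(tables)) {
    if (format == "tsv") {
      write_shift_tsv(tables[[label]], file.path(out_dir, paste0(label, ".tsv")))
    } else {
      write_nmrstar(tables[[label]], file.path(out_dir, paste0(label, ".str")))
    }
  }
  rows <- list()
  for (label in names(spec$conditions)) {
    sites <- spec$conditions[[label]]
    for (res in names(sites)) {
      offs <- sites[[res]]
      res_i <- as.integer(res)
      pos <- res_i - spec$first_residue + 1L
      rt <- substring(spec$sequence, pos, pos)
      rows[[paste(label, res)]] <- data.frame(
        condition = label, residue_number = res_i, residue_type = rt,
        d_hn = offs[["H"]], d_n = offs[["N"]], d_ca = offs[["CA"]],
        delta_combined = combined_delta(offs[["H"]], offs[["N"]],
                                        offs[["CA"]], rt, weights),
        stringsAsFactors = FALSE
      )
    }
  }
  manifest <- if (length(rows)) do.call(rbind, rows) else
    data.frame(condition = character(), residue_number = integer(),
               residue_type = character(), d_hn = numeric(), d_n = numeric(),
               d_ca = numeric(), delta_combined = numeric())
  rownames(manifest) <- NULL
  con <- file(file.path(out_dir, "manifest.csv"), "w")
  writeLines(c(.provenance_lines(), sprintf("# seed: %d", spec$seed)), con)
  utils::write.csv(manifest, con, row.names = FALSE, quote = FALSE)
  close(con)
  invisible(list(tables = tables, manifest = manifest))
}

#' Plot a CSP profile as a per-residue bar chart
#'
#' Combined differences against residue number, with optional horizontal
#' threshold lines — the conventional way of presenting a CSP analysis.
#'
#' @param x a [csp_profile].
#' @param thresholds optional `threshold_result` whose levels are drawn as
#'   dashed lines.
#' @param ... further arguments passed to [graphics::barplot()].
#' @return invisibly, the bar midpoints.
#' @export
plot.csp_profile <- function(x, thresholds = NULL, ...) {
  rec <- x$records
  h <- ifelse(rec$complete, rec$delta_combined, 0)
  mids <- graphics::barplot(h, names.arg = rec$residue_number,
                            xlab = "residue number",
                            ylab = expression(Delta * delta ~ "(ppm)"),
                            main = paste(x$pair_label, collapse = " vs "),
                            border = NA, ...)
  if (!is.null(thresholds)) {
    graphics::abline(h = thresholds$thresholds, lty = 2, col = "grey40")
  }
  invisible(mids)
}
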