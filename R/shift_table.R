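# The shift_table S3 class: one experimental condition's assigned backbone
# chemical shifts plus the protein sequence they belong to.

#' Construct a shift table
#'
#' A `shift_table` holds the assigned backbone chemical shifts of one
#' experimental condition: one row per (residue, nucleus) with the shift in
#' ppm, together with the protein sequence (author numbering) and a free-text
#' condition label.
#'
#' @param shifts data.frame with columns `residue_number` (integer),
#'   `residue_type` (one-letter code), `nucleus` (one of `"H"`, `"N"`,
#'   `"CA"`, `"CB"`, `"C"`; `"CO"` is accepted and stored as `"C"`), and
#'   `value` (ppm).
#' @param sequence one-letter amino-acid string, or `NULL` to reconstruct the
#'   covered stretch from the shift rows (positions without a shift become
#'   `"X"`).
#' @param first_residue author number of the first residue of `sequence`.
#' @param condition_label free-text label for the condition (e.g.
#'   `"60bp-linker"`).
#' @return object of class `shift_table` with elements `condition_label`,
#'   `sequence`, `first_residue` and `shifts` (rows sorted by residue then
#'   nucleus).
#' @details Invariants enforced: unique (residue, nucleus) pairs; finite
#'   shift values; residue types consistent with `sequence`; no amide H or N
#'   shifts on prolines.
#' @examples
#' st <- shift_table(
#'   data.frame(residue_number = 45, residue_type = "T",
#'              nucleus = c("H", "N", "CA"), value = c(8.10, 115.2, 62.1)),
#'   condition_label = "demo"
#' )
#' st
#' @export
shift_table <- function(shifts, sequence = NULL, first_residue = 1L,
                        condition_label = "") {
  stopifnot(is.data.frame(shifts))
  required <- c("residue_number", "residue_type", "nucleus", "value")
  missing_cols <- setdiff(required, names(shifts))
  if (length(missing_cols)) {
    stop("shift table is missing column(s): ", paste(missing_cols, collapse = ", "))
  }
  shifts <- shifts[required]
  shifts$residue_number <- as.integer(shifts$residue_number)
  shifts$residue_type <- toupper(as.character(shifts$residue_type))
  shifts$nucleus <- toupper(as.character(shifts$nucleus))
  shifts$nucleus[shifts$nucleus == "CO"] <- "C"
  shifts$value <- as.numeric(shifts$value)

  bad_nuc <- setdiff(unique(shifts$nucleus), NUCLEI)
  if (length(bad_nuc)) {
    stop("unknown nucleus label(s): ", paste(bad_nuc, collapse = ", "))
  }
  bad_type <- setdiff(unique(shifts$residue_type), AA_131)
  if (length(bad_type)) {
    stop("unknown residue type(s): ", paste(bad_type, collapse = ", "))
  }
  if (any(!is.finite(shifts$value))) {
    stop("non-finite chemical shift value(s)")
  }
  key <- paste(shifts$residue_number, shifts$nucleus)
  if (anyDuplicated(key)) {
    dup <- key[duplicated(key)][1L]
    stop("duplicate (residue, nucleus) assignment: ", dup)
  }
  # one residue number, one residue type
  tp <- unique(shifts[c("residue_number", "residue_type")])
  if (anyDuplicated(tp$residue_number)) {
    r <- tp$residue_number[duplicated(tp$residue_number)][1L]
    stop("residue ", r, " listed with conflicting residue types")
  }
  pro <- shifts$residue_type == "P" & shifts$nucleus %in% c("H", "N")
  if (any(pro)) {
    stop("proline residue(s) cannot carry amide H/N shifts: residue ",
         shifts$residue_number[pro][1L])
  }

  if (is.null(sequence)) {
    if (nrow(shifts)) {
      rng <- range(shifts$residue_number)
      first_residue <- rng[1L]
      seq_vec <- rep("X", rng[2L] - rng[1L] + 1L)
      seq_vec[tp$residue_number - first_residue + 1L] <- tp$residue_type
      sequence <- paste(seq_vec, collapse = "")
    } else {
      sequence <- ""
      first_residue <- 1L
    }
  } else {
    sequence <- toupper(sequence)
    first_residue <- as.integer(first_residue)
    pos <- shifts$residue_number - first_residue + 1L
    if (nrow(shifts) && (any(pos < 1L) || any(pos > nchar(sequence)))) {
      stop("shift rows fall outside the provided sequence range")
    }
    seq_types <- substring(sequence, pos, pos)
    bad <- seq_types != "X" & seq_types != shifts$residue_type
    if (any(bad)) {
      stop("residue type mismatch with sequence at residue ",
           shifts$residue_number[bad][1L], " (table ",
           shifts$residue_type[bad][1L], ", sequence ", seq_types[bad][1L], ")")
    }
  }

  shifts <- shifts[order(shifts$residue_number, match(shifts$nucleus, NUCLEI)), ]
  rownames(shifts) <- NULL
  structure(
    list(condition_label = as.character(condition_label),
         sequence = sequence,
         first_residue = as.integer(first_residue),
         shifts = shifts),
    class = "shift_table"
  )
}

#' @export
print.shift_table <- function(x, ...) {
  cat("<shift_table>", if (nzchar(x$condition_label)) x$condition_label else "(unlabelled)", "\n")
  n_res <- length(unique(x$shifts$residue_number))
  cat("  ", nrow(x$shifts), " shifts over ", n_res, " residues",
      if (n_res) paste0(" (", min(x$shifts$residue_number), "-",
                        max(x$shifts$residue_number), ")"),
      "\n", sep = "")
  cat("  nuclei:", paste(intersect(NUCLEI, unique(x$shifts$nucleus)),
                         collapse = " "), "\n")
  invisible(x)
}

#' Residue type at given author residue numbers
#'
#' @param table a [shift_table].
#' @param residue_number integer vector of author residue numbers.
#' @return one-letter codes (`NA` outside the sequence, `"X"` if unknown).
#' @export
residue_type_at <- function(table, residue_number) {
  stopifnot(inherits(table, "shift_table"))
  pos <- residue_number - table$first_residue + 1L
  out <- rep(NA_character_, length(pos))
  ok <- pos >= 1L & pos <= nchar(table$sequence)
  out[ok] <- substring(table$sequence, pos[ok], pos[ok])
  out
}

#' Residues counting as assigned in a shift table
#'
#' A residue counts as assigned when its amide fingerprint is present, i.e.
#' both the H and N shifts (the default, matching amide-detected spectra), or
#' all of H, N and CA when `require = "HNCA"`.
#'
#' @param table a [shift_table].
#' @param require `"HN"` (default) or `"HNCA"`.
#' @return sorted integer vector of residue numbers.
#' @export
assigned_residues <- function(table, require = c("HN", "HNCA")) {
  stopifnot(inherits(table, "shift_table"))
  require <- match.arg(require)
  need <- if (require == "HN") c("H", "N") else c("H", "N", "CA")
  s <- table$shifts[table$shifts$nucleus %in% need, ]
  cnt <- table(s$residue_number)
  sort(as.integer(names(cnt)[cnt == length(need)]))
}

# internal: shifts of one table as a named lookup value[paste(res, nucleus)]
.shift_lookup <- function(table) {
  stats::setNames(table$shifts$value,
                  paste(table$shifts$residue_number, table$shifts$nucleus))
}

# internal: check two tables agree on residue type at shared residue numbers
.check_sequence_agreement <- function(a, b) {
  shared <- intersect(unique(a$shifts$residue_number),
                      unique(b$shifts$residue_number))
  if (!length(shared)) return(invisible(TRUE))
  ta <- residue_type_at(a, shared)
  tb <- residue_type_at(b, shared)
  bad <- !is.na(ta) & !is.na(tb) & ta != "X" & tb != "X" & ta != tb
  if (any(bad)) {
    stop("sequence disagreement between conditions at residue ",
         shared[bad][1L], " (", ta[bad][1L], " vs ", tb[bad][1L], ")")
  }
  invisible(TRUE)
}
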