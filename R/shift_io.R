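# Readers and writers: NMR-STAR v3 assigned-chemical-shift loops, plain TSV
# shift tables, TALOS shift input, FASTA sequences and intensity TSVs.
#
# The NMR-STAR support is deliberately minimal: it targets the single
# backbone assigned-chemical-shift loop of a BMRB deposition and ignores
# everything else (ambiguity codes, errors, isotope labels).

ATOM_TO_NUCLEUS <- c(H = "H", HN = "H", N = "N", CA = "CA", CB = "CB",
                     C = "C", CO = "C")

# internal: tokenize STAR content, honouring quotes and skipping comments
.star_tokens <- function(lines) {
  lines <- sub("^\\s*#.*$", "", lines)
  toks <- regmatches(lines,
                     gregexpr("'[^']*'|\"[^\"]*\"|\\S+", lines))
  toks <- unlist(toks, use.names = FALSE)
  gsub("^['\"]|['\"]$", "", toks)
}

# internal: extract loops as list(tags = chr, rows = chr matrix)
.star_loops <- function(tokens) {
  loops <- list()
  i <- 1L
  n <- length(tokens)
  while (i <= n) {
    if (tokens[i] == "loop_") {
      i <- i + 1L
      tags <- character()
      while (i <= n && startsWith(tokens[i], "_")) {
        tags <- c(tags, tokens[i])
        i <- i + 1L
      }
      vals <- character()
      while (i <= n && !(tokens[i] %in% c("stop_", "loop_", "save_"))) {
        vals <- c(vals, tokens[i])
        i <- i + 1L
      }
      if (length(tags) && length(vals) %% length(tags) == 0L) {
        loops[[length(loops) + 1L]] <- list(
          tags = tags,
          rows = matrix(vals, ncol = length(tags), byrow = TRUE)
        )
      }
    }
    i <- i + 1L
  }
  loops
}

#' Read a shift table from an NMR-STAR v3 file
#'
#' Parses the assigned-chemical-shift loop (`_Atom_chem_shift.*` tags) of an
#' NMR-STAR v3 file, as deposited at the BMRB, into a [shift_table]. Author
#' residue numbering is used (`Auth_seq_ID` when present, otherwise
#' `Seq_ID`/`Comp_index_ID`). Backbone atoms H/HN, N, CA, CB and C/CO are
#' kept; all other atoms are ignored.
#'
#' @param path NMR-STAR file.
#' @param entity_selector optional entity ID used to pick one entity when the
#'   loop covers several; an error is raised if several entities are present
#'   and no selector is given.
#' @param condition_label label for the returned table; defaults to the
#'   file's `data_` block name (or the file name).
#' @param reference_offset optional named numeric vector of per-nucleus
#'   re-referencing offsets in ppm (names among `"H"`, `"N"`, `"CA"`,
#'   `"CB"`, `"C"`) added to the values on read. Default: no offset.
#' @return a [shift_table].
#' @seealso [write_nmrstar()], [read_shift_tsv()]
#' @export
read_nmrstar <- function(path, entity_selector = NULL, condition_label = NULL,
                         reference_offset = NULL) {
  lines <- readLines(path, warn = FALSE)
  tokens <- .star_tokens(lines)
  if (is.null(condition_label)) {
    dat <- grep("^data_", tokens, value = TRUE)
    condition_label <- if (length(dat)) sub("^data_", "", dat[1L]) else
      basename(path)
  }
  loops <- .star_loops(tokens)
  shift_loops <- Filter(function(l) any(startsWith(l$tags, "_Atom_chem_shift.")),
                        loops)
  if (!length(shift_loops)) {
    stop("no assigned-chemical-shift loop (_Atom_chem_shift) found in ", path)
  }
  if (length(shift_loops) > 1L && is.null(entity_selector)) {
    stop("multiple assigned-chemical-shift loops in ", path,
         "; supply entity_selector")
  }
  l <- shift_loops[[1L]]
  col <- function(tag) {
    j <- match(paste0("_Atom_chem_shift.", tag), l$tags)
    if (is.na(j)) NULL else l$rows[, j]
  }
  seq_id <- col("Auth_seq_ID")
  if (is.null(seq_id) || all(seq_id == ".")) seq_id <- col("Seq_ID")
  if (is.null(seq_id)) seq_id <- col("Comp_index_ID")
  if (is.null(seq_id)) stop("shift loop has no residue-number column")
  comp <- col("Comp_ID")
  atom <- col("Atom_ID")
  val <- col("Val")
  if (is.null(comp) || is.null(atom) || is.null(val)) {
    stop("shift loop lacks Comp_ID/Atom_ID/Val columns")
  }
  entity <- col("Entity_ID")
  keep <- rep(TRUE, nrow(l$rows))
  if (!is.null(entity)) {
    ids <- unique(entity[entity != "."])
    if (length(ids) > 1L) {
      if (is.null(entity_selector)) {
        stop("shift loop covers entities ", paste(ids, collapse = ", "),
             "; supply entity_selector")
      }
      keep <- entity == as.character(entity_selector)
      if (!any(keep)) stop("entity_selector ", entity_selector, " matches no rows")
    }
  }
  nuc <- unname(ATOM_TO_NUCLEUS[toupper(atom)])
  keep <- keep & !is.na(nuc) & val != "."
  res_type <- toupper(comp[keep])
  one <- ifelse(nchar(res_type) == 3L, aa_three_to_one(res_type), res_type)
  if (anyNA(one)) {
    stop("unknown residue type in shift loop: ",
         res_type[is.na(one)][1L])
  }
  values <- suppressWarnings(as.numeric(val[keep]))
  if (anyNA(values)) stop("non-numeric shift value in ", path)
  df <- data.frame(residue_number = as.integer(seq_id[keep]),
                   residue_type = one,
                   nucleus = nuc[keep],
                   value = values,
                   stringsAsFactors = FALSE)
  df <- .apply_reference_offset(df, reference_offset)
  shift_table(df, condition_label = condition_label)
}

.apply_reference_offset <- function(df, reference_offset) {
  if (is.null(reference_offset)) return(df)
  stopifnot(is.numeric(reference_offset), !is.null(names(reference_offset)))
  bad <- setdiff(names(reference_offset), NUCLEI)
  if (length(bad)) stop("reference_offset names must be nuclei, not: ",
                        paste(bad, collapse = ", "))
  for (nuc in names(reference_offset)) {
    sel <- df$nucleus == nuc
    df$value[sel] <- df$value[sel] + reference_offset[[nuc]]
  }
  df
}

#' Write a shift table as a minimal NMR-STAR v3 file
#'
#' Emits a single `data_` block with one assigned-chemical-shift loop that
#' [read_nmrstar()] reads back identically. Shift values are written with
#' three decimal places.
#'
#' @param table a [shift_table].
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_nmrstar <- function(table, path) {
  stopifnot(inherits(table, "shift_table"))
  label <- gsub("[^A-Za-z0-9_]", "_", table$condition_label)
  if (!nzchar(label)) label <- "shifts"
  s <- table$shifts
  hdr <- c(
    paste0("data_", label),
    "",
    "save_assigned_chemical_shifts",
    "   _Assigned_chem_shift_list.Sf_category   assigned_chemical_shifts",
    "   _Assigned_chem_shift_list.ID            1",
    "",
    "   loop_",
    "      _Atom_chem_shift.ID",
    "      _Atom_chem_shift.Entity_ID",
    "      _Atom_chem_shift.Comp_index_ID",
    "      _Atom_chem_shift.Auth_seq_ID",
    "      _Atom_chem_shift.Comp_ID",
    "      _Atom_chem_shift.Atom_ID",
    "      _Atom_chem_shift.Val",
    ""
  )
  rows <- if (nrow(s)) {
    sprintf("      %d 1 %d %d %s %s %.3f",
            seq_len(nrow(s)), s$residue_number, s$residue_number,
            aa_one_to_three(s$residue_type), s$nucleus, s$value)
  } else character()
  writeLines(c(hdr, rows, "", "   stop_", "", "save_"), path)
  invisible(path)
}

#' Read a shift table from TSV
#'
#' Expects a header with columns `residue_number`, `residue_type` (one- or
#' three-letter), `nucleus` (`H`, `N`, `CA`, `CB`, `C`/`CO`) and
#' `shift_ppm`. Lines starting with `#` are ignored.
#'
#' @inheritParams read_nmrstar
#' @param path TSV file.
#' @return a [shift_table].
#' @export
read_shift_tsv <- function(path, condition_label = NULL,
                           reference_offset = NULL) {
  df <- utils::read.delim(path, comment.char = "#", stringsAsFactors = FALSE,
                          colClasses = "character")
  required <- c("residue_number", "residue_type", "nucleus", "shift_ppm")
  missing_cols <- setdiff(required, names(df))
  if (length(missing_cols)) {
    stop("shift TSV is missing column(s): ", paste(missing_cols, collapse = ", "))
  }
  value <- suppressWarnings(as.numeric(df$shift_ppm))
  if (anyNA(value)) {
    stop("non-numeric shift_ppm value: ", df$shift_ppm[is.na(value)][1L])
  }
  rt <- toupper(df$residue_type)
  rt <- ifelse(nchar(rt) == 3L, aa_three_to_one(rt), rt)
  out <- data.frame(residue_number = as.integer(df$residue_number),
                    residue_type = rt,
                    nucleus = df$nucleus,
                    value = value,
                    stringsAsFactors = FALSE)
  out <- .apply_reference_offset(out, reference_offset)
  if (is.null(condition_label)) {
    condition_label <- sub("\\.[^.]*$", "", basename(path))
  }
  shift_table(out, condition_label = condition_label)
}

#' Write a shift table as TSV
#'
#' Columns `residue_number`, `residue_type`, `nucleus`, `shift_ppm`; values
#' at three decimal places so round-trips are exact at that precision.
#'
#' @param table a [shift_table].
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_shift_tsv <- function(table, path) {
  stopifnot(inherits(table, "shift_table"))
  s <- table$shifts
  lines <- c("residue_number\tresidue_type\tnucleus\tshift_ppm",
             sprintf("%d\t%s\t%s\t%.3f",
                     s$residue_number, s$residue_type, s$nucleus, s$value))
  writeLines(lines, path)
  invisible(path)
}

#' Export a shift table in TALOS input format
#'
#' Writes the standard TALOS chemical-shift input dialect (`DATA
#' FIRST_RESID`, `DATA SEQUENCE`, `VARS`/`FORMAT` header, one row per
#' residue-nucleus) so the assigned shifts can be fed to torsion-angle /
#' secondary-structure prediction. Amide protons are written with atom name
#' `HN`; prolines therefore produce no `HN` row.
#'
#' @param table a [shift_table].
#' @param path output file.
#' @return number of data rows written, invisibly.
#' @export
export_talos_input <- function(table, path) {
  stopifnot(inherits(table, "shift_table"))
  s <- table$shifts
  atom <- ifelse(s$nucleus == "H", "HN", s$nucleus)
  seq_chunks <- substring(table$sequence,
                          seq(1L, max(nchar(table$sequence), 1L), 10L),
                          pmin(seq(10L, max(nchar(table$sequence), 1L) + 9L, 10L),
                               nchar(table$sequence)))
  seq_chunks <- seq_chunks[nzchar(seq_chunks)]
  lines <- c(
    sprintf("DATA FIRST_RESID %d", table$first_residue),
    paste("DATA SEQUENCE", paste(seq_chunks, collapse = " ")),
    "",
    "VARS   RESID RESNAME ATOMNAME SHIFT",
    "FORMAT %4d   %1s     %4s      %8.3f",
    "",
    sprintf("%4d %1s %4s %8.3f", s$residue_number, s$residue_type, atom, s$value)
  )
  writeLines(lines, path)
  invisible(nrow(s))
}

#' Read a single protein sequence from FASTA
#'
#' @param path FASTA file; the first record is used.
#' @param first_residue author number of the first residue (default 1).
#' @return list with `sequence` (one-letter string), `first_residue` and
#'   `name` (FASTA header).
#' @export
read_fasta_sequence <- function(path, first_residue = 1L) {
  fa <- seqinr::read.fasta(path, seqtype = "AA", as.string = TRUE,
                           set.attributes = FALSE)
  if (!length(fa)) stop("no sequences in ", path)
  list(sequence = toupper(as.character(fa[[1L]])),
       first_residue = as.integer(first_residue),
       name = names(fa)[1L])
}

#' Read and write per-residue peak-intensity TSVs
#'
#' The TSV has a header with columns `residue_number` and `intensity`
#' (arbitrary positive units). `read_intensity_tsv()` returns an
#' `intensity_table`; see [intensity_profile()] for normalization.
#'
#' @param path TSV file.
#' @param condition_label label for the returned table.
#' @return `read_intensity_tsv()`: an `intensity_table` (list with
#'   `condition_label` and data.frame `intensities`);
#'   `write_intensity_tsv()`: `path`, invisibly.
#' @export
read_intensity_tsv <- function(path, condition_label = NULL) {
  df <- utils::read.delim(path, comment.char = "#", stringsAsFactors = FALSE)
  required <- c("residue_number", "intensity")
  missing_cols <- setdiff(required, names(df))
  if (length(missing_cols)) {
    stop("intensity TSV is missing column(s): ",
         paste(missing_cols, collapse = ", "))
  }
  if (is.null(condition_label)) {
    condition_label <- sub("\\.[^.]*$", "", basename(path))
  }
  intensity_table(df$residue_number, df$intensity, condition_label)
}

#' @rdname read_intensity_tsv
#' @param table an `intensity_table`.
#' @export
write_intensity_tsv <- function(table, path) {
  stopifnot(inherits(table, "intensity_table"))
  i <- table$intensities
  lines <- c("residue_number\tintensity",
             sprintf("%d\t%.6g", i$residue_number, i$raw_intensity))
  writeLines(lines, path)
  invisible(path)
}

#' Construct a per-residue intensity table
#'
#' @param residue_number integer vector, unique.
#' @param raw_intensity positive intensities (arbitrary units).
#' @param condition_label free-text label.
#' @return object of class `intensity_table`.
#' @export
intensity_table <- function(residue_number, raw_intensity,
                            condition_label = "") {
  residue_number <- as.integer(residue_number)
  raw_intensity <- as.numeric(raw_intensity)
  stopifnot(length(residue_number) == length(raw_intensity))
  if (anyDuplicated(residue_number)) {
    stop("duplicate residue_number in intensity table")
  }
  if (any(!is.finite(raw_intensity)) || any(raw_intensity <= 0)) {
    stop("intensities must be finite and positive")
  }
  structure(
    list(condition_label = as.character(condition_label),
         intensities = data.frame(residue_number = residue_number,
                                  raw_intensity = raw_intensity)),
    class = "intensity_table"
  )
}
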