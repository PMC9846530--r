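# Projection of per-residue values onto a coordinate file via the B-factor
# column, for coloring structures by chemical-shift perturbation.
#
# Only the temperature-factor field (columns 61-66) of ATOM/HETATM records
# on the selected chains is rewritten; every other byte of the file is
# preserved, so the output stays diff-able against the input.

#' Default category -> numeric code table for structure mapping
#'
#' `incomplete` 0, `below` 1, `significant` 2, `pronounced` 3.
#' @return named numeric vector.
#' @export
category_codes <- function() {
  c(incomplete = 0, below = 1, significant = 2, pronounced = 3)
}

#' Per-residue values from a profile or classification for B-factor mapping
#'
#' @param x a [csp_profile] (uses `delta_combined`), a `threshold_result`
#'   (uses its classification), or a named character vector of categories.
#' @param codes category -> code table, for categorical input.
#' @return named numeric vector residue_number -> value; incomplete
#'   combined differences are dropped (they take the map's fill value).
#' @export
bfactor_values <- function(x, codes = category_codes()) {
  if (inherits(x, "csp_profile")) {
    rec <- x$records[x$records$complete, ]
    return(stats::setNames(rec$delta_combined, rec$residue_number))
  }
  if (inherits(x, "threshold_result")) x <- x$classification
  if (is.character(x) && !is.null(names(x))) {
    if (length(unique(codes)) != length(codes)) {
      stop("category codes must be distinct")
    }
    bad <- setdiff(unique(x), names(codes))
    if (length(bad)) stop("unknown category: ", bad[1L])
    return(stats::setNames(unname(codes[x]), names(x)))
  }
  stop("cannot derive per-residue values from ", class(x)[1L])
}

#' Write per-residue values into a PDB file's B-factor column
#'
#' Every atom of a residue matched by author residue number on the selected
#' chains receives the residue's value in the temperature-factor field
#' (fixed columns 61-66, two decimals); residues on those chains without a
#' value receive `fill`. Atom records on other chains, and all non-ATOM
#' lines, are passed through byte-identically. Mapping the same profile onto
#' several chains (e.g. the two H3 copies in the histone octamer) gives each
#' chain the same per-residue values.
#'
#' @param x a [csp_profile], `threshold_result`, named character category
#'   vector, or named numeric vector (names = author residue numbers).
#' @param pdb_in input PDB file (fixed-column ATOM/HETATM records).
#' @param pdb_out output PDB file.
#' @param chains chain identifiers to map onto (e.g. `c("A", "E")`).
#' @param fill B-factor for unmatched residues on the selected chains
#'   (default 0).
#' @param codes category -> code table used for categorical `x`.
#' @return list with `n_mapped` (profile residues found on at least one
#'   selected chain) and `n_unmatched` (profile residues absent from all
#'   selected chains), invisibly.
#' @details Values outside the representable fixed-column range
#'   (-99.99 to 999.99) are clipped with a warning. Insertion codes are not
#'   supported.
#' @export
write_bfactor_map <- function(x, pdb_in, pdb_out, chains, fill = 0,
                              codes = category_codes()) {
  values <- if (is.numeric(x) && !is.null(names(x))) x else
    bfactor_values(x, codes)
  if (!length(values)) stop("no per-residue values to map")
  stopifnot(length(chains) >= 1L)

  lines <- readLines(pdb_in, warn = FALSE)
  is_atom <- grepl("^(ATOM  |HETATM)", lines)
  if (!any(is_atom)) stop("no ATOM/HETATM records in ", pdb_in)
  if (any(nchar(lines[is_atom]) < 66L)) {
    stop("malformed coordinate record (shorter than 66 columns) in ", pdb_in)
  }
  chain_id <- substring(lines, 22L, 22L)
  resno <- suppressWarnings(as.integer(substring(lines, 23L, 26L)))
  sel <- is_atom & chain_id %in% chains
  if (!any(sel)) stop("no atoms on chain(s) ", paste(chains, collapse = ", "))

  clip <- pmin(pmax(values, -99.99), 999.99)
  if (any(clip != values)) {
    warning("B-factor value(s) clipped to the representable range")
  }
  b <- clip[as.character(resno)]
  b[is.na(b)] <- fill
  new_field <- sprintf("%6.2f", b[sel])
  lines[sel] <- paste0(substring(lines[sel], 1L, 60L), new_field,
                       substring(lines[sel], 67L))
  writeLines(lines, pdb_out)

  present <- unique(resno[sel])
  mapped <- as.integer(names(values)) %in% present
  invisible(list(n_mapped = sum(mapped), n_unmatched = sum(!mapped)))
}
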