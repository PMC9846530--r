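# Fixture builders shared across the suite; everything is generated in code.

# small shift table: residues with H/N/CA (+ optional CB/C) around fixed values
toy_table <- function(residues = 45:47, types = c("T", "V", "A"),
                      label = "toy", jitter = 0) {
  rows <- do.call(rbind, lapply(seq_along(residues), function(i) {
    data.frame(residue_number = residues[i], residue_type = types[i],
               nucleus = c("H", "N", "CA"),
               value = c(8.1, 115.2, 62.1) + (i - 1) * 0.5 + jitter,
               stringsAsFactors = FALSE)
  }))
  shift_table(rows, condition_label = label)
}

# independently coded direct evaluation of the combined shift difference
direct_combined <- function(d_hn, d_n, d_ca, residue_type) {
  alpha <- if (residue_type == "G") 0.2 else 0.14
  sqrt(sum(c(d_hn^2, alpha * d_n^2, 0.3 * d_ca^2)))
}

# fixed-column PDB with n_res residues (2 atoms each) on each given chain
write_tiny_pdb <- function(path, chains = c("A", "B"), residues = 45:47,
                           bfac = 11.11) {
  lines <- character()
  serial <- 0L
  for (ch in chains) {
    for (r in residues) {
      for (atom in c("N", "CA")) {
        serial <- serial + 1L
        lines <- c(lines, sprintf(
          "ATOM  %5d %-4s %3s %1s%4d    %8.3f%8.3f%8.3f%6.2f%6.2f          %2s",
          serial, paste0(" ", atom), "ALA", ch, r,
          1.0 * serial, 2.0, 3.0, 1.00, bfac,
          substring(atom, 1, 1)))
      }
    }
  }
  writeLines(c(lines, "END"), path)
  invisible(path)
}

# two-condition synthetic spec with perturbations planted in one condition
planted_spec <- function(seed, sites, offsets = c(H = 0.1, N = 0.25, CA = 0.15)) {
  synthetic_spec(
    conditions = list(ref = list(),
                      pert = stats::setNames(rep(list(offsets), length(sites)),
                                             sites)),
    seed = seed
  )
}
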