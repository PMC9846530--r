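random_table <- function(seed, label = "rt") {
  set.seed(seed)
  base <- baseline_shifts(h3_sequence(), list(c(44, 56)),
                          condition_label = label)
  s <- base$shifts
  s$value <- round(s$value + rnorm(nrow(s), 0, 0.2), 3)
  shift_table(s, sequence = h3_sequence(), condition_label = label)
}

test_that("NMR-STAR write/read round-trips shift tables", {
  for (seed in 1:3) {
    tab <- random_table(seed)
    path <- withr::local_tempfile(fileext = ".str")
    write_nmrstar(tab, path)
    back <- read_nmrstar(path)
    expect_equal(back$shifts, tab$shifts, tolerance = 1e-9)
    expect_equal(back$condition_label, tab$condition_label)
  }
})

test_that("NMR-STAR reader handles a minimal hand-written loop", {
  path <- withr::local_tempfile(fileext = ".str")
  writeLines(c(
    "data_demo",
    "loop_",
    "  _Atom_chem_shift.ID",
    "  _Atom_chem_shift.Seq_ID",
    "  _Atom_chem_shift.Comp_ID",
    "  _Atom_chem_shift.Atom_ID",
    "  _Atom_chem_shift.Val",
    "  1 45 THR H  8.10",
    "  2 45 THR N  115.2",
    "  3 45 THR CA 62.1",
    "  4 45 THR HB 4.2",    # side-chain atom: ignored
    "stop_"), path)
  tab <- read_nmrstar(path)
  expect_equal(nrow(tab$shifts), 3L)
  expect_equal(residue_type_at(tab, 45), "T")
  expect_equal(tab$shifts$value[tab$shifts$nucleus == "H"], 8.10)
})

test_that("NMR-STAR reader rejects malformed and ambiguous input", {
  no_loop <- withr::local_tempfile(fileext = ".str")
  writeLines(c("data_x", "loop_", "  _Other.Tag", "  1", "stop_"), no_loop)
  expect_error(read_nmrstar(no_loop), "no assigned-chemical-shift loop")

  conflict <- withr::local_tempfile(fileext = ".str")
  writeLines(c(
    "data_x", "loop_",
    "  _Atom_chem_shift.Seq_ID", "  _Atom_chem_shift.Comp_ID",
    "  _Atom_chem_shift.Atom_ID", "  _Atom_chem_shift.Val",
    "  50 ALA CA 52.1",
    "  50 GLY CB 30.0",
    "stop_"), conflict)
  expect_error(read_nmrstar(conflict), "conflicting residue types")

  two_entities <- withr::local_tempfile(fileext = ".str")
  writeLines(c(
    "data_x", "loop_",
    "  _Atom_chem_shift.Entity_ID", "  _Atom_chem_shift.Seq_ID",
    "  _Atom_chem_shift.Comp_ID", "  _Atom_chem_shift.Atom_ID",
    "  _Atom_chem_shift.Val",
    "  1 45 THR CA 62.1",
    "  2 45 ALA CA 52.0",
    "stop_"), two_entities)
  expect_error(read_nmrstar(two_entities), "entity_selector")
  tab <- read_nmrstar(two_entities, entity_selector = 2)
  expect_equal(residue_type_at(tab, 45), "A")
})

test_that("TSV write/read round-trips and validates", {
  tab <- random_table(4)
  path <- withr::local_tempfile(fileext = ".tsv")
  write_shift_tsv(tab, path)
  back <- read_shift_tsv(path, condition_label = tab$condition_label)
  expect_equal(back$shifts, tab$shifts, tolerance = 1e-9)

  one <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c("residue_number\tresidue_type\tnucleus\tshift_ppm",
               "61\tL\tH\t9.5"), one)
  t1 <- read_shift_tsv(one)
  expect_equal(t1$shifts$value, 9.5)
  expect_equal(t1$shifts$nucleus, "H")

  dup <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c("residue_number\tresidue_type\tnucleus\tshift_ppm",
               "61\tL\tH\t9.5", "61\tL\tH\t9.6"), dup)
  expect_error(read_shift_tsv(dup), "duplicate")

  badnuc <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c("residue_number\tresidue_type\tnucleus\tshift_ppm",
               "61\tL\tHQ\t9.5"), badnuc)
  expect_error(read_shift_tsv(badnuc), "unknown nucleus")

  nonnum <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c("residue_number\tresidue_type\tnucleus\tshift_ppm",
               "61\tL\tH\tabc"), nonnum)
  expect_error(read_shift_tsv(nonnum), "non-numeric")
})

test_that("CO labels and re-referencing offsets are honoured on read", {
  path <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c("residue_number\tresidue_type\tnucleus\tshift_ppm",
               "45\tT\tCO\t174.7", "45\tT\tCA\t62.1"), path)
  tab <- read_shift_tsv(path, reference_offset = c(CA = 0.5))
  expect_setequal(tab$shifts$nucleus, c("C", "CA"))
  expect_equal(tab$shifts$value[tab$shifts$nucleus == "CA"], 62.6)
  expect_equal(tab$shifts$value[tab$shifts$nucleus == "C"], 174.7)
})

test_that("empty shift tables round-trip through NMR-STAR", {
  empty <- shift_table(data.frame(residue_number = integer(),
                                  residue_type = character(),
                                  nucleus = character(), value = numeric()),
                       condition_label = "empty")
  path <- withr::local_tempfile(fileext = ".str")
  write_nmrstar(empty, path)
  back <- read_nmrstar(path)
  expect_equal(nrow(back$shifts), 0L)
})

test_that("TALOS export writes one row per shift and skips proline HN", {
  df <- rbind(
    data.frame(residue_number = 65, residue_type = "L",
               nucleus = c("H", "N", "CA", "CB", "C"),
               value = c(8.2, 121.9, 55.1, 42.4, 177.6)),
    data.frame(residue_number = 66, residue_type = "P",
               nucleus = c("CA", "CB", "C"), value = c(63.3, 32.1, 177.3))
  )
  tab <- shift_table(df, condition_label = "talos")
  path <- withr::local_tempfile(fileext = ".tab")
  n <- export_talos_input(tab, path)
  expect_equal(n, nrow(df))
  lines <- readLines(path)
  data_rows <- grep("^\\s*\\d", lines, value = TRUE)
  expect_length(data_rows, nrow(df))
  expect_true(any(grepl("^DATA FIRST_RESID 65", lines)))
  expect_true(any(grepl("^DATA SEQUENCE", lines)))
  expect_true(any(grepl("\\bHN\\b", data_rows)))   # H written as HN
  expect_false(any(grepl("^\\s*66\\s+P\\s+HN", data_rows)))

  full <- random_table(5)
  full_path <- withr::local_tempfile(fileext = ".tab")
  expect_equal(export_talos_input(full, full_path), nrow(full$shifts))
})

test_that("FASTA sequences are read through seqinr", {
  path <- withr::local_tempfile(fileext = ".fasta")
  writeLines(c(">histone_h3", substring(h3_sequence(), 1, 60),
               substring(h3_sequence(), 61)), path)
  fa <- read_fasta_sequence(path)
  expect_equal(fa$sequence, h3_sequence())
  expect_equal(fa$name, "histone_h3")
})

test_that("intensity TSVs round-trip and validate positivity", {
  tab <- intensity_table(c(45L, 46L, 47L), c(10, 5, 2), "int")
  path <- withr::local_tempfile(fileext = ".tsv")
  write_intensity_tsv(tab, path)
  back <- read_intensity_tsv(path, condition_label = "int")
  expect_equal(back$intensities, tab$intensities)
  expect_error(intensity_table(1:2, c(1, -2)), "positive")
  expect_error(intensity_table(c(1, 1), c(1, 2)), "duplicate")
})
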