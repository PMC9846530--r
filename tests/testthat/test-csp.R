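test_that("combined_delta reproduces hand-computed cases", {
  expect_equal(combined_delta(0, 0, 0, "A"), 0)
  expect_equal(combined_delta(0.1, 0, 0, "A"), 0.1)
  expect_equal(combined_delta(0.05, 0.2, 0.1, "A"),
               sqrt(0.0025 + 0.14 * 0.04 + 0.3 * 0.01))
  # glycine branch vs default branch on identical input
  expect_equal(combined_delta(0, 0.2, 0, "G"), sqrt(0.2 * 0.04))
  expect_equal(combined_delta(0, 0.2, 0, "A"), sqrt(0.14 * 0.04))
})

test_that("combined_delta matches an independent direct evaluation", {
  set.seed(42)
  for (i in 1:1000) {
    d <- rnorm(3, 0, 0.3)
    rt <- sample(c("A", "G", "T", "L", "K"), 1)
    expect_equal(combined_delta(d[1], d[2], d[3], rt),
                 direct_combined(d[1], d[2], d[3], rt),
                 tolerance = 1e-12)
  }
})

test_that("combined_delta is sign-invariant, monotone and scale-equivariant", {
  set.seed(7)
  for (i in 1:50) {
    d <- rnorm(3, 0, 0.2)
    rt <- sample(c("A", "G"), 1)
    base <- combined_delta(d[1], d[2], d[3], rt)
    signs <- expand.grid(s1 = c(-1, 1), s2 = c(-1, 1), s3 = c(-1, 1))
    for (j in seq_len(nrow(signs))) {
      expect_equal(combined_delta(signs$s1[j] * d[1], signs$s2[j] * d[2],
                                  signs$s3[j] * d[3], rt), base)
    }
    # increasing |d_n| or |d_ca| never decreases the result
    expect_gte(combined_delta(d[1], d[2] * 2, d[3], rt), base)
    expect_gte(combined_delta(d[1], d[2], d[3] * 2, rt), base)
    # positive scaling is equivariant
    expect_equal(combined_delta(3 * d[1], 3 * d[2], 3 * d[3], rt), 3 * base)
  }
})

test_that("weights validate and non-default weights propagate", {
  expect_error(csp_weights(beta = -1), "beta")
  w <- csp_weights(alpha_default = 0.1, alpha_glycine = 0.1, beta = 1)
  expect_equal(combined_delta(0, 1, 1, "A", w), sqrt(0.1 + 1))
})

test_that("pairwise_profile computes per-residue differences a - b", {
  a <- shift_table(data.frame(residue_number = 45, residue_type = "T",
                              nucleus = c("H", "N", "CA"),
                              value = c(8.10, 115.2, 62.1)), condition_label = "a")
  b <- shift_table(data.frame(residue_number = 45, residue_type = "T",
                              nucleus = c("H", "N", "CA"),
                              value = c(8.00, 115.0, 62.0)), condition_label = "b")
  prof <- pairwise_profile(a, b)
  rec <- prof$records
  expect_equal(rec$d_hn, 0.10)
  expect_equal(rec$d_n, 0.20)
  expect_equal(rec$d_ca, 0.10)
  expect_true(rec$complete)
  # frozen from the independent direct evaluation of the formula
  expect_equal(rec$delta_combined, direct_combined(0.10, 0.20, 0.10, "T"))
  expect_equal(rec$delta_combined, 0.13638181, tolerance = 1e-7)
})

test_that("identical tables give an all-zero profile", {
  a <- toy_table()
  prof <- pairwise_profile(a, a)
  expect_true(all(prof$records$complete))
  expect_true(all(prof$records$delta_combined == 0))
})

test_that("missing nuclei yield partial, incomplete records", {
  a <- toy_table()
  b <- toy_table(label = "b")
  bs <- b$shifts[!(b$shifts$residue_number == 45 & b$shifts$nucleus == "CA"), ]
  b2 <- shift_table(bs, condition_label = "b")
  prof <- pairwise_profile(a, b2)
  r45 <- prof$records[prof$records$residue_number == 45, ]
  expect_false(r45$complete)
  expect_true(is.na(r45$delta_combined))
  expect_false(is.na(r45$d_hn))
  expect_false(is.na(r45$d_n))
  expect_true(is.na(r45$d_ca))
  # residues present in only one table still get a (partial) record
  expect_setequal(prof$records$residue_number, 45:47)
})

test_that("profiles are symmetric in table order up to sign", {
  set.seed(11)
  spec <- planted_spec(3, c(50L, 90L))
  tabs <- generate_condition_set(spec)
  p_ab <- pairwise_profile(tabs$ref, tabs$pert)
  p_ba <- pairwise_profile(tabs$pert, tabs$ref)
  expect_equal(p_ab$records$delta_combined, p_ba$records$delta_combined)
  expect_equal(p_ab$records$d_ca, -p_ba$records$d_ca)
})

test_that("sequence disagreement between conditions is an error", {
  a <- toy_table(types = c("T", "V", "A"))
  b <- toy_table(types = c("T", "V", "G"), label = "b")
  expect_error(pairwise_profile(a, b), "disagreement")
  expect_error(mean_abs_nucleus_diff(a, b, "CA"), "disagreement")
})

test_that("mean_abs_nucleus_diff matches hand arithmetic", {
  a <- shift_table(data.frame(residue_number = c(45, 46),
                              residue_type = c("T", "V"),
                              nucleus = "CA", value = c(62.1, 60.0)))
  b <- shift_table(data.frame(residue_number = c(45, 46),
                              residue_type = c("T", "V"),
                              nucleus = "CA", value = c(62.0, 60.3)))
  res <- mean_abs_nucleus_diff(a, b, "CA")
  expect_equal(res$n, 2L)
  expect_equal(res$mean, 0.2)
  expect_equal(res$sd, sd(c(0.1, 0.3)))  # sample SD, n - 1
  expect_equal(mean_abs_nucleus_diff(a, a, "CA")$mean, 0)
  # nucleus absent from both tables
  none <- mean_abs_nucleus_diff(a, b, "CB")
  expect_equal(none$n, 0L)
  expect_true(is.na(none$mean))
})

test_that("mean_combined_delta summarises complete records only", {
  prof <- structure(list(
    pair_label = c("x", "y"), weights = csp_weights(),
    records = data.frame(residue_number = 1:4, residue_type = "A",
                         d_hn = 0, d_n = 0, d_ca = 0,
                         delta_combined = c(0.02, 0.04, 0.12, NA),
                         complete = c(TRUE, TRUE, TRUE, FALSE))),
    class = "csp_profile")
  m <- mean_combined_delta(prof)
  expect_equal(m$n, 3L)
  expect_equal(m$mean, 0.06)
  expect_equal(m$sd, sd(c(0.02, 0.04, 0.12)))
  expect_equal(m$sd, 0.0529150, tolerance = 1e-6)
  prof$records$complete <- FALSE
  expect_error(mean_combined_delta(prof), "no complete records")
})

test_that("profile CSV export carries provenance and survives re-read", {
  spec <- planted_spec(5, 60L)
  tabs <- generate_condition_set(spec)
  prof <- pairwise_profile(tabs$pert, tabs$ref)
  path <- withr::local_tempfile(fileext = ".csv")
  write_profile_csv(prof, path)
  lines <- readLines(path)
  expect_true(any(grepl("^# nmrcsp", lines)))
  expect_true(any(grepl("^# weights:", lines)))
  back <- utils::read.csv(path, comment.char = "#")
  expect_equal(nrow(back), nrow(prof$records))
  expect_equal(back$delta_combined, prof$records$delta_combined,
               tolerance = 1e-12)
})
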