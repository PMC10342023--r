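test_that("relative accessibility normalizes by residue maximum and clamps", {
  expect_equal(relative_accessibility(129.0, "A"), 1.0)
  expect_equal(relative_accessibility(0, "A"), 0.0)
  expect_equal(relative_accessibility(104.0 * 1.1, "G"), 1.0)  # clamped
  expect_true(is.na(relative_accessibility(50, "X")))
  expect_error(relative_accessibility(-1, "A"), ">= 0")
})

test_that("8-state to 3-state collapse follows the stated mapping", {
  expect_equal(ss8_to_ss3(c("H", "G", "I")), rep("helix", 3))
  expect_equal(ss8_to_ss3(c("E", "B")), rep("strand", 2))
  expect_equal(ss8_to_ss3(c("T", "S", "-")), rep("loop", 3))
  expect_error(ss8_to_ss3("Q"), "unknown")
})

test_that("loop length is the maximal-run length, broadcast to the run", {
  expect_equal(loop_length_feature(rep("loop", 7)), rep(7L, 7))
  ss <- c("loop", "loop", "loop", "helix", "helix", "helix", "loop", "loop")
  expect_equal(loop_length_feature(ss), c(3L, 3L, 3L, 0L, 0L, 0L, 2L, 2L))
  expect_equal(loop_length_feature(rep("helix", 5)), rep(0L, 5))
})

test_that("loop length matches a brute-force run scanner on random strings", {
  set.seed(42)
  for (i in 1:25) {
    ss <- sample(c("helix", "strand", "loop"), sample(5:40, 1),
                 replace = TRUE)
    expect_equal(loop_length_feature(ss), loop_len_oracle(ss))
  }
})

test_that("termini flag marks unstructured ends, skipping short elements", {
  # first regular run (4 helices) starts at position 3
  ss <- c("loop", "loop", "helix", "helix", "helix", "helix", "loop")
  got <- termini_feature(ss)
  expect_equal(got[1:2], c(1L, 1L))
  expect_equal(got[3:6], rep(0L, 4))
  expect_equal(got[7], 1L)

  # leading 2-helix run is short -> treated as terminus
  ss2 <- c("loop", "helix", "helix", "loop", "loop",
           "helix", "helix", "helix", "helix")
  expect_equal(termini_feature(ss2), c(rep(1L, 5), rep(0L, 4)))

  expect_equal(termini_feature(rep("loop", 6)), rep(1L, 6))
})

test_that("termini flags are always a prefix block plus a suffix block", {
  set.seed(7)
  for (i in 1:40) {
    ss <- sample(c("helix", "strand", "loop"), sample(4:30, 1),
                 replace = TRUE)
    f <- termini_feature(ss)
    inner <- which(f == 0)
    if (length(inner) > 0) {
      # zeros form one contiguous block
      expect_equal(inner, seq(min(inner), max(inner)))
    } else {
      expect_true(all(f == 1))
    }
  }
})

test_that("min-max bounds fit, apply and clamp as stated", {
  b <- fit_normalization(data.frame(v = c(2, 4, 10)), "v")
  expect_equal(unname(b[["v"]]), c(2, 10))
  expect_equal(apply_normalization(4, b[["v"]]), 0.25)
  expect_equal(apply_normalization(12, b[["v"]]), 1.0)
  expect_equal(apply_normalization(0, b[["v"]]), 0.0)
  expect_error(fit_normalization(data.frame(v = c(3, 3, 3)), "v"),
               "degenerate")
})

test_that("feature vectors on an all-loop toy are uniform and flagged", {
  st <- generate_toy_structure(toy_spec(list(c("loop", 7)), seed = 5))
  f <- build_feature_vectors(st, "A", ss3 = attr(st, "ss_true"))
  expect_equal(f$ss_loop, rep(1L, 7))
  expect_equal(f$loop_len, rep(7L, 7))
  expect_equal(f$terminus, rep(1L, 7))
  expect_equal(f$ss_helix + f$ss_strand + f$ss_loop, rep(1L, 7))
})

test_that("helix-core residues of a mixed toy have the expected encoding", {
  st <- generate_toy_structure(
    toy_spec(list(c("loop", 4), c("helix", 8), c("loop", 4)), seed = 5))
  f <- build_feature_vectors(st, "A", ss3 = attr(st, "ss_true"))
  core <- 8  # middle of the helix
  expect_equal(f$ss_helix[core], 1L)
  expect_equal(f$loop_len[core], 0L)
  expect_equal(f$terminus[core], 0L)
  # one-hot property over the whole chain
  expect_true(all(f$ss_helix + f$ss_strand + f$ss_loop == 1L))
  # normalized features stay within [0, 1]
  nf <- normalize_features(f)$feats
  for (col in c("rel_acc", "loop_len_norm", "bfactor_norm")) {
    expect_true(all(nf[[col]] >= 0 & nf[[col]] <= 1, na.rm = TRUE))
  }
})

test_that("predicted models carry confidence instead of B-factor", {
  st <- generate_toy_structure(toy_spec(list(c("loop", 6)), seed = 3))
  st$source_kind <- "predicted"
  st$residues$tempfactor <- rep(100, 6)
  f <- build_feature_vectors(st, "A", ss3 = attr(st, "ss_true"))
  expect_null(f$bfactor_norm)
  expect_equal(f$confidence_norm, rep(1.0, 6))
  expect_true(all(model_features("predicted") != "bfactor_norm"))
})

test_that("DSSP input drives accessibility and secondary structure", {
  path <- withr::local_tempfile(fileext = ".pdb")
  dpath <- withr::local_tempfile(fileext = ".dssp")
  write_two_chain_pdb(path)
  write_dssp_fixture(dpath, ss = c("H", "H", "E"), acc = c(129, 52, 20),
                     aa = c("A", "G", "W"))
  st <- read_structure(path)
  f <- build_feature_vectors(st, "A", dssp = parse_dssp(dpath))
  expect_equal(f$ss_helix, c(1L, 1L, 0L))
  expect_equal(f$ss_strand, c(0L, 0L, 1L))
  expect_equal(f$rel_acc[1], 1.0)  # 129 / maxASA(ALA)
  expect_equal(f$rel_acc[2], 0.5)  # 52 / 104
})
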