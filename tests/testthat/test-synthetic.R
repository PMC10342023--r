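test_that("toy backbones honor the stated geometric constraints", {
  st <- generate_toy_structure(
    toy_spec(list(c("loop", 5), c("helix", 10), c("loop", 3)), seed = 1))
  expect_equal(nrow(st$residues), 18L)
  ca <- as.matrix(st$atoms[st$atoms$elety == "CA", c("x", "y", "z")])
  d <- sqrt(rowSums(diff(ca)^2))
  expect_true(all(abs(d - 3.8) < 0.1))
})

test_that("fixed seeds give byte-identical structures", {
  spec <- toy_spec(list(c("loop", 4), c("strand", 5), c("loop", 4)),
                   seed = 99)
  f1 <- withr::local_tempfile(fileext = ".pdb")
  f2 <- withr::local_tempfile(fileext = ".pdb")
  write_structure(generate_toy_structure(spec), f1)
  write_structure(generate_toy_structure(spec), f2)
  expect_identical(readLines(f1), readLines(f2))
})

test_that("helix rise per residue along the fitted axis is ~1.5 A", {
  st <- generate_toy_structure(toy_spec(list(c("helix", 14)), seed = 2))
  ca <- as.matrix(st$atoms[st$atoms$elety == "CA", c("x", "y", "z")])
  cc <- sweep(ca, 2, colMeans(ca))
  axis <- svd(cc)$v[, 1]  # principal axis of the helix
  proj <- cc %*% axis
  rises <- abs(diff(as.numeric(proj)))
  expect_equal(mean(rises), 1.5, tolerance = 0.05)
})

test_that("loop residues carry the planted B-factor bonus", {
  spec <- toy_spec(list(c("loop", 8), c("helix", 10), c("loop", 8)),
                   seed = 3, bfactor_base = 20, bfactor_loop = 10,
                   bfactor_sd = 1)
  st <- generate_toy_structure(spec)
  ss <- attr(st, "ss_true")
  b <- st$residues$tempfactor
  expect_gt(mean(b[ss == "loop"]), mean(b[ss == "helix"]) + 5)
})

test_that("a zero-coefficient plant cleaves at the intercept rate", {
  corpus <- generate_toy_corpus(10, seed = 6, sasa_n_points = 120)
  pm <- plant_model(beta = c(rel_acc = 0, ss_helix = 0, ss_strand = 0,
                             ss_loop = 0, loop_len_norm = 0,
                             terminus = 0, bfactor_norm = 0),
                    intercept = 0)
  p <- plant_probabilities(pm, corpus$feats)
  expect_equal(p, rep(0.5, nrow(corpus$feats)))
  planted <- plant_cleavage_events(corpus$feats, pm, seed = 1)
  rate <- mean(planted$labels[corpus$feats$complete])
  expect_gt(rate, 0.4); expect_lt(rate, 0.6)
})

test_that("accessibility-driven plants concentrate cleavages in exposed residues", {
  corpus <- generate_toy_corpus(50, seed = 7, sasa_n_points = 120)
  pm <- plant_model(beta = c(rel_acc = 4, ss_helix = 0, ss_strand = 0,
                             ss_loop = 0, loop_len_norm = 0,
                             terminus = 0, bfactor_norm = 0),
                    intercept = -3)
  planted <- plant_cleavage_events(corpus$feats, pm, seed = 2)
  f <- corpus$feats[corpus$feats$complete, ]
  lab <- planted$labels[corpus$feats$complete]
  ter <- cut(f$rel_acc, quantile(f$rel_acc, c(0, 1 / 3, 2 / 3, 1)),
             include.lowest = TRUE, labels = c("lo", "mid", "hi"))
  expect_gt(mean(lab[ter == "hi"]), mean(lab[ter == "lo"]))
})

test_that("true probabilities upper-bound a fitted model's AUC", {
  bm <- planted_benchmark(n_structures = 40, seed = 3)
  expect_gte(bm$bayes_auc + 0.03, bm$cv$mean_auc)  # sampling-noise slack
})

test_that("degenerate motif weights generate identical peptides", {
  w <- matrix(0, 20, 8, dimnames = list(aa_alphabet(), sb_window()))
  w["K", ] <- 1
  peps <- generate_motif_peptides(w, 5, seed = 1)
  expect_equal(peps, rep("KKKKKKKK", 5))
})

test_that("uniform weights give near-uniform column frequencies", {
  w <- matrix(1 / 20, 20, 8, dimnames = list(aa_alphabet(), sb_window()))
  peps <- generate_motif_peptides(w, 4000, seed = 2)
  col1 <- substr(peps, 1, 1)
  freq <- table(factor(col1, levels = aa_alphabet())) / length(peps)
  se <- sqrt(0.05 * 0.95 / 4000)
  expect_true(all(abs(freq - 0.05) < 3.5 * se + 1e-9))
})

test_that("a PSSM rebuilt from many generated peptides recovers the motif", {
  w <- motif_weights(enriched = list(P1 = c("K", "R")), p_enriched = 0.5)
  peps <- generate_motif_peptides(w, 5000, seed = 3)
  p <- build_pssm(peps)
  true_bits <- log2(w / (1 / 20))
  # recovery is limited by binomial sampling noise: bound every cell by
  # five times its own standard error on the log2 scale
  err <- abs(p$matrix - true_bits)
  se <- sqrt((1 - w) / (5000 * w)) / log(2)
  expect_true(all(err < 5 * se + 0.02))
  # enriched cells (largest counts) are recovered closely
  expect_lt(max(err["K", "P1"], err["R", "P1"]), 0.1)
})

test_that("fitted LDA weight signs recover the planted coefficient signs", {
  bm <- planted_benchmark(n_structures = 60, seed = 5)
  train <- sample(nrow(bm$dataset))
  nrm <- normalize_features(bm$dataset)
  fit <- lda_fit(as.matrix(nrm$feats[, model_features()]),
                 bm$dataset$label)
  beta <- plant_model()$beta
  strong <- names(beta)[abs(beta) >= 2]
  expect_true(all(fit$w[strong] > 0))
})
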