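test_that("symmetric one-dimensional classes give posterior 0.5 at zero", {
  eps <- 0.1
  X <- matrix(c(-1, -1 + eps, -1 - eps, 1, 1 + eps, 1 - eps), ncol = 1)
  y <- c(0, 0, 0, 1, 1, 1)
  m <- lda_fit(X, y)
  expect_equal(lda_predict(m, matrix(0)), 0.5, tolerance = 1e-9)
  expect_gt(lda_predict(m, matrix(1)), 0.5)
  expect_lt(lda_predict(m, matrix(-1)), 0.5)
})

test_that("the two-dimensional toy matches the hand-computed closed form", {
  # class 0: (0,0), (2,1); class 1: (1,2), (3,4)
  # mu0 = (1, 0.5), mu1 = (2, 3); centered scatters sum to
  # [[4, 3], [3, 2.5]]; ML pooled Sigma (divide by n = 4) =
  # [[1, 0.75], [0.75, 0.625]], Sigma^-1 = [[10, -12], [-12, 16]]
  # w = Sigma^-1 (1, 2.5) = (-20, 28)
  # b = -(mu0 + mu1) . w / 2 + log(1) = -(3, 3.5).(-20, 28)/2 = -19
  X <- rbind(c(0, 0), c(2, 1), c(1, 2), c(3, 4))
  y <- c(0, 0, 1, 1)
  m <- lda_fit(X, y, ridge = 0)
  expect_equal(unname(m$w), c(-20, 28), tolerance = 1e-10)
  expect_equal(m$b, -19, tolerance = 1e-10)
})

test_that("sufficient statistics: duplicating rows leaves the fit unchanged", {
  set.seed(21)
  X <- matrix(rnorm(60), ncol = 3)
  y <- rep(c(0, 1), each = 10)
  m1 <- lda_fit(X, y)
  m2 <- lda_fit(rbind(X, X), c(y, y))
  expect_equal(m2$w, m1$w, tolerance = 1e-9)
  expect_equal(m2$b, m1$b, tolerance = 1e-9)
  expect_equal(lda_predict(m2, X), lda_predict(m1, X), tolerance = 1e-9)
})

test_that("LDA scores are invariant under consistent affine feature maps", {
  set.seed(8)
  X <- matrix(rnorm(80), ncol = 4)
  y <- rep(c(0, 1), 10)
  A <- matrix(rnorm(16), 4)
  A <- A + diag(4) * 2  # keep it invertible
  shift <- rnorm(4)
  Xt <- sweep(X %*% A, 2, shift, "+")
  s <- lda_predict(lda_fit(X, y, ridge = 0), X)
  st <- lda_predict(lda_fit(Xt, y, ridge = 0), Xt)
  expect_equal(s, st, tolerance = 1e-8)
  # adding a constant to one feature at fit and predict time: no change
  X2 <- X; X2[, 2] <- X2[, 2] + 5
  s2 <- lda_predict(lda_fit(X2, y, ridge = 0), X2)
  expect_equal(s, s2, tolerance = 1e-8)
})

test_that("LDA posteriors agree with an independent reference implementation", {
  skip_if_not_installed("MASS")
  set.seed(31)
  # large n: the reference divides the pooled scatter by n - 2, ours by
  # n, so posteriors agree up to O(1/n)
  X <- matrix(rnorm(2000), ncol = 2)
  y <- rep(c(0, 1), each = 500)
  X[y == 1, ] <- X[y == 1, ] + 1
  colnames(X) <- c("f1", "f2")
  ours <- lda_predict(lda_fit(X, y, ridge = 0), X)
  ref <- MASS::lda(X, grouping = y)
  theirs <- predict(ref, X)$posterior[, "1"]
  expect_equal(ours, unname(theirs), tolerance = 2e-3)
})

test_that("single-class and mismatched inputs are rejected", {
  X <- matrix(rnorm(10), ncol = 1)
  expect_error(lda_fit(X, rep(1, 10)), "both classes")
  m <- lda_fit(matrix(rnorm(20), ncol = 2), rep(c(0, 1), 5))
  expect_error(lda_predict(m, matrix(rnorm(3), ncol = 3)), "mismatch")
  expect_error(roc_auc(c(1, 2), c(1, 1)), "both classes")
})

test_that("ROC endpoints and the worked example are exact", {
  expect_equal(roc_auc(c(1, 2, 3, 10, 11, 12),
                       c(0, 0, 0, 1, 1, 1))$auc, 1.0)
  expect_equal(roc_auc(rep(0.3, 8), rep(c(0, 1), 4))$auc, 0.5)
  r <- roc_auc(c(0.1, 0.4, 0.35, 0.8), c(0, 0, 1, 1))
  expect_equal(r$auc, 0.75)
  expect_equal(r$fpr[1], 0); expect_equal(r$tpr[length(r$tpr)], 1)
  expect_true(all(diff(r$fpr) >= 0) && all(diff(r$tpr) >= 0))
})

test_that("AUC equals Mann-Whitney pair counting on random instances", {
  set.seed(17)
  for (i in 1:100) {
    n <- sample(4:200, 1)
    y <- c(0, 1, rbinom(n - 2, 1, 0.4))
    s <- round(runif(n), sample(c(1, 2, 8), 1))  # induce ties sometimes
    expect_equal(roc_auc(s, y)$auc, auc_pair_oracle(s, y),
                 tolerance = 1e-12)
  }
})

test_that("AUC is rank-based and complements under label flips", {
  set.seed(19)
  y <- rbinom(60, 1, 0.5); y[1:2] <- c(0, 1)
  s <- rnorm(60)
  a <- roc_auc(s, y)$auc
  expect_equal(roc_auc(exp(3 * s), y)$auc, a, tolerance = 1e-12)
  expect_equal(roc_auc(s, 1 - y)$auc, 1 - a, tolerance = 1e-12)
})

test_that("AUC agrees with pROC on a random instance", {
  skip_if_not_installed("pROC")
  set.seed(23)
  y <- c(0, 1, rbinom(98, 1, 0.3))
  s <- rnorm(100)
  ref <- as.numeric(pROC::auc(pROC::roc(y, s, quiet = TRUE,
                                        direction = "<")))
  expect_equal(roc_auc(s, y)$auc, ref, tolerance = 1e-12)
})

test_that("cross-validation never leaks test rows into fold fitting", {
  inp_corpus <- generate_toy_corpus(14, seed = 4, sasa_n_points = 120)
  planted <- plant_cleavage_events(inp_corpus$feats, seed = 4)
  dataset <- data.frame(inp_corpus$feats_raw,
                        label = planted$labels)
  dataset <- dataset[dataset$complete, ]
  dataset$group <- dataset$structure_id
  spy_rows <- new.env(); spy_rows$train_n <- integer(0)
  spy <- list(
    fit = function(X, y) {
      spy_rows$train_n <- c(spy_rows$train_n, nrow(X))
      lda_fit(X, y)
    },
    predict = function(fit, X) lda_predict(fit, X)
  )
  cv <- cross_validate(dataset, k = 5, neg_ratio = 1, seed = 2,
                       scorer = spy)
  # each fold trained on 1:1 sampled rows, strictly fewer than the dataset
  expect_true(all(spy_rows$train_n < nrow(dataset)))
  # grouped folds: test groups never overlap across folds
  tested <- lapply(cv$folds, function(f) unique(dataset$group[f]))
  expect_equal(sort(unlist(tested)), sort(unique(dataset$group)))
  expect_false(any(duplicated(unlist(tested))))
  expect_true(all(is.finite(cv$fold_auc)))
})
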