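# Gaussian naive Bayes: used both as the fusion model that combines the
# structural susceptibility score with the protease-specificity PSSM
# score, and (via the scorer interface) as a general classifier.

#' Fit a Gaussian naive Bayes model
#'
#' Per class and per feature, a univariate Gaussian (sample mean and
#' variance, variance floored at `var_floor`); priors are the class
#' frequencies.
#'
#' @param X Numeric matrix (rows = examples).
#' @param y 0/1 labels.
#' @param var_floor Minimum per-feature variance (default 1e-9).
#' @return Object of class `gaussian_nb`: `mean` and `var` (2 x p
#'   matrices, rows = classes 0/1), `priors`, `features`.
#' @export
gaussian_nb_fit <- function(X, y, var_floor = 1e-9) {
  X <- as.matrix(X)
  y <- as.integer(y)
  if (length(unique(y)) < 2) stop("both classes must be present")
  if (any(!is.finite(X))) stop("scores must be finite")
  m <- rbind(colMeans(X[y == 0, , drop = FALSE]),
             colMeans(X[y == 1, , drop = FALSE]))
  v <- rbind(apply(X[y == 0, , drop = FALSE], 2, stats::var),
             apply(X[y == 1, , drop = FALSE], 2, stats::var))
  v <- pmax(v, var_floor)
  structure(
    list(mean = m, var = v, priors = c(mean(y == 0), mean(y == 1)),
         features = colnames(X)),
    class = "gaussian_nb"
  )
}

#' Posterior class-1 probability under a Gaussian naive Bayes model
#'
#' `P(1 | x) = pi1 prod_f N(x_f; m1f, v1f) / sum_c pi_c prod_f N(...)`,
#' computed in log space for stability.
#'
#' @param model A `gaussian_nb`.
#' @param X Numeric matrix with the model's feature columns.
#' @return Posteriors in (0, 1).
#' @export
gaussian_nb_predict <- function(model, X) {
  X <- as.matrix(X)
  if (ncol(X) != ncol(model$mean)) {
    stop("feature dimension mismatch")
  }
  loglik <- function(cls) {
    ll <- rep(log(model$priors[cls + 1]), nrow(X))
    for (f in seq_len(ncol(X))) {
      ll <- ll + stats::dnorm(X[, f], model$mean[cls + 1, f],
                              sqrt(model$var[cls + 1, f]), log = TRUE)
    }
    ll
  }
  l0 <- loglik(0L); l1 <- loglik(1L)
  as.numeric(1 / (1 + exp(l0 - l1)))
}

#' Fit the structural-score + PSSM-score fusion model
#'
#' @param structural_scores Structural susceptibility scores.
#' @param pssm_scores PSSM specificity scores (bits).
#' @param labels 0/1 cleavage labels.
#' @return A `gaussian_nb` over the two score features.
#' @export
combiner_fit <- function(structural_scores, pssm_scores, labels) {
  X <- cbind(structural = structural_scores, pssm = pssm_scores)
  gaussian_nb_fit(X, labels)
}

#' Fused posterior for candidate sites
#'
#' @param model Fusion model from [combiner_fit()].
#' @param structural_scores Structural susceptibility scores.
#' @param pssm_scores PSSM specificity scores.
#' @return Posterior cleavage probabilities in (0, 1).
#' @export
combiner_predict <- function(model, structural_scores, pssm_scores) {
  gaussian_nb_predict(model, cbind(structural = structural_scores,
                                   pssm = pssm_scores))
}
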