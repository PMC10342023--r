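# Linear discriminant analysis susceptibility scorer. Fisher/Gaussian LDA
# with a pooled within-class covariance, a small ridge on the diagonal
# (the one-hot secondary-structure block is otherwise rank-deficient), and
# a logistic posterior.

#' Fit a linear discriminant scorer
#'
#' Gaussian LDA with shared covariance: class means `mu0`, `mu1`, pooled
#' within-class covariance `Sigma + ridge * I`, discriminant direction
#' `w = Sigma^-1 (mu1 - mu0)`, intercept
#' `b = -(mu0 + mu1)' w / 2 + log(n1 / n0)`, and posterior
#' `P(y = 1 | x) = logistic(w'x + b)`.
#'
#' @param X Numeric matrix or data frame of feature rows.
#' @param y 0/1 labels.
#' @param ridge Diagonal regularizer added to the pooled covariance
#'   (default 1e-6).
#' @return Object of class `lda_scorer` with elements `w`, `b`, `mu0`,
#'   `mu1`, `sigma`, `priors`, `features`.
#' @export
lda_fit <- function(X, y, ridge = 1e-6) {
  X <- as.matrix(X)
  storage.mode(X) <- "double"
  y <- as.integer(y)
  if (length(unique(y)) < 2) stop("both classes must be present")
  if (any(!is.finite(X))) stop("feature matrix contains missing values")
  n0 <- sum(y == 0); n1 <- sum(y == 1)
  mu0 <- colMeans(X[y == 0, , drop = FALSE])
  mu1 <- colMeans(X[y == 1, , drop = FALSE])
  X0 <- sweep(X[y == 0, , drop = FALSE], 2, mu0)
  X1 <- sweep(X[y == 1, , drop = FALSE], 2, mu1)
  # maximum-likelihood pooled covariance (divide by n, not n - 2): makes
  # the fit an exact function of the sufficient statistics, so duplicating
  # every row leaves w and b unchanged
  sigma <- (crossprod(X0) + crossprod(X1)) / (n0 + n1)
  sigma <- sigma + diag(ridge, ncol(X))
  w <- tryCatch(solve(sigma, mu1 - mu0),
                error = function(e) stop("pooled covariance singular ",
                                         "even after ridge: ",
                                         conditionMessage(e)))
  b <- -sum((mu0 + mu1) * w) / 2 + log(n1 / n0)
  structure(
    list(w = w, b = b, mu0 = mu0, mu1 = mu1, sigma = sigma,
         priors = c(n0, n1) / (n0 + n1), ridge = ridge,
         features = colnames(X)),
    class = "lda_scorer"
  )
}

#' Score feature rows with a fitted linear discriminant
#'
#' @param model An `lda_scorer`.
#' @param X Feature matrix/data frame with the model's columns.
#' @return Posterior probabilities in (0, 1), monotone in the linear
#'   discriminant `w'x`.
#' @export
lda_predict <- function(model, X) {
  X <- as.matrix(X)
  if (!is.null(model$features) && !is.null(colnames(X))) {
    if (!all(model$features %in% colnames(X))) {
      stop("feature columns missing: ",
           paste(setdiff(model$features, colnames(X)), collapse = ", "))
    }
    X <- X[, model$features, drop = FALSE]
  }
  if (ncol(X) != length(model$w)) {
    stop("feature dimension mismatch: model has ", length(model$w),
         ", data has ", ncol(X))
  }
  as.numeric(stats::plogis(X %*% model$w + model$b))
}

#' Serialize a fitted scorer (with its normalization bounds) to JSON
#'
#' @param model An `lda_scorer`.
#' @param bounds Optional `norm_bounds` fitted with the model.
#' @param path Output path.
#' @param source_kind Feature regime the model was fitted for.
#' @return Invisibly, `path`.
#' @export
write_lda_model <- function(model, path, bounds = NULL,
                            source_kind = "experimental") {
  obj <- list(
    format = "strucleave-lda-1",
    source_kind = source_kind,
    features = model$features,
    w = unname(model$w), b = model$b,
    mu0 = unname(model$mu0), mu1 = unname(model$mu1),
    sigma = unname(model$sigma),
    priors = unname(model$priors), ridge = model$ridge,
    bounds = if (!is.null(bounds)) lapply(bounds, unname)
  )
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Read a serialized scorer
#'
#' @param path JSON file written by [write_lda_model()].
#' @return List with `model` (`lda_scorer`), `bounds` (`norm_bounds` or
#'   NULL) and `source_kind`.
#' @export
read_lda_model <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  if (is.null(obj$format) || obj$format != "strucleave-lda-1") {
    stop("not a strucleave LDA model file: ", path)
  }
  model <- structure(
    list(w = stats::setNames(obj$w, obj$features), b = obj$b,
         mu0 = stats::setNames(obj$mu0, obj$features),
         mu1 = stats::setNames(obj$mu1, obj$features),
         sigma = matrix(unlist(obj$sigma), length(obj$features)),
         priors = obj$priors, ridge = obj$ridge, features = obj$features),
    class = "lda_scorer"
  )
  bounds <- NULL
  if (!is.null(obj$bounds)) {
    bounds <- structure(lapply(obj$bounds, as.numeric),
                        class = "norm_bounds")
  }
  list(model = model, bounds = bounds, source_kind = obj$source_kind)
}
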