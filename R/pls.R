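#' Univariate partial least squares (PLS1) by NIPALS
#'
#' Centred PLS1 regression for a single response: successive latent
#' directions maximizing covariance with the residual response, computed by
#' the NIPALS recursion with deflation of the predictor matrix. Components
#' whose score norm collapses (rank deficiency) stop the extraction early
#' with a warning.
#'
#' @param X numeric predictor matrix (rows = samples).
#' @param y numeric response.
#' @param n_components number of latent variables; must not exceed
#'   `min(nrow(X) - 1, ncol(X))`.
#' @return Object of class `"pls_model"` with regression coefficients `B`
#'   (on the original scale), `intercept`, loadings/weights/scores and the
#'   number of components actually used.
#' @export
pls_fit <- function(X, y, n_components = 2L) {
  X <- as.matrix(X)
  y <- as.numeric(y)
  n <- nrow(X); p <- ncol(X)
  stopifnot(n == length(y), n >= 2)
  if (n_components > min(n - 1L, p))
    stop("n_components exceeds min(nrow(X) - 1, ncol(X))", call. = FALSE)
  xm <- colMeans(X); ym <- mean(y)
  E <- sweep(X, 2L, xm)
  f <- y - ym
  W <- matrix(0, p, n_components)   # weights
  P <- matrix(0, p, n_components)   # X loadings
  Q <- numeric(n_components)        # y loadings
  Tm <- matrix(0, n, n_components)  # scores
  used <- 0L
  for (a in seq_len(n_components)) {
    w <- crossprod(E, f)
    nw <- sqrt(sum(w^2))
    if (nw < 1e-12) {
      warning(sprintf("rank deficiency: stopping at %d component(s)", used),
              call. = FALSE)
      break
    }
    w <- w / nw
    t_a <- as.numeric(E %*% w)
    tt <- sum(t_a^2)
    if (tt < 1e-24) {
      warning(sprintf("rank deficiency: stopping at %d component(s)", used),
              call. = FALSE)
      break
    }
    p_a <- as.numeric(crossprod(E, t_a)) / tt
    q_a <- sum(f * t_a) / tt
    E <- E - tcrossprod(t_a, p_a)
    f <- f - q_a * t_a
    used <- a
    W[, a] <- w; P[, a] <- p_a; Q[a] <- q_a; Tm[, a] <- t_a
  }
  if (used == 0L) stop("no usable PLS component (constant data?)", call. = FALSE)
  W <- W[, seq_len(used), drop = FALSE]
  P <- P[, seq_len(used), drop = FALSE]
  Q <- Q[seq_len(used)]
  B <- W %*% solve(crossprod(P, W), Q)
  structure(list(B = as.numeric(B), intercept = ym - sum(xm * as.numeric(B)),
                 x_mean = xm, y_mean = ym, weights = W, loadings = P,
                 y_loadings = Q, scores = Tm[, seq_len(used), drop = FALSE],
                 n_components = used, model_kind = "PLS"),
            class = "pls_model")
}

#' Predict from a PLS1 model
#'
#' @param object a `"pls_model"`.
#' @param newdata matrix with the training feature dimension.
#' @param ... unused.
#' @return Numeric predictions.
#' @export
predict.pls_model <- function(object, newdata, ...) {
  newdata <- as.matrix(newdata)
  if (ncol(newdata) != length(object$B))
    stop("feature dimension mismatch", call. = FALSE)
  as.numeric(newdata %*% object$B + object$intercept)
}

#' @export
print.pls_model <- function(x, ...) {
  cat(sprintf("PLS1 (NIPALS): %d component(s), %d predictors\n",
              x$n_components, length(x$B)))
  invisible(x)
}

#' @export
coef.pls_model <- function(object, ...) {
  c(`(Intercept)` = object$intercept, object$B)
}
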