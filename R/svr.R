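#' SVR hyperparameters
#'
#' Hyperparameters of epsilon-insensitive support vector regression with a
#' radial-basis-function kernel in the \eqn{\exp(-d^2 / (2\gamma^2))}
#' convention.
#'
#' @param epsilon half-width of the insensitive tube, in response units.
#' @param C box-constraint penalty.
#' @param gamma RBF width.
#' @return Object of class `"svr_hyper"`.
#' @export
svr_hyper <- function(epsilon = 0.1, C = 100, gamma = 1) {
  stopifnot(epsilon >= 0, C > 0, gamma > 0)
  structure(list(epsilon = epsilon, C = C, gamma = gamma), class = "svr_hyper")
}

#' Radial basis function kernel
#'
#' \eqn{K(x_i, x_j) = \exp(-\|x_i - x_j\|^2 / (2\gamma^2))}. Note the
#' \eqn{2\gamma^2} denominator: `gamma` here is the kernel *width*, not the
#' scale factor used by some libraries (which equals \eqn{1/(2\gamma^2)}).
#'
#' @param xi,xj numeric vectors of equal length.
#' @param gamma width parameter, > 0.
#' @return Kernel value in (0, 1].
#' @export
#' @examples
#' rbf_kernel(c(0, 0), c(1, 1), gamma = 1)
rbf_kernel <- function(xi, xj, gamma) {
  stopifnot(length(xi) == length(xj), gamma > 0)
  exp(-sum((xi - xj)^2) / (2 * gamma^2))
}

# Pairwise RBF kernel matrix between rows of A and rows of B.
.rbf_kernel_matrix <- function(A, B, gamma) {
  d2 <- outer(rowSums(A^2), rowSums(B^2), "+") - 2 * tcrossprod(A, B)
  d2[d2 < 0] <- 0
  exp(-d2 / (2 * gamma^2))
}

#' Train an epsilon-SVR model
#'
#' Solves the epsilon-insensitive support vector regression dual problem
#' (via the libsvm solver) with an RBF kernel in the
#' \eqn{\exp(-d^2/(2\gamma^2))} convention, and stores the dual coefficients
#' \eqn{(\hat a - a)_i}, the bias \eqn{b^*} and the training inputs so that
#' predictions can be evaluated directly as
#' \eqn{f(x) = \sum_i (\hat a - a)_i K(x_i, x) + b^*}.
#'
#' @param X numeric matrix of predictors (rows = samples); a vector is
#'   treated as a single column.
#' @param y numeric response.
#' @param hyper an [svr_hyper()].
#' @return Object of class `"svr_model"` with fields `dual_coef` (length
#'   `nrow(X)`, zero for non-support vectors), `bias`, `hyper`, `X`.
#' @export
svr_train <- function(X, y, hyper = svr_hyper()) {
  X <- as.matrix(X)
  y <- as.numeric(y)
  stopifnot(nrow(X) >= 2, nrow(X) == length(y))
  fit <- e1071::svm(x = X, y = y, scale = FALSE, type = "eps-regression",
                    kernel = "radial", cost = hyper$C,
                    epsilon = hyper$epsilon,
                    gamma = 1 / (2 * hyper$gamma^2), fitted = FALSE)
  dual <- numeric(nrow(X))
  dual[fit$index] <- as.numeric(fit$coefs)
  structure(list(dual_coef = dual, bias = -fit$rho, hyper = hyper,
                 X = X, y = y, model_kind = "SVR"),
            class = "svr_model")
}

#' Predict from a trained SVR model
#'
#' Evaluates \eqn{\sum_i (\hat a - a)_i K(x_i, x) + b^*} row by row.
#'
#' @param object an `"svr_model"`.
#' @param newdata matrix (or vector) with the training feature dimension.
#' @param ... unused.
#' @return Numeric predictions.
#' @export
predict.svr_model <- function(object, newdata, ...) {
  newdata <- as.matrix(newdata)
  if (ncol(newdata) != ncol(object$X))
    stop("feature dimension mismatch", call. = FALSE)
  K <- .rbf_kernel_matrix(newdata, object$X, object$hyper$gamma)
  as.numeric(K %*% object$dual_coef + object$bias)
}

#' @export
print.svr_model <- function(x, ...) {
  cat(sprintf(paste0("epsilon-SVR (RBF): n = %d, support vectors = %d\n",
                     "  epsilon = %.4g, C = %.4g, gamma = %.4g, bias = %.4g\n"),
              nrow(x$X), sum(x$dual_coef != 0), x$hyper$epsilon, x$hyper$C,
              x$hyper$gamma, x$bias))
  invisible(x)
}

#' @export
coef.svr_model <- function(object, ...) object$dual_coef

#' @export
residuals.svr_model <- function(object, ...) {
  object$y - predict(object, object$X)
}
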