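# Internal ordinary-least-squares helpers.
#
# The stepwise search needs tens of thousands of small cross-validated OLS
# fits, so models are fitted from Gram matrices (X'X, X'y) accumulated once
# per fold; each candidate model then costs one small symmetric solve.
# Rank-deficient systems are resolved by the QR least-squares pseudo-solution
# with dependent coefficients set to zero.

psd_solve <- function(A, b) {
  A <- as.matrix(A)
  coef <- tryCatch(solve(A, b), error = function(e) {
    co <- qr.coef(qr(A), b)
    co[is.na(co)] <- 0
    co
  })
  as.numeric(coef)
}

# Precompute fold-wise Gram blocks for CV over the columns of X1 (which must
# already contain the intercept column).
gram_folds <- function(X1, y, fold) {
  folds <- sort(unique(fold))
  per <- lapply(folds, function(f) {
    idx <- fold == f
    Xf <- X1[idx, , drop = FALSE]
    yf <- y[idx]
    list(A = crossprod(Xf), b = crossprod(Xf, yf), yy = sum(yf^2),
         n = sum(idx))
  })
  list(A = crossprod(X1), b = crossprod(X1, y), per = per, n = length(y))
}

# CV mean squared error of the OLS model on columns S (indices into X1).
cv_mse_for <- function(g, S) {
  sse <- 0
  for (p in g$per) {
    At <- g$A[S, S, drop = FALSE] - p$A[S, S, drop = FALSE]
    bt <- g$b[S] - p$b[S]
    beta <- psd_solve(At, bt)
    sse <- sse + p$yy - 2 * sum(beta * p$b[S]) +
      drop(crossprod(beta, p$A[S, S, drop = FALSE] %*% beta))
  }
  max(sse, 0) / g$n
}

# Standardize columns with frozen centers/scales (constant columns pass
# through); a fixed affine reparameterization, so OLS predictions are
# unchanged while the Gram solves stay well conditioned.
scale_spec <- function(X) {
  center <- colMeans(X)
  scale <- apply(X, 2, stats::sd)
  scale[!is.finite(scale) | scale == 0] <- 1
  list(center = center, scale = scale)
}

apply_scale <- function(X, spec) {
  sweep(sweep(X, 2, spec$center, "-"), 2, spec$scale, "/")
}

# Plain OLS fit/predict used outside the stepwise inner loop.
ols_fit <- function(X, y) {
  X1 <- cbind(1, as.matrix(X))
  co <- qr.coef(qr(X1), y)
  co[is.na(co)] <- 0
  co
}

ols_predict <- function(coef, X) {
  drop(cbind(1, as.matrix(X)) %*% coef)
}
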