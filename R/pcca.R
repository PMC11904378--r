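#' Column-standardize an occasion matrix
#'
#' Centers each column to mean 0 and scales to unit sample variance
#' (denominator `n - 1`). Canonical correlations are invariant to affine
#' column rescaling, but weights and structure loadings are not; all pCCA
#' computations in this package operate on standardized columns because the
#' two blocks mix incommensurate units (hours, counts, scale scores).
#'
#' @param A numeric matrix or data frame, occasions in rows.
#' @return a numeric matrix of the same dimension with column means 0 and
#'   sample variances 1.
#' @examples
#' standardize(cbind(a = c(1, 2, 3), b = c(10, 30, 20)))
#' @export
standardize <- function(A) {
  A <- as_occasion_values(A)
  if (anyNA(A)) abort_input("missing values present; drop incomplete occasions first")
  sds <- apply(A, 2, stats::sd)
  if (any(sds == 0)) {
    bad <- colnames(A)[sds == 0]
    abort_input("constant column(s): ", paste(bad, collapse = ", "),
                " cannot be standardized")
  }
  scale(A, center = TRUE, scale = sds)[, , drop = FALSE]
}

as_occasion_values <- function(A) {
  if (is.data.frame(A)) {
    keep <- vapply(A, is.numeric, logical(1))
    A <- as.matrix(A[keep])
  }
  if (!is.matrix(A) || !is.numeric(A)) abort_input("expected a numeric matrix")
  if (is.null(colnames(A))) colnames(A) <- paste0("v", seq_len(ncol(A)))
  A
}

# symmetric inverse square root via eigendecomposition; tol guards rank
inv_sqrt_sym <- function(S, label, ridge) {
  e <- eigen(S, symmetric = TRUE)
  tol <- max(dim(S)) * .Machine$double.eps * max(e$values)
  if (any(e$values < tol)) {
    abort_input(label, " is rank deficient; supply a small positive ridge ",
                "(e.g. ridge = 1e-8) or remove collinear columns")
  }
  if (max(e$values) / min(e$values) > 1e8) {
    message(label, " is ill-conditioned (condition number > 1e8); ",
            "consider a small ridge")
  }
  e$vectors %*% (t(e$vectors) / sqrt(e$values))
}

#' Wilks' lambda from canonical correlations
#'
#' \eqn{\Lambda = \prod_k (1 - \rho_k^2)}. Values near 0 indicate strong
#' multivariate association between the two blocks; 1 indicates independence.
#'
#' @param rho numeric vector of canonical correlations, each in \[0, 1\].
#' @return a single number in \[0, 1\].
#' @examples
#' wilks_lambda(c(0.8, 0.5)) # 0.27
#' @export
wilks_lambda <- function(rho) {
  if (any(rho < 0 | rho > 1)) abort_input("canonical correlations must lie in [0, 1]")
  prod(1 - rho^2)
}

#' p-technique canonical correlation analysis of two occasion blocks
#'
#' Fits CCA to one person's occasions-by-variables blocks: `A_x` (media use)
#' and `A_y` (mental health), occasions as the sampling unit. Both blocks are
#' column-standardized, within-block covariance matrices
#' \eqn{S_{xx}, S_{yy}} (plus `ridge` times the identity) and the
#' cross-covariance \eqn{S_{xy}} are formed with denominator `n - 1`, and
#' the singular value decomposition of
#' \eqn{K = S_{xx}^{-1/2} S_{xy} S_{yy}^{-1/2}} yields the canonical
#' correlations (singular values) and, after back-transformation, the weight
#' vectors. Weights are rescaled so each canonical variate has unit sample
#' variance, and the sign of each weight pair is fixed so that the y-block
#' structure loading of largest magnitude is positive (CCA signs are
#' otherwise arbitrary; a deterministic convention is needed for
#' reproducible reports).
#'
#' Reported loadings are structure correlations — the correlation of each
#' standardized observed column with its own block's first canonical
#' variate — which are bounded by \[-1, 1\], unlike raw weights.
#'
#' @param A_x numeric matrix/data frame, occasions x media-use variables.
#' @param A_y numeric matrix/data frame, occasions x mental-health variables,
#'   same occasions in the same order.
#' @param ridge small non-negative number added to the diagonal of the
#'   within-block covariance matrices; default 0. Useful when `n` is close
#'   to the number of variables and a block is near-singular.
#' @return an object of class `pcca`: a list with elements `rho`
#'   (non-increasing canonical correlations), `x_weights`, `y_weights`
#'   (columns are weight vectors), `z_x`, `z_y` (variate time series, unit
#'   sample variance), `x_loadings`, `y_loadings` (structure correlations
#'   with the first variate), `wilks`, `n_occasions`, and `ridge`.
#' @examples
#' set.seed(1)
#' f <- rnorm(27)
#' A_x <- sapply(1:6, function(i) f + rnorm(27))
#' A_y <- sapply(1:5, function(i) f + rnorm(27))
#' fit <- fit_pcca(A_x, A_y)
#' fit$rho[1]
#' fit$wilks
#' @export
fit_pcca <- function(A_x, A_y, ridge = 0) {
  A_x <- as_occasion_values(A_x)
  A_y <- as_occasion_values(A_y)
  n <- nrow(A_x)
  p <- ncol(A_x); q <- ncol(A_y)
  if (nrow(A_y) != n) abort_input("blocks must share occasions: ", n, " vs ", nrow(A_y))
  if (n <= max(p, q) + 1) {
    abort_input("need more occasions than variables: n = ", n,
                " occasions but the larger block has ", max(p, q),
                " variables (require n > ", max(p, q) + 1, ")")
  }
  if (ridge < 0) abort_input("ridge must be non-negative")

  Zx <- standardize(A_x)
  Zy <- standardize(A_y)
  Sxx <- crossprod(Zx) / (n - 1) + diag(ridge, p)
  Syy <- crossprod(Zy) / (n - 1) + diag(ridge, q)
  Sxy <- crossprod(Zx, Zy) / (n - 1)

  Wxx <- inv_sqrt_sym(Sxx, "S_xx", ridge)
  Wyy <- inv_sqrt_sym(Syy, "S_yy", ridge)
  K <- Wxx %*% Sxy %*% Wyy
  sv <- svd(K)
  m <- min(p, q)
  rho <- pmin(pmax(sv$d[seq_len(m)], 0), 1)

  x_w <- Wxx %*% sv$u[, seq_len(m), drop = FALSE]
  y_w <- Wyy %*% sv$v[, seq_len(m), drop = FALSE]

  # enforce unit sample variance of the variates (exact even with ridge > 0)
  z_x <- Zx %*% x_w
  z_y <- Zy %*% y_w
  sx <- apply(z_x, 2, stats::sd)
  sy <- apply(z_y, 2, stats::sd)
  x_w <- sweep(x_w, 2, sx, "/"); z_x <- sweep(z_x, 2, sx, "/")
  y_w <- sweep(y_w, 2, sy, "/"); z_y <- sweep(z_y, 2, sy, "/")

  # sign convention per pair: largest-|.| y-block loading positive
  for (k in seq_len(m)) {
    ly <- stats::cor(Zy, z_y[, k])
    if (ly[which.max(abs(ly))] < 0) {
      x_w[, k] <- -x_w[, k]; y_w[, k] <- -y_w[, k]
      z_x[, k] <- -z_x[, k]; z_y[, k] <- -z_y[, k]
    }
  }

  x_loadings <- drop(stats::cor(Zx, z_x[, 1]))
  y_loadings <- drop(stats::cor(Zy, z_y[, 1]))
  names(x_loadings) <- colnames(A_x)
  names(y_loadings) <- colnames(A_y)
  rownames(x_w) <- colnames(A_x); rownames(y_w) <- colnames(A_y)

  structure(list(
    rho = rho,
    x_weights = x_w, y_weights = y_w,
    z_x = z_x, z_y = z_y,
    x_loadings = x_loadings, y_loadings = y_loadings,
    wilks = wilks_lambda(rho),
    n_occasions = n, ridge = ridge
  ), class = "pcca")
}

#' @export
print.pcca <- function(x, ...) {
  cat(sprintf("p-technique CCA: n = %d occasions, %d x %d variables\n",
              x$n_occasions, nrow(x$x_weights), nrow(x$y_weights)))
  cat(sprintf("  r = %.3f (first canonical pair), Wilks lambda = %.4f\n",
              x$rho[1], x$wilks))
  cat("  all canonical correlations:",
      paste(sprintf("%.3f", x$rho), collapse = ", "), "\n")
  invisible(x)
}
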