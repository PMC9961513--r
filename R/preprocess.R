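`%||%` <- function(a, b) if (is.null(a)) b else a

## Scaled abscissa in [-1, 1] for polynomial bases; keeps Vandermonde
## matrices well-conditioned at 288 bands.
poly_basis <- function(p_or_x, order) {
  x <- if (length(p_or_x) == 1L) seq_len(p_or_x) else p_or_x
  t <- if (length(x) > 1L) 2 * (x - min(x)) / (max(x) - min(x)) - 1 else 0
  outer(t, 0:order, `^`)
}

#' Detrend spectra by polynomial removal
#'
#' Per row, subtracts the least-squares polynomial of the given order fitted
#' against band index. Removes broad baseline curvature; a row-wise
#' transform (each spectrum is treated independently).
#'
#' @param X spectra matrix, rows = objects, columns = bands.
#' @param order polynomial order, `>= 1` (default 2, matching the baseline
#'   order used elsewhere in the default chains).
#' @return Matrix of residual spectra, same shape.
#' @export
detrend <- function(X, order = 2L) {
  X <- as.matrix(X)
  if (order < 1L) stop_input("detrend order must be >= 1")
  if (order >= ncol(X)) stop_input("detrend order (%d) >= n_bands (%d)", order, ncol(X))
  Q <- qr.Q(qr(poly_basis(ncol(X), order)))
  X - (X %*% Q) %*% t(Q)
}

#' Asymmetric weighted least-squares baseline removal
#'
#' Iteratively fits a weighted polynomial baseline to each spectrum:
#' points above the current baseline are down-weighted (weight
#' `w_above`), points below keep weight 1, so the fit hugs the lower
#' envelope and the subtraction limits negative signals. Iterates until the
#' weight vector changes by less than `tol` or `max_iter` is reached.
#'
#' @param X spectra matrix.
#' @param order baseline polynomial order (default 2).
#' @param max_iter,tol iteration controls.
#' @param w_above weight given to points above the fitted baseline.
#' @return Matrix of baseline-subtracted spectra.
#' @export
wls_baseline <- function(X, order = 2L, max_iter = 100L, tol = 1e-6,
                         w_above = 0.001) {
  X <- as.matrix(X)
  if (order < 0L) stop_input("baseline order must be >= 0")
  B <- poly_basis(ncol(X), order)
  out <- X
  for (r in seq_len(nrow(X))) {
    x <- X[r, ]
    w <- rep(1, length(x))
    for (it in seq_len(max_iter)) {
      Bw <- B * w
      coef <- solve(crossprod(B, Bw), crossprod(Bw, x))
      base <- drop(B %*% coef)
      w_new <- ifelse(x > base, w_above, 1)
      if (max(abs(w_new - w)) < tol) break
      w <- w_new
    }
    out[r, ] <- x - base
  }
  out
}

## Savitzky-Golay weight matrix: row i holds the convolution weights giving
## the deriv_order-th derivative at band i. Interior rows share one stencil;
## edge rows use a shrunken asymmetric window refit (no padding), so the
## filter stays exact for polynomials up to poly_order everywhere.
sg_matrix <- function(p, deriv_order, poly_order, window) {
  h <- (window - 1L) %/% 2L
  W <- matrix(0, p, p)
  coef_at <- function(offsets) {
    V <- outer(offsets, 0:poly_order, `^`)
    fact <- prod(seq_len(deriv_order))
    drop(fact * pinv(V)[deriv_order + 1L, ])
  }
  interior <- coef_at(-h:h)
  for (i in seq_len(p)) {
    lo <- max(1L, i - h); hi <- min(p, i + h)
    if (lo == i - h && hi == i + h) W[i, lo:hi] <- interior
    else W[i, lo:hi] <- coef_at((lo:hi) - i)
  }
  W
}

#' Savitzky-Golay derivative
#'
#' Per-row local-polynomial derivative: within a sliding window of
#' `window` points a polynomial of order `poly_order` is fitted by least
#' squares and its `deriv_order`-th derivative evaluated at the window
#' centre. Edges use a shrunken asymmetric window refit rather than
#' padding. Derivatives are with respect to band index (unit spacing).
#'
#' @param X spectra matrix.
#' @param deriv_order derivative order, 1 or 2.
#' @param poly_order fitting polynomial order (default 2).
#' @param window odd window length in points (default 15).
#' @return Matrix of derivative spectra.
#' @export
sg_derivative <- function(X, deriv_order, poly_order = 2L, window = 15L) {
  X <- as.matrix(X)
  if (window %% 2L == 0L) stop_input("SG window must be odd, got %d", window)
  if (!(deriv_order %in% 1:2)) stop_input("deriv_order must be 1 or 2")
  if (window <= poly_order || poly_order < deriv_order)
    stop_input("need window > poly_order >= deriv_order")
  if (window > ncol(X)) stop_input("SG window (%d) exceeds n_bands (%d)", window, ncol(X))
  X %*% t(sg_matrix(ncol(X), deriv_order, poly_order, window))
}

#' Standard normal variate
#'
#' Per row: `(x - mean(x)) / sd(x)` with the sample (n-1) standard
#' deviation. Removes per-spectrum multiplicative scatter and offset;
#' invariant under positive affine transforms of a row.
#'
#' @param X spectra matrix.
#' @return Matrix with every row at mean 0, sample sd 1.
#' @export
snv <- function(X) {
  X <- as.matrix(X)
  mu <- rowMeans(X)
  sd_ <- apply(X, 1L, stats::sd)
  zero <- which(sd_ == 0)
  if (length(zero))
    stop_input("SNV undefined: zero-variance row(s) %s",
               paste(utils::head(zero, 5L), collapse = ", "))
  (X - mu) / sd_
}

#' Extended multiplicative scatter correction
#'
#' `emsc_fit` stores the reference spectrum `m` (the calibration-set mean)
#' and a wavelength polynomial basis. `emsc_apply` models each row as
#' `x = a + b*m + sum_j d_j * lambda^j + e` by least squares and returns
#' the corrected row `(x - a - sum_j d_j * lambda^j) / b`, i.e. the
#' spectrum with additive offset, wavelength-dependent baseline and
#' multiplicative scatter removed. Row-wise at apply time: the fitted
#' reference never changes.
#'
#' @param X_cal calibration spectra used to form the reference.
#' @param wavelengths optional wavelength axis (nm); band index if `NULL`.
#' @param poly_order order of the wavelength polynomial (default 2).
#' @param reference explicit reference spectrum overriding the mean.
#' @param b_tol smallest admissible |b|.
#' @return `emsc_fit`: a fitted step. `emsc_apply`: corrected matrix.
#' @export
emsc_fit <- function(X_cal, wavelengths = NULL, poly_order = 2L,
                     reference = NULL) {
  X_cal <- as.matrix(X_cal)
  m <- reference %||% colMeans(X_cal)
  if (length(m) != ncol(X_cal))
    stop_input("reference length %d != n_bands %d", length(m), ncol(X_cal))
  wl <- wavelengths %||% seq_len(ncol(X_cal))
  P <- poly_basis(wl, poly_order)           # columns: 1, lambda, lambda^2, ...
  list(name = "emsc", reference = m, basis = P)
}

#' @rdname emsc_fit
#' @param step a fitted EMSC step.
#' @param X spectra to correct.
#' @export
emsc_apply <- function(step, X, b_tol = 1e-8) {
  X <- as.matrix(X)
  if (ncol(X) != length(step$reference))
    stop_input("band mismatch: data %d, fitted reference %d",
               ncol(X), length(step$reference))
  D <- cbind(step$basis[, 1L], step$reference, step$basis[, -1L, drop = FALSE])
  Dpinv <- pinv(D)
  coefs <- Dpinv %*% t(X)                    # (2 + order) x n
  b <- coefs[2L, ]
  if (any(abs(b) < b_tol))
    stop_input("EMSC degenerate: |b| < %g for row(s) %s", b_tol,
               paste(utils::head(which(abs(b) < b_tol), 5L), collapse = ", "))
  additive <- t(D[, -2L, drop = FALSE] %*% coefs[-2L, , drop = FALSE])
  (X - additive) / b
}

#' Orthogonal signal correction
#'
#' Removes from `X` the dominant variance components whose scores are
#' orthogonal to the response `Y` (class-indicator matrix): per component
#' the leading principal score of the centred calibration matrix is
#' projected out of the column space of `Y`, iterated to convergence, and
#' the matrix is deflated by that score and its loading. Calibration
#' scores are exactly `Y`-orthogonal by construction. New data are
#' deflated with the stored minimal-norm weights, never refitted.
#'
#' @param X_cal calibration spectra.
#' @param Y_cal class-indicator matrix (or factor/character labels).
#' @param n_components number of components to remove (default 1).
#' @param tol,max_iter inner convergence controls.
#' @return `osc_fit`: a fitted step with weights, loadings and calibration
#'   scores. `osc_apply`: the deflated matrix.
#' @export
osc_fit <- function(X_cal, Y_cal, n_components = 1L, tol = 1e-10,
                    max_iter = 500L) {
  X_cal <- as.matrix(X_cal)
  if (!is.matrix(Y_cal)) Y_cal <- class_indicator(Y_cal)
  if (nrow(X_cal) != nrow(Y_cal))
    stop_input("X_cal and Y_cal row counts differ")
  if (n_components < 1L) stop_input("n_components must be >= 1")
  mu <- colMeans(X_cal)
  Xc <- sweep(X_cal, 2L, mu)
  rk <- qr(Xc)$rank
  if (n_components >= rk)
    stop_input("n_components (%d) >= rank of centred X_cal (%d)", n_components, rk)
  Qy <- qr.Q(qr(Y_cal))
  orth <- function(t) t - Qy %*% crossprod(Qy, t)
  W <- P <- matrix(0, ncol(Xc), n_components)
  Tsc <- matrix(0, nrow(Xc), n_components)
  for (k in seq_len(n_components)) {
    sv <- svd(Xc)
    keep <- sv$d > max(tol, .Machine$double.eps) * sv$d[1L]
    Xpinv_t <- function(t) {                # minimal-norm w with Xc w ~ proj(t)
      co <- drop(crossprod(sv$u, t))
      co <- ifelse(keep, co / sv$d, 0)
      sv$v %*% co
    }
    t <- sv$u[, 1L, drop = FALSE] * sv$d[1L]
    for (it in seq_len(max_iter)) {
      t_old <- t
      to <- orth(t)
      w <- Xpinv_t(to)
      t <- Xc %*% w
      if (sqrt(sum((t - t_old)^2)) < tol * sqrt(sum(t^2))) break
    }
    to <- orth(t)                            # final, exactly Y-orthogonal
    w <- Xpinv_t(to)
    w <- w / sqrt(sum(w^2))
    p_load <- crossprod(Xc, to) / sum(to^2)
    Xc <- Xc - to %*% t(p_load)
    W[, k] <- w; P[, k] <- p_load; Tsc[, k] <- to
  }
  list(name = "osc", mean = mu, weights = W, loadings = P, scores = Tsc)
}

#' @rdname osc_fit
#' @param step a fitted OSC step.
#' @param X spectra to deflate.
#' @export
osc_apply <- function(step, X) {
  X <- as.matrix(X)
  if (ncol(X) != length(step$mean))
    stop_input("band mismatch: data %d, fitted OSC %d", ncol(X), length(step$mean))
  Xc <- sweep(X, 2L, step$mean)
  for (k in seq_len(ncol(step$weights))) {
    t <- Xc %*% step$weights[, k, drop = FALSE]
    t <- t / drop(crossprod(step$weights[, k], step$weights[, k]))
    Xc <- Xc - t %*% t(step$loadings[, k, drop = FALSE])
  }
  sweep(Xc, 2L, step$mean, `+`)
}

#' Mean centring with calibration means
#'
#' `mean_center_fit` stores the per-band calibration means;
#' `mean_center_apply` subtracts them from any matrix — held-out rows are
#' centred with the calibration means, never their own.
#'
#' @param X_cal calibration spectra.
#' @return `mean_center_fit`: a fitted step; `mean_center_apply`: centred data.
#' @export
mean_center_fit <- function(X_cal) {
  list(name = "mean_center", mean = colMeans(as.matrix(X_cal)))
}

#' @rdname mean_center_fit
#' @param step a fitted centring step.
#' @param X spectra to centre.
#' @export
mean_center_apply <- function(step, X) {
  X <- as.matrix(X)
  if (ncol(X) != length(step$mean))
    stop_input("band mismatch: data %d, fitted means %d", ncol(X), length(step$mean))
  sweep(X, 2L, step$mean)
}
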