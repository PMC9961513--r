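## NIPALS PLS2 core. X is deflated, Y is not. Columns of W are unit-norm
## weights; T holds the X scores. Stops early if X is exhausted (score
## norm ~ 0) and records the number of components actually extracted.
pls_nipals <- function(X, Y, ncomp, tol = 1e-12, max_iter = 200L) {
  X <- as.matrix(X); Y <- as.matrix(Y)
  n <- nrow(X); p <- ncol(X); q <- ncol(Y)
  mu_x <- colMeans(X); mu_y <- colMeans(Y)
  Xc <- sweep(X, 2L, mu_x); Yc <- sweep(Y, 2L, mu_y)
  ncomp <- min(ncomp, n - 1L, p)
  W <- P <- matrix(0, p, ncomp)
  Q <- matrix(0, q, ncomp)
  Tm <- matrix(0, n, ncomp)
  a_done <- 0L
  for (a in seq_len(ncomp)) {
    u <- Yc[, which.max(apply(Yc, 2L, stats::var)), drop = FALSE]
    t_score <- NULL
    for (it in seq_len(max_iter)) {
      w <- crossprod(Xc, u)
      nw <- sqrt(sum(w^2))
      if (nw < tol) break
      w <- w / nw
      t_new <- Xc %*% w
      qv <- crossprod(Yc, t_new) / drop(crossprod(t_new))
      u_new <- Yc %*% qv / drop(crossprod(qv))
      if (!is.null(t_score) &&
          sqrt(sum((t_new - t_score)^2)) < tol * sqrt(sum(t_new^2))) {
        t_score <- t_new; break
      }
      t_score <- t_new; u <- u_new
      if (q == 1L) break                    # single-column Y: one pass exact
    }
    if (is.null(t_score) || drop(crossprod(t_score)) < 1e-14) break
    tt <- drop(crossprod(t_score))
    p_load <- crossprod(Xc, t_score) / tt
    qv <- crossprod(Yc, t_score) / tt
    Xc <- Xc - t_score %*% t(p_load)
    W[, a] <- w; P[, a] <- p_load; Q[, a] <- qv; Tm[, a] <- t_score
    a_done <- a
  }
  list(ncomp = a_done, mu_x = mu_x, mu_y = mu_y,
       W = W[, seq_len(a_done), drop = FALSE],
       P = P[, seq_len(a_done), drop = FALSE],
       Q = Q[, seq_len(a_done), drop = FALSE],
       scores = Tm[, seq_len(a_done), drop = FALSE])
}

## Kernel PLS2 (crossprod-based, X-only deflation). Works entirely on
## X'X and X'Y, so the cost is independent of n once the crossprods are
## formed; algebraically equivalent to pls_nipals (the NIPALS weight is the
## dominant eigenvector of (X'Y)(X'Y)'). Used where many PLS fits on
## submatrices are needed (RMSECV fitness of the GA).
pls_kernel <- function(X, Y, ncomp) {
  X <- as.matrix(X); Y <- as.matrix(Y)
  mu_x <- colMeans(X); mu_y <- colMeans(Y)
  Xc <- sweep(X, 2L, mu_x); Yc <- sweep(Y, 2L, mu_y)
  M <- crossprod(Xc)                        # p x p
  A <- crossprod(Xc, Yc)                    # p x q
  p <- ncol(X); q <- ncol(Y)
  ncomp <- min(ncomp, nrow(X) - 1L, p)
  W <- P <- matrix(0, p, ncomp)
  Q <- matrix(0, q, ncomp)
  a_done <- 0L
  for (h in seq_len(ncomp)) {
    w <- if (q == 1L) A
         else A %*% eigen(crossprod(A), symmetric = TRUE)$vectors[, 1L]
    nw <- sqrt(sum(w^2))
    if (nw < 1e-14) break
    w <- w / nw
    Mw <- M %*% w
    tt <- drop(crossprod(w, Mw))            # = t't of the score
    if (tt < 1e-14) break
    p_load <- Mw / tt
    q_load <- crossprod(A, w) / tt
    M <- M - tt * tcrossprod(p_load)
    A <- A - tt * tcrossprod(p_load, q_load)
    W[, h] <- w; P[, h] <- p_load; Q[, h] <- q_load
    a_done <- h
  }
  list(ncomp = a_done, mu_x = mu_x, mu_y = mu_y,
       W = W[, seq_len(a_done), drop = FALSE],
       P = P[, seq_len(a_done), drop = FALSE],
       Q = Q[, seq_len(a_done), drop = FALSE])
}

## Regression coefficients for the first `a` components:
## B_a = W_a (P_a' W_a)^{-1} Q_a'.
pls_coef <- function(fit, a = fit$ncomp) {
  a <- min(a, fit$ncomp)
  if (a == 0L) return(matrix(0, length(fit$mu_x), length(fit$mu_y)))
  Wa <- fit$W[, 1:a, drop = FALSE]
  Pa <- fit$P[, 1:a, drop = FALSE]
  Qa <- fit$Q[, 1:a, drop = FALSE]
  Wa %*% solve(crossprod(Pa, Wa), t(Qa))
}

pls_predict <- function(fit, X, a = fit$ncomp) {
  sweep(sweep(as.matrix(X), 2L, fit$mu_x) %*% pls_coef(fit, a),
        2L, fit$mu_y, `+`)
}

## X-score rotation R = W (P'W)^{-1}; scores of new data = (X - mu) R.
pls_rotation <- function(fit, a = fit$ncomp) {
  a <- min(a, fit$ncomp)
  fit$W[, 1:a, drop = FALSE] %*%
    solve(crossprod(fit$P[, 1:a, drop = FALSE], fit$W[, 1:a, drop = FALSE]))
}

#' Fit a PLS-DA model
#'
#' Classes are coded as indicator columns and a NIPALS PLS2 regression of
#' the indicators on the (optionally pre-processed) spectra is fitted with
#' `n_lv` latent variables. Prediction assigns each sample to the class
#' with the largest predicted indicator value. The pre-processing chain is
#' fitted inside, on the calibration data only.
#'
#' @param X_cal calibration spectra matrix.
#' @param y_cal class labels (2 or more classes).
#' @param n_lv number of latent variables.
#' @param chain a [preprocess_chain()], preset name, or `NULL`.
#' @param wavelengths optional wavelength axis forwarded to the chain.
#' @return An object of class `plsda_model`.
#' @export
plsda_fit <- function(X_cal, y_cal, n_lv, chain = NULL, wavelengths = NULL) {
  X_cal <- as.matrix(X_cal)
  y_cal <- as.character(y_cal)
  classes <- sort(unique(y_cal))
  if (length(classes) < 2L) stop_input("PLS-DA needs >= 2 classes, got %d", length(classes))
  if (n_lv < 1L) stop_input("n_lv must be >= 1")
  fitted_chain <- if (is.null(chain)) NULL
                  else chain_fit(chain, X_cal, y_cal, wavelengths)
  Xp <- if (is.null(fitted_chain)) X_cal else chain_apply(fitted_chain, X_cal)
  Y <- class_indicator(y_cal, classes)
  fit <- pls_nipals(Xp, Y, n_lv)
  structure(list(pls = fit, n_lv = fit$ncomp, classes = classes,
                 chain = fitted_chain),
            class = "plsda_model")
}

#' @export
predict.plsda_model <- function(object, newdata, type = c("class", "indicator"),
                                ...) {
  type <- match.arg(type)
  X <- as.matrix(newdata)
  if (!is.null(object$chain)) X <- chain_apply(object$chain, X)
  Yhat <- pls_predict(object$pls, X)
  colnames(Yhat) <- object$classes
  if (type == "indicator") return(Yhat)
  object$classes[max.col(Yhat, ties.method = "first")]
}

#' Cross-validate the latent-variable count of PLS-DA
#'
#' For each fold of the CV plan the chain and model are refitted on the
#' fold's training rows and the held-out blind is predicted; per-LV mean
#' class errors are aggregated over the pooled CV predictions. The
#' selected LV count minimises the mean CV class error (ties go to fewer
#' LVs).
#'
#' @param X_cal,y_cal calibration spectra and labels.
#' @param chain pre-processing chain spec (refitted inside every fold).
#' @param lv_grid candidate LV counts.
#' @param cv a [venetian_blinds()] plan.
#' @param wavelengths optional wavelength axis.
#' @return List with `selected_lv`, `cv_table` (LV, mean class error in
#'   percent), and the pooled CV predictions at the selected LV.
#' @export
plsda_cv <- function(X_cal, y_cal, chain = NULL, lv_grid = 1:20,
                     cv = venetian_blinds(nrow(X_cal)), wavelengths = NULL) {
  X_cal <- as.matrix(X_cal); y_cal <- as.character(y_cal)
  classes <- sort(unique(y_cal))
  max_rank <- min(nrow(X_cal) - max(tabulate(cv$assignment)) - 1L, ncol(X_cal))
  lv_grid <- sort(unique(as.integer(lv_grid)))
  if (any(lv_grid > max_rank)) {
    warning(sprintf("lv_grid trimmed to <= %d (training-fold rank bound)", max_rank))
    lv_grid <- lv_grid[lv_grid <= max_rank]
  }
  if (length(lv_grid) == 0L) stop_input("empty lv_grid after rank trimming")
  max_lv <- max(lv_grid)
  pred <- array(NA_character_, c(nrow(X_cal), length(lv_grid)))
  for (f in sort(unique(cv$assignment))) {
    hold <- which(cv$assignment == f)
    train <- setdiff(seq_len(nrow(X_cal)), hold)
    fc <- if (is.null(chain)) NULL
          else chain_fit(chain, X_cal[train, , drop = FALSE], y_cal[train],
                         wavelengths)
    Xtr <- X_cal[train, , drop = FALSE]
    Xho <- X_cal[hold, , drop = FALSE]
    if (!is.null(fc)) { Xtr <- chain_apply(fc, Xtr); Xho <- chain_apply(fc, Xho) }
    fit <- pls_nipals(Xtr, class_indicator(y_cal[train], classes), max_lv)
    for (j in seq_along(lv_grid)) {
      Yhat <- pls_predict(fit, Xho, lv_grid[j])
      pred[hold, j] <- classes[max.col(Yhat, ties.method = "first")]
    }
  }
  mean_ce <- vapply(seq_along(lv_grid), function(j)
    mean(per_class_report(y_cal, pred[, j], classes)$class_error), numeric(1))
  best <- lv_grid[which.min(mean_ce)]       # which.min takes the first = fewest
  list(selected_lv = best,
       cv_table = data.frame(lv = lv_grid, mean_class_error = mean_ce),
       cv_pred = pred[, match(best, lv_grid)])
}

#' PLS data compression
#'
#' Projects spectra onto the first `n_lv` PLS latent variables of a
#' supervised PLS2 fit (indicators as Y). Used to compress the x-block
#' before the C-SVM and ANN discriminant models.
#'
#' @param X_cal,y_cal calibration spectra and labels.
#' @param n_lv number of latent variables retained.
#' @return List with `scores` (calibration score matrix) and `project`,
#'   a function mapping new spectra to the same score space.
#' @export
pls_compress <- function(X_cal, y_cal, n_lv) {
  X_cal <- as.matrix(X_cal)
  fit <- pls_nipals(X_cal, class_indicator(as.character(y_cal)), n_lv)
  R <- pls_rotation(fit)
  mu <- fit$mu_x
  list(scores = fit$scores, n_lv = fit$ncomp,
       project = function(X) sweep(as.matrix(X), 2L, mu) %*% R)
}
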