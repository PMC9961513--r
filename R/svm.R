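## RBF kernel matrix K[i, j] = exp(-gamma * ||a_i - b_j||^2).
rbf_kernel <- function(A, B, gamma) {
  A <- as.matrix(A); B <- as.matrix(B)
  d2 <- outer(rowSums(A^2), rowSums(B^2), `+`) - 2 * tcrossprod(A, B)
  d2[d2 < 0] <- 0
  exp(-gamma * d2)
}

## Platt SMO for a binary soft-margin SVM on a precomputed kernel.
## y in {-1, +1}; decision f(x) = sum_j alpha_j y_j K(x_j, x) + b.
## Deterministic: the second working-set index is chosen by maximal
## |E1 - E2| with ties to the lowest index; no randomness anywhere.
smo_binary <- function(K, y, C, tol = 1e-3, eps = 1e-12, max_sweeps = 2000L) {
  n <- length(y)
  alpha <- numeric(n)
  b <- 0
  fpart <- numeric(n)                       # sum_j alpha_j y_j K[, j]

  take_step <- function(i1, i2) {
    if (i1 == i2) return(FALSE)
    a1 <- alpha[i1]; a2 <- alpha[i2]
    y1 <- y[i1]; y2 <- y[i2]
    E1 <- fpart[i1] + b - y1; E2 <- fpart[i2] + b - y2
    s <- y1 * y2
    if (s > 0) { L <- max(0, a1 + a2 - C); H <- min(C, a1 + a2) }
    else { L <- max(0, a2 - a1); H <- min(C, C + a2 - a1) }
    if (H - L < eps) return(FALSE)
    eta <- K[i1, i1] + K[i2, i2] - 2 * K[i1, i2]
    if (eta <= eps) return(FALSE)           # degenerate curvature: skip
    a2new <- min(max(a2 + y2 * (E1 - E2) / eta, L), H)
    if (abs(a2new - a2) < eps * (a2new + a2 + eps)) return(FALSE)
    a1new <- a1 + s * (a2 - a2new)
    d1 <- y1 * (a1new - a1); d2 <- y2 * (a2new - a2)
    b1 <- b - E1 - d1 * K[i1, i1] - d2 * K[i1, i2]
    b2 <- b - E2 - d1 * K[i1, i2] - d2 * K[i2, i2]
    b <<- if (a1new > eps && a1new < C - eps) b1
          else if (a2new > eps && a2new < C - eps) b2
          else (b1 + b2) / 2
    fpart <<- fpart + d1 * K[, i1] + d2 * K[, i2]
    alpha[i1] <<- a1new; alpha[i2] <<- a2new
    TRUE
  }

  examine <- function(i2) {
    E2 <- fpart[i2] + b - y[i2]
    r2 <- E2 * y[i2]
    if ((r2 < -tol && alpha[i2] < C) || (r2 > tol && alpha[i2] > 0)) {
      nb <- which(alpha > eps & alpha < C - eps)
      if (length(nb) > 1L) {
        Enb <- fpart[nb] + b - y[nb]
        i1 <- nb[which.max(abs(E2 - Enb))]
        if (take_step(i1, i2)) return(TRUE)
      }
      for (i1 in c(nb, seq_len(n)))         # deterministic fallback scans
        if (take_step(i1, i2)) return(TRUE)
    }
    FALSE
  }

  examine_all <- TRUE
  for (sweep_i in seq_len(max_sweeps)) {
    changed <- 0L
    idx <- if (examine_all) seq_len(n) else which(alpha > eps & alpha < C - eps)
    for (i2 in idx) changed <- changed + examine(i2)
    if (examine_all) { if (changed == 0L) break; examine_all <- FALSE }
    else if (changed == 0L) examine_all <- TRUE
  }
  list(alpha = alpha, b = b, decision = fpart + b)
}

#' Fit an RBF C-SVM on PLS scores
#'
#' Soft-margin support vector machine with a radial basis function kernel,
#' trained by a deterministic SMO solver. Multi-class problems use
#' one-vs-one voting with ties broken by the lowest class index. Intended
#' to run on PLS-compressed scores (see [pls_compress()]).
#'
#' @param scores numeric matrix of (compressed) predictors.
#' @param y_cal class labels.
#' @param config list with `C` (cost, > 0) and `gamma` (RBF width, > 0).
#' @return An object of class `csvm_model`.
#' @export
svm_fit <- function(scores, y_cal, config = list(C = 1, gamma = 0.32)) {
  scores <- as.matrix(scores)
  y_cal <- as.character(y_cal)
  C <- config$C %||% 1; gamma <- config$gamma %||% 0.32
  if (C <= 0 || gamma <= 0) stop_input("SVM needs C > 0 and gamma > 0")
  classes <- sort(unique(y_cal))
  if (length(classes) < 2L) stop_input("SVM needs >= 2 classes")
  pairs <- utils::combn(length(classes), 2L)
  machines <- vector("list", ncol(pairs))
  for (m in seq_len(ncol(pairs))) {
    ci <- classes[pairs[1L, m]]; cj <- classes[pairs[2L, m]]
    idx <- which(y_cal %in% c(ci, cj))
    yb <- ifelse(y_cal[idx] == ci, 1, -1)
    Xb <- scores[idx, , drop = FALSE]
    fit <- smo_binary(rbf_kernel(Xb, Xb, gamma), yb, C)
    sv <- which(fit$alpha > 1e-12)
    machines[[m]] <- list(pos = ci, neg = cj,
                          sv_x = Xb[sv, , drop = FALSE],
                          sv_coef = fit$alpha[sv] * yb[sv],
                          b = fit$b)
  }
  structure(list(machines = machines, classes = classes, gamma = gamma, C = C),
            class = "csvm_model")
}

#' @export
predict.csvm_model <- function(object, newdata, ...) {
  X <- as.matrix(newdata)
  votes <- matrix(0L, nrow(X), length(object$classes),
                  dimnames = list(NULL, object$classes))
  for (m in object$machines) {
    f <- drop(rbf_kernel(X, m$sv_x, object$gamma) %*% m$sv_coef) + m$b
    winner <- ifelse(f >= 0, m$pos, m$neg)
    for (cl in unique(winner))
      votes[winner == cl, cl] <- votes[winner == cl, cl] + 1L
  }
  object$classes[max.col(votes, ties.method = "first")]
}
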