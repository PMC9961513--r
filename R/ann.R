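#' Fit a single-hidden-layer ANN discriminant model
#'
#' Feed-forward network with one logistic hidden layer (default 10 nodes)
#' and softmax class outputs, trained by full-batch BFGS on the
#' cross-entropy loss with a small L2 weight penalty for numerical
#' stability. Fully deterministic given `config$seed` (mandatory), which
#' controls only the weight initialisation. Intended to run on
#' PLS-compressed scores (see [pls_compress()]).
#'
#' @param scores numeric matrix of (compressed) predictors; must be finite.
#' @param y_cal class labels.
#' @param config list with `hidden_nodes` (default 10), `max_epochs`
#'   (BFGS iteration cap, default 500), `decay` (L2 penalty, default 1e-4)
#'   and `seed` (required).
#' @return An object of class `annda_model`.
#' @export
ann_fit <- function(scores, y_cal,
                    config = list(hidden_nodes = 10L, max_epochs = 500L,
                                  seed = 1L)) {
  X <- as.matrix(scores)
  if (!all(is.finite(X))) stop_input("ANN inputs must be finite")
  y_cal <- as.character(y_cal)
  classes <- sort(unique(y_cal))
  if (length(classes) < 2L) stop_input("ANN needs >= 2 classes")
  h <- as.integer(config$hidden_nodes %||% 10L)
  if (h < 1L) stop_input("hidden_nodes must be >= 1")
  maxit <- as.integer(config$max_epochs %||% 500L)
  decay <- config$decay %||% 1e-4
  if (is.null(config$seed)) stop_input("ANN config requires a seed")
  d <- ncol(X); K <- length(classes); n <- nrow(X)
  Y <- class_indicator(y_cal, classes)
  # standardize inputs for conditioning; fold into the stored model
  mu <- colMeans(X); sd_ <- apply(X, 2L, stats::sd); sd_[sd_ == 0] <- 1
  Xs <- sweep(sweep(X, 2L, mu), 2L, sd_, `/`)

  npar <- d * h + h + h * K + K
  unpack <- function(th) {
    i <- 0L
    W1 <- matrix(th[i + seq_len(d * h)], d, h); i <- i + d * h
    b1 <- th[i + seq_len(h)]; i <- i + h
    W2 <- matrix(th[i + seq_len(h * K)], h, K); i <- i + h * K
    b2 <- th[i + seq_len(K)]
    list(W1 = W1, b1 = b1, W2 = W2, b2 = b2)
  }
  forward <- function(pp, Xin) {
    H <- 1 / (1 + exp(-(sweep(Xin %*% pp$W1, 2L, pp$b1, `+`))))
    Z <- sweep(H %*% pp$W2, 2L, pp$b2, `+`)
    Z <- Z - apply(Z, 1L, max)
    P <- exp(Z); P <- P / rowSums(P)
    list(H = H, P = P)
  }
  loss <- function(th) {
    pp <- unpack(th)
    fw <- forward(pp, Xs)
    -sum(Y * log(pmax(fw$P, 1e-300))) / n +
      decay * (sum(pp$W1^2) + sum(pp$W2^2))
  }
  grad <- function(th) {
    pp <- unpack(th)
    fw <- forward(pp, Xs)
    dZ <- (fw$P - Y) / n
    gW2 <- crossprod(fw$H, dZ) + 2 * decay * pp$W2
    gb2 <- colSums(dZ)
    dH <- dZ %*% t(pp$W2) * fw$H * (1 - fw$H)
    gW1 <- crossprod(Xs, dH) + 2 * decay * pp$W1
    gb1 <- colSums(dH)
    c(as.vector(gW1), gb1, as.vector(gW2), gb2)
  }
  th0 <- with_seed(as.integer(config$seed),
                   stats::runif(npar, -0.5, 0.5) / sqrt(d + 1))
  opt <- stats::optim(th0, loss, grad, method = "BFGS",
                      control = list(maxit = maxit, reltol = 1e-12))
  structure(list(par = unpack(opt$par), classes = classes,
                 center = mu, scale = sd_, value = opt$value,
                 config = list(hidden_nodes = h, max_epochs = maxit,
                               decay = decay, seed = config$seed)),
            class = "annda_model")
}

#' @export
predict.annda_model <- function(object, newdata, type = c("class", "prob"),
                                ...) {
  type <- match.arg(type)
  X <- sweep(sweep(as.matrix(newdata), 2L, object$center), 2L, object$scale, `/`)
  pp <- object$par
  H <- 1 / (1 + exp(-(sweep(X %*% pp$W1, 2L, pp$b1, `+`))))
  Z <- sweep(H %*% pp$W2, 2L, pp$b2, `+`)
  Z <- Z - apply(Z, 1L, max)
  P <- exp(Z); P <- P / rowSums(P)
  colnames(P) <- object$classes
  if (type == "prob") return(P)
  object$classes[max.col(P, ties.method = "first")]
}
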