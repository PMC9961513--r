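# Shared fixture builders. Everything is generated in code at test time.

# Constant-valued cube with a given spatial size and band count.
flat_cube <- function(value, lines = 4, pixels = 5, bands = 6,
                      wavelengths = seq(1000, 2500, length.out = bands),
                      is_reflectance = FALSE) {
  hypercube(array(value, c(lines, pixels, bands)), wavelengths,
            is_reflectance = is_reflectance)
}

# Reflectance cube that is `bg` everywhere except rectangular blobs, each a
# list(rows =, cols =, value =).
blob_cube <- function(blobs, lines = 20, pixels = 20, bands = 8, bg = 0) {
  a <- array(bg, c(lines, pixels, bands))
  for (b in blobs) a[b$rows, b$cols, ] <- b$value
  hypercube(a, seq(1000, 2500, length.out = bands), is_reflectance = TRUE)
}

# Two-class spectra with a mean shift of `sep` standard deviations on all
# bands; deterministic under `seed`.
gauss_classes <- function(n_per = 25, bands = 30, sep = 5, sd = 1, seed = 7) {
  seedhsi:::with_seed(seed, {
    X <- rbind(matrix(rnorm(n_per * bands, 0, sd), n_per, bands),
               matrix(rnorm(n_per * bands, sep * sd, sd), n_per, bands))
    list(X = X, y = rep(c("A", "B"), each = n_per))
  })
}

# The GA band-recovery world: 200 x 288 spectra whose classes differ only
# inside bands 100:119 (a flat-top run of four absorbance features), mild
# scatter, iid noise.
ga_world <- function(seed = 11L) {
  wl <- seq(1000, 2500, length.out = 288)
  sig <- data.frame(center = wl[c(102, 107, 112, 117)], amplitude = 0.02,
                    width = 14)
  spec <- sim_spec(n_per_class = c(Ep = 100L, Em = 100L),
                   class_signals = list(Ep = sig, Em = sig[0, ]),
                   scatter_mult = c(0.98, 1.02),
                   scatter_add = c(-0.005, 0.005),
                   noise_sd = 0.01, rng_seed = seed)
  c(make_spectra(spec), list(informative = 100:119, wavelengths = wl))
}

# Naive Kennard-Stone oracle: recomputes every max-min distance from the
# full distance matrix at each step (no incremental caching), ties to the
# lowest index. Independent of the package implementation.
ks_oracle <- function(X, n_cal) {
  D <- as.matrix(dist(X))^2
  n <- nrow(X)
  best <- c(Inf, NA, NA)
  mx <- -Inf
  pair <- NULL
  for (i in seq_len(n - 1)) for (j in (i + 1):n)
    if (D[i, j] > mx) { mx <- D[i, j]; pair <- c(i, j) }
  sel <- pair
  while (length(sel) < n_cal) {
    cand <- setdiff(seq_len(n), sel)
    dmin <- vapply(cand, function(k) min(D[k, sel]), numeric(1))
    sel <- c(sel, cand[which.max(dmin)])
  }
  sort(sel)
}

# Pooled venetian-blinds CV accuracy (percent) of an lv-component PLS-DA
# on the given bands.
cv_accuracy <- function(X, y, bands = seq_len(ncol(X)), lv = 5,
                        n_splits = 10) {
  cvp <- venetian_blinds(nrow(X), n_splits)
  pred <- character(nrow(X))
  for (f in seq_len(n_splits)) {
    hold <- which(cvp$assignment == f)
    train <- setdiff(seq_len(nrow(X)), hold)
    fit <- plsda_fit(X[train, bands, drop = FALSE], y[train], lv)
    pred[hold] <- predict(fit, X[hold, bands, drop = FALSE])
  }
  mean(pred == y) * 100
}
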