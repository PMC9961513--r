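test_that("detrend removes exactly the fitted polynomial", {
  lin <- matrix(3 + 0.5 * (1:40), 1)
  expect_equal(max(abs(detrend(lin, 1))), 0, tolerance = 1e-10)
  quad <- matrix(1 - 2 * (1:40) + 0.1 * (1:40)^2, 1)
  expect_equal(max(abs(detrend(quad, 2))), 0, tolerance = 1e-8)

  # brute-force normal-equations oracle on a random 5-band row, order 1
  row <- seedhsi:::with_seed(13, matrix(rnorm(5), 1))
  t5 <- 2 * (0:4) / 4 - 1                     # the scaled abscissa used inside
  A <- cbind(1, t5)
  beta <- solve(t(A) %*% A, t(A) %*% drop(row))
  expect_equal(drop(detrend(row, 1)), drop(row) - drop(A %*% beta))

  expect_error(detrend(matrix(1:4, 1), 4), "n_bands")
  expect_error(detrend(matrix(1:4, 1), 0), ">= 1")
})

test_that("weighted least-squares baseline hugs the lower envelope", {
  t50 <- seq(-1, 1, length.out = 50)
  base <- 1 + 0.5 * t50 + 2 * t50^2
  # a spectrum that IS the order-2 baseline leaves ~0 residual
  expect_equal(max(abs(wls_baseline(matrix(base, 1), 2))), 0, tolerance = 1e-8)
  # baseline + one tall positive peak: peak recovered within 5%, flat off-peak
  pk <- base; pk[25] <- pk[25] + 5
  r <- drop(wls_baseline(matrix(pk, 1), 2))
  expect_lt(abs(r[25] - 5) / 5, 0.05)
  expect_lt(max(abs(r[-(23:27)])), 0.05)
  # all-zero row stays zero
  expect_equal(max(abs(wls_baseline(matrix(0, 1, 30), 2))), 0)
})

test_that("Savitzky-Golay derivatives are exact for polynomials", {
  i <- 0:49
  a <- 0.7
  d2 <- sg_derivative(matrix(a * i^2, 1), 2, 2, 15)
  expect_equal(unique(round(drop(d2), 10)), 2 * a)   # everywhere, edges refit
  d1 <- sg_derivative(matrix(rep(3.2, 50), 1), 1, 2, 15)
  expect_equal(max(abs(d1)), 0, tolerance = 1e-12)

  # sine vs analytic derivative: bounded deviation for a 15-point window
  x <- seq(0, 4 * pi, length.out = 200)
  h <- x[2] - x[1]
  d <- drop(sg_derivative(matrix(sin(x), 1), 1, 2, 15)) / h
  interior <- 8:193
  expect_lt(max(abs(d[interior] - cos(x[interior]))), 0.03)

  expect_error(sg_derivative(matrix(1:20, 1), 1, 2, 14), "odd")
  expect_error(sg_derivative(matrix(1:20, 1), 2, 1, 15), "poly_order")
})

test_that("SNV standardizes each row with the sample sd", {
  expect_equal(drop(snv(matrix(c(1, 2, 3), 1))), c(-1, 0, 1))
  X <- seedhsi:::with_seed(5, matrix(rnorm(60), 4, 15))
  Z <- snv(X)
  expect_equal(rowMeans(Z), rep(0, 4))
  expect_equal(apply(Z, 1, sd), rep(1, 4))
  # affine invariance for positive scaling
  expect_equal(snv(2.5 * X + 7), Z)
  expect_error(snv(matrix(1, 2, 5)), "zero-variance")
})

test_that("EMSC inverts the scatter model against the fitted reference", {
  X <- seedhsi:::with_seed(6, matrix(rnorm(40 * 30, 10), 40, 30))
  wl <- seq(1000, 2500, length.out = 30)
  st <- emsc_fit(X, wavelengths = wl, poly_order = 2)
  m <- colMeans(X)
  expect_equal(drop(emsc_apply(st, matrix(3 + 2 * m, 1))), m)
  expect_equal(drop(emsc_apply(st, matrix(m, 1))), m)
  # wavelength-linear contamination removed (verified against a direct solve)
  lam <- 2 * (wl - min(wl)) / diff(range(wl)) - 1
  x <- m + 0.01 * lam
  D <- cbind(1, m, lam, lam^2)
  cf <- qr.solve(D, x)
  direct <- (x - cf[1] - cf[3] * lam - cf[4] * lam^2) / cf[2]
  cor1 <- drop(emsc_apply(st, matrix(x, 1)))
  expect_equal(cor1, direct)
  expect_equal(cor1, m, tolerance = 1e-8)
  # degenerate multiplicative term errors
  expect_error(emsc_apply(st, matrix(0.001 * lam, 1) + 0.2), "degenerate")
})

test_that("OSC removes Y-orthogonal structure and nothing correlated", {
  set.seed(21)
  n <- 60
  y <- rep(c("A", "B"), each = n / 2)
  Y <- seedhsi:::class_indicator(y)
  sig <- as.numeric(y == "A") - 0.5          # Y-correlated score
  conf <- seedhsi:::with_seed(22, rnorm(n))   # orthogonal-ish nuisance score
  conf <- conf - Y %*% solve(crossprod(Y), crossprod(Y, conf))  # exactly orthogonal
  dir_sig <- seedhsi:::with_seed(23, rnorm(30))
  dir_conf <- seedhsi:::with_seed(24, rnorm(30))
  X <- sig %*% t(dir_sig) + 5 * conf %*% t(dir_conf) +
    seedhsi:::with_seed(25, matrix(rnorm(n * 30, 0, 0.01), n, 30))

  st <- osc_fit(X, Y, 1)
  # calibration scores exactly orthogonal to every indicator column
  expect_lt(max(abs(crossprod(st$scores, Y))), 1e-8)
  # the nuisance direction's variance share collapses after correction
  Xc <- osc_apply(st, X)
  share <- function(M, d) var(as.vector(scale(M, scale = FALSE) %*% d))
  expect_lt(share(Xc, dir_conf) / share(X, dir_conf), 0.01)
  # deflation reduces the dominant variance on refit
  sv_before <- svd(scale(X, scale = FALSE))$d[1]
  sv_after <- svd(scale(Xc, scale = FALSE))$d[1]
  expect_lt(sv_after, sv_before)
  expect_error(osc_fit(X[1:3, ], Y[1:3, ], 5), "rank")
})

test_that("mean centring applies calibration means to held-out rows", {
  st <- mean_center_fit(matrix(c(1, 3, 3, 5), 2, 2))
  expect_equal(mean_center_apply(st, matrix(c(1, 3, 3, 5), 2, 2)),
               matrix(c(-1, 1, -1, 1), 2, 2))
  expect_equal(drop(mean_center_apply(st, matrix(c(2, 4), 1))), c(0, 0))
  expect_error(mean_center_apply(st, matrix(1, 1, 3)), "mismatch")
})

test_that("chains compose, freeze state, and honour train/test hygiene", {
  w <- ga_world(2)
  X <- w$table$X[1:60, ]
  y <- w$table$labels$class[1:60]
  wl <- w$wavelengths

  # the six presets have the documented step sequences
  preset_steps <- function(p)
    vapply(preprocess_chain(p)$steps, `[[`, character(1), "name")
  expect_equal(preset_steps("pt1"), c("detrend", "wls_baseline", "mean_center"))
  expect_equal(preset_steps("pt2"), c("detrend", "wls_baseline",
                                      "sg_derivative", "mean_center"))
  expect_equal(preset_steps("pt3"), c("detrend", "wls_baseline",
                                      "sg_derivative", "emsc", "mean_center"))
  expect_equal(preset_steps("pt4"), c("detrend", "wls_baseline", "osc",
                                      "mean_center"))
  expect_equal(preset_steps("pt5"), c("detrend", "wls_baseline",
                                      "sg_derivative", "osc", "mean_center"))
  expect_equal(preset_steps("pt6"), c("detrend", "wls_baseline",
                                      "sg_derivative", "emsc", "osc",
                                      "mean_center"))
  d2p <- preprocess_chain("pt6")$steps[[3]]$params
  expect_equal(d2p, list(deriv_order = 2L, poly_order = 2L, window = 15L))
  expect_equal(preprocess_chain("pt6")$steps[[2]]$params$order, 2L)

  # empty chain is the identity; [snv] chain equals the direct call
  id <- chain_fit(preprocess_chain("none"), X)
  expect_equal(chain_apply(id, X), X)
  ch_snv <- chain_fit(preprocess_chain(list("snv")), X)
  expect_equal(chain_apply(ch_snv, X), snv(X))

  # fitted chain applied twice gives identical output; row count preserved
  fc <- chain_fit("pt6", X, y, wl)
  out1 <- chain_apply(fc, X)
  expect_identical(out1, chain_apply(fc, X))
  expect_equal(dim(out1), dim(X))

  # OSC without labels is rejected
  expect_error(chain_fit("pt6", X), "OSC")

  # hygiene: applying the calibration-fitted chain to held-out rows differs
  # from refitting on those rows (the sets differ, so state must differ)
  Xte <- w$table$X[61:120, ]
  yte <- w$table$labels$class[61:120]
  apply_cal <- chain_apply(fc, Xte)
  refit <- chain_apply(chain_fit("pt6", Xte, yte, wl), Xte)
  expect_gt(max(abs(apply_cal - refit)), 1e-8)

  # row-wise transforms commute with row permutation and duplication
  perm <- c(3, 1, 2)
  small <- X[1:3, ]
  for (f in list(function(M) detrend(M, 2),
                 function(M) sg_derivative(M, 2, 2, 15),
                 snv,
                 function(M) wls_baseline(M, 2))) {
    expect_equal(f(small)[perm, ], f(small[perm, ]))
    expect_equal(f(small[c(1, 1, 2, 3), ])[1, ], f(small)[1, ])
  }
})
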