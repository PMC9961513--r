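test_that("Kennard-Stone picks exterior points deterministically", {
  X <- matrix(c(0, 1, 10), 3, 1)
  s <- kennard_stone_split(X, 2 / 3)
  expect_equal(s$calibration_indices, c(1, 3))
  expect_equal(s$prediction_indices, 2)
  # reproducible
  X2 <- seedhsi:::with_seed(8, matrix(rnorm(60), 30, 2))
  expect_identical(kennard_stone_split(X2, 0.8), kennard_stone_split(X2, 0.8))
  # duplicate-only data: deterministic lowest-index tie-break
  dup <- matrix(1, 6, 3)
  sd_ <- kennard_stone_split(dup, 0.5)
  expect_equal(sd_$calibration_indices, 1:3)
  # calibration share within one row of the request
  expect_equal(length(kennard_stone_split(X2, 0.8)$calibration_indices), 24)
})

test_that("Kennard-Stone agrees with the naive oracle on small datasets", {
  for (draw in 1:50) {
    n <- 5 + (draw %% 8)
    X <- seedhsi:::with_seed(1000 + draw, matrix(rnorm(n * 3), n, 3))
    n_cal <- max(2, ceiling(0.7 * n))
    got <- kennard_stone_split(X, 0.7)$calibration_indices
    expect_equal(got, ks_oracle(X, n_cal), info = paste("draw", draw))
  }
})

test_that("venetian blinds assign row i to fold i mod n_splits", {
  cv <- venetian_blinds(20, 10)
  for (f in 1:10) expect_equal(which(cv$assignment == f), c(f, f + 10))
  expect_equal(venetian_blinds(10, 10)$assignment, 1:10)  # leave-one-out
  for (n in c(7, 23, 101)) {
    a <- venetian_blinds(n, 10)$assignment
    expect_equal(sort(unlist(lapply(1:10, function(f) which(a == f)))), 1:n)
    expect_lte(diff(range(tabulate(a))), 1)
  }
  expect_error(venetian_blinds(20, 1), "n_splits")
  expect_error(venetian_blinds(1, 10), "n >= 2")
  # more folds than rows degrades gracefully to leave-one-out
  expect_equal(venetian_blinds(5, 10)$assignment, 1:5)
})

test_that("PLS-DA separates well-separated Gaussian classes", {
  g <- gauss_classes(n_per = 30, bands = 288, sep = 5, seed = 7)
  fit <- plsda_fit(g$X, g$y, 3)
  expect_equal(mean(predict(fit, g$X) != g$y), 0)
  # successive LV scores mutually orthogonal
  Tm <- fit$pls$scores
  off <- crossprod(Tm) - diag(diag(crossprod(Tm)))
  expect_lt(max(abs(off)), 1e-6)
  # n_lv = 1 on 1-D separable data recovers the discriminating direction
  one <- cbind(c(rnorm(20, 0, 0.1), rnorm(20, 3, 0.1)))
  yy <- rep(c("A", "B"), each = 20)
  f1 <- plsda_fit(one, yy, 1)
  expect_gt(abs(cor(f1$pls$scores[, 1], as.numeric(yy == "B"))), 0.99)
  # duplicating every calibration row leaves the fitted directions unchanged
  f2 <- plsda_fit(g$X[rep(1:60, 2), ], g$y[rep(1:60, 2)], 3)
  expect_equal(abs(f2$pls$W), abs(fit$pls$W), tolerance = 1e-6)
  expect_error(plsda_fit(g$X, rep("A", 60), 2), "classes")
})

test_that("PLS-DA CV selects few LVs on separable data, chance on noise", {
  g <- gauss_classes(n_per = 30, bands = 50, sep = 5, seed = 7)
  sel <- plsda_cv(g$X, g$y, lv_grid = 1:6, cv = venetian_blinds(60))
  expect_lte(sel$selected_lv, 3)
  expect_lt(min(sel$cv_table$mean_class_error), 1)
  # label renaming leaves CV error invariant
  sel2 <- plsda_cv(g$X, ifelse(g$y == "A", "zeta", "eta"), lv_grid = 1:6,
                   cv = venetian_blinds(60))
  expect_equal(sel2$cv_table$mean_class_error, sel$cv_table$mean_class_error)
  # pure-noise labels: CV class error near 50% for two balanced classes
  # (labels shuffled so venetian folds are class-mixed)
  noise <- seedhsi:::with_seed(31, list(
    X = matrix(rnorm(400 * 30), 400, 30),
    y = sample(rep(c("A", "B"), 200))))
  seln <- plsda_cv(noise$X, noise$y, lv_grid = c(2, 5), cv = venetian_blinds(400))
  expect_gt(min(seln$cv_table$mean_class_error), 40)
  expect_lt(max(seln$cv_table$mean_class_error), 60)
})

test_that("PLS compression is lossless at full rank and consistent", {
  g <- gauss_classes(n_per = 15, bands = 10, sep = 4, seed = 9)
  comp <- pls_compress(g$X, g$y, 10)
  # projecting the calibration data reproduces the stored scores
  expect_equal(comp$project(g$X), comp$scores, tolerance = 1e-8,
               ignore_attr = TRUE)
  # full-rank limit: scores retain all X variance (reconstruction via loadings)
  fit <- seedhsi:::pls_nipals(g$X, seedhsi:::class_indicator(g$y), 10)
  Xc <- sweep(g$X, 2, fit$mu_x)
  expect_lt(max(abs(Xc - fit$scores %*% t(fit$P))), 1e-8)
  # compressed scores feed a linear rule that matches PLS-DA predictions
  pl <- plsda_fit(g$X, g$y, 3)
  comp3 <- pls_compress(g$X, g$y, 3)
  centroid <- rbind(colMeans(comp3$scores[g$y == "A", , drop = FALSE]),
                    colMeans(comp3$scores[g$y == "B", , drop = FALSE]))
  lin <- c("A", "B")[apply(comp3$project(g$X), 1, function(s)
    which.min(colSums((t(centroid) - s)^2)))]
  expect_equal(lin, predict(pl, g$X))
})

test_that("C-SVM solves separable, XOR and permutation-invariant problems", {
  g <- gauss_classes(n_per = 20, bands = 2, sep = 6, seed = 15)
  m <- svm_fit(g$X, g$y, list(C = 1e3, gamma = 0.5))
  expect_equal(mean(predict(m, g$X) != g$y), 0)
  # XOR needs the kernel
  sc <- matrix(c(0, 0, 0, 1, 1, 0, 1, 1), 4, 2, byrow = TRUE)
  yx <- c("p", "n", "n", "p")
  expect_equal(predict(svm_fit(sc, yx, list(C = 100, gamma = 2)), sc), yx)
  # joint permutation of training rows leaves predictions unchanged
  perm <- seedhsi:::with_seed(77, sample(40))
  m2 <- svm_fit(g$X[perm, ], g$y[perm], list(C = 1e3, gamma = 0.5))
  grid <- seedhsi:::with_seed(78, matrix(rnorm(20), 10, 2))
  expect_equal(predict(m2, grid), predict(m, grid))
  # 3-class one-vs-one
  X3 <- rbind(g$X, matrix(rnorm(40, 12), 20, 2))
  y3 <- c(g$y, rep("C", 20))
  expect_equal(mean(predict(svm_fit(X3, y3, list(C = 1e3, gamma = 0.5)), X3)
                    != y3), 0)
  expect_error(svm_fit(g$X, g$y, list(C = -1, gamma = 1)), "C > 0")
})

test_that("ANN-DA is seed-deterministic and fits separable scores", {
  g <- gauss_classes(n_per = 20, bands = 4, sep = 5, seed = 16)
  cfg <- list(hidden_nodes = 10, max_epochs = 300, seed = 42)
  a1 <- ann_fit(g$X, g$y, cfg)
  a2 <- ann_fit(g$X, g$y, cfg)
  expect_identical(predict(a1, g$X), predict(a2, g$X))
  expect_equal(unname(a1$par$W1), unname(a2$par$W1))
  expect_equal(mean(predict(a1, g$X) != g$y), 0)
  # a richer hidden layer does no worse on the same seed schedule
  small <- ann_fit(g$X, g$y, list(hidden_nodes = 2, max_epochs = 300, seed = 42))
  err_small <- mean(predict(small, g$X) != g$y)
  err_big <- mean(predict(a1, g$X) != g$y)
  expect_lte(err_big, err_small + 0.05)
  expect_error(ann_fit(matrix(c(1, NA, 2, 3), 2), c("a", "b"),
                       list(seed = 1)), "finite")
  expect_error(ann_fit(g$X, g$y, list(hidden_nodes = 10)), "seed")
})

test_that("evaluate_model reports all phases and is leakage-free", {
  w <- ga_world(3)
  tab <- spectra_table(w$table$X, w$wavelengths, labels = w$table$labels)
  split <- kennard_stone_split(tab$X, 0.9)
  cv <- venetian_blinds(length(split$calibration_indices), 10)
  spec <- list(classifier = "plsda", chain = "none", lv = 4)
  r1 <- evaluate_model(spec, tab, "class", split, cv)
  expect_equal(names(r1$per_class),
               c("class", "sensitivity_cal", "class_error_cal",
                 "sensitivity_cv", "class_error_cv",
                 "sensitivity_pred", "class_error_pred"))
  expect_equal(r1$overall_accuracy,
               100 - max(r1$per_class$class_error_cv,
                         r1$per_class$class_error_pred))
  # determinism on rerun
  r2 <- evaluate_model(spec, tab, "class", split, cv)
  expect_identical(r1$per_class, r2$per_class)
  # perfect separation yields the perfect report
  g <- gauss_classes(n_per = 25, bands = 30, sep = 8, seed = 10)
  tabg <- spectra_table(g$X, seq(1000, 2500, length.out = 30),
                        labels = data.frame(class = g$y))
  sg <- kennard_stone_split(tabg$X, 0.9)
  rg <- evaluate_model(list(classifier = "plsda", chain = "none", lv = 2),
                       tabg, "class", sg,
                       venetian_blinds(length(sg$calibration_indices)))
  expect_true(all(rg$per_class$sensitivity_cal == 1))
  expect_true(all(rg$per_class$class_error_cv == 0))
  expect_equal(rg$overall_accuracy, 100)
  # no leakage: corrupting the held-out prediction rows leaves the
  # calibration and CV phases (fitted state included) bit-identical
  tab_bad <- tab
  tab_bad$X[split$prediction_indices, ] <-
    tab_bad$X[split$prediction_indices, ] * 50 + 7
  r3 <- evaluate_model(spec, tab_bad, "class", split, cv)
  expect_identical(r3$per_class$sensitivity_cal, r1$per_class$sensitivity_cal)
  expect_identical(r3$per_class$sensitivity_cv, r1$per_class$sensitivity_cv)
  expect_equal(seedhsi:::pls_coef(r3$model$pls), seedhsi:::pls_coef(r1$model$pls))
})

test_that("CV accuracy does not decrease with class-signal amplitude", {
  # scaled-down sweep: one replicate per amplitude under a fixed seed
  accs <- vapply(c(0, 0.015, 0.05), function(a) {
    wl <- seq(1000, 2500, length.out = 288)
    sig <- data.frame(center = wl[c(105, 114)], amplitude = a * c(1, 0.8),
                      width = c(16, 16))
    sp <- make_spectra(sim_spec(n_per_class = c(Ep = 40L, Em = 40L),
                                class_signals = list(Ep = sig, Em = sig[0, ]),
                                noise_sd = 0.01, rng_seed = 19L))
    cv_accuracy(sp$table$X, sp$table$labels$class, lv = 4)
  }, numeric(1))
  expect_gte(accs[2], accs[1] - 5)
  expect_gte(accs[3], accs[2] - 5)
  expect_gt(accs[3], accs[1])
})
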