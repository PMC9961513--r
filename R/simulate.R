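## Gaussian absorbance feature over the wavelength axis.
gauss_band <- function(wl, center, amplitude, width) {
  amplitude * exp(-((wl - center) / width)^2)
}

## Smooth positive NIR-like reflectance template: broad water/starch-like
## absorbance bands plus a gentle downward trend, mapped through exp(-A).
default_base_spectrum <- function(wl) {
  t <- (wl - min(wl)) / diff(range(wl))
  A <- 0.40 + 0.10 * t +
    gauss_band(wl, 1450, 0.30, 80) +
    gauss_band(wl, 1940, 0.25, 90) +
    gauss_band(wl, 2100, 0.15, 120)
  exp(-A)
}

#' Simulation specification for synthetic seed spectra and images
#'
#' Describes the statistical world the analysis assumes: a smooth positive
#' base reflectance spectrum; class-dependent Gaussian absorption features
#' (defined in absorbance and applied multiplicatively, mimicking NIR band
#' physics); per-batch additive baseline tilt and offset; per-object
#' multiplicative/additive scatter; per-band Gaussian noise; and the seed
#' ellipse geometry for image generation.
#'
#' @param n_per_class named integer vector, objects per class.
#' @param wavelengths wavelength axis in nm (default 288 bands, 1000-2500).
#' @param class_signals named list (one entry per class) of data.frames
#'   with columns `center`, `amplitude`, `width` (nm, absorbance units).
#'   Default: one distinct double-dip signature per class.
#' @param batch_effects named list of `list(offset=, slope=)` reflectance
#'   baselines per batch; `NULL` for no batch structure.
#' @param batch_assignment function(class, i) -> batch name, or `NULL`.
#' @param scatter_mult,scatter_add ranges (length-2) of per-object
#'   multiplicative and additive scatter; `c(1,1)`/`c(0,0)` disable.
#' @param noise_sd per-band Gaussian noise sd on reflectance.
#' @param geometry list: `axes` (ellipse semi-axes in px), `spacing` (grid
#'   pitch in px), `background` (background reflectance), `pixel_noise_sd`.
#' @param rng_seed integer seed; geometry, scatter and noise use
#'   independent derived streams.
#' @return A `sim_spec` list.
#' @export
sim_spec <- function(n_per_class = c(A = 50L, B = 50L),
                     wavelengths = seq(1000, 2500, length.out = 288),
                     class_signals = NULL,
                     batch_effects = NULL,
                     batch_assignment = NULL,
                     scatter_mult = c(1, 1),
                     scatter_add = c(0, 0),
                     noise_sd = 0.004,
                     geometry = list(axes = c(6, 3), spacing = 20L,
                                     background = 0.05, pixel_noise_sd = 0),
                     rng_seed = 1L) {
  classes <- names(n_per_class)
  if (is.null(classes)) stop_input("n_per_class must be a named vector")
  if (is.null(class_signals)) {
    centers <- seq(1150, 2350, length.out = 2L * length(classes))
    class_signals <- stats::setNames(lapply(seq_along(classes), function(k)
      data.frame(center = centers[c(2L * k - 1L, 2L * k)],
                 amplitude = 0.02, width = 25)), classes)
  }
  stopifnot(noise_sd >= 0,
            all(vapply(class_signals, function(s) all(s$amplitude >= 0), logical(1))))
  structure(list(n_per_class = n_per_class, wavelengths = wavelengths,
                 class_signals = class_signals, batch_effects = batch_effects,
                 batch_assignment = batch_assignment,
                 scatter_mult = scatter_mult, scatter_add = scatter_add,
                 noise_sd = noise_sd, geometry = geometry,
                 rng_seed = as.integer(rng_seed)),
            class = "sim_spec")
}

## Noise-free class spectrum: base * exp(-sum of class absorbance bands).
class_clean_spectrum <- function(spec, class) {
  wl <- spec$wavelengths
  base <- default_base_spectrum(wl)
  sig <- spec$class_signals[[class]]
  A <- 0
  if (!is.null(sig) && nrow(sig))
    for (r in seq_len(nrow(sig)))
      A <- A + gauss_band(wl, sig$center[r], sig$amplitude[r], sig$width[r])
  base * exp(-A)
}

batch_tilt <- function(spec, batch) {
  if (is.null(batch) || is.null(spec$batch_effects[[batch]])) return(0)
  be <- spec$batch_effects[[batch]]
  t <- (spec$wavelengths - min(spec$wavelengths)) / diff(range(spec$wavelengths))
  (be$offset %||% 0) + (be$slope %||% 0) * (2 * t - 1)
}

#' Generate an object-wise spectra table with ground truth
#'
#' Each row is `b * (clean_class_spectrum + batch_tilt) + a + noise` with
#' per-object scatter `(b, a)` and per-band Gaussian noise. Deterministic
#' per `rng_seed`; the scatter and noise draws use independent derived
#' streams, so changing `noise_sd` leaves the scatter draws identical.
#'
#' @param spec a [sim_spec()].
#' @return List with `table` (a [spectra_table()] with `class` and `batch`
#'   label columns) and `truth` (per-object class, batch, `clean` matrix =
#'   noise-free scatter-free spectra, `expected` = scatter applied but
#'   noise-free).
#' @export
make_spectra <- function(spec) {
  stopifnot(inherits(spec, "sim_spec"))
  classes <- names(spec$n_per_class)
  cls <- rep(classes, times = spec$n_per_class)
  n <- length(cls)
  batch <- if (!is.null(spec$batch_assignment))
    vapply(seq_len(n), function(i) spec$batch_assignment(cls[i], i), character(1))
  else rep(NA_character_, n)
  p <- length(spec$wavelengths)
  clean <- t(vapply(seq_len(n), function(i)
    class_clean_spectrum(spec, cls[i]) + batch_tilt(spec, batch[i]),
    numeric(p)))
  sc <- with_seed(derive_seed(spec$rng_seed, "scatter"), list(
    b = stats::runif(n, spec$scatter_mult[1L], spec$scatter_mult[2L]),
    a = stats::runif(n, spec$scatter_add[1L], spec$scatter_add[2L])))
  expected <- clean * sc$b + sc$a
  noise <- with_seed(derive_seed(spec$rng_seed, "noise"),
                     matrix(stats::rnorm(n * p, 0, spec$noise_sd), n, p))
  X <- expected + noise
  labels <- data.frame(class = cls, batch = batch, stringsAsFactors = FALSE)
  list(table = spectra_table(X, spec$wavelengths, labels = labels),
       truth = list(class = cls, batch = batch, clean = clean,
                    expected = expected, scatter = sc))
}

#' Generate a raw hypercube with reference frames and ground truth
#'
#' Places elliptical seed objects on a dark background in a grid, gives
#' every pixel of an object that object's spectrum (class signal, batch
#' tilt and per-object scatter included; optional per-pixel noise), and
#' converts reflectance to raw counts as
#' `raw = dark + (white - dark) * R`, emitting the white/dark frames so
#' flat-field calibration is exercised end to end.
#'
#' @param spec a [sim_spec()].
#' @return List: `cube` (raw [hypercube()]), `refs`
#'   ([reference_frames()]), `truth` (true `mask` labels matrix in
#'   segmentation label order, per-object `class`, `batch`, `spectra` =
#'   the spectra painted on the objects (equal to `expected`, the
#'   scatter-only spectra, when `noise_sd = 0`), `areas`).
#' @export
make_hypercube <- function(spec) {
  stopifnot(inherits(spec, "sim_spec"))
  sp <- make_spectra(spec)
  n <- nrow(sp$table$X)
  g <- spec$geometry
  ax <- g$axes %||% c(6, 3)
  pitch <- g$spacing %||% 20L
  ncol_grid <- ceiling(sqrt(n))
  nrow_grid <- ceiling(n / ncol_grid)
  lines <- nrow_grid * pitch; pixels <- ncol_grid * pitch
  labels_img <- matrix(0L, lines, pixels)
  for (k in seq_len(n)) {
    gr <- (k - 1L) %/% ncol_grid; gc <- (k - 1L) %% ncol_grid
    cy <- gr * pitch + pitch / 2; cx <- gc * pitch + pitch / 2
    ii <- pmax(1L, floor(cy - ax[1L])):pmin(lines, ceiling(cy + ax[1L]))
    jj <- pmax(1L, floor(cx - ax[2L])):pmin(pixels, ceiling(cx + ax[2L]))
    for (i in ii) for (j in jj)
      if (((i - cy) / ax[1L])^2 + ((j - cx) / ax[2L])^2 <= 1) labels_img[i, j] <- k
  }
  p <- length(spec$wavelengths)
  bg <- g$background %||% 0.05
  R <- array(bg, dim = c(lines, pixels, p))
  flat <- matrix(R, lines * pixels, p)
  lab_vec <- as.vector(labels_img)
  for (k in seq_len(n)) {
    px <- which(lab_vec == k)
    # paint the object's spectrum (scatter and band noise included)
    flat[px, ] <- matrix(sp$table$X[k, ], length(px), p, byrow = TRUE)
  }
  pn <- g$pixel_noise_sd %||% 0
  if (pn > 0) {
    fg <- which(lab_vec > 0L)
    flat[fg, ] <- flat[fg, ] +
      with_seed(derive_seed(spec$rng_seed, "pixel_noise"),
                matrix(stats::rnorm(length(fg) * p, 0, pn), length(fg), p))
  }
  R <- array(flat, dim = c(lines, pixels, p))
  # instrument model: smooth band-dependent white level, constant dark
  t <- (spec$wavelengths - min(spec$wavelengths)) / diff(range(spec$wavelengths))
  white_spec <- 900 - 150 * t
  dark_spec <- rep(100, p)
  W <- matrix(white_spec, pixels, p, byrow = TRUE)
  D <- matrix(dark_spec, pixels, p, byrow = TRUE)
  raw <- array(0, dim = dim(R))
  for (b in seq_len(p))
    raw[, , b] <- dark_spec[b] + (white_spec[b] - dark_spec[b]) * R[, , b]
  cube <- hypercube(raw, spec$wavelengths, is_reflectance = FALSE)
  truth_mask <- label_components(labels_img > 0L)
  # map segmentation-order labels back to generated objects (majority overlap)
  obj_of <- integer(max(truth_mask))
  for (m in seq_len(max(truth_mask))) {
    ids <- labels_img[truth_mask == m]
    obj_of[m] <- as.integer(names(which.max(table(ids[ids > 0L]))))
  }
  ord <- obj_of
  list(cube = cube, refs = reference_frames(W, D),
       truth = list(mask = truth_mask, class = sp$truth$class[ord],
                    batch = sp$truth$batch[ord],
                    spectra = sp$table$X[ord, , drop = FALSE],
                    expected = sp$truth$expected[ord, , drop = FALSE],
                    areas = tabulate(truth_mask[truth_mask > 0L]),
                    labels = data.frame(class = sp$truth$class[ord],
                                        batch = sp$truth$batch[ord],
                                        stringsAsFactors = FALSE)))
}

## Study layout: cultivar x endophyte status x batch date, with the
## per-batch sample counts of the reference design (total 1057).
study_layout <- function() {
  data.frame(
    cultivar = c("Alto", "Trojan", "Rohan", "Rohan", "Governor",
                 "Bronsyn", "Trojan", "Trojan", "Rohan", "Governor"),
    endophyte_status = c(rep("E+", 5L), rep("E-", 5L)),
    batch_date = c("2018-07-11", "2018-07-11", "2017-09-01", "2013-12-17",
                   "2017-09-01", "2018-07-11", "2018-07-11", "2013-12-17",
                   "2013-12-17", "2013-12-17"),
    n = c(96L, 193L, 96L, 96L, 96L, 96L, 96L, 96L, 96L, 96L),
    stringsAsFactors = FALSE)
}

#' Synthetic table mirroring the study design
#'
#' Emits 1057 objects laid out as five cultivars by endophyte status by
#' batch date, with an endophyte absorbance signature, per-cultivar
#' signatures, per-batch baseline tilts, per-object scatter and band
#' noise. Effect sizes are fixed defaults calibrated once so the
#' full-spectrum PLS-DA reference pipeline lands in the 85-95% CV
#' accuracy band (see the methods vignette); they are not a reproduction
#' of any real dataset. Rows are ordered by cultivar then status then
#' batch, mimicking data organised in class order.
#'
#' @param seed integer seed.
#' @return List with `table` (a [spectra_table()] with `endophyte_status`,
#'   `cultivar`, `batch_date` labels) and `truth` (as [make_spectra()]).
#' @export
preset_study <- function(seed = 1L) {
  lay <- study_layout()
  groups <- sprintf("%s|%s|%s", lay$cultivar, lay$endophyte_status, lay$batch_date)
  n_per <- stats::setNames(lay$n, groups)
  cultivars <- c("Alto", "Bronsyn", "Governor", "Rohan", "Trojan")
  cult_centers <- stats::setNames(seq(1120, 2280, length.out = 5L), cultivars)
  signals <- lapply(groups, function(gkey) {
    parts <- strsplit(gkey, "|", fixed = TRUE)[[1L]]
    sig <- data.frame(center = cult_centers[[parts[1L]]],
                      amplitude = 0.030, width = 30)
    if (parts[2L] == "E+")
      sig <- rbind(sig, data.frame(center = c(1210, 1725, 2310),
                                   amplitude = 0.012, width = 22))
    sig
  })
  names(signals) <- groups
  batches <- list(
    "2013-12-17" = list(offset = 0.012, slope = 0.015),
    "2017-09-01" = list(offset = -0.006, slope = -0.010),
    "2018-07-11" = list(offset = 0.000, slope = 0.005))
  spec <- sim_spec(n_per_class = n_per,
                   class_signals = signals,
                   batch_effects = batches,
                   batch_assignment = function(cl, i)
                     strsplit(cl, "|", fixed = TRUE)[[1L]][3L],
                   scatter_mult = c(0.93, 1.07),
                   scatter_add = c(-0.02, 0.02),
                   noise_sd = 0.007,
                   rng_seed = seed)
  sp <- make_spectra(spec)
  parts <- do.call(rbind, strsplit(sp$truth$class, "|", fixed = TRUE))
  labels <- data.frame(cultivar = parts[, 1L],
                       endophyte_status = parts[, 2L],
                       batch_date = parts[, 3L],
                       stringsAsFactors = FALSE)
  ord <- order(labels$cultivar, labels$endophyte_status, labels$batch_date)
  table <- spectra_table(sp$table$X[ord, , drop = FALSE], spec$wavelengths,
                         labels = labels[ord, , drop = FALSE])
  truth <- list(class = sp$truth$class[ord],
                clean = sp$truth$clean[ord, , drop = FALSE],
                expected = sp$truth$expected[ord, , drop = FALSE],
                labels = labels[ord, , drop = FALSE])
  list(table = table, truth = truth)
}
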