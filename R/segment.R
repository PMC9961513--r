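#' Otsu's automatic threshold
#'
#' Maximizes between-class variance of a two-class split of the value
#' histogram. Used as the "auto" mode of [segment_reverse_mask()].
#'
#' @param x numeric vector of pixel values.
#' @param n_breaks histogram resolution.
#' @return Threshold value.
#' @export
otsu_threshold <- function(x, n_breaks = 256L) {
  x <- x[is.finite(x)]
  if (length(unique(x)) < 2L) return(max(x))
  h <- hist(x, breaks = seq(min(x), max(x), length.out = n_breaks + 1L),
            plot = FALSE)
  p <- h$counts / sum(h$counts)
  mids <- h$mids
  omega <- cumsum(p)
  mu <- cumsum(p * mids)
  mu_t <- mu[length(mu)]
  sigma_b <- (mu_t * omega - mu)^2 / (omega * (1 - omega))
  sigma_b[!is.finite(sigma_b)] <- 0
  mids[which.max(sigma_b)]
}

## Two-pass connected-component labelling (4-connectivity) with union-find.
label_components <- function(mask) {
  d <- dim(mask)
  labels <- matrix(0L, d[1L], d[2L])
  parent <- integer(0)
  find <- function(i) { while (parent[i] != i) i <- parent[i]; i }
  nxt <- 0L
  for (j in seq_len(d[2L])) for (i in seq_len(d[1L])) {
    if (!mask[i, j]) next
    up   <- if (i > 1L) labels[i - 1L, j] else 0L
    left <- if (j > 1L) labels[i, j - 1L] else 0L
    if (up == 0L && left == 0L) {
      nxt <- nxt + 1L; parent[nxt] <- nxt; labels[i, j] <- nxt
    } else if (up != 0L && left != 0L) {
      ru <- find(up); rl <- find(left)
      r <- min(ru, rl); parent[max(ru, rl)] <- r
      labels[i, j] <- r
    } else {
      labels[i, j] <- max(up, left)
    }
  }
  if (nxt == 0L) return(labels)
  roots <- vapply(seq_len(nxt), find, integer(1))
  relab <- integer(nxt)
  relab[sort(unique(roots))] <- seq_along(unique(roots))
  idx <- labels > 0L
  labels[idx] <- relab[roots[labels[idx]]]
  labels
}

#' Segment seeds from background by reverse mask
#'
#' Builds a binary "reverse mask" (background 0, sample pixels 1) by
#' thresholding the mean reflectance over a wavelength window, labels
#' 4-connected components, and drops components below a minimum pixel area.
#'
#' @param cube a reflectance [hypercube()].
#' @param band_range wavelength interval `c(lo, hi)` in nm averaged for
#'   thresholding; default the full range.
#' @param threshold numeric reflectance threshold, or `"auto"` for Otsu.
#' @param min_area smallest object retained, in pixels.
#' @return An object of class `segmentation_mask` with fields `mask`
#'   (logical matrix), `object_labels` (integer matrix, 0 = background,
#'   k > 0 = object id, ids contiguous), `n_objects`, `threshold`.
#' @export
segment_reverse_mask <- function(cube, band_range = NULL, threshold = "auto",
                                 min_area = 10L) {
  stopifnot(inherits(cube, "hypercube"))
  if (!cube$is_reflectance)
    stop_input("segmentation expects a reflectance-calibrated cube")
  wl <- cube$wavelengths
  if (is.null(band_range)) band_range <- range(wl)
  bands <- which(wl >= band_range[1L] & wl <= band_range[2L])
  if (length(bands) == 0) stop_input("band_range selects no bands")
  intensity <- apply(cube$data[, , bands, drop = FALSE], c(1L, 2L), mean)
  thr <- if (identical(threshold, "auto")) otsu_threshold(intensity)
         else as.numeric(threshold)
  mask <- intensity > thr
  labels <- label_components(mask)
  if (max(labels) > 0L) {
    areas <- tabulate(labels[labels > 0L])
    keep <- which(areas >= min_area)
    relab <- integer(max(labels))
    relab[keep] <- seq_along(keep)
    idx <- labels > 0L
    labels[idx] <- relab[labels[idx]]
    mask <- labels > 0L
  }
  if (!any(mask)) warning("segmentation found no foreground objects")
  structure(list(mask = mask, object_labels = labels,
                 n_objects = max(labels), threshold = thr),
            class = "segmentation_mask")
}

#' Extract object-wise mean spectra
#'
#' For each labelled object, averages the spectra of all its pixels: the
#' mean spectrum of the seed is used as the spectrum of that sample.
#'
#' @param cube a reflectance [hypercube()].
#' @param seg a `segmentation_mask` from [segment_reverse_mask()].
#' @param labels optional data.frame of per-object annotations (one row per
#'   object, e.g. columns `endophyte_status`, `cultivar`, `batch_date`).
#' @return A [spectra_table()] with one row per object; `object_meta` holds
#'   pixel counts and centroids.
#' @export
extract_spectra <- function(cube, seg, labels = NULL) {
  stopifnot(inherits(cube, "hypercube"), inherits(seg, "segmentation_mask"))
  d <- dim(cube$data)
  if (!all(dim(seg$object_labels) == d[1:2]))
    stop_input("mask dims (%d x %d) do not match cube spatial dims (%d x %d)",
               nrow(seg$object_labels), ncol(seg$object_labels), d[1L], d[2L])
  K <- seg$n_objects
  if (!is.null(labels) && nrow(labels) != K)
    stop_input("labels has %d rows but segmentation found %d objects",
               nrow(labels), K)
  X <- matrix(NA_real_, K, d[3L])
  meta <- data.frame(object_id = seq_len(K), n_pixels = NA_integer_,
                     centroid_line = NA_real_, centroid_pixel = NA_real_)
  flat <- matrix(cube$data, d[1L] * d[2L], d[3L])  # pixel-major spectra
  lab_vec <- as.vector(seg$object_labels)
  for (k in seq_len(K)) {
    px <- which(lab_vec == k)
    X[k, ] <- colMeans(flat[px, , drop = FALSE])
    rc <- arrayInd(px, d[1:2])
    meta$n_pixels[k] <- length(px)
    meta$centroid_line[k] <- mean(rc[, 1L])
    meta$centroid_pixel[k] <- mean(rc[, 2L])
  }
  spectra_table(X, cube$wavelengths, labels = labels, object_meta = meta)
}
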