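#' Construct a hypercube
#'
#' A hypercube is a 3-D array of lines x pixels x bands holding either raw
#' detector counts or calibrated reflectance, together with its wavelength
#' axis (nm, strictly increasing).
#'
#' @param data 3-D numeric array `(lines, pixels, bands)`.
#' @param wavelengths numeric vector, one entry per band, strictly increasing.
#' @param is_reflectance logical; `TRUE` once calibrated.
#' @return An object of class `hypercube`.
#' @export
hypercube <- function(data, wavelengths, is_reflectance = FALSE) {
  if (length(dim(data)) != 3L)
    stop_input("hypercube data must be a 3-D array, got %d dims", length(dim(data)))
  if (dim(data)[3L] != length(wavelengths))
    stop_input("bands dimension (%d) != length(wavelengths) (%d)",
               dim(data)[3L], length(wavelengths))
  if (any(diff(wavelengths) <= 0))
    stop_input("wavelengths must be strictly increasing")
  if (isTRUE(is_reflectance) && !all(is.finite(data)))
    stop_input("reflectance cube contains non-finite values")
  structure(list(data = data, wavelengths = as.numeric(wavelengths),
                 is_reflectance = isTRUE(is_reflectance)),
            class = "hypercube")
}

#' @export
print.hypercube <- function(x, ...) {
  d <- dim(x$data)
  cat(sprintf("<hypercube> %d lines x %d pixels x %d bands (%.0f-%.0f nm), %s\n",
              d[1], d[2], d[3], min(x$wavelengths), max(x$wavelengths),
              if (x$is_reflectance) "reflectance" else "raw counts"))
  invisible(x)
}

#' Construct white/dark reference frames
#'
#' References may be a full frame (`lines x pixels x bands`), a per-line
#' pushbroom reference (`pixels x bands`), or a single spectrum (`bands`).
#' Pushbroom scanners acquire the white/dark frames over a few scan lines;
#' 3-D references are averaged over their scan lines before use.
#'
#' @param white,dark arrays of white-tile and shutter-closed intensities.
#' @return An object of class `reference_frames` holding `pixels x bands`
#'   (or `1 x bands`) matrices.
#' @export
reference_frames <- function(white, dark) {
  norm_ref <- function(r, what) {
    if (is.null(dim(r))) r <- matrix(r, nrow = 1L)
    if (length(dim(r)) == 3L) r <- apply(r, c(2L, 3L), mean)  # average scan lines
    if (length(dim(r)) != 2L) stop_input("%s reference must be 1-, 2- or 3-D", what)
    r
  }
  structure(list(white = norm_ref(white, "white"), dark = norm_ref(dark, "dark")),
            class = "reference_frames")
}

## Expand a reference matrix to the cube's (lines, pixels, bands) layout.
expand_ref <- function(r, d, what) {
  if (nrow(r) == 1L) r <- r[rep(1L, d[2L]), , drop = FALSE]
  if (!all(dim(r) == d[2:3]))
    stop_input("%s reference (%d x %d) not broadcastable to cube pixels x bands (%d x %d)",
               what, nrow(r), ncol(r), d[2L], d[3L])
  aperm(array(t(r), dim = c(d[3L], d[2L], d[1L])), c(3L, 2L, 1L))
}

#' Calibrate raw counts to reflectance
#'
#' Applies the standard flat-field correction
#' `R = (I_S - I_D) / (I_W - I_D)` pixel- and band-wise, where `I_S` is the
#' raw sample image and `I_W`, `I_D` the white and dark reference frames.
#'
#' Reflectance outside `[0, 1]` is retained by default (scatter-correcting
#' pre-treatments can use it) and reported in the `clipped_range` attribute;
#' set `clip = TRUE` to clamp into `[0, 1]`.
#'
#' @param raw a raw-count [hypercube()].
#' @param refs a [reference_frames()] object.
#' @param clip clamp reflectance into `[0, 1]`?
#' @return A reflectance hypercube; the input is unmodified.
#' @export
calibrate_reflectance <- function(raw, refs, clip = FALSE) {
  stopifnot(inherits(raw, "hypercube"), inherits(refs, "reference_frames"))
  if (raw$is_reflectance) stop_input("cube is already reflectance-calibrated")
  d <- dim(raw$data)
  W <- expand_ref(refs$white, d, "white")
  D <- expand_ref(refs$dark, d, "dark")
  denom <- W - D
  if (any(denom <= 0)) {
    bad <- which(denom <= 0, arr.ind = TRUE)[1L, ]
    stop_input("white - dark <= 0 at line %d, pixel %d, band %d: calibration impossible",
               bad[1L], bad[2L], bad[3L])
  }
  R <- (raw$data - D) / denom
  out_of_range <- range(R)
  if (clip) R <- pmin(pmax(R, 0), 1)
  out <- hypercube(R, raw$wavelengths, is_reflectance = TRUE)
  attr(out, "clipped_range") <- out_of_range
  out
}
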