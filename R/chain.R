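## Registry of pre-treatment steps. Row-wise steps carry no fitted state;
## fit-dependent steps (emsc, osc, mean_center) freeze calibration-derived
## quantities that apply-time replays verbatim.
step_registry <- list(
  detrend = list(
    needs_y = FALSE,
    fit = function(X, Y, params, wl) NULL,
    apply = function(state, X, params, wl) detrend(X, params$order %||% 2L)),
  wls_baseline = list(
    needs_y = FALSE,
    fit = function(X, Y, params, wl) NULL,
    apply = function(state, X, params, wl)
      wls_baseline(X, params$order %||% 2L, params$max_iter %||% 100L,
                   params$tol %||% 1e-6)),
  sg_derivative = list(
    needs_y = FALSE,
    fit = function(X, Y, params, wl) NULL,
    apply = function(state, X, params, wl)
      sg_derivative(X, params$deriv_order %||% 2L, params$poly_order %||% 2L,
                    params$window %||% 15L)),
  snv = list(
    needs_y = FALSE,
    fit = function(X, Y, params, wl) NULL,
    apply = function(state, X, params, wl) snv(X)),
  emsc = list(
    needs_y = FALSE,
    fit = function(X, Y, params, wl)
      emsc_fit(X, wavelengths = wl, poly_order = params$poly_order %||% 2L),
    apply = function(state, X, params, wl) emsc_apply(state, X)),
  osc = list(
    needs_y = TRUE,
    fit = function(X, Y, params, wl)
      osc_fit(X, Y, n_components = params$n_components %||% 1L),
    apply = function(state, X, params, wl) osc_apply(state, X)),
  mean_center = list(
    needs_y = FALSE,
    fit = function(X, Y, params, wl) mean_center_fit(X),
    apply = function(state, X, params, wl) mean_center_apply(state, X))
)

## The six named pre-treatment presets used throughout the package. All
## start with detrend + order-2 baseline; derivative is the 2nd SG
## derivative (poly order 2, 15-point window); all end in mean centring.
chain_presets <- local({
  st <- function(name, ...) list(name = name, params = list(...))
  base2 <- list(st("detrend", order = 2L), st("wls_baseline", order = 2L))
  d2 <- st("sg_derivative", deriv_order = 2L, poly_order = 2L, window = 15L)
  mc <- st("mean_center")
  list(
    pt1 = c(base2, list(mc)),
    pt2 = c(base2, list(d2, mc)),
    pt3 = c(base2, list(d2, st("emsc"), mc)),
    pt4 = c(base2, list(st("osc"), mc)),
    pt5 = c(base2, list(d2, st("osc"), mc)),
    pt6 = c(base2, list(d2, st("emsc"), st("osc"), mc))
  )
})

#' Build a pre-processing chain
#'
#' A chain is an ordered list of pre-treatment steps applied left to right.
#' `spec` is either the name of a preset (`"pt1"` .. `"pt6"`, the six
#' standard combinations; `"none"` for the identity) or a list of
#' `list(name = , params = list(...))` entries with names from the step
#' registry: `detrend`, `wls_baseline`, `sg_derivative`, `snv`, `emsc`,
#' `osc`, `mean_center`.
#'
#' @param spec preset name or explicit step list.
#' @return An unfitted `preprocess_chain`.
#' @export
preprocess_chain <- function(spec = "none") {
  steps <- if (is.character(spec) && length(spec) == 1L) {
    if (spec == "none") list()
    else chain_presets[[spec]] %||%
      stop_input("unknown preset '%s' (use pt1..pt6 or none)", spec)
  } else {
    lapply(spec, function(s) {
      if (is.character(s)) s <- list(name = s)
      s$params <- s$params %||% list()
      s
    })
  }
  for (s in steps)
    if (is.null(step_registry[[s$name]]))
      stop_input("unknown pre-treatment step '%s'", s$name)
  structure(list(steps = steps, fitted = FALSE), class = "preprocess_chain")
}

#' Fit a chain on calibration data
#'
#' Steps are fitted in order, each on the output of its predecessors; the
#' fitted state is frozen for later [chain_apply()]. Fit-dependent steps
#' never see held-out data.
#'
#' @param chain a `preprocess_chain` (or preset name / step list).
#' @param X_cal calibration spectra matrix.
#' @param Y_cal class labels or indicator matrix; required when the chain
#'   contains OSC.
#' @param wavelengths optional wavelength axis passed to steps that use it.
#' @return The fitted chain.
#' @export
chain_fit <- function(chain, X_cal, Y_cal = NULL, wavelengths = NULL) {
  if (!inherits(chain, "preprocess_chain")) chain <- preprocess_chain(chain)
  X <- as.matrix(X_cal)
  if (any(vapply(chain$steps, function(s) step_registry[[s$name]]$needs_y,
                 logical(1))) && is.null(Y_cal))
    stop_input("chain contains OSC but no Y_cal was given")
  if (!is.null(Y_cal) && !is.matrix(Y_cal)) Y_cal <- class_indicator(Y_cal)
  for (i in seq_along(chain$steps)) {
    s <- chain$steps[[i]]
    reg <- step_registry[[s$name]]
    state <- reg$fit(X, Y_cal, s$params, wavelengths)
    chain$steps[[i]]$state <- state
    X <- reg$apply(state, X, s$params, wavelengths)
  }
  chain$fitted <- TRUE
  chain$wavelengths <- wavelengths
  chain
}

#' Apply a fitted chain
#'
#' Replays the fitted steps in order with their frozen state. Applying the
#' same fitted chain twice to the same data yields identical output.
#'
#' @param chain a fitted `preprocess_chain`.
#' @param X spectra matrix to transform.
#' @return The transformed matrix.
#' @export
chain_apply <- function(chain, X) {
  stopifnot(inherits(chain, "preprocess_chain"))
  if (!chain$fitted && length(chain$steps) > 0L)
    stop_input("chain must be fitted before apply (see chain_fit)")
  X <- as.matrix(X)
  for (s in chain$steps)
    X <- step_registry[[s$name]]$apply(s$state, X, s$params, chain$wavelengths)
  X
}

#' @export
print.preprocess_chain <- function(x, ...) {
  nm <- vapply(x$steps, `[[`, character(1), "name")
  cat(sprintf("<preprocess_chain> [%s]%s\n",
              if (length(nm)) paste(nm, collapse = " -> ") else "identity",
              if (x$fitted) " (fitted)" else ""))
  invisible(x)
}
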