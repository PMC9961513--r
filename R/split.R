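#' Kennard-Stone calibration/prediction split
#'
#' Deterministic max-min-distance sample selection: the first two
#' calibration picks are the globally most distant pair (Euclidean);
#' thereafter the candidate maximising its minimum distance to the chosen
#' set is added until the calibration share is reached. Exterior,
#' space-filling samples land in the calibration set; the remainder forms
#' the prediction set. Ties (including all-duplicate datasets) break to
#' the lowest row index, so the split is reproducible.
#'
#' @param X spectra matrix (or [spectra_table()]); distances are computed
#'   on these values as given — pre-process first if desired.
#' @param fraction calibration share in (0, 1); default 0.95. The
#'   calibration size is `ceiling(fraction * n)` capped at `n - 1`.
#' @return An object of class `split_plan` with sorted
#'   `calibration_indices`, `prediction_indices`, and `fraction`.
#' @export
kennard_stone_split <- function(X, fraction = 0.95) {
  if (inherits(X, "spectra_table")) X <- X$X
  X <- as.matrix(X)
  n <- nrow(X)
  if (n < 2L) stop_input("Kennard-Stone needs n >= 2")
  if (fraction <= 0 || fraction >= 1) stop_input("fraction must be in (0, 1)")
  n_cal <- min(max(2L, as.integer(ceiling(fraction * n))), n - 1L)
  sq <- rowSums(X^2)
  G <- tcrossprod(X)
  D2 <- outer(sq, sq, `+`) - 2 * G
  D2[D2 < 0] <- 0
  ut <- upper.tri(D2)
  mx <- max(D2[ut])
  hit <- which(D2 == mx & ut, arr.ind = TRUE)
  # lexicographically smallest maximal pair
  hit <- hit[order(hit[, 1L], hit[, 2L]), , drop = FALSE]
  sel <- c(hit[1L, 1L], hit[1L, 2L])
  mind2 <- pmin(D2[, sel[1L]], D2[, sel[2L]])
  mind2[sel] <- -Inf
  while (length(sel) < n_cal) {
    k <- which.max(mind2)                   # ties -> lowest index
    sel <- c(sel, k)
    mind2 <- pmin(mind2, D2[, k])
    mind2[k] <- -Inf
  }
  cal <- sort(unname(sel))
  structure(list(calibration_indices = cal,
                 prediction_indices = setdiff(seq_len(n), cal),
                 fraction = fraction),
            class = "split_plan")
}

#' @export
print.split_plan <- function(x, ...) {
  cat(sprintf("<split_plan> %d calibration / %d prediction (fraction %.3g)\n",
              length(x$calibration_indices), length(x$prediction_indices),
              x$fraction))
  invisible(x)
}

#' Venetian-blinds cross-validation plan
#'
#' Row `i` (in stored dataset order) is assigned to fold
#' `((i - 1) mod n_splits) + 1`: every `n_splits`-th sample shares a
#' blind. Fold balance therefore depends on the dataset ordering; use
#' [order_by_class()] to mimic data organised in class order.
#'
#' @param n number of rows.
#' @param n_splits number of folds (default 10).
#' @return An object of class `cv_plan` with fields `n_splits` and
#'   `assignment` (length-`n` fold ids).
#' @export
venetian_blinds <- function(n, n_splits = 10L) {
  n <- as.integer(n); n_splits <- as.integer(n_splits)
  if (n_splits < 2L)
    stop_input("need n_splits >= 2 (got %d)", n_splits)
  if (n < 2L) stop_input("need n >= 2")
  structure(list(n_splits = n_splits,
                 assignment = ((seq_len(n) - 1L) %% n_splits) + 1L),
            class = "cv_plan")
}

#' Reorder rows by class then batch
#'
#' Returns the permutation sorting rows by class (and optionally batch),
#' mirroring datasets organised in class order before venetian-blinds CV.
#'
#' @param labels vector of class labels.
#' @param batch optional secondary key.
#' @return Integer permutation of row indices.
#' @export
order_by_class <- function(labels, batch = NULL) {
  if (is.null(batch)) order(as.character(labels))
  else order(as.character(labels), as.character(batch))
}
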