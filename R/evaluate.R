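## Fit chain + classifier on (X_tr, y_tr) and predict both partitions.
## model_spec fields: classifier (plsda | csvm | annda), chain, lv,
## n_compress_lv, C, gamma, hidden_nodes, seed.
fit_and_predict <- function(model_spec, X_tr, y_tr, X_te, wavelengths = NULL) {
  cls <- model_spec$classifier %||% "plsda"
  chain <- model_spec$chain %||% "none"
  lv <- model_spec$lv %||% 10L
  if (cls == "plsda") {
    fit <- plsda_fit(X_tr, y_tr, lv, chain, wavelengths)
    return(list(cal = predict(fit, X_tr),
                pred = if (nrow(X_te)) predict(fit, X_te) else character(0),
                model = fit))
  }
  fc <- chain_fit(chain, X_tr, y_tr, wavelengths)
  Xtr_p <- chain_apply(fc, X_tr)
  Xte_p <- if (nrow(X_te)) chain_apply(fc, X_te) else X_te
  comp <- pls_compress(Xtr_p, y_tr, model_spec$n_compress_lv %||% lv)
  S_tr <- comp$scores
  S_te <- if (nrow(X_te)) comp$project(Xte_p) else matrix(0, 0, comp$n_lv)
  fit <- switch(cls,
    csvm = svm_fit(S_tr, y_tr, list(C = model_spec$C %||% 1,
                                    gamma = model_spec$gamma %||% 0.32)),
    annda = ann_fit(S_tr, y_tr,
                    list(hidden_nodes = model_spec$hidden_nodes %||% 10L,
                         max_epochs = model_spec$max_epochs %||% 500L,
                         seed = model_spec$seed %||%
                           stop_input("annda model_spec requires a seed"))),
    stop_input("unknown classifier '%s' (plsda, csvm, annda)", cls))
  list(cal = predict(fit, S_tr),
       pred = if (nrow(X_te)) predict(fit, S_te) else character(0),
       model = fit)
}

#' Evaluate a discriminant model: calibration, CV and prediction metrics
#'
#' Fits the model (pre-processing chain included) on the calibration rows
#' of the split, cross-validates it with per-fold chain refits, predicts
#' the held-out prediction set, and reports per-class sensitivity and
#' class error for each phase plus the overall accuracy
#' `100 - max(class error)` taken over the CV and prediction phases of
#' all classes ("whichever is higher").
#'
#' @param model_spec list: `classifier` (`"plsda"`, `"csvm"`, `"annda"`),
#'   `chain` (preset name or chain spec), `lv` (latent variables; `"auto"`
#'   selects by CV for PLS-DA), `n_compress_lv`, `C`, `gamma`,
#'   `hidden_nodes`, `seed`, `lv_grid`.
#' @param table a [spectra_table()].
#' @param label name of the label column in `table$labels`.
#' @param split a [kennard_stone_split()] plan (made on the table if `NULL`).
#' @param cv a [venetian_blinds()] plan over the calibration rows.
#' @return An object of class `model_report`: data.frame `per_class` with
#'   the six sensitivity/class-error columns, `overall_accuracy`,
#'   `selected_lv`, the fitted model, and the predictions.
#' @export
evaluate_model <- function(model_spec, table, label,
                           split = NULL, cv = NULL) {
  stopifnot(inherits(table, "spectra_table"))
  if (is.null(table$labels) || is.null(table$labels[[label]]))
    stop_input("table has no label column '%s'", label)
  y <- as.character(table$labels[[label]])
  X <- table$X
  if (is.null(split)) split <- kennard_stone_split(X, 0.95)
  ical <- split$calibration_indices; ipred <- split$prediction_indices
  X_cal <- X[ical, , drop = FALSE]; y_cal <- y[ical]
  X_prd <- X[ipred, , drop = FALSE]; y_prd <- y[ipred]
  if (is.null(cv)) cv <- venetian_blinds(length(ical))
  classes <- sort(unique(y))
  wl <- table$wavelengths

  if (identical(model_spec$lv, "auto")) {
    sel <- plsda_cv(X_cal, y_cal, model_spec$chain %||% "none",
                    model_spec$lv_grid %||% 1:20, cv, wl)
    model_spec$lv <- sel$selected_lv
    lv_curve <- sel$cv_table
  } else lv_curve <- NULL

  final <- fit_and_predict(model_spec, X_cal, y_cal, X_prd, wl)

  cv_pred <- character(length(ical))
  for (f in sort(unique(cv$assignment))) {
    hold <- which(cv$assignment == f)
    train <- setdiff(seq_along(ical), hold)
    fp <- fit_and_predict(model_spec, X_cal[train, , drop = FALSE],
                          y_cal[train], X_cal[hold, , drop = FALSE], wl)
    cv_pred[hold] <- fp$pred
  }

  rep_cal <- per_class_report(y_cal, final$cal, classes)
  rep_cv <- per_class_report(y_cal, cv_pred, classes)
  rep_prd <- if (length(ipred)) per_class_report(y_prd, final$pred, classes)
             else rep_cal[0, ]
  per_class <- data.frame(
    class = classes,
    sensitivity_cal = rep_cal$sensitivity,
    class_error_cal = rep_cal$class_error,
    sensitivity_cv = rep_cv$sensitivity,
    class_error_cv = rep_cv$class_error,
    sensitivity_pred = if (length(ipred)) rep_prd$sensitivity else NA_real_,
    class_error_pred = if (length(ipred)) rep_prd$class_error else NA_real_,
    stringsAsFactors = FALSE)
  oa <- overall_accuracy(c(rep_cv$class_error,
                           if (length(ipred)) rep_prd$class_error))
  structure(list(per_class = per_class, overall_accuracy = oa,
                 selected_lv = model_spec$lv, lv_curve = lv_curve,
                 model_spec = model_spec, model = final$model,
                 cv_pred = cv_pred, pred = final$pred,
                 split = split, cv = cv),
            class = "model_report")
}

#' @export
print.model_report <- function(x, ...) {
  cat("<model_report>", x$model_spec$classifier %||% "plsda",
      "| chain:", if (is.character(x$model_spec$chain)) x$model_spec$chain else "custom",
      "| LV:", x$selected_lv %||% NA, "\n")
  df <- x$per_class
  num <- vapply(df, is.numeric, logical(1))
  df[num] <- lapply(df[num], round_half_up, digits = 3)
  print(df, row.names = FALSE)
  cat(sprintf("overall accuracy: %.1f%%\n", x$overall_accuracy))
  invisible(x)
}

#' Write a model report as CSV and JSON
#'
#' CSV columns: `class, sensitivity_cal, class_error_cal, sensitivity_cv,
#' class_error_cv, sensitivity_pred, class_error_pred` with a footer row
#' `overall_accuracy`. The JSON mirror additionally embeds the model spec,
#' a config hash and the seed for provenance.
#'
#' @param report a `model_report`.
#' @param path output path without extension; writes `<path>.csv` and
#'   `<path>.json`.
#' @param seed seed recorded for provenance.
#' @return Invisibly, the two paths.
#' @export
write_report <- function(report, path, seed = NULL) {
  stopifnot(inherits(report, "model_report"))
  df <- report$per_class
  footer <- df[1L, ]; footer[] <- NA
  footer$class <- "overall_accuracy"
  footer$sensitivity_cal <- report$overall_accuracy
  out <- rbind(df, footer)
  utils::write.csv(out, paste0(path, ".csv"), row.names = FALSE, na = "")
  meta <- list(per_class = df, overall_accuracy = report$overall_accuracy,
               selected_lv = report$selected_lv,
               model_spec = report$model_spec[setdiff(names(report$model_spec),
                                                      NULL)],
               seed = seed,
               config_hash = digest::digest(report$model_spec))
  jsonlite::write_json(meta, paste0(path, ".json"), auto_unbox = TRUE,
                       digits = NA, pretty = TRUE)
  invisible(c(paste0(path, ".csv"), paste0(path, ".json")))
}
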