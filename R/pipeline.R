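log_msg <- function(fmt, ..., file = NULL) {
  line <- sprintf("[%s] %s", format(Sys.time(), "%H:%M:%S"), sprintf(fmt, ...))
  message(line)
  if (!is.null(file)) cat(line, "\n", file = file, append = TRUE)
  invisible(line)
}

#' Read a pipeline configuration file
#'
#' YAML (preferred) or JSON key/value configuration; see
#' [validate_config()] for the recognised fields.
#'
#' @param path config file path.
#' @return Named list.
#' @export
read_config <- function(path) {
  if (grepl("\\.json$", path)) jsonlite::read_json(path, simplifyVector = TRUE)
  else yaml::read_yaml(path)
}

#' Validate a pipeline configuration
#'
#' Checks the configuration schema before any stage runs: input source,
#' classifier name, chain spec, split fraction, CV splits, GA block, and
#' that label-requiring steps (OSC; any model) have a label column
#' configured.
#'
#' @param config named list (see [run_pipeline()]).
#' @return The config, with defaults filled in; errors on violations.
#' @export
validate_config <- function(config) {
  config$seed <- config$seed %||% 1L
  config$split <- config$split %||% list(fraction = 0.95)
  config$cv <- config$cv %||% list(n_splits = 10L)
  config$model <- config$model %||% list(classifier = "plsda", lv = "auto")
  config$model$chain <- config$model$chain %||% config$chain %||% "pt6"
  if (!(config$model$classifier %||% "plsda") %in% c("plsda", "csvm", "annda"))
    stop_input("config: unknown classifier '%s'", config$model$classifier)
  ch <- config$model$chain
  if (is.character(ch) && length(ch) == 1L &&
      !ch %in% c(names(chain_presets), "none"))
    stop_input("config: unknown chain preset '%s'", ch)
  chain_obj <- preprocess_chain(ch)   # validates step names
  needs_y <- any(vapply(chain_obj$steps,
                        function(s) step_registry[[s$name]]$needs_y, logical(1)))
  has_input <- !is.null(config$input$spectra) || !is.null(config$input$cube) ||
    !is.null(config$simulate)
  if (!has_input)
    stop_input("config: no input (input$spectra, input$cube or simulate block)")
  if (is.null(config$label))
    stop_input("config: 'label' (label column for Y) is required%s",
               if (needs_y) " - the chain contains OSC which must see Y at fit time"
               else "")
  fr <- config$split$fraction %||% 0.95
  if (fr <= 0 || fr >= 1) stop_input("config: split fraction must be in (0,1)")
  if ((config$cv$n_splits %||% 10L) < 2L) stop_input("config: cv n_splits must be >= 2")
  config
}

#' Run the full classification pipeline
#'
#' Config-driven orchestration of calibrate -> segment -> extract ->
#' pre-process -> split -> train/CV -> optional GA waveband selection ->
#' report. Stages whose inputs are provided directly are skipped (e.g.
#' start from a spectra table). Every run writes the resolved config,
#' its hash and the seed next to its outputs.
#'
#' Config fields: `seed`; one of `simulate` (`preset: study` or a
#' [sim_spec()]-shaped block), `input$spectra` (CSV path) or
#' `input$cube` + `input$white`/`input$dark` (ENVI paths); `segment`
#' (`threshold`, `min_area`); `label`; `model` (`classifier`, `chain`,
#' `lv`, `n_compress_lv`, `C`, `gamma`, `hidden_nodes`, `seed`); `split`
#' (`fraction`); `cv` (`n_splits`); `ga` (`enabled` plus [ga_config()]
#' fields); `out` (output directory).
#'
#' @param config named list or path to a YAML/JSON config file.
#' @return Invisibly, a list with the `model_report`, optional
#'   `ga_result`, the table used and the output paths.
#' @export
run_pipeline <- function(config) {
  if (is.character(config)) config <- read_config(config)
  config <- validate_config(config)
  out_dir <- config$out %||% "."
  if (!dir.exists(out_dir)) dir.create(out_dir, recursive = TRUE)
  log_file <- file.path(out_dir, "pipeline.log")
  stage <- function(name, expr) {
    log_msg("stage %s", name, file = log_file)
    tryCatch(expr, error = function(e)
      stop_input("stage '%s' failed: %s", name, conditionMessage(e)))
  }

  table <- if (!is.null(config$input$spectra)) {
    stage("load_spectra", read_spectra_table(config$input$spectra))
  } else if (!is.null(config$input$cube)) {
    cube <- stage("load_cube", read_cube(config$input$cube))
    refs <- stage("load_refs", reference_frames(
      read_cube(config$input$white)$data, read_cube(config$input$dark)$data))
    refl <- stage("calibrate", calibrate_reflectance(cube, refs))
    seg <- stage("segment", segment_reverse_mask(
      refl, threshold = config$segment$threshold %||% "auto",
      min_area = config$segment$min_area %||% 10L))
    lab <- if (!is.null(config$input$labels))
      utils::read.csv(config$input$labels, stringsAsFactors = FALSE) else NULL
    stage("extract", extract_spectra(refl, seg, lab))
  } else {
    stage("simulate", {
      sim <- config$simulate
      if (identical(sim$preset, "study"))
        preset_study(sim$seed %||% config$seed)$table
      else {
        np <- unlist(sim$n_per_class)
        sp <- sim_spec(n_per_class = np,
                       noise_sd = sim$noise_sd %||% 0.004,
                       rng_seed = sim$seed %||% config$seed)
        make_spectra(sp)$table
      }
    })
  }

  y <- table$labels[[config$label]]
  if (is.null(y)) stop_input("label column '%s' not present in table", config$label)

  ga_res <- NULL
  if (isTRUE(config$ga$enabled)) {
    ga_res <- stage("ga_select", {
      split0 <- kennard_stone_split(table$X, config$split$fraction %||% 0.95)
      ical <- split0$calibration_indices
      fc <- chain_fit(config$ga$chain %||% "pt5",
                      table$X[ical, , drop = FALSE], y[ical], table$wavelengths)
      Xp <- chain_apply(fc, table$X[ical, , drop = FALSE])
      cfg <- ga_config(population = config$ga$population %||% 64L,
                       max_generations = config$ga$max_generations %||% 100L,
                       mutation_rate = config$ga$mutation_rate %||% 0.005,
                       convergence_percent = config$ga$convergence_percent %||% 50,
                       n_iterations = config$ga$n_iterations %||% 1L,
                       max_lv = config$ga$max_lv %||% 10L,
                       rng_seed = config$ga$seed %||% config$seed)
      ga_run(Xp, y[ical], cfg,
             venetian_blinds(length(ical), config$cv$n_splits %||% 10L))
    })
    table <- subset_bands(table, ga_res$best_mask)
    log_msg("ga selected %d bands", ga_res$n_selected, file = log_file)
  }

  split <- stage("split", kennard_stone_split(table$X,
                                              config$split$fraction %||% 0.95))
  cvp <- venetian_blinds(length(split$calibration_indices),
                         config$cv$n_splits %||% 10L)
  spec <- config$model
  spec$seed <- spec$seed %||% config$seed
  report <- stage("train", evaluate_model(spec, table, config$label, split, cvp))

  paths <- write_report(report, file.path(out_dir, "report"), seed = config$seed)
  resolved <- config
  resolved$config_hash <- digest::digest(config)
  yaml::write_yaml(resolved, file.path(out_dir, "config_resolved.yaml"))
  if (!is.null(ga_res))
    jsonlite::write_json(list(best_mask = ga_res$best_mask,
                              n_selected = ga_res$n_selected,
                              fitness_trace = ga_res$fitness_trace,
                              seed = config$seed,
                              config_hash = resolved$config_hash),
                         file.path(out_dir, "ga_result.json"),
                         auto_unbox = TRUE, digits = NA)
  log_msg("done: overall accuracy %.1f%%", report$overall_accuracy,
          file = log_file)
  invisible(list(report = report, ga = ga_res, table = table, paths = paths))
}
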