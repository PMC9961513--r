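#' Genetic-algorithm configuration
#'
#' Defaults follow the standard chemometric GA parameterisation:
#' population 64, at most 100 generations, double (two-point) crossover,
#' per-gene mutation rate 0.005, termination when 50% of the population
#' share one gene vector, one GA iteration, single-band windows.
#'
#' @param population even population size.
#' @param max_generations generation cap.
#' @param mutation_rate per-gene flip probability in (0, 1).
#' @param convergence_percent stop when this share (in percent) of
#'   individuals are identical.
#' @param n_iterations independent GA replicate runs; best result is kept.
#' @param window_width bands per gene.
#' @param init_density probability a gene starts active.
#' @param max_lv latent-variable cap inside the RMSECV fitness.
#' @param rng_seed seed; mandatory for a run.
#' @return A `ga_config` list.
#' @export
ga_config <- function(population = 64L, max_generations = 100L,
                      mutation_rate = 0.005, convergence_percent = 50,
                      n_iterations = 1L, window_width = 1L,
                      init_density = 0.3, max_lv = 10L, rng_seed = NULL) {
  if (population %% 2L != 0L) stop_input("population must be even")
  if (mutation_rate <= 0 || mutation_rate >= 1)
    stop_input("mutation_rate must be in (0, 1)")
  structure(list(population = as.integer(population),
                 max_generations = as.integer(max_generations),
                 crossover = "double",
                 mutation_rate = mutation_rate,
                 convergence_percent = convergence_percent,
                 n_iterations = as.integer(n_iterations),
                 window_width = as.integer(window_width),
                 init_density = init_density,
                 max_lv = as.integer(max_lv),
                 rng_seed = rng_seed),
            class = "ga_config")
}

#' RMSECV fitness of a waveband mask
#'
#' PLS regression of the class-indicator matrix on the masked bands,
#' cross-validated with the given plan; the fitness is the root mean
#' squared CV residual of the indicator matrix at the LV count (up to
#' `max_lv`) minimising it. Lower is better. A mask too rank-deficient to
#' support a single LV receives the worst-case fitness (RMSE of the
#' mean-only model) rather than an error.
#'
#' @param mask logical/0-1 vector over bands (at least one active) or
#'   integer band indices.
#' @param X_cal,y_cal calibration spectra and labels (or indicator matrix).
#' @param cv a [venetian_blinds()] plan.
#' @param max_lv latent-variable cap.
#' @return RMSECV (single number).
#' @export
fitness_rmsecv <- function(mask, X_cal, y_cal, cv = venetian_blinds(nrow(X_cal)),
                           max_lv = 10L) {
  X_cal <- as.matrix(X_cal)
  bands <- if (length(mask) == ncol(X_cal) && all(mask %in% c(0, 1)))
    which(as.logical(mask)) else as.integer(mask)
  if (length(bands) < 1L) stop_input("mask selects no bands")
  Y <- if (is.matrix(y_cal)) y_cal else class_indicator(y_cal)
  Xm <- X_cal[, bands, drop = FALSE]
  worst <- sqrt(mean(sweep(Y, 2L, colMeans(Y))^2))
  sse <- numeric(max_lv)
  n_eff <- 0L
  for (f in sort(unique(cv$assignment))) {
    hold <- which(cv$assignment == f)
    train <- setdiff(seq_len(nrow(Xm)), hold)
    fit <- pls_kernel(Xm[train, , drop = FALSE], Y[train, , drop = FALSE], max_lv)
    if (fit$ncomp == 0L) return(worst)
    Xh <- sweep(Xm[hold, , drop = FALSE], 2L, fit$mu_x)
    for (a in seq_len(max_lv)) {
      res <- sweep(Y[hold, , drop = FALSE], 2L, fit$mu_y) -
        Xh %*% pls_coef(fit, min(a, fit$ncomp))
      sse[a] <- sse[a] + sum(res^2)
    }
    n_eff <- n_eff + length(hold)
  }
  sqrt(min(sse) / (n_eff * ncol(Y)))
}

#' Double (two-point) crossover
#'
#' Two cut points are chosen uniformly on `0..L`; the middle segments of
#' the two parents are exchanged. Children with no active gene are
#' repaired by activating one uniformly chosen locus.
#'
#' @param a,b parent 0/1 gene vectors of equal length.
#' @return List with children `a` and `b`. Uses the current RNG stream.
#' @export
two_point_crossover <- function(a, b) {
  L <- length(a)
  stopifnot(length(b) == L)
  cuts <- sort(sample.int(L + 1L, 2L, replace = TRUE) - 1L)
  child_a <- a; child_b <- b
  if (cuts[2L] > cuts[1L]) {
    seg <- (cuts[1L] + 1L):cuts[2L]
    child_a[seg] <- b[seg]; child_b[seg] <- a[seg]
  }
  repair <- function(g) {
    if (!any(g == 1L)) g[sample.int(length(g), 1L)] <- 1L
    g
  }
  list(a = repair(child_a), b = repair(child_b))
}

ga_run_once <- function(X_cal, Y, config, cv) {
  L <- ceiling(ncol(X_cal) / config$window_width)
  expand <- function(genes) {
    bands <- rep(genes, each = config$window_width)[seq_len(ncol(X_cal))]
    as.logical(bands)
  }
  memo <- new.env(hash = TRUE, parent = emptyenv())
  fit_of <- function(genes) {
    key <- paste(genes, collapse = "")
    got <- memo[[key]]
    if (!is.null(got)) return(got)
    val <- fitness_rmsecv(expand(genes), X_cal, Y, cv, config$max_lv)
    memo[[key]] <- val
    val
  }
  P <- config$population
  pop <- matrix(stats::rbinom(P * L, 1L, config$init_density), P, L)
  for (i in seq_len(P)) if (!any(pop[i, ] == 1L))
    pop[i, sample.int(L, 1L)] <- 1L
  trace_best <- trace_mean <- numeric(0)
  converged_at <- NA_integer_
  for (gen in seq_len(config$max_generations)) {
    fitn <- apply(pop, 1L, fit_of)
    ord <- order(fitn)
    trace_best <- c(trace_best, fitn[ord[1L]])
    trace_mean <- c(trace_mean, mean(fitn))
    keys <- apply(pop, 1L, paste, collapse = "")
    if (max(table(keys)) / P * 100 >= config$convergence_percent) {
      converged_at <- gen
      break
    }
    if (gen == config$max_generations) break
    elite <- pop[ord[1L], ]
    parents <- pop[ord[seq_len(P %/% 2L)], , drop = FALSE]
    children <- matrix(0L, P, L)
    for (k in seq_len(P %/% 2L)) {
      pick <- sample.int(nrow(parents), 2L, replace = nrow(parents) < 2L)
      cr <- two_point_crossover(parents[pick[1L], ], parents[pick[2L], ])
      mutate <- function(g) {
        flip <- stats::runif(L) < config$mutation_rate
        g[flip] <- 1L - g[flip]
        if (!any(g == 1L)) g[sample.int(L, 1L)] <- 1L
        g
      }
      children[2L * k - 1L, ] <- mutate(cr$a)
      children[2L * k, ] <- mutate(cr$b)
    }
    children[1L, ] <- elite                 # elitism: best survives unchanged
    pop <- children
  }
  fitn <- apply(pop, 1L, fit_of)
  best <- pop[which.min(fitn), ]
  list(best_genes = best, best_fitness = min(fitn),
       fitness_trace = data.frame(generation = seq_along(trace_best),
                                  best = trace_best, mean = trace_mean),
       selection_frequency = colSums(pop),
       converged_generation = converged_at,
       final_population = pop,
       expand = expand)
}

#' Run GA effective-wavelength selection (GA-PLS-DA)
#'
#' Evolves a population of binary waveband masks under the RMSECV fitness
#' of a cross-validated PLS regression on class indicators: rank-based
#' parent selection (top half breeds), double crossover, per-gene
#' mutation, one-individual elitism, and termination when the configured
#' share of the population is identical or the generation cap is reached.
#' Fully deterministic given `config$rng_seed`.
#'
#' @param X_cal,y_cal calibration spectra (typically pre-processed) and labels.
#' @param config a [ga_config()] with `rng_seed` set.
#' @param cv a [venetian_blinds()] plan.
#' @return An object of class `ga_result`: `best_mask` (band indices),
#'   `n_selected`, `best_fitness`, `fitness_trace`, `selection_frequency`
#'   (per-band counts in the final population), `converged_generation`.
#' @export
ga_run <- function(X_cal, y_cal, config = ga_config(),
                   cv = venetian_blinds(nrow(X_cal))) {
  stopifnot(inherits(config, "ga_config"))
  if (is.null(config$rng_seed)) stop_input("ga_config requires rng_seed")
  X_cal <- as.matrix(X_cal)
  Y <- if (is.matrix(y_cal)) y_cal else class_indicator(y_cal)
  runs <- lapply(seq_len(config$n_iterations), function(it)
    with_seed(derive_seed(config$rng_seed, paste0("ga", it)),
              ga_run_once(X_cal, Y, config, cv)))
  best_run <- runs[[which.min(vapply(runs, `[[`, numeric(1), "best_fitness"))]]
  mask <- which(best_run$expand(best_run$best_genes))
  structure(list(best_mask = mask, n_selected = length(mask),
                 best_fitness = best_run$best_fitness,
                 fitness_trace = best_run$fitness_trace,
                 selection_frequency = best_run$selection_frequency,
                 converged_generation = best_run$converged_generation,
                 config = config),
            class = "ga_result")
}

#' @export
print.ga_result <- function(x, ...) {
  cat(sprintf("<ga_result> %d bands selected, best RMSECV %.4g%s\n",
              x$n_selected, x$best_fitness,
              if (!is.na(x$converged_generation))
                sprintf(", converged at generation %d", x$converged_generation)
              else ""))
  invisible(x)
}
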