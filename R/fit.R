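## The user-facing fitting interface: gp4pg() runs the evolutionary
## search (one or many independent replicates) against an observed
## summary and returns a fitted-model object with the usual methods.

#' Fit a demographic model to observed summary statistics
#'
#' Runs the evolutionary search over the given competing topologies
#' against the observed SFS summary.  With `n_runs > 1` the search is
#' replicated independently (the search is a metaheuristic and can be
#' trapped in local optima; replication plus the topology support table
#' is the intended protocol) and the overall best model is returned.
#'
#' @param observed An [observed_stats()] object (from the VCF pipeline
#'   [observed_4jsfs()] or the synthetic factory [make_observed()]).
#' @param topologies A `gp4pg_model` or list of models, one per
#'   competing topology variant.
#' @param config An [engine_config()].
#' @param n_runs Number of independent replicate runs (default 1).
#' @param seed Master seed.
#' @return An object of class `gp4pg_fit` with `print()`, `summary()`,
#'   `coef()`, `plot()`, `simulate()` and `residuals()` methods.
#' @examples
#' \donttest{
#' sc <- scenario_basic(seed = 1, genome = genome_spec(50, 10000))
#' obs <- make_observed(sc, n_boot = 200)$observed
#' fit <- gp4pg(obs, sc$topologies,
#'              engine_config(population_size = 6, iterations = 3,
#'                            genome = sc$genome),
#'              seed = 1)
#' coef(fit)
#' }
#' @export
gp4pg <- function(observed, topologies, config = engine_config(),
                  n_runs = 1L, seed = 1L) {
  stopifnot(inherits(observed, "gp4pg_observed"))
  if (inherits(topologies, "gp4pg_model")) topologies <- list(topologies)
  reps <- run_replicates(topologies, observed, config, n_runs = n_runs,
                         seed = seed)
  best_i <- which.min(reps$final_errors)
  best <- reps$runs[[best_i]]$best
  structure(list(best_model = best$model, best_error = best$fitness,
                 best_run = best_i, runs = reps$runs,
                 support = reps$support,
                 final_errors = reps$final_errors,
                 observed = observed, config = config, seed = seed,
                 call = match.call()),
            class = "gp4pg_fit")
}

#' @export
print.gp4pg_fit <- function(x, ...) {
  cat("Demographic-model fit by evolutionary search\n")
  cat(sprintf("  %d run(s), best error %.4g (run %d), topology %s\n",
              length(x$runs), x$best_error, x$best_run,
              if (nzchar(x$best_model$topology_label))
                x$best_model$topology_label else "<unlabelled>"))
  if (length(x$runs) > 1L) {
    cat("  topology support:\n")
    print(x$support)
  }
  invisible(x)
}

#' @export
summary.gp4pg_fit <- function(object, ...) {
  rep <- trace_report(object$runs)
  out <- list(support = object$support, per_run = rep$per_run,
              final_error_range = rep$final_error_range,
              coefficients = stats::coef(object),
              best_error = object$best_error,
              topology = object$best_model$topology_label)
  class(out) <- "summary.gp4pg_fit"
  out
}

#' @export
print.summary.gp4pg_fit <- function(x, ...) {
  cat(sprintf("Best topology: %s (error %.4g)\n", x$topology, x$best_error))
  cat(sprintf("Final errors across runs: [%.4g, %.4g]\n",
              x$final_error_range[1], x$final_error_range[2]))
  cat("Support (runs won per topology):\n")
  print(x$support)
  cat("Fitted parameters of the best model:\n")
  print(x$coefficients)
  invisible(x)
}

#' @export
coef.gp4pg_fit <- function(object, ...) {
  model_coef(object$best_model)
}

#' Named parameter vector of a demographic model
#'
#' Split times (`t_split.<childA>:<childB>`), decay parameters
#' (`m_max.`/`m_min.`), per-ecodeme sizes (`ne.`), admixture times and
#' proportions.
#'
#' @param model A `gp4pg_model`.
#' @return Named numeric vector.
#' @export
model_coef <- function(model) {
  out <- numeric(0)
  for (e in model_splits(model)) {
    pair <- paste(e$child_a, e$child_b, sep = ":")
    out[paste0("t_split.", pair)] <- e$time
    out[paste0("m_max.", pair)] <- e$decay$m_max
    out[paste0("m_min.", pair)] <- e$decay$m_min
  }
  for (i in seq_len(nrow(model$ecodemes)))
    out[paste0("ne.", model$ecodemes$name[i])] <- model$ecodemes$ne[i]
  for (e in model$events) {
    if (e$type == "admixture_pulse") {
      key <- paste(e$source, e$target, sep = ">")
      out[paste0("t_admix.", key)] <- e$time
      out[paste0("p_admix.", key)] <- e$proportion
    } else if (e$type == "ne_change") {
      out[paste0("ne.", e$ecodeme, "@", round(e$time))] <- e$new_ne
    }
  }
  out
}

#' @export
plot.gp4pg_fit <- function(x, ...) {
  traces <- lapply(x$runs, `[[`, "trace")
  xmax <- max(vapply(traces, function(tr) max(tr$iteration), numeric(1)))
  ymax <- max(vapply(traces, function(tr) max(tr$best), numeric(1)))
  ymin <- min(vapply(traces, function(tr) min(tr$best), numeric(1)))
  graphics::plot(NULL, xlim = c(0, xmax), ylim = c(ymin, ymax),
                 xlab = "iteration", ylab = "best fitness error",
                 main = "Search error traces", log = if (ymin > 0) "y" else "",
                 ...)
  for (i in seq_along(traces))
    graphics::lines(traces[[i]]$iteration, traces[[i]]$best,
                    col = grDevices::adjustcolor(i, 0.7))
  invisible(x)
}

#' @export
simulate.gp4pg_fit <- function(object, nsim = 1, seed = NULL, ...) {
  if (is.null(seed)) seed <- object$seed
  out <- lapply(seq_len(nsim), function(i)
    simulate_dataset(object$best_model, object$config$genome,
                     seed = seed + i,
                     epoch_length = object$config$epoch_length))
  if (nsim == 1L) out[[1L]] else out
}

#' @export
residuals.gp4pg_fit <- function(object, nsim = 5L, seed = NULL, ...) {
  if (is.null(seed)) seed <- object$seed
  obs <- object$observed
  acc <- 0
  for (i in seq_len(nsim)) {
    sim <- simulate_dataset(object$best_model, object$config$genome,
                            seed = seed + i,
                            epoch_length = object$config$epoch_length)
    cc <- sim_to_counts2(sim, seed = seed + i)
    ss <- compute_sfs_summary(cc, obs$populations)
    if (obs$normalization == "proportions")
      ss <- suppressWarnings(normalize_sfs(ss))
    else ss$values <- ss$values * genome_scale_factor(obs, sim)
    acc <- acc + ss$values
  }
  (acc / nsim - obs$jsfs$values) / obs$sigma$values
}
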