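## The evolutionary search: a population of candidate demographic models
## evolved by invasive-weed-style fitness-proportional reproduction,
## mutation-only variation (the split topology is never altered), and
## rank-truncation selection with elitism.

#' Engine configuration
#'
#' @param population_size Number of candidate models kept per iteration.
#' @param iterations Maximum number of iterations (default 200).
#' @param s_min,s_max Offspring-count range of the reproduction rule
#'   (defaults 2 and 8: the best solution produces `s_max` offspring,
#'   the worst `s_min`).
#' @param epoch_length Migration-matrix update interval in generations.
#' @param genome [genome_spec()] used for every fitness simulation.
#' @param sim_replicates Simulations averaged per fitness evaluation.
#' @param normalization Scale on which simulated and observed summaries
#'   are compared.  `"counts"` (default) rescales simulated cell counts
#'   by the ratio of observed to simulated callable genome length, which
#'   keeps the total polymorphism level (hence absolute Ne and times)
#'   informative; `"proportions"` compares per-segment proportions only.
#' @param mutation Named list of per-operator probabilities and
#'   magnitudes; see [mutate_model()].
#' @param plateau_window,plateau_tol Stop early when the best error has
#'   not improved by more than `plateau_tol` over `plateau_window`
#'   iterations.
#' @param elitism Keep parents in the selection pool (guarantees a
#'   monotone non-increasing best-error trace).
#' @param retries Bounded resampling attempts for an operator that
#'   yields an invalid model before returning the parent copy.
#' @return An object of class `gp4pg_config`.
#' @export
engine_config <- function(population_size = 20L, iterations = 200L,
                          s_min = 2L, s_max = 8L, epoch_length = 200,
                          genome = genome_spec(),
                          sim_replicates = 1L,
                          normalization = c("counts", "proportions"),
                          mutation = list(),
                          plateau_window = 50L, plateau_tol = 0,
                          elitism = TRUE, retries = 20L) {
  stopifnot(s_min >= 1, s_min <= s_max, iterations >= 1,
            population_size >= 1)
  mut <- utils::modifyList(list(
    p_time = 0.6, p_ne = 0.4, p_migration = 0.3, p_admixture = 0.2,
    p_add = 0.1, p_remove = 0.1,
    ne_sd = 0.5, mig_sd = 0.7, admix_sd = 0.5, time_sd = 0.4,
    p_time_global = 0.3, ne_range = c(100, 1e5), time_cap = NULL), mutation)
  structure(list(population_size = as.integer(population_size),
                 iterations = as.integer(iterations),
                 s_min = as.integer(s_min), s_max = as.integer(s_max),
                 epoch_length = epoch_length, genome = genome,
                 sim_replicates = as.integer(sim_replicates),
                 normalization = match.arg(normalization),
                 mutation = mut,
                 plateau_window = plateau_window,
                 plateau_tol = plateau_tol,
                 elitism = isTRUE(elitism), retries = as.integer(retries)),
            class = "gp4pg_config")
}

#' Offspring allocation of the reproduction rule
#'
#' The number of offspring is linear in the fitness error and
#' decreasing: the best candidate (lowest error `f_min`) produces
#' `s_max` offspring, the worst (`f_max`) produces `s_min`:
#' \deqn{S = \mathrm{round}\!\left((S_{max}-S_{min})
#'   \frac{f_{max}-f}{f_{max}-f_{min}} + S_{min}\right)}
#' with round-half-to-even.  When all candidates have equal error every
#' one produces `s_max` offspring.
#'
#' @param f Fitness error(s) of the candidate(s).
#' @param f_min,f_max Population's best and worst error.
#' @param s_min,s_max Offspring range (defaults 2 and 8).
#' @return Integer offspring count(s) in `[s_min, s_max]`.
#' @export
offspring_count <- function(f, f_min, f_max, s_min = 2L, s_max = 8L) {
  if (any(f < f_min) || any(f > f_max))
    stop("f must lie within [f_min, f_max]")
  if (f_max == f_min) return(rep(as.integer(s_max), length(f)))
  as.integer(round((s_max - s_min) * (f_max - f) / (f_max - f_min) + s_min))
}

## Validity bracket (lo, hi) for an event's time: the widest interval on
## which every ecodeme the event touches stays alive and the split
## partial order is preserved.
event_time_bracket <- function(model, i) {
  e <- model$events[[i]]
  others <- model$events[-i]
  if (e$type == "soft_split") {
    lo <- 0; hi <- creation_time(model, e$parent)
    for (ch in c(e$child_a, e$child_b)) {
      for (s in others)
        if (s$type == "soft_split" && s$parent == ch)
          lo <- max(lo, s$time)
      for (o in others)   # non-split events needing the child alive
        if (touches(o, ch)) lo <- max(lo, o$time)
    }
    for (o in others)     # events needing the parent alive
      if (o$type != "soft_split" && touches(o, e$parent))
        hi <- min(hi, o$time)
  } else {
    who <- event_ecodemes(e)
    lo <- max(vapply(who, function(nm) parent_split_time(model, nm),
                     numeric(1)))
    hi <- min(vapply(who, function(nm) creation_time(model, nm), numeric(1)))
  }
  c(lo, hi)
}

event_ecodemes <- function(e) {
  switch(e$type,
    soft_split = c(e$parent, e$child_a, e$child_b),
    admixture_pulse = c(e$source, e$target),
    ne_change = ,
    deme_count_change = e$ecodeme,
    migration_rate_change = e$pair)
}

touches <- function(e, nm) nm %in% event_ecodemes(e) && e$type != "soft_split"

runif_log <- function(lo, hi) exp(stats::runif(1, log(lo), log(hi)))

#' Mutate a candidate demographic model
#'
#' Applies one or more stochastic operators and always returns a model
#' passing [validate_model()] (bounded retries, then the parent copy):
#' perturb an event time (log-uniform strictly inside its validity
#' bracket), perturb a per-topodeme Ne (log-normal), perturb migration
#' parameters (decay `m_max`/`m_min`, internal topodeme rate) or an
#' admixture proportion, add a random non-split event, or remove one.
#' The split topology (order and identity of splits) is never altered.
#' Uses R's RNG stream; seed with `set.seed()` for reproducibility.
#'
#' @param model A valid `gp4pg_model`.
#' @param config An [engine_config()] (its `mutation` element holds the
#'   operator probabilities).
#' @return A valid mutated `gp4pg_model`.
#' @export
mutate_model <- function(model, config = engine_config()) {
  mu <- config$mutation
  oldest <- {
    tt <- vapply(model$events, `[[`, numeric(1), "time")
    if (length(tt)) max(tt) else 1000
  }
  time_cap <- mu$time_cap %||% (4 * oldest)
  for (attempt in seq_len(config$retries)) {
    cand <- model
    touched <- FALSE

    if (length(cand$events) && stats::runif(1) < mu$p_time) {
      i <- sample.int(length(cand$events), 1L)
      br <- event_time_bracket(cand, i)
      lo <- max(br[1], 1)
      hi <- min(br[2], time_cap)
      if (hi > lo * (1 + 1e-9)) {
        ## mostly local multiplicative steps, occasionally a global
        ## log-uniform jump across the whole bracket
        tnew <- if (stats::runif(1) < mu$p_time_global) runif_log(lo, hi)
                else min(max(cand$events[[i]]$time *
                               exp(stats::rnorm(1, 0, mu$time_sd)),
                             lo * (1 + 1e-9)), hi * (1 - 1e-9))
        cand$events[[i]]$time <- tnew
        if (cand$events[[i]]$type == "soft_split")
          cand$events[[i]]$decay$T_split <- tnew
        touched <- TRUE
      }
    }

    if (stats::runif(1) < mu$p_ne) {
      ne_ev <- which(vapply(cand$events, function(e)
        e$type == "ne_change", logical(1)))
      if (length(ne_ev) && stats::runif(1) < 0.5) {
        i <- ne_ev[sample.int(length(ne_ev), 1L)]
        cand$events[[i]]$new_ne <- min(max(
          cand$events[[i]]$new_ne * exp(stats::rnorm(1, 0, mu$ne_sd)),
          mu$ne_range[1]), mu$ne_range[2])
      } else {
        j <- sample.int(nrow(cand$ecodemes), 1L)
        cand$ecodemes$ne[j] <- min(max(
          cand$ecodemes$ne[j] * exp(stats::rnorm(1, 0, mu$ne_sd)),
          mu$ne_range[1]), mu$ne_range[2])
      }
      touched <- TRUE
    }

    if (stats::runif(1) < mu$p_migration) {
      sp <- which(vapply(cand$events, function(e)
        e$type == "soft_split", logical(1)))
      pick <- stats::runif(1)
      if (length(sp) && pick < 0.6) {
        i <- sp[sample.int(length(sp), 1L)]
        d <- cand$events[[i]]$decay
        m <- max(d$m_max, 1e-5) * exp(stats::rnorm(1, 0, mu$mig_sd))
        d$m_max <- min(max(m, d$m_min), 0.5)
        if (stats::runif(1) < 0.3)
          d$m_min <- min(max(d$m_min * exp(stats::rnorm(1, 0, mu$mig_sd)),
                             0), d$m_max)
        cand$events[[i]]$decay <- d
      } else {
        j <- sample.int(nrow(cand$ecodemes), 1L)
        m <- max(cand$ecodemes$m_internal[j], 1e-5) *
          exp(stats::rnorm(1, 0, mu$mig_sd))
        cand$ecodemes$m_internal[j] <- min(m, 0.1)
      }
      touched <- TRUE
    }

    adm <- which(vapply(cand$events, function(e)
      e$type == "admixture_pulse", logical(1)))
    if (length(adm) && stats::runif(1) < mu$p_admixture) {
      i <- adm[sample.int(length(adm), 1L)]
      p <- stats::plogis(stats::qlogis(cand$events[[i]]$proportion) +
                           stats::rnorm(1, 0, mu$admix_sd))
      cand$events[[i]]$proportion <- min(max(p, 1e-4), 1 - 1e-4)
      touched <- TRUE
    }

    if (stats::runif(1) < mu$p_add) {
      ev <- random_event(cand, mu, time_cap)
      if (!is.null(ev)) {
        cand$events[[length(cand$events) + 1L]] <- ev
        touched <- TRUE
      }
    }

    rem <- which(vapply(cand$events, function(e)
      e$type != "soft_split", logical(1)))
    if (length(rem) && stats::runif(1) < mu$p_remove) {
      cand$events[[rem[sample.int(length(rem), 1L)]]] <- NULL
      touched <- TRUE
    }

    if (!touched) next
    if (length(validate_model(cand)) == 0L) return(cand)
  }
  model
}

## Draw a random addable event (never a split); NULL if infeasible.
random_event <- function(model, mu, time_cap) {
  type <- sample(c("ne_change", "deme_count_change", "admixture_pulse",
                   "migration_rate_change"), 1L)
  draw_time <- function(names) {
    lo <- max(c(1, vapply(names, function(nm)
      parent_split_time(model, nm), numeric(1))))
    hi <- min(c(time_cap, vapply(names, function(nm)
      creation_time(model, nm), numeric(1))))
    if (hi <= lo * (1 + 1e-9)) return(NULL)
    runif_log(lo, hi * (1 - 1e-9))
  }
  nm <- sample(model$ecodemes$name, 2L)
  switch(type,
    ne_change = {
      t <- draw_time(nm[1]); if (is.null(t)) return(NULL)
      ne_change(nm[1], t, runif_log(mu$ne_range[1], mu$ne_range[2]))
    },
    deme_count_change = {
      t <- draw_time(nm[1]); if (is.null(t)) return(NULL)
      deme_count_change(nm[1], t, sample(1:4, 1L))
    },
    admixture_pulse = {
      t <- draw_time(nm); if (is.null(t)) return(NULL)
      admixture_pulse(nm[1], nm[2], t, stats::runif(1, 0.01, 0.5))
    },
    migration_rate_change = {
      t <- draw_time(nm); if (is.null(t)) return(NULL)
      migration_rate_change(nm, t, runif_log(1e-5, 1e-2))
    })
}

#' Evaluate a candidate model against the observed summary
#'
#' Simulates the candidate (see [simulate_dataset()]), projects the
#' counts to two chromosomes per population, computes the SFS summary in
#' the observed normalization, and returns the standardized fitness
#' ([sfs_fitness()]).  Reproducible for a fixed candidate and seed; a
#' failed simulation yields `NA` (assigned the worst fitness in the
#' population by [step_population()]).
#'
#' @param model A `gp4pg_model`.
#' @param observed An [observed_stats()] object.
#' @param config An [engine_config()].
#' @param seed Simulation seed.
#' @return Numeric fitness error (or `NA` on simulation failure).
#' @export
evaluate_candidate <- function(model, observed, config, seed) {
  vals <- vapply(seq_len(config$sim_replicates), function(r) {
    tryCatch({
      sim <- simulate_dataset(model, config$genome, seed = seed + (r - 1L),
                              epoch_length = config$epoch_length)
      cc <- sim_to_counts2(sim, seed = seed + (r - 1L))
      ss <- compute_sfs_summary(cc, observed$jsfs$populations)
      if (config$normalization == "proportions") {
        ss <- suppressWarnings(normalize_sfs(ss))
      } else {
        fac <- genome_scale_factor(observed, sim)
        ss$values <- ss$values * fac
      }
      sfs_fitness(ss, observed$jsfs, observed$sigma)
    }, error = function(e) NA_real_)
  }, numeric(1))
  if (all(is.na(vals))) NA_real_ else mean(vals, na.rm = TRUE)
}

new_candidate <- function(model, fitness = NA_real_, parent = NA_integer_,
                          iteration = 0L, id = NA_integer_) {
  list(model = model, fitness = fitness, parent = parent,
       iteration = iteration, id = id)
}

#' One iteration of the evolutionary search
#'
#' Every evaluated candidate produces [offspring_count()] mutated
#' children; children are evaluated (one common simulation seed per
#' iteration, so candidates compete on the same draw), pooled with the
#' parents when elitism is on, ranked by fitness ascending and truncated
#' to the population size.
#'
#' @param population List of evaluated candidates.
#' @param observed An [observed_stats()] object.
#' @param config An [engine_config()].
#' @param sim_seed Common simulation seed for this iteration's children.
#' @param iteration Iteration counter stored on the children.
#' @return The next population (list of evaluated candidates).
#' @export
step_population <- function(population, observed, config, sim_seed,
                            iteration = 1L) {
  f <- vapply(population, `[[`, numeric(1), "fitness")
  worst <- max(f, na.rm = TRUE)
  f[is.na(f)] <- worst
  S <- offspring_count(f, min(f), max(f), config$s_min, config$s_max)
  children <- list()
  for (i in seq_along(population)) {
    for (k in seq_len(S[i])) {
      m <- mutate_model(population[[i]]$model, config)
      fit <- evaluate_candidate(m, observed, config, sim_seed)
      children[[length(children) + 1L]] <-
        new_candidate(m, fit, parent = population[[i]]$id,
                      iteration = iteration,
                      id = length(population) + length(children) + 1L)
    }
  }
  pool <- if (config$elitism) c(population, children) else children
  fp <- vapply(pool, `[[`, numeric(1), "fitness")
  fp[is.na(fp)] <- max(fp, na.rm = TRUE) + 1
  pool[order(fp)][seq_len(min(config$population_size, length(pool)))]
}

#' Run the evolutionary search
#'
#' Iterates [step_population()] from an initial set of models (recycled
#' to the population size) for `config$iterations` iterations or until
#' the error reaches zero or plateaus.  The whole run is reproducible
#' from `seed`.
#'
#' @param initial_models List of valid `gp4pg_model`s (one or more per
#'   competing topology; mutation never alters a topology, so topologies
#'   compete only through the mixed initial population).
#' @param observed An [observed_stats()] object.
#' @param config An [engine_config()].
#' @param seed Master seed of the run.
#' @return An object of class `gp4pg_run`: `best` candidate, `trace`
#'   data frame (iteration, best and mean error), selected `topology`,
#'   and the seed.
#' @export
run_gp4pg <- function(initial_models, observed, config = engine_config(),
                      seed = 1L) {
  stopifnot(length(initial_models) >= 1L)
  with_seed(seed, {
    init <- rep(initial_models,
                length.out = config$population_size)
    ## one common simulation seed for the entire run: fitness is a
    ## deterministic function of the model, so ranking is consistent and
    ## elitism cannot lock in a lucky draw
    sim_seed <- sample.int(2^31 - 2L, 1L)
    population <- lapply(seq_along(init), function(i)
      new_candidate(init[[i]],
                    evaluate_candidate(init[[i]], observed, config,
                                       sim_seed),
                    iteration = 0L, id = i))
    f0 <- vapply(population, `[[`, numeric(1), "fitness")
    trace <- data.frame(iteration = 0L, best = min(f0, na.rm = TRUE),
                        mean = mean(f0, na.rm = TRUE))
    n_done <- 0L
    for (it in seq_len(config$iterations)) {
      population <- step_population(population, observed, config,
                                    sim_seed = sim_seed,
                                    iteration = it)
      f <- vapply(population, `[[`, numeric(1), "fitness")
      trace <- rbind(trace, data.frame(iteration = it,
                                       best = min(f, na.rm = TRUE),
                                       mean = mean(f, na.rm = TRUE)))
      n_done <- it
      if (min(f, na.rm = TRUE) == 0) break
      if (it >= config$plateau_window) {
        recent <- trace$best[trace$iteration >= it - config$plateau_window]
        if (max(recent) - min(recent) <= config$plateau_tol) break
      }
    }
    best <- population[[1L]]
    structure(list(best = best, trace = trace,
                   topology = best$model$topology_label,
                   population = population, seed = seed,
                   iterations_run = n_done),
              class = "gp4pg_run")
  })
}

#' @export
print.gp4pg_run <- function(x, ...) {
  cat(sprintf("Search run (seed %s): %d iterations, best error %.4g, topology %s\n",
              format(x$seed), x$iterations_run, x$best$fitness,
              if (nzchar(x$topology)) x$topology else "<unlabelled>"))
  invisible(x)
}

#' Independent replicate runs over a set of competing topologies
#'
#' Runs the search `n_runs` times with independent seeds; each run's
#' initial population mixes all topology variants round-robin.  The
#' supported topology of a run is the label of its final best model.
#'
#' @param topologies List of valid `gp4pg_model`s, one per topology
#'   variant (labels must be set).
#' @param observed An [observed_stats()] object.
#' @param config An [engine_config()].
#' @param n_runs Number of independent runs (default 40).
#' @param seed Master seed; run `i` uses `seed + i`.
#' @return An object of class `gp4pg_replicates`: `support` (named count
#'   of runs won per topology), `final_errors`, and the list of runs.
#' @export
run_replicates <- function(topologies, observed, config = engine_config(),
                           n_runs = 40L, seed = 1L) {
  stopifnot(length(topologies) >= 1L)
  labels <- vapply(topologies, `[[`, character(1), "topology_label")
  runs <- lapply(seq_len(n_runs), function(i)
    run_gp4pg(topologies, observed, config, seed = seed + i))
  support <- table(factor(vapply(runs, `[[`, character(1), "topology"),
                          levels = unique(labels)))
  structure(list(support = support,
                 final_errors = vapply(runs, function(r) r$best$fitness,
                                       numeric(1)),
                 runs = runs, seed = seed),
            class = "gp4pg_replicates")
}

#' @export
print.gp4pg_replicates <- function(x, ...) {
  cat(sprintf("%d replicate runs; final errors in [%.4g, %.4g]\n",
              length(x$runs),
              if (length(x$runs)) min(x$final_errors) else NA,
              if (length(x$runs)) max(x$final_errors) else NA))
  if (length(x$runs)) {
    cat("Topology support (runs won):\n")
    print(x$support)
  }
  invisible(x)
}
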