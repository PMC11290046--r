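## Reading and writing model definition files (YAML), and export to a
## demes-style YAML with topodemes expanded to individual demes and the
## migration decay discretized by the epoch schedule.

event_to_list <- function(e) {
  switch(e$type,
    soft_split = list(type = "soft_split", parent = e$parent,
                      child_a = e$child_a, child_b = e$child_b,
                      time = e$time, m_max = e$decay$m_max,
                      m_min = e$decay$m_min,
                      lambda_decay = e$decay$lambda_decay),
    admixture_pulse = list(type = "admixture_pulse", source = e$source,
                           target = e$target, time = e$time,
                           proportion = e$proportion),
    ne_change = list(type = "ne_change", ecodeme = e$ecodeme,
                     time = e$time, new_ne = e$new_ne),
    deme_count_change = list(type = "deme_count_change",
                             ecodeme = e$ecodeme, time = e$time,
                             new_count = e$new_count),
    migration_rate_change = list(type = "migration_rate_change",
                                 pair = as.list(e$pair), time = e$time,
                                 new_rate = e$new_rate),
    stop("unknown event type: ", e$type))
}

event_from_list <- function(x) {
  switch(x$type,
    soft_split = soft_split(x$parent, x$child_a, x$child_b, x$time,
                            m_max = x$m_max %||% 0, m_min = x$m_min %||% 0,
                            lambda_decay = x$lambda_decay %||% 1),
    admixture_pulse = admixture_pulse(x$source, x$target, x$time,
                                      x$proportion),
    ne_change = ne_change(x$ecodeme, x$time, x$new_ne),
    deme_count_change = deme_count_change(x$ecodeme, x$time, x$new_count),
    migration_rate_change = migration_rate_change(unlist(x$pair), x$time,
                                                  x$new_rate),
    stop("unknown event type: ", x$type))
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Write / read a model definition file
#'
#' Model definition files are structured YAML listing the ecodemes
#' (name, lattice position, topodeme count, per-topodeme Ne, internal
#' migration), the events with times in generations, the topology label
#' and the sampling specification.  `read_model_config()` and
#' [write_model_config()] round-trip exactly.
#'
#' @param model A `gp4pg_model`.
#' @param path File path.
#' @return `write_model_config()` returns `path` invisibly;
#'   `read_model_config()` returns a validated `gp4pg_model`.
#' @export
write_model_config <- function(model, path) {
  eco <- model$ecodemes
  x <- list(
    topology_label = model$topology_label,
    mutation_rate = model$mutation_rate,
    generation_time = model$generation_time,
    ecodemes = lapply(seq_len(nrow(eco)), function(i)
      list(name = eco$name[i], position = eco$position[i],
           n_topodemes = eco$n_topodemes[i], ne = eco$ne[i],
           m_internal = eco$m_internal[i])),
    events = lapply(model$events, event_to_list),
    sampling = as.list(model$sampling))
  yaml::write_yaml(x, path, precision = 15L)
  invisible(path)
}

#' @rdname write_model_config
#' @export
read_model_config <- function(path) {
  x <- yaml::read_yaml(path)
  ecodemes <- lapply(x$ecodemes, function(e)
    ecodeme(e$name, e$position, e$n_topodemes %||% 1L, e$ne %||% 5000,
            e$m_internal %||% 1e-3))
  demographic_model(
    ecodemes = ecodemes,
    events = lapply(x$events, event_from_list),
    topology_label = x$topology_label %||% "",
    sampling = if (length(x$sampling))
      stats::setNames(as.integer(unlist(x$sampling)), names(x$sampling)),
    mutation_rate = x$mutation_rate %||% 1.61e-8,
    generation_time = x$generation_time %||% 29)
}

#' Export a model to demes-style YAML
#'
#' Expands every topodeme to an individual deme and discretizes the
#' migration decay into piecewise-constant migration entries following
#' [epoch_schedule()].  Times follow the demes convention (generations
#' before present; `start_time` of a deme is its creation).
#'
#' @param model A valid `gp4pg_model`.
#' @param path File path for the YAML output.
#' @param epoch_length Epoch length for the migration discretization.
#' @return `path`, invisibly.
#' @export
write_demes_yaml <- function(model, path, epoch_length = 200) {
  sched <- epoch_schedule(model, epoch_length)
  eco <- model$ecodemes
  demes <- list()
  for (i in seq_len(nrow(eco))) {
    nm <- eco$name[i]
    ct <- creation_time(model, nm)
    k_max <- max(vapply(sched, function(e)
      sum(e$demes$ecodeme == nm), integer(1)))
    for (j in seq_len(max(1L, k_max))) {
      d <- list(name = paste0(nm, ".", j))
      if (is.finite(ct)) {
        d$start_time <- ct
        par <- NULL
        for (s in model_splits(model))
          if (nm %in% c(s$child_a, s$child_b)) par <- s$parent
        kp <- n_topodemes_at(model, par, ct)
        d$ancestors <- list(paste0(par, ".", min(j, kp)))
      }
      ## piecewise-constant size epochs, oldest first per demes convention
      ne_ev <- Filter(function(e) e$type == "ne_change" && e$ecodeme == nm,
                      model$events)
      times <- sort(vapply(ne_ev, `[[`, numeric(1), "time"), decreasing = TRUE)
      times <- times[times < ct]
      ep <- list()
      for (tt in times)
        ep[[length(ep) + 1L]] <- list(end_time = tt,
                                      start_size = ne_at(model, nm, tt))
      ep[[length(ep) + 1L]] <- list(end_time = 0,
                                    start_size = ne_at(model, nm, 0))
      d$epochs <- ep
      demes[[length(demes) + 1L]] <- d
    }
  }
  migrations <- list()
  for (e in sched) {
    M <- e$M
    if (!is.finite(e$end) || nrow(M) < 2L) next
    idx <- which(upper.tri(M) & M > 0, arr.ind = TRUE)
    for (r in seq_len(nrow(idx))) {
      migrations[[length(migrations) + 1L]] <- list(
        demes = list(rownames(M)[idx[r, 1]], colnames(M)[idx[r, 2]]),
        start_time = e$end, end_time = e$start, rate = M[idx[r, 1], idx[r, 2]])
    }
  }
  pulses <- list()
  for (ev in model$events) {
    if (ev$type != "admixture_pulse") next
    ks <- n_topodemes_at(model, ev$source, ev$time)
    kt <- n_topodemes_at(model, ev$target, ev$time)
    for (j in seq_len(kt))
      pulses[[length(pulses) + 1L]] <- list(
        sources = list(paste0(ev$source, ".", min(j, ks))),
        dest = paste0(ev$target, ".", j),
        time = ev$time, proportions = list(ev$proportion))
  }
  out <- list(description = sprintf("topology %s", model$topology_label),
              time_units = "generations", demes = demes)
  if (length(migrations)) out$migrations <- migrations
  if (length(pulses)) out$pulses <- pulses
  yaml::write_yaml(out, path, precision = 15L)
  invisible(path)
}
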