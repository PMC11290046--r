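## Demographic models as time-ordered event graphs over ecodemes.
##
## An ecodeme is a named population unit occupying one slot on a 1-D
## lattice; internally it is structured as a nearest-neighbour
## stepping-stone chain of topodemes (local demes).  Models are built
## from a set of ecodemes plus a list of demographic events; population
## splits are "soft": after a split the two child ecodemes keep
## exchanging migrants at a rate that decays exponentially toward an
## asymptote.  All times are in generations before present (present = 0,
## increasing into the past); splits are instantaneous backward merges.

#' Define an ecodeme
#'
#' An ecodeme is a population unit placed on a one-dimensional lattice.
#' It contains `n_topodemes` local demes arranged as a nearest-neighbour
#' stepping-stone chain, each of diploid effective size `ne`.
#'
#' @param name Character label, unique within a model.
#' @param position Integer lattice index; ecodemes are ordered by
#'   position and the distance between adjacent ecodemes is zero, so
#'   lattice adjacency alone gates between-ecodeme migration.
#' @param n_topodemes Positive integer number of topodemes at present
#'   (time-varying via [deme_count_change()] events).
#' @param ne Positive diploid effective size per topodeme at present
#'   (time-varying via [ne_change()] events).
#' @param m_internal Per-generation migration proportion exchanged
#'   between adjacent topodemes within this ecodeme (0 disables internal
#'   migration, the "no current migration" model variants).
#' @return An object of class `gp4pg_ecodeme`.
#' @examples
#' ecodeme("WestAfrica", position = 1, n_topodemes = 2, ne = 1e4)
#' @export
ecodeme <- function(name, position, n_topodemes = 1L, ne = 5000,
                    m_internal = 1e-3) {
  stopifnot(is.character(name), length(name) == 1L, nzchar(name))
  structure(list(name = name, position = as.integer(position),
                 n_topodemes = as.integer(n_topodemes), ne = as.numeric(ne),
                 m_internal = as.numeric(m_internal)),
            class = "gp4pg_ecodeme")
}

#' Migration-decay parameters of a soft split
#'
#' After a split at time `T_split` the two child ecodemes exchange
#' migrants at a per-generation rate
#' \deqn{m(t) = m_{min} + (m_{max} - m_{min})
#'   e^{-\lambda (T_{split} - t)/L}}
#' where `t` is the time in generations before present (`t <= T_split`),
#' `L` the epoch length (default 200 generations, the migration-matrix
#' update interval) and `lambda_decay` the decay constant per epoch.
#' The rate equals `m_max` at the split and approaches `m_min` as the
#' divergence extends to infinity.
#'
#' @param m_max Per-generation migration proportion at the split.
#' @param m_min Asymptotic per-generation migration proportion.
#' @param T_split Time of the split, generations before present.
#' @param lambda_decay Positive decay constant per epoch.
#' @return An object of class `gp4pg_decay`.
#' @export
migration_decay <- function(m_max, m_min = 0, T_split, lambda_decay = 1) {
  if (!(m_min >= 0 && m_min <= m_max && m_max < 1))
    stop("migration decay requires 0 <= m_min <= m_max < 1")
  if (!(T_split > 0)) stop("T_split must be positive")
  if (!(lambda_decay > 0)) stop("lambda_decay must be positive")
  structure(list(m_max = as.numeric(m_max), m_min = as.numeric(m_min),
                 T_split = as.numeric(T_split),
                 lambda_decay = as.numeric(lambda_decay)),
            class = "gp4pg_decay")
}

#' Evaluate the post-split migration decay
#'
#' @param decay A [migration_decay()] object.
#' @param t Time in generations before present, `0 <= t <= T_split`.
#' @param epoch_length Epoch length in generations used as the time unit
#'   of the decay exponent.
#' @return Per-generation migration rate at `t`.
#' @export
migration_rate_at <- function(decay, t, epoch_length = 200) {
  stopifnot(inherits(decay, "gp4pg_decay"))
  if (any(t < 0)) stop("t must be non-negative")
  if (any(t > decay$T_split))
    stop("rate undefined before split (t > T_split: the ecodemes are merged)")
  w <- exp(-decay$lambda_decay * (decay$T_split - t) / epoch_length)
  decay$m_max * w + decay$m_min * (1 - w)   # exact at both boundaries
}

## ---- demographic events (tagged union) -------------------------------

new_event <- function(type, time, fields) {
  if (!is.numeric(time) || length(time) != 1L || !is.finite(time) || time <= 0)
    stop(sprintf("%s: event time must be a single positive number", type))
  structure(c(list(type = type, time = as.numeric(time)), fields),
            class = "gp4pg_event")
}

#' Demographic events
#'
#' Constructors for the events a demographic model is built from.  All
#' times are generations before present.
#'
#' * `soft_split(parent, child_a, child_b, time, ...)` — backward in
#'   time, `child_a` and `child_b` merge into `parent` at `time`;
#'   forward in time the parent splits into the two children, which then
#'   exchange migrants under the given decay (`m_max`, `m_min`,
#'   `lambda_decay`; see [migration_decay()], with `T_split = time`).
#' * `admixture_pulse(source, target, time, proportion)` — at `time`, a
#'   fraction `proportion` of `target`'s ancestry is instantaneously
#'   drawn from `source`.
#' * `ne_change(ecodeme, time, new_ne)` — per-topodeme effective size of
#'   `ecodeme` equals `new_ne` for all times at or older than `time`
#'   (until a yet older change); the ecodeme's own `ne` applies closer
#'   to the present.
#' * `deme_count_change(ecodeme, time, new_count)` — same convention for
#'   the topodeme count.
#' * `migration_rate_change(pair, time, new_rate)` — constant
#'   per-generation rate between the two named ecodemes for times at or
#'   older than `time` (until a yet older change or their merge),
#'   overriding the default (split-pair decay, or zero).
#'
#' @param parent,child_a,child_b,source,target,ecodeme Ecodeme names.
#' @param time Event time, generations before present (> 0).
#' @param m_max,m_min,lambda_decay Migration-decay parameters of a soft
#'   split.
#' @param proportion Admixture proportion in (0, 1).
#' @param new_ne Positive diploid effective size.
#' @param new_count Positive integer topodeme count.
#' @param pair Character vector of two distinct ecodeme names.
#' @param new_rate Per-generation migration proportion in \[0, 1).
#' @return An object of class `gp4pg_event`.
#' @name events
NULL

#' @rdname events
#' @export
soft_split <- function(parent, child_a, child_b, time, m_max = 0,
                       m_min = 0, lambda_decay = 1) {
  decay <- migration_decay(m_max = m_max, m_min = m_min, T_split = time,
                           lambda_decay = lambda_decay)
  new_event("soft_split", time,
            list(parent = parent, child_a = child_a, child_b = child_b,
                 decay = decay))
}

#' @rdname events
#' @export
admixture_pulse <- function(source, target, time, proportion) {
  if (!(proportion > 0 && proportion < 1))
    stop("admixture proportion must lie in (0, 1)")
  new_event("admixture_pulse", time,
            list(source = source, target = target,
                 proportion = as.numeric(proportion)))
}

#' @rdname events
#' @export
ne_change <- function(ecodeme, time, new_ne) {
  if (!(new_ne >= 1)) stop("new_ne must be >= 1")
  new_event("ne_change", time,
            list(ecodeme = ecodeme, new_ne = as.numeric(new_ne)))
}

#' @rdname events
#' @export
deme_count_change <- function(ecodeme, time, new_count) {
  if (!(new_count >= 1)) stop("new_count must be >= 1")
  new_event("deme_count_change", time,
            list(ecodeme = ecodeme, new_count = as.integer(new_count)))
}

#' @rdname events
#' @export
migration_rate_change <- function(pair, time, new_rate) {
  if (length(pair) != 2L || pair[1] == pair[2])
    stop("pair must name two distinct ecodemes")
  if (!(new_rate >= 0 && new_rate < 1)) stop("new_rate must lie in [0, 1)")
  new_event("migration_rate_change", time,
            list(pair = as.character(pair), new_rate = as.numeric(new_rate)))
}

## ---- model -----------------------------------------------------------

#' Assemble a demographic model
#'
#' A demographic model is a set of ecodemes plus a list of demographic
#' events.  Soft splits define a binary tree over the ecodemes: every
#' non-root ecodeme is created (backward: destroyed) by exactly one
#' split, and present-day (leaf) ecodemes are the ones never appearing
#' as a split parent.  Samples are drawn from leaf ecodemes.
#'
#' @param ecodemes List of [ecodeme()] objects (present-day and
#'   ancestral).
#' @param events List of [events] objects.
#' @param topology_label Free-form label identifying the split topology
#'   (e.g. `"D"` or `"D+mig"`).
#' @param sampling Named integer vector: sampled chromosomes per leaf
#'   ecodeme.  Defaults to 2 chromosomes for every leaf.
#' @param mutation_rate Per-bp per-generation mutation rate.
#' @param generation_time Generation time in years (used only to convert
#'   reported times).
#' @param validate If `TRUE` (default) fail on an invalid model.
#' @return An object of class `gp4pg_model`.
#' @examples
#' m <- demographic_model(
#'   ecodemes = list(ecodeme("A", 1), ecodeme("B", 2), ecodeme("AB", 3)),
#'   events = list(soft_split("AB", "A", "B", time = 1000, m_max = 0.01)))
#' @export
demographic_model <- function(ecodemes, events = list(),
                              topology_label = "",
                              sampling = NULL,
                              mutation_rate = 1.61e-8,
                              generation_time = 29,
                              validate = TRUE) {
  stopifnot(is.list(ecodemes), length(ecodemes) >= 1L)
  eco <- do.call(rbind, lapply(ecodemes, function(e) {
    stopifnot(inherits(e, "gp4pg_ecodeme"))
    data.frame(name = e$name, position = e$position,
               n_topodemes = e$n_topodemes, ne = e$ne,
               m_internal = e$m_internal, stringsAsFactors = FALSE)
  }))
  model <- structure(list(ecodemes = eco, events = events,
                          topology_label = topology_label,
                          sampling = sampling,
                          mutation_rate = mutation_rate,
                          generation_time = generation_time),
                     class = "gp4pg_model")
  if (is.null(sampling)) {
    leaves <- leaf_ecodemes(model)
    model$sampling <- stats::setNames(rep(2L, length(leaves)), leaves)
  } else {
    model$sampling <- stats::setNames(as.integer(sampling), names(sampling))
  }
  if (validate) {
    bad <- validate_model(model)
    if (length(bad))
      stop("invalid demographic model:\n  - ", paste(bad, collapse = "\n  - "))
  }
  model
}

model_splits <- function(model) {
  ev <- Filter(function(e) e$type == "soft_split", model$events)
  ev[order(vapply(ev, `[[`, numeric(1), "time"))]
}

#' @export
print.gp4pg_model <- function(x, ...) {
  sp <- model_splits(x)
  cat(sprintf("Demographic model [%s]: %d ecodemes, %d events (%d splits)\n",
              if (nzchar(x$topology_label)) x$topology_label else "unlabelled",
              nrow(x$ecodemes), length(x$events), length(sp)))
  cat(sprintf("  leaves: %s\n", paste(leaf_ecodemes(x), collapse = ", ")))
  for (e in sp)
    cat(sprintf("  split %s -> (%s, %s) at %g gen, m_max=%g m_min=%g\n",
                e$parent, e$child_a, e$child_b, e$time,
                e$decay$m_max, e$decay$m_min))
  invisible(x)
}

#' Present-day (sampled) ecodemes of a model
#'
#' @param model A `gp4pg_model`.
#' @return Character vector of ecodeme names that never act as a split
#'   parent, i.e. that persist to the present.
#' @export
leaf_ecodemes <- function(model) {
  parents <- vapply(model_splits(model), `[[`, character(1), "parent")
  setdiff(model$ecodemes$name, parents)
}

## Creation time: the time of the split in which `name` is a child
## (backward: the moment it disappears into its parent).  Inf for root.
creation_time <- function(model, name) {
  for (e in model_splits(model))
    if (name %in% c(e$child_a, e$child_b)) return(e$time)
  Inf
}

## Time of the split in which `name` is the parent (backward: the moment
## it comes into existence).  0 for leaves.
parent_split_time <- function(model, name) {
  for (e in model_splits(model)) if (e$parent == name) return(e$time)
  0
}

alive_at <- function(model, name, t) {
  t >= parent_split_time(model, name) & t < creation_time(model, name)
}

## Piecewise-constant look-up: `base` applies on [0, first change);
## a change at time T applies for t >= T until the next older change.
.state_at <- function(base, times, values, t) {
  if (length(times) == 0L) return(base)
  o <- order(times)
  times <- times[o]; values <- values[o]
  i <- findInterval(t, times)
  if (i == 0L) base else values[i]
}

ne_at <- function(model, name, t) {
  ev <- Filter(function(e) e$type == "ne_change" && e$ecodeme == name,
               model$events)
  .state_at(model$ecodemes$ne[model$ecodemes$name == name],
            vapply(ev, `[[`, numeric(1), "time"),
            vapply(ev, `[[`, numeric(1), "new_ne"), t)
}

n_topodemes_at <- function(model, name, t) {
  ev <- Filter(function(e) e$type == "deme_count_change" && e$ecodeme == name,
               model$events)
  as.integer(.state_at(model$ecodemes$n_topodemes[model$ecodemes$name == name],
                       vapply(ev, `[[`, numeric(1), "time"),
                       vapply(ev, `[[`, numeric(1), "new_count"), t))
}

## Migration rate between two ecodemes at time t: an explicit
## migration_rate_change overrides (from its time backward); otherwise
## split-pair decay; otherwise zero.
pair_rate_at <- function(model, a, b, t, epoch_length = 200) {
  ev <- Filter(function(e) e$type == "migration_rate_change" &&
                 setequal(e$pair, c(a, b)), model$events)
  if (length(ev)) {
    times <- vapply(ev, `[[`, numeric(1), "time")
    if (t >= min(times))
      return(.state_at(NA_real_, times,
                       vapply(ev, `[[`, numeric(1), "new_rate"), t))
  }
  for (e in model_splits(model))
    if (setequal(c(e$child_a, e$child_b), c(a, b)) && t <= e$time)
      return(migration_rate_at(e$decay, t, epoch_length))
  0
}

## ---- validation ------------------------------------------------------

#' Validate a demographic model
#'
#' Checks every structural invariant of the event graph and returns a
#' report rather than failing: ecodeme field ranges, unique names and
#' lattice positions, the split tree (exactly one root, every non-root
#' created by exactly one split, split times decreasing from root to
#' leaves), event references and time ranges (events only touch
#' ecodemes alive at their time), and the sampling specification.
#'
#' @param model A `gp4pg_model`.
#' @return Character vector of violations; `character(0)` if the model
#'   is valid.
#' @export
validate_model <- function(model) {
  bad <- character(0)
  eco <- model$ecodemes
  if (anyDuplicated(eco$name))
    bad <- c(bad, "duplicate ecodeme names")
  if (anyDuplicated(eco$position))
    bad <- c(bad, "ecodeme lattice positions are not distinct")
  if (any(eco$n_topodemes < 1))
    bad <- c(bad, "n_topodemes must be >= 1")
  if (any(eco$ne < 1))
    bad <- c(bad, "ne_per_topodeme must be >= 1")
  if (any(eco$m_internal < 0 | eco$m_internal >= 1))
    bad <- c(bad, "internal migration must lie in [0, 1)")

  exists_ok <- function(nm) all(nm %in% eco$name)
  splits <- model_splits(model)

  ## split tree structure
  child_of <- list()
  for (e in splits) {
    who <- c(e$parent, e$child_a, e$child_b)
    if (!exists_ok(who)) {
      bad <- c(bad, sprintf("split at t=%g names unknown ecodeme(s): %s",
                            e$time, paste(setdiff(who, eco$name),
                                          collapse = ", ")))
      next
    }
    if (anyDuplicated(who))
      bad <- c(bad, sprintf("split at t=%g: parent and children must be three distinct ecodemes",
                            e$time))
    for (ch in c(e$child_a, e$child_b)) {
      if (!is.null(child_of[[ch]]))
        bad <- c(bad, sprintf("ecodeme %s is created by more than one split", ch))
      child_of[[ch]] <- e$time
    }
  }
  roots <- setdiff(eco$name, names(child_of))
  if (length(roots) != 1L)
    bad <- c(bad, sprintf("model must have exactly one root ecodeme, found %d (%s)",
                          length(roots), paste(roots, collapse = ", ")))
  if (nrow(eco) != 1L + 2L * length(splits))
    bad <- c(bad, sprintf("%d ecodemes with %d splits: every non-root ecodeme must be created by exactly one split",
                          nrow(eco), length(splits)))
  for (e in splits) {
    ## a child's own split must be younger than the split creating it
    for (ch in c(e$child_a, e$child_b)) {
      pt <- parent_split_time(model, ch)
      if (pt > 0 && pt >= e$time)
        bad <- c(bad, sprintf("split of %s at t=%g is not younger than its creation at t=%g",
                              ch, pt, e$time))
    }
    ct <- creation_time(model, e$parent)
    if (ct <= e$time)
      bad <- c(bad, sprintf("parent %s of split at t=%g is itself created at t=%g (must be older)",
                            e$parent, e$time, ct))
  }

  ## non-split events
  for (e in model$events) {
    switch(e$type,
      admixture_pulse = {
        for (nm in c(e$source, e$target)) {
          if (!exists_ok(nm)) {
            bad <- c(bad, sprintf("admixture at t=%g names unknown ecodeme %s",
                                  e$time, nm)); next
          }
          if (e$time >= creation_time(model, nm))
            bad <- c(bad, sprintf("admixture at t=%g predates split creating %s: admixture predates split",
                                  e$time, nm))
          if (e$time < parent_split_time(model, nm))
            bad <- c(bad, sprintf("admixture at t=%g: %s does not yet exist (its own split is at t=%g)",
                                  e$time, nm, parent_split_time(model, nm)))
        }
        if (e$source == e$target)
          bad <- c(bad, sprintf("admixture at t=%g: source equals target", e$time))
      },
      ne_change = ,
      deme_count_change = {
        nm <- e$ecodeme
        if (!exists_ok(nm))
          bad <- c(bad, sprintf("%s at t=%g names unknown ecodeme %s",
                                e$type, e$time, nm))
        else if (e$time >= creation_time(model, nm) ||
                 e$time < parent_split_time(model, nm))
          bad <- c(bad, sprintf("%s at t=%g: ecodeme %s is not alive then",
                                e$type, e$time, nm))
      },
      migration_rate_change = {
        if (!exists_ok(e$pair))
          bad <- c(bad, sprintf("migration change at t=%g names unknown ecodeme(s)",
                                e$time))
        else if (!all(vapply(e$pair, function(nm) alive_at(model, nm, e$time),
                             logical(1))))
          bad <- c(bad, sprintf("migration change at t=%g: both ecodemes must be alive",
                                e$time))
      },
      soft_split = NULL,
      bad <- c(bad, sprintf("unknown event type %s", e$type)))
  }

  ## sampling: only leaves carry samples
  leaves <- leaf_ecodemes(model)
  bad_samp <- setdiff(names(model$sampling), leaves)
  if (length(bad_samp))
    bad <- c(bad, sprintf("sampling names non-leaf ecodeme(s): %s",
                          paste(bad_samp, collapse = ", ")))
  if (any(model$sampling < 1))
    bad <- c(bad, "sampled chromosome counts must be >= 1")
  bad
}

## ---- migration matrix and epoch schedule -----------------------------

## Topodeme labels of the alive ecodemes at time t, lattice order.
alive_demes_at <- function(model, t) {
  eco <- model$ecodemes[order(model$ecodemes$position), , drop = FALSE]
  alive <- vapply(eco$name, function(nm) alive_at(model, nm, t), logical(1))
  eco <- eco[alive, , drop = FALSE]
  out <- do.call(rbind, lapply(seq_len(nrow(eco)), function(i) {
    k <- n_topodemes_at(model, eco$name[i], t)
    data.frame(ecodeme = eco$name[i], index = seq_len(k),
               deme = paste0(eco$name[i], ".", seq_len(k)),
               ne = ne_at(model, eco$name[i], t),
               m_internal = eco$m_internal[i], stringsAsFactors = FALSE)
  }))
  out
}

#' Migration matrix over all topodemes alive at a time
#'
#' Builds the symmetric per-generation migration matrix at time `t`:
#' adjacent topodemes within an ecodeme exchange migrants at the
#' ecodeme's internal rate (nearest-neighbour stepping stone), and the
#' edge topodemes of a split pair of ecodemes exchange at the decay rate
#' of their split evaluated at `t` (or at an explicit
#' [migration_rate_change()] override).  All other entries are zero.
#'
#' @param model A valid `gp4pg_model`.
#' @param t Time in generations before present (>= 0).
#' @param epoch_length Epoch length used in the decay exponent.
#' @return Square numeric matrix with topodeme labels as dimnames.
#' @export
build_migration_matrix <- function(model, t, epoch_length = 200) {
  if (t < 0) stop("t must be non-negative")
  demes <- alive_demes_at(model, t)
  n <- nrow(demes)
  M <- matrix(0, n, n, dimnames = list(demes$deme, demes$deme))
  ## within-ecodeme stepping-stone chain
  for (nm in unique(demes$ecodeme)) {
    idx <- which(demes$ecodeme == nm)
    if (length(idx) > 1L) {
      r <- demes$m_internal[idx[1]]
      for (j in seq_len(length(idx) - 1L)) {
        M[idx[j], idx[j + 1L]] <- r
        M[idx[j + 1L], idx[j]] <- r
      }
    }
  }
  ## between-ecodeme rates through lattice-edge topodemes
  alive_eco <- unique(demes$ecodeme)
  if (length(alive_eco) > 1L) {
    for (i in seq_len(length(alive_eco) - 1L)) {
      for (j in seq((i + 1L), length(alive_eco))) {
        a <- alive_eco[i]; b <- alive_eco[j]   # a left of b on the lattice
        r <- pair_rate_at(model, a, b, t, epoch_length)
        if (r > 0) {
          ia <- max(which(demes$ecodeme == a))  # right edge of a
          ib <- min(which(demes$ecodeme == b))  # left edge of b
          M[ia, ib] <- r
          M[ib, ia] <- r
        }
      }
    }
  }
  M
}

#' Discretize a model into piecewise-constant epochs
#'
#' Tiles time from the present to the oldest event with epochs of at
#' most `epoch_length` generations.  Within an epoch every rate and size
#' is constant; the migration decay of each soft split is evaluated at
#' the epoch start.  Every discrete event time starts a new epoch
#' boundary even off the regular grid.  The final epoch is open-ended
#' (ancestral single population).
#'
#' @param model A valid `gp4pg_model`.
#' @param epoch_length Epoch length in generations (default 200, the
#'   migration-matrix update interval).
#' @return An object of class `gp4pg_epochs`: a list of epochs, each
#'   with elements `start`, `end`, `demes` (data frame of alive
#'   topodemes with sizes) and `M` (migration matrix).
#' @export
epoch_schedule <- function(model, epoch_length = 200) {
  bad <- validate_model(model)
  if (length(bad)) stop("invalid model: ", paste(bad, collapse = "; "))
  ev_times <- vapply(model$events, `[[`, numeric(1), "time")
  t_max <- if (length(ev_times)) max(ev_times) else 0
  grid <- if (t_max > 0) seq(0, t_max, by = epoch_length) else 0
  bounds <- sort(unique(c(0, grid, ev_times)))
  starts <- bounds
  ends <- c(bounds[-1L], Inf)
  epochs <- lapply(seq_along(starts), function(i) {
    demes <- alive_demes_at(model, starts[i])
    list(start = starts[i], end = ends[i], demes = demes,
         M = build_migration_matrix(model, starts[i], epoch_length))
  })
  structure(epochs, class = "gp4pg_epochs",
            epoch_length = epoch_length)
}

#' @export
print.gp4pg_epochs <- function(x, ...) {
  cat(sprintf("Epoch schedule: %d epochs (length %g generations)\n",
              length(x), attr(x, "epoch_length")))
  for (e in x[seq_len(min(10L, length(x)))])
    cat(sprintf("  [%g, %g): %d demes, total off-diagonal migration %.3g\n",
                e$start, e$end, nrow(e$demes), sum(e$M)))
  if (length(x) > 10L) cat("  ...\n")
  invisible(x)
}
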