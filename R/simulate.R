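## Coalescent simulation of a demographic model: the model's epoch
## schedule is compiled into a plan for the compiled structured
## coalescent (one non-recombining genealogy per genomic block), and the
## resulting mutations are returned as a per-site table of derived
## counts per sampled population.

#' Genome specification for simulation
#'
#' @param n_blocks Number of independent genomic blocks (>= 1).
#' @param block_length Block length in bp.
#' @param recombination Per-bp per-generation recombination rate within a
#'   block.  The built-in coalescent backend simulates each block as a
#'   single non-recombining genealogy, so only `0` is accepted; blocks
#'   are always independent of each other.
#' @param seed Optional default seed carried with the spec.
#' @return An object of class `gp4pg_genome`.
#' @export
genome_spec <- function(n_blocks = 200L, block_length = 20000L,
                        recombination = 0, seed = NULL) {
  stopifnot(n_blocks >= 1, block_length >= 1)
  if (recombination != 0)
    stop("the built-in coalescent backend simulates non-recombining blocks; ",
         "recombination must be 0")
  structure(list(n_blocks = as.integer(n_blocks),
                 block_length = as.integer(block_length),
                 recombination = recombination, seed = seed),
            class = "gp4pg_genome")
}

## Evaluate code under a fixed seed without disturbing the caller's RNG.
with_seed <- function(seed, code) {
  has_old <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (has_old) get(".Random.seed", envir = globalenv())
  on.exit(if (has_old) assign(".Random.seed", old, envir = globalenv())
          else suppressWarnings(rm(".Random.seed", envir = globalenv())))
  set.seed(seed)
  force(code)
}

## Flat tables of a model, precomputed once per simulation plan: ecodeme
## order, aliveness intervals, piecewise-constant Ne / topodeme-count
## regimes, split pairs and migration overrides.  Index space: ecodemes
## in lattice order.
model_tables <- function(model) {
  o <- order(model$ecodemes$position)
  eco <- model$ecodemes[o, , drop = FALSE]
  n <- nrow(eco)
  idx <- stats::setNames(seq_len(n), eco$name)
  psplit <- numeric(n); creation <- rep(Inf, n)
  splits <- list(); pulses <- list(); overrides <- list()
  ne_ev <- vector("list", n); k_ev <- vector("list", n)
  for (e in model$events) {
    switch(e$type,
      soft_split = {
        creation[idx[[e$child_a]]] <- e$time
        creation[idx[[e$child_b]]] <- e$time
        psplit[idx[[e$parent]]] <- e$time
        splits[[length(splits) + 1L]] <-
          list(a = idx[[e$child_a]], b = idx[[e$child_b]],
               parent = idx[[e$parent]], time = e$time,
               m_max = e$decay$m_max, m_min = e$decay$m_min,
               lambda = e$decay$lambda_decay)
      },
      ne_change = {
        i <- idx[[e$ecodeme]]
        ne_ev[[i]] <- rbind(ne_ev[[i]], c(e$time, e$new_ne))
      },
      deme_count_change = {
        i <- idx[[e$ecodeme]]
        k_ev[[i]] <- rbind(k_ev[[i]], c(e$time, e$new_count))
      },
      admixture_pulse = {
        pulses[[length(pulses) + 1L]] <-
          list(src = idx[[e$source]], tgt = idx[[e$target]],
               time = e$time, prob = e$proportion)
      },
      migration_rate_change = {
        overrides[[length(overrides) + 1L]] <-
          list(i = idx[[e$pair[1]]], j = idx[[e$pair[2]]],
               time = e$time, rate = e$new_rate)
      })
  }
  step_at <- function(tab, base, t) {
    if (is.null(tab)) return(base)
    tab <- tab[order(tab[, 1]), , drop = FALSE]
    k <- findInterval(t, tab[, 1])
    if (k == 0L) base else tab[k, 2]
  }
  list(names = eco$name, idx = idx, n = n, m_internal = eco$m_internal,
       base_k = eco$n_topodemes, base_ne = eco$ne,
       psplit = psplit, creation = creation, splits = splits,
       pulses = pulses, overrides = overrides,
       ne_ev = ne_ev, k_ev = k_ev, step_at = step_at,
       k_at = function(i, t) as.integer(step_at(k_ev[[i]], eco$n_topodemes[i], t)),
       ne_at = function(i, t) step_at(ne_ev[[i]], eco$ne[i], t))
}

## Per-generation migration rate between ecodemes i < j (lattice order)
## at time t: explicit override if one is in force, else split-pair
## decay, else zero.
pair_rate_tables <- function(tb, i, j, t, epoch_length) {
  best <- -Inf; rate <- NA_real_
  for (ov in tb$overrides) {
    if (((ov$i == i && ov$j == j) || (ov$i == j && ov$j == i)) &&
        t >= ov$time && ov$time > best) {
      best <- ov$time; rate <- ov$rate
    }
  }
  if (!is.na(rate)) return(rate)
  for (s in tb$splits)
    if (((s$a == i && s$b == j) || (s$a == j && s$b == i)) && t <= s$time) {
      w <- exp(-s$lambda * (s$time - t) / epoch_length)
      return(s$m_max * w + s$m_min * (1 - w))
    }
  0
}

## Compile a model into the simulator plan: a global universe of deme
## slots (per-ecodeme maximum topodeme count across epochs), per-epoch
## coalescence rates and migration matrices over that universe, and the
## boundary transitions (split merges, deme-count collapses, admixture
## pulses).
sim_plan <- function(model, epoch_length = 200) {
  tb <- model_tables(model)
  ev_times <- vapply(model$events, `[[`, numeric(1), "time")
  t_max <- if (length(ev_times)) max(ev_times) else 0
  grid <- if (t_max > 0) seq(0, t_max, by = epoch_length) else 0
  bounds <- sort(unique(c(0, grid, ev_times)))

  max_k <- tb$base_k
  for (i in seq_len(tb$n))
    if (!is.null(tb$k_ev[[i]])) max_k[i] <- max(max_k[i], tb$k_ev[[i]][, 2])
  max_k <- as.integer(max_k)
  offset <- c(0L, cumsum(max_k))[seq_len(tb$n)]
  n_demes <- sum(max_k)

  epochs <- vector("list", length(bounds))
  for (bi in seq_along(bounds)) {
    t <- bounds[bi]
    alive <- tb$psplit <= t & t < tb$creation
    coal <- numeric(n_demes)
    M <- matrix(0, n_demes, n_demes)
    k_t <- integer(tb$n)
    for (i in which(alive)) {
      k <- tb$k_at(i, t)
      k_t[i] <- k
      coal[offset[i] + seq_len(k)] <- 1 / (2 * tb$ne_at(i, t))
      if (k > 1L && tb$m_internal[i] > 0) {
        for (j in seq_len(k - 1L)) {
          M[offset[i] + j, offset[i] + j + 1L] <- tb$m_internal[i]
          M[offset[i] + j + 1L, offset[i] + j] <- tb$m_internal[i]
        }
      }
    }
    al <- which(alive)
    if (length(al) > 1L) {
      for (ii in seq_len(length(al) - 1L)) {
        for (jj in seq((ii + 1L), length(al))) {
          a <- al[ii]; b <- al[jj]       # a left of b in lattice order
          r <- pair_rate_tables(tb, a, b, t, epoch_length)
          if (r > 0) {
            ia <- offset[a] + k_t[a]     # right edge of a
            ib <- offset[b] + 1L         # left edge of b
            M[ia, ib] <- r; M[ib, ia] <- r
          }
        }
      }
    }
    epochs[[bi]] <- list(t0 = t,
                         t1 = if (bi < length(bounds)) bounds[bi + 1L]
                              else Inf,
                         coal = coal, M = M)
  }

  just_below <- function(tt) tt - 1e-9 * max(1, abs(tt))
  transitions <- list()
  for (s in tb$splits) {
    kp <- tb$k_at(s$parent, s$time)
    map <- seq_len(n_demes)
    for (ch in c(s$a, s$b)) {
      kc <- tb$k_at(ch, just_below(s$time))
      for (j in seq_len(max_k[ch]))
        map[offset[ch] + j] <- offset[s$parent] + min(min(j, kc), kp)
    }
    transitions[[length(transitions) + 1L]] <-
      list(time = s$time, kind = "remap", map = map, rank = 2L)
  }
  for (i in seq_len(tb$n)) {
    if (is.null(tb$k_ev[[i]])) next
    for (r in seq_len(nrow(tb$k_ev[[i]]))) {
      tt <- tb$k_ev[[i]][r, 1]
      k_new <- as.integer(tb$k_ev[[i]][r, 2])
      k_recent <- tb$k_at(i, just_below(tt))
      if (k_new < k_recent) {
        map <- seq_len(n_demes)
        for (j in seq(k_new + 1L, k_recent))
          map[offset[i] + j] <- offset[i] + k_new
        transitions[[length(transitions) + 1L]] <-
          list(time = tt, kind = "remap", map = map, rank = 2L)
      }
    }
  }
  for (p in tb$pulses) {
    ks <- tb$k_at(p$src, p$time)
    kt <- tb$k_at(p$tgt, p$time)
    transitions[[length(transitions) + 1L]] <-
      list(time = p$time, kind = "pulse",
           from = offset[p$tgt] + seq_len(kt),
           to = offset[p$src] + pmin(seq_len(kt), ks),
           prob = p$prob, rank = 1L)
  }
  if (length(transitions)) {
    o <- order(vapply(transitions, `[[`, numeric(1), "time"),
               vapply(transitions, `[[`, integer(1), "rank"))
    transitions <- transitions[o]
  }

  pops <- names(model$sampling)
  sample_demes <- integer(0)
  sample_pop <- character(0)
  for (p in pops) {
    i <- tb$idx[[p]]
    central <- as.integer(ceiling(tb$k_at(i, 0) / 2))
    sample_demes <- c(sample_demes, rep(offset[i] + central,
                                        model$sampling[[p]]))
    sample_pop <- c(sample_pop, rep(p, model$sampling[[p]]))
  }
  list(n_demes = n_demes, epochs = epochs, transitions = transitions,
       sample_demes = sample_demes, sample_pop = sample_pop,
       offset = offset, max_k = max_k, eco_order = tb$names)
}

#' Simulate polymorphism data from a demographic model
#'
#' Runs the structured coalescent over the model's epoch schedule
#' (see [epoch_schedule()]): every block is an independent
#' non-recombining genealogy of the sampled chromosomes (drawn from the
#' lattice-central topodeme of each sampled ecodeme), mutations follow
#' the infinite-sites model at the model's mutation rate, and migration
#' follows the piecewise-constant epoch discretization exactly.
#'
#' @param model A valid `gp4pg_model`.
#' @param genome A [genome_spec()].
#' @param seed Integer seed; the same model, genome and seed reproduce
#'   the identical site table.
#' @param epoch_length Epoch length in generations.
#' @return An object of class `gp4pg_sim`: list with `sites` (data frame
#'   of `block`, `pos` and one derived-count column per sampled
#'   population), `populations`, `n_chrom` (named chromosome counts),
#'   and `callable_length` (`n_blocks * block_length`).
#' @export
simulate_dataset <- function(model, genome = genome_spec(), seed,
                             epoch_length = 200) {
  bad <- validate_model(model)
  if (length(bad)) stop("invalid model: ", paste(bad, collapse = "; "))
  if (length(model$sampling) == 0L) stop("model samples no ecodemes")
  if (missing(seed)) seed <- genome$seed
  if (is.null(seed)) stop("a seed is required")
  plan <- sim_plan(model, epoch_length)
  raw <- .coalescent_blocks(plan$n_demes, plan$epochs, plan$transitions,
                            plan$sample_demes,
                            model$mutation_rate * genome$block_length,
                            genome$n_blocks, as.double(seed %% 2^31))
  pops <- unique(plan$sample_pop)
  counts <- matrix(0L, nrow(raw), length(pops),
                   dimnames = list(NULL, pops))
  for (p in pops) {
    cols <- which(plan$sample_pop == p) + 1L
    counts[, p] <- as.integer(rowSums(raw[, cols, drop = FALSE]))
  }
  pos <- with_seed(seed + 1L,
    as.integer(ceiling(stats::runif(nrow(raw)) * genome$block_length)))
  ord <- order(raw[, 1L], pos)
  sites <- data.frame(block = raw[ord, 1L], pos = pos[ord])
  sites <- cbind(sites, as.data.frame(counts[ord, , drop = FALSE]))
  structure(list(sites = sites, populations = pops,
                 n_chrom = model$sampling[pops],
                 callable_length = as.numeric(genome$n_blocks) *
                   genome$block_length,
                 genome = genome, seed = seed),
            class = "gp4pg_sim")
}

#' @export
print.gp4pg_sim <- function(x, ...) {
  cat(sprintf("Simulated dataset: %d segregating sites over %d blocks (%.3g bp callable)\n",
              nrow(x$sites), x$genome$n_blocks, x$callable_length))
  cat("  populations:", paste(x$populations, collapse = ", "), "\n")
  invisible(x)
}

#' Project per-site counts to two chromosomes per population
#'
#' The summary statistics use three derived-allele states per population
#' (0, 1 or 2 copies on two chromosomes).  Populations sampled at more
#' than two chromosomes are downsampled site-by-site with the
#' hypergeometric distribution.
#'
#' @param sim A `gp4pg_sim` (or a data frame of per-site counts with a
#'   `n_chrom` attribute-like named vector passed via `n_chrom`).
#' @param seed Seed for the downsampling draws.
#' @return Integer matrix of per-site counts in `{0, 1, 2}` with one
#'   column per population; block ids in attribute `"block"`.
#' @export
sim_to_counts2 <- function(sim, seed = 1L) {
  stopifnot(inherits(sim, "gp4pg_sim"))
  if (any(sim$n_chrom < 2L))
    stop("at least 2 chromosomes per population are required")
  counts <- as.matrix(sim$sites[, sim$populations, drop = FALSE])
  storage.mode(counts) <- "integer"
  if (any(sim$n_chrom > 2L)) {
    with_seed(seed, {
      for (p in sim$populations) {
        nc <- sim$n_chrom[[p]]
        if (nc > 2L) {
          der <- counts[, p]
          counts[, p] <- as.integer(stats::rhyper(length(der), m = der,
                                                  n = nc - der, k = 2L))
        }
      }
    })
  }
  attr(counts, "block") <- sim$sites$block
  counts
}

#' Write a simulated site table as tab-separated text
#'
#' @param sim A `gp4pg_sim`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_site_table <- function(sim, path) {
  utils::write.table(sim$sites, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' Emit a simulated dataset as a toy VCF
#'
#' One pseudo-diploid individual per population is written from the two
#' sampled chromosomes (REF fixed to `A`, ALT to `G`, ancestral `AA=A`),
#' with passing QUAL/FILTER/DP fields, so the observed-data pipeline can
#' be round-tripped against simulations.  Blocks are written as
#' chromosomes `block1`, `block2`, ...
#'
#' @param sim A `gp4pg_sim` with two chromosomes per population.
#' @param path Output `.vcf` path.
#' @return `path`, invisibly.
#' @export
sim_to_vcf <- function(sim, path) {
  if (any(sim$n_chrom != 2L))
    stop("sim_to_vcf requires exactly 2 chromosomes per population")
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c("##fileformat=VCFv4.2",
               "##INFO=<ID=AA,Number=1,Type=String,Description=\"Ancestral allele\">",
               "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"Genotype\">",
               "##FORMAT=<ID=DP,Number=1,Type=Integer,Description=\"Read depth\">",
               paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER",
                       "INFO", "FORMAT", sim$populations), collapse = "\t")),
             con)
  gt <- c("0/0", "0/1", "1/1")
  s <- sim$sites
  for (i in seq_len(nrow(s))) {
    geno <- vapply(sim$populations,
                   function(p) paste0(gt[s[[p]][i] + 1L], ":30"),
                   character(1))
    writeLines(paste(c(paste0("block", s$block[i]), s$pos[i], ".", "A", "G",
                       "50", "PASS", "AA=A", "GT:DP", geno), collapse = "\t"),
               con)
  }
  invisible(path)
}
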