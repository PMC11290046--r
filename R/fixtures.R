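## Synthetic-data factory: toy-scale topology sets, simulated "observed"
## datasets with a truth sidecar for recovery tests, and a deterministic
## toy VCF + BED fixture exercising every filter class of the
## observed-data pipeline.

#' Toy-scale fixture parameters
#'
#' Defaults chosen so a full engine run finishes in minutes on one CPU
#' while keeping coalescent-realistic magnitudes: per-topodeme Ne in the
#' thousands, split times spread over 500-4000 generations, soft-split
#' migration 0.01 decaying to 0, and one topodeme per ecodeme.
#'
#' @param ne Per-topodeme diploid effective size.
#' @param t_min,t_max Youngest and oldest split times (generations).
#' @param m_max,m_min Soft-split migration decay range.
#' @param lambda_decay Decay constant per epoch.
#' @param n_topodemes Topodemes per leaf ecodeme.
#' @param m_internal Within-ecodeme topodeme migration of the
#'   "+mig" variants.
#' @return A list of scale parameters.
#' @export
fixture_scale <- function(ne = 5000, t_min = 500, t_max = 4000,
                          m_max = 0.01, m_min = 0, lambda_decay = 1,
                          n_topodemes = 1L, m_internal = 1e-3) {
  list(ne = ne, t_min = t_min, t_max = t_max, m_max = m_max,
       m_min = m_min, lambda_decay = lambda_decay,
       n_topodemes = n_topodemes, m_internal = m_internal)
}

## Caterpillar model over the given tip order with join times `times`.
caterpillar_model <- function(tips, times, scale, label,
                              m_internal = scale$m_internal) {
  n <- length(tips)
  stopifnot(length(times) == n - 1L)
  ecodemes <- lapply(seq_along(tips), function(i)
    ecodeme(tips[i], position = i, n_topodemes = scale$n_topodemes,
            ne = scale$ne, m_internal = m_internal))
  events <- list()
  cur <- tips[1]
  for (j in seq_len(n - 1L)) {
    anc <- if (j == n - 1L) "root" else paste0("anc", j)
    ecodemes[[length(ecodemes) + 1L]] <-
      ecodeme(anc, position = n + j, n_topodemes = scale$n_topodemes,
              ne = scale$ne, m_internal = m_internal)
    events[[j]] <- soft_split(anc, cur, tips[j + 1L], time = times[j],
                              m_max = scale$m_max, m_min = scale$m_min,
                              lambda_decay = scale$lambda_decay)
    cur <- anc
  }
  demographic_model(ecodemes, events, topology_label = label)
}

#' Generate a set of competing topology fixtures
#'
#' Builds `n_base` distinct split topologies over `n_pops` populations:
#' a caterpillar backbone over populations `pop1..pop(n-1)` with a focal
#' population inserted at `n_base` different depths, emulating competing
#' hypotheses about when one group diverged.  Each base topology is
#' emitted in two variants — with and without migration between
#' topodemes — labelled `B+mig`, `B-mig`, `C+mig`, ... so `n_base = 6`
#' base topologies yield 12 configurations.
#'
#' @param n_pops Number of sampled populations (3 to 8).
#' @param n_base Number of base topologies (default
#'   `min(n_pops - 2, 6)`; at most `n_pops - 1` are distinct).
#' @param scale A [fixture_scale()].
#' @return List of valid `gp4pg_model`s of length `2 * n_base`.
#' @export
make_topology_fixtures <- function(n_pops, n_base = NULL,
                                   scale = fixture_scale()) {
  stopifnot(n_pops >= 3, n_pops <= 8)
  if (is.null(n_base)) n_base <- min(max(n_pops - 2L, 1L), 6L)
  stopifnot(n_base >= 1, n_base <= n_pops - 1L)
  backbone <- paste0("pop", seq_len(n_pops - 1L))
  times <- seq(scale$t_min, scale$t_max, length.out = n_pops - 1L)
  out <- list()
  for (k in seq_len(n_base)) {
    tips <- append(backbone, "focal", after = k)
    for (mig in c(TRUE, FALSE)) {
      label <- paste0(LETTERS[k + 1L], if (mig) "+mig" else "-mig")
      out[[length(out) + 1L]] <-
        caterpillar_model(tips, times, scale, label,
                          m_internal = if (mig) scale$m_internal else 0)
    }
  }
  out
}

#' Scenario: a truth model with known parameters among competitors
#'
#' @param truth A valid `gp4pg_model` generating the "observed" data.
#' @param topologies List of competing models; the truth's topology
#'   label must appear among them.
#' @param genome [genome_spec()] of the observed dataset.
#' @param seed Master seed.
#' @param tolerance_factor Recovery tolerance (factor-2 notion).
#' @param config Optional [engine_config()] recommended for the scenario.
#' @param recovery_target Name of the split (as `"childA:childB"`) whose
#'   time is the scenario's recovery parameter; defaults to the deepest
#'   split.  With two sampled chromosomes per population the time of a
#'   young split is identified only jointly with the child Ne (a drift
#'   ratio), so the deep divergence is the meaningful absolute-time
#'   target.
#' @return An object of class `gp4pg_scenario`.
#' @export
scenario_spec <- function(truth, topologies, genome = genome_spec(),
                          seed = 1L, tolerance_factor = 2, config = NULL,
                          recovery_target = NULL) {
  labels <- vapply(topologies, `[[`, character(1), "topology_label")
  if (!truth$topology_label %in% labels)
    stop("the truth topology must be among the competitors")
  splits <- model_splits(truth)
  if (is.null(recovery_target)) {
    deepest <- splits[[length(splits)]]
    recovery_target <- paste(deepest$child_a, deepest$child_b, sep = ":")
  }
  structure(list(truth = truth, topologies = topologies, genome = genome,
                 seed = seed, tolerance_factor = tolerance_factor,
                 config = config, recovery_target = recovery_target),
            class = "gp4pg_scenario")
}

#' Built-in scenarios
#'
#' `scenario_basic()` is a 4-population scenario (two base topologies,
#' four variants); `scenario_recovery3()` is the 3-population parameter
#' and topology recovery scenario: truth split times 1200 and 3000
#' generations, Ne 5000, soft splits decaying from 0.005, with one wrong
#' competing split order.
#'
#' @param seed Master seed.
#' @param genome [genome_spec()] of the observed dataset.
#' @return A `gp4pg_scenario`.
#' @export
scenario_basic <- function(seed = 1L, genome = genome_spec()) {
  topo <- make_topology_fixtures(4L, n_base = 2L)
  scenario_spec(truth = topo[[1L]], topologies = topo, genome = genome,
                seed = seed)
}

#' @rdname scenario_basic
#' @export
scenario_recovery3 <- function(seed = 1L,
                               genome = genome_spec(n_blocks = 500L,
                                                    block_length = 50000L)) {
  truth_scale <- fixture_scale(ne = 5000, t_min = 1200, t_max = 3000,
                               m_max = 0.005)
  truth <- caterpillar_model(c("pop1", "focal", "pop2"),
                             times = c(1200, 3000), scale = truth_scale,
                             label = "B+mig")
  ## competitors start away from the truth (wrong times and sizes) so
  ## recovery is earned by the search, not the start point; the decay
  ## parameters are shared with the truth because free post-split
  ## migration trades off against split time (split-time/migration
  ## degeneracy), which would make absolute times unidentifiable
  start_scale <- fixture_scale(ne = 1500, t_min = 400, t_max = 5000,
                               m_max = 0.005)
  topo <- make_topology_fixtures(3L, n_base = 2L, scale = start_scale)
  scenario_spec(truth = truth, topologies = topo, genome = genome,
                seed = seed,
                config = engine_config(population_size = 10L,
                                       iterations = 30L, genome = genome,
                                       sim_replicates = 2L,
                                       mutation = list(p_add = 0,
                                                       p_remove = 0,
                                                       p_migration = 0)))
}

#' Simulate the observed dataset of a scenario
#'
#' Simulates the truth model, projects to two chromosomes per
#' population, computes the SFS summary and its block-bootstrap sigma,
#' and (optionally) persists `4jsfs.tsv`, `sigma.tsv`, the truth model
#' config and a truth sidecar JSON for recovery assertions.  Byte-stable
#' for a fixed scenario and seed.
#'
#' @param scenario A [scenario_spec()].
#' @param dir Optional output directory.
#' @param n_boot Bootstrap replicates for sigma.
#' @param normalization Comparison scale.
#' @return List with `observed` ([observed_stats()]), `truth`, `sim`,
#'   and `paths` (when `dir` is given).
#' @export
make_observed <- function(scenario, dir = NULL, n_boot = 1000L,
                          normalization = "counts") {
  sim <- simulate_dataset(scenario$truth, scenario$genome,
                          seed = scenario$seed)
  cc <- sim_to_counts2(sim, seed = scenario$seed)
  obs <- observed_stats(cc, populations = sim$populations,
                        n_boot = n_boot, seed = scenario$seed,
                        normalization = normalization,
                        callable_length = sim$callable_length)
  paths <- NULL
  if (!is.null(dir)) {
    dir.create(dir, recursive = TRUE, showWarnings = FALSE)
    paths <- list(jsfs = file.path(dir, "4jsfs.tsv"),
                  sigma = file.path(dir, "sigma.tsv"),
                  truth = file.path(dir, "truth.yaml"),
                  sidecar = file.path(dir, "truth.json"))
    write_jsfs(obs$jsfs, paths$jsfs)
    write_jsfs(obs$sigma, paths$sigma)
    write_model_config(scenario$truth, paths$truth)
    splits <- model_splits(scenario$truth)
    jsonlite::write_json(list(
      topology = scenario$truth$topology_label,
      split_times = stats::setNames(
        lapply(splits, `[[`, "time"),
        vapply(splits, function(s) paste(s$child_a, s$child_b, sep = ":"),
               character(1))),
      ne = stats::setNames(as.list(scenario$truth$ecodemes$ne),
                           scenario$truth$ecodemes$name),
      seed = scenario$seed), paths$sidecar, auto_unbox = TRUE,
      digits = NA, pretty = TRUE)
  }
  list(observed = obs, truth = scenario$truth, sim = sim, paths = paths)
}

## ---- toy VCF fixture --------------------------------------------------

toy_patterns <- list(c(1, 0, 0, 0), c(0, 1, 0, 0), c(1, 1, 0, 0),
                     c(2, 1, 0, 1), c(0, 0, 1, 2), c(1, 2, 1, 0),
                     c(0, 1, 1, 1), c(2, 2, 1, 0))

#' Write the toy VCF / BED / population fixture
#'
#' Generates a small deterministic multi-sample VCF (4 populations, one
#' diploid each, chromosome `chr1` of 100 kb) in which every filter
#' class is represented exactly once — low depth, low QUAL, non-PASS,
#' multiallelic, an indel plus a SNP inside its 6-bp flank, records
#' inside each mask (repeats, CNV, CpG, gene + 20-kb flank), an
#' ancestral-mismatch and a missing-ancestral record, and a flipped
#' (ancestral = ALT) survivor — together with the mask BEDs, a
#' sample-to-population table, and a sidecar JSON recording the expected
#' survivor set and per-site derived counts (the fixture's construction
#' is the oracle for the pipeline).
#'
#' @param dir Output directory.
#' @param include_indels Include the indel and its flanking SNP.
#' @param flip_case Include the ancestral-equals-ALT survivor (if
#'   `FALSE` that record carries `AA=REF` like the others).
#' @return List with file `paths`, `chrom_lengths`, `pops`, and
#'   `expected` (survivor positions, per-stage drops, derived-count
#'   matrix).
#' @export
make_toy_vcf <- function(dir, include_indels = TRUE, flip_case = TRUE) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  pops <- stats::setNames(paste0("pop", 1:4), paste0("s", 1:4))
  gt_of <- function(count) c("0/0", "0/1", "1/1")[count + 1L]

  survivor_pos <- c(5000L, if (include_indels) 10007L, 14000L, 15000L,
                    18000L, 21000L, 24000L, 27000L, 31000L, 35000L,
                    38000L, 85000L, 88000L, 91000L, 94000L, 97000L)
  counts <- t(vapply(seq_along(survivor_pos), function(i)
    toy_patterns[[(i - 1L) %% length(toy_patterns) + 1L]], numeric(4)))
  colnames(counts) <- unname(pops)

  rows <- list()
  add <- function(pos, ref, alt, qual, filt, info, gts, dps = rep(30L, 4)) {
    rows[[length(rows) + 1L]] <<- paste(
      c("chr1", pos, ".", ref, alt, qual, filt, info, "GT:DP",
        paste(gts, dps, sep = ":")), collapse = "\t")
  }
  for (i in seq_along(survivor_pos)) {
    pos <- survivor_pos[i]
    if (pos == 14000L && flip_case) {
      ## ancestral = ALT: derived count c means alt count 2 - c
      add(pos, "A", "G", 50, "PASS", "AA=G", gt_of(2L - counts[i, ]))
    } else {
      add(pos, "A", "G", 50, "PASS", "AA=A", gt_of(counts[i, ]))
    }
  }
  add(6000L, "A", "G", 50, "PASS", "AA=A", gt_of(c(1, 0, 0, 0)),
      dps = c(3L, 30L, 30L, 30L))                       # (i) depth
  add(7000L, "A", "G", 10, "PASS", "AA=A", gt_of(c(1, 0, 0, 0)))  # (ii) qual
  add(8000L, "A", "G", 50, "q10", "AA=A", gt_of(c(1, 0, 0, 0)))   # (iii) PASS
  add(9000L, "A", "G,T", 50, "PASS", "AA=A",
      c("1/2", "0/0", "0/0", "0/0"))                    # (vi) multiallelic
  if (include_indels) {
    add(10000L, "AT", "A", 50, "PASS", "AA=A",
        gt_of(c(1, 0, 0, 0)))                           # (v) indel
    add(10004L, "A", "G", 50, "PASS", "AA=A",
        gt_of(c(0, 1, 0, 0)))                           # (v) 4-bp flank
  }
  add(30250L, "A", "G", 50, "PASS", "AA=A", gt_of(c(1, 0, 0, 0)))  # repeats
  add(32250L, "A", "G", 50, "PASS", "AA=A", gt_of(c(1, 0, 0, 0)))  # CNV
  add(34100L, "A", "G", 50, "PASS", "AA=A", gt_of(c(1, 0, 0, 0)))  # CpG
  add(41000L, "A", "G", 50, "PASS", "AA=A", gt_of(c(1, 0, 0, 0)))  # gene flank
  add(12000L, "A", "G", 50, "PASS", "AA=T", gt_of(c(1, 0, 0, 0)))  # mismatch
  add(13000L, "A", "G", 50, "PASS", "DP=120", gt_of(c(1, 0, 0, 0)))  # no AA

  paths <- list(vcf = file.path(dir, "toy.vcf"),
                pops = file.path(dir, "pops.tsv"),
                repeats = file.path(dir, "repeats.bed"),
                cnv = file.path(dir, "cnv.bed"),
                genes = file.path(dir, "genes.bed"),
                cpg = file.path(dir, "cpg.bed"),
                sidecar = file.path(dir, "expected.json"))
  ord <- order(as.integer(vapply(rows, function(r)
    strsplit(r, "\t")[[1]][2], character(1))))
  writeLines(c("##fileformat=VCFv4.2",
               "##contig=<ID=chr1,length=100000>",
               "##INFO=<ID=AA,Number=1,Type=String,Description=\"Ancestral allele\">",
               "##INFO=<ID=DP,Number=1,Type=Integer,Description=\"Depth\">",
               "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"Genotype\">",
               "##FORMAT=<ID=DP,Number=1,Type=Integer,Description=\"Read depth\">",
               paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL",
                       "FILTER", "INFO", "FORMAT", names(pops)),
                     collapse = "\t"),
               unlist(rows[ord])), paths$vcf)
  writeLines(paste(names(pops), unname(pops), sep = "\t"), paths$pops)
  writeLines("chr1\t30000\t30300", paths$repeats)
  writeLines("chr1\t32000\t32300", paths$cnv)
  writeLines("chr1\t60000\t60100", paths$genes)
  writeLines("chr1\t34000\t34150", paths$cpg)

  expected <- list(
    survivors = survivor_pos,
    counts = counts,
    blocks = ifelse(survivor_pos < 40000L, 1L, 2L),
    drops_filters = list(depth = 1L, qual = 1L, not_pass = 1L,
                         multiallelic = 1L,
                         indel = if (include_indels) 1L else 0L,
                         indel_flank = if (include_indels) 1L else 0L),
    drops_masks = list(repeats = 1L, cnv = 1L, genes = 1L, cpg = 1L),
    drops_polarization = list(missing_ancestral = 1L,
                              ancestral_mismatch = 1L),
    flips = if (flip_case) 14000L else integer(0))
  jsonlite::write_json(expected, paths$sidecar, auto_unbox = TRUE,
                       digits = NA, pretty = TRUE)
  list(paths = paths, chrom_lengths = c(chr1 = 100000L), pops = pops,
       expected = expected)
}
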