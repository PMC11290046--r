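test_that("offspring counts interpolate linearly and decrease with error", {
  expect_identical(offspring_count(1, 1, 9), 8L)    # best gets the most
  expect_identical(offspring_count(9, 1, 9), 2L)    # worst gets the least
  expect_identical(offspring_count(5, 1, 9), 5L)    # midpoint
  expect_identical(offspring_count(3, 3, 3), 8L)    # degenerate population
  expect_error(offspring_count(0.5, 1, 9), "within")
  expect_error(offspring_count(10, 1, 9), "within")
  f <- seq(1, 9, length.out = 7)
  S <- offspring_count(f, 1, 9)
  expect_true(all(diff(S) <= 0))
  expect_true(all(S >= 2 & S <= 8))
})

test_that("mutation respects operator rates, brackets and validity", {
  cfg0 <- engine_config(mutation = list(p_time = 0, p_ne = 0,
                                        p_migration = 0, p_admixture = 0,
                                        p_add = 0, p_remove = 0))
  m <- three_pop()
  set.seed(1)
  expect_identical(mutate_model(m, cfg0)$events, m$events)
  expect_identical(mutate_model(m, cfg0)$ecodemes, m$ecodemes)

  # time draws stay strictly inside the validity bracket
  m2 <- three_pop(t1 = 1000, t2 = 3000)
  m2$events <- c(m2$events, list(ne_change("A", 500, 8000)))
  i_recent <- 1L  # the split at 1000: bracketed by the ne_change (500)
                  # below and its parent's split (3000) above
  br <- gp4pg:::event_time_bracket(m2, i_recent)
  expect_equal(br, c(500, 3000))
  cfg_t <- engine_config(mutation = list(p_time = 1, p_ne = 0,
                                         p_migration = 0, p_admixture = 0,
                                         p_add = 0, p_remove = 0))
  set.seed(42)
  for (k in 1:300) {
    mm <- mutate_model(m2, cfg_t)
    times <- vapply(mm$events, `[[`, numeric(1), "time")
    expect_length(validate_model(mm), 0)
    # the recent split, wherever it moved, stays inside (500, 3000)
    expect_true(times[1] > 500 && times[1] < 3000)
  }

  # add / remove change the event count by one
  cfg_add <- engine_config(mutation = list(p_time = 0, p_ne = 0,
                                           p_migration = 0, p_admixture = 0,
                                           p_add = 1, p_remove = 0))
  cfg_rem <- engine_config(mutation = list(p_time = 0, p_ne = 0,
                                           p_migration = 0, p_admixture = 0,
                                           p_add = 0, p_remove = 1))
  set.seed(7)
  grew <- mutate_model(m2, cfg_add)
  expect_length(grew$events, length(m2$events) + 1L)
  shrunk <- mutate_model(m2, cfg_rem)
  expect_length(shrunk$events, length(m2$events) - 1L)
  # splits are never removed
  expect_length(gp4pg:::model_splits(shrunk), 2)

  # general mutation always returns a valid model
  cfg <- engine_config()
  set.seed(99)
  mm <- m2
  for (k in 1:100) {
    mm <- mutate_model(mm, cfg)
    expect_length(validate_model(mm), 0)
  }
  # the split topology never changes
  sp <- gp4pg:::model_splits(mm)
  expect_identical(vapply(sp, `[[`, character(1), "parent"),
                   c("anc1", "root"))
})

test_that("evaluation is reproducible and zero for a perfect match", {
  sc <- scenario_basic(seed = 2, genome = genome_spec(50, 10000))
  mo <- make_observed(sc, n_boot = 100)
  cfg <- engine_config(genome = sc$genome)
  f1 <- evaluate_candidate(sc$truth, mo$observed, cfg, seed = 33)
  f2 <- evaluate_candidate(sc$truth, mo$observed, cfg, seed = 33)
  expect_identical(f1, f2)
  expect_gte(f1, 0)

  # identical sim/obs with sigma all-epsilon gives exactly zero
  sim <- simulate_dataset(sc$truth, sc$genome, seed = sc$seed)
  cc <- sim_to_counts2(sim, seed = sc$seed)
  ss <- compute_4jsfs(cc)
  expect_identical(sfs_fitness(ss, ss, rep(1, length(ss$values))), 0)
})

test_that("a step pools parents with offspring and truncates by rank", {
  sc <- scenario_basic(seed = 2, genome = genome_spec(40, 10000))
  mo <- make_observed(sc, n_boot = 100)
  cfg <- engine_config(population_size = 2, genome = sc$genome)
  pop <- list(gp4pg:::new_candidate(sc$topologies[[1]], 1.0, id = 1),
              gp4pg:::new_candidate(sc$topologies[[2]], 5.0, id = 2))
  # best produces 8, worst 2: 10 children before truncation
  S <- offspring_count(c(1, 5), 1, 5, cfg$s_min, cfg$s_max)
  expect_identical(sum(S), 10L)
  set.seed(3)
  nxt <- step_population(pop, mo$observed, cfg, sim_seed = 11)
  expect_length(nxt, 2)
  f <- vapply(nxt, `[[`, numeric(1), "fitness")
  expect_true(all(diff(f) >= 0))

  # zero mutation rates + elitism: population unchanged after a step
  cfg0 <- engine_config(population_size = 2, genome = sc$genome,
                        mutation = list(p_time = 0, p_ne = 0,
                                        p_migration = 0, p_admixture = 0,
                                        p_add = 0, p_remove = 0))
  pop_eval <- lapply(seq_along(pop), function(i) {
    p <- pop[[i]]
    p$fitness <- evaluate_candidate(p$model, mo$observed, cfg0, seed = 11)
    p
  })
  set.seed(4)
  nxt0 <- step_population(pop_eval, mo$observed, cfg0, sim_seed = 11)
  expect_equal(sort(vapply(nxt0, `[[`, numeric(1), "fitness")),
               sort(vapply(pop_eval, `[[`, numeric(1), "fitness")))
  # best error cannot increase
  expect_lte(min(vapply(nxt0, `[[`, numeric(1), "fitness")),
             min(vapply(pop_eval, `[[`, numeric(1), "fitness")))
})

test_that("runs are deterministic, improve on the start and log traces", {
  sc <- scenario_basic(seed = 2, genome = genome_spec(40, 10000))
  mo <- make_observed(sc, n_boot = 100)
  cfg <- engine_config(population_size = 4, iterations = 3,
                       genome = sc$genome)
  r1 <- run_gp4pg(sc$topologies, mo$observed, cfg, seed = 5)
  r2 <- run_gp4pg(sc$topologies, mo$observed, cfg, seed = 5)
  expect_identical(r1$trace, r2$trace)
  expect_identical(gp4pg:::model_coef(r1$best$model),
                   gp4pg:::model_coef(r2$best$model))
  expect_lte(r1$trace$best[nrow(r1$trace)], r1$trace$best[1])
  expect_identical(nrow(r1$trace), 4L)  # initial + 3 iterations
  expect_true(r1$topology %in% c("B+mig", "B-mig", "C+mig", "C-mig"))

  # iterations = 1 equals exactly one step
  cfg1 <- engine_config(population_size = 4, iterations = 1,
                        genome = sc$genome)
  r3 <- run_gp4pg(sc$topologies, mo$observed, cfg1, seed = 5)
  expect_identical(nrow(r3$trace), 2L)
  expect_identical(r3$trace$best[1:2], r1$trace$best[1:2])
})

test_that("replicate runs tally topology support", {
  sc <- scenario_basic(seed = 2, genome = genome_spec(40, 10000))
  mo <- make_observed(sc, n_boot = 100)
  cfg <- engine_config(population_size = 4, iterations = 2,
                       genome = sc$genome)
  # single topology: support is total
  reps1 <- run_replicates(sc$topologies[1], mo$observed, cfg,
                          n_runs = 3, seed = 1)
  expect_identical(unname(reps1$support["B+mig"]), 3L)
  # zero runs: empty table
  reps0 <- run_replicates(sc$topologies, mo$observed, cfg,
                          n_runs = 0, seed = 1)
  expect_identical(sum(reps0$support), 0L)
  expect_length(reps0$final_errors, 0)
})
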