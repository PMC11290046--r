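test_that("topology factories emit the expected labelled variant sets", {
  # 6 base topologies over 8 populations give 12 configurations
  t8 <- make_topology_fixtures(8)
  expect_length(t8, 12)
  labs <- vapply(t8, `[[`, character(1), "topology_label")
  expect_setequal(labs, as.vector(outer(LETTERS[2:7], c("+mig", "-mig"),
                                        paste0)))
  # a single base topology over 3 populations gives 2 configurations
  t3 <- make_topology_fixtures(3)
  expect_length(t3, 2)
  # every emitted configuration validates
  for (m in c(t8, t3)) expect_length(validate_model(m), 0)
  # the +mig / -mig pair differ only in internal topodeme migration
  expect_true(all(t8[[1]]$ecodemes$m_internal > 0))
  expect_true(all(t8[[2]]$ecodemes$m_internal == 0))
  # distinct insertion depths give distinct split sets
  pairs <- vapply(t8[seq(1, 12, by = 2)], function(m)
    paste(vapply(gp4pg:::model_splits(m), function(s)
      paste(s$child_a, s$child_b), character(1)), collapse = "|"),
    character(1))
  expect_identical(anyDuplicated(pairs), 0L)
})

test_that("synthetic observed data is byte-stable and truth is recorded", {
  sc <- scenario_basic(seed = 3, genome = genome_spec(40, 10000))
  d1 <- tempfile(); d2 <- tempfile()
  make_observed(sc, d1, n_boot = 100)
  make_observed(sc, d2, n_boot = 100)
  for (f in c("4jsfs.tsv", "sigma.tsv", "truth.yaml", "truth.json"))
    expect_identical(readLines(file.path(d1, f)),
                     readLines(file.path(d2, f)), info = f)
  side <- jsonlite::read_json(file.path(d1, "truth.json"))
  expect_identical(side$topology, sc$truth$topology_label)
  expect_equal(side$split_times[[1]], gp4pg:::model_splits(sc$truth)[[1]]$time)

  # zero mutation rate: empty spectrum, sigma floored at epsilon
  sc0 <- sc
  sc0$truth$mutation_rate <- 0
  mo0 <- make_observed(sc0, n_boot = 50)
  expect_true(all(mo0$observed$jsfs$values == 0))
  expect_true(all(mo0$observed$sigma$values ==
                    mo0$observed$sigma$epsilon))
})

test_that("two-population truth reproduces the single-population spectrum", {
  # marginal SFS of each population under a hard ancient split matches
  # the neutral expectation theta / i on 2 chromosomes
  truth <- two_pop(T_split = 1e5, ne = 3000)
  g <- genome_spec(400, 10000)
  sim <- simulate_dataset(truth, g, seed = 17)
  theta <- 4 * 3000 * 1.61e-8 * sim$callable_length
  for (p in c("A", "B")) {
    xi <- tabulate(sim$sites[[p]], nbins = 1)  # singletons on 2 chromosomes
    expect_lt(abs(xi[1] - theta) / theta, 0.15)
  }
})

test_that("scenario objects validate their structure", {
  sc <- scenario_recovery3()
  expect_s3_class(sc, "gp4pg_scenario")
  expect_true(sc$truth$topology_label %in%
                vapply(sc$topologies, `[[`, character(1), "topology_label"))
  expect_match(sc$recovery_target, ":")
  expect_error(scenario_spec(two_pop(), make_topology_fixtures(3)),
               "must be among the competitors")
})
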