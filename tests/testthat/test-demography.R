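test_that("validation accepts valid models and reports violations", {
  # degenerate single-ecodeme model
  expect_length(validate_model(one_pop()), 0)

  # admixture older than the split that creates its populations
  m <- demographic_model(
    list(ecodeme("A", 1), ecodeme("B", 2), ecodeme("AB", 3)),
    list(soft_split("AB", "A", "B", 1000),
         admixture_pulse("A", "B", 2000, 0.1)),
    validate = FALSE)
  viol <- validate_model(m)
  expect_true(any(grepl("admixture predates split", viol)))

  # eight-ecodeme favoured-topology analogue is valid
  expect_length(validate_model(model_d8()), 0)

  # duplicated positions, bad tree shape
  m2 <- demographic_model(list(ecodeme("A", 1), ecodeme("B", 1)),
                          validate = FALSE)
  v2 <- validate_model(m2)
  expect_true(any(grepl("positions", v2)))
  expect_true(any(grepl("root", v2)))
})

test_that("constructor rejects invalid models while validate_model reports", {
  expect_error(demographic_model(
    list(ecodeme("A", 1), ecodeme("B", 2), ecodeme("AB", 3)),
    list(soft_split("AB", "A", "B", 1000),
         ne_change("A", 5000, 100))), "not alive")
})

test_that("migration decay matches the exponential formula and boundaries", {
  d <- migration_decay(m_max = 0.01, m_min = 0.001, T_split = 1000,
                       lambda_decay = 1)
  expect_identical(migration_rate_at(d, 1000), 0.01)   # rate at the split
  # one epoch after the split
  expect_equal(migration_rate_at(d, 800), 0.001 + 0.009 * exp(-1),
               tolerance = 1e-12)
  # asymptote
  expect_equal(migration_rate_at(d, 0, epoch_length = 10), 0.001,
               tolerance = 1e-12)
  expect_error(migration_rate_at(d, 1500), "undefined before split")
  # monotone non-increasing as divergence grows; constant when max == min
  tt <- seq(1000, 0, by = -50)
  expect_true(all(diff(migration_rate_at(d, tt)) <= 0))
  dc <- migration_decay(0.004, 0.004, 500)
  expect_true(all(migration_rate_at(dc, c(0, 100, 500)) == 0.004))
})

test_that("migration matrix is a stepping stone within and across ecodemes", {
  # single deme
  expect_identical(build_migration_matrix(one_pop(), 0),
                   matrix(0, 1, 1, dimnames = list("A.1", "A.1")))

  # 3 topodemes on a chain: neighbours exchange, non-neighbours do not
  m3 <- demographic_model(list(ecodeme("A", 1, n_topodemes = 3,
                                       m_internal = 2e-3)))
  M <- build_migration_matrix(m3, 0)
  expect_equal(M["A.1", "A.2"], 2e-3)
  expect_equal(M["A.2", "A.3"], 2e-3)
  expect_equal(M["A.1", "A.3"], 0)

  # cross-ecodeme entries equal the decay value one epoch after the split
  tp <- two_pop(T_split = 1000, m_max = 0.01, m_min = 0.001)
  M2 <- build_migration_matrix(tp, 800)
  expect_equal(M2["A.1", "B.1"], 0.001 + 0.009 * exp(-1), tolerance = 1e-12)
  expect_true(isSymmetric(M2))
  expect_true(all(M2 >= 0 & M2 < 1))
  expect_error(build_migration_matrix(tp, -5), "non-negative")
})

test_that("epoch schedule tiles time and evaluates decay at epoch starts", {
  tp <- two_pop(T_split = 1000, m_max = 0.01, m_min = 0.001)
  ep <- epoch_schedule(tp, 200)
  post <- Filter(function(e) e$end <= 1000, ep)
  expect_length(post, 5)
  # strictly increasing cross-pair migration toward the split (= strictly
  # decreasing forward in time since the split)
  rates <- vapply(post, function(e) e$M["A.1", "B.1"], numeric(1))
  expect_true(all(diff(rates) > 0))
  # schedule round-trips against the continuous rate function exactly
  d <- migration_decay(0.01, 0.001, 1000)
  for (e in post)
    expect_identical(e$M["A.1", "B.1"], migration_rate_at(d, e$start))

  # no events: a single open-ended epoch
  expect_length(epoch_schedule(one_pop()), 1)

  # boundary-aligned epoch length
  ep2 <- epoch_schedule(two_pop(T_split = 1000), epoch_length = 1000)
  expect_length(Filter(function(e) e$end <= 1000, ep2), 1)
})

test_that("backward lineage count of ecodemes drops by one per split", {
  for (m in list(two_pop(), three_pop(), model_d8())) {
    splits <- gp4pg:::model_splits(m)
    times <- vapply(splits, `[[`, numeric(1), "time")
    alive_n <- function(t) sum(vapply(m$ecodemes$name, function(nm)
      gp4pg:::alive_at(m, nm, t), logical(1)))
    n_before <- vapply(times - 1e-6, alive_n, numeric(1))
    n_after <- vapply(times + 1e-6, alive_n, numeric(1))
    expect_equal(n_before - n_after, rep(1, length(splits)))
    expect_equal(alive_n(max(times) + 1), 1)  # a single root remains
  }
})

test_that("model config files round-trip", {
  m <- model_d8()
  m$events <- c(m$events, list(admixture_pulse("MiddleEast", "Amazigh",
                                               40, 0.05),
                               ne_change("San", 500, 20000)))
  f <- tempfile(fileext = ".yaml")
  write_model_config(m, f)
  m2 <- read_model_config(f)
  expect_equal(m2$ecodemes, m$ecodemes)
  expect_equal(length(m2$events), length(m$events))
  expect_equal(gp4pg:::model_coef(m2), gp4pg:::model_coef(m))
  expect_identical(m2$topology_label, m$topology_label)
  expect_identical(m2$sampling, m$sampling)
})

test_that("demes-style export expands topodemes and discretizes decay", {
  m <- demographic_model(
    list(ecodeme("A", 1, n_topodemes = 2), ecodeme("B", 2),
         ecodeme("AB", 3)),
    list(soft_split("AB", "A", "B", 600, m_max = 0.01)))
  f <- tempfile(fileext = ".yaml")
  write_demes_yaml(m, f)
  y <- yaml::read_yaml(f)
  expect_identical(y$time_units, "generations")
  expect_length(y$demes, 4)  # A.1 A.2 B.1 AB.1
  expect_true(length(y$migrations) >= 3)  # decay entries per epoch + chain
  starts <- vapply(y$migrations, function(mm) mm$end_time, numeric(1))
  expect_true(all(starts >= 0))
})
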