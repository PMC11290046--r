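test_that("single-population SFS follows the neutral 1/i expectation", {
  n_chrom <- 6L
  g <- genome_spec(n_blocks = 400, block_length = 20000)
  sim <- simulate_dataset(one_pop(ne = 5000, n_chrom = n_chrom), g,
                          seed = 42)
  xi <- tabulate(sim$sites$A, nbins = n_chrom - 1L)
  theta <- 4 * 5000 * 1.61e-8 * sim$callable_length
  expected <- theta / seq_len(n_chrom - 1L)
  # each class within 15% of the closed form (Monte-Carlo error)
  expect_true(all(abs(xi - expected) / expected < 0.15))
  expect_equal(sim$callable_length, 400 * 20000)
})

test_that("anciently isolated populations show no shared polymorphism", {
  m <- two_pop(T_split = 2e5, m_max = 0, ne = 2000)
  sim <- simulate_dataset(m, genome_spec(300, 10000), seed = 11)
  s <- sim$sites
  shared <- s$A %in% 1L & s$B %in% 1L  # joint intermediate polymorphism
  expect_lt(mean(shared), 0.005)
  # each private spectrum matches the single-population expectation
  priv <- s$A[s$B == 0 | s$B == 2]
  xi <- tabulate(priv[priv > 0], nbins = 1L)
  theta <- 4 * 2000 * 1.61e-8 * sim$callable_length
  expect_lt(abs(xi[1] - theta) / theta, 0.2)
})

test_that("simulation is reproducible and seeds are respected", {
  m <- two_pop(1000, m_max = 0.01)
  g <- genome_spec(50, 10000)
  s1 <- simulate_dataset(m, g, seed = 9)
  s2 <- simulate_dataset(m, g, seed = 9)
  expect_identical(s1$sites, s2$sites)
  s3 <- simulate_dataset(m, g, seed = 10)
  expect_false(identical(s1$sites, s3$sites))
  # R's global RNG stream is untouched
  set.seed(1); before <- runif(1)
  set.seed(1); invisible(simulate_dataset(m, g, seed = 2)); after <- runif(1)
  expect_identical(before, after)
})

test_that("doubling the mutation rate doubles segregating sites", {
  m1 <- one_pop(); m2 <- one_pop()
  m2$mutation_rate <- 2 * m1$mutation_rate
  g <- genome_spec(1200, 10000)
  n1 <- nrow(simulate_dataset(m1, g, seed = 5)$sites)
  n2 <- nrow(simulate_dataset(m2, g, seed = 6)$sites)
  expect_lt(abs(n2 / n1 - 2), 0.15)
})

test_that("migration decay leaves more shared variation than a hard split", {
  g <- genome_spec(300, 20000)
  fst_proxy <- function(m_max) {
    s <- simulate_dataset(two_pop(1500, m_max = m_max, ne = 4000), g,
                          seed = 21)$sites
    # fixed differences indicate differentiation
    mean((s$A == 2 & s$B == 0) | (s$A == 0 & s$B == 2))
  }
  expect_gt(fst_proxy(0), fst_proxy(0.02))
})

test_that("counts projection to two chromosomes is exact or hypergeometric", {
  # already two chromosomes: identity, including monomorphic rows
  m <- two_pop(1000)
  sim <- simulate_dataset(m, genome_spec(20, 10000), seed = 3)
  cc <- sim_to_counts2(sim)
  expect_identical(unname(cc[, "A"]), sim$sites$A)
  expect_identical(attr(cc, "block"), sim$sites$block)

  # 4 chromosomes with 2 derived: Hypergeom(4,2,2) over many sites
  sim4 <- simulate_dataset(one_pop(n_chrom = 4L), genome_spec(300, 20000),
                           seed = 8)
  idx <- sim4$sites$A == 2L
  cc4 <- sim_to_counts2(sim4, seed = 123)
  freq <- tabulate(cc4[idx, "A"] + 1L, nbins = 3) / sum(idx)
  expect_equal(freq, c(1 / 6, 2 / 3, 1 / 6), tolerance = 0.08)

  sim$n_chrom["A"] <- 1L
  expect_error(sim_to_counts2(sim), "at least 2 chromosomes")
})

test_that("invalid inputs are rejected", {
  expect_error(genome_spec(recombination = 1e-8), "recombination")
  m <- demographic_model(list(ecodeme("A", 1), ecodeme("B", 2)),
                         validate = FALSE)
  expect_error(simulate_dataset(m, genome_spec(2, 100), seed = 1),
               "invalid model")
  m2 <- one_pop(); m2$sampling <- m2$sampling[0]
  expect_error(simulate_dataset(m2, genome_spec(2, 100), seed = 1),
               "samples no ecodemes")
})

test_that("site tables and VCF export round-trip through the pipeline", {
  sc <- scenario_basic(seed = 5, genome = genome_spec(10, 5000))
  sim <- simulate_dataset(sc$truth, sc$genome, seed = 5)
  f <- tempfile(fileext = ".tsv")
  write_site_table(sim, f)
  tab <- utils::read.table(f, header = TRUE, sep = "\t")
  expect_equal(nrow(tab), nrow(sim$sites))

  vcf <- tempfile(fileext = ".vcf")
  sim_to_vcf(sim, vcf)
  rec <- read_vcf_records(vcf)
  expect_equal(nrow(rec), nrow(sim$sites))
  flt <- filter_variants(rec)
  expect_equal(nrow(flt$records), nrow(rec))  # all clean by construction
  pol <- polarize(flt$records,
                  stats::setNames(sim$populations, sim$populations))
  counts_back <- as.matrix(pol$sites[, sim$populations])
  counts_orig <- as.matrix(sim$sites[, sim$populations])
  expect_true(all(counts_back == counts_orig))
})

test_that("admixture pulses move ancestry between ecodemes", {
  # focal receives a strong recent pulse from a long-diverged source:
  # sharing with the source must exceed the no-pulse model's
  base <- list(ecodeme("A", 1, ne = 3000), ecodeme("B", 2, ne = 3000),
               ecodeme("AB", 3, ne = 3000))
  no_pulse <- demographic_model(base, list(
    soft_split("AB", "A", "B", 8000)))
  pulse <- demographic_model(base, list(
    soft_split("AB", "A", "B", 8000),
    admixture_pulse("A", "B", 10, 0.4)))
  g <- genome_spec(300, 10000)
  shared <- function(m) {
    s <- simulate_dataset(m, g, seed = 13)$sites
    mean(s$A > 0 & s$A < 2 & s$B > 0 & s$B < 2)
  }
  expect_gt(shared(pulse), shared(no_pulse) + 0.01)
})
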