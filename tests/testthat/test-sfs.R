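test_that("site classification follows the documented base-3 coding", {
  expect_identical(classify_site(c(0, 0, 0, 0)), NA_integer_)
  expect_identical(classify_site(c(2, 2, 2, 2)), NA_integer_)
  # code 33, i.e. 0-based cell index 32 after dropping the all-zero code
  expect_identical(classify_site(c(1, 0, 2, 0)), 33L)
  expect_identical(classify_site(c(1, 0, 2, 0)) - 1L, 32L)
  expect_error(classify_site(c(3, 0, 0, 0)), "in \\{0, 1, 2\\}")
  expect_error(classify_site(c(1, 1, 1)), "four values")

  # full enumeration: the 79 retained codes are exactly 1..79
  all81 <- as.matrix(expand.grid(0:2, 0:2, 0:2, 0:2))[, 4:1]
  codes <- apply(all81, 1, function(r) classify_site(r))
  expect_identical(sort(codes[!is.na(codes)]), 1:79)
  expect_identical(sum(is.na(codes)), 2L)
})

test_that("4jSFS length follows the closed form and tallies sites", {
  expect_identical(jsfs4_length(4), 79L)
  expect_identical(jsfs4_length(8), 5530L)
  expect_identical(msfs_length(2), 7L)

  expect_error(compute_4jsfs(random_counts(10, 3)), "at least 4")

  # one site (1,1,1,1): a single count in the cell of code 40
  j <- compute_4jsfs(matrix(1L, 1, 4, dimnames = list(NULL, paste0("p", 1:4))))
  expect_equal(which(j$values == 1), 40)
  expect_equal(sum(j$values), 1)

  # zero sites
  j0 <- compute_4jsfs(random_counts(0, 5))
  expect_length(j0$values, jsfs4_length(5))
  expect_true(all(j0$values == 0))
})

test_that("per-quadruple totals equal quadruple-polymorphic site counts", {
  counts <- random_counts(500, 6, seed = 4)
  j <- compute_4jsfs(counts)
  quads <- utils::combn(6, 4, simplify = FALSE)
  for (qi in seq_along(quads)) {
    seg <- j$values[seq.int((qi - 1) * 79 + 1, qi * 79)]
    sub <- counts[, quads[[qi]], drop = FALSE]
    poly <- sum(!(rowSums(sub) == 0 | rowSums(sub) == 8))
    expect_equal(sum(seg), poly)
  }
})

test_that("4jSFS is permutation-equivariant in the population order", {
  counts <- random_counts(300, 5, seed = 9)
  perm <- c("p3", "p1", "p5", "p2", "p4")
  j_perm <- compute_4jsfs(counts, populations = perm)
  # oracle: recompute from physically permuted columns
  j_oracle <- compute_4jsfs(counts[, perm])
  expect_equal(j_perm$values, j_oracle$values)
})

test_that("normalization gives per-segment proportions and is idempotent", {
  counts <- random_counts(200, 5, seed = 2)
  j <- compute_4jsfs(counts)
  p1 <- normalize_sfs(j)
  sums <- vapply(seq_along(p1$segments), function(i)
    sum(p1$values[seq.int((i - 1) * 79 + 1, i * 79)]), numeric(1))
  expect_equal(sums, rep(1, length(p1$segments)))
  expect_equal(normalize_sfs(p1)$values, p1$values)
  # scale invariance
  j3 <- j; j3$values <- 3 * j$values
  expect_equal(normalize_sfs(j3)$values, p1$values)
  # all-zero segment left zero with a warning
  jz <- compute_4jsfs(matrix(0L, 3, 4, dimnames = list(NULL, paste0("p", 1:4))))
  expect_warning(pz <- normalize_sfs(jz), "no polymorphic sites")
  expect_true(all(pz$values == 0))
})

test_that("bootstrap sigma matches closed forms and floors at epsilon", {
  # identical blocks: zero deviation, floored to epsilon
  counts <- matrix(rep(c(1L, 0L, 0L, 0L), each = 20), 20, 4,
                   dimnames = list(NULL, paste0("p", 1:4)))
  sg <- bootstrap_sigma(counts, block = rep(1:2, each = 10),
                        n_boot = 50, seed = 1, epsilon = 1)
  expect_true(all(sg$values == 1))

  # cell counts {10, 0} over two blocks: resample sums are 0/10/20 with
  # probabilities 1/4, 1/2, 1/4, so the exact resampling sd is sqrt(50)
  counts4 <- matrix(rep(c(1L, 0L, 0L, 0L), 10), 10, 4, byrow = TRUE,
                    dimnames = list(NULL, paste0("p", 1:4)))
  counts4 <- rbind(counts4, matrix(c(0L, 1L, 0L, 0L), 1, 4,
                                   dimnames = list(NULL, paste0("p", 1:4))))
  sg4 <- bootstrap_sigma(counts4, block = c(rep(1L, 10), 2L),
                         n_boot = 4000, seed = 7, epsilon = 0.01)
  cell_1000 <- 27  # base-3 code of pattern (1,0,0,0)
  expect_equal(sg4$values[cell_1000], sqrt(50), tolerance = 0.05)

  expect_error(bootstrap_sigma(counts4, block = rep(1L, 11)),
               "at least 2 blocks")

  # default replicate count is 1000
  expect_identical(formals(bootstrap_sigma)$n_boot, 1000L)
})

test_that("standardized fitness matches the element-wise oracle", {
  a <- compute_4jsfs(random_counts(100, 4, seed = 1))
  b <- compute_4jsfs(random_counts(100, 4, seed = 2))
  expect_identical(sfs_fitness(a, a, rep(1, 79)), 0)
  # one cell off by two sigmas
  b2 <- a; b2$values[10] <- a$values[10] + 6
  expect_identical(sfs_fitness(b2, a, rep(3, 79)), 4)
  # random vectors, sigma 1: plain sum of squares
  oracle <- 0
  for (s in seq_along(a$values)) oracle <- oracle + (a$values[s] - b$values[s])^2
  expect_equal(sfs_fitness(a, b, rep(1, 79)), oracle)
  # invariance under a common permutation
  prm <- sample(79)
  ap <- a; ap$values <- a$values[prm]
  bp <- b; bp$values <- b$values[prm]
  sig <- runif(79, 0.5, 2)
  expect_equal(sfs_fitness(ap, bp, sig[prm]), sfs_fitness(a, b, sig))
  # mismatches are errors
  short <- a; short$values <- a$values[1:10]
  expect_error(sfs_fitness(short, a, rep(1, 79)), "matching lengths")
  swapped <- b; swapped$populations <- rev(b$populations)
  expect_error(sfs_fitness(swapped, a, rep(1, 79)), "population orders")
})

test_that("summary vectors persist as deterministic TSV", {
  j <- compute_4jsfs(random_counts(50, 4, seed = 3))
  f1 <- tempfile(); f2 <- tempfile()
  write_jsfs(j, f1); write_jsfs(j, f2)
  expect_identical(readLines(f1), readLines(f2))
  j2 <- read_jsfs(f1)
  expect_equal(j2$values, j$values)
  expect_identical(j2$populations, j$populations)
  expect_identical(j2$normalization, j$normalization)
  sg <- bootstrap_sigma(random_counts(50, 4, seed = 3),
                        block = rep(1:5, each = 10), n_boot = 50)
  f3 <- tempfile(); write_jsfs(sg, f3)
  sg2 <- read_jsfs(f3)
  expect_s3_class(sg2, "gp4pg_sigma")
  expect_equal(sg2$values, sg$values)
  expect_equal(sg2$epsilon, sg$epsilon)
})
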