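fx <- make_toy_vcf(file.path(tempdir(), "toyvcf"))
masks <- list(repeats = read_bed(fx$paths$repeats),
              cnv = read_bed(fx$paths$cnv),
              genes = read_bed(fx$paths$genes),
              cpg = read_bed(fx$paths$cpg))

test_that("site-level filters attribute drops to the stated criteria", {
  rec <- read_vcf_records(fx$paths$vcf)
  flt <- filter_variants(rec)
  for (nm in names(fx$expected$drops_filters))
    expect_identical(unname(flt$drops[nm]),
                     fx$expected$drops_filters[[nm]],
                     info = nm)
  expect_identical(flt$drops[["unscorable"]], 0L)

  # empty VCF: empty output
  f <- tempfile(fileext = ".vcf")
  writeLines(c("##fileformat=VCFv4.2",
               paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL",
                       "FILTER", "INFO", "FORMAT", "s1"), collapse = "\t")),
             f)
  e <- filter_variants(read_vcf_records(f))
  expect_identical(nrow(e$records), 0L)
  expect_true(all(e$drops == 0L))

  # all-passing input: identity
  clean <- flt$records
  again <- filter_variants(clean)
  expect_identical(nrow(again$records), nrow(clean))
  expect_true(all(again$drops == 0L))

  # order stability for independent predicates: each drop reason is
  # detected regardless of the other filters' thresholds
  relaxed <- filter_config(min_depth = 0, min_qual = 0,
                           require_pass = FALSE, indel_flank_bp = 0,
                           biallelic_only = TRUE)
  only_multi <- filter_variants(rec, relaxed)
  expect_identical(unname(only_multi$drops["multiallelic"]), 1L)
})

test_that("masks drop records with the documented 20-kb flank convention", {
  rec <- filter_variants(read_vcf_records(fx$paths$vcf))$records
  msk <- apply_masks(rec, masks)
  for (nm in names(fx$expected$drops_masks))
    expect_identical(unname(msk$drops[nm]), fx$expected$drops_masks[[nm]],
                     info = nm)
  # idempotent
  msk2 <- apply_masks(msk$records, masks)
  expect_identical(nrow(msk2$records), nrow(msk$records))
  expect_true(all(msk2$drops == 0L))

  # gene edge convention: gene occupies [100000, 100100) 0-based
  gene <- list(genes = data.frame(chrom = "c", start = 100000L,
                                  end = 100100L))
  probe <- data.frame(chrom = "c",
                      pos = c(100100L + 19999L,   # inside the flank
                              100100L + 20000L,   # at the flank edge
                              100100L + 20001L,   # beyond: retained
                              100000L - 19999L,   # left flank, masked
                              100000L - 20000L))  # left edge: retained
  kept <- apply_masks(probe, gene)$records$pos
  expect_identical(kept, c(100100L + 20001L, 100000L - 20000L))

  # interval-stabbing oracle on a random fixture
  set.seed(5)
  iv <- data.frame(chrom = "c", start = sort(sample(0:5000, 4)))
  iv$end <- iv$start + sample(50:400, 4)
  pts <- data.frame(chrom = "c", pos = sample(1:6000, 200))
  got <- apply_masks(pts, list(m = iv), gene_flank_bp = 0)$records$pos
  oracle <- pts$pos[!vapply(pts$pos, function(p)
    any(p > iv$start & p <= iv$end), logical(1))]
  expect_setequal(got, oracle)

  f1 <- tempfile(); writeLines("c\t10", f1)
  expect_error(read_bed(f1), "line 1")
  f2 <- tempfile(); writeLines(c("c\t0\t100", "c\t50\t20"), f2)
  expect_error(read_bed(f2), "line 2")
})

test_that("window density mask follows the sliding-window rule", {
  # 9,500 of 10,000 callable: retained (95% > 90%)
  keep <- window_density_mask(1:9500, chrom_lengths = c(chr = 10000L))
  expect_identical(nrow(keep), 1L)
  # 8,000 of 10,000: dropped
  drop <- window_density_mask(1:8000, chrom_lengths = c(chr = 10000L))
  expect_identical(nrow(drop), 0L)

  # staggered windows around the threshold against a brute-force oracle
  set.seed(11)
  len <- 60000L
  pos <- sort(sample.int(len, 57000L))
  got <- window_density_mask(pos, chrom_lengths = c(chr = len))
  starts <- seq(0L, len - 1L, by = 2500L)
  ok <- vapply(starts, function(w)
    (findInterval(w + 10000L, pos) - findInterval(w, pos)) / 10000L > 0.9,
    logical(1))
  expect_gt(sum(ok), 0); expect_lt(sum(ok), length(ok))
  oracle_iv <- data.frame(chrom = rep("chr", sum(ok)), start = starts[ok],
                          end = pmin(starts[ok] + 10000L, len))
  oracle <- gp4pg:::merge_intervals(oracle_iv)
  expect_equal(got$start, oracle$start)
  expect_equal(got$end, oracle$end)
})

test_that("polarization counts derived alleles and flips at AA=ALT", {
  rec <- apply_masks(filter_variants(read_vcf_records(fx$paths$vcf))$records,
                     masks)$records
  pol <- polarize(rec, fx$pops)
  expect_identical(unname(pol$drops["missing_ancestral"]), 1L)
  expect_identical(unname(pol$drops["ancestral_mismatch"]), 1L)
  # the flip record carries the intended derived counts
  i <- which(pol$sites$pos == 14000L)
  want <- fx$expected$counts[which(fx$expected$survivors == 14000L), ]
  expect_equal(unname(unlist(pol$sites[i, paste0("pop", 1:4)])),
               unname(want))
})

test_that("block assignment follows the callable mask or fixed tiles", {
  mask3 <- data.frame(chrom = "c", start = c(0L, 5000L, 9000L),
                      end = c(1000L, 6000L, 9500L))
  sites <- data.frame(chrom = "c",
                      pos = c(500L, 5500L, 9300L, 2000L))
  st <- make_blocks(sites, mask3)
  expect_identical(st$block, c(1L, 2L, 3L))          # 3 intervals, 3 blocks
  expect_false(2000L %in% st$pos)                    # outside mask excluded

  # fixed-width 1 Mb tiling of a 2.5 Mb interval gives 3 blocks
  big <- data.frame(chrom = "c", start = 0L, end = 2500000L)
  pts <- data.frame(chrom = "c",
                    pos = c(1L, 999999L, 1000000L, 1000001L, 2400000L))
  tl <- make_blocks(pts, big, scheme = "tiles", tile_bp = 1e6)
  expect_identical(tl$block, c(1L, 1L, 1L, 2L, 3L))  # boundary oracle
})

test_that("the full pipeline reproduces the fixture oracle end to end", {
  res <- observed_4jsfs(fx$paths$vcf, fx$pops,
                        masks = list(repeats = fx$paths$repeats,
                                     cnv = fx$paths$cnv,
                                     genes = fx$paths$genes,
                                     cpg = fx$paths$cpg),
                        chrom_lengths = fx$chrom_lengths,
                        n_boot = 100, seed = 1)
  st <- res$site_table
  expect_equal(sort(st$pos), sort(fx$expected$survivors))
  expect_equal(st$block[order(st$pos)],
               fx$expected$blocks[order(fx$expected$survivors)])
  cm <- as.matrix(st[order(st$pos), paste0("pop", 1:4)])
  ex <- fx$expected$counts[order(fx$expected$survivors), ]
  expect_true(all(cm == ex))
  # the hand-computed 4jSFS of the fixture is recovered exactly
  storage.mode(ex) <- "integer"
  colnames(ex) <- paste0("pop", 1:4)
  oracle <- compute_4jsfs(ex)
  got <- res$observed$jsfs
  expect_equal(got$values, oracle$values)

  # report and writers
  expect_identical(res$report$sites_out, nrow(st))
  bed <- tempfile(fileext = ".bed")
  write_callable_bed(res$callable_mask, bed)
  expect_equal(read_bed(bed)$start, res$callable_mask$start)
  js <- tempfile(fileext = ".json")
  write_filter_report(res$report, js)
  expect_identical(jsonlite::read_json(js)$filters$depth, 1L)
})

test_that("fixture variants without indels or flips behave accordingly", {
  fx2 <- make_toy_vcf(file.path(tempdir(), "toyvcf2"),
                      include_indels = FALSE)
  flt <- filter_variants(read_vcf_records(fx2$paths$vcf))
  expect_identical(unname(flt$drops["indel"]), 0L)
  expect_identical(unname(flt$drops["indel_flank"]), 0L)

  fx3 <- make_toy_vcf(file.path(tempdir(), "toyvcf3"), flip_case = FALSE)
  rec3 <- apply_masks(filter_variants(read_vcf_records(fx3$paths$vcf))$records,
                      masks)$records
  pol3 <- polarize(rec3, fx3$pops)
  i <- which(pol3$sites$pos == 14000L)
  want <- fx3$expected$counts[which(fx3$expected$survivors == 14000L), ]
  expect_equal(unname(unlist(pol3$sites[i, paste0("pop", 1:4)])),
               unname(want))
})
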