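## Observed-data pipeline: from a polarized multi-sample VCF and BED
## masks to the observed SFS summary, its block-bootstrap sigma and the
## callable-genome mask.
##
## Coordinate conventions: VCF positions are 1-based; BED intervals and
## all internal intervals are 0-based half-open [start, end).  A variant
## at 1-based position p falls in [start, end) iff start < p <= end.

#' Observed summary statistics for the engine
#'
#' Bundles the observed SFS summary vector, its block-bootstrap standard
#' errors and the per-site counts (kept for goodness-of-fit replicate
#' spectra).
#'
#' @param counts Integer matrix of per-site derived counts in
#'   `{0, 1, 2}`, one named column per population.
#' @param block Integer block id per site (defaults to the `"block"`
#'   attribute of `counts`).
#' @param populations Population order.
#' @param n_boot Bootstrap replicates for sigma (default 1000).
#' @param seed Bootstrap seed.
#' @param normalization Comparison scale.  The default, `"counts"`,
#'   compares raw cell counts, with simulated spectra rescaled by the
#'   ratio of callable genome lengths; `"proportions"` compares
#'   per-segment proportions, which are invariant to a joint rescaling
#'   of all times, sizes and inverse migration rates and therefore
#'   identify demographic parameters only up to that scaling.
#' @param epsilon Sigma floor in count units.
#' @param callable_length Callable genome length (bp) behind `counts`;
#'   used to rescale simulated spectra under `"counts"`.
#' @return An object of class `gp4pg_observed` with elements `jsfs`,
#'   `sigma`, `counts`, `block`, `callable_length`.
#' @export
observed_stats <- function(counts, block = attr(counts, "block"),
                           populations = colnames(counts),
                           n_boot = 1000L, seed = 1L,
                           normalization = c("counts", "proportions"),
                           epsilon = 1, callable_length = NA_real_) {
  normalization <- match.arg(normalization)
  jsfs <- compute_sfs_summary(counts, populations)
  if (normalization == "proportions")
    jsfs <- suppressWarnings(normalize_sfs(jsfs))
  sigma <- bootstrap_sigma(counts, block, populations, n_boot = n_boot,
                           seed = seed, epsilon = epsilon,
                           normalization = normalization)
  structure(list(jsfs = jsfs, sigma = sigma, counts = counts,
                 block = block, populations = populations,
                 normalization = normalization,
                 callable_length = callable_length),
            class = "gp4pg_observed")
}

#' @export
print.gp4pg_observed <- function(x, ...) {
  cat(sprintf("Observed summary: %d cells, %d sites in %d blocks, populations %s\n",
              length(x$jsfs$values), nrow(x$counts),
              length(unique(x$block)),
              paste(x$populations, collapse = ", ")))
  invisible(x)
}

## Ratio of observed to simulated callable genome length (1 when the
## observed length is unknown).
genome_scale_factor <- function(observed, sim) {
  ol <- observed$callable_length
  if (!is.null(ol) && length(ol) == 1L && is.finite(ol) && ol > 0 &&
      is.finite(sim$callable_length) && sim$callable_length > 0)
    ol / sim$callable_length
  else 1
}

## Block-bootstrap replicate summary vectors of the observed data
## (rows = replicates), on the observed normalization scale.
observed_replicates <- function(observed, n_reps = 40L, seed = 1L) {
  bl <- block_sfs_matrix(observed$counts, observed$block,
                         observed$populations)
  B <- nrow(bl$mat)
  nseg <- length(bl$segments)
  seg_of <- rep(seq_len(nseg), each = bl$seg_len)
  out <- matrix(0, n_reps, ncol(bl$mat))
  with_seed(seed, {
    for (r in seq_len(n_reps)) {
      draw <- tabulate(sample.int(B, B, replace = TRUE), nbins = B)
      v <- as.numeric(draw %*% bl$mat)
      if (observed$normalization == "proportions") {
        tot <- vapply(seq_len(nseg), function(i) sum(v[seg_of == i]),
                      numeric(1))
        tot[tot == 0] <- 1
        v <- v / tot[seg_of]
      }
      out[r, ] <- v
    }
  })
  out
}

## ---- filtering -------------------------------------------------------

#' Variant-filter configuration
#'
#' Defaults follow standard practice for building a high-confidence
#' callable set from a joint-called VCF: per-sample depth >= 5 reads,
#' QUAL >= 20, PASS records only, biallelic SNPs only, exclusion of a
#' 6-bp flank around indels, gene masks extended by 20 kb, and retention
#' of 10-kb windows (2500-bp step) whose callable-site density exceeds
#' 90%.
#'
#' @param min_depth Minimum per-sample read depth.
#' @param min_qual Minimum QUAL.
#' @param require_pass Keep only FILTER == PASS records.
#' @param biallelic_only Keep only biallelic SNPs.
#' @param indel_flank_bp Flank around indels within which SNPs are
#'   dropped.
#' @param gene_flank_bp Extension of gene mask intervals on both sides.
#' @param window_bp,step_bp,min_density Sliding-window density filter.
#' @param aa_key INFO key of the ancestral-allele annotation.
#' @return An object of class `gp4pg_filter_config`.
#' @export
filter_config <- function(min_depth = 5L, min_qual = 20, require_pass = TRUE,
                          biallelic_only = TRUE, indel_flank_bp = 6L,
                          gene_flank_bp = 20000L, window_bp = 10000L,
                          step_bp = 2500L, min_density = 0.90,
                          aa_key = "AA") {
  stopifnot(min_depth >= 0, min_qual >= 0, indel_flank_bp >= 0,
            step_bp <= window_bp)
  structure(list(min_depth = min_depth, min_qual = min_qual,
                 require_pass = require_pass,
                 biallelic_only = biallelic_only,
                 indel_flank_bp = indel_flank_bp,
                 gene_flank_bp = gene_flank_bp, window_bp = window_bp,
                 step_bp = step_bp, min_density = min_density,
                 aa_key = aa_key),
            class = "gp4pg_filter_config")
}

#' Read a multi-sample VCF into a record table
#'
#' Thin wrapper over `vcfR` returning one row per record with the fixed
#' fields, the per-sample minimum depth (`FORMAT/DP`, falling back to
#' `INFO/DP`), genotype strings, and an indel flag.
#'
#' @param path VCF path (plain or gzipped).
#' @return Data frame of records (zero rows for a site-free VCF).
#' @export
read_vcf_records <- function(path) {
  v <- suppressWarnings(vcfR::read.vcfR(path, verbose = FALSE))
  fix <- as.data.frame(v@fix, stringsAsFactors = FALSE)
  if (nrow(fix) == 0L)
    return(data.frame(chrom = character(0), pos = integer(0),
                      ref = character(0), alt = character(0),
                      qual = numeric(0), filter = character(0),
                      info = character(0), dp_min = numeric(0),
                      is_indel = logical(0)))
  rec <- data.frame(chrom = fix$CHROM, pos = as.integer(fix$POS),
                    ref = fix$REF, alt = fix$ALT,
                    qual = suppressWarnings(as.numeric(fix$QUAL)),
                    filter = fix$FILTER, info = fix$INFO,
                    stringsAsFactors = FALSE)
  gt <- vcfR::extract.gt(v, element = "GT")
  dp <- suppressWarnings(vcfR::extract.gt(v, element = "DP", as.numeric = TRUE))
  if (all(is.na(dp))) {
    info_dp <- suppressWarnings(as.numeric(sub(".*DP=([0-9]+).*", "\\1",
                                               rec$info)))
    info_dp[!grepl("DP=", rec$info)] <- NA
    rec$dp_min <- info_dp
  } else {
    rec$dp_min <- suppressWarnings(apply(dp, 1, min))
  }
  alts <- strsplit(rec$alt %||% "", ",")
  rec$is_indel <- nchar(rec$ref) > 1L |
    vapply(alts, function(a) any(nchar(a) > 1L), logical(1))
  rec$samples <- I(as.data.frame(gt, stringsAsFactors = FALSE))
  rec
}

#' Apply the site-level variant filters
#'
#' Applies the record-level criteria in order — (i) per-sample depth,
#' (ii) QUAL, (iii) PASS, (v) indel 6-bp flank (indels themselves are
#' dropped as non-SNPs), (vi) multiallelic / non-SNP — attributing each
#' dropped record to the first criterion it fails.  Records missing a
#' required field are dropped as `unscorable`.  Region masks (criterion
#' iv) are applied separately by [apply_masks()].
#'
#' @param records Record table from [read_vcf_records()].
#' @param config A [filter_config()].
#' @return List with `records` (survivors) and `drops` (named counts per
#'   criterion).
#' @export
filter_variants <- function(records, config = filter_config()) {
  drops <- c(unscorable = 0L, depth = 0L, qual = 0L, not_pass = 0L,
             indel = 0L, indel_flank = 0L, multiallelic = 0L)
  if (nrow(records) == 0L) return(list(records = records, drops = drops))
  reason <- rep(NA_character_, nrow(records))

  miss <- is.na(records$dp_min) | is.na(records$qual) |
    is.na(records$filter) | is.na(records$alt)
  reason[is.na(reason) & miss] <- "unscorable"
  reason[is.na(reason) & records$dp_min < config$min_depth] <- "depth"
  reason[is.na(reason) & records$qual < config$min_qual] <- "qual"
  if (config$require_pass)
    reason[is.na(reason) & records$filter != "PASS"] <- "not_pass"
  reason[is.na(reason) & records$is_indel] <- "indel"
  if (config$indel_flank_bp > 0) {
    near <- rep(FALSE, nrow(records))
    for (ch in unique(records$chrom)) {
      ipos <- records$pos[records$chrom == ch & records$is_indel]
      if (!length(ipos)) next
      idx <- which(records$chrom == ch & !records$is_indel)
      for (i in idx)
        if (any(abs(records$pos[i] - ipos) <= config$indel_flank_bp))
          near[i] <- TRUE
    }
    reason[is.na(reason) & near] <- "indel_flank"
  }
  if (config$biallelic_only) {
    multi <- grepl(",", records$alt) | nchar(records$ref) != 1L |
      (nchar(records$alt) != 1L & !grepl(",", records$alt))
    reason[is.na(reason) & multi] <- "multiallelic"
  }
  tab <- table(factor(reason, levels = names(drops)))
  drops[names(tab)] <- as.integer(tab)
  list(records = records[is.na(reason), , drop = FALSE], drops = drops)
}

## ---- intervals and masks ---------------------------------------------

#' Read a BED file of mask intervals
#'
#' Minimal strict BED reader: at least three tab- or space-separated
#' fields, integer `start < end`; a malformed line raises an error
#' naming its line number.  Intervals are returned 0-based half-open.
#'
#' @param path BED path.
#' @return Data frame with `chrom`, `start`, `end`.
#' @export
read_bed <- function(path) {
  lines <- readLines(path)
  keep <- !grepl("^(track|browser|#)", lines) & nzchar(lines)
  out <- data.frame(chrom = character(0), start = integer(0),
                    end = integer(0))
  for (i in which(keep)) {
    f <- strsplit(trimws(lines[i]), "[ \t]+")[[1]]
    if (length(f) < 3L)
      stop(sprintf("malformed BED line %d in %s: fewer than 3 fields",
                   i, path))
    s <- suppressWarnings(as.integer(f[2])); e <- suppressWarnings(as.integer(f[3]))
    if (is.na(s) || is.na(e) || s < 0 || e <= s)
      stop(sprintf("malformed BED line %d in %s: bad interval [%s, %s)",
                   i, path, f[2], f[3]))
    out <- rbind(out, data.frame(chrom = f[1], start = s, end = e,
                                 stringsAsFactors = FALSE))
  }
  out
}

## Merge overlapping/adjacent 0-based half-open intervals per chromosome.
merge_intervals <- function(iv) {
  if (nrow(iv) == 0L) return(iv)
  out <- NULL
  for (ch in unique(iv$chrom)) {
    x <- iv[iv$chrom == ch, , drop = FALSE]
    x <- x[order(x$start, x$end), , drop = FALSE]
    s <- x$start[1]; e <- x$end[1]
    for (i in seq_len(nrow(x))[-1]) {
      if (x$start[i] <= e) e <- max(e, x$end[i])
      else { out <- rbind(out, data.frame(chrom = ch, start = s, end = e))
             s <- x$start[i]; e <- x$end[i] }
    }
    out <- rbind(out, data.frame(chrom = ch, start = s, end = e))
  }
  rownames(out) <- NULL
  out
}

## TRUE for each (chrom, pos 1-based) falling inside any interval.
pos_in_intervals <- function(chrom, pos, iv) {
  hit <- rep(FALSE, length(pos))
  if (nrow(iv) == 0L) return(hit)
  for (ch in unique(iv$chrom)) {
    x <- iv[iv$chrom == ch, , drop = FALSE]
    idx <- which(chrom == ch)
    if (!length(idx)) next
    for (r in seq_len(nrow(x)))
      hit[idx] <- hit[idx] | (pos[idx] > x$start[r] & pos[idx] <= x$end[r])
  }
  hit
}

#' Drop records inside neutrality masks
#'
#' Removes records falling inside any mask interval.  A mask named
#' `"genes"` is extended by `gene_flank_bp` on both sides (strand
#' agnostic) before use: a record exactly 20,000 bp past a gene edge is
#' still masked, one at 20,001 bp is retained.  Idempotent.
#'
#' @param records Record table (or any data frame with `chrom`, `pos`).
#' @param masks Named list of BED data frames ([read_bed()]), e.g.
#'   `list(repeats = ..., cnv = ..., genes = ..., cpg = ...)`.
#' @param gene_flank_bp Gene flank in bp (default 20000).
#' @return List with `records` (survivors) and `drops` (count per mask).
#' @export
apply_masks <- function(records, masks, gene_flank_bp = 20000L) {
  drops <- stats::setNames(integer(length(masks)), names(masks))
  keep <- rep(TRUE, nrow(records))
  for (nm in names(masks)) {
    iv <- masks[[nm]]
    if (identical(nm, "genes") && nrow(iv)) {
      iv$start <- pmax(0L, iv$start - as.integer(gene_flank_bp))
      iv$end <- iv$end + as.integer(gene_flank_bp)
    }
    hit <- pos_in_intervals(records$chrom, records$pos, iv)
    drops[nm] <- sum(hit & keep)
    keep <- keep & !hit
  }
  list(records = records[keep, , drop = FALSE], drops = drops)
}

#' Callable mask from sliding-window density
#'
#' Slides windows of `window_bp` at `step_bp` along each chromosome and
#' retains windows whose callable-site density strictly exceeds
#' `min_density`; overlapping retained windows are merged into maximal
#' intervals.  (Density is the fraction of window positions that are
#' callable, i.e. pass the site-level filters and masks.)
#'
#' @param positions Data frame with `chrom` and 1-based `pos` of
#'   callable sites, or an integer vector (single unnamed chromosome).
#' @param chrom_lengths Named lengths in bp; defaults to the maximum
#'   callable position per chromosome.
#' @param window_bp,step_bp,min_density Window parameters.
#' @return A `gp4pg_mask`: merged 0-based half-open intervals.
#' @export
window_density_mask <- function(positions, chrom_lengths = NULL,
                                window_bp = 10000L, step_bp = 2500L,
                                min_density = 0.9) {
  if (is.numeric(positions) && is.null(dim(positions)))
    positions <- data.frame(chrom = "chr", pos = as.integer(positions))
  out <- data.frame(chrom = character(0), start = integer(0),
                    end = integer(0))
  for (ch in unique(positions$chrom)) {
    p <- sort(positions$pos[positions$chrom == ch])
    len <- if (!is.null(chrom_lengths) && ch %in% names(chrom_lengths))
      chrom_lengths[[ch]] else max(p)
    starts <- seq(0L, max(0L, len - 1L), by = step_bp)
    kept <- NULL
    for (w in starts) {
      n_in <- findInterval(w + window_bp, p) - findInterval(w, p)
      if (n_in / window_bp > min_density)
        kept <- rbind(kept, data.frame(chrom = ch, start = w,
                                       end = min(w + window_bp, len)))
    }
    if (!is.null(kept)) out <- rbind(out, kept)
  }
  structure(merge_intervals(out), class = c("gp4pg_mask", "data.frame"))
}

#' Polarize records to derived-allele counts
#'
#' The derived allele is the one differing from the ancestral allele
#' (INFO annotation `aa_key`, or an explicit per-record vector).  When
#' the ancestral matches the ALT, the counts flip (a `0/0` genotype
#' carries 2 derived copies).  Records whose ancestral allele matches
#' neither REF nor ALT, or is missing, are dropped and counted.
#'
#' @param records Record table with a `samples` genotype frame.
#' @param pops Named character vector mapping sample name to population.
#' @param ancestral Optional character vector of ancestral alleles per
#'   record; default reads `aa_key` from INFO.
#' @param aa_key INFO key carrying the ancestral allele.
#' @return List with `sites` (data frame `chrom`, `pos`, one derived
#'   count column per population) and `drops` (named counts).
#' @export
polarize <- function(records, pops, ancestral = NULL, aa_key = "AA") {
  if (is.null(ancestral)) {
    patt <- sprintf(".*(?:^|;)%s=([ACGTacgt]).*", aa_key)
    ancestral <- ifelse(grepl(sprintf("(^|;)%s=", aa_key), records$info),
                        sub(patt, "\\1", records$info), NA_character_)
  }
  ancestral <- toupper(ancestral)
  drops <- c(missing_ancestral = 0L, ancestral_mismatch = 0L)
  samples <- names(pops)
  pop_levels <- unique(unname(pops))
  n_alt <- function(gt) {
    if (is.na(gt) || gt %in% c(".", "./.", ".|.")) return(NA_integer_)
    sum(as.integer(strsplit(gt, "[/|]")[[1]]) > 0L)
  }
  rows <- vector("list", nrow(records))
  reason <- rep(NA_character_, nrow(records))
  for (i in seq_len(nrow(records))) {
    aa <- ancestral[i]
    if (is.na(aa)) { reason[i] <- "missing_ancestral"; next }
    flip <- FALSE
    if (aa == toupper(records$ref[i])) flip <- FALSE
    else if (aa == toupper(records$alt[i])) flip <- TRUE
    else { reason[i] <- "ancestral_mismatch"; next }
    cnt <- stats::setNames(numeric(length(pop_levels)), pop_levels)
    ok <- TRUE
    for (s in samples) {
      na <- n_alt(records$samples[[s]][i])
      if (is.na(na)) { ok <- FALSE; break }
      der <- if (flip) 2L - na else na
      cnt[pops[[s]]] <- cnt[pops[[s]]] + der
    }
    if (!ok) { reason[i] <- "missing_ancestral"; next }
    rows[[i]] <- c(pos = records$pos[i], cnt)
  }
  tab <- table(factor(reason, levels = names(drops)))
  drops[names(tab)] <- as.integer(tab)
  keep <- is.na(reason)
  sites <- if (any(keep)) {
    m <- do.call(rbind, rows[keep])
    data.frame(chrom = records$chrom[keep], pos = m[, "pos"],
               m[, pop_levels, drop = FALSE], check.names = FALSE,
               stringsAsFactors = FALSE)
  } else {
    cols <- c(list(chrom = character(0), pos = integer(0)),
              stats::setNames(rep(list(numeric(0)), length(pop_levels)),
                              pop_levels))
    as.data.frame(cols, check.names = FALSE)
  }
  rownames(sites) <- NULL
  list(sites = sites, drops = drops)
}

#' Assign sites to genomic blocks
#'
#' Blocks are the maximal intervals of the callable mask (default) or a
#' fixed-width tiling of each mask interval.  Sites outside the mask are
#' excluded; every retained site gets exactly one block id.
#'
#' @param sites Data frame with `chrom` and 1-based `pos` (e.g. from
#'   [polarize()]).
#' @param mask A `gp4pg_mask` / BED data frame of callable intervals.
#' @param scheme `"mask"` (one block per interval) or `"tiles"`.
#' @param tile_bp Tile width for `scheme = "tiles"`.
#' @return `sites` restricted to the mask with an integer `block`
#'   column.
#' @export
make_blocks <- function(sites, mask, scheme = c("mask", "tiles"),
                        tile_bp = 1e6) {
  scheme <- match.arg(scheme)
  block <- rep(NA_integer_, nrow(sites))
  next_id <- 0L
  for (r in seq_len(nrow(mask))) {
    iv <- mask[r, ]
    idx <- which(sites$chrom == iv$chrom & sites$pos > iv$start &
                   sites$pos <= iv$end)
    if (scheme == "mask") {
      block[idx] <- next_id + 1L
      next_id <- next_id + 1L
    } else {
      n_tiles <- as.integer(ceiling((iv$end - iv$start) / tile_bp))
      block[idx] <- next_id +
        as.integer(pmin(n_tiles,
                        (sites$pos[idx] - 1L - iv$start) %/% tile_bp + 1L))
      next_id <- next_id + n_tiles
    }
  }
  out <- sites[!is.na(block), , drop = FALSE]
  out$block <- block[!is.na(block)]
  rownames(out) <- NULL
  out
}

#' Observed 4jSFS from a VCF: the full filtering pipeline
#'
#' Runs, in order: site-level variant filters ([filter_variants()]),
#' neutrality masks with the 20-kb gene flank ([apply_masks()]),
#' ancestral polarization ([polarize()]), the sliding-window
#' callable-density mask ([window_density_mask()]; callable positions
#' are all positions outside the masks), blocking ([make_blocks()]) and
#' finally the SFS summary with its bootstrap sigma
#' ([observed_stats()]).
#'
#' @param vcf Path to the multi-sample VCF.
#' @param pops Named character vector sample -> population, or a path to
#'   a two-column TSV (sample, population).
#' @param masks Named list of BED paths or data frames.
#' @param chrom_lengths Named chromosome lengths in bp (required for the
#'   density windows).
#' @param ancestral Optional explicit ancestral alleles (default: INFO
#'   `AA`).
#' @param config A [filter_config()].
#' @param n_boot,seed Bootstrap parameters for sigma.
#' @param normalization Comparison scale.
#' @return List with `observed` ([observed_stats()]), `site_table`,
#'   `callable_mask` and `report` (drop counts per stage).
#' @export
observed_4jsfs <- function(vcf, pops, masks = list(), chrom_lengths,
                           ancestral = NULL, config = filter_config(),
                           n_boot = 1000L, seed = 1L,
                           normalization = "counts") {
  if (is.character(pops) && length(pops) == 1L && file.exists(pops)) {
    pt <- utils::read.table(pops, header = FALSE, sep = "\t",
                            stringsAsFactors = FALSE)
    pops <- stats::setNames(pt[[2]], pt[[1]])
  }
  masks <- lapply(masks, function(m) if (is.character(m)) read_bed(m) else m)
  rec <- read_vcf_records(vcf)
  flt <- filter_variants(rec, config)
  msk <- apply_masks(flt$records, masks, config$gene_flank_bp)
  pol <- polarize(msk$records, pops, ancestral = ancestral,
                  aa_key = config$aa_key)

  ## callable positions: everything outside the (flanked) masks
  flanked <- lapply(names(masks), function(nm) {
    iv <- masks[[nm]]
    if (identical(nm, "genes") && nrow(iv)) {
      iv$start <- pmax(0L, iv$start - as.integer(config$gene_flank_bp))
      iv$end <- iv$end + as.integer(config$gene_flank_bp)
    }
    iv
  })
  mask_all <- if (length(flanked)) merge_intervals(do.call(rbind, flanked))
              else data.frame(chrom = character(0), start = integer(0),
                              end = integer(0))
  callable <- do.call(rbind, lapply(names(chrom_lengths), function(ch) {
    pos <- seq_len(chrom_lengths[[ch]])
    iv <- mask_all[mask_all$chrom == ch, , drop = FALSE]
    if (nrow(iv))
      pos <- pos[!pos_in_intervals(rep(ch, length(pos)), pos, iv)]
    data.frame(chrom = ch, pos = pos, stringsAsFactors = FALSE)
  }))
  cmask <- window_density_mask(callable, chrom_lengths,
                               window_bp = config$window_bp,
                               step_bp = config$step_bp,
                               min_density = config$min_density)
  st <- make_blocks(pol$sites, cmask)
  pop_levels <- unique(unname(pops))
  counts <- as.matrix(st[, pop_levels, drop = FALSE])
  storage.mode(counts) <- "integer"
  attr(counts, "block") <- st$block
  obs <- observed_stats(counts, st$block, pop_levels, n_boot = n_boot,
                        seed = seed, normalization = normalization,
                        callable_length = sum(cmask$end - cmask$start))
  list(observed = obs, site_table = st, callable_mask = cmask,
       report = list(filters = as.list(flt$drops),
                     masks = as.list(msk$drops),
                     polarization = as.list(pol$drops),
                     sites_in = nrow(rec), sites_out = nrow(st)))
}

#' Write a callable mask as BED / the filter report as JSON
#'
#' @param mask A `gp4pg_mask` data frame.
#' @param report Report list from [observed_4jsfs()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_callable_bed <- function(mask, path) {
  utils::write.table(mask[, c("chrom", "start", "end")], path, sep = "\t",
                     quote = FALSE, row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' @rdname write_callable_bed
#' @export
write_filter_report <- function(report, path) {
  jsonlite::write_json(report, path, auto_unbox = TRUE, pretty = TRUE)
  invisible(path)
}
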