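## The fourfold joint site frequency spectrum (4jSFS) summary statistic.
##
## Every population contributes a derived-allele count on exactly two
## chromosomes (3 states: 0, 1, 2).  For each combination of four
## populations the joint spectrum has 3^4 = 81 cells; the two cells that
## are monomorphic across the whole quadruple (all-0 and all-2) are
## removed, leaving 3^4 - 2 = 79.  The summary vector concatenates the
## 79-cell segments of all C(n, 4) quadruples in lexicographic order of
## population indices.  For fewer than four populations the full
## multidimensional spectrum (3^n - 2 cells) plays the same role.

#' Summary-vector lengths
#'
#' `jsfs4_length(n)` is the fourfold joint-SFS length
#' \eqn{(3^4 - 2) \binom{n}{4}}; `msfs_length(n)` is the full
#' multidimensional SFS length \eqn{3^n - 2}.
#'
#' @param n Number of populations.
#' @return Integer vector length.
#' @export
jsfs4_length <- function(n) as.integer((3^4 - 2) * choose(n, 4))

#' @rdname jsfs4_length
#' @export
msfs_length <- function(n) as.integer(3^n - 2)

#' Classify a site into its 4jSFS cell
#'
#' A site's four per-population derived counts (each in `{0, 1, 2}`) are
#' encoded in base 3 as `c1*27 + c2*9 + c3*3 + c4`, giving codes 0..80.
#' The two quadruple-monomorphic codes (0 = all-ancestral, 80 = all
#' derived-fixed) are excluded; the remaining codes 1..79 index the
#' 79-cell segment directly (the 0-based cell index is `code - 1`).
#'
#' @param counts4 Integer vector of four counts in `{0, 1, 2}`.
#' @return The 1-based cell position (equal to the base-3 code) or
#'   `NA_integer_` for a monomorphic-excluded site.
#' @examples
#' classify_site(c(1, 0, 2, 0))  # code 33 -> 0-based index 32
#' @export
classify_site <- function(counts4) {
  if (length(counts4) != 4L || any(counts4 < 0 | counts4 > 2))
    stop("counts must be four values in {0, 1, 2}")
  code <- sum(counts4 * c(27L, 9L, 3L, 1L))
  if (code == 0L || code == 80L) return(NA_integer_)
  as.integer(code)
}

segment_codes <- function(counts, cols) {
  w <- 3L^(rev(seq_along(cols)) - 1L)
  code <- as.integer(as.matrix(counts[, cols, drop = FALSE]) %*% w)
  code[code == 0L | code == 3L^length(cols) - 1L] <- NA_integer_
  code
}

new_jsfs <- function(values, populations, segments, normalization) {
  structure(list(values = values, populations = populations,
                 segments = segments, normalization = normalization),
            class = "gp4pg_jsfs")
}

#' Compute the fourfold joint SFS
#'
#' Tallies per-site derived-count vectors (two chromosomes per
#' population) into the concatenated 79-cell segments of all
#' \eqn{\binom{n}{4}} population quadruples, in lexicographic order of
#' population indices.  Sites monomorphic across a quadruple are
#' excluded from that quadruple only.
#'
#' @param counts Integer matrix of per-site counts in `{0, 1, 2}` with
#'   one named column per population (e.g. from [sim_to_counts2()]).
#' @param populations Population order; defaults to the column order.
#' @return A `gp4pg_jsfs` with a values vector of length
#'   [jsfs4_length()]`(n)`.
#' @export
compute_4jsfs <- function(counts, populations = colnames(counts)) {
  counts <- as.matrix(counts)
  n <- length(populations)
  if (n < 4L) stop("the fourfold joint SFS requires at least 4 populations")
  if (any(counts < 0 | counts > 2))
    stop("counts must lie in {0, 1, 2}")
  counts <- counts[, populations, drop = FALSE]
  quads <- utils::combn(n, 4L, simplify = FALSE)
  values <- unlist(lapply(quads, function(q) {
    code <- segment_codes(counts, q)
    tabulate(code[!is.na(code)], nbins = 79L)
  }))
  new_jsfs(as.numeric(values), populations, quads, "counts")
}

## Summary statistic used by the engine: 4jSFS when n >= 4, otherwise
## the full multidimensional SFS (3^n - 2 cells) over all populations.
compute_sfs_summary <- function(counts, populations = colnames(counts)) {
  if (length(populations) >= 4L) return(compute_4jsfs(counts, populations))
  counts <- as.matrix(counts)[, populations, drop = FALSE]
  n <- length(populations)
  code <- segment_codes(counts, seq_len(n))
  values <- tabulate(code[!is.na(code)], nbins = msfs_length(n))
  new_jsfs(as.numeric(values), populations, list(seq_len(n)), "counts")
}

#' @export
print.gp4pg_jsfs <- function(x, ...) {
  cat(sprintf("Joint SFS summary: %d cells over %d segment(s) of %d populations (%s)\n",
              length(x$values), length(x$segments), length(x$populations),
              x$normalization))
  cat(sprintf("  total mass %.6g\n", sum(x$values)))
  invisible(x)
}

#' Normalize an SFS summary vector
#'
#' Per-segment proportions: each segment (79 cells per quadruple) is
#' scaled to sum to one so spectra from genomes of different callable
#' length are comparable.  All-zero segments are left zero with a
#' warning.  Idempotent.
#'
#' @param x A `gp4pg_jsfs`.
#' @param mode `"proportions"` (default) or `"counts"` (no-op).
#' @return The normalized `gp4pg_jsfs`.
#' @export
normalize_sfs <- function(x, mode = c("proportions", "counts")) {
  mode <- match.arg(mode)
  stopifnot(inherits(x, "gp4pg_jsfs"))
  if (mode == "counts") return(x)
  seg_len <- length(x$values) / length(x$segments)
  for (i in seq_along(x$segments)) {
    idx <- seq.int((i - 1L) * seg_len + 1L, i * seg_len)
    tot <- sum(x$values[idx])
    if (tot > 0) x$values[idx] <- x$values[idx] / tot
    else warning(sprintf("segment %d has no polymorphic sites; left zero", i))
  }
  x$normalization <- "proportions"
  x
}

## Per-block segment-count matrix (blocks x cells), shared by the
## bootstrap and the goodness-of-fit replicates.
block_sfs_matrix <- function(counts, block, populations) {
  if (length(populations) >= 4L)
    segs <- utils::combn(length(populations), 4L, simplify = FALSE)
  else segs <- list(seq_along(populations))
  seg_len <- if (length(populations) >= 4L) 79L
             else msfs_length(length(populations))
  blocks <- sort(unique(block))
  B <- length(blocks)
  bidx <- match(block, blocks)
  counts <- as.matrix(counts)[, populations, drop = FALSE]
  out <- matrix(0, B, seg_len * length(segs))
  for (i in seq_along(segs)) {
    code <- segment_codes(as.data.frame(counts), segs[[i]])
    keep <- !is.na(code)
    tab <- tabulate((bidx[keep] - 1L) * seg_len + code[keep],
                    nbins = B * seg_len)
    out[, seq.int((i - 1L) * seg_len + 1L, i * seg_len)] <-
      t(matrix(tab, nrow = seg_len))
  }
  list(mat = out, blocks = blocks, segments = segs, seg_len = seg_len)
}

#' Block-bootstrap standard errors of the SFS summary
#'
#' Resamples genomic blocks with replacement to the original block count
#' (Monte Carlo, `n_boot` replicate datasets of the same genomic size),
#' recomputes the summary vector per replicate, and returns the per-cell
#' standard deviation.  Cells with bootstrap deviation below the floor
#' `epsilon` are set to `epsilon` (the standardized fitness divides by
#' sigma, so zero-variance cells must not produce infinities).
#'
#' @param counts Integer matrix of per-site counts in `{0, 1, 2}` (one
#'   column per population) with a `"block"` attribute, e.g. from
#'   [sim_to_counts2()]; or pass `block` explicitly.
#' @param block Integer block id per site.
#' @param populations Population order.
#' @param n_boot Number of bootstrap replicates (default 1000).
#' @param seed Seed for the resampling.
#' @param epsilon Sigma floor in count units (default 1); under
#'   `normalization = "proportions"` the floor is scaled by each
#'   segment's observed total so it stays one count-equivalent.
#' @param normalization `"counts"` or `"proportions"`: scale of the
#'   replicate vectors whose deviation is measured.
#' @return A `gp4pg_sigma` object with the `values` vector.
#' @export
bootstrap_sigma <- function(counts, block = attr(counts, "block"),
                            populations = colnames(counts),
                            n_boot = 1000L, seed = 1L, epsilon = 1,
                            normalization = c("counts", "proportions")) {
  normalization <- match.arg(normalization)
  counts_n <- if (is.matrix(counts)) nrow(counts) else nrow(as.matrix(counts))
  if (counts_n == 0L) {
    ## site-free input: every cell is floored at epsilon
    nseg <- if (length(populations) >= 4L) choose(length(populations), 4L)
            else 1L
    seg_len <- if (length(populations) >= 4L) 79L
               else msfs_length(length(populations))
    segs <- if (length(populations) >= 4L)
      utils::combn(length(populations), 4L, simplify = FALSE)
    else list(seq_along(populations))
    return(structure(list(values = rep(epsilon, nseg * seg_len),
                          populations = populations, segments = segs,
                          epsilon = epsilon, normalization = normalization,
                          n_boot = n_boot),
                     class = "gp4pg_sigma"))
  }
  if (is.null(block)) stop("block ids are required")
  B <- length(unique(block))
  if (B < 2L) stop("sigma undefined: need at least 2 blocks")
  bl <- block_sfs_matrix(counts, block, populations)
  ncell <- ncol(bl$mat)
  nseg <- length(bl$segments)
  seg_of <- rep(seq_len(nseg), each = bl$seg_len)
  obs_tot <- vapply(seq_len(nseg), function(i)
    sum(bl$mat[, seg_of == i]), numeric(1))
  s1 <- numeric(ncell)
  s2 <- numeric(ncell)
  with_seed(seed, {
    for (r in seq_len(n_boot)) {
      draw <- tabulate(sample.int(B, B, replace = TRUE), nbins = B)
      v <- as.numeric(draw %*% bl$mat)
      if (normalization == "proportions") {
        tot <- vapply(seq_len(nseg), function(i) sum(v[seg_of == i]),
                      numeric(1))
        tot[tot == 0] <- 1
        v <- v / tot[seg_of]
      }
      s1 <- s1 + v
      s2 <- s2 + v * v
    }
  })
  sig <- sqrt(pmax(0, (s2 - s1^2 / n_boot) / (n_boot - 1)))
  floor_vec <- if (normalization == "proportions")
    epsilon / pmax(1, obs_tot)[seg_of] else rep(epsilon, ncell)
  sig <- pmax(sig, floor_vec)
  structure(list(values = sig, populations = populations,
                 segments = bl$segments, epsilon = epsilon,
                 normalization = normalization, n_boot = n_boot),
            class = "gp4pg_sigma")
}

#' Standardized fitness of a simulated SFS against the observed SFS
#'
#' The fitness (error) of a simulated dataset is
#' \deqn{f_{sim} = \sum_s \left(\frac{SS^s_{sim} - SS^s_{obs}}
#'   {\sigma^s_{obs}}\right)^2}
#' summed over every cell of the summary vector.  Zero if and only if
#' the two vectors agree on every cell; lower is better.
#'
#' @param ss_sim,ss_obs `gp4pg_jsfs` objects in the same normalization
#'   and population order.
#' @param sigma A `gp4pg_sigma` (or numeric vector) of matching length.
#' @return Non-negative numeric fitness value.
#' @export
sfs_fitness <- function(ss_sim, ss_obs, sigma) {
  stopifnot(inherits(ss_sim, "gp4pg_jsfs"), inherits(ss_obs, "gp4pg_jsfs"))
  sig <- if (inherits(sigma, "gp4pg_sigma")) sigma$values else as.numeric(sigma)
  if (length(ss_sim$values) != length(ss_obs$values) ||
      length(sig) != length(ss_obs$values))
    stop("summary vectors and sigma must have matching lengths")
  if (!identical(ss_sim$populations, ss_obs$populations))
    stop("population orders do not match")
  if (!identical(ss_sim$normalization, ss_obs$normalization))
    stop("normalizations do not match")
  sum(((ss_sim$values - ss_obs$values) / sig)^2)
}

cell_labels <- function(segments, seg_len, populations) {
  unlist(lapply(segments, function(q) {
    k <- length(q)
    codes <- seq_len(seg_len)
    ## skipped codes are 0 and 3^k - 1; cell position equals the code
    digits <- vapply(codes, function(cd) {
      d <- integer(k)
      for (j in k:1) { d[j] <- cd %% 3L; cd <- cd %/% 3L }
      paste(d, collapse = "")
    }, character(1))
    paste(paste(populations[q], collapse = ","), digits, sep = ":")
  }))
}

#' Write / read an SFS summary vector as tab-separated text
#'
#' The file carries the population order, normalization and cell codes
#' in comment headers and is byte-stable for fixed input.  Works for
#' both `gp4pg_jsfs` and `gp4pg_sigma` objects; `read_jsfs()` restores
#' the appropriate class.
#'
#' @param x A `gp4pg_jsfs` or `gp4pg_sigma`.
#' @param path File path.
#' @return `write_jsfs()` returns `path` invisibly; `read_jsfs()` the
#'   restored object.
#' @export
write_jsfs <- function(x, path) {
  seg_len <- length(x$values) / length(x$segments)
  lab <- cell_labels(x$segments, seg_len, x$populations)
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c(sprintf("#type: %s",
                       if (inherits(x, "gp4pg_sigma")) "sigma" else "jsfs"),
               sprintf("#populations: %s", paste(x$populations, collapse = ",")),
               sprintf("#normalization: %s", x$normalization),
               if (inherits(x, "gp4pg_sigma"))
                 sprintf("#epsilon: %.17g", x$epsilon),
               "cell\tvalue"), con)
  writeLines(sprintf("%s\t%.17g", lab, x$values), con)
  invisible(path)
}

#' @rdname write_jsfs
#' @export
read_jsfs <- function(path) {
  lines <- readLines(path)
  hdr <- grep("^#", lines, value = TRUE)
  get <- function(key) sub(sprintf("^#%s: ", key), "",
                           grep(sprintf("^#%s: ", key), hdr, value = TRUE))
  pops <- strsplit(get("populations"), ",")[[1]]
  body <- utils::read.table(text = lines[!grepl("^#", lines)], sep = "\t",
                            header = TRUE, stringsAsFactors = FALSE)
  segs_lab <- sub(":[0-9]+$", "", body$cell)
  segments <- lapply(unique(segs_lab), function(s)
    match(strsplit(s, ",")[[1]], pops))
  obj <- new_jsfs(body$value, pops, segments, get("normalization"))
  if (identical(get("type"), "sigma")) {
    obj <- structure(list(values = body$value, populations = pops,
                          segments = segments,
                          epsilon = as.numeric(get("epsilon")),
                          normalization = get("normalization"),
                          n_boot = NA_integer_),
                     class = "gp4pg_sigma")
  }
  obj
}
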