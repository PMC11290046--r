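## Goodness-of-fit of a fitted model: simulate replicate datasets,
## embed their SFS summaries with block-bootstrap replicates of the
## observed data by principal components, and score whether the observed
## data is an outlier relative to the simulated cloud.

#' PCA goodness-of-fit of a demographic model
#'
#' Simulates `n_sims` replicate datasets from the model, fits principal
#' components on the simulated summary matrix only, projects the
#' observed data (the mean of `n_obs_reps` block-bootstrap replicate
#' spectra, which are also returned as coordinates), and scores the
#' observed point by its Mahalanobis distance in the components
#' explaining at least `var_target` of the simulated variance.  The
#' percentile of that distance within the simulated cloud gives the
#' outlier call: the model is flagged as a poor fit when the observed
#' percentile exceeds `threshold` (default 99).
#'
#' @param model A valid `gp4pg_model` (typically the best fitted model).
#' @param observed An [observed_stats()] object (or a numeric matrix of
#'   observed replicate summary vectors, rows = replicates).
#' @param n_sims Number of simulated replicate datasets (default 1000).
#' @param genome [genome_spec()] for the simulations.
#' @param seed Seed.
#' @param n_obs_reps Observed block-bootstrap replicates (default 40).
#' @param var_target Minimum cumulative variance of retained components.
#' @param threshold Outlier percentile threshold.
#' @param epoch_length Epoch length for the simulations.
#' @param normalization Scale of the summary vectors; defaults to the
#'   observed object's normalization (`"counts"` rescales simulated
#'   spectra by the callable-length ratio).
#' @return An object of class `gp4pg_gof`: simulated and observed
#'   component coordinates, the observed Mahalanobis distance and
#'   percentile, and the outlier flag.
#' @export
gof_pca <- function(model, observed, n_sims = 1000L,
                    genome = genome_spec(), seed = 1L, n_obs_reps = 40L,
                    var_target = 0.9, threshold = 99,
                    epoch_length = 200,
                    normalization = NULL) {
  if (n_sims < 30L) stop("at least 30 simulations are required")
  if (inherits(observed, "gp4pg_observed")) {
    pops <- observed$populations
    obs_mat <- observed_replicates(observed, n_obs_reps, seed = seed)
    if (is.null(normalization)) normalization <- observed$normalization
  } else {
    obs_mat <- as.matrix(observed)
    pops <- names(model$sampling)
    if (is.null(normalization)) normalization <- "counts"
  }
  sims <- matrix(0, n_sims, ncol(obs_mat))
  for (i in seq_len(n_sims)) {
    sim <- simulate_dataset(model, genome, seed = seed + i,
                            epoch_length = epoch_length)
    cc <- sim_to_counts2(sim, seed = seed + i)
    ss <- compute_sfs_summary(cc, pops)
    if (normalization == "proportions")
      ss <- suppressWarnings(normalize_sfs(ss))
    else if (inherits(observed, "gp4pg_observed"))
      ss$values <- ss$values * genome_scale_factor(observed, sim)
    if (length(ss$values) != ncol(obs_mat))
      stop("simulated and observed summary lengths differ")
    sims[i, ] <- ss$values
  }
  keep <- apply(sims, 2, stats::sd) > 0
  if (!any(keep)) stop("degenerate simulation matrix: no cell varies")
  pc <- stats::prcomp(sims[, keep, drop = FALSE], center = TRUE,
                      scale. = FALSE)
  cum <- cumsum(pc$sdev^2) / sum(pc$sdev^2)
  k <- max(1L, which(cum >= var_target)[1])
  k <- min(k, ncol(pc$x))
  sd_k <- pc$sdev[seq_len(k)]
  d2_sim <- rowSums(sweep(pc$x[, seq_len(k), drop = FALSE], 2, sd_k,
                          "/")^2)
  project <- function(m) {
    sweep(m[, keep, drop = FALSE], 2, pc$center, "-") %*%
      pc$rotation[, seq_len(k), drop = FALSE]
  }
  obs_scores <- project(obs_mat)
  obs_point <- project(matrix(colMeans(obs_mat), 1))
  d2_obs <- sum((obs_point / sd_k)^2)
  percentile <- 100 * mean(d2_sim < d2_obs)
  structure(list(sim_scores = pc$x[, seq_len(k), drop = FALSE],
                 obs_scores = obs_scores,
                 obs_point = obs_point,
                 mahalanobis = d2_obs, percentile = percentile,
                 outlier = percentile > threshold,
                 threshold = threshold, n_components = k,
                 var_explained = cum[k], seed = seed),
            class = "gp4pg_gof")
}

#' @export
print.gp4pg_gof <- function(x, ...) {
  cat(sprintf("Goodness of fit: observed Mahalanobis %.3g (percentile %.1f%% of %d simulations, %d components, %.1f%% variance)\n",
              x$mahalanobis, x$percentile, nrow(x$sim_scores),
              x$n_components, 100 * x$var_explained))
  cat(sprintf("  outlier at the %g%% threshold: %s\n", x$threshold,
              if (x$outlier) "YES (poor fit)" else "no"))
  invisible(x)
}

#' @export
plot.gp4pg_gof <- function(x, ...) {
  lim1 <- range(c(x$sim_scores[, 1], x$obs_scores[, 1]))
  lim2 <- if (ncol(x$sim_scores) >= 2)
    range(c(x$sim_scores[, 2], x$obs_scores[, 2])) else c(-1, 1)
  y_sim <- if (ncol(x$sim_scores) >= 2) x$sim_scores[, 2]
           else rep(0, nrow(x$sim_scores))
  y_obs <- if (ncol(x$obs_scores) >= 2) x$obs_scores[, 2]
           else rep(0, nrow(x$obs_scores))
  graphics::plot(x$sim_scores[, 1], y_sim, pch = 16,
                 col = grDevices::adjustcolor("grey40", 0.5),
                 xlim = lim1, ylim = lim2, xlab = "PC1", ylab = "PC2",
                 main = "Simulated vs observed summary spectra", ...)
  graphics::points(x$obs_scores[, 1], y_obs, pch = 17, col = "red3")
  graphics::legend("topright", legend = c("simulated", "observed reps"),
                   pch = c(16, 17), col = c("grey40", "red3"), bty = "n")
  invisible(x)
}

#' Summarize a set of search runs
#'
#' Reports, per run, the final best error and the iteration of the last
#' improvement (the plateau point: 0 for a constant trace, the final
#' iteration for a strictly decreasing one), plus the topology support
#' table.
#'
#' @param runs A `gp4pg_replicates`, a list of `gp4pg_run`s, or a single
#'   run.
#' @return A list with `per_run` (data frame), `final_error_range` and
#'   `support`.
#' @export
trace_report <- function(runs) {
  if (inherits(runs, "gp4pg_replicates")) runs <- runs$runs
  if (inherits(runs, "gp4pg_run")) runs <- list(runs)
  stopifnot(length(runs) >= 1L)
  per_run <- do.call(rbind, lapply(seq_along(runs), function(i) {
    tr <- runs[[i]]$trace
    improved <- which(diff(tr$best) < 0)
    data.frame(run = i, seed = runs[[i]]$seed,
               final_error = tr$best[nrow(tr)],
               iterations = tr$iteration[nrow(tr)],
               last_improvement = if (length(improved))
                 tr$iteration[max(improved) + 1L] else 0L,
               topology = runs[[i]]$topology,
               stringsAsFactors = FALSE)
  }))
  support <- table(per_run$topology)
  list(per_run = per_run,
       final_error_range = range(per_run$final_error),
       support = support)
}
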