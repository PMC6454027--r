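# Nonparametric significance and latency machinery: two-sided
# sign-permutation testing with cluster-size correction, bootstrap
# peak/onset latency estimation, outlier trimming, and
# significant-timepoint counting per wavelet orientation.

# Sign-flip statistic maps: n_perm x n_time matrix of permuted means.
sign_perm_stats <- function(timecourses, n_perm, seed) {
  n_subj <- nrow(timecourses)
  with_seed(seed, {
    signs <- matrix(sample(c(-1, 1), n_perm * n_subj, replace = TRUE), n_perm, n_subj)
    (signs %*% timecourses) / n_subj
  })
}

#' Two-sided sign-permutation test on subject time-courses
#'
#' Under the null hypothesis of no signal, each subject's time-course is
#' symmetric around zero, so its sign is exchangeable. The observed
#' statistic is the mean over subjects at each timepoint; the null is
#' built by randomly multiplying each subject's series by +1 or -1. The
#' two-sided p-value at each timepoint is the proportion of sign-flip
#' draws (the observed assignment included, hence p >= 1/(n_perm + 1))
#' whose absolute statistic is at least the observed one.
#'
#' @param timecourses subject x time numeric matrix (>= 2 subjects).
#' @param n_perm Number of random sign assignments (default 1000; < 100
#'   triggers a resolution warning).
#' @param seed Integer seed.
#' @return Numeric vector of per-timepoint p-values in (0, 1\].
#' @export
sign_permutation_test <- function(timecourses, n_perm = 1000L, seed = 1L) {
  timecourses <- as.matrix(timecourses)
  if (nrow(timecourses) < 2L) stopf("need at least 2 subjects")
  if (!all(is.finite(timecourses))) stopf("timecourses must be finite")
  if (n_perm < 100L) warnf("n_perm = %d gives poor p-value resolution", n_perm)
  obs <- colMeans(timecourses)
  perm <- abs(sign_perm_stats(timecourses, n_perm, seed))
  tol <- 1e-12 * max(1, max(abs(obs)))
  exceed <- colSums(perm >= rep(abs(obs) - tol, each = n_perm))
  (1 + exceed) / (n_perm + 1)
}

#' Cluster-size correction for a per-timepoint p-value map
#'
#' Contiguous runs of timepoints with `p < cdt` form candidate clusters.
#' A null distribution of the maximum cluster size is built from the same
#' sign-flip permutation scheme: each permuted statistic map is converted
#' to p-values by its rank within the permutation distribution, and its
#' largest supra-threshold run is recorded. Clusters larger than the
#' (1 - alpha) quantile of that null are significant.
#'
#' @param p_values Per-timepoint p-values (from
#'   [sign_permutation_test()], same data and seed).
#' @param timecourses subject x time matrix the p-values came from.
#' @param cdt Cluster-defining threshold on uncorrected p (default 0.05).
#' @param alpha Corrected (family-wise) significance level (default 0.05).
#' @param n_perm Number of sign-flip permutations (default 1000).
#' @param seed Integer seed; use the same seed as the p-value map to
#'   reuse the identical permutation scheme.
#' @return Object of class `significance_mask`: list with `mask` (logical
#'   per timepoint), `clusters` (data.frame: start, stop, size,
#'   significant), `crit_size`, `cdt`, `alpha`, `n_perm`.
#' @export
cluster_correct <- function(p_values, timecourses, cdt = 0.05, alpha = 0.05,
                            n_perm = 1000L, seed = 1L) {
  timecourses <- as.matrix(timecourses)
  if (length(p_values) != ncol(timecourses)) {
    stopf("p_values and timecourses are not aligned")
  }
  runs_of <- function(flag) {
    r <- rle(flag)
    stop_i <- cumsum(r$lengths)
    start_i <- stop_i - r$lengths + 1L
    keep <- r$values
    data.frame(start = start_i[keep], stop = stop_i[keep], size = r$lengths[keep])
  }
  max_run <- function(flag) {
    r <- rle(flag)
    if (!any(r$values)) 0L else max(r$lengths[r$values])
  }
  perm <- abs(sign_perm_stats(timecourses, n_perm, seed))
  # permutation p-value of each permuted map, by rank within the null
  null_max <- integer(n_perm)
  perm_p <- matrix(0, n_perm, ncol(perm))
  for (t in seq_len(ncol(perm))) {
    rk <- rank(perm[, t], ties.method = "min")
    perm_p[, t] <- (n_perm - rk + 1) / n_perm
  }
  for (b in seq_len(n_perm)) null_max[b] <- max_run(perm_p[b, ] < cdt)
  crit <- stats::quantile(null_max, probs = 1 - alpha, type = 1, names = FALSE)
  cl <- runs_of(p_values < cdt)
  cl$significant <- cl$size > crit
  mask <- logical(length(p_values))
  for (k in which(cl$significant)) mask[cl$start[k]:cl$stop[k]] <- TRUE
  structure(
    list(
      mask = mask, clusters = cl, crit_size = crit,
      cdt = cdt, alpha = alpha, n_perm = n_perm
    ),
    class = "significance_mask"
  )
}

#' @export
print.significance_mask <- function(x, ...) {
  cat(sprintf(
    "<significance_mask> %d/%d timepoints significant in %d cluster(s) (crit size > %d, cdt %g, alpha %g)\n",
    sum(x$mask), length(x$mask), sum(x$clusters$significant), x$crit_size,
    x$cdt, x$alpha
  ))
  invisible(x)
}

#' Bootstrap estimate of peak or onset latency
#'
#' Resamples subjects with replacement `n_boot` times; each draw's
#' subject-average time-course yields one latency: for `kind = "peak"`,
#' the time of the maximum within `window_ms`; for `kind = "onset"`, the
#' start of the earliest significant cluster at or after stimulus onset,
#' with significance recomputed per draw via sign-permutation cluster
#' correction (`onset_n_perm` permutations). The point estimate comes
#' from the full (unresampled) subject sample; SEM and the 95% CI are the
#' standard deviation and the 2.5/97.5 percentiles (linear interpolation)
#' of the bootstrap distribution.
#'
#' @param timecourses subject x time matrix.
#' @param time_ms Time axis in ms, aligned with the columns.
#' @param window_ms Search window for peaks, default `c(0, 600)` ms.
#' @param n_boot Number of bootstrap draws (default 1000).
#' @param kind `"peak"` or `"onset"`.
#' @param seed Integer seed.
#' @param cdt,alpha,onset_n_perm Cluster-test parameters used in onset
#'   mode.
#' @return Object of class `latency_estimate`: list with `kind`,
#'   `estimate_ms`, `boot_mean_ms`, `sem_ms`, `ci95_ms`, `n_boot`,
#'   `prop_missing` (onset draws without any significant cluster), and
#'   `boot_ms` (the bootstrap latency sample).
#' @export
bootstrap_latency <- function(timecourses, time_ms, window_ms = c(0, 600),
                              n_boot = 1000L, kind = c("peak", "onset"),
                              seed = 1L, cdt = 0.05, alpha = 0.05,
                              onset_n_perm = 200L) {
  kind <- match.arg(kind)
  timecourses <- as.matrix(timecourses)
  n_subj <- nrow(timecourses)
  if (n_subj < 2L) stopf("need at least 2 subjects")
  win <- which(time_ms >= window_ms[1] & time_ms <= window_ms[2])
  if (!length(win)) stopf("peak window lies outside the time axis")
  peak_of <- function(avg) time_ms[win[which.max(avg[win])]]
  onset_of <- function(tc, sub_seed) {
    p <- sign_permutation_test(tc, n_perm = onset_n_perm, seed = sub_seed)
    m <- cluster_correct(p, tc,
      cdt = cdt, alpha = alpha,
      n_perm = onset_n_perm, seed = sub_seed
    )
    sig <- m$clusters[m$clusters$significant, , drop = FALSE]
    sig <- sig[time_ms[sig$start] >= 0, , drop = FALSE]
    if (!nrow(sig)) NA_real_ else time_ms[min(sig$start)]
  }
  point <- if (kind == "peak") {
    peak_of(colMeans(timecourses))
  } else {
    onset_of(timecourses, derive_seed(seed, 0L))
  }
  boot <- with_seed(derive_seed(seed, 404L), {
    draws <- matrix(
      sample.int(n_subj, n_boot * n_subj, replace = TRUE),
      n_boot, n_subj
    )
    vapply(seq_len(n_boot), function(b) {
      tc <- timecourses[draws[b, ], , drop = FALSE]
      if (kind == "peak") peak_of(colMeans(tc)) else onset_of(tc, derive_seed(seed, b))
    }, numeric(1))
  })
  ok <- !is.na(boot)
  structure(
    list(
      kind = kind, estimate_ms = point,
      boot_mean_ms = mean(boot[ok]),
      sem_ms = stats::sd(boot[ok]),
      ci95_ms = stats::quantile(boot[ok], c(0.025, 0.975), type = 7, names = FALSE),
      n_boot = n_boot, prop_missing = mean(!ok), boot_ms = boot
    ),
    class = "latency_estimate"
  )
}

#' @export
print.latency_estimate <- function(x, ...) {
  cat(sprintf(
    "<latency_estimate> %s = %g ms (boot %0.1f +/- %0.1f, CI95 %0.0f-%0.0f, n_boot %d)\n",
    x$kind, x$estimate_ms, x$boot_mean_ms, x$sem_ms,
    x$ci95_ms[1], x$ci95_ms[2], x$n_boot
  ))
  invisible(x)
}

#' Trim the extreme tails of a latency sample
#'
#' Removes values strictly below the `pct`-th or strictly above the
#' `(100 - pct)`-th percentile (linear-interpolation percentiles). Samples
#' too small to resolve the percentiles (fewer than `100 / pct` values)
#' are returned unchanged with a warning.
#'
#' @param latencies Numeric sample.
#' @param pct Tail percentage to discard on each side (default 5).
#' @return The trimmed sample.
#' @export
trim_outliers <- function(latencies, pct = 5) {
  if (length(latencies) < ceiling(100 / pct)) {
    warnf("sample of size %d too small to trim %g%% tails; returned unchanged",
          length(latencies), pct)
    return(latencies)
  }
  q <- stats::quantile(latencies, c(pct, 100 - pct) / 100, type = 7, names = FALSE)
  latencies[latencies >= q[1] & latencies <= q[2]]
}

#' Keep latencies at or below a cutoff
#'
#' Retains the early mode of a peak-latency distribution: values earlier
#' than or equal to `cutoff_ms` (default 150 ms, the canonical upper bound
#' for feedforward object recognition).
#'
#' @param latencies Numeric sample (ms).
#' @param cutoff_ms Inclusive upper bound (default 150).
#' @return The filtered sample.
#' @export
latency_histogram_filter <- function(latencies, cutoff_ms = 150) {
  latencies[latencies <= cutoff_ms]
}

#' Count significant timepoints per descriptor and orientation
#'
#' Tallies the significant timepoints of each descriptor's mask and sums
#' the counts of the oriented detail descriptors (bands H, V, D) across
#' levels, the quantity used to read out orientation anisotropy (the
#' oblique effect) from the time-courses.
#'
#' @param masks Named list of [significance_mask][cluster_correct]
#'   objects (or plain logical vectors), names = descriptor ids.
#' @param manifest data.frame with columns `id`, `level`, `band` mapping
#'   ids to levels and bands (default: the standard 25-descriptor
#'   manifest for the ids present).
#' @return List with `table` (data.frame: id, level, band,
#'   n_significant) and `orientation_sums` (named numeric, H/V/D).
#' @export
count_significant <- function(masks, manifest = NULL) {
  if (is.null(manifest)) {
    manifest <- descriptor_manifest(5L)
  }
  ids <- names(masks)
  man <- manifest[match(ids, manifest$id), , drop = FALSE]
  counts <- vapply(masks, function(m) {
    v <- if (inherits(m, "significance_mask")) m$mask else m
    sum(v)
  }, numeric(1))
  tab <- data.frame(
    id = ids, level = man$level, band = man$band,
    n_significant = as.integer(counts), stringsAsFactors = FALSE
  )
  sums <- vapply(c("H", "V", "D"), function(b) {
    sum(tab$n_significant[tab$band == b])
  }, numeric(1))
  list(table = tab, orientation_sums = sums)
}
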