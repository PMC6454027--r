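test_that("sign permutation p-values behave at the anchors", {
  zeros <- matrix(0, 6, 10)
  expect_equal(sign_permutation_test(zeros, n_perm = 200, seed = 1), rep(1, 10))
  expect_error(sign_permutation_test(matrix(1, 1, 5)), "2 subjects")
  expect_warning(sign_permutation_test(matrix(rnorm(20), 4), n_perm = 50, seed = 1), "resolution")
})

test_that("Monte-Carlo p agrees with the exhaustive sign-flip oracle", {
  set.seed(70)
  n_perm <- 2000L
  for (n_subj in c(6L, 10L, 12L)) {
    x <- rnorm(n_subj, mean = 0.5)
    p_ex <- exhaustive_sign_p(x)
    p_mc <- sign_permutation_test(matrix(x, ncol = 1), n_perm = n_perm, seed = n_subj)
    se <- sqrt(p_ex * (1 - p_ex) / n_perm)
    expect_lt(abs(p_mc - p_ex), 3 * se + 2 / (n_perm + 1))
  }
  # identical strictly positive responses: only the two all-same flips reach |obs|
  x16 <- rep(0.3, 16)
  expect_equal(exhaustive_sign_p(x16), 2 / 2^16)
  p_mc <- sign_permutation_test(matrix(x16, ncol = 1), n_perm = 1000, seed = 4)
  expect_lte(p_mc, 3 / 1001) # at most the observed + rare exact ties
})

test_that("null p-values are approximately uniform", {
  set.seed(71)
  tc <- matrix(rnorm(8 * 300), 8, 300)
  p <- sign_permutation_test(tc, n_perm = 500, seed = 7)
  ks <- suppressWarnings(stats::ks.test(p, "punif"))
  expect_lt(unname(ks$statistic), 0.1)
})

test_that("cluster correction flags the injected window and not empty maps", {
  # no sub-threshold p at all -> empty mask
  tc0 <- matrix(rnorm(8 * 50, sd = 0.1), 8, 50)
  p0 <- rep(0.8, 50)
  m0 <- cluster_correct(p0, tc0, n_perm = 200, seed = 1)
  expect_false(any(m0$mask))
  expect_equal(nrow(m0$clusters), 0L)

  # strong 25-timepoint signal recovered as one dominant cluster
  set.seed(72)
  tc <- matrix(rnorm(10 * 120, sd = 0.5), 10, 120)
  tc[, 41:65] <- tc[, 41:65] + 2
  p <- sign_permutation_test(tc, n_perm = 500, seed = 3)
  m <- cluster_correct(p, tc, n_perm = 500, seed = 3)
  sig <- m$clusters[m$clusters$significant, ]
  expect_gte(nrow(sig), 1)
  covered <- sum(m$mask[41:65])
  expect_gte(covered, 0.8 * 25)
  expect_lt(sum(m$mask[-(41:65)]), 10)
  # masked points lie inside listed significant clusters, which are disjoint
  inside <- logical(120)
  for (k in which(m$clusters$significant)) {
    inside[m$clusters$start[k]:m$clusters$stop[k]] <- TRUE
  }
  expect_identical(m$mask, inside)
})

test_that("family-wise error on null data stays near the nominal level", {
  set.seed(73)
  n_runs <- 300L
  hits <- vapply(seq_len(n_runs), function(r) {
    tc <- matrix(rnorm(8 * 120), 8, 120)
    p <- sign_permutation_test(tc, n_perm = 250, seed = r)
    m <- cluster_correct(p, tc, n_perm = 250, seed = r)
    any(m$mask)
  }, logical(1))
  expect_lte(mean(hits), 0.075)
})

test_that("bootstrap latency recovers degenerate and injected peaks", {
  # all subjects share a unique maximum
  t_ms <- seq(-100, 300, by = 10)
  base <- exp(-((t_ms - 120)^2) / (2 * 30^2))
  tc <- rbind(base, 2 * base, 0.5 * base)
  est <- bootstrap_latency(tc, t_ms, c(0, 300), n_boot = 100, kind = "peak", seed = 1)
  expect_equal(est$estimate_ms, 120)
  expect_equal(est$sem_ms, 0)
  expect_equal(est$ci95_ms, c(120, 120))

  # moderate noise: bootstrap mean within +/- 10 ms of the injected peak
  set.seed(74)
  noisy <- matrix(base, 10, length(t_ms), byrow = TRUE) +
    matrix(rnorm(10 * length(t_ms), sd = 0.25), 10)
  est2 <- bootstrap_latency(noisy, t_ms, c(0, 300), n_boot = 300, kind = "peak", seed = 2)
  expect_lt(abs(est2$boot_mean_ms - 120), 10)

  # two seeds agree within 2 bootstrap standard errors
  est3 <- bootstrap_latency(noisy, t_ms, c(0, 300), n_boot = 300, kind = "peak", seed = 9)
  se_boot <- est2$sem_ms / sqrt(300)
  expect_lt(abs(est2$boot_mean_ms - est3$boot_mean_ms), 2 * se_boot * sqrt(2) + 1e-9)
})

test_that("onset latency finds the first significant post-stimulus cluster", {
  set.seed(75)
  t_ms <- seq(-100, 300, by = 10)
  sig <- as.numeric(t_ms >= 60 & t_ms <= 200)
  tc <- 1.5 * matrix(sig, 10, length(t_ms), byrow = TRUE) +
    matrix(rnorm(10 * length(t_ms), sd = 0.3), 10)
  est <- bootstrap_latency(tc, t_ms, c(0, 300),
    n_boot = 50, kind = "onset",
    seed = 3, onset_n_perm = 200
  )
  expect_lt(abs(est$estimate_ms - 60), 30)
  expect_lte(est$prop_missing, 0.1)
})

test_that("outlier trimming and the latency cutoff follow their conventions", {
  x <- 1:100
  tr <- trim_outliers(x, 5)
  expect_length(tr, 90L)
  expect_equal(range(tr), c(6, 95))
  # frozen from the linear-interpolation percentile rule on 1..1000
  tr2 <- trim_outliers(1:1000, 5)
  expect_equal(range(tr2), c(51, 950))
  expect_equal(trim_outliers(rep(7, 50), 5), rep(7, 50)) # coincident percentiles
  expect_warning(out <- trim_outliers(1:10, 5), "too small")
  expect_identical(out, 1:10)

  expect_equal(latency_histogram_filter(c(108, 151)), 108)
  expect_equal(latency_histogram_filter(150), 150) # boundary inclusive
  expect_length(latency_histogram_filter(numeric(0)), 0L)
})

test_that("significant-timepoint counting sums runs and orientations", {
  mask_of <- function(idx, n = 60) {
    v <- logical(n)
    v[idx] <- TRUE
    v
  }
  masks <- list(
    W2 = mask_of(c(10:19, 40:44)), # level 1 H: 15 points
    W3 = mask_of(21:30), # level 1 V: 10
    W4 = mask_of(integer(0)), # level 1 D: 0
    W7 = mask_of(1:5), # level 2 H: 5
    W9 = mask_of(50) # level 2 D: 1
  )
  cnt <- count_significant(masks)
  expect_equal(cnt$table$n_significant[cnt$table$id == "W2"], 15L)
  expect_equal(unname(cnt$orientation_sums), c(20, 10, 1))
  empty <- count_significant(list(W2 = mask_of(integer(0))))
  expect_equal(sum(empty$table$n_significant), 0L)
})
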