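# Minimal epoch_set built directly, bypassing the generator, so each
# preprocessing stage can be fed hand-crafted traces.
manual_epochs <- function(arr, t_start_ms = -100, step_ms = 10) {
  d <- dim(arr)
  n_frontal <- min(2L, d[3])
  labels <- c(
    sprintf("FRT%03d", seq_len(n_frontal)),
    sprintf("MEG%03d", seq_len(max(0L, d[3] - n_frontal)))
  )
  structure(
    list(
      subjects = list(arr), t_start_ms = t_start_ms, step_ms = step_ms,
      time_ms = seq(t_start_ms, by = step_ms, length.out = d[4]),
      channel_labels = labels, frontal_channels = labels[seq_len(n_frontal)],
      valid = list(matrix(TRUE, d[1], d[2]))
    ),
    class = "epoch_set"
  )
}

test_that("baseline correction zeroes the pre-stimulus mean", {
  arr <- array(0, dim = c(1, 2, 3, 21))
  arr[1, 1, , ] <- 5 # constant trial
  arr[1, 2, 1, 1:10] <- c(1, 3, rep(2, 8)) # pre-stim mean 2
  arr[1, 2, 1, 11:21] <- 7
  ep <- baseline_correct(manual_epochs(arr))
  expect_equal(max(abs(ep$subjects[[1]][1, 1, , ])), 0) # constant -> zero
  expect_equal(ep$subjects[[1]][1, 2, 1, 21], 5) # 7 - baseline 2
  pre <- ep$time_ms < 0
  pre_means <- apply(ep$subjects[[1]][, , , pre, drop = FALSE], c(1, 2, 3), mean)
  expect_lt(max(abs(pre_means)), 1e-12)

  # zero-baseline trial passes through unchanged
  arr2 <- array(0, dim = c(1, 1, 1, 21))
  arr2[1, 1, 1, 11:21] <- 5
  ep2 <- baseline_correct(manual_epochs(arr2))
  expect_equal(ep2$subjects[[1]], arr2)

  post_only <- manual_epochs(array(1, dim = c(1, 1, 1, 5)), t_start_ms = 0)
  expect_error(baseline_correct(post_only), "pre-stimulus")
})

test_that("peak-to-peak rejection is strict at the threshold", {
  arr <- array(0, dim = c(1, 3, 2, 10))
  arr[1, 1, 1, 1:2] <- c(-3001, 3000) # ptp 6001 -> flagged
  arr[1, 2, , 1:2] <- rep(c(-3000, 3000), each = 2) # ptp exactly 6000 -> kept
  ep <- reject_bad_trials(manual_epochs(arr), ptp_threshold = 6000)
  expect_equal(ep$valid[[1]][1, ], c(FALSE, TRUE, TRUE))
  expect_equal(ep$rejection[[1]]$flagged, 1)
  # data untouched
  expect_equal(ep$subjects[[1]], arr)
})

test_that("low-pass filter passes low frequencies and kills high ones", {
  fs <- 1000
  t_s <- seq(0, 1.2, by = 1 / fs)
  n <- length(t_s)
  arr <- array(0, dim = c(1, 3, 1, n))
  arr[1, 1, 1, ] <- 4.2 # DC
  arr[1, 2, 1, ] <- sin(2 * pi * 10 * t_s)
  arr[1, 3, 1, ] <- sin(2 * pi * 90 * t_s)
  ep <- lowpass_filter(manual_epochs(arr, t_start_ms = -100, step_ms = 1), 30)
  mid <- 300:900 # avoid filtfilt edge transients
  expect_equal(ep$subjects[[1]][1, 1, 1, mid], rep(4.2, length(mid)), tolerance = 1e-9)
  expect_gte(max(abs(ep$subjects[[1]][1, 2, 1, mid])), 0.99)
  expect_lte(max(abs(ep$subjects[[1]][1, 3, 1, mid])), 0.10)
  expect_error(
    lowpass_filter(manual_epochs(arr, step_ms = 10), 60),
    "Nyquist"
  )
})

test_that("eyeblink removal is identity without blinks and removes the template", {
  d <- as.matrix(dist(matrix(rnorm(12), 6)))
  gt <- ground_truth(d, 100, 60, 0.5, seed = 21)
  clean <- generate_epochs(gt, 1, 6, 6, 20, c(-100, 300), 5)
  out <- remove_eyeblinks(clean, z_threshold = 8)
  expect_equal(out$subjects[[1]], clean$subjects[[1]], tolerance = 1e-12)
  # infinite threshold path on contaminated data
  inj <- inject_eyeblinks(clean, prop_trials = 0.5, amplitude = 30, seed = 4)
  out_inf <- remove_eyeblinks(inj$epochs, z_threshold = Inf)
  expect_identical(out_inf$subjects[[1]], inj$epochs$subjects[[1]])

  cleaned <- remove_eyeblinks(inj$epochs, z_threshold = 4)
  expect_gt(sum(cleaned$blink_report), 0)
  # residual projection on the known loading is near zero in blink trials
  resid <- vapply(which(inj$blink_trials[[1]][1, ]), function(tr) {
    max(abs(crossprod(inj$loading, cleaned$subjects[[1]][1, tr, , ])))
  }, numeric(1))
  before <- vapply(which(inj$blink_trials[[1]][1, ]), function(tr) {
    max(abs(crossprod(inj$loading, inj$epochs$subjects[[1]][1, tr, , ])))
  }, numeric(1))
  expect_lt(max(resid / before), 0.1)

  expect_error(
    remove_eyeblinks(clean, frontal_channels = "NOPE"),
    "NOPE"
  )
})

test_that("rejection flags are invariant to baseline correction order", {
  set.seed(33)
  arr <- array(rnorm(2 * 6 * 3 * 20, sd = 1500), dim = c(2, 6, 3, 20))
  ep <- manual_epochs(arr)
  a <- reject_bad_trials(baseline_correct(ep), 5000)
  b <- baseline_correct(reject_bad_trials(ep, 5000))
  expect_identical(a$valid, b$valid)
  expect_true(any(!a$valid[[1]]) && any(a$valid[[1]])) # fixture exercises both paths
})

test_that("preprocessing preserves shapes and metadata", {
  d <- as.matrix(dist(matrix(rnorm(8), 4)))
  gt <- ground_truth(d, 100, 50, 0.5, seed = 6)
  ep <- generate_epochs(gt, 2, 4, 4, 10, c(-100, 200), 10)
  out <- preprocess_epochs(ep)
  expect_equal(dim(out$subjects[[1]]), dim(ep$subjects[[1]]))
  expect_identical(out$time_ms, ep$time_ms)
  expect_identical(out$channel_labels, ep$channel_labels)
})
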