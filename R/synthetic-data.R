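#' Orientation profile for a generated stimulus
#'
#' Nonnegative weights controlling the horizontal, vertical and diagonal
#' edge energy of a generated image. At least one weight must be positive.
#'
#' @param horizontal,vertical,diagonal Nonnegative finite weights
#'   (arbitrary units).
#' @return A list of class `orientation_profile`.
#' @export
orientation_profile <- function(horizontal = 0, vertical = 0, diagonal = 0) {
  w <- c(horizontal = horizontal, vertical = vertical, diagonal = diagonal)
  if (!all(is.finite(w))) stopf("orientation weights must be finite")
  if (any(w < 0)) stopf("orientation weights must be nonnegative")
  if (all(w == 0)) stopf("at least one orientation weight must be > 0")
  structure(as.list(w), class = "orientation_profile")
}

#' Generate stimulus images with controlled oriented edge energy
#'
#' Each image superimposes three pure-orientation patterns — alternating
#' rows (horizontal stripes), alternating columns (vertical stripes) and a
#' checkerboard (diagonal structure) — whose contrasts are set by the
#' condition's [orientation_profile()], plus a small smooth random field
#' that differentiates stimuli sharing a profile. Each pattern loads on
#' exactly one level-1 Haar detail band, so the H/V/D band-energy ordering
#' of image k follows profile k's weight ordering.
#'
#' @param n_conditions Number of stimuli (>= 2).
#' @param size Image side length in pixels (>= 32).
#' @param profiles List of `n_conditions` [orientation_profile()] objects.
#' @param seed Integer seed; output is bit-identical for identical calls.
#' @return List of `size` x `size` matrices with values in \[0, 1\].
#' @export
generate_stimuli <- function(n_conditions, size, profiles, seed) {
  if (!is_count(n_conditions, min = 2L)) stopf("n_conditions must be >= 2")
  if (!is_count(size) || size < 32L) {
    stopf("size %d is below the minimum of 32 pixels per side", size)
  }
  if (length(profiles) != n_conditions) {
    stopf("need exactly one orientation profile per condition")
  }
  profiles <- lapply(profiles, function(p) {
    if (!inherits(p, "orientation_profile")) {
      p <- do.call(orientation_profile, as.list(p))
    }
    p
  })
  r <- matrix(seq_len(size), size, size)
  cl <- t(r)
  g_h <- (-1)^r          # alternating rows: pure level-1 H energy
  g_v <- (-1)^cl         # alternating columns: pure level-1 V energy
  g_d <- (-1)^(r + cl)   # checkerboard: pure level-1 D energy
  with_seed(seed, {
    lapply(seq_len(n_conditions), function(k) {
      p <- profiles[[k]]
      w <- c(p$horizontal, p$vertical, p$diagonal)
      w <- w / sum(w)
      img <- 0.5 + 0.42 * (w[1] * g_h + w[2] * g_v + w[3] * g_d)
      # smooth per-stimulus texture: separable 5-tap blur of white noise
      z <- matrix(stats::rnorm(size^2), size, size)
      blur <- function(m) {
        apply(m, 2, function(v) {
          as.numeric(stats::filter(v, rep(1 / 5, 5), circular = TRUE))
        })
      }
      z <- t(blur(t(blur(z))))
      img <- img + 0.05 * z / stats::sd(z)
      pmin(pmax(img, 0), 1)
    })
  })
}

#' Ground truth for a synthetic MEG epoch set
#'
#' Bundles the designed representational geometry and temporal profile
#' injected into generated epochs.
#'
#' @param model_rdm Symmetric condition x condition dissimilarity matrix
#'   (diagonal treated as zero), or a list of such matrices that are
#'   injected jointly in orthogonal channel subspaces.
#' @param signal_peak_ms Latency of maximal signal expression, ms after
#'   stimulus onset.
#' @param signal_width_ms Temporal FWHM of the Gaussian signal envelope, ms.
#' @param noise_sd Standard deviation of the additive Gaussian sensor noise
#'   (> 0), in the same units as the embedded condition patterns.
#' @param seed Integer seed for all generator randomness.
#' @param rdm_weights Optional numeric weights, one per RDM when
#'   `model_rdm` is a list (default all 1).
#' @return A list of class `ground_truth`.
#' @export
ground_truth <- function(model_rdm, signal_peak_ms, signal_width_ms,
                         noise_sd, seed, rdm_weights = NULL) {
  rdms <- if (is.matrix(model_rdm)) list(model_rdm) else model_rdm
  for (d in rdms) {
    if (!is.matrix(d) || nrow(d) != ncol(d)) stopf("model_rdm must be square")
    dd <- d
    diag(dd) <- 0
    if (!isTRUE(all.equal(dd, t(dd), tolerance = 1e-8))) {
      stopf("model_rdm must be symmetric")
    }
  }
  if (is.null(rdm_weights)) rdm_weights <- rep(1, length(rdms))
  if (!is.numeric(noise_sd) || noise_sd <= 0) stopf("noise_sd must be > 0")
  structure(
    list(
      model_rdm = rdms, rdm_weights = rdm_weights,
      signal_peak_ms = signal_peak_ms, signal_width_ms = signal_width_ms,
      noise_sd = noise_sd, seed = as.integer(seed)
    ),
    class = "ground_truth"
  )
}

#' Classical MDS embedding of a dissimilarity matrix
#'
#' Double-centers the squared dissimilarities, eigen-decomposes, and keeps
#' the axes with positive eigenvalues, so pairwise Euclidean distances
#' between the embedded points reproduce the input dissimilarities exactly
#' whenever the matrix is Euclidean-embeddable.
#'
#' @param d Symmetric n x n dissimilarity matrix, zero-treated diagonal.
#' @return n x p coordinate matrix, p = number of positive eigenvalues.
#' @export
mds_embed <- function(d) {
  n <- nrow(d)
  dd <- as.matrix(d)
  diag(dd) <- 0
  j <- diag(n) - 1 / n
  b <- -0.5 * j %*% (dd^2) %*% j
  e <- eigen((b + t(b)) / 2, symmetric = TRUE)
  keep <- e$values > max(e$values, 0) * 1e-9
  if (!any(keep)) stopf("model_rdm has no positive-eigenvalue axes")
  e$vectors[, keep, drop = FALSE] %*%
    diag(sqrt(e$values[keep]), sum(keep))
}

# Gaussian temporal envelope, hard-zeroed before stimulus onset: a
# stimulus-evoked response cannot precede the stimulus, and this keeps the
# pre-stimulus interval signal-free by construction.
signal_envelope <- function(time_ms, peak_ms, width_ms) {
  sigma <- width_ms / (2 * sqrt(2 * log(2)))
  env <- exp(-((time_ms - peak_ms)^2) / (2 * sigma^2))
  env[time_ms < 0] <- 0
  env
}

#' Generate a synthetic MEG epoch set with known representational geometry
#'
#' Condition-mean sensor patterns are built by classical MDS of the target
#' RDM ([mds_embed()]), embedded into channel space by a seeded random
#' orthogonal rotation, and modulated by a Gaussian temporal envelope
#' centered at `signal_peak_ms` (zero before stimulus onset). Independent
#' Gaussian noise of sd `noise_sd` is added per trial, channel and sample.
#' When `truth$model_rdm` is a list, each geometry is embedded in an
#' orthogonal channel subspace with its own weight, so several model RDMs
#' can drive the same epochs with controlled relative strength.
#'
#' @param truth A [ground_truth()] object.
#' @param n_subjects,n_conditions,n_trials,n_channels Design sizes;
#'   `n_trials` >= 2 per condition.
#' @param window_ms Length-2 numeric `(start, stop)` in ms relative to
#'   stimulus onset; must cover `signal_peak_ms`.
#' @param step_ms Sampling step in ms (1 ms = 1 kHz).
#' @return An object of class `epoch_set`: list with `subjects` (one
#'   condition x trial x channel x time array per subject), `t_start_ms`,
#'   `step_ms`, `time_ms`, `channel_labels`, `frontal_channels`, `valid`
#'   (condition x trial logical matrix per subject) and `truth`.
#' @export
generate_epochs <- function(truth, n_subjects, n_conditions, n_trials,
                            n_channels, window_ms = c(-150, 1000),
                            step_ms = 1) {
  stopifnot(inherits(truth, "ground_truth"))
  if (!is_count(n_trials, min = 2L)) stopf("n_trials must be >= 2")
  if (truth$signal_peak_ms < window_ms[1] || truth$signal_peak_ms > window_ms[2]) {
    stopf(
      "signal_peak_ms (%g) lies outside the epoch window (%g, %g)",
      truth$signal_peak_ms, window_ms[1], window_ms[2]
    )
  }
  for (d in truth$model_rdm) {
    if (nrow(d) != n_conditions) {
      stopf("model_rdm is %dx%d but n_conditions = %d", nrow(d), ncol(d), n_conditions)
    }
  }
  time_ms <- seq(window_ms[1], window_ms[2], by = step_ms)
  n_time <- length(time_ms)
  env <- signal_envelope(time_ms, truth$signal_peak_ms, truth$signal_width_ms)

  parts <- mapply(
    function(d, w) w * mds_embed(d),
    truth$model_rdm, truth$rdm_weights,
    SIMPLIFY = FALSE
  )
  pts <- do.call(cbind, parts)
  if (ncol(pts) > n_channels) {
    stopf(
      "embedding needs %d dimensions but only %d channels available",
      ncol(pts), n_channels
    )
  }
  patterns <- with_seed(derive_seed(truth$seed, 101L), {
    q <- qr.Q(qr(matrix(stats::rnorm(n_channels^2), n_channels)))
    pts %*% t(q[, seq_len(ncol(pts)), drop = FALSE])
  })

  n_frontal <- max(2L, round(0.1 * n_channels))
  labels <- c(
    sprintf("FRT%03d", seq_len(n_frontal)),
    sprintf("MEG%03d", seq_len(n_channels - n_frontal))
  )
  subjects <- vector("list", n_subjects)
  valid <- vector("list", n_subjects)
  for (s in seq_len(n_subjects)) {
    arr <- with_seed(derive_seed(truth$seed, 202L, s), {
      noise <- array(
        stats::rnorm(n_conditions * n_trials * n_channels * n_time,
          sd = truth$noise_sd
        ),
        dim = c(n_conditions, n_trials, n_channels, n_time)
      )
      sig <- array(0, dim = dim(noise))
      for (cc in seq_len(n_conditions)) {
        block <- outer(patterns[cc, ], env) # channel x time
        for (tr in seq_len(n_trials)) sig[cc, tr, , ] <- block
      }
      sig + noise
    })
    subjects[[s]] <- arr
    valid[[s]] <- matrix(TRUE, n_conditions, n_trials)
  }
  structure(
    list(
      subjects = subjects, t_start_ms = window_ms[1], step_ms = step_ms,
      time_ms = time_ms, channel_labels = labels,
      frontal_channels = labels[seq_len(n_frontal)], valid = valid,
      truth = truth
    ),
    class = "epoch_set"
  )
}

#' @export
print.epoch_set <- function(x, ...) {
  d <- dim(x$subjects[[1L]])
  cat(sprintf(
    "<epoch_set> %d subjects, %d conditions x %d trials x %d channels x %d samples (%g..%g ms, step %g)\n",
    length(x$subjects), d[1], d[2], d[3], d[4],
    x$time_ms[1], x$time_ms[length(x$time_ms)], x$step_ms
  ))
  invisible(x)
}

#' Inject synthetic eyeblink artifacts into an epoch set
#'
#' Adds a rank-1 artifact (a fixed channel loading times a Gaussian
#' temporal bump) to a random subset of trials. The loading is dominated
#' by the frontal channels, emulating the spatial signature of eyeblinks.
#' Used to exercise the eyeblink-removal stage against a known template.
#'
#' @param epochs An `epoch_set`.
#' @param prop_trials Proportion of trials to contaminate (default 0.3).
#' @param amplitude Peak artifact amplitude (default 20).
#' @param seed Integer seed.
#' @return List with `epochs` (contaminated copy), `loading` (channel
#'   vector, unit norm), and `blink_trials` (per subject, a logical
#'   condition x trial matrix of contaminated trials).
#' @export
inject_eyeblinks <- function(epochs, prop_trials = 0.3, amplitude = 20, seed = 1L) {
  stopifnot(inherits(epochs, "epoch_set"))
  n_chan <- length(epochs$channel_labels)
  frontal <- epochs$channel_labels %in% epochs$frontal_channels
  with_seed(derive_seed(seed, 303L), {
    loading <- stats::rnorm(n_chan, sd = 0.05)
    loading[frontal] <- 1 + abs(stats::rnorm(sum(frontal), sd = 0.2))
    loading <- loading / sqrt(sum(loading^2))
    t_ms <- epochs$time_ms
    blink_trials <- vector("list", length(epochs$subjects))
    for (s in seq_along(epochs$subjects)) {
      d <- dim(epochs$subjects[[s]])
      hit <- matrix(stats::runif(d[1] * d[2]) < prop_trials, d[1], d[2])
      blink_trials[[s]] <- hit
      for (cc in seq_len(d[1])) {
        for (tr in seq_len(d[2])) {
          if (!hit[cc, tr]) next
          center <- stats::runif(1, min(t_ms) + 50, max(t_ms) - 50)
          bump <- amplitude * exp(-((t_ms - center)^2) / (2 * 25^2))
          epochs$subjects[[s]][cc, tr, , ] <-
            epochs$subjects[[s]][cc, tr, , ] + outer(loading, bump)
        }
      }
    }
    list(epochs = epochs, loading = loading, blink_trials = blink_trials)
  })
}

#' Write stimulus images as 8-bit grayscale PNG files
#'
#' @param stimuli List of matrices in \[0, 1\] from [generate_stimuli()].
#' @param dir Output directory (created if missing).
#' @return Invisibly, the written file paths (`stimulus_001.png`, ...).
#' @export
write_stimuli_png <- function(stimuli, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  paths <- vapply(seq_along(stimuli), function(i) {
    p <- file.path(dir, sprintf("stimulus_%03d.png", i))
    png::writePNG(stimuli[[i]], p)
    p
  }, character(1))
  invisible(paths)
}
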