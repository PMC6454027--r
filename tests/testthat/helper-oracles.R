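# Independent oracles used to freeze expected values; these never call the
# implementation paths they check.

# Direct 2D inner-product Haar coefficients for dyadic (power-of-two sided)
# images: level-j basis functions are translated/dilated step and box
# functions, evaluated by explicit summation over each 2^j x 2^j block.
haar_oracle_level <- function(image, level) {
  blk <- 2L^level
  phi <- rep(1, blk) / sqrt(blk)
  psi <- c(rep(1, blk / 2L), rep(-1, blk / 2L)) / sqrt(blk)
  n_out <- nrow(image) / blk
  m_out <- ncol(image) / blk
  coef <- function(row_f, col_f) {
    out <- matrix(0, n_out, m_out)
    for (m in seq_len(n_out)) {
      for (n in seq_len(m_out)) {
        rows <- ((m - 1L) * blk + 1L):(m * blk)
        cols <- ((n - 1L) * blk + 1L):(n * blk)
        out[m, n] <- sum(image[rows, cols] * outer(row_f, col_f))
      }
    }
    out
  }
  list(
    A = coef(phi, phi), H = coef(psi, phi),
    V = coef(phi, psi), D = coef(psi, psi)
  )
}

# Exact two-sided sign-flip p-value by enumeration of all 2^n sign vectors
# at a single timepoint (n <= 16).
exhaustive_sign_p <- function(x) {
  n <- length(x)
  obs <- abs(mean(x))
  signs <- as.matrix(expand.grid(rep(list(c(-1, 1)), n)))
  stat <- abs(signs %*% x / n)
  mean(stat >= obs - 1e-12)
}

# Small synthetic epoch fixture shared across decoding tests: geometry from
# a Euclidean RDM of random points, normalized to mean off-diagonal 1.
fixture_epochs <- function(n_subjects = 2, n_conditions = 6, n_trials = 8,
                           n_channels = 16, window_ms = c(-100, 300),
                           step_ms = 10, peak_ms = 120, width_ms = 60,
                           noise_sd = 0.5, seed = 42L, rdm = NULL) {
  if (is.null(rdm)) {
    pts <- wavemeg:::with_seed(seed + 7L, matrix(rnorm(n_conditions * 3), n_conditions))
    rdm <- as.matrix(dist(pts))
    rdm <- rdm / mean(rdm[upper.tri(rdm)])
  }
  gt <- ground_truth(rdm, peak_ms, width_ms, noise_sd, seed = seed)
  ep <- generate_epochs(
    gt, n_subjects, n_conditions, n_trials, n_channels,
    window_ms, step_ms
  )
  ep
}

# A centered point configuration with (numerically) equal norms — a
# "spherical" representational geometry — built by alternating centering
# and norm-equalization. For such geometries the correlation distance of
# the embedded patterns is an exactly monotone function of the Euclidean
# distances, so the injected RDM is recoverable in rank terms.
spherical_config <- function(n_cond, p, seed) {
  x <- wavemeg:::with_seed(seed, matrix(rnorm(n_cond * p), n_cond, p))
  for (i in 1:200) {
    x <- sweep(x, 2, colMeans(x))
    x <- x / sqrt(rowSums(x^2))
  }
  x
}

# Normalized 1-Pearson model RDM with zeroed diagonal, ready for injection.
injectable_rdm <- function(vectors) {
  d <- model_rdm(vectors)
  diag(d) <- 0
  d / mean(d[upper.tri(d)])
}
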