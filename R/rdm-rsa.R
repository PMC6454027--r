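# Model (descriptor) RDM construction and representational similarity
# analysis: Spearman comparison of model vs neural RDMs per timepoint.

#' 1 - Pearson model RDM from descriptor vectors
#'
#' Cell (i, j) is one minus the Pearson correlation between the descriptor
#' vectors of stimuli i and j, giving dissimilarities in \[0, 2\] with an
#' undefined (NA) diagonal. A zero-variance descriptor vector makes its
#' cells NA with a warning.
#'
#' @param vectors n_stimuli x length matrix: row i is stimulus i's
#'   descriptor vector (e.g. one element of
#'   `build_descriptors(...)$vectors`).
#' @return n x n symmetric dissimilarity matrix, diagonal `NA`.
#' @export
model_rdm <- function(vectors) {
  if (!is.matrix(vectors)) vectors <- as.matrix(vectors)
  if (nrow(vectors) < 2L) stopf("need at least 2 stimuli")
  if (ncol(vectors) < 2L) stopf("descriptor vectors must have length >= 2")
  sds <- apply(vectors, 1, stats::sd)
  if (any(sds == 0)) {
    warnf("%d descriptor vector(s) have zero variance; their cells are NA", sum(sds == 0))
  }
  r <- suppressWarnings(stats::cor(t(vectors)))
  d <- 1 - r
  diag(d) <- NA_real_
  d
}

#' Spearman correlation between two RDMs
#'
#' Rank correlation over the vectorized strict upper triangles of two
#' same-shaped symmetric RDMs, excluding cells missing in either matrix;
#' ties receive average ranks.
#'
#' @param a,b Square symmetric matrices of equal dimension.
#' @return Spearman's rho in \[-1, 1\] (NA, with a warning, if either
#'   triangle is constant).
#' @export
rdm_spearman <- function(a, b) {
  if (!all(dim(a) == dim(b))) stopf("RDMs must have identical dimensions")
  va <- upper_vec(a)
  vb <- upper_vec(b)
  ok <- is.finite(va) & is.finite(vb)
  if (sum(ok) < 3L) stopf("fewer than 3 usable cell pairs")
  if (stats::sd(va[ok]) == 0 || stats::sd(vb[ok]) == 0) {
    warnf("RDM upper triangle is constant; Spearman correlation undefined")
    return(NA_real_)
  }
  stats::cor(va[ok], vb[ok], method = "spearman")
}

#' RSA time-course: model RDM vs neural RDM series
#'
#' Computes the Spearman correlation between a model RDM and each
#' subject's neural decoding RDM at every timepoint, plus the grand
#' average over subjects (averaged on the correlation scale).
#'
#' @param neural An `rdm_series` from [decoding_rdm_series()].
#' @param model A model RDM with the same condition set.
#' @return Object of class `rsa_timecourse`: list with `rho`
#'   (subject x time matrix), `grand` (mean over subjects), `time_ms`.
#' @export
rsa_timecourse <- function(neural, model) {
  stopifnot(inherits(neural, "rdm_series"))
  n_cond <- dim(neural$subjects[[1L]])[2L]
  if (!all(dim(model) == n_cond)) {
    stopf(
      "condition mismatch: model RDM is %dx%d, neural RDMs are %dx%d",
      nrow(model), ncol(model), n_cond, n_cond
    )
  }
  n_time <- length(neural$time_ms)
  rho <- matrix(NA_real_, length(neural$subjects), n_time)
  for (s in seq_along(neural$subjects)) {
    arr <- neural$subjects[[s]]
    for (t in seq_len(n_time)) {
      rho[s, t] <- rdm_spearman(arr[t, , ], model)
    }
  }
  structure(
    list(rho = rho, grand = colMeans(rho), time_ms = neural$time_ms),
    class = "rsa_timecourse"
  )
}

#' @export
print.rsa_timecourse <- function(x, ...) {
  pk <- which.max(x$grand)
  cat(sprintf(
    "<rsa_timecourse> %d subjects x %d timepoints; grand peak rho = %.3f at %g ms\n",
    nrow(x$rho), ncol(x$rho), x$grand[pk], x$time_ms[pk]
  ))
  invisible(x)
}
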