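# Time-resolved pairwise decoding of conditions from MEG pattern vectors.
# Raw trials are averaged into pseudo-trials (random groups) to raise SNR,
# then a linear soft-margin SVM is cross-validated across pseudo-trials at
# every timepoint, with the whole permute-average-crossvalidate cycle
# repeated n_reps times.

# Resolve the effective group size under the shortfall policy: with fewer
# than K * group_size usable trials, groups shrink to floor(n / K), never
# below 1; with fewer than K trials the condition cannot be decoded.
effective_group_size <- function(n_trials, K, group_size) {
  if (n_trials < K) {
    return(0L)
  }
  min(group_size, max(1L, floor(n_trials / K)))
}

#' Average raw trials into K pseudo-trials per condition
#'
#' Randomly partitions the (valid) raw trials of one condition into `K`
#' disjoint groups of `group_size` and averages within groups. With fewer
#' than `K * group_size` trials, the group size shrinks to
#' `floor(n / K)` (minimum 1); with fewer than `K` trials the condition
#' is excluded (returns `NULL` with a warning).
#'
#' @param trials Array of raw trials: trial x channel x time (or a
#'   trial x feature matrix, treated as a single timepoint).
#' @param K Number of pseudo-trials to form (default 4).
#' @param group_size Raw trials averaged per pseudo-trial (default 10).
#' @param seed Integer seed for the random partition.
#' @return List with `pseudo` (K x channel x time array), and `provenance`
#'   (list of raw-trial index vectors, disjoint).
#' @export
make_pseudotrials <- function(trials, K = 4L, group_size = 10L, seed = 1L) {
  if (is.matrix(trials)) {
    trials <- array(trials, dim = c(dim(trials), 1L))
  }
  n <- dim(trials)[1L]
  gs <- effective_group_size(n, K, group_size)
  if (gs == 0L) {
    warnf("only %d trials available for K = %d pseudo-trials; condition excluded", n, K)
    return(NULL)
  }
  perm <- with_seed(seed, sample.int(n))
  groups <- split(perm[seq_len(K * gs)], rep(seq_len(K), each = gs))
  pseudo <- array(0, dim = c(K, dim(trials)[2L], dim(trials)[3L]))
  for (k in seq_len(K)) {
    pseudo[k, , ] <- colMeans(trials[groups[[k]], , , drop = FALSE], dims = 1L)
  }
  list(pseudo = pseudo, provenance = unname(groups), group_size = gs, K = K)
}

# Leave-one-pseudo-trial-out accuracy of a linear SVM for one condition
# pair across all timepoints. pa, pb: K x channel x time arrays.
pair_fold_accuracy <- function(pa, pb, cost = 1) {
  K <- dim(pa)[1L]
  n_time <- dim(pa)[3L]
  acc <- numeric(n_time)
  lab <- factor(rep(c("a", "b"), each = K - 1L))
  for (t in seq_len(n_time)) {
    at <- pa[, , t, drop = TRUE]
    bt <- pb[, , t, drop = TRUE]
    if (is.null(dim(at))) {
      at <- matrix(at, nrow = K)
      bt <- matrix(bt, nrow = K)
    }
    hits <- 0
    for (k in seq_len(K)) {
      train <- rbind(at[-k, , drop = FALSE], bt[-k, , drop = FALSE])
      test <- rbind(at[k, ], bt[k, ])
      pred <- tryCatch(
        {
          fit <- e1071::svm(train, lab,
            kernel = "linear", cost = cost,
            scale = FALSE
          )
          as.character(stats::predict(fit, test))
        },
        error = function(e) c("a", "b")[c(1, 1)] # degenerate: one hit, one miss
      )
      hits <- hits + (pred[1] == "a") + (pred[2] == "b")
    }
    acc[t] <- hits / (2 * K)
  }
  acc
}

#' Pairwise decoding accuracy at a single timepoint
#'
#' Estimates how well a linear soft-margin SVM discriminates two
#' conditions from their raw trial patterns at one timepoint. Each
#' repetition draws a fresh random partition into pseudo-trials
#' ([make_pseudotrials()]), trains on K-1 pseudo-trials per condition and
#' tests on the held-out pair, over all K folds; the returned accuracy is
#' the mean over folds and repetitions.
#'
#' @param pa,pb Trial x feature matrices of raw trials for the two
#'   conditions (same feature dimension). Passing exactly `K` trials per
#'   condition reduces to leave-one-pattern-out over those patterns.
#' @param n_reps Repetitions of the permute-average-crossvalidate cycle
#'   (default 100).
#' @param seed Integer seed.
#' @param K Pseudo-trials per condition (default 4).
#' @param group_size Raw trials per pseudo-trial (default
#'   `floor(n / K)`).
#' @param cost Soft-margin regularization constant C (default 1).
#' @return Accuracy in \[0, 1\].
#' @export
decode_pair_timepoint <- function(pa, pb, n_reps = 100L, seed = 1L, K = 4L,
                                  group_size = NULL, cost = 1) {
  if (ncol(pa) != ncol(pb)) stopf("pa and pb must have the same feature dimension")
  if (K < 2L) stopf("K must be >= 2")
  if (is.null(group_size)) {
    group_size <- max(1L, floor(min(nrow(pa), nrow(pb)) / K))
  }
  accs <- numeric(n_reps)
  for (r in seq_len(n_reps)) {
    # one partition stream per repetition, shared by both conditions: the
    # index permutation carries no condition information, and identical
    # inputs then yield identical pseudo-trials (exact 0.5 tie-break)
    psa <- make_pseudotrials(pa, K, group_size, seed = derive_seed(seed, r))
    psb <- make_pseudotrials(pb, K, group_size, seed = derive_seed(seed, r))
    if (is.null(psa) || is.null(psb)) stopf("not enough trials for K = %d folds", K)
    accs[r] <- pair_fold_accuracy(psa$pseudo, psb$pseudo, cost = cost)
  }
  mean(accs)
}

#' Time-resolved pairwise decoding RDM series
#'
#' For every subject, unordered condition pair and timepoint, computes the
#' cross-validated pairwise SVM decoding accuracy and stores it
#' symmetrically in a condition x condition RDM per timepoint (diagonal
#' `NA`). Only valid (non-rejected) trials enter; a condition with fewer
#' than `K` valid trials is excluded (its rows/columns stay `NA`, with a
#' warning). Each (subject, pair) work unit uses its own derived seed, so
#' results are identical regardless of execution order.
#'
#' @param epochs A preprocessed `epoch_set`.
#' @param K,group_size,n_reps,cost Decoding parameters; see
#'   [decode_pair_timepoint()]. Defaults K = 4 groups of 10 trials, 100
#'   repetitions, C = 1.
#' @param seed Integer root seed.
#' @return Object of class `rdm_series`: list with `subjects` (one
#'   time x condition x condition accuracy array per subject), `time_ms`,
#'   and `params`.
#' @export
decoding_rdm_series <- function(epochs, K = 4L, group_size = 10L,
                                n_reps = 100L, cost = 1, seed = 1L) {
  stopifnot(inherits(epochs, "epoch_set"))
  n_cond <- dim(epochs$subjects[[1L]])[1L]
  n_time <- length(epochs$time_ms)
  out <- vector("list", length(epochs$subjects))
  for (s in seq_along(epochs$subjects)) {
    arr <- epochs$subjects[[s]]
    rdm <- array(NA_real_, dim = c(n_time, n_cond, n_cond))
    usable <- vapply(seq_len(n_cond), function(cc) {
      sum(epochs$valid[[s]][cc, ]) >= K
    }, logical(1))
    if (!all(usable)) {
      warnf(
        "subject %d: excluding %d condition(s) with fewer than K = %d valid trials",
        s, sum(!usable), K
      )
    }
    for (i in seq_len(n_cond - 1L)) {
      for (j in seq((i + 1L), n_cond)) {
        if (!usable[i] || !usable[j]) next
        ta <- arr[i, epochs$valid[[s]][i, ], , , drop = FALSE]
        tb <- arr[j, epochs$valid[[s]][j, ], , , drop = FALSE]
        ta <- array(ta, dim = dim(ta)[2:4])
        tb <- array(tb, dim = dim(tb)[2:4])
        gs <- min(
          effective_group_size(dim(ta)[1L], K, group_size),
          effective_group_size(dim(tb)[1L], K, group_size)
        )
        pair_seed <- derive_seed(seed, s, i * n_cond + j)
        acc_t <- numeric(n_time)
        for (r in seq_len(n_reps)) {
          psa <- make_pseudotrials(ta, K, gs, seed = derive_seed(pair_seed, r))
          psb <- make_pseudotrials(tb, K, gs, seed = derive_seed(pair_seed, r))
          acc_t <- acc_t + pair_fold_accuracy(psa$pseudo, psb$pseudo, cost = cost)
        }
        rdm[, i, j] <- rdm[, j, i] <- acc_t / n_reps
      }
    }
    out[[s]] <- rdm
  }
  structure(
    list(
      subjects = out, time_ms = epochs$time_ms,
      params = list(K = K, group_size = group_size, n_reps = n_reps, cost = cost, seed = seed)
    ),
    class = "rdm_series"
  )
}

#' @export
print.rdm_series <- function(x, ...) {
  d <- dim(x$subjects[[1L]])
  cat(sprintf(
    "<rdm_series> %d subjects, %d timepoints, %d x %d conditions\n",
    length(x$subjects), d[1], d[2], d[3]
  ))
  invisible(x)
}

#' Grand-average decoding accuracy time-course
#'
#' Mean decoding accuracy over all condition pairs and subjects at each
#' timepoint.
#'
#' @param series An `rdm_series`.
#' @return Numeric vector, one value per timepoint.
#' @export
grand_average_accuracy <- function(series) {
  stopifnot(inherits(series, "rdm_series"))
  per_subj <- vapply(series$subjects, function(a) {
    apply(a, 1, function(m) mean(m[upper.tri(m)], na.rm = TRUE))
  }, numeric(dim(series$subjects[[1L]])[1L]))
  rowMeans(as.matrix(per_subj))
}
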