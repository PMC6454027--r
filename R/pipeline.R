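# Stage orchestration: configuration with the study's canonical defaults,
# deterministic end-to-end runs on synthetic data, and CSV/JSON reporting.

#' Pipeline configuration with canonical defaults
#'
#' Collects every tunable of the pipeline in one validated list. Defaults
#' follow the study design the package models: 5 wavelet levels, K = 4
#' pseudo-trial groups of 10 trials, 100 decoding repetitions, 1,000
#' permutations and bootstrap draws, cluster-defining threshold and
#' corrected alpha of 0.05, 5% outlier trimming, and a 150 ms latency
#' cutoff. The synthetic block sets the generated study conditions.
#'
#' @param levels Wavelet decomposition levels.
#' @param K,group_size,n_reps,cost Decoding parameters.
#' @param n_perm,n_boot,cdt,alpha,trim_pct,peak_window_ms,latency_cutoff_ms
#'   Statistics parameters.
#' @param n_subjects,n_conditions,n_trials,n_channels,window_ms,step_ms
#'   Synthetic design sizes (fixture scale: 8 subjects, 12 conditions, 12
#'   trials, 32 channels, window (-100, 400) ms; the full-scale
#'   16/92/40/306 design over (-150, 1000) ms remains configurable).
#' @param lowpass_hz Preprocessing low-pass cutoff in Hz (default 30);
#'   must stay below the Nyquist frequency implied by `step_ms`.
#' @param stimulus_size Generated image side length in pixels.
#' @param signal_peak_ms,signal_width_ms,noise_sd Injected signal shape.
#' @param seed Root seed; every stage derives its own substream.
#' @return A list of class `pipeline_config`.
#' @export
pipeline_config <- function(levels = 5L, K = 4L, group_size = 10L,
                            n_reps = 100L, cost = 1,
                            n_perm = 1000L, n_boot = 1000L, cdt = 0.05,
                            alpha = 0.05, trim_pct = 5,
                            peak_window_ms = c(0, 600),
                            latency_cutoff_ms = 150,
                            n_subjects = 8L, n_conditions = 12L,
                            n_trials = 12L, n_channels = 32L,
                            window_ms = c(-100, 400), step_ms = 1,
                            lowpass_hz = 30, stimulus_size = 175L,
                            signal_peak_ms = 120, signal_width_ms = 80,
                            noise_sd = 1, seed = 1L) {
  cfg <- as.list(environment())
  stopifnot(
    is_count(cfg$levels), is_count(cfg$K, 2L), is_count(cfg$n_reps),
    is_count(cfg$n_subjects, 2L), is_count(cfg$n_conditions, 2L),
    cfg$cdt > 0, cfg$cdt < 1, cfg$alpha > 0, cfg$alpha < 1,
    cfg$noise_sd > 0
  )
  structure(cfg, class = "pipeline_config")
}

#' Run the synthetic end-to-end pipeline
#'
#' Executes the full chain on generated data: stimuli with mixed
#' orientation profiles; wavelet descriptor extraction; epoch simulation
#' whose representational geometry is the level-1 "All details" model RDM
#' of those stimuli; preprocessing; per-timepoint pairwise-SVM decoding
#' RDMs; RSA time-courses for every descriptor; sign-permutation cluster
#' statistics and bootstrap peak latencies; and a report written as one
#' time-course CSV plus one stat JSON per descriptor, a counts CSV and a
#' run manifest. Identical configurations reproduce byte-identical
#' outputs.
#'
#' @param config A [pipeline_config()].
#' @param out_dir Output directory (created if missing).
#' @param descriptors Character vector of descriptor ids to analyse
#'   (default: all `5 * levels`).
#' @param write_stimuli Also write the generated stimuli as PNGs.
#' @return Invisibly, a list with the in-memory stage results:
#'   `stimuli`, `descriptor_set`, `epochs`, `rdm_series`, `rsa` (named
#'   list of `rsa_timecourse`), `stats` (named list: p-values, mask,
#'   peak), `counts`, and `files`.
#' @export
run_pipeline <- function(config = pipeline_config(), out_dir = tempfile("wavemeg"),
                         descriptors = NULL, write_stimuli = FALSE) {
  stopifnot(inherits(config, "pipeline_config"))
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)

  # --- simulate stimuli ------------------------------------------------
  profiles <- lapply(seq_len(config$n_conditions), function(k) {
    w <- c(2, 1, 1, 2, 1, 2)[(k - 1L) %% 6L + 1L]
    orientation_profile(
      horizontal = w,
      vertical = c(1, 2, 1, 2, 2, 1)[(k - 1L) %% 6L + 1L],
      diagonal = c(1, 1, 2, 1, 2, 2)[(k - 1L) %% 6L + 1L]
    )
  })
  stimuli <- generate_stimuli(
    config$n_conditions, config$stimulus_size, profiles,
    seed = derive_seed(config$seed, 1L)
  )

  # --- descriptors -----------------------------------------------------
  dset <- build_descriptors(stimuli, levels = config$levels)
  if (is.null(descriptors)) descriptors <- dset$manifest$id

  # --- simulate epochs driven by the level-1 ALL-details geometry ------
  all1 <- dset$manifest$id[dset$manifest$level == 1L & dset$manifest$band == "ALL"]
  target_rdm <- model_rdm(dset$vectors[[all1]])
  tr <- target_rdm
  diag(tr) <- 0
  truth <- ground_truth(
    model_rdm = tr, signal_peak_ms = config$signal_peak_ms,
    signal_width_ms = config$signal_width_ms, noise_sd = config$noise_sd,
    seed = derive_seed(config$seed, 2L)
  )
  epochs <- generate_epochs(
    truth, config$n_subjects, config$n_conditions, config$n_trials,
    config$n_channels, config$window_ms, config$step_ms
  )

  # --- preprocess + decode ---------------------------------------------
  epochs <- preprocess_epochs(epochs, cutoff_hz = config$lowpass_hz)
  series <- decoding_rdm_series(
    epochs,
    K = config$K, group_size = config$group_size,
    n_reps = config$n_reps, cost = config$cost,
    seed = derive_seed(config$seed, 3L)
  )

  # --- rsa + stats + report --------------------------------------------
  files <- character(0)
  rsa_out <- list()
  stat_out <- list()
  masks <- list()
  for (id in descriptors) {
    tc <- rsa_timecourse(series, model_rdm(dset$vectors[[id]]))
    rsa_out[[id]] <- tc
    stat_seed <- derive_seed(config$seed, 4L, match(id, dset$manifest$id))
    p <- sign_permutation_test(tc$rho, n_perm = config$n_perm, seed = stat_seed)
    mask <- cluster_correct(p, tc$rho,
      cdt = config$cdt, alpha = config$alpha,
      n_perm = config$n_perm, seed = stat_seed
    )
    masks[[id]] <- mask
    peak <- bootstrap_latency(tc$rho, tc$time_ms,
      window_ms = config$peak_window_ms,
      n_boot = config$n_boot, kind = "peak",
      seed = stat_seed
    )
    stat_out[[id]] <- list(p_values = p, mask = mask, peak = peak)

    tc_df <- data.frame(time_ms = tc$time_ms, t(tc$rho), grand_mean = tc$grand)
    names(tc_df) <- c(
      "time_ms", paste0("subject_", seq_len(nrow(tc$rho))),
      "grand_mean"
    )
    f_csv <- file.path(out_dir, sprintf("timecourse_%s.csv", id))
    utils::write.csv(tc_df, f_csv, row.names = FALSE)
    f_json <- file.path(out_dir, sprintf("stats_%s.json", id))
    jsonlite::write_json(
      list(
        descriptor = id,
        clusters = mask$clusters,
        n_significant = sum(mask$mask),
        crit_size = mask$crit_size,
        peak_latency_ms = peak$estimate_ms,
        peak_ci95_ms = peak$ci95_ms,
        mean_peak_ms = peak$boot_mean_ms,
        sem_ms = peak$sem_ms
      ),
      f_json,
      auto_unbox = TRUE, digits = NA
    )
    files <- c(files, f_csv, f_json)
  }
  cnt <- count_significant(masks, manifest = dset$manifest)
  f_counts <- file.path(out_dir, "significant_counts.csv")
  utils::write.csv(cnt$table, f_counts, row.names = FALSE)
  f_manifest <- file.path(out_dir, "manifest.json")
  jsonlite::write_json(
    list(config = unclass(config), descriptors = descriptors),
    f_manifest,
    auto_unbox = TRUE, digits = NA
  )
  files <- c(files, f_counts, f_manifest)
  if (write_stimuli) {
    files <- c(files, write_stimuli_png(stimuli, file.path(out_dir, "stimuli")))
  }
  invisible(list(
    stimuli = stimuli, descriptor_set = dset, epochs = epochs,
    rdm_series = series, rsa = rsa_out, stats = stat_out,
    counts = cnt, files = files, out_dir = out_dir
  ))
}
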