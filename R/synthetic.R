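## Ground-truth synthetic cohorts: subjects x extinction blocks of simulated
## two-region ERP data whose extrinsic connection strengths covary with
## block number and freezing behaviour, for end-to-end validation of the
## inversion / model-selection / second-level pipeline.

.directions <- c("mcn_to_vlpag", "vlpag_to_mcn")

.per_direction <- function(x, what) {
  x <- unlist(x)   # accept JSON-parsed lists
  if (length(x) == 1L && is.null(names(x))) x <- rep(x, 2)
  if (is.null(names(x))) names(x) <- .directions
  bad <- setdiff(names(x), .directions)
  if (length(bad) || length(x) != 2L)
    stop(what, " must be a scalar or a length-2 vector named ",
         paste(.directions, collapse = ", "))
  x[.directions]
}

#' Cohort configuration
#'
#' Describes the simulated study: cohort size (defaults mirror a 6-subject,
#' 5-block, 7-trials-per-block extinction session), the linear model that
#' generates each subject-by-block latent log coupling strength, the freezing
#' trajectory, and the trial noise level.
#'
#' The latent log strength of direction `d` for subject `s`, block `b` is
#' `effect_mean_d + effect_trial_d (b - mean(b)) +
#'  effect_freeze_d (freeze_sb - mean(freeze)) + offset_sd`,
#' with `offset_sd ~ N(0, subject_sd^2)`.
#'
#' @param n_subjects,n_blocks,trials_per_block Cohort dimensions
#'   (defaults 6, 5, 7).
#' @param native_rate Native sampling rate in Hz (default 30000); only used
#'   when continuous recordings are synthesized.
#' @param effect_mean Baseline latent log strength per direction (scalar or
#'   named length-2 vector).
#' @param effect_trial Slope of latent log strength per block (centred).
#'   Default -0.4 on the MCN -> vlPAG direction, 0 on the return direction.
#' @param effect_freeze Slope of latent log strength per freezing percentage
#'   point (centred). Default -0.05 on MCN -> vlPAG, 0 on the return
#'   direction.
#' @param subject_sd Between-subject SD of the latent log strength
#'   (default 0.1).
#' @param noise_snr_db Trial-level signal-to-noise ratio in dB (default 10);
#'   `Inf` gives noiseless trials.
#' @param freeze_start,freeze_end,freeze_noise_sd Freezing trajectory:
#'   per-subject linear decline from `freeze_start` to `freeze_end` percent
#'   with additive Gaussian block noise, clipped to `[0, 100]`.
#' @param freeze_subject_sd Between-subject SD of each subject's own start
#'   and end freezing levels (animals extinguish at different rates);
#'   default 10 percentage points.
#' @param seed Integer seed for the generator.
#' @return An object of class `cohort_config`.
#' @export
cohort_config <- function(n_subjects = 6, n_blocks = 5, trials_per_block = 7,
                          native_rate = 30000,
                          effect_mean = 0,
                          effect_trial = c(mcn_to_vlpag = -0.4,
                                           vlpag_to_mcn = 0),
                          effect_freeze = c(mcn_to_vlpag = -0.05,
                                            vlpag_to_mcn = 0),
                          subject_sd = 0.1,
                          noise_snr_db = 10,
                          freeze_start = 80, freeze_end = 10,
                          freeze_noise_sd = 10, freeze_subject_sd = 10,
                          seed = 1L) {
  stopifnot(n_subjects >= 1, n_blocks >= 1, trials_per_block >= 1,
            native_rate > 2 * 32, subject_sd >= 0,
            is.finite(noise_snr_db) || is.infinite(noise_snr_db))
  structure(list(
    n_subjects = as.integer(n_subjects), n_blocks = as.integer(n_blocks),
    trials_per_block = as.integer(trials_per_block),
    native_rate = native_rate,
    effect_mean = .per_direction(effect_mean, "effect_mean"),
    effect_trial = .per_direction(effect_trial, "effect_trial"),
    effect_freeze = .per_direction(effect_freeze, "effect_freeze"),
    subject_sd = subject_sd, noise_snr_db = noise_snr_db,
    freeze_start = freeze_start, freeze_end = freeze_end,
    freeze_noise_sd = freeze_noise_sd, freeze_subject_sd = freeze_subject_sd,
    seed = as.integer(seed)
  ), class = "cohort_config")
}

#' Per-block freezing trajectory
#'
#' A monotone-decreasing mean trajectory (linear from `start_pct` to
#' `end_pct` across blocks) with additive Gaussian noise, clipped to
#' `[0, 100]` percent.
#'
#' @param n_blocks Number of extinction blocks.
#' @param start_pct,end_pct First and last block mean freezing (%);
#'   `0 <= end_pct <= start_pct <= 100` required.
#' @param noise_sd Additive Gaussian noise SD (%).
#' @param seed Optional integer seed; `NULL` uses the current RNG state.
#' @return Numeric vector of per-block freezing percentages.
#' @export
freezing_trajectory <- function(n_blocks, start_pct, end_pct, noise_sd = 0,
                                seed = NULL) {
  if (!(end_pct <= start_pct && start_pct <= 100 && end_pct >= 0))
    stop("freezing bounds must satisfy 0 <= end_pct <= start_pct <= 100")
  stopifnot(n_blocks >= 1, noise_sd >= 0)
  if (!is.null(seed)) set.seed(seed)
  mean_traj <- if (n_blocks == 1) start_pct else
    seq(start_pct, end_pct, length.out = n_blocks)
  pmin(pmax(mean_traj + stats::rnorm(n_blocks, 0, noise_sd), 0), 100)
}

#' Add trial noise to a noiseless ERP
#'
#' Generates `n` noisy copies of an [erp_pair()] at a per-channel SNR: each
#' channel receives i.i.d. Gaussian noise with SD
#' `rms(channel) * 10^(-snr_db / 20)`. An optional AR(1) coefficient lends
#' the noise temporal structure (variance is held at the target level).
#'
#' @param erp Noiseless [erp_pair()].
#' @param n Number of trials.
#' @param snr_db Signal-to-noise ratio in dB; `Inf` returns exact copies.
#' @param ar1 AR(1) coefficient of the noise in `[0, 1)`, default 0.
#' @return A 3-d array `(region, time, trial)`.
#' @export
make_noisy_trials <- function(erp, n, snr_db, ar1 = 0) {
  stopifnot(inherits(erp, "erp_pair"), n >= 1, ar1 >= 0, ar1 < 1)
  amp <- erp$amplitude
  nt <- ncol(amp)
  out <- array(rep(amp, n), dim = c(2, nt, n),
               dimnames = list(rownames(amp), NULL, NULL))
  if (is.infinite(snr_db)) return(out)
  sd_ch <- sqrt(rowMeans(amp^2)) * 10^(-snr_db / 20)
  for (k in seq_len(n)) {
    eps <- matrix(stats::rnorm(2 * nt), 2, nt) * sd_ch
    if (ar1 > 0) {
      eps <- t(apply(eps, 1, function(e) stats::filter(e, ar1, "recursive")))
      eps <- eps * sqrt(1 - ar1^2) / 1  # restore marginal variance
    }
    out[, , k] <- out[, , k] + eps
  }
  out
}

#' Generate a ground-truth cohort
#'
#' Simulates, for every subject and extinction block, the noiseless ERP pair
#' of the supplied model variant at that cell's latent extrinsic strengths,
#' adds `trials_per_block` noisy trials at the configured SNR, and averages
#' them into the observed ERP. The covariate table (subject, block,
#' freezing %) and the full ground truth are returned alongside the data.
#'
#' @param config A [cohort_config()].
#' @param variant The generating [model_variant()] (default: M1 of
#'   [build_model_space()]); must expose both extrinsic directions unless all
#'   injected effects are zero.
#' @param grid,input Forward-model settings.
#' @param keep_trials Logical; retain the single-trial arrays (default
#'   `FALSE`, only the trial average and the noiseless ERP are kept).
#' @return An object of class `cohort_dataset` with elements `config`,
#'   `covariates` (data frame), `truth` (data frame with the generating
#'   latent strengths), `erps` and `noiseless` (lists indexed
#'   `subject_block`), and optionally `trials`.
#' @export
generate_cohort <- function(config = cohort_config(),
                            variant = build_model_space()$M1,
                            grid = simulation_grid(), input = input_spec(),
                            keep_trials = FALSE) {
  stopifnot(inherits(config, "cohort_config"),
            inherits(variant, "model_variant"))
  pp <- pack_parameters(variant)
  a_names <- c(mcn_to_vlpag = "A_MCN_to_vlPAG", vlpag_to_mcn = "A_vlPAG_to_MCN")
  have <- stats::setNames(a_names %in% pp$name, names(a_names))
  inject <- abs(config$effect_mean) + abs(config$effect_trial) +
    abs(config$effect_freeze) + config$subject_sd
  if (any(!have & inject > 0))
    stop("variant ", variant$id,
         " has no free extrinsic parameter for an injected direction")

  set.seed(config$seed)
  ns <- config$n_subjects; nb <- config$n_blocks
  freeze <- t(vapply(seq_len(ns), function(s) {
    start_s <- min(max(config$freeze_start +
                         stats::rnorm(1, 0, config$freeze_subject_sd), 0), 100)
    end_s <- min(max(config$freeze_end +
                       stats::rnorm(1, 0, config$freeze_subject_sd), 0), start_s)
    freezing_trajectory(nb, start_s, end_s, config$freeze_noise_sd)
  }, numeric(nb)))
  offsets <- matrix(stats::rnorm(ns * 2, 0, config$subject_sd), ns, 2,
                    dimnames = list(NULL, .directions))
  block_c <- seq_len(nb) - mean(seq_len(nb))
  freeze_c <- freeze - mean(freeze)

  cov_tab <- data.frame(
    subject = rep(seq_len(ns), each = nb),
    block = rep(seq_len(nb), ns),
    freezing_pct = as.vector(t(freeze))
  )
  theta_tab <- cov_tab
  for (d in .directions) {
    theta_tab[[paste0("theta_", d)]] <-
      config$effect_mean[[d]] +
      config$effect_trial[[d]] * block_c[cov_tab$block] +
      config$effect_freeze[[d]] * as.vector(t(freeze_c)) +
      offsets[cov_tab$subject, d]
  }

  cm <- .compile_variant(variant, grid, input)
  erps <- noiseless <- vector("list", nrow(cov_tab))
  trials <- if (keep_trials) vector("list", nrow(cov_tab)) else NULL
  keys <- sprintf("s%02d_b%02d", cov_tab$subject, cov_tab$block)
  for (i in seq_len(nrow(cov_tab))) {
    theta <- numeric(0)
    for (d in .directions)
      if (have[[d]])
        theta[a_names[[d]]] <- theta_tab[[paste0("theta_", d)]][i]
    y <- tryCatch(.sim_compiled(cm, theta), error = function(e)
      stop("generation failed for subject ", cov_tab$subject[i], ", block ",
           cov_tab$block[i], " (theta = ",
           paste(sprintf("%.3f", theta), collapse = ", "), "): ",
           conditionMessage(e)))
    if (any(!is.finite(y)))
      stop("non-finite simulated waveform for subject ", cov_tab$subject[i],
           ", block ", cov_tab$block[i], " (theta = ",
           paste(sprintf("%.3f", theta), collapse = ", "), ")")
    clean <- erp_pair(grid$time_ms, y)
    tr <- make_noisy_trials(clean, config$trials_per_block,
                            config$noise_snr_db)
    avg <- apply(tr, c(1, 2), mean)
    rownames(avg) <- rownames(y)
    erps[[i]] <- erp_pair(grid$time_ms, avg,
                          n_trials = config$trials_per_block,
                          meta = list(subject = cov_tab$subject[i],
                                      block = cov_tab$block[i]))
    noiseless[[i]] <- clean
    if (keep_trials) trials[[i]] <- tr
  }
  names(erps) <- names(noiseless) <- keys
  if (keep_trials) names(trials) <- keys
  structure(list(config = config, covariates = cov_tab, truth = theta_tab,
                 erps = erps, noiseless = noiseless, trials = trials,
                 variant_id = variant$id),
            class = "cohort_dataset")
}

#' @export
print.cohort_dataset <- function(x, ...) {
  cat(sprintf("<cohort_dataset> %d subjects x %d blocks (variant %s, seed %d)\n",
              x$config$n_subjects, x$config$n_blocks, x$variant_id,
              x$config$seed))
  invisible(x)
}

#' Synthesize a continuous recording from an ERP
#'
#' Embeds an ERP pair at each event time into a continuous two-channel trace
#' at the native rate (linear interpolation from the ERP grid, with a cosine
#' ramp-down over the final `taper_ms` to avoid step discontinuities), plus
#' optional white noise. Used to exercise the preprocessing chain on data
#' with known ground truth.
#'
#' @param erp An [erp_pair()] (ideally simulated on an extended window so the
#'   taper lies outside the analysis window).
#' @param events_s Event times (s).
#' @param rate Native sampling rate (Hz), default 30000.
#' @param noise_sd Additive white-noise SD (same units as the ERP).
#' @param margin_s Silence before the first and after the last event (s).
#' @param taper_ms Length of the terminal cosine taper (ms).
#' @return A [raw_recording()] with one channel per region.
#' @export
synthesize_recording <- function(erp, events_s, rate = 30000, noise_sd = 0,
                                 margin_s = 0.5, taper_ms = 50) {
  stopifnot(inherits(erp, "erp_pair"), length(events_s) >= 1)
  dur <- max(events_s) + max(erp$time_ms) / 1000 + margin_s
  n <- ceiling(dur * rate)
  t_s <- (seq_len(n) - 1) / rate
  amp <- erp$amplitude
  tw <- erp$time_ms
  taper <- rep(1, length(tw))
  if (taper_ms > 0) {
    sel <- tw > max(tw) - taper_ms
    taper[sel] <- 0.5 * (1 + cos(pi * (tw[sel] - (max(tw) - taper_ms)) / taper_ms))
  }
  x <- matrix(stats::rnorm(2 * n, 0, noise_sd), 2, n)
  for (ev in events_s) {
    rel_ms <- (t_s - ev) * 1000
    sel <- rel_ms >= min(tw) & rel_ms <= max(tw)
    for (ch in 1:2)
      x[ch, sel] <- x[ch, sel] +
        stats::approx(tw, amp[ch, ] * taper, xout = rel_ms[sel])$y
  }
  raw_recording(x, rate, events_s,
                channels = data.frame(channel_id = 1:2,
                                      region = rownames(amp)))
}
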