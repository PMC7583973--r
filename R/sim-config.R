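#' Simulation configuration for a synthetic wearable IBI cohort
#'
#' Bundles every tunable of the cohort simulator with defaults calibrated to
#' the study conditions the package emulates: 102 patients wearing an upper-arm
#' PPG device for roughly a day (recording length drawn from a normal with
#' mean 23.0 h, SD 3.3 h), a rhythm mix of 43 sinus-only / 48 AF / 11 atrial
#' flutter patients, a cohort physical-activity level of 16.1% of five-minute
#' blocks with two diurnal peaks, and a quality/dropout model tuned so that the
#' cohort mean interpretable-time fraction lands near 77% with a large
#' between-patient spread.
#'
#' @param n_patients Number of patients in the cohort.
#' @param rhythm_mix Named proportions over `c(sinus, af, flutter)` patient
#'   kinds; must sum to 1. Patient counts are assigned by largest-remainder
#'   rounding so the default mix gives exactly 43/48/11 at `n_patients = 102`.
#' @param prop_paroxysmal Fraction of AF patients whose AF is paroxysmal
#'   (alternating sinus/AF bouts) rather than persistent.
#' @param duration_mean_h,duration_sd_h Mean and SD (hours) of the per-patient
#'   recording length; draws are truncated to `[8, 26]` h.
#' @param sinus,af,flutter,bouts,quality,activity Parameter blocks built by
#'   [sinus_params()], [af_params()], [flutter_params()], [bout_params()],
#'   [quality_params()] and [activity_params()].
#' @param seed Integer seed; the whole cohort is reproducible from it.
#'
#' @return An object of class `af_sim_config` (a validated list).
#' @seealso [generate_cohort()]
#' @export
sim_config <- function(n_patients = 102,
                       rhythm_mix = c(sinus = 43, af = 48, flutter = 11) / 102,
                       prop_paroxysmal = 0.5,
                       duration_mean_h = 23.0,
                       duration_sd_h = 3.3,
                       sinus = sinus_params(),
                       af = af_params(),
                       flutter = flutter_params(),
                       bouts = bout_params(),
                       quality = quality_params(),
                       activity = activity_params(),
                       seed = 1L) {
  stopifnot(
    n_patients >= 1, length(rhythm_mix) == 3,
    prop_paroxysmal >= 0, prop_paroxysmal <= 1,
    duration_mean_h > 0, duration_sd_h >= 0
  )
  if (is.null(names(rhythm_mix))) names(rhythm_mix) <- c("sinus", "af", "flutter")
  if (any(rhythm_mix < 0) || abs(sum(rhythm_mix) - 1) > 1e-8) {
    stop("rhythm_mix must be non-negative proportions summing to 1")
  }
  structure(list(
    n_patients = as.integer(n_patients), rhythm_mix = rhythm_mix,
    prop_paroxysmal = prop_paroxysmal,
    duration_mean_h = duration_mean_h, duration_sd_h = duration_sd_h,
    sinus = sinus, af = af, flutter = flutter, bouts = bouts,
    quality = quality, activity = activity, seed = as.integer(seed)
  ), class = "af_sim_config")
}

#' Parameter blocks for the cohort simulator
#'
#' Small validated lists holding the per-rhythm and per-process parameters of
#' the simulator. `sinus_params()` describes sinus rhythm as a mean RR with a
#' respiratory-sinus-arrhythmia (RSA) sinusoid plus white jitter;
#' `af_params()` describes AF as an i.i.d. gamma renewal process with a mean
#' RR and coefficient of variation; `flutter_params()` describes atrial
#' flutter as conduction-ratio multiples of a fixed atrial cycle with a
#' Poisson-switching ratio; `bout_params()` gives exponential bout-length
#' means for paroxysmal rhythm timelines; `quality_params()` controls the
#' per-beat quality buckets, the activity-dependent degradation, the
#' per-patient log-normal frailty and dropout bursts; `activity_params()`
#' controls the two-peak diurnal activity profile on five-minute blocks.
#'
#' `*_rr_sd_ms` entries are between-patient SDs: each simulated patient draws
#' one mean RR for the rhythm, so the cohort is heterogeneous in rate.
#'
#' @param mean_rr_ms Mean RR interval (ms).
#' @param rsa_amp_ms,rsa_freq_hz,jitter_sd_ms Amplitude (ms), frequency (Hz)
#'   and white-jitter SD (ms) of the sinus generator's slow RR modulation
#'   (a mixture of respiratory and baroreflex/Mayer-wave modulation; the
#'   0.1 Hz default keeps successive beats strongly correlated, as in real
#'   sinus-rhythm Poincare plots).
#' @param mean_rr_sd_ms Between-patient SD of the mean RR (ms).
#' @param cv Coefficient of variation of AF IBIs (dimensionless).
#' @param atrial_cycle_ms Atrial flutter cycle length (ms).
#' @param ratios Integer conduction ratios available to flutter (beats per
#'   `ratios` atrial cycles, e.g. 2:1, 3:1, 4:1).
#' @param switch_rate_per_h Poisson rate (events/hour) of conduction-ratio
#'   switches.
#' @param af_bout_mean_min,sinus_bout_mean_min,flutter_bout_mean_min Mean bout
#'   lengths (minutes) for paroxysmal timelines.
#' @param q_levels Number of quality buckets Q; bucket 0 is unusable.
#' @param base_q0_prob Baseline per-beat probability of quality 0 at rest for
#'   a patient with frailty 1.
#' @param active_multiplier Multiplier on the quality-0 probability during
#'   ACTIVE blocks; also drives the beat-quality downgrade probability
#'   `min(0.9, 0.25 * (active_multiplier - 1))` during activity.
#' @param frailty_sdlog SD (log scale) of the per-patient log-normal frailty
#'   multiplying the quality-0 probability.
#' @param dropout_rate_per_h,dropout_mean_s Rate (bursts/hour) and mean length
#'   (s) of dropout bursts that delete contiguous runs of beats.
#' @param good_quality_probs Probabilities over retained buckets `1..Q-1`.
#' @param artifact_sd_ms SD (ms) of the motion-artifact beat-time jitter
#'   applied to lowest-retained-quality beats during ACTIVE blocks.
#' @param lock_block_prob,lock_run_beats,lock_gap_beats Tracker-lock model:
#'   probability that an ACTIVE five-minute block is a lock episode, and the
#'   geometric mean lengths (beats) of locked runs and of the clean gaps
#'   between them inside such a block. Locked runs are re-timed onto a
#'   near-regular grid and flagged quality 1, so irregular rhythms look
#'   spuriously regular on most of that block while a minority of honestly
#'   detected beats remains.
#' @param active_miss_coef Coefficient of the pulse-misdetection probability
#'   during ACTIVE blocks, `min(0.3, active_miss_coef * (active_multiplier -
#'   1))` per retained beat; a missed pulse merges its IBI into the next beat
#'   (the detected interval doubles) and the absorbing beat is flagged
#'   quality 1.
#' @param active_fraction Target marginal fraction of ACTIVE five-minute
#'   blocks over the cohort.
#' @param peak_offset_h,peak_sd_h,peak_weight Centres (hours from recording
#'   start), widths (h) and relative weights of the two diurnal activity
#'   peaks (morning/after-breakfast and afternoon).
#'
#' @return A named list of validated parameters.
#' @name sim-params
NULL

#' @rdname sim-params
#' @export
sinus_params <- function(mean_rr_ms = 850, rsa_amp_ms = 30, rsa_freq_hz = 0.1,
                         jitter_sd_ms = 10, mean_rr_sd_ms = 80) {
  stopifnot(mean_rr_ms >= 400, mean_rr_ms <= 1500, rsa_amp_ms >= 0,
            rsa_freq_hz > 0, jitter_sd_ms >= 0, mean_rr_sd_ms >= 0)
  list(mean_rr_ms = mean_rr_ms, rsa_amp_ms = rsa_amp_ms,
       rsa_freq_hz = rsa_freq_hz, jitter_sd_ms = jitter_sd_ms,
       mean_rr_sd_ms = mean_rr_sd_ms)
}

#' @rdname sim-params
#' @export
af_params <- function(mean_rr_ms = 700, cv = 0.22, mean_rr_sd_ms = 70) {
  if (cv < 0) stop("AF coefficient of variation must be >= 0")
  stopifnot(mean_rr_ms > 0, mean_rr_sd_ms >= 0)
  list(mean_rr_ms = mean_rr_ms, cv = cv, mean_rr_sd_ms = mean_rr_sd_ms)
}

#' @rdname sim-params
#' @export
flutter_params <- function(atrial_cycle_ms = 250, ratios = c(2L, 3L, 4L),
                           switch_rate_per_h = 6, jitter_sd_ms = 5) {
  if (length(ratios) == 0) stop("flutter needs a non-empty conduction-ratio set")
  stopifnot(atrial_cycle_ms > 0, all(ratios >= 1), switch_rate_per_h >= 0,
            jitter_sd_ms >= 0)
  list(atrial_cycle_ms = atrial_cycle_ms, ratios = as.integer(ratios),
       switch_rate_per_h = switch_rate_per_h, jitter_sd_ms = jitter_sd_ms)
}

#' @rdname sim-params
#' @export
bout_params <- function(af_bout_mean_min = 45, sinus_bout_mean_min = 120,
                        flutter_bout_mean_min = 60) {
  stopifnot(af_bout_mean_min > 0, sinus_bout_mean_min > 0,
            flutter_bout_mean_min > 0)
  list(af_bout_mean_min = af_bout_mean_min,
       sinus_bout_mean_min = sinus_bout_mean_min,
       flutter_bout_mean_min = flutter_bout_mean_min)
}

#' @rdname sim-params
#' @export
quality_params <- function(q_levels = 4L, base_q0_prob = 0.08,
                           active_multiplier = 2.5, frailty_sdlog = 0.70,
                           dropout_rate_per_h = 1.5, dropout_mean_s = 60,
                           good_quality_probs = c(0.15, 0.25, 0.60),
                           artifact_sd_ms = 40,
                           lock_block_prob = 0.08, lock_run_beats = 60,
                           lock_gap_beats = 20,
                           active_miss_coef = 0.015) {
  if (base_q0_prob < 0 || base_q0_prob > 1) {
    stop("base_q0_prob must be a probability in [0, 1]")
  }
  if (any(good_quality_probs < 0) || abs(sum(good_quality_probs) - 1) > 1e-8) {
    stop("good_quality_probs must be probabilities summing to 1")
  }
  stopifnot(q_levels >= 2, length(good_quality_probs) == q_levels - 1,
            active_multiplier >= 1, frailty_sdlog >= 0,
            dropout_rate_per_h >= 0, dropout_mean_s > 0, artifact_sd_ms >= 0,
            lock_block_prob >= 0, lock_block_prob <= 1, lock_run_beats >= 1,
            lock_gap_beats >= 1, active_miss_coef >= 0)
  list(q_levels = as.integer(q_levels), base_q0_prob = base_q0_prob,
       active_multiplier = active_multiplier, frailty_sdlog = frailty_sdlog,
       dropout_rate_per_h = dropout_rate_per_h, dropout_mean_s = dropout_mean_s,
       good_quality_probs = good_quality_probs, artifact_sd_ms = artifact_sd_ms,
       lock_block_prob = lock_block_prob, lock_run_beats = lock_run_beats,
       lock_gap_beats = lock_gap_beats, active_miss_coef = active_miss_coef)
}

#' @rdname sim-params
#' @export
activity_params <- function(active_fraction = 0.161,
                            peak_offset_h = c(2.5, 8.5),
                            peak_sd_h = c(1.5, 2.5),
                            peak_weight = c(2.5, 2.0)) {
  if (active_fraction < 0 || active_fraction > 1) {
    stop("active_fraction must be in [0, 1]")
  }
  stopifnot(length(peak_offset_h) == length(peak_sd_h),
            length(peak_offset_h) == length(peak_weight),
            all(peak_sd_h > 0), all(peak_weight >= 0))
  list(active_fraction = active_fraction, peak_offset_h = peak_offset_h,
       peak_sd_h = peak_sd_h, peak_weight = peak_weight)
}
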