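#' Task configuration for the equiprobable Go/No-go paradigm
#'
#' Describes the experimental design that event sequences are generated from:
#' block structure, stimulus identities and their probabilities, the Go/No-go
#' mapping, stimulus duration, the stimulus-onset-asynchrony (SOA) range and
#' the EEG sampling rate.
#'
#' The defaults reproduce the task this package models: 10 blocks of 80
#' trials, four stimulus identities presented with equal probability
#' (p = 0.25, two mapped to Go and two to No-go), 260 ms stimulus duration,
#' SOA drawn uniformly from 1000--2000 ms, and EEG digitized at 250 Hz.
#'
#' @param n_blocks Number of blocks.
#' @param trials_per_block Trials in each block.
#' @param n_categories Number of distinct stimulus identities.
#' @param category_probability Presentation probability per identity; must
#'   sum to 1. Defaults to equiprobable.
#' @param go_fraction Fraction of identities mapped to the Go response.
#' @param stimulus_duration_ms Stimulus duration (ms).
#' @param soa_min_ms,soa_max_ms Bounds of the uniform SOA distribution (ms).
#'   `soa_min_ms` must be at least the stimulus duration.
#' @param sampling_rate_hz EEG sampling rate (Hz).
#' @return An object of class `task_config`.
#' @examples
#' task <- task_config()
#' task$n_blocks * task$trials_per_block  # 800 trials
#' @export
task_config <- function(n_blocks = 10L, trials_per_block = 80L,
                        n_categories = 4L, category_probability = NULL,
                        go_fraction = 0.5, stimulus_duration_ms = 260,
                        soa_min_ms = 1000, soa_max_ms = 2000,
                        sampling_rate_hz = 250) {
  n_blocks <- as.integer(n_blocks)
  trials_per_block <- as.integer(trials_per_block)
  n_categories <- as.integer(n_categories)
  if (is.null(category_probability))
    category_probability <- rep(1 / n_categories, n_categories)
  if (n_blocks < 1L || trials_per_block < 1L)
    stop_posterp("n_blocks and trials_per_block must be positive")
  if (n_categories < 2L)
    stop_posterp("need at least two stimulus identities")
  if (length(category_probability) != n_categories)
    stop_posterp("category_probability must have one entry per identity")
  if (any(category_probability < 0) || any(category_probability > 1))
    stop_posterp("category probabilities must lie in [0, 1]")
  if (abs(sum(category_probability) - 1) > 1e-8)
    stop_posterp("category probabilities must sum to 1")
  if (go_fraction <= 0 || go_fraction >= 1)
    stop_posterp("go_fraction must lie strictly between 0 and 1")
  if (soa_min_ms > soa_max_ms)
    stop_posterp("soa_min_ms must not exceed soa_max_ms")
  if (soa_min_ms < stimulus_duration_ms)
    stop_posterp("soa_min_ms must be at least the stimulus duration")
  if (sampling_rate_hz <= 0)
    stop_posterp("sampling_rate_hz must be positive")
  structure(list(
    n_blocks = n_blocks, trials_per_block = trials_per_block,
    n_categories = n_categories, category_probability = category_probability,
    go_fraction = go_fraction, stimulus_duration_ms = stimulus_duration_ms,
    soa_min_ms = soa_min_ms, soa_max_ms = soa_max_ms,
    sampling_rate_hz = sampling_rate_hz
  ), class = "task_config")
}

#' Behavioral generating profile
#'
#' Parameters of the first-order sequential response model used by the
#' synthetic-data generator. False-alarm probability on a No-go trial depends
#' on the previous trial's outcome; hit response times are drawn from a
#' right-skewed log-normal family parameterized by its median, with the
#' post-error median used whenever the previous trial was a false alarm.
#'
#' Defaults encode the group-level behavior the simulation is calibrated to:
#' false-alarm probability 0.111 after correct trials and 0.0404 after
#' errors, hit RT medians of 408 ms (pre-error) and 445 ms (post-error), and
#' a false-alarm RT median of 395 ms. The miss probability defaults to a
#' small non-zero value so the hit-rate ceiling correction path of the
#' signal-detection analysis is exercised.
#'
#' @param p_fa_after_correct Probability of a false alarm on a No-go trial
#'   whose predecessor was not an error.
#' @param p_fa_after_error Same probability when the predecessor was a false
#'   alarm.
#' @param p_miss Probability of a non-response to a Go stimulus.
#' @param rt_hit_pre_error_ms Median hit RT when the previous trial was not
#'   an error (ms).
#' @param rt_hit_post_error_ms Median hit RT when the previous trial was a
#'   false alarm (ms).
#' @param rt_fa_ms Median false-alarm RT (ms).
#' @param rt_spread_ms Approximate RT standard deviation (ms); converted
#'   internally to the log-normal sigma as `rt_spread_ms / median`.
#' @param rt_family RT distribution family; only `"lognormal"` is provided.
#' @return An object of class `behavior_profile`.
#' @export
behavior_profile <- function(p_fa_after_correct = 0.111,
                             p_fa_after_error = 0.0404,
                             p_miss = 0.01,
                             rt_hit_pre_error_ms = 408,
                             rt_hit_post_error_ms = 445,
                             rt_fa_ms = 395,
                             rt_spread_ms = 65,
                             rt_family = "lognormal") {
  probs <- c(p_fa_after_correct, p_fa_after_error, p_miss)
  if (any(probs < 0) || any(probs > 1))
    stop_posterp("probabilities must lie in [0, 1]")
  rts <- c(rt_hit_pre_error_ms, rt_hit_post_error_ms, rt_fa_ms)
  if (any(rts <= 0)) stop_posterp("RT location parameters must be positive")
  if (rt_spread_ms < 0) stop_posterp("rt_spread_ms must be non-negative")
  rt_family <- match.arg(rt_family, "lognormal")
  structure(list(
    p_fa_after_correct = p_fa_after_correct,
    p_fa_after_error = p_fa_after_error,
    p_miss = p_miss,
    rt_hit_pre_error_ms = rt_hit_pre_error_ms,
    rt_hit_post_error_ms = rt_hit_post_error_ms,
    rt_fa_ms = rt_fa_ms,
    rt_spread_ms = rt_spread_ms,
    rt_family = rt_family
  ), class = "behavior_profile")
}

#' Noise model for synthetic EEG
#'
#' Broadband background activity with a 1/f^a spectrum, an oscillatory
#' alpha-band component, and occasional large-amplitude artifact excursions
#' injected at the epoch level so the artifact-rejection stage has rejectable
#' material by construction.
#'
#' @param broadband_sd_uv Standard deviation of the broadband background
#'   (microvolts). An exponent of 0 makes it white.
#' @param one_over_f_exponent Spectral exponent a of the 1/f^a shaping.
#' @param alpha_band_amplitude_uv Amplitude of a 10 Hz sinusoid with random
#'   per-channel phase (microvolts).
#' @param artifact_rate Probability, per trial epoch, of injecting one
#'   large-amplitude excursion.
#' @param artifact_amplitude_uv Peak amplitude of injected artifacts; must
#'   exceed 120 microvolts so artifacts are rejectable by design.
#' @return An object of class `noise_model`.
#' @export
noise_model <- function(broadband_sd_uv = 10,
                        one_over_f_exponent = 1,
                        alpha_band_amplitude_uv = 4,
                        artifact_rate = 0.05,
                        artifact_amplitude_uv = 200) {
  if (broadband_sd_uv < 0 || alpha_band_amplitude_uv < 0 ||
      artifact_amplitude_uv < 0)
    stop_posterp("noise amplitudes must be non-negative")
  if (artifact_rate < 0 || artifact_rate > 1)
    stop_posterp("artifact_rate must lie in [0, 1]")
  if (artifact_rate > 0 && artifact_amplitude_uv <= 120)
    stop_posterp("artifact_amplitude_uv must exceed 120 microvolts")
  structure(list(
    broadband_sd_uv = broadband_sd_uv,
    one_over_f_exponent = one_over_f_exponent,
    alpha_band_amplitude_uv = alpha_band_amplitude_uv,
    artifact_rate = artifact_rate,
    artifact_amplitude_uv = artifact_amplitude_uv
  ), class = "noise_model")
}

#' Between-subject jitter specification
#'
#' Independent Gaussian perturbations of the population behavioral profile
#' and template gains, truncated to valid ranges: the simplest exchangeable
#' subject model for the repeated-measures analyses. The
#' `bp_rt_coupling_ms_per_uv` term makes a subject's expected post-error
#' motor-preparation (BP) amplitude drive their post-error RT median (a less
#' negative BP gives slower responses), which induces the positive
#' correlation between signed BP amplitude and hit RT that the correlation
#' analysis looks for.
#'
#' @param scale Multiplier applied to every standard deviation; `scale = 0`
#'   gives identical subjects.
#' @param sd_p_fa_correct,sd_p_fa_error,sd_p_miss SDs of the per-subject
#'   false-alarm and miss probabilities.
#' @param sd_rt_ms SD of the per-subject RT medians (ms).
#' @param sd_component_scale SD of a subject-level multiplicative gain
#'   applied to all ERP templates.
#' @param sd_pn_gain,sd_bp_gain SDs of the per-subject post-error condition
#'   gains of the prefrontal negativity and Bereitschaftspotential.
#' @param bp_rt_coupling_ms_per_uv Slope (ms per microvolt) linking the
#'   subject's expected post-error BP window amplitude to their post-error
#'   RT median.
#' @return An object of class `profile_jitter`.
#' @export
profile_jitter <- function(scale = 1,
                           sd_p_fa_correct = 0.03,
                           sd_p_fa_error = 0.015,
                           sd_p_miss = 0.005,
                           sd_rt_ms = 20,
                           sd_component_scale = 0.3,
                           sd_pn_gain = 0.25,
                           sd_bp_gain = 0.08,
                           bp_rt_coupling_ms_per_uv = 100) {
  if (scale < 0) stop_posterp("scale must be non-negative")
  structure(list(
    sd_p_fa_correct = scale * sd_p_fa_correct,
    sd_p_fa_error = scale * sd_p_fa_error,
    sd_p_miss = scale * sd_p_miss,
    sd_rt_ms = scale * sd_rt_ms,
    sd_component_scale = scale * sd_component_scale,
    sd_pn_gain = scale * sd_pn_gain,
    sd_bp_gain = scale * sd_bp_gain,
    bp_rt_coupling_ms_per_uv = scale * bp_rt_coupling_ms_per_uv
  ), class = "profile_jitter")
}

#' Default analysis montage
#'
#' The eight channels the analysis touches: bilateral prefrontal (Fp1, Fp2)
#' for the prefrontal negativity, central (C1, Cz, C2) for the
#' Bereitschaftspotential, parieto-occipital (PO7, PO8) for the visual N1
#' and P1, plus one EOG-like noise channel. A full 64-channel 10-10 montage
#' is available through [montage_1010()].
#'
#' @return Character vector of channel labels.
#' @export
default_montage <- function() {
  c("Fp1", "Fp2", "C1", "Cz", "C2", "PO7", "PO8", "VEOG")
}

#' Full 64-channel 10-10 montage
#'
#' Standard 10-10 labels for a 64-electrode cap.
#'
#' @return Character vector of 64 channel labels.
#' @export
montage_1010 <- function() {
  c("Fp1", "Fpz", "Fp2", "AF7", "AF3", "AFz", "AF4", "AF8",
    "F7", "F5", "F3", "F1", "Fz", "F2", "F4", "F6", "F8",
    "FT7", "FC5", "FC3", "FC1", "FCz", "FC2", "FC4", "FC6", "FT8",
    "T7", "C5", "C3", "C1", "Cz", "C2", "C4", "C6", "T8",
    "TP7", "CP5", "CP3", "CP1", "CPz", "CP2", "CP4", "CP6", "TP8",
    "P7", "P5", "P3", "P1", "Pz", "P2", "P4", "P6", "P8",
    "PO7", "PO3", "POz", "PO4", "PO8", "O1", "Oz", "O2",
    "M1", "M2", "VEOG", "HEOG")
}
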