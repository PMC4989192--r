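#' ERP component template
#'
#' Parametric forward model of one ERP component: a piecewise-linear
#' (triangular) time course that rises from zero at `ramp_onset_ms` to
#' `peak_amplitude_uv` at `peak_time_ms` and returns to zero at `offset_ms`,
#' projected onto the scalp through per-channel gains, time-locked either to
#' stimulus onset or to the response, and scaled multiplicatively by the
#' sequential condition of the trial it is placed on.
#'
#' Slow preparatory components (pN, BP) are negative-going pre-stimulus
#' ramps peaking at time 0; P1 is a positive and N1 a negative post-stimulus
#' peak; Ne and Pe are response-locked and applied only to error (false
#' alarm) trials.
#'
#' @param name Component name, one of `"pN"`, `"BP"`, `"P1"`, `"N1"`,
#'   `"Ne"`, `"Pe"`.
#' @param lock `"stimulus"` or `"response"`.
#' @param channel_weights Named numeric vector of unitless per-channel gains.
#' @param ramp_onset_ms,peak_time_ms,offset_ms Time course knots (ms
#'   relative to the lock event); must be increasing.
#' @param peak_amplitude_uv Peak amplitude (microvolts), signed.
#' @param condition_scaling Named numeric vector of multiplicative gains per
#'   condition label (conditions not listed use gain 1).
#' @param error_only Apply the template only to false-alarm trials.
#' @return An object of class `component_template`.
#' @export
component_template <- function(name, lock = c("stimulus", "response"),
                               channel_weights,
                               ramp_onset_ms, peak_time_ms, peak_amplitude_uv,
                               offset_ms,
                               condition_scaling = c(post_correct = 1,
                                                     post_error = 1),
                               error_only = FALSE) {
  name <- match.arg(name, c("pN", "BP", "P1", "N1", "Ne", "Pe"))
  lock <- match.arg(lock)
  if (is.null(names(channel_weights)) || any(!nzchar(names(channel_weights))))
    stop_posterp("channel_weights must be a named vector")
  if (!(ramp_onset_ms < peak_time_ms && peak_time_ms < offset_ms))
    stop_posterp("need ramp_onset_ms < peak_time_ms < offset_ms")
  if (name %in% c("pN", "BP")) {
    if (peak_amplitude_uv >= 0)
      stop_posterp(name, " must be negative-going")
    if (peak_time_ms != 0)
      stop_posterp(name, " must reach its peak at time 0 (stimulus onset)")
  }
  if (name == "P1" && peak_amplitude_uv <= 0)
    stop_posterp("P1 must be positive")
  if (name == "N1" && peak_amplitude_uv >= 0)
    stop_posterp("N1 must be negative")
  if (name %in% c("Ne", "Pe")) {
    if (lock != "response" || !error_only)
      stop_posterp(name, " must be response-locked and error-only")
  }
  structure(list(
    name = name, lock = lock, channel_weights = channel_weights,
    ramp_onset_ms = ramp_onset_ms, peak_time_ms = peak_time_ms,
    peak_amplitude_uv = peak_amplitude_uv, offset_ms = offset_ms,
    condition_scaling = condition_scaling, error_only = error_only
  ), class = "component_template")
}

#' Default component template set
#'
#' Templates calibrated so that, after the analysis pipeline's window
#' averaging, the group condition means reproduce the effect structure the
#' simulation targets: a prefrontal negativity (pN) whose (-600, 0) ms
#' window mean is -1.4 uV post-correct and is enhanced by a factor of about
#' 2.14 post-error (lateralized slightly to Fp2), and a central
#' Bereitschaftspotential (BP) whose (-500, 0) ms window mean is -1.8 uV
#' post-correct and is reduced to about 0.44 of that post-error. Because the
#' preparatory ramps rise linearly from their onset to stimulus onset, the
#' analysis-window mean equals half the peak amplitude in closed form.
#'
#' Visual P1 (PO8) and N1 (PO7) peaks carry no condition effect. The
#' response-locked error negativity (Ne) and error positivity (Pe) are
#' placed on false-alarm trials only; their amplitudes are kept modest with
#' a roughly charge-balanced biphasic shape so that, smeared by the
#' 1000-2000 ms SOA jitter, the previous trial's error activity leaves the
#' next trial's pre-stimulus analysis windows essentially unbiased. For the
#' same reason the preparatory ramps decay back to zero within 50 ms of
#' stimulus onset: the decay tail of the previous trial is the dominant
#' jitter-smeared contamination of the epoch-initial baseline, and a fast
#' post-stimulus resolution keeps the common baseline offset -- and with it
#' the bias of recovered condition-gain ratios -- small (see the methods
#' vignette for the smearing analysis).
#'
#' @return Named list of [component_template()] objects.
#' @export
default_templates <- function() {
  list(
    pN = component_template(
      "pN", "stimulus",
      channel_weights = c(Fp1 = 0.864, Fp2 = 1.136),
      ramp_onset_ms = -600, peak_time_ms = 0, peak_amplitude_uv = -2.8,
      offset_ms = 50,
      condition_scaling = c(post_correct = 1, post_error = 3.0 / 1.4)),
    BP = component_template(
      "BP", "stimulus",
      channel_weights = c(C1 = 1, Cz = 1, C2 = 1),
      ramp_onset_ms = -500, peak_time_ms = 0, peak_amplitude_uv = -3.6,
      offset_ms = 50,
      condition_scaling = c(post_correct = 1, post_error = 0.8 / 1.8)),
    P1 = component_template(
      "P1", "stimulus",
      channel_weights = c(PO8 = 1, PO7 = 0.4),
      ramp_onset_ms = 60, peak_time_ms = 110, peak_amplitude_uv = 4,
      offset_ms = 170),
    N1 = component_template(
      "N1", "stimulus",
      channel_weights = c(PO7 = 1, PO8 = 0.4),
      ramp_onset_ms = 90, peak_time_ms = 160, peak_amplitude_uv = -4,
      offset_ms = 230),
    Ne = component_template(
      "Ne", "response",
      channel_weights = c(Cz = 1, C1 = 0.8, C2 = 0.8, Fp1 = 0.3, Fp2 = 0.3),
      ramp_onset_ms = 0, peak_time_ms = 80, peak_amplitude_uv = -2.5,
      offset_ms = 200, error_only = TRUE),
    Pe = component_template(
      "Pe", "response",
      channel_weights = c(Cz = 0.8, C1 = 0.7, C2 = 0.7, Fp1 = 0.4, Fp2 = 0.4,
                          PO7 = 0.5, PO8 = 0.5),
      ramp_onset_ms = 120, peak_time_ms = 300, peak_amplitude_uv = 2.5,
      offset_ms = 560, error_only = TRUE)
  )
}

# Sampled triangular time course of a template.
# Returns list(offsets = sample offsets relative to the lock sample,
#              wave = amplitudes in uV).
template_waveform <- function(template, sampling_rate_hz) {
  fs <- sampling_rate_hz
  k0 <- round(template$ramp_onset_ms * fs / 1000)
  k1 <- round(template$offset_ms * fs / 1000)
  offsets <- k0:k1
  t_ms <- offsets * 1000 / fs
  a <- template$peak_amplitude_uv
  w <- ifelse(
    t_ms <= template$peak_time_ms,
    a * (t_ms - template$ramp_onset_ms) /
      (template$peak_time_ms - template$ramp_onset_ms),
    a * (template$offset_ms - t_ms) /
      (template$offset_ms - template$peak_time_ms))
  w <- clamp(w / a, 0, 1) * a  # guard tiny overshoot at the knots
  list(offsets = offsets, wave = w)
}

#' Restrict templates to a montage
#'
#' Drops channel weights that are absent from `montage` and removes
#' templates left with no channels. Useful for reduced-montage simulations.
#'
#' @param templates List of [component_template()] objects.
#' @param montage Character vector of channel labels.
#' @return Filtered template list.
#' @export
restrict_templates <- function(templates, montage) {
  out <- lapply(templates, function(tp) {
    keep <- names(tp$channel_weights) %in% montage
    if (!any(keep)) return(NULL)
    tp$channel_weights <- tp$channel_weights[keep]
    tp
  })
  out[!vapply(out, is.null, logical(1))]
}
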