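# 1/f^a shaped unit-variance noise (returned as an n x n_series matrix),
# synthesized in the frequency domain. One inverse FFT of a complex
# Gaussian spectrum yields two independent real shaped series (its real
# and imaginary parts), so `n_series` channels cost ceiling(n_series/2)
# FFTs. The shaped component is synthesized on a half-rate grid and
# linearly upsampled: its spectral mass lies far below the half-rate
# Nyquist (the analysis band ends at 25 Hz, where the interpolation
# rolloff is under 1 dB). DC is zeroed, so each series is zero-mean up to
# the end-truncation; scaling to unit variance is analytic (ensemble), not
# per-realization.
shaped_noise <- function(n, exponent, n_series = 1L) {
  if (exponent <= 0)
    return(matrix(stats::rnorm(n * n_series), n, n_series))
  n2 <- (n %/% 2L) + 2L              # half-rate samples needed
  m <- stats::nextn(max(n2, 2L), c(2L, 3L, 5L))
  fidx <- pmin(seq_len(m) - 1L, m - (seq_len(m) - 1L))
  w <- c(0, fidx[-1L]^(-exponent / 2))
  scale <- 1 / sqrt(sum(w^2))
  upsample2 <- function(v) {         # linear x2 interpolation
    a <- v[-length(v)]
    y <- rbind(a, (a + v[-1L]) / 2)  # interleave originals and midpoints
    dim(y) <- NULL
    y[seq_len(n)]
  }
  cols <- vector("list", n_series)
  for (k in seq_len(ceiling(n_series / 2))) {
    z <- complex(real = stats::rnorm(m) * w,
                 imaginary = stats::rnorm(m) * w)
    x <- stats::fft(z, inverse = TRUE)
    cols[[2L * k - 1L]] <- upsample2(Re(x)[seq_len(n2)] * scale)
    if (2L * k <= n_series)
      cols[[2L * k]] <- upsample2(Im(x)[seq_len(n2)] * scale)
  }
  do.call(cbind, cols)
}

#' Render continuous EEG from events, templates and a noise model
#'
#' Forward model for the simulated recording: a noise realization plus, for
#' every trial, each applicable component template placed at its lock time
#' (stimulus onset, or the response time for response-locked templates),
#' projected through its channel weights and scaled by the condition gain of
#' that trial. Stimulus-locked templates use the trial's sequential context
#' (post-error vs post-correct; block-initial trials count as post-correct);
#' error-only templates (Ne, Pe) are placed on false-alarm trials only. The
#' model is linear: rendering two template sets separately and summing
#' equals rendering them together. Deterministic given the seed.
#'
#' @param events An `event_log`.
#' @param templates List of [component_template()] objects; every template
#'   channel must be in `montage`.
#' @param noise A [noise_model()]; use zero amplitudes for a noiseless
#'   forward model.
#' @param montage Character vector of channel labels.
#' @param seed Optional integer seed; `NULL` continues the RNG stream.
#' @param sampling_rate_hz Sampling rate (Hz).
#' @param labels Optional precomputed [classify_trials()] output.
#' @param tail_ms Margin after the last event (on top of the 900 ms
#'   post-stimulus epoch limb).
#' @return An object of class `eeg_recording`: list with `data` (channels x
#'   samples matrix, microvolts), `channels`, `sfreq_hz`, `unit`.
#' @export
render_recording <- function(events, templates = default_templates(),
                             noise = noise_model(),
                             montage = default_montage(),
                             seed = NULL, sampling_rate_hz = 250,
                             labels = NULL, tail_ms = 1500) {
  stopifnot(inherits(noise, "noise_model"))
  if (!is.null(seed)) set.seed(seed)
  ev <- as.data.frame(events)
  fs <- sampling_rate_hz
  for (tp in templates) {
    unknown <- setdiff(names(tp$channel_weights), montage)
    if (length(unknown))
      stop_posterp("unknown channel label(s) in template ", tp$name, ": ",
                   paste(unknown, collapse = ", "))
  }

  n_samples <- ceiling((max(ev$onset_ms) + 900 + tail_ms) * fs / 1000)
  n_ch <- length(montage)

  # accumulate noise samples-major (contiguous per-channel columns), then
  # transpose once into the channels x samples container
  acc <- NULL
  if (noise$broadband_sd_uv > 0)
    acc <- noise$broadband_sd_uv *
      shaped_noise(n_samples, noise$one_over_f_exponent, n_ch)
  if (noise$alpha_band_amplitude_uv > 0) {
    if (is.null(acc)) acc <- matrix(0, n_samples, n_ch)
    ang <- 2 * pi * 10 * seq_len(n_samples) / fs
    sn <- sin(ang); cn <- cos(ang)
    phase <- stats::runif(n_ch, 0, 2 * pi)
    for (ch in seq_len(n_ch))
      acc[, ch] <- acc[, ch] + noise$alpha_band_amplitude_uv *
        (sn * cos(phase[ch]) + cn * sin(phase[ch]))
  }
  dat <- if (is.null(acc)) matrix(0, n_ch, n_samples) else t(acc)
  if (noise$artifact_rate > 0) {
    hit <- stats::runif(nrow(ev)) < noise$artifact_rate
    if (any(hit)) {
      pulse_n <- max(2L, round(0.2 * fs))  # 200 ms half-sine excursion
      pulse <- sin(pi * seq(0, 1, length.out = pulse_n))
      for (i in which(hit)) {
        ch <- sample.int(n_ch, 1)
        t0 <- stats::runif(1, ev$onset_ms[i] - 1100, ev$onset_ms[i] + 900 -
                             pulse_n * 1000 / fs)
        i0 <- round(t0 * fs / 1000) + 1L
        idx <- i0:(i0 + pulse_n - 1L)
        ok <- idx >= 1L & idx <= n_samples
        dat[ch, idx[ok]] <- dat[ch, idx[ok]] +
          sample(c(-1, 1), 1) * noise$artifact_amplitude_uv * pulse[ok]
      }
    }
  }

  if (length(templates)) {
    if (is.null(labels)) labels <- classify_trials(events)
    condition <- ifelse(labels$post_error, "post_error", "post_correct")
    is_fa <- labels$outcome == "false_alarm"
    lock_stim <- round(ev$onset_ms * fs / 1000) + 1L
    for (tp in templates) {
      wv <- template_waveform(tp, fs)
      if (tp$error_only) {
        sel <- which(is_fa & ev$response == 1L)
        gains <- rep(1, length(sel))
      } else if (tp$lock == "response") {
        sel <- which(ev$response == 1L)
        gains <- unname(tp$condition_scaling[condition[sel]])
        gains[is.na(gains)] <- 1
      } else {
        sel <- seq_len(nrow(ev))
        gains <- unname(tp$condition_scaling[condition])
        gains[is.na(gains)] <- 1
      }
      if (!length(sel)) next
      lock <- if (tp$lock == "response")
        round((ev$onset_ms[sel] + ev$rt_ms[sel]) * fs / 1000) + 1L
      else lock_stim[sel]
      idx_mat <- outer(wv$offsets, lock, "+")
      if (min(idx_mat) < 1L || max(idx_mat) > n_samples)
        stop_posterp("event epoch extends beyond the recording span")
      vals <- outer(wv$wave, gains)
      flat_idx <- as.vector(idx_mat)
      overlap <- anyDuplicated(flat_idx) > 0L
      for (chn in names(tp$channel_weights)) {
        ch <- match(chn, montage)
        v <- tp$channel_weights[[chn]] * as.vector(vals)
        if (!overlap) {
          dat[ch, flat_idx] <- dat[ch, flat_idx] + v
        } else {
          acc <- rowsum(v, flat_idx)
          ii <- as.integer(rownames(acc))
          dat[ch, ii] <- dat[ch, ii] + acc[, 1]
        }
      }
    }
  }

  structure(list(data = dat, channels = montage, sfreq_hz = fs, unit = "uV"),
            class = "eeg_recording")
}

#' @export
print.eeg_recording <- function(x, ...) {
  cat(sprintf("<eeg_recording> %d channels x %d samples @ %g Hz (%s)\n",
              nrow(x$data), ncol(x$data), x$sfreq_hz, x$unit))
  cat("channels:", paste(x$channels, collapse = ", "), "\n")
  invisible(x)
}

#' Write / read a continuous recording
#'
#' The on-disk container is a flat little-endian 32-bit float binary
#' (channels x samples, one channel's full time series after another) plus a
#' JSON sidecar `{channels, sfreq_hz, unit, n_samples}`. Sample indexing is
#' 0-based in the sidecar's documentation of time: sample k lies at
#' t = k / sfreq_hz.
#'
#' @param recording An `eeg_recording`.
#' @param path_prefix Path without extension; writes `<prefix>.dat` and
#'   `<prefix>.json`.
#' @return `write_recording` returns the prefix invisibly; `read_recording`
#'   returns an `eeg_recording`.
#' @export
write_recording <- function(recording, path_prefix) {
  stopifnot(inherits(recording, "eeg_recording"))
  con <- file(paste0(path_prefix, ".dat"), "wb")
  on.exit(close(con))
  writeBin(as.vector(t(recording$data)), con, size = 4L, endian = "little")
  jsonlite::write_json(
    list(channels = recording$channels, sfreq_hz = recording$sfreq_hz,
         unit = recording$unit, n_samples = ncol(recording$data),
         sample_indexing = "0-based; sample k at t = k / sfreq_hz"),
    paste0(path_prefix, ".json"), auto_unbox = TRUE, digits = NA)
  invisible(path_prefix)
}

#' @rdname write_recording
#' @export
read_recording <- function(path_prefix) {
  meta <- jsonlite::read_json(paste0(path_prefix, ".json"),
                              simplifyVector = TRUE)
  n_ch <- length(meta$channels)
  con <- file(paste0(path_prefix, ".dat"), "rb")
  on.exit(close(con))
  raw <- readBin(con, "numeric", n = n_ch * meta$n_samples, size = 4L,
                 endian = "little")
  structure(list(data = matrix(raw, n_ch, meta$n_samples, byrow = TRUE),
                 channels = meta$channels, sfreq_hz = meta$sfreq_hz,
                 unit = meta$unit),
            class = "eeg_recording")
}

# Draw one subject's true parameters from the population profile + jitter.
draw_subject_truth <- function(profile, templates, jitter) {
  g <- function(mu, sd, lo, hi) clamp(stats::rnorm(1, mu, sd), lo, hi)
  prof <- profile
  prof$p_fa_after_correct <- g(profile$p_fa_after_correct,
                               jitter$sd_p_fa_correct, 0, 1)
  prof$p_fa_after_error <- g(profile$p_fa_after_error,
                             jitter$sd_p_fa_error, 0, 1)
  prof$p_miss <- g(profile$p_miss, jitter$sd_p_miss, 0, 1)
  prof$rt_hit_pre_error_ms <- g(profile$rt_hit_pre_error_ms,
                                jitter$sd_rt_ms, 150, 950)
  prof$rt_fa_ms <- g(profile$rt_fa_ms, jitter$sd_rt_ms, 150, 950)

  subject_scale <- g(1, jitter$sd_component_scale, 0.2, 3)
  pn_pop <- if (!is.null(templates$pN))
    templates$pN$condition_scaling[["post_error"]] else 1
  bp_pop <- if (!is.null(templates$BP))
    templates$BP$condition_scaling[["post_error"]] else 1
  pn_gain <- g(pn_pop, jitter$sd_pn_gain, 0.1, 6)
  bp_gain <- g(bp_pop, jitter$sd_bp_gain, 0.02, 2)

  # subject's expected post-error BP analysis-window amplitude (uV): the
  # linear pre-stimulus ramp has window mean = peak/2
  bp_peak <- if (!is.null(templates$BP)) templates$BP$peak_amplitude_uv else 0
  mu_bp_subj <- bp_peak / 2 * subject_scale * bp_gain
  mu_bp_pop <- bp_peak / 2 * bp_pop
  rt_noise <- stats::rnorm(1, 0, jitter$sd_rt_ms)
  prof$rt_hit_post_error_ms <- clamp(
    profile$rt_hit_post_error_ms +
      jitter$bp_rt_coupling_ms_per_uv * (mu_bp_subj - mu_bp_pop) + rt_noise,
    150, 950)

  tpl <- templates
  for (nm in names(tpl)) {
    tpl[[nm]]$peak_amplitude_uv <- tpl[[nm]]$peak_amplitude_uv * subject_scale
    if (nm == "pN") tpl[[nm]]$condition_scaling[["post_error"]] <- pn_gain
    if (nm == "BP") tpl[[nm]]$condition_scaling[["post_error"]] <- bp_gain
  }
  list(profile = prof, templates = tpl,
       gains = list(subject_scale = subject_scale,
                    pn_post_error_gain = pn_gain,
                    bp_post_error_gain = bp_gain),
       expected = list(
         pes_ms = prof$rt_hit_post_error_ms - prof$rt_hit_pre_error_ms,
         pia = prof$p_fa_after_correct - prof$p_fa_after_error))
}

#' Simulate one subject
#'
#' Draws the subject's true parameters (profile and template gains) from the
#' population profile plus between-subject jitter, then generates the event
#' log and renders the continuous recording.
#'
#' @inheritParams generate_cohort
#' @param seed Integer seed for this subject.
#' @return List with `recording`, `events` and `truth` (the subject's
#'   generating parameters and closed-form expected quantities).
#' @export
simulate_subject <- function(task = task_config(),
                             profile = behavior_profile(),
                             templates = default_templates(),
                             noise = noise_model(),
                             montage = default_montage(),
                             jitter = profile_jitter(),
                             seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  truth <- draw_subject_truth(profile, templates, jitter)
  events <- generate_event_sequence(task, truth$profile, seed = NULL)
  recording <- render_recording(events, truth$templates, noise, montage,
                                seed = NULL,
                                sampling_rate_hz = task$sampling_rate_hz)
  list(recording = recording, events = events, truth = truth)
}

#' Generate a synthetic cohort
#'
#' Independent per-subject seeds are derived from the master seed, so two
#' calls with the same master seed produce bit-identical cohorts. Each
#' subject's ground truth (generating profile, template gains and
#' closed-form expected PES/PIA) is stored alongside the data.
#'
#' @param n_subjects Number of subjects (default 36).
#' @param task A [task_config()].
#' @param profile Population [behavior_profile()].
#' @param templates Population template set.
#' @param noise A [noise_model()].
#' @param montage Channel labels.
#' @param jitter A [profile_jitter()]; use `profile_jitter(scale = 0)` for
#'   identical subjects.
#' @param seed Master integer seed.
#' @return List of `n_subjects` lists, each with `recording`, `events`,
#'   `truth`.
#' @export
generate_cohort <- function(n_subjects = 36L, task = task_config(),
                            profile = behavior_profile(),
                            templates = default_templates(),
                            noise = noise_model(),
                            montage = default_montage(),
                            jitter = profile_jitter(), seed = NULL) {
  stopifnot(n_subjects >= 1)
  if (!is.null(seed)) set.seed(seed)
  seeds <- sample.int(.Machine$integer.max - 1L, n_subjects)
  lapply(seq_len(n_subjects), function(i)
    simulate_subject(task, profile, templates, noise, montage, jitter,
                     seed = seeds[i]))
}
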