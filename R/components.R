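#' Sample-by-sample paired t-test between two conditions
#'
#' Two-tailed paired t-test across subjects at every sample of every
#' requested channel, used to locate where two conditions differ
#' consistently in time. Subjects missing either condition are dropped
#' pairwise (their count is reported).
#'
#' @param evokeds_a,evokeds_b Lists of per-subject `evoked` objects (same
#'   subject order; `NULL` entries allowed and dropped pairwise).
#' @param channels Channels to test (default: all shared channels).
#' @param alpha Significance level for the mask.
#' @return An object of class `significance_mask`: matrices `t`, `p` and
#'   logical `sig` (channels x samples), with `times_ms`, `channels`,
#'   `alpha`, `n` (subjects used) and `n_dropped`.
#' @export
samplewise_paired_ttest <- function(evokeds_a, evokeds_b, channels = NULL,
                                    alpha = 0.05) {
  stopifnot(length(evokeds_a) == length(evokeds_b))
  ok <- !vapply(evokeds_a, is.null, logical(1)) &
    !vapply(evokeds_b, is.null, logical(1))
  n_dropped <- sum(!ok)
  a <- evokeds_a[ok]
  b <- evokeds_b[ok]
  n <- length(a)
  if (n < 3) stop_posterp("need at least 3 subjects with both conditions")
  channels <- channels %||% a[[1]]$channels
  times <- a[[1]]$times_ms
  n_smp <- length(times)
  rows <- match(channels, a[[1]]$channels)
  if (anyNA(rows)) stop_posterp("unknown channel label")

  tmat <- pmat <- matrix(NA_real_, length(channels), n_smp,
                         dimnames = list(channels, NULL))
  for (j in seq_along(channels)) {
    D <- t(vapply(seq_len(n), function(i)
      a[[i]]$data[rows[j], ] - b[[i]]$data[rows[j], ], numeric(n_smp)))
    mu <- colMeans(D)
    s <- sqrt((colSums(D^2) - n * mu^2) / (n - 1))
    tv <- mu / (s / sqrt(n))
    tv[s == 0 & mu == 0] <- 0
    tv[s == 0 & mu != 0] <- sign(mu[s == 0 & mu != 0]) * Inf
    tmat[j, ] <- tv
    pmat[j, ] <- 2 * stats::pt(-abs(tv), n - 1)
  }
  structure(list(t = tmat, p = pmat, sig = pmat < alpha,
                 times_ms = times, channels = channels, alpha = alpha,
                 n = n, n_dropped = n_dropped),
            class = "significance_mask")
}

#' Select an analysis window from a significance mask
#'
#' Operationalizes "consistently significant" as the longest run of
#' consecutive significant samples lasting at least `min_duration_ms`
#' within the search range, rounded outward to sample boundaries. When
#' several channels are given, a sample counts as significant only if it is
#' significant on all of them. Returns `NULL` when no run qualifies. The
#' result is invariant to mask values outside the search range.
#'
#' @param mask A `significance_mask`.
#' @param channels Channels whose joint significance defines the run
#'   (default: all channels in the mask).
#' @param min_duration_ms Minimum run duration (ms), default 40 (10
#'   consecutive samples at 250 Hz).
#' @param search_ms Search range `(start_ms, end_ms)`; default the whole
#'   epoch.
#' @param name Component name to attach.
#' @return A list of class `component_window` with `component`, `channels`
#'   and `window_ms`, or `NULL`.
#' @export
select_window <- function(mask, channels = NULL, min_duration_ms = 40,
                          search_ms = NULL, name = NA_character_) {
  stopifnot(inherits(mask, "significance_mask"))
  channels <- channels %||% mask$channels
  rows <- match(channels, mask$channels)
  if (anyNA(rows)) stop_posterp("channel not present in mask")
  sig <- colSums(mask$sig[rows, , drop = FALSE]) == length(rows)
  tms <- mask$times_ms
  if (!is.null(search_ms)) {
    inside <- tms >= search_ms[1] - .time_eps & tms <= search_ms[2] + .time_eps
    if (!any(inside)) stop_posterp("mask does not cover the search range")
    sig[!inside] <- FALSE
  }
  r <- rle(sig)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  dur <- (r$lengths - 1L) * diff(tms[1:2])  # run duration in ms
  cand <- which(r$values & dur >= min_duration_ms - .time_eps)
  if (!length(cand)) return(NULL)
  best <- cand[which.max(r$lengths[cand])]
  structure(list(component = name, channels = channels,
                 window_ms = c(tms[starts[best]], tms[ends[best]])),
            class = "component_window")
}

#' Default component quantification windows
#'
#' The fixed analysis windows the pipeline ships with: prefrontal
#' negativity (pN) as the mean amplitude at Fp1 and Fp2 over (-600, 0) ms;
#' Bereitschaftspotential (BP) as the mean amplitude at C1, Cz and C2 over
#' (-500, 0) ms; visual P1 as the positive peak at PO8 searched in
#' (60, 160) ms and N1 as the negative peak at PO7 searched in
#' (100, 220) ms. Data-driven window discovery ([select_window()]) is an
#' optional alternative mode, so quantification with the fixed windows never
#' depends on the discovery heuristic.
#'
#' @return Named list of window specifications.
#' @export
default_component_windows <- function() {
  list(
    pN = list(component = "pN", channels = c("Fp1", "Fp2"),
              window_ms = c(-600, 0), measure = "mean"),
    BP = list(component = "BP", channels = c("C1", "Cz", "C2"),
              window_ms = c(-500, 0), measure = "mean"),
    P1 = list(component = "P1", channels = "PO8", window_ms = c(60, 160),
              measure = "peak", polarity = "positive"),
    N1 = list(component = "N1", channels = "PO7", window_ms = c(100, 220),
              measure = "peak", polarity = "negative"))
}

#' Mean amplitude in a window
#'
#' Arithmetic mean of one channel's samples whose times fall inside
#' `[start, end]` (inclusive). Linear in the waveform.
#'
#' @param evoked An `evoked`.
#' @param channel Channel label.
#' @param window_ms `(start_ms, end_ms)`, inside the epoch span.
#' @return Mean amplitude (microvolts).
#' @export
mean_amplitude <- function(evoked, channel, window_ms) {
  row <- match(channel, evoked$channels)
  if (is.na(row)) stop_posterp("unknown channel: ", channel)
  tms <- evoked$times_ms
  if (window_ms[1] < tms[1] - .time_eps ||
      window_ms[2] > tms[length(tms)] + .time_eps)
    stop_posterp("window lies outside the epoch span")
  sel <- tms >= window_ms[1] - .time_eps & tms <= window_ms[2] + .time_eps
  mean(evoked$data[row, sel])
}

#' Peak amplitude and latency in a search window
#'
#' Extremum of the stated polarity within the window; the latency is the
#' time of that sample, with ties broken toward the earliest sample. A
#' warning is raised when the extremum sits on a window edge (the waveform
#' may be monotone across the window).
#'
#' @param evoked An `evoked`.
#' @param channel Channel label.
#' @param window_ms Search window `(start_ms, end_ms)`.
#' @param polarity `"positive"` or `"negative"`.
#' @return List with `amplitude_uv` and `latency_ms`.
#' @export
peak_measure <- function(evoked, channel, window_ms,
                         polarity = c("positive", "negative")) {
  polarity <- match.arg(polarity)
  row <- match(channel, evoked$channels)
  if (is.na(row)) stop_posterp("unknown channel: ", channel)
  tms <- evoked$times_ms
  if (window_ms[1] < tms[1] - .time_eps ||
      window_ms[2] > tms[length(tms)] + .time_eps)
    stop_posterp("search window lies outside the epoch span")
  sel <- which(tms >= window_ms[1] - .time_eps & tms <= window_ms[2] + .time_eps)
  v <- evoked$data[row, sel]
  k <- if (polarity == "positive") which.max(v) else which.min(v)
  if (k == 1L || k == length(v))
    warning("extremum lies on the search-window boundary", call. = FALSE)
  list(amplitude_uv = v[k], latency_ms = tms[sel[k]])
}

#' Quantify components for one subject
#'
#' Applies the window specifications to each available condition evoked and
#' emits a tidy table: one row per condition x component x channel, with
#' the mean amplitude (pN, BP) or peak amplitude and latency (P1, N1).
#'
#' @param evokeds Named list of `evoked` objects (e.g. the `evokeds` field
#'   of [build_condition_evokeds()]); `NULL` entries are skipped.
#' @param subject Subject identifier stored in the table.
#' @param windows Window specifications, default
#'   [default_component_windows()].
#' @param conditions Conditions to measure (default `post_error` and
#'   `post_correct`).
#' @return A `data.frame` with columns `subject`, `condition`, `component`,
#'   `channel`, `value_uv`, `latency_ms`.
#' @export
measure_components <- function(evokeds, subject = NA_character_,
                               windows = default_component_windows(),
                               conditions = c("post_error", "post_correct")) {
  rows <- list()
  for (cond in intersect(conditions, names(evokeds))) {
    evk <- evokeds[[cond]]
    if (is.null(evk)) next
    for (w in windows) {
      for (ch in w$channels) {
        if (!ch %in% evk$channels) next
        if (identical(w$measure, "peak")) {
          pk <- suppressWarnings(peak_measure(evk, ch, w$window_ms,
                                              w$polarity))
          rows[[length(rows) + 1L]] <- data.frame(
            subject = subject, condition = cond, component = w$component,
            channel = ch, value_uv = pk$amplitude_uv,
            latency_ms = pk$latency_ms, stringsAsFactors = FALSE)
        } else {
          rows[[length(rows) + 1L]] <- data.frame(
            subject = subject, condition = cond, component = w$component,
            channel = ch, value_uv = mean_amplitude(evk, ch, w$window_ms),
            latency_ms = NA_real_, stringsAsFactors = FALSE)
        }
      }
    }
  }
  if (!length(rows))
    return(data.frame(subject = character(), condition = character(),
                      component = character(), channel = character(),
                      value_uv = numeric(), latency_ms = numeric(),
                      stringsAsFactors = FALSE))
  do.call(rbind, rows)
}
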