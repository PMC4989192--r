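#' Classify trials by outcome and sequential context
#'
#' Assigns each trial its outcome label (hit, miss, correct rejection,
#' false alarm) and its sequential context flags. A trial is `post_error`
#' iff the previous trial of the same block was a false alarm,
#' `post_correct` iff it was a hit or a correct rejection, and `pre_error`
#' iff the next trial of the same block is a false alarm. Trials whose
#' predecessor was a miss carry neither post flag (a miss is neither a
#' correctly responded trial nor a false alarm), and the first trial of
#' each block carries no post flag; context never crosses block boundaries.
#'
#' @param events An `event_log` data frame, sorted by onset within block.
#' @return A `data.frame` of class `context_labels` with columns `trial`,
#'   `block`, `outcome`, `post_error`, `post_correct`, `pre_error` and
#'   `block_initial`.
#' @export
classify_trials <- function(events) {
  ev <- as.data.frame(events)
  if (anyDuplicated(ev$trial))
    stop_posterp("duplicated trial indices")
  if (any(unlist(tapply(ev$onset_ms, ev$block, function(x) diff(x) <= 0))))
    stop_posterp("events must be sorted by onset within block")

  responded <- ev$response == 1L
  outcome <- ifelse(ev$category == "go",
                    ifelse(responded, "hit", "miss"),
                    ifelse(responded, "false_alarm", "correct_rejection"))

  n <- nrow(ev)
  post_error <- post_correct <- pre_error <- logical(n)
  block_initial <- logical(n)
  for (b in unique(ev$block)) {
    idx <- which(ev$block == b)
    block_initial[idx[1]] <- TRUE
    if (length(idx) > 1) {
      prev <- outcome[idx[-length(idx)]]
      cur <- idx[-1]
      post_error[cur] <- prev == "false_alarm"
      post_correct[cur] <- prev %in% c("hit", "correct_rejection")
      nxt <- outcome[idx[-1]]
      pre_error[idx[-length(idx)]] <- nxt == "false_alarm"
    }
  }
  structure(data.frame(
    trial = ev$trial, block = ev$block, outcome = outcome,
    post_error = post_error, post_correct = post_correct,
    pre_error = pre_error, block_initial = block_initial,
    stringsAsFactors = FALSE
  ), class = c("context_labels", "data.frame"))
}

#' Behavioral summary of one subject
#'
#' Computes the conditional false-alarm rates (probability of a false alarm
#' on a No-go trial given the previous trial's outcome), the median hit RTs
#' in the pre-error and post-error contexts, the median false-alarm RT,
#' post-error slowing (PES = post-error minus pre-error hit RT median;
#' positive = slowing) and post-error improvement of accuracy (PIA =
#' post-correct minus post-error FA rate; positive = improvement). Contexts
#' with no qualifying trials yield `NA` fields listed in `missing_fields`
#' rather than fabricated zeros.
#'
#' @param events An `event_log`.
#' @param labels Optional precomputed [classify_trials()] output.
#' @return A list of class `behavioral_summary` with fields
#'   `fa_rate_post_correct`, `fa_rate_post_error`,
#'   `median_rt_pre_error_hits`, `median_rt_post_error_hits`,
#'   `median_rt_fa`, `pes_ms`, `pia`, `n_fa`, trial counts per context and
#'   `missing_fields`.
#' @export
behavioral_summary <- function(events, labels = classify_trials(events)) {
  ev <- as.data.frame(events)
  out <- labels$outcome

  nogo_pc <- labels$post_correct & ev$category == "nogo"
  nogo_pe <- labels$post_error & ev$category == "nogo"
  rate <- function(sel) {
    if (!any(sel)) return(NA_real_)
    mean(out[sel] == "false_alarm")
  }
  med <- function(sel) {
    if (!any(sel)) return(NA_real_)
    stats::median(ev$rt_ms[sel])
  }
  pre_hits <- labels$pre_error & out == "hit"
  post_hits <- labels$post_error & out == "hit"
  fa <- out == "false_alarm"

  s <- list(
    fa_rate_post_correct = rate(nogo_pc),
    fa_rate_post_error = rate(nogo_pe),
    median_rt_pre_error_hits = med(pre_hits),
    median_rt_post_error_hits = med(post_hits),
    median_rt_fa = med(fa),
    n_fa = sum(fa),
    n_nogo_post_correct = sum(nogo_pc),
    n_fa_post_correct = sum(nogo_pc & fa),
    n_nogo_post_error = sum(nogo_pe),
    n_fa_post_error = sum(nogo_pe & fa),
    n_pre_error_hits = sum(pre_hits),
    n_post_error_hits = sum(post_hits)
  )
  s$pes_ms <- s$median_rt_post_error_hits - s$median_rt_pre_error_hits
  s$pia <- s$fa_rate_post_correct - s$fa_rate_post_error
  core <- c("fa_rate_post_correct", "fa_rate_post_error",
            "median_rt_pre_error_hits", "median_rt_post_error_hits",
            "median_rt_fa", "pes_ms", "pia")
  s$missing_fields <- core[vapply(s[core], is.na, logical(1))]
  structure(s, class = "behavioral_summary")
}

#' Signal-detection measures with ceiling/floor correction
#'
#' Hit rate H and false-alarm rate FA are corrected for the degenerate
#' proportions 0 and 1 before the normal-quantile transform: a rate of 1 is
#' replaced by 1 - 1/(2N) and a rate of 0 by 1/(2N), each on its own trial
#' count N. Sensitivity is d' = z(H) - z(FA) and the response criterion is
#' C = -(z(H) + z(FA))/2, with z the standard-normal quantile function.
#'
#' @param n_hits,n_misses Counts of hits and misses (Go trials).
#' @param n_fa,n_cr Counts of false alarms and correct rejections (No-go
#'   trials).
#' @return A list of class `sdt_result` with fields `hit_rate_corrected`,
#'   `fa_rate_corrected`, `d_prime` and `criterion_c`.
#' @examples
#' sdt_metrics(400, 0, 44, 356)
#' @export
sdt_metrics <- function(n_hits, n_misses, n_fa, n_cr) {
  n_go <- n_hits + n_misses
  n_nogo <- n_fa + n_cr
  if (n_go < 1 || n_nogo < 1)
    stop_posterp("need at least one Go and one No-go trial")
  correct_rate <- function(r, n) {
    if (r >= 1) return(1 - 1 / (2 * n))
    if (r <= 0) return(1 / (2 * n))
    r
  }
  h <- correct_rate(n_hits / n_go, n_go)
  f <- correct_rate(n_fa / n_nogo, n_nogo)
  structure(list(
    hit_rate_corrected = h,
    fa_rate_corrected = f,
    d_prime = stats::qnorm(h) - stats::qnorm(f),
    criterion_c = -(stats::qnorm(h) + stats::qnorm(f)) / 2
  ), class = "sdt_result")
}

#' Subject inclusion decisions
#'
#' A subject enters the group analysis only with at least one false alarm
#' and at least `min_clean_fa` artifact-free false-alarm epochs (the
#' boundary is inclusive: exactly `min_clean_fa` clean epochs is enough).
#'
#' @param counts Data frame with columns `subject`, `n_fa_total` and
#'   `n_fa_artifact_free`.
#' @param min_clean_fa Minimum number of artifact-free FA epochs.
#' @return `counts` with added columns `included` (logical) and
#'   `exclusion_reason` (`"none"`, `"no_fa"` or `"lt_min_clean_fa"`).
#' @export
select_subjects <- function(counts, min_clean_fa = 20L) {
  stopifnot(all(c("subject", "n_fa_total", "n_fa_artifact_free") %in%
                  names(counts)))
  reason <- ifelse(counts$n_fa_total < 1, "no_fa",
                   ifelse(counts$n_fa_artifact_free < min_clean_fa,
                          "lt_min_clean_fa", "none"))
  counts$included <- reason == "none"
  counts$exclusion_reason <- reason
  counts
}
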