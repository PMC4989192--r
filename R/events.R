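#' Generate a Go/No-go event sequence with behavioral outcomes
#'
#' Simulates one subject's event log. Stimulus identities are balanced
#' exactly within each block (so the default task yields exactly 400 Go and
#' 400 No-go trials on every seed) and shuffled within block; onsets are
#' strictly increasing with a per-trial SOA drawn uniformly from the task's
#' SOA range. Responses follow a first-order sequential rule: the
#' false-alarm probability on a No-go trial depends on whether the previous
#' trial (same block) was a false alarm, and hit RTs are drawn from the
#' post-error distribution whenever the previous trial was a false alarm,
#' otherwise from the pre-error distribution. The first trial of a block has
#' no predecessor and uses the after-correct parameters. Sequential context
#' never crosses block boundaries.
#'
#' RTs are drawn from a log-normal distribution parameterized by its median
#' and clipped to the 100--1000 ms response-assignment window.
#'
#' @param task A [task_config()].
#' @param profile A [behavior_profile()].
#' @param seed Optional integer seed; `NULL` continues the current RNG
#'   stream.
#' @param lead_in_ms Silence before the first stimulus (must cover the
#'   longest pre-stimulus epoch).
#' @param inter_block_gap_ms Rest gap inserted between blocks.
#' @return A `data.frame` of class `event_log` with columns `onset_ms`,
#'   `block`, `trial`, `category` ("go"/"nogo"), `stim_id`, `response`
#'   (1/0) and `rt_ms` (`NA` when no response was given).
#' @examples
#' ev <- generate_event_sequence(task_config(), behavior_profile(), seed = 1)
#' table(ev$category)
#' @export
generate_event_sequence <- function(task = task_config(),
                                    profile = behavior_profile(),
                                    seed = NULL,
                                    lead_in_ms = 2500,
                                    inter_block_gap_ms = 3000) {
  stopifnot(inherits(task, "task_config"), inherits(profile, "behavior_profile"))
  if (!is.null(seed)) set.seed(seed)

  n_go_ids <- round(task$go_fraction * task$n_categories)
  npb <- task$trials_per_block
  counts <- task$category_probability * npb
  exact <- all(abs(counts - round(counts)) < 1e-9)

  sigma_for <- function(med) profile$rt_spread_ms / med
  draw_rt <- function(med, n) {
    clamp(med * exp(sigma_for(med) * stats::rnorm(n)), 100, 1000)
  }

  blocks <- vector("list", task$n_blocks)
  t_cursor <- lead_in_ms
  trial_no <- 0L
  for (b in seq_len(task$n_blocks)) {
    if (exact) {
      ids <- sample(rep.int(seq_len(task$n_categories), round(counts)))
    } else {
      ids <- sample.int(task$n_categories, npb, replace = TRUE,
                        prob = task$category_probability)
    }
    category <- ifelse(ids <= n_go_ids, "go", "nogo")
    soa <- stats::runif(npb, task$soa_min_ms, task$soa_max_ms)
    onset <- t_cursor + cumsum(c(0, soa[-npb]))
    t_cursor <- onset[npb] + soa[npb] + inter_block_gap_ms

    response <- integer(npb)
    rt <- rep(NA_real_, npb)
    prev_fa <- FALSE
    for (i in seq_len(npb)) {
      if (category[i] == "go") {
        if (stats::runif(1) >= profile$p_miss) {
          response[i] <- 1L
          med <- if (prev_fa) profile$rt_hit_post_error_ms else
            profile$rt_hit_pre_error_ms
          rt[i] <- draw_rt(med, 1)
        }
        prev_fa <- FALSE
      } else {
        p_fa <- if (prev_fa) profile$p_fa_after_error else
          profile$p_fa_after_correct
        if (stats::runif(1) < p_fa) {
          response[i] <- 1L
          rt[i] <- draw_rt(profile$rt_fa_ms, 1)
          prev_fa <- TRUE
        } else {
          prev_fa <- FALSE
        }
      }
    }
    blocks[[b]] <- data.frame(
      onset_ms = onset, block = b,
      trial = trial_no + seq_len(npb),
      category = category, stim_id = ids,
      response = response, rt_ms = rt,
      stringsAsFactors = FALSE)
    trial_no <- trial_no + npb
  }
  out <- do.call(rbind, blocks)
  rownames(out) <- NULL
  class(out) <- c("event_log", "data.frame")
  attr(out, "sampling_rate_hz") <- task$sampling_rate_hz
  out
}

#' Write / read an event log
#'
#' Tab-separated dialect with columns `onset_ms`, `block`, `trial`,
#' `category` (`go`/`nogo`), `stim_id`, `response` (1/0) and `rt_ms` (empty
#' when no response was given). Times are in ms from recording start.
#'
#' @param events An `event_log` data frame.
#' @param path File path.
#' @return `write_event_log` returns `path` invisibly; `read_event_log`
#'   returns an `event_log` data frame.
#' @export
write_event_log <- function(events, path) {
  df <- as.data.frame(events)
  df$rt_ms <- ifelse(is.na(df$rt_ms), "", format(df$rt_ms, digits = 15))
  utils::write.table(df, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = TRUE)
  invisible(path)
}

#' @rdname write_event_log
#' @export
read_event_log <- function(path) {
  df <- utils::read.table(path, header = TRUE, sep = "\t",
                          stringsAsFactors = FALSE,
                          colClasses = c(onset_ms = "numeric",
                                         block = "integer",
                                         trial = "integer",
                                         category = "character",
                                         stim_id = "integer",
                                         response = "integer",
                                         rt_ms = "character"))
  df$rt_ms <- suppressWarnings(as.numeric(df$rt_ms))
  class(df) <- c("event_log", "data.frame")
  df
}
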