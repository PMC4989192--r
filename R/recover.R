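#' Parameter-recovery study
#'
#' Simulates `n_replicates` independent cohorts under the configuration and
#' pushes each through the full analysis pipeline, comparing what the
#' pipeline recovers with what the generator injected: the conditional
#' false-alarm probabilities (recovered as pooled empirical rates), the
#' post-error slowing (recovered as the mean per-subject median RT
#' difference), and the post-error condition gain ratios of the prefrontal
#' negativity and the Bereitschaftspotential (recovered as the ratio of the
#' group-mean window amplitudes, post-error over post-correct, averaged
#' over each component's channels). The Condition main-effect p-values of
#' the repeated-measures ANOVAs are collected as well.
#'
#' Subjects are simulated and analyzed one at a time, so memory stays flat
#' regardless of cohort size.
#'
#' @param config A [pipeline_config()]; its `n_subjects`, generator
#'   settings and preprocessing parameters define each replicate.
#' @param n_replicates Number of replicate cohorts.
#' @param seed Master seed for the whole study.
#' @return An object of class `recovery_result`: data frame `replicates`
#'   (one row per cohort) with attribute-free columns `fa_rate_post_correct`,
#'   `fa_rate_post_error`, `pes_ms`, `pn_ratio`, `bp_ratio`,
#'   `p_pn_condition`, `p_bp_condition`, `n_included`; plus `injected`
#'   (closed-form generating values) and `summary` (recovered means, bias,
#'   rejection rates).
#' @export
recover_parameters <- function(config = pipeline_config(),
                               n_replicates = 20L, seed = 1L) {
  stopifnot(n_replicates >= 1)
  set.seed(seed)
  rep_seeds <- sample.int(.Machine$integer.max - 1L, n_replicates)

  pn_gain <- if (!is.null(config$templates$pN))
    config$templates$pN$condition_scaling[["post_error"]] else NA_real_
  bp_gain <- if (!is.null(config$templates$BP))
    config$templates$BP$condition_scaling[["post_error"]] else NA_real_
  injected <- list(
    fa_rate_post_correct = config$profile$p_fa_after_correct,
    fa_rate_post_error = config$profile$p_fa_after_error,
    pes_ms = config$profile$rt_hit_post_error_ms -
      config$profile$rt_hit_pre_error_ms,
    pn_ratio = pn_gain, bp_ratio = bp_gain)

  rows <- vector("list", n_replicates)
  for (r in seq_len(n_replicates)) {
    set.seed(rep_seeds[r])
    subj_seeds <- sample.int(.Machine$integer.max - 1L, config$n_subjects)
    res <- vector("list", config$n_subjects)
    for (i in seq_len(config$n_subjects)) {
      s <- simulate_subject(config$task, config$profile, config$templates,
                            config$noise, config$montage, config$jitter,
                            seed = subj_seeds[i])
      res[[i]] <- analyze_subject(s$recording, s$events, config,
                                  subject = sprintf("s%02d", i))
    }
    counts <- data.frame(
      subject = vapply(res, `[[`, "", "subject"),
      n_fa_total = vapply(res, function(x) x$counts$n_fa_total, 0),
      n_fa_artifact_free = vapply(res,
                                  function(x) x$counts$n_fa_artifact_free, 0))
    inclusion <- select_subjects(counts, config$min_clean_fa)
    inc <- res[inclusion$included]

    # group rate = unweighted mean of per-subject rates (the estimator a
    # mean-percentage-of-FAs group summary uses); weighting by trial count
    # would bias it, because high-FA subjects contribute fewer post-correct
    # trials by construction
    subj_mean <- function(f) {
      v <- vapply(res, function(x) x$behavior[[f]], 0)
      mean(v, na.rm = TRUE)
    }
    pes <- vapply(res, function(x) x$behavior$pes_ms, 0)

    ratio_for <- function(comp) {
      if (!length(inc)) return(NA_real_)
      m <- do.call(rbind, lapply(inc, `[[`, "measures"))
      m <- m[m$component == comp, ]
      if (!nrow(m)) return(NA_real_)
      num <- mean(m$value_uv[m$condition == "post_error"])
      den <- mean(m$value_uv[m$condition == "post_correct"])
      if (den == 0) NA_real_ else num / den
    }
    p_for <- function(comp) {
      if (length(inc) < 2) return(NA_real_)
      m <- do.call(rbind, lapply(inc, `[[`, "measures"))
      m <- m[m$component == comp, ]
      if (!nrow(m) || length(unique(m$channel)) < 2) return(NA_real_)
      a <- rm_anova_2way(m, dv = "value_uv", subject = "subject",
                         within = c("condition", "channel"))
      a$table$p[a$table$effect == "condition"]
    }
    nsum <- function(f) sum(vapply(res, function(x) x$behavior[[f]], 0))
    rows[[r]] <- data.frame(
      replicate = r,
      fa_rate_post_correct = subj_mean("fa_rate_post_correct"),
      fa_rate_post_error = subj_mean("fa_rate_post_error"),
      n_nogo_post_correct = nsum("n_nogo_post_correct"),
      n_nogo_post_error = nsum("n_nogo_post_error"),
      pes_ms = mean(pes, na.rm = TRUE),
      pn_ratio = ratio_for("pN"),
      bp_ratio = ratio_for("BP"),
      p_pn_condition = p_for("pN"),
      p_bp_condition = p_for("BP"),
      n_included = sum(inclusion$included))
  }
  reps <- do.call(rbind, rows)
  alpha <- config$stats$alpha
  summ <- data.frame(
    parameter = c("fa_rate_post_correct", "fa_rate_post_error", "pes_ms",
                  "pn_ratio", "bp_ratio"),
    injected = unlist(injected),
    recovered = c(mean(reps$fa_rate_post_correct, na.rm = TRUE),
                  mean(reps$fa_rate_post_error, na.rm = TRUE),
                  mean(reps$pes_ms, na.rm = TRUE),
                  mean(reps$pn_ratio, na.rm = TRUE),
                  mean(reps$bp_ratio, na.rm = TRUE)),
    row.names = NULL)
  summ$bias <- summ$recovered - summ$injected
  structure(list(
    replicates = reps, injected = injected, summary = summ,
    pn_rejection_rate = mean(reps$p_pn_condition < alpha, na.rm = TRUE),
    bp_rejection_rate = mean(reps$p_bp_condition < alpha, na.rm = TRUE),
    alpha = alpha, n_replicates = n_replicates,
    n_subjects = config$n_subjects),
    class = "recovery_result")
}

#' @export
print.recovery_result <- function(x, ...) {
  cat(sprintf("Parameter recovery: %d replicate cohorts of %d subjects\n",
              x$n_replicates, x$n_subjects))
  s <- x$summary
  for (i in seq_len(nrow(s)))
    cat(sprintf("  %-22s injected %8.4f  recovered %8.4f  bias %+8.4f\n",
                s$parameter[i], s$injected[i], s$recovered[i], s$bias[i]))
  cat(sprintf("  pN Condition effect significant (alpha = %.2f) in %.0f%% of replicates\n",
              x$alpha, 100 * x$pn_rejection_rate))
  if (!is.nan(x$bp_rejection_rate))
    cat(sprintf("  BP Condition effect significant in %.0f%% of replicates\n",
                100 * x$bp_rejection_rate))
  invisible(x)
}

#' Null-effect configuration
#'
#' Derives a configuration in which the two sequential conditions are
#' exchangeable by construction: all condition gains are set to 1 and the
#' response-locked error components (Ne, Pe) are removed, because their
#' jitter-smeared tail is a real post-error/post-correct difference and
#' would contaminate a calibration check of the test's false-positive rate.
#' The behavioral RT medians are equalized as well. Intended for null
#' calibration of the repeated-measures ANOVA and for null PES checks.
#'
#' @param base Base [pipeline_config()].
#' @param n_subjects Cohort size for the null runs.
#' @param montage Channel subset (templates are restricted to it).
#' @return A `pipeline_config`.
#' @export
null_effect_config <- function(base = pipeline_config(), n_subjects = 12L,
                               montage = c("Fp1", "Fp2")) {
  tpl <- lapply(base$templates, function(tp) {
    if (tp$error_only) return(NULL)
    tp$condition_scaling[] <- 1
    tp
  })
  tpl <- tpl[!vapply(tpl, is.null, logical(1))]
  tpl <- restrict_templates(tpl, montage)
  prof <- base$profile
  prof$rt_hit_post_error_ms <- prof$rt_hit_pre_error_ms
  jit <- base$jitter
  jit$bp_rt_coupling_ms_per_uv <- 0
  pipeline_config(
    n_subjects = n_subjects, task = base$task, profile = prof,
    templates = tpl, noise = base$noise, montage = montage, jitter = jit,
    preprocessing = base$preprocessing, windows = base$windows,
    stats = base$stats, min_clean_fa = base$min_clean_fa,
    include_controls = FALSE, seed = base$seed)
}
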