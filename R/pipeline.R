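#' Pipeline configuration
#'
#' Bundles every tunable of the simulate -> analyze -> report pipeline into
#' one object. Every default equals the package's standard analysis
#' parameter: the (-1100, 900) ms epoch at 250 Hz, the +-120 uV rejection
#' threshold, the 25 Hz zero-phase Butterworth smoother, the epoch-initial
#' 200 ms baseline, the fixed component windows, alpha = 0.05 without
#' sphericity correction, and a 36-subject cohort with at least 20
#' artifact-free false-alarm epochs required for inclusion. The
#' configuration round-trips losslessly through YAML via [write_config()]
#' and [read_config()].
#'
#' @param n_subjects Cohort size.
#' @param task,profile,templates,noise,montage,jitter Generator settings
#'   (see [task_config()], [behavior_profile()], [default_templates()],
#'   [noise_model()], [default_montage()], [profile_jitter()]).
#' @param preprocessing List: `window_ms`, `threshold_uv`, `cutoff_hz`,
#'   `baseline_scheme`.
#' @param windows Component windows (`"fixed"` uses
#'   [default_component_windows()]; or pass a window list; or
#'   `"discover"` to derive pN/BP windows from the sample-wise t-test mask).
#' @param stats List: `alpha`, `gg_correction`.
#' @param min_clean_fa Inclusion threshold on artifact-free FA epochs.
#' @param include_controls Build the control segmentations per subject.
#' @param seed Master seed; all pipeline randomness flows from it.
#' @return An object of class `pipeline_config`.
#' @export
pipeline_config <- function(n_subjects = 36L,
                            task = task_config(),
                            profile = behavior_profile(),
                            templates = default_templates(),
                            noise = noise_model(),
                            montage = default_montage(),
                            jitter = profile_jitter(),
                            preprocessing = list(),
                            windows = "fixed",
                            stats = list(),
                            min_clean_fa = 20L,
                            include_controls = FALSE,
                            seed = 1L) {
  pp <- utils::modifyList(list(window_ms = c(-1100, 900), threshold_uv = 120,
                               cutoff_hz = 25,
                               baseline_scheme = "epoch_initial_200ms"),
                          preprocessing)
  st <- utils::modifyList(list(alpha = 0.05, gg_correction = FALSE), stats)
  structure(list(
    n_subjects = as.integer(n_subjects), task = task, profile = profile,
    templates = templates, noise = noise, montage = montage,
    jitter = jitter, preprocessing = pp, windows = windows, stats = st,
    min_clean_fa = as.integer(min_clean_fa),
    include_controls = include_controls, seed = as.integer(seed)
  ), class = "pipeline_config")
}

strip_classes <- function(x) {
  if (is.list(x)) {
    x <- lapply(x, strip_classes)
    attributes(x) <- list(names = names(x))
  } else if (!is.null(names(x))) {
    x <- as.list(x)  # named vectors become YAML maps, keeping the names
  }
  x
}

#' Write / read a pipeline configuration (YAML)
#'
#' @param config A [pipeline_config()].
#' @param path YAML file path.
#' @return `write_config` returns `path` invisibly; `read_config` returns a
#'   `pipeline_config`.
#' @export
write_config <- function(config, path) {
  stopifnot(inherits(config, "pipeline_config"))
  yaml::write_yaml(strip_classes(unclass(config)), path, precision = 15L)
  invisible(path)
}

#' @rdname write_config
#' @export
read_config <- function(path) {
  raw <- yaml::read_yaml(path)
  tpls <- lapply(raw$templates, function(tp)
    component_template(tp$name, tp$lock, unlist(tp$channel_weights),
                       tp$ramp_onset_ms, tp$peak_time_ms,
                       tp$peak_amplitude_uv, tp$offset_ms,
                       unlist(tp$condition_scaling), isTRUE(tp$error_only)))
  jit <- structure(raw$jitter, class = "profile_jitter")
  windows <- raw$windows
  if (is.list(windows)) windows <- lapply(windows, function(w) w)
  pipeline_config(
    n_subjects = raw$n_subjects,
    task = do.call(task_config, raw$task),
    profile = do.call(behavior_profile, raw$profile),
    templates = tpls,
    noise = do.call(noise_model, raw$noise),
    montage = unlist(raw$montage),
    jitter = jit,
    preprocessing = lapply(raw$preprocessing, function(x)
      if (is.list(x)) unlist(x) else x),
    windows = windows,
    stats = raw$stats,
    min_clean_fa = raw$min_clean_fa,
    include_controls = isTRUE(raw$include_controls),
    seed = raw$seed)
}

resolve_windows <- function(config) {
  if (identical(config$windows, "fixed") ||
      identical(config$windows, "discover"))
    default_component_windows()
  else config$windows
}

#' Analyze one subject
#'
#' Runs the per-subject stages: trial classification, behavioral summary,
#' signal-detection metrics, condition evokeds (with artifact rejection and
#' the clean false-alarm count that feeds subject inclusion), and component
#' quantification.
#'
#' @param recording An `eeg_recording`.
#' @param events An `event_log`.
#' @param config A [pipeline_config()].
#' @param subject Subject identifier.
#' @param keep_evokeds Keep the evoked waveforms in the result (memory).
#' @return List with `subject`, `behavior`, `sdt`, `counts`
#'   (`n_fa_total`, `n_fa_artifact_free`), `measures` and optionally
#'   `evokeds`/`controls`.
#' @export
analyze_subject <- function(recording, events, config = pipeline_config(),
                            subject = "s01", keep_evokeds = FALSE) {
  labels <- classify_trials(events)
  behavior <- behavioral_summary(events, labels)
  out <- labels$outcome
  sdt <- sdt_metrics(sum(out == "hit"), sum(out == "miss"),
                     sum(out == "false_alarm"),
                     sum(out == "correct_rejection"))
  pp <- config$preprocessing
  evk <- build_condition_evokeds(
    recording, events, labels, window_ms = pp$window_ms,
    threshold_uv = pp$threshold_uv, cutoff_hz = pp$cutoff_hz,
    baseline_scheme = pp$baseline_scheme,
    include_controls = config$include_controls)
  measures <- measure_components(evk$evokeds, subject,
                                 windows = resolve_windows(config))
  res <- list(
    subject = subject, behavior = behavior, sdt = sdt,
    counts = list(n_fa_total = behavior$n_fa,
                  n_fa_artifact_free =
                    unname(evk$counts["error", "n_retained"])),
    epoch_counts = evk$counts,
    measures = measures)
  if (keep_evokeds) {
    res$evokeds <- evk$evokeds
    res$controls <- evk$controls
  }
  res
}

#' Analyze a cohort
#'
#' Applies [analyze_subject()] to every subject, applies the inclusion rule
#' (at least one false alarm and at least `min_clean_fa` artifact-free FA
#' epochs), and builds the cohort report from the included subjects.
#'
#' @param cohort List of subject lists (`recording`, `events`), e.g. from
#'   [generate_cohort()].
#' @param config A [pipeline_config()].
#' @param keep_evokeds Keep per-subject evokeds (needed for the sample-wise
#'   t-test / window discovery mode; heavier in memory).
#' @return A `pea_report` (see [build_report()]), with the per-subject
#'   results attached as `subject_results`.
#' @export
analyze_cohort <- function(cohort, config = pipeline_config(),
                           keep_evokeds = identical(config$windows,
                                                    "discover")) {
  ids <- sprintf("s%02d", seq_along(cohort))
  results <- lapply(seq_along(cohort), function(i)
    analyze_subject(cohort[[i]]$recording, cohort[[i]]$events, config,
                    subject = ids[i], keep_evokeds = keep_evokeds))
  windows <- NULL
  if (identical(config$windows, "discover")) {
    disc <- discover_windows(results, config)
    windows <- disc$windows
    for (i in seq_along(results))
      results[[i]]$measures <- measure_components(
        results[[i]]$evokeds, results[[i]]$subject, windows)
  }
  report <- build_report(results, config)
  if (!is.null(windows)) report$windows <- windows
  report$subject_results <- results
  report
}

# Data-driven refinement of the pN/BP quantification windows: a
# sample-wise paired t-test (post-error vs post-correct) across subjects,
# then the longest >=40 ms run of consecutive significance within the
# pre-stimulus search range. Falls back to the fixed defaults when no run
# qualifies or too few subjects carry both conditions.
discover_windows <- function(results, config) {
  wins <- default_component_windows()
  ev_a <- lapply(results, function(r) r$evokeds$post_error)
  ev_b <- lapply(results, function(r) r$evokeds$post_correct)
  ok <- sum(!vapply(ev_a, is.null, logical(1)) &
              !vapply(ev_b, is.null, logical(1)))
  if (ok < 3) return(list(windows = wins, mask = NULL))
  first <- which(!vapply(ev_a, is.null, logical(1)))[1]
  montage <- ev_a[[first]]$channels
  for (comp in c("pN", "BP")) {
    chans <- intersect(wins[[comp]]$channels, montage)
    if (!length(chans)) next
    mask <- samplewise_paired_ttest(ev_a, ev_b, chans,
                                    alpha = config$stats$alpha)
    w <- select_window(mask, chans, min_duration_ms = 40,
                       search_ms = c(-1000, 0), name = comp)
    if (!is.null(w)) wins[[comp]]$window_ms <- w$window_ms
  }
  list(windows = wins)
}

group_paired_t <- function(x, y) {
  ok <- stats::complete.cases(x, y)
  if (sum(ok) < 2) return(NULL)
  c(paired_t_test(x[ok], y[ok]), list(n_used = sum(ok)))
}

#' Build the cohort report
#'
#' Assembles the full inferential layer from per-subject analysis results:
#' the inclusion ledger; the behavioral table with paired t-tests for the
#' post-error improvement of accuracy (FA rate post-correct vs post-error)
#' and post-error slowing (post-error vs pre-error hit RT medians) plus the
#' FA-RT comparisons; group signal-detection means; the component table
#' (cell means and SDs); two-way repeated-measures ANOVAs
#' (Condition x Site) for the prefrontal negativity (Fp1, Fp2) and the
#' Bereitschaftspotential (C1, Cz, C2) with Bonferroni site post-hocs
#' within each condition; paired t-tests for P1/N1 amplitude and latency;
#' Pearson correlations between post-error component amplitudes and the
#' post-error median hit RT; and percent-change effect summaries for pN and
#' BP. Sections that need more subjects than are available are reported
#' absent with the reason `"insufficient n"`.
#'
#' @param subject_results List of [analyze_subject()] results.
#' @param config A [pipeline_config()].
#' @return An object of class `pea_report`.
#' @export
build_report <- function(subject_results, config = pipeline_config()) {
  counts <- data.frame(
    subject = vapply(subject_results, `[[`, "", "subject"),
    n_fa_total = vapply(subject_results,
                        function(r) r$counts$n_fa_total, 0),
    n_fa_artifact_free = vapply(subject_results,
                                function(r) r$counts$n_fa_artifact_free, 0),
    stringsAsFactors = FALSE)
  inclusion <- select_subjects(counts, config$min_clean_fa)
  inc <- subject_results[inclusion$included]
  n <- length(inc)
  alpha <- config$stats$alpha

  report <- list(
    meta = list(n_total = length(subject_results), n_included = n,
                min_clean_fa = config$min_clean_fa, alpha = alpha,
                seed = config$seed),
    inclusion = inclusion)
  if (n == 0) {
    report$reason <- "no analyzable subjects"
    class(report) <- "pea_report"
    return(report)
  }

  bfield <- function(f) vapply(inc, function(r) r$behavior[[f]], 0)
  behavior <- data.frame(
    subject = vapply(inc, `[[`, "", "subject"),
    fa_rate_post_correct = bfield("fa_rate_post_correct"),
    fa_rate_post_error = bfield("fa_rate_post_error"),
    median_rt_pre_error_hits = bfield("median_rt_pre_error_hits"),
    median_rt_post_error_hits = bfield("median_rt_post_error_hits"),
    median_rt_fa = bfield("median_rt_fa"),
    pes_ms = bfield("pes_ms"),
    pia = bfield("pia"),
    n_fa = bfield("n_fa"),
    stringsAsFactors = FALSE)
  report$behavior <- behavior
  report$behavior_group <- data.frame(
    measure = names(behavior)[-1],
    mean = vapply(behavior[-1], function(v) mean(v, na.rm = TRUE), 0),
    sd = vapply(behavior[-1], function(v) stats::sd(v, na.rm = TRUE), 0),
    row.names = NULL, stringsAsFactors = FALSE)
  report$behavior_tests <- list(
    pia = group_paired_t(behavior$fa_rate_post_correct,
                         behavior$fa_rate_post_error),
    pes = group_paired_t(behavior$median_rt_post_error_hits,
                         behavior$median_rt_pre_error_hits),
    fa_rt_vs_pre_error = group_paired_t(behavior$median_rt_fa,
                                        behavior$median_rt_pre_error_hits),
    fa_rt_vs_post_error = group_paired_t(behavior$median_rt_fa,
                                         behavior$median_rt_post_error_hits))

  sdt <- data.frame(
    d_prime = vapply(inc, function(r) r$sdt$d_prime, 0),
    criterion_c = vapply(inc, function(r) r$sdt$criterion_c, 0))
  report$sdt_group <- data.frame(
    measure = names(sdt),
    mean = colMeans(sdt), sd = vapply(sdt, stats::sd, 0),
    row.names = NULL, stringsAsFactors = FALSE)

  measures <- do.call(rbind, lapply(inc, `[[`, "measures"))
  report$components <- measures
  cell_stats <- function(comp, value = "value_uv") {
    d <- measures[measures$component == comp, ]
    if (!nrow(d)) return(NULL)
    ag <- stats::aggregate(d[[value]],
                           list(condition = d$condition, channel = d$channel),
                           function(v) c(mean = mean(v), sd = stats::sd(v)))
    data.frame(ag[1:2], mean = ag$x[, "mean"], sd = ag$x[, "sd"])
  }
  report$component_cells <- do.call(rbind, lapply(
    c("pN", "BP", "P1", "N1"),
    function(cp) {
      cs <- cell_stats(cp)
      if (is.null(cs)) return(NULL)
      cbind(component = cp, cs)
    }))

  anova_for <- function(comp) {
    d <- measures[measures$component == comp, ]
    if (n < 2 || !nrow(d) ||
        length(unique(d$condition)) < 2 || length(unique(d$channel)) < 2)
      return(list(reason = "insufficient n"))
    rm_anova_2way(d, dv = "value_uv", subject = "subject",
                  within = c("condition", "channel"),
                  gg_correction = config$stats$gg_correction)
  }
  report$anova_pn <- anova_for("pN")
  report$anova_bp <- anova_for("BP")

  posthoc_for <- function(comp) {
    d <- measures[measures$component == comp, ]
    if (n < 2 || !nrow(d) || length(unique(d$channel)) < 2) return(NULL)
    conds <- unique(d$condition)
    n_pairs <- ncol(utils::combn(unique(d$channel), 2))
    K <- n_pairs * length(conds)  # family: site pairs within each condition
    out <- lapply(conds, function(cc) {
      ph <- bonferroni_pairwise(d[d$condition == cc, ], dv = "value_uv",
                                subject = "subject", factor = "channel",
                                n_comparisons = K, alpha = alpha)
      cbind(condition = cc, ph)
    })
    do.call(rbind, out)
  }
  report$posthoc_pn <- posthoc_for("pN")
  report$posthoc_bp <- posthoc_for("BP")

  peak_tests <- function(comp) {
    d <- measures[measures$component == comp, ]
    if (n < 2 || !nrow(d)) return(NULL)
    pe <- d[d$condition == "post_error", ]
    pc <- d[d$condition == "post_correct", ]
    m <- merge(pe, pc, by = "subject", suffixes = c("_pe", "_pc"))
    list(amplitude = group_paired_t(m$value_uv_pe, m$value_uv_pc),
         latency = group_paired_t(m$latency_ms_pe, m$latency_ms_pc))
  }
  report$ttest_p1 <- peak_tests("P1")
  report$ttest_n1 <- peak_tests("N1")

  # correlations: post-error component amplitude vs post-error median hit RT
  cors <- list()
  rt <- behavior$median_rt_post_error_hits
  for (spec in list(c("BP", "C1"), c("BP", "Cz"), c("BP", "C2"),
                    c("pN", "Fp1"), c("pN", "Fp2"))) {
    d <- measures[measures$component == spec[1] &
                    measures$channel == spec[2] &
                    measures$condition == "post_error", ]
    d <- d[match(behavior$subject, d$subject), ]
    ok <- stats::complete.cases(d$value_uv, rt)
    nm <- paste0(tolower(spec[1]), "_", spec[2], "_vs_rt")
    cors[[nm]] <- if (sum(ok) >= 3)
      pearson_r(d$value_uv[ok], rt[ok]) else NULL
  }
  report$correlations <- cors

  pct_for <- function(comp) {
    cs <- cell_stats(comp)
    if (is.null(cs)) return(NULL)
    ref <- mean(cs$mean[cs$condition == "post_correct"])
    test <- mean(cs$mean[cs$condition == "post_error"])
    if (ref == 0 || (test != 0 && sign(ref) != sign(test)))
      return(list(reason = "sign-discordant or zero reference",
                  reference_uv = ref, test_uv = test))
    c(effect_percent_change(ref, test),
      list(reference_uv = ref, test_uv = test))
  }
  report$percent_change_pn <- pct_for("pN")
  report$percent_change_bp <- pct_for("BP")

  class(report) <- "pea_report"
  report
}

#' @export
print.pea_report <- function(x, ...) {
  cat("Post-error adjustment cohort report\n")
  cat(sprintf("  subjects: %d analyzed, %d included (>= %d clean FA epochs)\n",
              x$meta$n_total, x$meta$n_included, x$meta$min_clean_fa))
  if (!is.null(x$reason)) {
    cat("  ", x$reason, "\n")
    return(invisible(x))
  }
  bg <- x$behavior_group
  gv <- function(m) bg$mean[bg$measure == m]
  cat(sprintf("  FA rate: %.1f%% post-correct vs %.1f%% post-error (PIA %.1f points)\n",
              100 * gv("fa_rate_post_correct"), 100 * gv("fa_rate_post_error"),
              100 * gv("pia")))
  cat(sprintf("  hit RT median: %.0f ms pre-error vs %.0f ms post-error (PES %.0f ms)\n",
              gv("median_rt_pre_error_hits"), gv("median_rt_post_error_hits"),
              gv("pes_ms")))
  sg <- x$sdt_group
  cat(sprintf("  d' = %.2f, criterion C = %.2f\n",
              sg$mean[sg$measure == "d_prime"],
              sg$mean[sg$measure == "criterion_c"]))
  for (nm in c("anova_pn", "anova_bp")) {
    a <- x[[nm]]
    lab <- if (nm == "anova_pn") "pN" else "BP"
    if (inherits(a, "rm_anova")) {
      r <- a$table[1, ]
      cat(sprintf("  %s Condition: F(%d,%d) = %.2f, p = %.4g\n",
                  lab, r$df1, r$df2, r$F, r$p))
    } else cat(sprintf("  %s ANOVA: %s\n", lab, a$reason))
  }
  pc <- x$percent_change_bp
  if (!is.null(pc$percent))
    cat(sprintf("  BP percent change (post-error vs post-correct): %d%%\n",
                pc$percent_rounded))
  pc <- x$percent_change_pn
  if (!is.null(pc$percent))
    cat(sprintf("  pN percent change (post-error vs post-correct): %+d%%\n",
                pc$percent_rounded))
  invisible(x)
}

#' @export
summary.pea_report <- function(object, ...) {
  print(object)
  if (!is.null(object$correlations)) {
    cat("  correlations with post-error hit RT:\n")
    for (nm in names(object$correlations)) {
      cr <- object$correlations[[nm]]
      if (!is.null(cr))
        cat(sprintf("    %-16s r = %+.2f (n = %d, p = %.3g)\n",
                    nm, cr$r, cr$n, cr$p))
    }
  }
  invisible(object)
}

report_to_list <- function(report) {
  clean <- function(x) {
    if (inherits(x, "rm_anova"))
      return(list(table = x$table, cells = x$cells, n = x$n))
    if (is.data.frame(x)) return(x)
    if (is.list(x)) return(lapply(x, clean))
    x
  }
  keep <- setdiff(names(report), "subject_results")
  lapply(report[keep], clean)
}

#' Write a cohort report to disk
#'
#' Machine-readable JSON plus tab-separated tables for the inclusion
#' ledger, behavioral summaries, component measures and ANOVA tables.
#'
#' @param report A `pea_report`.
#' @param dir Output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_report <- function(report, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  jsonlite::write_json(report_to_list(report),
                       file.path(dir, "report.json"),
                       auto_unbox = TRUE, digits = NA, na = "null",
                       force = TRUE)
  wt <- function(df, name) {
    if (!is.null(df) && is.data.frame(df) && nrow(df))
      utils::write.table(df, file.path(dir, name), sep = "\t",
                         quote = FALSE, row.names = FALSE)
  }
  wt(report$inclusion, "inclusion.tsv")
  wt(report$behavior, "behavior.tsv")
  wt(report$components, "components.tsv")
  wt(report$component_cells, "component_cells.tsv")
  if (inherits(report$anova_pn, "rm_anova"))
    wt(report$anova_pn$table, "anova_pn.tsv")
  if (inherits(report$anova_bp, "rm_anova"))
    wt(report$anova_bp$table, "anova_bp.tsv")
  wt(report$posthoc_pn, "posthoc_pn.tsv")
  wt(report$posthoc_bp, "posthoc_bp.tsv")
  invisible(dir)
}
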