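#' Two-way repeated-measures ANOVA
#'
#' Classical within-subject partitioning for a complete balanced design
#' with two within-subject factors: each effect's mean square is tested
#' against its own subject-by-effect interaction mean square
#' (`Error(subject/(A*B))` in `aov` terms). No sphericity correction is
#' applied by default, so the degrees of freedom are the integer design
#' values (factor A at 2 levels: df = (1, n-1); factor B at 3 levels:
#' df = (2, 2(n-1))). A Greenhouse-Geisser correction of the p-values is
#' available behind `gg_correction = TRUE`.
#'
#' @param data Long data frame: one measurement per subject x factor cell.
#' @param dv Name of the dependent-variable column.
#' @param subject Name of the subject column.
#' @param within Character vector of the two within-subject factor columns.
#' @param gg_correction Apply Greenhouse-Geisser-adjusted p-values.
#' @return An object of class `rm_anova`: data frame `table` with one row
#'   per effect (`effect`, `df1`, `df2`, `F`, `p`), plus `cells` (per-cell
#'   means and SDs) and `n` (subjects).
#' @examples
#' d <- expand.grid(subject = paste0("s", 1:6),
#'                  condition = c("post_correct", "post_error"),
#'                  channel = c("C1", "Cz", "C2"))
#' d$value_uv <- rnorm(nrow(d))
#' rm_anova_2way(d, dv = "value_uv", within = c("condition", "channel"))
#' @export
rm_anova_2way <- function(data, dv = "value_uv", subject = "subject",
                          within = c("condition", "channel"),
                          gg_correction = FALSE) {
  stopifnot(length(within) == 2)
  d <- data.frame(S = factor(data[[subject]]),
                  A = factor(data[[within[1]]]),
                  B = factor(data[[within[2]]]),
                  y = data[[dv]])
  if (anyNA(d$y)) stop_posterp("missing values in the measure table")
  tab <- table(d$S, d$A, d$B)
  if (any(tab != 1))
    stop_posterp("design must be complete and balanced: one value per ",
                 "subject x cell (no silent imputation)")
  if (nlevels(d$A) < 2 || nlevels(d$B) < 2)
    stop_posterp("each within-subject factor needs at least 2 levels")
  n <- nlevels(d$S)
  if (n < 2) stop_posterp("insufficient n: need at least 2 subjects")

  fit <- stats::aov(y ~ A * B + Error(S / (A * B)), data = d)
  sm <- summary(fit)
  pick <- function(stratum, term) {
    tb <- sm[[stratum]][[1]]
    rn <- trimws(rownames(tb))
    i <- match(term, rn)
    j <- match("Residuals", rn)
    Fv <- tb$`F value`[i]
    pv <- tb$`Pr(>F)`[i]
    if (tb$`Sum Sq`[i] < 1e-12) {          # no effect variance at all
      Fv <- 0; pv <- 1
    } else if (tb$`Sum Sq`[j] < 1e-12) {   # perfectly consistent effect
      Fv <- Inf; pv <- 0
    }
    data.frame(effect = term, df1 = tb$Df[i], df2 = tb$Df[j],
               F = Fv, p = pv, stringsAsFactors = FALSE)
  }
  res <- rbind(pick("Error: S:A", "A"),
               pick("Error: S:B", "B"),
               pick("Error: S:A:B", "A:B"))
  res$effect <- c(within[1], within[2], paste(within, collapse = ":"))

  if (gg_correction) {
    # Greenhouse-Geisser epsilon from the double-centered covariance of the
    # within-cell matrix for each effect's contrast space; only multi-df
    # effects are adjusted.
    res$p_gg <- res$p
    eps <- function(Y) {           # subjects x levels matrix
      Sg <- stats::cov(Y)
      k <- ncol(Y)
      C <- diag(k) - 1 / k
      Sc <- C %*% Sg %*% C
      sum(diag(Sc))^2 / ((k - 1) * sum(Sc^2))
    }
    wide_B <- stats::xtabs(y ~ S + B, stats::aggregate(y ~ S + B, d, mean))
    eB <- eps(as.matrix(wide_B))
    res$p_gg[2] <- stats::pf(res$F[2], res$df1[2] * eB, res$df2[2] * eB,
                             lower.tail = FALSE)
    res$p_gg[3] <- NA_real_  # interaction left uncorrected
  }

  cells <- stats::aggregate(y ~ A + B, d,
                            function(v) c(mean = mean(v), sd = stats::sd(v)))
  cells <- data.frame(cells$A, cells$B, cells$y)
  names(cells) <- c(within, "mean", "sd")
  structure(list(table = res, cells = cells, n = n, dv = dv,
                 within = within),
            class = "rm_anova")
}

#' @export
print.rm_anova <- function(x, ...) {
  cat(sprintf("Repeated-measures ANOVA (%s), n = %d subjects\n", x$dv, x$n))
  tb <- x$table
  for (i in seq_len(nrow(tb)))
    cat(sprintf("  %-24s F(%d,%d) = %.3f, p = %.4g\n",
                tb$effect[i], tb$df1[i], tb$df2[i], tb$F[i], tb$p[i]))
  invisible(x)
}

#' Bonferroni-corrected pairwise comparisons
#'
#' Paired t-tests within subject over all unordered level pairs of one
#' within-subject factor, with multiplied-p Bonferroni adjustment:
#' adjusted p = min(1, raw p x number of comparisons). The multiplier
#' defaults to the number of pairs tested but can be set to the size of a
#' larger comparison family.
#'
#' @param data Long data frame with one value per subject x level.
#' @param dv,subject,factor Column names.
#' @param n_comparisons Bonferroni multiplier (default: number of pairs).
#' @param alpha Significance level for the `significant` flag.
#' @return Data frame of class `pairwise_comparisons`: `level_a`,
#'   `level_b`, `mean_diff`, `t`, `df`, `p_raw`, `p_bonferroni`,
#'   `significant`.
#' @export
bonferroni_pairwise <- function(data, dv = "value_uv", subject = "subject",
                                factor = "condition", n_comparisons = NULL,
                                alpha = 0.05) {
  d <- data.frame(S = factor(data[[subject]]),
                  L = factor(data[[factor]]),
                  y = data[[dv]])
  agg <- stats::aggregate(y ~ S + L, d, mean)
  wide <- stats::reshape(agg, idvar = "S", timevar = "L",
                         direction = "wide")
  levs <- levels(d$L)
  if (length(levs) < 2) stop_posterp("need at least 2 levels")
  prs <- utils::combn(levs, 2)
  K <- n_comparisons %||% ncol(prs)
  rows <- lapply(seq_len(ncol(prs)), function(i) {
    a <- wide[[paste0("y.", prs[1, i])]]
    b <- wide[[paste0("y.", prs[2, i])]]
    tt <- paired_t_test(a, b)
    data.frame(level_a = prs[1, i], level_b = prs[2, i],
               mean_diff = mean(a - b), t = tt$t, df = tt$df,
               p_raw = tt$p, stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  out$p_bonferroni <- pmin(1, out$p_raw * K)
  out$significant <- out$p_bonferroni < alpha
  class(out) <- c("pairwise_comparisons", "data.frame")
  out
}

#' Paired t-test
#'
#' Standard two-tailed paired t-test. When the differences have zero
#' variance the statistic is degenerate: a signed infinite t is reported
#' with p = 0 (flagged), or t = 0 with p = 1 when the sequences are
#' identical.
#'
#' @param a,b Equal-length per-subject value sequences (length >= 2).
#' @return List with `t`, `df`, `p`, `mean_diff`, `n` and `degenerate`.
#' @examples
#' paired_t_test(c(2, 4, 6), c(1, 2, 3))  # differences 1, 2, 3
#' @export
paired_t_test <- function(a, b) {
  stopifnot(length(a) == length(b), length(a) >= 2)
  d <- a - b
  n <- length(d)
  if (stats::sd(d) == 0) {
    if (mean(d) == 0)
      return(list(t = 0, df = n - 1, p = 1, mean_diff = 0, n = n,
                  degenerate = TRUE))
    return(list(t = sign(mean(d)) * Inf, df = n - 1, p = 0,
                mean_diff = mean(d), n = n, degenerate = TRUE))
  }
  tt <- stats::t.test(a, b, paired = TRUE)
  list(t = unname(tt$statistic), df = unname(tt$parameter),
       p = tt$p.value, mean_diff = mean(d), n = n, degenerate = FALSE)
}

#' Pearson correlation with two-tailed p
#'
#' Product-moment correlation with the p-value from the t transform
#' (`cor.test`). Errors on zero variance in either variable.
#'
#' @param x,y Equal-length numeric vectors (length >= 3).
#' @return List of class `correlation_result`: `r`, `n`, `t`, `p`.
#' @export
pearson_r <- function(x, y) {
  stopifnot(length(x) == length(y))
  if (length(x) < 3) stop_posterp("need at least 3 paired observations")
  if (stats::sd(x) == 0 || stats::sd(y) == 0)
    stop_posterp("zero variance in one of the variables")
  ct <- stats::cor.test(x, y, method = "pearson")
  structure(list(r = unname(ct$estimate), n = length(x),
                 t = unname(ct$statistic), p = ct$p.value),
            class = "correlation_result")
}

#' Percent amplitude change between two like-signed amplitudes
#'
#' `100 * (|test| - |reference|) / |reference|`: negative values are
#' amplitude reductions, positive values enhancements. Works on magnitudes
#' so the convention matches how negative-going components are described
#' ("smaller" meaning less negative). Sign-discordant inputs are rejected.
#'
#' @param reference_uv,test_uv Amplitudes of like sign (microvolts);
#'   `reference_uv` must be non-zero.
#' @return List with `percent` (full precision) and `percent_rounded`
#'   (nearest integer).
#' @examples
#' effect_percent_change(-1.8, -0.8)  # 56% reduction
#' @export
effect_percent_change <- function(reference_uv, test_uv) {
  if (reference_uv == 0) stop_posterp("reference amplitude must be non-zero")
  if (test_uv != 0 && sign(reference_uv) != sign(test_uv))
    stop_posterp("sign-discordant amplitudes: percent change is undefined")
  pct <- 100 * (abs(test_uv) - abs(reference_uv)) / abs(reference_uv)
  list(percent = pct, percent_rounded = round(pct))
}
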