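test_that("mean amplitude: constants, ramps, linearity", {
  times <- seq(-600, 0, by = 4)
  const <- make_evoked_obj(matrix(-3, 1, length(times)), "Fp1", times)
  expect_equal(mean_amplitude(const, "Fp1", c(-600, 0)), -3)
  # linear ramp 0 -> -2 over the window: midpoint -1
  ramp <- make_evoked_obj(matrix(seq(0, -2, length.out = length(times)), 1),
                          "Fp1", times)
  expect_equal(mean_amplitude(ramp, "Fp1", c(-600, 0)), -1)
  # linear in the waveform
  ramp3 <- ramp; ramp3$data <- 3 * ramp$data
  expect_equal(mean_amplitude(ramp3, "Fp1", c(-600, 0)),
               3 * mean_amplitude(ramp, "Fp1", c(-600, 0)))
  expect_error(mean_amplitude(ramp, "Fp1", c(-700, 0)), "outside")
  expect_error(mean_amplitude(ramp, "Oz", c(-600, 0)), "unknown channel")
})

test_that("peak measure finds the stated polarity with earliest-tie rule", {
  times <- seq(0, 400, by = 4)
  v <- pmax(0, 4 * (1 - abs(times - 100) / 60))  # triangular pulse at 100 ms
  ev <- make_evoked_obj(matrix(v, 1), "PO8", times)
  pk <- peak_measure(ev, "PO8", c(0, 400), "positive")
  expect_equal(pk$amplitude_uv, 4)
  expect_equal(pk$latency_ms, 100)
  ev_neg <- make_evoked_obj(matrix(-v, 1), "PO7", times)
  pk2 <- peak_measure(ev_neg, "PO7", c(0, 400), "negative")
  expect_equal(pk2$amplitude_uv, -4)
  expect_equal(pk2$latency_ms, 100)
  # tie broken toward the earliest sample
  flat <- make_evoked_obj(matrix(c(0, 1, 1, 0, 0), 1), "PO8",
                          seq(0, 16, by = 4))
  expect_equal(peak_measure(flat, "PO8", c(0, 16), "positive")$latency_ms, 4)
  # extremum on a window edge warns
  mono <- make_evoked_obj(matrix(seq(0, 1, length.out = 5), 1), "PO8",
                          seq(0, 16, by = 4))
  expect_warning(peak_measure(mono, "PO8", c(0, 16), "positive"), "boundary")
})

test_that("noiseless simulated P1 is recovered exactly at PO8", {
  ev <- make_events("go", 1L)
  rec <- render_recording(ev, default_templates()["P1"], quiet_noise(),
                          c("PO7", "PO8"), seed = 1)
  ep <- average_epochs(segment_epochs(rec, ev))
  pk <- peak_measure(ep, "PO8", c(60, 160), "positive")
  # the 110 ms analytic peak falls between samples at 250 Hz; the largest
  # sampled value sits at 112 ms on the falling limb: 4 * 58/60
  expect_equal(pk$amplitude_uv, 4 * 58 / 60, tolerance = 1e-9)
  expect_equal(pk$latency_ms, 112)
})

test_that("sample-wise paired t-test flags differences and stays silent under null", {
  times <- seq(-600, 0, by = 4)
  n_smp <- length(times)
  mk <- function(m) make_evoked_obj(matrix(m, 1, n_smp), "Fp1", times)
  # identical conditions: nothing significant
  a <- lapply(1:5, function(i) mk(rnorm(n_smp)))
  msk <- samplewise_paired_ttest(a, a, "Fp1")
  expect_false(any(msk$sig))
  # constant offset with zero noise: everything significant
  b <- lapply(a, function(e) { e$data <- e$data + 1; e })
  msk2 <- samplewise_paired_ttest(b, a, "Fp1")
  expect_true(all(msk2$sig))
  expect_true(all(msk2$t == Inf))
  # null calibration of the per-sample false-positive rate
  set.seed(77)
  n_sub <- 12
  reps <- replicate(30, {
    a1 <- lapply(seq_len(n_sub), function(i) mk(rnorm(n_smp)))
    b1 <- lapply(seq_len(n_sub), function(i) mk(rnorm(n_smp)))
    mean(samplewise_paired_ttest(a1, b1, "Fp1")$sig)
  })
  fpr <- mean(reps)
  n_tests <- 30 * n_smp
  expect_lt(abs(fpr - 0.05), 3 * sqrt(0.05 * 0.95 / n_tests))
  # fewer than 3 complete pairs errors; NULL subjects are dropped pairwise
  expect_error(samplewise_paired_ttest(a[1:2], a[1:2], "Fp1"), "3 subjects")
  a_na <- a; a_na[1] <- list(NULL)
  msk3 <- samplewise_paired_ttest(a_na, a, "Fp1")
  expect_equal(msk3$n, 4)
  expect_equal(msk3$n_dropped, 1)
})

test_that("select_window returns the longest qualifying significant run", {
  times <- seq(-600, 0, by = 4)
  n <- length(times)
  mkmask <- function(sig) {
    structure(list(t = matrix(0, 1, n), p = matrix(ifelse(sig, 0.01, 0.5), 1),
                   sig = matrix(sig, 1), times_ms = times, channels = "Fp1",
                   alpha = 0.05, n = 10, n_dropped = 0),
              class = "significance_mask")
  }
  # all significant: the whole search range
  w <- select_window(mkmask(rep(TRUE, n)), "Fp1", search_ms = c(-600, 0))
  expect_equal(w$window_ms, c(-600, 0))
  # alternating single samples: no 40 ms run
  expect_null(select_window(mkmask(rep(c(TRUE, FALSE), length.out = n)),
                            "Fp1"))
  # runs of 100 ms and 200 ms: the 200 ms run wins (brute-force oracle)
  sig <- rep(FALSE, n)
  sig[10:35] <- TRUE   # 26 samples = 100 ms
  sig[60:110] <- TRUE  # 51 samples = 200 ms
  w2 <- select_window(mkmask(sig), "Fp1")
  runs <- rle(sig)
  ends <- cumsum(runs$lengths)
  best <- which(runs$values & runs$lengths == max(runs$lengths[runs$values]))
  expect_equal(w2$window_ms,
               c(times[ends[best] - runs$lengths[best] + 1], times[ends[best]]))
  # invariance to samples outside the search range
  sig2 <- sig; sig2[1:5] <- TRUE
  w3 <- select_window(mkmask(sig2), "Fp1", search_ms = c(times[8], 0))
  expect_equal(w3$window_ms, w2$window_ms)
})

test_that("component quantification emits one tidy row per measure", {
  times <- seq(-1100, 900, by = 4)
  mont <- c("Fp1", "Fp2", "C1", "Cz", "C2", "PO7", "PO8")
  dat <- matrix(0, length(mont), length(times))
  rownames(dat) <- mont
  evo <- make_evoked_obj(dat, mont, times)
  evo$data["Fp1", times <= 0 & times >= -600] <- -2
  out <- measure_components(list(post_error = evo, post_correct = evo), "s1")
  expect_equal(nrow(out), 14)  # (2+3+1+1) channels x 2 conditions
  expect_equal(out$value_uv[out$channel == "Fp1" & out$component == "pN"],
               c(-2, -2))
  expect_true(all(is.na(out$latency_ms[out$component %in% c("pN", "BP")])))
  expect_true(all(!is.na(out$latency_ms[out$component %in% c("P1", "N1")])))
})
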