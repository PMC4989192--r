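test_that("the default epoch frame has 501 samples with the lock at t = 0", {
  ev <- make_events("go", 1L)
  rec <- make_recording(matrix(rnorm(2 * 2500), 2), c("Fp1", "Cz"))
  ep <- segment_epochs(rec, ev, "stimulus", c(-1100, 900))
  expect_equal(dim(ep$data), c(2L, 501L, 1L))  # channels x samples x epochs
  expect_equal(length(ep$times_ms), 501L)
  lock <- round(1100 / 1000 * 250) + 1L  # 1-based index of the lock sample
  expect_equal(ep$times_ms[lock], 0)
  expect_equal(ep$times_ms[1], -1100)
  expect_equal(ep$times_ms[501], 900)
})

test_that("a (0, 0) window returns the voltage at the lock sample", {
  dat <- matrix(seq_len(2000), 1)
  rec <- make_recording(dat, "Cz")
  ev <- make_events("go", 1L, onset0 = 4000)
  ep <- segment_epochs(rec, ev, "stimulus", c(0, 0))
  expect_equal(as.numeric(ep$data), dat[1, round(4000 * 250 / 1000) + 1])
})

test_that("epochs beyond the recording bounds are dropped, not fatal", {
  rec <- make_recording(matrix(0, 1, 1000), "Cz")
  ev <- make_events(c("go", "go"), c(1L, 1L), onset0 = 200, soa = 3500)
  ep <- segment_epochs(rec, ev, "stimulus", c(-1100, 900))
  expect_equal(dim(ep$data)[3], 0L)
  expect_equal(ep$n_dropped, 2L)
})

test_that("artifact rejection is strict at +-120 uV and order-independent", {
  dat <- matrix(0, 1, 4000)
  dat[1, 300] <- 121          # first epoch: just above threshold
  dat[1, 680] <- 120          # second epoch: exactly at threshold
  dat[1, 1060] <- -121        # third: negative excursion
  rec <- make_recording(dat, "Cz")
  ev <- make_events(rep("go", 3), rep(1L, 3), onset0 = 1200, soa = 1500)
  ep <- reject_artifacts(segment_epochs(rec, ev, window = c(-100, 100)))
  expect_equal(ep$retained, c(FALSE, TRUE, FALSE))
  expect_equal(ep$n_rejected, 2L)
  # order independence: reversing the event order permutes the mask
  ep2 <- reject_artifacts(segment_epochs(rec, ev[3:1, ],
                                         window = c(-100, 100)))
  expect_equal(ep2$retained, rev(ep$retained))
})

test_that("rejection counts follow the injected artifact rate (binomial)", {
  task <- task_config(n_blocks = 5L, trials_per_block = 100L,
                      soa_min_ms = 2100, soa_max_ms = 2400)  # no epoch overlap
  prof <- behavior_profile(p_miss = 0)
  ev <- generate_event_sequence(task, prof, seed = 6)
  nm <- noise_model(3, 0, 0, 0.1, 200)
  rec <- render_recording(ev, list(), nm, c("Cz"), seed = 9)
  ep <- reject_artifacts(segment_epochs(rec, ev))
  n <- dim(ep$data)[3]
  expect_equal(n, 500L)
  se <- sqrt(n * 0.1 * 0.9)
  expect_lt(abs(ep$n_rejected - n * 0.1), 3 * se)
})

test_that("averaging is the pointwise mean of retained epochs", {
  dat <- matrix(0, 1, 3000)
  idx <- round(c(1000, 2000) * 250 / 1000) + 1
  dat[1, idx[1]] <- 1; dat[1, idx[2]] <- -1
  rec <- make_recording(dat, "Cz")
  ev <- make_events(c("go", "go"), c(1L, 1L), onset0 = 1000, soa = 1000)
  ep <- segment_epochs(rec, ev, window = c(0, 40))
  avg <- average_epochs(ep)
  expect_equal(avg$data[1, 1], 0)          # (+1 - 1) / 2
  expect_equal(avg$n_epochs, 2L)
  ep$retained <- c(TRUE, FALSE)
  expect_equal(average_epochs(ep)$data[1, 1], 1)
  ep$retained <- c(FALSE, FALSE)
  expect_error(average_epochs(ep), "no retained epochs")
})

test_that("noiseless condition averages equal the condition-scaled template", {
  # several post-correct trials, pN only: average must equal one epoch
  ev <- make_events(rep("go", 4), rep(1L, 4), soa = 2600)
  rec <- render_recording(ev, default_templates()["pN"], quiet_noise(),
                          c("Fp1", "Fp2"), seed = 1)
  ep <- segment_epochs(rec, ev)
  avg <- average_epochs(ep)
  # linear ramp: value at -300 ms is half the Fp2 peak (weight 1.136)
  i300 <- which(abs(avg$times_ms + 300) < 1e-9)
  expect_equal(avg$data[2, i300], -2.8 * 1.136 / 2, tolerance = 1e-9)
  i0 <- which(abs(avg$times_ms) < 1e-9)
  expect_equal(avg$data[2, i0], -2.8 * 1.136, tolerance = 1e-9)
})

test_that("zero-phase Butterworth smoothing matches its analytic response", {
  fs <- 250
  n <- 2001
  tt <- seq_len(n) / fs
  mid <- 500:1500  # avoid filtfilt edge transients
  gain_for <- function(f_hz) {
    ev <- make_evoked_obj(matrix(sin(2 * pi * f_hz * tt), 1), "Cz",
                          (seq_len(n) - 1) * 4)
    sm <- smooth_evoked(ev, 25)
    sqrt(mean(sm$data[1, mid]^2) / mean(sin(2 * pi * f_hz * tt[mid])^2))
  }
  # DC gain exactly 1
  dc <- make_evoked_obj(matrix(5, 1, n), "Cz", (seq_len(n) - 1) * 4)
  expect_equal(smooth_evoked(dc, 25)$data[1, mid], rep(5, length(mid)),
               tolerance = 1e-6)
  # passband: 5 Hz attenuated by less than 1% (analytic: ~2.6e-6)
  expect_gt(gain_for(5), 0.99)
  # stopband: 50 Hz (one octave up) attenuated by at least 24 dB;
  # the two passes give about 48 dB analytically
  att_db <- -20 * log10(gain_for(50))
  expect_gt(att_db, 24)
  expect_gt(att_db, 40)
  # idempotence in the passband: smoothing twice changes a 2 Hz tone < 1%
  ev2 <- make_evoked_obj(matrix(sin(2 * pi * 2 * tt), 1), "Cz",
                         (seq_len(n) - 1) * 4)
  s1 <- smooth_evoked(ev2, 25)
  s2 <- smooth_evoked(s1, 25)
  expect_lt(max(abs(s2$data[1, mid] - s1$data[1, mid])), 0.01)
  expect_error(smooth_evoked(ev2, 200), "Nyquist")
})

test_that("baseline schemes subtract the right interval means", {
  times <- seq(-1100, 900, by = 4)
  dat <- matrix(5, 2, length(times))
  ev <- make_evoked_obj(dat, c("Fp1", "Cz"), times)
  for (sch in c("epoch_initial_200ms", "prestim_100ms")) {
    bc <- baseline_correct(ev, sch)
    expect_equal(max(abs(bc$data)), 0)
  }
  # default scheme corrects over (-1100, -900) on the (-1100, 900) window
  bc <- baseline_correct(ev, "epoch_initial_200ms")
  expect_equal(bc$baseline$interval_ms, c(-1100, -900))
  # an already zero-mean baseline leaves the waveform unchanged
  dat2 <- matrix(rnorm(2 * length(times)), 2)
  sel <- times <= -900
  dat2 <- dat2 - rowMeans(dat2[, sel])
  ev2 <- make_evoked_obj(dat2, c("Fp1", "Cz"), times)
  expect_equal(baseline_correct(ev2, "epoch_initial_200ms")$data, dat2,
               tolerance = 1e-12)
  # interval outside the window errors
  ev3 <- make_evoked_obj(dat[, 1:100, drop = FALSE], c("Fp1", "Cz"),
                         times[1:100])
  expect_error(baseline_correct(ev3, "prestim_100ms"), "outside")
})

test_that("baseline correction commutes with averaging (linearity)", {
  set.seed(4)
  times <- seq(-1100, 900, by = 4)
  n_ep <- 5
  epochs <- lapply(seq_len(n_ep), function(i)
    matrix(rnorm(length(times)), 1))
  # correct each epoch, then average
  corrected <- lapply(epochs, function(m) {
    ev <- make_evoked_obj(m, "Cz", times)
    baseline_correct(ev, "epoch_initial_200ms")$data
  })
  a <- Reduce(`+`, corrected) / n_ep
  # average, then correct
  ev_avg <- make_evoked_obj(Reduce(`+`, epochs) / n_ep, "Cz", times)
  b <- baseline_correct(ev_avg, "epoch_initial_200ms")$data
  expect_equal(a, b, tolerance = 1e-12)
})

test_that("stimulus- and response-locked frames agree after an RT shift", {
  # error trial, RT = 400 ms (a whole number of samples at 250 Hz)
  ev <- make_events("nogo", 1L, rt_ms = 400)
  rec <- render_recording(ev,
                          restrict_templates(default_templates()[c("Ne", "Pe")],
                                             "Cz"),
                          quiet_noise(), c("Cz"), seed = 1)
  ep_s <- segment_epochs(rec, ev, "stimulus", c(-100, 900))
  ep_r <- segment_epochs(rec, ev, "response", c(-500, 500))
  expect_equal(ep_s$data, ep_r$data)  # same absolute sample range
})

test_that("build_condition_evokeds sorts conditions and reports counts", {
  s <- simulate_subject(task_config(n_blocks = 4L, trials_per_block = 40L),
                        behavior_profile(p_fa_after_correct = 0.25,
                                         p_fa_after_error = 0.25),
                        noise = noise_model(5, 1, 2, 0, 200), seed = 14)
  evk <- build_condition_evokeds(s$recording, s$events)
  expect_setequal(names(evk$evokeds), c("post_error", "post_correct", "error"))
  lab <- classify_trials(s$events)
  expect_equal(unname(evk$counts["error", "n_epochs"]),
               sum(lab$outcome == "false_alarm"))
  # with artifact rate 0, every FA epoch survives
  expect_equal(unname(evk$counts["error", "n_retained"]),
               unname(evk$counts["error", "n_epochs"]))
  pe <- evk$evokeds$post_error
  expect_s3_class(pe, "evoked")
  # baseline mean is zero after correction
  sel <- pe$times_ms <= -900
  expect_lt(max(abs(rowMeans(pe$data[, sel]))), 1e-9)
})

test_that("control segmentations use the documented frames and baselines", {
  s <- simulate_subject(task_config(n_blocks = 2L, trials_per_block = 40L),
                        behavior_profile(p_fa_after_correct = 0.3,
                                         p_fa_after_error = 0.3),
                        noise = noise_model(5, 1, 2, 0, 200), seed = 3)
  evk <- build_condition_evokeds(s$recording, s$events,
                                 include_controls = TRUE)
  rl <- evk$controls$response_locked$error
  expect_equal(rl$lock, "response")
  expect_equal(rl$baseline$interval_ms, c(-1500, -1300))
  sl <- evk$controls$stimulus_locked$error
  expect_equal(sl$baseline$scheme, "prestim_100ms")
  ex <- evk$controls$expanded$post_correct
  expect_equal(range(ex$times_ms), c(-2000, 900))
  expect_equal(ex$baseline$interval_ms, c(-1100, -900))
})

test_that("a condition with no trials is reported absent", {
  ev <- make_events(rep("go", 30), rep(1L, 30))  # no FAs
  rec <- render_recording(ev, list(), noise_model(5, 0, 0, 0, 200),
                          c("Cz"), seed = 2)
  evk <- build_condition_evokeds(rec, ev)
  expect_null(evk$evokeds$error)
  expect_null(evk$evokeds$post_error)
  expect_equal(evk$reasons$error, "no_trials")
})
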