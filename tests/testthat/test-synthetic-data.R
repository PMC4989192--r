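test_that("default task yields exact category balance and bounded SOAs", {
  for (seed in c(1, 7, 42)) {
    ev <- generate_event_sequence(seed = seed)
    expect_equal(nrow(ev), 800)
    expect_equal(unname(table(ev$category)[c("go", "nogo")]),
                 c(400L, 400L), ignore_attr = TRUE)
    ioi <- unlist(tapply(ev$onset_ms, ev$block, diff))
    expect_true(all(ioi >= 1000 - 1e-9 & ioi <= 2000 + 1e-9))
    expect_true(all(diff(ev$onset_ms) > 0))
  }
})

test_that("degenerate response probabilities give no FAs and no misses", {
  prof <- behavior_profile(p_fa_after_correct = 0, p_fa_after_error = 0,
                           p_miss = 0)
  ev <- generate_event_sequence(task_config(), prof, seed = 3)
  lab <- classify_trials(ev)
  expect_equal(sum(lab$outcome == "false_alarm"), 0)
  expect_equal(sum(lab$outcome == "miss"), 0)
  expect_true(all(ev$response[ev$category == "go"] == 1L))
})

test_that("conditional FA rates converge to the profile values (binomial)", {
  task <- task_config(n_blocks = 13L, trials_per_block = 1600L)
  prof <- behavior_profile(p_fa_after_correct = 0.111,
                           p_fa_after_error = 0.25, p_miss = 0)
  ev <- generate_event_sequence(task, prof, seed = 8)
  lab <- classify_trials(ev)
  nogo <- ev$category == "nogo"
  for (ctx in list(list(sel = lab$post_correct, p = 0.111),
                   list(sel = lab$post_error, p = 0.25))) {
    sel <- ctx$sel & nogo
    n <- sum(sel)
    expect_gt(n, if (ctx$p > 0.2) 300 else 5000)
    phat <- mean(lab$outcome[sel] == "false_alarm")
    se <- sqrt(ctx$p * (1 - ctx$p) / n)
    expect_lt(abs(phat - ctx$p), 3 * se)
  }
})

test_that("hit RTs come from the post-error distribution after an FA", {
  prof <- behavior_profile(p_fa_after_correct = 0.3, p_fa_after_error = 0.3,
                           p_miss = 0, rt_hit_pre_error_ms = 400,
                           rt_hit_post_error_ms = 600, rt_spread_ms = 10)
  ev <- generate_event_sequence(task_config(), prof, seed = 12)
  lab <- classify_trials(ev)
  post_hits <- lab$outcome == "hit" & lab$post_error
  other_hits <- lab$outcome == "hit" & lab$post_correct
  expect_gt(median(ev$rt_ms[post_hits]), 550)
  expect_lt(median(ev$rt_ms[other_hits]), 450)
})

test_that("same master seed reproduces a cohort bit-identically", {
  tpl <- restrict_templates(default_templates(), c("Fp1", "Cz"))
  nm <- noise_model(2, 1, 1, 0.05, 200)
  c1 <- generate_cohort(2, tiny_task(), templates = tpl, noise = nm,
                        montage = c("Fp1", "Cz"), seed = 99)
  c2 <- generate_cohort(2, tiny_task(), templates = tpl, noise = nm,
                        montage = c("Fp1", "Cz"), seed = 99)
  expect_identical(c1[[1]]$events, c2[[1]]$events)
  expect_identical(c1[[2]]$recording$data, c2[[2]]$recording$data)
  expect_identical(c1[[1]]$truth, c2[[1]]$truth)
})

test_that("zero jitter reproduces the population profile in every subject", {
  co <- generate_cohort(1, tiny_task(), jitter = profile_jitter(scale = 0),
                        noise = quiet_noise(), seed = 5)
  tr <- co[[1]]$truth
  pop <- behavior_profile()
  for (f in c("p_fa_after_correct", "p_fa_after_error", "p_miss",
              "rt_hit_pre_error_ms", "rt_hit_post_error_ms", "rt_fa_ms"))
    expect_equal(tr$profile[[f]], pop[[f]])
  expect_equal(tr$gains$subject_scale, 1)
  expect_equal(tr$gains$pn_post_error_gain, 3 / 1.4)
  expect_equal(tr$gains$bp_post_error_gain, 0.8 / 1.8)
})

test_that("noiseless single-trial rendering reconstructs the template", {
  ev <- make_events("go", 1L, rt_ms = 400)
  tpl <- restrict_templates(default_templates()["BP"], c("Fp1", "Cz"))
  rec <- render_recording(ev, tpl, quiet_noise(), c("Fp1", "Cz"), seed = 1)
  onset_idx <- round(3000 * 250 / 1000) + 1
  expect_equal(rec$data[2, onset_idx], -3.6)  # peak amplitude at lock time
  # on the ramp, 300 ms before onset: 200/500 of the peak
  expect_equal(rec$data[2, onset_idx - 75], -3.6 * 200 / 500)
  expect_true(all(rec$data[1, ] == 0))  # no Fp1 weight in the BP template
})

test_that("response-locked templates are placed at the press, not the stimulus", {
  # one false alarm with a 400 ms RT; Ne peaks 80 ms after the response
  ev <- make_events("nogo", 1L, rt_ms = 400)
  tpl <- restrict_templates(default_templates()["Ne"], "Cz")
  rec <- render_recording(ev, tpl, quiet_noise(), c("Cz"), seed = 1)
  fs <- 250
  peak_idx <- which.min(rec$data[1, ])
  expected <- round((3000 + 400) * fs / 1000) + 1 + round(80 * fs / 1000)
  expect_equal(peak_idx, expected)
  stim_idx <- round(3000 * fs / 1000) + 1
  expect_equal(rec$data[1, stim_idx + round(80 * fs / 1000)], 0)
})

test_that("the forward model is linear in the template set", {
  ev <- generate_event_sequence(tiny_task(), seed = 21)
  mont <- c("Fp1", "Fp2", "C1", "Cz", "C2", "PO7", "PO8")
  tA <- default_templates()[c("pN", "P1")]
  tB <- default_templates()[c("BP", "N1", "Ne", "Pe")]
  rA <- render_recording(ev, tA, quiet_noise(), mont, seed = 1)
  rB <- render_recording(ev, tB, quiet_noise(), mont, seed = 1)
  rAB <- render_recording(ev, c(tA, tB), quiet_noise(), mont, seed = 1)
  expect_equal(rA$data + rB$data, rAB$data, tolerance = 1e-12)
})

test_that("noise-only recordings have zero mean and the requested spread", {
  ev <- make_events(rep("go", 3), rep(0L, 3), soa = 20000)
  nm <- noise_model(10, 0, 0, 0, 200)  # white
  rec <- render_recording(ev, list(), nm, c("Cz"), seed = 2)
  x <- rec$data[1, seq_len(10000)]
  expect_lt(abs(mean(x)), 3 * 10 / sqrt(10000))
  expect_equal(sd(rec$data[1, ]), 10, tolerance = 0.05)
  # 1/f-shaped noise is DC-free by construction
  nm2 <- noise_model(10, 1, 0, 0, 200)
  rec2 <- render_recording(ev, list(), nm2, c("Cz"), seed = 2)
  expect_lt(abs(mean(rec2$data[1, ])), 1)
})

test_that("templates referencing channels outside the montage are rejected", {
  ev <- make_events("go", 1L)
  expect_error(render_recording(ev, default_templates()["BP"], quiet_noise(),
                                c("Fp1", "Fp2"), seed = 1),
               "unknown channel")
  kept <- restrict_templates(default_templates(), c("Fp1", "Fp2"))
  expect_setequal(names(kept), c("pN", "Ne", "Pe"))  # P1/N1/BP have no Fp site
})

test_that("invalid configurations are rejected with clear errors", {
  expect_error(task_config(soa_min_ms = 100), "stimulus duration")
  expect_error(task_config(soa_min_ms = 1500, soa_max_ms = 1200), "exceed")
  expect_error(task_config(category_probability = c(0.5, 0.5, 0.5, 0.5)),
               "sum to 1")
  expect_error(behavior_profile(p_fa_after_correct = 1.2), "\\[0, 1\\]")
  expect_error(noise_model(artifact_rate = 0.1, artifact_amplitude_uv = 100),
               "120")
})
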