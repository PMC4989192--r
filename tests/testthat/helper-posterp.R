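# Shared fixtures, all built in code.

# a silent noise model for noiseless forward-model checks
quiet_noise <- function() noise_model(0, 1, 0, 0, 200)

# small task for fast structural tests (2 blocks x 20 trials, exact balance)
tiny_task <- function() task_config(n_blocks = 2L, trials_per_block = 20L)

# hand-built event log; onsets spaced by 1500 ms inside one block
make_events <- function(category, response, rt_ms = NULL, block = NULL,
                        onset0 = 3000, soa = 1500) {
  n <- length(category)
  if (is.null(rt_ms)) rt_ms <- ifelse(response == 1L, 400, NA_real_)
  if (is.null(block)) block <- rep(1L, n)
  onset <- onset0 + (seq_len(n) - 1) * soa
  df <- data.frame(onset_ms = onset, block = block, trial = seq_len(n),
                   category = category,
                   stim_id = ifelse(category == "go", 1L, 3L),
                   response = as.integer(response), rt_ms = rt_ms,
                   stringsAsFactors = FALSE)
  class(df) <- c("event_log", "data.frame")
  df
}

# hand-built recording from a channels x samples matrix
make_recording <- function(data, channels, sfreq = 250) {
  structure(list(data = data, channels = channels, sfreq_hz = sfreq,
                 unit = "uV"), class = "eeg_recording")
}

# 3-subject x 2-condition x 3-site toy measure table. Decomposed by hand
# with the textbook within-subject sum-of-squares formulas (each effect
# against its subject-by-effect interaction) before the implementation was
# written; the frozen expectations are
#   condition: F(1,2) = 300,         p = 0.003316758722
#   site:      F(2,4) = 24.14285714, p = 0.005852668040
#   cond:site: F(2,4) = 3,           p = 0.16
toy_table <- function() {
  d <- expand.grid(site = c("s1", "s2", "s3"),
                   condition = c("A1", "A2"),
                   subject = c("p1", "p2", "p3"),
                   stringsAsFactors = FALSE)
  d$value_uv <- c(2, 4, 3,  5, 7, 6,
                  1, 3, 2,  4, 8, 5,
                  3, 5, 5,  6, 9, 8)
  d
}

# hand-built evoked from a channels x samples matrix and a time axis
make_evoked_obj <- function(data, channels, times_ms, sfreq = 250) {
  structure(list(data = data, channels = channels, sfreq_hz = sfreq,
                 times_ms = times_ms, lock = "stimulus", n_epochs = 1L,
                 condition = NULL, baseline = NULL, filter = NULL),
            class = "evoked")
}
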