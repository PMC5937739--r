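test_that("default single-session paradigm emits 20 balanced trial markers", {
  sim <- cached("default_1sess",
                generate_dataset(paradigm_config(n_sessions = 1, seed = 7)))
  rec <- sim$recording
  expect_equal(nrow(rec$events), 20)
  expect_equal(rec$nirs_rate_hz, 12.5)
  expect_equal(rec$eeg_rate_hz, 1000)
  counts <- table(rec$events$label)
  expect_lte(abs(counts[["MA"]] - counts[["BL"]]), 1)
  expect_equal(dim(rec$nirs_intensity)[1:2], c(9L, 2L))
  expect_true(all(rec$nirs_intensity > 0))
  # montage: exactly the 10 frontal names flagged
  expect_setequal(rec$frontal,
                  c("AFp1", "AFp2", "AFF1h", "AFF2h", "AFF5h", "AFF6h",
                    "F3", "F4", "F7", "F8"))
  expect_equal(nrow(rec$eeg), 22)
})

test_that("trial onsets increase with at least instruction + task + min rest gaps", {
  sim <- small_sim()
  on <- sim$truth$trial_onsets_s
  p <- small_paradigm()
  expect_true(all(diff(on) >= p$task_s + p$rest_range_s[1] +
                    p$instruction_s - 1e-9))
  expect_equal(length(sim$truth$labels), 12)
})

test_that("identical seeds give bit-identical datasets", {
  a <- generate_dataset(small_paradigm(seed = 5))
  b <- generate_dataset(small_paradigm(seed = 5))
  expect_identical(a$recording$eeg, b$recording$eeg)
  expect_identical(a$recording$nirs_intensity, b$recording$nirs_intensity)
  expect_identical(a$truth, b$truth)
  c <- generate_dataset(small_paradigm(seed = 6))
  expect_false(identical(a$recording$eeg, c$recording$eeg))
})

test_that("alpha attenuation lowers MA task-window alpha power", {
  sim <- generate_dataset(
    small_paradigm(seed = 9, n_trials = 16),
    effect_config(alpha_attenuation_ma = 0.5)
  )
  rec <- sim$recording
  ep <- epoch(rec$eeg[rec$frontal, ], rec$events, c(0, 10),
              rec$eeg_rate_hz, "EEG")
  alpha_logpow <- vapply(seq_len(n_trials(ep)), function(i) {
    mean(vapply(seq_along(rec$frontal), function(ch) {
      p <- hybridbci:::welch_psd(ep$data[i, ch, ], ep$rate_hz)
      log(sum(p$power[p$freq >= 8 & p$freq <= 13]))
    }, numeric(1)))
  }, numeric(1))
  tt <- stats::t.test(alpha_logpow[ep$labels == "MA"],
                      alpha_logpow[ep$labels == "BL"])
  expect_lt(mean(alpha_logpow[ep$labels == "MA"]),
            mean(alpha_logpow[ep$labels == "BL"]))
  expect_lt(tt$p.value, 0.01)
})

test_that("invalid paradigm configurations are rejected", {
  expect_error(paradigm_config(task_s = -1), "positive")
  expect_error(paradigm_config(n_trials_per_session = 1), "at least 2")
  expect_error(paradigm_config(rest_range_s = c(5, 4)), "lo <= hi")
  expect_error(effect_config(alpha_attenuation_ma = 1.5), "\\[0, 1\\]")
})
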