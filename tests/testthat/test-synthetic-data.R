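test_that("stimulus waveform has the right shape, length and RMS", {
  spec <- stimulus_spec(1, 10)
  v <- make_stimulus_velocity(spec, duration = 45, rate = 1000)
  expect_length(v, 45000)
  expect_lt(max(v), 10 + 1e-9)
  expect_gt(max(v), 9.99)
  # RMS of a pure sinusoid is peak / sqrt(2)
  expect_equal(sqrt(mean(v^2)), 10 / sqrt(2), tolerance = 1e-6)
  expect_equal(v[1], 0)  # sine convention, phase 0

  v2 <- make_stimulus_velocity(stimulus_spec(0.5, 10), 44, 500)
  expect_length(v2, 22000)
  expect_equal(sqrt(mean(v2^2)), 10 / sqrt(2), tolerance = 1e-6)

  expect_error(make_stimulus_velocity(spec, 0, 1000),
               class = "vorlearn_invalid_argument")
  expect_error(make_stimulus_velocity(spec, 45, 50),
               class = "vorlearn_invalid_argument")
  expect_error(stimulus_spec(frequency = -1),
               class = "vorlearn_invalid_argument")
})

test_that("saccade trains are Poisson-like, non-overlapping and seed-deterministic", {
  expect_equal(nrow(sample_saccade_train(45, 0)), 0)
  expect_error(sample_saccade_train(45, -1),
               class = "vorlearn_invalid_argument")

  a <- sample_saccade_train(45, 1, seed = 101)
  b <- sample_saccade_train(45, 1, seed = 101)
  expect_identical(a, b)
  c <- sample_saccade_train(45, 1, seed = 102)
  expect_false(identical(a, c))

  # Monte-Carlo event count vs the analytic rate * duration mean; thinning
  # removes only a small fraction at rate 1/s with <= 80 ms durations.
  counts <- vapply(1:200, function(s)
    nrow(sample_saccade_train(45, 1, seed = s)), numeric(1))
  expect_gt(mean(counts), 45 - 4)
  expect_lt(mean(counts), 45 + 2)

  # non-overlap and ordering invariants over many seeds
  for (s in 1:25) {
    tr <- sample_saccade_train(30, 2, seed = s)
    if (nrow(tr) > 1) {
      expect_true(!is.unsorted(tr$onset))
      expect_true(all(tr$onset[-1] >= (tr$onset + tr$duration)[-nrow(tr)]))
    }
    expect_true(all(tr$onset + tr$duration <= 30))
    expect_true(all(abs(tr$peak_velocity) >= 100 &
                      abs(tr$peak_velocity) <= 300))
  }
})

test_that("synthesized traces invert through the measurement pipeline", {
  spec <- stimulus_spec(1, 10)
  # noise-free identity: programmed amplitude comes back
  m <- measure_test(clean_trace(gain = 1))
  expect_true(m$valid)
  expect_equal(m$amplitude, 10, tolerance = 0.01)
  # zero gain: amplitude at the noise floor
  m0 <- measure_test(clean_trace(gain = 0))
  expect_lt(m0$amplitude, 0.05)
  # realistic trace: saccades + noise, recovered within 2%
  sac <- sample_saccade_train(45, 1, seed = 7)
  tr <- synthesize_eye_trace(spec, true_state(gain = 0.8, noise_sd = 2),
                             sac, seed = 8)
  mr <- measure_test(tr)
  expect_true(mr$valid)
  expect_lt(abs(mr$amplitude - 8) / 8, 0.02)
  expect_gt(mr$excluded_fraction, 0)
})

test_that("overlapping or malformed saccade trains are rejected", {
  bad <- data.frame(onset = c(1, 1.01), duration = c(0.05, 0.05),
                    peak_velocity = c(200, 200))
  expect_error(
    synthesize_eye_trace(stimulus_spec(1, 10), true_state(), bad),
    class = "vorlearn_invalid_argument")
  bad2 <- data.frame(onset = 1, duration = -0.1, peak_velocity = 200)
  expect_error(
    synthesize_eye_trace(stimulus_spec(1, 10), true_state(), bad2),
    class = "vorlearn_invalid_argument")
})

test_that("trace synthesis is deterministic under a fixed seed", {
  spec <- stimulus_spec(1, 10)
  st <- true_state(gain = 0.9, noise_sd = 2, position_noise_sd = 0.01)
  t1 <- synthesize_eye_trace(spec, st, duration = 5, rate = 1000, seed = 42)
  t2 <- synthesize_eye_trace(spec, st, duration = 5, rate = 1000, seed = 42)
  expect_identical(t1$position, t2$position)
  t3 <- synthesize_eye_trace(spec, st, duration = 5, rate = 1000, seed = 43)
  expect_false(identical(t1$position, t3$position))
})

test_that("cohort simulation follows the design and is reproducible", {
  des <- experiment_design("vor_increase")
  expect_equal(des$test_times_min, c(0, 10, 20, 30))
  expect_equal(des$tests_per_block, 3L)
  expect_equal(des$test_duration, 45)
  train <- Filter(function(b) b$kind == "training", des$block_sequence)
  expect_length(train, 3)
  expect_true(all(vapply(train, `[[`, numeric(1), "duration") == 600))

  okr <- experiment_design("okr_adaptation")
  expect_equal(length(okr$test_times_min), 60L)
  expect_true(all(vapply(okr$block_sequence, `[[`, numeric(1),
                         "duration") == 50))

  pre <- experiment_design("vestibular_only_pretrain")
  expect_equal(pre$test_times_min, c(-30, -20, -10, 0, 10, 20, 30))

  coh <- cohort_spec(list(WT = list(n = 2, trajectory = c(0.8, 0.9, 1, 1.1))),
                     noise_sd = 1, saccade_rate = 0.5)
  s1 <- simulate_cohort(des, coh, seed = 5)
  expect_equal(nrow(s1$meta), 2 * 4 * 3)
  expect_identical(s1, simulate_cohort(des, coh, seed = 5))
  s2 <- simulate_cohort(des, coh, seed = 6)
  expect_false(identical(s1$traces[[1]]$position, s2$traces[[1]]$position))

  # trajectory length must match the design's testing time points
  bad <- cohort_spec(list(WT = list(n = 2, trajectory = c(0.8, 0.9))))
  expect_error(simulate_cohort(des, bad, seed = 1),
               class = "vorlearn_invalid_argument")
})
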