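test_that("recognition behavior follows the signal-detection model", {
  # no memory signal: AUC at chance
  labels <- rep(c(0L, 1L), 5000)
  beh <- simulate_recognition_behavior(labels, behavior_params(d_prime = 0), 1)
  tr <- make_recognition_trials(length(labels), labels = labels)
  tr$response_value <- beh$response_code
  auc <- auc_trapezoid(roc_points(confidence_counts(tr)))
  expect_lt(abs(auc - 0.5), 0.02)

  # saturating memory: every old trial ends at "old, confident"
  beh_inf <- simulate_recognition_behavior(labels,
                                           behavior_params(d_prime = 50), 2)
  expect_true(all(beh_inf$response_code[labels == 0L] == 36L))

  # d' = 1.5: empirical AUC matches the closed-form quantized-rating oracle
  p <- behavior_params(d_prime = 1.5)
  big <- rep(c(0L, 1L), 10000)
  beh15 <- simulate_recognition_behavior(big, p, 3)
  tr15 <- make_recognition_trials(length(big), labels = big)
  tr15$response_value <- beh15$response_code
  auc15 <- auc_trapezoid(roc_points(confidence_counts(tr15)))
  expect_lt(abs(auc15 - quantized_sdt_auc(1.5, p$criteria)), 0.01)
  expect_error(behavior_params(criteria = c(1, 0.5, 2, 3, 4)), "increasing")
})

test_that("timeline rendering emits the TTL grammar with variant tags", {
  tm <- task_timing()
  toy <- data.frame(
    trial_id = 1:2, phase = "learning",
    start_time = c(1, 6), stop_time = c(2, 7), delay1_time = c(2.5, 7.5),
    response_time = c(3.2, 8.1), delay2_time = c(3.7, 8.6),
    response_value = c(21L, 20L), category_name = "houses",
    stim_category = 1L, new_old_label = NA_integer_, stimulus_id = c("a", "b"))
  tl <- build_trial_timeline(toy, variant = 1, tm)
  expect_equal(tl$events$code,
               c(55L, 1L, 2L, 3L, 21L, 6L, 1L, 2L, 3L, 20L, 6L, 66L))
  expect_equal(nrow(tl$events), nrow(tl$tags))

  s <- generate_session(small_config(seed = 5, variant = 1L))
  learn_tags <- s$tags$xid[s$events$code %in% c(20, 21)]
  recog_tags <- s$tags$xid[s$events$code %in% 31:36]
  expect_true(all(learn_tags == 80L))
  expect_true(all(recog_tags == 81L))

  empty <- toy[0, ]
  tl0 <- build_trial_timeline(empty, variant = 2, tm)
  expect_equal(tl0$events$code, c(55L, 66L))

  bad <- toy
  bad$response_value[1] <- 35L  # recognition code in a learning trial
  expect_error(build_trial_timeline(bad, 1, tm), "illegal")
})

test_that("spike simulator matches Poisson statistics at baseline", {
  trials <- make_recognition_trials(100)
  spec <- neuron_spec("none", baseline_hz = 5)
  st <- simulate_spike_train(spec, trials, seed = 9)
  counts <- trial_rates(st, trials, analysis_window(0, 1))
  se <- sqrt(5 / 100)
  expect_lt(abs(mean(counts) - 5), 3 * se)
  fano <- stats::var(counts) / mean(counts)
  expect_gt(fano, 0.7)
  expect_lt(fano, 1.3)

  # vanishing rate: empty train
  spec0 <- neuron_spec("none", baseline_hz = 1e-9)
  expect_length(simulate_spike_train(spec0, trials, seed = 1), 0)

  # gain 1 on a tuned unit is a no-op relative to an untuned unit
  spec_g1 <- neuron_spec("VS", baseline_hz = 5, category_gain = 1,
                         pref_category = "cat1")
  expect_equal(simulate_spike_train(spec_g1, trials, seed = 4),
               simulate_spike_train(spec, trials, seed = 4))

  # refractory deletion leaves no ISI below the dead time
  expect_true(all(diff(st) >= spec$refractory_s))
})

test_that("tuned units fire above baseline only in matching response windows", {
  trials <- make_recognition_trials(100)
  spec <- neuron_spec("MS", baseline_hz = 5, memory_gain = 3,
                      pref_condition = "new")
  st <- simulate_spike_train(spec, trials, seed = 21)
  r <- trial_rates(st, trials, analysis_window())
  m_new <- mean(r[trials$new_old_label == 1L])
  m_old <- mean(r[trials$new_old_label == 0L])
  expect_gt(m_new, 2 * m_old)
  expect_lt(abs(m_old - 5), 3 * sqrt(5 / 50))
})

test_that("waveform synthesis is a scaled biphasic template plus noise", {
  wf <- synth_waveform(80, noise_sd_uv = 0)
  expect_length(wf, 256)
  expect_equal(max(abs(wf)), 80)

  wf_a <- synth_waveform(100, 5, seed = 3)
  wf_b <- synth_waveform(100, 5, seed = 3)
  expect_identical(wf_a, wf_b)
  expect_lt(abs(compute_snr(wf_a, 5) - 20), 3)
  expect_error(synth_waveform(-1, 0), "amplitude")
})

test_that("generated sessions have the task's structure and are seed-deterministic", {
  s <- generate_session(generator_config(seed = 31, n_units = 3))
  expect_equal(nrow(s$trials), 200)
  expect_equal(sum(s$trials$phase == "learning"), 100)
  rec <- s$trials[s$trials$phase == "recognition", ]
  expect_equal(sum(rec$new_old_label == 1L), 50)
  expect_equal(sum(rec$new_old_label == 0L), 50)
  expect_length(unique(s$trials$category_name), 5)
  # category balance: 20 per category at encoding, 10 + 10 at recognition
  enc <- s$trials[s$trials$phase == "learning", ]
  expect_true(all(table(enc$category_name) == 20))
  expect_true(all(table(rec$category_name, rec$new_old_label) == 10))
  # old images really were shown at encoding
  old_ids <- rec$stimulus_id[rec$new_old_label == 0L]
  expect_true(all(old_ids %in% enc$stimulus_id))
  expect_equal(nrow(s$events), nrow(s$tags))

  s_again <- generate_session(generator_config(seed = 31, n_units = 3))
  expect_identical(s, s_again)
  s_other <- generate_session(generator_config(seed = 32, n_units = 3))
  expect_false(identical(s$trials$response_value, s_other$trials$response_value))
})

test_that("session config files round into generator configs", {
  cfg_path <- system.file("extdata", "example_config.yaml", package = "mtlmem")
  cfg <- read_session_config(cfg_path)
  expect_length(cfg$sessions, 2)
  expect_equal(cfg$sessions[[1]]$session_id, "C01_s1")
  expect_equal(cfg$sessions[[2]]$behavior$d_prime, 1.2)
  expect_equal(cfg$alpha, 0.05)
})
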