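test_that("trial_rates counts spikes in the half-open analysis window", {
  tr <- data.frame(start_time = 0)
  expect_equal(trial_rates(c(0.25, 0.5, 1.0), tr, analysis_window()), 3.0)
  # right edge excluded, left edge included
  expect_equal(trial_rates(1.2, tr, analysis_window()), 0.0)
  expect_equal(trial_rates(0.2, tr, analysis_window()), 1.0)
  expect_equal(trial_rates(numeric(0), tr, analysis_window()), 0.0)
  expect_error(trial_rates(c(2, 1), tr), "sorted")
  close_tr <- data.frame(start_time = c(0, 0.5))
  expect_warning(trial_rates(0.3, close_tr, analysis_window()), "overlap")
})

test_that("psth conserves spikes and is flat for a homogeneous unit", {
  trials <- make_recognition_trials(100)
  st <- simulate_spike_train(neuron_spec("none", baseline_hz = 5), trials, 3)
  ph <- psth(st, trials, bin_s = 0.25, range_s = c(-1, 2))
  rel_counts <- sum(vapply(seq_len(nrow(trials)), function(i) {
    rel <- st - trials$start_time[i]
    sum(rel >= -1 & rel < 2)
  }, numeric(1)))
  expect_equal(sum(ph$counts), rel_counts)
  expect_true(all(abs(ph$mean_rate_hz - 5) < 2))

  # one spike per trial at +0.3 s lands in exactly one bin column
  st_delta <- sort(trials$start_time + 0.3)
  ph_d <- psth(st_delta, trials, bin_s = 0.25, range_s = c(-1, 2))
  nonzero <- which(colSums(ph_d$counts) > 0)
  expect_length(nonzero, 1)
  expect_equal(sum(ph_d$counts[, nonzero]), nrow(trials))
  expect_error(psth(st, trials, bin_s = 0), "bin_s")
})

test_that("VS ANOVA matches an explicit sums-of-squares oracle", {
  groups <- list(c(1, 2, 3), c(2, 3, 4), c(3, 4, 5), c(4, 5, 6), c(5, 6, 7))
  trials <- make_recognition_trials(15,
                                    categories = rep(paste0("cat", 1:5), each = 3))
  st <- spikes_for_rates(trials, unlist(groups))
  p <- select_vs_anova(st, trials, selection_config())
  oracle <- anova_oracle(groups)
  expect_equal(p, oracle$p, tolerance = 1e-10)

  # random small datasets
  set.seed(123)
  for (i in 1:20) {
    rates <- stats::rpois(15, 6)
    if (stats::var(rates) == 0) next
    sti <- spikes_for_rates(trials, rates)
    groups_i <- split(rates, rep(1:5, each = 3))
    expect_equal(select_vs_anova(sti, trials, selection_config()),
                 anova_oracle(groups_i)$p, tolerance = 1e-10)
  }

  # all rates equal: no between-category signal
  flat <- spikes_for_rates(trials, rep(4L, 15))
  expect_equal(select_vs_anova(flat, trials, selection_config()), 1)

  # fewer than 5 categories is an error, not a silent 4-group test
  tr4 <- make_recognition_trials(12, categories = rep(paste0("cat", 1:4), 3))
  expect_error(select_vs_anova(st, tr4, selection_config()), "5 category")
})

test_that("VS ANOVA detects category-tuned units", {
  trials <- make_recognition_trials(100)
  cfg <- selection_config(seed = 5)
  hits <- vapply(1:20, function(seed) {
    spec <- neuron_spec("VS", baseline_hz = 5, category_gain = 3,
                        pref_category = "cat2")
    st <- simulate_spike_train(spec, trials, seed)
    select_vs_anova(st, trials, cfg) < cfg$alpha
  }, logical(1))
  expect_gte(mean(hits), 0.9)
})

test_that("MS bootstrap p-values behave at the null and under strong effects", {
  trials <- make_recognition_trials(100)
  cfg <- selection_config(n_boot = 1000L, seed = 7)

  # identical rate vectors in both conditions: delta = 0, p = 1
  st_flat <- spikes_for_rates(trials, rep(5L, 100))
  expect_equal(select_ms_bootstrap(st_flat, trials, cfg), 1)

  # deterministic given the seed
  st <- simulate_spike_train(neuron_spec("none"), trials, 31)
  expect_identical(select_ms_bootstrap(st, trials, cfg),
                   select_ms_bootstrap(st, trials, cfg))

  # new-preferring 10 Hz vs 1 Hz unit is detected across seeds
  det <- vapply(1:20, function(seed) {
    spec <- neuron_spec("MS", baseline_hz = 1, memory_gain = 10,
                        pref_condition = "new")
    sts <- simulate_spike_train(spec, trials, seed)
    select_ms_bootstrap(sts, trials, cfg) <= 0.05
  }, logical(1))
  expect_gte(mean(det), 0.95)

  empty_cond <- make_recognition_trials(10, labels = rep(0L, 10))
  expect_error(select_ms_bootstrap(st, empty_cond, cfg), "non-empty")
})

test_that("population classification counts dual units in both totals", {
  results <- data.frame(unit_id = 1:4,
                        p_vs = c(0.01, 0.2, 0.01, 1),
                        p_ms = c(0.2, 0.01, 0.01, 1))
  pop <- classify_units_population(results, selection_config())
  expect_equal(pop$n_units, 4)
  expect_equal(pop$n_vs, 2)   # VS-only + dual
  expect_equal(pop$n_ms, 2)   # MS-only + dual
  expect_equal(pop$n_dual, 1)
  expect_lte(pop$n_dual, min(pop$n_vs, pop$n_ms))
  expect_equal(pop$prop_vs, 0.5)

  all_null <- data.frame(unit_id = 1:3, p_vs = rep(1, 3), p_ms = rep(1, 3))
  pop0 <- classify_units_population(all_null, selection_config())
  expect_equal(pop0$n_vs + pop0$n_ms + pop0$n_dual, 0)
  expect_equal(selection_label(0.01, 0.2, 0.05), "VS")
  expect_equal(selection_label(0.01, 0.01, 0.05), "dual")
})

test_that("ISI violation QC applies the strict 3% bound", {
  qc <- isi_violation_fraction(c(0, 0.001, 0.010, 0.020))
  expect_equal(qc$fraction, 1 / 3)
  expect_false(qc$qc_pass)

  clean <- isi_violation_fraction(seq(0, 9.99, by = 0.01))
  expect_equal(clean$fraction, 0)
  expect_true(clean$qc_pass)

  expect_true(isi_violation_fraction(numeric(0))$qc_pass)
  expect_true(isi_violation_fraction(5)$qc_pass)

  # monotone: appending a violating spike never flips fail -> pass
  set.seed(31)
  for (i in 1:10) {
    st <- cumsum(stats::runif(50, 0.001, 0.05))
    before <- isi_violation_fraction(st)
    st2 <- sort(c(st, st[25] + 0.001))
    after <- isi_violation_fraction(st2)
    expect_false(!before$qc_pass && after$qc_pass)
  }
})

test_that("SNR is peak amplitude over noise and scales linearly", {
  wf <- synth_waveform(100, noise_sd_uv = 0)
  expect_equal(compute_snr(wf, 5), 20)
  expect_equal(compute_snr(rep(0, 256), 5), 0)
  expect_equal(compute_snr(3 * wf, 5), 3 * compute_snr(wf, 5))
  expect_error(compute_snr(wf, 0), "noise_sd")
})

test_that("isolation distance grows with cluster separation", {
  set.seed(5)
  clus <- matrix(stats::rnorm(100 * 3), ncol = 3)
  vals <- vapply(c(2, 4, 8), function(sep) {
    other <- matrix(stats::rnorm(300 * 3, mean = sep), ncol = 3)
    isolation_distance(clus, other)
  }, numeric(1))
  expect_true(all(diff(vals) > 0))

  # outside points from the cluster's own distribution: the n-th closest of m
  # sits near the chi-square quantile of rank n/m
  set.seed(6)
  clus2 <- matrix(stats::rnorm(300 * 3), ncol = 3)
  other2 <- matrix(stats::rnorm(3000 * 3), ncol = 3)
  v <- isolation_distance(clus2, other2)
  expect_gt(v, stats::qchisq(0.06, df = 3))
  expect_lt(v, stats::qchisq(0.16, df = 3))

  # degenerate inputs
  const <- cbind(rep(1, 50), stats::rnorm(50), stats::rnorm(50))
  out <- isolation_distance(const, matrix(stats::rnorm(150), ncol = 3))
  expect_true(is.na(out))
  expect_match(attr(out, "undefined_reason"), "singular")
  small_other <- matrix(stats::rnorm(30), ncol = 3)
  out2 <- isolation_distance(clus2, small_other)
  expect_true(is.na(out2))
  expect_match(attr(out2, "undefined_reason"), "fewer outside")
})
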