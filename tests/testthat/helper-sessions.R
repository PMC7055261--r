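# shared fixtures, built in code

# compact task (20 + 20 trials) so full-session tests stay fast
small_timing <- function() {
  task_timing(n_encoding = 20L, n_recognition = 20L)
}

small_config <- function(seed = 1L, n_units = 4L, ...) {
  generator_config(seed = seed, n_units = n_units, n_electrodes = 4L,
                   timing = small_timing(), ...)
}

# recognition-only trials table with evenly spaced onsets; labels alternate
# old (0) / new (1) unless given
make_recognition_trials <- function(n = 100L, spacing_s = 4,
                                    labels = rep_len(c(0L, 1L), n),
                                    categories = rep_len(paste0("cat", 1:5), n)) {
  start <- spacing_s * seq_len(n)
  data.frame(trial_id = seq_len(n), phase = "recognition",
             start_time = start, stop_time = start + 1,
             delay1_time = start + 1.5, response_time = start + 2.2,
             delay2_time = start + 2.7,
             response_value = 33L, category_name = categories,
             stim_category = as.integer(factor(categories)),
             new_old_label = labels,
             stimulus_id = sprintf("s%03d", seq_len(n)))
}

# spike train engineered to yield exact integer rates in the 1 s analysis
# window [start + 0.2, start + 1.2) of each trial
spikes_for_rates <- function(trials, rates, window = analysis_window()) {
  stopifnot(nrow(trials) == length(rates))
  out <- unlist(lapply(seq_along(rates), function(i) {
    k <- rates[i]
    if (k == 0) return(numeric(0))
    trials$start_time[i] + window$offset_s +
      seq(0.01, window$length_s - 0.01, length.out = k)
  }))
  sort(out)
}

# independent one-way ANOVA oracle via explicit sums of squares
anova_oracle <- function(groups) {
  all_x <- unlist(groups)
  grand <- mean(all_x)
  ss_between <- sum(vapply(groups, function(g) {
    length(g) * (mean(g) - grand)^2
  }, numeric(1)))
  ss_within <- sum(vapply(groups, function(g) sum((g - mean(g))^2),
                          numeric(1)))
  df1 <- length(groups) - 1
  df2 <- length(all_x) - length(groups)
  f <- (ss_between / df1) / (ss_within / df2)
  list(F = f, p = stats::pf(f, df1, df2, lower.tail = FALSE))
}

# independent AUC oracle: Mann-Whitney with midrank tie handling on the
# (label, response-code) pairs underlying a 2 x 6 count table
mann_whitney_auc <- function(counts) {
  old <- rep(31:36, counts["old", ])
  new <- rep(31:36, counts["new", ])
  r <- rank(c(old, new))
  u <- sum(r[seq_along(old)]) - length(old) * (length(old) + 1) / 2
  u / (length(old) * length(new))
}

# closed-form AUC of the 6-level quantized equal-variance rating ROC
quantized_sdt_auc <- function(d_prime, criteria) {
  b <- c(-Inf, criteria, Inf)
  p_new <- diff(stats::pnorm(b, 0, 1))
  p_old <- diff(stats::pnorm(b, d_prime, 1))
  m <- outer(p_old, p_new)
  sum(m[lower.tri(m)]) + 0.5 * sum(diag(m))
}

# random 2 x 6 confidence count table with positive row sums
random_count_table <- function() {
  repeat {
    m <- matrix(stats::rpois(12, 6), nrow = 2,
                dimnames = list(c("old", "new"), 31:36))
    if (all(rowSums(m) > 0)) return(m)
  }
}
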