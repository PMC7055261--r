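#' Analysis window relative to stimulus onset
#'
#' The selectivity analyses count spikes in a 1 s window starting 200 ms
#' after stimulus onset. Windows are half-open `[t0, t0 + length)`.
#'
#' @param offset_s Start of the window after stimulus onset (s).
#' @param length_s Window length (s, > 0).
#' @export
analysis_window <- function(offset_s = 0.2, length_s = 1.0) {
  if (length_s <= 0) stop("length_s must be > 0")
  structure(list(offset_s = offset_s, length_s = length_s),
            class = "analysis_window")
}

#' Selection-test configuration
#'
#' @param alpha Significance threshold (default 0.05).
#' @param n_boot Bootstrap resamples for the memory-selectivity test
#'   (default 1000).
#' @param seed Integer seed for the bootstrap.
#' @param window An [analysis_window()].
#' @export
selection_config <- function(alpha = 0.05, n_boot = 1000L, seed = 1L,
                             window = analysis_window()) {
  if (alpha <= 0 || alpha >= 1) stop("alpha must be in (0, 1)")
  if (n_boot < 1) stop("n_boot must be >= 1")
  structure(list(alpha = alpha, n_boot = as.integer(n_boot),
                 seed = as.integer(seed), window = window),
            class = "selection_config")
}

#' Per-trial firing rates in the analysis window
#'
#' @param spike_times Sorted numeric spike times (s).
#' @param trials Trials data.frame (uses `start_time`).
#' @param window An [analysis_window()].
#' @return Numeric vector of rates (Hz), one per trial row.
#' @examples
#' tr <- data.frame(start_time = 0)
#' trial_rates(c(0.25, 0.5, 1.0), tr, analysis_window())  # 3 Hz
#' @export
trial_rates <- function(spike_times, trials, window = analysis_window()) {
  if (is.unsorted(spike_times)) stop("spike_times must be sorted")
  a <- trials$start_time + window$offset_s
  b <- a + window$length_s
  if (nrow(trials) > 1) {
    o <- order(a)
    if (any(b[o][-length(o)] > a[o][-1])) {
      warning("analysis windows of consecutive trials overlap")
    }
  }
  counts <- vapply(seq_along(a), function(i) {
    sum(spike_times >= a[i] & spike_times < b[i])
  }, numeric(1))
  counts / window$length_s
}

#' Peri-stimulus time histogram
#'
#' Spike counts binned relative to stimulus onset, one row per trial, plus the
#' trial-averaged rate curve. Bins are half-open `[left, right)`.
#'
#' @param spike_times Sorted spike times (s).
#' @param trials Trials data.frame (aligned on `start_time`).
#' @param bin_s Bin width (s, > 0).
#' @param range_s Two-element vector, window around onset (s).
#' @return List with `counts` (trials x bins integer matrix), `bin_edges`,
#'   `bin_centers` and `mean_rate_hz` (trial-mean counts / bin width).
#' @export
psth <- function(spike_times, trials, bin_s = 0.25, range_s = c(-1, 2)) {
  if (bin_s <= 0) stop("bin_s must be > 0")
  edges <- seq(range_s[1], range_s[2], by = bin_s)
  if (max(edges) < range_s[2]) edges <- c(edges, max(edges) + bin_s)
  n_bin <- length(edges) - 1
  counts <- matrix(0L, nrow = nrow(trials), ncol = n_bin)
  for (i in seq_len(nrow(trials))) {
    rel <- spike_times - trials$start_time[i]
    rel <- rel[rel >= edges[1] & rel < edges[n_bin + 1]]
    if (length(rel)) {
      counts[i, ] <- tabulate(findInterval(rel, edges), nbins = n_bin)
    }
  }
  list(counts = counts, bin_edges = edges,
       bin_centers = edges[-length(edges)] + bin_s / 2,
       mean_rate_hz = colMeans(counts) / bin_s)
}

#' Visual-selectivity screen: one-way ANOVA across image categories
#'
#' Tests whether a unit's firing rate in the analysis window of the
#' recognition (retrieval) trials depends on the image's visual category,
#' with a classical one-way F test across the 5 categories.
#'
#' @param spike_times Sorted spike times of the unit (s).
#' @param recognition_trials Recognition-phase trials (needs `start_time` and
#'   `category_name` with exactly 5 levels, each with >= 2 trials).
#' @param cfg A [selection_config()].
#' @return The ANOVA p-value.
#' @export
select_vs_anova <- function(spike_times, recognition_trials,
                            cfg = selection_config()) {
  cat <- factor(recognition_trials$category_name)
  if (nlevels(cat) != 5) {
    stop("visual-selectivity ANOVA needs exactly 5 category levels, got ",
         nlevels(cat))
  }
  if (any(table(cat) < 2)) stop("every category needs >= 2 trials")
  rates <- trial_rates(spike_times, recognition_trials, cfg$window)
  # a perfectly flat unit carries no between-group signal: F = 0, p = 1
  if (stats::var(rates) == 0) return(1)
  fit <- stats::aov(rates ~ cat)
  summary(fit)[[1]][["Pr(>F)"]][1]
}

#' Memory-selectivity screen: two-tailed bootstrap comparison of means
#'
#' Compares the analysis-window firing rate between novel (label 1) and
#' familiar (label 0) recognition trials. The observed statistic is
#' `mean(new) - mean(old)`; the null distribution is built by pooling all
#' rates and resampling, with replacement, two groups of the original sizes
#' `n_boot` times. The p-value uses the add-one correction
#' `(1 + #{|delta*| >= |delta|}) / (n_boot + 1)`, so it is always positive.
#' Deterministic given `cfg$seed`.
#'
#' @param spike_times Sorted spike times of the unit (s).
#' @param recognition_trials Recognition trials with `new_old_label`.
#' @param cfg A [selection_config()].
#' @return The bootstrap p-value.
#' @export
select_ms_bootstrap <- function(spike_times, recognition_trials,
                                cfg = selection_config()) {
  lab <- recognition_trials$new_old_label
  if (!all(lab %in% c(0L, 1L))) stop("recognition trials need 0/1 labels")
  rates <- trial_rates(spike_times, recognition_trials, cfg$window)
  r_new <- rates[lab == 1L]
  r_old <- rates[lab == 0L]
  if (!length(r_new) || !length(r_old)) {
    stop("both new and old conditions must be non-empty")
  }
  obs <- mean(r_new) - mean(r_old)
  pool <- c(r_new, r_old)
  n1 <- length(r_new); n <- length(pool)
  deltas <- with_seed(cfg$seed, {
    idx <- matrix(sample.int(n, cfg$n_boot * n, replace = TRUE),
                  nrow = cfg$n_boot)
    g1 <- matrix(pool[idx[, seq_len(n1)]], nrow = cfg$n_boot)
    g2 <- matrix(pool[idx[, (n1 + 1):n]], nrow = cfg$n_boot)
    rowMeans(g1) - rowMeans(g2)
  })
  (1 + sum(abs(deltas) >= abs(obs))) / (cfg$n_boot + 1)
}

#' Screen every unit of a session
#'
#' Runs the visual (ANOVA) and memory (bootstrap) selectivity screens on all
#' units over the recognition trials and collects quality metrics.
#'
#' @param s A `session_bundle` (generated or read from NWB).
#' @param cfg A [selection_config()]; each unit's bootstrap uses a sub-seed
#'   derived from `cfg$seed` and the unit id.
#' @return data.frame with one row per unit: `unit_id`, `p_vs`, `p_ms`,
#'   `label` (`none`/`VS`/`MS`/`dual`), `snr`, `isol_dist`,
#'   `isi_violation_fraction`, `qc_pass`.
#' @export
screen_units <- function(s, cfg = selection_config()) {
  rec <- s$trials[s$trials$phase == "recognition", ]
  out <- lapply(seq_len(nrow(s$units)), function(i) {
    st <- s$units$spike_times[[i]]
    ucfg <- cfg
    ucfg$seed <- derive_seed(cfg$seed, s$units$unit_id[i], 17L)
    p_vs <- select_vs_anova(st, rec, ucfg)
    p_ms <- select_ms_bootstrap(st, rec, ucfg)
    qc <- isi_violation_fraction(st)
    data.frame(unit_id = s$units$unit_id[i], p_vs = p_vs, p_ms = p_ms,
               label = selection_label(p_vs, p_ms, cfg$alpha),
               snr = s$units$snr[i], isol_dist = s$units$isol_dist[i],
               isi_violation_fraction = qc$fraction, qc_pass = qc$qc_pass)
  })
  do.call(rbind, out)
}

selection_label <- function(p_vs, p_ms, alpha) {
  vs <- p_vs < alpha
  ms <- p_ms < alpha
  if (vs && ms) "dual" else if (vs) "VS" else if (ms) "MS" else "none"
}

#' Population summary of selective-unit proportions
#'
#' Counts visually selective, memory selective and dual units in a screening
#' table. Dual units are counted in both the VS and MS totals, matching the
#' convention that a dual cell "qualifies as both".
#'
#' @param results Screening table from [screen_units()] (needs `p_vs`,
#'   `p_ms`).
#' @param cfg A [selection_config()] (threshold `alpha`).
#' @return List of class `population_summary`: `n_units`, `n_vs`, `n_ms`,
#'   `n_dual` and proportions `prop_vs`, `prop_ms`, `prop_dual`.
#' @export
classify_units_population <- function(results, cfg = selection_config()) {
  vs <- results$p_vs < cfg$alpha
  ms <- results$p_ms < cfg$alpha
  n <- nrow(results)
  out <- list(n_units = n, n_vs = sum(vs), n_ms = sum(ms),
              n_dual = sum(vs & ms),
              prop_vs = sum(vs) / n, prop_ms = sum(ms) / n,
              prop_dual = sum(vs & ms) / n)
  class(out) <- "population_summary"
  out
}

#' @export
print.population_summary <- function(x, ...) {
  cat(sprintf(
    "<population_summary> %d units: %d VS (%.1f%%), %d MS (%.1f%%), %d dual (%.1f%%)\n",
    x$n_units, x$n_vs, 100 * x$prop_vs, x$n_ms, 100 * x$prop_ms,
    x$n_dual, 100 * x$prop_dual))
  invisible(x)
}

#' Fraction of refractory-period violations
#'
#' Spike-sorting quality check: the fraction of inter-spike intervals shorter
#' than the absolute refractory period. A well-isolated unit must have
#' strictly less than 3% of its ISIs below 3 ms.
#'
#' @param spike_times Sorted spike times (s).
#' @param isi_threshold_s Refractory threshold (default 0.003 s).
#' @param max_fraction QC bound (default 0.03; pass requires
#'   `fraction < max_fraction`, strictly).
#' @return List with `fraction` and logical `qc_pass`.
#' @export
isi_violation_fraction <- function(spike_times, isi_threshold_s = 0.003,
                                   max_fraction = 0.03) {
  if (length(spike_times) < 2) {
    return(list(fraction = 0, qc_pass = TRUE))
  }
  isi <- diff(spike_times)
  frac <- mean(isi < isi_threshold_s)
  list(fraction = frac, qc_pass = frac < max_fraction)
}

#' Waveform signal-to-noise ratio
#'
#' Peak absolute amplitude of the mean waveform divided by the noise standard
#' deviation of the recording channel.
#'
#' @param waveform_mean Mean waveform (microvolts).
#' @param noise_sd Channel noise SD (microvolts, > 0).
#' @return Dimensionless SNR.
#' @export
compute_snr <- function(waveform_mean, noise_sd) {
  if (noise_sd <= 0) stop("noise_sd must be > 0")
  max(abs(waveform_mean)) / noise_sd
}

#' Isolation distance of a sorted cluster
#'
#' Mahalanobis-based cluster-separation metric: using the cluster's own
#' feature mean and covariance, the squared Mahalanobis distance of the n-th
#' closest spike *outside* the cluster, where n is the cluster size. Larger is
#' better; the metric is undefined when there are fewer outside spikes than
#' cluster spikes or when the cluster covariance is singular.
#'
#' @param cluster_features n x d matrix of the cluster's spike features.
#' @param other_features m x d matrix of all other spikes' features
#'   (requires m >= n).
#' @return Numeric isolation distance, or `NA` with attribute
#'   `undefined_reason` when it cannot be computed.
#' @export
isolation_distance <- function(cluster_features, other_features) {
  cluster_features <- as.matrix(cluster_features)
  other_features <- as.matrix(other_features)
  n <- nrow(cluster_features)
  if (nrow(other_features) < n) {
    return(structure(NA_real_, undefined_reason = "fewer outside spikes than cluster size"))
  }
  mu <- colMeans(cluster_features)
  S <- stats::cov(cluster_features)
  d2 <- tryCatch(stats::mahalanobis(other_features, mu, S),
                 error = function(e) NULL)
  if (is.null(d2) || !all(is.finite(d2))) {
    return(structure(NA_real_, undefined_reason = "singular cluster covariance"))
  }
  sort(d2)[n]
}
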