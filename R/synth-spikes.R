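#' Response profile of a simulated unit
#'
#' A unit is untuned (`"none"`), visually selective (`"VS"`: elevated firing
#' for one preferred image category), memory selective (`"MS"`: elevated firing
#' for new or for old items during recognition), or both (`"dual"`). Tuning is
#' multiplicative: during the response window of a matching trial the Poisson
#' rate is `baseline_hz * gain`.
#'
#' @param kind One of `"none"`, `"VS"`, `"MS"`, `"dual"`.
#' @param baseline_hz Baseline firing rate, Hz (> 0).
#' @param category_gain Rate multiplier on preferred-category trials (VS/dual;
#'   must be >= 1).
#' @param pref_category Preferred category name (VS/dual).
#' @param memory_gain Rate multiplier on preferred-condition recognition
#'   trials (MS/dual; >= 1).
#' @param pref_condition `"new"` or `"old"` (MS/dual).
#' @param latency_s Response latency after stimulus onset (default 0.2 s).
#' @param resp_duration_s Response-window length (default 1 s).
#' @param refractory_s Absolute refractory period; spikes closer than this to
#'   their predecessor are deleted (default 3 ms).
#' @return List of class `neuron_spec`.
#' @export
neuron_spec <- function(kind = c("none", "VS", "MS", "dual"),
                        baseline_hz = 5,
                        category_gain = 3, pref_category = NA_character_,
                        memory_gain = 3, pref_condition = c("new", "old"),
                        latency_s = 0.2, resp_duration_s = 1.0,
                        refractory_s = 0.003) {
  kind <- match.arg(kind)
  pref_condition <- match.arg(pref_condition)
  if (baseline_hz <= 0) stop("baseline_hz must be > 0")
  if (kind %in% c("VS", "dual") && category_gain < 1) {
    stop("category_gain must be >= 1 for tuned units")
  }
  if (kind %in% c("MS", "dual") && memory_gain < 1) {
    stop("memory_gain must be >= 1 for tuned units")
  }
  structure(list(kind = kind, baseline_hz = baseline_hz,
                 category_gain = category_gain, pref_category = pref_category,
                 memory_gain = memory_gain, pref_condition = pref_condition,
                 latency_s = latency_s, resp_duration_s = resp_duration_s,
                 refractory_s = refractory_s),
            class = "neuron_spec")
}

#' Simulate a unit's spike train over a session
#'
#' Piecewise-constant-rate (inhomogeneous) Poisson process over
#' `[0, t_end]`: the rate is `baseline_hz` everywhere except in the window
#' `[start_time + latency, start_time + latency + resp_duration)` of trials
#' matching the unit's tuning, where it is multiplied by the relevant gain(s).
#' A VS unit matches trials showing its preferred category (either phase); an
#' MS unit matches recognition trials of its preferred new/old condition; a
#' dual unit applies both multipliers where both match. The process is
#' simulated as a superposition of a homogeneous baseline train and extra
#' window-restricted trains at the excess rate, after which spikes closer than
#' `refractory_s` to the previous retained spike are deleted.
#'
#' @param spec A [neuron_spec()].
#' @param trials Trials data.frame with valid per-trial times.
#' @param seed Integer seed.
#' @param t_end Session end time (s); default just past the last trial.
#' @return Sorted numeric vector of spike times (s).
#' @export
simulate_spike_train <- function(spec, trials, seed = 1L,
                                 t_end = max(trials$delay2_time) + 1) {
  with_seed(seed, {
    spikes <- runif_poisson_window(spec$baseline_hz, 0, t_end)
    extra <- extra_gain_windows(spec, trials)
    if (nrow(extra)) {
      for (i in seq_len(nrow(extra))) {
        rate_extra <- spec$baseline_hz * (extra$gain[i] - 1)
        spikes <- c(spikes,
                    runif_poisson_window(rate_extra, extra$t0[i], extra$t1[i]))
      }
    }
    spikes <- sort(spikes)
    drop_refractory(spikes, spec$refractory_s)
  })
}

# per-trial response windows and their total gain multiplier (only rows with
# gain > 1 are returned)
extra_gain_windows <- function(spec, trials) {
  gain <- rep(1, nrow(trials))
  if (spec$kind %in% c("VS", "dual")) {
    m <- trials$category_name == spec$pref_category
    gain[m] <- gain[m] * spec$category_gain
  }
  if (spec$kind %in% c("MS", "dual")) {
    want <- if (spec$pref_condition == "new") 1L else 0L
    m <- trials$phase == "recognition" & !is.na(trials$new_old_label) &
      trials$new_old_label == want
    gain[m] <- gain[m] * spec$memory_gain
  }
  keep <- gain > 1
  data.frame(t0 = trials$start_time[keep] + spec$latency_s,
             t1 = trials$start_time[keep] + spec$latency_s + spec$resp_duration_s,
             gain = gain[keep])
}

# homogeneous Poisson spikes on [t0, t1) at `rate` Hz
runif_poisson_window <- function(rate, t0, t1) {
  if (rate <= 0 || t1 <= t0) return(numeric(0))
  n <- stats::rpois(1, rate * (t1 - t0))
  sort(stats::runif(n, t0, t1))
}

# delete spikes within `refractory` of the previously retained spike
drop_refractory <- function(spikes, refractory) {
  if (length(spikes) < 2 || refractory <= 0) return(spikes)
  keep <- logical(length(spikes))
  keep[1] <- TRUE
  last <- spikes[1]
  for (i in 2:length(spikes)) {
    if (spikes[i] - last >= refractory) {
      keep[i] <- TRUE
      last <- spikes[i]
    }
  }
  spikes[keep]
}

#' Synthesize a mean extracellular waveform
#'
#' Fixed biphasic template (difference of two Gaussians, a sharp negative
#' deflection followed by a broader positive rebound) scaled so its absolute
#' peak equals `amplitude_uv`, plus white noise. At the 100 kHz waveform
#' sampling rate the default 256 samples span 2.56 ms.
#'
#' @param amplitude_uv Peak absolute amplitude, microvolts (> 0).
#' @param noise_sd_uv Standard deviation of additive white noise, microvolts.
#' @param seed Integer seed (noise is deterministic given it).
#' @param n_samples Samples per waveform (default 256).
#' @return Numeric vector of length `n_samples` (microvolts).
#' @export
synth_waveform <- function(amplitude_uv, noise_sd_uv = 0, seed = 1L,
                           n_samples = 256L) {
  if (amplitude_uv <= 0) stop("amplitude_uv must be > 0")
  t <- seq_len(n_samples)
  tpl <- -exp(-((t - n_samples * 0.35)^2) / (2 * (n_samples * 0.04)^2)) +
    0.45 * exp(-((t - n_samples * 0.55)^2) / (2 * (n_samples * 0.10)^2))
  tpl <- tpl / max(abs(tpl)) * amplitude_uv
  if (noise_sd_uv > 0) {
    tpl <- tpl + with_seed(seed, stats::rnorm(n_samples, 0, noise_sd_uv))
  }
  tpl
}
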