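#' Generator configuration for a synthetic session
#'
#' @param session_id Session identifier (also used in file names).
#' @param variant Task variant 1, 2 or 3.
#' @param seed Integer master seed; every stochastic choice in the session
#'   derives deterministically from it.
#' @param n_units Number of sorted units to simulate.
#' @param frac_vs,frac_ms,frac_dual Fractions of visually selective, memory
#'   selective and dual units (remainder untuned); must sum to <= 1.
#' @param baseline_hz Baseline firing rate of simulated units.
#' @param category_gain,memory_gain Tuning multipliers for selective units.
#' @param n_electrodes Number of microwires in the electrode table.
#' @param timing A [task_timing()] object.
#' @param behavior A [behavior_params()] object.
#' @param subject_site Site prefix for the subject id: `"H"`, `"C"` or `"T"`.
#' @param start_year,start_month Calendar year/month of the session.
#' @param balanced_categories Enforce exact balance (20 encoding images per
#'   category; 10 old + 10 new per category at recognition). Default `TRUE`.
#' @return List of class `generator_config`.
#' @export
generator_config <- function(session_id = "C01_s1", variant = 1L, seed = 1L,
                             n_units = 20L, frac_vs = 0.2, frac_ms = 0.1,
                             frac_dual = 0.05, baseline_hz = 5,
                             category_gain = 3, memory_gain = 3,
                             n_electrodes = 8L,
                             timing = task_timing(),
                             behavior = behavior_params(),
                             subject_site = "C",
                             start_year = 2019L, start_month = 1L,
                             balanced_categories = TRUE) {
  fr <- c(frac_vs, frac_ms, frac_dual)
  if (any(fr < 0) || sum(fr) > 1) {
    stop("unit-kind fractions must be nonnegative and sum to <= 1")
  }
  if (!subject_site %in% c("H", "C", "T")) {
    stop("subject_site must be H, C or T")
  }
  structure(list(session_id = session_id, variant = as.integer(variant),
                 seed = as.integer(seed), n_units = as.integer(n_units),
                 frac_vs = frac_vs, frac_ms = frac_ms, frac_dual = frac_dual,
                 baseline_hz = baseline_hz, category_gain = category_gain,
                 memory_gain = memory_gain,
                 n_electrodes = as.integer(n_electrodes),
                 timing = timing, behavior = behavior,
                 subject_site = subject_site,
                 start_year = as.integer(start_year),
                 start_month = as.integer(start_month),
                 balanced_categories = balanced_categories),
            class = "generator_config")
}

#' Generate a complete synthetic session
#'
#' Produces a full [session_bundle()]: 100 encoding trials (20 per category by
#' default), 100 recognition trials — 50 repeats of encoding images (label 0,
#' old) and 50 new images (label 1), 10 + 10 per category, shuffled —
#' signal-detection behavior with 6-level confidence, the rendered TTL
#' event/experiment-ID streams, simulated units (untuned / VS / MS / dual
#' composition per the config) with spike trains, waveforms and quality
#' metrics, an electrode table with MTL locations, subject metadata, and
#' category-patterned placeholder images (16x16). Fully deterministic given
#' `cfg$seed`.
#'
#' The generator's ground truth (each unit's kind and preference) is attached
#' as `attr(bundle, "ground_truth")`; it is not part of the session schema and
#' is not serialized to NWB.
#'
#' @param cfg A [generator_config()].
#' @return A `session_bundle`.
#' @examples
#' s <- generate_session(generator_config(seed = 7, n_units = 4))
#' s
#' @export
generate_session <- function(cfg = generator_config()) {
  tm <- cfg$timing
  n_cat <- tm$n_categories
  cats <- tm$category_names

  ## --- stimulus assignment -------------------------------------------------
  enc <- with_seed(derive_seed(cfg$seed, 1), {
    if (cfg$balanced_categories) {
      if (tm$n_encoding %% n_cat != 0) {
        stop("n_encoding must be divisible by n_categories when balanced")
      }
      cat_idx <- sample(rep(seq_len(n_cat), tm$n_encoding / n_cat))
    } else {
      cat_idx <- sample(seq_len(n_cat), tm$n_encoding, replace = TRUE)
    }
    data.frame(stimulus_id = sprintf("%s_enc%03d", cats[cat_idx],
                                     seq_len(tm$n_encoding)),
               category_name = cats[cat_idx], stim_category = cat_idx)
  })
  rec <- with_seed(derive_seed(cfg$seed, 2), {
    n_old <- tm$n_recognition %/% 2L
    n_new <- tm$n_recognition - n_old
    if (cfg$balanced_categories) {
      per_cat <- n_old / n_cat
      old_rows <- unlist(lapply(seq_len(n_cat), function(k) {
        sample(which(enc$stim_category == k), per_cat)
      }))
      new_cat <- rep(seq_len(n_cat), n_new / n_cat)
    } else {
      old_rows <- sample(nrow(enc), n_old)
      new_cat <- sample(seq_len(n_cat), n_new, replace = TRUE)
    }
    old <- enc[old_rows, ]
    old$new_old_label <- 0L
    new <- data.frame(
      stimulus_id = sprintf("%s_new%03d", cats[new_cat], seq_len(n_new)),
      category_name = cats[new_cat], stim_category = new_cat,
      new_old_label = 1L)
    out <- rbind(old, new)
    out[sample(nrow(out)), ]
  })

  ## --- behavior ------------------------------------------------------------
  learn_beh <- simulate_learning_behavior(enc$category_name, cfg$behavior,
                                          derive_seed(cfg$seed, 3))
  recog_beh <- simulate_recognition_behavior(rec$new_old_label, cfg$behavior,
                                             derive_seed(cfg$seed, 4))

  ## --- trial timing --------------------------------------------------------
  trials <- rbind(
    data.frame(phase = "learning", enc,
               new_old_label = NA_integer_, rt = pmin(learn_beh$rt_s, tm$max_rt_s),
               response_value = learn_beh$response_code),
    data.frame(phase = "recognition",
               rec[, c("stimulus_id", "category_name", "stim_category")],
               new_old_label = rec$new_old_label,
               rt = pmin(recog_beh$rt_s, tm$max_rt_s),
               response_value = recog_beh$response_code)
  )
  n_tr <- nrow(trials)
  trial_span <- tm$stim_duration_s + tm$delay_stim_to_question_s +
    trials$rt + tm$post_response_s
  starts <- tm$iti_s + c(0, cumsum(trial_span[-n_tr] + tm$iti_s))
  trials$trial_id <- seq_len(n_tr)
  trials$start_time <- starts
  trials$stop_time <- starts + tm$stim_duration_s
  trials$delay1_time <- trials$stop_time + tm$delay_stim_to_question_s
  trials$response_time <- trials$delay1_time + trials$rt
  trials$delay2_time <- trials$response_time + tm$post_response_s
  trials$rt <- NULL
  trials <- trials[, c("trial_id", "phase", "start_time", "stop_time",
                       "delay1_time", "response_time", "delay2_time",
                       "response_value", "category_name", "stim_category",
                       "new_old_label", "stimulus_id")]
  rownames(trials) <- NULL

  tl <- build_trial_timeline(trials, cfg$variant, tm)

  ## --- stimuli (placeholder category-patterned images) ---------------------
  stim_ids <- unique(trials$stimulus_id)
  stimuli <- with_seed(derive_seed(cfg$seed, 5), {
    out <- lapply(stim_ids, function(id) {
      k <- trials$stim_category[match(id, trials$stimulus_id)]
      base <- outer(seq_len(16), seq_len(16),
                    function(i, j) (i * k + j) %% (k + 4))
      img <- (base * 25 + sample(0:24, 256, replace = TRUE)) %% 256
      storage.mode(img) <- "integer"
      img
    })
    names(out) <- stim_ids
    out
  })

  ## --- electrodes ----------------------------------------------------------
  areas <- c("Left Hippocampus", "Right Hippocampus",
             "Left Amygdala", "Right Amygdala")
  area_mni <- rbind(c(-25, -20, -12), c(25, -20, -12),
                    c(-22, -4, -18), c(22, -4, -18))
  electrodes <- with_seed(derive_seed(cfg$seed, 6), {
    a <- sample(rep_len(seq_along(areas), cfg$n_electrodes))
    data.frame(id = seq_len(cfg$n_electrodes) - 1L,
               location = areas[a],
               x = area_mni[a, 1] + round(stats::rnorm(cfg$n_electrodes, 0, 1.5), 1),
               y = area_mni[a, 2] + round(stats::rnorm(cfg$n_electrodes, 0, 1.5), 1),
               z = area_mni[a, 3] + round(stats::rnorm(cfg$n_electrodes, 0, 1.5), 1),
               filtering = "300-3000Hz",
               orig_channel = seq_len(cfg$n_electrodes),
               group_name = "microwires",
               device_name = "Neuralynx-Atlas")
  })

  ## --- units ---------------------------------------------------------------
  n_vs <- round(cfg$n_units * cfg$frac_vs)
  n_ms <- round(cfg$n_units * cfg$frac_ms)
  n_dual <- round(cfg$n_units * cfg$frac_dual)
  kinds <- c(rep("VS", n_vs), rep("MS", n_ms), rep("dual", n_dual),
             rep("none", cfg$n_units - n_vs - n_ms - n_dual))
  unit_meta <- with_seed(derive_seed(cfg$seed, 7), {
    data.frame(unit_id = seq_len(cfg$n_units),
               kind = sample(kinds),
               pref_category = sample(cats, cfg$n_units, replace = TRUE),
               pref_condition = sample(c("new", "old"), cfg$n_units,
                                       replace = TRUE),
               electrode_index = sample(cfg$n_electrodes, cfg$n_units,
                                        replace = TRUE),
               amplitude_uv = stats::runif(cfg$n_units, 50, 150),
               noise_sd_uv = stats::runif(cfg$n_units, 3, 8))
  })

  units <- unit_meta[, c("unit_id", "electrode_index")]
  units$orig_cluster_id <- units$unit_id * 10L
  units$spike_times <- vector("list", cfg$n_units)
  units$waveform_mean_encoding <- vector("list", cfg$n_units)
  units$waveform_mean_recognition <- vector("list", cfg$n_units)
  units$snr <- NA_real_
  units$isol_dist <- NA_real_
  for (i in seq_len(cfg$n_units)) {
    spec <- neuron_spec(kind = unit_meta$kind[i],
                        baseline_hz = cfg$baseline_hz,
                        category_gain = cfg$category_gain,
                        pref_category = unit_meta$pref_category[i],
                        memory_gain = cfg$memory_gain,
                        pref_condition = unit_meta$pref_condition[i])
    units$spike_times[[i]] <-
      simulate_spike_train(spec, trials, derive_seed(cfg$seed, 100 + i))
    units$waveform_mean_encoding[[i]] <-
      synth_waveform(unit_meta$amplitude_uv[i], unit_meta$noise_sd_uv[i],
                     derive_seed(cfg$seed, 200 + i))
    units$waveform_mean_recognition[[i]] <-
      synth_waveform(unit_meta$amplitude_uv[i], unit_meta$noise_sd_uv[i],
                     derive_seed(cfg$seed, 300 + i))
    units$snr[i] <- compute_snr(units$waveform_mean_encoding[[i]],
                                unit_meta$noise_sd_uv[i])
    units$isol_dist[i] <- with_seed(derive_seed(cfg$seed, 400 + i), {
      clus <- matrix(stats::rnorm(80 * 3), ncol = 3)
      sep <- stats::runif(1, 2, 6)
      other <- matrix(stats::rnorm(200 * 3, mean = sep), ncol = 3)
      isolation_distance(clus, other)
    })
  }

  subject <- list(
    subject_id = sprintf("%s%02d", cfg$subject_site,
                         (cfg$seed %% 89) + 1L),
    age = 20L + (cfg$seed %% 40L),
    sex = c("M", "F")[(cfg$seed %% 2L) + 1L],
    species = "Homo sapiens",
    description = "epilepsy monitoring; hybrid depth electrodes with microwires"
  )

  s <- session_bundle(session_id = cfg$session_id, variant = cfg$variant,
                      subject = subject, electrodes = electrodes,
                      units = units, events = tl$events, tags = tl$tags,
                      trials = trials, stimuli = stimuli,
                      start_year = cfg$start_year,
                      start_month = cfg$start_month)
  attr(s, "ground_truth") <- unit_meta[, c("unit_id", "kind", "pref_category",
                                           "pref_condition")]
  s
}

#' Read a declarative session configuration file
#'
#' YAML file listing one or more sessions plus shared analysis settings; each
#' session entry may set any [generator_config()] field (nested `timing:` and
#' `behavior:` maps are passed through to [task_timing()] and
#' [behavior_params()]). An `nwb_dir:` top-level key instead points the
#' pipeline at pre-existing NWB files (analysis-only mode).
#'
#' @param path Path to a YAML config file.
#' @return List with elements `sessions` (list of `generator_config`) and/or
#'   `nwb_dir`, plus `alpha` and `n_boot` analysis settings.
#' @export
read_session_config <- function(path) {
  raw <- yaml::read_yaml(path)
  out <- list(alpha = raw$alpha %||% 0.05,
              n_boot = raw$n_boot %||% 1000L,
              nwb_dir = raw$nwb_dir)
  if (!is.null(raw$sessions)) {
    out$sessions <- lapply(raw$sessions, function(sd) {
      args <- sd
      if (!is.null(args$timing)) args$timing <- do.call(task_timing, args$timing)
      if (!is.null(args$behavior)) {
        args$behavior <- do.call(behavior_params, args$behavior)
      }
      do.call(generator_config, args)
    })
  }
  out
}
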