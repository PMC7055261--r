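#' In-memory model of one recognition-memory session
#'
#' A `session_bundle` collects everything recorded in one session of the
#' new/old task: subject metadata, the electrode table, the sorted units with
#' their spike times, waveforms and quality metrics, the raw TTL event and
#' experiment-ID streams, the trials table, and the presented stimuli. It is
#' the in-memory mirror of one NWB session file.
#'
#' Field conventions:
#' * All times are seconds, numeric, relative to the start of the experiment.
#'   The NWB layer owns the (PHI-reduced) calendar `session_start_time`.
#' * `trials` is a data.frame with columns `trial_id`, `phase`
#'   (`"learning"`/`"recognition"`), `start_time` (stimulus onset),
#'   `stop_time` (stimulus offset), `delay1_time` (question-screen onset),
#'   `response_time`, `delay2_time` (end of trial), `response_value` (raw TTL),
#'   `category_name`, `stim_category` (integer), `new_old_label`
#'   (0 = old, 1 = new; `NA` for learning trials) and `stimulus_id`.
#' * `units` is a data.frame with columns `unit_id`, `electrode_index`
#'   (1-based row of `electrodes`), `orig_cluster_id`, `snr`, `isol_dist`, and
#'   list-columns `spike_times`, `waveform_mean_encoding`,
#'   `waveform_mean_recognition` (equal-length microvolt vectors sampled at
#'   `waveform_rate_hz`).
#' * `events`/`tags` are data.frames (`time_s`, `code`) / (`time_s`, `xid`)
#'   of identical length and order.
#'
#' @param session_id Character session identifier.
#' @param variant Task variant 1, 2 or 3 (fixes the experiment-ID pair).
#' @param subject List with `subject_id` (site prefix H/C/T), `age`, `sex`,
#'   `species`, `description`.
#' @param electrodes Electrode table (data.frame: `id`, `location`, `x`, `y`,
#'   `z`, `filtering`, `orig_channel`, `group_name`, `device_name`).
#' @param units Units table as described above.
#' @param events,tags Paired TTL / experiment-ID streams.
#' @param trials Trials table as described above.
#' @param stimuli Named list of integer image matrices, keyed by stimulus id.
#' @param start_year,start_month Calendar year/month of the session; the day
#'   is always serialized as the first of the month.
#' @param waveform_rate_hz Waveform sampling rate (default 100 kHz).
#' @return An object of class `session_bundle`.
#' @seealso [generate_session()], [validate_session()], [write_session_nwb()]
#' @export
session_bundle <- function(session_id, variant, subject, electrodes, units,
                           events, tags, trials, stimuli,
                           start_year = 2019L, start_month = 1L,
                           waveform_rate_hz = 1e5) {
  structure(list(
    session_id = as.character(session_id),
    variant = as.integer(variant),
    subject = subject,
    electrodes = electrodes,
    units = units,
    events = events,
    tags = tags,
    trials = trials,
    stimuli = stimuli,
    start_year = as.integer(start_year),
    start_month = as.integer(start_month),
    waveform_rate_hz = as.numeric(waveform_rate_hz)
  ), class = "session_bundle")
}

#' @export
print.session_bundle <- function(x, ...) {
  n_rec <- sum(x$trials$phase == "recognition")
  cat("<session_bundle> ", x$session_id,
      " (variant ", x$variant, ", subject ", x$subject$subject_id, ")\n",
      "  trials: ", nrow(x$trials), " (", nrow(x$trials) - n_rec,
      " learning + ", n_rec, " recognition)\n",
      "  units: ", nrow(x$units),
      ", electrodes: ", nrow(x$electrodes),
      ", events: ", nrow(x$events), "\n", sep = "")
  invisible(x)
}

#' Validate a session bundle against the schema invariants
#'
#' Checks every structural invariant of the session model and the TTL grammar
#' of the event stream: trial time ordering
#' (`start < stop <= delay1 <= response <= delay2`), response codes legal for
#' their phase, new/old labels present exactly on recognition trials, strictly
#' increasing spike times, equal-length paired waveform vectors, non-negative
#' SNR, resolvable electrode references, equal-length event/tag streams using
#' one legal variant pair, and the event grammar: stream starts with 55, ends
#' with 66, and each trial contributes the sequence
#' (1, 2, 3, response, 6) in order.
#'
#' Violations are reported, never raised, so a defective session can be
#' inspected.
#'
#' @param s A `session_bundle`.
#' @return Character vector of human-readable violations; empty if valid.
#' @export
validate_session <- function(s) {
  v <- character(0)
  say <- function(...) v <<- c(v, paste0(...))
  cm <- code_maps()

  ## subject
  if (!grepl("^[HCT]", s$subject$subject_id %||% "")) {
    say("subject_id must start with site prefix H, C or T: ",
        s$subject$subject_id)
  }

  ## trials
  tr <- s$trials
  for (i in seq_len(nrow(tr))) {
    t <- tr[i, ]
    if (!(t$start_time < t$stop_time && t$stop_time <= t$delay1_time &&
          t$delay1_time <= t$response_time && t$response_time <= t$delay2_time)) {
      say("trial ", t$trial_id, ": times not ordered ",
          "start<stop<=delay1<=response<=delay2")
    }
    if (!t$response_value %in% legal_responses(t$phase)) {
      say("trial ", t$trial_id, ": response ", t$response_value,
          " illegal for phase ", t$phase)
    }
    if (t$phase == "recognition" && is.na(t$new_old_label)) {
      say("trial ", t$trial_id, ": recognition trial lacks new/old label")
    }
    if (t$phase == "learning" && !is.na(t$new_old_label)) {
      say("trial ", t$trial_id, ": learning trial carries a new/old label")
    }
  }
  n_recog <- sum(tr$phase == "recognition")
  recog_stim <- tr$stimulus_id[tr$phase == "recognition"]
  if (length(recog_stim) && anyNA(recog_stim)) {
    say("recognition trials with missing stimulus_id")
  }

  ## units
  for (i in seq_len(nrow(s$units))) {
    u <- s$units[i, ]
    st <- u$spike_times[[1]]
    if (length(st) > 1 && any(diff(st) <= 0)) {
      say("unit ", u$unit_id, ": spike times not strictly increasing")
    }
    if (length(u$waveform_mean_encoding[[1]]) !=
        length(u$waveform_mean_recognition[[1]])) {
      say("unit ", u$unit_id, ": waveform vectors differ in length")
    }
    if (is.na(u$snr) || u$snr < 0) say("unit ", u$unit_id, ": negative SNR")
    if (u$electrode_index < 1 || u$electrode_index > nrow(s$electrodes)) {
      say("unit ", u$unit_id, ": electrode_index ", u$electrode_index,
          " not a row of the electrode table")
    }
  }

  ## electrodes
  if (anyDuplicated(s$electrodes$id)) say("duplicate electrode ids")

  ## event/tag streams
  ev <- s$events; tg <- s$tags
  if (nrow(ev) != nrow(tg)) {
    say("events and experiment_ids streams differ in length (",
        nrow(ev), " vs ", nrow(tg), ")")
  }
  bad <- setdiff(ev$code, as.integer(names(cm$ttl_codes)))
  if (length(bad)) say("unknown TTL codes: ", paste(bad, collapse = ", "))
  pair <- cm$variant_pairs[s$variant, ]
  bad_x <- setdiff(tg$xid, pair)
  if (length(bad_x)) {
    say("experiment IDs not in variant-", s$variant, " pair (",
        paste(pair, collapse = ","), "): ", paste(bad_x, collapse = ", "))
  }
  if (any(ev$time_s < 0)) say("negative event times")
  if (is.unsorted(ev$time_s)) say("event times not nondecreasing")

  ## TTL grammar: 55, then per trial (1,2,3,resp,6), then 66
  v <- c(v, check_ttl_grammar(ev$code))

  if (n_recog != length(recog_stim)) {
    say("recognition trial count does not match shown-stimulus count")
  }
  v
}

# grammar check on a bare code sequence; returns violations
check_ttl_grammar <- function(codes) {
  v <- character(0)
  n <- length(codes)
  if (n == 0) return("empty event stream")
  if (codes[1] != 55) v <- c(v, "event stream does not start with 55")
  if (codes[n] != 66) v <- c(v, "event stream lacks terminal 66")
  body <- codes[codes != 55 & codes != 66]
  if (length(body) %% 5 != 0) {
    v <- c(v, "event stream body length not a multiple of 5")
    return(v)
  }
  resp <- c(code_maps()$learning_responses, code_maps()$recognition_responses)
  if (length(body)) {
    m <- matrix(body, nrow = 5)
    ok <- m[1, ] == 1 & m[2, ] == 2 & m[3, ] == 3 &
      m[4, ] %in% resp & m[5, ] == 6
    if (!all(ok)) {
      v <- c(v, paste0("malformed trial sequence at trial(s) ",
                       paste(which(!ok), collapse = ", ")))
    }
  }
  v
}

`%||%` <- function(a, b) if (is.null(a)) b else a
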