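#' Task timing configuration
#'
#' Durations of the within-trial epochs and the session structure. The task
#' protocol does not fix stimulus pacing, so these are explicit generator
#' parameters: 1 s stimulus presentation, 0.5 s delay to the question screen,
#' 0.5 s from response to end-of-trial, 1 s inter-trial interval.
#'
#' @param stim_duration_s Stimulus on-screen time (s).
#' @param delay_stim_to_question_s Delay from stimulus offset to question
#'   screen (s).
#' @param max_rt_s Reaction times are truncated at this value (s).
#' @param post_response_s Delay from response to the end-of-trial marker (s).
#' @param iti_s Inter-trial interval (s).
#' @param n_encoding,n_recognition Trials per phase (100 each; the recognition
#'   block is 50 old + 50 new).
#' @param n_categories Number of visual categories (5).
#' @param category_names Names of the categories used in this session, drawn
#'   from the task's image-category list.
#' @return List of class `task_timing`.
#' @export
task_timing <- function(stim_duration_s = 1.0,
                        delay_stim_to_question_s = 0.5,
                        max_rt_s = 5.0,
                        post_response_s = 0.5,
                        iti_s = 1.0,
                        n_encoding = 100L,
                        n_recognition = 100L,
                        n_categories = 5L,
                        category_names = c("houses", "landscapes", "mobility",
                                           "phones", "animals")) {
  durs <- c(stim_duration_s, delay_stim_to_question_s, max_rt_s,
            post_response_s, iti_s)
  if (any(durs <= 0)) stop("all durations must be > 0")
  if (length(category_names) != n_categories) {
    stop("need exactly ", n_categories, " category names")
  }
  structure(list(stim_duration_s = stim_duration_s,
                 delay_stim_to_question_s = delay_stim_to_question_s,
                 max_rt_s = max_rt_s, post_response_s = post_response_s,
                 iti_s = iti_s, n_encoding = as.integer(n_encoding),
                 n_recognition = as.integer(n_recognition),
                 n_categories = as.integer(n_categories),
                 category_names = category_names),
            class = "task_timing")
}

# full list of visual categories used across task variants
task_category_pool <- function() {
  c("houses", "landscapes", "mobility", "phones", "animals", "fruits",
    "kids", "military", "space", "cars", "food", "people", "spatial")
}

#' Render the TTL timeline of a session
#'
#' Turns a trials table (with its per-trial times and response codes already
#' filled in) into the paired raw streams the acquisition system would have
#' produced: an event stream of TTL codes and an experiment-ID stream of equal
#' length. The stream is `55` (start of experiment), then for each trial the
#' sequence stimulus-onset `1`, stimulus-offset `2`, question-screen `3`, the
#' response code, end-of-trial `6`, and finally `66` (end of experiment).
#' Learning-block entries are tagged with the variant's learning experiment ID
#' and recognition-block entries with its recognition ID; the boundary markers
#' 55/66 take the ID of the adjacent block.
#'
#' @param trials Trials data.frame (see [session_bundle()]); learning block
#'   must precede the recognition block.
#' @param variant Task variant 1, 2 or 3.
#' @param timing A [task_timing()] object (used for the terminal marker time).
#' @return List with data.frames `events` (`time_s`, `code`) and `tags`
#'   (`time_s`, `xid`).
#' @export
build_trial_timeline <- function(trials, variant, timing = task_timing()) {
  pair <- variant_ids(variant)
  ph <- trials$phase
  if (is.unsorted(match(ph, c("learning", "recognition")))) {
    stop("learning block must precede recognition block")
  }
  for (i in seq_len(nrow(trials))) {
    if (!trials$response_value[i] %in% legal_responses(ph[i])) {
      stop("trial ", i, ": response code ", trials$response_value[i],
           " illegal for phase ", ph[i])
    }
  }
  n <- nrow(trials)
  if (n == 0) {
    t_end <- timing$iti_s
    return(list(
      events = data.frame(time_s = c(0, t_end), code = c(55L, 66L)),
      tags = data.frame(time_s = c(0, t_end), xid = rep(pair[["learning"]], 2))
    ))
  }
  codes <- as.vector(rbind(1L, 2L, 3L, as.integer(trials$response_value), 6L))
  times <- as.vector(rbind(trials$start_time, trials$stop_time,
                           trials$delay1_time, trials$response_time,
                           trials$delay2_time))
  xid_tr <- ifelse(ph == "learning", pair[["learning"]], pair[["recognition"]])
  xids <- rep(as.integer(xid_tr), each = 5L)
  t_end <- trials$delay2_time[n] + timing$iti_s
  events <- data.frame(time_s = c(0, times, t_end),
                       code = c(55L, codes, 66L))
  tags <- data.frame(time_s = events$time_s,
                     xid = c(xids[1], xids, xids[length(xids)]))
  list(events = events, tags = tags)
}
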