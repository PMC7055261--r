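#' Split raw event/tag streams into learning and recognition blocks
#'
#' Uses the experiment-ID stream to partition the TTL events by phase. The
#' boundary markers 55/66 are stripped first (their absence is a session
#' validator concern, not a parse failure). The tags must use exactly one
#' legal (learning, recognition) variant pair.
#'
#' @param events data.frame (`time_s`, `code`).
#' @param tags data.frame (`time_s`, `xid`), same length and order.
#' @return List with data.frames `learning` and `recognition` (either may be
#'   empty), and `variant`.
#' @export
split_blocks <- function(events, tags) {
  if (nrow(events) != nrow(tags)) {
    stop("events and experiment_ids streams differ in length")
  }
  keep <- !(events$code %in% c(55L, 66L))
  events <- events[keep, , drop = FALSE]
  tags <- tags[keep, , drop = FALSE]
  cm <- code_maps()
  unknown <- setdiff(unique(tags$xid), as.integer(names(cm$experiment_ids)))
  if (length(unknown)) {
    stop("unknown experiment IDs: ", paste(unknown, collapse = ", "))
  }
  variant <- variant_from_ids(tags$xid)  # errors on mixed pairs
  pair <- variant_ids(variant)
  list(learning = events[tags$xid == pair[["learning"]], , drop = FALSE],
       recognition = events[tags$xid == pair[["recognition"]], , drop = FALSE],
       variant = variant)
}

#' Decode a behavioral response code
#'
#' @param code Integer TTL response code.
#' @param phase `"learning"` or `"recognition"`.
#' @return For learning, a list with `answer` (`"yes-animal"`/`"no-animal"`);
#'   for recognition, a list with `judgment` (`"new"`/`"old"`; old iff
#'   `code >= 34`) and `confidence` (`"guess"`, `"probably"`, `"confident"`).
#' @examples
#' decode_response(36, "recognition")
#' @export
decode_response <- function(code, phase) {
  if (phase == "learning") {
    if (!code %in% c(20L, 21L)) {
      stop("code ", code, " is not a learning response (20/21)")
    }
    return(list(answer = if (code == 20L) "yes-animal" else "no-animal"))
  }
  if (phase == "recognition") {
    if (!code %in% 31:36) {
      stop("code ", code, " is not a recognition response (31..36)")
    }
    conf <- c("confident", "probably", "guess", "guess", "probably",
              "confident")[code - 30L]
    return(list(judgment = if (code >= 34L) "old" else "new",
                confidence = conf))
  }
  stop("unknown phase: ", phase)
}

#' Reconstruct trials from one block's event stream
#'
#' The inverse of [build_trial_timeline()] for a single block: chunks the
#' stream into repetitions of (stimulus-onset 1, stimulus-offset 2,
#' question-screen 3, response, end-of-trial 6) and reads the five trial times
#' and the response code off the markers. Ground-truth new/old labels are not
#' carried in the TTL stream (they live in the trials table of the file), so
#' for recognition blocks they are supplied as an ordered argument and joined
#' by position.
#'
#' @param block_events data.frame (`time_s`, `code`) of one block, boundary
#'   markers already stripped.
#' @param phase `"learning"` or `"recognition"`.
#' @param ground_truth_labels For recognition blocks, an integer vector
#'   (0 old / 1 new), one per trial, in presentation order.
#' @return Trials data.frame (timing fields, `response_value`, `phase`,
#'   `new_old_label`; stimulus metadata columns are `NA` since the TTL stream
#'   does not encode them).
#' @export
parse_block_to_trials <- function(block_events, phase,
                                  ground_truth_labels = NULL) {
  codes <- block_events$code
  times <- block_events$time_s
  n <- length(codes)
  if (n %% 5 != 0) {
    stop("block stream length ", n, " is not a multiple of 5; ",
         "truncated or corrupted block")
  }
  n_tr <- n %/% 5
  resp_ok <- legal_responses(phase)
  expected <- c(1L, 2L, 3L, NA, 6L)
  for (k in seq_len(n_tr)) {
    chunk <- codes[(5 * (k - 1) + 1):(5 * k)]
    for (j in c(1L, 2L, 3L, 5L)) {
      if (chunk[j] != expected[j]) {
        stop("grammar violation at trial ", k, ": expected code ",
             expected[j], ", found ", chunk[j])
      }
    }
    if (!chunk[4] %in% resp_ok) {
      stop("grammar violation at trial ", k, ": expected a ", phase,
           " response code, found ", chunk[4])
    }
  }
  if (phase == "recognition") {
    if (is.null(ground_truth_labels) || length(ground_truth_labels) != n_tr) {
      stop("recognition block needs one ground-truth label per trial (",
           n_tr, ")")
    }
  }
  m_t <- matrix(times, nrow = 5)
  m_c <- matrix(codes, nrow = 5)
  data.frame(
    trial_id = seq_len(n_tr),
    phase = phase,
    start_time = m_t[1, ], stop_time = m_t[2, ], delay1_time = m_t[3, ],
    response_time = m_t[4, ], delay2_time = m_t[5, ],
    response_value = as.integer(m_c[4, ]),
    category_name = NA_character_, stim_category = NA_integer_,
    new_old_label = if (phase == "recognition") {
      as.integer(ground_truth_labels)
    } else NA_integer_,
    stimulus_id = NA_character_
  )
}

#' Reconstruct the full trials table from raw streams
#'
#' Convenience wrapper: [split_blocks()] then [parse_block_to_trials()] per
#' block, re-numbering trials across the session.
#'
#' @param events,tags Raw paired streams.
#' @param recognition_labels Ordered 0/1 labels for the recognition block.
#' @return Combined trials data.frame (learning block first).
#' @export
parse_session_trials <- function(events, tags, recognition_labels) {
  blocks <- split_blocks(events, tags)
  learn <- parse_block_to_trials(blocks$learning, "learning")
  recog <- parse_block_to_trials(blocks$recognition, "recognition",
                                 recognition_labels)
  out <- rbind(learn, recog)
  out$trial_id <- seq_len(nrow(out))
  out
}
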