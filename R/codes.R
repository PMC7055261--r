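#' TTL event-marker and experiment-ID code tables
#'
#' The behavioral control system emits integer TTL markers at task events and
#' tags every marker with an integer experiment ID identifying the block
#' (learning vs. recognition) of one of three task variants. `code_maps()`
#' returns the complete code tables used throughout the package.
#'
#' Event markers: 55 start of experiment, 1 stimulus onset, 2 stimulus offset,
#' 3 question-screen onset, 20/21 learning responses (animal yes/no), 31--36
#' recognition responses (31 new-confident ... 36 old-confident), 6 end of
#' trial, 66 end of experiment. Experiment IDs: learning blocks use 80, 83 or
#' 88 and the recognition block of the same session uses the paired ID one
#' larger (81, 84, 89); the pair identifies the task variant (1, 2 or 3).
#'
#' @return A list with elements:
#'   \describe{
#'     \item{ttl_codes}{named integer vector mapping code to semantic label.}
#'     \item{learning_responses, recognition_responses}{legal response codes
#'       per phase.}
#'     \item{experiment_ids}{named integer vector mapping experiment ID to
#'       phase (`"learning"` or `"recognition"`).}
#'     \item{variant_pairs}{3x2 integer matrix, one row per task variant,
#'       columns `learning` and `recognition`.}
#'   }
#' @examples
#' cm <- code_maps()
#' cm$ttl_codes[["55"]]
#' cm$variant_pairs[1, ]
#' @export
code_maps <- function() {
  ttl <- c(
    "55" = "start_of_experiment",
    "1"  = "stimulus_onset",
    "2"  = "stimulus_offset",
    "3"  = "question_screen_onset",
    "20" = "response_learning_yes_animal",
    "21" = "response_learning_no_animal",
    "31" = "response_recognition_new_confident",
    "32" = "response_recognition_new_probably",
    "33" = "response_recognition_new_guess",
    "34" = "response_recognition_old_guess",
    "35" = "response_recognition_old_probably",
    "36" = "response_recognition_old_confident",
    "6"  = "end_of_trial",
    "66" = "end_of_experiment"
  )
  xid <- c(
    "80" = "learning", "83" = "learning", "88" = "learning",
    "81" = "recognition", "84" = "recognition", "89" = "recognition"
  )
  pairs <- cbind(learning = c(80L, 83L, 88L),
                 recognition = c(81L, 84L, 89L))
  rownames(pairs) <- c("variant1", "variant2", "variant3")
  list(
    ttl_codes = ttl,
    learning_responses = c(20L, 21L),
    recognition_responses = 31:36,
    experiment_ids = xid,
    variant_pairs = pairs
  )
}

#' Experiment-ID pair for a task variant
#'
#' @param variant Task variant, 1, 2 or 3.
#' @return Integer vector `c(learning =, recognition =)`.
#' @export
variant_ids <- function(variant) {
  stopifnot(length(variant) == 1, variant %in% 1:3)
  code_maps()$variant_pairs[variant, ]
}

#' Task variant for an experiment-ID pair
#'
#' Inverse of [variant_ids()]: given the set of experiment IDs observed in a
#' session's tag stream, identify which of the three task variants was run.
#'
#' @param xids Integer vector of experiment IDs (any length; duplicates fine).
#' @return Integer variant 1, 2 or 3.
#' @export
variant_from_ids <- function(xids) {
  cm <- code_maps()
  u <- sort(unique(as.integer(xids)))
  for (v in 1:3) {
    pair <- cm$variant_pairs[v, ]
    if (all(u %in% pair)) return(v)
  }
  stop("experiment IDs {", paste(u, collapse = ", "),
       "} do not match a single legal (learning, recognition) variant pair")
}

# legal response codes for a phase ("learning" | "recognition")
legal_responses <- function(phase) {
  cm <- code_maps()
  switch(phase,
         learning = cm$learning_responses,
         recognition = cm$recognition_responses,
         stop("unknown phase: ", phase))
}
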