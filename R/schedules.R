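# Trial-schedule generators for the three task conditions.
#
# The main condition crosses five comparison questions with all 12 ordered
# pairs of the session's four pictures (5 x 12 x reps trials). The
# no-comparison control re-uses the picture sequence but asks subjects to
# count red fixation crosses. The question-comparison control names one
# concept in the question text and shows two of the remaining three pictures
# (3 question elements x 4 named concepts x 3 unordered pairs = 36
# combinations, each presented in both picture orders).

#' Simulation configuration
#'
#' Collects every knob of the synthetic-session generator: the picture set,
#' question labels, repetition counts, event durations and inter-event gaps
#' (with picture-onset jitter), and the units to simulate.
#'
#' @param pictures character vector of four picture ids.
#' @param questions_main five question labels; the perceptual question
#'   (brightness) must be among them, see `perceptual_question`.
#' @param perceptual_question the label treated as perceptual (non-semantic).
#' @param question_elements three comparison stems used by the
#'   question-comparison control.
#' @param reps_per_combo main condition: repetitions of each
#'   question x ordered-pair combination (default 5, giving 300 trials).
#' @param n_no_comparison number of no-comparison control trials (default 60).
#' @param presentations_per_qcomp_combo presentations of each of the 36
#'   question-comparison combinations (default 2, realising both picture
#'   orders; 72 trials).
#' @param question_duration_ms,pic_duration_ms,prompt_duration_ms event
#'   durations in ms. Question and prompt are self-paced in the task and
#'   simulated at fixed durations.
#' @param gap_ms fixed inter-event gap in ms (question to pic1, pic1 to pic2,
#'   pic2 to prompt).
#' @param jitter_ms length-2 range of uniform jitter added to picture onsets.
#' @param iti_ms inter-trial interval in ms.
#' @param units tibble of unit metadata plus tuning columns, e.g. built with
#'   [tuning_grid()]; may be empty.
#' @param seed integer seed controlling schedule order, jitter and spikes.
#' @return a `sim_config` list.
#' @export
sim_config <- function(pictures = c("tie", "strawberry", "pretzel", "chair"),
                       questions_main = c("Bigger?", "Last seen in real life?",
                                          "More expensive?", "Like better?",
                                          "Brighter?"),
                       perceptual_question = "Brighter?",
                       question_elements = c("Bigger?", "More expensive?",
                                             "Like better?"),
                       reps_per_combo = 5,
                       n_no_comparison = 60,
                       presentations_per_qcomp_combo = 2,
                       question_duration_ms = 1500,
                       pic_duration_ms = 1000,
                       prompt_duration_ms = 2000,
                       gap_ms = 500,
                       jitter_ms = c(0, 200),
                       iti_ms = 1000,
                       units = tuning_grid(n = 0),
                       seed = 1L) {
  stopifnot(length(pictures) == 4, !anyDuplicated(pictures),
            length(questions_main) == 5,
            perceptual_question %in% questions_main,
            length(question_elements) == 3,
            reps_per_combo >= 0, n_no_comparison >= 0,
            presentations_per_qcomp_combo >= 0,
            question_duration_ms > 0, pic_duration_ms > 0,
            prompt_duration_ms > 0, gap_ms > 0,
            length(jitter_ms) == 2, all(jitter_ms >= 0),
            jitter_ms[2] >= jitter_ms[1])
  structure(
    list(pictures = pictures, questions_main = questions_main,
         perceptual_question = perceptual_question,
         question_elements = question_elements,
         reps_per_combo = reps_per_combo,
         n_no_comparison = n_no_comparison,
         presentations_per_qcomp_combo = presentations_per_qcomp_combo,
         question_duration_ms = question_duration_ms,
         pic_duration_ms = pic_duration_ms,
         prompt_duration_ms = prompt_duration_ms,
         gap_ms = gap_ms, jitter_ms = jitter_ms, iti_ms = iti_ms,
         units = tibble::as_tibble(units), seed = as.integer(seed)),
    class = "sim_config"
  )
}

#' All ordered pairs of a picture set
#' @param pictures character vector.
#' @return tibble with columns `pic1_id`, `pic2_id` (no self-pairs).
#' @export
ordered_picture_pairs <- function(pictures) {
  g <- tidyr::expand_grid(pic1_id = pictures, pic2_id = pictures)
  dplyr::filter(g, .data$pic1_id != .data$pic2_id)
}

# Assign event onset times to a schedule skeleton. Picture onsets carry
# uniform jitter on top of the fixed gap; the prompt follows pic2 offset.
assign_onsets <- function(sched, config, t0 = 0) {
  n <- nrow(sched)
  if (n == 0) {
    return(dplyr::mutate(sched, t_question = numeric(0), t_pic1 = numeric(0),
                         t_pic2 = numeric(0), t_prompt = numeric(0)))
  }
  jit <- function(n) ms_to_s(stats::runif(n, config$jitter_ms[1], config$jitter_ms[2]))
  q_dur <- ms_to_s(config$question_duration_ms)
  p_dur <- ms_to_s(config$pic_duration_ms)
  pr_dur <- ms_to_s(config$prompt_duration_ms)
  gap <- ms_to_s(config$gap_ms)
  iti <- ms_to_s(config$iti_ms)
  d_pic1 <- q_dur + gap + jit(n)
  d_pic2 <- d_pic1 + p_dur + gap + jit(n)
  d_prompt <- d_pic2 + p_dur + gap
  trial_len <- d_prompt + pr_dur + iti
  t_question <- t0 + c(0, cumsum(trial_len[-n]))
  dplyr::mutate(sched,
                t_question = t_question,
                t_pic1 = t_question + d_pic1,
                t_pic2 = t_question + d_pic2,
                t_prompt = t_question + d_prompt)
}

blank_trial_cols <- function(sched) {
  dplyr::mutate(sched,
                named_concept = NA_character_,
                fixcross1 = NA_character_, fixcross2 = NA_character_,
                response_key = NA_integer_)
}

#' Generate the main-comparison schedule
#'
#' Every combination of the five questions and the 12 ordered picture pairs
#' occurs exactly `reps_per_combo` times, in pseudo-random order under the
#' config seed. Defaults give 300 trials: 60 per question, 25 per ordered
#' pair, 5 per specific combination.
#'
#' @param config a [sim_config()].
#' @param t0 session time (seconds) at which the first trial starts.
#' @return tibble of trials (one row each) with assigned onset times.
#' @export
generate_main_schedule <- function(config, t0 = 0) {
  combos <- tidyr::expand_grid(
    question_id = config$questions_main,
    ordered_picture_pairs(config$pictures)
  )
  sched <- combos[rep(seq_len(nrow(combos)), times = config$reps_per_combo), ]
  if (nrow(sched) > 0) sched <- sched[sample.int(nrow(sched)), ]
  sched <- dplyr::mutate(sched,
                         condition = "main",
                         prompt_variant = "position_prompt")
  sched <- blank_trial_cols(sched)
  if (nrow(sched) > 0) {
    sched$response_key <- sample(c(1L, 2L), nrow(sched), replace = TRUE)
  }
  assign_onsets(sched, config, t0 = t0)
}

#' Generate the no-comparison control schedule
#'
#' `n_no_comparison` trials with the same event structure as the main
#' condition; subjects count red fixation crosses instead of comparing
#' pictures. Red-cross counts (none / one / both) are balanced, and prompt
#' texts are assigned so that each answer key is correct equally often.
#'
#' @inheritParams generate_main_schedule
#' @return tibble of trials.
#' @export
generate_no_comparison_schedule <- function(config, t0 = 0) {
  n <- config$n_no_comparison
  if (n == 0) {
    return(assign_onsets(blank_trial_cols(dplyr::mutate(
      ordered_picture_pairs(config$pictures)[0, ],
      question_id = character(0), condition = character(0),
      prompt_variant = character(0))), config, t0 = t0))
  }
  pairs <- ordered_picture_pairs(config$pictures)
  pair_rows <- rep(seq_len(nrow(pairs)), length.out = n)
  sched <- pairs[sample(pair_rows), ]
  # red-cross count 0/1/2 balanced; the single red cross alternates position
  n_red <- rep(0:2, length.out = n)[sample.int(n)]
  first_red <- sample(c(TRUE, FALSE), n, replace = TRUE)
  fix1 <- ifelse(n_red == 2 | (n_red == 1 & first_red), "red", "white")
  fix2 <- ifelse(n_red == 2 | (n_red == 1 & !first_red), "red", "white")
  # prompt text pairs the true count with a foil so each key is correct
  # equally often: response_key balanced over the schedule
  key <- rep(c(1L, 2L), length.out = n)[sample.int(n)]
  sched <- dplyr::mutate(sched,
                         condition = "no_comparison",
                         question_id = NA_character_,
                         named_concept = NA_character_,
                         prompt_variant = "count_prompt",
                         fixcross1 = fix1, fixcross2 = fix2,
                         response_key = key)
  assign_onsets(sched, config, t0 = t0)
}

#' Generate the question-comparison control schedule
#'
#' Enumerates question element x named concept x unordered pair of the three
#' remaining pictures (3 x 4 x 3 = 36 combinations) and presents each
#' `presentations_per_qcomp_combo` times; the default two presentations
#' realise the two picture orders. The named concept never appears as a
#' presented picture, and the response prompt refers back to the first or
#' second picture, balanced.
#'
#' @inheritParams generate_main_schedule
#' @return tibble of trials.
#' @export
generate_question_comparison_schedule <- function(config, t0 = 0) {
  pics <- config$pictures
  combos <- purrr::map_dfr(config$question_elements, function(el) {
    purrr::map_dfr(pics, function(named) {
      rest <- setdiff(pics, named)
      prs <- utils::combn(rest, 2)
      tibble::tibble(element = el, named_concept = named,
                     pa = prs[1, ], pb = prs[2, ])
    })
  })
  reps <- config$presentations_per_qcomp_combo
  if (reps == 0 || nrow(combos) == 0) {
    sched <- tibble::tibble(question_id = character(0),
                            named_concept = character(0),
                            pic1_id = character(0), pic2_id = character(0),
                            condition = character(0),
                            prompt_variant = character(0),
                            fixcross1 = character(0), fixcross2 = character(0),
                            response_key = integer(0))
    return(assign_onsets(sched, config, t0 = t0))
  }
  sched <- purrr::map_dfr(seq_len(reps), function(k) {
    # alternate picture order across the repetitions of each combination
    flip <- (k %% 2L) == 0L
    tibble::tibble(
      question_id = paste(combos$element, combos$named_concept, sep = " | "),
      named_concept = combos$named_concept,
      pic1_id = if (flip) combos$pb else combos$pa,
      pic2_id = if (flip) combos$pa else combos$pb
    )
  })
  n <- nrow(sched)
  sched <- dplyr::mutate(sched,
                         condition = "question_comparison",
                         prompt_variant = rep(c("first_picture", "second_picture"),
                                              length.out = n),
                         fixcross1 = NA_character_, fixcross2 = NA_character_,
                         response_key = sample(c(1L, 2L), n, replace = TRUE))
  sched <- sched[sample.int(n), ]
  assign_onsets(sched, config, t0 = t0)
}
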