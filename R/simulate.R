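# Inhomogeneous-Poisson spike simulation with planted concept-neuron
# phenomenology: preferred-picture responses, delayed relational
# reactivations, question-name responses, anticipation ramps before the
# second picture, and prompt-locked reinstatement.
#
# The intensity is baseline plus a set of rectangular (or ramped) bumps tied
# to trial events. Spikes are drawn by superposition: an independent Poisson
# process per intensity component, merged and sorted. For piecewise-defined
# intensities this sampling is exact.

# onset of the non-specific prompt response, ms after prompt
NONSPECIFIC_PROMPT_ONSET_MS <- 250

#' Unit tuning defaults
#'
#' Builds a units table (metadata plus ground-truth tuning) for the
#' simulator. All gains are additive firing-rate increments in Hz; latency
#' and durations are in ms. A gain of zero disables the corresponding
#' response component.
#'
#' @param n number of units.
#' @param baseline_rate baseline firing rate, Hz.
#' @param preferred_pic preferred picture id (`NA` for untuned units).
#' @param response_gain rate increment while responding to the preferred
#'   picture, Hz.
#' @param response_latency response onset after stimulus onset, ms.
#' @param response_duration response bump duration, ms.
#' @param reactivation_gain rate increment of the delayed relational
#'   reactivation, Hz.
#' @param reactivation_onset_delay extra delay of the reactivation onset
#'   relative to the direct-response latency, ms (default 400).
#' @param question_name_gain response to questions naming the preferred
#'   concept, Hz.
#' @param anticipation_gain peak of the linear pre-second-picture ramp, Hz.
#' @param prompt_reinstatement_gain reactivation when the response prompt
#'   refers back to the preferred concept, Hz.
#' @param nonspecific_prompt_gain prompt response independent of tuning, Hz.
#' @param region,hemisphere,bundle_id,kind unit metadata, recycled.
#' @param unit_id identifiers; default `u001`, `u002`, ...
#' @return tibble with one row per unit.
#' @export
tuning_grid <- function(n,
                        baseline_rate = 5,
                        preferred_pic = NA_character_,
                        response_gain = 0,
                        response_latency = 100,
                        response_duration = 300,
                        reactivation_gain = 0,
                        reactivation_onset_delay = 400,
                        question_name_gain = 0,
                        anticipation_gain = 0,
                        prompt_reinstatement_gain = 0,
                        nonspecific_prompt_gain = 0,
                        region = "H", hemisphere = "R", bundle_id = "b1",
                        kind = "single",
                        unit_id = sprintf("u%03d", seq_len(n))) {
  stopifnot(all(baseline_rate >= 0), all(response_gain >= 0),
            all(reactivation_gain >= 0), all(reactivation_onset_delay >= 0))
  tibble::tibble(
    unit_id = rep_len(unit_id, n),
    region = rep_len(region, n), hemisphere = rep_len(hemisphere, n),
    bundle_id = rep_len(as.character(bundle_id), n), kind = rep_len(kind, n),
    baseline_rate = rep_len(baseline_rate, n),
    preferred_pic = rep_len(preferred_pic, n),
    response_gain = rep_len(response_gain, n),
    response_latency = rep_len(response_latency, n),
    response_duration = rep_len(response_duration, n),
    reactivation_gain = rep_len(reactivation_gain, n),
    reactivation_onset_delay = rep_len(reactivation_onset_delay, n),
    question_name_gain = rep_len(question_name_gain, n),
    anticipation_gain = rep_len(anticipation_gain, n),
    prompt_reinstatement_gain = rep_len(prompt_reinstatement_gain, n),
    nonspecific_prompt_gain = rep_len(nonspecific_prompt_gain, n)
  )
}

# Enumerate the intensity bumps a tuning plants on a trial table.
# Returns a tibble: start (s), dur (s), gain (Hz), shape ("rect"/"ramp").
tuning_bumps <- function(trials, tuning) {
  lat <- ms_to_s(tuning$response_latency)
  dur <- ms_to_s(tuning$response_duration)
  delay <- ms_to_s(tuning$reactivation_onset_delay)
  pref <- tuning$preferred_pic
  out <- list()
  add <- function(start, gain, duration = dur, shape = "rect") {
    if (length(start) > 0 && gain > 0) {
      out[[length(out) + 1L]] <<- tibble::tibble(
        start = start, dur = duration, gain = gain, shape = shape)
    }
  }
  if (!is.na(pref)) {
    # direct response whenever the preferred picture is on screen
    add(trials$t_pic1[trials$pic1_id == pref] + lat, tuning$response_gain)
    add(trials$t_pic2[trials$pic2_id == pref] + lat, tuning$response_gain)
    # relational reactivation: main trials with preferred first -> after pic2
    rel <- trials$condition == "main" & trials$pic1_id == pref
    add(trials$t_pic2[rel] + lat + delay, tuning$reactivation_gain)
    # question-comparison trials naming the preferred concept -> after both
    # pictures, plus a response during the question itself
    qn <- trials$condition == "question_comparison" &
      !is.na(trials$named_concept) & trials$named_concept == pref
    add(trials$t_pic1[qn] + lat + delay, tuning$reactivation_gain)
    add(trials$t_pic2[qn] + lat + delay, tuning$reactivation_gain)
    add(trials$t_question[qn] + lat, tuning$question_name_gain)
    # anticipation ramp before pic2 in main trials without preferred first
    ant <- trials$condition == "main" & trials$pic1_id != pref
    add(trials$t_pic2[ant] - 0.5, tuning$anticipation_gain,
        duration = 0.5, shape = "ramp")
    # prompt reinstatement when the prompt refers back to the preferred pic
    back <- trials$condition == "question_comparison" &
      ((trials$prompt_variant == "first_picture" & trials$pic1_id == pref) |
         (trials$prompt_variant == "second_picture" & trials$pic2_id == pref))
    add(trials$t_prompt[back] + lat + delay, tuning$prompt_reinstatement_gain)
  }
  add(trials$t_prompt + ms_to_s(NONSPECIFIC_PROMPT_ONSET_MS),
      tuning$nonspecific_prompt_gain)
  if (length(out) == 0) {
    return(tibble::tibble(start = numeric(0), dur = numeric(0),
                          gain = numeric(0), shape = character(0)))
  }
  dplyr::bind_rows(out)
}

#' Simulate one unit's spike train
#'
#' Draws an inhomogeneous-Poisson spike train whose intensity is the unit's
#' baseline rate plus event-locked bumps determined by its tuning (see
#' [tuning_grid()] for the components). Sampling is by superposition of
#' independent Poisson processes, which is exact for the piecewise intensity
#' used here, and reproducible under `seed`.
#'
#' @param trials trial table with assigned onsets (see the schedule
#'   generators).
#' @param tuning one-row tibble (or list) of tuning parameters.
#' @param seed integer seed; `NULL` uses the current RNG state.
#' @param duration_s session duration; defaults to 5 s past the last prompt.
#' @return sorted numeric vector of spike times in seconds.
#' @export
simulate_unit <- function(trials, tuning, seed = NULL, duration_s = NULL) {
  with_seed(seed, simulate_unit_impl(trials, tuning, duration_s))
}

simulate_unit_impl <- function(trials, tuning, duration_s) {
  if (is.null(duration_s)) {
    duration_s <- if (nrow(trials) > 0) max(trials$t_prompt) + 5 else 10
  }
  lambda0 <- tuning$baseline_rate
  spikes <- if (lambda0 > 0) {
    stats::runif(stats::rpois(1, lambda0 * duration_s), 0, duration_s)
  } else numeric(0)
  bumps <- tuning_bumps(trials, tuning)
  if (nrow(bumps) > 0) {
    rect <- bumps[bumps$shape == "rect", ]
    if (nrow(rect) > 0) {
      k <- stats::rpois(nrow(rect), rect$gain * rect$dur)
      idx <- rep.int(seq_len(nrow(rect)), k)
      spikes <- c(spikes, rect$start[idx] + stats::runif(sum(k)) * rect$dur[idx])
    }
    ramp <- bumps[bumps$shape == "ramp", ]
    if (nrow(ramp) > 0) {
      # linear 0 -> gain ramp: expected count gain*dur/2, density prop. to
      # elapsed time; inverse-CDF placement start + dur*sqrt(U)
      k <- stats::rpois(nrow(ramp), ramp$gain * ramp$dur / 2)
      idx <- rep.int(seq_len(nrow(ramp)), k)
      spikes <- c(spikes,
                  ramp$start[idx] + ramp$dur[idx] * sqrt(stats::runif(sum(k))))
    }
  }
  spikes <- spikes[spikes >= 0 & spikes <= duration_s]
  sort(spikes)
}

#' Simulate a full session
#'
#' Composes the three trial schedules in task order (main, then the
#' no-comparison and question-comparison controls), simulates every
#' configured unit, and returns a validated session carrying the ground-truth
#' tuning in its units table. Fully deterministic under `config$seed`.
#'
#' @param config a [sim_config()].
#' @return an `rs_session`.
#' @export
simulate_session <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  set.seed(config$seed)
  main <- generate_main_schedule(config, t0 = 5)
  t1 <- if (nrow(main) > 0) max(main$t_prompt) + ms_to_s(config$prompt_duration_ms) + 5 else 5
  noc <- generate_no_comparison_schedule(config, t0 = t1)
  t2 <- if (nrow(noc) > 0) max(noc$t_prompt) + ms_to_s(config$prompt_duration_ms) + 5 else t1
  qc <- generate_question_comparison_schedule(config, t0 = t2)
  trials <- dplyr::bind_rows(main, noc, qc)
  trials <- dplyr::mutate(trials, trial_index = dplyr::row_number())
  trials <- dplyr::select(
    trials, "trial_index", "condition", "question_id", "named_concept",
    "pic1_id", "pic2_id", "t_question", "t_pic1", "t_pic2", "t_prompt",
    "fixcross1", "fixcross2", "prompt_variant", "response_key")
  duration_s <- if (nrow(trials) > 0) {
    max(trials$t_prompt) + ms_to_s(config$prompt_duration_ms) + 5
  } else 10
  units <- config$units
  n_units <- nrow(units)
  unit_seeds <- if (n_units > 0) {
    sample.int(.Machine$integer.max - 1L, n_units)
  } else integer(0)
  spikes <- purrr::map_dfr(seq_len(n_units), function(i) {
    st <- simulate_unit(trials, units[i, ], seed = unit_seeds[i],
                        duration_s = duration_s)
    tibble::tibble(unit_id = units$unit_id[i], spike_time_s = st)
  })
  if (n_units == 0) {
    spikes <- tibble::tibble(unit_id = character(0), spike_time_s = numeric(0))
  }
  new_session(trials, units, spikes, picture_set = config$pictures,
              session_id = sprintf("sim-seed%d", config$seed),
              duration_s = duration_s)
}
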