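# A recording session is a light S3 container: three tibbles (trials, units,
# spikes) plus a manifest. All downstream stages take the session first and
# return tibbles, so analyses chain with the pipe.

TRIAL_CONDITIONS <- c("main", "no_comparison", "question_comparison")
PROMPT_VARIANTS <- c("first_picture", "second_picture", "count_prompt", "position_prompt")
UNIT_REGIONS <- c("A", "H", "EC", "PHC")

# ground-truth tuning columns carried for synthetic units (units.csv)
TUNING_FIELDS <- c(
  "baseline_rate", "preferred_pic", "response_gain", "response_latency",
  "response_duration", "reactivation_gain", "reactivation_onset_delay",
  "question_name_gain", "anticipation_gain", "prompt_reinstatement_gain",
  "nonspecific_prompt_gain"
)

#' Construct a session object
#'
#' Bundles the trial event table, unit metadata and spike table of one
#' recording session and validates the invariants of the task design
#' (distinct pictures within a trial, strictly increasing event times,
#' sorted in-session spike times, picture ids drawn from the session's
#' four-picture set).
#'
#' @param trials tibble with one row per trial: `trial_index`, `condition`
#'   (`"main"`, `"no_comparison"`, `"question_comparison"`), `question_id`,
#'   `named_concept` (question-comparison only), `pic1_id`, `pic2_id`,
#'   `t_question`, `t_pic1`, `t_pic2`, `t_prompt` (seconds), `fixcross1`,
#'   `fixcross2` (`"white"`/`"red"`, no-comparison only), `prompt_variant`,
#'   `response_key`.
#' @param units tibble with one row per unit: `unit_id`, `region`
#'   (`"A"`, `"H"`, `"EC"`, `"PHC"`), `hemisphere` (`"L"`/`"R"`),
#'   `bundle_id`, `kind` (`"single"`/`"multi"`), plus optional ground-truth
#'   tuning columns for synthetic units.
#' @param spikes tibble with columns `unit_id`, `spike_time_s`.
#' @param picture_set character vector of the four picture ids.
#' @param session_id identifier string.
#' @param duration_s session duration in seconds; defaults to just past the
#'   last event or spike.
#' @return object of class `rs_session`.
#' @export
new_session <- function(trials, units, spikes, picture_set,
                        session_id = "synthetic", duration_s = NULL) {
  trials <- tibble::as_tibble(trials)
  units <- tibble::as_tibble(units)
  spikes <- tibble::as_tibble(spikes)
  if (is.null(duration_s)) {
    duration_s <- max(c(trials$t_prompt + 5, spikes$spike_time_s, 0), na.rm = TRUE)
  }
  x <- structure(
    list(session_id = session_id, picture_set = picture_set,
         trials = trials, units = units, spikes = spikes,
         duration_s = duration_s,
         spike_index = split(spikes$spike_time_s, spikes$unit_id)),
    class = "rs_session"
  )
  validate_session(x)
  x
}

#' Validate a session object
#'
#' Checks every structural invariant of the task design and errors with the
#' offending row/field on the first violation.
#'
#' @param session an `rs_session`.
#' @return the session, invisibly.
#' @export
validate_session <- function(session) {
  tr <- session$trials
  need <- c("trial_index", "condition", "question_id", "named_concept",
            "pic1_id", "pic2_id", "t_question", "t_pic1", "t_pic2", "t_prompt",
            "fixcross1", "fixcross2", "prompt_variant", "response_key")
  miss <- setdiff(need, names(tr))
  if (length(miss) > 0) {
    stop("trials table is missing column(s): ", paste(miss, collapse = ", "))
  }
  bad <- which(!tr$condition %in% TRIAL_CONDITIONS)
  if (length(bad) > 0) {
    stop("trial ", tr$trial_index[bad[1]], ": unknown condition '",
         tr$condition[bad[1]], "'")
  }
  bad <- which(!tr$pic1_id %in% session$picture_set |
                 !tr$pic2_id %in% session$picture_set)
  if (length(bad) > 0) {
    stop("trial ", tr$trial_index[bad[1]],
         ": picture id outside the session picture set")
  }
  bad <- which(tr$pic1_id == tr$pic2_id)
  if (length(bad) > 0) {
    stop("trial ", tr$trial_index[bad[1]], ": pic1_id equals pic2_id ('",
         tr$pic1_id[bad[1]], "')")
  }
  named <- which(!is.na(tr$named_concept))
  bad <- named[tr$named_concept[named] == tr$pic1_id[named] |
                 tr$named_concept[named] == tr$pic2_id[named]]
  if (length(bad) > 0) {
    stop("trial ", tr$trial_index[bad[1]],
         ": named_concept also appears as a presented picture")
  }
  ev <- cbind(tr$t_question, tr$t_pic1, tr$t_pic2, tr$t_prompt)
  bad <- which(apply(ev, 1, function(v) any(diff(v) <= 0)))
  if (length(bad) > 0) {
    stop("trial ", tr$trial_index[bad[1]],
         ": event times not strictly increasing")
  }
  un <- session$units
  for (col in c("unit_id", "region", "hemisphere", "bundle_id", "kind")) {
    if (!col %in% names(un)) stop("units table is missing column: ", col)
  }
  if (anyDuplicated(un$unit_id)) stop("duplicate unit_id in units table")
  if (nrow(un) > 0 && any(!un$region %in% UNIT_REGIONS)) {
    stop("units table: region must be one of ", paste(UNIT_REGIONS, collapse = ", "))
  }
  sp <- session$spikes
  if (!all(c("unit_id", "spike_time_s") %in% names(sp))) {
    stop("spikes table needs columns unit_id, spike_time_s")
  }
  if (nrow(sp) > 0) {
    if (any(!sp$unit_id %in% un$unit_id)) {
      stop("spikes table references unknown unit_id")
    }
    if (any(sp$spike_time_s < 0) || any(sp$spike_time_s > session$duration_s)) {
      stop("spike times outside [0, duration_s]")
    }
    srt <- dplyr::group_by(sp, .data$unit_id)
    srt <- dplyr::summarise(srt, ok = !is.unsorted(.data$spike_time_s))
    if (any(!srt$ok)) {
      stop("spike times not sorted for unit ", srt$unit_id[!srt$ok][1])
    }
  }
  invisible(session)
}

#' @export
print.rs_session <- function(x, ...) {
  cat("<rs_session> ", x$session_id, "\n", sep = "")
  cat("  pictures: ", paste(x$picture_set, collapse = ", "), "\n", sep = "")
  cond <- table(x$trials$condition)
  cat("  trials:   ", nrow(x$trials), " (",
      paste(names(cond), cond, sep = "=", collapse = ", "), ")\n", sep = "")
  cat("  units:    ", nrow(x$units), ", spikes: ", nrow(x$spikes), "\n", sep = "")
  invisible(x)
}

#' Spike times of one unit
#' @param session an `rs_session`.
#' @param unit_id unit identifier.
#' @return sorted numeric vector of spike times in seconds.
#' @export
unit_spikes <- function(session, unit_id) {
  s <- session$spike_index[[unit_id]]
  if (is.null(s)) numeric(0) else s
}

#' Write a session bundle to disk
#'
#' Writes `events.csv`, `units.csv`, `spikes.csv` and `manifest.json` into
#' `path`. The bundle is plain text, inspectable, and bit-stable for a fixed
#' field ordering; [read_session()] is its exact inverse.
#'
#' @param session an `rs_session`.
#' @param path directory to create/fill.
#' @return `path`, invisibly.
#' @export
write_session <- function(session, path) {
  dir.create(path, showWarnings = FALSE, recursive = TRUE)
  readr::write_csv(session$trials, file.path(path, "events.csv"), na = "")
  readr::write_csv(session$units, file.path(path, "units.csv"), na = "")
  readr::write_csv(session$spikes, file.path(path, "spikes.csv"), na = "")
  manifest <- list(
    format_version = 1L,
    session_id = session$session_id,
    picture_set = session$picture_set,
    duration_s = session$duration_s
  )
  jsonlite::write_json(manifest, file.path(path, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(path)
}

#' Read a session bundle from disk
#'
#' @param path directory containing `events.csv`, `units.csv`, `spikes.csv`
#'   and `manifest.json` as written by [write_session()].
#' @return a validated `rs_session`.
#' @export
read_session <- function(path) {
  man_path <- file.path(path, "manifest.json")
  if (!file.exists(man_path)) stop("no manifest.json under ", path)
  man <- jsonlite::read_json(man_path, simplifyVector = TRUE)
  trials <- readr::read_csv(
    file.path(path, "events.csv"), show_col_types = FALSE, progress = FALSE,
    col_types = readr::cols(
      trial_index = readr::col_integer(),
      condition = readr::col_character(),
      question_id = readr::col_character(),
      named_concept = readr::col_character(),
      pic1_id = readr::col_character(),
      pic2_id = readr::col_character(),
      t_question = readr::col_double(),
      t_pic1 = readr::col_double(),
      t_pic2 = readr::col_double(),
      t_prompt = readr::col_double(),
      fixcross1 = readr::col_character(),
      fixcross2 = readr::col_character(),
      prompt_variant = readr::col_character(),
      response_key = readr::col_integer()
    )
  )
  units_spec <- readr::cols(
    unit_id = readr::col_character(),
    region = readr::col_character(),
    hemisphere = readr::col_character(),
    bundle_id = readr::col_character(),
    kind = readr::col_character(),
    preferred_pic = readr::col_character(),
    .default = readr::col_double()
  )
  units <- readr::read_csv(file.path(path, "units.csv"),
                           show_col_types = FALSE, progress = FALSE,
                           col_types = units_spec)
  spikes <- readr::read_csv(
    file.path(path, "spikes.csv"), show_col_types = FALSE, progress = FALSE,
    col_types = readr::cols(unit_id = readr::col_character(),
                            spike_time_s = readr::col_double())
  )
  new_session(trials, units, spikes,
              picture_set = as.character(man$picture_set),
              session_id = man$session_id,
              duration_s = man$duration_s)
}
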