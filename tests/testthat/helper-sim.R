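# Fixtures are generated in code. small_config() shrinks the schedule for
# speed where the test's logic does not depend on the full trial counts.

small_config <- function(units = tuning_grid(0), seed = 101L, ...) {
  sim_config(reps_per_combo = 2, n_no_comparison = 24, units = units,
             seed = seed, ...)
}

strong_concept_units <- function(n, prefs = c("tie", "strawberry"),
                                 ids = sprintf("c%02d", seq_len(n))) {
  # gains ~3x the SD of per-trial baseline rates (sqrt(5 / 0.5) ~ 3.2 Hz)
  tuning_grid(n, preferred_pic = rep_len(prefs, n), response_gain = 12,
              question_name_gain = 10, reactivation_gain = 10,
              unit_id = ids)
}

# inject an extra Poisson spike burst into a train (used to plant effects
# the tuning grid does not parameterise, e.g. position-dependent gain)
inject_spikes <- function(spikes, starts, dur, rate) {
  k <- stats::rpois(length(starts), rate * dur)
  idx <- rep.int(seq_along(starts), k)
  sort(c(spikes, starts[idx] + stats::runif(sum(k)) * dur))
}

# session assembled from hand-built spike trains
manual_session <- function(trials, spike_list, picture_set,
                           region = "H", bundle_id = "b1") {
  units <- tuning_grid(length(spike_list), unit_id = names(spike_list),
                       region = region, bundle_id = bundle_id)
  spikes <- purrr::map_dfr(names(spike_list), function(id) {
    tibble::tibble(unit_id = id, spike_time_s = spike_list[[id]])
  })
  new_session(trials, units, spikes, picture_set = picture_set)
}
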