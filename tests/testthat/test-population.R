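make_classified <- function(units, seed) {
  s <- simulate_session(sim_config(units = units, seed = seed))
  list(session = s, classes = classify_units(s))
}

test_that("cross-condition correlations are computed for the four pairings", {
  x <- make_classified(strong_concept_units(8, ids = sprintf("c%d", 1:8)),
                       seed = 71)
  corr <- condition_response_correlation(x$session, x$classes)
  expect_equal(nrow(corr), 4)
  expect_true(all(abs(corr$r) <= 1))
  expect_true(all(corr$n == 8))
  vals <- attr(corr, "values")
  expect_equal(nrow(vals), 8)
  # planted question + reactivation tuning makes every window mean positive
  expect_true(all(vals$react_main_p2 > 0))
  expect_true(all(vals$resp_qcomp_q > 0))
  # fewer than three concept units is an error
  expect_error(condition_response_correlation(x$session, x$classes[1:2, ]),
               ">= 3")
})

test_that("relational reactivation is specific to semantic questions when planted so", {
  # build concept-like units whose reactivation is injected only in
  # relational main trials with a semantic question
  set.seed(72)
  cfg <- sim_config(units = tuning_grid(12, preferred_pic = "tie",
                                        response_gain = 12,
                                        question_name_gain = 10,
                                        unit_id = sprintf("u%02d", 1:12)),
                    seed = 72)
  s <- simulate_session(cfg)
  rel_sem <- s$trials$condition == "main" & s$trials$pic1_id == "tie" &
    s$trials$question_id != "Brighter?"
  starts <- s$trials$t_pic2[rel_sem] + 0.5
  spikes <- purrr::map_dfr(s$units$unit_id, function(u) {
    tibble::tibble(unit_id = u,
                   spike_time_s = inject_spikes(unit_spikes(s, u), starts,
                                                dur = 0.8, rate = 10))
  })
  s2 <- new_session(s$trials, s$units, spikes, s$picture_set,
                    duration_s = s$duration_s)
  cl <- classify_units(s2)
  grp <- relational_group_stats(s2, cl)$groups
  sem <- grp[grp$class_group == "concept" & grp$question_type == "semantic", ]
  per <- grp[grp$class_group == "concept" & grp$question_type == "perceptual", ]
  expect_lt(sem$p_vs_zero, 0.05)
  expect_gt(sem$median_z, per$median_z)
  expect_gt(per$p_vs_zero, 0.05)
})

test_that("positional effects are null when symmetric, positive when planted", {
  x <- make_classified(
    tuning_grid(20, preferred_pic = "tie", response_gain = 12,
                question_name_gain = 10, unit_id = sprintf("s%02d", 1:20)),
    seed = 73)
  pos <- positional_effect(x$session, x$classes)
  main_row <- pos$groups[pos$groups$condition == "main" &
                           pos$groups$region == "H", ]
  expect_gt(main_row$p_vs_zero, 0.05)
  expect_lt(abs(main_row$median_g), 0.3)

  # plant a 1.5x second-position gain by injecting spikes after pic2
  s <- x$session
  second <- s$trials$condition == "main" & s$trials$pic2_id == "tie"
  starts <- s$trials$t_pic2[second] + 0.1
  spikes <- purrr::map_dfr(s$units$unit_id, function(u) {
    tibble::tibble(unit_id = u,
                   spike_time_s = inject_spikes(unit_spikes(s, u), starts,
                                                dur = 0.3, rate = 6))
  })
  s2 <- new_session(s$trials, s$units, spikes, s$picture_set,
                    duration_s = s$duration_s)
  cl2 <- classify_units(s2)
  pos2 <- positional_effect(s2, cl2)
  main2 <- pos2$groups[pos2$groups$condition == "main" &
                         pos2$groups$region == "H", ]
  expect_gt(main2$median_g, 0)
  expect_lt(main2$p_vs_zero, 0.05)
})

test_that("prompt reinstatement shows up only for preferred-referring prompts", {
  units <- tuning_grid(10, preferred_pic = "tie", response_gain = 12,
                       question_name_gain = 10,
                       prompt_reinstatement_gain = 12,
                       unit_id = sprintf("p%02d", 1:10))
  x <- make_classified(units, seed = 74)
  pr <- prompt_reactivation(x$session, x$classes, n_perm = 300, seed = 3)
  cl <- pr$concept$cluster
  expect_false(is.null(cl))
  sig <- cl$clusters[cl$clusters$p_value < 0.05 & cl$clusters$sign > 0, ]
  expect_gte(nrow(sig), 1)
  # the cluster begins after the planted onset (latency 100 + delay 400)
  expect_gt(max(sig$end_ms), 500)
  # without planted prompt gain there is no first-vs-second difference
  y <- make_classified(
    tuning_grid(10, preferred_pic = "tie", response_gain = 12,
                question_name_gain = 10, unit_id = sprintf("q%02d", 1:10)),
    seed = 75)
  pr0 <- prompt_reactivation(y$session, y$classes, n_perm = 300, seed = 3)
  cl0 <- pr0$concept$cluster
  expect_equal(sum(cl0$clusters$p_value < 0.01), 0)
})
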