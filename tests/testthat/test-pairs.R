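test_that("pair trial categories partition the main trials", {
  cfg <- sim_config(units = tuning_grid(0), seed = 81)
  sched <- generate_main_schedule(cfg)
  cat_k <- pair_trial_category(sched, "tie", "chair")
  expect_true(all(cat_k %in% c("both_preferred", "only_second_preferred",
                               "only_first_preferred", "neither")))
  expect_equal(length(cat_k), nrow(sched))
  # exhaustive tally: 25 both (ordered pair), 50 second-only, 50 first-only
  expect_equal(sum(cat_k == "both_preferred"), 25)
  expect_equal(sum(cat_k == "only_second_preferred"), 50)
  expect_equal(sum(cat_k == "only_first_preferred"), 50)
  expect_equal(sum(cat_k == "neither"), 175)
})

test_that("pair enumeration respects preference, hemisphere and bundles", {
  cl <- tibble::tibble(
    unit_id = c("a", "b", "c", "d", "e"),
    label = c(rep("concept_reactivated", 4), "visual"),
    preferred_pic = c("tie", "chair", "tie", "pretzel", "chair"),
    hemisphere = c("R", "R", "R", "L", "R"),
    bundle_id = c("b1", "b1", "b2", "b1", "b1"),
    region = "H"
  )
  prs <- concept_pairs(cl)
  # visual unit excluded; d is in the other hemisphere; a-c share a picture
  expect_true(!"e" %in% c(prs$n1, prs$n2))
  expect_true(!"d" %in% c(prs$n1, prs$n2))
  expect_false(any(prs$pref_n1 == prs$pref_n2))
  within <- prs[prs$locality == "within_bundle", ]
  expect_setequal(paste(within$n1, within$n2), c("a b", "b a"))
  across <- prs[prs$locality == "across_bundle", ]
  expect_setequal(paste(across$n1, across$n2), c("b c", "c b"))
})

test_that("independent pairs show null rho; shared gain drives it positive", {
  units <- tuning_grid(6, preferred_pic = rep(c("tie", "chair"), 3),
                       response_gain = 12, question_name_gain = 10,
                       reactivation_gain = 10,
                       bundle_id = rep(c("b1", "b2", "b3"), each = 2),
                       unit_id = sprintf("i%02d", 1:6))
  s <- simulate_session(sim_config(units = units, seed = 82))
  cl <- classify_units(s)
  prr <- pair_response_reactivation(s, cl)
  g <- prr$groups
  expect_true(all(g$p_vs_zero[g$category == "neither"] > 0.05, na.rm = TRUE))

  # plant a shared per-trial gain: when a unit's bundle partner's preferred
  # picture appears second, the partner's response and the unit's late
  # (reactivation-window) activity share a common trial-wise modulation.
  # The late injection starts 1000 ms after pic2, outside the detection
  # window, so class labels are unaffected.
  set.seed(82)
  mn <- s$trials[s$trials$condition == "main", ]
  shared <- stats::runif(nrow(mn)) # common trial-to-trial modulation
  partner_of <- c(tie = "chair", chair = "tie")
  spikes <- purrr::map_dfr(seq_len(nrow(s$units)), function(i) {
    u <- s$units$unit_id[i]
    pref <- s$units$preferred_pic[i]
    st <- unit_spikes(s, u)
    resp_tr <- which(mn$pic2_id == pref) # n2 role: response window
    for (t in resp_tr) {
      st <- inject_spikes(st, mn$t_pic2[t], dur = 1.0, rate = 20 * shared[t])
    }
    react_tr <- which(mn$pic2_id == partner_of[[pref]]) # n1 role, late window
    for (t in react_tr) {
      st <- inject_spikes(st, mn$t_pic2[t] + 1.0, dur = 0.3,
                          rate = 30 * shared[t])
    }
    tibble::tibble(unit_id = u, spike_time_s = st)
  })
  s2 <- new_session(s$trials, s$units, spikes, s$picture_set,
                    duration_s = s$duration_s)
  cl2 <- classify_units(s2)
  prr2 <- pair_response_reactivation(s2, cl2)
  g2 <- prr2$groups
  bp <- g2[g2$category == "both_preferred" & g2$locality == "within_bundle", ]
  so <- g2[g2$category == "only_second_preferred" &
             g2$locality == "within_bundle", ]
  expect_gt(bp$median_rho, 0.2)
  expect_lt(bp$p_vs_zero, 0.05)
  expect_gt(so$median_rho, 0.2)
  ne <- g2[g2$category == "neither" & g2$locality == "within_bundle", ]
  expect_lt(abs(ne$median_rho), 0.2)
})

test_that("session-level pair CCG selects qualifying trials", {
  units <- tuning_grid(2, preferred_pic = c("tie", "chair"),
                       response_gain = 15, question_name_gain = 10,
                       unit_id = c("n1", "n2"))
  s <- simulate_session(sim_config(units = units, seed = 83))
  cl <- classify_units(s)
  x <- pair_ccg(s, cl, "n1", "n2", condition = "main", align = "pic2")
  expect_s3_class(x, "rs_ccg")
  expect_equal(attr(x, "n_trials"), 50) # both orders of the tie/chair pair
  x1 <- pair_ccg(s, cl, "n1", "n2", condition = "main", order = "a_first")
  expect_equal(attr(x1, "n_trials"), 25)
  expect_error(pair_ccg(s, cl, "n1", "n1"), "preferred")
})
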