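# Schedule balance is checked by exhaustive tallying over the generated
# trial tables, independent of the generators' internals.

test_that("main schedule reproduces the task's design counts", {
  cfg <- sim_config(units = tuning_grid(0), seed = 2)
  sched <- generate_main_schedule(cfg)
  expect_equal(nrow(sched), 300)
  expect_equal(unname(table(sched$question_id)), rep(60L, 5),
               ignore_attr = TRUE)
  pair_counts <- dplyr::count(sched, pic1_id, pic2_id)
  expect_equal(nrow(pair_counts), 12)
  expect_true(all(pair_counts$n == 25))
  combo_counts <- dplyr::count(sched, question_id, pic1_id, pic2_id)
  expect_equal(nrow(combo_counts), 60)
  expect_true(all(combo_counts$n == 5))
})

test_that("main schedule balance holds for any repetition count", {
  for (reps in c(0, 1, 3)) {
    cfg <- sim_config(reps_per_combo = reps, units = tuning_grid(0), seed = 3)
    sched <- generate_main_schedule(cfg)
    expect_equal(nrow(sched), 60 * reps)
    if (reps > 0) {
      tally <- dplyr::count(sched, question_id, pic1_id, pic2_id)
      expect_equal(nrow(tally), 60)
      expect_true(all(tally$n == reps))
      expect_true(all(sched$pic1_id != sched$pic2_id))
    }
  }
})

test_that("no-comparison schedule balances crosses and answer keys", {
  cfg <- sim_config(units = tuning_grid(0), seed = 4)
  sched <- generate_no_comparison_schedule(cfg)
  expect_equal(nrow(sched), 60)
  n_red <- (sched$fixcross1 == "red") + (sched$fixcross2 == "red")
  expect_equal(unname(table(n_red)), rep(20L, 3), ignore_attr = TRUE)
  keys <- table(sched$response_key)
  expect_lte(abs(keys[["1"]] - keys[["2"]]), 1)
  expect_true(all(sched$prompt_variant == "count_prompt"))
  cfg0 <- sim_config(n_no_comparison = 0, units = tuning_grid(0))
  expect_equal(nrow(generate_no_comparison_schedule(cfg0)), 0)
})

test_that("question-comparison schedule enumerates the 36 combinations twice", {
  cfg <- sim_config(units = tuning_grid(0), seed = 5)
  sched <- generate_question_comparison_schedule(cfg)
  expect_equal(nrow(sched), 72)
  # distinct combinations: element x named concept x unordered pair of the
  # remaining three pictures, tallied exhaustively
  combo <- dplyr::mutate(sched,
                         pair = purrr::map2_chr(pic1_id, pic2_id,
                                                ~ paste(sort(c(.x, .y)),
                                                        collapse = "|")))
  tally <- dplyr::count(combo, question_id, pair)
  expect_equal(nrow(tally), 3 * 4 * choose(3, 2))
  expect_true(all(tally$n == 2))
  # each combination is shown in both picture orders
  orders <- dplyr::count(sched, question_id, pic1_id, pic2_id)
  expect_true(all(orders$n == 1))
  # the named concept never appears on screen
  expect_true(all(sched$named_concept != sched$pic1_id))
  expect_true(all(sched$named_concept != sched$pic2_id))
  # prompt variants balanced
  expect_equal(unname(table(sched$prompt_variant)), c(36L, 36L),
               ignore_attr = TRUE)
  cfg0 <- sim_config(presentations_per_qcomp_combo = 0,
                     units = tuning_grid(0))
  expect_equal(nrow(generate_question_comparison_schedule(cfg0)), 0)
})

test_that("event onsets increase within trials and carry picture jitter", {
  cfg <- sim_config(units = tuning_grid(0), seed = 6)
  s <- simulate_session(cfg)
  tr <- s$trials
  expect_equal(nrow(tr), 300 + 60 + 72)
  expect_true(all(tr$t_question < tr$t_pic1))
  expect_true(all(tr$t_pic1 < tr$t_pic2))
  expect_true(all(tr$t_pic2 < tr$t_prompt))
  gap1 <- tr$t_pic1 - tr$t_question
  # jitter spreads the question->pic1 interval over the configured range
  expect_gt(diff(range(gap1)), 0.05)
  expect_true(all(gap1 >= 2.0 - 1e-9 & gap1 <= 2.2 + 1e-9))
})
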