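test_that("a zero-gain unit is homogeneous Poisson at its baseline rate", {
  cfg <- small_config()
  trials <- generate_main_schedule(cfg)
  lambda <- 6
  dur <- max(trials$t_prompt) + 5
  st <- simulate_unit(trials, tuning_grid(1, baseline_rate = lambda),
                      seed = 11, duration_s = dur)
  rate <- length(st) / dur
  se <- sqrt(lambda / dur)
  expect_lt(abs(rate - lambda), 3 * se)
})

test_that("a response bump appears only at preferred-picture onsets", {
  cfg <- small_config()
  trials <- generate_main_schedule(cfg)
  tun <- tuning_grid(1, preferred_pic = "tie", response_gain = 40,
                     response_latency = 100, response_duration = 300)
  st <- simulate_unit(trials, tun[1, ], seed = 12)
  # brute-force PSTH: 100-ms bins from -500 to 1500 ms around onsets
  psth <- function(events) {
    rel <- relative_spike_times(st, events, c(-500, 1500))
    counts <- table(cut(rel$t_ms, breaks = seq(-500, 1500, by = 100)))
    as.numeric(counts) / length(events)
  }
  pref_events <- c(trials$t_pic1[trials$pic1_id == "tie"],
                   trials$t_pic2[trials$pic2_id == "tie"])
  other_events <- c(trials$t_pic1[trials$pic1_id == "chair"],
                    trials$t_pic2[trials$pic2_id == "chair"])
  p_pref <- psth(pref_events)
  # peak bin of the preferred PSTH sits inside the planted bump (100-400 ms)
  peak_bin <- which.max(p_pref)
  expect_true(peak_bin %in% 7:9)
  # non-preferred onsets show no comparable modulation
  p_other <- psth(other_events)
  expect_lt(max(p_other) / max(p_pref), 0.5)
})

test_that("relational reactivation lags the direct response by the planted delay", {
  cfg <- small_config()
  trials <- generate_main_schedule(cfg)
  tun <- tuning_grid(1, preferred_pic = "tie", response_gain = 50,
                     reactivation_gain = 50, response_latency = 100,
                     reactivation_onset_delay = 400, response_duration = 200)
  st <- simulate_unit(trials, tun[1, ], seed = 13)
  rel <- trials$pic1_id == "tie"
  # 20-ms binned rate after pic2 in relational trials
  counts <- sapply(seq(0, 980, 20), function(a) {
    sum(count_spikes(st, trials$t_pic2[rel] + a / 1000,
                     trials$t_pic2[rel] + (a + 20) / 1000))
  })
  onset_bin <- which(counts > max(counts) / 2)[1]
  onset_ms <- (onset_bin - 1) * 20
  expect_lt(abs(onset_ms - 500), 60) # latency 100 + delay 400
})

test_that("simulation is reproducible and sessions are deterministic", {
  tun <- tuning_grid(1, preferred_pic = "tie", response_gain = 10)
  cfg <- small_config(units = tun)
  trials <- generate_main_schedule(cfg)
  expect_identical(simulate_unit(trials, tun[1, ], seed = 99),
                   simulate_unit(trials, tun[1, ], seed = 99))
  s1 <- simulate_session(cfg)
  s2 <- simulate_session(cfg)
  expect_identical(s1$spikes, s2$spikes)
  expect_identical(s1$trials, s2$trials)
  # written bundles are byte-identical under a fixed seed
  d1 <- withr::local_tempdir(); d2 <- withr::local_tempdir()
  write_session(s1, d1); write_session(s2, d2)
  for (f in c("events.csv", "spikes.csv", "units.csv")) {
    expect_identical(readLines(file.path(d1, f)), readLines(file.path(d2, f)))
  }
})

test_that("measured reactivation-window z never decreases with planted gain", {
  gains <- c(0, 5, 12)
  mean_z <- sapply(seq_along(gains), function(k) {
    cfg <- small_config(
      units = tuning_grid(50, preferred_pic = "tie",
                          response_gain = 12,
                          reactivation_gain = gains[k]),
      seed = 200 + k)
    s <- simulate_session(cfg)
    rel <- s$trials[s$trials$condition == "main" &
                      s$trials$pic1_id == "tie", ]
    zs <- sapply(s$units$unit_id, function(u) {
      z <- unit_z_series(s, u, rel, align = "pic2")
      mean(z$z[z$time_ms >= 500 & z$time_ms < 1300])
    })
    mean(zs)
  })
  expect_true(all(diff(mean_z) > 0))
  expect_lt(abs(mean_z[1]), 0.3) # no planted gain, no reactivation signal
})
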