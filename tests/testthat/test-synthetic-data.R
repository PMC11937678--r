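# Generators: determinism, analytic structure of the built-in signals, and
# the configuration errors the downstream stages rely on.

test_that("EEG generation is bit-identical under a fixed seed", {
  a <- small_eeg(seed = 7)
  b <- small_eeg(seed = 7)
  expect_identical(a$signal, b$signal)
  expect_identical(a$events, b$events)
  c <- small_eeg(seed = 8)
  expect_false(identical(a$signal, c$signal))
})

test_that("task/rest alpha band power follows erd_depth on noiseless signals", {
  fs <- 1000
  rec <- noiseless_eeg(erd_depth = 0.3)
  lap <- large_laplacian(rec)
  # windows fully inside rest [0,5] and inside the post-ramp task [6.2,12)
  rest_pw <- stft_power(lap[1:(3 * fs)], fs)
  task_pw <- stft_power(lap[1:(8 * fs)], fs)
  ratio <- task_pw$power[10] / rest_pw$power[10]
  expect_equal(ratio, 0.7, tolerance = 1e-3)

  flat <- noiseless_eeg(erd_depth = 0)
  lapf <- large_laplacian(flat)
  r0 <- stft_power(lapf[1:(3 * fs)], fs)$power[10] /
    stft_power(lapf[1:(8 * fs)], fs)$power[10]
  expect_equal(r0, 1, tolerance = 1e-3)
})

test_that("alpha band power scales with amplitude squared (noiseless)", {
  r1 <- noiseless_eeg(erd_depth = 0, alpha_amplitude = 2)
  r2 <- noiseless_eeg(erd_depth = 0, alpha_amplitude = 4)
  p1 <- stft_power(large_laplacian(r1)[1:3000], 1000)$power[10]
  p2 <- stft_power(large_laplacian(r2)[1:3000], 1000)$power[10]
  expect_equal(p2 / p1, 4, tolerance = 1e-9)
})

test_that("EEG config validation rejects bad depth, band and timing", {
  expect_error(eeg_sim_config(erd_depth = 1.2), "erd_depth")
  expect_error(eeg_sim_config(iaf_true = 14), "alpha band")
  expect_error(eeg_sim_config(trial_timing = c(rest = 5, task = 6)), "timing")
  expect_error(large_laplacian(small_eeg(), neighbors = c("F3", "Oz")), "Oz")
})

test_that("event table marks the four periods of every 17-s trial", {
  rec <- small_eeg(n_trials = 3)
  ev <- rec$events
  expect_equal(nrow(ev), 12)
  expect_equal(ev$label[1:4], c("rest", "ready", "task", "blank"))
  expect_equal(diff(ev$onset_sample[ev$label == "rest"]), rep(17000L, 2))
  expect_equal(ncol(rec$signal), 3 * 17 * 1000)
  # rest -> ready -> task order inside each trial
  expect_true(all(tapply(ev$onset_sample, ev$trial, function(o) all(diff(o) > 0))))
})

test_that("noiseless SEP average equals the component template exactly", {
  rec <- small_sep(n_stimuli = 50, noise_sd = 0)
  ep <- epoch_sep(rec)
  for (m in rec$montages) {
    E <- ep$epochs[[m]]
    expect_equal(max(abs(colMeans(E) - E[1, ])), 0)
  }
  # extremum of the N20 montage at exactly 20 ms
  avg <- colMeans(ep$epochs[["CPc-Fz"]])
  expect_equal(ep$time_ms[which.min(avg)], 20)
})

test_that("SEP recording length and onset spacing follow the config", {
  cfg <- sep_sim_config(n_stimuli = 40, seed = 1)
  rec <- generate_sep_session(cfg)
  expect_equal(unique(diff(rec$stim_onsets)), 5000L)
  # full-scale arithmetic: 1000 stimuli at 2 Hz, 10 kHz -> >= 500 s of samples
  full <- sep_sim_config(n_stimuli = 1000)
  isi <- full$sampling_rate / full$stim_rate
  expect_gte(2 * full$sampling_rate + full$n_stimuli * isi,
             500 * full$sampling_rate)
  expect_error(sep_sim_config(components = data.frame(
    name = "N9", montage = "EPi-EPc", latency_ms = 400, amplitude_uv = 3,
    width_ms = 3)), "latencies")
  expect_error(sep_sim_config(stim_rate = 100), "overlap")
})

test_that("doubling a SEP component amplitude increases its z amplitude", {
  comp <- sep_sim_config()$components
  comp2 <- comp
  comp2$amplitude_uv <- comp$amplitude_uv * 2
  z1 <- extract_all(small_sep(components = comp, seed = 5))
  z2 <- extract_all(small_sep(components = comp2, seed = 5))
  expect_true(all(z2$amplitude_z < z1$amplitude_z))  # more negative
})

test_that("behavior table is balanced, Bernoulli-consistent and deterministic", {
  cfg <- behavior_sim_config(seed = 31)
  tab <- generate_behavior(cfg)
  expect_equal(nrow(tab), 150)
  counts <- table(tab$block, tab$condition_s)
  expect_true(all(counts == 10))
  expect_true(all(tab$success %in% 0:1))
  expect_identical(tab, generate_behavior(cfg))

  # closed-form success probability at x = 6
  p6 <- 0.9 * exp(-0.8 * 6) + 0.05
  expect_equal(p6, 0.0574, tolerance = 1e-3)
  big <- generate_behavior(behavior_sim_config(n_blocks = 200, seed = 32))
  emp <- mean(big$success[big$condition_s == 6])
  expect_lt(abs(emp - p6), 0.015)

  # flat curve: equal expected rate across conditions
  flat <- generate_behavior(behavior_sim_config(b_true = 0, a_true = 0.4,
                                                n_blocks = 300, seed = 33))
  rates <- success_rates(flat)$rate
  expect_lt(diff(range(rates)), 0.05)

  expect_error(behavior_sim_config(a_true = 1.4, b_true = 0.05, c_true = 0.2),
               "\\[0, 1\\]")
})

test_that("group dataset is deterministic and encodes the effect deltas", {
  d1 <- generate_group_dataset(n_per_group = 2, seed = 9)
  d2 <- generate_group_dataset(n_per_group = 2, seed = 9)
  expect_identical(d1$subjects, d2$subjects)
  s1 <- materialize_session(d1, "S01", "eval1")
  s2 <- materialize_session(d2, "S01", "eval1")
  expect_identical(s1$eeg$signal, s2$eeg$signal)
  expect_identical(s1$sep$traces, s2$sep$traces)
  expect_identical(s1$behavior, s2$behavior)

  verum <- d1$subjects$subject[d1$subjects$group == "verum"][1]
  cfgs <- d1$configs[[verum]]
  expect_equal(cfgs$eval2$eeg$erd_depth - cfgs$eval1$eeg$erd_depth, 0.15)
  n20 <- function(cfg) cfg$components$amplitude_uv[cfg$components$name == "N20"]
  expect_equal(n20(cfgs$eval2$sep) - n20(cfgs$eval1$sep), 0.8)
  expect_equal(cfgs$eval2$behavior$b_true - cfgs$eval1$behavior$b_true, 0.35)
  expect_error(generate_group_dataset(n_per_group = 1), ">= 2")
})
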