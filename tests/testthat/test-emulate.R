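test_that("stimulation waveforms: pulse count, periodicity, merging, validation", {
  # burst of duration d at 200 Hz contains floor(d * 200) boundary-ruled pulses
  for (duty in c(0.2, 0.4, 0.55)) {
    wf <- generate_stim_waveform(2, burst_windows(duty, single = TRUE))
    d <- duty / 2                       # burst duration in seconds
    n_pulses <- sum(diff(c(0, wf$u1)) > 0)
    expect_equal(n_pulses, floor(d * 200), tolerance = 1)
    # envelope occupies exactly the burst window
    expect_equal(mean(wf$env1 > 0), duty, tolerance = 1e-3)
    expect_true(all(wf$u2 == 0) && all(wf$env2 == 0))
  }

  # empty windows: identically zero
  wf0 <- generate_stim_waveform(3, list(NULL, NULL))
  expect_true(all(wf0$u1 == 0) && all(wf0$env2 == 0))

  # waveform is exactly periodic: autocorrelation peaks at one-period lag
  wf <- generate_stim_waveform(4, burst_windows(0.3))
  f <- muscleloop:::stim_functions(wf, "pulses")
  tt <- seq(0, 1, by = wf$dt)
  u <- f[[1]](tt)
  lag <- round(0.25 / wf$dt)
  expect_lt(mean(u[seq_len(length(u) - lag)] != u[-seq_len(lag)]), 0.002)

  expect_warning(
    generate_stim_waveform(2, list(rbind(c(0, 2), c(1, 3)), NULL)),
    "merged")
  expect_error(generate_stim_waveform(2, burst_windows(0.4),
                                      pulse_rate = 200, pulse_width = 0.01),
               "non-overlapping")
  expect_error(generate_stim_waveform(2, list(matrix(c(-1, 1), ncol = 2), NULL)),
               "burst windows")
})

test_that("zero stimulation produces no motion and zero work", {
  cfg <- session_config(fix_load(), fix_muscle(), 2, reps = 2, seed = 5,
                        force_noise_sd = 0, pos_noise_sd = 0,
                        fatigue_rate = 0)
  wf <- generate_stim_waveform(2, list(NULL, NULL))
  ses <- emulate_workloop_session(cfg, wf)
  expect_lt(max(abs(ses$measurements$work_J)), 1e-12)
  rec <- ses$recordings[[1]]
  expect_lt(diff(range(rec$x_m)), 1e-12)
})

test_that("noise-free, fatigue-free emulation reproduces the direct simulation", {
  mu <- fix_muscle(); ld <- fix_load()
  cfg <- session_config(ld, mu, 2.4, reps = 2, seed = 5,
                        force_noise_sd = 0, pos_noise_sd = 0, fatigue_rate = 0)
  wf <- generate_stim_waveform(2.4, burst_windows(0.4, single = TRUE))
  ses <- emulate_workloop_session(cfg, wf)
  direct <- simulate_coupled_system(mu, ld, wf, horizon = 7 / 2.4,
                                    record_dt = max(wf$dt, 1 / (400 * 2.4)),
                                    freq = 2.4)
  expect_identical(ses$recordings[[1]]$x_m, direct$x_m)
  expect_identical(ses$recordings[[2]]$Fnet_N, direct$Fnet_N)
})

test_that("recorded channels carry the configured measurement noise", {
  mu <- fix_muscle(); ld <- fix_load()
  cfg <- session_config(ld, mu, 2.4, reps = 2, seed = 5,
                        force_noise_sd = 0.05, pos_noise_sd = 1e-5,
                        fatigue_rate = 0)
  wf <- generate_stim_waveform(2.4, burst_windows(0.4, single = TRUE))
  ses <- emulate_workloop_session(cfg, wf)
  rec <- ses$recordings[[1]]
  truth <- attr(rec, "truth")
  resF <- rec$F1_N - truth$F1_N
  expect_equal(sd(resF), 0.05, tolerance = 0.15)
  expect_equal(sd(rec$x_m - truth$x_m), 1e-5, tolerance = 0.15)
  expect_error(session_config(ld, mu, 2.4, force_noise_sd = -1), "non-negative")
})

test_that("fatigue makes per-repetition work non-increasing in expectation", {
  mu <- fix_muscle(); ld <- fix_load()
  wf <- generate_stim_waveform(2.4, burst_windows(0.4, single = TRUE))
  drops <- vapply(1:20, function(s) {
    cfg <- session_config(ld, mu, 2.4, reps = 4, seed = 1000 + s,
                          fatigue_rate = 0.05)
    m <- emulate_workloop_session(cfg, wf)$measurements
    mean(diff(m$work_J))
  }, numeric(1))
  expect_lt(mean(drops), 0)
  expect_gt(mean(drops < 0), 0.8)
})

test_that("condition randomisation is a uniform permutation under the seeded RNG", {
  # the protocols draw orders via sample(); verify uniformity over 3! cells
  draws <- with(new.env(), {
    set.seed(2024)
    replicate(6000, paste(sample(3), collapse = ""))
  })
  tab <- table(draws)
  expect_equal(length(tab), 6L)
  p <- chisq.test(tab)$p.value
  expect_gt(p, 0.01)
})

test_that("discard-first-cycle is a no-op on a pre-converged trajectory", {
  mu <- fix_muscle(); ld <- fix_load()
  wf <- generate_stim_waveform(2.4, burst_windows(0.4, single = TRUE))
  # start the recording from the periodic steady state: simulate long, keep tail
  long <- simulate_coupled_system(mu, ld, wf, horizon = 40 / 2.4,
                                  record_dt = 1 / (2.4 * 400))
  Tp <- 1 / 2.4
  tail7 <- long[long$time_s >= 33 * Tp - 1e-12, ]
  tail7$time_s <- tail7$time_s - tail7$time_s[1]
  cw_all <- cyclic_work(workloop(tail7, freq = 2.4), require_closed = FALSE)
  works <- cw_all$cycles$work_J[1:7]
  with_first <- mean(works)
  without_first <- mean(works[-1])
  expect_equal(with_first, without_first, tolerance = 5e-3)

  # whereas from rest the first cycle is atypical
  rest <- simulate_coupled_system(mu, ld, wf, horizon = 7 / 2.4,
                                  record_dt = 1 / (2.4 * 400), freq = 2.4)
  w_rest <- cyclic_work(workloop(rest), require_closed = FALSE)$cycles$work_J
  expect_gt(abs(w_rest[1] - mean(w_rest[-1])) / abs(mean(w_rest[-1])), 0.05)
})

test_that("ratio test: exact threshold, location invariance, detection power", {
  eq <- compare_ratio_test(rep(2, 5), 2)
  expect_equal(eq$t, 0)
  expect_equal(eq$p, 1)
  expect_true(eq$degenerate_variance)

  degen <- compare_ratio_test(rep(3, 5), 2)
  expect_equal(degen$p, 0)
  expect_equal(degen$stars, "**")

  set.seed(8)
  x <- rnorm(6, 2.5, 0.1)
  a <- compare_ratio_test(x, 2)
  b <- compare_ratio_test(x + 10, 12)
  expect_equal(a$t, b$t, tolerance = 1e-9)
  expect_equal(a$p, b$p, tolerance = 1e-9)

  # threshold + N(0.5, 0.1^2), n = 6: p < 0.01 almost always
  set.seed(9)
  hits <- mean(replicate(1000, compare_ratio_test(2 + rnorm(6, 0.5, 0.1), 2)$p < 0.01))
  expect_gte(hits, 0.95)
  expect_error(compare_ratio_test(1, 2), "length")
})

test_that("hypothesis 1 protocol: ordering randomised, P(f_opt) above both", {
  cfg <- session_config(fix_load(), fix_muscle(), c(2, 2.5, 3), reps = 6,
                        seed = 7)
  h1 <- run_hypothesis1_protocol(cfg, stim_source = "heuristic")
  m <- h1$measurements
  # each set holds one measurement per condition, in some permutation
  for (s in unique(m$set_id))
    expect_setequal(m$freq_Hz[m$set_id == s], c(2, 2.5, 3))
  expect_gt(length(unique(vapply(
    split(m, m$set_id), function(d) paste(d$freq_Hz[order(d$order)],
                                          collapse = ","),
    character(1)))), 1)

  s <- h1$table
  expect_equal(s$mean[s$freq_Hz == 2], 1)
  expect_equal(s$sd[s$freq_Hz == 2], 0)
  expect_gt(s$mean[s$freq_Hz == 2.5], 1)
  expect_gt(s$mean[s$freq_Hz == 2.5], s$mean[s$freq_Hz == 3])
  expect_lt(h1$tests$opt_vs_1$p, 0.05)

  # deterministic (noise- and fatigue-free) repetitions: zero dispersion
  cfg0 <- session_config(fix_load(), fix_muscle(), c(2, 2.5, 3), reps = 3,
                         seed = 7, force_noise_sd = 0, pos_noise_sd = 0,
                         fatigue_rate = 0)
  h0 <- run_hypothesis1_protocol(cfg0, stim_source = "heuristic")
  expect_equal(h0$table$sd[h0$table$freq_Hz == 2], 0)
  expect_lt(max(h0$table$sd), 1e-12)
})

test_that("hypothesis 1 protocol reproduces the ordering on the 4-6 Hz arm", {
  cfg <- session_config(fix_load(f_n = 4), fix_muscle(), c(4, 5, 6), reps = 4,
                        seed = 13)
  h1 <- run_hypothesis1_protocol(cfg, stim_source = "heuristic")
  s <- h1$table
  expect_gt(s$mean[s$freq_Hz == 5], 1)
  expect_gt(s$mean[s$freq_Hz == 5], s$mean[s$freq_Hz == 6])
})

test_that("hypothesis 2 protocol finds synergy above 2 past resonance", {
  mu <- fix_muscle()
  cfg <- session_config(fix_load(), list(mu, mu), 3, reps = 6, seed = 11)
  h2 <- run_hypothesis2_protocol(cfg, 3, stim_source = "heuristic")
  m <- h2$measurements
  expect_true(all(m$W1 + m$W2 > 0))
  expect_gt(h2$tests$S_vs_2$mean, 2)
  expect_lt(h2$tests$S_vs_2$p, 0.05)
  # the antagonist is a perturbed contralateral copy, not an exact clone
  expect_false(identical(h2$config$muscles[[1]]$D, h2$config$muscles[[2]]$D))

  # impedance-free surrogates (no stiffness modulation): S within noise of 2
  mf <- muscle_params(A = 0, B = 0, C = 2, D = 0, l0 = 0.03)
  cfgf <- session_config(fix_load(), list(mf, mf), 2, reps = 6, seed = 17,
                         fatigue_rate = 0)
  h2f <- run_hypothesis2_protocol(cfgf, 2, pair_cv = 0,
                                  stim_source = "heuristic")
  expect_equal(h2f$tests$S_vs_2$mean, 2, tolerance = 0.1)
})
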