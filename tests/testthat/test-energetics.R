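make_loop <- function(F0, x0, phi, freq = 2, n = 200, cycles = 1) {
  tt <- seq(0, cycles / freq, length.out = cycles * n + 1)
  w <- 2 * pi * freq
  tibble::tibble(time_s = tt, x_m = x0 * sin(w * tt - phi),
                 Fnet_N = F0 * sin(w * tt))
}

test_that("loop area: degenerate spring line is zero, ellipse is pi F0 x0 sin(phi)", {
  # F proportional to x encloses nothing
  d <- make_loop(2, 0.003, 0)
  d$Fnet_N <- 500 * d$x_m
  expect_equal(cyclic_work(workloop(d, freq = 2))$work_J, 0, tolerance = 1e-12)

  for (phi in c(0.3, 1.1, 2.5)) {
    d <- make_loop(2, 0.003, phi)
    cw <- cyclic_work(workloop(d, freq = 2))
    expect_equal(cw$work_J, pi * 2 * 0.003 * sin(phi), tolerance = 1e-3)
    expect_equal(cw$mean_power_W, cw$work_J * 2)
  }
})

test_that("loop area equals the time integral of F v on a periodic cycle", {
  # on the exactly periodic converged orbit the two discretisations of the
  # same integral agree to 0.1%
  sol <- single_solution_2p4()
  tr <- sol$trajectory
  area <- cyclic_work(workloop(tr, freq = sol$problem$freq))$work_J
  Wfv <- trapz_test(tr$time_s, tr$Fnet_N * tr$v_m_s)
  expect_equal(area, Wfv, tolerance = 1e-3)
})

test_that("open cycles are flagged and excluded when closure is required", {
  d <- make_loop(2, 0.003, 1, cycles = 2)
  second <- d$time_s > 0.5
  d$x_m[second] <- d$x_m[second] + 0.01 * (d$time_s[second] - 0.5)
  expect_warning(cw <- cyclic_work(workloop(d, freq = 2)), "open workloop")
  expect_equal(cw$cycles$closed, c(TRUE, FALSE))
  # the average uses only the closed first cycle
  expect_equal(cw$work_J, cw$cycles$work_J[1])
})

test_that("damper dissipation: closed form and equality with cyclic work", {
  ld <- fix_load()
  x0 <- 0.004; f <- 2.2; w <- 2 * pi * f
  tt <- seq(0, 1 / f, length.out = 801)
  tr <- tibble::tibble(time_s = tt, v_m_s = x0 * w * cos(w * tt))
  diss <- damper_dissipation(tr, ld, freq = f)
  expect_equal(diss$dissipation_J[1], pi * ld$b * w * x0^2, tolerance = 1e-4)

  expect_equal(nrow(damper_dissipation(tr, load_params(M = ld$M, b = 0, k = ld$k),
                                       freq = f)), 1)
  expect_equal(damper_dissipation(tr, load_params(M = ld$M, b = 0, k = ld$k),
                                  freq = f)$dissipation_J, 0)

  # on a converged steady-state orbit, work = dissipation (tested per cycle)
  sol <- single_solution_2p4()
  d2 <- damper_dissipation(sol$trajectory, sol$problem$load,
                           freq = sol$problem$freq)
  expect_equal(d2$dissipation_J[1], sol$work_J, tolerance = 5e-3)
})

test_that("synergy ratio: identities, bounds, and input validation", {
  expect_equal(synergy_ratio(1, 1, 4), 2)
  expect_equal(synergy_ratio(data.frame(W1 = 2, W2 = 2, W12 = 6)), 1.5)
  expect_error(synergy_ratio(1, -1, 2), "positive")
  expect_error(synergy_ratio(NA, 1, 2), "finite")

  ld <- fix_load()
  # identical impedance-free actuators: S = 2 at every frequency
  s <- impedance_free_synergy(ld, 5, 5, c(1, 2, 3, 4.5, 6))
  expect_true(all(abs(s$S - 2) < 1e-9))
  expect_lt(diff(range(s$S)), 1e-6)   # frequency independence
  # unequal bounds: 1 < S <= 2, approaching 1 as the ratio vanishes
  r <- c(0.01, 0.1, 0.5, 1)
  su <- impedance_free_synergy(ld, r * 4, rep(4, 4), 2.4)
  expect_true(all(su$S > 1 & su$S <= 2 + 1e-12))
  expect_true(all(diff(su$S) > 0))
  expect_lt(su$S[1], 1.05)
  expect_equal(su$S[4], 2)
})

test_that("matched stiffness nulls the combined reactance, uniquely", {
  ld <- fix_load()
  wn <- 2 * pi * ld$f_n
  expect_equal(matched_stiffness(ld, wn)$k_s_N_m, 0)

  m <- matched_stiffness(ld, 2 * pi * 2.4)
  expect_equal(m$k_s_N_m, (1.2^2 - 1) * ld$k, tolerance = 1e-12)
  expect_equal(m$combined_f_n_Hz, 2.4, tolerance = 1e-12)

  # below resonance the required stiffness is negative: clamped and flagged
  low <- matched_stiffness(ld, 2 * pi * 1.5)
  expect_true(low$clamped)
  expect_equal(low$k_s_N_m, 0)

  # uniqueness: bisection on the combined reactance finds the same k_s
  for (f in c(2.4, 3.1, 5)) {
    w <- 2 * pi * f
    react <- function(ks) (ld$M * w - (ld$k + ks) / w)
    ks_bi <- uniroot(react, c(0, 1e5), tol = 1e-12)$root
    expect_equal(matched_stiffness(ld, w)$k_s_N_m, ks_bi, tolerance = 1e-9)
  }
})

test_that("normalised power table pins P(f_n) at 1 and is scale invariant", {
  meas <- tidyr::expand_grid(set_id = 1:5, freq_Hz = c(2, 2.5, 3))
  profile <- c(1, 1.4, 0.6)          # per-frequency shape, identical per set
  set.seed(3)
  scales <- 10^runif(5, -1, 1)       # arbitrary per-set gain (fatigue etc.)
  meas$power_W <- as.vector(t(outer(scales, profile)))
  tab <- normalized_power_table(meas, f_n = 2)
  s <- tab$summary
  expect_equal(s$mean[s$freq_Hz == 2], 1)
  expect_equal(s$sd[s$freq_Hz == 2], 0)
  expect_equal(s$mean[s$freq_Hz == 2.5], 1.4, tolerance = 1e-12)
  expect_equal(s$sd[s$freq_Hz == 2.5], 0, tolerance = 1e-12)

  # scaling every power in one set by a positive constant changes nothing
  meas2 <- meas
  meas2$power_W[meas2$set_id == 3] <- meas2$power_W[meas2$set_id == 3] * 77
  tab2 <- normalized_power_table(meas2, f_n = 2)
  expect_equal(tab2$summary, tab$summary)

  # sets without a positive normaliser are excluded with a warning
  meas3 <- meas
  meas3$power_W[meas3$set_id == 2 & meas3$freq_Hz == 2] <- 0
  expect_warning(tab3 <- normalized_power_table(meas3, f_n = 2), "excluded")
  expect_equal(tab3$excluded_sets, 2)
  expect_equal(unique(tab3$summary$n), 4L)
})
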