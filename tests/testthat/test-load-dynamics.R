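test_that("load_params derives consistent natural frequency and damping ratio", {
  ld <- load_params(f_n = 2, zeta = 0.1, k = 1000)
  expect_equal(ld$f_n, 2)
  expect_equal(ld$zeta, 0.1)
  expect_equal(ld$M, 1000 / (4 * pi)^2)
  ld2 <- load_params(M = ld$M, b = ld$b, k = ld$k)
  expect_equal(ld2$f_n, 2)
  expect_error(load_params(k = -1))
})

test_that("load impedance: resistance b, reactance zero at resonance, monotone", {
  ld <- load_params(M = 1, b = 2, k = 100)
  # direct arithmetic: Z(5j) = 2 + j(5 - 20)
  expect_equal(load_impedance(ld, 5), complex(real = 2, imaginary = -15))
  wn <- sqrt(100 / 1)
  expect_equal(Im(load_impedance(ld, wn)), 0, tolerance = 1e-12)
  expect_equal(Mod(load_impedance(ld, wn)), 2)
  w <- seq(0.5, 50, length.out = 200)
  expect_true(all(Re(load_impedance(ld, w)) == 2))
  expect_true(all(diff(Im(load_impedance(ld, w))) > 0))
  expect_error(load_impedance(ld, 0), "pole")
})

test_that("Fourier steady state: closed forms and square-wave cross-check", {
  ld <- default_load()
  z <- steady_state_periodic_response(ld, complex(real = c(0, 0)), 5)
  expect_equal(z$mean_power_W, 0)

  # single sinusoid at resonance: |V| = F/b, P = F^2/(2b)
  wn <- 2 * pi * ld$f_n
  Fa <- 3
  r <- steady_state_periodic_response(ld, c(0, Fa), wn)
  expect_equal(Mod(r$harmonics$V[2]), Fa / ld$b, tolerance = 1e-12)
  expect_equal(r$mean_power_W, Fa^2 / (2 * ld$b), tolerance = 1e-12)

  # square wave: Fourier power agrees with direct time integration (deSolve,
  # an independent integrator) to steady state within 0.1%
  f0 <- 2.4; w0 <- 2 * pi * f0; Fm <- 2
  hmax <- 99
  co <- complex(length.out = hmax + 1)
  hodd <- seq(1, hmax, 2)
  co[hodd + 1] <- 4 * Fm / (pi * hodd)
  P_fourier <- steady_state_periodic_response(ld, co, w0)$mean_power_W
  sq <- function(t) Fm * sign(sin(w0 * t))
  rhs <- function(t, y, p) list(c(y[2], (sq(t) - ld$k * y[1] - ld$b * y[2]) / ld$M))
  tt <- seq(0, 42 / f0, by = 1 / (f0 * 800))
  out <- deSolve::lsoda(c(0, 0), tt, rhs, NULL, rtol = 1e-10, atol = 1e-12,
                        hmax = 1 / (f0 * 800))
  # steady-state power through the smooth damper identity P = b <v^2>
  last <- out[out[, 1] >= 40 / f0 - 1e-12, ]
  P_time <- ld$b * mean(last[-1, 3]^2)
  expect_equal(P_fourier, P_time, tolerance = 1e-3)

  expect_error(
    steady_state_periodic_response(load_params(M = 1, b = 0, k = 100),
                                   c(0, 1), sqrt(100)),
    "unbounded")
})

test_that("coupled simulation: equilibrium, passive ringing frequency, lsoda oracle", {
  mu <- fix_muscle(); ld <- fix_load()
  zero <- list(function(t) 0 * t, function(t) 0 * t)

  # passive equilibrium is a fixed point
  tr <- simulate_coupled_system(mu, ld, zero, horizon = 1)
  expect_lt(max(abs(tr$x_m - tr$x_m[1])), 1e-12)
  expect_lt(max(abs(tr$v_m_s)), 1e-12)

  # small passive release rings at sqrt((k + B1 + B2)/M)/2pi
  pair <- list(mu, mu)
  x_eq <- passive_equilibrium(pair, ld)
  tr2 <- simulate_coupled_system(pair, ld, zero,
                                 initial = c(x_eq + 1e-4, 0, 0, 0, 0, 0),
                                 horizon = 4, record_dt = 1e-3)
  xc <- tr2$x_m - x_eq
  zc <- which(diff(sign(xc)) != 0)
  f_obs <- (length(zc) - 1) / 2 / (tr2$time_s[zc[length(zc)]] - tr2$time_s[zc[1]])
  f_pred <- sqrt((ld$k + 2 * mu$B) / ld$M) / (2 * pi) *
    sqrt(1 - (ld$b / (2 * sqrt((ld$k + 2 * mu$B) * ld$M)))^2)
  expect_equal(f_obs, f_pred, tolerance = 0.005)

  # full coupled trajectory against deSolve::lsoda (independent integrator)
  wf <- generate_stim_waveform(2.4, burst_windows(0.4))
  tr3 <- simulate_coupled_system(pair, ld, wf, horizon = 1.2)
  stim <- muscleloop:::stim_functions(wf)
  rhs <- function(t, y, p) {
    u <- c(stim[[1]](t), stim[[2]](t))
    nf <- net_load_force(mu, mu, y[1], y[3], y[5], check_range = FALSE)
    list(c(y[2], (nf$Fnet_N - ld$k * y[1] - ld$b * y[2]) / ld$M,
           (y[4] - y[3]) / mu$tau_a, (u[1] - y[4]) / mu$tau_c,
           (y[6] - y[5]) / mu$tau_a, (u[2] - y[6]) / mu$tau_c))
  }
  y0 <- c(passive_equilibrium(pair, ld), 0, 0, 0, 0, 0)
  ref <- deSolve::lsoda(y0, tr3$time_s, rhs, NULL, rtol = 1e-9, atol = 1e-11,
                        hmax = wf$dt)
  expect_lt(max(abs(ref[, 2] - tr3$x_m)), 2e-6 * diff(range(tr3$x_m)))
  expect_lt(max(abs(ref[, 4] - tr3$a1)), 1e-5)

  # blow-up guard
  expect_error(
    simulate_coupled_system(mu, ld, zero, initial = c(10, 0, 0, 0, 0, 0),
                            horizon = 1, state_guard = 0.5),
    "guard")
})

test_that("energy bookkeeping holds along simulated trajectories", {
  mu <- fix_muscle(); ld <- fix_load()
  wf <- generate_stim_waveform(2.4, burst_windows(0.4))
  tr <- simulate_coupled_system(list(mu, mu), ld, wf, horizon = 2,
                                record_dt = 1e-4)
  eb <- energy_balance(tr)
  expect_lt(eb$residual_rel, 1e-4)
})

test_that("periodic steady state is reached under sustained burst stimulation", {
  # settling rate is b/2M; use a damped load so the 1% cycle-to-cycle
  # criterion is met within the recorded window
  ld <- load_params(f_n = 2, zeta = 0.45, k = 1000)
  mu <- fix_muscle()
  wf <- generate_stim_waveform(5, burst_windows(0.4))
  tr <- simulate_coupled_system(list(mu, mu), ld, wf, horizon = 7 / 5,
                                record_dt = 1 / (5 * 400))
  n_cyc <- 400
  x <- matrix(tr$x_m[1:(7 * n_cyc)], nrow = n_cyc)
  rms <- sqrt(colMeans((x[, -1] - x[, -7])^2)) / diff(range(tr$x_m))
  expect_lt(rms[6], 0.01)
})

test_that("trajectories round-trip through CSV", {
  mu <- fix_muscle(); ld <- fix_load()
  wf <- generate_stim_waveform(2, burst_windows(0.3))
  tr <- simulate_coupled_system(mu, ld, wf, horizon = 0.5)
  path <- withr::local_tempfile(fileext = ".csv")
  write_trajectory(tr, path)
  back <- read_trajectory(path)
  expect_equal(back$x_m, tr$x_m, tolerance = 1e-12)
  expect_equal(back$Fnet_N, tr$Fnet_N, tolerance = 1e-12)
  expect_named(back, c("time_s", "x_m", "v_m_s", "a1", "c1", "a2", "c2",
                       "u1", "u2", "F1_N", "F2_N", "Fnet_N"))
})
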