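test_that("costate dynamics match finite differences of the Hamiltonian", {
  pr <- ocp(list(fix_muscle(), fix_muscle()), fix_load(), 3)
  set.seed(1)
  h <- 1e-6
  for (i in 1:100) {
    st <- c(runif(1, -0.01, 0.01), runif(1, -0.3, 0.3), runif(4))
    co <- rnorm(6)
    u <- runif(2)
    out <- hamiltonian_costate(pr, st, co, u)
    fd <- vapply(1:6, function(j) {
      e <- replace(numeric(6), j, h)
      (hamiltonian_costate(pr, st + e, co, u)$H -
         hamiltonian_costate(pr, st - e, co, u)$H) / (2 * h)
    }, numeric(1))
    expect_equal(out$costate_dot, -fd, tolerance = 1e-6)
  }
})

test_that("Hamiltonian decomposes as running cost plus costate-weighted dynamics", {
  pr <- ocp(fix_muscle(), fix_load(), 2)
  st <- c(0.002, 0.05, 0.3, 0.2, 0, 0)
  co <- c(1, -0.2, 0.01, 0.005, 0, 0)
  out <- hamiltonian_costate(pr, st, co, c(0.7, 0))
  nf <- net_load_force(pr$muscles[[1]], pr$muscles[[2]], st[1], st[3], st[5],
                       check_range = FALSE)
  expect_equal(out$H, -nf$Fnet_N * st[2] + sum(co * out$state_dot))
  # with zero activations and costates, the (x, v) costate rates reduce to
  # the gradient of -F_net * v from the passive forces alone
  out0 <- hamiltonian_costate(pr, c(0.002, 0.05, 0, 0, 0, 0), rep(0, 6),
                              c(0, 0))
  K_passive <- pr$muscles[[1]]$B + pr$muscles[[2]]$B
  nf0 <- net_load_force(pr$muscles[[1]], pr$muscles[[2]], 0.002, 0, 0,
                        check_range = FALSE)
  expect_equal(out0$costate_dot[1], -K_passive * 0.05)
  expect_equal(out0$costate_dot[2], nf0$Fnet_N)
  expect_error(hamiltonian_costate(pr, st * NaN, co, c(0, 0)), "non-finite")
})

test_that("bang-bang law minimises H over the control corners, ties to u_min", {
  pr <- ocp(list(fix_muscle(), fix_muscle()), fix_load(), 3)
  set.seed(2)
  corners <- as.matrix(expand.grid(c(0, 1), c(0, 1)))
  for (i in 1:100) {
    st <- c(runif(1, -0.01, 0.01), runif(1, -0.3, 0.3), runif(4))
    co <- rnorm(6) * 10^runif(1, -3, 0)
    u <- bang_bang_control(pr, co)
    H_u <- hamiltonian_costate(pr, st, co, u)$H
    H_corners <- apply(corners, 1, function(cc)
      hamiltonian_costate(pr, st, co, cc)$H)
    expect_lte(H_u, min(H_corners) + 1e-12)
  }
  expect_equal(bang_bang_control(pr, rep(0, 6)), c(0, 0))  # documented tie-break
  expect_error(bang_bang_control(pr, rep(NA_real_, 6)), "non-finite")
})

test_that("unbounded controls are rejected as ill-posed", {
  m <- muscle_params(u_max = Inf)
  expect_error(ocp(m, fix_load(), 2), "ill-posed")
})

test_that("converged cyclic solution satisfies the Pontryagin conditions", {
  sol <- single_solution_2p4()
  expect_true(sol$converged)
  expect_false(sol$trivial)
  expect_gt(sol$work_J, 0)
  expect_lt(sol$residuals["state"], 1e-6)
  expect_lt(sol$residuals["costate"], 1e-6)
  # autonomous fixed-horizon problem: H constant along the orbit to 1%
  expect_lt(sol$H_rel_variation, 0.01)
  # bang-bang: controls at a bound except near switches
  expect_lt(sol$interior_fraction, 0.02)
  expect_false(sol$possibly_singular)

  tr <- sol$trajectory
  # controls obey the bang-bang law along the trajectory (away from switches)
  s_scale <- max(abs(tr$s1))
  away <- abs(tr$s1) > 0.02 * s_scale
  u_law <- ifelse(tr$s1[away] < 0, 1, 0)
  expect_lt(max(abs(tr$u1[away] - u_law)), 1e-2)

  # trajectory forces are recomputable from states (consistency residual)
  m1 <- sol$problem$muscles[[1]]
  F1 <- m1$A + m1$B * (m1$l0 - tr$x_m) + (m1$C + m1$D * (m1$l0 - tr$x_m)) * tr$a1
  expect_lt(max(abs(F1 - tr$F1_N)) / max(abs(tr$F1_N)), 1e-9)

  # state ODE residual at interior nodes (central differences)
  i <- seq(2, nrow(tr) - 1)
  dt2 <- tr$time_s[3] - tr$time_s[1]
  xdot <- (tr$x_m[i + 1] - tr$x_m[i - 1]) / dt2
  expect_lt(max(abs(xdot - tr$v_m_s[i])) / max(abs(tr$v_m_s)), 1e-3)
})

test_that("cyclic work equals damper dissipation on the converged orbit", {
  sol <- single_solution_2p4()
  tr <- sol$trajectory
  diss <- trapz_test(tr$time_s, sol$problem$load$b * tr$v_m_s^2)
  expect_equal(sol$work_J, diss, tolerance = 5e-3)
  # and the workloop is counter-clockwise: positive enclosed area
  wl <- cyclic_work(workloop(tr, freq = sol$problem$freq))
  expect_gt(wl$work_J, 0)
  expect_equal(wl$work_J, sol$work_J, tolerance = 5e-3)
})

test_that("muscle pair solves converge, alternate bursts, and dominate the single muscle", {
  sol12 <- pair_solution_2p4()
  sol1 <- single_solution_2p4()
  expect_true(sol12$converged)
  expect_gt(sol12$work_J, sol1$work_J)  # silent antagonist is feasible
  tr <- sol12$trajectory
  # both muscles produce saturated bursts...
  expect_gt(mean(tr$u1 > 0.99), 0.1)
  expect_gt(mean(tr$u2 > 0.99), 0.1)
  expect_gt(mean(tr$u1 < 0.01), 0.1)
  # ...in alternation: burst centroids about half a period apart
  Tp <- sol12$problem$T
  ph1 <- atan2(mean(sin(2 * pi * tr$time_s / Tp) * tr$u1),
               mean(cos(2 * pi * tr$time_s / Tp) * tr$u1))
  ph2 <- atan2(mean(sin(2 * pi * tr$time_s / Tp) * tr$u2),
               mean(cos(2 * pi * tr$time_s / Tp) * tr$u2))
  dphi <- abs(((ph1 - ph2 + pi) %% (2 * pi)) - pi)
  expect_gt(dphi, 0.6 * pi)
})

test_that("direct transcription reaches the boundary-value solution's work", {
  sol <- single_solution_2p4()
  dtx <- solve_transcription(sol$problem, n_intervals = 32)
  expect_equal(dtx$work_J, sol$work_J, tolerance = 0.02)
})

test_that("without activation-dependent stiffness the optimum sits at f_n", {
  # B = D = 0: the muscle is a bounded, lag-filtered force source, the
  # analytic impedance-free benchmark's optimum is the load resonance
  mf <- muscle_params(A = 0, B = 0, C = 2, D = 0, l0 = 0.03)
  ld <- fix_load()
  sw <- sweep_optimal_power(mf, ld, seq(1.6, 2.4, by = 0.2))
  expect_equal(f_star(sw), ld$f_n)
  bench <- impedance_free_optimal_power(ld, 2, seq(1.6, 2.4, by = 0.2))
  expect_equal(bench$freq_Hz[which.max(bench$mean_power_W)], ld$f_n)
})
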