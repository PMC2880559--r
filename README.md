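# muscleloop

Workloop energetics of muscle-actuated mass-spring-damper systems.

Skeletal muscle is not an ideal force source: its stiffness grows with
activation, so neural input changes the mechanical impedance a load sees.
When a muscle (or an antagonist pair) drives a second-order load
`M x'' + b x' + k x = F_net`, that activation-dependent stiffness lets the
nervous system *retune the resonance* of the coupled system. `muscleloop`
provides the computational machinery to study the energetic consequences:

* a **bilinear muscle model** `F(l, a) = A + B l + C a + D a l` with
  second-order excitation–contraction dynamics
  (`tau_c c' = u - c`, `tau_a a' = c - a`; 125 ms twitch rise, unity gain);
* forward simulation of the six-state **coupled muscle–load system**;
* **power-optimal cyclic control** via the Pontryagin minimum principle:
  with the Hamiltonian `H = -F_net v + lambda' f(z, u)` linear in the
  stimulus, optimal inputs are bang-bang, and the optimal orbit solves a
  cyclic two-point boundary value problem (solved here by a smoothed
  switching homotopy with damped-Newton shooting);
* **workloop energetics**: cyclic work `W = closed integral of F dx`, damper
  dissipation, the synergy ratio `S = W12 / (W1 + W2)`, and normalised-power
  tables;
* the **impedance-matching algebra**: a stiffness-dominated source transfers
  maximal power when its stiffness `k_s = M w^2 - k` nulls the load
  reactance, making the combined natural frequency equal the drive frequency;
* an **emulated virtual-load experiment pipeline** (stimulation waveforms,
  measurement noise, fatigue drift, randomised protocols) and **bilinear
  system identification** by least squares.

The headline model predictions: the power-optimal oscillation frequency of a
muscle-driven load exceeds the load natural frequency (`f* ~ 1.2 f_n` with
the default calibration), while an impedance-free bounded force source peaks
exactly at `f_n`; and an antagonist pair can produce more than twice the
power of its members acting alone (`S > 2`), which no fixed-impedance
actuator pair can.

## Worked example

```r
library(muscleloop)

mu <- default_muscle()     # stiffness-calibrated frog plantaris-like muscle
ld <- default_load()       # f_n = 2 Hz, zeta = 0.1, k = 1000 N/m

sol <- solve_cyclic_optimal_control(ocp(mu, ld, freq = 2.4))
sol
#> <ml_ocp_solution>
#>   f = 2.4 Hz, cyclic work J = 0.000971266 J, mean power = 0.00233104 W (1.55 W/kg)
#>   converged: TRUE (residuals: state 7.7e-09, costate 6.9e-09; beta = 40026.3)
```

The solution object carries the full trajectory (states, costates, switching
functions, bang-bang controls, Hamiltonian trace) as a tibble via `tidy(sol)`,
one-row diagnostics via `glance(sol)`, and plots via `autoplot(sol)`. The
cyclic work (0.97 mJ here, i.e. 2.3 mW at 2.4 Hz) equals the energy the
damper dissipates per cycle — the workloop is counter-clockwise, the muscle
does positive net work.

Sweeping frequency reproduces resonance tuning:

```r
sw <- sweep_optimal_power(mu, ld, seq(1.5, 3.5, by = 0.1))
f_star(sw)
#> [1] 2.4
```

Mean power rises from 0.15 mW at 1.5 Hz to a 2.33 mW peak at 2.4 Hz — 20%
*above* the 2 Hz load resonance — and collapses beyond ~2.8 Hz where even
full activation cannot add enough stiffness to match resonance. The
impedance-free benchmark on the same grid peaks at 2.0 Hz exactly:

```r
bench <- impedance_free_optimal_power(ld, F_max = 5, seq(1.5, 3.5, by = 0.1))
bench$freq_Hz[which.max(bench$mean_power_W)]
#> [1] 2
```

An emulated single-muscle experiment (randomised order, 7 cycles per
measurement with the first discarded, noise and fatigue drift):

```r
cfg <- session_config(ld, mu, frequencies = c(2, 2.5, 3), reps = 6, seed = 7)
h1 <- run_hypothesis1_protocol(cfg, stim_source = "heuristic")
h1$table
#>   freq_Hz  mean     sd     n      t            p stars
#> 1     2   1     0          6   0    1            ""
#> 2     2.5 1.91  0.239      6   9.39 0.000231     "**"
#> 3     3   0.185 0.0328     6 -60.9  0.0000000227 "**"
```

Normalised power at 2.5 Hz is about twice that at the natural frequency and
power at 3 Hz has collapsed — the emulated version of the resonance-tuning
experiment.

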