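# Shared fixtures, built in code at test time.

# small binding-curve population spanning the Hill curve
small_pop <- function(seed = 7, n_cells = 32, noise = FALSE, ...) {
  simulate_population(sim_config(n_cells = n_cells, poisson_noise = noise,
                                 seed = seed, ...))
}

# small saturated calibration population
small_cal <- function(seed = 8, n_cells = 16, noise = FALSE, ...) {
  simulate_population(saturated_sim_config(n_cells = n_cells,
                                           poisson_noise = noise,
                                           seed = seed, ...))
}

# record-level generator: per-cell concentrations and noisy occupancies
# without rendering images (for fit-level statistics)
make_records <- function(n = 268, kd = 592, hill_n = 2.93,
                         conc_lo = 30, conc_hi = 1500, noise_sd = 0.03) {
  conc <- exp(runif(n, log(conc_lo), log(conc_hi)))
  occ <- occupancy(conc, kd, hill_n) + rnorm(n, 0, noise_sd)
  data.frame(free_conc_est = conc, occupancy_est = occ,
             usable = TRUE, discarded = FALSE)
}

# independent steady-state oracle for the degradation model: integrate
# d theta/dt = kon*C*(1-theta) - (koff+kdeg)*theta to steady state with
# deSolve, then bisect on C for theta = 1/2
ode_half_occupancy <- function(kon, koff, kdeg) {
  theta_ss <- function(conc) {
    out <- deSolve::ode(
      y = c(theta = 0), times = c(0, 50 / (koff + kdeg)),
      func = function(t, y, p)
        list(kon * conc * (1 - y[1]) - (koff + kdeg) * y[1]),
      parms = NULL, rtol = 1e-12, atol = 1e-14)
    out[nrow(out), "theta"]
  }
  lo <- 1e-9
  hi <- 1e9
  for (i in 1:200) {
    mid <- sqrt(lo * hi)
    if (theta_ss(mid) < 0.5) lo <- mid else hi <- mid
  }
  sqrt(lo * hi)
}

# quantify + calibrate + concentrations for a population pair
quantified <- function(pop, cal, config = quant_config()) {
  cal_rec <- discard_bright(quantify_population(cal, config),
                            config$bright_discard_factor)
  ref <- calibrate_saturation(cal_rec, cal$config$lacO_repeats)
  rec <- quantify_population(pop, config)
  estimate_concentration(rec, ref, pop$config$lacO_repeats, config)
}
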