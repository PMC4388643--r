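# Shared fixture builders. Everything is generated in code; no binary data.

# A thermogram holding a rectangular power pulse of `height` ucal/s over
# [pulse_start, pulse_end], zero elsewhere, sampled every `dt` s.
rect_pulse_tg <- function(pulse_start = 100, pulse_end = 200, height = -1,
                          t_end = 600, dt = 5) {
  tt <- seq(0, t_end, by = dt)
  pp <- ifelse(tt >= pulse_start & tt <= pulse_end, height, 0)
  thermogram(tt, pp)
}

# A hand-built cell trajectory on a fine grid, for exercising
# render_thermogram in isolation from the ODE integrator.
manual_trajectory <- function(time, ideal_power, params) {
  structure(data.frame(time = time, S = 0, P = 0, E = 0,
                       ideal_power = ideal_power),
            params = params, dt_fine = diff(time[1:2]),
            class = c("cell_trajectory", "data.frame"))
}

# The enhanced titration design used in the robustness study: 30 x 2 uL of
# 5 mM substrate, 60 s spacing (substrate accumulates well past Km).
enhanced_schedule <- function(t0 = 300) {
  injection_schedule(time = t0 + 60 * (0:29), volume = 2, syringe_conc = 5000,
                     syringe_capacity = 60)
}

enhanced_params <- function(noise_sd = 0.01, seed = 1L) {
  sim_params(kcat = 0.234, Km = 56.7, E0 = 1.39, delta_h = -25040,
             cell = cell_config(volume = 200, E0 = 1.39),
             schedule = enhanced_schedule(), instrument_tau = 6,
             noise_sd = noise_sd, seed = seed, sample_interval = 5,
             final_hold = 60)
}

# Deterministic enthalpy calibration: the noise-free single-injection
# experiment processed through baseline correction and Eq-1 integration.
calibrate_dh <- function() {
  ps <- make_default_lsa_params("single_lsa", noise_sd = 0)
  sim <- simulate_itc(ps)
  bl <- fit_baseline(sim$thermogram, ps$schedule)
  tg <- baseline_correct(sim$thermogram, bl)
  estimate_delta_h_app(tg, ps$schedule, ps$cell)
}

# Full multiple-injection processing chain on a simulated experiment,
# returning the MM fit (enthalpy from `dh`, typically calibrate_dh()).
process_multi <- function(pm, dh, tau = 6, guard = 15) {
  sim <- simulate_itc(pm)
  bl <- fit_baseline(sim$thermogram, pm$schedule)
  tg <- baseline_correct(sim$thermogram, bl)
  tg <- deconvolve_tian(tg, tau = tau)
  rates <- power_to_rate(tg, dh, pm$cell)
  straj <- substrate_trajectory(tg, dh, pm$schedule, pm$cell)
  rc <- build_rate_curve(rates, straj, pm$schedule, tau = tau, guard = guard,
                         cell = pm$cell)
  fit_michaelis_menten(rc)
}
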