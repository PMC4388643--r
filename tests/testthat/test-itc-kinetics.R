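# The core inference: enthalpy, rates, residual substrate, rate curve.

test_that("apparent enthalpy is heat over converted moles, per convention", {
  # one 5 uL injection of 100 uM at t = 100 s followed by a -1 ucal/s pulse
  # whose trapezoidal area (including the 5 s ramps at its edges) is exactly
  # 100 s x -1 ucal/s: total heat -1e-4 cal
  tg <- rect_pulse_tg(pulse_start = 105, pulse_end = 200, height = -1,
                      t_end = 800)
  sch <- injection_schedule(time = 100, volume = 5, syringe_conc = 100)
  cell <- cell_config(volume = 200)

  # naive bolus accounting: 5e-10 mol
  dh <- estimate_delta_h_app(tg, sch, cell)
  expect_equal(dh$delta_h_app, -1e-4 / 5e-10)
  expect_equal(dh$converted_moles, 5e-10)
  # full displacement of the bolus: 4.875e-10 mol -> -2.0513e5 cal/mol
  dh_full <- estimate_delta_h_app(tg, sch, cell, bolus_displacement = "full")
  expect_equal(dh_full$converted_moles, 4.875e-10)
  expect_equal(dh_full$delta_h_app, -2.0513e5, tolerance = 1e-4)
  # half-exposure convention sits in between
  dh_half <- estimate_delta_h_app(tg, sch, cell, bolus_displacement = "half")
  expect_equal(dh_half$converted_moles, 5e-10 * (1 - 5 / 400))

  # zero heat gives zero enthalpy
  tg0 <- thermogram(seq(0, 800, 5), rep(0, 161))
  expect_equal(estimate_delta_h_app(tg0, sch, cell)$delta_h_app, 0)
})

test_that("incomplete conversion before the next injection is refused", {
  tt <- seq(0, 600, by = 5)
  tg <- thermogram(tt, ifelse(tt >= 100, -1, 0))   # never returns to baseline
  sch <- injection_schedule(time = 100, volume = 5, syringe_conc = 100)
  expect_error(estimate_delta_h_app(tg, sch, cell_config(volume = 200)),
               "incomplete conversion")
})

test_that("single-injection simulation recovers the generating enthalpy", {
  p <- make_default_lsa_params("single_lsa", noise_sd = 0)   # tau = 6
  sim <- simulate_itc(p)
  tg <- baseline_correct(sim$thermogram, fit_baseline(sim$thermogram, p$schedule))
  dh <- estimate_delta_h_app(tg, p$schedule, p$cell)
  expect_equal(dh$delta_h_app, -25040, tolerance = 0.02)
  # both injections give consistent per-injection estimates
  expect_lt(diff(range(dh$per_injection$delta_h)) / abs(dh$delta_h_app), 0.02)
})

test_that("power converts to rate through V * delta_H", {
  cell <- cell_config(volume = 200)
  tg <- thermogram(c(0, 5, 10), c(0, -0.501, 0))
  r <- power_to_rate(tg, -25040, cell)
  expect_equal(r$rate_uM_per_s[2], 0.10004, tolerance = 1e-4)
  expect_equal(r$rate_uM_per_s[c(1, 3)], c(0, 0))
  # flipping the sign of both power and enthalpy leaves rates unchanged
  tgf <- thermogram(c(0, 5, 10), c(0, 0.501, 0))
  expect_equal(power_to_rate(tgf, 25040, cell)$rate_uM_per_s, r$rate_uM_per_s)
  # zero enthalpy is a hard error with guidance
  expect_error(power_to_rate(tg, 0, cell), "single-injection")
})

test_that("residual substrate follows the cumulative-heat ledger", {
  # single 5 uL bolus of 100 uM (2.5 uM in-cell) at t = 100, constant power
  # thereafter: [P]_t grows linearly, so S hits S_total/2 when half the
  # total heat has flowed
  cell <- cell_config(volume = 200)
  sch <- injection_schedule(time = 100, volume = 5, syringe_conc = 100)
  tt <- seq(0, 600, by = 5)
  dh <- -25040
  # power such that conversion completes exactly at t = 500: 2.5 uM over
  # 400 s -> rate 0.00625 uM/s -> power = rate * V * dH * 1e-6
  pw <- ifelse(tt > 100 & tt <= 500, 0.00625 * 200 * dh * 1e-6, 0)
  tg <- thermogram(tt, pw)
  straj <- substrate_trajectory(tg, dh, sch, cell)
  expect_true(all(straj$S_uM[straj$time_s < 100] == 0))
  expect_true(all(straj$S_total_uM[straj$time_s >= 100] == 2.5))
  # midpoint of the heat at t = 302.5; at t = 300 [P] is just under half
  i <- which(straj$time_s == 300)
  expect_equal(straj$P_uM[i], 2.5 * (197.5 / 400), tolerance = 1e-6)
  # completion: residual substrate returns to ~0 and stays there
  expect_lt(max(abs(straj$S_uM[straj$time_s >= 505])), 1e-6)
})

test_that("an inconsistent enthalpy raises a sign-convention error", {
  cell <- cell_config(volume = 200)
  sch <- injection_schedule(time = 100, volume = 5, syringe_conc = 100)
  tt <- seq(0, 600, by = 5)
  pw <- ifelse(tt > 100 & tt <= 500, 0.00625 * 200 * -25040 * 1e-6, 0)
  tg <- thermogram(tt, pw)
  # enthalpy magnitude understated by 2x -> apparent [P] overshoots S_total
  expect_error(substrate_trajectory(tg, -12520, sch, cell), "negative")
})

test_that("rate curve windowing retains 6 points per interval by default", {
  p <- make_default_lsa_params("multi_lsa", noise_sd = 0)
  sim <- simulate_itc(p)
  tg <- baseline_correct(sim$thermogram, fit_baseline(sim$thermogram, p$schedule))
  tg <- deconvolve_tian(tg, tau = 6)
  rates <- power_to_rate(tg, -25040, p$cell)
  straj <- substrate_trajectory(tg, -25040, p$schedule, p$cell)
  rc <- build_rate_curve(rates, straj, p$schedule, tau = 6)   # settle = 30 s
  kept <- rc[rc$retained & rc$injection_idx %in% 1:29, ]
  counts <- table(kept$injection_idx)
  expect_true(all(counts == 6))   # samples at +30..55 s
  offs <- (kept$time_s - p$schedule$time_s[kept$injection_idx]) %% 60
  expect_true(all(offs >= 30 & offs <= 55))

  # with no settling window every post-first-injection point is retained
  rc0 <- build_rate_curve(rates, straj, p$schedule, settle = 0, tau = 0)
  expect_true(all(rc0$retained[rc0$time_s >= 300]))
  expect_true(!any(rc0$retained[rc0$time_s < 300]))
  # reason codes recorded for the exclusions
  excl <- attr(rc, "excluded_windows")
  expect_setequal(unique(vapply(excl, `[[`, "", "reason")),
                  c("pre_injection", "settling"))
  expect_error(build_rate_curve(rates, straj, p$schedule, settle = 1e6),
               "all points excluded")
})

test_that("within an interval the noise-free rate decays with the substrate", {
  p <- make_default_lsa_params("multi_lsa", noise_sd = 0)
  sim <- simulate_itc(p)
  tg <- baseline_correct(sim$thermogram, fit_baseline(sim$thermogram, p$schedule))
  tg <- deconvolve_tian(tg, tau = 6)
  rates <- power_to_rate(tg, -25040, p$cell)
  straj <- substrate_trajectory(tg, -25040, p$schedule, p$cell)
  rc <- build_rate_curve(rates, straj, p$schedule, tau = 6, guard = 15)
  kept <- rc[rc$retained & rc$injection_idx %in% 2:29, ]
  for (k in unique(kept$injection_idx)) {
    seg <- kept[kept$injection_idx == k, ]
    expect_true(all(diff(seg$S_uM) < 0))
    expect_true(all(diff(seg$rate_uM_per_s) < 1e-4))
  }
})

test_that("rate and substrate series are internally consistent (Eq 2 vs Eq 3)", {
  p <- make_default_lsa_params("multi_lsa", noise_sd = 0.01, seed = 3)
  sim <- simulate_itc(p)
  tg <- baseline_correct(sim$thermogram, fit_baseline(sim$thermogram, p$schedule))
  dh <- -25040
  rates <- power_to_rate(tg, dh, p$cell)
  straj <- substrate_trajectory(tg, dh, p$schedule, p$cell)
  # conservation by construction, asserted as a regression tripwire
  expect_equal(straj$S_uM + straj$P_uM, straj$S_total_uM, tolerance = 1e-12)
  # the cumulative trapezoid of the rate series reproduces the undiluted
  # product ledger (both derive from the same cumulative heat)
  ctz <- c(0, cumsum(diff(rates$time_s) *
                       (head(rates$rate_uM_per_s, -1) +
                          tail(rates$rate_uM_per_s, -1)) / 2))
  # [P] increments between samples with no intervening injection must match
  # the trapezoidal integral of the rate series (dilution steps only occur
  # at injection instants)
  inj_at <- straj$time_s %in% p$schedule$time_s
  dP <- diff(straj$P_uM); dC <- diff(ctz)
  ok <- !inj_at[-1] & straj$time_s[-1] > min(p$schedule$time_s)
  expect_equal(dP[ok], dC[ok], tolerance = 1e-10)
})

test_that("the rate curve is invariant under proportional volume rescaling", {
  # doubling the cell volume and every injected volume (same syringe
  # concentration) preserves v/V and c*v/V, hence all in-cell
  # concentrations, so the (S, rate) curve is unchanged
  base <- make_default_lsa_params("multi_lsa", noise_sd = 0)
  scaled <- base
  scaled$cell <- cell_config(volume = 400, E0 = 1.39)
  scaled$schedule <- injection_schedule(time = base$schedule$time_s,
                                        volume = 2, syringe_conc = 1000,
                                        syringe_capacity = 80)
  curves <- lapply(list(base, scaled), function(p) {
    sim <- simulate_itc(p)
    tg <- baseline_correct(sim$thermogram, fit_baseline(sim$thermogram, p$schedule))
    tg <- deconvolve_tian(tg, tau = 6)
    rates <- power_to_rate(tg, -25040, p$cell)
    straj <- substrate_trajectory(tg, -25040, p$schedule, p$cell)
    build_rate_curve(rates, straj, p$schedule, tau = 6, cell = p$cell)
  })
  expect_equal(curves[[1]]$S_uM, curves[[2]]$S_uM, tolerance = 1e-8)
  expect_equal(curves[[1]]$rate_E0_uM_per_s, curves[[2]]$rate_E0_uM_per_s,
               tolerance = 1e-8)
})

test_that("extracted rates track the simulator's true rates within 2%", {
  p <- make_default_lsa_params("multi_lsa", noise_sd = 0)
  traj <- simulate_cell(p)
  sim_tg <- render_thermogram(traj, p)
  tg <- baseline_correct(sim_tg, fit_baseline(sim_tg, p$schedule))
  tg <- deconvolve_tian(tg, tau = 6)
  rates <- power_to_rate(tg, -25040, p$cell)
  straj <- substrate_trajectory(tg, -25040, p$schedule, p$cell)
  rc <- build_rate_curve(rates, straj, p$schedule, tau = 6, guard = 15)
  kept <- rc[rc$retained, ]
  truth <- traj$ideal_power[match(kept$time_s, traj$time)] / (-25040 * 200) * 1e6
  expect_lt(max(abs(kept$rate_uM_per_s - truth)) / max(truth), 0.02)
})

test_that("rate curves round-trip through delimited text", {
  p <- make_default_lsa_params("multi_lsa", noise_sd = 0)
  sim <- simulate_itc(p)
  tg <- baseline_correct(sim$thermogram, fit_baseline(sim$thermogram, p$schedule))
  rates <- power_to_rate(tg, -25040, p$cell)
  straj <- substrate_trajectory(tg, -25040, p$schedule, p$cell)
  rc <- build_rate_curve(rates, straj, p$schedule, tau = 6)
  path <- withr::local_tempfile(fileext = ".csv")
  write_rate_curve(rc, path)
  back <- read_rate_curve(path)
  expect_equal(nrow(back), nrow(rc))
  expect_equal(back$S_uM, rc$S_uM, tolerance = 1e-12)
  expect_equal(back$retained, rc$retained)
})
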