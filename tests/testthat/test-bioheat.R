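test_that("pulse train validates duty cycle and exposes it", {
  expect_equal(pulse_train(repetition_rate = 50)$duty_cycle, 0.5)
  expect_equal(pulse_train(repetition_rate = 1)$duty_cycle, 0.01)
  expect_error(pulse_train(pulse_duration = 0.03, repetition_rate = 50),
               "duty")
  expect_error(pulse_train(amplitude = -1), "amplitude")
})

test_that("Joule source is sigma E^2 and scales with Vp^2", {
  fx <- make_parallel_plate(0.01, Vp = 40, sigma = 0.25)
  sol <- solve_field(fx$domain)
  p <- joule_source(sol)
  interior <- p[, 3:(ncol(p) - 2)]
  expect_equal(mean(interior), 0.25 * 4000^2, tolerance = 1e-7)
  # E = 100 V/m in wall tissue (sigma 0.25) deposits 2500 W/m^3
  sol100 <- sol
  sol100$field_magnitude[] <- 100
  expect_true(all(abs(joule_source(sol100)[fx$domain$material == 3L] -
                        2500) < 1e-9))
  sol0 <- sol
  sol0$field_magnitude[] <- 0
  expect_true(all(joule_source(sol0) == 0))
})

test_that("domain-integrated Joule power balances the electrode terminal power", {
  dom <- build_model(small_geometry(), electrode_configuration(1, 4, 0.013),
                     grid_spacing = 2.5e-4)
  sol <- solve_field(dom)
  p_total <- sum(joule_source(sol) * outer(dom$grid$dx, dom$grid$dy))
  I <- electrode_currents(sol)
  terminal <- sum(I[dom$electrode_active]) * 40
  expect_lt(abs(p_total / terminal - 1), 0.02)
})

test_that("equilibrium is preserved without a source", {
  dom <- build_model(small_geometry(), electrode_configuration(1, 2, 0.01),
                     grid_spacing = 5e-4)
  op <- bioheat_operator(dom, perfusion_factor = 1)
  theta <- numeric(length(op$M))
  for (i in 1:5) theta <- step_bioheat(op, theta, dt = 0.01)
  expect_lt(max(abs(theta)), 1e-9)
})

test_that("lumped perfused cell follows the Pennes ODE closed form", {
  fx <- make_lumped_thermal(p = 1e6, perfusion_factor = 1)
  op <- bioheat_operator(fx$domain, perfusion_factor = 1)
  tau <- fx$heat_capacity_volumetric / fx$sink_coefficient
  dt <- tau / 500
  theta <- 0
  for (i in 1:500) theta <- step_bioheat(op, theta, dt, source = fx$p)
  expect_equal(theta, fx$closed_form(tau), tolerance = 2e-3)
  # steady state equals source over sink coefficient
  for (i in 1:5000) theta <- step_bioheat(op, theta, 10 * dt, source = fx$p)
  expect_equal(theta, fx$p / fx$sink_coefficient, tolerance = 1e-6)
  # doubling the source doubles the steady rise (linearity)
  fx2 <- make_lumped_thermal(p = 2e6, perfusion_factor = 1)
  expect_equal(fx2$closed_form(1e9), 2 * fx$closed_form(1e9))
})

test_that("unperfused lumped cell heats as the adiabatic ramp", {
  fx <- make_lumped_thermal(p = 5e5, perfusion_factor = 0)
  op <- bioheat_operator(fx$domain, perfusion_factor = 0)
  theta <- 0
  for (i in 1:100) theta <- step_bioheat(op, theta, 0.01, source = fx$p)
  expect_equal(theta, fx$closed_form(1), tolerance = 1e-9)
  expect_equal(fx$closed_form(1), fx$p / fx$heat_capacity_volumetric)
})

test_that("enthalpy gain equals integrated Joule input on an insulated box", {
  dom <- fixture_domain_box()
  op <- bioheat_operator(dom, perfusion_factor = 0)
  p <- matrix(2e5, dom$grid$nx, dom$grid$ny)
  p[3:5, 3:5] <- 2e6  # concentrated hot spot, diffusion active
  theta <- numeric(length(op$M))
  nstep <- 50; dt <- 0.05
  for (i in seq_len(nstep)) theta <- step_bioheat(op, theta, dt, source = p)
  gained <- sum(op$M * theta)
  injected <- nstep * dt * sum(p * outer(dom$grid$dx, dom$grid$dy))
  expect_lt(abs(gained / injected - 1), 0.01)
})

test_that("session temperatures rise above baseline and saw-tooth per pulse", {
  dom <- build_model(small_geometry(), electrode_configuration(1, 2, 0.01),
                     grid_spacing = 5e-4)
  sol <- solve_field(dom)
  pt <- pulse_train(repetition_rate = 5, session_duration = 1)
  tr <- run_session(dom, pt, perfusion_factor = 0.01, solution = sol,
                    axial_length = 0.03)
  hist <- tr$temperature_history
  expect_true(all(hist$T_K >= tr$baseline - 1e-12))
  expect_gt(tr$max_wall_rise, 0)
  expect_true(all(tr$final_temperature_map >= tr$baseline - 1e-12))
  # pulse gating: per period the heated interval warms the wall probe much
  # faster than the conduction-fed cooling interval
  steps_per <- nrow(hist) / 5
  for (per in 2:5) {
    seg <- hist$T_K[((per - 1) * steps_per + 1):(per * steps_per)]
    on_rate <- (seg[10] - seg[1]) / (10 * 1e-3)
    off_rate <- (seg[length(seg)] - seg[10]) / 0.19
    expect_gt(on_rate, 3 * abs(off_rate))
  }
})

test_that("a perfused probe cell shows a saw-tooth under pulsed heating", {
  # lumped gated Pennes cell: local maxima at pulse ends, decay in between
  fx <- make_lumped_thermal(p = 1e6, perfusion_factor = 1)
  op <- bioheat_operator(fx$domain, perfusion_factor = 1)
  theta <- 0
  trace <- numeric(0)
  for (per in 1:5) {
    for (i in 1:10) {
      theta <- step_bioheat(op, theta, 1e-3, source = fx$p)
      trace <- c(trace, theta)
    }
    for (i in 1:9) {
      theta <- step_bioheat(op, theta, 1e-2, source = fx$p, source_on = FALSE)
      trace <- c(trace, theta)
    }
  }
  m <- matrix(trace, nrow = 19)
  expect_true(all(m[10, ] > m[1, ]))    # rises while the pulse is on
  expect_true(all(m[19, ] < m[10, ]))   # decays while it is off
  expect_true(all(diff(m[10, ]) > 0))   # envelope of pulse-end maxima grows
})

test_that("heating grows with repetition rate and falls with perfusion", {
  dom <- build_model(small_geometry(), electrode_configuration(1, 2, 0.01),
                     grid_spacing = 5e-4)
  sol <- solve_field(dom)
  rises_rate <- vapply(c(1, 10, 50), function(f) {
    run_session(dom, pulse_train(repetition_rate = f, session_duration = 2),
                perfusion_factor = 0.01, solution = sol,
                axial_length = 0.03)$max_wall_rise
  }, numeric(1))
  expect_true(all(diff(rises_rate) > 0))
  rises_perf <- vapply(c(1, 0.1, 0.01), function(w) {
    run_session(dom, pulse_train(repetition_rate = 50, session_duration = 2),
                perfusion_factor = w, solution = sol,
                axial_length = 0.03)$max_wall_rise
  }, numeric(1))
  expect_true(all(diff(rises_perf) > 0))  # lower perfusion -> hotter
})

test_that("halving the time step changes the session rise by < 2 %", {
  dom <- build_model(small_geometry(), electrode_configuration(1, 2, 0.01),
                     grid_spacing = 5e-4)
  sol <- solve_field(dom)
  pt <- pulse_train(repetition_rate = 10, session_duration = 2)
  r1 <- run_session(dom, pt, 0.01, solution = sol, dt_on = 1e-3,
                    dt_off = 1e-2, axial_length = 0.03)$max_wall_rise
  r2 <- run_session(dom, pt, 0.01, solution = sol, dt_on = 5e-4,
                    dt_off = 5e-3, axial_length = 0.03)$max_wall_rise
  expect_lt(abs(r1 / r2 - 1), 0.02)
})

test_that("invalid steps are rejected", {
  fx <- make_lumped_thermal(p = 0)
  op <- bioheat_operator(fx$domain)
  expect_error(step_bioheat(op, 0, dt = -1), "time-step error")
})
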