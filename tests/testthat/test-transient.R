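test_that("the simulated step response matches the closed-form C-R-C exponential", {
  st <- crc_stack()
  k <- crc_constants(st)
  V0 <- 1
  # near-instantaneous ramp stands in for the step; after it the medium
  # voltage decays as V0 * Cs/(Cs+C2) * exp(-t/tau)
  w <- wf_trapezoid(V0, rise = k$tau / 1e4, width = 3 * k$tau)
  res <- simulate_transient(st, w, t_span = c(0, 2 * k$tau),
                            max_step = k$tau / 500)
  sel <- res$time > k$tau / 100 & res$time < 1.5 * k$tau
  exact <- V0 * k$Cs / (k$Cs + k$C2) * exp(-(res$time[sel] - w$rise) / k$tau)
  expect_lt(max(abs(res$v[sel, 2] - exact) / abs(exact)), 1e-4)
})

test_that("KVL holds to machine precision at every output time", {
  s <- build_setup("brighton1992")
  res <- simulate_transient(s, t_span = c(0, 10 / 60e3))
  expect_lt(res$diagnostics$max_kvl_residual, 1e-8 * max(abs(res$V_source)))
  h <- build_setup("hartig2000")
  res2 <- simulate_transient(h, t_span = c(0, h$waveform$period))
  expect_lt(res2$diagnostics$max_kvl_residual, 1e-8 * max(abs(res2$V_source)))
})

test_that("steady-state amplitudes reproduce the phasor solution on every drive", {
  for (id in setdiff(cc_setups(), "khaw2021")) {
    s <- build_setup(id)
    f <- matched_frequency(s$waveform)
    A <- matched_amplitude(s$waveform)
    an <- solve_stack_phasor(s, A, f)$E_medium
    res <- simulate_transient(s, wf_sinusoid(A, f), t_span = c(0, 10 / f))
    ss <- steady_state_amplitude(res)
    expect_lt(rel_err(ss$amplitude, an), 0.01)
    expect_lt(res$diagnostics$n_steps, 1e5)
  }
})

test_that("a DC drive relaxes to the resistive-divider (effectively zero) field", {
  k <- build_setup("khaw2021")
  res <- simulate_transient(k, t_span = c(0, 1))
  expect_lt(abs(res$E_medium[length(res$E_medium)]), 1e-9)
  expect_equal(res$E_medium[length(res$E_medium)],
               solve_stack_phasor(k, 14.2, 0)$E_medium, tolerance = 1e-6)
})

test_that("phase leads distinguish resistive and capacitor-dominated ladders", {
  salt <- material("electrolyte", 1, 1)
  rrr <- stack_setup("rrr", list(layer(salt, 1e-3), layer(salt, 2e-3, role = "medium"),
                                 layer(salt, 1e-3)),
                     radius = 0.01, waveform = wf_sinusoid(1, 100))
  ss <- steady_state_amplitude(simulate_transient(rrr, t_span = c(0, 10 / 100)))
  expect_lt(abs(ss$phase_lead), 1e-6)
  expect_equal(ss$amplitude, 1 * 0.5 / 2e-3, tolerance = 1e-6)  # resistive divider
  b <- build_setup("brighton1992")
  ssb <- steady_state_amplitude(simulate_transient(b, t_span = c(0, 10 / 60e3)))
  expect_lt(abs(ssb$phase_lead - pi / 2), 2 * pi / 180)
})

test_that("trapezoidal pulses put all the field on the edges", {
  r <- build_setup("rodan1978")
  pr <- trapezoid_pulse_response(r)
  expect_lt(rel_err(pr$rising_peak, 5.9e-3), 0.05)
  expect_lt(rel_err(-pr$falling_peak, 5.9e-3), 0.05)
  # symmetric edges: equal magnitude, opposite sign
  expect_equal(pr$falling_peak, -pr$rising_peak, tolerance = 1e-6)
  expect_lt(pr$plateau_max_abs, 1e-3 * abs(pr$rising_peak))
  expect_error(trapezoid_pulse_response(r, wf_dc(1)), "trapezoid")
})

test_that("the sawtooth field peaks on the fast edge and nearly vanishes on the slow one", {
  h <- build_setup("hartig2000")
  w <- h$waveform
  res <- simulate_transient(h, t_span = c(0, w$period))
  edge <- res$time <= w$rise
  late <- res$time > 0.1 * w$period          # deep in the slow falling ramp
  peak <- max(abs(res$E_medium[edge]))
  expect_lt(rel_err(peak, 5.5), 0.05)
  expect_lt(max(abs(res$E_medium[late])), 1e-3 * peak)
  expect_true(all(res$E_medium[late] < 0))   # opposite sign on the falling ramp
  # per-edge slew-rate estimates bracket the simulated fields
  expect_lt(rel_err(peak, quick_capacitive_estimate(h, 100 / 45e-9)), 0.05)
  e_fall <- quick_capacitive_estimate(h, -100 / 62.5e-3)
  expect_lt(rel_err(min(res$E_medium[late]), e_fall), 0.05)
})

test_that("halving the step changes reported peaks by less than 0.1%", {
  s <- build_setup("brighton1992")
  per <- 1 / 60e3
  a1 <- steady_state_amplitude(simulate_transient(s, t_span = c(0, 10 * per),
                                                  max_step = per / 256))$amplitude
  a2 <- steady_state_amplitude(simulate_transient(s, t_span = c(0, 10 * per),
                                                  max_step = per / 512))$amplitude
  expect_lt(rel_err(a2, a1), 1e-3)
  h <- build_setup("hartig2000")
  p1 <- max(abs(simulate_transient(h, t_span = c(0, h$waveform$period))$E_medium))
  p2 <- max(abs(simulate_transient(h, t_span = c(0, h$waveform$period),
                                   min_edge_steps = 40)$E_medium))
  expect_lt(rel_err(p2, p1), 1e-3)
})

test_that("no net charge crosses the stack over a full period", {
  s <- build_setup("brighton1992")
  res <- simulate_transient(s, t_span = c(0, 10 / 60e3))
  t <- res$time; I <- res$I
  trapz <- function(x, y) sum(diff(x) * (head(y, -1) + tail(y, -1)) / 2)
  sel <- t >= 9 / 60e3
  Q <- cumsum(c(0, diff(t) * (head(I, -1) + tail(I, -1)) / 2))
  expect_lt(abs(trapz(t[sel], I[sel])), 1e-6 * max(abs(Q)))
})

test_that("simulation inputs are validated", {
  s <- build_setup("brighton1992")
  expect_error(simulate_transient(s, t_span = c(1, 1)), "increasing")
  expect_error(simulate_transient(stack_setup(s$id, s$layers, s$radius),
                                  t_span = c(0, 1)), "waveform")
  res <- simulate_transient(s, t_span = c(0, 10 / 60e3))
  expect_error(steady_state_amplitude(
    simulate_transient(s, t_span = c(0, 2 / 60e3))), "5 periods")
  h <- build_setup("hartig2000")
  expect_error(steady_state_amplitude(
    simulate_transient(h, t_span = c(0, h$waveform$period))), "sinusoidal")
})

test_that("transient results export to a stable CSV layout", {
  s <- build_setup("brighton1992")
  res <- simulate_transient(s, t_span = c(0, 5 / 60e3))
  path <- tempfile(fileext = ".csv")
  on.exit(unlink(path))
  df <- transient_to_csv(res, path)
  got <- utils::read.csv(path)
  expect_identical(names(got), names(df))
  expect_true(all(c("t", "V_source", "I") %in% names(got)))
  expect_equal(got$E_Culture_Medium, unname(res$E[, res$medium]), tolerance = 1e-6)
})
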