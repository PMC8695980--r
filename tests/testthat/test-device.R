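test_that("window function matches its closed form and locks the boundaries", {
  # boundary the state moves toward is locked for that polarity
  expect_identical(memristor_window(1, +1), 0)
  expect_identical(memristor_window(0, -1), 0)
  expect_equal(memristor_window(0.5, +1), 0.5)
  # general (j, p): j (1-x)^p for positive current, j x^p for negative
  for (x in c(0, 0.2, 0.7, 1)) for (p in c(0.5, 1, 2)) {
    expect_equal(memristor_window(x, +1, j = 2, p = p), 2 * (1 - x)^p)
    expect_equal(memristor_window(x, -1, j = 2, p = p), 2 * x^p)
  }
  expect_error(memristor_window(1.2, +1), "outside")
  expect_error(memristor_window(-0.1, -1), "outside")
})

test_that("drift rate has a dead zone and the documented branch values", {
  st0 <- device_state(0, dp)
  expect_identical(drift_rate(0, st0, dp), 0)
  expect_identical(drift_rate(0.0199, st0, dp), 0)
  expect_identical(drift_rate(-0.0199, device_state(0.5, dp), dp), 0)
  # at the threshold the polynomial factor vanishes
  expect_equal(drift_rate(dp$v_off, st0, dp), 0)
  expect_equal(drift_rate(dp$v_on, device_state(0.5, dp), dp), 0)
  # one threshold-voltage unit above v_off at x = 0: rate = k_off
  expect_equal(drift_rate(0.04, st0, dp), 21)
  # negative branch scales with the window j x^p
  expect_equal(drift_rate(-0.04, device_state(0.5, dp), dp),
               -28 * 1 * 0.5)
})

test_that("apply_pulse reproduces the single-step Euler closed form", {
  # zero voltage or zero duration leave the state untouched
  st <- device_state(0.3, dp)
  expect_equal(apply_pulse(st, 0, 1, dp)$w, 0.3)
  expect_equal(apply_pulse(st, 0.5, 0, dp)$w, 0.3)
  # potentiating pulse from x = 0 (the Z-stage design point)
  got <- apply_pulse(device_state(0, dp), 0.1932, 5e-4, dp)$w
  expect_equal(got, euler_pulse_oracle(0, 0.1932, 5e-4), tolerance = 1e-14)
  expect_equal(got, 0.09093, tolerance = 1e-4)
  # depressing pulse from x = 0.5
  got <- apply_pulse(device_state(0.5, dp), -0.1499, 5e-4, dp)$w
  expect_equal(got, euler_pulse_oracle(0.5, -0.1499, 5e-4), tolerance = 1e-14)
  expect_equal(got, 0.45453, tolerance = 1e-4)
})

test_that("single-substep pulses equal the affine coefficient maps", {
  # w' = C w + D (positive) and w' = E w (negative) to machine precision
  set.seed(11)
  for (k in 1:50) {
    x <- stats::runif(1)
    v <- stats::runif(1, dp$v_off, 0.5)
    co <- update_coefficients(v, 5e-4, dp)
    expect_equal(apply_pulse(device_state(x, dp), v, 5e-4, dp)$w,
                 co$C * x + co$D, tolerance = 1e-12)
    v <- stats::runif(1, -0.5, dp$v_on)
    co <- update_coefficients(v, 5e-4, dp)
    expect_equal(apply_pulse(device_state(x, dp), v, 5e-4, dp)$w,
                 co$E * x, tolerance = 1e-12)
  }
})

test_that("state stays in [0, 1] under random waveforms and big pulses abort", {
  set.seed(21)
  for (rep in 1:5) {
    st <- device_state(stats::runif(1), dp)
    for (v in stats::runif(200, -0.6, 0.6)) {
      st <- apply_pulse(st, v, 1e-3, dp)
      expect_gte(st$w, 0)
      expect_lte(st$w, dp$w_max)
    }
  }
  # without the window (p = 0 makes f constant) a huge Euler step overshoots
  flat <- device_params(window_p = 0)
  expect_error(apply_pulse(device_state(0, flat), 0.5, 0.1, flat),
               "substeps")
})

test_that("waveforms strictly inside the dead zone leave w unchanged exactly", {
  set.seed(31)
  st <- device_state(0.4, dp)
  for (v in stats::runif(100, -0.0199, 0.0199)) {
    st <- apply_pulse(st, v, 1e-3, dp)
  }
  expect_identical(st$w, 0.4)
})

test_that("Euler integration converges to the analytic exponential", {
  # constant v > v_off, p = 1: dx/dt = c (1 - x), x(t) = 1 - e^{-c t}
  v <- 0.1; t_end <- 0.05
  c_rate <- dp$k_off * (v / dp$v_off - 1) / dp$w_max
  exact <- 1 - exp(-c_rate * t_end)
  err <- vapply(c(10, 20, 40, 80), function(n)
    abs(apply_pulse(device_state(0, dp), v, t_end, dp, substeps = n)$w -
          exact), numeric(1))
  expect_true(all(diff(err) < 0))              # monotone refinement
  expect_lt(err[4], err[1] / 4)                # at least first-order
  expect_lt(err[4], 5e-3)
})

test_that("resistance map is affine and exactly invertible", {
  expect_equal(read_resistance(device_state(0, dp), dp), 2e3)
  expect_equal(read_resistance(device_state(1, dp), dp), 200e3)
  expect_equal(read_resistance(device_state(0.5, dp), dp), 101e3)
  r <- read_resistance(device_state(0.37, dp), dp)
  expect_equal((r - dp$r_on) / (dp$r_off - dp$r_on), 0.37)
  expect_error(device_state(1.5, dp), "outside")
})

test_that("iv_sweep produces a pinched hysteresis loop", {
  # zero and sub-threshold waveforms keep the state frozen
  sw <- iv_sweep(rep(0, 20), 1e-3, dp, device_state(0.3, dp))
  expect_true(all(sw$i == 0))
  expect_true(all(sw$x == 0.3))
  sw <- iv_sweep(runif(50, -0.019, 0.019), 1e-3, dp, device_state(0.3, dp))
  expect_true(all(sw$x == 0.3))
  # symmetric sine: current vanishes whenever the voltage does (pinched)
  tt <- seq(0, 2 * pi, length.out = 201)
  sw <- iv_sweep(0.2 * sin(tt), 1e-3, dp, device_state(0.2, dp))
  expect_true(all(abs(sw$i[sw$v == 0]) == 0))
  expect_true(all(sw$x >= 0 & sw$x <= 1))
  expect_named(sw, c("t", "v", "i", "x", "r"))
})
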