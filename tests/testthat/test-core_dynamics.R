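# Single-unit dynamics: leaky integrator, adaptive photoreceptor,
# rectification, delay line, Euler stepping.

test_that("leaky integrator follows its defining update and fixed point", {
  # single Euler step of da/dt = (-0 + 1)/1 over 0.1 ms
  st <- step_lin(lin_state(tau = 1), input_sum = 1, dt = 0.1)
  expect_equal(st$a, 0.1)

  # fixed point: constant input 0.7 for any tau
  for (tau in c(1, 5, 100)) {
    a <- run_lin(rep(0.7, 20000), tau, dt = 0.1)
    expect_equal(a[length(a)], 0.7, tolerance = 1e-6)
  }

  # free decay from a = 1 with tau = 5 ms reaches e^-1 after 5 ms
  a <- run_lin(rep(0, 50), tau = 5, dt = 0.1, a0 = 1)
  expect_lt(abs(a[50] - exp(-1)), 0.01)

  expect_error(step_lin(lin_state(5), 0, dt = 0), "dt")
  expect_error(lin_state(tau = -1), "tau")
  expect_warning(step_lin(lin_state(tau = 0.05), 0, dt = 0.1), "unstable")
})

test_that("run_lin is step-equivalent to looping step_lin", {
  set.seed(42)
  x <- runif(30)
  st <- lin_state(tau = 3, a = 0.2)
  loop <- numeric(30)
  for (i in seq_along(x)) {
    st <- step_lin(st, x[i], dt = 0.1)
    loop[i] <- st$a
  }
  expect_equal(run_lin(x, 3, 0.1, a0 = 0.2), loop)
})

test_that("the leaky integrator is a linear filter", {
  set.seed(7)
  x1 <- runif(500); x2 <- runif(500)
  a <- 1.7; b <- -0.4
  resp <- function(x) run_lin(x, tau = 5, dt = 0.1)
  expect_equal(resp(a * x1 + b * x2), a * resp(x1) + b * resp(x2),
               tolerance = 1e-12)
})

test_that("adaptive photoreceptor is a pure change detector", {
  # constant input: adaptation converges to the input, output to zero
  st <- adaptive_lin_state()
  for (i in 1:50000) st <- step_adaptive_lin(st, 0.5, 0.1)
  expect_equal(st$alpha, 0.5, tolerance = 1e-6)
  expect_equal(st$a_pr, 0, tolerance = 1e-6)

  # zero DC gain: mean output over the last second of a 5 s constant run
  a <- run_adaptive_lin(rep(0.8, 50000), dt = 0.1)
  expect_lt(abs(mean(a[40001:50000])), 1e-3)

  # onset 0 -> 1: positive transient then decay; offset 1 -> 0: negative
  a_on <- run_adaptive_lin(rep(1, 2000), dt = 0.1)
  expect_gt(max(a_on), 0.1)
  expect_lt(a_on[2000], max(a_on) / 2)
  a_off <- run_adaptive_lin(c(rep(1, 5000), rep(0, 2000)), dt = 0.1)
  expect_lt(min(a_off[5001:7000]), -0.1)
})

test_that("adaptive step response matches a dense-step reference within 2%", {
  # reference solution of the same ODEs at dt = 0.001 ms
  ref <- run_adaptive_lin(rep(1, 30000), dt = 0.001)
  coarse <- run_adaptive_lin(rep(1, 300), dt = 0.1)
  expect_equal(max(coarse), max(ref), tolerance = 0.02)
  t_peak_coarse <- which.max(coarse) * 0.1
  t_peak_ref <- which.max(ref) * 0.001
  expect_equal(t_peak_coarse, t_peak_ref, tolerance = 0.02)
})

test_that("rectification modes implement their definitions", {
  expect_equal(rectify(-0.3, "offset_only"), 0.3)
  expect_equal(rectify(0.3, "offset_only"), 0)
  expect_equal(rectify(-0.3, "full"), 0.3)
  expect_equal(rectify(-0.3, "none"), -0.3)
  expect_equal(rectify(0.3, "onset_only"), 0.3)
  expect_equal(rectify(-0.3, "onset_only"), 0)
  # vectorised over matrices without dropping shape
  m <- matrix(c(-1, 2, -3, 4), 2)
  expect_identical(dim(rectify(m, "offset_only")), dim(m))
  expect_error(rectify(1, "sideways"))
})

test_that("delay line is sample-exact", {
  # impulse in, impulse out 50 steps later (5 ms at 0.1 ms)
  dl <- delay_line(5, 0.1)
  out <- numeric(60)
  x <- c(1, rep(0, 59))
  for (i in 1:60) {
    r <- step_delay_line(dl, x[i]); dl <- r$line; out[i] <- r$out
  }
  expect_equal(which(out == 1), 51L)  # emitted on the step after 50 delays

  # zero delay is the identity
  dl0 <- delay_line(0, 0.1)
  expect_equal(step_delay_line(dl0, 0.7)$out, 0.7)

  # sinusoid is phase-shifted by exactly d, sample for sample
  tt <- (0:999) * 0.1
  x <- sin(2 * pi * tt / 7)
  shifted <- delay_series(x, 150)  # 15 ms at 0.1 ms
  dl <- delay_line(15, 0.1)
  out <- numeric(1000)
  for (i in 1:1000) {
    r <- step_delay_line(dl, x[i]); dl <- r$line; out[i] <- r$out
  }
  expect_identical(out, shifted)

  expect_warning(delay_line(5.03, 0.1), "rounded")
})

test_that("halving dt changes a 2 s trajectory by under 1%", {
  tt1 <- (0:19999) * 0.1 / 1000
  tt2 <- (0:39999) * 0.05 / 1000
  x1 <- 0.5 + 0.4 * sin(2 * pi * 3 * tt1)
  x2 <- 0.5 + 0.4 * sin(2 * pi * 3 * tt2)
  a1 <- run_lin(x1, tau = 15, dt = 0.1)
  a2 <- run_lin(x2, tau = 15, dt = 0.05)
  expect_equal(a1[20000], a2[40000], tolerance = 0.01)
})
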