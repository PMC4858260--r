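# Detector assembly: single AVDU, arrays, floored ratio readout, and the
# equivalence of the three implementations (per-step R, vectorised R,
# compiled).

test_that("constant equal luminance silences the detector", {
  p <- avdu_params()
  st <- avdu_state(p)
  r <- NULL
  for (i in 1:10000) {
    r <- step_avdu(st, 0.7, 0.7)
    st <- r$state
  }
  expect_lt(abs(r$fast_out), 1e-3)
  expect_lt(abs(r$slow_out), 1e-3)
})

test_that("mirroring the stimulus flips the sign of a fully opponent AVDU", {
  p <- avdu_params(f_reg = 1, rect_mode = "none", input_stage = "bypass")
  tt <- (0:4999) * 0.1 / 1000
  a <- 0.5 + 0.3 * sin(2 * pi * 8 * tt)
  b <- 0.5 + 0.3 * sin(2 * pi * 8 * tt - pi / 3)
  fwd <- run_avdu_array_ref(cbind(a, b), 1, 2, p)
  mir <- run_avdu_array_ref(cbind(b, a), 1, 2, p)
  expect_lt(max(abs(fwd$mean_fast + mir$mean_fast)), 1e-6)
  expect_lt(max(abs(fwd$mean_slow + mir$mean_slow)), 1e-6)
})

test_that("simplified linear RHD matches the closed-form correlator mean", {
  # fixed delays, adaptive stage bypassed, no rectification, F = 1:
  # the subunit is an ideal correlator of two tau_b-filtered sinusoids, so
  # its time-averaged output is amp^2 g^2 sin(w d) sin(dphi)
  d1 <- 5; d2 <- 25
  p <- avdu_params(delay_mode = "fixed", d1 = d1, d2 = d2, f_reg = 1,
                   rect_mode = "none", input_stage = "bypass")
  f <- 10                       # Hz
  dphi <- pi / 3                # spatial phase offset between the two inputs
  amp <- 0.25
  tt <- (0:29999) * 0.1 / 1000  # 3 s at 0.1 ms
  lum_from <- 0.5 + amp * sin(2 * pi * f * tt)
  lum_to <- 0.5 + amp * sin(2 * pi * f * tt - dphi)
  out <- run_avdu_array_ref(cbind(lum_from, lum_to), 1, 2, p)
  # average over whole periods after transients: 2.0 s to 3.0 s
  win <- tt >= 2 & tt < 3
  g2 <- 1 / (1 + (2 * pi * f * 0.001)^2)  # tau_b = 1 ms, squared gain
  for (d in c(d1, d2)) {
    pred <- amp^2 * g2 * sin(2 * pi * f * d / 1000) * sin(dphi)
    got <- mean(out[[if (d == d1) "mean_fast" else "mean_slow"]][win])
    expect_equal(got, pred, tolerance = 0.05)
  }
})

test_that("the ratio readout divides count-normalised sums with a floored denominator", {
  # the division rule itself
  floored_ratio <- function(num, den, floor = 0.01) num / pmax(den, floor)
  expect_equal(floored_ratio(0, 0), 0)            # 0 / 0.01
  expect_equal(floored_ratio(0.02, 0.005), 2.0)   # floor active
  expect_equal(floored_ratio(0.02, 0.04), 0.5)    # plain division

  # and the array honours it step for step (single AVDU, so sums are means)
  set.seed(11)
  p <- avdu_params()
  lum <- matrix(runif(4000), 2000, 2)
  out <- run_avdu_array(lum, 1, 2, p)
  expect_equal(out$ratio, floored_ratio(out$sum_fast, out$sum_slow,
                                        p$denom_floor))
  expect_true(any(out$sum_slow < p$denom_floor))  # the floor was exercised

  # all-zero input: ratio pinned at 0, S stays 0
  z <- run_avdu_array(matrix(0, 100, 2), 1, 2, p)
  expect_true(all(z$ratio == 0) && all(z$S == 0))
})

test_that("compiled, vectorised-R and per-step-R paths agree exactly", {
  set.seed(3)
  lum <- matrix(runif(400 * 5), 400, 5)
  from <- 1:4; to <- 2:5
  variants <- list(
    avdu_params(),
    avdu_params(delay_mode = "fixed", d1 = 2, d2 = 15),
    avdu_params(rect_mode = "none", input_stage = "bypass", f_reg = 1),
    avdu_params(ratio_order = "smooth_then_divide"),
    avdu_params(rect_mode = "full", f_reg = 0.5))
  for (p in variants) {
    a <- run_avdu_array(lum, from, to, p, backend = "cpp")
    b <- run_avdu_array(lum, from, to, p, backend = "ref")
    expect_equal(a$S, b$S, tolerance = 1e-12)
    expect_equal(a$mean_fast, b$mean_fast, tolerance = 1e-12)
    expect_equal(a$sum_slow, b$sum_slow, tolerance = 1e-12)
  }
  # per-step state machine against the vectorised pipeline
  p <- avdu_params(delay_mode = "fixed", d1 = 1, d2 = 3)
  st <- array_state(p, 5, from, to)
  s_loop <- numeric(100)
  for (i in 1:100) {
    r <- step_array(st, lum[i, ]); st <- r$state; s_loop[i] <- r$sums$S
  }
  expect_equal(s_loop, run_avdu_array_ref(lum[1:100, ], from, to, p)$S)
})

test_that("subunit probes behave like optomotor detectors", {
  p <- avdu_params()
  # static grating: both probes silent after adaptation
  r0 <- quick_response(p, 19, 0)
  expect_lt(abs(r0[["fast"]]), 1e-3)
  expect_lt(abs(r0[["slow"]]), 1e-3)

  # equal arms: identical subcircuits give identical probes
  pe <- avdu_params(tau1 = 15, tau2 = 15)
  re <- quick_response(pe, 19, 100)
  expect_equal(re[["fast"]], re[["slow"]], tolerance = 1e-10)

  # the 15 ms arm rolls off: 10 Hz beats 100 Hz
  r10 <- quick_response(p, 19, 10 * 19)
  r100 <- quick_response(p, 19, 100 * 19)
  expect_gt(r10[["slow"]], r100[["slow"]])
})

test_that("reversing the stimulus suppresses both subunit responses", {
  # the correlator subunits are direction selective at the optomotor level:
  # anti-preferred motion reduces each subunit's population response (the
  # behaviour of the fast/slow *ratio* under reversal is reported by
  # invariance_report and discussed in the vignette)
  p <- avdu_params()
  fwd <- quick_response(p, 38, 100)
  rev <- quick_response(p, 38, -100)
  expect_gt(fwd[["fast"]], 0)
  expect_lt(rev[["fast"]], fwd[["fast"]])
  expect_lt(rev[["slow"]], fwd[["slow"]])
})

test_that("parameter validation enforces the fast-numerator convention", {
  expect_error(avdu_params(tau1 = 20, tau2 = 15), "numerator")
  expect_error(avdu_params(delay_mode = "fixed", d1 = 20, d2 = 15), "numerator")
  expect_error(avdu_params(f_reg = 1.5), "f_reg")
  expect_error(avdu_params(denom_floor = 0), "denom_floor")
  expect_silent(avdu_params(tau1 = 15, tau2 = 15))  # equal-delay limit allowed
})
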