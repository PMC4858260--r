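# Measurement protocols and curve fitting.

test_that("measure_response is silent for blank stimuli and deterministic", {
  p <- avdu_params()
  sys <- build_test_system(p)
  g0 <- grating("square", 38, 100, contrast = 0)
  expect_lt(abs(measure_response(sys, g0, duration = 1, window = 0.5)[["S"]]),
            1e-3)
  g <- grating("square", 38, 100)
  a <- measure_response(sys, g, duration = 1, window = 0.5)
  b <- measure_response(sys, g, duration = 1, window = 0.5)
  expect_identical(a, b)
})

test_that("the 2-s protocol reaches steady state", {
  p <- avdu_params()
  sys <- build_test_system(p)
  g <- grating("square", 38, 150)
  s2 <- measure_response(sys, g, duration = 2, window = 1)[["S"]]
  s4 <- measure_response(sys, g, duration = 4, window = 1)[["S"]]
  expect_equal(s2, s4, tolerance = 0.02)
})

test_that("fit_forms recovers exact generating forms with adjusted R2 = 1", {
  # suppressWarnings: lm warns about "essentially perfect fit" on exact data
  x <- 10^seq(1, 3, length.out = 10)
  flog <- suppressWarnings(fit_forms(data.frame(x = x, y = 2 + 3 * log(x))))
  expect_equal(flog$best, "logarithmic")
  expect_equal(flog$table$adj_r_squared[flog$table$form == "logarithmic"], 1)

  flin <- suppressWarnings(fit_forms(data.frame(x = x, y = 1 + 0.01 * x)))
  expect_equal(flin$best, "linear")
  expect_equal(flin$table$adj_r_squared[flin$table$form == "linear"], 1)

  fexp <- suppressWarnings(
    fit_forms(data.frame(x = seq(1, 10), y = 0.5 * exp(0.3 * seq(1, 10)))))
  expect_equal(fexp$best, "exponential")

  # exponential unavailable when responses are non-positive
  fneg <- suppressWarnings(
    fit_forms(data.frame(x = x, y = seq(-10, -1, length.out = 10))))
  expect_false(fneg$table$available[fneg$table$form == "exponential"])
  expect_error(fit_forms(data.frame(x = 1:3, y = 1:3)), "4 points")
})

test_that("log fit matches a hand-built normal-equations oracle on noisy data", {
  set.seed(99)
  x <- 10^seq(1, 3, length.out = 10)
  y <- 2 + 3 * log(x) + rnorm(10, sd = 0.1)
  f <- fit_forms(data.frame(x = x, y = y))
  # independent OLS: beta = (X'X)^-1 X'y
  X <- cbind(1, log(x))
  beta <- solve(t(X) %*% X, t(X) %*% y)
  got <- coef(f, "logarithmic")
  expect_equal(unname(got), as.numeric(beta), tolerance = 1e-10)
  se <- sqrt(diag(solve(t(X) %*% X)) *
               sum((y - X %*% beta)^2) / (length(x) - 2))
  expect_true(all(abs(as.numeric(beta) - c(2, 3)) < 3 * se))
})

test_that("nonlinear exponential refinement is available on request", {
  x <- seq(1, 10)
  y <- 0.5 * exp(0.3 * x) * exp(rnorm(10, sd = 0.01))
  f <- fit_forms(data.frame(x = x, y = y), nls_exp = TRUE)
  expect_s3_class(f$fits$exponential_nls, "nls")
  expect_equal(unname(coef(f$fits$exponential_nls)), c(0.5, 0.3),
               tolerance = 0.05)
})

test_that("grid constructors give the documented density and limits", {
  g <- av_grid()
  expect_equal(range(g), c(10, 1000))
  expect_gte(length(g), 21)
  expect_true(all(diff(g) > 0))
  tg <- tf_grid()
  expect_equal(range(tg), c(0.25, 100))
  expect_gte(length(tg), 27)
})

test_that("response curve bookkeeping: peaks and ordering helpers", {
  curve <- data.frame(wavelength = rep(c(11, 19), each = 3),
                      tf = rep(c(1, 10, 100), 2),
                      fast = c(0.1, 0.9, 0.2, 0.2, 0.8, 0.1),
                      slow = c(0.1, 0.5, 0.9, 0.3, 0.2, 0.1))
  class(curve) <- c("avdu_response_curve", "data.frame")
  attr(curve, "kind") <- "temporal_frequency"
  pk <- peak_frequency(curve, "fast")
  expect_equal(unname(pk), c(10, 10))
  expect_equal(unname(peak_frequency(curve, "slow")), c(100, 1))
})

test_that("delay-pair ordering: closer time constants give flatter AV tuning", {
  # scaled-down sweep (shortened protocol, 6 points): the 10/15 ms pair is
  # flatter than the tuned 5/15 ms pair, and both rise with AV overall
  grid <- av_grid(per_decade = 2.5)
  sweep_s <- function(p) vapply(grid, function(av)
    quick_response(p, 38, av)[["S"]], numeric(1))
  s_tuned <- sweep_s(avdu_params(tau1 = 5, tau2 = 15))
  s_close <- sweep_s(avdu_params(tau1 = 10, tau2 = 15))
  slope <- function(s) unname(coef(stats::lm(s ~ log10(grid)))[2])
  expect_lt(slope(s_close), slope(s_tuned))
  expect_gt(s_tuned[length(grid)], s_tuned[1])
  expect_gt(s_close[length(grid)], s_close[1])
})

test_that("the command-line driver writes tables and a JSON summary", {
  out <- file.path(tempdir(), "avdu-cli-test")
  cfg <- file.path(tempdir(), "cfg.json")
  jsonlite::write_json(list(constant_freqs = 0.15, variable_freqs = 0.1,
                            f_values = 0.25, duration = 1, window = 0.5,
                            detector = list(tau1 = 5, tau2 = 15)),
                       cfg, auto_unbox = TRUE)
  suppressMessages(avdu_cli(c("corridor-1a", "--config", cfg, "--out", out)))
  expect_true(file.exists(file.path(out, "experiment_1a.csv")))
  smry <- jsonlite::fromJSON(file.path(out, "summary.json"))
  expect_true("assessment" %in% names(smry))
  tab <- utils::read.csv(file.path(out, "experiment_1a.csv"))
  expect_equal(nrow(tab), 1L)
  expect_error(avdu_cli(character(0)), "usage")
  expect_error(avdu_cli("no-such-command"), "usage")
})

test_that("configuration files map onto parameter objects", {
  cfg <- file.path(tempdir(), "cfg2.json")
  jsonlite::write_json(list(detector = list(delay_mode = "fixed", d1 = 2,
                                            d2 = 15, f_reg = 0),
                            controller = list(t_x = 1.2, control_dt = 20),
                            duration = 3),
                       cfg, auto_unbox = TRUE)
  conf <- read_avdu_config(cfg)
  expect_s3_class(conf$params, "avdu_params")
  expect_equal(conf$params$delay_mode, "fixed")
  expect_equal(conf$params$f_reg, 0)
  expect_s3_class(conf$controller, "controller_params")
  expect_equal(conf$controller$t_x, 1.2)
  expect_equal(conf$duration, 3)
})
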