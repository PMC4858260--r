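# AVDU assembly: photoreceptor stage -> rectifier -> per-location direct and
# delayed channels -> per-pair correlation (progressive - F * regressive,
# filtered by a tau_R LIN) -> array sums -> floored ratio -> tau_S smoothing.
#
# Two step-equivalent implementations exist: a per-step R state machine
# (array_state / step_array, also backing the single-unit step_avdu) and a
# vectorised whole-run pipeline (run_avdu_array_ref) built from recursive
# filters. The compiled runner in src/ must agree with both; tests hold it to
# that.

lam_of <- function(params, tau, dt) if (params$tau_divisor) dt / tau else dt * tau

#' Create the state of an AVDU array
#'
#' An array is a set of AVDUs over `n_loc` visual locations, wired by index
#' pairs `from -> to` where `to` is the location reached by motion in the
#' preferred direction. Neighbouring AVDUs share photoreceptor and channel
#' states per location; each AVDU owns its two subunit subtraction LINs, and
#' the array owns one smoothing LIN.
#'
#' @param params An [avdu_params()] object.
#' @param n_loc Number of visual input locations.
#' @param from,to Integer vectors of equal length wiring each AVDU's input
#'   pair (1-based location indices; preferred motion runs from `from` to
#'   `to`).
#' @param dt Simulation step in ms (default 0.1), fixed at creation because
#'   fixed-mode delay buffers are sample-aligned.
#' @return An object of class `avdu_array_state`.
#' @export
array_state <- function(params, n_loc, from, to, dt = 0.1) {
  stopifnot(inherits(params, "avdu_params"))
  from <- as.integer(from); to <- as.integer(to)
  if (length(from) != length(to))
    stop("`from` and `to` must have equal length")
  if (length(from) && (min(from, to) < 1L || max(from, to) > n_loc))
    stop("wiring indices out of range")
  st <- list(params = params, n_loc = as.integer(n_loc), from = from, to = to,
             dt = dt,
             a_pr = numeric(n_loc), alpha = numeric(n_loc),
             dir = numeric(n_loc),
             del1 = numeric(n_loc), del2 = numeric(n_loc),
             r1 = numeric(length(from)), r2 = numeric(length(from)),
             s = 0, s_fast = 0, s_slow = 0)
  if (params$delay_mode == "fixed") {
    k <- delay_steps(params, dt)
    st$k1 <- k[1]; st$k2 <- k[2]
    st$buf1 <- matrix(0, max(k[1], 1L), n_loc)
    st$buf2 <- matrix(0, max(k[2], 1L), n_loc)
    st$pos1 <- 1L; st$pos2 <- 1L
  }
  structure(st, class = "avdu_array_state")
}

#' Advance an AVDU array by one simulation step
#'
#' @param state An [array_state()].
#' @param frame Numeric vector of luminances, one per location, in `[0, 1]`.
#' @param dt Step size in ms; must match the step the state was built with.
#' @return A list with the updated `state` and `sums`, a list holding the
#'   instantaneous array sums `sum_fast` and `sum_slow`, the floored ratio
#'   `ratio = sum_fast / max(sum_slow, denom_floor)`, and the smoothed array
#'   output `S`.
#' @export
step_array <- function(state, frame, dt = state$dt) {
  p <- state$params
  if (length(frame) != state$n_loc)
    stop(sprintf("frame has %d samples but the array expects %d",
                 length(frame), state$n_loc))
  if (abs(dt - state$dt) > 1e-12)
    stop("`dt` differs from the step the array state was built with")
  if (p$input_stage == "adaptive") {
    a_pr <- state$a_pr +
      lam_of(p, p$tau_pr, dt) * (-state$a_pr - state$alpha + frame)
    state$alpha <- state$alpha +
      lam_of(p, p$tau_alpha, dt) * (-state$alpha + frame)
    state$a_pr <- a_pr
    sig <- a_pr
  } else {
    sig <- frame
  }
  rp <- rectify(sig, p$rect_mode)
  state$dir <- state$dir + lam_of(p, p$tau_b, dt) * (-state$dir + rp)
  if (p$delay_mode == "dynamic") {
    state$del1 <- state$del1 + lam_of(p, p$tau1, dt) * (-state$del1 + rp)
    state$del2 <- state$del2 + lam_of(p, p$tau2, dt) * (-state$del2 + rp)
  } else {
    if (state$k1 > 0L) {
      out1 <- state$buf1[state$pos1, ]
      state$buf1[state$pos1, ] <- rp
      state$pos1 <- if (state$pos1 == state$k1) 1L else state$pos1 + 1L
    } else out1 <- rp
    if (state$k2 > 0L) {
      out2 <- state$buf2[state$pos2, ]
      state$buf2[state$pos2, ] <- rp
      state$pos2 <- if (state$pos2 == state$k2) 1L else state$pos2 + 1L
    } else out2 <- rp
    state$del1 <- state$del1 + lam_of(p, p$tau_b, dt) * (-state$del1 + out1)
    state$del2 <- state$del2 + lam_of(p, p$tau_b, dt) * (-state$del2 + out2)
  }
  if (length(state$from)) {
    prog1 <- state$del1[state$from] * state$dir[state$to]
    reg1 <- state$dir[state$from] * state$del1[state$to]
    prog2 <- state$del2[state$from] * state$dir[state$to]
    reg2 <- state$dir[state$from] * state$del2[state$to]
    state$r1 <- state$r1 +
      lam_of(p, p$tau_r, dt) * (-state$r1 + prog1 - p$f_reg * reg1)
    state$r2 <- state$r2 +
      lam_of(p, p$tau_r, dt) * (-state$r2 + prog2 - p$f_reg * reg2)
  }
  sum_fast <- sum(state$r1)
  sum_slow <- sum(state$r2)
  lam_s <- lam_of(p, p$tau_s, dt)
  if (p$ratio_order == "divide_then_smooth") {
    ratio <- sum_fast / max(sum_slow, p$denom_floor)
    state$s <- state$s + lam_s * (-state$s + ratio)
    s_out <- state$s
  } else {
    state$s_fast <- state$s_fast + lam_s * (-state$s_fast + sum_fast)
    state$s_slow <- state$s_slow + lam_s * (-state$s_slow + sum_slow)
    ratio <- state$s_fast / max(state$s_slow, p$denom_floor)
    s_out <- ratio
  }
  list(state = state,
       sums = list(sum_fast = sum_fast, sum_slow = sum_slow,
                   ratio = ratio, S = s_out))
}

#' Mean pre-division subunit outputs of an array
#'
#' Returns the current population means of the fast and slow subunit
#' subtraction LINs, i.e. the correlator responses before the ratio stage.
#' These are the quantities compared against optomotor-neuron tuning curves.
#'
#' @param state An [array_state()], typically after stepping.
#' @return Named numeric vector with `fast` and `slow` means.
#' @export
subunit_probe <- function(state) {
  if (!length(state$r1)) return(c(fast = 0, slow = 0))
  c(fast = mean(state$r1), slow = mean(state$r2))
}

#' Create the state of a single AVDU
#'
#' Convenience two-location array: one detector over one input pair, with
#' preferred motion from the left (first) to the right (second) input.
#'
#' @inheritParams array_state
#' @return An `avdu_array_state` with two locations and one detector.
#' @export
avdu_state <- function(params, dt = 0.1) {
  array_state(params, n_loc = 2L, from = 1L, to = 2L, dt = dt)
}

#' Advance a single AVDU by one simulation step
#'
#' @param state State from [avdu_state()].
#' @param lum_left,lum_right Luminances in `[0, 1]` at the two input
#'   locations (preferred motion runs left to right).
#' @param dt Step size in ms.
#' @return A list with the updated `state` and the two subunit outputs
#'   `fast_out` and `slow_out` (the tau_R-filtered correlator responses).
#' @export
step_avdu <- function(state, lum_left, lum_right, dt = state$dt) {
  res <- step_array(state, c(lum_left, lum_right), dt)
  list(state = res$state, fast_out = res$state$r1[1], slow_out = res$state$r2[1])
}

#' Run an AVDU array over a luminance movie (reference implementation)
#'
#' Vectorised whole-run pipeline, step-equivalent to looping [step_array()]:
#' every stage is a recursive filter over the full time series. Pure R and
#' independent of the compiled runner, so it serves as the oracle the
#' compiled path is tested against.
#'
#' @param lum Numeric matrix of luminances, one row per step, one column per
#'   location.
#' @param from,to Wiring as in [array_state()].
#' @param params An [avdu_params()].
#' @param dt Step size in ms (default 0.1).
#' @return A data frame with one row per step: `sum_fast`, `sum_slow`,
#'   `ratio`, `S`, and the pre-division population means `mean_fast`,
#'   `mean_slow`.
#' @export
run_avdu_array_ref <- function(lum, from, to, params, dt = 0.1) {
  stopifnot(is.matrix(lum), inherits(params, "avdu_params"))
  n <- nrow(lum)
  sig <- if (params$input_stage == "adaptive") {
    run_adaptive_lin(lum, params$tau_pr, params$tau_alpha, dt)
  } else lum
  rp <- rectify(sig, params$rect_mode)
  dir <- run_lin(rp, params$tau_b, dt)
  if (params$delay_mode == "dynamic") {
    del1 <- run_lin(rp, params$tau1, dt)
    del2 <- run_lin(rp, params$tau2, dt)
  } else {
    k <- delay_steps(params, dt)
    del1 <- run_lin(delay_series(rp, k[1]), params$tau_b, dt)
    del2 <- run_lin(delay_series(rp, k[2]), params$tau_b, dt)
  }
  drive1 <- del1[, from, drop = FALSE] * dir[, to, drop = FALSE] -
    params$f_reg * dir[, from, drop = FALSE] * del1[, to, drop = FALSE]
  drive2 <- del2[, from, drop = FALSE] * dir[, to, drop = FALSE] -
    params$f_reg * dir[, from, drop = FALSE] * del2[, to, drop = FALSE]
  r1 <- run_lin(drive1, params$tau_r, dt)
  r2 <- run_lin(drive2, params$tau_r, dt)
  sum_fast <- rowSums(r1)
  sum_slow <- rowSums(r2)
  if (params$ratio_order == "divide_then_smooth") {
    ratio <- sum_fast / pmax(sum_slow, params$denom_floor)
    s <- run_lin(ratio, params$tau_s, dt)
  } else {
    sf <- run_lin(sum_fast, params$tau_s, dt)
    ss <- run_lin(sum_slow, params$tau_s, dt)
    ratio <- sf / pmax(ss, params$denom_floor)
    s <- ratio
  }
  data.frame(t = (seq_len(n) - 1) * dt, sum_fast = sum_fast,
             sum_slow = sum_slow, ratio = ratio, S = s,
             mean_fast = rowMeans(r1), mean_slow = rowMeans(r2))
}

#' Run an AVDU array over a luminance movie
#'
#' Main entry point: identical contract to [run_avdu_array_ref()] but backed
#' by the compiled stepper, which is orders of magnitude faster and is the
#' engine behind all sweep and experiment drivers.
#'
#' @inheritParams run_avdu_array_ref
#' @param backend `"cpp"` (default) or `"ref"` for the pure-R pipeline.
#' @return See [run_avdu_array_ref()].
#' @export
run_avdu_array <- function(lum, from, to, params, dt = 0.1,
                           backend = c("cpp", "ref")) {
  backend <- match.arg(backend)
  if (backend == "ref") return(run_avdu_array_ref(lum, from, to, params, dt))
  stopifnot(is.matrix(lum), inherits(params, "avdu_params"))
  if (length(from) != length(to)) stop("`from`/`to` length mismatch")
  if (length(from) && (min(from, to) < 1L || max(from, to) > ncol(lum)))
    stop("wiring indices out of range")
  if (params$delay_mode == "fixed") delay_steps(params, dt)  # warn on rounding
  out <- cpp_run_array(lum, as.integer(from) - 1L, as.integer(to) - 1L,
                       params_for_cpp(params, dt), dt)
  data.frame(t = (seq_len(nrow(lum)) - 1) * dt, out)
}

# Flatten avdu_params into the numeric/flag list the compiled code expects.
params_for_cpp <- function(params, dt) {
  k <- if (params$delay_mode == "fixed") {
    c(round(params$d1 / dt), round(params$d2 / dt))
  } else c(0, 0)
  list(dynamic = params$delay_mode == "dynamic",
       tau1 = params$tau1, tau2 = params$tau2,
       k1 = as.integer(k[1]), k2 = as.integer(k[2]),
       f_reg = params$f_reg, tau_b = params$tau_b, tau_r = params$tau_r,
       tau_s = params$tau_s, tau_pr = params$tau_pr,
       tau_alpha = params$tau_alpha, denom_floor = params$denom_floor,
       rect = match(params$rect_mode,
                    c("none", "onset_only", "offset_only", "full")) - 1L,
       adaptive = params$input_stage == "adaptive",
       divide_first = params$ratio_order == "divide_then_smooth",
       tau_divisor = params$tau_divisor)
}
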