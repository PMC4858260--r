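# Single-unit dynamics: leaky-integrator neural units (LINs), the adapting
# photoreceptor unit, rectification and fixed delay lines. All time constants
# and dt are in milliseconds; activities are dimensionless. Integration is
# forward Euler; the convention throughout the package is that each stage of a
# feedforward pipeline is updated in order, so a downstream unit sees the
# freshly updated activity of its upstream unit within the same step.

#' Leaky-integrator neural unit state
#'
#' A rate-coded leaky integrator with dynamics `da/dt = (-a + sum(x)) / tau`:
#' the activity `a` integrates its summed input and decays towards it with a
#' single characteristic time constant. This is the only neuron model used by
#' the angular-velocity detector; every filtering, subtraction and smoothing
#' stage is one of these units with a different `tau`.
#'
#' @param tau Time constant in ms (> 0).
#' @param a Initial activity (default 0).
#' @param tau_divisor Interpret `tau` as a divisor of the drive (the default,
#'   so that larger `tau` means slower dynamics). Setting `FALSE` multiplies
#'   the drive by `tau` instead; this alternative reading is provided only for
#'   comparison and is unstable for large `tau` at the default step size.
#' @return An object of class `lin_state`.
#' @seealso [step_lin()], [run_lin()]
#' @export
lin_state <- function(tau, a = 0, tau_divisor = TRUE) {
  if (!is.numeric(tau) || length(tau) != 1L || !is.finite(tau) || tau <= 0)
    stop("`tau` must be a single positive number (ms)")
  structure(list(a = a, tau = tau, tau_divisor = isTRUE(tau_divisor)),
            class = "lin_state")
}

#' Advance a leaky integrator by one Euler step
#'
#' @param state A [lin_state()].
#' @param input_sum Summed input to the unit (dimensionless).
#' @param dt Step size in ms; must satisfy `dt <= tau` for stability.
#' @return The updated `lin_state`; its `$a` is the unit's output.
#' @export
step_lin <- function(state, input_sum, dt) {
  if (!is.numeric(dt) || length(dt) != 1L || !is.finite(dt) || dt <= 0)
    stop("`dt` must be a single positive number (ms)")
  if (state$tau <= 0) stop("`tau` must be positive (ms)")
  if (state$tau_divisor && dt > state$tau)
    warning("dt > tau: explicit Euler step is unstable")
  rate <- if (state$tau_divisor) dt / state$tau else dt * state$tau
  state$a <- state$a + rate * (-state$a + input_sum)
  state
}

#' Run a leaky integrator over an input series
#'
#' Convenience vectorised form of repeated [step_lin()] calls: returns the
#' activity trajectory of a LIN driven by `x[1], x[2], ...` from a zero (or
#' given) initial state. Implemented as a first-order recursive filter, so it
#' is exactly step-equivalent to the loop form.
#'
#' @param x Numeric vector (or one-column-per-unit matrix) of inputs, one per
#'   step.
#' @param tau Time constant in ms.
#' @param dt Step size in ms.
#' @param a0 Initial activity (default 0).
#' @return Numeric vector (or matrix) of activities after each step.
#' @export
run_lin <- function(x, tau, dt, a0 = 0) {
  if (tau <= 0 || dt <= 0) stop("`tau` and `dt` must be positive (ms)")
  lam <- dt / tau
  if (is.matrix(x)) {
    out <- stats::filter(x * lam, 1 - lam, method = "recursive",
                         init = matrix(a0, 1L, ncol(x)))
    matrix(as.numeric(out), nrow(x), ncol(x))
  } else {
    as.numeric(stats::filter(x * lam, 1 - lam, method = "recursive",
                             init = a0))
  }
}

#' Adaptive photoreceptor unit state
#'
#' Models the fast-adapting photoreceptor/laminar stage as a LIN with a
#' subtractive adaptation current:
#' `da_PR/dt = (-a_PR - alpha + x) / tau_PR`,
#' `dalpha/dt = (-alpha + x) / tau_alpha`.
#' Under constant luminance the adaptation `alpha` converges to the input and
#' the output `a_PR` decays to zero, so the unit is a pure luminance-change
#' detector with zero DC gain.
#'
#' @param tau_pr Output time constant in ms (default 8).
#' @param tau_alpha Adaptation time constant in ms (default 15).
#' @param a_pr,alpha Initial output and adaptation state (default 0).
#' @return An object of class `adaptive_lin_state`.
#' @export
adaptive_lin_state <- function(tau_pr = 8, tau_alpha = 15, a_pr = 0,
                               alpha = 0) {
  if (tau_pr <= 0 || tau_alpha <= 0)
    stop("time constants must be positive (ms)")
  structure(list(a_pr = a_pr, alpha = alpha, tau_pr = tau_pr,
                 tau_alpha = tau_alpha),
            class = "adaptive_lin_state")
}

#' Advance an adaptive photoreceptor unit by one Euler step
#'
#' Both equations are stepped simultaneously (each derivative evaluated at the
#' pre-step state).
#'
#' @param state An [adaptive_lin_state()].
#' @param x Input luminance.
#' @param dt Step size in ms.
#' @return The updated state; `$a_pr` is the unit's output.
#' @export
step_adaptive_lin <- function(state, x, dt) {
  if (dt <= 0) stop("`dt` must be positive (ms)")
  a_pr <- state$a_pr + dt / state$tau_pr * (-state$a_pr - state$alpha + x)
  alpha <- state$alpha + dt / state$tau_alpha * (-state$alpha + x)
  state$a_pr <- a_pr
  state$alpha <- alpha
  state
}

#' Run an adaptive photoreceptor unit over an input series
#'
#' Vectorised step-equivalent of repeated [step_adaptive_lin()] calls from a
#' zero initial state.
#'
#' @param x Numeric vector or matrix of luminance inputs, one row per step.
#' @param tau_pr,tau_alpha Time constants in ms.
#' @param dt Step size in ms.
#' @return Output activities `a_pr` after each step (same shape as `x`).
#' @export
run_adaptive_lin <- function(x, tau_pr = 8, tau_alpha = 15, dt = 0.1) {
  # alpha[n] depends only on x; a_pr[n] uses alpha[n-1] (simultaneous update)
  alpha <- run_lin(x, tau_alpha, dt)
  if (is.matrix(x)) {
    alpha_lag <- rbind(0, alpha[-nrow(alpha), , drop = FALSE])
  } else {
    alpha_lag <- c(0, alpha[-length(alpha)])
  }
  run_lin(x - alpha_lag, tau_pr, dt)
}

#' Rectify an activity
#'
#' The adaptive photoreceptor output carries luminance onsets as positive and
#' offsets as negative transients. Neurons downstream of the lamina fire
#' action potentials and cannot carry both signs, so the signal is rectified
#' before it reaches the correlator arms. Four conventions are supported:
#' `"none"` (identity), `"onset_only"` (`max(0, a)`), `"offset_only"`
#' (`max(0, -a)`, the package default further downstream) and `"full"`
#' (`abs(a)`).
#'
#' @param a Numeric activity (vectorised).
#' @param mode One of `"none"`, `"onset_only"`, `"offset_only"`, `"full"`.
#' @return Rectified activity, same shape as `a`.
#' @export
rectify <- function(a, mode) {
  switch(match.arg(mode, c("none", "onset_only", "offset_only", "full")),
         none = a,
         onset_only = pmax(a, 0),
         offset_only = pmax(-a, 0),
         full = abs(a))
}

#' Fixed delay line
#'
#' A sample-aligned delay: the output at step `n` is the input at step
#' `n - round(d / dt)`, with zeros emitted for the first `d` ms. Models a pure
#' axonal propagation delay, which shifts the signal without distorting it.
#'
#' @param d Delay in ms (>= 0).
#' @param dt Simulation step in ms. If `d` is not a multiple of `dt` the
#'   buffer length is rounded with a warning.
#' @return An object of class `delay_line`.
#' @export
delay_line <- function(d, dt) {
  if (d < 0 || dt <= 0) stop("need d >= 0 and dt > 0 (ms)")
  k <- round(d / dt)
  if (abs(d - k * dt) > 1e-9 * max(1, dt))
    warning(sprintf("delay %g ms is not a multiple of dt = %g ms; rounded to %d steps",
                    d, dt, k))
  structure(list(d = d, dt = dt, k = k,
                 buf = if (k > 0) numeric(k) else numeric(0),
                 pos = 1L),
            class = "delay_line")
}

#' Advance a delay line by one step
#'
#' @param line A [delay_line()].
#' @param x Input sample.
#' @return A list with the updated `line` and the delayed `out` sample.
#' @export
step_delay_line <- function(line, x) {
  if (line$k == 0L) return(list(line = line, out = x))
  out <- line$buf[line$pos]
  line$buf[line$pos] <- x
  line$pos <- if (line$pos == line$k) 1L else line$pos + 1L
  list(line = line, out = out)
}

# Shift a series (or each column of a matrix) by k steps, zero-filled: the
# vectorised equivalent of a delay_line over a whole run.
delay_series <- function(x, k) {
  if (k == 0L) return(x)
  if (is.matrix(x)) {
    rbind(matrix(0, k, ncol(x)), x[seq_len(nrow(x) - k), , drop = FALSE])
  } else {
    c(numeric(k), x[seq_len(length(x) - k)])
  }
}
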