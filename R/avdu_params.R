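#' Angular-velocity detector unit (AVDU) parameters
#'
#' One AVDU looks at two neighbouring visual locations through adapting,
#' rectifying photoreceptor units and correlates them twice: once in a "fast"
#' Reichardt-Hassenstein subunit with a short delay and once in a "slow"
#' subunit with a long delay. Across an array the fast and slow subunit
#' outputs are summed separately, and the ratio fast/slow (denominator floored
#' at `denom_floor`) is smoothed by a final LIN to give the AV estimate `S`.
#'
#' The delay in each correlator arm can be implemented two ways:
#' `"dynamic"` uses a LIN with a slow time constant (`tau1`, `tau2`) so the
#' delayed signal is also low-pass distorted, mimicking slow membrane or
#' synaptic dynamics; `"fixed"` uses a pure sample delay (`d1`, `d2`) followed
#' by a fast LIN, mimicking axonal propagation delay. The fast subunit (the
#' smaller delay) is always the numerator of the ratio.
#'
#' @param delay_mode `"dynamic"` (default) or `"fixed"`.
#' @param tau1,tau2 Dynamic-delay time constants in ms (defaults 5 and 15, the
#'   tuned pair); requires `tau1 < tau2`.
#' @param d1,d2 Fixed delays in ms (defaults 2 and 15); requires `d1 < d2`.
#' @param f_reg Scaling `F` of the regressive (anti-preferred) channel before
#'   subtraction, in `[0, 1]`. `F = 1` gives the classical fully
#'   direction-opponent correlator, `F = 0` a half-detector; the default 0.25
#'   trades direction selectivity against spatial-frequency invariance.
#' @param tau_b Base time constant in ms of all otherwise-unspecified LINs
#'   (direct channels, post-delay filters); default 1.
#' @param tau_r Time constant in ms of the per-subunit subtraction LIN
#'   (default 5).
#' @param tau_s Time constant in ms of the final array-level smoothing LIN
#'   (default 100).
#' @param tau_pr,tau_alpha Photoreceptor-stage time constants in ms
#'   (defaults 8 and 15); see [adaptive_lin_state()].
#' @param denom_floor Lower bound applied to the slow-subunit array sum
#'   before the division (default 0.01), standing in for the tonic firing
#'   rate of the denominator neuron; only the denominator is floored, so `S`
#'   may be negative.
#' @param rect_mode Rectification applied to the photoreceptor output before
#'   the correlators; see [rectify()]. Default `"offset_only"`.
#' @param input_stage `"adaptive"` (default) routes luminance through the
#'   adaptive photoreceptor unit; `"bypass"` feeds raw luminance to the
#'   rectifier, which (with `rect_mode = "none"`) reduces each subunit to a
#'   textbook linear correlator for analytic cross-checks.
#' @param ratio_order `"divide_then_smooth"` (default): the instantaneous
#'   ratio of sums drives the final smoothing LIN. The alternative
#'   `"smooth_then_divide"` smooths the two sums first and divides the
#'   smoothed values.
#' @param tau_divisor Time-constant reading; see [lin_state()]. Default TRUE.
#' @return An object of class `avdu_params`.
#' @examples
#' p <- avdu_params()                      # tuned 5/15 ms dynamic detector
#' avdu_params(delay_mode = "fixed", d1 = 2, d2 = 15)
#' @export
avdu_params <- function(delay_mode = c("dynamic", "fixed"),
                        tau1 = 5, tau2 = 15, d1 = 2, d2 = 15,
                        f_reg = 0.25, tau_b = 1, tau_r = 5, tau_s = 100,
                        tau_pr = 8, tau_alpha = 15,
                        denom_floor = 0.01,
                        rect_mode = c("offset_only", "onset_only", "none",
                                      "full"),
                        input_stage = c("adaptive", "bypass"),
                        ratio_order = c("divide_then_smooth",
                                        "smooth_then_divide"),
                        tau_divisor = TRUE) {
  delay_mode <- match.arg(delay_mode)
  rect_mode <- match.arg(rect_mode)
  input_stage <- match.arg(input_stage)
  ratio_order <- match.arg(ratio_order)
  taus <- c(tau1 = tau1, tau2 = tau2, tau_b = tau_b, tau_r = tau_r,
            tau_s = tau_s, tau_pr = tau_pr, tau_alpha = tau_alpha)
  if (any(!is.finite(taus)) || any(taus <= 0))
    stop("all time constants must be positive and finite (ms)")
  if (delay_mode == "dynamic" && tau1 > tau2)
    stop("`tau1` must not exceed `tau2`: the fast subunit is the numerator")
  if (delay_mode == "fixed") {
    if (d1 < 0 || d2 <= 0 || d1 > d2)
      stop("need 0 <= d1 <= d2: the fast subunit is the numerator")
  }
  if (!is.finite(f_reg) || f_reg < 0 || f_reg > 1)
    stop("`f_reg` must lie in [0, 1]")
  if (!is.finite(denom_floor) || denom_floor <= 0)
    stop("`denom_floor` must be positive")
  structure(list(delay_mode = delay_mode, tau1 = tau1, tau2 = tau2,
                 d1 = d1, d2 = d2, f_reg = f_reg, tau_b = tau_b,
                 tau_r = tau_r, tau_s = tau_s, tau_pr = tau_pr,
                 tau_alpha = tau_alpha, denom_floor = denom_floor,
                 rect_mode = rect_mode, input_stage = input_stage,
                 ratio_order = ratio_order,
                 tau_divisor = isTRUE(tau_divisor)),
            class = "avdu_params")
}

#' @export
print.avdu_params <- function(x, ...) {
  cat("Angular-velocity detector unit parameters\n")
  if (x$delay_mode == "dynamic") {
    cat(sprintf("  delay: dynamic, tau1 = %g ms (fast), tau2 = %g ms (slow)\n",
                x$tau1, x$tau2))
  } else {
    cat(sprintf("  delay: fixed, d1 = %g ms (fast), d2 = %g ms (slow)\n",
                x$d1, x$d2))
  }
  cat(sprintf("  F (regressive scaling) = %g, rectification = %s\n",
              x$f_reg, x$rect_mode))
  cat(sprintf("  tau_b = %g, tau_R = %g, tau_S = %g, tau_PR = %g, tau_alpha = %g ms\n",
              x$tau_b, x$tau_r, x$tau_s, x$tau_pr, x$tau_alpha))
  cat(sprintf("  denominator floor = %g, input stage = %s, ratio order = %s\n",
              x$denom_floor, x$input_stage, x$ratio_order))
  invisible(x)
}

# Integer number of buffer steps for the fixed delays at resolution dt.
delay_steps <- function(params, dt) {
  k1 <- round(params$d1 / dt)
  k2 <- round(params$d2 / dt)
  if (abs(params$d1 - k1 * dt) > 1e-9 || abs(params$d2 - k2 * dt) > 1e-9)
    warning("fixed delays are not multiples of dt; rounded to sample alignment")
  c(k1, k2)
}
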