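# Grating stimuli and the flat 100x2 test-system sampling geometry.

#' Moving grating stimulus
#'
#' A square-wave or sinusoidal luminance grating drifting at a signed angular
#' velocity. Luminance at visual angle `theta` and time `t` is
#' `mean * (1 + contrast * w(phi))` with
#' `phi = 2 * pi * (theta - av * t - phase0) / wavelength`; `w` is `sin` for
#' sinusoids and `sign(sin)` for square waves (the bright half-cycle starts at
#' phase 0). With `mean_luminance = 0.5` the output spans `[0, 1]` at full
#' Michelson contrast. The temporal frequency seen at a fixed point is
#' `|av| / wavelength`.
#'
#' @param waveform `"square"` or `"sine"`.
#' @param wavelength Spatial wavelength in degrees (> 0).
#' @param angular_velocity Signed drift rate in deg/s; positive drifts toward
#'   increasing angle.
#' @param contrast Michelson contrast in `[0, 1]`.
#' @param mean_luminance Mean luminance (default 0.5).
#' @param phase0 Phase offset in degrees.
#' @return An object of class `grating`.
#' @export
grating <- function(waveform = c("square", "sine"), wavelength,
                    angular_velocity = 0, contrast = 1,
                    mean_luminance = 0.5, phase0 = 0) {
  waveform <- match.arg(waveform)
  if (!is.finite(wavelength) || wavelength <= 0)
    stop("`wavelength` must be positive (deg)")
  if (contrast < 0 || contrast > 1) stop("`contrast` must lie in [0, 1]")
  if (mean_luminance * (1 + contrast) > 1 + 1e-12 || mean_luminance < 0)
    stop("luminance would leave [0, 1]; lower `mean_luminance` or `contrast`")
  structure(list(waveform = waveform, wavelength = wavelength,
                 angular_velocity = angular_velocity, contrast = contrast,
                 mean_luminance = mean_luminance, phase0 = phase0),
            class = "grating")
}

#' Evaluate a grating's luminance
#'
#' @param g A [grating()].
#' @param angle Visual angle(s) in degrees.
#' @param t Time(s) in seconds (recycled against `angle`).
#' @return Luminance value(s) in `[0, 1]`.
#' @export
grating_luminance <- function(g, angle, t = 0) {
  phi <- 2 * pi * (angle - g$angular_velocity * t - g$phase0) / g$wavelength
  w <- if (g$waveform == "sine") sin(phi) else ifelse(sin(phi) >= 0, 1, -1)
  g$mean_luminance * (1 + g$contrast * w)
}

#' Flat test-system sampling geometry
#'
#' The tuning rig: `n_per_row * n_rows` point receptors on a line grid with
#' fixed angular spacing, rows parallel to the motion axis so every row sees
#' the same stimulus. Detectors sit on adjacent within-row pairs, preferred
#' direction toward increasing angle, giving `n_per_row - 1` AVDUs per row.
#' The default 100 x 2 grid at 2 degree spacing spans a 200 x 4 degree field
#' and carries 198 AVDUs feeding one shared summation stage.
#'
#' @param n_per_row Receptors per row (default 100).
#' @param n_rows Number of rows (default 2).
#' @param spacing Inter-receptor angular spacing in degrees (default 2).
#' @return An object of class `test_array_geometry` with receptor `angles`
#'   (one per location, rows concatenated) and the AVDU wiring.
#' @export
test_array_geometry <- function(n_per_row = 100, n_rows = 2, spacing = 2) {
  if (n_per_row < 2) stop("need at least two receptors per row")
  row_angles <- (seq_len(n_per_row) - 1) * spacing
  from <- to <- integer(0)
  for (r in seq_len(n_rows)) {
    off <- (r - 1L) * n_per_row
    from <- c(from, off + seq_len(n_per_row - 1L))
    to <- c(to, off + seq_len(n_per_row - 1L) + 1L)
  }
  structure(list(n_per_row = as.integer(n_per_row),
                 n_rows = as.integer(n_rows), spacing = spacing,
                 angles = rep(row_angles, n_rows),
                 from = from, to = to,
                 n_avdus = as.integer(n_rows * (n_per_row - 1L))),
            class = "test_array_geometry")
}

#' Sample a grating with the test-array geometry
#'
#' Point-samples the grating at every receptor's angular position; rows are
#' parallel to the motion axis, so rows receive identical samples.
#'
#' @param geom A [test_array_geometry()].
#' @param g A [grating()].
#' @param t Time in seconds (scalar or vector; a vector gives a matrix with
#'   one row per time).
#' @return Luminance vector of length `n_per_row * n_rows`, or a matrix with
#'   one row per element of `t`.
#' @export
sample_test_array <- function(geom, g, t = 0) {
  if (length(t) == 1L) return(grating_luminance(g, geom$angles, t))
  ang <- outer(-g$angular_velocity * t, geom$angles, "+")
  phi <- 2 * pi * (ang - g$phase0) / g$wavelength
  w <- if (g$waveform == "sine") sin(phi) else ifelse(sin(phi) >= 0, 1, -1)
  g$mean_luminance * (1 + g$contrast * w)
}

#' Convert spatial frequencies between bee scale and model scale
#'
#' The simulated eye has about one fifth the angular resolution of the bee
#' eye, so corridor experiments present spatial frequencies five times lower
#' than the bee-scale values quoted for the behavioural literature. This is
#' the single conversion used everywhere.
#'
#' @param f Spatial frequency in cycles/degree.
#' @param direction `"bee_to_model"` (divide by 5) or `"model_to_bee"`
#'   (multiply by 5).
#' @return Converted frequency in cycles/degree.
#' @export
scale_spatial_frequency <- function(f, direction = c("bee_to_model",
                                                     "model_to_bee")) {
  switch(match.arg(direction), bee_to_model = f / 5, model_to_bee = f * 5)
}
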