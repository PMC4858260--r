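# Corridor experiment drivers: centering with unequal walls (1A), square- vs
# sine-wave centering (1B), and visual odometry (2). All wall spatial
# frequencies in these drivers are quoted on the bee scale (c/deg as the bee
# would see them) and converted with scale_spatial_frequency(), since the
# model eye has one fifth the bee's resolution.

default_exp_config <- function() {
  list(width = 20, height = 20, length = 300,
       duration = 5, window = 2,
       start_x = c(-3, 3), start_z = 6, start_v = 40,
       floor_freq = 0.1,              # bee-scale c/deg on the floor
       contrast = 1, dt = 0.1,
       controller = controller_params())
}

merge_config <- function(defaults, config) {
  for (nm in names(config)) defaults[[nm]] <- config[[nm]]
  defaults
}

# Corridor world with the constant pattern on the left wall and the variable
# pattern on the right wall, both specified on the bee scale.
centering_world <- function(cfg, const_freq, var_freq,
                            const_wave = "sine", var_wave = "sine") {
  corridor_world(
    width = cfg$width, height = cfg$height, length = cfg$length,
    left_wall = wall_pattern(const_wave,
                             scale_spatial_frequency(const_freq),
                             contrast = cfg$contrast),
    right_wall = wall_pattern(var_wave,
                              scale_spatial_frequency(var_freq),
                              contrast = cfg$contrast),
    floor = wall_pattern("square", scale_spatial_frequency(cfg$floor_freq),
                         contrast = cfg$contrast))
}

# Mean final-window lateral offset averaged over the two starting positions,
# with the spread across the pair. Positive offsets point toward the
# variable (right) wall.
paired_offset <- function(world, system, cfg) {
  offs <- vapply(cfg$start_x, function(x0) {
    traj <- run_trial(world, system, cfg$controller, duration = cfg$duration,
                      start = bee_pose(x = x0, z = cfg$start_z,
                                       v = cfg$start_v), dt = cfg$dt)
    final_offset(traj, cfg$window)
  }, numeric(1))
  c(offset = mean(offs), spread = diff(range(offs)))
}

#' Corridor-centering experiment with one variable wall
#'
#' One wall (left) holds a constant sinusoidal spatial frequency while the
#' other (right) sweeps a range of sinusoidal frequencies; the mean lateral
#' position over the final seconds of each 5-s flight measures the deviation
#' from perfect centering. Bees drift toward the higher-frequency wall; an
#' AV detector with residual spatial-frequency dependence reproduces the
#' direction and ordering of those deviations. Each condition is run from
#' two starting positions either side of the centre; the model is otherwise
#' deterministic.
#'
#' @param config Named list overriding the defaults: `constant_freqs`
#'   (bee-scale c/deg, default `c(0.15, 0.6)`), `variable_freqs` (default
#'   `c(0.05, 0.1, 0.15, 0.2, 0.3, 0.4, 0.6, 0.8)`), `f_values` (regressive
#'   scalings, default `c(0, 0.25, 0.5)`), `params` (base [avdu_params()]),
#'   corridor dimensions, `duration`, `window`, `start_x`, `start_z`,
#'   `start_v`, `contrast`, `floor_freq`, `controller`, `dt`.
#' @return A data frame of class `avdu_experiment` with one row per
#'   condition: `f_reg`, `constant_freq`, `variable_freq`, `offset` (cm,
#'   positive toward the variable wall), `spread` (between-start range), and
#'   an `assessment` attribute from [assess_centering_pattern()].
#' @export
experiment_1a <- function(config = list()) {
  cfg <- merge_config(c(default_exp_config(),
                        list(constant_freqs = c(0.15, 0.6),
                             variable_freqs = c(0.05, 0.1, 0.15, 0.2, 0.3,
                                                0.4, 0.6, 0.8),
                             f_values = c(0, 0.25, 0.5),
                             params = avdu_params())),
                      config)
  grid <- expand.grid(f_reg = cfg$f_values, constant_freq = cfg$constant_freqs,
                      variable_freq = cfg$variable_freqs)
  rows <- lapply(seq_len(nrow(grid)), function(i) {
    pars <- cfg$params
    pars$f_reg <- grid$f_reg[i]
    system <- build_full_system(pars)
    world <- centering_world(cfg, grid$constant_freq[i], grid$variable_freq[i])
    po <- paired_offset(world, system, cfg)
    cbind(grid[i, , drop = FALSE], offset = po[["offset"]],
          spread = po[["spread"]])
  })
  tab <- do.call(rbind, rows)
  rownames(tab) <- NULL
  attr(tab, "assessment") <- assess_centering_pattern(tab)
  attr(tab, "config") <- cfg
  class(tab) <- c("avdu_experiment", "data.frame")
  tab
}

#' Assess centering deviations by sign and rank
#'
#' Deviation magnitudes in the behavioural literature are figure readings,
#' not numeric targets, so agreement is operationalised scale-free: per
#' regressive-scaling level, (a) the fraction of unequal-wall conditions
#' whose offset points toward the higher-frequency wall, and (b) the
#' Spearman rank correlation between the offsets and the log frequency ratio
#' of the two walls. A level "agrees" when the sign fraction is at least
#' 0.75 and the rank correlation at least 0.8.
#'
#' @param tab An [experiment_1a()]-style data frame with columns `f_reg`,
#'   `constant_freq`, `variable_freq`, `offset`.
#' @param sign_threshold,rank_threshold Agreement thresholds (defaults 0.75
#'   and 0.8).
#' @return Data frame with one row per `f_reg`: `sign_fraction`, `spearman`,
#'   `agrees`.
#' @export
assess_centering_pattern <- function(tab, sign_threshold = 0.75,
                                     rank_threshold = 0.8) {
  res <- lapply(split(tab, tab$f_reg), function(d) {
    uneq <- d$variable_freq != d$constant_freq
    expected <- sign(d$variable_freq - d$constant_freq)
    sign_frac <- mean(sign(d$offset[uneq]) == expected[uneq])
    rho <- stats::cor(d$offset, log(d$variable_freq / d$constant_freq),
                      method = "spearman")
    data.frame(f_reg = d$f_reg[1], sign_fraction = sign_frac, spearman = rho,
               agrees = sign_frac >= sign_threshold && rho >= rank_threshold)
  })
  out <- do.call(rbind, res)
  rownames(out) <- NULL
  out
}

#' Corridor-centering experiment with square- and sine-wave walls
#'
#' The wide-band/narrow-band comparison: the constant (left) wall is always
#' sinusoidal, the variable (right) wall is sinusoidal or square, and both
#' walls take each of two spatial frequencies, giving eight combinations.
#' The square-wave cell at the higher frequency is flagged as the
#' combination known to deviate from the behavioural pattern.
#'
#' @param config As [experiment_1a()]; relevant defaults here are `freqs =
#'   c(0.15, 0.6)` (bee scale) and `f_values = c(0, 0.25)`.
#' @return A data frame of class `avdu_experiment` with columns `f_reg`,
#'   `constant_freq`, `variable_freq`, `variable_waveform`, `offset`,
#'   `spread`, `known_exception`.
#' @export
experiment_1b <- function(config = list()) {
  cfg <- merge_config(c(default_exp_config(),
                        list(freqs = c(0.15, 0.6),
                             f_values = c(0, 0.25),
                             params = avdu_params())),
                      config)
  grid <- expand.grid(f_reg = cfg$f_values, constant_freq = cfg$freqs,
                      variable_freq = cfg$freqs,
                      variable_waveform = c("sine", "square"),
                      stringsAsFactors = FALSE)
  rows <- lapply(seq_len(nrow(grid)), function(i) {
    pars <- cfg$params
    pars$f_reg <- grid$f_reg[i]
    system <- build_full_system(pars)
    world <- centering_world(cfg, grid$constant_freq[i], grid$variable_freq[i],
                             var_wave = grid$variable_waveform[i])
    po <- paired_offset(world, system, cfg)
    cbind(grid[i, , drop = FALSE], offset = po[["offset"]],
          spread = po[["spread"]])
  })
  tab <- do.call(rbind, rows)
  rownames(tab) <- NULL
  tab$known_exception <- tab$variable_waveform == "square" &
    tab$variable_freq == max(cfg$freqs)
  attr(tab, "config") <- cfg
  class(tab) <- c("avdu_experiment", "data.frame")
  tab
}

#' Visual-odometry experiment
#'
#' Flies the model down a corridor with identical square-wave gratings on
#' both walls for 5 s and computes the odometry metric
#' [odometry_metric()] — summed lateral detector output per cm travelled —
#' per wall spatial frequency. A usable visual odometer yields a near
#' constant metric across frequencies.
#'
#' @param config As [experiment_1a()]; relevant defaults here are `freqs =
#'   seq(0.1, 0.8, by = 0.1)` (bee scale) and a single start at the corridor
#'   centre.
#' @return A data frame of class `avdu_experiment` with columns `freq`
#'   (bee-scale c/deg), `d_e` (odometry metric) and `distance` (cm flown).
#' @export
experiment_odometry <- function(config = list()) {
  cfg <- merge_config(c(default_exp_config(),
                        list(freqs = seq(0.1, 0.8, by = 0.1),
                             params = avdu_params())),
                      config)
  system <- build_full_system(cfg$params)
  rows <- lapply(cfg$freqs, function(f) {
    world <- centering_world(cfg, f, f, const_wave = "square",
                             var_wave = "square")
    traj <- run_trial(world, system, cfg$controller, duration = cfg$duration,
                      start = bee_pose(x = 0, z = cfg$start_z,
                                       v = cfg$start_v), dt = cfg$dt)
    data.frame(freq = f, d_e = odometry_metric(traj),
               distance = traj$y[nrow(traj)] - traj$y[1])
  })
  tab <- do.call(rbind, rows)
  attr(tab, "config") <- cfg
  class(tab) <- c("avdu_experiment", "data.frame")
  tab
}

#' @export
print.avdu_experiment <- function(x, ...) {
  print.data.frame(transform(as.data.frame(x)))
  a <- attr(x, "assessment")
  if (!is.null(a)) {
    cat("\nSign/rank agreement with the behavioural deviation pattern:\n")
    print(a)
  }
  invisible(x)
}
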