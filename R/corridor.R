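# The minimal corridor world and the 32x32 ommatidial sampling of it.
# Axes: +x lateral toward the right wall (0 = corridor centre), +y along the
# corridor, +z up (floor at z = 0). The corridor repeats indefinitely along
# y, so trials never run out of pattern.

#' Corridor surface pattern
#'
#' A static grating painted on a corridor wall or floor, varying along the
#' corridor axis. Its spatial frequency is quoted in cycles/degree *as seen
#' from the corridor centre* (model scale; see [scale_spatial_frequency()]
#' for the bee-scale conversion) and is converted to cycles/cm on the surface
#' when the world is built.
#'
#' @param waveform `"square"`, `"sine"` or `"uniform"` (no pattern).
#' @param freq_cpd Spatial frequency in cycles/degree at the corridor centre
#'   (model scale). Ignored for `"uniform"`.
#' @param contrast Michelson contrast in `[0, 1]`.
#' @param mean_luminance Mean luminance (default 0.5).
#' @param phase_cm Pattern phase offset along the corridor in cm.
#' @return An object of class `wall_pattern`.
#' @export
wall_pattern <- function(waveform = c("square", "sine", "uniform"),
                         freq_cpd = 0, contrast = 1, mean_luminance = 0.5,
                         phase_cm = 0) {
  waveform <- match.arg(waveform)
  if (waveform != "uniform" && (!is.finite(freq_cpd) || freq_cpd <= 0))
    stop("`freq_cpd` must be positive for a patterned surface")
  if (contrast < 0 || contrast > 1) stop("`contrast` must lie in [0, 1]")
  structure(list(waveform = waveform, freq_cpd = freq_cpd,
                 contrast = contrast, mean_luminance = mean_luminance,
                 phase_cm = phase_cm),
            class = "wall_pattern")
}

#' Corridor world
#'
#' A box corridor with patterned left/right walls and floor, uniform ceiling
#' and (notional) ends. Surface frequencies are converted from cycles/degree
#' at the corridor centre to cycles/cm using the small-angle relation at the
#' centre-to-surface distance (half the width for walls, half the height for
#' the floor).
#'
#' @param width,height Corridor cross-section in cm (defaults 20 x 20).
#' @param length Corridor length in cm (default 300); cosmetic only, since
#'   patterns repeat along the axis and trials never hit an end wall.
#' @param left_wall,right_wall,floor [wall_pattern()]s. The default floor
#'   carries a 0.02 cycles/degree (model scale) square wave so the ventral
#'   detectors receive optic flow for the height controller.
#' @param ceiling_luminance,end_luminance Luminance of the unpatterned
#'   surfaces (default 0.5).
#' @return An object of class `corridor_world`.
#' @export
corridor_world <- function(width = 20, height = 20, length = 300,
                           left_wall = wall_pattern("square", 0.03),
                           right_wall = wall_pattern("square", 0.03),
                           floor = wall_pattern("square", 0.02),
                           ceiling_luminance = 0.5, end_luminance = 0.5) {
  if (width <= 0 || height <= 0 || length <= 0)
    stop("corridor dimensions must be positive (cm)")
  for (w in list(left_wall, right_wall, floor))
    if (!inherits(w, "wall_pattern")) stop("surfaces must be wall_pattern objects")
  structure(list(width = width, height = height, length = length,
                 left_wall = left_wall, right_wall = right_wall,
                 floor = floor, ceiling_luminance = ceiling_luminance,
                 end_luminance = end_luminance),
            class = "corridor_world")
}

#' Convert a centre-viewed angular frequency to a surface frequency
#'
#' @param freq_cpd Cycles/degree subtended at the viewing distance.
#' @param distance_cm Viewing distance in cm.
#' @return Cycles/cm on the surface.
#' @export
cpd_to_cycles_per_cm <- function(freq_cpd, distance_cm) {
  freq_cpd * (180 / pi) / distance_cm
}

surface_for_cpp <- function(pattern, distance_cm) {
  code <- match(pattern$waveform, c("square", "sine", "uniform")) - 1L
  list(waveform = code,
       freq_cm = if (pattern$waveform == "uniform") 0 else
         cpd_to_cycles_per_cm(pattern$freq_cpd, distance_cm),
       contrast = pattern$contrast, mean = pattern$mean_luminance,
       phase_cm = pattern$phase_cm)
}

world_for_cpp <- function(world) {
  list(width = world$width, height = world$height,
       left = surface_for_cpp(world$left_wall, world$width / 2),
       right = surface_for_cpp(world$right_wall, world$width / 2),
       floor = surface_for_cpp(world$floor, world$height / 2),
       ceiling_luminance = world$ceiling_luminance,
       end_luminance = world$end_luminance)
}

#' Bee pose
#'
#' @param x Lateral position in cm (0 = corridor centre, positive toward the
#'   right wall).
#' @param y Along-corridor position in cm.
#' @param z Height in cm.
#' @param v Forward speed in cm/s (>= 0).
#' @return An object of class `bee_pose`.
#' @export
bee_pose <- function(x = 0, y = 0, z = 6, v = 40) {
  if (v < 0) stop("forward speed must be non-negative")
  structure(list(x = x, y = y, z = z, v = v), class = "bee_pose")
}

#' Ommatidial sampling grid
#'
#' An equirectangular grid of point-sampling ommatidia centred on the flight
#' axis: columns span the horizontal field of view left to right, rows span
#' the vertical field bottom (row 1, looking down) to top. Each ommatidium
#' casts a single ray; no acceptance-function blur is applied.
#'
#' @param n_rows,n_cols Grid size (default 32 x 32).
#' @param hfov,vfov Field of view in degrees (defaults 260 x 180).
#' @return An object of class `ommatidial_grid` with per-row elevations and
#'   per-column azimuths in degrees.
#' @export
ommatidial_grid <- function(n_rows = 32, n_cols = 32, hfov = 260, vfov = 180) {
  structure(list(n_rows = as.integer(n_rows), n_cols = as.integer(n_cols),
                 hfov = hfov, vfov = vfov,
                 azimuth = -hfov / 2 + hfov * (seq_len(n_cols) - 0.5) / n_cols,
                 elevation = -vfov / 2 + vfov * (seq_len(n_rows) - 0.5) / n_rows),
            class = "ommatidial_grid")
}

# Unit ray directions (x, y, z) for given (row, col) index pairs.
grid_directions <- function(grid, rows, cols) {
  az <- grid$azimuth[cols] * pi / 180
  el <- grid$elevation[rows] * pi / 180
  cbind(sin(az) * cos(el), cos(az) * cos(el), sin(el))
}

#' Render the corridor onto the ommatidial grid
#'
#' Casts one ray per ommatidium from the bee's position and returns the
#' luminance of the first surface hit. Deterministic: identical pose and
#' world give identical frames.
#'
#' @param world A [corridor_world()].
#' @param pose A [bee_pose()]; a pose outside the corridor volume is clamped
#'   inside with a warning.
#' @param grid An [ommatidial_grid()].
#' @return A numeric `n_rows x n_cols` matrix of luminances in `[0, 1]`;
#'   row 1 is the bottom (most ventral) row, column 1 the leftmost.
#' @export
render_corridor <- function(world, pose, grid = ommatidial_grid()) {
  stopifnot(inherits(world, "corridor_world"), inherits(pose, "bee_pose"))
  hw <- world$width / 2
  if (abs(pose$x) >= hw || pose$z <= 0 || pose$z >= world$height) {
    warning("pose outside the corridor volume; clamped inside")
    pose$x <- min(max(pose$x, -hw + 1e-6), hw - 1e-6)
    pose$z <- min(max(pose$z, 1e-6), world$height - 1e-6)
  }
  idx <- expand.grid(row = seq_len(grid$n_rows), col = seq_len(grid$n_cols))
  dirs <- grid_directions(grid, idx$row, idx$col)
  lum <- cpp_render(dirs, c(pose$x, pose$y, pose$z), world_for_cpp(world))
  matrix(lum, grid$n_rows, grid$n_cols)
}

#' Retinotopic subregion layout of the full system
#'
#' Places the three AVDU arrays on the ommatidial grid: `left` and `right`
#' band across the lateral field with horizontal preferred direction away
#' from the frame centre, and `centre` sits in the ventral field (rows count
#' from the bottom) with downward preferred direction — also away from the
#' centre. Indices are 1-based and inclusive. The defaults give 11 AVDUs per
#' row in the lateral subregions and 5 per column in the centre one.
#'
#' Note the right subregion spans columns 21-32: a 13-column band (20-32)
#' would wire 12 detectors per row, contradicting the 11-per-row count that
#' the layout is defined by, so the 12-column mirror of the left band is
#' used.
#'
#' @param left_rows,left_cols,right_rows,right_cols,centre_rows,centre_cols
#'   Integer index ranges on the grid.
#' @return An object of class `subregion_layout`.
#' @export
subregion_layout <- function(left_rows = 9:14, left_cols = 1:12,
                             right_rows = 9:14, right_cols = 21:32,
                             centre_rows = 1:6, centre_cols = 13:19) {
  cells <- function(rows, cols) {
    as.matrix(expand.grid(row = rows, col = cols))
  }
  a <- cells(left_rows, left_cols)
  b <- cells(right_rows, right_cols)
  cc <- cells(centre_rows, centre_cols)
  key <- function(m) paste(m[, 1], m[, 2])
  if (length(intersect(key(a), key(b))) || length(intersect(key(a), key(cc))) ||
      length(intersect(key(b), key(cc))))
    stop("subregions overlap")
  structure(list(left_rows = left_rows, left_cols = left_cols,
                 right_rows = right_rows, right_cols = right_cols,
                 centre_rows = centre_rows, centre_cols = centre_cols),
            class = "subregion_layout")
}

# Locations and AVDU wiring of one subregion. Returns local (row, col)
# cells, the ray-direction matrix, and from/to local indices oriented along
# the preferred direction.
subregion_wiring <- function(rows, cols, direction, grid) {
  nr <- length(rows); nc <- length(cols)
  loc <- expand.grid(row = rows, col = cols)  # row index varies fastest
  lidx <- function(r, c) match(r, rows) + (match(c, cols) - 1L) * nr
  from <- to <- integer(0)
  if (direction %in% c("left", "right")) {
    for (r in rows) {
      for (j in seq_len(nc - 1L)) {
        if (direction == "left") {  # preferred motion toward smaller columns
          from <- c(from, lidx(r, cols[j + 1L])); to <- c(to, lidx(r, cols[j]))
        } else {
          from <- c(from, lidx(r, cols[j])); to <- c(to, lidx(r, cols[j + 1L]))
        }
      }
    }
  } else {  # "down": preferred motion toward smaller rows (ventral)
    for (c in cols) {
      for (i in seq_len(nr - 1L)) {
        from <- c(from, lidx(rows[i + 1L], c)); to <- c(to, lidx(rows[i], c))
      }
    }
  }
  list(rows = rows, cols = cols,
       dirs = grid_directions(grid, loc$row, loc$col),
       from = from, to = to, n_loc = nrow(loc), n_avdus = length(from))
}

#' Build the flat test system
#'
#' The tuning rig: a detector array over the [test_array_geometry()], all
#' AVDUs sharing one parameter set and one summation/ratio stage.
#'
#' @param params An [avdu_params()].
#' @param geom A [test_array_geometry()].
#' @return An object of class `avdu_test_system` with an `n_avdus` count.
#' @export
build_test_system <- function(params, geom = test_array_geometry()) {
  stopifnot(inherits(params, "avdu_params"),
            inherits(geom, "test_array_geometry"))
  structure(list(params = params, geom = geom, n_avdus = geom$n_avdus,
                 n_per_row = geom$n_per_row - 1L),
            class = "avdu_test_system")
}

#' @export
print.avdu_test_system <- function(x, ...) {
  cat(sprintf("Test system: %d x %d receptor grid (%g deg spacing), %d AVDUs (%d per row)\n",
              x$geom$n_per_row, x$geom$n_rows, x$geom$spacing, x$n_avdus,
              x$n_per_row))
  invisible(x)
}

#' Build the full (corridor) system
#'
#' Wires the three subregion arrays of the [subregion_layout()] onto the
#' ommatidial grid. Each subregion feeds its own summation/ratio/smoothing
#' stage; the three smoothed outputs S_L, S_R, S_C drive the flight
#' controller.
#'
#' @param params An [avdu_params()].
#' @param layout A [subregion_layout()].
#' @param grid An [ommatidial_grid()].
#' @return An object of class `avdu_full_system`.
#' @export
build_full_system <- function(params, layout = subregion_layout(),
                              grid = ommatidial_grid()) {
  stopifnot(inherits(params, "avdu_params"),
            inherits(layout, "subregion_layout"),
            inherits(grid, "ommatidial_grid"))
  subs <- list(
    left = subregion_wiring(layout$left_rows, layout$left_cols, "left", grid),
    right = subregion_wiring(layout$right_rows, layout$right_cols, "right",
                             grid),
    centre = subregion_wiring(layout$centre_rows, layout$centre_cols, "down",
                              grid))
  structure(list(params = params, layout = layout, grid = grid,
                 subregions = subs,
                 n_avdus = vapply(subs, `[[`, 0L, "n_avdus")),
            class = "avdu_full_system")
}

#' @export
print.avdu_full_system <- function(x, ...) {
  cat(sprintf("Full system on a %d x %d ommatidial grid\n",
              x$grid$n_rows, x$grid$n_cols))
  for (nm in names(x$subregions)) {
    s <- x$subregions[[nm]]
    cat(sprintf("  %-6s rows %d-%d, cols %d-%d: %d locations, %d AVDUs\n",
                nm, min(s$rows), max(s$rows), min(s$cols), max(s$cols),
                s$n_loc, s$n_avdus))
  }
  invisible(x)
}
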