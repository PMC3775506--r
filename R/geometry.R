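#' Wrap points onto the unit torus
#'
#' Maps coordinates into `[0, 1)` by taking them modulo 1. The visual space of
#' the model is the unit square with opposite edges identified ("pac-man"
#' topology), so every position-valued quantity passes through this function.
#'
#' @param p Numeric vector (or matrix) of coordinates.
#' @return Object of the same shape with all values in `[0, 1)`.
#' @export
#' @examples
#' wrap_torus(c(-0.1, 0.25, 1.7)) # 0.9 0.25 0.7
wrap_torus <- function(p) {
  p - floor(p)
}

#' Minimal-image displacement on the unit torus
#'
#' Returns the displacement from `a` to `b` using the nearest periodic image,
#' so each component lies in `[-0.5, 0.5)`.
#'
#' @param ax,ay Coordinates of the first point(s).
#' @param bx,by Coordinates of the second point(s). Vectors recycle.
#' @return List with components `dx`, `dy` (displacement a -> b).
#' @export
torus_displacement <- function(ax, ay, bx, by) {
  dx <- wrap_torus(bx - ax + 0.5) - 0.5
  dy <- wrap_torus(by - ay + 0.5) - 0.5
  list(dx = dx, dy = dy)
}

#' Distance between two points on the unit torus
#'
#' Euclidean norm of the minimal-image displacement; the largest possible
#' value on the unit torus is \eqn{\sqrt{2}/2}.
#'
#' @inheritParams torus_displacement
#' @return Numeric vector of distances.
#' @export
torus_distance <- function(ax, ay, bx, by) {
  d <- torus_displacement(ax, ay, bx, by)
  sqrt(d$dx^2 + d$dy^2)
}

#' Specification of the retinotopic tuning lattice
#'
#' Describes the lattice of receptive-field centers and preferred velocities
#' from which a population's tuning properties are assembled: `n_cells`
#' hexagonal grid cells, each holding `n_speeds` log-spaced speeds crossed
#' with `n_angles` uniformly spaced directions, plus Gaussian dispersal.
#'
#' @param n_cells Number of hexagonal grid cells (must factor into a
#'   near-square rows-by-columns layout).
#' @param n_speeds Number of distinct preferred speeds per cell.
#' @param n_angles Number of distinct preferred directions per cell.
#' @param v_min,v_max Smallest and largest preferred speed (space units / s).
#' @param jitter_x Dispersal standard deviation applied to positions
#'   (space units).
#' @param jitter_v Dispersal standard deviation for velocity components,
#'   expressed as a fraction of each neuron's speed.
#' @return Object of class `grid_spec`.
#' @export
grid_spec <- function(n_cells = 100L, n_speeds = 10L, n_angles = 10L,
                      v_min = 0.1, v_max = 4.0,
                      jitter_x = 0.01, jitter_v = 0.05) {
  stopifnot(n_cells >= 1, n_speeds >= 1, n_angles >= 1,
            v_min > 0, v_min < v_max, jitter_x >= 0, jitter_v >= 0)
  structure(list(n_cells = as.integer(n_cells),
                 n_speeds = as.integer(n_speeds),
                 n_angles = as.integer(n_angles),
                 v_min = v_min, v_max = v_max,
                 jitter_x = jitter_x, jitter_v = jitter_v),
            class = "grid_spec")
}

# Factor n into rows x cols with rows the largest divisor <= sqrt(n).
hex_grid_dims <- function(n_cells) {
  rows <- floor(sqrt(n_cells))
  while (rows > 1 && n_cells %% rows != 0) rows <- rows - 1
  if (rows == 1 && n_cells > 2) {
    stop("n_cells = ", n_cells,
         " cannot be arranged as a rows x cols offset layout; ",
         "choose a value with a divisor near its square root (e.g. 100 = 10 x 10).")
  }
  c(rows = rows, cols = n_cells %/% rows)
}

#' Hexagonal grid of receptive-field centers on the unit torus
#'
#' Lays `n_cells` centers on an offset (hexagonal) lattice covering the unit
#' square: rows are spaced `1/rows` apart, columns `1/cols`, and every other
#' row is shifted by half a column spacing. Because spacings divide 1, the
#' pattern tiles the torus seamlessly (accepting a slight distortion of the
#' ideal hexagon).
#'
#' @param n_cells Number of grid cells.
#' @return data.frame with columns `x`, `y`, one row per cell, all in `[0,1)`.
#' @export
#' @examples
#' g <- build_hex_grid(100)
#' nrow(g) # 100
build_hex_grid <- function(n_cells) {
  dims <- hex_grid_dims(n_cells)
  rows <- dims[["rows"]]; cols <- dims[["cols"]]
  row_idx <- rep(seq_len(rows), each = cols)
  col_idx <- rep(seq_len(cols), times = rows)
  x <- (col_idx - 0.5) / cols + ifelse(row_idx %% 2 == 0, 0.5 / cols, 0)
  y <- (row_idx - 0.5) / rows
  data.frame(x = wrap_torus(x), y = wrap_torus(y))
}

#' Lattice of preferred velocities
#'
#' Crosses `n_speeds` speeds, log-spaced between `v_min` and `v_max` (equal
#' neuron counts per speed give a density favoring slow motion, consistent
#' with a Weber-law speed scale), with `n_angles` directions uniform on
#' `[0, 2*pi)`.
#'
#' @inheritParams grid_spec
#' @return data.frame with columns `u`, `v` (`n_speeds * n_angles` rows).
#' @export
sample_preferred_velocities <- function(n_speeds, n_angles, v_min = 0.1, v_max = 4.0) {
  if (v_min <= 0) stop("v_min must be > 0: speeds are log-spaced.")
  stopifnot(v_min < v_max, n_speeds >= 1, n_angles >= 1)
  speeds <- if (n_speeds == 1) v_max else
    exp(seq(log(v_min), log(v_max), length.out = n_speeds))
  angles <- seq(0, 2 * pi, length.out = n_angles + 1L)[seq_len(n_angles)]
  grid <- expand.grid(speed = speeds, angle = angles)
  data.frame(u = grid$speed * cos(grid$angle),
             v = grid$speed * sin(grid$angle))
}

#' Assemble a population's tuning-property table
#'
#' Builds the deterministic lattice of (cell position) x (preferred velocity)
#' combinations, assigns combinations to `n_target` neurons round-robin, and
#' disperses each neuron's properties with Gaussian jitter to emulate natural
#' variability. Positions are wrapped back onto the torus; velocity jitter is
#' proportional to each neuron's speed and the resulting speed is capped at
#' `v_max`.
#'
#' If `n_target` exceeds the number of combinations, every combination is used
#' at least once (replicates are jittered independently). If it is smaller,
#' combinations are consumed in cell-fastest order so that spatial coverage
#' stays as even as possible.
#'
#' @param spec A [grid_spec()].
#' @param n_target Number of neurons in the population.
#' @param beta_x,beta_v Tuning widths for space and velocity stored with the
#'   table (shared by all neurons).
#' @return Object of class `tuning_table`: a data.frame with columns
#'   `neuron_id`, `x`, `y`, `u`, `v` and attributes `beta_x`, `beta_v`,
#'   `v_max`.
#' @export
assemble_population <- function(spec, n_target, beta_x = 0.15, beta_v = 0.15) {
  stopifnot(inherits(spec, "grid_spec"), n_target >= 1)
  centers <- build_hex_grid(spec$n_cells)
  vels <- sample_preferred_velocities(spec$n_speeds, spec$n_angles,
                                      spec$v_min, spec$v_max)
  n_combo <- nrow(centers) * nrow(vels)
  # cell index varies fastest so truncation still covers all cells evenly
  cell_i <- rep(seq_len(nrow(centers)), times = nrow(vels))
  vel_i <- rep(seq_len(nrow(vels)), each = nrow(centers))
  pick <- (seq_len(n_target) - 1L) %% n_combo + 1L
  x <- centers$x[cell_i[pick]]
  y <- centers$y[cell_i[pick]]
  u <- vels$u[vel_i[pick]]
  v <- vels$v[vel_i[pick]]
  if (spec$jitter_x > 0) {
    x <- wrap_torus(x + stats::rnorm(n_target, 0, spec$jitter_x))
    y <- wrap_torus(y + stats::rnorm(n_target, 0, spec$jitter_x))
  }
  if (spec$jitter_v > 0) {
    speed <- sqrt(u^2 + v^2)
    u <- u + stats::rnorm(n_target, 0, spec$jitter_v * speed)
    v <- v + stats::rnorm(n_target, 0, spec$jitter_v * speed)
    new_speed <- sqrt(u^2 + v^2)
    over <- new_speed > spec$v_max
    if (any(over)) {
      scale <- spec$v_max / new_speed[over]
      u[over] <- u[over] * scale
      v[over] <- v[over] * scale
    }
  }
  tab <- data.frame(neuron_id = seq_len(n_target), x = x, y = y, u = u, v = v)
  attr(tab, "beta_x") <- beta_x
  attr(tab, "beta_v") <- beta_v
  attr(tab, "v_max") <- spec$v_max
  class(tab) <- c("tuning_table", "data.frame")
  tab
}

#' Validate a tuning-property table
#'
#' Checks the structural invariants: positions in `[0,1)`, strictly positive
#' speeds no larger than `v_max`, positive tuning widths.
#'
#' @param tab A `tuning_table`.
#' @return Invisibly `tab`; stops on violation.
#' @export
validate_tuning <- function(tab) {
  stopifnot(all(c("neuron_id", "x", "y", "u", "v") %in% names(tab)))
  if (any(tab$x < 0 | tab$x >= 1 | tab$y < 0 | tab$y >= 1))
    stop("tuning positions must lie in [0, 1)")
  speed <- sqrt(tab$u^2 + tab$v^2)
  vmax <- attr(tab, "v_max") %||% Inf
  if (any(speed <= 0)) stop("preferred speeds must be strictly positive")
  if (any(speed > vmax + 1e-9)) stop("preferred speeds exceed v_max")
  bx <- attr(tab, "beta_x"); bv <- attr(tab, "beta_v")
  if (!is.null(bx) && bx <= 0) stop("beta_x must be > 0")
  if (!is.null(bv) && bv <= 0) stop("beta_v must be > 0")
  invisible(tab)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# Arithmetic (half-away-from-zero) rounding: in-degrees like round(0.005 * N)
# follow the conventional rule, not banker's rounding.
round_half_up <- function(x) floor(x + 0.5)
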