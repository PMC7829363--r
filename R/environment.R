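# synthetic_env: arenas with holes of known topology, and exploratory
# trajectories emulating non-preferential rodent navigation.

#' Construct a planar arena with holes of known topology
#'
#' The environment is an axis-aligned rectangular arena minus a set of
#' pairwise-disjoint obstacles ("holes"), each an axis-aligned rectangle or a
#' disc lying strictly inside the arena. Because the holes are convex,
#' disjoint and interior, the accessible region is always connected, so the
#' reference Betti numbers are exact by construction:
#' `b0 = 1`, `b1 = number of holes`.
#'
#' @param width,height Arena dimensions in cm.
#' @param holes List of hole specifications. A rectangular hole is
#'   `list(type = "rect", center = c(x, y), width = w, height = h)`; a disc is
#'   `list(type = "disc", center = c(x, y), radius = r)` (all cm).
#' @return An object of class `pc_environment` with fields `width`, `height`,
#'   `holes` and `reference_betti` (named integer vector `b0`, `b1`).
#' @examples
#' env <- make_environment(150, 150,
#'   holes = list(list(type = "rect", center = c(75, 75), width = 40, height = 40)))
#' env$reference_betti
#' @export
make_environment <- function(width, height, holes = list()) {
  stopifnot(is.numeric(width), is.numeric(height), width > 0, height > 0)
  holes <- lapply(holes, normalize_hole)
  for (h in holes) {
    bb <- hole_bbox(h)
    if (bb[1] <= 0 || bb[2] <= 0 || bb[3] >= width || bb[4] >= height)
      stop("hole is not strictly inside the arena")
  }
  if (length(holes) > 1) {
    for (i in seq_along(holes)[-1]) for (j in seq_len(i - 1)) {
      if (holes_overlap(holes[[i]], holes[[j]]))
        stop("holes overlap")
    }
  }
  structure(
    list(width = width, height = height, holes = holes,
         reference_betti = c(b0 = 1L, b1 = length(holes))),
    class = "pc_environment")
}

normalize_hole <- function(h) {
  if (is.null(h$type)) stop("hole needs a 'type' (\"rect\" or \"disc\")")
  if (h$type == "rect") {
    stopifnot(length(h$center) == 2, h$width > 0, h$height > 0)
    h$bbox <- c(h$center[1] - h$width / 2, h$center[2] - h$height / 2,
                h$center[1] + h$width / 2, h$center[2] + h$height / 2)
  } else if (h$type == "disc") {
    stopifnot(length(h$center) == 2, h$radius > 0)
    h$bbox <- c(h$center - h$radius, h$center + h$radius)
  } else stop("unknown hole type: ", h$type)
  h
}

hole_bbox <- function(h) h$bbox

holes_overlap <- function(a, b) {
  if (a$type == "rect" && b$type == "rect") {
    !(a$bbox[3] <= b$bbox[1] || b$bbox[3] <= a$bbox[1] ||
      a$bbox[4] <= b$bbox[2] || b$bbox[4] <= a$bbox[2])
  } else if (a$type == "disc" && b$type == "disc") {
    sum((a$center - b$center)^2) < (a$radius + b$radius)^2
  } else {
    d <- if (a$type == "disc") a else b
    r <- if (a$type == "disc") b else a
    cx <- min(max(d$center[1], r$bbox[1]), r$bbox[3])
    cy <- min(max(d$center[2], r$bbox[2]), r$bbox[4])
    sum((d$center - c(cx, cy))^2) < d$radius^2
  }
}

point_in_hole <- function(x, y, hole) {
  if (hole$type == "rect") {
    x > hole$bbox[1] & x < hole$bbox[3] & y > hole$bbox[2] & y < hole$bbox[4]
  } else {
    (x - hole$center[1])^2 + (y - hole$center[2])^2 < hole$radius^2
  }
}

#' Test whether points lie in the accessible region of an environment
#'
#' @param env A [make_environment()] object.
#' @param x,y Coordinate vectors (cm).
#' @return Logical vector.
#' @export
is_accessible <- function(env, x, y) {
  ok <- x >= 0 & x <= env$width & y >= 0 & y <= env$height
  for (h in env$holes) ok <- ok & !point_in_hole(x, y, h)
  ok
}

holes_matrix <- function(env) {
  if (length(env$holes) == 0) return(matrix(0, 0, 5))
  t(vapply(env$holes, function(h) {
    if (h$type == "rect") c(0, h$bbox) else c(1, h$center, h$radius, 0)
  }, numeric(5)))
}

#' Simulate non-preferential exploratory navigation
#'
#' The animal's speed follows an Ornstein-Uhlenbeck process (reflected at
#' zero) around `speed_mean`, while the heading diffuses; walls and hole
#' boundaries reflect the motion specularly. The resulting paths have rodent
#' momentum (smooth, persistent headings) but no preferred subregion: the
#' long-run occupancy of the accessible area is approximately uniform.
#'
#' @param env A [make_environment()] object.
#' @param duration Session length in seconds.
#' @param speed_mean,speed_sd Stationary mean and SD of running speed (cm/s).
#' @param dt Time step (s).
#' @param relax Speed relaxation rate (1/s).
#' @param turn_sd Heading diffusion (rad per sqrt(s)).
#' @param start Optional start position `c(x, y)`; by default a uniformly
#'   sampled accessible point. A start inside a hole is an error.
#' @param seed Optional RNG seed; the same seed reproduces the trajectory
#'   bitwise.
#' @return A `pc_trajectory`: a `data.frame` with columns `t`, `x`, `y` and
#'   attributes `dt` and `env`.
#' @export
simulate_trajectory <- function(env, duration, speed_mean = 20, speed_sd = 8,
                                dt = 0.01, relax = 0.5, turn_sd = 2,
                                start = NULL, seed = NULL) {
  stopifnot(inherits(env, "pc_environment"), duration >= 0,
            speed_mean > 0, speed_sd > 0, dt > 0)
  with_seed(seed, {
    if (is.null(start)) {
      repeat {
        start <- c(stats::runif(1, 0, env$width), stats::runif(1, 0, env$height))
        if (is_accessible(env, start[1], start[2])) break
      }
    } else if (!is_accessible(env, start[1], start[2])) {
      stop("start position is not in the accessible region")
    }
    n <- floor(duration / dt + 1e-9)
    if (n == 0) {
      pos <- matrix(start, 1, 2)
    } else {
      phi0 <- stats::runif(1, 0, 2 * pi)
      s0 <- abs(stats::rnorm(1, speed_mean, speed_sd))
      pos <- ou_trajectory_cpp(start[1], start[2], phi0, s0, n, dt,
                               speed_mean, speed_sd, relax, turn_sd,
                               stats::rnorm(n), stats::rnorm(n),
                               env$width, env$height, holes_matrix(env))
    }
    traj <- data.frame(t = seq(0, by = dt, length.out = nrow(pos)),
                       x = pos[, 1], y = pos[, 2])
    structure(traj, dt = dt, env = env,
              class = c("pc_trajectory", "data.frame"))
  })
}

#' Instantaneous speeds along a trajectory
#'
#' Finite-difference speeds (cm/s); the first value is repeated so the vector
#' matches the number of trajectory samples.
#' @param traj A [simulate_trajectory()] object.
#' @return Numeric vector of speeds.
#' @export
trajectory_speeds <- function(traj) {
  dt <- attr(traj, "dt")
  n <- nrow(traj)
  if (n < 2) return(rep(0, n))
  v <- sqrt(diff(traj$x)^2 + diff(traj$y)^2) / dt
  c(v[1], v)
}

#' Occupancy map of a trajectory
#'
#' Dwell time (s) per spatial bin over a regular grid covering the arena.
#' Entries sum to the session duration; bins fully inside holes receive zero.
#'
#' @param traj A `pc_trajectory`.
#' @param env The environment the trajectory was simulated in.
#' @param grid Number of bins per axis, or `c(nx, ny)`.
#' @return Matrix of dwell times (nx rows indexing x, ny columns indexing y).
#' @export
occupancy_map <- function(traj, env, grid = 10) {
  if (length(grid) == 1) grid <- c(grid, grid)
  dt <- attr(traj, "dt")
  n <- nrow(traj)
  # each sample except the last contributes one dt of dwell
  use <- if (n > 1) seq_len(n - 1) else 1L
  ix <- pmin(pmax(floor(traj$x[use] / env$width * grid[1]) + 1L, 1L), grid[1])
  iy <- pmin(pmax(floor(traj$y[use] / env$height * grid[2]) + 1L, 1L), grid[2])
  m <- matrix(0, grid[1], grid[2])
  tab <- table(factor(ix, levels = seq_len(grid[1])),
               factor(iy, levels = seq_len(grid[2])))
  m[] <- as.numeric(tab)
  m * if (n > 1) dt else 0
}

#' Fraction of accessible area per occupancy-grid bin
#'
#' Monte-Carlo estimate of the accessible area contained in each bin of the
#' occupancy grid; used to compare occupancy against the uniform expectation.
#' @inheritParams occupancy_map
#' @param samples_per_bin Uniform points drawn per bin.
#' @param seed RNG seed.
#' @return Matrix of areas (cm^2) matching [occupancy_map()] layout.
#' @export
accessible_area_map <- function(env, grid = 10, samples_per_bin = 200, seed = 1) {
  if (length(grid) == 1) grid <- c(grid, grid)
  bw <- env$width / grid[1]; bh <- env$height / grid[2]
  with_seed(seed, {
    m <- matrix(0, grid[1], grid[2])
    for (i in seq_len(grid[1])) for (j in seq_len(grid[2])) {
      x <- stats::runif(samples_per_bin, (i - 1) * bw, i * bw)
      y <- stats::runif(samples_per_bin, (j - 1) * bh, j * bh)
      m[i, j] <- mean(is_accessible(env, x, y)) * bw * bh
    }
    m
  })
}

#' Write / read a trajectory as delimited text
#'
#' Columns `t,x,y` (seconds, cm, cm) with a header line; round-trips
#' loss-free.
#' @param traj A `pc_trajectory`.
#' @param path File path.
#' @export
write_trajectory <- function(traj, path) {
  fwrite(data.table(t = traj$t, x = traj$x, y = traj$y), path)
  invisible(path)
}

#' @rdname write_trajectory
#' @param env Environment to attach to the trajectory read back.
#' @param dt Time step; inferred from the time column when `NULL`.
#' @export
read_trajectory <- function(path, env = NULL, dt = NULL) {
  d <- fread(path)
  stopifnot(all(c("t", "x", "y") %in% names(d)))
  dt <- dt %||% (if (nrow(d) > 1) d$t[2] - d$t[1] else 0.01)
  structure(as.data.frame(d[, c("t", "x", "y")]), dt = dt, env = env,
            class = c("pc_trajectory", "data.frame"))
}
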