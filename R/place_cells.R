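# place_cells: Gaussian place-field ensembles and theta/gamma-modulated
# inhomogeneous Poisson spike trains.

# Field-size convention: s_i is the diameter at which the Gaussian tuning
# curve has fallen to 0.2 of its peak, so the Gaussian SD is s_i / (2 sqrt(2 ln 5)).
size_to_sigma <- function(s) s / (2 * sqrt(2 * log(5)))

#' Sample a place-field map
#'
#' Draws `N` Gaussian place fields with centres uniform over the arena
#' rectangle (fields may extend over holes), field sizes from a log-normal
#' distribution with mode `s` and SD `b * s`, and peak firing rates from a
#' log-normal with mode `f` and SD `a * f`. With `a = b = 0` all fields are
#' identical.
#'
#' @param env A [make_environment()] object.
#' @param s Mode of the field-size distribution (cm).
#' @param f Mode of the peak-rate distribution (Hz).
#' @param N Number of cells.
#' @param a,b Dimensionless SD coefficients: `sd(rate) = a * f`,
#'   `sd(size) = b * s`.
#' @param field_cutoff Compact-support cutoff in Gaussian SD units: the cell
#'   is silent beyond `field_cutoff * sigma_i` from its field centre. The
#'   default (2.45 SD, the 5%-of-peak contour) reflects the operational
#'   definition of place-field extent — firing is confined to the field.
#'   `Inf` gives the pure (infinite-support) Gaussian.
#' @param seed RNG seed.
#' @return A `pc_field_map`: list with `centers` (N x 2 matrix, cm), `size`
#'   (cm), `rate` (Hz), `sigma` (Gaussian SD, cm) and the ensemble parameters.
#' @export
sample_place_field_map <- function(env, s = 23, f = 28, N = 350,
                                   a = 0.3, b = 0.3, field_cutoff = 2.45,
                                   seed = NULL) {
  stopifnot(inherits(env, "pc_environment"), s > 0, f > 0, N >= 1, a >= 0, b >= 0)
  with_seed(seed, {
    centers <- cbind(stats::runif(N, 0, env$width), stats::runif(N, 0, env$height))
    size <- rlnorm_mode_sd(N, s, b * s)
    rate <- rlnorm_mode_sd(N, f, a * f)
    structure(list(centers = centers, size = size, rate = rate,
                   sigma = size_to_sigma(size), field_cutoff = field_cutoff,
                   params = list(s = s, f = f, N = N, a = a, b = b)),
              class = "pc_field_map")
  })
}

#' Theta/gamma modulation configuration
#'
#' Controls the rhythmic modulation of place-cell firing. The theta factor
#' implements phase precession: a cell's preferred theta phase advances
#' linearly from 2*pi at field entry to 0 at exit (fraction measured along the
#' instantaneous heading), and spiking is modulated by a raised cosine of the
#' offset from the preferred phase raised to `theta_sharpness`. The gamma
#' factor is a Boltzmann weight `exp(-A_gamma(t) / tau)` with
#' `A_gamma(t) = (1 + cos(2 pi f_gamma t)) / 2` normalised to `[0, 1]`, so
#' spikes concentrate at gamma troughs; `tau = Inf` ("infinitely hot")
#' disables gamma coupling, and the physiological default is the mean gamma
#' amplitude, `tau = 0.5`.
#'
#' @param theta_on,gamma_on Enable the respective factor.
#' @param theta_freq Theta frequency (Hz).
#' @param theta_sharpness Exponent of the raised-cosine precession factor
#'   (dimensionless, >= 0; larger values lock spikes more tightly to the
#'   preferred phase).
#' @param gamma_freq Gamma frequency (Hz).
#' @param tau Effective temperature of the gamma Boltzmann factor (same units
#'   as the normalised gamma amplitude). May be a scalar or one value per
#'   cell.
#' @return A `pc_modulation` list.
#' @export
modulation_config <- function(theta_on = FALSE, gamma_on = FALSE,
                              theta_freq = 8, theta_sharpness = 1,
                              gamma_freq = 60, tau = 0.5) {
  stopifnot(theta_freq > 0, gamma_freq > 0, all(tau > 0), theta_sharpness >= 0)
  structure(list(theta_on = theta_on, gamma_on = gamma_on,
                 theta_freq = theta_freq, theta_sharpness = theta_sharpness,
                 gamma_freq = gamma_freq, tau = tau),
            class = "pc_modulation")
}

cell_tau <- function(mod, i) {
  if (length(mod$tau) == 1) mod$tau else mod$tau[i]
}

# Raised-cosine precession factor for one cell along positions/velocities.
theta_factor <- function(t, dx, dy, vx, vy, radius, freq, sharpness) {
  vn <- sqrt(vx^2 + vy^2)
  vn[vn < 1e-9] <- 1e-9
  u <- (dx * vx + dy * vy) / vn            # signed progress along heading
  frac <- pmin(pmax((u + radius) / (2 * radius), 0), 1)
  pref <- 2 * pi * (1 - frac)              # entry -> exit maps 2*pi -> 0
  phase <- (2 * pi * freq * t) %% (2 * pi)
  ((1 + cos(phase - pref)) / 2)^sharpness
}

gamma_amplitude <- function(t, freq) (1 + cos(2 * pi * freq * t)) / 2

#' Instantaneous firing rate of one cell
#'
#' `rate = f_i * G_i(position) * Theta_i(t) * exp(-A_gamma(t) / tau_i)`, where
#' `G_i` is the unit-peak Gaussian place-field tuning curve. Both modulation
#' factors are identically 1 when switched off (`tau = Inf` likewise disables
#' the gamma factor), so the rate never exceeds the cell's peak rate.
#'
#' @param map A [sample_place_field_map()] object.
#' @param cell Cell index.
#' @param position `c(x, y)` in cm.
#' @param t Time (s).
#' @param mod A [modulation_config()].
#' @param velocity Optional `c(vx, vy)` (cm/s); required for the precession
#'   factor, which depends on the traversal direction.
#' @return Rate in Hz.
#' @export
instantaneous_rate <- function(map, cell, position, t,
                               mod = modulation_config(), velocity = c(1, 0)) {
  stopifnot(t >= 0)
  dx <- position[1] - map$centers[cell, 1]
  dy <- position[2] - map$centers[cell, 2]
  cutoff <- map$field_cutoff %||% Inf
  g <- exp(-(dx^2 + dy^2) / (2 * map$sigma[cell]^2))
  if (is.finite(cutoff) && dx^2 + dy^2 > (cutoff * map$sigma[cell])^2) g <- 0
  th <- if (mod$theta_on)
    theta_factor(t, dx, dy, velocity[1], velocity[2], map$size[cell] / 2,
                 mod$theta_freq, mod$theta_sharpness) else 1
  tau <- cell_tau(mod, cell)
  ga <- if (mod$gamma_on && is.finite(tau))
    exp(-gamma_amplitude(t, mod$gamma_freq) / tau) else 1
  map$rate[cell] * g * th * ga
}

#' Generate spike trains along a trajectory
#'
#' Inhomogeneous Poisson spiking by thinning on the trajectory's time grid:
#' each cell emits at most one spike per time step, with per-step probability
#' `1 - exp(-rate * dt)`. Rates are evaluated with [instantaneous_rate()]'s
#' formula, vectorised over the trajectory.
#'
#' @param map A `pc_field_map`.
#' @param traj A `pc_trajectory`.
#' @param mod A [modulation_config()].
#' @param seed RNG seed.
#' @return A `pc_spikes` object: list with `trains` (per-cell sorted spike
#'   times, s), `duration` and `n_cells`.
#' @export
generate_spike_trains <- function(map, traj, mod = modulation_config(),
                                  seed = NULL) {
  dt <- attr(traj, "dt")
  n <- nrow(traj)
  N <- nrow(map$centers)
  duration <- traj$t[n]
  vx <- c(diff(traj$x), 0) / dt
  vy <- c(diff(traj$y), 0) / dt
  gam <- if (mod$gamma_on) gamma_amplitude(traj$t, mod$gamma_freq) else NULL
  with_seed(seed, {
    trains <- vector("list", N)
    for (i in seq_len(N)) {
      dx <- traj$x - map$centers[i, 1]
      dy <- traj$y - map$centers[i, 2]
      d2 <- dx^2 + dy^2
      sig <- map$sigma[i]
      cutoff <- min(map$field_cutoff %||% Inf, 4) # beyond 4 SD the rate is negligible
      idx <- which(d2 < (cutoff * sig)^2)
      if (length(idx) == 0) { trains[[i]] <- numeric(0); next }
      rate <- map$rate[i] * exp(-d2[idx] / (2 * sig^2))
      if (mod$theta_on)
        rate <- rate * theta_factor(traj$t[idx], dx[idx], dy[idx],
                                    vx[idx], vy[idx], map$size[i] / 2,
                                    mod$theta_freq, mod$theta_sharpness)
      tau <- cell_tau(mod, i)
      if (mod$gamma_on && is.finite(tau))
        rate <- rate * exp(-gam[idx] / tau)
      p <- -expm1(-rate * dt)
      hit <- stats::runif(length(idx)) < p
      trains[[i]] <- traj$t[idx][hit]
    }
    structure(list(trains = trains, duration = duration, n_cells = N),
              class = "pc_spikes")
  })
}

#' Write / read a spike raster as delimited text
#'
#' Columns `cell_id` (0-based integer) and `spike_time_s`, sorted by time,
#' with a header line.
#' @param spikes A `pc_spikes` object.
#' @param path File path.
#' @export
write_spike_raster <- function(spikes, path) {
  d <- rbindlist(lapply(seq_along(spikes$trains), function(i) {
    if (length(spikes$trains[[i]]) == 0) return(NULL)
    data.table(cell_id = i - 1L, spike_time_s = spikes$trains[[i]])
  }))
  if (is.null(d) || nrow(d) == 0)
    d <- data.table(cell_id = integer(0), spike_time_s = numeric(0))
  setorder(d, spike_time_s)
  fwrite(d, path)
  invisible(path)
}

#' @rdname write_spike_raster
#' @param n_cells Total number of cells (cells that never spiked are kept as
#'   empty trains); inferred from the data when `NULL`.
#' @param duration Session length (s); inferred as the last spike time when
#'   `NULL`.
#' @export
read_spike_raster <- function(path, n_cells = NULL, duration = NULL) {
  d <- fread(path)
  stopifnot(all(c("cell_id", "spike_time_s") %in% names(d)))
  n_cells <- n_cells %||% (if (nrow(d)) max(d$cell_id) + 1L else 0L)
  trains <- vector("list", n_cells)
  for (i in seq_len(n_cells)) trains[[i]] <- numeric(0)
  if (nrow(d)) {
    sp <- split(d$spike_time_s, factor(d$cell_id + 1L, levels = seq_len(n_cells)))
    for (i in seq_len(n_cells)) trains[[i]] <- sort(sp[[i]])
  }
  structure(list(trains = trains,
                 duration = duration %||% (if (nrow(d)) max(d$spike_time_s) else 0),
                 n_cells = n_cells),
            class = "pc_spikes")
}

#' Nerve complex of a place-field cover
#'
#' Evaluates the Alexandrov-Cech nerve of the cover of the accessible region
#' by the place fields (each field taken as the disc of diameter `s_i` around
#' its centre): a simplex is included for every set of up to `d_max + 1`
#' fields whose common intersection with the accessible region is non-empty.
#' Intersections are detected on a regular grid of sample points.
#'
#' @param map A `pc_field_map`.
#' @param env The environment.
#' @param resolution Grid spacing (cm) used to detect common overlaps.
#' @param d_max Maximum simplex dimension retained.
#' @return A `pc_complex` (all filtration times zero).
#' @export
nerve_complex <- function(map, env, resolution = 2, d_max = 3) {
  xs <- seq(resolution / 2, env$width, by = resolution)
  ys <- seq(resolution / 2, env$height, by = resolution)
  pts <- expand.grid(x = xs, y = ys)
  keep <- is_accessible(env, pts$x, pts$y)
  pts <- pts[keep, ]
  r <- map$size / 2
  seen <- new.env(hash = TRUE)
  simp <- list()
  for (k in seq_len(nrow(pts))) {
    d2 <- (pts$x[k] - map$centers[, 1])^2 + (pts$y[k] - map$centers[, 2])^2
    act <- which(d2 <= r^2)
    if (length(act) == 0) next
    for (sz in seq_len(min(length(act), d_max + 1))) {
      combs <- utils::combn(act, sz)
      for (c_i in seq_len(ncol(combs))) {
        key <- simplex_key(combs[, c_i])
        if (is.null(seen[[key]])) {
          seen[[key]] <- TRUE
          simp[[length(simp) + 1L]] <- combs[, c_i]
        }
      }
    }
  }
  filtered_complex(simp, rep(0, length(simp)), check = FALSE)
}
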