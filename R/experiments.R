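# experiments: end-to-end learning sessions and parameter-scan drivers
# (learning region, coactivity-window scan, synaptic criticality,
# additivity of learning times across subdomains).

#' Run one topological learning session
#'
#' Full pipeline: place-field map -> spike trains -> coactivity events ->
#' pairwise coactivity graph -> clique (or detection) filtered complex ->
#' persistence -> learning time against the environment's reference Betti
#' numbers.
#'
#' @param env A [make_environment()] object.
#' @param traj A [simulate_trajectory()] trajectory.
#' @param map Optional pre-sampled [sample_place_field_map()]; when `NULL` a
#'   map is sampled from `s, f, N, a, b` with `seed`.
#' @param s,f,N,a,b Ensemble parameters (used when `map` is `NULL`).
#' @param mod A [modulation_config()].
#' @param cfg A [coactivity_config()].
#' @param mode Complex construction mode, see [build_filtered_complex()].
#' @param d_max Complex dimension cap (2 suffices for the planar `b0`, `b1`
#'   learning criterion).
#' @param horizon Session cap (s) for declaring success; defaults to the
#'   trajectory length.
#' @param seed RNG seed (map sampling and spiking).
#' @param events Optional pre-computed events (skips spiking/detection).
#' @return A `pc_session` list: `learning` ([learning_time()] result),
#'   `barcode`, `complex_size`, `n_links`, `events`, `graph`.
#' @export
run_learning_session <- function(env, traj, map = NULL, s = 23, f = 28,
                                 N = 350, a = 0.3, b = 0.3,
                                 mod = modulation_config(),
                                 cfg = coactivity_config(),
                                 mode = "clique", d_max = 2,
                                 horizon = NULL, seed = NULL, events = NULL) {
  if (is.null(events)) {
    seeds <- derive_seeds(seed, 3)
    if (is.null(map))
      map <- sample_place_field_map(env, s = s, f = f, N = N, a = a, b = b,
                                    seed = seeds[[1]])
    spikes <- generate_spike_trains(map, traj, mod, seed = seeds[[2]])
    events <- detect_coactivity_events(spikes, cfg, seed = seeds[[3]])
  }
  horizon <- horizon %||% attr(events, "duration")
  if (mode == "clique") {
    graph <- build_coactivity_graph(events)
    cfg$d_max <- as.integer(d_max)
    fc <- build_filtered_complex(graph, "clique", cfg)
  } else {
    graph <- build_coactivity_graph(events)
    cfg$d_max <- as.integer(d_max)
    fc <- build_filtered_complex(events, "detection", cfg)
  }
  bc <- persistence_barcode(fc, d_max = d_max)
  lr <- learning_time(bc, env$reference_betti, horizon = horizon)
  structure(list(learning = lr, barcode = bc,
                 complex_size = length(fc$simplices),
                 n_links = nrow(graph$edges),
                 events = events, graph = graph),
            class = "pc_session")
}

#' Learning-region scan over (s, f, N)
#'
#' For each lattice point, `reps` independent place-field maps are drawn over
#' a single fixed trajectory (statistical alternatives are generated by
#' randomising maps, not trajectories) and the learning time distribution and
#' success rate are recorded. The learning region is the set of points whose
#' success rate reaches `level`.
#'
#' @param env Environment.
#' @param traj Trajectory (shared by all points).
#' @param grid `data.frame` with columns `s`, `f`, `N` (one row per lattice
#'   point).
#' @param reps Replicate maps per point.
#' @param mod,cfg Modulation and coactivity configuration.
#' @param horizon Session cap (s).
#' @param level Success-rate threshold defining the region mask.
#' @param seed Master seed.
#' @return A `pc_region_scan`: the grid with `mean_t_min`, `success_rate`,
#'   `in_region`, `reps`.
#' @export
run_learning_region_scan <- function(env, traj, grid, reps = 3,
                                     mod = modulation_config(),
                                     cfg = coactivity_config(),
                                     horizon = NULL, level = 0.9,
                                     seed = NULL) {
  stopifnot(nrow(grid) >= 1, reps >= 1)
  seeds <- derive_seeds(seed, nrow(grid) * reps)
  res <- lapply(seq_len(nrow(grid)), function(i) {
    tm <- numeric(0); succ <- logical(reps)
    for (r in seq_len(reps)) {
      sess <- run_learning_session(env, traj, s = grid$s[i], f = grid$f[i],
                                   N = grid$N[i], mod = mod, cfg = cfg,
                                   horizon = horizon,
                                   seed = seeds[[(i - 1) * reps + r]])
      succ[r] <- sess$learning$success
      if (sess$learning$success) tm <- c(tm, sess$learning$t_min)
    }
    data.frame(s = grid$s[i], f = grid$f[i], N = grid$N[i],
               mean_t_min = if (length(tm)) mean(tm) else NA_real_,
               success_rate = mean(succ), reps = reps)
  })
  out <- do.call(rbind, res)
  out$in_region <- !is.na(out$success_rate) & out$success_rate >= level
  structure(out, class = c("pc_region_scan", "data.frame"))
}

#' Coactivity-window scan
#'
#' Sweeps the coactivity window width `w`, recording mean learning time and
#' success rate; fits `T_min(w) ~ w^(-alpha)` by OLS on log-log values over
#' the decreasing branch (successful points left of the minimum), and
#' reports the stable plateau (successive points whose local log-log slope
#' magnitude falls below `plateau_slope`).
#'
#' Spike trains do not depend on `w`, so each replicate's raster is reused
#' across the whole grid.
#'
#' @param env,traj,mod Environment, shared trajectory, modulation.
#' @param w_grid Ascending window widths (s).
#' @param reps Replicate maps per width.
#' @param s,f,N,a,b Ensemble parameters.
#' @param cfg Base coactivity configuration (its `w` is overridden).
#' @param horizon Session cap (s).
#' @param plateau_slope Log-log slope magnitude below which the dependence is
#'   considered flat.
#' @param min_success Minimum success rate for a width to enter the fit.
#' @param seed Master seed.
#' @return A `pc_window_scan` list: `table` (per-width stats), `alpha`
#'   (fitted exponent, `NA` when fewer than 4 widths qualify), `alpha_se`,
#'   `fit_points`, `plateau` (range of stable widths or `NULL`).
#' @export
run_window_scan <- function(env, traj, w_grid, reps = 3, s = 23, f = 28,
                            N = 350, a = 0.3, b = 0.3,
                            mod = modulation_config(),
                            cfg = coactivity_config(),
                            horizon = NULL, plateau_slope = 0.3,
                            min_success = 0.5, seed = NULL) {
  stopifnot(!is.unsorted(w_grid))
  seeds <- derive_seeds(seed, reps)
  tmat <- matrix(NA_real_, reps, length(w_grid))
  smat <- matrix(FALSE, reps, length(w_grid))
  for (r in seq_len(reps)) {
    rs <- derive_seeds(seeds[[r]], 3)
    map <- sample_place_field_map(env, s = s, f = f, N = N, a = a, b = b,
                                  seed = rs[[1]])
    spikes <- generate_spike_trains(map, traj, mod, seed = rs[[2]])
    for (j in seq_along(w_grid)) {
      cfg_j <- cfg; cfg_j$w <- w_grid[j]
      events <- detect_coactivity_events(spikes, cfg_j, seed = rs[[3]])
      sess <- run_learning_session(env, traj, cfg = cfg_j,
                                   horizon = horizon, events = events)
      smat[r, j] <- sess$learning$success
      if (sess$learning$success) tmat[r, j] <- sess$learning$t_min
    }
  }
  tab <- data.frame(w = w_grid,
                    mean_t_min = colMeans(tmat, na.rm = TRUE),
                    success_rate = colMeans(smat))
  tab$mean_t_min[is.nan(tab$mean_t_min)] <- NA_real_
  fit <- fit_decreasing_power_law(tab, min_success)
  plateau <- find_plateau(tab, plateau_slope, min_success)
  structure(list(table = tab, alpha = fit$alpha, alpha_se = fit$se,
                 fit_points = fit$n, fit = fit$model, plateau = plateau),
            class = "pc_window_scan")
}

fit_decreasing_power_law <- function(tab, min_success) {
  ok <- tab$success_rate >= min_success & !is.na(tab$mean_t_min)
  if (sum(ok) >= 1) {
    jmin <- which(ok)[which.min(tab$mean_t_min[ok])]
    ok <- ok & seq_len(nrow(tab)) <= jmin
  }
  if (sum(ok) < 4)
    return(list(alpha = NA_real_, se = NA_real_, n = sum(ok), model = NULL))
  m <- stats::lm(log(mean_t_min) ~ log(w), data = tab[ok, ])
  list(alpha = -unname(stats::coef(m)[2]),
       se = unname(sqrt(diag(stats::vcov(m)))[2]), n = sum(ok), model = m)
}

find_plateau <- function(tab, plateau_slope, min_success) {
  ok <- which(tab$success_rate >= min_success & !is.na(tab$mean_t_min))
  if (length(ok) < 2) return(NULL)
  w <- tab$w[ok]; tm <- tab$mean_t_min[ok]
  sl <- diff(log(tm)) / diff(log(w))
  flat <- which(abs(sl) < plateau_slope)
  if (length(flat) == 0) return(NULL)
  c(w[min(flat)], w[max(flat) + 1])
}

#' Synaptic-failure scan
#'
#' Sweeps the spike-transmission mode `p_star` (and optionally the readout
#' response mode `q_star`), filtering the coactivity events through the
#' synapse model before complex construction. Records learning time, success
#' rate, surviving link count `N2` and the final first Betti number, then
#' estimates the critical probability (largest sub-critical `p_star`), the
#' divergence exponent `kappa` of `T_min ~ (p - p_crit)^(-kappa)` and the
#' link-scaling exponent `delta` of `N2 ~ (p - p_crit)^delta`.
#'
#' @param env,traj Environment and shared trajectory.
#' @param p_grid Grid of transmission modes in `[0, 1]` (ascending).
#' @param q_grid Optional grid of response modes scanned at `p_star = 1`.
#' @param reps Replicate maps per grid value.
#' @param s,f,N,a,b Ensemble parameters.
#' @param delta_p,delta_q Probability spreads.
#' @param mod,cfg Modulation and coactivity configuration.
#' @param horizon Session cap (s).
#' @param success_floor Success rate below which a point counts as
#'   sub-critical.
#' @param seed Master seed.
#' @return A `pc_synaptic_scan` list: `table`, `q_table`, `p_crit`, `kappa`,
#'   `delta`, `b1_growth` (slope of `log b1` vs `p_crit - p` on sub-critical
#'   points, `NA` when unsupported).
#' @export
run_synaptic_scan <- function(env, traj, p_grid, q_grid = NULL, reps = 3,
                              s = 23, f = 28, N = 350, a = 0.3, b = 0.3,
                              delta_p = 0.05, delta_q = 0.05,
                              mod = modulation_config(),
                              cfg = coactivity_config(),
                              horizon = NULL, success_floor = 0.5,
                              seed = NULL) {
  stopifnot(all(p_grid >= 0 & p_grid <= 1))
  seeds <- derive_seeds(seed, reps)
  scan_one <- function(p, q, rs) {
    rs2 <- derive_seeds(rs, 5)
    map <- sample_place_field_map(env, s = s, f = f, N = N, a = a, b = b,
                                  seed = rs2[[1]])
    spikes <- generate_spike_trains(map, traj, mod, seed = rs2[[2]])
    events <- detect_coactivity_events(spikes, cfg, seed = rs2[[3]])
    model <- synapse_model(p, delta_p, q, delta_q, seed = rs2[[4]])
    fev <- apply_synaptic_filter(events, model, seed = rs2[[5]])
    sess <- run_learning_session(env, traj, cfg = cfg, horizon = horizon,
                                 events = fev)
    list(success = sess$learning$success, t_min = sess$learning$t_min,
         n2 = sess$n_links,
         b1 = sum(sess$barcode$dim == 1 & is.infinite(sess$barcode$death)))
  }
  run_grid <- function(grid, vary) {
    do.call(rbind, lapply(grid, function(g) {
      rows <- lapply(seq_len(reps), function(r)
        if (vary == "p") scan_one(g, 1, seeds[[r]])
        else scan_one(1, g, seeds[[r]]))
      tm <- vapply(rows, function(x) x$t_min, numeric(1))
      sc <- vapply(rows, function(x) x$success, logical(1))
      data.frame(p = if (vary == "p") g else 1,
                 q = if (vary == "q") g else 1,
                 mean_t_min = if (any(sc)) mean(tm[sc]) else NA_real_,
                 success_rate = mean(sc),
                 n2 = mean(vapply(rows, function(x) x$n2, numeric(1))),
                 b1 = mean(vapply(rows, function(x) x$b1, numeric(1))))
    }))
  }
  tab <- run_grid(sort(p_grid), "p")
  qtab <- if (!is.null(q_grid)) run_grid(sort(q_grid), "q") else NULL
  sub <- tab$success_rate < success_floor
  p_crit <- if (any(sub)) max(tab$p[sub]) else NA_real_
  kappa <- delta <- b1_growth <- NA_real_
  if (!is.na(p_crit)) {
    sup <- tab$p > p_crit & tab$success_rate >= success_floor &
      !is.na(tab$mean_t_min)
    if (sum(sup) >= 4) {
      mk <- stats::lm(log(mean_t_min) ~ log(p - p_crit), data = tab[sup, ])
      kappa <- -unname(stats::coef(mk)[2])
      md <- stats::lm(log(n2) ~ log(p - p_crit), data = tab[sup, ])
      delta <- unname(stats::coef(md)[2])
    }
    below <- tab$p <= p_crit & tab$b1 > 0
    if (sum(below) >= 3) {
      mb <- stats::lm(log(b1) ~ I(p_crit - p), data = tab[below, ])
      b1_growth <- unname(stats::coef(mb)[2])
    }
  }
  structure(list(table = tab, q_table = qtab, p_crit = p_crit,
                 kappa = kappa, delta = delta, b1_growth = b1_growth),
            class = "pc_synaptic_scan")
}

#' Split an environment into two subdomains along a vertical cut
#'
#' The subdomains meet at `x = x_cut` but do not overlap; each inherits the
#' holes lying inside it. A hole intersected by the cut would disconnect a
#' subdomain boundary and is an error.
#'
#' @param env Environment.
#' @param x_cut Cut coordinate (cm), strictly inside the arena.
#' @return List of two environments `E1` (left) and `E2` (right), each
#'   carrying attributes `x_range` describing its slab in the parent frame.
#' @export
split_environment <- function(env, x_cut) {
  stopifnot(x_cut > 0, x_cut < env$width)
  for (h in env$holes)
    if (h$bbox[1] < x_cut && h$bbox[3] > x_cut)
      stop("cut passes through a hole")
  mk <- function(x0, x1) {
    hs <- Filter(function(h) h$bbox[1] >= x0 && h$bbox[3] <= x1, env$holes)
    hs <- lapply(hs, function(h) { h$center[1] <- h$center[1] - x0; h$bbox <- NULL
      h })
    e <- make_environment(x1 - x0, env$height, hs)
    attr(e, "x_range") <- c(x0, x1)
    e
  }
  list(E1 = mk(0, x_cut), E2 = mk(x_cut, env$width))
}

# Restrict spikes to a subdomain and remap their times to the cumulative
# dwell time spent inside it (the subdomain's own session clock).
# `cells` optionally restricts the roster (e.g. to the cells whose field
# centres lie in the subdomain); others are silenced.
restrict_spikes_to_slab <- function(spikes, traj, x_range, cells = NULL) {
  dt <- attr(traj, "dt")
  inside <- traj$x >= x_range[1] & traj$x <= x_range[2]
  dwell <- c(0, cumsum(inside[-length(inside)])) * dt
  remap <- stats::approxfun(traj$t, dwell, rule = 2)
  trains <- lapply(seq_along(spikes$trains), function(i) {
    tt <- spikes$trains[[i]]
    if (length(tt) == 0) return(numeric(0))
    if (!is.null(cells) && !(i %in% cells)) return(numeric(0))
    idx <- pmin(findInterval(tt, traj$t) + 0L, nrow(traj))
    idx[idx < 1] <- 1L
    keep <- inside[idx]
    sort(remap(tt[keep]))
  })
  structure(list(trains = trains, duration = max(dwell),
                 n_cells = spikes$n_cells),
            class = "pc_spikes")
}

#' Additivity of learning times across complementary subdomains
#'
#' Splits the arena into two slabs; each slab's map is carried by the cells
#' whose field centres lie inside it, using only the spikes they emitted
#' while the animal was inside the slab, on the slab's own dwell-time clock.
#' Computes the three learning times and tests
#' whether `T_min(E) - [T_min(E1) + T_min(E2)]` differs from zero (paired
#' t-test over replicates).
#'
#' Replicates draw an independent trajectory *and* map each, so the paired
#' differences carry genuine between-session variability: with a single
#' shared trajectory, any late trajectory-specific transient resets every
#' replicate's learning time identically and the paired test probes that
#' artifact instead of the structural claim. Pass `traj` to force a shared
#' fixed trajectory.
#'
#' @param env Environment.
#' @param x_cut Cut coordinate (cm).
#' @param reps Replicate maps.
#' @param duration Session length (s) when trajectories are drawn per
#'   replicate.
#' @param traj Optional fixed trajectory shared by all replicates.
#' @param s,f,N,a,b Ensemble parameters.
#' @param mod,cfg Modulation and coactivity configuration.
#' @param seed Master seed.
#' @return A `pc_additivity` list: `table` (per replicate: `t_full`, `t_e1`,
#'   `t_e2`, `sum_parts`), `mean_difference`, `p_value`, `n_used` (replicates
#'   where all three runs succeeded).
#' @export
run_additivity_experiment <- function(env, x_cut, reps = 5, duration = 2000,
                                      traj = NULL, s = 23,
                                      f = 28, N = 350, a = 0.3, b = 0.3,
                                      mod = modulation_config(),
                                      cfg = coactivity_config(),
                                      seed = NULL) {
  halves <- split_environment(env, x_cut)
  seeds <- derive_seeds(seed, reps)
  fixed_traj <- traj
  rows <- lapply(seq_len(reps), function(r) {
    rs <- derive_seeds(seeds[[r]], 4)
    traj <- fixed_traj %||%
      simulate_trajectory(env, duration, seed = rs[[4]])
    map <- sample_place_field_map(env, s = s, f = f, N = N, a = a, b = b,
                                  seed = rs[[1]])
    spikes <- generate_spike_trains(map, traj, mod, seed = rs[[2]])
    full_ev <- detect_coactivity_events(spikes, cfg, seed = rs[[3]])
    sess <- run_learning_session(env, traj, cfg = cfg, events = full_ev)
    part <- lapply(halves, function(e) {
      xr <- attr(e, "x_range")
      roster <- which(map$centers[, 1] >= xr[1] & map$centers[, 1] <= xr[2])
      sp <- restrict_spikes_to_slab(spikes, traj, xr, cells = roster)
      ev <- detect_coactivity_events(sp, cfg, seed = rs[[3]])
      graph <- build_coactivity_graph(ev)
      fc <- build_filtered_complex(graph, "clique", cfg)
      learning_time(persistence_barcode(fc, d_max = 2), e$reference_betti,
                    horizon = sp$duration)
    })
    data.frame(t_full = sess$learning$t_min,
               t_e1 = part$E1$t_min, t_e2 = part$E2$t_min)
  })
  tab <- do.call(rbind, rows)
  tab$sum_parts <- tab$t_e1 + tab$t_e2
  ok <- stats::complete.cases(tab)
  diff <- tab$t_full[ok] - tab$sum_parts[ok]
  pt <- if (sum(ok) >= 2 && stats::sd(diff) > 0)
    stats::t.test(diff)$p.value else NA_real_
  structure(list(table = tab, mean_difference = mean(diff),
                 p_value = pt, n_used = sum(ok)),
            class = "pc_additivity")
}
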