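# flicker: transient coactivity graphs/complexes. Links are granted finite
# lifetimes after each activation; the resulting time-dependent clique
# complex F(t) may gain and lose simplexes ("flicker") while its large-scale
# topology can remain stable.

#' Flicker evolution configuration
#'
#' Modes:
#' \describe{
#' \item{`exponential`}{each (re)activation grants the link an independent
#'   exponential lifetime with mean `tau`; the link is present while any such
#'   lease is unexpired, so survival measured from the last activation decays
#'   as `exp(-t/tau)` and reactivation can only extend life. The spread of
#'   the exponential draws produces a long-lived "survivor" pool.}
#' \item{`quenched`}{a link dies exactly `tau` after its last activation.}
#' \item{`windowed`}{a link is active at `t` iff it activated within
#'   `[t - varpi, t]`; Betti series are evaluated on a grid of step
#'   `delta_varpi`.}
#' \item{`random`}{control: each link's activations are replaced by a Poisson
#'   stream matching its empirical rate; deaths as in `exponential`.}
#' }
#' `tau = Inf` reproduces the perennial, ever-growing graph in every mode.
#'
#' @param mode One of `"exponential"`, `"quenched"`, `"windowed"`, `"random"`.
#' @param tau Proper link decay constant (s).
#' @param varpi Integration window (s) for the windowed mode.
#' @param delta_varpi Evaluation step (s) for the windowed mode (kept at or
#'   above `0.01 * varpi`).
#' @param seed RNG seed.
#' @return A `pc_flicker_config` list.
#' @export
flicker_config <- function(mode = c("exponential", "quenched", "windowed",
                                    "random"),
                           tau = 90, varpi = 300, delta_varpi = varpi / 20,
                           seed = NULL) {
  mode <- match.arg(mode)
  stopifnot(tau > 0, varpi > 0)
  if (mode == "windowed" && delta_varpi < 0.01 * varpi)
    stop("delta_varpi must be at least 0.01 * varpi")
  structure(list(mode = mode, tau = tau, varpi = varpi,
                 delta_varpi = delta_varpi, seed = seed),
            class = "pc_flicker_config")
}

link_events_from <- function(events) {
  pairs <- events[events$order == 2L, ]
  data.table(u = vapply(pairs$cells, `[`, integer(1), 1L),
             v = vapply(pairs$cells, `[`, integer(1), 2L),
             time = pairs$time)
}

#' Evolve a flickering link timeline
#'
#' Applies the configured survival rule to every link's activation history,
#' producing the alive spans (birth/death log) of each link. Vertices appear
#' at their first activation and never decay.
#'
#' @param events A `pc_events` object (order-2 events are the link
#'   activations), or a `data.table` with columns `u`, `v`, `time`.
#' @param cfg A [flicker_config()].
#' @param duration Session length (s); spans are censored there.
#' @return A `pc_flicker`: list with `spans` (`data.table` `u`, `v`, `birth`,
#'   `death`; `death = Inf` marks survivors censored at session end),
#'   `activations` (per-link activation times), `vertices`, `duration`,
#'   `cfg`.
#' @export
evolve_flicker_timeline <- function(events, cfg = flicker_config(),
                                    duration = NULL) {
  le <- if (inherits(events, "pc_events")) link_events_from(events)
        else data.table::copy(as.data.table(events))
  duration <- duration %||% attr(events, "duration") %||% max(le$time)
  setorder(le, time)
  acts <- le[, list(times = list(time)), by = list(u, v)]
  with_seed(cfg$seed, {
    spans <- rbindlist(lapply(seq_len(nrow(acts)), function(i) {
      tt <- acts$times[[i]]
      if (cfg$mode == "random") {
        rate <- length(tt) / duration
        n <- stats::rpois(1, rate * duration)
        tt <- sort(stats::runif(n, 0, duration))
        if (length(tt) == 0) return(NULL)
      }
      sp <- link_spans(tt, cfg, duration)
      if (nrow(sp) == 0) return(NULL)
      data.table(u = acts$u[i], v = acts$v[i],
                 birth = sp$birth, death = sp$death)
    }))
    if (is.null(spans) || nrow(spans) == 0)
      spans <- data.table(u = integer(0), v = integer(0),
                          birth = numeric(0), death = numeric(0))
    verts <- le[, list(first = min(time)), by = list(u)]
    verts2 <- le[, list(first = min(time)), by = list(v)]
    setnames(verts2, "v", "u")
    verts <- rbind(verts, verts2)[, list(first = min(first)), by = u]
    setnames(verts, "u", "id")
    structure(list(spans = spans, activations = acts, vertices = verts,
                   duration = duration, cfg = cfg),
              class = "pc_flicker")
  })
}

# Alive spans of one link given its activation times and the survival rule.
link_spans <- function(tt, cfg, duration) {
  if (is.infinite(cfg$tau) && cfg$mode != "windowed")
    return(data.table(birth = tt[1], death = Inf))
  if (cfg$mode == "windowed") {
    # active on [a_i, a_i + varpi], merged across overlapping activations
    gap <- which(diff(tt) > cfg$varpi)
    starts <- tt[c(1L, gap + 1L)]
    ends <- pmin(tt[c(gap, length(tt))] + cfg$varpi, Inf)
    ends[ends >= duration] <- Inf
    return(data.table(birth = starts, death = ends))
  }
  draw <- function(n) {
    if (cfg$mode == "quenched") rep(cfg$tau, n) else stats::rexp(n, 1 / cfg$tau)
  }
  leases <- tt + draw(length(tt))
  births <- numeric(0); deaths <- numeric(0)
  cur_birth <- tt[1]; cur_death <- leases[1]
  if (length(tt) > 1) for (k in 2:length(tt)) {
    if (tt[k] <= cur_death) {
      cur_death <- max(cur_death, leases[k])
    } else {
      births <- c(births, cur_birth); deaths <- c(deaths, cur_death)
      cur_birth <- tt[k]; cur_death <- leases[k]
    }
  }
  births <- c(births, cur_birth)
  deaths <- c(deaths, if (cur_death >= duration) Inf else cur_death)
  data.table(birth = births, death = deaths)
}

#' Active links of a flicker timeline at a time point
#'
#' @param tl A `pc_flicker`.
#' @param t Time (s).
#' @return `data.table` with columns `u`, `v`.
#' @export
active_links_at <- function(tl, t) {
  sp <- tl$spans
  sp[sp$birth <= t & sp$death > t, c("u", "v")]
}

#' Betti time series of a flickering complex
#'
#' At each time point the clique complex (dimension-capped) of the active
#' link set is built and its Z2 Betti numbers computed.
#'
#' In the decaying modes vertices appear at their first activation and never
#' decay (as place cells do in a learned environment), so a cell whose links
#' have all decayed counts as an isolated component. In the windowed
#' (finite-latency) mode the complex is built from the window's events alone,
#' so a cell with no link activity inside the window is absent rather than
#' isolated.
#'
#' @param tl A `pc_flicker`.
#' @param times Evaluation times (s); defaults to a grid of `n_steps` points.
#' @param n_steps Number of grid points when `times` is `NULL`.
#' @param d_max Clique-complex dimension cap (2 suffices for `b0`, `b1`).
#' @return `data.frame` with columns `t`, `b0`, ..., `b_dmax` and `n_links`.
#' @export
betti_time_series <- function(tl, times = NULL, n_steps = 50, d_max = 2) {
  times <- times %||% seq(0, tl$duration, length.out = n_steps + 1)[-1]
  res <- matrix(0L, length(times), d_max + 1)
  nl <- integer(length(times))
  windowed <- identical(tl$cfg$mode, "windowed")
  for (k in seq_along(times)) {
    act <- active_links_at(tl, times[k])
    nl[k] <- nrow(act)
    vs <- if (windowed) sort(unique(c(act$u, act$v)))
          else tl$vertices$id[tl$vertices$first <= times[k]]
    res[k, ] <- betti_of_link_set(act, vs, d_max)
  }
  out <- data.frame(t = times, res, n_links = nl)
  names(out) <- c("t", paste0("b", 0:d_max), "n_links")
  out
}

# Betti numbers of the clique complex over an edge set (+ isolated vertices).
betti_of_link_set <- function(edges, vertex_ids, d_max) {
  if (length(vertex_ids) == 0) return(integer(d_max + 1))
  simp <- as.list(as.integer(vertex_ids))
  if (nrow(edges) > 0) {
    g <- igraph::graph_from_data_frame(
      data.frame(from = as.character(edges$u), to = as.character(edges$v)),
      directed = FALSE,
      vertices = data.frame(name = as.character(vertex_ids)))
    cl <- igraph::cliques(g, min = 2, max = d_max + 1L)
    vn <- as.integer(igraph::V(g)$name)
    simp <- c(simp, lapply(cl, function(ci) sort(vn[as.integer(ci)])))
  }
  b <- betti_z2_cpp(simp, as.integer(d_max))
  b
}

#' Lifetime statistics of a flicker timeline
#'
#' Link (order m = 2) lifetimes are the spans between a birth and the next
#' death of the same link; spans censored at session end are the "survivor"
#' pool and are excluded from the exponential fit (maximum-likelihood mean).
#' Triangle (m = 3) lifetimes are the intersections of the three member
#' links' alive spans. Also reports the mean reactivation interval between
#' successive activations of a link.
#'
#' @param tl A `pc_flicker`.
#' @param orders Clique orders to analyse (2 and/or 3).
#' @return A `pc_lifetimes` list: per order, `lifetimes`, fitted mean
#'   `tau_e`, `n_survivors`, `survivor_fraction`; plus `reactivation_interval`
#'   (s).
#' @export
lifetime_statistics <- function(tl, orders = c(2, 3)) {
  out <- list()
  sp <- tl$spans
  gaps <- unlist(lapply(tl$activations$times, function(tt)
    if (length(tt) > 1) diff(tt) else numeric(0)))
  out$reactivation_interval <- if (length(gaps)) mean(gaps) else NA_real_
  if (2 %in% orders) {
    fin <- is.finite(sp$death)
    lt <- sp$death[fin] - sp$birth[fin]
    out$order2 <- list(lifetimes = lt,
                       tau_e = if (length(lt)) mean(lt) else NA_real_,
                       n_survivors = sum(!fin),
                       survivor_fraction = mean(!fin))
  }
  if (3 %in% orders) {
    lt3 <- triangle_lifetimes(tl)
    fin <- is.finite(lt3$death)
    lt <- lt3$death[fin] - lt3$birth[fin]
    out$order3 <- list(lifetimes = lt,
                       tau_e = if (length(lt)) mean(lt) else NA_real_,
                       n_survivors = sum(!fin),
                       survivor_fraction = if (nrow(lt3)) mean(!fin) else NA_real_)
  }
  structure(out, class = "pc_lifetimes")
}

triangle_lifetimes <- function(tl) {
  sp <- tl$spans
  ekey <- paste(pmin(sp$u, sp$v), pmax(sp$u, sp$v))
  spans_by_edge <- split(sp[, c("birth", "death")], ekey)
  edges <- unique(data.table(u = pmin(sp$u, sp$v), v = pmax(sp$u, sp$v)))
  g <- igraph::graph_from_data_frame(
    data.frame(from = as.character(edges$u), to = as.character(edges$v)),
    directed = FALSE)
  tri <- igraph::cliques(g, min = 3, max = 3)
  vn <- as.integer(igraph::V(g)$name)
  res <- list()
  for (ci in seq_along(tri)) {
    vv <- sort(vn[as.integer(tri[[ci]])])
    kk <- c(paste(vv[1], vv[2]), paste(vv[1], vv[3]), paste(vv[2], vv[3]))
    segs <- lapply(kk, function(k) spans_by_edge[[k]])
    res[[length(res) + 1L]] <- intersect_spans(segs)
  }
  if (length(res) == 0)
    return(data.table(birth = numeric(0), death = numeric(0)))
  rbindlist(res)
}

# Intersection of k span lists: intervals where all links are simultaneously
# alive (sweep over boundary points).
intersect_spans <- function(segs) {
  pts <- sort(unique(unlist(lapply(segs, function(s) c(s$birth, s$death[is.finite(s$death)])))))
  if (length(pts) == 0) return(data.table(birth = numeric(0), death = numeric(0)))
  alive_at <- function(t) all(vapply(segs, function(s)
    any(s$birth <= t & s$death > t), logical(1)))
  mids <- c(pts, utils::tail(pts, 1) + 1)
  state <- vapply(seq_along(pts), function(i) {
    probe <- if (i < length(pts)) (pts[i] + pts[i + 1]) / 2 else pts[i] + 1e-9
    alive_at(probe)
  }, logical(1))
  births <- numeric(0); deaths <- numeric(0)
  open_birth <- NA_real_
  for (i in seq_along(pts)) {
    if (state[i] && is.na(open_birth)) open_birth <- pts[i]
    if (!state[i] && !is.na(open_birth)) {
      births <- c(births, open_birth); deaths <- c(deaths, pts[i])
      open_birth <- NA_real_
    }
  }
  if (!is.na(open_birth)) { births <- c(births, open_birth); deaths <- c(deaths, Inf) }
  data.table(birth = births, death = deaths)
}

#' Topological-stability summary of a Betti time series
#'
#' Fluctuation fraction: the share of post-formation samples whose
#' `(b0, b1)` differ from the reference. When a list of series indexed by a
#' parameter grid is given, also reports the smallest grid value achieving
#' zero fluctuation (the stabilization threshold).
#'
#' @param series A [betti_time_series()] data frame, or a named list of them
#'   (names = grid values) for the threshold search.
#' @param reference Reference Betti numbers `(b0, b1)`.
#' @param formation_time Only samples at `t >= formation_time` are scored.
#' @return A `pc_stability` list: `fluctuation_fraction` (per series) and,
#'   for a grid, `threshold` (smallest grid value with zero fluctuation,
#'   `NA` if none).
#' @export
stability_summary <- function(series, reference, formation_time = 0) {
  reference <- as.integer(reference[1:2])
  frac_of <- function(s) {
    s <- s[s$t >= formation_time, ]
    if (nrow(s) == 0) return(NA_real_)
    mean(!(s$b0 == reference[1] & s$b1 == reference[2]))
  }
  if (is.data.frame(series)) {
    structure(list(fluctuation_fraction = frac_of(series), threshold = NA_real_),
              class = "pc_stability")
  } else {
    fr <- vapply(series, frac_of, numeric(1))
    grid <- as.numeric(names(series))
    ok <- which(fr == 0)
    structure(list(fluctuation_fraction = fr,
                   threshold = if (length(ok)) min(grid[ok]) else NA_real_),
              class = "pc_stability")
  }
}

#' Inject replay events into a link-activation stream
#'
#' Adds activation events at Poisson-distributed times; each replay reuses a
#' uniformly sampled link that had already activated before the replay time,
#' emulating endogenous reactivation of the stored map. Rate 0 is the
#' identity.
#'
#' @param events A `pc_events` object or a `data.table` `u`, `v`, `time`.
#' @param rate Replay rate (events per minute).
#' @param seed RNG seed.
#' @param duration Session length (s).
#' @return A `data.table` of link activations `u`, `v`, `time`, sorted.
#' @export
inject_replays <- function(events, rate, seed = NULL, duration = NULL) {
  le <- if (inherits(events, "pc_events")) link_events_from(events)
        else data.table::copy(as.data.table(events))
  duration <- duration %||% attr(events, "duration") %||% max(le$time)
  stopifnot(rate >= 0)
  setorder(le, time)
  if (rate == 0) return(le)
  with_seed(seed, {
    n <- stats::rpois(1, rate * duration / 60)
    if (n == 0) return(le)
    tt <- sort(stats::runif(n, 0, duration))
    firsts <- le[, list(first = min(time)), by = list(u, v)]
    add <- rbindlist(lapply(tt, function(t0) {
      cand <- which(firsts$first < t0)
      if (length(cand) == 0) return(NULL)
      i <- cand[sample.int(length(cand), 1)]
      data.table(u = firsts$u[i], v = firsts$v[i], time = t0)
    }))
    out <- rbind(le, add)
    setorder(out, time)
    out
  })
}

#' Export a flicker event log and reconstruct active sets from it
#'
#' Log lines `t,link_u,link_v,event` with `event` `birth` or `death`;
#' replaying the log reproduces the active link set at any time.
#' @param tl A `pc_flicker`.
#' @param path File path.
#' @export
write_flicker_log <- function(tl, path) {
  sp <- tl$spans
  d <- rbind(data.table(t = sp$birth, link_u = sp$u, link_v = sp$v, event = "birth"),
             data.table(t = sp$death[is.finite(sp$death)],
                        link_u = sp$u[is.finite(sp$death)],
                        link_v = sp$v[is.finite(sp$death)], event = "death"))
  setorder(d, t)
  fwrite(d, path)
  invisible(path)
}

#' @rdname write_flicker_log
#' @param t Time at which to reconstruct the active link set.
#' @export
read_flicker_active_set <- function(path, t) {
  d <- fread(path)
  is_birth <- d$event == "birth" & d$t <= t
  is_death <- d$event == "death" & d$t <= t
  key_b <- paste(d$link_u[is_birth], d$link_v[is_birth])
  key_d <- paste(d$link_u[is_death], d$link_v[is_death])
  cb <- table(key_b); cd <- table(key_d)
  alive <- names(cb)[cb > ifelse(is.na(cd[names(cb)]), 0, cd[names(cb)])]
  if (length(alive) == 0) return(data.table(u = integer(0), v = integer(0)))
  parts <- strsplit(alive, " ")
  data.table(u = as.integer(vapply(parts, `[`, character(1), 1)),
             v = as.integer(vapply(parts, `[`, character(1), 2)))
}
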