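# coactivity: windowed coactivity events, coactivity graphs, filtered
# simplicial complexes (detection and clique-accumulation modes),
# cell-assembly selection and synaptic-failure filtering.

#' Coactivity detection configuration
#'
#' @param w Coactivity window width (s). The standard physiological estimate
#'   is ~200 ms.
#' @param placement `"binned"` (consecutive non-overlapping windows, the
#'   default) or `"sliding"` (overlapping windows advanced by `step`).
#' @param step Step between sliding windows (s); ignored for binned placement.
#' @param jitter Per-window width perturbation fraction `j` in `[0, 1)`:
#'   widths are drawn uniformly from `[w(1-j), w(1+j)]`.
#' @param shift Global shift of the window grid: a number in `[0, w)`, or
#'   `"random"` to draw it uniformly (seeded).
#' @param k_max Detection order: every subset of co-firing cells up to size
#'   `k_max` yields an event (pairs always; `k_max = 2` detects pairs only).
#' @param varpi Integration window (s) for clique accumulation: a clique is
#'   deemed formed at the earliest time by which all of its links have
#'   activated within the trailing window `varpi`. `Inf` accumulates plain
#'   first appearances.
#' @param d_max Maximum simplex dimension kept in constructed complexes
#'   (computing `b0..b2` needs simplexes up to dimension 3; scans typically
#'   use 2).
#' @return A `pc_coactivity_config` list.
#' @export
coactivity_config <- function(w = 0.2, placement = c("binned", "sliding"),
                              step = w / 4, jitter = 0, shift = 0,
                              k_max = 2L, varpi = Inf, d_max = 3L) {
  placement <- match.arg(placement)
  stopifnot(w > 0, jitter >= 0, jitter < 1, varpi >= w, d_max >= 1, k_max >= 2)
  structure(list(w = w, placement = placement, step = step, jitter = jitter,
                 shift = shift, k_max = as.integer(k_max), varpi = varpi,
                 d_max = as.integer(d_max)),
            class = "pc_coactivity_config")
}

#' Detect coactivity events in spike trains
#'
#' Splits the session into coactivity windows and, for every window in which
#' two or more cells fire, emits one event per subset of the co-firing cells
#' up to size `k_max`. Event time is the window centre. Window-width jitter
#' and a global grid shift are applied when configured (seeded).
#'
#' @param spikes A `pc_spikes` object.
#' @param cfg A [coactivity_config()].
#' @param seed RNG seed (used for jitter / random shift).
#' @return A `pc_events` object: `data.table` with columns `time`, `order`
#'   (tuple size) and `cells` (list of sorted cell ids), sorted by time, with
#'   attributes `duration` and `first_spike` (per-cell first spike time).
#' @export
detect_coactivity_events <- function(spikes, cfg = coactivity_config(),
                                     seed = NULL) {
  duration <- spikes$duration
  cell <- rep.int(seq_along(spikes$trains), lengths(spikes$trains))
  tm <- unlist(spikes$trains, use.names = FALSE)
  if (length(tm) == 0) {
    ev <- data.table(time = numeric(0), order = integer(0), cells = list())
    return(as_events(ev, duration, rep(Inf, spikes$n_cells)))
  }
  first_spike <- vapply(spikes$trains,
                        function(s) if (length(s)) s[1] else Inf, numeric(1))
  with_seed(seed, {
    shift <- if (identical(cfg$shift, "random"))
      stats::runif(1, 0, cfg$w) else cfg$shift
    if (cfg$placement == "binned") {
      nw <- ceiling((duration + cfg$w) / (cfg$w * (1 - cfg$jitter))) + 1L
      widths <- if (cfg$jitter > 0)
        stats::runif(nw, cfg$w * (1 - cfg$jitter), cfg$w * (1 + cfg$jitter))
      else rep(cfg$w, nw)
      bounds <- shift - cfg$w + cumsum(c(0, widths))
      bin <- findInterval(tm, bounds)
      centers <- (bounds[-1] + bounds[-length(bounds)]) / 2
      ev <- events_from_groups(cell, bin, centers, cfg$k_max)
    } else {
      starts <- seq(shift - cfg$w, duration, by = cfg$step)
      ord <- order(tm)
      tm_s <- tm[ord]; cell_s <- cell[ord]
      lo <- findInterval(starts, tm_s) + 1L            # first spike >= start
      hi <- findInterval(starts + cfg$w - 1e-12, tm_s) # last spike < start + w
      rows <- list()
      for (k in seq_along(starts)) {
        if (hi[k] < lo[k]) next
        act <- sort(unique(cell_s[lo[k]:hi[k]]))
        if (length(act) < 2) next
        rows[[length(rows) + 1L]] <-
          tuples_for_group(act, starts[k] + cfg$w / 2, cfg$k_max)
      }
      ev <- if (length(rows)) rbindlist(rows)
      else data.table(time = numeric(0), order = integer(0), cells = list())
    }
    as_events(ev, duration, first_spike)
  })
}

tuples_for_group <- function(act, center, k_max) {
  out <- list()
  for (sz in 2:min(length(act), k_max)) {
    combs <- utils::combn(act, sz, simplify = FALSE)
    out[[length(out) + 1L]] <-
      data.table(time = center, order = sz, cells = combs)
  }
  rbindlist(out)
}

events_from_groups <- function(cell, bin, centers, k_max) {
  keep <- bin >= 1 & bin <= length(centers)
  d <- data.table(cell = cell[keep], bin = bin[keep])
  d <- unique(d)
  empty <- data.table(time = numeric(0), order = integer(0), cells = list())
  if (k_max == 2L) {
    # vectorised pair enumeration: self-join within bins
    j <- d[d, on = "bin", allow.cartesian = TRUE]
    j <- j[j$cell < j$i.cell]
    if (nrow(j) == 0) return(empty)
    return(data.table(time = centers[j$bin], order = 2L,
                      cells = Map(c, j$cell, j$i.cell)))
  }
  counts <- d[, .N, by = bin][N >= 2]
  if (nrow(counts) == 0) return(empty)
  d <- d[bin %in% counts$bin]
  setorder(d, bin, cell)
  grp <- split(d$cell, d$bin)
  rbindlist(lapply(names(grp), function(b) {
    tuples_for_group(grp[[b]], centers[as.integer(b)], k_max)
  }))
}

as_events <- function(ev, duration, first_spike) {
  setorder(ev, time)
  structure(ev, duration = duration, first_spike = first_spike,
            class = c("pc_events", class(ev)))
}

#' Build the pairwise coactivity graph
#'
#' One link per distinct pair of cells observed coactive, with its complete
#' activation history: first activation time, all activation times, count and
#' rate (events per minute over the session).
#'
#' @param events A `pc_events` object (order-2 events are used).
#' @param duration Session length (s); defaults to the events attribute.
#' @return A `pc_cograph`: list with `edges` (`data.table` `u`, `v`, `first`,
#'   `count`, `rate`, `times`), `vertices` (`id`, `first`) and `duration`.
#' @export
build_coactivity_graph <- function(events, duration = NULL) {
  duration <- duration %||% attr(events, "duration")
  pairs <- events[events$order == 2L, ]
  if (nrow(pairs) == 0) {
    edges <- data.table(u = integer(0), v = integer(0), first = numeric(0),
                        count = integer(0), rate = numeric(0), times = list())
    verts <- data.table(id = integer(0), first = numeric(0))
  } else {
    u <- vapply(pairs$cells, `[`, integer(1), 1L)
    v <- vapply(pairs$cells, `[`, integer(1), 2L)
    d <- data.table(u = u, v = v, time = pairs$time)
    edges <- d[, list(first = min(time), count = .N,
                      times = list(sort(time))), by = list(u, v)]
    edges[, "rate" := edges$count / (duration / 60)]
    setorder(edges, first)
    fs <- attr(events, "first_spike")
    ids <- sort(unique(c(edges$u, edges$v)))
    vfirst <- vapply(ids, function(i)
      min(edges$first[edges$u == i | edges$v == i]), numeric(1))
    if (!is.null(fs)) vfirst <- pmin(vfirst, fs[ids])
    verts <- data.table(id = ids, first = vfirst)
  }
  structure(list(edges = edges, vertices = verts, duration = duration),
            class = "pc_cograph")
}

#' Filtered complex: container and constructor
#'
#' A filtered simplicial complex: simplexes (sorted vertex tuples) with their
#' first-appearance times, closed under faces, with `t(face) <= t(coface)`.
#' Simplexes are stored in filtration order (time, then dimension, then
#' lexicographic vertex order).
#'
#' @param simplices List of sorted integer vertex vectors.
#' @param times Numeric filtration times, one per simplex.
#' @param check Validate face closure and filtration monotonicity.
#' @return A `pc_complex`: list with `simplices`, `dim`, `time`.
#' @export
filtered_complex <- function(simplices, times, check = TRUE) {
  stopifnot(length(simplices) == length(times))
  simplices <- lapply(simplices, function(v) sort(as.integer(v)))
  dims <- lengths(simplices) - 1L
  if (check) {
    keys <- vapply(simplices, simplex_key, character(1))
    if (anyDuplicated(keys)) stop("duplicate simplexes")
  }
  # order by (time, dim, lexicographic vertices) without string keys
  kmax <- max(c(1L, lengths(simplices)))
  ordcols <- lapply(seq_len(kmax), function(j)
    vapply(simplices, function(v) if (length(v) >= j) v[j] else 0L, integer(1)))
  o <- do.call(order, c(list(times, dims), ordcols))
  fc <- structure(list(simplices = simplices[o], dim = dims[o],
                       time = times[o]),
                  class = "pc_complex")
  if (check) validate_complex(fc)
  fc
}

validate_complex <- function(fc) {
  tmap <- new.env(hash = TRUE)
  keys <- vapply(fc$simplices, simplex_key, character(1))
  for (i in seq_along(keys)) tmap[[keys[i]]] <- fc$time[i]
  for (i in seq_along(fc$simplices)) {
    v <- fc$simplices[[i]]
    if (length(v) == 1) next
    for (k in seq_along(v)) {
      ft <- tmap[[simplex_key(v[-k])]]
      if (is.null(ft)) stop("complex is not closed under faces")
      if (ft > fc$time[i] + 1e-9)
        stop("face appears later than its coface (non-monotone filtration)")
    }
  }
  invisible(fc)
}

#' Number of simplexes per dimension and the density ratios eta_d
#'
#' `eta_d = N_d / choose(N, d + 1)` measures which fraction of all possible
#' `d`-simplexes over `N` cells is realised.
#' @param fc A `pc_complex`.
#' @param n_cells Ensemble size `N`.
#' @return `data.table` with `dim`, `N_d`, `eta_d`.
#' @export
complex_stats <- function(fc, n_cells) {
  dims <- sort(unique(fc$dim))
  data.table(dim = dims,
             N_d = vapply(dims, function(d) sum(fc$dim == d), integer(1)),
             eta_d = vapply(dims, function(d)
               sum(fc$dim == d) / choose(n_cells, d + 1), numeric(1)))
}

#' Build a filtered coactivity complex
#'
#' Two construction modes:
#' \describe{
#' \item{`"detection"`}{from events: a `k`-simplex appears at the first
#'   window in which all `k + 1` cells fired together (requires events
#'   detected with `k_max >= d_max + 1` for simplexes above dimension 1).}
#' \item{`"clique"`}{from the pairwise coactivity graph: a clique of links
#'   appears at the earliest time `t` by which every constituent link has
#'   activated at least once within the look-back window `[t - varpi, t]`;
#'   `varpi = Inf` reduces to the maximum of the links' first-activation
#'   times.}
#' }
#' Face closure is guaranteed by construction in both modes and the dimension
#' is capped at `cfg$d_max`.
#'
#' @param x A `pc_events` (detection mode) or `pc_cograph` (clique mode).
#' @param mode `"clique"` or `"detection"`.
#' @param cfg A [coactivity_config()] (uses `varpi` and `d_max`).
#' @param vertex_times Optional named vector of per-cell first-activity
#'   times; defaults to the times recorded in `x`.
#' @return A `pc_complex`.
#' @export
build_filtered_complex <- function(x, mode = c("clique", "detection"),
                                   cfg = coactivity_config(),
                                   vertex_times = NULL) {
  mode <- match.arg(mode)
  if (mode == "detection") {
    stopifnot(inherits(x, "pc_events"))
    ev <- x[x$order <= cfg$d_max + 1L, ]
    keys <- vapply(ev$cells, simplex_key, character(1))
    d <- data.table(tuple = keys, time = ev$time)
    firsts <- d[, list(time = min(time)), by = tuple]
    simp <- lapply(strsplit(firsts$tuple, " "), as.integer)
    times <- firsts$time
    fs <- vertex_times %||% attr(x, "first_spike")
    ids <- sort(unique(unlist(simp)))
    vt <- if (is.null(fs)) {
      vapply(ids, function(i)
        min(times[vapply(simp, function(s) i %in% s, logical(1))]), numeric(1))
    } else pmin(fs[ids], vapply(ids, function(i)
      min(c(Inf, times[vapply(simp, function(s) i %in% s, logical(1))])),
      numeric(1)))
    simp <- c(as.list(ids), simp)
    times <- c(vt, times)
    filtered_complex(simp, times, check = FALSE)
  } else {
    stopifnot(inherits(x, "pc_cograph"))
    clique_complex_from_graph(x, cfg$varpi, cfg$d_max,
                              vertex_times = vertex_times)
  }
}

clique_complex_from_graph <- function(graph, varpi = Inf, d_max = 3L,
                                      vertex_times = NULL) {
  edges <- graph$edges
  verts <- graph$vertices
  if (!is.null(vertex_times)) {
    verts <- data.table(id = as.integer(names(vertex_times)),
                        first = as.numeric(vertex_times))
  }
  simp <- as.list(verts$id)
  times <- verts$first
  if (nrow(edges) > 0) {
    g <- igraph::graph_from_data_frame(
      data.frame(from = as.character(edges$u), to = as.character(edges$v)),
      directed = FALSE,
      vertices = data.frame(name = as.character(verts$id)))
    vn <- as.integer(igraph::V(g)$name)
    ekey <- pmin(edges$u, edges$v) * 1e5 + pmax(edges$u, edges$v)
    if (is.infinite(varpi)) {
      efirst <- edges$first
      lookup <- function(a, b) {
        idx <- match(pmin(a, b) * 1e5 + pmax(a, b), ekey)
        efirst[idx]
      }
      simp <- c(simp, as.list(edges$u))
      for (i in seq_along(edges$u)) # store edges as pairs
        simp[[length(verts$id) + i]] <- c(min(edges$u[i], edges$v[i]),
                                          max(edges$u[i], edges$v[i]))
      times <- c(times, efirst)
      if (d_max >= 2) {
        tri <- matrix(as.integer(igraph::triangles(g)), nrow = 3)
        if (ncol(tri) > 0) {
          a <- vn[tri[1, ]]; b <- vn[tri[2, ]]; c3 <- vn[tri[3, ]]
          lo <- pmin(a, b, c3); hi <- pmax(a, b, c3); mid <- a + b + c3 - lo - hi
          tt <- pmax(lookup(lo, mid), lookup(lo, hi), lookup(mid, hi))
          tm <- rbind(lo, mid, hi)
          dimnames(tm) <- NULL
          simp <- c(simp, lapply(seq_len(ncol(tm)), function(j) tm[, j]))
          times <- c(times, tt)
        }
      }
      if (d_max >= 3) {
        for (sz in 4:(d_max + 1L)) {
          cl <- igraph::cliques(g, min = sz, max = sz)
          if (length(cl) == 0) next
          vm <- vapply(cl, function(ci) sort(vn[as.integer(ci)]),
                       integer(sz))
          combos <- utils::combn(sz, 2)
          tt <- rep(-Inf, ncol(vm))
          for (p in seq_len(ncol(combos))) {
            tt <- pmax(tt, lookup(vm[combos[1, p], ], vm[combos[2, p], ]))
          }
          simp <- c(simp, lapply(seq_len(ncol(vm)), function(j) vm[, j]))
          times <- c(times, tt)
        }
      }
    } else {
      cl <- igraph::cliques(g, min = 2, max = d_max + 1L)
      etimes <- edges$times
      for (c_i in seq_along(cl)) {
        vv <- sort(vn[as.integer(cl[[c_i]])])
        pr <- utils::combn(vv, 2)
        idx <- match(pr[1, ] * 1e5 + pr[2, ], ekey)
        tt <- clique_formation_time(etimes[idx], varpi)
        if (is.na(tt) || !is.finite(tt)) next
        simp[[length(simp) + 1L]] <- vv
        times <- c(times, tt)
      }
    }
  }
  filtered_complex(simp, times, check = FALSE)
}

# Earliest time t at which every link has an activation in [t - varpi, t].
clique_formation_time <- function(time_lists, varpi) {
  k <- length(time_lists)
  if (k == 1) return(time_lists[[1]][1])
  ev <- data.table(time = unlist(time_lists),
                   link = rep.int(seq_len(k), lengths(time_lists)))
  setorder(ev, time)
  last <- rep(-Inf, k)
  for (r in seq_len(nrow(ev))) {
    last[ev$link[r]] <- ev$time[r]
    if (min(last) >= ev$time[r] - varpi) return(ev$time[r])
  }
  NA_real_
}

#' Select a cell-assembly subgraph
#'
#' Restricts the coactivity graph to its most prominent links, emulating
#' Hebbian selection of frequently coactive cell groups. Mode `xi` keeps the
#' links whose activation rate exceeds the threshold `xi` (events/min); mode
#' `n0` keeps, for every vertex, its `n0` most frequently coactive
#' neighbours (union over vertices). The vertex set is preserved.
#'
#' @param graph A `pc_cograph`.
#' @param xi Rate threshold (events/min); links with `rate > xi` are kept.
#' @param n0 Per-vertex neighbour count (used when `xi` is `NULL`).
#' @return A `pc_cograph` with the restricted edge set.
#' @export
select_assembly_subgraph <- function(graph, xi = NULL, n0 = NULL) {
  edges <- graph$edges
  if (!is.null(xi)) {
    stopifnot(xi >= 0)
    keep <- edges$rate > xi
  } else {
    stopifnot(!is.null(n0), n0 >= 1)
    long <- rbind(data.table(id = edges$u, other = edges$v,
                             count = edges$count, row = seq_len(nrow(edges))),
                  data.table(id = edges$v, other = edges$u,
                             count = edges$count, row = seq_len(nrow(edges))))
    setorder(long, id, -count)
    top <- long[, utils::head(.SD, n0), by = id]
    keep <- seq_len(nrow(edges)) %in% top$row
  }
  structure(list(edges = edges[keep, ], vertices = graph$vertices,
                 duration = graph$duration),
            class = "pc_cograph")
}

#' Synapse model: transmission and readout-response probabilities
#'
#' Probabilities are drawn once per (assembly, link) — transmission — and
#' once per assembly — readout response — from Gaussians with modes `p_star`
#' / `q_star` and SDs `delta_p` / `delta_q`, truncated to `[0, 1]`.
#' `delta = 0` makes them deterministic.
#'
#' @param p_star Mode of the spike-transmission probability.
#' @param delta_p SD of the transmission probability.
#' @param q_star Mode of the readout-response probability.
#' @param delta_q SD of the response probability.
#' @param seed RNG seed for the per-assembly draws.
#' @return A `pc_synapse_model` list.
#' @export
synapse_model <- function(p_star = 1, delta_p = 0, q_star = 1, delta_q = 0,
                          seed = NULL) {
  stopifnot(p_star >= 0, p_star <= 1, q_star >= 0, q_star <= 1,
            delta_p >= 0, delta_q >= 0)
  structure(list(p_star = p_star, delta_p = delta_p,
                 q_star = q_star, delta_q = delta_q, seed = seed),
            class = "pc_synapse_model")
}

rtrunc01 <- function(n, mode, sd) {
  if (sd == 0) return(rep(mode, n))
  x <- stats::rnorm(n, mode, sd)
  while (any(bad <- x < 0 | x > 1))
    x[bad] <- stats::rnorm(sum(bad), mode, sd)
  x
}

#' Apply synaptic transmission/readout failure to coactivity events
#'
#' Cell assemblies are modelled as the maximal cliques of the pairwise
#' coactivity graph. Each link (synapse) feeds the readout neuron of one
#' assembly — the first maximal clique containing it; a pairwise event is
#' transmitted with that (assembly, link)'s probability and registered with
#' the assembly's response probability, both drawn once from truncated
#' Gaussians. Only registered events feed complex construction. With
#' `p_star = q_star = 1` and zero spreads the filter is the identity.
#'
#' @param events A `pc_events` object (order-2 events are filtered; higher
#'   orders are dropped, as assemblies are clique-based).
#' @param model A [synapse_model()].
#' @param assemblies Optional list of integer vertex vectors; defaults to the
#'   maximal cliques of the coactivity graph built from `events`.
#' @param seed RNG seed for the per-event Bernoulli draws.
#' @return A `pc_events` object with the surviving pairwise events.
#' @export
apply_synaptic_filter <- function(events, model, assemblies = NULL,
                                  seed = NULL) {
  pairs <- events[events$order == 2L, ]
  duration <- attr(events, "duration")
  fs <- attr(events, "first_spike")
  if (nrow(pairs) == 0) return(as_events(pairs, duration, fs))
  if (is.null(assemblies)) {
    graph <- build_coactivity_graph(events, duration)
    g <- igraph::graph_from_data_frame(
      data.frame(from = as.character(graph$edges$u),
                 to = as.character(graph$edges$v)), directed = FALSE)
    mc <- igraph::max_cliques(g)
    vn <- as.integer(igraph::V(g)$name)
    assemblies <- lapply(mc, function(cl) sort(vn[as.integer(cl)]))
  }
  with_seed(model$seed, {
    qs <- rtrunc01(length(assemblies), model$q_star, model$delta_q)
    # per-(assembly, link) transmission probabilities
    pl <- rbindlist(lapply(seq_along(assemblies), function(ai) {
      vv <- assemblies[[ai]]
      if (length(vv) < 2) return(NULL)
      pr <- utils::combn(vv, 2)
      data.table(lk = paste(pr[1, ], pr[2, ]), asm = ai,
                 p = rtrunc01(ncol(pr), model$p_star, model$delta_p))
    }))
  })
  pl[, "q" := qs[pl$asm]]
  # one synapse per link: the first assembly containing the pair
  pl <- pl[!duplicated(pl$lk), ]
  u <- vapply(pairs$cells, `[`, integer(1), 1L)
  v <- vapply(pairs$cells, `[`, integer(1), 2L)
  idx <- match(paste(u, v), pl$lk)
  pq <- pl$p[idx] * pl$q[idx]
  pq[is.na(pq)] <- 0
  with_seed(seed, {
    keep <- stats::runif(nrow(pairs)) < pq
    as_events(pairs[keep, ], duration, fs)
  })
}

#' Write / read a filtered complex as plain text
#'
#' One simplex per line: `t_sigma v0 v1 ... vk`, whitespace-delimited, times
#' with six decimals. The reader accepts lines in any order.
#' @param fc A `pc_complex`.
#' @param path File path.
#' @export
write_complex <- function(fc, path) {
  lines <- vapply(seq_along(fc$simplices), function(i)
    paste(sprintf("%.6f", fc$time[i]),
          paste(fc$simplices[[i]], collapse = " ")), character(1))
  writeLines(lines, path)
  invisible(path)
}

#' @rdname write_complex
#' @export
read_complex <- function(path) {
  lines <- readLines(path)
  lines <- lines[nzchar(trimws(lines))]
  parts <- strsplit(trimws(lines), "\\s+")
  times <- vapply(parts, function(p) as.numeric(p[1]), numeric(1))
  simp <- lapply(parts, function(p) as.integer(p[-1]))
  filtered_complex(simp, times, check = TRUE)
}
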