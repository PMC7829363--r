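# Shared fixtures: reference triangulations, canonical study conditions, and
# small simulated sessions cached across tests.

# --- reference triangulated surfaces ---------------------------------------

# minimal 7-vertex triangulation of the 2-torus (14 triangles)
torus_triangulation <- function() {
  tri <- list()
  for (i in 0:6) {
    tri[[length(tri) + 1L]] <- sort(c(i, (i + 1) %% 7, (i + 3) %% 7) + 1L)
    tri[[length(tri) + 1L]] <- sort(c(i, (i + 2) %% 7, (i + 3) %% 7) + 1L)
  }
  tri
}

# boundary of the octahedron (triangulated 2-sphere)
octahedron_boundary <- function() {
  list(c(1, 2, 3), c(1, 3, 4), c(1, 4, 5), c(1, 5, 2),
       c(6, 2, 3), c(6, 3, 4), c(6, 4, 5), c(6, 5, 2))
}

# square annulus: outer square 1-4, inner square 5-8, eight ring triangles
annulus_triangulation <- function() {
  list(c(1, 2, 5), c(2, 6, 5), c(2, 3, 6), c(3, 7, 6),
       c(3, 4, 7), c(4, 8, 7), c(4, 1, 8), c(1, 5, 8))
}

# boundary of the (d+1)-simplex: a triangulated d-sphere
simplex_boundary <- function(d) {
  utils::combn(seq_len(d + 2), d + 1, simplify = FALSE)
}

# --- random filtered complexes (for persistence <-> rank equivalence) ------

# Random clique-ish filtered complex with <= ~max_simplices simplexes:
# random graph on n vertices with random edge times; cliques appear at the
# max of their edge times (a valid monotone filtration).
random_filtered_complex <- function(n = 12, p = 0.35, d_max = 3) {
  adj <- matrix(stats::runif(n * n) < p, n, n)
  adj[lower.tri(adj, diag = TRUE)] <- FALSE
  et <- matrix(stats::runif(n * n, 0, 10), n, n)
  simp <- as.list(seq_len(n))
  times <- stats::runif(n, 0, 1)
  g <- igraph::graph_from_adjacency_matrix(adj + t(adj) > 0, mode = "undirected")
  cl <- igraph::cliques(g, min = 2, max = d_max + 1)
  for (ci in cl) {
    vv <- sort(as.integer(ci))
    pr <- utils::combn(vv, 2)
    tt <- max(vapply(seq_len(ncol(pr)), function(j)
      et[pr[1, j], pr[2, j]], numeric(1)), times[vv])
    simp[[length(simp) + 1L]] <- vv
    times <- c(times, tt)
  }
  filtered_complex(simp, times, check = FALSE)
}

# sub-complex at filtration value t
truncate_complex <- function(fc, t) {
  keep <- fc$time <= t
  filtered_complex(fc$simplices[keep], fc$time[keep], check = FALSE)
}

# --- canonical study conditions --------------------------------------------

# 1.5 x 1.5 m arena with a central 60 x 60 cm hole: the canonical
# "arena with a hole" environment used by the simulation experiments.
canonical_env <- function() {
  make_environment(150, 150, holes = list(
    list(type = "rect", center = c(75, 75), width = 60, height = 60)))
}

# cache expensive shared fixtures for the duration of one test run
.fixture_cache <- new.env(parent = emptyenv())
cached <- function(name, expr) {
  if (is.null(.fixture_cache[[name]])) .fixture_cache[[name]] <- force(expr)
  .fixture_cache[[name]]
}

# canonical 25-min theta-modulated session at (s, f, N) = (23, 28, 350)
canonical_session <- function() {
  cached("canonical_session", {
    env <- canonical_env()
    traj <- simulate_trajectory(env, 1500, seed = 101)
    map <- sample_place_field_map(env, seed = 102)
    spikes <- generate_spike_trains(map, traj,
                                    modulation_config(theta_on = TRUE),
                                    seed = 103)
    events <- detect_coactivity_events(spikes, coactivity_config(), seed = 104)
    list(env = env, traj = traj, map = map, spikes = spikes, events = events)
  })
}

# small quick-learning setup for cheap paired experiments
quick_env <- function() make_environment(100, 100)
quick_traj <- function() cached("quick_traj",
  simulate_trajectory(quick_env(), 600, seed = 7))

# tiny spike-train object from a list of per-cell spike times
spikes_from_list <- function(trains, duration) {
  structure(list(trains = trains, duration = duration,
                 n_cells = length(trains)),
            class = "pc_spikes")
}

# hand-built pc_events object from a list of list(t = ..., cells = ...)
as_events_for_test <- function(rows, duration) {
  ev <- data.table::data.table(
    time = vapply(rows, function(r) r$t, numeric(1)),
    order = vapply(rows, function(r) length(r$cells), integer(1)),
    cells = lapply(rows, function(r) sort(as.integer(r$cells))))
  fs <- rep(Inf, max(unlist(lapply(rows, function(r) r$cells))))
  for (r in rows) fs[r$cells] <- pmin(fs[r$cells], r$t)
  topomap:::as_events(ev, duration, fs)
}

# synthetic link-activation stream: n_links links, regular or Poisson
# reactivation with mean interval dt_react over a session
synthetic_link_events <- function(n_links = 100, dt_react = 30,
                                  duration = 1500, regular = FALSE) {
  data.table::rbindlist(lapply(seq_len(n_links), function(i) {
    start <- stats::runif(1, 0, dt_react)
    tt <- if (regular) seq(start, duration, by = dt_react)
          else sort(stats::runif(stats::rpois(1, duration / dt_react), 0, duration))
    if (length(tt) == 0) return(NULL)
    data.table::data.table(u = i, v = i + n_links, time = tt)
  }))
}
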