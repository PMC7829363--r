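test_that("binned detection groups spikes by coactivity window", {
  sp <- spikes_from_list(list(0.05, 0.12), 1)
  ev <- detect_coactivity_events(sp, coactivity_config(w = 0.2))
  expect_equal(nrow(ev), 1L)
  expect_equal(ev$cells[[1]], c(1L, 2L))
  expect_equal(ev$order, 2L)

  sp2 <- spikes_from_list(list(0.05, 0.40), 1)
  ev2 <- detect_coactivity_events(sp2, coactivity_config(w = 0.2))
  expect_equal(nrow(ev2), 0L)

  # higher detection orders: every subset up to k_max
  sp3 <- spikes_from_list(list(0.01, 0.05, 0.12), 1)
  ev3 <- detect_coactivity_events(sp3, coactivity_config(w = 0.2, k_max = 3))
  expect_equal(sum(ev3$order == 2), 3L)
  expect_equal(sum(ev3$order == 3), 1L)

  # sliding placement catches pairs split across bin boundaries
  sp4 <- spikes_from_list(list(0.19, 0.21), 1)
  expect_equal(nrow(detect_coactivity_events(sp4, coactivity_config(w = 0.2))), 0L)
  evs <- detect_coactivity_events(sp4, coactivity_config(w = 0.2,
                                                         placement = "sliding",
                                                         step = 0.05))
  expect_gt(nrow(evs), 0L)
})

test_that("window jitter and shifts barely perturb event statistics", {
  # bound frozen from a 20-seed oracle run on a 10-min raster: relative
  # deviation of pair-event counts at j = 0.5 stayed below 4%
  env <- quick_env()
  traj <- quick_traj()
  map <- sample_place_field_map(env, N = 80, seed = 31)
  spikes <- generate_spike_trains(map, traj, seed = 32)
  n0 <- nrow(detect_coactivity_events(spikes, coactivity_config(jitter = 0)))
  for (k in 1:5) {
    nj <- nrow(detect_coactivity_events(
      spikes, coactivity_config(jitter = 0.5, shift = "random"), seed = k))
    expect_lt(abs(nj - n0) / n0, 0.1)
  }
})

test_that("the coactivity graph aggregates complete link histories", {
  empty <- detect_coactivity_events(spikes_from_list(list(0.1), 1),
                                    coactivity_config())
  g0 <- build_coactivity_graph(empty)
  expect_equal(nrow(g0$edges), 0L)

  # a pair recurring five times, another once
  trains <- list(c(0.1, 1.1, 2.1, 3.1, 4.1), c(0.15, 1.15, 2.15, 3.15, 4.15),
                 c(2.18))
  sp <- spikes_from_list(trains, 60)
  ev <- detect_coactivity_events(sp, coactivity_config(w = 0.2))
  g <- build_coactivity_graph(ev)
  e12 <- g$edges[g$edges$u == 1 & g$edges$v == 2, ]
  expect_equal(e12$count, 5L)
  expect_equal(e12$first, min(ev$time))
  expect_equal(e12$rate, 5 / 1) # events per minute over 60 s
  # edge count equals the brute-force number of distinct pairs
  pairs <- unique(vapply(ev$cells[ev$order == 2], paste, character(1),
                         collapse = "-"))
  expect_equal(nrow(g$edges), length(pairs))
})

test_that("clique accumulation dates simplexes by their slowest link", {
  ev <- as_events_for_test(
    list(list(t = 1, cells = c(1, 2)), list(t = 2, cells = c(2, 3)),
         list(t = 3, cells = c(1, 3))), duration = 10)
  g <- build_coactivity_graph(ev)
  fc <- build_filtered_complex(g, "clique", coactivity_config(d_max = 2))
  tri <- which(fc$dim == 2)
  expect_length(tri, 1L)
  expect_equal(fc$simplices[[tri]], c(1L, 2L, 3L))
  expect_equal(fc$time[tri], 3)
  # detection mode sees no triple event, hence no 2-simplex
  fcd <- build_filtered_complex(ev, "detection", coactivity_config(d_max = 2))
  expect_equal(sum(fcd$dim == 2), 0L)
})

test_that("finite integration windows gate clique formation", {
  # links activate at 1, 2, 13; with varpi = 5 the triangle can only form
  # once all three links fire within one look-back window
  ev <- as_events_for_test(
    list(list(t = 1, cells = c(1, 2)), list(t = 2, cells = c(2, 3)),
         list(t = 13, cells = c(1, 3)),
         list(t = 14, cells = c(1, 2)), list(t = 15, cells = c(2, 3))),
    duration = 30)
  g <- build_coactivity_graph(ev)
  fc5 <- build_filtered_complex(g, "clique",
                                coactivity_config(varpi = 5, d_max = 2))
  tri <- which(fc5$dim == 2)
  expect_equal(fc5$time[tri], 15)
  # varpi = Inf reduces to plain first-appearance accumulation
  fcI <- build_filtered_complex(g, "clique", coactivity_config(d_max = 2))
  expect_equal(fcI$time[which(fcI$dim == 2)], 13)
})

test_that("constructed complexes satisfy closure, monotonicity and growth", {
  env <- quick_env()
  traj <- quick_traj()
  map <- sample_place_field_map(env, N = 80, seed = 33)
  spikes <- generate_spike_trains(map, traj, seed = 34)
  ev <- detect_coactivity_events(spikes, coactivity_config(k_max = 3))
  g <- build_coactivity_graph(ev)
  fc <- build_filtered_complex(g, "clique", coactivity_config(d_max = 3))
  expect_silent(topomap:::validate_complex(fc))
  fcd <- build_filtered_complex(ev, "detection", coactivity_config(d_max = 2))
  expect_silent(topomap:::validate_complex(fcd))
  # growth monotonicity: the complex at t is contained in the complex at t'
  keys <- vapply(fc$simplices, paste, character(1), collapse = " ")
  for (tt in c(100, 300, 600)) {
    expect_true(all(keys[fc$time <= tt] %in% keys[fc$time <= 600]))
  }
  # every simultaneously detected simplex is also an accumulated clique
  kd <- vapply(fcd$simplices, paste, character(1), collapse = " ")
  expect_true(all(kd %in% keys))
  # eta_1 matches brute-force pair counting
  st <- complex_stats(fc, 80)
  expect_equal(st$N_d[st$dim == 1], nrow(g$edges))
  expect_equal(st$eta_d[st$dim == 1], nrow(g$edges) / choose(80, 2))
})

test_that("assembly selection restricts links as configured", {
  env <- quick_env()
  traj <- quick_traj()
  map <- sample_place_field_map(env, N = 80, seed = 35)
  spikes <- generate_spike_trains(map, traj, seed = 36)
  ev <- detect_coactivity_events(spikes, coactivity_config())
  g <- build_coactivity_graph(ev)
  expect_equal(nrow(select_assembly_subgraph(g, xi = 0)$edges), nrow(g$edges))
  expect_equal(nrow(select_assembly_subgraph(g, xi = max(g$edges$rate))$edges), 0L)
  gn <- select_assembly_subgraph(g, n0 = 3)
  expect_lt(nrow(gn$edges), nrow(g$edges))
  expect_identical(gn$vertices, g$vertices)
  # every kept link is among some endpoint's top-3 partners
  for (r in seq_len(min(nrow(gn$edges), 20))) {
    u <- gn$edges$u[r]; v <- gn$edges$v[r]; cnt <- gn$edges$count[r]
    topu <- sort(g$edges$count[g$edges$u == u | g$edges$v == u],
                 decreasing = TRUE)[3]
    topv <- sort(g$edges$count[g$edges$u == v | g$edges$v == v],
                 decreasing = TRUE)[3]
    expect_true(cnt >= min(topu, topv, na.rm = TRUE))
  }
})

test_that("degree-capped selection yields heavier-tailed degrees than rate thresholding", {
  env <- quick_env()
  skews <- vapply(1:6, function(k) {
    traj <- simulate_trajectory(env, 300, seed = 40 + k)
    map <- sample_place_field_map(env, N = 100, seed = 50 + k)
    spikes <- generate_spike_trains(map, traj, seed = 60 + k)
    g <- build_coactivity_graph(detect_coactivity_events(spikes, coactivity_config()))
    gn <- select_assembly_subgraph(g, n0 = 4)
    # match edge counts by choosing xi at the same quantile
    xi <- stats::quantile(g$edges$rate, 1 - nrow(gn$edges) / nrow(g$edges))
    gx <- select_assembly_subgraph(g, xi = xi)
    deg <- function(gg) {
      d <- table(c(gg$edges$u, gg$edges$v))
      (mean((d - mean(d))^3) / stats::sd(d)^3)
    }
    deg(gn) - deg(gx)
  }, numeric(1))
  expect_gt(mean(skews), 0)
})

test_that("synaptic filtering thins events at the configured probabilities", {
  ev <- as_events_for_test(
    lapply(seq_len(5000), function(i) list(t = i * 0.01, cells = c(1, 2))),
    duration = 50)
  ident <- apply_synaptic_filter(ev, synapse_model(1, 0, 1, 0), seed = 1)
  expect_equal(nrow(ident), nrow(ev))
  none <- apply_synaptic_filter(ev, synapse_model(0, 0, 1, 0), seed = 1)
  expect_equal(nrow(none), 0L)
  # binomial oracle: retained fraction ~ p * q within 3 binomial SDs
  p <- 0.6; q <- 0.8
  kept <- nrow(apply_synaptic_filter(ev, synapse_model(p, 0, q, 0), seed = 2))
  expect_lt(abs(kept / 5000 - p * q), 3 * sqrt(p * q * (1 - p * q) / 5000))
})
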