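test_that("infinite decay reproduces the perennial growing graph", {
  set.seed(70)
  le <- synthetic_link_events(n_links = 50, dt_react = 20, duration = 600)
  tl <- evolve_flicker_timeline(le, flicker_config(tau = Inf), duration = 600)
  firsts <- le[, list(first = min(time)), by = list(u, v)]
  for (tt in c(50, 300, 599)) {
    act <- active_links_at(tl, tt)
    expect_equal(nrow(act), sum(firsts$first <= tt))
  }
  expect_true(all(is.infinite(tl$spans$death)))
  # quenched mode agrees in the tau -> Inf limit
  tlq <- evolve_flicker_timeline(le, flicker_config(mode = "quenched",
                                                    tau = Inf), duration = 600)
  expect_equal(tlq$spans, tl$spans)
})

test_that("quenched decay kills a link exactly tau after its last activation", {
  le <- data.table::data.table(u = 1L, v = 2L, time = c(10, 40))
  tl <- evolve_flicker_timeline(le, flicker_config(mode = "quenched", tau = 50),
                                duration = 1000)
  expect_equal(tl$spans$birth, 10)
  expect_equal(tl$spans$death, 90) # rejuvenated at 40, dies at 40 + 50
  # single activation: alive exactly on [t0, t0 + tau]
  tl1 <- evolve_flicker_timeline(data.table::data.table(u = 1L, v = 2L, time = 10),
                                 flicker_config(mode = "quenched", tau = 50),
                                 duration = 1000)
  expect_equal(tl1$spans$birth, 10)
  expect_equal(tl1$spans$death, 60)
})

test_that("exponential decay without reactivation follows the survival law", {
  # one activation per link: lifetimes must be Exp(tau)
  le <- data.table::data.table(u = seq_len(2000), v = seq_len(2000) + 2000,
                               time = rep(0, 2000))
  tl <- evolve_flicker_timeline(le, flicker_config(tau = 40, seed = 71),
                                duration = 1e6)
  lt <- tl$spans$death - tl$spans$birth
  ks <- stats::ks.test(lt, "pexp", rate = 1 / 40)
  expect_gt(ks$p.value, 0.01)
})

test_that("reactivation extends effective lifetimes beyond the proper decay time", {
  # oracle run (regular 30 s reactivation, tau = 90 s, 300 links) gave
  # tau_e(2)/tau ~ 3.2 with a substantial survivor pool
  set.seed(72)
  le <- synthetic_link_events(n_links = 300, dt_react = 30, duration = 1500,
                              regular = TRUE)
  tl <- evolve_flicker_timeline(le, flicker_config(tau = 90, seed = 73),
                                duration = 1500)
  st <- lifetime_statistics(tl, orders = 2)
  expect_gt(st$order2$tau_e / 90, 2)
  expect_lt(st$order2$tau_e / 90, 4.5)
  expect_gt(st$order2$survivor_fraction, 0.1)
  expect_equal(st$reactivation_interval, 30, tolerance = 0.01)
})

test_that("triangle lifetimes are bounded by their links' common spans", {
  # hand-built spans: triangle alive only while all three links are
  le <- data.table::data.table(u = c(1L, 1L, 2L), v = c(2L, 3L, 3L),
                               time = c(0, 5, 8))
  tl <- evolve_flicker_timeline(le, flicker_config(mode = "quenched", tau = 10),
                                duration = 100)
  lt3 <- topomap:::triangle_lifetimes(tl)
  expect_equal(lt3$birth, 8)  # last link appears
  expect_equal(lt3$death, 10) # first link dies at 0 + 10
  st <- lifetime_statistics(tl)
  expect_lte(st$order3$tau_e, min(tl$spans$death - tl$spans$birth))
})

test_that("Betti series match an independent cycle-rank oracle", {
  # bipartite (triangle-free) active graphs: b1 = E - V + C exactly
  set.seed(74)
  for (rep in 1:5) {
    nu <- 6; nv <- 6
    pairs <- expand.grid(u = 1:nu, v = nu + (1:nv))
    pick <- pairs[stats::runif(nrow(pairs)) < 0.3, ]
    if (nrow(pick) == 0) next
    le <- data.table::data.table(u = pick$u, v = pick$v,
                                 time = stats::runif(nrow(pick), 0, 10))
    tl <- evolve_flicker_timeline(le, flicker_config(tau = Inf), duration = 100)
    ser <- betti_time_series(tl, times = c(5, 50), d_max = 2)
    for (i in 1:2) {
      tt <- ser$t[i]
      act <- active_links_at(tl, tt)
      vs <- tl$vertices$id[tl$vertices$first <= tt]
      g <- igraph::graph_from_data_frame(
        data.frame(from = act$u, to = act$v), directed = FALSE,
        vertices = data.frame(name = vs))
      comp <- igraph::components(g)$no
      expect_equal(ser$b0[i], comp)
      expect_equal(ser$b1[i], nrow(act) - length(vs) + comp)
    }
  }
})

test_that("constant active sets give constant Betti series", {
  le <- data.table::data.table(u = c(1L, 2L, 3L), v = c(2L, 3L, 1L),
                               time = c(1, 1, 1))
  tl <- evolve_flicker_timeline(le, flicker_config(tau = Inf), duration = 50)
  ser <- betti_time_series(tl, times = c(10, 20, 30), d_max = 2)
  expect_true(all(ser$b0 == 1) && all(ser$b1 == 0)) # filled triangle
})

test_that("stability summaries score topological fluctuation", {
  ok <- data.frame(t = 1:10, b0 = rep(1, 10), b1 = rep(1, 10))
  bad <- data.frame(t = 1:10, b0 = rep(2, 10), b1 = rep(1, 10))
  expect_equal(stability_summary(ok, c(1, 1))$fluctuation_fraction, 0)
  expect_equal(stability_summary(bad, c(1, 1))$fluctuation_fraction, 1)
  mixed <- data.frame(t = 1:10, b0 = c(rep(2, 4), rep(1, 6)), b1 = rep(1, 10))
  expect_equal(stability_summary(mixed, c(1, 1), formation_time = 5)$fluctuation_fraction, 0)
  th <- stability_summary(list(`10` = bad, `20` = mixed, `30` = ok), c(1, 1),
                          formation_time = 5)
  expect_equal(th$threshold, 20)
})

test_that("fluctuation decreases with slower decay, and quenched flickers more", {
  set.seed(75)
  frac_for <- function(le, mode, tau, seed) {
    tl <- evolve_flicker_timeline(le, flicker_config(mode = mode, tau = tau,
                                                     seed = seed),
                                  duration = 600)
    ser <- betti_time_series(tl, times = seq(200, 600, by = 50), d_max = 2)
    ref <- c(1, 0)
    mean(!(ser$b0 == ref[1] & ser$b1 == ref[2]))
  }
  # dense synthetic link set whose full graph is connected and loop-filled:
  # a triangulated band (fan strip: chi = 1, so (b0, b1) = (1, 0) when whole)
  le0 <- data.table::rbindlist(lapply(1:12, function(i) {
    data.table::data.table(u = c(i, i, i + 1L), v = c(i + 1L, i + 100L, i + 100L),
                           time = NA_real_)
  }))
  gaps <- c(20, 35, 50)
  d_exp <- d_quench <- numeric(0)
  for (k in 1:6) {
    le <- data.table::copy(le0)
    le <- le[rep(seq_len(nrow(le)), each = 12)]
    le[, "time" := stats::runif(nrow(le), 0, 600)]
    f_small <- frac_for(le, "exponential", 40, seed = k)
    f_large <- frac_for(le, "exponential", 160, seed = k)
    d_exp <- c(d_exp, f_small - f_large)
    f_q <- frac_for(le, "quenched", 40, seed = k)
    d_quench <- c(d_quench, f_q - f_small)
  }
  expect_gte(mean(d_exp), 0)    # slower decay stabilises
  expect_gte(mean(d_quench), 0) # fixed lifetimes flicker at least as much
})

test_that("random-control rewiring matches the empirical link statistics", {
  set.seed(76)
  le <- synthetic_link_events(n_links = 200, dt_react = 20, duration = 1000)
  tl <- evolve_flicker_timeline(le, flicker_config(mode = "random", tau = 60,
                                                   seed = 77),
                                duration = 1000)
  # birth counts comparable to the empirical activation counts
  expect_equal(nrow(tl$spans) > 0, TRUE)
  n_acts <- nrow(le)
  n_births <- sum(vapply(tl$activations$times, length, integer(1)))
  expect_lt(abs(n_births - n_acts) / n_acts, 0.2)
})

test_that("replay injection reuses previously active links", {
  set.seed(78)
  le <- synthetic_link_events(n_links = 40, dt_react = 50, duration = 600)
  expect_equal(as.data.frame(inject_replays(le, rate = 0)),
               as.data.frame(le[order(time)]))
  aug <- inject_replays(le, rate = 6, seed = 79, duration = 600)
  expect_gt(nrow(aug), nrow(le))
  new_rows <- data.table::fsetdiff(aug, le[order(time)])
  firsts <- le[, list(first = min(time)), by = list(u, v)]
  for (r in seq_len(nrow(new_rows))) {
    f <- firsts[firsts$u == new_rows$u[r] & firsts$v == new_rows$v[r], ]
    expect_equal(nrow(f), 1L)
    expect_lt(f$first, new_rows$time[r])
  }
})

test_that("replays damp topological fluctuations on average", {
  set.seed(80)
  diffs <- numeric(0)
  for (k in 1:6) {
    # a chain of links whose decay occasionally disconnects the graph
    le <- data.table::rbindlist(lapply(1:40, function(i) {
      tt <- sort(stats::runif(stats::rpois(1, 10), 0, 600))
      if (length(tt) == 0) tt <- stats::runif(1, 0, 600)
      data.table::data.table(u = i, v = i + 1L, time = tt)
    }))
    frac <- function(events, seed) {
      tl <- evolve_flicker_timeline(events, flicker_config(tau = 60, seed = seed),
                                    duration = 600)
      ser <- betti_time_series(tl, times = seq(300, 600, by = 60), d_max = 1)
      mean(ser$b0 != 1)
    }
    base <- frac(le, 90 + k)
    with_rep <- frac(inject_replays(le, rate = 30, seed = 90 + k,
                                    duration = 600), 90 + k)
    diffs <- c(diffs, base - with_rep)
  }
  expect_gte(mean(diffs), 0)
})

test_that("the event log reconstructs every active set exactly", {
  set.seed(81)
  le <- synthetic_link_events(n_links = 30, dt_react = 40, duration = 500)
  tl <- evolve_flicker_timeline(le, flicker_config(tau = 50, seed = 82),
                                duration = 500)
  path <- withr::local_tempfile(fileext = ".csv")
  write_flicker_log(tl, path)
  for (tt in c(100, 250, 400)) {
    direct <- active_links_at(tl, tt)
    replayed <- read_flicker_active_set(path, tt)
    key <- function(d) sort(paste(d$u, d$v))
    expect_identical(key(replayed), key(direct))
  }
})

test_that("windowed timelines renew their simplex pool at the varpi timescale", {
  sess <- canonical_session()
  le <- topomap:::link_events_from(sess$events)
  tl <- evolve_flicker_timeline(le, flicker_config(mode = "windowed",
                                                   varpi = 600),
                                duration = 1500)
  times <- seq(700, 1450, by = 75)
  sets <- lapply(times, function(tt) {
    a <- active_links_at(tl, tt)
    paste(a$u, a$v)
  })
  counts <- lengths(sets)
  expect_lt(stats::sd(counts) / mean(counts), 0.15)
  jacc <- function(a, b) length(intersect(a, b)) / length(union(a, b))
  near <- mean(vapply(seq_len(length(sets) - 1), function(i)
    jacc(sets[[i]], sets[[i + 1]]), numeric(1)))
  far <- jacc(sets[[1]], sets[[length(sets)]]) # lag > varpi
  expect_gt(near, far)
})
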