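# homology: Z2 simplicial homology, persistence over the first-appearance
# filtration, learning-time extraction, simplicial paths and Alexandrov
# neighborhoods.

#' Betti numbers over Z2
#'
#' `b_k = dim ker(boundary_k) - dim im(boundary_{k+1})` computed by Gaussian
#' elimination of the boundary matrices over GF(2).
#'
#' @param x A `pc_complex`, or a list of sorted integer vertex vectors.
#' @param d_max Highest dimension reported; defaults to the complex's top
#'   dimension.
#' @return Integer vector `(b0, b1, ..., b_dmax)`.
#' @examples
#' octa <- lapply(list(c(1,2,3), c(1,3,4), c(1,4,5), c(1,5,2),
#'                     c(6,2,3), c(6,3,4), c(6,4,5), c(6,5,2)), identity)
#' betti_numbers(close_under_faces(octa))  # sphere: 1 0 1
#' @export
betti_numbers <- function(x, d_max = NULL) {
  simp <- if (inherits(x, "pc_complex")) x$simplices else
    lapply(x, function(v) sort(as.integer(v)))
  if (length(simp) == 0) return(integer(max(0, d_max %||% 0) + 1))
  betti_z2_cpp(simp, if (is.null(d_max)) -1L else as.integer(d_max))
}

#' Close a set of simplexes under faces
#'
#' Adds every missing face of every simplex. When `times` are supplied a face
#' receives the minimum time over its cofaces (preserving filtration
#' monotonicity); otherwise all times are zero.
#' @param simplices List of integer vertex vectors.
#' @param times Optional filtration times.
#' @return A `pc_complex`.
#' @export
close_under_faces <- function(simplices, times = NULL) {
  times <- times %||% rep(0, length(simplices))
  tmap <- new.env(hash = TRUE)
  add <- function(v, t) {
    key <- simplex_key(v)
    old <- tmap[[key]]
    if (is.null(old) || old > t) tmap[[key]] <- t
    if (length(v) > 1)
      for (k in seq_along(v)) add(v[-k], t)
  }
  for (i in seq_along(simplices))
    add(sort(as.integer(simplices[[i]])), times[i])
  keys <- ls(tmap)
  filtered_complex(lapply(strsplit(keys, " "), as.integer),
                   vapply(keys, function(k) tmap[[k]], numeric(1)),
                   check = FALSE)
}

#' Boundary matrix of a complex in dimension d
#'
#' Dense 0/1 matrix of the GF(2) boundary operator from `d`-simplexes
#' (columns) to `(d-1)`-simplexes (rows); intended for small complexes and
#' verification.
#' @param fc A `pc_complex`.
#' @param d Dimension (>= 1).
#' @return 0/1 matrix.
#' @export
boundary_matrix <- function(fc, d) {
  rows <- which(fc$dim == d - 1L)
  cols <- which(fc$dim == d)
  ridx <- stats::setNames(seq_along(rows),
                          vapply(fc$simplices[rows], simplex_key, character(1)))
  m <- matrix(0L, length(rows), length(cols))
  for (j in seq_along(cols)) {
    v <- fc$simplices[[cols[j]]]
    for (k in seq_along(v)) {
      r <- ridx[[simplex_key(v[-k])]]
      if (is.null(r)) stop("complex is not closed under faces")
      m[r, j] <- 1L
    }
  }
  m
}

#' Persistence barcode of a filtered complex
#'
#' Standard boundary-matrix reduction over GF(2) in filtration order (ties
#' broken by dimension, then lexicographic vertex order). At every filtration
#' value `t` the number of intervals containing `t` equals the Betti number
#' of the sub-complex at `t`.
#'
#' @param fc A `pc_complex` (monotone filtration).
#' @param d_max Highest homology dimension reported.
#' @param drop_empty Drop zero-length intervals (birth time equals death
#'   time); they carry no homology at any filtration value.
#' @return A `pc_barcode`: `data.table` with columns `dim`, `birth`, `death`
#'   (`Inf` for essential classes).
#' @export
persistence_barcode <- function(fc, d_max = NULL, drop_empty = TRUE) {
  stopifnot(inherits(fc, "pc_complex"))
  if (length(fc$simplices) == 0) {
    bc <- data.table(dim = integer(0), birth = numeric(0), death = numeric(0))
    return(structure(bc, class = c("pc_barcode", class(bc))))
  }
  if (is.unsorted(fc$time)) stop("non-monotone filtration")
  pairs <- persistence_z2_cpp(fc$simplices)
  bc <- data.table(dim = pairs[, 1],
                   birth = fc$time[pairs[, 2]],
                   death = ifelse(is.na(pairs[, 3]), Inf, fc$time[pairs[, 3]]))
  if (!is.null(d_max)) bc <- bc[bc$dim <= d_max, ]
  if (drop_empty) bc <- bc[bc$death > bc$birth, ]
  setorder(bc, dim, birth)
  structure(bc, class = c("pc_barcode", class(bc)))
}

#' Betti numbers at a filtration value, from a barcode
#'
#' @param barcode A [persistence_barcode()] result.
#' @param t Filtration value.
#' @param d_max Highest dimension reported.
#' @return Integer vector `(b0, ..., b_dmax)`.
#' @export
betti_at <- function(barcode, t, d_max = 2) {
  vapply(0:d_max, function(d)
    sum(barcode$dim == d & barcode$birth <= t & barcode$death > t), integer(1))
}

#' Learning time of a filtered complex or Betti timeline
#'
#' The minimal time `T_min` after which the low Betti numbers (`b0`, `b1`
#' for planar environments) equal the environment's reference values for the
#' whole remaining session. For a filtered complex this is the latest of the
#' last spurious interval's death and the essential classes' births, provided
#' the final topology is correct; for a sampled Betti timeline it is the
#' earliest sample after which all samples are correct.
#'
#' @param x A `pc_complex`, `pc_barcode`, or a `data.frame` timeline with
#'   columns `t`, `b0`, `b1`.
#' @param reference Reference Betti numbers, e.g.
#'   `env$reference_betti` (`b0`, `b1`).
#' @param horizon Optional cap (s): a learning time beyond the horizon counts
#'   as failure.
#' @return A `pc_learning` list: `t_min` (s, `NA` on failure), `success`,
#'   `final_betti`.
#' @export
learning_time <- function(x, reference, horizon = NULL) {
  reference <- as.integer(reference[1:2])
  if (is.data.frame(x) && !inherits(x, "pc_barcode") && all(c("t", "b0", "b1") %in% names(x))) {
    ok <- x$b0 == reference[1] & x$b1 == reference[2]
    if (!length(ok) || !ok[length(ok)]) {
      return(structure(list(t_min = NA_real_, success = FALSE,
                            final_betti = c(utils::tail(x$b0, 1), utils::tail(x$b1, 1))),
                       class = "pc_learning"))
    }
    bad <- which(!ok)
    t_min <- if (length(bad)) x$t[max(bad) + 1L] else x$t[1]
    final <- reference
  } else {
    bc <- if (inherits(x, "pc_barcode")) x else persistence_barcode(x)
    low <- bc[bc$dim <= 1L, ]
    final <- c(sum(low$dim == 0 & is.infinite(low$death)),
               sum(low$dim == 1 & is.infinite(low$death)))
    if (!identical(as.integer(final), reference)) {
      return(structure(list(t_min = NA_real_, success = FALSE,
                            final_betti = final), class = "pc_learning"))
    }
    finite_deaths <- low$death[is.finite(low$death)]
    essential_births <- low$birth[is.infinite(low$death)]
    t_min <- max(c(finite_deaths, essential_births, 0))
  }
  success <- TRUE
  if (!is.null(horizon) && (is.na(t_min) || t_min > horizon)) success <- FALSE
  structure(list(t_min = if (success) t_min else NA_real_, success = success,
                 final_betti = final),
            class = "pc_learning")
}

#' Simplicial path traced by a trajectory across a field map
#'
#' The sequence of maximal simplexes (sets of concurrently active place
#' fields, i.e. fields containing the current position) entered along the
#' trajectory, with entry times; reports the shared-face fraction between
#' consecutive simplexes and whether the path is closed (identical first and
#' last simplex).
#'
#' @param traj A `pc_trajectory`.
#' @param map A `pc_field_map`.
#' @param stride Evaluate every `stride`-th trajectory sample.
#' @return A `pc_simplicial_path`: list with `simplices`, `entry_times`,
#'   `contiguity` (fraction of consecutive pairs sharing at least one
#'   vertex), `closed`.
#' @export
simplicial_path <- function(traj, map, stride = 1L) {
  idx <- seq(1L, nrow(traj), by = stride)
  r2 <- (map$size / 2)^2
  out <- list(); entry <- numeric(0); last_key <- NULL
  for (k in idx) {
    d2 <- (traj$x[k] - map$centers[, 1])^2 + (traj$y[k] - map$centers[, 2])^2
    act <- which(d2 <= r2)
    if (length(act) == 0) next
    key <- simplex_key(act)
    if (is.null(last_key) || key != last_key) {
      out[[length(out) + 1L]] <- act
      entry <- c(entry, traj$t[k])
      last_key <- key
    }
  }
  shared <- if (length(out) >= 2)
    vapply(seq_len(length(out) - 1), function(i)
      length(intersect(out[[i]], out[[i + 1]])) > 0, logical(1))
  else logical(0)
  structure(list(simplices = out, entry_times = entry,
                 contiguity = if (length(shared)) mean(shared) else NA_real_,
                 closed = length(out) >= 2 &&
                   identical(out[[1]], out[[length(out)]])),
            class = "pc_simplicial_path")
}

#' Alexandrov neighborhood of a simplex
#'
#' In the finite (Alexandrov) topology on a simplicial complex, the minimal
#' open neighborhood of a simplex is the set of its cofaces, including the
#' simplex itself — the basis of the "memory space" reading of the coactivity
#' complex.
#'
#' @param fc A `pc_complex`.
#' @param simplex Integer vertex vector; must be present in the complex.
#' @return List of simplexes (integer vectors).
#' @export
alexandrov_neighborhood <- function(fc, simplex) {
  simplex <- sort(as.integer(simplex))
  keys <- vapply(fc$simplices, simplex_key, character(1))
  if (!(simplex_key(simplex) %in% keys)) stop("simplex not in complex")
  fc$simplices[vapply(fc$simplices, function(s) all(simplex %in% s), logical(1))]
}

#' Write / read a barcode as delimited text
#'
#' Lines `dim,birth,death` with `inf` for immortal classes.
#' @param barcode A `pc_barcode`.
#' @param path File path.
#' @export
write_barcode <- function(barcode, path) {
  d <- data.table(dim = barcode$dim, birth = barcode$birth,
                  death = ifelse(is.infinite(barcode$death), "inf",
                                 as.character(barcode$death)))
  fwrite(d, path)
  invisible(path)
}

#' @rdname write_barcode
#' @export
read_barcode <- function(path) {
  d <- fread(path, colClasses = list(character = "death"))
  bc <- data.table(dim = as.integer(d$dim), birth = as.numeric(d$birth),
                   death = ifelse(d$death == "inf", Inf, suppressWarnings(as.numeric(d$death))))
  structure(bc, class = c("pc_barcode", class(bc)))
}
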