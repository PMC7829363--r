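# Internal helpers shared across modules.

#' @importFrom Rcpp sourceCpp
#' @importFrom data.table data.table as.data.table := .N .SD rbindlist setorder setnames fwrite fread
#' @useDynLib topomap, .registration = TRUE
NULL

# Evaluate `expr` under a fixed RNG seed without disturbing the caller's
# random stream. seed = NULL leaves the stream untouched.
with_seed <- function(seed, expr) {
  if (is.null(seed)) return(eval.parent(substitute(expr)))
  if (!exists(".Random.seed", envir = globalenv(), inherits = FALSE)) stats::runif(1)
  old <- get(".Random.seed", envir = globalenv())
  on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  set.seed(seed)
  eval.parent(substitute(expr))
}

# Draw n sub-seeds (< 2^31) from a master seed, for seeding nested
# simulations deterministically.
derive_seeds <- function(seed, n) {
  if (is.null(seed)) return(rep(list(NULL), n))
  with_seed(seed, as.list(sample.int(.Machine$integer.max - 1L, n, replace = FALSE)))
}

# Log-normal sample parameterised by its mode and standard deviation
# (positive support, unimodal). sd = 0 degenerates to the mode.
rlnorm_mode_sd <- function(n, mode, sd) {
  stopifnot(mode > 0, sd >= 0)
  if (sd == 0) return(rep(mode, n))
  # mode = exp(mu - v), sd^2 = (e^v - 1) e^(2mu + v)  with v = sigma_ln^2
  # => (sd/mode)^2 = (e^v - 1) e^(3v); solve for v
  ratio2 <- (sd / mode)^2
  f <- function(v) (exp(v) - 1) * exp(3 * v) - ratio2
  v <- stats::uniroot(f, c(1e-12, 20), tol = 1e-12)$root
  stats::rlnorm(n, meanlog = log(mode) + v, sdlog = sqrt(v))
}

# Canonical string key for a sorted vertex tuple.
simplex_key <- function(v) paste(v, collapse = " ")

`%||%` <- function(a, b) if (is.null(a)) b else a
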