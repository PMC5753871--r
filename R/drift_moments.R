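#' Drift-time parameters
#'
#' Container for the two diffusion-scaled drift times of the split model:
#' `t1` is the drift accumulated on the modern branch (from the common
#' ancestor to the present, in units of generations / (2 Ne of the modern
#' population)) and `t2` the drift accumulated on the ancient branch (from
#' the common ancestor to the death of the sampled individuals, scaled by
#' the ancient effective size). `t2 = 0` is the continuity hypothesis: the
#' ancient panel belongs to a population directly ancestral to the modern
#' one.
#'
#' @param t1,t2 Non-negative finite drift times in diffusion units.
#' @return An object of class `drift_params`.
#' @examples
#' drift_params(0.02, 0.05)
#' @export
drift_params <- function(t1, t2) {
  if (!is.numeric(t1) || !is.numeric(t2) || length(t1) != 1L || length(t2) != 1L)
    stop("t1 and t2 must be single numeric values", call. = FALSE)
  if (!is.finite(t1) || !is.finite(t2) || t1 < 0 || t2 < 0)
    stop("drift times must be finite and >= 0", call. = FALSE)
  structure(list(t1 = t1, t2 = t2), class = "drift_params")
}

#' @export
print.drift_params <- function(x, ...) {
  cat(sprintf("drift parameters: t1 = %g, t2 = %g (diffusion units)\n", x$t1, x$t2))
  invisible(x)
}

check_order <- function(n) {
  if (length(n) != 1L || !is.numeric(n) || !is.finite(n) || n < 1 || n != round(n))
    stop("moment order n must be a single integer >= 1", call. = FALSE)
  as.integer(n)
}

#' Moment generators of the Wright-Fisher diffusion
#'
#' `forward_generator()` builds the tridiagonal matrix whose exponential
#' evolves the vector of binomial moments E[Y^k (1-Y)^(n-k)] forward in time
#' under pure drift (ancestor to ancient population). `backward_generator()`
#' builds its backward-in-time counterpart, which evolves the moments from
#' the modern population back to the common ancestor; it corresponds to
#' time-reversal of the neutral diffusion under the 1/z frequency-spectrum
#' weighting of the ancestral allele frequency.
#'
#' Rows and columns are indexed by derived-allele count k = 0..n. The
#' forward matrix has sub-diagonal i(i-1)/2, diagonal -i(n-i) and
#' super-diagonal (n-i)(n-i-1)/2; the backward matrix replaces (n-i) by
#' (n-i+1) in the last two.
#'
#' @param n Number of sampled chromosomes (moment order), integer >= 1.
#' @return A dense (n+1) x (n+1) base matrix.
#' @examples
#' forward_generator(2)
#' backward_generator(2)
#' @export
forward_generator <- function(n) {
  n <- check_order(n)
  i <- 0:n
  Q <- matrix(0, n + 1L, n + 1L)
  Q[cbind(i + 1L, i + 1L)] <- -i * (n - i)
  if (n >= 1) {
    i <- 1:n
    Q[cbind(i + 1L, i)] <- i * (i - 1) / 2       # sub-diagonal
    i <- 0:(n - 1L)
    Q[cbind(i + 1L, i + 2L)] <- (n - i) * (n - i - 1) / 2  # super-diagonal
  }
  Q
}

#' @rdname forward_generator
#' @export
backward_generator <- function(n) {
  n <- check_order(n)
  i <- 0:n
  Q <- matrix(0, n + 1L, n + 1L)
  Q[cbind(i + 1L, i + 1L)] <- -i * (n - i + 1)
  i <- 1:n
  Q[cbind(i + 1L, i)] <- i * (i - 1) / 2
  i <- 0:(n - 1L)
  Q[cbind(i + 1L, i + 2L)] <- (n - i + 1) * (n - i) / 2
  Q
}

#' Seed moment vector at the modern frequency
#'
#' Entry k (k = 0..n) is x^k (1-x)^(n-k): the binomial moments of a point
#' mass at the modern derived-allele frequency x. This is the initial
#' condition for the backward stage of the moment evolution.
#'
#' @param n Moment order (number of chromosomes).
#' @param x Modern derived-allele frequency; must lie in [0, 1], and strictly
#'   inside (0, 1) for inference (boundary values are permitted for simulator
#'   internals only).
#' @return Numeric vector of length n + 1.
#' @examples
#' seed_moments(2, 0.5)
#' @export
seed_moments <- function(n, x) {
  n <- check_order(n)
  if (any(!is.finite(x)) || any(x < 0) || any(x > 1))
    stop("x must lie in [0, 1]", call. = FALSE)
  k <- 0:n
  if (length(x) == 1L) x^k * (1 - x)^(n - k)
  else outer(x, k, function(x, k) x^k * (1 - x)^(n - k))
}

#' Operator cache for moment exponentials
#'
#' Creates a small cache that stores, per distinct order n at fixed drift
#' times, the matrix exponentials exp(Q t2), exp(Qd t1) and their product.
#' Used to share the (cheap but repeated) exponentiations across sites and
#' across likelihood evaluations at the same parameter values. Results are
#' bit-identical to the uncached path; hit/miss counters are kept for
#' diagnostics.
#'
#' @return An environment of class `moment_cache`.
#' @examples
#' cache <- moment_cache()
#' p1 <- binomial_moments(4, 0.3, drift_params(0.01, 0.02), cache = cache)
#' p2 <- binomial_moments(4, 0.3, drift_params(0.01, 0.02), cache = cache)
#' cache_stats(cache)  # one miss, one hit
#' @export
moment_cache <- function() {
  e <- new.env(parent = emptyenv())
  e$store <- new.env(parent = emptyenv())
  e$hits <- 0L
  e$misses <- 0L
  class(e) <- "moment_cache"
  e
}

#' @rdname moment_cache
#' @param cache A `moment_cache`.
#' @export
cache_stats <- function(cache) {
  stopifnot(inherits(cache, "moment_cache"))
  list(hits = cache$hits, misses = cache$misses,
       entries = length(ls(cache$store)))
}

expm_dense <- function(A) {
  # scaling-and-squaring on the dense matrix; Q-down is non-normal so
  # eigendecomposition routes are avoided deliberately
  as.matrix(Matrix::expm(Matrix::Matrix(A, sparse = FALSE)))
}

#' Moment-evolution operators at fixed drift times
#'
#' Returns `E2 = exp(Q t2)`, `E1 = exp(Qd t1)` and their product
#' `M = E2 E1` for order `n`, consulting/filling `cache` when supplied.
#'
#' @inheritParams binomial_moments
#' @return List with elements `M`, `E1`, `E2`, `Q`, `Qd`.
#' @export
moment_operator <- function(n, params, cache = NULL) {
  n <- check_order(n)
  stopifnot(inherits(params, "drift_params"))
  key <- sprintf("%d|%.17g|%.17g", n, params$t1, params$t2)
  if (!is.null(cache)) {
    stopifnot(inherits(cache, "moment_cache"))
    hit <- get0(key, envir = cache$store, inherits = FALSE)
    if (!is.null(hit)) {
      cache$hits <- cache$hits + 1L
      return(hit)
    }
    cache$misses <- cache$misses + 1L
  }
  Q <- forward_generator(n)
  Qd <- backward_generator(n)
  E1 <- if (params$t1 == 0) diag(n + 1L) else expm_dense(Qd * params$t1)
  E2 <- if (params$t2 == 0) diag(n + 1L) else expm_dense(Q * params$t2)
  out <- list(M = E2 %*% E1, E1 = E1, E2 = E2, Q = Q, Qd = Qd)
  if (any(!is.finite(out$M)))
    stop(sprintf("matrix exponentiation produced non-finite entries (n=%d, t1=%g, t2=%g)",
                 n, params$t1, params$t2), call. = FALSE)
  if (!is.null(cache)) assign(key, out, envir = cache$store)
  out
}

#' Binomial moments of the ancient allele frequency
#'
#' Computes p_k = E[Y^k (1-Y)^(n-k)] for k = 0..n, where Y is the allele
#' frequency in the ancient population conditional on the modern frequency
#' x, under the split-drift model with drift times (t1, t2). Obtained as
#' exp(Q t2) exp(Qd t1) h_n(x) by dense matrix exponentiation.
#'
#' Tiny negative entries from round-off are clamped to zero; the vector is
#' then renormalized so that sum(choose(n,k) p_k) = 1, but only if the
#' pre-clamp departure from 1 is below 1e-6 — a larger departure signals a
#' genuinely broken computation and raises an error rather than being
#' silently repaired.
#'
#' @param n Moment order (chromosomes sampled in the ancient population).
#' @param x Modern derived-allele frequency in (0, 1).
#' @param params A [drift_params()] object.
#' @param cache Optional [moment_cache()].
#' @return Numeric vector p of length n + 1, entries in [0, 1].
#' @examples
#' # with t1 = t2 = 0 the moments are the seed vector
#' all.equal(binomial_moments(3, 0.4, drift_params(0, 0)), seed_moments(3, 0.4))
#' @export
binomial_moments <- function(n, x, params, cache = NULL) {
  n <- check_order(n)
  if (length(x) != 1L || !is.finite(x) || x <= 0 || x >= 1)
    stop("x must lie strictly in (0, 1)", call. = FALSE)
  op <- moment_operator(n, params, cache)
  p <- drop(op$M %*% seed_moments(n, x))
  norm <- sum(choose(n, 0:n) * p)
  if (!is.finite(norm) || abs(norm - 1) >= 1e-6)
    stop(sprintf("moment vector failed normalization check (sum=%.8g, n=%d, t1=%g, t2=%g)",
                 norm, n, params$t1, params$t2), call. = FALSE)
  p <- pmin(pmax(p, 0), 1)
  p / sum(choose(n, 0:n) * p)
}

#' Sampling probabilities of derived-allele counts in an ancient sample
#'
#' P_k = choose(n, k) p_k: the probability of observing k derived alleles
#' among n chromosomes drawn from the ancient population, given modern
#' frequency x and drift times (t1, t2).
#'
#' @inheritParams binomial_moments
#' @return Numeric probability vector of length n + 1 summing to 1.
#' @examples
#' # no drift: plain binomial sampling at x
#' all.equal(sampling_probs(5, 0.3, drift_params(0, 0)), dbinom(0:5, 5, 0.3))
#' @export
sampling_probs <- function(n, x, params, cache = NULL) {
  p <- binomial_moments(n, x, params, cache)
  choose(n, 0:n) * p
}
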