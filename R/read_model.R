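#' Genotype likelihood of ancient read counts
#'
#' Probability of observing `d` derived and `a` ancestral reads at a site in
#' one diploid individual with true genotype `g` (0 = homozygous ancestral,
#' 1 = heterozygous, 2 = homozygous derived), under binomial sampling of
#' reads with a symmetric per-read error `eps`: a truly derived base is read
#' as ancestral (and vice versa) with probability `eps`. The per-read
#' derived probabilities are eps, 1/2 and 1 - eps for g = 0, 1, 2. `eps`
#' absorbs both sequencing error and postmortem damage.
#'
#' @param a,d Non-negative integer counts of ancestral / derived reads
#'   (vectorized).
#' @param g Genotype, in {0, 1, 2}.
#' @param eps Per-read error probability, in [0, 0.5).
#' @return Likelihood value(s), including the binomial coefficient
#'   choose(a + d, d).
#' @examples
#' genotype_likelihood(1, 1, 1, 0.01)   # 2 * 0.5^2 = 0.5
#' genotype_likelihood(2, 0, 0, 0.1)    # (1 - 0.1)^2 = 0.81
#' @export
genotype_likelihood <- function(a, d, g, eps) {
  if (any(g != 0 & g != 1 & g != 2)) stop("genotype must be 0, 1 or 2", call. = FALSE)
  check_eps(eps)
  if (any(a < 0) || any(d < 0) || any(a != round(a)) || any(d != round(d)))
    stop("read counts must be non-negative integers", call. = FALSE)
  p <- c(eps, 0.5, 1 - eps)[g + 1]
  choose(a + d, d) * p^d * (1 - p)^a
}

check_eps <- function(eps) {
  if (any(!is.finite(eps)) || any(eps < 0) || any(eps >= 0.5))
    stop("eps must lie in [0, 0.5)", call. = FALSE)
  invisible(eps)
}

#' Allele-count weights for one site
#'
#' Collapses the read data of m diploid individuals at one site into the
#' weights W_k (k = 0..2m): the sum, over genotype configurations with total
#' derived count k, of the product over individuals of choose(2, g_i) times
#' the genotype likelihood of their reads. The site likelihood is then
#' sum_k W_k p_{2m,k}; the choose(2, g_i) factors supply all combinatorics
#' (by Vandermonde's identity their configuration sum is choose(2m, k), so
#' no extra binomial coefficient multiplies the moment vector).
#'
#' Computed by sequential convolution of the per-individual triplets
#' (P(R|0), 2 P(R|1), P(R|2)) in O(m^2) time rather than by enumerating the
#' 3^m genotype configurations.
#'
#' @param a,d Integer vectors of length m: ancestral / derived read counts
#'   per individual.
#' @param eps Error probability, a single shared value or one per
#'   individual.
#' @return Numeric vector W of length 2m + 1 with attribute `"m"`.
#' @examples
#' count_weights(0, 1, 0.1)       # (0.1, 1, 0.9)
#' count_weights(0, 0, 0.01)      # uncovered individual: (1, 2, 1)
#' @export
count_weights <- function(a, d, eps) {
  m <- length(a)
  if (length(d) != m || m < 1) stop("a and d must have equal length >= 1", call. = FALSE)
  if (length(eps) == 1L) eps <- rep(eps, m)
  if (length(eps) != m) stop("eps must have length 1 or m", call. = FALSE)
  check_eps(eps)
  W <- 1
  for (i in seq_len(m)) {
    tri <- c(genotype_likelihood(a[i], d[i], 0, eps[i]),
             2 * genotype_likelihood(a[i], d[i], 1, eps[i]),
             genotype_likelihood(a[i], d[i], 2, eps[i]))
    W <- conv3(W, tri)
  }
  structure(W, m = m)
}

# linear convolution of a vector with a length-3 kernel
conv3 <- function(w, tri) {
  n <- length(w)
  out <- numeric(n + 2L)
  out[1:n] <- w * tri[1]
  out[2:(n + 1L)] <- out[2:(n + 1L)] + w * tri[2]
  out[3:(n + 2L)] <- out[3:(n + 2L)] + w * tri[3]
  out
}

#' Log-likelihood of one site
#'
#' Combines the allele-count weights W (order 2m) with the binomial moment
#' vector p of the same order at the site's modern frequency:
#' log( sum_k W_k p_k ). Returns -Inf (with a warning) if the sum
#' underflows to zero.
#'
#' @param W Weights from [count_weights()].
#' @param p Moments from [binomial_moments()] of matching order.
#' @return Single log-likelihood value.
#' @export
site_loglik <- function(W, p) {
  if (length(W) != length(p))
    stop("order mismatch between count weights and moment vector", call. = FALSE)
  s <- sum(W * p)
  if (!is.finite(s) || s <= 0) {
    warning("site likelihood underflowed to zero; returning -Inf")
    return(-Inf)
  }
  log(s)
}
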