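# Independent oracles used across the suite. These deliberately avoid the
# code paths they check: brute-force enumeration instead of convolution,
# discrete-chain linear algebra instead of the diffusion-moment engine.

# W_k by explicit enumeration of all 3^m genotype configurations with
# multiplicity weights choose(2, g); the convolution in count_weights()
# must reproduce this exactly.
count_weights_enum <- function(a, d, eps) {
  m <- length(a)
  if (length(eps) == 1L) eps <- rep(eps, m)
  W <- numeric(2 * m + 1)
  grid <- as.matrix(expand.grid(rep(list(0:2), m)))
  for (r in seq_len(nrow(grid))) {
    g <- grid[r, ]
    contrib <- prod(vapply(seq_len(m), function(i)
      choose(2, g[i]) * genotype_likelihood(a[i], d[i], g[i], eps[i]),
      numeric(1)))
    k <- sum(g)
    W[k + 1] <- W[k + 1] + contrib
  }
  W
}

# Exact posterior binomial moments on a discrete Wright-Fisher chain:
# ancestral frequency with prior ~ 1/z on the segregating states, propagated
# tau1 generations to the modern state (conditioning on X = x), and tau2
# generations along the ancient branch. N1, N2 are the diploid sizes of the
# two branches. Dense matrix powers; independent of the moment engine.
wf_grid_moments <- function(n, x_idx, N1, tau1, N2, tau2) {
  S1 <- 2 * N1
  zs <- (1:(S1 - 1)) / S1
  P1 <- outer(zs, 1:(S1 - 1), function(z, j) dbinom(j, S1, z))
  Pt1 <- diag(S1 - 1)
  for (g in seq_len(tau1)) Pt1 <- Pt1 %*% P1
  prior <- 1 / zs
  w <- prior * Pt1[, x_idx]
  w <- w / sum(w)                     # posterior over ancestral z given x
  # ancient branch: map ancestral states onto the size-N2 chain and run
  # forward tau2 generations (including absorption)
  S2 <- 2 * N2
  ys <- (0:S2) / S2
  Pz <- outer(zs, 0:S2, function(z, j) dbinom(j, S2, z))  # one resize step
  P2 <- outer(ys, 0:S2, function(y, j) dbinom(j, S2, y))
  Pt2 <- Pz
  for (g in seq_len(tau2 - 1)) Pt2 <- Pt2 %*% P2
  fy <- drop(w %*% Pt2)               # distribution of ancient frequency
  vapply(0:n, function(k) sum(fy * ys^k * (1 - ys)^(n - k)), numeric(1))
}

# forward-only Monte-Carlo oracle: P(k derived among n) after tau
# generations of drift from known frequency x (t1 = 0 case)
wf_mc_sampling_probs <- function(n, x, Ne, tau, reps) {
  z <- wf_forward(rep(x, reps), Ne, tau)
  k <- rbinom(reps, n, z)
  tabulate(k + 1L, nbins = n + 1L) / reps
}


# reduced deterministic start grid used in replicate studies (multi-start
# agreement at the default grid is itself under test elsewhere)
fast_opts <- function(...) fit_options(t_starts = c(0.01, 0.2),
                                       eps_starts = 0.005, ...)
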