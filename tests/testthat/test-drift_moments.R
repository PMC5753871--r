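test_that("generator matrices match the printed entry formulas", {
  # n = 1: every forward entry formula vanishes
  expect_equal(forward_generator(1), matrix(0, 2, 2))
  expect_equal(forward_generator(2),
               rbind(c(0, 1, 0), c(0, -1, 0), c(0, 1, 0)))
  expect_equal(forward_generator(3)[2, ], c(0, -2, 1, 0))
  expect_equal(backward_generator(1), rbind(c(0, 1), c(0, -1)))
  expect_equal(backward_generator(2),
               rbind(c(0, 3, 0), c(0, -2, 1), c(0, 1, -2)))
  # structure: tridiagonal with non-negative off-diagonals
  for (n in c(4, 9)) {
    for (Q in list(forward_generator(n), backward_generator(n))) {
      expect_true(all(Q[abs(row(Q) - col(Q)) > 1] == 0))
      expect_true(all(Q[abs(row(Q) - col(Q)) == 1] >= 0))
    }
  }
  expect_error(forward_generator(0), "integer >= 1")
  expect_error(backward_generator(2.5), "integer >= 1")
})

test_that("seed vector holds the point-mass moments and obeys the binomial theorem", {
  expect_equal(seed_moments(2, 0.5), c(0.25, 0.25, 0.25))
  expect_equal(seed_moments(1, 0.3), c(0.7, 0.3))
  for (n in c(1, 5, 17)) for (x in c(0.02, 0.4, 0.97)) {
    h <- seed_moments(n, x)
    expect_equal(sum(choose(n, 0:n) * h), 1, tolerance = 1e-12)
  }
  expect_error(seed_moments(3, 1.2), "\\[0, 1\\]")
})

test_that("order-1 moments follow the closed form and carry no t2 information", {
  # exp(Qd t) for n = 1 is ((1, 1 - e^-t), (0, e^-t)) since Qd^2 = -Qd
  for (t1 in c(0, 0.05, 0.8)) {
    E <- as.matrix(Matrix::expm(backward_generator(1) * t1))
    expect_equal(E, rbind(c(1, 1 - exp(-t1)), c(0, exp(-t1))), tolerance = 1e-12)
    for (t2 in c(0, 0.3, 5)) {
      p <- binomial_moments(1, 0.3, drift_params(t1, t2))
      expect_equal(p, c(1 - 0.3 * exp(-t1), 0.3 * exp(-t1)), tolerance = 1e-10)
    }
  }
})

test_that("zero drift returns the seed vector and binomial sampling", {
  for (n in c(1, 4, 12)) for (x in c(0.1, 0.5, 0.9)) {
    expect_equal(binomial_moments(n, x, drift_params(0, 0)),
                 seed_moments(n, x), tolerance = 1e-12)
    expect_equal(sampling_probs(n, x, drift_params(0, 0)),
                 dbinom(0:n, n, x), tolerance = 1e-12)
  }
})

test_that("moments stay normalized and the drift mean is a martingale", {
  for (n in c(2, 7, 23, 40)) for (x in c(0.01, 0.37, 0.99)) {
    for (t1 in c(0, 0.4, 2)) {
      base_mean <- NULL
      for (t2 in c(0, 0.07, 1, 2)) {
        p <- binomial_moments(n, x, drift_params(t1, t2))
        expect_true(all(p >= 0 & p <= 1))
        expect_equal(sum(choose(n, 0:n) * p), 1, tolerance = 1e-8)
        mean_k <- sum((0:n) / n * choose(n, 0:n) * p)
        if (is.null(base_mean)) base_mean <- mean_k
        # forward drift preserves the mean frequency
        expect_equal(mean_k, base_mean, tolerance = 1e-8)
      }
    }
  }
})

test_that("moment vectors of adjacent orders are mutually consistent", {
  # p_{n-1,k} = p_{n,k} + p_{n,k+1}
  params <- drift_params(0.03, 0.11)
  for (n in c(2, 5, 11, 20)) for (x in c(0.08, 0.6)) {
    pn <- binomial_moments(n, x, params)
    pm <- binomial_moments(n - 1, x, params)
    expect_equal(pm, pn[-length(pn)] + pn[-1], tolerance = 1e-9)
  }
})

test_that("heterozygosity decays monotonically in t2 and vanishes at large t2", {
  x <- 0.5
  het <- vapply(c(0, 0.1, 0.5, 1, 2, 8), function(t2)
    binomial_moments(2, x, drift_params(0, t2))[2], numeric(1))
  expect_true(all(diff(het) <= 1e-12))
  expect_lt(het[length(het)], 1e-3)
  # E[Y(1-Y)] decays exactly as e^{-t2} when t1 = 0
  expect_equal(het[2] / het[1], exp(-0.1), tolerance = 1e-8)
})

test_that("forward-stage sampling probabilities match Wright-Fisher Monte Carlo", {
  # t1 = 0: drift from known frequency x for 2 Ne t2 generations
  set.seed(401)
  n <- 20; x <- 0.3; Ne <- 1000; t2 <- 0.05; reps <- 200000
  emp <- wf_mc_sampling_probs(n, x, Ne, tau = round(2 * Ne * t2), reps = reps)
  thy <- sampling_probs(n, x, drift_params(0, t2))
  se <- sqrt(pmax(thy * (1 - thy), 1e-12) / reps)
  expect_true(all(abs(emp - thy) <= 3 * se + 1e-9))
})

test_that("joint (t1 > 0, t2 > 0) moments match the exact discrete-chain oracle", {
  # small discrete WF chain, 1/z ancestral prior; diffusion error is O(1/N)
  N1 <- 150; tau1 <- 6   # t1 = 0.02
  N2 <- 150; tau2 <- 15  # t2 = 0.05
  x_idx <- 90            # x = 0.3
  for (n in c(1, 2, 6)) {
    grid <- wf_grid_moments(n, x_idx, N1, tau1, N2, tau2)
    thy <- binomial_moments(n, x_idx / (2 * N1),
                            drift_params(tau1 / (2 * N1), tau2 / (2 * N2)))
    expect_equal(grid, thy, tolerance = 0.02)
  }
})

test_that("the operator cache is transparent and counts hits", {
  cache <- moment_cache()
  params <- drift_params(0.02, 0.05)
  p1 <- binomial_moments(8, 0.25, params, cache = cache)
  s <- cache_stats(cache)
  expect_equal(s$misses, 1L)
  p2 <- binomial_moments(8, 0.25, params, cache = cache)
  expect_equal(cache_stats(cache)$hits, 1L)
  expect_identical(p1, p2)
  # changed parameters are a different key, not a stale hit
  p3 <- binomial_moments(8, 0.25, drift_params(0.02, 0.06), cache = cache)
  expect_equal(cache_stats(cache)$misses, 2L)
  expect_false(identical(p1, p3))
  # cached and uncached results are bit-identical
  expect_identical(p1, binomial_moments(8, 0.25, params))
})

test_that("invalid moment inputs are rejected", {
  expect_error(drift_params(-0.1, 0), "finite and >= 0")
  expect_error(drift_params(0, Inf), "finite and >= 0")
  expect_error(binomial_moments(3, 0, drift_params(0, 0)), "strictly in")
  expect_error(binomial_moments(3, 1, drift_params(0, 0)), "strictly in")
})
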