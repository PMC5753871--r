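make_sim <- function(L = 400, m = 3, coverage = 2, seed = 5, ...)
  simulate_dataset(L = L, m = m, coverage = coverage, seed = seed, ...)

test_that("dataset construction filters and validates", {
  x <- c(0.5, 0, 0.3, 1, 0.8)
  anc <- matrix(1, 5, 2); der <- matrix(0, 5, 2)
  anc[3, ] <- 0  # site 3 segregating but uncovered
  ds <- continuity_dataset(x, anc, der)
  expect_equal(n_sites(ds), 2L)
  expect_equal(attr(ds, "n_dropped_nonseg"), 2L)
  expect_equal(attr(ds, "n_dropped_noreads"), 1L)
  expect_error(continuity_dataset(0.5, matrix(-1), matrix(1)), "non-negative")
  expect_error(continuity_dataset(c(0, 1), matrix(1, 2, 1), matrix(0, 2, 1)),
               "no usable sites")
})

test_that("dataset log-likelihood matches per-site composition and closed forms", {
  # single site, one derived read: log(eps + (1 - 2 eps) x e^{-t1})
  eps <- 0.03; x <- 0.4; t1 <- 0.06
  ds <- continuity_dataset(x, matrix(0), matrix(1))
  for (t2 in c(0, 0.5)) {
    expect_equal(as.numeric(data_loglik(ds, drift_params(t1, t2), eps)),
                 log(eps + (1 - 2 * eps) * x * exp(-t1)), tolerance = 1e-10)
  }
  # sum over sites equals sum of site_loglik
  ds <- make_sim(L = 60, m = 2, seed = 9)
  params <- drift_params(0.02, 0.05)
  persite <- vapply(seq_len(n_sites(ds)), function(l)
    site_loglik(count_weights(ds$anc[l, ], ds$der[l, ], 0.01),
                binomial_moments(4, ds$x[l], params)), numeric(1))
  expect_equal(as.numeric(data_loglik(ds, params, 0.01)), sum(persite),
               tolerance = 1e-8)
})

test_that("duplicating a dataset doubles the log-likelihood", {
  ds <- make_sim(L = 150, seed = 13)
  dd <- continuity_dataset(c(ds$x, ds$x), rbind(ds$anc, ds$anc),
                           rbind(ds$der, ds$der))
  p <- drift_params(0.05, 0.02)
  expect_equal(as.numeric(data_loglik(dd, p, 0.01)),
               2 * as.numeric(data_loglik(ds, p, 0.01)), tolerance = 1e-9)
})

test_that("with no drift and no error the likelihood is binomial genotype sampling", {
  set.seed(17)
  L <- 200; m <- 2
  x <- runif(L, 0.1, 0.9)
  G <- matrix(rbinom(L * m, 2, rep(x, m)), L, m)
  reads <- simulate_reads(G, coverage = 3, eps = 1e-9, contamination = 0)
  keep <- rowSums(reads$anc + reads$der) > 0
  ds <- continuity_dataset(x, reads$anc, reads$der)
  # eps ~ 0: reads are deterministic given genotypes; the likelihood reduces
  # to HWE genotype sampling at x for the genotypes compatible with the reads
  ll <- as.numeric(data_loglik(ds, drift_params(0, 0), eps = 1e-9))
  ref <- 0
  for (l in which(keep)) {
    lsite <- 0
    for (i in 1:m) {
      a <- reads$anc[l, i]; d <- reads$der[l, i]
      pg <- dbinom(0:2, 2, x[l])
      lik_g <- c(as.numeric(d == 0), 0.5^(a + d) * choose(a + d, d),
                 as.numeric(a == 0))
      lsite <- lsite + log(sum(pg * lik_g))
    }
    ref <- ref + lsite
  }
  expect_equal(ll, ref, tolerance = 1e-6)
})

test_that("compiled and reference likelihood cores agree to near machine precision", {
  ds <- make_sim(L = 300, m = 4, coverage = 1.5, seed = 23)
  ctx <- continuitest:::loglik_context(ds)
  for (pars in list(c(0.02, 0.05, 0.01), c(0.3, 0.001, 0.12), c(0, 0, 0.03))) {
    a <- continuitest:::ll_eval(ctx, pars[1], pars[2], pars[3], grad = TRUE)
    b <- continuitest:::ll_eval_r(ctx, pars[1], pars[2], pars[3], grad = TRUE)
    expect_equal(a$value, b$value, tolerance = 1e-10)
    expect_equal(a$dt1, b$dt1, tolerance = 1e-8)
    expect_equal(a$dt2, b$dt2, tolerance = 1e-8)
    expect_equal(a$deps, b$deps, tolerance = 1e-8)
  }
  # per-individual error rates
  epsv <- c(0.01, 0.05, 0.002, 0.2)
  a <- continuitest:::ll_eval(ctx, 0.02, 0.05, epsv, grad = TRUE, eps_shared = FALSE)
  b <- continuitest:::ll_eval_r(ctx, 0.02, 0.05, epsv, grad = TRUE, eps_shared = FALSE)
  expect_equal(a$deps, b$deps, tolerance = 1e-8)
})

test_that("analytic gradients match central finite differences", {
  ds <- make_sim(L = 250, m = 3, coverage = 2, seed = 29)
  ctx <- continuitest:::loglik_context(ds)
  h <- 1e-6
  at <- c(t1 = 0.03, t2 = 0.08, eps = 0.02)
  g <- continuitest:::ll_eval(ctx, at[1], at[2], at[3], grad = TRUE)
  fd <- function(i) {
    p <- at; p[i] <- p[i] + h; up <- continuitest:::ll_eval(ctx, p[1], p[2], p[3])$value
    p <- at; p[i] <- p[i] - h; dn <- continuitest:::ll_eval(ctx, p[1], p[2], p[3])$value
    (up - dn) / (2 * h)
  }
  expect_equal(g$dt1, fd(1), tolerance = 1e-4)
  expect_equal(g$dt2, fd(2), tolerance = 1e-4)
  expect_equal(g$deps, fd(3), tolerance = 1e-4)
})

test_that("likelihood is invariant to site order and individual order", {
  ds <- make_sim(L = 200, m = 3, seed = 31)
  p <- drift_params(0.04, 0.03)
  perm <- sample(n_sites(ds))
  ds_s <- continuity_dataset(ds$x[perm], ds$anc[perm, ], ds$der[perm, ])
  expect_equal(as.numeric(data_loglik(ds_s, p, 0.01)),
               as.numeric(data_loglik(ds, p, 0.01)), tolerance = 1e-9)
  ds_i <- continuity_dataset(ds$x, ds$anc[, 3:1], ds$der[, 3:1])
  expect_equal(as.numeric(data_loglik(ds_i, p, 0.01)),
               as.numeric(data_loglik(ds, p, 0.01)), tolerance = 1e-9)
})

test_that("caching does not change the likelihood bit pattern", {
  ds <- make_sim(L = 150, seed = 37)
  p <- drift_params(0.02, 0.05)
  cache <- moment_cache()
  l1 <- data_loglik(ds, p, 0.01, cache = cache)
  l2 <- data_loglik(ds, p, 0.01, cache = cache)  # cache hit
  l3 <- data_loglik(ds, p, 0.01)                 # no cache
  expect_identical(as.numeric(l1), as.numeric(l2))
  expect_identical(as.numeric(l1), as.numeric(l3))
  expect_gte(cache_stats(cache)$hits, 1L)
})
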