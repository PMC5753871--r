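test_that("generation-to-diffusion conversion is exact", {
  expect_equal(drift_time(400, 10000), 0.02)
  expect_equal(drift_time(100, 1000), 0.05)
  expect_equal(drift_time(0, 500), 0)
  expect_error(drift_time(-1, 100), "tau")
  expect_error(drift_time(10, 0), "Ne")
  d <- demography_config(10000, 1000, 400, 300)
  expect_equal(d$t1, 0.02)
  expect_equal(d$t2, 0.05)
  expect_error(demography_config(sample_age_gen = 500), "predate")
})

test_that("modern frequency spectra have the advertised shape and are seeded", {
  set.seed(73)
  xu <- sample_modern_freqs(10000, "uniform")
  expect_true(all(xu > 0 & xu < 1))
  expect_lt(abs(mean(xu) - 0.5), 3 * sd(xu) / sqrt(length(xu)))
  xn <- sample_modern_freqs(20000, "neutral")
  counts <- table(cut(xn, c(0.005, 0.1, 0.3, 0.6, 0.995)))
  dens <- as.numeric(counts) / diff(c(0.005, 0.1, 0.3, 0.6, 0.995))
  expect_true(all(diff(dens) < 0))  # 1/x density falls across bins
  set.seed(99); a <- sample_modern_freqs(50, "neutral")
  set.seed(99); b <- sample_modern_freqs(50, "neutral")
  expect_identical(a, b)
})

test_that("model-exact genotypes reproduce Hardy-Weinberg at zero drift", {
  set.seed(79)
  x <- rep(0.3, 50000)
  G <- sample_ancient_genotypes(x, 1, drift_params(0, 0))
  obs <- tabulate(G + 1L, 3) / length(G)
  hw <- dbinom(0:2, 2, 0.3)
  se <- sqrt(hw * (1 - hw) / length(G))
  expect_true(all(abs(obs - hw) < 3 * se + 1e-4))
})

test_that("model-exact allele counts follow the sampling distribution", {
  set.seed(83)
  m <- 2; x <- rep(0.4, 40000)
  params <- drift_params(0.02, 0.05)
  G <- sample_ancient_genotypes(x, m, params)
  k <- rowSums(G)
  expected <- sampling_probs(2 * m, 0.4, params) * length(x)
  gof <- suppressWarnings(chisq.test(tabulate(k + 1L, 2 * m + 1), p = expected / sum(expected)))
  expect_gt(gof$p.value, 0.001)
  # strong ancient drift wipes out heterozygotes
  G2 <- sample_ancient_genotypes(rep(0.5, 4000), 1, drift_params(0, 6))
  expect_lt(mean(G2 == 1), 0.01)
})

test_that("Wright-Fisher propagation has the diffusion's mean and variance", {
  expect_equal(wf_forward(c(0.2, 0.8), 100, 0), c(0.2, 0.8))
  set.seed(89)
  z <- wf_forward(rep(0.3, 100000), 2000, 40)  # t = 0.01
  expect_lt(abs(mean(z) - 0.3), 3 * sd(z) / sqrt(length(z)))
  expect_equal(var(z), 0.3 * 0.7 * 40 / 4000, tolerance = 0.1)
})

test_that("read simulation obeys depth, error and contamination semantics", {
  set.seed(97)
  G <- matrix(rbinom(4000, 2, 0.4), 2000, 2)
  r0 <- simulate_reads(G, coverage = 0)
  expect_true(all(r0$anc == 0 & r0$der == 0))
  # pure homozygous-derived, no error, no contamination
  r1 <- simulate_reads(matrix(2L, 500, 1), coverage = 3, eps = 0)
  expect_true(all(r1$anc == 0))
  # full contamination: derived fraction is the error-folded modern frequency
  x <- rep(0.25, 2000)
  eps <- 0.05
  r2 <- simulate_reads(G, coverage = 4, eps = eps, contamination = 1, x = x)
  frac <- sum(r2$der) / sum(r2$der + r2$anc)
  p <- (1 - eps) * 0.25 + eps * 0.75
  expect_lt(abs(frac - p), 3 * sqrt(p * (1 - p) / sum(r2$der + r2$anc)))
})

test_that("simulated datasets are reproducible and carry provenance", {
  d1 <- simulate_dataset(L = 300, m = 2, coverage = 1, seed = 101)
  d2 <- simulate_dataset(L = 300, m = 2, coverage = 1, seed = 101)
  expect_identical(d1$x, d2$x)
  expect_identical(d1$der, d2$der)
  prov <- attr(d1, "provenance")
  expect_equal(prov$seed, 101)
  expect_equal(prov$engine, "model_exact")
  # the seeded call restores the ambient RNG stream
  set.seed(5); before <- runif(1)
  set.seed(5); invisible(simulate_dataset(L = 50, m = 1, coverage = 1, seed = 7))
  expect_identical(runif(1), before)
})

test_that("scenario and engine constraints are enforced", {
  expect_error(simulate_dataset(L = 100, scenario = admixture_scenario("ghost", f = 0.1)),
               "wright_fisher")
  expect_error(simulate_dataset(L = 100, engine = "wright_fisher",
                                scenario = admixture_scenario("secondary_contact",
                                                              f = 0.1, time_gen = 350)),
               "postdate")
  expect_error(admixture_scenario("secondary_contact", f = 1.5), "fraction")
})

test_that("both generators imply the same fitted demography", {
  # cross-validation of the model-exact sampler against the independent
  # forward Wright-Fisher engine at the default demography
  n_rep <- 10L
  fit_one <- function(engine, seed) {
    ds <- simulate_dataset(L = 4000, m = 3, coverage = 1, seed = seed,
                           engine = engine)
    f <- fit_full(ds, fast_opts())
    c(f$t1, f$t2)
  }
  me <- t(vapply(seq_len(n_rep), function(i) fit_one("model_exact", 400 + i),
                 numeric(2)))
  wf <- t(vapply(seq_len(n_rep), function(i) fit_one("wright_fisher", 500 + i),
                 numeric(2)))
  for (j in 1:2) {
    se <- sqrt(var(me[, j]) / n_rep + var(wf[, j]) / n_rep)
    expect_lt(abs(mean(me[, j]) - mean(wf[, j])), 3 * se)
  }
})

test_that("total secondary contact makes ancient and modern continuous", {
  # complete replacement: the modern population descends through the
  # sampled population, so the ancient-branch drift collapses to zero
  ds <- simulate_dataset(L = 10000, m = 5, coverage = 4, seed = 113,
                         engine = "wright_fisher",
                         scenario = admixture_scenario("secondary_contact", f = 1))
  f <- fit_full(ds, fast_opts())
  expect_lt(f$t2, 0.01)
})
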