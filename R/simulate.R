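#' Convert generations to diffusion drift time
#'
#' Branch lengths are measured in diffusion units t = tau / (2 Ne), where
#' tau is the branch length in generations and Ne the diploid effective
#' size of the population the branch runs through.
#'
#' @param tau Branch length in generations (>= 0).
#' @param Ne Diploid effective population size (> 0).
#' @return Drift time in diffusion units.
#' @examples
#' drift_time(400, 10000)  # 0.02
#' drift_time(100, 1000)   # 0.05
#' @export
drift_time <- function(tau, Ne) {
  if (any(!is.finite(tau)) || any(tau < 0)) stop("tau must be >= 0", call. = FALSE)
  if (any(!is.finite(Ne)) || any(Ne <= 0)) stop("Ne must be > 0", call. = FALSE)
  tau / (2 * Ne)
}

#' Demographic configuration of the split model
#'
#' The ancient panel's population split from the modern population
#' `split_gen` generations ago; the sampled individuals died
#' `sample_age_gen` generations ago. The modern branch therefore spans
#' `split_gen` generations at size `Ne_modern` (t1 = split_gen /
#' (2 Ne_modern)) and the ancient branch `split_gen - sample_age_gen`
#' generations at size `Ne_ancient` (t2). Defaults reproduce the
#' simulation design used throughout: split 400 generations ago, modern Ne
#' 10,000, ancient Ne 1,000, sample age 300 generations, so t1 = 0.02 and
#' t2 = 0.05.
#'
#' @param Ne_modern,Ne_ancient Diploid effective sizes.
#' @param split_gen Split time in generations before present.
#' @param sample_age_gen Age of the ancient sample in generations.
#' @return A list of class `demography_config` including derived `t1`, `t2`.
#' @export
demography_config <- function(Ne_modern = 10000, Ne_ancient = 1000,
                              split_gen = 400, sample_age_gen = 300) {
  if (sample_age_gen > split_gen)
    stop("sample age cannot predate the population split", call. = FALSE)
  if (min(Ne_modern, Ne_ancient) <= 0 || split_gen <= 0 || sample_age_gen < 0)
    stop("sizes and times must be positive", call. = FALSE)
  structure(list(
    Ne_modern = Ne_modern, Ne_ancient = Ne_ancient,
    split_gen = split_gen, sample_age_gen = sample_age_gen,
    tau1 = split_gen, tau2 = split_gen - sample_age_gen,
    t1 = drift_time(split_gen, Ne_modern),
    t2 = drift_time(max(split_gen - sample_age_gen, 0), Ne_ancient)),
    class = "demography_config")
}

#' Admixture scenario for the Wright-Fisher engine
#'
#' `"secondary_contact"`: after the ancient sample's death, the ancient
#' population contributes a single pulse of fraction `f` into the modern
#' population `time_gen` generations before present. `"ghost"`: the
#' ancient sample is drawn from the lineage directly ancestral to the
#' modern population (true continuity), but an unsampled outgroup that
#' diverged `ghost_split_gen` generations ago pulses fraction `f` into the
#' modern population `time_gen` generations ago. Defaults follow the
#' simulated designs: pulse 200 generations ago, ghost divergence 800
#' generations ago (0.04 diffusion units at Ne 10,000).
#'
#' @param mode One of `"none"`, `"secondary_contact"`, `"ghost"`.
#' @param f Admixture fraction in [0, 1].
#' @param time_gen Pulse time, generations before present.
#' @param ghost_split_gen Ghost divergence time, generations before present.
#' @return A list of class `admixture_scenario`.
#' @export
admixture_scenario <- function(mode = c("none", "secondary_contact", "ghost"),
                               f = 0, time_gen = 200, ghost_split_gen = 800) {
  mode <- match.arg(mode)
  if (f < 0 || f > 1) stop("admixture fraction must lie in [0, 1]", call. = FALSE)
  structure(list(mode = mode, f = f, time_gen = time_gen,
                 ghost_split_gen = ghost_split_gen),
            class = "admixture_scenario")
}

#' Draw modern derived-allele frequencies
#'
#' Emulates the frequencies of segregating SNPs in the modern reference
#' panel. `"neutral"` draws from the 1/x site-frequency spectrum truncated
#' to (1/(2 n_panel), 1 - 1/(2 n_panel)); `"uniform"` draws uniformly on
#' the same interval.
#'
#' @param L Number of sites.
#' @param spectrum `"neutral"` (default) or `"uniform"`.
#' @param n_panel Diploid size of the modern panel fixing the truncation.
#' @return Numeric vector of frequencies strictly inside (0, 1).
#' @export
sample_modern_freqs <- function(L, spectrum = c("neutral", "uniform"),
                                n_panel = 100) {
  stopifnot(L >= 1)
  spectrum <- match.arg(spectrum)
  lo <- 1 / (2 * n_panel); hi <- 1 - lo
  if (spectrum == "uniform") return(runif(L, lo, hi))
  # inverse-CDF draw from density 1/x on [lo, hi]
  u <- runif(L)
  lo * exp(u * log(hi / lo))
}

#' Model-exact ancient genotypes
#'
#' Draws, for each site, the derived-allele count k among 2m ancient
#' chromosomes from the model's own sampling distribution P_{2m,k}(x; t1,
#' t2), assigns the k derived alleles to chromosome slots uniformly at
#' random, and pairs consecutive slots into m diploid genotypes.
#'
#' @param x Vector of modern derived-allele frequencies.
#' @param m Number of ancient diploids.
#' @param params A [drift_params()].
#' @param cache Optional [moment_cache()].
#' @return Integer matrix (length(x) sites x m) of genotypes in {0, 1, 2}.
#' @export
sample_ancient_genotypes <- function(x, m, params, cache = NULL) {
  n <- 2L * m
  op <- moment_operator(n, params, cache)
  H <- outer(x, 0:n, function(x, k) x^k * (1 - x)^(n - k))
  P <- (H %*% t(op$M)) * rep(choose(n, 0:n), each = length(x))
  P <- pmax(P, 0)
  P <- P / rowSums(P)
  # inverse-CDF draw of k per site
  cum <- t(apply(P, 1L, cumsum))
  k <- rowSums(runif(length(x)) > cum[, -ncol(cum), drop = FALSE])
  G <- matrix(0L, length(x), m)
  for (l in seq_along(x)) {
    if (k[l] == 0L) next
    slots <- sample.int(n, k[l])
    gl <- tabulate((slots + 1L) %/% 2L, nbins = m)
    G[l, ] <- as.integer(gl)
  }
  G
}

#' Forward Wright-Fisher propagation of allele frequencies
#'
#' Propagates each frequency through `tau` generations of binomial
#' resampling in a diploid population of size `Ne` (2 Ne chromosomes).
#' Serves as the model-independent oracle for the diffusion moments.
#'
#' @param z Vector of initial frequencies in [0, 1].
#' @param Ne Diploid effective size.
#' @param tau Number of generations (integer >= 0).
#' @return Vector of final frequencies.
#' @export
wf_forward <- function(z, Ne, tau) {
  stopifnot(all(z >= 0 & z <= 1), Ne > 0, tau >= 0)
  n_chrom <- 2 * Ne
  for (g in seq_len(tau)) z <- rbinom(length(z), n_chrom, z) / n_chrom
  z
}

# one-generation admixture pulse: recipient frequency becomes the mixture
r_admix_pulse <- function(z_recipient, z_donor, f) (1 - f) * z_recipient + f * z_donor

# truncated 1/z draw for ancestral frequencies
r_neutral_freq <- function(L, Ne) {
  lo <- 1 / (2 * Ne); hi <- 1 - lo
  u <- runif(L)
  lo * exp(u * log(hi / lo))
}

#' Simulate sequencing reads over genotypes
#'
#' Per individual and site, read depth is Poisson(`coverage`); each read is
#' drawn from a modern contaminant with probability `contamination` (in
#' which case it carries the derived allele with probability x, the modern
#' frequency), otherwise from the individual's genotype (heterozygotes
#' transmit the derived allele with probability 1/2); finally the observed
#' allele is flipped with error probability `eps`.
#'
#' @param G Genotype matrix (sites x individuals) in {0, 1, 2}.
#' @param coverage Mean read depth per site per individual.
#' @param eps Per-read error probability.
#' @param contamination Contamination fraction c in [0, 1].
#' @param x Modern derived-allele frequency per site (contaminant source).
#' @return List of matrices `anc`, `der` (sites x individuals).
#' @export
simulate_reads <- function(G, coverage, eps = 0.01, contamination = 0, x = NULL) {
  G <- as.matrix(G)
  stopifnot(coverage >= 0, contamination >= 0, contamination <= 1)
  check_eps(eps)
  L <- nrow(G); m <- ncol(G)
  if (is.null(x)) x <- rep(0, L)
  depth <- matrix(rpois(L * m, coverage), L, m)
  p_true <- (1 - contamination) * (G / 2) + contamination * x
  p_der <- p_true * (1 - eps) + (1 - p_true) * eps
  der <- matrix(rbinom(L * m, depth, p_der), L, m)
  list(anc = depth - der, der = der)
}

#' Simulate an ancient-panel dataset
#'
#' End-to-end generator reproducing the statistical structure the
#' likelihood assumes: modern frequencies of segregating SNPs, ancient
#' diploid genotypes under the split-drift model, Poisson read depth,
#' symmetric read error, contamination, and (with the Wright-Fisher
#' engine) the secondary-contact and ghost admixture scenarios.
#'
#' Engines: `"model_exact"` draws ancient allele counts from the model's
#' own sampling distribution (backward-forward moments) — exact but
#' circular by construction. `"wright_fisher"` simulates discrete binomial
#' resampling forward in time from an ancestral frequency drawn from the
#' truncated 1/z neutral spectrum, computes the modern frequency from the
#' simulated modern population, and is therefore an independent oracle; it
#' is also the only engine supporting admixture scenarios.
#'
#' @param L Number of segregating sites to emit.
#' @param m Number of ancient diploid individuals.
#' @param coverage Mean read depth per individual per site.
#' @param eps Per-read error probability used in simulation.
#' @param contamination Contamination fraction.
#' @param demography A [demography_config()].
#' @param scenario An [admixture_scenario()].
#' @param engine `"model_exact"` or `"wright_fisher"`.
#' @param spectrum Modern-frequency spectrum for the model-exact engine.
#' @param seed Optional integer seed (restores the RNG state on exit).
#' @param population Population label for the dataset.
#' @return A [continuity_dataset()], with the simulation configuration in
#'   attribute `"provenance"`.
#' @examples
#' ds <- simulate_dataset(L = 500, m = 2, coverage = 1, seed = 42)
#' ds
#' @export
simulate_dataset <- function(L = 20000, m = 5, coverage = 4, eps = 0.01,
                             contamination = 0,
                             demography = demography_config(),
                             scenario = admixture_scenario("none"),
                             engine = c("model_exact", "wright_fisher"),
                             spectrum = c("neutral", "uniform"),
                             seed = NULL, population = "sim") {
  engine <- match.arg(engine)
  spectrum <- match.arg(spectrum)
  stopifnot(inherits(demography, "demography_config"),
            inherits(scenario, "admixture_scenario"))
  if (scenario$mode != "none" && engine != "wright_fisher")
    stop("admixture scenarios require the wright_fisher engine", call. = FALSE)
  if (scenario$mode == "secondary_contact" &&
      scenario$time_gen > demography$sample_age_gen)
    stop("secondary contact must postdate the ancient sample", call. = FALSE)
  if (!is.null(seed)) {
    old_seed <- get0(".Random.seed", envir = globalenv())
    on.exit(if (!is.null(old_seed)) assign(".Random.seed", old_seed, envir = globalenv()))
    set.seed(seed)
  }
  sim <- if (engine == "model_exact") {
    sim_model_exact(L, m, demography, spectrum)
  } else {
    sim_wright_fisher(L, m, demography, scenario)
  }
  reads <- simulate_reads(sim$G, coverage, eps, contamination, sim$x)
  ds <- continuity_dataset(sim$x, reads$anc, reads$der, population = population)
  attr(ds, "provenance") <- list(
    L = L, m = m, coverage = coverage, eps = eps,
    contamination = contamination, engine = engine, spectrum = spectrum,
    demography = unclass(demography), scenario = unclass(scenario),
    seed = seed)
  ds
}

sim_model_exact <- function(L, m, demography, spectrum) {
  x <- sample_modern_freqs(L, spectrum)
  G <- sample_ancient_genotypes(x, m, drift_params(demography$t1, demography$t2))
  list(x = x, G = G)
}

# forward Wright-Fisher simulation of the (up to three population) history;
# emits exactly L sites segregating in the modern population
sim_wright_fisher <- function(L, m, demography, scenario) {
  got_x <- numeric(0); got_G <- NULL
  batch <- ceiling(L * 1.4)
  guard <- 0L
  while (length(got_x) < L && guard < 50L) {
    guard <- guard + 1L
    s <- sim_wf_batch(batch, m, demography, scenario)
    got_x <- c(got_x, s$x)
    got_G <- rbind(got_G, s$G)
    batch <- max(1000L, ceiling((L - length(got_x)) * 1.6))
  }
  if (length(got_x) < L)
    stop("Wright-Fisher engine failed to produce enough segregating sites", call. = FALSE)
  idx <- seq_len(L)
  list(x = got_x[idx], G = got_G[idx, , drop = FALSE])
}

sim_wf_batch <- function(L, m, demography, scenario) {
  Ne1 <- demography$Ne_modern; Ne2 <- demography$Ne_ancient
  split <- demography$split_gen; age <- demography$sample_age_gen
  mode <- scenario$mode; f <- scenario$f
  if (mode == "ghost") {
    # true continuity: the ancient sample is taken from the modern lineage
    # itself; an unsampled outgroup that branched at the ghost split pulses
    # into the modern lineage after the sample's death
    gsplit <- scenario$ghost_split_gen
    ptime <- scenario$time_gen
    z0 <- r_neutral_freq(L, Ne1)                      # frequency at ghost split
    ghost <- wf_forward(z0, Ne1, gsplit - ptime)      # ghost branch to the pulse
    y <- wf_forward(z0, Ne1, gsplit - age)            # main lineage to sampling
    zm <- wf_forward(y, Ne1, age - ptime)             # main lineage to the pulse
    zm <- r_admix_pulse(zm, ghost, f)
    x <- wf_forward(zm, Ne1, ptime)
  } else {
    z <- r_neutral_freq(L, Ne1)                       # ancestral frequency
    y <- wf_forward(z, Ne2, split - age)              # ancient branch to sample
    if (mode == "secondary_contact") {
      ptime <- scenario$time_gen
      y_pulse <- wf_forward(y, Ne2, age - ptime)      # ancient pop lives on
      zm <- wf_forward(z, Ne1, split - ptime)
      zm <- r_admix_pulse(zm, y_pulse, f)
      x <- wf_forward(zm, Ne1, ptime)
    } else {
      x <- wf_forward(z, Ne1, split)
    }
  }
  keep <- x > 0 & x < 1
  if (!any(keep)) return(list(x = numeric(0), G = matrix(0L, 0L, m)))
  yk <- y[keep]
  chrom <- rbinom(2L * m * sum(keep), 1L, rep(yk, each = 2L * m))
  cmat <- matrix(chrom, ncol = 2L * m, byrow = TRUE)
  G <- sapply(seq_len(m), function(i) cmat[, 2L * i - 1L] + cmat[, 2L * i])
  if (sum(keep) == 1L) G <- matrix(G, nrow = 1L)
  list(x = x[keep], G = G)
}
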