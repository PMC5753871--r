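#' Fitting options
#'
#' Controls the deterministic multi-start bounded optimization of the
#' likelihood. The default start grid crosses log-spaced drift times
#' (`t_starts`, used for both t1 and t2 in the full model) with two error
#' rates (`eps_starts`), giving 3 x 3 x 2 = 18 starts for the full model and
#' 3 x 2 = 6 for the continuity null. Each start is refined with bounded
#' quasi-Newton (L-BFGS-B) using the analytic gradient; the best final
#' log-likelihood wins, with ties within `tol` broken by smallest t1 + t2,
#' then smallest eps (parsimony).
#'
#' @param t_starts Start values for drift times (diffusion units).
#' @param eps_starts Start values for the error rate.
#' @param t_max Upper optimizer bound on each drift time; beyond ~10
#'   diffusion units the moments are numerically at fixation.
#' @param eps_mode `"shared"` (one error rate, coestimated), `"per_individual"`
#'   (one coestimated rate per individual), or `"fixed"` (pinned to
#'   `eps_fixed`, not estimated).
#' @param eps_fixed Error rate(s) used when `eps_mode = "fixed"`.
#' @param tol Convergence / tie-breaking tolerance on the log-likelihood.
#' @param maxit Maximum L-BFGS-B iterations per start.
#' @param extra_starts Optional numeric matrix of additional start points,
#'   columns (t1, t2, eps).
#' @return A list of class `fit_options`.
#' @export
fit_options <- function(t_starts = c(0.005, 0.05, 0.5),
                        eps_starts = c(0.001, 0.01),
                        t_max = 10,
                        eps_mode = c("shared", "per_individual", "fixed"),
                        eps_fixed = 0.01,
                        tol = 1e-6,
                        maxit = 200L,
                        extra_starts = NULL) {
  structure(list(t_starts = t_starts, eps_starts = eps_starts, t_max = t_max,
                 eps_mode = match.arg(eps_mode), eps_fixed = eps_fixed,
                 tol = tol, maxit = maxit, extra_starts = extra_starts),
            class = "fit_options")
}

EPS_LO <- 1e-6
EPS_HI <- 0.5 - 1e-6

# objective closure: negative log-likelihood and gradient over the free
# parameter vector; layout: (t1[, t2][, eps...])
make_objective <- function(ctx, null, opts) {
  eps_mode <- opts$eps_mode
  n_eps <- switch(eps_mode, shared = 1L, per_individual = ctx$m, fixed = 0L)
  eps_fixed <- if (eps_mode == "fixed") {
    check_eps(opts$eps_fixed)
    rep(opts$eps_fixed, length.out = ctx$m)
  } else NULL
  last <- new.env(parent = emptyenv()); last$par <- NULL
  evaluate <- function(par) {
    t1 <- par[1L]
    t2 <- if (null) 0 else par[2L]
    eps <- if (n_eps > 0L) par[(length(par) - n_eps + 1L):length(par)] else eps_fixed
    r <- suppressWarnings(
      ll_eval(ctx, t1, t2, eps, grad = TRUE, eps_shared = (eps_mode == "shared")))
    g <- -r$dt1
    if (!null) g <- c(g, -r$dt2)
    if (n_eps > 0L) g <- c(g, -r$deps)
    last$par <- par; last$value <- -r$value; last$grad <- g
    invisible(r)
  }
  list(
    fn = function(par) { evaluate(par); last$value },
    gr = function(par) {
      if (is.null(last$par) || !identical(last$par, par)) evaluate(par)
      last$grad
    },
    n_eps = n_eps)
}

start_grid <- function(null, opts, m) {
  es <- opts$eps_starts
  if (opts$eps_mode == "fixed") es <- NA_real_
  if (null) {
    g <- expand.grid(t1 = opts$t_starts, eps = es)
  } else {
    g <- expand.grid(t1 = opts$t_starts, t2 = opts$t_starts, eps = es)
  }
  g <- as.matrix(g)
  if (!is.null(opts$extra_starts)) {
    ex <- as.matrix(opts$extra_starts)
    if (null && ncol(ex) == 3L) ex <- ex[, -2L, drop = FALSE]  # drop t2 column
    g <- rbind(g, ex)
  }
  g
}

fit_engine <- function(ds, null, opts) {
  stopifnot(inherits(ds, "continuity_dataset"), inherits(opts, "fit_options"))
  if (n_sites(ds) < 100)
    warning(sprintf("only %d usable sites; estimates will be unstable", n_sites(ds)))
  ctx <- loglik_context(ds)
  obj <- make_objective(ctx, null, opts)
  n_eps <- obj$n_eps
  starts <- start_grid(null, opts, ctx$m)
  lower <- c(0, if (!null) 0, rep(EPS_LO, n_eps))
  upper <- c(opts$t_max, if (!null) opts$t_max, rep(EPS_HI, n_eps))
  results <- vector("list", nrow(starts))
  for (s in seq_len(nrow(starts))) {
    p0 <- starts[s, ]
    eps0 <- if (n_eps > 0L) rep(p0[length(p0)], n_eps) else NULL
    par0 <- c(p0[1L], if (!null) p0[2L], eps0)
    par0 <- pmin(pmax(par0, lower), upper)
    results[[s]] <- tryCatch(
      optim(par0, obj$fn, obj$gr, method = "L-BFGS-B",
            lower = lower, upper = upper,
            control = list(maxit = opts$maxit, factr = 1e4)),
      error = function(e) NULL)
  }
  ok <- !vapply(results, is.null, logical(1))
  if (!any(ok)) stop("optimization failed from every start", call. = FALSE)
  results <- results[ok]
  vals <- vapply(results, function(r) -r$value, numeric(1))
  best_val <- max(vals)
  cand <- which(vals >= best_val - opts$tol)
  # parsimony tie-break: smallest total drift, then smallest eps
  if (length(cand) > 1L) {
    tdrift <- vapply(results[cand], function(r)
      r$par[1L] + if (!null) r$par[2L] else 0, numeric(1))
    cand <- cand[order(tdrift, vapply(results[cand], function(r)
      if (n_eps > 0L) mean(r$par[(length(r$par) - n_eps + 1L):length(r$par)])
      else 0, numeric(1)))]
  }
  best <- results[[cand[1L]]]
  par <- best$par
  # a line-search abort at the optimum is corroborated convergence when a
  # cleanly converged start reaches the same log-likelihood
  conv_codes <- vapply(results, function(r) r$convergence, numeric(1))
  converged <- best$convergence == 0 ||
    any(conv_codes == 0 & vals >= -best$value - opts$tol)
  eps_hat <- if (n_eps > 0L) par[(length(par) - n_eps + 1L):length(par)]
             else rep(opts$eps_fixed, length.out = ctx$m)
  if (n_eps == 1L) eps_hat <- unname(eps_hat)
  structure(list(
    t1 = unname(par[1L]),
    t2 = if (null) 0 else unname(par[2L]),
    eps = unname(eps_hat),
    lnL = -best$value,
    model = if (null) "null" else "full",
    converged = converged,
    n_starts = length(results),
    n_starts_agreeing = sum(vals >= best_val - 1e-4),
    n_sites = n_sites(ds),
    m = ctx$m,
    population = ds$population,
    options = opts), class = "continuity_fit")
}

#' Maximum-likelihood fit of the drift model
#'
#' `fit_full()` maximizes the read-count likelihood over (t1, t2, eps);
#' `fit_null()` fits the continuity null, pinning t2 = 0 and maximizing
#' over (t1, eps). Both use a deterministic multi-start grid refined by
#' bounded L-BFG-S with analytic gradients, so refitting the same data with
#' the same options is bit-identical.
#'
#' @param ds A [continuity_dataset()].
#' @param opts A [fit_options()].
#' @return An object of class `continuity_fit` with elements `t1`, `t2`,
#'   `eps`, `lnL`, `converged`, `n_starts_agreeing`, among others.
#' @examples
#' ds <- simulate_dataset(L = 2000, m = 2, coverage = 2, seed = 7)
#' fit_full(ds)
#' @export
fit_full <- function(ds, opts = fit_options()) fit_engine(ds, null = FALSE, opts)

#' @rdname fit_full
#' @export
fit_null <- function(ds, opts = fit_options()) fit_engine(ds, null = TRUE, opts)

#' @export
print.continuity_fit <- function(x, ...) {
  cat(sprintf("continuity_fit (%s model), population '%s'\n", x$model, x$population))
  cat(sprintf("  t1 = %.5f  t2 = %.5f  eps = %s\n", x$t1, x$t2,
              paste(sprintf("%.5f", x$eps), collapse = ", ")))
  cat(sprintf("  lnL = %.3f over %d sites, %d individuals\n", x$lnL, x$n_sites, x$m))
  cat(sprintf("  converged: %s; %d/%d starts within 1e-4 of optimum\n",
              x$converged, x$n_starts_agreeing, x$n_starts))
  invisible(x)
}

#' Likelihood-ratio test of population continuity
#'
#' Fits the full model and the continuity null (t2 = 0) and reports the
#' likelihood-ratio statistic 2 (lnL_full - lnL_null), clamped at zero.
#' Because t2 sits on the boundary of the parameter space under the null,
#' the statistic's asymptotic null distribution is the 50:50 mixture of a
#' point mass at 0 and chi-squared with 1 df; `p_mixture` (the default
#' decision value) uses that mixture, `p_chi2_1df` the plain chi-squared.
#' The null solution is always injected as an extra start for the full fit
#' so the nesting inequality lnL_full >= lnL_null holds by construction.
#'
#' @inheritParams fit_full
#' @return An object of class `continuity_lrt` with the two fits, `lrt`,
#'   `p_chi2_1df` and `p_mixture`.
#' @examples
#' ds <- simulate_dataset(L = 2000, m = 2, coverage = 2, seed = 7)
#' continuity_test(ds)
#' @export
continuity_test <- function(ds, opts = fit_options()) {
  fit0 <- fit_null(ds, opts)
  eps0 <- if (opts$eps_mode == "fixed") opts$eps_fixed[1L] else mean(fit0$eps)
  opts_full <- opts
  opts_full$extra_starts <- rbind(opts$extra_starts,
                                  c(fit0$t1, 1e-4, eps0))
  fit1 <- fit_full(ds, opts_full)
  if (!fit0$converged || !fit1$converged)
    warning("at least one of the two fits did not converge")
  lrt <- 2 * (fit1$lnL - fit0$lnL)
  if (lrt < -1e-6)
    warning(sprintf("full-model lnL below null lnL by %.3g; optimizer artifact", -lrt))
  lrt <- max(lrt, 0)
  structure(list(
    fit_full = fit1, fit_null = fit0,
    lnL_full = fit1$lnL, lnL_null = fit0$lnL,
    lrt = lrt,
    p_chi2_1df = pchisq(lrt, df = 1, lower.tail = FALSE),
    p_mixture = if (lrt <= 0) 1 else 0.5 * pchisq(lrt, df = 1, lower.tail = FALSE)),
    class = "continuity_lrt")
}

#' @export
print.continuity_lrt <- function(x, ...) {
  cat("likelihood-ratio test of continuity (H0: t2 = 0)\n")
  cat(sprintf("  full: t1 = %.5f, t2 = %.5f, lnL = %.3f\n",
              x$fit_full$t1, x$fit_full$t2, x$lnL_full))
  cat(sprintf("  null: t1 = %.5f,            lnL = %.3f\n",
              x$fit_null$t1, x$lnL_null))
  cat(sprintf("  LRT = %.4f; p = %.4g (boundary mixture), %.4g (chi-squared 1 df)\n",
              x$lrt, x$p_mixture, x$p_chi2_1df))
  invisible(x)
}

#' Nonparametric bootstrap confidence intervals
#'
#' Resamples sites (or blocks of `block` consecutive sites, for linked
#' data) with replacement, refits the full model on each replicate, and
#' returns 2.5/97.5 percentile intervals for t1, t2 and eps. Seeded and
#' reproducible. Replicates whose fit fails are dropped and counted; more
#' than 10% failures is an error.
#'
#' By default each replicate is started from the original point estimate
#' plus one interior grid point, which is sufficient for the unimodal
#' resampled likelihoods; pass `opts` to override.
#'
#' @inheritParams fit_full
#' @param B Number of bootstrap replicates.
#' @param seed Integer seed for the resampling.
#' @param block Block length in consecutive-site units (1 = iid sites).
#' @param opts Optional [fit_options()]; if `NULL`, a fast two-start option
#'   set anchored at the original MLE is used.
#' @return An object of class `continuity_boot`: matrix `ci` (2 x params),
#'   the replicate estimates, and the failure count.
#' @export
bootstrap_ci <- function(ds, B = 200L, seed = 1L, block = 1L, opts = NULL) {
  stopifnot(inherits(ds, "continuity_dataset"), B >= 2L, block >= 1L)
  point <- if (is.null(opts)) fit_full(ds) else fit_full(ds, opts)
  if (is.null(opts)) {
    opts <- fit_options(t_starts = numeric(0), eps_starts = numeric(0))
    opts$extra_starts <- rbind(c(point$t1, point$t2, mean(point$eps)),
                               c(0.05, 0.05, 0.01))
    # expand.grid of empty vectors yields zero rows; starts are the extras
  }
  L <- n_sites(ds)
  n_blocks <- ceiling(L / block)
  est <- matrix(NA_real_, B, 3L,
                dimnames = list(NULL, c("t1", "t2", "eps")))
  old_seed <- get0(".Random.seed", envir = globalenv())
  on.exit(if (!is.null(old_seed)) assign(".Random.seed", old_seed, envir = globalenv()))
  set.seed(seed)
  for (b in seq_len(B)) {
    starts_b <- sample.int(n_blocks, n_blocks, replace = TRUE)
    idx <- unlist(lapply((starts_b - 1L) * block + 1L,
                         function(s) s:min(s + block - 1L, L)))
    rds <- ds
    rds$x <- ds$x[idx]
    rds$anc <- ds$anc[idx, , drop = FALSE]
    rds$der <- ds$der[idx, , drop = FALSE]
    f <- tryCatch(suppressWarnings(fit_full(rds, opts)), error = function(e) NULL)
    if (!is.null(f)) est[b, ] <- c(f$t1, f$t2, mean(f$eps))
  }
  failed <- sum(is.na(est[, 1L]))
  if (failed > 0.1 * B)
    stop(sprintf("%d of %d bootstrap replicates failed", failed, B), call. = FALSE)
  ci <- apply(est, 2L, quantile, probs = c(0.025, 0.975), na.rm = TRUE)
  structure(list(ci = ci, estimates = est, point = point,
                 B = B, failed = failed, block = block, seed = seed),
            class = "continuity_boot")
}

#' @export
print.continuity_boot <- function(x, ...) {
  cat(sprintf("nonparametric bootstrap, %d replicates (%d failed), block = %d\n",
              x$B, x$failed, x$block))
  print(round(x$ci, 5))
  invisible(x)
}
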