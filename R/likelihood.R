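#' Ancient-panel dataset
#'
#' Bundles, for one ancient population analyzed against one modern
#' population: the modern derived-allele frequency per site and the
#' per-individual ancestral/derived read counts. Sites whose modern
#' frequency is not strictly inside (0, 1) (the model conditions on
#' segregating sites) and sites with no reads in any individual carry no
#' information and are dropped at construction; the drop counts are kept as
#' attributes and surface in [print()] and the i/o filter accounting.
#'
#' @param x Numeric vector of modern derived-allele frequencies, one per
#'   site.
#' @param anc,der Integer matrices (sites x individuals) of ancestral and
#'   derived read counts; vectors are accepted for a single individual.
#' @param individuals Optional character vector of individual IDs.
#' @param population Population label.
#' @return An object of class `continuity_dataset` with elements `x`,
#'   `anc`, `der`, `individuals`, `population` and attributes
#'   `n_dropped_nonseg`, `n_dropped_noreads`.
#' @export
continuity_dataset <- function(x, anc, der, individuals = NULL,
                               population = "ancient_panel") {
  anc <- as.matrix(anc); der <- as.matrix(der)
  storage.mode(anc) <- "double"; storage.mode(der) <- "double"
  L <- length(x)
  if (nrow(anc) != L || nrow(der) != L || ncol(anc) != ncol(der))
    stop("dimension mismatch between x, anc and der", call. = FALSE)
  if (any(anc < 0) || any(der < 0) || any(anc != round(anc)) || any(der != round(der)))
    stop("read counts must be non-negative integers", call. = FALSE)
  m <- ncol(anc)
  if (is.null(individuals)) individuals <- colnames(anc)
  if (is.null(individuals)) individuals <- sprintf("ind%d", seq_len(m))
  seg <- is.finite(x) & x > 0 & x < 1
  covered <- rowSums(anc + der) > 0
  keep <- seg & covered
  ds <- structure(
    list(x = as.numeric(x[keep]), anc = anc[keep, , drop = FALSE],
         der = der[keep, , drop = FALSE],
         individuals = as.character(individuals), population = population),
    class = "continuity_dataset",
    n_dropped_nonseg = sum(!seg),
    n_dropped_noreads = sum(seg & !covered))
  if (length(ds$x) == 0L) stop("no usable sites after filtering", call. = FALSE)
  ds
}

#' @export
print.continuity_dataset <- function(x, ...) {
  cat(sprintf("continuity_dataset: population '%s', %d sites x %d individuals\n",
              x$population, length(x$x), ncol(x$anc)))
  cov <- colSums(x$anc + x$der) / length(x$x)
  cat(sprintf("  mean coverage per individual: %s\n",
              paste(sprintf("%.2f", cov), collapse = ", ")))
  cat(sprintf("  dropped at construction: %d non-segregating, %d read-free sites\n",
              attr(x, "n_dropped_nonseg"), attr(x, "n_dropped_noreads")))
  invisible(x)
}

#' Number of sites / individuals in a dataset
#' @param ds A [continuity_dataset()].
#' @return Integer.
#' @export
n_sites <- function(ds) length(ds$x)

#' @rdname n_sites
#' @export
n_individuals <- function(ds) ncol(ds$anc)

# ---- vectorized likelihood core ------------------------------------------
#
# All sites are evaluated at the fixed panel order n = 2m; individuals with
# no reads at a site contribute the exact (1, 2, 1) genotype-weight triplet,
# which by the marginalization identity leaves the site likelihood
# unchanged, so no per-site order reduction is needed and every site shares
# one pair of matrix exponentials. Per-individual triplets are rescaled by
# the heterozygote likelihood 0.5^(a+d) (eps-free, so the scale constant
# drops out of all eps derivatives); the per-site log constant
# sum_i [log choose(a_i+d_i, d_i) + (a_i+d_i) log 1/2] is added back at the
# end.

loglik_context <- function(ds) {
  m <- ncol(ds$anc)
  n <- 2L * m
  k <- 0:n
  H <- outer(ds$x, k, function(x, k) x^k * (1 - x)^(n - k))
  const <- rowSums(lchoose(ds$anc + ds$der, ds$der) - log(2) * (ds$anc + ds$der))
  tA <- t(ds$anc); storage.mode(tA) <- "integer"
  tD <- t(ds$der); storage.mode(tD) <- "integer"
  list(A = ds$anc, D = ds$der, tA = tA, tD = tD, H = H, tH = t(H),
       const = const, L = length(ds$x), m = m, n = n, Cnk = choose(n, k))
}

# scaled per-individual triplet columns: T0 = (2 eps)^d (2(1-eps))^a,
# T1 = 2, T2 = (2(1-eps))^d (2 eps)^a
triplet_cols <- function(ctx, i, eps_i) {
  a <- ctx$A[, i]; d <- ctx$D[, i]
  list(t0 = (2 * eps_i)^d * (2 * (1 - eps_i))^a,
       t2 = (2 * (1 - eps_i))^d * (2 * eps_i)^a)
}

# d/deps of the scaled triplet
triplet_cols_deriv <- function(ctx, i, eps_i) {
  a <- ctx$A[, i]; d <- ctx$D[, i]
  u <- 2 * eps_i; v <- 2 * (1 - eps_i)
  dt0 <- 2 * d * ifelse(d == 0, 0, u^(d - 1)) * v^a -
         2 * a * u^d * ifelse(a == 0, 0, v^(a - 1))
  dt2 <- -2 * d * ifelse(d == 0, 0, v^(d - 1)) * u^a +
          2 * a * v^d * ifelse(a == 0, 0, u^(a - 1))
  list(t0 = dt0, t2 = dt2)
}

# convolve an L x w weight matrix with per-site triplet columns (t0, 2, t2)
conv3_mat <- function(W, tri) {
  L <- nrow(W); w <- ncol(W)
  out <- matrix(0, L, w + 2L)
  out[, 1:w] <- W * tri$t0
  out[, 2:(w + 1L)] <- out[, 2:(w + 1L)] + 2 * W
  out[, 3:(w + 2L)] <- out[, 3:(w + 2L)] + W * tri$t2
  out
}

# general convolution of two weight matrices (used for leave-one-out)
conv_mat <- function(Wa, Wb) {
  L <- nrow(Wa); wa <- ncol(Wa); wb <- ncol(Wb)
  out <- matrix(0, L, wa + wb - 1L)
  for (j in seq_len(wb)) {
    idx <- j:(j + wa - 1L)
    out[, idx] <- out[, idx] + Wa * Wb[, j]
  }
  out
}

# prefix convolutions of the scaled triplets; prefix[[i]] excludes
# individuals i..m, prefix[[m+1]] is the full weight matrix W
weight_prefixes <- function(ctx, eps) {
  m <- ctx$m
  pref <- vector("list", m + 1L)
  pref[[1L]] <- matrix(1, ctx$L, 1L)
  for (i in seq_len(m))
    pref[[i + 1L]] <- conv3_mat(pref[[i]], triplet_cols(ctx, i, eps[i]))
  pref
}

weight_suffixes <- function(ctx, eps) {
  m <- ctx$m
  suf <- vector("list", m + 1L)
  suf[[m + 1L]] <- matrix(1, ctx$L, 1L)
  for (i in rev(seq_len(m)))
    suf[[i]] <- conv3_mat(suf[[i + 1L]], triplet_cols(ctx, i, eps[i]))
  suf
}

# Full evaluation: log-likelihood and (optionally) its analytic gradient
# with respect to t1, t2 and eps (shared scalar or per-individual vector).
# The per-site convolutions run in compiled code; ll_eval_r below is the
# plain-R reference implementation kept for cross-checking.
ll_eval <- function(ctx, t1, t2, eps, grad = FALSE, eps_shared = TRUE,
                    cache = NULL) {
  if (length(eps) == 1L) eps <- rep(eps, ctx$m)
  op <- moment_operator(ctx$n, drift_params(t1, t2), cache)
  tP <- op$M %*% ctx$tH
  if (grad) {
    tP1 <- (op$E2 %*% op$Qd %*% op$E1) %*% ctx$tH
    tP2 <- (op$Q %*% op$M) %*% ctx$tH
  } else {
    tP1 <- tP2 <- matrix(0, 0L, 0L)
  }
  r <- .ll_core(ctx$tA, ctx$tD, tP, tP1, tP2, ctx$const, eps, grad, grad,
                eps_shared)
  if (r$n_bad > 0L)
    warning(sprintf("%d site(s) with zero likelihood excluded", r$n_bad))
  out <- list(value = r$value, n_bad = r$n_bad)
  if (grad) {
    out$dt1 <- r$dt1
    out$dt2 <- r$dt2
    out$deps <- if (eps_shared) r$deps[1L] else r$deps
  }
  out
}

ll_eval_r <- function(ctx, t1, t2, eps, grad = FALSE, eps_shared = TRUE,
                      cache = NULL) {
  if (length(eps) == 1L) eps <- rep(eps, ctx$m)
  op <- moment_operator(ctx$n, drift_params(t1, t2), cache)
  pref <- weight_prefixes(ctx, eps)
  W <- pref[[ctx$m + 1L]]
  P <- ctx$H %*% t(op$M)
  lik <- rowSums(W * P)
  bad <- !is.finite(lik) | lik <= 0
  if (any(bad)) {
    lik[bad] <- NA_real_
    warning(sprintf("%d site(s) with zero likelihood excluded", sum(bad)))
  }
  ll <- sum(log(lik[!bad])) + sum(ctx$const[!bad])
  out <- list(value = ll, n_bad = sum(bad))
  if (grad) {
    ok <- !bad
    invlik <- 1 / lik[ok]
    M1 <- op$E2 %*% op$Qd %*% op$E1
    M2 <- op$Q %*% op$M
    out$dt1 <- sum(rowSums(W[ok, , drop = FALSE] *
                           (ctx$H[ok, , drop = FALSE] %*% t(M1))) * invlik)
    out$dt2 <- sum(rowSums(W[ok, , drop = FALSE] *
                           (ctx$H[ok, , drop = FALSE] %*% t(M2))) * invlik)
    suf <- weight_suffixes(ctx, eps)
    deps <- numeric(ctx$m)
    for (i in seq_len(ctx$m)) {
      dWi <- conv_mat(conv3_mat_deriv(pref[[i]], triplet_cols_deriv(ctx, i, eps[i])),
                      suf[[i + 1L]])
      deps[i] <- sum(rowSums(dWi[ok, , drop = FALSE] * P[ok, , drop = FALSE]) * invlik)
    }
    out$deps <- if (eps_shared) sum(deps) else deps
  }
  out
}

# convolution with a derivative triplet (middle entry 0)
conv3_mat_deriv <- function(W, dtri) {
  L <- nrow(W); w <- ncol(W)
  out <- matrix(0, L, w + 2L)
  out[, 1:w] <- W * dtri$t0
  out[, 3:(w + 2L)] <- out[, 3:(w + 2L)] + W * dtri$t2
  out
}

#' Log-likelihood of a dataset
#'
#' Total log-likelihood of the read data: the sum over sites of
#' log( sum_k W_k p_{2m,k}(x_l) ), with the moment exponentials shared
#' across sites. Deterministic for fixed inputs; sites whose likelihood
#' underflows to zero are excluded with a warning and counted in the
#' `"n_excluded"` attribute.
#'
#' @param ds A [continuity_dataset()].
#' @param params A [drift_params()].
#' @param eps Per-read error probability: one shared value or one per
#'   individual.
#' @param cache Optional [moment_cache()].
#' @return Log-likelihood (numeric scalar) with attribute `n_excluded`.
#' @examples
#' ds <- simulate_dataset(L = 200, m = 2, coverage = 1, seed = 1)
#' data_loglik(ds, drift_params(0.02, 0.05), eps = 0.01)
#' @export
data_loglik <- function(ds, params, eps = 0.01, cache = NULL) {
  stopifnot(inherits(ds, "continuity_dataset"), inherits(params, "drift_params"))
  check_eps(eps)
  ctx <- loglik_context(ds)
  if (!length(eps) %in% c(1L, ctx$m))
    stop("eps must have length 1 or one entry per individual", call. = FALSE)
  r <- ll_eval(ctx, params$t1, params$t2, eps, grad = FALSE, cache = cache)
  structure(r$value, n_excluded = r$n_bad)
}
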