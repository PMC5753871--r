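#include <Rcpp.h>
#include <vector>
#include <cmath>
using namespace Rcpp;

// Per-site likelihood core shared by all parameter evaluations.
//
// For each site l the caller supplies the moment-side row tP[, l] =
// M h_n(x_l) (and, for gradients, the same rows under the t1- and
// t2-derivative operators). All per-site matrices arrive transposed
// (sites in columns) so one site's data is contiguous. This routine
// builds the allele-count weights W_k by sequential convolution of the
// per-individual genotype-likelihood triplets (scaled by the heterozygote
// likelihood, so a triplet is (T0, 2, T2) with T0 = (2e)^d (2(1-e))^a and
// T2 = (2(1-e))^d (2e)^a), accumulates sum_l log(sum_k W_k P_k) + c_l,
// and optionally the analytic gradient with respect to t1, t2 and the
// error rate(s). For a shared error rate dW/de is carried through the
// convolution recursion by the product rule; per-individual rates use
// leave-one-out prefix/suffix convolutions. Sites whose likelihood is not
// positive are skipped and counted.

// [[Rcpp::export(name = ".ll_core")]]
List ll_core(const IntegerMatrix& tA, const IntegerMatrix& tD,
             const NumericMatrix& tP,
             const NumericMatrix& tP1, const NumericMatrix& tP2,
             const NumericVector& cvec,
             const NumericVector& eps, bool grad, bool want_t2,
             bool eps_shared) {
  const int m = tA.nrow(), L = tA.ncol(), n = 2 * m, K = n + 1;

  int maxdep = 0;
  const int* tAp = INTEGER(tA); const int* tDp = INTEGER(tD);
  for (int j = 0; j < L * m; ++j) {
    int dep = tAp[j] + tDp[j];
    if (dep > maxdep) maxdep = dep;
  }
  // per-individual power tables for (2e) and (2(1-e))
  std::vector<std::vector<double>> pu(m), pv(m);
  for (int i = 0; i < m; ++i) {
    double u = 2.0 * eps[i], v = 2.0 * (1.0 - eps[i]);
    pu[i].resize(maxdep + 1); pv[i].resize(maxdep + 1);
    pu[i][0] = 1.0; pv[i][0] = 1.0;
    for (int k = 1; k <= maxdep; ++k) {
      pu[i][k] = pu[i][k - 1] * u;
      pv[i][k] = pv[i][k - 1] * v;
    }
  }

  const double* Pp = REAL(tP);
  const double* P1p = grad ? REAL(tP1) : nullptr;
  const double* P2p = (grad && want_t2) ? REAL(tP2) : nullptr;

  double ll = 0.0, dt1 = 0.0, dt2 = 0.0;
  NumericVector deps(m);
  int n_bad = 0;

  std::vector<double> W(K), dWs(K), nw(K), ndw(K), tmp(K), dW(K);
  std::vector<std::vector<double>> pref, suf;
  if (grad && !eps_shared) {
    pref.assign(m + 1, std::vector<double>(K, 0.0));
    suf.assign(m + 1, std::vector<double>(K, 0.0));
  }
  std::vector<double> t0(m), t2v(m), dt0(m), dt2v(m);

  for (int l = 0; l < L; ++l) {
    const int* a_l = tAp + (size_t)l * m;
    const int* d_l = tDp + (size_t)l * m;
    const double* P_l = Pp + (size_t)l * K;
    for (int i = 0; i < m; ++i) {
      int a = a_l[i], d = d_l[i];
      t0[i] = pu[i][d] * pv[i][a];
      t2v[i] = pv[i][d] * pu[i][a];
      if (grad) {
        dt0[i] = (d > 0 ? 2.0 * d * pu[i][d - 1] * pv[i][a] : 0.0)
               - (a > 0 ? 2.0 * a * pu[i][d] * pv[i][a - 1] : 0.0);
        dt2v[i] = (a > 0 ? 2.0 * a * pv[i][d] * pu[i][a - 1] : 0.0)
                - (d > 0 ? 2.0 * d * pv[i][d - 1] * pu[i][a] : 0.0);
      }
    }

    bool pair_grad = grad && eps_shared;
    std::fill(W.begin(), W.end(), 0.0); W[0] = 1.0;
    if (pair_grad) std::fill(dWs.begin(), dWs.end(), 0.0);
    int w = 1;
    for (int i = 0; i < m; ++i) {
      std::fill(nw.begin(), nw.end(), 0.0);
      if (pair_grad) std::fill(ndw.begin(), ndw.end(), 0.0);
      for (int k = 0; k < w; ++k) {
        double val = W[k];
        nw[k] += val * t0[i];
        nw[k + 1] += 2.0 * val;
        nw[k + 2] += val * t2v[i];
        if (pair_grad) {
          // product rule: conv(dW, T_i) + conv(W, dT_i)
          double dval = dWs[k];
          ndw[k] += dval * t0[i] + val * dt0[i];
          ndw[k + 1] += 2.0 * dval;
          ndw[k + 2] += dval * t2v[i] + val * dt2v[i];
        }
      }
      std::swap(W, nw);
      if (pair_grad) std::swap(dWs, ndw);
      w += 2;
    }

    double lik = 0.0;
    for (int k = 0; k < K; ++k) lik += W[k] * P_l[k];
    if (!(lik > 0.0) || !std::isfinite(lik)) { ++n_bad; continue; }
    ll += std::log(lik) + cvec[l];

    if (!grad) continue;
    double inv = 1.0 / lik;
    const double* P1_l = P1p + (size_t)l * K;
    double s1 = 0.0;
    for (int k = 0; k < K; ++k) s1 += W[k] * P1_l[k];
    dt1 += s1 * inv;
    if (want_t2) {
      const double* P2_l = P2p + (size_t)l * K;
      double s2 = 0.0;
      for (int k = 0; k < K; ++k) s2 += W[k] * P2_l[k];
      dt2 += s2 * inv;
    }
    if (eps_shared) {
      double se = 0.0;
      for (int k = 0; k < K; ++k) se += dWs[k] * P_l[k];
      deps[0] += se * inv;
    } else {
      // leave-one-out via prefix/suffix convolutions
      std::fill(pref[0].begin(), pref[0].end(), 0.0); pref[0][0] = 1.0;
      for (int i = 0; i < m; ++i) {
        int wi = 2 * i + 1;
        std::vector<double>& in = pref[i];
        std::vector<double>& out = pref[i + 1];
        std::fill(out.begin(), out.end(), 0.0);
        for (int k = 0; k < wi; ++k) {
          double val = in[k];
          out[k] += val * t0[i];
          out[k + 1] += 2.0 * val;
          out[k + 2] += val * t2v[i];
        }
      }
      std::fill(suf[m].begin(), suf[m].end(), 0.0); suf[m][0] = 1.0;
      for (int i = m - 1; i >= 0; --i) {
        int wi = 2 * (m - 1 - i) + 1;
        std::vector<double>& in = suf[i + 1];
        std::vector<double>& out = suf[i];
        std::fill(out.begin(), out.end(), 0.0);
        for (int k = 0; k < wi; ++k) {
          double val = in[k];
          out[k] += val * t0[i];
          out[k + 1] += 2.0 * val;
          out[k + 2] += val * t2v[i];
        }
      }
      for (int i = 0; i < m; ++i) {
        int wp = 2 * i + 1;
        std::fill(tmp.begin(), tmp.end(), 0.0);
        for (int k = 0; k < wp; ++k) {
          double val = pref[i][k];
          tmp[k] += val * dt0[i];
          tmp[k + 2] += val * dt2v[i];
        }
        int ws = 2 * (m - 1 - i) + 1;
        std::fill(dW.begin(), dW.end(), 0.0);
        for (int k = 0; k < wp + 2 && k < K; ++k) {
          double val = tmp[k];
          if (val == 0.0) continue;
          for (int j = 0; j < ws; ++j) dW[k + j] += val * suf[i + 1][j];
        }
        double se = 0.0;
        for (int k = 0; k < K; ++k) se += dW[k] * P_l[k];
        deps[i] += se * inv;
      }
    }
  }
  return List::create(_["value"] = ll, _["dt1"] = dt1, _["dt2"] = dt2,
                      _["deps"] = deps, _["n_bad"] = n_bad);
}
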