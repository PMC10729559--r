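#include <Rcpp.h>
using namespace Rcpp;

// Two-state (IBD / DBD) hidden Markov model over a pair of haploid
// genotypes, with distance-dependent transitions
//   a_ij(d) = delta_ij * exp(-k*rho*d) + (1 - exp(-k*rho*d)) * pi_j,
// stationary distribution pi = (f, 1-f), and per-site emission
// probabilities supplied by the caller.  EM updates: f <- mean posterior
// IBD occupancy; k <- expected state-switch count / (rho * total gap).
// Scaled forward-backward; Viterbi in log space with a reset to pi at
// every chromosome start.
//
// e_ibd, e_dbd : per-site emission probabilities (length T)
// gap          : bp distance to the previous used site (ignored at starts)
// new_chrom    : TRUE where the chain restarts
// [[Rcpp::export]]
List ibd_hmm_core(NumericVector e_ibd, NumericVector e_dbd,
                  NumericVector gap, LogicalVector new_chrom,
                  double rho, double f_init, double k_init,
                  int max_iters, double tol) {
  const int T = e_ibd.size();
  if (T < 1) stop("no informative sites");
  double f = f_init, k = k_init;
  NumericVector a1(T), a2(T), b1(T), b2(T), cvec(T);
  double loglik = 0.0, f_post = f_init;

  double total_gap = 0.0;
  for (int t = 0; t < T; ++t) if (!new_chrom[t]) total_gap += gap[t];
  if (total_gap <= 0) total_gap = 1.0;

  const double f_lo = 1e-4, f_hi = 1.0 - 1e-4;
  const double k_lo = 1e-3, k_hi = 1e6;

  for (int iter = 0; iter < max_iters; ++iter) {
    const double pi1 = f, pi2 = 1.0 - f;
    // forward (scaled)
    loglik = 0.0;
    for (int t = 0; t < T; ++t) {
      double x1, x2;
      if (new_chrom[t]) {
        x1 = pi1 * e_ibd[t];
        x2 = pi2 * e_dbd[t];
      } else {
        const double q = std::exp(-k * rho * gap[t]);
        const double p11 = q + (1 - q) * pi1, p12 = (1 - q) * pi2;
        const double p21 = (1 - q) * pi1,     p22 = q + (1 - q) * pi2;
        x1 = (a1[t - 1] * p11 + a2[t - 1] * p21) * e_ibd[t];
        x2 = (a1[t - 1] * p12 + a2[t - 1] * p22) * e_dbd[t];
      }
      double c = x1 + x2;
      if (c <= 0 || !std::isfinite(c)) c = 1e-300;
      a1[t] = x1 / c; a2[t] = x2 / c; cvec[t] = c;
      loglik += std::log(c);
    }
    // backward (scaled by the same c)
    for (int t = T - 1; t >= 0; --t) {
      if (t == T - 1 || new_chrom[t + 1]) {
        b1[t] = 1.0; b2[t] = 1.0;
      } else {
        const double q = std::exp(-k * rho * gap[t + 1]);
        const double p11 = q + (1 - q) * pi1, p12 = (1 - q) * pi2;
        const double p21 = (1 - q) * pi1,     p22 = q + (1 - q) * pi2;
        const double n1 = e_ibd[t + 1] * b1[t + 1];
        const double n2 = e_dbd[t + 1] * b2[t + 1];
        b1[t] = (p11 * n1 + p12 * n2) / cvec[t + 1];
        b2[t] = (p21 * n1 + p22 * n2) / cvec[t + 1];
      }
    }
    // E-step accumulators
    double occ = 0.0, switches = 0.0;
    for (int t = 0; t < T; ++t) {
      occ += a1[t] * b1[t];
      if (t > 0 && !new_chrom[t]) {
        const double q = std::exp(-k * rho * gap[t]);
        const double p12 = (1 - q) * pi2;
        const double p21 = (1 - q) * pi1;
        const double xi12 = a1[t - 1] * p12 * e_dbd[t] * b2[t] / cvec[t];
        const double xi21 = a2[t - 1] * p21 * e_ibd[t] * b1[t] / cvec[t];
        switches += xi12 + xi21;
      }
    }
    f_post = occ / T;
    double f_new = std::min(std::max(f_post, f_lo), f_hi);
    double k_new = std::min(std::max(switches / (rho * total_gap), k_lo),
                            k_hi);
    const bool done = std::abs(f_new - f) < tol && std::abs(k_new - k) < tol;
    f = f_new; k = k_new;
    if (done) break;
  }

  // Viterbi at the final parameters (log space)
  IntegerVector path(T);
  NumericVector d1(T), d2(T);
  IntegerVector ptr1(T), ptr2(T);
  const double pi1 = f, pi2 = 1.0 - f;
  for (int t = 0; t < T; ++t) {
    const double le1 = std::log(std::max(e_ibd[t], 1e-300));
    const double le2 = std::log(std::max(e_dbd[t], 1e-300));
    if (new_chrom[t]) {
      d1[t] = std::log(pi1) + le1;
      d2[t] = std::log(pi2) + le2;
      ptr1[t] = ptr2[t] = 0;
    } else {
      const double q = std::exp(-k * rho * gap[t]);
      const double l11 = std::log(q + (1 - q) * pi1);
      const double l12 = std::log(std::max((1 - q) * pi2, 1e-300));
      const double l21 = std::log(std::max((1 - q) * pi1, 1e-300));
      const double l22 = std::log(q + (1 - q) * pi2);
      const double c11 = d1[t - 1] + l11, c21 = d2[t - 1] + l21;
      const double c12 = d1[t - 1] + l12, c22 = d2[t - 1] + l22;
      if (c11 >= c21) { d1[t] = c11 + le1; ptr1[t] = 1; }
      else           { d1[t] = c21 + le1; ptr1[t] = 2; }
      if (c12 >= c22) { d2[t] = c12 + le2; ptr2[t] = 1; }
      else           { d2[t] = c22 + le2; ptr2[t] = 2; }
    }
  }
  // backtrace per chromosome block
  int t = T - 1;
  while (t >= 0) {
    // find block start
    int s = t;
    while (!new_chrom[s]) --s;
    int state = (d1[t] >= d2[t]) ? 1 : 2;
    for (int u = t; u > s; --u) {
      path[u] = state;
      state = (state == 1) ? ptr1[u] : ptr2[u];
    }
    path[s] = state;
    t = s - 1;
  }

  double f_vit = 0.0;
  for (int u = 0; u < T; ++u) if (path[u] == 1) f_vit += 1.0;
  f_vit /= T;

  return List::create(
    _["f"] = f, _["k"] = k, _["loglik"] = loglik,
    _["f_posterior"] = f_post, _["f_viterbi"] = f_vit,
    _["path"] = path);
}
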