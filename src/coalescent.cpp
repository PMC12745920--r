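// Structured two-deme coalescent simulator used as an independent Monte-Carlo
// check on the diffusion engine. Genealogies of n1 + n2 sampled chromosomes
// are traced backwards through a sequence of epochs with (possibly
// exponentially changing) deme sizes and constant per-epoch migration.
// Expected spectrum entries per unit theta are 0.5 * E[branch length
// subtending (i, j) samples], with time in 2*N_ref generations. Exponential
// size change is handled by exact inversion of the integrated coalescence
// intensity, not by stepwise approximation. Uses R's RNG (set.seed applies).

#include <Rcpp.h>
#include <vector>
#include <cmath>
using namespace Rcpp;

// Waiting time until a coalescence in a deme whose backward size is
// nu(u) = nu0 * exp(g * (u0 + u)) given k lineages; returns R_PosInf when the
// event never happens. E is a standard exponential draw.
static double coal_wait(double E, double k2pairs, double nu0, double g, double u0) {
  if (k2pairs <= 0) return R_PosInf;
  if (g == 0.0) return E * nu0 / k2pairs;
  // Lambda(w) = k2pairs/nu0 * (exp(-g*u0) - exp(-g*(u0+w))) / g  ==  E
  double rhs = std::exp(-g * u0) - g * E * nu0 / k2pairs;
  if (rhs <= 0) return R_PosInf;
  double w = -std::log(rhs) / g - u0;
  return (w > 0) ? w : 0.0;
}

// [[Rcpp::export]]
List coal_jsfs_cpp(int n1, int n2, int nreps,
                   NumericVector dur,     // backward epoch durations (last = Inf ancestral)
                   NumericVector nu1_0, NumericVector g1,
                   NumericVector nu2_0, NumericVector g2,
                   NumericVector m12, NumericVector m21) {
  const int R1 = n1 + 1, R2 = n2 + 1;
  NumericMatrix sum(R1, R2), sumsq(R1, R2);
  const int nep = dur.size();
  std::vector<int> deme(n1 + n2), c1(n1 + n2), c2(n1 + n2);
  std::vector<double> acc(R1 * R2);

  for (int rep = 0; rep < nreps; ++rep) {
    int k = n1 + n2;
    for (int i = 0; i < n1; ++i) { deme[i] = 0; c1[i] = 1; c2[i] = 0; }
    for (int i = 0; i < n2; ++i) { deme[n1 + i] = 1; c1[n1 + i] = 0; c2[n1 + i] = 1; }
    std::fill(acc.begin(), acc.end(), 0.0);

    int ep = 0;
    double u = 0.0;  // time within current backward epoch
    while (k > 1) {
      int k1 = 0;
      for (int i = 0; i < k; ++i) if (deme[i] == 0) ++k1;
      int k2 = k - k1;
      double p1 = k1 * (k1 - 1) / 2.0, p2 = k2 * (k2 - 1) / 2.0;

      double wc1 = coal_wait(exp_rand(), p1, nu1_0[ep], g1[ep], u);
      double wc2 = coal_wait(exp_rand(), p2, nu2_0[ep], g2[ep], u);
      double wm12 = (k1 > 0 && m12[ep] > 0) ? exp_rand() / (k1 * m12[ep]) : R_PosInf;
      double wm21 = (k2 > 0 && m21[ep] > 0) ? exp_rand() / (k2 * m21[ep]) : R_PosInf;

      int ev = 0;  // 0 c1, 1 c2, 2 m12, 3 m21
      double w = wc1;
      if (wc2 < w) { w = wc2; ev = 1; }
      if (wm12 < w) { w = wm12; ev = 2; }
      if (wm21 < w) { w = wm21; ev = 3; }

      double remain = dur[ep] - u;
      if (w >= remain && ep < nep - 1) {  // cross into older epoch
        for (int i = 0; i < k; ++i) acc[c1[i] * R2 + c2[i]] += remain;
        ++ep; u = 0.0;
        if (ep == nep - 1) {  // ancestral single deme
          for (int i = 0; i < k; ++i) deme[i] = 0;
        }
        continue;
      }
      for (int i = 0; i < k; ++i) acc[c1[i] * R2 + c2[i]] += w;
      u += w;

      if (ev <= 1) {  // coalescence in deme ev
        int d = ev;
        int kk = (d == 0) ? k1 : k2;
        int pick1 = (int)std::floor(unif_rand() * kk);
        int pick2 = (int)std::floor(unif_rand() * (kk - 1));
        if (pick2 >= pick1) ++pick2;
        int ia = -1, ib = -1, seen = 0;
        for (int i = 0; i < k; ++i) {
          if (deme[i] == d) {
            if (seen == pick1) ia = i;
            if (seen == pick2) ib = i;
            ++seen;
          }
        }
        c1[ia] += c1[ib]; c2[ia] += c2[ib];
        deme[ib] = deme[k - 1]; c1[ib] = c1[k - 1]; c2[ib] = c2[k - 1];
        --k;
      } else {  // migration: move one lineage between demes
        int from = (ev == 2) ? 0 : 1;
        int kk = (from == 0) ? k1 : k2;
        int pick = (int)std::floor(unif_rand() * kk);
        int seen = 0;
        for (int i = 0; i < k; ++i) {
          if (deme[i] == from) {
            if (seen == pick) { deme[i] = 1 - from; break; }
            ++seen;
          }
        }
      }
    }
    for (int i = 0; i < R1; ++i)
      for (int j = 0; j < R2; ++j) {
        double v = 0.5 * acc[i * R2 + j];
        sum(i, j) += v;
        sumsq(i, j) += v * v;
      }
  }

  NumericMatrix mean(R1, R2), se(R1, R2);
  for (int i = 0; i < R1; ++i)
    for (int j = 0; j < R2; ++j) {
      double m = sum(i, j) / nreps;
      mean(i, j) = m;
      double var = (sumsq(i, j) / nreps - m * m) * nreps / (nreps - 1.0);
      se(i, j) = std::sqrt(std::max(var, 0.0) / nreps);
    }
  return List::create(_["mean"] = mean, _["se"] = se);
}
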