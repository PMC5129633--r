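#include <Rcpp.h>
#include <cmath>
using namespace Rcpp;

// Felsenstein pruning over compressed site patterns with a discrete-gamma
// rate mixture. Transition matrices are built per edge and per rate category
// from the eigen-decomposition of the (symmetrized) GTR rate matrix:
// P(t) = A diag(exp(lambda * t * r)) Ainv.
//
// edge: (nedge x 2) 1-based node indices in postorder (children before
//       parents), ape convention: tips 1..ntip.
// tippart: 4 x npat x ntip array of tip partial likelihoods (ambiguity codes
//       and missing data already expanded to 0/1 masks).
// Underflow is handled by per-pattern scaling accumulated in log space.

static inline void edge_pmat(const double* A, const double* Ainv,
                             const double* lambda, double t, double* P) {
  double e[4];
  for (int i = 0; i < 4; ++i) e[i] = std::exp(lambda[i] * t);
  for (int i = 0; i < 4; ++i) {
    for (int j = 0; j < 4; ++j) {
      double s = 0.0;
      // column-major: A[i + 4*k], Ainv[k + 4*j]
      for (int k = 0; k < 4; ++k) s += A[i + 4 * k] * e[k] * Ainv[k + 4 * j];
      P[i + 4 * j] = s > 0.0 ? s : 0.0;
    }
  }
}

// [[Rcpp::export(name = ".cpp_pruning_loglik")]]
NumericVector cpp_pruning_loglik(IntegerMatrix edge, int ntip,
                                 NumericVector tippart, NumericVector weights,
                                 NumericVector pi, NumericMatrix A,
                                 NumericMatrix Ainv, NumericVector lambda,
                                 NumericVector brlen, NumericVector rates,
                                 bool persite) {
  const int nedge = edge.nrow();
  const int npat = weights.size();
  const int ncat = rates.size();

  int maxnode = ntip;
  for (int e = 0; e < nedge; ++e) {
    if (edge(e, 0) > maxnode) maxnode = edge(e, 0);
    if (edge(e, 1) > maxnode) maxnode = edge(e, 1);
  }
  const int ntot = maxnode;
  const int root = edge(nedge - 1, 0);

  std::vector<double> patloglik((size_t)npat * ncat);
  // pattern-major partials: part[node][state][pattern], contiguous in p so
  // the 4x4 edge update vectorizes over patterns
  std::vector<double> part((size_t)ntot * 4 * npat);
  std::vector<double> tipl((size_t)ntip * 4 * npat);
  std::vector<double> logscale(npat);
  std::vector<double> contrib((size_t)4 * npat);
  double P[16];
  const double* Ap = A.begin();
  const double* Aip = Ainv.begin();
  const double* lam = lambda.begin();
  const double* tp = tippart.begin();

  for (int tip = 0; tip < ntip; ++tip)
    for (int p = 0; p < npat; ++p)
      for (int i = 0; i < 4; ++i)
        tipl[((size_t)tip * 4 + i) * npat + p] =
            tp[i + 4 * ((size_t)p + (size_t)npat * tip)];

  for (int c = 0; c < ncat; ++c) {
    std::copy(tipl.begin(), tipl.end(), part.begin());
    std::fill(part.begin() + (size_t)ntip * 4 * npat, part.end(), 1.0);
    std::fill(logscale.begin(), logscale.end(), 0.0);

    for (int e = 0; e < nedge; ++e) {
      const int par = edge(e, 0) - 1;
      const int chi = edge(e, 1) - 1;
      edge_pmat(Ap, Aip, lam, brlen[e] * rates[c], P);
      const double* Lc = &part[(size_t)chi * 4 * npat];
      double* Lp = &part[(size_t)par * 4 * npat];
      for (int i = 0; i < 4; ++i) {
        const double pi0 = P[i], pi1 = P[i + 4], pi2 = P[i + 8],
                     pi3 = P[i + 12];
        double* ci = &contrib[(size_t)i * npat];
        for (int p = 0; p < npat; ++p)
          ci[p] = pi0 * Lc[p] + pi1 * Lc[npat + p] + pi2 * Lc[2 * npat + p] +
                  pi3 * Lc[3 * npat + p];
      }
      for (int p = 0; p < npat; ++p) {
        const double c0 = contrib[p], c1 = contrib[npat + p],
                     c2 = contrib[2 * npat + p], c3 = contrib[3 * npat + p];
        double m = c0 > c1 ? c0 : c1;
        if (c2 > m) m = c2;
        if (c3 > m) m = c3;
        if (m < 1e-80) {  // rescale rarely, only near underflow
          if (m <= 0.0) {
            Lp[p] = Lp[npat + p] = Lp[2 * npat + p] = Lp[3 * npat + p] = 0.0;
            continue;
          }
          const double inv = 1.0 / m;
          Lp[p] *= c0 * inv;
          Lp[npat + p] *= c1 * inv;
          Lp[2 * npat + p] *= c2 * inv;
          Lp[3 * npat + p] *= c3 * inv;
          logscale[p] += std::log(m);
        } else {
          Lp[p] *= c0;
          Lp[npat + p] *= c1;
          Lp[2 * npat + p] *= c2;
          Lp[3 * npat + p] *= c3;
        }
      }
    }

    const double* Lr = &part[(size_t)(root - 1) * 4 * npat];
    for (int p = 0; p < npat; ++p) {
      double s = pi[0] * Lr[p] + pi[1] * Lr[npat + p] +
                 pi[2] * Lr[2 * npat + p] + pi[3] * Lr[3 * npat + p];
      patloglik[(size_t)p * ncat + c] =
          (s > 0.0 ? std::log(s) : R_NegInf) + logscale[p];
    }
  }

  NumericVector out(persite ? npat : 1);
  double total = 0.0;
  const double logncat = std::log((double)ncat);
  for (int p = 0; p < npat; ++p) {
    double mx = R_NegInf;
    for (int c = 0; c < ncat; ++c)
      if (patloglik[(size_t)p * ncat + c] > mx)
        mx = patloglik[(size_t)p * ncat + c];
    double acc = 0.0;
    for (int c = 0; c < ncat; ++c)
      acc += std::exp(patloglik[(size_t)p * ncat + c] - mx);
    double ll = mx + std::log(acc) - logncat;
    if (persite) out[p] = ll;
    total += weights[p] * ll;
  }
  if (!persite) out[0] = total;
  return out;
}

// Simulate states down a tree: edges in cladewise order (parents before
// children). Uses R's RNG so results are reproducible via set.seed().
// Returns ntip x nsites integer states in 1..4.
// [[Rcpp::export(name = ".cpp_simulate_states")]]
IntegerMatrix cpp_simulate_states(IntegerMatrix edge, int ntip,
                                  NumericVector brlen, NumericMatrix A,
                                  NumericMatrix Ainv, NumericVector lambda,
                                  NumericVector pi, NumericVector rates,
                                  int nsites) {
  const int nedge = edge.nrow();
  const int ncat = rates.size();
  int maxnode = ntip;
  for (int e = 0; e < nedge; ++e) {
    if (edge(e, 0) > maxnode) maxnode = edge(e, 0);
    if (edge(e, 1) > maxnode) maxnode = edge(e, 1);
  }
  const int root = edge(0, 0);
  std::vector<int> cat(nsites);
  for (int s = 0; s < nsites; ++s)
    cat[s] = (int)(unif_rand() * ncat) % ncat;

  std::vector<int> states((size_t)maxnode * nsites);
  double cpi[4];
  cpi[0] = pi[0];
  for (int i = 1; i < 4; ++i) cpi[i] = cpi[i - 1] + pi[i];
  for (int s = 0; s < nsites; ++s) {
    double u = unif_rand() * cpi[3];
    int st = 0;
    while (st < 3 && u > cpi[st]) ++st;
    states[(size_t)(root - 1) * nsites + s] = st;
  }

  std::vector<double> Pcum((size_t)ncat * 16);
  double P[16];
  for (int e = 0; e < nedge; ++e) {
    const int par = edge(e, 0) - 1;
    const int chi = edge(e, 1) - 1;
    for (int c = 0; c < ncat; ++c) {
      edge_pmat(A.begin(), Ainv.begin(), lambda.begin(),
                brlen[e] * rates[c], P);
      for (int i = 0; i < 4; ++i) {
        double rs = P[i] + P[i + 4] + P[i + 8] + P[i + 12];
        double acc = 0.0;
        for (int j = 0; j < 4; ++j) {
          acc += P[i + 4 * j] / rs;
          Pcum[c * 16 + i * 4 + j] = acc;
        }
      }
    }
    for (int s = 0; s < nsites; ++s) {
      const int ps = states[(size_t)par * nsites + s];
      const double* row = &Pcum[(size_t)cat[s] * 16 + ps * 4];
      double u = unif_rand();
      int st = 0;
      while (st < 3 && u > row[st]) ++st;
      states[(size_t)chi * nsites + s] = st;
    }
  }
  IntegerMatrix out(ntip, nsites);
  for (int t = 0; t < ntip; ++t)
    for (int s = 0; s < nsites; ++s)
      out(t, s) = states[(size_t)t * nsites + s] + 1;
  return out;
}

// Multinomial likelihood statistic T = sum_p N_p ln(N_p / N) over site
// patterns (columns of an integer state matrix, rows = taxa in fixed order).
// [[Rcpp::export(name = ".cpp_multinomial_T")]]
double cpp_multinomial_T(IntegerMatrix states) {
  const int ntip = states.nrow();
  const int nsites = states.ncol();
  std::map<std::vector<int>, int> counts;
  std::vector<int> key(ntip);
  for (int s = 0; s < nsites; ++s) {
    for (int t = 0; t < ntip; ++t) key[t] = states(t, s);
    ++counts[key];
  }
  double T = 0.0;
  for (const auto& kv : counts)
    T += kv.second * std::log((double)kv.second / nsites);
  return T;
}
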