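// Non-negative matrix factorization core: multiplicative (Frobenius) updates
// followed by projected-gradient refinement, repeated over random restarts.
// Uses R's RNG so set.seed() on the R side governs determinism.
#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]
using namespace Rcpp;

static double frob_cost(const arma::mat& D, const arma::mat& B,
                        const arma::mat& H) {
  return arma::accu(arma::square(D - B * H));
}

// Lee-Seung multiplicative updates; appends per-iteration cost to trace.
// Cost is evaluated from cached cross-products:
//   E = ||D||^2 - 2 tr(B' D H') + tr((B'B)(HH'))
static double mult_phase(const arma::mat& D, arma::mat& B, arma::mat& H,
                         int max_iter, double tol, double normD2,
                         std::vector<double>& trace) {
  const double eps = 1e-12;
  double prev = frob_cost(D, B, H);
  trace.push_back(prev);
  for (int it = 0; it < max_iter; ++it) {
    arma::mat BtD = B.t() * D;                 // K x T
    H %= BtD / ((B.t() * B) * H + eps);
    arma::mat DHt = D * H.t();                 // N x K
    arma::mat HHt = H * H.t();                 // K x K
    B %= DHt / (B * HHt + eps);
    double c = normD2 - 2.0 * arma::accu(B % DHt) +
               arma::accu((B.t() * B) % HHt);
    if (c < 0) c = 0;                          // roundoff floor near exact fits
    trace.push_back(c);
    if (prev - c <= tol * std::max(prev, 1e-300)) { prev = c; break; }
    prev = c;
  }
  return prev;
}

// Alternating projected-gradient refinement with backtracking; only accepts
// cost decreases, so the trace stays non-increasing.
static double pg_phase(const arma::mat& D, arma::mat& B, arma::mat& H,
                       int max_iter, double tol, std::vector<double>& trace) {
  double cost = frob_cost(D, B, H);
  double aB = 1e-3, aH = 1e-3;
  for (int it = 0; it < max_iter; ++it) {
    double start = cost;
    // B step
    {
      arma::mat g = 2.0 * (B * H - D) * H.t();
      for (int bt = 0; bt < 20; ++bt) {
        arma::mat B2 = arma::clamp(B - aB * g, 0.0, arma::datum::inf);
        double c2 = frob_cost(D, B2, H);
        if (c2 < cost) { B = B2; cost = c2; aB *= 1.5; break; }
        aB *= 0.5;
      }
    }
    // H step
    {
      arma::mat g = 2.0 * B.t() * (B * H - D);
      for (int bt = 0; bt < 20; ++bt) {
        arma::mat H2 = arma::clamp(H - aH * g, 0.0, arma::datum::inf);
        double c2 = frob_cost(D, B, H2);
        if (c2 < cost) { H = H2; cost = c2; aH *= 1.5; break; }
        aH *= 0.5;
      }
    }
    trace.push_back(cost);
    if (start - cost <= tol * std::max(start, 1e-300)) break;
  }
  return cost;
}

// [[Rcpp::export(name = ".cpp_nmf")]]
List cpp_nmf(const arma::mat& D, int K, int restarts, int max_iter,
             double tol, int pg_iter) {
  const int n = D.n_rows, t = D.n_cols;
  const double normD2 = arma::accu(arma::square(D));
  const double scale = std::sqrt(arma::accu(D) / (n * t * (double)K) + 1e-12);
  arma::mat bestB, bestH;
  double bestE = arma::datum::inf;
  std::vector<double> bestTrace;
  RNGScope scope;
  for (int r = 0; r < restarts; ++r) {
    arma::mat B(n, K), H(K, t);
    for (arma::uword i = 0; i < B.n_elem; ++i) B(i) = unif_rand() * scale;
    for (arma::uword i = 0; i < H.n_elem; ++i) H(i) = unif_rand() * scale;
    std::vector<double> trace;
    mult_phase(D, B, H, max_iter, tol, normD2, trace);
    pg_phase(D, B, H, pg_iter, tol * 0.1, trace);
    double E = frob_cost(D, B, H);             // exact final cost
    if (E < bestE) {
      bestE = E; bestB = B; bestH = H; bestTrace = trace;
    }
  }
  return List::create(_["B"] = bestB, _["H"] = bestH, _["E"] = bestE,
                      _["cost_trace"] = bestTrace,
                      _["restarts_used"] = restarts);
}
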