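// Numerical core: Erlangization kernel powering, forward likelihood
// recursion over the hidden phase, and exact event-driven simulation.
#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]

using namespace Rcpp;

// Clip tiny negative entries (round-off from the linear solve or the
// squaring) and renormalize each row to sum 1.  Entries at or below
// -tol signal a numerically broken solve and raise an error.
static void clip_and_renormalize(arma::mat& P, const double tol) {
  const arma::uword n = P.n_rows;
  double worst = P.min();
  if (worst <= -tol)
    stop("transition kernel has entry %g <= -%g: numerical solve is broken",
         worst, tol);
  P.clamp(0.0, arma::datum::inf);
  for (arma::uword i = 0; i < n; ++i) {
    double s = arma::accu(P.row(i));
    if (s <= 0.0)
      stop("transition kernel row %d has zero mass", (int)(i + 1));
    P.row(i) /= s;
  }
}

// (Pi)^ell by repeated squaring; ell must be a power of two (checked in
// R).  Rows are re-normalized after every squaring so stochasticity is
// preserved to round-off throughout.
// [[Rcpp::export]]
arma::mat kernel_power_cpp(arma::mat Pi, const int ell, const double neg_tol) {
  clip_and_renormalize(Pi, neg_tol);
  int k = ell;
  while (k > 1) {
    Pi = Pi * Pi;
    clip_and_renormalize(Pi, neg_tol);
    k /= 2;
  }
  return Pi;
}

// Scaled forward recursion for one series of counts under a lag-Delta
// kernel P on the truncated state space (level-major flat index
// m*nE + phase).  When increments = true, P is read at source level 0
// and the observed count increment (exact for the level-homogeneous
// pure-birth case); a negative increment then has probability zero.
// Returns the log-probability of counts[1..n] given counts[0], with
// the hidden phase initialised at pi0.  -Inf signals probability zero.
// [[Rcpp::export]]
double forward_loglik_cpp(const arma::mat& P, const int nE,
                          const IntegerVector& counts,
                          const arma::rowvec& pi0,
                          const bool increments) {
  const int n = counts.size() - 1;
  const int C = (int)(P.n_rows / nE) - 1;
  std::vector<double> alpha(pi0.begin(), pi0.end()), anew(nE);
  double loglik = 0.0;
  for (int i = 1; i <= n; ++i) {
    const int m_prev = counts[i - 1], m_next = counts[i];
    int src, dst;
    if (increments) {
      const int inc = m_next - m_prev;
      if (inc < 0) return R_NegInf;
      if (inc > C)
        stop("count increment %d exceeds kernel truncation %d", inc, C);
      src = 0; dst = inc;
    } else {
      if (m_prev > C || m_next > C)
        stop("observed count exceeds kernel truncation C = %d", C);
      src = m_prev; dst = m_next;
    }
    std::fill(anew.begin(), anew.end(), 0.0);
    for (int x = 0; x < nE; ++x) {
      const double a = alpha[x];
      if (a == 0.0) continue;
      // column-major: entry (src*nE + x, dst*nE + y)
      const double* col = P.memptr() + (arma::uword)(src * nE + x);
      const arma::uword ld = P.n_rows;
      for (int y = 0; y < nE; ++y)
        anew[y] += a * col[(arma::uword)(dst * nE + y) * ld];
    }
    double scale = 0.0;
    for (int y = 0; y < nE; ++y) scale += anew[y];
    if (scale <= 0.0 || !std::isfinite(scale)) return R_NegInf;
    loglik += std::log(scale);
    for (int y = 0; y < nE; ++y) alpha[y] = anew[y] / scale;
  }
  return loglik;
}

// Batched version: one call for a whole observation set.
// [[Rcpp::export]]
NumericVector forward_loglik_set_cpp(const arma::mat& P, const int nE,
                                     const List& counts_list,
                                     const arma::rowvec& pi0,
                                     const bool increments) {
  const int N = counts_list.size();
  NumericVector out(N);
  for (int k = 0; k < N; ++k)
    out[k] = forward_loglik_cpp(P, nE, counts_list[k], pi0, increments);
  return out;
}

// Exact event-driven (Gillespie) simulation of {X_t, M_t}.  Phase
// coding: 0 = off (only when has_switch), 1..L = birth phases; a birth
// fires on completion of phase L and returns the phase to 1.  Counts
// are unbounded (no truncation).  Uses R's RNG so set.seed() governs
// reproducibility.  Returns the count at grid times 0, Delta, ...,
// n*Delta; if keep_path, also the full jump chain.
// [[Rcpp::export]]
List simulate_grid_cpp(const double q_on, const double q_off,
                       const NumericVector& lambdas, const double mu,
                       const bool has_switch, const int n,
                       const double delta, const int m0, const int x0,
                       const bool keep_path) {
  RNGScope scope;
  const int L = lambdas.size();
  int x = x0, m = m0;
  double t = 0.0;
  const double t_max = n * delta;
  IntegerVector grid(n + 1);
  int gi = 0;
  std::vector<double> jump_t;
  std::vector<int> jump_x, jump_m;
  if (keep_path) { jump_t.push_back(0.0); jump_x.push_back(x); jump_m.push_back(m); }

  for (;;) {
    // enabled transitions from (x, m)
    double rate_switch = 0.0, rate_phase = 0.0, rate_death = mu * m;
    if (has_switch && x == 0) rate_switch = q_on;          // off -> on
    if (x >= 1) {
      if (has_switch && x == 1) rate_switch = q_off;       // on -> off
      rate_phase = lambdas[x - 1];                         // phase advance / birth
    }
    const double total = rate_switch + rate_phase + rate_death;
    double t_next;
    if (total <= 0.0) t_next = R_PosInf;
    else t_next = t + R::rexp(1.0 / total);
    // emit grid observations passed before the next jump
    while (gi <= n && gi * delta <= t_next) { grid[gi] = m; ++gi; }
    if (gi > n || t_next > t_max) break;
    t = t_next;
    const double u = unif_rand() * total;
    if (u < rate_switch) {
      x = (x == 0) ? 1 : 0;
    } else if (u < rate_switch + rate_phase) {
      if (x == L) { m += 1; x = 1; }                       // birth
      else x += 1;
    } else {
      m -= 1;                                              // death
    }
    if (keep_path) { jump_t.push_back(t); jump_x.push_back(x); jump_m.push_back(m); }
  }
  if (keep_path)
    return List::create(_["counts"] = grid,
                        _["times"] = wrap(jump_t),
                        _["phase"] = wrap(jump_x),
                        _["count"] = wrap(jump_m));
  return List::create(_["counts"] = grid);
}
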