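#include <Rcpp.h>
#include <vector>
#include <cmath>
using namespace Rcpp;

// Exact (direct-method) stochastic simulation of the three-species chain.
// Species per cell: r (HetR, immobile), s (PatS), n (HetN); s and n hop to
// nearest neighbours.  A per-cell duplication channel at rate rho*V grows
// the filament; rho = 0 gives the fixed-domain algorithm.
//
// Channels per cell (index):
//  0..2  production of R, S, N at alpha*V
//  3     HetR autoactivation, beta_R * V * h(r/V)
//  4     PatS activation,     beta_S * V * h(r/V)
//  5..7  linear decay k*x
//  8     trimolecular 2R+S -> 0, mu_S * r(r-1) s / V^2
//  9     trimolecular 2R+N -> 0, mu_N * r(r-1) n / V^2
// 10,11  S hop left / right (absent past an open edge)
// 12,13  N hop left / right
// 14     cell duplication, rho*V

static const int NCH = 15;

struct Pars {
  double aR, aS, aN, bR, bS, K2, kR, kS, kN, muS, muN, DS, DN;
};

static inline double hill_count(double r, double V, const Pars &p) {
  double x = r / V;
  double x2 = x * x;
  return x2 / (p.K2 + x2);
}

static void cell_propensities(int i, int omega,
                              const std::vector<double> &r,
                              const std::vector<double> &s,
                              const std::vector<double> &n,
                              double V, const Pars &p, double dup_rate,
                              bool periodic, double *a) {
  double h = hill_count(r[i], V, p);
  a[0] = p.aR * V;
  a[1] = p.aS * V;
  a[2] = p.aN * V;
  a[3] = p.bR * V * h;
  a[4] = p.bS * V * h;
  a[5] = p.kR * r[i];
  a[6] = p.kS * s[i];
  a[7] = p.kN * n[i];
  double tri = r[i] * (r[i] - 1.0) / (V * V);
  a[8] = p.muS * tri * s[i];
  a[9] = p.muN * tri * n[i];
  bool has_left  = (i > 0) || (periodic && omega > 2);
  bool has_right = (i < omega - 1) || (periodic && omega > 2);
  a[10] = has_left  ? p.DS * s[i] : 0.0;
  a[11] = has_right ? p.DS * s[i] : 0.0;
  a[12] = has_left  ? p.DN * n[i] : 0.0;
  a[13] = has_right ? p.DN * n[i] : 0.0;
  a[14] = dup_rate;
}

// [[Rcpp::export]]
List ssa_chain_cpp(NumericVector par, double V,
                   NumericMatrix init, double tau_end,
                   NumericVector sample_times,
                   double rho, int split_rule, int max_omega,
                   bool periodic) {
  Pars p;
  p.aR = par[0]; p.aS = par[1]; p.aN = par[2];
  p.bR = par[3]; p.bS = par[4];
  p.K2 = par[5] * par[5];
  p.kR = par[6]; p.kS = par[7]; p.kN = par[8];
  p.muS = par[9]; p.muN = par[10];
  p.DS = par[11]; p.DN = par[12];

  int omega = init.nrow();
  if (max_omega < omega) max_omega = omega;
  std::vector<double> r(omega), s(omega), n(omega);
  for (int i = 0; i < omega; ++i) {
    r[i] = init(i, 0); s[i] = init(i, 1); n[i] = init(i, 2);
  }

  double dup_rate = rho * V;
  bool truncated = false;

  std::vector<double> prop((size_t)max_omega * NCH, 0.0);
  std::vector<double> cellsum(max_omega, 0.0);
  double total = 0.0;

  auto refresh_cell = [&](int i) {
    double *a = &prop[(size_t)i * NCH];
    cell_propensities(i, omega, r, s, n, V, p, dup_rate, periodic, a);
    double cs = 0.0;
    for (int c = 0; c < NCH; ++c) cs += a[c];
    total += cs - cellsum[i];
    cellsum[i] = cs;
  };
  auto refresh_all = [&]() {
    total = 0.0;
    for (int i = 0; i < omega; ++i) {
      double *a = &prop[(size_t)i * NCH];
      cell_propensities(i, omega, r, s, n, V, p, dup_rate, periodic, a);
      double cs = 0.0;
      for (int c = 0; c < NCH; ++c) cs += a[c];
      cellsum[i] = cs;
      total += cs;
    }
  };
  refresh_all();

  int nsamp = sample_times.size();
  NumericVector out((size_t)nsamp * max_omega * 3, 0.0);
  IntegerVector omega_out(nsamp, 0);
  std::vector<double> dup_t;
  std::vector<int> dup_cell;

  auto record = [&](int k) {
    for (int i = 0; i < omega; ++i) {
      out[(size_t)k + (size_t)nsamp * i] = r[i];
      out[(size_t)k + (size_t)nsamp * (i + max_omega)] = s[i];
      out[(size_t)k + (size_t)nsamp * (i + 2 * max_omega)] = n[i];
    }
    omega_out[k] = omega;
  };

  double t = 0.0;
  int k = 0;
  long long ev = 0;
  while (true) {
    if (total <= 0.0 || !std::isfinite(total)) {
      // absorbing state (or all rates zero): state frozen until tau_end
      while (k < nsamp && sample_times[k] <= tau_end) record(k++);
      break;
    }
    double dt = -std::log(unif_rand()) / total;
    double t_new = t + dt;
    while (k < nsamp && sample_times[k] < t_new &&
           sample_times[k] <= tau_end)
      record(k++);
    if (t_new > tau_end) {
      while (k < nsamp && sample_times[k] <= tau_end) record(k++);
      break;
    }
    t = t_new;

    // pick cell, then channel within the cell
    double u = unif_rand() * total;
    int ci = omega - 1;
    double acc = 0.0;
    for (int i = 0; i < omega; ++i) {
      acc += cellsum[i];
      if (u <= acc) { ci = i; break; }
    }
    double *a = &prop[(size_t)ci * NCH];
    double u2 = u - (acc - cellsum[ci]);
    int ch = NCH - 1;
    double acc2 = 0.0;
    for (int c = 0; c < NCH; ++c) {
      acc2 += a[c];
      if (u2 <= acc2) { ch = c; break; }
    }

    bool left = false;
    switch (ch) {
    case 0: case 3: r[ci] += 1; refresh_cell(ci); break;
    case 1: case 4: s[ci] += 1; refresh_cell(ci); break;
    case 2: n[ci] += 1; refresh_cell(ci); break;
    case 5: r[ci] -= 1; refresh_cell(ci); break;
    case 6: s[ci] -= 1; refresh_cell(ci); break;
    case 7: n[ci] -= 1; refresh_cell(ci); break;
    case 8: r[ci] -= 2; s[ci] -= 1; refresh_cell(ci); break;
    case 9: r[ci] -= 2; n[ci] -= 1; refresh_cell(ci); break;
    case 10: case 12: left = true;  // fall through
    case 11: case 13: {
      int cj = left ? ci - 1 : ci + 1;
      if (cj < 0) cj = omega - 1;            // periodic wrap
      if (cj >= omega) cj = 0;
      if (ch <= 11) { s[ci] -= 1; s[cj] += 1; }
      else          { n[ci] -= 1; n[cj] += 1; }
      refresh_cell(ci); refresh_cell(cj);
      break;
    }
    case 14: {  // duplication of cell ci -> two adjacent daughters
      dup_t.push_back(t);
      dup_cell.push_back(ci + 1);  // 1-based for R
      double rl, sl, nl;
      if (split_rule == 1) {
        rl = R::rbinom(r[ci], 0.5);
        sl = R::rbinom(s[ci], 0.5);
        nl = R::rbinom(n[ci], 0.5);
      } else {
        // equal split, odd molecule to the left daughter
        rl = (double)(((long long)r[ci] + 1) / 2);
        sl = (double)(((long long)s[ci] + 1) / 2);
        nl = (double)(((long long)n[ci] + 1) / 2);
      }
      double rr = r[ci] - rl, sr = s[ci] - sl, nr = n[ci] - nl;
      r.insert(r.begin() + ci + 1, rr);
      s.insert(s.begin() + ci + 1, sr);
      n.insert(n.begin() + ci + 1, nr);
      r[ci] = rl; s[ci] = sl; n[ci] = nl;
      ++omega;
      if (omega >= max_omega) { dup_rate = 0.0; truncated = true; }
      refresh_all();
      break;
    }
    }

    if (++ev % 4000000 == 0) refresh_all();  // guard against FP drift
  }

  out.attr("dim") = IntegerVector::create(nsamp, max_omega, 3);
  return List::create(_["counts"] = out,
                      _["omega"] = omega_out,
                      _["dup_times"] = NumericVector(dup_t.begin(), dup_t.end()),
                      _["dup_cells"] = IntegerVector(dup_cell.begin(), dup_cell.end()),
                      _["truncated"] = truncated,
                      _["n_events"] = (double)ev);
}
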