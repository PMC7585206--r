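#include <Rcpp.h>
#include <vector>
#include <algorithm>
#include <cstdint>

using namespace Rcpp;

// Solvers for the linear ordering problem underlying most-likely splicing
// order inference: maximize sum_{rank(i) < rank(j)} logD[i][j] over all
// permutations of 1..n. Both solvers are exact.

// ---------------------------------------------------------------------------
// Subset dynamic program (Held-Karp style), n <= 20.
//
// f(S) = best score achievable ordering the elements of S among themselves,
// where the first-spliced element i of S contributes sum_{j in S\{i}} logD[i][j].
// Pairs between S and already-placed elements are accounted for when the
// earlier element is placed, so f(full set) is the global optimum.
// Also counts the number of optimal permutations exactly (ties at `tol`).
// ---------------------------------------------------------------------------

// [[Rcpp::export]]
List lop_solve_dp(NumericMatrix logD, double tol) {
  const int n = logD.nrow();
  if (n < 1 || n > 20) stop("subset DP solver requires 1 <= n <= 20");
  const std::size_t nsub = std::size_t(1) << n;
  std::vector<double> f(nsub, 0.0);
  for (std::size_t S = 1; S < nsub; ++S) {
    double best = R_NegInf;
    for (int i = 0; i < n; ++i) {
      if (!((S >> i) & 1)) continue;
      double w = 0.0;
      for (int j = 0; j < n; ++j)
        if (j != i && ((S >> j) & 1)) w += logD(i, j);
      double v = w + f[S ^ (std::size_t(1) << i)];
      if (v > best) best = v;
    }
    f[S] = best;
  }

  // exact count of optimal orders (capped to avoid overflow; only ==1 matters)
  const double cap = 1e15;
  std::vector<double> g(nsub, 0.0);
  g[0] = 1.0;
  for (std::size_t S = 1; S < nsub; ++S) {
    double cnt = 0.0;
    for (int i = 0; i < n; ++i) {
      if (!((S >> i) & 1)) continue;
      double w = 0.0;
      for (int j = 0; j < n; ++j)
        if (j != i && ((S >> j) & 1)) w += logD(i, j);
      if (w + f[S ^ (std::size_t(1) << i)] >= f[S] - tol)
        cnt += g[S ^ (std::size_t(1) << i)];
    }
    g[S] = std::min(cnt, cap);
  }

  // lexicographically smallest optimal order
  IntegerVector order(n);
  std::size_t S = nsub - 1;
  for (int pos = 0; pos < n; ++pos) {
    for (int i = 0; i < n; ++i) {
      if (!((S >> i) & 1)) continue;
      double w = 0.0;
      for (int j = 0; j < n; ++j)
        if (j != i && ((S >> j) & 1)) w += logD(i, j);
      if (w + f[S ^ (std::size_t(1) << i)] >= f[S] - tol) {
        order[pos] = i + 1;
        S ^= (std::size_t(1) << i);
        break;
      }
    }
  }

  return List::create(_["order"] = order,
                      _["value"] = f[nsub - 1],
                      _["n_optima"] = g[nsub - 1],
                      _["unique"] = (g[nsub - 1] == 1.0));
}

// ---------------------------------------------------------------------------
// Exact branch and bound for the 0-1 linear ordering program, n < 100.
//
// The integer program has binaries y[i][j] (i before j) with triangle
// constraints; its feasible points are exactly the total orders, so a
// depth-first search over order prefixes with an admissible bound solves the
// same program exactly. Bound for a node = score of the fixed prefix (all
// pairs involving a placed element are resolved) + sum over unordered pairs
// of still-free elements of max(logD[i][j], logD[j][i]).
// ---------------------------------------------------------------------------

namespace {

struct BnB {
  int n;
  const NumericMatrix &logD;
  std::vector<std::vector<double>> M;   // pairwise max, for the bound
  std::vector<int> best_order;
  double best_val;
  // phase 2 (uniqueness): count full solutions with value >= target
  bool counting;
  double target;
  int n_found;
  std::vector<int> cur;

  BnB(const NumericMatrix &ld) : n(ld.nrow()), logD(ld), best_val(R_NegInf),
      counting(false), target(0.0), n_found(0) {
    M.assign(n, std::vector<double>(n, 0.0));
    for (int i = 0; i < n; ++i)
      for (int j = 0; j < n; ++j)
        M[i][j] = std::max(logD(i, j), logD(j, i));
  }

  double score(const std::vector<int> &ord) const {
    double s = 0.0;
    for (int a = 0; a < n; ++a)
      for (int b = a + 1; b < n; ++b) s += logD(ord[a], ord[b]);
    return s;
  }

  // greedy incumbent: sort by net outgoing weight, then adjacent-swap descent
  std::vector<int> incumbent() const {
    std::vector<int> ord(n);
    std::vector<double> wins(n, 0.0);
    for (int i = 0; i < n; ++i) {
      ord[i] = i;
      for (int j = 0; j < n; ++j)
        if (j != i) wins[i] += logD(i, j) - logD(j, i);
    }
    std::stable_sort(ord.begin(), ord.end(),
                     [&](int a, int b) { return wins[a] > wins[b]; });
    bool moved = true;
    while (moved) {
      moved = false;
      for (int k = 0; k + 1 < n; ++k) {
        int a = ord[k], b = ord[k + 1];
        if (logD(b, a) > logD(a, b)) {
          std::swap(ord[k], ord[k + 1]);
          moved = true;
        }
      }
    }
    return ord;
  }

  void dfs(std::vector<int> &free_el, double cur_score, double ub_rem) {
    if (counting && n_found >= 2) return;
    const double eps = 1e-9;
    if (free_el.empty()) {
      if (counting) {
        if (cur_score >= target - eps) {
          ++n_found;
          if (n_found == 1) best_order = cur;  // not used in counting phase
        }
      } else if (cur_score > best_val + 1e-12) {
        best_val = cur_score;
        best_order = cur;
      }
      return;
    }
    double bound = cur_score + ub_rem;
    if (counting) {
      if (bound < target - eps) return;
    } else {
      if (bound <= best_val + 1e-12) return;
    }
    // order candidates by their contribution against the remaining set
    std::vector<std::pair<double, int>> cand;
    cand.reserve(free_el.size());
    for (size_t a = 0; a < free_el.size(); ++a) {
      int i = free_el[a];
      double w = 0.0;
      for (size_t b = 0; b < free_el.size(); ++b)
        if (b != a) w += logD(i, free_el[b]);
      cand.push_back(std::make_pair(w, i));
    }
    std::sort(cand.begin(), cand.end(),
              [](const std::pair<double, int> &x, const std::pair<double, int> &y) {
                return x.first > y.first;
              });
    for (size_t c = 0; c < cand.size(); ++c) {
      int i = cand[c].second;
      double w = cand[c].first;
      // removing i from the free set: drop its bound terms
      double drop = 0.0;
      for (size_t b = 0; b < free_el.size(); ++b)
        if (free_el[b] != i) drop += M[i][free_el[b]];
      std::vector<int> rest;
      rest.reserve(free_el.size() - 1);
      for (size_t b = 0; b < free_el.size(); ++b)
        if (free_el[b] != i) rest.push_back(free_el[b]);
      cur.push_back(i);
      dfs(rest, cur_score + w, ub_rem - drop);
      cur.pop_back();
      if (counting && n_found >= 2) return;
    }
  }

  double ub_full() const {
    double u = 0.0;
    for (int i = 0; i < n; ++i)
      for (int j = i + 1; j < n; ++j) u += M[i][j];
    return u;
  }
};

} // namespace

// [[Rcpp::export]]
List lop_solve_bnb(NumericMatrix logD, double tol) {
  const int n = logD.nrow();
  if (n < 1 || n >= 100) stop("branch-and-bound solver requires 1 <= n < 100");
  BnB solver(logD);

  std::vector<int> inc = solver.incumbent();
  solver.best_order = inc;
  solver.best_val = solver.score(inc);

  std::vector<int> free_el(n);
  for (int i = 0; i < n; ++i) free_el[i] = i;
  solver.cur.clear();
  solver.dfs(free_el, 0.0, solver.ub_full());

  std::vector<int> opt = solver.best_order;
  double z = solver.best_val;

  // uniqueness: count solutions attaining the optimum (stop at 2)
  solver.counting = true;
  solver.target = z;
  solver.n_found = 0;
  solver.cur.clear();
  solver.dfs(free_el, 0.0, solver.ub_full());
  bool unique = (solver.n_found <= 1);
  (void)tol;

  IntegerVector order(n);
  for (int i = 0; i < n; ++i) order[i] = opt[i] + 1;
  return List::create(_["order"] = order,
                      _["value"] = z,
                      _["unique"] = unique);
}
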