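#include <Rcpp.h>
#include <vector>
using namespace Rcpp;

// Constrained maximum-base-pair (Nussinov-style) folding.
//
// Pairs are drawn from {AU, UA, GC, CG, GU, UG}; the hairpin rule requires
// j - i > 3.  Constraints: fixed pairs must appear, forbidden positions may
// not pair, new pairs may be confined to a region, and everything must be
// mutually non-crossing (nested skeleton only).  Deterministic traceback:
// on ties, position i pairs with the smallest admissible partner (the
// bifurcation point), and pairing is preferred over leaving i unpaired.

static bool complementary(char a, char b) {
  return (a == 'A' && b == 'U') || (a == 'U' && b == 'A') ||
         (a == 'G' && b == 'C') || (a == 'C' && b == 'G') ||
         (a == 'G' && b == 'U') || (a == 'U' && b == 'G');
}

struct FoldCtx {
  const std::string& s;
  const IntegerVector& fixed;     // 1-based partner, 0 = none
  const LogicalVector& forbidden;
  int rlo, rhi;                   // 1-based inclusive region; 0 = whole
  std::vector<std::pair<int,int> > fpairs;
  std::vector<int> memo;          // (n+2)^2
  int n;
  FoldCtx(const std::string& s_, const IntegerVector& f,
          const LogicalVector& fb, int rlo_, int rhi_)
    : s(s_), fixed(f), forbidden(fb), rlo(rlo_), rhi(rhi_) {
    n = s.size();
    for (int i = 1; i <= n; ++i)
      if (fixed[i - 1] > i) fpairs.push_back(std::make_pair(i, fixed[i - 1]));
    memo.assign((n + 2) * (n + 2), -1);
  }
  bool can_pair(int i, int j) const {  // 1-based
    if (fixed[i - 1] == j) return true;          // a fixed pair
    if (fixed[i - 1] != 0 || fixed[j - 1] != 0) return false;
    if (forbidden[i - 1] || forbidden[j - 1]) return false;
    if (j - i <= 3) return false;
    if (!complementary(s[i - 1], s[j - 1])) return false;
    if (rlo > 0 && (i < rlo || j > rhi)) return false;
    for (size_t p = 0; p < fpairs.size(); ++p) {
      int a = fpairs[p].first, b = fpairs[p].second;
      if ((i < a && a < j && j < b) || (a < i && i < b && b < j)) return false;
    }
    return true;
  }
  int N(int i, int j) {
    if (i >= j) return 0;
    int& mm = memo[i * (n + 2) + j];
    if (mm >= 0) return mm;
    int best = -1;
    if (fixed[i - 1] == 0) best = N(i + 1, j);
    if (fixed[i - 1] != 0 && fixed[i - 1] > i) {
      int k = fixed[i - 1];
      best = std::max(best, 1 + N(i + 1, k - 1) + N(k + 1, j));
    } else if (fixed[i - 1] == 0) {
      for (int k = i + 4; k <= j; ++k)
        if (can_pair(i, k))
          best = std::max(best, 1 + N(i + 1, k - 1) + N(k + 1, j));
    }
    if (best < 0) stop("infeasible folding subproblem");  // not reachable
    return mm = best;
  }
  void trace(int i, int j, std::vector<std::pair<int,int> >& out) {
    while (i < j) {
      int best = N(i, j);
      bool paired = false;
      int klo = (fixed[i - 1] > i) ? fixed[i - 1] : i + 4;
      int khi = (fixed[i - 1] > i) ? fixed[i - 1] : j;
      if (fixed[i - 1] == 0 || fixed[i - 1] > i) {
        for (int k = klo; k <= khi; ++k) {
          if (!can_pair(i, k)) continue;
          if (1 + N(i + 1, k - 1) + N(k + 1, j) == best) {
            out.push_back(std::make_pair(i, k));
            trace(i + 1, k - 1, out);
            i = k + 1;  // continue with the right part iteratively
            paired = true;
            break;
          }
        }
      }
      if (!paired) ++i;  // i left unpaired
    }
  }
};

// [[Rcpp::export(name = ".fold_cpp")]]
List fold_cpp(std::string seq, IntegerVector fixed_partner,
              LogicalVector forbidden, int region_lo, int region_hi) {
  int n = seq.size();
  if ((int)fixed_partner.size() != n || (int)forbidden.size() != n)
    stop("constraint vectors must match sequence length");
  FoldCtx ctx(seq, fixed_partner, forbidden, region_lo, region_hi);
  int total = (n > 0) ? ctx.N(1, n) : 0;
  std::vector<std::pair<int,int> > pairs;
  if (n > 0) ctx.trace(1, n, pairs);
  if ((int)pairs.size() != total) stop("internal error: traceback mismatch");
  IntegerVector pi(pairs.size()), pj(pairs.size());
  LogicalVector pf(pairs.size());
  for (size_t k = 0; k < pairs.size(); ++k) {
    pi[k] = pairs[k].first; pj[k] = pairs[k].second;
    pf[k] = fixed_partner[pairs[k].first - 1] == pairs[k].second;
  }
  return List::create(_["i"] = pi, _["j"] = pj, _["fixed"] = pf,
                      _["count"] = total);
}
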