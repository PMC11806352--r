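#include <Rcpp.h>
#include <limits>
using namespace Rcpp;

// Semi-global affine-gap alignment: the query is aligned in full, template
// overhangs at either end are free (fit alignment, so fragments map into
// long templates).  A gap of length L costs open + (L-1) * extend.
//
// States: M (match/mismatch), X (insertion: query-only), Y (deletion:
// template-only).  Deterministic traceback: on ties prefer Match, then
// Delete, then Insert; at the terminal row the largest template column wins.
//
// 'N' matches nothing (scored as a mismatch against anything).

static const double NEG = -1e18;
static const double EPS = 1e-9;

// [[Rcpp::export(name = ".align_cpp")]]
List align_cpp(std::string q, std::string t,
               double match, double mismatch,
               double gap_open, double gap_extend) {
  const int n = q.size(), m = t.size();
  if (n == 0 || m == 0) stop("empty sequence");

  std::vector<double> M((n + 1) * (m + 1), NEG);
  std::vector<double> X((n + 1) * (m + 1), NEG);
  std::vector<double> Y((n + 1) * (m + 1), NEG);
  auto at = [m](int i, int j) { return i * (m + 1) + j; };

  M[at(0, 0)] = 0.0;
  for (int j = 1; j <= m; ++j) Y[at(0, j)] = 0.0;  // free leading template gap
  for (int i = 1; i <= n; ++i)
    X[at(i, 0)] = gap_open + (i - 1) * gap_extend;

  for (int i = 1; i <= n; ++i) {
    for (int j = 1; j <= m; ++j) {
      const char a = q[i - 1], b = t[j - 1];
      const double s = (a == b && a != 'N') ? match : mismatch;
      double dm = std::max(M[at(i - 1, j - 1)],
                  std::max(X[at(i - 1, j - 1)], Y[at(i - 1, j - 1)]));
      M[at(i, j)] = (dm <= NEG) ? NEG : dm + s;

      double xo = std::max(M[at(i - 1, j)], Y[at(i - 1, j)]);
      double x1 = (xo <= NEG) ? NEG : xo + gap_open;
      double x2 = (X[at(i - 1, j)] <= NEG) ? NEG : X[at(i - 1, j)] + gap_extend;
      X[at(i, j)] = std::max(x1, x2);

      double yo = std::max(M[at(i, j - 1)], X[at(i, j - 1)]);
      double y1 = (yo <= NEG) ? NEG : yo + gap_open;
      double y2 = (Y[at(i, j - 1)] <= NEG) ? NEG : Y[at(i, j - 1)] + gap_extend;
      Y[at(i, j)] = std::max(y1, y2);
    }
  }

  // Terminal: free trailing template gap -> best over columns of row n,
  // preferring larger j, and M over Y over X within a column.
  double best = NEG;
  int bj = -1, bstate = 0;  // 0 = M, 1 = X, 2 = Y
  const int order[3] = {0, 2, 1};
  for (int j = 0; j <= m; ++j) {
    for (int oi = 0; oi < 3; ++oi) {
      int s = order[oi];
      double v = (s == 0) ? M[at(n, j)] : (s == 1 ? X[at(n, j)] : Y[at(n, j)]);
      if (v <= NEG) continue;
      if (v > best + EPS || (v > best - EPS && j > bj)) {
        best = v; bj = j; bstate = s;
      }
    }
  }
  if (bj < 0) stop("alignment infeasible");

  std::vector<char> ops;  // collected reversed
  for (int j = m; j > bj; --j) ops.push_back('D');  // free trailing deletes

  int i = n, j = bj, state = bstate;
  while (i > 0 || j > 0) {
    if (state == 0) {       // M consumed (i, j)
      const char a = q[i - 1], b = t[j - 1];
      const double s = (a == b && a != 'N') ? match : mismatch;
      const double v = M[at(i, j)] - s;
      ops.push_back('M');
      --i; --j;
      if (i == 0 && j == 0) break;
      if (std::abs(M[at(i, j)] - v) < EPS) state = 0;
      else if (std::abs(Y[at(i, j)] - v) < EPS) state = 2;
      else state = 1;
    } else if (state == 1) { // X consumed query nt i
      ops.push_back('I');
      const double v = X[at(i, j)];
      --i;
      if (i == 0 && j == 0) break;
      if (j == 0) { state = 1; continue; }  // leading query-insert chain
      if (std::abs(M[at(i, j)] + gap_open - v) < EPS) state = 0;
      else if (std::abs(Y[at(i, j)] + gap_open - v) < EPS) state = 2;
      else state = 1;
    } else {                 // Y consumed template nt j
      ops.push_back('D');
      const double v = Y[at(i, j)];
      --j;
      if (i == 0 && j == 0) break;
      if (i == 0) { state = 2; continue; }  // free leading delete chain
      if (std::abs(M[at(i, j)] + gap_open - v) < EPS) state = 0;
      else if (std::abs(X[at(i, j)] + gap_open - v) < EPS) state = 1;
      else state = 2;
    }
  }
  std::reverse(ops.begin(), ops.end());

  // Sanity: op counts must reconstruct both lengths.
  int cq = 0, ct = 0;
  for (char op : ops) { if (op != 'D') ++cq; if (op != 'I') ++ct; }
  if (cq != n || ct != m) stop("internal error: inconsistent traceback");

  IntegerVector posmap(n, NA_INTEGER), revmap(m, NA_INTEGER);
  int qi = 0, tj = 0;
  std::vector<char> opv; std::vector<int> lenv;
  for (char op : ops) {
    if (op == 'M') { posmap[qi] = tj + 1; revmap[tj] = qi + 1; ++qi; ++tj; }
    else if (op == 'I') ++qi;
    else ++tj;
    if (!opv.empty() && opv.back() == op) lenv.back()++;
    else { opv.push_back(op); lenv.push_back(1); }
  }
  CharacterVector opcodes(opv.size());
  for (size_t k = 0; k < opv.size(); ++k)
    opcodes[k] = std::string(1, opv[k]);
  return List::create(_["op"] = opcodes,
                      _["len"] = IntegerVector(lenv.begin(), lenv.end()),
                      _["score"] = best,
                      _["posmap"] = posmap,
                      _["revmap"] = revmap);
}
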