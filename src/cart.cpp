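// Fully grown classification trees over categorical sequence features.
//
// Features are integer-coded nucleotide states in 0..4 (A, C, G, U, '-').
// Splits are binary category subsets, chosen by information gain (entropy in
// bits). Ties break deterministically: lowest column index first, then the
// lexicographically smallest left subset (subsets read as increasing category
// sequences). Growth continues through zero-gain plateaus until every leaf is
// pure or constant on all features, so resubstitution accuracy always equals
// the per-unique-row majority bound.

#include <Rcpp.h>
#include <cmath>
#include <vector>
using namespace Rcpp;

static const int NCAT = 5;
static const double GAIN_TOL = 1e-12;

static inline double h_counts(const std::vector<double>& cnt, double n) {
  if (n <= 0.0) return 0.0;
  double h = 0.0;
  for (double c : cnt)
    if (c > 0.0) h -= (c / n) * std::log2(c / n);
  return h;
}

// lexicographic order on subsets viewed as increasing category sequences
static bool lex_less(int a, int b) {
  std::vector<int> va, vb;
  for (int c = 0; c < NCAT; ++c) {
    if (a & (1 << c)) va.push_back(c);
    if (b & (1 << c)) vb.push_back(c);
  }
  return std::lexicographical_compare(va.begin(), va.end(), vb.begin(), vb.end());
}

struct Split {
  int col = -1;
  int mask = 0;        // left categories (observed at the node)
  double gain = -1.0;
  double nl = 0.0, nr = 0.0;
};

static Split find_best_split(const IntegerMatrix& X, const IntegerVector& y,
                             const std::vector<int>& idx, int nclass) {
  const int p = X.ncol();
  const double n = static_cast<double>(idx.size());
  std::vector<double> parent(nclass, 0.0);
  for (int r : idx) parent[y[r]] += 1.0;
  const double hp = h_counts(parent, n);

  Split best;
  std::vector<std::vector<double>> cnt(NCAT, std::vector<double>(nclass));
  std::vector<double> catTot(NCAT);
  std::vector<double> lc(nclass), rc(nclass);

  for (int j = 0; j < p; ++j) {
    for (int c = 0; c < NCAT; ++c) {
      catTot[c] = 0.0;
      std::fill(cnt[c].begin(), cnt[c].end(), 0.0);
    }
    for (int r : idx) {
      const int c = X(r, j);
      cnt[c][y[r]] += 1.0;
      catTot[c] += 1.0;
    }
    int obsMask = 0, firstObs = -1, nobs = 0;
    for (int c = 0; c < NCAT; ++c)
      if (catTot[c] > 0.0) {
        obsMask |= (1 << c);
        if (firstObs < 0) firstObs = c;
        ++nobs;
      }
    if (nobs < 2) continue;
    // enumerate proper nonempty subsets containing the first observed
    // category (canonical representative of each binary partition)
    for (int m = 1; m < (1 << NCAT); ++m) {
      if ((m & obsMask) != m) continue;
      if (!(m & (1 << firstObs))) continue;
      if (m == obsMask) continue;
      double nl = 0.0;
      std::fill(lc.begin(), lc.end(), 0.0);
      for (int c = 0; c < NCAT; ++c)
        if (m & (1 << c)) {
          nl += catTot[c];
          for (int k = 0; k < nclass; ++k) lc[k] += cnt[c][k];
        }
      const double nr = n - nl;
      for (int k = 0; k < nclass; ++k) rc[k] = parent[k] - lc[k];
      const double gain =
          hp - (nl / n) * h_counts(lc, nl) - (nr / n) * h_counts(rc, nr);
      bool better = false;
      if (gain > best.gain + GAIN_TOL) {
        better = true;
      } else if (std::fabs(gain - best.gain) <= GAIN_TOL && j == best.col &&
                 lex_less(m, best.mask)) {
        better = true;
      }
      if (better) {
        best.col = j;
        best.mask = m;
        best.gain = gain;
        best.nl = nl;
        best.nr = nr;
      }
    }
  }
  return best;
}

// [[Rcpp::export]]
List cart_best_split_cpp(IntegerMatrix X, IntegerVector y, int nclass) {
  std::vector<int> idx(X.nrow());
  for (int i = 0; i < X.nrow(); ++i) idx[i] = i;
  Split s = find_best_split(X, y, idx, nclass);
  return List::create(_["col"] = s.col + 1, _["mask"] = s.mask,
                      _["gain"] = s.gain);
}

// [[Rcpp::export]]
List cart_fit_cpp(IntegerMatrix X, IntegerVector y, int nclass) {
  const int n = X.nrow();
  std::vector<int> split_col, left_mask, route_mask, child_l, child_r, pred,
      nn;
  std::vector<std::vector<int>> counts;
  // work stack: (node id, row indices)
  std::vector<std::pair<int, std::vector<int>>> stack;

  auto new_node = [&](const std::vector<int>& idx) {
    split_col.push_back(-1);
    left_mask.push_back(0);
    route_mask.push_back(0);
    child_l.push_back(-1);
    child_r.push_back(-1);
    std::vector<int> cc(nclass, 0);
    for (int r : idx) ++cc[y[r]];
    int best = 0;
    for (int k = 1; k < nclass; ++k)
      if (cc[k] > cc[best]) best = k;  // ties -> lowest class index
    pred.push_back(best);
    nn.push_back(static_cast<int>(idx.size()));
    counts.push_back(cc);
    return static_cast<int>(split_col.size()) - 1;
  };

  std::vector<int> all(n);
  for (int i = 0; i < n; ++i) all[i] = i;
  int root = new_node(all);
  stack.emplace_back(root, std::move(all));
  long resub_correct = 0;

  while (!stack.empty()) {
    int node = stack.back().first;
    std::vector<int> idx = std::move(stack.back().second);
    stack.pop_back();

    bool pure = counts[node][pred[node]] == static_cast<int>(idx.size());
    Split s;
    if (!pure) s = find_best_split(X, y, idx, nclass);
    if (pure || s.col < 0) {  // leaf: pure, or constant on all features
      resub_correct += counts[node][pred[node]];
      continue;
    }

    // routing mask: observed left categories, plus node-unobserved
    // categories sent to the larger child (ties -> left)
    std::vector<double> catTot(NCAT, 0.0);
    for (int r : idx) catTot[X(r, s.col)] += 1.0;
    int rmask = s.mask;
    for (int c = 0; c < NCAT; ++c)
      if (catTot[c] == 0.0 && s.nl >= s.nr) rmask |= (1 << c);

    std::vector<int> li, ri;
    li.reserve(static_cast<size_t>(s.nl));
    ri.reserve(static_cast<size_t>(s.nr));
    for (int r : idx) {
      if (s.mask & (1 << X(r, s.col)))
        li.push_back(r);
      else
        ri.push_back(r);
    }
    split_col[node] = s.col;
    left_mask[node] = s.mask;
    route_mask[node] = rmask;
    int l = new_node(li), r = new_node(ri);
    child_l[node] = l;
    child_r[node] = r;
    stack.emplace_back(l, std::move(li));
    stack.emplace_back(r, std::move(ri));
  }

  const int nnode = static_cast<int>(split_col.size());
  IntegerMatrix cmat(nnode, nclass);
  for (int i = 0; i < nnode; ++i)
    for (int k = 0; k < nclass; ++k) cmat(i, k) = counts[i][k];

  return List::create(
      _["split_col"] = wrap(split_col), _["left_mask"] = wrap(left_mask),
      _["route_mask"] = wrap(route_mask), _["left"] = wrap(child_l),
      _["right"] = wrap(child_r), _["pred"] = wrap(pred), _["n"] = wrap(nn),
      _["counts"] = cmat,
      _["resub_accuracy"] = static_cast<double>(resub_correct) / n);
}

// [[Rcpp::export]]
IntegerVector cart_predict_cpp(IntegerVector split_col,
                               IntegerVector route_mask, IntegerVector left,
                               IntegerVector right, IntegerVector pred,
                               IntegerMatrix X) {
  const int n = X.nrow();
  IntegerVector out(n);
  for (int r = 0; r < n; ++r) {
    int node = 0;
    while (split_col[node] >= 0) {
      const int c = X(r, split_col[node]);
      node = (route_mask[node] & (1 << c)) ? left[node] : right[node];
    }
    out[r] = pred[node];
  }
  return out;
}
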