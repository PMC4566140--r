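// Minimum-free-energy folding of a single stem-loop under a
// nearest-neighbor-lite energy model: per-step stack bonuses by pair type
// (WC/WC, WC/GU, GU/GU), size-independent loop penalties (hairpin, bulge,
// internal), a minimum hairpin loop, and no multibranch loops -- the
// structure space is a single ladder of nested pairs, which is the shape a
// miRNA precursor search needs. Loop sides are capped at max_loop nt.
#include <Rcpp.h>
using namespace Rcpp;

// pair type: 0 = not pairable, 1 = Watson-Crick, 2 = G:U wobble
static inline int pair_type(char a, char b) {
  if ((a == 'A' && b == 'U') || (a == 'U' && b == 'A')) return 1;
  if ((a == 'G' && b == 'C') || (a == 'C' && b == 'G')) return 1;
  if ((a == 'G' && b == 'U') || (a == 'U' && b == 'G')) return 2;
  return 0;
}

// [[Rcpp::export(name = ".fold_stem")]]
List fold_stem(std::string seq,
               double stack_wc, double stack_wc_gu, double stack_gu,
               double hairpin_pen, double bulge_pen, double internal_pen,
               int min_loop, int max_loop) {
  const int n = (int)seq.size();
  const double INF = 1e9;
  // H[i][j]: best energy of a stem closed by pair (i,j), inward
  std::vector<std::vector<double> > H(n, std::vector<double>(n, INF));
  // backtrace: inner pair encoded as k*n+l, -1 = hairpin closes here
  std::vector<std::vector<int> > bt(n, std::vector<int>(n, -2));
  std::vector<std::vector<int> > ptype(n, std::vector<int>(n, 0));
  for (int i = 0; i < n; ++i)
    for (int j = i + 1; j < n; ++j)
      ptype[i][j] = pair_type(seq[i], seq[j]);

  for (int span = min_loop + 1; span < n; ++span) {
    for (int i = 0; i + span < n; ++i) {
      int j = i + span;
      if (!ptype[i][j]) continue;
      double best = INF;
      int arg = -2;
      if (j - i - 1 >= min_loop) { best = hairpin_pen; arg = -1; }
      int kmax = std::min(j - 1, i + 1 + max_loop);
      for (int k = i + 1; k <= kmax; ++k) {
        int lmin = std::max(k + 1, j - 1 - max_loop);
        for (int l = j - 1; l >= lmin; --l) {
          if (!ptype[k][l]) continue;
          if (H[k][l] >= INF) continue;
          double step;
          bool bulge5 = (k > i + 1), bulge3 = (l < j - 1);
          if (!bulge5 && !bulge3) {
            int t1 = ptype[i][j], t2 = ptype[k][l];
            if (t1 == 1 && t2 == 1) step = stack_wc;
            else if (t1 == 2 && t2 == 2) step = stack_gu;
            else step = stack_wc_gu;
          } else if (bulge5 != bulge3) {
            step = bulge_pen;
          } else {
            step = internal_pen;
          }
          double e = step + H[k][l];
          if (e < best) { best = e; arg = k * n + l; }
        }
      }
      H[i][j] = best;
      bt[i][j] = arg;
    }
  }

  // outermost pair: strict improvement scan, i ascending then j descending
  double mfe = 0.0;
  int bi = -1, bj = -1;
  for (int i = 0; i < n; ++i)
    for (int j = n - 1; j > i; --j)
      if (H[i][j] < mfe) { mfe = H[i][j]; bi = i; bj = j; }

  std::string db(n, '.');
  if (bi >= 0) {
    int i = bi, j = bj;
    while (true) {
      db[i] = '('; db[j] = ')';
      int arg = bt[i][j];
      if (arg < 0) break;
      i = arg / n; j = arg % n;
    }
  }
  return List::create(_["structure"] = db, _["mfe"] = mfe);
}
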