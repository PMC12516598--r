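#include <Rcpp.h>
#include <limits>
using namespace Rcpp;

// Affine-gap global alignment (Gotoh 1982), match +1 / mismatch -1,
// a maximal gap run of length k costs gop + gep * k (opening charged once,
// extension per gap symbol), terminal gaps penalised. Three-state DP:
// M ends in an aligned pair, X ends with a gap in s2 (consumes s1),
// Y ends with a gap in s1 (consumes s2).

static const double NEG = -std::numeric_limits<double>::infinity();

struct Gotoh {
  int n, m;
  std::vector<double> M, X, Y;
  double& at(std::vector<double>& V, int i, int j) { return V[i * (m + 1) + j]; }
};

// Tie-break among co-optimal moves: diagonal (M) first, then a gap in the
// shorter input sequence, then a gap in the longer one.
// [[Rcpp::export]]
List gotoh_align_cpp(std::string s1, std::string s2, double gop, double gep,
                     bool traceback = true) {
  int n = s1.size(), m = s2.size();
  if (n == 0 || m == 0) stop("sequences must be nonempty");
  double open = gop + gep, ext = gep;

  Gotoh g; g.n = n; g.m = m;
  size_t sz = (size_t)(n + 1) * (m + 1);
  g.M.assign(sz, NEG); g.X.assign(sz, NEG); g.Y.assign(sz, NEG);
  g.at(g.M, 0, 0) = 0.0;
  for (int i = 1; i <= n; ++i) g.at(g.X, i, 0) = -(gop + gep * i);
  for (int j = 1; j <= m; ++j) g.at(g.Y, 0, j) = -(gop + gep * j);

  for (int i = 1; i <= n; ++i) {
    for (int j = 1; j <= m; ++j) {
      double s = (s1[i - 1] == s2[j - 1]) ? 1.0 : -1.0;
      double dM = g.at(g.M, i - 1, j - 1), dX = g.at(g.X, i - 1, j - 1),
             dY = g.at(g.Y, i - 1, j - 1);
      g.at(g.M, i, j) = s + std::max(dM, std::max(dX, dY));
      g.at(g.X, i, j) = std::max(g.at(g.M, i - 1, j) - open,
                        std::max(g.at(g.X, i - 1, j) - ext,
                                 g.at(g.Y, i - 1, j) - open));
      g.at(g.Y, i, j) = std::max(g.at(g.M, i, j - 1) - open,
                        std::max(g.at(g.X, i, j - 1) - open,
                                 g.at(g.Y, i, j - 1) - ext));
    }
  }

  double sM = g.at(g.M, n, m), sX = g.at(g.X, n, m), sY = g.at(g.Y, n, m);
  double best = std::max(sM, std::max(sX, sY));

  if (!traceback)
    return List::create(_["score"] = best);

  // state codes: 0 = M, 1 = X (gap in s2), 2 = Y (gap in s1)
  bool s1_shorter = n <= m;
  int pref[3];
  pref[0] = 0;
  pref[1] = s1_shorter ? 2 : 1;  // gap in the shorter sequence
  pref[2] = s1_shorter ? 1 : 2;

  const double eps = 1e-9;
  int state = pref[0];
  {
    double sc[3] = {sM, sX, sY};
    for (int k = 0; k < 3; ++k)
      if (sc[pref[k]] >= best - eps) { state = pref[k]; break; }
  }

  std::string a1, a2;
  a1.reserve(n + m); a2.reserve(n + m);
  int i = n, j = m, id = 0;
  while (i > 0 || j > 0) {
    if (state == 0) {
      double s = (s1[i - 1] == s2[j - 1]) ? 1.0 : -1.0;
      if (s1[i - 1] == s2[j - 1]) ++id;
      a1.push_back(s1[i - 1]); a2.push_back(s2[j - 1]);
      double target = g.at(g.M, i, j) - s;
      double prev[3] = {g.at(g.M, i - 1, j - 1), g.at(g.X, i - 1, j - 1),
                        g.at(g.Y, i - 1, j - 1)};
      --i; --j;
      if (i == 0 && j == 0) break;
      for (int k = 0; k < 3; ++k)
        if (prev[pref[k]] >= target - eps) { state = pref[k]; break; }
    } else if (state == 1) {  // gap in s2: emit s1 char over '-'
      a1.push_back(s1[i - 1]); a2.push_back('-');
      double target = g.at(g.X, i, j);
      double prev[3] = {g.at(g.M, i - 1, j) - open, g.at(g.X, i - 1, j) - ext,
                        g.at(g.Y, i - 1, j) - open};
      --i;
      if (i == 0 && j == 0) break;
      for (int k = 0; k < 3; ++k)
        if (prev[pref[k]] >= target - eps) { state = pref[k]; break; }
    } else {  // gap in s1
      a1.push_back('-'); a2.push_back(s2[j - 1]);
      double target = g.at(g.Y, i, j);
      double prev[3] = {g.at(g.M, i, j - 1) - open, g.at(g.X, i, j - 1) - open,
                        g.at(g.Y, i, j - 1) - ext};
      --j;
      if (i == 0 && j == 0) break;
      for (int k = 0; k < 3; ++k)
        if (prev[pref[k]] >= target - eps) { state = pref[k]; break; }
    }
  }
  std::reverse(a1.begin(), a1.end());
  std::reverse(a2.begin(), a2.end());

  return List::create(_["aligned1"] = a1, _["aligned2"] = a2,
                      _["score"] = best, _["id_count"] = id);
}

// Number of identical columns of the optimal alignment for every pair of
// sequences; used to build whole-corpus PID/distance matrices cheaply.
// [[Rcpp::export]]
IntegerMatrix gotoh_id_matrix_cpp(CharacterVector seqs, double gop, double gep) {
  int n = seqs.size();
  IntegerMatrix out(n, n);
  std::vector<std::string> ss(n);
  for (int i = 0; i < n; ++i) ss[i] = as<std::string>(seqs[i]);
  for (int i = 0; i < n; ++i) {
    out(i, i) = ss[i].size();
    for (int j = i + 1; j < n; ++j) {
      List r = gotoh_align_cpp(ss[i], ss[j], gop, gep, true);
      int id = as<int>(r["id_count"]);
      out(i, j) = id; out(j, i) = id;
    }
  }
  return out;
}

// Mean quartet delta: for each quartet order the three pairwise-sum
// quantities m1 <= m2 <= m3; delta = (m3 - m2) / (m3 - m1), 0 when m3 == m1.
// [[Rcpp::export]]
List delta_score_cpp(NumericMatrix D, bool per_taxon = false) {
  int n = D.nrow();
  if (n < 4) stop("delta score needs at least 4 taxa");
  long double total = 0.0;
  double nq = 0.0;
  std::vector<long double> tx(n, 0.0);
  std::vector<double> txn(n, 0.0);
  for (int i = 0; i < n - 3; ++i)
    for (int j = i + 1; j < n - 2; ++j)
      for (int k = j + 1; k < n - 1; ++k)
        for (int l = k + 1; l < n; ++l) {
          double s1 = D(i, j) + D(k, l);
          double s2 = D(i, k) + D(j, l);
          double s3 = D(i, l) + D(j, k);
          double m1 = std::min(s1, std::min(s2, s3));
          double m3 = std::max(s1, std::max(s2, s3));
          double m2 = s1 + s2 + s3 - m1 - m3;
          double d = (m3 > m1) ? (m3 - m2) / (m3 - m1) : 0.0;
          total += d; nq += 1.0;
          if (per_taxon) {
            tx[i] += d; tx[j] += d; tx[k] += d; tx[l] += d;
            txn[i] += 1; txn[j] += 1; txn[k] += 1; txn[l] += 1;
          }
        }
  List out = List::create(_["overall_delta"] = (double)(total / nq),
                          _["n_quartets"] = nq);
  if (per_taxon) {
    NumericVector pt(n);
    for (int i = 0; i < n; ++i) pt[i] = (double)(tx[i] / txn[i]);
    out["per_taxon"] = pt;
  }
  return out;
}
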