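#include <Rcpp.h>
#include <string>
#include <vector>
#include <climits>
using namespace Rcpp;

// Global (end-to-end) alignment with unit costs: match 0, mismatch 1, indel 1.
// Distance = (mismatches + indel columns) / alignment columns, taken from a
// deterministic traceback (preference: diagonal, then up/deletion, then
// left/insertion). An optional band restricts |i - j| <= band; cells outside
// the band are unreachable, so a banded distance can only over-estimate the
// unrestricted one -- callers use it as a fast screen when only "is the
// distance <= d" matters and the band covers 2*d*max_len.

static const int NW_INF = INT_MAX / 4;

// [[Rcpp::export(name = ".nw_align")]]
List nw_align(std::string a, std::string b, int band = -1) {
  // canonical argument order: the minimal edit count is symmetric, but the
  // traceback's indel/column split need not be; ordering the pair makes the
  // reported distance exactly symmetric
  if (b < a) std::swap(a, b);
  const int n = a.size(), m = b.size();
  if (n == 0 || m == 0)
    stop("sequences must be non-empty");

  std::vector<std::vector<int> > D(n + 1, std::vector<int>(m + 1, NW_INF));
  D[0][0] = 0;
  for (int i = 1; i <= n; ++i)
    if (band < 0 || i <= band) D[i][0] = i;
  for (int j = 1; j <= m; ++j)
    if (band < 0 || j <= band) D[0][j] = j;

  for (int i = 1; i <= n; ++i) {
    int jlo = 1, jhi = m;
    if (band >= 0) {
      jlo = std::max(1, i - band);
      jhi = std::min(m, i + band);
    }
    for (int j = jlo; j <= jhi; ++j) {
      int diag = D[i - 1][j - 1];
      if (diag < NW_INF) diag += (a[i - 1] == b[j - 1] ? 0 : 1);
      int up   = D[i - 1][j] < NW_INF ? D[i - 1][j] + 1 : NW_INF;
      int left = D[i][j - 1] < NW_INF ? D[i][j - 1] + 1 : NW_INF;
      int best = std::min(diag, std::min(up, left));
      D[i][j] = best;
    }
  }

  if (D[n][m] >= NW_INF)
    stop("band too narrow: end cell unreachable");

  // traceback, preferring diagonal > up > left
  int i = n, j = m;
  int mismatches = 0, indels = 0, matches = 0;
  while (i > 0 || j > 0) {
    if (i > 0 && j > 0 && D[i - 1][j - 1] < NW_INF &&
        D[i][j] == D[i - 1][j - 1] + (a[i - 1] == b[j - 1] ? 0 : 1)) {
      if (a[i - 1] == b[j - 1]) ++matches; else ++mismatches;
      --i; --j;
    } else if (i > 0 && D[i - 1][j] < NW_INF && D[i][j] == D[i - 1][j] + 1) {
      ++indels; --i;
    } else if (j > 0 && D[i][j - 1] < NW_INF && D[i][j] == D[i][j - 1] + 1) {
      ++indels; --j;
    } else {
      stop("traceback failed");  // unreachable for a consistent matrix
    }
  }

  const int columns = matches + mismatches + indels;
  return List::create(
    _["edits"] = mismatches + indels,
    _["mismatches"] = mismatches,
    _["indels"] = indels,
    _["columns"] = columns,
    _["distance"] = (double)(mismatches + indels) / (double)columns);
}

// [[Rcpp::export(name = ".nw_distance")]]
double nw_distance(std::string a, std::string b, int band = -1) {
  if (a == b) return 0.0;
  List r = nw_align(a, b, band);
  return as<double>(r["distance"]);
}

// Distances from one query to many subjects; avoids R-level loop overhead in
// the clustering inner loop.
// [[Rcpp::export(name = ".nw_distance_many")]]
NumericVector nw_distance_many(std::string a, std::vector<std::string> bs,
                               int band = -1) {
  NumericVector out(bs.size());
  for (size_t k = 0; k < bs.size(); ++k)
    out[k] = (a == bs[k]) ? 0.0 : as<double>(nw_align(a, bs[k], band)["distance"]);
  return out;
}
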