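#include <Rcpp.h>
using namespace Rcpp;

// Position-wise mismatch with 'N' (uncalled) mismatching everything,
// including another 'N'.  Sequences are assumed upper-case ASCII.
static inline bool base_mismatch(char a, char b) {
  return a != b || a == 'N' || b == 'N';
}

// Hamming distance between two equal-length strings, stopping early once
// the count exceeds `cap` (return value is then cap + 1).
// [[Rcpp::export]]
int hamming_cpp(std::string a, std::string b, int cap) {
  if (a.size() != b.size())
    stop("sequences have unequal lengths (%d vs %d)", (int)a.size(), (int)b.size());
  int d = 0;
  for (size_t i = 0; i < a.size(); ++i) {
    if (base_mismatch(a[i], b[i])) {
      if (++d > cap) return cap + 1;
    }
  }
  return d;
}

// Best-stratum assignment of read bins against a hairpin library.
// For each bin returns the minimal distance (NA if > max_mismatch), the
// number of library sequences attaining it, and the 1-based index of the
// first such sequence.  Early exit past min(best - 1, max_mismatch) keeps
// the inner loop cheap once a good match is known.
// [[Rcpp::export]]
IntegerMatrix align_bins_cpp(CharacterVector bins, CharacterVector lib,
                             int max_mismatch) {
  const int nb = bins.size(), nl = lib.size();
  if (nl == 0) stop("empty hairpin library");
  std::vector<std::string> libs(nl);
  for (int j = 0; j < nl; ++j) libs[j] = as<std::string>(lib[j]);
  const size_t L = libs[0].size();
  for (int j = 1; j < nl; ++j)
    if (libs[j].size() != L) stop("library sequences have unequal lengths");

  IntegerMatrix out(nb, 3);
  colnames(out) = CharacterVector::create("distance", "n_best", "best_idx");
  for (int i = 0; i < nb; ++i) {
    const std::string s = as<std::string>(bins[i]);
    if (s.size() != L)
      stop("bin %d has length %d, library has %d", i + 1, (int)s.size(), (int)L);
    int best = max_mismatch + 1, nbest = 0, idx = NA_INTEGER;
    for (int j = 0; j < nl; ++j) {
      const char *t = libs[j].c_str();
      // beating the current best requires d <= min(best, max_mismatch); once
      // d exceeds that it can at most tie a stratum we already count, so the
      // early-exit bound is the current stratum itself
      int bound = best < max_mismatch ? best : max_mismatch;
      int d = 0;
      bool over = false;
      for (size_t k = 0; k < L; ++k) {
        if (base_mismatch(s[k], t[k]) && ++d > bound) { over = true; break; }
      }
      if (over) continue;
      if (d < best) { best = d; nbest = 1; idx = j + 1; }
      else if (d == best) { ++nbest; }
    }
    if (best > max_mismatch) {
      out(i, 0) = NA_INTEGER; out(i, 1) = 0; out(i, 2) = NA_INTEGER;
    } else {
      out(i, 0) = best; out(i, 1) = nbest; out(i, 2) = idx;
    }
  }
  return out;
}

// Histogram of all pairwise hamming distances (each unordered pair once),
// bucketed at 0..max_report plus an overflow bucket.
// [[Rcpp::export]]
IntegerVector pairwise_hamming_hist_cpp(CharacterVector seqs, int max_report) {
  const int n = seqs.size();
  std::vector<std::string> ss(n);
  for (int i = 0; i < n; ++i) ss[i] = as<std::string>(seqs[i]);
  IntegerVector hist(max_report + 2);  // [0..max_report], then ">max_report"
  for (int i = 0; i < n; ++i) {
    const size_t L = ss[i].size();
    for (int j = i + 1; j < n; ++j) {
      if (ss[j].size() != L) stop("library sequences have unequal lengths");
      int d = 0;
      bool over = false;
      for (size_t k = 0; k < L; ++k) {
        if (base_mismatch(ss[i][k], ss[j][k]) && ++d > max_report) {
          over = true; break;
        }
      }
      if (over) ++hist[max_report + 1]; else ++hist[d];
    }
  }
  return hist;
}
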