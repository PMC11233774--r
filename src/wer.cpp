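#include <Rcpp.h>
using namespace Rcpp;

// Levenshtein alignment between two token sequences with uniform costs.
// Backtracking ties are broken preferring substitution over insertion over
// deletion; the tie-break affects the alignment path, never the distance.
static void edit_counts(const std::vector<std::string>& ref,
                        const std::vector<std::string>& hyp,
                        int& S, int& D, int& I) {
  const int n = ref.size(), m = hyp.size();
  std::vector<std::vector<int>> d(n + 1, std::vector<int>(m + 1));
  for (int i = 0; i <= n; ++i) d[i][0] = i;
  for (int j = 0; j <= m; ++j) d[0][j] = j;
  for (int i = 1; i <= n; ++i) {
    for (int j = 1; j <= m; ++j) {
      int sub = d[i - 1][j - 1] + (ref[i - 1] == hyp[j - 1] ? 0 : 1);
      int del = d[i - 1][j] + 1;
      int ins = d[i][j - 1] + 1;
      d[i][j] = std::min(sub, std::min(del, ins));
    }
  }
  S = D = I = 0;
  int i = n, j = m;
  while (i > 0 || j > 0) {
    if (i > 0 && j > 0 &&
        d[i][j] == d[i - 1][j - 1] + (ref[i - 1] == hyp[j - 1] ? 0 : 1)) {
      if (ref[i - 1] != hyp[j - 1]) ++S;
      --i; --j;
    } else if (j > 0 && d[i][j] == d[i][j - 1] + 1) {
      ++I; --j;
    } else {
      ++D; --i;
    }
  }
}

static std::vector<std::string> to_vec(const CharacterVector& x) {
  std::vector<std::string> out;
  out.reserve(x.size());
  for (R_xlen_t i = 0; i < x.size(); ++i) out.push_back(as<std::string>(x[i]));
  return out;
}

// Distance-only Levenshtein with two-row memory, for long token streams.
// [[Rcpp::export]]
int wer_distance_cpp(CharacterVector ref, CharacterVector hyp) {
  std::vector<std::string> a = to_vec(ref), b = to_vec(hyp);
  if (a.size() < b.size()) std::swap(a, b);
  const int n = a.size(), m = b.size();
  std::vector<int> prev(m + 1), cur(m + 1);
  for (int j = 0; j <= m; ++j) prev[j] = j;
  for (int i = 1; i <= n; ++i) {
    cur[0] = i;
    for (int j = 1; j <= m; ++j) {
      int sub = prev[j - 1] + (a[i - 1] == b[j - 1] ? 0 : 1);
      cur[j] = std::min(sub, std::min(prev[j] + 1, cur[j - 1] + 1));
    }
    std::swap(prev, cur);
  }
  return prev[m];
}

// [[Rcpp::export]]
IntegerVector wer_counts_cpp(CharacterVector ref, CharacterVector hyp) {
  int S, D, I;
  edit_counts(to_vec(ref), to_vec(hyp), S, D, I);
  return IntegerVector::create(_["S"] = S, _["D"] = D, _["I"] = I);
}

// Pairwise total edit distance (S + D + I) for a list of token sequences,
// computed through the same alignment routine as wer_counts_cpp.
// [[Rcpp::export]]
IntegerMatrix edit_distance_pairs_cpp(List seqs) {
  const int k = seqs.size();
  std::vector<std::vector<std::string>> v(k);
  for (int i = 0; i < k; ++i) v[i] = to_vec(seqs[i]);
  IntegerMatrix out(k, k);
  for (int a = 0; a < k; ++a) {
    for (int b = 0; b < k; ++b) {
      int S, D, I;
      edit_counts(v[a], v[b], S, D, I);
      out(a, b) = S + D + I;
    }
  }
  return out;
}
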