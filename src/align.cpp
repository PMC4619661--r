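#include <Rcpp.h>
#include <unordered_set>
#include <string>
using namespace Rcpp;

// Semi-global alignment: the whole pattern is aligned against any substring
// of the subject (free subject ends), with unit-cost edit operations
// (substitution, insertion, deletion).  For every pattern we report the
// minimal edit distance over all placements, the 0-based subject start and
// end of one optimal placement (leftmost end on ties), and the number of
// distinct end positions attaining the minimum -- the quantity used to
// decide placement uniqueness across targets and strands.
//
// [[Rcpp::export]]
IntegerMatrix align_semiglobal(CharacterVector patterns, std::string subject) {
  const int m = subject.size();
  const int np = patterns.size();
  IntegerMatrix out(np, 4); // cost, start, end, n_best_ends
  colnames(out) = CharacterVector::create("cost", "start", "end", "n_best");

  std::vector<int> prev(m + 1), cur(m + 1);
  std::vector<int> sprev(m + 1), scur(m + 1); // start bookkeeping

  for (int p = 0; p < np; ++p) {
    std::string pat = as<std::string>(patterns[p]);
    const int n = pat.size();
    if (n == 0 || n > m) { // caller screens these; mark as unalignable
      out(p, 0) = NA_INTEGER; out(p, 1) = NA_INTEGER;
      out(p, 2) = NA_INTEGER; out(p, 3) = 0;
      continue;
    }
    for (int j = 0; j <= m; ++j) { prev[j] = 0; sprev[j] = j; }
    for (int i = 1; i <= n; ++i) {
      cur[0] = i; scur[0] = 0;
      const char pc = pat[i - 1];
      for (int j = 1; j <= m; ++j) {
        int diag = prev[j - 1] + (pc == subject[j - 1] ? 0 : 1);
        int up = prev[j] + 1;      // consume pattern (insertion vs subject)
        int left = cur[j - 1] + 1; // consume subject (deletion from pattern)
        int best = diag, sbest = sprev[j - 1];
        if (up < best || (up == best && sprev[j] < sbest)) {
          best = up; sbest = sprev[j];
        }
        if (left < best || (left == best && scur[j - 1] < sbest)) {
          best = left; sbest = scur[j - 1];
        }
        cur[j] = best; scur[j] = sbest;
      }
      std::swap(prev, cur); std::swap(sprev, scur);
    }
    int minc = prev[0], argj = 0, nbest = 1;
    for (int j = 1; j <= m; ++j) {
      if (prev[j] < minc) { minc = prev[j]; argj = j; nbest = 1; }
      else if (prev[j] == minc) ++nbest;
    }
    out(p, 0) = minc;
    out(p, 1) = sprev[argj];
    out(p, 2) = argj;
    out(p, 3) = nbest;
  }
  return out;
}

// Exact k-mer prefilter: TRUE for patterns sharing at least one exact k-mer
// with the subject.  With at most e edits, a length-L pattern keeps an
// unedited stretch of at least ceil((L - e) / (e + 1)) bases, so a filter
// with k no larger than that bound never discards an alignable read.
//
// [[Rcpp::export]]
LogicalVector kmer_prefilter(CharacterVector patterns, std::string subject,
                             int k) {
  const int m = subject.size();
  LogicalVector out(patterns.size());
  if (k <= 0 || k > m) { std::fill(out.begin(), out.end(), true); return out; }
  std::unordered_set<std::string> kmers;
  for (int j = 0; j + k <= m; ++j) kmers.insert(subject.substr(j, k));
  for (int p = 0; p < patterns.size(); ++p) {
    std::string pat = as<std::string>(patterns[p]);
    bool hit = false;
    for (int j = 0; j + k <= (int)pat.size() && !hit; ++j) {
      hit = kmers.count(pat.substr(j, k)) > 0;
    }
    out[p] = hit;
  }
  return out;
}
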