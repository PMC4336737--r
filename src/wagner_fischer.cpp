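#include <Rcpp.h>
#include <string>
#include <vector>
using namespace Rcpp;

// Wagner-Fischer dynamic programme over two residue strings, minimising
// match/mismatch/gap costs, with a deterministic traceback that prefers
// match > substitution > deletion (gap in b) > insertion (gap in a).
// Shared by the pairwise aligner, the identity/overlap computation used by
// redundancy clustering, and the progressive multiple-alignment core.

struct WfResult {
  std::string aa, ab;
  int dist;
  int matches;
  int overlap; // columns with residues in both sequences
};

static WfResult wf_core(const std::string& a, const std::string& b,
                        int match, int mismatch, int gap) {
  const int n = a.size(), m = b.size();
  std::vector<int> prev(m + 1), cur(m + 1);
  // full matrix needed for traceback; store as flat ints
  std::vector<int> D((n + 1) * (m + 1));
  for (int j = 0; j <= m; ++j) D[j] = j * gap;
  for (int i = 1; i <= n; ++i) {
    D[i * (m + 1)] = i * gap;
    for (int j = 1; j <= m; ++j) {
      int sub = D[(i - 1) * (m + 1) + (j - 1)] + (a[i - 1] == b[j - 1] ? match : mismatch);
      int del = D[(i - 1) * (m + 1) + j] + gap;
      int ins = D[i * (m + 1) + (j - 1)] + gap;
      int v = sub < del ? sub : del;
      if (ins < v) v = ins;
      D[i * (m + 1) + j] = v;
    }
  }
  WfResult r;
  r.dist = D[n * (m + 1) + m];
  r.matches = 0;
  r.overlap = 0;
  std::string ra, rb;
  int i = n, j = m;
  while (i > 0 || j > 0) {
    int here = D[i * (m + 1) + j];
    if (i > 0 && j > 0) {
      bool eq = a[i - 1] == b[j - 1];
      int sub = D[(i - 1) * (m + 1) + (j - 1)] + (eq ? match : mismatch);
      if (sub == here && eq) { // match preferred
        ra.push_back(a[i - 1]); rb.push_back(b[j - 1]);
        ++r.matches; ++r.overlap; --i; --j; continue;
      }
      if (sub == here) {       // then substitution
        ra.push_back(a[i - 1]); rb.push_back(b[j - 1]);
        ++r.overlap; --i; --j; continue;
      }
    }
    if (i > 0 && D[(i - 1) * (m + 1) + j] + gap == here) { // deletion: gap in b
      ra.push_back(a[i - 1]); rb.push_back('-'); --i; continue;
    }
    ra.push_back('-'); rb.push_back(b[j - 1]); --j;        // insertion
  }
  r.aa.assign(ra.rbegin(), ra.rend());
  r.ab.assign(rb.rbegin(), rb.rend());
  return r;
}

// [[Rcpp::export(name = ".wf_align_cpp")]]
List wf_align_cpp(std::string a, std::string b,
                  int match = 0, int mismatch = 1, int gap = 1) {
  WfResult r = wf_core(a, b, match, mismatch, gap);
  return List::create(_["aligned_a"] = r.aa, _["aligned_b"] = r.ab,
                      _["distance"] = r.dist, _["matches"] = r.matches,
                      _["overlap"] = r.overlap);
}

// [[Rcpp::export(name = ".wf_stats_cpp")]]
NumericVector wf_stats_cpp(std::string a, std::string b,
                           int match = 0, int mismatch = 1, int gap = 1) {
  WfResult r = wf_core(a, b, match, mismatch, gap);
  double identity = r.overlap > 0 ? (double)r.matches / r.overlap : 0.0;
  return NumericVector::create(_["identity"] = identity,
                               _["overlap"] = r.overlap,
                               _["distance"] = r.dist,
                               _["matches"] = r.matches);
}

// All-pairs identity/overlap under the Wagner-Fischer alignment, for the
// 95%/10-residue redundancy clustering. Returns identity and overlap matrices.
// [[Rcpp::export(name = ".wf_pairs_cpp")]]
List wf_pairs_cpp(CharacterVector seqs, int match = 0, int mismatch = 1, int gap = 1) {
  const int n = seqs.size();
  NumericMatrix ident(n, n), over(n, n);
  std::vector<std::string> s(n);
  for (int i = 0; i < n; ++i) s[i] = as<std::string>(seqs[i]);
  for (int i = 0; i < n; ++i) {
    ident(i, i) = 1.0;
    over(i, i) = s[i].size();
    for (int j = i + 1; j < n; ++j) {
      WfResult r = wf_core(s[i], s[j], match, mismatch, gap);
      double id = r.overlap > 0 ? (double)r.matches / r.overlap : 0.0;
      ident(i, j) = ident(j, i) = id;
      over(i, j) = over(j, i) = r.overlap;
    }
  }
  return List::create(_["identity"] = ident, _["overlap"] = over);
}
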