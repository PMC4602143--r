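#include <Rcpp.h>
#include <cstdint>
#include <string>
#include <vector>
using namespace Rcpp;

// Global (Needleman-Wunsch) alignment identity, CD-HIT-style:
// match +1, mismatch 0, linear gap -0.5 per gap column; identity = number of
// identical aligned columns of the optimal alignment / length of the shorter
// sequence. 'X' never counts as identical (ambiguity code scores as
// mismatch). Among co-optimal alignments the one with the most identical
// columns is preferred.
//
// Scores are doubled (match +2, gap -1) so the DP runs in integers.

namespace {

double nw_identity_impl(const std::string& a, const std::string& b) {
  const int n = (int)a.size(), m = (int)b.size();
  if (n == 0 || m == 0) stop("empty sequence");
  std::vector<int32_t> prevS(m + 1), curS(m + 1);
  std::vector<int32_t> prevM(m + 1), curM(m + 1);
  for (int j = 0; j <= m; ++j) { prevS[j] = -j; prevM[j] = 0; }
  const char* bp = b.c_str();
  for (int i = 1; i <= n; ++i) {
    curS[0] = -i;
    curM[0] = 0;
    const char ai = a[i - 1];
    int32_t diagS = prevS[0], diagM = prevM[0];
    for (int j = 1; j <= m; ++j) {
      const bool is_match = (ai == bp[j - 1]) && ai != 'X';
      int32_t s = diagS + (is_match ? 2 : 0);
      int32_t mm = diagM + (is_match ? 1 : 0);
      const int32_t up = prevS[j] - 1;
      if (up > s || (up == s && prevM[j] > mm)) { s = up; mm = prevM[j]; }
      const int32_t lf = curS[j - 1] - 1;
      if (lf > s || (lf == s && curM[j - 1] > mm)) { s = lf; mm = curM[j - 1]; }
      diagS = prevS[j];
      diagM = prevM[j];
      curS[j] = s;
      curM[j] = mm;
    }
    prevS.swap(curS);
    prevM.swap(curM);
  }
  const int shorter = n < m ? n : m;
  return (double)prevM[m] / (double)shorter;
}

} // namespace

// [[Rcpp::export(name = ".nw_identity_cpp")]]
double nw_identity_cpp(std::string a, std::string b) {
  return nw_identity_impl(a, b);
}

// [[Rcpp::export(name = ".nw_identity_many_cpp")]]
NumericVector nw_identity_many_cpp(std::string a, std::vector<std::string> refs) {
  NumericVector out(refs.size());
  for (size_t i = 0; i < refs.size(); ++i) out[i] = nw_identity_impl(a, refs[i]);
  return out;
}

// Index (1-based) of the first reference whose identity to `a` reaches
// `threshold`, honouring the order of `refs`; 0 if none does. Used by the
// greedy incremental clustering pass.
// [[Rcpp::export(name = ".nw_first_match_cpp")]]
int nw_first_match_cpp(std::string a, std::vector<std::string> refs, double threshold) {
  for (size_t i = 0; i < refs.size(); ++i) {
    if (nw_identity_impl(a, refs[i]) >= threshold) return (int)(i + 1);
  }
  return 0;
}

// Whole greedy pass in one call: sequences arrive pre-sorted (length
// descending, ties id ascending); each joins the first existing cluster
// whose founder it matches at >= threshold, else founds a new cluster.
// Returns a list: cluster (1-based founder index per record) and
// identity_to_rep.
// [[Rcpp::export(name = ".greedy_assign_cpp")]]
List greedy_assign_cpp(std::vector<std::string> seqs, double threshold) {
  const int n = (int)seqs.size();
  IntegerVector cluster(n);
  NumericVector ident(n);
  std::vector<int> founders;  // record index of each cluster founder
  for (int i = 0; i < n; ++i) {
    int hit = 0;
    double hit_id = 1.0;
    for (size_t c = 0; c < founders.size(); ++c) {
      const double idn = nw_identity_impl(seqs[i], seqs[founders[c]]);
      if (idn >= threshold) { hit = (int)c + 1; hit_id = idn; break; }
    }
    if (hit > 0) {
      cluster[i] = hit;
      ident[i] = hit_id;
    } else {
      founders.push_back(i);
      cluster[i] = (int)founders.size();
      ident[i] = 1.0;
    }
    if ((i & 63) == 0) Rcpp::checkUserInterrupt();
  }
  return List::create(_["cluster"] = cluster, _["identity_to_rep"] = ident);
}
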