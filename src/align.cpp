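#include <Rcpp.h>
#include <string>
#include <unordered_set>
#include <vector>
using namespace Rcpp;

// Local (Smith-Waterman) alignment score with affine gaps.
// match reward > 0, mismatch penalty < 0; a gap of length L costs
// gap_open + L * gap_extend (NCBI blastn convention). 'N' mismatches
// everything, including another 'N'.
static double sw_affine(const std::string& a, const std::string& b,
                        double match, double mismatch,
                        double gap_open, double gap_extend) {
  const int n = (int)a.size(), m = (int)b.size();
  if (n == 0 || m == 0) return 0.0;
  const double open_cost = gap_open + gap_extend;
  const double NEG = -1e18;
  std::vector<double> Hprev(m + 1, 0.0), Hcur(m + 1, 0.0);
  std::vector<double> Ecur(m + 1, NEG);
  std::vector<double> Fprev(m + 1, NEG), Fcur(m + 1, NEG);
  double best = 0.0;
  for (int i = 1; i <= n; ++i) {
    Hcur[0] = 0.0; Ecur[0] = NEG; Fcur[0] = NEG;
    for (int j = 1; j <= m; ++j) {
      // E: gap consuming b, extends along the row
      Ecur[j] = std::max(Hcur[j - 1] - open_cost, Ecur[j - 1] - gap_extend);
      // F: gap consuming a, extends down the column
      Fcur[j] = std::max(Hprev[j] - open_cost, Fprev[j] - gap_extend);
      bool is_match = (a[i - 1] == b[j - 1]) && a[i - 1] != 'N';
      double s = Hprev[j - 1] + (is_match ? match : mismatch);
      double h = std::max(0.0, std::max(s, std::max(Ecur[j], Fcur[j])));
      Hcur[j] = h;
      if (h > best) best = h;
    }
    std::swap(Hprev, Hcur);
    std::swap(Fprev, Fcur);
    std::fill(Ecur.begin(), Ecur.end(), NEG);
  }
  return best;
}

static bool share_word(const std::string& a, const std::string& b, int w) {
  if ((int)a.size() < w || (int)b.size() < w) return false;
  std::unordered_set<std::string> words;
  for (int i = 0; i + w <= (int)a.size(); ++i) {
    std::string word = a.substr(i, w);
    if (word.find('N') == std::string::npos) words.insert(word);
  }
  for (int j = 0; j + w <= (int)b.size(); ++j) {
    std::string word = b.substr(j, w);
    if (word.find('N') == std::string::npos && words.count(word)) return true;
  }
  return false;
}

// [[Rcpp::export(name = ".sw_score")]]
double sw_score(std::string a, std::string b, double match, double mismatch,
                double gap_open, double gap_extend, int word_size,
                bool require_seed) {
  if (require_seed && !share_word(a, b, word_size)) return 0.0;
  return sw_affine(a, b, match, mismatch, gap_open, gap_extend);
}

// Full cross score matrix between two probe sets (rows = a, cols = b).
// [[Rcpp::export(name = ".sw_score_matrix")]]
NumericMatrix sw_score_matrix(CharacterVector a, CharacterVector b,
                              double match, double mismatch,
                              double gap_open, double gap_extend,
                              int word_size, bool require_seed) {
  const int n = a.size(), m = b.size();
  std::vector<std::string> av(n), bv(m);
  for (int i = 0; i < n; ++i) av[i] = as<std::string>(a[i]);
  for (int j = 0; j < m; ++j) bv[j] = as<std::string>(b[j]);
  NumericMatrix out(n, m);
  for (int i = 0; i < n; ++i) {
    for (int j = 0; j < m; ++j) {
      if (require_seed && !share_word(av[i], bv[j], word_size)) {
        out(i, j) = 0.0;
      } else {
        out(i, j) = sw_affine(av[i], bv[j], match, mismatch,
                              gap_open, gap_extend);
      }
    }
  }
  return out;
}
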