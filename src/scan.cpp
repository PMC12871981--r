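#include <Rcpp.h>
#include <unordered_map>
#include <set>
#include <string>
using namespace Rcpp;

// Greedy left-to-right non-overlapping motif scan.
//
// motif/kind/strand describe the motif table: kind 0 = canonical, 1 = variant,
// 2 = mutant; strand 0 = G, 1 = C. When the same string occurs under several
// kinds the lowest kind code wins (canonical beats variant beats mutant).
//
// At each position the winning motif is chosen by (canonical first, then
// longest, then variant before mutant). Canonical precedence over longer
// variants is essential: inside a pure canonical array every repeat is also
// the prefix of a one-base-insertion variant (e.g. GGTTAGG), so plain
// longest-match would misclassify invariant telomere as variant repeats.
// Matched spans never overlap; unmatched positions advance by one base.
// Returns 1-based starts.
// [[Rcpp::export]]
DataFrame cpp_scan_motifs(std::string seq, CharacterVector motif,
                          IntegerVector kind, IntegerVector strand) {
  std::unordered_map<std::string, std::pair<int, int> > table;
  std::set<int, std::greater<int> > lens;
  for (int i = 0; i < motif.size(); ++i) {
    std::string m = as<std::string>(motif[i]);
    lens.insert((int)m.size());
    std::unordered_map<std::string, std::pair<int, int> >::iterator it =
        table.find(m);
    if (it == table.end() || kind[i] < it->second.first)
      table[m] = std::make_pair(kind[i], strand[i]);
  }
  int n = (int)seq.size();
  std::vector<int> h_start, h_width, h_kind, h_strand;
  int pos = 0;
  while (pos < n) {
    int best_len = -1, best_kind = 0, best_strand = 0;
    for (std::set<int, std::greater<int> >::iterator L = lens.begin();
         L != lens.end(); ++L) {
      if (pos + *L > n) continue;
      std::unordered_map<std::string, std::pair<int, int> >::iterator it =
          table.find(seq.substr(pos, *L));
      if (it == table.end()) continue;
      bool better;
      if (best_len < 0) {
        better = true;
      } else {
        int cand_can = it->second.first == 0 ? 0 : 1;
        int best_can = best_kind == 0 ? 0 : 1;
        if (cand_can != best_can) better = cand_can < best_can;
        else if (*L != best_len) better = *L > best_len;
        else better = it->second.first < best_kind;
      }
      if (better) {
        best_len = *L;
        best_kind = it->second.first;
        best_strand = it->second.second;
        if (best_kind == 0) break;  // canonical cannot be beaten
      }
    }
    if (best_len > 0) {
      h_start.push_back(pos + 1);
      h_width.push_back(best_len);
      h_kind.push_back(best_kind);
      h_strand.push_back(best_strand);
      pos += best_len;
    } else {
      ++pos;
    }
  }
  return DataFrame::create(_["start"] = h_start, _["width"] = h_width,
                           _["kind"] = h_kind, _["strand"] = h_strand);
}

// All windows of length |pattern| whose Hamming distance to pattern is
// <= max_errors. Ambiguous bases (anything but an exact byte match) count
// as mismatches. Returns 1-based starts, sorted.
// [[Rcpp::export]]
DataFrame cpp_hamming_find(std::string seq, std::string pattern,
                           int max_errors) {
  int n = (int)seq.size(), m = (int)pattern.size();
  std::vector<int> starts, errors;
  for (int i = 0; i + m <= n; ++i) {
    int e = 0;
    for (int j = 0; j < m; ++j) {
      if (seq[i + j] != pattern[j] && ++e > max_errors) break;
    }
    if (e <= max_errors) {
      starts.push_back(i + 1);
      errors.push_back(e);
    }
  }
  return DataFrame::create(_["start"] = starts, _["errors"] = errors);
}
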