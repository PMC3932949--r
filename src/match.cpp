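#include <Rcpp.h>
#include <string>
#include <vector>
using namespace Rcpp;

// uppercase, DNA-normalised (U -> T) copy
static std::string norm(const char *s) {
  std::string out(s);
  for (auto &c : out) {
    c = std::toupper(static_cast<unsigned char>(c));
    if (c == 'U') c = 'T';
  }
  return out;
}

static std::string revcomp(const std::string &s) {
  std::string out(s.size(), 'N');
  for (size_t i = 0; i < out.size(); ++i) {
    char c = s[s.size() - 1 - i];
    switch (c) {
      case 'A': out[i] = 'T'; break;
      case 'T': out[i] = 'A'; break;
      case 'G': out[i] = 'C'; break;
      case 'C': out[i] = 'G'; break;
      default:  out[i] = 'N'; break;
    }
  }
  return out;
}

// All substring matches of each tag in each reference with at most max_mm
// substitutions, on both strands when both_strands is true. Returns 1-based
// start positions on the reference forward strand.
// [[Rcpp::export(name = ".match_tags_cpp")]]
DataFrame match_tags_cpp(CharacterVector tags, CharacterVector refs,
                         int max_mm = 1, bool both_strands = true) {
  std::vector<int> tag_idx, ref_idx, start, mism;
  std::vector<char> strand;
  std::vector<std::string> T(tags.size()), Trc;
  for (int i = 0; i < tags.size(); ++i) T[i] = norm(tags[i]);
  if (both_strands) {
    Trc.resize(tags.size());
    for (int i = 0; i < tags.size(); ++i) Trc[i] = revcomp(T[i]);
  }
  for (int r = 0; r < refs.size(); ++r) {
    std::string R = norm(refs[r]);
    const int rl = (int)R.size();
    for (int t = 0; t < (int)T.size(); ++t) {
      const int tl = (int)T[t].size();
      if (tl == 0 || tl > rl) continue;
      for (int pass = 0; pass < (both_strands ? 2 : 1); ++pass) {
        const std::string &pat = pass == 0 ? T[t] : Trc[t];
        for (int p = 0; p + tl <= rl; ++p) {
          int mm = 0;
          for (int k = 0; k < tl; ++k) {
            if (pat[k] != R[p + k] && ++mm > max_mm) break;
          }
          if (mm <= max_mm) {
            tag_idx.push_back(t + 1);
            ref_idx.push_back(r + 1);
            start.push_back(p + 1);
            strand.push_back(pass == 0 ? '+' : '-');
            mism.push_back(mm);
          }
        }
      }
    }
  }
  CharacterVector str(strand.size());
  for (size_t i = 0; i < strand.size(); ++i)
    str[i] = std::string(1, strand[i]);
  return DataFrame::create(
      _["tag_idx"] = tag_idx, _["ref_idx"] = ref_idx, _["start"] = start,
      _["strand"] = str, _["mismatches"] = mism,
      _["stringsAsFactors"] = false);
}
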