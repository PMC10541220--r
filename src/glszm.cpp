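#include <Rcpp.h>
#include <vector>
using namespace Rcpp;

// Zone enumeration for the gray-level size zone matrix.
// `gl` is an integer matrix of discretized gray levels with NA outside the
// mask. A zone is a maximal connected component of equal-valued in-mask
// pixels under 4- or 8-connectivity. Returns an integer matrix with one row
// per zone: (gray level, zone size).
// [[Rcpp::export(name = ".glszm_zones_cpp")]]
IntegerMatrix glszm_zones_cpp(IntegerMatrix gl, int connectivity) {
  const int nr = gl.nrow(), nc = gl.ncol();
  std::vector<bool> seen(static_cast<size_t>(nr) * nc, false);
  std::vector<int> levels, sizes, stack;
  stack.reserve(64);

  const int dr8[8] = {-1, -1, -1, 0, 0, 1, 1, 1};
  const int dc8[8] = {-1, 0, 1, -1, 1, -1, 0, 1};
  const int dr4[4] = {-1, 1, 0, 0};
  const int dc4[4] = {0, 0, -1, 1};
  const int nnb = (connectivity == 4) ? 4 : 8;
  const int *dr = (connectivity == 4) ? dr4 : dr8;
  const int *dc = (connectivity == 4) ? dc4 : dc8;

  for (int c0 = 0; c0 < nc; ++c0) {
    for (int r0 = 0; r0 < nr; ++r0) {
      const size_t idx0 = static_cast<size_t>(c0) * nr + r0;
      if (seen[idx0] || gl(r0, c0) == NA_INTEGER) continue;
      const int lev = gl(r0, c0);
      int size = 0;
      seen[idx0] = true;
      stack.clear();
      stack.push_back(static_cast<int>(idx0));
      while (!stack.empty()) {
        const int idx = stack.back();
        stack.pop_back();
        ++size;
        const int r = idx % nr, c = idx / nr;
        for (int k = 0; k < nnb; ++k) {
          const int rr = r + dr[k], cc = c + dc[k];
          if (rr < 0 || rr >= nr || cc < 0 || cc >= nc) continue;
          const size_t nidx = static_cast<size_t>(cc) * nr + rr;
          if (seen[nidx] || gl(rr, cc) != lev) continue;
          seen[nidx] = true;
          stack.push_back(static_cast<int>(nidx));
        }
      }
      levels.push_back(lev);
      sizes.push_back(size);
    }
  }

  IntegerMatrix out(levels.size(), 2);
  for (size_t i = 0; i < levels.size(); ++i) {
    out(i, 0) = levels[i];
    out(i, 1) = sizes[i];
  }
  colnames(out) = CharacterVector::create("level", "size");
  return out;
}
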