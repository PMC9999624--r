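// Local alignment (Smith-Waterman with affine gaps, Gotoh recurrences)
// used by align_search() to extend seeded candidate windows. A gap of
// length k costs gap_open + k * gap_ext.

#include <Rcpp.h>
#include <vector>
#include <string>
using namespace Rcpp;

// [[Rcpp::export(name = ".sw_align")]]
List sw_align(std::string query, std::string target,
              double match = 1.0, double mismatch = -2.0,
              double gap_open = 5.0, double gap_ext = 2.0) {
  const int n = query.size(), m = target.size();
  if (n == 0 || m == 0)
    return List::create(_["score"] = 0.0);
  const double NEG = -1e30;
  std::vector<double> Hprev(m + 1, 0.0), Hcur(m + 1, 0.0);
  std::vector<double> Eprev(m + 1, NEG), Ecur(m + 1, NEG); // gap in target (vertical)
  // traceback matrices: tbH 0=stop,1=diag,2=fromE(vert),3=fromF(horiz)
  std::vector<unsigned char> tbH((size_t)(n + 1) * (m + 1), 0);
  std::vector<unsigned char> tbE((size_t)(n + 1) * (m + 1), 0); // 1=open
  std::vector<unsigned char> tbF((size_t)(n + 1) * (m + 1), 0);
  double best = 0.0; int bi = 0, bj = 0;
  for (int i = 1; i <= n; ++i) {
    double F = NEG; // gap along row (horizontal)
    Hcur[0] = 0.0;
    for (int j = 1; j <= m; ++j) {
      size_t idx = (size_t)i * (m + 1) + j;
      // E: vertical gap (consumes query)
      double e_open = Hprev[j] - gap_open - gap_ext;
      double e_ext = Eprev[j] - gap_ext;
      double E = std::max(e_open, e_ext);
      tbE[idx] = e_open >= e_ext ? 1 : 0;
      // F: horizontal gap (consumes target)
      double f_open = Hcur[j - 1] - gap_open - gap_ext;
      double f_ext = F - gap_ext;
      double Fv = std::max(f_open, f_ext);
      tbF[idx] = f_open >= f_ext ? 1 : 0;
      F = Fv;
      double s = (query[i - 1] == target[j - 1]) ? match : mismatch;
      double diag = Hprev[j - 1] + s;
      double h = 0.0; unsigned char tb = 0;
      if (diag >= h) { h = diag; tb = 1; }
      if (E > h) { h = E; tb = 2; }
      if (Fv > h) { h = Fv; tb = 3; }
      Hcur[j] = h;
      Ecur[j] = E;
      tbH[idx] = tb;
      if (h > best) { best = h; bi = i; bj = j; }
    }
    std::swap(Hprev, Hcur);
    std::swap(Eprev, Ecur);
  }
  if (best <= 0.0)
    return List::create(_["score"] = 0.0);
  // traceback from (bi, bj)
  int i = bi, j = bj, matches = 0, columns = 0;
  int state = 0; // 0 = in H, 1 = in E, 2 = in F
  int qend = bi, tend = bj, qstart = bi, tstart = bj;
  while (i > 0 && j > 0) {
    size_t idx = (size_t)i * (m + 1) + j;
    if (state == 0) {
      unsigned char tb = tbH[idx];
      if (tb == 0) break;
      if (tb == 1) {
        ++columns;
        if (query[i - 1] == target[j - 1]) ++matches;
        qstart = i; tstart = j;
        --i; --j;
      } else if (tb == 2) state = 1;
      else state = 2;
    } else if (state == 1) { // vertical gap: consume query base
      ++columns;
      qstart = i;
      bool opened = tbE[idx] == 1;
      --i;
      if (opened) state = 0;
    } else { // horizontal gap: consume target base
      ++columns;
      tstart = j;
      bool opened = tbF[idx] == 1;
      --j;
      if (opened) state = 0;
    }
  }
  return List::create(_["score"] = best,
                      _["qstart"] = qstart, _["qend"] = qend,
                      _["tstart"] = tstart, _["tend"] = tend,
                      _["matches"] = matches, _["columns"] = columns);
}
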