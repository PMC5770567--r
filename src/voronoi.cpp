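#include <Rcpp.h>
#include <algorithm>
#include <cmath>
#include <vector>
using namespace Rcpp;

// Periodic 2D Voronoi tessellation by incremental half-plane clipping.
//
// The cell of site i on the torus is the intersection of half-planes bounded
// by the perpendicular bisectors between i and every periodic image (3x3
// shifts) of every site, including i's own images. Candidates are processed
// in order of increasing distance with the standard termination rule: once
// the next candidate is farther than twice the farthest current cell vertex,
// no later candidate can cut the cell.
//
// Each final polygon edge remembers which candidate generated it, giving the
// Delaunay neighbour set and the shared-edge lengths directly.

namespace {

struct Cand {
  double dx, dy, d2;
  int id; // 0-based original site index
};

} // namespace

// [[Rcpp::export(name = ".voronoi_cells")]]
List voronoi_cells(NumericVector x, NumericVector y, double Lx, double Ly) {
  const int n = x.size();
  if (n < 3) stop("need at least 3 sites");

  List verts(n);
  NumericVector areas(n);
  List nbrs(n), edge_len(n);

  std::vector<Cand> cand;
  cand.reserve(9 * n);

  for (int i = 0; i < n; ++i) {
    cand.clear();
    for (int j = 0; j < n; ++j) {
      for (int sx = -1; sx <= 1; ++sx) {
        for (int sy = -1; sy <= 1; ++sy) {
          if (j == i && sx == 0 && sy == 0) continue;
          double dx = x[j] + sx * Lx - x[i];
          double dy = y[j] + sy * Ly - y[i];
          Cand c;
          c.dx = dx; c.dy = dy; c.d2 = dx * dx + dy * dy; c.id = j;
          cand.push_back(c);
        }
      }
    }
    std::sort(cand.begin(), cand.end(),
              [](const Cand &a, const Cand &b) { return a.d2 < b.d2; });

    // initial polygon: generous square centred on the site (coordinates
    // relative to the site); own periodic images always bound the cell
    double R0 = Lx + Ly;
    std::vector<double> px = {-R0, R0, R0, -R0};
    std::vector<double> py = {-R0, -R0, R0, R0};
    std::vector<int> eid = {-1, -2, -3, -4}; // edge k: vertex k -> k+1

    std::vector<double> qx, qy;
    std::vector<int> qe;

    for (size_t c = 0; c < cand.size(); ++c) {
      // termination: farthest vertex distance^2
      double maxv2 = 0.0;
      for (size_t v = 0; v < px.size(); ++v) {
        double v2 = px[v] * px[v] + py[v] * py[v];
        if (v2 > maxv2) maxv2 = v2;
      }
      if (cand[c].d2 > 4.0 * maxv2) break;

      // half-plane: ux*p + uy*q <= h  (bisector between origin and candidate)
      double ux = cand[c].dx, uy = cand[c].dy;
      double h = 0.5 * cand[c].d2;

      const size_t m = px.size();
      qx.clear(); qy.clear(); qe.clear();
      bool cut = false;
      for (size_t v = 0; v < m; ++v) {
        size_t w = (v + 1) % m;
        double fv = ux * px[v] + uy * py[v] - h;
        double fw = ux * px[w] + uy * py[w] - h;
        bool inv = fv <= 0.0, inw = fw <= 0.0;
        if (inv) {
          qx.push_back(px[v]); qy.push_back(py[v]); qe.push_back(eid[v]);
        }
        if (inv != inw) {
          double t = fv / (fv - fw);
          qx.push_back(px[v] + t * (px[w] - px[v]));
          qy.push_back(py[v] + t * (py[w] - py[v]));
          // leaving the half-plane: new edge belongs to this candidate
          // until the re-entry point
          qe.push_back(inv ? (int)c : eid[v]);
          cut = true;
        }
      }
      if (cut) { px.swap(qx); py.swap(qy); eid.swap(qe); }
      if (px.size() < 3) stop("degenerate Voronoi cell (coincident sites?)");
    }

    // area (shoelace) and per-candidate edge lengths
    const size_t m = px.size();
    double A = 0.0;
    for (size_t v = 0; v < m; ++v) {
      size_t w = (v + 1) % m;
      A += px[v] * py[w] - px[w] * py[v];
    }
    A = 0.5 * std::fabs(A);
    areas[i] = A;

    // collect neighbours: aggregate edge length by originating site id
    std::vector<int> ids;
    std::vector<double> lens;
    for (size_t v = 0; v < m; ++v) {
      size_t w = (v + 1) % m;
      if (eid[v] < 0) stop("Voronoi cell unbounded; box replication failed");
      int sid = cand[eid[v]].id;
      double len = std::hypot(px[w] - px[v], py[w] - py[v]);
      if (len <= 1e-8) continue; // corner contacts from tie-break jitter
      bool found = false;
      for (size_t u = 0; u < ids.size(); ++u) {
        if (ids[u] == sid) { lens[u] += len; found = true; break; }
      }
      if (!found) { ids.push_back(sid); lens.push_back(len); }
    }

    NumericMatrix V(m, 2);
    for (size_t v = 0; v < m; ++v) {
      V(v, 0) = px[v] + x[i];
      V(v, 1) = py[v] + y[i];
    }
    verts[i] = V;
    IntegerVector nb(ids.size());
    NumericVector el(ids.size());
    for (size_t u = 0; u < ids.size(); ++u) {
      nb[u] = ids[u] + 1; // 1-based site ids for R
      el[u] = lens[u];
    }
    nbrs[i] = nb;
    edge_len[i] = el;
  }

  return List::create(_["vertices"] = verts, _["area"] = areas,
                      _["neighbors"] = nbrs, _["edge_lengths"] = edge_len);
}
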