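#include <Rcpp.h>
#include <unordered_map>
#include <vector>
#include <cstdint>

using namespace Rcpp;

// Iso-surface extraction from a scalar field sampled on a regular grid, by
// marching tetrahedra on the Freudenthal (Kuhn) 6-tetrahedra cube split.
// The split shares the main cube diagonal and assigns every cube face the
// same diagonal under translation, so the extracted surface is watertight
// whenever the zero level set stays inside the grid. Field convention:
// negative inside, positive outside; emitted triangles are wound so their
// normals point toward the positive (outside) region.

namespace {

struct VertexPool {
  std::unordered_map<uint64_t, int> edge_map;
  std::vector<double> coords;  // x,y,z triples

  int edge_vertex(uint64_t a, uint64_t b, double fa, double fb,
                  const double *pa, const double *pb) {
    if (a > b) {
      std::swap(a, b);
      std::swap(fa, fb);
      const double *tmp = pa;
      pa = pb;
      pb = tmp;
    }
    uint64_t key = a * 0x100000000ull + b;
    std::unordered_map<uint64_t, int>::iterator it = edge_map.find(key);
    if (it != edge_map.end()) return it->second;
    double t = fa / (fa - fb);
    int id = (int)(coords.size() / 3);
    for (int k = 0; k < 3; ++k) coords.push_back(pa[k] + t * (pb[k] - pa[k]));
    edge_map[key] = id;
    return id;
  }
};

}  // namespace

// [[Rcpp::export(name = ".cpp_marching_tetra")]]
List cpp_marching_tetra(NumericVector field, IntegerVector dims,
                        NumericVector origin, double spacing) {
  int nx = dims[0], ny = dims[1], nz = dims[2];
  const double *f = REAL(field);

  // Freudenthal tetrahedra: corner bit code dx | dy<<1 | dz<<2.
  static const int tets[6][4] = {{0, 1, 3, 7}, {0, 1, 5, 7}, {0, 2, 3, 7},
                                 {0, 2, 6, 7}, {0, 4, 5, 7}, {0, 4, 6, 7}};

  VertexPool pool;
  std::vector<int> faces;

  double corner_pos[8][3];
  uint64_t corner_id[8];
  double corner_f[8];

  for (int iz = 0; iz < nz - 1; ++iz) {
    for (int iy = 0; iy < ny - 1; ++iy) {
      for (int ix = 0; ix < nx - 1; ++ix) {
        bool all_pos = true, all_neg = true;
        for (int c = 0; c < 8; ++c) {
          int dx = c & 1, dy = (c >> 1) & 1, dz = (c >> 2) & 1;
          uint64_t gid = (uint64_t)(ix + dx) +
                         (uint64_t)nx * ((uint64_t)(iy + dy) +
                                         (uint64_t)ny * (uint64_t)(iz + dz));
          corner_id[c] = gid;
          double v = f[gid];
          if (v >= 0 && v < 1e-12) v = 1e-12;   // keep zeros off the lattice
          if (v < 0 && v > -1e-12) v = -1e-12;
          corner_f[c] = v;
          corner_pos[c][0] = origin[0] + spacing * (ix + dx);
          corner_pos[c][1] = origin[1] + spacing * (iy + dy);
          corner_pos[c][2] = origin[2] + spacing * (iz + dz);
          if (v < 0) all_pos = false; else all_neg = false;
        }
        if (all_pos || all_neg) continue;

        for (int t = 0; t < 6; ++t) {
          int vi[4] = {tets[t][0], tets[t][1], tets[t][2], tets[t][3]};
          int inside[4], nin = 0, outside[4], nout = 0;
          for (int k = 0; k < 4; ++k) {
            if (corner_f[vi[k]] < 0) inside[nin++] = vi[k];
            else outside[nout++] = vi[k];
          }
          if (nin == 0 || nin == 4) continue;

          int tri[2][3];
          int ntri = 0;
          if (nin == 1 || nin == 3) {
            int apex = (nin == 1) ? inside[0] : outside[0];
            int *others = (nin == 1) ? outside : inside;
            for (int k = 0; k < 3; ++k)
              tri[0][k] = pool.edge_vertex(
                  corner_id[apex], corner_id[others[k]], corner_f[apex],
                  corner_f[others[k]], corner_pos[apex], corner_pos[others[k]]);
            ntri = 1;
          } else {  // 2 in / 2 out: quad split into two triangles
            int a = inside[0], b = inside[1], c = outside[0], d = outside[1];
            int vac = pool.edge_vertex(corner_id[a], corner_id[c], corner_f[a],
                                       corner_f[c], corner_pos[a], corner_pos[c]);
            int vad = pool.edge_vertex(corner_id[a], corner_id[d], corner_f[a],
                                       corner_f[d], corner_pos[a], corner_pos[d]);
            int vbc = pool.edge_vertex(corner_id[b], corner_id[c], corner_f[b],
                                       corner_f[c], corner_pos[b], corner_pos[c]);
            int vbd = pool.edge_vertex(corner_id[b], corner_id[d], corner_f[b],
                                       corner_f[d], corner_pos[b], corner_pos[d]);
            tri[0][0] = vac; tri[0][1] = vad; tri[0][2] = vbd;
            tri[1][0] = vac; tri[1][1] = vbd; tri[1][2] = vbc;
            ntri = 2;
          }

          // Orient: normal must point from the inside region to the outside.
          double ref[3] = {0, 0, 0};
          for (int k = 0; k < nout; ++k)
            for (int a = 0; a < 3; ++a) ref[a] += corner_pos[outside[k]][a] / nout;
          for (int k = 0; k < nin; ++k)
            for (int a = 0; a < 3; ++a) ref[a] -= corner_pos[inside[k]][a] / nin;

          for (int q = 0; q < ntri; ++q) {
            const double *p0 = &pool.coords[3 * tri[q][0]];
            const double *p1 = &pool.coords[3 * tri[q][1]];
            const double *p2 = &pool.coords[3 * tri[q][2]];
            double e1[3], e2[3], nrm[3];
            for (int a = 0; a < 3; ++a) {
              e1[a] = p1[a] - p0[a];
              e2[a] = p2[a] - p0[a];
            }
            nrm[0] = e1[1] * e2[2] - e1[2] * e2[1];
            nrm[1] = e1[2] * e2[0] - e1[0] * e2[2];
            nrm[2] = e1[0] * e2[1] - e1[1] * e2[0];
            double dot = nrm[0] * ref[0] + nrm[1] * ref[1] + nrm[2] * ref[2];
            if (dot < 0) std::swap(tri[q][1], tri[q][2]);
            faces.push_back(tri[q][0] + 1);
            faces.push_back(tri[q][1] + 1);
            faces.push_back(tri[q][2] + 1);
          }
        }
      }
    }
  }

  int nv = (int)(pool.coords.size() / 3);
  int nf = (int)(faces.size() / 3);
  NumericMatrix V(nv, 3);
  for (int i = 0; i < nv; ++i)
    for (int a = 0; a < 3; ++a) V(i, a) = pool.coords[3 * i + a];
  IntegerMatrix F(nf, 3);
  for (int i = 0; i < nf; ++i)
    for (int a = 0; a < 3; ++a) F(i, a) = faces[3 * i + a];
  return List::create(_["vertices"] = V, _["faces"] = F);
}
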