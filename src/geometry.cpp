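// Geometry kernels: exact 3D Euclidean distance transform (separable
// lower-envelope algorithm, anisotropic spacing), isosurface extraction by
// marching tetrahedra over the Kuhn 6-tetrahedron cube decomposition with
// edge-welded vertices and union-find surface components, and a uniform-grid
// nearest-neighbour point query.

#include <RcppArmadillo.h>
#include <unordered_map>
// [[Rcpp::depends(RcppArmadillo)]]
using namespace Rcpp;

static const double INF = 1e30;

// 1D squared-distance transform along samples at spacing s (lower envelope).
static void dt1d(const double* f, double* d, int n, double s,
                 std::vector<int>& v, std::vector<double>& z) {
  const double NINF = -std::numeric_limits<double>::infinity();
  const double PINF = std::numeric_limits<double>::infinity();
  v.resize(n + 1); z.resize(n + 2);
  int k = 0;
  v[0] = 0; z[0] = NINF; z[1] = PINF;
  double s2 = s * s;
  for (int q = 1; q < n; ++q) {
    double fq = f[q];
    while (true) {
      int p = v[k];
      double sden = 2.0 * s2 * (q - p);
      double inter = (fq - f[p] + s2 * ((double)q * q - (double)p * p)) / sden;
      if (inter <= z[k]) { --k; continue; }
      ++k; v[k] = q; z[k] = inter; z[k + 1] = PINF;
      break;
    }
  }
  k = 0;
  for (int q = 0; q < n; ++q) {
    while (z[k + 1] < q) ++k;
    double dq = (double)(q - v[k]) * s;
    d[q] = dq * dq + f[v[k]];
  }
}

// [[Rcpp::export]]
NumericVector cpp_edt3d(LogicalVector seeds, NumericVector spacing) {
  IntegerVector dm = seeds.attr("dim");
  int D = dm[0], H = dm[1], W = dm[2];
  size_t n = (size_t)D * H * W;
  std::vector<double> g(n);
  for (size_t i = 0; i < n; ++i) g[i] = seeds[i] ? 0.0 : INF;
  std::vector<int> v; std::vector<double> z;
  std::vector<double> line(std::max(D, std::max(H, W)));
  std::vector<double> dline(line.size());
  // axis 1 (stride 1)
  for (int k = 0; k < W; ++k)
    for (int j = 0; j < H; ++j) {
      double* p = g.data() + ((size_t)k * H + j) * D;
      dt1d(p, dline.data(), D, spacing[0], v, z);
      std::copy(dline.begin(), dline.begin() + D, p);
    }
  // axis 2 (stride D)
  for (int k = 0; k < W; ++k)
    for (int i = 0; i < D; ++i) {
      double* base = g.data() + (size_t)k * H * D + i;
      for (int j = 0; j < H; ++j) line[j] = base[(size_t)j * D];
      dt1d(line.data(), dline.data(), H, spacing[1], v, z);
      for (int j = 0; j < H; ++j) base[(size_t)j * D] = dline[j];
    }
  // axis 3 (stride D*H)
  for (int j = 0; j < H; ++j)
    for (int i = 0; i < D; ++i) {
      double* base = g.data() + (size_t)j * D + i;
      for (int k = 0; k < W; ++k) line[k] = base[(size_t)k * H * D];
      dt1d(line.data(), dline.data(), W, spacing[2], v, z);
      for (int k = 0; k < W; ++k) base[(size_t)k * H * D] = dline[k];
    }
  NumericVector out(n);
  out.attr("dim") = dm;
  for (size_t i = 0; i < n; ++i) out[i] = std::sqrt(g[i]);
  return out;
}

struct UF {
  std::vector<int> p;
  UF(int n) : p(n) { for (int i = 0; i < n; ++i) p[i] = i; }
  int find(int x) { while (p[x] != x) { p[x] = p[p[x]]; x = p[x]; } return x; }
  void unite(int a, int b) { a = find(a); b = find(b); if (a != b) p[a] = b; }
};

// Kuhn decomposition: 6 tetrahedra sharing the 0 -> 7 cube diagonal, one per
// coordinate-ascending path; consistent across a translated grid of cubes.
static const int TETS[6][4] = {
  {0, 1, 3, 7}, {0, 1, 5, 7}, {0, 2, 3, 7},
  {0, 2, 6, 7}, {0, 4, 5, 7}, {0, 4, 6, 7}
};

// [[Rcpp::export]]
List cpp_march_tets(NumericVector vol, double level, NumericVector spacing,
                    bool largest_only) {
  IntegerVector dm = vol.attr("dim");
  int D = dm[0], H = dm[1], W = dm[2];
  const double* vp = vol.begin();
  std::unordered_map<uint64_t, int> edge_id;
  std::vector<double> verts;           // x,y,z triples (mm)
  std::vector<int> faces;              // 0-based vertex index triples
  auto gval = [&](int i, int j, int k) {
    return vp[((size_t)k * H + j) * D + i];
  };
  auto glin = [&](int i, int j, int k) -> uint64_t {
    return ((uint64_t)k * H + j) * D + i;
  };
  int cx[8], cy[8], cz[8];
  for (int c = 0; c < 8; ++c) { cx[c] = c & 1; cy[c] = (c >> 1) & 1; cz[c] = (c >> 2) & 1; }
  auto edge_vertex = [&](int i0, int j0, int k0, int ca, int cb) -> int {
    int ia = i0 + cx[ca], ja = j0 + cy[ca], ka = k0 + cz[ca];
    int ib = i0 + cx[cb], jb = j0 + cy[cb], kb = k0 + cz[cb];
    uint64_t la = glin(ia, ja, ka), lb = glin(ib, jb, kb);
    uint64_t key = (std::min(la, lb) << 32) | (std::max(la, lb) & 0xffffffffu);
    auto it = edge_id.find(key);
    if (it != edge_id.end()) return it->second;
    double va = gval(ia, ja, ka), vb = gval(ib, jb, kb);
    double t = (level - va) / (vb - va);
    if (t < 0) t = 0; if (t > 1) t = 1;
    double x = (ia + t * (ib - ia)) * spacing[0];
    double y = (ja + t * (jb - ja)) * spacing[1];
    double zc = (ka + t * (kb - ka)) * spacing[2];
    int id = (int)(verts.size() / 3);
    verts.push_back(x); verts.push_back(y); verts.push_back(zc);
    edge_id[key] = id;
    return id;
  };
  for (int k = 0; k + 1 < W; ++k)
    for (int j = 0; j + 1 < H; ++j)
      for (int i = 0; i + 1 < D; ++i) {
        double cv[8];
        bool in[8];
        int nin_cube = 0;
        for (int c = 0; c < 8; ++c) {
          cv[c] = gval(i + cx[c], j + cy[c], k + cz[c]);
          in[c] = cv[c] < level;
          nin_cube += in[c];
        }
        if (nin_cube == 0 || nin_cube == 8) continue;
        for (int t = 0; t < 6; ++t) {
          const int* T = TETS[t];
          int neg[4], pos[4], nn = 0, np = 0;
          for (int m = 0; m < 4; ++m) {
            if (in[T[m]]) neg[nn++] = T[m]; else pos[np++] = T[m];
          }
          if (nn == 0 || nn == 4) continue;
          if (nn == 1) {
            int a = edge_vertex(i, j, k, neg[0], pos[0]);
            int b = edge_vertex(i, j, k, neg[0], pos[1]);
            int c = edge_vertex(i, j, k, neg[0], pos[2]);
            faces.push_back(a); faces.push_back(b); faces.push_back(c);
          } else if (nn == 3) {
            int a = edge_vertex(i, j, k, neg[0], pos[0]);
            int b = edge_vertex(i, j, k, neg[1], pos[0]);
            int c = edge_vertex(i, j, k, neg[2], pos[0]);
            faces.push_back(a); faces.push_back(b); faces.push_back(c);
          } else {
            int ac = edge_vertex(i, j, k, neg[0], pos[0]);
            int ad = edge_vertex(i, j, k, neg[0], pos[1]);
            int bc = edge_vertex(i, j, k, neg[1], pos[0]);
            int bd = edge_vertex(i, j, k, neg[1], pos[1]);
            faces.push_back(ac); faces.push_back(ad); faces.push_back(bd);
            faces.push_back(ac); faces.push_back(bd); faces.push_back(bc);
          }
        }
      }
  int nv = (int)(verts.size() / 3);
  int nf = (int)(faces.size() / 3);
  if (nv == 0) {
    return List::create(_["vertices"] = NumericMatrix(0, 3),
                        _["faces"] = IntegerMatrix(0, 3));
  }
  std::vector<int> vkeep(nv, 1);
  if (largest_only && nv > 0) {
    UF uf(nv);
    for (int f = 0; f < nf; ++f) {
      uf.unite(faces[3 * f], faces[3 * f + 1]);
      uf.unite(faces[3 * f], faces[3 * f + 2]);
    }
    std::unordered_map<int, int> count;
    for (int v = 0; v < nv; ++v) count[uf.find(v)]++;
    int best = -1, bestn = -1;
    for (auto& kv : count) if (kv.second > bestn) { bestn = kv.second; best = kv.first; }
    for (int v = 0; v < nv; ++v) vkeep[v] = (uf.find(v) == best);
  }
  std::vector<int> remap(nv, -1);
  int nv2 = 0;
  for (int v = 0; v < nv; ++v) if (vkeep[v]) remap[v] = nv2++;
  NumericMatrix V(nv2, 3);
  for (int v = 0; v < nv; ++v)
    if (vkeep[v])
      for (int c = 0; c < 3; ++c) V(remap[v], c) = verts[3 * v + c];
  std::vector<int> fkeep;
  for (int f = 0; f < nf; ++f)
    if (vkeep[faces[3 * f]] && vkeep[faces[3 * f + 1]] && vkeep[faces[3 * f + 2]])
      fkeep.push_back(f);
  IntegerMatrix F((int)fkeep.size(), 3);
  for (size_t f = 0; f < fkeep.size(); ++f)
    for (int c = 0; c < 3; ++c) F((int)f, c) = remap[faces[3 * fkeep[f] + c]] + 1;  // 1-based
  return List::create(_["vertices"] = V, _["faces"] = F);
}

// One-way nearest-neighbour distances from each query point to the reference
// point set, via a uniform cell grid with expanding-shell pruning.
// [[Rcpp::export]]
NumericVector cpp_nn_dist(NumericMatrix query, NumericMatrix ref) {
  int nq = query.nrow(), nr = ref.nrow();
  if (nr == 0) stop("empty reference point set");
  NumericVector out(nq);
  double lo[3], hi[3];
  for (int c = 0; c < 3; ++c) {
    lo[c] = ref(0, c); hi[c] = ref(0, c);
    for (int i = 1; i < nr; ++i) {
      lo[c] = std::min(lo[c], ref(i, c));
      hi[c] = std::max(hi[c], ref(i, c));
    }
  }
  double vol = 1.0;
  for (int c = 0; c < 3; ++c) vol *= std::max(hi[c] - lo[c], 1e-9);
  double h = std::max(std::cbrt(vol / std::max(nr, 1)) * 2.0, 1e-6);
  int nc[3];
  for (int c = 0; c < 3; ++c)
    nc[c] = std::max(1, (int)std::floor((hi[c] - lo[c]) / h) + 1);
  auto cell_of = [&](double x, int c) {
    int v = (int)std::floor((x - lo[c]) / h);
    return std::min(std::max(v, 0), nc[c] - 1);
  };
  std::vector<std::vector<int>> cells((size_t)nc[0] * nc[1] * nc[2]);
  for (int i = 0; i < nr; ++i) {
    int a = cell_of(ref(i, 0), 0), b = cell_of(ref(i, 1), 1), c = cell_of(ref(i, 2), 2);
    cells[((size_t)c * nc[1] + b) * nc[0] + a].push_back(i);
  }
  int maxring = std::max(nc[0], std::max(nc[1], nc[2]));
  for (int q = 0; q < nq; ++q) {
    double px = query(q, 0), py = query(q, 1), pz = query(q, 2);
    int qa = cell_of(px, 0), qb = cell_of(py, 1), qc = cell_of(pz, 2);
    double best = std::numeric_limits<double>::infinity();
    for (int r = 0; r <= maxring; ++r) {
      double ringmin = std::numeric_limits<double>::infinity();
      bool any = false;
      for (int dc = -r; dc <= r; ++dc) {
        int cc = qc + dc; if (cc < 0 || cc >= nc[2]) continue;
        for (int db = -r; db <= r; ++db) {
          int cb = qb + db; if (cb < 0 || cb >= nc[1]) continue;
          for (int da = -r; da <= r; ++da) {
            if (std::max(std::abs(da), std::max(std::abs(db), std::abs(dc))) != r)
              continue;
            int ca = qa + da; if (ca < 0 || ca >= nc[0]) continue;
            any = true;
            // lower bound: distance from point to cell box
            double bx0 = lo[0] + ca * h, by0 = lo[1] + cb * h, bz0 = lo[2] + cc * h;
            double ddx = std::max(std::max(bx0 - px, px - (bx0 + h)), 0.0);
            double ddy = std::max(std::max(by0 - py, py - (by0 + h)), 0.0);
            double ddz = std::max(std::max(bz0 - pz, pz - (bz0 + h)), 0.0);
            double lb2 = ddx * ddx + ddy * ddy + ddz * ddz;
            ringmin = std::min(ringmin, lb2);
            if (lb2 >= best) continue;
            const std::vector<int>& cell =
              cells[((size_t)cc * nc[1] + cb) * nc[0] + ca];
            for (int id : cell) {
              double ex = ref(id, 0) - px, ey = ref(id, 1) - py, ez = ref(id, 2) - pz;
              double d2 = ex * ex + ey * ey + ez * ez;
              if (d2 < best) best = d2;
            }
          }
        }
      }
      if (any && ringmin > best && std::isfinite(best)) break;
    }
    out[q] = std::sqrt(best);
  }
  return out;
}
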