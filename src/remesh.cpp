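// Local remeshing operators: Delaunay-style edge flipping (planar flipping
// optimization) and isotropic remeshing (split / collapse / valence flip /
// tangential relax). The R wrapper re-projects remeshed vertices onto the
// input surface, so the tangential relax here only needs to stay near it.
#include <Rcpp.h>
#include <cmath>
#include <vector>
#include <array>
#include <unordered_map>
#include <algorithm>
using namespace Rcpp;

typedef std::array<double, 3> P3;
typedef std::array<int, 3> Tri;

static inline P3 sub(const P3 &a, const P3 &b) { return {a[0]-b[0], a[1]-b[1], a[2]-b[2]}; }
static inline double dot3(const P3 &a, const P3 &b) { return a[0]*b[0]+a[1]*b[1]+a[2]*b[2]; }
static inline P3 cross3(const P3 &a, const P3 &b) {
  return {a[1]*b[2]-a[2]*b[1], a[2]*b[0]-a[0]*b[2], a[0]*b[1]-a[1]*b[0]};
}
static inline double nrm(const P3 &a) { return std::sqrt(dot3(a, a)); }

static double min_angle(const P3 &a, const P3 &b, const P3 &c) {
  double la = nrm(sub(b, c)), lb = nrm(sub(a, c)), lc = nrm(sub(a, b));
  if (la <= 0 || lb <= 0 || lc <= 0) return 0.0;
  auto ang = [](double opp, double s1, double s2) {
    double cs = (s1 * s1 + s2 * s2 - opp * opp) / (2.0 * s1 * s2);
    cs = std::max(-1.0, std::min(1.0, cs));
    return std::acos(cs);
  };
  return std::min({ang(la, lb, lc), ang(lb, la, lc), ang(lc, la, lb)});
}

static double tri_area(const P3 &a, const P3 &b, const P3 &c) {
  return 0.5 * nrm(cross3(sub(b, a), sub(c, a)));
}

struct EdgeMap {
  std::unordered_map<long long, std::vector<int>> m;
  long long N;
  explicit EdgeMap(long long nverts) : N(nverts) {}
  long long key(int a, int b) const {
    return (long long)std::min(a, b) * N + std::max(a, b);
  }
  void add(int a, int b, int f) { m[key(a, b)].push_back(f); }
};

struct Mesh {
  std::vector<P3> v;
  std::vector<Tri> f;
  std::vector<char> fdead;

  EdgeMap edges() const {
    EdgeMap em((long long)v.size());
    for (size_t i = 0; i < f.size(); ++i) {
      if (fdead[i]) continue;
      em.add(f[i][0], f[i][1], (int)i);
      em.add(f[i][1], f[i][2], (int)i);
      em.add(f[i][2], f[i][0], (int)i);
    }
    return em;
  }
  int opposite(int fi, int a, int b) const {
    for (int k = 0; k < 3; ++k) {
      int x = f[fi][k];
      if (x != a && x != b) return x;
    }
    return -1;
  }
  int alive_faces() const {
    int n = 0;
    for (size_t i = 0; i < f.size(); ++i) if (!fdead[i]) ++n;
    return n;
  }
};

// flip rule 0: minimum-angle improvement (PFO); 1: valence regularization
static int flip_pass(Mesh &M, int rule) {
  EdgeMap em = M.edges();
  std::vector<int> valence;
  if (rule == 1) {
    valence.assign(M.v.size(), 0);
    for (auto &kv : em.m) {
      int a = (int)(kv.first / em.N), b = (int)(kv.first % em.N);
      valence[a]++; valence[b]++;
    }
  }
  std::vector<char> touched(M.f.size(), 0);
  int flips = 0;
  for (auto &kv : em.m) {
    if (kv.second.size() != 2) continue;       // boundary or non-manifold
    int f1 = kv.second[0], f2 = kv.second[1];
    if (M.fdead[f1] || M.fdead[f2] || touched[f1] || touched[f2]) continue;
    int a = (int)(kv.first / em.N), b = (int)(kv.first % em.N);
    int c = M.opposite(f1, a, b), d = M.opposite(f2, a, b);
    if (c < 0 || d < 0 || c == d) continue;
    if (em.m.count(em.key(c, d))) continue;    // flipped edge already exists
    const P3 &pa = M.v[a], &pb = M.v[b], &pc = M.v[c], &pd = M.v[d];
    if (tri_area(pa, pd, pc) < 1e-12 || tri_area(pb, pc, pd) < 1e-12) continue;
    bool do_flip = false;
    if (rule == 0) {
      double before = std::min(min_angle(pa, pb, pc), min_angle(pa, pb, pd));
      double after = std::min(min_angle(pa, pd, pc), min_angle(pb, pc, pd));
      do_flip = after > before + 1e-9;
    } else {
      auto dev = [&](int x, int delta) {
        int t = valence[x] + delta - 6;
        return t * t;
      };
      int before = dev(a, 0) + dev(b, 0) + dev(c, 0) + dev(d, 0);
      int after = dev(a, -1) + dev(b, -1) + dev(c, 1) + dev(d, 1);
      do_flip = after < before;
    }
    if (!do_flip) continue;
    M.f[f1] = {a, d, c};
    M.f[f2] = {b, c, d};
    touched[f1] = touched[f2] = 1;
    if (rule == 1) { valence[a]--; valence[b]--; valence[c]++; valence[d]++; }
    ++flips;
  }
  return flips;
}

// [[Rcpp::export]]
IntegerMatrix pfo_flip_cpp(NumericMatrix V, IntegerMatrix F0, int max_passes) {
  Mesh M;
  M.v.resize(V.nrow());
  for (int i = 0; i < V.nrow(); ++i) M.v[i] = {V(i, 0), V(i, 1), V(i, 2)};
  M.f.resize(F0.nrow());
  for (int i = 0; i < F0.nrow(); ++i) M.f[i] = {F0(i, 0), F0(i, 1), F0(i, 2)};
  M.fdead.assign(M.f.size(), 0);
  for (int p = 0; p < max_passes; ++p) {
    if (flip_pass(M, 0) == 0) break;
  }
  IntegerMatrix out((int)M.f.size(), 3);
  for (size_t i = 0; i < M.f.size(); ++i)
    for (int k = 0; k < 3; ++k) out((int)i, k) = M.f[i][k];
  return out;
}

static int split_pass(Mesh &M, double lmax) {
  EdgeMap em = M.edges();
  std::vector<char> touched(M.f.size(), 0);
  int splits = 0;
  std::vector<std::pair<double, long long>> longe;
  for (auto &kv : em.m) {
    int a = (int)(kv.first / em.N), b = (int)(kv.first % em.N);
    double l = nrm(sub(M.v[a], M.v[b]));
    if (l > lmax) longe.push_back({-l, kv.first});
  }
  std::sort(longe.begin(), longe.end());      // longest first
  for (auto &pr : longe) {
    long long k = pr.second;
    auto it = em.m.find(k);
    if (it == em.m.end()) continue;
    int a = (int)(k / em.N), b = (int)(k % em.N);
    bool skip = false;
    for (int fi : it->second)
      if (M.fdead[fi] || touched[fi]) { skip = true; break; }
    if (skip) continue;
    P3 mid = {(M.v[a][0] + M.v[b][0]) / 2, (M.v[a][1] + M.v[b][1]) / 2,
              (M.v[a][2] + M.v[b][2]) / 2};
    int mi = (int)M.v.size();
    M.v.push_back(mid);
    for (int fi : it->second) {
      int c = M.opposite(fi, a, b);
      M.fdead[fi] = 1;
      M.f.push_back({a, mi, c});
      M.fdead.push_back(1 * 0);
      M.f.push_back({mi, b, c});
      M.fdead.push_back(0);
      touched.push_back(1);
      touched.push_back(1);
    }
    ++splits;
  }
  return splits;
}

static int collapse_pass(Mesh &M, double lmin, double lmax) {
  EdgeMap em = M.edges();
  // vertex -> incident faces, vertex valence neighborhoods
  std::vector<std::vector<int>> vfaces(M.v.size());
  for (size_t i = 0; i < M.f.size(); ++i) {
    if (M.fdead[i]) continue;
    for (int k = 0; k < 3; ++k) vfaces[M.f[i][k]].push_back((int)i);
  }
  std::vector<char> vtouched(M.v.size(), 0);
  int collapses = 0;
  std::vector<std::pair<double, long long>> shorte;
  for (auto &kv : em.m) {
    int a = (int)(kv.first / em.N), b = (int)(kv.first % em.N);
    double l = nrm(sub(M.v[a], M.v[b]));
    if (l < lmin) shorte.push_back({l, kv.first});
  }
  std::sort(shorte.begin(), shorte.end());    // shortest first
  for (auto &pr : shorte) {
    long long k = pr.second;
    int a = (int)(k / em.N), b = (int)(k % em.N);
    if (vtouched[a] || vtouched[b]) continue;
    auto it = em.m.find(k);
    if (it == em.m.end() || it->second.size() != 2) continue;  // interior only
    // link condition: common vertex neighbors of a and b must be exactly the
    // two opposite vertices of the shared faces
    std::vector<int> na, nb;
    for (int fi : vfaces[a]) {
      if (M.fdead[fi]) continue;
      for (int kk = 0; kk < 3; ++kk) if (M.f[fi][kk] != a) na.push_back(M.f[fi][kk]);
    }
    for (int fi : vfaces[b]) {
      if (M.fdead[fi]) continue;
      for (int kk = 0; kk < 3; ++kk) if (M.f[fi][kk] != b) nb.push_back(M.f[fi][kk]);
    }
    std::sort(na.begin(), na.end()); na.erase(std::unique(na.begin(), na.end()), na.end());
    std::sort(nb.begin(), nb.end()); nb.erase(std::unique(nb.begin(), nb.end()), nb.end());
    std::vector<int> common;
    std::set_intersection(na.begin(), na.end(), nb.begin(), nb.end(),
                          std::back_inserter(common));
    int c1 = M.opposite(it->second[0], a, b), c2 = M.opposite(it->second[1], a, b);
    std::vector<int> expect = {c1, c2};
    std::sort(expect.begin(), expect.end());
    common.erase(std::remove(common.begin(), common.end(), a), common.end());
    common.erase(std::remove(common.begin(), common.end(), b), common.end());
    if (common != expect) continue;
    P3 mid = {(M.v[a][0] + M.v[b][0]) / 2, (M.v[a][1] + M.v[b][1]) / 2,
              (M.v[a][2] + M.v[b][2]) / 2};
    // guard: no surviving edge may become overlong or degenerate
    bool ok = true;
    for (int x : na) {
      if (x == b) continue;
      double l = nrm(sub(mid, M.v[x]));
      if (l > lmax || l < 1e-9) { ok = false; break; }
    }
    for (int x : nb) {
      if (!ok || x == a) continue;
      double l = nrm(sub(mid, M.v[x]));
      if (l > lmax || l < 1e-9) { ok = false; break; }
    }
    if (!ok) continue;
    // collapse b into a at the midpoint
    M.v[a] = mid;
    for (int fi : vfaces[b]) {
      if (M.fdead[fi]) continue;
      Tri &t = M.f[fi];
      bool has_a = (t[0] == a || t[1] == a || t[2] == a);
      if (has_a) { M.fdead[fi] = 1; continue; }      // the two shared faces
      for (int kk = 0; kk < 3; ++kk) if (t[kk] == b) t[kk] = a;
      vfaces[a].push_back(fi);
    }
    vtouched[a] = vtouched[b] = 1;
    for (int x : na) vtouched[x] = 1;
    for (int x : nb) vtouched[x] = 1;
    ++collapses;
  }
  return collapses;
}

static void relax_pass(Mesh &M, double lambda) {
  // tangential Laplacian smoothing: move toward the neighbor centroid,
  // projected off the area-weighted vertex normal
  std::vector<P3> acc(M.v.size(), {0, 0, 0});
  std::vector<double> cnt(M.v.size(), 0);
  std::vector<P3> vnorm(M.v.size(), {0, 0, 0});
  std::vector<char> boundary(M.v.size(), 0);
  EdgeMap em = M.edges();
  for (auto &kv : em.m) {
    int a = (int)(kv.first / em.N), b = (int)(kv.first % em.N);
    acc[a][0] += M.v[b][0]; acc[a][1] += M.v[b][1]; acc[a][2] += M.v[b][2];
    acc[b][0] += M.v[a][0]; acc[b][1] += M.v[a][1]; acc[b][2] += M.v[a][2];
    cnt[a]++; cnt[b]++;
    if (kv.second.size() != 2) { boundary[a] = boundary[b] = 1; }
  }
  for (size_t i = 0; i < M.f.size(); ++i) {
    if (M.fdead[i]) continue;
    P3 n = cross3(sub(M.v[M.f[i][1]], M.v[M.f[i][0]]),
                  sub(M.v[M.f[i][2]], M.v[M.f[i][0]]));
    for (int k = 0; k < 3; ++k) {
      int vi = M.f[i][k];
      vnorm[vi][0] += n[0]; vnorm[vi][1] += n[1]; vnorm[vi][2] += n[2];
    }
  }
  for (size_t i = 0; i < M.v.size(); ++i) {
    if (cnt[i] == 0 || boundary[i]) continue;
    P3 cen = {acc[i][0] / cnt[i], acc[i][1] / cnt[i], acc[i][2] / cnt[i]};
    P3 d = sub(cen, M.v[i]);
    double nl = nrm(vnorm[i]);
    if (nl > 1e-12) {
      P3 n = {vnorm[i][0] / nl, vnorm[i][1] / nl, vnorm[i][2] / nl};
      double dn = dot3(d, n);
      d[0] -= dn * n[0]; d[1] -= dn * n[1]; d[2] -= dn * n[2];
    }
    M.v[i][0] += lambda * d[0];
    M.v[i][1] += lambda * d[1];
    M.v[i][2] += lambda * d[2];
  }
}

// [[Rcpp::export]]
List er_remesh_cpp(NumericMatrix V, IntegerMatrix F0, double target_edge,
                   int passes) {
  Mesh M;
  M.v.resize(V.nrow());
  for (int i = 0; i < V.nrow(); ++i) M.v[i] = {V(i, 0), V(i, 1), V(i, 2)};
  M.f.resize(F0.nrow());
  for (int i = 0; i < F0.nrow(); ++i) M.f[i] = {F0(i, 0), F0(i, 1), F0(i, 2)};
  M.fdead.assign(M.f.size(), 0);
  const double lmax = 4.0 / 3.0 * target_edge;
  const double lmin = 4.0 / 5.0 * target_edge;
  for (int p = 0; p < passes; ++p) {
    split_pass(M, lmax);
    collapse_pass(M, lmin, lmax);
    flip_pass(M, 1);
    relax_pass(M, 0.5);
    if (M.alive_faces() < 4) break;
  }
  // compact: drop dead/degenerate faces, remap vertices
  std::vector<Tri> faces;
  for (size_t i = 0; i < M.f.size(); ++i) {
    if (M.fdead[i]) continue;
    Tri t = M.f[i];
    if (t[0] == t[1] || t[1] == t[2] || t[0] == t[2]) continue;
    if (tri_area(M.v[t[0]], M.v[t[1]], M.v[t[2]]) < 1e-12) continue;
    faces.push_back(t);
  }
  std::vector<int> remap(M.v.size(), -1);
  int nv = 0;
  for (auto &t : faces)
    for (int k = 0; k < 3; ++k)
      if (remap[t[k]] < 0) remap[t[k]] = nv++;
  NumericMatrix Vout(nv, 3);
  for (size_t i = 0; i < M.v.size(); ++i) {
    if (remap[i] < 0) continue;
    for (int k = 0; k < 3; ++k) Vout(remap[i], k) = M.v[i][k];
  }
  IntegerMatrix Fout((int)faces.size(), 3);
  for (size_t i = 0; i < faces.size(); ++i)
    for (int k = 0; k < 3; ++k) Fout((int)i, k) = remap[faces[i][k]];
  return List::create(_["vertices"] = Vout, _["faces"] = Fout);
}
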