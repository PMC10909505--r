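// Core vertex-model engine: polygonal mesh geometry, analytic forces for the
// area-elasticity / contractility / line-tension energy, overdamped Euler
// stepping, T1/T2 surgery, centroid-line cell division, and the main
// simulation loop.  Vertex indices are 0-based internally; the R wrappers
// convert.  All randomness goes through R's RNG so set.seed() governs runs.
#include <Rcpp.h>
#include <unordered_map>
#include <algorithm>
#include <cmath>
using namespace Rcpp;

struct Mesh {
  std::vector<double> vx, vy;
  std::vector<int> vid;                  // stable vertex ids
  std::vector< std::vector<int> > loops; // per-cell CCW vertex indices
  std::vector<int> cid;                  // stable cell ids
  std::vector<double> birth, tc;         // per-cell state (aligned with loops)
  std::vector<int> parent;
  int next_vid = 0, next_cid = 0;
  double time = 0.0;
  size_t nv() const { return vx.size(); }
  size_t nc() const { return loops.size(); }
};

// ---------------------------------------------------------------- conversion

static Mesh meshFromList(const List& ml) {
  Mesh m;
  NumericMatrix V = ml["vertices"];
  m.vx.resize(V.nrow()); m.vy.resize(V.nrow());
  for (int i = 0; i < V.nrow(); ++i) { m.vx[i] = V(i,0); m.vy[i] = V(i,1); }
  IntegerVector vid = ml["vertex_id"];
  m.vid.assign(vid.begin(), vid.end());
  List cells = ml["cells"];
  m.loops.resize(cells.size());
  for (int c = 0; c < cells.size(); ++c) {
    IntegerVector L = cells[c];
    m.loops[c].resize(L.size());
    for (int k = 0; k < L.size(); ++k) m.loops[c][k] = L[k] - 1;
  }
  IntegerVector cid = ml["cell_id"];
  m.cid.assign(cid.begin(), cid.end());
  NumericVector b = ml["birth_time"], t = ml["tc"];
  m.birth.assign(b.begin(), b.end());
  m.tc.assign(t.begin(), t.end());
  IntegerVector p = ml["parent_id"];
  m.parent.assign(p.begin(), p.end());
  m.time = as<double>(ml["time"]);
  m.next_vid = as<int>(ml["next_vertex_id"]);
  m.next_cid = as<int>(ml["next_cell_id"]);
  return m;
}

static List meshToList(const Mesh& m) {
  NumericMatrix V(m.nv(), 2);
  for (size_t i = 0; i < m.nv(); ++i) { V(i,0) = m.vx[i]; V(i,1) = m.vy[i]; }
  List cells(m.nc());
  for (size_t c = 0; c < m.nc(); ++c) {
    IntegerVector L(m.loops[c].size());
    for (size_t k = 0; k < m.loops[c].size(); ++k) L[k] = m.loops[c][k] + 1;
    cells[c] = L;
  }
  return List::create(
    _["vertices"] = V,
    _["vertex_id"] = IntegerVector(m.vid.begin(), m.vid.end()),
    _["cells"] = cells,
    _["cell_id"] = IntegerVector(m.cid.begin(), m.cid.end()),
    _["birth_time"] = NumericVector(m.birth.begin(), m.birth.end()),
    _["tc"] = NumericVector(m.tc.begin(), m.tc.end()),
    _["parent_id"] = IntegerVector(m.parent.begin(), m.parent.end()),
    _["time"] = m.time,
    _["next_vertex_id"] = m.next_vid,
    _["next_cell_id"] = m.next_cid);
}

// ------------------------------------------------------------------ geometry

static double polyArea(const Mesh& m, const std::vector<int>& L) {
  double s = 0.0; size_t n = L.size();
  for (size_t k = 0; k < n; ++k) {
    int i = L[k], j = L[(k + 1) % n];
    s += m.vx[i] * m.vy[j] - m.vx[j] * m.vy[i];
  }
  return 0.5 * s;
}

static double polyPerim(const Mesh& m, const std::vector<int>& L) {
  double s = 0.0; size_t n = L.size();
  for (size_t k = 0; k < n; ++k) {
    int i = L[k], j = L[(k + 1) % n];
    double dx = m.vx[j] - m.vx[i], dy = m.vy[j] - m.vy[i];
    s += std::sqrt(dx * dx + dy * dy);
  }
  return s;
}

static void polyCentroid(const Mesh& m, const std::vector<int>& L,
                         double& cx, double& cy) {
  // area-weighted polygon centroid
  double a = 0.0, sx = 0.0, sy = 0.0; size_t n = L.size();
  for (size_t k = 0; k < n; ++k) {
    int i = L[k], j = L[(k + 1) % n];
    double cr = m.vx[i] * m.vy[j] - m.vx[j] * m.vy[i];
    a += cr; sx += (m.vx[i] + m.vx[j]) * cr; sy += (m.vy[i] + m.vy[j]) * cr;
  }
  a *= 0.5;
  if (std::fabs(a) < 1e-300) { // degenerate: fall back to vertex mean
    cx = cy = 0.0;
    for (size_t k = 0; k < n; ++k) { cx += m.vx[L[k]]; cy += m.vy[L[k]]; }
    cx /= n; cy /= n; return;
  }
  cx = sx / (6.0 * a); cy = sy / (6.0 * a);
}

// ---------------------------------------------------------------- edge cache

struct EdgeCache {
  std::vector<int> ea, eb, mult;     // unique undirected edges + multiplicity
  std::vector<int> degree;           // per-vertex incident unique edges
  // CSR view of the loops for the hot force loop: loop_off[c]..loop_off[c+1]
  // indexes loop_v (vertex) and loop_e (edge id of segment k -> k+1)
  std::vector<int> loop_off, loop_v, loop_e;
  std::vector<char> on_boundary;   // vertex touches a multiplicity-1 edge
  bool valid = false;
  void build(const Mesh& m) {
    ea.clear(); eb.clear(); mult.clear();
    degree.assign(m.nv(), 0);
    loop_off.assign(m.nc() + 1, 0);
    loop_v.clear(); loop_e.clear();
    std::unordered_map<long long,int> idx;
    idx.reserve(m.nv() * 2);
    for (size_t c = 0; c < m.nc(); ++c) {
      const std::vector<int>& L = m.loops[c];
      size_t n = L.size();
      for (size_t k = 0; k < n; ++k) {
        int i = L[k], j = L[(k + 1) % n];
        int a = std::min(i, j), b = std::max(i, j);
        long long key = ((long long)a << 32) | (unsigned int)b;
        auto it = idx.find(key);
        int e;
        if (it == idx.end()) {
          e = (int)ea.size();
          idx[key] = e;
          ea.push_back(a); eb.push_back(b); mult.push_back(1);
          degree[a]++; degree[b]++;
        } else {
          e = it->second;
          mult[e]++;
        }
        loop_v.push_back(i); loop_e.push_back(e);
      }
      loop_off[c + 1] = (int)loop_v.size();
    }
    on_boundary.assign(m.nv(), 0);
    for (size_t e = 0; e < ea.size(); ++e)
      if (mult[e] == 1) { on_boundary[ea[e]] = 1; on_boundary[eb[e]] = 1; }
    valid = true;
  }
};

// per-step scratch: unique-edge lengths and inverse lengths
struct GeomScratch { std::vector<double> len, inv; };

static void edgeLengths(const Mesh& m, const EdgeCache& ec, GeomScratch& gs,
                        bool strict) {
  size_t E = ec.ea.size();
  gs.len.resize(E); gs.inv.resize(E);
  for (size_t e = 0; e < E; ++e) {
    double dx = m.vx[ec.eb[e]] - m.vx[ec.ea[e]];
    double dy = m.vy[ec.eb[e]] - m.vy[ec.ea[e]];
    double l = std::sqrt(dx * dx + dy * dy);
    if (l < 1e-12) {
      if (strict) stop("degenerate zero-length edge: force undefined");
      l = 1e-12;
    }
    gs.len[e] = l; gs.inv[e] = 1.0 / l;
  }
}

// -------------------------------------------------------------- force/energy

static double energyOf(const Mesh& m, const std::vector<double>& A0,
                       double K, double Lam, double Gam, const EdgeCache& ec) {
  double E = 0.0;
  for (size_t c = 0; c < m.nc(); ++c) {
    double A = polyArea(m, m.loops[c]), L = polyPerim(m, m.loops[c]);
    E += 0.5 * K * (A - A0[c]) * (A - A0[c]) + 0.5 * Gam * L * L;
  }
  for (size_t e = 0; e < ec.ea.size(); ++e)
    {
      double dx = m.vx[ec.eb[e]] - m.vx[ec.ea[e]], dy = m.vy[ec.eb[e]] - m.vy[ec.ea[e]];
      E += Lam * std::sqrt(dx * dx + dy * dy);
    }
  return E;
}

// F = -grad E, using the per-step edge lengths in `gs`.
// areas optionally returned (computed anyway).
static void forcesOf(const Mesh& m, const std::vector<double>& A0,
                     double K, double Lam, double Gam, const EdgeCache& ec,
                     const GeomScratch& gs,
                     std::vector<double>& fx, std::vector<double>& fy,
                     std::vector<double>* areas = nullptr) {
  fx.assign(m.nv(), 0.0); fy.assign(m.nv(), 0.0);
  if (areas) areas->assign(m.nc(), 0.0);
  const double* vx = m.vx.data(); const double* vy = m.vy.data();
  for (size_t c = 0; c < m.nc(); ++c) {
    int s0 = ec.loop_off[c], s1 = ec.loop_off[c + 1], n = s1 - s0;
    double A = 0.0, P = 0.0;
    for (int k = s0; k < s1; ++k) {
      int i = ec.loop_v[k], j = ec.loop_v[k + 1 == s1 ? s0 : k + 1];
      A += vx[i] * vy[j] - vx[j] * vy[i];
      P += gs.len[ec.loop_e[k]];
    }
    A *= 0.5;
    if (areas) (*areas)[c] = A;
    double ka = K * (A - A0[c]), gp = Gam * P;
    (void)n;
    for (int k = s0; k < s1; ++k) {
      int i = ec.loop_v[k];
      int kp = k == s0 ? s1 - 1 : k - 1, kn = k + 1 == s1 ? s0 : k + 1;
      int ip = ec.loop_v[kp], in = ec.loop_v[kn];
      // shoelace area gradient: dA/dri = 0.5 * (y_next - y_prev, x_prev - x_next)
      fx[i] -= ka * 0.5 * (vy[in] - vy[ip]);
      fy[i] -= ka * 0.5 * (vx[ip] - vx[in]);
      // perimeter gradient: unit vectors away from both loop neighbours
      double invp = gs.inv[ec.loop_e[kp]], invn = gs.inv[ec.loop_e[k]];
      fx[i] -= gp * ((vx[i] - vx[ip]) * invp + (vx[i] - vx[in]) * invn);
      fy[i] -= gp * ((vy[i] - vy[ip]) * invp + (vy[i] - vy[in]) * invn);
    }
  }
  // line tension: each unique undirected edge contributes once
  for (size_t e = 0; e < ec.ea.size(); ++e) {
    int a = ec.ea[e], b = ec.eb[e];
    double w = Lam * gs.inv[e];
    double dx = m.vx[a] - m.vx[b], dy = m.vy[a] - m.vy[b];
    fx[a] -= w * dx; fy[a] -= w * dy;
    fx[b] += w * dx; fy[b] += w * dy;
  }
}


// ---- simple-polygon checks (used to vet T1 results in crowded regions) ----

static inline double cross2d(double ux, double uy, double vx, double vy) {
  return ux * vy - uy * vx;
}

static bool segProperCross(double ax, double ay, double bx, double by,
                           double cx, double cy, double dx, double dy) {
  double d1 = cross2d(dx - cx, dy - cy, ax - cx, ay - cy);
  double d2 = cross2d(dx - cx, dy - cy, bx - cx, by - cy);
  double d3 = cross2d(bx - ax, by - ay, cx - ax, cy - ay);
  double d4 = cross2d(bx - ax, by - ay, dx - ax, dy - ay);
  return d1 * d2 < 0 && d3 * d4 < 0;
}

static bool loopSimple(const Mesh& m, const std::vector<int>& L) {
  size_t n = L.size();
  if (n < 4) return true;
  for (size_t p = 0; p < n; ++p) {
    size_t pn = (p + 1) % n;
    for (size_t q = p + 1; q < n; ++q) {
      size_t qn = (q + 1) % n;
      if (q == pn || qn == p) continue;  // adjacent segments share a vertex
      if (segProperCross(m.vx[L[p]], m.vy[L[p]], m.vx[L[pn]], m.vy[L[pn]],
                         m.vx[L[q]], m.vy[L[q]], m.vx[L[qn]], m.vy[L[qn]]))
        return false;
    }
  }
  return true;
}

// ---------------------------------------------------------------- T1 surgery

// Find position of directed edge a->b in loop; -1 if absent.
static int findDirectedEdge(const std::vector<int>& L, int a, int b) {
  size_t n = L.size();
  for (size_t k = 0; k < n; ++k)
    if (L[k] == a && L[(k + 1) % n] == b) return (int)k;
  return -1;
}

static bool contains(const std::vector<int>& L, int v) {
  return std::find(L.begin(), L.end(), v) != L.end();
}

// T1 swap on interior edge (a,b); returns false (with reason) if ineligible.
static bool applyT1(Mesh& m, int a, int b, double l_new,
                    int* cells_out, std::string& why) {
  int P = -1, Q = -1, R = -1, S = -1;
  for (size_t c = 0; c < m.nc(); ++c) {
    if (findDirectedEdge(m.loops[c], a, b) >= 0) P = (int)c;
    else if (findDirectedEdge(m.loops[c], b, a) >= 0) Q = (int)c;
  }
  if (P < 0 || Q < 0) { why = "edge not interior"; return false; }
  for (size_t c = 0; c < m.nc(); ++c) {
    if ((int)c == P || (int)c == Q) continue;
    if (contains(m.loops[c], a)) R = (int)c;
    if (contains(m.loops[c], b)) S = (int)c;
  }
  if (R < 0 || S < 0) { why = "endpoint lacks a third cell (boundary or non-3-fold)"; return false; }
  if (R == S) { why = "flanking cells coincide"; return false; }
  if (m.loops[P].size() < 4 || m.loops[Q].size() < 4) { why = "cell would drop below 3 sides"; return false; }

  std::vector<int> saveP = m.loops[P], saveQ = m.loops[Q],
                   saveR = m.loops[R], saveS = m.loops[S];
  double sax = m.vx[a], say = m.vy[a], sbx = m.vx[b], sby = m.vy[b];

  // geometry: rotate about midpoint; a stays with P's side, b with Q's side
  double mx = 0.5 * (m.vx[a] + m.vx[b]), my = 0.5 * (m.vy[a] + m.vy[b]);
  double dx = m.vx[b] - m.vx[a], dy = m.vy[b] - m.vy[a];
  double l = std::hypot(dx, dy);
  if (l < 1e-14) { why = "zero-length edge"; return false; }
  double nx = -dy / l, ny = dx / l;  // left of a->b points into P (CCW)
  m.vx[a] = mx + 0.5 * l_new * nx; m.vy[a] = my + 0.5 * l_new * ny;
  m.vx[b] = mx - 0.5 * l_new * nx; m.vy[b] = my - 0.5 * l_new * ny;

  // combinatorics: P loses b, Q loses a, R gains b before a, S gains a before b
  std::vector<int>& LP = m.loops[P];
  LP.erase(std::find(LP.begin(), LP.end(), b));
  std::vector<int>& LQ = m.loops[Q];
  LQ.erase(std::find(LQ.begin(), LQ.end(), a));
  std::vector<int>& LR = m.loops[R];
  LR.insert(std::find(LR.begin(), LR.end(), a), b);
  std::vector<int>& LS = m.loops[S];
  LS.insert(std::find(LS.begin(), LS.end(), b), a);

  // reject the swap if it tangles any incident loop (crowded junctions):
  // restore the saved loops/positions and report, so sweeps can skip it
  if (!(loopSimple(m, m.loops[P]) && loopSimple(m, m.loops[Q]) &&
        loopSimple(m, m.loops[R]) && loopSimple(m, m.loops[S]) &&
        polyArea(m, m.loops[P]) > 0 && polyArea(m, m.loops[Q]) > 0 &&
        polyArea(m, m.loops[R]) > 0 && polyArea(m, m.loops[S]) > 0)) {
    m.loops[P] = saveP; m.loops[Q] = saveQ; m.loops[R] = saveR; m.loops[S] = saveS;
    m.vx[a] = sax; m.vy[a] = say; m.vx[b] = sbx; m.vy[b] = sby;
    why = "swap would tangle an incident cell";
    return false;
  }
  if (cells_out) { cells_out[0] = m.cid[P]; cells_out[1] = m.cid[Q];
                   cells_out[2] = m.cid[R]; cells_out[3] = m.cid[S]; }
  return true;
}

// ---------------------------------------------------------------- T2 surgery

static void dropUnusedVertices(Mesh& m) {
  std::vector<char> used(m.nv(), 0);
  for (size_t c = 0; c < m.nc(); ++c)
    for (int v : m.loops[c]) used[v] = 1;
  std::vector<int> remap(m.nv(), -1);
  size_t w = 0;
  for (size_t i = 0; i < m.nv(); ++i) {
    if (used[i]) {
      remap[i] = (int)w;
      m.vx[w] = m.vx[i]; m.vy[w] = m.vy[i]; m.vid[w] = m.vid[i];
      ++w;
    }
  }
  m.vx.resize(w); m.vy.resize(w); m.vid.resize(w);
  for (size_t c = 0; c < m.nc(); ++c)
    for (size_t k = 0; k < m.loops[c].size(); ++k)
      m.loops[c][k] = remap[m.loops[c][k]];
}

static void eraseCell(Mesh& m, int c) {
  m.loops.erase(m.loops.begin() + c);
  m.cid.erase(m.cid.begin() + c);
  m.birth.erase(m.birth.begin() + c);
  m.tc.erase(m.tc.begin() + c);
  m.parent.erase(m.parent.begin() + c);
}

// Remove a 3-sided cell.  Interior triangles collapse to a single vertex at
// the centroid; triangles with a boundary edge are peeled (loop deleted).
// Returns 1 interior T2, 2 boundary peel, 0 skipped (reason in why).
static int applyT2(Mesh& m, int c, std::string& why) {
  if (m.loops[c].size() != 3) { why = "cell is not 3-sided"; return 0; }
  std::vector<int> tri = m.loops[c];
  // classify the three edges
  bool interior = true;
  for (int k = 0; k < 3; ++k) {
    int a = tri[k], b = tri[(k + 1) % 3];
    bool shared = false;
    for (size_t o = 0; o < m.nc(); ++o) {
      if ((int)o == c) continue;
      if (findDirectedEdge(m.loops[o], b, a) >= 0 ||
          findDirectedEdge(m.loops[o], a, b) >= 0) { shared = true; break; }
    }
    if (!shared) { interior = false; break; }
  }
  if (interior) {
    // neighbours about to lose a side must keep >= 3
    for (size_t o = 0; o < m.nc(); ++o) {
      if ((int)o == c) continue;
      int hits = 0;
      for (int v : tri) if (contains(m.loops[o], v)) ++hits;
      if (hits >= 2 && m.loops[o].size() < 4) { why = "neighbour would degenerate"; return 0; }
    }
    double cx, cy; polyCentroid(m, m.loops[c], cx, cy);
    int nv = (int)m.nv();
    m.vx.push_back(cx); m.vy.push_back(cy); m.vid.push_back(m.next_vid++);
    for (size_t o = 0; o < m.nc(); ++o) {
      if ((int)o == c) continue;
      std::vector<int>& L = m.loops[o];
      bool touched = false;
      for (size_t k = 0; k < L.size(); ++k)
        for (int v : tri) if (L[k] == v) { L[k] = nv; touched = true; }
      if (touched) { // collapse consecutive duplicates of the new vertex
        std::vector<int> out;
        for (size_t k = 0; k < L.size(); ++k)
          if (out.empty() || out.back() != L[k]) out.push_back(L[k]);
        if (out.size() > 1 && out.front() == out.back()) out.pop_back();
        L = out;
      }
    }
    eraseCell(m, c);
    dropUnusedVertices(m);
    return 1;
  }
  // boundary peel: drop the loop, keep shared vertices
  eraseCell(m, c);
  dropUnusedVertices(m);
  return 2;
}

// ------------------------------------------------------------ topology sweep

struct Events {
  std::vector<double> time;
  std::vector<int> kind;          // 0 division, 1 T1, 2 T2, 3 peel
  std::vector<int> c1, c2, c3, c4;
  std::vector<double> x1, x2;     // division: parent age, parent area
  void push(double t, int k, int a, int b, int c, int d,
            double u = NA_REAL, double v = NA_REAL) {
    time.push_back(t); kind.push_back(k);
    c1.push_back(a); c2.push_back(b); c3.push_back(c); c4.push_back(d);
    x1.push_back(u); x2.push_back(v);
  }
};

// Merge the low-degree endpoint of a short boundary edge into the other
// endpoint (moved to the midpoint).  Boundary edges cannot T1-swap (there is
// no fourth cell); without this move near-degenerate kinks accumulate on the
// free boundary.  Only a degree-2 endpoint (member of a single cell) is
// removable without creating a 4-fold vertex.
// Merge vertex b of a short edge into vertex a (moved to the midpoint).
// Used where a T1 cannot act: boundary edges (no fourth cell) and edges
// hanging off many-fold boundary vertices.  The keeper must be a boundary
// vertex (or b of degree <= 2) so no interior vertex ever exceeds degree 3.
// Guarded: every touched loop must stay a simple positive-area polygon with
// no repeated vertex, else the merge is reverted.
static bool mergeShortEdge(Mesh& m, int a, int b, const EdgeCache& ec,
                           int* cell_out) {
  // keep the boundary / higher-degree endpoint
  bool a_ok = ec.on_boundary[a] || ec.degree[b] <= 2;
  bool b_ok = ec.on_boundary[b] || ec.degree[a] <= 2;
  if (!a_ok && !b_ok) return false;
  if (!a_ok || (b_ok && ec.degree[b] > ec.degree[a])) std::swap(a, b);
  std::vector<size_t> touched;
  for (size_t c = 0; c < m.nc(); ++c)
    if (contains(m.loops[c], b)) touched.push_back(c);
  if (touched.empty()) return false;
  std::vector< std::vector<int> > saved;
  for (size_t c : touched) saved.push_back(m.loops[c]);
  double sax = m.vx[a], say = m.vy[a];
  m.vx[a] = 0.5 * (m.vx[a] + m.vx[b]);
  m.vy[a] = 0.5 * (m.vy[a] + m.vy[b]);
  bool ok = true;
  int owner_cid = NA_INTEGER;
  for (size_t c : touched) {
    std::vector<int>& L = m.loops[c];
    if (contains(L, a)) owner_cid = m.cid[c];
    for (size_t k = 0; k < L.size(); ++k) if (L[k] == b) L[k] = a;
    std::vector<int> out;
    for (int v : L) if (out.empty() || out.back() != v) out.push_back(v);
    if (out.size() > 1 && out.front() == out.back()) out.pop_back();
    L = out;
    int a_count = 0;
    for (int v : L) if (v == a) ++a_count;
    if (L.size() < 3 || a_count > 1 || polyArea(m, L) <= 0 || !loopSimple(m, L))
      ok = false;
  }
  if (!ok) {
    for (size_t t = 0; t < touched.size(); ++t) m.loops[touched[t]] = saved[t];
    m.vx[a] = sax; m.vy[a] = say;
    return false;
  }
  if (cell_out) *cell_out = owner_cid;
  dropUnusedVertices(m);
  return true;
}

// Repeatedly apply eligible T1s (shortest edge first, ties by lowest vertex
// id pair), boundary collapses, then T2s (smallest area first) until
// quiescent or the cap.  `ec` must be valid on entry and is valid on exit.
static int sweepTopology(Mesh& m, double l_t1, double l_new, double a_t2,
                         Events& ev, int max_iter, EdgeCache& ec) {
  int n_events = 0;
  std::vector<long long> rejected;  // vetoed this sweep (by stable vertex ids)
  auto edge_key = [&m](int a, int b) {
    long long lo = std::min(m.vid[a], m.vid[b]), hi = std::max(m.vid[a], m.vid[b]);
    return (lo << 32) | hi;
  };
  const double l_t1_sq = l_t1 * l_t1;
  for (int iter = 0; iter < max_iter; ++iter) {
    if (!ec.valid) ec.build(m);
    // candidate T1 edges (squared lengths: no sqrt in the scan)
    int best = -1; double best_sq = l_t1_sq;
    const double* vx = m.vx.data(); const double* vy = m.vy.data();
    for (size_t e = 0; e < ec.ea.size(); ++e) {
      if (ec.mult[e] != 2) continue;
      int a = ec.ea[e], b = ec.eb[e];
      double dx = vx[b] - vx[a], dy = vy[b] - vy[a];
      double lsq = dx * dx + dy * dy;
      if (lsq >= best_sq) continue;
      if (ec.degree[a] != 3 || ec.degree[b] != 3) continue;
      if (std::find(rejected.begin(), rejected.end(), edge_key(a, b)) !=
          rejected.end()) continue;
      if (lsq < best_sq - 1e-18 ||
          (std::fabs(lsq - best_sq) <= 1e-18 && best >= 0 &&
           std::min(m.vid[a], m.vid[b]) <
             std::min(m.vid[ec.ea[best]], m.vid[ec.eb[best]]))) {
        best = (int)e; best_sq = lsq;
      }
    }
    if (best >= 0) {
      int cells[4]; std::string why;
      if (applyT1(m, ec.ea[best], ec.eb[best], l_new, cells, why)) {
        ev.push(m.time, 1, cells[0], cells[1], cells[2], cells[3]);
        ++n_events; ec.valid = false;
        continue;
      }
      // vetoed or ineligible: remember and try the next candidate
      rejected.push_back(edge_key(ec.ea[best], ec.eb[best]));
      continue;
    }
    // remaining short edges that a T1 cannot treat (boundary edges, edges at
    // many-fold boundary vertices): merge the removable endpoint
    {
      int bbest = -1; double bsq = l_t1_sq;
      for (size_t e = 0; e < ec.ea.size(); ++e) {
        int a = ec.ea[e], b = ec.eb[e];
        // interior edges between two tri-junctions are T1 candidates, not merges
        if (ec.mult[e] == 2 && ec.degree[a] == 3 && ec.degree[b] == 3) continue;
        if (!ec.on_boundary[a] && !ec.on_boundary[b] &&
            ec.degree[a] > 2 && ec.degree[b] > 2) continue;
        double dx = vx[b] - vx[a], dy = vy[b] - vy[a];
        double lsq = dx * dx + dy * dy;
        if (lsq >= bsq) continue;
        if (std::find(rejected.begin(), rejected.end(), edge_key(a, b)) !=
            rejected.end()) continue;
        bbest = (int)e; bsq = lsq;
      }
      if (bbest >= 0) {
        int cell_out = NA_INTEGER;
        if (mergeShortEdge(m, ec.ea[bbest], ec.eb[bbest], ec, &cell_out)) {
          ev.push(m.time, 4, cell_out, NA_INTEGER, NA_INTEGER, NA_INTEGER);
          ++n_events; ec.valid = false;
        } else {
          rejected.push_back(edge_key(ec.ea[bbest], ec.eb[bbest]));
        }
        continue;
      }
    }
    // candidate T2 triangles
    int tri = -1; double tri_area = a_t2;
    for (size_t c = 0; c < m.nc(); ++c) {
      if (m.loops[c].size() != 3) continue;
      double A = polyArea(m, m.loops[c]);
      if (A < tri_area) { tri = (int)c; tri_area = A; }
    }
    if (tri >= 0) {
      std::string why;
      int cidr = m.cid[tri];
      int res = applyT2(m, tri, why);
      if (res > 0) {
        ev.push(m.time, res == 1 ? 2 : 3, cidr, NA_INTEGER, NA_INTEGER, NA_INTEGER);
        ++n_events; ec.valid = false;
        continue;
      }
    }
    return n_events;
  }
  return -n_events; // cap reached (signalled as negative)
}

// ------------------------------------------------------------- cell division

static double shortAxisAngle(const Mesh& m, const std::vector<int>& L) {
  // minor principal axis of the vertex scatter about the centroid
  double cx = 0, cy = 0; size_t n = L.size();
  for (int v : L) { cx += m.vx[v]; cy += m.vy[v]; }
  cx /= n; cy /= n;
  double sxx = 0, sxy = 0, syy = 0;
  for (int v : L) {
    double dx = m.vx[v] - cx, dy = m.vy[v] - cy;
    sxx += dx * dx; sxy += dx * dy; syy += dy * dy;
  }
  double th = 0.5 * std::atan2(2.0 * sxy, sxx - syy); // major-axis angle
  return th + M_PI / 2.0;
}

// Split cell c by the line through its centroid at `angle`.  Returns true on
// success; daughters replace the parent (index c) and append at the end.
static bool divideCell(Mesh& m, int c, double angle,
                       double tc1, double tc2, Events* ev) {
  const std::vector<int> L = m.loops[c];
  size_t n = L.size();
  if (n < 4) return false;
  double cx, cy; polyCentroid(m, L, cx, cy);
  double dx = std::cos(angle), dy = std::sin(angle);
  // intersections of the infinite line with the polygon edges
  std::vector<int> hit_k; std::vector<double> hit_x, hit_y;
  for (size_t k = 0; k < n; ++k) {
    int u = L[k], v = L[(k + 1) % n];
    double ex = m.vx[v] - m.vx[u], ey = m.vy[v] - m.vy[u];
    double den = ex * dy - ey * dx;
    if (std::fabs(den) < 1e-14) continue;
    double t = ((cx - m.vx[u]) * dy - (cy - m.vy[u]) * dx) / den;
    if (t > 1e-6 && t < 1.0 - 1e-6) {
      hit_k.push_back((int)k);
      hit_x.push_back(m.vx[u] + t * ex);
      hit_y.push_back(m.vy[u] + t * ey);
    }
  }
  if (hit_k.size() != 2) return false;
  int k1 = hit_k[0], k2 = hit_k[1];
  double parent_area = polyArea(m, L);
  double parent_age = m.time - m.birth[c];
  int parent_cid = m.cid[c];

  // new vertices
  size_t nv0 = m.nv();
  int i1 = (int)nv0;
  m.vx.push_back(hit_x[0]); m.vy.push_back(hit_y[0]); m.vid.push_back(m.next_vid++);
  int i2 = (int)nv0 + 1;
  m.vx.push_back(hit_x[1]); m.vy.push_back(hit_y[1]); m.vid.push_back(m.next_vid++);
  if (std::hypot(hit_x[1] - hit_x[0], hit_y[1] - hit_y[0]) < 1e-9) {
    m.vx.resize(nv0); m.vy.resize(nv0); m.vid.resize(nv0);
    m.next_vid -= 2;
    return false;
  }

  // daughter loops: d1 = i1, L[k1+1..k2], i2 ; d2 = i2, L[k2+1..k1], i1
  std::vector<int> d1, d2;
  d1.push_back(i1);
  for (size_t k = k1 + 1; ; ++k) { d1.push_back(L[k % n]); if ((int)(k % n) == k2) break; }
  d1.push_back(i2);
  d2.push_back(i2);
  for (size_t k = k2 + 1; ; ++k) { d2.push_back(L[k % n]); if ((int)(k % n) == (int)k1) break; }
  d2.push_back(i1);
  double a1 = polyArea(m, d1), a2 = polyArea(m, d2);
  if (a1 < 1e-12 || a2 < 1e-12) {
    m.vx.resize(nv0); m.vy.resize(nv0); m.vid.resize(nv0);
    m.next_vid -= 2;
    return false;
  }

  // insert the new vertices into the neighbouring cells' loops
  for (int which = 0; which < 2; ++which) {
    int k = which == 0 ? k1 : k2, newv = which == 0 ? i1 : i2;
    int u = L[k], v = L[(k + 1) % n];
    for (size_t o = 0; o < m.nc(); ++o) {
      if ((int)o == c) continue;
      int pos = findDirectedEdge(m.loops[o], v, u);
      if (pos >= 0) {
        m.loops[o].insert(m.loops[o].begin() + pos + 1, newv);
        break;
      }
    }
  }

  int cid1 = m.next_cid++, cid2 = m.next_cid++;
  m.loops[c] = d1; m.cid[c] = cid1; m.birth[c] = m.time; m.tc[c] = tc1;
  m.parent[c] = parent_cid;
  m.loops.push_back(d2); m.cid.push_back(cid2); m.birth.push_back(m.time);
  m.tc.push_back(tc2); m.parent.push_back(parent_cid);
  if (ev) ev->push(m.time, 0, parent_cid, cid1, cid2, NA_INTEGER,
                   parent_age, parent_area);
  return true;
}

// --------------------------------------------------------------- R interface

// [[Rcpp::export]]
double cpp_energy(List mesh, NumericVector targets, double K, double Lambda,
                  double Gamma) {
  Mesh m = meshFromList(mesh);
  if ((size_t)targets.size() != m.nc()) stop("one target area per cell required");
  EdgeCache ec; ec.build(m);
  std::vector<double> A0(targets.begin(), targets.end());
  return energyOf(m, A0, K, Lambda, Gamma, ec);
}

// [[Rcpp::export]]
NumericMatrix cpp_forces(List mesh, NumericVector targets, double K,
                         double Lambda, double Gamma) {
  Mesh m = meshFromList(mesh);
  if ((size_t)targets.size() != m.nc()) stop("one target area per cell required");
  EdgeCache ec; ec.build(m);
  GeomScratch gs; edgeLengths(m, ec, gs, true);
  std::vector<double> A0(targets.begin(), targets.end()), fx, fy;
  forcesOf(m, A0, K, Lambda, Gamma, ec, gs, fx, fy);
  NumericMatrix F(m.nv(), 2);
  for (size_t i = 0; i < m.nv(); ++i) { F(i,0) = fx[i]; F(i,1) = fy[i]; }
  return F;
}

// [[Rcpp::export]]
List cpp_relax(List mesh, NumericVector targets, double K, double Lambda,
               double Gamma, double gamma, double dt, double tol,
               int max_steps) {
  Mesh m = meshFromList(mesh);
  if ((size_t)targets.size() != m.nc()) stop("one target area per cell required");
  EdgeCache ec; ec.build(m);
  GeomScratch gs;
  std::vector<double> A0(targets.begin(), targets.end()), fx, fy;
  double mu = dt / gamma;
  bool converged = false;
  int steps = 0;
  for (; steps < max_steps; ++steps) {
    edgeLengths(m, ec, gs, false);
    forcesOf(m, A0, K, Lambda, Gamma, ec, gs, fx, fy);
    double fmax = 0.0;
    for (size_t i = 0; i < m.nv(); ++i)
      fmax = std::max(fmax, std::hypot(fx[i], fy[i]));
    if (fmax < tol) { converged = true; break; }
    for (size_t i = 0; i < m.nv(); ++i) { m.vx[i] += mu * fx[i]; m.vy[i] += mu * fy[i]; }
    m.time += dt;
  }
  return List::create(_["mesh"] = meshToList(m), _["converged"] = converged,
                      _["steps"] = steps);
}

// [[Rcpp::export]]
List cpp_t1(List mesh, int a, int b, double l_new) {
  Mesh m = meshFromList(mesh);
  int cells[4]; std::string why;
  bool ok = applyT1(m, a - 1, b - 1, l_new, cells, why);
  return List::create(_["mesh"] = meshToList(m), _["applied"] = ok,
                      _["reason"] = why,
                      _["cells"] = ok ? IntegerVector::create(cells[0], cells[1], cells[2], cells[3])
                                      : IntegerVector(0));
}

// [[Rcpp::export]]
List cpp_t2(List mesh, int cell_index) {
  Mesh m = meshFromList(mesh);
  std::string why;
  int res = applyT2(m, cell_index - 1, why);
  return List::create(_["mesh"] = meshToList(m), _["result"] = res,
                      _["reason"] = why);
}

static DataFrame eventsToDf(const Events& ev) {
  CharacterVector kind(ev.kind.size());
  for (size_t i = 0; i < ev.kind.size(); ++i)
    kind[i] = ev.kind[i] == 0 ? "division" : ev.kind[i] == 1 ? "T1"
            : ev.kind[i] == 2 ? "T2" : ev.kind[i] == 3 ? "peel" : "collapse";
  return DataFrame::create(
    _["time"] = NumericVector(ev.time.begin(), ev.time.end()),
    _["kind"] = kind,
    _["cell1"] = IntegerVector(ev.c1.begin(), ev.c1.end()),
    _["cell2"] = IntegerVector(ev.c2.begin(), ev.c2.end()),
    _["cell3"] = IntegerVector(ev.c3.begin(), ev.c3.end()),
    _["cell4"] = IntegerVector(ev.c4.begin(), ev.c4.end()),
    _["parent_age"] = NumericVector(ev.x1.begin(), ev.x1.end()),
    _["parent_area"] = NumericVector(ev.x2.begin(), ev.x2.end()),
    _["stringsAsFactors"] = false);
}

// [[Rcpp::export]]
List cpp_sweep(List mesh, double l_t1, double l_new, double a_t2,
               int max_iter) {
  Mesh m = meshFromList(mesh);
  Events ev;
  EdgeCache ec; ec.build(m);
  int n = sweepTopology(m, l_t1, l_new, a_t2, ev, max_iter, ec);
  return List::create(_["mesh"] = meshToList(m), _["events"] = eventsToDf(ev),
                      _["capped"] = n < 0);
}

// [[Rcpp::export]]
List cpp_divide(List mesh, int cell_index, double angle, double tc1,
                double tc2, int max_retries) {
  Mesh m = meshFromList(mesh);
  Events ev;
  bool ok = divideCell(m, cell_index - 1, angle, tc1, tc2, &ev);
  for (int r = 0; !ok && r < max_retries; ++r)
    ok = divideCell(m, cell_index - 1, unif_rand() * M_PI, tc1, tc2, &ev);
  return List::create(_["mesh"] = meshToList(m), _["applied"] = ok,
                      _["events"] = eventsToDf(ev));
}

// ------------------------------------------------------------ main sim loop

// [[Rcpp::export]]
List cpp_run(List mesh, List params, List control) {
  Mesh m = meshFromList(mesh);
  const double K = as<double>(params["K"]), Lam = as<double>(params["Lambda"]),
    Gam = as<double>(params["Gamma"]), gamma = as<double>(params["gamma"]),
    dt = as<double>(params["dt"]), Tc = as<double>(params["Tc"]),
    eps = as<double>(params["epsilon"]), A_f = as<double>(params["A_f"]),
    A_c = as<double>(params["A_c"]);
  const bool gate = as<bool>(params["with_area_gate"]);
  const bool divisions = as<bool>(params["divisions_enabled"]);
  const int angle_mode = as<int>(params["division_rule"]); // 0 random, 1 short axis
  const double l_t1 = as<double>(params["l_t1"]),
    l_new = as<double>(params["l_new"]), a_t2 = as<double>(params["a_t2"]);
  const double t_max = as<double>(control["t_max"]);
  const double n_max = as<double>(control["n_max"]);
  const double snap_dt = as<double>(control["snapshot_dt"]);
  const int topo_iter = as<int>(control["max_topo_iter"]);
  const double max_steps = as<double>(control["max_steps"]);

  const double mu = dt / gamma;
  EdgeCache ec; ec.build(m);
  GeomScratch gs;
  Events ev;
  std::vector<double> A0, fx, fy, areas;
  long cum_div = 0, cum_t1 = 0, cum_t2 = 0;

  std::vector<double> s_time, s_n, s_area_mean, s_area_sd, s_shape;
  std::vector<double> s_div, s_t1, s_t2;
  auto record = [&](void) {
    double n = (double)m.nc(), sa = 0, saa = 0, ss = 0;
    for (size_t c = 0; c < m.nc(); ++c) {
      double A = polyArea(m, m.loops[c]), P = polyPerim(m, m.loops[c]);
      sa += A; saa += A * A; ss += P / std::sqrt(A);
    }
    s_time.push_back(m.time); s_n.push_back(n);
    s_area_mean.push_back(sa / n);
    s_area_sd.push_back(n > 1 ? std::sqrt(std::max(0.0, (saa - sa * sa / n) / (n - 1))) : 0.0);
    s_shape.push_back(ss / n);
    s_div.push_back((double)cum_div); s_t1.push_back((double)cum_t1);
    s_t2.push_back((double)cum_t2);
  };
  record();
  double next_snap = m.time + snap_dt;

  double steps = 0;
  bool step_capped = false;
  while (m.time < t_max - 1e-12 && (double)m.nc() < n_max) {
    if (++steps > max_steps) { step_capped = true; break; }
    if (!ec.valid) ec.build(m);
    // target areas from the cell-cycle schedule
    A0.resize(m.nc());
    for (size_t c = 0; c < m.nc(); ++c) {
      double age = m.time - m.birth[c];
      A0[c] = age < 0.5 * m.tc[c] ? 1.0 : std::min(2.0 * age / m.tc[c], A_f);
    }
    edgeLengths(m, ec, gs, false);
    forcesOf(m, A0, K, Lam, Gam, ec, gs, fx, fy, &areas);
    for (size_t i = 0; i < m.nv(); ++i) { m.vx[i] += mu * fx[i]; m.vy[i] += mu * fy[i]; }
    m.time += dt;

    // topology (shares the edge cache; invalidates it only on events)
    int nev = sweepTopology(m, l_t1, l_new, a_t2, ev, topo_iter, ec);
    if (nev != 0) {
      int na = nev < 0 ? -nev : nev;
      for (int e = (int)ev.kind.size() - na; e < (int)ev.kind.size(); ++e) {
        if (ev.kind[e] == 1 || ev.kind[e] == 4) ++cum_t1;
        else if (ev.kind[e] == 2 || ev.kind[e] == 3) ++cum_t2;
      }
    }

    // divisions (after mechanics + topology, once per step)
    if (divisions) {
      size_t nc0 = m.nc();
      for (size_t c = 0; c < nc0; ++c) {
        double age = m.time - m.birth[c];
        if (age < m.tc[c]) continue;
        if (gate && polyArea(m, m.loops[c]) < A_c) continue;
        if (m.loops[c].size() < 4) continue; // triangle: defer one step
        double tc1 = eps * Tc + exp_rand() * (1.0 - eps) * Tc;
        double tc2 = eps * Tc + exp_rand() * (1.0 - eps) * Tc;
        double ang = angle_mode == 1 ? shortAxisAngle(m, m.loops[c])
                                     : unif_rand() * M_PI;
        bool ok = divideCell(m, (int)c, ang, tc1, tc2, &ev);
        for (int r = 0; !ok && r < 8; ++r)
          ok = divideCell(m, (int)c, unif_rand() * M_PI, tc1, tc2, &ev);
        if (ok) { ++cum_div; ec.valid = false; }
      }
    }

    if (m.time >= next_snap - 1e-9) {
      record();
      while (next_snap <= m.time + 1e-9) next_snap += snap_dt;
    }
    if (steps == std::floor(steps / 50000.0) * 50000.0) checkUserInterrupt();
  }
  record();

  DataFrame metrics = DataFrame::create(
    _["time"] = NumericVector(s_time.begin(), s_time.end()),
    _["n_cells"] = NumericVector(s_n.begin(), s_n.end()),
    _["mean_area"] = NumericVector(s_area_mean.begin(), s_area_mean.end()),
    _["sd_area"] = NumericVector(s_area_sd.begin(), s_area_sd.end()),
    _["mean_shape_index"] = NumericVector(s_shape.begin(), s_shape.end()),
    _["divisions"] = NumericVector(s_div.begin(), s_div.end()),
    _["t1_events"] = NumericVector(s_t1.begin(), s_t1.end()),
    _["t2_events"] = NumericVector(s_t2.begin(), s_t2.end()));

  return List::create(_["mesh"] = meshToList(m), _["events"] = eventsToDf(ev),
                      _["metrics"] = metrics, _["step_capped"] = step_capped,
                      _["steps"] = steps);
}
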