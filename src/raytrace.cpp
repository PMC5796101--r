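// Monte Carlo forward ray tracing on triangle meshes.
//
// Photon packets are emitted from collimated-beam, diffuse-sky-dome and
// Lambertian-disc (lamp) sources, intersected with the scene via a BVH
// (Moller-Trumbore primitive test), and scattered bi-Lambertianly at each
// surface hit with survival probabilities (rho, tau).  Packet weight is
// constant across the whole trace (rays are allocated to sources in
// proportion to source flux), so the energy ledger
//   emitted = absorbed + escaped + truncated
// closes exactly in packet counts.
//
// All randomness comes from a self-contained PCG32 generator seeded from a
// single integer, so traces are bitwise reproducible and independent of R's
// RNG state.

#include <Rcpp.h>
#include <vector>
#include <algorithm>
#include <cmath>
#include <cstdint>

using namespace Rcpp;

static const double HIT_EPS = 1e-9;   // minimum hit distance / restart offset (m)

// ---------------------------------------------------------------- RNG (PCG32)

struct Pcg32 {
  uint64_t state, inc;
  Pcg32(uint64_t seed, uint64_t seq = 54u) {
    state = 0u; inc = (seq << 1u) | 1u;
    next(); state += seed; next();
  }
  uint32_t next() {
    uint64_t old = state;
    state = old * 6364136223846793005ULL + inc;
    uint32_t xorshifted = (uint32_t)(((old >> 18u) ^ old) >> 27u);
    uint32_t rot = (uint32_t)(old >> 59u);
    return (xorshifted >> rot) | (xorshifted << ((-rot) & 31));
  }
  double runif() {           // uniform in [0, 1)
    return next() * (1.0 / 4294967296.0);
  }
};

// ---------------------------------------------------------------- geometry

struct Vec3 {
  double x, y, z;
  Vec3() : x(0), y(0), z(0) {}
  Vec3(double x_, double y_, double z_) : x(x_), y(y_), z(z_) {}
  Vec3 operator+(const Vec3& o) const { return Vec3(x + o.x, y + o.y, z + o.z); }
  Vec3 operator-(const Vec3& o) const { return Vec3(x - o.x, y - o.y, z - o.z); }
  Vec3 operator*(double s)       const { return Vec3(x * s, y * s, z * s); }
};
static inline double dot(const Vec3& a, const Vec3& b) {
  return a.x * b.x + a.y * b.y + a.z * b.z;
}
static inline Vec3 cross(const Vec3& a, const Vec3& b) {
  return Vec3(a.y * b.z - a.z * b.y, a.z * b.x - a.x * b.z, a.x * b.y - a.y * b.x);
}
static inline double norm(const Vec3& a) { return std::sqrt(dot(a, a)); }
static inline Vec3 normalize(const Vec3& a) {
  double n = norm(a);
  return (n > 0) ? a * (1.0 / n) : a;
}

// orthonormal basis perpendicular to unit vector n (Duff et al. branchless ONB)
static inline void onb(const Vec3& n, Vec3& t1, Vec3& t2) {
  double sign = (n.z >= 0.0) ? 1.0 : -1.0;
  double a = -1.0 / (sign + n.z);
  double b = n.x * n.y * a;
  t1 = Vec3(1.0 + sign * n.x * n.x * a, sign * b, -sign * n.x);
  t2 = Vec3(b, sign + n.y * n.y * a, -n.y);
}

// cosine-weighted direction about unit axis n
static inline Vec3 cosine_sample(const Vec3& n, Pcg32& rng) {
  Vec3 t1, t2; onb(n, t1, t2);
  double u1 = rng.runif(), u2 = rng.runif();
  double r = std::sqrt(u1), phi = 2.0 * M_PI * u2;
  double zc = std::sqrt(std::max(0.0, 1.0 - u1));
  return normalize(t1 * (r * std::cos(phi)) + t2 * (r * std::sin(phi)) + n * zc);
}

// Moller-Trumbore; returns t > HIT_EPS or -1
static inline double tri_intersect(const Vec3& o, const Vec3& d,
                                   const Vec3& v0, const Vec3& v1, const Vec3& v2,
                                   double& uu, double& vv) {
  Vec3 e1 = v1 - v0, e2 = v2 - v0;
  Vec3 p = cross(d, e2);
  double det = dot(e1, p);
  if (std::fabs(det) < 1e-12) return -1.0;
  double inv = 1.0 / det;
  Vec3 tv = o - v0;
  double u = dot(tv, p) * inv;
  if (u < 0.0 || u > 1.0) return -1.0;
  Vec3 q = cross(tv, e1);
  double v = dot(d, q) * inv;
  if (v < 0.0 || u + v > 1.0) return -1.0;
  double t = dot(e2, q) * inv;
  if (t <= HIT_EPS) return -1.0;
  uu = u; vv = v;
  return t;
}

// ---------------------------------------------------------------- mesh + BVH

struct Mesh {
  std::vector<Vec3> v0, e1v, e2v, nrm;   // per-triangle precomputed
  std::vector<Vec3> cen;
  int n;
};

struct BvhNode {
  double lo[3], hi[3];
  int left, right;       // -1 for leaf
  int start, count;      // into index array, for leaves
};

struct Bvh {
  std::vector<BvhNode> nodes;
  std::vector<int> idx;

  void build(const Mesh& m) {
    idx.resize(m.n);
    for (int i = 0; i < m.n; ++i) idx[i] = i;
    nodes.clear();
    nodes.reserve(2 * m.n);
    if (m.n > 0) build_node(m, 0, m.n);
  }

  int build_node(const Mesh& m, int start, int count) {
    int id = (int)nodes.size();
    nodes.push_back(BvhNode());
    BvhNode nd;
    for (int a = 0; a < 3; ++a) { nd.lo[a] = 1e300; nd.hi[a] = -1e300; }
    for (int i = start; i < start + count; ++i) {
      int t = idx[i];
      const Vec3 pts[3] = { m.v0[t], m.v0[t] + m.e1v[t], m.v0[t] + m.e2v[t] };
      for (int k = 0; k < 3; ++k) {
        const double c[3] = { pts[k].x, pts[k].y, pts[k].z };
        for (int a = 0; a < 3; ++a) {
          nd.lo[a] = std::min(nd.lo[a], c[a]);
          nd.hi[a] = std::max(nd.hi[a], c[a]);
        }
      }
    }
    if (count <= 4) {
      nd.left = nd.right = -1; nd.start = start; nd.count = count;
      nodes[id] = nd;
      return id;
    }
    int axis = 0;
    double ext[3] = { nd.hi[0] - nd.lo[0], nd.hi[1] - nd.lo[1], nd.hi[2] - nd.lo[2] };
    if (ext[1] > ext[axis]) axis = 1;
    if (ext[2] > ext[axis]) axis = 2;
    int mid = start + count / 2;
    std::nth_element(idx.begin() + start, idx.begin() + mid,
                     idx.begin() + start + count,
                     [&](int a, int b) {
                       double ca = (axis == 0) ? m.cen[a].x : (axis == 1) ? m.cen[a].y : m.cen[a].z;
                       double cb = (axis == 0) ? m.cen[b].x : (axis == 1) ? m.cen[b].y : m.cen[b].z;
                       return ca < cb;
                     });
    nd.start = -1; nd.count = -1;
    nodes[id] = nd;                          // placeholder with bbox
    int l = build_node(m, start, mid - start);
    int r = build_node(m, mid, start + count - mid);
    nodes[id].left = l; nodes[id].right = r;
    return id;
  }

  // closest hit; returns triangle index or -1
  int nearest(const Mesh& m, const Vec3& o, const Vec3& d,
              double& tbest, double& ubest, double& vbest) const {
    if (nodes.empty()) return -1;
    double invd[3] = {
      d.x != 0 ? 1.0 / d.x : 1e300,
      d.y != 0 ? 1.0 / d.y : 1e300,
      d.z != 0 ? 1.0 / d.z : 1e300 };
    double oo[3] = { o.x, o.y, o.z };
    int stack[64]; int sp = 0;
    stack[sp++] = 0;
    int best = -1; tbest = 1e300;
    while (sp > 0) {
      const BvhNode& nd = nodes[stack[--sp]];
      double t0 = 0.0, t1 = tbest;
      bool miss = false;
      for (int a = 0; a < 3; ++a) {
        double ta = (nd.lo[a] - oo[a]) * invd[a];
        double tb = (nd.hi[a] - oo[a]) * invd[a];
        if (ta > tb) std::swap(ta, tb);
        t0 = std::max(t0, ta); t1 = std::min(t1, tb);
        if (t0 > t1) { miss = true; break; }
      }
      if (miss) continue;
      if (nd.left < 0) {
        for (int i = nd.start; i < nd.start + nd.count; ++i) {
          int tr = idx[i];
          double uu, vv;
          double t = tri_intersect(o, d, m.v0[tr], m.v0[tr] + m.e1v[tr],
                                   m.v0[tr] + m.e2v[tr], uu, vv);
          if (t > 0 && t < tbest) { tbest = t; best = tr; ubest = uu; vbest = vv; }
        }
      } else {
        if (sp < 62) { stack[sp++] = nd.left; stack[sp++] = nd.right; }
      }
    }
    return best;
  }
};

static Mesh make_mesh(const NumericMatrix& V, const IntegerMatrix& F) {
  Mesh m;
  m.n = F.nrow();
  m.v0.resize(m.n); m.e1v.resize(m.n); m.e2v.resize(m.n);
  m.nrm.resize(m.n); m.cen.resize(m.n);
  for (int i = 0; i < m.n; ++i) {
    Vec3 a(V(F(i, 0), 0), V(F(i, 0), 1), V(F(i, 0), 2));
    Vec3 b(V(F(i, 1), 0), V(F(i, 1), 1), V(F(i, 1), 2));
    Vec3 c(V(F(i, 2), 0), V(F(i, 2), 1), V(F(i, 2), 2));
    m.v0[i] = a; m.e1v[i] = b - a; m.e2v[i] = c - a;
    m.nrm[i] = normalize(cross(m.e1v[i], m.e2v[i]));
    m.cen[i] = (a + b + c) * (1.0 / 3.0);
  }
  return m;
}

static int brute_nearest(const Mesh& m, const Vec3& o, const Vec3& d,
                         double& tbest, double& ubest, double& vbest) {
  int best = -1; tbest = 1e300;
  for (int i = 0; i < m.n; ++i) {
    double uu, vv;
    double t = tri_intersect(o, d, m.v0[i], m.v0[i] + m.e1v[i],
                             m.v0[i] + m.e2v[i], uu, vv);
    if (t > 0 && t < tbest) { tbest = t; best = i; ubest = uu; vbest = vv; }
  }
  return best;
}

// [[Rcpp::export]]
NumericMatrix cpp_nearest_hit(NumericMatrix V, IntegerMatrix F,
                              NumericMatrix origins, NumericMatrix dirs,
                              bool use_bvh) {
  Mesh m = make_mesh(V, F);
  Bvh bvh;
  if (use_bvh) bvh.build(m);
  int nr = origins.nrow();
  NumericMatrix out(nr, 5);   // tri (1-based, NA if none), t, u, v, 0
  for (int i = 0; i < nr; ++i) {
    Vec3 o(origins(i, 0), origins(i, 1), origins(i, 2));
    Vec3 d = normalize(Vec3(dirs(i, 0), dirs(i, 1), dirs(i, 2)));
    double t, u = 0, v = 0;
    int hit = use_bvh ? bvh.nearest(m, o, d, t, u, v)
                      : brute_nearest(m, o, d, t, u, v);
    if (hit < 0) {
      out(i, 0) = NA_REAL; out(i, 1) = NA_REAL; out(i, 2) = NA_REAL; out(i, 3) = NA_REAL;
    } else {
      out(i, 0) = hit + 1; out(i, 1) = t; out(i, 2) = u; out(i, 3) = v;
    }
  }
  return out;
}

// ---------------------------------------------------------------- sources

// source descriptors are prepared in R; see trace_scene()
struct SkyPatch { double flux, cos0, cos1, phi0, phi1; };

struct Source {
  int type;                   // 1 beam, 2 sky, 3 lamp
  double flux;                // total emitted (umol / s)
  Vec3 dir;                   // beam
  Vec3 center; double radius; // beam/sky: bounding-sphere; lamp: disc
  double back;                // distance to pull emission disc back
  std::vector<SkyPatch> patches;
  std::vector<double> patch_cum;
};

static void emit_packet(const Source& s, Pcg32& rng, Vec3& o, Vec3& d) {
  if (s.type == 1) {                 // collimated beam
    d = s.dir;
    Vec3 t1, t2; onb(d, t1, t2);
    double r = s.radius * std::sqrt(rng.runif());
    double phi = 2.0 * M_PI * rng.runif();
    Vec3 p = s.center + t1 * (r * std::cos(phi)) + t2 * (r * std::sin(phi));
    o = p - d * s.back;
  } else if (s.type == 2) {          // sky dome patch
    double u = rng.runif() * s.patch_cum.back();
    size_t k = std::lower_bound(s.patch_cum.begin(), s.patch_cum.end(), u) -
               s.patch_cum.begin();
    if (k >= s.patches.size()) k = s.patches.size() - 1;
    const SkyPatch& p = s.patches[k];
    double ct = p.cos1 + rng.runif() * (p.cos0 - p.cos1);   // uniform in solid angle
    double st = std::sqrt(std::max(0.0, 1.0 - ct * ct));
    double phi = p.phi0 + rng.runif() * (p.phi1 - p.phi0);
    d = Vec3(st * std::cos(phi), st * std::sin(phi), -ct);  // downward
    Vec3 t1, t2; onb(d, t1, t2);
    double r = s.radius * std::sqrt(rng.runif());
    double ph2 = 2.0 * M_PI * rng.runif();
    Vec3 q = s.center + t1 * (r * std::cos(ph2)) + t2 * (r * std::sin(ph2));
    o = q - d * s.back;
  } else {                           // lamp: Lambertian disc, emits downward
    double r = s.radius * std::sqrt(rng.runif());
    double phi = 2.0 * M_PI * rng.runif();
    o = s.center + Vec3(r * std::cos(phi), r * std::sin(phi), 0.0);
    d = cosine_sample(Vec3(0, 0, -1), rng);
  }
}

// ---------------------------------------------------------------- trace

// [[Rcpp::export]]
List cpp_trace(NumericMatrix V, IntegerMatrix F,
               IntegerVector elem_of_tri,         // 0-based element index per triangle
               NumericVector rho_elem, NumericVector tau_elem,
               List sources,
               double n_rays_req, int max_impacts,
               int seed, int nbatch,
               List patch_frames,                  // per-element detector grids (may be empty)
               double detector_pitch) {
  Mesh m = make_mesh(V, F);
  Bvh bvh; bvh.build(m);

  int nelem = rho_elem.size();
  int nsrc = sources.size();
  std::vector<Source> src(nsrc);
  double total_flux = 0.0;
  for (int i = 0; i < nsrc; ++i) {
    List sl = sources[i];
    Source& s = src[i];
    s.type = as<int>(sl["type"]);
    s.flux = as<double>(sl["flux"]);
    NumericVector c = sl["center"];
    s.center = Vec3(c[0], c[1], c[2]);
    s.radius = as<double>(sl["radius"]);
    s.back = sl.containsElementNamed("back") ? as<double>(sl["back"]) : 0.0;
    if (s.type == 1) {
      NumericVector d = sl["dir"];
      s.dir = normalize(Vec3(d[0], d[1], d[2]));
    }
    if (s.type == 2) {
      NumericMatrix pm = sl["patches"];   // flux, cos0, cos1, phi0, phi1
      double cum = 0.0;
      for (int k = 0; k < pm.nrow(); ++k) {
        SkyPatch p = { pm(k, 0), pm(k, 1), pm(k, 2), pm(k, 3), pm(k, 4) };
        s.patches.push_back(p);
        cum += p.flux;
        s.patch_cum.push_back(cum);
      }
    }
    total_flux += s.flux;
  }

  // detector grids: map element -> slot
  int nframes = patch_frames.size();
  std::vector<int> frame_of_elem(nelem, -1);
  std::vector<Vec3> fr_origin(nframes), fr_e1(nframes), fr_e2(nframes);
  std::vector<int> fr_nu(nframes), fr_nv(nframes);
  std::vector< std::vector<double> > fr_tally(nframes);
  for (int i = 0; i < nframes; ++i) {
    List fl = patch_frames[i];
    int el = as<int>(fl["elem"]);        // 0-based
    frame_of_elem[el] = i;
    NumericVector o = fl["origin"], a = fl["e1"], b = fl["e2"];
    fr_origin[i] = Vec3(o[0], o[1], o[2]);
    fr_e1[i] = Vec3(a[0], a[1], a[2]);
    fr_e2[i] = Vec3(b[0], b[1], b[2]);
    fr_nu[i] = as<int>(fl["nu"]);
    fr_nv[i] = as<int>(fl["nv"]);
    fr_tally[i].assign((size_t)fr_nu[i] * fr_nv[i], 0.0);
  }

  // outputs
  NumericVector incident(nelem), absorbed(nelem);
  NumericMatrix incident_batch(nelem, nbatch);
  double escaped = 0.0, truncated = 0.0, emitted = 0.0;

  if (total_flux <= 0.0 || n_rays_req < 1) {
    return List::create(_["incident"] = incident,
                        _["incident_batch"] = incident_batch,
                        _["absorbed"] = absorbed,
                        _["emitted"] = 0.0, _["escaped"] = 0.0,
                        _["truncated"] = 0.0,
                        _["n_rays"] = 0.0,
                        _["patch_tallies"] = List(0));
  }

  // allocate rays to sources proportional to flux (largest remainder)
  double n_rays = std::floor(n_rays_req);
  std::vector<double> exact(nsrc);
  std::vector<long long> nall(nsrc);
  long long assigned = 0;
  for (int i = 0; i < nsrc; ++i) {
    exact[i] = n_rays * src[i].flux / total_flux;
    nall[i] = (long long)std::floor(exact[i]);
    assigned += nall[i];
  }
  std::vector<int> order(nsrc);
  for (int i = 0; i < nsrc; ++i) order[i] = i;
  std::stable_sort(order.begin(), order.end(), [&](int a, int b) {
    return (exact[a] - std::floor(exact[a])) > (exact[b] - std::floor(exact[b]));
  });
  for (int i = 0; assigned < (long long)n_rays; ++i, ++assigned)
    nall[order[i % nsrc]] += 1;

  double w = total_flux / n_rays;   // constant packet weight (umol / s)
  Pcg32 rng((uint64_t)(uint32_t)seed);

  long long gray = 0;
  for (int is = 0; is < nsrc; ++is) {
    const Source& s = src[is];
    for (long long r = 0; r < nall[is]; ++r, ++gray) {
      int batch = (int)(gray % nbatch);
      Vec3 o, d;
      emit_packet(s, rng, o, d);
      emitted += w;
      bool alive = true;
      int impacts = 0;
      while (alive) {
        double t, uu, vv;
        int hit = bvh.nearest(m, o, d, t, uu, vv);
        if (hit < 0) { escaped += w; break; }
        ++impacts;
        int el = elem_of_tri[hit];
        incident[el] += w;
        incident_batch(el, batch) += w;
        Vec3 p = o + d * t;
        int fr = frame_of_elem[el];
        if (fr >= 0) {
          double lu = dot(p - fr_origin[fr], fr_e1[fr]);
          double lv = dot(p - fr_origin[fr], fr_e2[fr]);
          int iu = (int)std::floor(lu / detector_pitch);
          int iv = (int)std::floor(lv / detector_pitch);
          if (iu >= 0 && iu < fr_nu[fr] && iv >= 0 && iv < fr_nv[fr])
            fr_tally[fr][(size_t)iv * fr_nu[fr] + iu] += w;
        }
        double u = rng.runif();
        double rho = rho_elem[el], tau = tau_elem[el];
        if (u < rho) {                       // diffuse reflection, incident side
          Vec3 n = m.nrm[hit];
          if (dot(d, n) > 0) n = n * (-1.0);
          if (impacts >= max_impacts) { truncated += w; break; }
          d = cosine_sample(n, rng);
          o = p + d * HIT_EPS;
        } else if (u < rho + tau) {          // diffuse transmission, far side
          Vec3 n = m.nrm[hit];
          if (dot(d, n) < 0) n = n * (-1.0);
          if (impacts >= max_impacts) { truncated += w; break; }
          d = cosine_sample(n, rng);
          o = p + d * HIT_EPS;
        } else {
          absorbed[el] += w;
          break;
        }
      }
    }
  }

  List tallies(nframes);
  for (int i = 0; i < nframes; ++i) {
    NumericMatrix g(fr_nu[i], fr_nv[i]);
    for (int iv = 0; iv < fr_nv[i]; ++iv)
      for (int iu = 0; iu < fr_nu[i]; ++iu)
        g(iu, iv) = fr_tally[i][(size_t)iv * fr_nu[i] + iu];
    tallies[i] = g;
  }

  return List::create(_["incident"] = incident,
                      _["incident_batch"] = incident_batch,
                      _["absorbed"] = absorbed,
                      _["emitted"] = emitted,
                      _["escaped"] = escaped,
                      _["truncated"] = truncated,
                      _["n_rays"] = n_rays,
                      _["patch_tallies"] = tallies);
}
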