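// Particle-based stochastic reaction-diffusion engine with site-level rules.
//
// Reactions never delete particles: binding sets a bond between two sites and
// co-locates the pair's clusters, unbinding clears it and separates the
// partners at the unbinding radius, flag rules toggle a site bit. Second-order
// rules are resolved at collision time through precompiled condition-signature
// tables (the hash table replacing network expansion); the candidate subset's
// combined rate fixes the binding radius and a uniform draw selects the
// branch. A well-mixed SSA sampler reuses the same compiled rule tables for
// validation runs without positions.

#include <Rcpp.h>
#include <vector>
#include <cmath>
#include <chrono>
#include <array>
using namespace Rcpp;

namespace {

struct Cond { int target, via, site, val; };  // target: 0 self, 1 partner-via, 2 left, 3 right

struct O1Rule {
  int kind;        // 0 flag, 1 unbind, 2 remove
  int site, val;
  double rate, urad;
  int label, dir, ptype, psite;
  std::vector<Cond> conds;
};

struct Group {
  int ta, tb, nprobe;
  std::vector<int> p_who, p_target, p_via, p_site;
  std::vector<int> sig2subset;
  std::vector<int> sub_off, sub_rule;
  std::vector<double> sub_cum, sub_tot, sub_r2;
  double maxr;
};

struct Model {
  int T, maxS;
  std::vector<int> nsites, mobile, participates;
  std::vector<double> D;                 // um^2/s
  std::vector<int> skind;                // T*maxS, 1 = binding site
  std::vector<int> pairgroup;            // T*T -> group id or -1
  std::vector<Group> groups;
  // order-2 directed rules (global arrays)
  std::vector<int> o2_bsA, o2_bsB, o2_label;
  std::vector<double> o2_kv;             // um^3/s
  // order-1 rules
  std::vector<O1Rule> o1;
  std::vector<std::vector<int>> o1_of_type;
  // observables
  std::vector<int> obs_type;
  std::vector<std::vector<Cond>> obs_conds;
  // geometry
  double L[3];
  int bc[6];
  double absorb_prob[6];
  int absorb_mask[6];
  bool periodic_axis[3];
};

struct World {
  int cap, n;                            // capacity, current high-water index
  std::vector<int> type, state, left, right, anchored, alive, nbonds;
  std::vector<double> pos;               // 3*cap
  std::vector<int> bondp, bonds;         // maxS*cap
  int maxS;
};

std::vector<Cond> read_conds(const List& cm, const char* coff_name,
                             const char* tgt, const char* via,
                             const char* site, const char* val, int i) {
  IntegerVector coff = cm[coff_name];
  IntegerVector t = cm[tgt], v = cm[via], s = cm[site], x = cm[val];
  std::vector<Cond> out;
  for (int k = coff[i]; k < coff[i + 1]; ++k)
    out.push_back(Cond{t[k], v[k], s[k], x[k]});
  return out;
}

Model read_model(const List& cm) {
  Model m;
  m.T = as<int>(cm["T"]);
  m.maxS = as<int>(cm["maxS"]);
  m.nsites = as<std::vector<int>>(cm["nsites"]);
  m.mobile = as<std::vector<int>>(cm["mobile"]);
  m.participates = as<std::vector<int>>(cm["participates"]);
  m.D = as<std::vector<double>>(cm["D"]);
  m.skind = as<std::vector<int>>(cm["skind"]);
  m.pairgroup = as<std::vector<int>>(cm["pairgroup"]);
  List gl = cm["groups"];
  for (int gi = 0; gi < gl.size(); ++gi) {
    List g = gl[gi];
    Group G;
    G.ta = as<int>(g["ta"]); G.tb = as<int>(g["tb"]);
    G.p_who = as<std::vector<int>>(g["p_who"]);
    G.p_target = as<std::vector<int>>(g["p_target"]);
    G.p_via = as<std::vector<int>>(g["p_via"]);
    G.p_site = as<std::vector<int>>(g["p_site"]);
    G.nprobe = (int)G.p_who.size();
    G.sig2subset = as<std::vector<int>>(g["sig2subset"]);
    G.sub_off = as<std::vector<int>>(g["sub_off"]);
    G.sub_rule = as<std::vector<int>>(g["sub_rule"]);
    G.sub_cum = as<std::vector<double>>(g["sub_cum"]);
    G.sub_tot = as<std::vector<double>>(g["sub_tot"]);
    G.sub_r2 = as<std::vector<double>>(g["sub_r2"]);
    G.maxr = as<double>(g["maxr"]);
    m.groups.push_back(G);
  }
  m.o2_bsA = as<std::vector<int>>(cm["o2_bsA"]);
  m.o2_bsB = as<std::vector<int>>(cm["o2_bsB"]);
  m.o2_label = as<std::vector<int>>(cm["o2_label"]);
  m.o2_kv = as<std::vector<double>>(cm["o2_kv"]);
  {
    IntegerVector kind = cm["o1_kind"], site = cm["o1_site"], val = cm["o1_val"];
    NumericVector rate = cm["o1_rate"], urad = cm["o1_urad"];
    IntegerVector lab = cm["o1_label"], dir = cm["o1_dir"];
    IntegerVector pty = cm["o1_ptype"], psi = cm["o1_psite"], own = cm["o1_owner"];
    int n1 = kind.size();
    m.o1_of_type.assign(m.T, {});
    for (int i = 0; i < n1; ++i) {
      O1Rule r;
      r.kind = kind[i]; r.site = site[i]; r.val = val[i];
      r.rate = rate[i]; r.urad = urad[i]; r.label = lab[i]; r.dir = dir[i];
      r.ptype = pty[i]; r.psite = psi[i];
      r.conds = read_conds(cm, "o1_coff", "c_target", "c_via", "c_site",
                           "c_val", i);
      m.o1.push_back(r);
      m.o1_of_type[own[i]].push_back(i);
    }
  }
  {
    IntegerVector ot = cm["obs_type"];
    for (int i = 0; i < ot.size(); ++i) {
      m.obs_type.push_back(ot[i]);
      m.obs_conds.push_back(read_conds(cm, "obs_coff", "oc_target", "oc_via",
                                       "oc_site", "oc_val", i));
    }
  }
  NumericVector L = cm["L"];
  IntegerVector bc = cm["bc"], am = cm["absorb_mask"];
  NumericVector ap = cm["absorb_prob"];
  for (int d = 0; d < 3; ++d) m.L[d] = L[d];
  for (int f = 0; f < 6; ++f) {
    m.bc[f] = bc[f]; m.absorb_prob[f] = ap[f]; m.absorb_mask[f] = am[f];
  }
  for (int d = 0; d < 3; ++d)
    m.periodic_axis[d] = (m.bc[2 * d] == 1 && m.bc[2 * d + 1] == 1);
  return m;
}

World read_world(const List& st, int cap, int maxS) {
  World w;
  IntegerVector ty = st["ptype"], sa = st["state"], lf = st["left"],
                rg = st["right"], an = st["anchored"], al = st["alive"];
  NumericMatrix pos = st["pos"];
  IntegerMatrix bp = st["bondp"], bs = st["bonds"];
  int n0 = ty.size();
  w.cap = cap; w.n = n0; w.maxS = maxS;
  w.type.assign(cap, 0); w.state.assign(cap, 0);
  w.left.assign(cap, -1); w.right.assign(cap, -1);
  w.anchored.assign(cap, 0); w.alive.assign(cap, 0); w.nbonds.assign(cap, 0);
  w.pos.assign(3 * (size_t)cap, 0.0);
  w.bondp.assign((size_t)maxS * cap, -1);
  w.bonds.assign((size_t)maxS * cap, -1);
  for (int i = 0; i < n0; ++i) {
    w.type[i] = ty[i]; w.state[i] = sa[i]; w.left[i] = lf[i];
    w.right[i] = rg[i]; w.anchored[i] = an[i]; w.alive[i] = al[i];
    for (int d = 0; d < 3; ++d) w.pos[3 * (size_t)i + d] = pos(i, d);
    int nb = 0;
    for (int s = 0; s < maxS; ++s) {
      w.bondp[(size_t)maxS * i + s] = bp(i, s);
      w.bonds[(size_t)maxS * i + s] = bs(i, s);
      if (bp(i, s) >= 0) ++nb;
    }
    w.nbonds[i] = nb;
  }
  return w;
}


// Marsaglia-Tsang ziggurat sampler for standard normals, driven by R's
// uniform stream (one seed fixes the whole run); tables built on first use.
struct Ziggurat {
  int kn[128];
  double wn[128], fn[128];
  Ziggurat() {
    const double m1 = 2147483648.0;
    double dn = 3.442619855899, tn = dn;
    const double vn = 9.91256303526217e-3;
    double q = vn / std::exp(-0.5 * dn * dn);
    kn[0] = (int)((dn / q) * m1);
    kn[1] = 0;
    wn[0] = q / m1;
    wn[127] = dn / m1;
    fn[0] = 1.0;
    fn[127] = std::exp(-0.5 * dn * dn);
    for (int i = 126; i >= 1; i--) {
      dn = std::sqrt(-2.0 * std::log(vn / dn + std::exp(-0.5 * dn * dn)));
      kn[i + 1] = (int)((dn / tn) * m1);
      tn = dn;
      fn[i] = std::exp(-0.5 * dn * dn);
      wn[i] = dn / m1;
    }
  }
  inline double draw() {
    for (;;) {
      double u = unif_rand();
      int hz = (int)(u * 4294967296.0 - 2147483648.0);
      int iz = hz & 127;
      if (std::abs(hz) < kn[iz]) return hz * wn[iz];
      // fallback
      double x, y;
      if (iz == 0) {
        const double r = 3.442619855899;
        do {
          x = -std::log(unif_rand()) / r;
          y = -std::log(unif_rand());
        } while (y + y < x * x);
        return (hz > 0) ? r + x : -(r + x);
      }
      x = hz * wn[iz];
      if (fn[iz] + unif_rand() * (fn[iz - 1] - fn[iz]) <
          std::exp(-0.5 * x * x))
        return x;
    }
  }
};
static Ziggurat zigg;
inline double fast_norm() { return zigg.draw(); }

inline int getbit(int st, int s) { return (st >> s) & 1; }
inline void setbit(int& st, int s, int v) {
  st = v ? (st | (1 << s)) : (st & ~(1 << s));
}

inline bool eval_cond(const World& w, const Cond& c, int p) {
  int q = p;
  if (c.target == 2) { q = w.left[p]; if (q < 0) return false; }
  else if (c.target == 3) { q = w.right[p]; if (q < 0) return false; }
  if (c.target == 1) {
    int pp = w.bondp[(size_t)w.maxS * q + c.via];
    if (pp < 0) return 0 == c.val;       // unbound partner probes read as 0
    q = pp;
  }
  return getbit(w.state[q], c.site) == c.val;
}

inline bool eval_conds(const World& w, const std::vector<Cond>& cs, int p) {
  for (const Cond& c : cs) if (!eval_cond(w, c, p)) return false;
  return true;
}

// connected component through bonds (rings are linked by position, not bonds)
void cluster_of(const World& w, int p, std::vector<int>& out,
                std::vector<int>& stamp, int tick) {
  out.clear();
  std::vector<int> stack{p};
  stamp[p] = tick;
  while (!stack.empty()) {
    int q = stack.back(); stack.pop_back();
    out.push_back(q);
    for (int s = 0; s < w.maxS; ++s) {
      int r = w.bondp[(size_t)w.maxS * q + s];
      if (r >= 0 && stamp[r] != tick) { stamp[r] = tick; stack.push_back(r); }
    }
  }
}

struct EventLog {
  std::vector<double> t;
  std::vector<int> label, dir, p1, p2;
  bool collect;
  void add(double tt, int lab, int d, int a, int b) {
    if (!collect) return;
    t.push_back(tt); label.push_back(lab); dir.push_back(d);
    p1.push_back(a + 1); p2.push_back(b >= 0 ? b + 1 : NA_INTEGER);
  }
};

void rand_unit(double* v) {
  double n2;
  do {
    v[0] = fast_norm(); v[1] = fast_norm(); v[2] = fast_norm();
    n2 = v[0] * v[0] + v[1] * v[1] + v[2] * v[2];
  } while (n2 < 1e-12);
  double inv = 1.0 / std::sqrt(n2);
  v[0] *= inv; v[1] *= inv; v[2] *= inv;
}

inline double wrap_coord(double x, double L) {
  int guard = 0;
  while (x < 0 && ++guard < 1024) x += L;
  while (x >= L && ++guard < 1024) x -= L;
  return (x >= 0 && x < L) ? x : 0.0;
}

void reflect_into_box(const Model& m, double* x) {
  for (int d = 0; d < 3; ++d) {
    if (m.periodic_axis[d]) {
      x[d] = wrap_coord(x[d], m.L[d]);
    } else {
      int guard = 0;
      while ((x[d] < 0 || x[d] > m.L[d]) && ++guard < 64) {
        if (x[d] < 0) x[d] = -x[d];
        if (x[d] > m.L[d]) x[d] = 2 * m.L[d] - x[d];
      }
      if (x[d] < 0) x[d] = 0;
      if (x[d] > m.L[d]) x[d] = m.L[d];
    }
  }
}

// returns true if the particle was absorbed (free eligible singletons only)
bool boundary_particle(const Model& m, World& w, int p, const double* old_pos,
                       double Dclu, double dt, bool absorbable) {
  double* x = &w.pos[3 * (size_t)p];
  for (int d = 0; d < 3; ++d) {
    if (m.periodic_axis[d]) {
      x[d] = wrap_coord(x[d], m.L[d]);
      continue;
    }
    int guard = 0;
    while ((x[d] < 0 || x[d] > m.L[d]) && ++guard < 64) {
      int face = (x[d] < 0) ? 2 * d : 2 * d + 1;
      if (m.bc[face] == 2 && absorbable &&
          ((m.absorb_mask[face] >> w.type[p]) & 1)) {
        if (unif_rand() < m.absorb_prob[face]) return true;
      }
      if (x[d] < 0) x[d] = -x[d]; else x[d] = 2 * m.L[d] - x[d];
    }
  }
  // transient-crossing absorption (Brownian bridge) for absorbing faces
  if (absorbable && Dclu > 0) {
    for (int f = 0; f < 6; ++f) {
      if (m.bc[f] != 2 || !((m.absorb_mask[f] >> w.type[p]) & 1)) continue;
      int d = f / 2;
      double x0 = (f % 2 == 0) ? old_pos[d] : m.L[d] - old_pos[d];
      double x1 = (f % 2 == 0) ? x[d] : m.L[d] - x[d];
      if (x0 <= 0 || x1 <= 0) continue;
      double e = x0 * x1 / (Dclu * dt);
      if (e > 28) continue;          // crossing probability below 1e-12
      double pc = std::exp(-e);
      if (unif_rand() < m.absorb_prob[f] * pc) return true;
    }
  }
  return false;
}

void do_bind(const Model& m, World& w, int a, int b, int rid,
             std::vector<int>& stamp, int& tick, std::vector<int>& cl1,
             std::vector<int>& cl2) {
  int sA = m.o2_bsA[rid], sB = m.o2_bsB[rid];
  w.bondp[(size_t)w.maxS * a + sA] = b; w.bonds[(size_t)w.maxS * a + sA] = sB;
  w.bondp[(size_t)w.maxS * b + sB] = a; w.bonds[(size_t)w.maxS * b + sB] = sA;
  setbit(w.state[a], sA, 1); setbit(w.state[b], sB, 1);
  w.nbonds[a]++; w.nbonds[b]++;
  // co-locate: the faster cluster moves to the slower/anchored one
  cluster_of(w, a, cl1, stamp, ++tick);
  bool anchA = false; double DA = 1e30;
  for (int q : cl1) {
    if (w.anchored[q] || !m.mobile[w.type[q]]) anchA = true;
    DA = std::min(DA, m.D[w.type[q]]);
  }
  // b's members are now part of a's component; recompute b side before bond?
  // simpler: decide mover by the two particles' own cluster state pre-merge:
  // use per-particle anchor/D computed from the merged cluster minus the
  // other side is unnecessary -- move b's old cluster to a if a is anchored
  // or slower, else move a's old cluster to b.
  (void)cl2;
  bool anchB = false; double DB = m.D[w.type[b]];
  // b's pre-merge cluster: walk from b but never crossing the new bond
  {
    cl2.clear();
    std::vector<int> stack{b};
    ++tick; stamp[b] = tick;
    while (!stack.empty()) {
      int q = stack.back(); stack.pop_back();
      cl2.push_back(q);
      if (w.anchored[q] || !m.mobile[w.type[q]]) anchB = true;
      DB = std::min(DB, m.D[w.type[q]]);
      for (int s = 0; s < w.maxS; ++s) {
        if (q == b && s == sB) continue;
        int r = w.bondp[(size_t)w.maxS * q + s];
        if (q == a && s == sA) continue;
        if (r >= 0 && stamp[r] != tick && !(q == b && r == a)) {
          stamp[r] = tick; stack.push_back(r);
        }
      }
    }
  }
  // recompute a's pre-merge cluster the same way
  {
    cl1.clear();
    std::vector<int> stack{a};
    ++tick; stamp[a] = tick;
    anchA = false; DA = m.D[w.type[a]];
    while (!stack.empty()) {
      int q = stack.back(); stack.pop_back();
      cl1.push_back(q);
      if (w.anchored[q] || !m.mobile[w.type[q]]) anchA = true;
      DA = std::min(DA, m.D[w.type[q]]);
      for (int s = 0; s < w.maxS; ++s) {
        int r = w.bondp[(size_t)w.maxS * q + s];
        if (q == a && s == sA) continue;
        if (r >= 0 && stamp[r] != tick) { stamp[r] = tick; stack.push_back(r); }
      }
    }
  }
  const std::vector<int>* mover; int target;
  if (anchA && anchB) { mover = nullptr; target = -1; }
  else if (anchA) { mover = &cl2; target = a; }
  else if (anchB) { mover = &cl1; target = b; }
  else if (DA > DB) { mover = &cl1; target = b; }
  else { mover = &cl2; target = a; }
  if (mover) {
    const double* tp = &w.pos[3 * (size_t)target];
    for (int q : *mover)
      for (int d = 0; d < 3; ++d) w.pos[3 * (size_t)q + d] = tp[d];
  }
}

void do_unbind(const Model& m, World& w, int i, const O1Rule& r,
               std::vector<int>& stamp, int& tick, std::vector<int>& cl) {
  int s = r.site;
  int j = w.bondp[(size_t)w.maxS * i + s];
  if (j < 0) stop("unbind on free site (internal error)");
  int js = w.bonds[(size_t)w.maxS * i + s];
  if (r.ptype >= 0 && w.type[j] != r.ptype)
    stop("bond partner type mismatch (internal error)");
  w.bondp[(size_t)w.maxS * i + s] = -1; w.bonds[(size_t)w.maxS * i + s] = -1;
  w.bondp[(size_t)w.maxS * j + js] = -1; w.bonds[(size_t)w.maxS * j + js] = -1;
  setbit(w.state[i], s, 0); setbit(w.state[j], js, 0);
  w.nbonds[i]--; w.nbonds[j]--;
  // separate: displace the unanchored freed cluster by the unbinding radius
  cluster_of(w, j, cl, stamp, ++tick);
  bool anchJ = false;
  for (int q : cl) if (w.anchored[q] || !m.mobile[w.type[q]]) anchJ = true;
  int mover = -1;
  if (!anchJ) mover = j;
  else {
    cluster_of(w, i, cl, stamp, ++tick);
    bool anchI = false;
    for (int q : cl) if (w.anchored[q] || !m.mobile[w.type[q]]) anchI = true;
    if (!anchI) mover = i;
  }
  if (mover >= 0 && r.urad > 0) {
    cluster_of(w, mover, cl, stamp, ++tick);
    double u[3]; rand_unit(u);
    for (int q : cl) {
      for (int d = 0; d < 3; ++d) w.pos[3 * (size_t)q + d] += r.urad * u[d];
    }
    // fold back into the box (no absorption on placement)
    for (int q : cl) reflect_into_box(m, &w.pos[3 * (size_t)q]);
  }
}

void debug_checks(const Model& m, const World& w, double tnow) {
  for (int i = 0; i < w.n; ++i) {
    if (!w.alive[i]) continue;
    int ty = w.type[i];
    for (int s = 0; s < m.nsites[ty]; ++s) {
      int j = w.bondp[(size_t)w.maxS * i + s];
      bool bit = getbit(w.state[i], s);
      bool isbind = m.skind[(size_t)m.maxS * ty + s] == 1;
      if (isbind && bit != (j >= 0))
        stop("site-bit/bond inconsistency at t=%f particle %d site %d",
             tnow, i + 1, s + 1);
      if (j >= 0) {
        int js = w.bonds[(size_t)w.maxS * i + s];
        if (w.bondp[(size_t)w.maxS * j + js] != i)
          stop("bond asymmetry at t=%f particle %d", tnow, i + 1);
        if (!w.alive[j]) stop("bond to dead particle at t=%f", tnow);
        for (int d = 0; d < 3; ++d)
          if (std::abs(w.pos[3 * (size_t)i + d] - w.pos[3 * (size_t)j + d]) >
              1e-9)
            stop("bound pair not co-located at t=%f particle %d", tnow, i + 1);
      }
    }
    if (w.left[i] >= 0 && w.right[w.left[i]] != i)
      stop("ring neighbour asymmetry at particle %d", i + 1);
  }
}

List world_to_list(const World& w) {
  int n = w.n;
  IntegerVector ty(n), sa(n), lf(n), rg(n), an(n), al(n);
  NumericMatrix pos(n, 3);
  IntegerMatrix bp(n, w.maxS), bs(n, w.maxS);
  for (int i = 0; i < n; ++i) {
    ty[i] = w.type[i]; sa[i] = w.state[i]; lf[i] = w.left[i];
    rg[i] = w.right[i]; an[i] = w.anchored[i]; al[i] = w.alive[i];
    for (int d = 0; d < 3; ++d) pos(i, d) = w.pos[3 * (size_t)i + d];
    for (int s = 0; s < w.maxS; ++s) {
      bp(i, s) = w.bondp[(size_t)w.maxS * i + s];
      bs(i, s) = w.bonds[(size_t)w.maxS * i + s];
    }
  }
  return List::create(_["ptype"] = ty, _["pos"] = pos, _["state"] = sa,
                      _["bondp"] = bp, _["bonds"] = bs, _["left"] = lf,
                      _["right"] = rg, _["anchored"] = an, _["alive"] = al);
}

}  // namespace

// [[Rcpp::export]]
List engine_run(List cm, List st, List simp) {
  Model m = read_model(cm);
  double dt = as<double>(simp["dt"]);
  int nsteps = as<int>(simp["nsteps"]);
  int record_every = as<int>(simp["record_every"]);
  double t0 = as<double>(simp["t0"]);
  bool debug = as<bool>(simp["debug"]);
  IntegerVector influx_counts = simp["influx_counts"];
  int influx_type = as<int>(simp["influx_type"]);
  NumericVector influx_pos = simp["influx_pos"];
  bool has_influx = influx_counts.size() > 0;
  long total_influx = 0;
  for (int i = 0; i < influx_counts.size(); ++i) total_influx += influx_counts[i];

  IntegerVector ty0 = st["ptype"];
  int cap = ty0.size() + (int)total_influx;
  World w = read_world(st, cap, m.maxS);

  EventLog ev; ev.collect = as<bool>(simp["collect_events"]);

  // records
  int nrec = 1 + nsteps / record_every;
  int nobs = (int)m.obs_type.size();
  IntegerMatrix counts(nrec, nobs + m.T);
  NumericVector rec_times(nrec);
  std::vector<long> absorbed(m.T, 0), removed(m.T, 0);
  long influx_added = 0;

  // per-type grids: each second-order group probes from its currently
  // smaller side into the other type's grid. Cells are no smaller than the
  // largest binding radius involving the type; immobile types are gridded
  // once (their particles never move).
  std::vector<double> maxr_t(m.T, 1e-9);
  for (const Group& g : m.groups) {
    maxr_t[g.ta] = std::max(maxr_t[g.ta], g.maxr);
    maxr_t[g.tb] = std::max(maxr_t[g.tb], g.maxr);
  }
  std::vector<std::array<int, 3>> nct(m.T);
  std::vector<std::array<double, 3>> cszt(m.T), inv_cszt(m.T);
  std::vector<std::vector<int>> thead(m.T);
  std::vector<std::vector<int>> tocc(m.T);
  std::vector<int> cell_next(cap, -1);
  std::vector<char> static_built(m.T, 0);
  // probe direction per group is fixed: the faster-diffusing (and typically
  // transient, spatially clustered) species probes the slower one's grid
  std::vector<char> probe_type(m.T, 0), target_needed(m.T, 0);
  std::vector<int> group_target(m.groups.size());
  for (size_t gi = 0; gi < m.groups.size(); ++gi) {
    const Group& g = m.groups[gi];
    int probe = (m.D[g.ta] >= m.D[g.tb]) ? g.ta : g.tb;
    int target = (probe == g.ta) ? g.tb : g.ta;
    group_target[gi] = target;
    probe_type[probe] = 1;
    target_needed[target] = 1;
  }
  std::vector<int> type_cap(m.T, 0);
  {
    IntegerVector ty0v = st["ptype"];
    for (int i = 0; i < ty0v.size(); ++i) type_cap[ty0v[i]]++;
    if (has_influx) type_cap[influx_type] += (int)total_influx;
  }
  for (int t = 0; t < m.T; ++t) {
    if (!m.participates[t]) continue;
    std::array<int, 3> nc;
    for (int d = 0; d < 3; ++d)
      nc[d] = std::max(1, std::min(128,
                                   (int)std::floor(m.L[d] / (2 * maxr_t[t]))));
    // keep the head array small enough to stay cache-resident: about four
    // cells per particle of this type, capped
    double tot = (double)nc[0] * nc[1] * nc[2];
    double cap_cells = std::min(8192.0, std::max(64.0, 4.0 * type_cap[t]));
    if (tot > cap_cells) {
      double f = std::cbrt(cap_cells / tot);
      for (int d = 0; d < 3; ++d) nc[d] = std::max(1, (int)(nc[d] * f));
    }
    nct[t] = nc;
    for (int d = 0; d < 3; ++d) {
      cszt[t][d] = m.L[d] / nc[d];
      inv_cszt[t][d] = nc[d] / m.L[d];
    }
    thead[t].assign((size_t)nc[0] * nc[1] * nc[2], -1);
    tocc[t].reserve(1024);
  }
  std::vector<std::vector<int>> probe_groups_of_type(m.T);
  for (size_t gi = 0; gi < m.groups.size(); ++gi) {
    const Group& g = m.groups[gi];
    int probe = (group_target[gi] == g.ta) ? g.tb : g.ta;
    probe_groups_of_type[probe].push_back((int)gi);
  }
  std::vector<int> perm; perm.reserve(cap);
  std::vector<int> alive_list; alive_list.reserve(cap);
  std::vector<int> pos_in_alive(cap, -1);
  for (int i = 0; i < w.n; ++i)
    if (w.alive[i]) { pos_in_alive[i] = (int)alive_list.size();
                      alive_list.push_back(i); }
  std::vector<int> deaths;
  auto add_alive = [&](int i) {
    pos_in_alive[i] = (int)alive_list.size(); alive_list.push_back(i);
  };
  auto flush_deaths = [&]() {
    for (int i : deaths) {
      int idx = pos_in_alive[i], last = (int)alive_list.size() - 1;
      alive_list[idx] = alive_list[last];
      pos_in_alive[alive_list[idx]] = idx;
      alive_list.pop_back();
      pos_in_alive[i] = -1;
    }
    deaths.clear();
  };
  std::vector<int> reacted(cap, 0);
  std::vector<int> stamp(cap, 0); int tick = 0;
  std::vector<int> visited(cap, 0); int vtick = 0;
  std::vector<int> cl1, cl2, members;
  std::vector<double> oldpos(3 * (size_t)cap);

  bool any_o2 = !m.groups.empty();

  auto record = [&](int ri, double tnow) {
    rec_times[ri] = tnow;
    std::vector<int> cnt(nobs + m.T, 0);
    for (int i : alive_list) {
      cnt[nobs + w.type[i]]++;
      for (int o = 0; o < nobs; ++o)
        if (m.obs_type[o] == w.type[i] && eval_conds(w, m.obs_conds[o], i))
          cnt[o]++;
    }
    for (int k = 0; k < nobs + m.T; ++k) counts(ri, k) = cnt[k];
    if (debug) debug_checks(m, w, tnow);
  };

  record(0, t0);
  int ri = 1;

  bool profile = simp.containsElementNamed("profile") &&
                 as<bool>(simp["profile"]);
  double tim[4] = {0, 0, 0, 0};
  double tsub[3] = {0, 0, 0};
  auto tclk = [&]() { return std::chrono::duration<double>(
      std::chrono::steady_clock::now().time_since_epoch()).count(); };
  double tmark = 0;

  for (int step = 0; step < nsteps; ++step) {
    double tnow = t0 + (step + 1) * dt;
    if (step % 2048 == 0) Rcpp::checkUserInterrupt();
    if (profile) tmark = tclk();
    for (int i : alive_list) reacted[i] = 0;

    // 1. influx injection at the source point
    if (has_influx && influx_counts[step] > 0) {
      for (int k = 0; k < influx_counts[step]; ++k) {
        if (w.n >= cap) stop("influx capacity exceeded (internal)");
        int i = w.n++;
        w.type[i] = influx_type; w.state[i] = 0; w.alive[i] = 1;
        w.left[i] = w.right[i] = -1; w.anchored[i] = 0; w.nbonds[i] = 0;
        for (int s = 0; s < w.maxS; ++s) {
          w.bondp[(size_t)w.maxS * i + s] = -1;
          w.bonds[(size_t)w.maxS * i + s] = -1;
        }
        for (int d = 0; d < 3; ++d) w.pos[3 * (size_t)i + d] = influx_pos[d];
        add_alive(i);
        influx_added++;
      }
    }

    // 2. diffusion (cluster-wise) + boundaries
    ++vtick;
    for (int i : alive_list) {
      if (visited[i] == vtick) continue;
      if (w.nbonds[i] == 0) {
        visited[i] = vtick;
        bool mob = m.mobile[w.type[i]] && !w.anchored[i];
        double Dp = m.D[w.type[i]];
        double* x = &w.pos[3 * (size_t)i];
        double op[3] = {x[0], x[1], x[2]};
        if (mob && Dp > 0) {
          double sd = std::sqrt(2 * Dp * dt);
          for (int d = 0; d < 3; ++d) x[d] += sd * fast_norm();
        }
        bool absorbable = w.left[i] < 0;  // free singleton
        if (boundary_particle(m, w, i, op, mob ? Dp : 0.0, dt, absorbable)) {
          w.alive[i] = 0; absorbed[w.type[i]]++; deaths.push_back(i);
        }
      } else {
        cluster_of(w, i, members, stamp, ++tick);
        bool anch = false; double Dmin = 1e30;
        for (int q : members) {
          visited[q] = vtick;
          if (w.anchored[q] || !m.mobile[w.type[q]]) anch = true;
          Dmin = std::min(Dmin, m.D[w.type[q]]);
        }
        if (!anch && Dmin > 0) {
          double sd = std::sqrt(2 * Dmin * dt);
          double dx[3] = {sd * fast_norm(), sd * fast_norm(), sd * fast_norm()};
          for (int q : members)
            for (int d = 0; d < 3; ++d) w.pos[3 * (size_t)q + d] += dx[d];
          // boundary: cluster members share a position; reflect via the first
          double op[3] = {w.pos[3 * (size_t)members[0]] - dx[0],
                          w.pos[3 * (size_t)members[0] + 1] - dx[1],
                          w.pos[3 * (size_t)members[0] + 2] - dx[2]};
          (void)op;
          reflect_into_box(m, &w.pos[3 * (size_t)members[0]]);
          for (size_t k = 1; k < members.size(); ++k)
            for (int d = 0; d < 3; ++d)
              w.pos[3 * (size_t)members[k] + d] =
                  w.pos[3 * (size_t)members[0] + d];
        }
      }
    }

    flush_deaths();
    if (profile) { double tn = tclk(); tim[0] += tn - tmark; tmark = tn; }
    // 3. bimolecular reactions: per-group directional probing
    if (any_o2) {
      double tz0 = profile ? tclk() : 0;
      // (re)build target grids; immobile types keep their one-time grid
      for (int t = 0; t < m.T; ++t) {
        if (!target_needed[t]) continue;
        if (!m.mobile[t] && static_built[t]) continue;
        for (int c : tocc[t]) thead[t][c] = -1;
        tocc[t].clear();
      }
      for (int i : alive_list) {
        int t = w.type[i];
        if (!target_needed[t]) continue;
        if (!m.mobile[t] && static_built[t]) continue;
        const std::array<int, 3>& nc = nct[t];
        int cx = std::min(nc[0] - 1,
                          (int)(w.pos[3 * (size_t)i] * inv_cszt[t][0]));
        int cy = std::min(nc[1] - 1,
                          (int)(w.pos[3 * (size_t)i + 1] * inv_cszt[t][1]));
        int cz = std::min(nc[2] - 1,
                          (int)(w.pos[3 * (size_t)i + 2] * inv_cszt[t][2]));
        int c = (cz * nc[1] + cy) * nc[0] + cx;
        if (thead[t][c] < 0) tocc[t].push_back(c);
        cell_next[i] = thead[t][c]; thead[t][c] = i;
      }
      for (int t = 0; t < m.T; ++t)
        if (target_needed[t] && !m.mobile[t]) static_built[t] = 1;
      if (profile) { double tn = tclk(); tsub[0] += tn - tz0; tz0 = tn; }
      // probe in randomized particle order
      perm.clear();
      for (int i : alive_list)
        if (probe_type[w.type[i]]) perm.push_back(i);
      for (int k = (int)perm.size() - 1; k > 0; --k) {
        int j = (int)(unif_rand() * (k + 1));
        if (j > k) j = k;
        std::swap(perm[k], perm[j]);
      }
      if (profile) { double tn = tclk(); tsub[1] += tn - tz0; tz0 = tn; }
      auto try_pair = [&](int i, int j) -> bool {
        // i = probing particle, j = candidate from the target grid
        if (reacted[j] || !w.alive[j]) return false;
        int gid = m.pairgroup[w.type[i] * m.T + w.type[j]];
        if (gid < 0) return false;
        const Group& g = m.groups[gid];
        int a = (w.type[i] == g.ta) ? i : j;
        int b = (a == i) ? j : i;
        double d2 = 0;
        for (int d = 0; d < 3; ++d) {
          double dd = w.pos[3 * (size_t)i + d] - w.pos[3 * (size_t)j + d];
          if (m.periodic_axis[d]) {
            if (dd > 0.5 * m.L[d]) dd -= m.L[d];
            if (dd < -0.5 * m.L[d]) dd += m.L[d];
          }
          d2 += dd * dd;
        }
        if (d2 > g.maxr * g.maxr) return false;
        // condition signature -> candidate subset (the hash-table lookup)
        int sig = 0;
        for (int k = 0; k < g.nprobe; ++k) {
          int p = g.p_who[k] ? b : a;
          int bit;
          if (g.p_target[k] == 1) {
            int pp = w.bondp[(size_t)w.maxS * p + g.p_via[k]];
            bit = (pp < 0) ? 0 : getbit(w.state[pp], g.p_site[k]);
          } else if (g.p_target[k] == 2) {
            int lp = w.left[p];
            bit = (lp < 0) ? 0 : getbit(w.state[lp], g.p_site[k]);
          } else {
            bit = getbit(w.state[p], g.p_site[k]);
          }
          sig |= bit << k;
        }
        int sub = g.sig2subset[sig];
        if (sub < 0) return false;
        if (d2 >= g.sub_r2[sub]) return false;
        double u = unif_rand() * g.sub_tot[sub];
        int rid = -1;
        for (int k = g.sub_off[sub]; k < g.sub_off[sub + 1]; ++k) {
          if (u <= g.sub_cum[k]) { rid = g.sub_rule[k]; break; }
        }
        if (rid < 0) rid = g.sub_rule[g.sub_off[sub + 1] - 1];
        do_bind(m, w, a, b, rid, stamp, tick, cl1, cl2);
        ev.add(tnow, m.o2_label[rid], 1, a, b);
        reacted[i] = reacted[j] = 1;
        return true;
      };
      for (int ii = 0; ii < (int)perm.size(); ++ii) {
        int i = perm[ii];
        if (reacted[i]) continue;
        const std::vector<int>& pgs = probe_groups_of_type[w.type[i]];
        for (size_t pg = 0; pg < pgs.size() && !reacted[i]; ++pg) {
          int gi = pgs[pg];
          int tgt = group_target[gi];
          const std::array<int, 3>& nc = nct[tgt];
          // octant scan: cells are at least twice the binding radius, so the
          // own cell plus the neighbour on the closer side per axis covers
          // every candidate within range
          int cc[3], sd2[3];
          for (int d = 0; d < 3; ++d) {
            double u = w.pos[3 * (size_t)i + d] * inv_cszt[tgt][d];
            int cd = std::min(nc[d] - 1, (int)u);
            cc[d] = cd;
            sd2[d] = (u - cd < 0.5) ? -1 : 1;
          }
          for (int bz = 0; bz < 2 && !reacted[i]; ++bz)
          for (int by = 0; by < 2 && !reacted[i]; ++by)
          for (int bx = 0; bx < 2 && !reacted[i]; ++bx) {
            int ex = cc[0] + bx * sd2[0], ey = cc[1] + by * sd2[1],
                ez = cc[2] + bz * sd2[2];
            if (m.periodic_axis[0]) ex = (ex + nc[0]) % nc[0];
            if (m.periodic_axis[1]) ey = (ey + nc[1]) % nc[1];
            if (m.periodic_axis[2]) ez = (ez + nc[2]) % nc[2];
            if (ex < 0 || ex >= nc[0] || ey < 0 || ey >= nc[1] ||
                ez < 0 || ez >= nc[2]) continue;
            int c = (ez * nc[1] + ey) * nc[0] + ex;
            for (int j = thead[tgt][c]; j >= 0; j = cell_next[j]) {
              if (try_pair(i, j)) break;
            }
          }
        }
      }
      if (profile) tsub[2] += tclk() - tz0;
    }

    if (profile) { double tn = tclk(); tim[1] += tn - tmark; tmark = tn; }
    // 4. first-order reactions
    for (int i : alive_list) {
      if (reacted[i]) continue;
      const std::vector<int>& rl = m.o1_of_type[w.type[i]];
      if (rl.empty()) continue;
      double ktot = 0;
      for (int rid : rl) {
        const O1Rule& r = m.o1[rid];
        if (r.rate > 0 && eval_conds(w, r.conds, i)) ktot += r.rate;
      }
      if (ktot <= 0) continue;
      if (unif_rand() >= 1.0 - std::exp(-ktot * dt)) continue;
      double u = unif_rand() * ktot, acc = 0;
      int chosen = -1;
      for (int rid : rl) {
        const O1Rule& r = m.o1[rid];
        if (r.rate > 0 && eval_conds(w, r.conds, i)) {
          acc += r.rate;
          if (u <= acc) { chosen = rid; break; }
        }
      }
      if (chosen < 0) continue;
      const O1Rule& r = m.o1[chosen];
      if (r.kind == 0) {
        setbit(w.state[i], r.site, r.val);
        ev.add(tnow, r.label, r.dir, i, -1);
      } else if (r.kind == 1) {
        int j = w.bondp[(size_t)w.maxS * i + r.site];
        do_unbind(m, w, i, r, stamp, tick, cl1);
        ev.add(tnow, r.label, r.dir, i, j);
        if (j >= 0) reacted[j] = 1;
      } else {
        if (w.nbonds[i] > 0) stop("removal of a bonded particle (rule error)");
        w.alive[i] = 0; removed[w.type[i]]++; deaths.push_back(i);
        ev.add(tnow, r.label, r.dir, i, -1);
      }
      reacted[i] = 1;
    }
    flush_deaths();

    if (profile) { double tn = tclk(); tim[2] += tn - tmark; tmark = tn; }
    // 5. record
    if ((step + 1) % record_every == 0) record(ri++, tnow);
    if (profile) { double tn = tclk(); tim[3] += tn - tmark; }
  }
  if (profile)
    Rprintf("profile: diffusion %.2fs bimolecular %.2fs first-order %.2fs record %.2fs (bi: setup %.2f shuffle %.2f probe %.2f)\n",
            tim[0], tim[1], tim[2], tim[3], tsub[0], tsub[1], tsub[2]);

  List ledger = List::create(
      _["influx_added"] = (double)influx_added,
      _["absorbed"] = IntegerVector(absorbed.begin(), absorbed.end()),
      _["removed"] = IntegerVector(removed.begin(), removed.end()));
  List events = List::create(
      _["time"] = NumericVector(ev.t.begin(), ev.t.end()),
      _["label"] = IntegerVector(ev.label.begin(), ev.label.end()),
      _["dir"] = IntegerVector(ev.dir.begin(), ev.dir.end()),
      _["p1"] = IntegerVector(ev.p1.begin(), ev.p1.end()),
      _["p2"] = IntegerVector(ev.p2.begin(), ev.p2.end()));
  return List::create(_["times"] = rec_times, _["counts"] = counts,
                      _["events"] = events, _["state"] = world_to_list(w),
                      _["ledger"] = ledger);
}

// ---------------------------------------------------------------------------
// Well-mixed SSA over the same compiled rule set (network-free: propensities
// are products of per-side match counts maintained incrementally; no species
// enumeration).

namespace {

struct MatchList {
  int type;
  std::vector<Cond> conds;
  std::vector<int> members;
  std::vector<int> posof;   // particle -> index in members, -1
  void init(int cap) { posof.assign(cap, -1); }
  void sync(const World& w, int p) {
    bool want = w.alive[p] && w.type[p] == type && eval_conds(w, conds, p);
    bool have = posof[p] >= 0;
    if (want && !have) {
      posof[p] = (int)members.size();
      members.push_back(p);
    } else if (!want && have) {
      int idx = posof[p], last = (int)members.size() - 1;
      members[idx] = members[last];
      posof[members[idx]] = idx;
      members.pop_back();
      posof[p] = -1;
    }
  }
  int pick() const {
    int k = (int)(unif_rand() * members.size());
    if (k >= (int)members.size()) k = (int)members.size() - 1;
    return members[k];
  }
};

}  // namespace

// [[Rcpp::export]]
List ssa_run(List cm, List st, List simp) {
  Model m = read_model(cm);
  double t_end = as<double>(simp["t_end"]);
  double rec_dt = as<double>(simp["rec_dt"]);
  double volume = as<double>(simp["volume"]);
  NumericVector pulse_t = simp["pulse_t"];
  IntegerVector pulse_n = simp["pulse_n"];
  int pulse_type = as<int>(simp["pulse_type"]);
  bool collect_events = as<bool>(simp["collect_events"]);

  IntegerVector ty0 = st["ptype"];
  long total_pulse = 0;
  for (int i = 0; i < pulse_n.size(); ++i) total_pulse += pulse_n[i];
  int cap = ty0.size() + (int)total_pulse;
  World w = read_world(st, cap, m.maxS);

  int nO2 = (int)m.o2_kv.size();
  int nO1 = (int)m.o1.size();
  int nobs = (int)m.obs_type.size();

  // build match lists: 2 per order-2 rule (sides), 1 per order-1, 1 per obs
  std::vector<MatchList> lists(2 * nO2 + nO1 + nobs);
  {
    // per-rule side conditions are passed explicitly by the R compiler
    // (the SSA needs per-side match sets, not collision signatures)
    IntegerVector aoff = cm["o2A_coff"];
    IntegerVector atgt = cm["a_target"], avia = cm["a_via"], asite = cm["a_site"],
                  aval = cm["a_val"];
    IntegerVector boff = cm["o2B_coff"];
    IntegerVector btgt = cm["b_target"], bvia = cm["b_via"], bsite = cm["b_site"],
                  bval = cm["b_val"];
    IntegerVector o2ta = cm["o2_ta"], o2tb = cm["o2_tb"];
    for (int r = 0; r < nO2; ++r) {
      lists[2 * r].type = o2ta[r];
      for (int k = aoff[r]; k < aoff[r + 1]; ++k)
        lists[2 * r].conds.push_back(Cond{atgt[k], avia[k], asite[k], aval[k]});
      lists[2 * r + 1].type = o2tb[r];
      for (int k = boff[r]; k < boff[r + 1]; ++k)
        lists[2 * r + 1].conds.push_back(Cond{btgt[k], bvia[k], bsite[k], bval[k]});
    }
    IntegerVector own = cm["o1_owner"];
    for (int r = 0; r < nO1; ++r) {
      lists[2 * nO2 + r].type = own[r];
      lists[2 * nO2 + r].conds = m.o1[r].conds;
    }
    for (int o = 0; o < nobs; ++o) {
      lists[2 * nO2 + nO1 + o].type = m.obs_type[o];
      lists[2 * nO2 + nO1 + o].conds = m.obs_conds[o];
    }
  }
  std::vector<std::vector<int>> lists_of_type(m.T);
  for (size_t l = 0; l < lists.size(); ++l) {
    lists[l].init(cap);
    lists_of_type[lists[l].type].push_back((int)l);
  }
  std::vector<long> type_count(m.T, 0);
  auto refresh = [&](int p) {
    for (int l : lists_of_type[w.type[p]]) lists[l].sync(w, p);
  };
  for (int i = 0; i < w.n; ++i) {
    if (w.alive[i]) type_count[w.type[i]]++;
    refresh(i);
  }
  auto touch_neighbors = [&](int p, std::vector<int>& aff) {
    aff.push_back(p);
    for (int s = 0; s < w.maxS; ++s) {
      int q = w.bondp[(size_t)w.maxS * p + s];
      if (q >= 0) aff.push_back(q);
    }
    if (w.right[p] >= 0) aff.push_back(w.right[p]);
  };

  int nrec = (int)std::floor(t_end / rec_dt + 1e-9) + 1;
  IntegerMatrix counts(nrec, nobs + m.T);
  NumericVector rec_times(nrec);
  EventLog ev; ev.collect = collect_events;
  std::vector<long> removed(m.T, 0);
  long injected = 0;

  auto record = [&](int ri, double tnow) {
    rec_times[ri] = tnow;
    for (int o = 0; o < nobs; ++o)
      counts(ri, o) = (int)lists[2 * nO2 + nO1 + o].members.size();
    for (int t = 0; t < m.T; ++t) counts(ri, nobs + t) = (int)type_count[t];
  };

  double t = 0;
  int ri = 0, pi = 0;
  record(ri++, 0.0);
  double next_rec = rec_dt;
  long nevents = 0;

  while (t < t_end) {
    if ((++nevents & 0x3FFF) == 0) Rcpp::checkUserInterrupt();
    // propensities
    double a0 = 0;
    for (int r = 0; r < nO2; ++r)
      a0 += m.o2_kv[r] / volume * lists[2 * r].members.size() *
            lists[2 * r + 1].members.size();
    for (int r = 0; r < nO1; ++r)
      a0 += m.o1[r].rate * lists[2 * nO2 + r].members.size();
    double tnext = (a0 > 0) ? t + exp_rand() / a0 : t_end + 1;
    double boundary = std::min(t_end, next_rec);
    if (pi < pulse_t.size()) boundary = std::min(boundary, (double)pulse_t[pi]);
    if (tnext > boundary) {
      t = boundary;
      if (pi < pulse_t.size() && boundary == (double)pulse_t[pi]) {
        for (int k = 0; k < pulse_n[pi]; ++k) {
          int i = w.n++;
          if (i >= cap) stop("pulse capacity exceeded");
          w.type[i] = pulse_type; w.state[i] = 0; w.alive[i] = 1;
          w.left[i] = w.right[i] = -1; w.anchored[i] = 0; w.nbonds[i] = 0;
          for (int s = 0; s < w.maxS; ++s) {
            w.bondp[(size_t)w.maxS * i + s] = -1;
            w.bonds[(size_t)w.maxS * i + s] = -1;
          }
          type_count[pulse_type]++;
          refresh(i);
          injected++;
        }
        pi++;
        continue;
      }
      if (t >= next_rec - 1e-12 && ri < nrec) {
        record(ri++, next_rec);
        next_rec += rec_dt;
        continue;
      }
      if (t >= t_end) break;
      continue;
    }
    t = tnext;
    // select the reaction channel
    double u = unif_rand() * a0, acc = 0;
    int rsel = -1; bool is_o2 = true;
    for (int r = 0; r < nO2; ++r) {
      acc += m.o2_kv[r] / volume * lists[2 * r].members.size() *
             lists[2 * r + 1].members.size();
      if (u <= acc) { rsel = r; break; }
    }
    if (rsel < 0) {
      is_o2 = false;
      for (int r = 0; r < nO1; ++r) {
        acc += m.o1[r].rate * lists[2 * nO2 + r].members.size();
        if (u <= acc) { rsel = r; break; }
      }
    }
    if (rsel < 0) continue;
    std::vector<int> aff;
    if (is_o2) {
      int a = lists[2 * rsel].pick();
      int b = lists[2 * rsel + 1].pick();
      int sA = m.o2_bsA[rsel], sB = m.o2_bsB[rsel];
      w.bondp[(size_t)w.maxS * a + sA] = b; w.bonds[(size_t)w.maxS * a + sA] = sB;
      w.bondp[(size_t)w.maxS * b + sB] = a; w.bonds[(size_t)w.maxS * b + sB] = sA;
      setbit(w.state[a], sA, 1); setbit(w.state[b], sB, 1);
      w.nbonds[a]++; w.nbonds[b]++;
      ev.add(t, m.o2_label[rsel], 1, a, b);
      touch_neighbors(a, aff); touch_neighbors(b, aff);
    } else {
      const O1Rule& r = m.o1[rsel];
      int i = lists[2 * nO2 + rsel].pick();
      if (r.kind == 0) {
        setbit(w.state[i], r.site, r.val);
        ev.add(t, r.label, r.dir, i, -1);
        touch_neighbors(i, aff);
      } else if (r.kind == 1) {
        int j = w.bondp[(size_t)w.maxS * i + r.site];
        if (j < 0) stop("unbind on free site (ssa internal)");
        int js = w.bonds[(size_t)w.maxS * i + r.site];
        touch_neighbors(i, aff); touch_neighbors(j, aff);
        w.bondp[(size_t)w.maxS * i + r.site] = -1;
        w.bonds[(size_t)w.maxS * i + r.site] = -1;
        w.bondp[(size_t)w.maxS * j + js] = -1;
        w.bonds[(size_t)w.maxS * j + js] = -1;
        setbit(w.state[i], r.site, 0); setbit(w.state[j], js, 0);
        w.nbonds[i]--; w.nbonds[j]--;
        ev.add(t, r.label, r.dir, i, j);
      } else {
        if (w.nbonds[i] > 0) stop("removal of a bonded particle (rule error)");
        touch_neighbors(i, aff);
        w.alive[i] = 0; removed[w.type[i]]++;
        type_count[w.type[i]]--;
        ev.add(t, r.label, r.dir, i, -1);
      }
    }
    for (int p : aff) refresh(p);
  }
  while (ri < nrec) { record(ri, next_rec); ri++; next_rec += rec_dt; }

  List ledger = List::create(
      _["influx_added"] = (double)injected,
      _["absorbed"] = IntegerVector(m.T, 0),
      _["removed"] = IntegerVector(removed.begin(), removed.end()));
  List events = List::create(
      _["time"] = NumericVector(ev.t.begin(), ev.t.end()),
      _["label"] = IntegerVector(ev.label.begin(), ev.label.end()),
      _["dir"] = IntegerVector(ev.dir.begin(), ev.dir.end()),
      _["p1"] = IntegerVector(ev.p1.begin(), ev.p1.end()),
      _["p2"] = IntegerVector(ev.p2.begin(), ev.p2.end()));
  return List::create(_["times"] = rec_times, _["counts"] = counts,
                      _["events"] = events, _["state"] = world_to_list(w),
                      _["ledger"] = ledger);
}
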