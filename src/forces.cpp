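// Elastic network forces for the triangulated cell surface.
//
// Energy terms: linear stretching springs on edges (septin-ring edges use a
// rest-length-scaled coefficient, folded into the per-edge coefficient on
// the R side), cosine bending on hinges, harmonic area resistance on faces,
// Morse self-avoidance between non-connected vertex pairs, plus the turgor
// pressure force lumped to vertices. Dihedral-angle gradients follow the
// standard hinge formulas (Bridson et al. 2003).
//
// The Morse term uses a spatial hash grid to collect candidate pairs; the
// relaxation loop refreshes the candidate list only after vertices have
// accumulated enough displacement to possibly change it.

#include <Rcpp.h>
#include <unordered_map>
#include <unordered_set>
#include <cmath>
#include <vector>
#include <utility>
using namespace Rcpp;

static inline void cross3(const double* a, const double* b, double* out) {
  out[0] = a[1] * b[2] - a[2] * b[1];
  out[1] = a[2] * b[0] - a[0] * b[2];
  out[2] = a[0] * b[1] - a[1] * b[0];
}
static inline double dot3(const double* a, const double* b) {
  return a[0] * b[0] + a[1] * b[1] + a[2] * b[2];
}
static inline double norm3(const double* a) { return std::sqrt(dot3(a, a)); }

struct MeshView {
  int n, m, ne;
  const double* V; // column-major n x 3
  const int* F;    // column-major m x 3, 1-based
  const int* E;    // ne x 2, 1-based, E[,1] < E[,2]
  const int* EO;   // ne x 2 opposite vertices, 1-based
};

static inline void getv(const MeshView& mv, int i, double* out) {
  out[0] = mv.V[i];
  out[1] = mv.V[i + mv.n];
  out[2] = mv.V[i + 2 * mv.n];
}

static std::unordered_set<long long> build_adjacency(const MeshView& mv) {
  std::unordered_set<long long> adj;
  adj.reserve(2 * mv.ne);
  for (int e = 0; e < mv.ne; ++e) {
    long long i = mv.E[e] - 1, j = mv.E[e + mv.ne] - 1;
    adj.insert(i * (long long)mv.n + j);
  }
  return adj;
}

// non-adjacent vertex pairs within `range` (spatial hash grid, cell = range)
static void build_morse_pairs(const MeshView& mv,
                              const std::unordered_set<long long>& adj,
                              double range,
                              std::vector<std::pair<int, int> >& pairs) {
  pairs.clear();
  const int n = mv.n;
  double lo[3] = {R_PosInf, R_PosInf, R_PosInf};
  for (int i = 0; i < n; ++i)
    for (int d3 = 0; d3 < 3; ++d3)
      if (mv.V[i + d3 * n] < lo[d3]) lo[d3] = mv.V[i + d3 * n];
  std::unordered_map<long long, std::vector<int> > grid;
  grid.reserve(n);
  const long long B = 1 << 20;
  auto cell_of = [&](int i, int* cc) {
    for (int d3 = 0; d3 < 3; ++d3)
      cc[d3] = (int)std::floor((mv.V[i + d3 * n] - lo[d3]) / range);
  };
  for (int i = 0; i < n; ++i) {
    int cc[3];
    cell_of(i, cc);
    grid[(cc[0] * B + cc[1]) * B + cc[2]].push_back(i);
  }
  double r2 = range * range;
  for (int i = 0; i < n; ++i) {
    int cc[3];
    cell_of(i, cc);
    double pi[3];
    getv(mv, i, pi);
    for (int dx = -1; dx <= 1; ++dx)
      for (int dy = -1; dy <= 1; ++dy)
        for (int dz = -1; dz <= 1; ++dz) {
          long long key = ((long long)(cc[0] + dx) * B + (cc[1] + dy)) * B + (cc[2] + dz);
          std::unordered_map<long long, std::vector<int> >::iterator it = grid.find(key);
          if (it == grid.end()) continue;
          for (size_t t = 0; t < it->second.size(); ++t) {
            int j = it->second[t];
            if (j <= i) continue;
            if (adj.count((long long)i * n + j) || adj.count((long long)j * n + i))
              continue;
            double pj[3];
            getv(mv, j, pj);
            double d[3] = {pj[0] - pi[0], pj[1] - pi[1], pj[2] - pi[2]};
            if (dot3(d, d) <= r2) pairs.push_back(std::make_pair(i, j));
          }
        }
  }
}

// Accumulates forces into Fout (n x 3 column-major) and fills energies
// {stretch, bend, area, morse}.
static void accumulate_forces(const MeshView& mv,
                              const double* L0, const double* theta0,
                              const double* A0,
                              const double* ks_edge, const double* kb_edge,
                              const double* ka_face,
                              double Dm, double am, double Lm, double P,
                              const std::vector<std::pair<int, int> >& mpairs,
                              double* Fout, double* energies) {
  const int n = mv.n, m = mv.m, ne = mv.ne;
  double e_stretch = 0, e_bend = 0, e_area = 0, e_morse = 0;
  std::fill(Fout, Fout + 3 * (size_t)n, 0.0);

  // --- per-face: area resistance + turgor ---------------------------------
  for (int f = 0; f < m; ++f) {
    int i0 = mv.F[f] - 1, i1 = mv.F[f + m] - 1, i2 = mv.F[f + 2 * m] - 1;
    double p0[3], p1[3], p2[3];
    getv(mv, i0, p0); getv(mv, i1, p1); getv(mv, i2, p2);
    double e1[3] = {p1[0] - p0[0], p1[1] - p0[1], p1[2] - p0[2]};
    double e2[3] = {p2[0] - p0[0], p2[1] - p0[1], p2[2] - p0[2]};
    double N[3];
    cross3(e1, e2, N);
    double nn = norm3(N);
    double A = 0.5 * nn;
    if (A <= 0 || !std::isfinite(A)) continue;
    double nhat[3] = {N[0] / nn, N[1] / nn, N[2] / nn};
    double dA = A - A0[f];
    e_area += 0.5 * ka_face[f] / A0[f] * dA * dA;
    double dEdA = ka_face[f] * dA / A0[f];
    int idx[3] = {i0, i1, i2};
    double* pts[3] = {p0, p1, p2};
    for (int c = 0; c < 3; ++c) {
      int j = (c + 1) % 3, k = (c + 2) % 3;
      double d[3] = {pts[k][0] - pts[j][0], pts[k][1] - pts[j][1], pts[k][2] - pts[j][2]};
      double g[3];
      cross3(nhat, d, g);
      for (int d3 = 0; d3 < 3; ++d3)
        Fout[idx[c] + d3 * n] += -dEdA * 0.5 * g[d3] + P * N[d3] / 6.0;
    }
  }

  // --- stretching springs --------------------------------------------------
  for (int e = 0; e < ne; ++e) {
    int i = mv.E[e] - 1, j = mv.E[e + ne] - 1;
    double pi[3], pj[3];
    getv(mv, i, pi); getv(mv, j, pj);
    double d[3] = {pj[0] - pi[0], pj[1] - pi[1], pj[2] - pi[2]};
    double L = norm3(d);
    double dL = L - L0[e];
    e_stretch += 0.5 * ks_edge[e] * dL * dL;
    if (L > 0) {
      double fmag = ks_edge[e] * dL / L;
      for (int d3 = 0; d3 < 3; ++d3) {
        Fout[i + d3 * n] += fmag * d[d3];
        Fout[j + d3 * n] -= fmag * d[d3];
      }
    }
  }

  // --- bending hinges ------------------------------------------------------
  for (int e = 0; e < ne; ++e) {
    if (kb_edge[e] == 0) continue;
    if (mv.EO[e + ne] <= 0) continue;  // boundary edge: no hinge
    int p0i = mv.E[e] - 1, p1i = mv.E[e + ne] - 1;
    int q1i = mv.EO[e] - 1, q2i = mv.EO[e + ne] - 1;
    double p0[3], p1[3], q1[3], q2[3];
    getv(mv, p0i, p0); getv(mv, p1i, p1); getv(mv, q1i, q1); getv(mv, q2i, q2);
    double ev[3] = {p1[0] - p0[0], p1[1] - p0[1], p1[2] - p0[2]};
    double l = norm3(ev);
    if (l <= 0) continue;
    double ehat[3] = {ev[0] / l, ev[1] / l, ev[2] / l};
    double a1[3] = {q1[0] - p0[0], q1[1] - p0[1], q1[2] - p0[2]};
    double b1[3] = {q1[0] - p1[0], q1[1] - p1[1], q1[2] - p1[2]};
    double a2[3] = {q2[0] - p1[0], q2[1] - p1[1], q2[2] - p1[2]};
    double b2[3] = {q2[0] - p0[0], q2[1] - p0[1], q2[2] - p0[2]};
    double N1[3], N2[3];
    cross3(a1, b1, N1); // outward for face (p0,p1,q1)
    cross3(a2, b2, N2); // outward for face (p1,p0,q2)
    double n1n = norm3(N1), n2n = norm3(N2);
    if (n1n <= 0 || n2n <= 0) continue;
    double n1h[3] = {N1[0] / n1n, N1[1] / n1n, N1[2] / n1n};
    double n2h[3] = {N2[0] / n2n, N2[1] / n2n, N2[2] / n2n};
    double cx[3];
    cross3(n2h, n1h, cx);
    double s = dot3(cx, ehat);
    double c = dot3(n1h, n2h);
    double theta_s = std::atan2(s, c);      // signed dihedral
    double theta = std::fabs(theta_s);      // unsigned angle between normals
    e_bend += kb_edge[e] * (1.0 - std::cos(theta - theta0[e]));
    double sgn = (theta_s >= 0) ? 1.0 : -1.0;
    double dEdth = kb_edge[e] * std::sin(theta - theta0[e]) * sgn;
    if (dEdth == 0) continue;
    double inv1 = 1.0 / (n1n * n1n), inv2 = 1.0 / (n2n * n2n);
    double c11 = dot3(a1, ehat);  // (q1 - p0) . ehat
    double c12 = dot3(b1, ehat);  // (q1 - p1) . ehat
    double c21 = dot3(b2, ehat);  // (q2 - p0) . ehat
    double c22 = dot3(a2, ehat);  // (q2 - p1) . ehat
    for (int d3 = 0; d3 < 3; ++d3) {
      double g1 = l * N1[d3] * inv1;
      double g2 = l * N2[d3] * inv2;
      Fout[q1i + d3 * n] -= dEdth * g1;
      Fout[q2i + d3 * n] -= dEdth * g2;
      Fout[p0i + d3 * n] -= dEdth * (c12 * N1[d3] * inv1 + c22 * N2[d3] * inv2);
      Fout[p1i + d3 * n] -= dEdth * (-c11 * N1[d3] * inv1 - c21 * N2[d3] * inv2);
    }
  }

  // --- Morse self-avoidance over the candidate pair list -------------------
  if (Dm > 0 && Lm > 0) {
    for (size_t t = 0; t < mpairs.size(); ++t) {
      int i = mpairs[t].first, j = mpairs[t].second;
      double pi[3], pj[3];
      getv(mv, i, pi); getv(mv, j, pj);
      double d[3] = {pj[0] - pi[0], pj[1] - pi[1], pj[2] - pi[2]};
      double L = norm3(d);
      if (L > Lm || L <= 0) continue;
      double ex = std::exp(-am * (L - Lm));
      double one = 1.0 - ex;
      e_morse += Dm * one * one;
      double dEdL = 2.0 * Dm * one * am * ex;
      double fmag = dEdL / L;
      for (int d3 = 0; d3 < 3; ++d3) {
        Fout[i + d3 * n] += fmag * d[d3];
        Fout[j + d3 * n] -= fmag * d[d3];
      }
    }
  }

  energies[0] = e_stretch;
  energies[1] = e_bend;
  energies[2] = e_area;
  energies[3] = e_morse;
}

static MeshView make_view(const NumericMatrix& V, const IntegerMatrix& F,
                          const IntegerMatrix& E, const IntegerMatrix& EO) {
  MeshView mv;
  mv.n = V.nrow(); mv.m = F.nrow(); mv.ne = E.nrow();
  mv.V = V.begin(); mv.F = F.begin(); mv.E = E.begin();
  mv.EO = EO.begin();
  return mv;
}

// [[Rcpp::export(name = ".bm_forces")]]
List bm_forces(NumericMatrix V, IntegerMatrix F, IntegerMatrix E,
               IntegerMatrix EF, IntegerMatrix EO,
               NumericVector L0, NumericVector theta0, NumericVector A0,
               NumericVector ks_edge, NumericVector kb_edge, NumericVector ka_face,
               double Dm, double am, double Lm, double P) {
  MeshView mv = make_view(V, F, E, EO);
  NumericMatrix Fout(mv.n, 3);
  double energies[4];
  std::vector<std::pair<int, int> > mpairs;
  if (Dm > 0 && Lm > 0) {
    std::unordered_set<long long> adj = build_adjacency(mv);
    build_morse_pairs(mv, adj, Lm, mpairs);
  }
  accumulate_forces(mv, L0.begin(), theta0.begin(), A0.begin(),
                    ks_edge.begin(), kb_edge.begin(), ka_face.begin(),
                    Dm, am, Lm, P, mpairs, Fout.begin(), energies);
  return List::create(
    _["force"] = Fout,
    _["e_stretch"] = energies[0], _["e_bend"] = energies[1],
    _["e_area"] = energies[2], _["e_morse"] = energies[3]);
}

// Forward-Euler overdamped relaxation: x <- x + (dt/c) * F until the
// maximum vertex force magnitude drops below ftol or max_steps is reached.
// The Morse candidate list is refreshed once accumulated motion could
// bring unseen pairs into range (margin 0.3 * Lm on the search radius).
// [[Rcpp::export(name = ".bm_relax")]]
List bm_relax(NumericMatrix V, IntegerMatrix F, IntegerMatrix E,
              IntegerMatrix EF, IntegerMatrix EO,
              NumericVector L0, NumericVector theta0, NumericVector A0,
              NumericVector ks_edge, NumericVector kb_edge, NumericVector ka_face,
              double Dm, double am, double Lm, double P,
              double c, double dt, int max_steps, double ftol,
              double dmax) {
  MeshView mv = make_view(V, F, E, EO);
  NumericMatrix Vw = clone(V);
  mv.V = Vw.begin();
  std::vector<double> Fbuf(3 * (size_t)mv.n);
  double energies[4] = {0, 0, 0, 0};
  int steps = 0;
  bool converged = false, finite = true;
  double fmax = R_PosInf;
  bool use_morse = (Dm > 0 && Lm > 0);
  std::unordered_set<long long> adj;
  std::vector<std::pair<int, int> > mpairs;
  double margin = 0.3 * Lm, moved = 0.0;
  if (use_morse) {
    adj = build_adjacency(mv);
    build_morse_pairs(mv, adj, Lm + margin, mpairs);
  }
  while (steps < max_steps) {
    if (use_morse && moved > margin / 2) {
      build_morse_pairs(mv, adj, Lm + margin, mpairs);
      moved = 0.0;
    }
    accumulate_forces(mv, L0.begin(), theta0.begin(), A0.begin(),
                      ks_edge.begin(), kb_edge.begin(), ka_face.begin(),
                      Dm, am, Lm, P, mpairs, Fbuf.data(), energies);
    fmax = 0;
    for (int i = 0; i < mv.n; ++i) {
      double f2 = Fbuf[i] * Fbuf[i] + Fbuf[i + mv.n] * Fbuf[i + mv.n] +
                  Fbuf[i + 2 * mv.n] * Fbuf[i + 2 * mv.n];
      if (f2 > fmax) fmax = f2;
    }
    fmax = std::sqrt(fmax);
    if (!std::isfinite(fmax)) { finite = false; break; }
    if (fmax < ftol) { converged = true; break; }
    double sc = dt / c;
    // trust-region cap: no vertex moves more than dmax per step, which
    // keeps stiff refined elements stable under the explicit update
    if (sc * fmax > dmax) sc = dmax / fmax;
    for (size_t k = 0; k < Fbuf.size(); ++k) Vw[k] += sc * Fbuf[k];
    moved += sc * fmax;
    ++steps;
    for (int i = 0; i < mv.n && finite; ++i)
      for (int d3 = 0; d3 < 3; ++d3)
        if (!std::isfinite(Vw(i, d3))) finite = false;
    if (!finite) break;
  }
  return List::create(
    _["V"] = Vw, _["steps"] = steps, _["converged"] = converged,
    _["finite"] = finite, _["fmax"] = fmax,
    _["e_stretch"] = energies[0], _["e_bend"] = energies[1],
    _["e_area"] = energies[2], _["e_morse"] = energies[3]);
}
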