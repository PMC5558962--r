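// Monodomain reaction-diffusion core: forward-Euler integration of the
// four-variable minimal ventricular model coupled by an anisotropic,
// spatially varying diffusion tensor on a regular node-centred grid.
//
// The divergence term is discretised in conservative flux form: fluxes are
// evaluated on cell faces from face-averaged tensor components, normal
// derivatives as two-point differences and transverse derivatives as the
// mean of the central differences at the two adjacent nodes (one-sided at
// grid boundaries). Boundary faces carry zero flux (isolating Neumann
// boundary), so the discrete integral of u is conserved to round-off when
// the reaction term is off.

#include <Rcpp.h>
#include <cmath>
#include <vector>

using namespace Rcpp;

// Column order of the parameter matrix; must match .mv_param_names in R.
enum ParCol {
  P_u_o = 0, P_u_u, P_theta_v, P_theta_w, P_theta_vminus, P_theta_o,
  P_tau_v1minus, P_tau_v2minus, P_tau_vplus,
  P_tau_w1minus, P_tau_w2minus, P_k_wminus, P_u_wminus, P_tau_wplus,
  P_tau_fi, P_tau_o1, P_tau_o2, P_tau_so1, P_tau_so2, P_k_so, P_u_so,
  P_tau_s1, P_tau_s2, P_k_s, P_u_s, P_tau_si, P_tau_winf, P_w_inf_star,
  P_NCOL
};

static inline double heav(double x) { return x >= 0.0 ? 1.0 : 0.0; }

struct Grid {
  int nx, ny, nz;
  double ds;
  inline int idx(int i, int j, int k) const { return i + nx * (j + ny * k); }
};

// one-sided/central derivative of u along each axis at node (i,j,k)
static inline double d_dx(const double* u, const Grid& g, int i, int j, int k) {
  if (g.nx == 1) return 0.0;
  const int n = g.idx(i, j, k);
  if (i == 0) return (u[n + 1] - u[n]) / g.ds;
  if (i == g.nx - 1) return (u[n] - u[n - 1]) / g.ds;
  return (u[n + 1] - u[n - 1]) / (2.0 * g.ds);
}
static inline double d_dy(const double* u, const Grid& g, int i, int j, int k) {
  if (g.ny == 1) return 0.0;
  const int n = g.idx(i, j, k), s = g.nx;
  if (j == 0) return (u[n + s] - u[n]) / g.ds;
  if (j == g.ny - 1) return (u[n] - u[n - s]) / g.ds;
  return (u[n + s] - u[n - s]) / (2.0 * g.ds);
}
static inline double d_dz(const double* u, const Grid& g, int i, int j, int k) {
  if (g.nz == 1) return 0.0;
  const int n = g.idx(i, j, k), s = g.nx * g.ny;
  if (k == 0) return (u[n + s] - u[n]) / g.ds;
  if (k == g.nz - 1) return (u[n] - u[n - s]) / g.ds;
  return (u[n + s] - u[n - s]) / (2.0 * g.ds);
}

// Precomputed faces of one orientation: node pair (a, b) and the
// face-averaged tensor components (normal, cross1, cross2) already divided
// by ds^2 (normal) or ds (cross, which multiplies a transverse derivative).
struct Face {
  int a, b, ia, ja, ka; // ia..ka: grid coordinates of node a
  double dn, dc1, dc2;
};

static void build_faces(const NumericMatrix& tens, const Grid& g, int axis,
                        std::vector<Face>& faces, bool& any_cross) {
  faces.clear();
  any_cross = false;
  const int ncol_n = axis;                    // xx, yy, zz
  const int ncol_c1 = axis == 0 ? 3 : (axis == 1 ? 3 : 4); // xy, xy, xz
  const int ncol_c2 = axis == 0 ? 4 : (axis == 1 ? 5 : 5); // xz, yz, yz
  const int ni = axis == 0 ? g.nx - 1 : g.nx;
  const int nj = axis == 1 ? g.ny - 1 : g.ny;
  const int nk = axis == 2 ? g.nz - 1 : g.nz;
  const double inv_ds2 = 1.0 / (g.ds * g.ds), inv_ds = 1.0 / g.ds;
  for (int k = 0; k < nk; ++k)
    for (int j = 0; j < nj; ++j)
      for (int i = 0; i < ni; ++i) {
        Face f;
        f.ia = i; f.ja = j; f.ka = k;
        f.a = g.idx(i, j, k);
        f.b = axis == 0 ? g.idx(i + 1, j, k)
            : axis == 1 ? g.idx(i, j + 1, k) : g.idx(i, j, k + 1);
        f.dn = 0.5 * (tens(f.a, ncol_n) + tens(f.b, ncol_n)) * inv_ds2;
        f.dc1 = 0.5 * (tens(f.a, ncol_c1) + tens(f.b, ncol_c1)) * inv_ds;
        f.dc2 = 0.5 * (tens(f.a, ncol_c2) + tens(f.b, ncol_c2)) * inv_ds;
        // cross terms that multiply a derivative along a collapsed
        // dimension vanish identically
        if (axis == 0 && g.ny == 1) f.dc1 = 0.0;
        if ((axis == 0 || axis == 1) && g.nz == 1) { if (axis == 0) f.dc2 = 0.0; else f.dc2 = 0.0; }
        if (axis == 1 && g.nx == 1) f.dc1 = 0.0;
        if (axis == 2 && g.nx == 1) f.dc1 = 0.0;
        if (axis == 2 && g.ny == 1) f.dc2 = 0.0;
        if (f.dc1 != 0.0 || f.dc2 != 0.0) any_cross = true;
        faces.push_back(f);
      }
}

// divergence accumulation for one face orientation
static void apply_faces(const std::vector<Face>& faces, int axis,
                        bool any_cross, const double* u, const Grid& g,
                        double* out) {
  if (!any_cross) {
    for (const Face& f : faces) {
      const double F = f.dn * (u[f.b] - u[f.a]);
      out[f.a] += F;
      out[f.b] -= F;
    }
    return;
  }
  for (const Face& f : faces) {
    double F = f.dn * (u[f.b] - u[f.a]);
    const int i = f.ia, j = f.ja, k = f.ka;
    if (axis == 0) {
      if (f.dc1 != 0.0)
        F += f.dc1 * 0.5 * (d_dy(u, g, i, j, k) + d_dy(u, g, i + 1, j, k));
      if (f.dc2 != 0.0)
        F += f.dc2 * 0.5 * (d_dz(u, g, i, j, k) + d_dz(u, g, i + 1, j, k));
    } else if (axis == 1) {
      if (f.dc1 != 0.0)
        F += f.dc1 * 0.5 * (d_dx(u, g, i, j, k) + d_dx(u, g, i, j + 1, k));
      if (f.dc2 != 0.0)
        F += f.dc2 * 0.5 * (d_dz(u, g, i, j, k) + d_dz(u, g, i, j + 1, k));
    } else {
      if (f.dc1 != 0.0)
        F += f.dc1 * 0.5 * (d_dx(u, g, i, j, k) + d_dx(u, g, i, j, k + 1));
      if (f.dc2 != 0.0)
        F += f.dc2 * 0.5 * (d_dy(u, g, i, j, k) + d_dy(u, g, i, j, k + 1));
    }
    out[f.a] += F;
    out[f.b] -= F;
  }
}

// [[Rcpp::export]]
NumericVector cpp_aniso_div(NumericVector u, IntegerVector dims, double ds,
                            NumericMatrix tensors) {
  Grid g{dims[0], dims[1], dims[2], ds};
  const int N = g.nx * g.ny * g.nz;
  if (u.size() != N || tensors.nrow() != N)
    stop("field/tensor size does not match grid");
  std::vector<double> uf(u.begin(), u.end()), out(N, 0.0);
  std::vector<Face> faces;
  bool any_cross;
  for (int axis = 0; axis < 3; ++axis) {
    if ((axis == 0 && g.nx == 1) || (axis == 1 && g.ny == 1) ||
        (axis == 2 && g.nz == 1))
      continue;
    build_faces(tensors, g, axis, faces, any_cross);
    apply_faces(faces, axis, any_cross, uf.data(), g, out.data());
  }
  return NumericVector(out.begin(), out.end());
}

// lead-field potential: phi = -sum_n grad(V)_n . h_n * ds^3 with
// V = 85.7 u - 84 mV (the offset drops out of the gradient).
static double lead_field_phi(const double* u, const Grid& g,
                             const double* hx, const double* hy,
                             const double* hz) {
  double acc = 0.0;
  for (int k = 0; k < g.nz; ++k)
    for (int j = 0; j < g.ny; ++j)
      for (int i = 0; i < g.nx; ++i) {
        const int n = g.idx(i, j, k);
        acc += d_dx(u, g, i, j, k) * hx[n] + d_dy(u, g, i, j, k) * hy[n] +
               d_dz(u, g, i, j, k) * hz[n];
      }
  return -85.7 * acc * g.ds * g.ds * g.ds;
}

// [[Rcpp::export]]
double cpp_lead_field(NumericVector u, IntegerVector dims, double ds,
                      NumericMatrix h) {
  Grid g{dims[0], dims[1], dims[2], ds};
  const int N = g.nx * g.ny * g.nz;
  if (u.size() != N || h.nrow() != N)
    stop("field/weight size does not match grid");
  std::vector<double> uf(u.begin(), u.end());
  std::vector<double> hx(N), hy(N), hz(N);
  for (int n = 0; n < N; ++n) { hx[n] = h(n, 0); hy[n] = h(n, 1); hz[n] = h(n, 2); }
  return lead_field_phi(uf.data(), g, hx.data(), hy.data(), hz.data());
}

// flat copy of the per-type parameter rows
struct CellPar { double p[P_NCOL]; };

// [[Rcpp::export]]
List cpp_mono_run(NumericVector u0, NumericVector v0, NumericVector w0,
                  NumericVector s0, IntegerVector dims, double ds,
                  NumericMatrix tensors, IntegerVector ctype,
                  NumericMatrix params, IntegerVector stim_nodes,
                  double stim_amp, double stim_dur, NumericVector stim_times,
                  double duration, double dt, IntegerVector trace_nodes,
                  int trace_stride, double act_threshold,
                  Nullable<NumericMatrix> h_epi_, Nullable<NumericMatrix> h_endo_,
                  int ecg_stride, bool reaction_on = true) {
  Grid g{dims[0], dims[1], dims[2], ds};
  const int N = g.nx * g.ny * g.nz;
  if (u0.size() != N || tensors.nrow() != N || ctype.size() != N)
    stop("state/tensor/ctype size does not match grid");
  if (params.ncol() != P_NCOL) stop("parameter matrix has wrong width");
  const int ntype = params.nrow();
  std::vector<CellPar> par(ntype);
  for (int r = 0; r < ntype; ++r)
    for (int c = 0; c < P_NCOL; ++c) par[r].p[c] = params(r, c);
  std::vector<int> ct(N);
  for (int n = 0; n < N; ++n) {
    ct[n] = ctype[n];
    if (ct[n] < 0 || ct[n] >= ntype) stop("cell-type index out of range");
  }
  if (!(dt > 0.0)) stop("dt must be positive");

  std::vector<double> u(u0.begin(), u0.end()), v(v0.begin(), v0.end()),
      w(w0.begin(), w0.end()), s(s0.begin(), s0.end()), divu(N, 0.0);
  std::vector<char> stim_mask(N, 0);
  for (int m = 0; m < stim_nodes.size(); ++m) {
    if (stim_nodes[m] < 0 || stim_nodes[m] >= N)
      stop("stimulus node index out of range");
    stim_mask[stim_nodes[m]] = 1;
  }

  // precomputed faces per orientation
  std::vector<Face> faces[3];
  bool any_cross[3] = {false, false, false};
  bool have_axis[3] = {g.nx > 1, g.ny > 1, g.nz > 1};
  for (int axis = 0; axis < 3; ++axis)
    if (have_axis[axis]) build_faces(tensors, g, axis, faces[axis], any_cross[axis]);
  const bool have_diff = have_axis[0] || have_axis[1] || have_axis[2];

  const int nsteps = (int)std::lround(duration / dt);
  const int nstim = stim_times.size();
  const int ntrace = trace_nodes.size();
  const int nsamp = (trace_stride > 0 && ntrace > 0) ? nsteps / trace_stride + 1 : 0;
  NumericMatrix traces(nsamp, ntrace);
  NumericVector trace_time(nsamp);

  const bool do_ecg = h_epi_.isNotNull() && h_endo_.isNotNull() && ecg_stride > 0;
  std::vector<double> hex, hey, hez, hnx, hny, hnz;
  if (do_ecg) {
    NumericMatrix he(h_epi_), hn(h_endo_);
    if (he.nrow() != N || hn.nrow() != N)
      stop("lead-field weight matrix size does not match grid");
    hex.resize(N); hey.resize(N); hez.resize(N);
    hnx.resize(N); hny.resize(N); hnz.resize(N);
    for (int n = 0; n < N; ++n) {
      hex[n] = he(n, 0); hey[n] = he(n, 1); hez[n] = he(n, 2);
      hnx[n] = hn(n, 0); hny[n] = hn(n, 1); hnz[n] = hn(n, 2);
    }
  }
  const int necg = do_ecg ? nsteps / ecg_stride + 1 : 0;
  NumericMatrix ecg(std::max(necg, 0), 2);
  NumericVector ecg_time(std::max(necg, 0));

  // first upward crossing of act_threshold per node per stimulus window
  std::vector<double> act(std::max(N * nstim, 1), NA_REAL);
  std::vector<char> crossed(N, 1); // armed only once a beat window begins
  int cur_beat = -1;

  int isamp = 0, iecg = 0;
  double max_over = 0.0;
  const int check_every = std::max(1, (int)std::lround(1.0 / dt));

  for (int step = 0; step <= nsteps; ++step) {
    const double t = step * dt;

    if (nsamp > 0 && step % trace_stride == 0 && isamp < nsamp) {
      for (int m = 0; m < ntrace; ++m) traces(isamp, m) = u[trace_nodes[m]];
      trace_time[isamp++] = t;
    }
    if (do_ecg && step % ecg_stride == 0 && iecg < necg) {
      ecg(iecg, 0) = lead_field_phi(u.data(), g, hex.data(), hey.data(), hez.data());
      ecg(iecg, 1) = lead_field_phi(u.data(), g, hnx.data(), hny.data(), hnz.data());
      ecg_time[iecg++] = t;
    }
    if (step == nsteps) break;

    // beat index: last stimulus whose onset is <= t
    int beat = cur_beat;
    while (beat + 1 < nstim && t >= stim_times[beat + 1] - 1e-9) ++beat;
    if (beat != cur_beat) {
      cur_beat = beat;
      std::fill(crossed.begin(), crossed.end(), 0); // arm detectors
    }
    double amp = 0.0;
    if (cur_beat >= 0 && t - stim_times[cur_beat] < stim_dur - 1e-9)
      amp = stim_amp;

    if (have_diff) {
      std::fill(divu.begin(), divu.end(), 0.0);
      for (int axis = 0; axis < 3; ++axis)
        if (have_axis[axis])
          apply_faces(faces[axis], axis, any_cross[axis], u.data(), g,
                      divu.data());
    }

    double* actb = (cur_beat >= 0) ? &act[(size_t)N * cur_beat] : nullptr;
    for (int n = 0; n < N; ++n) {
      const double un = u[n];
      double du = have_diff ? divu[n] : 0.0;
      if (amp != 0.0 && stim_mask[n]) du += amp;
      if (reaction_on) {
        const double* p = par[ct[n]].p;
        const double Huv = heav(un - p[P_theta_v]);
        const double Huw = heav(un - p[P_theta_w]);
        const double Huo = heav(un - p[P_theta_o]);
        const double Huvm = heav(un - p[P_theta_vminus]);
        const double tau_o = (1.0 - Huo) * p[P_tau_o1] + Huo * p[P_tau_o2];
        const double tau_so = p[P_tau_so1] +
          (p[P_tau_so2] - p[P_tau_so1]) *
            (1.0 + std::tanh(p[P_k_so] * (un - p[P_u_so]))) / 2.0;
        const double J_fi =
          -v[n] * Huv * (un - p[P_theta_v]) * (p[P_u_u] - un) / p[P_tau_fi];
        const double J_so =
          (un - p[P_u_o]) * (1.0 - Huw) / tau_o + Huw / tau_so;
        const double J_si = -Huw * w[n] * s[n] / p[P_tau_si];
        du += -(J_fi + J_so + J_si);

        const double tau_vminus =
          (1.0 - Huvm) * p[P_tau_v1minus] + Huvm * p[P_tau_v2minus];
        const double tau_wminus = p[P_tau_w1minus] +
          (p[P_tau_w2minus] - p[P_tau_w1minus]) *
            (1.0 + std::tanh(p[P_k_wminus] * (un - p[P_u_wminus]))) / 2.0;
        const double tau_s = (1.0 - Huw) * p[P_tau_s1] + Huw * p[P_tau_s2];
        const double v_inf = un < p[P_theta_vminus] ? 1.0 : 0.0;
        // w_inf evaluated at max(u, 0): identical on the model's physical
        // range, but keeps the gate target in [0, 1] when the
        // cross-derivative stencil transiently undershoots the resting u
        const double upos = un > 0.0 ? un : 0.0;
        const double w_inf = (1.0 - Huo) * (1.0 - upos / p[P_tau_winf]) +
                             Huo * p[P_w_inf_star];

        double vn = v[n] + ((1.0 - Huv) * (v_inf - v[n]) / tau_vminus -
                            Huv * v[n] / p[P_tau_vplus]) * dt;
        double wn = w[n] + ((1.0 - Huw) * (w_inf - w[n]) / tau_wminus -
                            Huw * w[n] / p[P_tau_wplus]) * dt;
        double sn = s[n] +
          ((1.0 + std::tanh(p[P_k_s] * (un - p[P_u_s]))) / 2.0 - s[n]) /
            tau_s * dt;
        if (vn < 0.0) { if (-vn > max_over) max_over = -vn; vn = 0.0; }
        else if (vn > 1.0) { if (vn - 1.0 > max_over) max_over = vn - 1.0; vn = 1.0; }
        if (wn < 0.0) { if (-wn > max_over) max_over = -wn; wn = 0.0; }
        else if (wn > 1.0) { if (wn - 1.0 > max_over) max_over = wn - 1.0; wn = 1.0; }
        if (sn < 0.0) { if (-sn > max_over) max_over = -sn; sn = 0.0; }
        else if (sn > 1.0) { if (sn - 1.0 > max_over) max_over = sn - 1.0; sn = 1.0; }
        v[n] = vn; w[n] = wn; s[n] = sn;
      }
      const double un_new = un + du * dt;
      if (actb && !crossed[n] && un < act_threshold &&
          un_new >= act_threshold) {
        actb[n] = t + dt * (act_threshold - un) / (un_new - un);
        crossed[n] = 1;
      }
      u[n] = un_new;
    }

    if (step % check_every == 0) {
      for (int n = 0; n < N; ++n)
        if (!std::isfinite(u[n]))
          stop("numerical instability: non-finite u at node %d, t = %.3f ms "
               "(dt = %g ms)", n + 1, t, dt);
      if (max_over > 1e-9)
        stop("gate overshoot %g exceeds tolerance 1e-9 at t = %.3f ms "
             "(dt = %g ms)", max_over, t, dt);
    }
  }

  if (max_over > 1e-9)
    stop("gate overshoot %g exceeds tolerance 1e-9 (dt = %g ms)", max_over, dt);

  NumericMatrix act_out(N, std::max(nstim, 1));
  std::fill(act_out.begin(), act_out.end(), NA_REAL);
  if (nstim > 0)
    for (size_t q = 0; q < (size_t)N * nstim; ++q) act_out[q] = act[q];

  return List::create(
      _["u"] = NumericVector(u.begin(), u.end()),
      _["v"] = NumericVector(v.begin(), v.end()),
      _["w"] = NumericVector(w.begin(), w.end()),
      _["s"] = NumericVector(s.begin(), s.end()),
      _["traces"] = traces, _["trace_time"] = trace_time,
      _["act"] = act_out, _["ecg"] = ecg, _["ecg_time"] = ecg_time);
}
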