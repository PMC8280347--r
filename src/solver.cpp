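// Explicit central-difference finite-element engine on average-nodal-pressure
// (ANP) linear tetrahedra.  Total-Lagrangian kinematics; compressible
// neo-Hookean deviatoric response with optional Prony-series relaxation
// (soft tissue) or J2 radial-return plasticity on the elastic left
// Cauchy-Green tensor (bone); volumetric law p = K ln(Jbar)/Jbar evaluated
// from node-averaged volume ratios within each material group; rigid-sphere
// frictionless penalty contact; lumped (row-sum) mass.

#include <Rcpp.h>
#include <cmath>
#include <vector>
using namespace Rcpp;

static inline double det3(const double* F) {
  // column-major 3x3
  return F[0] * (F[4] * F[8] - F[7] * F[5])
       - F[3] * (F[1] * F[8] - F[7] * F[2])
       + F[6] * (F[1] * F[5] - F[4] * F[2]);
}

static inline void inv3(const double* F, double J, double* Fi) {
  double invJ = 1.0 / J;
  Fi[0] =  (F[4] * F[8] - F[7] * F[5]) * invJ;
  Fi[1] = -(F[1] * F[8] - F[7] * F[2]) * invJ;
  Fi[2] =  (F[1] * F[5] - F[4] * F[2]) * invJ;
  Fi[3] = -(F[3] * F[8] - F[6] * F[5]) * invJ;
  Fi[4] =  (F[0] * F[8] - F[6] * F[2]) * invJ;
  Fi[5] = -(F[0] * F[5] - F[3] * F[2]) * invJ;
  Fi[6] =  (F[3] * F[7] - F[6] * F[4]) * invJ;
  Fi[7] = -(F[0] * F[7] - F[6] * F[1]) * invJ;
  Fi[8] =  (F[0] * F[4] - F[3] * F[1]) * invJ;
}

// C = A * B (column-major 3x3)
static inline void mm3(const double* A, const double* B, double* C) {
  for (int c = 0; c < 3; ++c)
    for (int r = 0; r < 3; ++r)
      C[c * 3 + r] = A[r] * B[c * 3] + A[3 + r] * B[c * 3 + 1] +
                     A[6 + r] * B[c * 3 + 2];
}

// sym(A A^T) style: given column-major f and symmetric b (6: 11,22,33,12,13,23),
// compute f b f^T (symmetric out)
static inline void push_sym(const double* f, const double* b, double* out) {
  double B[9] = { b[0], b[3], b[4],
                  b[3], b[1], b[5],
                  b[4], b[5], b[2] };  // column-major full
  double T[9], P[9];
  mm3(f, B, T);
  // P = T * f^T : P[c*3+r] = sum_k T[k*3+r] * f[k*3+c]
  for (int c = 0; c < 3; ++c)
    for (int r = 0; r < 3; ++r)
      P[c * 3 + r] = T[r] * f[c] + T[3 + r] * f[c + 3] + T[6 + r] * f[c + 6];
  out[0] = P[0]; out[1] = P[4]; out[2] = P[8];
  out[3] = 0.5 * (P[3] + P[1]);
  out[4] = 0.5 * (P[6] + P[2]);
  out[5] = 0.5 * (P[7] + P[5]);
}

struct Mat {
  double rho, K, G, sigy, H;
  bool plastic;
  std::vector<double> g, tau;
};

// [[Rcpp::export]]
List cpp_fe_run(NumericMatrix nodes0, IntegerMatrix elems, IntegerVector region,
                List mats, List state, double dt, int nsteps,
                IntegerMatrix slot_of, int nslots, IntegerVector slot_region,
                NumericVector nodal_area, IntegerVector boundary_nodes,
                List contact, NumericVector gravity, double damping,
                Nullable<NumericMatrix> fext_, IntegerVector fixed_nodes,
                Nullable<IntegerMatrix> fixed_dofs_,
                int hist_stride, int field_stride, bool check_stability,
                double stability_tol) {
  const int n = nodes0.nrow(), m = elems.nrow();
  const int nr = (int)mats.size();

  std::vector<Mat> M(nr);
  for (int r = 0; r < nr; ++r) {
    List mr = mats[r];
    M[r].rho = as<double>(mr["density"]);
    M[r].K = as<double>(mr["bulk_modulus"]);
    M[r].G = as<double>(mr["shear_modulus"]);
    M[r].plastic = mr.containsElementNamed("yield_stress") &&
                   !Rf_isNull(mr["yield_stress"]);
    M[r].sigy = M[r].plastic ? as<double>(mr["yield_stress"]) : 0.0;
    M[r].H = as<double>(mr["hardening_modulus"]);
    M[r].g = as<std::vector<double> >(mr["prony_weights"]);
    M[r].tau = as<std::vector<double> >(mr["prony_times"]);
  }
  int ntermsmax = 0;
  for (int r = 0; r < nr; ++r)
    ntermsmax = std::max(ntermsmax, (int)M[r].g.size());

  // precompute reference shape gradients, volumes, lumped mass
  std::vector<double> gradN(m * 12);  // per elem: 4 nodes x 3 comps
  std::vector<double> V0(m);
  std::vector<double> mass(n, 0.0);
  for (int e = 0; e < m; ++e) {
    int a0 = elems(e, 0) - 1, a1 = elems(e, 1) - 1, a2 = elems(e, 2) - 1,
        a3 = elems(e, 3) - 1;
    double D[9];  // columns are the edge vectors (column-major)
    D[0] = nodes0(a1, 0) - nodes0(a0, 0);
    D[1] = nodes0(a1, 1) - nodes0(a0, 1);
    D[2] = nodes0(a1, 2) - nodes0(a0, 2);
    D[3] = nodes0(a2, 0) - nodes0(a0, 0);
    D[4] = nodes0(a2, 1) - nodes0(a0, 1);
    D[5] = nodes0(a2, 2) - nodes0(a0, 2);
    D[6] = nodes0(a3, 0) - nodes0(a0, 0);
    D[7] = nodes0(a3, 1) - nodes0(a0, 1);
    D[8] = nodes0(a3, 2) - nodes0(a0, 2);
    double Jd = det3(D);
    if (Jd <= 0) stop("degenerate element %d in reference mesh", e + 1);
    V0[e] = Jd / 6.0;
    double Di[9];
    inv3(D, Jd, Di);
    // gradN_a (a=1..3 of local 2..4) = rows of Di; gradN_0 = -sum
    for (int a = 1; a < 4; ++a)
      for (int j = 0; j < 3; ++j)
        gradN[e * 12 + a * 3 + j] = Di[j * 3 + (a - 1)];
    for (int j = 0; j < 3; ++j)
      gradN[e * 12 + 0 + j] = -(gradN[e * 12 + 3 + j] + gradN[e * 12 + 6 + j] +
                                gradN[e * 12 + 9 + j]);
    double me = M[region[e] - 1].rho * V0[e] / 4.0;
    mass[a0] += me; mass[a1] += me; mass[a2] += me; mass[a3] += me;
  }

  // state arrays (copied in, returned out)
  NumericMatrix xin = state["x"], vin = state["v"];
  std::vector<double> x(n * 3), v(n * 3);
  for (int i = 0; i < n; ++i)
    for (int j = 0; j < 3; ++j) {
      x[i * 3 + j] = xin(i, j);
      v[i * 3 + j] = vin(i, j);
    }
  std::vector<double> Fprev = as<std::vector<double> >(state["Fprev"]);
  std::vector<double> tau0 = as<std::vector<double> >(state["tau0"]);
  std::vector<double> hvis = as<std::vector<double> >(state["hvis"]);
  std::vector<double> be = as<std::vector<double> >(state["be"]);
  std::vector<double> ebar = as<std::vector<double> >(state["ebar"]);
  std::vector<double> edil = as<std::vector<double> >(state["edil"]);
  std::vector<double> edist = as<std::vector<double> >(state["edist"]);
  double t = as<double>(state["t"]);
  double W_int = as<double>(state["W_int"]);
  double Wp = as<double>(state["Wp"]);
  double Wgrav = as<double>(state["Wgrav"]);
  std::vector<double> IEreg = as<std::vector<double> >(state["IE_region"]);
  if ((int)IEreg.size() < nr) IEreg.resize(nr, 0.0);
  if (hvis.size() < (size_t)m * 6 * std::max(1, ntermsmax))
    hvis.resize((size_t)m * 6 * std::max(1, ntermsmax), 0.0);

  // Prony factors per region/term
  std::vector<double> ef(nr * std::max(1, ntermsmax), 0.0),
      em(nr * std::max(1, ntermsmax), 0.0), ginf(nr, 1.0);
  for (int r = 0; r < nr; ++r) {
    double gs = 0.0;
    for (size_t k = 0; k < M[r].g.size(); ++k) {
      gs += M[r].g[k];
      ef[r * ntermsmax + k] = std::exp(-dt / M[r].tau[k]);
      em[r * ntermsmax + k] = std::exp(-dt / (2.0 * M[r].tau[k]));
    }
    ginf[r] = 1.0 - gs;
  }

  // contact
  bool has_contact = as<bool>(contact["enabled"]);
  double cc[3] = {0, 0, 0}, cv[3] = {0, 0, 0}, cR = 0, ckp = 0;
  if (has_contact) {
    NumericVector c0 = contact["center"], cvel = contact["velocity"];
    for (int j = 0; j < 3; ++j) { cc[j] = c0[j]; cv[j] = cvel[j]; }
    cR = as<double>(contact["radius"]);
    ckp = as<double>(contact["penalty_stiffness"]);
  }
  double t0 = t;

  bool has_fext = fext_.isNotNull();
  NumericMatrix fext;
  if (has_fext) fext = as<NumericMatrix>(fext_);
  std::vector<char> is_fixed(n * 3, 0);
  for (int k = 0; k < fixed_nodes.size(); ++k)
    for (int j = 0; j < 3; ++j) is_fixed[(fixed_nodes[k] - 1) * 3 + j] = 1;
  if (fixed_dofs_.isNotNull()) {
    IntegerMatrix fd = as<IntegerMatrix>(fixed_dofs_);
    for (int i = 0; i < n; ++i)
      for (int j = 0; j < 3; ++j)
        if (fd(i, j)) is_fixed[i * 3 + j] = 1;
  }
  bool has_grav = gravity[0] != 0 || gravity[1] != 0 || gravity[2] != 0;

  double Mtot = 0.0;
  double com0[3] = {0, 0, 0};
  for (int i = 0; i < n; ++i) {
    Mtot += mass[i];
    for (int j = 0; j < 3; ++j) com0[j] += mass[i] * nodes0(i, j);
  }
  for (int j = 0; j < 3; ++j) com0[j] /= Mtot;

  double KE0 = 0.0;
  for (int i = 0; i < n; ++i)
    KE0 += 0.5 * mass[i] * (v[i * 3] * v[i * 3] + v[i * 3 + 1] * v[i * 3 + 1] +
                            v[i * 3 + 2] * v[i * 3 + 2]);

  // outputs
  int nh = nsteps / std::max(1, hist_stride) + 1;
  int histcols = 13 + nr;
  NumericMatrix hist(nh, histcols);
  int hrow = 0;
  int ns = field_stride > 0 ? nsteps / field_stride : 0;
  NumericVector snap_t(std::max(ns, 0));
  NumericMatrix snapF(ns > 0 ? m : 1, ns > 0 ? ns * 9 : 1);
  NumericMatrix snapL(ns > 0 ? m : 1, ns > 0 ? ns * 9 : 1);
  NumericMatrix snapS(ns > 0 ? m : 1, ns > 0 ? ns * 6 : 1);
  NumericMatrix snapEd(ns > 0 ? m : 1, ns > 0 ? ns * 2 : 1);
  int srow = 0;

  std::vector<double> f(n * 3), Fcur(m * 9), Jel(m), sig(m * 6), Lel(m * 9);
  // previous-step stress for midpoint work accounting; carried in the state
  // so that checkpoint/resume reproduces a continuous run exactly
  std::vector<double> sigprev(m * 6, 0.0);
  bool have_sigprev = false;
  if (state.containsElementNamed("sigprev")) {
    std::vector<double> sp = as<std::vector<double> >(state["sigprev"]);
    if (sp.size() == (size_t)m * 6) {
      sigprev = sp;
      have_sigprev = true;
    }
  }
  std::vector<double> slotsum(nslots), slotden(nslots, 0.0), pnod(nslots);
  for (int e = 0; e < m; ++e)
    for (int a = 0; a < 4; ++a) slotden[slot_of(e, a) - 1] += V0[e];

  double fc_tot[3] = {0, 0, 0}, Econ = 0.0, acc_g = 0.0;

  auto record_hist = [&](double tt) {
    double KE = 0.0, comx[3] = {0, 0, 0};
    for (int i = 0; i < n; ++i) {
      KE += 0.5 * mass[i] * (v[i * 3] * v[i * 3] + v[i * 3 + 1] * v[i * 3 + 1] +
                             v[i * 3 + 2] * v[i * 3 + 2]);
      for (int j = 0; j < 3; ++j) comx[j] += mass[i] * x[i * 3 + j];
    }
    hist(hrow, 0) = tt;
    for (int j = 0; j < 3; ++j) {
      hist(hrow, 1 + j) = fc_tot[j];
      hist(hrow, 4 + j) = comx[j] / Mtot - com0[j];
    }
    hist(hrow, 7) = KE;
    hist(hrow, 8) = W_int;
    hist(hrow, 9) = Econ;
    hist(hrow, 10) = Wp;
    hist(hrow, 11) = Wgrav;
    hist(hrow, 12) = acc_g;
    for (int r = 0; r < nr; ++r) hist(hrow, 13 + r) = IEreg[r];
    ++hrow;
  };
  record_hist(t);

  for (int step = 0; step < nsteps; ++step) {
    std::fill(f.begin(), f.end(), 0.0);
    std::fill(slotsum.begin(), slotsum.end(), 0.0);

    // pass 1: kinematics and nodal volume-ratio averaging
    for (int e = 0; e < m; ++e) {
      double* F = &Fcur[e * 9];
      const double* gN = &gradN[e * 12];
      for (int k = 0; k < 9; ++k) F[k] = 0.0;
      for (int a = 0; a < 4; ++a) {
        int ia = elems(e, a) - 1;
        const double* xa = &x[ia * 3];
        for (int j = 0; j < 3; ++j) {      // column j
          double g = gN[a * 3 + j];
          F[j * 3 + 0] += xa[0] * g;
          F[j * 3 + 1] += xa[1] * g;
          F[j * 3 + 2] += xa[2] * g;
        }
      }
      double J = det3(F);
      if (J <= 0.0)
        stop("element inversion (J <= 0) in element %d at t = %g s",
             e + 1, t);
      Jel[e] = J;
      for (int a = 0; a < 4; ++a) slotsum[slot_of(e, a) - 1] += V0[e] * J;
    }
    for (int s = 0; s < nslots; ++s) {
      double Jbar = slotsum[s] / slotden[s];
      if (Jbar <= 0.0) stop("non-positive averaged volume ratio at node slot");
      double K = M[slot_region[s] - 1].K;
      pnod[s] = K * std::log(Jbar) / Jbar;  // tension-positive volumetric stress
    }

    // pass 2: stress, internal force, energy
    for (int e = 0; e < m; ++e) {
      const int r = region[e] - 1;
      const Mat& mt = M[r];
      double* F = &Fcur[e * 9];
      const double J = Jel[e];
      double svol = 0.25 * (pnod[slot_of(e, 0) - 1] + pnod[slot_of(e, 1) - 1] +
                            pnod[slot_of(e, 2) - 1] + pnod[slot_of(e, 3) - 1]);
      double sdev[6];

      if (mt.plastic) {
        // multiplicative J2 plasticity on the elastic left Cauchy-Green
        double* Fo = &Fprev[e * 9];
        double Foi[9], frel[9];
        double Jo = det3(Fo);
        inv3(Fo, Jo, Foi);
        mm3(F, Foi, frel);
        double jf = det3(frel);
        double sc = std::pow(jf, -1.0 / 3.0);
        for (int k = 0; k < 9; ++k) frel[k] *= sc;
        double betr[6];
        push_sym(frel, &be[e * 6], betr);
        double trb = betr[0] + betr[1] + betr[2];
        double sd[6] = { mt.G * (betr[0] - trb / 3.0),
                         mt.G * (betr[1] - trb / 3.0),
                         mt.G * (betr[2] - trb / 3.0),
                         mt.G * betr[3], mt.G * betr[4], mt.G * betr[5] };
        double snorm = std::sqrt(sd[0] * sd[0] + sd[1] * sd[1] + sd[2] * sd[2] +
                                 2 * (sd[3] * sd[3] + sd[4] * sd[4] +
                                      sd[5] * sd[5]));
        double ytol = std::sqrt(2.0 / 3.0) * (mt.sigy + mt.H * ebar[e]);
        if (snorm > ytol) {
          double mubar = mt.G * trb / 3.0;
          double dgam = (snorm - ytol) /
                        (2.0 * mubar * (1.0 + mt.H / (3.0 * mubar)));
          double fac = 1.0 - 2.0 * mubar * dgam / snorm;
          for (int k = 0; k < 6; ++k) sd[k] *= fac;
          ebar[e] += std::sqrt(2.0 / 3.0) * dgam;
          double ynew = std::sqrt(2.0 / 3.0) * (mt.sigy + mt.H * ebar[e]);
          Wp += dgam * ynew * V0[e];
          for (int k = 0; k < 6; ++k) be[e * 6 + k] = sd[k] / mt.G;
          be[e * 6 + 0] += trb / 3.0;
          be[e * 6 + 1] += trb / 3.0;
          be[e * 6 + 2] += trb / 3.0;
        } else {
          for (int k = 0; k < 6; ++k) be[e * 6 + k] = betr[k];
        }
        for (int k = 0; k < 6; ++k) sdev[k] = sd[k] / J;  // Kirchhoff -> Cauchy
      } else {
        // neo-Hookean deviatoric Kirchhoff stress, Prony relaxation
        double Jm23 = std::pow(J, -2.0 / 3.0);
        double bb[6] = {
          Jm23 * (F[0] * F[0] + F[3] * F[3] + F[6] * F[6]),
          Jm23 * (F[1] * F[1] + F[4] * F[4] + F[7] * F[7]),
          Jm23 * (F[2] * F[2] + F[5] * F[5] + F[8] * F[8]),
          Jm23 * (F[0] * F[1] + F[3] * F[4] + F[6] * F[7]),
          Jm23 * (F[0] * F[2] + F[3] * F[5] + F[6] * F[8]),
          Jm23 * (F[1] * F[2] + F[4] * F[5] + F[7] * F[8]) };
        double trb = bb[0] + bb[1] + bb[2];
        double t0n[6] = { mt.G * (bb[0] - trb / 3.0),
                          mt.G * (bb[1] - trb / 3.0),
                          mt.G * (bb[2] - trb / 3.0),
                          mt.G * bb[3], mt.G * bb[4], mt.G * bb[5] };
        double seff[6];
        int nt = (int)mt.g.size();
        if (nt == 0) {
          for (int k = 0; k < 6; ++k) seff[k] = t0n[k];
        } else {
          for (int k = 0; k < 6; ++k) seff[k] = ginf[r] * t0n[k];
          for (int q = 0; q < nt; ++q) {
            double* h = &hvis[((size_t)e * ntermsmax + q) * 6];
            double efa = ef[r * ntermsmax + q], ema = em[r * ntermsmax + q];
            double gq = mt.g[q];
            for (int k = 0; k < 6; ++k) {
              h[k] = efa * h[k] + ema * (t0n[k] - tau0[e * 6 + k]);
              seff[k] += gq * h[k];
            }
          }
          for (int k = 0; k < 6; ++k) tau0[e * 6 + k] = t0n[k];
        }
        for (int k = 0; k < 6; ++k) sdev[k] = seff[k] / J;
      }

      double s6[6] = { sdev[0] + svol, sdev[1] + svol, sdev[2] + svol,
                       sdev[3], sdev[4], sdev[5] };
      for (int k = 0; k < 6; ++k) sig[e * 6 + k] = s6[k];

      // velocity gradient L = (F - Fprev)/dt * Fmid^{-1} (midpoint form:
      // exactly skew under rigid rotation, so no spurious strain power)
      double Fi[9];
      inv3(F, J, Fi);
      double dF[9], Fmid[9];
      for (int k = 0; k < 9; ++k) {
        dF[k] = (F[k] - Fprev[e * 9 + k]) / dt;
        Fmid[k] = 0.5 * (F[k] + Fprev[e * 9 + k]);
      }
      double Jmid = det3(Fmid);
      double Fmi[9];
      inv3(Fmid, Jmid, Fmi);
      double L[9];
      mm3(dF, Fmi, L);
      for (int k = 0; k < 9; ++k) Lel[e * 9 + k] = L[k];
      double D[6] = { L[0], L[4], L[8],
                      0.5 * (L[1] + L[3]), 0.5 * (L[2] + L[6]),
                      0.5 * (L[5] + L[7]) };
      // midpoint stress against midpoint rate: avoids the secular
      // quadrature error of end-of-step stress for near-CFL ringing modes
      double smid[6];
      const double* sp = &sigprev[e * 6];
      for (int k = 0; k < 6; ++k)
        smid[k] = have_sigprev ? 0.5 * (s6[k] + sp[k]) : s6[k];
      double sdd = smid[0] * D[0] + smid[1] * D[1] + smid[2] * D[2] +
                   2 * (smid[3] * D[3] + smid[4] * D[4] + smid[5] * D[5]);
      double trD = D[0] + D[1] + D[2];
      double sm = (smid[0] + smid[1] + smid[2]) / 3.0;
      double dW = V0[e] * Jmid * sdd * dt;
      W_int += dW;
      IEreg[r] += dW;
      edil[e] += sm * trD * dt;
      edist[e] += (sdd - sm * trD) * dt;
      for (int k = 0; k < 9; ++k) Fprev[e * 9 + k] = F[k];
      for (int k = 0; k < 6; ++k) sigprev[e * 6 + k] = s6[k];

      // internal nodal forces: f_a -= V0 * P gradN_a, P = J sigma F^{-T}
      double S[9] = { s6[0], s6[3], s6[4],
                      s6[3], s6[1], s6[5],
                      s6[4], s6[5], s6[2] };
      double P[9];
      // P = J * S * Fi^T : P[c*3+r] = J * sum_k S[k*3+r] * Fi[k*3+c]
      for (int c = 0; c < 3; ++c)
        for (int rr = 0; rr < 3; ++rr)
          P[c * 3 + rr] = J * (S[rr] * Fi[c] + S[3 + rr] * Fi[c + 3] +
                               S[6 + rr] * Fi[c + 6]);
      const double* gN = &gradN[e * 12];
      for (int a = 0; a < 4; ++a) {
        int ia = elems(e, a) - 1;
        for (int i = 0; i < 3; ++i)
          f[ia * 3 + i] -= V0[e] * (P[i] * gN[a * 3] + P[3 + i] * gN[a * 3 + 1] +
                                    P[6 + i] * gN[a * 3 + 2]);
      }
    }

    have_sigprev = true;

    // contact (rigid sphere, frictionless penalty)
    fc_tot[0] = fc_tot[1] = fc_tot[2] = 0.0;
    Econ = 0.0;
    if (has_contact) {
      double tloc = t - t0;
      double c_now[3] = { cc[0] + cv[0] * tloc, cc[1] + cv[1] * tloc,
                          cc[2] + cv[2] * tloc };
      for (int k = 0; k < boundary_nodes.size(); ++k) {
        int i = boundary_nodes[k] - 1;
        double d0 = x[i * 3] - c_now[0], d1 = x[i * 3 + 1] - c_now[1],
               d2 = x[i * 3 + 2] - c_now[2];
        double rr = std::sqrt(d0 * d0 + d1 * d1 + d2 * d2);
        if (rr < cR) {
          if (rr < 1e-12)
            stop("contact node %d coincides with impactor centre", i + 1);
          double pen = cR - rr;
          double fmag = ckp * nodal_area[i] * pen;
          double nx = d0 / rr, ny = d1 / rr, nz = d2 / rr;
          f[i * 3] += fmag * nx;
          f[i * 3 + 1] += fmag * ny;
          f[i * 3 + 2] += fmag * nz;
          fc_tot[0] += fmag * nx;
          fc_tot[1] += fmag * ny;
          fc_tot[2] += fmag * nz;
          Econ += 0.5 * ckp * nodal_area[i] * pen * pen;
        }
      }
    }

    if (has_grav) {
      double gw = 0.0;
      for (int i = 0; i < n; ++i)
        for (int j = 0; j < 3; ++j) {
          f[i * 3 + j] += mass[i] * gravity[j];
          gw += mass[i] * gravity[j] * v[i * 3 + j];
        }
      Wgrav += gw * dt;
    }
    if (damping > 0)
      for (int i = 0; i < n; ++i)
        for (int j = 0; j < 3; ++j)
          f[i * 3 + j] -= damping * mass[i] * v[i * 3 + j];
    if (has_fext)
      for (int i = 0; i < n; ++i)
        for (int j = 0; j < 3; ++j) f[i * 3 + j] += fext(i, j);

    // net force -> COM acceleration magnitude in g (proper acceleration:
    // the free-fall gravity offset is excluded, as an accelerometer would)
    double fs[3] = {0, 0, 0};
    for (int i = 0; i < n; ++i)
      for (int j = 0; j < 3; ++j)
        if (!is_fixed[i * 3 + j]) fs[j] += f[i * 3 + j];
    if (has_grav)
      for (int j = 0; j < 3; ++j) fs[j] -= Mtot * gravity[j];
    acc_g = std::sqrt(fs[0] * fs[0] + fs[1] * fs[1] + fs[2] * fs[2]) /
            (Mtot * 9.81);

    // central-difference update
    for (int i = 0; i < n; ++i) {
      double invm = 1.0 / mass[i];
      for (int j = 0; j < 3; ++j) {
        if (is_fixed[i * 3 + j]) {
          v[i * 3 + j] = 0.0;
          continue;
        }
        v[i * 3 + j] += dt * f[i * 3 + j] * invm;
        x[i * 3 + j] += dt * v[i * 3 + j];
      }
    }
    t += dt;

    if (hist_stride > 0 && (step + 1) % hist_stride == 0 && hrow < nh)
      record_hist(t);
    if (field_stride > 0 && (step + 1) % field_stride == 0 && srow < ns) {
      snap_t[srow] = t;
      for (int e = 0; e < m; ++e) {
        for (int k = 0; k < 9; ++k) {
          snapF(e, srow * 9 + k) = Fcur[e * 9 + k];
          snapL(e, srow * 9 + k) = Lel[e * 9 + k];
        }
        for (int k = 0; k < 6; ++k) snapS(e, srow * 6 + k) = sig[e * 6 + k];
        snapEd(e, srow * 2) = edil[e];
        snapEd(e, srow * 2 + 1) = edist[e];
      }
      ++srow;
    }

    if (check_stability && (step + 1) % 200 == 0) {
      double KE = 0.0;
      for (int i = 0; i < n; ++i)
        KE += 0.5 * mass[i] *
              (v[i * 3] * v[i * 3] + v[i * 3 + 1] * v[i * 3 + 1] +
               v[i * 3 + 2] * v[i * 3 + 2]);
      double budget = KE0 + Wgrav - KE - W_int - Econ;
      // reference energy scale: initial KE, or the gravity work for runs
      // that start from rest (never a vanishing denominator)
      double ref = std::max(std::max(KE0, std::fabs(Wgrav)), 1e-3);
      if (-budget > stability_tol * ref)
        stop("instability detected at t = %g s: energy grew by %.3g%% of the "
             "initial kinetic energy without input", t,
             -budget / ref * 100.0);
    }
  }

  NumericMatrix xout(n, 3), vout(n, 3);
  for (int i = 0; i < n; ++i)
    for (int j = 0; j < 3; ++j) {
      xout(i, j) = x[i * 3 + j];
      vout(i, j) = v[i * 3 + j];
    }
  List newstate = List::create(
      _["x"] = xout, _["v"] = vout, _["t"] = t, _["Fprev"] = Fprev,
      _["sigprev"] = sigprev,
      _["tau0"] = tau0, _["hvis"] = hvis, _["be"] = be, _["ebar"] = ebar,
      _["edil"] = edil, _["edist"] = edist, _["W_int"] = W_int, _["Wp"] = Wp,
      _["Wgrav"] = Wgrav, _["IE_region"] = IEreg);
  return List::create(
      _["hist"] = hist, _["state"] = newstate, _["snap_t"] = snap_t,
      _["snapF"] = snapF, _["snapL"] = snapL, _["snapS"] = snapS,
      _["snapEd"] = snapEd, _["n_snaps"] = srow, _["KE0"] = KE0,
      _["mass"] = NumericVector(mass.begin(), mass.end()));
}

// locate points in a tetrahedral mesh (barycentric test); returns 1-based
// element index or 0 when outside
// [[Rcpp::export]]
IntegerVector cpp_locate_points(NumericMatrix nodes, IntegerMatrix elems,
                                NumericMatrix pts, double tol = 1e-9) {
  const int m = elems.nrow(), np = pts.nrow();
  std::vector<double> Di(m * 9), x0(m * 3);
  std::vector<double> bb(m * 6);
  for (int e = 0; e < m; ++e) {
    int a0 = elems(e, 0) - 1;
    double D[9];
    for (int a = 1; a < 4; ++a) {
      int ia = elems(e, a) - 1;
      D[(a - 1) * 3 + 0] = nodes(ia, 0) - nodes(a0, 0);
      D[(a - 1) * 3 + 1] = nodes(ia, 1) - nodes(a0, 1);
      D[(a - 1) * 3 + 2] = nodes(ia, 2) - nodes(a0, 2);
    }
    double J = det3(D);
    inv3(D, J, &Di[e * 9]);
    for (int j = 0; j < 3; ++j) x0[e * 3 + j] = nodes(a0, j);
    for (int j = 0; j < 3; ++j) {
      double lo = nodes(a0, j), hi = nodes(a0, j);
      for (int a = 1; a < 4; ++a) {
        int ia = elems(e, a) - 1;
        lo = std::min(lo, nodes(ia, j));
        hi = std::max(hi, nodes(ia, j));
      }
      bb[e * 6 + j] = lo;
      bb[e * 6 + 3 + j] = hi;
    }
  }
  IntegerVector out(np);
  for (int p = 0; p < np; ++p) {
    double px = pts(p, 0), py = pts(p, 1), pz = pts(p, 2);
    int found = 0;
    for (int e = 0; e < m; ++e) {
      if (px < bb[e * 6] - tol || px > bb[e * 6 + 3] + tol ||
          py < bb[e * 6 + 1] - tol || py > bb[e * 6 + 4] + tol ||
          pz < bb[e * 6 + 2] - tol || pz > bb[e * 6 + 5] + tol)
        continue;
      double r0 = px - x0[e * 3], r1 = py - x0[e * 3 + 1],
             r2 = pz - x0[e * 3 + 2];
      const double* A = &Di[e * 9];
      double l1 = A[0] * r0 + A[3] * r1 + A[6] * r2;
      double l2 = A[1] * r0 + A[4] * r1 + A[7] * r2;
      double l3 = A[2] * r0 + A[5] * r1 + A[8] * r2;
      double l0 = 1.0 - l1 - l2 - l3;
      if (l0 >= -tol && l1 >= -tol && l2 >= -tol && l3 >= -tol) {
        found = e + 1;
        break;
      }
    }
    out[p] = found;
  }
  return out;
}
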