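// Fixed-step stochastic Heun integrator for the delayed thalamocortical
// neural-mass network. Each synapse is a critically damped second-order
// system (y, ydot); membrane potentials are signed sums of PSPs; long-range
// coupling is the delayed PYR (or TC) output rate weighted by the
// connectivity matrix. Noise and delayed inputs are held constant over a
// step (zero-order hold), so the scheme is deterministic given the
// pre-generated noise matrix.
#include <Rcpp.h>
#include <cmath>
#include <vector>
using namespace Rcpp;

static const int NSYN_CTX = 17;
static const int NSYN_THA = 8;

static inline double sigm(double v, const double *p) {
  // p = {e0, r, v0}
  return 2.0 * p[0] / (1.0 + std::exp(p[1] * (p[2] - v)));
}

// Membrane potentials of one cortical column from its synapse PSPs.
// Synapse order (see .cortical_synapse_table in R):
//  0 pyr_pyr2   1 pyr2_pyr  2 pyr_pv    3 pyr_sst   4 pv_pyr
//  5 sst_apical 6 sst_basal 7 sst_pv    8 vip_sst   9 ngfc_pyr
// 10 pyr_ngfc  11 noise_pyr 12 lr_pyr  13 lr_pv    14 lr_sst
// 15 lr_vip    16 lr_ngfc
static inline void ctx_potentials(const double *yi, double *v) {
  v[0] = yi[1] + yi[11] + yi[12] - yi[4] - yi[5] - yi[6] - yi[9]; // PYR
  v[1] = yi[0];                                                  // PYR2
  v[2] = yi[2] + yi[13] - yi[7];                                 // PV
  v[3] = yi[3] + yi[14] - yi[8];                                 // SST
  v[4] = yi[15];                                                 // VIP
  v[5] = yi[10] + yi[16];                                        // NGFC
}

// Thalamic synapse order: 0 ctx_tc 1 ctx_rn1 2 ctx_rn2 3 tc_rn1 4 tc_rn2
// 5 rn1_tc 6 rn2_tc 7 noise_tc
static inline void tha_potentials(const double *yt, double *v) {
  v[0] = yt[0] + yt[7] - yt[5] - yt[6]; // TC
  v[1] = yt[1] + yt[3];                 // RN1
  v[2] = yt[2] + yt[4];                 // RN2
}

struct EngineParams {
  int n_ctx;
  bool has_tha;
  int n;      // n_ctx + has_tha
  int nsyn;   // total synapse count
  // flattened per-synapse constants: a1 = W/tau, a2 = 2/tau, a3 = 1/tau^2
  std::vector<double> a1, a2, a3, C;
  // sigmoid params: ctx regions 6 pops * 3, thalamus 3 pops * 3
  std::vector<double> sig;
  std::vector<double> noise_mean, noise_sd; // per region
};

// Synaptic drive u for every synapse of the network given PSPs y,
// the per-region delayed coupling input cp, held noise rates un,
// and held external per-subpopulation rates (may be null).
static void compute_inputs(const EngineParams &P, const double *y,
                           const double *cp, const double *un,
                           const double *ext, double *u, double *proj_rate) {
  double v[6], r[6];
  for (int i = 0; i < P.n_ctx; ++i) {
    const double *yi = y + (size_t)i * NSYN_CTX;
    const double *sg = P.sig.data() + (size_t)i * 18;
    ctx_potentials(yi, v);
    for (int p = 0; p < 6; ++p) r[p] = sigm(v[p], sg + 3 * p);
    const double *Ci = P.C.data() + (size_t)i * NSYN_CTX;
    double *ui = u + (size_t)i * NSYN_CTX;
    const double lr = cp[i];
    const double *e = ext ? ext + (size_t)i * 6 : nullptr;
    ui[0] = Ci[0] * r[0];
    ui[1] = Ci[1] * r[1];
    ui[2] = Ci[2] * r[0];
    ui[3] = Ci[3] * r[0];
    ui[4] = Ci[4] * r[2];
    ui[5] = Ci[5] * r[3];
    ui[6] = Ci[6] * r[3];
    ui[7] = Ci[7] * r[3];
    ui[8] = Ci[8] * r[4];
    ui[9] = Ci[9] * r[5];
    ui[10] = Ci[10] * r[0];
    ui[11] = Ci[11] * un[i];
    ui[12] = Ci[12] * (lr + (e ? e[0] : 0.0));
    ui[13] = Ci[13] * (lr + (e ? e[2] : 0.0));
    ui[14] = Ci[14] * (lr + (e ? e[3] : 0.0));
    ui[15] = Ci[15] * (lr + (e ? e[4] : 0.0));
    ui[16] = Ci[16] * (lr + (e ? e[5] : 0.0));
    proj_rate[i] = r[0];
  }
  if (P.has_tha) {
    const int it = P.n_ctx;
    const double *yt = y + (size_t)it * NSYN_CTX;
    const double *sg = P.sig.data() + (size_t)it * 18;
    double vt[3], rt[3];
    tha_potentials(yt, vt);
    for (int p = 0; p < 3; ++p) rt[p] = sigm(vt[p], sg + 3 * p);
    const double *Ct = P.C.data() + (size_t)it * NSYN_CTX;
    double *ut = u + (size_t)it * NSYN_CTX;
    const double drive = cp[it] + (ext ? ext[(size_t)it * 6] : 0.0);
    ut[0] = Ct[0] * drive;
    ut[1] = Ct[1] * drive;
    ut[2] = Ct[2] * drive;
    ut[3] = Ct[3] * rt[0];
    ut[4] = Ct[4] * rt[0];
    ut[5] = Ct[5] * rt[1];
    ut[6] = Ct[6] * rt[2];
    ut[7] = Ct[7] * un[it];
    proj_rate[it] = rt[0];
  }
}

// [[Rcpp::export(name = ".engine_simulate")]]
List engine_simulate(int n_ctx,
                     NumericMatrix Wc, NumericMatrix TAUc, NumericMatrix Cc,
                     NumericMatrix SIGc, NumericMatrix NOISEc,
                     bool has_tha,
                     NumericVector Wt, NumericVector TAUt, NumericVector Ct,
                     NumericVector SIGt, NumericVector NOISEt,
                     NumericMatrix K, IntegerMatrix Dsteps,
                     NumericMatrix Z,
                     int nsteps, double dt,
                     NumericMatrix ext,
                     bool record_pops) {
  EngineParams P;
  P.n_ctx = n_ctx;
  P.has_tha = has_tha;
  P.n = n_ctx + (has_tha ? 1 : 0);
  if (P.n < 1) stop("network must contain at least one mass");
  // every region (incl. thalamus) gets a NSYN_CTX-wide slot; thalamic slots
  // beyond NSYN_THA are unused (a1 = 0 keeps them inert).
  P.nsyn = P.n * NSYN_CTX;
  P.a1.assign(P.nsyn, 0.0);
  P.a2.assign(P.nsyn, 1.0); // benign damping for unused slots
  P.a3.assign(P.nsyn, 0.0);
  P.C.assign(P.nsyn, 0.0);
  P.sig.assign((size_t)P.n * 18, 0.0);
  P.noise_mean.assign(P.n, 0.0);
  P.noise_sd.assign(P.n, 0.0);

  for (int i = 0; i < n_ctx; ++i) {
    for (int k = 0; k < NSYN_CTX; ++k) {
      double W = Wc(i, k), tau = TAUc(i, k);
      if (!(tau > 0)) stop("non-positive synaptic time constant");
      size_t idx = (size_t)i * NSYN_CTX + k;
      P.a1[idx] = W / tau;
      P.a2[idx] = 2.0 / tau;
      P.a3[idx] = 1.0 / (tau * tau);
      P.C[idx] = Cc(i, k);
    }
    for (int q = 0; q < 18; ++q) P.sig[(size_t)i * 18 + q] = SIGc(i, q);
    P.noise_mean[i] = NOISEc(i, 0);
    P.noise_sd[i] = NOISEc(i, 1);
  }
  if (has_tha) {
    int it = n_ctx;
    for (int k = 0; k < NSYN_THA; ++k) {
      double W = Wt[k], tau = TAUt[k];
      if (!(tau > 0)) stop("non-positive thalamic time constant");
      size_t idx = (size_t)it * NSYN_CTX + k;
      P.a1[idx] = W / tau;
      P.a2[idx] = 2.0 / tau;
      P.a3[idx] = 1.0 / (tau * tau);
      P.C[idx] = Ct[k];
    }
    for (int q = 0; q < 9; ++q) P.sig[(size_t)it * 18 + q] = SIGt[q];
    P.noise_mean[it] = NOISEt[0];
    P.noise_sd[it] = NOISEt[1];
  }
  const int n = P.n;
  if (K.nrow() != n || K.ncol() != n) stop("coupling matrix dimension mismatch");
  if (Dsteps.nrow() != n || Dsteps.ncol() != n) stop("delay matrix dimension mismatch");
  if (Z.nrow() < nsteps || Z.ncol() != n) stop("noise matrix dimension mismatch");
  const bool has_ext = ext.nrow() > 0;
  if (has_ext && (ext.nrow() < nsteps || ext.ncol() != 6 * n))
    stop("external input matrix must be nsteps x 6*n");

  // resting projection rates used as pre-history for the delayed coupling
  std::vector<double> rest(n);
  for (int i = 0; i < n; ++i) rest[i] = sigm(0.0, P.sig.data() + (size_t)i * 18);

  int maxd = 0;
  for (int i = 0; i < n; ++i)
    for (int j = 0; j < n; ++j)
      if (Dsteps(i, j) > maxd) maxd = Dsteps(i, j);
  const int L = maxd + 1;
  std::vector<double> hist((size_t)L * n);
  for (int s = 0; s < L; ++s)
    for (int j = 0; j < n; ++j) hist[(size_t)s * n + j] = rest[j];

  std::vector<double> y(P.nsyn, 0.0), z(P.nsyn, 0.0);
  std::vector<double> u1(P.nsyn), u2(P.nsyn);
  std::vector<double> yp(P.nsyn), zp(P.nsyn);
  std::vector<double> cp(n), un(n), rate(n);
  std::vector<double> extrow;
  if (has_ext) extrow.assign((size_t)n * 6, 0.0);

  NumericMatrix lfp(nsteps, n);
  NumericMatrix pops;
  int npop_cols = 6 * n_ctx + (has_tha ? 3 : 0);
  if (record_pops) pops = NumericMatrix(nsteps, npop_cols);

  double v6[6], v3[3];
  for (int s = 0; s < nsteps; ++s) {
    // record state at time s*dt and push projection rates into history
    for (int i = 0; i < n_ctx; ++i) {
      ctx_potentials(y.data() + (size_t)i * NSYN_CTX, v6);
      lfp(s, i) = v6[0];
      if (record_pops)
        for (int p = 0; p < 6; ++p) pops(s, 6 * i + p) = v6[p];
      rate[i] = sigm(v6[0], P.sig.data() + (size_t)i * 18);
    }
    if (has_tha) {
      int it = n_ctx;
      tha_potentials(y.data() + (size_t)it * NSYN_CTX, v3);
      lfp(s, it) = v3[0];
      if (record_pops)
        for (int p = 0; p < 3; ++p) pops(s, 6 * n_ctx + p) = v3[p];
      rate[it] = sigm(v3[0], P.sig.data() + (size_t)it * 18);
    }
    for (int j = 0; j < n; ++j) hist[(size_t)(s % L) * n + j] = rate[j];

    // delayed, weighted coupling input per region (held over the step)
    for (int i = 0; i < n; ++i) {
      double acc = 0.0;
      for (int j = 0; j < n; ++j) {
        double w = K(i, j);
        if (w == 0.0) continue;
        int sl = s - Dsteps(i, j);
        acc += w * (sl < 0 ? rest[j] : hist[(size_t)(sl % L) * n + j]);
      }
      cp[i] = acc;
    }
    // white-noise intensity scaling: the held-per-step rate fluctuation has
    // SD sd/sqrt(dt), giving a step-size-invariant spectral density sd^2
    const double nscale = 1.0 / std::sqrt(dt);
    for (int i = 0; i < n; ++i)
      un[i] = P.noise_mean[i] + P.noise_sd[i] * nscale * Z(s, i);
    if (has_ext)
      for (int i = 0; i < n; ++i)
        for (int p = 0; p < 6; ++p)
          extrow[(size_t)i * 6 + p] = ext(s, 6 * i + p);

    const double *extp = has_ext ? extrow.data() : nullptr;
    // Heun predictor
    compute_inputs(P, y.data(), cp.data(), un.data(), extp, u1.data(), rate.data());
    for (int k = 0; k < P.nsyn; ++k) {
      double dz1 = P.a1[k] * u1[k] - P.a2[k] * z[k] - P.a3[k] * y[k];
      yp[k] = y[k] + dt * z[k];
      zp[k] = z[k] + dt * dz1;
    }
    // Heun corrector (held inputs re-evaluated at the predictor state)
    compute_inputs(P, yp.data(), cp.data(), un.data(), extp, u2.data(), rate.data());
    for (int k = 0; k < P.nsyn; ++k) {
      double dz1 = P.a1[k] * u1[k] - P.a2[k] * z[k] - P.a3[k] * y[k];
      double dz2 = P.a1[k] * u2[k] - P.a2[k] * zp[k] - P.a3[k] * yp[k];
      double dy1 = z[k], dy2 = zp[k];
      y[k] += 0.5 * dt * (dy1 + dy2);
      z[k] += 0.5 * dt * (dz1 + dz2);
    }
    for (int i = 0; i < n; ++i) {
      const double *yi = y.data() + (size_t)i * NSYN_CTX;
      for (int k = 0; k < NSYN_CTX; ++k) {
        if (!std::isfinite(yi[k]) || std::fabs(yi[k]) > 1e7) {
          stop("numerical blow-up in region %d at step %d", i + 1, s + 1);
        }
      }
    }
  }

  List out = List::create(_["lfp"] = lfp);
  if (record_pops) out["pops"] = pops;
  return out;
}
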