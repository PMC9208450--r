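#include <Rcpp.h>
#include <cmath>
using namespace Rcpp;

// Fused closed-loop step: plant -> muscle kinematics -> sensors ->
// motoneurons (+ plasticity). Arithmetic mirrors the R reference engine
// (run_simulation_r) operation for operation so the two can be compared
// bit-for-bit in tests.

static inline double clamp(double x, double lo, double hi) {
  return x < lo ? lo : (x > hi ? hi : x);
}

static inline double sensor_eval(int type, double L, double V, double A) {
  double out;
  switch (type) {
  case 1: { // spindle Ia with fusimotor action
    double II = clamp(((L - 0.2) * 1.25 + A) / 2.0, 0.0, 1.0);
    out = ((1.5 + std::log10(A + 0.1)) * V + A + II * 0.2) / 2.0;
    break;
  }
  case 2: // Ia without fusimotor effect (alpha-only)
    out = (L + V) / 2.0;
    break;
  case 3: // Golgi tendon organ Ib
    out = A * L;
    break;
  case 4: { // spindle II
    out = ((L - 0.2) * 1.25 + A) / 2.0;
    break;
  }
  default:
    stop("unknown sensor type");
  }
  return clamp(out, 0.0, 1.0);
}

// [[Rcpp::export(name = ".sim_core")]]
List sim_core(NumericMatrix drive, NumericMatrix W0, int sensor_type,
              List par, Nullable<List> state0, bool learn,
              int snapshot_every, bool record) {
  const int T = drive.nrow();
  if (drive.ncol() != 4 || W0.nrow() != 4 || W0.ncol() != 4)
    stop("drive must be T x 4 and W0 4 x 4");

  const double dt    = as<double>(par["dt"]);
  const double D     = as<double>(par["damping"]);
  const double gain  = as<double>(par["gain"]);
  const double ms    = as<double>(par["muscle_strength"]);
  const double vref  = as<double>(par["v_ref"]);
  const double lim   = as<double>(par["limb_limit"]);
  const double wallL = as<double>(par["wall_left"]);
  const double wallR = as<double>(par["wall_right"]);
  const double off   = as<double>(par["limb_offset"]);
  const double stick = as<double>(par["stiction_fraction"]) * gain * ms *
                       2.0 * lim;
  const double KA    = as<double>(par["K_A"]);
  const double KL    = as<double>(par["K_L"]);
  const double KM    = as<double>(par["K_M"]);
  const double Kleak = as<double>(par["leak_gain"]);
  const double Khp   = as<double>(par["hp_gain"]);
  const double eexp  = as<double>(par["eta_exponent"]);
  const double escl  = as<double>(par["eta_scale"]);
  const double emax  = as<double>(par["eta_max"]);
  const bool apg_shunt = as<bool>(par["apg_shunt"]);
  const double gms   = gain * ms;

  // state
  double extL = 0, extR = 0, body = 0;
  double A[4] = {0, 0, 0, 0};
  double W[16], lsig[16];
  double num[4] = {0, 0, 0, 0}, den[4] = {0, 0, 0, 0};
  double leak_tr[4] = {0, 0, 0, 0}, Pbar[4] = {0, 0, 0, 0};
  double lp[4] = {0, 0, 0, 0}, P[4] = {0, 0, 0, 0};
  for (int i = 0; i < 4; ++i)
    for (int j = 0; j < 4; ++j) { W[i * 4 + j] = W0(i, j); lsig[i * 4 + j] = 0; }

  if (state0.isNotNull()) {
    List st(state0);
    NumericVector w = st["W"], ls = st["l"], a = st["A"], nu = st["num"],
                  de = st["den"], lt = st["leak_trace"], pb = st["Pbar"],
                  lpv = st["lp"], pv = st["P"];
    extL = as<double>(st["ext_l"]); extR = as<double>(st["ext_r"]);
    body = as<double>(st["body"]);
    for (int i = 0; i < 4; ++i) {
      A[i] = a[i]; num[i] = nu[i]; den[i] = de[i]; leak_tr[i] = lt[i];
      Pbar[i] = pb[i]; lp[i] = lpv[i]; P[i] = pv[i];
    }
    for (int j = 0; j < 16; ++j) { W[j] = w[j]; lsig[j] = ls[j]; }
  }

  const int nsnap = snapshot_every > 0 ? T / snapshot_every : 0;
  NumericMatrix snaps(nsnap, 17);
  int isnap = 0;
  NumericMatrix traces(record ? T : 0, record ? 19 : 0);

  double sens[4], Lno[4], V[4], Anew[4];

  for (int t = 0; t < T; ++t) {
    // --- plant update (uses activations from the previous step) ---
    double sLE = lim - extL, sLF = lim + extL;
    double sRF = lim + extR, sRE = lim - extR;
    if (sLE < 0) sLE = 0; if (sLF < 0) sLF = 0;
    if (sRF < 0) sRF = 0; if (sRE < 0) sRE = 0;
    double fL = gms * (A[0] * sLE - A[1] * sLF);
    double fR = gms * (A[3] * sRE - A[2] * sRF);
    double newL = extL + (fL / D) * dt;
    double newR = extR + (fR / D) * dt;
    double ubL = std::min(lim, body - off - wallL);
    double ubR = std::min(lim, wallR - off - body);
    newL = clamp(newL, -lim, ubL);
    newR = clamp(newR, -lim, ubR);
    double gap = newL + newR + 2.0 * off; // limb-limb contact when < 0
    if (gap < 0) { newL -= gap / 2.0; newR -= gap / 2.0; }
    double vL = (newL - extL) / dt, vR = (newR - extR) / dt;

    // body: propulsion only when braced on both walls, above stiction
    double pL = body - off - newL, pR = body + off + newR;
    double FLW = 0, FRW = 0;
    if (pL <= wallL + 1e-9) {
      FLW = gms * (lim + newL) * (A[0] - A[1]);
      if (FLW < 0) FLW = 0;
    }
    if (pR >= wallR - 1e-9) {
      FRW = -gms * (lim + newR) * (A[3] - A[2]);
      if (FRW > 0) FRW = 0;
    }
    if (FLW > 0 && FRW < 0) {
      double FB = FLW - FRW;
      if (std::fabs(FB) > stick) body += (FB / D) * dt;
    }
    extL = newL; extR = newR;

    // --- normalized muscle kinematics ---
    Lno[0] = 0.2 + 0.1 * (lim - extL); Lno[1] = 0.2 + 0.1 * (lim + extL);
    Lno[2] = 0.2 + 0.1 * (lim + extR); Lno[3] = 0.2 + 0.1 * (lim - extR);
    V[0] = clamp(0.1 * (-vL) / vref, -1.0, 1.0);
    V[1] = clamp(0.1 * ( vL) / vref, -1.0, 1.0);
    V[2] = clamp(0.1 * ( vR) / vref, -1.0, 1.0);
    V[3] = clamp(0.1 * (-vR) / vref, -1.0, 1.0);

    // --- sensors (beta-MN fusimotor: activation of the same muscle) ---
    for (int m = 0; m < 4; ++m)
      sens[m] = sensor_eval(sensor_type, Lno[m], V[m], A[m]);

    // --- motoneurons and plasticity ---
    for (int i = 0; i < 4; ++i) {
      double syn = 0; // learnable (sensory) synapses
      for (int j = 0; j < 4; ++j) {
        double wp = W[i * 4 + j] > 0 ? W[i * 4 + j] : 0.0;
        syn += sens[j] * wp;
      }
      // fixed drive synapse (w = 1, excitatory) always excites; it shunts
      // only when apg_shunt is set (see package vignette)
      double ss = syn + drive(t, i);
      double sd = apg_shunt ? ss : syn;
      num[i] = num[i] * (1 - KA) + ss * KA;
      den[i] = den[i] * (1 - KA) + sd * KA;
      leak_tr[i] = leak_tr[i] * (1 - Kleak) + sd * Kleak;
      double k = std::max(0.5, 2.0 * leak_tr[i]);
      P[i] = clamp(num[i] / (k + den[i]), -1.0, 1.0);
      double Pp = P[i] > 0 ? P[i] : 0.0;
      Pbar[i] = Pbar[i] * (1 - KM) + Pp * KM;
      lp[i] = lp[i] * (1 - Khp) + P[i] * Khp;
      double hp = P[i] - lp[i];
      if (learn) {
        double eta = escl * std::pow(Pbar[i], eexp);
        if (eta > emax) eta = emax;
        if (eta < 0) eta = 0;
        for (int j = 0; j < 4; ++j) {
          int ij = i * 4 + j;
          double drv = sens[j] * W[ij] * (hp - Pbar[i]);
          lsig[ij] = clamp(lsig[ij] * (1 - KL) + drv * KL, -1.0, 1.0);
          double c = lsig[ij] >= 0 ? 1.0 - W[ij] : W[ij];
          W[ij] = clamp(W[ij] + lsig[ij] * eta * c, -1.0, 1.0);
        }
      }
      Anew[i] = std::max(0.0, (Pp - 0.1) / 0.9);
    }
    for (int i = 0; i < 4; ++i) A[i] = Anew[i];

    if ((t & 1023) == 0 &&
        (!std::isfinite(P[0]) || !std::isfinite(extL) || !std::isfinite(extR)))
      stop("non-finite state at step %d", t);

    if (snapshot_every > 0 && (t + 1) % snapshot_every == 0 && isnap < nsnap) {
      snaps(isnap, 0) = (t + 1) * dt;
      for (int j = 0; j < 16; ++j) snaps(isnap, j + 1) = W[j];
      ++isnap;
    }
    if (record) {
      for (int i = 0; i < 4; ++i) {
        traces(t, i) = P[i];
        traces(t, 4 + i) = A[i];
        traces(t, 8 + i) = sens[i];
      }
      traces(t, 12) = extL; traces(t, 13) = extR; traces(t, 14) = body;
      traces(t, 15) = vL; traces(t, 16) = vR;
      traces(t, 17) = FLW; traces(t, 18) = FRW;
    }
  }

  NumericMatrix Wout(4, 4);
  NumericVector Wflat(16), lflat(16);
  for (int i = 0; i < 4; ++i)
    for (int j = 0; j < 4; ++j) {
      Wout(i, j) = W[i * 4 + j];
      Wflat[i * 4 + j] = W[i * 4 + j];
      lflat[i * 4 + j] = lsig[i * 4 + j];
    }
  List state = List::create(
    _["ext_l"] = extL, _["ext_r"] = extR, _["body"] = body,
    _["A"] = NumericVector(A, A + 4),
    _["num"] = NumericVector(num, num + 4),
    _["den"] = NumericVector(den, den + 4),
    _["leak_trace"] = NumericVector(leak_tr, leak_tr + 4),
    _["Pbar"] = NumericVector(Pbar, Pbar + 4),
    _["lp"] = NumericVector(lp, lp + 4),
    _["P"] = NumericVector(P, P + 4),
    _["W"] = Wflat, _["l"] = lflat);
  return List::create(_["W"] = Wout, _["snapshots"] = snaps,
                      _["state"] = state, _["traces"] = traces,
                      _["n_steps"] = T);
}
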