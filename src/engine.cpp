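// Compiled kernels: bonded + remote energy/forces, BAOAB Langevin integrator,
// and a worm-like-chain sampler. Units: Angstrom, ps, kcal/mol, Dalton.

#include <Rcpp.h>
#include <cmath>
#include <vector>
using namespace Rcpp;

static const double KB = 1.987204e-3;    // kcal/mol/K
static const double ACC = 418.4;         // (kcal/mol/A)/Da -> A/ps^2
static const double COULOMB = 332.0637;  // kcal*A/(mol*e^2)

// truncated quartic polynomial: E = K2 d^2 + K3 d^3 + K4 d^4, d = x - x0
static inline double poly_e(double d, double K2, double K3, double K4,
                            double *dEdx) {
  *dEdx = d * (2.0 * K2 + d * (3.0 * K3 + d * 4.0 * K4));
  return d * d * (K2 + d * (K3 + d * K4));
}

static inline int bp_sep(int a, int b, int nbp, bool circular) {
  int d = a > b ? a - b : b - a;
  if (circular && nbp - d < d) d = nbp - d;
  return d;
}

struct RemotePar {
  double q, sigma, epsLJ, epsR, kappa, cutoff;
};

// channels: 0 stacking, 1 pairing, 2 fan, 3 distant, 4 angle, 5 LJ, 6 ele
static void eval_bonded(const std::vector<double> &x, int n,
                        const NumericMatrix &bonds, const NumericMatrix &angles,
                        std::vector<double> &f, double *channels) {
  const int nb = bonds.nrow();
  for (int b = 0; b < nb; ++b) {
    int i = (int)bonds(b, 0) - 1, j = (int)bonds(b, 1) - 1;
    double dx = x[j] - x[i], dy = x[j + n] - x[i + n], dz = x[j + 2 * n] - x[i + 2 * n];
    double r = std::sqrt(dx * dx + dy * dy + dz * dz);
    double dEdr;
    double e = poly_e(r - bonds(b, 5), bonds(b, 2), bonds(b, 3), bonds(b, 4), &dEdr);
    int ch = (int)bonds(b, 6) - 1;
    channels[ch] += e;
    if (r > 1e-12) {
      double g = dEdr / r;
      f[i] += g * dx; f[i + n] += g * dy; f[i + 2 * n] += g * dz;
      f[j] -= g * dx; f[j + n] -= g * dy; f[j + 2 * n] -= g * dz;
    }
  }
  const int na = angles.nrow();
  for (int a = 0; a < na; ++a) {
    int ia = (int)angles(a, 0) - 1, ib = (int)angles(a, 1) - 1, ic = (int)angles(a, 2) - 1;
    double ux = x[ia] - x[ib], uy = x[ia + n] - x[ib + n], uz = x[ia + 2 * n] - x[ib + 2 * n];
    double vx = x[ic] - x[ib], vy = x[ic + n] - x[ib + n], vz = x[ic + 2 * n] - x[ib + 2 * n];
    double nu = std::sqrt(ux * ux + uy * uy + uz * uz);
    double nv = std::sqrt(vx * vx + vy * vy + vz * vz);
    double ct = (ux * vx + uy * vy + uz * vz) / (nu * nv);
    if (ct > 1.0) ct = 1.0; else if (ct < -1.0) ct = -1.0;
    double theta = std::acos(ct);
    double dEdt;
    channels[4] += poly_e(theta - angles(a, 6), angles(a, 3), angles(a, 4),
                          angles(a, 5), &dEdt);
    double st = std::sqrt(1.0 - ct * ct);
    if (st < 1e-8) st = 1e-8;
    // dtheta/da = -(v_hat - ct*u_hat)/(nu*st); F = -dE/dtheta * dtheta/dx
    double cda = dEdt / (nu * st), cdc = dEdt / (nv * st);
    double uhx = ux / nu, uhy = uy / nu, uhz = uz / nu;
    double vhx = vx / nv, vhy = vy / nv, vhz = vz / nv;
    double fax = cda * (vhx - ct * uhx), fay = cda * (vhy - ct * uhy), faz = cda * (vhz - ct * uhz);
    double fcx = cdc * (uhx - ct * vhx), fcy = cdc * (uhy - ct * vhy), fcz = cdc * (uhz - ct * vhz);
    f[ia] += fax; f[ia + n] += fay; f[ia + 2 * n] += faz;
    f[ic] += fcx; f[ic + n] += fcy; f[ic + 2 * n] += fcz;
    f[ib] -= fax + fcx; f[ib + n] -= fay + fcy; f[ib + 2 * n] -= faz + fcz;
  }
}

static inline void remote_pair(const std::vector<double> &x, int n, int i, int j,
                               const RemotePar &rp, std::vector<double> &f,
                               double *channels) {
  double dx = x[j] - x[i], dy = x[j + n] - x[i + n], dz = x[j + 2 * n] - x[i + 2 * n];
  double r2 = dx * dx + dy * dy + dz * dz;
  if (r2 >= rp.cutoff * rp.cutoff) return;
  if (r2 < 1e-20)
    stop("overlapping beads %d and %d in remote term (r = 0)", i + 1, j + 1);
  double r = std::sqrt(r2);
  double sr2 = rp.sigma * rp.sigma / r2;
  double sr6 = sr2 * sr2 * sr2;
  double elj = 4.0 * rp.epsLJ * (sr6 * sr6 - sr6);
  double dljdr = 4.0 * rp.epsLJ * (-12.0 * sr6 * sr6 + 6.0 * sr6) / r;
  double eel = COULOMB * rp.q * rp.q * std::exp(-rp.kappa * r) / (rp.epsR * r);
  double deldr = -eel * (rp.kappa + 1.0 / r);
  channels[5] += elj;
  channels[6] += eel;
  double g = (dljdr + deldr) / r;
  f[i] += g * dx; f[i + n] += g * dy; f[i + 2 * n] += g * dz;
  f[j] -= g * dx; f[j + n] -= g * dy; f[j + 2 * n] -= g * dz;
}

static void eval_remote_direct(const std::vector<double> &x, int n,
                               const RemotePar &rp, const IntegerVector &bpPos,
                               int nbp, bool circular, std::vector<double> &f,
                               double *channels) {
  for (int i = 0; i < n; ++i)
    for (int j = i + 1; j < n; ++j) {
      if (bp_sep(bpPos[i], bpPos[j], nbp, circular) <= 5) continue;
      remote_pair(x, n, i, j, rp, f, channels);
    }
}

struct NeighborList {
  std::vector<int> pi, pj;
  std::vector<double> x0;
  double skin;
  void build(const std::vector<double> &x, int n, const RemotePar &rp,
             const IntegerVector &bpPos, int nbp, bool circular) {
    pi.clear(); pj.clear();
    double rl = rp.cutoff + skin;
    double rl2 = rl * rl;
    for (int i = 0; i < n; ++i)
      for (int j = i + 1; j < n; ++j) {
        if (bp_sep(bpPos[i], bpPos[j], nbp, circular) <= 5) continue;
        double dx = x[j] - x[i], dy = x[j + n] - x[i + n], dz = x[j + 2 * n] - x[i + 2 * n];
        if (dx * dx + dy * dy + dz * dz < rl2) { pi.push_back(i); pj.push_back(j); }
      }
    x0 = x;
  }
  bool stale(const std::vector<double> &x, int n) const {
    double lim = 0.25 * skin * skin;  // (skin/2)^2
    for (int i = 0; i < n; ++i) {
      double dx = x[i] - x0[i], dy = x[i + n] - x0[i + n], dz = x[i + 2 * n] - x0[i + 2 * n];
      if (dx * dx + dy * dy + dz * dz > lim) return true;
    }
    return false;
  }
  void eval(const std::vector<double> &x, int n, const RemotePar &rp,
            std::vector<double> &f, double *channels) const {
    for (size_t k = 0; k < pi.size(); ++k)
      remote_pair(x, n, pi[k], pj[k], rp, f, channels);
  }
};

static RemotePar as_remote(const List &remote) {
  RemotePar rp;
  rp.q = as<double>(remote["q"]);
  rp.sigma = as<double>(remote["sigma"]);
  rp.epsLJ = as<double>(remote["epsLJ"]);
  rp.epsR = as<double>(remote["epsR"]);
  rp.kappa = as<double>(remote["kappa"]);
  rp.cutoff = as<double>(remote["cutoff"]);
  return rp;
}

// [[Rcpp::export]]
List cpp_energy_forces(NumericMatrix coords, NumericMatrix bonds,
                       NumericMatrix angles, bool doRemote, List remote,
                       IntegerVector bpPos, int nbp, bool circular,
                       std::string remoteMethod = "direct",
                       double skin = 2.0) {
  const int n = coords.nrow();
  std::vector<double> x(coords.begin(), coords.end());
  std::vector<double> f(3 * n, 0.0);
  double channels[7] = {0, 0, 0, 0, 0, 0, 0};
  eval_bonded(x, n, bonds, angles, f, channels);
  if (doRemote) {
    RemotePar rp = as_remote(remote);
    if (remoteMethod == "direct") {
      eval_remote_direct(x, n, rp, bpPos, nbp, circular, f, channels);
    } else if (remoteMethod == "list") {
      NeighborList nl; nl.skin = skin;
      nl.build(x, n, rp, bpPos, nbp, circular);
      nl.eval(x, n, rp, f, channels);
    } else {
      stop("unknown remote method '%s' (direct, list)", remoteMethod.c_str());
    }
  }
  NumericMatrix forces(n, 3);
  for (int i = 0; i < n; ++i) {
    forces(i, 0) = f[i]; forces(i, 1) = f[i + n]; forces(i, 2) = f[i + 2 * n];
  }
  NumericVector en = NumericVector::create(
      _["stacking"] = channels[0], _["pairing"] = channels[1],
      _["fan"] = channels[2], _["distant"] = channels[3],
      _["angle"] = channels[4], _["LJ"] = channels[5],
      _["electrostatic"] = channels[6]);
  return List::create(_["energies"] = en, _["forces"] = forces,
                      _["total"] = channels[0] + channels[1] + channels[2] +
                                   channels[3] + channels[4] + channels[5] +
                                   channels[6]);
}

// Box-Muller normal deviates from the seeded uniform stream (R RNG).
struct BoxMuller {
  bool have;
  double spare;
  BoxMuller() : have(false), spare(0.0) {}
  double next() {
    if (have) { have = false; return spare; }
    double u1 = unif_rand(), u2 = unif_rand();
    while (u1 <= 1e-300) u1 = unif_rand();
    double m = std::sqrt(-2.0 * std::log(u1));
    spare = m * std::sin(2.0 * M_PI * u2);
    have = true;
    return m * std::cos(2.0 * M_PI * u2);
  }
};

// BAOAB Langevin velocity-Verlet. Returns saved frames, energy log, final
// state. Aborts with the offending step index on non-finite forces/coords.
// [[Rcpp::export]]
List cpp_run_langevin(NumericMatrix coords, NumericMatrix vels,
                      NumericVector masses, NumericMatrix bonds,
                      NumericMatrix angles, bool doRemote, List remote,
                      IntegerVector bpPos, int nbp, bool circular,
                      double dt, double gamma, double temperature,
                      int nSteps, int stride, int logEvery,
                      double skin = 2.0) {
  const int n = coords.nrow();
  std::vector<double> x(coords.begin(), coords.end());
  std::vector<double> v(vels.begin(), vels.end());
  std::vector<double> f(3 * n, 0.0);
  std::vector<double> invm(n), sigv(n);
  for (int i = 0; i < n; ++i) {
    invm[i] = ACC / masses[i];
    sigv[i] = std::sqrt(ACC * KB * temperature / masses[i]);
  }
  const double c1 = std::exp(-gamma * dt);
  const double c2 = std::sqrt(1.0 - c1 * c1);
  const double hdt = 0.5 * dt;
  BoxMuller bm;
  RemotePar rp;
  NeighborList nl; nl.skin = skin;
  if (doRemote) {
    rp = as_remote(remote);
    nl.build(x, n, rp, bpPos, nbp, circular);
  }
  double channels[7];
  double checksum;

  auto forces = [&]() {
    std::fill(f.begin(), f.end(), 0.0);
    std::fill(channels, channels + 7, 0.0);
    eval_bonded(x, n, bonds, angles, f, channels);
    if (doRemote) {
      if (nl.stale(x, n)) nl.build(x, n, rp, bpPos, nbp, circular);
      nl.eval(x, n, rp, f, channels);
    }
    checksum = 0.0;
    for (int i = 0; i < 3 * n; ++i) checksum += f[i];
  };

  forces();
  int nf = nSteps / stride + 1;
  NumericVector framesOut(Dimension(n, 3, nf));
  NumericVector times(nf);
  int fi = 0;
  auto save = [&](int step) {
    for (int i = 0; i < n; ++i) {
      framesOut[fi * 3 * n + i] = x[i];
      framesOut[fi * 3 * n + n + i] = x[i + n];
      framesOut[fi * 3 * n + 2 * n + i] = x[i + 2 * n];
    }
    times[fi] = step * dt;
    ++fi;
  };
  save(0);

  int nlog = (logEvery > 0) ? (nSteps / logEvery + 1) : 0;
  NumericMatrix elog(nlog, 10);
  int li = 0;
  double keMid = -1.0;  // kinetic energy at the thermostat point of the step
  auto kinetic = [&]() {
    double ke = 0.0;
    for (int i = 0; i < n; ++i)
      ke += 0.5 * masses[i] *
            (v[i] * v[i] + v[i + n] * v[i + n] + v[i + 2 * n] * v[i + 2 * n]) / ACC;
    return ke;
  };
  auto logE = [&](int step) {
    if (li >= nlog) return;
    // post-O velocities sample the Maxwell distribution without the on-step
    // Verlet bias; fall back to on-step velocities when there is no bath
    double ke = (keMid >= 0.0) ? keMid : kinetic();
    elog(li, 0) = step;
    double tot = ke;
    for (int c = 0; c < 7; ++c) { elog(li, c + 1) = channels[c]; tot += channels[c]; }
    elog(li, 8) = ke;
    elog(li, 9) = tot;
    ++li;
  };
  if (logEvery > 0) logE(0);

  for (int step = 1; step <= nSteps; ++step) {
    // B
    for (int i = 0; i < n; ++i) {
      double a = invm[i];
      v[i] += hdt * f[i] * a;
      v[i + n] += hdt * f[i + n] * a;
      v[i + 2 * n] += hdt * f[i + 2 * n] * a;
    }
    // A
    for (int i = 0; i < 3 * n; ++i) x[i] += hdt * v[i];
    // O
    if (gamma > 0.0 && temperature >= 0.0) {
      for (int i = 0; i < n; ++i) {
        double s = c2 * sigv[i];
        v[i] = c1 * v[i] + s * bm.next();
        v[i + n] = c1 * v[i + n] + s * bm.next();
        v[i + 2 * n] = c1 * v[i + 2 * n] + s * bm.next();
      }
      if (logEvery > 0 && step % logEvery == 0) keMid = kinetic();
    }
    // A
    for (int i = 0; i < 3 * n; ++i) x[i] += hdt * v[i];
    // B
    forces();
    if (!std::isfinite(checksum))
      stop("non-finite force at step %d (simulation diverged)", step);
    for (int i = 0; i < n; ++i) {
      double a = invm[i];
      v[i] += hdt * f[i] * a;
      v[i + n] += hdt * f[i + n] * a;
      v[i + 2 * n] += hdt * f[i + 2 * n] * a;
    }
    if (step % stride == 0) {
      double cs = 0.0;
      for (int i = 0; i < 3 * n; ++i) cs += x[i];
      if (!std::isfinite(cs))
        stop("non-finite coordinate at step %d (simulation diverged)", step);
      save(step);
    }
    if (logEvery > 0 && step % logEvery == 0) logE(step);
  }

  NumericMatrix xf(n, 3), vf(n, 3);
  for (int i = 0; i < n; ++i)
    for (int d = 0; d < 3; ++d) { xf(i, d) = x[i + d * n]; vf(i, d) = v[i + d * n]; }
  colnames(elog) = CharacterVector::create(
      "step", "stacking", "pairing", "fan", "distant", "angle", "LJ",
      "electrostatic", "kinetic", "total");
  return List::create(_["frames"] = framesOut, _["times"] = times,
                      _["coords"] = xf, _["velocities"] = vf,
                      _["energyLog"] = elog, _["nSaved"] = fi);
}

// Discrete worm-like chains: per step the local frame is bent by independent
// Gaussian angles about its two transverse axes (sd bendSd each), so
// <beta^2> = 2 bendSd^2 and PL ~= stepLen / bendSd^2. Returns the vertex
// curves, (nSteps+1) x 3 x nFrames.
// [[Rcpp::export]]
NumericVector cpp_wlc_curves(int nSteps, int nFrames, double stepLen,
                             double bendSd) {
  NumericVector out(Dimension(nSteps + 1, 3, nFrames));
  BoxMuller bm;
  int npt = nSteps + 1;
  for (int fr = 0; fr < nFrames; ++fr) {
    double t[3] = {0, 0, 1}, e1[3] = {1, 0, 0}, e2[3] = {0, 1, 0};
    double p[3] = {0, 0, 0};
    out[fr * 3 * npt] = 0; out[fr * 3 * npt + npt] = 0; out[fr * 3 * npt + 2 * npt] = 0;
    for (int s = 1; s <= nSteps; ++s) {
      double a1 = bendSd * bm.next(), a2 = bendSd * bm.next();
      // rotate t about e1 by a1: t' = cos*t + sin*(e1 x t); e2 follows
      double c = std::cos(a1), sn = std::sin(a1);
      double cx = e1[1] * t[2] - e1[2] * t[1], cy = e1[2] * t[0] - e1[0] * t[2],
             cz = e1[0] * t[1] - e1[1] * t[0];
      double tn[3] = {c * t[0] + sn * cx, c * t[1] + sn * cy, c * t[2] + sn * cz};
      double e2n[3];
      cx = e1[1] * e2[2] - e1[2] * e2[1]; cy = e1[2] * e2[0] - e1[0] * e2[2];
      cz = e1[0] * e2[1] - e1[1] * e2[0];
      // e2 is not orthogonal to e1's rotation? e2 rotates the same way
      e2n[0] = c * e2[0] + sn * cx; e2n[1] = c * e2[1] + sn * cy; e2n[2] = c * e2[2] + sn * cz;
      // rotate about e2n by a2
      c = std::cos(a2); sn = std::sin(a2);
      cx = e2n[1] * tn[2] - e2n[2] * tn[1]; cy = e2n[2] * tn[0] - e2n[0] * tn[2];
      cz = e2n[0] * tn[1] - e2n[1] * tn[0];
      double t2[3] = {c * tn[0] + sn * cx, c * tn[1] + sn * cy, c * tn[2] + sn * cz};
      double e1n[3];
      cx = e2n[1] * e1[2] - e2n[2] * e1[1]; cy = e2n[2] * e1[0] - e2n[0] * e1[2];
      cz = e2n[0] * e1[1] - e2n[1] * e1[0];
      e1n[0] = c * e1[0] + sn * cx; e1n[1] = c * e1[1] + sn * cy; e1n[2] = c * e1[2] + sn * cz;
      // re-orthonormalize
      double nt = std::sqrt(t2[0] * t2[0] + t2[1] * t2[1] + t2[2] * t2[2]);
      for (int d = 0; d < 3; ++d) t[d] = t2[d] / nt;
      double dot = e1n[0] * t[0] + e1n[1] * t[1] + e1n[2] * t[2];
      for (int d = 0; d < 3; ++d) e1n[d] -= dot * t[d];
      double ne1 = std::sqrt(e1n[0] * e1n[0] + e1n[1] * e1n[1] + e1n[2] * e1n[2]);
      for (int d = 0; d < 3; ++d) e1[d] = e1n[d] / ne1;
      e2[0] = t[1] * e1[2] - t[2] * e1[1];
      e2[1] = t[2] * e1[0] - t[0] * e1[2];
      e2[2] = t[0] * e1[1] - t[1] * e1[0];
      for (int d = 0; d < 3; ++d) p[d] += stepLen * t[d];
      out[fr * 3 * npt + 0 * npt + s] = p[0];
      out[fr * 3 * npt + 1 * npt + s] = p[1];
      out[fr * 3 * npt + 2 * npt + s] = p[2];
    }
  }
  return out;
}
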