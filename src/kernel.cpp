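#include <Rcpp.h>
#include <cmath>
#include <cstdint>
using namespace Rcpp;

// xoshiro256+ for the per-domain nucleotide flips: the only hot RNG path.
// Seeded from R's RNG stream at kernel entry, so set.seed() at the R level
// fixes the whole trajectory.
namespace {
struct Xoshiro {
  uint64_t s[4];
  static uint64_t splitmix(uint64_t& x) {
    uint64_t z = (x += 0x9e3779b97f4a7c15ULL);
    z = (z ^ (z >> 30)) * 0xbf58476d1ce4e5b9ULL;
    z = (z ^ (z >> 27)) * 0x94d049bb133111ebULL;
    return z ^ (z >> 31);
  }
  explicit Xoshiro(uint64_t seed) {
    for (int i = 0; i < 4; ++i) s[i] = splitmix(seed);
  }
  static uint64_t rotl(uint64_t x, int k) { return (x << k) | (x >> (64 - k)); }
  double next() {
    const uint64_t result = s[0] + s[3];
    const uint64_t t = s[1] << 17;
    s[2] ^= s[0]; s[3] ^= s[1]; s[1] ^= s[2]; s[0] ^= s[3];
    s[2] ^= t; s[3] = rotl(s[3], 45);
    return (result >> 11) * 0x1.0p-53;
  }
};
} // namespace

// Free-KaiA conservation: the left-hand side of
//   xA + xA/V * sum_k[ g_k pB0_k / (1 + xA g_k) ]
//      + (xA gCBA / (1 + xA gCBA)) * SB/V  =  AT/(2V)
// is continuous and strictly increasing in xA, so the root on [0, AT/(2V)]
// exists and is unique. Safeguarded Newton with bisection fallback.
// All arguments already in concentration units (counts / V).
static double solve_xA(const std::vector<double>& g,
                       const std::vector<double>& pB0,
                       double SBc, double Vinv, double gCBA, double AT2c,
                       double x0, int* err) {
  const int N = (int)g.size();
  if (AT2c <= 0.0) return 0.0;
  double lo = 0.0, hi = AT2c;
  double x = (x0 > 0.0 && x0 < AT2c) ? x0 : 0.5 * AT2c;
  const double tol = 1e-10 * AT2c;
  for (int it = 0; it < 100; ++it) {
    double acc = 0.0, accp = 0.0;
    for (int k = 0; k < N; ++k) {
      double d = 1.0 / (1.0 + x * g[k]);
      double w = g[k] * pB0[k] * d;
      acc  += w;
      accp += w * d;
    }
    double dB = 1.0 / (1.0 + x * gCBA);
    double f  = x - AT2c + x * Vinv * acc + x * gCBA * dB * SBc;
    double fp = 1.0 + Vinv * accp + gCBA * dB * dB * SBc;
    if (std::fabs(f) < tol) return x;
    if (f > 0.0) hi = x; else lo = x;
    double xn = x - f / fp;
    if (!(xn > lo && xn < hi)) xn = 0.5 * (lo + hi);
    if (std::fabs(xn - x) < 1e-14 * AT2c + 1e-300) return xn;
    x = xn;
  }
  if (hi - lo < 1e-8 * AT2c) return 0.5 * (lo + hi);
  *err = 1;
  return x;
}

// Advance the ensemble n_steps of width dt, recording every record_every
// steps. Rate constants in `pars` are the effective (temperature-scaled)
// values; d0..d4 are in kB*T0 units and `t_ratio` = T0[K]/T[K] supplies
// beta in the structural quasi-equilibrium. Concentrations are counts / V.
// Update order per step: (i) stochastic nucleotide flips in the CI domains,
// (ii) structure-dependent rate constants, (iii) Euler update of the KaiB
// ring occupancy pB, (iv) free KaiA/KaiB from conservation, then pA from the
// CII quasi-equilibrium, (v) Euler update of D, (vi) the structural
// quasi-equilibrium X (self-consistent fixed point by default).
// [[Rcpp::export]]
List kai_kernel(List state, List pars, int n_steps, int record_every,
                IntegerVector track) {
  NumericVector pA = clone(as<NumericVector>(state["pA"]));
  NumericMatrix pB = clone(as<NumericMatrix>(state["pB"])); // N x 7
  NumericVector D  = clone(as<NumericVector>(state["D"]));
  NumericVector X  = clone(as<NumericVector>(state["X"]));
  IntegerMatrix q  = clone(as<IntegerMatrix>(state["q"]));  // N x 6
  double xA = as<double>(state["xA"]);
  double xB = as<double>(state["xB"]);
  double t0 = as<double>(state["t"]);

  const int N = pA.size();
  const double dt   = as<double>(pars["dt"]);
  const double hA0  = as<double>(pars["hA0"]),  fA0 = as<double>(pars["fA0"]);
  const double hB0  = as<double>(pars["hB0"]),  fB0 = as<double>(pars["fB0"]);
  const double gCBA = as<double>(pars["hAB"]) / as<double>(pars["fAB"]);
  const double kp   = as<double>(pars["kp"]),   kdp = as<double>(pars["kdp"]);
  const double fhyd = as<double>(pars["f_hyd"]);
  const double dADP0 = as<double>(pars["dADP0"]); // effective lifetime scale
  const double d0 = as<double>(pars["d0"]), d1 = as<double>(pars["d1"]),
               d2 = as<double>(pars["d2"]), d3 = as<double>(pars["d3"]),
               d4 = as<double>(pars["d4"]);
  const double AX = as<double>(pars["A_X"]), BX = as<double>(pars["B_X"]),
               CX = as<double>(pars["C_X"]);
  const double P0   = as<double>(pars["P0"]);
  const double AT2c = as<double>(pars["AT2c"]), BTc = as<double>(pars["BTc"]);
  const double Vinv = as<double>(pars["Vinv"]);
  const double t_ratio = as<double>(pars["t_ratio"]); // T0[K]/T[K]
  const bool   incl0   = as<bool>(pars["include_pB0"]);
  // ADP release scheme: 0 = memoryless hazard dt/Delta(X) (exponential
  // lifetimes), 1 = aging clock da = dt/Delta(X(t)) with release at a >= 1
  // (lifetime tracks the structure but is sharply peaked at Delta)
  const int adp_scheme = as<int>(pars["adp_scheme"]);
  // X update: 1 = self-consistent fixed point of
  //   X = (1 + tanh(beta*(c - d4*X)))/2   (unique: RHS decreases in X),
  // using F(q,X) = q*X - (1-q)*(1-X) = X - (1-q); 0 = one-step lag.
  const int x_scheme = as<int>(pars["x_scheme"]);
  const double neg_tol = 1e-9;
  const double p_hyd = fhyd * dt;
  if (p_hyd >= 1.0) stop("step size too large: f_hyd*dt >= 1");
  const bool shareAB = (AX == BX);

  const int n_rec = n_steps / record_every;
  NumericMatrix rec(n_rec, 7); // t, D_mean, X_mean, q_mean, releases, xA, xB
  const int n_tr = track.size();
  NumericMatrix trD(n_tr > 0 ? n_rec : 0, n_tr);
  NumericMatrix trX(n_tr > 0 ? n_rec : 0, n_tr);

  std::vector<double> g(N), pB0v(N);
  std::vector<int8_t> qv(6 * N);
  std::vector<double> pBv(7 * N);
  std::vector<double> age(6 * N, 0.0);
  for (int k = 0; k < N; ++k) {
    for (int i = 0; i < 6; ++i) qv[6 * k + i] = (int8_t)q(k, i);
    for (int i = 0; i < 7; ++i) pBv[7 * k + i] = pB(k, i);
  }
  if (state.containsElementNamed("adp_age")) {
    NumericVector a0 = as<NumericVector>(state["adp_age"]);
    if (a0.size() == 6 * N) for (int i = 0; i < 6 * N; ++i) age[i] = a0[i];
  }
  double* pAp = REAL(pA);
  double* Dp  = REAL(D);
  double* Xp  = REAL(X);

  RNGScope scope;
  // continue the internal stream across kernel calls when the caller hands
  // back a previous state (so segmented runs are bit-identical to
  // unsegmented ones); otherwise seed it from R's RNG
  Xoshiro rng((uint64_t)(unif_rand() * 9007199254740992.0));
  if (state.containsElementNamed("rng_state")) {
    NumericVector rs = as<NumericVector>(state["rng_state"]);
    if (rs.size() == 8) {
      for (int i = 0; i < 4; ++i) {
        rng.s[i] = ((uint64_t)(uint32_t)rs[2 * i] << 32) |
                   (uint64_t)(uint32_t)rs[2 * i + 1];
      }
    }
  }

  int solver_err = 0, neg_err = 0;
  long releases_acc = 0;
  int irec = 0;
  double max_resid = 0.0; // worst free-KaiA conservation residual

  for (int s = 1; s <= n_steps; ++s) {
    double SB = 0.0; // total bound KaiB monomers (counts)
    for (int k = 0; k < N; ++k) {
      const double y = 2.0 * Xp[k] - 1.0;
      const double tA = std::tanh(y / AX);
      // tanh(y/2) = t / (1 + sqrt(1 - t^2)) with t = tanh(y) lets the
      // default C_X = 2*A_X case reuse the same tanh
      const double tB = shareAB ? tA : std::tanh(y / BX);
      const double tC = (CX == 2.0 * AX)
        ? tA / (1.0 + std::sqrt(1.0 - tA * tA))
        : std::tanh(y / CX);

      // (i) ATPase: hydrolysis 0->1 with prob f_hyd*dt, ADP release 1->0
      // with hazard dt / Delta_ADP(X)
      double dl = dADP0 * (1.0 - tC);
      double inv_dl = (dl > 0.0) ? dt / dl : 2.0;
      double p_rel = inv_dl > 1.0 ? 1.0 : inv_dl;
      int8_t* qk = &qv[6 * k];
      double* ak = &age[6 * k];
      for (int i = 0; i < 6; ++i) {
        double u = rng.next();
        if (qk[i] == 0) {
          if (u < p_hyd) { qk[i] = 1; ak[i] = 0.0; }
        } else if (adp_scheme == 0) {
          if (u < p_rel) { qk[i] = 0; ++releases_acc; }
        } else {
          ak[i] += inv_dl;
          if (ak[i] >= 1.0) { qk[i] = 0; ++releases_acc; }
        }
      }

      // (ii) structure-dependent rates from the current (lagged) X
      double fA = fA0 * (1.0 - tA);
      g[k] = (fA > 0.0) ? hA0 * (1.0 + tA) / fA : 1e300;
      double hBx = hB0 * (1.0 - tB) * xB, fB = fB0 * (1.0 + tB);

      // (iii) KaiB ring: explicit Euler on the 7-state birth-death chain;
      // binding (6-i) hB xB out of state i, unbinding i fB
      double* b = &pBv[7 * k];
      double nb[7];
      double prev = 0.0;
      for (int i = 0; i < 7; ++i) {
        double flux = -((6 - i) * hBx + i * fB) * b[i];
        if (i > 0) flux += (7 - i) * hBx * prev;
        if (i < 6) flux += (i + 1) * fB * b[i + 1];
        prev = b[i];
        nb[i] = b[i] + dt * flux;
      }
      bool clipped = false;
      for (int i = 0; i < 7; ++i) {
        if (nb[i] < 0.0) {
          if (nb[i] < -neg_tol) neg_err = 1;
          nb[i] = 0.0; clipped = true;
        }
      }
      if (clipped) {
        double ssum = 0.0;
        for (int i = 0; i < 7; ++i) ssum += nb[i];
        if (ssum > 0.0) for (int i = 0; i < 7; ++i) nb[i] /= ssum;
      }
      double sb_k = 0.0;
      for (int i = 0; i < 7; ++i) { b[i] = nb[i]; sb_k += i * nb[i]; }
      SB += sb_k;
      pB0v[k] = nb[0];
    }
    if (neg_err) stop("integration unstable: pB < -1e-9 (reduce dt)");

    // (iv) conservation: xB explicit, xA by root finding; then pA from the
    // CII quasi-equilibrium pA = pB0 * xA g / (1 + xA g)
    xB = BTc - SB * Vinv;
    if (xB < 0.0) {
      if (xB < -1e-8 * BTc) stop("KaiB conservation violated: bound > BT");
      xB = 0.0;
    }
    xA = solve_xA(g, pB0v, SB * Vinv, Vinv, gCBA, AT2c, xA, &solver_err);
    if (solver_err) stop("free-KaiA solver failed to converge");
    if (AT2c > 0.0) {
      double chk = xA - AT2c;
      for (int k = 0; k < N; ++k) {
        chk += xA * Vinv * g[k] * pB0v[k] / (1.0 + xA * g[k]);
      }
      chk += xA * gCBA / (1.0 + xA * gCBA) * SB * Vinv;
      if (std::fabs(chk) > max_resid) max_resid = std::fabs(chk);
    }

    for (int k = 0; k < N; ++k) {
      double xg = xA * g[k];
      pAp[k] = pB0v[k] * xg / (1.0 + xg);

      // (v) phosphorylation: dD/dt = kp H+ (1-D) - kdp H- D, z = pA/P0
      double z = pAp[k] / P0;
      double hz = 1.0 / (1.0 + z);
      Dp[k] += dt * hz * (kp * z * (1.0 - Dp[k]) - kdp * Dp[k]);
      if (Dp[k] < 0.0) Dp[k] = 0.0; else if (Dp[k] > 1.0) Dp[k] = 1.0;

      // (vi) structural field from the lagged X, then update X
      const int8_t* qk = &qv[6 * k];
      int qs = qk[0] + qk[1] + qk[2] + qk[3] + qk[4] + qk[5];
      double qbar = qs / 6.0;
      double bsum = incl0 ? 1.0 : (1.0 - pBv[7 * k]);
      if (bsum < 0.0) bsum = 0.0;
      double c = d0 + d1 * pAp[k] - d2 * bsum - d3 * (2.0 * Dp[k] - 1.0)
                 + d4 * (1.0 - qbar);
      if (x_scheme == 0) {
        Xp[k] = 0.5 * (1.0 + std::tanh((c - d4 * Xp[k]) * t_ratio));
      } else {
        // Newton on h(X) = X - (1 + tanh(beta*(c - d4 X)))/2, h' >= 1
        double x = Xp[k];
        for (int it = 0; it < 40; ++it) {
          double th = std::tanh((c - d4 * x) * t_ratio);
          double h = x - 0.5 * (1.0 + th);
          double hp = 1.0 + 0.5 * t_ratio * d4 * (1.0 - th * th);
          double xn = x - h / hp;
          if (xn < 0.0) xn = 0.0; else if (xn > 1.0) xn = 1.0;
          if (std::fabs(xn - x) < 1e-9) { x = xn; break; }
          x = xn;
        }
        Xp[k] = x;
      }
    }

    if (s % record_every == 0) {
      double Dm = 0.0, Xm = 0.0;
      long qm = 0;
      for (int k = 0; k < N; ++k) {
        Dm += Dp[k]; Xm += Xp[k];
        const int8_t* qk = &qv[6 * k];
        qm += qk[0] + qk[1] + qk[2] + qk[3] + qk[4] + qk[5];
      }
      rec(irec, 0) = t0 + s * dt;
      rec(irec, 1) = Dm / N;
      rec(irec, 2) = Xm / N;
      rec(irec, 3) = qm / (6.0 * N);
      rec(irec, 4) = (double)releases_acc;
      rec(irec, 5) = xA;
      rec(irec, 6) = xB;
      for (int j = 0; j < n_tr; ++j) {
        trD(irec, j) = Dp[track[j] - 1];
        trX(irec, j) = Xp[track[j] - 1];
      }
      releases_acc = 0;
      ++irec;
    }
  }

  for (int k = 0; k < N; ++k) {
    for (int i = 0; i < 6; ++i) q(k, i) = qv[6 * k + i];
    for (int i = 0; i < 7; ++i) pB(k, i) = pBv[7 * k + i];
  }
  NumericVector age_out(6 * N);
  for (int i = 0; i < 6 * N; ++i) age_out[i] = age[i];
  NumericVector rng_out(8);
  for (int i = 0; i < 4; ++i) {
    rng_out[2 * i] = (double)(uint32_t)(rng.s[i] >> 32);
    rng_out[2 * i + 1] = (double)(uint32_t)(rng.s[i] & 0xffffffffULL);
  }
  List out_state = List::create(
    _["pA"] = pA, _["pB"] = pB, _["D"] = D, _["X"] = X, _["q"] = q,
    _["xA"] = xA, _["xB"] = xB, _["t"] = t0 + n_steps * dt,
    _["adp_age"] = age_out, _["max_xA_resid"] = max_resid,
    _["rng_state"] = rng_out);
  return List::create(_["rec"] = rec, _["trD"] = trD, _["trX"] = trX,
                      _["state"] = out_state);
}
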