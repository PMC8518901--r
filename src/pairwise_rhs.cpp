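#include <Rcpp.h>
using namespace Rcpp;

// Right-hand side of the heterogeneous pairwise SIR model with the clustered
// triple closure.  State layout (M degree classes):
//   [ S(M) | I(M) | R(M) | SI(M*M) | SS(M*M) | II(M*M) ]
// and, when full_pairs is true, three further blocks SR, RI, RR (M*M each)
// that are only needed to verify edge-count conservation.
//
// Pair matrices are ordered-pair counts: SI(k,l) = [S_k I_l], stored
// column-major with row index k.  Triples [A_k B_l C_m] are closed through
//   ((l-1)/l) * ( (1-phi) AB*BC/[B_l] + phi AB*BC*CA/([A_k][B_l][C_m]) ).
// Closed moment systems can drive compartments slightly negative when a
// degree class burns out; inside the closure every count is therefore
// clamped at zero and divisions are regularised.  Two regimes need
// different treatment: susceptible-class denominators use the floored
// inverse 1/max(S,eps), which keeps the pair-destruction terms active
// (bounded by 1/eps) while a class burns out, so pair counts cannot
// outlive their nodes; infected/recovered denominators, which only appear
// under sums whose numerators vanish at least linearly with the
// compartment, use the smooth inverse D/(D^2+eps^2), which suppresses the
// term as the compartment empties instead of amplifying rounding noise by
// 1/eps.  Both forms converge to exact division as eps -> 0 on positive
// trajectories.

static inline double rinv_floor(double d, double eps) {
  return 1.0 / std::max(d, eps);
}

static inline double rinv_smooth(double d, double eps) {
  return d > 0.0 ? d / (d * d + eps * eps) : 0.0;
}

static inline double pos(double x) { return x > 0.0 ? x : 0.0; }

// Two readings of the clustered (triangle) term are supported.  With
// normalized = false it is exactly phi * AB*BC*CA/([A][B][C]) as typeset.
// With normalized = true the triangle term is the Keeling-style correction
// generalised to degree classes: the base closure AB*BC/[B] is multiplied by
// phi * [CA] / E[CA], where E[CA] = deg_C deg_A [C][A] / (<k>N) is the
// proportional-mixing expectation of the closing pair, i.e. an extra factor
// kNtot/(deg_A*deg_C) relative to the printed form (kNtot = total stubs).
// The normalised form is dimensionally consistent (triples scale with N).

// [[Rcpp::export]]
NumericVector pairwise_rhs_cpp(NumericVector y, NumericVector deg,
                               double tau, double gamma, double phi,
                               double eps, bool full_pairs,
                               bool normalized, double kNtot) {
  const int M = deg.size();
  const int M2 = M * M;
  const double *S = &y[0], *I = &y[M];
  const double *SI = &y[3 * M], *SS = &y[3 * M + M2], *II = &y[3 * M + 2 * M2];
  const double *SR = nullptr, *RI = nullptr;
  if (full_pairs) {
    SR = &y[3 * M + 3 * M2];
    RI = &y[3 * M + 4 * M2];
  }

  NumericVector dy(y.size());
  double *dS = &dy[0], *dI = &dy[M], *dR = &dy[2 * M];
  double *dSI = &dy[3 * M], *dSS = &dy[3 * M + M2], *dII = &dy[3 * M + 2 * M2];

  std::vector<double> invS(M), invI(M), cfac(M), SIrow(M), SIrowP(M);
  for (int k = 0; k < M; ++k) {
    invS[k] = rinv_floor(S[k], eps);
    invI[k] = rinv_smooth(I[k], eps);
    cfac[k] = (deg[k] - 1.0) / deg[k];
    double s = 0.0, sp = 0.0;
    for (int l = 0; l < M; ++l) {
      s += SI[k + l * M];
      sp += pos(SI[k + l * M]);
    }
    SIrow[k] = s;
    SIrowP[k] = sp;
  }

  // W(k,l) = sum_a w_a SI(k,a) SI(l,a) / I_a ; V(k,l) = sum_a w_a SI(k,a) II(l,a) / I_a
  // with w_a = 1/deg_a in normalised mode (part of the E[CA] weighting).
  std::vector<double> W(M2, 0.0), V(M2, 0.0);
  if (phi > 0.0) {
    for (int a = 0; a < M; ++a) {
      const double w = normalized ? invI[a] / deg[a] : invI[a];
      for (int l = 0; l < M; ++l) {
        const double sla = pos(SI[l + a * M]) * w;
        const double ila = pos(II[l + a * M]) * w;
        if (sla == 0.0 && ila == 0.0) continue;
        for (int k = 0; k < M; ++k) {
          const double ska = pos(SI[k + a * M]);
          W[k + l * M] += ska * sla;
          V[k + l * M] += ska * ila;
        }
      }
    }
  }

  std::vector<double> T1(M2), T2(M2);
  for (int l = 0; l < M; ++l) {
    for (int k = 0; k < M; ++k) {
      const int kl = k + l * M;
      double t1 = (1.0 - phi) * pos(SS[kl]) * SIrowP[l] * invS[l];
      double t2 = (1.0 - phi) * SIrowP[k] * pos(SI[kl]) * invS[k];
      if (phi > 0.0) {
        const double f1 = normalized ? kNtot / deg[k] : 1.0;
        const double f2 = normalized ? kNtot / deg[l] : 1.0;
        t1 += phi * f1 * pos(SS[kl]) * invS[k] * invS[l] * W[kl];
        t2 += phi * f2 * pos(SI[kl]) * invS[k] * invI[l] * V[kl];
      }
      T1[kl] = cfac[l] * t1;
      T2[kl] = cfac[k] * t2;
    }
  }

  for (int k = 0; k < M; ++k) {
    dS[k] = -tau * SIrow[k];
    dI[k] = tau * SIrow[k] - gamma * I[k];
    dR[k] = gamma * I[k];
  }
  for (int l = 0; l < M; ++l) {
    for (int k = 0; k < M; ++k) {
      const int kl = k + l * M, lk = l + k * M;
      dSI[kl] = -gamma * SI[kl] + tau * (T1[kl] - T2[kl] - SI[kl]);
      dSS[kl] = -tau * (T1[kl] + T1[lk]);
      dII[kl] = -2.0 * gamma * II[kl] +
                tau * (T2[kl] + T2[lk] + SI[kl] + SI[lk]);
    }
  }

  if (full_pairs) {
    double *dSR = &dy[3 * M + 3 * M2];
    double *dRI = &dy[3 * M + 4 * M2];
    double *dRR = &dy[3 * M + 5 * M2];
    std::vector<double> invR(M), X(M2, 0.0);
    const double *Rc = &y[2 * M];
    for (int k = 0; k < M; ++k) invR[k] = rinv_smooth(Rc[k], eps);
    if (phi > 0.0) {
      // X(k,l) = sum_a w_a SI(k,a) RI(l,a) / I_a
      for (int a = 0; a < M; ++a) {
        const double w = normalized ? invI[a] / deg[a] : invI[a];
        for (int l = 0; l < M; ++l) {
          const double rla = pos(RI[l + a * M]) * w;
          if (rla == 0.0) continue;
          for (int k = 0; k < M; ++k)
            X[k + l * M] += pos(SI[k + a * M]) * rla;
        }
      }
    }
    for (int l = 0; l < M; ++l) {
      for (int k = 0; k < M; ++k) {
        const int kl = k + l * M, lk = l + k * M;
        // sum_a [I_a S_k R_l], centre k
        double tsr = (1.0 - phi) * SIrowP[k] * pos(SR[kl]) * invS[k];
        // sum_a [R_k S_l I_a], centre l
        double trs = (1.0 - phi) * pos(SR[lk]) * SIrowP[l] * invS[l];
        if (phi > 0.0) {
          const double fsr = normalized ? kNtot / deg[l] : 1.0;
          const double frs = normalized ? kNtot / deg[k] : 1.0;
          tsr += phi * fsr * pos(SR[kl]) * invS[k] * invR[l] * X[kl];
          trs += phi * frs * pos(SR[lk]) * invS[l] * invR[k] * X[lk];
        }
        tsr *= cfac[k];
        trs *= cfac[l];
        dSR[kl] = gamma * SI[kl] - tau * tsr;
        dRI[kl] = gamma * II[kl] + tau * trs - gamma * RI[kl];
        dRR[kl] = gamma * (RI[kl] + RI[lk]);
      }
    }
  }
  return dy;
}
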