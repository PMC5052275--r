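#include <Rcpp.h>
using namespace Rcpp;

// Exponential race model of cued temporal-order judgments.
//
// Timeline (reference onset = 0): probe at soa, cue at soa - coa.  Every
// racer starts its exponential clock t0 after its own onset.  The cue races
// to be categorized as the probe and is censored (masked) at the physical
// probe onset, so its window has length coa - t0.  When the reference
// appears before the cue (soa > coa) it races at the neutral-condition rate
// until cue onset and at v_r afterwards (regime 0, "switch"); regime 1
// ("neutral") keeps the reference at the neutral rate for the whole trial
// whenever soa > coa.  All internal arithmetic is in seconds.

struct RaceProb {
  double p_via_cue;
  double p_via_probe;
};

static inline double clampd(double x, double lo, double hi) {
  return x < lo ? lo : (x > hi ? hi : x);
}

// integral of vcp * exp(-vcp x) * exp(logK - rho x) over [a, b], vcp > 0;
// the endpoint exponents logK - lam*x are <= 0 on valid segments, so the
// log form stays finite for arbitrarily large hazards
static inline double seg_int(double vcp, double logK, double rho,
                             double a, double b) {
  if (b <= a) return 0.0;
  double lam = vcp + rho;
  return vcp / lam * (std::exp(logK - lam * a) - std::exp(logK - lam * b));
}

// core computation; all times in seconds, rates in Hz
static RaceProb race_prob(double vp, double vr, double vcp, double vn,
                          double t0, double soa, double coa,
                          bool nocue, int regime) {
  if (nocue) {
    vp = vn; vr = vn; vcp = 0.0; coa = 0.0;
  }
  // reference hazard: r1 on [0, d), r2 afterwards (race time, starts t0
  // after reference onset)
  double r1, r2, d;
  if (nocue) {
    r1 = r2 = vn; d = 0.0;
  } else if (regime == 0) {
    r1 = vn; r2 = vr; d = std::max(soa - coa - t0, 0.0);
  } else {
    if (soa > coa) { r1 = r2 = vn; } else { r1 = r2 = vr; }
    d = 0.0;
  }

  double W = nocue ? 0.0 : std::max(coa - t0, 0.0);
  double kappa = (vcp > 0.0 && W > 0.0) ? -std::expm1(-vcp * W) : 0.0;

  // A = P(probe completes before reference), probe race offset = soa
  double A;
  if (vp <= 0.0) {
    A = 0.0;
  } else if (soa <= 0.0) {
    double E = std::exp(-(vp + r1) * d);
    double I = vp / (vp + r1) * (1.0 - E) + E * vp / (vp + r2);
    A = 1.0 - std::exp(vp * soa) * (1.0 - I);
  } else {
    double S = std::exp(-r1 * std::min(soa, d) - r2 * std::max(soa - d, 0.0));
    double dp = std::max(d - soa, 0.0);
    double E = std::exp(-(vp + r1) * dp);
    A = S * (vp / (vp + r1) * (1.0 - E) + E * vp / (vp + r2));
  }

  // B = P(cue-as-probe event occurs inside its window and beats reference)
  double B = 0.0;
  if (vcp > 0.0 && W > 0.0) {
    double g = soa - coa;  // cue race start in reference race time
    double b1 = clampd(-g, 0.0, W);      // reference race not yet started
    double b2 = clampd(d - g, b1, W);    // reference racing at r1
    B += seg_int(vcp, 0.0, 0.0, 0.0, b1);
    B += seg_int(vcp, -r1 * g, r1, b1, b2);
    B += seg_int(vcp, -r1 * d - r2 * (g - d), r2, b2, W);
  }

  RaceProb out;
  out.p_via_cue = clampd(B, 0.0, 1.0);
  out.p_via_probe = clampd((1.0 - kappa) * A, 0.0, 1.0);
  return out;
}

// [[Rcpp::export]]
NumericMatrix race_decompose_cpp(NumericVector vp, NumericVector vr,
                                 NumericVector vcp, NumericVector vn,
                                 double t0_ms, NumericVector soa_ms,
                                 NumericVector coa_ms, LogicalVector nocue,
                                 int regime) {
  int n = soa_ms.size();
  NumericMatrix out(n, 2);
  for (int i = 0; i < n; ++i) {
    RaceProb rp = race_prob(vp[i], vr[i], vcp[i], vn[i], t0_ms / 1000.0,
                            soa_ms[i] / 1000.0, coa_ms[i] / 1000.0,
                            nocue[i], regime);
    out(i, 0) = rp.p_via_cue;
    out(i, 1) = rp.p_via_probe;
  }
  colnames(out) = CharacterVector::create("p_via_cue", "p_via_probe");
  return out;
}

// ---------------------------------------------------------------------------
// Hierarchical sampler
//
// Subject-level parameters are log rates theta[j] with theta[j] ~
// N(mu[g], sigma[g]) for hyper group g = par_group[j]; mu has a normal
// prior (m0, s0), sigma a half-normal prior (scale sig_scale).  Rows of the
// dataset reference parameters through index quadruples (ivp, ivr, ivcp,
// ivn); ivcp = -1 pins the cue-as-probe rate at zero (rates-only variant).
// Updates: scalar adaptive random-walk Metropolis for theta and log sigma
// (target acceptance 0.44, Robbins-Monro during warmup), conjugate Gibbs
// for mu.

struct RowData {
  std::vector<int> n, k, ivp, ivr, ivcp, ivn;
  std::vector<double> soa, coa;
  std::vector<int> nocue;
  double t0;
  int regime;
};

static inline double row_loglik(const RowData& D, int i,
                                const std::vector<double>& theta) {
  double vp = std::exp(theta[D.ivp[i]]);
  double vr = std::exp(theta[D.ivr[i]]);
  double vcp = D.ivcp[i] < 0 ? 0.0 : std::exp(theta[D.ivcp[i]]);
  double vn = std::exp(theta[D.ivn[i]]);
  RaceProb rp = race_prob(vp, vr, vcp, vn, D.t0, D.soa[i], D.coa[i],
                          D.nocue[i] != 0, D.regime);
  double p = clampd(rp.p_via_cue + rp.p_via_probe, 1e-12, 1.0 - 1e-12);
  return D.k[i] * std::log(p) + (D.n[i] - D.k[i]) * std::log1p(-p);
}

static RowData build_rowdata(List rows, double t0_s, int regime) {
  RowData D;
  IntegerVector n = rows["n"], k = rows["k"], ivp = rows["ivp"],
    ivr = rows["ivr"], ivcp = rows["ivcp"], ivn = rows["ivn"],
    nocue = rows["nocue"];
  NumericVector soa = rows["soa_s"], coa = rows["coa_s"];
  int m = n.size();
  D.n.assign(n.begin(), n.end());
  D.k.assign(k.begin(), k.end());
  D.ivp.assign(ivp.begin(), ivp.end());
  D.ivr.assign(ivr.begin(), ivr.end());
  D.ivcp.assign(ivcp.begin(), ivcp.end());
  D.ivn.assign(ivn.begin(), ivn.end());
  D.nocue.assign(nocue.begin(), nocue.end());
  D.soa.assign(soa.begin(), soa.end());
  D.coa.assign(coa.begin(), coa.end());
  (void)m;
  D.t0 = t0_s;
  D.regime = regime;
  return D;
}

// empirical covariance -> lower Cholesky factor, from running moments
static void refresh_chol(const std::vector<double>& sum,
                         const std::vector<double>& sqsum, int n, int d,
                         std::vector<double>& Lout) {
  std::vector<double> cov(d * d, 0.0);
  for (int i = 0; i < d; ++i) {
    for (int j = 0; j <= i; ++j) {
      double c = (sqsum[i * d + j] - sum[i] * sum[j] / n) / (n - 1);
      if (!std::isfinite(c)) return;
      cov[i * d + j] = cov[j * d + i] = c;
    }
    cov[i * d + i] += 1e-5;
  }
  std::vector<double> L(d * d, 0.0);
  for (int i = 0; i < d; ++i) {
    for (int j = 0; j <= i; ++j) {
      double s = cov[i * d + j];
      for (int k = 0; k < j; ++k) s -= L[i * d + k] * L[j * d + k];
      if (i == j) {
        if (s <= 0) return;  // keep the previous factor
        L[i * d + i] = std::sqrt(s);
      } else {
        L[i * d + j] = s / L[j * d + j];
      }
    }
  }
  Lout = L;
}

// [[Rcpp::export]]
List run_mwg_chain(List rows, List blocks, List block_rows,
                   IntegerVector par_group, List group_members,
                   List hblocks, List hblock_rows,
                   NumericVector m0, NumericVector s0,
                   NumericVector sig_scale, NumericVector theta_init,
                   NumericVector mu_init, NumericVector sigma_init,
                   int n_warmup, int n_iter, double t0_s, int regime) {
  RowData D = build_rowdata(rows, t0_s, regime);
  int np = theta_init.size();
  int ng = mu_init.size();
  int nrow = (int)D.n.size();
  int nb = blocks.size();

  std::vector<double> theta(theta_init.begin(), theta_init.end());
  std::vector<double> mu(mu_init.begin(), mu_init.end());
  std::vector<double> lsig(ng);
  for (int g = 0; g < ng; ++g) lsig[g] = std::log(sigma_init[g]);

  // cached per-row log likelihood
  std::vector<double> rowlik(nrow);
  for (int i = 0; i < nrow; ++i) rowlik[i] = row_loglik(D, i, theta);

  std::vector< std::vector<int> > bmem(nb), brow(nb);
  for (int b = 0; b < nb; ++b) {
    IntegerVector v = blocks[b];
    bmem[b].assign(v.begin(), v.end());
    IntegerVector w = block_rows[b];
    brow[b].assign(w.begin(), w.end());
  }
  std::vector< std::vector<int> > gmem(ng);
  for (int g = 0; g < ng; ++g) {
    IntegerVector v = group_members[g];
    gmem[g].assign(v.begin(), v.end());
  }
  int nh = hblocks.size();
  std::vector< std::vector<int> > hmem(nh), hrow(nh);
  for (int h = 0; h < nh; ++h) {
    IntegerVector v = hblocks[h];
    hmem[h].assign(v.begin(), v.end());
    IntegerVector w = hblock_rows[h];
    hrow[h].assign(w.begin(), w.end());
  }

  // per-block adaptation state: running moments of the block draws and a
  // Cholesky factor of the empirical covariance (Haario-style adaptive
  // Metropolis), plus a log scale tuned to the dimension-specific target
  // acceptance rate
  std::vector<double> lscale(nb, 0.0), lstep_s(ng, std::log(0.3));
  std::vector< std::vector<double> > bsum(nb), bsqsum(nb), bchol(nb);
  std::vector<int> bcount(nb, 0);
  for (int b = 0; b < nb; ++b) {
    int d = bmem[b].size();
    bsum[b].assign(d, 0.0);
    bsqsum[b].assign(d * d, 0.0);
    bchol[b].assign(d * d, 0.0);
    for (int i = 0; i < d; ++i) bchol[b][i * d + i] = 0.15;
  }

  // translation-move adaptation state (positions are the group means)
  std::vector<double> hscale(nh, std::log(0.3));
  std::vector< std::vector<double> > hsum(nh), hsqsum(nh), hchol(nh);
  std::vector<int> hcount(nh, 0);
  for (int h = 0; h < nh; ++h) {
    int d = hmem[h].size();
    hsum[h].assign(d, 0.0);
    hsqsum[h].assign(d * d, 0.0);
    hchol[h].assign(d * d, 0.0);
    for (int i = 0; i < d; ++i) hchol[h][i * d + i] = 0.15;
  }

  int total = n_warmup + n_iter;
  NumericMatrix draws(n_iter, np + 2 * ng);

  for (int it = 0; it < total; ++it) {
    double gam = std::pow(it + 1.0, -0.6);
    bool adapting = it < n_warmup;

    // subject-level blocks: joint random-walk along the adapted covariance
    for (int b = 0; b < nb; ++b) {
      int d = bmem[b].size();
      double target = d == 1 ? 0.44 : 0.234;
      double sc = std::exp(lscale[b]) * 2.38 / std::sqrt((double)d);
      std::vector<double> cur(d), prop(d), z(d);
      for (int i = 0; i < d; ++i) { cur[i] = theta[bmem[b][i]]; z[i] = norm_rand(); }
      bool bad = false;
      for (int i = 0; i < d; ++i) {
        double step = 0.0;
        for (int j = 0; j <= i; ++j) step += bchol[b][i * d + j] * z[j];
        prop[i] = cur[i] + sc * step;
        if (!std::isfinite(prop[i]) || std::fabs(prop[i]) > 15.0) bad = true;
      }
      if (bad) { if (adapting) lscale[b] += gam * (0.0 - target); continue; }
      for (int i = 0; i < d; ++i) theta[bmem[b][i]] = prop[i];
      double dll = 0.0;
      std::vector<double> newlik(brow[b].size());
      for (size_t a = 0; a < brow[b].size(); ++a) {
        int i = brow[b][a];
        newlik[a] = row_loglik(D, i, theta);
        dll += newlik[a] - rowlik[i];
      }
      for (int i = 0; i < d; ++i) {
        int g = par_group[bmem[b][i]];
        double sg = std::exp(lsig[g]);
        dll += (-0.5 * std::pow((prop[i] - mu[g]) / sg, 2))
             - (-0.5 * std::pow((cur[i] - mu[g]) / sg, 2));
      }
      double alpha = dll >= 0 ? 1.0 : std::exp(dll);
      if (unif_rand() < alpha) {
        for (size_t a = 0; a < brow[b].size(); ++a) rowlik[brow[b][a]] = newlik[a];
      } else {
        for (int i = 0; i < d; ++i) theta[bmem[b][i]] = cur[i];
      }
      if (adapting) {
        lscale[b] += gam * (alpha - target);
        bcount[b]++;
        for (int i = 0; i < d; ++i) {
          double xi = theta[bmem[b][i]];
          bsum[b][i] += xi;
          for (int j = 0; j <= i; ++j) {
            bsqsum[b][i * d + j] += xi * theta[bmem[b][j]];
          }
        }
        // refresh the Cholesky factor periodically once moments stabilize
        if (bcount[b] >= 100 && bcount[b] % 50 == 0) {
          refresh_chol(bsum[b], bsqsum[b], bcount[b], d, bchol[b]);
        }
      }
    }

    // joint translation moves: shift a condition's group means together
    // with all their subject-level members (the within-subject prior
    // terms are invariant), moving efficiently along group-level ridges;
    // repeated several times per sweep because these directions carry the
    // longest autocorrelations
    for (int hrep = 0; hrep < 4; ++hrep)
    for (int h = 0; h < nh; ++h) {
      int d = hmem[h].size();
      double target = d == 1 ? 0.44 : 0.234;
      double sc = std::exp(hscale[h]) * 2.38 / std::sqrt((double)d);
      std::vector<double> z(d), delta(d);
      for (int i = 0; i < d; ++i) z[i] = norm_rand();
      for (int i = 0; i < d; ++i) {
        double step = 0.0;
        for (int j = 0; j <= i; ++j) step += hchol[h][i * d + j] * z[j];
        delta[i] = sc * step;
      }
      bool bad = false;
      for (int i = 0; i < d; ++i) {
        if (!std::isfinite(delta[i]) || std::fabs(delta[i]) > 10.0) bad = true;
      }
      if (bad) continue;
      std::vector< std::vector<double> > saved(d);
      double dprior = 0.0;
      for (int i = 0; i < d; ++i) {
        int g = hmem[h][i];
        double mn = mu[g] + delta[i];
        dprior += (-0.5 * std::pow((mn - m0[g]) / s0[g], 2))
                - (-0.5 * std::pow((mu[g] - m0[g]) / s0[g], 2));
        saved[i].resize(gmem[g].size());
        for (size_t a = 0; a < gmem[g].size(); ++a) {
          saved[i][a] = theta[gmem[g][a]];
          theta[gmem[g][a]] += delta[i];
        }
      }
      double dll = dprior;
      std::vector<double> newlik(hrow[h].size());
      for (size_t a = 0; a < hrow[h].size(); ++a) {
        int i = hrow[h][a];
        newlik[a] = row_loglik(D, i, theta);
        dll += newlik[a] - rowlik[i];
      }
      double alpha = dll >= 0 ? 1.0 : std::exp(dll);
      if (unif_rand() < alpha) {
        for (int i = 0; i < d; ++i) mu[hmem[h][i]] += delta[i];
        for (size_t a = 0; a < hrow[h].size(); ++a) rowlik[hrow[h][a]] = newlik[a];
      } else {
        for (int i = 0; i < d; ++i) {
          int g = hmem[h][i];
          for (size_t a = 0; a < gmem[g].size(); ++a) {
            theta[gmem[g][a]] = saved[i][a];
          }
        }
      }
      if (adapting) {
        hscale[h] += gam * (alpha - target);
        hcount[h]++;
        for (int i = 0; i < d; ++i) {
          double xi = mu[hmem[h][i]];
          hsum[h][i] += xi;
          for (int j = 0; j <= i; ++j) hsqsum[h][i * d + j] += xi * mu[hmem[h][j]];
        }
        if (hcount[h] >= 100 && hcount[h] % 50 == 0) {
          refresh_chol(hsum[h], hsqsum[h], hcount[h], d, hchol[h]);
        }
      }
    }

    // group means: conjugate normal update (sigma bounded away from zero
    // so the precision stays finite)
    for (int g = 0; g < ng; ++g) {
      double sg = std::max(std::exp(lsig[g]), 1e-4);
      double prec = gmem[g].size() / (sg * sg) + 1.0 / (s0[g] * s0[g]);
      double sum = 0.0;
      for (size_t a = 0; a < gmem[g].size(); ++a) sum += theta[gmem[g][a]];
      double mean = (sum / (sg * sg) + m0[g] / (s0[g] * s0[g])) / prec;
      mu[g] = mean + norm_rand() / std::sqrt(prec);
    }

    // group spreads: random walk on log sigma, half-normal prior
    for (int g = 0; g < ng; ++g) {
      double cur = lsig[g];
      double prop = cur + std::exp(lstep_s[g]) * norm_rand();
      if (prop < -7.0 || prop > 3.0) { if (adapting) lstep_s[g] += gam * (0.0 - 0.44); continue; }
      double scur = std::exp(cur), sprop = std::exp(prop);
      double ll = 0.0;
      for (size_t a = 0; a < gmem[g].size(); ++a) {
        double z = theta[gmem[g][a]] - mu[g];
        ll += (-prop - 0.5 * z * z / (sprop * sprop))
            - (-cur - 0.5 * z * z / (scur * scur));
      }
      // half-normal prior on sigma + Jacobian of the log transform
      ll += -0.5 * (sprop * sprop - scur * scur) / (sig_scale[g] * sig_scale[g]);
      ll += prop - cur;
      double alpha = ll >= 0 ? 1.0 : std::exp(ll);
      if (unif_rand() < alpha) lsig[g] = prop;
      if (adapting) lstep_s[g] += gam * (alpha - 0.44);
    }

    if (!adapting) {
      int r = it - n_warmup;
      for (int j = 0; j < np; ++j) draws(r, j) = theta[j];
      for (int g = 0; g < ng; ++g) {
        draws(r, np + g) = mu[g];
        draws(r, np + ng + g) = std::exp(lsig[g]);
      }
    }
  }

  double lp = 0.0;
  for (int i = 0; i < nrow; ++i) lp += rowlik[i];
  return List::create(_["draws"] = draws, _["final_loglik"] = lp);
}

// per-draw, per-row log likelihood (for LOO-based model comparison);
// draws holds subject-level theta in its first np columns
// [[Rcpp::export]]
NumericMatrix loglik_matrix_cpp(NumericMatrix draws, int np, List rows,
                                double t0_s, int regime) {
  RowData D = build_rowdata(rows, t0_s, regime);
  int S = draws.nrow();
  int nrow = (int)D.n.size();
  NumericMatrix out(S, nrow);
  std::vector<double> theta(np);
  for (int s = 0; s < S; ++s) {
    for (int j = 0; j < np; ++j) theta[j] = draws(s, j);
    for (int i = 0; i < nrow; ++i) out(s, i) = row_loglik(D, i, theta);
  }
  return out;
}
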