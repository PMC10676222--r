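// Bespoke Gibbs-within-slice sampler for the multilevel bivariate VAR(1)
// model. Blocks:
//   - person-specific parameters (intercepts; optionally AR/CR): conjugate
//     bivariate/4-dim normal draws given the within-level likelihood and the
//     between-level prior
//   - between-level coefficients B: conjugate normal (prior N(0, 100))
//   - random-effect variances: slice steps honouring the uniform(0, 100)
//     prior on the variance
//   - fixed VAR / covariate effects: joint conjugate normal with priors
//     N(0, 10) (AR/CR) and N(0, 1) (covariate effects)
//   - process-noise variances and correlation: univariate slice steps under
//     uniform(0, 100) / uniform(-1, 1) priors
//   - (BFIML mode) missing dependent-variable and x1 cells sampled from
//     their full conditionals; x1 has its own AR(1) model with weakly
//     informative priors
// All randomness flows through R's RNG so set.seed() on the R side governs.
#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]
using namespace Rcpp;

static arma::vec rnorm_vec(int k) {
  arma::vec z(k);
  for (int i = 0; i < k; ++i) z[i] = R::norm_rand();
  return z;
}

// draw from N(P^{-1} b, P^{-1}) given precision P and linear term b
static arma::vec mvn_prec_draw(const arma::mat& P, const arma::vec& b) {
  arma::mat U = arma::chol(P);  // P = U' U
  arma::vec v = arma::solve(arma::trimatl(U.t()), b);
  arma::vec m = arma::solve(arma::trimatu(U), v);
  return m + arma::solve(arma::trimatu(U), rnorm_vec(P.n_rows));
}

// univariate slice sampler (stepping out + shrinkage) on (lo, hi)
template <class F>
static double slice_sample(double x0, F logf, double lo, double hi,
                           double w) {
  double fx0 = logf(x0);
  if (!std::isfinite(fx0)) return x0;
  double logy = fx0 - R::exp_rand();
  double u = R::unif_rand() * w;
  double L = std::max(x0 - u, lo + 1e-12);
  double Rr = std::min(L + w, hi - 1e-12);
  int steps = 50;
  while (L > lo + 1e-10 && logf(L) > logy && steps-- > 0)
    L = std::max(L - w, lo + 1e-12);
  steps = 50;
  while (Rr < hi - 1e-10 && logf(Rr) > logy && steps-- > 0)
    Rr = std::min(Rr + w, hi - 1e-12);
  for (int it = 0; it < 100; ++it) {
    double x1 = L + R::unif_rand() * (Rr - L);
    if (logf(x1) >= logy) return x1;
    if (x1 < x0) L = x1; else Rr = x1;
  }
  return x0;
}

// V = A V A' + Q (2x2) via the vec identity
static arma::mat dlyap2(const arma::mat& A, const arma::mat& Q) {
  arma::mat K = arma::kron(A, A);
  arma::vec v = arma::solve(arma::eye(4, 4) - K, arma::vectorise(Q));
  return arma::reshape(v, 2, 2);
}

// [[Rcpp::export]]
List mvar_gibbs_cpp(arma::mat y, arma::mat x,
                    arma::ivec pid, arma::ivec prev,
                    arma::mat Xb,
                    bool random_var, bool augment,
                    List prior, List ctrl, List init) {
  const int n = y.n_rows;
  const int N = Xb.n_rows;
  const int p = Xb.n_cols;
  const double v_fix = as<double>(prior["between_fixed_var"]);   // 100
  const double v_var = as<double>(prior["fixed_var_params_var"]); // 10
  const double v_cov = as<double>(prior["cov_effects_var"]);      // 1
  const double var_hi = as<double>(prior["noise_var_upper"]);     // 100
  const double re_hi = as<double>(prior["re_var_upper"]);         // 100
  const int n_iter = as<int>(ctrl["iterations"]);
  const int n_burn = as<int>(ctrl["burn_in"]);
  const int thin = as<int>(ctrl["thin"]);
  const bool est_arcr = as<bool>(ctrl["est_arcr"]);
  const bool est_cd = as<bool>(ctrl["est_cd"]);
  const bool est_sigma = as<bool>(ctrl["est_sigma"]);
  const bool est_corr = as<bool>(ctrl["est_corr"]);
  const bool delta_zero = as<bool>(ctrl["delta_zero"]);
  const bool est_between = as<bool>(ctrl["est_between"]);

  // state
  arma::mat mu = as<arma::mat>(init["mu"]);        // N x 2
  arma::mat B = as<arma::mat>(init["B"]);          // nrows x p
  arma::vec delta2 = as<arma::vec>(init["delta2"]); // matches B rows
  arma::vec arv = as<arma::vec>(init["ar"]);       // 2
  arma::vec crv = as<arma::vec>(init["cr"]);       // 2
  arma::vec cd = as<arma::vec>(init["cd"]);        // c1 c2 d1 d2
  arma::vec sig = as<arma::vec>(init["sigma"]);    // s1sq s2sq rho
  arma::mat phi;                                   // N x 4 person AR/CR
  if (random_var) phi = as<arma::mat>(init["phi"]);
  double x_ar = as<double>(init["x_ar"]);
  double x_var = as<double>(init["x_var"]);

  // missingness bookkeeping (augment mode)
  arma::umat miss_y(n, 2, arma::fill::zeros);
  arma::uvec miss_x1(n, arma::fill::zeros);
  std::vector<int> succ(n, -1);
  for (int r = 0; r < n; ++r)
    if (prev[r] >= 0) succ[prev[r]] = r;
  if (augment) {
    for (int r = 0; r < n; ++r) {
      if (!std::isfinite(y(r, 0))) { miss_y(r, 0) = 1; y(r, 0) = 0.0; }
      if (!std::isfinite(y(r, 1))) { miss_y(r, 1) = 1; y(r, 1) = 0.0; }
      if (!std::isfinite(x(r, 0))) { miss_x1[r] = 1; x(r, 0) = 0.0; }
    }
  }

  // per-person target rows (rows with a lag predecessor)
  std::vector<std::vector<int> > rows_i(N);
  for (int r = 0; r < n; ++r)
    if (prev[r] >= 0) rows_i[pid[r]].push_back(r);
  // first row per person (no predecessor)
  std::vector<int> first_row(N, -1);
  for (int r = n - 1; r >= 0; --r)
    if (prev[r] < 0) first_row[pid[r]] = r;
  // vectorised index sets for the fixed-VAR hot path
  arma::uvec tgt_idx, prv_idx, pid_tgt, pid_all(n);
  {
    std::vector<arma::uword> tg, pv;
    for (int r = 0; r < n; ++r) {
      pid_all[r] = pid[r];
      if (prev[r] >= 0) { tg.push_back(r); pv.push_back(prev[r]); }
    }
    tgt_idx = arma::uvec(tg); prv_idx = arma::uvec(pv);
    pid_tgt = pid_all.elem(tgt_idx);
  }
  const int m_tgt = tgt_idx.n_elem;
  arma::vec ni_cnt(N, arma::fill::zeros);
  for (int i = 0; i < N; ++i) ni_cnt[i] = rows_i[i].size();

  const int n_keep = (n_iter - n_burn) / thin;
  const int npar = (random_var ? 6 * p + 6 : 2 * p + 2 + 4) + 4 + 3 +
                   (augment ? 2 : 0);
  arma::mat out(n_keep, npar);
  arma::mat ymean(n, 2, arma::fill::zeros);
  arma::vec x1mean(n, arma::fill::zeros);
  int keep = 0;

  auto Sigma_of = [&](const arma::vec& s) {
    arma::mat S(2, 2);
    double off = s[2] * std::sqrt(s[0] * s[1]);
    S(0, 0) = s[0]; S(1, 1) = s[1]; S(0, 1) = off; S(1, 0) = off;
    return S;
  };

  for (int it = 0; it < n_iter; ++it) {
    arma::mat A(2, 2), Cm(2, 2);
    A(0, 0) = arv[0]; A(0, 1) = crv[0];
    A(1, 0) = crv[1]; A(1, 1) = arv[1];
    Cm(0, 0) = cd[0]; Cm(1, 0) = cd[1];   // c1, c2 on x1
    Cm(0, 1) = cd[2]; Cm(1, 1) = cd[3];   // d1, d2 on x2
    arma::mat Sigma = Sigma_of(sig);
    arma::mat Siginv = arma::inv_sympd(Sigma);

    // stationary-law prior pieces, needed only when augmenting; transient
    // non-stationary draws of A fall back to the one-step noise law
    arma::mat Vzinv;
    bool vz_ok = false;
    if (augment) {
      arma::cx_vec ev = arma::eig_gen(A);
      if (arma::abs(ev).max() < 0.995) {
        arma::mat Vz = dlyap2(A, Sigma);
        vz_ok = Vz.is_sympd();
        if (vz_ok) Vzinv = arma::inv_sympd(Vz);
      }
      if (!vz_ok) Vzinv = Siginv;
    }

    // ---- data augmentation -------------------------------------------
    if (augment) {
      arma::vec ccol = Cm.col(0);
      arma::mat AtSiA = A.t() * Siginv * A;
      for (int r = 0; r < n; ++r) {
        if (!miss_y(r, 0) && !miss_y(r, 1) && !miss_x1[r]) continue;
        arma::mat Ai = A, Ci = Cm;
        if (random_var) {
          int i = pid[r];
          Ai(0, 0) = phi(i, 0); Ai(1, 1) = phi(i, 1);
          Ai(0, 1) = phi(i, 2); Ai(1, 0) = phi(i, 3);
        }
        int i = pid[r];
        arma::vec mui = mu.row(i).t();
        // ---- dependent variables ----
        if (miss_y(r, 0) || miss_y(r, 1)) {
          arma::mat P(2, 2, arma::fill::zeros);
          arma::vec l(2, arma::fill::zeros);
          arma::vec xr = x.row(r).t();
          if (prev[r] >= 0) {
            arma::vec m1 = mui + Ai * (y.row(prev[r]).t() - mui) + Ci * xr;
            P += Siginv; l += Siginv * m1;
          } else {
            arma::vec m1 = mui + Ci * xr;
            P += Vzinv; l += Vzinv * m1;
          }
          if (succ[r] >= 0) {
            int s = succ[r];
            arma::vec zs = y.row(s).t() - mui;
            arma::vec rhs = zs - Ci * x.row(s).t() + Ai * mui;
            arma::mat AtSi = Ai.t() * Siginv;
            P += AtSi * Ai; l += AtSi * rhs;
          }
          if (miss_y(r, 0) && miss_y(r, 1)) {
            arma::vec d = mvn_prec_draw(P, l);
            y(r, 0) = d[0]; y(r, 1) = d[1];
          } else {
            // one component observed: scalar conditional from (P, l)
            int mi = miss_y(r, 0) ? 0 : 1;
            int oi = 1 - mi;
            double mean = (l[mi] - P(mi, oi) * y(r, oi)) / P(mi, mi);
            y(r, mi) = mean + R::norm_rand() / std::sqrt(P(mi, mi));
          }
        }
        // ---- x1 ----
        if (miss_x1[r]) {
          double Pq = 0.0, lq = 0.0;
          if (prev[r] >= 0) {
            Pq += 1.0 / x_var;
            lq += x_ar * x(prev[r], 0) / x_var;
          } else {
            double v0 = x_var / (1.0 - x_ar * x_ar);
            Pq += 1.0 / v0;
          }
          if (succ[r] >= 0) {
            Pq += x_ar * x_ar / x_var;
            lq += x_ar * x(succ[r], 0) / x_var;
          }
          arma::vec dcol = Cm.col(1);
          if (prev[r] >= 0) {
            arma::vec zr = y.row(r).t() - mui;
            arma::vec zq = y.row(prev[r]).t() - mui;
            arma::vec d0 = zr - Ai * zq - dcol * x(r, 1);
            arma::vec cc = Ci.col(0);
            Pq += arma::as_scalar(cc.t() * Siginv * cc);
            lq += arma::as_scalar(cc.t() * Siginv * d0);
          } else {
            arma::vec d0 = y.row(r).t() - mui - dcol * x(r, 1);
            arma::vec cc = Ci.col(0);
            Pq += arma::as_scalar(cc.t() * Vzinv * cc);
            lq += arma::as_scalar(cc.t() * Vzinv * d0);
          }
          x(r, 0) = lq / Pq + R::norm_rand() / std::sqrt(Pq);
        }
      }
      // covariate AR(1) model parameters (x1 complete now)
      double sxx = 0.0, sxy = 0.0, ssr = 0.0; int mcnt = 0;
      for (int r = 0; r < n; ++r) {
        if (prev[r] < 0) continue;
        double xq = x(prev[r], 0), xr = x(r, 0);
        sxx += xq * xq; sxy += xq * xr; ++mcnt;
      }
      double Pa = sxx / x_var + 1.0;  // prior N(0, 1)
      double ma = (sxy / x_var) / Pa;
      x_ar = ma + R::norm_rand() / std::sqrt(Pa);
      if (x_ar >= 0.999) x_ar = 0.999;
      if (x_ar <= -0.999) x_ar = -0.999;
      for (int r = 0; r < n; ++r) {
        if (prev[r] < 0) continue;
        double e = x(r, 0) - x_ar * x(prev[r], 0);
        ssr += e * e;
      }
      double m2 = (double)mcnt;
      x_var = slice_sample(x_var, [&](double v) {
        return -0.5 * m2 * std::log(v) - ssr / (2.0 * v);
      }, 0.0, var_hi, std::max(0.5 * x_var, 0.05));
    }

    // refresh contiguous column views (augment mode mutates y / x)
    arma::vec y1c = y.col(0), y2c = y.col(1);
    arma::vec x1c = x.col(0), x2c = x.col(1);
    arma::vec y1t = y1c.elem(tgt_idx), y2t = y2c.elem(tgt_idx);
    arma::vec y1p = y1c.elem(prv_idx), y2p = y2c.elem(prv_idx);
    arma::vec x1t = x1c.elem(tgt_idx), x2t = x2c.elem(tgt_idx);

    // ---- person means -------------------------------------------------
    arma::mat G = arma::eye(2, 2) - A;
    if (!delta_zero && !random_var) {
      arma::mat Q = G.t() * Siginv * G;
      arma::mat GtSi = G.t() * Siginv;
      arma::mat Dinv = arma::diagmat(1.0 / delta2.subvec(0, 1));
      arma::vec h1 = y1t - A(0, 0) * y1p - A(0, 1) * y2p -
                     Cm(0, 0) * x1t - Cm(0, 1) * x2t;
      arma::vec h2 = y2t - A(1, 0) * y1p - A(1, 1) * y2p -
                     Cm(1, 0) * x1t - Cm(1, 1) * x2t;
      arma::vec H1(N, arma::fill::zeros), H2(N, arma::fill::zeros);
      for (int k = 0; k < m_tgt; ++k) {
        H1[pid_tgt[k]] += h1[k];
        H2[pid_tgt[k]] += h2[k];
      }
      arma::mat Mprior = Xb * B.rows(0, 1).t();  // N x 2
      for (int i = 0; i < N; ++i) {
        arma::vec Hsum = {H1[i], H2[i]};
        arma::vec mprior = Mprior.row(i).t();
        arma::mat P = Dinv + ni_cnt[i] * Q;
        arma::vec l = Dinv * mprior + GtSi * Hsum;
        if (augment && first_row[i] >= 0 &&
            (miss_y(first_row[i], 0) || miss_y(first_row[i], 1))) {
          int r0 = first_row[i];
          P += Vzinv;
          l += Vzinv * (y.row(r0).t() - Cm * x.row(r0).t());
        }
        arma::vec d = mvn_prec_draw(P, l);
        mu(i, 0) = d[0]; mu(i, 1) = d[1];
      }
    } else if (!delta_zero && random_var) {
      // person means with person-specific A
      for (int i = 0; i < N; ++i) {
        arma::mat Ai(2, 2);
        Ai(0, 0) = phi(i, 0); Ai(1, 1) = phi(i, 1);
        Ai(0, 1) = phi(i, 2); Ai(1, 0) = phi(i, 3);
        arma::mat Gi = arma::eye(2, 2) - Ai;
        arma::mat Qi = Gi.t() * Siginv * Gi;
        arma::vec Hsum(2, arma::fill::zeros);
        int ni = rows_i[i].size();
        for (size_t k = 0; k < rows_i[i].size(); ++k) {
          int r = rows_i[i][k];
          Hsum += y.row(r).t() - Ai * y.row(prev[r]).t() - Cm * x.row(r).t();
        }
        arma::mat Dinv = arma::diagmat(1.0 / delta2.subvec(0, 1));
        arma::vec mprior = B.rows(0, 1) * Xb.row(i).t();
        arma::mat P = Dinv + ni * Qi;
        arma::vec l = Dinv * mprior + Gi.t() * Siginv * Hsum;
        arma::vec d = mvn_prec_draw(P, l);
        mu(i, 0) = d[0]; mu(i, 1) = d[1];
      }
    } else if (est_between) {
      // delta == 0: mu deterministic; joint vec(B) conjugate update
      arma::mat Q = G.t() * Siginv * G;
      arma::mat Mx(p, p, arma::fill::zeros);
      arma::mat Hx(2, p, arma::fill::zeros);
      for (int r = 0; r < n; ++r) {
        if (prev[r] < 0) continue;
        int i = pid[r];
        arma::vec h = y.row(r).t() - A * y.row(prev[r]).t() -
                      Cm * x.row(r).t();
        Mx += Xb.row(i).t() * Xb.row(i);
        Hx += h * Xb.row(i);
      }
      arma::mat P = arma::kron(Mx, Q) +
                    arma::eye(2 * p, 2 * p) / v_fix;
      arma::vec l = arma::vectorise(G.t() * Siginv * Hx);
      arma::vec vb = mvn_prec_draw(P, l);
      B.rows(0, 1) = arma::reshape(vb, 2, p);
      mu = Xb * B.rows(0, 1).t();
    }

    // ---- between-level coefficients and RE variances ------------------
    if (!delta_zero && est_between) {
      for (int d = 0; d < 2; ++d) {
        arma::mat P = Xb.t() * Xb / delta2[d] +
                      arma::eye(p, p) / v_fix;
        arma::vec l = Xb.t() * mu.col(d) / delta2[d];
        B.row(d) = mvn_prec_draw(P, l).t();
        arma::vec res = mu.col(d) - Xb * B.row(d).t();
        double S = arma::dot(res, res);
        double Nn = (double)N;
        delta2[d] = slice_sample(delta2[d], [&](double v) {
          return -0.5 * Nn * std::log(v) - S / (2.0 * v);
        }, 0.0, re_hi, std::max(0.5 * delta2[d], 0.01));
      }
    }

    // ---- VAR and covariate effects ------------------------------------
    if (!random_var && (est_arcr || est_cd)) {
      // order: (ar1, cr1, c1, d1, ar2, cr2, c2, d2)
      double q11 = Siginv(0, 0), q12 = Siginv(0, 1), q22 = Siginv(1, 1);
      arma::vec mu1t = arma::vec(mu.col(0)).elem(pid_tgt);
      arma::vec mu2t = arma::vec(mu.col(1)).elem(pid_tgt);
      arma::vec z1t = y1t - mu1t, z2t = y2t - mu2t;
      arma::vec z1p = y1p - mu1t, z2p = y2p - mu2t;
      arma::mat U1 = arma::join_rows(z1p, z2p, x1t, x2t);
      arma::mat U2 = arma::join_rows(z2p, z1p, x1t, x2t);
      arma::mat M11 = U1.t() * U1;
      arma::mat M22 = U2.t() * U2;
      arma::mat M12 = U1.t() * U2;
      arma::vec t1 = U1.t() * (q11 * z1t + q12 * z2t);
      arma::vec t2 = U2.t() * (q12 * z1t + q22 * z2t);
      arma::mat P(8, 8, arma::fill::zeros);
      P.submat(0, 0, 3, 3) = q11 * M11;
      P.submat(4, 4, 7, 7) = q22 * M22;
      P.submat(0, 4, 3, 7) = q12 * M12;
      P.submat(4, 0, 7, 3) = q12 * M12.t();
      arma::vec b = arma::join_cols(t1, t2);
      arma::vec pri = {1 / v_var, 1 / v_var, 1 / v_cov, 1 / v_cov,
                       1 / v_var, 1 / v_var, 1 / v_cov, 1 / v_cov};
      P += arma::diagmat(pri);
      arma::vec theta = {arv[0], crv[0], cd[0], cd[2],
                         arv[1], crv[1], cd[1], cd[3]};
      arma::uvec act;
      if (est_arcr && est_cd) act = {0, 1, 2, 3, 4, 5, 6, 7};
      else if (est_arcr) act = {0, 1, 4, 5};
      else act = {2, 3, 6, 7};
      arma::uvec inact(8 - act.n_elem);
      {
        int k2 = 0;
        for (int j = 0; j < 8; ++j)
          if (!arma::any(act == (unsigned)j)) inact[k2++] = j;
      }
      arma::vec bc = b.elem(act);
      if (inact.n_elem > 0)
        bc -= P.submat(act, inact) * theta.elem(inact);
      arma::vec d = mvn_prec_draw(P.submat(act, act), bc);
      theta.elem(act) = d;
      arv[0] = theta[0]; crv[0] = theta[1];
      cd[0] = theta[2]; cd[2] = theta[3];
      arv[1] = theta[4]; crv[1] = theta[5];
      cd[1] = theta[6]; cd[3] = theta[7];
    } else if (random_var) {
      // person-specific AR/CR, prior N(Bphi Xb_i, diag(delta2_phi))
      double q11 = Siginv(0, 0), q12 = Siginv(0, 1), q22 = Siginv(1, 1);
      arma::mat Bphi = B.rows(2, 5);        // ar1 ar2 cr1 cr2 rows
      arma::vec d2phi = delta2.subvec(2, 5);
      arma::mat Dinv = arma::diagmat(1.0 / d2phi);
      for (int i = 0; i < N; ++i) {
        arma::mat P = Dinv;
        arma::vec mprior = Bphi * Xb.row(i).t();
        arma::vec l = Dinv * mprior;
        for (size_t k = 0; k < rows_i[i].size(); ++k) {
          int r = rows_i[i][k];
          arma::vec zr = y.row(r).t() - mu.row(i).t() - Cm * x.row(r).t();
          arma::vec zq = y.row(prev[r]).t() - mu.row(i).t();
          // W row1: (zq1, 0, zq2, 0); row2: (0, zq2, 0, zq1)
          arma::vec w1 = {zq[0], 0.0, zq[1], 0.0};
          arma::vec w2 = {0.0, zq[1], 0.0, zq[0]};
          P += q11 * w1 * w1.t() + q22 * w2 * w2.t() +
               q12 * (w1 * w2.t() + w2 * w1.t());
          l += w1 * (q11 * zr[0] + q12 * zr[1]) +
               w2 * (q12 * zr[0] + q22 * zr[1]);
        }
        arma::vec d = mvn_prec_draw(P, l);
        if (d.is_finite()) phi.row(i) = d.t();
      }
      // between-level rows and RE variances for phi
      for (int j = 0; j < 4; ++j) {
        arma::mat P = Xb.t() * Xb / delta2[2 + j] +
                      arma::eye(p, p) / v_fix;
        arma::vec l = Xb.t() * phi.col(j) / delta2[2 + j];
        B.row(2 + j) = mvn_prec_draw(P, l).t();
        arma::vec res = phi.col(j) - Xb * B.row(2 + j).t();
        double S = arma::dot(res, res);
        double Nn = (double)N;
        delta2[2 + j] = slice_sample(delta2[2 + j], [&](double v) {
          return -0.5 * Nn * std::log(v) - S / (2.0 * v);
        }, 0.0, re_hi, std::max(0.5 * delta2[2 + j], 0.005));
      }
      if (est_cd) {
        // covariate effects: order (c1, d1, c2, d2)
        arma::mat M11(2, 2, arma::fill::zeros), M22(2, 2, arma::fill::zeros),
                  M12(2, 2, arma::fill::zeros);
        arma::vec t1(2, arma::fill::zeros), t2(2, arma::fill::zeros);
        for (int r = 0; r < n; ++r) {
          if (prev[r] < 0) continue;
          int i = pid[r];
          arma::mat Ai(2, 2);
          Ai(0, 0) = phi(i, 0); Ai(1, 1) = phi(i, 1);
          Ai(0, 1) = phi(i, 2); Ai(1, 0) = phi(i, 3);
          arma::vec e = (y.row(r).t() - mu.row(i).t()) -
                        Ai * (y.row(prev[r]).t() - mu.row(i).t());
          arma::vec u = {x(r, 0), x(r, 1)};
          M11 += u * u.t(); M22 += u * u.t(); M12 += u * u.t();
          t1 += u * (q11 * e[0] + q12 * e[1]);
          t2 += u * (q12 * e[0] + q22 * e[1]);
        }
        arma::mat P(4, 4, arma::fill::zeros);
        P.submat(0, 0, 1, 1) = q11 * M11;
        P.submat(2, 2, 3, 3) = q22 * M22;
        P.submat(0, 2, 1, 3) = q12 * M12;
        P.submat(2, 0, 3, 1) = q12 * M12.t();
        P += arma::eye(4, 4) / v_cov;
        arma::vec b = arma::join_cols(t1, t2);
        arma::vec d = mvn_prec_draw(P, b);
        cd[0] = d[0]; cd[2] = d[1]; cd[1] = d[2]; cd[3] = d[3];
      }
    }

    // ---- process-noise covariance -------------------------------------
    if (est_sigma) {
      arma::vec mu1t = arma::vec(mu.col(0)).elem(pid_tgt);
      arma::vec mu2t = arma::vec(mu.col(1)).elem(pid_tgt);
      arma::vec z1t = y1t - mu1t, z2t = y2t - mu2t;
      arma::vec z1p = y1p - mu1t, z2p = y2p - mu2t;
      arma::vec a1v(m_tgt), a2v(m_tgt), c1v(m_tgt), c2v(m_tgt);
      if (random_var) {
        for (int k = 0; k < m_tgt; ++k) {
          int i = pid_tgt[k];
          a1v[k] = phi(i, 0); a2v[k] = phi(i, 1);
          c1v[k] = phi(i, 2); c2v[k] = phi(i, 3);
        }
      } else {
        a1v.fill(arv[0]); a2v.fill(arv[1]);
        c1v.fill(crv[0]); c2v.fill(crv[1]);
      }
      arma::vec e1 = z1t - a1v % z1p - c1v % z2p -
                     Cm(0, 0) * x1t - Cm(0, 1) * x2t;
      arma::vec e2 = z2t - a2v % z2p - c2v % z1p -
                     Cm(1, 0) * x1t - Cm(1, 1) * x2t;
      double S11 = arma::dot(e1, e1);
      double S22 = arma::dot(e2, e2);
      double S12 = arma::dot(e1, e2);
      double m2 = (double)m_tgt;
      auto nll = [&](double s1, double s2, double r) {
        double omr = 1.0 - r * r;
        double quad = (S11 / s1 - 2.0 * r * S12 / std::sqrt(s1 * s2) +
                       S22 / s2) / omr;
        return -0.5 * m2 * std::log(s1 * s2 * omr) - 0.5 * quad;
      };
      sig[0] = slice_sample(sig[0], [&](double v) {
        return nll(v, sig[1], sig[2]);
      }, 0.0, var_hi, std::max(0.5 * sig[0], 0.05));
      sig[1] = slice_sample(sig[1], [&](double v) {
        return nll(sig[0], v, sig[2]);
      }, 0.0, var_hi, std::max(0.5 * sig[1], 0.05));
      if (est_corr) {
        sig[2] = slice_sample(sig[2], [&](double v) {
          return nll(sig[0], sig[1], v);
        }, -1.0, 1.0, 0.1);
      }
    }

    // ---- record -------------------------------------------------------
    if (it >= n_burn && ((it - n_burn) % thin) == 0) {
      int c = 0;
      int nb = random_var ? 6 : 2;
      for (int d = 0; d < nb; ++d)
        for (int j = 0; j < p; ++j) out(keep, c++) = B(d, j);
      for (int d = 0; d < nb; ++d) out(keep, c++) = delta2[d];
      if (!random_var) {
        out(keep, c++) = arv[0]; out(keep, c++) = arv[1];
        out(keep, c++) = crv[0]; out(keep, c++) = crv[1];
      }
      out(keep, c++) = cd[0]; out(keep, c++) = cd[1];
      out(keep, c++) = cd[2]; out(keep, c++) = cd[3];
      out(keep, c++) = sig[0]; out(keep, c++) = sig[1];
      out(keep, c++) = sig[2];
      if (augment) { out(keep, c++) = x_ar; out(keep, c++) = x_var; }
      if (augment) { ymean += y; x1mean += x.col(0); }
      ++keep;
    }
  }
  if (augment && keep > 0) { ymean /= keep; x1mean /= keep; }
  return List::create(_["draws"] = out,
                      _["ymean"] = ymean, _["x1mean"] = x1mean);
}
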