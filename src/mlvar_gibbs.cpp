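// Gibbs sampler for the hierarchical Bayesian VAR(1) with latent
// person-mean centering, person-level random lagged coefficients and
// means, group-dummy regression at the between level, and missing-data
// augmentation by forward-filter backward-sampling on each person's
// state sequence. All randomness comes from R's RNG so set.seed()
// governs the chains.

#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]

using namespace arma;

static vec rnorm_vec(int n) {
  vec v(n);
  for (int i = 0; i < n; ++i) v(i) = R::norm_rand();
  return v;
}

// draw from N(Q^{-1} b, Q^{-1}) given precision Q and linear term b
static vec mvn_prec(const mat& Q, const vec& b) {
  mat Qs = 0.5 * (Q + Q.t());
  mat R;
  if (!chol(R, Qs)) {
    Qs.diag() += 1e-8 * (1.0 + Qs.diag().max());
    R = chol(Qs);
  }
  vec mean_ = solve(trimatu(R), solve(trimatl(R.t()), b));
  return mean_ + solve(trimatu(R), rnorm_vec(Q.n_rows));
}

// draw from N(m, S) for a possibly ill-conditioned covariance S
static vec mvn_cov(const vec& m, const mat& S) {
  mat Ss = 0.5 * (S + S.t());
  mat R;
  if (!chol(R, Ss)) {
    Ss.diag() += 1e-10 + 1e-8 * std::max(0.0, Ss.diag().max());
    if (!chol(R, Ss)) return m;  // numerically degenerate: zero variance
  }
  return m + R.t() * rnorm_vec(m.n_elem);
}

// Sigma ~ inverse-Wishart(nu, S) via the Bartlett decomposition
static mat riwish(double nu, const mat& S) {
  const int d = S.n_rows;
  mat Sinv = inv_sympd(0.5 * (S + S.t()));
  mat L = chol(0.5 * (Sinv + Sinv.t()), "lower");
  mat A(d, d, fill::zeros);
  for (int i = 0; i < d; ++i) {
    A(i, i) = std::sqrt(R::rchisq(nu - i));
    for (int j = 0; j < i; ++j) A(i, j) = R::norm_rand();
  }
  mat W = L * A;
  mat X = W * W.t();                 // Wishart(nu, Sinv)
  return inv_sympd(0.5 * (X + X.t()));
}

// stationary covariance of the VAR(1); false when Phi is explosive
static bool stationary_cov_cpp(const mat& Phi, const mat& Sigma, mat& P0) {
  const int d = Phi.n_rows;
  cx_vec ev = eig_gen(Phi);
  if (abs(ev).max() >= 0.999) return false;
  mat K = eye(d * d, d * d) - kron(Phi, Phi);
  vec p;
  if (!solve(p, K, vectorise(Sigma))) return false;
  P0 = reshape(p, d, d);
  P0 = 0.5 * (P0 + P0.t());
  mat Rchk;
  return chol(Rchk, P0);  // require positive definiteness
}

// FFBS draw of one person's latent series given Phi, mu, Sigma; observed
// entries of Y are held fixed, missing entries (mis[t]) are sampled.
static void ffbs_impute(mat& Y, const std::vector<uvec>& mis,
                        const std::vector<uvec>& obs,
                        const mat& Phi, const vec& mu, const mat& Sigma) {
  const int T = Y.n_rows, d = Y.n_cols;
  mat P0;
  if (!stationary_cov_cpp(Phi, Sigma, P0)) P0 = 10.0 * Sigma;

  cube Pf(d, d, T), Pp(d, d, T);
  mat mf(d, T), mp(d, T);
  vec m = mu;
  mat P = P0;
  for (int t = 0; t < T; ++t) {
    if (t > 0) {
      m = mu + Phi * (mf.col(t - 1) - mu);
      P = Phi * Pf.slice(t - 1) * Phi.t() + Sigma;
      P = 0.5 * (P + P.t());
    }
    mp.col(t) = m;
    Pp.slice(t) = P;
    const uvec& o = obs[t];
    const uvec& ms = mis[t];
    if (o.n_elem > 0) {
      vec yo = Y.row(t).t();
      vec yobs = yo(o);
      if (ms.n_elem == 0) {
        m = yo;  // fully observed
        P.zeros();
      } else {
        mat Poo = P.submat(o, o);
        mat Pmo = P.submat(ms, o);
        mat K = solve(Poo, Pmo.t()).t();  // Pmo Poo^{-1}
        vec mm = m(ms) + K * (yobs - m(o));
        mat Pmm = P.submat(ms, ms) - K * Pmo.t();
        m = yo;
        m(ms) = mm;
        P.zeros();
        P.submat(ms, ms) = 0.5 * (Pmm + Pmm.t());
      }
    }
    mf.col(t) = m;
    Pf.slice(t) = P;
  }

  // backward sampling
  vec x = mf.col(T - 1);
  if (mis[T - 1].n_elem > 0) {
    const uvec& ms = mis[T - 1];
    vec mlast = mf.col(T - 1);
    x(ms) = mvn_cov(mlast(ms), Pf.slice(T - 1).submat(ms, ms));
  }
  Y.row(T - 1) = x.t();
  for (int t = T - 2; t >= 0; --t) {
    mat J = solve(Pp.slice(t + 1), Phi * Pf.slice(t)).t();
    vec mstar = mf.col(t) + J * (x - mp.col(t + 1));
    x = Y.row(t).t();
    const uvec& ms = mis[t];
    if (ms.n_elem > 0) {
      mat Pstar = Pf.slice(t) - J * Pp.slice(t + 1) * J.t();
      vec sub = mvn_cov(mstar(ms), Pstar.submat(ms, ms));
      x(ms) = sub;
    }
    Y.row(t) = x.t();
  }
}

// [[Rcpp::export]]
Rcpp::List mlvar_gibbs_cpp(Rcpp::List Y_list, const arma::mat& X,
                           int n_iter, int n_burn, int thin,
                           double prior_var_gamma,
                           double tau_a0, double tau_b0,
                           double sigma_nu0, const arma::mat& sigma_S0) {
  const int n = Y_list.size();
  const int p = X.n_cols;
  mat Y0 = Rcpp::as<mat>(Y_list[0]);
  const int d = Y0.n_cols;
  const int q = d * d + d;  // vec(Phi) then mu

  std::vector<mat> Y(n);
  std::vector<std::vector<uvec>> mis(n), obs(n);
  std::vector<bool> has_missing(n, false);
  ivec Tlen(n);
  int n_missing_total = 0;

  for (int i = 0; i < n; ++i) {
    Y[i] = Rcpp::as<mat>(Y_list[i]);
    const int T = Y[i].n_rows;
    Tlen(i) = T;
    mis[i].resize(T);
    obs[i].resize(T);
    for (int t = 0; t < T; ++t) {
      std::vector<uword> m_idx, o_idx;
      for (int j = 0; j < d; ++j) {
        if (std::isnan(Y[i](t, j))) m_idx.push_back(j); else o_idx.push_back(j);
      }
      mis[i][t] = uvec(m_idx);
      obs[i][t] = uvec(o_idx);
      if (!m_idx.empty()) has_missing[i] = true;
      n_missing_total += m_idx.size();
    }
    // initialize missing cells at the person's item means
    for (int j = 0; j < d; ++j) {
      vec col = Y[i].col(j);
      uvec fin = find_finite(col);
      double m0 = fin.n_elem > 0 ? mean(col(fin)) : 4.0;
      for (int t = 0; t < T; ++t) if (std::isnan(Y[i](t, j))) Y[i](t, j) = m0;
    }
  }

  // state
  std::vector<mat> Phi(n, mat(d, d, fill::zeros));
  std::vector<vec> Mu(n);
  mat Theta(n, q);
  for (int i = 0; i < n; ++i) {
    Mu[i] = mean(Y[i], 0).t();
    Theta.row(i) = join_cols(vectorise(Phi[i]), Mu[i]).t();
  }
  mat Gamma(p, q, fill::zeros);
  Gamma.row(0) = mean(Theta, 0);
  vec tau2(q, fill::value(0.05));
  mat Sigma = eye(d, d);
  const mat XtX = X.t() * X;
  const mat Ip = eye(p, p);
  const mat Id = eye(d, d);

  const int n_keep = (n_iter - n_burn) / thin;
  mat out_gamma(n_keep, p * q);
  mat out_sigma(n_keep, d * d);
  int keep = 0;

  for (int iter = 1; iter <= n_iter; ++iter) {
    mat SigInv = inv_sympd(0.5 * (Sigma + Sigma.t()));

    // (1) impute missing grid cells by FFBS
    for (int i = 0; i < n; ++i) {
      if (has_missing[i]) ffbs_impute(Y[i], mis[i], obs[i], Phi[i], Mu[i], Sigma);
    }

    // (2) person-level coefficient matrices and latent means
    mat Sres(d, d, fill::zeros);
    double nres = 0.0;
    for (int i = 0; i < n; ++i) {
      const int T = Tlen(i);
      rowvec prior_mean = X.row(i) * Gamma;  // length q
      vec m_phi = prior_mean.subvec(0, d * d - 1).t();
      vec m_mu = prior_mean.subvec(d * d, q - 1).t();
      vec itau_phi = 1.0 / tau2.subvec(0, d * d - 1);
      vec itau_mu = 1.0 / tau2.subvec(d * d, q - 1);

      mat Z = Y[i].rows(1, T - 1);
      mat Xl = Y[i].rows(0, T - 2);
      Z.each_row() -= Mu[i].t();
      Xl.each_row() -= Mu[i].t();

      mat Sxx = Xl.t() * Xl;
      mat Czx = Z.t() * Xl;
      mat Q = kron(Sxx, SigInv);
      Q.diag() += itau_phi;
      vec b = vectorise(SigInv * Czx) + m_phi % itau_phi;
      vec vphi = mvn_prec(Q, b);
      Phi[i] = reshape(vphi, d, d);

      mat A = Id - Phi[i];
      vec zsum(d, fill::zeros);
      for (int t = 1; t < T; ++t) {
        zsum += Y[i].row(t).t() - Phi[i] * Y[i].row(t - 1).t();
      }
      mat Qm = (T - 1) * (A.t() * SigInv * A);
      Qm.diag() += itau_mu;
      vec bm = A.t() * SigInv * zsum + m_mu % itau_mu;
      Mu[i] = mvn_prec(Qm, bm);
      Theta.row(i) = join_cols(vphi, Mu[i]).t();

      // innovation residuals under the updated person parameters
      mat Zc = Y[i].rows(1, T - 1);
      mat Xc = Y[i].rows(0, T - 2);
      Zc.each_row() -= Mu[i].t();
      Xc.each_row() -= Mu[i].t();
      mat E = Zc - Xc * Phi[i].t();
      Sres += E.t() * E;
      nres += T - 1;
    }
    if (!Theta.is_finite()) {
      Rcpp::stop("sampler diverged (non-finite person parameters) at iteration %d",
                 iter);
    }

    // (3) between-level group regression and random-effect variances
    for (int j = 0; j < q; ++j) {
      mat Qg = XtX / tau2(j) + Ip / prior_var_gamma;
      vec bg = X.t() * Theta.col(j) / tau2(j);
      vec beta = mvn_prec(Qg, bg);
      Gamma.col(j) = beta;
      vec resid = Theta.col(j) - X * beta;
      double shape = tau_a0 + 0.5 * n;
      double rate = tau_b0 + 0.5 * dot(resid, resid);
      tau2(j) = 1.0 / R::rgamma(shape, 1.0 / rate);
      if (tau2(j) < 1e-12) tau2(j) = 1e-12;
    }

    // (4) innovation covariance
    Sigma = riwish(sigma_nu0 + nres, sigma_S0 + Sres);

    if (iter > n_burn && ((iter - n_burn) % thin == 0)) {
      out_gamma.row(keep) = vectorise(Gamma).t();  // column-major: p fast, q slow
      out_sigma.row(keep) = vectorise(Sigma).t();
      ++keep;
    }
  }

  return Rcpp::List::create(
    Rcpp::Named("gamma") = out_gamma,
    Rcpp::Named("sigma") = out_sigma,
    Rcpp::Named("n_missing") = n_missing_total,
    Rcpp::Named("n_kept") = keep);
}
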