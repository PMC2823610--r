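// Compiled cores: the Metropolis-within-Gibbs sampler for the latent
// allele-frequency surfaces, the continuous-assignment (CAM) location
// random walk, SAM likelihood scoring across posterior draws, and
// point-in-polygon.  All randomness goes through R's RNG so that draws are
// bit-reproducible under set.seed().

#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]
using namespace Rcpp;

static const double EARTH_R = 6371.0;

static double hav_km(double lat1, double lon1, double lat2, double lon2) {
  const double r = M_PI / 180.0;
  double dlat = (lat2 - lat1) * r / 2.0, dlon = (lon2 - lon1) * r / 2.0;
  double a = std::sin(dlat) * std::sin(dlat) +
             std::cos(lat1 * r) * std::cos(lat2 * r) *
             std::sin(dlon) * std::sin(dlon);
  double s = std::sqrt(a);
  if (s > 1.0) s = 1.0;
  return 2.0 * EARTH_R * std::asin(s);
}

// Even-odd ray casting; points on a vertex or edge count as inside.
static bool pip_one(double lat, double lon,
                    const arma::vec& plat, const arma::vec& plon) {
  int n = plat.n_elem;
  // drop an explicit closing vertex
  if (n > 1 && plat(n - 1) == plat(0) && plon(n - 1) == plon(0)) n--;
  bool inside = false;
  for (int i = 0, j = n - 1; i < n; j = i++) {
    double yi = plat(i), xi = plon(i), yj = plat(j), xj = plon(j);
    // boundary check: collinear and within segment bounding box
    double cross = (xj - xi) * (lat - yi) - (yj - yi) * (lon - xi);
    if (cross == 0.0 &&
        lon >= std::min(xi, xj) && lon <= std::max(xi, xj) &&
        lat >= std::min(yi, yj) && lat <= std::max(yi, yj))
      return true;
    if ((yi > lat) != (yj > lat)) {
      double xint = xi + (xj - xi) * (lat - yi) / (yj - yi);
      if (lon < xint) inside = !inside;
    }
  }
  return inside;
}

// [[Rcpp::export]]
LogicalVector pip_cpp(NumericVector lat, NumericVector lon,
                      NumericVector poly_lat, NumericVector poly_lon) {
  arma::vec plat(poly_lat.begin(), poly_lat.size());
  arma::vec plon(poly_lon.begin(), poly_lon.size());
  int n = lat.size();
  LogicalVector out(n);
  for (int i = 0; i < n; i++) out[i] = pip_one(lat[i], lon[i], plat, plon);
  return out;
}

struct LocusIndex {
  std::vector<std::vector<int>> cols;  // columns per locus
  LocusIndex(const IntegerVector& locus_of, int n_loci) : cols(n_loci) {
    for (int k = 0; k < locus_of.size(); k++)
      cols[locus_of[k] - 1].push_back(k);
  }
};

// log-likelihood contribution of one locus at one site given latent column
// values x (vector over that locus' columns) and counts n.
static double locus_ll(const arma::rowvec& x, const arma::rowvec& n) {
  double m = x.max();
  double lse = 0.0;
  for (arma::uword k = 0; k < x.n_elem; k++) lse += std::exp(x(k) - m);
  lse = m + std::log(lse);
  double ll = 0.0;
  for (arma::uword k = 0; k < x.n_elem; k++)
    if (n(k) > 0.0) ll += n(k) * (x(k) - lse);
  return ll;
}

// [[Rcpp::export]]
List fit_run_cpp(NumericMatrix counts_, IntegerVector locus_of, int n_loci,
                 NumericMatrix D_, int burn_in, int iterations, int thinning,
                 bool sample_hyper, double alpha0, double beta0, double tau20,
                 List priors) {
  arma::mat counts(counts_.begin(), counts_.nrow(), counts_.ncol(), true);
  arma::mat D(D_.begin(), D_.nrow(), D_.ncol(), true);
  const int S = counts.n_rows, K = counts.n_cols;
  LocusIndex li(locus_of, n_loci);

  const double mu_sd = priors["mu_sd"];
  const double la_m = priors["log_alpha_mean"], la_s = priors["log_alpha_sd"];
  const double lb_m = priors["log_beta_mean"], lb_s = priors["log_beta_sd"];
  const double lt_m = priors["log_tau2_mean"], lt_s = priors["log_tau2_sd"];

  double la = std::log(alpha0), lb = std::log(beta0), lt = std::log(tau20);

  arma::mat X(S, K);
  for (int k = 0; k < K; k++)
    for (int s = 0; s < S; s++)
      X(s, k) = std::log(counts(s, k) + 0.5);
  arma::vec mu(K);
  for (int k = 0; k < K; k++) mu(k) = arma::mean(X.col(k));

  // precision representation of the covariance (shared across columns)
  arma::mat P;           // Sigma^{-1}
  double logdet;
  auto build_prec = [&](double a, double b, double t, arma::mat& P_,
                        double& ld) -> bool {
    arma::mat Sig = b * arma::exp(-D / a);
    Sig.diag() += t;
    arma::mat L;
    if (!arma::chol(L, Sig, "lower")) return false;
    ld = 2.0 * arma::sum(arma::log(L.diag()));
    P_ = arma::inv_sympd(Sig);
    return true;
  };
  if (!build_prec(std::exp(la), std::exp(lb), std::exp(lt), P, logdet))
    stop("initial covariance not positive definite");

  // caches: V = X - 1 mu', PV = P V, q(k) = V_k' P V_k, colsumPV(k) = 1'P V_k
  arma::mat V = X;
  V.each_row() -= mu.t();
  arma::mat PV = P * V;
  arma::rowvec q = arma::sum(PV % V, 0);
  arma::rowvec colsumPV = arma::sum(PV, 0);
  double onePone = arma::accu(P);
  auto refresh_caches = [&]() {
    V = X;
    V.each_row() -= mu.t();
    PV = P * V;
    q = arma::sum(PV % V, 0);
    colsumPV = arma::sum(PV, 0);
    onePone = arma::accu(P);
  };

  // cached per-site per-locus log-likelihood
  arma::mat ll(S, n_loci, arma::fill::zeros);
  auto refresh_ll = [&](int l) {
    const std::vector<int>& ck = li.cols[l];
    for (int s = 0; s < S; s++) {
      arma::rowvec x(ck.size()), n(ck.size());
      for (size_t j = 0; j < ck.size(); j++) {
        x(j) = X(s, ck[j]);
        n(j) = counts(s, ck[j]);
      }
      ll(s, l) = locus_ll(x, n);
    }
  };
  for (int l = 0; l < n_loci; l++) refresh_ll(l);

  double step_lat = 0.5, step_mu = 0.3, step_hyp = 0.3;
  long acc_lat = 0, try_lat = 0, acc_mu = 0, try_mu = 0,
       acc_hyp = 0, try_hyp = 0;
  long w_acc_lat = 0, w_try_lat = 0, w_acc_mu = 0, w_try_mu = 0,
       w_acc_hyp = 0, w_try_hyp = 0;

  const int total_cycles = burn_in + iterations * thinning;
  arma::cube keep_latent(S, K, iterations);
  arma::mat keep_mu(iterations, K), keep_hyper(iterations, 3);
  int kept = 0;
  arma::vec delta(S), Pd(S), newll(S);
  arma::rowvec xbuf, nbuf;

  for (int cyc = 0; cyc < total_cycles; cyc++) {
    bool in_burn = cyc < burn_in;
    // latent field updates, one site-block proposal per locus-allele column
    for (int l = 0; l < n_loci; l++) {
      const std::vector<int>& ck = li.cols[l];
      const size_t A = ck.size();
      xbuf.set_size(A); nbuf.set_size(A);
      for (size_t j = 0; j < A; j++) nbuf(j) = counts(0, ck[j]);
      for (size_t jj = 0; jj < A; jj++) {
        int k = ck[jj];
        for (int s = 0; s < S; s++) delta(s) = step_lat * norm_rand();
        Pd = P * delta;
        // quad(new) - quad(cur) = 2 delta'P(x-mu) + delta'P delta
        double dquad = 2.0 * arma::dot(delta, PV.col(k)) +
                       arma::dot(delta, Pd);
        double dll = 0.0;
        for (int s = 0; s < S; s++) {
          for (size_t j = 0; j < A; j++) {
            xbuf(j) = X(s, ck[j]);
            nbuf(j) = counts(s, ck[j]);
          }
          xbuf(jj) += delta(s);
          newll(s) = locus_ll(xbuf, nbuf);
          dll += newll(s) - ll(s, l);
        }
        try_lat++; w_try_lat++;
        if (std::log(unif_rand()) < -0.5 * dquad + dll) {
          X.col(k) += delta;
          V.col(k) += delta;
          PV.col(k) += Pd;
          q(k) += dquad;
          colsumPV(k) += arma::accu(Pd);
          for (int s = 0; s < S; s++) ll(s, l) = newll(s);
          acc_lat++; w_acc_lat++;
        }
      }
    }
    // mu updates (random walk; data enter only through the latent prior)
    for (int k = 0; k < K; k++) {
      double dm = step_mu * norm_rand();
      double mp = mu(k) + dm;
      // V_k' P V_k with mu(k) -> mp:  q - 2 dm 1'PV_k + dm^2 1'P1
      double dquad = -2.0 * dm * colsumPV(k) + dm * dm * onePone;
      double d = -0.5 * dquad -
                 0.5 * (mp * mp - mu(k) * mu(k)) / (mu_sd * mu_sd);
      try_mu++; w_try_mu++;
      if (std::log(unif_rand()) < d) {
        mu(k) = mp;
        V.col(k) -= dm;
        PV.col(k) -= dm * P * arma::ones(S);
        q(k) += dquad;
        colsumPV(k) -= dm * onePone;
        acc_mu++; w_acc_mu++;
      }
    }
    // hyperparameter updates, log-scale random walks
    if (sample_hyper) {
      for (int p = 0; p < 3; p++) {
        double lv = (p == 0) ? la : (p == 1) ? lb : lt;
        double pm = (p == 0) ? la_m : (p == 1) ? lb_m : lt_m;
        double ps = (p == 0) ? la_s : (p == 1) ? lb_s : lt_s;
        double lp = lv + step_hyp * norm_rand();
        double a2 = std::exp(p == 0 ? lp : la);
        double b2 = std::exp(p == 1 ? lp : lb);
        double t2 = std::exp(p == 2 ? lp : lt);
        arma::mat P2;
        double ld2;
        try_hyp++; w_try_hyp++;
        if (!build_prec(a2, b2, t2, P2, ld2)) continue;
        double cur_prior = -0.5 * arma::accu(q) - 0.5 * K * logdet;
        arma::mat PV2 = P2 * V;
        double new_quad = arma::accu(PV2 % V);
        double new_prior = -0.5 * new_quad - 0.5 * K * ld2;
        double dhyp = -0.5 * ((lp - pm) * (lp - pm) -
                              (lv - pm) * (lv - pm)) / (ps * ps);
        if (std::log(unif_rand()) < new_prior - cur_prior + dhyp) {
          if (p == 0) la = lp; else if (p == 1) lb = lp; else lt = lp;
          P = P2; logdet = ld2;
          PV = PV2;
          q = arma::sum(PV % V, 0);
          colsumPV = arma::sum(PV, 0);
          onePone = arma::accu(P);
          acc_hyp++; w_acc_hyp++;
        }
      }
    }
    // step-size adaptation during burn-in only (frozen afterwards)
    if (in_burn && (cyc + 1) % 50 == 0) {
      if (w_try_lat > 0) {
        double r = (double)w_acc_lat / w_try_lat;
        if (r < 0.2) step_lat *= std::exp(-0.2);
        else if (r > 0.4) step_lat *= std::exp(0.2);
      }
      if (w_try_mu > 0) {
        double r = (double)w_acc_mu / w_try_mu;
        if (r < 0.2) step_mu *= std::exp(-0.2);
        else if (r > 0.4) step_mu *= std::exp(0.2);
      }
      if (w_try_hyp > 0) {
        double r = (double)w_acc_hyp / w_try_hyp;
        if (r < 0.2) step_hyp *= std::exp(-0.2);
        else if (r > 0.4) step_hyp *= std::exp(0.2);
      }
      w_acc_lat = w_try_lat = w_acc_mu = w_try_mu = 0;
      w_acc_hyp = w_try_hyp = 0;
      acc_lat = try_lat = acc_mu = try_mu = acc_hyp = try_hyp = 0;
    }
    if (cyc == burn_in - 1) {  // reset counters: report post-burn rates
      acc_lat = try_lat = acc_mu = try_mu = acc_hyp = try_hyp = 0;
    }
    if (!in_burn && (cyc - burn_in + 1) % thinning == 0 && kept < iterations) {
      keep_latent.slice(kept) = X;
      keep_mu.row(kept) = mu.t();
      keep_hyper(kept, 0) = std::exp(la);
      keep_hyper(kept, 1) = std::exp(lb);
      keep_hyper(kept, 2) = std::exp(lt);
      kept++;
    }
  }

  NumericVector accept = NumericVector::create(
      try_lat > 0 ? (double)acc_lat / try_lat : NA_REAL,
      try_mu > 0 ? (double)acc_mu / try_mu : NA_REAL,
      try_hyp > 0 ? (double)acc_hyp / try_hyp : NA_REAL);
  return List::create(_["latent"] = keep_latent, _["mu"] = keep_mu,
                      _["hyper"] = keep_hyper, _["accept"] = accept);
}

// Mean log-likelihood of a query genotype at every site for every retained
// draw.  latent: S x K x nd cube; returns nd x S matrix (no het constant).
// [[Rcpp::export]]
NumericMatrix sam_scores_cpp(NumericVector latent_, IntegerVector dims,
                             NumericVector q, IntegerVector locus_of,
                             int n_loci) {
  const int S = dims[0], K = dims[1], nd = dims[2];
  arma::cube latent(latent_.begin(), S, K, nd, false);
  LocusIndex li(locus_of, n_loci);
  NumericMatrix out(nd, S);
  for (int d = 0; d < nd; d++) {
    for (int s = 0; s < S; s++) {
      double tot = 0.0;
      for (int l = 0; l < n_loci; l++) {
        const std::vector<int>& ck = li.cols[l];
        bool any = false;
        for (size_t j = 0; j < ck.size(); j++)
          if (q[ck[j]] > 0) { any = true; break; }
        if (!any) continue;
        arma::rowvec x(ck.size()), n(ck.size());
        for (size_t j = 0; j < ck.size(); j++) {
          x(j) = latent(s, ck[j], d);
          n(j) = q[ck[j]];
        }
        tot += locus_ll(x, n);
      }
      out(d, s) = tot;
    }
  }
  return out;
}

// CAM location random walk for one run.  Draws are cycled over the chain:
// draw index = floor(cycle / thinning) mod nd.
// [[Rcpp::export]]
List cam_run_cpp(NumericVector latent_, IntegerVector dims, NumericMatrix mu_,
                 NumericMatrix hyper_, NumericVector q,
                 IntegerVector locus_of, int n_loci,
                 NumericVector site_lat, NumericVector site_lon,
                 NumericMatrix D_, NumericVector poly_lat,
                 NumericVector poly_lon, int burn_in, int iterations,
                 int thinning, double step_init) {
  const int S = dims[0], K = dims[1], nd = dims[2];
  arma::cube latent(latent_.begin(), S, K, nd, false);
  arma::mat mu(mu_.begin(), mu_.nrow(), mu_.ncol(), true);
  arma::mat hyper(hyper_.begin(), hyper_.nrow(), hyper_.ncol(), true);
  arma::mat D(D_.begin(), D_.nrow(), D_.ncol(), true);
  arma::vec plat(poly_lat.begin(), poly_lat.size());
  arma::vec plon(poly_lon.begin(), poly_lon.size());
  LocusIndex li(locus_of, n_loci);

  // per-draw kriging weights: B_d = Sigma_d^{-1} (X_d - 1 mu_d')
  std::vector<arma::mat> B(nd);
  for (int d = 0; d < nd; d++) {
    arma::mat Sig = hyper(d, 1) * arma::exp(-D / hyper(d, 0));
    Sig.diag() += hyper(d, 2);
    arma::mat Xc = latent.slice(d);
    Xc.each_row() -= mu.row(d);
    B[d] = arma::solve(Sig, Xc, arma::solve_opts::likely_sympd);
  }

  auto loglik_at = [&](double lat, double lon, int d) {
    arma::vec cc(S);
    for (int s = 0; s < S; s++)
      cc(s) = hyper(d, 1) *
              std::exp(-hav_km(lat, lon, site_lat[s], site_lon[s]) /
                       hyper(d, 0));
    arma::rowvec latq = mu.row(d) + cc.t() * B[d];
    double tot = 0.0;
    for (int l = 0; l < n_loci; l++) {
      const std::vector<int>& ck = li.cols[l];
      bool any = false;
      for (size_t j = 0; j < ck.size(); j++)
        if (q[ck[j]] > 0) { any = true; break; }
      if (!any) continue;
      arma::rowvec x(ck.size()), n(ck.size());
      for (size_t j = 0; j < ck.size(); j++) {
        x(j) = latq(ck[j]);
        n(j) = q[ck[j]];
      }
      tot += locus_ll(x, n);
    }
    return tot;
  };

  const double lat_lo = plat.min(), lat_hi = plat.max();
  const double lon_lo = plon.min(), lon_hi = plon.max();
  double lat = NA_REAL, lon = NA_REAL;
  bool found = false;
  for (int t = 0; t < 1000; t++) {
    double la = lat_lo + (lat_hi - lat_lo) * unif_rand();
    double lo = lon_lo + (lon_hi - lon_lo) * unif_rand();
    if (pip_one(la, lo, plat, plon)) { lat = la; lon = lo; found = true; break; }
  }
  if (!found)
    stop("CAM initialisation failed: no interior point in 1000 draws");

  double step = step_init;
  long acc = 0, tries = 0, w_acc = 0, w_try = 0;
  const int total_cycles = burn_in + iterations * thinning;
  NumericMatrix chain(iterations, 2);
  int kept = 0;
  for (int cyc = 0; cyc < total_cycles; cyc++) {
    int d = (cyc / thinning) % nd;
    double cur_ll = loglik_at(lat, lon, d);
    double plat2 = lat + step * norm_rand();
    double plon2 = lon + step * norm_rand();
    tries++; w_try++;
    if (pip_one(plat2, plon2, plat, plon)) {
      double new_ll = loglik_at(plat2, plon2, d);
      if (std::log(unif_rand()) < new_ll - cur_ll) {
        lat = plat2; lon = plon2;
        acc++; w_acc++;
      }
    }
    if (cyc < burn_in && (cyc + 1) % 50 == 0 && w_try > 0) {
      double r = (double)w_acc / w_try;
      if (r < 0.2) step *= std::exp(-0.15);
      else if (r > 0.5) step *= std::exp(0.15);
      w_acc = w_try = 0;
    }
    if (cyc == burn_in - 1) { acc = tries = 0; }
    if (cyc >= burn_in && (cyc - burn_in + 1) % thinning == 0 &&
        kept < iterations) {
      chain(kept, 0) = lat;
      chain(kept, 1) = lon;
      kept++;
    }
  }
  return List::create(_["chain"] = chain,
                      _["accept"] = tries > 0 ? (double)acc / tries : NA_REAL,
                      _["step"] = step);
}
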