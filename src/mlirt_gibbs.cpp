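#include <Rcpp.h>
using namespace Rcpp;

// Gibbs sampler for the Bayesian multilevel graded normal-ogive IRT
// model:
//   P(X_pwi >= k | theta_pw) = Phi(a_iw * theta_pw - (b_ik + d_iw))
//   theta_pw = u_w + e_pw,  u_w ~ N(0, su2),  e_pw ~ N(0, st2)
// Wave-level item structure by model id:
//   1: a_iw = a_i, d_iw = 0
//   2: d_iw ~ N(0, sb2_i) (item-wise intercept variance)
//   3: d_iw ~ N(0, sb2)   (homogeneous intercept variance)
//   4: model 2 + a_iw ~ N(a_i, sa2_i), hyperpriors
//      a_i ~ N(mu_a, tau2_a), b_ik ~ N(mu_b, tau2_b), all estimated
// Estimation: truncated-normal data augmentation for the latent ogive
// responses, conjugate normal / inverse-gamma updates, and a
// Metropolis step for the ordered category thresholds taken against the
// ogive likelihood (the augmented data are redrawn immediately after,
// making it a partially collapsed update), with proposal SDs tuned
// during burn-in. After every sweep the scale is fixed by rescaling so
// the mean item slope equals one; the likelihood is invariant under
// this rescaling.
//
// Observation arrays must arrive sorted by person-wave; iw_order and
// cat_order are permutations of observation indices sorted by item-wave
// and by item-category, with CSR-style start offsets.

// standard normal CDF via erfc: accurate to ~1e-16 in both tails and
// about three times faster than the library pnorm
static inline double fast_pnorm(double x) {
  return 0.5 * std::erfc(-x * M_SQRT1_2);
}
static inline double fast_pnorm_upper(double x) {   // P(X > x)
  return 0.5 * std::erfc(x * M_SQRT1_2);
}

// truncated standard-normal-plus-mu (sd 1) via tail-aware inversion
static double rtnorm1(double mu, double lo, double hi) {
  double a = lo - mu, b = hi - mu, z;
  if (a >= 0.0) {            // right tail: work with upper-tail probs
    double pa = fast_pnorm_upper(a), pb = fast_pnorm_upper(b);
    double u = pb + unif_rand() * (pa - pb);
    if (u < 1e-300) u = 1e-300;
    z = R::qnorm(u, 0, 1, 0, 0);
  } else if (b <= 0.0) {     // left tail
    double pa = fast_pnorm(a), pb = fast_pnorm(b);
    double u = pa + unif_rand() * (pb - pa);
    if (u < 1e-300) u = 1e-300;
    z = R::qnorm(u, 0, 1, 1, 0);
  } else {
    double pa = fast_pnorm(a), pb = fast_pnorm(b);
    double u = pa + unif_rand() * (pb - pa);
    z = R::qnorm(u, 0, 1, 1, 0);
  }
  if (z < a) z = a;
  if (z > b) z = b;
  return mu + z;
}

static inline double rtnorm_ms(double mean, double sd, double lo, double hi) {
  return mean + sd * rtnorm1(0.0, (lo - mean) / sd, (hi - mean) / sd);
}

static inline double rinvgamma(double shape, double scale) {
  return 1.0 / R::rgamma(shape, 1.0 / scale);
}

// log P(X = c) for one cell given mu = a*theta - d and the item's
// threshold block (length K-1)
static inline double log_cat_prob(double mu, int c, int K,
                                  const double* thr) {
  // P(X >= k) = Phi(mu - thr[k-1]) decreases in k, so
  // P(X = c) = Phi(mu - thr[c-1]) - Phi(mu - thr[c])
  double ge_c = (c == 0) ? 1.0 : fast_pnorm(mu - thr[c - 1]);
  double ge_c1 = (c == K - 1) ? 0.0 : fast_pnorm(mu - thr[c]);
  double p = ge_c - ge_c1;
  if (p < 1e-300) p = 1e-300;
  return std::log(p);
}

// [[Rcpp::export]]
List mlirt_gibbs_cpp(IntegerVector obs_pw, IntegerVector obs_item,
                     IntegerVector obs_wave, IntegerVector obs_x,
                     int n_pw, int n_items, int n_waves,
                     IntegerVector K, IntegerVector pw_wave,
                     IntegerVector pw_starts,
                     IntegerVector iw_order, IntegerVector iw_starts,
                     IntegerVector cat_order, IntegerVector cat_starts,
                     IntegerVector cat_offsets, IntegerVector thr_offsets,
                     int model, int n_iter, int burn_in, int thin,
                     int dev_every, List prior, List control) {
  const int M = obs_pw.size();
  const int n_thr_total = thr_offsets[n_items];

  // ---- priors -----------------------------------------------------------
  const double pr_a_mean = prior["a_mean"],   pr_a_var = prior["a_var"];
  const double pr_b_mean = prior["b_mean"],   pr_b_var = prior["b_var"];
  const double ig_shape = prior["ig_shape"],  ig_scale = prior["ig_scale"];
  const double hyper_var = prior["hyper_var"];

  // ---- control ----------------------------------------------------------
  const bool fix_items = control["fix_items"];
  const bool do_rescale = as<bool>(control["rescale"]) && !fix_items;
  const double fix_su2 = control["fix_su2"];   // < 0 means "estimate"
  const double fix_st2 = control["fix_st2"];
  const bool keep_theta = control["keep_theta"];

  // ---- state ------------------------------------------------------------
  std::vector<double> a(n_items, 1.0);            // item slopes a_i
  std::vector<double> aw(n_items * n_waves, 1.0); // wave slopes a_iw
  std::vector<double> thr(n_thr_total);           // thresholds b_ik
  std::vector<double> d(n_items * n_waves, 0.0);  // wave offsets d_iw
  std::vector<double> theta(n_pw, 0.0), u(n_waves, 0.0), Z(M, 0.0);
  std::vector<double> sb2(n_items, 0.25), sa2(n_items, 0.04);
  double sb2_hom = 0.25;
  double su2 = (fix_su2 >= 0) ? fix_su2 : 0.25;
  double st2 = (fix_st2 >= 0) ? fix_st2 : 1.0;
  double mu_a = 1.0, tau2_a = 0.25, mu_b = 0.0, tau2_b = 1.0;

  if (fix_items) {
    NumericVector a_fix = control["a_fix"], thr_fix = control["thr_fix"];
    for (int i = 0; i < n_items; i++) a[i] = a_fix[i];
    for (int t = 0; t < n_thr_total; t++) thr[t] = thr_fix[t];
  } else {
    // spread starting thresholds so ordering holds from sweep one
    for (int i = 0; i < n_items; i++) {
      int o = thr_offsets[i], nth = K[i] - 1;
      for (int t = 0; t < nth; t++)
        thr[o + t] = -1.0 + 2.0 * (t + 1.0) / (nth + 1.0);
    }
  }
  for (int i = 0; i < n_items; i++)
    for (int w = 0; w < n_waves; w++) aw[i * n_waves + w] = a[i];

  // observations per item-wave (for conjugate updates) and per wave
  std::vector<int> n_iw(n_items * n_waves, 0);
  for (int m = 0; m < M; m++) n_iw[obs_item[m] * n_waves + obs_wave[m]]++;
  std::vector<int> n_w(n_waves, 0);
  for (int p = 0; p < n_pw; p++) n_w[pw_wave[p]]++;
  std::vector<int> waves_per_item(n_items, 0);
  for (int i = 0; i < n_items; i++)
    for (int w = 0; w < n_waves; w++)
      if (n_iw[i * n_waves + w] > 0) waves_per_item[i]++;

  // Metropolis bookkeeping for thresholds
  std::vector<double> prop_sd(n_thr_total, 0.2);
  std::vector<int> acc(n_thr_total, 0), att(n_thr_total, 0);

  // ---- storage ----------------------------------------------------------
  const int n_keep = (n_iter - burn_in) / thin;
  NumericMatrix a_draws(n_keep, n_items), u_draws(n_keep, n_waves);
  NumericMatrix b_draws(n_keep, n_thr_total);
  NumericVector su2_draws(n_keep), st2_draws(n_keep), icc_draws(n_keep);
  std::vector<double> th_mean(n_pw, 0.0), th_m2(n_pw, 0.0);
  std::vector<double> d_mean(n_items * n_waves, 0.0);
  std::vector<double> aw_mean(n_items * n_waves, 0.0);
  std::vector<double> dev_draws;
  NumericMatrix theta_draws(keep_theta ? n_keep : 1,
                            keep_theta ? n_pw : 1);
  int kept = 0;

  const bool has_d = (model >= 2);
  const bool wave_slopes = (model == 4);
  const bool hier = (model == 4);

  for (int iter = 0; iter < n_iter; iter++) {
    // -- 1. thresholds: random-walk Metropolis against the ogive ---------
    if (!fix_items) {
      for (int i = 0; i < n_items; i++) {
        int o = thr_offsets[i], Ki = K[i];
        for (int t = 1; t <= Ki - 1; t++) {
          int ti = o + t - 1;
          double old_b = thr[ti];
          double new_b = old_b + norm_rand() * prop_sd[ti];
          att[ti]++;
          double lo_b = (t == 1) ? R_NegInf : thr[ti - 1];
          double hi_b = (t == Ki - 1) ? R_PosInf : thr[ti + 1];
          if (new_b <= lo_b || new_b >= hi_b) continue;
          // only categories t-1 (upper bound) and t (lower bound) move
          double ll = 0.0;
          for (int c = t - 1; c <= t; c++) {
            int s0 = cat_starts[cat_offsets[i] + c];
            int s1 = cat_starts[cat_offsets[i] + c + 1];
            for (int s = s0; s < s1; s++) {
              int m = cat_order[s];
              int iw = i * n_waves + obs_wave[m];
              double mu = aw[iw] * theta[obs_pw[m]] - d[iw];
              thr[ti] = new_b;
              double lp_new = log_cat_prob(mu, c, Ki, &thr[o]);
              thr[ti] = old_b;
              double lp_old = log_cat_prob(mu, c, Ki, &thr[o]);
              ll += lp_new - lp_old;
            }
          }
          double b_pm = hier ? mu_b : pr_b_mean;
          double b_pv = hier ? tau2_b : pr_b_var;
          ll += (-(new_b - b_pm) * (new_b - b_pm)
                 + (old_b - b_pm) * (old_b - b_pm)) / (2.0 * b_pv);
          if (std::log(unif_rand()) < ll) { thr[ti] = new_b; acc[ti]++; }
        }
      }
      // tune proposals during burn-in toward 20-50% acceptance
      if (iter < burn_in && (iter + 1) % 25 == 0) {
        for (int t = 0; t < n_thr_total; t++) {
          if (att[t] == 0) continue;
          double rate = (double)acc[t] / att[t];
          prop_sd[t] *= std::exp(0.8 * (rate - 0.35));
          if (prop_sd[t] < 0.01) prop_sd[t] = 0.01;
          if (prop_sd[t] > 2.0) prop_sd[t] = 2.0;
          acc[t] = 0; att[t] = 0;
        }
      }
    }

    // -- 2. latent responses Z -------------------------------------------
    for (int m = 0; m < M; m++) {
      int i = obs_item[m], c = obs_x[m];
      int o = thr_offsets[i], Ki = K[i], iw = i * n_waves + obs_wave[m];
      double mu = aw[iw] * theta[obs_pw[m]] - d[iw];
      double lo = (c == 0) ? R_NegInf : thr[o + c - 1];
      double hi = (c == Ki - 1) ? R_PosInf : thr[o + c];
      Z[m] = rtnorm1(mu, lo, hi);
    }

    // -- 3. abilities theta ----------------------------------------------
    for (int p = 0; p < n_pw; p++) {
      double prec = 1.0 / st2, mean_num = u[pw_wave[p]] / st2;
      for (int s = pw_starts[p]; s < pw_starts[p + 1]; s++) {
        int iw = obs_item[s] * n_waves + obs_wave[s];
        double aa = aw[iw];
        prec += aa * aa;
        mean_num += aa * (Z[s] + d[iw]);
      }
      theta[p] = mean_num / prec + norm_rand() / std::sqrt(prec);
      if (std::fabs(theta[p]) > 50.0)
        stop("sampler divergence: |theta| > 50 at person-wave %d", p + 1);
    }

    // -- 4. wave effects and ability variances ---------------------------
    {
      std::vector<double> sum_w(n_waves, 0.0);
      for (int p = 0; p < n_pw; p++) sum_w[pw_wave[p]] += theta[p];
      for (int w = 0; w < n_waves; w++) {
        double prec = 1.0 / su2 + n_w[w] / st2;
        u[w] = (sum_w[w] / st2) / prec + norm_rand() / std::sqrt(prec);
      }
      if (fix_su2 < 0) {
        double ss = 0.0;
        for (int w = 0; w < n_waves; w++) ss += u[w] * u[w];
        su2 = rinvgamma(ig_shape + 0.5 * n_waves, ig_scale + 0.5 * ss);
      }
      if (fix_st2 < 0) {
        double ss = 0.0;
        for (int p = 0; p < n_pw; p++) {
          double e = theta[p] - u[pw_wave[p]];
          ss += e * e;
        }
        st2 = rinvgamma(ig_shape + 0.5 * n_pw, ig_scale + 0.5 * ss);
      }
    }

    // -- 5. slopes --------------------------------------------------------
    if (!fix_items) {
      for (int i = 0; i < n_items; i++) {
        double pm = hier ? mu_a : pr_a_mean;
        double pv = hier ? tau2_a : pr_a_var;
        if (!wave_slopes) {
          // one slope per item, pooled over waves, truncated > 0
          double stt = 0.0, stz = 0.0;
          for (int w = 0; w < n_waves; w++) {
            int iw = i * n_waves + w;
            for (int s = iw_starts[iw]; s < iw_starts[iw + 1]; s++) {
              int m = iw_order[s];
              double th = theta[obs_pw[m]];
              stt += th * th;
              stz += th * (Z[m] + d[iw]);
            }
          }
          double prec = 1.0 / pv + stt;
          a[i] = rtnorm_ms((pm / pv + stz) / prec, 1.0 / std::sqrt(prec),
                           0.0, R_PosInf);
          for (int w = 0; w < n_waves; w++) aw[i * n_waves + w] = a[i];
        } else {
          // wave-specific slopes around the item slope
          for (int w = 0; w < n_waves; w++) {
            int iw = i * n_waves + w;
            if (n_iw[iw] == 0) { aw[iw] = a[i]; continue; }
            double stt = 0.0, stz = 0.0;
            for (int s = iw_starts[iw]; s < iw_starts[iw + 1]; s++) {
              int m = iw_order[s];
              double th = theta[obs_pw[m]];
              stt += th * th;
              stz += th * (Z[m] + d[iw]);
            }
            double prec = 1.0 / sa2[i] + stt;
            aw[iw] = rtnorm_ms((a[i] / sa2[i] + stz) / prec,
                               1.0 / std::sqrt(prec), 0.0, R_PosInf);
          }
          // item slope given its wave slopes
          double sum_aw = 0.0;
          int Wi = 0;
          for (int w = 0; w < n_waves; w++)
            if (n_iw[i * n_waves + w] > 0) {
              sum_aw += aw[i * n_waves + w];
              Wi++;
            }
          double prec = 1.0 / pv + Wi / sa2[i];
          a[i] = rtnorm_ms((pm / pv + sum_aw / sa2[i]) / prec,
                           1.0 / std::sqrt(prec), 0.0, R_PosInf);
          // slope variance
          double ss = 0.0;
          for (int w = 0; w < n_waves; w++)
            if (n_iw[i * n_waves + w] > 0) {
              double e = aw[i * n_waves + w] - a[i];
              ss += e * e;
            }
          sa2[i] = rinvgamma(ig_shape + 0.5 * Wi, ig_scale + 0.5 * ss);
        }
      }
      if (hier) {
        // hyper-updates for slope and threshold locations
        double sa = 0.0;
        for (int i = 0; i < n_items; i++) sa += a[i];
        double prec = 1.0 / hyper_var + n_items / tau2_a;
        mu_a = (sa / tau2_a) / prec + norm_rand() / std::sqrt(prec);
        double ss = 0.0;
        for (int i = 0; i < n_items; i++) ss += (a[i] - mu_a) * (a[i] - mu_a);
        tau2_a = rinvgamma(ig_shape + 0.5 * n_items, ig_scale + 0.5 * ss);
        double sb = 0.0;
        for (int t = 0; t < n_thr_total; t++) sb += thr[t];
        prec = 1.0 / hyper_var + n_thr_total / tau2_b;
        mu_b = (sb / tau2_b) / prec + norm_rand() / std::sqrt(prec);
        ss = 0.0;
        for (int t = 0; t < n_thr_total; t++)
          ss += (thr[t] - mu_b) * (thr[t] - mu_b);
        tau2_b = rinvgamma(ig_shape + 0.5 * n_thr_total, ig_scale + 0.5 * ss);
      }
    }

    // -- 6. wave offsets d_iw and their variances ------------------------
    if (has_d) {
      std::vector<double> ss_scratch(n_items, 0.0);
      for (int i = 0; i < n_items; i++) {
        double v = (model == 3) ? sb2_hom : sb2[i];
        double ss_d = 0.0;
        for (int w = 0; w < n_waves; w++) {
          int iw = i * n_waves + w;
          if (n_iw[iw] == 0) { d[iw] = 0.0; continue; }
          double sr = 0.0;
          for (int s = iw_starts[iw]; s < iw_starts[iw + 1]; s++) {
            int m = iw_order[s];
            sr += aw[iw] * theta[obs_pw[m]] - Z[m];
          }
          double prec = 1.0 / v + n_iw[iw];
          d[iw] = sr / prec + norm_rand() / std::sqrt(prec);
          ss_d += d[iw] * d[iw];
        }
        ss_scratch[i] = ss_d;
        if (model != 3)
          sb2[i] = rinvgamma(ig_shape + 0.5 * waves_per_item[i],
                             ig_scale + 0.5 * ss_d);
      }
      if (model == 3) {
        double ss = 0.0;
        int n_tot = 0;
        for (int i = 0; i < n_items; i++) {
          ss += ss_scratch[i];
          n_tot += waves_per_item[i];
        }
        sb2_hom = rinvgamma(ig_shape + 0.5 * n_tot, ig_scale + 0.5 * ss);
      }
    }

    // -- 7. identification: mean item slope = 1 --------------------------
    if (do_rescale) {
      double c = 0.0;
      for (int i = 0; i < n_items; i++) c += a[i];
      c /= n_items;
      for (int i = 0; i < n_items; i++) a[i] /= c;
      for (size_t j = 0; j < aw.size(); j++) aw[j] /= c;
      for (int p = 0; p < n_pw; p++) theta[p] *= c;
      for (int w = 0; w < n_waves; w++) u[w] *= c;
      su2 *= c * c; st2 *= c * c;
      mu_a /= c; tau2_a /= c * c;
      for (int i = 0; i < n_items; i++) sa2[i] /= c * c;
    }

    // -- 8. store ---------------------------------------------------------
    if (iter >= burn_in && (iter - burn_in) % thin == 0) {
      for (int i = 0; i < n_items; i++) a_draws(kept, i) = a[i];
      for (int t = 0; t < n_thr_total; t++) b_draws(kept, t) = thr[t];
      for (int w = 0; w < n_waves; w++) u_draws(kept, w) = u[w];
      su2_draws[kept] = su2; st2_draws[kept] = st2;
      icc_draws[kept] = su2 / (su2 + st2);
      for (int p = 0; p < n_pw; p++) {
        double delta = theta[p] - th_mean[p];
        th_mean[p] += delta / (kept + 1);
        th_m2[p] += delta * (theta[p] - th_mean[p]);
        if (keep_theta) theta_draws(kept, p) = theta[p];
      }
      for (size_t j = 0; j < d.size(); j++) {
        d_mean[j] += (d[j] - d_mean[j]) / (kept + 1);
        aw_mean[j] += (aw[j] - aw_mean[j]) / (kept + 1);
      }
      if (kept % dev_every == 0) {
        double dev = 0.0;
        for (int m = 0; m < M; m++) {
          int i = obs_item[m], iw = i * n_waves + obs_wave[m];
          double mu = aw[iw] * theta[obs_pw[m]] - d[iw];
          dev += log_cat_prob(mu, obs_x[m], K[i], &thr[thr_offsets[i]]);
        }
        dev_draws.push_back(-2.0 * dev);
      }
      kept++;
    }
    if (iter % 200 == 0) Rcpp::checkUserInterrupt();
  }

  long long acc_total = 0, att_total = 0;
  for (int t = 0; t < n_thr_total; t++) { acc_total += acc[t]; att_total += att[t]; }

  NumericVector th_mean_out(n_pw), th_sd_out(n_pw);
  for (int p = 0; p < n_pw; p++) {
    th_mean_out[p] = th_mean[p];
    th_sd_out[p] = kept > 1 ? std::sqrt(th_m2[p] / (kept - 1)) : 0.0;
  }

  return List::create(
    _["a"] = a_draws, _["b"] = b_draws, _["u"] = u_draws,
    _["sigma_u2"] = su2_draws, _["sigma_theta2"] = st2_draws,
    _["icc"] = icc_draws,
    _["theta_mean"] = th_mean_out, _["theta_sd"] = th_sd_out,
    _["theta_draws"] = theta_draws,
    _["d_mean"] = NumericVector(d_mean.begin(), d_mean.end()),
    _["aw_mean"] = NumericVector(aw_mean.begin(), aw_mean.end()),
    _["deviance"] = NumericVector(dev_draws.begin(), dev_draws.end()),
    _["mh_acceptance"] = att_total > 0 ? (double)acc_total / att_total
                                       : NA_REAL,
    _["prop_sd"] = NumericVector(prop_sd.begin(), prop_sd.end()),
    _["n_kept"] = kept);
}
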