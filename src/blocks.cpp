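// Log-posterior and gradient kernels for the choice and rating blocks on
// the unconstrained parameter scale. These mirror the R closures in fit.R
// (backend = "r") exactly; the R versions are kept as a cross-check.
#include <Rcpp.h>
using namespace Rcpp;

static inline double inv_logit(double x) {
  if (x >= 0) {
    return 1.0 / (1.0 + std::exp(-x));
  }
  double e = std::exp(x);
  return e / (1.0 + e);
}

static inline double log1pexp_c(double x) {
  return (x > 0 ? x : 0.0) + std::log1p(std::exp(-std::fabs(x)));
}

// ---- choice block -----------------------------------------------------
// q: beta[15], log_sigma_t, log_sigma_r, u[nt] (centred), v_raw[nr]
// beta: alpha[3], b_attr[3], b_form[3], b_heal[3], b_pp, b_rs, b_side

// [[Rcpp::export]]
double choice_lp_cpp(NumericVector q, IntegerVector y, IntegerVector ci,
                     NumericVector dA, NumericVector dF, NumericVector dH,
                     NumericVector zpp, NumericVector zrs,
                     NumericVector side, IntegerVector ti, IntegerVector ri,
                     int nt, int nr, NumericVector prior_mean,
                     NumericVector prior_sd, double rate) {
  const int n = y.size();
  const double st = std::exp(q[15]), sr = std::exp(q[16]);
  const double *b = q.begin();
  const double *u = q.begin() + 17;
  const double *v = q.begin() + 17 + nt;
  double lp = 0.0;
  for (int i = 0; i < n; ++i) {
    const int c = ci[i] - 1;
    double eta = b[c] + b[3 + c] * dA[i] + b[6 + c] * dF[i] +
      b[9 + c] * dH[i] + b[12] * zpp[i] + b[13] * zrs[i] + b[14] * side[i] +
      u[ti[i] - 1] + sr * v[ri[i] - 1];
    lp += y[i] * eta - log1pexp_c(eta);
  }
  for (int j = 0; j < 15; ++j) {
    double d = (q[j] - prior_mean[j]) / prior_sd[j];
    lp -= 0.5 * d * d;
  }
  lp += -rate * (st + sr) + q[15] + q[16];
  double su2 = 0.0, sv2 = 0.0;
  for (int t = 0; t < nt; ++t) su2 += u[t] * u[t];
  for (int r = 0; r < nr; ++r) sv2 += v[r] * v[r];
  lp += -0.5 * su2 / (st * st) - nt * q[15] - 0.5 * sv2;
  return lp;
}

// [[Rcpp::export]]
NumericVector choice_grad_cpp(NumericVector q, IntegerVector y,
                              IntegerVector ci, NumericVector dA,
                              NumericVector dF, NumericVector dH,
                              NumericVector zpp, NumericVector zrs,
                              NumericVector side, IntegerVector ti,
                              IntegerVector ri, int nt, int nr,
                              NumericVector prior_mean,
                              NumericVector prior_sd, double rate) {
  const int n = y.size();
  const double st = std::exp(q[15]), sr = std::exp(q[16]);
  const double *b = q.begin();
  const double *u = q.begin() + 17;
  const double *v = q.begin() + 17 + nt;
  NumericVector g(q.size());
  double gv_dot = 0.0;
  for (int i = 0; i < n; ++i) {
    const int c = ci[i] - 1;
    double eta = b[c] + b[3 + c] * dA[i] + b[6 + c] * dF[i] +
      b[9 + c] * dH[i] + b[12] * zpp[i] + b[13] * zrs[i] + b[14] * side[i] +
      u[ti[i] - 1] + sr * v[ri[i] - 1];
    double r_ = y[i] - inv_logit(eta);
    g[c] += r_;
    g[3 + c] += r_ * dA[i];
    g[6 + c] += r_ * dF[i];
    g[9 + c] += r_ * dH[i];
    g[12] += r_ * zpp[i];
    g[13] += r_ * zrs[i];
    g[14] += r_ * side[i];
    g[17 + ti[i] - 1] += r_;
    g[17 + nt + ri[i] - 1] += sr * r_;
    gv_dot += r_ * v[ri[i] - 1];
  }
  for (int j = 0; j < 15; ++j) g[j] -= (q[j] - prior_mean[j]) /
    (prior_sd[j] * prior_sd[j]);
  double su2 = 0.0;
  for (int t = 0; t < nt; ++t) su2 += u[t] * u[t];
  g[15] = su2 / (st * st) - nt - rate * st + 1.0;
  g[16] = sr * gv_dot - rate * sr + 1.0;
  for (int t = 0; t < nt; ++t) g[17 + t] -= u[t] / (st * st);
  for (int r = 0; r < nr; ++r) g[17 + nt + r] -= v[r];
  return g;
}

// ---- rating block -----------------------------------------------------
// q: b[10], cut_raw[6], log_sigma[3], w[nt] (centred), x[nr] (centred),
// z_raw[np]
// b: a_mas[3], a_fem[3], g_mas_pp, g_mas_rs, g_fem_pp, g_fem_rs

// [[Rcpp::export]]
double rating_lp_cpp(NumericVector q, IntegerVector y, IntegerVector ci,
                     IntegerVector mas, NumericVector zpp, NumericVector zrs,
                     IntegerVector ti, IntegerVector ri, IntegerVector pi_,
                     int nt, int nr, int np, NumericVector prior_mean,
                     NumericVector prior_sd, double cut_mean, double cut_sd,
                     double rate) {
  const int n = y.size();
  const double *b = q.begin();
  double cut[8];
  cut[0] = R_NegInf;
  cut[1] = q[10];
  for (int k = 2; k <= 6; ++k) cut[k] = cut[k - 1] + std::exp(q[10 + k - 1]);
  cut[7] = R_PosInf;
  const double sT = std::exp(q[16]), sR = std::exp(q[17]),
    sP = std::exp(q[18]);
  const double *w = q.begin() + 19;
  const double *x = q.begin() + 19 + nt;
  const double *z = q.begin() + 19 + nt + nr;
  double lp = 0.0;
  for (int i = 0; i < n; ++i) {
    const int c = ci[i] - 1;
    double phi;
    if (mas[i]) {
      phi = b[c] + b[6] * zpp[i] + b[7] * zrs[i];
    } else {
      phi = b[3 + c] + b[8] * zpp[i] + b[9] * zrs[i];
    }
    phi += w[ti[i] - 1] + x[ri[i] - 1] + sP * z[pi_[i] - 1];
    const int k = y[i];
    double s1 = (k == 1) ? 1.0 : inv_logit(phi - cut[k - 1]);
    double s2 = (k == 7) ? 0.0 : inv_logit(phi - cut[k]);
    double pk = s1 - s2;
    if (pk <= 0) return R_NegInf;
    lp += std::log(pk);
  }
  for (int j = 0; j < 10; ++j) {
    double d = (q[j] - prior_mean[j]) / prior_sd[j];
    lp -= 0.5 * d * d;
  }
  for (int j = 10; j < 16; ++j) {
    double d = (q[j] - cut_mean) / cut_sd;
    lp -= 0.5 * d * d;
  }
  lp += -rate * (sT + sR + sP) + q[16] + q[17] + q[18];
  double sw2 = 0.0, sx2 = 0.0, sz2 = 0.0;
  for (int t = 0; t < nt; ++t) sw2 += w[t] * w[t];
  for (int r = 0; r < nr; ++r) sx2 += x[r] * x[r];
  for (int p = 0; p < np; ++p) sz2 += z[p] * z[p];
  lp += -0.5 * sw2 / (sT * sT) - nt * q[16] -
    0.5 * sx2 / (sR * sR) - nr * q[17] - 0.5 * sz2;
  return lp;
}

// [[Rcpp::export]]
NumericVector rating_grad_cpp(NumericVector q, IntegerVector y,
                              IntegerVector ci, IntegerVector mas,
                              NumericVector zpp, NumericVector zrs,
                              IntegerVector ti, IntegerVector ri,
                              IntegerVector pi_, int nt, int nr, int np,
                              NumericVector prior_mean,
                              NumericVector prior_sd, double cut_mean,
                              double cut_sd, double rate) {
  const int n = y.size();
  const double *b = q.begin();
  double cut[8];
  cut[0] = R_NegInf;
  cut[1] = q[10];
  for (int k = 2; k <= 6; ++k) cut[k] = cut[k - 1] + std::exp(q[10 + k - 1]);
  cut[7] = R_PosInf;
  const double sT = std::exp(q[16]), sR = std::exp(q[17]),
    sP = std::exp(q[18]);
  const double *w = q.begin() + 19;
  const double *x = q.begin() + 19 + nt;
  const double *z = q.begin() + 19 + nt + nr;
  NumericVector g(q.size());
  double gcut[7];  // gradient w.r.t. ordered cut-points 1..6
  for (int k = 0; k < 7; ++k) gcut[k] = 0.0;
  double gz_dot = 0.0;
  for (int i = 0; i < n; ++i) {
    const int c = ci[i] - 1;
    double phi;
    if (mas[i]) {
      phi = b[c] + b[6] * zpp[i] + b[7] * zrs[i];
    } else {
      phi = b[3 + c] + b[8] * zpp[i] + b[9] * zrs[i];
    }
    phi += w[ti[i] - 1] + x[ri[i] - 1] + sP * z[pi_[i] - 1];
    const int k = y[i];
    double s1 = (k == 1) ? 1.0 : inv_logit(phi - cut[k - 1]);
    double s2 = (k == 7) ? 0.0 : inv_logit(phi - cut[k]);
    double pk = s1 - s2;
    if (pk < 1e-300) pk = 1e-300;
    double gphi = 1.0 - s1 - s2;
    if (k > 1) gcut[k - 1] += -s1 * (1.0 - s1) / pk;
    if (k < 7) gcut[k] += s2 * (1.0 - s2) / pk;
    if (mas[i]) {
      g[c] += gphi;
      g[6] += gphi * zpp[i];
      g[7] += gphi * zrs[i];
    } else {
      g[3 + c] += gphi;
      g[8] += gphi * zpp[i];
      g[9] += gphi * zrs[i];
    }
    g[19 + ti[i] - 1] += gphi;
    g[19 + nt + ri[i] - 1] += gphi;
    g[19 + nt + nr + pi_[i] - 1] += sP * gphi;
    gz_dot += gphi * z[pi_[i] - 1];
  }
  // chain rule through the ordered transform (reverse cumulative sum)
  double acc = 0.0;
  double graw[6];
  for (int k = 6; k >= 1; --k) {
    acc += gcut[k];
    graw[k - 1] = (k == 1) ? acc : acc * std::exp(q[10 + k - 1]);
  }
  for (int j = 0; j < 10; ++j) g[j] -= (q[j] - prior_mean[j]) /
    (prior_sd[j] * prior_sd[j]);
  for (int j = 0; j < 6; ++j) g[10 + j] = graw[j] -
    (q[10 + j] - cut_mean) / (cut_sd * cut_sd);
  double sw2 = 0.0, sx2 = 0.0;
  for (int t = 0; t < nt; ++t) sw2 += w[t] * w[t];
  for (int r = 0; r < nr; ++r) sx2 += x[r] * x[r];
  g[16] = sw2 / (sT * sT) - nt - rate * sT + 1.0;
  g[17] = sx2 / (sR * sR) - nr - rate * sR + 1.0;
  g[18] = sP * gz_dot - rate * sP + 1.0;
  for (int t = 0; t < nt; ++t) g[19 + t] -= w[t] / (sT * sT);
  for (int r = 0; r < nr; ++r) g[19 + nt + r] -= x[r] / (sR * sR);
  for (int p = 0; p < np; ++p) g[19 + nt + nr + p] -= z[p];
  return g;
}
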