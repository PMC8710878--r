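#include <Rcpp.h>
using namespace Rcpp;

// Joint log posterior and gradient for the phylogenetic Weber-fraction
// model, non-centered in every random-effect block.
//
// Unconstrained parameter vector (in order):
//   beta0; [beta1]; log sigma_{species,study,subject,task}; [logit lambda];
//   z_species (S); z_study (J); z_subject (K); z_task (T)
//
// Species effects use the eigendecomposition V = Q diag(d) Q', so that
// M(lambda) = Q diag(lambda d + 1 - lambda) Q' and the non-centered effect
// is u = sigma_sp * Q diag(sqrt(m)) z — gradients in lambda flow through
// sqrt(m) analytically. Likelihood per trial: Bernoulli with
// p = Phi(c / w), c = |n1 - n2| / sqrt(n1^2 + n2^2), log w = linear
// predictor. Trials with c = 0 contribute log(0.5) and no gradient.
//
// [[Rcpp::export]]
List weber_lp_grad(NumericVector theta, List data) {
  const NumericMatrix Q = data["Q"];
  const NumericVector d = data["d"];
  const IntegerVector sp = data["sp"], st = data["st"],
                      su = data["su"], ta = data["ta"];
  const NumericVector cvec = data["cvec"];
  const IntegerVector y = data["y"];
  const NumericVector wt = data["wt"];
  const NumericVector x = data["x"];
  const int has_beta1 = as<int>(data["has_beta1"]);
  const double lambda_fixed = as<double>(data["lambda_fixed"]);
  const double b0_loc = as<double>(data["b0_loc"]);
  const double b0_sd = as<double>(data["b0_sd"]);
  const double b1_sd = as<double>(data["b1_sd"]);
  const double sig_sd = as<double>(data["sig_sd"]);

  const int S = Q.nrow();
  const int J = as<int>(data["J"]);
  const int K = as<int>(data["K"]);
  const int T = as<int>(data["T"]);
  const int N = cvec.size();

  int off = 0;
  const double beta0 = theta[off++];
  double beta1 = 0.0;
  int i_b1 = -1;
  if (has_beta1) { i_b1 = off; beta1 = theta[off++]; }
  const int i_ssp = off, i_sst = off + 1, i_ssu = off + 2, i_sta = off + 3;
  off += 4;
  const double sig_sp = std::exp(theta[i_ssp]);
  const double sig_st = std::exp(theta[i_sst]);
  const double sig_su = std::exp(theta[i_ssu]);
  const double sig_ta = std::exp(theta[i_sta]);
  int i_ell = -1;
  double lam;
  if (lambda_fixed < 0) {
    i_ell = off;
    lam = 1.0 / (1.0 + std::exp(-theta[off++]));
  } else {
    lam = lambda_fixed;
  }
  const int i_zsp = off;          // S entries
  const int i_zst = i_zsp + S;    // J entries
  const int i_zsu = i_zst + J;    // K entries
  const int i_zta = i_zsu + K;    // T entries
  if ((int)theta.size() != i_zta + T)
    stop("parameter vector has wrong length");

  NumericVector grad(theta.size());
  double lp = 0.0;

  // priors on regression coefficients
  lp += -0.5 * std::pow((beta0 - b0_loc) / b0_sd, 2);
  grad[0] += -(beta0 - b0_loc) / (b0_sd * b0_sd);
  if (has_beta1) {
    lp += -0.5 * std::pow(beta1 / b1_sd, 2);
    grad[i_b1] += -beta1 / (b1_sd * b1_sd);
  }
  // half-normal priors on scales, with log-scale jacobian
  const int isig[4] = {i_ssp, i_sst, i_ssu, i_sta};
  const double sigv[4] = {sig_sp, sig_st, sig_su, sig_ta};
  for (int q = 0; q < 4; ++q) {
    lp += -0.5 * sigv[q] * sigv[q] / (sig_sd * sig_sd) + theta[isig[q]];
    grad[isig[q]] += -sigv[q] * sigv[q] / (sig_sd * sig_sd) + 1.0;
  }
  // uniform prior on lambda with logit jacobian
  if (i_ell >= 0) {
    lp += std::log(lam) + std::log1p(-lam);
    grad[i_ell] += 1.0 - 2.0 * lam;
  }
  // standard-normal priors on all z blocks
  for (int i = i_zsp; i < i_zta + T; ++i) {
    lp += -0.5 * theta[i] * theta[i];
    grad[i] += -theta[i];
  }

  // species effects u = sig_sp * Q diag(sqrt(m)) z
  std::vector<double> m(S), sh(S), v(S), u_sp(S);
  for (int i = 0; i < S; ++i) {
    m[i] = lam * d[i] + (1.0 - lam);
    if (m[i] < 1e-12) m[i] = 1e-12;
    sh[i] = std::sqrt(m[i]);
    v[i] = sh[i] * theta[i_zsp + i];
  }
  for (int i = 0; i < S; ++i) {
    double acc = 0.0;
    for (int j = 0; j < S; ++j) acc += Q(i, j) * v[j];
    u_sp[i] = sig_sp * acc;
  }

  // likelihood
  std::vector<double> a_sp(S, 0.0), a_st(J, 0.0), a_su(K, 0.0), a_ta(T, 0.0);
  double g_b0 = 0.0, g_b1 = 0.0;
  const double LOG_HALF = std::log(0.5);
  for (int t = 0; t < N; ++t) {
    const double lw = beta0 + beta1 * x[sp[t]] + u_sp[sp[t]] +
      sig_st * theta[i_zst + st[t]] + sig_su * theta[i_zsu + su[t]] +
      sig_ta * theta[i_zta + ta[t]];
    if (cvec[t] == 0.0) { lp += wt[t] * LOG_HALF; continue; }
    const double w = std::exp(lw);
    // cap the standardized difference: beyond ~1e6 the trial probability is
    // numerically 0/1 anyway, and an uncapped ratio overflows the gradient
    // during extreme warmup excursions
    double zt = cvec[t] / w;
    if (zt > 1e6) zt = 1e6;
    double glw;
    if (y[t] == 1) {
      const double logp = R::pnorm(zt, 0.0, 1.0, 1, 1);
      lp += wt[t] * logp;
      glw = -wt[t] * zt * std::exp(R::dnorm(zt, 0.0, 1.0, 1) - logp);
    } else {
      const double logq = R::pnorm(zt, 0.0, 1.0, 0, 1);
      lp += wt[t] * logq;
      glw = wt[t] * zt * std::exp(R::dnorm(zt, 0.0, 1.0, 1) - logq);
    }
    g_b0 += glw;
    if (has_beta1) g_b1 += glw * x[sp[t]];
    a_sp[sp[t]] += glw;
    a_st[st[t]] += glw;
    a_su[su[t]] += glw;
    a_ta[ta[t]] += glw;
  }
  grad[0] += g_b0;
  if (has_beta1) grad[i_b1] += g_b1;

  // chain rule into the species block: tvec = Q' a_sp
  double g_ell_lik = 0.0, g_ssp_lik = 0.0;
  for (int j = 0; j < S; ++j) {
    double tj = 0.0;
    for (int i = 0; i < S; ++i) tj += Q(i, j) * a_sp[i];
    grad[i_zsp + j] += sig_sp * sh[j] * tj;
    if (i_ell >= 0)
      g_ell_lik += tj * (d[j] - 1.0) / (2.0 * sh[j]) * theta[i_zsp + j];
    g_ssp_lik += tj * v[j];  // sum_i a_i u_i = sig * t.v
  }
  grad[i_ssp] += sig_sp * g_ssp_lik;
  if (i_ell >= 0) grad[i_ell] += sig_sp * g_ell_lik * lam * (1.0 - lam);

  for (int j = 0; j < J; ++j) {
    grad[i_zst + j] += sig_st * a_st[j];
    grad[i_sst] += sig_st * a_st[j] * theta[i_zst + j];
  }
  for (int k = 0; k < K; ++k) {
    grad[i_zsu + k] += sig_su * a_su[k];
    grad[i_ssu] += sig_su * a_su[k] * theta[i_zsu + k];
  }
  for (int t = 0; t < T; ++t) {
    grad[i_zta + t] += sig_ta * a_ta[t];
    grad[i_sta] += sig_ta * a_ta[t] * theta[i_zta + t];
  }

  return List::create(_["value"] = lp, _["grad"] = grad);
}
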