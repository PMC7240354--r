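// Prediction-constrained supervised LDA: MAP document-topic inference by
// exponentiated-gradient ascent on the simplex, and exact reverse-mode
// differentiation of the training objective through the unrolled inference
// iterations (gradients w.r.t. topics, label weights and bias).
#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]
using namespace arma;

static inline mat floor_mat(const mat& m, double eps) {
  return arma::max(m, eps * ones<mat>(m.n_rows, m.n_cols));
}

// One forward EG pass. X: n x V counts; phi: K x V topics (rows on simplex).
// Maximizes sum_v x_v log(sum_k pi_k phi_kv) + (alpha-1) sum_k log pi_k
// with n_iters multiplicative steps of size `step` from uniform init.
// If traj != nullptr, stores pi after every step (slices 0..n_iters).
// Per-document step: step / max(1, total count), so one step size behaves
// uniformly across document lengths (the data gradient scales with counts).
static vec doc_steps(const mat& X, double step) {
  vec tot = sum(X, 1);
  return step / clamp(tot, 1.0, datum::inf);
}

static mat eg_forward(const mat& X, const mat& phi, double alpha,
                      int n_iters, double step, double eps, cube* traj) {
  const uword n = X.n_rows, K = phi.n_rows;
  vec steps = doc_steps(X, step);
  mat Pi(n, K, fill::value(1.0 / K));
  if (traj) traj->slice(0) = Pi;
  for (int t = 1; t <= n_iters; ++t) {
    mat m = Pi * phi;                       // n x V mixture probabilities
    mat mfl = floor_mat(m, eps);
    mat A = (X / mfl) % conv_to<mat>::from(m >= eps);
    mat G = A * phi.t();                    // n x K
    if (alpha != 1.0) G += (alpha - 1.0) / clamp(Pi, 1e-100, datum::inf);
    mat logw = arma::log(clamp(Pi, 1e-300, datum::inf)) + (G.each_col() % steps);
    logw.each_col() -= arma::max(logw, 1);  // softmax shift (exact: Pi' invariant)
    mat W = arma::exp(logw);
    Pi = W.each_col() / sum(W, 1);
    if (traj) traj->slice(t) = Pi;
  }
  return Pi;
}

// [[Rcpp::export]]
Rcpp::List cpp_estimate_doc_topics(const arma::mat& X, const arma::mat& phi,
                                   double alpha, int n_iters, double step,
                                   double eps) {
  mat Pi = eg_forward(X, phi, alpha, n_iters, step, eps, nullptr);
  mat mfl = floor_mat(Pi * phi, eps);
  vec obj = sum(X % arma::log(mfl), 1);
  if (alpha != 1.0) obj += (alpha - 1.0) * sum(arma::log(clamp(Pi, 1e-300, datum::inf)), 1);
  return Rcpp::List::create(Rcpp::Named("pi") = Pi, Rcpp::Named("objective") = obj);
}

// Loss: sum_d [ -sum_v x_v log(m_v) - lambda * logBern(y_d | sigmoid(eta.pi + b)) ]
//       - tau * sum log(phi) + l2_eta * sum(eta^2)
// [[Rcpp::export]]
Rcpp::List cpp_pc_loss_grad(const arma::mat& X, const arma::vec& y,
                            const arma::mat& phi, const arma::vec& eta,
                            double bias, double alpha, double lambda,
                            int n_iters, double step, double eps,
                            double tau, double l2_eta, bool want_grad) {
  const uword n = X.n_rows, K = phi.n_rows;
  vec steps = doc_steps(X, step);
  cube traj(n, K, n_iters + 1);
  mat Pi = eg_forward(X, phi, alpha, n_iters, step, eps, &traj);

  mat m = Pi * phi;
  mat mfl = floor_mat(m, eps);
  mat mask = conv_to<mat>::from(m >= eps);
  mat A = (X / mfl) % mask;
  vec z = Pi * eta + bias;
  vec p = 1.0 / (1.0 + arma::exp(-z));
  vec label_ll = y % arma::log(clamp(p, 1e-300, 1.0)) +
                 (1.0 - y) % arma::log(clamp(1.0 - p, 1e-300, 1.0));
  double data_ll = accu(X % arma::log(mfl));
  double loss = -data_ll - lambda * accu(label_ll)
                - tau * accu(arma::log(clamp(phi, 1e-300, datum::inf)))
                + l2_eta * dot(eta, eta);
  if (!want_grad) {
    return Rcpp::List::create(Rcpp::Named("loss") = loss,
                              Rcpp::Named("pi") = Pi,
                              Rcpp::Named("prob") = p);
  }

  vec resid = y - p;                         // d(label_ll)/dz
  vec grad_eta = -lambda * (Pi.t() * resid) + 2.0 * l2_eta * eta;
  double grad_bias = -lambda * accu(resid);
  // adjoint of Pi at the top of the unroll
  mat Pibar = -(A * phi.t());
  Pibar -= lambda * (resid * eta.t());
  // direct gradient w.r.t. phi from the final data term and the prior
  mat phibar = -(Pi.t() * A) - tau / clamp(phi, 1e-300, datum::inf);

  for (int t = n_iters; t >= 1; --t) {
    const mat& Pin = traj.slice(t - 1);      // input of step t
    mat mt = Pin * phi;
    mat mflt = floor_mat(mt, eps);
    mat maskt = conv_to<mat>::from(mt >= eps);
    mat At = (X / mflt) % maskt;
    mat Gt = At * phi.t();
    if (alpha != 1.0) Gt += (alpha - 1.0) / clamp(Pin, 1e-100, datum::inf);
    mat logw = arma::log(clamp(Pin, 1e-300, datum::inf)) + (Gt.each_col() % steps);
    logw.each_col() -= arma::max(logw, 1);
    mat W = arma::exp(logw);
    vec S = sum(W, 1);
    mat Piout = W.each_col() / S;            // equals traj.slice(t)

    vec dotPP = sum(Pibar % Piout, 1);
    mat Ubar = (Pibar.each_col() - dotPP);
    Ubar.each_col() /= S;
    mat P1 = Ubar % (W / clamp(Pin, 1e-300, datum::inf)); // direct pi term
    mat Gbar = Ubar % W;
    Gbar.each_col() %= steps;

    mat Avec = Gbar * phi;                   // n x V
    mat B = ((X % Avec) / (mflt % mflt)) % maskt;
    mat P2 = -(B * phi.t());
    if (alpha != 1.0) P2 -= Gbar % ((alpha - 1.0) / square(clamp(Pin, 1e-100, datum::inf)));

    phibar += Gbar.t() * At - Pin.t() * B;
    Pibar = P1 + P2;
  }
  return Rcpp::List::create(Rcpp::Named("loss") = loss,
                            Rcpp::Named("pi") = Pi,
                            Rcpp::Named("prob") = p,
                            Rcpp::Named("grad_phi") = phibar,
                            Rcpp::Named("grad_eta") = grad_eta,
                            Rcpp::Named("grad_bias") = grad_bias);
}
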