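// Feedforward network templated on a fixed-step fourth-order Runge-Kutta
// integrator: prediction is one RK4 step whose four stage derivatives are
// all evaluated by the same sub-network f. Training minimizes mean squared
// error on the final flow point with full-batch Adam. Gradients are exact
// backpropagation through the composed stages (the stage inputs depend on
// earlier stage outputs, so each stage contributes both a parameter
// gradient and an input gradient that flows back to earlier stages).
#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]

using arma::mat;
using arma::vec;
using arma::uvec;

namespace {

// act: 0 = tanh, 1 = relu (hidden layers; output layer is linear)
// Inputs are standardized as (y - mu) / sigma before the first layer; the
// affine map is part of the model, not the data, so every RK4 stage sees
// the same transformation and the input gradient picks up a 1/sigma.
struct Net {
  std::vector<mat> W; // aliases into flat parameter vector
  std::vector<vec> b;
  int act;
  double mu = 0.0, sigma = 1.0;

  // build aliasing views over the flat storage; reserve first so vector
  // growth can never copy (and thereby detach) an aliasing view
  Net(double *flat, const std::vector<int> &widths, int act_) : act(act_) {
    W.reserve(widths.size() - 1);
    b.reserve(widths.size() - 1);
    std::size_t off = 0;
    for (std::size_t l = 1; l < widths.size(); ++l) {
      int fi = widths[l - 1], fo = widths[l];
      W.emplace_back(flat + off, fi, fo, false, true);
      off += std::size_t(fi) * fo;
      b.emplace_back(flat + off, fo, false, true);
      off += fo;
    }
  }

  std::size_t n_layers() const { return W.size(); }

  // forward pass; activations[l] is the output of layer l (l = 0 is the
  // standardized input)
  vec forward(const vec &y, std::vector<mat> &activations) const {
    std::size_t L = n_layers();
    activations.resize(L + 1);
    activations[0] = mat((y - mu) / sigma);
    activations[0].reshape(y.n_elem, 1);
    for (std::size_t l = 1; l <= L; ++l) {
      mat z = activations[l - 1] * W[l - 1];
      z.each_row() += b[l - 1].t();
      if (l < L) {
        if (act == 0) z = arma::tanh(z);
        else z = arma::clamp(z, 0.0, arma::datum::inf);
      }
      activations[l] = std::move(z);
    }
    return activations[L].col(0);
  }

  // backward pass for one stage evaluation; accumulates into gW/gb and
  // returns the gradient with respect to the stage input
  vec backward(const std::vector<mat> &activations, const vec &gout,
               std::vector<mat> &gW, std::vector<vec> &gb) const {
    std::size_t L = n_layers();
    mat gz_own(gout);
    gz_own.reshape(gout.n_elem, 1);
    for (std::size_t l = L; l >= 1; --l) {
      gW[l - 1] += activations[l - 1].t() * gz_own;
      gb[l - 1] += arma::sum(gz_own, 0).t();
      mat ga = gz_own * W[l - 1].t();
      if (l > 1) {
        if (act == 0) gz_own = ga % (1.0 - arma::square(activations[l - 1]));
        else gz_own = ga % arma::conv_to<mat>::from(activations[l - 1] > 0);
      } else {
        gz_own = std::move(ga);
      }
    }
    return gz_own.col(0) / sigma;
  }
};

std::size_t n_params(const std::vector<int> &widths) {
  std::size_t n = 0;
  for (std::size_t l = 1; l < widths.size(); ++l)
    n += std::size_t(widths[l - 1]) * widths[l] + widths[l];
  return n;
}

std::vector<mat> zeros_like_W(const Net &net) {
  std::vector<mat> g;
  for (const mat &w : net.W) g.emplace_back(arma::zeros<mat>(w.n_rows,
                                                             w.n_cols));
  return g;
}
std::vector<vec> zeros_like_b(const Net &net) {
  std::vector<vec> g;
  for (const vec &bb : net.b) g.emplace_back(arma::zeros<vec>(bb.n_elem));
  return g;
}

// loss and (optionally) flat gradient of one full-batch RK4 prediction
double rk4_loss_grad(Net &net, const vec &y, const vec &target, double dt,
                     double *gflat, const std::vector<int> &widths) {
  std::vector<mat> c1, c2, c3, c4;
  vec k1 = net.forward(y, c1);
  vec a2 = y + (dt / 2.0) * k1;
  vec k2 = net.forward(a2, c2);
  vec a3 = y + (dt / 2.0) * k2;
  vec k3 = net.forward(a3, c3);
  vec a4 = y + dt * k3;
  vec k4 = net.forward(a4, c4);
  vec pred = y + (dt / 6.0) * (k1 + 2.0 * k2 + 2.0 * k3 + k4);
  vec resid = pred - target;
  double loss = arma::dot(resid, resid) / resid.n_elem;
  if (gflat == nullptr) return loss;

  std::vector<mat> gW = zeros_like_W(net);
  std::vector<vec> gb = zeros_like_b(net);
  vec dyn = (2.0 / resid.n_elem) * resid;
  vec dk4 = (dt / 6.0) * dyn;
  vec da4 = net.backward(c4, dk4, gW, gb);
  vec dk3 = (2.0 * dt / 6.0) * dyn + dt * da4;
  vec da3 = net.backward(c3, dk3, gW, gb);
  vec dk2 = (2.0 * dt / 6.0) * dyn + (dt / 2.0) * da3;
  vec da2 = net.backward(c2, dk2, gW, gb);
  vec dk1 = (dt / 6.0) * dyn + (dt / 2.0) * da2;
  net.backward(c1, dk1, gW, gb);

  std::size_t off = 0;
  for (std::size_t l = 0; l < gW.size(); ++l) {
    std::copy(gW[l].memptr(), gW[l].memptr() + gW[l].n_elem, gflat + off);
    off += gW[l].n_elem;
    std::copy(gb[l].memptr(), gb[l].memptr() + gb[l].n_elem, gflat + off);
    off += gb[l].n_elem;
  }
  return loss;
}

std::vector<int> as_widths(const Rcpp::IntegerVector &w) {
  return std::vector<int>(w.begin(), w.end());
}

} // namespace

// [[Rcpp::export(name = ".cpp_rk4net_loss_grad")]]
Rcpp::List cpp_rk4net_loss_grad(const arma::vec &flat,
                                const Rcpp::IntegerVector &widths,
                                const arma::vec &y, const arma::vec &target,
                                double dt, int act, double mu,
                                double sigma) {
  std::vector<int> wd = as_widths(widths);
  if (flat.n_elem != n_params(wd)) Rcpp::stop("parameter vector length mismatch");
  vec params = flat;
  vec grad(params.n_elem, arma::fill::zeros);
  Net net(params.memptr(), wd, act);
  net.mu = mu; net.sigma = sigma;
  double loss = rk4_loss_grad(net, y, target, dt, grad.memptr(), wd);
  return Rcpp::List::create(Rcpp::Named("loss") = loss,
                            Rcpp::Named("grad") = grad);
}

// [[Rcpp::export(name = ".cpp_mlp_forward")]]
arma::vec cpp_mlp_forward(const arma::vec &flat,
                          const Rcpp::IntegerVector &widths,
                          const arma::vec &y, int act, double mu,
                          double sigma) {
  std::vector<int> wd = as_widths(widths);
  if (flat.n_elem != n_params(wd)) Rcpp::stop("parameter vector length mismatch");
  vec params = flat;
  Net net(params.memptr(), wd, act);
  net.mu = mu; net.sigma = sigma;
  std::vector<mat> cache;
  return net.forward(y, cache);
}

// [[Rcpp::export(name = ".cpp_rk4net_train")]]
Rcpp::List cpp_rk4net_train(const arma::vec &flat0,
                            const Rcpp::IntegerVector &widths,
                            const arma::vec &y_train,
                            const arma::vec &t_train, const arma::vec &y_val,
                            const arma::vec &t_val, double dt, double lr,
                            int epochs, double beta1, double beta2,
                            double adam_eps, int act,
                            double lr_final_fraction, double mu,
                            double sigma) {
  std::vector<int> wd = as_widths(widths);
  if (flat0.n_elem != n_params(wd)) Rcpp::stop("parameter vector length mismatch");
  vec params = flat0;
  vec grad(params.n_elem, arma::fill::zeros);
  vec m(params.n_elem, arma::fill::zeros);
  vec v(params.n_elem, arma::fill::zeros);
  Net net(params.memptr(), wd, act);
  net.mu = mu; net.sigma = sigma;
  vec train_loss(epochs), val_loss(epochs);
  bool has_val = y_val.n_elem > 0;
  std::vector<mat> cache;
  for (int e = 0; e < epochs; ++e) {
    grad.zeros();
    double loss = rk4_loss_grad(net, y_train, t_train, dt, grad.memptr(), wd);
    if (!std::isfinite(loss))
      Rcpp::stop("training diverged: non-finite loss at epoch %d", e + 1);
    train_loss[e] = loss;
    if (has_val)
      val_loss[e] = rk4_loss_grad(net, y_val, t_val, dt, nullptr, wd);
    // Adam update with bias correction
    m = beta1 * m + (1.0 - beta1) * grad;
    v = beta2 * v + (1.0 - beta2) * arma::square(grad);
    double bc1 = 1.0 - std::pow(beta1, e + 1);
    double bc2 = 1.0 - std::pow(beta2, e + 1);
    double lr_e = lr;
    if (lr_final_fraction != 1.0 && epochs > 1)
      lr_e = lr * std::pow(lr_final_fraction, double(e) / (epochs - 1));
    params -= lr_e * (m / bc1) / (arma::sqrt(v / bc2) + adam_eps);
    if (e % 256 == 0) Rcpp::checkUserInterrupt();
  }
  return Rcpp::List::create(Rcpp::Named("params") = params,
                            Rcpp::Named("train_loss") = train_loss,
                            Rcpp::Named("val_loss") = val_loss);
}
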