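// Minibatch-Adam trainer and forward pass for small dense networks.
// Layers are (M_l, b_l) pairs acting on row vectors: v_l = act(v_{l-1} M_l + b_l).
// Optional unweighted skip connection: the final layer sees [a_last_hidden, x].

#include <RcppArmadillo.h>
#include <random>
// [[Rcpp::depends(RcppArmadillo)]]

using namespace Rcpp;
using arma::mat;
using arma::rowvec;

namespace {

// activation codes: 0 = linear, 1 = relu, 2 = sigmoid_times_two
inline mat apply_act(const mat& z, int act) {
  if (act == 1) return arma::clamp(z, 0.0, arma::datum::inf);
  if (act == 2) return 2.0 / (1.0 + arma::exp(-z));
  return z;
}

// derivative of the activation expressed through the activation value a
inline mat act_deriv(const mat& a, int act) {
  if (act == 1) return arma::conv_to<mat>::from(a > 0.0);
  if (act == 2) return a % (1.0 - a / 2.0);  // 2*s*(1-s) with s = a/2
  return arma::ones<mat>(a.n_rows, a.n_cols);
}

struct Net {
  std::vector<mat> W;
  std::vector<rowvec> b;
  std::vector<int> act;
  bool skip;
};

Net unpack(const List& weights, const List& biases,
           const IntegerVector& acts, bool skip) {
  Net net;
  net.skip = skip;
  const int L = weights.size();
  for (int l = 0; l < L; ++l) {
    net.W.push_back(as<mat>(weights[l]));
    net.b.push_back(as<rowvec>(biases[l]));
    net.act.push_back(acts[l]);
  }
  return net;
}

mat net_forward(const Net& net, const mat& X) {
  const size_t L = net.W.size();
  mat a = X;
  for (size_t l = 0; l < L; ++l) {
    const mat& in = (net.skip && l == L - 1)
        ? static_cast<const mat&>(arma::join_rows(a, X))
        : a;
    mat z = in * net.W[l];
    z.each_row() += net.b[l];
    if (net.skip && l == L - 1) {
      a = apply_act(z, net.act[l]);
    } else {
      a = apply_act(z, net.act[l]);
    }
  }
  return a;
}

double mse_total(const Net& net, const mat& X, const mat& Y) {
  mat P = net_forward(net, X);
  return arma::accu(arma::square(P - Y)) / X.n_rows;
}

rowvec mse_per_output(const Net& net, const mat& X, const mat& Y) {
  mat P = net_forward(net, X);
  return arma::sum(arma::square(P - Y), 0) / X.n_rows;
}

}  // namespace

// [[Rcpp::export(name = ".cpp_forward")]]
arma::mat cpp_forward(List weights, List biases, IntegerVector acts,
                      bool skip, const arma::mat& X) {
  Net net = unpack(weights, biases, acts, skip);
  return net_forward(net, X);
}

// Trains with Adam on the summed-squared-error-per-sample objective
// (mean over the batch of ||g(x) - y||^2). Validation MSE is tracked every
// eval_every iterations; the parameter state with the lowest validation loss
// is returned. Stops after `patience` evaluations without improvement or
// after max_epochs passes over the training data.
// [[Rcpp::export(name = ".cpp_train_adam")]]
List cpp_train_adam(List weights, List biases, IntegerVector acts, bool skip,
                    const arma::mat& X, const arma::mat& Y,
                    const arma::mat& Xval, const arma::mat& Yval,
                    double lr, int batch_size, int max_epochs,
                    int eval_every, int patience, int seed) {
  Net net = unpack(weights, biases, acts, skip);
  const size_t L = net.W.size();
  const arma::uword n = X.n_rows;
  if (Y.n_rows != n) stop("X and Y row counts differ");
  if (batch_size < 1) stop("batch_size must be >= 1");

  // Adam state
  std::vector<mat> mW(L), vW(L);
  std::vector<rowvec> mb(L), vb(L);
  for (size_t l = 0; l < L; ++l) {
    mW[l].zeros(net.W[l].n_rows, net.W[l].n_cols);
    vW[l].zeros(net.W[l].n_rows, net.W[l].n_cols);
    mb[l].zeros(net.b[l].n_elem);
    vb[l].zeros(net.b[l].n_elem);
  }
  const double beta1 = 0.9, beta2 = 0.999, eps = 1e-8;

  std::mt19937_64 rng(static_cast<uint64_t>(seed));
  std::vector<arma::uword> order(n);
  for (arma::uword i = 0; i < n; ++i) order[i] = i;

  std::vector<mat> bestW = net.W;
  std::vector<rowvec> bestb = net.b;
  double best_val = mse_total(net, Xval, Yval);
  long best_iter = 0;
  int evals_since_best = 0;

  std::vector<double> hist_iter, hist_val;
  std::vector<rowvec> hist_per_out;
  hist_iter.push_back(0);
  hist_val.push_back(best_val);
  hist_per_out.push_back(mse_per_output(net, Xval, Yval));

  std::vector<mat> A(L + 1);
  long iter = 0;
  double t_adam = 0;  // Adam timestep for bias correction
  bool stop_now = false;

  for (int epoch = 0; epoch < max_epochs && !stop_now; ++epoch) {
    std::shuffle(order.begin(), order.end(), rng);
    for (arma::uword start = 0; start < n && !stop_now; start += batch_size) {
      const arma::uword end = std::min<arma::uword>(start + batch_size, n);
      arma::uvec idx(end - start);
      for (arma::uword i = start; i < end; ++i) idx[i - start] = order[i];
      const mat Xb = X.rows(idx);
      const mat Yb = Y.rows(idx);
      const double nb = static_cast<double>(Xb.n_rows);

      // forward, caching activations
      A[0] = Xb;
      for (size_t l = 0; l < L; ++l) {
        const mat& in = (net.skip && l == L - 1)
            ? static_cast<const mat&>(arma::join_rows(A[l], Xb))
            : A[l];
        mat z = in * net.W[l];
        z.each_row() += net.b[l];
        A[l + 1] = apply_act(z, net.act[l]);
      }

      if (!A[L].is_finite()) stop("non-finite network output at iteration %ld",
                                  iter);

      // backward
      mat delta = (2.0 / nb) * (A[L] - Yb);
      delta %= act_deriv(A[L], net.act[L - 1]);
      t_adam += 1.0;
      const double bc1 = 1.0 - std::pow(beta1, t_adam);
      const double bc2 = 1.0 - std::pow(beta2, t_adam);
      for (int l = static_cast<int>(L) - 1; l >= 0; --l) {
        mat in = (net.skip && l == static_cast<int>(L) - 1)
            ? arma::join_rows(A[l], Xb) : A[l];
        mat gW = in.t() * delta;
        rowvec gb = arma::sum(delta, 0);
        if (l > 0) {
          mat back;
          if (net.skip && l == static_cast<int>(L) - 1) {
            // gradient flows only through the learned path; the skipped copy
            // of x carries no parameters upstream of itself
            back = delta * net.W[l].rows(0, A[l].n_cols - 1).t();
          } else {
            back = delta * net.W[l].t();
          }
          delta = back % act_deriv(A[l], net.act[l - 1]);
        }
        // Adam update
        mW[l] = beta1 * mW[l] + (1.0 - beta1) * gW;
        vW[l] = beta2 * vW[l] + (1.0 - beta2) * arma::square(gW);
        mb[l] = beta1 * mb[l] + (1.0 - beta1) * gb;
        vb[l] = beta2 * vb[l] + (1.0 - beta2) * arma::square(gb);
        net.W[l] -= lr * (mW[l] / bc1) / (arma::sqrt(vW[l] / bc2) + eps);
        net.b[l] -= lr * (mb[l] / bc1) / (arma::sqrt(vb[l] / bc2) + eps);
      }

      ++iter;
      if (iter % eval_every == 0) {
        const double vloss = mse_total(net, Xval, Yval);
        hist_iter.push_back(static_cast<double>(iter));
        hist_val.push_back(vloss);
        hist_per_out.push_back(mse_per_output(net, Xval, Yval));
        if (vloss < best_val) {
          best_val = vloss;
          best_iter = iter;
          bestW = net.W;
          bestb = net.b;
          evals_since_best = 0;
        } else if (++evals_since_best >= patience) {
          stop_now = true;
        }
        Rcpp::checkUserInterrupt();
      }
    }
  }

  // final state may beat the last recorded evaluation
  const double vloss = mse_total(net, Xval, Yval);
  if (vloss < best_val) {
    best_val = vloss;
    best_iter = iter;
    bestW = net.W;
    bestb = net.b;
  }

  List outW(L), outb(L);
  for (size_t l = 0; l < L; ++l) {
    outW[l] = bestW[l];
    outb[l] = NumericVector(bestb[l].begin(), bestb[l].end());
  }
  const size_t nh = hist_iter.size();
  mat per_out(nh, hist_per_out[0].n_elem);
  for (size_t i = 0; i < nh; ++i) per_out.row(i) = hist_per_out[i];
  return List::create(
      _["weights"] = outW, _["biases"] = outb,
      _["history_iteration"] = hist_iter, _["history_val_loss"] = hist_val,
      _["history_per_output"] = per_out,
      _["best_val"] = best_val, _["best_iteration"] = best_iter,
      _["iterations"] = iter);
}
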