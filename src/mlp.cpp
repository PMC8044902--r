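// Backpropagation core for the deep tanh network: per-sample (online)
// gradient descent with momentum and weight decay.  All layers, including
// the output, use tanh, so targets must be pre-scaled into (-1, 1) on the
// R side.  Loss is 0.5 * squared error per sample; reported errors are
// full-pass mean squared errors.

#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]
using namespace Rcpp;

typedef std::vector<arma::mat> MatList;
typedef std::vector<arma::rowvec> VecList;

static MatList as_mats(List L) {
  MatList out;
  for (int i = 0; i < L.size(); ++i) out.push_back(as<arma::mat>(L[i]));
  return out;
}

static VecList as_vecs(List L) {
  VecList out;
  for (int i = 0; i < L.size(); ++i) out.push_back(as<arma::rowvec>(L[i]));
  return out;
}

static List wrap_mats(const MatList& M) {
  List out(M.size());
  for (size_t i = 0; i < M.size(); ++i) out[i] = M[i];
  return out;
}

static List wrap_vecs(const VecList& V) {
  List out(V.size());
  for (size_t i = 0; i < V.size(); ++i) out[i] = V[i];
  return out;
}

// Forward pass for a single sample; fills activations a[0..L] where
// a[0] = x and a[l] = tanh(a[l-1] W[l-1] + b[l-1]).
static void forward_row(const MatList& W, const VecList& b,
                        const arma::rowvec& x, VecList& a) {
  a[0] = x;
  for (size_t l = 0; l < W.size(); ++l) {
    a[l + 1] = arma::tanh(a[l] * W[l] + b[l]);
  }
}

// Backprop for one sample.  Returns the loss 0.5*||a_L - y||^2 and fills
// dW/db with the gradients.
static double grad_row(const MatList& W, const VecList& b,
                       const arma::rowvec& x, const arma::rowvec& y,
                       VecList& a, MatList& dW, VecList& db) {
  forward_row(W, b, x, a);
  size_t L = W.size();
  arma::rowvec err = a[L] - y;
  double loss = 0.5 * arma::dot(err, err);
  arma::rowvec delta = err % (1.0 - arma::square(a[L]));
  for (size_t l = L; l-- > 0;) {
    dW[l] = a[l].t() * delta;
    db[l] = delta;
    if (l > 0) {
      delta = (delta * W[l].t()) % (1.0 - arma::square(a[l]));
    }
  }
  return loss;
}

// [[Rcpp::export]]
List mlp_forward_cpp(List W_, List b_, const arma::mat& X) {
  MatList W = as_mats(W_);
  VecList b = as_vecs(b_);
  size_t L = W.size();
  List acts(L + 1);
  arma::mat cur = X;
  acts[0] = cur;
  for (size_t l = 0; l < L; ++l) {
    cur = arma::tanh(cur * W[l] + arma::repmat(b[l], cur.n_rows, 1));
    acts[l + 1] = cur;
  }
  return acts;
}

// [[Rcpp::export]]
List mlp_grad_cpp(List W_, List b_, const arma::rowvec& x,
                  const arma::rowvec& y) {
  MatList W = as_mats(W_);
  VecList b = as_vecs(b_);
  size_t L = W.size();
  VecList a(L + 1);
  MatList dW(L);
  VecList db(L);
  double loss = grad_row(W, b, x, y, a, dW, db);
  return List::create(_["loss"] = loss, _["dW"] = wrap_mats(dW),
                      _["db"] = wrap_vecs(db));
}

static double full_mse(const MatList& W, const VecList& b,
                       const arma::mat& X, const arma::mat& Y) {
  if (X.n_rows == 0) return NA_REAL;
  arma::mat cur = X;
  for (size_t l = 0; l < W.size(); ++l) {
    cur = arma::tanh(cur * W[l] + arma::repmat(b[l], cur.n_rows, 1));
  }
  arma::mat err = cur - Y;
  return arma::accu(arma::square(err)) / err.n_elem;
}

// order: epochs x n_train matrix of 0-based training-row visit orders.
// snap_from/snap_to: 1-based epoch window within which the test-error
// minimizing weights are retained.
// [[Rcpp::export]]
List mlp_train_cpp(List W_, List b_, const arma::mat& Xtr,
                   const arma::mat& Ytr, const arma::mat& Xte,
                   const arma::mat& Yte, double lr, double momentum,
                   double decay, const arma::imat& order,
                   int snap_from, int snap_to, bool batch = false) {
  MatList W = as_mats(W_);
  VecList b = as_vecs(b_);
  size_t L = W.size();
  MatList vW(L);
  VecList vb(L);
  MatList dW(L);
  VecList db(L);
  VecList a(L + 1);
  for (size_t l = 0; l < L; ++l) {
    vW[l] = arma::zeros<arma::mat>(W[l].n_rows, W[l].n_cols);
    vb[l] = arma::zeros<arma::rowvec>(b[l].n_elem);
  }
  int epochs = order.n_rows;
  int ntr = order.n_cols;
  arma::vec train_mse(epochs), test_mse(epochs);
  bool has_test = Xte.n_rows > 0;
  MatList bestW = W;
  VecList bestb = b;
  double best_err = arma::datum::inf;
  int best_epoch = -1;

  MatList sW(L);
  VecList sb(L);
  for (int e = 0; e < epochs; ++e) {
    if (batch) {
      for (size_t l = 0; l < L; ++l) {
        sW[l] = arma::zeros<arma::mat>(W[l].n_rows, W[l].n_cols);
        sb[l] = arma::zeros<arma::rowvec>(b[l].n_elem);
      }
      for (int i = 0; i < ntr; ++i) {
        int r = order(e, i);
        grad_row(W, b, Xtr.row(r), Ytr.row(r), a, dW, db);
        for (size_t l = 0; l < L; ++l) { sW[l] += dW[l]; sb[l] += db[l]; }
      }
      for (size_t l = 0; l < L; ++l) {
        vW[l] = momentum * vW[l] - lr * (sW[l] / ntr + decay * W[l]);
        vb[l] = momentum * vb[l] - lr * (sb[l] / ntr);
        W[l] += vW[l];
        b[l] += vb[l];
      }
    } else {
      for (int i = 0; i < ntr; ++i) {
        int r = order(e, i);
        arma::rowvec x = Xtr.row(r);
        arma::rowvec y = Ytr.row(r);
        grad_row(W, b, x, y, a, dW, db);
        for (size_t l = 0; l < L; ++l) {
          vW[l] = momentum * vW[l] - lr * (dW[l] + decay * W[l]);
          vb[l] = momentum * vb[l] - lr * db[l];
          W[l] += vW[l];
          b[l] += vb[l];
        }
      }
    }
    train_mse(e) = full_mse(W, b, Xtr, Ytr);
    test_mse(e) = has_test ? full_mse(W, b, Xte, Yte) : NA_REAL;
    if (!std::isfinite(train_mse(e))) {
      stop("training diverged (non-finite error) at epoch %d; "
           "try a smaller learning rate", e + 1);
    }
    int ep1 = e + 1;
    if (ep1 >= snap_from && ep1 <= snap_to) {
      double sel = has_test ? test_mse(e) : train_mse(e);
      if (sel < best_err) {
        best_err = sel;
        bestW = W;
        bestb = b;
        best_epoch = ep1;
      }
    }
  }
  return List::create(
    _["W"] = wrap_mats(bestW), _["b"] = wrap_vecs(bestb),
    _["W_final"] = wrap_mats(W), _["b_final"] = wrap_vecs(b),
    _["train_mse"] = train_mse, _["test_mse"] = test_mse,
    _["best_epoch"] = best_epoch);
}
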