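// Shallow fully connected networks for the cascaded quantification pipeline.
// Single-threaded on purpose: training must be bit-reproducible under a seed.
#include <RcppArmadillo.h>
#include <random>
// [[Rcpp::depends(RcppArmadillo)]]

using namespace arma;

namespace {

const double BN_EPS = 1e-5;
const double BN_MOMENTUM = 0.1;
const double CLIP_P = 1e-12;   // probability floor inside the cross-entropy
const double LOG1P_FLOOR = -1.0 + 1e-9;

struct Layer {
  mat W;        // (out x in)
  vec b;
  // batch-norm parameters (classifiers only)
  vec gamma, beta, run_mean, run_var;
};

struct Net {
  std::vector<Layer> layers;  // hidden layers
  mat W_out;                  // (C x last_hidden)
  vec b_out;
  bool batchnorm;
};

// columns are samples throughout
mat forward_eval(const Net &net, const mat &X) {
  mat a = X;
  for (const Layer &L : net.layers) {
    mat z = L.W * a;
    z.each_col() += L.b;
    if (net.batchnorm) {
      z.each_col() -= L.run_mean;
      z.each_col() /= sqrt(L.run_var + BN_EPS);
      z.each_col() %= L.gamma;
      z.each_col() += L.beta;
    }
    a = clamp(z, 0.0, datum::inf);  // ReLU
  }
  mat out = net.W_out * a;
  out.each_col() += net.b_out;
  return out;
}

mat softmax_cols(const mat &logits) {
  mat z = logits;
  rowvec mx = max(z, 0);
  z.each_row() -= mx;
  z = exp(z);
  rowvec s = sum(z, 0);
  z.each_row() /= s;
  return z;
}

// data loss (no L2 term); Y one-hot (C x n) for CCE, (1 x n) otherwise
double data_loss(int loss_kind, const mat &out, const mat &Y) {
  const double n = (double)out.n_cols;
  if (loss_kind == 0) {                       // categorical cross-entropy
    mat p = softmax_cols(out);
    p = clamp(p, CLIP_P, 1.0);
    return -accu(Y % log(p)) / n;
  } else if (loss_kind == 1) {                // mean squared error
    return accu(square(Y - out)) / n;
  } else {                                    // printed RMSLE form:
    mat yp = clamp(out, LOG1P_FLOOR, datum::inf); // mean |log1p y - log1p y'|
    return accu(abs(log1p(Y) - log1p(yp))) / n;
  }
}

}  // namespace

// [[Rcpp::export]]
Rcpp::List nn_train_cpp(const arma::mat &X_in,      // n x p (standardised)
                        const arma::mat &Y_in,      // n x C one-hot, or n x 1
                        const arma::ivec &hidden,
                        const arma::vec &dropout,
                        int loss_kind,              // 0 CCE, 1 MSE, 2 RMSLE
                        bool batchnorm,
                        int batch_size,
                        double lr0, double lr_factor, int lr_period,
                        double l2,
                        int max_epochs,
                        bool early_stop, double early_tol, int early_patience,
                        double out_loc, double out_scale,
                        unsigned int seed) {
  mat X = X_in.t();   // p x n
  mat Y = Y_in.t();   // C x n
  const uword n = X.n_cols;
  const uword n_hidden = hidden.n_elem;

  std::mt19937 rng(seed);
  std::uniform_real_distribution<double> unif(0.0, 1.0);

  Net net;
  net.batchnorm = batchnorm;
  uword fan_in = X.n_rows;
  for (uword l = 0; l < n_hidden; ++l) {
    Layer L;
    uword h = (uword)hidden[l];
    double bound = 1.0 / std::sqrt((double)fan_in);
    L.W.set_size(h, fan_in);
    for (uword j = 0; j < fan_in; ++j)     // column-major fill, fixed order
      for (uword i = 0; i < h; ++i)
        L.W(i, j) = (2.0 * unif(rng) - 1.0) * bound;
    L.b = zeros<vec>(h);
    if (batchnorm) {
      L.gamma = ones<vec>(h); L.beta = zeros<vec>(h);
      L.run_mean = zeros<vec>(h); L.run_var = ones<vec>(h);
    }
    net.layers.push_back(L);
    fan_in = h;
  }
  {
    // the output layer is initialised at the location/scale of the training
    // targets (out_loc, out_scale); with heavily scaled regression targets a
    // unit-scale initial output cannot reach the target range within the
    // learning-rate budget of the printed schedule
    uword C = Y.n_rows;
    double bound = out_scale / std::sqrt((double)fan_in);
    net.W_out.set_size(C, fan_in);
    for (uword j = 0; j < fan_in; ++j)
      for (uword i = 0; i < C; ++i)
        net.W_out(i, j) = (2.0 * unif(rng) - 1.0) * bound;
    net.b_out = vec(C, fill::value(out_loc));
  }

  // Adam state, one slot per parameter tensor
  std::vector<mat> mW(n_hidden + 1), vW(n_hidden + 1);
  std::vector<vec> mb(n_hidden + 1), vb(n_hidden + 1);
  std::vector<vec> mg(n_hidden), vg(n_hidden), mbeta(n_hidden), vbeta(n_hidden);
  for (uword l = 0; l < n_hidden; ++l) {
    mW[l] = zeros(size(net.layers[l].W)); vW[l] = mW[l];
    mb[l] = zeros<vec>(net.layers[l].b.n_elem); vb[l] = mb[l];
    if (batchnorm) {
      mg[l] = zeros<vec>(net.layers[l].gamma.n_elem); vg[l] = mg[l];
      mbeta[l] = mg[l]; vbeta[l] = mg[l];
    }
  }
  mW[n_hidden] = zeros(size(net.W_out)); vW[n_hidden] = mW[n_hidden];
  mb[n_hidden] = zeros<vec>(net.b_out.n_elem); vb[n_hidden] = mb[n_hidden];

  const double b1 = 0.9, b2 = 0.999, adam_eps = 1e-8;
  long step = 0;

  std::vector<double> trace;
  trace.reserve(max_epochs);
  double best_loss = datum::inf;
  int best_epoch = -1, since_improve = 0;
  Net best = net;
  bool diverged = false;

  std::vector<uword> idx(n);
  for (uword i = 0; i < n; ++i) idx[i] = i;

  int epochs_run = 0;
  for (int epoch = 0; epoch < max_epochs; ++epoch) {
    epochs_run = epoch + 1;
    double lr = lr0 * std::pow(lr_factor, (double)(epoch / lr_period));
    std::shuffle(idx.begin(), idx.end(), rng);

    // partial final batches are kept unless batch norm is active
    // (batch statistics are undefined on tiny remainders)
    uword nb;
    if (batchnorm) {
      nb = n / (uword)batch_size;
      if (nb == 0) nb = 1;
    } else {
      nb = (n + (uword)batch_size - 1) / (uword)batch_size;
    }
    for (uword bi = 0; bi < nb; ++bi) {
      uword lo = bi * (uword)batch_size;
      uword hi = std::min(lo + (uword)batch_size, n);
      uword m = hi - lo;
      uvec take(m);
      for (uword i = 0; i < m; ++i) take[i] = idx[lo + i];
      mat a = X.cols(take);
      mat y = Y.cols(take);

      // ---- forward (training mode) ----
      std::vector<mat> acts(n_hidden + 1);  // inputs to each layer
      std::vector<mat> zs(n_hidden), zhats(n_hidden), masks(n_hidden);
      std::vector<vec> mus(n_hidden), vars(n_hidden);
      acts[0] = a;
      for (uword l = 0; l < n_hidden; ++l) {
        Layer &L = net.layers[l];
        mat z = L.W * acts[l];
        z.each_col() += L.b;
        if (batchnorm) {
          vec mu = mean(z, 1);
          mat zc = z.each_col() - mu;
          vec var_ = mean(square(zc), 1);
          mat zhat = zc.each_col() / sqrt(var_ + BN_EPS);
          mus[l] = mu; vars[l] = var_; zhats[l] = zhat;
          L.run_mean = (1.0 - BN_MOMENTUM) * L.run_mean + BN_MOMENTUM * mu;
          L.run_var  = (1.0 - BN_MOMENTUM) * L.run_var  + BN_MOMENTUM * var_;
          z = zhat.each_col() % L.gamma;
          z.each_col() += L.beta;
        }
        zs[l] = z;
        mat h = clamp(z, 0.0, datum::inf);
        double rate = dropout[l];
        mat mask(h.n_rows, h.n_cols, fill::ones);
        if (rate > 0.0) {
          double keep = 1.0 - rate;
          for (uword j = 0; j < mask.n_cols; ++j)
            for (uword i = 0; i < mask.n_rows; ++i)
              mask(i, j) = (unif(rng) < keep) ? 1.0 / keep : 0.0;
          h %= mask;
        }
        masks[l] = mask;
        acts[l + 1] = h;
      }
      mat out = net.W_out * acts[n_hidden];
      out.each_col() += net.b_out;

      // ---- output gradient ----
      mat dout;
      double mm = (double)m;
      if (loss_kind == 0) {
        dout = (softmax_cols(out) - y) / mm;
      } else if (loss_kind == 1) {
        dout = 2.0 * (out - y) / mm;
      } else {
        mat yp = clamp(out, LOG1P_FLOOR, datum::inf);
        mat d = log1p(y) - log1p(yp);
        dout = -sign(d) / ((1.0 + yp) * mm);
      }

      // ---- backward + Adam ----
      ++step;
      double c1 = 1.0 - std::pow(b1, (double)step);
      double c2 = 1.0 - std::pow(b2, (double)step);
      auto adam = [&](mat &theta, mat &mth, mat &vth, const mat &g) {
        mth = b1 * mth + (1.0 - b1) * g;
        vth = b2 * vth + (1.0 - b2) * square(g);
        theta -= lr * (mth / c1) / (sqrt(vth / c2) + adam_eps);
      };
      auto adamv = [&](vec &theta, vec &mth, vec &vth, const vec &g) {
        mth = b1 * mth + (1.0 - b1) * g;
        vth = b2 * vth + (1.0 - b2) * square(g);
        theta -= lr * (mth / c1) / (sqrt(vth / c2) + adam_eps);
      };

      mat dW_out = dout * acts[n_hidden].t() + l2 * net.W_out;
      vec db_out = sum(dout, 1);
      mat da = net.W_out.t() * dout;
      adam(net.W_out, mW[n_hidden], vW[n_hidden], dW_out);
      adamv(net.b_out, mb[n_hidden], vb[n_hidden], db_out);

      for (int l = (int)n_hidden - 1; l >= 0; --l) {
        Layer &L = net.layers[l];
        mat dh = da % masks[l];
        mat dz_post = dh % (zs[l] > 0);  // through ReLU
        mat dz;
        if (batchnorm) {
          vec dgamma = sum(dz_post % zhats[l], 1);
          vec dbeta = sum(dz_post, 1);
          mat dzhat = dz_post.each_col() % L.gamma;
          double mcols = (double)dz_post.n_cols;
          vec t1 = mean(dzhat, 1);
          vec t2 = mean(dzhat % zhats[l], 1);
          dz = dzhat;
          dz.each_col() -= t1;
          dz -= zhats[l].each_col() % t2;
          dz.each_col() /= sqrt(vars[l] + BN_EPS);
          (void)mcols;
          adamv(L.gamma, mg[l], vg[l], dgamma);
          adamv(L.beta, mbeta[l], vbeta[l], dbeta);
        } else {
          dz = dz_post;
        }
        mat dW = dz * acts[l].t() + l2 * L.W;
        vec db = sum(dz, 1);
        if (l > 0) da = L.W.t() * dz;
        adam(L.W, mW[l], vW[l], dW);
        adamv(L.b, mb[l], vb[l], db);
      }
    }

    // ---- epoch bookkeeping on the full training set, eval mode ----
    double ep_loss = data_loss(loss_kind, forward_eval(net, X), Y);
    trace.push_back(ep_loss);
    if (!std::isfinite(ep_loss)) { diverged = true; break; }
    // the early-stop counter only resets on a decrease of at least early_tol,
    // but any strict improvement updates the returned checkpoint
    if (ep_loss < best_loss - early_tol) since_improve = 0; else ++since_improve;
    if (ep_loss < best_loss) {
      best_loss = ep_loss;
      best_epoch = epoch + 1;
      best = net;
    }
    if (early_stop && since_improve >= early_patience) break;
  }

  Rcpp::List Ws(n_hidden + 1), bs(n_hidden + 1), gammas(n_hidden),
      betas(n_hidden), rmeans(n_hidden), rvars(n_hidden);
  for (uword l = 0; l < n_hidden; ++l) {
    Ws[l] = best.layers[l].W;
    bs[l] = best.layers[l].b;
    if (batchnorm) {
      gammas[l] = best.layers[l].gamma;
      betas[l] = best.layers[l].beta;
      rmeans[l] = best.layers[l].run_mean;
      rvars[l] = best.layers[l].run_var;
    }
  }
  Ws[n_hidden] = best.W_out;
  bs[n_hidden] = best.b_out;

  return Rcpp::List::create(
      Rcpp::Named("W") = Ws, Rcpp::Named("b") = bs,
      Rcpp::Named("gamma") = gammas, Rcpp::Named("beta") = betas,
      Rcpp::Named("run_mean") = rmeans, Rcpp::Named("run_var") = rvars,
      Rcpp::Named("batchnorm") = batchnorm,
      Rcpp::Named("trace") = trace,
      Rcpp::Named("best_loss") = best_loss,
      Rcpp::Named("best_epoch") = best_epoch,
      Rcpp::Named("epochs_run") = epochs_run,
      Rcpp::Named("diverged") = diverged);
}

// [[Rcpp::export]]
arma::mat nn_predict_cpp(const Rcpp::List &params, const arma::mat &X_in) {
  Rcpp::List Ws = params["W"], bs = params["b"];
  bool batchnorm = Rcpp::as<bool>(params["batchnorm"]);
  uword n_hidden = (uword)Ws.size() - 1;
  Net net;
  net.batchnorm = batchnorm;
  Rcpp::List gammas, betas, rmeans, rvars;
  if (batchnorm) {
    gammas = Rcpp::List(params["gamma"]); betas = Rcpp::List(params["beta"]);
    rmeans = Rcpp::List(params["run_mean"]); rvars = Rcpp::List(params["run_var"]);
  }
  for (uword l = 0; l < n_hidden; ++l) {
    Layer L;
    L.W = Rcpp::as<mat>(Ws[l]);
    L.b = Rcpp::as<vec>(bs[l]);
    if (batchnorm) {
      L.gamma = Rcpp::as<vec>(gammas[l]); L.beta = Rcpp::as<vec>(betas[l]);
      L.run_mean = Rcpp::as<vec>(rmeans[l]); L.run_var = Rcpp::as<vec>(rvars[l]);
    }
    net.layers.push_back(L);
  }
  net.W_out = Rcpp::as<mat>(Ws[n_hidden]);
  net.b_out = Rcpp::as<vec>(bs[n_hidden]);
  return forward_eval(net, X_in.t()).t();  // n x C
}
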