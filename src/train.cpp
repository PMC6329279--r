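#include <Rcpp.h>
#include <cmath>
#include <vector>
using namespace Rcpp;

// Biased matrix factorization trained on individual (sample, gene, value)
// cells: pred = dot(G_a, S_i) + b_a + b_i, loss = batch mean squared error.
// Adam keeps one global step counter; only rows touched by a batch are
// updated (lazy sparse Adam). All parameter updates are applied after the
// whole batch gradient is accumulated, so gene and sample roles are exactly
// exchangeable under transposition of the input.

static inline double predict_one(const NumericMatrix &G, const NumericMatrix &S,
                                 const NumericVector &bg, const NumericVector &bs,
                                 int a, int i, int m) {
  double d = bg[a] + bs[i];
  for (int t = 0; t < m; ++t) d += G(a, t) * S(i, t);
  return d;
}

// [[Rcpp::export]]
List cf_train(NumericMatrix G0, NumericMatrix S0,
              NumericVector bg0, NumericVector bs0,
              IntegerVector cell_sample, IntegerVector cell_gene,
              NumericVector cell_value,
              IntegerVector val_sample, IntegerVector val_gene,
              NumericVector val_value,
              List epoch_orders, int batch_size,
              double lr, double beta1, double beta2, double eps,
              double weight_decay) {
  NumericMatrix G = clone(G0), S = clone(S0);
  NumericVector bg = clone(bg0), bs = clone(bs0);
  const int k = G.nrow(), n = S.nrow(), m = G.ncol();
  const int N = cell_value.size();
  const int n_epochs = epoch_orders.size();

  // Adam state
  NumericMatrix mG(k, m), vG(k, m), mS(n, m), vS(n, m);
  NumericVector mbg(k), vbg(k), mbs(n), vbs(n);

  // dense gradient accumulators, zeroed sparsely per batch
  NumericMatrix gG(k, m), gS(n, m);
  NumericVector gbg(k), gbs(n);
  std::vector<int> touched_g, touched_s;
  std::vector<char> seen_g(k, 0), seen_s(n, 0);
  std::vector<double> err(batch_size);

  NumericVector train_mse(n_epochs), val_mse(n_epochs);
  long step = 0;

  for (int ep = 0; ep < n_epochs; ++ep) {
    IntegerVector ord = epoch_orders[ep];
    if (ord.size() != N) stop("epoch order length must equal cell count");
    double ep_sse = 0.0;
    int pos = 0;
    while (pos < N) {
      int B = std::min(batch_size, N - pos);
      touched_g.clear();
      touched_s.clear();
      // forward pass with current parameters
      double batch_sse = 0.0;
      for (int j = 0; j < B; ++j) {
        int c = ord[pos + j];
        int a = cell_gene[c], i = cell_sample[c];
        double e = predict_one(G, S, bg, bs, a, i, m) - cell_value[c];
        err[j] = e;
        batch_sse += e * e;
      }
      if (!std::isfinite(batch_sse)) {
        stop("training loss became non-finite; lower the learning rate");
      }
      ep_sse += batch_sse;
      // accumulate gradient of batch MSE
      for (int j = 0; j < B; ++j) {
        int c = ord[pos + j];
        int a = cell_gene[c], i = cell_sample[c];
        double coef = 2.0 * err[j] / B;
        if (!seen_g[a]) { seen_g[a] = 1; touched_g.push_back(a); }
        if (!seen_s[i]) { seen_s[i] = 1; touched_s.push_back(i); }
        for (int t = 0; t < m; ++t) {
          gG(a, t) += coef * S(i, t);
          gS(i, t) += coef * G(a, t);
        }
        gbg[a] += coef;
        gbs[i] += coef;
      }
      // Adam update on touched rows
      ++step;
      double bc1 = 1.0 - std::pow(beta1, (double) step);
      double bc2 = 1.0 - std::pow(beta2, (double) step);
      for (int a : touched_g) {
        for (int t = 0; t < m; ++t) {
          double g = gG(a, t) + weight_decay * G(a, t);
          mG(a, t) = beta1 * mG(a, t) + (1.0 - beta1) * g;
          vG(a, t) = beta2 * vG(a, t) + (1.0 - beta2) * g * g;
          G(a, t) -= lr * (mG(a, t) / bc1) / (std::sqrt(vG(a, t) / bc2) + eps);
          gG(a, t) = 0.0;
        }
        double g = gbg[a] + weight_decay * bg[a];
        mbg[a] = beta1 * mbg[a] + (1.0 - beta1) * g;
        vbg[a] = beta2 * vbg[a] + (1.0 - beta2) * g * g;
        bg[a] -= lr * (mbg[a] / bc1) / (std::sqrt(vbg[a] / bc2) + eps);
        gbg[a] = 0.0;
        seen_g[a] = 0;
      }
      for (int i : touched_s) {
        for (int t = 0; t < m; ++t) {
          double g = gS(i, t) + weight_decay * S(i, t);
          mS(i, t) = beta1 * mS(i, t) + (1.0 - beta1) * g;
          vS(i, t) = beta2 * vS(i, t) + (1.0 - beta2) * g * g;
          S(i, t) -= lr * (mS(i, t) / bc1) / (std::sqrt(vS(i, t) / bc2) + eps);
          gS(i, t) = 0.0;
        }
        double g = gbs[i] + weight_decay * bs[i];
        mbs[i] = beta1 * mbs[i] + (1.0 - beta1) * g;
        vbs[i] = beta2 * vbs[i] + (1.0 - beta2) * g * g;
        bs[i] -= lr * (mbs[i] / bc1) / (std::sqrt(vbs[i] / bc2) + eps);
        gbs[i] = 0.0;
        seen_s[i] = 0;
      }
      pos += B;
    }
    train_mse[ep] = ep_sse / N;
    // held-out cells scored with end-of-epoch parameters
    int Nv = val_value.size();
    if (Nv > 0) {
      double sse = 0.0;
      for (int c = 0; c < Nv; ++c) {
        double e = predict_one(G, S, bg, bs, val_gene[c], val_sample[c], m)
          - val_value[c];
        sse += e * e;
      }
      val_mse[ep] = sse / Nv;
    } else {
      val_mse[ep] = NA_REAL;
    }
    Rcpp::checkUserInterrupt();
  }

  return List::create(_["G"] = G, _["S"] = S, _["b_gene"] = bg,
                      _["b_sample"] = bs, _["train_mse"] = train_mse,
                      _["val_mse"] = val_mse, _["steps"] = (double) step);
}

// Gradient of the mean squared error of one mini-batch with respect to all
// parameters, returned dense. Shared contract with the training loop above;
// used directly by the learning-rate finder and by finite-difference checks.
// [[Rcpp::export]]
List cf_batch_gradient(NumericMatrix G, NumericMatrix S,
                       NumericVector bg, NumericVector bs,
                       IntegerVector cell_sample, IntegerVector cell_gene,
                       NumericVector cell_value, double weight_decay) {
  const int k = G.nrow(), n = S.nrow(), m = G.ncol();
  const int B = cell_value.size();
  NumericMatrix gG(k, m), gS(n, m);
  NumericVector gbg(k), gbs(n);
  double sse = 0.0;
  for (int j = 0; j < B; ++j) {
    int a = cell_gene[j], i = cell_sample[j];
    double e = predict_one(G, S, bg, bs, a, i, m) - cell_value[j];
    sse += e * e;
    double coef = 2.0 * e / B;
    for (int t = 0; t < m; ++t) {
      gG(a, t) += coef * S(i, t);
      gS(i, t) += coef * G(a, t);
    }
    gbg[a] += coef;
    gbs[i] += coef;
  }
  if (weight_decay != 0.0) {
    for (int a = 0; a < k; ++a) {
      for (int t = 0; t < m; ++t) gG(a, t) += weight_decay * G(a, t);
      gbg[a] += weight_decay * bg[a];
    }
    for (int i = 0; i < n; ++i) {
      for (int t = 0; t < m; ++t) gS(i, t) += weight_decay * S(i, t);
      gbs[i] += weight_decay * bs[i];
    }
  }
  return List::create(_["gG"] = gG, _["gS"] = gS, _["gbg"] = gbg,
                      _["gbs"] = gbs, _["mse"] = sse / B);
}

// [[Rcpp::export]]
double cf_cells_mse(NumericMatrix G, NumericMatrix S,
                    NumericVector bg, NumericVector bs,
                    IntegerVector cell_sample, IntegerVector cell_gene,
                    NumericVector cell_value) {
  const int m = G.ncol();
  const int N = cell_value.size();
  if (N == 0) return NA_REAL;
  double sse = 0.0;
  for (int c = 0; c < N; ++c) {
    double e = predict_one(G, S, bg, bs, cell_gene[c], cell_sample[c], m)
      - cell_value[c];
    sse += e * e;
  }
  return sse / N;
}
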