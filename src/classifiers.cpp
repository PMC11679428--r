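// Deterministic classifier kernels for the SFS / nested-CV harness.
// All randomized fits (RF bootstrap, MLP init and shuffling) consume an
// explicit integer seed through a private mt19937 stream so that repeated
// runs are bit-identical; vote and argmax ties resolve to the lowest index.

#include <RcppArmadillo.h>
#include <random>
#include <algorithm>
// [[Rcpp::depends(RcppArmadillo)]]
using namespace Rcpp;

static inline double clampd(double x, double lo, double hi) {
  return x < lo ? lo : (x > hi ? hi : x);
}

// ---------------------------------------------------------------------------
// Penalized logistic regression: mean log-loss + lambda * P(beta),
// intercept unpenalized. L2 by damped Newton (IRLS), L1 by FISTA.
// ---------------------------------------------------------------------------

static double lr_objective(const arma::mat& Xa, const arma::vec& y,
                           const arma::vec& beta, double lambda, bool l1) {
  arma::vec eta = Xa * beta;
  // numerically stable log(1 + exp(-s*eta)) with s = 2y-1
  arma::vec s = 2.0 * y - 1.0;
  arma::vec m = -(s % eta);
  double loss = 0.0;
  for (arma::uword i = 0; i < m.n_elem; ++i)
    loss += (m(i) > 0) ? m(i) + std::log1p(std::exp(-m(i)))
                       : std::log1p(std::exp(m(i)));
  loss /= Xa.n_rows;
  arma::vec b = beta.subvec(1, beta.n_elem - 1);
  return loss + (l1 ? lambda * arma::accu(arma::abs(b))
                    : 0.5 * lambda * arma::dot(b, b));
}

// [[Rcpp::export]]
arma::vec cpp_lr_fit(const arma::mat& X, const arma::vec& y,
                     double lambda, bool l1) {
  arma::uword n = X.n_rows, p = X.n_cols;
  arma::mat Xa(n, p + 1);
  Xa.col(0).ones();
  if (p > 0) Xa.cols(1, p) = X;
  arma::vec beta(p + 1, arma::fill::zeros);
  arma::vec pen(p + 1, arma::fill::value(lambda));
  pen(0) = 0.0;

  if (!l1) {
    double obj = lr_objective(Xa, y, beta, lambda, false);
    for (int it = 0; it < 50; ++it) {
      arma::vec mu = 1.0 / (1.0 + arma::exp(-(Xa * beta)));
      arma::vec w = mu % (1.0 - mu) + 1e-10;
      arma::vec grad = Xa.t() * (mu - y) / n + pen % beta;
      if (arma::norm(grad, "inf") < 1e-9) break;
      arma::mat H = Xa.t() * (Xa.each_col() % w) / n;
      H.diag() += pen;
      H.diag() += 1e-12;
      arma::vec step = arma::solve(H, grad, arma::solve_opts::fast);
      double t = 1.0;
      arma::vec cand;
      double cobj = 0.0;
      int half = 0;
      for (; half < 30; ++half) {
        cand = beta - t * step;
        cobj = lr_objective(Xa, y, cand, lambda, false);
        if (cobj <= obj + 1e-14) break;
        t *= 0.5;
      }
      if (half == 30) break;
      double delta = obj - cobj;
      beta = cand;
      obj = cobj;
      if (delta < 1e-12 && arma::norm(t * step, "inf") < 1e-9) break;
    }
    return beta;
  }

  // FISTA for L1: Lipschitz bound from the largest eigenvalue of Xa'Xa / (4n)
  arma::vec v(p + 1, arma::fill::ones);
  v /= arma::norm(v);
  double lam_max = 1.0;
  for (int it = 0; it < 25; ++it) {
    arma::vec u = Xa.t() * (Xa * v);
    lam_max = arma::norm(u);
    if (lam_max < 1e-30) break;
    v = u / lam_max;
  }
  double L = 0.25 * lam_max / n + 1e-8;
  arma::vec z = beta, beta_old = beta;
  double tk = 1.0;
  for (int it = 0; it < 2000; ++it) {
    arma::vec mu = 1.0 / (1.0 + arma::exp(-(Xa * z)));
    arma::vec grad = Xa.t() * (mu - y) / n;
    arma::vec w = z - grad / L;
    // soft-threshold all but the intercept
    for (arma::uword j = 1; j < w.n_elem; ++j) {
      double a = w(j), s = lambda / L;
      w(j) = (a > s) ? a - s : ((a < -s) ? a + s : 0.0);
    }
    double tk1 = 0.5 * (1.0 + std::sqrt(1.0 + 4.0 * tk * tk));
    z = w + ((tk - 1.0) / tk1) * (w - beta);
    double ch = arma::norm(w - beta, "inf");
    beta = w;
    tk = tk1;
    if (ch < 1e-8) break;
  }
  return beta;
}

// [[Rcpp::export]]
arma::vec cpp_lr_decision(const arma::vec& beta, const arma::mat& X) {
  arma::vec eta(X.n_rows, arma::fill::value(beta(0)));
  if (X.n_cols > 0) eta += X * beta.subvec(1, beta.n_elem - 1);
  return eta;
}

// ---------------------------------------------------------------------------
// C-SVM with hinge loss by dual coordinate descent (cyclic order, hence
// deterministic). Linear kernel uses an augmented all-ones feature as the
// bias; the RBF kernel uses K + 1 which absorbs the bias into the
// regularized part of the model.
// ---------------------------------------------------------------------------

static arma::mat pairwise_sqdist(const arma::mat& A, const arma::mat& B) {
  arma::vec a2 = arma::sum(arma::square(A), 1);
  arma::vec b2 = arma::sum(arma::square(B), 1);
  arma::mat D = -2.0 * (A * B.t());
  D.each_col() += a2;
  D.each_row() += b2.t();
  D.transform([](double v) { return v < 0 ? 0.0 : v; });
  return D;
}

// [[Rcpp::export]]
List cpp_svm_fit(const arma::mat& X, const arma::vec& y01, double C,
                 std::string kernel, double gamma,
                 double tol = 1e-3, int max_epochs = 400) {
  arma::uword n = X.n_rows;
  arma::vec y = 2.0 * y01 - 1.0;

  if (kernel == "linear") {
    arma::uword p = X.n_cols;
    arma::mat Xa(n, p + 1);
    if (p > 0) Xa.cols(0, p - 1) = X;
    Xa.col(p).ones();
    arma::vec alpha(n, arma::fill::zeros);
    arma::vec w(p + 1, arma::fill::zeros);
    arma::vec Qii = arma::sum(arma::square(Xa), 1);
    for (int ep = 0; ep < max_epochs; ++ep) {
      double max_pg = 0.0;
      for (arma::uword i = 0; i < n; ++i) {
        double G = y(i) * arma::dot(w, Xa.row(i)) - 1.0;
        double pg = G;
        if (alpha(i) <= 0.0 && G >= 0.0) pg = 0.0;
        if (alpha(i) >= C && G <= 0.0) pg = 0.0;
        if (std::fabs(pg) > max_pg) max_pg = std::fabs(pg);
        if (std::fabs(pg) > 1e-12) {
          double anew = clampd(alpha(i) - G / Qii(i), 0.0, C);
          double d = anew - alpha(i);
          if (d != 0.0) {
            w += (d * y(i)) * Xa.row(i).t();
            alpha(i) = anew;
          }
        }
      }
      if (max_pg < tol) break;
    }
    return List::create(_["kernel"] = "linear", _["w"] = w);
  }

  // RBF
  arma::mat K = arma::exp(-gamma * pairwise_sqdist(X, X)) + 1.0;
  arma::vec alpha(n, arma::fill::zeros);
  arma::vec G(n, arma::fill::value(-1.0));
  for (int ep = 0; ep < max_epochs; ++ep) {
    double max_pg = 0.0;
    for (arma::uword i = 0; i < n; ++i) {
      double pg = G(i);
      if (alpha(i) <= 0.0 && G(i) >= 0.0) pg = 0.0;
      if (alpha(i) >= C && G(i) <= 0.0) pg = 0.0;
      if (std::fabs(pg) > max_pg) max_pg = std::fabs(pg);
      if (std::fabs(pg) > 1e-12) {
        double anew = clampd(alpha(i) - G(i) / K(i, i), 0.0, C);
        double d = anew - alpha(i);
        if (d != 0.0) {
          G += (d * y(i)) * (y % K.col(i));
          alpha(i) = anew;
        }
      }
    }
    if (max_pg < tol) break;
  }
  arma::uvec sv = arma::find(alpha > 1e-12);
  arma::vec coef = alpha(sv) % y(sv);
  arma::mat svX = X.rows(sv);
  return List::create(_["kernel"] = "rbf", _["coef"] = coef,
                      _["sv"] = svX, _["gamma"] = gamma);
}

// [[Rcpp::export]]
arma::vec cpp_svm_decision(List model, const arma::mat& Xnew) {
  std::string kernel = as<std::string>(model["kernel"]);
  if (kernel == "linear") {
    arma::vec w = as<arma::vec>(model["w"]);
    arma::uword p = w.n_elem - 1;
    arma::vec f(Xnew.n_rows, arma::fill::value(w(p)));
    if (p > 0) f += Xnew * w.subvec(0, p - 1);
    return f;
  }
  arma::vec coef = as<arma::vec>(model["coef"]);
  arma::mat sv = as<arma::mat>(model["sv"]);
  double gamma = as<double>(model["gamma"]);
  if (coef.n_elem == 0) return arma::vec(Xnew.n_rows, arma::fill::zeros);
  arma::mat Kt = arma::exp(-gamma * pairwise_sqdist(Xnew, sv)) + 1.0;
  return Kt * coef;
}

// ---------------------------------------------------------------------------
// K-nearest neighbours, Euclidean metric. Distance ties resolve to the
// lowest training-row index; an even vote split predicts class 0.
// ---------------------------------------------------------------------------

static int knn_vote(const double* d2, const int* ytr, int n, int k) {
  std::vector<int> idx(n);
  for (int i = 0; i < n; ++i) idx[i] = i;
  int kk = std::min(k, n);
  std::partial_sort(idx.begin(), idx.begin() + kk, idx.end(),
                    [&](int a, int b) {
                      if (d2[a] != d2[b]) return d2[a] < d2[b];
                      return a < b;
                    });
  int ones = 0;
  for (int j = 0; j < kk; ++j) ones += ytr[idx[j]];
  return (2 * ones > kk) ? 1 : 0;
}

// [[Rcpp::export]]
IntegerVector cpp_knn_predict(const arma::mat& Xtr, const IntegerVector& ytr,
                              const arma::mat& Xte, int k) {
  arma::mat D = pairwise_sqdist(Xte, Xtr);
  int n = Xtr.n_rows, m = Xte.n_rows;
  std::vector<int> yv(ytr.begin(), ytr.end());
  IntegerVector out(m);
  std::vector<double> row(n);
  for (int i = 0; i < m; ++i) {
    for (int j = 0; j < n; ++j) row[j] = D(i, j);
    out[i] = knn_vote(row.data(), yv.data(), n, k);
  }
  return out;
}

// ---------------------------------------------------------------------------
// Random forest: bagged CART trees with per-node feature subsampling
// (mtry = floor(sqrt(p))), gini or entropy split quality, depth cap.
// ---------------------------------------------------------------------------

struct TreeBuf {
  std::vector<int> feat, left, right, pred;
  std::vector<double> thr;
  int add() {
    feat.push_back(-1); thr.push_back(0.0);
    left.push_back(-1); right.push_back(-1); pred.push_back(0);
    return (int)feat.size() - 1;
  }
};

static double node_impurity(int n0, int n1, bool entropy) {
  double n = n0 + n1;
  if (n <= 0) return 0.0;
  double p0 = n0 / n, p1 = n1 / n;
  if (!entropy) return 1.0 - p0 * p0 - p1 * p1;
  double h = 0.0;
  if (p0 > 0) h -= p0 * std::log2(p0);
  if (p1 > 0) h -= p1 * std::log2(p1);
  return h;
}

static void rf_build(TreeBuf& T, int node, std::vector<int>& idx,
                     const arma::mat& X, const std::vector<int>& y,
                     int depth, int max_depth, bool entropy, int mtry,
                     std::mt19937& g) {
  int n = (int)idx.size(), n1 = 0;
  for (int i : idx) n1 += y[i];
  int n0 = n - n1;
  T.pred[node] = (n1 > n0) ? 1 : 0;
  if (n0 == 0 || n1 == 0 || depth >= max_depth || n < 2) return;

  int p = X.n_cols;
  std::vector<int> feats(p);
  for (int j = 0; j < p; ++j) feats[j] = j;
  for (int j = 0; j < mtry; ++j) {  // partial Fisher-Yates
    int r = j + (int)(g() % (uint32_t)(p - j));
    std::swap(feats[j], feats[r]);
  }

  double parent = node_impurity(n0, n1, entropy);
  double best_gain = 1e-12;
  int best_f = -1;
  double best_thr = 0.0;
  std::vector<std::pair<double, int>> vals(n);
  for (int jj = 0; jj < mtry; ++jj) {
    int f = feats[jj];
    for (int i = 0; i < n; ++i) vals[i] = {X(idx[i], f), y[idx[i]]};
    std::sort(vals.begin(), vals.end(),
              [](const std::pair<double, int>& a,
                 const std::pair<double, int>& b) { return a.first < b.first; });
    int l0 = 0, l1 = 0;
    for (int i = 0; i < n - 1; ++i) {
      if (vals[i].second) ++l1; else ++l0;
      if (vals[i].first == vals[i + 1].first) continue;
      double wl = (double)(i + 1) / n, wr = 1.0 - wl;
      double gain = parent - wl * node_impurity(l0, l1, entropy)
                           - wr * node_impurity(n0 - l0, n1 - l1, entropy);
      if (gain > best_gain) {
        best_gain = gain;
        best_f = f;
        best_thr = 0.5 * (vals[i].first + vals[i + 1].first);
      }
    }
  }
  if (best_f < 0) return;

  std::vector<int> li, ri;
  for (int i : idx)
    if (X(i, best_f) <= best_thr) li.push_back(i); else ri.push_back(i);
  if (li.empty() || ri.empty()) return;
  T.feat[node] = best_f;
  T.thr[node] = best_thr;
  int L = T.add(), R = T.add();
  T.left[node] = L;
  T.right[node] = R;
  rf_build(T, L, li, X, y, depth + 1, max_depth, entropy, mtry, g);
  rf_build(T, R, ri, X, y, depth + 1, max_depth, entropy, mtry, g);
}

// [[Rcpp::export]]
List cpp_rf_fit(const arma::mat& X, const IntegerVector& y, int n_trees,
                int max_depth, std::string criterion, int seed) {
  int n = X.n_rows, p = X.n_cols;
  bool entropy = (criterion == "entropy");
  int mtry = std::max(1, (int)std::floor(std::sqrt((double)p)));
  std::mt19937 g((uint32_t)seed);
  std::vector<int> yv(y.begin(), y.end());
  List trees(n_trees);
  for (int t = 0; t < n_trees; ++t) {
    std::vector<int> idx(n);
    for (int i = 0; i < n; ++i) idx[i] = (int)(g() % (uint32_t)n);
    TreeBuf T;
    int root = T.add();
    rf_build(T, root, idx, X, yv, 0, max_depth, entropy, mtry, g);
    int m = (int)T.feat.size();
    arma::mat M(m, 5);
    for (int i = 0; i < m; ++i) {
      M(i, 0) = T.feat[i]; M(i, 1) = T.thr[i];
      M(i, 2) = T.left[i]; M(i, 3) = T.right[i]; M(i, 4) = T.pred[i];
    }
    trees[t] = M;
  }
  return List::create(_["trees"] = trees);
}

// [[Rcpp::export]]
IntegerVector cpp_rf_predict(List model, const arma::mat& Xnew) {
  List trees = model["trees"];
  int m = Xnew.n_rows, nt = trees.size();
  IntegerVector out(m);
  std::vector<arma::mat> tm(nt);
  for (int t = 0; t < nt; ++t) tm[t] = as<arma::mat>(trees[t]);
  for (int i = 0; i < m; ++i) {
    int ones = 0;
    for (int t = 0; t < nt; ++t) {
      const arma::mat& M = tm[t];
      int node = 0;
      while (M(node, 0) >= 0) {
        int f = (int)M(node, 0);
        node = (Xnew(i, f) <= M(node, 1)) ? (int)M(node, 2) : (int)M(node, 3);
      }
      ones += (int)M(node, 4);
    }
    out[i] = (2 * ones > nt) ? 1 : 0;
  }
  return out;
}

// ---------------------------------------------------------------------------
// Multilayer perceptron: one hidden layer of rectified-linear units, sigmoid
// output, cross-entropy loss, Adam updates on shuffled mini-batches, early
// stopping on a held-out validation slice of the training rows.
// ---------------------------------------------------------------------------

static double mlp_gauss(std::mt19937& g) {  // Box-Muller, implementation-stable
  double u1 = (g() + 0.5) / 4294967296.0;
  double u2 = (g() + 0.5) / 4294967296.0;
  return std::sqrt(-2.0 * std::log(u1)) * std::cos(6.283185307179586 * u2);
}

static double mlp_loss(const arma::mat& W1, const arma::vec& b1,
                       const arma::vec& w2, double b2,
                       const arma::mat& X, const arma::vec& y) {
  arma::mat H = X * W1.t();
  H.each_row() += b1.t();
  H.transform([](double v) { return v > 0 ? v : 0.0; });
  arma::vec f = H * w2 + b2;
  double loss = 0.0;
  for (arma::uword i = 0; i < f.n_elem; ++i) {
    double m = (2.0 * y(i) - 1.0) * f(i);
    loss += (m > 0) ? std::log1p(std::exp(-m)) : -m + std::log1p(std::exp(m));
  }
  return loss / f.n_elem;
}

// [[Rcpp::export]]
List cpp_mlp_fit(const arma::mat& X, const arma::vec& y, int hidden,
                 int batch, double lr, int max_epochs, int patience,
                 double val_frac, int seed) {
  int n = X.n_rows, p = X.n_cols;
  std::mt19937 g((uint32_t)seed);
  arma::mat W1(hidden, p);
  arma::vec b1(hidden, arma::fill::zeros), w2(hidden);
  double b2 = 0.0;
  double s1 = std::sqrt(2.0 / std::max(1, p)), s2 = std::sqrt(2.0 / hidden);
  for (int i = 0; i < hidden; ++i)
    for (int j = 0; j < p; ++j) W1(i, j) = s1 * mlp_gauss(g);
  for (int i = 0; i < hidden; ++i) w2(i) = s2 * mlp_gauss(g);

  std::vector<int> perm(n);
  for (int i = 0; i < n; ++i) perm[i] = i;
  for (int i = 0; i < n - 1; ++i) {
    int r = i + (int)(g() % (uint32_t)(n - i));
    std::swap(perm[i], perm[r]);
  }
  int nval = (int)std::floor(val_frac * n);
  arma::uvec vidx(nval > 0 ? nval : 0), tidx(n - (nval > 0 ? nval : 0));
  for (int i = 0; i < nval; ++i) vidx(i) = perm[i];
  for (int i = nval; i < n; ++i) tidx(i - nval) = perm[i];
  bool use_val = nval >= 2;
  arma::mat Xtr = X.rows(tidx), Xva;
  arma::vec ytr = y(tidx), yva;
  if (use_val) { Xva = X.rows(vidx); yva = y(vidx); }
  if (arma::accu(ytr) == 0 || arma::accu(ytr) == ytr.n_elem) {
    Xtr = X; ytr = y; use_val = false;  // degenerate split: train on all rows
  }
  int ntr = Xtr.n_rows;

  // Adam state
  arma::mat mW1(arma::size(W1), arma::fill::zeros), vW1(arma::size(W1), arma::fill::zeros);
  arma::vec mb1(hidden, arma::fill::zeros), vb1(hidden, arma::fill::zeros);
  arma::vec mw2(hidden, arma::fill::zeros), vw2(hidden, arma::fill::zeros);
  double mb2 = 0.0, vb2 = 0.0;
  const double be1 = 0.9, be2 = 0.999, eps = 1e-8;
  long tstep = 0;

  arma::mat bW1 = W1; arma::vec bb1 = b1, bw2 = w2; double bb2 = b2;
  double best_val = std::numeric_limits<double>::infinity();
  int since_best = 0;
  std::vector<double> train_loss_hist;
  std::vector<int> ord(ntr);
  for (int i = 0; i < ntr; ++i) ord[i] = i;

  for (int ep = 0; ep < max_epochs; ++ep) {
    for (int i = 0; i < ntr - 1; ++i) {
      int r = i + (int)(g() % (uint32_t)(ntr - i));
      std::swap(ord[i], ord[r]);
    }
    for (int start = 0; start < ntr; start += batch) {
      int B = std::min(batch, ntr - start);
      arma::uvec bi(B);
      for (int i = 0; i < B; ++i) bi(i) = ord[start + i];
      arma::mat Xb = Xtr.rows(bi);
      arma::vec yb = ytr(bi);
      arma::mat Z = Xb * W1.t();
      Z.each_row() += b1.t();
      arma::mat H = Z;
      H.transform([](double v) { return v > 0 ? v : 0.0; });
      arma::vec f = H * w2 + b2;
      arma::vec pr = 1.0 / (1.0 + arma::exp(-f));
      arma::vec df = (pr - yb) / B;
      arma::vec gw2 = H.t() * df;
      double gb2 = arma::accu(df);
      arma::mat dH = df * w2.t();                  // B x hidden
      dH %= arma::conv_to<arma::mat>::from(Z > 0); // ReLU gate
      arma::mat gW1 = dH.t() * Xb;
      arma::vec gb1 = arma::sum(dH, 0).t();

      ++tstep;
      double c1 = 1.0 - std::pow(be1, (double)tstep);
      double c2 = 1.0 - std::pow(be2, (double)tstep);
      mW1 = be1 * mW1 + (1 - be1) * gW1; vW1 = be2 * vW1 + (1 - be2) * arma::square(gW1);
      W1 -= lr * (mW1 / c1) / (arma::sqrt(vW1 / c2) + eps);
      mb1 = be1 * mb1 + (1 - be1) * gb1; vb1 = be2 * vb1 + (1 - be2) * arma::square(gb1);
      b1 -= lr * (mb1 / c1) / (arma::sqrt(vb1 / c2) + eps);
      mw2 = be1 * mw2 + (1 - be1) * gw2; vw2 = be2 * vw2 + (1 - be2) * arma::square(gw2);
      w2 -= lr * (mw2 / c1) / (arma::sqrt(vw2 / c2) + eps);
      mb2 = be1 * mb2 + (1 - be1) * gb2; vb2 = be2 * vb2 + (1 - be2) * gb2 * gb2;
      b2 -= lr * (mb2 / c1) / (std::sqrt(vb2 / c2) + eps);
    }
    train_loss_hist.push_back(mlp_loss(W1, b1, w2, b2, Xtr, ytr));
    if (use_val) {
      double vl = mlp_loss(W1, b1, w2, b2, Xva, yva);
      if (vl < best_val - 1e-9) {
        best_val = vl;
        bW1 = W1; bb1 = b1; bw2 = w2; bb2 = b2;
        since_best = 0;
      } else if (++since_best >= patience) break;
    }
  }
  if (!use_val) { bW1 = W1; bb1 = b1; bw2 = w2; bb2 = b2; }
  return List::create(_["W1"] = bW1, _["b1"] = bb1, _["w2"] = bw2,
                      _["b2"] = bb2, _["train_loss"] = train_loss_hist);
}

// [[Rcpp::export]]
arma::vec cpp_mlp_predict_prob(List model, const arma::mat& X) {
  arma::mat W1 = as<arma::mat>(model["W1"]);
  arma::vec b1 = as<arma::vec>(model["b1"]);
  arma::vec w2 = as<arma::vec>(model["w2"]);
  double b2 = as<double>(model["b2"]);
  arma::mat H = X * W1.t();
  H.each_row() += b1.t();
  H.transform([](double v) { return v > 0 ? v : 0.0; });
  arma::vec f = H * w2 + b2;
  return 1.0 / (1.0 + arma::exp(-f));
}

// ---------------------------------------------------------------------------
// SFS candidate sweep: mean inner-CV accuracy for every candidate feature
// appended to the current selected set, for the fast classifier kernels.
// folds: list of list(Xtr, ytr, Xva, yva) with 0/1 integer labels.
// sel / cand are 0-based column indices into the fold matrices.
// ---------------------------------------------------------------------------

// [[Rcpp::export]]
arma::vec cpp_sfs_sweep(List folds, const arma::uvec& sel,
                        const arma::uvec& cand, std::string clf, List params) {
  int nf = folds.size(), nc = cand.n_elem;
  arma::vec acc(nc, arma::fill::zeros);
  if (nc == 0) return acc;

  if (clf == "knn") {
    int k = as<int>(params["k"]);
    for (int fi = 0; fi < nf; ++fi) {
      List fold = folds[fi];
      arma::mat Xtr = as<arma::mat>(fold["Xtr"]);
      arma::mat Xva = as<arma::mat>(fold["Xva"]);
      IntegerVector ytr = fold["ytr"], yva = fold["yva"];
      std::vector<int> ytrv(ytr.begin(), ytr.end());
      arma::mat base;  // nva x ntr squared distance on the selected set
      if (sel.n_elem > 0)
        base = pairwise_sqdist(Xva.cols(sel), Xtr.cols(sel));
      else
        base = arma::mat(Xva.n_rows, Xtr.n_rows, arma::fill::zeros);
      int ntr = Xtr.n_rows, nva = Xva.n_rows;
      std::vector<double> row(ntr);
      for (int c = 0; c < nc; ++c) {
        arma::vec tj = Xtr.col(cand(c)), vj = Xva.col(cand(c));
        int good = 0;
        for (int i = 0; i < nva; ++i) {
          for (int j = 0; j < ntr; ++j) {
            double d = vj(i) - tj(j);
            row[j] = base(i, j) + d * d;
          }
          if (knn_vote(row.data(), ytrv.data(), ntr, k) == yva[i]) ++good;
        }
        acc(c) += (double)good / nva;
      }
    }
    return acc / nf;
  }

  bool is_lr = (clf == "lr");
  double lambda = 0.0, C = 1.0, gamma = 0.0;
  bool l1 = false;
  std::string kernel = "linear";
  if (is_lr) {
    lambda = as<double>(params["strength"]);
    l1 = (as<std::string>(params["penalty"]) == "l1");
  } else if (clf == "svm") {
    C = as<double>(params["C"]);
    kernel = as<std::string>(params["kernel"]);
    if (kernel == "rbf") gamma = as<double>(params["gamma"]);
  } else {
    stop("cpp_sfs_sweep: unsupported classifier '%s'", clf.c_str());
  }

  for (int fi = 0; fi < nf; ++fi) {
    List fold = folds[fi];
    arma::mat Xtr = as<arma::mat>(fold["Xtr"]);
    arma::mat Xva = as<arma::mat>(fold["Xva"]);
    arma::vec ytr = as<arma::vec>(fold["ytr"]);
    IntegerVector yva = fold["yva"];
    int nva = Xva.n_rows;
    arma::uword s = sel.n_elem;
    arma::mat Xtr_s(Xtr.n_rows, s + 1), Xva_s(Xva.n_rows, s + 1);
    if (s > 0) {
      Xtr_s.cols(0, s - 1) = Xtr.cols(sel);
      Xva_s.cols(0, s - 1) = Xva.cols(sel);
    }
    for (int c = 0; c < nc; ++c) {
      Xtr_s.col(s) = Xtr.col(cand(c));
      Xva_s.col(s) = Xva.col(cand(c));
      arma::vec dec;
      if (is_lr) {
        arma::vec beta = cpp_lr_fit(Xtr_s, ytr, lambda, l1);
        dec = cpp_lr_decision(beta, Xva_s);
      } else {
        List m = cpp_svm_fit(Xtr_s, ytr, C, kernel, gamma);
        dec = cpp_svm_decision(m, Xva_s);
      }
      int good = 0;
      for (int i = 0; i < nva; ++i)
        if ((dec(i) > 0) == (yva[i] == 1)) ++good;
      acc(c) += (double)good / nva;
    }
  }
  return acc / nf;
}
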