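// Multi-restart full-batch Adam on the max-aggregated MIL logistic loss.
//
// X is the row-bound motif feature matrix of all samples WITH a leading
// intercept column; grp maps each row to its 0-based sample index (rows of
// one sample are contiguous). B0 holds one initial parameter column per
// restart; all restarts are advanced in lock step so the per-step logit
// computation is a single dense matrix product.
//
// The per-sample prediction is sigmoid(max logit). Only the argmax motif
// of each sample receives gradient (ties: lowest row index). Training loss
// is recorded AFTER each update, so loss_by_step(t, r) is the loss of
// restart r after t+1 updates; the held-out max logit is recorded on the
// same schedule.

#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]

using namespace arma;

static inline double sigmoid(double x) {
  if (x >= 0.0) {
    return 1.0 / (1.0 + std::exp(-x));
  }
  double e = std::exp(x);
  return e / (1.0 + e);
}

// Per-sample column-wise max and argmax of L (rows grouped by sample).
static void group_max(const mat& L, const std::vector<int>& start,
                      const std::vector<int>& stop, mat& best, umat& argmax) {
  const int n = (int)start.size();
  const int R = (int)L.n_cols;
  for (int r = 0; r < R; ++r) {
    const double* col = L.colptr(r);
    for (int j = 0; j < n; ++j) {
      double m = col[start[j]];
      int a = start[j];
      for (int i = start[j] + 1; i < stop[j]; ++i) {
        if (col[i] > m) { m = col[i]; a = i; }
      }
      best(j, r) = m;
      argmax(j, r) = (uword)a;
    }
  }
}

// [[Rcpp::export]]
Rcpp::List cpp_mil_fit(const arma::mat& X, const arma::ivec& grp, int n,
                       const arma::vec& y, const arma::mat& B0,
                       int n_steps, double lr, double b1, double b2,
                       double eps, const arma::mat& Xh, bool has_heldout,
                       double clip) {
  const int d = (int)X.n_cols;
  const int R = (int)B0.n_cols;
  const int M = (int)X.n_rows;

  std::vector<int> start(n, -1), stop(n, 0);
  for (int i = 0; i < M; ++i) {
    int g = grp(i);
    if (start[g] < 0) start[g] = i;
    stop[g] = i + 1;
  }

  mat B = B0;
  mat Mt(d, R, fill::zeros), Vt(d, R, fill::zeros);
  mat loss_by_step(n_steps, R, fill::zeros);
  mat hstep(has_heldout ? n_steps : 0, has_heldout ? R : 0);

  mat best(n, R), G(d, R);
  umat amax(n, R);
  mat resid(n, R);

  auto record_loss = [&](int slot) {
    for (int r = 0; r < R; ++r) {
      double loss = 0.0;
      for (int j = 0; j < n; ++j) {
        double p = sigmoid(best(j, r));
        double pc = std::min(std::max(p, clip), 1.0 - clip);
        loss -= y(j) * std::log(pc) + (1.0 - y(j)) * std::log(1.0 - pc);
      }
      loss_by_step(slot, r) = loss / n;
    }
  };

  for (int t = 0; t < n_steps; ++t) {
    mat L = X * B;  // M x R
    group_max(L, start, stop, best, amax);
    if (t > 0) record_loss(t - 1);

    // subgradient: (p - y)/n on the argmax row of each sample
    G.zeros();
    for (int r = 0; r < R; ++r) {
      for (int j = 0; j < n; ++j) {
        double rs = sigmoid(best(j, r)) - y(j);
        resid(j, r) = rs;
        const uword a = amax(j, r);
        for (int k = 0; k < d; ++k) G(k, r) += rs * X(a, k);
      }
    }
    G /= (double)n;

    Mt = b1 * Mt + (1.0 - b1) * G;
    Vt = b2 * Vt + (1.0 - b2) * (G % G);
    double c1 = 1.0 - std::pow(b1, t + 1);
    double c2 = 1.0 - std::pow(b2, t + 1);
    B -= lr * (Mt / c1) / (sqrt(Vt / c2) + eps);

    if (has_heldout) {
      mat Lh = Xh * B;  // mh x R
      for (int r = 0; r < R; ++r) {
        hstep(t, r) = Lh.col(r).max();
      }
    }
  }

  // loss after the final update
  {
    mat L = X * B;
    group_max(L, start, stop, best, amax);
    record_loss(n_steps - 1);
  }

  return Rcpp::List::create(
      Rcpp::Named("B") = B,
      Rcpp::Named("loss_by_step") = loss_by_step,
      Rcpp::Named("heldout_logit_by_step") = hstep);
}
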