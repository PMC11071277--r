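// Hot path of the subvolume fitter: full-batch Adam on the sinusoidal
// coordinate network against the reprojection MSE. Mirrors the R reference
// implementation in reconstruct.R (engine = "r") operation for operation;
// the R path stays authoritative for regularized objectives.
#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]
using namespace arma;

// layers: list of list(W = fan_in x fan_out, b = fan_out)
// X:      n_vox x in_features encoded coordinates (xzy voxel order)
// A:      sparse projector, (l*nx) x (nx*nz)
// P:      measured projections, (l*nx) x j
// lrs:    per-iteration learning rates
// [[Rcpp::export]]
Rcpp::List cn_train_cpp(Rcpp::List layers, double omega0,
                        const arma::mat& X, const arma::sp_mat& A,
                        const arma::mat& P, const arma::vec& lrs,
                        double beta1, double beta2, double eps) {
  const int nl = layers.size();
  std::vector<mat> W(nl);
  std::vector<rowvec> b(nl);
  for (int i = 0; i < nl; ++i) {
    Rcpp::List li = layers[i];
    W[i] = Rcpp::as<mat>(li["W"]);
    b[i] = Rcpp::as<rowvec>(li["b"]);
  }
  const sp_mat At = A.t();
  const int iters = lrs.n_elem;
  const double n_meas = static_cast<double>(P.n_elem);
  const uword j = P.n_cols;
  const uword nslice = At.n_rows;  // nx * nz

  // Adam state
  std::vector<mat> mW(nl), vW(nl);
  std::vector<rowvec> mb(nl), vb(nl);
  for (int i = 0; i < nl; ++i) {
    mW[i] = zeros<mat>(size(W[i])); vW[i] = zeros<mat>(size(W[i]));
    mb[i] = zeros<rowvec>(b[i].n_elem); vb[i] = zeros<rowvec>(b[i].n_elem);
  }

  std::vector<mat> act(nl);     // layer inputs
  std::vector<mat> Z(nl - 1);   // pre-activations of sine layers
  vec loss_trace(iters);
  double best_loss = datum::inf;
  int best_iter = 0;
  std::vector<mat> bestW = W;
  std::vector<rowvec> bestb = b;

  for (int it = 0; it < iters; ++it) {
    // forward
    act[0] = X;
    for (int i = 0; i < nl - 1; ++i) {
      Z[i] = act[i] * W[i];
      Z[i].each_row() += b[i];
      act[i + 1] = sin(omega0 * Z[i]);
    }
    mat out = act[nl - 1] * W[nl - 1];
    out.each_row() += b[nl - 1];

    // reprojection residual and loss
    mat V(out.memptr(), nslice, j, false, true);
    mat resid = A * V - P;
    double loss = accu(square(resid)) / n_meas;
    loss_trace(it) = loss;
    if (!std::isfinite(loss)) {
      return Rcpp::List::create(
        Rcpp::Named("diverged_at") = it + 1,
        Rcpp::Named("loss_trace") = loss_trace.head(it + 1));
    }
    if (loss < best_loss) {
      best_loss = loss;
      best_iter = it + 1;
      bestW = W; bestb = b;
    }

    // gradient of the loss w.r.t. the network output
    mat dV = (At * resid) * (2.0 / n_meas);
    mat dout(dV.memptr(), out.n_rows, 1, false, true);

    // backward
    const double bc1 = 1.0 - std::pow(beta1, it + 1);
    const double bc2 = 1.0 - std::pow(beta2, it + 1);
    mat d = dout;
    for (int i = nl - 1; i >= 0; --i) {
      mat gW = act[i].t() * d;
      rowvec gb = sum(d, 0);
      if (i > 0) {
        mat da = d * W[i].t();
        d = da % (omega0 * cos(omega0 * Z[i - 1]));
      }
      // Adam update
      mW[i] = beta1 * mW[i] + (1.0 - beta1) * gW;
      vW[i] = beta2 * vW[i] + (1.0 - beta2) * square(gW);
      mb[i] = beta1 * mb[i] + (1.0 - beta1) * gb;
      vb[i] = beta2 * vb[i] + (1.0 - beta2) * square(gb);
      W[i] -= lrs(it) * (mW[i] / bc1) / (sqrt(vW[i] / bc2) + eps);
      b[i] -= lrs(it) * (mb[i] / bc1) / (sqrt(vb[i] / bc2) + eps);
    }
  }

  Rcpp::List outW(nl);
  for (int i = 0; i < nl; ++i) {
    outW[i] = Rcpp::List::create(Rcpp::Named("W") = bestW[i],
                                 Rcpp::Named("b") = vectorise(bestb[i]));
  }
  return Rcpp::List::create(
    Rcpp::Named("layers") = outW,
    Rcpp::Named("loss_trace") = loss_trace,
    Rcpp::Named("best_loss") = best_loss,
    Rcpp::Named("best_iter") = best_iter);
}
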