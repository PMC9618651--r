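// Batched LSTM forward / backward-through-time kernels.
//
// Convention: inputs arrive as cubes with one slice per timestep
// (n_rows = batch, n_cols = features, n_slices = timesteps).  Gate
// pre-activations are ordered [input, forget, candidate, output] along
// the 4h columns of W, U and b.  Initial hidden and cell states are zero.
//
// The input projection X * W is hoisted out of the time loop into one
// (batch * timesteps) x features GEMM — on a single CPU this dominates
// the cost of many small per-timestep multiplies; only the recurrent
// term H * U stays inside the loop.

#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]

using namespace arma;

static inline mat sigmoid(const mat& x) { return 1.0 / (1.0 + exp(-x)); }

// Stack the timestep slices of a cube into a (B*T, k) matrix.
static mat stack_slices(const cube& X) {
  const uword B = X.n_rows, k = X.n_cols, T = X.n_slices;
  mat out(B * T, k);
  for (uword t = 0; t < T; ++t) out.rows(t * B, t * B + B - 1) = X.slice(t);
  return out;
}

// [[Rcpp::export]]
Rcpp::List lstm_forward_cpp(const arma::cube& X, const arma::mat& W,
                            const arma::mat& U, const arma::vec& b) {
  const uword B = X.n_rows, T = X.n_slices;
  const uword h = U.n_rows;
  if (W.n_cols != 4 * h || b.n_elem != 4 * h)
    Rcpp::stop("inconsistent LSTM parameter shapes");
  if (X.n_cols != W.n_rows)
    Rcpp::stop("input feature dimension does not match W");

  mat A_all = stack_slices(X) * W;  // one big GEMM for all timesteps
  A_all.each_row() += b.t();

  cube H(B, h, T), C(B, h, T), G(B, 4 * h, T);
  mat hprev(B, h, fill::zeros), cprev(B, h, fill::zeros);

  for (uword t = 0; t < T; ++t) {
    mat A = A_all.rows(t * B, t * B + B - 1) + hprev * U;
    mat gi = sigmoid(A.cols(0, h - 1));
    mat gf = sigmoid(A.cols(h, 2 * h - 1));
    mat gg = tanh(A.cols(2 * h, 3 * h - 1));
    mat go = sigmoid(A.cols(3 * h, 4 * h - 1));
    mat c = gf % cprev + gi % gg;
    mat hc = go % tanh(c);
    G.slice(t).cols(0, h - 1) = gi;
    G.slice(t).cols(h, 2 * h - 1) = gf;
    G.slice(t).cols(2 * h, 3 * h - 1) = gg;
    G.slice(t).cols(3 * h, 4 * h - 1) = go;
    C.slice(t) = c;
    H.slice(t) = hc;
    hprev = std::move(hc);
    cprev = std::move(c);
  }
  return Rcpp::List::create(Rcpp::Named("H") = H, Rcpp::Named("C") = C,
                            Rcpp::Named("G") = G);
}

// [[Rcpp::export]]
Rcpp::List lstm_backward_cpp(const arma::cube& dH, const arma::cube& X,
                             const arma::cube& H, const arma::cube& C,
                             const arma::cube& G, const arma::mat& W,
                             const arma::mat& U) {
  const uword B = X.n_rows, n = X.n_cols, T = X.n_slices;
  const uword h = U.n_rows;

  mat dA_all(B * T, 4 * h);
  mat dU(h, 4 * h, fill::zeros);
  mat dhnext(B, h, fill::zeros), dcnext(B, h, fill::zeros);

  for (uword tt = T; tt-- > 0;) {
    const mat& Gt = G.slice(tt);
    mat gi = Gt.cols(0, h - 1);
    mat gf = Gt.cols(h, 2 * h - 1);
    mat gg = Gt.cols(2 * h, 3 * h - 1);
    mat go = Gt.cols(3 * h, 4 * h - 1);
    mat tc = tanh(C.slice(tt));

    mat dh = dH.slice(tt) + dhnext;
    mat do_ = dh % tc;
    mat dc = dcnext + dh % go % (1.0 - tc % tc);
    mat di = dc % gg;
    mat dg = dc % gi;
    mat df = (tt > 0) ? mat(dc % C.slice(tt - 1)) : mat(B, h, fill::zeros);
    dcnext = dc % gf;

    mat dA(B, 4 * h);
    dA.cols(0, h - 1) = di % gi % (1.0 - gi);
    dA.cols(h, 2 * h - 1) = df % gf % (1.0 - gf);
    dA.cols(2 * h, 3 * h - 1) = dg % (1.0 - gg % gg);
    dA.cols(3 * h, 4 * h - 1) = do_ % go % (1.0 - go);
    if (tt > 0) dU += H.slice(tt - 1).t() * dA;
    dhnext = dA * U.t();
    dA_all.rows(tt * B, tt * B + B - 1) = dA;
  }

  mat Xmat = stack_slices(X);
  mat dW = Xmat.t() * dA_all;       // one big GEMM
  mat dXmat = dA_all * W.t();       // one big GEMM
  rowvec db = sum(dA_all, 0);

  cube dX(B, n, T);
  for (uword t = 0; t < T; ++t) dX.slice(t) = dXmat.rows(t * B, t * B + B - 1);

  return Rcpp::List::create(Rcpp::Named("dX") = dX, Rcpp::Named("dW") = dW,
                            Rcpp::Named("dU") = dU,
                            Rcpp::Named("db") = db.t());
}
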