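// Training loops for the 1-D convolutional autoencoder and the severity
// regression heads. Convolutions use "same" zero padding and are evaluated
// as one GEMM over an im2col matrix. Optimizer is RMSprop. All shuffling
// orders are generated in R and passed in, so results are reproducible
// from the R RNG seed alone.

#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]

using namespace arma;

namespace {

struct Conv {
  mat W;   // c_out x (c_in * K), column blocks ordered by tap
  vec b;
  int c_in, K;
};

struct Dense {
  mat W;
  vec b;
};

struct Opt {
  mat sW;
  vec sb;
  Opt(const mat& W, const vec& b) : sW(size(W), fill::zeros),
                                    sb(size(b), fill::zeros) {}
};

const double kRho = 0.9, kEps = 1e-8;

void rms_update(mat& P, vec& b, const mat& gW, const vec& gb, Opt& o,
                double lr) {
  o.sW = kRho * o.sW + (1 - kRho) * (gW % gW);
  P -= lr * gW / (sqrt(o.sW) + kEps);
  o.sb = kRho * o.sb + (1 - kRho) * (gb % gb);
  b -= lr * gb / (sqrt(o.sb) + kEps);
}

// gather whole samples (length-L column blocks) of X into one batch
mat gather(const mat& X, const uvec& bs, int L) {
  mat Xb(X.n_rows, L * bs.n_elem);
  for (uword j = 0; j < bs.n_elem; ++j)
    Xb.cols(j * L, (j + 1) * L - 1) = X.cols(bs[j] * L, (bs[j] + 1) * L - 1);
  return Xb;
}

mat im2col(const mat& X, int L, int B, int K) {
  int cin = X.n_rows, pad = (K - 1) / 2, Lp = L + 2 * pad;
  mat Xp(cin, Lp * B, fill::zeros);
  for (int b = 0; b < B; ++b)
    Xp.cols(b * Lp + pad, b * Lp + pad + L - 1) = X.cols(b * L, (b + 1) * L - 1);
  mat M(cin * K, L * B);
  for (int t = 0; t < K; ++t)
    for (int b = 0; b < B; ++b)
      M.submat(t * cin, b * L, (t + 1) * cin - 1, (b + 1) * L - 1) =
          Xp.cols(b * Lp + t, b * Lp + t + L - 1);
  return M;
}

mat conv_fwd(const Conv& c, const mat& X, int L, int B, mat& Mcache) {
  Mcache = im2col(X, L, B, c.K);
  mat out = c.W * Mcache;
  out.each_col() += c.b;
  return out;
}

// returns dX unless last (input) layer
mat conv_bwd(const Conv& c, const mat& M, const mat& dOut, int L, int B,
             mat& dW, vec& db, bool need_dx) {
  dW = dOut * M.t();
  db = sum(dOut, 1);
  if (!need_dx) return mat();
  int cin = c.c_in, K = c.K, pad = (K - 1) / 2, Lp = L + 2 * pad;
  mat dM = c.W.t() * dOut;
  mat dXp(cin, Lp * B, fill::zeros);
  for (int t = 0; t < K; ++t)
    for (int b = 0; b < B; ++b)
      dXp.cols(b * Lp + t, b * Lp + t + L - 1) +=
          dM.submat(t * cin, b * L, (t + 1) * cin - 1, (b + 1) * L - 1);
  mat dX(cin, L * B);
  for (int b = 0; b < B; ++b)
    dX.cols(b * L, (b + 1) * L - 1) = dXp.cols(b * Lp + pad, b * Lp + pad + L - 1);
  return dX;
}

mat pool_fwd(const mat& X, int L, int B) {
  mat P(X.n_rows, B);
  for (int b = 0; b < B; ++b)
    P.col(b) = mean(X.cols(b * L, (b + 1) * L - 1), 1);
  return P;
}

mat pool_bwd(const mat& dP, int L, int B) {
  mat dX(dP.n_rows, L * B);
  for (int b = 0; b < B; ++b)
    dX.cols(b * L, (b + 1) * L - 1) = repmat(dP.col(b) / L, 1, L);
  return dX;
}

Conv as_conv(const Rcpp::List& l) {
  Conv c;
  c.W = Rcpp::as<mat>(l["W"]);
  c.b = Rcpp::as<vec>(l["b"]);
  c.c_in = Rcpp::as<int>(l["c_in"]);
  c.K = Rcpp::as<int>(l["K"]);
  return c;
}

Rcpp::List conv_out(const Conv& c) {
  return Rcpp::List::create(Rcpp::Named("W") = c.W, Rcpp::Named("b") = c.b,
                            Rcpp::Named("c_in") = c.c_in,
                            Rcpp::Named("K") = c.K);
}

uvec batch_of(const Rcpp::IntegerMatrix& orders, int epoch, int from, int to) {
  uvec bs(to - from + 1);
  for (int i = from; i <= to; ++i) bs[i - from] = orders(epoch, i) - 1;
  return bs;
}

}  // namespace

// [[Rcpp::export(name = ".cpp_train_autoencoder")]]
Rcpp::List cpp_train_autoencoder(const arma::mat& X, int L,
                                 Rcpp::List params,
                                 const arma::uvec& train_ids1,
                                 const arma::uvec& val_ids1,
                                 int epochs, int batch, double lr,
                                 const Rcpp::IntegerMatrix& orders) {
  Conv c1 = as_conv(params["conv1"]), c2 = as_conv(params["conv2"]),
       c3 = as_conv(params["conv3"]), c4 = as_conv(params["conv4"]);
  Opt o1(c1.W, c1.b), o2(c2.W, c2.b), o3(c3.W, c3.b), o4(c4.W, c4.b);
  uvec val_ids = val_ids1 - 1;
  mat Xval = gather(X, val_ids, L);
  int Bval = val_ids.n_elem;
  int n_train = train_ids1.n_elem;
  vec train_hist(epochs), val_hist(epochs);

  for (int e = 0; e < epochs; ++e) {
    double ep_loss = 0;
    int n_b = 0;
    for (int start = 0; start < n_train; start += batch) {
      int stop = std::min(start + batch - 1, n_train - 1);
      uvec bs = batch_of(orders, e, start, stop);
      int B = bs.n_elem;
      mat Xb = gather(X, bs, L);
      mat M1, M2, M3, M4;
      mat z1 = conv_fwd(c1, Xb, L, B, M1);  mat m1 = conv_to<mat>::from(z1 > 0);
      mat z2 = conv_fwd(c2, z1 % m1, L, B, M2); mat m2 = conv_to<mat>::from(z2 > 0);
      mat z3 = conv_fwd(c3, z2 % m2, L, B, M3); mat m3 = conv_to<mat>::from(z3 > 0);
      mat xhat = conv_fwd(c4, z3 % m3, L, B, M4);
      mat diff = xhat - Xb;
      double loss = accu(diff % diff) / diff.n_elem;
      if (!std::isfinite(loss))
        Rcpp::stop("non-finite reconstruction loss");
      ep_loss += loss; ++n_b;
      mat dxh = 2.0 * diff / diff.n_elem;
      mat dW; vec db;
      mat dx4 = conv_bwd(c4, M4, dxh, L, B, dW, db, true);
      mat gW4 = dW; vec gb4 = db;
      mat dx3 = conv_bwd(c3, M3, dx4 % m3, L, B, dW, db, true);
      mat gW3 = dW; vec gb3 = db;
      mat dx2 = conv_bwd(c2, M2, dx3 % m2, L, B, dW, db, true);
      mat gW2 = dW; vec gb2 = db;
      conv_bwd(c1, M1, dx2 % m1, L, B, dW, db, false);
      rms_update(c1.W, c1.b, dW, db, o1, lr);
      rms_update(c2.W, c2.b, gW2, gb2, o2, lr);
      rms_update(c3.W, c3.b, gW3, gb3, o3, lr);
      rms_update(c4.W, c4.b, gW4, gb4, o4, lr);
    }
    train_hist[e] = ep_loss / n_b;
    mat M;
    mat z1 = conv_fwd(c1, Xval, L, Bval, M);
    mat z2 = conv_fwd(c2, z1 % conv_to<mat>::from(z1 > 0), L, Bval, M);
    mat z3 = conv_fwd(c3, z2 % conv_to<mat>::from(z2 > 0), L, Bval, M);
    mat xhat = conv_fwd(c4, z3 % conv_to<mat>::from(z3 > 0), L, Bval, M);
    mat diff = xhat - Xval;
    val_hist[e] = accu(diff % diff) / diff.n_elem;
  }
  return Rcpp::List::create(
      Rcpp::Named("params") = Rcpp::List::create(
          Rcpp::Named("conv1") = conv_out(c1), Rcpp::Named("conv2") = conv_out(c2),
          Rcpp::Named("conv3") = conv_out(c3), Rcpp::Named("conv4") = conv_out(c4)),
      Rcpp::Named("train_loss") = train_hist,
      Rcpp::Named("val_loss") = val_hist);
}

// [[Rcpp::export(name = ".cpp_train_regressor")]]
Rcpp::List cpp_train_regressor(const arma::mat& X, const arma::vec& y, int L,
                               Rcpp::List params, int epochs, int batch,
                               double lr, const Rcpp::IntegerMatrix& orders) {
  Conv c1 = as_conv(params["conv1"]), c2 = as_conv(params["conv2"]);
  Dense d1{Rcpp::as<mat>(Rcpp::as<Rcpp::List>(params["d1"])["W"]),
           Rcpp::as<vec>(Rcpp::as<Rcpp::List>(params["d1"])["b"])};
  Dense d2{Rcpp::as<mat>(Rcpp::as<Rcpp::List>(params["d2"])["W"]),
           Rcpp::as<vec>(Rcpp::as<Rcpp::List>(params["d2"])["b"])};
  Opt o1(c1.W, c1.b), o2(c2.W, c2.b), od1(d1.W, d1.b), od2(d2.W, d2.b);
  int n = y.n_elem;

  for (int e = 0; e < epochs; ++e) {
    for (int start = 0; start < n; start += batch) {
      int stop = std::min(start + batch - 1, n - 1);
      uvec bs = batch_of(orders, e, start, stop);
      int B = bs.n_elem;
      mat Xb = gather(X, bs, L);
      mat M1, M2;
      mat z1 = conv_fwd(c1, Xb, L, B, M1); mat m1 = conv_to<mat>::from(z1 > 0);
      mat z2 = conv_fwd(c2, z1 % m1, L, B, M2); mat m2 = conv_to<mat>::from(z2 > 0);
      mat P = pool_fwd(z2 % m2, L, B);
      mat h_pre = d1.W * P; h_pre.each_col() += d1.b;
      mat mh = conv_to<mat>::from(h_pre > 0);
      mat h = h_pre % mh;
      mat yhat_m = d2.W * h;
      rowvec yhat = yhat_m.row(0) + d2.b[0];
      rowvec dyv = 2.0 * (yhat - y(bs).t()) / B;
      if (!dyv.is_finite()) Rcpp::stop("non-finite regression loss");
      mat dy(dyv);
      mat gWd2 = dy * h.t(); vec gbd2 = sum(dy, 1);
      mat dh = (d2.W.t() * dy) % mh;
      mat gWd1 = dh * P.t(); vec gbd1 = sum(dh, 1);
      mat dP = d1.W.t() * dh;
      mat da2 = pool_bwd(dP, L, B) % m2;
      mat dW; vec db;
      mat dx2 = conv_bwd(c2, M2, da2, L, B, dW, db, true);
      mat gW2 = dW; vec gb2 = db;
      conv_bwd(c1, M1, dx2 % m1, L, B, dW, db, false);
      rms_update(c1.W, c1.b, dW, db, o1, lr);
      rms_update(c2.W, c2.b, gW2, gb2, o2, lr);
      rms_update(d1.W, d1.b, gWd1, gbd1, od1, lr);
      rms_update(d2.W, d2.b, gWd2, gbd2, od2, lr);
    }
  }
  return Rcpp::List::create(
      Rcpp::Named("conv1") = conv_out(c1), Rcpp::Named("conv2") = conv_out(c2),
      Rcpp::Named("d1") = Rcpp::List::create(Rcpp::Named("W") = d1.W,
                                             Rcpp::Named("b") = d1.b),
      Rcpp::Named("d2") = Rcpp::List::create(Rcpp::Named("W") = d2.W,
                                             Rcpp::Named("b") = d2.b));
}
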