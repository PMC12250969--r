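// Multi-view brain-network classifier: forward pass, backpropagation and
// Adam training loop.
//
// Input layout: one epoch's multi-view tensor (N views of CxC = 8x8
// connectivity matrices) is a column of length N*64; view k occupies rows
// [k*64, k*64+63] in column-major 8x8 order. The pipeline is
//   mask (zero rows/cols of every view) ->
//   per-view attention: softmax over the 64 entries of relu(W_k o G_k) ->
//   conv stack 16@3x3 / 32@3x3 / 64@2x2 (stride 1, no padding, ReLU) ->
//   flatten (64*3*3 = 576) -> linear 576/256/128/64/n_classes
//   (ReLU on hidden linear layers, none on the output).
// All randomness (init, shuffling) lives on the R side; this code is
// deterministic.

#define ARMA_NO_DEBUG
#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]
using namespace arma;

namespace {

struct Params {
  mat Wv;                 // N x 64 view-attention weights
  mat K1, K2, K3;         // conv kernels: 16x(N*9), 32x144, 64x128
  vec b1, b2, b3;
  mat A1, A2, A3, A4, A5; // linear weights
  vec c1, c2, c3, c4, c5;
};

Params unpack(const Rcpp::List& p) {
  Params q;
  q.Wv = Rcpp::as<mat>(p["Wv"]);
  q.K1 = Rcpp::as<mat>(p["K1"]); q.b1 = Rcpp::as<vec>(p["b1"]);
  q.K2 = Rcpp::as<mat>(p["K2"]); q.b2 = Rcpp::as<vec>(p["b2"]);
  q.K3 = Rcpp::as<mat>(p["K3"]); q.b3 = Rcpp::as<vec>(p["b3"]);
  q.A1 = Rcpp::as<mat>(p["A1"]); q.c1 = Rcpp::as<vec>(p["c1"]);
  q.A2 = Rcpp::as<mat>(p["A2"]); q.c2 = Rcpp::as<vec>(p["c2"]);
  q.A3 = Rcpp::as<mat>(p["A3"]); q.c3 = Rcpp::as<vec>(p["c3"]);
  q.A4 = Rcpp::as<mat>(p["A4"]); q.c4 = Rcpp::as<vec>(p["c4"]);
  q.A5 = Rcpp::as<mat>(p["A5"]); q.c5 = Rcpp::as<vec>(p["c5"]);
  return q;
}

Rcpp::List pack(const Params& q) {
  return Rcpp::List::create(
    Rcpp::Named("Wv") = q.Wv,
    Rcpp::Named("K1") = q.K1, Rcpp::Named("b1") = q.b1,
    Rcpp::Named("K2") = q.K2, Rcpp::Named("b2") = q.b2,
    Rcpp::Named("K3") = q.K3, Rcpp::Named("b3") = q.b3,
    Rcpp::Named("A1") = q.A1, Rcpp::Named("c1") = q.c1,
    Rcpp::Named("A2") = q.A2, Rcpp::Named("c2") = q.c2,
    Rcpp::Named("A3") = q.A3, Rcpp::Named("c3") = q.c3,
    Rcpp::Named("A4") = q.A4, Rcpp::Named("c4") = q.c4,
    Rcpp::Named("A5") = q.A5, Rcpp::Named("c5") = q.c5);
}

// Activations retained for the backward pass.
struct Cache {
  mat Gm;                   // masked input, (N*64) x B
  mat Att;                  // post-attention, (N*64) x B
  mat X1, Z1;               // conv1 im2col + relu'd output
  mat X2, Z2;
  mat X3, Z3;
  mat F, H1, H2, H3, H4;    // flatten + linear activations
  mat logits;
};

// Forward pass. N views, B samples; mask is a 64-vector (all ones = none).
void forward(const Params& q, const mat& X, const vec& mask, Cache& c) {
  const uword NV = q.Wv.n_rows, B = X.n_cols;

  c.Gm = X;
  for (uword k = 0; k < NV; ++k)
    c.Gm.rows(k * 64, k * 64 + 63).each_col() %= mask;

  // attention: per view, softmax over the 64 entries of relu(Wv_k o g)
  c.Att.set_size(NV * 64, B);
  for (uword k = 0; k < NV; ++k) {
    mat h = c.Gm.rows(k * 64, k * 64 + 63);
    h.each_col() %= q.Wv.row(k).t();
    h.transform([](double v) { return v > 0 ? v : 0.0; });
    rowvec mx = max(h, 0);
    h.each_row() -= mx;
    h = exp(h);
    h.each_row() /= sum(h, 0);
    c.Att.rows(k * 64, k * 64 + 63) = h;
  }

  // conv1: N channels, 8x8 -> 16 channels, 6x6
  c.X1.set_size(NV * 9, B * 36);
  for (uword b = 0; b < B; ++b)
    for (uword pc = 0; pc < 6; ++pc)
      for (uword pr = 0; pr < 6; ++pr) {
        const uword col = b * 36 + pr + 6 * pc;
        for (uword dc = 0; dc < 3; ++dc)
          for (uword dr = 0; dr < 3; ++dr) {
            const uword o = dr + 3 * dc;
            const uword pix = (pr + dr) + 8 * (pc + dc);
            for (uword n = 0; n < NV; ++n)
              c.X1(n + NV * o, col) = c.Att(n * 64 + pix, b);
          }
      }
  c.Z1 = q.K1 * c.X1;
  c.Z1.each_col() += q.b1;
  c.Z1.transform([](double v) { return v > 0 ? v : 0.0; });

  // conv2: 16 channels, 6x6 -> 32 channels, 4x4
  c.X2.set_size(144, B * 16);
  for (uword b = 0; b < B; ++b)
    for (uword qc = 0; qc < 4; ++qc)
      for (uword qr = 0; qr < 4; ++qr) {
        const uword col = b * 16 + qr + 4 * qc;
        for (uword dc = 0; dc < 3; ++dc)
          for (uword dr = 0; dr < 3; ++dr) {
            const uword o = dr + 3 * dc;
            const uword p = (qr + dr) + 6 * (qc + dc);
            for (uword ch = 0; ch < 16; ++ch)
              c.X2(ch + 16 * o, col) = c.Z1(ch, b * 36 + p);
          }
      }
  c.Z2 = q.K2 * c.X2;
  c.Z2.each_col() += q.b2;
  c.Z2.transform([](double v) { return v > 0 ? v : 0.0; });

  // conv3: 32 channels, 4x4 -> 64 channels, 3x3
  c.X3.set_size(128, B * 9);
  for (uword b = 0; b < B; ++b)
    for (uword rc = 0; rc < 3; ++rc)
      for (uword rr = 0; rr < 3; ++rr) {
        const uword col = b * 9 + rr + 3 * rc;
        for (uword dc = 0; dc < 2; ++dc)
          for (uword dr = 0; dr < 2; ++dr) {
            const uword o = dr + 2 * dc;
            const uword p = (rr + dr) + 4 * (rc + dc);
            for (uword ch = 0; ch < 32; ++ch)
              c.X3(ch + 32 * o, col) = c.Z2(ch, b * 16 + p);
          }
      }
  c.Z3 = q.K3 * c.X3;
  c.Z3.each_col() += q.b3;
  c.Z3.transform([](double v) { return v > 0 ? v : 0.0; });

  // flatten: 64 x 3 x 3 -> 576
  c.F.set_size(576, B);
  for (uword b = 0; b < B; ++b)
    c.F.col(b) = vectorise(c.Z3.cols(b * 9, b * 9 + 8));

  c.H1 = q.A1 * c.F;  c.H1.each_col() += q.c1;
  c.H1.transform([](double v) { return v > 0 ? v : 0.0; });
  c.H2 = q.A2 * c.H1; c.H2.each_col() += q.c2;
  c.H2.transform([](double v) { return v > 0 ? v : 0.0; });
  c.H3 = q.A3 * c.H2; c.H3.each_col() += q.c3;
  c.H3.transform([](double v) { return v > 0 ? v : 0.0; });
  c.H4 = q.A4 * c.H3; c.H4.each_col() += q.c4;
  c.H4.transform([](double v) { return v > 0 ? v : 0.0; });
  c.logits = q.A5 * c.H4;
  c.logits.each_col() += q.c5;
}

// Softmax cross-entropy; fills per-sample probability matrix.
double ce_loss(const mat& logits, const ivec& y, const vec& cw, mat& probs) {
  const uword B = logits.n_cols;
  probs = logits;
  rowvec mx = max(probs, 0);
  probs.each_row() -= mx;
  probs = exp(probs);
  probs.each_row() /= sum(probs, 0);
  double wsum = 0, loss = 0;
  for (uword b = 0; b < B; ++b) {
    const double w = cw(y(b));
    loss -= w * std::log(std::max(probs(y(b), b), 1e-300));
    wsum += w;
  }
  return loss / wsum;
}

// Backward pass; returns gradients in g. If dX is non-null, also computes
// the gradient with respect to the raw (pre-mask) input tensor.
void backward(const Params& q, const Cache& c, const ivec& y, const vec& cw,
              const vec& mask, Params& g, mat* dX) {
  const uword NV = q.Wv.n_rows, B = c.Att.n_cols;

  mat probs;
  ce_loss(c.logits, y, cw, probs);
  double wsum = 0;
  for (uword b = 0; b < B; ++b) wsum += cw(y(b));
  mat dlog = probs;
  for (uword b = 0; b < B; ++b) {
    dlog(y(b), b) -= 1.0;
    dlog.col(b) *= cw(y(b)) / wsum;
  }

  g.A5 = dlog * c.H4.t();          g.c5 = sum(dlog, 1);
  mat d = q.A5.t() * dlog;         d %= conv_to<mat>::from(c.H4 > 0);
  g.A4 = d * c.H3.t();             g.c4 = sum(d, 1);
  d = q.A4.t() * d;                d %= conv_to<mat>::from(c.H3 > 0);
  g.A3 = d * c.H2.t();             g.c3 = sum(d, 1);
  d = q.A3.t() * d;                d %= conv_to<mat>::from(c.H2 > 0);
  g.A2 = d * c.H1.t();             g.c2 = sum(d, 1);
  d = q.A2.t() * d;                d %= conv_to<mat>::from(c.H1 > 0);
  g.A1 = d * c.F.t();              g.c1 = sum(d, 1);
  mat dF = q.A1.t() * d;

  // unflatten -> conv3
  mat dZ3(64, B * 9);
  for (uword b = 0; b < B; ++b)
    dZ3.cols(b * 9, b * 9 + 8) = reshape(dF.col(b), 64, 9);
  dZ3 %= conv_to<mat>::from(c.Z3 > 0);
  g.K3 = dZ3 * c.X3.t();           g.b3 = sum(dZ3, 1);
  mat dX3 = q.K3.t() * dZ3;

  mat dZ2(32, B * 16, fill::zeros);
  for (uword b = 0; b < B; ++b)
    for (uword rc = 0; rc < 3; ++rc)
      for (uword rr = 0; rr < 3; ++rr) {
        const uword col = b * 9 + rr + 3 * rc;
        for (uword dc = 0; dc < 2; ++dc)
          for (uword dr = 0; dr < 2; ++dr) {
            const uword o = dr + 2 * dc;
            const uword p = (rr + dr) + 4 * (rc + dc);
            for (uword ch = 0; ch < 32; ++ch)
              dZ2(ch, b * 16 + p) += dX3(ch + 32 * o, col);
          }
      }
  dZ2 %= conv_to<mat>::from(c.Z2 > 0);
  g.K2 = dZ2 * c.X2.t();           g.b2 = sum(dZ2, 1);
  mat dX2 = q.K2.t() * dZ2;

  mat dZ1(16, B * 36, fill::zeros);
  for (uword b = 0; b < B; ++b)
    for (uword qc = 0; qc < 4; ++qc)
      for (uword qr = 0; qr < 4; ++qr) {
        const uword col = b * 16 + qr + 4 * qc;
        for (uword dc = 0; dc < 3; ++dc)
          for (uword dr = 0; dr < 3; ++dr) {
            const uword o = dr + 3 * dc;
            const uword p = (qr + dr) + 6 * (qc + dc);
            for (uword ch = 0; ch < 16; ++ch)
              dZ1(ch, b * 36 + p) += dX2(ch + 16 * o, col);
          }
      }
  dZ1 %= conv_to<mat>::from(c.Z1 > 0);
  g.K1 = dZ1 * c.X1.t();           g.b1 = sum(dZ1, 1);
  mat dX1 = q.K1.t() * dZ1;

  mat dAtt(NV * 64, B, fill::zeros);
  for (uword b = 0; b < B; ++b)
    for (uword pc = 0; pc < 6; ++pc)
      for (uword pr = 0; pr < 6; ++pr) {
        const uword col = b * 36 + pr + 6 * pc;
        for (uword dc = 0; dc < 3; ++dc)
          for (uword dr = 0; dr < 3; ++dr) {
            const uword o = dr + 3 * dc;
            const uword pix = (pr + dr) + 8 * (pc + dc);
            for (uword n = 0; n < NV; ++n)
              dAtt(n * 64 + pix, b) += dX1(n + NV * o, col);
          }
      }

  // attention backward: softmax -> relu -> Hadamard with Wv (and mask)
  g.Wv.zeros(NV, 64);
  if (dX) dX->zeros(NV * 64, B);
  for (uword k = 0; k < NV; ++k) {
    const mat s = c.Att.rows(k * 64, k * 64 + 63);
    mat u = dAtt.rows(k * 64, k * 64 + 63);
    const rowvec dot = sum(u % s, 0);
    u.each_row() -= dot;
    mat dh = s % u;
    // relu gate: pre-activation was Wv_k o Gm; positive iff product positive
    const mat gm = c.Gm.rows(k * 64, k * 64 + 63);
    mat pre = gm;
    pre.each_col() %= q.Wv.row(k).t();
    dh %= conv_to<mat>::from(pre > 0);
    g.Wv.row(k) = sum(dh % gm, 1).t();
    if (dX) {
      mat dg = dh;
      dg.each_col() %= q.Wv.row(k).t() % mask;  // d/d(raw input): mask gates
      dX->rows(k * 64, k * 64 + 63) = dg;
    }
  }
}

template <typename T>
void adam_step(T& w, const T& grad, T& m, T& v, double lr,
               double b1, double b2, double eps, double t) {
  m = b1 * m + (1 - b1) * grad;
  v = b2 * v + (1 - b2) * (grad % grad);
  const double bc1 = 1 - std::pow(b1, t), bc2 = 1 - std::pow(b2, t);
  w -= lr * (m / bc1) / (sqrt(v / bc2) + eps);
}

} // namespace

// [[Rcpp::export]]
arma::mat cpp_forward(Rcpp::List params, const arma::mat& X,
                      const arma::vec& mask) {
  Params q = unpack(params);
  Cache c;
  forward(q, X, mask, c);
  return c.logits;
}

// [[Rcpp::export]]
Rcpp::List cpp_loss_grads(Rcpp::List params, const arma::mat& X,
                          const arma::ivec& y, const arma::vec& mask,
                          const arma::vec& class_w) {
  Params q = unpack(params);
  Cache c;
  forward(q, X, mask, c);
  mat probs;
  const double loss = ce_loss(c.logits, y, class_w, probs);
  Params g;
  mat dX;
  backward(q, c, y, class_w, mask, g, &dX);
  return Rcpp::List::create(Rcpp::Named("loss") = loss,
                            Rcpp::Named("grads") = pack(g),
                            Rcpp::Named("input_grad") = dX);
}

// [[Rcpp::export]]
Rcpp::List cpp_train(Rcpp::List params, const arma::mat& X,
                     const arma::ivec& y, const arma::imat& order,
                     int batch_size, double lr, double beta1, double beta2,
                     double eps, const arma::vec& class_w, bool freeze_wv,
                     const arma::vec& mask) {
  Params q = unpack(params);
  const uword iters = order.n_rows, n = order.n_cols;

  std::vector<mat*> ws = {&q.Wv, &q.K1, &q.K2, &q.K3,
                          &q.A1, &q.A2, &q.A3, &q.A4, &q.A5};
  std::vector<vec*> bs = {&q.b1, &q.b2, &q.b3,
                          &q.c1, &q.c2, &q.c3, &q.c4, &q.c5};
  std::vector<mat> mW(ws.size()), vW(ws.size());
  std::vector<vec> mB(bs.size()), vB(bs.size());
  for (size_t i = 0; i < ws.size(); ++i) {
    mW[i].zeros(ws[i]->n_rows, ws[i]->n_cols);
    vW[i].zeros(ws[i]->n_rows, ws[i]->n_cols);
  }
  for (size_t i = 0; i < bs.size(); ++i) {
    mB[i].zeros(bs[i]->n_elem);
    vB[i].zeros(bs[i]->n_elem);
  }

  vec trace(iters);
  double t = 0;
  Cache c;
  Params g;
  for (uword it = 0; it < iters; ++it) {
    double epoch_loss = 0;
    uword n_batches = 0;
    for (uword start = 0; start < n; start += batch_size) {
      const uword stop = std::min<uword>(start + batch_size, n) - 1;
      const uword B = stop - start + 1;
      mat Xb(X.n_rows, B);
      ivec yb(B);
      for (uword b = 0; b < B; ++b) {
        const uword idx = order(it, start + b) - 1;  // 1-based from R
        Xb.col(b) = X.col(idx);
        yb(b) = y(idx);
      }
      forward(q, Xb, mask, c);
      mat probs;
      epoch_loss += ce_loss(c.logits, yb, class_w, probs);
      ++n_batches;
      backward(q, c, yb, class_w, mask, g, nullptr);

      t += 1;
      std::vector<mat*> gw = {&g.Wv, &g.K1, &g.K2, &g.K3,
                              &g.A1, &g.A2, &g.A3, &g.A4, &g.A5};
      std::vector<vec*> gb = {&g.b1, &g.b2, &g.b3,
                              &g.c1, &g.c2, &g.c3, &g.c4, &g.c5};
      for (size_t i = 0; i < ws.size(); ++i) {
        if (i == 0 && freeze_wv) continue;
        adam_step(*ws[i], *gw[i], mW[i], vW[i], lr, beta1, beta2, eps, t);
      }
      for (size_t i = 0; i < bs.size(); ++i)
        adam_step(*bs[i], *gb[i], mB[i], vB[i], lr, beta1, beta2, eps, t);
    }
    trace(it) = epoch_loss / n_batches;
    if (it % 10 == 0) Rcpp::checkUserInterrupt();
  }
  return Rcpp::List::create(Rcpp::Named("params") = pack(q),
                            Rcpp::Named("loss_trace") = trace);
}
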