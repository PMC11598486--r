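// Peephole LSTM forecaster: batched forward pass, backpropagation through
// time and full-batch Adam training. One scalar input per step, `window`
// steps per sample, a configurable activation layer on the final hidden
// state and a single linear output unit.
//
// Cell equations (diagonal peephole form):
//   i_t = sigmoid(Wxi x_t + Whi h_{t-1} + pci (.) c_{t-1} + bi)
//   f_t = sigmoid(Wxf x_t + Whf h_{t-1} + pcf (.) c_{t-1} + bf)
//   g_t = tanh  (Wxc x_t + Whc h_{t-1} + bc)
//   c_t = f_t (.) c_{t-1} + i_t (.) g_t
//   o_t = sigmoid(Wxo x_t + Who h_{t-1} + pco (.) c_t + bo)
//   h_t = o_t (.) tanh(c_t)
// Output: yhat = wy' act(h_T) + by.
//
// The four gates are computed from one stacked (4H x H) recurrent matrix
// and one stacked input/bias vector per step, so each time step costs two
// GEMMs forward and three backward; per-element work runs through fused
// Armadillo expressions on preallocated cubes.

// [[Rcpp::depends(RcppArmadillo)]]
#include <RcppArmadillo.h>
using namespace arma;

namespace {

// Gate row blocks in the stacked matrices: i, f, g(=candidate), o.
struct Packed {
  mat Wx;            // 4H x 1
  mat Wh;            // 4H x H
  vec pci, pcf, pco; // H
  vec b;             // 4H
  vec wy;            // H
  double by;
  uword H;
};

Packed pack_params(const Rcpp::List& par) {
  Packed p;
  mat Wxi = Rcpp::as<mat>(par["Wxi"]), Wxf = Rcpp::as<mat>(par["Wxf"]),
      Wxc = Rcpp::as<mat>(par["Wxc"]), Wxo = Rcpp::as<mat>(par["Wxo"]);
  p.H = Wxi.n_rows;
  p.Wx = join_vert(join_vert(Wxi, Wxf), join_vert(Wxc, Wxo));
  p.Wh = join_vert(join_vert(Rcpp::as<mat>(par["Whi"]), Rcpp::as<mat>(par["Whf"])),
                   join_vert(Rcpp::as<mat>(par["Whc"]), Rcpp::as<mat>(par["Who"])));
  p.pci = Rcpp::as<vec>(par["pci"]);
  p.pcf = Rcpp::as<vec>(par["pcf"]);
  p.pco = Rcpp::as<vec>(par["pco"]);
  p.b = join_vert(join_vert(Rcpp::as<vec>(par["bi"]), Rcpp::as<vec>(par["bf"])),
                  join_vert(Rcpp::as<vec>(par["bc"]), Rcpp::as<vec>(par["bo"])));
  p.wy = Rcpp::as<vec>(par["wy"]);
  p.by = Rcpp::as<mat>(par["by"])(0, 0);
  return p;
}

Rcpp::List unpack_params(const Packed& p) {
  const uword H = p.H;
  auto blk = [&](const mat& m, int g) { return mat(m.rows(g * H, (g + 1) * H - 1)); };
  return Rcpp::List::create(
      Rcpp::Named("Wxi") = blk(p.Wx, 0), Rcpp::Named("Wxf") = blk(p.Wx, 1),
      Rcpp::Named("Wxc") = blk(p.Wx, 2), Rcpp::Named("Wxo") = blk(p.Wx, 3),
      Rcpp::Named("Whi") = blk(p.Wh, 0), Rcpp::Named("Whf") = blk(p.Wh, 1),
      Rcpp::Named("Whc") = blk(p.Wh, 2), Rcpp::Named("Who") = blk(p.Wh, 3),
      Rcpp::Named("pci") = mat(p.pci), Rcpp::Named("pcf") = mat(p.pcf),
      Rcpp::Named("pco") = mat(p.pco),
      Rcpp::Named("bi") = mat(p.b.subvec(0, H - 1)),
      Rcpp::Named("bf") = mat(p.b.subvec(H, 2 * H - 1)),
      Rcpp::Named("bc") = mat(p.b.subvec(2 * H, 3 * H - 1)),
      Rcpp::Named("bo") = mat(p.b.subvec(3 * H, 4 * H - 1)),
      Rcpp::Named("wy") = mat(p.wy),
      Rcpp::Named("by") = mat(1, 1, fill::value(p.by)));
}

// tanh through exp: cheaper than std::tanh and exact at the saturated ends.
inline mat fast_tanh(const mat& x) {
  return 1.0 - 2.0 / (exp(2.0 * x) + 1.0);
}

struct Workspace {
  cube I, F, G, O, C, TC, HS;  // H x N x T caches
  mat Z, dz;                   // 4H x N
  mat zeros_HN;                // H x N
  mat U, dH, dC, dCnext;       // H x N
  vec yhat;
  void resize(uword H, uword N, uword T) {
    I.set_size(H, N, T); F.set_size(H, N, T); G.set_size(H, N, T);
    O.set_size(H, N, T); C.set_size(H, N, T); TC.set_size(H, N, T);
    HS.set_size(H, N, T);
    Z.set_size(4 * H, N); dz.set_size(4 * H, N);
    zeros_HN.zeros(H, N);
    U.set_size(H, N); dH.set_size(H, N); dC.set_size(H, N);
    dCnext.set_size(H, N);
    yhat.set_size(N);
  }
};

// X is (window x n_samples); each column is one sample's input sequence.
void forward_pass(const Packed& p, const mat& X, int activation, Workspace& w) {
  const uword T = X.n_rows, N = X.n_cols, H = p.H;
  for (uword t = 0; t < T; ++t) {
    const mat& hprev = (t > 0) ? w.HS.slice(t - 1) : w.zeros_HN;
    const mat& cprev = (t > 0) ? w.C.slice(t - 1) : w.zeros_HN;
    w.Z = p.Wh * hprev;
    w.Z += p.Wx * X.row(t);
    w.Z.each_col() += p.b;
    w.I.slice(t) = 1.0 / (1.0 + exp(-(w.Z.rows(0, H - 1) + cprev.each_col() % p.pci)));
    w.F.slice(t) = 1.0 / (1.0 + exp(-(w.Z.rows(H, 2 * H - 1) + cprev.each_col() % p.pcf)));
    w.G.slice(t) = fast_tanh(w.Z.rows(2 * H, 3 * H - 1));
    w.C.slice(t) = w.F.slice(t) % cprev + w.I.slice(t) % w.G.slice(t);
    w.O.slice(t) = 1.0 / (1.0 + exp(-(w.Z.rows(3 * H, 4 * H - 1) +
                                      w.C.slice(t).each_col() % p.pco)));
    w.TC.slice(t) = fast_tanh(w.C.slice(t));
    w.HS.slice(t) = w.O.slice(t) % w.TC.slice(t);
  }
  const mat& hT = w.HS.slice(T - 1);
  switch (activation) {
    case 0: w.U = hT; break;                         // linear
    case 1: w.U = 1.0 / (1.0 + exp(-hT)); break;     // sigmoid
    case 2: w.U = clamp(hT, 0.0, datum::inf); break; // relu
    default: w.U = fast_tanh(hT); break;             // tanh
  }
  w.yhat = w.U.t() * p.wy + p.by;
}

double weight_penalty(const Packed& p, double l2) {
  if (l2 <= 0) return 0.0;
  return l2 * (accu(square(p.Wx)) + accu(square(p.Wh)) + accu(square(p.pci)) +
               accu(square(p.pcf)) + accu(square(p.pco)) + accu(square(p.wy)));
}

// Gradient container mirrors Packed.
struct Grads {
  mat Wx, Wh;
  vec pci, pcf, pco, b, wy;
  double by;
  void zero(uword H, uword N) {
    (void)N;
    Wx.zeros(4 * H, 1); Wh.zeros(4 * H, H);
    pci.zeros(H); pcf.zeros(H); pco.zeros(H);
    b.zeros(4 * H); wy.zeros(H); by = 0.0;
  }
};

double loss_grad(const Packed& p, const mat& X, const vec& y, double l2,
                 int activation, Workspace& w, Grads& g) {
  const uword T = X.n_rows, N = X.n_cols, H = p.H;
  forward_pass(p, X, activation, w);
  double loss = accu(square(w.yhat - y)) / double(N) + weight_penalty(p, l2);
  g.zero(H, N);

  vec dyhat = 2.0 * (w.yhat - y) / double(N);
  g.wy = w.U * dyhat;
  g.by = accu(dyhat);
  w.dH = p.wy * dyhat.t();
  const mat& hT = w.HS.slice(T - 1);
  switch (activation) {
    case 0: break;
    case 1: w.dH %= w.U % (1.0 - w.U); break;
    case 2: w.dH %= conv_to<mat>::from(hT > 0.0); break;
    default: w.dH %= 1.0 - w.U % w.U; break;
  }
  w.dC.zeros();

  for (int t = int(T) - 1; t >= 0; --t) {
    const mat& I = w.I.slice(t);
    const mat& F = w.F.slice(t);
    const mat& G = w.G.slice(t);
    const mat& O = w.O.slice(t);
    const mat& Ct = w.C.slice(t);
    const mat& TC = w.TC.slice(t);
    const mat& cprev = (t > 0) ? w.C.slice(t - 1) : w.zeros_HN;
    const mat& hprev = (t > 0) ? w.HS.slice(t - 1) : w.zeros_HN;

    // output gate first: it sees the *current* cell state
    w.dz.rows(3 * H, 4 * H - 1) = (w.dH % TC) % O % (1.0 - O);
    w.dC += w.dH % O % (1.0 - TC % TC) +
            w.dz.rows(3 * H, 4 * H - 1).each_col() % p.pco;
    w.dz.rows(0, H - 1) = (w.dC % G) % I % (1.0 - I);
    w.dz.rows(H, 2 * H - 1) = (w.dC % cprev) % F % (1.0 - F);
    w.dz.rows(2 * H, 3 * H - 1) = (w.dC % I) % (1.0 - G % G);

    g.Wx += w.dz * X.row(t).t();
    g.Wh += w.dz * hprev.t();
    g.b += sum(w.dz, 1);
    g.pci += sum(w.dz.rows(0, H - 1) % cprev, 1);
    g.pcf += sum(w.dz.rows(H, 2 * H - 1) % cprev, 1);
    g.pco += sum(w.dz.rows(3 * H, 4 * H - 1) % Ct, 1);

    w.dCnext = w.dC % F + w.dz.rows(0, H - 1).each_col() % p.pci +
               w.dz.rows(H, 2 * H - 1).each_col() % p.pcf;
    w.dH = p.Wh.t() * w.dz;
    w.dC = w.dCnext;
  }
  if (l2 > 0) {
    g.Wx += 2.0 * l2 * p.Wx;   g.Wh += 2.0 * l2 * p.Wh;
    g.pci += 2.0 * l2 * p.pci; g.pcf += 2.0 * l2 * p.pcf;
    g.pco += 2.0 * l2 * p.pco; g.wy += 2.0 * l2 * p.wy;
  }
  return loss;
}

}  // namespace

// [[Rcpp::export]]
arma::vec lstm_forward_cpp(Rcpp::List params, arma::mat X, int activation) {
  if (X.n_cols == 0) return vec();
  Packed p = pack_params(params);
  Workspace w;
  w.resize(p.H, X.n_cols, X.n_rows);
  forward_pass(p, X, activation, w);
  return w.yhat;
}

// [[Rcpp::export]]
Rcpp::List lstm_loss_grad_cpp(Rcpp::List params, arma::mat X, arma::vec y,
                              double l2, int activation) {
  Packed p = pack_params(params);
  Workspace w;
  w.resize(p.H, X.n_cols, X.n_rows);
  Grads g;
  double loss = loss_grad(p, X, y, l2, activation, w, g);
  Packed gp = p;
  gp.Wx = g.Wx; gp.Wh = g.Wh; gp.pci = g.pci; gp.pcf = g.pcf; gp.pco = g.pco;
  gp.b = g.b; gp.wy = g.wy; gp.by = g.by;
  return Rcpp::List::create(Rcpp::Named("loss") = loss,
                            Rcpp::Named("gradients") = unpack_params(gp));
}

// [[Rcpp::export]]
Rcpp::List lstm_train_cpp(Rcpp::List params0, arma::mat X, arma::vec y,
                          int epochs, double lr, double l2, int activation) {
  Packed p = pack_params(params0);
  Workspace w;
  w.resize(p.H, X.n_cols, X.n_rows);
  Grads g;

  // Adam state over the packed parameter blocks.
  std::vector<mat*> blocks;
  Grads gm, gv;
  gm.zero(p.H, X.n_cols);
  gv.zero(p.H, X.n_cols);
  const double b1 = 0.9, b2 = 0.999, eps = 1e-8;

  auto adam_update = [&](mat& theta, mat& mstate, mat& vstate, const mat& grad,
                         double c1, double c2) {
    mstate = b1 * mstate + (1.0 - b1) * grad;
    vstate = b2 * vstate + (1.0 - b2) * square(grad);
    theta -= lr * (mstate / c1) / (sqrt(vstate / c2) + eps);
  };
  auto adam_update_vec = [&](vec& theta, vec& mstate, vec& vstate,
                             const vec& grad, double c1, double c2) {
    mstate = b1 * mstate + (1.0 - b1) * grad;
    vstate = b2 * vstate + (1.0 - b2) * square(grad);
    theta -= lr * (mstate / c1) / (sqrt(vstate / c2) + eps);
  };

  double m_by = 0.0, v_by = 0.0;
  vec history(epochs, fill::zeros);
  for (int e = 0; e < epochs; ++e) {
    double loss = loss_grad(p, X, y, l2, activation, w, g);
    if (!std::isfinite(loss)) {
      Rcpp::stop("Training diverged: non-finite loss at epoch %d "
                 "(learning rate too high?)", e + 1);
    }
    history(e) = loss;
    double c1 = 1.0 - std::pow(b1, e + 1), c2 = 1.0 - std::pow(b2, e + 1);
    adam_update(p.Wx, gm.Wx, gv.Wx, g.Wx, c1, c2);
    adam_update(p.Wh, gm.Wh, gv.Wh, g.Wh, c1, c2);
    adam_update_vec(p.pci, gm.pci, gv.pci, g.pci, c1, c2);
    adam_update_vec(p.pcf, gm.pcf, gv.pcf, g.pcf, c1, c2);
    adam_update_vec(p.pco, gm.pco, gv.pco, g.pco, c1, c2);
    adam_update_vec(p.b, gm.b, gv.b, g.b, c1, c2);
    adam_update_vec(p.wy, gm.wy, gv.wy, g.wy, c1, c2);
    m_by = b1 * m_by + (1.0 - b1) * g.by;
    v_by = b2 * v_by + (1.0 - b2) * g.by * g.by;
    p.by -= lr * (m_by / c1) / (std::sqrt(v_by / c2) + eps);
  }
  forward_pass(p, X, activation, w);
  double final_loss = accu(square(w.yhat - y)) / double(X.n_cols) +
                      weight_penalty(p, l2);
  return Rcpp::List::create(Rcpp::Named("params") = unpack_params(p),
                            Rcpp::Named("loss_history") = history,
                            Rcpp::Named("final_loss") = final_loss);
}
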