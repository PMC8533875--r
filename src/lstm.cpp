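// Shallow LSTM binary classifier: forward pass, backpropagation through
// time, and Adam updates. Sequences are feature matrices (D rows x T
// frames) consumed frame by frame; the last hidden state feeds a dense
// layer with a 2-unit softmax head ({No, Yes}).
//
// All stochastic choices (weight init, shuffle order) are made on the R
// side and passed in, so results are a pure function of the inputs.
#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]

using namespace arma;

static inline mat sigm(const mat& x) { return 1.0 / (1.0 + exp(-x)); }

// gate row blocks within the stacked 4H weight matrices: i, f, g, o
struct Gates {
  mat i, f, g, o;
};

// forward one sequence, recording activations for BPTT
static void forward_seq(const mat& Wx, const mat& Wh, const vec& b,
                        const mat& x, mat& I, mat& F, mat& G, mat& O,
                        mat& C, mat& Ht) {
  const uword H = Wh.n_cols, T = x.n_cols;
  vec h(H, fill::zeros), c(H, fill::zeros);
  for (uword t = 0; t < T; ++t) {
    vec z = Wx * x.col(t) + Wh * h + b;
    vec i = 1.0 / (1.0 + exp(-z.subvec(0, H - 1)));
    vec f = 1.0 / (1.0 + exp(-z.subvec(H, 2 * H - 1)));
    vec g = tanh(z.subvec(2 * H, 3 * H - 1));
    vec o = 1.0 / (1.0 + exp(-z.subvec(3 * H, 4 * H - 1)));
    c = f % c + i % g;
    h = o % tanh(c);
    I.col(t) = i; F.col(t) = f; G.col(t) = g; O.col(t) = o;
    C.col(t) = c; Ht.col(t) = h;
  }
}

static vec softmax2(const vec& z) {
  vec s = z - z.max();
  vec e = exp(s);
  return e / accu(e);
}

// [[Rcpp::export]]
arma::mat lstm_prob_cpp(const arma::cube& X, const Rcpp::List& w) {
  mat Wx = w["Wx"], Wh = w["Wh"], Wd = w["Wd"];
  vec b = w["b"], bd = w["bd"];
  const uword H = Wh.n_cols, T = X.n_cols, n = X.n_slices;
  mat out(n, 2);
  mat I(H, T), F(H, T), G(H, T), O(H, T), C(H, T), Ht(H, T);
  for (uword s = 0; s < n; ++s) {
    forward_seq(Wx, Wh, b, X.slice(s), I, F, G, O, C, Ht);
    out.row(s) = softmax2(Wd * Ht.col(T - 1) + bd).t();
  }
  return out;
}

struct Adam {
  mat m, v;
  Adam(uword r, uword c) : m(r, c, fill::zeros), v(r, c, fill::zeros) {}
  void step(mat& w, const mat& g, double lr, double t) {
    m = 0.9 * m + 0.1 * g;
    v = 0.999 * v + 0.001 * (g % g);
    mat mh = m / (1.0 - std::pow(0.9, t));
    mat vh = v / (1.0 - std::pow(0.999, t));
    w -= lr * mh / (sqrt(vh) + 1e-8);
  }
};

// [[Rcpp::export]]
Rcpp::List lstm_train_cpp(const arma::cube& X, const arma::ivec& y,
                          const Rcpp::List& w0, int epochs, int batch,
                          double lr, const arma::imat& order) {
  mat Wx = Rcpp::as<mat>(w0["Wx"]), Wh = Rcpp::as<mat>(w0["Wh"]);
  mat Wd = Rcpp::as<mat>(w0["Wd"]);
  vec b = Rcpp::as<vec>(w0["b"]), bd = Rcpp::as<vec>(w0["bd"]);
  const uword H = Wh.n_cols, D = Wx.n_cols, T = X.n_cols, n = X.n_slices;

  Adam aWx(4 * H, D), aWh(4 * H, H), ab(4 * H, 1), aWd(2, H), abd(2, 1);
  double tstep = 0.0;

  mat I(H, T), F(H, T), G(H, T), O(H, T), C(H, T), Ht(H, T);

  for (int ep = 0; ep < epochs; ++ep) {
    for (uword start = 0; start < n; start += batch) {
      const uword stop = std::min<uword>(start + batch, n);
      mat gWx(4 * H, D, fill::zeros), gWh(4 * H, H, fill::zeros);
      vec gb(4 * H, fill::zeros);
      mat gWd(2, H, fill::zeros);
      vec gbd(2, fill::zeros);

      for (uword k = start; k < stop; ++k) {
        const uword s = (uword)order(ep, k);  // 0-based sample index
        const mat& x = X.slice(s);
        forward_seq(Wx, Wh, b, x, I, F, G, O, C, Ht);

        vec p = softmax2(Wd * Ht.col(T - 1) + bd);
        vec target(2, fill::zeros);
        target((uword)y(s)) = 1.0;
        vec dz = p - target;  // dL/dlogits, cross-entropy + softmax

        gWd += dz * Ht.col(T - 1).t();
        gbd += dz;

        vec dh = Wd.t() * dz;
        vec dc(H, fill::zeros);
        for (sword t = T - 1; t >= 0; --t) {
          vec cc = C.col(t);
          vec tc = tanh(cc);
          vec o = O.col(t), i = I.col(t), f = F.col(t), g = G.col(t);
          vec do_ = dh % tc % o % (1.0 - o);
          dc += dh % o % (1.0 - tc % tc);
          vec di = dc % g % i % (1.0 - i);
          vec dg = dc % i % (1.0 - g % g);
          vec cprev = (t > 0) ? vec(C.col(t - 1)) : vec(H, fill::zeros);
          vec df = dc % cprev % f % (1.0 - f);
          vec dgates = join_cols(join_cols(di, df), join_cols(dg, do_));
          gWx += dgates * x.col(t).t();
          if (t > 0) gWh += dgates * Ht.col(t - 1).t();
          gb += dgates;
          dh = Wh.t() * dgates;
          dc = dc % f;
        }
      }

      const double bs = (double)(stop - start);
      tstep += 1.0;
      aWx.step(Wx, gWx / bs, lr, tstep);
      aWh.step(Wh, gWh / bs, lr, tstep);
      mat bM(b.memptr(), 4 * H, 1, false);
      ab.step(bM, gb / bs, lr, tstep);
      aWd.step(Wd, gWd / bs, lr, tstep);
      mat bdM(bd.memptr(), 2, 1, false);
      abd.step(bdM, gbd / bs, lr, tstep);
    }
  }

  return Rcpp::List::create(
      Rcpp::Named("Wx") = Wx, Rcpp::Named("Wh") = Wh,
      Rcpp::Named("b") = b, Rcpp::Named("Wd") = Wd,
      Rcpp::Named("bd") = bd);
}
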