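// Compiled engine for the relative-attention transformer backbone.
// Mirrors the pure-R reference implementation (R/nn.R) exactly; the two
// are cross-checked in the test suite.
// [[Rcpp::depends(RcppArmadillo)]]
#include <RcppArmadillo.h>
using namespace Rcpp;

static const double LN_EPS = 1e-5;

struct LayerP {
  arma::mat Wq, Wk, Wv, Wr, Wo, W1, W2;
  arma::vec u, v, bo, g1, b1, b1f, b2f, g2, b2;
};

static LayerP getLayer(const List& params, int l) {
  std::string pre = "L" + std::to_string(l) + ".";
  LayerP p;
  p.Wq = as<arma::mat>(params[pre + "Wq"]);
  p.Wk = as<arma::mat>(params[pre + "Wk"]);
  p.Wv = as<arma::mat>(params[pre + "Wv"]);
  p.Wr = as<arma::mat>(params[pre + "Wr"]);
  p.Wo = as<arma::mat>(params[pre + "Wo"]);
  p.W1 = as<arma::mat>(params[pre + "W1"]);
  p.W2 = as<arma::mat>(params[pre + "W2"]);
  p.u = as<arma::vec>(params[pre + "u"]);
  p.v = as<arma::vec>(params[pre + "v"]);
  p.bo = as<arma::vec>(params[pre + "bo"]);
  p.g1 = as<arma::vec>(params[pre + "g1"]);
  p.b1 = as<arma::vec>(params[pre + "b1"]);
  p.b1f = as<arma::vec>(params[pre + "b1f"]);
  p.b2f = as<arma::vec>(params[pre + "b2f"]);
  p.g2 = as<arma::vec>(params[pre + "g2"]);
  p.b2 = as<arma::vec>(params[pre + "b2"]);
  return p;
}

// row-wise layer normalization; keeps xhat and inv for backprop
static void lnFwd(const arma::mat& S, const arma::vec& g, const arma::vec& b,
                  arma::mat& out, arma::mat& xhat, arma::vec& inv) {
  arma::vec mu = arma::mean(S, 1);
  arma::mat Xc = S.each_col() - mu;
  arma::vec var = arma::mean(arma::square(Xc), 1);
  inv = 1.0 / arma::sqrt(var + LN_EPS);
  xhat = Xc.each_col() % inv;
  out = (xhat.each_row() % g.t());
  out.each_row() += b.t();
}

static void lnBwd(const arma::mat& dY, const arma::mat& xhat,
                  const arma::vec& inv, const arma::vec& g,
                  arma::mat& dS, arma::vec& dg, arma::vec& db) {
  const double D = (double)dY.n_cols;
  arma::mat dxhat = dY.each_row() % g.t();
  arma::vec t1 = arma::sum(dxhat, 1);
  arma::vec t2 = arma::sum(dxhat % xhat, 1);
  arma::mat tmp = xhat.each_col() % t2;
  tmp.each_col() += t1;
  dS = (dxhat - tmp / D);
  dS.each_col() %= inv;
  dg = arma::sum(dY % xhat, 0).t();
  db = arma::sum(dY, 0).t();
}

static void softmaxRows(arma::mat& E) {
  arma::vec m = arma::max(E, 1);
  E.each_col() -= m;
  E = arma::exp(E);
  arma::vec s = arma::sum(E, 1);
  E.each_col() /= s;
}

// forward intermediates kept on the C++ side between the forward and
// backward calls (avoids copying large attention matrices through R)
struct LayerCache {
  arma::mat Xin, Q, KE, V, KR, O, X1, Hpre, Hf, xhat1, xhat2;
  arma::vec inv1, inv2;
  std::vector<arma::mat> A;
};
struct FwdCache {
  std::vector<LayerCache> layers;
};

// Forward pass over one sequence. X0: n x D input embeddings; Rrel:
// (2n-1) x D sinusoidal relative encodings. Returns the backbone output
// and, when wantCache, an external pointer to the intermediates.
// [[Rcpp::export]]
List cpp_tf_forward(List params, int nLayers, int nHeads,
                    const arma::mat& X0, const arma::mat& Rrel,
                    bool wantCache) {
  const int n = X0.n_rows, D = X0.n_cols, dh = D / nHeads;
  const double scale = 1.0 / std::sqrt((double)dh);
  arma::mat X = X0;
  FwdCache* cache = wantCache ? new FwdCache() : nullptr;
  if (cache) cache->layers.resize(nLayers);
  for (int l = 1; l <= nLayers; ++l) {
    LayerP P = getLayer(params, l);
    arma::mat Xin = X;
    arma::mat Q = X * P.Wq, KE = X * P.Wk, V = X * P.Wv;
    arma::mat KR = Rrel * P.Wr;
    arma::mat O(n, D);
    std::vector<arma::mat> Alist(nHeads);
    for (int h = 0; h < nHeads; ++h) {
      int c0 = h * dh, c1 = c0 + dh - 1;
      arma::mat Qh = Q.cols(c0, c1);
      arma::mat ACu = Qh; ACu.each_row() += P.u.subvec(c0, c1).t();
      arma::mat Qv = Qh; Qv.each_row() += P.v.subvec(c0, c1).t();
      arma::mat E = ACu * KE.cols(c0, c1).t();
      arma::mat BDfull = Qv * KR.cols(c0, c1).t();
      for (int j = 0; j < n; ++j)
        for (int i = 0; i < n; ++i)
          E(i, j) += BDfull(i, n - 1 + i - j);
      E *= scale;
      softmaxRows(E);
      O.cols(c0, c1) = E * V.cols(c0, c1);
      Alist[h] = std::move(E);
    }
    arma::mat attnOut = O * P.Wo;
    attnOut.each_row() += P.bo.t();
    arma::mat X1, xhat1; arma::vec inv1;
    lnFwd(Xin + attnOut, P.g1, P.b1, X1, xhat1, inv1);
    arma::mat Hpre = X1 * P.W1;
    Hpre.each_row() += P.b1f.t();
    arma::mat Hf = arma::clamp(Hpre, 0.0, arma::datum::inf);
    arma::mat F2 = Hf * P.W2;
    F2.each_row() += P.b2f.t();
    arma::mat X2, xhat2; arma::vec inv2;
    lnFwd(X1 + F2, P.g2, P.b2, X2, xhat2, inv2);
    if (cache) {
      LayerCache& cc = cache->layers[l - 1];
      cc.Xin = std::move(Xin); cc.Q = std::move(Q); cc.KE = std::move(KE);
      cc.V = std::move(V); cc.KR = std::move(KR); cc.O = std::move(O);
      cc.X1 = X1; cc.Hpre = std::move(Hpre); cc.Hf = std::move(Hf);
      cc.xhat1 = std::move(xhat1); cc.xhat2 = std::move(xhat2);
      cc.inv1 = std::move(inv1); cc.inv2 = std::move(inv2);
      cc.A = std::move(Alist);
    }
    X = std::move(X2);
  }
  List out = List::create(_["out"] = X);
  if (cache)
    out["cache"] = XPtr<FwdCache>(cache, true);
  return out;
}

// Backward pass matching cpp_tf_forward. dOut: gradient wrt the
// backbone output. Returns per-layer parameter gradients plus dX0.
// [[Rcpp::export]]
List cpp_tf_backward(List params, int nLayers, int nHeads, SEXP cachePtr,
                     const arma::mat& dOut, const arma::mat& Rrel) {
  XPtr<FwdCache> cache(cachePtr);
  const int D = dOut.n_cols, dh = D / nHeads;
  const double scale = 1.0 / std::sqrt((double)dh);
  arma::mat dX = dOut;
  List grads;
  for (int l = nLayers; l >= 1; --l) {
    LayerP P = getLayer(params, l);
    LayerCache& cc = cache->layers[l - 1];
    const int n = cc.Xin.n_rows;

    arma::mat dS2; arma::vec dg2, db2;
    lnBwd(dX, cc.xhat2, cc.inv2, P.g2, dS2, dg2, db2);
    arma::mat dX1 = dS2;
    arma::mat dW2 = cc.Hf.t() * dS2;
    arma::vec db2f = arma::sum(dS2, 0).t();
    arma::mat dHf = dS2 * P.W2.t();
    arma::mat dHpre = dHf % arma::conv_to<arma::mat>::from(cc.Hpre > 0);
    arma::mat dW1 = cc.X1.t() * dHpre;
    arma::vec db1f = arma::sum(dHpre, 0).t();
    dX1 += dHpre * P.W1.t();
    arma::mat dS1; arma::vec dg1, db1;
    lnBwd(dX1, cc.xhat1, cc.inv1, P.g1, dS1, dg1, db1);
    arma::mat dWo = cc.O.t() * dS1;
    arma::vec dbo = arma::sum(dS1, 0).t();
    arma::mat dO = dS1 * P.Wo.t();

    arma::mat dQ(n, D, arma::fill::zeros), dKE(n, D, arma::fill::zeros),
      dV(n, D, arma::fill::zeros), dKR(2 * n - 1, D, arma::fill::zeros);
    arma::vec du(D, arma::fill::zeros), dv(D, arma::fill::zeros);
    for (int h = 0; h < nHeads; ++h) {
      int c0 = h * dh, c1 = c0 + dh - 1;
      const arma::mat& A = cc.A[h];
      arma::mat Vh = cc.V.cols(c0, c1);
      arma::mat dOh = dO.cols(c0, c1);
      arma::mat dA = dOh * Vh.t();
      dV.cols(c0, c1) = A.t() * dOh;
      arma::vec rs = arma::sum(dA % A, 1);
      arma::mat dZ = A % (dA.each_col() - rs);
      dZ *= scale;
      arma::mat KEh = cc.KE.cols(c0, c1), KRh = cc.KR.cols(c0, c1);
      arma::mat Qh = cc.Q.cols(c0, c1);
      arma::mat ACu = Qh; ACu.each_row() += P.u.subvec(c0, c1).t();
      arma::mat Qv = Qh; Qv.each_row() += P.v.subvec(c0, c1).t();
      arma::mat G1 = dZ * KEh;
      dKE.cols(c0, c1) = dZ.t() * ACu;
      arma::mat dBDfull(n, 2 * n - 1, arma::fill::zeros);
      for (int j = 0; j < n; ++j)
        for (int i = 0; i < n; ++i)
          dBDfull(i, n - 1 + i - j) += dZ(i, j);
      arma::mat G2 = dBDfull * KRh;
      dKR.cols(c0, c1) += dBDfull.t() * Qv;
      dQ.cols(c0, c1) = G1 + G2;
      du.subvec(c0, c1) = arma::sum(G1, 0).t();
      dv.subvec(c0, c1) = arma::sum(G2, 0).t();
    }
    std::string pre = "L" + std::to_string(l) + ".";
    grads.push_back(wrap(arma::mat(cc.Xin.t() * dQ)), pre + "Wq");
    grads.push_back(wrap(arma::mat(cc.Xin.t() * dKE)), pre + "Wk");
    grads.push_back(wrap(arma::mat(cc.Xin.t() * dV)), pre + "Wv");
    grads.push_back(wrap(arma::mat(Rrel.t() * dKR)), pre + "Wr");
    grads.push_back(wrap(du), pre + "u");
    grads.push_back(wrap(dv), pre + "v");
    grads.push_back(wrap(dWo), pre + "Wo");
    grads.push_back(wrap(dbo), pre + "bo");
    grads.push_back(wrap(dg1), pre + "g1");
    grads.push_back(wrap(db1), pre + "b1");
    grads.push_back(wrap(dW1), pre + "W1");
    grads.push_back(wrap(db1f), pre + "b1f");
    grads.push_back(wrap(dW2), pre + "W2");
    grads.push_back(wrap(db2f), pre + "b2f");
    grads.push_back(wrap(dg2), pre + "g2");
    grads.push_back(wrap(db2), pre + "b2");
    dX = dS1 + dQ * P.Wq.t() + dKE * P.Wk.t() + dV * P.Wv.t();
  }
  grads.push_back(wrap(dX), "dX0");
  return grads;
}

// Batched inference over B equal-length windows. X0: (B*w) x D stacked
// input embeddings, window-major rows. Rrel: (2w-1) x D. When
// onlyRow >= 0, the final layer is evaluated only at that window
// position and the result is B x D (one row per window); otherwise
// (B*w) x D.
// [[Rcpp::export]]
arma::mat cpp_tf_forward_batch(List params, int nLayers, int nHeads,
                               const arma::mat& X0, const arma::mat& Rrel,
                               int w, int onlyRow) {
  const int D = X0.n_cols, dh = D / nHeads;
  const int B = X0.n_rows / w;
  const double scale = 1.0 / std::sqrt((double)dh);
  arma::mat X = X0;
  std::vector<double> qu(w * dh), qv(w * dh), keb(w * dh), vb(w * dh),
    krb((2 * w - 1) * dh), eb(w * w), ob(w * dh);
  for (int l = 1; l <= nLayers; ++l) {
    const bool last = (l == nLayers) && onlyRow >= 0;
    LayerP P = getLayer(params, l);
    arma::mat Xin;
    if (last) {
      // residual stream restricted to the scored row of each window
      Xin.set_size(B, D);
      for (int b = 0; b < B; ++b) Xin.row(b) = X.row(b * w + onlyRow);
    } else Xin = X;
    arma::mat Q = X * P.Wq, KE = X * P.Wk, V = X * P.Wv;
    arma::mat KR = Rrel * P.Wr;
    const int outRows = last ? B : B * w;
    arma::mat O(outRows, D);
    const int i0 = last ? onlyRow : 0, i1 = last ? onlyRow + 1 : w;
    for (int h = 0; h < nHeads; ++h) {
      const int c0 = h * dh;
      const double* up = P.u.memptr() + c0;
      const double* vp = P.v.memptr() + c0;
      // head slice of the shared relative-key matrix, local layout
      for (int r = 0; r < 2 * w - 1; ++r)
        for (int d = 0; d < dh; ++d)
          krb[r * dh + d] = KR(r, c0 + d);
      for (int b = 0; b < B; ++b) {
        const int r0 = b * w;
        for (int i = 0; i < w; ++i)
          for (int d = 0; d < dh; ++d) {
            const double q = Q(r0 + i, c0 + d);
            qu[i * dh + d] = q + up[d];
            qv[i * dh + d] = q + vp[d];
            keb[i * dh + d] = KE(r0 + i, c0 + d);
            vb[i * dh + d] = V(r0 + i, c0 + d);
          }
        for (int i = i0; i < i1; ++i) {
          double* erow = &eb[i * w];
          double mx = -INFINITY;
          for (int j = 0; j < w; ++j) {
            double ac = 0, bd = 0;
            const double* qup = &qu[i * dh];
            const double* qvp = &qv[i * dh];
            const double* kep = &keb[j * dh];
            const double* krp = &krb[(w - 1 + i - j) * dh];
            for (int d = 0; d < dh; ++d) {
              ac += qup[d] * kep[d];
              bd += qvp[d] * krp[d];
            }
            erow[j] = (ac + bd) * scale;
            if (erow[j] > mx) mx = erow[j];
          }
          double Z = 0;
          for (int j = 0; j < w; ++j) { erow[j] = std::exp(erow[j] - mx); Z += erow[j]; }
          double* orow = &ob[i * dh];
          for (int d = 0; d < dh; ++d) orow[d] = 0;
          for (int j = 0; j < w; ++j) {
            const double a = erow[j] / Z;
            const double* vrow = &vb[j * dh];
            for (int d = 0; d < dh; ++d) orow[d] += a * vrow[d];
          }
          const int outR = last ? b : r0 + i;
          for (int d = 0; d < dh; ++d) O(outR, c0 + d) = ob[i * dh + d];
        }
      }
    }
    arma::mat attnOut = O * P.Wo;
    attnOut.each_row() += P.bo.t();
    arma::mat X1, xhat1; arma::vec inv1;
    lnFwd(Xin + attnOut, P.g1, P.b1, X1, xhat1, inv1);
    arma::mat Hpre = X1 * P.W1;
    Hpre.each_row() += P.b1f.t();
    arma::mat Hf = arma::clamp(Hpre, 0.0, arma::datum::inf);
    arma::mat F2 = Hf * P.W2;
    F2.each_row() += P.b2f.t();
    arma::mat X2, xhat2; arma::vec inv2;
    lnFwd(X1 + F2, P.g2, P.b2, X2, xhat2, inv2);
    X = std::move(X2);
  }
  return X;
}
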