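// Compiled training kernels for the two small neural detectors. The whole
// forward + backward pass of each network runs here in float32 (the
// arithmetic the embedded targets use), with parameters and gradients
// exchanged with R in double precision. Layouts match the R side:
// activation cubes are (batch, time, maps) for the CNN and (batch, channel,
// time) for the LSTM; matrix views are time-major with batch fastest.

#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]

using namespace arma;

static fmat toF(const mat& x) { return conv_to<fmat>::from(x); }
static fvec toFv(const vec& x) { return conv_to<fvec>::from(x); }
static mat toD(const fmat& x) { return conv_to<mat>::from(x); }
static vec toDv(const fvec& x) { return conv_to<vec>::from(x); }

// im2col over the time axis: A (B, T, M), kernel K -> (B*J) x (K*M)
static fmat im2col_time(const fcube& A, const int K) {
  const int B = A.n_rows, T = A.n_cols, M = A.n_slices;
  const int J = T - K + 1;
  fmat out(B * (size_t)J, K * (size_t)M);
  for (int m = 0; m < M; ++m) {
    for (int k = 0; k < K; ++k) {
      float* dst = out.colptr((size_t)k * M + m);
      for (int j = 0; j < J; ++j) {
        std::memcpy(dst + (size_t)j * B, A.slice(m).colptr(j + k),
                    B * sizeof(float));
      }
    }
  }
  return out;
}

static void col2im_time(const fmat& dM2, fcube& dA, const int K) {
  const int B = dA.n_rows, T = dA.n_cols, M = dA.n_slices;
  const int J = T - K + 1;
  for (int m = 0; m < M; ++m) {
    for (int k = 0; k < K; ++k) {
      const float* src = dM2.colptr((size_t)k * M + m);
      for (int j = 0; j < J; ++j) {
        float* dst = dA.slice(m).colptr(j + k);
        const float* s = src + (size_t)j * B;
        for (int bb = 0; bb < B; ++bb) dst[bb] += s[bb];
      }
    }
  }
}

static fmat dropMask(const size_t n, const size_t m, const double p) {
  Rcpp::NumericVector u = Rcpp::runif((int)(n * m));
  fmat out(n, m);
  const float scale = 1.0f / (1.0f - (float)p);
  for (size_t i = 0; i < n * m; ++i)
    out(i) = (u[i] >= p) ? scale : 0.0f;
  return out;
}

struct ConvCache {
  fmat M2;      // im2col of the layer input
  fmat xhat;    // batch-norm normalized pre-activation
  fmat act;     // post-ReLU activation (pre-pool), (B*J) x F
  fmat drop;    // dropout mask on the pooled output (empty if none)
  fvec va;      // batch variance used
  int J, Jp, K, pool;
};

// One conv -> BN -> ReLU -> pool -> dropout block, float32.
static fcube convBlockFwd(const fcube& A, const fmat& W, const fvec& b,
                          const fvec& gamma, const fvec& beta,
                          fvec& rmean, fvec& rvar, const bool training,
                          const int pool, const double dropout,
                          const float momentum, ConvCache& cc) {
  const int B = A.n_rows, T = A.n_cols, M = A.n_slices;
  const int K = W.n_rows / M;
  const int J = T - K + 1;
  const int F = W.n_cols;
  cc.K = K; cc.J = J; cc.pool = pool;
  cc.M2 = im2col_time(A, K);
  fmat Z = cc.M2 * W;
  Z.each_row() += b.t();
  fvec mu(F), va(F);
  if (training) {
    mu = mean(Z, 0).t();
    va = var(Z, 1, 0).t();
    rmean = momentum * rmean + (1.0f - momentum) * mu;
    rvar = momentum * rvar + (1.0f - momentum) * va;
  } else {
    mu = rmean;
    va = rvar;
  }
  cc.va = va;
  frowvec inv = 1.0f / sqrt(va.t() + 1e-5f);
  Z.each_row() -= mu.t();
  Z.each_row() %= inv;
  cc.xhat = Z;
  Z.each_row() %= gamma.t();
  Z.each_row() += beta.t();
  Z.transform([](float v) { return v > 0.0f ? v : 0.0f; });
  cc.act = Z;
  const int Jp = (pool > 1) ? J / pool : J;
  cc.Jp = Jp;
  fcube Y(B, Jp, F);
  if (pool > 1) {
    for (int f = 0; f < F; ++f) {
      const float* zc = cc.act.colptr(f);
      for (int jp = 0; jp < Jp; ++jp) {
        float* yc = Y.slice(f).colptr(jp);
        const float* s0 = zc + (size_t)jp * pool * B;
        for (int bb = 0; bb < B; ++bb) {
          float mv = s0[bb];
          for (int q = 1; q < pool; ++q) {
            const float v = s0[(size_t)q * B + bb];
            if (v > mv) mv = v;
          }
          yc[bb] = mv;
        }
      }
    }
  } else {
    std::memcpy(Y.memptr(), cc.act.memptr(), cc.act.n_elem * sizeof(float));
  }
  if (training && dropout > 0) {
    cc.drop = dropMask(B * (size_t)Jp, F, dropout);
    fmat Ym((float*)Y.memptr(), B * (size_t)Jp, F, false, true);
    Ym %= cc.drop;
  }
  return Y;
}

// Backward through the block; dY (B*Jp) x F view, returns dA and grads.
static fcube convBlockBwd(const fcube& A, const fmat& W, const fvec& gamma,
                          const ConvCache& cc, fmat dY,
                          fmat& dW, fvec& db, fvec& dgamma, fvec& dbeta,
                          const bool needDA) {
  const int B = A.n_rows, T = A.n_cols, M = A.n_slices;
  const int F = W.n_cols;
  const int J = cc.J, Jp = cc.Jp, pool = cc.pool;
  if (cc.drop.n_elem) dY %= cc.drop;
  fmat dAct(B * (size_t)J, F, fill::zeros);
  if (pool > 1) {
    for (int f = 0; f < F; ++f) {
      const float* zc = cc.act.colptr(f);
      float* dc = dAct.colptr(f);
      const float* dyc = dY.colptr(f);
      for (int jp = 0; jp < Jp; ++jp) {
        const float* s0 = zc + (size_t)jp * pool * B;
        float* d0 = dc + (size_t)jp * pool * B;
        const float* dy = dyc + (size_t)jp * B;
        for (int bb = 0; bb < B; ++bb) {
          int best = 0;
          float bv = s0[bb];
          for (int q = 1; q < pool; ++q) {
            const float v = s0[(size_t)q * B + bb];
            if (v > bv) { bv = v; best = q; }
          }
          d0[(size_t)best * B + bb] = dy[bb];
        }
      }
    }
  } else {
    dAct = dY;
  }
  // ReLU mask from cached activation
  const float* ap = cc.act.memptr();
  float* dp = dAct.memptr();
  for (size_t i = 0; i < cc.act.n_elem; ++i)
    if (ap[i] <= 0.0f) dp[i] = 0.0f;
  // batch-norm backward
  dgamma = sum(dAct % cc.xhat, 0).t();
  dbeta = sum(dAct, 0).t();
  fmat dxhat = dAct;
  dxhat.each_row() %= gamma.t();
  frowvec m1 = mean(dxhat, 0);
  frowvec m2 = mean(dxhat % cc.xhat, 0);
  fmat dZ = dxhat;
  dZ.each_row() -= m1;
  fmat tmp = cc.xhat;
  tmp.each_row() %= m2;
  dZ -= tmp;
  dZ.each_row() %= frowvec(1.0f / sqrt(cc.va.t() + 1e-5f));
  // conv backward (input gradient skipped for the data layer)
  dW = cc.M2.t() * dZ;
  db = sum(dZ, 0).t();
  if (!needDA) return fcube();
  fmat dM2 = dZ * W.t();
  fcube dA(B, T, M, fill::zeros);
  col2im_time(dM2, dA, cc.K);
  return dA;
}

// Full CNN pass: 3 conv blocks + 2 ReLU dense layers + sigmoid output.
// Computes the class-weighted binary cross-entropy and, if wantGrad, all
// parameter gradients. Returns updated batch-norm running stats.
// [[Rcpp::export(name = ".cnnPassCpp")]]
Rcpp::List cnnPassCpp(const arma::cube& X, const arma::vec& y,
                      const arma::vec& w, const Rcpp::List& params,
                      const Rcpp::List& bnState, const bool training,
                      const double dropout, const bool wantGrad) {
  const int B = X.n_rows;
  const int pools[3] = {4, 4, 0};
  fcube A = conv_to<fcube>::from(X);
  std::vector<fmat> Wc(3), Wd(3);
  std::vector<fvec> bc(3), gam(3), bet(3), rm(3), rv(3), bd(3);
  for (int i = 0; i < 3; ++i) {
    Wc[i] = toF(Rcpp::as<mat>(params["W" + std::to_string(i + 1)]));
    bc[i] = toFv(Rcpp::as<vec>(params["b" + std::to_string(i + 1)]));
    gam[i] = toFv(Rcpp::as<vec>(params["gamma" + std::to_string(i + 1)]));
    bet[i] = toFv(Rcpp::as<vec>(params["beta" + std::to_string(i + 1)]));
    Rcpp::List st = bnState[i];
    rm[i] = toFv(Rcpp::as<vec>(st["rmean"]));
    rv[i] = toFv(Rcpp::as<vec>(st["rvar"]));
    Wd[i] = toF(Rcpp::as<mat>(params["Wd" + std::to_string(i + 1)]));
    bd[i] = toFv(Rcpp::as<vec>(params["bd" + std::to_string(i + 1)]));
  }
  std::vector<ConvCache> cc(3);
  std::vector<fcube> Ain(3);
  for (int i = 0; i < 3; ++i) {
    Ain[i] = A;
    A = convBlockFwd(A, Wc[i], bc[i], gam[i], bet[i], rm[i], rv[i],
                     training, pools[i], dropout, 0.9f, cc[i]);
  }
  const int flatN = A.n_cols * A.n_slices;
  fmat flat((float*)A.memptr(), B, flatN, false, true);
  fmat h1 = flat * Wd[0];
  h1.each_row() += bd[0].t();
  fmat r1 = conv_to<fmat>::from(h1 > 0.0f);
  fmat a1 = h1 % r1;
  fmat h2 = a1 * Wd[1];
  h2.each_row() += bd[1].t();
  fmat r2 = conv_to<fmat>::from(h2 > 0.0f);
  fmat a2 = h2 % r2;
  fvec logitsF = a2 * Wd[2].col(0) + bd[2](0);
  vec logits = toDv(logitsF);
  // weighted BCE on logits (double precision)
  vec p = 1.0 / (1.0 + exp(-logits));
  p = clamp(p, 1e-12, 1.0 - 1e-12);
  const double loss =
      -mean(w % (y % log(p) + (1.0 - y) % log(1.0 - p)));
  Rcpp::List bnNew(3);
  for (int i = 0; i < 3; ++i) {
    bnNew[i] = Rcpp::List::create(Rcpp::Named("rmean") = toDv(rm[i]),
                                  Rcpp::Named("rvar") = toDv(rv[i]));
  }
  Rcpp::List out = Rcpp::List::create(
      Rcpp::Named("logits") = logits, Rcpp::Named("loss") = loss,
      Rcpp::Named("bnState") = bnNew);
  if (!wantGrad) return out;

  fvec dlog = toFv(vec(w % (p - y) / (double)B));
  Rcpp::List g;
  g["Wd3"] = toD(a2.t() * dlog);
  g["bd3"] = Rcpp::wrap(accu(dlog));
  fmat da2 = dlog * Wd[2].col(0).t();
  da2 %= r2;
  g["Wd2"] = toD(a1.t() * da2);
  g["bd2"] = toDv(fvec(sum(da2, 0).t()));
  fmat da1 = da2 * Wd[1].t();
  da1 %= r1;
  g["Wd1"] = toD(flat.t() * da1);
  g["bd1"] = toDv(fvec(sum(da1, 0).t()));
  fmat dflat = da1 * Wd[0].t();
  fcube dA(B, A.n_cols, A.n_slices);
  std::memcpy(dA.memptr(), dflat.memptr(), dflat.n_elem * sizeof(float));
  for (int i = 2; i >= 0; --i) {
    fmat dYm((float*)dA.memptr(), (size_t)B * cc[i].Jp, Wc[i].n_cols,
             false, true);
    fmat dW;
    fvec db, dgamma, dbeta;
    dA = convBlockBwd(Ain[i], Wc[i], gam[i], cc[i], dYm,
                      dW, db, dgamma, dbeta, i > 0);
    g["W" + std::to_string(i + 1)] = toD(dW);
    g["b" + std::to_string(i + 1)] = toDv(db);
    g["gamma" + std::to_string(i + 1)] = toDv(dgamma);
    g["beta" + std::to_string(i + 1)] = toDv(dbeta);
  }
  out["grads"] = g;
  return out;
}

static inline fmat sigm(const fmat& x) { return 1.0f / (1.0f + exp(-x)); }

// Full LSTM-network pass: LSTM recurrence over X (B, C, T), per-step
// dropout, the (linear) time-distributed dense + global average pooling
// head folded as meanH * V, and the sigmoid output unit.
// [[Rcpp::export(name = ".rnnPassCpp")]]
Rcpp::List rnnPassCpp(const arma::cube& X, const arma::vec& y,
                      const arma::vec& w, const Rcpp::List& params,
                      const bool training, const double dropout,
                      const bool wantGrad) {
  const int B = X.n_rows, C = X.n_cols, T = X.n_slices;
  fmat W = toF(Rcpp::as<mat>(params["W"]));
  fvec b = toFv(Rcpp::as<vec>(params["b"]));
  fmat V = toF(Rcpp::as<mat>(params["V"]));
  fvec c0 = toFv(Rcpp::as<vec>(params["c0"]));
  fvec wout = toFv(Rcpp::as<mat>(params["wout"]).col(0));
  const float bout = (float)Rcpp::as<double>(params["bout"]);
  const int H = W.n_cols / 4;
  const bool drop = training && dropout > 0;

  fcube Xf = conv_to<fcube>::from(X);
  fmat h(B, H, fill::zeros), c(B, H, fill::zeros), sumH(B, H, fill::zeros);
  fcube gates, cs, hs, tcs, masks;
  if (wantGrad) {
    gates.set_size(B, 4 * H, T);
    cs.set_size(B, H, T);
    hs.set_size(B, H, T);
    tcs.set_size(B, H, T);
  }
  if (drop) masks.set_size(B, H, T);
  fmat xh(B, C + H), z(B, 4 * H), tc(B, H);
  const size_t n = (size_t)B * H;
  for (int t = 0; t < T; ++t) {
    xh.cols(0, C - 1) = Xf.slice(t);
    xh.cols(C, C + H - 1) = h;
    z = xh * W;
    z.each_row() += b.t();
    float* gi = z.colptr(0);
    float* gf = z.colptr(H);
    float* gg = z.colptr(2 * H);
    float* go = z.colptr(3 * H);
    float* cp = c.memptr();
    float* hp = h.memptr();
    float* tp = tc.memptr();
    float* sp = sumH.memptr();
    for (size_t i = 0; i < n; ++i) {
      gi[i] = 1.0f / (1.0f + std::exp(-gi[i]));
      gf[i] = 1.0f / (1.0f + std::exp(-gf[i]));
      gg[i] = std::tanh(gg[i]);
      go[i] = 1.0f / (1.0f + std::exp(-go[i]));
      cp[i] = gf[i] * cp[i] + gi[i] * gg[i];
      tp[i] = std::tanh(cp[i]);
      hp[i] = go[i] * tp[i];
    }
    if (wantGrad) {
      gates.slice(t) = z;
      cs.slice(t) = c;
      hs.slice(t) = h;
      tcs.slice(t) = tc;
    }
    if (drop) {
      masks.slice(t) = dropMask(B, H, dropout);
      const float* mp = masks.slice(t).memptr();
      for (size_t i = 0; i < n; ++i) sp[i] += hp[i] * mp[i];
    } else {
      for (size_t i = 0; i < n; ++i) sp[i] += hp[i];
    }
  }
  fmat meanH = sumH / (float)T;
  fmat pooled = meanH * V;
  pooled.each_row() += c0.t();
  fvec logitsF = pooled * wout + bout;
  vec logits = toDv(logitsF);
  vec p = 1.0 / (1.0 + exp(-logits));
  p = clamp(p, 1e-12, 1.0 - 1e-12);
  const double loss =
      -mean(w % (y % log(p) + (1.0 - y) % log(1.0 - p)));
  Rcpp::List out = Rcpp::List::create(Rcpp::Named("logits") = logits,
                                      Rcpp::Named("loss") = loss);
  if (!wantGrad) return out;

  fvec dlog = toFv(vec(w % (p - y) / (double)B));
  Rcpp::List g;
  g["wout"] = toD(pooled.t() * dlog);
  g["bout"] = Rcpp::wrap((double)accu(dlog));
  fmat dpooled = dlog * wout.t();
  g["V"] = toD(meanH.t() * dpooled);
  g["c0"] = toDv(fvec(sum(dpooled, 0).t()));
  fmat dhOut = (dpooled * V.t()) / (float)T;  // same at every step
  fmat dW(W.n_rows, W.n_cols, fill::zeros);
  fvec db(4 * H, fill::zeros);
  fmat dhNext(B, H, fill::zeros), dcNext(B, H, fill::zeros);
  fmat dz(B, 4 * H), dxh(B, C + H);
  const fmat zeroBH(B, H, fill::zeros);
  const float* doutp = dhOut.memptr();
  for (int t = T - 1; t >= 0; --t) {
    const fmat& gt = gates.slice(t);
    const float* gi = gt.colptr(0);
    const float* gf = gt.colptr(H);
    const float* gg = gt.colptr(2 * H);
    const float* go = gt.colptr(3 * H);
    const float* tp = tcs.slice(t).memptr();
    const float* cPrev = (t > 0) ? cs.slice(t - 1).memptr() : zeroBH.memptr();
    const float* mp = drop ? masks.slice(t).memptr() : nullptr;
    float* dzi = dz.colptr(0);
    float* dzf = dz.colptr(H);
    float* dzg = dz.colptr(2 * H);
    float* dzo = dz.colptr(3 * H);
    float* dhn = dhNext.memptr();
    float* dcn = dcNext.memptr();
    for (size_t i = 0; i < n; ++i) {
      const float dh = dhn[i] + (mp ? doutp[i] * mp[i] : doutp[i]);
      const float dcc = dcn[i] + dh * go[i] * (1.0f - tp[i] * tp[i]);
      dzi[i] = (dcc * gg[i]) * gi[i] * (1.0f - gi[i]);
      dzf[i] = (dcc * cPrev[i]) * gf[i] * (1.0f - gf[i]);
      dzg[i] = (dcc * gi[i]) * (1.0f - gg[i] * gg[i]);
      dzo[i] = (dh * tp[i]) * go[i] * (1.0f - go[i]);
      dcn[i] = dcc * gf[i];
    }
    xh.cols(0, C - 1) = Xf.slice(t);
    xh.cols(C, C + H - 1) = (t > 0) ? hs.slice(t - 1) : zeroBH;
    dW += xh.t() * dz;
    db += sum(dz, 0).t();
    dxh = dz * W.t();
    dhNext = dxh.cols(C, C + H - 1);
  }
  g["W"] = toD(dW);
  g["b"] = toDv(db);
  out["grads"] = g;
  return out;
}
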