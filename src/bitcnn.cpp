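// BIT-CNN core: forward pass, back-propagation and Grad-CAM gradient
// capture for the beat-interval-texture CNN, written directly against
// Armadillo (im2col + GEMM convolutions).  Layout conventions:
//   feature maps: arma::cube (H x W x C), one cube per sample
//   im2col:       (H*W) x (kh*kw*Cin), column j = c*kh*kw + dx*kh + dy
//   conv weights: (kh*kw*Cin) x Cout ; dense weights: (in) x (out)
// Batch norm uses eps 1e-3 and running-stat momentum 0.9; pooling uses
// stride = window with ceil semantics (clipped windows, averages over the
// actual element count).
#include <RcppArmadillo.h>
#include <random>
#include <cstring>
#include <cstdio>
// [[Rcpp::depends(RcppArmadillo)]]
using namespace Rcpp;
using arma::cube;
using arma::mat;
using arma::vec;
using arma::uword;

struct Cfg {
  int H, W, K, sa_k, fa_hidden, n_classes;
  arma::ivec lb, hb, obo;
  double dropout;
};

static Cfg parse_cfg(const List& cl) {
  Cfg c;
  c.H = as<int>(cl["height"]);
  c.W = as<int>(cl["width"]);
  c.K = as<int>(cl["K"]);
  c.sa_k = as<int>(cl["spatial_attention_kernel"]);
  c.fa_hidden = as<int>(cl["fa_hidden"]);
  c.n_classes = as<int>(cl["n_classes"]);
  c.lb = as<arma::ivec>(cl["lb_filters"]);
  c.hb = as<arma::ivec>(cl["hb_filters"]);
  c.obo = as<arma::ivec>(cl["one_by_one"]);
  c.dropout = as<double>(cl["dropout_rate"]);
  return c;
}

struct PEntry {
  std::string name;
  int r, c;
  bool trainable;
  int fan_in, fan_out;
  size_t off;
};

// single source of truth for the parameter vector layout
static std::vector<PEntry> make_layout(const Cfg& cfg) {
  std::vector<PEntry> L;
  size_t off = 0;
  auto add = [&](std::string name, int r, int c, bool tr, int fi, int fo) {
    L.push_back({name, r, c, tr, fi, fo, off});
    off += (size_t)r * c;
  };
  int cin = 1;
  for (int b = 0; b < 3; ++b) {
    int f = cfg.lb[b], o = cfg.obo[b], kk = cfg.K * cin;
    char nm[64];
    snprintf(nm, 64, "lb%d", b + 1);
    std::string p(nm);
    add(p + "_conv_w", kk, f, true, kk, cfg.K * f);
    add(p + "_conv_b", f, 1, true, 0, 0);
    add(p + "_bn_gamma", f, 1, true, 0, 0);
    add(p + "_bn_beta", f, 1, true, 0, 0);
    add(p + "_bn_rmean", f, 1, false, 0, 0);
    add(p + "_bn_rvar", f, 1, false, 0, 0);
    add(p + "_one_w", f, o, true, f, o);
    add(p + "_one_b", o, 1, true, 0, 0);
    cin = 2 * o;
  }
  const char* pth[3] = {"b", "i", "t"};
  for (int s = 0; s < 3; ++s) {
    int f = cfg.hb[s], o = cfg.obo[3 + s];
    char nm[64];
    snprintf(nm, 64, "hb%d", s + 4);
    std::string p(nm);
    for (int q = 0; q < 3; ++q) {
      int kh = (q == 0) ? 1 : cfg.K;
      int kw = (q == 1) ? 1 : cfg.K;
      int kk = kh * kw * cin;
      std::string pp = p + "_" + pth[q];
      add(pp + "_conv_w", kk, f, true, kk, kh * kw * f);
      add(pp + "_conv_b", f, 1, true, 0, 0);
      add(pp + "_bn_gamma", f, 1, true, 0, 0);
      add(pp + "_bn_beta", f, 1, true, 0, 0);
      add(pp + "_bn_rmean", f, 1, false, 0, 0);
      add(pp + "_bn_rvar", f, 1, false, 0, 0);
      add(pp + "_one_w", f, o, true, f, o);
      add(pp + "_one_b", o, 1, true, 0, 0);
    }
    add(p + "_sa_w", 2 * cfg.sa_k * cfg.sa_k, 1, true,
        2 * cfg.sa_k * cfg.sa_k, cfg.sa_k * cfg.sa_k);
    cin = 6 * o;
  }
  int C2 = 2 * cin;  // cin is now the HB output channel count
  add("fa_w1", C2, cfg.fa_hidden, true, C2, cfg.fa_hidden);
  add("fa_b1", cfg.fa_hidden, 1, true, 0, 0);
  add("fa_w2", cfg.fa_hidden, C2, true, cfg.fa_hidden, C2);
  add("fa_b2", C2, 1, true, 0, 0);
  add("fc_w", C2, cfg.n_classes, true, C2, cfg.n_classes);
  add("fc_b", cfg.n_classes, 1, true, 0, 0);
  return L;
}

static size_t layout_size(const std::vector<PEntry>& L) {
  const PEntry& e = L.back();
  return e.off + (size_t)e.r * e.c;
}

struct ParView {
  const std::vector<PEntry>* L;
  double* p;
  mat operator()(const std::string& name) const {
    for (const PEntry& e : *L)
      if (e.name == name) return mat(p + e.off, e.r, e.c, false, true);
    stop("unknown parameter: " + name);
    return mat();
  }
};

// ---------------------------------------------------------------- im2col

static void im2col(const cube& A, int kh, int kw, mat& M) {
  int H = A.n_rows, W = A.n_cols, C = A.n_slices;
  int ph = kh / 2, pw = kw / 2;
  M.zeros((size_t)H * W, (size_t)kh * kw * C);
  for (int c = 0; c < C; ++c)
    for (int dx = 0; dx < kw; ++dx)
      for (int dy = 0; dy < kh; ++dy) {
        int j = c * kh * kw + dx * kh + dy;
        int oy = dy - ph, ox = dx - pw;
        int y0 = std::max(0, -oy), y1 = std::min(H, H - oy);
        int x0 = std::max(0, -ox), x1 = std::min(W, W - ox);
        if (y1 <= y0 || x1 <= x0) continue;
        double* Mcol = M.colptr(j);
        for (int x = x0; x < x1; ++x) {
          const double* src = A.slice_colptr(c, x + ox) + (y0 + oy);
          std::memcpy(Mcol + (size_t)x * H + y0, src,
                      (size_t)(y1 - y0) * sizeof(double));
        }
      }
}

static void col2im_acc(const mat& dM, int kh, int kw, cube& dA) {
  int H = dA.n_rows, W = dA.n_cols, C = dA.n_slices;
  int ph = kh / 2, pw = kw / 2;
  for (int c = 0; c < C; ++c)
    for (int dx = 0; dx < kw; ++dx)
      for (int dy = 0; dy < kh; ++dy) {
        int j = c * kh * kw + dx * kh + dy;
        int oy = dy - ph, ox = dx - pw;
        int y0 = std::max(0, -oy), y1 = std::min(H, H - oy);
        int x0 = std::max(0, -ox), x1 = std::min(W, W - ox);
        if (y1 <= y0 || x1 <= x0) continue;
        const double* Mcol = dM.colptr(j);
        for (int x = x0; x < x1; ++x) {
          double* dst = dA.slice_colptr(c, x + ox) + (y0 + oy);
          const double* src = Mcol + (size_t)x * H + y0;
          for (int y = 0; y < y1 - y0; ++y) dst[y] += src[y];
        }
      }
}

static cube conv_same(const cube& A, const mat& W, const vec& b, int kh,
                      int kw) {
  mat M;
  im2col(A, kh, kw, M);
  mat Y = M * W;
  Y.each_row() += b.t();
  return cube(Y.memptr(), A.n_rows, A.n_cols, W.n_cols);
}

// gradient pieces for one conv: accumulates dW, db; returns dA
static cube conv_same_bwd(const cube& A, const mat& W, int kh, int kw,
                          const cube& dY, mat& dW, vec& db) {
  int H = A.n_rows, Wd = A.n_cols;
  mat M;
  im2col(A, kh, kw, M);
  mat dYm(const_cast<double*>(dY.memptr()), (size_t)H * Wd, dY.n_slices,
          false, true);
  dW += M.t() * dYm;
  db += arma::sum(dYm, 0).t();
  mat dM = dYm * W.t();
  cube dA(H, Wd, A.n_slices, arma::fill::zeros);
  col2im_acc(dM, kh, kw, dA);
  return dA;
}

// 1x1 convolution: plain channel mixing
static cube conv1x1(const cube& A, const mat& W, const vec& b) {
  int H = A.n_rows, Wd = A.n_cols;
  mat Am(const_cast<double*>(A.memptr()), (size_t)H * Wd, A.n_slices, false,
         true);
  mat Y = Am * W;
  Y.each_row() += b.t();
  return cube(Y.memptr(), H, Wd, W.n_cols);
}

static cube conv1x1_bwd(const cube& A, const mat& W, const cube& dY, mat& dW,
                        vec& db) {
  int H = A.n_rows, Wd = A.n_cols;
  mat Am(const_cast<double*>(A.memptr()), (size_t)H * Wd, A.n_slices, false,
         true);
  mat dYm(const_cast<double*>(dY.memptr()), (size_t)H * Wd, dY.n_slices,
          false, true);
  dW += Am.t() * dYm;
  db += arma::sum(dYm, 0).t();
  mat dAm = dYm * W.t();
  return cube(dAm.memptr(), H, Wd, A.n_slices);
}

// ------------------------------------------------------------- batch norm

struct BnCache {
  vec mu, var;
};

static const double BN_EPS = 1e-3;
static const double BN_MOM = 0.9;

static void bn_forward(std::vector<cube>& X, const vec& gamma,
                       const vec& beta, vec& rmean, vec& rvar, bool training,
                       BnCache& cache, bool update_running) {
  int C = X[0].n_slices;
  size_t m = (size_t)X.size() * X[0].n_rows * X[0].n_cols;
  vec mu(C), var(C);
  if (training) {
    for (int c = 0; c < C; ++c) {
      double s = 0, s2 = 0;
      for (const cube& x : X) {
        const mat& sl = x.slice(c);
        s += arma::accu(sl);
        s2 += arma::dot(arma::vectorise(sl), arma::vectorise(sl));
      }
      mu[c] = s / m;
      var[c] = s2 / m - mu[c] * mu[c];
      if (var[c] < 0) var[c] = 0;
    }
    if (update_running) {
      rmean = BN_MOM * rmean + (1 - BN_MOM) * mu;
      rvar = BN_MOM * rvar + (1 - BN_MOM) * var;
    }
  } else {
    mu = rmean;
    var = rvar;
  }
  cache.mu = mu;
  cache.var = var;
  for (cube& x : X)
    for (int c = 0; c < C; ++c) {
      double istd = 1.0 / std::sqrt(var[c] + BN_EPS);
      x.slice(c) = gamma[c] * ((x.slice(c) - mu[c]) * istd) + beta[c];
    }
}

// dX from dY given cached pre-BN X; accumulates dgamma/dbeta
static void bn_backward(const std::vector<cube>& Xpre,
                        const std::vector<cube>& dY, const vec& gamma,
                        const BnCache& cache, bool training,
                        std::vector<cube>& dX, vec& dgamma, vec& dbeta) {
  int C = Xpre[0].n_slices;
  size_t m = (size_t)Xpre.size() * Xpre[0].n_rows * Xpre[0].n_cols;
  dX.resize(Xpre.size());
  for (size_t i = 0; i < Xpre.size(); ++i)
    dX[i].set_size(Xpre[0].n_rows, Xpre[0].n_cols, C);
  for (int c = 0; c < C; ++c) {
    double istd = 1.0 / std::sqrt(cache.var[c] + BN_EPS);
    if (!training) {
      double g = gamma[c] * istd;
      double sdy = 0, sdyx = 0;
      for (size_t i = 0; i < Xpre.size(); ++i) {
        dX[i].slice(c) = g * dY[i].slice(c);
        sdy += arma::accu(dY[i].slice(c));
        sdyx += arma::accu(dY[i].slice(c) %
                           ((Xpre[i].slice(c) - cache.mu[c]) * istd));
      }
      dgamma[c] += sdyx;
      dbeta[c] += sdy;
      continue;
    }
    double sdy = 0, sdyx = 0;
    for (size_t i = 0; i < Xpre.size(); ++i) {
      sdy += arma::accu(dY[i].slice(c));
      sdyx += arma::accu(dY[i].slice(c) %
                         ((Xpre[i].slice(c) - cache.mu[c]) * istd));
    }
    dgamma[c] += sdyx;
    dbeta[c] += sdy;
    double gi = gamma[c] * istd / (double)m;
    for (size_t i = 0; i < Xpre.size(); ++i) {
      mat xhat = (Xpre[i].slice(c) - cache.mu[c]) * istd;
      dX[i].slice(c) = gi * ((double)m * dY[i].slice(c) - sdy - xhat * sdyx);
    }
  }
}

// ----------------------------------------------------------------- pooling

// mode 0: window (1,2) (low-level, width only); mode 1: window (2,2)
static cube dual_pool(const cube& A, int mode) {
  int H = A.n_rows, W = A.n_cols, C = A.n_slices;
  int wh = (mode == 0) ? 1 : 2, ww = 2;
  int Ho = (H + wh - 1) / wh, Wo = (W + ww - 1) / ww;
  cube Y(Ho, Wo, 2 * C);
  for (int c = 0; c < C; ++c)
    for (int ox = 0; ox < Wo; ++ox)
      for (int oy = 0; oy < Ho; ++oy) {
        int y0 = oy * wh, x0 = ox * ww;
        int y1 = std::min(H, y0 + wh), x1 = std::min(W, x0 + ww);
        double mx = -arma::datum::inf, s = 0;
        int cnt = 0;
        for (int x = x0; x < x1; ++x)
          for (int y = y0; y < y1; ++y) {
            double v = A(y, x, c);
            if (v > mx) mx = v;
            s += v;
            ++cnt;
          }
        Y(oy, ox, c) = mx;
        Y(oy, ox, C + c) = s / cnt;
      }
  return Y;
}

static cube dual_pool_bwd(const cube& A, const cube& dY, int mode) {
  int H = A.n_rows, W = A.n_cols, C = A.n_slices;
  int wh = (mode == 0) ? 1 : 2, ww = 2;
  int Ho = dY.n_rows, Wo = dY.n_cols;
  cube dA(H, W, C, arma::fill::zeros);
  for (int c = 0; c < C; ++c)
    for (int ox = 0; ox < Wo; ++ox)
      for (int oy = 0; oy < Ho; ++oy) {
        int y0 = oy * wh, x0 = ox * ww;
        int y1 = std::min(H, y0 + wh), x1 = std::min(W, x0 + ww);
        // max branch: route to first maximum in scan order
        double mx = -arma::datum::inf;
        int my = y0, mxx = x0, cnt = (y1 - y0) * (x1 - x0);
        for (int x = x0; x < x1; ++x)
          for (int y = y0; y < y1; ++y)
            if (A(y, x, c) > mx) {
              mx = A(y, x, c);
              my = y;
              mxx = x;
            }
        dA(my, mxx, c) += dY(oy, ox, c);
        double g = dY(oy, ox, C + c) / cnt;
        for (int x = x0; x < x1; ++x)
          for (int y = y0; y < y1; ++y) dA(y, x, c) += g;
      }
  return dA;
}

// -------------------------------------------------------- spatial attention

static mat sa_scores(const cube& Z, const mat& Wsa, int k, cube& two) {
  int H = Z.n_rows, W = Z.n_cols, C = Z.n_slices;
  two.set_size(H, W, 2);
  two.slice(0) = arma::mean(Z, 2);
  two.slice(1) = arma::max(Z, 2);
  (void)C;
  cube pre = conv_same(two, Wsa, vec(1, arma::fill::zeros), k, k);
  return 1.0 / (1.0 + arma::exp(-pre.slice(0)));
}

static cube sa_forward(const cube& Z, const mat& Wsa, int k, mat& s_out) {
  cube two;
  mat s = sa_scores(Z, Wsa, k, two);
  s_out = s;
  cube Y = Z;
  for (uword c = 0; c < Z.n_slices; ++c) Y.slice(c) %= s;
  return Y;
}

static cube sa_backward(const cube& Z, const mat& Wsa, int k, const mat& s,
                        const cube& dY, mat& dWsa) {
  int H = Z.n_rows, W = Z.n_cols, C = Z.n_slices;
  cube dZ(H, W, C);
  mat dS(H, W, arma::fill::zeros);
  for (int c = 0; c < C; ++c) {
    dZ.slice(c) = dY.slice(c) % s;
    dS += dY.slice(c) % Z.slice(c);
  }
  mat dpre = dS % s % (1 - s);
  cube two;
  two.set_size(H, W, 2);
  two.slice(0) = arma::mean(Z, 2);
  two.slice(1) = arma::max(Z, 2);
  cube dpre_c(dpre.memptr(), H, W, 1);
  vec dbdummy(1, arma::fill::zeros);
  cube dtwo = conv_same_bwd(two, Wsa, k, k, dpre_c, dWsa, dbdummy);
  // mean branch spreads over channels; max branch routes to argmax channel
  for (int x = 0; x < W; ++x)
    for (int y = 0; y < H; ++y) {
      double g = dtwo(y, x, 0) / C;
      double mx = Z(y, x, 0);
      int mc = 0;
      for (int c = 1; c < C; ++c)
        if (Z(y, x, c) > mx) {
          mx = Z(y, x, c);
          mc = c;
        }
      for (int c = 0; c < C; ++c) dZ(y, x, c) += g;
      dZ(y, x, mc) += dtwo(y, x, 1);
    }
  return dZ;
}

// ------------------------------------------------------------ net caches

struct UnitCache {            // one shaped-conv -> BN -> ReLU -> 1x1 unit
  std::vector<cube> A1;       // post-ReLU (input of 1x1)
  std::vector<cube> Z;        // post 1x1
  BnCache bn;
};

struct LbCache {
  UnitCache u;
  std::vector<cube> Cpre;     // conv output, pre-BN
};

struct HbCache {
  UnitCache u[3];
  std::vector<cube> Cpre[3];
  std::vector<cube> ZS[3];    // post spatial attention
  std::vector<mat> S[3];      // attention score grids
  std::vector<cube> mask;     // dropout masks (training only)
};

struct NetState {
  std::vector<std::vector<cube>> blocks;  // outputs of blocks 1..6
  std::vector<LbCache> lb;
  std::vector<HbCache> hb;
  mat rep, h1, sc, emb, logits, probs;    // per-sample columns
};

// forward pass over a batch; caches kept for backward when `keep` is true
static void net_forward(const Cfg& cfg, ParView P, const std::vector<cube>& X,
                        bool training, bool update_running, uint64_t seed,
                        NetState& st) {
  size_t N = X.size();
  st.blocks.assign(6, {});
  st.lb.assign(3, LbCache());
  st.hb.assign(3, HbCache());
  std::vector<cube> cur = X;
  char nm[64];
  for (int b = 0; b < 3; ++b) {
    snprintf(nm, 64, "lb%d", b + 1);
    std::string p(nm);
    mat Wc = P(p + "_conv_w");
    vec bc = arma::vectorise(P(p + "_conv_b"));
    vec gamma = arma::vectorise(P(p + "_bn_gamma"));
    vec beta = arma::vectorise(P(p + "_bn_beta"));
    mat rmean_m = P(p + "_bn_rmean"), rvar_m = P(p + "_bn_rvar");
    vec rmean = arma::vectorise(rmean_m), rvar = arma::vectorise(rvar_m);
    mat W1 = P(p + "_one_w");
    vec b1 = arma::vectorise(P(p + "_one_b"));
    LbCache& C = st.lb[b];
    C.Cpre.resize(N);
    C.u.A1.resize(N);
    C.u.Z.resize(N);
    std::vector<cube> conv(N);
    for (size_t i = 0; i < N; ++i) conv[i] = conv_same(cur[i], Wc, bc, 1, cfg.K);
    C.Cpre = conv;
    bn_forward(conv, gamma, beta, rmean, rvar, training, C.u.bn,
               update_running);
    if (training && update_running) {
      rmean_m.col(0) = rmean;
      rvar_m.col(0) = rvar;
    }
    std::vector<cube> out(N);
    for (size_t i = 0; i < N; ++i) {
      conv[i].transform([](double v) { return v > 0 ? v : 0.0; });
      C.u.A1[i] = conv[i];
      C.u.Z[i] = conv1x1(conv[i], W1, b1);
      out[i] = dual_pool(C.u.Z[i], 0);
    }
    st.blocks[b] = out;
    cur = out;
  }
  const char* pth[3] = {"b", "i", "t"};
  std::mt19937_64 rng(seed);
  std::uniform_real_distribution<double> unif(0.0, 1.0);
  for (int s = 0; s < 3; ++s) {
    snprintf(nm, 64, "hb%d", s + 4);
    std::string p(nm);
    HbCache& C = st.hb[s];
    mat Wsa = P(p + "_sa_w");
    std::vector<cube> pathout[3];
    for (int q = 0; q < 3; ++q) {
      int kh = (q == 0) ? 1 : cfg.K;
      int kw = (q == 1) ? 1 : cfg.K;
      std::string pp = p + "_" + pth[q];
      mat Wc = P(pp + "_conv_w");
      vec bc = arma::vectorise(P(pp + "_conv_b"));
      vec gamma = arma::vectorise(P(pp + "_bn_gamma"));
      vec beta = arma::vectorise(P(pp + "_bn_beta"));
      mat rmean_m = P(pp + "_bn_rmean"), rvar_m = P(pp + "_bn_rvar");
      vec rmean = arma::vectorise(rmean_m), rvar = arma::vectorise(rvar_m);
      mat W1 = P(pp + "_one_w");
      vec b1 = arma::vectorise(P(pp + "_one_b"));
      std::vector<cube> conv(N);
      for (size_t i = 0; i < N; ++i)
        conv[i] = conv_same(cur[i], Wc, bc, kh, kw);
      C.Cpre[q] = conv;
      bn_forward(conv, gamma, beta, rmean, rvar, training, C.u[q].bn,
                 update_running);
      if (training && update_running) {
        rmean_m.col(0) = rmean;
        rvar_m.col(0) = rvar;
      }
      C.u[q].A1.resize(N);
      C.u[q].Z.resize(N);
      C.ZS[q].resize(N);
      C.S[q].resize(N);
      pathout[q].resize(N);
      for (size_t i = 0; i < N; ++i) {
        conv[i].transform([](double v) { return v > 0 ? v : 0.0; });
        C.u[q].A1[i] = conv[i];
        C.u[q].Z[i] = conv1x1(conv[i], W1, b1);
        C.ZS[q][i] = sa_forward(C.u[q].Z[i], Wsa, cfg.sa_k, C.S[q][i]);
        pathout[q][i] = dual_pool(C.ZS[q][i], 1);
      }
    }
    // concatenate the three paths [B || I || T], then dropout
    std::vector<cube> out(N);
    C.mask.resize((training && cfg.dropout > 0) ? N : 0);
    for (size_t i = 0; i < N; ++i) {
      int Ho = pathout[0][i].n_rows, Wo = pathout[0][i].n_cols;
      int Cp = pathout[0][i].n_slices;
      cube cat(Ho, Wo, 3 * Cp);
      for (int q = 0; q < 3; ++q)
        cat.slices(q * Cp, (q + 1) * Cp - 1) = pathout[q][i];
      if (training && cfg.dropout > 0) {
        cube msk(Ho, Wo, 3 * Cp);
        double keep = 1.0 - cfg.dropout;
        for (uword t = 0; t < msk.n_elem; ++t)
          msk[t] = (unif(rng) < keep) ? 1.0 / keep : 0.0;
        C.mask[i] = msk;
        cat %= msk;
      }
      out[i] = cat;
    }
    st.blocks[3 + s] = out;
    cur = out;
  }
  // FA + FC
  int Chb = cur[0].n_slices, C2 = 2 * Chb;
  mat W1 = P("fa_w1"), W2 = P("fa_w2"), Wfc = P("fc_w");
  vec b1 = arma::vectorise(P("fa_b1"));
  vec b2 = arma::vectorise(P("fa_b2"));
  vec bfc = arma::vectorise(P("fc_b"));
  st.rep.set_size(C2, N);
  st.h1.set_size(cfg.fa_hidden, N);
  st.sc.set_size(C2, N);
  st.emb.set_size(C2, N);
  st.logits.set_size(cfg.n_classes, N);
  st.probs.set_size(cfg.n_classes, N);
  for (size_t i = 0; i < N; ++i) {
    vec rep(C2);
    for (int c = 0; c < Chb; ++c) {
      rep[c] = arma::mean(arma::vectorise(cur[i].slice(c)));
      rep[Chb + c] = cur[i].slice(c).max();
    }
    vec h1v = W1.t() * rep + b1;
    h1v.transform([](double v) { return v > 0 ? v : 0.0; });
    vec scv = 1.0 / (1.0 + arma::exp(-(W2.t() * h1v + b2)));
    vec embv = rep % scv;
    vec lg = Wfc.t() * embv + bfc;
    vec pr = arma::exp(lg - lg.max());
    pr /= arma::accu(pr);
    st.rep.col(i) = rep;
    st.h1.col(i) = h1v;
    st.sc.col(i) = scv;
    st.emb.col(i) = embv;
    st.logits.col(i) = lg;
    st.probs.col(i) = pr;
  }
}

struct GradView {
  const std::vector<PEntry>* L;
  double* g;
  mat operator()(const std::string& name) const {
    for (const PEntry& e : *L)
      if (e.name == name) return mat(g + e.off, e.r, e.c, false, true);
    stop("unknown parameter: " + name);
    return mat();
  }
};

// backward from dlogits; fills parameter gradients, optionally captures the
// gradient arriving at each block output (for Grad-CAM)
static void net_backward(const Cfg& cfg, ParView P, const std::vector<cube>& X,
                         NetState& st, const mat& dlogits, bool training,
                         GradView G, std::vector<std::vector<cube>>* dblocks) {
  size_t N = X.size();
  int Chb = st.blocks[5][0].n_slices, C2 = 2 * Chb;
  mat W1 = P("fa_w1"), W2 = P("fa_w2"), Wfc = P("fc_w");
  mat dW1 = G("fa_w1"), dW2 = G("fa_w2"), dWfc = G("fc_w");
  mat db1 = G("fa_b1"), db2 = G("fa_b2"), dbfc = G("fc_b");
  if (dblocks) dblocks->assign(6, {});
  std::vector<cube> dcur(N);
  const std::vector<cube>& top = st.blocks[5];
  int Ht = top[0].n_rows, Wt = top[0].n_cols;
  for (size_t i = 0; i < N; ++i) {
    vec dlg = dlogits.col(i);
    dWfc += st.emb.col(i) * dlg.t();
    dbfc.col(0) += dlg;
    vec demb = Wfc * dlg;
    vec drep = demb % st.sc.col(i);
    vec dsc = demb % st.rep.col(i);
    vec da2 = dsc % st.sc.col(i) % (1 - st.sc.col(i));
    dW2 += st.h1.col(i) * da2.t();
    db2.col(0) += da2;
    vec dh1 = W2 * da2;
    vec h1v = st.h1.col(i);
    for (int k = 0; k < cfg.fa_hidden; ++k)
      if (h1v[k] <= 0) dh1[k] = 0;
    dW1 += st.rep.col(i) * dh1.t();
    db1.col(0) += dh1;
    drep += W1 * dh1;
    cube d(Ht, Wt, Chb, arma::fill::zeros);
    double inv = 1.0 / ((double)Ht * Wt);
    for (int c = 0; c < Chb; ++c) {
      d.slice(c).fill(drep[c] * inv);
      // GMP: route to (first) spatial argmax
      const mat& sl = top[i].slice(c);
      uword idx = sl.index_max();
      d.slice(c)[idx] += drep[Chb + c];
    }
    dcur[i] = d;
  }
  (void)C2;
  const char* pth[3] = {"b", "i", "t"};
  char nm[64];
  for (int s = 2; s >= 0; --s) {
    if (dblocks) (*dblocks)[3 + s] = dcur;
    snprintf(nm, 64, "hb%d", s + 4);
    std::string p(nm);
    HbCache& C = st.hb[s];
    mat Wsa = P(p + "_sa_w");
    mat dWsa = G(p + "_sa_w");
    const std::vector<cube>& below = (s == 0) ? st.blocks[2] : st.blocks[2 + s];
    std::vector<cube> dnext(N);
    for (size_t i = 0; i < N; ++i)
      dnext[i].zeros(below[i].n_rows, below[i].n_cols, below[i].n_slices);
    for (size_t i = 0; i < N; ++i)
      if (training && C.mask.size()) dcur[i] %= C.mask[i];
    int Cp = st.hb[s].ZS[0][0].n_slices * 2;  // per-path pooled channels
    for (int q = 0; q < 3; ++q) {
      int kh = (q == 0) ? 1 : cfg.K;
      int kw = (q == 1) ? 1 : cfg.K;
      std::string pp = p + "_" + pth[q];
      mat Wc = P(pp + "_conv_w");
      mat W1x = P(pp + "_one_w");
      vec gamma = arma::vectorise(P(pp + "_bn_gamma"));
      mat dWc = G(pp + "_conv_w"), dW1x = G(pp + "_one_w");
      mat dbc = G(pp + "_conv_b"), db1x = G(pp + "_one_b");
      mat dgm = G(pp + "_bn_gamma"), dbt = G(pp + "_bn_beta");
      vec dbc_v(dbc.n_rows, arma::fill::zeros);
      vec db1x_v(db1x.n_rows, arma::fill::zeros);
      vec dg_v(dgm.n_rows, arma::fill::zeros), db_v(dbt.n_rows, arma::fill::zeros);
      std::vector<cube> dA1(N);
      for (size_t i = 0; i < N; ++i) {
        cube dpath = dcur[i].slices(q * Cp, (q + 1) * Cp - 1);
        cube dzs = dual_pool_bwd(C.ZS[q][i], dpath, 1);
        cube dz = sa_backward(C.u[q].Z[i], Wsa, cfg.sa_k, C.S[q][i], dzs, dWsa);
        cube da1 = conv1x1_bwd(C.u[q].A1[i], W1x, dz, dW1x, db1x_v);
        da1.elem(arma::find(C.u[q].A1[i] <= 0)).zeros();
        dA1[i] = da1;
      }
      std::vector<cube> dCpre;
      bn_backward(C.Cpre[q], dA1, gamma, C.u[q].bn, training, dCpre, dg_v,
                  db_v);
      for (size_t i = 0; i < N; ++i)
        dnext[i] += conv_same_bwd(below[i], Wc, kh, kw, dCpre[i], dWc, dbc_v);
      dbc.col(0) += dbc_v;
      db1x.col(0) += db1x_v;
      dgm.col(0) += dg_v;
      dbt.col(0) += db_v;
    }
    dcur = dnext;
  }
  for (int b = 2; b >= 0; --b) {
    if (dblocks) (*dblocks)[b] = dcur;
    snprintf(nm, 64, "lb%d", b + 1);
    std::string p(nm);
    LbCache& C = st.lb[b];
    mat Wc = P(p + "_conv_w");
    mat W1x = P(p + "_one_w");
    vec gamma = arma::vectorise(P(p + "_bn_gamma"));
    mat dWc = G(p + "_conv_w"), dW1x = G(p + "_one_w");
    mat dbc = G(p + "_conv_b"), db1x = G(p + "_one_b");
    mat dgm = G(p + "_bn_gamma"), dbt = G(p + "_bn_beta");
    vec dbc_v(dbc.n_rows, arma::fill::zeros);
    vec db1x_v(db1x.n_rows, arma::fill::zeros);
    vec dg_v(dgm.n_rows, arma::fill::zeros), db_v(dbt.n_rows, arma::fill::zeros);
    const std::vector<cube>& below = (b == 0) ? X : st.blocks[b - 1];
    std::vector<cube> dA1(N);
    for (size_t i = 0; i < N; ++i) {
      cube dz = dual_pool_bwd(C.u.Z[i], dcur[i], 0);
      cube da1 = conv1x1_bwd(C.u.A1[i], W1x, dz, dW1x, db1x_v);
      da1.elem(arma::find(C.u.A1[i] <= 0)).zeros();
      dA1[i] = da1;
    }
    std::vector<cube> dCpre;
    bn_backward(C.Cpre, dA1, gamma, C.u.bn, training, dCpre, dg_v, db_v);
    std::vector<cube> dnext(N);
    for (size_t i = 0; i < N; ++i)
      dnext[i] = conv_same_bwd(below[i], Wc, 1, cfg.K, dCpre[i], dWc, dbc_v);
    dbc.col(0) += dbc_v;
    db1x.col(0) += db1x_v;
    dgm.col(0) += dg_v;
    dbt.col(0) += db_v;
    dcur = dnext;
  }
}

// ------------------------------------------------------------ R interface

static std::vector<cube> batch_from_array(const arma::cube& X) {
  std::vector<cube> out(X.n_slices);
  for (uword i = 0; i < X.n_slices; ++i) {
    out[i] = cube(const_cast<double*>(X.slice_colptr(i, 0)), X.n_rows,
                  X.n_cols, 1);
  }
  return out;
}

// [[Rcpp::export]]
DataFrame cpp_param_layout(List cfg) {
  Cfg c = parse_cfg(cfg);
  std::vector<PEntry> L = make_layout(c);
  int n = L.size();
  CharacterVector name(n);
  IntegerVector nr(n), nc(n), fi(n), fo(n);
  LogicalVector tr(n);
  for (int i = 0; i < n; ++i) {
    name[i] = L[i].name;
    nr[i] = L[i].r;
    nc[i] = L[i].c;
    tr[i] = L[i].trainable;
    fi[i] = L[i].fan_in;
    fo[i] = L[i].fan_out;
  }
  return DataFrame::create(_["name"] = name, _["nrow"] = nr, _["ncol"] = nc,
                           _["trainable"] = tr, _["fan_in"] = fi,
                           _["fan_out"] = fo);
}

// [[Rcpp::export]]
List cpp_forward(List cfg, NumericVector par, arma::cube X,
                 bool training = false, double seed = 0, bool capture = false) {
  Cfg c = parse_cfg(cfg);
  std::vector<PEntry> L = make_layout(c);
  if ((size_t)par.size() != layout_size(L))
    stop("parameter vector has wrong length");
  ParView P{&L, par.begin()};
  std::vector<cube> batch = batch_from_array(X);
  NetState st;
  net_forward(c, P, batch, training, false, (uint64_t)seed, st);
  List out = List::create(_["probs"] = wrap(mat(st.probs.t())),
                          _["logits"] = wrap(mat(st.logits.t())),
                          _["embedding"] = wrap(mat(st.emb.t())),
                          _["scores"] = wrap(mat(st.sc.t())),
                          _["representation"] = wrap(mat(st.rep.t())));
  if (capture) {
    List blocks(6);
    for (int b = 0; b < 6; ++b) {
      List bl(st.blocks[b].size());
      for (size_t i = 0; i < st.blocks[b].size(); ++i)
        bl[i] = wrap(st.blocks[b][i]);
      blocks[b] = bl;
    }
    out["blocks"] = blocks;
  }
  return out;
}

// [[Rcpp::export]]
List cpp_loss_grad(List cfg, NumericVector par, arma::cube X,
                   arma::mat Y, double seed = 0) {
  Cfg c = parse_cfg(cfg);
  std::vector<PEntry> L = make_layout(c);
  if ((size_t)par.size() != layout_size(L))
    stop("parameter vector has wrong length");
  NumericVector par_new = clone(par);
  ParView P{&L, par_new.begin()};
  std::vector<cube> batch = batch_from_array(X);
  size_t N = batch.size();
  if (Y.n_rows != N || (int)Y.n_cols != c.n_classes)
    stop("label matrix has wrong shape");
  NetState st;
  net_forward(c, P, batch, true, true, (uint64_t)seed, st);
  double loss = 0;
  mat dlogits(c.n_classes, N);
  for (size_t i = 0; i < N; ++i) {
    vec y = Y.row(i).t();
    vec pr = st.probs.col(i);
    loss += -arma::dot(y, arma::log(pr + 1e-12));
    dlogits.col(i) = (pr - y) / (double)N;
  }
  loss /= (double)N;
  NumericVector grad((R_xlen_t)layout_size(L));
  GradView G{&L, grad.begin()};
  net_backward(c, P, batch, st, dlogits, true, G, nullptr);
  return List::create(_["loss"] = loss, _["grad"] = grad,
                      _["par_new"] = par_new,
                      _["probs"] = wrap(mat(st.probs.t())));
}

// [[Rcpp::export]]
List cpp_gradcam(List cfg, NumericVector par, arma::cube X, int class_idx) {
  Cfg c = parse_cfg(cfg);
  std::vector<PEntry> L = make_layout(c);
  ParView P{&L, par.begin()};
  std::vector<cube> batch = batch_from_array(X);
  NetState st;
  net_forward(c, P, batch, false, false, 0, st);
  mat dlogits(c.n_classes, batch.size(), arma::fill::zeros);
  for (size_t i = 0; i < batch.size(); ++i) dlogits(class_idx - 1, i) = 1.0;
  NumericVector grad((R_xlen_t)layout_size(L));
  GradView G{&L, grad.begin()};
  std::vector<std::vector<cube>> dblocks;
  net_backward(c, P, batch, st, dlogits, false, G, &dblocks);
  List acts(6), grads(6);
  for (int b = 0; b < 6; ++b) {
    acts[b] = wrap(st.blocks[b][0]);
    grads[b] = wrap(dblocks[b][0]);
  }
  return List::create(_["activations"] = acts, _["gradients"] = grads,
                      _["logits"] = wrap(mat(st.logits.t())));
}

// ---- single-op helpers for unit tests ------------------------------------

// [[Rcpp::export]]
arma::cube cpp_conv2d_same(arma::cube x, arma::mat w, arma::vec bias, int kh,
                           int kw) {
  return conv_same(x, w, bias, kh, kw);
}

// [[Rcpp::export]]
arma::cube cpp_dual_pool(arma::cube x, int mode) { return dual_pool(x, mode); }

// [[Rcpp::export]]
List cpp_spatial_attention(arma::cube x, arma::mat w, int k) {
  mat s;
  cube y = sa_forward(x, w, k, s);
  return List::create(_["output"] = y, _["scores"] = s);
}

// [[Rcpp::export]]
List cpp_feature_attention(arma::cube x, arma::mat w1, arma::vec b1,
                           arma::mat w2, arma::vec b2) {
  int C = x.n_slices, C2 = 2 * C;
  vec rep(C2);
  for (int c = 0; c < C; ++c) {
    rep[c] = arma::mean(arma::vectorise(x.slice(c)));
    rep[C + c] = x.slice(c).max();
  }
  vec h1 = w1.t() * rep + b1;
  h1.transform([](double v) { return v > 0 ? v : 0.0; });
  vec sc = 1.0 / (1.0 + arma::exp(-(w2.t() * h1 + b2)));
  return List::create(_["representation"] = rep, _["scores"] = sc,
                      _["embedding"] = rep % sc);
}
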