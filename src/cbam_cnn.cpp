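// Compact CNN with a convolutional block attention module (CBAM),
// implemented directly on Armadillo matrices so the repeated
// cross-validation loop stays fast on one CPU.
//
// Architecture (same-padded 7x7 convolutions, stride 1):
//   conv1 -> ReLU -> [CBAM] -> maxpool(2x2,2)
//   conv2 -> ReLU -> [CBAM] -> maxpool(2x2,2)
//   dropout -> fully connected -> softmax(2)
//
// CBAM: channel attention  Mc = sigmoid(MLP(avgpool F) + MLP(maxpool F))
//       spatial attention  Ms = sigmoid(conv7x7([avg_c F'; max_c F']))
//       F'' = Ms (x) (Mc (x) F)  (broadcast element-wise products)
//
// Performance notes: convolutions run as one GEMM per sample on a
// transposed im2col matrix (H*W x Cin*k*k) whose construction copies
// contiguous column segments; per-sample buffers live in reusable
// context structs so the training loop does not allocate.

#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]

using namespace arma;

static inline double sigmoid_d(double z) { return 1.0 / (1.0 + std::exp(-z)); }

// ---------------------------------------------------------------- conv2d ---

// transposed im2col: cols is (H*W) x (Cin*k*k); column (c*k+dy)*k+dx of
// cols holds, at row j*H+i, the input value x(i+dy-p, j+dx-p, c) (0 when
// outside).  Writes are contiguous runs over i.
static void im2col_t(const cube& x, int Cin, int k, mat& cols) {
  const int H = x.n_rows, W = x.n_cols, p = k / 2;
  cols.zeros(H * W, Cin * k * k);
  for (int c = 0; c < Cin; ++c) {
    const double* xs = x.slice_memptr(c);
    for (int dy = 0; dy < k; ++dy) {
      const int i0 = std::max(0, p - dy);            // first valid out row
      const int i1 = std::min(H, H + p - dy);        // one past last
      if (i1 <= i0) continue;
      for (int dx = 0; dx < k; ++dx) {
        double* col = cols.colptr((c * k + dy) * k + dx);
        const int j0 = std::max(0, p - dx);
        const int j1 = std::min(W, W + p - dx);
        for (int j = j0; j < j1; ++j) {
          const double* src = xs + (j + dx - p) * H + (i0 + dy - p);
          std::copy(src, src + (i1 - i0), col + j * H + i0);
        }
      }
    }
  }
}

// adjoint: scatter-add gcols (H*W x Cin*k*k) back onto gx
static void col2im_t_add(cube& gx, const mat& gcols, int Cin, int k) {
  const int H = gx.n_rows, W = gx.n_cols, p = k / 2;
  for (int c = 0; c < Cin; ++c) {
    double* xs = gx.slice_memptr(c);
    for (int dy = 0; dy < k; ++dy) {
      const int i0 = std::max(0, p - dy);
      const int i1 = std::min(H, H + p - dy);
      if (i1 <= i0) continue;
      for (int dx = 0; dx < k; ++dx) {
        const double* col = gcols.colptr((c * k + dy) * k + dx);
        const int j0 = std::max(0, p - dx);
        const int j1 = std::min(W, W + p - dx);
        for (int j = j0; j < j1; ++j) {
          double* dst = xs + (j + dx - p) * H + (i0 + dy - p);
          const double* src = col + j * H + i0;
          for (int i = 0; i < i1 - i0; ++i) dst[i] += src[i];
        }
      }
    }
  }
}

// matrix view (no copy) of a cube's memory as (H*W) x n_slices
static inline mat cube_as_mat(cube& x) {
  return mat(x.memptr(), x.n_rows * x.n_cols, x.n_slices, false, true);
}
static inline const mat cube_as_cmat(const cube& x) {
  return mat(const_cast<double*>(x.memptr()),
             x.n_rows * x.n_cols, x.n_slices, false, true);
}

// y (preallocated H x W x Cout) = conv(x) given its im2col matrix
static void conv_fwd(const mat& cols, const mat& W, const vec& b, cube& y) {
  mat ym = cube_as_mat(y);
  ym = cols * W.t();
  ym.each_row() += b.t();
}

// ---------------------------------------------------------------- pooling --

struct PoolCtx { ucube idx; };             // argmax (linear in input slice)

static void maxpool_fwd(const cube& x, cube& y, PoolCtx& ctx) {
  const int H = x.n_rows, S = x.n_slices;
  const int Ho = H / 2, Wo = x.n_cols / 2;
  y.set_size(Ho, Wo, S);
  ctx.idx.set_size(Ho, Wo, S);
  for (int s = 0; s < S; ++s) {
    const mat& xs = x.slice(s);
    for (int j = 0; j < Wo; ++j)
      for (int i = 0; i < Ho; ++i) {
        const int bi = 2 * i, bj = 2 * j;
        int ai = bi, aj = bj;
        double v = xs(bi, bj);
        if (xs(bi + 1, bj) > v) { v = xs(bi + 1, bj); ai = bi + 1; }
        if (xs(bi, bj + 1) > v) { v = xs(bi, bj + 1); ai = bi; aj = bj + 1; }
        if (xs(bi + 1, bj + 1) > v) { v = xs(bi + 1, bj + 1); ai = bi + 1; aj = bj + 1; }
        y(i, j, s) = v;
        ctx.idx(i, j, s) = aj * H + ai;
      }
  }
}

static void maxpool_bwd(const cube& gy, const PoolCtx& ctx, cube& gx) {
  gx.zeros();
  for (uword s = 0; s < gy.n_slices; ++s) {
    double* g = gx.slice_memptr(s);
    for (uword j = 0; j < gy.n_cols; ++j)
      for (uword i = 0; i < gy.n_rows; ++i)
        g[ctx.idx(i, j, s)] += gy(i, j, s);
  }
}

// -------------------------------------------------------------- CBAM ------

struct CbamParams {
  mat W0, W1;                               // shared MLP (no biases)
  mat sW;                                   // 1 x (2*k*k) spatial kernel
  double sb;                                // spatial bias
  int k;
};

struct CbamCtx {
  const cube* Fin;                          // block input (not owned)
  vec v_avg, v_max, h_avg, h_max, mc;       // channel branch
  uvec arg_sp;                              // spatial argmax per channel
  cube Fp, desc;                            // F' and [avg;max] descriptor
  mat ms;                                   // spatial map
  umat arg_ch;                              // channel argmax per pixel
  mat cols;                                 // im2col of desc
  cube gFp, gdesc;                          // backward scratch
  mat gms, gpre, gcols;
};

static void cbam_fwd(const cube& F, const CbamParams& P, CbamCtx& ctx,
                     cube& out) {
  const int H = F.n_rows, W = F.n_cols, C = F.n_slices, HW = H * W;
  ctx.Fin = &F;
  ctx.v_avg.set_size(C); ctx.v_max.set_size(C); ctx.arg_sp.set_size(C);
  for (int c = 0; c < C; ++c) {
    const mat& s = F.slice(c);
    ctx.v_avg(c) = accu(s) / HW;
    ctx.arg_sp(c) = s.index_max();
    ctx.v_max(c) = s(ctx.arg_sp(c));
  }
  ctx.h_avg = clamp(P.W0 * ctx.v_avg, 0.0, datum::inf);
  ctx.h_max = clamp(P.W0 * ctx.v_max, 0.0, datum::inf);
  ctx.mc = 1.0 / (1.0 + exp(-(P.W1 * ctx.h_avg + P.W1 * ctx.h_max)));
  ctx.Fp = F;
  for (int c = 0; c < C; ++c) ctx.Fp.slice(c) *= ctx.mc(c);
  // channel-wise average / maximum planes
  ctx.desc.set_size(H, W, 2);
  mat& savg = ctx.desc.slice(0);
  mat& smax = ctx.desc.slice(1);
  savg = ctx.Fp.slice(0);
  smax = ctx.Fp.slice(0);
  ctx.arg_ch.zeros(H, W);
  for (int c = 1; c < C; ++c) {
    const double* s = ctx.Fp.slice_memptr(c);
    double* mx = smax.memptr();
    uword* ac = ctx.arg_ch.memptr();
    double* av = savg.memptr();
    for (int i = 0; i < HW; ++i) {
      av[i] += s[i];
      if (s[i] > mx[i]) { mx[i] = s[i]; ac[i] = c; }
    }
  }
  savg /= C;
  im2col_t(ctx.desc, 2, P.k, ctx.cols);
  vec pre = ctx.cols * P.sW.t() + P.sb;     // (H*W) x 1
  ctx.ms = reshape(pre, H, W);
  ctx.ms.transform(sigmoid_d);
  out.set_size(H, W, C);
  for (int c = 0; c < C; ++c) out.slice(c) = ctx.Fp.slice(c) % ctx.ms;
}

struct CbamGrads { mat gW0, gW1, gsW; double gsb; };

// gradient w.r.t. the block input, written into gF; parameter
// gradients accumulate into G
static void cbam_bwd(const cube& gOut, const CbamParams& P, CbamCtx& ctx,
                     CbamGrads& G, cube& gF) {
  const cube& F = *ctx.Fin;
  const int H = F.n_rows, W = F.n_cols, C = F.n_slices, HW = H * W;
  // spatial attention backward
  ctx.gFp.set_size(H, W, C);
  ctx.gms.zeros(H, W);
  cube& gFp = ctx.gFp;
  for (int c = 0; c < C; ++c) {
    gFp.slice(c) = gOut.slice(c) % ctx.ms;
    ctx.gms += gOut.slice(c) % ctx.Fp.slice(c);
  }
  ctx.gpre = ctx.gms % ctx.ms % (1.0 - ctx.ms);
  vec gprev(ctx.gpre.memptr(), HW, false, true);   // column-major = im2col rows
  G.gsW += gprev.t() * ctx.cols;
  G.gsb += accu(ctx.gpre);
  ctx.gcols = gprev * P.sW;                        // HW x (2*k*k)
  ctx.gdesc.zeros(H, W, 2);
  col2im_t_add(ctx.gdesc, ctx.gcols, 2, P.k);
  const mat& gsavg = ctx.gdesc.slice(0);
  const mat& gsmax = ctx.gdesc.slice(1);
  for (int c = 0; c < C; ++c) gFp.slice(c) += gsavg / C;
  {
    const double* gm = gsmax.memptr();
    const uword* ac = ctx.arg_ch.memptr();
    for (int i = 0; i < HW; ++i)
      gFp.slice_memptr(ac[i])[i] += gm[i];
  }
  // channel attention backward
  gF.set_size(H, W, C);
  vec gmc(C);
  for (int c = 0; c < C; ++c) {
    gF.slice(c) = gFp.slice(c) * ctx.mc(c);
    gmc(c) = accu(gFp.slice(c) % F.slice(c));
  }
  vec gpre_c = gmc % ctx.mc % (1.0 - ctx.mc);
  for (int branch = 0; branch < 2; ++branch) {
    const vec& h = branch ? ctx.h_max : ctx.h_avg;
    const vec& v = branch ? ctx.v_max : ctx.v_avg;
    G.gW1 += gpre_c * h.t();
    vec gh = (P.W1.t() * gpre_c) % conv_to<vec>::from(h > 0);
    G.gW0 += gh * v.t();
    vec gv = P.W0.t() * gh;
    for (int c = 0; c < C; ++c) {
      if (branch == 0)
        gF.slice(c) += gv(c) / HW;          // avg-pool spreads uniformly
      else
        gF.slice(c)(ctx.arg_sp(c)) += gv(c);  // max-pool routes to argmax
    }
  }
}

// ------------------------------------------------------------ the network --

struct NetCfg {
  int F1, F2, k, n_classes;
  bool cbam1, cbam2;
  double dropout, lr, beta1, beta2, eps;
  int batch, epochs;
};

static NetCfg parse_cfg(const Rcpp::List& cfg) {
  NetCfg c;
  Rcpp::IntegerVector filt = cfg["conv_filters"];
  c.F1 = filt[0]; c.F2 = filt[1];
  c.k = Rcpp::as<int>(cfg["conv_kernel"]);
  c.n_classes = 2;
  Rcpp::LogicalVector cb = cfg["cbam_blocks"];
  c.cbam1 = cb[0]; c.cbam2 = cb[1];
  c.dropout = Rcpp::as<double>(cfg["dropout_rate"]);
  c.lr = Rcpp::as<double>(cfg["learning_rate"]);
  c.beta1 = 0.9; c.beta2 = 0.999; c.eps = 1e-8;
  c.batch = Rcpp::as<int>(cfg["batch_size"]);
  c.epochs = Rcpp::as<int>(cfg["max_epochs"]);
  return c;
}

enum ParIdx { iW1, ib1, icW0_1, icW1_1, isW1, isb1,
              iW2, ib2, icW0_2, icW1_2, isW2, isb2,
              iWf, ibf, NPAR };

static const char* par_names[NPAR] = {
  "W1", "b1", "c1_W0", "c1_W1", "s1_W", "s1_b",
  "W2", "b2", "c2_W0", "c2_W1", "s2_W", "s2_b",
  "Wf", "bf" };

static std::vector<mat> parse_params(const Rcpp::List& par) {
  std::vector<mat> P(NPAR);
  for (int i = 0; i < NPAR; ++i)
    P[i] = Rcpp::as<mat>(par[par_names[i]]);
  return P;
}

static Rcpp::List wrap_params(const std::vector<mat>& P) {
  Rcpp::List out;
  for (int i = 0; i < NPAR; ++i) out[par_names[i]] = P[i];
  return out;
}

static CbamParams cbam_par(const std::vector<mat>& P, int layer, int k) {
  CbamParams cp;
  cp.W0 = P[layer == 1 ? icW0_1 : icW0_2];
  cp.W1 = P[layer == 1 ? icW1_1 : icW1_2];
  cp.sW = P[layer == 1 ? isW1 : isW2];
  cp.sb = P[layer == 1 ? isb1 : isb2](0, 0);
  cp.k = k;
  return cp;
}

// reusable per-sample context: buffer sizes are constant across
// samples, so nothing reallocates after the first pass
struct FwdCtx {
  cube x;                   // 1-slice input
  mat cols1, cols2;         // im2col matrices
  cube z1, a1, c1, p1;      // conv1 pipeline
  cube z2, a2, c2, p2;      // conv2 pipeline
  CbamCtx cb1, cb2;
  PoolCtx pool1, pool2;
  vec f, drop_mask, prob;
  // backward scratch
  cube gp2, gc2, ga2, gz2, gp1, gc1, ga1, gz1, gcb;
  mat gcols2;
};

static vec forward_sample(const double* img, int H, int W,
                          const std::vector<mat>& P, const NetCfg& cfg,
                          bool train, FwdCtx& ctx) {
  ctx.x.set_size(H, W, 1);
  std::copy(img, img + H * W, ctx.x.memptr());
  im2col_t(ctx.x, 1, cfg.k, ctx.cols1);
  ctx.z1.set_size(H, W, cfg.F1);
  conv_fwd(ctx.cols1, P[iW1], vec(P[ib1].col(0)), ctx.z1);
  ctx.a1 = ctx.z1; ctx.a1.clamp(0.0, datum::inf);
  if (cfg.cbam1) cbam_fwd(ctx.a1, cbam_par(P, 1, cfg.k), ctx.cb1, ctx.c1);
  else ctx.c1 = ctx.a1;
  maxpool_fwd(ctx.c1, ctx.p1, ctx.pool1);

  const int H2 = H / 2, W2 = W / 2;
  im2col_t(ctx.p1, cfg.F1, cfg.k, ctx.cols2);
  ctx.z2.set_size(H2, W2, cfg.F2);
  conv_fwd(ctx.cols2, P[iW2], vec(P[ib2].col(0)), ctx.z2);
  ctx.a2 = ctx.z2; ctx.a2.clamp(0.0, datum::inf);
  if (cfg.cbam2) cbam_fwd(ctx.a2, cbam_par(P, 2, cfg.k), ctx.cb2, ctx.c2);
  else ctx.c2 = ctx.a2;
  maxpool_fwd(ctx.c2, ctx.p2, ctx.pool2);

  ctx.f = vectorise(ctx.p2);
  if (train && cfg.dropout > 0) {
    const double keep = 1.0 - cfg.dropout;
    ctx.drop_mask.set_size(ctx.f.n_elem);
    for (uword i = 0; i < ctx.f.n_elem; ++i)
      ctx.drop_mask(i) = (unif_rand() < keep) ? 1.0 / keep : 0.0;
    ctx.f %= ctx.drop_mask;
  } else ctx.drop_mask.reset();
  vec logits = P[iWf] * ctx.f + P[ibf].col(0);
  logits -= logits.max();
  vec ex = exp(logits);
  ctx.prob = ex / accu(ex);
  return ctx.prob;
}

static void backward_sample(FwdCtx& ctx, int y, const std::vector<mat>& P,
                            const NetCfg& cfg, std::vector<mat>& G, double wt) {
  const int H = ctx.z1.n_rows, W = ctx.z1.n_cols;
  const int H2 = H / 2, W2 = W / 2;
  vec dlog = ctx.prob * wt; dlog(y) -= wt;
  G[iWf] += dlog * ctx.f.t();
  G[ibf].col(0) += dlog;
  vec gf = P[iWf].t() * dlog;
  if (ctx.drop_mask.n_elem) gf %= ctx.drop_mask;
  ctx.gp2.set_size(H2 / 2, W2 / 2, cfg.F2);
  std::copy(gf.memptr(), gf.memptr() + gf.n_elem, ctx.gp2.memptr());

  ctx.gc2.set_size(H2, W2, cfg.F2);
  maxpool_bwd(ctx.gp2, ctx.pool2, ctx.gc2);
  cube* ga2 = &ctx.gc2;
  if (cfg.cbam2) {
    CbamParams cp = cbam_par(P, 2, cfg.k);
    CbamGrads cg { zeros<mat>(size(cp.W0)), zeros<mat>(size(cp.W1)),
                   zeros<mat>(size(cp.sW)), 0.0 };
    cbam_bwd(ctx.gc2, cp, ctx.cb2, cg, ctx.gcb);
    G[icW0_2] += cg.gW0; G[icW1_2] += cg.gW1;
    G[isW2] += cg.gsW;   G[isb2](0, 0) += cg.gsb;
    ga2 = &ctx.gcb;
  }
  ctx.gz2 = *ga2;
  for (uword i = 0; i < ctx.gz2.n_elem; ++i)
    if (ctx.z2(i) <= 0) ctx.gz2(i) = 0;

  {  // conv2 backward
    const mat Gm = cube_as_cmat(ctx.gz2);          // (H2*W2) x F2 view
    G[iW2] += Gm.t() * ctx.cols2;
    G[ib2].col(0) += sum(Gm, 0).t();
    ctx.gcols2 = Gm * P[iW2];                      // (H2*W2) x (F1*k*k)
    ctx.gp1.zeros(H2, W2, cfg.F1);
    col2im_t_add(ctx.gp1, ctx.gcols2, cfg.F1, cfg.k);
  }

  ctx.gc1.set_size(H, W, cfg.F1);
  maxpool_bwd(ctx.gp1, ctx.pool1, ctx.gc1);
  cube* ga1 = &ctx.gc1;
  if (cfg.cbam1) {
    CbamParams cp = cbam_par(P, 1, cfg.k);
    CbamGrads cg { zeros<mat>(size(cp.W0)), zeros<mat>(size(cp.W1)),
                   zeros<mat>(size(cp.sW)), 0.0 };
    cbam_bwd(ctx.gc1, cp, ctx.cb1, cg, ctx.gcb);
    G[icW0_1] += cg.gW0; G[icW1_1] += cg.gW1;
    G[isW1] += cg.gsW;   G[isb1](0, 0) += cg.gsb;
    ga1 = &ctx.gcb;
  }
  ctx.gz1 = *ga1;
  for (uword i = 0; i < ctx.gz1.n_elem; ++i)
    if (ctx.z1(i) <= 0) ctx.gz1(i) = 0;

  {  // conv1 backward (input gradient not needed)
    const mat Gm = cube_as_cmat(ctx.gz1);
    G[iW1] += Gm.t() * ctx.cols1;
    G[ib1].col(0) += sum(Gm, 0).t();
  }
}

// ------------------------------------------------------------- interface ---

// [[Rcpp::export]]
Rcpp::List cpp_nn_train(Rcpp::List params, const arma::cube& X,
                        const arma::ivec& y, Rcpp::List cfg_list) {
  Rcpp::RNGScope rng;
  NetCfg cfg = parse_cfg(cfg_list);
  std::vector<mat> P = parse_params(params);
  std::vector<mat> M(NPAR), U(NPAR), G(NPAR);
  for (int i = 0; i < NPAR; ++i) {
    M[i] = zeros<mat>(size(P[i]));
    U[i] = zeros<mat>(size(P[i]));
    G[i] = zeros<mat>(size(P[i]));
  }
  const int N = X.n_slices, H = X.n_rows, W = X.n_cols;
  long tstep = 0;
  std::vector<double> ep_loss, ep_acc;
  FwdCtx ctx;
  for (int ep = 0; ep < cfg.epochs; ++ep) {
    // Fisher-Yates shuffle driven by R's RNG (reproducible via set.seed)
    std::vector<int> ord(N);
    for (int i = 0; i < N; ++i) ord[i] = i;
    for (int i = N - 1; i > 0; --i) {
      int j = (int)std::floor(unif_rand() * (i + 1));
      if (j > i) j = i;
      std::swap(ord[i], ord[j]);
    }
    double loss = 0; int correct = 0;
    for (int start = 0; start < N; start += cfg.batch) {
      const int B = std::min(cfg.batch, N - start);
      for (int i = 0; i < NPAR; ++i) G[i].zeros();
      for (int b = 0; b < B; ++b) {
        const int n = ord[start + b];
        vec p = forward_sample(X.slice_memptr(n), H, W, P, cfg, true, ctx);
        loss += -std::log(std::max(p(y(n)), 1e-12));
        if (p.index_max() == (uword)y(n)) ++correct;
        backward_sample(ctx, y(n), P, cfg, G, 1.0 / B);
      }
      // Adamax update
      ++tstep;
      const double corr = 1.0 - std::pow(cfg.beta1, (double)tstep);
      for (int i = 0; i < NPAR; ++i) {
        M[i] = cfg.beta1 * M[i] + (1.0 - cfg.beta1) * G[i];
        U[i] = max(cfg.beta2 * U[i], abs(G[i]));
        P[i] -= (cfg.lr / corr) * (M[i] / (U[i] + cfg.eps));
      }
    }
    ep_loss.push_back(loss / N);
    ep_acc.push_back((double)correct / N);
    Rcpp::checkUserInterrupt();
  }
  return Rcpp::List::create(
    Rcpp::Named("params") = wrap_params(P),
    Rcpp::Named("loss") = ep_loss,
    Rcpp::Named("accuracy") = ep_acc);
}

// [[Rcpp::export]]
arma::mat cpp_nn_predict(Rcpp::List params, const arma::cube& X,
                         Rcpp::List cfg_list) {
  NetCfg cfg = parse_cfg(cfg_list);
  std::vector<mat> P = parse_params(params);
  mat out(X.n_slices, 2);
  FwdCtx ctx;
  for (uword n = 0; n < X.n_slices; ++n)
    out.row(n) = forward_sample(X.slice_memptr(n), X.n_rows, X.n_cols,
                                P, cfg, false, ctx).t();
  return out;
}

// loss and analytic gradients without dropout (for gradient checking)
// [[Rcpp::export]]
Rcpp::List cpp_nn_grad(Rcpp::List params, const arma::cube& X,
                       const arma::ivec& y, Rcpp::List cfg_list) {
  NetCfg cfg = parse_cfg(cfg_list);
  cfg.dropout = 0;
  std::vector<mat> P = parse_params(params);
  std::vector<mat> G(NPAR);
  for (int i = 0; i < NPAR; ++i) G[i] = zeros<mat>(size(P[i]));
  double loss = 0;
  const int N = X.n_slices;
  FwdCtx ctx;
  for (int n = 0; n < N; ++n) {
    vec p = forward_sample(X.slice_memptr(n), X.n_rows, X.n_cols,
                           P, cfg, false, ctx);
    loss += -std::log(std::max(p(y(n)), 1e-12)) / N;
    backward_sample(ctx, y(n), P, cfg, G, 1.0 / N);
  }
  return Rcpp::List::create(Rcpp::Named("loss") = loss,
                            Rcpp::Named("grads") = wrap_params(G));
}

// ---- granular operations exposed for oracle tests -------------------------

// same-padded single-sample convolution; x: H x W x Cin, W: Cout x (Cin*k*k)
// [[Rcpp::export]]
arma::cube cpp_conv2d(const arma::cube& x, const arma::mat& W,
                      const arma::vec& b, int k) {
  if ((int)W.n_cols != (int)x.n_slices * k * k)
    Rcpp::stop("kernel matrix does not match input channels");
  mat cols;
  im2col_t(x, x.n_slices, k, cols);
  cube y(x.n_rows, x.n_cols, W.n_rows);
  conv_fwd(cols, W, b, y);
  return y;
}

// [[Rcpp::export]]
arma::vec cpp_channel_attention(const arma::cube& F, const arma::mat& W0,
                                const arma::mat& W1) {
  if (W0.n_cols != F.n_slices || W1.n_rows != F.n_slices)
    Rcpp::stop("MLP weight shapes do not match the channel count");
  CbamParams cp { W0, W1, zeros<mat>(1, 2 * 49), 0.0, 7 };
  CbamCtx ctx;
  cube out;
  cbam_fwd(F, cp, ctx, out);
  return ctx.mc;
}

// [[Rcpp::export]]
arma::mat cpp_spatial_attention(const arma::cube& Fp, const arma::mat& sW,
                                double sb, int k) {
  if ((int)sW.n_cols != 2 * k * k)
    Rcpp::stop("spatial kernel must have 2*k*k weights");
  const int H = Fp.n_rows, W = Fp.n_cols;
  cube desc(H, W, 2);
  desc.slice(0) = mean(Fp, 2);
  desc.slice(1) = max(Fp, 2);
  mat cols;
  im2col_t(desc, 2, k, cols);
  vec pre = cols * sW.t() + sb;
  mat ms = reshape(pre, H, W);
  ms.transform(sigmoid_d);
  return ms;
}

// [[Rcpp::export]]
arma::cube cpp_cbam(const arma::cube& F, const arma::mat& W0,
                    const arma::mat& W1, const arma::mat& sW, double sb,
                    int k) {
  CbamParams cp { W0, W1, sW, sb, k };
  CbamCtx ctx;
  cube out;
  cbam_fwd(F, cp, ctx, out);
  return out;
}
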