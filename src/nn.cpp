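#include <RcppArmadillo.h>
#include <map>
#include <vector>
#include <string>
#include <cstring>
// [[Rcpp::depends(RcppArmadillo)]]
using namespace Rcpp;
using arma::fmat;
using arma::fcube;
using arma::fvec;

// A small single-precision graph executor for the 2-D segmentation
// networks. Activations are (H, W, C) cubes per sample; a network is a
// linear list of layer specs with explicit node references for skip
// connections. Convolutions go through an im2col laid out as (S, k*k*C)
// so that every inner loop is contiguous and the matrix products hit
// BLAS. All maths is deterministic.

struct LayerSpec {
  std::string op, name;
  int from, with, k, stride, pad, r;
  std::vector<std::string> pn;
};

typedef std::vector<fcube> Tensor; // one cube per batch sample

static std::vector<LayerSpec> parse_layers(List layers) {
  std::vector<LayerSpec> out;
  for (int i = 0; i < layers.size(); ++i) {
    List l = layers[i];
    LayerSpec s;
    s.op   = as<std::string>(l["op"]);
    s.name = l.containsElementNamed("name") ? as<std::string>(l["name"]) : "";
    s.from = l.containsElementNamed("from") ? as<int>(l["from"]) : -1;
    s.with = l.containsElementNamed("with") ? as<int>(l["with"]) : -1;
    s.k      = l.containsElementNamed("k") ? as<int>(l["k"]) : 3;
    s.stride = l.containsElementNamed("stride") ? as<int>(l["stride"]) : 1;
    s.pad    = l.containsElementNamed("pad") ? as<int>(l["pad"]) : -999;
    s.r      = l.containsElementNamed("r") ? as<int>(l["r"]) : 2;
    if (s.pad == -999) s.pad = (s.k - 1) / 2;
    if (l.containsElementNamed("pn")) {
      CharacterVector pn = l["pn"];
      for (int j = 0; j < pn.size(); ++j) s.pn.push_back(as<std::string>(pn[j]));
    }
    out.push_back(s);
  }
  return out;
}

struct ParamStore {
  std::map<std::string, fvec> val;
  std::map<std::string, IntegerVector> dims;
  void load(List params) {
    CharacterVector nm = params.names();
    for (int i = 0; i < params.size(); ++i) {
      NumericVector p = params[i];
      std::string n = as<std::string>(nm[i]);
      fvec v(p.size());
      const double* src = p.begin();
      for (R_xlen_t j = 0; j < p.size(); ++j) v[j] = (float)src[j];
      val[n] = v;
      RObject d = p.attr("dim");
      dims[n] = d.isNULL() ? IntegerVector::create((int)p.size())
                           : as<IntegerVector>(d);
    }
  }
};

static double dsum(const float* p, size_t n) {
  double s = 0;
  for (size_t i = 0; i < n; ++i) s += p[i];
  return s;
}

// im2col with columns indexed by (ki, kj, c) and rows by s = ho + Ho*wo.
static fmat im2col_t(const fcube& x, int k, int stride, int pad,
                     int Ho, int Wo) {
  const int H = x.n_rows, W = x.n_cols, C = x.n_slices;
  const int S = Ho * Wo;
  fmat cols(S, k * k * C, arma::fill::zeros);
  for (int c = 0; c < C; ++c) {
    const float* xc = x.slice_memptr(c);
    for (int kj = 0; kj < k; ++kj)
      for (int ki = 0; ki < k; ++ki) {
        float* dst = cols.colptr(ki + k * (kj + k * c));
        const int ho0 = std::max(0, (pad - ki + stride - 1) / stride);
        const int ho1 = std::min(Ho - 1, (H - 1 + pad - ki) / stride);
        for (int wo = 0; wo < Wo; ++wo) {
          const int wi = wo * stride - pad + kj;
          if (wi < 0 || wi >= W) continue;
          const float* src = xc + (size_t)H * wi - pad + ki;
          float* d2 = dst + (size_t)Ho * wo;
          if (stride == 1)
            for (int ho = ho0; ho <= ho1; ++ho) d2[ho] = src[ho];
          else
            for (int ho = ho0; ho <= ho1; ++ho) d2[ho] = src[ho * stride];
        }
      }
  }
  return cols;
}

static void col2im_acc_t(const fmat& cols, fcube& dx, int k, int stride,
                         int pad, int Ho, int Wo) {
  const int H = dx.n_rows, W = dx.n_cols, C = dx.n_slices;
  for (int c = 0; c < C; ++c) {
    float* xc = dx.slice_memptr(c);
    for (int kj = 0; kj < k; ++kj)
      for (int ki = 0; ki < k; ++ki) {
        const float* src0 = cols.colptr(ki + k * (kj + k * c));
        const int ho0 = std::max(0, (pad - ki + stride - 1) / stride);
        const int ho1 = std::min(Ho - 1, (H - 1 + pad - ki) / stride);
        for (int wo = 0; wo < Wo; ++wo) {
          const int wi = wo * stride - pad + kj;
          if (wi < 0 || wi >= W) continue;
          float* d2 = xc + (size_t)H * wi - pad + ki;
          const float* src = src0 + (size_t)Ho * wo;
          if (stride == 1)
            for (int ho = ho0; ho <= ho1; ++ho) d2[ho] += src[ho];
          else
            for (int ho = ho0; ho <= ho1; ++ho) d2[ho * stride] += src[ho];
        }
      }
  }
}

// Flatten (H, W, C) cube to (S, C) matrix (pure memcpy) and back.
static fmat cube_to_mat(const fcube& x) {
  const int S = x.n_rows * x.n_cols, C = x.n_slices;
  fmat m(S, C);
  for (int c = 0; c < C; ++c)
    std::memcpy(m.colptr(c), x.slice_memptr(c), sizeof(float) * S);
  return m;
}

struct RunState {
  std::vector<fvec> bnMean, bnVar;
  std::vector<std::vector<arma::uvec>> poolIdx;       // argmax offsets
  std::vector<std::vector<fmat>> atF, atG, atH, atB;  // attention caches
};

static Tensor layer_forward(const LayerSpec& L, const Tensor& in,
                            const Tensor* with, ParamStore& P,
                            List& bnstate, bool train, int li, RunState& st,
                            List& bnNew) {
  const int N = in.size();
  Tensor out(N);
  if (L.op == "conv") {
    const fvec& wv = P.val[L.pn[0]];
    const fvec& bv = P.val[L.pn[1]];
    IntegerVector wd = P.dims[L.pn[0]]; // (k, k, Cin, Cout)
    const int k = wd[0], Cin = wd[2], Cout = wd[3];
    const fmat Wm(const_cast<float*>(wv.memptr()), k * k * Cin, Cout,
                  false, true);
    for (int n = 0; n < N; ++n) {
      const int H = in[n].n_rows, W = in[n].n_cols;
      const int Ho = (H + 2 * L.pad - k) / L.stride + 1;
      const int Wo = (W + 2 * L.pad - k) / L.stride + 1;
      const int S = Ho * Wo;
      fmat cols = im2col_t(in[n], k, L.stride, L.pad, Ho, Wo);
      fmat Y = cols * Wm; // (S, Cout)
      out[n].set_size(Ho, Wo, Cout);
      for (int co = 0; co < Cout; ++co) {
        float* o = out[n].slice_memptr(co);
        const float* y = Y.colptr(co);
        const float b = bv[co];
        for (int s = 0; s < S; ++s) o[s] = y[s] + b;
      }
    }
  } else if (L.op == "convt") { // kernel 2, stride 2
    const fvec& wv = P.val[L.pn[0]];
    const fvec& bv = P.val[L.pn[1]];
    IntegerVector wd = P.dims[L.pn[0]]; // (2, 2, Cin, Cout)
    const int Cin = wd[2], Cout = wd[3];
    for (int n = 0; n < N; ++n) {
      const int H = in[n].n_rows, W = in[n].n_cols;
      const int S = H * W;
      out[n].set_size(2 * H, 2 * W, Cout);
      fmat Xm = cube_to_mat(in[n]); // (S, Cin)
      for (int dj = 0; dj < 2; ++dj)
        for (int di = 0; di < 2; ++di) {
          fmat Ws(Cin, Cout);
          for (int co = 0; co < Cout; ++co)
            for (int ci = 0; ci < Cin; ++ci)
              Ws(ci, co) = wv[di + 2 * (dj + 2 * (ci + (R_xlen_t)Cin * co))];
          fmat Y = Xm * Ws; // (S, Cout)
          for (int co = 0; co < Cout; ++co) {
            float* oc = out[n].slice_memptr(co);
            const float* y = Y.colptr(co);
            const float b = bv[co];
            for (int w = 0; w < W; ++w) {
              float* o = oc + (size_t)2 * H * (2 * w + dj) + di;
              const float* ys = y + (size_t)H * w;
              for (int h = 0; h < H; ++h) o[2 * h] = ys[h] + b;
            }
          }
        }
    }
  } else if (L.op == "bn") {
    const fvec& g = P.val[L.pn[0]];
    const fvec& b = P.val[L.pn[1]];
    const int C = in[0].n_slices;
    fvec mean(C), var(C);
    if (train) {
      for (int c = 0; c < C; ++c) {
        double s = 0, ss = 0; size_t m = 0;
        for (int n = 0; n < N; ++n) {
          const float* p = in[n].slice_memptr(c);
          const size_t sz = in[n].n_rows * in[n].n_cols;
          for (size_t i = 0; i < sz; ++i) { s += p[i]; ss += p[i] * p[i]; }
          m += sz;
        }
        const double mu = s / m;
        mean[c] = (float)mu;
        double v = ss / m - mu * mu;
        var[c] = (float)(v > 0 ? v : 0);
      }
      NumericVector rm = bnstate[L.name + ".mean"];
      NumericVector rv = bnstate[L.name + ".var"];
      NumericVector nm(C), nv(C);
      for (int c = 0; c < C; ++c) {
        nm[c] = 0.9 * rm[c] + 0.1 * mean[c];
        nv[c] = 0.9 * rv[c] + 0.1 * var[c];
      }
      bnNew[L.name + ".mean"] = nm;
      bnNew[L.name + ".var"] = nv;
    } else {
      NumericVector rm = bnstate[L.name + ".mean"];
      NumericVector rv = bnstate[L.name + ".var"];
      for (int c = 0; c < C; ++c) { mean[c] = rm[c]; var[c] = rv[c]; }
    }
    st.bnMean[li] = mean; st.bnVar[li] = var;
    const float eps = 1e-5f;
    for (int n = 0; n < N; ++n) {
      out[n].set_size(arma::size(in[n]));
      const size_t sz = in[n].n_rows * in[n].n_cols;
      for (int c = 0; c < C; ++c) {
        const float iv = g[c] / std::sqrt(var[c] + eps);
        const float sh = b[c] - mean[c] * iv;
        const float* p = in[n].slice_memptr(c);
        float* o = out[n].slice_memptr(c);
        for (size_t i = 0; i < sz; ++i) o[i] = p[i] * iv + sh;
      }
    }
  } else if (L.op == "relu") {
    for (int n = 0; n < N; ++n) out[n] = arma::clamp(in[n], 0.0f, 3e38f);
  } else if (L.op == "add") {
    for (int n = 0; n < N; ++n) out[n] = in[n] + (*with)[n];
  } else if (L.op == "concat") {
    for (int n = 0; n < N; ++n)
      out[n] = arma::join_slices(in[n], (*with)[n]);
  } else if (L.op == "maxpool") {
    st.poolIdx[li].resize(N);
    for (int n = 0; n < N; ++n) {
      const int H = in[n].n_rows, W = in[n].n_cols, C = in[n].n_slices;
      const int Ho = H / 2, Wo = W / 2;
      out[n].set_size(Ho, Wo, C);
      st.poolIdx[li][n].set_size((size_t)Ho * Wo * C);
      arma::uvec& idx = st.poolIdx[li][n];
      size_t q = 0;
      for (int c = 0; c < C; ++c) {
        const float* p = in[n].slice_memptr(c);
        float* o = out[n].slice_memptr(c);
        for (int w = 0; w < Wo; ++w)
          for (int h = 0; h < Ho; ++h) {
            const size_t base = (size_t)2 * h + (size_t)H * 2 * w;
            size_t best = base; float bv2 = p[base];
            const size_t cand[3] = {base + 1, base + H, base + H + 1};
            for (int t = 0; t < 3; ++t)
              if (p[cand[t]] > bv2) { bv2 = p[cand[t]]; best = cand[t]; }
            o[h + (size_t)Ho * w] = bv2;
            idx[q++] = best;
          }
      }
    }
  } else if (L.op == "pshuffle") {
    const int r = L.r;
    for (int n = 0; n < N; ++n) {
      const int H = in[n].n_rows, W = in[n].n_cols, C4 = in[n].n_slices;
      const int C = C4 / (r * r), Ho = H * r;
      out[n].set_size(Ho, W * r, C);
      for (int c = 0; c < C; ++c) {
        float* oc = out[n].slice_memptr(c);
        for (int dy = 0; dy < r; ++dy)
          for (int dx = 0; dx < r; ++dx) {
            const float* ic = in[n].slice_memptr(c * r * r + dy * r + dx);
            for (int w = 0; w < W; ++w) {
              float* o = oc + (size_t)Ho * (w * r + dx) + dy;
              const float* s = ic + (size_t)H * w;
              for (int h = 0; h < H; ++h) o[(size_t)h * r] = s[h];
            }
          }
      }
    }
  } else if (L.op == "sattn") {
    const fvec& wf = P.val[L.pn[0]];
    const fvec& wg = P.val[L.pn[1]];
    const fvec& wh = P.val[L.pn[2]];
    const float gamma = P.val[L.pn[3]][0];
    const int C = in[0].n_slices, C8 = P.dims[L.pn[0]][1];
    const fmat Wf(const_cast<float*>(wf.memptr()), C, C8, false, true);
    const fmat Wg(const_cast<float*>(wg.memptr()), C, C8, false, true);
    const fmat Wh(const_cast<float*>(wh.memptr()), C, C, false, true);
    st.atF[li].resize(N); st.atG[li].resize(N);
    st.atH[li].resize(N); st.atB[li].resize(N);
    for (int n = 0; n < N; ++n) {
      const int H = in[n].n_rows, W = in[n].n_cols, S = H * W;
      fmat X = cube_to_mat(in[n]).t(); // (C, S)
      fmat F = Wf.t() * X, G = Wg.t() * X, Hh = Wh.t() * X;
      fmat E = F.t() * G; // (S, S): E(i, j) = f_i . g_j
      fmat B(S, S);
      for (int j = 0; j < S; ++j) {
        fvec col = E.col(j);
        col -= col.max();
        fvec e = arma::exp(col);
        B.col(j) = e / arma::accu(e);
      }
      fmat O = Hh * B; // (C, S)
      st.atF[li][n] = F; st.atG[li][n] = G; st.atH[li][n] = Hh;
      st.atB[li][n] = B;
      fmat Ym = (X + gamma * O).t(); // (S, C)
      out[n].set_size(H, W, C);
      for (int c = 0; c < C; ++c)
        std::memcpy(out[n].slice_memptr(c), Ym.colptr(c),
                    sizeof(float) * S);
    }
  } else if (L.op == "softmax") {
    for (int n = 0; n < N; ++n) {
      const int H = in[n].n_rows, W = in[n].n_cols, C = in[n].n_slices;
      const size_t S = (size_t)H * W;
      out[n].set_size(H, W, C);
      if (C == 2) {
        const float* a = in[n].slice_memptr(0);
        const float* b = in[n].slice_memptr(1);
        float* oa = out[n].slice_memptr(0);
        float* ob = out[n].slice_memptr(1);
        for (size_t s = 0; s < S; ++s) {
          const float m = std::max(a[s], b[s]);
          const float ea = std::exp(a[s] - m), eb = std::exp(b[s] - m);
          const float z = ea + eb;
          oa[s] = ea / z; ob[s] = eb / z;
        }
      } else {
        for (size_t s = 0; s < S; ++s) {
          float mx = -3e38f;
          for (int c = 0; c < C; ++c)
            mx = std::max(mx, in[n].slice_memptr(c)[s]);
          float z = 0;
          for (int c = 0; c < C; ++c) {
            const float e = std::exp(in[n].slice_memptr(c)[s] - mx);
            out[n].slice_memptr(c)[s] = e;
            z += e;
          }
          for (int c = 0; c < C; ++c) out[n].slice_memptr(c)[s] /= z;
        }
      }
    }
  } else {
    stop("unknown layer op: " + L.op);
  }
  return out;
}

static void acc_grad(std::map<std::string, fvec>& G, const std::string& n,
                     const fvec& g) {
  auto it = G.find(n);
  if (it == G.end()) G[n] = g; else it->second += g;
}

// [[Rcpp::export]]
List cpp_net_run(List layers, List params, List bnstate, NumericVector x,
                 Nullable<NumericVector> target, bool train) {
  std::vector<LayerSpec> L = parse_layers(layers);
  const int nl = (int)L.size();
  ParamStore P;
  P.load(params);
  IntegerVector xd = x.attr("dim"); // (H, W, C, N)
  const int H0 = xd[0], W0 = xd[1], C0 = xd[2], N = xd[3];
  Tensor input(N);
  for (int n = 0; n < N; ++n) {
    input[n].set_size(H0, W0, C0);
    const double* src = x.begin() + (R_xlen_t)n * H0 * W0 * C0;
    float* dst = input[n].memptr();
    const R_xlen_t sz = (R_xlen_t)H0 * W0 * C0;
    for (R_xlen_t i = 0; i < sz; ++i) dst[i] = (float)src[i];
  }
  RunState st;
  st.bnMean.resize(nl); st.bnVar.resize(nl);
  st.poolIdx.resize(nl);
  st.atF.resize(nl); st.atG.resize(nl); st.atH.resize(nl); st.atB.resize(nl);
  List bnNew = clone(bnstate);
  std::vector<Tensor> node(nl + 1);
  node[0] = input;
  for (int i = 0; i < nl; ++i) {
    int from = (L[i].from < 0) ? i : L[i].from;
    const Tensor* withT = (L[i].with >= 0) ? &node[L[i].with] : nullptr;
    node[i + 1] = layer_forward(L[i], node[from], withT, P, bnstate, train,
                                i, st, bnNew);
  }
  const Tensor& probs = node[nl];
  if (target.isNull()) {
    const int Ho = probs[0].n_rows, Wo = probs[0].n_cols,
              Co = probs[0].n_slices;
    NumericVector out((R_xlen_t)Ho * Wo * Co * N);
    for (int n = 0; n < N; ++n) {
      double* dst = out.begin() + (R_xlen_t)n * Ho * Wo * Co;
      const float* src = probs[n].memptr();
      const R_xlen_t sz = (R_xlen_t)Ho * Wo * Co;
      for (R_xlen_t i = 0; i < sz; ++i) dst[i] = src[i];
    }
    out.attr("dim") = IntegerVector::create(Ho, Wo, Co, N);
    return List::create(_["probs"] = out);
  }

  // ---- generalized Dice loss over the pooled batch ----
  NumericVector tv(target);
  const int nc = probs[0].n_slices;
  Tensor tgt(N);
  {
    IntegerVector td = tv.attr("dim");
    if (td[0] != (int)probs[0].n_rows || td[1] != (int)probs[0].n_cols ||
        td[2] != nc || td[3] != N)
      stop("target shape does not match network output");
    for (int n = 0; n < N; ++n) {
      tgt[n].set_size(td[0], td[1], td[2]);
      const double* src = tv.begin() + (R_xlen_t)n * td[0] * td[1] * td[2];
      float* dst = tgt[n].memptr();
      const R_xlen_t sz = (R_xlen_t)td[0] * td[1] * td[2];
      for (R_xlen_t i = 0; i < sz; ++i) dst[i] = (float)src[i];
    }
  }
  std::vector<double> rl(nc, 0), pl(nc, 0), il(nc, 0), wl(nc, 0);
  for (int n = 0; n < N; ++n) {
    const size_t sz = (size_t)probs[n].n_rows * probs[n].n_cols;
    for (int c = 0; c < nc; ++c) {
      const float* t = tgt[n].slice_memptr(c);
      const float* p = probs[n].slice_memptr(c);
      double a = 0, b = 0, d = 0;
      for (size_t i = 0; i < sz; ++i) { a += t[i]; b += p[i]; d += t[i] * p[i]; }
      rl[c] += a; pl[c] += b; il[c] += d;
    }
  }
  double Nn = 0, Dd = 0;
  for (int c = 0; c < nc; ++c) {
    wl[c] = rl[c] > 0 ? 1.0 / (rl[c] * rl[c]) : 0.0;
    Nn += wl[c] * il[c];
    Dd += wl[c] * (rl[c] + pl[c]);
  }
  double loss = (Dd > 0) ? 1.0 - 2.0 * Nn / Dd : 0.0;

  std::vector<Tensor> grad(nl + 1);
  grad[nl].resize(N);
  for (int n = 0; n < N; ++n) {
    grad[nl][n].set_size(arma::size(probs[n]));
    const size_t sz = (size_t)probs[n].n_rows * probs[n].n_cols;
    for (int c = 0; c < nc; ++c) {
      float* g = grad[nl][n].slice_memptr(c);
      const float* t = tgt[n].slice_memptr(c);
      if (Dd > 0) {
        const float a = (float)(-2.0 * wl[c] / Dd);
        const float b = (float)(-2.0 * wl[c] * (-Nn) / (Dd * Dd));
        // d/dp [1 - 2N/D] = -2 (w t D - N w) / D^2
        const float c1 = (float)(-2.0 * wl[c] / Dd);
        const float c0 = (float)(2.0 * wl[c] * Nn / (Dd * Dd));
        (void)a; (void)b;
        for (size_t i = 0; i < sz; ++i) g[i] = c1 * t[i] + c0;
      } else {
        std::memset(g, 0, sizeof(float) * sz);
      }
    }
  }

  std::map<std::string, fvec> G;
  for (int i = nl - 1; i >= 0; --i) {
    const LayerSpec& Li = L[i];
    Tensor& dout = grad[i + 1];
    if (dout.empty()) continue;
    int fromNode = (Li.from < 0) ? i : Li.from;
    Tensor& inT = node[fromNode];
    const int Nb = (int)dout.size();
    auto ensure = [&](int nodeId, const Tensor& like) {
      if (grad[nodeId].empty()) {
        grad[nodeId].resize(like.size());
        for (size_t n = 0; n < like.size(); ++n)
          grad[nodeId][n].zeros(like[n].n_rows, like[n].n_cols,
                                like[n].n_slices);
      }
    };
    if (Li.op == "conv") {
      const fvec& wv = P.val[Li.pn[0]];
      IntegerVector wd = P.dims[Li.pn[0]];
      const int k = wd[0], Cin = wd[2], Cout = wd[3];
      const fmat Wm(const_cast<float*>(wv.memptr()), k * k * Cin, Cout,
                    false, true);
      fvec dW(wv.n_elem, arma::fill::zeros), dB(Cout, arma::fill::zeros);
      fmat dWm(dW.memptr(), k * k * Cin, Cout, false, true);
      ensure(fromNode, inT);
      for (int n = 0; n < Nb; ++n) {
        const int Ho = dout[n].n_rows, Wo = dout[n].n_cols;
        fmat dY = cube_to_mat(dout[n]); // (S, Cout)
        fmat cols = im2col_t(inT[n], k, Li.stride, Li.pad, Ho, Wo);
        dWm += cols.t() * dY;
        for (int co = 0; co < Cout; ++co)
          dB[co] += (float)dsum(dY.colptr(co), dY.n_rows);
        fmat dcols = dY * Wm.t(); // (S, kkC)
        col2im_acc_t(dcols, grad[fromNode][n], k, Li.stride, Li.pad, Ho, Wo);
      }
      acc_grad(G, Li.pn[0], dW);
      acc_grad(G, Li.pn[1], dB);
    } else if (Li.op == "convt") {
      const fvec& wv = P.val[Li.pn[0]];
      IntegerVector wd = P.dims[Li.pn[0]];
      const int Cin = wd[2], Cout = wd[3];
      fvec dW(wv.n_elem, arma::fill::zeros), dB(Cout, arma::fill::zeros);
      ensure(fromNode, inT);
      for (int n = 0; n < Nb; ++n) {
        const int H = inT[n].n_rows, W = inT[n].n_cols;
        fmat Xm = cube_to_mat(inT[n]); // (S, Cin)
        for (int dj = 0; dj < 2; ++dj)
          for (int di = 0; di < 2; ++di) {
            fmat dY(H * W, Cout);
            for (int co = 0; co < Cout; ++co) {
              const float* dc = dout[n].slice_memptr(co);
              float* y = dY.colptr(co);
              for (int w = 0; w < W; ++w) {
                const float* o = dc + (size_t)2 * H * (2 * w + dj) + di;
                float* ys = y + (size_t)H * w;
                for (int h = 0; h < H; ++h) ys[h] = o[2 * h];
              }
            }
            fmat Ws(Cin, Cout);
            for (int co = 0; co < Cout; ++co)
              for (int ci = 0; ci < Cin; ++ci)
                Ws(ci, co) = wv[di + 2 * (dj + 2 * (ci + (R_xlen_t)Cin * co))];
            fmat dWs = Xm.t() * dY; // (Cin, Cout)
            for (int co = 0; co < Cout; ++co) {
              for (int ci = 0; ci < Cin; ++ci)
                dW[di + 2 * (dj + 2 * (ci + (R_xlen_t)Cin * co))] +=
                  dWs(ci, co);
              dB[co] += (float)dsum(dY.colptr(co), dY.n_rows);
            }
            fmat dX = dY * Ws.t(); // (S, Cin)
            for (int c = 0; c < Cin; ++c) {
              float* g = grad[fromNode][n].slice_memptr(c);
              const float* s = dX.colptr(c);
              const size_t sz = (size_t)H * W;
              for (size_t q = 0; q < sz; ++q) g[q] += s[q];
            }
          }
      }
      acc_grad(G, Li.pn[0], dW);
      acc_grad(G, Li.pn[1], dB);
    } else if (Li.op == "bn") {
      const fvec& g = P.val[Li.pn[0]];
      const int C = inT[0].n_slices;
      const float eps = 1e-5f;
      fvec dG(C, arma::fill::zeros), dBt(C, arma::fill::zeros);
      ensure(fromNode, inT);
      for (int c = 0; c < C; ++c) {
        const float mu = st.bnMean[i][c];
        const float iv = 1.0f / std::sqrt(st.bnVar[i][c] + eps);
        double sdy = 0, sdyx = 0; size_t M = 0;
        for (int n = 0; n < Nb; ++n) {
          const float* xp = inT[n].slice_memptr(c);
          const float* dp = dout[n].slice_memptr(c);
          const size_t sz = (size_t)inT[n].n_rows * inT[n].n_cols;
          for (size_t q = 0; q < sz; ++q) {
            sdy += dp[q];
            sdyx += dp[q] * (xp[q] - mu) * iv;
          }
          M += sz;
        }
        dG[c] = (float)sdyx;
        dBt[c] = (float)sdy;
        const float gc = g[c];
        const float mdy = (float)(sdy / M), mdyx = (float)(sdyx / M);
        for (int n = 0; n < Nb; ++n) {
          const float* xp = inT[n].slice_memptr(c);
          const float* dp = dout[n].slice_memptr(c);
          float* gp = grad[fromNode][n].slice_memptr(c);
          const size_t sz = (size_t)inT[n].n_rows * inT[n].n_cols;
          if (train)
            for (size_t q = 0; q < sz; ++q)
              gp[q] += gc * iv * (dp[q] - mdy - (xp[q] - mu) * iv * mdyx);
          else
            for (size_t q = 0; q < sz; ++q) gp[q] += gc * iv * dp[q];
        }
      }
      acc_grad(G, Li.pn[0], dG);
      acc_grad(G, Li.pn[1], dBt);
    } else if (Li.op == "relu") {
      ensure(fromNode, inT);
      for (int n = 0; n < Nb; ++n) {
        const float* xp = inT[n].memptr();
        const float* dp = dout[n].memptr();
        float* gp = grad[fromNode][n].memptr();
        const size_t sz = inT[n].n_elem;
        for (size_t q = 0; q < sz; ++q)
          if (xp[q] > 0) gp[q] += dp[q];
      }
    } else if (Li.op == "add") {
      ensure(fromNode, inT);
      ensure(Li.with, node[Li.with]);
      for (int n = 0; n < Nb; ++n) {
        grad[fromNode][n] += dout[n];
        grad[Li.with][n] += dout[n];
      }
    } else if (Li.op == "concat") {
      ensure(fromNode, inT);
      ensure(Li.with, node[Li.with]);
      const int C1 = inT[0].n_slices;
      const int C2 = node[Li.with][0].n_slices;
      for (int n = 0; n < Nb; ++n) {
        grad[fromNode][n] += dout[n].slices(0, C1 - 1);
        grad[Li.with][n] += dout[n].slices(C1, C1 + C2 - 1);
      }
    } else if (Li.op == "maxpool") {
      ensure(fromNode, inT);
      for (int n = 0; n < Nb; ++n) {
        const int Ho = dout[n].n_rows, Wo = dout[n].n_cols,
                  C = dout[n].n_slices;
        const arma::uvec& idx = st.poolIdx[i][n];
        size_t q = 0;
        for (int c = 0; c < C; ++c) {
          float* gp = grad[fromNode][n].slice_memptr(c);
          const float* dp = dout[n].slice_memptr(c);
          for (int w = 0; w < Wo; ++w)
            for (int h = 0; h < Ho; ++h)
              gp[idx[q++]] += dp[h + (size_t)Ho * w];
        }
      }
    } else if (Li.op == "pshuffle") {
      ensure(fromNode, inT);
      const int r = Li.r;
      for (int n = 0; n < Nb; ++n) {
        const int H = inT[n].n_rows, W = inT[n].n_cols;
        const int C = dout[n].n_slices, Ho = H * r;
        for (int c = 0; c < C; ++c) {
          const float* dc = dout[n].slice_memptr(c);
          for (int dy = 0; dy < r; ++dy)
            for (int dx = 0; dx < r; ++dx) {
              float* gp = grad[fromNode][n].slice_memptr(c * r * r +
                                                         dy * r + dx);
              for (int w = 0; w < W; ++w) {
                const float* o = dc + (size_t)Ho * (w * r + dx) + dy;
                float* gs = gp + (size_t)H * w;
                for (int h = 0; h < H; ++h) gs[h] += o[(size_t)h * r];
              }
            }
        }
      }
    } else if (Li.op == "sattn") {
      const fvec& wf = P.val[Li.pn[0]];
      const fvec& wg = P.val[Li.pn[1]];
      const fvec& wh = P.val[Li.pn[2]];
      const float gamma = P.val[Li.pn[3]][0];
      const int C = inT[0].n_slices, C8 = P.dims[Li.pn[0]][1];
      const fmat Wf(const_cast<float*>(wf.memptr()), C, C8, false, true);
      const fmat Wg(const_cast<float*>(wg.memptr()), C, C8, false, true);
      const fmat Wh(const_cast<float*>(wh.memptr()), C, C, false, true);
      fvec dWf(wf.n_elem, arma::fill::zeros),
           dWg(wg.n_elem, arma::fill::zeros),
           dWh(wh.n_elem, arma::fill::zeros), dGam(1, arma::fill::zeros);
      fmat dWfM(dWf.memptr(), C, C8, false, true);
      fmat dWgM(dWg.memptr(), C, C8, false, true);
      fmat dWhM(dWh.memptr(), C, C, false, true);
      ensure(fromNode, inT);
      for (int n = 0; n < Nb; ++n) {
        const int H = inT[n].n_rows, W = inT[n].n_cols, S = H * W;
        fmat X = cube_to_mat(inT[n]).t();  // (C, S)
        fmat dY = cube_to_mat(dout[n]).t();
        const fmat& F = st.atF[i][n];
        const fmat& Gm = st.atG[i][n];
        const fmat& Hm = st.atH[i][n];
        const fmat& B = st.atB[i][n];
        fmat O = Hm * B;
        dGam[0] += (float)arma::accu(dY % O);
        fmat dO = gamma * dY;
        fmat dH = dO * B.t();
        fmat dBm = Hm.t() * dO;
        fmat dE(S, S);
        for (int j = 0; j < S; ++j) {
          fvec bj = B.col(j), dbj = dBm.col(j);
          const float dot = arma::dot(bj, dbj);
          dE.col(j) = bj % (dbj - dot);
        }
        fmat dF = Gm * dE.t();
        fmat dG2 = F * dE;
        dWfM += X * dF.t();
        dWgM += X * dG2.t();
        dWhM += X * dH.t();
        fmat dX = (dY + Wf * dF + Wg * dG2 + Wh * dH).t(); // (S, C)
        for (int c = 0; c < C; ++c) {
          float* gp = grad[fromNode][n].slice_memptr(c);
          const float* s = dX.colptr(c);
          for (int q = 0; q < S; ++q) gp[q] += s[q];
        }
      }
      acc_grad(G, Li.pn[0], dWf);
      acc_grad(G, Li.pn[1], dWg);
      acc_grad(G, Li.pn[2], dWh);
      acc_grad(G, Li.pn[3], dGam);
    } else if (Li.op == "softmax") {
      ensure(fromNode, inT);
      const Tensor& y = node[i + 1];
      for (int n = 0; n < Nb; ++n) {
        const int C = y[n].n_slices;
        const size_t S = (size_t)y[n].n_rows * y[n].n_cols;
        if (C == 2) {
          const float* ya = y[n].slice_memptr(0);
          const float* yb = y[n].slice_memptr(1);
          const float* da = dout[n].slice_memptr(0);
          const float* db = dout[n].slice_memptr(1);
          float* ga = grad[fromNode][n].slice_memptr(0);
          float* gb = grad[fromNode][n].slice_memptr(1);
          for (size_t s = 0; s < S; ++s) {
            const float dot = da[s] * ya[s] + db[s] * yb[s];
            ga[s] += ya[s] * (da[s] - dot);
            gb[s] += yb[s] * (db[s] - dot);
          }
        } else {
          for (size_t s = 0; s < S; ++s) {
            float dot = 0;
            for (int c = 0; c < C; ++c)
              dot += dout[n].slice_memptr(c)[s] * y[n].slice_memptr(c)[s];
            for (int c = 0; c < C; ++c)
              grad[fromNode][n].slice_memptr(c)[s] +=
                y[n].slice_memptr(c)[s] * (dout[n].slice_memptr(c)[s] - dot);
          }
        }
      }
    } else {
      stop("unknown layer op in backward: " + Li.op);
    }
  }

  List gradOut;
  CharacterVector nm = params.names();
  for (int i = 0; i < params.size(); ++i) {
    std::string n = as<std::string>(nm[i]);
    auto it = G.find(n);
    NumericVector gv(P.val[n].n_elem);
    if (it != G.end())
      for (R_xlen_t j = 0; j < gv.size(); ++j) gv[j] = it->second[j];
    NumericVector orig = params[i];
    RObject d = orig.attr("dim");
    if (!d.isNULL()) gv.attr("dim") = d;
    gradOut[n] = gv;
  }
  return List::create(_["loss"] = loss, _["grads"] = gradOut,
                      _["bn"] = bnNew);
}

// Single-sample convolution helper for initialization checks and tests.
// x: (H, W, Cin); w: (k, k, Cin, Cout); returns (Ho, Wo, Cout).
// [[Rcpp::export]]
NumericVector cpp_conv2d(NumericVector x, NumericVector w, NumericVector bias,
                         int stride, int pad) {
  IntegerVector xd = x.attr("dim"), wd = w.attr("dim");
  const int H = xd[0], W = xd[1], C = xd[2];
  const int k = wd[0], Cout = wd[3];
  fcube xc(H, W, C);
  { float* p = xc.memptr();
    for (R_xlen_t i = 0; i < x.size(); ++i) p[i] = (float)x[i]; }
  const int Ho = (H + 2 * pad - k) / stride + 1;
  const int Wo = (W + 2 * pad - k) / stride + 1;
  fvec wv(w.size());
  for (R_xlen_t j = 0; j < w.size(); ++j) wv[j] = (float)w[j];
  const fmat Wm(const_cast<float*>(wv.memptr()), k * k * C, Cout, false, true);
  fmat cols = im2col_t(xc, k, stride, pad, Ho, Wo);
  fmat Y = cols * Wm;
  NumericVector out((R_xlen_t)Ho * Wo * Cout);
  for (int co = 0; co < Cout; ++co)
    for (int s = 0; s < Ho * Wo; ++s)
      out[s + (R_xlen_t)Ho * Wo * co] = Y(s, co) + bias[co];
  out.attr("dim") = IntegerVector::create(Ho, Wo, Cout);
  return out;
}

// Pixel shuffle of a single (H, W, C*r^2) array to (H*r, W*r, C); channel
// c*r^2 + dy*r + dx feeds spatial offset (dy, dx).
// [[Rcpp::export]]
NumericVector cpp_pixel_shuffle(NumericVector x, int r) {
  IntegerVector xd = x.attr("dim");
  const int H = xd[0], W = xd[1], C4 = xd[2], C = C4 / (r * r);
  NumericVector out((R_xlen_t)H * r * W * r * C);
  const int Ho = H * r, Wo = W * r;
  for (int c = 0; c < C; ++c)
    for (int dy = 0; dy < r; ++dy)
      for (int dx = 0; dx < r; ++dx) {
        const int ci = c * r * r + dy * r + dx;
        for (int w = 0; w < W; ++w)
          for (int h = 0; h < H; ++h)
            out[(h * r + dy) + (R_xlen_t)Ho * (w * r + dx) +
                (R_xlen_t)Ho * Wo * c] =
              x[h + (R_xlen_t)H * w + (R_xlen_t)H * W * ci];
      }
  out.attr("dim") = IntegerVector::create(Ho, Wo, C);
  return out;
}
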