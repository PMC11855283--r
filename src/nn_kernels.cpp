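// Numerical kernels: 3D convolution (im2col + BLAS gemm), 3D max pooling,
// and cell-list geometry queries (cutoff contact tests, dot occlusion).
// Activations are laid out as column-major (D, H, W, C, N) arrays; conv
// weights as (K, K, K, Cin, Cout).
#include <RcppArmadillo.h>
#include <unordered_map>
#include <vector>
// [[Rcpp::depends(RcppArmadillo)]]
using namespace Rcpp;

static inline long long cell_key(long long cx, long long cy, long long cz) {
  // pack three signed cell coordinates into one key (21 bits each)
  return ((cx + 1048576LL)) | ((cy + 1048576LL) << 21) | ((cz + 1048576LL) << 42);
}

typedef std::unordered_map<long long, std::vector<int> > CellMap;

static CellMap build_cells(const NumericMatrix& pts, double cell) {
  CellMap m;
  for (int i = 0; i < pts.nrow(); ++i) {
    long long cx = (long long)std::floor(pts(i, 0) / cell);
    long long cy = (long long)std::floor(pts(i, 1) / cell);
    long long cz = (long long)std::floor(pts(i, 2) / cell);
    m[cell_key(cx, cy, cz)].push_back(i);
  }
  return m;
}

// For each query point, TRUE iff some reference point lies within `cutoff`
// (Euclidean, <=). Exact: cell edge = cutoff, so any point within cutoff of
// the query sits in one of the 27 neighbouring cells.
// [[Rcpp::export]]
LogicalVector within_cutoff_cpp(NumericMatrix query, NumericMatrix ref, double cutoff) {
  const double c2 = cutoff * cutoff;
  CellMap cells = build_cells(ref, cutoff);
  LogicalVector out(query.nrow());
  for (int i = 0; i < query.nrow(); ++i) {
    const double qx = query(i, 0), qy = query(i, 1), qz = query(i, 2);
    long long cx = (long long)std::floor(qx / cutoff);
    long long cy = (long long)std::floor(qy / cutoff);
    long long cz = (long long)std::floor(qz / cutoff);
    bool hit = false;
    for (long long dx = -1; dx <= 1 && !hit; ++dx)
      for (long long dy = -1; dy <= 1 && !hit; ++dy)
        for (long long dz = -1; dz <= 1 && !hit; ++dz) {
          CellMap::const_iterator it = cells.find(cell_key(cx + dx, cy + dy, cz + dz));
          if (it == cells.end()) continue;
          const std::vector<int>& v = it->second;
          for (size_t k = 0; k < v.size(); ++k) {
            const int j = v[k];
            const double ddx = qx - ref(j, 0), ddy = qy - ref(j, 1), ddz = qz - ref(j, 2);
            if (ddx * ddx + ddy * ddy + ddz * ddz <= c2) { hit = true; break; }
          }
        }
    out[i] = hit;
  }
  return out;
}

// Dot occlusion for surface generation: dot i (sitting on the expanded
// sphere of atom parent[i], 1-based) is occluded iff it lies strictly inside
// some OTHER atom's expanded sphere (radius radii[j]), with a small relative
// tolerance so tangent dots survive.
// [[Rcpp::export]]
LogicalVector occluded_cpp(NumericMatrix dots, IntegerVector parent,
                           NumericMatrix centers, NumericVector radii) {
  double rmax = 0.0;
  for (int j = 0; j < radii.size(); ++j) rmax = std::max(rmax, radii[j]);
  if (rmax <= 0) return LogicalVector(dots.nrow());
  CellMap cells = build_cells(centers, rmax);
  LogicalVector out(dots.nrow());
  for (int i = 0; i < dots.nrow(); ++i) {
    const double qx = dots(i, 0), qy = dots(i, 1), qz = dots(i, 2);
    long long cx = (long long)std::floor(qx / rmax);
    long long cy = (long long)std::floor(qy / rmax);
    long long cz = (long long)std::floor(qz / rmax);
    bool occ = false;
    for (long long dx = -1; dx <= 1 && !occ; ++dx)
      for (long long dy = -1; dy <= 1 && !occ; ++dy)
        for (long long dz = -1; dz <= 1 && !occ; ++dz) {
          CellMap::const_iterator it = cells.find(cell_key(cx + dx, cy + dy, cz + dz));
          if (it == cells.end()) continue;
          const std::vector<int>& v = it->second;
          for (size_t k = 0; k < v.size(); ++k) {
            const int j = v[k];
            if (j == parent[i] - 1) continue;
            const double r = radii[j] * (1.0 - 1e-9);
            const double ddx = qx - centers(j, 0), ddy = qy - centers(j, 1),
                         ddz = qz - centers(j, 2);
            if (ddx * ddx + ddy * ddy + ddz * ddz < r * r) { occ = true; break; }
          }
        }
    out[i] = occ;
  }
  return out;
}

static inline int conv_out_dim(int in, int K, int stride, int pad, int dil) {
  return (in + 2 * pad - dil * (K - 1) - 1) / stride + 1;
}

// Fill rows [row0, row0+nrows) of the im2col matrix for sample n.
static void im2col_chunk(const double* x, int D, int H, int W, int Cin,
                         int K, int stride, int pad, int dil,
                         int Do, int Ho, int Wo,
                         long long row0, long long nrows, arma::mat& col) {
  const long long DH = (long long)D * H;
  for (long long r = 0; r < nrows; ++r) {
    const long long v = row0 + r;
    const int od = (int)(v % Do);
    const int oh = (int)((v / Do) % Ho);
    const int ow = (int)(v / ((long long)Do * Ho));
    const int id0 = od * stride - pad;
    const int ih0 = oh * stride - pad;
    const int iw0 = ow * stride - pad;
    for (int ci = 0; ci < Cin; ++ci) {
      const double* xc = x + (long long)ci * DH * W;
      for (int kw = 0; kw < K; ++kw) {
        const int iw = iw0 + kw * dil;
        for (int kh = 0; kh < K; ++kh) {
          const int ih = ih0 + kh * dil;
          for (int kd = 0; kd < K; ++kd) {
            const int id = id0 + kd * dil;
            const long long cc = (long long)kd + K * ((long long)kh + K * ((long long)kw + K * (long long)ci));
            double val = 0.0;
            if (id >= 0 && id < D && ih >= 0 && ih < H && iw >= 0 && iw < W)
              val = xc[(long long)id + D * ((long long)ih + (long long)H * iw)];
            col(r, cc) = val;
          }
        }
      }
    }
  }
}

// [[Rcpp::export]]
NumericVector conv3d_fw_cpp(NumericVector x, IntegerVector xd,
                            NumericVector w, IntegerVector wd,
                            NumericVector bias, int stride, int pad, int dilation) {
  const int D = xd[0], H = xd[1], W = xd[2], Cin = xd[3], N = xd[4];
  const int K = wd[0], Cout = wd[4];
  const int Do = conv_out_dim(D, K, stride, pad, dilation);
  const int Ho = conv_out_dim(H, K, stride, pad, dilation);
  const int Wo = conv_out_dim(W, K, stride, pad, dilation);
  const long long Vo = (long long)Do * Ho * Wo;
  const long long Kc = (long long)K * K * K * Cin;
  NumericVector out((long long)Vo * Cout * N);
  out.attr("dim") = IntegerVector::create(Do, Ho, Wo, Cout, N);
  arma::mat Wm(w.begin(), Kc, Cout, false, true);
  const long long chunk = std::max(1LL, std::min(Vo, 6000000LL / std::max(1LL, Kc)));
  arma::mat col(chunk, Kc);
  const long long xstride = (long long)D * H * W * Cin;
  const long long ostride = Vo * Cout;
  for (int n = 0; n < N; ++n) {
    const double* xn = x.begin() + (long long)n * xstride;
    double* on = out.begin() + (long long)n * ostride;
    for (long long row0 = 0; row0 < Vo; row0 += chunk) {
      const long long nr = std::min(chunk, Vo - row0);
      arma::mat colv = col.rows(0, nr - 1);
      im2col_chunk(xn, D, H, W, Cin, K, stride, pad, dilation, Do, Ho, Wo, row0, nr, colv);
      arma::mat res = colv * Wm; // nr x Cout
      for (int co = 0; co < Cout; ++co) {
        double* oc = on + (long long)co * Vo + row0;
        const double b = bias[co];
        for (long long r = 0; r < nr; ++r) oc[r] = res(r, co) + b;
      }
    }
  }
  return out;
}

// [[Rcpp::export]]
List conv3d_bw_cpp(NumericVector x, IntegerVector xd,
                   NumericVector w, IntegerVector wd,
                   NumericVector gout, int stride, int pad, int dilation) {
  const int D = xd[0], H = xd[1], W = xd[2], Cin = xd[3], N = xd[4];
  const int K = wd[0], Cout = wd[4];
  const int Do = conv_out_dim(D, K, stride, pad, dilation);
  const int Ho = conv_out_dim(H, K, stride, pad, dilation);
  const int Wo = conv_out_dim(W, K, stride, pad, dilation);
  const long long Vo = (long long)Do * Ho * Wo;
  const long long Kc = (long long)K * K * K * Cin;
  NumericVector gx(x.size());
  gx.attr("dim") = xd;
  arma::mat gW(Kc, Cout, arma::fill::zeros);
  arma::vec gB(Cout, arma::fill::zeros);
  arma::mat Wm(w.begin(), Kc, Cout, false, true);
  const long long chunk = std::max(1LL, std::min(Vo, 6000000LL / std::max(1LL, Kc)));
  const long long xstride = (long long)D * H * W * Cin;
  const long long ostride = Vo * Cout;
  const long long DH = (long long)D * H;
  for (int n = 0; n < N; ++n) {
    const double* xn = x.begin() + (long long)n * xstride;
    double* gxn = gx.begin() + (long long)n * xstride;
    const double* gn = gout.begin() + (long long)n * ostride;
    for (long long row0 = 0; row0 < Vo; row0 += chunk) {
      const long long nr = std::min(chunk, Vo - row0);
      arma::mat col(nr, Kc);
      im2col_chunk(xn, D, H, W, Cin, K, stride, pad, dilation, Do, Ho, Wo, row0, nr, col);
      arma::mat G(nr, Cout);
      for (int co = 0; co < Cout; ++co) {
        const double* gc = gn + (long long)co * Vo + row0;
        for (long long r = 0; r < nr; ++r) G(r, co) = gc[r];
      }
      gW += col.t() * G;
      gB += arma::sum(G, 0).t();
      arma::mat gcol = G * Wm.t(); // nr x Kc
      // col2im scatter-add
      for (long long r = 0; r < nr; ++r) {
        const long long v = row0 + r;
        const int od = (int)(v % Do);
        const int oh = (int)((v / Do) % Ho);
        const int ow = (int)(v / ((long long)Do * Ho));
        const int id0 = od * stride - pad;
        const int ih0 = oh * stride - pad;
        const int iw0 = ow * stride - pad;
        for (int ci = 0; ci < Cin; ++ci) {
          double* gxc = gxn + (long long)ci * DH * W;
          for (int kw = 0; kw < K; ++kw) {
            const int iw = iw0 + kw * dilation;
            if (iw < 0 || iw >= W) continue;
            for (int kh = 0; kh < K; ++kh) {
              const int ih = ih0 + kh * dilation;
              if (ih < 0 || ih >= H) continue;
              for (int kd = 0; kd < K; ++kd) {
                const int id = id0 + kd * dilation;
                if (id < 0 || id >= D) continue;
                const long long cc = (long long)kd + K * ((long long)kh + K * ((long long)kw + K * (long long)ci));
                gxc[(long long)id + D * ((long long)ih + (long long)H * iw)] += gcol(r, cc);
              }
            }
          }
        }
      }
    }
  }
  NumericVector gw(w.size());
  gw.attr("dim") = wd;
  std::copy(gW.begin(), gW.end(), gw.begin());
  NumericVector gb(Cout);
  std::copy(gB.begin(), gB.end(), gb.begin());
  return List::create(_["gx"] = gx, _["gw"] = gw, _["gb"] = gb);
}

// [[Rcpp::export]]
List maxpool3d_fw_cpp(NumericVector x, IntegerVector xd, int K, int stride, int pad) {
  const int D = xd[0], H = xd[1], W = xd[2], C = xd[3], N = xd[4];
  const int Do = conv_out_dim(D, K, stride, pad, 1);
  const int Ho = conv_out_dim(H, K, stride, pad, 1);
  const int Wo = conv_out_dim(W, K, stride, pad, 1);
  const long long Vo = (long long)Do * Ho * Wo;
  const long long Vi = (long long)D * H * W;
  NumericVector out(Vo * C * N);
  out.attr("dim") = IntegerVector::create(Do, Ho, Wo, C, N);
  IntegerVector idx(Vo * C * N); // linear spatial index into input, per (voxel,channel,sample)
  long long o = 0;
  for (int n = 0; n < N; ++n) {
    for (int c = 0; c < C; ++c) {
      const double* xc = x.begin() + ((long long)n * C + c) * Vi;
      for (int ow = 0; ow < Wo; ++ow)
        for (int oh = 0; oh < Ho; ++oh)
          for (int od = 0; od < Do; ++od) {
            double best = -INFINITY;
            long long bidx = -1;
            for (int kw = 0; kw < K; ++kw) {
              const int iw = ow * stride - pad + kw;
              if (iw < 0 || iw >= W) continue;
              for (int kh = 0; kh < K; ++kh) {
                const int ih = oh * stride - pad + kh;
                if (ih < 0 || ih >= H) continue;
                for (int kd = 0; kd < K; ++kd) {
                  const int id = od * stride - pad + kd;
                  if (id < 0 || id >= D) continue;
                  const long long li = (long long)id + D * ((long long)ih + (long long)H * iw);
                  if (xc[li] > best) { best = xc[li]; bidx = li; }
                }
              }
            }
            // out is ordered od fastest, matching the loop order below
            const long long oo = (long long)od + Do * ((long long)oh + (long long)Ho * ow);
            out[((long long)n * C + c) * Vo + oo] = best;
            idx[((long long)n * C + c) * Vo + oo] = (int)bidx;
            ++o;
          }
    }
  }
  return List::create(_["out"] = out, _["idx"] = idx);
}

// [[Rcpp::export]]
NumericVector maxpool3d_bw_cpp(IntegerVector idx, NumericVector gout,
                               IntegerVector xd, IntegerVector od) {
  const long long Vi = (long long)xd[0] * xd[1] * xd[2];
  const long long Vo = (long long)od[0] * od[1] * od[2];
  const int C = xd[3], N = xd[4];
  NumericVector gx(Vi * C * N);
  gx.attr("dim") = xd;
  for (long long cn = 0; cn < (long long)C * N; ++cn) {
    double* g = gx.begin() + cn * Vi;
    const double* go = gout.begin() + cn * Vo;
    const int* ix = idx.begin() + cn * Vo;
    for (long long v = 0; v < Vo; ++v) g[ix[v]] += go[v];
  }
  return gx;
}
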