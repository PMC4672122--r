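// Morphological shared-weight network core: gray-scale Hit-Miss feature
// layers with learned structuring elements (SEs shared across window
// positions), a fully connected sigmoid classifier, per-sample gradient
// descent with weight-elimination regularization.
//
// Conventions:
//  - images are column-major H x W vectors, pixel (i,j) -> i + j*H;
//  - the miss SE is stored as applied (already reflected);
//  - min/max subgradients are routed to the first raster-order
//    arg-extremum (ties broken by SE offset index order);
//  - replicate padding: SE offsets are clamped to the frame.
#include <Rcpp.h>
#include <vector>
#include <random>
#include <algorithm>
#include <cmath>
using namespace Rcpp;

static inline int clampi(int v, int lo, int hi) {
  return v < lo ? lo : (v > hi ? hi : v);
}
static inline double sigmoid(double x) { return 1.0 / (1.0 + std::exp(-x)); }

struct Model {
  int H, W, K, nlayers, nhidden, nout, nf;
  std::vector<int> offy, offx;                       // SE domain offsets
  std::vector<std::vector<int>> parent;              // [layer][map], 0-based
  std::vector<std::vector<std::vector<double>>> hit; // [layer][map][K]
  std::vector<std::vector<std::vector<double>>> miss;
  std::vector<double> W1, b1, W2, b2;                // W1: nh x nf col-major
};

static Model parse_model(const List& model) {
  Model m;
  IntegerVector isz = model["input_size"];
  m.H = isz[0]; m.W = isz[1];
  IntegerMatrix off = model["se_offsets"];
  m.K = off.nrow();
  m.offy.resize(m.K); m.offx.resize(m.K);
  for (int k = 0; k < m.K; ++k) { m.offy[k] = off(k, 0); m.offx[k] = off(k, 1); }
  List layers = model["layers"];
  m.nlayers = layers.size();
  m.parent.resize(m.nlayers);
  m.hit.resize(m.nlayers); m.miss.resize(m.nlayers);
  for (int l = 0; l < m.nlayers; ++l) {
    List lay = layers[l];
    IntegerVector par = lay["parent"];
    NumericMatrix hitm = lay["hit"], missm = lay["miss"];
    int nm = hitm.ncol();
    m.parent[l].resize(nm);
    m.hit[l].resize(nm); m.miss[l].resize(nm);
    for (int q = 0; q < nm; ++q) {
      m.parent[l][q] = par[q] - 1;
      m.hit[l][q].assign(hitm.column(q).begin(), hitm.column(q).end());
      m.miss[l][q].assign(missm.column(q).begin(), missm.column(q).end());
    }
  }
  NumericMatrix W1 = model["W1"], W2 = model["W2"];
  NumericVector b1 = model["b1"], b2 = model["b2"];
  m.nhidden = W1.nrow(); m.nf = W1.ncol(); m.nout = W2.nrow();
  m.W1.assign(W1.begin(), W1.end());
  m.b1.assign(b1.begin(), b1.end());
  m.W2.assign(W2.begin(), W2.end());
  m.b2.assign(b2.begin(), b2.end());
  return m;
}

static List serialize_model(const Model& m, const List& tmpl) {
  List out = clone(tmpl);
  List layers = out["layers"];
  for (int l = 0; l < m.nlayers; ++l) {
    List lay = layers[l];
    NumericMatrix hitm = lay["hit"], missm = lay["miss"];
    int nm = hitm.ncol();
    for (int q = 0; q < nm; ++q)
      for (int k = 0; k < m.K; ++k) {
        hitm(k, q) = m.hit[l][q][k];
        missm(k, q) = m.miss[l][q][k];
      }
  }
  NumericMatrix W1 = out["W1"], W2 = out["W2"];
  NumericVector b1 = out["b1"], b2 = out["b2"];
  std::copy(m.W1.begin(), m.W1.end(), W1.begin());
  std::copy(m.b1.begin(), m.b1.end(), b1.begin());
  std::copy(m.W2.begin(), m.W2.end(), W2.begin());
  std::copy(m.b2.begin(), m.b2.end(), b2.begin());
  return out;
}

struct Fwd {
  // per layer, per map: replicate-padded input, map values and the
  // separate hit/miss extrema (kept so backward can recover the
  // arg-extrema by exact equality scan)
  std::vector<std::vector<std::vector<double>>> pad_in;
  std::vector<std::vector<std::vector<double>>> maps, neth, netm;
  std::vector<double> Oh, Oo;                        // activations
};

static inline int r_off(const Model& m, int k, int Hp) {
  return m.offy[k] + m.offx[k] * Hp;
}

static int se_radius(const Model& m) {
  int r = 0;
  for (int k = 0; k < m.K; ++k)
    r = std::max(r, std::max(std::abs(m.offy[k]), std::abs(m.offx[k])));
  return r;
}

static void pad_replicate(const double* in, int H, int W, int r,
                          std::vector<double>& out) {
  const int Hp = H + 2 * r, Wp = W + 2 * r;
  out.resize((size_t)Hp * Wp);
  for (int j = 0; j < Wp; ++j) {
    const double* col = in + (size_t)clampi(j - r, 0, W - 1) * H;
    double* dst = out.data() + (size_t)j * Hp;
    for (int i = 0; i < Hp; ++i) dst[i] = col[clampi(i - r, 0, H - 1)];
  }
}

// k-outer min/max scan over the padded input: for every position the
// hit net is min_k pad[p+k] - t_hit[k], the miss net max_k pad[p+k] -
// t_miss[k]. The inner loop is contiguous and branch-free.
static void hit_miss_layer(const std::vector<double>& pad, int H, int W,
                           int r, const Model& m,
                           const std::vector<double>& hit,
                           const std::vector<double>& miss,
                           std::vector<double>& out,
                           std::vector<double>& neth,
                           std::vector<double>& netm) {
  const int K = m.K, Hp = H + 2 * r;
  const size_t HW = (size_t)H * W;
  neth.assign(HW, R_PosInf);
  netm.assign(HW, R_NegInf);
  out.resize(HW);
  for (int k = 0; k < K; ++k) {
    const double th = hit[k], tm = miss[k];
    const int base_off = (r + m.offy[k]) + (r + m.offx[k]) * Hp;
    for (int j = 0; j < W; ++j) {
      const double* src = pad.data() + base_off + (size_t)j * Hp;
      double* mn = neth.data() + (size_t)j * H;
      double* mx = netm.data() + (size_t)j * H;
      for (int i = 0; i < H; ++i) {
        double v = src[i];
        double a = v - th, b = v - tm;
        mn[i] = a < mn[i] ? a : mn[i];
        mx[i] = b > mx[i] ? b : mx[i];
      }
    }
  }
  for (size_t p = 0; p < HW; ++p) out[p] = neth[p] - netm[p];
}

static void forward(const std::vector<double>& img, const Model& m, Fwd& f) {
  const int HW = m.H * m.W, r = se_radius(m);
  f.maps.resize(m.nlayers); f.pad_in.resize(m.nlayers);
  f.neth.resize(m.nlayers); f.netm.resize(m.nlayers);
  for (int l = 0; l < m.nlayers; ++l) {
    int nm = (int)m.hit[l].size();
    f.maps[l].resize(nm); f.pad_in[l].resize(nm);
    f.neth[l].resize(nm); f.netm[l].resize(nm);
    for (int q = 0; q < nm; ++q) {
      f.maps[l][q].resize(HW);
      const double* in = (l == 0) ? img.data()
                                  : f.maps[l - 1][m.parent[l][q]].data();
      pad_replicate(in, m.H, m.W, r, f.pad_in[l][q]);
      hit_miss_layer(f.pad_in[l][q], m.H, m.W, r, m, m.hit[l][q],
                     m.miss[l][q], f.maps[l][q], f.neth[l][q],
                     f.netm[l][q]);
    }
  }
  // classifier: features = concatenated last-layer maps; accumulate
  // feature-major so W1 is read contiguously
  const int L = m.nlayers - 1, nmL = (int)m.hit[L].size();
  const int nh = m.nhidden;
  std::vector<double> acc(nh);
  for (int hN = 0; hN < nh; ++hN) acc[hN] = m.b1[hN];
  for (int q = 0; q < nmL; ++q) {
    const double* mp = f.maps[L][q].data();
    const double* w = &m.W1[(size_t)q * HW * nh];
    for (int p = 0; p < HW; ++p) {
      double v = mp[p];
      const double* wp = w + (size_t)p * nh;
      for (int hN = 0; hN < nh; ++hN) acc[hN] += v * wp[hN];
    }
  }
  f.Oh.assign(nh, 0.0);
  for (int hN = 0; hN < nh; ++hN) f.Oh[hN] = sigmoid(acc[hN]);
  f.Oo.assign(m.nout, 0.0);
  for (int o = 0; o < m.nout; ++o) {
    double s = m.b2[o];
    for (int hN = 0; hN < m.nhidden; ++hN)
      s += m.W2[o + hN * m.nout] * f.Oh[hN];
    f.Oo[o] = sigmoid(s);
  }
}

struct Grad {
  std::vector<std::vector<std::vector<double>>> hit, miss;
  std::vector<double> W1, b1, W2, b2;
  double E;
};

static void init_grad(const Model& m, Grad& g) {
  g.hit.resize(m.nlayers); g.miss.resize(m.nlayers);
  for (int l = 0; l < m.nlayers; ++l) {
    int nm = (int)m.hit[l].size();
    g.hit[l].assign(nm, std::vector<double>(m.K, 0.0));
    g.miss[l].assign(nm, std::vector<double>(m.K, 0.0));
  }
  g.W1.assign(m.W1.size(), 0.0);
  g.b1.assign(m.b1.size(), 0.0);
  g.W2.assign(m.W2.size(), 0.0);
  g.b2.assign(m.b2.size(), 0.0);
}

// Gradient of the per-sample squared error E = 1/2 sum (t_o - O_o)^2
// with respect to every parameter, with subgradient routing through the
// recorded arg-extrema of each Hit-Miss window.
static void backward(const std::vector<double>& img, const Model& m,
                     const Fwd& f, const std::vector<double>& target,
                     Grad& g) {
  const int HW = m.H * m.W;
  g.E = 0.0;
  std::vector<double> go(m.nout), gh(m.nhidden, 0.0);
  for (int o = 0; o < m.nout; ++o) {
    double e = f.Oo[o] - target[o];
    g.E += 0.5 * e * e;
    go[o] = e * f.Oo[o] * (1.0 - f.Oo[o]);       // dE/dnet_o
  }
  for (int o = 0; o < m.nout; ++o) {
    for (int hN = 0; hN < m.nhidden; ++hN) {
      g.W2[o + hN * m.nout] = go[o] * f.Oh[hN];
      gh[hN] += go[o] * m.W2[o + hN * m.nout];
    }
    g.b2[o] = go[o];
  }
  for (int hN = 0; hN < m.nhidden; ++hN)
    gh[hN] *= f.Oh[hN] * (1.0 - f.Oh[hN]);       // dE/dnet_h
  // feature deltas dE/da for the last feature layer
  const int L = m.nlayers - 1, nmL = (int)m.hit[L].size();
  std::vector<std::vector<double>> delta(nmL, std::vector<double>(HW, 0.0));
  for (int q = 0; q < nmL; ++q) {
    for (int p = 0; p < HW; ++p) {
      size_t fidx = (size_t)q * HW + p;
      double d = 0.0;
      const double* w = &m.W1[fidx * m.nhidden];
      for (int hN = 0; hN < m.nhidden; ++hN) {
        d += gh[hN] * w[hN];
        g.W1[hN + fidx * m.nhidden] = gh[hN] * f.maps[L][q][p];
      }
      delta[q][p] = d;
    }
  }
  for (int hN = 0; hN < m.nhidden; ++hN) g.b1[hN] = gh[hN];
  // descend through the feature layers. The arg-extremum of each
  // window is recovered by exact-equality scan (ascending k keeps the
  // first-raster-order tie rule) against the recorded extrema.
  const int r = se_radius(m), Hp = m.H + 2 * r;
  for (int l = L; l >= 0; --l) {
    int nm = (int)m.hit[l].size();
    std::vector<std::vector<double>> dprev;
    if (l > 0) {
      int nmp = (int)m.hit[l - 1].size();
      dprev.assign(nmp, std::vector<double>(HW, 0.0));
    }
    for (int q = 0; q < nm; ++q) {
      const std::vector<double>& pad = f.pad_in[l][q];
      const double* nh = f.neth[l][q].data();
      const double* nmx = f.netm[l][q].data();
      const double* th = m.hit[l][q].data();
      const double* tm = m.miss[l][q].data();
      for (int j = 0; j < m.W; ++j)
        for (int i = 0; i < m.H; ++i) {
          int p = i + j * m.H;
          double d = delta[q][p];
          if (d == 0.0) continue;
          const double* base = pad.data() + (i + r) + (size_t)(j + r) * Hp;
          const double vh = nh[p], vm = nmx[p];
          int kh = -1, km = -1;
          for (int k = 0; k < m.K; ++k) {
            double v = base[r_off(m, k, Hp)];
            if (kh < 0 && v - th[k] == vh) { kh = k; if (km >= 0) break; }
            if (km < 0 && v - tm[k] == vm) { km = k; if (kh >= 0) break; }
          }
          if (kh < 0) kh = 0;
          if (km < 0) km = 0;
          g.hit[l][q][kh] -= d;       // dE/dt_hit at argmin
          g.miss[l][q][km] += d;      // dE/dt_miss at argmax
          if (l > 0) {
            int ph = clampi(i + m.offy[kh], 0, m.H - 1) +
                     clampi(j + m.offx[kh], 0, m.W - 1) * m.H;
            int pm = clampi(i + m.offy[km], 0, m.H - 1) +
                     clampi(j + m.offx[km], 0, m.W - 1) * m.H;
            dprev[m.parent[l][q]][ph] += d;
            dprev[m.parent[l][q]][pm] -= d;
          }
        }
    }
    if (l > 0) delta = std::move(dprev);
  }
}

// derivative of the weight-elimination penalty term (w/w0)^2/(1+(w/w0)^2)
static inline double pen_grad(double wv, double w0) {
  double r = wv / w0, d = 1.0 + r * r;
  return (2.0 * wv / (w0 * w0)) / (d * d);
}

// [[Rcpp::export]]
List cpp_msnn_forward(const NumericMatrix& img, const List& model,
                      bool keep = false) {
  Model m = parse_model(model);
  if (img.nrow() != m.H || img.ncol() != m.W)
    stop("subimage is %dx%d but the model expects %dx%d", img.nrow(),
         img.ncol(), m.H, m.W);
  std::vector<double> x(img.begin(), img.end());
  Fwd f;
  forward(x, m, f);
  List out = List::create(_["scores"] = NumericVector(f.Oo.begin(), f.Oo.end()),
                          _["hidden"] = NumericVector(f.Oh.begin(), f.Oh.end()));
  if (keep) {
    const int L = m.nlayers - 1;
    List maps(m.nlayers);
    for (int l = 0; l < m.nlayers; ++l) {
      int nm = (int)m.hit[l].size();
      List lm(nm);
      for (int q = 0; q < nm; ++q) {
        NumericMatrix mm(m.H, m.W);
        std::copy(f.maps[l][q].begin(), f.maps[l][q].end(), mm.begin());
        lm[q] = mm;
      }
      maps[l] = lm;
    }
    int nmL = (int)m.hit[L].size();
    NumericVector feat(nmL * m.H * m.W);
    for (int q = 0; q < nmL; ++q)
      std::copy(f.maps[L][q].begin(), f.maps[L][q].end(),
                feat.begin() + (size_t)q * m.H * m.W);
    out["feature_maps"] = maps;
    out["features"] = feat;
  }
  return out;
}

// [[Rcpp::export]]
List cpp_msnn_grad(const NumericMatrix& img, const NumericVector& target,
                   const List& model) {
  Model m = parse_model(model);
  std::vector<double> x(img.begin(), img.end());
  std::vector<double> t(target.begin(), target.end());
  Fwd f; forward(x, m, f);
  Grad g; init_grad(m, g);
  backward(x, m, f, t, g);
  List layers(m.nlayers);
  for (int l = 0; l < m.nlayers; ++l) {
    int nm = (int)m.hit[l].size();
    NumericMatrix gh(m.K, nm), gm(m.K, nm);
    for (int q = 0; q < nm; ++q)
      for (int k = 0; k < m.K; ++k) {
        gh(k, q) = g.hit[l][q][k];
        gm(k, q) = g.miss[l][q][k];
      }
    layers[l] = List::create(_["hit"] = gh, _["miss"] = gm);
  }
  NumericMatrix gW1(m.nhidden, m.nf), gW2(m.nout, m.nhidden);
  std::copy(g.W1.begin(), g.W1.end(), gW1.begin());
  std::copy(g.W2.begin(), g.W2.end(), gW2.begin());
  return List::create(_["layers"] = layers, _["W1"] = gW1,
                      _["b1"] = NumericVector(g.b1.begin(), g.b1.end()),
                      _["W2"] = gW2,
                      _["b2"] = NumericVector(g.b2.begin(), g.b2.end()),
                      _["E"] = g.E,
                      _["scores"] = NumericVector(f.Oo.begin(), f.Oo.end()));
}

// Sequential (per-sample) gradient-descent training with optional
// weight-elimination penalty on the classifier weights (and on the SE
// values when regularize_ses). Presentation order is reshuffled every
// epoch from a generator seeded by cfg$seed. Stops when the stop metric
// (mean or median per-sample E over the epoch) reaches mse_target, when
// the metric has plateaued over `patience` epochs, or at max_epochs.
// [[Rcpp::export]]
List cpp_msnn_train(const List& images, const IntegerVector& labels,
                    const List& model, const List& cfg) {
  Model m = parse_model(model);
  const int n = images.size(), HW = m.H * m.W;
  std::vector<std::vector<double>> X(n);
  for (int s = 0; s < n; ++s) {
    NumericMatrix im = images[s];
    if (im.nrow() != m.H || im.ncol() != m.W)
      stop("sample %d is %dx%d but the model expects %dx%d", s + 1,
           im.nrow(), im.ncol(), m.H, m.W);
    X[s].assign(im.begin(), im.end());
  }
  std::vector<std::vector<double>> T(n, std::vector<double>(m.nout, 0.0));
  for (int s = 0; s < n; ++s) {
    int lb = labels[s];
    if (lb < 1 || lb > m.nout) stop("label out of range");
    T[s][lb - 1] = 1.0;
  }
  const double eta = as<double>(cfg["eta"]);
  const int max_epochs = as<int>(cfg["max_epochs"]);
  const double mse_target = as<double>(cfg["mse_target"]);
  const double lambda = as<double>(cfg["lambda"]);
  const double w0 = as<double>(cfg["w0"]);
  const bool reg_ses = as<bool>(cfg["regularize_ses"]);
  const bool shuffle = as<bool>(cfg["shuffle"]);
  const int patience = as<int>(cfg["patience"]);
  const double patience_tol = as<double>(cfg["patience_tol"]);
  const std::string metric = as<std::string>(cfg["stop_metric"]);
  std::mt19937 rng((unsigned)as<double>(cfg["seed"]));

  std::vector<int> idx(n);
  for (int s = 0; s < n; ++s) idx[s] = s;
  Fwd f; Grad g; init_grad(m, g);
  std::vector<double> meanE, medE, Es(n);
  std::string reason = "max_epochs";
  int epoch = 0;
  (void)HW;
  for (epoch = 0; epoch < max_epochs; ++epoch) {
    if (shuffle) std::shuffle(idx.begin(), idx.end(), rng);
    for (int s0 = 0; s0 < n; ++s0) {
      int s = idx[s0];
      forward(X[s], m, f);
      backward(X[s], m, f, T[s], g);
      Es[s] = g.E;
      // apply accumulated updates, then clear the accumulators
      for (size_t k = 0; k < m.W2.size(); ++k) {
        m.W2[k] -= eta * (g.W2[k] + lambda * pen_grad(m.W2[k], w0));
        g.W2[k] = 0.0;
      }
      for (size_t k = 0; k < m.W1.size(); ++k) {
        m.W1[k] -= eta * (g.W1[k] + lambda * pen_grad(m.W1[k], w0));
        g.W1[k] = 0.0;
      }
      for (size_t k = 0; k < m.b2.size(); ++k) { m.b2[k] -= eta * g.b2[k]; g.b2[k] = 0.0; }
      for (size_t k = 0; k < m.b1.size(); ++k) { m.b1[k] -= eta * g.b1[k]; g.b1[k] = 0.0; }
      for (int l = 0; l < m.nlayers; ++l)
        for (size_t q = 0; q < m.hit[l].size(); ++q)
          for (int k = 0; k < m.K; ++k) {
            double ph = reg_ses ? lambda * pen_grad(m.hit[l][q][k], w0) : 0.0;
            double pm = reg_ses ? lambda * pen_grad(m.miss[l][q][k], w0) : 0.0;
            m.hit[l][q][k] -= eta * (g.hit[l][q][k] + ph);
            m.miss[l][q][k] -= eta * (g.miss[l][q][k] + pm);
            g.hit[l][q][k] = 0.0; g.miss[l][q][k] = 0.0;
          }
    }
    double mu = 0.0;
    for (int s = 0; s < n; ++s) mu += Es[s];
    mu /= n;
    std::vector<double> tmp(Es);
    std::nth_element(tmp.begin(), tmp.begin() + n / 2, tmp.end());
    double med = tmp[n / 2];
    if (n % 2 == 0) {
      double hi = tmp[n / 2];
      std::nth_element(tmp.begin(), tmp.begin() + n / 2 - 1, tmp.end());
      med = 0.5 * (hi + tmp[n / 2 - 1]);
    }
    meanE.push_back(mu);
    medE.push_back(med);
    if (!std::isfinite(mu))
      stop("training diverged (non-finite error) at epoch %d", epoch + 1);
    double track = (metric == "median") ? med : mu;
    if (track <= mse_target) { reason = "mse_target"; ++epoch; break; }
    if (patience > 0 && epoch >= patience) {
      double past = (metric == "median") ? medE[epoch - patience]
                                         : meanE[epoch - patience];
      if (past - track < patience_tol * past) {
        reason = "plateau"; ++epoch; break;
      }
    }
    if ((epoch & 15) == 0) Rcpp::checkUserInterrupt();
  }
  return List::create(_["model"] = serialize_model(m, model),
                      _["mean_error"] = NumericVector(meanE.begin(), meanE.end()),
                      _["median_error"] = NumericVector(medE.begin(), medE.end()),
                      _["epochs"] = (double)meanE.size(),
                      _["stopped"] = reason);
}

// [[Rcpp::export]]
NumericMatrix cpp_msnn_predict(const List& images, const List& model) {
  Model m = parse_model(model);
  const int n = images.size();
  NumericMatrix out(n, m.nout);
  Fwd f;
  for (int s = 0; s < n; ++s) {
    NumericMatrix im = images[s];
    std::vector<double> x(im.begin(), im.end());
    forward(x, m, f);
    for (int o = 0; o < m.nout; ++o) out(s, o) = f.Oo[o];
    if ((s & 63) == 0) Rcpp::checkUserInterrupt();
  }
  return out;
}

// Slide the model window over the image with the given stride and
// return one score plane per output class. Plane cell (pi, pj)
// corresponds to the window whose top-left pixel is
// ((pi-1)*stride + 1, (pj-1)*stride + 1) in 1-based image coordinates.
// [[Rcpp::export]]
List cpp_scan_detect(const NumericMatrix& image, const List& model,
                     int stride) {
  Model m = parse_model(model);
  const int H = image.nrow(), W = image.ncol();
  if (H < m.H || W < m.W)
    stop("image (%dx%d) is smaller than the model window (%dx%d)", H, W,
         m.H, m.W);
  const int nI = (H - m.H) / stride + 1, nJ = (W - m.W) / stride + 1;
  List planes(m.nout);
  std::vector<NumericMatrix> P;
  for (int o = 0; o < m.nout; ++o) P.push_back(NumericMatrix(nI, nJ));
  std::vector<double> x(m.H * m.W);
  Fwd f;
  for (int pj = 0; pj < nJ; ++pj) {
    for (int pi = 0; pi < nI; ++pi) {
      int i0 = pi * stride, j0 = pj * stride;
      for (int j = 0; j < m.W; ++j)
        for (int i = 0; i < m.H; ++i)
          x[i + j * m.H] = image(i0 + i, j0 + j);
      forward(x, m, f);
      for (int o = 0; o < m.nout; ++o) P[o](pi, pj) = f.Oo[o];
    }
    Rcpp::checkUserInterrupt();
  }
  for (int o = 0; o < m.nout; ++o) planes[o] = P[o];
  return planes;
}
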