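// Compiled training loop for the adversarial model. Mirrors the R
// reference engine (R/train.R, engine = "R"): dense leaky-ReLU networks,
// manual backpropagation, Adam updates, discriminator weight clipping,
// warm-up, and the plateau + label-stability stopping rule. All random
// draws come from R's RNG, so a run is a deterministic function of
// (data, control, seed) exactly like the R engine.

#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]

using namespace Rcpp;
using arma::mat;
using arma::rowvec;
using arma::uvec;

namespace {

struct Net {
  std::vector<mat> W;
  std::vector<rowvec> b;
  double slope;
  int head;  // 0 linear, 1 softmax, 2 sigmoid
};

struct Adam {
  std::vector<mat> mW, vW;
  std::vector<rowvec> mb, vb;
  int t = 0;
};

Net netFromList(List L) {
  Net n;
  List W = L["W"], b = L["b"];
  for (int i = 0; i < W.size(); ++i) {
    n.W.push_back(as<mat>(W[i]));
    n.b.push_back(as<rowvec>(b[i]));
  }
  n.slope = as<double>(L["slope"]);
  std::string h = as<std::string>(L["head"]);
  n.head = h == "linear" ? 0 : (h == "softmax" ? 1 : 2);
  return n;
}

List netToList(const Net& n, List original) {
  List W(n.W.size()), b(n.b.size());
  for (size_t i = 0; i < n.W.size(); ++i) {
    W[i] = n.W[i];
    b[i] = NumericVector(n.b[i].begin(), n.b[i].end());
  }
  List out = clone(original);
  out["W"] = W;
  out["b"] = b;
  return out;
}

Adam adamInit(const Net& n) {
  Adam a;
  for (size_t i = 0; i < n.W.size(); ++i) {
    a.mW.push_back(mat(arma::size(n.W[i]), arma::fill::zeros));
    a.vW.push_back(mat(arma::size(n.W[i]), arma::fill::zeros));
    a.mb.push_back(rowvec(n.b[i].n_elem, arma::fill::zeros));
    a.vb.push_back(rowvec(n.b[i].n_elem, arma::fill::zeros));
  }
  return a;
}

inline mat leakyGrad(const mat& z, double slope) {
  return arma::conv_to<mat>::from(z > 0) +
         slope * arma::conv_to<mat>::from(z <= 0);
}
inline mat leaky(const mat& z, double slope) {
  return z % leakyGrad(z, slope);
}

struct Cache {
  std::vector<mat> A, Z;
  mat out;
};

void forward(const Net& n, const mat& X, Cache& c, bool keep) {
  size_t L = n.W.size();
  if (keep) { c.A.assign(L, mat()); c.Z.assign(L, mat()); }
  mat H = X;
  for (size_t l = 0; l < L; ++l) {
    if (keep) c.A[l] = H;
    mat Zl = H * n.W[l];
    Zl.each_row() += n.b[l];
    if (keep) c.Z[l] = Zl;
    if (l + 1 < L) {
      H = leaky(Zl, n.slope);
    } else if (n.head == 0) {
      H = Zl;
    } else if (n.head == 1) {
      Zl.each_col() -= arma::max(Zl, 1);
      mat E = arma::exp(Zl);
      E.each_col() /= arma::sum(E, 1);
      H = E;
    } else {
      H = 1.0 / (1.0 + arma::exp(-Zl));
    }
  }
  c.out = H;
}

struct Grads {
  std::vector<mat> dW;
  std::vector<rowvec> db;
  mat dInput;
};

void backward(const Net& n, const Cache& c, const mat& dZlast, Grads& g) {
  size_t L = n.W.size();
  g.dW.assign(L, mat());
  g.db.assign(L, rowvec());
  mat dZ = dZlast, dA;
  for (size_t l = L; l-- > 0;) {
    g.dW[l] = c.A[l].t() * dZ;
    g.db[l] = arma::sum(dZ, 0);
    dA = dZ * n.W[l].t();
    if (l > 0) dZ = dA % leakyGrad(c.Z[l - 1], n.slope);
  }
  g.dInput = dA;
}

void adamStep(Net& n, const Grads& g, Adam& a, double lr,
              double b1 = 0.9, double b2 = 0.999, double eps = 1e-8) {
  a.t += 1;
  double c1 = 1 - std::pow(b1, a.t), c2 = 1 - std::pow(b2, a.t);
  for (size_t l = 0; l < n.W.size(); ++l) {
    a.mW[l] = b1 * a.mW[l] + (1 - b1) * g.dW[l];
    a.vW[l] = b2 * a.vW[l] + (1 - b2) * arma::square(g.dW[l]);
    n.W[l] -= lr * (a.mW[l] / c1) / (arma::sqrt(a.vW[l] / c2) + eps);
    a.mb[l] = b1 * a.mb[l] + (1 - b1) * g.db[l];
    a.vb[l] = b2 * a.vb[l] + (1 - b2) * arma::square(g.db[l]);
    n.b[l] -= lr * (a.mb[l] / c1) / (arma::sqrt(a.vb[l] / c2) + eps);
  }
}

void clipNet(Net& n, double c) {
  for (size_t l = 0; l < n.W.size(); ++l) {
    n.W[l] = arma::clamp(n.W[l], -c, c);
    n.b[l] = arma::clamp(n.b[l], -c, c);
  }
}

// minibatch row indices from R's RNG (uniform with replacement)
uvec sampleRows(int n, int B) {
  uvec idx(B);
  for (int i = 0; i < B; ++i) {
    int k = (int)(unif_rand() * n);
    if (k >= n) k = n - 1;
    idx[i] = (arma::uword)k;
  }
  return idx;
}

mat sampleZ(int M, int B) {
  mat z(B, M, arma::fill::zeros);
  for (int i = 0; i < B; ++i) {
    int k = (int)(unif_rand() * M);
    if (k >= M) k = M - 1;
    z(i, k) = 1.0;
  }
  return z;
}

uvec argmaxRows(const mat& P) {
  uvec lab(P.n_rows);
  for (arma::uword i = 0; i < P.n_rows; ++i) {
    double best = P(i, 0);
    arma::uword bj = 0;
    for (arma::uword j = 1; j < P.n_cols; ++j)
      if (P(i, j) > best) { best = P(i, j); bj = j; }
    lab[i] = bj + 1;
  }
  return lab;
}

double ariLabels(const uvec& a, const uvec& b, int M) {
  mat tab(M, M, arma::fill::zeros);
  for (arma::uword i = 0; i < a.n_elem; ++i) tab(a[i] - 1, b[i] - 1) += 1.0;
  double n = (double)a.n_elem;
  auto ch2 = [](double x) { return x * (x - 1) / 2; };
  double sumnij = 0, sa = 0, sb = 0;
  for (int i = 0; i < M; ++i) {
    sa += ch2(arma::accu(tab.row(i)));
    sb += ch2(arma::accu(tab.col(i)));
    for (int j = 0; j < M; ++j) sumnij += ch2(tab(i, j));
  }
  double expected = sa * sb / ch2(n);
  double denom = (sa + sb) / 2 - expected;
  if (std::abs(denom) < 4e-16) return 1.0;
  return (sumnij - expected) / denom;
}

}  // namespace

// [[Rcpp::export(name = ".cppTrainLoop")]]
List cppTrainLoop(const arma::mat& Xcn, const arma::mat& Xpt, int M,
                  List fnetL, List gnetL, List dnetL, List ctrl) {
  Net f = netFromList(fnetL), g = netFromList(gnetL), d = netFromList(dnetL);
  Adam aF = adamInit(f), aG = adamInit(g), aD = adamInit(d);

  const int B = as<int>(ctrl["batchSize"]);
  const int maxIter = as<int>(ctrl["maxIter"]);
  const int dSteps = as<int>(ctrl["dSteps"]);
  const int dWarmup = ctrl.containsElementNamed("dWarmup")
                        ? as<int>(ctrl["dWarmup"]) : 0;
  const double mu = as<double>(ctrl["mu"]);
  const double lambda = as<double>(ctrl["lambda"]);
  const double lrG = as<double>(ctrl["lrG"]);
  const double lrD = as<double>(ctrl["lrD"]);
  const double clipR = as<double>(ctrl["clipRadius"]);
  const bool clipAll = as<bool>(ctrl["clipAll"]);
  const bool residual = as<bool>(ctrl["residual"]);
  const bool printedForm =
      as<std::string>(ctrl["ganForm"]) == "printed";
  const int W = as<int>(ctrl["plateauWindow"]);
  const double tol = as<double>(ctrl["plateauTol"]);
  const double collapseThr = as<double>(ctrl["collapseThreshold"]);
  const double labStab = as<double>(ctrl["labelStabilityARI"]);
  const int checkEvery = as<int>(ctrl["checkEvery"]);
  const double eps = as<double>(ctrl["eps"]);

  const int nCN = Xcn.n_rows, nPT = Xpt.n_rows;
  mat hist(maxIter, 3);
  hist.fill(arma::datum::nan);
  bool converged = false;
  uvec lastLabs;
  bool haveLabs = false, wasStable = false;
  int used = maxIter;

  Cache cf, cdR, cdF, cg;

  auto dStep = [&]() -> double {
    uvec ic = sampleRows(nCN, B), ip = sampleRows(nPT, B);
    mat xb = Xcn.rows(ic), yb = Xpt.rows(ip);
    mat zb = sampleZ(M, B);
    forward(f, arma::join_rows(xb, zb), cf, false);
    mat fake = residual ? mat(cf.out + xb) : cf.out;
    forward(d, yb, cdR, true);
    forward(d, fake, cdF, true);
    mat pR = cdR.out, pF = cdF.out;
    mat dzR = (pR - 1.0) / B;
    mat dzF = printedForm ? mat((1.0 - pF) / B) : mat(pF / B);
    Grads gR, gF;
    backward(d, cdR, dzR, gR);
    backward(d, cdF, dzF, gF);
    for (size_t l = 0; l < d.W.size(); ++l) {
      gR.dW[l] += gF.dW[l];
      gR.db[l] += gF.db[l];
    }
    adamStep(d, gR, aD, lrD);
    clipNet(d, clipR);
    mat cpR = arma::clamp(pR, eps, 1 - eps), cpF = arma::clamp(pF, eps, 1 - eps);
    if (printedForm)
      return arma::mean(arma::mean(arma::log(cpR))) +
             arma::mean(arma::mean(1.0 - arma::log(cpF)));
    return arma::mean(arma::mean(arma::log(cpR))) +
           arma::mean(arma::mean(arma::log(1.0 - cpF)));
  };

  for (int w = 0; w < dWarmup; ++w) dStep();

  for (int t = 1; t <= maxIter; ++t) {
    double advVal = 0;
    for (int s = 0; s < dSteps; ++s) advVal = dStep();

    uvec ic = sampleRows(nCN, B);
    mat xb = Xcn.rows(ic);
    mat zb = sampleZ(M, B);
    forward(f, arma::join_rows(xb, zb), cf, true);
    mat fake = residual ? mat(cf.out + xb) : cf.out;
    forward(d, fake, cdF, true);
    forward(g, fake, cg, true);
    mat pF = cdF.out, q = cg.out;
    Grads gD, gG, gF;
    backward(d, cdF, mat(-(1.0 - pF) / B), gD);
    backward(g, cg, mat(lambda * (q - zb) / B), gG);
    mat dY = gD.dInput + mu * arma::sign(fake - xb) / B + gG.dInput;
    backward(f, cf, dY, gF);
    adamStep(f, gF, aF, lrG);
    adamStep(g, gG, aG, lrG);
    if (clipAll) { clipNet(f, clipR); clipNet(g, clipR); }

    double chg = arma::mean(arma::sum(arma::abs(fake - xb), 1));
    mat qc = arma::clamp(q, eps, 1.0);
    double clu = arma::mean(-arma::sum(zb % arma::log(qc), 1));
    hist(t - 1, 0) = advVal;
    hist(t - 1, 1) = chg;
    hist(t - 1, 2) = clu;
    if (!std::isfinite(advVal) || !std::isfinite(chg) || !std::isfinite(clu))
      stop("non-finite loss at iteration %d", t);

    if (t >= 2 * W && t % checkEvery == 0) {
      rowvec cur = arma::mean(hist.rows(t - W, t - 1).cols(1, 2), 0);
      rowvec prev = arma::mean(hist.rows(t - 2 * W, t - W - 1).cols(1, 2), 0);
      if (arma::all(arma::abs(cur - prev) < tol)) {
        Cache cpt;
        forward(g, Xpt, cpt, false);
        uvec labs = argmaxRows(cpt.out);
        uvec cnt(M, arma::fill::zeros);
        for (arma::uword i = 0; i < labs.n_elem; ++i) cnt[labs[i] - 1]++;
        bool stable = haveLabs &&
          ariLabels(labs, lastLabs, M) >= labStab &&
          (double)cnt.min() / nPT >= collapseThr;
        lastLabs = labs;
        haveLabs = true;
        if (stable && wasStable) {
          converged = true;
          used = t;
          break;
        }
        wasStable = stable;
      } else {
        wasStable = false;
      }
    }
  }

  mat histOut = hist.rows(0, used - 1);
  return List::create(
      _["f"] = netToList(f, fnetL), _["g"] = netToList(g, gnetL),
      _["d"] = netToList(d, dnetL), _["hist"] = histOut,
      _["converged"] = converged);
}
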