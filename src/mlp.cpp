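// Fully connected coordinate network (x,y,t) -> (u,v,p) with exact
// forward-propagated first and second input derivatives and reverse-mode
// parameter gradients. Hidden layers use a per-neuron trainable gain
// ("gamma") applied to the activation: h = g * act(W a + b); the output
// layer is affine. Derivative channels carried per batch:
//   0: value, 1: d/dx, 2: d/dy, 3: d/dt, 4: d2/dx2, 5: d2/dy2
// Reverse mode through the derivative channels needs activation derivatives
// up to third order.
#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]
using namespace arma;

namespace {

struct Net {
  std::vector<mat> W;   // hidden weights, W[k] is n_k x n_{k-1}
  std::vector<rowvec> b;
  std::vector<rowvec> g;
  mat Wout;             // 3 x n_last
  rowvec bout;
  bool gain;
  int act;              // 0 sigmoid, 1 tanh
  rowvec center, scale; // input normalisation (x - c) / s
};

int theta_length(const ivec& sizes, bool gain) {
  int m = 3, len = 0;
  for (uword k = 0; k < sizes.n_elem; ++k) {
    int n = sizes(k);
    len += n * m + n + (gain ? n : 0);
    m = n;
  }
  len += 3 * m + 3;
  return len;
}

Net unpack(const vec& theta, const ivec& sizes, bool gain, int act,
           const rowvec& center, const rowvec& scale) {
  Net net;
  net.gain = gain; net.act = act; net.center = center; net.scale = scale;
  int m = 3; uword pos = 0;
  for (uword k = 0; k < sizes.n_elem; ++k) {
    int n = sizes(k);
    net.W.push_back(reshape(theta.subvec(pos, pos + n * m - 1), n, m)); pos += n * m;
    net.b.push_back(theta.subvec(pos, pos + n - 1).t()); pos += n;
    if (gain) { net.g.push_back(theta.subvec(pos, pos + n - 1).t()); pos += n; }
    else      { net.g.push_back(rowvec(n, fill::ones)); }
    m = n;
  }
  net.Wout = reshape(theta.subvec(pos, pos + 3 * m - 1), 3, m); pos += 3 * m;
  net.bout = theta.subvec(pos, pos + 2).t();
  return net;
}

vec pack_grad(const Net& net, const std::vector<mat>& dW,
              const std::vector<rowvec>& db, const std::vector<rowvec>& dg,
              const mat& dWout, const rowvec& dbout, uword len) {
  vec out(len); uword pos = 0;
  for (size_t k = 0; k < dW.size(); ++k) {
    out.subvec(pos, pos + dW[k].n_elem - 1) = vectorise(dW[k]); pos += dW[k].n_elem;
    out.subvec(pos, pos + db[k].n_elem - 1) = db[k].t(); pos += db[k].n_elem;
    if (net.gain) { out.subvec(pos, pos + dg[k].n_elem - 1) = dg[k].t(); pos += dg[k].n_elem; }
  }
  out.subvec(pos, pos + dWout.n_elem - 1) = vectorise(dWout); pos += dWout.n_elem;
  out.subvec(pos, pos + 2) = dbout.t();
  return out;
}

// activation value and first three derivatives
void act_derivs(int act, const mat& Z, int depth,
                mat& S, mat& S1, mat& S2, mat& S3) {
  if (act == 0) {
    S = 1.0 / (1.0 + exp(-Z));
    if (depth >= 1) S1 = S % (1.0 - S);
    if (depth >= 2) S2 = S1 % (1.0 - 2.0 * S);
    if (depth >= 3) S3 = S2 % (1.0 - 2.0 * S) - 2.0 * S1 % S1;
  } else {
    S = tanh(Z);
    if (depth >= 1) S1 = 1.0 - S % S;
    if (depth >= 2) S2 = -2.0 * S % S1;
    if (depth >= 3) S3 = -2.0 * (S1 % S1 + S % S2);
  }
}

// per-layer cache for reverse mode
struct LayerCache {
  std::vector<mat> A;   // input channels present (size nch)
  std::vector<mat> Z;   // pre-activation channels x,y,t (first-deriv) as needed
  mat Zxx, Zyy;
  mat S, S1, S2, S3;
};

struct Cache {
  std::vector<LayerCache> layers;
  std::vector<mat> Aout; // input channels to output layer
};

// order: 0 value only, 1 + first derivs, 2 + (xx, yy)
// returns output channels O[ch]; fills cache if keep
std::vector<mat> forward(const Net& net, const mat& X, int order,
                         Cache* cache) {
  uword N = X.n_rows;
  int nch = (order == 0) ? 1 : (order == 1 ? 4 : 6);
  std::vector<mat> A(nch);
  A[0] = X;
  A[0].each_row() -= net.center;
  A[0].each_row() /= net.scale;
  if (order >= 1) {
    for (int c = 1; c <= 3; ++c) {
      A[c] = zeros<mat>(N, 3);
      A[c].col(c - 1).fill(1.0 / net.scale(c - 1));
    }
  }
  if (order >= 2) { A[4] = zeros<mat>(N, 3); A[5] = zeros<mat>(N, 3); }

  int actdepth = (order == 0) ? 1 : (order == 1 ? 2 : 3);
  // when a cache is kept for reverse mode, activation derivatives one order
  // deeper are needed than for the forward values alone
  if (cache) actdepth = (order == 0) ? 1 : 3;
  for (size_t k = 0; k < net.W.size(); ++k) {
    LayerCache lc;
    std::vector<mat> Zc(nch);
    for (int c = 0; c < nch; ++c) Zc[c] = A[c] * net.W[k].t();
    Zc[0].each_row() += net.b[k];
    act_derivs(net.act, Zc[0], actdepth, lc.S, lc.S1, lc.S2, lc.S3);
    std::vector<mat> H(nch);
    H[0] = lc.S;
    if (order >= 1) for (int c = 1; c <= 3; ++c) H[c] = lc.S1 % Zc[c];
    if (order >= 2) {
      H[4] = lc.S2 % (Zc[1] % Zc[1]) + lc.S1 % Zc[4];
      H[5] = lc.S2 % (Zc[2] % Zc[2]) + lc.S1 % Zc[5];
    }
    for (int c = 0; c < nch; ++c) H[c].each_row() %= net.g[k];
    if (cache) {
      lc.A = std::move(A);
      lc.Z = std::move(Zc);
      cache->layers.push_back(std::move(lc));
    }
    A = std::move(H);
  }
  std::vector<mat> O(nch);
  for (int c = 0; c < nch; ++c) O[c] = A[c] * net.Wout.t();
  O[0].each_row() += net.bout;
  if (cache) cache->Aout = std::move(A);
  return O;
}

// reverse mode: Obar are adjoints of output channels (may contain empty mats
// meaning zero). Accumulates parameter gradients.
void backward(const Net& net, const Cache& cache, std::vector<mat>& Obar,
              std::vector<mat>& dW, std::vector<rowvec>& db,
              std::vector<rowvec>& dg, mat& dWout, rowvec& dbout) {
  int nch = (int)Obar.size();
  uword N = 0;
  for (int c = 0; c < nch; ++c) if (Obar[c].n_elem) { N = Obar[c].n_rows; break; }
  // output layer
  std::vector<mat> Ab(nch);
  for (int c = 0; c < nch; ++c) {
    if (!Obar[c].n_elem) { Ab[c] = mat(); continue; }
    dWout += Obar[c].t() * cache.Aout[c];
    Ab[c] = Obar[c] * net.Wout;
  }
  if (Obar[0].n_elem) dbout += sum(Obar[0], 0);

  for (int k = (int)net.W.size() - 1; k >= 0; --k) {
    const LayerCache& lc = cache.layers[k];
    const rowvec& g = net.g[k];
    int n = (int)g.n_elem;
    // multiply adjoints of H by gain and accumulate gain gradient
    // H[c] = g * Hraw[c]; Hraw values recomputed from cache
    mat Zb, Zxb, Zyb, Ztb, Zxxb, Zyyb;
    mat Hb0, Hb1, Hb2, Hb3, Hb4, Hb5;
    // convenient handles (empty => zero)
    mat& Hb = Ab[0];
    // gain gradient + adjoint through gain
    rowvec dgk(n, fill::zeros);
    auto gmul = [&](mat& M) { if (M.n_elem) M.each_row() %= g; };
    // raw H channels for gain gradient
    if (Hb.n_elem) dgk += sum(Hb % lc.S, 0);
    if (nch > 1) {
      for (int c = 1; c <= 3; ++c)
        if (Ab[c].n_elem) dgk += sum(Ab[c] % (lc.S1 % lc.Z[c]), 0);
    }
    if (nch > 4) {
      if (Ab[4].n_elem)
        dgk += sum(Ab[4] % (lc.S2 % (lc.Z[1] % lc.Z[1]) + lc.S1 % lc.Z[4]), 0);
      if (Ab[5].n_elem)
        dgk += sum(Ab[5] % (lc.S2 % (lc.Z[2] % lc.Z[2]) + lc.S1 % lc.Z[5]), 0);
    }
    dg[k] += dgk;
    for (int c = 0; c < nch; ++c) gmul(Ab[c]);

    // adjoints of pre-activations
    uword rows = lc.S.n_rows;
    Zb = zeros<mat>(rows, n);
    if (Hb.n_elem) Zb += Hb % lc.S1;
    if (nch > 1) {
      for (int c = 1; c <= 3; ++c)
        if (Ab[c].n_elem) Zb += Ab[c] % lc.S2 % lc.Z[c];
    }
    if (nch > 4) {
      if (Ab[4].n_elem)
        Zb += Ab[4] % (lc.S3 % (lc.Z[1] % lc.Z[1]) + lc.S2 % lc.Z[4]);
      if (Ab[5].n_elem)
        Zb += Ab[5] % (lc.S3 % (lc.Z[2] % lc.Z[2]) + lc.S2 % lc.Z[5]);
    }
    std::vector<mat> Zcb(nch);
    Zcb[0] = Zb;
    if (nch > 1) {
      for (int c = 1; c <= 3; ++c) {
        mat t;
        if (Ab[c].n_elem) t = Ab[c] % lc.S1;
        if (c == 1 && nch > 4 && Ab[4].n_elem) {
          mat extra = Ab[4] % (2.0 * lc.S2 % lc.Z[1]);
          t = t.n_elem ? mat(t + extra) : extra;
        }
        if (c == 2 && nch > 4 && Ab[5].n_elem) {
          mat extra = Ab[5] % (2.0 * lc.S2 % lc.Z[2]);
          t = t.n_elem ? mat(t + extra) : extra;
        }
        Zcb[c] = t;
      }
    }
    if (nch > 4) {
      Zcb[4] = Ab[4].n_elem ? mat(Ab[4] % lc.S1) : mat();
      Zcb[5] = Ab[5].n_elem ? mat(Ab[5] % lc.S1) : mat();
    }
    // parameter gradients and input adjoints
    for (int c = 0; c < nch; ++c) {
      if (!Zcb[c].n_elem) { Ab[c] = mat(); continue; }
      dW[k] += Zcb[c].t() * lc.A[c];
      Ab[c] = Zcb[c] * net.W[k];
    }
    db[k] += sum(Zcb[0], 0);
  }
  (void)N;
}

Net net_from_arch(const vec& theta, const Rcpp::List& arch) {
  ivec sizes = Rcpp::as<ivec>(arch["sizes"]);
  bool gain = Rcpp::as<bool>(arch["gain"]);
  int act = Rcpp::as<int>(arch["act"]);
  rowvec center = Rcpp::as<rowvec>(arch["center"]);
  rowvec scale = Rcpp::as<rowvec>(arch["scale"]);
  if ((int)theta.n_elem != theta_length(sizes, gain))
    Rcpp::stop("parameter vector length does not match architecture");
  return unpack(theta, sizes, gain, act, center, scale);
}

} // namespace

// [[Rcpp::export]]
int cpp_theta_length(Rcpp::IntegerVector sizes, bool gain) {
  return theta_length(Rcpp::as<ivec>(sizes), gain);
}

// [[Rcpp::export]]
Rcpp::List cpp_mlp_eval(const arma::vec& theta, Rcpp::List arch,
                        const arma::mat& X, int order) {
  Net net = net_from_arch(theta, arch);
  std::vector<mat> O = forward(net, X, order, nullptr);
  Rcpp::List out = Rcpp::List::create(Rcpp::Named("value") = O[0]);
  if (order >= 1) {
    out["dx"] = O[1]; out["dy"] = O[2]; out["dt"] = O[3];
  }
  if (order >= 2) { out["dxx"] = O[4]; out["dyy"] = O[5]; }
  return out;
}

// batches: optional named elements
//   data: list(X, u, v)          ic: list(X, u, v)
//   body: list(X, nx, ny, un)    pedge: list(X)    inlet: list(X, u, v)
//   eq:   list(X)
// lambda: c(data, ic, bc, eq); Re > 0; continuity: include div-free residual
// [[Rcpp::export]]
Rcpp::List cpp_pinn_obj(const arma::vec& theta, Rcpp::List arch,
                        Rcpp::List batches, const arma::vec& lambda,
                        double Re, bool continuity, bool want_grad) {
  Net net = net_from_arch(theta, arch);
  std::vector<mat> dW; std::vector<rowvec> db, dg;
  mat dWout; rowvec dbout;
  if (want_grad) {
    for (size_t k = 0; k < net.W.size(); ++k) {
      dW.push_back(zeros<mat>(net.W[k].n_rows, net.W[k].n_cols));
      db.push_back(rowvec(net.b[k].n_elem, fill::zeros));
      dg.push_back(rowvec(net.g[k].n_elem, fill::zeros));
    }
    dWout = zeros<mat>(3, net.W.empty() ? 3 : net.W.back().n_rows);
    dbout = rowvec(3, fill::zeros);
  }
  double L_data = 0, L_ic = 0, L_body = 0, L_pedge = 0, L_inlet = 0, L_eq = 0;

  auto vel_term = [&](Rcpp::List bt, double lam, double& Lacc) {
    mat X = Rcpp::as<mat>(bt["X"]);
    vec u = Rcpp::as<vec>(bt["u"]), v = Rcpp::as<vec>(bt["v"]);
    uword N = X.n_rows; if (N == 0) return;
    Cache cache; Cache* cp = want_grad ? &cache : nullptr;
    std::vector<mat> O = forward(net, X, 0, cp);
    vec ru = O[0].col(0) - u, rv = O[0].col(1) - v;
    Lacc = (accu(ru % ru) + accu(rv % rv)) / N;
    if (want_grad && lam > 0) {
      std::vector<mat> Ob(1);
      Ob[0] = zeros<mat>(N, 3);
      Ob[0].col(0) = lam * 2.0 * ru / N;
      Ob[0].col(1) = lam * 2.0 * rv / N;
      backward(net, cache, Ob, dW, db, dg, dWout, dbout);
    }
  };

  if (batches.containsElementNamed("data"))
    vel_term(batches["data"], lambda(0), L_data);
  if (batches.containsElementNamed("ic"))
    vel_term(batches["ic"], lambda(1), L_ic);
  if (batches.containsElementNamed("inlet"))
    vel_term(batches["inlet"], lambda(2), L_inlet);

  if (batches.containsElementNamed("body")) {
    Rcpp::List bt = batches["body"];
    mat X = Rcpp::as<mat>(bt["X"]);
    vec nx = Rcpp::as<vec>(bt["nx"]), ny = Rcpp::as<vec>(bt["ny"]);
    vec un = Rcpp::as<vec>(bt["un"]);
    uword N = X.n_rows;
    if (N > 0) {
      Cache cache; Cache* cp = want_grad ? &cache : nullptr;
      std::vector<mat> O = forward(net, X, 0, cp);
      vec r = O[0].col(0) % nx + O[0].col(1) % ny - un;
      L_body = accu(r % r) / N;
      if (want_grad && lambda(2) > 0) {
        std::vector<mat> Ob(1);
        Ob[0] = zeros<mat>(N, 3);
        Ob[0].col(0) = lambda(2) * 2.0 * (r % nx) / N;
        Ob[0].col(1) = lambda(2) * 2.0 * (r % ny) / N;
        backward(net, cache, Ob, dW, db, dg, dWout, dbout);
      }
    }
  }

  if (batches.containsElementNamed("pedge")) {
    Rcpp::List bt = batches["pedge"];
    mat X = Rcpp::as<mat>(bt["X"]);
    uword N = X.n_rows;
    if (N > 0) {
      Cache cache; Cache* cp = want_grad ? &cache : nullptr;
      std::vector<mat> O = forward(net, X, 0, cp);
      vec p = O[0].col(2);
      L_pedge = accu(p % p) / N;
      if (want_grad && lambda(2) > 0) {
        std::vector<mat> Ob(1);
        Ob[0] = zeros<mat>(N, 3);
        Ob[0].col(2) = lambda(2) * 2.0 * p / N;
        backward(net, cache, Ob, dW, db, dg, dWout, dbout);
      }
    }
  }

  if (batches.containsElementNamed("eq")) {
    Rcpp::List bt = batches["eq"];
    mat X = Rcpp::as<mat>(bt["X"]);
    uword N = X.n_rows;
    if (N > 0) {
      Cache cache; Cache* cp = want_grad ? &cache : nullptr;
      std::vector<mat> O = forward(net, X, 2, cp);
      vec u = O[0].col(0), v = O[0].col(1);
      vec ux = O[1].col(0), vx = O[1].col(1), px = O[1].col(2);
      vec uy = O[2].col(0), vy = O[2].col(1), py = O[2].col(2);
      vec ut = O[3].col(0), vt = O[3].col(1);
      vec uxx = O[4].col(0), vxx = O[4].col(1);
      vec uyy = O[5].col(0), vyy = O[5].col(1);
      vec ex = ut + u % ux + v % uy + px - (uxx + uyy) / Re;
      vec ey = vt + u % vx + v % vy + py - (vxx + vyy) / Re;
      L_eq = (accu(ex % ex) + accu(ey % ey)) / N;
      vec ec;
      if (continuity) { ec = ux + vy; L_eq += accu(ec % ec) / N; }
      if (want_grad && lambda(3) > 0) {
        double lam = lambda(3);
        vec a = lam * 2.0 * ex / N, bb2 = lam * 2.0 * ey / N;
        std::vector<mat> Ob(6);
        for (int c = 0; c < 6; ++c) Ob[c] = zeros<mat>(N, 3);
        Ob[0].col(0) = a % ux + bb2 % vx;
        Ob[0].col(1) = a % uy + bb2 % vy;
        Ob[1].col(0) = a % u;  Ob[1].col(1) = bb2 % u;  Ob[1].col(2) = a;
        Ob[2].col(0) = a % v;  Ob[2].col(1) = bb2 % v;  Ob[2].col(2) = bb2;
        Ob[3].col(0) = a;      Ob[3].col(1) = bb2;
        Ob[4].col(0) = -a / Re; Ob[4].col(1) = -bb2 / Re;
        Ob[5].col(0) = -a / Re; Ob[5].col(1) = -bb2 / Re;
        if (continuity) {
          vec cc = lam * 2.0 * ec / N;
          Ob[1].col(0) += cc;
          Ob[2].col(1) += cc;
        }
        backward(net, cache, Ob, dW, db, dg, dWout, dbout);
      }
    }
  }

  double L_bc = L_body + L_pedge + L_inlet;
  double total = lambda(0) * L_data + lambda(1) * L_ic + lambda(2) * L_bc +
                 lambda(3) * L_eq;
  Rcpp::List out = Rcpp::List::create(
      Rcpp::Named("loss") = total,
      Rcpp::Named("terms") = Rcpp::NumericVector::create(
          Rcpp::Named("data") = L_data, Rcpp::Named("ic") = L_ic,
          Rcpp::Named("bc") = L_bc, Rcpp::Named("eq") = L_eq,
          Rcpp::Named("bc_body") = L_body, Rcpp::Named("bc_pressure") = L_pedge,
          Rcpp::Named("bc_inlet") = L_inlet));
  if (want_grad)
    out["grad"] = pack_grad(net, dW, db, dg, dWout, dbout, theta.n_elem);
  return out;
}
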