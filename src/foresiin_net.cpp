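// Recurrent core of the ForeSIIN model.
//
// Three variants over a T x m summarized sequence:
//   0 "independent": one GRU (scalar input, hidden h) + one small head per
//     feature, combined additively: z = b + sum_j w_j * u_j. The per-feature
//     effect e_j = w_j * u_j is the interpretability contract.
//   1 "shared_head": per-feature GRUs, concatenated final states through one
//     shared head -> logit.
//   2 "pooled_gru": a single GRU over the m-dimensional input -> head -> logit.
//
// Parameters live in one flat vector (layouts below, column-major matrices).
// All recurrences are batched across patients (hidden states are h x n
// matrices). Gradients are exact backpropagation-through-time, verified
// against finite differences in the test suite; for the per-feature variants
// the forward gate caches of each branch are recomputed during the backward
// pass so memory stays O(h * n * T) regardless of m. Only the final hidden
// state feeds the head.

#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]
using namespace arma;

static inline mat sigm(const mat& x) { return 1.0 / (1.0 + exp(-x)); }

// numerically stable binary cross-entropy on the logit scale, per element
static inline rowvec bce_logit(const rowvec& z, const rowvec& y) {
  return max(z, zeros<rowvec>(z.n_elem)) - y % z + log1p(exp(-abs(z)));
}

struct Gru {
  mat Wr, Wz, Wc, Ur, Uz, Uc;
  vec br, bz, bc;
  void zeros_like(int h, int d) {
    Wr.zeros(h, d); Wz.zeros(h, d); Wc.zeros(h, d);
    Ur.zeros(h, h); Uz.zeros(h, h); Uc.zeros(h, h);
    br.zeros(h); bz.zeros(h); bc.zeros(h);
  }
};

struct Head {
  mat W1; vec b1, w2; double b2 = 0.0;
  void zeros_like(int k, int hin) {
    W1.zeros(k, hin); b1.zeros(k); w2.zeros(k); b2 = 0.0;
  }
};

static Gru read_gru(const double* p, size_t& off, int h, int d) {
  Gru g;
  g.Wr = mat(&p[off], h, d); off += (size_t)h * d;
  g.Wz = mat(&p[off], h, d); off += (size_t)h * d;
  g.Wc = mat(&p[off], h, d); off += (size_t)h * d;
  g.Ur = mat(&p[off], h, h); off += (size_t)h * h;
  g.Uz = mat(&p[off], h, h); off += (size_t)h * h;
  g.Uc = mat(&p[off], h, h); off += (size_t)h * h;
  g.br = vec(&p[off], h); off += h;
  g.bz = vec(&p[off], h); off += h;
  g.bc = vec(&p[off], h); off += h;
  return g;
}

static Head read_head(const double* p, size_t& off, int k, int hin) {
  Head hd;
  hd.W1 = mat(&p[off], k, hin); off += (size_t)k * hin;
  hd.b1 = vec(&p[off], k); off += k;
  hd.w2 = vec(&p[off], k); off += k;
  hd.b2 = p[off]; off += 1;
  return hd;
}

static void write_block(vec& out, size_t& off, const mat& x) {
  std::copy(x.memptr(), x.memptr() + x.n_elem, out.memptr() + off);
  off += x.n_elem;
}

static void write_gru(vec& out, size_t& off, const Gru& g) {
  write_block(out, off, g.Wr); write_block(out, off, g.Wz);
  write_block(out, off, g.Wc); write_block(out, off, g.Ur);
  write_block(out, off, g.Uz); write_block(out, off, g.Uc);
  write_block(out, off, g.br); write_block(out, off, g.bz);
  write_block(out, off, g.bc);
}

static void write_head(vec& out, size_t& off, const Head& hd) {
  write_block(out, off, hd.W1); write_block(out, off, hd.b1);
  write_block(out, off, hd.w2);
  out[off++] = hd.b2;
}

// Batched GRU forward over a d x n x T input (X.slice(t) = inputs at step t).
// If caches are supplied (non-null), gate activations and hidden states are
// stored for BPTT; Hs has T+1 slices with slice 0 = h0 = 0.
static void gru_forward(const Gru& g, const cube& X, mat& H,
                        cube* Hs, cube* Rs, cube* Zs, cube* Cs, cube* UCs) {
  const int T = X.n_slices;
  H.zeros();
  if (Hs) Hs->slice(0).zeros();
  for (int t = 0; t < T; ++t) {
    const mat& xt = X.slice(t);
    mat R = g.Wr * xt + g.Ur * H; R.each_col() += g.br; R = sigm(R);
    mat Z = g.Wz * xt + g.Uz * H; Z.each_col() += g.bz; Z = sigm(Z);
    mat UC = g.Uc * H;
    mat C = g.Wc * xt + R % UC; C.each_col() += g.bc; C = tanh(C);
    H = Z % H + (1.0 - Z) % C;
    if (Hs) {
      Rs->slice(t) = R; Zs->slice(t) = Z; Cs->slice(t) = C;
      UCs->slice(t) = UC; Hs->slice(t + 1) = H;
    }
  }
}

// Batched BPTT; dH is the gradient at the final hidden state (h x n).
static void gru_backward(const Gru& g, Gru& gg, const cube& X,
                         const cube& Hs, const cube& Rs, const cube& Zs,
                         const cube& Cs, const cube& UCs, mat dH) {
  const int T = X.n_slices;
  for (int t = T - 1; t >= 0; --t) {
    const mat& Hp = Hs.slice(t);
    const mat& R = Rs.slice(t);
    const mat& Z = Zs.slice(t);
    const mat& C = Cs.slice(t);
    const mat& UC = UCs.slice(t);
    const mat& xt = X.slice(t);
    mat dZ = dH % (Hp - C);
    mat dC = dH % (1.0 - Z);
    mat dHp = dH % Z;
    mat dac = dC % (1.0 - C % C);
    gg.Wc += dac * xt.t();
    gg.bc += sum(dac, 1);
    mat dR = dac % UC;
    mat duc = dac % R;
    gg.Uc += duc * Hp.t();
    dHp += g.Uc.t() * duc;
    mat daz = dZ % Z % (1.0 - Z);
    gg.Wz += daz * xt.t();
    gg.Uz += daz * Hp.t();
    gg.bz += sum(daz, 1);
    dHp += g.Uz.t() * daz;
    mat dar = dR % R % (1.0 - R);
    gg.Wr += dar * xt.t();
    gg.Ur += dar * Hp.t();
    gg.br += sum(dar, 1);
    dHp += g.Ur.t() * dar;
    dH = std::move(dHp);
  }
}

// head forward: V = tanh(W1 * Hin + b1); u = w2'V + b2  (1 x n)
static rowvec head_forward(const Head& hd, const mat& Hin, mat& V) {
  V = hd.W1 * Hin;
  V.each_col() += hd.b1;
  V = tanh(V);
  return hd.w2.t() * V + hd.b2;
}

static mat head_backward(const Head& hd, Head& ghd,
                         const mat& Hin, const mat& V, const rowvec& du) {
  ghd.w2 += V * du.t();
  ghd.b2 += accu(du);
  mat dVp = (hd.w2 * du) % (1.0 - V % V);
  ghd.W1 += dVp * Hin.t();
  ghd.b1 += sum(dVp, 1);
  return hd.W1.t() * dVp;
}

// Extract branch j's scalar series as a 1 x n x T cube from the (T, m, n)
// data cube.
static cube branch_input(const cube& X, int j) {
  const int T = X.n_rows, n = X.n_slices;
  cube Xj(1, n, T);
  for (int i = 0; i < n; ++i)
    for (int t = 0; t < T; ++t)
      Xj(0, i, t) = X(t, j, i);
  return Xj;
}

// Transpose the (T, m, n) data cube into m x n x T step slices.
static cube pooled_input(const cube& X) {
  const int T = X.n_rows, m = X.n_cols, n = X.n_slices;
  cube Xp(m, n, T);
  for (int i = 0; i < n; ++i)
    for (int t = 0; t < T; ++t)
      for (int j = 0; j < m; ++j)
        Xp(j, i, t) = X(t, j, i);
  return Xp;
}

// [[Rcpp::export]]
Rcpp::List fsn_apply(Rcpp::NumericVector par_, Rcpp::NumericVector x_,
                     Rcpp::IntegerVector dims, int variant, int h, int k,
                     Rcpp::Nullable<Rcpp::NumericVector> y_, double lambda,
                     bool want_grad) {
  const int T = dims[0], m = dims[1], n = dims[2];
  if ((size_t)x_.size() != (size_t)T * m * n)
    Rcpp::stop("dimension error: input has %d values, expected %d x %d x %d",
               (int)x_.size(), T, m, n);
  const cube X(x_.begin(), T, m, n, false);
  const double* p = par_.begin();
  const size_t P = par_.size();

  const bool has_y = y_.isNotNull();
  rowvec y;
  if (has_y) {
    Rcpp::NumericVector yy(y_);
    if ((int)yy.size() != n) Rcpp::stop("labels/outputs misaligned");
    y = rowvec(yy.begin(), n);
    for (int i = 0; i < n; ++i)
      if (y[i] != 0.0 && y[i] != 1.0)
        Rcpp::stop("validation error: labels must be 0 or 1");
  }
  if (want_grad && !has_y) Rcpp::stop("gradient requires labels");

  // ---- read parameters ------------------------------------------------
  size_t off = 0;
  std::vector<Gru> grus;
  std::vector<Head> heads;
  Head shead; Gru pgru; Head phead;
  vec wcomb; double bcomb = 0.0;
  if (variant == 0) {
    for (int j = 0; j < m; ++j) {
      grus.push_back(read_gru(p, off, h, 1));
      heads.push_back(read_head(p, off, k, h));
    }
    wcomb = vec(&p[off], m); off += m;
    bcomb = p[off]; off += 1;
  } else if (variant == 1) {
    for (int j = 0; j < m; ++j) grus.push_back(read_gru(p, off, h, 1));
    shead = read_head(p, off, k, m * h);
  } else if (variant == 2) {
    pgru = read_gru(p, off, h, m);
    phead = read_head(p, off, k, h);
  } else Rcpp::stop("unknown variant code");
  if (off != P)
    Rcpp::stop("parameter vector has length %d, expected %d", (int)P, (int)off);

  rowvec z(n, fill::zeros);
  mat U, E;  // n x m branch outputs / effects (independent variant)
  mat Hcat;  // (m*h) x n concatenated final states (shared head)
  mat HT(h, n), V;
  double loss = NA_REAL;

  // ---- forward --------------------------------------------------------
  if (variant == 0) {
    U.set_size(n, m); E.set_size(n, m);
    z.fill(bcomb);
    for (int j = 0; j < m; ++j) {
      cube Xj = branch_input(X, j);
      gru_forward(grus[j], Xj, HT, nullptr, nullptr, nullptr, nullptr, nullptr);
      rowvec uj = head_forward(heads[j], HT, V);
      U.col(j) = uj.t();
      E.col(j) = wcomb[j] * uj.t();
      z += wcomb[j] * uj;
    }
  } else if (variant == 1) {
    Hcat.set_size(m * h, n);
    for (int j = 0; j < m; ++j) {
      cube Xj = branch_input(X, j);
      gru_forward(grus[j], Xj, HT, nullptr, nullptr, nullptr, nullptr, nullptr);
      Hcat.rows(j * h, (j + 1) * h - 1) = HT;
    }
    z = head_forward(shead, Hcat, V);
  } else {
    cube Xp = pooled_input(X);
    cube Hs(h, n, T + 1), Rs(h, n, T), Zs(h, n, T), Cs(h, n, T), UCs(h, n, T);
    if (want_grad) {
      gru_forward(pgru, Xp, HT, &Hs, &Rs, &Zs, &Cs, &UCs);
      z = head_forward(phead, HT, V);
      rowvec dz = (sigm(z) - y) / n;
      Gru gpgru; gpgru.zeros_like(h, m);
      Head gphead; gphead.zeros_like(k, h);
      mat dH = head_backward(phead, gphead, HT, V, dz);
      gru_backward(pgru, gpgru, Xp, Hs, Rs, Zs, Cs, UCs, dH);
      loss = accu(bce_logit(z, y)) / n;
      vec gradv(P);
      size_t goff = 0;
      write_gru(gradv, goff, gpgru);
      write_head(gradv, goff, gphead);
      return Rcpp::List::create(
        Rcpp::Named("logit") = Rcpp::NumericVector(z.begin(), z.end()),
        Rcpp::Named("loss") = loss,
        Rcpp::Named("grad") = Rcpp::NumericVector(gradv.begin(), gradv.end()));
    }
    gru_forward(pgru, Xp, HT, nullptr, nullptr, nullptr, nullptr, nullptr);
    z = head_forward(phead, HT, V);
  }

  if (has_y) {
    loss = accu(bce_logit(z, y)) / n;
    // composite term: every branch output is its own sub-classifier,
    // trained against the shared label through sigmoid(u_j)
    if (variant == 0 && lambda > 0) {
      double lb = 0.0;
      for (int j = 0; j < m; ++j)
        lb += accu(bce_logit(U.col(j).t(), y));
      loss += lambda * lb / (m * (double)n);
    }
  }

  // ---- backward (per-feature variants): recompute branch caches -------
  Rcpp::List out = Rcpp::List::create(
    Rcpp::Named("logit") = Rcpp::NumericVector(z.begin(), z.end()),
    Rcpp::Named("loss") = has_y ? Rcpp::wrap(loss) : R_NilValue);

  if (want_grad && variant != 2) {
    rowvec dz = (sigm(z) - y) / n;
    vec gradv(P, fill::zeros);
    cube Hs(h, n, T + 1), Rs(h, n, T), Zs(h, n, T), Cs(h, n, T), UCs(h, n, T);
    size_t goff = 0;
    Gru gg; Head gh;
    if (variant == 0) {
      vec gwcomb(m, fill::zeros);
      double gbcomb = accu(dz);
      for (int j = 0; j < m; ++j) {
        cube Xj = branch_input(X, j);
        gru_forward(grus[j], Xj, HT, &Hs, &Rs, &Zs, &Cs, &UCs);
        rowvec uj = head_forward(heads[j], HT, V);
        gwcomb[j] = accu(dz % uj);
        rowvec du = wcomb[j] * dz;
        if (lambda > 0)
          du += (lambda / m) * (sigm(uj) - y) / n;
        gg.zeros_like(h, 1);
        gh.zeros_like(k, h);
        mat dH = head_backward(heads[j], gh, HT, V, du);
        gru_backward(grus[j], gg, Xj, Hs, Rs, Zs, Cs, UCs, dH);
        write_gru(gradv, goff, gg);
        write_head(gradv, goff, gh);
      }
      write_block(gradv, goff, gwcomb);
      gradv[goff++] = gbcomb;
    } else {
      Head gshead; gshead.zeros_like(k, m * h);
      mat dHcat = head_backward(shead, gshead, Hcat, V, dz);
      for (int j = 0; j < m; ++j) {
        cube Xj = branch_input(X, j);
        gru_forward(grus[j], Xj, HT, &Hs, &Rs, &Zs, &Cs, &UCs);
        gg.zeros_like(h, 1);
        mat dH = dHcat.rows(j * h, (j + 1) * h - 1);
        gru_backward(grus[j], gg, Xj, Hs, Rs, Zs, Cs, UCs, dH);
        write_gru(gradv, goff, gg);
      }
      write_head(gradv, goff, gshead);
    }
    out["grad"] = Rcpp::NumericVector(gradv.begin(), gradv.end());
  }

  if (variant == 0) {
    out["branch"] = Rcpp::wrap(U);
    out["effects"] = Rcpp::wrap(E);
  }
  return out;
}

// [[Rcpp::export]]
int fsn_param_count(int variant, int h, int k, int m) {
  const size_t gru1 = 6 * (size_t)h + 3 * (size_t)h * h;  // d = 1
  if (variant == 0)
    return (int)(m * (gru1 + (size_t)k * h + 2 * k + 1) + m + 1);
  if (variant == 1)
    return (int)(m * gru1 + (size_t)k * m * h + 2 * k + 1);
  return (int)(3 * (size_t)h * m + 3 * (size_t)h * h + 3 * (size_t)h +
               (size_t)k * h + 2 * k + 1);
}
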