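#include <Rcpp.h>
#include <cstdint>
#include <cmath>
#include <vector>
#include <algorithm>
using namespace Rcpp;

// Portable deterministic RNG (splitmix64) so that a given integer seed yields
// byte-identical training runs on any platform, independent of R's RNG state.
struct SplitMix {
  uint64_t state;
  explicit SplitMix(uint64_t seed) : state(seed) {}
  uint64_t next() {
    uint64_t z = (state += 0x9E3779B97F4A7C15ULL);
    z = (z ^ (z >> 30)) * 0xBF58476D1CE4E5B9ULL;
    z = (z ^ (z >> 27)) * 0x94D049BB133111EBULL;
    return z ^ (z >> 31);
  }
  // uniform in [0, 1)
  double unif() { return (next() >> 11) * (1.0 / 9007199254740992.0); }
  // uniform integer in 0..n-1
  int unif_int(int n) {
    int k = (int)(unif() * n);
    return k >= n ? n - 1 : k;
  }
};

// ---------------------------------------------------------------------------
// I-H-1 network: hidden layer tanh, output unit (tanh + 1)/2 against {0,1}
// targets.  W1 is (I+1) x H with the bias on the last row; W2 has length
// H + 1 with the bias last.

static inline double net_output(const std::vector<double> &W1,
                                const std::vector<double> &W2,
                                const double *x, int I, int H,
                                double *h /* length H, filled */) {
  for (int j = 0; j < H; ++j) {
    double s = W1[j * (I + 1) + I];  // bias
    for (int i = 0; i < I; ++i) s += W1[j * (I + 1) + i] * x[i];
    h[j] = std::tanh(s);
  }
  double s = W2[H];
  for (int j = 0; j < H; ++j) s += W2[j] * h[j];
  return (std::tanh(s) + 1.0) / 2.0;
}

// X row-major (n x I) in a flat buffer
static double mse_on(const std::vector<double> &W1, const std::vector<double> &W2,
                     const double *X, const double *y, int n, int I, int H) {
  if (n == 0) return NA_REAL;
  std::vector<double> h(H);
  double acc = 0.0;
  for (int s = 0; s < n; ++s) {
    double o = net_output(W1, W2, X + (size_t)s * I, I, H, h.data());
    double e = o - y[s];
    acc += e * e;
  }
  return acc / n;
}

static std::vector<double> rowmajor(const NumericMatrix &X) {
  std::vector<double> out((size_t)X.nrow() * X.ncol());
  for (int s = 0; s < X.nrow(); ++s)
    for (int i = 0; i < X.ncol(); ++i) out[(size_t)s * X.ncol() + i] = X(s, i);
  return out;
}

// Per-pattern backpropagation with momentum; sequential updates, pattern
// order reshuffled every epoch.  Early stopping: training halts when the
// test-partition MSE has not improved by at least `threshold` within the
// last `window` epochs; the weights at the best test MSE seen are returned.
// [[Rcpp::export]]
List ann_train_cpp(NumericMatrix Xtr, NumericVector ytr,
                   NumericMatrix Xte, NumericVector yte,
                   int hidden, double lr, double momentum,
                   int max_epochs, int window, double threshold,
                   int seed) {
  const int n = Xtr.nrow(), I = Xtr.ncol(), H = hidden;
  const int nte = Xte.nrow();
  const int nw1 = (I + 1) * H, nw2 = H + 1;
  SplitMix rng((uint64_t)seed * 2654435761ULL + 1ULL);

  std::vector<double> xtr = rowmajor(Xtr), xte = rowmajor(Xte);
  std::vector<double> ytr_(ytr.begin(), ytr.end()), yte_(yte.begin(), yte.end());

  std::vector<double> W1(nw1), W2(nw2), V1(nw1, 0.0), V2(nw2, 0.0);
  for (int k = 0; k < nw1; ++k) W1[k] = rng.unif() - 0.5;
  for (int k = 0; k < nw2; ++k) W2[k] = rng.unif() - 0.5;

  std::vector<int> ord(n);
  for (int s = 0; s < n; ++s) ord[s] = s;
  std::vector<double> h(H);

  std::vector<double> bW1 = W1, bW2 = W2;
  double best_mse = R_PosInf;   // strict minimum -> kept weights
  double bench_mse = R_PosInf;  // benchmark for >= threshold improvements
  int last_improve = 0, epoch = 0;

  for (epoch = 1; epoch <= max_epochs; ++epoch) {
    // Fisher-Yates shuffle
    for (int s = n - 1; s > 0; --s) {
      int j = rng.unif_int(s + 1);
      std::swap(ord[s], ord[j]);
    }
    for (int si = 0; si < n; ++si) {
      int s = ord[si];
      const double *x = xtr.data() + (size_t)s * I;
      // forward
      for (int j = 0; j < H; ++j) {
        double acc = W1[j * (I + 1) + I];
        for (int i = 0; i < I; ++i) acc += W1[j * (I + 1) + i] * x[i];
        h[j] = std::tanh(acc);
      }
      double net2 = W2[H];
      for (int j = 0; j < H; ++j) net2 += W2[j] * h[j];
      double t = std::tanh(net2);
      double o = (t + 1.0) / 2.0;
      // backward: d/dnet2 of (o - y)^2 = 2 (o - y) (1 - t^2)/2
      double d2 = (o - ytr_[s]) * (1.0 - t * t);
      for (int j = 0; j < H; ++j) {
        double g = d2 * h[j];
        V2[j] = -lr * g + momentum * V2[j];
        double d1 = d2 * W2[j] * (1.0 - h[j] * h[j]);
        W2[j] += V2[j];
        for (int i = 0; i < I; ++i) {
          int k = j * (I + 1) + i;
          V1[k] = -lr * d1 * x[i] + momentum * V1[k];
          W1[k] += V1[k];
        }
        int kb = j * (I + 1) + I;
        V1[kb] = -lr * d1 + momentum * V1[kb];
        W1[kb] += V1[kb];
      }
      V2[H] = -lr * d2 + momentum * V2[H];
      W2[H] += V2[H];
      if (!std::isfinite(W2[H]))
        stop("ANN training diverged (non-finite weights) at epoch %d", epoch);
    }
    double te = mse_on(W1, W2, xte.data(), yte_.data(), nte, I, H);
    if (!std::isfinite(te))
      stop("ANN training diverged (non-finite test MSE) at epoch %d", epoch);
    if (te < best_mse) { best_mse = te; bW1 = W1; bW2 = W2; }
    if (bench_mse - te >= threshold) { bench_mse = te; last_improve = epoch; }
    if (epoch - last_improve >= window) break;
  }
  if (epoch > max_epochs) epoch = max_epochs;

  NumericMatrix W1out(I + 1, H);
  for (int j = 0; j < H; ++j)
    for (int i = 0; i <= I; ++i) W1out(i, j) = bW1[j * (I + 1) + i];
  NumericVector W2out(nw2);
  for (int k = 0; k < nw2; ++k) W2out[k] = bW2[k];

  return List::create(
    _["W1"] = W1out, _["W2"] = W2out, _["epochs"] = epoch,
    _["train_mse"] = mse_on(bW1, bW2, xtr.data(), ytr_.data(), n, I, H),
    _["test_mse"] = best_mse);
}

// [[Rcpp::export]]
NumericVector ann_predict_cpp(NumericMatrix W1, NumericVector W2,
                              NumericMatrix X) {
  int n = X.nrow(), I = X.ncol(), H = W1.ncol();
  if (W1.nrow() != I + 1) stop("weight/input dimension mismatch");
  std::vector<double> w1(W1.nrow() * H), w2(W2.size());
  for (int j = 0; j < H; ++j)
    for (int i = 0; i <= I; ++i) w1[j * (I + 1) + i] = W1(i, j);
  for (int k = 0; k < W2.size(); ++k) w2[k] = W2[k];
  std::vector<double> x(I), h(H);
  NumericVector out(n);
  for (int s = 0; s < n; ++s) {
    for (int i = 0; i < I; ++i) x[i] = X(s, i);
    out[s] = net_output(w1, w2, x.data(), I, H, h.data());
  }
  return out;
}

// Mean squared error over the batch and its analytic gradient; used by the
// finite-difference gradient checks.
// [[Rcpp::export]]
List ann_loss_grad_cpp(NumericMatrix W1, NumericVector W2,
                       NumericMatrix X, NumericVector y) {
  int n = X.nrow(), I = X.ncol(), H = W1.ncol();
  if (W1.nrow() != I + 1) stop("weight/input dimension mismatch");
  NumericMatrix g1(I + 1, H);
  NumericVector g2(H + 1);
  std::vector<double> h(H);
  double loss = 0.0;
  for (int s = 0; s < n; ++s) {
    for (int j = 0; j < H; ++j) {
      double acc = W1(I, j);
      for (int i = 0; i < I; ++i) acc += W1(i, j) * X(s, i);
      h[j] = std::tanh(acc);
    }
    double net2 = W2[H];
    for (int j = 0; j < H; ++j) net2 += W2[j] * h[j];
    double t = std::tanh(net2);
    double o = (t + 1.0) / 2.0;
    double e = o - y[s];
    loss += e * e;
    double d2 = 2.0 * e * (1.0 - t * t) / 2.0 / n;
    g2[H] += d2;
    for (int j = 0; j < H; ++j) {
      g2[j] += d2 * h[j];
      double d1 = d2 * W2[j] * (1.0 - h[j] * h[j]);
      g1(I, j) += d1;
      for (int i = 0; i < I; ++i) g1(i, j) += d1 * X(s, i);
    }
  }
  return List::create(_["loss"] = loss / n, _["gW1"] = g1, _["gW2"] = g2);
}

// ---------------------------------------------------------------------------
// GA + feedforward 20-2-2 reducer.  A chromosome is nf feature genes in
// [0,1) followed by the network weights in [-1,1]: hidden layer
// (nf+1) x 2 column-blocks then output layer 3 x 2 column-blocks, bias last
// in each block.  Fitness = number of correctly argmax-classified samples
// (output tie -> class 0).

struct GaCtx {
  const std::vector<double> &X;  // column-major n x p
  const std::vector<int> &y;
  int n, p, nf, H, nout;
};

static int ga_fitness(const std::vector<double> &genes, const GaCtx &c) {
  const int n = c.n;
  const int woff = c.nf;
  const int w1sz = (c.nf + 1) * c.H;
  std::vector<const double *> col(c.nf);
  for (int j = 0; j < c.nf; ++j) {
    int k = (int)(genes[j] * c.p);
    if (k >= c.p) k = c.p - 1;
    col[j] = c.X.data() + (size_t)k * n;
  }
  int correct = 0;
  std::vector<double> h(c.H), o(c.nout);
  for (int s = 0; s < n; ++s) {
    for (int j = 0; j < c.H; ++j) {
      double acc = genes[woff + j * (c.nf + 1) + c.nf];
      for (int i = 0; i < c.nf; ++i)
        acc += genes[woff + j * (c.nf + 1) + i] * col[i][s];
      h[j] = std::tanh(acc);
    }
    for (int k = 0; k < c.nout; ++k) {
      double acc = genes[woff + w1sz + k * (c.H + 1) + c.H];
      for (int j = 0; j < c.H; ++j)
        acc += genes[woff + w1sz + k * (c.H + 1) + j] * h[j];
      o[k] = std::tanh(acc);
    }
    int pred = 0;
    for (int k = 1; k < c.nout; ++k) if (o[k] > o[pred]) pred = k;
    if (pred == c.y[s]) ++correct;
  }
  return correct;
}

// Steady-state GA: per generation two tournament parents produce two
// children (single-point crossover with prob p_cross, per-gene uniform
// resampling mutation with prob p_mut); the N-1 fittest of population plus
// children survive, joined by the fitter child, so the best-so-far is never
// lost.  Runs until the evaluation counter reaches `budget`.
// [[Rcpp::export]]
List gann_run_cpp(NumericMatrix X, IntegerVector y,
                  int pop_size, int chrom_features, int hidden, int n_out,
                  double p_cross, double p_mut, int tournament,
                  int budget, int seed) {
  const int p = X.ncol(), nsamp = X.nrow();
  std::vector<double> xflat(X.begin(), X.end());     // column-major
  std::vector<int> yvec(y.begin(), y.end());
  GaCtx ctx{xflat, yvec, nsamp, p, chrom_features, hidden, n_out};
  const int nW = (chrom_features + 1) * hidden + (hidden + 1) * n_out;
  const int L = chrom_features + nW;
  SplitMix rng((uint64_t)seed * 0x9E3779B97F4A7C15ULL + 7ULL);

  if (budget < pop_size) stop("evaluation budget smaller than population size");

  std::vector<std::vector<double>> pop(pop_size, std::vector<double>(L));
  std::vector<int> fit(pop_size);
  for (int c = 0; c < pop_size; ++c) {
    for (int g = 0; g < chrom_features; ++g) pop[c][g] = rng.unif();
    for (int g = chrom_features; g < L; ++g) pop[c][g] = 2.0 * rng.unif() - 1.0;
    fit[c] = ga_fitness(pop[c], ctx);
  }
  int evals = pop_size;

  std::vector<double> traj;
  traj.push_back(*std::max_element(fit.begin(), fit.end()));

  auto tourney = [&]() -> int {
    int best = rng.unif_int(pop_size);
    for (int t = 1; t < tournament; ++t) {
      int c = rng.unif_int(pop_size);
      if (fit[c] > fit[best] || (fit[c] == fit[best] && rng.unif() < 0.5))
        best = c;
    }
    return best;
  };

  while (evals + 2 <= budget) {
    int a = tourney(), b = tourney();
    std::vector<double> c1 = pop[a], c2 = pop[b];
    if (rng.unif() < p_cross) {
      int cut = 1 + rng.unif_int(L - 1);  // cut in 1..L-1, same for both
      for (int g = cut; g < L; ++g) std::swap(c1[g], c2[g]);
    }
    for (auto *ch : {&c1, &c2})
      for (int g = 0; g < L; ++g)
        if (rng.unif() < p_mut)
          (*ch)[g] = g < chrom_features ? rng.unif() : 2.0 * rng.unif() - 1.0;
    int f1 = ga_fitness(c1, ctx), f2 = ga_fitness(c2, ctx);
    evals += 2;

    // N-1 best of (pop U children) + fitter child
    std::vector<int> rank(pop_size + 2);
    for (int i = 0; i < pop_size + 2; ++i) rank[i] = i;
    auto fof = [&](int i) { return i < pop_size ? fit[i] : (i == pop_size ? f1 : f2); };
    std::stable_sort(rank.begin(), rank.end(),
                     [&](int i, int j) { return fof(i) > fof(j); });
    std::vector<std::vector<double>> np;
    np.reserve(pop_size);
    std::vector<int> nf_;
    for (int i = 0; i < pop_size - 1; ++i) {
      int r = rank[i];
      np.push_back(r < pop_size ? pop[r] : (r == pop_size ? c1 : c2));
      nf_.push_back(fof(r));
    }
    if (f1 >= f2) { np.push_back(c1); nf_.push_back(f1); }
    else          { np.push_back(c2); nf_.push_back(f2); }
    pop.swap(np);
    fit = nf_;
    traj.push_back(*std::max_element(fit.begin(), fit.end()));
  }

  int best = 0;
  for (int c = 1; c < pop_size; ++c) if (fit[c] > fit[best]) best = c;
  NumericVector fg(chrom_features), wg(nW);
  for (int g = 0; g < chrom_features; ++g) fg[g] = pop[best][g];
  for (int g = 0; g < nW; ++g) wg[g] = pop[best][chrom_features + g];
  return List::create(
    _["feature_genes"] = fg, _["weight_genes"] = wg,
    _["best_fitness"] = fit[best],
    _["trajectory"] = NumericVector(traj.begin(), traj.end()),
    _["evaluations"] = evals);
}
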