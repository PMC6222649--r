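#include <Rcpp.h>
#include <cmath>
#include <vector>
using namespace Rcpp;

// One epoch of online (per-pattern) back-propagation with momentum — the
// generalized delta rule. Error per pattern is E = 0.5 * (t - o)^2; the
// update is dw(t) = -eta * dE/dw + alpha * dw(t-1), applied after every
// pattern in the order given by `ord` (0-based). Weight matrices are
// n_in x n_out; activations are tanh everywhere, optionally linear at the
// output. Inputs are cloned; the updated state is returned.
// [[Rcpp::export]]
List ann_epoch_cpp(List W, List b, List dW, List dB,
                   NumericMatrix X, NumericVector y, IntegerVector ord,
                   double eta, double alpha, bool linear_output) {
  const int L = W.size();
  std::vector<NumericMatrix> Wv(L), dWv(L);
  std::vector<NumericVector> bv(L), dBv(L);
  for (int l = 0; l < L; ++l) {
    Wv[l]  = clone(as<NumericMatrix>(W[l]));
    dWv[l] = clone(as<NumericMatrix>(dW[l]));
    bv[l]  = clone(as<NumericVector>(b[l]));
    dBv[l] = clone(as<NumericVector>(dB[l]));
  }
  const int d = X.ncol();
  std::vector< std::vector<double> > a(L + 1), delta(L);
  a[0].resize(d);
  for (int l = 0; l < L; ++l) {
    a[l + 1].resize(bv[l].size());
    delta[l].resize(bv[l].size());
  }

  for (int pi = 0; pi < ord.size(); ++pi) {
    const int i = ord[pi];
    for (int j = 0; j < d; ++j) a[0][j] = X(i, j);

    // forward pass
    for (int l = 0; l < L; ++l) {
      const int nin = Wv[l].nrow(), nout = Wv[l].ncol();
      const bool lin = linear_output && (l == L - 1);
      for (int o = 0; o < nout; ++o) {
        double s = bv[l][o];
        for (int in = 0; in < nin; ++in) s += a[l][in] * Wv[l](in, o);
        a[l + 1][o] = lin ? s : std::tanh(s);
      }
    }

    const double out = a[L][0];
    if (!std::isfinite(out)) stop("non-finite network output during training");
    const double err = y[i] - out;

    // delta_j = -dE/dnet_j; for the output: (t - o) * f'(net)
    delta[L - 1][0] = linear_output ? err : err * (1.0 - out * out);
    for (int l = L - 2; l >= 0; --l) {
      const int nj = delta[l].size(), no = delta[l + 1].size();
      for (int j = 0; j < nj; ++j) {
        double s = 0.0;
        for (int o = 0; o < no; ++o) s += delta[l + 1][o] * Wv[l + 1](j, o);
        const double aj = a[l + 1][j];
        delta[l][j] = s * (1.0 - aj * aj);
      }
    }

    // momentum update, applied immediately (online learning)
    for (int l = 0; l < L; ++l) {
      const int nin = Wv[l].nrow(), nout = Wv[l].ncol();
      for (int o = 0; o < nout; ++o) {
        const double dl = delta[l][o];
        for (int in = 0; in < nin; ++in) {
          const double upd = eta * dl * a[l][in] + alpha * dWv[l](in, o);
          dWv[l](in, o) = upd;
          Wv[l](in, o) += upd;
        }
        const double updb = eta * dl + alpha * dBv[l][o];
        dBv[l][o] = updb;
        bv[l][o] += updb;
      }
    }
  }

  List Wout(L), bout(L), dWout(L), dBout(L);
  for (int l = 0; l < L; ++l) {
    Wout[l] = Wv[l]; bout[l] = bv[l]; dWout[l] = dWv[l]; dBout[l] = dBv[l];
  }
  return List::create(_["W"] = Wout, _["b"] = bout,
                      _["dW"] = dWout, _["dB"] = dBout);
}
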