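// Hot inner kernels of the network step: accumulation of spike-driven
// synaptic input over a compressed-sparse-column edge store (columns =
// presynaptic units) and the in-place ABS weight update over all edges.
// Raw pointer access: these loops run once per simulated step over the
// full edge store, so per-element accessor overhead matters.
#include <Rcpp.h>
using namespace Rcpp;

// Sum of weights of edges from the given (0-based) spiking presynaptic
// units, accumulated onto their postsynaptic targets.
// [[Rcpp::export]]
NumericVector csc_spike_input(IntegerVector p_, IntegerVector i_,
                              NumericVector x_, IntegerVector spikes_,
                              int n_post) {
  NumericVector out_(n_post);
  const int *p = INTEGER(p_);
  const int *i = INTEGER(i_);
  const double *x = REAL(x_);
  const int *spikes = INTEGER(spikes_);
  double *out = REAL(out_);
  const int ns = spikes_.size();
  for (int s = 0; s < ns; ++s) {
    const int col = spikes[s];
    const int kend = p[col + 1];
    for (int k = p[col]; k < kend; ++k) out[i[k]] += x[k];
  }
  return out_;
}

// One ABS update of every edge weight, in place, with clipping.
// pre_active[j]: presynaptic rate estimate of column j >= theta_pre.
// Branch order makes LTP win at v == theta_plus.
// [[Rcpp::export]]
void abs_plasticity_csc(IntegerVector p_, IntegerVector i_,
                        NumericVector x_, LogicalVector pre_active_,
                        NumericVector v_post_, double theta_plus,
                        double theta_minus, double delta, double w_min,
                        double w_max) {
  const int *p = INTEGER(p_);
  const int *i = INTEGER(i_);
  double *x = REAL(x_);
  const int *act = LOGICAL(pre_active_);
  const double *v = REAL(v_post_);
  const int ncol = p_.size() - 1;
  for (int j = 0; j < ncol; ++j) {
    const bool a = act[j] != 0;
    const int kend = p[j + 1];
    for (int k = p[j]; k < kend; ++k) {
      const double vv = v[i[k]];
      double w = x[k];
      if (a) {
        if (vv >= theta_plus) w += delta;
        else if (vv >= theta_minus) w -= delta;
        else continue;
      } else if (vv >= theta_plus) {
        w -= delta;
      } else {
        continue;
      }
      if (w > w_max) w = w_max;
      else if (w < w_min) w = w_min;
      x[k] = w;
    }
  }
}
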