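#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]

// Propagate a linear compartmental system on a uniform time grid with bolus
// doses into the first compartment. Exact for linear kinetics: one matrix
// exponential of A*dt, then repeated matrix-vector propagation.
//
// A:          system matrix (1/h), compartments x compartments
// dt:         grid step (h)
// n_steps:    number of steps; grid has n_steps + 1 points
// dose_step:  0-based grid indices of doses (sorted, may repeat)
// dose_amt:   dose amounts (umol) entering compartment 0
// central:    0-based index of the observation (central) compartment
//
// Returns the amount (umol) in the central compartment at each grid point.
// [[Rcpp::export]]
arma::vec pk_step_profile(const arma::mat& A, double dt, int n_steps,
                          const arma::ivec& dose_step,
                          const arma::vec& dose_amt, int central) {
  arma::mat M = arma::expmat(A * dt);
  arma::vec v(A.n_rows, arma::fill::zeros);
  arma::vec out(n_steps + 1);
  unsigned int d = 0;
  for (int i = 0; i <= n_steps; ++i) {
    while (d < dose_step.n_elem && dose_step[d] == i) {
      v[0] += dose_amt[d];
      ++d;
    }
    out[i] = v[central];
    if (i < n_steps) v = M * v;
  }
  return out;
}
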