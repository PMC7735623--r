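#include <Rcpp.h>
using namespace Rcpp;

// Lattice random walk on a star: branches of n_sites[i] lattice steps,
// outward step probability q[i].  Walkers start at the junction; there a
// branch is picked uniformly and an outward step taken with probability
// q (else the walker stays put for that step).  Interior sites step
// outward with q, inward with 1-q; reaching site n_sites[i] absorbs.
// Every attempt costs one lattice time step (tau = h^2 / D).
// Uses R's RNG so set.seed() gives bit-identical results.
// [[Rcpp::export]]
List walk_star_cpp(IntegerVector n_sites, NumericVector q,
                   int n_walkers, double max_steps) {
  const int nb = n_sites.size();
  IntegerVector branch(n_walkers, NA_INTEGER);
  NumericVector steps(n_walkers, NA_REAL);

  for (int w = 0; w < n_walkers; ++w) {
    int b = -1;   // -1 = junction
    int site = 0;
    double t = 0.0;
    while (t < max_steps) {
      t += 1.0;
      if (b < 0) {
        int j = (int)(unif_rand() * nb);
        if (j == nb) j = nb - 1;  // guard against unif_rand() == 1
        if (unif_rand() < q[j]) {
          b = j;
          site = 1;
          if (site == n_sites[b]) { branch[w] = b + 1; steps[w] = t; break; }
        }
      } else {
        if (unif_rand() < q[b]) {
          ++site;
          if (site == n_sites[b]) { branch[w] = b + 1; steps[w] = t; break; }
        } else {
          --site;
          if (site == 0) b = -1;
        }
      }
    }
  }
  return List::create(_["branch"] = branch, _["steps"] = steps);
}
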