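#include <Rcpp.h>
using namespace Rcpp;

// Rejection sampler for a Gaussian (ideal) chain pinned at fixed anchor
// points and confined to a sphere of radius `a` centred at the origin.
//
// The chain is discretised on `grid` (contour coordinates in Kuhn lengths,
// strictly increasing, first and last bead pinned).  `pins` holds 0-based
// indices of pinned beads and `pinpos` their 3D positions (3 x npin).
// Between consecutive pins beads are drawn sequentially from the Brownian
// bridge conditional law; a draw is abandoned as soon as any bead leaves
// the sphere.  `sig2` is the per-axis variance accumulated per unit Kuhn
// length (b^2/3 in um^2).
//
// Returns the accepted locus positions (n_acc x 3, bead index `iloc`),
// the number of attempts consumed, and the accepted count.
// [[Rcpp::export]]
List sample_confined_chain(NumericVector grid, IntegerVector pins,
                           NumericMatrix pinpos, double sig2, double a,
                           int iloc, int n_target, int max_attempts) {
  const int nb = grid.size(), npin = pins.size();
  const double a2 = a * a;
  NumericMatrix out(n_target, 3);
  std::vector<double> x(nb), y(nb), z(nb);
  int acc = 0, att = 0;
  while (acc < n_target && att < max_attempts) {
    att++;
    bool ok = true;
    for (int p = 0; p < npin; p++) {
      int i = pins[p];
      x[i] = pinpos(0, p); y[i] = pinpos(1, p); z[i] = pinpos(2, p);
      if (x[i] * x[i] + y[i] * y[i] + z[i] * z[i] > a2 * (1.0 + 1e-9))
        stop("pinned bead lies outside the confining sphere");
    }
    for (int p = 0; p < npin - 1 && ok; p++) {
      int i0 = pins[p], i1 = pins[p + 1];
      for (int i = i0 + 1; i < i1 && ok; i++) {
        double d = grid[i] - grid[i - 1];
        double rem = grid[i1] - grid[i - 1];
        double w = d / rem;
        double s = sqrt(sig2 * d * (rem - d) / rem);
        x[i] = x[i - 1] + (x[i1] - x[i - 1]) * w + R::norm_rand() * s;
        y[i] = y[i - 1] + (y[i1] - y[i - 1]) * w + R::norm_rand() * s;
        z[i] = z[i - 1] + (z[i1] - z[i - 1]) * w + R::norm_rand() * s;
        if (x[i] * x[i] + y[i] * y[i] + z[i] * z[i] > a2) ok = false;
      }
    }
    if (ok) {
      out(acc, 0) = x[iloc]; out(acc, 1) = y[iloc]; out(acc, 2) = z[iloc];
      acc++;
    }
  }
  return List::create(_["loc"] = out, _["n_acc"] = acc, _["attempts"] = att);
}
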