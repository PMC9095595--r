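#include <Rcpp.h>
using namespace Rcpp;

// Independent-swap randomization of a binary incidence matrix: performs
// n_iter successful 2x2 checkerboard swaps chosen uniformly among random
// row/column pairs. Row and column sums are preserved exactly. Uses R's RNG
// stream so results are reproducible under set.seed() and bit-identical to
// the pure-R reference implementation.
// [[Rcpp::export(name = ".indep_swap_cpp")]]
IntegerMatrix indep_swap_cpp(IntegerMatrix m_in, int n_iter, double max_tries) {
  IntegerMatrix m = clone(m_in);
  int nr = m.nrow(), nc = m.ncol();
  if (nr < 2 || nc < 2 || n_iter <= 0) {
    if (n_iter > 0) Rf_warning("matrix too small for checkerboard swaps; returned unchanged");
    return m;
  }
  int done = 0;
  double tries = 0.0;
  while (done < n_iter && tries < max_tries) {
    tries += 1.0;
    int r1 = (int)(unif_rand() * nr);
    int r2 = (int)(unif_rand() * (nr - 1));
    if (r2 >= r1) r2 += 1;
    int c1 = (int)(unif_rand() * nc);
    int c2 = (int)(unif_rand() * (nc - 1));
    if (c2 >= c1) c2 += 1;
    int a = m(r1, c1), b = m(r1, c2), c = m(r2, c1), d = m(r2, c2);
    if ((a == 1 && d == 1 && b == 0 && c == 0) ||
        (a == 0 && d == 0 && b == 1 && c == 1)) {
      m(r1, c1) = 1 - a; m(r1, c2) = 1 - b;
      m(r2, c1) = 1 - c; m(r2, c2) = 1 - d;
      ++done;
    }
  }
  if (done < n_iter)
    Rf_warning("independent swap: only %d of %d swaps achieved within attempt budget (matrix may lack checkerboards)",
               done, n_iter);
  return m;
}
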