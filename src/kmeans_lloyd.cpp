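// Lloyd iterations for k-means on window x edge matrices.
// R owns initialization (kmeans++), restarts and seeding; this kernel
// only iterates assignment/update from given initial centers, with
// empty clusters reseeded to the point farthest from its centroid.
#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]

// [[Rcpp::export(name = ".lloyd_iterate")]]
Rcpp::List lloyd_iterate(const arma::mat& x, arma::mat centers,
                         int max_iter) {
  const arma::uword n = x.n_rows;
  const arma::uword k = centers.n_rows;
  arma::vec xsq = arma::sum(arma::square(x), 1);
  arma::uvec cl(n, arma::fill::zeros);
  arma::uvec cl_old(n, arma::fill::ones);
  double obj = 0.0;

  for (int iter = 0; iter < max_iter; ++iter) {
    arma::vec csq = arma::sum(arma::square(centers), 1);
    // d(i, j) = ||x_i||^2 - 2 x_i c_j' + ||c_j||^2
    arma::mat d = -2.0 * (x * centers.t());
    d.each_col() += xsq;
    d.each_row() += csq.t();
    d.transform([](double v) { return v < 0.0 ? 0.0 : v; });

    arma::uvec cl_new(n);
    arma::vec best(n);
    for (arma::uword i = 0; i < n; ++i) {
      arma::uword j;
      best(i) = d.row(i).min(j);
      cl_new(i) = j;
    }
    // reseed empty clusters to the currently worst-fit point
    arma::uvec counts(k, arma::fill::zeros);
    for (arma::uword i = 0; i < n; ++i) counts(cl_new(i))++;
    for (arma::uword j = 0; j < k; ++j) {
      if (counts(j) == 0) {
        arma::uword far = best.index_max();
        counts(cl_new(far))--;
        centers.row(j) = x.row(far);
        cl_new(far) = j;
        counts(j) = 1;
        best(far) = 0.0;
      }
    }
    obj = arma::accu(best);

    // update centers
    arma::mat sums(k, x.n_cols, arma::fill::zeros);
    arma::vec cnt(k, arma::fill::zeros);
    for (arma::uword i = 0; i < n; ++i) {
      sums.row(cl_new(i)) += x.row(i);
      cnt(cl_new(i)) += 1.0;
    }
    for (arma::uword j = 0; j < k; ++j)
      if (cnt(j) > 0) centers.row(j) = sums.row(j) / cnt(j);

    if (arma::all(cl_new == cl)) { cl = cl_new; break; }
    cl = cl_new;
    (void)cl_old;
  }

  // final assignment/objective against the final centers
  arma::vec csq = arma::sum(arma::square(centers), 1);
  arma::mat d = -2.0 * (x * centers.t());
  d.each_col() += xsq;
  d.each_row() += csq.t();
  d.transform([](double v) { return v < 0.0 ? 0.0 : v; });
  arma::uvec cl_fin(n);
  double total = 0.0;
  for (arma::uword i = 0; i < n; ++i) {
    arma::uword j;
    total += d.row(i).min(j);
    cl_fin(i) = j;
  }
  return Rcpp::List::create(
      Rcpp::Named("centers") = centers,
      Rcpp::Named("cluster") =
          Rcpp::IntegerVector(cl_fin.begin(), cl_fin.end()),
      Rcpp::Named("objective") = total);
}
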