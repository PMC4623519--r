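// Least-squares superposition RMSD (Kabsch) over trajectory frames.
// Proper rotations are enforced: if the optimal orthogonal transform is a
// reflection, the smallest singular value is negated.

// [[Rcpp::depends(RcppArmadillo)]]
#include <RcppArmadillo.h>

using namespace Rcpp;

namespace {

// A, B: m x 3, already mean-centred. Returns the minimised RMSD.
double kabsch_rmsd_centred(const arma::mat& A, const arma::mat& B) {
  double e0 = arma::accu(A % A) + arma::accu(B % B);
  arma::mat H = A.t() * B; // 3 x 3
  arma::mat U, V;
  arma::vec s;
  if (!arma::svd(U, s, V, H)) Rcpp::stop("SVD failure in RMSD computation");
  double d = arma::det(U) * arma::det(V);
  double tr = s(0) + s(1) + ((d < 0) ? -s(2) : s(2));
  double msd = (e0 - 2.0 * tr) / A.n_rows;
  return msd > 0 ? std::sqrt(msd) : 0.0;
}

arma::mat frame_slice(const NumericVector& frames, int nf, int m, int f) {
  arma::mat X(m, 3);
  for (int k = 0; k < m; ++k)
    for (int d = 0; d < 3; ++d) X(k, d) = frames[f + nf * (k + m * d)];
  return X;
}

double rmsd_pair(arma::mat A, arma::mat B, bool fit) {
  if (fit) {
    A.each_row() -= arma::mean(A, 0);
    B.each_row() -= arma::mean(B, 0);
    return kabsch_rmsd_centred(A, B);
  }
  arma::mat D = A - B;
  return std::sqrt(arma::accu(D % D) / A.n_rows);
}

} // namespace

// [[Rcpp::export(name = ".rmsd_matrix_cpp")]]
NumericMatrix rmsd_matrix_cpp(NumericVector frames, bool fit) {
  IntegerVector dims = frames.attr("dim");
  int nf = dims[0], m = dims[1];
  NumericMatrix out(nf, nf);
  std::vector<arma::mat> fr(nf);
  for (int f = 0; f < nf; ++f) {
    fr[f] = frame_slice(frames, nf, m, f);
    if (fit) fr[f].each_row() -= arma::mean(fr[f], 0);
  }
  for (int a = 0; a < nf; ++a) {
    for (int b = a + 1; b < nf; ++b) {
      double r = fit ? kabsch_rmsd_centred(fr[a], fr[b])
                     : std::sqrt(arma::accu(arma::square(fr[a] - fr[b])) / m);
      out(a, b) = r;
      out(b, a) = r;
    }
  }
  return out;
}

// [[Rcpp::export(name = ".rmsd_to_refs_cpp")]]
NumericMatrix rmsd_to_refs_cpp(NumericVector frames, NumericVector refs,
                               bool fit) {
  IntegerVector fd = frames.attr("dim");
  IntegerVector rd = refs.attr("dim");
  int nf = fd[0], m = fd[1], nr = rd[0];
  if (rd[1] != m) stop("selection sizes differ between frames and references");
  NumericMatrix out(nf, nr);
  std::vector<arma::mat> rf(nr);
  for (int r = 0; r < nr; ++r) {
    rf[r] = frame_slice(refs, nr, m, r);
    if (fit) rf[r].each_row() -= arma::mean(rf[r], 0);
  }
  for (int f = 0; f < nf; ++f) {
    arma::mat A = frame_slice(frames, nf, m, f);
    if (fit) A.each_row() -= arma::mean(A, 0);
    for (int r = 0; r < nr; ++r) {
      out(f, r) = fit ? kabsch_rmsd_centred(A, rf[r]) : rmsd_pair(A, rf[r], false);
    }
  }
  return out;
}

// Single-pass leader clustering: each frame joins the first existing leader
// within `cutoff` RMSD, else founds a new cluster.
// [[Rcpp::export(name = ".leader_pass_cpp")]]
List leader_pass_cpp(NumericVector frames, double cutoff, bool fit) {
  IntegerVector dims = frames.attr("dim");
  int nf = dims[0], m = dims[1];
  std::vector<arma::mat> fr(nf);
  for (int f = 0; f < nf; ++f) {
    fr[f] = frame_slice(frames, nf, m, f);
    if (fit) fr[f].each_row() -= arma::mean(fr[f], 0);
  }
  std::vector<int> leaders;
  IntegerVector assign(nf);
  for (int f = 0; f < nf; ++f) {
    int hit = -1;
    for (size_t l = 0; l < leaders.size(); ++l) {
      double r = fit ? kabsch_rmsd_centred(fr[f], fr[leaders[l]])
                     : std::sqrt(arma::accu(arma::square(fr[f] - fr[leaders[l]])) / m);
      if (r <= cutoff) { hit = (int)l; break; }
    }
    if (hit < 0) {
      leaders.push_back(f);
      hit = (int)leaders.size() - 1;
    }
    assign[f] = hit + 1;
  }
  IntegerVector lead(leaders.size());
  for (size_t l = 0; l < leaders.size(); ++l) lead[l] = leaders[l] + 1;
  return List::create(_["assignment"] = assign, _["leaders"] = lead);
}
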