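// Batched rigid-body kernels: pairwise superposition-RMSD profiles for the
// central-frame search (O(F^2) 3x3 SVDs) and per-frame Kabsch transports.
// Coordinates arrive as an N x 3 x F cube in nm.

#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]

using namespace arma;

// Proper rotation (det = +1) minimising ||R * P' - Q'|| for row-point sets
// already centred at the origin; returns sum of corrected singular values.
static double kabsch_core(const mat& Pc, const mat& Qc, mat& R) {
    mat H = Pc.t() * Qc;           // 3x3 cross-covariance
    mat U, V;
    vec s;
    svd(U, s, V, H);
    double d = det(V * U.t()) < 0.0 ? -1.0 : 1.0;
    mat D = eye(3, 3);
    D(2, 2) = d;
    R = V * D * U.t();             // maps centred P onto centred Q
    return s(0) + s(1) + d * s(2);
}

// [[Rcpp::export]]
Rcpp::List cpp_kabsch(const arma::mat& P, const arma::mat& Q) {
    rowvec pc = mean(P, 0), qc = mean(Q, 0);
    mat Pc = P.each_row() - pc, Qc = Q.each_row() - qc;
    mat R;
    double strace = kabsch_core(Pc, Qc, R);
    double n = static_cast<double>(P.n_rows);
    double e = accu(square(Pc)) + accu(square(Qc)) - 2.0 * strace;
    double rmsd = std::sqrt(std::max(e, 0.0) / n);
    vec t = qc.t() - R * pc.t();
    return Rcpp::List::create(Rcpp::Named("R") = R,
                              Rcpp::Named("t") = t,
                              Rcpp::Named("rmsd") = rmsd);
}

// Sum over analysed frames j of the minimised RMSD between frames i and j.
// `frames` holds 0-based indices of the analysed subset.
// [[Rcpp::export]]
arma::vec cpp_rmsd_profile(const arma::cube& coords,
                           const arma::uvec& frames) {
    const uword m = frames.n_elem;
    const double n = static_cast<double>(coords.n_rows);
    std::vector<mat> centred(m);
    vec ssq(m);
    for (uword a = 0; a < m; ++a) {
        mat X = coords.slice(frames(a));
        X.each_row() -= mean(X, 0);
        centred[a] = X;
        ssq(a) = accu(square(X));
    }
    vec profile(m, fill::zeros);
    mat R;
    for (uword a = 0; a < m; ++a) {
        for (uword b = a + 1; b < m; ++b) {
            double strace = kabsch_core(centred[a], centred[b], R);
            double e = ssq(a) + ssq(b) - 2.0 * strace;
            double r = std::sqrt(std::max(e, 0.0) / n);
            profile(a) += r;
            profile(b) += r;
        }
    }
    return profile;
}

// Kabsch fit of a fixed reference point set onto every frame; returns the
// 3x3xF rotation cube, per-frame translations and RMSDs.
// [[Rcpp::export]]
Rcpp::List cpp_kabsch_series(const arma::mat& ref, const arma::cube& coords) {
    const uword F = coords.n_slices;
    const double n = static_cast<double>(ref.n_rows);
    rowvec rc = mean(ref, 0);
    mat Rc = ref.each_row() - rc;
    double ssq_ref = accu(square(Rc));
    cube rot(3, 3, F);
    mat trans(F, 3);
    vec rmsd(F);
    mat R;
    for (uword f = 0; f < F; ++f) {
        mat X = coords.slice(f);
        rowvec xc = mean(X, 0);
        X.each_row() -= xc;
        double strace = kabsch_core(Rc, X, R);
        double e = ssq_ref + accu(square(X)) - 2.0 * strace;
        rot.slice(f) = R;
        rmsd(f) = std::sqrt(std::max(e, 0.0) / n);
        trans.row(f) = xc - rc * R.t();
    }
    return Rcpp::List::create(Rcpp::Named("rotations") = rot,
                              Rcpp::Named("translations") = trans,
                              Rcpp::Named("rmsd") = rmsd);
}
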