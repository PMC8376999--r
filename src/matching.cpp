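#include <Rcpp.h>
#include <algorithm>
#include <cmath>
using namespace Rcpp;

// Trimmed nearest-neighbour distance between two dot patterns at a fixed
// translation of the template. For every query dot the Euclidean distance to
// its nearest (shifted) template dot is taken; the distances are sorted and
// the mean of the smallest ceil(trim * n_query) is returned, discarding the
// largest remainder as outliers (mis-detected dots).
static double trimmed_nn(const double* qx, const double* qy, int nq,
                         const double* tx, const double* ty, int nt,
                         double dx, double dy, double trim,
                         std::vector<double>& buf) {
    buf.resize(nq);
    for (int i = 0; i < nq; ++i) {
        double best = R_PosInf;
        for (int j = 0; j < nt; ++j) {
            double ex = qx[i] - (tx[j] + dx);
            double ey = qy[i] - (ty[j] + dy);
            double d2 = ex * ex + ey * ey;
            if (d2 < best) best = d2;
        }
        buf[i] = best;
    }
    int keep = (int)std::ceil(trim * nq);
    if (keep < 1) keep = 1;
    if (keep > nq) keep = nq;
    std::partial_sort(buf.begin(), buf.begin() + keep, buf.end());
    double s = 0.0;
    for (int i = 0; i < keep; ++i) s += std::sqrt(buf[i]);
    return s / keep;
}

// [[Rcpp::export]]
double cpp_distance_at_shift(NumericMatrix query, NumericMatrix templ,
                             double dx, double dy, double trim) {
    std::vector<double> buf;
    return trimmed_nn(&query(0, 0), &query(0, 1), query.nrow(),
                      &templ(0, 0), &templ(0, 1), templ.nrow(),
                      dx, dy, trim, buf);
}

// Exhaustive shift-grid search. Shifts are visited in lexicographic (dx, dy)
// order and the running minimum is replaced only on strict improvement, so
// ties resolve to the lexicographically smallest shift.
// [[Rcpp::export]]
List cpp_distance_grid(NumericMatrix query, NumericMatrix templ,
                       NumericVector dxs, NumericVector dys, double trim) {
    std::vector<double> buf;
    double best = R_PosInf, bdx = 0.0, bdy = 0.0;
    for (int a = 0; a < dxs.size(); ++a) {
        for (int b = 0; b < dys.size(); ++b) {
            double d = trimmed_nn(&query(0, 0), &query(0, 1), query.nrow(),
                                  &templ(0, 0), &templ(0, 1), templ.nrow(),
                                  dxs[a], dys[b], trim, buf);
            if (d < best) { best = d; bdx = dxs[a]; bdy = dys[b]; }
        }
    }
    return List::create(_["distance"] = best,
                        _["shift"] = NumericVector::create(bdx, bdy));
}
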