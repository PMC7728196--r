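#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]

using namespace arma;

// Lawson-Hanson active-set method for min ||A x - b||_2 subject to x >= 0.
// The optional warm start seeds the passive set from the positive entries of
// x0; if the resulting least-squares solution is not strictly feasible the
// solver falls back to a cold start, so warm starting never changes the
// solution, only the path to it.
static vec nnls_lh(const mat& A, const vec& b, const vec* x0)
{
    const uword k = A.n_cols;
    vec x(k, fill::zeros);
    if (k == 0) return x;

    uvec inP(k, fill::zeros);
    const double gtol = 10.0 * datum::eps *
        std::max(A.n_rows, k) * (norm(A, "inf") + 1.0) * (norm(b, "inf") + 1.0);

    auto ls_on_passive = [&](vec& z) {
        uvec idx = find(inP == 1);
        z.zeros(k);
        if (idx.is_empty()) return;
        vec zp = solve(A.cols(idx), b);
        z(idx) = zp;
    };

    if (x0 != nullptr && x0->n_elem == k) {
        uvec pos = find(*x0 > 0);
        if (!pos.is_empty()) {
            inP(pos).ones();
            vec z;
            ls_on_passive(z);
            uvec idx = find(inP == 1);
            if (z(idx).min() > 0) {
                x = z;
            } else {
                inP.zeros();
            }
        }
    }

    vec w = A.t() * (b - A * x);
    const uword max_steps = 30 * k + 50;
    for (uword it = 0; it < max_steps; ++it) {
        double wmax = gtol;
        sword jmax = -1;
        for (uword j = 0; j < k; ++j) {
            if (!inP(j) && w(j) > wmax) { wmax = w(j); jmax = (sword) j; }
        }
        if (jmax < 0) break;
        inP((uword) jmax) = 1;

        for (uword inner = 0; inner < max_steps; ++inner) {
            vec z;
            ls_on_passive(z);
            uvec idx = find(inP == 1);
            if (idx.is_empty()) { x.zeros(); break; }
            if (z(idx).min() > 0) { x = z; break; }
            double alpha = datum::inf;
            for (uword t = 0; t < idx.n_elem; ++t) {
                const uword j = idx(t);
                if (z(j) <= 0) {
                    const double a = x(j) / (x(j) - z(j));
                    if (a < alpha) alpha = a;
                }
            }
            x += alpha * (z - x);
            const double xtol = 1e-12 * (1.0 + x.max());
            for (uword t = 0; t < idx.n_elem; ++t) {
                const uword j = idx(t);
                if (x(j) <= xtol) { x(j) = 0.0; inP(j) = 0; }
            }
        }
        w = A.t() * (b - A * x);
    }
    return x;
}

// Non-negative least squares min ||A X - B||_F, X >= 0, solved column by
// column of B. X0 (same shape as the result) optionally warm starts each
// column's active set.
// [[Rcpp::export]]
arma::mat cpp_nnls(const arma::mat& A, const arma::mat& B,
                   Rcpp::Nullable<Rcpp::NumericMatrix> X0 = R_NilValue)
{
    const uword k = A.n_cols, m = B.n_cols;
    mat X(k, m, fill::zeros);
    mat W0;
    bool warm = false;
    if (X0.isNotNull()) {
        W0 = Rcpp::as<mat>(X0);
        warm = (W0.n_rows == k && W0.n_cols == m);
    }
    for (uword j = 0; j < m; ++j) {
        if (warm) {
            vec w0 = W0.col(j);
            X.col(j) = nnls_lh(A, B.col(j), &w0);
        } else {
            X.col(j) = nnls_lh(A, B.col(j), nullptr);
        }
    }
    return X;
}

// Heavily weighted equality fallback for min ||W h - y|| s.t. h >= 0 and
// sum(h) = 1, used only when the QR route is unavailable (rank-deficient W).
static vec sum_constrained_penalty(const mat& W, const vec& y)
{
    const double mu = 1e6 * (1.0 + norm(y, "inf"));
    mat Aa = join_cols(W, mu * ones<rowvec>(W.n_cols));
    vec ba = join_cols(y, vec{mu});
    return nnls_lh(Aa, ba, nullptr);
}

// Exact per-sample proportion step: for every column y of Y solve
//   min ||W h - y||^2  s.t.  h >= 0, sum(h) <= 1.
// Strategy: solve the NNLS relaxation first (batch, warm-startable); any
// column whose relaxed optimum violates the sum constraint is re-solved
// exactly as a least-squares-with-inequalities (LSI) problem through the
// classical reduction to least distance programming (LDP), which costs one
// small NNLS per column. All-zero columns of W are excluded and their
// coefficients fixed at zero.
// [[Rcpp::export]]
arma::mat cpp_solve_h(const arma::mat& W, const arma::mat& Y,
                      Rcpp::Nullable<Rcpp::NumericMatrix> H0 = R_NilValue)
{
    const uword k = W.n_cols, m = Y.n_cols;
    mat H(k, m, fill::zeros);
    if (k == 0) return H;

    uvec alive = find(sum(abs(W), 0).t() > 0);
    const uword ka = alive.n_elem;
    if (ka == 0) return H;
    mat Wa = W.cols(alive);

    mat Ha;
    if (H0.isNotNull()) {
        mat H0m = Rcpp::as<mat>(H0);
        if (H0m.n_rows == k && H0m.n_cols == m) {
            mat H0a = H0m.rows(alive);
            Ha = cpp_nnls(Wa, Y, Rcpp::wrap(H0a));
        } else {
            Ha = cpp_nnls(Wa, Y);
        }
    } else {
        Ha = cpp_nnls(Wa, Y);
    }

    uvec viol = find(sum(Ha, 0).t() > 1.0 + 1e-12);
    if (!viol.is_empty()) {
        mat Q, R;
        qr_econ(Q, R, Wa);
        const vec rd = abs(R.diag());
        const bool full_rank = rd.min() > 1e-12 * (rd.max() + datum::eps);

        if (!full_rank) {
            for (uword t = 0; t < viol.n_elem; ++t) {
                const uword j = viol(t);
                Ha.col(j) = sum_constrained_penalty(Wa, Y.col(j));
            }
        } else {
            const mat Rinv = inv(trimatu(R));
            // constraint matrix G = [I; -1'] transformed by R^{-1}
            mat Gt = join_cols(Rinv, -sum(Rinv, 0));      // (ka+1) x ka
            mat Et_top = Gt.t();                          // ka x (ka+1)
            vec h0(ka + 1, fill::zeros);
            h0(ka) = -1.0;
            mat QtY = Q.t() * Y.cols(viol);
            vec f(ka + 1, fill::zeros);
            f(ka) = 1.0;

            for (uword t = 0; t < viol.n_elem; ++t) {
                const uword j = viol(t);
                vec ht = h0 - Gt * QtY.col(t);
                mat E = join_cols(Et_top, ht.t());        // (ka+1) x (ka+1)
                vec u = nnls_lh(E, f, nullptr);
                vec r = E * u - f;
                if (std::abs(r(ka)) < 1e-12) {
                    Ha.col(j) = sum_constrained_penalty(Wa, Y.col(j));
                } else {
                    vec z = -r.head(ka) / r(ka);
                    vec h = Rinv * (z + QtY.col(t));
                    h.transform([](double v) { return v < 0.0 ? 0.0 : v; });
                    Ha.col(j) = h;
                }
            }
        }
    }

    H.rows(alive) = Ha;
    return H;
}
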