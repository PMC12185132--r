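#include <Rcpp.h>
#include <vector>
#include <cmath>
using namespace Rcpp;

// 1-D total-variation proximal operator
//   argmin_x 0.5 * sum_i (x_i - y_i)^2 + lam * sum_i |x_{i+1} - x_i|
// solved exactly through its dual, a box-constrained tridiagonal QP
//   min_{|u_k| <= lam} 0.5 || y - D'u ||^2 ,  (D'u)_i = u_{i-1} - u_i ,
// by cyclic coordinate descent (each coordinate update is a closed-form
// clip; the dual Hessian DD' is positive definite, so CD converges to the
// unique optimum).  Chains here are condition chains: n is small (<= ~11),
// so a tolerance of 1e-14 on the sweep change costs microseconds.
static void tv1d_prox(const double *y, double *x, int n, double lam) {
    if (n == 1 || lam <= 0.0) {
        for (int i = 0; i < n; ++i) x[i] = y[i];
        return;
    }
    const int m = n - 1;
    std::vector<double> u(m, 0.0);
    // x = y - D'u maintained implicitly through r
    std::vector<double> r(y, y + n);
    for (int sweep = 0; sweep < 2000; ++sweep) {
        double delta = 0.0;
        for (int k = 0; k < m; ++k) {
            // gradient wrt u_k is -(r[k+1] - r[k]); diagonal of DD' is 2
            double unew = u[k] + (r[k + 1] - r[k]) / 2.0;
            if (unew > lam) unew = lam;
            else if (unew < -lam) unew = -lam;
            double d = unew - u[k];
            if (d != 0.0) {
                // (D'u)_k gets -u_k, (D'u)_{k+1} gets +u_k
                r[k] += d;
                r[k + 1] -= d;
                u[k] = unew;
                double ad = std::fabs(d);
                if (ad > delta) delta = ad;
            }
        }
        if (delta < 1e-14) break;
    }
    for (int i = 0; i < n; ++i) x[i] = r[i];
}

static inline double soft(double x, double t) {
    if (x > t) return x - t;
    if (x < -t) return x + t;
    return 0.0;
}

// Fused-chain proximal operator over many coordinates.
//
// Each column of A holds the K values of one gene-pair coordinate along the
// condition chain.  W ((K-1) x M, binary) flags whether adjacent conditions
// are fused for that coordinate.  Solves, per column,
//   argmin_z 0.5||z-a||^2 + l1 ||z||_1 + l2 sum_k W_k |z_{k+1} - z_k| ,
// splitting the chain where W_k = 0, applying the exact TV prox within each
// fused segment, then soft-thresholding by l1 (exact for the fused-lasso
// signal approximator: the l1 term commutes with the TV prox).
// [[Rcpp::export(name = ".fused_chain_prox")]]
NumericMatrix fused_chain_prox(NumericMatrix A, NumericMatrix W,
                               double l1, double l2) {
    const int K = A.nrow(), M = A.ncol();
    if (K > 1 && (W.nrow() != K - 1 || W.ncol() != M))
        stop("weight matrix must be (K-1) x M");
    NumericMatrix Z(K, M);
    std::vector<double> buf(K), out(K);
    for (int m = 0; m < M; ++m) {
        int start = 0;
        for (int k = 0; k < K; ++k) {
            bool cut = (k == K - 1) || (W(k, m) == 0.0);
            if (!cut) continue;
            int len = k - start + 1;
            for (int i = 0; i < len; ++i) buf[i] = A(start + i, m);
            tv1d_prox(buf.data(), out.data(), len, l2);
            for (int i = 0; i < len; ++i) Z(start + i, m) = soft(out[i], l1);
            start = k + 1;
        }
    }
    return Z;
}
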