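/* Compiled kernels for the vectorized mass-action evaluation:
 *   v_j  = kf_j * prod_k xa[XR[j,k]] - kb_j * prod_k xa[XP[j,k]]
 *   dx   = H v
 * with xa = c(x, 1) so padding slots (index n+1) contribute a factor 1.
 * The Jacobian uses the product rule per index-table slot; repeated
 * reactants accumulate, reproducing d(kf x^2)/dx = 2 kf x.
 */
#include <R.h>
#include <Rinternals.h>
#include <R_ext/Rdynload.h>

/* rate vector into v[m]; xa has length n+1 */
static void rates(const double *xa, const double *kf, const double *kb,
                  const int *xr, const int *xp, int m, int pr, int pq,
                  double *v)
{
    for (int j = 0; j < m; j++) {
        double fwd = kf[j];
        for (int k = 0; k < pr; k++)
            fwd *= xa[xr[j + k * (R_xlen_t) m] - 1];
        double bwd = kb[j];
        if (bwd != 0.0)
            for (int k = 0; k < pq; k++)
                bwd *= xa[xp[j + k * (R_xlen_t) m] - 1];
        v[j] = fwd - bwd;
    }
}

SEXP C_ma_deriv(SEXP sy, SEXP skf, SEXP skb, SEXP sxr, SEXP sxp, SEXP sh)
{
    int n = LENGTH(sy);
    int m = LENGTH(skf);
    int pr = m > 0 ? LENGTH(sxr) / m : 0;
    int pq = m > 0 ? LENGTH(sxp) / m : 0;
    SEXP sdx = PROTECT(allocVector(REALSXP, n));
    double *dx = REAL(sdx);
    double *h = REAL(sh);
    double *xa = (double *) R_alloc(n + 1, sizeof(double));
    for (int i = 0; i < n; i++) xa[i] = REAL(sy)[i];
    xa[n] = 1.0;
    double *v = (double *) R_alloc(m > 0 ? m : 1, sizeof(double));
    rates(xa, REAL(skf), REAL(skb), INTEGER(sxr), INTEGER(sxp), m, pr, pq, v);
    for (int i = 0; i < n; i++) dx[i] = 0.0;
    for (int j = 0; j < m; j++) {
        double vj = v[j];
        if (vj == 0.0) continue;
        const double *hcol = h + (R_xlen_t) j * n;
        for (int i = 0; i < n; i++) dx[i] += hcol[i] * vj;
    }
    UNPROTECT(1);
    return sdx;
}

SEXP C_ma_jac(SEXP sy, SEXP skf, SEXP skb, SEXP sxr, SEXP sxp, SEXP sh)
{
    int n = LENGTH(sy);
    int m = LENGTH(skf);
    int pr = m > 0 ? LENGTH(sxr) / m : 0;
    int pq = m > 0 ? LENGTH(sxp) / m : 0;
    const int *xr = INTEGER(sxr), *xp = INTEGER(sxp);
    const double *kf = REAL(skf), *kb = REAL(skb), *h = REAL(sh);
    SEXP sj = PROTECT(allocMatrix(REALSXP, n, n));
    double *J = REAL(sj);
    for (R_xlen_t i = 0; i < (R_xlen_t) n * n; i++) J[i] = 0.0;
    double *xa = (double *) R_alloc(n + 1, sizeof(double));
    for (int i = 0; i < n; i++) xa[i] = REAL(sy)[i];
    xa[n] = 1.0;
    /* dv_j/dx_i accumulated straight into J: J += H[,j] (dv_j/dx_i) e_i' */
    for (int j = 0; j < m; j++) {
        const double *hcol = h + (R_xlen_t) j * n;
        for (int k = 0; k < pr; k++) {
            int tgt = xr[j + k * (R_xlen_t) m] - 1;
            if (tgt >= n) continue; /* padding slot */
            double g = kf[j];
            for (int k2 = 0; k2 < pr; k2++)
                if (k2 != k) g *= xa[xr[j + k2 * (R_xlen_t) m] - 1];
            if (g == 0.0) continue;
            double *jcol = J + (R_xlen_t) tgt * n;
            for (int i = 0; i < n; i++)
                if (hcol[i] != 0.0) jcol[i] += hcol[i] * g;
        }
        if (kb[j] != 0.0) {
            for (int k = 0; k < pq; k++) {
                int tgt = xp[j + k * (R_xlen_t) m] - 1;
                if (tgt >= n) continue;
                double g = kb[j];
                for (int k2 = 0; k2 < pq; k2++)
                    if (k2 != k) g *= xa[xp[j + k2 * (R_xlen_t) m] - 1];
                if (g == 0.0) continue;
                double *jcol = J + (R_xlen_t) tgt * n;
                for (int i = 0; i < n; i++)
                    if (hcol[i] != 0.0) jcol[i] -= hcol[i] * g;
            }
        }
    }
    UNPROTECT(1);
    return sj;
}

static const R_CallMethodDef callMethods[] = {
    {"C_ma_deriv", (DL_FUNC) &C_ma_deriv, 6},
    {"C_ma_jac",   (DL_FUNC) &C_ma_jac,   6},
    {NULL, NULL, 0}
};

void R_init_netkin(DllInfo *info)
{
    R_registerRoutines(info, NULL, callMethods, NULL, NULL);
    R_useDynamicSymbols(info, FALSE);
}
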