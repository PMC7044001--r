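/* Error-bounded lossy quantizer: per-row previous-value predictor with
 * residual quantization at step 2e.  The first pixel of every detector row
 * and any non-finite pixel are stored verbatim (escape), so constant rows
 * reconstruct exactly and masked pixels survive the round trip.  The
 * guarantee |x_hat - x| <= e holds by construction for every finite pixel.
 */
#include "jfproc.h"
#include <math.h>

#define JF_LOSSY_ESCAPE INT32_MIN

SEXP C_lossy_encode(SEXP x, SEXP nrow_, SEXP ncol_, SEXP e_)
{
    int nr = Rf_asInteger(nrow_), nc = Rf_asInteger(ncol_);
    double e = Rf_asReal(e_);
    if (!(e > 0)) Rf_error("error bound must be positive");
    const double *xv = REAL(x);
    double step = 2.0 * e;

    SEXP codes = PROTECT(Rf_allocVector(INTSXP, (R_xlen_t)nr * nc));
    int *cv = INTEGER(codes);
    /* worst case: everything escapes */
    SEXP esc = PROTECT(Rf_allocVector(REALSXP, (R_xlen_t)nr * nc));
    double *ev = REAL(esc);
    R_xlen_t n_esc = 0, idx = 0;

    for (int r = 0; r < nr; r++) {
        double prev = 0.0;
        int have_prev = 0;
        for (int c = 0; c < nc; c++, idx++) {
            double v = xv[r + (R_xlen_t)c * nr]; /* column-major input */
            if (!have_prev || !R_FINITE(v)) {
                cv[idx] = JF_LOSSY_ESCAPE;
                ev[n_esc++] = v;
                if (R_FINITE(v)) { prev = v; have_prev = 1; }
                continue;
            }
            double q = (v - prev) / step;
            double qr = (q >= 0) ? floor(q + 0.5) : ceil(q - 0.5);
            if (fabs(qr) > 1073741823.0) { /* residual too large for int32 */
                cv[idx] = JF_LOSSY_ESCAPE;
                ev[n_esc++] = v;
                prev = v;
                continue;
            }
            cv[idx] = (int)qr;
            prev = prev + qr * step;
        }
    }
    SEXP esc_out = PROTECT(Rf_allocVector(REALSXP, n_esc));
    memcpy(REAL(esc_out), ev, (size_t)n_esc * sizeof(double));
    SEXP out = PROTECT(Rf_allocVector(VECSXP, 2));
    SET_VECTOR_ELT(out, 0, codes);
    SET_VECTOR_ELT(out, 1, esc_out);
    SEXP nm = PROTECT(Rf_allocVector(STRSXP, 2));
    SET_STRING_ELT(nm, 0, Rf_mkChar("codes"));
    SET_STRING_ELT(nm, 1, Rf_mkChar("escapes"));
    Rf_setAttrib(out, R_NamesSymbol, nm);
    UNPROTECT(5);
    return out;
}

SEXP C_lossy_decode(SEXP codes, SEXP escapes, SEXP nrow_, SEXP ncol_, SEXP e_)
{
    int nr = Rf_asInteger(nrow_), nc = Rf_asInteger(ncol_);
    double e = Rf_asReal(e_);
    double step = 2.0 * e;
    const int *cv = INTEGER(codes);
    const double *ev = REAL(escapes);
    R_xlen_t n_esc_avail = XLENGTH(escapes);
    if (XLENGTH(codes) != (R_xlen_t)nr * nc)
        Rf_error("code count does not match dimensions");

    SEXP out = PROTECT(Rf_allocMatrix(REALSXP, nr, nc));
    double *ov = REAL(out);
    R_xlen_t n_esc = 0, idx = 0;
    for (int r = 0; r < nr; r++) {
        double prev = 0.0;
        for (int c = 0; c < nc; c++, idx++) {
            double v;
            if (cv[idx] == JF_LOSSY_ESCAPE) {
                if (n_esc >= n_esc_avail) Rf_error("escape table exhausted");
                v = ev[n_esc++];
                if (R_FINITE(v)) prev = v;
            } else {
                v = prev + (double)cv[idx] * step;
                prev = v;
            }
            ov[r + (R_xlen_t)c * nr] = v;
        }
    }
    UNPROTECT(1);
    return out;
}
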