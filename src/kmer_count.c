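#include <R.h>
#include <Rinternals.h>
#include <string.h>

/* Dense k-mer counting over a character vector of reads.
 *
 * Rolling 2-bit encoding (A=0, C=1, G=2, T=3, leftmost base most
 * significant).  Any window touching a non-ACGT character (N or other
 * ambiguity codes) is skipped: the rolling window is reset at the
 * offending base.  Counts are returned as doubles so that flowcell-level
 * merges stay exact far beyond 32-bit range (exact up to 2^53).
 */
SEXP C_count_kmers(SEXP seqs, SEXP k_)
{
    const int k = Rf_asInteger(k_);
    if (k < 1 || k > 12)
        Rf_error("k must be between 1 and 12");
    const R_xlen_t nseq = XLENGTH(seqs);
    const R_xlen_t nk = (R_xlen_t)1 << (2 * k);
    const unsigned int mask = (unsigned int)(nk - 1);

    int code[256];
    for (int i = 0; i < 256; i++) code[i] = -1;
    code['A'] = code['a'] = 0;
    code['C'] = code['c'] = 1;
    code['G'] = code['g'] = 2;
    code['T'] = code['t'] = 3;

    SEXP ans = PROTECT(Rf_allocVector(REALSXP, nk));
    double *cnt = REAL(ans);
    memset(cnt, 0, (size_t)nk * sizeof(double));

    for (R_xlen_t i = 0; i < nseq; i++) {
        SEXP s = STRING_ELT(seqs, i);
        if (s == NA_STRING) continue;
        const char *p = CHAR(s);
        const R_xlen_t len = XLENGTH(s);
        unsigned int idx = 0;
        int valid = 0;
        for (R_xlen_t j = 0; j < len; j++) {
            const int c = code[(unsigned char)p[j]];
            if (c < 0) {            /* N or other: reset the window */
                valid = 0;
                idx = 0;
                continue;
            }
            idx = ((idx << 2) | (unsigned int)c) & mask;
            if (++valid >= k) cnt[idx]++;
        }
    }
    UNPROTECT(1);
    return ans;
}

/* Canberra distance with the 0/0 -> 0 convention over the full
 * component range (no term dropping, no renormalisation). */
SEXP C_canberra(SEXP x_, SEXP y_)
{
    const R_xlen_t n = XLENGTH(x_);
    if (XLENGTH(y_) != n)
        Rf_error("vectors must have equal length");
    const double *x = REAL(x_);
    const double *y = REAL(y_);
    double d = 0.0;
    for (R_xlen_t i = 0; i < n; i++) {
        const double den = x[i] + y[i];
        if (den > 0.0) d += (x[i] > y[i] ? x[i] - y[i] : y[i] - x[i]) / den;
    }
    return Rf_ScalarReal(d);
}
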