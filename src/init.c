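#include <R.h>
#include <Rinternals.h>
#include <R_ext/Rdynload.h>

SEXP C_count_kmers(SEXP seqs, SEXP k_);
SEXP C_canberra(SEXP x_, SEXP y_);

static const R_CallMethodDef CallEntries[] = {
    {"C_count_kmers", (DL_FUNC) &C_count_kmers, 2},
    {"C_canberra",    (DL_FUNC) &C_canberra,    2},
    {NULL, NULL, 0}
};

void R_init_kmerbatch(DllInfo *dll)
{
    R_registerRoutines(dll, NULL, CallEntries, NULL, NULL);
    R_useDynamicSymbols(dll, FALSE);
}
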