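/* Inertia of a dense symmetric matrix via the LAPACK Bunch-Kaufman
 * LDL^T (dsytrf) factorization: the eigenvalue signs of the 1x1 and
 * 2x2 diagonal blocks of D give the inertia without an
 * eigendecomposition.  Zero pivots are declared with a relative
 * threshold on the block eigenvalues. */

#define USE_FC_LEN_T
#include <R.h>
#include <Rinternals.h>
#include <R_ext/Lapack.h>
#ifndef FCONE
# define FCONE
#endif
#include <math.h>
#include <stdlib.h>
#include <string.h>

SEXP C_ldl_inertia(SEXP Amat, SEXP tol_)
{
    if (!isReal(Amat) || !isMatrix(Amat))
        error("matrix must be a numeric (double) matrix");
    int n = nrows(Amat);
    if (ncols(Amat) != n) error("matrix must be square");
    double tol = asReal(tol_);

    SEXP ans = PROTECT(allocVector(INTSXP, 3));
    int *cnt = INTEGER(ans);
    cnt[0] = cnt[1] = cnt[2] = 0;
    if (n == 0) { UNPROTECT(1); return ans; }

    double *a = (double *) R_alloc((size_t) n * n, sizeof(double));
    memcpy(a, REAL(Amat), (size_t) n * n * sizeof(double));
    int *ipiv = (int *) R_alloc(n, sizeof(int));
    int info = 0, lwork = -1;
    double wkopt;
    F77_CALL(dsytrf)("L", &n, a, &n, ipiv, &wkopt, &lwork, &info
                     FCONE);
    lwork = (int) wkopt;
    if (lwork < n) lwork = 64 * n;
    double *work = (double *) R_alloc(lwork, sizeof(double));
    F77_CALL(dsytrf)("L", &n, a, &n, ipiv, work, &lwork, &info
                     FCONE);
    if (info < 0)
        error("dsytrf failed with illegal argument %d; consider regularizing the matrix", -info);
    /* info > 0 flags an exactly singular D block: still a complete
     * factorization, handled by the zero threshold below. */

    /* collect eigenvalues of the diagonal blocks of D */
    double *ev = (double *) R_alloc(n, sizeof(double));
    int nev = 0;
    int i = 0;
    while (i < n) {
        if (ipiv[i] > 0) {
            ev[nev++] = a[i + (size_t) n * i];
            i += 1;
        } else {
            double d11 = a[i + (size_t) n * i];
            double d21 = a[(i + 1) + (size_t) n * i];
            double d22 = a[(i + 1) + (size_t) n * (i + 1)];
            double tr2 = 0.5 * (d11 + d22);
            double disc = sqrt(0.25 * (d11 - d22) * (d11 - d22) + d21 * d21);
            ev[nev++] = tr2 + disc;
            ev[nev++] = tr2 - disc;
            i += 2;
        }
    }
    double amax = 0.0;
    for (i = 0; i < nev; i++)
        if (fabs(ev[i]) > amax) amax = fabs(ev[i]);
    double thresh = tol * amax;
    for (i = 0; i < nev; i++) {
        if (fabs(ev[i]) <= thresh) cnt[2]++;
        else if (ev[i] > 0) cnt[0]++;
        else cnt[1]++;
    }
    UNPROTECT(1);
    return ans;
}
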