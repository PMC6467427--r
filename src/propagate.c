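/* Implicit-Euler forward propagation of gLV / saturable-gLV dynamics
 * over a discretization grid, with optional forward sensitivities with
 * respect to the experiment's local parameter vector
 * (mu_1, a_11..a_1n, ..., mu_n, a_n1..a_nn[, K_11..K_1n, ...]).
 *
 * Node kinds: 0 = initial node, 1 = implicit Euler step, 2 = dilution
 * jump (state multiplied by the dilution factor).  Scalar gLV steps use
 * the closed-form quadratic root; all other steps use Newton iteration
 * with a preference for nonnegative roots (the transcribed problem
 * bounds states below by zero).
 */

#define USE_FC_LEN_T
#include <R.h>
#include <Rinternals.h>
#include <R_ext/Lapack.h>
#include <math.h>
#include <string.h>
#ifndef FCONE
# define FCONE
#endif

/* f_s = (mu_s + sum_j a_sj * g_sj(x_j)) x_s with g = x (gLV) or
 * x/(K+x) (saturable) */
static void eval_f(int n, int sat, const double *x, const double *mu,
                   const double *alpha, const double *K, double *f)
{
    for (int s = 0; s < n; s++) {
        double acc = mu[s];
        for (int j = 0; j < n; j++) {
            double a = alpha[s + n * j];
            if (sat) {
                double k = K[s + n * j];
                acc += a * x[j] / (k + x[j]);
            } else acc += a * x[j];
        }
        f[s] = acc * x[s];
    }
}

/* A = I - h * df/dx  (column-major) */
static void eval_A(int n, int sat, double h, const double *x,
                   const double *mu, const double *alpha, const double *K,
                   double *A)
{
    for (int s = 0; s < n; s++) {
        double percap = mu[s];
        for (int j = 0; j < n; j++) {
            double a = alpha[s + n * j];
            if (sat) {
                double k = K[s + n * j];
                percap += a * x[j] / (k + x[j]);
            } else percap += a * x[j];
        }
        for (int j = 0; j < n; j++) {
            double gx;
            if (sat) {
                double k = K[s + n * j];
                double den = k + x[j];
                gx = k / (den * den);
            } else gx = 1.0;
            double d = alpha[s + n * j] * gx * x[s];
            if (j == s) d += percap;
            A[s + n * j] = ((j == s) ? 1.0 : 0.0) - h * d;
        }
    }
}

/* df/dtheta_local (n x p, column-major) */
static void eval_ftheta(int n, int sat, const double *x, const double *mu,
                        const double *alpha, const double *K, double *ft,
                        int p)
{
    memset(ft, 0, (size_t) n * p * sizeof(double));
    for (int s = 0; s < n; s++) {
        int off = s * (n + 1);
        ft[s + n * off] = x[s];                      /* d/dmu_s */
        for (int j = 0; j < n; j++) {
            double g;
            if (sat) {
                double k = K[s + n * j];
                g = x[j] / (k + x[j]);
            } else g = x[j];
            ft[s + n * (off + 1 + j)] = g * x[s];    /* d/da_sj */
        }
        if (sat) {
            int koff = n * (n + 1) + s * n;
            for (int j = 0; j < n; j++) {
                double k = K[s + n * j];
                double den = k + x[j];
                double gK = -x[j] / (den * den);
                ft[s + n * (koff + j)] =
                    alpha[s + n * j] * gK * x[s];    /* d/dK_sj */
            }
        }
    }
}

static double resid_norm(int n, int sat, double h, const double *xp,
                         const double *mu, const double *alpha,
                         const double *K, const double *z, double *f,
                         double *r)
{
    eval_f(n, sat, z, mu, alpha, K, f);
    double rmax = 0.0;
    for (int s = 0; s < n; s++) {
        r[s] = z[s] - xp[s] - h * f[s];
        if (!R_FINITE(r[s])) return R_PosInf;
        if (fabs(r[s]) > rmax) rmax = fabs(r[s]);
    }
    return rmax;
}

/* damped Newton on the implicit step residual */
static int newton_try(int n, int sat, double h, const double *xp,
                      const double *mu, const double *alpha,
                      const double *K, double tol, int maxit,
                      double cap, double *z, double *A, double *f,
                      double *r, int *ipiv, double *dz, double *zt,
                      double *rt)
{
    double rmax = resid_norm(n, sat, h, xp, mu, alpha, K, z, f, r);
    if (!R_FINITE(rmax)) return 0;
    for (int it = 0; it < maxit; it++) {
        double zmax = 0.0;
        for (int s = 0; s < n; s++)
            if (fabs(z[s]) > zmax) zmax = fabs(z[s]);
        if (zmax > cap) return 0;
        if (rmax < tol || (it == maxit - 1 && rmax < 1e-8)) return 1;
        eval_A(n, sat, h, z, mu, alpha, K, A);
        memcpy(dz, r, n * sizeof(double));
        int info = 0, nrhs = 1;
        F77_CALL(dgesv)(&n, &nrhs, A, &n, ipiv, dz, &n, &info);
        if (info != 0) return 0;
        double t = 1.0, rnew = R_PosInf;
        int accepted = 0;
        for (int ls = 0; ls < 8; ls++, t *= 0.5) {
            for (int s = 0; s < n; s++) zt[s] = z[s] - t * dz[s];
            rnew = resid_norm(n, sat, h, xp, mu, alpha, K, zt, f, rt);
            if (R_FINITE(rnew) && rnew < rmax) { accepted = 1; break; }
        }
        if (!accepted) return rmax < 1e-8;
        memcpy(z, zt, n * sizeof(double));
        memcpy(r, rt, n * sizeof(double));
        rmax = rnew;
    }
    return 0;
}

/* Solve one implicit Euler step of size h from xp into z.  Tries a few
 * starting points with damped Newton; if all fail, bootstraps a
 * starting point by recursive half-stepping (the half-step states are
 * only predictors; the returned root always solves the full-h step). */
static int step_solve(int n, int sat, double h, const double *xp,
                      const double *mu, const double *alpha,
                      const double *K, double tol, int maxit, double cap,
                      int depth, double *z, double *A, double *f,
                      double *r, int *ipiv, double *dz, double *zt,
                      double *rt, double *zb, int *have_fb, double *work)
{
    eval_f(n, sat, xp, mu, alpha, K, f);
    for (int trial = 0; trial < 3; trial++) {
        for (int s = 0; s < n; s++) {
            double v = (trial == 0) ? xp[s] + h * f[s]
                : (trial == 1) ? xp[s]
                : (xp[s] > 1e-6 ? xp[s] : 1e-6);
            if (trial == 0 && (!R_FINITE(v) || v < 0)) v = xp[s];
            z[s] = v;
        }
        if (newton_try(n, sat, h, xp, mu, alpha, K, tol, maxit, cap,
                       z, A, f, r, ipiv, dz, zt, rt)) {
            double zmin = z[0];
            for (int s = 1; s < n; s++) if (z[s] < zmin) zmin = z[s];
            if (zmin >= -1e-9) {
                for (int s = 0; s < n; s++) if (z[s] < 0) z[s] = 0;
                return 1;
            }
            if (!*have_fb) { memcpy(zb, z, n * sizeof(double));
                             *have_fb = 1; }
        }
    }
    if (depth > 0) {
        /* half-step continuation: predictor from two h/2 solves */
        double *xm = work;          /* n scratch */
        int fb2 = 0;
        if (step_solve(n, sat, 0.5 * h, xp, mu, alpha, K, tol, maxit,
                       cap, depth - 1, xm, A, f, r, ipiv, dz, zt, rt,
                       zb, &fb2, work + n) &&
            step_solve(n, sat, 0.5 * h, xm, mu, alpha, K, tol, maxit,
                       cap, depth - 1, z, A, f, r, ipiv, dz, zt, rt,
                       zb, &fb2, work + n)) {
            if (newton_try(n, sat, h, xp, mu, alpha, K, tol, maxit, cap,
                           z, A, f, r, ipiv, dz, zt, rt)) {
                double zmin = z[0];
                for (int s = 1; s < n; s++) if (z[s] < zmin) zmin = z[s];
                if (zmin >= -1e-9) {
                    for (int s = 0; s < n; s++) if (z[s] < 0) z[s] = 0;
                    return 1;
                }
                if (!*have_fb) { memcpy(zb, z, n * sizeof(double));
                                 *have_fb = 1; }
            }
        }
    }
    return 0;
}

SEXP C_propagate(SEXP times_, SEXP kind_, SEXP dfac_, SEXP x0_, SEXP mu_,
                 SEXP alpha_, SEXP Ksat_, SEXP sens_, SEXP tol_,
                 SEXP maxit_, SEXP cap_)
{
    int J = LENGTH(times_);
    int n = LENGTH(x0_);
    int sat = !isNull(Ksat_);
    int p = sat ? n * (2 * n + 1) : n * (n + 1);
    int want_sens = asLogical(sens_);
    double tol = asReal(tol_), cap = asReal(cap_);
    int maxit = asInteger(maxit_);
    const double *times = REAL(times_);
    const int *kind = INTEGER(kind_);
    double dfac = asReal(dfac_);
    const double *mu = REAL(mu_), *alpha = REAL(alpha_);
    const double *K = sat ? REAL(Ksat_) : NULL;

    SEXP states_ = PROTECT(allocMatrix(REALSXP, J, n));
    double *states = REAL(states_);
    for (int i = 0; i < J * n; i++) states[i] = NA_REAL;
    SEXP sens_out = R_NilValue;
    double *sens = NULL;
    if (want_sens) {
        SEXP dim = PROTECT(allocVector(INTSXP, 3));
        INTEGER(dim)[0] = J; INTEGER(dim)[1] = n; INTEGER(dim)[2] = p;
        sens_out = PROTECT(allocArray(REALSXP, dim));
        sens = REAL(sens_out);
        memset(sens, 0, (size_t) J * n * p * sizeof(double));
    }

    double *xp = (double *) R_alloc(n, sizeof(double));
    double *z = (double *) R_alloc(n, sizeof(double));
    double *zb = (double *) R_alloc(n, sizeof(double));
    double *f = (double *) R_alloc(n, sizeof(double));
    double *r = (double *) R_alloc(n, sizeof(double));
    double *A = (double *) R_alloc((size_t) n * n, sizeof(double));
    double *ft = (double *) R_alloc((size_t) n * p, sizeof(double));
    double *Srhs = (double *) R_alloc((size_t) n * p, sizeof(double));
    double *dzv = (double *) R_alloc(n, sizeof(double));
    double *ztv = (double *) R_alloc(n, sizeof(double));
    double *rtv = (double *) R_alloc(n, sizeof(double));
    double *workv = (double *) R_alloc((size_t) 8 * n, sizeof(double));
    int *ipiv = (int *) R_alloc(n, sizeof(int));

    int fail_node = -1;
    for (int s = 0; s < n; s++) states[0 + J * s] = REAL(x0_)[s];

    for (int j = 1; j < J && fail_node < 0; j++) {
        for (int s = 0; s < n; s++) xp[s] = states[(j - 1) + J * s];
        if (kind[j] == 2) {                       /* dilution jump */
            for (int s = 0; s < n; s++)
                states[j + J * s] = dfac * xp[s];
            if (want_sens)
                for (int s = 0; s < n; s++)
                    for (int q = 0; q < p; q++)
                        sens[j + J * (s + n * q)] =
                            dfac * sens[(j - 1) + J * (s + n * q)];
            continue;
        }
        double h = times[j] - times[j - 1];
        int okstep = 0;
        if (n == 1 && !sat) {                     /* closed-form quadratic */
            double Aq = h * alpha[0], Bq = h * mu[0] - 1.0, Cq = xp[0];
            if (fabs(Aq) < 1e-14) {
                double zz = -Cq / Bq;
                if (R_FINITE(zz) && zz >= -1e-12) {
                    z[0] = zz > 0 ? zz : 0; okstep = 1;
                }
            } else {
                double disc = Bq * Bq - 4.0 * Aq * Cq;
                if (disc >= 0) {
                    double sq = sqrt(disc);
                    double qq = -0.5 * (Bq + (Bq >= 0 ? sq : -sq));
                    double r1 = qq / Aq;
                    double r2 = (qq != 0) ? Cq / qq : 0.0;
                    double best = NA_REAL;
                    if (R_FINITE(r1) && r1 >= -1e-12) best = r1;
                    if (R_FINITE(r2) && r2 >= -1e-12 &&
                        (!R_FINITE(best) ||
                         fabs(r2 - xp[0]) < fabs(best - xp[0])))
                        best = r2;
                    if (R_FINITE(best)) {
                        z[0] = best > 0 ? best : 0; okstep = 1;
                    }
                }
            }
        } else {
            int have_fallback = 0;
            okstep = step_solve(n, sat, h, xp, mu, alpha, K, tol, maxit,
                                cap, 6, z, A, f, r, ipiv, dzv, ztv, rtv,
                                zb, &have_fallback, workv);
            if (!okstep && have_fallback) {
                /* accept a marginally negative converged root */
                double zmin = zb[0];
                for (int s = 1; s < n; s++) if (zb[s] < zmin) zmin = zb[s];
                if (zmin > -1e-6) {
                    memcpy(z, zb, n * sizeof(double));
                    okstep = 1;
                }
            }
        }
        if (!okstep) { fail_node = j; break; }
        for (int s = 0; s < n; s++) states[j + J * s] = z[s];
        if (want_sens) {
            eval_A(n, sat, h, z, mu, alpha, K, A);
            eval_ftheta(n, sat, z, mu, alpha, K, ft, p);
            for (int q = 0; q < p; q++)
                for (int s = 0; s < n; s++)
                    Srhs[s + n * q] = sens[(j - 1) + J * (s + n * q)] +
                        h * ft[s + n * q];
            int info = 0;
            F77_CALL(dgesv)(&n, &p, A, &n, ipiv, Srhs, &n, &info);
            if (info != 0) { fail_node = j; break; }
            for (int q = 0; q < p; q++)
                for (int s = 0; s < n; s++)
                    sens[j + J * (s + n * q)] = Srhs[s + n * q];
        }
    }

    SEXP out = PROTECT(allocVector(VECSXP, 3));
    SET_VECTOR_ELT(out, 0, ScalarLogical(fail_node < 0));
    SET_VECTOR_ELT(out, 1, states_);
    SET_VECTOR_ELT(out, 2, want_sens ? sens_out : R_NilValue);
    SEXP nms = PROTECT(allocVector(STRSXP, 3));
    SET_STRING_ELT(nms, 0, mkChar("ok"));
    SET_STRING_ELT(nms, 1, mkChar("states"));
    SET_STRING_ELT(nms, 2, mkChar("sens"));
    setAttrib(out, R_NamesSymbol, nms);
    SEXP fn = PROTECT(ScalarInteger(fail_node < 0 ? NA_INTEGER
                                    : fail_node + 1));
    setAttrib(out, install("fail_node"), fn);
    UNPROTECT(want_sens ? 6 : 4);
    return out;
}
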