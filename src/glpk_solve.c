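/* Minimal GLPK simplex interface for bounded linear programs.
 *
 * Solves  min/max  obj' x
 *         s.t.     row_lb <= A x <= row_ub
 *                  col_lb <=   x <= col_ub
 *
 * A is passed as a triplet (ia, ja, ar), 1-based indices as GLPK expects.
 * An optional warm-start basis (row and column statuses from a previous
 * solve) makes the lexicographic stage solves and flux variability
 * subproblems start from a primal-feasible vertex, which is both faster
 * and numerically far more reliable than a cold phase I on models whose
 * bound proxies span six orders of magnitude.
 *
 * Returns list(status, objective, x, rstat, cstat).
 * Status: 1 optimal, 2 infeasible, 3 unbounded, 4 other failure.
 */

#include <R.h>
#include <Rinternals.h>
#include <glpk.h>

static int bound_type(double lb, double ub)
{
    int lb_fin = R_FINITE(lb), ub_fin = R_FINITE(ub);
    if (lb_fin && ub_fin)
        return (lb == ub) ? GLP_FX : GLP_DB;
    if (lb_fin)
        return GLP_LO;
    if (ub_fin)
        return GLP_UP;
    return GLP_FR;
}

SEXP C_glpk_solve(SEXP s_nrow, SEXP s_ncol,
                  SEXP s_ia, SEXP s_ja, SEXP s_ar,
                  SEXP s_rlb, SEXP s_rub,
                  SEXP s_clb, SEXP s_cub,
                  SEXP s_obj, SEXP s_maximize,
                  SEXP s_rstat, SEXP s_cstat)
{
    int nrow = asInteger(s_nrow), ncol = asInteger(s_ncol);
    int nnz = length(s_ar);
    int maximize = asLogical(s_maximize);
    int have_basis = (s_rstat != R_NilValue) && (s_cstat != R_NilValue) &&
        length(s_rstat) == nrow && length(s_cstat) == ncol;
    int i, ret, st;

    glp_prob *lp = glp_create_prob();
    glp_set_obj_dir(lp, maximize ? GLP_MAX : GLP_MIN);
    if (nrow > 0) glp_add_rows(lp, nrow);
    glp_add_cols(lp, ncol);

    double *rlb = REAL(s_rlb), *rub = REAL(s_rub);
    for (i = 0; i < nrow; i++)
        glp_set_row_bnds(lp, i + 1, bound_type(rlb[i], rub[i]), rlb[i], rub[i]);

    double *clb = REAL(s_clb), *cub = REAL(s_cub), *obj = REAL(s_obj);
    for (i = 0; i < ncol; i++) {
        glp_set_col_bnds(lp, i + 1, bound_type(clb[i], cub[i]), clb[i], cub[i]);
        glp_set_obj_coef(lp, i + 1, obj[i]);
    }

    if (nnz > 0) {
        /* glp_load_matrix reads from index 1 */
        int *ia = (int *) R_alloc(nnz + 1, sizeof(int));
        int *ja = (int *) R_alloc(nnz + 1, sizeof(int));
        double *ar = (double *) R_alloc(nnz + 1, sizeof(double));
        int *ia0 = INTEGER(s_ia), *ja0 = INTEGER(s_ja);
        double *ar0 = REAL(s_ar);
        for (i = 0; i < nnz; i++) {
            ia[i + 1] = ia0[i];
            ja[i + 1] = ja0[i];
            ar[i + 1] = ar0[i];
        }
        glp_load_matrix(lp, nnz, ia, ja, ar);
    }

    glp_smcp parm;
    glp_init_smcp(&parm);
    parm.msg_lev = GLP_MSG_ERR;
    parm.presolve = GLP_OFF;

    glp_term_out(GLP_OFF);
    if (have_basis) {
        int *rs = INTEGER(s_rstat), *cs = INTEGER(s_cstat);
        for (i = 0; i < nrow; i++) glp_set_row_stat(lp, i + 1, rs[i]);
        for (i = 0; i < ncol; i++) glp_set_col_stat(lp, i + 1, cs[i]);
    }
    ret = glp_simplex(lp, &parm);
    st = glp_get_status(lp);

    /* Anything short of a proven optimum or unboundedness — including a
     * phase-I NOFEAS verdict, which can be spurious on ill-conditioned
     * cold bases — is re-checked from a fresh basis with the presolver. */
    if (!(ret == 0 && (st == GLP_OPT || st == GLP_UNBND))) {
        parm.presolve = GLP_ON;
        glp_std_basis(lp);
        ret = glp_simplex(lp, &parm);
        st = glp_get_status(lp);
    }
    glp_term_out(GLP_ON);

    int status;
    if (ret == 0 && st == GLP_OPT)
        status = 1;
    else if ((ret == 0 && st == GLP_NOFEAS) || ret == GLP_ENOPFS)
        status = 2;
    else if ((ret == 0 && st == GLP_UNBND) || ret == GLP_ENODFS)
        status = 3;
    else
        status = 4;

    SEXP ans = PROTECT(allocVector(VECSXP, 5));
    SEXP nm = PROTECT(allocVector(STRSXP, 5));
    SET_STRING_ELT(nm, 0, mkChar("status"));
    SET_STRING_ELT(nm, 1, mkChar("objective"));
    SET_STRING_ELT(nm, 2, mkChar("x"));
    SET_STRING_ELT(nm, 3, mkChar("rstat"));
    SET_STRING_ELT(nm, 4, mkChar("cstat"));
    setAttrib(ans, R_NamesSymbol, nm);

    SET_VECTOR_ELT(ans, 0, ScalarInteger(status));
    SET_VECTOR_ELT(ans, 1, ScalarReal(status == 1 ? glp_get_obj_val(lp) : NA_REAL));

    SEXP x = PROTECT(allocVector(REALSXP, ncol));
    if (status == 1)
        for (i = 0; i < ncol; i++)
            REAL(x)[i] = glp_get_col_prim(lp, i + 1);
    else
        for (i = 0; i < ncol; i++)
            REAL(x)[i] = NA_REAL;
    SET_VECTOR_ELT(ans, 2, x);

    SEXP rstat = PROTECT(allocVector(INTSXP, nrow));
    for (i = 0; i < nrow; i++)
        INTEGER(rstat)[i] = glp_get_row_stat(lp, i + 1);
    SET_VECTOR_ELT(ans, 3, rstat);
    SEXP cstat = PROTECT(allocVector(INTSXP, ncol));
    for (i = 0; i < ncol; i++)
        INTEGER(cstat)[i] = glp_get_col_stat(lp, i + 1);
    SET_VECTOR_ELT(ans, 4, cstat);

    glp_delete_prob(lp);
    UNPROTECT(5);
    return ans;
}
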