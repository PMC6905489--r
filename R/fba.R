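#' Objective helper
#'
#' @param terms named numeric vector of weights keyed by reaction id, or a
#'   character vector of reaction ids (weights 1).
#' @param direction `"max"` or `"min"`.
#' @return An object of class `flux_objective`.
#' @export
flux_objective <- function(terms, direction = c("max", "min")) {
  direction <- match.arg(direction)
  if (is.character(terms)) terms <- setNames(rep(1, length(terms)), terms)
  stopifnot(length(terms) >= 1, !is.null(names(terms)))
  structure(list(terms = terms, direction = direction),
            class = "flux_objective")
}

model_objective <- function(model) {
  if (nrow(model$objective) == 0) {
    abort("model has no objective; supply one explicitly")
  }
  flux_objective(setNames(model$objective$weight, model$objective$reaction),
                 model$objective_direction)
}

# ---- LP compilation ---------------------------------------------------------

# Compile model to the raw LP consumed by the GLPK binding.
# Rows: metabolite steady-state rows (= 0), ratio rows (v_a - r v_b = 0),
# coupling rows. Columns: one per reaction.
compile_lp <- function(model) {
  nmet <- nrow(model$metabolites)
  nrxn <- nrow(model$reactions)
  ia <- match(model$stoich$metabolite, model$metabolites$id)
  ja <- match(model$stoich$reaction, model$reactions$id)
  ar <- model$stoich$coef
  rlb <- rep(0, nmet)
  rub <- rep(0, nmet)
  row <- nmet
  if (nrow(model$ratio_constraints) > 0) {
    for (k in seq_len(nrow(model$ratio_constraints))) {
      rc <- model$ratio_constraints[k, ]
      row <- row + 1
      ia <- c(ia, row, row)
      ja <- c(ja, match(c(rc$reaction_a, rc$reaction_b), model$reactions$id))
      ar <- c(ar, 1, -rc$ratio)
      rlb <- c(rlb, 0); rub <- c(rub, 0)
    }
  }
  if (nrow(model$couplings) > 0) {
    for (k in seq_len(nrow(model$couplings))) {
      cp <- model$couplings[k, ]
      rxns <- cp$reactions[[1]]
      row <- row + 1
      ia <- c(ia, rep(row, length(rxns)))
      ja <- c(ja, match(rxns, model$reactions$id))
      ar <- c(ar, cp$coefs[[1]])
      rlb <- c(rlb, cp$lower); rub <- c(rub, cp$upper)
    }
  }
  list(nrow = row, ncol = nrxn,
       ia = as.integer(ia), ja = as.integer(ja), ar = as.numeric(ar),
       rlb = rlb, rub = rub,
       clb = model$reactions$lower, cub = model$reactions$upper,
       rxn = model$reactions$id)
}

# GLPK basis status codes for warm starts
GLP_BS <- 1L
GLP_NL <- 2L

lp_solve_raw <- function(lp, obj, maximize, basis = NULL) {
  ans <- .Call(C_glpk_solve,
               as.integer(lp$nrow), as.integer(lp$ncol),
               as.integer(lp$ia), as.integer(lp$ja), as.numeric(lp$ar),
               as.numeric(lp$rlb), as.numeric(lp$rub),
               as.numeric(lp$clb), as.numeric(lp$cub),
               as.numeric(obj), isTRUE(maximize),
               if (is.null(basis)) NULL else as.integer(basis$rstat),
               if (is.null(basis)) NULL else as.integer(basis$cstat))
  ans$status <- c("optimal", "infeasible", "unbounded", "failed")[ans$status]
  ans
}

# carry a basis across a structural extension: new rows start basic, new
# columns start nonbasic at their lower bound
extend_basis <- function(ans, new_rows = 0, new_cols = 0) {
  list(rstat = c(ans$rstat, rep(GLP_BS, new_rows)),
       cstat = c(ans$cstat, rep(GLP_NL, new_cols)))
}

lp_add_row <- function(lp, terms_idx, coefs, lower, upper) {
  lp$nrow <- lp$nrow + 1
  lp$ia <- c(lp$ia, rep(lp$nrow, length(terms_idx)))
  lp$ja <- c(lp$ja, as.integer(terms_idx))
  lp$ar <- c(lp$ar, coefs)
  lp$rlb <- c(lp$rlb, lower)
  lp$rub <- c(lp$rub, upper)
  lp
}

obj_vector <- function(lp, objective) {
  v <- numeric(lp$ncol)
  idx <- match(names(objective$terms), lp$rxn)
  if (anyNA(idx)) {
    abort(paste0("objective references unknown reaction(s): ",
                 paste(names(objective$terms)[is.na(idx)], collapse = ", ")))
  }
  v[idx] <- objective$terms
  v
}

# Add |v| columns: for every structural column i, a column t_i with rows
# t_i - v_i >= 0 and t_i + v_i >= 0; minimizing sum(t) minimizes sum |v|.
lp_with_abs_columns <- function(lp) {
  n <- lp$ncol
  tcol <- n + seq_len(n)
  lp$ncol <- 2L * n
  lp$clb <- c(lp$clb, rep(0, n))
  lp$cub <- c(lp$cub, rep(Inf, n))
  base <- lp$nrow
  lp$ia <- c(lp$ia, rep(base + seq_len(n), each = 2),
             rep(base + n + seq_len(n), each = 2))
  lp$ja <- c(lp$ja, as.integer(rbind(tcol, seq_len(n))),
             as.integer(rbind(tcol, seq_len(n))))
  lp$ar <- c(lp$ar, rep(c(1, -1), n), rep(c(1, 1), n))
  lp$nrow <- base + 2L * n
  lp$rlb <- c(lp$rlb, rep(0, 2 * n))
  lp$rub <- c(lp$rub, rep(Inf, 2 * n))
  lp$n_structural <- n
  lp
}

# ---- solution container -----------------------------------------------------

new_flux_distribution <- function(model, fluxes, objective_value, status,
                                  stages = NULL) {
  fl <- tibble(reaction = model$reactions$id, flux = fluxes)
  structure(list(fluxes = fl,
                 objective_value = objective_value,
                 status = status,
                 total_abs_flux = if (all(is.finite(fluxes))) sum(abs(fluxes)) else NA_real_,
                 stages = stages),
            class = "flux_distribution")
}

#' @export
print.flux_distribution <- function(x, ...) {
  cat("<flux_distribution> status:", x$status,
      "| objective:", format(x$objective_value, digits = 6),
      "| total |v|:", format(x$total_abs_flux, digits = 6), "\n")
  invisible(x)
}

#' Extract fluxes from a solution
#'
#' @param solution a `flux_distribution`.
#' @param ids reaction ids; default all.
#' @return Named numeric vector of fluxes.
#' @export
fluxes <- function(solution, ids = NULL) {
  v <- setNames(solution$fluxes$flux, solution$fluxes$reaction)
  if (is.null(ids)) return(v)
  missing <- setdiff(ids, names(v))
  if (length(missing) > 0) {
    abort(paste0("unknown reaction(s): ", paste(missing, collapse = ", ")))
  }
  v[ids]
}

# ---- solvers ----------------------------------------------------------------

#' Flux balance analysis
#'
#' Solves `min/max c'v` subject to `S v = 0`, the flux bounds and any ratio
#' or coupling constraints stored on the model.
#'
#' @param model a `metabolic_model`.
#' @param objective a [flux_objective()]; defaults to the model's stored
#'   objective.
#' @return A `flux_distribution`; on infeasibility or unboundedness the
#'   status field says so and no fluxes are fabricated.
#' @export
solve_fba <- function(model, objective = NULL) {
  objective <- objective %||% model_objective(model)
  lp <- compile_lp(model)
  ans <- lp_solve_raw(lp, obj_vector(lp, objective),
                      objective$direction == "max")
  new_flux_distribution(model, ans$x, ans$objective, ans$status)
}

#' Parsimonious flux balance analysis
#'
#' Finds, among all flux distributions attaining the FBA optimum, one with
#' minimal total absolute flux `sum(|v_i|)`. Equivalent to
#' [lexicographic_solve()] with a single objective and a final parsimony
#' stage.
#'
#' @inheritParams solve_fba
#' @return A `flux_distribution` whose `objective_value` equals the FBA
#'   optimum and whose `total_abs_flux` is minimal among the alternative
#'   optima.
#' @export
solve_pfba <- function(model, objective = NULL) {
  objective <- objective %||% model_objective(model)
  lexicographic_solve(model, list(objective), final_parsimony = TRUE)
}

#' Lexicographic multi-objective solve
#'
#' Optimizes the objectives in order; after each stage the achieved optimum
#' is pinned (within a relative tolerance) as a constraint before the next
#' stage runs. With `final_parsimony = TRUE` a last stage minimizes the total
#' absolute flux, i.e. the solve ends in a parsimonious FBA over the
#' lexicographically constrained optimum set.
#'
#' @param model a `metabolic_model`.
#' @param objectives list of [flux_objective()] values, first = highest
#'   priority.
#' @param final_parsimony minimize `sum(|v|)` as the last stage.
#' @param stage_tol relative tolerance with which each stage optimum is held.
#' @return A `flux_distribution`; `$stages` is a tibble with one row per
#'   stage and its achieved value. If a stage fails, `status` names it.
#' @export
lexicographic_solve <- function(model, objectives, final_parsimony = TRUE,
                                stage_tol = 1e-6) {
  stopifnot(length(objectives) >= 1)
  lp <- compile_lp(model)
  stage_val <- numeric(0)
  stage_lab <- character(0)
  basis <- NULL
  for (k in seq_along(objectives)) {
    ob <- objectives[[k]]
    ov <- obj_vector(lp, ob)
    ans <- lp_solve_raw(lp, ov, ob$direction == "max", basis)
    if (ans$status != "optimal") {
      return(new_flux_distribution(
        model, rep(NA_real_, nrow(model$reactions)), NA_real_,
        paste0(ans$status, " (stage ", k, ": ",
               paste(names(ob$terms), collapse = "+"), ")")))
    }
    z <- ans$objective
    eps <- stage_tol * max(1, abs(z))
    idx <- which(ov != 0)
    if (ob$direction == "max") {
      lp <- lp_add_row(lp, idx, ov[idx], z - eps, Inf)
    } else {
      lp <- lp_add_row(lp, idx, ov[idx], -Inf, z + eps)
    }
    basis <- extend_basis(ans, new_rows = 1)
    stage_val <- c(stage_val, z)
    stage_lab <- c(stage_lab, paste0(ob$direction, ": ",
                                     paste(names(ob$terms), collapse = "+")))
  }
  if (final_parsimony) {
    lpa <- lp_with_abs_columns(lp)
    obj <- c(numeric(lpa$n_structural), rep(1, lpa$n_structural))
    ans <- lp_solve_raw(lpa, obj, FALSE,
                        extend_basis(list(rstat = basis$rstat,
                                          cstat = basis$cstat),
                                     new_rows = 2L * lpa$n_structural,
                                     new_cols = lpa$n_structural))
    if (ans$status != "optimal") {
      return(new_flux_distribution(
        model, rep(NA_real_, nrow(model$reactions)), NA_real_,
        paste0(ans$status, " (stage parsimony)")))
    }
    v <- ans$x[seq_len(lpa$n_structural)]
    stage_val <- c(stage_val, ans$objective)
    stage_lab <- c(stage_lab, "min: total absolute flux")
  } else {
    v <- ans$x
  }
  out <- new_flux_distribution(model, v, stage_val[1], "optimal",
                               stages = tibble(stage = stage_lab,
                                               value = stage_val))
  out
}

#' Flux variability analysis
#'
#' Computes, for each queried reaction, the minimal and maximal flux
#' attainable while the context objectives are held near their optima. The
#' stage objectives are pinned as in [lexicographic_solve()]; the *last*
#' context quantity (the total absolute flux when `final_parsimony = TRUE`,
#' following the near-optimal-space analysis of the two-cell experiments) is
#' allowed to deviate by `deviation` (e.g. `0.015` = 1.5%).
#'
#' @param model a `metabolic_model`.
#' @param objectives list of [flux_objective()]; defaults to the model
#'   objective.
#' @param reactions reaction ids to query; default all.
#' @param deviation allowed relative deviation of the final context quantity.
#' @param final_parsimony include the minimal-total-flux context stage.
#' @param stage_tol tolerance for pinning the non-final stages.
#' @return A tibble of class `fva_result` with columns `reaction`, `min`,
#'   `max`; attributes record the context optima and deviation.
#' @export
run_fva <- function(model, objectives = NULL, reactions = NULL,
                    deviation = 0.015, final_parsimony = TRUE,
                    stage_tol = 1e-6) {
  objectives <- objectives %||% list(model_objective(model))
  reactions <- reactions %||% model$reactions$id
  ridx <- rxn_index(model, reactions)
  lp <- compile_lp(model)
  nstage <- length(objectives)
  basis <- NULL
  for (k in seq_along(objectives)) {
    ob <- objectives[[k]]
    ov <- obj_vector(lp, ob)
    ans <- lp_solve_raw(lp, ov, ob$direction == "max", basis)
    if (ans$status != "optimal") {
      abort(paste0("FVA context stage ", k, " is ", ans$status))
    }
    z <- ans$objective
    last <- (k == nstage) && !final_parsimony
    slack <- if (last) deviation * max(1e-9, abs(z)) else stage_tol * max(1, abs(z))
    idx <- which(ov != 0)
    if (ob$direction == "max") {
      lp <- lp_add_row(lp, idx, ov[idx], z - slack, Inf)
    } else {
      lp <- lp_add_row(lp, idx, ov[idx], -Inf, z + slack)
    }
    basis <- extend_basis(ans, new_rows = 1)
  }
  if (final_parsimony) {
    lp <- lp_with_abs_columns(lp)
    obj <- c(numeric(lp$n_structural), rep(1, lp$n_structural))
    ans <- lp_solve_raw(lp, obj, FALSE,
                        extend_basis(basis, new_rows = 2L * lp$n_structural,
                                     new_cols = lp$n_structural))
    if (ans$status != "optimal") abort("FVA parsimony context is infeasible")
    total <- ans$objective
    # the tiny absolute slack keeps the deviation-0 case numerically feasible
    lp <- lp_add_row(lp, lp$n_structural + seq_len(lp$n_structural),
                     rep(1, lp$n_structural), -Inf,
                     (1 + deviation) * total + 1e-9 * max(1, total))
    basis <- extend_basis(ans, new_rows = 1)
  }
  n <- length(lp$clb)
  mins <- maxs <- numeric(length(ridx))
  for (j in seq_along(ridx)) {
    ov <- numeric(n)
    ov[ridx[j]] <- 1
    lo <- lp_solve_raw(lp, ov, FALSE, basis)
    hi <- lp_solve_raw(lp, ov, TRUE, basis)
    if (lo$status != "optimal" || hi$status != "optimal") {
      abort(paste0("FVA subproblem failed for ", reactions[j]))
    }
    mins[j] <- lo$objective
    maxs[j] <- hi$objective
  }
  structure(tibble(reaction = reactions, min = mins, max = maxs),
            class = c("fva_result", "tbl_df", "tbl", "data.frame"),
            deviation = deviation)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Verify that a solution satisfies the model constraints
#'
#' Checks the steady-state residual `|S v|`, the bounds and all ratio and
#' coupling constraints of an optimal solution; used by the property tests.
#'
#' @param model a `metabolic_model`.
#' @param solution a `flux_distribution` with status `"optimal"`.
#' @param tol absolute tolerance, scaled by the largest flux magnitude.
#' @return TRUE invisibly, or an error describing the violation.
#' @export
check_solution <- function(model, solution, tol = 1e-6) {
  stopifnot(solution$status == "optimal")
  v <- fluxes(solution)
  scale <- max(1, max(abs(v)))
  resid <- stoichiometric_matrix(model) %*% v
  if (max(abs(resid)) > tol * scale) {
    abort(paste0("steady-state violation: max |S v| = ", max(abs(resid))))
  }
  rr <- model$reactions
  if (any(v < rr$lower - tol * scale) || any(v > rr$upper + tol * scale)) {
    abort("bound violation in solution")
  }
  if (nrow(model$ratio_constraints) > 0) {
    d <- v[model$ratio_constraints$reaction_a] -
      model$ratio_constraints$ratio * v[model$ratio_constraints$reaction_b]
    if (max(abs(d)) > tol * scale) abort("ratio constraint violated")
  }
  if (nrow(model$couplings) > 0) {
    for (k in seq_len(nrow(model$couplings))) {
      cp <- model$couplings[k, ]
      val <- sum(cp$coefs[[1]] * v[cp$reactions[[1]]])
      if (val < cp$lower - tol * scale || val > cp$upper + tol * scale) {
        abort(paste0("coupling constraint violated: ", cp$id))
      }
    }
  }
  invisible(TRUE)
}
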