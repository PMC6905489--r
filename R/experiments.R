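#' Default enzyme registry
#'
#' Declarative mapping from enzyme labels to the reaction ids of the reduced
#' leaf network (cell prefixes are expanded automatically on two-cell
#' models). Supply your own mapping for models with a different id scheme.
#'
#' @return Named list of character vectors of reaction ids.
#' @export
default_enzyme_registry <- function() {
  list(PEPC = "PEPC_c", PPDK = "PPDK_h", NADP_ME = "NADPME_h",
       NAD_ME = "NADME_m", PEP_CK = "PEPCK_c", GDC = "GDC_m")
}

# expand registry entries with the cell prefixes present in the model
expand_registry <- function(model, registry = default_enzyme_registry()) {
  pf <- model$annotations$cells
  map(registry, function(ids) {
    if (is.null(pf)) return(intersect(ids, model$reactions$id))
    intersect(as.vector(outer(paste0(pf, "_"), ids, paste0)),
              model$reactions$id)
  })
}

phloem_objective <- function(model) {
  pf <- model$annotations$cells
  ids <- if (is.null(pf)) c("Ex_Suc", "Ex_AA")
         else paste0(pf[2], c("_Ex_Suc", "_Ex_AA"))
  flux_objective(setNames(c(1, 1), ids), "max")
}

oxygenation_objective <- function(model) {
  reg <- model$annotations$rubisco
  ids <- if (is.null(reg)) "RBO_h" else c(reg$m_rbo, reg$b_rbo)
  flux_objective(setNames(rep(1, length(ids)), ids), "min")
}

experiment_objectives <- function(model, minimize_photorespiration) {
  if (minimize_photorespiration) {
    list(phloem_objective(model), oxygenation_objective(model))
  } else {
    list(phloem_objective(model))
  }
}

sum_flux <- function(v, ids) if (length(ids) == 0) 0 else sum(v[ids])

# one-row feature record for scan grids
extract_features <- function(model, solution,
                             registry = default_enzyme_registry()) {
  reg <- expand_registry(model, registry)
  rub <- model$annotations$rubisco
  pf <- model$annotations$cells
  mb <- if (is.null(pf)) character() else interface_transporters(model)
  if (solution$status != "optimal") {
    out <- tibble(status = solution$status, phloem = NA_real_,
                  co2_uptake = NA_real_)
    for (nm in tolower(names(reg))) out[[nm]] <- NA_real_
    return(out)
  }
  v <- fluxes(solution)
  co2_ids <- intersect(if (is.null(pf)) "Im_CO2" else paste0(pf, "_Im_CO2"),
                       model$reactions$id)
  phloem_ids <- names(phloem_objective(model)$terms)
  out <- tibble(
    status = solution$status,
    phloem = sum_flux(v, phloem_ids),
    co2_uptake = sum_flux(v, co2_ids)
  )
  for (nm in names(reg)) out[[tolower(nm)]] <- sum_flux(v, reg[[nm]])
  if (!is.null(rub)) {
    out$rubisco_m <- v[[rub$m_rbc]]
    out$rubisco_b_native <- v[[rub$b_rbc_native]]
    out$rubisco_b_ccm <- v[[rub$b_rbc_ccm]]
    out$oxygenation <- v[[rub$m_rbo]] + v[[rub$b_rbo]]
  }
  out$total_abs_flux <- solution$total_abs_flux
  for (id in mb) {
    out[[paste0("mb_", sub("^\\[MB\\]_", "", id))]] <- v[[id]]
  }
  out
}

new_scan <- function(tbl, axes) {
  structure(tbl, class = c("c4_scan", class(tibble())), axes = axes)
}

#' Scan the photorespiration level of the two-cell model
#'
#' For each oxygenation : carboxylation ratio the constraint is re-pinned on
#' both native Rubisco populations, the model is solved lexicographically
#' (maximal bundle-sheath phloem output, optionally minimal oxygenation,
#' then minimal total flux), and the C4-diagnostic fluxes are extracted:
#' PEPC, PPDK, the three decarboxylases, glycine decarboxylase, the three
#' Rubisco populations and every intercellular transporter.
#'
#' @param two_cell a composed two-cell model.
#' @param ratios grid of oxygenation : carboxylation ratios.
#' @param minimize_photorespiration add the oxygenation-minimizing stage
#'   between the phloem and parsimony stages.
#' @param registry enzyme registry, see [default_enzyme_registry()].
#' @return A `c4_scan` tibble, one row per grid point; infeasible points are
#'   recorded with their status, never dropped.
#' @export
photorespiration_scan <- function(two_cell, ratios = seq(0, 1, by = 0.05),
                                  minimize_photorespiration = FALSE,
                                  registry = default_enzyme_registry()) {
  if (length(unlist(expand_registry(two_cell, registry)["PEPC"])) == 0) {
    abort(paste0("photorespiration scan requires reaction(s) for PEPC, which ",
                 "the model does not contain (was the C4 subsystem excluded ",
                 "from the fixture config?)"))
  }
  objs <- experiment_objectives(two_cell, minimize_photorespiration)
  rows <- map(ratios, function(r) {
    m <- set_two_cell_photorespiration(two_cell, r)
    sol <- lexicographic_solve(m, objs, final_parsimony = TRUE)
    mutate(extract_features(m, sol, registry), ratio = r, .before = 1)
  })
  new_scan(bind_rows(rows), axes = "ratio")
}

#' Knock out all but one decarboxylation enzyme
#'
#' Bounds the two non-kept decarboxylases to zero flux in both cells and
#' solves under the stressed condition: oxygenation : carboxylation 1 : 3 on
#' the native populations with objectives maximal phloem output, minimal
#' photorespiration, minimal total flux.
#'
#' @param two_cell a composed two-cell model.
#' @param keep `"NADP_ME"`, `"NAD_ME"` or `"PEP_CK"`.
#' @param photorespiration ratio for the native populations.
#' @param registry enzyme registry.
#' @return A `flux_distribution` with attribute `"kept"`.
#' @export
knockout_decarboxylation <- function(two_cell,
                                     keep = c("NADP_ME", "NAD_ME", "PEP_CK"),
                                     photorespiration = 1 / 3,
                                     registry = default_enzyme_registry()) {
  keep <- match.arg(keep)
  m <- knockout_model(two_cell, keep, photorespiration, registry)
  sol <- lexicographic_solve(m, experiment_objectives(m, TRUE),
                             final_parsimony = TRUE)
  attr(sol, "kept") <- keep
  sol
}

knockout_model <- function(two_cell, keep, photorespiration,
                           registry = default_enzyme_registry()) {
  decarb <- c("NADP_ME", "NAD_ME", "PEP_CK")
  if (!keep %in% decarb) abort(paste0("unknown decarboxylase label: ", keep))
  reg <- expand_registry(two_cell, registry)
  off <- unlist(reg[setdiff(decarb, keep)], use.names = FALSE)
  require_reactions(two_cell, unlist(reg[decarb]), "decarboxylase knockout")
  two_cell %>%
    set_bounds(off, lower = 0, upper = 0) %>%
    set_two_cell_photorespiration(photorespiration)
}

#' Near-optimal variability of the intercellular transporters
#'
#' Flux variability analysis over every `[MB]` transporter, holding the
#' phloem optimum and the minimal-oxygenation optimum and allowing the
#' minimal total flux to deviate by `deviation` (default 1.5%). Positive
#' fluxes run mesophyll to bundle sheath.
#'
#' @param two_cell a composed two-cell model.
#' @param keep optionally restrict decarboxylation to one enzyme first
#'   (as in [knockout_decarboxylation()]).
#' @param deviation allowed relative increase of the total-flux minimum.
#' @param photorespiration ratio for the native populations.
#' @param registry enzyme registry.
#' @return An `fva_result` tibble with the parsimonious fluxes attached as
#'   the `"solution"` attribute.
#' @export
transport_fva <- function(two_cell, keep = NULL, deviation = 0.015,
                          photorespiration = 1 / 3,
                          registry = default_enzyme_registry()) {
  m <- if (is.null(keep)) set_two_cell_photorespiration(two_cell, photorespiration)
       else knockout_model(two_cell, keep, photorespiration, registry)
  mb <- interface_transporters(m)
  if (length(mb) == 0) abort("model has no interface transporters")
  objs <- experiment_objectives(m, TRUE)
  res <- run_fva(m, objs, reactions = mb, deviation = deviation,
                 final_parsimony = TRUE)
  sol <- lexicographic_solve(m, objs, final_parsimony = TRUE)
  attr(res, "solution") <- tidy(sol) %>% filter(.data$reaction %in% mb)
  res
}

#' Light amount and distribution grid
#'
#' Varies the total photon flux density and its bundle-sheath : mesophyll
#' split. Per grid point the photon uptake is fixed to the requested total
#' and split (the ordering constraint is released; excess photons must be
#' dissipated), the model is solved, and decarboxylase activities are
#' reported both absolutely and relative to the CO2 uptake rate
#' (`share_* = flux / co2_uptake`, undefined where the uptake is zero).
#'
#' @param two_cell a composed two-cell model.
#' @param totals grid of total photon flux densities, umol/(m^2 s).
#' @param ratios grid of photon(B)/photon(M) splits.
#' @param minimize_photorespiration include the oxygenation-minimizing stage.
#' @param registry enzyme registry.
#' @return A `c4_scan` tibble over the `total` x `split` grid.
#' @export
light_scan <- function(two_cell, totals = seq(0, 1000, by = 50),
                       ratios = seq(0.1, 2, by = 0.1),
                       minimize_photorespiration = TRUE,
                       registry = default_enzyme_registry()) {
  grid <- tidyr::expand_grid(total = totals, split = ratios)
  rows <- pmap(grid, function(total, split) {
    m <- set_two_cell_bounds(two_cell, co2_m = 40, ppfd_total = total,
                             ppfd_ratio = split, ppfd_fixed = TRUE,
                             enforce_ordering = FALSE)
    sol <- lexicographic_solve(m, experiment_objectives(m, minimize_photorespiration),
                               final_parsimony = TRUE)
    mutate(extract_features(m, sol, registry),
           total = total, split = split, .before = 1)
  })
  out <- bind_rows(rows) %>%
    mutate(across(dplyr::any_of(c("nadp_me", "nad_me", "pep_ck")),
                  ~ ifelse(.data$co2_uptake > 1e-9, .x / .data$co2_uptake,
                           NA_real_),
                  .names = "share_{.col}"))
  new_scan(out, axes = c("total", "split"))
}

#' Nutrient-limitation scan
#'
#' Bounds the uptake of nitrate, water or CO2 (summed over both cells) to a
#' grid of values and records the phloem output and decarboxylase shares at
#' each point.
#'
#' @param two_cell a composed two-cell model.
#' @param nutrient `"NO3"`, `"H2O"` or `"CO2"`.
#' @param grid uptake bounds, umol/(m^2 s).
#' @param minimize_photorespiration include the oxygenation-minimizing stage.
#' @param registry enzyme registry.
#' @return A `c4_scan` tibble over the grid.
#' @export
limitation_scan <- function(two_cell, nutrient = c("NO3", "H2O", "CO2"),
                            grid = NULL,
                            minimize_photorespiration = TRUE,
                            registry = default_enzyme_registry()) {
  nutrient <- match.arg(nutrient)
  pf <- cell_prefixes(two_cell)
  if (is.null(grid)) {
    grid <- switch(nutrient, NO3 = seq(0, 1, by = 0.1),
                   H2O = seq(0, 50, by = 5), CO2 = seq(0, 40, by = 4))
  }
  objs <- experiment_objectives(two_cell, minimize_photorespiration)
  rows <- map(grid, function(g) {
    m <- switch(
      nutrient,
      NO3 = add_coupling(two_cell, "limit:NO3",
                         setNames(c(1, 1), paste0(pf, "_Im_NO3")),
                         lower = 0, upper = g),
      H2O = add_coupling(two_cell, "limit:H2O",
                         setNames(c(1, 1), paste0(pf, "_Im_H2O")),
                         lower = -Inf, upper = g),
      CO2 = set_bounds(two_cell, paste0(pf[1], "_Im_CO2"), lower = 0, upper = g)
    )
    sol <- lexicographic_solve(m, objs, final_parsimony = TRUE)
    mutate(extract_features(m, sol, registry), bound = g, .before = 1)
  })
  out <- bind_rows(rows) %>% mutate(nutrient = nutrient, .before = 1)
  new_scan(out, axes = "bound")
}

#' Aspartate : malate transport-ratio scan
#'
#' Pins the flux ratio of the aspartate and malate intercellular
#' transporters (`v([MB]_ASP) = ratio * v([MB]_MAL)`, two-sided, so a zero
#' malate flux forces zero aspartate flux) and records which decarboxylation
#' enzyme the optimum uses at each ratio.
#'
#' @param two_cell a composed two-cell model.
#' @param ratios grid of aspartate : malate flux ratios.
#' @param keep optionally restrict decarboxylation to one enzyme.
#' @param minimize_photorespiration include the oxygenation-minimizing stage.
#' @param registry enzyme registry.
#' @return A `c4_scan` tibble over the grid.
#' @export
transport_ratio_scan <- function(two_cell, ratios = seq(0, 4, by = 0.5),
                                 keep = NULL,
                                 minimize_photorespiration = TRUE,
                                 registry = default_enzyme_registry()) {
  require_reactions(two_cell, c("[MB]_ASP", "[MB]_MAL"), "transport-ratio scan")
  base <- if (is.null(keep)) two_cell
          else knockout_model(two_cell, keep, 1 / 3, registry)
  objs <- experiment_objectives(base, minimize_photorespiration)
  rows <- map(ratios, function(r) {
    m <- add_ratio_constraint(base, "[MB]_ASP", "[MB]_MAL", r,
                              id = "transport:asp_mal")
    sol <- lexicographic_solve(m, objs, final_parsimony = TRUE)
    mutate(extract_features(m, sol, registry), asp_mal = r, .before = 1)
  })
  new_scan(bind_rows(rows), axes = "asp_mal")
}

#' Cofactor production/consumption accounting by subsystem
#'
#' Sums the net production and consumption of a cofactor pool (all
#' compartment species of ATP, NADPH or NADH) per reaction subsystem in a
#' solved flux distribution and converts the sums to percentages of the
#' total. Transport reactions moving the cofactor between compartments
#' cancel and do not appear.
#'
#' @param model the solved `metabolic_model`.
#' @param solution an optimal `flux_distribution` for `model`.
#' @param cofactor `"ATP"`, `"NADPH"` or `"NADH"`.
#' @param tol net rates below this are ignored.
#' @return An `energy_account` with `producers` and `consumers` tibbles
#'   (`subsystem`, `flux`, `percent`); percentages sum to 100 on each side.
#' @export
energy_accounting <- function(model, solution,
                              cofactor = c("ATP", "NADPH", "NADH"),
                              tol = 1e-9) {
  cofactor <- match.arg(cofactor)
  stopifnot(solution$status == "optimal")
  pat <- paste0("(^|_)", cofactor, "_[a-z]+$")
  species <- grep(pat, model$metabolites$id, value = TRUE)
  if (length(species) == 0) {
    abort(paste0("cofactor ", cofactor, " not present in the model"))
  }
  v <- fluxes(solution)
  net <- model$stoich %>%
    filter(.data$metabolite %in% species) %>%
    group_by(.data$reaction) %>%
    summarise(rate = sum(.data$coef) * v[[.data$reaction[1]]],
              .groups = "drop") %>%
    left_join(select(model$reactions, "id", "subsystem"),
              by = c(reaction = "id"))
  side <- function(sign) {
    tb <- net %>%
      filter(sign * .data$rate > tol) %>%
      group_by(.data$subsystem) %>%
      summarise(flux = sign * sum(.data$rate), .groups = "drop") %>%
      arrange(dplyr::desc(.data$flux))
    mutate(tb, percent = 100 * .data$flux / sum(.data$flux))
  }
  structure(list(cofactor = cofactor, producers = side(1),
                 consumers = side(-1)),
            class = "energy_account")
}

#' @export
print.energy_account <- function(x, ...) {
  cat("<energy_account>", x$cofactor, "\n producers:\n")
  print(as.data.frame(x$producers), row.names = FALSE)
  cat(" consumers:\n")
  print(as.data.frame(x$consumers), row.names = FALSE)
  invisible(x)
}

#' Linearity of phloem output in CO2 or light supply
#'
#' Solves the one-cell model along a grid of CO2-uptake or photon-supply
#' caps and reports the phloem output per point together with the detected
#' saturation breakpoint (the first grid value whose forward slope falls
#' below half of the initial slope). Points whose maintenance demand cannot
#' be met (no light) are recorded as infeasible.
#'
#' @param one_cell a composed one-cell model.
#' @param axis `"CO2"` or `"PPFD"`.
#' @param grid axis values; defaults to 0..20 (CO2) or 0..400 (PPFD).
#' @return A `c4_scan` tibble with attribute `"breakpoint"`.
#' @export
linearity_probe <- function(one_cell, axis = c("CO2", "PPFD"), grid = NULL) {
  axis <- match.arg(axis)
  if (is.null(grid)) {
    grid <- if (axis == "CO2") seq(0, 20, by = 2) else seq(0, 400, by = 25)
  }
  ex_id <- if (axis == "CO2") "Im_CO2" else "Im_hnu"
  require_reactions(one_cell, ex_id, "linearity probe")
  rows <- map(grid, function(g) {
    m <- set_bounds(one_cell, ex_id, lower = 0, upper = g)
    sol <- solve_pfba(m)
    if (sol$status == "optimal") {
      v <- fluxes(sol, c("Ex_Suc", "Ex_AA", "Im_CO2", "Im_hnu"))
      tibble(value = g, status = sol$status, phloem = v[["Ex_Suc"]] + v[["Ex_AA"]],
             co2_uptake = v[["Im_CO2"]], ppfd = v[["Im_hnu"]])
    } else {
      tibble(value = g, status = sol$status, phloem = NA_real_,
             co2_uptake = NA_real_, ppfd = NA_real_)
    }
  })
  out <- bind_rows(rows)
  ok <- filter(out, .data$status == "optimal")
  breakpoint <- NA_real_
  if (nrow(ok) >= 3) {
    slopes <- diff(ok$phloem) / diff(ok$value)
    ref <- max(slopes, na.rm = TRUE)
    flat <- which(slopes < 0.5 * ref)
    if (length(flat) > 0 && ref > 0) breakpoint <- ok$value[flat[1]]
  }
  structure(new_scan(out, axes = "value"), breakpoint = breakpoint)
}
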