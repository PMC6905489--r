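#' Add a flux-ratio constraint
#'
#' Installs the linear coupling `v_a = ratio * v_b` between two reactions.
#' Ratio constraints are stored as data on the model and compiled into extra
#' zero-rows of the constraint matrix at solve time; bounds are never
#' manipulated to emulate them. Adding a constraint with an existing `id`
#' replaces it, which is how scans re-pin a ratio per grid point.
#'
#' @param model a `metabolic_model`.
#' @param reaction_a,reaction_b reaction ids; the constraint reads
#'   `v_a = ratio * v_b`.
#' @param ratio finite, non-negative real.
#' @param id constraint identifier; defaults to `"<a>~<b>"`.
#' @return The modified model.
#' @export
add_ratio_constraint <- function(model, reaction_a, reaction_b, ratio,
                                 id = NULL) {
  rxn_index(model, c(reaction_a, reaction_b))
  if (!is.finite(ratio) || ratio < 0) {
    abort("ratio must be finite and non-negative")
  }
  if (is.null(id)) id <- paste0(reaction_a, "~", reaction_b)
  model$ratio_constraints <- bind_rows(
    filter(model$ratio_constraints, .data$id != !!id),
    tibble(id = id, reaction_a = reaction_a, reaction_b = reaction_b,
           ratio = ratio)
  )
  model
}

#' Add or replace a general linear coupling constraint
#'
#' Enforces `lower <= sum(coefs * v[reactions]) <= upper`. Used for the
#' two-cell photon budget (total photosynthetic photon flux density and the
#' mesophyll/bundle-sheath ordering or split).
#'
#' @param model a `metabolic_model`.
#' @param id constraint identifier; re-using an id replaces the constraint.
#' @param terms named numeric vector: coefficients keyed by reaction id.
#' @param lower,upper constraint bounds (use `-Inf`/`Inf` for one-sided).
#' @return The modified model.
#' @export
add_coupling <- function(model, id, terms, lower = -Inf, upper = Inf) {
  rxn_index(model, names(terms))
  if (lower > upper) abort("coupling lower bound exceeds upper bound")
  model$couplings <- bind_rows(
    filter(model$couplings, .data$id != !!id),
    tibble(id = id, reactions = list(names(terms)),
           coefs = list(unname(as.numeric(terms))),
           lower = lower, upper = upper)
  )
  model
}

#' Remove coupling constraints by id
#'
#' @param model a `metabolic_model`.
#' @param ids coupling ids to remove (missing ids are ignored).
#' @return The modified model.
#' @export
remove_coupling <- function(model, ids) {
  model$couplings <- filter(model$couplings, !.data$id %in% ids)
  model
}

#' Pin the photorespiration level of a Rubisco population
#'
#' Installs the ratio constraint `v_RBO = ratio * v_RBC` on a named
#' oxygenation/carboxylation reaction pair. Only the native Rubisco
#' populations ever receive this constraint; the CCM-dependent population of
#' a two-cell model carboxylates free of any forced oxygenation.
#'
#' @param model a `metabolic_model`.
#' @param ratio oxygenation : carboxylation ratio (e.g. `0.1` for the ambient
#'   one-cell condition, `1/3` for the stressed two-cell condition).
#' @param rbo_id,rbc_id the Rubisco oxygenation and carboxylation reaction ids.
#' @return The modified model.
#' @seealso [photorespiration_ratio_from_gas()] to derive the ratio from
#'   Rubisco specificity and gas partial pressures.
#' @export
fix_photorespiration <- function(model, ratio, rbo_id = "RBO_h",
                                 rbc_id = "RBC_h") {
  if (!is.finite(ratio) || ratio < 0) {
    abort("photorespiration ratio must be finite and non-negative")
  }
  add_ratio_constraint(model, rbo_id, rbc_id, ratio,
                       id = paste0("photorespiration:", rbo_id))
}

#' Oxygenation : carboxylation ratio from gas partial pressures
#'
#' Convenience converter: the ratio equals `(1 / SR) * pO2 / pCO2` where `SR`
#' is the specificity of Rubisco for CO2 over O2.
#'
#' @param specificity Rubisco CO2/O2 specificity (dimensionless).
#' @param p_o2,p_co2 partial pressures in any common unit.
#' @return The oxygenation : carboxylation flux ratio.
#' @export
photorespiration_ratio_from_gas <- function(specificity, p_o2, p_co2) {
  if (specificity <= 0 || p_co2 <= 0) {
    abort("specificity and pCO2 must be positive")
  }
  (1 / specificity) * p_o2 / p_co2
}

# ---- proton buffers ---------------------------------------------------------

#' Add proton sink/source reactions for every compartment
#'
#' The protonation state of most intracellular transport substrates is
#' unknown, so compartment proton pools are buffered by one fully reversible
#' sink/source reaction `<-> H_x` per compartment. Idempotent: existing
#' buffers are left untouched. Thylakoid-lumen and mitochondrial
#' intermembrane proton pools used to couple the ATP synthases are distinct
#' species and are never buffered.
#'
#' @param model a `metabolic_model`.
#' @param infinity_proxy bound magnitude for the reversible buffers.
#' @return The modified model.
#' @export
add_proton_buffers <- function(model, infinity_proxy = INF_PROXY) {
  if (length(model$compartments) == 0) {
    abort("model declares no compartments")
  }
  for (cmp in model$compartments) {
    h_id <- paste0("H_", cmp)
    sink_id <- paste0("Sink_H_", cmp)
    # cell-prefixed copies keep their own buffers when duplicated later
    if (sink_id %in% model$reactions$id) next
    if (!h_id %in% model$metabolites$id) {
      model <- add_metabolite(model, h_id, name = "proton", compartment = cmp)
    }
    model <- add_reaction(model, sink_id, stoich = c(setNames(1, h_id)),
                          lower = -infinity_proxy, upper = infinity_proxy,
                          name = paste0("proton sink/source (", cmp, ")"),
                          subsystem = "proton buffer")
  }
  model
}

# ---- maintenance ------------------------------------------------------------

#' Default non-growth-associated maintenance costs
#'
#' ATP hydrolysis fluxes for protein turnover by compartment, in
#' umol/(m^2 s). The peroxisome hosts no ATP/ADP pool, so its cost is folded
#' into the cytosol when the maintenance reactions are installed.
#'
#' @return Named numeric vector of costs for `c`, `h`, `m`, `p`.
#' @export
default_maintenance <- function() {
  c(c = 0.0427, h = 0.1527, m = 0.0091, p = 0.0076)
}

#' Install maintenance (NGAM) reactions
#'
#' Adds `NGAM_c`, `NGAM_h` and `NGAM_m` of the form
#' `ATP_x + H2O_x -> ADP_x + H_x + Pi_x` with both bounds fixed to the given
#' cost, so every feasible solution carries exactly that flux. The
#' peroxisomal cost is added onto the cytosolic one because the peroxisome
#' carries no adenylate pool.
#'
#' @param model a `metabolic_model`.
#' @param costs named numeric vector of per-compartment costs, as
#'   [default_maintenance()].
#' @param cell_prefix optional id prefix (used internally when maintaining
#'   both cells of a two-cell model).
#' @return The modified model.
#' @export
add_maintenance <- function(model, costs = default_maintenance(),
                            cell_prefix = "") {
  fixed <- c(c = unname(costs["c"] + ifelse(is.na(costs["p"]), 0, costs["p"])),
             h = unname(costs["h"]),
             m = unname(costs["m"]))
  for (cmp in names(fixed)) {
    species <- paste0(cell_prefix, c("ATP_", "H2O_", "ADP_", "H_", "Pi_"), cmp)
    missing <- setdiff(species, model$metabolites$id)
    if (length(missing) > 0) {
      abort(paste0("maintenance reaction for compartment '", cmp,
                   "' needs missing species: ", paste(missing, collapse = ", ")))
    }
    id <- paste0(cell_prefix, "NGAM_", cmp)
    st <- setNames(c(-1, -1, 1, 1, 1), species)
    if (id %in% model$reactions$id) {
      model <- set_stoichiometry(model, id, st)
    } else {
      model <- add_reaction(model, id, st, name = paste0("maintenance ATPase (", cmp, ")"),
                            subsystem = "maintenance")
    }
    model <- set_bounds(model, id, lower = fixed[[cmp]], upper = fixed[[cmp]])
  }
  model
}

# ---- boundary specification -------------------------------------------------

#' Boundary (exchange) flux specification
#'
#' @param bounds tibble with columns `reaction`, `lower`, `upper`.
#' @param infinity_proxy replacement value for infinite bounds.
#' @param zero_other_exports force all export reactions not named in `bounds`
#'   to zero flux.
#' @return An object of class `boundary_spec`.
#' @export
boundary_spec <- function(bounds, infinity_proxy = INF_PROXY,
                          zero_other_exports = TRUE) {
  bounds <- as_tibble(bounds)
  stopifnot(all(c("reaction", "lower", "upper") %in% names(bounds)))
  if (any(bounds$lower > bounds$upper)) {
    abort(paste0("boundary lower bound exceeds upper bound for: ",
                 paste(bounds$reaction[bounds$lower > bounds$upper],
                       collapse = ", ")))
  }
  structure(list(bounds = bounds, infinity_proxy = infinity_proxy,
                 zero_other_exports = zero_other_exports),
            class = "boundary_spec")
}

#' Default photoautotrophic boundary specification
#'
#' Import bounds for the one-cell leaf model: photons, nitrate, sulfate,
#' hydrogen sulfide and phosphate freely importable; CO2 uptake capped at
#' `co2_upper`; ammonium import closed so nitrate is the sole nitrogen
#' source; water and oxygen freely exchanged in both directions; sucrose,
#' amino-acid and starch exports open; all other exports closed.
#'
#' @param co2_upper CO2 uptake cap in umol/(m^2 s) (20 for the one-cell
#'   model, 40 for the mesophyll of the two-cell model).
#' @param infinity_proxy proxy for unbounded fluxes.
#' @return A `boundary_spec`.
#' @export
default_boundary_spec <- function(co2_upper = 20, infinity_proxy = INF_PROXY) {
  inf <- infinity_proxy
  boundary_spec(tibble(
    reaction = c("Im_hnu", "Im_CO2", "Im_NO3", "Im_NH4", "Im_SO4", "Im_H2S",
                 "Im_Pi", "Im_H2O", "Im_O2", "Ex_Suc", "Ex_AA", "Ex_starch"),
    lower = c(0, 0, 0, 0, 0, 0, 0, -inf, -inf, 0, 0, 0),
    upper = c(inf, co2_upper, inf, 0, inf, inf, inf, inf, inf, inf, inf, inf)
  ), infinity_proxy = infinity_proxy)
}

#' Apply a boundary specification to a model
#'
#' Sets the listed exchange bounds exactly and, unless disabled, forces every
#' unlisted export reaction (single-metabolite reaction consuming its
#' metabolite) to zero flux. Proton buffers are not exchanges with the
#' environment and are left untouched.
#'
#' @param model a `metabolic_model`.
#' @param spec a `boundary_spec`.
#' @param cell_prefix optional id prefix for two-cell models.
#' @return The modified model.
#' @export
set_boundary <- function(model, spec = default_boundary_spec(),
                         cell_prefix = "") {
  stopifnot(inherits(spec, "boundary_spec"))
  ids <- paste0(cell_prefix, spec$bounds$reaction)
  idx <- match(ids, model$reactions$id)
  if (anyNA(idx)) {
    abort(paste0("boundary spec names unknown exchange(s): ",
                 paste(ids[is.na(idx)], collapse = ", ")))
  }
  model <- set_bounds(model, ids, lower = spec$bounds$lower,
                      upper = spec$bounds$upper)
  if (spec$zero_other_exports) {
    exch <- exchange_ids(model)
    exch <- exch[startsWith(exch, cell_prefix) | cell_prefix == ""]
    coefs <- model$stoich$coef[match(exch, model$stoich$reaction)]
    exports <- exch[coefs < 0]
    other <- setdiff(exports, ids)
    other <- setdiff(other, grep("^Sink_H_|_Sink_H_", model$reactions$id,
                                 value = TRUE))
    if (length(other) > 0) {
      model <- set_bounds(model, other, lower = 0, upper = 0)
    }
  }
  model
}

# ---- elemental conservation -------------------------------------------------

#' Check elemental conservation of all internal reactions
#'
#' Sums `coef * element_count` over each reaction. Boundary and pseudo
#' reactions — anything touching a single metabolite, which covers exchanges,
#' proton buffers and photon import — are exempt and reported as such.
#' Reactions involving a metabolite with a missing element count are reported
#' as `unchecked`.
#'
#' @param model a `metabolic_model`.
#' @param element `"carbon"` or `"nitrogen"`.
#' @param tol imbalance magnitude below which a reaction counts as balanced.
#' @return Tibble with columns `reaction`, `delta`, `status`
#'   (`"flagged"`, `"exempt"`, `"unchecked"`); balanced internal reactions
#'   are omitted, so an empty tibble filtered to `status == "flagged"` means
#'   the model conserves the element.
#' @export
check_conservation <- function(model, element = c("carbon", "nitrogen"),
                               tol = 1e-9) {
  element <- match.arg(element)
  counts <- setNames(model$metabolites[[element]], model$metabolites$id)
  exempt <- exchange_ids(model)
  st <- model$stoich
  st$n_el <- counts[st$metabolite]
  per <- st %>%
    group_by(.data$reaction) %>%
    summarise(delta = sum(.data$coef * .data$n_el),
              unchecked = anyNA(.data$n_el), .groups = "drop")
  per %>%
    mutate(status = dplyr::case_when(
      .data$reaction %in% exempt ~ "exempt",
      .data$unchecked ~ "unchecked",
      abs(.data$delta) > tol ~ "flagged",
      TRUE ~ "balanced"
    )) %>%
    filter(.data$status != "balanced") %>%
    select("reaction", "delta", "status") %>%
    arrange(.data$status, .data$reaction)
}
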