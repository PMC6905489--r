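#' Intercellular transport interface specification
#'
#' Which cytosolic metabolites may move between mesophyll and bundle sheath.
#' The default transportable set covers amino acids (including the C4 and
#' photorespiratory carriers alanine, aspartate, glutamate, glycine and
#' serine), sugars and single-phosphorylated sugars, mono-/di-/tri-carboxylic
#' acids, glyceric acids, glycolate/glycerate, triose phosphates and CO2.
#' Nucleotides, redox cofactors, pyrophosphate/orthophosphate, protons and
#' bicarbonate are never exchanged; oxaloacetate is excluded because its in
#' vivo concentration is very low and it is unstable in aqueous solution.
#'
#' @param transportable character vector of metabolite base names (id without
#'   the compartment suffix).
#' @param excluded character vector of base names that must not be exchanged.
#' @param fixed_ratios optional named numeric vector: transport flux ratios
#'   to pin, e.g. `c(ASP = 2)` meaning `v([MB]_ASP) = 2 * v([MB]_MAL)` when
#'   given as `ASP/MAL` via [transport_ratio_scan()].
#' @return An object of class `cell_interface_spec`.
#' @export
cell_interface_spec <- function(transportable = default_transportable(),
                                excluded = default_excluded(),
                                fixed_ratios = NULL) {
  overlap <- intersect(transportable, excluded)
  if (length(overlap) > 0) {
    abort(paste0("metabolites both transportable and excluded: ",
                 paste(overlap, collapse = ", ")))
  }
  structure(list(transportable = transportable, excluded = excluded,
                 fixed_ratios = fixed_ratios),
            class = "cell_interface_spec")
}

#' @rdname cell_interface_spec
#' @export
default_transportable <- function() {
  c("ALA", "ASP", "GLU", "GLY", "SER", "AA",
    "SUC", "HexP", "PEP", "PYR",
    "CIT", "ICIT", "AKG", "MAL",
    "PGA", "GCA", "GCEA", "TP", "CO2")
}

#' @rdname cell_interface_spec
#' @export
default_excluded <- function() {
  c("OAA", "HCO3", "H", "Pi", "ATP", "ADP",
    "NAD", "NADH", "NADP", "NADPH", "NH4")
}

cell_prefixes <- function(model) {
  model$annotations$cells %||% c("[M]", "[B]")
}

#' Duplicate a one-cell model into two prefixed cell copies
#'
#' Every metabolite, reaction, ratio constraint and coupling is copied per
#' cell with its id prefixed (`[M]_`, `[B]_`), exactly doubling the
#' component counts; maintenance fluxes and boundary bounds are carried
#' along with the reactions. The objective is duplicated over both cells and
#' is typically re-pointed at the bundle-sheath phloem exports afterwards.
#'
#' @param model a `metabolic_model`.
#' @param prefixes length-2 character vector of cell tags.
#' @return A `metabolic_model` tagged with the cell prefixes (a two-cell
#'   model).
#' @export
duplicate_cells <- function(model, prefixes = c("[M]", "[B]")) {
  stopifnot(length(prefixes) == 2)
  validate_model(model)
  for (p in prefixes) {
    if (any(startsWith(model$metabolites$id, p)) ||
        any(startsWith(model$reactions$id, p))) {
      abort(paste0("prefix collision: ids starting with '", p,
                   "' already exist"))
    }
  }
  tag <- function(ids, p) paste0(p, "_", ids)
  per_cell <- function(p) {
    list(
      metabolites = mutate(model$metabolites, id = tag(.data$id, p)),
      reactions = mutate(model$reactions, id = tag(.data$id, p)),
      stoich = mutate(model$stoich, reaction = tag(.data$reaction, p),
                      metabolite = tag(.data$metabolite, p)),
      objective = mutate(model$objective, reaction = tag(.data$reaction, p)),
      ratio = mutate(model$ratio_constraints, id = tag(.data$id, p),
                     reaction_a = tag(.data$reaction_a, p),
                     reaction_b = tag(.data$reaction_b, p)),
      couplings = mutate(model$couplings, id = tag(.data$id, p),
                         reactions = map(.data$reactions, ~ tag(.x, p)))
    )
  }
  parts <- map(prefixes, per_cell)
  two <- metabolic_model(
    metabolites = bind_rows(map(parts, "metabolites")),
    reactions = bind_rows(map(parts, "reactions")),
    stoich = bind_rows(map(parts, "stoich")),
    objective = bind_rows(map(parts, "objective")),
    objective_direction = model$objective_direction,
    ratio_constraints = bind_rows(map(parts, "ratio")),
    couplings = bind_rows(map(parts, "couplings")),
    compartments = model$compartments,
    annotations = model$annotations
  )
  two$annotations$cells <- prefixes
  two
}

#' Connect the two cell copies with reversible transporters
#'
#' Adds one reversible `[MB]_<name>` reaction per transportable cytosolic
#' metabolite, moving it from the mesophyll cytosol to the bundle-sheath
#' cytosol (positive flux = mesophyll to bundle sheath). Excluded metabolites
#' get no transporter; no other inter-cell coupling exists.
#'
#' @param two_cell a duplicated model from [duplicate_cells()].
#' @param interface a [cell_interface_spec()].
#' @param mb_prefix prefix for interface transporter ids.
#' @return The linked two-cell model.
#' @export
link_cells <- function(two_cell, interface = cell_interface_spec(),
                       mb_prefix = "[MB]") {
  stopifnot(inherits(interface, "cell_interface_spec"))
  pf <- cell_prefixes(two_cell)
  for (nm in interface$transportable) {
    m_id <- paste0(pf[1], "_", nm, "_c")
    b_id <- paste0(pf[2], "_", nm, "_c")
    missing <- setdiff(c(m_id, b_id), two_cell$metabolites$id)
    if (length(missing) > 0) {
      abort(paste0("transportable metabolite '", nm,
                   "' has no cytosolic species: ",
                   paste(missing, collapse = ", ")))
    }
    two_cell <- add_reaction(
      two_cell, paste0(mb_prefix, "_", nm),
      setNames(c(-1, 1), c(m_id, b_id)),
      lower = -INF_PROXY, upper = INF_PROXY,
      name = paste0(nm, " intercellular transporter"),
      subsystem = "intercellular transport"
    )
  }
  two_cell$annotations$interface <- list(
    transportable = interface$transportable,
    excluded = interface$excluded
  )
  two_cell
}

#' Interface transporter ids of a two-cell model
#'
#' @param two_cell a linked two-cell model.
#' @param mb_prefix interface prefix.
#' @return Character vector of `[MB]_*` reaction ids.
#' @export
interface_transporters <- function(two_cell, mb_prefix = "[MB]") {
  ids <- two_cell$reactions$id
  ids[startsWith(ids, paste0(mb_prefix, "_"))]
}

#' Install the dual Rubisco population in the bundle sheath
#'
#' Splits the bundle-sheath CO2 pool into an external part, supplied by the
#' mesophyll through the interface transporter, and the internal part
#' produced by bundle-sheath reactions. The native Rubisco population binds
#' external CO2 — its carboxylation is the new `[B]_RBC_h_Ex`, paired with
#' the existing `[B]_RBO_h` under the forced oxygenation : carboxylation
#' ratio — while the pre-existing `[B]_RBC_h` becomes the CCM-dependent
#' population: it carboxylates free of any oxygenation constraint but can
#' only consume internally released CO2. External CO2 may only move to the
#' chloroplast (`[B]_Tr_CO2h_Ex`) and react with Rubisco (`[B]_RBC_h_Ex`).
#'
#' @param two_cell a linked two-cell model.
#' @return The model with the dual population and its registry installed.
#' @export
install_ccm_rubisco <- function(two_cell) {
  pf <- cell_prefixes(two_cell)
  B <- function(x) paste0(pf[2], "_", x)
  M <- function(x) paste0(pf[1], "_", x)
  needed <- c(B("RBC_h"), B("RBO_h"), B("RuBP_h"), B("PGA_h"), "[MB]_CO2")
  require_reactions(two_cell, intersect(needed, c(B("RBC_h"), B("RBO_h"), "[MB]_CO2")),
                    "CCM Rubisco installation")
  met_index(two_cell, c(B("RuBP_h"), B("PGA_h"), B("CO2_c")))

  two_cell <- two_cell %>%
    add_metabolite(B("CO2_ex_c"), name = "external CO2 (from mesophyll)",
                   compartment = "c", carbon = 1) %>%
    add_metabolite(B("CO2_ex_h"), name = "external CO2 (chloroplast)",
                   compartment = "h", carbon = 1)

  # the interface CO2 transporter delivers into the external pool only
  two_cell <- set_stoichiometry(
    two_cell, "[MB]_CO2",
    setNames(c(-1, 1), c(M("CO2_c"), B("CO2_ex_c")))
  )

  two_cell <- two_cell %>%
    add_reaction(B("Tr_CO2h_Ex"),
                 setNames(c(-1, 1), c(B("CO2_ex_c"), B("CO2_ex_h"))),
                 lower = 0, upper = INF_PROXY,
                 name = "external CO2 uptake into chloroplast",
                 subsystem = "intracellular transport") %>%
    add_reaction(B("RBC_h_Ex"),
                 setNames(c(-1, -1, 2),
                          c(B("RuBP_h"), B("CO2_ex_h"), B("PGA_h"))),
                 lower = 0, upper = INF_PROXY,
                 name = "native Rubisco carboxylase (external CO2)",
                 subsystem = "Calvin cycle")

  # the native population's ratio constraint follows its carboxylation
  rc <- two_cell$ratio_constraints
  hit <- (rc$reaction_a == B("RBO_h") & rc$reaction_b == B("RBC_h")) |
    (rc$reaction_b == B("RBO_h") & rc$reaction_a == B("RBC_h"))
  rc$reaction_a[hit & rc$reaction_a == B("RBC_h")] <- B("RBC_h_Ex")
  rc$reaction_b[hit & rc$reaction_b == B("RBC_h")] <- B("RBC_h_Ex")
  two_cell$ratio_constraints <- rc

  two_cell$annotations$rubisco <- list(
    m_rbc = M("RBC_h"), m_rbo = M("RBO_h"),
    b_rbc_native = B("RBC_h_Ex"), b_rbo = B("RBO_h"),
    b_rbc_ccm = B("RBC_h")
  )
  two_cell
}

#' Set the two-cell uptake bounds and photon budget
#'
#' Mesophyll CO2 uptake is capped at `co2_m` (the two-cell default is 40
#' umol/(m^2 s)); bundle-sheath CO2 import is closed, so environmental
#' carbon must be bridged by the mesophyll. The total photon uptake of both
#' cells is budgeted by a coupling constraint, with either the
#' bundle-sheath-no-larger-than-mesophyll ordering (default) or a fixed
#' bundle-sheath : mesophyll split for light-distribution grids.
#'
#' @param two_cell a composed two-cell model.
#' @param co2_m mesophyll CO2 uptake cap.
#' @param ppfd_total total photon budget for both cells.
#' @param ppfd_ratio optional fixed ratio photon(B)/photon(M); releases the
#'   ordering constraint (grids explore ratios up to 2).
#' @param ppfd_fixed force total photon uptake equal to `ppfd_total` instead
#'   of at most `ppfd_total` (used by the light grid, where excess photons
#'   must be dissipated).
#' @param enforce_ordering keep the B <= M photon ordering; an error is
#'   raised if a ratio above 1 is requested while the ordering is enforced.
#' @return The model with bounds and couplings installed.
#' @export
set_two_cell_bounds <- function(two_cell, co2_m = 40, ppfd_total = 1000,
                                ppfd_ratio = NULL, ppfd_fixed = FALSE,
                                enforce_ordering = is.null(ppfd_ratio)) {
  stopifnot(is.finite(co2_m), is.finite(ppfd_total), co2_m >= 0,
            ppfd_total >= 0)
  pf <- cell_prefixes(two_cell)
  m_hnu <- paste0(pf[1], "_Im_hnu")
  b_hnu <- paste0(pf[2], "_Im_hnu")
  two_cell <- two_cell %>%
    set_bounds(paste0(pf[1], "_Im_CO2"), lower = 0, upper = co2_m) %>%
    set_bounds(paste0(pf[2], "_Im_CO2"), lower = 0, upper = 0) %>%
    add_coupling("ppfd:total", setNames(c(1, 1), c(m_hnu, b_hnu)),
                 lower = if (ppfd_fixed) ppfd_total else 0,
                 upper = ppfd_total)
  if (!is.null(ppfd_ratio)) {
    if (ppfd_ratio < 0) abort("ppfd_ratio must be non-negative")
    if (ppfd_ratio > 1 && enforce_ordering) {
      abort("ppfd_ratio > 1 conflicts with the B <= M ordering; release it")
    }
    two_cell <- two_cell %>%
      remove_coupling("ppfd:ordering") %>%
      add_coupling("ppfd:split", setNames(c(1, -ppfd_ratio), c(b_hnu, m_hnu)),
                   lower = 0, upper = 0)
  } else if (enforce_ordering) {
    two_cell <- two_cell %>%
      remove_coupling("ppfd:split") %>%
      add_coupling("ppfd:ordering", setNames(c(1, -1), c(b_hnu, m_hnu)),
                   lower = -Inf, upper = 0)
  }
  two_cell
}

#' Re-pin the photorespiration ratio of both native Rubisco populations
#'
#' Removes every existing photorespiration ratio constraint and installs the
#' given oxygenation : carboxylation ratio on the mesophyll native pair and
#' on the bundle-sheath native pair (the external-CO2 carboxylation). The
#' CCM-dependent population never receives a constraint.
#'
#' @param two_cell a composed two-cell model with the Rubisco registry.
#' @param ratio oxygenation : carboxylation ratio.
#' @return The model with the ratio installed.
#' @export
set_two_cell_photorespiration <- function(two_cell, ratio) {
  reg <- two_cell$annotations$rubisco
  if (is.null(reg)) {
    abort("model has no Rubisco registry (run install_ccm_rubisco() first)")
  }
  two_cell$ratio_constraints <- filter(
    two_cell$ratio_constraints,
    !grepl("photorespiration", .data$id)
  )
  two_cell %>%
    fix_photorespiration(ratio, reg$m_rbo, reg$m_rbc) %>%
    fix_photorespiration(ratio, reg$b_rbo, reg$b_rbc_native)
}

#' Assemble the ready-to-solve two-cell model
#'
#' Duplicates the one-cell model into mesophyll/bundle-sheath copies, links
#' the cytosols through the interface transporters, installs the dual
#' Rubisco population, sets the two-cell uptake bounds and photon budget,
#' points the objective at the bundle-sheath phloem output and pins the
#' photorespiration ratio of both native populations.
#'
#' @param one_cell a composed one-cell model (see [compose_one_cell()]).
#' @param interface a [cell_interface_spec()].
#' @param photorespiration oxygenation : carboxylation ratio for the native
#'   populations (the stressed two-cell condition is 1/3).
#' @param co2_m,ppfd_total see [set_two_cell_bounds()].
#' @return A solvable two-cell `metabolic_model`.
#' @export
compose_two_cell <- function(one_cell = compose_one_cell(),
                             interface = cell_interface_spec(),
                             photorespiration = 1 / 3,
                             co2_m = 40, ppfd_total = 1000) {
  two <- one_cell %>%
    duplicate_cells() %>%
    link_cells(interface) %>%
    install_ccm_rubisco() %>%
    set_two_cell_bounds(co2_m = co2_m, ppfd_total = ppfd_total)
  pf <- cell_prefixes(two)
  two <- set_objective(two, setNames(c(1, 1), paste0(pf[2], c("_Ex_Suc", "_Ex_AA"))),
                       "max")
  set_two_cell_photorespiration(two, photorespiration)
}
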