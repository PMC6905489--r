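#' Compartmented stoichiometric model
#'
#' The central container of the package: a metabolic network with metabolite
#' and reaction tables, a sparse stoichiometry triplet, flux bounds, an
#' objective, flux-ratio constraints and general linear coupling constraints.
#' All tables are tibbles so that model contents compose naturally with dplyr
#' verbs; the model itself is a list-of-tibbles with class
#' `metabolic_model`.
#'
#' Fluxes are expressed throughout in umol/(m^2 s). Unbounded fluxes are
#' approximated by a large finite proxy (default `1e6`), following the
#' convention of the boundary table the leaf models use.
#'
#' @param metabolites tibble with columns `id`, `name`, `compartment`,
#'   `carbon`, `nitrogen` (element counts per molecule; fractional values are
#'   allowed for lumped species such as a mean amino acid with 5.5 carbons).
#' @param reactions tibble with columns `id`, `name`, `lower`, `upper`,
#'   `subsystem`.
#' @param stoich tibble with columns `reaction`, `metabolite`, `coef`
#'   (signed stoichiometric coefficients; negative = consumed).
#' @param objective tibble with columns `reaction`, `weight`.
#' @param objective_direction `"max"` or `"min"`.
#' @param ratio_constraints tibble with columns `id`, `reaction_a`,
#'   `reaction_b`, `ratio`, each enforcing `v_a = ratio * v_b`.
#' @param couplings tibble with columns `id`, `reactions` (list of character),
#'   `coefs` (list of numeric), `lower`, `upper`: general linear constraints
#'   `lower <= sum(coefs * v[reactions]) <= upper`.
#' @param compartments character vector of compartment codes (e.g.
#'   `c("c", "h", "m", "p")`).
#' @param annotations named list of free-form metadata.
#'
#' @return An object of class `metabolic_model`.
#' @export
metabolic_model <- function(metabolites = empty_metabolites(),
                            reactions = empty_reactions(),
                            stoich = empty_stoich(),
                            objective = empty_objective(),
                            objective_direction = "max",
                            ratio_constraints = empty_ratio_constraints(),
                            couplings = empty_couplings(),
                            compartments = character(),
                            annotations = list()) {
  model <- structure(
    list(
      metabolites = as_tibble(metabolites),
      reactions = as_tibble(reactions),
      stoich = as_tibble(stoich),
      objective = as_tibble(objective),
      objective_direction = match.arg(objective_direction, c("max", "min")),
      ratio_constraints = as_tibble(ratio_constraints),
      couplings = as_tibble(couplings),
      compartments = compartments,
      annotations = annotations
    ),
    class = "metabolic_model"
  )
  validate_model(model)
  model
}

empty_metabolites <- function() {
  tibble(id = character(), name = character(), compartment = character(),
         carbon = numeric(), nitrogen = numeric())
}
empty_reactions <- function() {
  tibble(id = character(), name = character(), lower = numeric(),
         upper = numeric(), subsystem = character())
}
empty_stoich <- function() {
  tibble(reaction = character(), metabolite = character(), coef = numeric())
}
empty_objective <- function() tibble(reaction = character(), weight = numeric())
empty_ratio_constraints <- function() {
  tibble(id = character(), reaction_a = character(), reaction_b = character(),
         ratio = numeric())
}
empty_couplings <- function() {
  tibble(id = character(), reactions = list(), coefs = list(),
         lower = numeric(), upper = numeric())
}

#' Validate a metabolic model's structural invariants
#'
#' Checks identifier uniqueness, compartment membership, bound ordering,
#' stoichiometric references and ratio-constraint references. Called by the
#' constructor and by the model-mutating operations.
#'
#' @param model a `metabolic_model`.
#' @return The model, invisibly; errors describe the violated invariant.
#' @export
validate_model <- function(model) {
  met <- model$metabolites
  rxn <- model$reactions
  if (anyDuplicated(met$id)) {
    abort(paste0("duplicated metabolite id(s): ",
                 paste(unique(met$id[duplicated(met$id)]), collapse = ", ")))
  }
  if (anyDuplicated(rxn$id)) {
    abort(paste0("duplicated reaction id(s): ",
                 paste(unique(rxn$id[duplicated(rxn$id)]), collapse = ", ")))
  }
  if (length(model$compartments) > 0 && nrow(met) > 0) {
    bad <- setdiff(unique(met$compartment), model$compartments)
    if (length(bad) > 0) {
      abort(paste0("metabolite compartment(s) outside the declared set: ",
                   paste(bad, collapse = ", ")))
    }
  }
  if (nrow(rxn) > 0 && any(rxn$lower > rxn$upper)) {
    bad <- rxn$id[rxn$lower > rxn$upper]
    abort(paste0("lower bound exceeds upper bound for: ",
                 paste(bad, collapse = ", ")))
  }
  if (nrow(model$stoich) > 0) {
    bad <- setdiff(unique(model$stoich$metabolite), met$id)
    if (length(bad) > 0) {
      abort(paste0("stoichiometry references unknown metabolite(s): ",
                   paste(bad, collapse = ", ")))
    }
    bad <- setdiff(unique(model$stoich$reaction), rxn$id)
    if (length(bad) > 0) {
      abort(paste0("stoichiometry references unknown reaction(s): ",
                   paste(bad, collapse = ", ")))
    }
  }
  for (tb in list(model$objective["reaction"],
                  model$ratio_constraints[c("reaction_a", "reaction_b")])) {
    ids <- unlist(tb, use.names = FALSE)
    bad <- setdiff(ids, rxn$id)
    if (length(bad) > 0) {
      abort(paste0("constraint/objective references unknown reaction(s): ",
                   paste(bad, collapse = ", ")))
    }
  }
  if (nrow(model$ratio_constraints) > 0) {
    r <- model$ratio_constraints$ratio
    if (any(!is.finite(r)) || any(r < 0)) {
      abort("ratio constraints must have finite, non-negative ratios")
    }
  }
  if (nrow(model$couplings) > 0) {
    bad <- setdiff(unlist(model$couplings$reactions), rxn$id)
    if (length(bad) > 0) {
      abort(paste0("coupling references unknown reaction(s): ",
                   paste(bad, collapse = ", ")))
    }
  }
  invisible(model)
}

#' @export
print.metabolic_model <- function(x, ...) {
  cat("<metabolic_model>",
      nrow(x$metabolites), "metabolites,",
      nrow(x$reactions), "reactions,",
      length(x$compartments), "compartments\n")
  if (nrow(x$ratio_constraints) > 0) {
    cat("  ratio constraints:", nrow(x$ratio_constraints), "\n")
  }
  if (nrow(x$couplings) > 0) {
    cat("  coupling constraints:", nrow(x$couplings), "\n")
  }
  if (nrow(x$objective) > 0) {
    cat("  objective (", x$objective_direction, "): ",
        paste(x$objective$reaction, collapse = " + "), "\n", sep = "")
  }
  invisible(x)
}

# ---- element access helpers -------------------------------------------------

rxn_index <- function(model, ids) {
  idx <- match(ids, model$reactions$id)
  if (anyNA(idx)) {
    abort(paste0("unknown reaction(s): ", paste(ids[is.na(idx)], collapse = ", ")))
  }
  idx
}

met_index <- function(model, ids) {
  idx <- match(ids, model$metabolites$id)
  if (anyNA(idx)) {
    abort(paste0("unknown metabolite(s): ", paste(ids[is.na(idx)], collapse = ", ")))
  }
  idx
}

#' Dense stoichiometric matrix
#'
#' @param model a `metabolic_model`.
#' @return A numeric matrix with one row per metabolite and one column per
#'   reaction, dimnames set to the respective ids.
#' @export
stoichiometric_matrix <- function(model) {
  S <- matrix(0, nrow(model$metabolites), nrow(model$reactions),
              dimnames = list(model$metabolites$id, model$reactions$id))
  if (nrow(model$stoich) > 0) {
    S[cbind(match(model$stoich$metabolite, model$metabolites$id),
            match(model$stoich$reaction, model$reactions$id))] <- model$stoich$coef
  }
  S
}

# ---- model mutation helpers -------------------------------------------------

#' Add a metabolite to a model
#'
#' @param model a `metabolic_model`.
#' @param id,name,compartment,carbon,nitrogen metabolite fields.
#' @return The modified model.
#' @export
add_metabolite <- function(model, id, name = id, compartment, carbon = 0,
                           nitrogen = 0) {
  if (id %in% model$metabolites$id) {
    abort(paste0("metabolite already exists: ", id))
  }
  model$metabolites <- bind_rows(
    model$metabolites,
    tibble(id = id, name = name, compartment = compartment,
           carbon = carbon, nitrogen = nitrogen)
  )
  if (!compartment %in% model$compartments) {
    model$compartments <- c(model$compartments, compartment)
  }
  model
}

#' Add a reaction to a model
#'
#' @param model a `metabolic_model`.
#' @param id reaction identifier, unique within the model.
#' @param stoich named numeric vector of signed coefficients keyed by
#'   metabolite id (negative = consumed).
#' @param lower,upper flux bounds in umol/(m^2 s).
#' @param name,subsystem descriptive fields.
#' @return The modified model.
#' @export
add_reaction <- function(model, id, stoich, lower = 0, upper = INF_PROXY,
                         name = id, subsystem = "") {
  if (id %in% model$reactions$id) {
    abort(paste0("reaction already exists: ", id))
  }
  if (length(stoich) == 0) {
    abort(paste0("reaction must have at least one stoichiometric coefficient: ", id))
  }
  if (lower > upper) {
    abort(paste0("lower bound exceeds upper bound for: ", id))
  }
  met_index(model, names(stoich))
  model$reactions <- bind_rows(
    model$reactions,
    tibble(id = id, name = name, lower = lower, upper = upper,
           subsystem = subsystem)
  )
  model$stoich <- bind_rows(
    model$stoich,
    tibble(reaction = id, metabolite = names(stoich),
           coef = unname(as.numeric(stoich)))
  )
  model
}

#' Remove reactions from a model
#'
#' Also removes any objective terms, ratio constraints and couplings that
#' reference the removed reactions.
#'
#' @param model a `metabolic_model`.
#' @param ids reaction ids to drop.
#' @return The modified model.
#' @export
remove_reaction <- function(model, ids) {
  rxn_index(model, ids)
  model$reactions <- filter(model$reactions, !.data$id %in% ids)
  model$stoich <- filter(model$stoich, !.data$reaction %in% ids)
  model$objective <- filter(model$objective, !.data$reaction %in% ids)
  model$ratio_constraints <- filter(model$ratio_constraints,
                                    !.data$reaction_a %in% ids,
                                    !.data$reaction_b %in% ids)
  if (nrow(model$couplings) > 0) {
    hit <- map_dbl(model$couplings$reactions, ~ sum(.x %in% ids)) > 0
    model$couplings <- model$couplings[!hit, ]
  }
  model
}

#' Set flux bounds on one or more reactions
#'
#' @param model a `metabolic_model`.
#' @param ids reaction ids.
#' @param lower,upper new bounds, recycled along `ids`; `NA` keeps the
#'   current value.
#' @return The modified model.
#' @export
set_bounds <- function(model, ids, lower = NA, upper = NA) {
  idx <- rxn_index(model, ids)
  lower <- rep_len(lower, length(ids))
  upper <- rep_len(upper, length(ids))
  lo <- ifelse(is.na(lower), model$reactions$lower[idx], lower)
  up <- ifelse(is.na(upper), model$reactions$upper[idx], upper)
  if (any(lo > up)) {
    abort(paste0("lower bound exceeds upper bound for: ",
                 paste(ids[lo > up], collapse = ", ")))
  }
  model$reactions$lower[idx] <- lo
  model$reactions$upper[idx] <- up
  model
}

#' Replace the stoichiometry of a reaction
#'
#' @param model a `metabolic_model`.
#' @param id reaction id.
#' @param stoich named numeric vector of new signed coefficients.
#' @return The modified model.
#' @export
set_stoichiometry <- function(model, id, stoich) {
  rxn_index(model, id)
  met_index(model, names(stoich))
  model$stoich <- bind_rows(
    filter(model$stoich, .data$reaction != id),
    tibble(reaction = id, metabolite = names(stoich),
           coef = unname(as.numeric(stoich)))
  )
  model
}

#' Set the model objective
#'
#' @param model a `metabolic_model`.
#' @param terms named numeric vector of objective weights keyed by reaction id.
#' @param direction `"max"` or `"min"`.
#' @return The modified model.
#' @export
set_objective <- function(model, terms, direction = "max") {
  rxn_index(model, names(terms))
  model$objective <- tibble(reaction = names(terms),
                            weight = unname(as.numeric(terms)))
  model$objective_direction <- match.arg(direction, c("max", "min"))
  model
}

#' Look up fluxes or bounds for reactions
#'
#' @param model a `metabolic_model`.
#' @param ids reaction ids (default: all).
#' @return Tibble of reaction rows.
#' @export
reaction_info <- function(model, ids = NULL) {
  if (is.null(ids)) return(model$reactions)
  model$reactions[rxn_index(model, ids), ]
}

#' Stoichiometry of one reaction as a named vector
#'
#' @param model a `metabolic_model`.
#' @param id reaction id.
#' @return Named numeric vector of signed coefficients.
#' @export
reaction_stoich <- function(model, id) {
  rxn_index(model, id)
  rows <- filter(model$stoich, .data$reaction == id)
  setNames(rows$coef, rows$metabolite)
}

# Reactions touching a single metabolite: boundary exchanges, sinks, sources.
exchange_ids <- function(model) {
  counts <- table(model$stoich$reaction)
  names(counts)[counts == 1]
}
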