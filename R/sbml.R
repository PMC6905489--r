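NS_SBML <- "http://www.sbml.org/sbml/level3/version1/core"
NS_FBC <- "http://www.sbml.org/sbml/level3/version1/fbc/version2"
NS_CF <- "https://c4flux.r-lib.org/annotations"

# SBML SIds are [A-Za-z_][A-Za-z0-9_]*; cell prefixes like "[M]_" are not.
# The true id is carried in a cf:id attribute and restored on read.
sanitize_sid <- function(id) {
  out <- gsub("[^A-Za-z0-9_]", "", id)
  bad <- !grepl("^[A-Za-z_]", out)
  out[bad] <- paste0("x", out[bad])
  # disambiguate collisions introduced by sanitizing
  make.unique(out, sep = "_dup")
}

fmt_num <- function(x) formatC(x, format = "g", digits = 17)

#' Write a model as SBML Level 3 with the flux-balance package
#'
#' Species, compartments, reactions, bounds (as FBC bound parameters) and the
#' active objective are written as standard SBML + FBC. Package-specific
#' state that SBML has no construct for — element counts of lumped species,
#' subsystems, ratio and coupling constraints, and the annotation list
#' (cell-prefix metadata, Rubisco registry, interface spec) — is carried in a
#' documented annotation block under the `cf` namespace, so
#' `read_sbml(write_sbml(m))` reproduces the model up to ordering.
#'
#' @param model a `metabolic_model`; validated before writing.
#' @param path file to write.
#' @return `path`, invisibly.
#' @export
write_sbml <- function(model, path) {
  validate_model(model)
  sid_met <- setNames(sanitize_sid(model$metabolites$id), model$metabolites$id)
  sid_rxn <- setNames(sanitize_sid(model$reactions$id), model$reactions$id)

  doc <- xml2::xml_new_root(
    "sbml",
    xmlns = NS_SBML, "xmlns:fbc" = NS_FBC, "xmlns:cf" = NS_CF,
    level = "3", version = "1", "fbc:required" = "false"
  )
  mdl <- xml2::xml_add_child(doc, "model", id = "leaf_model",
                             "fbc:strict" = "true")

  cmps <- xml2::xml_add_child(mdl, "listOfCompartments")
  for (cmp in model$compartments) {
    xml2::xml_add_child(cmps, "compartment", id = cmp, constant = "true")
  }

  if (nrow(model$metabolites) > 0) {
    sps <- xml2::xml_add_child(mdl, "listOfSpecies")
    for (i in seq_len(nrow(model$metabolites))) {
      m <- model$metabolites[i, ]
      xml2::xml_add_child(
        sps, "species", id = sid_met[[m$id]], name = m$name,
        compartment = m$compartment, hasOnlySubstanceUnits = "false",
        boundaryCondition = "false", constant = "false",
        "cf:id" = m$id, "cf:carbon" = fmt_num(m$carbon),
        "cf:nitrogen" = fmt_num(m$nitrogen)
      )
    }
  }

  # one shared parameter per distinct bound value, cobra-style
  bnd_vals <- sort(unique(c(model$reactions$lower, model$reactions$upper)))
  bnd_ids <- setNames(paste0("bnd_", seq_along(bnd_vals)), fmt_num(bnd_vals))
  if (length(bnd_vals) > 0) {
    prs <- xml2::xml_add_child(mdl, "listOfParameters")
    for (i in seq_along(bnd_vals)) {
      xml2::xml_add_child(prs, "parameter", id = unname(bnd_ids[i]),
                          value = fmt_num(bnd_vals[i]), constant = "true",
                          "sboTerm" = "SBO:0000625")
    }
  }

  if (nrow(model$reactions) > 0) {
    rxs <- xml2::xml_add_child(mdl, "listOfReactions")
    for (i in seq_len(nrow(model$reactions))) {
      r <- model$reactions[i, ]
      rx <- xml2::xml_add_child(
        rxs, "reaction", id = sid_rxn[[r$id]], name = r$name,
        reversible = if (r$lower < 0) "true" else "false", fast = "false",
        "fbc:lowerFluxBound" = unname(bnd_ids[fmt_num(r$lower)]),
        "fbc:upperFluxBound" = unname(bnd_ids[fmt_num(r$upper)]),
        "cf:id" = r$id, "cf:subsystem" = r$subsystem
      )
      st <- filter(model$stoich, .data$reaction == r$id)
      reac <- filter(st, .data$coef < 0)
      prod <- filter(st, .data$coef > 0)
      if (nrow(reac) > 0) {
        lr <- xml2::xml_add_child(rx, "listOfReactants")
        for (j in seq_len(nrow(reac))) {
          xml2::xml_add_child(lr, "speciesReference",
                              species = sid_met[[reac$metabolite[j]]],
                              stoichiometry = fmt_num(-reac$coef[j]),
                              constant = "true")
        }
      }
      if (nrow(prod) > 0) {
        lp <- xml2::xml_add_child(rx, "listOfProducts")
        for (j in seq_len(nrow(prod))) {
          xml2::xml_add_child(lp, "speciesReference",
                              species = sid_met[[prod$metabolite[j]]],
                              stoichiometry = fmt_num(prod$coef[j]),
                              constant = "true")
        }
      }
    }
  }

  if (nrow(model$objective) > 0) {
    lo <- xml2::xml_add_child(mdl, "fbc:listOfObjectives",
                              "fbc:activeObjective" = "obj")
    ob <- xml2::xml_add_child(
      lo, "fbc:objective", "fbc:id" = "obj",
      "fbc:type" = if (model$objective_direction == "max") "maximize" else "minimize"
    )
    lfo <- xml2::xml_add_child(ob, "fbc:listOfFluxObjectives")
    for (i in seq_len(nrow(model$objective))) {
      xml2::xml_add_child(lfo, "fbc:fluxObjective",
                          "fbc:reaction" = sid_rxn[[model$objective$reaction[i]]],
                          "fbc:coefficient" = fmt_num(model$objective$weight[i]))
    }
  }

  ann <- xml2::xml_add_child(mdl, "annotation")
  cfc <- xml2::xml_add_child(ann, "cf:constraints")
  if (nrow(model$ratio_constraints) > 0) {
    for (i in seq_len(nrow(model$ratio_constraints))) {
      rc <- model$ratio_constraints[i, ]
      xml2::xml_add_child(cfc, "cf:ratioConstraint", "cf:cid" = rc$id,
                          "cf:a" = rc$reaction_a, "cf:b" = rc$reaction_b,
                          "cf:ratio" = fmt_num(rc$ratio))
    }
  }
  if (nrow(model$couplings) > 0) {
    for (i in seq_len(nrow(model$couplings))) {
      cp <- model$couplings[i, ]
      nd <- xml2::xml_add_child(cfc, "cf:coupling", "cf:cid" = cp$id,
                                "cf:lower" = fmt_num(cp$lower),
                                "cf:upper" = fmt_num(cp$upper))
      for (j in seq_along(cp$reactions[[1]])) {
        xml2::xml_add_child(nd, "cf:term",
                            "cf:reaction" = cp$reactions[[1]][j],
                            "cf:coef" = fmt_num(cp$coefs[[1]][j]))
      }
    }
  }
  if (length(model$annotations) > 0) {
    meta <- xml2::xml_add_child(ann, "cf:meta")
    xml2::xml_set_text(meta, jsonlite::toJSON(model$annotations,
                                              auto_unbox = TRUE, digits = NA))
  }

  xml2::write_xml(doc, path)
  invisible(path)
}

#' Read a model from SBML Level 3 + FBC
#'
#' Loads compartments, species, reactions with bounds, the active objective
#' and any package annotation block written by [write_sbml()]. Counts of
#' loaded components are reported via a message; a model without an FBC
#' objective is loaded with an empty objective and a warning.
#'
#' @param path SBML file.
#' @param quiet suppress the component-count message.
#' @return A `metabolic_model`.
#' @export
read_sbml <- function(path, quiet = FALSE) {
  doc <- tryCatch(xml2::read_xml(path), error = function(e) {
    abort(paste0("cannot parse SBML document '", path, "': ",
                 conditionMessage(e)))
  })
  ns <- c(s = NS_SBML, fbc = NS_FBC, cf = NS_CF)
  mdl <- xml2::xml_find_first(doc, ".//s:model", ns)
  if (inherits(mdl, "xml_missing")) {
    abort("malformed SBML: no <model> element found")
  }
  attr_or <- function(node, name, default = NA_character_) {
    v <- xml2::xml_attr(node, name, ns = ns)
    ifelse(is.na(v), default, v)
  }

  comp_nodes <- xml2::xml_find_all(mdl, ".//s:listOfCompartments/s:compartment", ns)
  compartments <- xml2::xml_attr(comp_nodes, "id")

  sp_nodes <- xml2::xml_find_all(mdl, ".//s:listOfSpecies/s:species", ns)
  sid <- xml2::xml_attr(sp_nodes, "id")
  true_id <- attr_or(sp_nodes, "cf:id", NA)
  met_id <- ifelse(is.na(true_id), sid, true_id)
  metabolites <- tibble(
    id = met_id,
    name = ifelse(is.na(xml2::xml_attr(sp_nodes, "name")), met_id,
                  xml2::xml_attr(sp_nodes, "name")),
    compartment = xml2::xml_attr(sp_nodes, "compartment"),
    carbon = as.numeric(attr_or(sp_nodes, "cf:carbon", NA)),
    nitrogen = as.numeric(attr_or(sp_nodes, "cf:nitrogen", NA))
  )
  sid_to_id <- setNames(met_id, sid)

  par_nodes <- xml2::xml_find_all(mdl, ".//s:listOfParameters/s:parameter", ns)
  par_val <- setNames(as.numeric(xml2::xml_attr(par_nodes, "value")),
                      xml2::xml_attr(par_nodes, "id"))

  rx_nodes <- xml2::xml_find_all(mdl, ".//s:listOfReactions/s:reaction", ns)
  rsid <- xml2::xml_attr(rx_nodes, "id")
  rtrue <- attr_or(rx_nodes, "cf:id", NA)
  rxn_id <- ifelse(is.na(rtrue), rsid, rtrue)
  rsid_to_id <- setNames(rxn_id, rsid)

  lb_ref <- xml2::xml_attr(rx_nodes, "fbc:lowerFluxBound", ns = ns)
  ub_ref <- xml2::xml_attr(rx_nodes, "fbc:upperFluxBound", ns = ns)
  no_bounds <- is.na(lb_ref) | is.na(ub_ref)
  if (any(no_bounds)) {
    abort(paste0("reaction(s) without flux bounds: ",
                 paste(rxn_id[no_bounds], collapse = ", ")))
  }
  reactions <- tibble(
    id = rxn_id,
    name = ifelse(is.na(xml2::xml_attr(rx_nodes, "name")), rxn_id,
                  xml2::xml_attr(rx_nodes, "name")),
    lower = unname(par_val[lb_ref]),
    upper = unname(par_val[ub_ref]),
    subsystem = attr_or(rx_nodes, "cf:subsystem", "")
  )
  if (anyNA(reactions$lower) || anyNA(reactions$upper)) {
    bad <- rxn_id[is.na(reactions$lower) | is.na(reactions$upper)]
    abort(paste0("flux-bound parameter missing for reaction(s): ",
                 paste(bad, collapse = ", ")))
  }

  stoich_rows <- map(seq_along(rx_nodes), function(i) {
    node <- rx_nodes[[i]]
    grab <- function(xpath, sign) {
      refs <- xml2::xml_find_all(node, xpath, ns)
      if (length(refs) == 0) return(NULL)
      sp <- xml2::xml_attr(refs, "species")
      unknown <- setdiff(sp, names(sid_to_id))
      if (length(unknown) > 0) {
        abort(paste0("reaction '", rxn_id[i],
                     "' references undeclared species: ",
                     paste(unknown, collapse = ", ")))
      }
      tibble(reaction = rxn_id[i], metabolite = unname(sid_to_id[sp]),
             coef = sign * as.numeric(xml2::xml_attr(refs, "stoichiometry")))
    }
    bind_rows(grab(".//s:listOfReactants/s:speciesReference", -1),
              grab(".//s:listOfProducts/s:speciesReference", 1))
  })
  stoich <- bind_rows(stoich_rows)
  if (nrow(stoich) == 0) stoich <- empty_stoich()

  obj_nodes <- xml2::xml_find_all(
    mdl, ".//fbc:listOfObjectives/fbc:objective/fbc:listOfFluxObjectives/fbc:fluxObjective", ns)
  if (length(obj_nodes) == 0) {
    warn("SBML document declares no flux objective; loading with an empty objective")
    objective <- empty_objective()
    objective_direction <- "max"
  } else {
    obj_parent <- xml2::xml_find_first(mdl, ".//fbc:listOfObjectives/fbc:objective", ns)
    objective <- tibble(
      reaction = unname(rsid_to_id[xml2::xml_attr(obj_nodes, "fbc:reaction", ns = ns)]),
      weight = as.numeric(xml2::xml_attr(obj_nodes, "fbc:coefficient", ns = ns))
    )
    objective_direction <- if (identical(xml2::xml_attr(obj_parent, "fbc:type", ns = ns),
                                         "minimize")) "min" else "max"
  }

  rc_nodes <- xml2::xml_find_all(mdl, ".//cf:constraints/cf:ratioConstraint", ns)
  ratio_constraints <- if (length(rc_nodes) == 0) empty_ratio_constraints() else
    tibble(id = xml2::xml_attr(rc_nodes, "cf:cid", ns = ns),
           reaction_a = xml2::xml_attr(rc_nodes, "cf:a", ns = ns),
           reaction_b = xml2::xml_attr(rc_nodes, "cf:b", ns = ns),
           ratio = as.numeric(xml2::xml_attr(rc_nodes, "cf:ratio", ns = ns)))

  cp_nodes <- xml2::xml_find_all(mdl, ".//cf:constraints/cf:coupling", ns)
  couplings <- if (length(cp_nodes) == 0) empty_couplings() else
    bind_rows(map(cp_nodes, function(nd) {
      terms <- xml2::xml_find_all(nd, ".//cf:term", ns)
      tibble(id = xml2::xml_attr(nd, "cf:cid", ns = ns),
             reactions = list(xml2::xml_attr(terms, "cf:reaction", ns = ns)),
             coefs = list(as.numeric(xml2::xml_attr(terms, "cf:coef", ns = ns))),
             lower = as.numeric(xml2::xml_attr(nd, "cf:lower", ns = ns)),
             upper = as.numeric(xml2::xml_attr(nd, "cf:upper", ns = ns)))
    }))

  meta_node <- xml2::xml_find_first(mdl, ".//cf:meta", ns)
  annotations <- if (inherits(meta_node, "xml_missing")) list() else
    jsonlite::fromJSON(xml2::xml_text(meta_node), simplifyVector = TRUE,
                       simplifyDataFrame = FALSE, simplifyMatrix = FALSE)

  model <- metabolic_model(
    metabolites = metabolites, reactions = reactions, stoich = stoich,
    objective = objective, objective_direction = objective_direction,
    ratio_constraints = ratio_constraints, couplings = couplings,
    compartments = compartments, annotations = annotations
  )
  if (!quiet) {
    inform(paste0("loaded ", nrow(metabolites), " metabolites, ",
                  nrow(reactions), " reactions, ",
                  length(compartments), " compartments"))
  }
  model
}
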