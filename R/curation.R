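#' Construct a curation action
#'
#' Curation is data, not code: each action is a row with a `kind` drawn from
#' `add_reaction`, `remove_reaction`, `set_bounds`, `swap_cofactor`,
#' `set_stoichiometry`, `add_transport`, `fix_zero_flux`, and a kind-specific
#' `payload`. Action lists are auditable and replayable on any input model
#' via [apply_curation()].
#'
#' @param kind action kind.
#' @param note free-text provenance/observation note.
#' @param ... payload fields for the kind.
#' @return One-row tibble with columns `kind`, `payload`, `note`.
#' @export
curation_action <- function(kind, ..., note = "") {
  kind <- match.arg(kind, c("add_reaction", "remove_reaction", "set_bounds",
                            "swap_cofactor", "set_stoichiometry",
                            "add_transport", "fix_zero_flux"))
  tibble(kind = kind, payload = list(list(...)), note = note)
}

#' The packaged default curation set
#'
#' Encodes, against the reduced leaf network's id scheme, the corrections
#' that turn the pre-curation core into the curated one-cell state:
#' cofactor swaps making the extra-chloroplast malate dehydrogenases
#' NAD-dependent, addition of cyclic electron flow, alternative oxidases,
#' cytosolic/chloroplastic/mitochondrial alanine aminotransferases and the
#' dicarboxylate/ATP carrier transport reactions, H+/ATP stoichiometry fixes
#' (3:1 chloroplast, 4:1 mitochondria), unidirectionality of every
#' decarboxylase, proton sink/source reactions per compartment, and
#' zero-flux caps for the chloroplastic NADP dehydrogenase, the plastoquinol
#' oxidase and the chloroplastic ADP/ATP carrier.
#'
#' @param config the [fixture_config()] whose stoichiometric knobs (H+/ATP
#'   ratios) the fixes should target.
#' @return Tibble of curation actions.
#' @export
default_curation <- function(config = fixture_config()) {
  defs <- fixture_reactions(config)
  by_id <- setNames(defs, map_chr(defs, "id"))
  act <- list()

  for (id in c("MDH_c", "MDH_m", "MDH_p")) {
    act <- c(act, list(curation_action(
      "swap_cofactor", reaction = id, from = "NADP", to = "NAD",
      note = "NAD-dependent malate dehydrogenase outside the chloroplast"
    )))
  }

  added <- keep(defs, ~ isTRUE(.x$curation))
  for (d in added) {
    kind <- if (startsWith(d$id, "Tr_")) "add_transport" else "add_reaction"
    act <- c(act, list(curation_action(
      kind, id = d$id, stoich = d$stoich, lower = d$lower, upper = d$upper,
      name = d$name, subsystem = d$subsystem,
      note = paste0("added: ", d$name)
    )))
  }

  act <- c(act, list(
    curation_action("set_stoichiometry", reaction = "ATPSyn_h",
                    stoich = by_id$ATPSyn_h$stoich,
                    note = "H+/ATP ratio 3:1 (chloroplast)"),
    curation_action("set_stoichiometry", reaction = "ATPSyn_m",
                    stoich = by_id$ATPSyn_m$stoich,
                    note = "H+/ATP ratio 4:1 (mitochondria)")
  ))

  for (id in c("NADPME_h", "NADME_m", "PEPCK_c", "PDH_m", "IDH_m",
               "AKGDH_m", "GDC_m")) {
    act <- c(act, list(curation_action(
      "set_bounds", reaction = id, lower = 0, upper = NA,
      note = "decarboxylation made unidirectional towards decarboxylation"
    )))
  }

  for (cmp in c("c", "h", "m", "p")) {
    act <- c(act, list(curation_action(
      "add_reaction", id = paste0("Sink_H_", cmp),
      stoich = setNames(1, paste0("H_", cmp)),
      lower = -INF_PROXY, upper = INF_PROXY,
      name = paste0("proton sink/source (", cmp, ")"),
      subsystem = "proton buffer",
      note = "proton sink/source per compartment"
    )))
  }

  for (id in c("iCitDHNADP_h", "AOX4_h", "Tr_ATP_hc")) {
    act <- c(act, list(curation_action(
      "fix_zero_flux", reaction = id,
      note = paste0("no flux assumed for ", id)
    )))
  }

  bind_rows(act)
}

swap_cofactor_stoich <- function(model, reaction, from, to) {
  st <- reaction_stoich(model, reaction)
  pat_red <- paste0("^", from, "H_([a-z])$")
  pat_ox <- paste0("^", from, "_([a-z])$")
  hit <- grepl(pat_red, names(st)) | grepl(pat_ox, names(st))
  if (!any(hit)) {
    abort(paste0("reaction '", reaction, "' does not use cofactor ", from))
  }
  new_names <- names(st)
  new_names[grepl(pat_red, new_names)] <-
    sub(pat_red, paste0(to, "H_\\1"), new_names[grepl(pat_red, new_names)])
  new_names[grepl(pat_ox, new_names)] <-
    sub(pat_ox, paste0(to, "_\\1"), new_names[grepl(pat_ox, new_names)])
  setNames(unname(st), new_names)
}

#' Apply a sequence of curation actions
#'
#' Actions are applied in order; the change report (one row per action with
#' the touched reaction and a description) is attached as the
#' `"curation_report"` attribute, retrievable with [curation_report()].
#'
#' @param model a `metabolic_model`.
#' @param actions tibble of actions from [curation_action()] /
#'   [default_curation()].
#' @return The curated model.
#' @export
apply_curation <- function(model, actions) {
  report <- list()
  for (i in seq_len(nrow(actions))) {
    kind <- actions$kind[i]
    p <- actions$payload[[i]]
    target <- p$reaction %||% p$id %||% ""
    detail <- switch(
      kind,
      add_reaction = ,
      add_transport = {
        model <- add_reaction(model, p$id, p$stoich,
                              lower = p$lower %||% 0,
                              upper = p$upper %||% INF_PROXY,
                              name = p$name %||% p$id,
                              subsystem = p$subsystem %||% "")
        paste0("added reaction ", p$id)
      },
      remove_reaction = {
        model <- remove_reaction(model, p$id)
        paste0("removed reaction ", p$id)
      },
      set_bounds = {
        model <- set_bounds(model, p$reaction,
                            lower = p$lower %||% NA, upper = p$upper %||% NA)
        paste0("bounds of ", p$reaction, " set to [",
               p$lower %||% "kept", ", ", p$upper %||% "kept", "]")
      },
      swap_cofactor = {
        st <- swap_cofactor_stoich(model, p$reaction, p$from, p$to)
        model <- set_stoichiometry(model, p$reaction, st)
        paste0(p$reaction, ": cofactor ", p$from, " -> ", p$to)
      },
      set_stoichiometry = {
        model <- set_stoichiometry(model, p$reaction, p$stoich)
        paste0("stoichiometry of ", p$reaction, " replaced")
      },
      fix_zero_flux = {
        model <- set_bounds(model, p$reaction, lower = 0, upper = 0)
        paste0(p$reaction, " fixed to zero flux")
      },
      abort(paste0("unknown curation action kind: ", kind))
    )
    report[[i]] <- tibble(action = i, kind = kind, target = target,
                          detail = detail, note = actions$note[i])
  }
  validate_model(model)
  attr(model, "curation_report") <- bind_rows(report)
  model
}

#' Retrieve the change report of the last [apply_curation()] call
#'
#' @param model a curated `metabolic_model`.
#' @return Tibble with one row per applied action.
#' @export
curation_report <- function(model) {
  rep <- attr(model, "curation_report")
  if (is.null(rep)) {
    abort("model carries no curation report (was apply_curation() used?)")
  }
  rep
}
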