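#' Run configuration
#'
#' Assembles and validates the configuration consumed by [run_pipeline()].
#' Exactly one model source is used: the bundled network generator
#' (`model = "fixture"`) or a path to an SBML L3/FBC file.
#'
#' @param model `"fixture"` or a path to an SBML file.
#' @param curate apply the packaged default curation set (only meaningful
#'   when the source is the pre-curation fixture or a compatible model).
#' @param experiments character vector drawn from `"one_cell"`,
#'   `"photorespiration_scan"`, `"knockouts"`, `"transport_fva"`,
#'   `"light_scan"`, `"limitation_scan"`, `"transport_ratio_scan"`,
#'   `"energy"`, `"linearity"`.
#' @param out_dir output directory (created if absent).
#' @param grids optional named list overriding the per-experiment grids
#'   (`ratios`, `totals`, `splits`, `limit_grid`, `asp_mal`).
#' @param photorespiration one-cell ratio; the two-cell experiments use
#'   `two_cell_photorespiration`.
#' @param two_cell_photorespiration ratio for the native populations.
#' @param seed integer seed recorded in the log and forwarded to any
#'   randomized fixture variant.
#' @return A validated list of class `run_config`.
#' @export
run_config <- function(model = "fixture", curate = TRUE,
                       experiments = c("one_cell", "photorespiration_scan",
                                       "knockouts"),
                       out_dir = tempfile("c4flux_run_"),
                       grids = list(),
                       photorespiration = 0.1,
                       two_cell_photorespiration = 1 / 3,
                       seed = 1L) {
  known <- c("one_cell", "photorespiration_scan", "knockouts",
             "transport_fva", "light_scan", "limitation_scan",
             "transport_ratio_scan", "energy", "linearity")
  bad <- setdiff(experiments, known)
  if (length(bad) > 0) {
    abort(paste0("unknown experiment(s): ", paste(bad, collapse = ", ")))
  }
  if (!identical(model, "fixture") && !file.exists(model)) {
    abort(paste0("model source does not exist: ", model))
  }
  structure(list(model = model, curate = curate, experiments = experiments,
                 out_dir = out_dir, grids = grids,
                 photorespiration = photorespiration,
                 two_cell_photorespiration = two_cell_photorespiration,
                 seed = as.integer(seed)),
            class = "run_config")
}

#' Load a run configuration from a YAML file
#'
#' @param path YAML file whose keys mirror the [run_config()] arguments.
#' @return A `run_config`.
#' @export
read_run_config <- function(path) {
  raw <- yaml::read_yaml(path)
  do.call(run_config, raw)
}

write_tsv <- function(df, path) {
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
}

#' Execute the configured analysis stages
#'
#' Runs the selected experiments in dependency order (one-cell assembly
#' first, two-cell composition whenever a two-cell experiment is selected),
#' writing per-experiment TSV tables (`scan.tsv`, full `fluxes.tsv` per
#' solution), an SBML snapshot of each composed model, a machine-readable
#' `summary.json` of headline quantities, and a `run.log` with solver status
#' per stage.
#'
#' @param config a [run_config()].
#' @return The summary list, invisibly; written artifacts live in
#'   `config$out_dir`.
#' @export
run_pipeline <- function(config = run_config()) {
  stopifnot(inherits(config, "run_config"))
  dir.create(config$out_dir, showWarnings = FALSE, recursive = TRUE)
  log_path <- file.path(config$out_dir, "run.log")
  log_line <- function(...) {
    cat(paste0(format(Sys.time(), "%H:%M:%S"), " ", ..., "\n"),
        file = log_path, append = TRUE)
  }
  log_line("run seed ", config$seed, "; solver GLPK simplex via bundled interface")
  summary <- list(seed = config$seed)

  network <- if (identical(config$model, "fixture")) {
    if (config$curate) build_reduced_leaf_network(fixture_config(seed = config$seed))
    else build_reduced_leaf_network(fixture_config(seed = config$seed),
                                    curated = FALSE) %>%
      apply_curation(default_curation())
  } else {
    m <- read_sbml(config$model, quiet = TRUE)
    if (config$curate) m <- apply_curation(m, default_curation())
    m
  }
  one <- compose_one_cell(network, photorespiration = config$photorespiration)
  write_sbml(one, file.path(config$out_dir, "one_cell.sbml"))

  exp_dir <- function(name) {
    d <- file.path(config$out_dir, name)
    dir.create(d, showWarnings = FALSE)
    d
  }
  need_two <- any(config$experiments %in%
                    c("photorespiration_scan", "knockouts", "transport_fva",
                      "light_scan", "limitation_scan", "transport_ratio_scan"))
  two <- NULL
  if (need_two) {
    two <- compose_two_cell(one,
                            photorespiration = config$two_cell_photorespiration)
    write_sbml(two, file.path(config$out_dir, "two_cell.sbml"))
  }

  if ("one_cell" %in% config$experiments) {
    d <- exp_dir("one_cell")
    sol <- solve_pfba(one)
    log_line("one_cell: ", sol$status)
    write_tsv(tidy(sol), file.path(d, "fluxes.tsv"))
    v <- fluxes(sol)
    summary$one_cell <- list(
      status = sol$status,
      co2_uptake = unname(v["Im_CO2"]),
      phloem = unname(v["Ex_Suc"] + v["Ex_AA"]),
      suc_aa_ratio = unname(v["Ex_Suc"] / v["Ex_AA"]),
      suc_starch_ratio = unname(v["Ex_Suc"] / v["Ex_starch"]),
      ppfd = unname(v["Im_hnu"]),
      total_abs_flux = sol$total_abs_flux
    )
  }
  if ("photorespiration_scan" %in% config$experiments) {
    d <- exp_dir("photorespiration_scan")
    ratios <- config$grids$ratios %||% seq(0, 1, by = 0.05)
    scan <- photorespiration_scan(two, ratios)
    log_line("photorespiration_scan: ", sum(scan$status == "optimal"), "/",
             nrow(scan), " optimal")
    write_tsv(as_tibble(scan), file.path(d, "scan.tsv"))
    summary$photorespiration_scan <- list(
      pepc_low = scan$pepc[1], pepc_high = scan$pepc[nrow(scan)],
      gdc_peak = max(scan$gdc, na.rm = TRUE)
    )
  }
  if ("knockouts" %in% config$experiments) {
    d <- exp_dir("knockouts")
    for (keep in c("NADP_ME", "NAD_ME", "PEP_CK")) {
      sol <- knockout_decarboxylation(two, keep)
      log_line("knockout keep=", keep, ": ", sol$status)
      write_tsv(tidy(sol), file.path(d, paste0("fluxes_", keep, ".tsv")))
      v <- fluxes(sol)
      summary$knockouts[[keep]] <- list(
        status = sol$status,
        pepc = unname(v["[M]_PEPC_c"] + v["[B]_PEPC_c"]),
        co2_uptake = unname(v["[M]_Im_CO2"] + v["[B]_Im_CO2"])
      )
    }
  }
  if ("transport_fva" %in% config$experiments) {
    d <- exp_dir("transport_fva")
    for (keep in c("NADP_ME", "NAD_ME", "PEP_CK")) {
      res <- transport_fva(two, keep = keep)
      write_tsv(tidy(res), file.path(d, paste0("fva_", keep, ".tsv")))
      log_line("transport_fva keep=", keep, ": ", nrow(res), " transporters")
    }
  }
  if ("light_scan" %in% config$experiments) {
    d <- exp_dir("light_scan")
    scan <- light_scan(two,
                       totals = config$grids$totals %||% seq(0, 1000, by = 100),
                       ratios = config$grids$splits %||% seq(0.1, 2, by = 0.19))
    log_line("light_scan: ", sum(scan$status == "optimal"), "/", nrow(scan),
             " optimal")
    write_tsv(as_tibble(scan), file.path(d, "scan.tsv"))
  }
  if ("limitation_scan" %in% config$experiments) {
    d <- exp_dir("limitation_scan")
    for (nutrient in c("NO3", "H2O", "CO2")) {
      scan <- limitation_scan(two, nutrient,
                              grid = config$grids$limit_grid[[nutrient]])
      write_tsv(as_tibble(scan), file.path(d, paste0("scan_", nutrient, ".tsv")))
      log_line("limitation_scan ", nutrient, ": ",
               sum(scan$status == "optimal"), "/", nrow(scan), " optimal")
    }
  }
  if ("transport_ratio_scan" %in% config$experiments) {
    d <- exp_dir("transport_ratio_scan")
    scan <- transport_ratio_scan(two, ratios = config$grids$asp_mal %||%
                                   seq(0, 4, by = 0.5))
    write_tsv(as_tibble(scan), file.path(d, "scan.tsv"))
    log_line("transport_ratio_scan: ", sum(scan$status == "optimal"), "/",
             nrow(scan), " optimal")
  }
  if ("energy" %in% config$experiments) {
    d <- exp_dir("energy")
    sol <- solve_pfba(one)
    for (cof in c("ATP", "NADPH", "NADH")) {
      acct <- energy_accounting(one, sol, cof)
      write_tsv(tidy(acct), file.path(d, paste0("account_", cof, ".tsv")))
      if (cof == "ATP") {
        lr <- filter(acct$producers, .data$subsystem == "light reactions")
        summary$energy <- list(atp_light_share = if (nrow(lr)) lr$percent else 0)
      }
    }
    log_line("energy accounting written")
  }
  if ("linearity" %in% config$experiments) {
    d <- exp_dir("linearity")
    for (axis in c("CO2", "PPFD")) {
      probe <- linearity_probe(one, axis)
      write_tsv(as_tibble(probe), file.path(d, paste0("probe_", axis, ".tsv")))
      log_line("linearity ", axis, ": breakpoint ",
               format(attr(probe, "breakpoint")))
    }
  }

  jsonlite::write_json(summary, file.path(config$out_dir, "summary.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(summary)
}
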