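test_that("model invariants are enforced", {
  expect_error(
    metabolic_model(compartments = "c") |>
      add_metabolite("A_c", compartment = "c") |>
      add_metabolite("A_c", compartment = "c"),
    "already exists")
  expect_error(
    toy_chain() |> add_reaction("bad", c(A_c = -1), lower = 2, upper = 1),
    "lower bound exceeds")
  expect_error(
    toy_chain() |> add_reaction("bad", c(Missing_c = -1)),
    "unknown metabolite")
  expect_error(set_bounds(toy_chain(), "nope", lower = 0), "unknown reaction")
})

test_that("proton buffers are added per compartment and are idempotent", {
  net <- build_reduced_leaf_network()
  buffered <- add_proton_buffers(net)
  expect_equal(nrow(buffered$reactions), nrow(net$reactions) + 4)
  sinks <- grep("^Sink_H_", buffered$reactions$id, value = TRUE)
  expect_setequal(sinks, paste0("Sink_H_", c("c", "h", "m", "p")))
  # fully reversible
  info <- reaction_info(buffered, sinks)
  expect_true(all(info$lower < 0 & info$upper > 0))
  # idempotent
  again <- add_proton_buffers(buffered)
  expect_equal(nrow(again$reactions), nrow(buffered$reactions))

  # single-compartment model gets exactly one buffer
  toy <- add_proton_buffers(toy_chain())
  expect_equal(sum(startsWith(toy$reactions$id, "Sink_H_")), 1)
})

test_that("maintenance reactions carry the fixed compartment costs", {
  m <- build_reduced_leaf_network() |> add_proton_buffers() |> add_maintenance()
  info <- reaction_info(m, c("NGAM_c", "NGAM_h", "NGAM_m"))
  # peroxisomal cost is folded into the cytosol
  expect_equal(info$lower, c(0.0427 + 0.0076, 0.1527, 0.0091))
  expect_equal(info$upper, info$lower)
  # the fixed flux appears in any feasible solution
  sol <- solve_pfba(cached_one_cell())
  expect_equal(unname(fluxes(sol, c("NGAM_c", "NGAM_h", "NGAM_m"))),
               c(0.0503, 0.1527, 0.0091), tolerance = 1e-9)
  # missing species are reported with compartment and species
  expect_error(add_maintenance(toy_chain()), "missing species")
})

test_that("boundary specification sets exchanges and closes other exports", {
  m <- build_reduced_leaf_network() |> add_proton_buffers() |> set_boundary()
  expect_equal(unname(unlist(reaction_info(m, "Im_CO2")[, c("lower", "upper")])),
               c(0, 20))
  expect_equal(unname(unlist(reaction_info(m, "Im_H2O")[, c("lower", "upper")])),
               c(-1e6, 1e6))
  expect_equal(unname(unlist(reaction_info(m, "Im_O2")[, c("lower", "upper")])),
               c(-1e6, 1e6))
  # nitrate is the sole nitrogen source
  expect_equal(unname(unlist(reaction_info(m, "Im_NH4")[, c("lower", "upper")])),
               c(0, 0))
  # unlisted exports are forced to zero
  expect_equal(unname(unlist(reaction_info(m, "Ex_CO2")[, c("lower", "upper")])),
               c(0, 0))
  # proton buffers are untouched by the export-closing rule
  expect_lt(reaction_info(m, "Sink_H_c")$lower, 0)

  expect_error(boundary_spec(tibble::tibble(reaction = "x", lower = 2, upper = 1)),
               "exceeds upper")
  bad <- boundary_spec(tibble::tibble(reaction = "NotAnExchange",
                                      lower = 0, upper = 1))
  expect_error(set_boundary(build_reduced_leaf_network(), bad),
               "unknown exchange")
})

test_that("elemental conservation flags exactly the broken reactions", {
  net <- build_reduced_leaf_network()
  expect_equal(nrow(dplyr::filter(check_conservation(net, "carbon"),
                                  status == "flagged")), 0)
  expect_equal(nrow(dplyr::filter(check_conservation(net, "nitrogen"),
                                  status == "flagged")), 0)

  # a reaction dropping one carbon is flagged with its imbalance
  broken <- set_stoichiometry(net, "RBC_h",
                              c(RuBP_h = -1, CO2_h = -1, PGA_h = 2,
                                CO2_c = -1))
  rep <- check_conservation(broken, "carbon")
  flagged <- dplyr::filter(rep, status == "flagged")
  expect_equal(flagged$reaction, "RBC_h")
  expect_equal(flagged$delta, -1)

  # boundary/pseudo reactions (single metabolite) are exempt, not flagged
  buf <- add_proton_buffers(net)
  rep2 <- check_conservation(buf, "carbon")
  expect_true(all(dplyr::filter(rep2, grepl("^Sink_H_", reaction))$status ==
                    "exempt"))
  expect_true(all(dplyr::filter(rep2, reaction == "Im_CO2")$status == "exempt"))
})

test_that("photorespiration ratio helpers validate input and convert gas ratios", {
  expect_error(fix_photorespiration(cached_one_cell(), -0.1), "non-negative")
  # ratio = (1/SR) * pO2/pCO2
  expect_equal(photorespiration_ratio_from_gas(100, 210, 0.21), 10)
  expect_equal(photorespiration_ratio_from_gas(2000, 210, 0.21 * 5), 0.1)
  expect_error(photorespiration_ratio_from_gas(0, 1, 1), "positive")
})
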