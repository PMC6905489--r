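test_that("the generated network is balanced, compartmented and right-sized", {
  net <- build_reduced_leaf_network()
  expect_setequal(net$compartments, c("c", "h", "m", "p"))
  expect_gte(nrow(net$reactions), 60)
  expect_lte(nrow(net$reactions), 120)
  expect_true(validate_model(net) |> is.list())
  expect_equal(nrow(dplyr::filter(check_conservation(net, "carbon"),
                                  status == "flagged")), 0)
  expect_equal(nrow(dplyr::filter(check_conservation(net, "nitrogen"),
                                  status == "flagged")), 0)
  # generation is deterministic
  expect_identical(build_reduced_leaf_network(), net)
})

test_that("the one-cell pipeline is carbon-limited at its CO2 bound", {
  sol <- solve_pfba(cached_one_cell())
  expect_equal(sol$status, "optimal")
  expect_equal(unname(fluxes(sol, "Im_CO2")), 20, tolerance = 1e-4)
  # carbon-limited, not light-limited: photons stay strictly below any cap
  # near the paper's regime and output scales with carbon (see linearity test)
  expect_lt(unname(fluxes(sol, "Im_hnu")), 400)
})

test_that("excluding the light reactions removes all phloem output", {
  dark <- build_reduced_leaf_network(fixture_config(light_reactions = FALSE,
                                                    cyclic_electron_flow = FALSE))
  m <- dark |>
    add_proton_buffers() |>
    set_boundary() |>
    set_objective(c(Ex_Suc = 1, Ex_AA = 1), "max")
  s <- solve_fba(m)
  expect_equal(s$status, "optimal")
  expect_equal(s$objective_value, 0, tolerance = 1e-9)
})

test_that("excluded subsystems make downstream drivers fail with the dependency named", {
  no_c4 <- build_reduced_leaf_network(fixture_config(c4_enzymes = FALSE))
  expect_false("PEPC_c" %in% no_c4$reactions$id)
  one <- no_c4 |> add_proton_buffers() |> add_maintenance() |> set_boundary() |>
    set_objective(c(Ex_Suc = 1, Ex_AA = 1), "max")
  two <- duplicate_cells(one)
  expect_error(photorespiration_scan(two, 0.1), "requires reaction")
})

test_that("bound jitter is deterministic, identity at zero, and brackets the optimum", {
  one <- cached_one_cell()
  p1 <- perturb_fixture(one, seed = 42, jitter_fraction = 0.1)
  p2 <- perturb_fixture(one, seed = 42, jitter_fraction = 0.1)
  expect_equal(p1$reactions, p2$reactions)
  expect_false(isTRUE(all.equal(p1$reactions$upper, one$reactions$upper)))

  p0 <- perturb_fixture(one, seed = 7, jitter_fraction = 0)
  expect_equal(p0$reactions, one$reactions)

  # fixed (equality) bounds are skipped and reported
  expect_true("NGAM_h" %in% attr(p1, "skipped_fixed"))
  ngam <- reaction_info(p1, "NGAM_h")
  expect_equal(ngam$lower, 0.1527)

  # LP monotonicity: optimum under jitter <= 10% lies between the optima
  # with all free bounds scaled down/up by 10%
  scale_free <- function(m, f) {
    free <- m$reactions$lower < m$reactions$upper
    m$reactions$lower[free] <- m$reactions$lower[free] * f
    m$reactions$upper[free] <- m$reactions$upper[free] * f
    m
  }
  z_lo <- solve_pfba(scale_free(one, 0.9))$objective_value
  z_hi <- solve_pfba(scale_free(one, 1.1))$objective_value
  z_p <- solve_pfba(p1)$objective_value
  expect_gte(z_p, z_lo - 1e-6)
  expect_lte(z_p, z_hi + 1e-6)
})
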