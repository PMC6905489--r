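test_that("duplication exactly doubles the model with prefixed ids", {
  one <- cached_one_cell()
  two <- duplicate_cells(one)
  expect_equal(nrow(two$metabolites), 2 * nrow(one$metabolites))
  expect_equal(nrow(two$reactions), 2 * nrow(one$reactions))
  expect_true(all(startsWith(two$reactions$id, "[M]_") |
                    startsWith(two$reactions$id, "[B]_")))
  # each cell carries its own copy of every ratio constraint
  expect_equal(nrow(two$ratio_constraints), 2 * nrow(one$ratio_constraints))
  # bounds travel with the reactions (maintenance in both cells)
  expect_equal(reaction_info(two, "[M]_NGAM_h")$lower, 0.1527)
  expect_equal(reaction_info(two, "[B]_NGAM_h")$lower, 0.1527)
  expect_error(duplicate_cells(two), "prefix collision")
})

test_that("cell symmetry: before CCM installation and bound specialization, the\n          prefix-swapped model is isomorphic", {
  two <- duplicate_cells(cached_one_cell()) |> link_cells()
  swap <- function(x) {
    y <- gsub("[M]_", "@TMP@", x, fixed = TRUE)
    y <- gsub("[B]_", "[M]_", y, fixed = TRUE)
    gsub("@TMP@", "[B]_", y, fixed = TRUE)
  }
  rx <- two$reactions
  rx$id <- swap(rx$id)
  expect_setequal(rx$id, two$reactions$id)
  st <- two$stoich
  st$reaction <- swap(st$reaction)
  st$metabolite <- swap(st$metabolite)
  # a swapped reversible interface transporter is the same reaction written
  # in the opposite direction: canonicalize orientation before comparing
  canon <- function(d) {
    d <- dplyr::arrange(d, reaction, metabolite)
    flips <- d |>
      dplyr::group_by(reaction) |>
      dplyr::summarise(flip = coef[1] > 0 & startsWith(reaction[1], "[MB]"))
    d <- dplyr::left_join(d, flips, by = "reaction")
    sort(paste(d$reaction, d$metabolite, ifelse(d$flip, -d$coef, d$coef)))
  }
  expect_identical(canon(st), canon(two$stoich))
})

test_that("the interface contains exactly the transportable set, with exclusions", {
  two <- cached_two_cell()
  mb <- interface_transporters(two)
  expect_setequal(sub("^\\[MB\\]_", "", mb), default_transportable())
  expect_true("[MB]_MAL" %in% mb)
  # oxaloacetate, protons, bicarbonate, phosphate, cofactors are never exchanged
  expect_false(any(c("[MB]_OAA", "[MB]_H", "[MB]_HCO3", "[MB]_Pi",
                     "[MB]_ATP", "[MB]_NADPH") %in% two$reactions$id))
  # transporters are reversible, positive = mesophyll to bundle sheath
  info <- reaction_info(two, "[MB]_MAL")
  expect_lt(info$lower, 0)
  st <- reaction_stoich(two, "[MB]_MAL")
  expect_equal(unname(st["[M]_MAL_c"]), -1)
  expect_equal(unname(st["[B]_MAL_c"]), 1)

  expect_error(cell_interface_spec(transportable = "OAA"),
               "both transportable and excluded")
  expect_error(link_cells(duplicate_cells(cached_one_cell()),
                          cell_interface_spec(transportable = "NotAMet")),
               "no cytosolic species")
})

test_that("an empty interface disconnects the cells and kills bundle-sheath output", {
  two <- duplicate_cells(cached_one_cell()) |>
    link_cells(cell_interface_spec(transportable = character())) |>
    set_two_cell_bounds()
  two <- set_objective(two, c("[B]_Ex_Suc" = 1, "[B]_Ex_AA" = 1), "max")
  s <- solve_fba(two)
  # with no CO2 import and no interface, B cannot acquire carbon
  if (s$status == "optimal") expect_equal(s$objective_value, 0, tolerance = 1e-6)
  else expect_match(s$status, "infeasible")
})

test_that("the dual Rubisco population seals external and internal CO2 pools", {
  two <- cached_two_cell()
  # native external-CO2 carboxylation cannot run backwards and has no
  # oxygenation partner of its own
  expect_equal(reaction_info(two, "[B]_RBC_h_Ex")$lower, 0)
  # external CO2 species participate in exactly the transporter chain and
  # the native carboxylation
  users <- unique(two$stoich$reaction[two$stoich$metabolite %in%
                                        c("[B]_CO2_ex_c", "[B]_CO2_ex_h")])
  expect_setequal(users, c("[MB]_CO2", "[B]_Tr_CO2h_Ex", "[B]_RBC_h_Ex"))
  # the CCM population consumes only internal CO2
  st <- reaction_stoich(two, "[B]_RBC_h")
  expect_true("[B]_CO2_h" %in% names(st))
  expect_false(any(grepl("CO2_ex", names(st))))
  # the ratio constraint sits on the native pair, never the CCM population
  rc <- two$ratio_constraints
  pr <- rc[grepl("photorespiration", rc$id), ]
  expect_setequal(pr$reaction_b, c("[M]_RBC_h", "[B]_RBC_h_Ex"))
  expect_false("[B]_RBC_h" %in% c(pr$reaction_a, pr$reaction_b))
})

test_that("CCM carboxylation is bounded by internal CO2 production", {
  two <- cached_two_cell()
  # with all bundle-sheath CO2-releasing reactions closed, the sealed
  # internal pool forces the CCM population to zero flux
  closed <- set_bounds(two,
                       paste0("[B]_", c("PDH_m", "IDH_m", "AKGDH_m", "GDC_m",
                                        "NADPME_h", "NADME_m", "PEPCK_c")),
                       lower = 0, upper = 0)
  s <- lexicographic_solve(closed, list(phloem_obj(closed)),
                           final_parsimony = TRUE)
  expect_equal(s$status, "optimal")
  expect_equal(unname(fluxes(s, "[B]_RBC_h")), 0, tolerance = 1e-6)

  # per-solution mass balance: CCM flux never exceeds internal CO2 release
  sol <- lexicographic_solve(two, list(phloem_obj(two)), final_parsimony = TRUE)
  v <- fluxes(sol)
  b_int_co2 <- c("[B]_CO2_c", "[B]_CO2_h", "[B]_CO2_m")
  producers <- dplyr::filter(two$stoich, metabolite %in% b_int_co2)
  release <- sum(pmax(producers$coef * v[producers$reaction], 0))
  expect_lte(unname(v["[B]_RBC_h"]), release + 1e-6)
})

test_that("two-cell bounds: mesophyll CO2 cap 40, bundle sheath import closed", {
  two <- cached_two_cell()
  expect_equal(unname(unlist(reaction_info(two, "[M]_Im_CO2")[, c("lower", "upper")])),
               c(0, 40))
  expect_equal(unname(unlist(reaction_info(two, "[B]_Im_CO2")[, c("lower", "upper")])),
               c(0, 0))
  # photon budget and ordering couplings are installed
  expect_true(all(c("ppfd:total", "ppfd:ordering") %in% two$couplings$id))
  # requesting a >1 split while ordering is enforced is refused
  expect_error(set_two_cell_bounds(two, ppfd_ratio = 1.5, enforce_ordering = TRUE),
               "ordering")
})

test_that("without photons no phloem sap can be produced", {
  two <- set_two_cell_bounds(cached_two_cell(), ppfd_total = 0)
  s <- lexicographic_solve(two, list(phloem_obj(two)), final_parsimony = TRUE)
  # the fixed maintenance demand cannot be met without any energy input,
  # so there is no feasible solution at all — a fortiori no phloem output
  phloem_possible <- s$status == "optimal" && s$objective_value > 1e-6
  expect_false(phloem_possible)
})
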