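test_that("the photorespiration scan shows the C3 to C2 to C4 transition", {
  two <- cached_two_cell()
  scan <- photorespiration_scan(two, ratios = c(0, 0.1, 1 / 3, 0.75, 1))
  expect_equal(nrow(scan), 5)
  expect_true(all(scan$status == "optimal"))
  # PEPC is barely detectable at low photorespiration (anaplerotic only)
  expect_lt(scan$pepc[1], 2)
  # and non-decreasing along the grid up to all CO2 funnelled through PEPC
  expect_true(all(diff(scan$pepc) >= -1e-6))
  expect_equal(scan$pepc[nrow(scan)], 40, tolerance = 1e-3)
  expect_equal(scan$co2_uptake[nrow(scan)], 40, tolerance = 1e-3)
  # the CCM population is (near) idle without photorespiratory pressure:
  # only bundle-sheath respiratory CO2, which cannot leave the sealed
  # internal pool, is refixed
  expect_lt(scan$rubisco_b_ccm[1], 0.05 * scan$co2_uptake[1])
  # the C2 intermediate: glycine-decarboxylase CO2 shuttling peaks at
  # intermediate ratios
  expect_gt(max(scan$gdc[2:4]), scan$gdc[1])
})

test_that("scans are deterministic", {
  two <- cached_two_cell()
  s1 <- photorespiration_scan(two, ratios = c(0.1, 0.5))
  s2 <- photorespiration_scan(two, ratios = c(0.1, 0.5))
  expect_identical(as.data.frame(s1), as.data.frame(s2))
})

test_that("each decarboxylation knockout still evolves a C4 cycle", {
  two <- cached_two_cell()
  sols <- lapply(c("NADP_ME", "NAD_ME", "PEP_CK"), function(k)
    knockout_decarboxylation(two, k))
  for (i in seq_along(sols)) {
    s <- sols[[i]]
    expect_equal(s$status, "optimal")
    v <- fluxes(s)
    # bounded-out enzymes carry exactly zero flux
    off <- setdiff(c("NADPME_h", "NADME_m", "PEPCK_c"),
                   c("NADPME_h", "NADME_m", "PEPCK_c")[i])
    for (cell in c("[M]_", "[B]_")) {
      expect_equal(unname(v[paste0(cell, off)]), c(0, 0))
    }
    # PEPC carries the full CO2 uptake under minimized photorespiration
    expect_equal(unname(v["[M]_PEPC_c"]), 40, tolerance = 1e-3)
    expect_equal(unname(v["[M]_Im_CO2"]), 40, tolerance = 1e-3)
    # the kept decarboxylase is the active one in the bundle sheath
    kept_id <- paste0("[B]_", c("NADPME_h", "NADME_m", "PEPCK_c")[i])
    expect_gt(unname(v[kept_id]), 30)
  }
  # the core mesophyll C4 module is identical across the three modes
  core <- paste0("[M]_", c("PEPC_c", "CA_c", "Im_CO2", "PPDK_h", "RBC_h",
                           "RBO_h"))
  for (i in 2:3) {
    expect_equal(unname(fluxes(sols[[1]], core)), unname(fluxes(sols[[i]], core)),
                 tolerance = 1e-3)
  }
  expect_error(knockout_decarboxylation(two, "PPDK"), "arg")
})

test_that("transport FVA exposes the aspartate/alanine alternative for NAD-ME", {
  two <- cached_two_cell()
  fv <- transport_fva(two, keep = "NAD_ME", deviation = 0.015)
  iv <- function(id) as.list(fv[fv$reaction == id, ])
  # malate/pyruvate is the parsimonious shuttle, but within 1.5% of the
  # flux minimum the aspartate/alanine shuttle can take over substantially
  expect_gt(iv("[MB]_ASP")$max, 10)
  expect_lt(iv("[MB]_MAL")$min, 30)
  expect_lt(iv("[MB]_ALA")$min, -10)
  # NADP-ME shows only minor variation in the same near-optimal space
  fvn <- transport_fva(two, keep = "NADP_ME", deviation = 0.015)
  span <- function(r, id) {
    row <- r[r$reaction == id, ]
    row$max - row$min
  }
  expect_lt(span(fvn, "[MB]_ASP"), span(fv, "[MB]_ASP"))
  # every parsimonious transporter flux lies within its interval
  sol <- attr(fv, "solution")
  m <- dplyr::left_join(sol, tidy(fv), by = "reaction")
  expect_true(all(m$flux >= m$min - 1e-5 & m$flux <= m$max + 1e-5))

  # deviation 0: a transporter without alternatives has a degenerate interval
  fv0 <- transport_fva(two, keep = "NAD_ME", deviation = 0)
  expect_lt(span(fv0, "[MB]_CO2"), 1e-3)
})

test_that("light limitation reduces CO2 uptake and favours PEP-CK", {
  two <- cached_two_cell()
  scan <- light_scan(two, totals = c(0, 200, 400, 800), ratios = c(0.1, 1))
  # zero-light points are recorded as infeasible, never dropped
  expect_equal(nrow(scan), 8)
  expect_true(all(grepl("infeasible", scan$status[scan$total == 0])))
  ok <- dplyr::filter(scan, status == "optimal")
  # below the saturating light level the CO2 uptake stays under its cap
  expect_true(all(ok$co2_uptake[ok$total <= 400] < 40 - 1e-6))
  expect_true(all(abs(ok$co2_uptake[ok$total == 800] - 40) < 1e-3))
  # PEP-CK, the ATP-sparing decarboxylase, dominates under light limitation
  lim <- dplyr::filter(ok, total == 200)
  expect_true(all(lim$pep_ck > lim$nadp_me))
  expect_true(all(lim$pep_ck > lim$nad_me))
  # shares are well defined at light-limited points and within [0, 1]
  expect_true(all(lim$share_pep_ck >= 0 & lim$share_pep_ck <= 1 + 1e-6))
})

test_that("nutrient limitation scales output without changing the C4 mode", {
  two <- cached_two_cell()
  no3 <- limitation_scan(two, "NO3", grid = c(0, 0.5, 1))
  # closing nitrate kills phloem output through the amino-acid coupling
  expect_equal(no3$phloem[1], 0, tolerance = 1e-6)
  expect_gt(no3$phloem[3], no3$phloem[2])

  co2 <- limitation_scan(two, "CO2", grid = c(10, 20, 40))
  # halving the limiting bound halves the output
  expect_equal(co2$phloem[2] / co2$phloem[1], 2, tolerance = 1e-3)
  # while decarboxylase proportions stay the same
  share <- co2$nadp_me / co2$co2_uptake
  expect_lt(max(share) - min(share), 1e-3)
  # the unlimited end reproduces the unconstrained optimum
  base <- lexicographic_solve(two, list(phloem_obj(two)), final_parsimony = TRUE)
  ref <- sum(fluxes(base, c("[B]_Ex_Suc", "[B]_Ex_AA")))
  expect_equal(co2$phloem[3], ref, tolerance = 1e-6)

  expect_error(limitation_scan(two, "Fe"), "arg")
})

test_that("the aspartate:malate transport ratio is enforced and steers the mode", {
  two <- cached_two_cell()
  scan <- transport_ratio_scan(two, ratios = c(0, 1, 4))
  expect_true(all(scan$status == "optimal"))
  # the installed two-sided ratio holds exactly at every grid point
  expect_equal(scan$mb_ASP, scan$asp_mal * scan$mb_MAL, tolerance = 1e-6)
  # malate-dominated transport favours NADP-ME over the other decarboxylases
  expect_gt(scan$nadp_me[1], scan$nad_me[1])
  expect_gt(scan$nadp_me[1], scan$pep_ck[1])
})

test_that("energy accounting normalizes to 100% per side", {
  # toy with a single producer
  m <- metabolic_model(compartments = "c") |>
    add_metabolite("ATP_c", compartment = "c", carbon = 10) |>
    add_metabolite("ADP_c", compartment = "c", carbon = 10) |>
    add_reaction("make", c(ADP_c = -1, ATP_c = 1), 0, 10, subsystem = "synthesis") |>
    add_reaction("spend", c(ATP_c = -1, ADP_c = 1), 0, 10, subsystem = "use") |>
    add_reaction("drive", c(ADP_c = 1), 0, 0) |>
    set_objective(c(spend = 1), "max")
  m <- set_bounds(m, "spend", lower = 2, upper = 2)
  acct <- energy_accounting(m, solve_fba(m), "ATP")
  expect_equal(acct$producers$subsystem, "synthesis")
  expect_equal(acct$producers$percent, 100)
  expect_equal(acct$consumers$percent, 100)

  one <- cached_one_cell()
  sol <- solve_pfba(one)
  for (cof in c("ATP", "NADPH", "NADH")) {
    a <- energy_accounting(one, sol, cof)
    expect_equal(sum(a$producers$percent), 100, tolerance = 0.1)
    expect_equal(sum(a$consumers$percent), 100, tolerance = 0.1)
  }
  # in the leaf model, nearly all ATP comes from the light reactions
  atp <- energy_accounting(one, sol, "ATP")
  light <- dplyr::filter(atp$producers, subsystem == "light reactions")
  expect_gt(light$percent, 90)
  expect_error(energy_accounting(m, solve_fba(m), "NADPH"), "not present")
})

test_that("phloem output is linear in CO2 and saturates with light", {
  one <- cached_one_cell()
  co2 <- linearity_probe(one, "CO2", grid = seq(0, 20, by = 4))
  expect_true(all(co2$status == "optimal"))
  expect_equal(co2$phloem[1], 0, tolerance = 1e-6)
  fit <- stats::lm(phloem ~ value, data = as.data.frame(co2))
  expect_gt(summary(fit)$r.squared, 1 - 1e-9)

  ppfd <- linearity_probe(one, "PPFD", grid = seq(0, 300, by = 50))
  ok <- dplyr::filter(ppfd, status == "optimal")
  # linear while light-limited, flat once the CO2 bound binds
  expect_equal(attr(ppfd, "breakpoint"), 200, tolerance = 50)
  expect_equal(ok$phloem[nrow(ok)], ok$phloem[nrow(ok) - 1], tolerance = 1e-6)
  expect_lt(max(ok$co2_uptake), 20 + 1e-6)
})

test_that("carbon closure holds at every solved grid point", {
  two <- cached_two_cell()
  scan <- photorespiration_scan(two, ratios = c(0.1, 1 / 3))
  for (i in seq_len(nrow(scan))) {
    # carbon in equals carbon out: CO2 in = 12 C per sucrose and starch
    # unit + 5.5 C per amino acid, for both cells' exports
    m <- set_two_cell_photorespiration(two, scan$ratio[i])
    sol <- lexicographic_solve(m, list(phloem_obj(m)), final_parsimony = TRUE)
    v <- fluxes(sol)
    c_in <- v[["[M]_Im_CO2"]] + v[["[B]_Im_CO2"]]
    ex <- function(id) v[[paste0("[M]_", id)]] + v[[paste0("[B]_", id)]]
    c_out <- 12 * ex("Ex_Suc") + 12 * ex("Ex_starch") + 5.5 * ex("Ex_AA")
    expect_equal(c_in, c_out, tolerance = 1e-4)
  }
})
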