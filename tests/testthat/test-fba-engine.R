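test_that("FBA finds capacity-limited optima and honest failure statuses", {
  s <- solve_fba(toy_chain(5))
  expect_equal(s$status, "optimal")
  expect_equal(s$objective_value, 5)

  # forcing flux through a dead-end reaction has no steady state
  dead <- toy_chain(5) |>
    add_metabolite("D_c", compartment = "c") |>
    add_reaction("dead", c(D_c = 1), 1, 2)
  sd <- solve_fba(dead)
  expect_equal(sd$status, "infeasible")
  expect_true(all(is.na(sd$fluxes$flux)))

  # diamond: objective equals single-route capacity whichever route is used
  sdm <- solve_fba(toy_diamond(5))
  expect_equal(sdm$objective_value, 5)
})

test_that("pFBA picks the short route and beats every vertex by total flux", {
  m <- toy_diamond(5)
  s <- solve_pfba(m)
  v <- fluxes(s)
  # brute force: both vertex solutions achieve z = 5; their total |v| is
  # 15 (short) and 25 (long); parsimony must select the short route
  verts <- diamond_vertices(5)
  vert_totals <- vapply(verts, function(x) sum(abs(x)), numeric(1))
  expect_equal(s$objective_value, 5)
  expect_equal(s$total_abs_flux, min(vert_totals), tolerance = 1e-4)
  expect_equal(unname(v["short"]), 5, tolerance = 1e-4)
  expect_equal(unname(v["long1"]), 0, tolerance = 1e-6)
  expect_lte(s$total_abs_flux, min(vert_totals) + 1e-6)

  # pFBA objective value always equals the FBA optimum
  expect_equal(s$objective_value, solve_fba(m)$objective_value)
})

test_that("pFBA zeroes feasible internal loops", {
  s <- solve_pfba(toy_loop(5))
  v <- fluxes(s)
  expect_equal(unname(v["loop_f"]), 0, tolerance = 1e-9)
  expect_equal(unname(v["loop_b"]), 0, tolerance = 1e-9)
  expect_equal(s$objective_value, 5)
})

test_that("ratio constraints couple fluxes exactly, including ratio zero", {
  m <- toy_shuttles(4) |>
    add_ratio_constraint("shuttle1", "shuttle2", 1)
  v <- fluxes(solve_pfba(m))
  expect_equal(unname(v["shuttle1"]), unname(v["shuttle2"]), tolerance = 1e-8)

  m22 <- toy_shuttles(4.4) |>
    add_ratio_constraint("shuttle1", "shuttle2", 2.2)
  v22 <- fluxes(solve_pfba(m22))
  expect_equal(unname(v22["shuttle1"]), 2.2 * unname(v22["shuttle2"]),
               tolerance = 1e-8)

  m0 <- toy_shuttles(4) |>
    add_ratio_constraint("shuttle1", "shuttle2", 0)
  v0 <- fluxes(solve_pfba(m0))
  expect_equal(unname(v0["shuttle1"]), 0, tolerance = 1e-9)

  expect_error(add_ratio_constraint(toy_chain(), "imp", "nope", 1),
               "unknown reaction")
  expect_error(add_ratio_constraint(toy_chain(), "imp", "out", -1),
               "non-negative")
})

test_that("lexicographic solving preserves earlier optima and degenerates to pFBA", {
  m <- toy_diamond(5)
  obj <- flux_objective(c(out = 1), "max")
  lex <- lexicographic_solve(m, list(obj), final_parsimony = TRUE)
  pf <- solve_pfba(m, obj)
  expect_equal(lex$objective_value, pf$objective_value)
  expect_equal(lex$total_abs_flux, pf$total_abs_flux, tolerance = 1e-8)

  # secondary minimization: route flux through the long arm is minimized
  # subject to the primary optimum; exhaustive check against the vertices
  lex2 <- lexicographic_solve(
    m, list(obj, flux_objective(c(long1 = 1), "min")), final_parsimony = TRUE)
  expect_equal(lex2$objective_value, 5)
  expect_equal(unname(fluxes(lex2)["long1"]), 0, tolerance = 1e-8)

  # infeasibility at a stage names the stage
  bad <- set_bounds(toy_chain(5), "out", lower = 10, upper = 20)
  sb <- lexicographic_solve(bad, list(flux_objective(c(out = 1), "max")))
  expect_match(sb$status, "infeasible \\(stage 1")
})

test_that("FVA brackets the optimum, nests with deviation, and spans alternate shuttles", {
  m <- toy_shuttles(4)
  # both equal-cost shuttles span [0, full flux] in the near-optimal space
  fv <- run_fva(m, reactions = c("shuttle1", "shuttle2"), deviation = 0.015)
  expect_true(all(fv$min <= 1e-6))
  expect_true(all(fv$max >= 4 - 1e-6))

  # a reaction with both bounds fixed has a degenerate interval
  mfix <- set_bounds(toy_chain(5), "imp", lower = 3, upper = 3)
  ffix <- run_fva(mfix, reactions = "imp", deviation = 0.015)
  expect_equal(ffix$min, 3, tolerance = 1e-6)
  expect_equal(ffix$max, 3, tolerance = 1e-6)

  # pFBA fluxes lie within their FVA intervals; 0-deviation intervals nest
  # inside 1.5%-deviation intervals
  pf <- fluxes(solve_pfba(m))
  f0 <- run_fva(m, reactions = m$reactions$id, deviation = 0)
  f15 <- run_fva(m, reactions = m$reactions$id, deviation = 0.015)
  expect_true(all(pf[f15$reaction] >= f15$min - 1e-6))
  expect_true(all(pf[f15$reaction] <= f15$max + 1e-6))
  expect_true(all(f0$min >= f15$min - 1e-6))
  expect_true(all(f0$max <= f15$max + 1e-6))
})

test_that("optimal solutions satisfy steady state, bounds and couplings", {
  for (m in list(toy_chain(5), toy_diamond(3), toy_shuttles(4))) {
    s <- solve_pfba(m)
    expect_true(check_solution(m, s))
    v <- fluxes(s)
    resid <- stoichiometric_matrix(m) %*% v
    expect_lte(max(abs(resid)), 1e-6 * max(1, max(abs(v))))
  }
})

test_that("scaling all bounds by a positive factor scales every optimal flux", {
  m <- toy_diamond(5)
  base <- fluxes(solve_pfba(m))
  for (lambda in c(0.5, 2, 10)) {
    ms <- m
    ms$reactions$lower <- ms$reactions$lower * lambda
    ms$reactions$upper <- ms$reactions$upper * lambda
    vs <- fluxes(solve_pfba(ms))
    expect_equal(unname(vs), unname(base * lambda), tolerance = 1e-6)
  }
})

test_that("couplings constrain linear combinations two-sidedly", {
  m <- toy_shuttles(4) |>
    add_coupling("cap", c(shuttle1 = 1, shuttle2 = 1), lower = 0, upper = 2)
  s <- solve_fba(m)
  expect_equal(s$objective_value, 2, tolerance = 1e-8)
  m2 <- remove_coupling(m, "cap")
  expect_equal(solve_fba(m2)$objective_value, 4, tolerance = 1e-8)
})
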