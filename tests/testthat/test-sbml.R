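test_that("toy documents round-trip with exact counts and contents", {
  m <- toy_chain(5)
  path <- withr::local_tempfile(fileext = ".sbml")
  write_sbml(m, path)
  m2 <- read_sbml(path, quiet = TRUE)
  expect_equal(nrow(m2$metabolites), 2)
  expect_equal(nrow(m2$reactions), 3)
  expect_equal(dplyr::arrange(m2$reactions, id), dplyr::arrange(m$reactions, id))
  expect_equal(dplyr::arrange(m2$stoich, reaction, metabolite),
               dplyr::arrange(m$stoich, reaction, metabolite))
  expect_equal(m2$objective, m$objective)
})

test_that("ratio constraints, couplings and annotations survive the round trip", {
  m <- toy_shuttles(4) |>
    add_ratio_constraint("shuttle1", "shuttle2", 2.2) |>
    add_coupling("cap", c(shuttle1 = 1, shuttle2 = 1), lower = 0, upper = 3)
  m$annotations$note <- list(kind = "toy", version = 2)
  path <- withr::local_tempfile(fileext = ".sbml")
  write_sbml(m, path)
  m2 <- read_sbml(path, quiet = TRUE)
  expect_equal(m2$ratio_constraints, m$ratio_constraints)
  expect_equal(m2$couplings, m$couplings)
  expect_equal(m2$annotations$note$kind, "toy")
  # and the reloaded model solves identically
  expect_equal(solve_pfba(m2)$objective_value, solve_pfba(m)$objective_value,
               tolerance = 1e-9)
})

test_that("the composed models round-trip through SBML including cell metadata", {
  two <- cached_two_cell()
  path <- withr::local_tempfile(fileext = ".sbml")
  write_sbml(two, path)
  t2 <- read_sbml(path, quiet = TRUE)
  expect_equal(dplyr::arrange(t2$stoich, reaction, metabolite),
               dplyr::arrange(two$stoich, reaction, metabolite))
  expect_equal(t2$annotations$cells, c("[M]", "[B]"))
  expect_equal(sort(t2$ratio_constraints$id), sort(two$ratio_constraints$id))
  s <- lexicographic_solve(t2, list(phloem_obj(t2)), final_parsimony = TRUE)
  expect_equal(s$status, "optimal")
})

test_that("an empty model writes a valid zero-species document", {
  m <- metabolic_model(compartments = "c")
  path <- withr::local_tempfile(fileext = ".sbml")
  write_sbml(m, path)
  expect_warning(m2 <- read_sbml(path, quiet = TRUE), "no flux objective")
  expect_equal(nrow(m2$metabolites), 0)
  expect_equal(nrow(m2$reactions), 0)
})

test_that("a model without an objective loads with a warning, bad documents fail loudly", {
  m <- toy_chain(5)
  m$objective <- m$objective[0, ]
  path <- withr::local_tempfile(fileext = ".sbml")
  write_sbml(m, path)
  expect_warning(read_sbml(path, quiet = TRUE), "no flux objective")

  bad <- withr::local_tempfile(fileext = ".sbml")
  writeLines("<sbml><model><unclosed></model>", bad)
  expect_error(read_sbml(bad, quiet = TRUE), "cannot parse|no <model>")

  # a reaction without flux bounds is rejected with its id
  txt <- readLines(write_sbml(toy_chain(5), withr::local_tempfile(fileext = ".sbml")))
  txt <- sub('fbc:lowerFluxBound="[^"]*" ?', "", txt)
  nb <- withr::local_tempfile(fileext = ".sbml")
  writeLines(txt, nb)
  expect_error(read_sbml(nb, quiet = TRUE), "without flux bounds")
})

test_that("the bundled example document loads", {
  path <- system.file("extdata", "toy_leaf.sbml", package = "c4flux")
  expect_true(nzchar(path))
  m <- read_sbml(path, quiet = TRUE)
  expect_gt(nrow(m$reactions), 0)
  expect_equal(solve_fba(m)$status, "optimal")
})
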