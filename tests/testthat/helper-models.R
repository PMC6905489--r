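# Shared toy networks and lazily cached composed models.

INF <- c4flux:::INF_PROXY

# linear chain: imp (cap `cap`) -> conv -> out
toy_chain <- function(cap = 5) {
  metabolic_model(compartments = "c") |>
    add_metabolite("A_c", compartment = "c", carbon = 1) |>
    add_metabolite("B_c", compartment = "c", carbon = 1) |>
    add_reaction("imp", c(A_c = 1), 0, cap) |>
    add_reaction("conv", c(A_c = -1, B_c = 1), 0, INF) |>
    add_reaction("out", c(B_c = -1), 0, INF) |>
    set_objective(c(out = 1), "max")
}

# diamond: one 1-step route and one 3-step route of equal capacity
toy_diamond <- function(cap = 5) {
  m <- metabolic_model(compartments = "c")
  for (id in c("A_c", "B_c", "X1_c", "X2_c")) {
    m <- add_metabolite(m, id, compartment = "c", carbon = 1)
  }
  m |>
    add_reaction("imp", c(A_c = 1), 0, cap) |>
    add_reaction("short", c(A_c = -1, B_c = 1), 0, cap) |>
    add_reaction("long1", c(A_c = -1, X1_c = 1), 0, cap) |>
    add_reaction("long2", c(X1_c = -1, X2_c = 1), 0, cap) |>
    add_reaction("long3", c(X2_c = -1, B_c = 1), 0, cap) |>
    add_reaction("out", c(B_c = -1), 0, INF) |>
    set_objective(c(out = 1), "max")
}

# chain plus a feasible internal loop that does not affect the objective
toy_loop <- function(cap = 5) {
  toy_chain(cap) |>
    add_metabolite("L_c", compartment = "c", carbon = 1) |>
    add_reaction("loop_f", c(A_c = -1, L_c = 1), -INF, INF) |>
    add_reaction("loop_b", c(L_c = -1, A_c = 1), -INF, INF)
}

# two interchangeable carrier shuttles of equal length between two pools
toy_shuttles <- function(cap = 4) {
  m <- metabolic_model(compartments = "c")
  for (id in c("S_c", "P_c", "M1_c", "M2_c")) {
    m <- add_metabolite(m, id, compartment = "c", carbon = 1)
  }
  m |>
    add_reaction("imp", c(S_c = 1), 0, cap) |>
    add_reaction("load1", c(S_c = -1, M1_c = 1), 0, INF) |>
    add_reaction("shuttle1", c(M1_c = -1, P_c = 1), 0, INF) |>
    add_reaction("load2", c(S_c = -1, M2_c = 1), 0, INF) |>
    add_reaction("shuttle2", c(M2_c = -1, P_c = 1), 0, INF) |>
    add_reaction("out", c(P_c = -1), 0, INF) |>
    set_objective(c(out = 1), "max")
}

# enumerate the two route-extreme vertex solutions of the diamond by hand
diamond_vertices <- function(cap = 5) {
  list(
    short = c(imp = cap, short = cap, long1 = 0, long2 = 0, long3 = 0, out = cap),
    long = c(imp = cap, short = 0, long1 = cap, long2 = cap, long3 = cap, out = cap)
  )
}

local_cache <- new.env(parent = emptyenv())

cached_one_cell <- function() {
  if (is.null(local_cache$one)) local_cache$one <- compose_one_cell()
  local_cache$one
}

cached_two_cell <- function() {
  if (is.null(local_cache$two)) {
    local_cache$two <- compose_two_cell(cached_one_cell())
  }
  local_cache$two
}

phloem_obj <- function(model) c4flux:::phloem_objective(model)
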