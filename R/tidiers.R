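#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' Tidy a flux distribution
#'
#' @param x a `flux_distribution`.
#' @param active_only keep only reactions with flux above `tol` in magnitude.
#' @param tol magnitude threshold for `active_only`.
#' @param ... unused.
#' @return Tibble with columns `reaction`, `flux`.
#' @export
tidy.flux_distribution <- function(x, active_only = FALSE, tol = 1e-9, ...) {
  out <- x$fluxes
  if (active_only) out <- filter(out, abs(.data$flux) > tol)
  out
}

#' One-row summary of a flux distribution
#'
#' @param x a `flux_distribution`.
#' @param ... unused.
#' @return Tibble with `status`, `objective_value`, `total_abs_flux`,
#'   `n_active`.
#' @export
glance.flux_distribution <- function(x, ...) {
  tibble(status = x$status,
         objective_value = x$objective_value,
         total_abs_flux = x$total_abs_flux,
         n_active = sum(abs(x$fluxes$flux) > 1e-9, na.rm = TRUE))
}

#' Tidy an FVA result
#'
#' @param x an `fva_result`.
#' @param ... unused.
#' @return Tibble with columns `reaction`, `min`, `max`, `span`.
#' @export
tidy.fva_result <- function(x, ...) {
  as_tibble(x) %>% mutate(span = .data$max - .data$min)
}

#' Tidy an energy account
#'
#' @param x an `energy_account`.
#' @param ... unused.
#' @return Tibble with columns `cofactor`, `role`, `subsystem`, `flux`,
#'   `percent`.
#' @export
tidy.energy_account <- function(x, ...) {
  bind_rows(
    mutate(x$producers, role = "producer"),
    mutate(x$consumers, role = "consumer")
  ) %>%
    mutate(cofactor = x$cofactor) %>%
    select("cofactor", "role", "subsystem", "flux", "percent")
}
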