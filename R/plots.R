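#' @importFrom ggplot2 autoplot ggplot aes geom_line geom_point geom_tile
#'   geom_errorbar labs facet_wrap scale_fill_viridis_c theme_minimal
#' @export
ggplot2::autoplot

#' Plot a scan result
#'
#' One-axis scans (photorespiration, limitation, transport-ratio, linearity)
#' are drawn as flux-versus-axis line plots over the key C4 features;
#' the two-axis light grid is drawn as heat maps of the decarboxylase
#' shares.
#'
#' @param object a `c4_scan`.
#' @param features feature columns to draw (defaults to the C4 diagnostics
#'   present in the scan).
#' @param ... unused.
#' @return A ggplot object.
#' @export
autoplot.c4_scan <- function(object,
                             features = c("pepc", "ppdk", "nadp_me",
                                          "nad_me", "pep_ck", "gdc",
                                          "phloem", "co2_uptake"),
                             ...) {
  axes <- attr(object, "axes")
  df <- as_tibble(object)
  if (length(axes) == 2) {
    shares <- grep("^share_", names(df), value = TRUE)
    long <- tidyr::pivot_longer(df, dplyr::all_of(shares),
                                names_to = "enzyme", values_to = "share")
    return(
      ggplot(long, aes(x = .data[[axes[1]]], y = .data[[axes[2]]],
                       fill = .data$share)) +
        geom_tile() +
        facet_wrap(~enzyme) +
        scale_fill_viridis_c(na.value = "grey85") +
        labs(x = "total PPFD [umol/(m2 s)]", y = "PPFD(B) / PPFD(M)",
             fill = "flux / CO2 uptake") +
        theme_minimal()
    )
  }
  features <- intersect(features, names(df))
  long <- tidyr::pivot_longer(df, dplyr::all_of(features),
                              names_to = "feature", values_to = "flux")
  ggplot(long, aes(x = .data[[axes[1]]], y = .data$flux,
                   colour = .data$feature)) +
    geom_line() + geom_point(size = 0.8) +
    labs(x = axes[1], y = "flux [umol/(m2 s)]", colour = NULL) +
    theme_minimal()
}

#' Plot an FVA result
#'
#' Error-bar plot of the near-optimal flux interval per reaction, with the
#' parsimonious solution marked when it was recorded alongside (as
#' [transport_fva()] does). Positive fluxes run mesophyll to bundle sheath.
#'
#' @param object an `fva_result`.
#' @param ... unused.
#' @return A ggplot object.
#' @export
autoplot.fva_result <- function(object, ...) {
  df <- tidy(object)
  df$reaction <- factor(df$reaction, levels = df$reaction[order(df$max)])
  p <- ggplot(df, aes(x = .data$reaction)) +
    geom_errorbar(aes(ymin = .data$min, ymax = .data$max), width = 0.3) +
    labs(x = NULL, y = "flux [umol/(m2 s)]") +
    theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 60, hjust = 1))
  sol <- attr(object, "solution")
  if (!is.null(sol)) {
    sol$reaction <- factor(sol$reaction, levels = levels(df$reaction))
    p <- p + geom_point(data = sol, aes(y = .data$flux), size = 1)
  }
  p
}

#' Plot an energy account
#'
#' @param object an `energy_account`.
#' @param ... unused.
#' @return A ggplot object with producer and consumer shares.
#' @export
autoplot.energy_account <- function(object, ...) {
  df <- tidy(object)
  ggplot(df, aes(x = .data$percent,
                 y = stats::reorder(.data$subsystem, .data$percent))) +
    ggplot2::geom_col() +
    facet_wrap(~role, scales = "free_y") +
    labs(x = paste0("% of ", object$cofactor, " turnover"), y = NULL) +
    theme_minimal()
}
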