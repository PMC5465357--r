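process_fill_scale <- function() {
  ggplot2::scale_fill_manual(values = c(
    bDNF = "#1f78b4", fDNF = "#33a02c", cDNF = "#b2df8a",
    AMO = "#fdbf6f", nDNF = "#e31a1c"), name = "process")
}

#' Stacked source-contribution plot
#'
#' One stacked bar of clipped process fractions per core, faceted by
#' prescribed reduction fraction (and scenario when present) — the standard
#' presentation of a source partition.
#'
#' @param object an `n2o_partition` tibble from [partition_n2o()] or
#'   [run_scenarios()].
#' @param ... unused.
#' @return A ggplot object.
#' @method autoplot n2o_partition
#' @export
autoplot.n2o_partition <- function(object, ...) {
  p <- ggplot2::ggplot(object,
                       ggplot2::aes(x = .data$core_id, y = .data$f,
                                    fill = .data$process)) +
    ggplot2::geom_col(position = "stack") +
    process_fill_scale() +
    ggplot2::labs(x = NULL, y = "fraction of N2O production") +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 45, hjust = 1))
  if ("scenario" %in% names(object)) {
    p + ggplot2::facet_grid(ggplot2::vars(.data$f_red),
                            ggplot2::vars(.data$scenario),
                            labeller = ggplot2::label_both)
  } else {
    p + ggplot2::facet_wrap(ggplot2::vars(.data$f_red),
                            labeller = ggplot2::label_both)
  }
}

#' Monte Carlo interval plot
#'
#' Point estimates with central 95% Monte Carlo intervals per process and
#' core.
#'
#' @param object an `n2o_mc_tbl` tibble from [mc_partition()], or a single
#'   `n2o_mc` object.
#' @param ... unused.
#' @return A ggplot object.
#' @method autoplot n2o_mc_tbl
#' @export
autoplot.n2o_mc_tbl <- function(object, ...) {
  ggplot2::ggplot(object,
                  ggplot2::aes(x = .data$process, y = .data$mean,
                               colour = .data$process)) +
    ggplot2::geom_pointrange(ggplot2::aes(ymin = .data$q025, ymax = .data$q975)) +
    ggplot2::facet_grid(ggplot2::vars(.data$f_red), ggplot2::vars(.data$core_id),
                        labeller = ggplot2::label_both) +
    ggplot2::labs(x = NULL, y = "fraction of N2O production") +
    ggplot2::guides(colour = "none") +
    ggplot2::theme_minimal()
}

#' @rdname autoplot.n2o_mc_tbl
#' @method autoplot n2o_mc
#' @export
autoplot.n2o_mc <- function(object, ...) {
  df <- tidy(object)
  class(df) <- c("n2o_mc_tbl", class(df))
  autoplot(df, ...)
}

#' Flux summary plot
#'
#' Steady-state fluxes per core with 1 s.d. error bars, faceted by species
#' (note N2O fluxes are in umol, other species in mmol, per m^2 per day).
#'
#' @param object an `n2o_flux` tibble from [estimate_fluxes()].
#' @param ... unused.
#' @return A ggplot object.
#' @method autoplot n2o_flux
#' @export
autoplot.n2o_flux <- function(object, ...) {
  ggplot2::ggplot(object,
                  ggplot2::aes(x = .data$core_id, y = .data$flux)) +
    ggplot2::geom_hline(yintercept = 0, linetype = 2, colour = "grey50") +
    ggplot2::geom_pointrange(ggplot2::aes(ymin = .data$flux - .data$flux_sd,
                                          ymax = .data$flux + .data$flux_sd)) +
    ggplot2::facet_wrap(ggplot2::vars(.data$species), scales = "free_y") +
    ggplot2::labs(x = NULL, y = "flux (mmol m-2 d-1; N2O: umol m-2 d-1)") +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 45, hjust = 1))
}
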