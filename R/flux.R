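#' Sediment surface area of a core liner
#'
#' Inner cross-sectional area of a cylindrical core liner from its outer
#' diameter and wall thickness.
#'
#' @param outer_diameter outer diameter, cm (default 10).
#' @param wall_thickness wall thickness, cm (default 0.3175, i.e. 1/8 inch).
#' @return Area in m^2.
#' @examples
#' core_area()            # 10 cm OD, 1/8" wall: 6.887e-3 m^2
#' @export
core_area <- function(outer_diameter = 10, wall_thickness = 0.3175) {
  check_finite(outer_diameter, "outer_diameter")
  check_finite(wall_thickness, "wall_thickness")
  if (any(outer_diameter <= 0) || any(wall_thickness < 0) ||
      any(2 * wall_thickness >= outer_diameter)) {
    stop_invalid("need 0 <= 2 * wall_thickness < outer_diameter.",
                 class = "n2osource_config_error")
  }
  inner_radius_cm <- (outer_diameter - 2 * wall_thickness) / 2
  pi * inner_radius_cm^2 * 1e-4
}

#' Detect the steady-state window of an incubation series
#'
#' Flow-through incubations approach a steady state in which the
#' effluent-influent concentration difference is time-invariant (typically
#' after ~3 days). This finds the largest trailing window, starting at or
#' after `min_day`, in which the fitted linear trend of the concentration
#' difference, relative to its window mean, stays below `slope_tol`.
#'
#' @param series one core-and-species incubation series: a data frame with
#'   columns `time_d`, `influent_uM`, `effluent_uM` (times strictly
#'   increasing).
#' @param min_day earliest allowed window start, days (default 3).
#' @param slope_tol maximum tolerated relative trend, fraction per day
#'   (default 0.05).
#' @param scale_floor concentration floor (micromolar) used as the trend
#'   denominator when the mean difference is near zero (default 0.05).
#' @return A list `window` with `t_start`, `t_end`, `n_points`.
#' @export
detect_steady_state <- function(series, min_day = 3, slope_tol = 0.05,
                                scale_floor = 0.05) {
  stopifnot(is.data.frame(series),
            all(c("time_d", "influent_uM", "effluent_uM") %in% names(series)))
  check_number(min_day, "min_day", min = 0)
  check_number(slope_tol, "slope_tol", min = 0)
  t <- series$time_d
  if (is.unsorted(t, strictly = TRUE)) {
    stop_invalid("`time_d` must be strictly increasing.")
  }
  d <- series$effluent_uM - series$influent_uM
  candidates <- which(t >= min_day)
  candidates <- candidates[candidates <= length(t) - 2L]  # need >= 3 points
  if (!length(candidates)) {
    abort("fewer than 3 points at or after `min_day`.",
          class = c("n2osource_no_steady_state", "n2osource_error"))
  }
  for (i in candidates) {
    idx <- i:length(t)
    slope <- coef(lm(d[idx] ~ t[idx]))[2]
    rel <- abs(slope) / max(abs(mean(d[idx])), scale_floor)
    if (is.finite(rel) && rel <= slope_tol) {
      return(list(t_start = t[i], t_end = t[length(t)], n_points = length(idx)))
    }
  }
  abort("no trailing window satisfies the steady-state trend tolerance.",
        class = c("n2osource_no_steady_state", "n2osource_error"))
}

flux_unit <- function(species) {
  ifelse(toupper(species) == "N2O", "umol m-2 d-1", "mmol m-2 d-1")
}

#' Steady-state benthic flux from a flow-through incubation
#'
#' Computes the mass flux as (effluent - influent) x flow rate / area,
#' averaged over the steady-state window; negative fluxes denote uptake by
#' the sediment. Per-timepoint fluxes are averaged, which equals the flux of
#' the averaged concentration difference when the flow rate is constant.
#' The flux s.d. combines the scatter of the concentration difference and
#' of the flow rate by independent first-order propagation.
#'
#' @param series one core-and-species incubation series: a data frame with
#'   columns `time_d`, `influent_uM`, `effluent_uM`, `flow_mL_min`, and
#'   optionally `core_id`, `species`.
#' @param window steady-state window from [detect_steady_state()], or `NULL`
#'   to detect it here.
#' @param area sediment surface area in m^2 (default [core_area()] of the
#'   standard liner).
#' @param ... passed to [detect_steady_state()] when `window` is `NULL`.
#' @return A one-row tibble: `core_id`, `species`, `flux`, `flux_sd`,
#'   `unit` (mmol m-2 d-1, or umol m-2 d-1 for N2O), `t_start`, `t_end`,
#'   `n_points`.
#' @export
compute_flux <- function(series, window = NULL, area = core_area(), ...) {
  stopifnot(is.data.frame(series),
            all(c("time_d", "influent_uM", "effluent_uM", "flow_mL_min")
                %in% names(series)))
  check_number(area, "area", min = 1e-12)
  if (any(series$flow_mL_min <= 0)) stop_invalid("`flow_mL_min` must be positive.")
  if (is.null(window)) window <- detect_steady_state(series, ...)
  idx <- series$time_d >= window$t_start & series$time_d <= window$t_end
  if (sum(idx) < 2L) {
    abort("steady-state window holds fewer than 2 points.",
          class = c("n2osource_insufficient_data", "n2osource_error"))
  }
  w <- series[idx, ]
  species <- w$species[1] %||% NA_character_
  d_uM <- w$effluent_uM - w$influent_uM              # umol / L
  r_Ld <- w$flow_mL_min * 1440 / 1000                # L / d
  flux_umol <- mean(d_uM) * mean(r_Ld) / area        # umol m-2 d-1
  # independent first-order propagation of the s.d. of mean(d) and mean(r)
  sd_d <- if (nrow(w) > 1) sd(d_uM) else 0
  sd_r <- if (nrow(w) > 1) sd(r_Ld) else 0
  sd_umol <- sqrt((mean(r_Ld) / area * sd_d)^2 + (mean(d_uM) / area * sd_r)^2)
  scale <- if (identical(toupper(species), "N2O")) 1 else 1e-3
  tibble::tibble(
    core_id = w$core_id[1] %||% NA_character_,
    species = species,
    flux = flux_umol * scale,
    flux_sd = sd_umol * scale,
    unit = flux_unit(species %||% ""),
    t_start = window$t_start, t_end = window$t_end, n_points = nrow(w)
  )
}

#' Steady-state fluxes for a whole incubation table
#'
#' Data-frame-first wrapper: splits a long incubation table by core and
#' species, detects each steady-state window and computes each flux.
#'
#' @param data long incubation table with columns `core_id`, `species`,
#'   `time_d`, `influent_uM`, `effluent_uM`, `flow_mL_min`.
#' @param min_day,slope_tol passed to [detect_steady_state()].
#' @param area sediment surface area, m^2.
#' @return A tibble of class `n2o_flux`, one row per core and species.
#' @export
estimate_fluxes <- function(data, min_day = 3, slope_tol = 0.05,
                            area = core_area()) {
  stopifnot(is.data.frame(data),
            all(c("core_id", "species", "time_d", "influent_uM",
                  "effluent_uM", "flow_mL_min") %in% names(data)))
  out <- data |>
    dplyr::group_by(.data$core_id, .data$species) |>
    dplyr::group_modify(function(g, key) {
      g <- dplyr::arrange(g, .data$time_d)
      g$core_id <- key$core_id
      g$species <- key$species
      w <- detect_steady_state(g, min_day = min_day, slope_tol = slope_tol)
      compute_flux(g, window = w, area = area)[-(1:2)]
    }) |>
    dplyr::ungroup()
  class(out) <- c("n2o_flux", class(out))
  out
}
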