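#' Tidy a process_fractions object
#'
#' @param x a `process_fractions` from [partition_core()] or
#'   [solve_fractions()].
#' @param ... unused.
#' @return A tibble with one row per process: `process`, `f_raw`, `f`
#'   (clipped, `NA` if not yet clipped), `f_red`.
#' @method tidy process_fractions
#' @export
tidy.process_fractions <- function(x, ...) {
  tibble::tibble(
    process = names(x$f_raw),
    f_raw = unname(x$f_raw),
    f = if (is.null(x$f)) NA_real_ else unname(x$f),
    f_red = x$f_red
  )
}

#' @rdname tidy.process_fractions
#' @method glance process_fractions
#' @export
glance.process_fractions <- function(x, ...) {
  tibble::tibble(f_red = x$f_red, residual_norm = x$residual_norm,
                 feasible = x$feasible,
                 clipped = !is.null(x$f))
}

#' Tidy a Monte Carlo partition
#'
#' @param x an `n2o_mc` from [run_monte_carlo()].
#' @param ... unused.
#' @return `tidy()`: the per-process summary tibble (mean, s.d., 2.5/50/97.5
#'   percentiles of the clipped draws) with `core_id` and `f_red`.
#'   `glance()`: a one-row run summary.
#' @method tidy n2o_mc
#' @export
tidy.n2o_mc <- function(x, ...) {
  dplyr::mutate(x$summary, core_id = x$core_id, f_red = x$f_red, .before = 1)
}

#' @rdname tidy.n2o_mc
#' @method glance n2o_mc
#' @export
glance.n2o_mc <- function(x, ...) {
  tibble::tibble(
    core_id = x$core_id, f_red = x$f_red, n_draws = x$n_draws,
    n_infeasible = x$n_infeasible, infeasible_frac = x$infeasible_frac,
    high_infeasible = x$high_infeasible,
    seed = x$seed %||% NA_integer_, config_hash = x$config_hash
  )
}
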