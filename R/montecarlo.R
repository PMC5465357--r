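mc_measurement_fields <- function() required_partition_fields()

#' Monte Carlo uncertainty propagation for one core's partition
#'
#' Propagates both measurement uncertainty (the s.d. of each steady-state
#' isotope composition) and endmember uncertainty (the s.d. of each
#' endmember dd15n and SP, and of the AMO kinetic offset) through the
#' mass-balance inversion. Per draw, every uncertain quantity is perturbed
#' by an independent Gaussian, the four-process system is rebuilt and
#' solved, and the raw solution is clipped to the simplex; draws whose raw
#' solution falls outside \[-`feas_tol`, 1 + `feas_tol`\] (or whose drawn
#' NO2- 17O-excess drops below the informative floor) are counted as
#' infeasible and excluded from the summaries.
#'
#' @param record one core's steady-state record (one-row data frame or named
#'   list); every measurement used must carry a companion `<field>_sd`.
#' @param ems an [endmember_set()].
#' @param f_red prescribed N2O-reduction fraction in \[0, 1\].
#' @param n_draws number of Monte Carlo draws (default 10000).
#' @param seed optional integer seed for reproducibility.
#' @param floor,feas_tol as in [partition_core()].
#' @return An object of class `n2o_mc`: a list with `summary` (tibble of
#'   per-process mean, s.d. and 2.5/50/97.5 percentiles of the clipped
#'   draws), `point` (the unperturbed `process_fractions`), `n_draws`,
#'   `n_infeasible`, `infeasible_frac`, `high_infeasible` (flag raised when
#'   more than half the draws are infeasible), `seed`, `f_red`,
#'   `config_hash`.
#' @examples
#' rec <- list(core_id = "HN-1",
#'             d15n_no3 = 4.6, d15n_no3_sd = 0.2,
#'             d15n_n2o = 0.0, d15n_n2o_sd = 0.6,
#'             sp_n2o = 16.2, sp_n2o_sd = 5.0,
#'             cap17o_no2 = 8.5, cap17o_no2_sd = 2.4,
#'             cap17o_n2o = 6.5, cap17o_n2o_sd = 1.2,
#'             d15n_trn = 11.9, d15n_trn_sd = 1.1)
#' run_monte_carlo(rec, default_endmembers(), f_red = 0.1,
#'                 n_draws = 500, seed = 1)
#' @export
run_monte_carlo <- function(record, ems = default_endmembers(), f_red = 0.1,
                            n_draws = 10000, seed = NULL,
                            floor = 1, feas_tol = 0.02) {
  stopifnot(inherits(ems, "endmember_set"))
  record <- as_record_list(record)
  check_number(f_red, "f_red", min = 0, max = 1)
  if (!is.numeric(n_draws) || n_draws < 100) {
    stop_invalid("`n_draws` must be at least 100.")
  }
  n_draws <- as.integer(n_draws)
  if (!is.null(seed)) set.seed(as.integer(seed))

  # point estimate from the unperturbed record
  point <- partition_core(record, ems, f_red = f_red, floor = floor,
                          feas_tol = feas_tol)

  fields <- mc_measurement_fields()
  meas <- matrix(NA_real_, n_draws, length(fields),
                 dimnames = list(NULL, fields))
  for (field in fields) {
    mu <- record[[field]]
    sigma <- record[[paste0(field, "_sd")]]
    if (is.null(sigma) || is.na(sigma)) {
      abort(paste0("record lacks the s.d. `", field, "_sd` required for ",
                   "Monte Carlo propagation."),
            class = c("n2osource_missing_measurement", "n2osource_error"))
    }
    meas[, field] <- rnorm(n_draws, mu, sigma)
  }

  # endmember draws: dd15n for the non-AMO processes, sp for all, amo eps
  procs <- ems$process
  i_amo <- which(procs == "AMO")
  dd_draw <- sapply(seq_along(procs), function(j) {
    if (j == i_amo) rep(0, n_draws)      # filled per draw from pools + eps
    else rnorm(n_draws, ems$dd15n[j], ems$dd15n_sd[j])
  })
  sp_draw <- sapply(seq_along(procs), function(j) {
    rnorm(n_draws, ems$sp[j], ems$sp_sd[j])
  })
  eps_draw <- rnorm(n_draws, attr(ems, "amo_eps"), attr(ems, "amo_eps_sd"))

  sp_eps_red <- attr(ems, "sp_eps_red")
  n15_eps_red <- attr(ems, "n15_eps_red")
  o_t <- ems$o_transfer
  ones <- rep(1, 4)

  clipped <- matrix(NA_real_, n_draws, 4, dimnames = list(NULL, procs))
  n_infeasible <- 0L
  for (i in seq_len(n_draws)) {
    c17_no2 <- meas[i, "cap17o_no2"]
    if (abs(c17_no2) < floor) { n_infeasible <- n_infeasible + 1L; next }
    dd <- dd_draw[i, ]
    dd[i_amo] <- (meas[i, "d15n_no3"] - meas[i, "d15n_trn"]) + eps_draw[i]
    A <- rbind(ones, o_t, dd, sp_draw[i, ])
    b <- c(1,
           meas[i, "cap17o_n2o"] / c17_no2,
           (meas[i, "d15n_no3"] - meas[i, "d15n_n2o"]) + f_red * n15_eps_red,
           meas[i, "sp_n2o"] + f_red * sp_eps_red)
    f <- tryCatch(solve(A, b), error = function(e) NULL)
    if (is.null(f) || any(f < -feas_tol) || any(f > 1 + feas_tol)) {
      n_infeasible <- n_infeasible + 1L
      next
    }
    f <- pmax(f, 0)
    clipped[i, ] <- f / sum(f)
  }

  keep <- !is.na(clipped[, 1])
  if (!any(keep)) {
    abort("all Monte Carlo draws were infeasible.",
          class = c("n2osource_infeasible", "n2osource_error"))
  }
  infeasible_frac <- n_infeasible / n_draws
  high_infeasible <- infeasible_frac > 0.5
  if (high_infeasible) {
    warn(sprintf("More than half of the Monte Carlo draws (%.1f%%) were infeasible; summaries describe the feasible subset only.",
                 100 * infeasible_frac))
  }
  kept <- clipped[keep, , drop = FALSE]
  qs <- apply(kept, 2, quantile, probs = c(0.025, 0.5, 0.975), names = FALSE)
  summary <- tibble::tibble(
    process = procs,
    mean = unname(colMeans(kept)),
    sd = unname(apply(kept, 2, sd)),
    q025 = unname(qs[1, ]), q50 = unname(qs[2, ]), q975 = unname(qs[3, ])
  )
  structure(list(
    summary = summary,
    point = point,
    n_draws = n_draws,
    n_infeasible = n_infeasible,
    infeasible_frac = infeasible_frac,
    high_infeasible = high_infeasible,
    seed = seed,
    f_red = f_red,
    core_id = record$core_id %||% NA_character_,
    config_hash = endmember_hash(ems)
  ), class = "n2o_mc")
}

#' @export
print.n2o_mc <- function(x, ...) {
  cat("<n2o_mc>  core:", x$core_id, " f_red =", format(x$f_red),
      " draws:", x$n_draws,
      sprintf(" infeasible: %.1f%%", 100 * x$infeasible_frac), "\n")
  print(as.data.frame(x$summary), digits = 3, row.names = FALSE)
  invisible(x)
}

#' Monte Carlo partitions for many cores
#'
#' Data-frame-first wrapper around [run_monte_carlo()]. Per-core seeds are
#' derived deterministically from `seed`, so the whole table is reproducible
#' from a single integer.
#'
#' @inheritParams run_monte_carlo
#' @param records a data frame of steady-state records, one row per core.
#' @param f_red numeric vector of reduction fractions to evaluate.
#' @param seed master seed (integer) for the per-core seed stream.
#' @return A tibble of class `n2o_mc_tbl`: one row per core, f_red and
#'   process with the clipped-draw summaries plus `infeasible_frac`,
#'   `n_draws`, `seed` and `config_hash`.
#' @export
mc_partition <- function(records, ems = default_endmembers(),
                         f_red = c(0.1, 0.9), n_draws = 10000, seed = NULL,
                         floor = 1, feas_tol = 0.02) {
  stopifnot(is.data.frame(records), nrow(records) > 0)
  combos <- tidyr::expand_grid(i = seq_len(nrow(records)), fr = f_red)
  if (!is.null(seed)) set.seed(as.integer(seed))
  combos$run_seed <- sample.int(.Machine$integer.max, nrow(combos))
  out <- purrr::pmap_dfr(combos, function(i, fr, run_seed) {
    rec <- records[i, ]
    mc <- run_monte_carlo(rec, ems, f_red = fr, n_draws = n_draws,
                          seed = run_seed, floor = floor, feas_tol = feas_tol)
    dplyr::mutate(mc$summary,
                  core_id = mc$core_id, f_red = fr,
                  point = unname(mc$point$f),
                  infeasible_frac = mc$infeasible_frac,
                  n_draws = mc$n_draws, seed = run_seed,
                  config_hash = mc$config_hash,
                  .before = 1)
  })
  out <- dplyr::relocate(out, "core_id", "f_red", "process")
  class(out) <- c("n2o_mc_tbl", class(out))
  out
}
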