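#' Build the four-process isotope mass-balance system
#'
#' Assembles the linear system whose solution is the vector of fractional
#' contributions f of the four active N2O production processes. The four
#' rows are:
#' \enumerate{
#'   \item closure: \eqn{\sum_i f_i = 1};
#'   \item 17O-excess balance: \eqn{\sum_i f_i\, o_i = }\code{o_ratio_meas},
#'     where \eqn{o_i} is each process's O-transfer coefficient — N2O
#'     reduction is mass-dependent and leaves this row untouched;
#'   \item delta-15N offset balance:
#'     \eqn{\sum_i f_i\, \Delta\delta^{15}N_i - f_{red}\,\epsilon^{15}_{red} = }
#'     \code{dd15n_meas};
#'   \item site-preference balance:
#'     \eqn{\sum_i f_i\, SP_i - f_{red}\,\epsilon^{SP}_{red} = }\code{sp_meas},
#'     with \eqn{\epsilon^{SP}_{red} = -6} permil by default, so a larger
#'     prescribed reduction fraction shifts the measured SP up relative to
#'     the production-weighted mean.
#' }
#'
#' @param dd15n_meas measured steady-state delta-15N(NO3-) - delta-15N(N2O),
#'   permil.
#' @param sp_meas measured N2O site preference, permil.
#' @param o_ratio_meas measured cap-delta-17O(N2O) / cap-delta-17O(NO2-),
#'   dimensionless (see [precursor_fraction()]).
#' @param ems an [endmember_set()] whose AMO `dd15n` has been filled in
#'   (see [amo_dd15n()]).
#' @param f_red prescribed fraction of gross N2O production consumed by
#'   bacterial N2O reduction, in \[0, 1\].
#' @return A list with elements `A` (4x4 matrix, unknowns in endmember
#'   order), `b` (right-hand side), `processes`, `f_red`.
#' @export
build_system <- function(dd15n_meas, sp_meas, o_ratio_meas, ems, f_red) {
  stopifnot(inherits(ems, "endmember_set"))
  check_finite(dd15n_meas, "dd15n_meas")
  check_finite(sp_meas, "sp_meas")
  check_finite(o_ratio_meas, "o_ratio_meas")
  check_number(f_red, "f_red", min = 0, max = 1)
  if (any(is.na(ems$dd15n))) {
    stop_invalid(paste("endmember dd15n contains NA (the AMO endmember must be",
                       "injected via amo_dd15n() before building the system)."))
  }
  A <- rbind(rep(1, 4), ems$o_transfer, ems$dd15n, ems$sp)
  dimnames(A) <- list(c("closure", "o_ratio", "dd15n", "sp"), ems$process)
  b <- c(closure = 1,
         o_ratio = o_ratio_meas,
         dd15n = dd15n_meas + f_red * attr(ems, "n15_eps_red"),
         sp = sp_meas + f_red * attr(ems, "sp_eps_red"))
  if (qr(A)$rank < 4L) {
    sig <- apply(A, 2, paste, collapse = "/")
    dup <- ems$process[duplicated(sig) | duplicated(sig, fromLast = TRUE)]
    offender <- if (length(dup)) paste(dup, collapse = ", ") else
      paste(ems$process, collapse = ", ")
    abort(paste0("endmember geometry is collinear (processes: ", offender,
                 "); the four-process system cannot be solved."),
          class = c("n2osource_collinear", "n2osource_error"))
  }
  list(A = A, b = b, processes = ems$process, f_red = f_red)
}

#' Solve the mass-balance system for raw process fractions
#'
#' Exact linear solution of the system built by [build_system()]. Raw
#' fractions may fall outside \[0, 1\] when the measured composition lies
#' outside the endmember simplex; the solution is flagged infeasible when any
#' fraction is below `-feas_tol` or above `1 + feas_tol`.
#'
#' @param system output of [build_system()].
#' @param feas_tol feasibility tolerance on the raw fractions (default 0.02).
#' @return A `process_fractions` object: list with `f_raw` (named), `f`
#'   (clipped fractions, `NULL` until [clip_renormalize()]), `f_red`,
#'   `residual_norm`, `feasible`.
#' @export
solve_fractions <- function(system, feas_tol = 0.02) {
  check_number(feas_tol, "feas_tol", min = 0)
  f <- tryCatch(solve(system$A, system$b), error = function(e) {
    abort(paste0("singular mass-balance system: ", conditionMessage(e)),
          class = c("n2osource_collinear", "n2osource_error"))
  })
  names(f) <- system$processes
  structure(list(
    f_raw = f,
    f = NULL,
    f_red = system$f_red,
    residual_norm = sqrt(sum((system$A %*% f - system$b)^2)),
    feasible = all(f >= -feas_tol & f <= 1 + feas_tol)
  ), class = "process_fractions")
}

#' Clip negative fractions and renormalise to the simplex
#'
#' Small negative raw fractions are set to zero and the remaining fractions
#' rescaled to sum to one — the presentation rule used for stacked source
#' contributions. Idempotent.
#'
#' @param x a `process_fractions` object or a named numeric vector of raw
#'   fractions.
#' @return Same type as the input, with clipped fractions (in the `f` field
#'   for `process_fractions` input).
#' @examples
#' clip_renormalize(c(bDNF = 0.5, fDNF = 0.6, AMO = -0.1, nDNF = 0))
#' @export
clip_renormalize <- function(x) {
  if (inherits(x, "process_fractions")) {
    x$f <- clip_renormalize(x$f_raw)
    return(x)
  }
  check_finite(x, "fractions")
  y <- pmax(x, 0)
  tot <- sum(y)
  if (tot <= 0) {
    abort("all fractions are non-positive; nothing to renormalise.",
          class = c("n2osource_infeasible", "n2osource_error"))
  }
  y / tot
}

#' Forward model: compose measurements from known process fractions
#'
#' Exact linear composition of the three measured quantities (delta-15N
#' offset, site preference, 17O-excess ratio) from prescribed fractional
#' contributions, endmembers, and reduction fraction — the inverse of
#' [solve_fractions()], used by the synthetic-data generator and for
#' validation.
#'
#' @param f named numeric vector of fractional contributions over the active
#'   processes; must be non-negative and sum to 1 (within 1e-6).
#' @param ems an [endmember_set()] with AMO dd15n filled in.
#' @param f_red prescribed N2O-reduction fraction in \[0, 1\].
#' @return A list with `dd15n_meas`, `sp_meas`, `o_ratio_meas`.
#' @export
forward_model <- function(f, ems, f_red = 0) {
  stopifnot(inherits(ems, "endmember_set"))
  check_number(f_red, "f_red", min = 0, max = 1)
  if (is.null(names(f)) || !setequal(names(f), ems$process)) {
    stop_invalid("`f` must be named by the active processes of `ems`.")
  }
  f <- f[ems$process]
  check_finite(f, "f")
  if (any(f < -1e-9) || abs(sum(f) - 1) > 1e-6) {
    stop_invalid("`f` must be a feasible composition (non-negative, summing to 1).")
  }
  if (any(is.na(ems$dd15n))) {
    stop_invalid("endmember dd15n contains NA; inject the AMO endmember first.")
  }
  list(
    dd15n_meas = sum(f * ems$dd15n) - f_red * attr(ems, "n15_eps_red"),
    sp_meas = sum(f * ems$sp) - f_red * attr(ems, "sp_eps_red"),
    o_ratio_meas = sum(f * ems$o_transfer)
  )
}

# fill the data-dependent AMO endmember from a record's steady-state pools
inject_amo <- function(ems, d15n_no3, d15n_trn, eps = attr(ems, "amo_eps")) {
  i <- which(ems$process == "AMO")
  ems$dd15n[i] <- amo_dd15n(d15n_no3, d15n_trn, eps)
  # first-order s.d. for the AMO dd15n (used only for reporting; the Monte
  # Carlo perturbs the underlying pools and eps directly)
  ems$dd15n_sd[i] <- attr(ems, "amo_eps_sd")
  ems
}

#' Partition one core's N2O flux among production processes
#'
#' End-to-end inversion for a single steady-state record: computes the
#' measured delta-15N offset (delta-15N NO3- minus delta-15N N2O), the
#' 17O-excess ratio via [precursor_fraction()], injects the data-dependent
#' AMO endmember via [amo_dd15n()], then builds, solves and clips the
#' four-process system. Requires the record fields `d15n_no3`, `d15n_n2o`,
#' `sp_n2o`, `cap17o_no2`, `cap17o_n2o` and `d15n_trn` (the TRN delta-15N is
#' used as the proxy for the NH4+ substrate); a missing field raises an
#' error naming it, which is how records from incubations without a nitrate
#' 17O label (no measurable cap-delta-17O) are rejected.
#'
#' @param record one core's steady-state record: a one-row data frame or
#'   named list (see [read_steady_table()] for the schema).
#' @param ems an [endmember_set()].
#' @param f_red prescribed N2O-reduction fraction in \[0, 1\].
#' @param floor informative-anomaly floor passed to [precursor_fraction()].
#' @param feas_tol feasibility tolerance passed to [solve_fractions()].
#' @return A `process_fractions` object with raw (`f_raw`) and clipped (`f`)
#'   fractions.
#' @examples
#' rec <- list(d15n_no3 = 4.6, d15n_n2o = 0.0, sp_n2o = 16.2,
#'             cap17o_no2 = 8.5, cap17o_n2o = 6.5, d15n_trn = 11.9)
#' partition_core(rec, default_endmembers(), f_red = 0.1)
#' @export
partition_core <- function(record, ems = default_endmembers(), f_red = 0.1,
                           floor = 1, feas_tol = 0.02) {
  stopifnot(inherits(ems, "endmember_set"))
  record <- as_record_list(record)
  for (field in required_partition_fields()) {
    v <- record[[field]]
    if (is.null(v) || length(v) != 1L || is.na(v)) {
      abort(paste0("record is missing required measurement `", field, "`",
                   if (!is.null(record$core_id)) paste0(" (core ", record$core_id, ")"),
                   "; cores without it cannot be partitioned."),
            class = c("n2osource_missing_measurement", "n2osource_error"),
            field = field)
    }
  }
  ems <- inject_amo(ems, record$d15n_no3, record$d15n_trn)
  dd15n_meas <- record$d15n_no3 - record$d15n_n2o
  o_ratio <- precursor_fraction(record$cap17o_n2o, record$cap17o_no2, floor = floor)
  sys <- build_system(dd15n_meas, record$sp_n2o, o_ratio, ems, f_red)
  pf <- solve_fractions(sys, feas_tol = feas_tol)
  clip_renormalize(pf)
}

#' @export
print.process_fractions <- function(x, ...) {
  cat("<process_fractions>  f_red =", format(x$f_red), "\n")
  m <- rbind(raw = x$f_raw, clipped = if (is.null(x$f)) rep(NA_real_, length(x$f_raw)) else x$f)
  print(round(m, 4))
  cat("residual_norm:", format(x$residual_norm, digits = 3),
      " feasible:", x$feasible, "\n")
  invisible(x)
}

#' Partition many cores across prescribed reduction scenarios
#'
#' Data-frame-first wrapper around [partition_core()]: one row of output per
#' core, reduction fraction and process, carrying both the raw (diagnostic)
#' and clipped (presentation) fractions plus provenance columns.
#'
#' @param records a data frame of steady-state records, one row per core
#'   (schema of [read_steady_table()]).
#' @param ems an [endmember_set()].
#' @param f_red numeric vector of prescribed N2O-reduction fractions to
#'   evaluate (default `c(0.1, 0.9)`, a low- and a high-consumption
#'   scenario).
#' @param floor,feas_tol passed to [partition_core()].
#' @return A tibble of class `n2o_partition` with columns `core_id`,
#'   `f_red`, `process`, `f_raw`, `f`, `residual_norm`, `feasible`,
#'   `config_hash`.
#' @export
partition_n2o <- function(records, ems = default_endmembers(),
                          f_red = c(0.1, 0.9), floor = 1, feas_tol = 0.02) {
  stopifnot(is.data.frame(records), nrow(records) > 0)
  check_number(f_red, "f_red", min = 0, max = 1)
  hash <- endmember_hash(ems)
  out <- purrr::map_dfr(seq_len(nrow(records)), function(i) {
    rec <- records[i, ]
    purrr::map_dfr(f_red, function(fr) {
      pf <- partition_core(rec, ems, f_red = fr, floor = floor,
                           feas_tol = feas_tol)
      tibble::tibble(
        core_id = rec$core_id %||% as.character(i),
        f_red = fr,
        process = names(pf$f_raw),
        f_raw = unname(pf$f_raw),
        f = unname(pf$f),
        residual_norm = pf$residual_norm,
        feasible = pf$feasible
      )
    })
  })
  out$config_hash <- hash
  class(out) <- c("n2o_partition", class(out))
  out
}
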