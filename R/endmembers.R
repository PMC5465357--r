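n2o_processes <- c("bDNF", "fDNF", "cDNF", "AMO", "nDNF")

#' Construct an endmember set
#'
#' An endmember set describes, for each of four active N2O production
#' processes, the isotopic signature used by the mass-balance inversion:
#' the steady-state delta-15N offset between NO3- and the emitted N2O
#' (`dd15n`, permil, positive when N2O is depleted relative to NO3-), the
#' N2O site preference (`sp`, permil), and the O-transfer coefficient
#' (`o_transfer`, the factor multiplying the steady-state NO2- 17O-excess in
#' the cap-delta-17O balance: 1 for processes using the ambient NO2-/NO3-
#' pool, 0 for processes whose O derives from O2/H2O or nitrifier-internal
#' NO2-). Exactly one of fungal denitrification (`fDNF`) and
#' chemodenitrification (`cDNF`) is active at a time; they occupy the same
#' high-SP, NO2--consuming role and are considered as alternative cases.
#'
#' The `AMO` endmember's `dd15n` is data-dependent (it is built from the
#' steady-state delta-15N difference between NO3- and the reduced-N pool plus
#' the kinetic offset `amo_eps`; see [amo_dd15n()]) and is therefore `NA`
#' until injected by [partition_core()].
#'
#' @param endmembers a data frame with columns `process`, `dd15n`,
#'   `dd15n_sd`, `sp`, `sp_sd`, `o_transfer` (one row per active process).
#' @param sp_eps_red kinetic isotope effect on SP for respiratory N2O
#'   reduction, permil (default -6; reduction enriches the residual N2O in SP).
#' @param n15_eps_red corresponding effect on the dd15n balance, permil
#'   (default 0: the delta-15N balance carries no explicit reduction term).
#' @param amo_eps,amo_eps_sd kinetic delta-15N offset between NH3 and N2O for
#'   ammonia oxidation, permil (default 3.7 +/- 3; N2O depleted vs NH3).
#' @return An `endmember_set`: a tibble with the reduction and AMO constants
#'   attached as attributes.
#' @seealso [default_endmembers()], [read_endmembers()]
#' @export
endmember_set <- function(endmembers, sp_eps_red = -6, n15_eps_red = 0,
                          amo_eps = 3.7, amo_eps_sd = 3) {
  req <- c("process", "dd15n", "dd15n_sd", "sp", "sp_sd", "o_transfer")
  missing_cols <- setdiff(req, names(endmembers))
  if (length(missing_cols)) {
    stop_invalid(paste0("endmember table lacks column(s): ",
                        paste(missing_cols, collapse = ", ")),
                 class = "n2osource_config_error")
  }
  em <- tibble::as_tibble(endmembers)[req]
  if (!all(em$process %in% n2o_processes)) {
    stop_invalid(paste0("unknown process name(s): ",
                        paste(setdiff(em$process, n2o_processes), collapse = ", ")),
                 class = "n2osource_config_error")
  }
  if (anyDuplicated(em$process)) {
    stop_invalid("duplicated process in endmember table.",
                 class = "n2osource_config_error")
  }
  if (nrow(em) != 4L || sum(c("fDNF", "cDNF") %in% em$process) != 1L ||
      !all(c("bDNF", "AMO", "nDNF") %in% em$process)) {
    stop_invalid(paste("an endmember set must contain bDNF, AMO, nDNF and exactly",
                       "one of fDNF/cDNF."), class = "n2osource_config_error")
  }
  check_number(em$o_transfer, "o_transfer", min = 0, max = 1)
  sd_cols <- c(em$dd15n_sd[em$process != "AMO"], em$sp_sd)
  if (any(!is.finite(sd_cols)) || any(sd_cols < 0)) {
    stop_invalid("endmember s.d. values must be finite and non-negative.",
                 class = "n2osource_config_error")
  }
  check_number(sp_eps_red, "sp_eps_red")
  check_number(n15_eps_red, "n15_eps_red")
  check_number(amo_eps, "amo_eps")
  check_number(amo_eps_sd, "amo_eps_sd", min = 0)
  # canonical process order: mixing processes first, AMO-side last
  ord <- order(match(em$process, n2o_processes))
  em <- em[ord, ]
  structure(em,
            class = c("endmember_set", class(tibble::tibble())),
            sp_eps_red = sp_eps_red, n15_eps_red = n15_eps_red,
            amo_eps = amo_eps, amo_eps_sd = amo_eps_sd)
}

#' Default endmember sets
#'
#' A literature-guided default parameterisation of the four-process model,
#' shipped for convenience and fully overridable; these values are working
#' defaults, not an authoritative compilation. Denitrification endmembers
#' carry low dd15n because diffusion limitation suppresses expression of the
#' intrinsic enzyme-level isotope effects in organic-rich sediments. Site
#' preferences: bacterial denitrification and nitrifier-denitrification low
#' (-5 +/- 5 permil), fungal denitrification high (37 +/- 3 permil),
#' chemodenitrification intermediate (16 +/- 5 permil), ammonia oxidation via
#' NH2OH high (33 +/- 4 permil). O-transfer is 1 for the NO2--consuming
#' denitrification pathways, 0 for AMO (O from O2/H2O) and 0 for
#' nitrifier-denitrification (assumed to reduce only nitrifier-internal NO2-
#' carrying no 17O anomaly).
#'
#' @param case `"fDNF"` (case 1, fungal denitrification active; default) or
#'   `"cDNF"` (case 2, chemodenitrification replaces it).
#' @return An [endmember_set()].
#' @examples
#' default_endmembers()
#' default_endmembers("cDNF")
#' @export
default_endmembers <- function(case = c("fDNF", "cDNF")) {
  case <- match.arg(case)
  x_dnf <- if (case == "fDNF") {
    list(process = "fDNF", sp = 37, sp_sd = 3)
  } else {
    list(process = "cDNF", sp = 16, sp_sd = 5)
  }
  em <- tibble::tribble(
    ~process,       ~dd15n, ~dd15n_sd, ~sp,       ~sp_sd,       ~o_transfer,
    "bDNF",         0,      2,         -5,        5,            1,
    x_dnf$process,  0,      2,         x_dnf$sp,  x_dnf$sp_sd,  1,
    "AMO",          NA,     NA,        33,        4,            0,
    "nDNF",         56.9,   5,         -5,        5,            0
  )
  endmember_set(em)
}

#' AMO endmember delta-15N offset on the NO3--referenced scale
#'
#' The ammonia-oxidation endmember is expressed on the common dd15n scale
#' (delta-15N of NO3- minus delta-15N of N2O) by adding the steady-state
#' difference between the NO3- and NH4+ pools to the kinetic NH3-to-N2O
#' offset `eps` (N2O depleted relative to its NH3 source).
#'
#' @param d15n_no3 steady-state delta-15N of NO3-, permil.
#' @param d15n_nh4 steady-state delta-15N of the NH4+ substrate, permil
#'   (the TRN delta-15N is accepted as its proxy).
#' @param eps kinetic NH3-to-N2O offset, permil (default 3.7).
#' @return dd15n of the AMO endmember, permil. Vectorised.
#' @examples
#' amo_dd15n(4.6, 11.9, 3.7)
#' @export
amo_dd15n <- function(d15n_no3, d15n_nh4, eps = 3.7) {
  check_finite(d15n_no3, "d15n_no3")
  check_finite(d15n_nh4, "d15n_nh4")
  check_finite(eps, "eps")
  (d15n_no3 - d15n_nh4) + eps
}

#' Read / write endmember configuration
#'
#' Endmember sets are stored as YAML with top-level keys `endmembers` (a map
#' from process name to `dd15n`, `dd15n_sd`, `sp`, `sp_sd`, `o_transfer`),
#' `reduction` (`sp_eps`, `n15_eps`) and `amo_eps` (`mean`, `sd`). A shipped
#' default lives at
#' `system.file("extdata", "endmembers_default.yml", package = "n2osource")`.
#'
#' @param path file path.
#' @param ems an [endmember_set()].
#' @return `read_endmembers()` returns an [endmember_set()];
#'   `write_endmembers()` returns `path` invisibly.
#' @export
read_endmembers <- function(path) {
  if (!file.exists(path)) {
    stop_invalid(paste0("endmember config not found: ", path),
                 class = "n2osource_config_error")
  }
  cfg <- yaml::read_yaml(path)
  if (is.null(cfg$endmembers)) {
    stop_invalid("endmember config lacks an `endmembers` key.",
                 class = "n2osource_config_error")
  }
  em <- purrr::imap_dfr(cfg$endmembers, function(row, proc) {
    tibble::tibble(process = proc,
                   dd15n = row$dd15n %||% NA_real_,
                   dd15n_sd = row$dd15n_sd %||% NA_real_,
                   sp = row$sp, sp_sd = row$sp_sd,
                   o_transfer = row$o_transfer)
  })
  red <- cfg$reduction %||% list()
  amo <- cfg$amo_eps %||% list()
  endmember_set(em,
                sp_eps_red = red$sp_eps %||% -6,
                n15_eps_red = red$n15_eps %||% 0,
                amo_eps = amo$mean %||% 3.7,
                amo_eps_sd = amo$sd %||% 3)
}

#' @rdname read_endmembers
#' @export
write_endmembers <- function(ems, path) {
  stopifnot(inherits(ems, "endmember_set"))
  rows <- purrr::map(seq_len(nrow(ems)), function(i) {
    r <- as.list(ems[i, c("dd15n", "dd15n_sd", "sp", "sp_sd", "o_transfer")])
    r[!vapply(r, is.na, logical(1))]
  })
  names(rows) <- ems$process
  cfg <- list(
    endmembers = rows,
    reduction = list(sp_eps = attr(ems, "sp_eps_red"),
                     n15_eps = attr(ems, "n15_eps_red")),
    amo_eps = list(mean = attr(ems, "amo_eps"), sd = attr(ems, "amo_eps_sd"))
  )
  yaml::write_yaml(cfg, path)
  invisible(path)
}

#' Configuration hash of an endmember set
#'
#' A short stable hash of all endmember values and constants, carried in
#' every output table for provenance.
#'
#' @param ems an [endmember_set()].
#' @return A character scalar.
#' @export
endmember_hash <- function(ems) {
  stopifnot(inherits(ems, "endmember_set"))
  rlang::hash(list(as.data.frame(ems),
                   attr(ems, "sp_eps_red"), attr(ems, "n15_eps_red"),
                   attr(ems, "amo_eps"), attr(ems, "amo_eps_sd")))
}
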