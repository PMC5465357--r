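# Per-treatment generator defaults: steady-state source compositions (permil),
# measurement noise (1 s.d. of each measured quantity, permil), and
# steady-state concentrations (micromolar). Compositions and dispersions are
# set at the scale observed in nitrate-amendment flow-through incubations of
# organic-rich intertidal sediments; the 17O-excess fields exist only for the
# nitrate-amended treatments (HN/LOHN), which receive an atmospherically
# derived, 17O-anomalous nitrate label.
treatment_defaults <- function() {
  tibble::tribble(
    ~treatment, ~d15n_no3_src, ~d15n_no3_sd, ~cap17o_no3_src, ~cap17o_no3_sd,
    ~cap17o_no2_src, ~cap17o_no2_sd, ~d15n_trn_src, ~d15n_trn_sd,
    ~d15n_n2o_sd, ~cap17o_n2o_sd, ~sp_n2o_sd,
    ~no3_in, ~no3_eff, ~no2_eff, ~nh4_eff, ~n2o_in, ~n2o_eff, ~trn_eff,
    "LN",   14.0, 1.0, NA,   NA,  NA,  NA,  11.9, 1.1, 1.7, NA,  3.4,
      20, 7.5, 2.0, 19, 0.01, 0.058, 40,
    "LOLN", 14.0, 0.6, NA,   NA,  NA,  NA,  11.6, 1.9, 2.0, NA,  3.2,
      20, 9.0, 2.0, 22, 0.01, 0.026, 40,
    "HN",    4.6, 0.2, 14.7, 0.7, 8.5, 1.2, 11.9, 1.1, 0.6, 1.2, 3.0,
      140, 112, 3.5, 23, 0.01, 0.14, 40,
    "LOHN",  5.3, 0.5, 14.7, 0.6, 9.2, 1.2, 12.9, 1.9, 1.1, 1.3, 2.5,
      140, 94, 6.4, 19, 0.01, 0.14, 40
  )
}

#' Construct one core's ground truth
#'
#' A `core_truth` row prescribes everything the forward generator needs: the
#' true process fractions, the true reduction fraction, the source-pool
#' compositions, steady-state concentrations, the exponential approach
#' timescale and the measurement noise levels. Defaults come from the
#' per-treatment generator table; any field can be overridden per core.
#'
#' @param core_id core label.
#' @param treatment one of `"LN"`, `"LOLN"`, `"HN"`, `"LOHN"`.
#' @param f named fractions over `c("bDNF","fDNF","AMO","nDNF")` (or with
#'   `cDNF` in place of `fDNF`); non-negative, summing to 1.
#' @param f_red true N2O-reduction fraction.
#' @param site site label.
#' @param tau exponential approach timescale, days (must be positive).
#' @param ... per-field overrides of the treatment defaults (source
#'   compositions `*_src`, noise `*_sd`, concentrations).
#' @return A one-row tibble of class `core_truth`.
#' @export
core_truth <- function(core_id, treatment = "HN",
                       f = c(bDNF = 45, fDNF = 36, AMO = 12, nDNF = 8) / 101,
                       f_red = 0.1, site = "MD", tau = 1, ...) {
  td <- treatment_defaults()
  if (!treatment %in% td$treatment) {
    stop_invalid(paste0("unknown treatment `", treatment, "`."),
                 class = "n2osource_config_error")
  }
  check_number(f_red, "f_red", min = 0, max = 1)
  if (tau <= 0) stop_invalid("`tau` must be positive.")
  check_finite(f, "f")
  if (any(f < -1e-9) || abs(sum(f) - 1) > 1e-6 || is.null(names(f))) {
    stop_invalid("`f` must be a named, non-negative composition summing to 1.")
  }
  row <- td[td$treatment == treatment, ]
  over <- list(...)
  bad <- setdiff(names(over), names(row))
  if (length(bad)) {
    stop_invalid(paste0("unknown truth field(s): ", paste(bad, collapse = ", ")),
                 class = "n2osource_config_error")
  }
  for (nm in names(over)) row[[nm]] <- over[[nm]]
  out <- dplyr::bind_cols(
    tibble::tibble(core_id = core_id, site = site, treatment = treatment),
    tibble::as_tibble(as.list(setNames(as.numeric(f), paste0("f_", names(f))))),
    tibble::tibble(f_red = f_red, tau = tau),
    row[setdiff(names(row), "treatment")]
  )
  class(out) <- c("core_truth", class(out))
  out
}

truth_fractions <- function(truth) {
  fcols <- grep("^f_(?!red$)", names(truth), perl = TRUE, value = TRUE)
  setNames(as.numeric(truth[1, fcols]), sub("^f_", "", fcols))
}

#' Draw a perturbed endmember realisation
#'
#' Samples one realisation of an endmember set from its own uncertainty
#' (independent Gaussians on each dd15n, SP and the AMO kinetic offset),
#' e.g. to emulate between-core variation in the effective endmembers when
#' calibrating the Monte Carlo intervals.
#'
#' @param ems an [endmember_set()].
#' @return An [endmember_set()] with perturbed means and the same s.d.s.
#' @export
draw_endmembers <- function(ems) {
  stopifnot(inherits(ems, "endmember_set"))
  em <- tibble::as_tibble(ems)
  not_amo <- em$process != "AMO"
  em$dd15n[not_amo] <- rnorm(sum(not_amo), em$dd15n[not_amo], em$dd15n_sd[not_amo])
  em$sp <- rnorm(nrow(em), em$sp, em$sp_sd)
  endmember_set(em,
                sp_eps_red = attr(ems, "sp_eps_red"),
                n15_eps_red = attr(ems, "n15_eps_red"),
                amo_eps = rnorm(1, attr(ems, "amo_eps"), attr(ems, "amo_eps_sd")),
                amo_eps_sd = attr(ems, "amo_eps_sd"))
}

#' Forward-generate one steady-state record from a known truth
#'
#' Composes the noise-free measured quantities from the true fractions via
#' [forward_model()], converts them to absolute pool compositions using the
#' truth's source values (delta-15N of N2O from the NO3- source minus the
#' composed offset; 17O-excess of N2O as the composed O-ratio times the
#' NO2- source anomaly), then adds independent Gaussian measurement noise at
#' the truth's per-field levels. Treatments without a 17O label yield `NA`
#' 17O-excess fields, so such records are (by design) rejected by
#' [partition_core()].
#'
#' @param truth a [core_truth()] row.
#' @param ems the true [endmember_set()] generating the signal.
#' @param seed optional integer seed.
#' @param noise_scale multiplier on all noise s.d.s (0 gives a noise-free
#'   record; default 1).
#' @return A one-row tibble in the steady-state record schema of
#'   [read_steady_table()], including `<field>_sd` columns at the truth's
#'   noise levels.
#' @export
generate_steady_record <- function(truth, ems = default_endmembers(),
                                   seed = NULL, noise_scale = 1) {
  stopifnot(inherits(truth, "core_truth"), inherits(ems, "endmember_set"))
  check_number(noise_scale, "noise_scale", min = 0)
  if (!is.null(seed)) set.seed(as.integer(seed))
  f <- truth_fractions(truth)
  ems_t <- inject_amo(ems, truth$d15n_no3_src, truth$d15n_trn_src)
  fwd <- forward_model(f, ems_t, f_red = truth$f_red)
  labelled <- is.finite(truth$cap17o_no2_src)
  jitter <- function(mu, sd) {
    if (!is.finite(mu)) return(NA_real_)
    mu + rnorm(1, 0, noise_scale * sd)
  }
  tibble::tibble(
    core_id = truth$core_id, site = truth$site, treatment = truth$treatment,
    d15n_no3 = jitter(truth$d15n_no3_src, truth$d15n_no3_sd),
    d15n_no3_sd = truth$d15n_no3_sd,
    cap17o_no3 = jitter(truth$cap17o_no3_src, truth$cap17o_no3_sd),
    cap17o_no3_sd = truth$cap17o_no3_sd,
    cap17o_no2 = jitter(truth$cap17o_no2_src, truth$cap17o_no2_sd),
    cap17o_no2_sd = truth$cap17o_no2_sd,
    d15n_trn = jitter(truth$d15n_trn_src, truth$d15n_trn_sd),
    d15n_trn_sd = truth$d15n_trn_sd,
    d15n_n2o = jitter(truth$d15n_no3_src - fwd$dd15n_meas, truth$d15n_n2o_sd),
    d15n_n2o_sd = truth$d15n_n2o_sd,
    cap17o_n2o = if (labelled)
      jitter(fwd$o_ratio_meas * truth$cap17o_no2_src, truth$cap17o_n2o_sd)
      else NA_real_,
    cap17o_n2o_sd = truth$cap17o_n2o_sd,
    sp_n2o = jitter(fwd$sp_meas, truth$sp_n2o_sd),
    sp_n2o_sd = truth$sp_n2o_sd,
    conc_no3 = truth$no3_eff, conc_no2 = truth$no2_eff,
    conc_nh4 = truth$nh4_eff, conc_n2o = truth$n2o_eff,
    conc_trn = truth$trn_eff
  )
}

#' Forward-generate a flow-through incubation time series
#'
#' Effluent concentrations approach steady state exponentially,
#' \eqn{c(t) = c_{ss} + (c_0 - c_{ss})\,e^{-t/\tau}}, starting from the
#' influent composition; flow rate is jittered around 1.8 mL/min with s.d.
#' 0.06, and additive Gaussian concentration noise is applied per species.
#'
#' @param truth a [core_truth()] row (supplies influent/steady
#'   concentrations and `tau`).
#' @param n_points number of sampling points (at least 6; default 16,
#'   i.e. twice daily).
#' @param seed optional integer seed.
#' @param duration incubation length, days (at least 8; default 8).
#' @param noise_scale multiplier on concentration and flow noise (default 1).
#' @return A long tibble: `core_id`, `species`, `time_d`, `influent_uM`,
#'   `effluent_uM`, `flow_mL_min`.
#' @export
generate_timeseries <- function(truth, n_points = 16, seed = NULL,
                                duration = 8, noise_scale = 1) {
  stopifnot(inherits(truth, "core_truth"))
  if (truth$tau <= 0) stop_invalid("`tau` must be positive.")
  if (n_points < 6) stop_invalid("`n_points` must be at least 6.")
  if (duration < 8) stop_invalid("`duration` must be at least 8 days.")
  if (!is.null(seed)) set.seed(as.integer(seed))
  t <- seq(duration / n_points, duration, length.out = n_points)
  spec <- tibble::tribble(
    ~species, ~c_in,          ~c_ss,          ~conc_sd,
    "NO3",    truth$no3_in,   truth$no3_eff,  1.0,
    "NO2",    0,              truth$no2_eff,  0.2,
    "NH4",    0,              truth$nh4_eff,  0.5,
    "N2O",    truth$n2o_in,   truth$n2o_eff,  0.003
  )
  purrr::pmap_dfr(spec, function(species, c_in, c_ss, conc_sd) {
    eff <- c_ss + (c_in - c_ss) * exp(-t / truth$tau) +
      rnorm(n_points, 0, noise_scale * conc_sd)
    tibble::tibble(
      core_id = truth$core_id, species = species, time_d = t,
      influent_uM = c_in,
      effluent_uM = pmax(eff, 0),
      flow_mL_min = 1.8 + rnorm(n_points, 0, noise_scale * 0.06)
    )
  })
}

#' Generate a full synthetic incubation study
#'
#' Builds a study of `cores_per` cores per site per treatment (default 3
#' sites x 4 treatments x 2 cores = 24 cores). Per core, true process
#' fractions are drawn from a Dirichlet distribution centred on a
#' denitrification-dominated composition (mean bDNF 0.45, fDNF 0.36, AMO
#' 0.12, nDNF 0.08, concentration parameter 10 to allow realistic between-
#' core heterogeneity), the steady-state record is forward-generated with
#' measurement noise, and the concentration time series are simulated.
#'
#' @param sites character vector of site labels (default `c("MD","MX","SD")`).
#' @param treatments subset of `c("LN","LOLN","HN","LOHN")`.
#' @param cores_per cores per site per treatment (default 2).
#' @param ems true [endmember_set()] used for the forward composition.
#' @param f_red true reduction fraction for all cores (default 0.1).
#' @param dirichlet_mean,dirichlet_conc mean composition and concentration
#'   parameter of the truth distribution.
#' @param seed master seed; the whole study is bit-reproducible from it.
#' @param noise_scale multiplier on all noise levels.
#' @return A list of class `n2o_study`: `truths` (one row per core),
#'   `records` (steady-state table), `series` (long incubation table),
#'   `seed`.
#' @export
generate_study <- function(sites = c("MD", "MX", "SD"),
                           treatments = c("LN", "LOLN", "HN", "LOHN"),
                           cores_per = 2, ems = default_endmembers(),
                           f_red = 0.1,
                           dirichlet_mean = c(bDNF = 45, fDNF = 36,
                                              AMO = 12, nDNF = 8) / 101,
                           dirichlet_conc = 10, seed = NULL, noise_scale = 1) {
  if (!is.null(seed)) set.seed(as.integer(seed))
  design <- tidyr::expand_grid(site = sites, treatment = treatments,
                               rep = seq_len(cores_per))
  n <- nrow(design)
  alpha <- dirichlet_mean * dirichlet_conc
  fmat <- sapply(alpha, function(a) rgamma(n, shape = a))
  fmat <- fmat / rowSums(fmat)
  rec_seeds <- sample.int(.Machine$integer.max, n)
  ts_seeds <- sample.int(.Machine$integer.max, n)
  truths <- purrr::map_dfr(seq_len(n), function(i) {
    core_truth(
      core_id = paste(design$site[i], design$treatment[i], design$rep[i], sep = "-"),
      treatment = design$treatment[i],
      f = setNames(fmat[i, ], names(dirichlet_mean)),
      f_red = f_red, site = design$site[i]
    )
  })
  records <- purrr::map_dfr(seq_len(n), function(i) {
    generate_steady_record(truths[i, ], ems, seed = rec_seeds[i],
                           noise_scale = noise_scale)
  })
  series <- purrr::map_dfr(seq_len(n), function(i) {
    generate_timeseries(truths[i, ], seed = ts_seeds[i],
                        noise_scale = noise_scale)
  })
  structure(list(truths = truths, records = records, series = series,
                 seed = seed),
            class = "n2o_study")
}

#' @export
print.n2o_study <- function(x, ...) {
  cat("<n2o_study> ", nrow(x$truths), "cores;",
      nrow(x$series), "time-series rows; seed:",
      if (is.null(x$seed)) "none" else x$seed, "\n")
  print(dplyr::count(x$truths, .data$site, .data$treatment), n = 5)
  invisible(x)
}
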