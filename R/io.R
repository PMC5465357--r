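# Column schema of the steady-state isotope table. Isotope columns are in
# permil, concentrations in micromolar; each measurement may carry a
# companion `<field>_sd` column. Cells "ND" (not detected), "^" (not
# measured) and empty cells parse to NA.
steady_schema <- function() {
  meas <- c("d15n_no3", "cap17o_no3", "d15n_no2", "cap17o_no2",
            "d15n_trn", "d15n_tdn", "d15n_n2o", "cap17o_n2o", "sp_n2o")
  conc <- c("conc_no3", "conc_no2", "conc_nh4", "conc_n2o", "conc_trn",
            "conc_tdn")
  list(id = c("core_id", "site", "treatment"),
       numeric = c(as.vector(rbind(meas, paste0(meas, "_sd"))),
                   as.vector(rbind(conc, paste0(conc, "_sd")))))
}

na_tokens <- c("", "ND", "NA", "^")

read_delim_ext <- function(path) {
  delim <- if (grepl("\\.tsv$|\\.txt$", path, ignore.case = TRUE)) "\t" else ","
  readr::read_delim(path, delim = delim, col_types = readr::cols(.default = "c"),
                    na = character(), trim_ws = TRUE, progress = FALSE,
                    show_col_types = FALSE)
}

parse_numeric_cols <- function(raw, cols, path) {
  for (col in cols) {
    x <- trimws(raw[[col]])
    x[x %in% na_tokens] <- NA
    parsed <- suppressWarnings(as.numeric(x))
    bad <- which(!is.na(x) & is.na(parsed))
    if (length(bad)) {
      abort(sprintf("cannot parse `%s` in %s: line %d, column `%s` (value \"%s\").",
                    raw[[col]][bad[1]], path, bad[1] + 1L, col, raw[[col]][bad[1]]),
            class = c("n2osource_parse_error", "n2osource_error"))
    }
    raw[[col]] <- parsed
  }
  raw
}

#' Read a steady-state isotope table
#'
#' Reads a delimited (comma, or tab for `.tsv`/`.txt`) table of per-core
#' steady-state compositions. Expected columns: identifiers `core_id`,
#' `site`, `treatment`; isotope measurements `d15n_no3`, `cap17o_no3`,
#' `d15n_no2`, `cap17o_no2`, `d15n_trn` (or `d15n_tdn`), `d15n_n2o`,
#' `cap17o_n2o`, `sp_n2o`, each optionally with a `<field>_sd` companion
#' (permil); and optional concentrations `conc_no3`, `conc_no2`, `conc_nh4`,
#' `conc_n2o`, `conc_trn`, `conc_tdn` (micromolar). Cells `ND`, `^` or empty
#' become `NA`. Unknown columns, unparseable cells and duplicated `core_id`
#' raise located errors.
#'
#' @param path file path.
#' @return A tibble, one row per core.
#' @export
read_steady_table <- function(path) {
  if (!file.exists(path)) {
    stop_invalid(paste0("file not found: ", path), class = "n2osource_parse_error")
  }
  raw <- read_delim_ext(path)
  schema <- steady_schema()
  unknown <- setdiff(names(raw), c(schema$id, schema$numeric))
  if (length(unknown)) {
    abort(paste0("unknown column(s) in ", path, ": ",
                 paste(unknown, collapse = ", ")),
          class = c("n2osource_parse_error", "n2osource_error"))
  }
  if (!"core_id" %in% names(raw)) {
    abort(paste0("missing required column `core_id` in ", path),
          class = c("n2osource_parse_error", "n2osource_error"))
  }
  if (anyDuplicated(raw$core_id)) {
    dup <- raw$core_id[duplicated(raw$core_id)][1]
    abort(paste0("duplicate core_id `", dup, "` in ", path),
          class = c("n2osource_parse_error", "n2osource_error"))
  }
  parse_numeric_cols(raw, intersect(schema$numeric, names(raw)), path)
}

#' Write a steady-state isotope table
#'
#' @param records tibble of steady-state records.
#' @param path output path (`.csv`, or `.tsv` for tab-delimited).
#' @return `path`, invisibly.
#' @export
write_steady_table <- function(records, path) {
  stopifnot(is.data.frame(records))
  if (grepl("\\.tsv$", path, ignore.case = TRUE)) {
    readr::write_tsv(records, path)
  } else {
    readr::write_csv(records, path)
  }
  invisible(path)
}

#' Read a long incubation time-series table
#'
#' Expected columns: `core_id`, `species` (NO3, NO2, NH4 or N2O), `time_d`
#' (days since start), `influent_uM`, `effluent_uM` (micromolar),
#' `flow_mL_min`.
#'
#' @param path file path.
#' @return A tibble.
#' @export
read_incubation_series <- function(path) {
  if (!file.exists(path)) {
    stop_invalid(paste0("file not found: ", path), class = "n2osource_parse_error")
  }
  raw <- read_delim_ext(path)
  req <- c("core_id", "species", "time_d", "influent_uM", "effluent_uM",
           "flow_mL_min")
  missing_cols <- setdiff(req, names(raw))
  if (length(missing_cols)) {
    abort(paste0("missing column(s) in ", path, ": ",
                 paste(missing_cols, collapse = ", ")),
          class = c("n2osource_parse_error", "n2osource_error"))
  }
  unknown <- setdiff(names(raw), req)
  if (length(unknown)) {
    abort(paste0("unknown column(s) in ", path, ": ",
                 paste(unknown, collapse = ", ")),
          class = c("n2osource_parse_error", "n2osource_error"))
  }
  parse_numeric_cols(raw, setdiff(req, c("core_id", "species")), path)
}

#' @rdname read_incubation_series
#' @param series tibble in the incubation schema.
#' @export
write_incubation_series <- function(series, path) {
  write_steady_table(series, path)
}
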