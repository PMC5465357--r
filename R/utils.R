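# internal helpers: argument checks that fail loudly with classed conditions,
# so callers (and the Monte Carlo loop) can distinguish failure modes.

stop_invalid <- function(msg, class = "n2osource_invalid_value", ...) {
  abort(msg, class = c(class, "n2osource_error"), ...)
}

check_finite <- function(x, name) {
  if (!is.numeric(x) || any(!is.finite(x))) {
    stop_invalid(sprintf("`%s` must be finite numeric (got %s).", name,
                         paste(utils::head(format(x), 3), collapse = ", ")))
  }
  invisible(x)
}

check_number <- function(x, name, min = -Inf, max = Inf) {
  check_finite(x, name)
  if (any(x < min) || any(x > max)) {
    stop_invalid(sprintf("`%s` must lie in [%s, %s].", name, format(min), format(max)),
                 class = "n2osource_config_error")
  }
  invisible(x)
}

# fields of a steady-state record required by the mass-balance inversion
required_partition_fields <- function() {
  c("d15n_no3", "d15n_n2o", "sp_n2o", "cap17o_no2", "cap17o_n2o", "d15n_trn")
}

as_record_list <- function(record) {
  if (is.data.frame(record)) {
    if (nrow(record) != 1L) {
      stop_invalid("`record` must be a single row (one core).")
    }
    record <- as.list(record)
  }
  if (!is.list(record)) stop_invalid("`record` must be a one-row data frame or named list.")
  record
}
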