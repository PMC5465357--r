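# shared in-code fixtures: the high-nitrate treatment-mean record and
# random generators for property-style tests

hn_mean_record <- function() {
  list(core_id = "HN-mean",
       d15n_no3 = 4.6, d15n_no3_sd = 0.2,
       d15n_n2o = 0.0, d15n_n2o_sd = 0.6,
       sp_n2o = 16.2, sp_n2o_sd = 5.0,
       cap17o_no2 = 8.5, cap17o_no2_sd = 2.4,
       cap17o_n2o = 6.5, cap17o_n2o_sd = 1.2,
       d15n_trn = 11.9, d15n_trn_sd = 1.1)
}

# a random full-rank endmember set (AMO dd15n pre-filled so build_system can
# be used directly, bypassing the per-record AMO injection)
random_endmembers <- function() {
  endmember_set(tibble::tibble(
    process = c("bDNF", "fDNF", "AMO", "nDNF"),
    dd15n = c(runif(2, -5, 5), runif(1, -10, 5), runif(1, 20, 60)),
    dd15n_sd = rep(1, 4),
    sp = c(runif(1, -10, 0), runif(1, 25, 40), runif(1, 25, 40),
           runif(1, -10, 0)),
    sp_sd = rep(1, 4),
    o_transfer = c(1, 1, 0, runif(1, 0, 0.3))
  ))
}

random_simplex <- function(alpha = rep(1, 4)) {
  g <- rgamma(length(alpha), alpha)
  g / sum(g)
}
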