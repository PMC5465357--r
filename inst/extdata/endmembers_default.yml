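# Default endmember configuration for the four-process N2O mass balance
# (case 1: fungal denitrification active). Values are literature-guided
# working defaults, NOT an authoritative compilation; override freely.
# dd15n: steady-state delta15N(NO3-) - delta15N(N2O) offset, permil.
#   Denitrification offsets are prescribed low: diffusion limitation in
#   organic-rich sediments suppresses expression of enzyme-level effects.
# sp: N2O site preference, permil.
# o_transfer: coefficient on the steady-state NO2- 17O-excess in the
#   cap-delta-17O balance (1 = O from the ambient NO2-/NO3- pool, 0 = O from
#   O2/H2O or nitrifier-internal NO2-).
# The AMO dd15n is data-dependent (built per record from the NO3-/TRN
# delta15N difference plus amo_eps) and is therefore not set here.
endmembers:
  bDNF:
    dd15n: 0.0
    dd15n_sd: 2.0
    sp: -5.0
    sp_sd: 5.0
    o_transfer: 1.0
  fDNF:
    dd15n: 0.0
    dd15n_sd: 2.0
    sp: 37.0
    sp_sd: 3.0
    o_transfer: 1.0
  AMO:
    sp: 33.0
    sp_sd: 4.0
    o_transfer: 0.0
  nDNF:
    dd15n: 56.9
    dd15n_sd: 5.0
    sp: -5.0
    sp_sd: 5.0
    o_transfer: 0.0
reduction:
  sp_eps: -6.0   # kinetic isotope effect on SP for N2O reduction, permil
  n15_eps: 0.0   # no explicit reduction term in the delta15N balance
amo_eps:
  mean: 3.7      # kinetic NH3 -> N2O delta15N offset, permil
  sd: 3.0
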