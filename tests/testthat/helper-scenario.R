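# Shared fixtures, built in code. Coarse grids keep unit tests fast; the
# acceptance file runs the reference 15-min grid.

cached_forcing <- local({
  cache <- list()
  function(dt = 2, seed = 1) {
    key <- paste(dt, seed, sep = "_")
    if (is.null(cache[[key]]))
      cache[[key]] <<- generate_forcing(default_bloom_specs(),
                                        environment_spec(),
                                        dt = dt, seed = seed)
    cache[[key]]
  }
})

# a micro forcing record with hand-checkable bacterial kinetics
micro_record <- function() {
  list(time_h = 0,
       B_DA = 100, B_NF = 50, B_OP = 1000,
       mu_DA = 1, mu_NF = 0.5, mu_OP = 100,
       lysis_DA = 0.5, lysis_NF = 0.2, lysis_OP = 100,
       graz_DA = 0.3, graz_NF = 0.1, graz_OP = 0,
       sed_DA = 0.2, sed_OP = 2,
       BC = 50, SBC = 100, bmx = 0.2, k_sbc = 25, y_BC = 0.3,
       T_degC = 10, u10_ms = 5, J_Wm2 = 100, kD_m1 = 0.5, depth_m = 17)
}

zero_bloom_specs <- function() {
  list(bloom_spec("DA", 75, 0, 10, 0),
       bloom_spec("NF", 150, 0, 15, 0),
       bloom_spec("OP", 115, 0, 9, 0))
}
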