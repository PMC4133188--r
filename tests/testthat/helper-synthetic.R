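# Shared fixtures, built in code.  The linear test spring drives air flow
# of roughly 150 -> 120 uL/s over a 240 uL dose with the default geometry.

pp_test_geom <- function() device_geometry()
pp_test_fluid <- function() fluid_props()

pp_test_spring <- function(F0 = 23.5, slope = 2e7, V_max = uL_to_m3(260)) {
  spring_curve(c(0, V_max), c(F0, F0 - slope * V_max))
}

# One noise-free synthetic subject (air + tissue), cached per session since
# several test files reuse it.
pp_test_subject <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) {
      geom <- pp_test_geom(); fl <- pp_test_fluid()
      spring <- pp_test_spring()
      truth <- tissue_params(k = 5e-11, K = 1e5)
      cache <<- list(
        geom = geom, fluid = fl, spring = spring, truth = truth,
        air = simulate_injection(spring, "air", geom, fl, uL_to_m3(240),
                                 jitter_sd = 0),
        tissue = simulate_injection(spring, truth, geom, fl, uL_to_m3(240),
                                    jitter_sd = 0)
      )
    }
    cache
  }
})
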