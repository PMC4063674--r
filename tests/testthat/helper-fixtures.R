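# Shared fixtures. Simulations in tests use shortened protocols where the
# science allows it; the canonical instance (full protocol) is computed once
# per test run and cached here.

short_proto <- function(settle = 20, record = 40, dt = 1e-4)
  sim_protocol(warmup = 200, settle = settle, record = record, dt = dt)

canonical_instance <- local({
  val <- NULL
  function() {
    if (is.null(val)) {
      ics <- canonical_initial_conditions()
      val <<- simulate_instance(param_vector(), ics)
    }
    val
  }
})

# tiny isolated grid for sweep-machinery tests: 3 levels of gP x 2 of gK2,
# short protocol keeps each simulation ~fractions of a second
tiny_grid <- function()
  grid_spec(levels_pct = c(50, 100, 150),
            e_leak_mv = -60,
            fix = list(SynS = 0, SynG = 0, K2 = c(100, 150),
                       h = 100, CaS = 100, Leak = 100))
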