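test_that("standard gating forms evaluate to their closed-form values", {
  k2 <- hco_model_spec()$channels$K2$activation
  # sigmoid midpoint at V = -b
  expect_equal(steady_state_gate(k2, -0.020), 0.5)
  # direct scalar evaluation of 1/(1 + exp(-83 * (-0.030)))
  expect_equal(steady_state_gate(k2, -0.050), 1 / (1 + exp(-83 * -0.030)),
               tolerance = 1e-12)
  expect_equal(steady_state_gate(k2, -0.050), 0.0766, tolerance = 1e-3)
  # depolarized limit of an activation gate (a < 0) is 1
  expect_equal(steady_state_gate(k2, 1), 1)
  # time constant: midpoint value tau_c + tau_d/2, depolarized limit tau_c
  expect_equal(gate_time_constant(k2, -0.035), 0.057 + 0.043 / 2)
  expect_equal(gate_time_constant(k2, 1), 0.057, tolerance = 1e-9)
  # tau_d = 0 gives a voltage-independent constant
  flat <- gate_spec(a = -100, b = 0.04, tau_c = 2e-3, tau_d = 0)
  expect_equal(gate_time_constant(flat, -0.08), 2e-3)
  expect_equal(gate_time_constant(flat, 0.02), 2e-3)
})

test_that("every tabulated gate crosses one half at V = -b and has positive tau", {
  spec <- hco_model_spec()
  V <- seq(-0.1, 0.05, by = 1e-3)
  for (ch in spec$channels) {
    for (g in Filter(Negate(is.null), list(ch$activation, ch$inactivation))) {
      if (g$form_id == "standard")
        expect_equal(steady_state_gate(g, -g$b), 0.5, tolerance = 1e-12)
      ss <- steady_state_gate(g, V)
      expect_true(all(ss >= 0 & ss <= 1))
      expect_true(all(gate_time_constant(g, V) > 0))
    }
  }
})

test_that("channel table matches the model's structure", {
  spec <- hco_model_spec()
  expect_named(spec$channels, c("Na", "P", "CaF", "CaS", "h", "K1", "K2", "KA"))
  no_inact <- names(Filter(function(ch) ch$y == 0, spec$channels))
  expect_setequal(no_inact, c("P", "h", "K2"))
  for (ch in spec$channels) {
    expect_true(ch$x %in% 1:3)
    expect_true(ch$y %in% 0:1)
    if (ch$y == 0) expect_null(ch$inactivation)
  }
})

test_that("channel currents follow gbar * m^x * h^y * (V - E)", {
  k2 <- hco_model_spec()$channels$K2
  expect_equal(channel_current(k2, 0, 0.3, V = -0.04), 0)
  # arithmetic: x = 2, m = 0.5, driving force 0.04 -> g/4 * 0.04
  expect_equal(channel_current(k2, 10e-9, 0.5, V = k2$E_rev + 0.04),
               10e-9 * 0.25 * 0.04)
  # fully activated at reversal: zero current
  expect_equal(channel_current(k2, 80e-9, 1, V = k2$E_rev), 0)
  expect_error(channel_current(k2, -1e-9, 0.5, V = 0), "negative")
})

test_that("canonical parameter set carries the printed values", {
  p <- canonical_parameters()
  expect_equal(p$gbar[["CaS"]], 3.2e-9)
  expect_equal(p$gbar[["h"]], 4e-9)
  expect_equal(p$gbar[["P"]], 7e-9)
  expect_equal(p$gbar[["K2"]], 80e-9)
  expect_equal(p$gbar[["Leak"]], 8e-9)
  expect_equal(p$gbar[["SynS"]], 60e-9)
  expect_equal(p$gbar[["SynG"]], 30e-9)
  expect_equal(p$gbar[["Na"]], 200e-9)
  expect_equal(p$gbar[["CaF"]], 5e-9)
  expect_equal(p$gbar[["K1"]], 100e-9)
  expect_equal(p$gbar[["KA"]], 80e-9)
  expect_equal(p$E_Leak, -0.060)
  expect_gt(p$C, 0)
  expect_equal(p$I_inject, 0)
  # percent scaling and E_Leak conversion
  pv <- param_vector(c(P = 50, K2 = 175), E_Leak_mV = -70)
  expect_equal(pv$gbar[["P"]], 3.5e-9)
  expect_equal(pv$gbar[["K2"]], 140e-9)
  expect_equal(pv$E_Leak, -0.070)
  expect_error(param_vector(c(Na = 50)), "not swept")
})

test_that("synaptic function is normalized to unit peak and zero at onset", {
  syn <- hco_model_spec()$synapse
  expect_equal(synaptic_function(0), 0)
  tt <- seq(0, 0.2, by = 1e-5)
  f <- synaptic_function(tt)
  expect_equal(max(f), 1, tolerance = 1e-6)
  expect_true(all(f >= 0 & f <= 1))
  # spike-mediated current: no spikes -> 0; at the analytic peak lag the
  # current equals M * gbar * (V - E_syn)
  expect_equal(spike_synapse_current(numeric(0), 0.5, -0.05, 60e-9, 10), 0)
  tpk <- syn$tau_decay * syn$tau_rise / (syn$tau_decay - syn$tau_rise) *
    log(syn$tau_decay / syn$tau_rise)
  expect_equal(spike_synapse_current(0, 0.5, -0.05, 60e-9, tpk),
               0.5 * 60e-9 * (-0.05 - syn$E_Syn), tolerance = 1e-6)
  expect_error(spike_synapse_current(c(2, 1), 0.5, -0.05, 60e-9, 3), "sorted")
})

test_that("graded synaptic current saturates with the Ca pool and vanishes without drive", {
  expect_equal(graded_synapse_current(0, -0.04, 30e-9), 0)
  expect_equal(graded_synapse_current(1e-10, -0.04, 0), 0)
  pools <- seq(0, 1e-10, length.out = 30)
  g <- graded_synapse_current(pools, -0.04, 30e-9) / (-0.04 - hco_model_spec()$synapse$E_Syn)
  expect_true(all(diff(g) >= 0)) # nondecreasing in the pool
  expect_lt(max(g), 30e-9 + 1e-18)
})

test_that("network right-hand side respects symmetry, equilibria and decoupling", {
  p <- canonical_parameters()
  # symmetric state with symmetric coupling: derivative of A equals B
  y <- initial_state(-0.05, -0.05)
  d <- network_rhs(0, y, p)[[1]]
  expect_equal(d[1:18], d[19:36], tolerance = 1e-12)
  # gates initialized at steady state have zero derivative
  expect_equal(max(abs(d[2:14])), 0, tolerance = 1e-10)
  # passive membrane: with only leak, dV/dt = -(gL/C)(V - EL)
  pl <- p
  pl$gbar[setdiff(names(pl$gbar), "Leak")] <- 0
  yl <- initial_state(-0.03, -0.03)
  dl <- network_rhs(0, yl, pl)[[1]]
  expect_equal(dl[1], -pl$gbar[["Leak"]] / pl$C * (-0.03 - pl$E_Leak),
               tolerance = 1e-9)
  expect_error(network_rhs(0, replace(y, 1, NaN), p), "non-finite")
})
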