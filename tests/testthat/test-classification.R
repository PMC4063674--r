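test_that("spike detection follows the -20 mV crossing rule", {
  t <- seq(0, 2, by = 1e-4)
  # constant sub-threshold trace: nothing
  expect_equal(nrow(detect_spikes(t, rep(-0.050, length(t)))), 0)
  # oscillation peaking at -25 mV never crosses: nothing
  v <- -0.040 + 0.015 * sin(2 * pi * 10 * t)
  expect_equal(nrow(detect_spikes(t, v)), 0)
  # three supra-threshold excursions: exactly three spikes at the peaks
  v2 <- rep(-0.050, length(t))
  for (ts in c(0.5, 1.0, 1.5)) {
    ix <- abs(t - ts) <= 0.002
    v2[ix] <- pmax(v2[ix], -0.002 - 25 * abs(t[ix] - ts))
  }
  sp <- detect_spikes(t, v2)
  expect_equal(nrow(sp), 3)
  expect_equal(sp$time, c(0.5, 1.0, 1.5), tolerance = 1e-4)
  expect_equal(sp$amplitude, rep(-0.002, 3), tolerance = 1e-4)
  expect_error(detect_spikes(rev(t), v2), "increasing")
})

test_that("burst grouping splits at 1 s gaps and needs three spikes", {
  b <- group_bursts(c(0, 0.2, 0.4, 2.0, 2.2, 2.4))
  expect_length(b, 2)
  # max gap 0.9 s never splits
  b2 <- group_bursts(c(0, 0.9, 1.8, 2.7))
  expect_length(b2, 1)
  expect_length(b2[[1]]$times, 4)
  # two spikes never form a burst; they are retained as strays
  b3 <- group_bursts(c(0, 0.2))
  expect_length(b3, 0)
  expect_equal(nrow(attr(b3, "stray")), 2)
  # middle spike of an even burst: lower middle (index ceiling(n/2))
  expect_equal(b2[[1]]$middle, 0.9)
  expect_error(group_bursts(c(2, 1)), "sorted")
})

test_that("burst metrics recover period, duty cycle and antiphase", {
  mk <- function(times) {
    structure(list(times = times, amps = rep(0, length(times)),
                   first = times[1], last = times[length(times)],
                   middle = times[ceiling(length(times) / 2)]),
              class = "hco_burst")
  }
  # bursts spanning 6 s, middles 10 s apart -> periods {10, 10}, CV 0,
  # duty 60%
  bA <- lapply(c(7, 17, 27), function(m) mk(seq(m - 3, m + 3, by = 0.5)))
  m <- burst_metrics(bA, NULL, window = c(0, 40), trim_edges = FALSE)
  expect_equal(m$A$periods, c(10, 10))
  expect_equal(m$A$period_cv, 0)
  expect_equal(m$A$duty, 60)
  # B lagging by half a cycle -> phase 0.5
  bB <- lapply(c(12, 22, 32), function(m) mk(seq(m - 3, m + 3, by = 0.5)))
  m2 <- burst_metrics(bA, bB, window = c(0, 40), trim_edges = FALSE)
  expect_equal(m2$phase, 0.5)
  # spike frequency: (n-1)/(last-first) averaged over bursts
  expect_equal(m$A$freq, 12 / 6)
})

test_that("classification applies the definitions' bounds as printed", {
  trace_label <- function(period, duty, phase, amp_cv = 0, coupled = TRUE,
                          freq_spikes = 12) {
    g <- gen_bursting_trace(period = period, duty_pct = duty, phase = phase,
                            spikes_per_burst = freq_spikes, amp_cv = amp_cv,
                            n_cycles = 8, dt = 2e-4, seed = 7)
    p <- if (coupled) param_vector() else param_vector(c(SynS = 0, SynG = 0))
    x <- structure(list(
      spikes = list(A = detect_spikes(g$t, g$V_A), B = detect_spikes(g$t, g$V_B)),
      min_V = c(A = min(g$V_A), B = min(g$V_B)),
      plateau = c(A = 0, B = 0),
      window = c(start = 0, end = max(g$t)),
      failed = FALSE, params = p), class = "hco_trace")
    classify_trace(x)
  }
  # realistic burster: period 10 s, ~13 Hz, regular
  cl <- trace_label(10, 60, 0.5, coupled = FALSE, freq_spikes = 80)
  expect_equal(cl$category, "burster")
  expect_true(cl$realistic)
  # same activity with a synapse present is an HCO
  cl2 <- trace_label(10, 60, 0.5, coupled = TRUE, freq_spikes = 80)
  expect_equal(cl2$category, "HCO")
  expect_true(cl2$realistic)
  # phase 0.30 with all else passing is not an HCO
  cl3 <- trace_label(10, 60, 0.30, coupled = TRUE, freq_spikes = 80)
  expect_false(cl3$category == "HCO")
  # period 4 s: an HCO, but not realistic (5-15 s band)
  cl4 <- trace_label(4, 60, 0.5, coupled = TRUE, freq_spikes = 40)
  expect_equal(cl4$category, "HCO")
  expect_false(cl4$realistic)
  # amplitude CV of 0.10 fails the 'less than 0.07' normal-spike rule
  cl5 <- trace_label(10, 60, 0.5, amp_cv = 0.10, coupled = FALSE,
                     freq_spikes = 80)
  expect_false(cl5$category == "burster")
})

test_that("classifier round-trips synthetic traces across specs", {
  for (spec in list(list(period = 8, duty = 55, phase = 0.5),
                    list(period = 12, duty = 65, phase = 0.48),
                    list(period = 6, duty = 52, phase = 0.52))) {
    g <- gen_bursting_trace(period = spec$period, duty_pct = spec$duty,
                            phase = spec$phase, spikes_per_burst = 60,
                            n_cycles = 7, dt = 2e-4, seed = 11)
    spA <- detect_spikes(g$t, g$V_A)
    spB <- detect_spikes(g$t, g$V_B)
    m <- burst_metrics(group_bursts(spA), group_bursts(spB),
                       window = c(0, max(g$t)))
    expect_equal(m$A$period_mean, spec$period, tolerance = 1e-3)
    expect_equal(m$A$duty, spec$duty, tolerance = 0.01)
    expect_equal(m$phase, spec$phase, tolerance = 0.01)
    # spike recovery is sample-exact
    expect_equal(length(spA$time), length(g$truth$spikes_A))
    expect_lt(max(abs(spA$time - sort(g$truth$spikes_A))), 2e-4 + 1e-9)
  }
})

test_that("classification is invariant to sub-threshold noise", {
  g <- gen_bursting_trace(period = 10, duty_pct = 60, phase = 0.5,
                          spikes_per_burst = 60, n_cycles = 6, dt = 2e-4)
  set.seed(42)
  noise <- stats::runif(length(g$t), -5e-4, 5e-4) # < 1 mV, never crossing
  base <- burst_metrics(group_bursts(detect_spikes(g$t, g$V_A)), NULL,
                        window = c(0, max(g$t)))
  nz <- burst_metrics(group_bursts(detect_spikes(g$t, g$V_A + noise)), NULL,
                      window = c(0, max(g$t)))
  expect_equal(nz$A$n_bursts, base$A$n_bursts)
  expect_equal(nz$A$period_mean, base$A$period_mean, tolerance = 1e-3)
})
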