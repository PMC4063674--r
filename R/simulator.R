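#' Simulation protocol for the parameter screen
#'
#' The screen protocol: the canonical model is run for `warmup` seconds to
#' produce the shared initial conditions (one cell bursting, the other
#' inhibited); every instance is then integrated from those conditions for
#' `settle` seconds to establish stable activity and for a further `record`
#' seconds from which spike times and voltage statistics are taken.
#'
#' @param warmup canonical warm-up duration (s), default 200
#' @param settle settling duration per instance (s), default 100
#' @param record recorded duration per instance (s), default 100
#' @param dt integration step of the exponential-Euler kernel (s),
#'   default 1e-4
#' @param sample_dt trace sampling interval (s), `NA` to discard traces
#'   (spike times come from in-step event detection either way); must be
#'   at most 0.5 ms when set
#' @param threshold spike-detection threshold (V), default -0.020
#' @return An object of class `hco_protocol`.
#' @export
sim_protocol <- function(warmup = 200, settle = 100, record = 100,
                         dt = 1e-4, sample_dt = NA, threshold = -0.020) {
  stopifnot(record > 0, settle >= 0, warmup >= 0, dt > 0)
  if (!is.na(sample_dt)) {
    stopifnot(sample_dt >= dt, sample_dt <= 5e-4 + 1e-12)
  }
  structure(list(warmup = warmup, settle = settle, record = record,
                 dt = dt, sample_dt = sample_dt, threshold = threshold),
            class = "hco_protocol")
}

#' Integrate the two-cell model
#'
#' Low-level integration entry point. The `"euler"` backend is the
#' production fixed-step exponential-Euler kernel with in-step spike-event
#' detection; `"adaptive"` integrates the identical right-hand side
#' ([network_rhs()]) with `deSolve::lsodar`, using root finding on the
#' threshold crossings to apply the spike-triggered synaptic events, and
#' serves as an independent verification backend.
#'
#' @param p an `hco_params` object
#' @param state0 initial state (length-36 numeric, [state_names()] order)
#' @param duration integration time (s)
#' @param t0 start time (s)
#' @param record_from absolute time from which spikes/trace/statistics are
#'   kept (default `t0`: keep everything)
#' @param dt kernel step (euler) (s)
#' @param sample_dt trace sampling interval (s) or `NA` for no trace
#' @param threshold spike threshold (V)
#' @param backend `"euler"` or `"adaptive"`
#' @param rtol,atol relative/absolute tolerance (adaptive backend)
#' @param track_gates also report the global min/max reached by any gating
#'   variable (euler backend)
#' @return A list with `state` (final state), `t_end`, `failed`,
#'   per-neuron spike times/amplitudes, `min_V_*`, `plateau_*` (longest
#'   continuous supra-threshold excursion, s), and optionally `trace`
#'   (data.frame `t`, `V_A`, `V_B`).
#' @export
integrate_hco <- function(p, state0, duration, t0 = 0, record_from = t0,
                          dt = 1e-4, sample_dt = NA, threshold = -0.020,
                          backend = c("euler", "adaptive"),
                          rtol = 1e-6, atol = 1e-9, track_gates = FALSE) {
  backend <- match.arg(backend)
  stopifnot(inherits(p, "hco_params"), length(state0) == 36, duration > 0)
  if (backend == "adaptive")
    return(.integrate_adaptive(p, state0, duration, t0, record_from,
                               sample_dt, threshold, rtol, atol))
  k <- .kernel_pack(p)
  sample_every <- if (is.na(sample_dt)) 0L else as.integer(round(sample_dt / dt))
  res <- .hco_kernel_run(k$gbar, k$E_Leak, k$C, k$I_inject, k$gates, k$syn,
                         as.numeric(state0), t0, duration, dt, record_from,
                         threshold, sample_every, track_gates)
  res$state <- stats::setNames(res$state, state_names())
  if (!is.null(res$trace)) res$trace <- as.data.frame(res$trace)
  res
}

# adaptive verification backend: lsodar with root finding at threshold
# crossings; events increment the presynaptic traces s1/s2 on rising
# crossings only. Spike peak times are then read off the dense output.
.integrate_adaptive <- function(p, state0, duration, t0, record_from,
                                sample_dt, threshold, rtol, atol) {
  if (is.na(sample_dt)) sample_dt <- 1e-4
  times <- seq(t0, t0 + duration, by = sample_dt)
  rootfun <- function(t, y, parms) c(y[1] - threshold, y[19] - threshold)
  eventfun <- function(t, y, parms) {
    d <- network_rhs(t, y, parms)[[1]]
    for (n in 0:1) {
      iv <- 1 + 18 * n
      if (abs(y[iv] - threshold) < 1e-6 && d[iv] > 0) {
        y[iv + 15] <- y[iv + 15] + 1 # s1
        y[iv + 16] <- y[iv + 16] + 1 # s2
      }
    }
    y
  }
  out <- deSolve::lsodar(y = as.numeric(state0), times = times,
                         func = network_rhs, parms = p,
                         rootfunc = rootfun,
                         events = list(func = eventfun, root = TRUE),
                         rtol = rtol, atol = atol, maxsteps = 50000)
  tr <- data.frame(t = out[, 1], V_A = out[, 2], V_B = out[, 20])
  keep <- tr$t >= record_from
  spk <- lapply(c("V_A", "V_B"), function(cl)
    detect_spikes(tr$t[keep], tr[[cl]][keep], threshold))
  final <- stats::setNames(as.numeric(out[nrow(out), -1]), state_names())
  list(state = final, t_end = out[nrow(out), 1],
       failed = any(!is.finite(out[nrow(out), -1])),
       spike_times_A = spk[[1]]$time, spike_amps_A = spk[[1]]$amplitude,
       spike_times_B = spk[[2]]$time, spike_amps_B = spk[[2]]$amplitude,
       min_V_A = min(tr$V_A[keep]), min_V_B = min(tr$V_B[keep]),
       plateau_A = .longest_run(tr$t[keep], tr$V_A[keep] >= threshold),
       plateau_B = .longest_run(tr$t[keep], tr$V_B[keep] >= threshold),
       trace = tr[keep, , drop = FALSE])
}

.longest_run <- function(t, flag) {
  if (!length(flag) || !any(flag)) return(0)
  r <- rle(flag)
  dt <- if (length(t) > 1) t[2] - t[1] else 0
  max(r$lengths[r$values]) * dt
}

#' Shared initial conditions from the canonical warm-up
#'
#' Runs the canonical half-center oscillator for the warm-up duration so
#' that one neuron ends in its bursting state while the other is inhibited;
#' the resulting asymmetric network state is used, identically, as the
#' initial condition of every instance in a screen. The warm-up itself
#' starts from rest-like but asymmetric potentials (A at -45 mV, B at
#' -60 mV, gates at steady state) to break the exact symmetry of the
#' network. The result is cached per (dt, warmup) within the session and is
#' deterministic at fixed solver settings.
#'
#' @param proto an [sim_protocol()] object
#' @return Named state vector of length 36 (class `numeric`), with attribute
#'   `t` equal to the warm-up duration.
#' @export
canonical_initial_conditions <- function(proto = sim_protocol()) {
  key <- sprintf("ics_%g_%g", proto$dt, proto$warmup)
  if (!is.null(.hco_cache[[key]])) return(.hco_cache[[key]])
  p <- canonical_parameters()
  res <- integrate_hco(p, initial_state(), duration = proto$warmup,
                       dt = proto$dt, threshold = proto$threshold)
  if (res$failed) stop("canonical warm-up integration failed")
  st <- res$state
  attr(st, "t") <- res$t_end
  .hco_cache[[key]] <- st
  st
}

#' Simulate one model instance under the screen protocol
#'
#' Integrates an instance from the shared canonical initial conditions for
#' `settle + record` seconds and returns the recorded window's spike trains
#' and voltage statistics. Numerical blow-up is caught and flagged (`failed`),
#' never silently dropped.
#'
#' @param p an `hco_params` object (e.g. from [param_vector()])
#' @param ics initial network state, default [canonical_initial_conditions()]
#' @param proto an [sim_protocol()] object
#' @param backend integration backend, see [integrate_hco()]
#' @return An object of class `hco_trace`: list with per-neuron `spikes`
#'   (data.frames `time`, `amplitude`), `min_V`, `plateau`, the recorded
#'   `window` (start/end, s), `failed`, `params`, and optionally `trace`.
#' @export
simulate_instance <- function(p, ics = canonical_initial_conditions(proto),
                              proto = sim_protocol(),
                              backend = "euler") {
  t0 <- attr(ics, "t")
  if (is.null(t0)) t0 <- 0
  res <- integrate_hco(p, ics, duration = proto$settle + proto$record,
                       t0 = t0, record_from = t0 + proto$settle,
                       dt = proto$dt, sample_dt = proto$sample_dt,
                       threshold = proto$threshold, backend = backend)
  structure(list(
    spikes = list(
      A = data.frame(time = res$spike_times_A, amplitude = res$spike_amps_A),
      B = data.frame(time = res$spike_times_B, amplitude = res$spike_amps_B)),
    min_V = c(A = res$min_V_A, B = res$min_V_B),
    plateau = c(A = res$plateau_A, B = res$plateau_B),
    window = c(start = t0 + proto$settle,
               end = t0 + proto$settle + proto$record),
    failed = isTRUE(res$failed),
    state = res$state,
    trace = res$trace,
    params = p), class = "hco_trace")
}

#' @export
print.hco_trace <- function(x, ...) {
  cat("<hco_trace>", if (x$failed) "FAILED" else "", "\n")
  cat(sprintf("  recorded window: %.1f - %.1f s\n",
              x$window["start"], x$window["end"]))
  cat(sprintf("  spikes: A %d, B %d; min V: A %.1f mV, B %.1f mV\n",
              nrow(x$spikes$A), nrow(x$spikes$B),
              1000 * x$min_V["A"], 1000 * x$min_V["B"]))
  invisible(x)
}
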