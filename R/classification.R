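#' Detect spikes in a sampled voltage trace
#'
#' A spike is recognized only where the waveform crosses the threshold
#' (default -20 mV) upward; its time is the local maximum following the
#' crossing and its amplitude that peak value. One spike per supra-threshold
#' excursion.
#'
#' @param t time grid (s), strictly increasing
#' @param V sampled membrane potential (V)
#' @param threshold detection threshold (V), default -0.020
#' @return data.frame with columns `time`, `amplitude`.
#' @export
detect_spikes <- function(t, V, threshold = -0.020) {
  stopifnot(length(t) == length(V))
  if (is.unsorted(t, strictly = TRUE)) stop("time vector must be strictly increasing")
  above <- V >= threshold
  if (!any(above)) return(data.frame(time = numeric(0), amplitude = numeric(0)))
  r <- rle(above)
  ends <- cumsum(r$lengths)
  starts <- c(1, utils::head(ends, -1) + 1)
  times <- amps <- numeric(0)
  for (k in which(r$values)) {
    if (starts[k] == 1) next # already above threshold at trace start: no crossing
    seg <- starts[k]:ends[k]
    i <- seg[which.max(V[seg])]
    times <- c(times, t[i])
    amps <- c(amps, V[i])
  }
  data.frame(time = times, amplitude = amps)
}

#' Group a spike train into bursts
#'
#' Bursts are maximal runs of spikes separated by inter-spike gaps shorter
#' than the minimum inter-burst interval (1 s); a run must contain at least
#' `min_spikes` (3) spikes to count as a burst. Sub-threshold runs are kept
#' as stray spikes in the `stray` attribute.
#'
#' @param spikes data.frame (`time`, `amplitude`) or numeric vector of
#'   sorted spike times
#' @param min_gap minimum inter-burst interval (s), default 1
#' @param min_spikes minimum spikes per burst, default 3
#' @return List of `hco_burst` objects (fields `times`, `amps`, `first`,
#'   `last`, `middle`), with attribute `stray` (data.frame of left-over
#'   spikes).
#' @export
group_bursts <- function(spikes, min_gap = 1, min_spikes = 3) {
  if (is.numeric(spikes)) spikes <- data.frame(time = spikes,
                                               amplitude = rep(NA_real_, length(spikes)))
  if (is.unsorted(spikes$time)) stop("spike times must be sorted")
  n <- nrow(spikes)
  if (!n) return(structure(list(), stray = spikes))
  grp <- cumsum(c(1, diff(spikes$time) >= min_gap))
  bursts <- list()
  stray <- spikes[0, ]
  for (g in split(seq_len(n), grp)) {
    if (length(g) >= min_spikes) {
      tt <- spikes$time[g]
      mid <- tt[ceiling(length(tt) / 2)] # even counts: lower middle spike
      bursts[[length(bursts) + 1]] <- structure(
        list(times = tt, amps = spikes$amplitude[g],
             first = tt[1], last = tt[length(tt)], middle = mid),
        class = "hco_burst")
    } else {
      stray <- rbind(stray, spikes[g, ])
    }
  }
  structure(bursts, stray = stray)
}

# per-neuron burst statistics; periods require >= 2 bursts. Spike amplitude
# is measured as spike height above the detection threshold: model spikes
# peak near 0 mV, so the CV of raw peak potentials is numerically unstable.
.neuron_burst_stats <- function(bursts, threshold = -0.020) {
  nb <- length(bursts)
  out <- list(n_bursts = nb, defined = nb >= 2)
  if (nb) {
    out$middles <- vapply(bursts, `[[`, numeric(1), "middle")
    out$durations <- vapply(bursts, function(b) b$last - b$first, numeric(1))
    out$freqs <- vapply(bursts, function(b)
      (length(b$times) - 1) / (b$last - b$first), numeric(1))
    out$amp_cv <- vapply(bursts, function(b) {
      a <- b$amps - threshold
      m <- mean(a)
      if (!is.finite(m) || m == 0) return(NA_real_)
      stats::sd(a) / abs(m)
    }, numeric(1))
  }
  if (nb >= 2) {
    out$periods <- diff(out$middles)
    out$period_mean <- mean(out$periods)
    out$period_cv <- if (length(out$periods) >= 2)
      stats::sd(out$periods) / out$period_mean else 0
    out$duty <- mean(out$durations) / out$period_mean * 100
    out$freq <- mean(out$freqs)
  } else {
    out[c("period_mean", "period_cv", "duty", "freq")] <- NA_real_
  }
  out
}

# per-cycle relative phase of B's burst middles within A's cycles
.relative_phase <- function(mid_A, mid_B) {
  if (length(mid_A) < 2 || !length(mid_B)) return(NA_real_)
  ph <- c()
  for (i in seq_len(length(mid_A) - 1)) {
    b <- mid_B[mid_B >= mid_A[i] & mid_B < mid_A[i + 1]]
    if (length(b) == 1)
      ph <- c(ph, (b - mid_A[i]) / (mid_A[i + 1] - mid_A[i]))
  }
  if (!length(ph)) NA_real_ else mean(ph)
}

#' Burst metrics of a recorded window
#'
#' Computes, per neuron: cycle periods (intervals between middle spikes of
#' consecutive bursts) and their coefficient of variation, mean intraburst
#' spike frequency (\eqn{(n-1)/(t_{last}-t_{first})} averaged over bursts),
#' duty cycle (mean burst duration over mean period, %), and per-burst
#' spike-amplitude CVs; and, for the pair, the mean per-cycle relative phase
#' of neuron B's burst middles within neuron A's cycles.
#'
#' Bursts truncated by the window edges (first spike within `min_gap` of the
#' window start, or last spike within `min_gap` of its end) are dropped when
#' `trim_edges` is set: their inter-burst bounds cannot be verified and a
#' partial burst corrupts the duration and period statistics.
#'
#' @param bursts_A,bursts_B burst lists from [group_bursts()] (`bursts_B`
#'   may be `NULL` for single-cell analyses)
#' @param window length-2 numeric, start/end of the recorded window (s)
#' @param min_V optional named numeric, minimum membrane potential per
#'   neuron over the window (V)
#' @param threshold spike threshold (V); amplitudes enter the CV as height
#'   above this threshold
#' @param trim_edges drop bursts touching the window edges (default TRUE)
#' @param min_gap minimum inter-burst interval used for edge trimming (s)
#' @return An object of class `hco_metrics`.
#' @export
burst_metrics <- function(bursts_A, bursts_B = NULL, window, min_V = NULL,
                          threshold = -0.020, trim_edges = TRUE,
                          min_gap = 1) {
  if (trim_edges) {
    keep <- function(b) b$first >= window[1] + min_gap &&
      b$last <= window[2] - min_gap
    bursts_A <- Filter(keep, bursts_A)
    if (!is.null(bursts_B)) bursts_B <- Filter(keep, bursts_B)
  }
  A <- .neuron_burst_stats(bursts_A, threshold)
  B <- if (!is.null(bursts_B)) .neuron_burst_stats(bursts_B, threshold)
  phase <- if (!is.null(B)) .relative_phase(A$middles, B$middles) else NA_real_
  structure(list(A = A, B = B, phase = phase,
                 window = as.numeric(window), min_V = min_V),
            class = "hco_metrics")
}

#' @export
print.hco_metrics <- function(x, ...) {
  cat("<hco_metrics>\n")
  for (nm in c("A", "B")) {
    s <- x[[nm]]
    if (is.null(s)) next
    cat(sprintf("  %s: %d bursts; period %.2f s (CV %.3f); %.1f Hz; duty %.1f%%\n",
                nm, s$n_bursts, s$period_mean, s$period_cv, s$freq, s$duty))
  }
  if (!is.na(x$phase)) cat(sprintf("  phase: %.3f\n", x$phase))
  invisible(x)
}

# classification constants: the screen's activity definitions
.hco_rules <- list(
  burst_window = 40,      # s; >= 2 bursts required within the final 40 s
  min_bursts = 2,
  amp_cv_max = 0.07,      # "less than": strict
  period_cv_max = 0.05,   # strict
  phase_range = c(0.45, 0.55), # open interval
  realistic_period = c(5, 15),   # closed bounds
  realistic_freq = c(8, 25),
  realistic_duty = c(50, 70),
  plateau_max = 5         # s above threshold -> plateau neuron
)

# does one neuron show regular bursting (>=2 bursts in the trailing 40 s,
# normal spikes in every burst, small period variation)?
.neuron_bursting <- function(s, window) {
  if (!s$n_bursts) return(FALSE)
  w0 <- max(window[1], window[2] - .hco_rules$burst_window)
  n40 <- sum(s$middles >= w0 & s$middles <= window[2])
  if (n40 < .hco_rules$min_bursts || !s$defined) return(FALSE)
  cv <- s$amp_cv[is.finite(s$amp_cv)] # NA = no amplitude information
  if (any(cv >= .hco_rules$amp_cv_max)) return(FALSE)
  is.finite(s$period_cv) && s$period_cv < .hco_rules$period_cv_max
}

# descriptive sub-label for a neuron that is not regularly bursting
.neuron_sublabel <- function(s, n_spikes, plateau) {
  if (plateau > .hco_rules$plateau_max) return("plateau")
  if (n_spikes == 0) return("silent")
  if (s$n_bursts == 0) return("spiking")
  "irregular"
}

#' Classify one simulated instance
#'
#' Applies the screen's activity definitions to the burst metrics of an
#' instance. Coupled instances (any synaptic conductance nonzero) are
#' labelled `HCO` when both neurons burst regularly (at least two bursts in
#' the trailing 40 s, spike-amplitude CV below 0.07 within every burst,
#' period CV below 0.05) and the mean relative phase lies in the open
#' interval (0.45, 0.55); isolated instances whose twin neurons both burst
#' regularly are `burster`s. The `realistic` flag (defined for HCOs and
#' bursters only) additionally requires a period of 5--15 s and a mean
#' spike frequency of 8--25 Hz, plus a duty cycle of 50--70% for HCOs
#' (closed bounds). Other instances receive a descriptive label: `silent`,
#' `spiking`, `plateau`, `irregular`, or -- for isolated twins that settle
#' on different activity types -- `bistable-suspect`.
#'
#' @param m an [burst_metrics()] object
#' @param p the instance's `hco_params`
#' @param n_spikes named integer (`A`, `B`): spike counts in the window
#' @param plateau named numeric (`A`, `B`): longest supra-threshold
#'   excursion (s)
#' @param failed was the integration flagged as failed?
#' @return List with `category`, `realistic`, and the summary metrics used.
#' @export
classify_instance <- function(m, p, n_spikes = c(A = NA, B = NA),
                              plateau = c(A = 0, B = 0), failed = FALSE) {
  stopifnot(inherits(m, "hco_metrics"))
  coupled <- p$gbar[["SynS"]] != 0 || p$gbar[["SynG"]] != 0
  out <- list(category = NA_character_, realistic = NA, coupled = coupled,
              period = NA_real_, period_cv = NA_real_, freq = NA_real_,
              duty = NA_real_, phase = m$phase)
  if (failed) {
    out$category <- "failed"
    return(out)
  }
  sA <- m$A; sB <- m$B
  if (is.null(sB)) stop("classification needs both neurons' metrics")
  burstA <- .neuron_bursting(sA, m$window)
  burstB <- .neuron_bursting(sB, m$window)
  both_burst <- burstA && burstB
  if (both_burst) {
    out$period <- mean(c(sA$period_mean, sB$period_mean))
    out$period_cv <- max(sA$period_cv, sB$period_cv)
    out$freq <- mean(c(sA$freq, sB$freq))
    out$duty <- mean(c(sA$duty, sB$duty))
  }
  rl <- .hco_rules
  if (coupled) {
    phase_ok <- is.finite(m$phase) &&
      m$phase > rl$phase_range[1] && m$phase < rl$phase_range[2]
    if (both_burst && phase_ok) {
      out$category <- "HCO"
      out$realistic <- out$period >= rl$realistic_period[1] &&
        out$period <= rl$realistic_period[2] &&
        out$freq >= rl$realistic_freq[1] & out$freq <= rl$realistic_freq[2] &&
        out$duty >= rl$realistic_duty[1] && out$duty <= rl$realistic_duty[2]
      return(out)
    }
  } else if (both_burst) {
    out$category <- "burster"
    out$realistic <- out$period >= rl$realistic_period[1] &&
      out$period <= rl$realistic_period[2] &&
      out$freq >= rl$realistic_freq[1] && out$freq <= rl$realistic_freq[2]
    return(out)
  }
  # non-HCO / non-burster: descriptive sub-label
  labA <- if (burstA) "bursting" else .neuron_sublabel(sA, n_spikes[["A"]], plateau[["A"]])
  labB <- if (burstB) "bursting" else .neuron_sublabel(sB, n_spikes[["B"]], plateau[["B"]])
  out$category <- if (labA == labB) {
    if (labA == "bursting") "irregular" else labA # coupled pair bursting out of phase
  } else if (!coupled) "bistable-suspect" else "irregular"
  out
}

#' Classify a simulated trace end-to-end
#'
#' Convenience wrapper: spike trains of an [simulate_instance()] result are
#' grouped into bursts, burst metrics computed over the recorded window,
#' and the instance classified.
#'
#' @param x an `hco_trace` object
#' @return The [classify_instance()] result, with the `hco_metrics` object
#'   attached as attribute `metrics`.
#' @export
classify_trace <- function(x) {
  stopifnot(inherits(x, "hco_trace"))
  bA <- group_bursts(x$spikes$A)
  bB <- group_bursts(x$spikes$B)
  m <- burst_metrics(bA, bB, window = x$window, min_V = x$min_V)
  res <- classify_instance(m, x$params,
                           n_spikes = c(A = nrow(x$spikes$A), B = nrow(x$spikes$B)),
                           plateau = x$plateau, failed = x$failed)
  attr(res, "metrics") <- m
  res
}
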