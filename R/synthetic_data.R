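# Synthetic-data generators. They emulate the statistical structure the
# analysis stages assume -- parameter clouds with a dominant linear
# direction, two-neuron traces with known burst structure, instance tables
# with known family structure -- so classification, PCA/ODR, KS and family
# analyses are testable without running any large sweep. All generators are
# pure functions of (spec, seed).

#' Generate a parameter group with an embedded linear correlation
#'
#' Draws `n` points along a line through `center` with direction
#' `direction` (position uniform over `±spread`), adds isotropic Gaussian
#' noise of standard deviation `sigma` in every coordinate, and optionally
#' snaps each coordinate to the sweep lattice (conductance fractions
#' 0--1.75 in steps of 0.25; E_Leak -70..-50 mV in 5 mV steps when a
#' column is named `E_Leak`).
#'
#' @param n number of instances
#' @param direction numeric direction vector (any dimension; normalized
#'   internally)
#' @param center numeric center point (same length)
#' @param spread half-width of the uniform spread along the line
#' @param sigma isotropic noise standard deviation
#' @param snap snap to the grid lattice?
#' @param seed RNG seed
#' @param columns optional column names
#' @return Numeric matrix (`n` rows).
#' @export
gen_correlated_group <- function(n, direction, center = rep(0, length(direction)),
                                 spread = 1, sigma = 0, snap = FALSE,
                                 seed = 1, columns = NULL) {
  stopifnot(n >= 1, length(direction) == length(center), sigma >= 0)
  d <- direction / sqrt(sum(direction^2))
  set.seed(seed)
  tpos <- stats::runif(n, -spread, spread)
  M <- outer(tpos, d) + matrix(center, n, length(d), byrow = TRUE)
  if (sigma > 0) M <- M + matrix(stats::rnorm(n * length(d), 0, sigma), n)
  if (!is.null(columns)) colnames(M) <- columns
  if (snap) {
    for (j in seq_len(ncol(M))) {
      if (!is.null(colnames(M)) && colnames(M)[j] == "E_Leak") {
        lat <- c(-70, -65, -60, -55, -50) / 1000
        M[, j] <- lat[apply(abs(outer(M[, j], lat, "-")), 1, which.min)]
      } else {
        M[, j] <- pmin(1.75, pmax(0, round(M[, j] / 0.25) * 0.25))
      }
    }
  }
  M
}

#' Generate a two-neuron voltage trace with known burst structure
#'
#' Builds a piecewise waveform per neuron: bursts of stereotyped triangular
#' spikes (peaking above the -20 mV detection threshold) riding on a
#' depolarized plateau, separated by hyperpolarized interburst intervals;
#' neuron B is a copy of neuron A delayed by `phase` cycles. Passed through
#' [detect_spikes()] / [group_bursts()] / [burst_metrics()], the trace
#' reproduces the requested period, duty cycle, spike frequency, amplitude
#' CV and phase to within one sampling interval.
#'
#' @param period cycle period (s)
#' @param n_cycles number of cycles
#' @param spikes_per_burst spikes per burst (>= 3)
#' @param duty_pct duty cycle (%), in (0, 100)
#' @param amp_mean mean spike peak (V), above the -20 mV threshold
#' @param amp_cv coefficient of variation of spike height above threshold
#' @param phase relative phase of neuron B in \[0, 1)
#' @param jitter per-spike timing jitter SD (s)
#' @param dt sampling interval (s)
#' @param baseline interburst potential (V)
#' @param seed RNG seed
#' @return List `t`, `V_A`, `V_B` plus the ground-truth spike times.
#' @export
gen_bursting_trace <- function(period = 10, n_cycles = 6, spikes_per_burst = 12,
                               duty_pct = 60, amp_mean = 0, amp_cv = 0,
                               phase = 0.5, jitter = 0, dt = 1e-4,
                               baseline = -0.050, seed = 1) {
  stopifnot(period > 0, duty_pct > 0, duty_pct < 100, spikes_per_burst >= 3)
  burst_len <- duty_pct / 100 * period
  isi <- burst_len / (spikes_per_burst - 1)
  spike_halfwidth <- 2e-3
  if (isi <= 2 * spike_halfwidth)
    stop("infeasible spec: spikes would overlap (duty x period too small for spike count)")
  if (period - burst_len < 1 + 2 * spike_halfwidth)
    stop("infeasible spec: interburst interval must exceed the 1 s burst separator")
  set.seed(seed)
  total <- (n_cycles + 2) * period
  t <- seq(0, total, by = dt)
  threshold <- -0.020
  build <- function(offset) {
    V <- rep(baseline, length(t))
    spk <- c()
    for (cy in 0:(n_cycles + 1)) {
      t0 <- cy * period + offset
      for (k in 0:(spikes_per_burst - 1)) {
        ts <- t0 + k * isi + if (jitter > 0) stats::rnorm(1, 0, jitter) else 0
        amp <- amp_mean
        if (amp_cv > 0) {
          h <- (amp_mean - threshold) * (1 + stats::rnorm(1, 0, amp_cv))
          amp <- threshold + max(h, 1e-3)
        }
        lo <- ts - spike_halfwidth
        hi <- ts + spike_halfwidth
        ix <- which(t >= lo & t <= hi)
        tri <- 1 - abs(t[ix] - ts) / spike_halfwidth
        V[ix] <- pmax(V[ix], baseline + (amp - baseline) * tri)
        if (ts >= 0 && ts <= total) spk <- c(spk, ts)
      }
    }
    list(V = V, spk = spk)
  }
  A <- build(period) # skip one period so no burst is cut at the edges
  B <- build(period + phase * period)
  list(t = t, V_A = A$V, V_B = B$V,
       truth = list(spikes_A = A$spk, spikes_B = B$spk,
                    period = period, duty_pct = duty_pct, phase = phase))
}

#' Generate an instance table with known family structure
#'
#' Builds a parameter table on the sweep lattice whose partition into
#' one-parameter families along `varied` has exactly the requested
#' size census. Families of size k get k distinct ascending levels of the
#' varied parameter; fixed tuples differ between families so no two merge.
#'
#' @param census named vector: `census[["k"]]` families of size k (e.g.
#'   `c("1" = 5, "2" = 3)`)
#' @param varied varied parameter name (default `"K2"`)
#' @param periods optional list: for each family (in generation order) a
#'   vector of member periods; defaults to decreasing periods drawn
#'   around 10 s
#' @param seed RNG seed
#' @return data.frame of instance records (level columns plus `period`).
#' @export
gen_family_table <- function(census, varied = "K2", periods = NULL, seed = 1) {
  sizes <- rep(as.integer(names(census)), census)
  if (!length(sizes))
    return(cbind(.empty_instances()[c(.swept_conductances, "E_Leak")],
                 period = numeric(0))[0, ])
  set.seed(seed)
  levels_pct <- c(0, 25, 50, 75, 100, 125, 150, 175)
  cols <- c(.swept_conductances, "E_Leak")
  fixed_cols <- setdiff(cols, varied)
  rows <- list()
  for (i in seq_along(sizes)) {
    k <- sizes[i]
    # a distinct fixed tuple per family (enumerate level combinations)
    fixed <- stats::setNames(as.list(levels_pct[1 + (i %/% 8^(0:6)) %% 8][seq_along(fixed_cols)]),
                             fixed_cols)
    if ("E_Leak" %in% fixed_cols) fixed$E_Leak <- c(-70, -65, -60, -55, -50)[1 + i %% 5]
    vlev <- sort(sample(levels_pct, k))
    per <- if (!is.null(periods)) periods[[i]] else sort(stats::runif(k, 5, 15), decreasing = TRUE)
    for (j in seq_len(k)) {
      r <- as.data.frame(fixed)
      r[[varied]] <- vlev[j]
      r$period <- per[j]
      rows[[length(rows) + 1]] <- r
    }
  }
  df <- do.call(rbind, rows)
  df[, c(cols, "period")]
}
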