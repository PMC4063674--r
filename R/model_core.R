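#' @useDynLib hcosweep, .registration = TRUE
#' @importFrom Rcpp sourceCpp
NULL

# Package-local cache (model spec, canonical initial conditions, ...)
.hco_cache <- new.env(parent = emptyenv())

#' Load the canonical half-center oscillator model definition
#'
#' The two-cell model is a pair of reciprocally inhibitory single-compartment
#' leech heart-interneuron models with eight voltage-gated currents each
#' (inward: fast Na \eqn{I_{Na}}, persistent Na \eqn{I_P}, fast and slow
#' low-threshold Ca \eqn{I_{CaF}}, \eqn{I_{CaS}}, hyperpolarization-activated
#' \eqn{I_h}; outward: delayed-rectifier \eqn{I_{K1}}, persistent K
#' \eqn{I_{K2}}, fast transient \eqn{I_{KA}}), a leak current, and two
#' inhibitory synaptic mechanisms: graded transmission driven by a
#' presynaptic Ca pool, and spike-mediated transmission triggered by
#' presynaptic spike events. The full definition (gating kinetics, reversal
#' potentials, synapse constants, canonical maximal conductances) ships as a
#' YAML resource and is parsed once per session. All units are SI.
#'
#' @return A nested list with elements `membrane`, `reversal_potentials`,
#'   `channels` (each with `x`, `y`, `E_rev` and `hco_gate` specs),
#'   `synapse`, and `canonical`.
#' @export
hco_model_spec <- function() {
  if (!is.null(.hco_cache$model_spec)) return(.hco_cache$model_spec)
  path <- system.file("extdata", "hco_model.yaml", package = "hcosweep")
  raw <- yaml::read_yaml(path)
  chans <- lapply(names(raw$channels), function(nm) {
    ch <- raw$channels[[nm]]
    act <- do.call(gate_spec, ch$activation)
    ina <- if (!is.null(ch$inactivation)) do.call(gate_spec, ch$inactivation)
    structure(list(name = nm, x = as.integer(ch$x), y = as.integer(ch$y),
                   E_rev = ch$E_rev, activation = act, inactivation = ina),
              class = "hco_channel")
  })
  names(chans) <- names(raw$channels)
  spec <- list(membrane = raw$membrane,
               reversal_potentials = raw$reversal_potentials,
               channels = chans,
               synapse = raw$synapse,
               canonical = raw$canonical)
  spec$synapse$norm_const <- .syn_norm_const(spec$synapse)
  .hco_cache$model_spec <- spec
  spec
}

#' Construct a gating-variable specification
#'
#' Steady states follow the standard Boltzmann form
#' \eqn{x_\infty(V) = 1/(1 + e^{a(V+b)})} and voltage-dependent time
#' constants the standard form
#' \eqn{\tau(V) = \tau_c + \tau_d/(1 + e^{\tau_a(V+\tau_b)})}, except for
#' three special cases carried by `form_id`/`tau_form`: the h-current
#' steady-state activation (`h_ss`), the Na inactivation time constant
#' (`na_h`, which adds a \eqn{1/\cosh} term), and the CaF activation time
#' constant (`caf_m`, a pure \eqn{1/\cosh} form).
#'
#' @param a steepness of the steady-state sigmoid (1/V)
#' @param b half-activation offset (V); the standard form crosses 0.5 at
#'   `V = -b`
#' @param tau_a,tau_b,tau_c,tau_d time-constant shape parameters (1/V, V, s, s)
#' @param form_id `"standard"` or `"h_ss"`
#' @param tau_form `"standard"`, `"na_h"`, or `"caf_m"`
#' @return An object of class `hco_gate`.
#' @export
gate_spec <- function(a, b, tau_a = 0, tau_b = 0, tau_c = 1e-4, tau_d = 0,
                      form_id = "standard", tau_form = "standard") {
  form_id <- match.arg(form_id, c("standard", "h_ss"))
  tau_form <- match.arg(tau_form, c("standard", "na_h", "caf_m"))
  stopifnot(is.finite(a), is.finite(b), is.finite(tau_c), is.finite(tau_d))
  structure(list(a = a, b = b, tau_a = tau_a, tau_b = tau_b,
                 tau_c = tau_c, tau_d = tau_d,
                 form_id = form_id, tau_form = tau_form),
            class = "hco_gate")
}

#' Steady-state value of a gating variable
#'
#' @param spec an [gate_spec()] object
#' @param V membrane potential (V); vectorized
#' @return Steady-state open fraction in \[0, 1\].
#' @export
steady_state_gate <- function(spec, V) {
  stopifnot(inherits(spec, "hco_gate"), all(is.finite(V)))
  switch(spec$form_id,
    standard = 1 / (1 + exp(spec$a * (V + spec$b))),
    h_ss = 1 / (1 + 2 * exp(180 * (V + 0.047)) + exp(500 * (V + 0.047))),
    stop("unknown form_id: ", spec$form_id)
  )
}

#' Voltage-dependent time constant of a gating variable
#'
#' @inheritParams steady_state_gate
#' @return Time constant (s), strictly positive.
#' @export
gate_time_constant <- function(spec, V) {
  stopifnot(inherits(spec, "hco_gate"), all(is.finite(V)))
  tau <- switch(spec$tau_form,
    standard = spec$tau_c + spec$tau_d / (1 + exp(spec$tau_a * (V + spec$tau_b))),
    na_h = 0.004 + 0.006 / (1 + exp(500 * (V + 0.028))) +
      0.01 / cosh(300 * (V + 0.027)),
    caf_m = 0.011 + 0.024 / cosh(330 * (V + 0.0467)),
    stop("unknown tau_form: ", spec$tau_form)
  )
  if (any(tau <= 0)) stop("nonpositive gating time constant; model definition error")
  tau
}

#' Ionic current through one voltage-gated channel
#'
#' \eqn{I = \bar g \, m^x h^y (V - E_{ion})}; positive values are outward.
#'
#' @param chan an `hco_channel` element of [hco_model_spec()]
#' @param gbar maximal conductance (S), nonnegative
#' @param m activation variable in \[0, 1\]
#' @param h inactivation variable in \[0, 1\] (ignored when the channel has
#'   no inactivation gate, `y = 0`)
#' @param V membrane potential (V)
#' @return Current (A).
#' @export
channel_current <- function(chan, gbar, m, h = 1, V) {
  if (any(gbar < 0)) stop("negative maximal conductance")
  stopifnot(all(m >= 0 & m <= 1), all(h >= 0 & h <= 1))
  hy <- if (chan$y == 0) 1 else h^chan$y
  gbar * m^chan$x * hy * (V - chan$E_rev)
}

# peak-normalisation constant for the difference-of-exponentials synaptic
# function f(t) = k (e^{-t/tau_decay} - e^{-t/tau_rise}); k is chosen so
# max_t f(t) = 1
.syn_norm_const <- function(syn) {
  td <- syn$tau_decay; tr <- syn$tau_rise
  tpk <- td * tr / (td - tr) * log(td / tr)
  1 / (exp(-tpk / td) - exp(-tpk / tr))
}

#' Normalized spike-triggered synaptic function
#'
#' Difference-of-exponentials conductance time course with unit peak:
#' \eqn{f(t) = k(e^{-t/\tau_{decay}} - e^{-t/\tau_{rise}})}, \eqn{f \le 1},
#' \eqn{f(0) = 0}.
#'
#' @param t time since the spike event (s); vectorized, negative values give 0
#' @param syn synapse constants, defaulting to the canonical model's
#' @return Dimensionless conductance scale in \[0, 1\].
#' @export
synaptic_function <- function(t, syn = hco_model_spec()$synapse) {
  ifelse(t >= 0,
         syn$norm_const * (exp(-t / syn$tau_decay) - exp(-t / syn$tau_rise)),
         0)
}

#' Graded synaptic current
#'
#' Postsynaptic current of the graded (Ca-pool driven) synapse:
#' \eqn{I = \bar g_{SynG}\, P^3/(C_{grad} + P^3) (V_{post} - E_{Syn})}, where
#' `pool` is the presynaptic Ca pool (integrated low-threshold Ca current
#' with first-order decay).
#'
#' @param pool presynaptic Ca pool (A s), nonnegative
#' @param V_post postsynaptic membrane potential (V)
#' @param gbar_SynG maximal graded conductance (S)
#' @param syn synapse constants
#' @return Current (A).
#' @export
graded_synapse_current <- function(pool, V_post, gbar_SynG,
                                   syn = hco_model_spec()$synapse) {
  if (any(pool < 0)) stop("negative presynaptic Ca pool")
  if (any(gbar_SynG < 0)) stop("negative maximal conductance")
  sat <- pool^3 / (syn$pool_C + pool^3)
  gbar_SynG * sat * (V_post - syn$E_Syn)
}

#' Spike-mediated synaptic current
#'
#' Sums the normalized synaptic function over recent presynaptic spike
#' events, modulated by the synapse's modulation variable `M`:
#' \eqn{I = M \bar g_{SynS} \sum_{\hat t} f(t - \hat t) (V_{post} - E_{Syn})}.
#' Events old enough that `f` has decayed below `cutoff` are dropped.
#'
#' @param spike_times presynaptic spike-event times (s), sorted ascending
#' @param M modulation variable in \[0, 1\]
#' @param V_post postsynaptic membrane potential (V)
#' @param gbar_SynS maximal spike-mediated conductance (S)
#' @param t current time (s)
#' @param syn synapse constants
#' @param cutoff drop events once `f < cutoff` (default 1e-6)
#' @return Current (A).
#' @export
spike_synapse_current <- function(spike_times, M, V_post, gbar_SynS, t,
                                  syn = hco_model_spec()$synapse,
                                  cutoff = 1e-6) {
  if (is.unsorted(spike_times)) stop("spike_times must be sorted ascending")
  stopifnot(M >= 0, M <= 1)
  if (!length(spike_times)) return(0)
  dtim <- t - spike_times
  f <- synaptic_function(dtim, syn)
  f[f < cutoff] <- 0
  M * gbar_SynS * sum(f) * (V_post - syn$E_Syn)
}

#' Canonical model parameters
#'
#' The canonical parameter set of the half-center oscillator screen:
#' \eqn{\bar g_{Na}} = 200, \eqn{\bar g_P} = 7, \eqn{\bar g_{CaF}} = 5,
#' \eqn{\bar g_{CaS}} = 3.2, \eqn{\bar g_h} = 4, \eqn{\bar g_{K1}} = 100,
#' \eqn{\bar g_{K2}} = 80, \eqn{\bar g_{KA}} = 80, \eqn{\bar g_{Leak}} = 8,
#' \eqn{\bar g_{SynS}} = 60, \eqn{\bar g_{SynG}} = 30 (all nS), and
#' \eqn{E_{Leak}} = -60 mV. Internally everything is SI (S, V).
#'
#' @return An object of class `hco_params`: list with `gbar` (named numeric,
#'   S), `E_Leak` (V), `C` (F), `I_inject` (A).
#' @export
canonical_parameters <- function() {
  spec <- hco_model_spec()
  structure(list(gbar = unlist(spec$canonical$gbar),
                 E_Leak = spec$canonical$E_Leak,
                 C = spec$membrane$C,
                 I_inject = spec$membrane$I_inject),
            class = "hco_params")
}

# the seven swept conductances, in the fixed analysis-space column order
.swept_conductances <- c("SynS", "SynG", "P", "K2", "h", "CaS", "Leak")

#' Build a model-parameter set from sweep levels
#'
#' Scales the seven swept maximal conductances (\eqn{\bar g_{SynS}},
#' \eqn{\bar g_{SynG}}, \eqn{\bar g_P}, \eqn{\bar g_{K2}}, \eqn{\bar g_h},
#' \eqn{\bar g_{CaS}}, \eqn{\bar g_{Leak}}) as percentages of their canonical
#' values and sets the leak reversal potential, leaving the fast-current
#' conductances (\eqn{\bar g_{Na}}, \eqn{\bar g_{K1}}, \eqn{\bar g_{KA}},
#' \eqn{\bar g_{CaF}}) at canonical.
#'
#' @param levels_pct named numeric of percent levels (0--175) for any subset
#'   of `SynS, SynG, P, K2, h, CaS, Leak`; omitted names stay at 100.
#' @param E_Leak_mV leak reversal potential (mV), default -60
#' @return An `hco_params` object.
#' @export
param_vector <- function(levels_pct = c(), E_Leak_mV = -60) {
  p <- canonical_parameters()
  if (length(levels_pct)) {
    bad <- setdiff(names(levels_pct), .swept_conductances)
    if (length(bad)) stop("not swept parameters: ", paste(bad, collapse = ", "))
    if (any(levels_pct < 0)) stop("negative percent level")
    p$gbar[names(levels_pct)] <- p$gbar[names(levels_pct)] * levels_pct / 100
  }
  p$E_Leak <- E_Leak_mV / 1000
  p
}

# ---- state vector layout -----------------------------------------------
# per neuron: V, 13 gates, Ca pool, M, s1, s2  (18 states; A then B)
.gate_names <- c("mNa", "hNa", "mP", "mCaF", "hCaF", "mCaS", "hCaS",
                 "mh", "mK1", "hK1", "mK2", "mKA", "hKA")
.neuron_state_names <- c("V", .gate_names, "pool", "M", "s1", "s2")

#' State-variable names of the two-cell network
#'
#' @return Character vector of length 36 (`A.V`, `A.mNa`, ..., `B.s2`).
#' @export
state_names <- function() {
  c(paste0("A.", .neuron_state_names), paste0("B.", .neuron_state_names))
}

# ordered list of (channel, gate) used everywhere: gives one gate_spec per
# state-vector gate slot
.gate_table <- function(spec = hco_model_spec()) {
  ch <- spec$channels
  list(ch$Na$activation, ch$Na$inactivation, ch$P$activation,
       ch$CaF$activation, ch$CaF$inactivation,
       ch$CaS$activation, ch$CaS$inactivation,
       ch$h$activation,
       ch$K1$activation, ch$K1$inactivation,
       ch$K2$activation,
       ch$KA$activation, ch$KA$inactivation)
}

#' Resting network state at given membrane potentials
#'
#' Gates are set to their steady states at the respective potential, the Ca
#' pool and synaptic event traces to zero, and M to its steady state.
#'
#' @param V_A,V_B initial membrane potentials (V)
#' @return Named numeric state vector of length 36.
#' @export
initial_state <- function(V_A = -0.045, V_B = -0.060) {
  spec <- hco_model_spec()
  gt <- .gate_table(spec)
  one <- function(V) {
    g <- vapply(gt, steady_state_gate, numeric(1), V = V)
    syn <- spec$synapse
    Minf <- syn$M_inf_floor + syn$M_inf_amp /
      (1 + exp(syn$M_inf_a * (V + syn$M_inf_b)))
    c(V, g, 0, Minf, 0, 0)
  }
  stats::setNames(c(one(V_A), one(V_B)), state_names())
}

# intrinsic + leak currents of one neuron given its state slice (R reference
# path; the C++ kernel re-implements this independently)
.neuron_currents <- function(s, p, spec) {
  ch <- spec$channels
  g <- p$gbar
  list(
    Na  = channel_current(ch$Na,  g[["Na"]],  s[["mNa"]],  s[["hNa"]],  s[["V"]]),
    P   = channel_current(ch$P,   g[["P"]],   s[["mP"]],   1,           s[["V"]]),
    CaF = channel_current(ch$CaF, g[["CaF"]], s[["mCaF"]], s[["hCaF"]], s[["V"]]),
    CaS = channel_current(ch$CaS, g[["CaS"]], s[["mCaS"]], s[["hCaS"]], s[["V"]]),
    h   = channel_current(ch$h,   g[["h"]],   s[["mh"]],   1,           s[["V"]]),
    K1  = channel_current(ch$K1,  g[["K1"]],  s[["mK1"]],  s[["hK1"]],  s[["V"]]),
    K2  = channel_current(ch$K2,  g[["K2"]],  s[["mK2"]],  1,           s[["V"]]),
    KA  = channel_current(ch$KA,  g[["KA"]],  s[["mKA"]],  s[["hKA"]],  s[["V"]]),
    Leak = g[["Leak"]] * (s[["V"]] - p$E_Leak)
  )
}

#' Right-hand side of the coupled two-cell ODE system
#'
#' Membrane equation \eqn{C \dot V = -(\sum I_{ion} + I_{Leak} + I_{SynG} +
#' I_{SynS} - I_{inject})} plus first-order gate kinetics
#' \eqn{\dot x = (x_\infty(V) - x)/\tau_x(V)}, the presynaptic Ca pool, the
#' synaptic modulation variable M, and the two exponential traces `s1`, `s2`
#' that carry the spike-triggered synaptic conductance (incremented by one
#' at each presynaptic spike event; their difference, scaled by the
#' normalization constant, equals the summed synaptic function). Each
#' neuron's synaptic terms use the *other* neuron as the presynaptic source;
#' with both synaptic conductances zero the two cells are fully decoupled.
#'
#' In the `deSolve` calling convention: `network_rhs(t, y, p)` with `y` a
#' 36-vector in [state_names()] order and `p` an `hco_params` object.
#'
#' @param t time (s)
#' @param y state vector (length 36)
#' @param p an `hco_params` object
#' @return A list whose first element is the derivative vector.
#' @export
network_rhs <- function(t, y, p) {
  if (any(!is.finite(y))) stop("non-finite state; integration failure")
  spec <- hco_model_spec()
  syn <- spec$synapse
  gt <- .gate_table(spec)
  y <- stats::setNames(as.numeric(y), state_names())
  deriv <- numeric(36)
  sl <- list(A = 1:18, B = 19:36)
  for (who in c("A", "B")) {
    other <- if (who == "A") "B" else "A"
    s <- y[sl[[who]]]
    names(s) <- .neuron_state_names
    so <- y[sl[[other]]]
    names(so) <- .neuron_state_names
    V <- s[["V"]]
    cur <- .neuron_currents(s, p, spec)
    # synaptic currents: presynaptic source is the other neuron
    sat <- so[["pool"]]^3 / (syn$pool_C + so[["pool"]]^3)
    I_syng <- p$gbar[["SynG"]] * sat * (V - syn$E_Syn)
    fsum <- syn$norm_const * (so[["s1"]] - so[["s2"]])
    I_syns <- p$gbar[["SynS"]] * so[["M"]] * fsum * (V - syn$E_Syn)
    dV <- -(Reduce(`+`, cur) + I_syng + I_syns - p$I_inject) / p$C
    dg <- vapply(seq_along(gt), function(i) {
      (steady_state_gate(gt[[i]], V) - s[[1 + i]]) / gate_time_constant(gt[[i]], V)
    }, numeric(1))
    dpool <- -(cur$CaF + cur$CaS) - syn$pool_B * s[["pool"]]
    Minf <- syn$M_inf_floor + syn$M_inf_amp /
      (1 + exp(syn$M_inf_a * (V + syn$M_inf_b)))
    dM <- (Minf - s[["M"]]) / syn$tau_M
    ds1 <- -s[["s1"]] / syn$tau_decay
    ds2 <- -s[["s2"]] / syn$tau_rise
    deriv[sl[[who]]] <- c(dV, dg, dpool, dM, ds1, ds2)
  }
  list(deriv)
}

# pack model constants into the flat numeric form the C++ kernel expects
.kernel_pack <- function(p) {
  spec <- hco_model_spec()
  gt <- .gate_table(spec)
  form_code <- c(standard = 0, h_ss = 1)
  tau_code <- c(standard = 0, na_h = 1, caf_m = 2)
  gates <- t(vapply(gt, function(g) {
    c(form_code[[g$form_id]], g$a, g$b,
      tau_code[[g$tau_form]], g$tau_a, g$tau_b, g$tau_c, g$tau_d)
  }, numeric(8)))
  syn <- spec$synapse
  list(
    gbar = as.numeric(p$gbar[c("Na", "P", "CaF", "CaS", "h", "K1", "K2",
                               "KA", "Leak", "SynS", "SynG")]),
    E_Leak = p$E_Leak, C = p$C, I_inject = p$I_inject,
    gates = gates,
    syn = c(syn$E_Syn, syn$tau_decay, syn$tau_rise, syn$norm_const,
            syn$M_inf_floor, syn$M_inf_amp, syn$M_inf_a, syn$M_inf_b,
            syn$tau_M, syn$pool_B, syn$pool_C)
  )
}
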