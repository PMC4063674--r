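# Canonical single-compartment leech heart-interneuron half-center oscillator
# model definition. Units are SI throughout: volts, seconds, siemens, farads,
# amperes. Steady states follow x_inf(V) = 1/(1 + exp(a*(V + b))) and time
# constants tau(V) = tau_c + tau_d/(1 + exp(tau_a*(V + tau_b))) unless a gate
# carries a special form_id (h-current steady state; Na inactivation and CaF
# activation time constants, which involve 1/cosh terms).
model: leech-heart-interneuron-hco
version: 1
membrane:
  C: 0.5e-9           # total membrane capacitance (F)
  I_inject: 0.0       # injected current (A); zero in every screen
reversal_potentials:  # (V)
  E_Na: 0.045
  E_Ca: 0.135
  E_h: -0.021
  E_K: -0.070
  E_Syn: -0.0625
channels:
  Na:
    x: 3
    "y": 1
    E_rev: 0.045
    activation:   {form_id: standard, a: -150.0, b: 0.029,
                   tau_form: standard, tau_a: 0.0, tau_b: 0.0, tau_c: 1.0e-4, tau_d: 0.0}
    inactivation: {form_id: standard, a: 500.0, b: 0.030,
                   tau_form: na_h, tau_a: 500.0, tau_b: 0.028, tau_c: 0.004, tau_d: 0.006}
  P:
    x: 1
    "y": 0
    E_rev: 0.045
    activation:   {form_id: standard, a: -120.0, b: 0.039,
                   tau_form: standard, tau_a: 400.0, tau_b: 0.057, tau_c: 0.01, tau_d: 0.2}
  CaF:
    x: 2
    "y": 1
    E_rev: 0.135
    activation:   {form_id: standard, a: -600.0, b: 0.0467,
                   tau_form: caf_m, tau_a: 330.0, tau_b: 0.0467, tau_c: 0.011, tau_d: 0.024}
    inactivation: {form_id: standard, a: 350.0, b: 0.0555,
                   tau_form: standard, tau_a: 270.0, tau_b: 0.055, tau_c: 0.06, tau_d: 0.31}
  CaS:
    x: 2
    "y": 1
    E_rev: 0.135
    activation:   {form_id: standard, a: -420.0, b: 0.0472,
                   tau_form: standard, tau_a: -400.0, tau_b: 0.0487, tau_c: 0.005, tau_d: 0.134}
    inactivation: {form_id: standard, a: 360.0, b: 0.055,
                   tau_form: standard, tau_a: -250.0, tau_b: 0.043, tau_c: 0.2, tau_d: 5.25}
  h:
    x: 2
    "y": 0
    E_rev: -0.021
    activation:   {form_id: h_ss, a: 180.0, b: 0.047,
                   tau_form: standard, tau_a: -100.0, tau_b: 0.073, tau_c: 0.7, tau_d: 1.7}
  K1:
    x: 2
    "y": 1
    E_rev: -0.070
    activation:   {form_id: standard, a: -143.0, b: 0.021,
                   tau_form: standard, tau_a: 150.0, tau_b: 0.016, tau_c: 0.001, tau_d: 0.011}
    inactivation: {form_id: standard, a: 111.0, b: 0.028,
                   tau_form: standard, tau_a: -143.0, tau_b: 0.013, tau_c: 0.5, tau_d: 0.2}
  K2:
    x: 2
    "y": 0
    E_rev: -0.070
    activation:   {form_id: standard, a: -83.0, b: 0.020,
                   tau_form: standard, tau_a: 200.0, tau_b: 0.035, tau_c: 0.057, tau_d: 0.043}
  KA:
    x: 2
    "y": 1
    E_rev: -0.070
    activation:   {form_id: standard, a: -130.0, b: 0.044,
                   tau_form: standard, tau_a: 200.0, tau_b: 0.030, tau_c: 0.005, tau_d: 0.011}
    inactivation: {form_id: standard, a: 160.0, b: 0.063,
                   tau_form: standard, tau_a: -300.0, tau_b: 0.055, tau_c: 0.026, tau_d: 0.0085}
synapse:
  E_Syn: -0.0625      # synaptic reversal potential (V)
  tau_decay: 0.011    # decay time of the spike-triggered conductance (s)
  tau_rise: 0.002     # rise time of the spike-triggered conductance (s)
  # modulation variable M of the spike-mediated synapse:
  # M_inf = 0.1 + 0.9/(1 + exp(-1000*(Vpre + 0.040))), tau_M = 0.2 s
  M_inf_floor: 0.1
  M_inf_amp: 0.9
  M_inf_a: -1000.0
  M_inf_b: 0.040
  tau_M: 0.2
  # presynaptic Ca pool driving graded transmission:
  # dP/dt = -(I_CaF + I_CaS) - B*P, g_graded = gbar_SynG * P^3/(C_grad + P^3)
  pool_B: 10.0        # pool decay rate (1/s)
  pool_C: 1.0e-32     # half-saturation constant (A^3 s^3)
canonical:            # maximal conductances of the canonical model (S)
  gbar:
    Na: 200.0e-9
    P: 7.0e-9
    CaF: 5.0e-9
    CaS: 3.2e-9
    h: 4.0e-9
    K1: 100.0e-9
    K2: 80.0e-9
    KA: 80.0e-9
    Leak: 8.0e-9
    SynS: 60.0e-9
    SynG: 30.0e-9
  E_Leak: -0.060      # leak reversal potential (V)
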