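# Default model parameters.
#
# Channel/transporter kinetic constants are literature-style defaults for CA1
# pyramidal cells (delayed rectifier / A-type / M / h / L-type calcium gating,
# two-state KCC2 carrier with neuronal affinities, two-faced NKCC1 carrier,
# saturating Na/K-ATPase, plasma-membrane calcium pump, Na/Ca exchanger,
# first-order glial potassium buffering). Densities marked "calibrated" are
# determined at run time by balance_rest().

physical:
  temperature_c: 32.0
  capacitance_uf_cm2: 1.0
  axial_resistivity_ohm_cm: 150.0

solver:
  dt_ms: 0.02
  v_init_mV: -66.0

shell_fraction: 0.15

ions:
  # Longitudinal diffusion constants, um^2/ms (= 1e-5 cm^2/s).
  diffusion_um2_ms: {na: 1.33, k: 1.96, cl: 2.08, ca: 0.60}
  initial_mM:
    na_i: 12.0
    k_i: 140.0
    cl_i: 4.5
    ca_i: 5.0e-5
    na_o: 151.0
    k_o: 3.5
    cl_o: 131.0
    ca_o: 2.0
  hco3_i_mM: 15.0
  hco3_o_mM: 25.0

glial_buffer:
  total_mM: 500.0          # total buffer, expressed in shell-volume mM
  kf_per_mM_ms: 4.0e-6     # K+ + B -> KB
  kb_per_ms: 1.4e-5        # KB -> K+ + B ; kb/kf = 3.5 mM rest equilibrium

regions:
  apical_proximal_max_um: 150.0
  radiatum_medial_max_um: 300.0
  radiatum_distal_max_um: 400.0
  oriens_proximal_max_um: 100.0
  trunk_radius_um: 0.6

na_markov:
  gbar_axon_S_cm2: 0.1
  gbar_thick_S_cm2: 0.014    # soma and dendrites with radius > 0.6 um
  gbar_thin_S_cm2: 0.0014
  radius_threshold_um: 0.6
  slow_distance_um: 250.0
  rates:
    am_a: 0.4      # activation forward, linoid
    am_th: -34.0
    am_q: 7.2
    bm_a: 0.124    # activation backward, reverse linoid
    bm_th: -34.0
    bm_q: 7.2
    koi_a: 1.5     # open -> fast-inactivated, a*exp(v/b)
    koi_b: 60.0
    kic_a: 5.0e-4  # fast-inactivated -> closed recovery, a*exp(-v/b)
    kic_b: 10.0
    kis_a: 0.002   # fast- -> slow-inactivated (6-state only), a*exp(v/b)
    kis_b: 100.0
    ksi_a: 0.001   # slow-inactivated recovery, a*exp(-(v-vh)/b)
    ksi_vh: -60.0
    ksi_b: 40.0

gaba:
  quantal_nS: 1.0
  hco3_fraction: 0.2        # 1:4 bicarbonate:chloride permeability
  densities_per_um:
    soma: 1.7
    apical_proximal: 1.7
    radiatum_thick_medial: 0.5
    radiatum_thick_distal_or_thin: 0.15
    lacunosum_moleculare: 0.12
    oriens_proximal: 0.61
    oriens_distal: 0.1
    axon: 0.0
  rates:
    kon_per_mM_ms: 5.0   # per binding site
    koff_per_ms: 0.13
    beta_per_ms: 2.5     # doubly bound -> open
    alpha_per_ms: 0.25   # open -> doubly bound
    d1_on_per_ms: 0.004  # singly bound -> slow desensitized
    d1_off_per_ms: 0.001
    d2_on_per_ms: 0.2    # doubly bound -> fast desensitized
    d2_off_per_ms: 0.02

transporters:
  kcc2:
    umax_mA_cm2: 0.02
    km_k_mM: 5.2
    km_cl_mM: 9.6
  nkcc1:
    umax_mA_cm2: calibrated   # set so NKCC1 Cl loading balances KCC2 at rest
    km_na_mM: 15.0
    km_k_mM: 10.0
    km_cl_mM: 35.0
    k_loaded_per_ms: 0.3
    k_empty_per_ms: 0.3
  nak:
    imax_mA_cm2: calibrated
    km_na_mM: 10.0
    km_k_mM: 3.5
    margin: 0.20              # pump set 20% above the minimum balancing rate
  ca_pump:
    imax_mA_cm2: 2.2e-5
    km_mM: 5.0e-4
  nacax:
    scale_mA_cm2: calibrated  # set to balance calcium pump + channels at rest
    km_na_mM: 87.5
    km_ca_mM: 1.38
    gamma: 0.35
    ksat: 0.1

hh_channels:
  kdr:
    ion: k
    density: {soma: 0.040, axon: 0.040, apical: 0.020, basal: 0.020}
    gates:
      - {name: n, exponent: 2, inf_vhalf: 13.0, inf_slope: 8.8,
         tau_base: 0.8, tau_amp: 18.0, tau_vmax: -25.0, tau_sig1: 20.0, tau_sig2: 20.0}
  ka:
    ion: k
    density: {soma: 0.0075, axon: 0.0075, apical: 0.0075, basal: 0.0075,
              dist_slope_per_um: 0.011, dist_factor_max: 5.0}
    gates:
      - {name: a, exponent: 3, inf_vhalf: -10.0, inf_slope: 15.0,
         tau_base: 0.4, tau_amp: 2.0, tau_vmax: -30.0, tau_sig1: 25.0, tau_sig2: 25.0}
      - {name: b, exponent: 1, inf_vhalf: -56.0, inf_slope: -8.0,
         tau_base: 6.0, tau_amp: 20.0, tau_vmax: -60.0, tau_sig1: 25.0, tau_sig2: 25.0}
  km:
    ion: k
    density: {soma: 1.0e-3, axon: 1.0e-3, apical: 1.0e-3, basal: 1.0e-3}
    gates:
      - {name: m, exponent: 1, inf_vhalf: -35.0, inf_slope: 6.0,
         tau_base: 20.0, tau_amp: 60.0, tau_vmax: -40.0, tau_sig1: 20.0, tau_sig2: 20.0}
  ih:
    ion: mixed
    erev_mV: -30.0
    na_fraction: 0.35
    density: {soma: 1.9e-4, axon: 0.0, apical: 1.9e-4, basal: 1.9e-4,
              dist_slope_per_um: 0.017, dist_factor_max: 7.0}
    gates:
      - {name: q, exponent: 1, inf_vhalf: -82.0, inf_slope: -7.0,
         tau_base: 20.0, tau_amp: 40.0, tau_vmax: -75.0, tau_sig1: 20.0, tau_sig2: 20.0}
  cal:
    ion: ca
    density: {soma: 3.0e-5, axon: 0.0, apical: 3.0e-5, basal: 3.0e-5}
    gates:
      - {name: m, exponent: 2, inf_vhalf: -5.0, inf_slope: 6.0,
         tau_base: 0.5, tau_amp: 2.0, tau_vmax: -20.0, tau_sig1: 15.0, tau_sig2: 15.0}
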