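# Shared fixtures and cached simulations (computed once per test run).

.fixture_cache <- new.env(parent = emptyenv())

cached <- function(key, expr) {
  if (!exists(key, envir = .fixture_cache)) {
    assign(key, force(expr), envir = .fixture_cache)
  }
  get(key, envir = .fixture_cache)
}

# reduced CA1-like cell, calibrated at -66 mV
ca1_model <- function() {
  cached("ca1", balance_rest(attach_mechanisms(make_fixture("pyramidal"))))
}

ball_stick_model <- function() {
  cached("bs", balance_rest(attach_mechanisms(make_fixture("ball_and_stick"))))
}

branched_model <- function() {
  cached("branched", balance_rest(attach_mechanisms(make_fixture("branched"))))
}

soma_of <- function(model) which(model$geometry$region == "soma")[1]

# control HFS (sodium blocked, as in the mechanism-dissection figures)
hfs_ctrl <- function() {
  cached("hfs_ctrl",
         run_hfs(ca1_model(), activation = 0.8, na_scale = 0, post_ms = 1500))
}

hfs_quinine <- function() {
  cached("hfs_quinine",
         run_intervention(ca1_model(), gaba_inhibition = 0.6, activation = 0.8,
                          na_scale = 0, post_ms = 1500))
}

hfs_kcc2_60 <- function() {
  cached("hfs_kcc2_60",
         run_intervention(ca1_model(), kcc2_inhibition = 0.6, activation = 0.8,
                          na_scale = 0, post_ms = 1500))
}

hfs_kcc2_100 <- function() {
  cached("hfs_kcc2_100",
         run_intervention(ca1_model(), kcc2_inhibition = 1, activation = 0.8,
                          na_scale = 0, post_ms = 1500))
}

# uniform synapse density across every region (for geometry-only properties)
uniform_density <- function(per_um = 0.5) {
  as.list(stats::setNames(rep(per_um, length(ionshift:::REGIONS)),
                          ionshift:::REGIONS))
}

# passive single-compartment model: one leak conductance, nothing else
passive_single <- function(gleak_S_cm2 = 5e-5) {
  m <- attach_mechanisms(make_fixture("single"))
  m$mech$hh_g[] <- 0
  m$mech$na_gbar[] <- 0
  m$mech$gaba_gbar[] <- 0
  m$mech$kcc2_U[] <- 0
  m$mech$capump_imax[] <- 0
  m$calibration <- list(
    v_rest = NA_real_, margin = 0,
    nak_imax = 0, i_pump_rest = 0, i_pump_min = 0,
    gleak_na = 0, gleak_k = gleak_S_cm2, gleak_cl = 0,
    nkcc1_U = 0, nacax_scale = 0, residuals = matrix(0, 1, 4)
  )
  m
}

# strip all mechanisms from a calibrated model (sealed-cell configuration:
# no pumps, channels, leaks or transporters; diffusion/buffering remain)
seal_model <- function(m) {
  m$mech$hh_g[] <- 0
  m$mech$na_gbar[] <- 0
  m$mech$gaba_gbar[] <- 0
  m$mech$kcc2_U[] <- 0
  m$mech$capump_imax[] <- 0
  m$calibration$nak_imax[] <- 0
  m$calibration$gleak_na[] <- 0
  m$calibration$gleak_k[] <- 0
  m$calibration$gleak_cl[] <- 0
  m$calibration$nkcc1_U[] <- 0
  m$calibration$nacax_scale[] <- 0
  m
}

total_moles <- function(conc, kb, geom) {
  out <- vapply(1:4, function(j) {
    sum(conc[, j] * geom$vol_i_cm3 + conc[, j + 4] * geom$vol_o_cm3)
  }, numeric(1))
  out[2] <- out[2] + sum(kb * geom$vol_o_cm3)  # buffered K+ counts as K
  out
}

# mixed-radius fixture: two apical sticks of equal length, thick vs thin,
# with a uniform synapse density so only geometry differs
radius_contrast_run <- function() {
  cached("radius_run", {
    mk <- new_ion_model(
      length_um = c(20, rep(25, 4), rep(25, 4)),
      radius_um = c(10, rep(1.0, 4), rep(0.4, 4)),
      parent = c(NA, 1, 2, 3, 4, 1, 6, 7, 8),
      type = c(1, rep(4, 8)))
    mk <- balance_rest(attach_mechanisms(mk, gaba_densities = uniform_density()))
    n <- nrow(mk$geometry)
    pr <- ion_protocol(duration_ms = 800,
                       trains = list(hfs_train(start_ms = 100)),
                       train_targets = list(seq_len(n)),
                       gaba_scale = rep(0.8, n), na_scale = 0,
                       record_dt_ms = 2)
    list(model = mk, trace = simulate(mk, pr))
  })
}

secondary_pulse_runs <- function() {
  cached("secondary", {
    m <- ca1_model()
    list(distal = run_secondary_pulse(m, "distal_dendrites"),
         perisomatic = run_secondary_pulse(m, "perisomatic"),
         no_hfs = run_secondary_pulse(m, "distal_dendrites", with_hfs = FALSE))
  })
}

kcc2_recovery_fit <- function() {
  cached("kcc2_fit", {
    m <- ball_stick_model()
    target <- chloride_clearance_curve(m, duration_ms = 2500)
    list(target = target,
         fit = fit_kcc2_density(m, target, interval = c(0.3, 3)))
  })
}

dt_halving_peaks <- function() {
  cached("dt_halving", {
    m <- ca1_model()
    comps <- target_compartments(m, c("soma", "apical"))
    n <- nrow(m$geometry); sc <- rep(0, n); sc[comps] <- 0.8
    pr <- ion_protocol(duration_ms = 1000,
                       trains = list(hfs_train(start_ms = 100)),
                       train_targets = list(comps), gaba_scale = sc,
                       na_scale = 0, record_dt_ms = 1)
    soma <- soma_of(m)
    t1 <- simulate(m, pr, dt_ms = 0.02)
    t2 <- simulate(m, pr, dt_ms = 0.01)
    base <- mean(t1$v[t1$time < 100, soma])
    c(coarse = max(t1$v[, soma]) - base, fine = max(t2$v[, soma]) - base)
  })
}
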