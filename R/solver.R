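#' Attach channels, synapses and transporters to a morphology
#'
#' Fills per-compartment densities: Hodgkin-Huxley channel conductances (with
#' region bases and optional distance gradients), the fast-sodium maximal
#' conductance (0.1 S/cm2 in the axon, 0.014 S/cm2 in the soma and dendrites
#' with radius above the 0.6 um threshold, 0.0014 S/cm2 in thinner dendrites)
#' together with its slow-inactivation fraction gradient, GABA-A synapses at
#' the layer densities, and transporter densities. Pump/leak/exchanger values
#' marked "calibrated" are filled by [balance_rest()].
#'
#' @param model an `ion_model`.
#' @param gaba_densities optional synapse-density override (see
#'   [place_synapses()]).
#' @return the model with a `mech` component.
#' @export
attach_mechanisms <- function(model, gaba_densities = NULL) {
  g <- model$geometry
  p <- model$params
  n <- nrow(g)

  chan_names <- names(p$hh_channels)
  hh_g <- matrix(0, n, length(chan_names),
                 dimnames = list(NULL, chan_names))
  chan_ion <- integer(length(chan_names))
  chan_erev <- rep(NA_real_, length(chan_names))
  chan_nafrac <- rep(0, length(chan_names))
  gates_flat <- list()
  for (ci in seq_along(chan_names)) {
    ch <- p$hh_channels[[ci]]
    d <- ch$density
    base <- c(d$soma, d$axon, d$basal, d$apical)[match(g$type, c(1, 2, 3, 4))]
    fac <- rep(1, n)
    if (!is.null(d$dist_slope_per_um)) {
      dendr <- g$type %in% c(3L, 4L)
      fac[dendr] <- pmin(1 + d$dist_slope_per_um * g$dist_um[dendr],
                         d$dist_factor_max)
    }
    hh_g[, ci] <- base * fac
    chan_ion[ci] <- switch(ch$ion, na = 0L, k = 1L, ca = 2L, mixed = 3L)
    if (!is.null(ch$erev_mV)) chan_erev[ci] <- ch$erev_mV
    if (!is.null(ch$na_fraction)) chan_nafrac[ci] <- ch$na_fraction
    for (gt in ch$gates) gates_flat[[length(gates_flat) + 1L]] <-
      c(list(channel = ci), gt)
  }

  nm <- p$na_markov
  na_gbar <- ifelse(g$type == 2L, nm$gbar_axon_S_cm2,
                    ifelse(g$radius_um > nm$radius_threshold_um,
                           nm$gbar_thick_S_cm2, nm$gbar_thin_S_cm2))
  na_fraction <- slow_na_fraction(g$dist_um, nm$slow_distance_um)
  na_fraction[g$type %in% c(1L, 2L)] <- 0  # soma and axon: 5-state only

  syn <- place_synapses(model, gaba_densities)

  model$mech <- list(
    chan_names = chan_names, hh_g = hh_g, chan_ion = chan_ion,
    chan_erev = chan_erev, chan_nafrac = chan_nafrac, gates_flat = gates_flat,
    na_gbar = na_gbar, na_fraction = na_fraction,
    gaba_count = syn$count, gaba_gbar = syn$gbar_S_cm2,
    # KCC2 is somatodendritic; the axon carries no KCC2 (or NKCC1 loading)
    kcc2_U = ifelse(g$type == 2L, 0, p$transporters$kcc2$umax_mA_cm2),
    capump_imax = rep(p$transporters$ca_pump$imax_mA_cm2, n)
  )
  model
}

#' Initial dynamical state of a model
#'
#' Voltage at the configured resting potential, Hodgkin-Huxley gates at
#' steady state, sodium and GABA-A Markov schemes at their stationary
#' distributions, the NKCC1 carrier at its steady split, and the glial buffer
#' equilibrated to the resting extracellular potassium.
#'
#' @param model an `ion_model` with mechanisms attached.
#' @param v_mV initial membrane potential (defaults to the solver setting).
#' @return a named list (class `ion_state`).
#' @export
initial_state <- function(model, v_mV = model$params$solver$v_init_mV) {
  stopifnot(!is.null(model$mech))
  p <- model$params
  n <- nrow(model$geometry)
  conc <- matrix(rep(initial_concentrations(p), each = n), n, 8,
                 dimnames = list(NULL, ION_COLS))
  gf <- model$mech$gates_flat
  gates <- vapply(gf, function(gt) rep(gate_inf(gt, v_mV), n),
                  numeric(n))
  gates <- matrix(gates, n, length(gf))
  na5 <- matrix(rep(markov_equilibrium(build_na_scheme(p, FALSE), v_mV),
                    each = n), n, 5)
  na6 <- matrix(rep(markov_equilibrium(build_na_scheme(p, TRUE), v_mV),
                    each = n), n, 6)
  gaba <- matrix(rep(c(1, 0, 0, 0, 0, 0), each = n), n, 6)
  tp <- p$transporters$nkcc1
  y <- rep(nkcc1_steady_y(conc[1, 1], conc[1, 5], conc[1, 2], conc[1, 6],
                          conc[1, 3], conc[1, 7], tp), n)
  kb <- rep(glial_buffer_equilibrium(conc[1, 6], p$glial_buffer), n)
  structure(list(t = 0, v = rep(v_mV, n), conc = conc, gates = gates,
                 na5 = na5, na6 = na6, gaba = gaba, y = y, kb = kb),
            class = "ion_state")
}

#' Protocol description
#'
#' A timed set of stimuli and interventions applied during [simulate()].
#'
#' @param duration_ms simulated time.
#' @param injections data frame with columns `comp`, `t0_ms`, `t1_ms`,
#'   `amp_nA` (constant current steps), or `NULL`.
#' @param noise data frame with columns `comp`, `mean_nA`, `sd_nA` (Gaussian
#'   current drawn each time step), or `NULL`.
#' @param trains list of [transmitter_train()] objects.
#' @param train_targets list of integer compartment vectors, one per train.
#' @param gaba_scale per-compartment multiplier on the synaptic conductance
#'   (activation fraction times any pharmacological inhibition); scalar or
#'   length-n vector.
#' @param glut list describing glutamate-like pulses: `comps`, `onsets_ms`,
#'   `gmax_nS`, `tau_rise_ms`, `tau_decay_ms`, or `NULL`.
#' @param clamp voltage clamp: list with `comps`, `times_ms`, `values_mV`
#'   (piecewise-constant command), or `NULL`.
#' @param k_clamp extracellular-potassium clamp: `TRUE` freezes `[K]o` at its
#'   initial value; a list `(times_ms, values_mM)` imposes a waveform
#'   (linearly interpolated) in every shell.
#' @param kcc2_frozen_k if `TRUE`, KCC2 senses the resting `[K]o` while all
#'   other mechanisms see the true value.
#' @param kcc2_scale,na_scale multipliers on KCC2 transport and fast-sodium
#'   conductance.
#' @param conc_dynamics,diffusion,buffer logical switches for concentration
#'   updates, longitudinal diffusion and glial buffering.
#' @param record_dt_ms recording interval.
#' @return an object of class `ion_protocol`.
#' @export
ion_protocol <- function(duration_ms, injections = NULL, noise = NULL,
                         trains = list(), train_targets = list(),
                         gaba_scale = 1, glut = NULL, clamp = NULL,
                         k_clamp = NULL, kcc2_frozen_k = FALSE,
                         kcc2_scale = 1, na_scale = 1, conc_dynamics = TRUE,
                         diffusion = TRUE, buffer = TRUE,
                         record_dt_ms = 0.5) {
  stopifnot(duration_ms > 0, length(trains) == length(train_targets))
  structure(list(
    duration_ms = duration_ms, injections = injections, noise = noise,
    trains = trains, train_targets = train_targets, gaba_scale = gaba_scale,
    glut = glut, clamp = clamp, k_clamp = k_clamp,
    kcc2_frozen_k = isTRUE(kcc2_frozen_k), kcc2_scale = kcc2_scale,
    na_scale = na_scale, conc_dynamics = isTRUE(conc_dynamics),
    diffusion = isTRUE(diffusion), buffer = isTRUE(buffer),
    record_dt_ms = record_dt_ms
  ), class = "ion_protocol")
}

# numeric model description consumed by the compiled engine
compile_engine_model <- function(model) {
  g <- model$geometry
  p <- model$params
  m <- model$mech
  cal <- model$calibration
  if (is.null(cal)) {
    stop("model is not calibrated; run balance_rest() first", call. = FALSE)
  }
  gf <- m$gates_flat
  gate_pars <- t(vapply(gf, function(gt) c(gt$inf_vhalf, gt$inf_slope,
                                           gt$tau_base, gt$tau_amp,
                                           gt$tau_vmax, gt$tau_sig1,
                                           gt$tau_sig2), numeric(7)))
  tr <- p$transporters
  list(
    n = nrow(g),
    parent = ifelse(is.na(g$parent), -1L, g$parent - 1L),
    area = g$area_cm2, vol_i = g$vol_i_cm3, vol_o = g$vol_o_cm3,
    g_ax = ifelse(is.na(model$g_axial), 0, model$g_axial),
    surf_i = ifelse(is.na(model$diff_surf_i), 0, model$diff_surf_i),
    surf_o = ifelse(is.na(model$diff_surf_o), 0, model$diff_surf_o),
    ddist = ifelse(is.na(model$diff_dist), 1, model$diff_dist),
    cm = p$physical$capacitance_uf_cm2,
    rtf = rtf_mV(p$physical$temperature_c),
    d_ion = unlist(p$ions$diffusion_um2_ms)[ION_NAMES] * 1e-8,
    hh_g = m$hh_g,
    chan_ion = m$chan_ion,
    chan_erev = ifelse(is.na(m$chan_erev), 0, m$chan_erev),
    chan_nafrac = m$chan_nafrac,
    gate_chan = vapply(gf, function(gt) gt$channel - 1L, integer(1)),
    gate_exp = vapply(gf, function(gt) as.numeric(gt$exponent), numeric(1)),
    gate_pars = gate_pars,
    na_gbar = m$na_gbar, na_fraction = m$na_fraction,
    na5_trans = scheme_matrix(build_na_scheme(p, FALSE)),
    na6_trans = scheme_matrix(build_na_scheme(p, TRUE)),
    gaba_trans = scheme_matrix(build_gaba_scheme(p)),
    gaba_gbar = m$gaba_gbar,
    hco3_frac = p$gaba$hco3_fraction,
    e_hco3 = nernst(p$ions$hco3_o_mM, p$ions$hco3_i_mM, -1,
                    p$physical$temperature_c),
    kcc2_U = m$kcc2_U, kcc2_km_k = tr$kcc2$km_k_mM,
    kcc2_km_cl = tr$kcc2$km_cl_mM,
    nkcc1_U = cal$nkcc1_U, nkcc1_km_na = tr$nkcc1$km_na_mM,
    nkcc1_km_k = tr$nkcc1$km_k_mM, nkcc1_km_cl = tr$nkcc1$km_cl_mM,
    nkcc1_kt = tr$nkcc1$k_loaded_per_ms, nkcc1_ke = tr$nkcc1$k_empty_per_ms,
    nak_imax = cal$nak_imax, nak_km_na = tr$nak$km_na_mM,
    nak_km_k = tr$nak$km_k_mM,
    capump_imax = m$capump_imax, capump_km = tr$ca_pump$km_mM,
    nacax_scale = cal$nacax_scale, nacax_km_na = tr$nacax$km_na_mM,
    nacax_km_ca = tr$nacax$km_ca_mM, nacax_gamma = tr$nacax$gamma,
    nacax_ksat = tr$nacax$ksat,
    gleak_na = cal$gleak_na, gleak_k = cal$gleak_k, gleak_cl = cal$gleak_cl,
    buf_total = p$glial_buffer$total_mM,
    buf_kf = p$glial_buffer$kf_per_mM_ms,
    buf_kb = p$glial_buffer$kb_per_ms,
    k_o_rest = p$ions$initial_mM$k_o
  )
}

compile_engine_protocol <- function(model, protocol, dt) {
  n <- nrow(model$geometry)
  pr <- protocol
  inj <- pr$injections
  if (is.null(inj)) inj <- data.frame(comp = integer(0), t0_ms = numeric(0),
                                      t1_ms = numeric(0), amp_nA = numeric(0))
  noise <- pr$noise
  if (is.null(noise)) noise <- data.frame(comp = integer(0),
                                          mean_nA = numeric(0),
                                          sd_nA = numeric(0))
  gaba_scale <- rep_len(pr$gaba_scale, n)
  glut <- pr$glut
  clamp <- pr$clamp
  kc <- pr$k_clamp
  k_mode <- 0L; k_times <- numeric(0); k_vals <- numeric(0)
  if (isTRUE(kc)) {
    k_mode <- 1L
  } else if (is.list(kc)) {
    k_mode <- 2L; k_times <- kc$times_ms; k_vals <- kc$values_mM
  }
  list(
    nsteps = as.integer(round(pr$duration_ms / dt)),
    dt = dt,
    inj_comp = as.integer(inj$comp) - 1L, inj_t0 = inj$t0_ms,
    inj_t1 = inj$t1_ms, inj_amp = inj$amp_nA * 1e-6,
    noise_comp = as.integer(noise$comp) - 1L,
    noise_mean = noise$mean_nA * 1e-6, noise_sd = noise$sd_nA * 1e-6,
    train_onsets = lapply(pr$trains, function(tr) tr$onsets),
    train_peak = vapply(pr$trains, function(tr) tr$peak, numeric(1)),
    train_sq = vapply(pr$trains, function(tr) tr$square, numeric(1)),
    train_tau = vapply(pr$trains, function(tr) tr$tau, numeric(1)),
    train_targets = lapply(pr$train_targets, function(x) as.integer(x) - 1L),
    gaba_scale = gaba_scale,
    glut_comp = if (is.null(glut)) integer(0) else as.integer(glut$comps) - 1L,
    glut_onsets = if (is.null(glut)) numeric(0) else glut$onsets_ms,
    # gmax_nS is the total pulse conductance, divided across the target region
    glut_gmax = if (is.null(glut)) 0 else
      glut$gmax_nS * 1e-9 / length(glut$comps),
    glut_tau_r = if (is.null(glut)) 0.5 else glut$tau_rise_ms,
    glut_tau_d = if (is.null(glut)) 2 else glut$tau_decay_ms,
    clamp_comp = if (is.null(clamp)) integer(0) else as.integer(clamp$comps) - 1L,
    clamp_times = if (is.null(clamp)) numeric(0) else clamp$times_ms,
    clamp_vals = if (is.null(clamp)) numeric(0) else clamp$values_mV,
    k_mode = k_mode, k_times = k_times, k_vals = k_vals,
    kcc2_frozen_k = pr$kcc2_frozen_k,
    kcc2_scale = pr$kcc2_scale, na_scale = pr$na_scale,
    conc_dyn = pr$conc_dynamics, diffusion_on = pr$diffusion,
    buffer_on = pr$buffer,
    record_stride = max(1L, as.integer(round(pr$record_dt_ms / dt)))
  )
}

#' Run a simulation
#'
#' Advances the coupled voltage/state/concentration system with the
#' operator-split implicit-Euler scheme: explicit gate and carrier updates,
#' implicit Markov updates, a direct (Hines-ordered) implicit solve for the
#' voltage on the branched tree, then concentration, glial-buffer and
#' diffusion updates from the per-ion membrane currents evaluated at the new
#' voltage.
#'
#' @param model a calibrated `ion_model`.
#' @param protocol an [ion_protocol()].
#' @param dt_ms time step (default from the model parameters, 0.02 ms).
#' @param state optional initial `ion_state` (defaults to the calibrated
#'   rest).
#' @return a `trace_set`: recorded time series plus spike times, cumulative
#'   per-ion membrane charge, and the final state.
#' @export
simulate <- function(model, protocol, dt_ms = model$params$solver$dt_ms,
                     state = NULL) {
  if (is.null(state)) state <- initial_state(model)
  mc <- compile_engine_model(model)
  pc <- compile_engine_protocol(model, protocol, dt_ms)
  out <- engine_run(mc, list(v = state$v, conc = state$conc,
                             gates = state$gates, na5 = state$na5,
                             na6 = state$na6, gaba = state$gaba,
                             y = state$y, kb = state$kb), pc)
  new_trace_set(out, model, protocol, dt_ms, t0 = state$t)
}

new_trace_set <- function(out, model, protocol, dt, t0 = 0) {
  fs <- out$final_state
  final <- structure(list(t = t0 + protocol$duration_ms, v = fs$v,
                          conc = fs$conc, gates = fs$gates, na5 = fs$na5,
                          na6 = fs$na6, gaba = fs$gaba, y = fs$y,
                          kb = fs$kb), class = "ion_state")
  structure(list(
    time = t0 + out$t, v = out$v,
    conc = stats::setNames(out$conc, ION_COLS),
    e_cl = out$e_cl, e_gaba = out$e_gaba,
    i_gaba_cl = out$i_gaba_cl, i_gaba_hco3 = out$i_gaba_hco3,
    i_kcc2 = out$i_kcc2,
    clamp_i = out$clamp_i,
    spikes = data.frame(comp = out$spike_comp + 1L, t_ms = t0 + out$spike_t),
    charge = out$charge,
    final_state = final,
    meta = list(dt_ms = dt, n = nrow(model$geometry),
                regions = model$geometry$region,
                dist_um = model$geometry$dist_um)
  ), class = "trace_set")
}

#' @export
print.trace_set <- function(x, ...) {
  cat(sprintf("<trace_set> %d samples x %d compartments, t = %.4g..%.4g ms, %d spikes\n",
              length(x$time), x$meta$n, min(x$time), max(x$time),
              nrow(x$spikes)))
  invisible(x)
}

#' Long-format data frame of a recorded series
#'
#' @param x a `trace_set`.
#' @param series name of a recorded series (`"v"`, `"e_gaba"`, `"e_cl"`,
#'   `"i_gaba_cl"`, `"i_gaba_hco3"`, `"i_kcc2"`, or a concentration column
#'   such as `"cl_i"`, `"k_o"`).
#' @param comps compartments to include (default all).
#' @return data frame with `t_ms`, `comp`, `value`.
#' @export
trace_series <- function(x, series, comps = seq_len(x$meta$n)) {
  m <- if (series %in% names(x$conc)) x$conc[[series]] else x[[series]]
  if (is.null(m)) stop("unknown series: ", series, call. = FALSE)
  data.frame(t_ms = rep(x$time, length(comps)),
             comp = rep(comps, each = length(x$time)),
             value = as.vector(m[, comps]))
}

#' Write recorded traces as delimited text
#'
#' @param x a `trace_set`.
#' @param path output file (tab separated).
#' @param series which series to include.
#' @export
write_traces <- function(x, path, series = c("v", "e_gaba")) {
  dfs <- lapply(series, function(s) {
    d <- trace_series(x, s); d$series <- s; d
  })
  utils::write.table(do.call(rbind, dfs), path, sep = "\t",
                     row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Detect action potentials in a voltage trace
#'
#' Upward crossings of the 0 mV threshold with a 2 ms refractory period.
#'
#' @param t_ms time base.
#' @param v voltage vector.
#' @param threshold_mV,refractory_ms detection settings.
#' @return spike times, ms.
#' @export
detect_spikes <- function(t_ms, v, threshold_mV = 0, refractory_ms = 2) {
  up <- which(v[-1] >= threshold_mV & v[-length(v)] < threshold_mV) + 1L
  if (!length(up)) return(numeric(0))
  times <- t_ms[up]
  keep <- c(TRUE, diff(times) > refractory_ms)
  while (!all(keep)) {
    times <- times[keep]
    keep <- c(TRUE, diff(times) > refractory_ms)
  }
  times
}

#' Axial current between adjacent compartments
#'
#' `I = g_axial (V_to - V_from) / area_to` (mA/cm2, normalised to the target
#' membrane area). The sign follows the membrane convention for the target
#' compartment: current flowing into the target that depolarises it is
#' negative.
#'
#' @param model an `ion_model`.
#' @param v_from,v_to membrane potentials (vectors over time are fine), mV.
#' @param from,to adjacent compartment indices.
#' @return current density, mA/cm2.
#' @export
measure_axial_current <- function(model, from, to, v_from, v_to) {
  g <- model$geometry
  pf <- g$parent[to]; pt <- g$parent[from]
  if (!(identical(pf, as.integer(from)) || identical(pt, as.integer(to)))) {
    stop("compartments are not adjacent", call. = FALSE)
  }
  gax <- if (identical(pf, as.integer(from))) model$g_axial[to] else
    model$g_axial[from]
  gax * (v_to - v_from) / g$area_cm2[to]
}

#' Somatic voltage clamp run
#'
#' Clamps the named compartments to a piecewise-constant command by exact row
#' substitution in the cable system; unclamped compartments evolve freely
#' (space-clamp failure in the dendrites is therefore reproduced). The
#' reported clamp current is the total membrane plus axial current required
#' to hold the command.
#'
#' @param model calibrated `ion_model`.
#' @param times_ms,values_mV piecewise-constant command waveform.
#' @param comps compartments held by the electrode (default: soma).
#' @param duration_ms simulated time.
#' @param ... further arguments to [ion_protocol()] (e.g. trains).
#' @return a `trace_set`; `$clamp_i` holds the electrode current (nA) per
#'   clamped compartment.
#' @export
voltage_clamp_run <- function(model, times_ms, values_mV,
                              comps = which(model$geometry$region == "soma"),
                              duration_ms = max(times_ms) + 100, ...) {
  stopifnot(length(comps) >= 1)
  proto <- ion_protocol(duration_ms = duration_ms,
                        clamp = list(comps = comps, times_ms = times_ms,
                                     values_mV = values_mV), ...)
  simulate(model, proto)
}

# ---- reference stepper (R composition of the module functions) -------------

#' One reference step of the operator-split scheme in pure R
#'
#' Composes the exported module functions (gate updates, implicit Markov
#' updates, transporter currents, a dense implicit voltage solve, and the
#' concentration/buffer/diffusion updates) in the same order as the compiled
#' engine. Used to validate the engine step-for-step on small fixtures; too
#' slow for production runs.
#'
#' @param model calibrated `ion_model`.
#' @param state an `ion_state`.
#' @param dt time step, ms.
#' @param ligand_mM per-compartment transmitter concentration at the end of
#'   the step.
#' @param i_inj_nA per-compartment injected current.
#' @param clamp optional list(comps, values_mV).
#' @param gaba_scale,kcc2_scale,na_scale multipliers as in [ion_protocol()].
#' @param conc_dynamics,diffusion,buffer stage switches.
#' @return list with the updated `state` and per-compartment per-ion membrane
#'   currents (`currents`, mA/cm2) evaluated at the new voltage.
#' @export
step_reference <- function(model, state, dt, ligand_mM = 0, i_inj_nA = 0,
                           clamp = NULL, gaba_scale = 1, kcc2_scale = 1,
                           na_scale = 1, conc_dynamics = TRUE,
                           diffusion = TRUE, buffer = TRUE) {
  p <- model$params
  m <- model$mech
  cal <- model$calibration
  g <- model$geometry
  n <- nrow(g)
  ligand <- rep_len(ligand_mM, n)
  i_inj <- rep_len(i_inj_nA, n) * 1e-6  # mA
  gaba_scale <- rep_len(gaba_scale, n)
  rtf <- rtf_mV(p$physical$temperature_c)
  tr <- p$transporters

  v <- state$v
  conc <- state$conc

  # (1) explicit gate updates at the old voltage
  gates <- state$gates
  for (k in seq_along(m$gates_flat)) {
    gt <- m$gates_flat[[k]]
    xinf <- gate_inf(gt, v); tau <- gate_tau(gt, v)
    gates[, k] <- pmin(pmax(gates[, k] + dt * (xinf - gates[, k]) / tau, 0), 1)
  }
  # explicit NKCC1 carrier update (currents use the updated split)
  nk_pars <- tr$nkcc1; nk_pars$umax_mA_cm2 <- 1
  nk <- nkcc1_current(conc[, 1], conc[, 5], conc[, 2], conc[, 6], conc[, 3],
                      conc[, 7], state$y, nk_pars, dt = dt)
  y <- nk$y
  i_nkcc1 <- cal$nkcc1_U *
    (y * tr$nkcc1$k_loaded_per_ms * nk$p_out_loaded -
       (1 - y) * tr$nkcc1$k_loaded_per_ms * nk$p_in_loaded)

  # (2) implicit Markov updates at the old voltage, new ligand
  na5s <- build_na_scheme(p, FALSE); na6s <- build_na_scheme(p, TRUE)
  gabas <- build_gaba_scheme(p)
  na5 <- state$na5; na6 <- state$na6; gab <- state$gaba
  for (i in seq_len(n)) {
    na5[i, ] <- markov_step_implicit(na5s, na5[i, ], v[i], 0, dt)
    na6[i, ] <- markov_step_implicit(na6s, na6[i, ], v[i], 0, dt)
    gab[i, ] <- markov_step_implicit(gabas, gab[i, ], v[i], ligand[i], dt)
  }

  # (3) per-ion linear current coefficients I_ion(V') = A V' + B
  E <- reversal_potentials(conc, p$ions$hco3_i_mM, p$ions$hco3_o_mM,
                           p$physical$temperature_c, p$gaba$hco3_fraction)
  A <- matrix(0, n, 5); B <- matrix(0, n, 5)  # na k cl ca hco3
  add <- function(ion, a, b) {
    A[, ion] <<- A[, ion] + a; B[, ion] <<- B[, ion] + b
  }
  for (ci in seq_along(m$chan_names)) {
    open <- rep(1, n)
    for (k in seq_along(m$gates_flat)) {
      gt <- m$gates_flat[[k]]
      if (gt$channel == ci) open <- open * gates[, k]^gt$exponent
    }
    gch <- m$hh_g[, ci] * open
    ion <- m$chan_ion[ci]
    if (ion == 0L) add(1, gch, -gch * E$e_na)
    else if (ion == 1L) add(2, gch, -gch * E$e_k)
    else if (ion == 2L) add(4, gch, -gch * E$e_ca)
    else {
      f <- m$chan_nafrac[ci]; eh <- m$chan_erev[ci]
      add(1, f * gch, -f * gch * eh)
      add(2, (1 - f) * gch, -(1 - f) * gch * eh)
    }
  }
  gna <- na_scale * na_conductance(m$na_gbar, m$na_fraction, na5[, 4], na6[, 4])
  add(1, gna, -gna * E$e_na)
  ggab <- m$gaba_gbar * gaba_scale * gab[, 4]
  f <- p$gaba$hco3_fraction
  add(3, (1 - f) * ggab, -(1 - f) * ggab * E$e_cl)
  add(5, f * ggab, -f * ggab * E$e_hco3)
  add(1, cal$gleak_na, -cal$gleak_na * E$e_na)
  add(2, cal$gleak_k, -cal$gleak_k * E$e_k)
  add(3, cal$gleak_cl, -cal$gleak_cl * E$e_cl)
  # constant (voltage-evaluated-explicitly) transporter currents
  pump <- nak_pump(conc[, 1], conc[, 6], cal$nak_imax, tr$nak$km_na_mM,
                   tr$nak$km_k_mM)
  add(1, 0, pump$i_na); add(2, 0, pump$i_k)
  kcc <- kcc2_currents(conc[, 2], conc[, 6], conc[, 3], conc[, 7],
                       m$kcc2_U * kcc2_scale, tr$kcc2$km_k_mM,
                       tr$kcc2$km_cl_mM)
  add(2, 0, kcc$i_k); add(3, 0, kcc$i_cl)
  add(1, 0, -0.5 * i_nkcc1); add(2, 0, -0.5 * i_nkcc1); add(3, 0, i_nkcc1)
  cax <- nacax_and_capump(v, conc[, 1], conc[, 5], conc[, 4], conc[, 8],
                          cal$nacax_scale, tr$nacax, m$capump_imax,
                          tr$ca_pump$km_mM, rtf)
  add(1, 0, cax$i_na); add(4, 0, cax$i_ca)

  # (4) dense implicit voltage solve
  Atot <- rowSums(A); Btot <- rowSums(B)
  cvec <- p$physical$capacitance_uf_cm2 * g$area_cm2 * 1e-3
  M <- matrix(0, n, n)
  rhs <- cvec / dt * v - g$area_cm2 * Btot + i_inj
  diag(M) <- cvec / dt + g$area_cm2 * Atot
  for (i in seq_len(n)[-1]) {
    pa <- g$parent[i]; gax <- model$g_axial[i]
    M[i, i] <- M[i, i] + gax; M[pa, pa] <- M[pa, pa] + gax
    M[i, pa] <- M[i, pa] - gax; M[pa, i] <- M[pa, i] - gax
  }
  if (!is.null(clamp)) {
    for (j in seq_along(clamp$comps)) {
      i <- clamp$comps[j]
      M[i, ] <- 0; M[i, i] <- 1; rhs[i] <- clamp$values_mV[j]
    }
  }
  vn <- solve(M, rhs)

  # (5) per-ion membrane currents at the new voltage -> concentrations
  I <- A * vn + B  # n x 5 (na k cl ca hco3)
  new_conc <- conc
  if (conc_dynamics) {
    new_conc <- concentration_step(conc, I[, 1:4, drop = FALSE], g$area_cm2,
                                   g$vol_i_cm3, g$vol_o_cm3, dt)
    kb <- state$kb
    if (buffer) {
      gb <- glial_buffer_step(new_conc[, 6], kb, p$glial_buffer, dt)
      new_conc[, 6] <- gb$k_o; kb <- gb$kb
    }
    if (diffusion) {
      new_conc <- diffusion_step(new_conc, g$parent, model$diff_surf_i,
                                 model$diff_surf_o, model$diff_dist,
                                 g$vol_i_cm3, g$vol_o_cm3,
                                 p$ions$diffusion_um2_ms, dt)
    }
  } else kb <- state$kb

  state$v <- vn; state$conc <- new_conc; state$gates <- gates
  state$na5 <- na5; state$na6 <- na6; state$gaba <- gab
  state$y <- y; state$kb <- kb; state$t <- state$t + dt
  list(state = state, currents = I)
}
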