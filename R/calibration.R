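#' Balance the model at its resting potential
#'
#' The calibration algorithm determines, per compartment, the remaining free
#' homeostasis parameters so that every ion has zero net flux at the resting
#' potential (default -66 mV) with the initial concentrations:
#'
#' 1. the Na/Ca exchanger scale is set so exchanger plus calcium-pump plus
#'    calcium-channel flux is zero;
#' 2. the NKCC1 density is set so chloride loading balances resting KCC2
#'    extrusion (chloride leak defaults to zero);
#' 3. the minimum Na/K pump rate balancing the remaining sodium influx is
#'    computed and the pump is set `margin` (default 20%) above it;
#' 4. sodium and potassium leak conductances are solved so the net Na+ and K+
#'    fluxes are zero; the pump margin is what creates the potassium-leak
#'    headroom that lets the cell depolarise to extracellular potassium
#'    transients.
#'
#' Because every compartment is balanced at a common potential, axial currents
#' vanish and the assembled model rests at `v_rest`.
#'
#' @param model an `ion_model` with mechanisms attached.
#' @param v_rest resting potential, mV.
#' @param margin fractional pump reserve above the minimum balancing rate.
#' @return the model with a `calibration` component; see also
#'   [calibration_summary()].
#' @export
balance_rest <- function(model, v_rest = -66, margin = 0.20) {
  stopifnot(!is.null(model$mech))
  p <- model$params
  m <- model$mech
  g <- model$geometry
  n <- nrow(g)
  tr <- p$transporters
  rtf <- rtf_mV(p$physical$temperature_c)
  conc <- matrix(rep(initial_concentrations(p), each = n), n, 8)
  E <- reversal_potentials(conc, p$ions$hco3_i_mM, p$ions$hco3_o_mM,
                           p$physical$temperature_c, p$gaba$hco3_fraction)

  # channel currents at rest (gates at steady state, Markov at equilibrium)
  i_na <- i_k <- i_ca <- rep(0, n)
  for (ci in seq_along(m$chan_names)) {
    open <- rep(1, n)
    for (k in seq_along(m$gates_flat)) {
      gt <- m$gates_flat[[k]]
      if (gt$channel == ci) open <- open * gate_inf(gt, v_rest)^gt$exponent
    }
    gch <- m$hh_g[, ci] * open
    ion <- m$chan_ion[ci]
    if (ion == 0L) i_na <- i_na + gch * (v_rest - E$e_na)
    else if (ion == 1L) i_k <- i_k + gch * (v_rest - E$e_k)
    else if (ion == 2L) i_ca <- i_ca + gch * (v_rest - E$e_ca)
    else {
      f <- m$chan_nafrac[ci]
      i_na <- i_na + f * gch * (v_rest - m$chan_erev[ci])
      i_k <- i_k + (1 - f) * gch * (v_rest - m$chan_erev[ci])
    }
  }
  o5 <- markov_equilibrium(build_na_scheme(p, FALSE), v_rest)[4]
  o6 <- markov_equilibrium(build_na_scheme(p, TRUE), v_rest)[4]
  gna <- na_conductance(m$na_gbar, m$na_fraction, o5, o6)
  i_na <- i_na + gna * (v_rest - E$e_na)

  # calcium: exchanger scale balances pump + channel flux
  i_cap <- ca_pump_current(conc[, 4], m$capump_imax, tr$ca_pump$km_mM)
  ix_needed <- (i_ca + i_cap) / 2
  ix_raw <- nacax_current(v_rest, conc[, 1], conc[, 5], conc[, 4], conc[, 8],
                          1, tr$nacax, rtf)
  nacax_scale <- ix_needed / ix_raw
  if (any(nacax_scale < 0)) {
    bad <- which(nacax_scale < 0)[1]
    stop(sprintf(
      "calibration infeasible: exchanger cannot balance calcium in compartment %d",
      bad), call. = FALSE)
  }

  # chloride: NKCC1 loading balances KCC2 extrusion
  kcc <- kcc2_currents(conc[, 2], conc[, 6], conc[, 3], conc[, 7], m$kcc2_U,
                       tr$kcc2$km_k_mM, tr$kcc2$km_cl_mM)
  nk_pars <- tr$nkcc1; nk_pars$umax_mA_cm2 <- 1
  y0 <- nkcc1_steady_y(conc[1, 1], conc[1, 5], conc[1, 2], conc[1, 6],
                       conc[1, 3], conc[1, 7], nk_pars)
  nk <- nkcc1_current(conc[, 1], conc[, 5], conc[, 2], conc[, 6], conc[, 3],
                      conc[, 7], y0, nk_pars)
  j_unit <- nk$i_nkcc1  # inward cycle flux for unit density
  if (any(j_unit <= 0 & kcc$i_k > 0)) {
    stop("calibration infeasible: NKCC1 cannot load chloride at rest",
         call. = FALSE)
  }
  nkcc1_U <- ifelse(kcc$i_k > 0, kcc$i_k / j_unit, 0)
  i_nkcc1 <- nkcc1_U * j_unit

  # sodium: minimum pump rate, then margin and leak
  i_na_other <- i_na + 3 * nacax_scale * ix_raw - 0.5 * i_nkcc1
  if (any(i_na_other >= 0)) {
    bad <- which(i_na_other >= 0)[1]
    stop(sprintf(
      "calibration infeasible: no resting sodium influx to pump in compartment %d",
      bad), call. = FALSE)
  }
  i_pump_min <- -i_na_other / 3
  sat <- 1 / ((1 + tr$nak$km_na_mM / conc[, 1])^3 *
                (1 + tr$nak$km_k_mM / conc[, 6])^2)
  nak_imax <- (1 + margin) * i_pump_min / sat
  i_pump <- (1 + margin) * i_pump_min
  gleak_na <- -(i_na_other + 3 * i_pump) / (v_rest - E$e_na)

  # potassium leak closes the balance
  i_k_other <- i_k + kcc$i_k - 0.5 * i_nkcc1 - 2 * i_pump
  gleak_k <- -i_k_other / (v_rest - E$e_k)
  if (any(gleak_k < 0)) {
    bad <- which(gleak_k < 0)[1]
    stop(sprintf(
      "calibration infeasible: negative potassium leak in compartment %d (increase the pump margin)",
      bad), call. = FALSE)
  }
  gleak_cl <- rep(0, n)

  resid <- cbind(
    na = i_na_other + 3 * i_pump + gleak_na * (v_rest - E$e_na),
    k = i_k_other + gleak_k * (v_rest - E$e_k),
    cl = -kcc$i_k + i_nkcc1 + gleak_cl * (v_rest - E$e_cl),
    ca = i_ca + i_cap - 2 * nacax_scale * ix_raw
  )
  model$calibration <- list(
    v_rest = v_rest, margin = margin,
    nak_imax = nak_imax, i_pump_rest = i_pump, i_pump_min = i_pump_min,
    gleak_na = pmax(gleak_na, 0), gleak_k = gleak_k, gleak_cl = gleak_cl,
    nkcc1_U = nkcc1_U, nacax_scale = nacax_scale,
    residuals = resid
  )
  model
}

#' Per-compartment calibration summary
#'
#' @param model a calibrated `ion_model`.
#' @return data frame with pump maxima, leak conductances, transporter
#'   densities, and residual per-ion fluxes (mA/cm2).
#' @export
calibration_summary <- function(model) {
  cal <- model$calibration
  if (is.null(cal)) stop("model is not calibrated", call. = FALSE)
  data.frame(id = model$geometry$id, region = model$geometry$region,
             nak_imax = cal$nak_imax, gleak_na = cal$gleak_na,
             gleak_k = cal$gleak_k, gleak_cl = cal$gleak_cl,
             nkcc1_U = cal$nkcc1_U, nacax_scale = cal$nacax_scale,
             resid_na = cal$residuals[, 1], resid_k = cal$residuals[, 2],
             resid_cl = cal$residuals[, 3], resid_ca = cal$residuals[, 4])
}

#' Steady-state depolarization from an extracellular potassium step
#'
#' Clamps `[K]o` in every shell to `delta_mM` above rest, lets the model
#' settle, and reports the somatic steady-state depolarization.
#'
#' @param model calibrated `ion_model`.
#' @param delta_mM size of the potassium step.
#' @param settle_ms settling time before measurement.
#' @return depolarization in mV.
#' @export
check_k_sensitivity <- function(model, delta_mM = 4, settle_ms = 3000) {
  if (delta_mM == 0) return(0)
  k0 <- model$params$ions$initial_mM$k_o
  proto <- ion_protocol(
    duration_ms = settle_ms,
    k_clamp = list(times_ms = c(0, settle_ms), values_mM = rep(k0 + delta_mM, 2)),
    record_dt_ms = 5
  )
  tr <- simulate(model, proto)
  soma <- which(model$geometry$region == "soma")[1]
  tail_idx <- tr$time > settle_ms - 200
  mean(tr$v[tail_idx, soma]) - model$calibration$v_rest
}

#' Somatic input resistance
#'
#' Small hyperpolarizing somatic current step; the steady-state voltage
#' deflection divided by the current gives the input resistance.
#'
#' @param model calibrated `ion_model`.
#' @param amp_nA step amplitude (default -0.05 nA = -50 pA).
#' @param dur_ms step duration.
#' @return resistance in megaohms.
#' @export
input_resistance <- function(model, amp_nA = -0.05, dur_ms = 600) {
  soma <- which(model$geometry$region == "soma")[1]
  proto <- ion_protocol(
    duration_ms = dur_ms + 100,
    injections = data.frame(comp = soma, t0_ms = 50, t1_ms = 50 + dur_ms,
                            amp_nA = amp_nA),
    record_dt_ms = 1
  )
  tr <- simulate(model, proto)
  v0 <- mean(tr$v[tr$time < 50, soma])
  v1 <- mean(tr$v[tr$time > 50 + dur_ms - 100 & tr$time < 50 + dur_ms, soma])
  (v1 - v0) / amp_nA
}

#' Tune the h-current density to a target input resistance
#'
#' One-parameter bisection on a global multiplier of the h-current density;
#' the model is recalibrated at every evaluation.
#'
#' @param model `ion_model` with mechanisms attached.
#' @param target_MOhm target somatic input resistance.
#' @param lower,upper multiplier bracket.
#' @param tol relative tolerance on the multiplier.
#' @return list with the tuned `model`, the `multiplier` and the achieved
#'   resistance `rin_MOhm`.
#' @export
fit_ih_input_resistance <- function(model, target_MOhm, lower = 0.05,
                                    upper = 20, tol = 0.01) {
  ih_col <- which(model$mech$chan_names == "ih")
  base <- model$mech$hh_g[, ih_col]
  eval_rin <- function(mult) {
    m2 <- model
    m2$mech$hh_g[, ih_col] <- base * mult
    m2 <- balance_rest(m2, model$params$solver$v_init_mV)
    input_resistance(m2)
  }
  f <- function(mult) eval_rin(mult) - target_MOhm
  flo <- f(lower); fhi <- f(upper)
  if (sign(flo) == sign(fhi)) {
    stop("target input resistance is not bracketed by the h-current range",
         call. = FALSE)
  }
  root <- stats::uniroot(f, c(lower, upper), tol = tol * (upper - lower))
  mult <- root$root
  m2 <- model
  m2$mech$hh_g[, ih_col] <- base * mult
  m2 <- balance_rest(m2, model$params$solver$v_init_mV)
  list(model = m2, multiplier = mult, rin_MOhm = input_resistance(m2))
}

#' Simulated dendritic chloride clearance
#'
#' Loads the whole cell with chloride and records the decay of `[Cl]i` in the
#' compartment nearest the requested distance, with synaptic input silent.
#'
#' @param model calibrated `ion_model`.
#' @param load_mM initial intracellular chloride.
#' @param duration_ms simulated time.
#' @param dist_um distance of the monitored compartment from the soma.
#' @param kcc2_scale multiplier on KCC2 transport.
#' @return data frame with `t_ms` and `cl_mM`.
#' @export
chloride_clearance_curve <- function(model, load_mM = 20, duration_ms = 4000,
                                     dist_um = 200, kcc2_scale = 1) {
  st <- initial_state(model)
  st$conc[, 3] <- load_mM
  proto <- ion_protocol(duration_ms = duration_ms, record_dt_ms = 10,
                        kcc2_scale = kcc2_scale, na_scale = 0)
  tr <- simulate(model, proto, state = st)
  comp <- which.min(abs(model$geometry$dist_um - dist_um))
  data.frame(t_ms = tr$time, cl_mM = tr$conc$cl_i[, comp])
}

#' Fit the KCC2 transport density to a chloride-clearance curve
#'
#' Least-squares fit of the simulated dendritic chloride clearance (monitored
#' about 200 um from the soma after a chloride load) to a target curve, over
#' a multiplicative scale on the KCC2 maximal transport rate. The model is
#' recalibrated at every evaluation so chloride remains balanced at rest.
#'
#' @param model calibrated `ion_model`.
#' @param clearance data frame with `t_ms`, `cl_mM` (monotone decay toward
#'   baseline).
#' @param interval multiplier search interval.
#' @inheritParams chloride_clearance_curve
#' @return list with the fitted `umax` (mA/cm2), the `scale` relative to the
#'   model's current density, and the fit `residual` (root-mean-square, mM).
#' @export
fit_kcc2_density <- function(model, clearance, interval = c(0.1, 10),
                             load_mM = 20, dist_um = 200) {
  if (any(diff(stats::filter(clearance$cl_mM, rep(1 / 5, 5),
                             sides = 2)[3:(nrow(clearance) - 2)] ) > 0.5)) {
    stop("clearance curve is not a monotone decay", call. = FALSE)
  }
  base_U <- model$mech$kcc2_U
  objective <- function(s) {
    m2 <- model
    m2$mech$kcc2_U <- base_U * s
    m2 <- balance_rest(m2, model$params$solver$v_init_mV)
    sim <- chloride_clearance_curve(m2, load_mM = load_mM,
                                    duration_ms = max(clearance$t_ms),
                                    dist_um = dist_um)
    target <- stats::approx(clearance$t_ms, clearance$cl_mM, sim$t_ms,
                            rule = 2)$y
    mean((sim$cl_mM - target)^2)
  }
  opt <- stats::optimize(objective, interval = interval, tol = 1e-3)
  rms <- sqrt(opt$objective)
  # reject fits whose residual is large relative to the clearance excursion
  span <- max(clearance$cl_mM) - min(clearance$cl_mM)
  if (rms > max(0.25 * span, 0.05)) {
    stop(sprintf(
      "KCC2 density fit did not converge: residual %.2f mM over a %.2f mM clearance",
      rms, span), call. = FALSE)
  }
  list(umax = base_U[1] * opt$minimum, scale = opt$minimum, residual = rms)
}
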