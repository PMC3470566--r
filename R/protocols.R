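#' Compartments belonging to a named target
#'
#' Target keywords: `"soma"`, `"apical"` (all apical layers), `"basal"`,
#' `"axon"`, `"distal_dendrites"` (apical beyond 200 um), `"perisomatic"`
#' (soma plus dendrites within 50 um), `"apical_proximal"`, or any single
#' region label.
#'
#' @param model an `ion_model`.
#' @param targets character vector of keywords.
#' @return integer compartment indices.
#' @export
target_compartments <- function(model, targets) {
  g <- model$geometry
  apical <- c("apical_proximal", "radiatum_thick_medial",
              "radiatum_thick_distal_or_thin", "lacunosum_moleculare")
  out <- integer(0)
  for (tg in targets) {
    idx <- switch(tg,
      soma = which(g$region == "soma"),
      apical = which(g$region %in% apical),
      basal = which(g$region %in% c("oriens_proximal", "oriens_distal")),
      axon = which(g$region == "axon"),
      distal_dendrites = which(g$region %in% apical & g$dist_um > 200),
      perisomatic = which(g$region == "soma" |
                            (g$type %in% c(3L, 4L) & g$dist_um < 50)),
      which(g$region == tg)
    )
    if (!length(idx)) stop("no compartments for target: ", tg, call. = FALSE)
    out <- c(out, idx)
  }
  sort(unique(out))
}

#' High-frequency GABAergic stimulation
#'
#' Delivers a train of GABA transmitter pulses (default 40 pulses at 100 Hz,
#' 1 mM for 1 ms with a 0.1 ms decay) to every synapse in the target regions
#' at the given activation fraction, under current clamp (optionally with a
#' somatic bias current) or somatic voltage clamp.
#'
#' @param model calibrated `ion_model`.
#' @param activation fraction of the maximal synaptic conductance activated.
#' @param targets stimulated regions (see [target_compartments()]).
#' @param mode `"free"` (current clamp) or `"clamp"` (somatic voltage clamp
#'   at `clamp_mV`).
#' @param clamp_mV holding potential for `mode = "clamp"`.
#' @param bias_nA constant somatic bias current spanning the stimulus.
#' @param n_pulses,rate_hz train layout.
#' @param hfs_start_ms stimulus onset (the model settles at rest before it).
#' @param post_ms simulated time after the train.
#' @param gaba_inhibition fraction of GABA-A conductance blocked
#'   pharmacologically (applied everywhere).
#' @param kcc2_inhibition fraction of KCC2 transport blocked.
#' @param na_scale fast-sodium multiplier (0 blocks spikes, as in the
#'   dissection figures).
#' @param k_clamp,kcc2_frozen_k see [ion_protocol()].
#' @param record_dt_ms recording interval.
#' @return a `trace_set` with attribute `hfs_window = c(start, end)` (ms).
#' @export
run_hfs <- function(model, activation = 0.8, targets = c("soma", "apical"),
                    mode = c("free", "clamp"), clamp_mV = -75, bias_nA = 0,
                    n_pulses = 40, rate_hz = 100, hfs_start_ms = 200,
                    post_ms = 2600, gaba_inhibition = 0, kcc2_inhibition = 0,
                    na_scale = 1, k_clamp = NULL, kcc2_frozen_k = FALSE,
                    record_dt_ms = 1) {
  mode <- match.arg(mode)
  if (is.null(model$calibration)) {
    stop("model must be calibrated with balance_rest() before stimulation",
         call. = FALSE)
  }
  n <- nrow(model$geometry)
  comps <- target_compartments(model, targets)
  scale <- rep(0, n)
  scale[comps] <- activation * (1 - gaba_inhibition)
  hfs_end <- hfs_start_ms + n_pulses * 1000 / rate_hz
  duration <- hfs_end + post_ms
  soma <- which(model$geometry$region == "soma")[1]
  inj <- NULL
  if (bias_nA != 0) {
    inj <- data.frame(comp = soma, t0_ms = max(hfs_start_ms - 500, 0),
                      t1_ms = hfs_end + 1100, amp_nA = bias_nA)
  }
  clamp <- NULL
  if (mode == "clamp") {
    clamp <- list(comps = which(model$geometry$region == "soma"),
                  times_ms = 0, values_mV = clamp_mV)
  }
  proto <- ion_protocol(
    duration_ms = duration, injections = inj,
    trains = list(hfs_train(n_pulses, rate_hz, start_ms = hfs_start_ms)),
    train_targets = list(comps),
    gaba_scale = scale, clamp = clamp, k_clamp = k_clamp,
    kcc2_frozen_k = kcc2_frozen_k, kcc2_scale = 1 - kcc2_inhibition,
    na_scale = na_scale, record_dt_ms = record_dt_ms
  )
  out <- simulate(model, proto)
  attr(out, "hfs_window") <- c(hfs_start_ms, hfs_end)
  out
}

#' Summary metrics of an HFS voltage response
#'
#' @param trace a `trace_set` from [run_hfs()].
#' @param model the model used.
#' @param comp compartment to summarise (default soma).
#' @return list with baseline, peak hyperpolarization and depolarization
#'   (mV relative to baseline), their times, the depolarization duration
#'   above 2 mV, and the area above baseline (mV*ms).
#' @export
hfs_metrics <- function(trace, model, comp = NULL) {
  if (is.null(comp)) comp <- which(model$geometry$region == "soma")[1]
  w <- attr(trace, "hfs_window")
  t <- trace$time; v <- trace$v[, comp]
  base <- mean(v[t < w[1]])
  hyp_idx <- t >= w[1] & t <= w[1] + 150
  dep_idx <- t >= w[1] + 150
  dv <- v - base
  dt <- stats::median(diff(t))
  above <- dep_idx & dv > 2
  list(baseline_mV = base,
       peak_hyperpolarization_mV = min(dv[hyp_idx]),
       t_hyper_ms = t[hyp_idx][which.min(dv[hyp_idx])],
       peak_depolarization_mV = max(dv[dep_idx]),
       t_depol_ms = t[dep_idx][which.max(dv[dep_idx])],
       depol_duration_ms = sum(above) * dt,
       depol_area_mV_ms = sum(pmax(dv[dep_idx], 0)) * dt,
       switch_ms = {
         cross <- which(dep_idx & dv > 0)
         if (length(cross)) t[cross[1]] - w[1] else NA_real_
       })
}

#' Second identical HFS during or after the depolarization
#'
#' Runs a control HFS to locate the response phase, then delivers a second
#' identical train either on the falling phase of the depolarization (25%
#' decay from peak) or after recovery (somatic voltage back within 1 mV of
#' rest). The immediate response in each compartment is classified by the
#' sign of `E_GABA - V` at the onset of the second train.
#'
#' @inheritParams run_hfs
#' @param phase `"falling"` or `"recovered"`.
#' @param ... further arguments to [run_hfs()].
#' @return a `trace_set` with attributes `second_onset_ms` and
#'   `classification` (per-compartment `"depolarizing"`/`"hyperpolarizing"`).
#' @export
run_second_hfs <- function(model, phase = c("falling", "recovered"),
                           activation = 0.8, targets = c("soma", "apical"),
                           na_scale = 0, ...) {
  phase <- match.arg(phase)
  ctrl <- run_hfs(model, activation = activation, targets = targets,
                  na_scale = na_scale, ...)
  w <- attr(ctrl, "hfs_window")
  soma <- which(model$geometry$region == "soma")[1]
  t <- ctrl$time; v <- ctrl$v[, soma]
  base <- mean(v[t < w[1]])
  dep_idx <- which(t >= w[1] + 150)
  pk <- dep_idx[which.max(v[dep_idx])]
  if (phase == "falling") {
    target_v <- base + 0.75 * (v[pk] - base)
    after <- dep_idx[dep_idx > pk & v[dep_idx] <= target_v]
    onset <- if (length(after)) t[after[1]] else t[pk] + 200
  } else {
    after <- dep_idx[dep_idx > pk & v[dep_idx] <= base + 1]
    onset <- if (length(after)) t[after[1]] + 200 else max(t) - 600
  }

  n <- nrow(model$geometry)
  comps <- target_compartments(model, targets)
  scale <- rep(0, n); scale[comps] <- activation
  tr1 <- hfs_train(start_ms = w[1])
  tr2 <- hfs_train(start_ms = onset)
  proto <- ion_protocol(
    duration_ms = onset + 3000,
    trains = list(tr1, tr2), train_targets = list(comps, comps),
    gaba_scale = scale, na_scale = na_scale, record_dt_ms = 1
  )
  out <- simulate(model, proto)
  attr(out, "hfs_window") <- w
  attr(out, "second_onset_ms") <- onset
  i0 <- which.min(abs(out$time - onset))
  drive <- out$e_gaba[i0, ] - out$v[i0, ]
  attr(out, "classification") <- ifelse(drive > 0, "depolarizing",
                                        "hyperpolarizing")
  out
}

#' Override the extracellular shell fraction beyond a distance
#'
#' Rebuilds shell volumes (and the diffusion couplings that depend on them)
#' with a different extracellular volume fraction for compartments beyond
#' `beyond_um` from the soma. The rest-state calibration is unaffected.
#'
#' @param model an `ion_model`.
#' @param fraction new shell fraction (e.g. 0.22).
#' @param beyond_um apply beyond this path distance.
#' @return the modified model.
#' @export
set_shell_fraction <- function(model, fraction, beyond_um = 100) {
  g <- model$geometry
  sel <- g$dist_um > beyond_um & g$type != 1L
  g$shell_frac[sel] <- fraction
  g$vol_o_cm3 <- g$shell_frac * g$vol_i_cm3
  model$geometry <- g
  recompute_coupling(model)
}

#' HFS with interventions
#'
#' Convenience wrapper combining the pharmacological and ionic interventions
#' studied with the HFS protocol: partial GABA-A block (quinine), partial
#' KCC2 block, clamping the extracellular potassium transient (fully frozen
#' or to a waveform), a KCC2 transporter blind to the potassium transient,
#' and an enlarged dendritic extracellular space.
#'
#' @inheritParams run_hfs
#' @param gaba_inhibition,kcc2_inhibition blocked fractions in \[0, 1\].
#' @param k_clamp `TRUE`, `NULL`, or a waveform list (see [ion_protocol()]).
#' @param shell_fraction,shell_beyond_um extracellular-volume intervention
#'   (`NULL` to keep the default shell).
#' @param ... further arguments to [run_hfs()].
#' @return a `trace_set` (attribute `hfs_window` as in [run_hfs()]).
#' @export
run_intervention <- function(model, gaba_inhibition = 0, kcc2_inhibition = 0,
                             k_clamp = NULL, kcc2_frozen_k = FALSE,
                             shell_fraction = NULL, shell_beyond_um = 100,
                             ...) {
  if (isTRUE(k_clamp) && kcc2_frozen_k) {
    stop("conflicting potassium modes: choose k_clamp or kcc2_frozen_k",
         call. = FALSE)
  }
  if (!is.null(shell_fraction)) {
    model <- set_shell_fraction(model, shell_fraction, shell_beyond_um)
  }
  run_hfs(model, gaba_inhibition = gaba_inhibition,
          kcc2_inhibition = kcc2_inhibition, k_clamp = k_clamp,
          kcc2_frozen_k = kcc2_frozen_k, ...)
}

#' Single GABA pulse at a chosen location after HFS
#'
#' Applies the HFS train to the soma and apical dendrites, then a single
#' transmitter pulse confined to either the distal dendrites (> 200 um) or
#' the perisomatic region, and classifies the somatic response as excitatory
#' (action potential or net depolarization) or inhibitory.
#'
#' @inheritParams run_hfs
#' @param location `"distal_dendrites"` or `"perisomatic"`.
#' @param t_after_hfs_ms delay from the end of the train to the test pulse.
#' @param with_hfs set `FALSE` for the control (pulse from rest).
#' @param ... further arguments (passed to [ion_protocol()] construction).
#' @return list with the `trace`, the `classification`, the somatic response
#'   `delta_mV`, and the number of somatic spikes in the response window.
#' @export
run_secondary_pulse <- function(model, location = c("distal_dendrites",
                                                    "perisomatic"),
                                t_after_hfs_ms = 600, activation = 0.8,
                                hfs_start_ms = 200, with_hfs = TRUE,
                                na_scale = 1) {
  location <- match.arg(location)
  n <- nrow(model$geometry)
  hfs_comps <- target_compartments(model, c("soma", "apical"))
  pulse_comps <- target_compartments(model, location)
  hfs_end <- hfs_start_ms + 400
  pulse_t <- if (with_hfs) hfs_end + t_after_hfs_ms else hfs_start_ms
  scale <- rep(0, n)
  scale[union(hfs_comps, pulse_comps)] <- activation
  trains <- list(transmitter_train(pulse_t))
  targets <- list(pulse_comps)
  if (with_hfs) {
    trains <- c(list(hfs_train(start_ms = hfs_start_ms)), trains)
    targets <- c(list(hfs_comps), targets)
  }
  proto <- ion_protocol(duration_ms = pulse_t + 400, trains = trains,
                        train_targets = targets, gaba_scale = scale,
                        na_scale = na_scale, record_dt_ms = 0.5)
  tr <- simulate(model, proto)
  soma <- which(model$geometry$region == "soma")[1]
  pre <- tr$time > pulse_t - 10 & tr$time <= pulse_t
  post <- tr$time > pulse_t + 2 & tr$time < pulse_t + 60
  delta <- mean(tr$v[post, soma]) - mean(tr$v[pre, soma])
  spk <- sum(tr$spikes$comp == soma & tr$spikes$t_ms > pulse_t &
               tr$spikes$t_ms < pulse_t + 100)
  list(trace = tr,
       classification = if (spk > 0 || delta > 0) "excitatory" else "inhibitory",
       delta_mV = delta, spikes = spk, pulse_t_ms = pulse_t)
}

#' Time-resolved membrane resistance during HFS
#'
#' Brief hyperpolarizing probe pulses are applied to a compartment at a fixed
#' interval; the somatic deflection caused by each pulse (isolated by
#' comparison with an identical run without probes) is normalised to the
#' pre-stimulus baseline. Values near zero indicate shunting
#' ("short-circuited" membrane).
#'
#' @inheritParams run_hfs
#' @param probe_comp compartment receiving the probe (index).
#' @param probe_nA,probe_ms probe amplitude and width.
#' @param interval_ms probe period.
#' @param total_ms probing duration.
#' @param apical_activation activation fraction on the apical dendrites
#'   (somatic and distal conductance fixed at `activation`).
#' @return data frame with `t_ms`, `deflection_mV`, `normalized`, plus
#'   attribute `hfs_window`.
#' @export
probe_membrane_resistance <- function(model, probe_comp,
                                      probe_nA = -0.1, probe_ms = 5,
                                      interval_ms = 50, total_ms = 2000,
                                      activation = 0.8,
                                      apical_activation = activation,
                                      hfs_start_ms = 500, na_scale = 0) {
  n <- nrow(model$geometry)
  soma <- target_compartments(model, "soma")
  apical <- target_compartments(model, "apical")
  comps <- c(soma, apical)
  scale <- rep(0, n)
  scale[soma] <- activation
  scale[apical] <- apical_activation
  hfs_end <- hfs_start_ms + 400
  pulse_t <- seq(interval_ms, total_ms - interval_ms, by = interval_ms)
  inj <- data.frame(comp = probe_comp, t0_ms = pulse_t,
                    t1_ms = pulse_t + probe_ms, amp_nA = probe_nA)
  base_proto <- function(injections) ion_protocol(
    duration_ms = total_ms, injections = injections,
    trains = list(hfs_train(start_ms = hfs_start_ms)),
    train_targets = list(comps), gaba_scale = scale, na_scale = na_scale,
    record_dt_ms = 0.5
  )
  with_probe <- simulate(model, base_proto(inj))
  without <- simulate(model, base_proto(NULL))
  soma1 <- soma[1]
  defl <- vapply(pulse_t, function(t0) {
    idx <- with_probe$time >= t0 + probe_ms - 1 & with_probe$time <= t0 + probe_ms
    mean(with_probe$v[idx, soma1] - without$v[idx, soma1])
  }, numeric(1))
  baseline <- mean(abs(defl[pulse_t + probe_ms < hfs_start_ms]))
  out <- data.frame(t_ms = pulse_t, deflection_mV = defl,
                    normalized = abs(defl) / baseline)
  attr(out, "hfs_window") <- c(hfs_start_ms, hfs_end)
  out
}

wilson_ci <- function(k, n, conf = 0.95) {
  z <- stats::qnorm(1 - (1 - conf) / 2)
  p <- k / n
  den <- 1 + z^2 / n
  centre <- (p + z^2 / (2 * n)) / den
  half <- z * sqrt(p * (1 - p) / n + z^2 / (4 * n^2)) / den
  c(lower = max(0, centre - half), upper = min(1, centre + half))
}

#' Spike probability around glutamatergic input with and without HFS
#'
#' A noisy somatic current holds the cell near threshold while 10 Hz
#' glutamate-like conductance pulses are applied to the proximal apical or
#' basal dendrites. The probability of an action potential within 10 ms of
#' each pulse is estimated over repeated trials (Wilson 95% confidence
#' intervals); an optional HFS train (soma plus apical dendrites) spans part
#' of the run.
#'
#' @inheritParams run_hfs
#' @param glutamate_target `"apical_proximal"` or `"basal"`.
#' @param trials number of independent trials.
#' @param seed RNG seed (each trial derives its own stream deterministically).
#' @param noise_mean_nA,noise_sd_nA noisy somatic drive.
#' @param glut_gmax_nS peak glutamate conductance per pulse.
#' @param glut_rate_hz glutamate pulse rate.
#' @param with_hfs apply the HFS train.
#' @param duration_ms trial length.
#' @return data frame per glutamate pulse: time, firing probability, Wilson
#'   CI bounds, and the epoch (`pre`, `hfs_early`, `hfs_late`, `post`).
#' @export
spike_probability_run <- function(model, glutamate_target = c("apical_proximal",
                                                              "basal"),
                                  trials = 30, seed = 1,
                                  noise_mean_nA = 0, noise_sd_nA = 0.05,
                                  glut_gmax_nS = 2.5, glut_rate_hz = 10,
                                  with_hfs = TRUE, activation = 0.8,
                                  hfs_start_ms = 400, duration_ms = 1400) {
  glutamate_target <- match.arg(glutamate_target)
  if (trials < 1) stop("trials must be >= 1", call. = FALSE)
  n <- nrow(model$geometry)
  soma <- which(model$geometry$region == "soma")[1]
  glut_comps <- target_compartments(model, glutamate_target)
  glut_on <- seq(50, duration_ms - 20, by = 1000 / glut_rate_hz)
  hfs_comps <- target_compartments(model, c("soma", "apical"))
  scale <- rep(0, n); scale[hfs_comps] <- activation
  trains <- list(); targets <- list()
  hfs_end <- hfs_start_ms + 400
  if (with_hfs) {
    trains <- list(hfs_train(start_ms = hfs_start_ms))
    targets <- list(hfs_comps)
  }
  proto <- ion_protocol(
    duration_ms = duration_ms,
    noise = data.frame(comp = soma, mean_nA = noise_mean_nA,
                       sd_nA = noise_sd_nA),
    trains = trains, train_targets = targets, gaba_scale = scale,
    glut = list(comps = glut_comps, onsets_ms = glut_on,
                gmax_nS = glut_gmax_nS, tau_rise_ms = 0.5, tau_decay_ms = 2),
    record_dt_ms = 5
  )
  hits <- matrix(0L, trials, length(glut_on))
  for (tr in seq_len(trials)) {
    set.seed(seed + tr)
    out <- simulate(model, proto)
    st <- out$spikes$t_ms[out$spikes$comp == soma]
    hits[tr, ] <- vapply(glut_on, function(t0)
      as.integer(any(st > t0 & st <= t0 + 10)), integer(1))
  }
  k <- colSums(hits)
  ci <- t(vapply(k, wilson_ci, numeric(2), n = trials))
  epoch <- ifelse(glut_on < hfs_start_ms, "pre",
                  ifelse(glut_on < hfs_start_ms + 150, "hfs_early",
                         ifelse(glut_on < hfs_end, "hfs_late", "post")))
  if (!with_hfs) epoch <- rep("pre", length(glut_on))
  data.frame(t_ms = glut_on, p = k / trials, lower = ci[, 1],
             upper = ci[, 2], epoch = epoch)
}

#' Sensitivity of the GABA-mediated depolarization to key parameters
#'
#' Re-runs the HFS protocol (sodium current disabled, so the depolarization
#' is uncontaminated by spikes) with each parameter scaled by the given
#' factors: initial intracellular chloride, KCC2 transport density, glial
#' potassium-buffer capacity, GABA-A bicarbonate permeability fraction, and
#' GABA-A conductance density. The model is recalibrated for every
#' perturbation.
#'
#' @inheritParams run_hfs
#' @param parameters subset of `c("cl_i", "kcc2_density", "k_buffer",
#'   "hco3_fraction", "gaba_conductance")`.
#' @param factors multiplicative perturbations.
#' @param ... further arguments to [run_hfs()].
#' @return data frame sorted by absolute effect on peak depolarization, with
#'   the control row first.
#' @export
sensitivity_sweep <- function(model, parameters = c("cl_i", "kcc2_density",
                                                    "k_buffer",
                                                    "hco3_fraction",
                                                    "gaba_conductance"),
                              factors = c(0.5, 1.5), activation = 0.8, ...) {
  known <- c("cl_i", "kcc2_density", "k_buffer", "hco3_fraction",
             "gaba_conductance")
  bad <- setdiff(parameters, known)
  if (length(bad)) stop("unknown parameter(s): ", paste(bad, collapse = ", "),
                        call. = FALSE)
  perturb <- function(param, f) {
    m2 <- model
    if (param == "cl_i") {
      m2$params$ions$initial_mM$cl_i <- m2$params$ions$initial_mM$cl_i * f
    } else if (param == "kcc2_density") {
      m2$mech$kcc2_U <- m2$mech$kcc2_U * f
    } else if (param == "k_buffer") {
      m2$params$glial_buffer$total_mM <- m2$params$glial_buffer$total_mM * f
    } else if (param == "hco3_fraction") {
      m2$params$gaba$hco3_fraction <- min(m2$params$gaba$hco3_fraction * f, 1)
    } else if (param == "gaba_conductance") {
      m2$mech$gaba_gbar <- m2$mech$gaba_gbar * f
    }
    balance_rest(m2, model$params$solver$v_init_mV)
  }
  run_one <- function(m2) {
    tr <- run_hfs(m2, activation = activation, na_scale = 0, ...)
    mets <- hfs_metrics(tr, m2)
    c(peak = mets$peak_depolarization_mV, area = mets$depol_area_mV_ms)
  }
  ctrl <- run_one(balance_rest(model, model$params$solver$v_init_mV))
  rows <- data.frame(parameter = "control", factor = 1,
                     peak_depol_mV = ctrl["peak"], area_mV_ms = ctrl["area"])
  for (pm in parameters) {
    for (f in factors) {
      res <- run_one(perturb(pm, f))
      rows <- rbind(rows, data.frame(parameter = pm, factor = f,
                                     peak_depol_mV = res["peak"],
                                     area_mV_ms = res["area"]))
    }
  }
  rownames(rows) <- NULL
  rows$effect_mV <- rows$peak_depol_mV - ctrl["peak"]
  rows[c(1, 1 + order(-abs(rows$effect_mV[-1]))), ]
}
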