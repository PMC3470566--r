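#' GABA transmitter pulse trains
#'
#' High-frequency stimulation is modelled as square pulses of transmitter at a
#' peak concentration (default 1 mM) held for a fixed duration (1 ms) and
#' decaying exponentially afterwards with a 0.1 ms time constant; the standard
#' train delivers 40 pulses at 100 Hz.
#'
#' @param onsets_ms pulse onset times, ms.
#' @param peak_mM peak transmitter concentration, mM.
#' @param square_ms square-pulse duration, ms.
#' @param tau_ms exponential decay time constant after each pulse, ms.
#' @return an object of class `transmitter_train`.
#' @export
transmitter_train <- function(onsets_ms, peak_mM = 1, square_ms = 1,
                              tau_ms = 0.1) {
  stopifnot(peak_mM > 0, tau_ms > 0, square_ms >= 0)
  structure(list(onsets = sort(as.numeric(onsets_ms)), peak = peak_mM,
                 square = square_ms, tau = tau_ms),
            class = "transmitter_train")
}

#' @rdname transmitter_train
#' @param n_pulses,rate_hz number and rate of pulses in a regular train.
#' @param start_ms onset of the first pulse, ms.
#' @export
hfs_train <- function(n_pulses = 40, rate_hz = 100, start_ms = 0,
                      peak_mM = 1, square_ms = 1, tau_ms = 0.1) {
  transmitter_train(start_ms + (seq_len(n_pulses) - 1) * 1000 / rate_hz,
                    peak_mM, square_ms, tau_ms)
}

#' Transmitter concentration at time t
#'
#' @param train a [transmitter_train()].
#' @param t time, ms (vectorised, >= 0).
#' @return concentration, mM.
#' @export
#' @examples
#' tr <- hfs_train(n_pulses = 2)
#' transmitter_concentration(tr, c(0.5, 1.1, 5))
transmitter_concentration <- function(train, t) {
  if (any(t < 0)) stop("t must be >= 0", call. = FALSE)
  out <- numeric(length(t))
  for (on in train$onsets) {
    dt <- t - on
    within <- dt >= 0 & dt <= train$square
    after <- dt > train$square
    out[within] <- pmax(out[within], train$peak)
    out[after] <- pmax(out[after],
                       train$peak * exp(-(dt[after] - train$square) / train$tau))
  }
  out
}

#' Place GABA-A synapses at layer-specific densities
#'
#' Each compartment receives `round(density * length)` synapses (round half
#' up), each contributing the quantal conductance; the per-area synaptic
#' conductance density is stored with the model mechanisms.
#'
#' @param model an `ion_model` with labelled regions.
#' @param densities named vector/list, synapses per micrometre per region
#'   (defaults to the layer table in the model parameters).
#' @param quantal_nS quantal conductance per synapse, nS.
#' @return a data frame with per-compartment synapse counts and conductance
#'   densities (S/cm2).
#' @export
place_synapses <- function(model, densities = NULL,
                           quantal_nS = model$params$gaba$quantal_nS) {
  g <- model$geometry
  if (is.null(densities)) densities <- model$params$gaba$densities_per_um
  dens <- unlist(densities)
  missing <- setdiff(unique(g$region), names(dens))
  if (length(missing)) {
    stop("no synapse density configured for region(s): ",
         paste(missing, collapse = ", "), call. = FALSE)
  }
  count <- floor(dens[g$region] * g$length_um + 0.5)
  gbar <- count * quantal_nS * 1e-9 / g$area_cm2
  data.frame(id = g$id, region = g$region, count = as.integer(count),
             gbar_S_cm2 = gbar)
}

#' Chloride and bicarbonate currents through the GABA-A receptor
#'
#' The open-receptor conductance is split 4:1 between chloride and
#' bicarbonate (permeability ratio HCO3:Cl = 1:4), giving
#' `I_Cl = 0.8 g O (V - E_Cl)` and `I_HCO3 = 0.2 g O (V - E_HCO3)`; the
#' implied reversal potential is the weighted average
#' `E_GABA = 0.8 E_Cl + 0.2 E_HCO3`.
#'
#' @param open open-state occupancy in \[0, 1\].
#' @param v membrane potential, mV.
#' @param e_cl,e_hco3 chloride and bicarbonate Nernst potentials, mV.
#' @param g synaptic conductance density, S/cm2.
#' @param hco3_fraction bicarbonate fraction of the conductance.
#' @return list with `i_cl`, `i_hco3` (mA/cm2, outward positive) and `e_gaba`
#'   (mV).
#' @export
gaba_current <- function(open, v, e_cl, e_hco3, g, hco3_fraction = 0.2) {
  if (any(open < -1e-12 | open > 1 + 1e-12)) {
    stop("open occupancy outside [0, 1]", call. = FALSE)
  }
  f <- hco3_fraction
  list(
    i_cl = (1 - f) * g * open * (v - e_cl),
    i_hco3 = f * g * open * (v - e_hco3),
    e_gaba = (1 - f) * e_cl + f * e_hco3
  )
}
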