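#' Distance gradient of slowly inactivating sodium current
#'
#' The fraction of fast sodium conductance carried by the slowly inactivating
#' (6-state) scheme grows linearly with path distance from the soma:
#' `fraction = distance/250` below 250 um and 1 beyond; the soma itself
#' carries only the 5-state scheme.
#'
#' @param distance_um path distance from the soma, micrometres (>= 0).
#' @param slow_distance_um distance at which the gradient saturates.
#' @return fraction in \[0, 1\] (vectorised).
#' @export
#' @examples
#' slow_na_fraction(c(0, 125, 300))
slow_na_fraction <- function(distance_um, slow_distance_um = 250) {
  if (any(distance_um < 0)) stop("distance must be >= 0", call. = FALSE)
  pmin(distance_um / slow_distance_um, 1)
}

#' Sodium conductance from mixed Markov schemes
#'
#' `g = g_bar * ((1 - fraction) * O5 + fraction * O6)` where `O5` and `O6` are
#' the open-state occupancies of the 5- and 6-state schemes.
#'
#' @param g_bar maximal conductance density, S/cm2.
#' @param fraction slow-scheme fraction from [slow_na_fraction()].
#' @param o5,o6 open-state occupancies in \[0, 1\].
#' @return conductance density, S/cm2.
#' @export
na_conductance <- function(g_bar, fraction, o5, o6) {
  if (any(o5 < -1e-12 | o5 > 1 + 1e-12 | o6 < -1e-12 | o6 > 1 + 1e-12)) {
    stop("Markov occupancy outside [0, 1]: state corrupted", call. = FALSE)
  }
  g_bar * ((1 - fraction) * o5 + fraction * o6)
}

#' Implicit-Euler update of a Markov occupancy vector
#'
#' Solves `(I - dt * t(Q(V, ligand))) p' = p` and renormalises the result to
#' the probability simplex. The implicit update is unconditionally stable, so
#' the stiff receptor and sodium-channel schemes can be advanced at the cable
#' time step.
#'
#' @param scheme a `markov_scheme`.
#' @param p occupancy vector on the simplex.
#' @param v membrane potential, mV.
#' @param ligand ligand concentration, mM.
#' @param dt time step, ms (> 0).
#' @return updated occupancy vector.
#' @export
markov_step_implicit <- function(scheme, p, v, ligand = 0, dt) {
  stopifnot(dt > 0, length(p) == length(scheme$states))
  if (abs(sum(p) - 1) > 1e-6 || any(p < -1e-9)) {
    stop("occupancy must lie on the probability simplex", call. = FALSE)
  }
  Q <- markov_rate_matrix(scheme, v, ligand)
  A <- diag(length(p)) - dt * t(Q)
  pn <- tryCatch(solve(A, p), error = function(e) {
    stop(sprintf("implicit Markov solve failed (v=%.2f, ligand=%.3g): %s",
                 v, ligand, conditionMessage(e)), call. = FALSE)
  })
  pn[pn < 0 & pn > -1e-10] <- 0
  if (any(pn < 0)) {
    stop("implicit Markov update produced a negative occupancy", call. = FALSE)
  }
  unname(pn / sum(pn))
}

#' Stationary distribution of a Markov scheme
#'
#' @inheritParams markov_step_implicit
#' @return the equilibrium occupancy at fixed voltage/ligand.
#' @export
markov_equilibrium <- function(scheme, v, ligand = 0) {
  Q <- markov_rate_matrix(scheme, v, ligand)
  n <- nrow(Q)
  A <- rbind(t(Q), rep(1, n))
  b <- c(rep(0, n), 1)
  p <- qr.solve(A, b)
  p[p < 0] <- 0
  unname(p / sum(p))
}

#' Hodgkin-Huxley channel current and explicit gate update
#'
#' Current `I = g_bar * prod(gate^exponent) * (V - E)` (mA/cm2 with g in
#' S/cm2 and V in mV). Gates are advanced one explicit Euler step of
#' `dx/dt = (xinf(V) - x)/tau(V)` and clipped to \[0, 1\].
#'
#' @param gates list of gate specs (see [gate_inf()]).
#' @param x numeric vector of current gate values in \[0, 1\].
#' @param v membrane potential, mV.
#' @param e_rev reversal potential, mV.
#' @param g_bar maximal conductance density, S/cm2.
#' @param dt time step, ms.
#' @return list with `current` (mA/cm2, at the pre-update gates) and `gates`
#'   (updated values).
#' @export
hh_current <- function(gates, x, v, e_rev, g_bar, dt) {
  stopifnot(length(x) == length(gates))
  open <- 1
  xn <- x
  for (j in seq_along(gates)) {
    open <- open * x[j]^gates[[j]]$exponent
    xinf <- gate_inf(gates[[j]], v)
    tau <- gate_tau(gates[[j]], v)
    xn[j] <- min(max(x[j] + dt * (xinf - x[j]) / tau, 0), 1)
  }
  list(current = g_bar * open * (v - e_rev), gates = xn)
}
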