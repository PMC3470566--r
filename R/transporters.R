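#' KCC2 potassium-chloride cotransport
#'
#' Two-state electroneutral carrier reduced under rapid binding: the net flux
#' is proportional to the difference of the intra- and extracellular KCl ion
#' products with saturable binding, so transport vanishes exactly at
#' thermodynamic equilibrium `[K]i[Cl]i = [K]o[Cl]o` and reverses sign across
#' it. The potassium current is `I_KCC2` and the chloride current `-I_KCC2`
#' (zero net charge).
#'
#' @param k_i,k_o,cl_i,cl_o ion concentrations, mM (> 0).
#' @param umax maximal transport rate expressed as a current density, mA/cm2.
#' @param km_k,km_cl binding affinities, mM.
#' @return list with `i_k` and `i_cl` (mA/cm2, outward positive; `i_cl ==
#'   -i_k`).
#' @export
#' @examples
#' p <- default_parameters()$transporters$kcc2
#' kcc2_currents(140, 3.5, 4.5, 131, p$umax_mA_cm2, p$km_k_mM, p$km_cl_mM)
kcc2_currents <- function(k_i, k_o, cl_i, cl_o, umax, km_k, km_cl) {
  if (any(c(k_i, k_o, cl_i, cl_o) <= 0)) {
    stop("KCC2: non-positive concentration (homeostasis failure)",
         call. = FALSE)
  }
  num <- k_i * cl_i - k_o * cl_o
  den <- (k_i + km_k) * (cl_i + km_cl) + (k_o + km_k) * (cl_o + km_cl)
  i_k <- umax * num / den
  list(i_k = i_k, i_cl = -i_k)
}

#' NKCC1 sodium-potassium-chloride cotransport
#'
#' Two-faced carrier: a fraction `y` of carriers faces the extracellular side.
#' On each face the fully loaded probability follows rapid-equilibrium binding
#' of Na, K and two Cl; loaded and empty carriers translocate with fixed rate
#' constants. The net inward cycle flux J carries Na:K:Cl at 1:1:2, so the
#' per-ion currents are `I_Na = I_K = -0.5 * I_NKCC1` and `I_Cl = I_NKCC1`
#' with `I_NKCC1 = 2 F J` expressed as a current density; total charge flux is
#' identically zero.
#'
#' @param na_i,na_o,k_i,k_o,cl_i,cl_o concentrations, mM (> 0).
#' @param y fraction of carriers facing outside, in \[0, 1\].
#' @param pars NKCC1 parameter list (`umax_mA_cm2`, `km_na_mM`, `km_k_mM`,
#'   `km_cl_mM`, `k_loaded_per_ms`, `k_empty_per_ms`).
#' @param dt time step for the carrier-state update, ms (0 evaluates currents
#'   without advancing `y`).
#' @return list with `i_na`, `i_k`, `i_cl` (mA/cm2), `i_nkcc1`, the updated
#'   `y`, and the face probabilities `p_out_loaded`, `p_in_loaded`.
#' @export
nkcc1_current <- function(na_i, na_o, k_i, k_o, cl_i, cl_o, y, pars, dt = 0) {
  if (any(c(na_i, na_o, k_i, k_o, cl_i, cl_o) <= 0)) {
    stop("NKCC1: non-positive concentration (homeostasis failure)",
         call. = FALSE)
  }
  stopifnot(all(y >= 0 & y <= 1))
  load <- function(na, k, cl) {
    l <- (na / pars$km_na_mM) * (k / pars$km_k_mM) * (cl / pars$km_cl_mM)^2
    l / (1 + l)
  }
  p_o <- load(na_o, k_o, cl_o)
  p_i <- load(na_i, k_i, cl_i)
  kt <- pars$k_loaded_per_ms; ke <- pars$k_empty_per_ms
  # inward cycle flux, per-carrier units; umax folds in density and 2F
  j <- y * kt * p_o - (1 - y) * kt * p_i
  i_nkcc1 <- pars$umax_mA_cm2 * j
  if (dt > 0) {
    dy <- (1 - y) * (kt * p_i + ke * (1 - p_i)) -
      y * (kt * p_o + ke * (1 - p_o))
    y <- pmin(pmax(y + dt * dy, 0), 1)
  }
  list(i_na = -0.5 * i_nkcc1, i_k = -0.5 * i_nkcc1, i_cl = i_nkcc1,
       i_nkcc1 = i_nkcc1, y = y, p_out_loaded = p_o, p_in_loaded = p_i)
}

#' Steady-state NKCC1 carrier distribution
#' @inheritParams nkcc1_current
#' @return steady-state `y`.
#' @export
nkcc1_steady_y <- function(na_i, na_o, k_i, k_o, cl_i, cl_o, pars) {
  load <- function(na, k, cl) {
    l <- (na / pars$km_na_mM) * (k / pars$km_k_mM) * (cl / pars$km_cl_mM)^2
    l / (1 + l)
  }
  p_o <- load(na_o, k_o, cl_o); p_i <- load(na_i, k_i, cl_i)
  kt <- pars$k_loaded_per_ms; ke <- pars$k_empty_per_ms
  rin <- kt * p_i + ke * (1 - p_i)
  rout <- kt * p_o + ke * (1 - p_o)
  rin / (rin + rout)
}

#' Na/K-ATPase pump currents
#'
#' Saturating pump with 3 Na out : 2 K in stoichiometry:
#' `I_pump = i_max / ((1 + km_na/[Na]i)^3 (1 + km_k/[K]o)^2)`,
#' `I_Na = 3 I_pump`, `I_K = -2 I_pump` (one net charge out per cycle).
#'
#' @param na_i,k_o concentrations, mM.
#' @param i_max maximal pump current density, mA/cm2 (> 0).
#' @param km_na,km_k half-activation concentrations, mM.
#' @return list with `i_na`, `i_k`, `i_pump` (mA/cm2).
#' @export
nak_pump <- function(na_i, k_o, i_max, km_na = 10, km_k = 3.5) {
  stopifnot(all(i_max > 0))
  i_pump <- i_max / ((1 + km_na / na_i)^3 * (1 + km_k / k_o)^2)
  list(i_na = 3 * i_pump, i_k = -2 * i_pump, i_pump = i_pump)
}

#' Plasma-membrane calcium pump
#'
#' Saturable extrusion `I = i_max [Ca]i / ([Ca]i + km)` (mA/cm2, outward).
#'
#' @param ca_i intracellular calcium, mM.
#' @param i_max maximal pump current density, mA/cm2.
#' @param km half-activation, mM.
#' @return calcium current density, mA/cm2.
#' @export
ca_pump_current <- function(ca_i, i_max, km) {
  i_max * ca_i / (ca_i + km)
}

#' Sodium-calcium exchanger current
#'
#' Voltage- and concentration-dependent exchanger (3 Na : 1 Ca). `I_NaCaX` is
#' the net membrane current (one charge per cycle); per-ion currents are
#' `I_Na = 3 I_NaCaX`, `I_Ca = -2 I_NaCaX`.
#'
#' @param v membrane potential, mV.
#' @param na_i,na_o,ca_i,ca_o concentrations, mM.
#' @param scale exchanger scale factor, mA/cm2.
#' @param pars exchanger parameters (`km_na_mM`, `km_ca_mM`, `gamma`, `ksat`).
#' @param rtf thermal voltage RT/F, mV.
#' @return net exchanger current density, mA/cm2 (positive = reverse mode,
#'   calcium entry).
#' @export
nacax_current <- function(v, na_i, na_o, ca_i, ca_o, scale, pars,
                          rtf = rtf_mV(32)) {
  ef <- exp(pars$gamma * v / rtf)
  er <- exp(-(1 - pars$gamma) * v / rtf)
  num <- na_i^3 * ca_o * ef - na_o^3 * ca_i * er
  den <- (pars$km_na_mM^3 + na_o^3) * (pars$km_ca_mM + ca_o) *
    (1 + pars$ksat * er)
  scale * num / den
}

#' Combined calcium handling (exchanger + pump)
#'
#' @inheritParams nacax_current
#' @param capump_imax,capump_km calcium pump parameters.
#' @return list with per-ion currents `i_na` (exchanger sodium), `i_ca`
#'   (exchanger calcium plus pump), and components `i_nacax`, `i_capump`.
#' @export
nacax_and_capump <- function(v, na_i, na_o, ca_i, ca_o, scale, pars,
                             capump_imax, capump_km, rtf = rtf_mV(32)) {
  if (any(c(na_i, na_o, ca_i, ca_o) <= 0)) {
    stop("calcium handling: non-positive concentration", call. = FALSE)
  }
  ix <- nacax_current(v, na_i, na_o, ca_i, ca_o, scale, pars, rtf)
  ip <- ca_pump_current(ca_i, capump_imax, capump_km)
  list(i_na = 3 * ix, i_ca = -2 * ix + ip, i_nacax = ix, i_capump = ip)
}
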