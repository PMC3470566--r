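#' Convert membrane currents to concentration changes
#'
#' For each ion, `d[X]i/dt = -I_X * area / (z F vol_i)` with the
#' opposite-signed change in the extracellular shell scaled by the shell
#' volume; moles are conserved across the membrane exactly. Currents are
#' signed outward-positive.
#'
#' @param conc n x 8 concentration matrix, columns
#'   `na_i, k_i, cl_i, ca_i, na_o, k_o, cl_o, ca_o` (mM).
#' @param currents n x 4 matrix of per-ion membrane current densities
#'   (mA/cm2), columns na, k, cl, ca.
#' @param area_cm2,vol_i_cm3,vol_o_cm3 compartment geometry.
#' @param dt time step, ms.
#' @return updated concentration matrix.
#' @export
concentration_step <- function(conc, currents, area_cm2, vol_i_cm3,
                               vol_o_cm3, dt) {
  conc <- as.matrix(conc)
  for (j in seq_along(ION_NAMES)) {
    dmol <- -currents[, j] * area_cm2 * dt / (ION_Z[j] * FARADAY)  # mmol
    conc[, j] <- conc[, j] + dmol / vol_i_cm3
    conc[, j + 4] <- conc[, j + 4] - dmol / vol_o_cm3
  }
  bad <- which(conc <= 0, arr.ind = TRUE)
  if (nrow(bad)) {
    stop(sprintf(
      "homeostasis failure: %s driven non-positive in compartment %d",
      ION_COLS[bad[1, 2]], bad[1, 1]), call. = FALSE)
  }
  conc
}

#' Glial buffering of extracellular potassium
#'
#' First-order reversible uptake `K+ + B <-> KB` in the extracellular shell:
#' `d[KB]/dt = kf [K]o [B] - kb [KB]` with `[B] = B_total - [KB]`; the free
#' potassium change is the negative of the bound change, so potassium moles
#' are conserved between pools. With `kb/kf` equal to the resting `[K]o` and
#' the buffer half-occupied at rest, a step perturbation relaxes back to
#' baseline on a ~1 s timescale.
#'
#' @param k_o extracellular potassium, mM.
#' @param kb bound potassium (shell-volume mM).
#' @param pars buffer parameters (`total_mM`, `kf_per_mM_ms`, `kb_per_ms`).
#' @param dt time step, ms.
#' @return list with updated `k_o` and `kb`.
#' @export
glial_buffer_step <- function(k_o, kb, pars, dt) {
  free <- pars$total_mM - kb
  dkb <- (pars$kf_per_mM_ms * k_o * free - pars$kb_per_ms * kb) * dt
  dkb <- pmin(pmax(dkb, -kb), free)       # never overshoot either pool
  list(k_o = k_o - dkb, kb = kb + dkb)
}

#' Equilibrium bound-buffer load for a given extracellular potassium
#' @inheritParams glial_buffer_step
#' @return bound potassium at equilibrium, shell-volume mM.
#' @export
glial_buffer_equilibrium <- function(k_o, pars) {
  pars$total_mM * pars$kf_per_mM_ms * k_o /
    (pars$kf_per_mM_ms * k_o + pars$kb_per_ms)
}

#' Longitudinal diffusion between connected compartments
#'
#' Fickian exchange along the tree for both the intracellular and the
#' extracellular pools: the molar flux between a compartment and its parent is
#' `D * surface * (C_parent - C_child) / distance`, applied explicitly. Total
#' moles of each ion over the tree are conserved.
#'
#' @inheritParams concentration_step
#' @param parent parent index per compartment (`NA` for the root).
#' @param surf_i_cm2,surf_o_cm2 connecting cross-sections to the parent, cm2.
#' @param dist_cm centre-to-centre distance to the parent, cm.
#' @param d_um2_ms named diffusion constants (um2/ms) for na, k, cl, ca.
#' @return updated concentration matrix.
#' @export
diffusion_step <- function(conc, parent, surf_i_cm2, surf_o_cm2, dist_cm,
                           vol_i_cm3, vol_o_cm3, d_um2_ms, dt) {
  conc <- as.matrix(conc)
  dcm <- unlist(d_um2_ms)[ION_NAMES] * 1e-8  # um2/ms -> cm2/ms
  for (i in seq_along(parent)) {
    p <- parent[i]
    if (is.na(p)) next
    for (j in seq_along(ION_NAMES)) {
      # intracellular pool
      f <- dcm[j] * surf_i_cm2[i] * (conc[p, j] - conc[i, j]) / dist_cm[i] * dt
      conc[i, j] <- conc[i, j] + f / vol_i_cm3[i]
      conc[p, j] <- conc[p, j] - f / vol_i_cm3[p]
      # extracellular shell
      jo <- j + 4
      f <- dcm[j] * surf_o_cm2[i] * (conc[p, jo] - conc[i, jo]) / dist_cm[i] * dt
      conc[i, jo] <- conc[i, jo] + f / vol_o_cm3[i]
      conc[p, jo] <- conc[p, jo] - f / vol_o_cm3[p]
    }
  }
  conc
}

#' Reversal potentials from the ionic state
#'
#' Nernst potentials for Na+, K+, Cl-, Ca2+ and (fixed) HCO3-, plus the
#' GABA-A reversal potential as the permeability-weighted average
#' `E_GABA = (1 - f) E_Cl + f E_HCO3` with bicarbonate fraction `f` (default
#' 0.2).
#'
#' @param conc concentration matrix (n x 8) or a single row.
#' @param hco3_i,hco3_o fixed bicarbonate concentrations, mM.
#' @param temperature_c bath temperature.
#' @param hco3_fraction bicarbonate fraction of the GABA-A conductance.
#' @return data frame with columns `e_na, e_k, e_cl, e_ca, e_hco3, e_gaba`
#'   (mV).
#' @export
reversal_potentials <- function(conc, hco3_i = 15, hco3_o = 25,
                                temperature_c = 32, hco3_fraction = 0.2) {
  conc <- rbind(conc)
  e_na <- nernst(conc[, 5], conc[, 1], 1, temperature_c)
  e_k <- nernst(conc[, 6], conc[, 2], 1, temperature_c)
  e_cl <- nernst(conc[, 7], conc[, 3], -1, temperature_c)
  e_ca <- nernst(conc[, 8], conc[, 4], 2, temperature_c)
  e_hco3 <- nernst(hco3_o, hco3_i, -1, temperature_c)
  data.frame(e_na = e_na, e_k = e_k, e_cl = e_cl, e_ca = e_ca,
             e_hco3 = e_hco3,
             e_gaba = (1 - hco3_fraction) * e_cl + hco3_fraction * e_hco3)
}
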