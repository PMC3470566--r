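#' Load model parameters
#'
#' Reads a structured parameter file (YAML) describing channel gating,
#' Markov-scheme rate constants, transporter kinetics, initial ion
#' concentrations, glial buffering, and solver settings. With no argument the
#' package defaults are returned.
#'
#' Entries whose value is the string `"calibrated"` are placeholders filled in
#' by [balance_rest()] (Na/K pump maximum, leak conductances, NKCC1 density,
#' Na/Ca exchanger scale).
#'
#' @param path path to a YAML parameter file; `NULL` for the packaged
#'   defaults.
#' @return a nested list of parameters (class `ionshift_params`).
#' @export
load_parameters <- function(path = NULL) {
  if (is.null(path)) {
    path <- system.file("extdata", "default_parameters.yaml",
                        package = "ionshift", mustWork = TRUE)
  }
  p <- yaml::read_yaml(path)
  # "calibrated" placeholders become NA to be filled by balance_rest()
  p <- rapply(p, function(x) {
    if (identical(x, "calibrated")) NA_real_ else x
  }, how = "replace")
  class(p) <- c("ionshift_params", "list")
  p
}

#' Package default parameters
#' @return see [load_parameters()].
#' @export
default_parameters <- function() load_parameters(NULL)

#' Initial concentration vector in internal column order
#' @keywords internal
initial_concentrations <- function(params) {
  ini <- params$ions$initial_mM
  out <- vapply(ION_COLS, function(nm) as.numeric(ini[[nm]]), numeric(1))
  if (any(out <= 0)) stop("initial concentrations must be positive", call. = FALSE)
  out
}

#' Steady-state value of a Hodgkin-Huxley gate
#'
#' Gates use a Boltzmann steady state
#' `xinf = 1 / (1 + exp(-(V - vhalf)/slope))` (negative `slope` gives an
#' inactivation-type curve) and a bell-shaped voltage-dependent time constant
#' `tau = base + amp / (exp((V - vmax)/sig1) + exp(-(V - vmax)/sig2))`.
#'
#' @param gate a gate spec (named list with `inf_vhalf`, `inf_slope`,
#'   `tau_base`, `tau_amp`, `tau_vmax`, `tau_sig1`, `tau_sig2`).
#' @param v membrane potential, mV (vectorised).
#' @return steady-state open fraction in \[0, 1\].
#' @export
gate_inf <- function(gate, v) {
  1 / (1 + exp(-(v - gate$inf_vhalf) / gate$inf_slope))
}

#' Time constant of a Hodgkin-Huxley gate (ms)
#' @rdname gate_inf
#' @export
gate_tau <- function(gate, v) {
  gate$tau_base + gate$tau_amp /
    (exp((v - gate$tau_vmax) / gate$tau_sig1) +
       exp(-(v - gate$tau_vmax) / gate$tau_sig2))
}

# ---- Markov scheme construction -------------------------------------------

# Transition rate forms understood by both the R rate evaluator and the
# compiled engine:
#   1 const      r = p1
#   2 expv       r = p1 * exp((v - p2) / p3)
#   3 linoid     r = p1 * (v - p2) / (1 - exp(-(v - p2) / p3))
#   4 ligand     r = p1 * ligand
#   5 linoid_rev r = p1 * (p2 - v) / (1 - exp(-(p2 - v) / p3))
eval_rate <- function(type, p1, p2, p3, v, ligand = 0) {
  switch(type,
    p1,
    p1 * exp((v - p2) / p3),
    {
      x <- v - p2
      ifelse(abs(x) < 1e-6, p1 * p3, p1 * x / (1 - exp(-x / p3)))
    },
    p1 * ligand,
    {
      x <- p2 - v
      ifelse(abs(x) < 1e-6, p1 * p3, p1 * x / (1 - exp(-x / p3)))
    }
  )
}

new_markov_scheme <- function(states, transitions, conducting, p0) {
  stopifnot(nrow(transitions) >= 1, all(p0 >= 0), abs(sum(p0) - 1) < 1e-12)
  structure(
    list(states = states, transitions = transitions,
         conducting = conducting, p0 = p0),
    class = "markov_scheme"
  )
}

#' Rate (generator) matrix of a Markov scheme
#'
#' Returns the generator Q (per ms) at a given voltage and ligand
#' concentration: `Q[i, j]` is the transition rate from state i to state j for
#' `i != j`, and rows sum to zero.
#'
#' @param scheme a `markov_scheme` (see [build_na_scheme()],
#'   [build_gaba_scheme()]).
#' @param v membrane potential, mV.
#' @param ligand ligand (transmitter) concentration, mM.
#' @return an n_states x n_states generator matrix.
#' @export
markov_rate_matrix <- function(scheme, v, ligand = 0) {
  n <- length(scheme$states)
  Q <- matrix(0, n, n, dimnames = list(scheme$states, scheme$states))
  tr <- scheme$transitions
  for (k in seq_len(nrow(tr))) {
    r <- eval_rate(tr$type[k], tr$p1[k], tr$p2[k], tr$p3[k], v, ligand)
    if (r < 0) stop("negative transition rate", call. = FALSE)
    Q[tr$from[k], tr$to[k]] <- Q[tr$from[k], tr$to[k]] + r
  }
  diag(Q) <- diag(Q) - rowSums(Q)
  Q
}

#' Fast-sodium Markov schemes
#'
#' Builds the 5-state scheme (three closed states, open, fast-inactivated;
#' no slow inactivation) or the 6-state scheme (adds a slowly recovering
#' inactivated state). Activation transitions follow an m^3-equivalent ladder;
#' the 6-state scheme enters the slow-inactivated state from the
#' fast-inactivated state, so channel availability accumulates a slowly
#' recovering deficit during repetitive firing.
#'
#' @param params model parameters (see [load_parameters()]).
#' @param slow logical; `TRUE` builds the 6-state scheme.
#' @return a `markov_scheme`.
#' @export
build_na_scheme <- function(params, slow = FALSE) {
  r <- params$na_markov$rates
  tr <- function(from, to, type, p1, p2 = 0, p3 = 1) {
    data.frame(from = from, to = to, type = type, p1 = p1, p2 = p2, p3 = p3)
  }
  am <- function(mult) tr(NA, NA, 3, mult * r$am_a, r$am_th, r$am_q)
  bm <- function(mult) tr(NA, NA, 5, mult * r$bm_a, r$bm_th, r$bm_q)
  t1 <- am(3); t1$from <- 1; t1$to <- 2
  t2 <- bm(1); t2$from <- 2; t2$to <- 1
  t3 <- am(2); t3$from <- 2; t3$to <- 3
  t4 <- bm(2); t4$from <- 3; t4$to <- 2
  t5 <- am(1); t5$from <- 3; t5$to <- 4
  t6 <- bm(3); t6$from <- 4; t6$to <- 3
  t7 <- tr(4, 5, 2, r$koi_a, 0, r$koi_b)           # open -> inactivated
  t8 <- tr(5, 1, 2, r$kic_a, 0, -r$kic_b)          # recovery
  trans <- rbind(t1, t2, t3, t4, t5, t6, t7, t8)
  states <- c("C1", "C2", "C3", "O", "I")
  if (slow) {
    states <- c(states, "S")
    trans <- rbind(
      trans,
      tr(5, 6, 2, r$kis_a, 0, r$kis_b),            # I -> S
      tr(6, 5, 2, r$ksi_a, r$ksi_vh, -r$ksi_b)     # S -> I
    )
  }
  p0 <- c(1, rep(0, length(states) - 1))
  new_markov_scheme(states, trans, conducting = 4L, p0 = p0)
}

#' GABA-A receptor Markov scheme
#'
#' Six states: unbound closed, singly bound, doubly bound, open, and one
#' desensitized state off each bound closed state
#' (C <-> C1 <-> C2 <-> O; C1 <-> D1 slow; C2 <-> D2 fast). Binding
#' transitions are proportional to the transmitter concentration with the
#' statistical factors of two identical binding sites.
#'
#' @inheritParams build_na_scheme
#' @return a `markov_scheme` with conducting state `O`.
#' @export
build_gaba_scheme <- function(params) {
  r <- params$gaba$rates
  tr <- function(from, to, type, p1, p2 = 0, p3 = 1) {
    data.frame(from = from, to = to, type = type, p1 = p1, p2 = p2, p3 = p3)
  }
  trans <- rbind(
    tr(1, 2, 4, 2 * r$kon_per_mM_ms),
    tr(2, 1, 1, r$koff_per_ms),
    tr(2, 3, 4, r$kon_per_mM_ms),
    tr(3, 2, 1, 2 * r$koff_per_ms),
    tr(3, 4, 1, r$beta_per_ms),
    tr(4, 3, 1, r$alpha_per_ms),
    tr(2, 5, 1, r$d1_on_per_ms),
    tr(5, 2, 1, r$d1_off_per_ms),
    tr(3, 6, 1, r$d2_on_per_ms),
    tr(6, 3, 1, r$d2_off_per_ms)
  )
  new_markov_scheme(
    states = c("C", "C1", "C2", "O", "D1", "D2"),
    transitions = trans, conducting = 4L,
    p0 = c(1, 0, 0, 0, 0, 0)
  )
}

# Transitions of a scheme as plain numeric matrix for the compiled engine:
# columns from, to (0-based), type, p1, p2, p3.
scheme_matrix <- function(scheme) {
  tr <- scheme$transitions
  cbind(tr$from - 1L, tr$to - 1L, tr$type, tr$p1, tr$p2, tr$p3)
}
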