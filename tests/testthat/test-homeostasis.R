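p <- default_parameters()

test_that("currents convert to concentration changes with exact unit algebra", {
  conc <- matrix(rep(initial_concentrations(p), each = 2), 2, 8,
                 dimnames = list(NULL, ionshift:::ION_COLS))
  area <- c(1e-5, 2e-6); vi <- c(1e-9, 5e-11); vo <- 0.15 * vi
  zero <- matrix(0, 2, 4)
  expect_identical(concentration_step(conc, zero, area, vi, vo, 1), conc)

  # dimensional oracle: constant K+ efflux of 0.01 mA/cm2 over 1 ms
  I <- zero; I[1, 2] <- 0.01
  out <- concentration_step(conc, I, area, vi, vo, 1)
  d_oracle <- 0.01 * area[1] * 1 / (1 * 96485.332 * vi[1])
  expect_equal(out[1, "k_i"], conc[1, "k_i"] - d_oracle, tolerance = 1e-12)
  # shell gain amplified by the intracellular/shell volume ratio (1/0.15)
  expect_equal(unname(out[1, "k_o"] - conc[1, "k_o"]),
               unname(conc[1, "k_i"] - out[1, "k_i"]) / 0.15,
               tolerance = 1e-10)
  # membrane transfer conserves moles exactly
  expect_equal(out[1, "k_i"] * vi[1] + out[1, "k_o"] * vo[1],
               conc[1, "k_i"] * vi[1] + conc[1, "k_o"] * vo[1],
               tolerance = 1e-18)

  I_kill <- zero; I_kill[2, 4] <- 1  # drive Ca_i negative
  expect_error(concentration_step(conc, I_kill, area, vi, vo, 10),
               "homeostasis failure.*ca_i.*compartment 2")
})

test_that("glial buffering is a conservative first-order uptake", {
  gb <- p$glial_buffer
  kb0 <- glial_buffer_equilibrium(3.5, gb)
  # equilibrated buffer at baseline potassium is a fixed point
  out <- glial_buffer_step(3.5, kb0, gb, 1)
  expect_equal(out$k_o, 3.5, tolerance = 1e-12)
  # a +4 mM step decays monotonically toward baseline, conserving moles
  ko <- 7.5; kb <- kb0
  total <- ko + kb
  trace <- numeric(4000)
  for (k in 1:4000) {  # 4 s at 1 ms
    st <- glial_buffer_step(ko, kb, gb, 1)
    ko <- st$k_o; kb <- st$kb
    trace[k] <- ko
    expect_equal(ko + kb, total, tolerance = 1e-12)
  }
  expect_true(all(diff(trace) < 0))
  expect_lt(trace[4000] - 3.5, 0.5 * 4)  # well on its way back by 4 s
})

test_that("glial buffering tempers the stimulus-evoked potassium transient", {
  m <- ca1_model()
  comps <- target_compartments(m, c("soma", "apical"))
  n <- nrow(m$geometry); sc <- rep(0, n); sc[comps] <- 0.8
  mk_proto <- function(buffer) ion_protocol(
    duration_ms = 700, trains = list(hfs_train(start_ms = 100)),
    train_targets = list(comps), gaba_scale = sc, na_scale = 0,
    buffer = buffer, record_dt_ms = 2)
  with_buf <- simulate(m, mk_proto(TRUE))
  no_buf <- simulate(m, mk_proto(FALSE))
  expect_gt(max(no_buf$conc$k_o), max(with_buf$conc$k_o))
})

test_that("longitudinal diffusion equilibrates a two-box system analytically", {
  # two connected compartments, closed system
  m <- make_fixture("ball_and_stick", nseg = 1L, stick_length_um = 50,
                    stick_radius_um = 10, soma_radius_um = 10,
                    soma_length_um = 50)
  g <- m$geometry
  conc <- matrix(rep(initial_concentrations(p), each = 2), 2, 8)
  conc[1, 2] <- 150; conc[2, 2] <- 130  # K_i gradient
  expect_identical(
    diffusion_step(matrix(rep(initial_concentrations(p), each = 2), 2, 8),
                   g$parent, m$diff_surf_i, m$diff_surf_o, m$diff_dist,
                   g$vol_i_cm3, g$vol_o_cm3, p$ions$diffusion_um2_ms, 1),
    matrix(rep(initial_concentrations(p), each = 2), 2, 8))  # uniform: no flux

  dt <- 0.02
  dk <- p$ions$diffusion_um2_ms$k * 1e-8
  lambda <- dk * m$diff_surf_i[2] / m$diff_dist[2] *
    (1 / g$vol_i_cm3[1] + 1 / g$vol_i_cm3[2])
  cc <- conc
  nstep <- 5000
  for (s in 1:nstep) {
    cc <- diffusion_step(cc, g$parent, m$diff_surf_i, m$diff_surf_o,
                         m$diff_dist, g$vol_i_cm3, g$vol_o_cm3,
                         p$ions$diffusion_um2_ms, dt)
  }
  delta0 <- conc[1, 2] - conc[2, 2]
  expect_equal(cc[1, 2] - cc[2, 2], delta0 * exp(-lambda * nstep * dt),
               tolerance = 2e-3)
  # moles conserved over the tree
  expect_equal(sum(cc[, 2] * g$vol_i_cm3), sum(conc[, 2] * g$vol_i_cm3),
               tolerance = 1e-12)
})

test_that("reversal potentials follow the Nernst equation with correct signs", {
  conc <- matrix(initial_concentrations(p), 1, 8)
  E <- reversal_potentials(conc, temperature_c = 32)
  rtf <- rtf_mV(32)
  expect_equal(E$e_k, rtf * log(3.5 / 140))
  expect_equal(E$e_cl, -rtf * log(131 / 4.5))   # negative valence
  expect_equal(E$e_ca, rtf / 2 * log(2 / 5e-5))
  expect_equal(E$e_gaba, 0.8 * E$e_cl + 0.2 * E$e_hco3)

  # equal concentrations: 0 mV; tenfold cation gradient: RT/F ln(10)
  eq <- matrix(c(10, 10, 10, 10, 10, 10, 10, 10), 1, 8)
  Eeq <- reversal_potentials(eq, hco3_i = 15, hco3_o = 15)
  expect_equal(unlist(Eeq[c("e_na", "e_k", "e_cl", "e_ca", "e_hco3")]),
               c(e_na = 0, e_k = 0, e_cl = 0, e_ca = 0, e_hco3 = 0))
  expect_equal(nernst(140, 14, 1, 32), rtf_mV(32) * log(10))

  # raising intracellular chloride depolarizes E_Cl and E_GABA monotonically
  cls <- seq(4, 20, by = 2)
  ecl <- vapply(cls, function(ci) {
    cc <- conc; cc[3] <- ci
    reversal_potentials(cc)$e_cl
  }, numeric(1))
  expect_true(all(diff(ecl) > 0))
  expect_error(nernst(-1, 10, 1), "positive")
})
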