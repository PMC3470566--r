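test_that("stimulation requires a calibrated model and zero activation is silent", {
  raw <- attach_mechanisms(make_fixture("ball_and_stick"))
  expect_error(run_hfs(raw), "calibrated")
  m <- ca1_model()
  soma <- soma_of(m)
  quiet <- run_hfs(m, activation = 0, post_ms = 300, na_scale = 0)
  # no synaptic response: only the sub-mV offset from silencing the resting
  # sodium window current
  expect_lt(diff(range(quiet$v[, soma])), 0.6)
  expect_lt(max(abs(quiet$v[, soma] - -66)), 1)
})

test_that("HFS produces hyperpolarization followed by slow depolarization", {
  m <- ca1_model()
  tr <- hfs_ctrl()
  mets <- hfs_metrics(tr, m)
  expect_lt(mets$peak_hyperpolarization_mV, -3)
  expect_gt(mets$peak_depolarization_mV, 2)
  expect_gt(mets$t_depol_ms, mets$t_hyper_ms)
  expect_gt(mets$depol_duration_ms, 100)
  # chloride loads and extracellular potassium accumulates during the train
  expect_gt(max(tr$conc$cl_i), 10)
  expect_gt(max(tr$conc$k_o), 5.5)
})

test_that("the soma is tied to its GABA-A reversal during the train", {
  m <- ca1_model()
  soma <- soma_of(m)
  runs <- lapply(c(-0.2, 0, 0.2), function(b)
    run_hfs(m, activation = 0.8, na_scale = 0, bias_nA = b, post_ms = 400))
  at <- function(tr, t) tr$v[which.min(abs(tr$time - t)), soma]
  pre <- vapply(runs, at, numeric(1), t = 180)   # bias on, train not yet
  late <- vapply(runs, at, numeric(1), t = 570)  # last pulses of the train
  expect_gt(diff(range(pre)), 12)
  expect_lt(diff(range(late)), 0.5 * diff(range(pre)))
})

test_that("peak dendritic E_GABA exceeds somatic E_GABA after the train", {
  m <- ca1_model()
  tr <- hfs_ctrl()
  soma <- soma_of(m)
  dend <- which(m$geometry$type == 4L)
  expect_gt(max(tr$e_gaba[, dend]), max(tr$e_gaba[, soma]) + 10)
  # peak chloride load grows with distance along a uniform-density cable
  mb <- balance_rest(attach_mechanisms(make_fixture("ball_and_stick"),
                                       gaba_densities = uniform_density()))
  nb <- nrow(mb$geometry)
  prb <- ion_protocol(duration_ms = 800,
                      trains = list(hfs_train(start_ms = 100)),
                      train_targets = list(seq_len(nb)),
                      gaba_scale = rep(0.8, nb), na_scale = 0,
                      record_dt_ms = 2)
  tb <- simulate(mb, prb)
  pk <- apply(tb$conc$cl_i, 2, max)[-1]
  expect_true(all(diff(pk) > 0))
})

test_that("smaller-radius compartments accumulate more chloride", {
  rr <- radius_contrast_run()
  pk <- apply(rr$trace$conc$cl_i, 2, max) - 4.5
  thick <- pk[3:5]; thin <- pk[7:9]  # matched positions along the two sticks
  expect_true(all(thin > thick))
})

test_that("partial GABA-A block preserves hyperpolarization but cuts depolarization", {
  m <- ca1_model()
  mc <- hfs_metrics(hfs_ctrl(), m)
  mq <- hfs_metrics(hfs_quinine(), m)
  # hyperpolarization magnitude preserved within 10%
  expect_lt(abs(mq$peak_hyperpolarization_mV - mc$peak_hyperpolarization_mV) /
              abs(mc$peak_hyperpolarization_mV), 0.10)
  # depolarization reduced by more than half
  expect_lt(mq$peak_depolarization_mV, 0.5 * mc$peak_depolarization_mV)
  # and the switch from hyperpolarization to depolarization is slower
  expect_gt(mq$switch_ms, mc$switch_ms)
  # the potassium transient is diminished but not eliminated
  expect_lt(max(hfs_quinine()$conc$k_o), max(hfs_ctrl()$conc$k_o))
  expect_gt(max(hfs_quinine()$conc$k_o), 4)
})

test_that("KCC2 block raises and prolongs E_GABA depolarization, lowers [K]o", {
  m <- ca1_model()
  ctrl <- hfs_ctrl(); k60 <- hfs_kcc2_60()
  dend <- which(m$geometry$type == 4L)
  # dendritic GABA-A reversal more depolarized, and for longer
  expect_gt(max(k60$e_gaba[, dend]), max(ctrl$e_gaba[, dend]))
  late <- which.min(abs(ctrl$time - 2000))
  expect_gt(max(k60$e_gaba[late, dend]), max(ctrl$e_gaba[late, dend]) + 1)
  # somatic depolarization at least as large, firing not reduced
  expect_gte(hfs_metrics(k60, m)$peak_depolarization_mV,
             hfs_metrics(ctrl, m)$peak_depolarization_mV)
  # dendritic extracellular potassium transient is smaller
  pk_c <- apply(ctrl$conc$k_o[, dend], 2, max)
  pk_k <- apply(k60$conc$k_o[, dend], 2, max)
  expect_lt(max(pk_k), max(pk_c))
})

test_that("the potassium transient originates mostly from KCC2 extrusion", {
  m <- ca1_model()
  dend <- which(m$geometry$type == 4L)
  pc <- apply(hfs_ctrl()$conc$k_o[, dend], 2, max) - 3.5
  pk <- apply(hfs_kcc2_100()$conc$k_o[, dend], 2, max) - 3.5
  share <- (pc - pk) / pc
  # in a substantial set of dendritic shells KCC2 supplies over half of the
  # transient, and it is the dominant source overall
  expect_gt(mean(share > 0.5), 0.25)
  expect_gt(stats::median(share), 0.4)
})

test_that("removing the potassium transient attenuates the depolarization", {
  m <- ca1_model()
  mc <- hfs_metrics(hfs_ctrl(), m)
  frozen <- run_intervention(m, k_clamp = TRUE, activation = 0.8,
                             na_scale = 0, post_ms = 1500)
  blind <- run_intervention(m, kcc2_frozen_k = TRUE, activation = 0.8,
                            na_scale = 0, post_ms = 1500)
  mf <- hfs_metrics(frozen, m); mb <- hfs_metrics(blind, m)
  # both reduce the depolarization only modestly (well under 4 mV)
  expect_lt(mf$peak_depolarization_mV, mc$peak_depolarization_mV)
  expect_lt(mb$peak_depolarization_mV, mc$peak_depolarization_mV)
  expect_lt(mc$peak_depolarization_mV - mf$peak_depolarization_mV, 4)
  expect_lt(mc$peak_depolarization_mV - mb$peak_depolarization_mV, 4)
  expect_error(run_intervention(m, k_clamp = TRUE, kcc2_frozen_k = TRUE),
               "conflicting")
})

test_that("a larger dendritic extracellular space lowers [K]o transients only", {
  m <- ca1_model()
  sh <- run_intervention(m, shell_fraction = 0.22, shell_beyond_um = 100,
                         activation = 0.8, na_scale = 0, post_ms = 1500)
  dend <- which(m$geometry$dist_um > 100 & m$geometry$type == 4L)
  drop <- apply(hfs_ctrl()$conc$k_o[, dend], 2, max) -
    apply(sh$conc$k_o[, dend], 2, max)
  expect_gt(max(drop), 0.8)   # around 1-2 mM depending on the compartment
  expect_lt(max(drop), 4)
  # the depolarization persists
  expect_gt(hfs_metrics(sh, m)$peak_depolarization_mV,
            0.5 * hfs_metrics(hfs_ctrl(), m)$peak_depolarization_mV)
})

test_that("a second HFS hyperpolarizes the soma but depolarizes the dendrites", {
  m <- ca1_model()
  g <- m$geometry
  soma <- soma_of(m)
  s2 <- run_second_hfs(m, "falling")
  cl <- attr(s2, "classification")
  expect_equal(unname(cl[soma]), "hyperpolarizing")
  # chloride-loaded radiatum dendrites; compartments in the sparsely
  # innervated distal band keep a resting reversal and are not asserted
  dend <- which(g$type == 4L & g$dist_um >= 140 & g$dist_um <= 280)
  expect_true(all(cl[dend] == "depolarizing"))
  on2 <- attr(s2, "second_onset_ms")
  i0 <- which.min(abs(s2$time - on2))
  w <- s2$time > on2 & s2$time <= on2 + 20
  # immediate somatic hyperpolarization, immediate dendritic depolarization
  expect_lt(min(s2$v[w, soma] - s2$v[i0, soma]), -0.5)
  d1 <- dend[1]
  expect_gt(max(s2$v[w, d1] - s2$v[i0, d1]), 0.5)
  # somatic GABA-A current stays hyperpolarizing while the axial current
  # from the adjacent dendrite turns depolarizing
  resp <- s2$time >= on2 & s2$time <= on2 + 400
  i_soma <- s2$i_gaba_cl[resp, soma] + s2$i_gaba_hco3[resp, soma]
  expect_true(all(i_soma >= -1e-12))
  adj <- which(g$parent == soma & g$type == 4L)[1]
  ax <- measure_axial_current(m, from = adj, to = soma,
                              s2$v[resp, adj], s2$v[resp, soma])
  expect_lt(min(ax), -0.002)  # depolarizing axial inflow
})

test_that("after recovery a second HFS gives brief weak hyperpolarization then strong depolarization", {
  m <- ca1_model()
  soma <- soma_of(m)
  s3 <- run_second_hfs(m, "recovered")
  on3 <- attr(s3, "second_onset_ms")
  j0 <- which.min(abs(s3$time - on3))
  early <- s3$time > on3 & s3$time <= on3 + 150
  later <- s3$time > on3 & s3$time <= on3 + 1000
  dip <- min(s3$v[early, soma] - s3$v[j0, soma])
  rise <- max(s3$v[later, soma] - s3$v[j0, soma])
  expect_lt(dip, 0)          # a hyperpolarization exists...
  expect_gt(dip, -3)         # ...but with low amplitude
  expect_gt(rise, 3)         # followed by robust depolarization
})

test_that("a secondary GABA pulse excites from the distal dendrites only", {
  runs <- secondary_pulse_runs()
  expect_equal(runs$distal$classification, "excitatory")
  expect_gt(runs$distal$delta_mV, 1)
  expect_equal(runs$perisomatic$classification, "inhibitory")
  expect_lt(runs$perisomatic$delta_mV, -1)
  # without the preceding train, GABA is classically inhibitory anywhere
  expect_equal(runs$no_hfs$classification, "inhibitory")
})

test_that("HFS collapses the membrane resistance, most severely distally", {
  m <- ca1_model()
  g <- m$geometry
  distal <- which(g$type == 4L & g$dist_um > 350)[1]
  prox <- which(g$type == 4L & g$dist_um > 180 & g$dist_um < 260 &
                  g$radius_um > 0.6)[1]
  rp_d <- probe_membrane_resistance(m, distal, activation = 0.8)
  w <- attr(rp_d, "hfs_window")
  during <- function(rp) rp$t_ms > w[1] + 100 & rp$t_ms < w[2]
  before <- function(rp) rp$t_ms + 10 < w[1]
  expect_equal(mean(rp_d$normalized[before(rp_d)]), 1, tolerance = 0.05)
  expect_lt(mean(rp_d$normalized[during(rp_d)]), 0.1)   # short-circuited
  rp_p <- probe_membrane_resistance(m, prox, activation = 0.8)
  expect_lt(mean(rp_p$normalized[during(rp_p)]), 0.15)  # ~5% of baseline
  expect_gt(mean(rp_p$normalized[during(rp_p)]),
            mean(rp_d$normalized[during(rp_d)]))
  # resistance recovers after the train
  after <- rp_d$t_ms > w[2] + 600
  expect_gt(mean(rp_d$normalized[after]), 0.5)
})

test_that("glutamate-evoked spiking is gated by HFS epoch", {
  m <- ca1_model()
  # no drive, no spikes
  silent <- spike_probability_run(m, "apical_proximal", trials = 3, seed = 2,
                                  with_hfs = FALSE, noise_sd_nA = 0,
                                  glut_gmax_nS = 0.001)
  expect_true(all(silent$p == 0))
  base <- spike_probability_run(m, "apical_proximal", trials = 8, seed = 3,
                                with_hfs = FALSE)
  expect_lt(mean(base$p), 0.5)   # subthreshold working point
  expect_gt(mean(base$p), 0.05)
  expect_true(all(base$lower <= base$p & base$p <= base$upper))
  hfs <- spike_probability_run(m, "apical_proximal", trials = 8, seed = 3,
                               with_hfs = TRUE)
  by_epoch <- tapply(hfs$p, hfs$epoch, mean)
  # apical input is silenced during the train and enhanced by the
  # depolarization that follows it
  expect_equal(unname(by_epoch["hfs_early"]), 0)
  expect_lt(by_epoch["hfs_late"], mean(base$p))
  expect_gt(by_epoch["post"], mean(base$p))
  # basal input is likewise silenced at train onset
  bas <- spike_probability_run(m, "basal", trials = 4, seed = 3,
                               with_hfs = TRUE, glut_gmax_nS = 2.3)
  expect_equal(unname(tapply(bas$p, bas$epoch, mean)["hfs_early"]), 0)
  expect_error(spike_probability_run(m, "basal", trials = 0), "trials")
})

test_that("the depolarization is robust except to GABA-A conductance itself", {
  m <- ca1_model()
  sweep <- sensitivity_sweep(m, parameters = c("gaba_conductance", "cl_i"),
                             factors = 0.5, post_ms = 800)
  ctrl <- sweep[sweep$parameter == "control", ]
  gaba <- sweep[sweep$parameter == "gaba_conductance", ]
  cl <- sweep[sweep$parameter == "cl_i", ]
  # halving GABA-A conductance drastically reduces the excitation
  expect_lt(gaba$peak_depol_mV, 0.5 * ctrl$peak_depol_mV)
  # halving initial chloride perturbs it far less
  expect_gt(cl$peak_depol_mV, gaba$peak_depol_mV)
  # a unit factor reproduces the control exactly
  ident <- sensitivity_sweep(m, parameters = "kcc2_density", factors = 1,
                             post_ms = 800)
  expect_equal(ident$peak_depol_mV[ident$parameter == "kcc2_density"],
               ident$peak_depol_mV[ident$parameter == "control"],
               tolerance = 1e-12)
  expect_error(sensitivity_sweep(m, parameters = "nonsense"), "unknown")
})
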