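test_that("passive step response matches the analytic RC solution", {
  g0 <- 5e-5
  m <- passive_single(g0)
  e_k <- nernst(3.5, 140, 1, 32)
  st <- initial_state(m, v_mV = e_k)
  amp <- 0.05  # nA
  pr <- ion_protocol(duration_ms = 120,
                     injections = data.frame(comp = 1, t0_ms = 10,
                                             t1_ms = 120, amp_nA = amp),
                     conc_dynamics = FALSE, record_dt_ms = 0.1)
  tr <- simulate(m, pr, state = st)
  area <- m$geometry$area_cm2
  r_mohm <- 1 / (g0 * area) * 1e-9   # ohms -> 1e3 MOhm? (mV per nA)
  dv_inf <- amp * 1e-9 / (g0 * area) * 1e3  # mV
  tau <- 1e-3 * 1 / g0               # ms (Cm = 1 uF/cm2)
  tt <- tr$time
  analytic <- e_k + ifelse(tt <= 10, 0, dv_inf * (1 - exp(-(tt - 10) / tau)))
  err <- max(abs(tr$v[, 1] - analytic)) / dv_inf
  expect_lt(err, 1e-3)
  # end of the trace sits on the analytic curve
  expect_equal(tr$v[length(tt), 1], analytic[length(tt)], tolerance = 1e-4)
})

test_that("the Hines tree solve equals the dense solve", {
  m <- branched_model()
  st <- initial_state(m)
  set.seed(3)
  st$v <- st$v + stats::runif(length(st$v), -15, 15)
  ref <- step_reference(m, st, dt = 0.02)
  pr <- ion_protocol(duration_ms = 0.02, record_dt_ms = 0.02)
  eng <- simulate(m, pr, state = st)
  expect_lt(max(abs(ref$state$v - eng$final_state$v)), 1e-12)
  expect_lt(max(abs(ref$state$conc - eng$final_state$conc)), 1e-12)
})

test_that("the compiled engine reproduces the composed module functions", {
  m <- branched_model()
  st <- initial_state(m)
  n <- nrow(m$geometry)
  tr_train <- transmitter_train(0.1)
  dt <- 0.02
  inj <- c(0.1, rep(0, n - 1))
  pr <- ion_protocol(duration_ms = 40 * dt, trains = list(tr_train),
                     train_targets = list(seq_len(n)), gaba_scale = 0.8,
                     injections = data.frame(comp = 1, t0_ms = 0, t1_ms = 1,
                                             amp_nA = 0.1),
                     record_dt_ms = 40 * dt)
  eng <- simulate(m, pr, state = st)
  stR <- st
  for (s in 1:40) {
    lig <- transmitter_concentration(tr_train, s * dt)
    stR <- step_reference(m, stR, dt, ligand_mM = lig, i_inj_nA = inj,
                          gaba_scale = 0.8)$state
  }
  fs <- eng$final_state
  expect_lt(max(abs(stR$v - fs$v)), 1e-10)
  expect_lt(max(abs(stR$conc - fs$conc)), 1e-10)
  expect_lt(max(abs(stR$gates - fs$gates)), 1e-12)
  expect_lt(max(abs(stR$na5 - fs$na5)), 1e-12)
  expect_lt(max(abs(stR$na6 - fs$na6)), 1e-12)
  expect_lt(max(abs(stR$gaba - fs$gaba)), 1e-12)
  expect_lt(max(abs(stR$y - fs$y)), 1e-12)
  expect_lt(max(abs(stR$kb - fs$kb)), 1e-12)
})

test_that("a frozen model with no stimulus is an exact fixed point", {
  m <- passive_single()
  m$calibration$gleak_k <- 0  # no conductances at all
  st <- initial_state(m, v_mV = -66)
  pr <- ion_protocol(duration_ms = 10, conc_dynamics = FALSE,
                     record_dt_ms = 1)
  tr <- simulate(m, pr, state = st)
  expect_lt(max(abs(tr$v - -66)), 1e-12)
})

test_that("the implicit voltage solve is stable at 50x the production step", {
  m <- ca1_model()
  pr <- ion_protocol(duration_ms = 500, na_scale = 0, conc_dynamics = FALSE,
                     record_dt_ms = 5)
  tr <- simulate(m, pr, dt_ms = 1)
  expect_true(all(is.finite(tr$v)))
  expect_true(all(tr$v > -120 & tr$v < 60))
})

test_that("halving the time step leaves the stimulus response unchanged", {
  pk <- dt_halving_peaks()
  expect_lt(abs(pk["coarse"] - pk["fine"]) / abs(pk["fine"]), 0.005)
})

test_that("axial current measurement matches hand arithmetic and conventions", {
  m <- branched_model()
  expect_equal(measure_axial_current(m, from = 2, to = 1, -60, -60), 0)
  gax <- m$g_axial[2]; a1 <- m$geometry$area_cm2[1]
  expect_equal(measure_axial_current(m, from = 2, to = 1, -50, -70),
               gax * (-70 - -50) / a1)
  # depolarizing current into the target carries a negative sign
  expect_lt(measure_axial_current(m, from = 2, to = 1, -50, -70), 0)
  expect_error(measure_axial_current(m, from = 3, to = 1, -50, -70),
               "not adjacent")
})

test_that("voltage clamp holds the command and reports near-zero current at rest", {
  m <- ca1_model()
  soma <- soma_of(m)
  tr <- voltage_clamp_run(m, times_ms = 0, values_mV = -66,
                          duration_ms = 200, record_dt_ms = 1)
  expect_lt(max(abs(tr$v[, soma] - -66)), 1e-9)
  expect_lt(max(abs(tr$clamp_i[-1, 1])), 0.02)  # nA

  # space-clamp failure: dendrites escape the command under strong conductance
  comps <- target_compartments(m, "apical")
  n <- nrow(m$geometry); sc <- rep(0, n); sc[comps] <- 0.8
  tr2 <- voltage_clamp_run(m, times_ms = 0, values_mV = -75,
                           duration_ms = 700,
                           trains = list(hfs_train(start_ms = 100)),
                           train_targets = list(comps), gaba_scale = sc,
                           na_scale = 0, record_dt_ms = 1)
  dend <- which(m$geometry$dist_um > 150 & m$geometry$type == 4L)
  during <- tr2$time > 200 & tr2$time < 500
  expect_lt(max(abs(tr2$v[during, soma] - -75)), 1e-9)
  expect_gt(max(abs(tr2$v[during, dend] - -75)), 3)
})

test_that("identical protocols with identical seeds are bit-reproducible", {
  m <- ca1_model()
  soma <- soma_of(m)
  pr <- ion_protocol(duration_ms = 150,
                     noise = data.frame(comp = soma, mean_nA = 0,
                                        sd_nA = 0.05),
                     record_dt_ms = 1)
  set.seed(99); a <- simulate(m, pr)
  set.seed(99); b <- simulate(m, pr)
  expect_identical(a$v, b$v)
  expect_identical(a$conc$cl_i, b$conc$cl_i)
  set.seed(100); c2 <- simulate(m, pr)
  expect_false(identical(a$v, c2$v))
})

test_that("trace sets expose series, spikes and writers", {
  m <- ca1_model()
  soma <- soma_of(m)
  pr <- ion_protocol(duration_ms = 400,
                     injections = data.frame(comp = soma, t0_ms = 50,
                                             t1_ms = 350, amp_nA = 0.3),
                     record_dt_ms = 0.5)
  tr <- simulate(m, pr)
  expect_s3_class(tr, "trace_set")
  expect_gt(nrow(tr$spikes), 0)
  d <- trace_series(tr, "v", comps = soma)
  expect_equal(nrow(d), length(tr$time))
  d2 <- trace_series(tr, "cl_i", comps = 1:2)
  expect_equal(nrow(d2), 2 * length(tr$time))
  path <- withr::local_tempfile(fileext = ".tsv")
  write_traces(tr, path)
  expect_true(file.exists(path))
  back <- utils::read.delim(path)
  expect_setequal(unique(back$series), c("v", "e_gaba"))
  # R-side spike detection agrees with the engine's counter
  st <- detect_spikes(tr$time, tr$v[, soma])
  expect_equal(length(st), sum(tr$spikes$comp == soma))
})
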