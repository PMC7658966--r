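test_that("flow profiles have the commanded shape and deliver the commanded volume", {
  cfg <- simulation_config(ramp_viscosity_coeff = 0, seed = 1L)
  ps <- injector_config("ps", "PS", 6, 10)
  p15 <- injection_protocol("p15", "Gadoterate", 15, 5, "vVol")

  # zero ramp: perfect rectangle; CM phase is exactly 3.0 s wide
  prof <- make_flow_profile(ps, p15, cfg)
  expect_true(all(prof$Q %in% c(0, 5)))
  cm_time <- sum((prof$c_in > 0) * prof$dt)
  expect_lt(abs(cm_time - 3), 2 * prof$dt)
  expect_lt(abs(sum(prof$Q * prof$c_in) * prof$dt - 15) / 15, 0.005)
  # total pumped volume = CM + line + flush
  expect_lt(abs(sum(prof$Q) * prof$dt - (15 + 6 + 25)), 0.05)

  # RP with zero pulsation equals the PS profile
  cfg0 <- simulation_config(pulsatility_amp = 0, seed = 1L)
  rp <- injector_config("rp", "RP", 6, 10)
  expect_equal(make_flow_profile(rp, p15, cfg0)$Q,
               make_flow_profile(ps, p15, cfg0)$Q)

  # delivered CM volume within 0.5% with ramps and pulsation
  cfg2 <- simulation_config(seed = 1L)
  p10 <- injection_protocol("p10", "Gadoterate", 10, 2.5, "cVol")
  for (inj in list(ps, injector_config("rp2", "RP", 80, 4))) {
    pr <- make_flow_profile(inj, p10, cfg2)
    expect_lt(abs(sum(pr$Q * pr$c_in) * pr$dt - 10) / 10, 0.005)
  }

  # underpowered configuration is rejected
  weak <- injector_config("weak", "PS", 6, max_pressure = 0.05)
  m2 <- injection_protocol("m2", "Gadoterate", 2, 5, "mVol")
  expect_error(make_flow_profile(weak, m2, simulation_config()), "underpowered")
})

test_that("single-tank washout follows the closed-form exponential", {
  # step input of saline-displacing contrast through one tank of volume V at
  # constant flow Q: outlet is 1 - exp(-Q t / V)
  cfg <- simulation_config(ramp_viscosity_coeff = 0, pulsatility_amp = 0, seed = 1L)
  V <- 8; Q <- 2
  inj <- injector_config("x", "PS", V, 10)
  # long injection so c_in stays 1 over the window we compare
  prot <- injection_protocol("p", "Gadoterate", 60, Q, "cVol",
                             injection_delay_s = 2, saline_flush_ml = 5)
  prof <- make_flow_profile(inj, prot, cfg)
  tr <- simulate_transport(prof, V, "Gadoterate", cfg, n_tanks = 1L)
  tp <- prof$time_s - prof$pump_start_s
  win <- tp > 0 & tp < 60 / Q
  expected <- 1 - exp(-Q * tp[win] / V)
  expect_lt(max(abs(tr$c_out[win] - expected)), 0.01)
})

test_that("transport conserves mass across random configurations", {
  set.seed(606)
  worst <- 0
  for (i in 1:50) {
    V <- runif(1, 2, 60)
    Q <- runif(1, 1, 5)
    vol <- runif(1, 2, 15)
    pump <- sample(c("PS", "RP"), 1)
    inj <- injector_config("x", pump, V, runif(1, 4, 10))
    prot <- injection_protocol("p", sample(c("Gadoterate", "Gadoteridol"), 1),
                               vol, Q, "vVol", injection_delay_s = 1,
                               saline_flush_ml = 25)
    cfg <- simulation_config(n_tanks_base = 300L, seed = i)
    prof <- make_flow_profile(inj, prot, cfg)
    tr <- simulate_transport(prof, V, prot$cm_type, cfg)
    # everything fed in is either past the outlet or still in the line
    expect_lt(abs(tr$mass_error), 0.01)
    expect_lt(abs(tr$delivered_ml - vol) / vol, 0.005)
    worst <- max(worst, abs(tr$mass_error))
  }
  expect_lt(worst, 0.01)
})

test_that("the zero-dispersion limit passes a boxcar through unchanged", {
  inj <- injector_config("x", "PS", line_volume_ml = 0.5, max_pressure = 50)
  prot <- injection_protocol("p", "Gadoterate", 10, 5, "vVol")
  cfg <- simulation_config(n_tanks_base = 60L, noise_sd = 1e-4,
                           ramp_viscosity_coeff = 0, seed = 1L)
  rec <- simulate_recording(inj, prot, cfg, seed = 12L)
  res <- score_recording(rec, prot)
  expect_gt(res$cbcf, 0.999)
})

test_that("sensor readout has the closed-form intensity and is deterministic", {
  cfg <- simulation_config(noise_sd = 0, epsilon_path = 1,
                           baseline_intensity = 100, seed = 1L)
  t <- seq(0, 12, by = 0.01)
  rec0 <- sensor_readout(t, rep(0, length(t)), cfg)
  expect_true(all(rec0$signal == 100))
  c1 <- rep(0, length(t)); c1[600:700] <- 1
  rec1 <- sensor_readout(t, c1, cfg)
  on_grid <- rec1$time_s >= t[610] & rec1$time_s <= t[690]
  expect_equal(unique(rec1$signal[on_grid]), 100 * exp(-1))

  cfgn <- simulation_config(noise_sd = 0.5, seed = 1L)
  ra <- sensor_readout(t, c1, cfgn, seed = 99L)
  rb <- sensor_readout(t, c1, cfgn, seed = 99L)
  expect_identical(ra$signal, rb$signal)

  expect_error(sensor_readout(t, c1 + 0.5, cfg), "concentration")
})

test_that("study generation is deterministic and enumeration-stable", {
  design <- tiny_design(days = 2L)
  cfg <- fast_config()
  recs1 <- generate_study(design, cfg)
  recs2 <- generate_study(design, cfg)
  expect_length(recs1, 2L * 2L * 2L)
  expect_identical(lapply(recs1, `[[`, "signal"), lapply(recs2, `[[`, "signal"))
  man <- attr(recs1, "manifest")
  expect_equal(nrow(man), 8L)
  expect_setequal(man$recording_id, vapply(recs1, `[[`, "", "recording_id"))

  # single-cell design gives one recording
  solo <- study_design(list(injector_config("a", "PS", 6, 10)),
                       list(injection_protocol("p", "Gadoterate", 5, 5, "vVol")),
                       days = 1L)
  expect_length(generate_study(solo, cfg), 1L)

  # adding a protocol never perturbs existing recordings
  bigger <- study_design(design$injectors,
                         c(design$protocols,
                           list(injection_protocol("extra", "Gadoteridol", 5, 5, "vVol"))),
                         days = 2L)
  recs3 <- generate_study(bigger, cfg)
  ids1 <- vapply(recs1, `[[`, "", "recording_id")
  ids3 <- vapply(recs3, `[[`, "", "recording_id")
  common <- intersect(ids1, ids3)
  expect_length(common, 8L)
  sig1 <- setNames(lapply(recs1, `[[`, "signal"), ids1)
  sig3 <- setNames(lapply(recs3, `[[`, "signal"), ids3)
  expect_identical(sig1[common], sig3[common])
})

test_that("mean cBCF falls strictly as line volume grows", {
  prot <- injection_protocol("p", "Gadoterate", 10, 5, "vVol")
  volumes <- c(5, 15, 35, 70, 110)
  means <- numeric(length(volumes))
  for (k in seq_along(volumes)) {
    vals <- numeric(20)
    for (r in 1:20) {
      inj <- injector_config("x", "PS", volumes[k], 10)
      cfg <- simulation_config(n_tanks_base = 300L, seed = 2000L + r)
      rec <- simulate_recording(inj, prot, cfg, seed = 7000L + 100L * k + r)
      vals[r] <- score_recording(rec, prot)$cbcf
    }
    means[k] <- mean(vals)
  }
  expect_true(all(diff(means) < 0))
})

test_that("viscosity protects the bolus: Gadoterate scores at least as well", {
  inj <- injector_config("x", "RP", 60, 6)
  means <- sapply(c("Gadoterate", "Gadoteridol"), function(cm) {
    prot <- injection_protocol("p", cm, 10, 5, "vVol")
    mean(sapply(1:10, function(r) {
      cfg <- simulation_config(n_tanks_base = 300L, seed = 3000L + r)
      score_recording(simulate_recording(inj, prot, cfg, seed = 400L + r),
                      prot)$cbcf
    }))
  })
  expect_gte(means[["Gadoterate"]], means[["Gadoteridol"]])
})
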