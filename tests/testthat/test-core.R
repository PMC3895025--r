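test_that("DMSPp tendency follows quota times carbon fluxes", {
  p <- sulfur_params()
  # zero record -> all zero
  z <- dmspp_tendency(list(mu_DA = 0, lysis_DA = 0), p)
  expect_true(all(unlist(z[-1]) == 0) && all(z$tendency == 0))
  # growth only: 0.00092 * 100 = 0.092 mmolS m^-3 h^-1
  r <- list(mu_OP = 100)
  expect_equal(dmspp_tendency(r, p)$tendency[["OP"]], 0.092,
               tolerance = 1e-12)
  # lysis split 10/90 between phyto lyase and DMSPd release
  r <- list(lysis_OP = 100)
  out <- dmspp_tendency(r, p)
  expect_equal(out$f1_phyto_lyase, 0.0092, tolerance = 1e-12)
  expect_equal(out$f2_lysis_release, 0.0828, tolerance = 1e-12)
  expect_equal(out$tendency[["OP"]], -0.092, tolerance = 1e-12)
  # grazing split by graz_to_DMS
  p2 <- sulfur_params(graz_to_DMS = 0.3)
  out <- dmspp_tendency(list(graz_DA = 10), p2)
  expect_equal(out$f3b_grazing_to_DMS, 0.3 * 0.000072 * 10, tolerance = 1e-15)
  expect_equal(out$f3_grazing_release, 0.7 * 0.000072 * 10, tolerance = 1e-15)
  expect_error(dmspp_tendency(list(mu_DA = -1), p), "non-negative")
})

test_that("bacterial carbon uptake is Michaelis-Menten", {
  expect_equal(bacterial_C_uptake(list(bmx = 0.2, BC = 50, SBC = 0,
                                       k_sbc = 25)), 0)
  # half-saturation identity
  expect_equal(bacterial_C_uptake(list(bmx = 0.2, BC = 50, SBC = 25,
                                       k_sbc = 25)), 0.2 * 50 / 2)
  # hand evaluation: 0.2*50*100/125 = 8
  expect_equal(bacterial_C_uptake(micro_record()), 8, tolerance = 1e-12)
  expect_error(bacterial_C_uptake(list(bmx = 0.2, BC = 50, SBC = 10,
                                       k_sbc = 0)), "k_sbc")
})

test_that("DMSPd uptake, S need and the partition match hand arithmetic", {
  p <- sulfur_params()
  r <- micro_record()
  expect_equal(dmspd_uptake(r, p, sulfur_state(DMSPd = 0)), 0)
  # 1 * 8 * 0.1/100 = 0.008
  expect_equal(dmspd_uptake(r, p, sulfur_state(DMSPd = 0.1)), 0.008,
               tolerance = 1e-12)
  p5 <- sulfur_params(ratio_S_DMSPd = 0.5)
  expect_equal(dmspd_uptake(r, p5, sulfur_state(DMSPd = 0.1)), 0.004,
               tolerance = 1e-12)
  # Sneed = (0.3*8/12)*0.01 = 0.002 (0.2 mmolC of growth per hour times
  # the 0.01 molS:molC bacterial quota)
  expect_equal(s_need(r, p), 2e-3, tolerance = 1e-12)
  expect_equal(s_need(r, sulfur_params(SC_BC = 0.02)), 4e-3,
               tolerance = 1e-12)
  r0 <- r; r0$SBC <- 0
  expect_equal(s_need(r0, p), 0)

  # partition: f5 = 0.0002, residual 0.0098 split 10/90
  out <- partition_dmspd(0.01, 2e-4, p)
  expect_equal(out$f5_S_assimilation, 2e-4, tolerance = 1e-15)
  expect_equal(out$f7_bact_lyase, 0.00098, tolerance = 1e-15)
  expect_equal(out$f6_demethylation, 0.00882, tolerance = 1e-15)
  expect_equal(out$S_deficit, 0)
  # limitation branch: uptake < Sneed shuts the bacterial lyase off
  out <- partition_dmspd(1e-4, 2e-4, p)
  expect_equal(out$f5_S_assimilation, 1e-4)
  expect_equal(out$f6_demethylation, 0)
  expect_equal(out$f7_bact_lyase, 0)
  expect_equal(out$S_deficit, 1e-4)
  # lyase_Bact = 0 -> no cleavage for any uptake
  out <- partition_dmspd(0.01, 2e-4, sulfur_params(lyase_Bact = 0))
  expect_equal(out$f7_bact_lyase, 0)
})

test_that("DMS uptake includes the deficit top-up and respects the cap", {
  p <- sulfur_params()
  r <- micro_record()
  expect_equal(dms_uptake(r, p, sulfur_state(DMS = 0)), 0)
  # 1 * 8 * 0.02/100 = 0.0016
  expect_equal(dms_uptake(r, p, sulfur_state(DMS = 0.02)), 0.0016,
               tolerance = 1e-12)
  expect_equal(dms_uptake(r, sulfur_params(ratio_S_DMS = 0.5),
                          sulfur_state(DMS = 0.02)), 8e-4, tolerance = 1e-12)
  # top-up adds the deficit
  expect_equal(dms_uptake(r, p, sulfur_state(DMS = 0.02), S_deficit = 1e-4),
               0.0017, tolerance = 1e-12)
  # pool cap: uptake * dt <= DMS
  expect_equal(dms_uptake(r, p, sulfur_state(DMS = 0.02), S_deficit = 1,
                          dt = 0.25), 0.02 / 0.25, tolerance = 1e-12)
})

test_that("photooxidation is depth-attenuated first-order loss", {
  p <- sulfur_params()
  expect_equal(photooxidation(micro_record(), p, sulfur_state(DMS = 0)), 0)
  # hand evaluation: 0.09*(1-exp(-8.5))/8.5*0.02
  expect_equal(photooxidation(micro_record(), p, sulfur_state(DMS = 0.02)),
               0.09 * (1 - exp(-8.5)) / 8.5 * 0.02, tolerance = 1e-15)
  # kD*H -> 0 limit approaches the surface rate K0*DMS
  r <- micro_record(); r$kD_m1 <- 1e-9; r$depth_m <- 1
  expect_equal(photooxidation(r, p, sulfur_state(DMS = 0.02)), 0.09 * 0.02,
               tolerance = 1e-6)
  r$kD_m1 <- 0
  expect_error(photooxidation(r, p, sulfur_state(DMS = 0.02)), "positive")
})

test_that("one Euler step matches an independent spreadsheet-style oracle", {
  p <- sulfur_params()
  r <- micro_record()
  dt <- 0.25
  st <- sulfur_state(DMSPp_DA = 0.0072, DMSPp_NF = 0.046, DMSPp_OP = 0.92,
                     DMSPd = 0.1, DMS = 0.02)
  got <- step_euler(st, r, p, dt)

  # oracle: literal re-derivation with plain arithmetic
  SC <- c(0.000072, 0.00092, 0.00092)
  mu <- c(1, 0.5, 100); lys <- c(0.5, 0.2, 100)
  grz <- c(0.3, 0.1, 0); sed <- c(0.2, 0, 2)
  f1 <- sum(0.1 * SC * lys); f2 <- sum(0.9 * SC * lys)
  f3 <- sum(SC * grz); f4 <- sum(SC * sed)
  P2 <- unclass(st)[1:3] + dt * SC * (mu - lys - grz - sed)
  uc <- 0.2 * 50 * 100 / 125
  sneed <- 0.3 * uc / 12 * 0.01
  U <- min(1 * uc * 0.1 / 100, 0.1 / dt)
  f5 <- min(U, sneed); f7 <- 0.1 * (U - f5); f6 <- 0.9 * (U - f5)
  d2 <- 0.1 + dt * (f2 + f3 - U)
  f8 <- 1 * uc * 0.02 / 100
  sc_dms <- 2674.0 - 147.12 * 10 + 3.726 * 100 - 0.038 * 1000
  kk <- (0.048495620150019972 * 5 + 0.34387841998134477 * 25 -
           0.015093299269392584 * 125) * (sc_dms / 600)^(-0.5) / 100
  f9 <- kk * 0.02 / 17
  f10 <- 0.09 * (1 - exp(-8.5)) / 8.5 * 0.02
  m2 <- 0.02 + dt * (f1 + f7 - f8 - f9 - f10)

  expect_equal(unclass(got$state),
               c(DMSPp_DA = P2[[1]], DMSPp_NF = P2[[2]], DMSPp_OP = P2[[3]],
                 DMSPd = d2, DMS = m2), tolerance = 1e-12)
  led <- got$ledger
  expect_equal(unname(led[c("f1_phyto_lyase", "f2_lysis_release",
                            "f3_grazing_release", "f4_sedimentation",
                            "f5_S_assimilation", "f6_demethylation",
                            "f7_bact_lyase", "f8_DMS_bact_uptake",
                            "f9_emission", "f10_photooxidation")]),
               c(f1, f2, f3, f4, f5, f6, f7, f8, f9, f10), tolerance = 1e-12)
})

test_that("step_euler trivial cases and guards", {
  p <- sulfur_params()
  r <- micro_record()
  for (cn in c("mu_DA", "mu_NF", "mu_OP", "lysis_DA", "lysis_NF", "lysis_OP",
               "graz_DA", "graz_NF", "graz_OP", "sed_DA", "sed_OP", "BC"))
    r[[cn]] <- 0
  out <- step_euler(sulfur_state(), r, p, 0.25)
  expect_true(all(unclass(out$state) == 0))
  expect_true(all(out$ledger == 0))
  expect_error(step_euler(sulfur_state(), r, p, 0), "dt")
  r$u10_ms <- NaN
  expect_error(step_euler(sulfur_state(), r, p, 0.25), "NaN")
})

test_that("no DMS source keeps DMS exactly zero over a full run", {
  f <- cached_forcing(dt = 2, seed = 1)
  p <- sulfur_params(y_DMS_DA = 0, y_DMS_NF = 0, y_DMS_OP = 0,
                     lyase_Bact = 0, graz_to_DMS = 0)
  sim <- run_simulation(f, p)
  expect_true(all(sim$states$DMS == 0))
})

test_that("DMSPp is exactly linear in the quotas", {
  f <- cached_forcing(dt = 2, seed = 1)
  p1 <- sulfur_params()
  p2 <- sulfur_params(SC_DA = 2 * p1$SC_DA, SC_NF = 2 * p1$SC_NF,
                      SC_OP = 2 * p1$SC_OP)
  s1 <- run_simulation(f, p1)
  s2 <- run_simulation(f, p2)
  for (cn in c("DMSPp_DA", "DMSPp_NF", "DMSPp_OP"))
    expect_equal(s2$states[[cn]], 2 * s1$states[[cn]], tolerance = 1e-12)
})

test_that("simulation invariants: non-negativity, conservation, S-rule", {
  f <- cached_forcing(dt = 2, seed = 4)
  sim <- run_simulation(f, sulfur_params(graz_to_DMS = 0.3))
  expect_true(all(as.matrix(sim$states) >= 0))
  expect_true(all(as.matrix(sim$ledger) >= 0))
  led <- sim$ledger
  # per-step sulfur conservation
  tot <- rowSums(sim$states)
  prod <- led$prod_DA + led$prod_NF + led$prod_OP
  outs <- led$f4_sedimentation + led$f5_S_assimilation +
    led$f6_demethylation + led$f8_DMS_bact_uptake + led$f9_emission +
    led$f10_photooxidation
  resid <- diff(tot) + sim$dt * outs - sim$dt * prod
  expect_lt(max(abs(resid)) / max(tot), 1e-10)
  # bacterial lyase shut off whenever the S need exceeds the DMSPd uptake
  expect_true(all(led$f7_bact_lyase[led$Sneed > led$dmspd_uptake + 1e-15] == 0))
})

test_that("default run reproduces the seasonal timing structure", {
  f <- cached_forcing(dt = 2, seed = 1)
  sim <- run_simulation(f, sulfur_params())
  t_pp <- sim$time[which.max(rowSums(sim$states[, 1:3]))]
  t_dd <- sim$time[which.max(sim$states$DMSPd)]
  t_ms <- sim$time[which.max(sim$states$DMS)]
  expect_gt(t_dd, t_pp)             # dissolved peak lags particulate peak
  expect_gt((t_dd - t_pp) / 24, 3)  # by several days
  expect_gt(t_ms, t_pp)             # DMS maximum in between
  expect_lt(t_ms, t_dd)
})

test_that("quota-equivalence oracle: DMSPp_n stays SC_n * B_n", {
  f <- cached_forcing(dt = 2, seed = 1)
  p <- sulfur_params()
  sim <- run_simulation(f, p)  # default init is quota equilibrium
  for (ft in c("DA", "NF", "OP")) {
    ref <- p[[paste0("SC_", ft)]] * f[[paste0("B_", ft)]]
    expect_lt(max(abs(sim$states[[paste0("DMSPp_", ft)]] - ref)) / max(ref),
              1e-9)
  }
})
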