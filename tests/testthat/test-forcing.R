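test_that("zero-biomass scenario yields identically zero plankton fluxes", {
  f <- generate_forcing(zero_bloom_specs(), environment_spec(), dt = 6,
                        seed = 1)
  for (cn in c("B_DA", "B_NF", "B_OP", "mu_DA", "mu_NF", "mu_OP",
               "lysis_DA", "lysis_NF", "lysis_OP", "graz_DA", "graz_NF",
               "graz_OP", "sed_DA", "sed_OP"))
    expect_true(all(f[[cn]] == 0), label = cn)
})

test_that("default scenario hits the stated bloom amplitudes", {
  f <- cached_forcing(dt = 0.25, seed = 1)
  expect_equal(max(f$B_OP), 1600, tolerance = 1e-6)
  chl <- forcing_chl(f)
  expect_equal(max(chl$chl_total), 25, tolerance = 0.1)  # ~25 mg Chl m^-3
  expect_equal(nrow(validate_forcing(f)), 0)
})

test_that("generated series close the discrete carbon balance exactly", {
  f <- cached_forcing(dt = 2, seed = 5)
  n <- nrow(f)
  dt <- diff(f$time_h)
  for (ft in c("DA", "NF", "OP")) {
    B <- f[[paste0("B_", ft)]]
    sed <- if (ft == "NF") 0 else f[[paste0("sed_", ft)]]
    net <- f[[paste0("mu_", ft)]] - f[[paste0("lysis_", ft)]] -
      f[[paste0("graz_", ft)]] - sed
    expect_lt(max(abs(diff(B) / dt - net[-n])), 1e-9)
    expect_true(all(f[[paste0("mu_", ft)]] >= 0))
  }
})

test_that("structural zeros and bacterial lag hold for all t", {
  f <- cached_forcing(dt = 2, seed = 1)
  expect_true(all(f$graz_OP == 0))
  expect_false("sed_NF" %in% names(f))
  # bacterial maximum trails the Phaeocystis biomass maximum
  expect_gt(f$time_h[which.max(f$BC)], f$time_h[which.max(f$B_OP)])
  # lysis flux peaks after the biomass peak (descending-limb ramp)
  expect_gt(f$time_h[which.max(f$lysis_OP)], f$time_h[which.max(f$B_OP)])
})

test_that("seed determinism and seed sensitivity", {
  a <- generate_forcing(default_bloom_specs(), environment_spec(), dt = 6,
                        seed = 11)
  b <- generate_forcing(default_bloom_specs(), environment_spec(), dt = 6,
                        seed = 11)
  expect_identical(as.data.frame(a), as.data.frame(b))
  c <- generate_forcing(default_bloom_specs(), environment_spec(), dt = 6,
                        seed = 12)
  expect_false(identical(a$u10_ms, c$u10_ms))
})

test_that("wind statistics match the stated climate over 10 seeds", {
  springs <- exceed <- numeric(10)
  for (s in 1:10) {
    f <- cached_forcing(dt = 6, seed = s)
    doy <- f$time_h / 24 + 1
    springs[s] <- mean(f$u10_ms[doy >= 91 & doy <= 151])  # Apr-May
    exceed[s] <- mean(f$u10_ms > 8)
  }
  expect_lt(abs(mean(springs) - 3.3), 0.5)
  expect_lt(mean(exceed), 0.06)
  expect_true(all(vapply(1:10, function(s) all(cached_forcing(6, s)$u10_ms >= 0),
                         TRUE)))
})

test_that("CSV round trip is lossless and validation errors are named", {
  f <- cached_forcing(dt = 6, seed = 2)
  path <- tempfile(fileext = ".csv")
  on.exit(unlink(path))
  write_forcing(f, path)
  g <- read_forcing(path)
  expect_identical(lapply(as.data.frame(g), c), lapply(as.data.frame(f), c))

  # missing mandatory column is reported by name
  x <- data.table::fread(path)
  x$u10_ms <- NULL
  data.table::fwrite(x, path)
  expect_error(read_forcing(path), "u10_ms")

  # NaN biomass is reported with its row index
  write_forcing(f, path)
  x <- data.table::fread(path)
  x$B_OP[17] <- NaN
  data.table::fwrite(x, path)
  expect_error(read_forcing(path), "B_OP at row 17")

  # non-monotone time
  write_forcing(f, path)
  x <- data.table::fread(path)
  x$time_h[3] <- x$time_h[2]
  data.table::fwrite(x, path)
  expect_error(read_forcing(path), "time_h")
})

test_that("validate_forcing reports injected violations at the right place", {
  f <- cached_forcing(dt = 6, seed = 1)
  expect_equal(nrow(validate_forcing(f)), 0)

  g <- f
  g$graz_OP[100] <- 1
  rep1 <- validate_forcing(g)
  expect_true(any(rep1$field == "graz_OP" & rep1$row == 100))

  # hand-constructed carbon imbalance at one step
  h <- f
  h$mu_DA[50] <- h$mu_DA[50] + 1
  rep2 <- validate_forcing(h)
  bal <- rep2[grepl("balance", rep2$message), ]
  expect_equal(nrow(bal), 1)
  expect_equal(bal$row, 50)
  expect_equal(bal$field, "B_DA")
})

test_that("bloom_spec rejects structural-zero violations", {
  expect_error(bloom_spec("OP", 115, 1600, 9,
                          loss_partition = c(lysis = 0.8, grazing = 0.1,
                                             sedimentation = 0.1)),
               "not grazed")
  expect_error(bloom_spec("NF", 150, 150, 15,
                          loss_partition = c(lysis = 0.8, grazing = 0.1,
                                             sedimentation = 0.1)),
               "do not sediment")
  expect_error(generate_forcing(default_bloom_specs(), environment_spec(),
                                dt = -1), "dt")
  expect_error(generate_forcing(list(), environment_spec()), "non-empty")
})
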