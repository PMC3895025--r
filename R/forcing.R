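#' Bloom specification
#'
#' One Gaussian biomass pulse for a phytoplankton functional type (FT).
#' Several specs may share an `ft`; their pulses are summed. The loss
#' partition routes the total carbon loss of the FT to lysis, grazing and
#' sedimentation, and must respect the structural zeros of the community:
#' Phaeocystis colonies (`OP`) are not grazed, and nanoflagellates (`NF`)
#' do not sediment.
#'
#' @param ft `"DA"` (diatoms), `"NF"` (nanoflagellates) or `"OP"`
#'   (Phaeocystis colonies).
#' @param peak_day day of year of the biomass maximum.
#' @param peak_biomass biomass at the peak (mgC m^-3).
#' @param width Gaussian sigma of the pulse, in days.
#' @param baseline background biomass (mgC m^-3), `<= peak_biomass`.
#' @param loss_partition named fractions `c(lysis=, grazing=, sedimentation=)`
#'   summing to 1.
#' @return An object of class `bloom_spec`.
#' @export
bloom_spec <- function(ft, peak_day, peak_biomass, width, baseline = 0,
                       loss_partition = c(lysis = 1, grazing = 0,
                                          sedimentation = 0)) {
  ft <- match.arg(ft, FT_IDS)
  lp <- loss_partition[c("lysis", "grazing", "sedimentation")]
  if (anyNA(lp)) stop("loss_partition needs lysis, grazing, sedimentation")
  if (any(lp < 0) || any(lp > 1) || abs(sum(lp) - 1) > 1e-10)
    stop("loss_partition fractions must lie in [0,1] and sum to 1")
  if (ft == "OP" && lp[["grazing"]] > 0)
    stop("structural zero violated: Phaeocystis colonies (OP) are not grazed")
  if (ft == "NF" && lp[["sedimentation"]] > 0)
    stop("structural zero violated: nanoflagellates (NF) do not sediment")
  if (peak_biomass < baseline || baseline < 0)
    stop("need peak_biomass >= baseline >= 0")
  if (width <= 0) stop("width must be positive (days)")
  structure(list(ft = ft, peak_day = peak_day, peak_biomass = peak_biomass,
                 width = width, baseline = baseline, loss_partition = lp),
            class = "bloom_spec")
}

#' Environment specification
#'
#' Physical forcing of the box: depth, seasonal temperature and irradiance
#' sinusoids, light extinction, an autocorrelated daily wind model, constant
#' bacterial substrate parameters, and per-FT C:Chl ratios used only for
#' diagnostics and the empirical algorithms.
#'
#' Wind: daily values follow an AR(1) process around a seasonal mean
#' `wind_mean0 + wind_mean_amp * cos(2*pi*(doy - wind_phase_day)/365)` with a
#' seasonal standard deviation of the same phase, truncated at zero and
#' linearly interpolated to the model grid. The defaults give a spring
#' (Apr-May) mean of 3.3 m s^-1 with sd ~1.7, higher winter winds, and
#' < 6 % of hourly values above 8 m s^-1.
#'
#' @param H box depth (m).
#' @param temp_mean,temp_amp,temp_min_day annual mean and amplitude (degC)
#'   and day-of-year of minimum temperature.
#' @param J_mean,J_amp,J_min_day daily-mean surface irradiance sinusoid
#'   (W m^-2) and day of minimum.
#' @param diel logical; superimpose a truncated-cosine diel cycle on
#'   irradiance (daily means preserved).
#' @param kD light extinction coefficient (m^-1).
#' @param wind_mean0,wind_mean_amp,wind_phase_day,wind_sd0,wind_sd_amp,wind_ar1
#'   wind model parameters (see Details).
#' @param c_chl named per-FT carbon:chlorophyll ratios (mgC : mgChl).
#' @param BC_baseline,BC_gain,BC_tau_h,exud_frac bacterial biomass response:
#'   baseline (mgC m^-3) plus `BC_gain` (h) times an exponential moving
#'   average (time constant `BC_tau_h`, h) of the substrate-release flux
#'   `exud_frac * total biomass + total lysis` (mgC m^-3 h^-1). The
#'   exudation term makes bacterial maxima sit at the decline of each bloom
#'   and relax afterwards, rather than weeks later.
#' @param SBC,bmx,k_sbc,y_BC monomeric substrate concentration (mgC m^-3),
#'   maximal bacterial specific growth (h^-1), substrate half-saturation
#'   (mgC m^-3), bacterial growth efficiency (0-1).
#' @return An object of class `environment_spec`.
#' @export
environment_spec <- function(H = 17,
                             temp_mean = 11, temp_amp = 6, temp_min_day = 46,
                             J_mean = 120, J_amp = 95, J_min_day = 355,
                             diel = TRUE, kD = 0.5,
                             wind_mean0 = 3.65, wind_mean_amp = 1.5,
                             wind_phase_day = 15,
                             wind_sd0 = 1.7, wind_sd_amp = 0.4,
                             wind_ar1 = 0.7,
                             c_chl = c(DA = 64, NF = 64, OP = 64),
                             BC_baseline = 30, BC_gain = 2, BC_tau_h = 60,
                             exud_frac = 0.01,
                             SBC = 15, bmx = 0.05, k_sbc = 25, y_BC = 0.3) {
  if (H <= 0) stop("H must be positive")
  if (kD <= 0) stop("kD must be positive")
  if (y_BC <= 0 || y_BC >= 1) stop("y_BC must lie in (0, 1)")
  if (k_sbc <= 0) stop("k_sbc must be positive")
  if (anyNA(c_chl[FT_IDS]) || any(c_chl[FT_IDS] <= 0))
    stop("c_chl must give positive ratios for DA, NF, OP")
  structure(list(H = H, temp_mean = temp_mean, temp_amp = temp_amp,
                 temp_min_day = temp_min_day, J_mean = J_mean, J_amp = J_amp,
                 J_min_day = J_min_day, diel = isTRUE(diel), kD = kD,
                 wind_mean0 = wind_mean0, wind_mean_amp = wind_mean_amp,
                 wind_phase_day = wind_phase_day, wind_sd0 = wind_sd0,
                 wind_sd_amp = wind_sd_amp, wind_ar1 = wind_ar1,
                 c_chl = c_chl[FT_IDS], BC_baseline = BC_baseline,
                 BC_gain = BC_gain, BC_tau_h = BC_tau_h,
                 exud_frac = exud_frac, SBC = SBC,
                 bmx = bmx, k_sbc = k_sbc, y_BC = y_BC),
            class = "environment_spec")
}

#' Default coastal bloom scenario
#'
#' The reference synthetic scenario: a spring diatom bloom, a short intense
#' Phaeocystis colony bloom peaking at 1600 mgC m^-3 (~25 mg Chl a m^-3
#' total at C:Chl = 64), a nanoflagellate bloom, and a broader summer diatom
#' bloom.
#'
#' @return List of [bloom_spec()] objects.
#' @export
default_bloom_specs <- function() {
  list(
    bloom_spec("DA", peak_day = 75, peak_biomass = 400, width = 10,
               baseline = 10,
               loss_partition = c(lysis = 0.5, grazing = 0.3,
                                  sedimentation = 0.2)),
    bloom_spec("OP", peak_day = 115, peak_biomass = 1600, width = 9,
               baseline = 5,
               loss_partition = c(lysis = 0.9, grazing = 0,
                                  sedimentation = 0.1)),
    bloom_spec("NF", peak_day = 150, peak_biomass = 150, width = 15,
               baseline = 10,
               loss_partition = c(lysis = 0.6, grazing = 0.4,
                                  sedimentation = 0)),
    bloom_spec("DA", peak_day = 200, peak_biomass = 300, width = 20,
               baseline = 10,
               loss_partition = c(lysis = 0.5, grazing = 0.3,
                                  sedimentation = 0.2))
  )
}

# Run fn with a private RNG stream; global .Random.seed is untouched.
with_local_seed <- function(seed, fn) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  fn()
}

forcing_flux_cols <- function() {
  c(paste0("mu_", FT_IDS), paste0("lysis_", FT_IDS), paste0("graz_", FT_IDS),
    "sed_DA", "sed_OP")
}

forcing_schema <- function() {
  c("time_h", paste0("B_", FT_IDS), forcing_flux_cols(),
    "BC", "SBC", "bmx", "k_sbc", "y_BC",
    "T_degC", "u10_ms", "J_Wm2", "kD_m1", "depth_m")
}

#' Generate a synthetic forcing series
#'
#' Builds an internally consistent full-year forcing time series from bloom
#' and environment specifications. Biomass trajectories are sums of baseline
#' plus Gaussian pulses; growth and loss fluxes are derived so the discrete
#' carbon balance closes exactly: for every interior step,
#' `(B[i+1]-B[i])/dt == mu[i] - lysis[i] - graz[i] - sed[i]`.
#' The specific loss rate of each pulse ramps from 10 % to 90 % of the
#' pulse's intrinsic rate (1/sigma) across the descending limb, so lysis
#' peaks after the biomass peak and the dissolved-DMSP maximum lags the
#' particulate one. Bacterial biomass is a lagged smoothed response to the
#' the substrate-release flux, exudation plus lysis (maxima at the decline
#' of each bloom).
#'
#' @param bloom_specs list of [bloom_spec()] objects (non-empty).
#' @param env an [environment_spec()].
#' @param dt time step in hours (> 0; the year must be a whole number of
#'   steps).
#' @param seed integer seed for the wind series (all other terms are
#'   deterministic).
#' @param days length of the year in days (default 365).
#' @return A `forcing_series`: a data.frame with the columns of
#'   [forcing_schema()] and attributes `dt` and `days`. Rows are grid points
#'   `0, dt, ..., days*24`; flux columns in row `i` apply over
#'   `[t_i, t_i + dt)` (the final row repeats the penultimate fluxes and is
#'   not integrated).
#' @export
#' @examples
#' f <- generate_forcing(default_bloom_specs(), environment_spec(),
#'                       dt = 6, seed = 1)
#' max(f$B_OP)
generate_forcing <- function(bloom_specs, env = environment_spec(),
                             dt = 0.25, seed = 1, days = 365) {
  if (!length(bloom_specs)) stop("bloom_specs must be non-empty")
  if (!inherits(env, "environment_spec")) stop("env must be an environment_spec")
  if (!is.numeric(dt) || dt <= 0) stop("dt must be a positive number of hours")
  hours <- days * 24
  n_step <- hours / dt
  if (abs(n_step - round(n_step)) > 1e-9)
    stop("the year must be a whole number of steps")
  n_step <- round(n_step)
  t_h <- seq(0, hours, by = dt)
  np <- n_step + 1L
  doy <- t_h / 24 + 1

  out <- data.frame(time_h = t_h)

  # --- biomass: baseline + Gaussian pulses; loss-rate ramp per pulse -------
  for (ft in FT_IDS) {
    specs <- Filter(function(s) s$ft == ft, bloom_specs)
    B <- numeric(np)
    pulses <- list()
    rates <- list()
    base <- 0
    if (length(specs)) {
      base <- max(vapply(specs, function(s) s$baseline, 0))
      for (s in specs) {
        sigma_h <- s$width * 24
        tp_h <- (s$peak_day - 1) * 24
        amp <- s$peak_biomass - s$baseline
        pulses[[length(pulses) + 1]] <- amp * exp(-0.5 * ((t_h - tp_h) / sigma_h)^2)
        g <- 1 / sigma_h  # intrinsic specific rate of the pulse (h^-1)
        ramp <- pmin(pmax((t_h - tp_h) / (2 * sigma_h), 0), 1)
        rates[[length(rates) + 1]] <- g * (0.1 + 0.8 * ramp)
      }
      B <- base + Reduce(`+`, pulses)
    }
    # pulse-weighted specific loss rate
    if (length(pulses)) {
      wsum <- Reduce(`+`, lapply(pulses, function(p) p + 1e-12))
      lnum <- Reduce(`+`, Map(function(p, r) (p + 1e-12) * r, pulses, rates))
      l <- lnum / wsum
    } else l <- numeric(np)

    dB <- c(diff(B) / dt, 0)
    L <- pmax(l * B, -dB, 0)
    mu <- dB + L
    # final row has no interval: repeat previous fluxes
    if (np > 1) { L[np] <- L[np - 1]; mu[np] <- mu[np - 1] }

    lp <- if (length(specs)) specs[[1]]$loss_partition else
      c(lysis = 1, grazing = 0, sedimentation = 0)
    out[[paste0("B_", ft)]] <- B
    out[[paste0("mu_", ft)]] <- mu
    out[[paste0("lysis_", ft)]] <- lp[["lysis"]] * L
    out[[paste0("graz_", ft)]] <- lp[["grazing"]] * L
    if (ft != "NF") out[[paste0("sed_", ft)]] <- lp[["sedimentation"]] * L
  }
  out$graz_OP <- rep(0, np)  # structural zero, kept as explicit column

  # --- bacteria: lagged response to substrate release ----------------------
  # exudation (proportional to standing biomass) + lysis products; the EMA
  # lag puts bacterial maxima at the decline of each bloom
  TL <- out$lysis_DA + out$lysis_NF + out$lysis_OP +
    env$exud_frac * (out$B_DA + out$B_NF + out$B_OP)
  e <- numeric(np)
  a <- dt / env$BC_tau_h
  for (i in seq_len(np - 1L)) e[i + 1L] <- e[i] + a * (TL[i] - e[i])
  out$BC <- env$BC_baseline + env$BC_gain * e
  out$SBC <- rep(env$SBC, np)
  out$bmx <- rep(env$bmx, np)
  out$k_sbc <- rep(env$k_sbc, np)
  out$y_BC <- rep(env$y_BC, np)

  # --- physics -------------------------------------------------------------
  out$T_degC <- env$temp_mean -
    env$temp_amp * cos(2 * pi * (doy - env$temp_min_day) / days)
  Jd <- env$J_mean - env$J_amp * cos(2 * pi * (doy - env$J_min_day) / days)
  Jd <- pmax(Jd, 0)
  if (env$diel) {
    hod <- t_h %% 24
    out$J_Wm2 <- Jd * pi * pmax(0, cos(2 * pi * (hod - 12) / 24))
  } else out$J_Wm2 <- Jd

  # --- wind: AR(1) daily values, interpolated to the grid ------------------
  nd <- days + 1L
  dd <- seq_len(nd)
  m_d <- env$wind_mean0 +
    env$wind_mean_amp * cos(2 * pi * (dd - env$wind_phase_day) / days)
  s_d <- env$wind_sd0 +
    env$wind_sd_amp * cos(2 * pi * (dd - env$wind_phase_day) / days)
  x <- with_local_seed(seed, function() {
    eps <- rnorm(nd, 0, sqrt(1 - env$wind_ar1^2))
    z <- numeric(nd)
    z[1] <- rnorm(1)
    for (i in 2:nd) z[i] <- env$wind_ar1 * z[i - 1] + eps[i]
    z
  })
  u_d <- pmax(m_d + s_d * x, 0)
  out$u10_ms <- approx((dd - 1) * 24, u_d, xout = t_h)$y

  out$kD_m1 <- rep(env$kD, np)
  out$depth_m <- rep(env$H, np)

  out <- out[, forcing_schema()]
  attr(out, "dt") <- dt
  attr(out, "days") <- days
  attr(out, "c_chl") <- env$c_chl
  class(out) <- c("forcing_series", "data.frame")
  out
}

#' Write / read a forcing series (CSV)
#'
#' Plain CSV with the exact column set of [forcing_schema()]. Doubles are
#' written with shortest round-trip precision, so `read_forcing(write_forcing(x))`
#' reproduces `x` bit for bit. The structurally zero columns `graz_OP` and
#' `sed_NF` may be absent on read (`sed_NF` never exists; a missing `graz_OP`
#' is filled with zeros).
#'
#' @param series a `forcing_series`.
#' @param path file path.
#' @return `write_forcing` returns `path` invisibly; `read_forcing` returns a
#'   validated `forcing_series`.
#' @export
write_forcing <- function(series, path) {
  stopifnot(inherits(series, "forcing_series"))
  df <- as.data.frame(series)
  # %.17g guarantees exact double round trip (fwrite's default 15
  # significant digits does not)
  chr <- as.data.frame(lapply(df, function(col) sprintf("%.17g", col)))
  names(chr) <- names(df)
  data.table::fwrite(chr, path, quote = FALSE)
  invisible(path)
}

#' @rdname write_forcing
#' @export
read_forcing <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  x <- data.table::setDF(data.table::fread(path, colClasses = "double"))
  need <- setdiff(forcing_schema(), "graz_OP")
  missing <- setdiff(need, names(x))
  if (length(missing))
    stop("forcing file is missing mandatory column(s): ",
         paste(missing, collapse = ", "))
  if (!"graz_OP" %in% names(x)) x$graz_OP <- 0
  extra <- setdiff(names(x), forcing_schema())
  if (length(extra))
    stop("forcing file has unknown column(s): ", paste(extra, collapse = ", "))
  x <- x[, forcing_schema()]
  if (is.unsorted(x$time_h, strictly = TRUE))
    stop("column time_h must be strictly increasing")
  for (b in paste0("B_", FT_IDS)) {
    bad <- which(!is.finite(x[[b]]))
    if (length(bad))
      stop("non-finite biomass in column ", b, " at row ", bad[1])
    bad <- which(x[[b]] < 0)
    if (length(bad))
      stop("negative biomass in column ", b, " at row ", bad[1])
  }
  dts <- diff(x$time_h)
  if (length(dts) && diff(range(dts)) > 1e-8 * dts[1])
    stop("time_h must lie on a regular grid")
  attr(x, "dt") <- if (length(dts)) dts[1] else NA_real_
  attr(x, "days") <- (max(x$time_h) - min(x$time_h)) / 24
  class(x) <- c("forcing_series", "data.frame")
  x
}

#' Validate a forcing series
#'
#' Report-based invariant checking: non-negativity of biomasses and fluxes,
#' structural zeros (`graz_OP`, and absence of NF sedimentation), bacterial
#' growth efficiency in (0, 1), positive depth and extinction, and discrete
#' carbon closure `|dB/dt - (mu - lysis - graz - sed)| <= tol` at every
#' interior grid point.
#'
#' @param series a `forcing_series`.
#' @param tol carbon-closure tolerance (mgC m^-3 h^-1).
#' @return A data.frame (class `forcing_validation`) with one row per
#'   violation: `row`, `field`, `message`. Zero rows means the series
#'   satisfies every invariant.
#' @export
validate_forcing <- function(series, tol = 1e-9) {
  stopifnot(inherits(series, "forcing_series"))
  if (!nrow(series)) stop("series is empty")
  rep_rows <- list()
  add <- function(row, field, msg)
    rep_rows[[length(rep_rows) + 1]] <<- data.frame(row = row, field = field,
                                                    message = msg)
  nonneg <- c(paste0("B_", FT_IDS), forcing_flux_cols(), "BC", "SBC", "u10_ms",
              "J_Wm2")
  for (cn in nonneg) {
    bad <- which(!is.finite(series[[cn]]) | series[[cn]] < 0)
    for (r in bad) add(r, cn, "negative or non-finite value")
  }
  bad <- which(series$graz_OP > 0)
  for (r in bad) add(r, "graz_OP", "structural zero violated: OP is not grazed")
  bad <- which(series$y_BC <= 0 | series$y_BC >= 1)
  for (r in bad) add(r, "y_BC", "bacterial growth efficiency outside (0,1)")
  bad <- which(series$depth_m <= 0)
  for (r in bad) add(r, "depth_m", "non-positive depth")
  bad <- which(series$kD_m1 <= 0)
  for (r in bad) add(r, "kD_m1", "non-positive extinction coefficient")

  n <- nrow(series)
  if (n > 1) {
    dt <- diff(series$time_h)
    for (ft in FT_IDS) {
      B <- series[[paste0("B_", ft)]]
      sed <- if (ft == "NF") 0 else series[[paste0("sed_", ft)]]
      net <- series[[paste0("mu_", ft)]] - series[[paste0("lysis_", ft)]] -
        series[[paste0("graz_", ft)]] - sed
      resid <- abs(diff(B) / dt - net[-n])
      bad <- which(resid > tol)
      for (r in bad)
        add(r, paste0("B_", ft),
            sprintf("carbon balance residual %.3e exceeds tolerance", resid[r]))
    }
  }
  out <- if (length(rep_rows)) do.call(rbind, rep_rows) else
    data.frame(row = integer(), field = character(), message = character())
  class(out) <- c("forcing_validation", "data.frame")
  out
}

#' Total chlorophyll a of a forcing series
#'
#' Converts per-FT carbon biomass to chlorophyll with the C:Chl ratios of the
#' generating [environment_spec()] (stored on the series; defaults used when
#' absent, e.g. after a CSV round trip).
#'
#' @param series a `forcing_series`.
#' @param c_chl optional named C:Chl vector overriding the stored one.
#' @return Data frame with per-FT and total Chl a (mg m^-3).
#' @export
forcing_chl <- function(series, c_chl = NULL) {
  cc <- c_chl %||% attr(series, "c_chl") %||% environment_spec()$c_chl
  out <- data.frame(time_h = series$time_h)
  for (ft in FT_IDS)
    out[[paste0("chl_", ft)]] <- series[[paste0("B_", ft)]] / cc[[ft]]
  out$chl_total <- out$chl_DA + out$chl_NF + out$chl_OP
  out
}

`%||%` <- function(a, b) if (is.null(a)) b else a
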