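#' @title DMS(P) kinetics
#' @description
#' The elementary process rates of the sulfur module. All fluxes are in
#' mmolS m^-3 h^-1 and are evaluated on beginning-of-step quantities
#' (fully explicit scheme). A `record` is one row of a `forcing_series`
#' (or an equivalent named list).
#' @name kinetics
NULL

as_record <- function(record) {
  r <- as.list(record)
  if (is.null(r$time_h)) r$time_h <- 0
  r
}

ft_par <- function(params, prefix) {
  vapply(FT_IDS, function(ft) params[[paste0(prefix, ft)]], 0)
}

#' Particulate DMSP tendency and release fluxes
#'
#' For each functional type n, dDMSPp_n/dt = SC_n (mu_n - lysis_n -
#' grazing_n - sed_n): production follows growth, and all carbon losses
#' export sulfur in proportion to the fixed quota. The release fluxes are
#' split as: a fraction `y_DMS_n` of the lysis release is cleaved directly
#' to DMS by phytoplankton DMSP-lyase (f1), the rest becomes DMSPd (f2);
#' grazed DMSPp becomes DMSPd (f3) except the optional fraction
#' `graz_to_DMS` routed straight to DMS (f3b); sedimented DMSPp leaves the
#' box (f4).
#'
#' @param record one forcing record (named list or single data.frame row).
#' @param params a [sulfur_params()].
#' @return List with `tendency` (named per-FT, mmolS m^-3 h^-1) and the
#'   ledger contributions `f1_phyto_lyase`, `f2_lysis_release`,
#'   `f3_grazing_release`, `f3b_grazing_to_DMS`, `f4_sedimentation`, and
#'   per-FT `production`.
#' @export
#' @examples
#' r <- list(mu_OP = 100, lysis_OP = 0, graz_OP = 0, sed_OP = 0)
#' dmspp_tendency(r, sulfur_params())$tendency[["OP"]]
dmspp_tendency <- function(record, params) {
  r <- as_record(record)
  SC <- ft_par(params, "SC_")
  y <- ft_par(params, "y_DMS_")
  g2d <- params$graz_to_DMS
  mu <- lys <- grz <- sed <- numeric(3)
  names(mu) <- FT_IDS
  for (i in seq_along(FT_IDS)) {
    ft <- FT_IDS[i]
    mu[i]  <- r[[paste0("mu_", ft)]]    %||% 0
    lys[i] <- r[[paste0("lysis_", ft)]] %||% 0
    grz[i] <- r[[paste0("graz_", ft)]]  %||% 0
    sed[i] <- r[[paste0("sed_", ft)]]   %||% 0
  }
  v <- c(mu, lys, grz, sed)
  if (anyNA(v) || any(v < 0)) stop("forcing fluxes must be non-negative")
  tend <- SC * (mu - lys - grz - sed)
  names(tend) <- FT_IDS
  list(tendency = tend,
       production = SC * mu,
       f1_phyto_lyase = sum(y * SC * lys),
       f2_lysis_release = sum((1 - y) * SC * lys),
       f3_grazing_release = (1 - g2d) * sum(SC * grz),
       f3b_grazing_to_DMS = g2d * sum(SC * grz),
       f4_sedimentation = sum(SC * sed))
}

#' Bacterial carbon uptake
#'
#' Michaelis-Menten consumption of monomeric substrates:
#' uptake_C = bmx * BC * SBC / (SBC + k_sbc), in mgC m^-3 h^-1.
#'
#' @inheritParams dmspp_tendency
#' @return Carbon uptake (mgC m^-3 h^-1).
#' @export
#' @examples
#' bacterial_C_uptake(list(bmx = 0.2, BC = 50, SBC = 100, k_sbc = 25))
bacterial_C_uptake <- function(record) {
  r <- as_record(record)
  if (r$k_sbc <= 0) stop("k_sbc must be positive")
  if (r$SBC < 0) stop("SBC must be non-negative")
  r$bmx * r$BC * r$SBC / (r$SBC + r$k_sbc)
}

#' Bacterial DMSPd uptake
#'
#' Carbon uptake scaled by the DMSPd : substrate stoichiometry and the
#' fraction of the community using DMSPd:
#' uptake = ratio_S_DMSPd * uptake_C * DMSPd / SBC. When `dt` is given the
#' rate is capped so no more than the standing DMSPd pool can be consumed
#' within one step.
#'
#' @inheritParams dmspp_tendency
#' @param state a [sulfur_state()].
#' @param dt optional step length (h) for the pool cap.
#' @return DMSPd uptake (mmolS m^-3 h^-1).
#' @export
dmspd_uptake <- function(record, params, state, dt = NULL) {
  r <- as_record(record)
  d <- state[["DMSPd"]]
  if (d <= 0 || r$SBC <= 0) return(0)
  u <- params$ratio_S_DMSPd * bacterial_C_uptake(r) * d / r$SBC
  if (!is.null(dt)) u <- min(u, d / dt)
  u
}

#' Bacterial sulfur need
#'
#' S required to sustain bacterial growth:
#' Sneed = (y_BC * uptake_C / 12) * SC_BC, converting mgC to mmolC with
#' 12 mgC per mmolC.
#'
#' @inheritParams dmspd_uptake
#' @return Sneed (mmolS m^-3 h^-1).
#' @export
#' @examples
#' s_need(list(bmx = 0.2, BC = 50, SBC = 100, k_sbc = 25, y_BC = 0.3),
#'        sulfur_params())
s_need <- function(record, params) {
  r <- as_record(record)
  if (r$y_BC <= 0 || r$y_BC >= 1) stop("y_BC must lie in (0, 1)")
  (r$y_BC * bacterial_C_uptake(r) / MGC_PER_MMOLC) * params$SC_BC
}

#' Partition of consumed DMSPd
#'
#' Bacteria first assimilate what they need (f5 = min(uptake, Sneed)); of
#' the residual, a fraction `lyase_Bact` is cleaved to DMS (f7) and the rest
#' demethylated to MeSH/sulfate (f6). When the uptake cannot cover the S
#' need, the bacterial lyase is shut off (f7 = 0) and the shortfall is
#' returned as `S_deficit`, to be covered from DMS.
#'
#' @param uptake DMSPd uptake (mmolS m^-3 h^-1).
#' @param Sneed bacterial S need (mmolS m^-3 h^-1).
#' @param params a [sulfur_params()].
#' @return List with `f5_S_assimilation`, `f6_demethylation`,
#'   `f7_bact_lyase`, `S_deficit`.
#' @export
#' @examples
#' partition_dmspd(0.01, 0.0002, sulfur_params())
partition_dmspd <- function(uptake, Sneed, params) {
  if (uptake < 0 || Sneed < 0) stop("uptake and Sneed must be non-negative")
  f5 <- min(uptake, Sneed)
  resid <- uptake - f5
  deficit <- max(Sneed - uptake, 0)
  if (deficit > 0) {
    f7 <- 0
    f6 <- resid  # zero by construction
  } else {
    f7 <- params$lyase_Bact * resid
    f6 <- (1 - params$lyase_Bact) * resid
  }
  list(f5_S_assimilation = f5, f6_demethylation = f6, f7_bact_lyase = f7,
       S_deficit = deficit)
}

#' Bacterial DMS uptake
#'
#' Base consumption proportional to carbon uptake and the DMS : substrate
#' ratio, ratio_S_DMS * uptake_C * DMS / SBC, plus a top-up drawn from DMS
#' to cover any unmet bacterial S need; the total is capped at the standing
#' DMS pool per step when `dt` is given.
#'
#' @inheritParams dmspd_uptake
#' @param S_deficit unmet S need from [partition_dmspd()].
#' @return DMS uptake f8 (mmolS m^-3 h^-1).
#' @export
dms_uptake <- function(record, params, state, S_deficit = 0, dt = NULL) {
  r <- as_record(record)
  dms <- state[["DMS"]]
  if (dms <= 0) return(0)
  base <- if (r$SBC > 0)
    params$ratio_S_DMS * bacterial_C_uptake(r) * dms / r$SBC else 0
  f8 <- base + S_deficit
  if (!is.null(dt)) f8 <- min(f8, dms / dt)
  f8
}

#' DMS photooxidation
#'
#' Depth-averaged first-order photolysis to DMSO. The surface rate `K0`
#' attenuates with light down the box, giving the column-mean factor
#' (1 - exp(-kD H)) / (kD H):
#' f10 = K0 * (1 - exp(-kD H)) / (kD H) * DMS.
#' With `params$photolysis_diel`, the rate additionally scales with the
#' instantaneous irradiance relative to its daily mean (off by default).
#'
#' @inheritParams dmspd_uptake
#' @return Photooxidation flux f10 (mmolS m^-3 h^-1).
#' @export
#' @examples
#' photooxidation(list(kD_m1 = 0.5, depth_m = 17), sulfur_params(),
#'                sulfur_state(DMS = 0.02))
photooxidation <- function(record, params, state) {
  r <- as_record(record)
  kD <- r$kD_m1 %||% r$kD
  H <- r$depth_m %||% r$H
  if (kD <= 0 || H <= 0) stop("kD and H must be positive")
  rate <- params$K0 * (1 - exp(-kD * H)) / (kD * H)
  if (params$photolysis_diel && !is.null(r$J_Wm2) && !is.null(r$J_daily_mean))
    rate <- rate * if (r$J_daily_mean > 0) r$J_Wm2 / r$J_daily_mean else 0
  rate * state[["DMS"]]
}

# One explicit Euler step on precomputed scalar inputs. Returns the new
# state followed by the (post-limiting) ledger entries. The same routine
# backs step_euler() and the run_simulation() inner loop.
#
# prodS/lysS/grzS/sedS: per-FT sulfur fluxes SC_n * {mu,lysis,graz,sed}_n.
.step_core <- function(state, prodS, lysS, grzS, sedS, y, g2d, lyase,
                       uc, sneed, upd_rate, dms_rate, photo_rate, emis_rate,
                       dt) {
  P <- state[1:3]; DMSPd <- state[4]; DMS <- state[5]

  # DMSPp sinks, proportionally limited per FT
  sinks <- lysS + grzS + sedS
  avail <- P + dt * prodS
  scale <- ifelse(dt * sinks > avail & sinks > 0, avail / (dt * sinks), 1)
  lysS <- lysS * scale; grzS <- grzS * scale; sedS <- sedS * scale
  f1 <- sum(y * lysS)
  f2 <- sum((1 - y) * lysS)
  f3 <- (1 - g2d) * sum(grzS)
  f3b <- g2d * sum(grzS)
  f4 <- sum(sedS)
  P2 <- P + dt * (prodS - lysS - grzS - sedS)

  # DMSPd uptake and partition
  U <- min(upd_rate * DMSPd, DMSPd / dt)
  f5 <- min(U, sneed)
  resid <- U - f5
  deficit <- max(sneed - U, 0)
  if (deficit > 0) { f7 <- 0; f6 <- resid } else {
    f7 <- lyase * resid; f6 <- (1 - lyase) * resid
  }
  DMSPd2 <- DMSPd + dt * (f2 + f3 - U)

  # DMS sinks: bacterial uptake (with S-deficit top-up), emission,
  # photooxidation; proportional limiter keeps the pool non-negative
  f8 <- min(dms_rate * DMS + deficit, DMS / dt)
  f9 <- emis_rate * DMS
  f10 <- photo_rate * DMS
  src <- f1 + f3b + f7
  snk <- f8 + f9 + f10
  if (dt * snk > DMS + dt * src && snk > 0) {
    sc <- (DMS + dt * src) / (dt * snk)
    f8 <- f8 * sc; f9 <- f9 * sc; f10 <- f10 * sc
  }
  unmet <- max(deficit - f8, 0)
  DMS2 <- DMS + dt * (src - f8 - f9 - f10)

  c(P2, DMSPd2, DMS2,
    f1, f2, f3, f3b, f4, f5, f6, f7, f8, f9, f10,
    sneed, uc, U, unmet, prodS)
}

ledger_names <- function() {
  c("f1_phyto_lyase", "f2_lysis_release", "f3_grazing_release",
    "f3b_grazing_to_DMS", "f4_sedimentation", "f5_S_assimilation",
    "f6_demethylation", "f7_bact_lyase", "f8_DMS_bact_uptake",
    "f9_emission", "f10_photooxidation", "Sneed", "uptake_C",
    "dmspd_uptake", "S_unmet", "prod_DA", "prod_NF", "prod_OP")
}

#' One explicit Euler step
#'
#' Advances the five sulfur pools over `dt` hours with all fluxes evaluated
#' on the beginning-of-step state, then proportionally limited so no pool is
#' overdrawn. The returned ledger records the post-limiting fluxes, so the
#' per-step sulfur balance closes exactly.
#'
#' @inheritParams dmspd_uptake
#' @param state a [sulfur_state()].
#' @param dt step length (h), > 0.
#' @return List with `state` (the updated [sulfur_state()]) and `ledger`
#'   (named numeric vector of fluxes, mmolS m^-3 h^-1, plus diagnostics
#'   `Sneed`, `uptake_C`, `dmspd_uptake`, `S_unmet` and per-FT production).
#' @export
step_euler <- function(state, record, params, dt) {
  if (!is.numeric(dt) || dt <= 0) stop("dt must be positive")
  r <- as_record(record)
  if (anyNA(unlist(r[intersect(names(r), forcing_schema())])))
    stop("NaN/NA in forcing record")
  pt <- dmspp_tendency(r, params)
  SC <- ft_par(params, "SC_")
  lysS <- SC * vapply(FT_IDS, function(ft) r[[paste0("lysis_", ft)]] %||% 0, 0)
  grzS <- SC * vapply(FT_IDS, function(ft) r[[paste0("graz_", ft)]] %||% 0, 0)
  sedS <- SC * vapply(FT_IDS, function(ft) r[[paste0("sed_", ft)]] %||% 0, 0)
  uc <- bacterial_C_uptake(r)
  sneed <- s_need(r, params)
  upd_rate <- if (r$SBC > 0) params$ratio_S_DMSPd * uc / r$SBC else 0
  dms_rate <- if (r$SBC > 0) params$ratio_S_DMS * uc / r$SBC else 0
  kD <- r$kD_m1 %||% r$kD; H <- r$depth_m %||% r$H
  photo_rate <- params$K0 * (1 - exp(-kD * H)) / (kD * H)
  emis_rate <- k_dms(r$u10_ms %||% 0, r$T_degC %||% 10, params$k_method) / H
  out <- .step_core(unclass(state), pt$production, lysS, grzS, sedS,
                    ft_par(params, "y_DMS_"), params$graz_to_DMS,
                    params$lyase_Bact, uc, sneed, upd_rate, dms_rate,
                    photo_rate, emis_rate, dt)
  st <- sulfur_state(out[1], out[2], out[3], out[4], out[5])
  led <- out[-(1:5)]
  names(led) <- ledger_names()
  list(state = st, ledger = led)
}

#' Run the box simulation
#'
#' Integrates the sulfur pools over a forcing series with the explicit Euler
#' scheme, one step per forcing interval, and collects the complete per-step
#' flux ledger.
#'
#' @param forcing a `forcing_series` (see [generate_forcing()] /
#'   [read_forcing()]).
#' @param params a [sulfur_params()].
#' @param init initial [sulfur_state()]. The default starts the particulate
#'   pools at quota equilibrium (SC_n * B_n(0)) and the dissolved pools at
#'   zero.
#' @return A `dms_simulation`: list with `time` (h, length n), `states`
#'   (data.frame, n rows: pools at each grid point), `ledger` (data.frame,
#'   n-1 rows: fluxes over each interval), `dt`, `H`, and `params`.
#' @export
#' @examples
#' f <- generate_forcing(default_bloom_specs(), environment_spec(),
#'                       dt = 6, seed = 1)
#' sim <- run_simulation(f, sulfur_params())
#' max(sim$states$DMS)
run_simulation <- function(forcing, params = sulfur_params(), init = NULL) {
  stopifnot(inherits(forcing, "forcing_series"))
  n <- nrow(forcing)
  if (n < 2) stop("forcing must cover at least one step")
  dt <- forcing$time_h[2] - forcing$time_h[1]
  if (is.null(init)) {
    SC <- ft_par(params, "SC_")
    init <- sulfur_state(SC[1] * forcing$B_DA[1], SC[2] * forcing$B_NF[1],
                         SC[3] * forcing$B_OP[1])
  }
  if (anyNA(as.data.frame(forcing))) stop("NaN/NA in forcing")

  SC <- ft_par(params, "SC_")
  y <- ft_par(params, "y_DMS_")
  prodS <- cbind(SC[1] * forcing$mu_DA, SC[2] * forcing$mu_NF,
                 SC[3] * forcing$mu_OP)
  lysS <- cbind(SC[1] * forcing$lysis_DA, SC[2] * forcing$lysis_NF,
                SC[3] * forcing$lysis_OP)
  grzS <- cbind(SC[1] * forcing$graz_DA, SC[2] * forcing$graz_NF,
                SC[3] * forcing$graz_OP)
  sedS <- cbind(SC[1] * forcing$sed_DA, 0 * forcing$sed_DA,
                SC[3] * forcing$sed_OP)
  uc <- forcing$bmx * forcing$BC * forcing$SBC / (forcing$SBC + forcing$k_sbc)
  sneed <- (forcing$y_BC * uc / MGC_PER_MMOLC) * params$SC_BC
  upd_rate <- ifelse(forcing$SBC > 0, params$ratio_S_DMSPd * uc / forcing$SBC, 0)
  dms_rate <- ifelse(forcing$SBC > 0, params$ratio_S_DMS * uc / forcing$SBC, 0)
  photo_rate <- params$K0 *
    (1 - exp(-forcing$kD_m1 * forcing$depth_m)) /
    (forcing$kD_m1 * forcing$depth_m)
  emis_rate <- k_dms(forcing$u10_ms, forcing$T_degC, params$k_method) /
    forcing$depth_m

  states <- matrix(0, n, 5)
  colnames(states) <- c("DMSPp_DA", "DMSPp_NF", "DMSPp_OP", "DMSPd", "DMS")
  ledger <- matrix(0, n - 1, length(ledger_names()))
  colnames(ledger) <- ledger_names()
  st <- unclass(init)
  states[1, ] <- st
  g2d <- params$graz_to_DMS; lyb <- params$lyase_Bact
  for (i in seq_len(n - 1)) {
    out <- .step_core(st, prodS[i, ], lysS[i, ], grzS[i, ], sedS[i, ],
                      y, g2d, lyb, uc[i], sneed[i], upd_rate[i], dms_rate[i],
                      photo_rate[i], emis_rate[i], dt)
    st <- out[1:5]
    if (anyNA(st) || any(st < -1e-12))
      stop("numerical failure: negative or NaN pool at step ", i)
    states[i + 1, ] <- st
    ledger[i, ] <- out[-(1:5)]
  }
  structure(list(time = forcing$time_h, states = as.data.frame(states),
                 ledger = as.data.frame(ledger), dt = dt,
                 H = forcing$depth_m[1], params = params),
            class = "dms_simulation")
}

#' @export
print.dms_simulation <- function(x, ...) {
  cat("<dms_simulation>", length(x$time), "grid points, dt =", x$dt, "h\n")
  cat("  peak DMSPp:", format(max(rowSums(x$states[, 1:3])), digits = 4),
      "mmolS m^-3\n")
  cat("  peak DMSPd:", format(max(x$states$DMSPd), digits = 4),
      " peak DMS:", format(max(x$states$DMS), digits = 4), "\n")
  invisible(x)
}
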