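#' Annual areal sulfur budget
#'
#' Integrates a simulation flux ledger over a full year and scales by the
#' box depth, giving areal fluxes in mmolS m^-2 y^-1, together with pool
#' storage changes and closure residuals of the particulate-DMSP and DMS
#' balances.
#'
#' @param sim a `dms_simulation` from [run_simulation()], covering at least
#'   one full year, or a ledger data.frame (then `dt`, `H` and `states` must
#'   be supplied).
#' @param dt,H,states overrides when `sim` is a bare ledger.
#' @return A `budget_table`: list with `fluxes` (named areal integrals),
#'   `storage` (pool changes over the year), `shares` (see
#'   [compute_shares()]) and `closure` (relative residuals of the DMSPp and
#'   DMS balances).
#' @export
#' @examples
#' f <- generate_forcing(default_bloom_specs(), environment_spec(),
#'                       dt = 6, seed = 1)
#' b <- integrate_budget(run_simulation(f, sulfur_params()))
#' b$shares$dms_sinks
integrate_budget <- function(sim, dt = NULL, H = NULL, states = NULL) {
  if (inherits(sim, "dms_simulation")) {
    ledger <- sim$ledger; dt <- sim$dt; H <- sim$H; states <- sim$states
    hours <- sim$time[length(sim$time)] - sim$time[1]
  } else {
    ledger <- sim
    if (is.null(dt) || is.null(H)) stop("dt and H required for a bare ledger")
    hours <- nrow(ledger) * dt
  }
  if (hours < 365 * 24 - 1e-6)
    stop("budget requires a horizon of at least one year (got ",
         round(hours / 24, 1), " days)")
  tot <- function(col) sum(ledger[[col]]) * dt * H
  fluxes <- c(
    production_DA = tot("prod_DA"), production_NF = tot("prod_NF"),
    production_OP = tot("prod_OP"),
    production_total = tot("prod_DA") + tot("prod_NF") + tot("prod_OP"),
    phyto_lyase = tot("f1_phyto_lyase"),
    lysis_release = tot("f2_lysis_release"),
    grazing_release = tot("f3_grazing_release"),
    grazing_to_DMS = tot("f3b_grazing_to_DMS"),
    sedimentation = tot("f4_sedimentation"),
    S_assimilation = tot("f5_S_assimilation"),
    demethylation = tot("f6_demethylation"),
    bact_lyase = tot("f7_bact_lyase"),
    DMS_bact_uptake = tot("f8_DMS_bact_uptake"),
    emission = tot("f9_emission"),
    photooxidation = tot("f10_photooxidation"))
  storage <- NULL
  closure <- NULL
  if (!is.null(states)) {
    n <- nrow(states)
    dPp <- sum(states[n, 1:3] - states[1, 1:3]) * H
    dDd <- (states$DMSPd[n] - states$DMSPd[1]) * H
    dDMS <- (states$DMS[n] - states$DMS[1]) * H
    storage <- c(dDMSPp = dPp, dDMSPd = dDd, dDMS = dDMS)
    rel <- function(resid, scale) if (scale > 0) abs(resid) / scale else abs(resid)
    closure <- c(
      DMSPp = rel(fluxes[["production_total"]] - dPp -
                    fluxes[["phyto_lyase"]] - fluxes[["lysis_release"]] -
                    fluxes[["grazing_release"]] - fluxes[["grazing_to_DMS"]] -
                    fluxes[["sedimentation"]],
                  fluxes[["production_total"]]),
      DMS = rel(fluxes[["phyto_lyase"]] + fluxes[["grazing_to_DMS"]] +
                  fluxes[["bact_lyase"]] - dDMS -
                  fluxes[["DMS_bact_uptake"]] - fluxes[["emission"]] -
                  fluxes[["photooxidation"]],
                fluxes[["phyto_lyase"]] + fluxes[["grazing_to_DMS"]] +
                  fluxes[["bact_lyase"]]))
  }
  structure(list(fluxes = fluxes, storage = storage,
                 shares = compute_shares(fluxes), closure = closure),
            class = "budget_table")
}

#' Percentage shares of the sulfur budget
#'
#' Derives the headline percentages from a set of annual areal fluxes:
#' per-FT shares of total DMSPp production; the fate of consumed DMSPd
#' (assimilation / demethylation / bacterial cleavage); the fate of the
#' gross DMS production (bacterial uptake / photooxidation / emission); and
#' emission as a share of DMSPp production. Shares are reported rounded to
#' the nearest integer percent (and exactly, under `$exact`).
#'
#' The input may be a full [integrate_budget()] flux vector or a partial
#' named list, e.g. printed literature values. Accepted names:
#' `phyto_lyase`, `bact_lyase`, `DMS_bact_uptake`, `emission`,
#' `photooxidation`, `S_assimilation`, `demethylation`, `grazing_to_DMS`,
#' `production_DA/NF/OP/total`. A missing `photooxidation` is defined as the
#' residual of the gross DMS production after bacterial uptake and emission.
#'
#' @param fluxes named numeric vector or list of fluxes (mmolS m^-2 y^-1).
#' @return List of named percent vectors: `ft_production`, `dmspd_fate`,
#'   `dms_sinks`, `emission_of_production`; unrounded values in `$exact`.
#'   Shares whose denominator is zero are returned as `NA` and flagged.
#' @export
#' @examples
#' # printed worked example: DMS sinks 83 / 14 / 3 %
#' compute_shares(list(phyto_lyase = 3.2, bact_lyase = 3.2,
#'                     DMS_bact_uptake = 5.3, emission = 0.19))$dms_sinks
compute_shares <- function(fluxes) {
  f <- as.list(fluxes)
  g <- function(nm) if (!is.null(f[[nm]])) f[[nm]] else NA_real_
  pct <- function(x, den) if (!is.na(den) && den > 0) 100 * x / den else NA_real_

  exact <- list()

  prod_tot <- g("production_total")
  if (is.na(prod_tot)) {
    p <- c(g("production_DA"), g("production_NF"), g("production_OP"))
    if (!anyNA(p)) prod_tot <- sum(p)
  }
  ftp <- c(DA = pct(g("production_DA"), prod_tot),
           NF = pct(g("production_NF"), prod_tot),
           OP = pct(g("production_OP"), prod_tot))
  exact$ft_production <- ftp

  upt <- c(g("S_assimilation"), g("demethylation"), g("bact_lyase"))
  if (!anyNA(upt)) {
    den <- sum(upt)
    exact$dmspd_fate <- c(assimilation = pct(upt[1], den),
                          demethylation = pct(upt[2], den),
                          cleavage = pct(upt[3], den))
  }

  gross <- sum(g("phyto_lyase"), g("bact_lyase"),
               if (!is.na(g("grazing_to_DMS"))) g("grazing_to_DMS") else 0)
  photo <- g("photooxidation")
  if (is.na(photo) && !is.na(gross) && !anyNA(c(g("DMS_bact_uptake"),
                                                g("emission"))))
    photo <- gross - g("DMS_bact_uptake") - g("emission")  # residual closure
  exact$dms_sinks <- c(bacterial_uptake = pct(g("DMS_bact_uptake"), gross),
                       photooxidation = pct(photo, gross),
                       emission = pct(g("emission"), gross))

  exact$emission_of_production <- pct(g("emission"), prod_tot)

  out <- lapply(exact, function(v) if (is.numeric(v)) round(v) else v)
  out$exact <- exact
  out$undefined <- names(Filter(function(v) anyNA(v), exact))
  out
}

#' @export
print.budget_table <- function(x, ...) {
  cat("<budget_table> annual areal fluxes (mmolS m^-2 y^-1)\n")
  print(round(x$fluxes, 3))
  if (!is.null(x$closure))
    cat("closure residuals (relative): DMSPp",
        format(x$closure[["DMSPp"]], digits = 3), " DMS",
        format(x$closure[["DMS"]], digits = 3), "\n")
  invisible(x)
}
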