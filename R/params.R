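#' Sulfur-cycle parameter set
#'
#' Builds the parameter list driving the DMS(P) kinetics. Defaults are the
#' reference values of the coastal application this package reproduces:
#' fixed phytoplankton S:C quotas per functional type (FT), a bacterial S:C
#' quota, phytoplankton DMSP-lyase yields, the bacterial cleavage fraction of
#' non-assimilated dissolved DMSP (DMSPd), the surface photooxidation rate,
#' and the fractions of the bacterial community using DMSPd / DMS as a sulfur
#' source.
#'
#' Units: phytoplankton quotas `SC_DA`, `SC_NF`, `SC_OP` are mmolS per mgC
#' (the molar S:C ratio divided by 12 gC molC^-1); `SC_BC` is molS:molC;
#' `K0` is h^-1; all yields and fractions are dimensionless in \[0, 1\].
#'
#' @param SC_DA,SC_NF,SC_OP phytoplankton S:C quotas (mmolS mgC^-1).
#' @param SC_BC bacterial S:C quota (molS:molC).
#' @param y_DMS_DA,y_DMS_NF,y_DMS_OP fraction of DMSPp released by lysis that
#'   is cleaved directly to DMS by phytoplankton DMSP-lyase.
#' @param lyase_Bact fraction of bacterially consumed, non-assimilated DMSPd
#'   cleaved to DMS (the remainder is demethylated).
#' @param K0 sea-surface DMS photooxidation rate (h^-1).
#' @param ratio_S_DMSPd,ratio_S_DMS fraction of the bacterial community using
#'   DMSPd (resp. DMS) as substrate.
#' @param graz_to_DMS fraction of grazed DMSPp routed directly to DMS
#'   (0 in the reference run; 0.3 in the grazing-conversion variant).
#' @param k_method gas-transfer-velocity parameterization, `"yang"` or
#'   `"nightingale"`.
#' @param photolysis_diel if `TRUE`, scale photooxidation by the instantaneous
#'   irradiance relative to its daily mean (off by default; the reference
#'   formulation uses depth attenuation only).
#'
#' @return An object of class `sulfur_params` (a named list).
#' @export
#' @examples
#' p <- sulfur_params()
#' p$SC_OP * 12   # molar S:C of Phaeocystis, 0.011 molS:molC
sulfur_params <- function(SC_DA = 0.000072, SC_NF = 0.00092, SC_OP = 0.00092,
                          SC_BC = 0.01,
                          y_DMS_DA = 0.1, y_DMS_NF = 0.1, y_DMS_OP = 0.1,
                          lyase_Bact = 0.1, K0 = 0.09,
                          ratio_S_DMSPd = 1, ratio_S_DMS = 1,
                          graz_to_DMS = 0,
                          k_method = c("yang", "nightingale"),
                          photolysis_diel = FALSE) {
  k_method <- match.arg(k_method)
  p <- list(SC_DA = SC_DA, SC_NF = SC_NF, SC_OP = SC_OP, SC_BC = SC_BC,
            y_DMS_DA = y_DMS_DA, y_DMS_NF = y_DMS_NF, y_DMS_OP = y_DMS_OP,
            lyase_Bact = lyase_Bact, K0 = K0,
            ratio_S_DMSPd = ratio_S_DMSPd, ratio_S_DMS = ratio_S_DMS,
            graz_to_DMS = graz_to_DMS, k_method = k_method,
            photolysis_diel = isTRUE(photolysis_diel))
  validate_sulfur_params(p)
  class(p) <- "sulfur_params"
  p
}

validate_sulfur_params <- function(p) {
  quotas <- c("SC_DA", "SC_NF", "SC_OP", "SC_BC", "K0")
  for (q in quotas)
    if (!is.numeric(p[[q]]) || length(p[[q]]) != 1 || is.na(p[[q]]) || p[[q]] < 0)
      stop("parameter '", q, "' must be a single non-negative number")
  fracs <- c("y_DMS_DA", "y_DMS_NF", "y_DMS_OP", "lyase_Bact",
             "ratio_S_DMSPd", "ratio_S_DMS", "graz_to_DMS")
  for (f in fracs)
    if (!is.numeric(p[[f]]) || length(p[[f]]) != 1 || is.na(p[[f]]) ||
        p[[f]] < 0 || p[[f]] > 1)
      stop("parameter '", f, "' must lie in [0, 1]")
  invisible(p)
}

#' Initial sulfur state
#'
#' The three sulfur pools tracked by the simulator, all in mmolS m^-3:
#' particulate DMSP per functional type (summing to the bulk DMSPp pool),
#' dissolved DMSP, and DMS.
#'
#' @param DMSPp_DA,DMSPp_NF,DMSPp_OP per-FT particulate DMSP (mmolS m^-3).
#' @param DMSPd dissolved DMSP (mmolS m^-3).
#' @param DMS dimethylsulfide (mmolS m^-3).
#' @return An object of class `sulfur_state` (a named numeric vector).
#' @export
sulfur_state <- function(DMSPp_DA = 0, DMSPp_NF = 0, DMSPp_OP = 0,
                         DMSPd = 0, DMS = 0) {
  s <- as.numeric(c(DMSPp_DA, DMSPp_NF, DMSPp_OP, DMSPd, DMS))
  names(s) <- c("DMSPp_DA", "DMSPp_NF", "DMSPp_OP", "DMSPd", "DMS")
  if (anyNA(s) || any(s < 0)) stop("all sulfur pools must be non-negative")
  class(s) <- "sulfur_state"
  s
}
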