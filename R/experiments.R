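#' Built-in sensitivity tests
#'
#' The 21 parameter-perturbation experiments of the reference sensitivity
#' sweep: phytoplankton S:C quotas (including the Skeletonema-like diatom
#' value 0.0034 molS:molC), phytoplankton lyase yields globally and per
#' group, bacterial S:C extremes (1:37 and 1:196), the fractions of the
#' bacterial community using DMSPd and/or DMS, the bacterial cleavage
#' fraction, wind-speed perturbations, and the alternative
#' gas-transfer-velocity parameterization. Quotas are specified in
#' molS:molC as published and converted internally (/12) to mmolS mgC^-1.
#'
#' @return A list of 21 `sensitivity_test` objects, each with `id`,
#'   `description`, `params` (sulfur-parameter overrides) and `wind`
#'   (`NULL`, or a list `type = "constant"`/`"scale"` with `value`).
#' @export
#' @examples
#' length(builtin_tests())
builtin_tests <- function() {
  q <- function(mol_per_molC) mol_per_molC / MGC_PER_MMOLC
  tst <- function(id, description, params = list(), wind = NULL)
    structure(list(id = id, description = description, params = params,
                   wind = wind), class = "sensitivity_test")
  list(
    tst("test1", "SC_NF, SC_OP = 0.018 molS:molC",
        list(SC_NF = q(0.018), SC_OP = q(0.018))),
    tst("test2", "SC_NF, SC_OP = 0.004 molS:molC",
        list(SC_NF = q(0.004), SC_OP = q(0.004))),
    tst("test3", "SC_DA = 0.00212 molS:molC", list(SC_DA = q(0.00212))),
    tst("test4", "SC_DA = 0", list(SC_DA = 0)),
    tst("test5", "SC_DA = 0.0034 molS:molC (Skeletonema-like)",
        list(SC_DA = q(0.0034))),
    tst("test6", "phytoplankton lyase yields = 0",
        list(y_DMS_DA = 0, y_DMS_NF = 0, y_DMS_OP = 0)),
    tst("test7", "phytoplankton lyase yields = 0.25",
        list(y_DMS_DA = 0.25, y_DMS_NF = 0.25, y_DMS_OP = 0.25)),
    tst("test8", "phytoplankton lyase yields = 0.5",
        list(y_DMS_DA = 0.5, y_DMS_NF = 0.5, y_DMS_OP = 0.5)),
    tst("test9", "y_DMS_NF, y_DMS_OP = 0.5",
        list(y_DMS_NF = 0.5, y_DMS_OP = 0.5)),
    tst("test10", "y_DMS_DA = 0.5", list(y_DMS_DA = 0.5)),
    tst("test11", "SC_BC = 1:37 molS:molC", list(SC_BC = 1 / 37)),
    tst("test12", "SC_BC = 1:196 molS:molC", list(SC_BC = 1 / 196)),
    tst("test13", "Ratio_BC = 0.75 (DMSPd and DMS)",
        list(ratio_S_DMSPd = 0.75, ratio_S_DMS = 0.75)),
    tst("test14", "Ratio_BC = 0.5 (DMSPd and DMS)",
        list(ratio_S_DMSPd = 0.5, ratio_S_DMS = 0.5)),
    tst("test15", "Ratio_BC for DMSPd = 0.5", list(ratio_S_DMSPd = 0.5)),
    tst("test16", "Ratio_BC for DMS = 0.5", list(ratio_S_DMS = 0.5)),
    tst("test17", "bacterial cleavage fraction = 0.25",
        list(lyase_Bact = 0.25)),
    tst("test18", "constant wind 3.9 m s^-1", wind = list(type = "constant",
                                                          value = 3.9)),
    tst("test19", "wind -25 %", wind = list(type = "scale", value = 0.75)),
    tst("test20", "wind +25 %", wind = list(type = "scale", value = 1.25)),
    tst("test21", "Nightingale k600 parameterization",
        list(k_method = "nightingale"))
  )
}

apply_sensitivity_test <- function(test, params, forcing) {
  if (length(test$params)) {
    for (nm in names(test$params))
      if (!nm %in% names(params)) stop("unresolvable parameter path: ", nm)
    params <- utils::modifyList(unclass(params), test$params)
    class(params) <- "sulfur_params"
    validate_sulfur_params(params)
  }
  if (!is.null(test$wind)) {
    forcing$u10_ms <- switch(test$wind$type,
      constant = rep(test$wind$value, nrow(forcing)),
      scale = forcing$u10_ms * test$wind$value,
      stop("unknown wind perturbation type: ", test$wind$type))
  }
  list(params = params, forcing = forcing)
}

#' Run a sensitivity experiment
#'
#' Runs one full-year simulation per test on identical forcing (except where
#' the test perturbs the wind), plus the unperturbed reference, and tabulates
#' the annual mean DMS concentration and the annual air-sea emission.
#'
#' @param forcing a `forcing_series`, or `NULL` to generate the default
#'   scenario at `dt` with `seed`.
#' @param tests list of tests from [builtin_tests()] (or a compatible
#'   structure); may be a subset.
#' @param params reference [sulfur_params()].
#' @param seed,dt forwarded to [generate_forcing()] when `forcing` is `NULL`.
#' @param keep_budgets if `TRUE`, attach the full [integrate_budget()] of
#'   each run as the `budgets` attribute.
#' @return A data.frame (`reference` row first) with columns `id`,
#'   `description`, `mean_DMS_umol_m3`, `F_DMS_mmol_m2_y`.
#' @export
run_experiment <- function(forcing = NULL, tests = builtin_tests(),
                           params = sulfur_params(), seed = 1, dt = 0.25,
                           keep_budgets = FALSE) {
  if (is.null(forcing))
    forcing <- generate_forcing(default_bloom_specs(), environment_spec(),
                                dt = dt, seed = seed)
  run1 <- function(p, f) {
    sim <- run_simulation(f, p)
    list(mean_DMS = mean(sim$states$DMS) * 1000,
         F_DMS = sum(sim$ledger$f9_emission) * sim$dt * sim$H,
         budget = if (keep_budgets) integrate_budget(sim) else NULL)
  }
  ref <- run1(params, forcing)
  rows <- list(data.frame(id = "reference", description = "reference run",
                          mean_DMS_umol_m3 = ref$mean_DMS,
                          F_DMS_mmol_m2_y = ref$F_DMS))
  budgets <- list(reference = ref$budget)
  for (t in tests) {
    mod <- apply_sensitivity_test(t, params, forcing)
    res <- run1(mod$params, mod$forcing)
    rows[[length(rows) + 1]] <-
      data.frame(id = t$id, description = t$description,
                 mean_DMS_umol_m3 = res$mean_DMS,
                 F_DMS_mmol_m2_y = res$F_DMS)
    budgets[[t$id]] <- res$budget
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  if (keep_budgets) attr(out, "budgets") <- budgets
  out
}
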