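#' Parameter-recovery simulation for the individual-hutch (B2G) model
#'
#' Each replicate generates a fresh year of hourly climate, a cohort of `n`
#' calves with births uniform over twelve months, computes every calf's
#' exposure quartile through the full climate -> effective temperature ->
#' LCT -> proportion chain, draws DLWG from the generating linear predictor
#' (exposure category + birth weight + exit age), re-assembles the analysis
#' table through the pipeline, and fits the multivariable model. Averaging
#' the replicate estimates checks that the chain returns the generating
#' coefficients.
#'
#' @param n_reps number of replicates.
#' @param n cohort size per replicate.
#' @param seed base seed; replicate r uses seed + r - 1.
#' @param cohort_config generator configuration (seed is overridden per
#'   replicate).
#' @param climate_config climate configuration (seed overridden likewise).
#' @return data frame with one row per replicate: intercept, birth_weight,
#'   exit_age, cat2, cat3, cat4 estimates (NA when a category level was
#'   absent in that replicate).
#' @export
recover_b2g <- function(n_reps = 200, n = 271, seed = 1,
                        cohort_config = cohort_gen_config(n_calves = n),
                        climate_config = climate_gen_config()) {
  rows <- lapply(seq_len(n_reps), function(r) {
    climate_config$seed <- seed + r - 1
    cohort_config$seed <- seed + r - 1
    climate <- generate_climate(climate_config)
    bundle <- generate_cohort(cohort_config, climate, phases = "b2g")
    asm <- assemble_b2g(as_study(bundle, climate))
    fit <- fit_growth_model(asm$data, "dlwg",
                            c("category", "birth_weight", "exit_age"))
    cf <- stats::coef(fit)
    lab <- b2g_scheme()$labels
    data.frame(
      replicate = r,
      intercept = unname(cf["(Intercept)"]),
      birth_weight = unname(cf["birth_weight"]),
      exit_age = unname(cf["exit_age"]),
      cat2 = unname(cf[paste0("category", lab[2])]),
      cat3 = unname(cf[paste0("category", lab[3])]),
      cat4 = unname(cf[paste0("category", lab[4])])
    )
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Parameter-recovery simulation for the group-pen (G2E) mixed model
#'
#' Each replicate generates climate and a cohort of `n` fully eligible
#' calves, assembles the group-pen analysis table through the pipeline
#' (slope DLWG from the twice-weekly weighings, measured average CMR
#' intake, exposure category over the pen window), and fits the linear
#' mixed model with crossed random intercepts for rearing group, pen and
#' feeder system.
#'
#' @inheritParams recover_b2g
#' @return data frame with one row per replicate: entry_age, cmr,
#'   cat2..cat4 estimates and the three random-intercept variances.
#' @export
recover_g2e <- function(n_reps = 200, n = 221, seed = 1,
                        cohort_config = cohort_gen_config(n_calves = n),
                        climate_config = climate_gen_config()) {
  rows <- lapply(seq_len(n_reps), function(r) {
    climate_config$seed <- seed + r - 1
    cohort_config$seed <- seed + r - 1
    climate <- generate_climate(climate_config)
    bundle <- generate_cohort(cohort_config, climate)
    asm <- assemble_g2e(as_study(bundle, climate))
    fit <- fit_growth_model(asm$data, "dlwg",
                            c("category", "entry_age", "cmr_intake"),
                            random = c("group_id", "pen_id",
                                       "feeder_system"))
    cf <- lme4::fixef(fit)
    vc <- as.data.frame(lme4::VarCorr(fit))
    vv <- stats::setNames(vc$vcov, vc$grp)
    lab <- g2e_scheme()$labels
    data.frame(
      replicate = r,
      entry_age = unname(cf["entry_age"]),
      cmr = unname(cf["cmr_intake"]),
      cat2 = unname(cf[paste0("category", lab[2])]),
      cat3 = unname(cf[paste0("category", lab[3])]),
      cat4 = unname(cf[paste0("category", lab[4])]),
      var_group = unname(vv["group_id"]),
      var_pen = unname(vv["pen_id"]),
      var_feeder = unname(vv["feeder_system"])
    )
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
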