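#' Pipeline run configuration
#'
#' Bundles every stage's parameters plus the sensitivity switches. At
#' most one mechanism may be excluded per run, matching the
#' one-mechanism-fails sensitivity design.
#'
#' @param seed master seed; all stage streams derive from it so paired
#'   runs share common random numbers.
#' @param n_people synthetic sample size (default 1508).
#' @param scenario a [scenario_params()] object.
#' @param child_weight a [child_weight_params()] object.
#' @param adult_weight an [adult_weight_params()] object.
#' @param impute_alpha,impute_min_n imputation model-selection level and
#'   minimum stratum size.
#' @param horizon lifetable horizon in years: 10 (default), 30 or 100.
#' @param mc_runs Monte Carlo draws for uncertainty intervals (0 =
#'   deterministic run only).
#' @param exclude_mechanism `NULL` or one of "reformulation", "portion",
#'   "sales_weighting": that mechanism fails, its share of the reduction
#'   is lost.
#' @param verified_only drop people with imputed or self-reported height,
#'   weight or PAL before analysis.
#' @param include_over_80s extend the sample and cohorts beyond age 80
#'   (to 90).
#' @param bmi_rolling_3yr smooth age-specific BMI means with a 3-year
#'   rolling average before health modelling.
#' @param ref_bmi reference BMI for the relative-risk scaling.
#' @return list of class `run_config`.
#' @export
run_config <- function(seed = 1, n_people = 1508,
                       scenario = scenario_params(),
                       child_weight = child_weight_params(),
                       adult_weight = adult_weight_params(),
                       impute_alpha = 0.05, impute_min_n = 30,
                       horizon = 10, mc_runs = 2000,
                       exclude_mechanism = NULL,
                       verified_only = FALSE,
                       include_over_80s = FALSE,
                       bmi_rolling_3yr = FALSE,
                       ref_bmi = 22) {
  if (!horizon %in% c(10, 30, 100))
    stop("'horizon' must be one of 10, 30, 100")
  if (!is.null(exclude_mechanism)) {
    exclude_mechanism <- match.arg(exclude_mechanism,
      c("reformulation", "portion", "sales_weighting"))
    scenario$mechanisms_enabled <-
      setdiff(scenario$mechanisms_enabled, exclude_mechanism)
  }
  structure(list(seed = as.integer(seed), n_people = as.integer(n_people),
                 scenario = scenario, child_weight = child_weight,
                 adult_weight = adult_weight,
                 impute_alpha = impute_alpha, impute_min_n = impute_min_n,
                 horizon = horizon, mc_runs = as.integer(mc_runs),
                 exclude_mechanism = exclude_mechanism,
                 verified_only = isTRUE(verified_only),
                 include_over_80s = isTRUE(include_over_80s),
                 bmi_rolling_3yr = isTRUE(bmi_rolling_3yr),
                 ref_bmi = ref_bmi),
            class = "run_config")
}

# daily energy intake per person from the diary items
person_daily_kcal <- function(items) {
  tapply(items$energy, items$person_id, sum)
}

#' Run the full sugar-reduction health-impact pipeline
#'
#' Executes the full chain: synthesise (or accept) survey data, impute
#' missing anthropometrics, apply the sugar reduction scenario, convert
#' calorie reductions into weight and BMI changes (children via the trial
#' coefficient, adults via the energy-balance model, 18-year-olds
#' recomputed by the adult method for health modelling), and propagate
#' the adult BMI change through the multistate lifetable, optionally with
#' Monte Carlo uncertainty.
#'
#' @param config a [run_config()] object.
#' @param data optional named list of inputs (`people`, `items`,
#'   `diseases`, `population`, `background_mortality`,
#'   `unrelated_costs`); any that are missing are synthesised from the
#'   seed.
#' @return object of class `sugar_report`: calorie summary, weight/BMI
#'   summary, prevalence tables, mechanism attribution, lifetable result
#'   and (if `mc_runs > 0`) Monte Carlo intervals, with the configuration
#'   echoed.
#' @export
run_pipeline <- function(config = run_config(), data = NULL) {
  if (!inherits(config, "run_config"))
    stop("'config' must come from run_config()")
  age_hi <- if (config$include_over_80s) 90L else 80L
  synth <- synthetic_config(n_people = config$n_people, seed = config$seed,
                            age_range = c(4L, age_hi))
  people <- data$people %||% generate_population(synth)
  items <- data$items %||% generate_diaries(people, synth)
  diseases <- data$diseases %||% generate_disease_tables(config$seed)
  population <- data$population %||%
    synthetic_population_table(ages = 18:age_hi)
  bg_mort <- data$background_mortality %||% background_mortality_table()
  unrel <- data$unrelated_costs %||% unrelated_cost_table()

  kcal <- person_daily_kcal(items)
  people$daily_kcal <- as.numeric(kcal[people$id])
  people$daily_kcal[is.na(people$daily_kcal)] <- 0

  models <- fit_imputers(people, alpha = config$impute_alpha,
                         min_n = config$impute_min_n)
  people <- impute_people(people, models, seed = config$seed)

  if (config$verified_only) {
    keep <- people$measurement_flag == "measured" &
      !people$height_imputed & !people$weight_imputed & !people$pal_imputed
    people <- people[keep, , drop = FALSE]
    items <- items[items$person_id %in% people$id, , drop = FALSE]
  }

  scen_items <- apply_scenario(items, default_policy_table(), config$scenario)
  deltas <- person_calorie_delta(scen_items, params = config$scenario)
  cal_summary <- cohort_summary(deltas, people)

  m <- merge(people, deltas, by.x = "id", by.y = "person_id")
  child <- m$age <= 18
  m$weight_delta <- NA_real_
  m$weight_delta[child] <- child_weight_change(m$sugar_kcal[child],
                                               config$child_weight)
  m$weight_delta[!child] <- adult_weight_change(
    m$total_kcal[!child], m$pal[!child], m$sex[!child], config$adult_weight)
  m$bmi_baseline <- m$weight / m$height^2
  m$bmi_delta <- bmi_change(m$weight_delta, m$height)
  m$bmi_scenario <- m$bmi_baseline - m$bmi_delta

  wsum <- weight_bmi_summary(m)
  prev <- prevalence_table(m, m$bmi_baseline, m$bmi_scenario)
  attribution <- mechanism_attribution(deltas, people)

  # health modelling: adults 18+, 18-year-olds recomputed by adult method
  ad <- m[m$age >= 18, , drop = FALSE]
  ad$weight_delta <- adult_weight_change(ad$total_kcal, ad$pal, ad$sex,
                                         config$adult_weight)
  ad$bmi_delta <- bmi_change(ad$weight_delta, ad$height)
  bmi_b <- ad$bmi_baseline
  bmi_s <- ad$bmi_baseline - ad$bmi_delta
  if (config$bmi_rolling_3yr) {
    bmi_b <- smooth_bmi_3yr(ad, bmi_b)
    bmi_s <- smooth_bmi_3yr(ad, bmi_s)
  }
  lt <- run_lifetable(ad, bmi_b, bmi_s, diseases,
                      population = population,
                      background_mortality = bg_mort,
                      unrelated_costs = unrel,
                      horizon = config$horizon, ref_bmi = config$ref_bmi)
  mc <- NULL
  if (config$mc_runs > 0)
    mc <- lifetable_monte_carlo(ad, bmi_b, bmi_s, diseases,
                                population = population,
                                background_mortality = bg_mort,
                                unrelated_costs = unrel,
                                horizon = config$horizon,
                                ref_bmi = config$ref_bmi,
                                mc = mc_config(n_runs = config$mc_runs,
                                               seed = config$seed))
  structure(list(config = config, seed = config$seed,
                 n_people = nrow(people),
                 calorie_summary = cal_summary,
                 weight_summary = wsum,
                 prevalence = prev$prevalence,
                 obese_change = prev$obese_change,
                 attribution = attribution,
                 lifetable = lt, mc = mc,
                 imputation = imputation_report(models)),
            class = "sugar_report")
}

# band x sex weighted means of weight and BMI change
weight_bmi_summary <- function(m) {
  m$band <- age_band(m$age)
  groups <- split(m, list(m$band, m$sex), drop = TRUE)
  rows <- lapply(groups, function(g) data.frame(
    band = as.character(g$band[1]), sex = g$sex[1], n = nrow(g),
    weight_change_kg = weighted_mean(g$weight_delta, g$survey_weight),
    bmi_change = weighted_mean(g$bmi_delta, g$survey_weight),
    stringsAsFactors = FALSE))
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out[order(out$band, out$sex), ]
}

#' Share of the calorie reduction attributable to each mechanism
#'
#' Survey-weighted percentage of the calorie reduction delivered by each
#' mechanism, by age band. For adult bands the portion share includes
#' the non-sugar calories it removes (those enter the adult weight
#' model); for child bands only sugar calories count, since the
#' children's weight model uses sugar alone.
#'
#' @param deltas per-person deltas from [person_calorie_delta()].
#' @param people persons data.frame.
#' @return data.frame: band, mechanism, kcal_per_day, share_pct (shares
#'   sum to 100 within band).
#' @export
mechanism_attribution <- function(deltas, people) {
  m <- merge(deltas, people[, c("id", "age", "survey_weight")],
             by.x = "person_id", by.y = "id")
  m$band <- age_band(m$age)
  rows <- list()
  for (b in levels(droplevels(m$band))) {
    g <- m[m$band == b, ]
    w <- g$survey_weight
    adult <- b == "19-80"
    portion_kcal <- if (adult) g$kcal_portion else
      g$kcal_portion - g$nonsugar_kcal
    parts <- c(reformulation = weighted_mean(g$kcal_reformulation, w),
               portion = weighted_mean(portion_kcal, w),
               sales_weighting = weighted_mean(g$kcal_sales_weighting, w))
    tot <- sum(parts)
    rows[[b]] <- data.frame(band = b, mechanism = names(parts),
                            kcal_per_day = unname(parts),
                            share_pct = if (tot > 0)
                              100 * unname(parts) / tot else 0,
                            stringsAsFactors = FALSE)
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Run the battery of sensitivity analyses
#'
#' Repeats the pipeline under the eight alternative specifications:
#' 30-year and lifetime (100-year) horizons, verified height and weight
#' only, including over-80s, 3-year rolling-average BMI, and the failure
#' of each single mechanism. All runs are deterministic (no Monte Carlo)
#' and share the master seed, so differences between columns reflect the
#' specification, not sampling noise.
#'
#' @param config baseline [run_config()].
#' @param data optional input data list passed through to
#'   [run_pipeline()].
#' @return data.frame with one row per analysis x sex: QALYs gained,
#'   cost change, and incident-case changes for each disease.
#' @export
sensitivity_analysis <- function(config = run_config(mc_runs = 0),
                                 data = NULL) {
  specs <- list(
    horizon_30yr = list(horizon = 30),
    lifetime_100yr = list(horizon = 100),
    verified_only = list(verified_only = TRUE),
    include_over_80s = list(include_over_80s = TRUE),
    bmi_3yr_average = list(bmi_rolling_3yr = TRUE),
    exclude_reformulation = list(exclude_mechanism = "reformulation"),
    exclude_portion = list(exclude_mechanism = "portion"),
    exclude_sales_weighting = list(exclude_mechanism = "sales_weighting"))
  rows <- list()
  for (nm in names(specs)) {
    cfg <- config
    cfg$mc_runs <- 0L
    for (k in names(specs[[nm]])) {
      if (k == "exclude_mechanism") {
        cfg$exclude_mechanism <- specs[[nm]][[k]]
        cfg$scenario$mechanisms_enabled <- setdiff(
          c("reformulation", "portion", "sales_weighting"),
          specs[[nm]][[k]])
      } else cfg[[k]] <- specs[[nm]][[k]]
    }
    rep <- run_pipeline(cfg, data)
    lt <- rep$lifetable
    wide <- stats::reshape(lt$cases, idvar = "sex", timevar = "disease",
                           direction = "wide")
    names(wide) <- sub("cases_change\\.", "cases_", names(wide))
    row <- merge(lt$by_sex, wide, by = "sex")
    row <- cbind(analysis = nm, row, stringsAsFactors = FALSE)
    rows[[nm]] <- row
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' @export
print.sugar_report <- function(x, ...) {
  cat("Sugar reduction programme simulation (seed ", x$seed, ", n = ",
      x$n_people, ", horizon ", x$config$horizon, " years)\n\n", sep = "")
  cat("Calorie reduction by age band and sex (kcal/day, weighted means):\n")
  print(x$calorie_summary[, c("band", "sex", "sugar_kcal", "nonsugar_kcal",
                              "pct_of_baseline_sugar",
                              "pct_of_baseline_energy")],
        row.names = FALSE, digits = 3)
  cat("\nWeight and BMI change by age band and sex:\n")
  print(x$weight_summary, row.names = FALSE, digits = 3)
  cat("\nObese-class change:\n")
  print(x$obese_change, row.names = FALSE, digits = 3)
  cat("\n")
  print(x$lifetable)
  if (!is.null(x$mc)) {
    cat("\nMonte Carlo 95% uncertainty intervals (",
        x$config$mc_runs, " runs):\n", sep = "")
    print(as.data.frame(x$mc)[x$mc$measure %in%
      c("qalys_male", "qalys_female", "qalys_total",
        "cost_male", "cost_female", "cost_total"), ],
      row.names = FALSE, digits = 4)
  }
  invisible(x)
}

#' @export
summary.sugar_report <- function(object, ...) {
  cat("Pipeline stages completed: synthesis, imputation, scenario, ",
      "weight/BMI, lifetable", if (!is.null(object$mc)) ", Monte Carlo",
      "\n", sep = "")
  cat("Mechanism attribution (% of calorie reduction):\n")
  print(object$attribution, row.names = FALSE, digits = 3)
  invisible(object)
}
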