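#' Population impact fraction
#'
#' Weighted population impact fraction (PIF) of shifting the exposure
#' distribution from `exposure_baseline` to `exposure_scenario`:
#' \deqn{PIF = \frac{\sum_i w_i RR(x_i) - \sum_i w_i RR(x_i')}
#'                  {\sum_i w_i RR(x_i)}}
#' with \eqn{RR(x) = rr^{x - x_{ref}}} for a per-unit relative risk `rr`.
#' Zero when the distributions are identical or the relative risk is
#' flat; positive when exposure falls and risk increases with exposure.
#'
#' @param exposure_baseline,exposure_scenario exposure values (e.g. BMI)
#'   for the same individuals, same order.
#' @param weights sampling weights; one per individual, shared by both
#'   distributions.
#' @param rr relative risk per unit of exposure.
#' @param ref reference exposure at which RR = 1 (default 22; the PIF is
#'   invariant to this choice, it only scales both sums).
#' @return the population impact fraction, a scalar in (-Inf, 1].
#' @examples
#' # two-person toy: baseline RRs (2, 1), scenario RRs (1, 1) -> 1/3
#' pif(c(23, 22), c(22, 22), weights = c(1, 1), rr = 2, ref = 22)
#' @export
pif <- function(exposure_baseline, exposure_scenario, weights = NULL,
                rr, ref = 22) {
  n <- length(exposure_baseline)
  if (length(exposure_scenario) != n)
    stop("baseline and scenario exposure distributions differ in length")
  if (is.null(weights)) weights <- rep(1, n)
  if (length(weights) != n)
    stop("weights do not match the exposure distributions")
  if (n == 0L) stop("empty exposure distribution")
  if (rr <= 0) stop("relative risk must be positive")
  rr_b <- rr^(exposure_baseline - ref)
  rr_s <- rr^(exposure_scenario - ref)
  (sum(weights * rr_b) - sum(weights * rr_s)) / sum(weights * rr_b)
}

# per-disease PIFs by sex, pooled over adult ages
pif_by_sex <- function(adults, bmi_baseline, bmi_scenario, diseases,
                       ref_bmi = 22) {
  dis <- unique(diseases[, c("disease", "rr_per_bmi_unit")])
  dis <- dis[!duplicated(dis$disease), ]
  sexes <- c("male", "female")
  out <- matrix(0, nrow = 2, ncol = nrow(dis),
                dimnames = list(sexes, dis$disease))
  for (s in sexes) {
    sel <- adults$sex == s
    if (!any(sel)) next
    for (j in seq_len(nrow(dis)))
      out[s, j] <- pif(bmi_baseline[sel], bmi_scenario[sel],
                       adults$survey_weight[sel],
                       rr = dis$rr_per_bmi_unit[j], ref = ref_bmi)
  }
  out
}

# Exact one-interval update of the per-disease illness-death process
# (healthy s, prevalent c, dead-from-disease implicit) with constant
# rates: incidence i, case fatality f, remission r. Uses the analytic
# matrix exponential of [[-i, r], [i, -(f+r)]]; vectorised over cohorts.
step_disease <- function(s, c, i, f, r = 0, dt = 1) {
  tr <- -(i + f + r)
  det <- i * f
  disc <- sqrt(pmax(tr^2 - 4 * det, 0))
  l1 <- (tr + disc) / 2
  l2 <- (tr - disc) / 2
  den <- l1 - l2
  E1 <- exp(l1 * dt); E2 <- exp(l2 * dt)
  near <- abs(den) < 1e-12
  # distinct eigenvalues: expm = (E1 (A - l2 I) - E2 (A - l1 I)) / (l1 - l2)
  dsafe <- ifelse(near, 1, den)
  a11 <- (E1 * (-i - l2) - E2 * (-i - l1)) / dsafe
  a12 <- (E1 * r - E2 * r) / dsafe
  a21 <- (E1 * i - E2 * i) / dsafe
  a22 <- (E1 * (-(f + r) - l2) - E2 * (-(f + r) - l1)) / dsafe
  if (any(near)) {
    # repeated eigenvalue limit: expm = e^l (I + dt (A - l I))
    El <- exp(l1 * dt)
    a11[near] <- (El * (1 + dt * (-i - l1)))[near]
    a12[near] <- (El * dt * r)[near]
    a21[near] <- (El * dt * i)[near]
    a22[near] <- (El * (1 + dt * (-(f + r) - l1)))[near]
  }
  list(s = a11 * s + a12 * c, c = a21 * s + a22 * c)
}

# Precompute age-indexed rate arrays for the cohort simulation so the
# Monte Carlo loop only repeats the cheap arithmetic.
lifetable_prep <- function(population, diseases, background_mortality,
                           unrelated_costs, horizon) {
  if (horizon < 1) stop("'horizon' must be at least 1 year")
  dis_names <- unique(diseases$disease)
  d <- length(dis_names)
  n <- nrow(population)
  amax <- max(diseases$age)
  key <- function(sex, age) paste(sex, pmin(age, amax))
  dkey <- paste(diseases$sex, diseases$age)
  mkey <- paste(background_mortality$sex,
                pmin(background_mortality$age, max(background_mortality$age)))
  ukey <- paste(unrelated_costs$sex, unrelated_costs$age)

  inc <- array(0, c(n, d, horizon))
  cf <- array(0, c(n, d, horizon))
  bg <- matrix(0, n, horizon)
  unrel <- matrix(0, n, horizon)
  for (t in seq_len(horizon)) {
    a <- population$age + (t - 1)
    for (j in seq_len(d)) {
      rows <- match(paste(dis_names[j], key(population$sex, a)),
                    paste(diseases$disease, dkey))
      if (anyNA(rows)) stop("disease table does not cover ages needed for ",
                            dis_names[j])
      inc[, j, t] <- diseases$incidence[rows]
      cf[, j, t] <- diseases$case_fatality[rows]
    }
    mrows <- match(key(population$sex, a), mkey)
    if (anyNA(mrows)) stop("background mortality table does not cover all ages")
    bg[, t] <- background_mortality$rate[mrows]
    urows <- match(paste(population$sex,
                         pmin(a, max(unrelated_costs$age))), ukey)
    unrel[, t] <- unrelated_costs$annual_cost[urows]
  }
  first <- match(dis_names, diseases$disease)
  list(n = n, d = d, horizon = horizon, dis_names = dis_names,
       sex = population$sex, N0 = population$count, disc = rep(1, horizon),
       inc = inc, cf = cf, bg = bg, unrel = unrel,
       remission = diseases$remission[first],
       rr_diabetes = diseases$rr_diabetes[first],
       utility = diseases$utility_decrement[first],
       cost = diseases$annual_cost[first],
       diab_col = match("diabetes", dis_names))
}

# One arm of the proportional multistate lifetable. pif_mat is
# [cohort x disease]; diab_ref, when given, is the baseline arm's
# start-of-year diabetes prevalence trajectory [cohort x year] used to
# scale incidence of diabetes-sensitive diseases by the relative change
# in diabetes prevalence between arms.
run_arm <- function(prep, pif_mat, utility = prep$utility,
                    cost = prep$cost, diab_ref = NULL) {
  n <- prep$n; d <- prep$d; h <- prep$horizon
  s <- matrix(1, n, d); c <- matrix(0, n, d)
  N <- prep$N0
  cases <- matrix(0, n, d, dimnames = list(NULL, prep$dis_names))
  ly <- qaly <- cost_acc <- numeric(n)
  deaths_total <- numeric(n)
  diab_traj <- matrix(0, n, h)
  rem <- matrix(prep$remission, n, d, byrow = TRUE)
  u_mat <- matrix(utility, n, d, byrow = TRUE)
  rrd <- prep$rr_diabetes
  jd <- prep$diab_col

  for (t in seq_len(h)) {
    p <- c / (s + c)            # prevalence among alive, start of year
    diab_traj[, t] <- if (!is.na(jd)) p[, jd] else 0
    i_eff <- prep$inc[, , t] * (1 - pif_mat)
    if (!is.null(diab_ref) && !is.na(jd)) {
      num <- 1 + outer(p[, jd], rrd - 1)
      den <- 1 + outer(diab_ref[, t], rrd - 1)
      i_eff <- i_eff * (num / den)
    }
    cf_t <- prep$cf[, , t]
    m <- prep$bg[, t] + rowSums(p * cf_t)
    Nn <- N * exp(-m)
    deaths_total <- deaths_total + (N - Nn)
    ly_t <- (N + Nn) / 2
    cases <- cases + (s / (s + c)) * (1 - exp(-i_eff)) * N
    ly <- ly + ly_t
    qaly <- qaly + prep$disc[t] * ly_t * exp(rowSums(log(1 - p * u_mat)))
    cost_acc <- cost_acc + prep$disc[t] * ly_t *
      (as.numeric(p %*% cost) + prep$unrel[, t])
    upd <- step_disease(s, c, i_eff, cf_t, rem)
    s <- upd$s; c <- upd$c
    N <- Nn
  }
  list(cases = cases, life_years = ly, qalys = qaly, costs = cost_acc,
       final_pop = N, deaths = deaths_total, diab_traj = diab_traj,
       sex = prep$sex)
}

sum_by_sex <- function(x, sex) {
  vapply(c("male", "female"), function(s) sum(x[sex == s]), numeric(1))
}

#' Run the proportional multistate lifetable model
#'
#' Translates an adult BMI reduction into chronic-disease outcomes.
#' Per-disease population impact fractions are computed by sex from the
#' individual-level baseline and scenario BMI distributions, then applied
#' to disease incidence in a closed-cohort multistate lifetable of the
#' modelled population. Baseline and scenario arms share one code path;
#' with no BMI change every output difference is exactly zero.
#'
#' Comorbidity combines multiplicatively (one disease's prevalence does
#' not alter another's), except diabetes, which also acts as a risk
#' factor: incidence of diabetes-sensitive diseases in the scenario arm
#' is scaled by the relative change in diabetes prevalence between arms.
#' QALYs are mid-year person-years weighted by the product of
#' (1 - prevalence x utility decrement) over diseases; costs combine
#' prevalence-weighted annual disease costs with an unrelated-cost
#' schedule applied to all person-years, so added longevity carries its
#' healthcare cost.
#'
#' @param adults data.frame of adults (`sex`, `survey_weight`).
#' @param bmi_baseline,bmi_scenario individual BMI vectors aligned with
#'   `adults`.
#' @param diseases long-format disease parameter table as from
#'   [generate_disease_tables()].
#' @param population cohort population table (`sex`, `age`, `count`).
#' @param background_mortality table from [background_mortality_table()].
#' @param unrelated_costs table from [unrelated_cost_table()].
#' @param horizon simulation horizon in years (default 10).
#' @param ref_bmi reference BMI at which the per-unit relative risks
#'   equal 1 (default 22).
#' @param discount_rate annual discount rate applied to QALYs and costs
#'   (default 0, undiscounted).
#' @return object of class `lifetable_result`: list with `by_sex`
#'   (QALYs gained, life years gained, cost change by sex), `cases`
#'   (change in incident cases, scenario minus baseline, per disease and
#'   sex), `pifs`, `horizon`, and the raw `baseline`/`scenario` arms.
#' @export
run_lifetable <- function(adults, bmi_baseline, bmi_scenario, diseases,
                          population = synthetic_population_table(),
                          background_mortality = background_mortality_table(),
                          unrelated_costs = unrelated_cost_table(),
                          horizon = 10, ref_bmi = 22, discount_rate = 0) {
  stopifnot(nrow(adults) == length(bmi_baseline),
            nrow(adults) == length(bmi_scenario))
  prep <- lifetable_prep(population, diseases, background_mortality,
                         unrelated_costs, horizon)
  if (discount_rate != 0)
    prep$disc <- (1 + discount_rate)^-(seq_len(horizon) - 1)
  pifs <- pif_by_sex(adults, bmi_baseline, bmi_scenario, diseases, ref_bmi)
  pif_mat <- pifs[prep$sex, unique(diseases$disease), drop = FALSE]
  zero <- matrix(0, prep$n, prep$d)

  base <- run_arm(prep, zero)
  scen <- run_arm(prep, pif_mat, diab_ref = base$diab_traj)

  by_sex <- data.frame(
    sex = c("male", "female"),
    qalys_gained = unname(sum_by_sex(scen$qalys - base$qalys, prep$sex)),
    life_years_gained = unname(sum_by_sex(scen$life_years - base$life_years,
                                          prep$sex)),
    cost_change = unname(sum_by_sex(scen$costs - base$costs, prep$sex)),
    stringsAsFactors = FALSE)
  cases_delta <- scen$cases - base$cases
  cases <- do.call(rbind, lapply(prep$dis_names, function(dn) data.frame(
    disease = dn, sex = c("male", "female"),
    cases_change = unname(sum_by_sex(cases_delta[, dn], prep$sex)),
    stringsAsFactors = FALSE)))
  structure(list(by_sex = by_sex, cases = cases, pifs = pifs,
                 horizon = horizon, baseline = base, scenario = scen,
                 prep_sex = prep$sex),
            class = "lifetable_result")
}

#' @export
print.lifetable_result <- function(x, ...) {
  cat("Proportional multistate lifetable result (", x$horizon,
      "-year horizon)\n\n", sep = "")
  cat("Outcome changes (scenario - baseline):\n")
  print(x$by_sex, row.names = FALSE)
  cat("\nIncident cases change by disease:\n")
  wide <- stats::reshape(x$cases, idvar = "disease", timevar = "sex",
                         direction = "wide")
  names(wide) <- sub("cases_change\\.", "", names(wide))
  print(wide, row.names = FALSE)
  invisible(x)
}

#' Monte Carlo configuration
#'
#' Controls the probabilistic sensitivity analysis: which parameter
#' groups vary (per-BMI-unit relative risks, lognormal; annual disease
#' costs, gamma; utility decrements, beta) and the spread of each.
#'
#' @param n_runs number of Monte Carlo draws (default 2000).
#' @param seed integer seed.
#' @param vary character subset of `c("rr", "cost", "utility")`.
#' @param rr_sdlog standard deviation of log RR per BMI unit draws.
#' @param cost_cv coefficient of variation of cost draws.
#' @param utility_conc beta concentration of utility-decrement draws
#'   (larger = tighter).
#' @return list of class `mc_config`.
#' @export
mc_config <- function(n_runs = 2000, seed = 1,
                      vary = c("rr", "cost", "utility"),
                      rr_sdlog = 0.015, cost_cv = 0.10,
                      utility_conc = 80) {
  if (n_runs < 1) stop("'n_runs' must be >= 1")
  bad <- setdiff(vary, c("rr", "cost", "utility"))
  if (length(bad)) stop("unknown parameter group(s): ",
                        paste(bad, collapse = ", "))
  structure(list(n_runs = as.integer(n_runs), seed = as.integer(seed),
                 vary = vary, rr_sdlog = rr_sdlog, cost_cv = cost_cv,
                 utility_conc = utility_conc),
            class = "mc_config")
}

# draw one perturbed copy of the disease table under the MC config;
# diseases with RR exactly 1 (longevity-only) are never given a BMI link
perturb_diseases <- function(diseases, config) {
  out <- diseases
  dis <- unique(diseases$disease)
  for (dn in dis) {
    sel <- out$disease == dn
    if ("rr" %in% config$vary) {
      rr0 <- out$rr_per_bmi_unit[sel][1]
      if (rr0 != 1)
        out$rr_per_bmi_unit[sel] <- exp(log(rr0) +
                                          stats::rnorm(1, 0, config$rr_sdlog))
    }
    if ("cost" %in% config$vary) {
      c0 <- out$annual_cost[sel][1]
      if (c0 > 0 && config$cost_cv > 0)
        out$annual_cost[sel] <- stats::rgamma(1, shape = 1 / config$cost_cv^2,
                                              scale = c0 * config$cost_cv^2)
    }
    if ("utility" %in% config$vary) {
      u0 <- out$utility_decrement[sel][1]
      if (u0 > 0 && u0 < 1)
        out$utility_decrement[sel] <- stats::rbeta(
          1, u0 * config$utility_conc, (1 - u0) * config$utility_conc)
    }
  }
  out
}

#' Monte Carlo uncertainty analysis
#'
#' Repeatedly perturbs the disease parameter table (relative risks,
#' costs, utility values), evaluates a model function on each draw, and
#' summarises each output as the mean of draws with a 95\% uncertainty
#' interval (empirical 2.5th-97.5th centiles). Deterministic given the
#' seed in `config`.
#'
#' @param fn function taking a perturbed disease table and returning a
#'   named numeric vector of outputs.
#' @param diseases central disease parameter table.
#' @param config an [mc_config()] object.
#' @return object of class `mc_result`: data.frame with columns
#'   `measure`, `mean`, `lower`, `upper`, plus attribute `draws` (the
#'   run-by-measure matrix).
#' @export
monte_carlo <- function(fn, diseases, config = mc_config()) {
  set.seed(derive_seed(config$seed, "montecarlo"))
  draws <- NULL
  for (r in seq_len(config$n_runs)) {
    v <- fn(perturb_diseases(diseases, config))
    if (is.null(draws))
      draws <- matrix(NA_real_, config$n_runs, length(v),
                      dimnames = list(NULL, names(v)))
    draws[r, ] <- v
  }
  qs <- apply(draws, 2, stats::quantile, probs = c(0.025, 0.975),
              names = FALSE, type = 7)
  out <- data.frame(measure = colnames(draws),
                    mean = colMeans(draws),
                    lower = qs[1, ], upper = qs[2, ],
                    stringsAsFactors = FALSE)
  rownames(out) <- NULL
  attr(out, "draws") <- draws
  class(out) <- c("mc_result", "data.frame")
  out
}

#' Lifetable outcomes with Monte Carlo uncertainty
#'
#' Runs [run_lifetable()] under Monte Carlo perturbation of the disease
#' parameters. The rate arrays are precomputed once; each draw re-derives
#' the population impact fractions from the drawn relative risks and
#' re-runs both lifetable arms.
#'
#' @inheritParams run_lifetable
#' @param mc an [mc_config()] object.
#' @return an `mc_result` data.frame covering QALYs, costs and incident
#'   case changes by sex.
#' @export
lifetable_monte_carlo <- function(adults, bmi_baseline, bmi_scenario,
                                  diseases,
                                  population = synthetic_population_table(),
                                  background_mortality =
                                    background_mortality_table(),
                                  unrelated_costs = unrelated_cost_table(),
                                  horizon = 10, ref_bmi = 22,
                                  mc = mc_config()) {
  prep <- lifetable_prep(population, diseases, background_mortality,
                         unrelated_costs, horizon)
  zero <- matrix(0, prep$n, prep$d)
  dis_names <- prep$dis_names
  fn <- function(dis_draw) {
    first <- match(dis_names, dis_draw$disease)
    utility <- dis_draw$utility_decrement[first]
    cost <- dis_draw$annual_cost[first]
    pifs <- pif_by_sex(adults, bmi_baseline, bmi_scenario, dis_draw, ref_bmi)
    pif_mat <- pifs[prep$sex, dis_names, drop = FALSE]
    base <- run_arm(prep, zero, utility, cost)
    scen <- run_arm(prep, pif_mat, utility, cost, diab_ref = base$diab_traj)
    q <- sum_by_sex(scen$qalys - base$qalys, prep$sex)
    co <- sum_by_sex(scen$costs - base$costs, prep$sex)
    cd <- scen$cases - base$cases
    cases <- unlist(lapply(dis_names, function(dn)
      stats::setNames(sum_by_sex(cd[, dn], prep$sex),
                      paste0("cases_", dn, "_", c("male", "female")))))
    c(qalys_male = q[["male"]], qalys_female = q[["female"]],
      qalys_total = sum(q),
      cost_male = co[["male"]], cost_female = co[["female"]],
      cost_total = sum(co), cases)
  }
  monte_carlo(fn, diseases, mc)
}
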