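#' Configuration for the synthetic diet-survey generator
#'
#' Builds the configuration object for [generate_population()] and
#' [generate_diaries()]. Defaults emulate a National Diet and Nutrition
#' Survey style sample: 1508 respondents aged 4-80, in-scope (free) sugars
#' contributing about 7\% of energy in children and 5\% in adults, and
#' realistic missingness in height, weight and physical activity level.
#'
#' @param n_people number of survey respondents to simulate.
#' @param seed integer random seed; identical seed and config give
#'   byte-identical output.
#' @param age_range integer vector of length 2; default `c(4, 80)`.
#' @param target_sugar_share_children expected fraction of total energy
#'   from in-scope sugars for ages 4-18.
#' @param target_sugar_share_adults same for ages 19 and over.
#' @param missingness_rates named list with elements `height`, `weight`,
#'   `pal`: the fraction of each variable set to missing.
#' @param self_report_rate fraction of non-missing height/weight pairs
#'   flagged as self-reported rather than measured.
#' @param category_mix named numeric vector of relative weights over the
#'   ten in-scope food categories (see [default_policy_table()]); default
#'   is a plausible mix dominated by confectionery, biscuits and cereals.
#' @param natural_sugar_fraction fraction of item sugar that is exempt
#'   natural sugar in allowance-flagged categories (default 0.10).
#' @param weight_cv coefficient of variation of the survey sampling
#'   weights (default 0.3).
#' @return An object of class `synthetic_config`.
#' @export
synthetic_config <- function(n_people = 1508,
                             seed = 1,
                             age_range = c(4L, 80L),
                             target_sugar_share_children = 0.07,
                             target_sugar_share_adults = 0.05,
                             missingness_rates = list(height = 0.05,
                                                      weight = 0.07,
                                                      pal = 0.20),
                             self_report_rate = 0.15,
                             category_mix = NULL,
                             natural_sugar_fraction = 0.10,
                             weight_cv = 0.3) {
  if (!is.numeric(n_people) || length(n_people) != 1L || n_people < 1)
    stop("'n_people' must be a single count >= 1")
  if (length(age_range) != 2L || age_range[1] < 0 || age_range[2] <= age_range[1])
    stop("'age_range' must be two increasing non-negative ages")
  assert_fraction(target_sugar_share_children, "target_sugar_share_children")
  assert_fraction(target_sugar_share_adults, "target_sugar_share_adults")
  for (v in c("height", "weight", "pal")) {
    if (is.null(missingness_rates[[v]]))
      stop("'missingness_rates' must name '", v, "'")
    assert_fraction(missingness_rates[[v]], paste0("missingness_rates$", v))
  }
  assert_fraction(self_report_rate, "self_report_rate")
  assert_fraction(natural_sugar_fraction, "natural_sugar_fraction")
  cats <- default_policy_table()$category
  if (is.null(category_mix)) {
    category_mix <- c(breakfast_cereals = 1.5, yogurts = 1.0, biscuits = 1.5,
                      cakes = 1.2, morning_goods = 0.8, puddings = 0.8,
                      ice_cream = 0.8, chocolate_confectionery = 1.5,
                      sweet_confectionery = 1.0, sweet_spreads_sauces = 0.6)
  }
  bad <- setdiff(names(category_mix), cats)
  if (length(bad)) stop("unknown categories in 'category_mix': ",
                        paste(bad, collapse = ", "))
  if (any(category_mix < 0) || sum(category_mix) <= 0)
    stop("'category_mix' weights must be non-negative with positive sum")
  structure(list(n_people = as.integer(n_people), seed = as.integer(seed),
                 age_range = as.integer(age_range),
                 target_sugar_share_children = target_sugar_share_children,
                 target_sugar_share_adults = target_sugar_share_adults,
                 missingness_rates = missingness_rates,
                 self_report_rate = self_report_rate,
                 category_mix = category_mix,
                 natural_sugar_fraction = natural_sugar_fraction,
                 weight_cv = weight_cv),
            class = "synthetic_config")
}

# smooth median height (m) by age for the child growth emulation;
# anchors loosely follow UK growth charts
child_height_median <- function(age, sex) {
  anchors_age <- c(4, 6, 8, 10, 12, 14, 16, 18)
  h_m <- c(1.03, 1.16, 1.28, 1.39, 1.50, 1.64, 1.73, 1.76)
  h_f <- c(1.02, 1.15, 1.27, 1.38, 1.51, 1.59, 1.62, 1.63)
  hm <- stats::approx(anchors_age, h_m, xout = pmin(age, 18))$y
  hf <- stats::approx(anchors_age, h_f, xout = pmin(age, 18))$y
  ifelse(sex == "male", hm, hf)
}

# median BMI-for-age of the child reference population (kg/m^2); rises
# through adolescence towards the adult thresholds
child_bmi_median <- function(age, sex) {
  anchors_age <- c(4, 5, 7, 9, 11, 13, 15, 17, 19)
  b_m <- c(15.3, 15.3, 15.5, 16.0, 16.9, 18.2, 19.8, 21.0, 22.0)
  b_f <- c(15.3, 15.3, 15.4, 16.0, 17.0, 18.6, 20.2, 21.2, 22.0)
  bm <- stats::approx(anchors_age, b_m, xout = pmin(pmax(age, 4), 19))$y
  bf <- stats::approx(anchors_age, b_f, xout = pmin(pmax(age, 4), 19))$y
  ifelse(sex == "male", bm, bf)
}

#' Generate a synthetic survey population
#'
#' Simulates respondents with age, sex, anthropometrics (height, weight),
#' physical activity level (PAL), a daily energy target, survey sampling
#' weights, and configured missingness. Heights and BMIs are drawn from
#' age/sex-conditional lognormal-style distributions tuned so that adult
#' obesity prevalence (BMI >= 30) is near one quarter, in line with
#' contemporary English survey estimates.
#'
#' @param config a [synthetic_config()] object.
#' @return data.frame with one row per person: `id`, `age`, `sex`,
#'   `height`, `weight`, `measurement_flag`, `pal`, `survey_weight`,
#'   `energy_target`.
#' @examples
#' people <- generate_population(synthetic_config(n_people = 50, seed = 7))
#' table(people$sex)
#' @export
generate_population <- function(config) {
  if (!inherits(config, "synthetic_config"))
    stop("'config' must be created by synthetic_config()")
  set.seed(derive_seed(config$seed, "population"))
  n <- config$n_people
  ages_all <- seq(config$age_range[1], config$age_range[2])
  # guarantee coverage of every single-year age when n allows, then fill
  age <- if (n >= length(ages_all)) {
    c(ages_all, sample(ages_all, n - length(ages_all), replace = TRUE))
  } else sample(ages_all, n)
  age <- sample(age)  # shuffle so ids are not age-ordered
  sex <- sample(c("male", "female"), n, replace = TRUE)

  child <- age <= 18
  height <- numeric(n); bmi <- numeric(n)
  # children: reference-median height with modest spread; BMI spread wider
  # and shifted above the reference median so that overweight/obesity
  # prevalence matches modern survey levels rather than the reference's
  height[child] <- child_height_median(age[child], sex[child]) *
    exp(stats::rnorm(sum(child), 0, 0.035))
  bmi[child] <- child_bmi_median(age[child], sex[child]) *
    exp(stats::rnorm(sum(child), 0.04, 0.17))
  # adults: fixed mean stature by sex; BMI lognormal with slight age drift
  nm <- sum(!child & sex == "male"); nf <- sum(!child & sex == "female")
  height[!child & sex == "male"]   <- stats::rnorm(nm, 1.75, 0.07)
  height[!child & sex == "female"] <- stats::rnorm(nf, 1.62, 0.065)
  meanlog <- log(24.5 + 0.035 * pmax(age - 18, 0))
  bmi[!child] <- exp(stats::rnorm(sum(!child), meanlog[!child], 0.205))
  weight <- bmi * height^2

  pal <- pmax(stats::rnorm(n, 1.6, 0.15), 1.2)
  survey_weight <- stats::rgamma(n, shape = 1 / config$weight_cv^2,
                                 scale = config$weight_cv^2)

  # daily energy targets (kcal/day) by age and sex
  e_base <- ifelse(child, 1250 + 52 * pmin(age, 17),
                   ifelse(sex == "male", 2280, 1850))
  energy_target <- e_base * exp(stats::rnorm(n, 0, 0.15))

  miss <- config$missingness_rates
  h_miss <- stats::runif(n) < miss$height
  w_miss <- stats::runif(n) < miss$weight
  p_miss <- stats::runif(n) < miss$pal
  flag <- ifelse(h_miss & w_miss, "missing",
                 ifelse(stats::runif(n) < config$self_report_rate,
                        "self_reported", "measured"))
  height[h_miss] <- NA_real_
  weight[w_miss] <- NA_real_
  pal[p_miss] <- NA_real_

  data.frame(id = sprintf("P%05d", seq_len(n)), age = as.integer(age),
             sex = sex, height = height, weight = weight,
             measurement_flag = flag, pal = pal,
             survey_weight = survey_weight,
             energy_target = energy_target,
             stringsAsFactors = FALSE)
}

#' Generate synthetic diet diaries
#'
#' Emits per-day average food items for each person. Each person's
#' in-scope (free) sugar energy is calibrated to the configured share of
#' total energy (7\% for children, 5\% for adults by default, with
#' person-level lognormal variation), spread over several of the ten
#' targeted food categories, plus one out-of-scope filler item carrying
#' the remaining energy. Natural (exempt) sugar is non-zero only in
#' allowance-flagged categories (dairy and dried-fruit-containing).
#'
#' @param people data.frame from [generate_population()].
#' @param config the same [synthetic_config()] object.
#' @return data.frame with one row per person-item: `person_id`,
#'   `category`, `subgroup`, `amount` (g/day), `sugar` (g/day in-scope),
#'   `natural_sugar` (g/day exempt), `energy` (kcal/day).
#' @export
generate_diaries <- function(people, config) {
  if (!is.data.frame(people) || nrow(people) == 0L)
    stop("'people' must be a non-empty data.frame of persons")
  if (!inherits(config, "synthetic_config"))
    stop("'config' must be created by synthetic_config()")
  set.seed(derive_seed(config$seed, "diaries"))
  policy <- default_policy_table()
  mix <- config$category_mix[config$category_mix > 0]
  allow_cats <- policy$category[policy$natural_allowance]

  out <- vector("list", nrow(people))
  for (i in seq_len(nrow(people))) {
    p <- people[i, ]
    target <- if (p$age <= 18) config$target_sugar_share_children
              else config$target_sugar_share_adults
    # person-level variation around the target share, mean-one multiplier
    share <- target * exp(stats::rnorm(1, -0.25^2 / 2, 0.25))
    share <- min(share, 0.25)
    sugar_energy <- share * p$energy_target
    n_cat <- min(length(mix), sample(3:6, 1))
    cats <- sample(names(mix), n_cat, prob = mix)
    alloc <- as.numeric(stats::rgamma(n_cat, shape = 1.2))
    alloc <- sugar_energy * alloc / sum(alloc)
    sugar_g <- alloc / config_sugar_kcal_per_g()
    # targeted categories are sugar-dense, so the portion mechanism
    # removes mostly sugar and only modest non-sugar calories
    item_sugar_share <- stats::runif(n_cat, 0.45, 0.95)
    energy <- alloc / item_sugar_share
    amount <- energy / stats::runif(n_cat, 2.0, 4.5)
    natural <- ifelse(cats %in% allow_cats,
                      config$natural_sugar_fraction * sugar_g, 0)
    rest <- max(p$energy_target - sum(energy), 0)
    # the filler item carries the person's remaining, non-targeted sugars
    # (about 15% of energy) so that reductions can be reported as a share
    # of total baseline sugar intake, as diet surveys do
    filler_sugar_g <- min(0.15 * p$energy_target, 0.8 * rest) /
      config_sugar_kcal_per_g()
    out[[i]] <- data.frame(
      person_id = p$id,
      category = c(cats, "out_of_scope"),
      subgroup = c(paste0(cats, "_item"), "other_foods"),
      amount = c(amount, rest / 2.2),
      sugar = c(sugar_g, filler_sugar_g),
      natural_sugar = c(natural, 0),
      energy = c(energy, rest),
      stringsAsFactors = FALSE)
  }
  items <- do.call(rbind, out)
  items[items$amount > 0, , drop = FALSE]
}

# sugar energy density used by the generator; mirrors the scenario default
config_sugar_kcal_per_g <- function() 3.75

#' Generate synthetic disease parameter tables
#'
#' Builds a long-format parameter table for the eleven modelled chronic
#' diseases: age/sex-specific incidence and case fatality, relative risk
#' per BMI unit (1.0 for lung and stomach cancer, which enter the model
#' only through longevity), relative risk conferred by prevalent diabetes,
#' utility decrement while prevalent, and annual healthcare cost. All
#' magnitudes are synthetic but plausible for an English adult population;
#' they are not estimates from any epidemiological source.
#'
#' @param seed integer seed controlling mild disease-level jitter of the
#'   incidence scale.
#' @param ages integer vector of ages covered (default 18:100).
#' @return data.frame with columns `disease`, `sex`, `age`, `incidence`,
#'   `case_fatality`, `remission`, `rr_per_bmi_unit`, `rr_diabetes`,
#'   `utility_decrement`, `annual_cost`.
#' @export
generate_disease_tables <- function(seed = 1, ages = 18:100) {
  specs <- data.frame(
    disease = c("cardiovascular_disease", "stroke", "diabetes",
                "breast_cancer", "colorectal_cancer", "lung_cancer",
                "stomach_cancer", "cirrhosis", "pancreatic_cancer",
                "kidney_cancer", "liver_cancer"),
    inc0   = c(2.0e-3, 8.0e-4, 3.5e-3, 1.2e-3, 6.0e-4, 5.0e-4,
               1.5e-4, 2.5e-4, 1.2e-4, 1.8e-4, 1.0e-4),
    slope  = c(0.055, 0.070, 0.030, 0.030, 0.055, 0.060,
               0.060, 0.020, 0.060, 0.045, 0.050),
    cf     = c(0.080, 0.100, 0.010, 0.030, 0.100, 0.400,
               0.350, 0.120, 0.500, 0.080, 0.450),
    rr_bmi = c(1.06, 1.05, 1.10, 1.03, 1.03, 1.00,
               1.00, 1.05, 1.02, 1.04, 1.04),
    rr_dia = c(1.80, 1.80, 1.00, 1.00, 1.20, 1.00,
               1.00, 1.00, 1.50, 1.30, 1.40),
    util   = c(0.12, 0.18, 0.05, 0.10, 0.12, 0.20,
               0.18, 0.15, 0.20, 0.12, 0.18),
    cost   = c(2500, 3200, 1500, 4200, 4500, 5200,
               4800, 3000, 5200, 4000, 5000),
    stringsAsFactors = FALSE)
  set.seed(derive_seed(seed, "disease"))
  jitter <- exp(stats::rnorm(nrow(specs), 0, 0.05))
  grid <- expand.grid(disease = specs$disease, sex = c("male", "female"),
                      age = ages, stringsAsFactors = FALSE)
  k <- match(grid$disease, specs$disease)
  inc <- specs$inc0[k] * jitter[k] * exp(specs$slope[k] * (grid$age - 40))
  inc <- pmin(inc, 0.10)
  # female incidence slightly lower for most diseases; breast cancer is
  # female-only
  inc[grid$sex == "female"] <- inc[grid$sex == "female"] * 0.85
  inc[grid$disease == "breast_cancer" & grid$sex == "male"] <- 0
  inc[grid$disease == "breast_cancer" & grid$sex == "female"] <-
    inc[grid$disease == "breast_cancer" & grid$sex == "female"] / 0.85
  data.frame(grid,
             incidence = inc,
             case_fatality = specs$cf[k],
             remission = 0,
             rr_per_bmi_unit = specs$rr_bmi[k],
             rr_diabetes = specs$rr_dia[k],
             utility_decrement = specs$util[k],
             annual_cost = specs$cost[k],
             stringsAsFactors = FALSE)
}

#' Synthetic England-like adult population table
#'
#' Cohort population counts by sex and single year of age for the
#' lifetable model. Counts follow a smooth, England-2014-like shape
#' (roughly 330,000 per single year of age in early adulthood, tapering
#' at older ages); they are synthetic, not official mid-year estimates.
#'
#' @param ages integer vector of ages (default 18:80).
#' @return data.frame with columns `sex`, `age`, `count`.
#' @export
synthetic_population_table <- function(ages = 18:80) {
  taper <- function(a) 335000 * ifelse(a <= 55, 1, exp(-0.025 * (a - 55)))
  grid <- expand.grid(sex = c("male", "female"), age = ages,
                      stringsAsFactors = FALSE)
  grid$count <- taper(grid$age) * ifelse(grid$sex == "female", 1.03, 1.0)
  grid[order(grid$sex, grid$age), ]
}

#' Synthetic background mortality table
#'
#' All-cause background mortality rates (per person-year) by sex and age
#' for causes other than the modelled diseases, following a Gompertz-like
#' schedule.
#'
#' @param ages integer vector of ages (default 18:105).
#' @return data.frame with columns `sex`, `age`, `rate`.
#' @export
background_mortality_table <- function(ages = 18:105) {
  grid <- expand.grid(sex = c("male", "female"), age = ages,
                      stringsAsFactors = FALSE)
  base <- 2.4e-4 * exp(0.088 * (grid$age - 18))
  grid$rate <- base * ifelse(grid$sex == "female", 0.8, 1.0)
  grid[order(grid$sex, grid$age), ]
}

#' Synthetic schedule of unrelated future healthcare costs
#'
#' Annual per-person healthcare cost (currency units/year) for conditions
#' outside the modelled disease set, by sex and age. Applied to
#' incremental life years so that added longevity carries its healthcare
#' cost.
#'
#' @param ages integer vector of ages (default 18:105).
#' @return data.frame with columns `sex`, `age`, `annual_cost`.
#' @export
unrelated_cost_table <- function(ages = 18:105) {
  grid <- expand.grid(sex = c("male", "female"), age = ages,
                      stringsAsFactors = FALSE)
  grid$annual_cost <- 900 + 28 * pmax(grid$age - 40, 0)^1.25
  grid[order(grid$sex, grid$age), ]
}

#' Write the synthetic dataset to CSV files
#'
#' Writes `persons.csv`, `food_items.csv`, `disease_parameters.csv`,
#' `population.csv`, `background_mortality.csv` and `unrelated_costs.csv`
#' into `dir`.
#'
#' @param config a [synthetic_config()] object.
#' @param dir output directory (created if needed).
#' @return invisibly, a named list of the generated data.frames.
#' @export
write_synthetic_data <- function(config, dir) {
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  people <- generate_population(config)
  items <- generate_diaries(people, config)
  diseases <- generate_disease_tables(config$seed)
  pop <- synthetic_population_table()
  mort <- background_mortality_table()
  unrel <- unrelated_cost_table()
  utils::write.csv(people, file.path(dir, "persons.csv"), row.names = FALSE)
  utils::write.csv(items, file.path(dir, "food_items.csv"), row.names = FALSE)
  utils::write.csv(diseases, file.path(dir, "disease_parameters.csv"),
                   row.names = FALSE)
  utils::write.csv(pop, file.path(dir, "population.csv"), row.names = FALSE)
  utils::write.csv(mort, file.path(dir, "background_mortality.csv"),
                   row.names = FALSE)
  utils::write.csv(unrel, file.path(dir, "unrelated_costs.csv"),
                   row.names = FALSE)
  invisible(list(people = people, items = items, diseases = diseases,
                 population = pop, background_mortality = mort,
                 unrelated_costs = unrel))
}
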