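#' Parameters of the children's sugar-to-weight model
#'
#' Children's weight change is modelled from randomised-trial evidence as
#' a linear coefficient: 0.041 kg of body weight per gram of sugar per
#' day (interpreted as the weight difference accrued over two years).
#' Non-sugar calories are deliberately excluded for children.
#'
#' @param kg_per_g_sugar_per_day weight change per gram of daily sugar
#'   (default 0.041 kg per g/day).
#' @param sugar_energy_density kcal per gram of sugar (default 3.75).
#' @return list of class `child_weight_params`.
#' @export
child_weight_params <- function(kg_per_g_sugar_per_day = 0.041,
                                sugar_energy_density = 3.75) {
  if (kg_per_g_sugar_per_day <= 0 || sugar_energy_density <= 0)
    stop("child weight parameters must be positive")
  structure(list(kg_per_g_sugar_per_day = kg_per_g_sugar_per_day,
                 sugar_energy_density = sugar_energy_density),
            class = "child_weight_params")
}

#' Children's weight change from a sugar calorie reduction
#'
#' Converts a daily sugar calorie reduction to grams of sugar (at the
#' configured energy density) and multiplies by the trial-based
#' coefficient. Linear and vectorised.
#'
#' @param sugar_kcal_delta kcal/day of sugar removed (>= 0).
#' @param params [child_weight_params()].
#' @return weight reduction in kg.
#' @examples
#' child_weight_change(23.5)  # 23.5 kcal/day -> about 0.26 kg
#' @export
child_weight_change <- function(sugar_kcal_delta,
                                params = child_weight_params()) {
  if (any(sugar_kcal_delta < 0, na.rm = TRUE))
    stop("'sugar_kcal_delta' is a reduction and must be >= 0")
  (sugar_kcal_delta / params$sugar_energy_density) *
    params$kg_per_g_sugar_per_day
}

#' Parameters of the adult energy-balance weight model
#'
#' The adult model follows the Christiansen-Garby energy-conservation
#' argument: a sustained intake reduction is balanced, at the new
#' equilibrium, by the fall in energy expenditure caused by the lost
#' tissue. Expenditure falls by PAL times the resting energy cost of the
#' lost tissue, which is a mix of fat and lean mass. The defaults use
#' resting energy costs of about 4.5 kcal/kg/day for fat tissue and 19.7
#' kcal/kg/day for lean tissue, with the fat fraction of weight change
#' 0.60 in men and 0.75 in women; all are external physiological
#' constants taken from the energy-metabolism literature and are
#' configurable.
#'
#' @param rmr_coeff_fat resting energy cost of fat tissue, kcal/kg/day.
#' @param rmr_coeff_lean resting energy cost of lean tissue, kcal/kg/day.
#' @param fat_fraction named vector: fraction of weight change that is
#'   fat, by sex.
#' @param pal_default physical activity level used when a person's PAL is
#'   missing.
#' @return list of class `adult_weight_params`.
#' @export
adult_weight_params <- function(rmr_coeff_fat = 4.5,
                                rmr_coeff_lean = 19.7,
                                fat_fraction = c(male = 0.60, female = 0.75),
                                pal_default = 1.6) {
  if (rmr_coeff_fat <= 0 || rmr_coeff_lean <= 0)
    stop("tissue energy coefficients must be positive")
  assert_fraction(fat_fraction, "fat_fraction")
  if (!all(c("male", "female") %in% names(fat_fraction)))
    stop("'fat_fraction' must name male and female")
  structure(list(rmr_coeff_fat = rmr_coeff_fat,
                 rmr_coeff_lean = rmr_coeff_lean,
                 fat_fraction = fat_fraction,
                 pal_default = pal_default),
            class = "adult_weight_params")
}

#' Adult equilibrium weight change from a calorie reduction
#'
#' Solves the energy-balance equation at the new steady state: the intake
#' reduction `delta_kcal` equals PAL times the resting energy cost of the
#' lost tissue,
#' \deqn{\Delta I = PAL \times (f c_{fat} + (1-f) c_{lean}) \times \Delta W,}
#' giving the closed form
#' \eqn{\Delta W = \Delta I / (PAL (f c_{fat} + (1-f) c_{lean}))}.
#' Both sugar and non-sugar calorie reductions enter. Monotone increasing
#' in the calorie reduction and decreasing in PAL.
#'
#' @param total_kcal_delta kcal/day removed (sugar plus non-sugar; >= 0).
#' @param pal physical activity level(s); missing values take
#'   `params$pal_default`.
#' @param sex "male"/"female", recycled against `total_kcal_delta`.
#' @param params [adult_weight_params()].
#' @return equilibrium weight reduction in kg.
#' @examples
#' adult_weight_change(26.3, pal = 1.6, sex = "male")
#' @export
adult_weight_change <- function(total_kcal_delta, pal = NA, sex,
                                params = adult_weight_params()) {
  if (any(total_kcal_delta < 0, na.rm = TRUE))
    stop("'total_kcal_delta' is a reduction and must be >= 0")
  pal <- ifelse(is.na(pal), params$pal_default, pal)
  if (any(pal <= 0)) stop("PAL must be positive")
  f <- params$fat_fraction[sex]
  tissue_cost <- f * params$rmr_coeff_fat + (1 - f) * params$rmr_coeff_lean
  unname(total_kcal_delta / (pal * tissue_cost))
}

#' BMI change from a weight change
#'
#' @param weight_delta weight reduction in kg.
#' @param height height in metres (must be non-missing: imputation runs
#'   before this step).
#' @return BMI reduction, kg/m^2.
#' @export
bmi_change <- function(weight_delta, height) {
  if (any(is.na(height)))
    stop("missing height at BMI step: imputation must run first")
  weight_delta / height^2
}

#' Child BMI category reference table
#'
#' Loads the bundled table of child BMI-for-age category cut-offs (-2 SD,
#' +1 SD, +2 SD around the reference median) by sex and age. The bundled
#' file is a synthetic approximation of the WHO 2007 growth-reference
#' cut-offs, smooth in age and anchored so the +1 SD and +2 SD curves
#' approach the adult 25 and 30 thresholds at age 19; replace it with the
#' official values via `path` for real analyses. Four-year-olds use the
#' five-year-old cut-offs.
#'
#' @param path optional CSV with columns `sex`, `age_years`,
#'   `cut_minus2sd`, `cut_plus1sd`, `cut_plus2sd`.
#' @return data.frame of cut-offs.
#' @export
load_bmi_reference <- function(path = NULL) {
  if (is.null(path))
    path <- system.file("extdata", "child_bmi_cutoffs_synthetic.csv",
                        package = "sugarsim", mustWork = TRUE)
  ref <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("sex", "age_years", "cut_minus2sd", "cut_plus1sd", "cut_plus2sd")
  miss <- setdiff(need, names(ref))
  if (length(miss)) stop("BMI reference missing columns: ",
                         paste(miss, collapse = ", "))
  bad <- with(ref, cut_minus2sd >= cut_plus1sd | cut_plus1sd >= cut_plus2sd)
  if (any(bad)) stop("BMI reference cut-offs must be strictly increasing")
  ref
}

# fixed adult thresholds with half-open bands: >= lower, < upper
adult_bmi_breaks <- c(18.5, 25.0, 30.0, 35.0)

#' Classify BMI into weight-status categories
#'
#' Children (ages 4-18) are classified against the age/sex reference
#' cut-offs: underweight below -2 SD, normal up to +1 SD, overweight up
#' to and including +2 SD, and obese strictly above +2 SD. Adults use the
#' fixed thresholds 18.5 / 25 / 30 / 35 with half-open bands (a BMI of
#' exactly 30 is obese; exactly 35 is very obese).
#'
#' @param age integer age(s) in years.
#' @param sex "male"/"female".
#' @param bmi BMI value(s).
#' @param reference child cut-off table from [load_bmi_reference()].
#' @return factor with levels underweight, normal, overweight, obese,
#'   very_obese.
#' @export
classify_bmi <- function(age, sex, bmi, reference = load_bmi_reference()) {
  n <- max(length(age), length(sex), length(bmi))
  age <- rep_len(age, n); sex <- rep_len(sex, n); bmi <- rep_len(bmi, n)
  lvls <- c("underweight", "normal", "overweight", "obese", "very_obese")
  out <- character(n)
  child <- age <= 18
  if (any(child)) {
    if (any(age[child] < 4))
      stop("age below the BMI reference range (children start at 4)")
    ref_age <- pmax(age[child], 5)  # 4-year-olds take the 5-year cut-offs
    k <- match(paste(sex[child], ref_age),
               paste(reference$sex, reference$age_years))
    if (any(is.na(k)))
      stop("child age outside BMI reference table: ",
           paste(unique(ref_age[is.na(k)]), collapse = ", "))
    b <- bmi[child]
    out[child] <- ifelse(b < reference$cut_minus2sd[k], "underweight",
                  ifelse(b <= reference$cut_plus1sd[k], "normal",
                  ifelse(b <= reference$cut_plus2sd[k], "overweight",
                         "obese")))
  }
  if (any(!child)) {
    b <- bmi[!child]
    out[!child] <- ifelse(b < 18.5, "underweight",
                   ifelse(b < 25, "normal",
                   ifelse(b < 30, "overweight",
                   ifelse(b < 35, "obese", "very_obese"))))
  }
  factor(out, levels = lvls)
}

#' Weight-status prevalence before and after the intervention
#'
#' Survey-weighted prevalence of each BMI category by age band and sex,
#' at baseline and under the scenario, with the change in the obese
#' classes (obese plus very obese) expressed both as a percentage of
#' baseline obese cases and in percentage points.
#'
#' @param people persons data.frame (`id`, `age`, `sex`,
#'   `survey_weight`).
#' @param bmi_baseline,bmi_scenario BMI vectors aligned with `people`.
#' @param reference child cut-off table.
#' @return list with `prevalence` (band x sex x category rows with
#'   baseline/scenario shares) and `obese_change` (band x sex rows with
#'   `pct_of_baseline_obese` and `percentage_points`).
#' @export
prevalence_table <- function(people, bmi_baseline, bmi_scenario,
                             reference = load_bmi_reference()) {
  stopifnot(nrow(people) == length(bmi_baseline),
            nrow(people) == length(bmi_scenario))
  cat_b <- classify_bmi(people$age, people$sex, bmi_baseline, reference)
  cat_s <- classify_bmi(people$age, people$sex, bmi_scenario, reference)
  band <- age_band(people$age)
  w <- people$survey_weight
  groups <- split(seq_len(nrow(people)), list(band, people$sex), drop = TRUE)
  prev_rows <- list(); obese_rows <- list()
  for (g in names(groups)) {
    i <- groups[[g]]
    tw <- sum(w[i])
    lvls <- levels(cat_b)
    pb <- vapply(lvls, function(l) sum(w[i][cat_b[i] == l]) / tw, numeric(1))
    ps <- vapply(lvls, function(l) sum(w[i][cat_s[i] == l]) / tw, numeric(1))
    parts <- strsplit(g, "\\.")[[1]]
    prev_rows[[g]] <- data.frame(band = parts[1], sex = parts[2],
                                 category = lvls, baseline = pb,
                                 scenario = ps, stringsAsFactors = FALSE)
    ob <- c("obese", "very_obese")
    base_ob <- sum(pb[ob]); scen_ob <- sum(ps[ob])
    obese_rows[[g]] <- data.frame(
      band = parts[1], sex = parts[2],
      baseline_obese = base_ob, scenario_obese = scen_ob,
      pct_of_baseline_obese = if (base_ob > 0)
        100 * (base_ob - scen_ob) / base_ob else 0,
      percentage_points = 100 * (base_ob - scen_ob),
      stringsAsFactors = FALSE)
  }
  prevalence <- do.call(rbind, prev_rows)
  obese_change <- do.call(rbind, obese_rows)
  rownames(prevalence) <- rownames(obese_change) <- NULL
  list(prevalence = prevalence, obese_change = obese_change)
}

#' Smooth age-specific BMI means with a 3-year rolling average
#'
#' Sensitivity helper: replaces, within each sex, the single-age mean of
#' the supplied BMI values with its 3-year rolling average (window age-1
#' to age+1), preserving each individual's deviation from the age mean.
#' Reduces the volatility of small single-age groups.
#'
#' @param people persons data.frame (`age`, `sex`).
#' @param bmi BMI vector aligned with `people`.
#' @return smoothed BMI vector.
#' @export
smooth_bmi_3yr <- function(people, bmi) {
  out <- bmi
  for (s in unique(people$sex)) {
    sel <- people$sex == s
    ages <- sort(unique(people$age[sel]))
    mu <- vapply(ages, function(a) mean(bmi[sel & people$age == a]),
                 numeric(1))
    mu_s <- vapply(seq_along(ages), function(j) {
      win <- abs(ages - ages[j]) <= 1
      mean(mu[win])
    }, numeric(1))
    shift <- mu_s - mu
    out[sel] <- bmi[sel] + shift[match(people$age[sel], ages)]
  }
  out
}
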