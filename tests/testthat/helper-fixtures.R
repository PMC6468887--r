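# Small fixtures shared across test files; everything is built in code.

make_item <- function(category = "sweet_spreads_sauces", sugar = 10,
                      natural = 0, energy = 100, amount = 50,
                      person_id = "p1") {
  data.frame(person_id = person_id, category = category,
             subgroup = "test", amount = amount, sugar = sugar,
             natural_sugar = natural, energy = energy,
             stringsAsFactors = FALSE)
}

# constant-rate disease table over an age range, one row per sex x age
make_disease_table <- function(name = "disease_a", incidence = 0.01,
                               case_fatality = 0.05, remission = 0,
                               rr_per_bmi_unit = 1.05, rr_diabetes = 1,
                               utility_decrement = 0.1, annual_cost = 1000,
                               ages = 18:105) {
  grid <- expand.grid(sex = c("male", "female"), age = ages,
                      stringsAsFactors = FALSE)
  data.frame(disease = name, grid, incidence = incidence,
             case_fatality = case_fatality, remission = remission,
             rr_per_bmi_unit = rr_per_bmi_unit, rr_diabetes = rr_diabetes,
             utility_decrement = utility_decrement,
             annual_cost = annual_cost, stringsAsFactors = FALSE)
}

make_population <- function(ages = c(40, 60), count = 1000) {
  grid <- expand.grid(sex = c("male", "female"), age = ages,
                      stringsAsFactors = FALSE)
  grid$count <- count
  grid
}

make_bg_mortality <- function(rate = 0.005, ages = 18:130) {
  grid <- expand.grid(sex = c("male", "female"), age = ages,
                      stringsAsFactors = FALSE)
  grid$rate <- rate
  grid
}

make_unrelated <- function(cost = 0, ages = 18:130) {
  grid <- expand.grid(sex = c("male", "female"), age = ages,
                      stringsAsFactors = FALSE)
  grid$annual_cost <- cost
  grid
}

age_band_of <- function(person_id, people) {
  age <- people$age[match(person_id, people$id)]
  ifelse(age <= 10, "4-10", ifelse(age <= 18, "11-18", "19-80"))
}

# small adult panel with fixed BMI values for lifetable input
make_adults <- function(n = 6, bmi = NULL, sex = NULL) {
  if (is.null(sex)) sex <- rep(c("male", "female"), length.out = n)
  if (is.null(bmi)) bmi <- seq(24, 34, length.out = n)
  data.frame(id = paste0("a", seq_len(n)), sex = sex,
             survey_weight = rep(1, n), bmi = bmi,
             stringsAsFactors = FALSE)
}
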