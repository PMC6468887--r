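# brute-force PIF oracle: explicit sums, independent of the vectorised code
pif_brute <- function(b, s, w, rr, ref) {
  num <- 0; den <- 0
  for (i in seq_along(b)) {
    num <- num + w[i] * rr^(b[i] - ref) - w[i] * rr^(s[i] - ref)
    den <- den + w[i] * rr^(b[i] - ref)
  }
  num / den
}

test_that("PIF is zero for identical distributions or flat relative risk", {
  b <- c(24, 28, 33)
  expect_equal(pif(b, b, rr = 1.1), 0)
  expect_equal(pif(b, b - 1, rr = 1), 0)
})

test_that("PIF reproduces the two-person hand example of 1/3", {
  # baseline RRs (2, 1), scenario RRs (1, 1): (3 - 2) / 3
  expect_equal(pif(c(23, 22), c(22, 22), c(1, 1), rr = 2, ref = 22), 1 / 3)
})

test_that("PIF equals brute-force summation on small random distributions", {
  set.seed(41)
  for (k in 1:25) {
    n <- sample(1:10, 1)
    b <- runif(n, 20, 40)
    s <- b - runif(n, 0, 2)
    w <- runif(n, 0.2, 3)
    rr <- runif(1, 1, 1.3)
    expect_equal(pif(b, s, w, rr = rr, ref = 22),
                 pif_brute(b, s, w, rr, 22), tolerance = 1e-12)
  }
  expect_error(pif(c(1, 2), c(1, 2), weights = 1, rr = 1.1), "weights")
  expect_error(pif(numeric(0), numeric(0), rr = 1.1), "empty")
})

test_that("single-disease prevalence matches the analytic illness-death solution", {
  i <- 0.02; f <- 0.05
  s <- 1; c <- 0
  for (t in 1:50) {
    upd <- sugarsim:::step_disease(s, c, i, f)
    s <- upd$s; c <- upd$c
    # closed form of the constant-rate system at time t
    s_exact <- exp(-i * t)
    c_exact <- i * (exp(-i * t) - exp(-f * t)) / (f - i)
    expect_equal(s, s_exact, tolerance = 1e-6)
    expect_equal(c, c_exact, tolerance = 1e-6)
    expect_equal(c / (s + c), c_exact / (s_exact + c_exact),
                 tolerance = 1e-6)
  }
})

test_that("step_disease handles the equal-rate and remission cases", {
  # i == f: repeated eigenvalue limit c(t) = i t e^{-i t}
  upd <- sugarsim:::step_disease(1, 0, 0.03, 0.03)
  expect_equal(upd$c, 0.03 * exp(-0.03), tolerance = 1e-9)
  # zero rates: identity
  upd0 <- sugarsim:::step_disease(0.7, 0.2, 0, 0)
  expect_equal(upd0$s, 0.7)
  expect_equal(upd0$c, 0.2)
  # with remission, mass is conserved when there is no case fatality
  upd_r <- sugarsim:::step_disease(0.6, 0.4, 0.1, 0, r = 0.2)
  expect_equal(upd_r$s + upd_r$c, 1, tolerance = 1e-9)
})

test_that("with no disease the life years equal the plain lifetable value", {
  dis <- make_disease_table(incidence = 0, case_fatality = 0)
  pop <- make_population(ages = c(40, 60), count = 1000)
  bg <- make_bg_mortality(rate = 0.01)
  adults <- make_adults()
  res <- run_lifetable(adults, rep(30, 6), rep(30, 6), dis,
                       population = pop, background_mortality = bg,
                       unrelated_costs = make_unrelated(0), horizon = 10)
  # oracle: N_t = 1000 e^{-0.01 t}, LY = sum (N_t + N_{t+1})/2
  Nt <- 1000 * exp(-0.01 * (0:10))
  ly_exact <- sum((Nt[-11] + Nt[-1]) / 2)
  expect_equal(sum(res$baseline$life_years), 4 * ly_exact,
               tolerance = 1e-10)
  expect_true(all(res$baseline$cases == 0))
})

test_that("cohort conservation holds exactly at every step", {
  dis <- make_disease_table(incidence = 0.02, case_fatality = 0.1)
  pop <- make_population(ages = c(30, 50, 70), count = 500)
  res <- run_lifetable(make_adults(), seq(26, 36, 2), seq(25, 35, 2), dis,
                       population = pop,
                       background_mortality = make_bg_mortality(0.008),
                       unrelated_costs = make_unrelated(100), horizon = 25)
  for (arm in list(res$baseline, res$scenario))
    expect_equal(unname(arm$final_pop + arm$deaths), pop$count,
                 tolerance = 1e-12)
})

test_that("a null intervention produces exactly zero deltas", {
  dis <- rbind(make_disease_table("diabetes", 0.004, 0.01,
                                  rr_per_bmi_unit = 1.1),
               make_disease_table("cvd", 0.01, 0.08, rr_per_bmi_unit = 1.06,
                                  rr_diabetes = 1.8))
  bmi <- seq(24, 36, 2)
  res <- run_lifetable(make_adults(7, bmi), bmi, bmi, dis,
                       population = make_population(),
                       background_mortality = make_bg_mortality(),
                       unrelated_costs = make_unrelated(500), horizon = 15)
  expect_identical(res$by_sex$qalys_gained, c(0, 0))
  expect_identical(res$by_sex$life_years_gained, c(0, 0))
  expect_identical(res$by_sex$cost_change, c(0, 0))
  expect_identical(res$cases$cases_change, rep(0, 4))
})

test_that("BMI-linked diseases are averted; longevity-only diseases rise", {
  dis <- rbind(make_disease_table("fatal_bmi_disease", 0.02, 0.3,
                                  rr_per_bmi_unit = 1.1),
               make_disease_table("longevity_only", 0.005, 0.1,
                                  rr_per_bmi_unit = 1.0))
  bmi_b <- seq(26, 38, 2)
  res <- run_lifetable(make_adults(7, bmi_b), bmi_b, bmi_b - 1, dis,
                       population = make_population(ages = c(50, 65)),
                       background_mortality = make_bg_mortality(0.01),
                       unrelated_costs = make_unrelated(0), horizon = 30)
  averted <- res$cases$cases_change[res$cases$disease == "fatal_bmi_disease"]
  expect_true(all(averted < 0))
  expect_true(all(res$by_sex$life_years_gained > 0))
  rises <- res$cases$cases_change[res$cases$disease == "longevity_only"]
  expect_true(all(rises >= 0))
})

test_that("diabetes risk-factor coupling amplifies averted cases downstream", {
  base_dis <- rbind(make_disease_table("diabetes", 0.006, 0.02,
                                       rr_per_bmi_unit = 1.1),
                    make_disease_table("cvd", 0.01, 0.1,
                                       rr_per_bmi_unit = 1.06,
                                       rr_diabetes = 1.0))
  coupled <- base_dis
  coupled$rr_diabetes[coupled$disease == "cvd"] <- 2.0
  bmi_b <- seq(26, 38, 2)
  args <- list(adults = make_adults(7, bmi_b), bmi_baseline = bmi_b,
               bmi_scenario = bmi_b - 1,
               population = make_population(ages = c(45, 60)),
               background_mortality = make_bg_mortality(0.005),
               unrelated_costs = make_unrelated(0), horizon = 20)
  res0 <- do.call(run_lifetable, c(args, list(diseases = base_dis)))
  res1 <- do.call(run_lifetable, c(args, list(diseases = coupled)))
  cvd0 <- sum(res0$cases$cases_change[res0$cases$disease == "cvd"])
  cvd1 <- sum(res1$cases$cases_change[res1$cases$disease == "cvd"])
  # with the coupling, falling diabetes prevalence averts extra cvd cases
  expect_lt(cvd1, cvd0)
})

test_that("longer horizons accumulate at least as many QALYs", {
  dis <- make_disease_table(incidence = 0.01, case_fatality = 0.1,
                            rr_per_bmi_unit = 1.08)
  bmi_b <- seq(26, 36, 2)
  args <- list(adults = make_adults(6, bmi_b), bmi_baseline = bmi_b,
               bmi_scenario = bmi_b - 0.7, diseases = dis,
               population = make_population(),
               background_mortality = make_bg_mortality(),
               unrelated_costs = make_unrelated(200))
  q10 <- sum(do.call(run_lifetable, c(args, list(horizon = 10)))$by_sex$qalys_gained)
  q30 <- sum(do.call(run_lifetable, c(args, list(horizon = 30)))$by_sex$qalys_gained)
  expect_gt(q30, q10)
  expect_gt(q10, 0)
})

test_that("Monte Carlo with fixed parameters collapses to zero-width intervals", {
  dis <- make_disease_table(incidence = 0.01, case_fatality = 0.05)
  fn <- function(d) c(out = d$annual_cost[1] + d$rr_per_bmi_unit[1])
  res <- monte_carlo(fn, dis, mc_config(n_runs = 50, seed = 1,
                                        vary = character(0)))
  expect_equal(res$lower, res$upper)
  expect_equal(res$mean, res$lower)
})

test_that("Monte Carlo is reproducible given the seed", {
  dis <- make_disease_table(incidence = 0.01)
  fn <- function(d) c(rr = d$rr_per_bmi_unit[1], cost = d$annual_cost[1])
  r1 <- monte_carlo(fn, dis, mc_config(n_runs = 200, seed = 7))
  r2 <- monte_carlo(fn, dis, mc_config(n_runs = 200, seed = 7))
  expect_identical(as.data.frame(r1), as.data.frame(r2))
  r3 <- monte_carlo(fn, dis, mc_config(n_runs = 200, seed = 8))
  expect_false(identical(r1$mean, r3$mean))
})

test_that("pass-through interval matches the sampling distribution's centiles", {
  dis <- make_disease_table(annual_cost = 1000)
  cv <- 0.10
  fn <- function(d) c(cost = d$annual_cost[1])
  res <- monte_carlo(fn, dis, mc_config(n_runs = 2000, seed = 3,
                                        vary = "cost", cost_cv = cv))
  shape <- 1 / cv^2
  theo <- qgamma(c(0.025, 0.975), shape = shape, scale = 1000 / shape)
  # Monte Carlo error at n = 2000 is a few percent in the tails
  expect_lt(abs(res$lower - theo[1]) / theo[1], 0.03)
  expect_lt(abs(res$upper - theo[2]) / theo[2], 0.03)
  # longevity-only diseases never acquire a BMI link in perturbation
  dis1 <- make_disease_table(rr_per_bmi_unit = 1)
  fnrr <- function(d) c(rr = d$rr_per_bmi_unit[1])
  resrr <- monte_carlo(fnrr, dis1, mc_config(n_runs = 20, seed = 2))
  expect_equal(resrr$lower, 1)
  expect_equal(resrr$upper, 1)
})
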