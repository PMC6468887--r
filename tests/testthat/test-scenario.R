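test_that("reformulation removes 20% of eligible sugar and its energy", {
  out <- apply_policy_to_item(make_item(sugar = 10, natural = 0,
                                        energy = 100))
  expect_equal(out$sugar, 8)
  expect_equal(out$energy, 92.5)
  expect_equal(out$amount, 50)  # product size unchanged

  # natural allowance: only the non-exempt sugar is cut
  out2 <- apply_policy_to_item(make_item(sugar = 10, natural = 2,
                                         energy = 100))
  expect_equal(out2$sugar, (10 - 2) * 0.8 + 2)
})

test_that("portion mechanism scales the whole item uniformly", {
  item <- make_item(category = "chocolate_confectionery", sugar = 10,
                    energy = 100, amount = 100)
  out <- apply_policy_to_item(item)
  expect_equal(out$amount, 80)
  expect_equal(out$sugar, 8)
  expect_equal(out$energy, 80)
  expect_equal(out$nonsugar_kcal, 20 - 2 * 3.75)
})

test_that("equal split across mechanisms preserves the 20% sugar total", {
  # cakes: reformulation + portion, each takes half the 20%
  item <- make_item(category = "cakes", sugar = 10, energy = 100,
                    amount = 100)
  out <- apply_policy_to_item(item)
  expect_equal(out$sugar_removed_g, 2)        # full 20% of 10 g
  expect_equal(out$kcal_reformulation, 1 * 3.75)
  expect_equal(out$kcal_portion, 10)          # 10% of 100 kcal
  expect_equal(out$amount, 90)
  # three-mechanism category: shares of 20/3 % each
  item3 <- make_item(category = "biscuits", sugar = 9, energy = 90)
  out3 <- apply_policy_to_item(item3)
  expect_equal(out3$sugar_removed_g, 0.2 * 9, tolerance = 1e-12)
})

test_that("out-of-scope items and zero reduction are strict no-ops", {
  item <- make_item(category = "out_of_scope", sugar = 5, energy = 80)
  out <- apply_policy_to_item(item)
  expect_equal(out$sugar, 5)
  expect_equal(out$energy, 80)
  expect_equal(out$sugar_removed_g, 0)

  p0 <- scenario_params(reduction_fraction = 0)
  items <- generate_diaries(
    generate_population(synthetic_config(n_people = 40, seed = 8)),
    synthetic_config(n_people = 40, seed = 8))
  out0 <- apply_scenario(items, params = p0)
  expect_equal(out0$sugar, items$sugar)
  expect_equal(out0$energy, items$energy)
  expect_equal(out0$amount, items$amount)
  expect_true(all(out0$sugar_removed_g == 0))
})

test_that("energy conservation holds exactly for every item", {
  cfg <- synthetic_config(n_people = 150, seed = 4)
  items <- generate_diaries(generate_population(cfg), cfg)
  out <- apply_scenario(items)
  expect_equal(out$energy,
               out$energy_baseline - out$sugar_removed_g * 3.75 -
                 out$nonsugar_kcal,
               tolerance = 1e-12)
})

test_that("mechanism attributions add up to each person's total delta", {
  cfg <- synthetic_config(n_people = 120, seed = 13)
  items <- generate_diaries(generate_population(cfg), cfg)
  d <- person_calorie_delta(items)
  expect_equal(d$kcal_reformulation + d$kcal_portion + d$kcal_sales_weighting,
               d$total_kcal, tolerance = 1e-9)
  expect_equal(d$sugar_kcal + d$nonsugar_kcal, d$total_kcal,
               tolerance = 1e-9)
  expect_true(all(d$sugar_kcal >= 0 & d$nonsugar_kcal >= -1e-12))
})

test_that("disabling a mechanism never increases any person's delta", {
  cfg <- synthetic_config(n_people = 100, seed = 21)
  items <- generate_diaries(generate_population(cfg), cfg)
  full <- person_calorie_delta(items)
  for (m in c("reformulation", "portion", "sales_weighting")) {
    p <- scenario_params(mechanisms_enabled = setdiff(
      c("reformulation", "portion", "sales_weighting"), m))
    reduced <- person_calorie_delta(items, params = p)
    expect_true(all(reduced$total_kcal <= full$total_kcal + 1e-9),
                info = paste("excluding", m))
  }
  # all mechanisms disabled: zero delta for everyone
  none <- person_calorie_delta(items,
    params = scenario_params(mechanisms_enabled = character(0)))
  expect_true(all(none$total_kcal == 0))
})

test_that("person deltas are linear in sugar content", {
  item <- make_item(sugar = 10, natural = 0, energy = 200)
  d1 <- person_calorie_delta(item)
  item2 <- item; item2$sugar <- 20
  d2 <- person_calorie_delta(item2)
  expect_equal(d2$sugar_kcal, 2 * d1$sugar_kcal)
})

test_that("cohort summary matches a hand-computed weighted mean", {
  people <- data.frame(id = c("p1", "p2", "p3"), age = c(30, 40, 50),
                       sex = "female", survey_weight = c(1, 2, 3),
                       stringsAsFactors = FALSE)
  deltas <- data.frame(person_id = c("p1", "p2", "p3"),
                       sugar_kcal = c(10, 20, 30),
                       nonsugar_kcal = c(1, 2, 3),
                       kcal_reformulation = c(10, 20, 30),
                       kcal_portion = c(1, 2, 3),
                       kcal_sales_weighting = 0,
                       baseline_sugar_kcal = c(100, 100, 100),
                       baseline_energy_kcal = c(2000, 2000, 2000),
                       total_kcal = c(11, 22, 33),
                       stringsAsFactors = FALSE)
  s <- cohort_summary(deltas, people)
  # brute-force weighted mean: (10*1 + 20*2 + 30*3) / 6
  expect_equal(s$sugar_kcal, (10 + 40 + 90) / 6)
  expect_equal(s$nonsugar_kcal, (1 + 4 + 9) / 6)
  expect_equal(s$pct_of_baseline_sugar, 100 * ((10 + 40 + 90) / 6) / 100)
  # uniform weights reduce to the arithmetic mean
  people$survey_weight <- 1
  s2 <- cohort_summary(deltas, people)
  expect_equal(s2$sugar_kcal, mean(c(10, 20, 30)))
})

test_that("the default policy table mirrors the programme's mechanism grid", {
  pol <- default_policy_table()
  expect_equal(nrow(pol), 10)
  expect_true(all(rowSums(pol[, c("reformulation", "portion",
                                  "sales_weighting")]) >= 1))
  # spot checks of the published mechanism assignment
  expect_true(pol$sales_weighting[pol$category == "breakfast_cereals"])
  expect_false(pol$portion[pol$category == "breakfast_cereals"])
  expect_true(all(unlist(pol[pol$category == "yogurts",
                             c("reformulation", "portion",
                               "sales_weighting")])))
  expect_false(pol$reformulation[pol$category == "chocolate_confectionery"])
})

test_that("policy tables round-trip through CSV", {
  dir <- withr::local_tempdir()
  path <- file.path(dir, "policy.csv")
  write.csv(default_policy_table(), path, row.names = FALSE)
  back <- read_policy_table(path)
  expect_equal(back, default_policy_table())
})
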