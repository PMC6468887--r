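#' Apply the sugar reduction scenario to a table of food items
#'
#' Core scenario arithmetic. For every item in an in-scope category the
#' category's mechanisms each remove an equal share of the target
#' reduction (default 20\%):
#' \itemize{
#'   \item \emph{reformulation} and \emph{sales weighting} remove their
#'     share of the item's allowance-adjusted sugar mass, and the energy
#'     of the removed grams (at `sugar_energy_density` kcal/g);
#'   \item \emph{portion} scales the whole item (amount, sugar, natural
#'     sugar, energy) down by its share, so non-sugar calories are
#'     removed too.
#' }
#' For categories carrying a natural-sugar allowance, the exempt grams are
#' subtracted before the percentage cut and added back afterwards, so only
#' the non-exempt sugar is reduced by the sugar-only mechanisms. When a
#' mechanism is disabled (`mechanisms_enabled`), its share of the
#' reduction is lost, not redistributed.
#'
#' @param items data.frame of food items as from [generate_diaries()]
#'   (columns `person_id`, `category`, `amount`, `sugar`,
#'   `natural_sugar`, `energy`).
#' @param policy policy table as from [default_policy_table()].
#' @param params a [scenario_params()] object.
#' @return the items with adjusted `amount`, `sugar`, `natural_sugar`,
#'   `energy`, plus attribution columns `sugar_removed_g`,
#'   `kcal_reformulation`, `kcal_portion`, `kcal_sales_weighting`,
#'   `nonsugar_kcal` and the baseline values `energy_baseline`,
#'   `sugar_baseline`.
#' @export
apply_scenario <- function(items, policy = default_policy_table(),
                           params = scenario_params()) {
  stopifnot(is.data.frame(items))
  need <- c("person_id", "category", "amount", "sugar", "natural_sugar",
            "energy")
  miss <- setdiff(need, names(items))
  if (length(miss)) stop("items missing columns: ",
                         paste(miss, collapse = ", "))
  validate_policy_table(policy)
  if (any(items$sugar < items$natural_sugar) || any(items$natural_sugar < 0))
    stop("item invariant violated: need sugar >= natural_sugar >= 0")

  k <- match(items$category, policy$category)  # NA = out of scope
  in_scope <- !is.na(k)
  r <- params$reduction_fraction
  dens <- params$sugar_energy_density

  mech_on <- function(m) {
    on <- rep(FALSE, nrow(items))
    on[in_scope] <- policy[[m]][k[in_scope]] & (m %in% params$mechanisms_enabled)
    on
  }
  # the equal split is over the category's full mechanism set, so a
  # disabled mechanism's share is simply lost
  n_mech <- rep(0, nrow(items))
  n_mech[in_scope] <- rowSums(policy[k[in_scope],
                      c("reformulation", "portion", "sales_weighting")])
  share <- ifelse(n_mech > 0, r / pmax(n_mech, 1), 0)

  eligible <- items$sugar - items$natural_sugar  # allowance-adjusted sugar

  ref_on <- mech_on("reformulation")
  sal_on <- mech_on("sales_weighting")
  por_on <- mech_on("portion")

  sug_ref <- ifelse(ref_on, share * eligible, 0)
  sug_sal <- ifelse(sal_on, share * eligible, 0)
  # portion shrinks the physical product uniformly, exempt sugar included
  sug_por <- ifelse(por_on, share * items$sugar, 0)
  kcal_por <- ifelse(por_on, share * items$energy, 0)

  out <- items
  out$sugar_removed_g <- sug_ref + sug_sal + sug_por
  out$kcal_reformulation <- sug_ref * dens
  out$kcal_sales_weighting <- sug_sal * dens
  out$kcal_portion <- kcal_por
  out$nonsugar_kcal <- kcal_por - sug_por * dens
  out$energy_baseline <- items$energy
  out$sugar_baseline <- items$sugar

  out$sugar <- items$sugar - out$sugar_removed_g
  out$natural_sugar <- items$natural_sugar * ifelse(por_on, 1 - share, 1)
  out$energy <- items$energy - out$sugar_removed_g * dens - out$nonsugar_kcal
  out$amount <- items$amount * ifelse(por_on, 1 - share, 1)

  if (any(out$sugar < -1e-9) || any(out$energy < -1e-9))
    stop("scenario produced negative sugar or energy; input nutrient data ",
         "are inconsistent (energy too low for stated sugar)")
  out
}

#' Apply the scenario to a single food item
#'
#' Convenience wrapper around [apply_scenario()] for one item.
#'
#' @param item one-row data.frame (or list coercible to one).
#' @inheritParams apply_scenario
#' @return one-row data.frame as returned by [apply_scenario()].
#' @examples
#' item <- data.frame(person_id = "p1", category = "sweet_spreads_sauces",
#'                    amount = 50, sugar = 10, natural_sugar = 0, energy = 100)
#' apply_policy_to_item(item)  # reformulation-only category: 20% sugar cut
#' @export
apply_policy_to_item <- function(item, policy = default_policy_table(),
                                 params = scenario_params()) {
  item <- as.data.frame(item, stringsAsFactors = FALSE)
  if (nrow(item) != 1L) stop("'item' must be a single food item")
  apply_scenario(item, policy, params)
}

#' Per-person calorie reduction under the scenario
#'
#' Aggregates item-level removals to one row per person: sugar calories
#' removed, non-sugar calories removed (portion mechanism only), the
#' attribution to each mechanism, and the person's baseline sugar and
#' total energy.
#'
#' @param items scenario output from [apply_scenario()]; alternatively raw
#'   items plus `policy`/`params`, in which case the scenario is applied
#'   first.
#' @inheritParams apply_scenario
#' @return data.frame with one row per person: `person_id`, `sugar_kcal`,
#'   `nonsugar_kcal`, `total_kcal`, `kcal_reformulation`, `kcal_portion`,
#'   `kcal_sales_weighting`, `baseline_sugar_kcal`, `baseline_energy_kcal`.
#' @export
person_calorie_delta <- function(items, policy = default_policy_table(),
                                 params = scenario_params()) {
  if (!"sugar_removed_g" %in% names(items))
    items <- apply_scenario(items, policy, params)
  dens <- params$sugar_energy_density
  agg <- function(x) tapply(x, items$person_id, sum)
  ids <- sort(unique(items$person_id))
  d <- data.frame(
    person_id = ids,
    sugar_kcal = as.numeric(agg(items$sugar_removed_g * dens)[ids]),
    nonsugar_kcal = as.numeric(agg(items$nonsugar_kcal)[ids]),
    kcal_reformulation = as.numeric(agg(items$kcal_reformulation)[ids]),
    kcal_portion = as.numeric(agg(items$kcal_portion)[ids]),
    kcal_sales_weighting = as.numeric(agg(items$kcal_sales_weighting)[ids]),
    baseline_sugar_kcal = as.numeric(agg(items$sugar_baseline * dens)[ids]),
    baseline_energy_kcal = as.numeric(agg(items$energy_baseline)[ids]),
    stringsAsFactors = FALSE)
  d$total_kcal <- d$sugar_kcal + d$nonsugar_kcal
  d
}

#' Cohort summary of calorie reductions
#'
#' Survey-weighted summary of per-person calorie reductions by age band
#' (4-10, 11-18, 19-80) and sex: mean sugar kcal/day removed, mean
#' non-sugar kcal/day removed (with weighted median and interquartile
#' range, since portion losses are highly skewed), and the reductions as
#' percentages of baseline sugar calories and baseline total calories.
#'
#' @param deltas per-person deltas from [person_calorie_delta()].
#' @param people persons data.frame (needs `id`, `age`, `sex`,
#'   `survey_weight`).
#' @return data.frame with one row per band x sex present in the data.
#' @export
cohort_summary <- function(deltas, people) {
  m <- merge(deltas, people[, c("id", "age", "sex", "survey_weight")],
             by.x = "person_id", by.y = "id")
  if (nrow(m) == 0L) stop("no persons join the calorie deltas")
  m$band <- age_band(m$age)
  groups <- split(m, list(m$band, m$sex), drop = TRUE)
  rows <- lapply(groups, function(g) {
    w <- g$survey_weight
    q <- weighted_quantile(g$nonsugar_kcal, w, c(0.25, 0.5, 0.75))
    data.frame(
      band = as.character(g$band[1]), sex = g$sex[1], n = nrow(g),
      sugar_kcal = weighted_mean(g$sugar_kcal, w),
      nonsugar_kcal = weighted_mean(g$nonsugar_kcal, w),
      nonsugar_kcal_median = q[2],
      nonsugar_kcal_q25 = q[1], nonsugar_kcal_q75 = q[3],
      total_kcal = weighted_mean(g$total_kcal, w),
      pct_of_baseline_sugar = 100 *
        weighted_mean(g$sugar_kcal, w) /
        weighted_mean(g$baseline_sugar_kcal, w),
      pct_of_baseline_energy = 100 *
        weighted_mean(g$sugar_kcal, w) /
        weighted_mean(g$baseline_energy_kcal, w),
      pct_total_of_baseline_energy = 100 *
        weighted_mean(g$total_kcal, w) /
        weighted_mean(g$baseline_energy_kcal, w),
      stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out[order(out$band, out$sex), ]
}
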