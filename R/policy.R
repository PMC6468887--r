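#' Default category policy table for the sugar reduction programme
#'
#' Returns the category-by-mechanism policy of the UK sugar reduction
#' programme: for each of the ten targeted food categories, which of the
#' three reduction mechanisms (reformulation, portion size reduction,
#' shifting sales weighting) applies, and whether the category carries a
#' natural-sugar allowance (sugars intrinsic to dairy or dried fruit that
#' are exempt from the percentage cut).
#'
#' @return A data.frame with columns `category`, `reformulation`,
#'   `portion`, `sales_weighting` (logical mechanism flags) and
#'   `natural_allowance` (logical).
#' @examples
#' default_policy_table()
#' @export
default_policy_table <- function() {
  tab <- data.frame(
    category = c("breakfast_cereals", "yogurts", "biscuits", "cakes",
                 "morning_goods", "puddings", "ice_cream",
                 "chocolate_confectionery", "sweet_confectionery",
                 "sweet_spreads_sauces"),
    reformulation   = c(TRUE,  TRUE,  TRUE,  TRUE,  TRUE,  TRUE,  TRUE,  FALSE, FALSE, TRUE),
    portion         = c(FALSE, TRUE,  TRUE,  TRUE,  TRUE,  TRUE,  TRUE,  TRUE,  TRUE,  FALSE),
    sales_weighting = c(TRUE,  TRUE,  TRUE,  FALSE, FALSE, FALSE, FALSE, FALSE, FALSE, FALSE),
    stringsAsFactors = FALSE
  )
  # dairy categories plus breakfast cereals (dried fruit) keep a small
  # exempt allowance of naturally occurring sugars
  tab$natural_allowance <- tab$category %in%
    c("yogurts", "ice_cream", "breakfast_cereals")
  tab
}

#' Read a category policy table from CSV
#'
#' The CSV must have columns `category`, `reformulation`, `portion`,
#' `sales_weighting`, `natural_allowance`; mechanism columns may be coded
#' as logical or 0/1.
#'
#' @param path path to the CSV file.
#' @return data.frame in the same shape as [default_policy_table()].
#' @export
read_policy_table <- function(path) {
  tab <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("category", "reformulation", "portion", "sales_weighting",
            "natural_allowance")
  miss <- setdiff(need, names(tab))
  if (length(miss))
    stop("policy table missing columns: ", paste(miss, collapse = ", "))
  for (cl in need[-1]) tab[[cl]] <- as.logical(tab[[cl]])
  validate_policy_table(tab)
  tab
}

validate_policy_table <- function(policy) {
  k <- rowSums(policy[, c("reformulation", "portion", "sales_weighting")])
  if (any(k == 0))
    stop("every in-scope category must have at least one mechanism: ",
         paste(policy$category[k == 0], collapse = ", "))
  invisible(policy)
}

#' Scenario parameters for the sugar reduction programme
#'
#' @param reduction_fraction target proportional sugar reduction
#'   (default 0.20, the programme's 20\% target).
#' @param sugar_energy_density energy content of sugar in kcal per gram
#'   (default 3.75, the carbohydrate-as-monosaccharide convention).
#' @param mechanisms_enabled character vector naming the active
#'   mechanisms; disabling one emulates its failure in sensitivity
#'   analyses. The lost reduction is not redistributed to the others.
#' @param equal_split when several mechanisms apply to a category, each
#'   contributes an equal share of the total reduction (default TRUE).
#' @param natural_allowance_fraction fraction of an item's sugar treated
#'   as the exempt natural allowance in flagged categories (default 0.10).
#' @return An object of class `scenario_params`.
#' @examples
#' scenario_params()
#' scenario_params(mechanisms_enabled = c("reformulation", "portion"))
#' @export
scenario_params <- function(reduction_fraction = 0.20,
                            sugar_energy_density = 3.75,
                            mechanisms_enabled = c("reformulation", "portion",
                                                   "sales_weighting"),
                            equal_split = TRUE,
                            natural_allowance_fraction = 0.10) {
  assert_fraction(reduction_fraction, "reduction_fraction")
  if (!is.numeric(sugar_energy_density) || sugar_energy_density <= 0)
    stop("'sugar_energy_density' must be > 0")
  all_mech <- c("reformulation", "portion", "sales_weighting")
  bad <- setdiff(mechanisms_enabled, all_mech)
  if (length(bad))
    stop("unknown mechanism(s): ", paste(bad, collapse = ", "))
  mechanisms_enabled <- unique(mechanisms_enabled)  # may be empty: all fail
  assert_fraction(natural_allowance_fraction, "natural_allowance_fraction")
  structure(list(reduction_fraction = reduction_fraction,
                 sugar_energy_density = sugar_energy_density,
                 mechanisms_enabled = mechanisms_enabled,
                 equal_split = isTRUE(equal_split),
                 natural_allowance_fraction = natural_allowance_fraction),
            class = "scenario_params")
}
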