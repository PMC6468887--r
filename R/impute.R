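#' Fit regression imputation models for height, weight and PAL
#'
#' Fits linear imputation models separately by age band (4-18, 19-80) and
#' sex, for each of height, weight and physical activity level. Within
#' each stratum, nested candidate models (intercept-only; + age; + age +
#' daily calorie intake) are compared by sequential likelihood-ratio
#' tests; the largest model whose added term is significant at `alpha` is
#' kept. The residual standard deviation of the chosen model is stored
#' and later used to add stochastic variation to imputed values.
#'
#' Strata with fewer than `min_n` complete cases fall back to the stratum
#' mean and standard deviation (recorded in the model as intercept-only
#' with `fallback = TRUE`).
#'
#' @param people persons data.frame with columns `age`, `sex`, `height`,
#'   `weight`, `pal` and `daily_kcal` (diary-derived total energy,
#'   kcal/day).
#' @param alpha significance level of the likelihood-ratio tests
#'   (default 0.05).
#' @param min_n minimum complete cases per stratum before falling back to
#'   the stratum mean (default 30).
#' @return An object of class `imputation_models`: a list of per
#'   stratum-variable models, each with elements `variable`, `band`,
#'   `sex`, `formula_terms`, `coefficients`, `residual_sd`, `n`,
#'   `fallback`.
#' @export
fit_imputers <- function(people, alpha = 0.05, min_n = 30) {
  stopifnot(is.data.frame(people))
  need <- c("age", "sex", "height", "weight", "pal", "daily_kcal")
  miss <- setdiff(need, names(people))
  if (length(miss)) stop("people missing columns: ",
                         paste(miss, collapse = ", "))
  assert_fraction(alpha, "alpha")
  people$band <- ifelse(people$age <= 18, "4-18", "19-80")
  models <- list()
  for (v in c("height", "weight", "pal")) {
    for (b in unique(people$band)) for (s in unique(people$sex)) {
      d <- people[people$band == b & people$sex == s &
                    !is.na(people[[v]]) & !is.na(people$daily_kcal), ]
      key <- paste(v, b, s, sep = ":")
      if (nrow(d) < min_n) {
        models[[key]] <- list(variable = v, band = b, sex = s,
                              formula_terms = character(0),
                              coefficients = c(`(Intercept)` = mean(d[[v]])),
                              residual_sd = if (nrow(d) > 1) stats::sd(d[[v]]) else 0,
                              n = nrow(d), fallback = TRUE)
        next
      }
      y <- d[[v]]
      m0 <- stats::lm(y ~ 1, data = d)
      m1 <- stats::lm(y ~ age, data = d)
      m2 <- stats::lm(y ~ age + daily_kcal, data = d)
      lrt_p <- function(small, big) {
        stat <- 2 * (stats::logLik(big) - stats::logLik(small))
        stats::pchisq(as.numeric(stat), df = 1, lower.tail = FALSE)
      }
      chosen <- m0; terms <- character(0)
      if (lrt_p(m0, m1) < alpha) {
        chosen <- m1; terms <- "age"
        if (lrt_p(m1, m2) < alpha) {
          chosen <- m2; terms <- c("age", "daily_kcal")
        }
      }
      models[[key]] <- list(variable = v, band = b, sex = s,
                            formula_terms = terms,
                            coefficients = stats::coef(chosen),
                            residual_sd = stats::sigma(chosen),
                            n = nrow(d), fallback = FALSE)
    }
  }
  structure(models, class = "imputation_models")
}

impute_predict <- function(model, person) {
  co <- model$coefficients
  pred <- unname(co["(Intercept)"])
  if ("age" %in% model$formula_terms) pred <- pred + co["age"] * person$age
  if ("daily_kcal" %in% model$formula_terms)
    pred <- pred + co["daily_kcal"] * person$daily_kcal
  unname(pred)
}

# physically plausible floors for redrawn/truncated imputations
imputation_floor <- c(height = 0.8, weight = 10, pal = 1.05)

#' Impute missing anthropometrics and PAL
#'
#' Replaces each missing height, weight or PAL value by the linear
#' prediction from its stratum model plus a Normal(0, residual SD) draw.
#' Observed values and survey weights are never altered. Draws implying a
#' physically impossible value (non-positive height/weight, PAL <= 1) are
#' redrawn up to `max_redraws` times and then truncated at a documented
#' floor.
#'
#' @param people persons data.frame (needs `daily_kcal`; see
#'   [fit_imputers()]).
#' @param models an `imputation_models` object from [fit_imputers()].
#' @param seed integer seed making the stochastic completion reproducible.
#' @param max_redraws redraw attempts before truncation (default 10).
#' @return `people` with missing values filled and logical provenance
#'   columns `height_imputed`, `weight_imputed`, `pal_imputed` added.
#' @export
impute_people <- function(people, models, seed = 1, max_redraws = 10) {
  if (!inherits(models, "imputation_models"))
    stop("'models' must come from fit_imputers()")
  set.seed(derive_seed(seed, "imputation"))
  out <- people
  out$band <- ifelse(out$age <= 18, "4-18", "19-80")
  for (v in c("height", "weight", "pal")) {
    flag_col <- paste0(v, "_imputed")
    out[[flag_col]] <- FALSE
    idx <- which(is.na(out[[v]]))
    for (i in idx) {
      key <- paste(v, out$band[i], out$sex[i], sep = ":")
      model <- models[[key]]
      if (is.null(model))
        stop("no imputation model for stratum ", key)
      pred <- impute_predict(model, out[i, ])
      val <- pred + stats::rnorm(1, 0, model$residual_sd)
      tries <- 0
      floor_v <- imputation_floor[[v]]
      while (val < floor_v && tries < max_redraws) {
        val <- pred + stats::rnorm(1, 0, model$residual_sd)
        tries <- tries + 1
      }
      if (val < floor_v) val <- floor_v
      out[[v]][i] <- val
      out[[flag_col]][i] <- TRUE
    }
  }
  out$band <- NULL
  out
}

#' Imputation report
#'
#' One row per stratum x variable: complete cases used, model terms
#' chosen by the likelihood-ratio search, residual SD, and whether the
#' stratum fell back to its mean.
#'
#' @param models an `imputation_models` object.
#' @return data.frame suitable for writing as CSV.
#' @export
imputation_report <- function(models) {
  rows <- lapply(models, function(m) data.frame(
    variable = m$variable, band = m$band, sex = m$sex, n = m$n,
    model = if (length(m$formula_terms) == 0) "intercept"
            else paste(m$formula_terms, collapse = "+"),
    residual_sd = m$residual_sd, fallback = m$fallback,
    stringsAsFactors = FALSE))
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
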