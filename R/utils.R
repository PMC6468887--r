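#' @keywords internal
"_PACKAGE"

# Survey-weight-aware summaries used throughout: all population summaries in
# this package respect sampling weights.

weighted_mean <- function(x, w) {
  stopifnot(length(x) == length(w))
  ok <- !is.na(x)
  if (!any(ok)) return(NA_real_)
  sum(x[ok] * w[ok]) / sum(w[ok])
}

weighted_quantile <- function(x, w, probs) {
  ok <- !is.na(x)
  x <- x[ok]; w <- w[ok]
  if (length(x) == 0L) return(rep(NA_real_, length(probs)))
  o <- order(x)
  x <- x[o]; w <- w[o]
  cw <- cumsum(w) / sum(w)
  vapply(probs, function(p) x[which(cw >= p)[1L]], numeric(1))
}

weighted_median <- function(x, w) weighted_quantile(x, w, 0.5)

# Derive labelled sub-seeds from one master seed so that each stochastic
# stage (population synthesis, imputation, Monte Carlo) has its own
# reproducible stream, and paired scenario/baseline runs share common
# random numbers. Kept below 2^31 - 1.
derive_seed <- function(seed, label) {
  offsets <- c(population = 11L, diaries = 23L, disease = 37L,
               imputation = 53L, montecarlo = 71L, misc = 97L)
  off <- offsets[[label]]
  if (is.null(off)) stop("unknown seed label: ", label)
  as.integer((as.numeric(seed) * 1009 + off) %% 2147483587)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

age_band <- function(age) {
  cut(age, breaks = c(-Inf, 10, 18, Inf),
      labels = c("4-10", "11-18", "19-80"), right = TRUE)
}

assert_fraction <- function(x, name) {
  if (!is.numeric(x) || any(is.na(x)) || any(x < 0) || any(x > 1))
    stop(sprintf("'%s' must be a fraction in [0, 1]", name), call. = FALSE)
  invisible(x)
}
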