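#' Construct a wound series
#'
#' Dated area measurements for one patient; day 0 is the first dressing.
#'
#' @param patientId identifier string.
#' @param days strictly increasing observation days, first = 0.
#' @param areasCm2 positive areas, one per day.
#' @param siteClass "facial" or "non_facial".
#' @return A [WoundSeries-class].
#' @export
woundSeries <- function(patientId, days, areasCm2,
                        siteClass = c("facial", "non_facial")) {
  siteClass <- match.arg(siteClass)
  new("WoundSeries", patientId = as.character(patientId),
      siteClass = siteClass, days = as.numeric(days),
      areasCm2 = as.numeric(areasCm2))
}

#' Degree of decrease, in percent
#'
#' 100 * (initial - final) / initial: the relative reduction of the defect
#' from the start of dressing to the final scar.  Negative when the wound
#' grew.
#'
#' @param initial initial defect area (> 0).
#' @param final final scar area (>= 0).
#' @return Percent decrease.
#' @examples
#' decreaseRate(10, 5)   # 50
#' @export
decreaseRate <- function(initial, final) {
  if (any(initial <= 0)) stop("initial area must be positive")
  100 * (initial - final) / initial
}

#' Day of half the final decrement
#'
#' The healing-velocity milestone: the first day at which the area reaches
#' A_half = A0 - 0.5 * (A0 - A_final).  With \code{mode = "interp"}
#' (default) the crossing is linearly interpolated between the bracketing
#' visits; with \code{mode = "nearest"} the nearer of the two visit days is
#' returned.  For a non-monotonic series the first crossing counts.
#'
#' @param series a [WoundSeries-class].
#' @param mode "interp" or "nearest".
#' @return Day of the crossing (real).
#' @section Errors: "half-decrement undefined" for a single-visit series or
#'   when the final area is not below the initial area.
#' @examples
#' s <- woundSeries("p1", c(0, 14), c(10, 4))
#' halfDecrementDay(s)   # 7 (threshold 7, linear interpolation)
#' @export
halfDecrementDay <- function(series, mode = c("interp", "nearest")) {
  mode <- match.arg(mode)
  stopifnot(is(series, "WoundSeries"))
  a <- series@areasCm2; d <- series@days
  if (length(a) < 2L || a[length(a)] >= a[1])
    stop("half-decrement undefined (single observation or no net decrease)")
  thr <- a[1] - 0.5 * (a[1] - a[length(a)])
  below <- which(a <= thr)
  i <- below[1]                       # first visit at/below threshold
  if (i == 1L) return(d[1])
  if (a[i] == thr) return(d[i])
  frac <- (a[i - 1] - thr) / (a[i - 1] - a[i])
  tCross <- d[i - 1] + frac * (d[i] - d[i - 1])
  if (mode == "interp") tCross
  else if (abs(tCross - d[i - 1]) <= abs(d[i] - tCross)) d[i - 1] else d[i]
}

#' Summarize one healing series
#'
#' @param series a [WoundSeries-class].
#' @param halfMode passed to [halfDecrementDay()].
#' @return A [HealingSummary-class]; an undefined half-decrement day is
#'   reported as NA, not an error.
#' @export
summarizeSeries <- function(series, halfMode = "interp") {
  stopifnot(is(series, "WoundSeries"))
  a <- series@areasCm2; d <- series@days
  half <- tryCatch(halfDecrementDay(series, mode = halfMode),
                   error = function(e) NA_real_)
  new("HealingSummary", patientId = series@patientId,
      siteClass = series@siteClass,
      initialAreaCm2 = a[1], finalAreaCm2 = a[length(a)],
      decreaseRatePct = decreaseRate(a[1], a[length(a)]),
      halfDecrementDay = half,
      nObservations = length(a), followUpDays = d[length(d)])
}

#' Per-group descriptive table of healing summaries
#'
#' @param summaries list of [HealingSummary-class] objects.
#' @param labels group label per summary (defaults to each summary's site
#'   class).
#' @return data.frame with one row per group: n, mean and sample SD (n-1)
#'   of the decrease rate and of the half-decrement day (undefined
#'   half-days excluded, their count reported).  An empty group yields an
#'   NA row.
#' @export
groupTable <- function(summaries, labels = NULL) {
  if (is.null(labels))
    labels <- vapply(summaries, function(s) s@siteClass, character(1))
  stopifnot(length(labels) == length(summaries))
  groups <- unique(labels)
  rows <- lapply(groups, function(g) {
    ss <- summaries[labels == g]
    if (!length(ss))
      return(data.frame(group = g, n = 0L, mean_decrease_pct = NA_real_,
                        sd_decrease_pct = NA_real_, mean_half_day = NA_real_,
                        sd_half_day = NA_real_, n_half_undefined = NA_integer_))
    dr <- vapply(ss, function(s) s@decreaseRatePct, numeric(1))
    hd <- vapply(ss, function(s) s@halfDecrementDay, numeric(1))
    hdOk <- hd[!is.na(hd)]
    data.frame(
      group = g, n = length(ss),
      mean_decrease_pct = mean(dr),
      sd_decrease_pct = if (length(dr) > 1) stats::sd(dr) else NA_real_,
      mean_half_day = if (length(hdOk)) mean(hdOk) else NA_real_,
      sd_half_day = if (length(hdOk) > 1) stats::sd(hdOk) else NA_real_,
      n_half_undefined = sum(is.na(hd)))
  })
  do.call(rbind, rows)
}

#' Simulate an exponential-decay healing series
#'
#' A(t) = A0 * exp(-lambda t) observed at fixed visit intervals with
#' multiplicative log-normal measurement noise of coefficient of variation
#' \code{cv}.  Defaults emulate a typical secondary-intention course:
#' lambda = 0.1/day sampled weekly over 8 weeks.
#'
#' @param A0 initial area, cm^2.
#' @param lambda decay rate per day.
#' @param intervalDays visit spacing.
#' @param followUpDays last visit day.
#' @param cv multiplicative noise CV (0 = noiseless).
#' @param seed RNG seed.
#' @param patientId,siteClass series metadata.
#' @return A [WoundSeries-class].
#' @export
simulateHealingSeries <- function(A0 = 10, lambda = 0.1, intervalDays = 7,
                                  followUpDays = 56, cv = 0.05, seed = 1L,
                                  patientId = "sim", siteClass = "facial") {
  days <- seq(0, followUpDays, by = intervalDays)
  mu <- A0 * exp(-lambda * days)
  areas <- if (cv > 0) {
    sdlog <- sqrt(log(1 + cv^2))
    withSeed(seed, mu * stats::rlnorm(length(mu), -sdlog^2 / 2, sdlog))
  } else mu
  woundSeries(patientId, days, areas, siteClass)
}

#' Analytic half-decrement day of a sampled exponential decay
#'
#' Closed-form crossing of A0 - 0.5 (A0 - A0 exp(-lambda T)) for the
#' noiseless series: t = -log(0.5 (1 + exp(-lambda T))) / lambda.
#'
#' @param lambda decay rate per day.
#' @param followUpDays last visit day T.
#' @return Crossing day.
#' @export
analyticHalfDay <- function(lambda, followUpDays) {
  -log(0.5 * (1 + exp(-lambda * followUpDays))) / lambda
}

#' Simulate a facial / non-facial healing cohort
#'
#' Per-subject decrease rates are drawn from Normal(67, 12.5^2) for facial
#' and Normal(53, 18^2) for non-facial sites, truncated to (0, 100]; each
#' subject gets an exponential-decay series whose final area realizes the
#' drawn decrease rate exactly.
#'
#' @param nPerGroup subjects per group.
#' @param seed RNG seed.
#' @param facialMean,facialSd,nonFacialMean,nonFacialSd group parameters.
#' @return list of [WoundSeries-class] objects (facial first).
#' @export
simulateCohort <- function(nPerGroup = 30L, seed = 1L,
                           facialMean = 67, facialSd = 12.5,
                           nonFacialMean = 53, nonFacialSd = 18) {
  withSeed(seed, {
    draw <- function(n, m, s) {
      out <- numeric(0)
      while (length(out) < n) {
        x <- stats::rnorm(2 * n, m, s)
        out <- c(out, x[x > 0 & x <= 100])
      }
      out[seq_len(n)]
    }
    rates <- c(draw(nPerGroup, facialMean, facialSd),
               draw(nPerGroup, nonFacialMean, nonFacialSd))
    sites <- rep(c("facial", "non_facial"), each = nPerGroup)
    lapply(seq_along(rates), function(i) {
      A0 <- 10
      Af <- A0 * (1 - rates[i] / 100)
      Tf <- 56
      lambda <- -log(Af / A0) / Tf
      days <- seq(0, Tf, by = 7)
      woundSeries(sprintf("sim%02d", i), days, A0 * exp(-lambda * days),
                  sites[i])
    })
  })
}

setMethod("show", "WoundSeries", function(object) {
  cat(sprintf("WoundSeries %s (%s): %d visits over %g days, %.2f -> %.2f cm^2\n",
              object@patientId, object@siteClass, length(object@days),
              object@days[length(object@days)], object@areasCm2[1],
              object@areasCm2[length(object@areasCm2)]))
})

setMethod("show", "HealingSummary", function(object) {
  cat(sprintf(
    "HealingSummary %s (%s): decrease %.1f%%, half-decrement day %s, %d visits / %g days\n",
    object@patientId, object@siteClass, object@decreaseRatePct,
    ifelse(is.na(object@halfDecrementDay), "undefined",
           sprintf("%.1f", object@halfDecrementDay)),
    object@nObservations, object@followUpDays))
})
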