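## Growth-rate extraction from plate-reader OD600 curves.
##
## The estimator is the field-standard sliding-window fit: ordinary least
## squares of ln(OD) on time over every run of `window` consecutive
## readings, keeping the steepest window whose R-squared exceeds a strict
## acceptance threshold. Readings at or below `odFloor` are treated as
## blank/noise-dominated and never enter a window.

#' Fit an exponential growth rate by sliding-window regression
#'
#' Scans every run of `window` consecutive readings whose OD exceeds
#' `odFloor`, fits ln(OD) against time by ordinary least squares, and
#' returns the window with the maximal slope among those with
#' R-squared strictly greater than `r2Min`. Ties on slope resolve to the
#' earliest window. Windows with zero variance in ln(OD) have undefined
#' R-squared and never qualify, so a perfectly flat curve yields an
#' unqualified estimate rather than a zero rate.
#'
#' Inputs are assumed background-corrected; no blank subtraction is
#' applied.
#'
#' @param curve An [ODCurve-class].
#' @param window Number of consecutive time points per fit (default 5).
#' @param r2Min Strict lower bound on the window R-squared (default 0.99).
#' @param odFloor Readings at or below this OD are excluded before the
#'   log transform (default 0.01).
#' @return A [GrowthRateEstimate-class]; `isQualified()` is `FALSE` when
#'   no window met the threshold.
#' @export
#' @examples
#' t <- seq(0, 200, 10)
#' fitExponentialRate(ODCurve("w1", t, 0.01 * exp(0.02 * t)))
fitExponentialRate <- function(curve, window = 5L, r2Min = 0.99,
                               odFloor = 0.01) {
  stopifnot(is(curve, "ODCurve"))
  window <- as.integer(window)
  if (window < 3L) stop("'window' must be at least 3 points")
  od <- curve@od
  times <- curve@times
  usable <- od > odFloor
  if (sum(usable) < window)
    stop("insufficient data: sample '", curve@sampleId, "' has ",
         sum(usable), " readings above the OD floor (", odFloor,
         "), need at least ", window)

  n <- length(od)
  best <- list(slope = -Inf, start = NA_integer_, r2 = NA_real_)
  for (i in seq_len(n - window + 1L)) {
    idx <- i:(i + window - 1L)
    if (!all(usable[idx])) next
    y <- log(od[idx])
    x <- times[idx]
    mx <- mean(x); my <- mean(y)
    sxx <- sum((x - mx)^2)
    sxy <- sum((x - mx) * (y - my))
    syy <- sum((y - my)^2)
    if (syy <= 0) next                       # flat in log space: R2 undefined
    slope <- sxy / sxx
    r2 <- (sxy * sxy) / (sxx * syy)
    if (r2 > r2Min && slope > best$slope) {  # strict > keeps earliest tie
      best <- list(slope = slope, start = i, r2 = r2)
    }
  }
  if (is.na(best$start))
    new("GrowthRateEstimate", rate = NA_real_, windowStart = NA_integer_,
        windowR2 = NA_real_, qualified = FALSE)
  else
    new("GrowthRateEstimate", rate = best$slope,
        windowStart = best$start, windowR2 = min(best$r2, 1),
        qualified = TRUE)
}

#' Growth rate relative to the wild type, in percent
#'
#' @param sample,wildtype Qualified [GrowthRateEstimate-class] objects.
#' @return Numeric percentage: `100 * rate(sample) / rate(wildtype)`.
#' @export
#' @examples
#' t <- seq(0, 200, 10)
#' s <- fitExponentialRate(ODCurve("s", t, 0.01 * exp(0.0124 * t)))
#' w <- fitExponentialRate(ODCurve("w", t, 0.01 * exp(0.02 * t)))
#' relativeGrowthRate(s, w)  # 62
relativeGrowthRate <- function(sample, wildtype) {
  stopifnot(is(sample, "GrowthRateEstimate"),
            is(wildtype, "GrowthRateEstimate"))
  if (!sample@qualified || !wildtype@qualified)
    stop("relative growth rate requires qualified estimates for both ",
         "sample and wild type")
  if (wildtype@rate <= 0)
    stop("wild-type growth rate must be positive")
  100 * sample@rate / wildtype@rate
}

#' Summarise a recovery trajectory
#'
#' Given per-cycle relative growth rates for one sample or clone, reports
#' the maximal relative rate attained and the first dilution cycle at
#' which the relative rate reached the threshold (90% of wild type by
#' default), or `NA` if never reached.
#'
#' @param cycles Non-decreasing integer vector of dilution-cycle indices
#'   (0 = day the founding sample was taken).
#' @param relativeRates Matching vector of percent-of-wild-type values.
#' @param threshold Recovery threshold in percent (default 90).
#' @return List with `maxRelativeRate` and `firstCycleAtThreshold`
#'   (`NA_integer_` when the threshold was never reached).
#' @export
#' @examples
#' recoverySummary(c(0, 8, 16), c(76.2, 70, 76.2))  # never reaches 90
recoverySummary <- function(cycles, relativeRates, threshold = 90) {
  if (length(cycles) == 0L) stop("empty recovery trajectory")
  if (length(cycles) != length(relativeRates))
    stop("'cycles' and 'relativeRates' must have equal length")
  if (is.unsorted(cycles)) stop("'cycles' must be non-decreasing")
  hit <- which(relativeRates >= threshold)
  list(maxRelativeRate = max(relativeRates),
       firstCycleAtThreshold = if (length(hit)) as.integer(cycles[min(hit)])
                               else NA_integer_)
}

#' Read a plate-reader CSV into a list of OD curves
#'
#' Expects a UTF-8 CSV whose first column, `time_min`, holds measurement
#' times in minutes ('.' decimal separator) and whose remaining columns
#' each hold one well's OD600 readings; header names become sample ids.
#'
#' @param path Path to the CSV file.
#' @return Named list of [ODCurve-class] objects, one per well column.
#' @export
readPlateCsv <- function(path) {
  df <- utils::read.csv(path, check.names = FALSE, stringsAsFactors = FALSE)
  if (nrow(df) == 0L || ncol(df) < 2L)
    stop("plate file '", path, "' must contain a time column and at least ",
         "one well column")
  timeCol <- names(df)[1L]
  tvals <- suppressWarnings(as.numeric(df[[1L]]))
  if (anyNA(tvals)) {
    bad <- which(is.na(tvals))[1L]
    stop("non-numeric time value at data row ", bad, ", column '", timeCol, "'")
  }
  if (is.unsorted(tvals, strictly = TRUE))
    stop("time column '", timeCol, "' is not strictly increasing ",
         "(duplicated or decreasing timestamps)")
  curves <- lapply(names(df)[-1L], function(wl) {
    v <- suppressWarnings(as.numeric(df[[wl]]))
    if (anyNA(v)) {
      bad <- which(is.na(v))[1L]
      stop("non-numeric OD value at data row ", bad, ", column '", wl, "'")
    }
    ODCurve(wl, tvals, v)
  })
  names(curves) <- names(df)[-1L]
  curves
}
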