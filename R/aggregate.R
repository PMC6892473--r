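#' Daily unit means of a gridded field (centroid rule)
#'
#' Collapses a per-cell daily field to per-unit daily series by unweighted
#' arithmetic averaging over the member cells of each unit, i.e. the cells
#' whose centroid falls inside the unit polygon. Units with no assigned cell
#' are returned as rows of NA (missing series), mirroring how a county
#' smaller than one grid cell is reported without data.
#'
#' @param x a \linkS4class{SmokeFieldSet}
#' @param assignment a \linkS4class{CellAssignment} built on the same grid
#' @param assay name of the assay to aggregate (default "fire")
#' @return numeric matrix (units x days); rownames are unit ids (all units in
#'   the assignment, empty ones included), colnames ISO dates
#' @export
unitDailyMean <- function(x, assignment, assay = "fire") {
  g <- smokeGridOf(x)
  ga <- assignment@grid
  if (g@nCols != ga@nCols || g@nRows != ga@nRows ||
      g@cellSize != ga@cellSize || g@originX != ga@originX ||
      g@originY != ga@originY)
    stop("assignment was built on a different grid")
  vals <- SummarizedExperiment::assay(x, assay)
  tb <- assignmentTable(assignment)
  ids <- unitIds(assignment)
  out <- matrix(NA_real_, length(ids), ncol(vals),
                dimnames = list(ids, colnames(vals)))
  for (u in setdiff(ids, emptyUnits(assignment))) {
    cells <- tb$cell[tb$unit_id == u]
    out[u, ] <- colMeans(vals[cells, , drop = FALSE])
  }
  out
}

.sdBy <- function(v, type) {
  n <- length(v)
  if (n == 0L) return(NA_real_)
  if (type == "population") sqrt(sum((v - mean(v))^2) / n)
  else if (n < 2L) NA_real_ else stats::sd(v)
}

#' Annual and period summaries of unit daily series
#'
#' \code{annualSummary} computes, per unit and calendar year, the mean and
#' standard deviation of the daily values together with the number of days
#' used. \code{periodSummary} pools all days whose year falls in
#' \code{years}. The standard deviation is population-style (divide by n) by
#' default; set \code{sdType = "sample"} for the n-1 convention. All
#' available days of a unit-year are used; \code{minFraction} optionally
#' blanks unit-years covering less than that fraction of the calendar year.
#' Empty selections yield NA, never zero.
#'
#' @param series units x days matrix from \code{\link{unitDailyMean}} (or a
#'   named numeric vector for a single day set); colnames must be ISO dates
#' @param years integer vector of calendar years (default: all present)
#' @param sdType "population" (default) or "sample"
#' @param minFraction minimum fraction of the year's days that must be
#'   present (default 0 = no rule)
#' @return data.frame with columns unit_id, year, mean, sd, n_days
#'   (\code{periodSummary}: unit_id, mean, sd, n_days)
#' @export
annualSummary <- function(series, years = NULL,
                          sdType = c("population", "sample"),
                          minFraction = 0) {
  sdType <- match.arg(sdType)
  series <- .asSeriesMatrix(series)
  dates <- as.Date(colnames(series))
  yr <- as.integer(format(dates, "%Y"))
  if (is.null(years)) years <- sort(unique(yr))
  out <- expand.grid(unit_id = rownames(series), year = years,
                     stringsAsFactors = FALSE)
  out <- out[order(out$unit_id, out$year), , drop = FALSE]
  rownames(out) <- NULL
  out$mean <- NA_real_; out$sd <- NA_real_; out$n_days <- 0L
  for (i in seq_len(nrow(out))) {
    sel <- yr == out$year[i]
    v <- series[out$unit_id[i], sel]
    v <- v[!is.na(v)]
    nInYear <- as.integer(as.Date(sprintf("%d-12-31", out$year[i])) -
                          as.Date(sprintf("%d-01-01", out$year[i]))) + 1L
    out$n_days[i] <- length(v)
    if (length(v) > 0L && length(v) >= minFraction * nInYear) {
      out$mean[i] <- mean(v)
      out$sd[i] <- .sdBy(v, sdType)
    }
  }
  out
}

#' @rdname annualSummary
#' @export
periodSummary <- function(series, years = NULL,
                          sdType = c("population", "sample")) {
  sdType <- match.arg(sdType)
  series <- .asSeriesMatrix(series)
  dates <- as.Date(colnames(series))
  yr <- as.integer(format(dates, "%Y"))
  if (is.null(years)) years <- sort(unique(yr))
  sel <- yr %in% years
  out <- data.frame(unit_id = rownames(series), mean = NA_real_,
                    sd = NA_real_, n_days = 0L, stringsAsFactors = FALSE)
  for (i in seq_len(nrow(out))) {
    v <- series[i, sel]
    v <- v[!is.na(v)]
    out$n_days[i] <- length(v)
    if (length(v) > 0L) {
      out$mean[i] <- mean(v)
      out$sd[i] <- .sdBy(v, sdType)
    }
  }
  out
}

.asSeriesMatrix <- function(series) {
  if (is.matrix(series)) {
    if (is.null(colnames(series)))
      stop("series must carry ISO dates as colnames")
    if (is.null(rownames(series)))
      rownames(series) <- as.character(seq_len(nrow(series)))
    return(series)
  }
  m <- matrix(series, nrow = 1L, dimnames = list("series", names(series)))
  m
}

#' Percent of PM2.5 attributable to fire
#'
#' \code{100 * fireMean / allMean}, the share of the all-source mean
#' concentration contributed by fire over a common set of days and cells.
#' Returned at full precision; the conventional presentation rounds to one
#' decimal. A non-positive all-source mean makes the share undefined: NA
#' with a warning.
#'
#' @param fireMean,allMean mean concentrations (ug/m3), vectorised
#' @return numeric vector of percentages
#' @examples
#' round(percentAttributable(4.40, 8.90), 1)  # 49.4
#' @export
percentAttributable <- function(fireMean, allMean) {
  out <- 100 * fireMean / allMean
  bad <- !is.na(allMean) & allMean <= 0
  if (any(bad)) {
    warning(sprintf("%d value(s) with non-positive all-source mean: NA", sum(bad)))
    out[bad] <- NA_real_
  }
  out
}

#' Quartile breaks of pooled unit-year annual means
#'
#' Computes the 25th/50th/75th percentiles of the pooled unit-year annual
#' mean fire-PM2.5 values by linear interpolation between order statistics
#' (\code{stats::quantile} type 7), plus the observed maximum. These define
#' the four exposure classes used to bin unit populations.
#'
#' @param values numeric vector of pooled unit-year annual means; at least 4
#'   finite values are required; NA values are dropped
#' @param type percentile method passed to \code{stats::quantile} (default 7,
#'   linear interpolation)
#' @return an \linkS4class{ExposureClassBreaks}
#' @examples
#' quartileBreaks(1:8)  # 2.75 / 4.5 / 6.25, max 8
#' @export
quartileBreaks <- function(values, type = 7) {
  v <- values[is.finite(values)]
  if (length(v) < 4L)
    stop("at least 4 finite values are required for quartile breaks")
  q <- unname(stats::quantile(v, c(0.25, 0.5, 0.75), type = type))
  exposureClassBreaks(q[1], q[2], q[3], max(v))
}

#' @rdname quartileBreaks
#' @param q1,q2,q3 cut points (ug/m3)
#' @param maxValue observed maximum (ug/m3)
#' @export
exposureClassBreaks <- function(q1, q2, q3, maxValue = q3) {
  new("ExposureClassBreaks", q1 = as.numeric(q1), q2 = as.numeric(q2),
      q3 = as.numeric(q3), maxValue = as.numeric(maxValue))
}

#' @rdname accessors
#' @export
setMethod("breakPoints", "ExposureClassBreaks", function(x)
  c(q1 = x@q1, q2 = x@q2, q3 = x@q3, max = x@maxValue))

setMethod("show", "ExposureClassBreaks", function(object) {
  cat(sprintf(
    "ExposureClassBreaks (ug/m3): [0, %g] (%g, %g] (%g, %g] (%g, max %g]\n",
    object@q1, object@q1, object@q2, object@q2, object@q3, object@q3,
    object@maxValue))
})

#' Classify annual mean fire-PM2.5 into exposure classes 1-4
#'
#' Intervals are lower-open/upper-closed: class 1 = [0, q1], class 2 =
#' (q1, q2], class 3 = (q2, q3], class 4 = (q3, Inf). A value of 0 belongs
#' to class 1. Negative inputs (possible when the fire difference is not
#' clipped) are placed in class 1 with a warning. NA stays NA (missing
#' units).
#'
#' @param x numeric vector of annual mean fire-PM2.5 (ug/m3)
#' @param breaks an \linkS4class{ExposureClassBreaks}
#' @return integer vector of classes in 1..4 (NA preserved)
#' @examples
#' b <- exposureClassBreaks(0.34, 0.56, 0.86, 20.3)
#' classifyExposure(c(0.34, 0.35, 20.3), b)  # 1 2 4
#' @export
classifyExposure <- function(x, breaks) {
  stopifnot(is(breaks, "ExposureClassBreaks"))
  neg <- !is.na(x) & x < 0
  if (any(neg))
    warning(sprintf("%d negative value(s) placed in class 1", sum(neg)))
  out <- rep(NA_integer_, length(x))
  ok <- !is.na(x)
  out[ok] <- 1L + (x[ok] > breaks@q1) + (x[ok] > breaks@q2) +
    (x[ok] > breaks@q3)
  out[neg] <- 1L
  out
}
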