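#' Smokewave parameters
#'
#' @param threshold exceedance threshold in ug/m3; the default 35 is the 24-h
#'   NAAQS PM2.5 level
#' @param minDays minimum number of consecutive exceedance days; the default
#'   3 reads "more than two consecutive days" literally
#' @return a \linkS4class{SmokewaveParams}
#' @export
smokewaveParams <- function(threshold = 35, minDays = 3) {
  new("SmokewaveParams", threshold = as.numeric(threshold),
      minDays = as.integer(minDays))
}

setMethod("show", "SmokewaveParams", function(object) {
  cat(sprintf("SmokewaveParams: > %g ug/m3 for >= %d consecutive days\n",
              object@threshold, object@minDays))
})

#' Detect smokewave episodes in a daily series
#'
#' Finds all maximal runs of consecutive days on which the daily fire-PM2.5
#' value is strictly greater than the threshold and the run lasts at least
#' \code{minDays} days. Consecutiveness is judged on the calendar: a gap in
#' the dates splits runs. Episodes carry start and end date, length and peak
#' concentration. Maximality means no adjacent day could extend a reported
#' episode.
#'
#' @param values numeric vector of daily concentrations for one cell or unit
#' @param dates Date vector aligned with \code{values}; if NULL, days are
#'   taken as consecutive integers 1..n
#' @param params a \linkS4class{SmokewaveParams}
#' @return data.frame with columns start, end, length, peak (zero rows if no
#'   episode qualifies)
#' @examples
#' detectSmokewaves(c(36, 36, 36))             # one 3-day episode
#' detectSmokewaves(c(36, 36, 0, 36, 36, 36, 36))  # only the 4-day run
#' @export
detectSmokewaves <- function(values, dates = NULL, params = smokewaveParams()) {
  stopifnot(is(params, "SmokewaveParams"))
  n <- length(values)
  if (is.null(dates)) {
    dates <- as.Date("1970-01-01") + seq_len(n) - 1L
    asIndex <- TRUE
  } else {
    dates <- as.Date(dates)
    asIndex <- FALSE
  }
  if (length(dates) != n)
    stop("values and dates must have equal length")
  if (anyNA(dates) || anyDuplicated(dates))
    stop("dates must be unique and non-missing")
  if (is.unsorted(dates, strictly = TRUE))
    stop("dates must be in increasing order")
  empty <- data.frame(start = as.Date(character()), end = as.Date(character()),
                      length = integer(), peak = numeric())
  if (n == 0L) return(empty)
  ex <- !is.na(values) & values > params@threshold
  # segment id increments at calendar gaps so runs never cross a gap
  seg <- cumsum(c(1L, as.integer(diff(dates) != 1)))
  grp <- cumsum(c(1L, as.integer(diff(as.integer(ex)) != 0 |
                                 diff(seg) != 0)))
  out <- empty
  for (g in unique(grp[ex])) {
    idx <- which(grp == g)
    if (length(idx) >= params@minDays) {
      out <- rbind(out, data.frame(
        start = dates[idx[1L]], end = dates[idx[length(idx)]],
        length = length(idx), peak = max(values[idx])))
    }
  }
  if (asIndex) {
    out$start <- as.integer(out$start - as.Date("1970-01-01")) + 1L
    out$end <- as.integer(out$end - as.Date("1970-01-01")) + 1L
  }
  rownames(out) <- NULL
  out
}

#' Count smokewave episodes per cell or unit and per year
#'
#' Runs \code{\link{detectSmokewaves}} on every row of a daily series matrix
#' (grid cells or administrative units) and counts episodes by calendar
#' year. An episode spanning a year boundary is counted once, in the year of
#' its start date. The period total is the row sum of the yearly counts.
#' Rows that are entirely NA (missing units) yield NA counts.
#'
#' @param series units/cells x days matrix with ISO-date colnames, e.g. from
#'   \code{\link{unitDailyMean}}, or an assay of a
#'   \linkS4class{SmokeFieldSet}
#' @param params a \linkS4class{SmokewaveParams}
#' @param years calendar years to tabulate (default: all in the series)
#' @return data.frame with column id, one column per year (named
#'   \code{y<year>}) and \code{total}
#' @export
smokewaveCounts <- function(series, params = smokewaveParams(), years = NULL) {
  series <- .asSeriesMatrix(series)
  dates <- as.Date(colnames(series))
  if (is.null(years))
    years <- sort(unique(as.integer(format(dates, "%Y"))))
  out <- data.frame(id = rownames(series), stringsAsFactors = FALSE)
  cnt <- matrix(0L, nrow(series), length(years),
                dimnames = list(NULL, paste0("y", years)))
  for (i in seq_len(nrow(series))) {
    v <- series[i, ]
    if (all(is.na(v))) { cnt[i, ] <- NA_integer_; next }
    ep <- detectSmokewaves(v, dates, params)
    if (nrow(ep) > 0L) {
      ey <- as.integer(format(ep$start, "%Y"))
      for (k in seq_along(years))
        cnt[i, k] <- sum(ey == years[k])
    }
  }
  out <- cbind(out, as.data.frame(cnt))
  out$total <- rowSums(cnt)
  out
}
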