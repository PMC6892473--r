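#' Construct a SmokeFieldSet from per-cell per-day matrices
#'
#' @param grid a \linkS4class{SmokeGrid}
#' @param dates Date vector, one per column, strictly increasing
#' @param ... named numeric matrices (cells x days), e.g.
#'   \code{all_sources = }, \code{no_fire = }. Rows follow the linear cell
#'   index of \code{\link{cellCentroids}}.
#' @return a \linkS4class{SmokeFieldSet}
#' @examples
#' g <- smokeGrid(0, 0, 1000, nCols = 2, nRows = 2)
#' d <- as.Date("2008-01-01") + 0:4
#' m <- matrix(5, nrow = 4, ncol = 5)
#' fs <- smokeFieldSet(g, d, all_sources = m, no_fire = m)
#' @export
smokeFieldSet <- function(grid, dates, ...) {
  asy <- list(...)
  if (length(asy) == 0L) stop("at least one assay matrix is required")
  dates <- as.Date(dates)
  if (any(is.na(dates)) || is.unsorted(dates, strictly = TRUE))
    stop("dates must be strictly increasing with no NA")
  nCell <- grid@nCols * grid@nRows
  for (nm in names(asy)) {
    a <- asy[[nm]]
    if (!is.matrix(a) || nrow(a) != nCell || ncol(a) != length(dates))
      stop(sprintf("assay '%s' must be a %d x %d matrix", nm, nCell,
                   length(dates)))
    dimnames(asy[[nm]]) <- list(NULL, as.character(dates))
  }
  se <- SummarizedExperiment(
    assays = asy,
    rowData = DataFrame(cellCentroids(grid)),
    colData = DataFrame(date = dates, row.names = as.character(dates))
  )
  metadata(se)$grid <- grid
  out <- as(se, "SmokeFieldSet")
  validObject(out)
  out
}

#' @rdname accessors
#' @export
setMethod("smokeGridOf", "SmokeFieldSet", function(x) metadata(x)$grid)

#' @rdname accessors
#' @export
setMethod("fieldDates", "SmokeFieldSet", function(x) colData(x)$date)

#' Attribute fire-PM2.5 by differencing paired model runs
#'
#' Computes the fire-attributable concentration field as
#' \code{fire = all_sources - no_fire}, per cell and day (the "brute-force
#' zero-out" attribution: one run with all emission sources, one with fire
#' sources removed). With \code{clipNegative = FALSE} (default) negative
#' differences -- which can arise from nonlinear transport and chemistry --
#' are retained, so \code{fire + no_fire} reconstructs \code{all_sources}
#' exactly. With clipping on, negatives are set to 0 and their count is
#' reported via a message.
#'
#' @param x a \linkS4class{SmokeFieldSet} with assays \code{all_sources} and
#'   \code{no_fire} on the same grid and dates
#' @param clipNegative set negative differences to zero (default FALSE)
#' @param ... unused
#' @return \code{x} with a \code{fire} assay added
#' @rdname fireDifference
#' @export
setMethod("fireDifference", "SmokeFieldSet",
  function(x, clipNegative = FALSE, ...) {
    for (nm in c("all_sources", "no_fire"))
      if (!nm %in% assayNames(x))
        stop(sprintf("assay '%s' is required", nm))
    fire <- assay(x, "all_sources") - assay(x, "no_fire")
    if (clipNegative) {
      nneg <- sum(fire < 0)
      if (nneg > 0)
        message(sprintf("fireDifference: clipped %d negative cell-day(s) to 0",
                        nneg))
      fire[fire < 0] <- 0
    }
    assays(x)$fire <- fire
    x
  })

#' Collapse hourly concentrations to local-time daily means
#'
#' Averages hourly values into 24-h daily means where the day runs midnight
#' to midnight in local time, obtained by shifting the UTC timestamps by a
#' whole-hour offset (e.g. -8 for Pacific Standard Time). Partial first/last
#' local days (fewer than 24 hours present) are dropped and reported via a
#' message.
#'
#' @param hourly numeric matrix (cells x hours) or vector of hourly values
#' @param times POSIXct UTC timestamps, one per hour, strictly increasing and
#'   hourly-spaced
#' @param utcOffsetHours integer offset in [-12, 14] added to UTC to obtain
#'   local time
#' @return list with \code{values} (cells x days matrix), \code{dates}
#'   (local Date vector) and \code{droppedHours}
#' @examples
#' tt <- as.POSIXct("2008-01-01 00:00", tz = "UTC") + 3600 * (0:47)
#' dailyFromHourly(1:48, tt, 0)$values  # 12.5 and 36.5
#' @export
dailyFromHourly <- function(hourly, times, utcOffsetHours) {
  if (length(utcOffsetHours) != 1L || !is.finite(utcOffsetHours) ||
      utcOffsetHours != round(utcOffsetHours) ||
      utcOffsetHours < -12 || utcOffsetHours > 14)
    stop("utcOffsetHours must be a whole number of hours in [-12, 14]")
  if (is.vector(hourly)) hourly <- matrix(hourly, nrow = 1L)
  if (ncol(hourly) != length(times))
    stop("one hourly value column per timestamp is required")
  dt <- as.numeric(diff(times), units = "hours")
  if (length(dt) && any(abs(dt - 1) > 1e-9))
    stop("timestamps must be strictly increasing and hourly spaced")
  local <- times + utcOffsetHours * 3600
  day <- as.Date(format(local, "%Y-%m-%d", tz = "UTC"))
  cnt <- table(day)
  full <- as.Date(names(cnt)[cnt == 24L])
  dropped <- sum(cnt[cnt != 24L])
  if (dropped > 0)
    message(sprintf("dailyFromHourly: dropped %d hour(s) in partial local days",
                    dropped))
  if (length(full) == 0L)
    stop("no complete local day in the input")
  vals <- vapply(full, function(d) rowMeans(hourly[, day == d, drop = FALSE]),
                 numeric(nrow(hourly)))
  if (nrow(hourly) == 1L) vals <- matrix(vals, nrow = 1L)
  colnames(vals) <- as.character(full)
  list(values = vals, dates = full, droppedHours = dropped)
}

#' Read / write gridded daily fields as long-format CSV
#'
#' The on-disk dialect is a long CSV with header \code{date,row,col,value}:
#' one line per cell-day, ISO-8601 dates, 1-based row/col indices and
#' concentrations in ug/m3 printed with full double precision, so a
#' write/read cycle is lossless.
#'
#' @param path CSV path
#' @param grid the \linkS4class{SmokeGrid} the field lives on
#' @return \code{readDailyFieldCSV}: list with \code{values} (cells x days
#'   matrix) and \code{dates}; \code{writeDailyFieldCSV}: \code{path},
#'   invisibly
#' @export
readDailyFieldCSV <- function(path, grid) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("date", "row", "col", "value")
  if (!all(need %in% names(df)))
    stop("field CSV must have columns date,row,col,value")
  dates <- sort(unique(as.Date(df$date)))
  nCell <- grid@nCols * grid@nRows
  vals <- matrix(NA_real_, nCell, length(dates),
                 dimnames = list(NULL, as.character(dates)))
  cell <- (df$row - 1L) * grid@nCols + df$col
  if (any(cell < 1L | cell > nCell))
    stop("row/col indices outside the grid")
  j <- match(as.character(as.Date(df$date)), colnames(vals))
  vals[cbind(cell, j)] <- df$value
  if (anyNA(vals))
    stop("field CSV does not cover every cell-day")
  list(values = vals, dates = dates)
}

#' @rdname readDailyFieldCSV
#' @param values cells x days numeric matrix (linear cell index rows)
#' @param dates Date vector, one per column
#' @export
writeDailyFieldCSV <- function(values, dates, grid, path) {
  cen <- cellCentroids(grid)
  n <- nrow(values)
  if (n != grid@nCols * grid@nRows || ncol(values) != length(dates))
    stop("values must be a full cells x days matrix for the grid")
  df <- data.frame(
    date = rep(as.character(as.Date(dates)), each = n),
    row = rep(cen$row, times = length(dates)),
    col = rep(cen$col, times = length(dates)),
    value = sprintf("%.17g", as.vector(values)),
    stringsAsFactors = FALSE
  )
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}
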