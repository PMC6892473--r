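#' Match monitor coordinates to grid cells
#'
#' Returns the cell whose rectangle contains each point. Cells are half-open
#' \code{[left, right) x [bottom, top)}, so every interior point of the grid
#' extent maps to exactly one cell and a point exactly on an interior
#' vertical edge belongs to the cell on its right. Points outside the extent
#' (including the exact right/top edge) are dropped with a warning and
#' returned as NA.
#'
#' @param x,y point coordinates in the grid's projected system
#' @param grid a \linkS4class{SmokeGrid}
#' @return data.frame with columns cell, col, row (NA rows for dropped
#'   points)
#' @export
matchMonitorToCell <- function(x, y, grid) {
  col <- floor((x - grid@originX) / grid@cellSize) + 1L
  row <- floor((y - grid@originY) / grid@cellSize) + 1L
  ok <- col >= 1L & col <= grid@nCols & row >= 1L & row <= grid@nRows &
    is.finite(x) & is.finite(y)
  if (any(!ok))
    warning(sprintf("%d point(s) outside the grid extent dropped", sum(!ok)))
  col[!ok] <- NA_integer_; row[!ok] <- NA_integer_
  data.frame(cell = (row - 1L) * grid@nCols + col, col = col, row = row)
}

#' Stratify monitor-days by predicted wildfire impact
#'
#' Labels each monitor-day "wildfire-impacted" when the model's predicted
#' fire contribution to PM2.5 carbon is strictly greater than the threshold
#' (default 0.34 ug/m3, the first exposure-class break of the California
#' study configuration), and "little-or-no" when it is less than or equal to
#' it. The evaluation threshold and the class break are independent knobs
#' that merely coincide in that configuration.
#'
#' @param predFireCarbon predicted fire PM2.5-carbon per monitor-day (ug/m3)
#' @param threshold stratification threshold (ug/m3)
#' @return factor with levels "wildfire-impacted", "little-or-no"
#' @export
stratifyByFireImpact <- function(predFireCarbon, threshold = 0.34) {
  if (any(!is.finite(predFireCarbon)))
    stop("predictions must be finite")
  factor(ifelse(predFireCarbon > threshold, "wildfire-impacted",
                "little-or-no"),
         levels = c("wildfire-impacted", "little-or-no"))
}

#' Observed / predicted PM2.5-carbon summary per stratum and year
#'
#' For every stratum-year with at least one matched monitor-day pair:
#' the number of pairs, the mean observed and mean predicted PM2.5 carbon,
#' and the bias \code{difference = mean predicted - mean observed},
#' computed at full precision (presentation conventionally rounds to one
#' decimal). Empty stratum-years are omitted.
#'
#' @param obs,pred observed and predicted PM2.5 carbon (ug/m3), pairwise
#'   matched
#' @param stratum stratum label per pair (e.g. from
#'   \code{\link{stratifyByFireImpact}})
#' @param year calendar year per pair
#' @return data.frame with columns stratum, year, n, mean_obs, mean_pred,
#'   difference
#' @export
stratumSummary <- function(obs, pred, stratum, year) {
  n <- length(obs)
  if (length(pred) != n || length(stratum) != n || length(year) != n)
    stop("obs, pred, stratum and year must have equal length")
  keep <- !is.na(obs) & !is.na(pred)
  dropped <- sum(!keep)
  if (dropped > 0)
    message(sprintf("stratumSummary: %d pair(s) with a missing side excluded",
                    dropped))
  df <- data.frame(obs = obs[keep], pred = pred[keep],
                   stratum = as.character(stratum)[keep],
                   year = as.integer(year)[keep])
  if (nrow(df) == 0L)
    return(data.frame(stratum = character(), year = integer(), n = integer(),
                      mean_obs = numeric(), mean_pred = numeric(),
                      difference = numeric()))
  key <- interaction(df$stratum, df$year, drop = TRUE)
  out <- do.call(rbind, lapply(levels(key), function(k) {
    g <- df[key == k, ]
    data.frame(stratum = g$stratum[1], year = g$year[1], n = nrow(g),
               mean_obs = mean(g$obs), mean_pred = mean(g$pred),
               difference = mean(g$pred) - mean(g$obs))
  }))
  out <- out[order(out$stratum, out$year), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Read / write monitor records
#'
#' Monitor CSVs carry one row per monitor-day:
#' \code{monitor_id,x,y,date,obs_carbon[,pred_carbon[,pred_fire_carbon]]},
#' with coordinates in the grid system, ISO dates and concentrations in
#' ug/m3. Observations must be non-negative and (monitor_id, date) unique.
#'
#' @param path CSV path
#' @return data.frame of monitor records
#' @export
readMonitorRecords <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("monitor_id", "x", "y", "date", "obs_carbon")
  if (!all(need %in% names(df)))
    stop("monitor CSV must have columns monitor_id,x,y,date,obs_carbon")
  df$date <- as.Date(df$date)
  if (anyDuplicated(df[c("monitor_id", "date")]))
    stop("(monitor_id, date) must be unique")
  if (any(df$obs_carbon < 0, na.rm = TRUE))
    stop("observations must be non-negative")
  df
}

#' @rdname readMonitorRecords
#' @param records monitor record data.frame
#' @export
writeMonitorRecords <- function(records, path) {
  rec <- records
  rec$date <- as.character(as.Date(rec$date))
  for (cn in intersect(names(rec),
                       c("x", "y", "obs_carbon", "pred_carbon",
                         "pred_fire_carbon")))
    rec[[cn]] <- sprintf("%.17g", rec[[cn]])
  utils::write.csv(rec, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}
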