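#' @import methods
#' @importFrom S4Vectors DataFrame metadata "metadata<-"
#' @importFrom SummarizedExperiment SummarizedExperiment assay assays "assays<-" assayNames rowData colData
NULL

#' Regular projected model grid
#'
#' A \code{SmokeGrid} describes a regular grid of square cells in a planar
#' projected coordinate system, as used by chemical-transport models such as
#' the 12-km national CMAQ runs. Cell \code{(col, row)} (1-based) has its
#' lower-left corner at \code{(originX + (col-1)*cellSize,
#' originY + (row-1)*cellSize)} and its centroid half a cell further in each
#' direction. Coordinates are planar; no geodesic computation is performed.
#'
#' @slot originX,originY projected coordinates (m) of the lower-left corner of
#'   cell (1, 1)
#' @slot cellSize cell edge length (m), e.g. 12000
#' @slot nCols,nRows grid dimensions (positive integers)
#' @slot crs free-text label of the projected coordinate system
#' @export
setClass("SmokeGrid",
  representation(
    originX = "numeric", originY = "numeric", cellSize = "numeric",
    nCols = "integer", nRows = "integer", crs = "character"
  )
)

setValidity("SmokeGrid", function(object) {
  msg <- NULL
  if (length(object@cellSize) != 1L || !is.finite(object@cellSize) ||
      object@cellSize <= 0)
    msg <- c(msg, "cellSize must be a single positive number")
  if (length(object@nCols) != 1L || is.na(object@nCols) || object@nCols < 1L)
    msg <- c(msg, "nCols must be a positive integer")
  if (length(object@nRows) != 1L || is.na(object@nRows) || object@nRows < 1L)
    msg <- c(msg, "nRows must be a positive integer")
  if (length(object@originX) != 1L || !is.finite(object@originX) ||
      length(object@originY) != 1L || !is.finite(object@originY))
    msg <- c(msg, "origin coordinates must be single finite numbers")
  if (is.null(msg)) TRUE else msg
})

#' Collection of administrative-unit polygons
#'
#' Polygons are stored as lists of rings (two-column coordinate matrices) in
#' the grid's planar coordinate system. Ring orientation is not significant;
#' containment uses the even-odd parity rule, so holes are supported as
#' additional rings. Unit identifiers must be unique.
#'
#' @slot unitIds character vector of unique unit identifiers
#' @slot unitNames character vector of display names
#' @slot polygons list (one element per unit) of lists of rings; each ring is
#'   a numeric matrix with columns x, y (implicitly closed)
#' @export
setClass("AdminUnitSet",
  representation(
    unitIds = "character", unitNames = "character", polygons = "list"
  )
)

setValidity("AdminUnitSet", function(object) {
  msg <- NULL
  n <- length(object@unitIds)
  if (anyDuplicated(object@unitIds))
    msg <- c(msg, "unit ids must be unique")
  if (length(object@unitNames) != n || length(object@polygons) != n)
    msg <- c(msg, "unitIds, unitNames and polygons must have equal length")
  for (i in seq_len(n)) {
    rings <- object@polygons[[i]]
    if (!is.list(rings) || length(rings) == 0L) {
      msg <- c(msg, sprintf("unit '%s' has no rings", object@unitIds[i]))
      next
    }
    for (ring in rings) {
      if (!is.matrix(ring) || ncol(ring) != 2L || nrow(ring) < 3L ||
          !all(is.finite(ring))) {
        msg <- c(msg, sprintf(
          "unit '%s': each ring must be a finite numeric matrix with >= 3 vertices",
          object@unitIds[i]))
        break
      }
      if (!.ringIsSimple(ring)) {
        msg <- c(msg, sprintf("unit '%s': self-intersecting ring",
                              object@unitIds[i]))
        break
      }
    }
  }
  if (is.null(msg)) TRUE else msg
})

#' Assignment of grid cells to administrative units (centroid rule)
#'
#' Records, for a given grid and unit collection, which unit contains each
#' cell centroid. Cells whose centroid falls in no unit are kept as
#' unassigned and excluded from unit statistics; units containing no centroid
#' are flagged empty (and later reported as missing).
#'
#' @slot table data.frame with columns \code{cell}, \code{col}, \code{row},
#'   \code{unit_id} (one row per assigned cell)
#' @slot unassigned integer vector of linear cell indices in no unit
#' @slot emptyUnits character vector of unit ids with zero assigned cells
#' @slot grid the \linkS4class{SmokeGrid} the assignment was built on
#' @export
setClass("CellAssignment",
  representation(
    table = "data.frame", unassigned = "integer",
    emptyUnits = "character", grid = "SmokeGrid"
  )
)

setValidity("CellAssignment", function(object) {
  tb <- object@table
  msg <- NULL
  if (!all(c("cell", "col", "row", "unit_id") %in% names(tb)))
    msg <- c(msg, "table must have columns cell, col, row, unit_id")
  else if (anyDuplicated(tb$cell))
    msg <- c(msg, "a cell may be assigned to at most one unit")
  if (is.null(msg)) TRUE else msg
})

#' Paired daily concentration fields on a model grid
#'
#' A \code{SmokeFieldSet} is a \linkS4class{SummarizedExperiment} whose rows
#' are grid cells and whose columns are calendar days. Assays hold per-cell
#' per-day 24-h mean PM2.5 concentrations (ug/m3) for the paired model runs:
#' \code{all_sources}, \code{no_fire}, and (after differencing) \code{fire};
#' synthetic scenarios additionally carry the injected \code{fire_truth}.
#' \code{rowData} stores cell column/row indices and centroid coordinates;
#' \code{colData} stores the dates; the \linkS4class{SmokeGrid} lives in
#' \code{metadata(x)$grid}.
#'
#' The run fields \code{all_sources} and \code{no_fire} must be non-negative;
#' a \code{fire} difference field may contain small negatives (nonlinear
#' transport/chemistry) unless clipping is requested at differencing time.
#'
#' @export
setClass("SmokeFieldSet", contains = "SummarizedExperiment")

setValidity("SmokeFieldSet", function(object) {
  msg <- NULL
  g <- metadata(object)$grid
  if (!is(g, "SmokeGrid"))
    msg <- c(msg, "metadata(x)$grid must be a SmokeGrid")
  else if (nrow(object) != g@nCols * g@nRows)
    msg <- c(msg, "number of rows must equal nCols * nRows of the grid")
  if (!"date" %in% names(colData(object)))
    msg <- c(msg, "colData must contain a 'date' column")
  for (nm in intersect(assayNames(object), c("all_sources", "no_fire"))) {
    a <- assay(object, nm)
    if (!all(is.finite(a)))
      msg <- c(msg, sprintf("assay '%s' must be finite", nm))
    else if (any(a < 0))
      msg <- c(msg, sprintf("assay '%s' must be non-negative", nm))
  }
  if (is.null(msg)) TRUE else msg
})

#' Quartile breaks defining four annual fire-PM2.5 exposure classes
#'
#' The three cut points are the 25th/50th/75th percentiles of pooled
#' unit-year annual mean fire-PM2.5 values; \code{maxValue} records the
#' observed maximum (the printed upper bound of class 4). Intervals are
#' lower-open/upper-closed: class 1 is [0, q1], class 2 (q1, q2], class 3
#' (q2, q3], class 4 (q3, Inf).
#'
#' @slot q1,q2,q3 concentration cut points (ug/m3), non-decreasing
#' @slot maxValue observed maximum of the pooled values (ug/m3)
#' @export
setClass("ExposureClassBreaks",
  representation(q1 = "numeric", q2 = "numeric", q3 = "numeric",
                 maxValue = "numeric")
)

setValidity("ExposureClassBreaks", function(object) {
  v <- c(object@q1, object@q2, object@q3, object@maxValue)
  if (length(v) != 4L || !all(is.finite(v)))
    return("q1, q2, q3, maxValue must be single finite numbers")
  if (object@q1 < 0 || object@q1 > object@q2 || object@q2 > object@q3 ||
      object@q3 > object@maxValue)
    return("breaks must satisfy 0 <= q1 <= q2 <= q3 <= maxValue")
  TRUE
})

#' Smokewave detection parameters
#'
#' A smokewave is a maximal run of consecutive days on which daily fire-PM2.5
#' strictly exceeds \code{threshold} for at least \code{minDays} days. The
#' defaults follow the study definition: the 35 ug/m3 24-h NAAQS level
#' exceeded for more than two consecutive days (i.e. at least 3).
#'
#' @slot threshold exceedance threshold (ug/m3), > 0
#' @slot minDays minimum run length in days, >= 1
#' @export
setClass("SmokewaveParams",
  representation(threshold = "numeric", minDays = "integer")
)

setValidity("SmokewaveParams", function(object) {
  if (length(object@threshold) != 1L || !is.finite(object@threshold) ||
      object@threshold <= 0)
    return("threshold must be a single positive number")
  if (length(object@minDays) != 1L || is.na(object@minDays) ||
      object@minDays < 1L)
    return("minDays must be a positive integer")
  TRUE
})
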