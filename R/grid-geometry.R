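#' Build a regular projected model grid
#'
#' Constructs the geometry of a regular grid of square cells, such as the
#' 12-km grid of a national chemical-transport-model run. The centroid of
#' cell \code{(col, row)} (1-based) is at
#' \code{(originX + (col - 0.5) * cellSize, originY + (row - 0.5) * cellSize)}.
#'
#' @param originX,originY projected coordinates (m) of the lower-left corner
#'   of the grid
#' @param cellSize cell edge length (m); the study grid used 12000
#' @param nCols,nRows number of columns / rows (>= 1)
#' @param crs free-text label of the projected coordinate system
#' @return a \linkS4class{SmokeGrid}
#' @examples
#' g <- smokeGrid(0, 0, cellSize = 12000, nCols = 10, nRows = 8)
#' head(cellCentroids(g))
#' @export
smokeGrid <- function(originX = 0, originY = 0, cellSize = 12000,
                      nCols, nRows, crs = "planar") {
  if (!is.numeric(cellSize) || length(cellSize) != 1L || !is.finite(cellSize) ||
      cellSize <= 0)
    stop("cellSize must be a single positive number")
  nCols <- as.integer(nCols); nRows <- as.integer(nRows)
  if (is.na(nCols) || is.na(nRows) || nCols < 1L || nRows < 1L)
    stop("nCols and nRows must be positive integers")
  new("SmokeGrid", originX = as.numeric(originX), originY = as.numeric(originY),
      cellSize = as.numeric(cellSize), nCols = nCols, nRows = nRows,
      crs = as.character(crs))
}

#' Cell centroids of a grid
#'
#' Returns one row per cell with 1-based \code{col}/\code{row} indices, the
#' linear cell index \code{cell = (row - 1) * nCols + col}, and the centroid
#' coordinates.
#'
#' @param x a \linkS4class{SmokeGrid}
#' @param ... unused
#' @return data.frame with columns cell, col, row, x, y
#' @rdname cellCentroids
#' @export
setMethod("cellCentroids", "SmokeGrid", function(x, ...) {
  col <- rep(seq_len(x@nCols), times = x@nRows)
  row <- rep(seq_len(x@nRows), each = x@nCols)
  data.frame(
    cell = (row - 1L) * x@nCols + col,
    col = col, row = row,
    x = x@originX + (col - 0.5) * x@cellSize,
    y = x@originY + (row - 0.5) * x@cellSize
  )
})

setMethod("show", "SmokeGrid", function(object) {
  cat(sprintf(
    "SmokeGrid: %d cols x %d rows, cell %g m, origin (%g, %g), crs '%s'\n",
    object@nCols, object@nRows, object@cellSize, object@originX,
    object@originY, object@crs))
})

## ---- polygon primitives (even-odd parity with boundary detection) ----

## TRUE unless two non-adjacent edges of the ring properly intersect
.ringIsSimple <- function(ring) {
  p <- .closeRing(ring)
  n <- nrow(p) - 1L
  if (n < 3L) return(FALSE)
  for (i in seq_len(n - 1L)) {
    for (j in seq(i + 1L, n)) {
      # skip adjacent edges (share an endpoint), incl. wrap-around pair
      if (j == i + 1L || (i == 1L && j == n)) next
      if (.segmentsCross(p[i, ], p[i + 1L, ], p[j, ], p[j + 1L, ]))
        return(FALSE)
    }
  }
  TRUE
}

.closeRing <- function(ring) {
  if (!isTRUE(all.equal(ring[1L, ], ring[nrow(ring), ], check.attributes = FALSE)))
    ring <- rbind(ring, ring[1L, ])
  unname(ring)
}

.segmentsCross <- function(a, b, c, d) {
  o <- function(p, q, r) sign((q[1] - p[1]) * (r[2] - p[2]) -
                              (q[2] - p[2]) * (r[1] - p[1]))
  o1 <- o(a, b, c); o2 <- o(a, b, d); o3 <- o(c, d, a); o4 <- o(c, d, b)
  (o1 != o2 && o3 != o4 && o1 != 0 && o2 != 0 && o3 != 0 && o4 != 0)
}

## Classify points against one ring: 0 = outside, 1 = inside, 2 = on boundary.
## Even-odd ray casting (ray to +x); boundaryTol is an absolute distance-free
## tolerance on the collinearity cross-product, 0 means exact arithmetic.
.pointsInRing <- function(px, py, ring, boundaryTol = 0) {
  p <- .closeRing(ring)
  n <- nrow(p) - 1L
  inside <- rep(FALSE, length(px))
  boundary <- rep(FALSE, length(px))
  for (i in seq_len(n)) {
    x1 <- p[i, 1]; y1 <- p[i, 2]; x2 <- p[i + 1L, 1]; y2 <- p[i + 1L, 2]
    # on-segment test
    cross <- (x2 - x1) * (py - y1) - (y2 - y1) * (px - x1)
    within <- px >= pmin(x1, x2) - boundaryTol &
              px <= pmax(x1, x2) + boundaryTol &
              py >= pmin(y1, y2) - boundaryTol &
              py <= pmax(y1, y2) + boundaryTol
    boundary <- boundary | (abs(cross) <= boundaryTol & within)
    # crossing test (half-open in y so shared vertices count once)
    crosses <- ((y1 > py) != (y2 > py))
    if (any(crosses)) {
      xin <- x1 + (py - y1) * (x2 - x1) / (y2 - y1)
      inside <- xor(inside, crosses & px < xin)
    }
  }
  out <- integer(length(px))
  out[inside] <- 1L
  out[boundary] <- 2L
  out
}

## Parity across all rings of a unit (supports holes); boundary of any ring
## counts as boundary.
.pointsInUnit <- function(px, py, rings, boundaryTol = 0) {
  parity <- rep(FALSE, length(px))
  boundary <- rep(FALSE, length(px))
  for (ring in rings) {
    st <- .pointsInRing(px, py, ring, boundaryTol)
    boundary <- boundary | st == 2L
    parity <- xor(parity, st >= 1L)
  }
  out <- integer(length(px))
  out[parity] <- 1L
  out[boundary] <- 2L
  out
}

#' Construct a collection of administrative-unit polygons
#'
#' @param unitIds unique character identifiers
#' @param unitNames display names (defaults to the ids)
#' @param polygons list with one element per unit; each element is a list of
#'   rings, a ring being a numeric matrix with columns x, y. A single matrix
#'   is accepted as shorthand for one ring. Rings may be open or closed; ring
#'   orientation is ignored; additional rings act as holes (even-odd rule).
#' @return an \linkS4class{AdminUnitSet}
#' @export
adminUnits <- function(unitIds, polygons, unitNames = unitIds) {
  polygons <- lapply(polygons, function(p) if (is.matrix(p)) list(p) else p)
  polygons <- lapply(polygons, function(rs)
    lapply(rs, function(r) {
      r <- as.matrix(r); storage.mode(r) <- "double"; unname(r)
    }))
  new("AdminUnitSet", unitIds = as.character(unitIds),
      unitNames = as.character(unitNames), polygons = polygons)
}

#' @rdname accessors
#' @param x an object
#' @export
setMethod("unitIds", "AdminUnitSet", function(x) x@unitIds)

#' @rdname accessors
#' @export
setMethod("unitNames", "AdminUnitSet", function(x) x@unitNames)

#' @rdname accessors
#' @export
setMethod("unitPolygons", "AdminUnitSet", function(x) {
  names(x@polygons) <- x@unitIds
  x@polygons
})

setMethod("length", "AdminUnitSet", function(x) length(x@unitIds))

setMethod("show", "AdminUnitSet", function(object) {
  cat(sprintf("AdminUnitSet with %d units: %s\n", length(object),
              paste(utils::head(object@unitIds, 6), collapse = ", ")))
})

#' Assign grid cells to administrative units by the centroid rule
#'
#' A cell contributes to the unit whose polygon contains the cell centroid.
#' Cells whose centroid lies in no unit are retained as unassigned (the
#' model grid typically extends beyond the study region); units containing no
#' centroid are flagged empty and carry no data downstream. If a centroid
#' lies in more than one unit (overlapping polygons) or exactly on a shared
#' boundary, it is assigned to the unit whose id sorts first lexicographically
#' and a warning is emitted; the rule is deterministic and order-independent.
#'
#' @param grid a \linkS4class{SmokeGrid}
#' @param units an \linkS4class{AdminUnitSet} in the grid's coordinate system
#' @param boundaryTol absolute tolerance for the on-boundary test (0 = exact)
#' @param ... unused
#' @return a \linkS4class{CellAssignment}
#' @rdname assignCells
#' @export
setMethod("assignCells", signature("SmokeGrid", "AdminUnitSet"),
  function(grid, units, boundaryTol = 0, ...) {
    cen <- cellCentroids(grid)
    nCell <- nrow(cen)
    ids <- unitIds(units)
    ord <- order(ids)  # lexicographic priority for ties
    assigned <- rep(NA_character_, nCell)
    nContaining <- integer(nCell)
    onBoundary <- rep(FALSE, nCell)
    for (k in ord) {
      st <- .pointsInUnit(cen$x, cen$y, units@polygons[[k]], boundaryTol)
      hit <- st >= 1L
      onBoundary <- onBoundary | st == 2L
      nContaining <- nContaining + hit
      take <- hit & is.na(assigned)
      assigned[take] <- ids[k]
    }
    multi <- sum(nContaining > 1L)
    if (multi > 0L)
      warning(sprintf(
        "%d cell centroid(s) contained in more than one unit; assigned to the lexicographically first unit id",
        multi))
    bnd <- sum(onBoundary & nContaining == 1L)
    if (bnd > 0L)
      warning(sprintf("%d cell centroid(s) lie exactly on a unit boundary", bnd))
    keep <- !is.na(assigned)
    tb <- data.frame(cell = cen$cell[keep], col = cen$col[keep],
                     row = cen$row[keep], unit_id = assigned[keep],
                     stringsAsFactors = FALSE)
    new("CellAssignment",
        table = tb,
        unassigned = cen$cell[!keep],
        emptyUnits = setdiff(ids, unique(tb$unit_id)),
        grid = grid)
  })

#' @rdname accessors
#' @export
setMethod("assignmentTable", "CellAssignment", function(x) x@table)

#' @rdname accessors
#' @export
setMethod("emptyUnits", "CellAssignment", function(x) x@emptyUnits)

#' @rdname accessors
#' @export
setMethod("unassignedCells", "CellAssignment", function(x) x@unassigned)

#' @rdname accessors
#' @export
setMethod("unitIds", "CellAssignment", function(x)
  sort(unique(c(x@table$unit_id, x@emptyUnits))))

setMethod("show", "CellAssignment", function(object) {
  cat(sprintf(
    "CellAssignment: %d cells assigned to %d units; %d unassigned; %d empty unit(s)\n",
    nrow(object@table), length(unique(object@table$unit_id)),
    length(object@unassigned), length(object@emptyUnits)))
})

#' Cells assigned to one unit
#'
#' @param assignment a \linkS4class{CellAssignment}
#' @param unit_id a unit identifier
#' @return integer vector of linear cell indices (possibly empty)
#' @export
cellsForUnit <- function(assignment, unit_id) {
  tb <- assignmentTable(assignment)
  tb$cell[tb$unit_id == unit_id]
}
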