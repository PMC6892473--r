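#' Accessors for firePM classes
#'
#' Small read-only accessors: \code{unitIds}/\code{unitNames}/
#' \code{unitPolygons} on \linkS4class{AdminUnitSet};
#' \code{assignmentTable}, \code{emptyUnits}, \code{unassignedCells} and
#' \code{unitIds} on \linkS4class{CellAssignment}; \code{smokeGridOf} and
#' \code{fieldDates} on \linkS4class{SmokeFieldSet}; \code{breakPoints} on
#' \linkS4class{ExposureClassBreaks}.
#'
#' @param x an object
#' @name accessors
NULL

#' @rdname cellCentroids
#' @export
setGeneric("cellCentroids", function(x, ...) standardGeneric("cellCentroids"))

#' @rdname assignCells
#' @export
setGeneric("assignCells", function(grid, units, ...)
  standardGeneric("assignCells"))

#' @rdname accessors
#' @export
setGeneric("unitIds", function(x) standardGeneric("unitIds"))

#' @rdname accessors
#' @export
setGeneric("unitNames", function(x) standardGeneric("unitNames"))

#' @rdname accessors
#' @export
setGeneric("unitPolygons", function(x) standardGeneric("unitPolygons"))

#' @rdname accessors
#' @export
setGeneric("assignmentTable", function(x) standardGeneric("assignmentTable"))

#' @rdname accessors
#' @export
setGeneric("emptyUnits", function(x) standardGeneric("emptyUnits"))

#' @rdname accessors
#' @export
setGeneric("unassignedCells", function(x) standardGeneric("unassignedCells"))

#' @rdname accessors
#' @export
setGeneric("smokeGridOf", function(x) standardGeneric("smokeGridOf"))

#' @rdname accessors
#' @export
setGeneric("fieldDates", function(x) standardGeneric("fieldDates"))

#' @rdname fireDifference
#' @export
setGeneric("fireDifference", function(x, ...) standardGeneric("fireDifference"))

#' @rdname accessors
#' @export
setGeneric("breakPoints", function(x) standardGeneric("breakPoints"))
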