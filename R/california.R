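#' Published California 2007-2013 summary tables
#'
#' Small reference tables shipped with the package, transcribed from the
#' published statewide CMAQ wildland-fire exposure assessment for
#' California, 2007-2013 (12-km paired runs). They are the inputs for the
#' derived-arithmetic checks -- percent attributable to fire, at-risk sums
#' and shares, and model-evaluation biases -- and for the replication run
#' configuration. Concentrations are in ug/m3; at-risk population columns
#' are in millions of persons, the health-event columns in counts.
#'
#' \itemize{
#'   \item \code{californiaAnnualTable()}: statewide mean daily PM2.5 by
#'     year (all-source and fire-only mean and sd, printed percent
#'     attributable), plus the period "average" row.
#'   \item \code{californiaCountyTable()}: the same by county; one county
#'     (smaller than a grid cell) carries NA ("no data").
#'   \item \code{californiaAtRiskTable()}: population at risk by exposure
#'     class in the \code{\link{asAtRiskTable}} layout. Note the printed
#'     Total row is kept as published; it is not the exact column sum
#'     (published rounding), so shares use the printed totals.
#'   \item \code{californiaEvalTable()}: observed/predicted PM2.5-carbon
#'     means and printed differences per stratum and year.
#'   \item \code{californiaBreaks()}: the study's exposure class breaks,
#'     0.34 / 0.56 / 0.86 ug/m3 with observed maximum 20.3.
#' }
#'
#' @return a data.frame (or an \linkS4class{ExposureClassBreaks} for
#'   \code{californiaBreaks})
#' @examples
#' ann <- californiaAnnualTable()
#' round(percentAttributable(ann$fire_mean, ann$all_mean), 1)
#' @name californiaTables
NULL

.extdata <- function(fn)
  system.file("extdata", fn, package = "firePM", mustWork = TRUE)

#' @rdname californiaTables
#' @export
californiaAnnualTable <- function() {
  utils::read.csv(.extdata("california_annual_pm25.csv"),
                  stringsAsFactors = FALSE)
}

#' @rdname californiaTables
#' @export
californiaCountyTable <- function() {
  utils::read.csv(.extdata("california_county_pm25.csv"),
                  stringsAsFactors = FALSE)
}

#' @rdname californiaTables
#' @export
californiaAtRiskTable <- function() {
  asAtRiskTable(utils::read.csv(.extdata("california_at_risk.csv"),
                                stringsAsFactors = FALSE))
}

#' @rdname californiaTables
#' @export
californiaEvalTable <- function() {
  utils::read.csv(.extdata("california_carbon_eval.csv"),
                  stringsAsFactors = FALSE)
}

#' @rdname californiaTables
#' @export
californiaBreaks <- function() {
  exposureClassBreaks(0.34, 0.56, 0.86, 20.3)
}
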