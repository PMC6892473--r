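#' Pooled cell-level summary over assigned cells
#'
#' Mean and standard deviation of a field over all cell-days of cells that
#' are assigned to some unit (the study-region cells; unassigned cells are
#' excluded), per year and over the whole period -- the statewide "mean daily
#' concentration" arithmetic.
#'
#' @param x a \linkS4class{SmokeFieldSet}
#' @param assignment a \linkS4class{CellAssignment} on the same grid
#' @param assay assay name
#' @param sdType "population" (default) or "sample"
#' @return data.frame with columns year ("all" = whole period), mean, sd,
#'   n_cell_days
#' @export
pooledCellSummary <- function(x, assignment, assay = "fire",
                              sdType = c("population", "sample")) {
  sdType <- match.arg(sdType)
  vals <- SummarizedExperiment::assay(x, assay)
  cells <- sort(assignmentTable(assignment)$cell)
  vals <- vals[cells, , drop = FALSE]
  yr <- format(fieldDates(x), "%Y")
  rows <- lapply(c(sort(unique(yr)), "all"), function(y) {
    v <- if (y == "all") as.vector(vals)
         else as.vector(vals[, yr == y, drop = FALSE])
    data.frame(year = y, mean = mean(v), sd = .sdBy(v, sdType),
               n_cell_days = length(v), stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}

#' Build a pipeline run configuration
#'
#' Collects every tunable of the end-to-end pipeline. Inputs are either a
#' \code{\link{scenarioConfig}} (synthetic mode) or file paths to the long
#' CSV fields, unit GeoJSON, population CSV and optional monitor CSV
#' (file mode, which also needs \code{grid}). The defaults hold the study
#' constants: the 35 ug/m3 24-h NAAQS smokewave threshold with a minimum
#' run of 3 days, and the 0.34 ug/m3 evaluation threshold. Class breaks are
#' computed from the data unless \code{fixedBreaks} pins them (e.g.
#' \code{californiaBreaks()} for the replication configuration). Every
#' effective setting is echoed into the output metadata.
#'
#' @param scenario optional \code{\link{scenarioConfig}}
#' @param allCSV,noFireCSV,unitsGeoJSON,populationCSV,monitorCSV input paths
#'   (file mode)
#' @param grid \linkS4class{SmokeGrid} for file mode
#' @param threshold,minDays smokewave parameters
#' @param evalThreshold stratification threshold for model evaluation
#' @param fixedBreaks optional \linkS4class{ExposureClassBreaks}
#' @param clipNegative clip negative fire differences to zero
#' @param percentileType \code{stats::quantile} type for quartile breaks
#' @param sdType "population" or "sample" standard deviations
#' @param minClass lowest class counted as "at risk" in share reporting
#' @param carbonFraction carbon fraction used to derive predicted carbon
#'   from the fields when monitor records carry none
#' @param seed run seed (forwarded to the scenario when it has none set)
#' @return list of class \code{RunConfig}
#' @export
runConfig <- function(scenario = NULL, allCSV = NULL, noFireCSV = NULL,
                      unitsGeoJSON = NULL, populationCSV = NULL,
                      monitorCSV = NULL, grid = NULL,
                      threshold = 35, minDays = 3, evalThreshold = 0.34,
                      fixedBreaks = NULL, clipNegative = FALSE,
                      percentileType = 7,
                      sdType = c("population", "sample"), minClass = 2,
                      carbonFraction = 0.5, seed = 1) {
  sdType <- match.arg(sdType)
  if (is.null(scenario) &&
      (is.null(allCSV) || is.null(noFireCSV) || is.null(unitsGeoJSON) ||
       is.null(populationCSV) || is.null(grid)))
    stop("either a scenario or the full set of input paths plus grid is required")
  if (!is.null(fixedBreaks)) stopifnot(is(fixedBreaks, "ExposureClassBreaks"))
  structure(list(scenario = scenario, allCSV = allCSV, noFireCSV = noFireCSV,
                 unitsGeoJSON = unitsGeoJSON, populationCSV = populationCSV,
                 monitorCSV = monitorCSV, grid = grid,
                 threshold = threshold, minDays = as.integer(minDays),
                 evalThreshold = evalThreshold, fixedBreaks = fixedBreaks,
                 clipNegative = isTRUE(clipNegative),
                 percentileType = percentileType, sdType = sdType,
                 minClass = as.integer(minClass),
                 carbonFraction = carbonFraction, seed = as.integer(seed)),
            class = "RunConfig")
}

#' Read a run configuration from a YAML file
#'
#' Scalar keys mirror the \code{\link{runConfig}} arguments; a nested
#' \code{scenario:} mapping is passed to \code{\link{scenarioConfig}}, a
#' \code{fixedBreaks:} sequence of three or four numbers to
#' \code{\link{exposureClassBreaks}}, and a \code{grid:} mapping to
#' \code{\link{smokeGrid}}.
#'
#' @param path YAML path
#' @return list of class \code{RunConfig}
#' @export
runConfigFromYAML <- function(path) {
  y <- yaml::read_yaml(path)
  if (!is.null(y$scenario)) y$scenario <- do.call(scenarioConfig, y$scenario)
  if (!is.null(y$fixedBreaks)) {
    b <- as.numeric(y$fixedBreaks)
    y$fixedBreaks <- if (length(b) >= 4) exposureClassBreaks(b[1], b[2], b[3], b[4])
                     else exposureClassBreaks(b[1], b[2], b[3])
  }
  if (!is.null(y$grid)) y$grid <- do.call(smokeGrid, y$grid)
  do.call(runConfig, y)
}

.stage <- function(name, expr) {
  tryCatch(expr, error = function(e)
    stop(sprintf("stage '%s' failed: %s", name, conditionMessage(e)),
         call. = FALSE))
}

#' Run the exposure-assessment pipeline end to end
#'
#' Executes difference -> aggregate -> summarise -> classify -> smokewaves
#' -> at-risk -> evaluate on synthetic or file inputs and writes all outputs
#' under \code{outdir}: unit daily fire series, annual and period summaries,
#' exposure classes, smokewave episode lists and per-unit/per-cell counts,
#' the at-risk table, the evaluation table, a GeoJSON of units with joined
#' smokewave counts for mapping, and \code{summary.json} echoing every
#' effective setting alongside the headline numbers. Reruns with the same
#' configuration and seed produce byte-identical outputs. Any stage failure
#' aborts with a stage-named error and removes files written so far.
#'
#' @param config a \code{\link{runConfig}}
#' @param outdir output directory (created if needed)
#' @return the summary list, invisibly
#' @export
runPipeline <- function(config, outdir) {
  stopifnot(inherits(config, "RunConfig"))
  dir.create(outdir, showWarnings = FALSE, recursive = TRUE)
  written <- character(0)
  put <- function(fn) { p <- file.path(outdir, fn); written <<- c(written, p); p }
  on.exit({
    # reached only via error: drop partial outputs
    unlink(written)
  })

  inputs <- .stage("inputs", {
    if (!is.null(config$scenario)) {
      sc <- simulateScenario(config$scenario)
      list(fields = sc$fields, units = sc$units, assignment = sc$assignment,
           population = sc$population, monitors = sc$monitors)
    } else {
      g <- config$grid
      allF <- readDailyFieldCSV(config$allCSV, g)
      nof <- readDailyFieldCSV(config$noFireCSV, g)
      if (!identical(as.character(allF$dates), as.character(nof$dates)))
        stop("all-sources and no-fire fields cover different dates")
      fields <- smokeFieldSet(g, allF$dates, all_sources = allF$values,
                              no_fire = nof$values)
      units <- readUnitsGeoJSON(config$unitsGeoJSON)
      list(fields = fields, units = units,
           assignment = assignCells(g, units),
           population = readPopulationTable(config$populationCSV),
           monitors = if (!is.null(config$monitorCSV))
             readMonitorRecords(config$monitorCSV) else NULL)
    }
  })

  fields <- .stage("difference",
    fireDifference(inputs$fields, clipNegative = config$clipNegative))

  agg <- .stage("aggregate", {
    list(fire = unitDailyMean(fields, inputs$assignment, "fire"),
         all = unitDailyMean(fields, inputs$assignment, "all_sources"))
  })

  summaries <- .stage("summarise", {
    ann <- annualSummary(agg$fire, sdType = config$sdType)
    perFire <- periodSummary(agg$fire, sdType = config$sdType)
    perAll <- periodSummary(agg$all, sdType = config$sdType)
    perFire$percent_attributable <- suppressWarnings(
      percentAttributable(perFire$mean, perAll$mean))
    pooledFire <- pooledCellSummary(fields, inputs$assignment, "fire",
                                    config$sdType)
    pooledAll <- pooledCellSummary(fields, inputs$assignment, "all_sources",
                                   config$sdType)
    list(annual = ann, periodFire = perFire, periodAll = perAll,
         pooledFire = pooledFire, pooledAll = pooledAll)
  })

  classes <- .stage("classify", {
    breaks <- config$fixedBreaks %||%
      quartileBreaks(summaries$annual$mean, type = config$percentileType)
    cl <- classifyExposure(summaries$periodFire$mean, breaks)
    names(cl) <- summaries$periodFire$unit_id
    list(breaks = breaks, classes = cl)
  })

  sw <- .stage("smokewaves", {
    params <- smokewaveParams(config$threshold, config$minDays)
    unitCounts <- smokewaveCounts(agg$fire, params)
    cellCounts <- smokewaveCounts(
      SummarizedExperiment::assay(fields, "fire"), params)
    episodes <- do.call(rbind, lapply(rownames(agg$fire), function(u) {
      v <- agg$fire[u, ]
      if (all(is.na(v))) return(NULL)
      ep <- detectSmokewaves(v, as.Date(colnames(agg$fire)), params)
      if (nrow(ep) == 0L) return(NULL)
      cbind(unit_id = u, ep)
    }))
    if (is.null(episodes))
      episodes <- data.frame(unit_id = character(), start = as.Date(character()),
                             end = as.Date(character()), length = integer(),
                             peak = numeric())
    list(params = params, unitCounts = unitCounts, cellCounts = cellCounts,
         episodes = episodes)
  })

  risk <- .stage("at-risk", {
    atRisk <- tabulateAtRisk(classes$classes, inputs$population)
    fa <- suppressWarnings(fractionAbove(atRisk, minClass = config$minClass))
    counts <- sw$unitCounts$total
    names(counts) <- sw$unitCounts$id
    nYears <- length(unique(format(fieldDates(fields), "%Y")))
    list(atRisk = atRisk, fractionAbove = fa,
         swAny = smokewavePopulation(counts, inputs$population, 1),
         swYearly = smokewavePopulation(counts, inputs$population, nYears),
         swTwiceYearly = smokewavePopulation(counts, inputs$population,
                                             2L * nYears))
  })

  evaluation <- if (is.null(inputs$monitors)) NULL else .stage("evaluate", {
    mon <- inputs$monitors
    if (is.null(mon$pred_carbon) || is.null(mon$pred_fire_carbon)) {
      cells <- matchMonitorToCell(mon$x, mon$y, smokeGridOf(fields))$cell
      j <- match(as.character(as.Date(mon$date)),
                 as.character(fieldDates(fields)))
      mon$pred_carbon <- config$carbonFraction *
        SummarizedExperiment::assay(fields, "all_sources")[cbind(cells, j)]
      mon$pred_fire_carbon <- config$carbonFraction *
        SummarizedExperiment::assay(fields, "fire")[cbind(cells, j)]
    }
    lab <- stratifyByFireImpact(mon$pred_fire_carbon, config$evalThreshold)
    stratumSummary(mon$obs_carbon, mon$pred_carbon, lab,
                   format(as.Date(mon$date), "%Y"))
  })

  .stage("outputs", {
    dts <- as.Date(colnames(agg$fire))
    long <- data.frame(
      unit_id = rep(rownames(agg$fire), times = ncol(agg$fire)),
      date = rep(as.character(dts), each = nrow(agg$fire)),
      fire_pm25 = as.vector(agg$fire))
    utils::write.csv(long, put("unit_daily_fire.csv"), row.names = FALSE)
    utils::write.csv(summaries$annual, put("annual_summary.csv"),
                     row.names = FALSE)
    per <- summaries$periodFire
    names(per)[names(per) == "mean"] <- "fire_mean"
    names(per)[names(per) == "sd"] <- "fire_sd"
    per$all_mean <- summaries$periodAll$mean
    per$all_sd <- summaries$periodAll$sd
    utils::write.csv(per, put("period_summary.csv"), row.names = FALSE)
    utils::write.csv(
      data.frame(unit_id = names(classes$classes),
                 exposure_class = unname(classes$classes)),
      put("exposure_classes.csv"), row.names = FALSE)
    epi <- sw$episodes
    epi$start <- as.character(epi$start); epi$end <- as.character(epi$end)
    utils::write.csv(epi, put("smokewave_episodes_unit.csv"),
                     row.names = FALSE)
    utils::write.csv(sw$unitCounts, put("smokewave_counts_unit.csv"),
                     row.names = FALSE)
    utils::write.csv(sw$cellCounts, put("smokewave_counts_cell.csv"),
                     row.names = FALSE)
    utils::write.csv(risk$atRisk, put("at_risk.csv"), row.names = FALSE)
    if (!is.null(evaluation))
      utils::write.csv(evaluation, put("evaluation.csv"), row.names = FALSE)
    swAttr <- sw$unitCounts
    names(swAttr)[names(swAttr) == "id"] <- "unit_id"
    writeUnitsGeoJSON(inputs$units, put("units_smokewaves.geojson"),
                      attributes = swAttr)
    NULL
  })

  summary <- .stage("summary", {
    s <- list(
      settings = list(
        threshold = config$threshold, minDays = config$minDays,
        evalThreshold = config$evalThreshold,
        clipNegative = config$clipNegative,
        percentileType = config$percentileType, sdType = config$sdType,
        minClass = config$minClass, carbonFraction = config$carbonFraction,
        breaks = as.list(breakPoints(classes$breaks)),
        breaksFixed = !is.null(config$fixedBreaks),
        seed = if (!is.null(config$scenario)) config$scenario$seed
               else config$seed),
      pooled = list(
        fire_mean = summaries$pooledFire$mean[summaries$pooledFire$year == "all"],
        fire_sd = summaries$pooledFire$sd[summaries$pooledFire$year == "all"],
        all_mean = summaries$pooledAll$mean[summaries$pooledAll$year == "all"],
        all_sd = summaries$pooledAll$sd[summaries$pooledAll$year == "all"]),
      fractionAbove = risk$fractionAbove,
      smokewavePopulation = list(any = risk$swAny, yearly = risk$swYearly,
                                 twiceYearly = risk$swTwiceYearly),
      evaluation = evaluation)
    s$pooled$percent_attributable <- suppressWarnings(
      percentAttributable(s$pooled$fire_mean, s$pooled$all_mean))
    jsonlite::write_json(s, put("summary.json"), auto_unbox = TRUE,
                         digits = NA, pretty = TRUE, dataframe = "rows",
                         force = TRUE)
    s
  })

  on.exit()  # success: keep outputs
  invisible(summary)
}
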