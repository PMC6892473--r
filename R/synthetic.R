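#' Configure a synthetic smoke scenario
#'
#' Bundles every knob of the synthetic-data generator: grid geometry, date
#' range, the smooth positive background model, the fire-event list (or the
#' rates at which events are drawn), the rectangular unit tiling, the
#' population model and the monitor network. The generator emulates the
#' statistical shape of chemical-transport-model output -- a spatiotemporally
#' smooth background plus sparse, short-lived advected plumes giving many
#' near-zero fire-PM2.5 days punctuated by sharp multi-day peaks -- not the
#' physics that produces it.
#'
#' Background values are \code{(mean + seasonal sinusoid) * lognormal AR(1)
#' noise}: the AR(1) process lives on the log scale (so the field is
#' strictly positive and \code{ar1} is the lag-1 autocorrelation of the
#' log-values) and the lognormal factor is mean-corrected to 1. Monitor
#' observations are \code{carbonFraction * (background + fire truth) *
#' biasFactor * mean-1 lognormal noise}, sampled every \code{cadence} days
#' (1, 3 or 6, mirroring routine 1-in-3 / 1-in-6 monitoring schedules).
#'
#' @param nCols,nRows,cellSize,originX,originY,crs grid geometry (defaults:
#'   20 x 20 cells of 12000 m)
#' @param startDate first day (ISO string or Date)
#' @param nYears number of whole calendar years simulated
#' @param backgroundMean mean background (no-fire) level, ug/m3; scalar or
#'   one value per cell
#' @param seasonalAmplitude amplitude of the seasonal sinusoid (ug/m3); must
#'   be smaller than the background mean
#' @param ar1 lag-1 autocorrelation of the log-scale background noise
#' @param noiseSd standard deviation of the log-scale background noise
#' @param nEventsPerYear number of fire events drawn per calendar year
#'   (ignored when \code{events} is given)
#' @param peakRange,durationRange,sigmaRange,advectionMax ranges for drawn
#'   event peaks (ug/m3), durations (days), Gaussian spatial scales (cells)
#'   and per-component advection speeds (cells/day)
#' @param events optional explicit list of \code{\link{fireEvent}} objects
#' @param unitsX,unitsY rectangular unit tiling of the grid extent
#' @param includeTinyUnit also add one sub-cell unit that contains no cell
#'   centroid (so it is flagged empty and reported as missing downstream)
#' @param popScale,popSdLog scale and log-sd of unit total populations
#' @param nMonitors,cadence,carbonFraction,monitorNoiseSd,biasFactor monitor
#'   network: number of sites, sampling cadence in days (1, 3 or 6), carbon
#'   fraction of PM2.5 in (0, 1], multiplicative noise log-sd, and bias
#'   factor (scalar, or named per-year vector e.g. \code{c("2007" = 0.9)})
#' @param seed master seed; one stream per generator is split off
#'   deterministically so e.g. adding monitors does not perturb the fields
#' @return a validated list of class \code{ScenarioConfig}
#' @export
scenarioConfig <- function(nCols = 20, nRows = 20, cellSize = 12000,
                           originX = 0, originY = 0, crs = "planar-12km",
                           startDate = "2007-01-01", nYears = 2,
                           backgroundMean = 3.7, seasonalAmplitude = 1.2,
                           ar1 = 0.5, noiseSd = 0.3,
                           nEventsPerYear = 5, peakRange = c(150, 400),
                           durationRange = c(4, 10), sigmaRange = c(1.5, 3),
                           advectionMax = 1, events = NULL,
                           unitsX = 4, unitsY = 2, includeTinyUnit = TRUE,
                           popScale = 1e5, popSdLog = 0.8,
                           nMonitors = 10, cadence = 1, carbonFraction = 0.5,
                           monitorNoiseSd = 0.1, biasFactor = 1,
                           seed = 1) {
  cfg <- list(nCols = as.integer(nCols), nRows = as.integer(nRows),
              cellSize = cellSize, originX = originX, originY = originY,
              crs = crs, startDate = as.Date(startDate),
              nYears = as.integer(nYears),
              backgroundMean = backgroundMean,
              seasonalAmplitude = seasonalAmplitude, ar1 = ar1,
              noiseSd = noiseSd, nEventsPerYear = nEventsPerYear,
              peakRange = peakRange, durationRange = durationRange,
              sigmaRange = sigmaRange, advectionMax = advectionMax,
              events = events, unitsX = as.integer(unitsX),
              unitsY = as.integer(unitsY),
              includeTinyUnit = isTRUE(includeTinyUnit),
              popScale = popScale, popSdLog = popSdLog,
              nMonitors = as.integer(nMonitors), cadence = as.integer(cadence),
              carbonFraction = carbonFraction,
              monitorNoiseSd = monitorNoiseSd, biasFactor = biasFactor,
              seed = as.integer(seed))
  stopifnot(cfg$nCols >= 1L, cfg$nRows >= 1L, cfg$cellSize > 0,
            cfg$nYears >= 1L, cfg$noiseSd >= 0, cfg$monitorNoiseSd >= 0,
            cfg$ar1 >= 0, cfg$ar1 < 1, cfg$popSdLog >= 0)
  if (!(cfg$cadence %in% c(1L, 3L, 6L)))
    stop("cadence must be 1, 3 or 6 days")
  if (cfg$carbonFraction <= 0 || cfg$carbonFraction > 1)
    stop("carbonFraction must be in (0, 1]")
  if (min(cfg$backgroundMean) <= cfg$seasonalAmplitude)
    stop("backgroundMean must exceed seasonalAmplitude (positivity)")
  if (any(cfg$biasFactor <= 0)) stop("bias factors must be positive")
  class(cfg) <- "ScenarioConfig"
  cfg
}

#' Study-scale replication scenario
#'
#' A scenario emulating the shape of the California study conditions at desk
#' scale: 12-km cells, 7 whole years, a 4 x 4 unit tiling plus one sub-cell
#' unit, and sparse large advected plumes calibrated so that fire
#' contributes roughly a quarter of the period-mean all-source PM2.5 and
#' unit series show mostly sub-1 ug/m3 fire days with isolated multi-day
#' peaks above the 35 ug/m3 smokewave threshold.
#'
#' @param seed master seed
#' @param ... overrides passed to \code{\link{scenarioConfig}}
#' @return a \code{ScenarioConfig}
#' @export
replicationScenarioConfig <- function(seed = 1, ...) {
  scenarioConfig(nYears = 7, unitsX = 4, unitsY = 4, nEventsPerYear = 6,
                 seed = seed, ...)
}

#' Describe a single synthetic fire event
#'
#' A fire event adds an isotropic Gaussian plume, advected linearly, with a
#' trapezoidal temporal profile: for day \code{k = 0, ..., duration - 1} of
#' the event the cell at distance \code{d} (cell units) from the advected
#' centre \code{origin + k * (vx, vy)} receives
#' \code{peak * profile(k) * exp(-d^2 / (2 * sigma^2))}, where
#' \code{profile} rises linearly over the first \code{riseFrac} of the
#' duration, holds at 1, and decays over the last \code{decayFrac}.
#' Contributions of overlapping events are additive.
#'
#' @param originCol,originRow centre at the first event day, in (continuous)
#'   cell-index coordinates
#' @param start first day (Date or ISO string)
#' @param duration number of days (>= 1)
#' @param peak plateau amplitude at the plume centre (ug/m3, > 0)
#' @param sigma Gaussian spatial scale in cells (> 0)
#' @param vx,vy advection velocity (cells/day)
#' @param riseFrac,decayFrac rise / decay fractions of the duration
#' @return a list of class \code{FireEvent}
#' @export
fireEvent <- function(originCol, originRow, start, duration, peak, sigma,
                      vx = 0, vy = 0, riseFrac = 0.25, decayFrac = 0.25) {
  stopifnot(duration >= 1, peak > 0, sigma > 0,
            riseFrac >= 0, decayFrac >= 0, riseFrac + decayFrac <= 1)
  structure(list(originCol = originCol, originRow = originRow,
                 start = as.Date(start), duration = as.integer(duration),
                 peak = peak, sigma = sigma, vx = vx, vy = vy,
                 riseFrac = riseFrac, decayFrac = decayFrac),
            class = "FireEvent")
}

#' Trapezoidal temporal profile of a fire event
#'
#' @param k 0-based day index within the event
#' @param event a \code{\link{fireEvent}}
#' @return profile value in [0, 1]
#' @export
eventProfile <- function(k, event) {
  u <- (k + 0.5) / event$duration
  p <- pmin(1,
            if (event$riseFrac > 0) u / event$riseFrac else Inf,
            if (event$decayFrac > 0) (1 - u) / event$decayFrac else Inf)
  pmax(p, 0)
}

## deterministic per-generator stream seeds split from the master seed
.streamSeed <- function(seed, k) {
  (as.double(seed) * 7 + k * 1000003) %% 2147483629
}

.scenarioGrid <- function(config) {
  smokeGrid(config$originX, config$originY, config$cellSize,
            config$nCols, config$nRows, config$crs)
}

.scenarioDates <- function(config) {
  y0 <- as.integer(format(config$startDate, "%Y"))
  end <- as.Date(sprintf("%d-12-31", y0 + config$nYears - 1L))
  seq(config$startDate, end, by = "day")
}

#' Simulate the no-fire background field
#'
#' @param config a \code{\link{scenarioConfig}}
#' @param seed seed for this generator's stream (default: split from the
#'   config's master seed)
#' @return list with \code{values} (cells x days matrix) and \code{dates}
#' @export
simulateBackground <- function(config,
                               seed = .streamSeed(config$seed, 1)) {
  dates <- .scenarioDates(config)
  nCell <- config$nCols * config$nRows
  nDay <- length(dates)
  level <- rep_len(config$backgroundMean, nCell)
  doy <- as.integer(format(dates, "%j"))
  seasonal <- config$seasonalAmplitude * sin(2 * pi * doy / 365.25)
  sdv <- config$noiseSd
  set.seed(seed)
  e <- matrix(0, nCell, nDay)
  if (sdv > 0) {
    rho <- config$ar1
    e[, 1] <- stats::rnorm(nCell, 0, sdv)
    if (nDay > 1)
      for (t in 2:nDay)
        e[, t] <- rho * e[, t - 1] +
          stats::rnorm(nCell, 0, sdv * sqrt(1 - rho^2))
  }
  vals <- (level + rep(seasonal, each = nCell)) * exp(e - sdv^2 / 2)
  dim(vals) <- c(nCell, nDay)
  colnames(vals) <- as.character(dates)
  list(values = vals, dates = dates)
}

#' Draw random fire events for a scenario
#'
#' Event origins are uniform over the grid, start days uniform within each
#' year's fire season (May-October), and peaks, durations, spatial scales
#' and advection components uniform over the configured ranges.
#'
#' @inheritParams simulateBackground
#' @return list of \code{\link{fireEvent}} objects
#' @export
randomFireEvents <- function(config, seed = .streamSeed(config$seed, 2)) {
  set.seed(seed)
  y0 <- as.integer(format(config$startDate, "%Y"))
  ev <- list()
  for (y in y0:(y0 + config$nYears - 1L)) {
    season0 <- as.Date(sprintf("%d-05-01", y))
    season1 <- as.Date(sprintf("%d-10-31", y))
    for (i in seq_len(config$nEventsPerYear)) {
      ev[[length(ev) + 1L]] <- fireEvent(
        originCol = stats::runif(1, 0.5, config$nCols + 0.5),
        originRow = stats::runif(1, 0.5, config$nRows + 0.5),
        start = season0 + floor(stats::runif(1) *
                                  as.integer(season1 - season0 + 1L)),
        duration = sample(seq(config$durationRange[1],
                              config$durationRange[2]), 1L),
        peak = stats::runif(1, config$peakRange[1], config$peakRange[2]),
        sigma = stats::runif(1, config$sigmaRange[1], config$sigmaRange[2]),
        vx = stats::runif(1, -config$advectionMax, config$advectionMax),
        vy = stats::runif(1, -config$advectionMax, config$advectionMax))
    }
  }
  ev
}

#' Simulate the fire-truth field from a list of events
#'
#' Deterministic given the events: each event adds its advected Gaussian
#' plume (see \code{\link{fireEvent}}) to an all-zero field; days of an
#' event falling outside the scenario date range are clipped with a
#' warning.
#'
#' @inheritParams simulateBackground
#' @param events list of \code{\link{fireEvent}}; by default drawn with
#'   \code{\link{randomFireEvents}}
#' @return list with \code{values}, \code{dates} and \code{events}
#' @export
simulateFire <- function(config, events = NULL,
                         seed = .streamSeed(config$seed, 2)) {
  dates <- .scenarioDates(config)
  if (is.null(events))
    events <- config$events %||% randomFireEvents(config, seed)
  nCell <- config$nCols * config$nRows
  vals <- matrix(0, nCell, length(dates),
                 dimnames = list(NULL, as.character(dates)))
  cen <- cellCentroids(.scenarioGrid(config))
  clipped <- 0L
  for (ev in events) {
    for (k in seq_len(ev$duration) - 1L) {
      j <- match(as.character(ev$start + k), colnames(vals))
      if (is.na(j)) { clipped <- clipped + 1L; next }
      cx <- ev$originCol + k * ev$vx
      cy <- ev$originRow + k * ev$vy
      d2 <- (cen$col - cx)^2 + (cen$row - cy)^2
      vals[, j] <- vals[, j] +
        ev$peak * eventProfile(k, ev) * exp(-d2 / (2 * ev$sigma^2))
    }
  }
  if (clipped > 0L)
    warning(sprintf("%d event day(s) outside the date range clipped", clipped))
  list(values = vals, dates = dates, events = events)
}

#' Compose paired model runs from background and fire truth
#'
#' Builds the all-sources field as \code{background + plume} and returns a
#' \linkS4class{SmokeFieldSet} carrying \code{no_fire}, \code{all_sources}
#' and the stored \code{fire_truth}, so the downstream run differencing can
#' be validated against the injected truth. The stored truth is the
#' representable difference \code{all_sources - no_fire} (it deviates from
#' the analytic plume by at most one unit in the last place of the summed
#' field -- a rounding inherent to composing in double precision), which is
#' exactly what an ideal attribution of the composed runs can recover, so
#' \code{\link{fireDifference}} reproduces it bit for bit.
#'
#' @param background,fire lists with \code{values}/\code{dates} from
#'   \code{\link{simulateBackground}} / \code{\link{simulateFire}}
#' @param grid the scenario's \linkS4class{SmokeGrid}
#' @return a \linkS4class{SmokeFieldSet}
#' @export
composeFields <- function(background, fire, grid) {
  if (!identical(as.character(background$dates), as.character(fire$dates)) ||
      !all(dim(background$values) == dim(fire$values)))
    stop("background and fire fields must share grid and dates")
  allv <- background$values + fire$values
  smokeFieldSet(grid, background$dates,
                all_sources = allv,
                no_fire = background$values,
                fire_truth = allv - background$values)
}

#' Generate the rectangular unit tiling of a scenario
#'
#' Tiles the grid extent with \code{unitsX} x \code{unitsY} rectangles of
#' (near-)equal cell counts, and optionally adds one sub-cell square unit
#' centred on an interior grid-line intersection so that it contains no cell
#' centroid -- emulating an administrative unit smaller than a grid cell
#' that ends up with no data.
#'
#' @inheritParams simulateBackground
#' @return an \linkS4class{AdminUnitSet}
#' @export
generateUnits <- function(config) {
  g <- .scenarioGrid(config)
  cbx <- unique(round(seq(0, config$nCols, length.out = config$unitsX + 1L)))
  cby <- unique(round(seq(0, config$nRows, length.out = config$unitsY + 1L)))
  ids <- character(0); polys <- list()
  k <- 0L
  for (iy in seq_len(length(cby) - 1L)) {
    for (ix in seq_len(length(cbx) - 1L)) {
      k <- k + 1L
      x0 <- g@originX + cbx[ix] * g@cellSize
      x1 <- g@originX + cbx[ix + 1L] * g@cellSize
      y0 <- g@originY + cby[iy] * g@cellSize
      y1 <- g@originY + cby[iy + 1L] * g@cellSize
      ids[k] <- sprintf("U%02d", k)
      polys[[k]] <- rbind(c(x0, y0), c(x1, y0), c(x1, y1), c(x0, y1))
    }
  }
  if (config$includeTinyUnit && config$nCols >= 2L && config$nRows >= 2L) {
    cx <- g@originX + g@cellSize
    cy <- g@originY + g@cellSize
    h <- 0.2 * g@cellSize
    k <- k + 1L
    ids[k] <- "U_TINY"
    polys[[k]] <- rbind(c(cx - h, cy - h), c(cx + h, cy - h),
                        c(cx + h, cy + h), c(cx - h, cy + h))
  }
  adminUnits(ids, polys, unitNames = sub("^U", "Unit ", ids))
}

#' Generate a per-unit population / health-count table
#'
#' Unit total populations are lognormal draws around \code{popScale}; the
#' demographic columns are plausible fractions of the total with uniform
#' jitter, and the health-event counts are Poisson draws at fixed per-capita
#' rates. The sub-cell unit (if present) gets a small population so the
#' "Missing" row of the at-risk table is exercised.
#'
#' @inheritParams simulateBackground
#' @param unitIds unit identifiers (typically from
#'   \code{\link{generateUnits}})
#' @return data.frame in the \code{\link{readPopulationTable}} layout
#' @export
generatePopulation <- function(config, unitIds,
                               seed = .streamSeed(config$seed, 3)) {
  set.seed(seed)
  n <- length(unitIds)
  scale <- rep(config$popScale, n)
  scale[unitIds == "U_TINY"] <- config$popScale / 200
  total <- round(scale * stats::rlnorm(n, 0, config$popSdLog))
  total <- pmax(total, 100)
  df <- data.frame(
    unit_id = unitIds,
    total_population = total,
    under18 = round(total * stats::runif(n, 0.20, 0.28)),
    over65 = round(total * stats::runif(n, 0.10, 0.16)),
    poverty = round(total * stats::runif(n, 0.25, 0.40)),
    asthma_ed = stats::rpois(n, total * 0.008),
    heart_attack = stats::rpois(n, total * 5e-4),
    births = stats::rpois(n, total * 0.012),
    stringsAsFactors = FALSE
  )
  df
}

#' Generate monitor records from the scenario's truth fields
#'
#' Places monitors uniformly inside the grid extent and samples observation
#' days at the configured cadence. The observed PM2.5 carbon is
#' \code{carbonFraction * all_sources * biasFactor(year) * noise} with mean-1
#' multiplicative lognormal noise; the record also carries the model-side
#' \code{pred_carbon = carbonFraction * all_sources} and
#' \code{pred_fire_carbon = carbonFraction * fire_truth} at the monitor's
#' cell, so evaluation can be run without re-deriving predictions.
#'
#' @inheritParams simulateBackground
#' @param fields the scenario \linkS4class{SmokeFieldSet} (with
#'   \code{fire_truth})
#' @return data.frame of monitor records (see
#'   \code{\link{readMonitorRecords}})
#' @export
generateMonitors <- function(config, fields,
                             seed = .streamSeed(config$seed, 4)) {
  set.seed(seed)
  g <- smokeGridOf(fields)
  dates <- fieldDates(fields)
  allv <- assay(fields, "all_sources")
  firev <- assay(fields, "fire_truth")
  n <- config$nMonitors
  mx <- g@originX + stats::runif(n) * g@nCols * g@cellSize
  my <- g@originY + stats::runif(n) * g@nRows * g@cellSize
  cells <- matchMonitorToCell(mx, my, g)$cell
  dayIdx <- seq(1L, length(dates), by = config$cadence)
  yrs <- format(dates, "%Y")
  recs <- vector("list", n)
  for (m in seq_len(n)) {
    bias <- if (length(config$biasFactor) == 1L && is.null(names(config$biasFactor)))
      rep(config$biasFactor, length(dayIdx))
    else {
      b <- config$biasFactor[yrs[dayIdx]]
      if (anyNA(b)) stop("biasFactor must name every simulated year")
      unname(b)
    }
    noise <- exp(stats::rnorm(length(dayIdx), 0, config$monitorNoiseSd) -
                   config$monitorNoiseSd^2 / 2)
    predC <- config$carbonFraction * allv[cells[m], dayIdx]
    recs[[m]] <- data.frame(
      monitor_id = sprintf("M%03d", m),
      x = mx[m], y = my[m],
      date = dates[dayIdx],
      obs_carbon = unname(predC * bias * noise),
      pred_carbon = unname(predC),
      pred_fire_carbon = unname(config$carbonFraction *
                                  firev[cells[m], dayIdx]),
      stringsAsFactors = FALSE
    )
  }
  do.call(rbind, recs)
}

#' Generate a complete synthetic scenario
#'
#' Runs every generator with deterministic per-generator streams split from
#' the master seed and returns all pipeline inputs plus the stored truth:
#' the paired fields (with \code{fire_truth}), the unit polygons, the
#' centroid-rule cell assignment, the population table, the monitor records
#' and the event list.
#'
#' @inheritParams simulateBackground
#' @return list of class \code{SmokeScenario} with elements \code{fields},
#'   \code{units}, \code{assignment}, \code{population}, \code{monitors},
#'   \code{events}, \code{config}
#' @examples
#' sc <- simulateScenario(scenarioConfig(nYears = 1, nMonitors = 3, seed = 7))
#' sc$fields
#' @export
simulateScenario <- function(config) {
  stopifnot(inherits(config, "ScenarioConfig"))
  bg <- simulateBackground(config)
  fire <- simulateFire(config)
  fields <- composeFields(bg, fire, .scenarioGrid(config))
  units <- generateUnits(config)
  assignment <- assignCells(smokeGridOf(fields), units)
  population <- generatePopulation(config, unitIds(units))
  monitors <- if (config$nMonitors > 0L) generateMonitors(config, fields)
              else NULL
  structure(list(fields = fields, units = units, assignment = assignment,
                 population = population, monitors = monitors,
                 events = fire$events, config = config),
            class = "SmokeScenario")
}
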