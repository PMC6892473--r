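#' Read a per-unit population / health-count table
#'
#' The CSV must have a \code{unit_id} column plus numeric columns of
#' population or event counts (the conventional set: total_population,
#' under18, over65, poverty, asthma_ed, heart_attack, births -- but any
#' numeric columns are accepted). All values must be non-negative and unit
#' ids unique.
#'
#' @param path CSV path
#' @return data.frame keyed by unit_id
#' @export
readPopulationTable <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  .checkPopulationTable(df)
  df
}

.checkPopulationTable <- function(df) {
  if (!"unit_id" %in% names(df))
    stop("population table needs a unit_id column")
  if (anyDuplicated(df$unit_id))
    stop("duplicate unit_id in population table")
  num <- setdiff(names(df), c("unit_id", "name"))
  for (cn in num) {
    if (!is.numeric(df[[cn]]))
      stop(sprintf("population column '%s' must be numeric", cn))
    if (any(df[[cn]] < 0, na.rm = TRUE))
      stop(sprintf("population column '%s' has negative values", cn))
  }
  invisible(df)
}

#' Proportionally allocate a pooled count row to small units
#'
#' Some count sources pool small units into a single "unidentified" row
#' (e.g. birth registries that only identify units above a population
#' cut-off). This spreads the pooled row's value for \code{column} across
#' the receiving units proportionally to their \code{by} column (total
#' population by default), adds the shares to their own values, and drops
#' the pooled row.
#'
#' @param pop population table (data.frame with unit_id)
#' @param column name of the count column to allocate
#' @param pooledId unit_id of the pooled row
#' @param to character vector of receiving unit ids
#' @param by column used for proportional shares (default total_population)
#' @return the population table with the allocation applied
#' @export
allocatePooledCounts <- function(pop, column, pooledId, to,
                                 by = "total_population") {
  .checkPopulationTable(pop)
  i <- match(pooledId, pop$unit_id)
  if (is.na(i)) stop(sprintf("pooled row '%s' not found", pooledId))
  j <- match(to, pop$unit_id)
  if (anyNA(j)) stop("some receiving unit ids are not in the table")
  w <- pop[[by]][j]
  if (sum(w) <= 0) stop("receiving units have zero total weight")
  pop[[column]][j] <- pop[[column]][j] + pop[[column]][i] * w / sum(w)
  pop[-i, , drop = FALSE]
}

#' Tabulate populations at risk by exposure class
#'
#' Attributes each unit's population and event counts wholly to the unit's
#' exposure class (no within-unit apportionment) and sums per class. Units
#' present in the population table but without a class (empty units,
#' missing data) are summed in a "Missing" row; the "Total" row is the
#' column total over all units, so class rows plus Missing equal Total for
#' every variable.
#'
#' @param classes named integer vector mapping unit_id to class 1..4 (NA =
#'   missing); typically \code{classifyExposure} output named by unit
#' @param pop population table (data.frame with unit_id and numeric columns)
#' @return data.frame with a \code{class} column ("1".."4", "Missing",
#'   "Total") and one numeric column per input variable
#' @export
tabulateAtRisk <- function(classes, pop) {
  .checkPopulationTable(pop)
  if (is.null(names(classes)))
    stop("'classes' must be named by unit_id")
  if (any(!is.na(classes) & !(classes %in% 1:4)))
    stop("classes must be in 1..4 or NA")
  vars <- setdiff(names(pop), c("unit_id", "name"))
  cl <- classes[match(pop$unit_id, names(classes))]  # NA where unclassified
  rows <- c(as.character(1:4), "Missing", "Total")
  out <- data.frame(class = rows, stringsAsFactors = FALSE)
  for (v in vars) {
    s <- numeric(6)
    for (k in 1:4) s[k] <- sum(pop[[v]][!is.na(cl) & cl == k])
    s[5] <- sum(pop[[v]][is.na(cl)])
    s[6] <- sum(pop[[v]])
    out[[v]] <- s
  }
  out
}

#' Coerce a published class-level table to the at-risk layout
#'
#' Validates a data.frame already aggregated by exposure class (a
#' \code{class} column with values "1".."4", optionally "Missing" and
#' "Total"). If the Total row is absent it is computed as the column sum of
#' the class and Missing rows; if present it is kept as printed (published
#' tables sometimes round rows independently of their total).
#'
#' @param df data.frame with a class column and numeric variable columns
#' @return data.frame in the \code{\link{tabulateAtRisk}} layout
#' @export
asAtRiskTable <- function(df) {
  if (!"class" %in% names(df)) stop("need a 'class' column")
  df$class <- as.character(df$class)
  known <- c(as.character(1:4), "Missing", "Total")
  if (!all(df$class %in% known))
    stop("class values must be 1..4, Missing or Total")
  if (anyDuplicated(df$class)) stop("duplicate class rows")
  vars <- setdiff(names(df), "class")
  have <- df$class
  rows <- c(as.character(1:4), "Missing", "Total")
  out <- data.frame(class = rows, stringsAsFactors = FALSE)
  for (v in vars) {
    s <- numeric(6); names(s) <- rows
    s[have[have != "Total"]] <- df[[v]][df$class != "Total"]
    s["Total"] <- if ("Total" %in% have) df[[v]][df$class == "Total"]
                  else sum(s[1:5])
    out[[v]] <- unname(s)
  }
  out
}

#' Share of each variable in exposure classes at or above a cut point
#'
#' For every variable, sums the class rows with class >= \code{minClass} and
#' expresses the sum as a percentage of the table's Total row. With the
#' default \code{minClass = 2} this is the share living in units above the
#' first quartile break (the "top three quartiles"). Values are returned
#' unrounded; presentation conventionally rounds population shares to one
#' decimal and event-count shares to the nearest integer.
#'
#' @param atRisk an at-risk table from \code{\link{tabulateAtRisk}} or
#'   \code{\link{asAtRiskTable}}
#' @param minClass lowest class included in the numerator (2..4)
#' @param variables variables to report (default: all)
#' @return data.frame with columns variable, sum_above, total, percent
#' @export
fractionAbove <- function(atRisk, minClass = 2, variables = NULL) {
  stopifnot("class" %in% names(atRisk))
  if (!(minClass %in% 1:4)) stop("minClass must be in 1..4")
  vars <- variables %||% setdiff(names(atRisk), "class")
  sel <- atRisk$class %in% as.character(seq(minClass, 4))
  tot <- atRisk$class == "Total"
  if (!any(tot)) stop("at-risk table has no Total row")
  out <- data.frame(variable = vars, sum_above = NA_real_, total = NA_real_,
                    percent = NA_real_, stringsAsFactors = FALSE)
  for (i in seq_along(vars)) {
    s <- sum(atRisk[[vars[i]]][sel])
    tt <- atRisk[[vars[i]]][tot]
    out$sum_above[i] <- s
    out$total[i] <- tt
    if (is.na(tt) || tt == 0) {
      warning(sprintf("zero or missing total for '%s'; percent undefined",
                      vars[i]))
    } else {
      out$percent[i] <- 100 * s / tt
    }
  }
  out
}

#' Population living in units with at least a given number of smokewaves
#'
#' Sums a population column over the units whose period smokewave total
#' meets \code{minTotalEpisodes}, and reports the share of the grand total.
#' Over a 7-year study period, thresholds of 7 and 14 correspond to "at
#' least one" and "at least two" smokewaves per year on average.
#'
#' @param counts named numeric vector of period smokewave totals per unit
#'   (e.g. the \code{total} column of \code{\link{smokewaveCounts}} named by
#'   id); NA counts (missing units) never qualify
#' @param pop population table
#' @param minTotalEpisodes minimum period episode count (>= 1)
#' @param column population column to sum (default total_population)
#' @return list with population, percent, n_units
#' @export
smokewavePopulation <- function(counts, pop, minTotalEpisodes,
                                column = "total_population") {
  .checkPopulationTable(pop)
  if (is.null(names(counts))) stop("'counts' must be named by unit_id")
  cc <- counts[match(pop$unit_id, names(counts))]
  qual <- !is.na(cc) & cc >= minTotalEpisodes
  tot <- sum(pop[[column]])
  s <- sum(pop[[column]][qual])
  list(population = s,
       percent = if (tot > 0) 100 * s / tot else NA_real_,
       n_units = sum(qual))
}

`%||%` <- function(a, b) if (is.null(a)) b else a
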