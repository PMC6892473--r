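suppressPackageStartupMessages(library(SummarizedExperiment))

# Independent oracles, deliberately written as plain scalar scans so they
# share no code path with the package internals.

# even-odd ray casting for a single open ring (classic j-trailing loop)
oraclePointInRing <- function(px, py, ring) {
  n <- nrow(ring)
  inside <- FALSE
  j <- n
  for (i in seq_len(n)) {
    xi <- ring[i, 1]; yi <- ring[i, 2]
    xj <- ring[j, 1]; yj <- ring[j, 2]
    if ((yi > py) != (yj > py)) {
      xint <- (xj - xi) * (py - yi) / (yj - yi) + xi
      if (px < xint) inside <- !inside
    }
    j <- i
  }
  inside
}

# exhaustive scan enumerating all maximal exceedance runs
oracleEpisodes <- function(v, threshold, minDays) {
  eps <- NULL
  i <- 1L
  n <- length(v)
  while (i <= n) {
    if (!is.na(v[i]) && v[i] > threshold) {
      j <- i
      while (j < n && !is.na(v[j + 1L]) && v[j + 1L] > threshold) j <- j + 1L
      if (j - i + 1L >= minDays)
        eps <- rbind(eps, data.frame(start = i, end = j, length = j - i + 1L,
                                     peak = max(v[i:j])))
      i <- j + 1L
    } else {
      i <- i + 1L
    }
  }
  if (is.null(eps))
    eps <- data.frame(start = integer(), end = integer(),
                      length = integer(), peak = numeric())
  eps
}

# a rectangle ring (open) from bounds
rectRing <- function(x0, y0, x1, y1) {
  rbind(c(x0, y0), c(x1, y0), c(x1, y1), c(x0, y1))
}

# small deterministic field set: values v[cell, day] = cell + day/10
toyFieldSet <- function(nCols = 2, nRows = 2, nDays = 4, cellSize = 1) {
  g <- smokeGrid(0, 0, cellSize, nCols = nCols, nRows = nRows)
  n <- nCols * nRows
  d <- as.Date("2008-01-01") + seq_len(nDays) - 1L
  all <- outer(seq_len(n), seq_len(nDays) / 10, `+`)
  nof <- matrix(1, n, nDays)
  smokeFieldSet(g, d, all_sources = all, no_fire = nof)
}
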