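#' Read administrative units from GeoJSON
#'
#' Reads a GeoJSON FeatureCollection of Polygon / MultiPolygon features into
#' an \linkS4class{AdminUnitSet}. Each feature must carry \code{unit_id} and
#' \code{name} properties. Coordinates are taken as planar values in the
#' grid's coordinate system; no reprojection is performed. All rings of a
#' (Multi)Polygon are pooled and interpreted under the even-odd parity rule,
#' so interior rings act as holes.
#'
#' @param path path to a GeoJSON file
#' @return an \linkS4class{AdminUnitSet}
#' @export
readUnitsGeoJSON <- function(path) {
  gj <- jsonlite::read_json(path, simplifyVector = FALSE)
  if (!identical(gj$type, "FeatureCollection"))
    stop("expected a GeoJSON FeatureCollection")
  feats <- gj$features
  ids <- character(length(feats)); nms <- character(length(feats))
  polys <- vector("list", length(feats))
  for (i in seq_along(feats)) {
    f <- feats[[i]]
    pr <- f$properties
    if (is.null(pr$unit_id) || is.null(pr$name))
      stop("each feature needs 'unit_id' and 'name' properties")
    ids[i] <- as.character(pr$unit_id)
    nms[i] <- as.character(pr$name)
    geom <- f$geometry
    ringList <- switch(geom$type,
      Polygon = geom$coordinates,
      MultiPolygon = do.call(c, geom$coordinates),
      stop(sprintf("unsupported geometry type '%s'", geom$type)))
    polys[[i]] <- lapply(ringList, function(ring)
      do.call(rbind, lapply(ring, function(pt) c(pt[[1]], pt[[2]]))))
  }
  adminUnits(ids, polys, nms)
}

#' Write administrative units (optionally with joined attributes) to GeoJSON
#'
#' Writes an \linkS4class{AdminUnitSet} as a FeatureCollection of Polygon
#' features. Extra per-unit attributes (e.g. smokewave counts for mapping)
#' can be joined onto the feature properties via \code{attributes}, a
#' data.frame keyed by \code{unit_id}.
#'
#' @param units an \linkS4class{AdminUnitSet}
#' @param path output path
#' @param attributes optional data.frame with a \code{unit_id} column; its
#'   remaining columns are added to each feature's properties
#' @return \code{path}, invisibly
#' @export
writeUnitsGeoJSON <- function(units, path, attributes = NULL) {
  if (!is.null(attributes)) {
    if (!"unit_id" %in% names(attributes))
      stop("'attributes' must have a unit_id column")
    if (anyDuplicated(attributes$unit_id))
      stop("duplicate unit_id in 'attributes'")
  }
  feats <- lapply(seq_along(units@unitIds), function(i) {
    props <- list(unit_id = units@unitIds[i], name = units@unitNames[i])
    if (!is.null(attributes)) {
      j <- match(units@unitIds[i], attributes$unit_id)
      if (!is.na(j))
        for (cn in setdiff(names(attributes), "unit_id"))
          props[[cn]] <- attributes[[cn]][j]
    }
    rings <- lapply(units@polygons[[i]], function(r) {
      r <- .closeRing(r)
      lapply(seq_len(nrow(r)), function(k) c(r[k, 1], r[k, 2]))
    })
    list(type = "Feature", properties = props,
         geometry = list(type = "Polygon", coordinates = rings))
  })
  out <- list(type = "FeatureCollection", features = feats)
  jsonlite::write_json(out, path, auto_unbox = TRUE, digits = NA,
                       pretty = FALSE)
  invisible(path)
}
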