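#' Read a GAL contiguity file
#'
#' GAL is the plain-text neighbour-list interchange format used by GeoDa:
#' a header line giving the number of regions, then for each region a line
#' `id count` followed by a line listing its neighbours' ids.
#'
#' @param path GAL file path.
#' @param symmetrize If `TRUE`, an asymmetric neighbour list (A lists B but
#'   B omits A) is repaired by taking the union; if `FALSE` (default) it is
#'   rejected.
#' @return An unstandardized `spatial_weights` object, region order as in
#'   the file.
#' @export
read_gal <- function(path, symmetrize = FALSE) {
  lines <- readLines(path)
  lines <- lines[trimws(lines) != ""]
  if (!length(lines)) stop("empty GAL file: ", path)
  header <- strsplit(trimws(lines[1L]), "\\s+")[[1L]]
  # GeoDa headers may carry "0 n shapefile key"; the count is the first
  # integer > 0
  nums <- suppressWarnings(as.integer(header))
  n <- nums[which(!is.na(nums) & nums > 0L)[1L]]
  if (is.na(n)) stop("GAL parse error at line 1: no region count in header")
  cursor <- 2L
  ids <- character(n)
  nbrs <- vector("list", n)
  for (r in seq_len(n)) {
    if (cursor > length(lines)) {
      stop("GAL parse error: file declares ", n, " regions but record ", r,
           " is missing (line ", cursor, ")")
    }
    rec <- strsplit(trimws(lines[cursor]), "\\s+")[[1L]]
    if (length(rec) != 2L) {
      stop("GAL parse error at line ", cursor,
           ": expected 'id count', got '", lines[cursor], "'")
    }
    k <- suppressWarnings(as.integer(rec[2L]))
    if (is.na(k) || k < 0L) {
      stop("GAL parse error at line ", cursor, ": bad neighbour count")
    }
    ids[r] <- rec[1L]
    if (k > 0L && cursor + 1L > length(lines)) {
      stop("GAL parse error: neighbour line for region '", rec[1L],
           "' missing after line ", cursor)
    }
    nb <- if (k == 0L) character(0) else
      strsplit(trimws(lines[cursor + 1L]), "\\s+")[[1L]]
    if (length(nb) != k) {
      stop("GAL parse error at line ", cursor + 1L, ": region '", rec[1L],
           "' declares ", k, " neighbours but lists ", length(nb))
    }
    nbrs[[r]] <- nb
    cursor <- cursor + (if (k == 0L) 1L else 2L)
  }
  regions <- region_set(ids)
  W0 <- matrix(0, n, n)
  for (r in seq_len(n)) {
    j <- match(nbrs[[r]], ids)
    if (anyNA(j)) {
      stop("GAL parse error: region '", ids[r], "' lists unknown neighbour ",
           paste(nbrs[[r]][is.na(j)], collapse = ", "))
    }
    W0[r, j] <- 1
  }
  if (any(W0 != t(W0))) {
    if (!symmetrize) {
      bad <- which(W0 != t(W0), arr.ind = TRUE)[1L, ]
      stop("asymmetric GAL neighbour structure (e.g. ", ids[bad[1L]],
           " vs ", ids[bad[2L]], "); use symmetrize = TRUE to take the union")
    }
    W0 <- pmax(W0, t(W0))
  }
  diag(W0) <- 0
  new_spatial_weights(regions, W0)
}

#' Write a weights object to a GAL file
#'
#' @param w A `spatial_weights` object (binary structure is written).
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_gal <- function(w, path) {
  stopifnot(inherits(w, "spatial_weights"))
  ids <- w$regions$ids
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(as.character(w$regions$n), con)
  for (r in seq_len(w$regions$n)) {
    nb <- ids[w$W0[r, ] != 0]
    writeLines(paste(ids[r], length(nb)), con)
    if (length(nb)) writeLines(paste(nb, collapse = " "), con)
  }
  invisible(path)
}

#' Read polygons from a GeoJSON file
#'
#' Minimal reader for FeatureCollections of `Polygon` / `MultiPolygon`
#' geometries, returning outer rings keyed by a feature property. Intended
#' as input for [build_rook_from_polygons()].
#'
#' @param path GeoJSON file.
#' @param id_property Name of the feature property holding the region id.
#' @return Named list of two-column coordinate matrices (outer rings; a
#'   MultiPolygon contributes its largest part's outer ring).
#' @export
read_geojson_polygons <- function(path, id_property = "id") {
  gj <- jsonlite::read_json(path)
  if (is.null(gj$features)) stop("not a GeoJSON FeatureCollection: ", path)
  out <- list()
  for (f in gj$features) {
    id <- f$properties[[id_property]]
    if (is.null(id)) {
      stop("feature without property '", id_property, "' in ", path)
    }
    geom <- f$geometry
    ring <- switch(geom$type,
      Polygon = geom$coordinates[[1L]],
      MultiPolygon = {
        parts <- lapply(geom$coordinates, `[[`, 1L)
        parts[[which.max(vapply(parts, length, 1L))]]
      },
      stop("unsupported geometry type: ", geom$type)
    )
    out[[as.character(id)]] <-
      do.call(rbind, lapply(ring, function(p) c(p[[1L]], p[[2L]])))
  }
  out
}

#' Rook adjacency of mainland China's 31 provinces
#'
#' Loads the packaged provincial adjacency edge list. The edge list was
#' reconstructed from public provincial geography (it is a package fixture,
#' not an official boundary product). Hainan, an island, has no shared land
#' boundary; by the usual convention it is linked to its geographically
#' closest province, Guangdong, which is applied here unless
#' `patch_hainan = FALSE`.
#'
#' @param patch_hainan Link Hainan to Guangdong (default `TRUE`).
#' @param standardize Row-standardize the result (default `TRUE`).
#' @return A `spatial_weights` object over the 31 provinces.
#' @export
china_provinces <- function(patch_hainan = TRUE, standardize = TRUE) {
  path <- system.file("extdata", "china_provinces_edges.csv",
                      package = "spatpanel", mustWork = TRUE)
  ids_path <- system.file("extdata", "china_provinces_ids.txt",
                          package = "spatpanel", mustWork = TRUE)
  regions <- region_set(readLines(ids_path))
  w <- read_edge_csv(path, regions)
  if (patch_hainan) {
    w <- patch_islands(w, cbind("Hainan", "Guangdong"))
  }
  if (standardize) w <- row_standardize(w)
  w
}
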