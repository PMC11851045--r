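#' Define an ordered set of regions
#'
#' A `region_set` fixes the identity and ordering of the spatial units.
#' Every weight matrix, attribute vector and panel built downstream shares
#' this ordering, so results can be joined back to region identifiers
#' without ambiguity.
#'
#' @param ids Character vector of unique region identifiers (at least 2).
#' @return An object of class `region_set` with elements `ids` and `n`.
#' @export
region_set <- function(ids) {
  ids <- as.character(ids)
  if (anyDuplicated(ids)) {
    stop("region ids must be unique; duplicated: ",
         paste(unique(ids[duplicated(ids)]), collapse = ", "))
  }
  if (length(ids) < 2L) stop("a region set needs at least 2 regions")
  structure(list(ids = ids, n = length(ids)), class = "region_set")
}

#' @export
print.region_set <- function(x, ...) {
  cat("<region_set> n =", x$n, "\n")
  cat(" ", paste(utils::head(x$ids, 8L), collapse = ", "),
      if (x$n > 8L) "...", "\n")
  invisible(x)
}

as_region_set <- function(x) {
  if (inherits(x, "region_set")) return(x)
  region_set(x)
}

new_spatial_weights <- function(regions, W0, standardized = FALSE, W = NULL) {
  dimnames(W0) <- list(regions$ids, regions$ids)
  stopifnot(nrow(W0) == regions$n, ncol(W0) == regions$n)
  if (any(diag(W0) != 0)) stop("contiguity matrix must have zero diagonal")
  if (!isTRUE(all.equal(W0, t(W0), tolerance = 0)) && any(W0 != t(W0))) {
    stop("contiguity matrix must be symmetric")
  }
  if (!is.null(W)) dimnames(W) <- list(regions$ids, regions$ids)
  structure(
    list(regions = regions, W0 = W0, W = W, standardized = standardized),
    class = "spatial_weights"
  )
}

#' @export
print.spatial_weights <- function(x, ...) {
  deg <- rowSums(x$W0)
  cat("<spatial_weights> n =", x$regions$n,
      " links =", sum(x$W0) / 2,
      " standardized:", x$standardized, "\n")
  if (any(deg == 0)) {
    cat("  isolates:", paste(x$regions$ids[deg == 0], collapse = ", "), "\n")
  }
  invisible(x)
}

#' Region identifiers of a weights object
#' @param w A `spatial_weights` object.
#' @return Character vector of region ids in matrix order.
#' @export
region_ids <- function(w) w$regions$ids

#' Isolated regions of a weights object
#' @param w A `spatial_weights` object.
#' @return Character vector of ids whose contiguity row is all zero.
#' @export
isolates <- function(w) w$regions$ids[rowSums(w$W0) == 0]

#' Build a rook-contiguity weight matrix from an edge list
#'
#' Each edge declares a shared boundary between two regions; the resulting
#' binary matrix `W0` has a symmetric 1 for every listed pair and 0
#' elsewhere. The matrix is not row-standardized yet; see
#' [row_standardize()].
#'
#' @param edges Two-column matrix or data frame of region-id pairs
#'   (columns `src`, `dst` or positional).
#' @param regions A `region_set` (or character vector of ids) fixing order.
#' @return An unstandardized `spatial_weights` object.
#' @examples
#' w <- build_rook_from_edges(cbind(c("A", "B"), c("B", "C")),
#'                            region_set(c("A", "B", "C")))
#' w$W0
#' @export
build_rook_from_edges <- function(edges, regions) {
  regions <- as_region_set(regions)
  if (is.data.frame(edges)) edges <- as.matrix(edges)
  if (length(edges) == 0L) {
    edges <- matrix(character(0), ncol = 2L)
  }
  if (ncol(edges) != 2L) stop("edges must have two columns (src, dst)")
  edges <- matrix(as.character(edges), ncol = 2L,
                  dimnames = list(NULL, c("src", "dst")))
  unknown <- setdiff(c(edges), regions$ids)
  if (length(unknown)) {
    stop("unknown region id(s) in edge list: ",
         paste(unique(unknown), collapse = ", "))
  }
  if (any(edges[, 1L] == edges[, 2L])) {
    stop("self-pairs are not allowed in a contiguity edge list")
  }
  W0 <- matrix(0, regions$n, regions$n)
  i <- match(edges[, 1L], regions$ids)
  j <- match(edges[, 2L], regions$ids)
  W0[cbind(i, j)] <- 1
  W0[cbind(j, i)] <- 1
  new_spatial_weights(regions, W0)
}

#' Derive rook contiguity from polygon geometries
#'
#' Two regions are adjacent if and only if their boundaries share a segment
#' of positive length; polygons touching only at a corner point are not
#' neighbours (rook, not queen).
#'
#' @param geoms Named list of polygons, each a two-column coordinate matrix
#'   of the outer ring (closed or open), or the parsed result of
#'   [read_geojson_polygons()].
#' @param tol Coordinate tolerance for segment matching (default `1e-9`).
#' @return An unstandardized `spatial_weights` object over `names(geoms)`.
#' @export
build_rook_from_polygons <- function(geoms, tol = 1e-9) {
  if (is.null(names(geoms)) || any(names(geoms) == "")) {
    stop("polygon list must be named by region id")
  }
  rings <- lapply(geoms, function(g) {
    g <- as.matrix(g)
    if (ncol(g) != 2L || nrow(g) < 3L) stop("invalid polygon geometry")
    if (any(!is.finite(g))) stop("invalid polygon geometry: non-finite coords")
    # close the ring if open
    if (any(abs(g[1L, ] - g[nrow(g), ]) > tol)) g <- rbind(g, g[1L, ])
    g
  })
  regions <- region_set(names(geoms))
  n <- regions$n
  W0 <- matrix(0, n, n)
  segs <- lapply(rings, ring_segments)
  for (a in seq_len(n - 1L)) {
    for (b in (a + 1L):n) {
      if (shared_boundary_length(segs[[a]], segs[[b]], tol) > tol) {
        W0[a, b] <- W0[b, a] <- 1
      }
    }
  }
  new_spatial_weights(regions, W0)
}

ring_segments <- function(ring) {
  m <- nrow(ring) - 1L
  cbind(ring[seq_len(m), , drop = FALSE], ring[seq_len(m) + 1L, , drop = FALSE])
}

# Total length of collinear overlap between two segment sets.
shared_boundary_length <- function(sa, sb, tol) {
  total <- 0
  for (i in seq_len(nrow(sa))) {
    p1 <- sa[i, 1:2]; p2 <- sa[i, 3:4]
    d <- p2 - p1
    len <- sqrt(sum(d^2))
    if (len <= tol) next
    u <- d / len
    for (j in seq_len(nrow(sb))) {
      q1 <- sb[j, 1:2]; q2 <- sb[j, 3:4]
      # both endpoints of the other segment must lie on the line of (p1,p2)
      off1 <- abs((q1[1] - p1[1]) * u[2] - (q1[2] - p1[2]) * u[1])
      off2 <- abs((q2[1] - p1[1]) * u[2] - (q2[2] - p1[2]) * u[1])
      if (off1 > tol || off2 > tol) next
      t1 <- sum((q1 - p1) * u)
      t2 <- sum((q2 - p1) * u)
      lo <- max(0, min(t1, t2))
      hi <- min(len, max(t1, t2))
      if (hi - lo > tol) total <- total + (hi - lo)
    }
  }
  total
}

#' Patch isolated regions into a contiguity matrix
#'
#' Regions without any shared land boundary (in the packaged China fixture,
#' the island province Hainan) are linked by hand to a stated mainland
#' neighbour, mirroring the convention of assigning an island to its
#' geographically closest province.
#'
#' @param w A `spatial_weights` object (unstandardized).
#' @param patch_pairs Two-column matrix/data frame of (isolate, neighbour)
#'   id pairs.
#' @return `spatial_weights` with the symmetric links added. Errors if any
#'   isolate remains after patching.
#' @export
patch_islands <- function(w, patch_pairs) {
  stopifnot(inherits(w, "spatial_weights"))
  W0 <- w$W0
  ids <- w$regions$ids
  if (length(patch_pairs)) {
    if (is.data.frame(patch_pairs)) patch_pairs <- as.matrix(patch_pairs)
    patch_pairs <- matrix(as.character(patch_pairs), ncol = 2L)
    unknown <- setdiff(c(patch_pairs), ids)
    if (length(unknown)) {
      stop("unknown region id(s) in patch list: ",
           paste(unique(unknown), collapse = ", "))
    }
    iso <- isolates(w)
    for (r in seq_len(nrow(patch_pairs))) {
      a <- patch_pairs[r, 1L]; b <- patch_pairs[r, 2L]
      if (a == b) stop("patch pair may not be a self-pair: ", a)
      if (!(a %in% iso)) {
        warning("patch names '", a, "' as isolate but it already has ",
                "neighbours; link added anyway")
      }
      i <- match(a, ids); j <- match(b, ids)
      W0[i, j] <- W0[j, i] <- 1
    }
  }
  out <- new_spatial_weights(w$regions, W0)
  left <- isolates(out)
  if (length(left)) {
    stop("isolated region(s) remain after patching: ",
         paste(left, collapse = ", "))
  }
  out
}

#' Nearest-neighbour candidates for isolates
#'
#' Helper for assembling a patch list: for every isolated region it reports
#' the non-isolated region with the smallest centroid distance. The user
#' confirms (or overrides) the pairing before calling [patch_islands()].
#'
#' @param w A `spatial_weights` object.
#' @param centroids Two-column matrix of region centroids, rows ordered as
#'   `region_ids(w)` (or named by id).
#' @return Data frame with columns `isolate`, `candidate`, `distance`.
#' @export
suggest_island_patches <- function(w, centroids) {
  centroids <- as.matrix(centroids)
  if (!is.null(rownames(centroids))) {
    centroids <- centroids[w$regions$ids, , drop = FALSE]
  }
  stopifnot(nrow(centroids) == w$regions$n)
  iso <- isolates(w)
  if (!length(iso)) {
    return(data.frame(isolate = character(0), candidate = character(0),
                      distance = numeric(0)))
  }
  others <- setdiff(w$regions$ids, iso)
  out <- lapply(iso, function(a) {
    d <- sqrt(colSums((t(centroids[others, , drop = FALSE]) -
                         centroids[match(a, w$regions$ids), ])^2))
    data.frame(isolate = a, candidate = others[which.min(d)],
               distance = min(d))
  })
  do.call(rbind, out)
}

#' Row-standardize a contiguity matrix
#'
#' Divides every row of the binary matrix by its row sum so the spatial lag
#' `W x` becomes a neighbour average; this is the conventional scaling for
#' Moran statistics and for the spatial panel likelihoods, and the closed
#' form of the total-effect decomposition assumes it.
#'
#' @param w A `spatial_weights` object with no isolated rows.
#' @return `spatial_weights` with `W` filled and `standardized = TRUE`.
#' @export
row_standardize <- function(w) {
  stopifnot(inherits(w, "spatial_weights"))
  iso <- isolates(w)
  if (length(iso)) {
    stop("cannot row-standardize: isolated region(s) ",
         paste(iso, collapse = ", "))
  }
  W <- w$W0 / rowSums(w$W0)
  new_spatial_weights(w$regions, w$W0, standardized = TRUE, W = W)
}

#' Active weight matrix of a weights object
#'
#' @param w A `spatial_weights` object.
#' @param binary If `TRUE` return the binary `W0` even when a standardized
#'   matrix is available.
#' @return Numeric n-by-n matrix.
#' @export
weights_matrix <- function(w, binary = FALSE) {
  if (binary || !w$standardized) w$W0 else w$W
}

#' Read an edge-list CSV into a rook weights object
#'
#' @param path CSV file with header columns `src,dst`.
#' @param regions Optional `region_set`; defaults to the sorted union of ids
#'   appearing in the file.
#' @return An unstandardized `spatial_weights` object.
#' @export
read_edge_csv <- function(path, regions = NULL) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  if (!all(c("src", "dst") %in% names(df))) {
    stop("edge CSV must have header columns src,dst: ", path)
  }
  if (is.null(regions)) {
    regions <- region_set(sort(unique(c(df$src, df$dst))))
  }
  build_rook_from_edges(df[, c("src", "dst")], regions)
}

#' Write a weights object as an edge-list CSV
#' @param w A `spatial_weights` object.
#' @param path Output file.
#' @return `path`, invisibly.
#' @export
write_edge_csv <- function(w, path) {
  idx <- which(upper.tri(w$W0) & w$W0 != 0, arr.ind = TRUE)
  df <- data.frame(src = w$regions$ids[idx[, 1L]],
                   dst = w$regions$ids[idx[, 2L]])
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}
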