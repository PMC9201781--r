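# Range-dynamics post-processing: presence maps, centroids, migration
# vectors, cost distances, least-cost corridors and the corridor network.

#' Threshold a suitability raster into presence/absence
#'
#' @param suit suitability raster.
#' @param threshold presence threshold (cell >= threshold -> 1).
#' @return binary `hg_raster` (nodata preserved).
#' @export
presence_absence <- function(suit, threshold) {
  stopifnot(is.finite(threshold))
  v <- (suit$values >= threshold) + 0
  new_raster(v, suit$xllcorner, suit$yllcorner, suit$cellsize, suit$nodata)
}

#' Invert suitability into a friction (dispersal cost) layer
#'
#' `friction = 1 - suitability`; values must lie in `[0, 1]`.
#'
#' @param suit suitability raster in `[0, 1]`.
#' @return friction `hg_raster`.
#' @export
friction_layer <- function(suit) {
  v <- suit$values
  if (any(v < -1e-12 | v > 1 + 1e-12, na.rm = TRUE))
    hg_stop("suitability values outside [0, 1]")
  new_raster(1 - v, suit$xllcorner, suit$yllcorner, suit$cellsize, suit$nodata)
}

#' Presence-block centroids
#'
#' Partitions the raster into square blocks of `block_deg` (which must be
#' a multiple of the cell size, anchored at the raster origin) and returns,
#' for every block containing at least one presence cell, the unweighted
#' mean of the centers of its presence cells.
#'
#' @param pa binary presence/absence raster.
#' @param block_deg block size in degrees.
#' @return data.frame with `lon`, `lat`, `n_cells`, `block`.
#' @export
block_centroids <- function(pa, block_deg = 0.625) {
  ratio <- block_deg / pa$cellsize
  if (abs(ratio - round(ratio)) > 1e-6)
    hg_stop("block size must be a multiple of the cell size")
  ax <- raster_axes(pa)
  idx <- which(pa$values == 1, arr.ind = TRUE)
  if (!nrow(idx))
    return(data.frame(lon = numeric(0), lat = numeric(0),
                      n_cells = integer(0), block = character(0)))
  cx <- ax$x[idx[, 2]]
  cy <- ax$y[idx[, 1]]
  bx <- floor((cx - pa$xllcorner) / block_deg)
  by <- floor((cy - pa$yllcorner) / block_deg)
  key <- paste(bx, by)
  out <- data.frame(lon = as.numeric(tapply(cx, key, mean)),
                    lat = as.numeric(tapply(cy, key, mean)),
                    n_cells = as.integer(tapply(cx, key, length)),
                    block = names(tapply(cx, key, mean)))
  rownames(out) <- NULL
  out[order(out$lon, out$lat), ]
}

#' Migration vectors between two centroid sets
#'
#' One vector per first-period centroid, pointing to its great-circle
#' nearest second-period centroid (ties resolve to the smallest (lon,
#' lat) pair).
#'
#' @param c1,c2 data.frames with `lon`, `lat` (from [block_centroids()]).
#' @return data.frame `from_lon, from_lat, to_lon, to_lat, length_km`.
#' @export
migration_vectors <- function(c1, c2) {
  if (!nrow(c2)) hg_stop("second-period centroid set is empty")
  c2 <- c2[order(c2$lon, c2$lat), ]
  out <- lapply(seq_len(nrow(c1)), function(i) {
    d <- great_circle_km(c(c1$lon[i], c1$lat[i]), cbind(c2$lon, c2$lat))
    j <- which(d <= min(d) + 1e-9)[1]
    data.frame(from_lon = c1$lon[i], from_lat = c1$lat[i],
               to_lon = c2$lon[j], to_lat = c2$lat[j], length_km = d[j])
  })
  do.call(rbind, out)
}

# 8-connected lattice over valid cells; edge weight = mean friction of the
# two cells times step length (1 orthogonal, sqrt(2) diagonal, cell units)
make_cost_graph <- function(friction) {
  f <- friction$values
  nr <- nrow(f); nc <- ncol(f)
  id <- matrix(seq_len(nr * nc), nr, nc)
  edges <- list(); w <- list()
  shifts <- list(c(0, 1, 1), c(1, 0, 1), c(1, 1, sqrt(2)), c(1, -1, sqrt(2)))
  for (s in shifts) {
    dr <- s[1]; dc <- s[2]; len <- s[3]
    r1 <- seq_len(nr - dr)
    c1 <- if (dc >= 0) seq_len(nc - dc) else seq(1 - dc, nc)
    a <- id[r1, c1, drop = FALSE]
    b <- id[r1 + dr, c1 + dc, drop = FALSE]
    fa <- f[a]; fb <- f[b]
    ok <- !is.na(fa) & !is.na(fb)
    edges[[length(edges) + 1L]] <- cbind(a[ok], b[ok])
    w[[length(w) + 1L]] <- (fa[ok] + fb[ok]) / 2 * len
  }
  em <- do.call(rbind, edges)
  g <- igraph::make_empty_graph(n = nr * nc, directed = FALSE)
  g <- igraph::add_edges(g, t(em))
  igraph::E(g)$weight <- unlist(w)
  g
}

#' Accumulated cost distance from a source point
#'
#' Dijkstra shortest-path cost over the 8-connected cell lattice; moving
#' between adjacent cells costs the mean of their friction values times
#' the step length (1 orthogonal, sqrt(2) diagonal, in cell units).
#' Nodata cells are impassable.
#'
#' @param friction friction raster.
#' @param source `c(lon, lat)` on a valid cell.
#' @param graph optional precomputed lattice graph (internal reuse).
#' @return `hg_raster` of accumulated costs (unreachable cells `Inf`,
#'   nodata preserved as `NA`).
#' @export
cost_distance <- function(friction, source, graph = NULL) {
  rc <- raster_cell(friction, source[1], source[2])
  if (anyNA(rc)) hg_stop("source outside raster extent")
  if (is.na(friction$values[rc])) hg_stop("source on a nodata cell")
  if (is.null(graph)) graph <- make_cost_graph(friction)
  v <- (rc[, "col"] - 1) * friction$nrows + rc[, "row"]
  dist <- igraph::distances(graph, v = v, algorithm = "dijkstra")[1, ]
  m <- matrix(dist, friction$nrows, friction$ncols)
  m[is.na(friction$values)] <- NA
  new_raster(m, friction$xllcorner, friction$yllcorner, friction$cellsize,
             friction$nodata)
}

#' Least-cost corridor between two points
#'
#' The corridor-cost surface is `cost_from_a + cost_from_b`; its minimum
#' is the least-cost-path (LCP) cost. Cells are classed by the fraction
#' by which their corridor cost exceeds the LCP cost:
#' `[0, 1%) -> weight 5`, `[1%, 2%) -> 2`, `[2%, 5%) -> 1`, else 0
#' (disjoint bands; set `cumulative = TRUE` to let inner bands also carry
#' the outer weights summed).
#'
#' @param friction friction raster.
#' @param a,b endpoints `c(lon, lat)`.
#' @param classes upper class bounds as fractions above the LCP cost.
#' @param weights integer weight per class (same length).
#' @param cumulative sum class weights cumulatively instead of banding.
#' @param graph optional precomputed lattice graph.
#' @return list with `surface` (weighted `hg_raster`), `lcp_cost`,
#'   `classes`, `weights`.
#' @export
least_cost_corridor <- function(friction, a, b,
                                classes = c(0.01, 0.02, 0.05),
                                weights = c(5, 2, 1),
                                cumulative = FALSE, graph = NULL) {
  stopifnot(length(classes) == length(weights))
  if (is.null(graph)) graph <- make_cost_graph(friction)
  ca <- cost_distance(friction, a, graph = graph)
  cb <- cost_distance(friction, b, graph = graph)
  cc <- ca$values + cb$values
  lcp <- suppressWarnings(min(cc, na.rm = TRUE))
  out <- matrix(0, friction$nrows, friction$ncols)
  if (!is.finite(lcp)) {
    warning("endpoints unreachable from each other: empty corridor surface")
    out[is.na(friction$values)] <- NA
    return(list(surface = new_raster(out, friction$xllcorner, friction$yllcorner,
                                     friction$cellsize, friction$nodata),
                lcp_cost = Inf, classes = classes, weights = weights))
  }
  ratio <- if (lcp > 0) (cc - lcp) / lcp else ifelse(cc > lcp, Inf, 0)
  bounds <- c(0, classes)
  for (i in seq_along(classes)) {
    sel <- !is.na(ratio) & is.finite(ratio) &
      ratio >= bounds[i] & ratio < bounds[i + 1]
    if (cumulative) {
      inner <- !is.na(ratio) & is.finite(ratio) & ratio < bounds[i + 1]
      out[inner] <- out[inner] + weights[i]
    } else {
      out[sel] <- weights[i]
    }
  }
  out[is.na(friction$values)] <- NA
  list(surface = new_raster(out, friction$xllcorner, friction$yllcorner,
                            friction$cellsize, friction$nodata),
       lcp_cost = lcp, classes = classes, weights = weights)
}

#' Summed least-cost-corridor network over shared-haplotype site pairs
#'
#' Computes the weighted corridor surface for every site pair that shares
#' a haplotype and sums them into a dispersal-network raster. Cost fields
#' are cached per site, so each site costs one Dijkstra pass.
#'
#' @param ds an `hg_dataset` (already thinned to one site per grid cell).
#' @param suit suitability raster in `[0, 1]`.
#' @param pairs data.frame of site pairs (default
#'   [shared_haplotype_pairs()]).
#' @param classes,weights,cumulative corridor classing, see
#'   [least_cost_corridor()].
#' @return an `hg_corridors`: `surface` (summed weights), `pair_costs`
#'   (per-pair LCP costs), `classes`, `weights`.
#' @export
corridor_network <- function(ds, suit, pairs = shared_haplotype_pairs(ds),
                             classes = c(0.01, 0.02, 0.05),
                             weights = c(5, 2, 1), cumulative = FALSE) {
  friction <- friction_layer(suit)
  total <- matrix(0, friction$nrows, friction$ncols)
  total[is.na(friction$values)] <- NA
  if (!nrow(pairs)) {
    warning("no shared-haplotype pairs: zero corridor surface")
    return(structure(list(surface = new_raster(total, friction$xllcorner,
                                               friction$yllcorner,
                                               friction$cellsize,
                                               friction$nodata),
                          pair_costs = data.frame(), classes = classes,
                          weights = weights),
                     class = "hg_corridors"))
  }
  graph <- make_cost_graph(friction)
  cache <- list()
  cost_of <- function(code) {
    if (is.null(cache[[code]])) {
      i <- match(code, ds$sites$code)
      cache[[code]] <<- cost_distance(friction,
                                      c(ds$sites$lon[i], ds$sites$lat[i]),
                                      graph = graph)
    }
    cache[[code]]
  }
  costs <- numeric(nrow(pairs))
  for (p in seq_len(nrow(pairs))) {
    ca <- cost_of(pairs$a[p]); cb <- cost_of(pairs$b[p])
    cc <- ca$values + cb$values
    lcp <- suppressWarnings(min(cc, na.rm = TRUE))
    costs[p] <- lcp
    if (!is.finite(lcp)) next
    ratio <- if (lcp > 0) (cc - lcp) / lcp else ifelse(cc > lcp, Inf, 0)
    bounds <- c(0, classes)
    for (i in seq_along(classes)) {
      if (cumulative) {
        sel <- !is.na(ratio) & is.finite(ratio) & ratio < bounds[i + 1]
      } else {
        sel <- !is.na(ratio) & is.finite(ratio) &
          ratio >= bounds[i] & ratio < bounds[i + 1]
      }
      total[sel] <- total[sel] + weights[i]
    }
  }
  structure(list(surface = new_raster(total, friction$xllcorner,
                                      friction$yllcorner, friction$cellsize,
                                      friction$nodata),
                 pair_costs = data.frame(a = pairs$a, b = pairs$b,
                                         lcp_cost = costs),
                 classes = classes, weights = weights),
            class = "hg_corridors")
}

#' @export
print.hg_corridors <- function(x, ...) {
  cat("corridor network:", nrow(x$pair_costs), "site pairs, max summed weight",
      max(x$surface$values, na.rm = TRUE), "\n")
  invisible(x)
}
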