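# Synthetic-data generators: alignments realizing a haplotype network,
# multi-site count data, environmental landscapes and occurrence samples.
# All generators are pure functions of (parameters, seed).

#' Network specification of the packaged study system
#'
#' The five-haplotype linear network of the packaged dataset: path
#' H2 -1- H1 -3- H4 -2- H3 -1- H5 (seven mutational steps in total over a
#' 717-bp indel-coded alignment), with one step of the H1-H4 branch
#' realized as a 96-bp indel.
#'
#' @return an `hg_networkspec`: `labels`, `branches` (from, to, steps),
#'   `L`, `indel` (branch + length), `counts` (default per-haplotype
#'   sample sizes for the packaged synthetic alignment).
#' @export
paper_network_spec <- function() {
  new_network_spec(
    labels = paste0("H", 1:5),
    branches = data.frame(from = c("H2", "H1", "H4", "H3"),
                          to = c("H1", "H4", "H3", "H5"),
                          steps = c(1L, 3L, 2L, 1L)),
    L = 717L,
    indel = list(branch = c("H1", "H4"), length = 96L),
    counts = c(H1 = 3L, H2 = 1L, H3 = 3L, H4 = 1L, H5 = 2L))
}

#' Construct a haplotype network specification
#'
#' @param labels haplotype labels.
#' @param branches data.frame (`from`, `to`, `steps` >= 1) forming a tree.
#' @param L coded alignment length (bp); total steps must not exceed L.
#' @param indel optional list (`branch` = c(from, to), `length` bp): one
#'   step of that branch is realized as a shared gap run.
#' @param counts per-haplotype sample counts.
#' @return an `hg_networkspec`.
#' @export
new_network_spec <- function(labels, branches, L, indel = NULL,
                             counts = NULL) {
  stopifnot(all(branches$steps >= 1), sum(branches$steps) <= L)
  if (is.null(counts)) counts <- stats::setNames(rep(1L, length(labels)), labels)
  structure(list(labels = labels, branches = branches, L = as.integer(L),
                 indel = indel, counts = counts),
            class = "hg_networkspec")
}

#' Path-sum distance matrix of a network specification
#'
#' @param spec an `hg_networkspec`.
#' @return labelled step-distance matrix over the observed haplotypes.
#' @export
spec_distances <- function(spec) {
  g <- igraph::graph_from_data_frame(spec$branches, directed = FALSE)
  d <- igraph::distances(g, weights = spec$branches$steps)
  d[spec$labels, spec$labels]
}

#' Generate an alignment realizing a network specification
#'
#' A random invariant backbone is drawn and each branch step toggles one
#' distinct random column, so collapsed haplotypes reproduce the
#' specified path distances exactly; an indel step is realized as a
#' shared gap run (so the raw alignment is `indel_length - 1` columns
#' longer than the coded length `L`).
#'
#' @param spec an `hg_networkspec`.
#' @param seed integer seed.
#' @return an `hg_alignment` with `sum(spec$counts)` records, ordered so
#'   that haplotype first appearances follow the label order.
#' @export
generate_alignment <- function(spec, seed = 1) {
  set.seed(seed)
  total_steps <- sum(spec$branches$steps)
  has_indel <- !is.null(spec$indel)
  L_raw <- spec$L + if (has_indel) spec$indel$length - 1L else 0L
  backbone <- sample(c("A", "C", "G", "T"), L_raw, replace = TRUE)
  n_sub <- total_steps - if (has_indel) 1L else 0L
  # reserve a contiguous block for the indel, then distinct substitution sites
  if (has_indel) {
    start <- sample.int(L_raw - spec$indel$length + 1L, 1)
    block <- start:(start + spec$indel$length - 1L)
  } else block <- integer(0)
  sub_cols <- sample(setdiff(seq_len(L_raw), block), n_sub)
  # assign step events to branches
  g <- igraph::graph_from_data_frame(spec$branches, directed = FALSE)
  seqs <- matrix(backbone, nrow = length(spec$labels), ncol = L_raw,
                 byrow = TRUE, dimnames = list(spec$labels, NULL))
  root <- spec$labels[1]
  # walk the tree from the root; each branch applies its own step columns
  col_pool <- sub_cols
  apply_branch <- function(parent, child, steps, carries_indel) {
    n_cols <- steps - if (carries_indel) 1L else 0L
    cols <- integer(0)
    if (n_cols > 0) {
      cols <- col_pool[seq_len(n_cols)]
      col_pool <<- col_pool[-seq_len(n_cols)]
    }
    # child and everything beyond inherits the changes
    sub <- igraph::delete_edges(g, igraph::get_edge_ids(g, c(parent, child)))
    comp <- igraph::components(sub)$membership
    below <- names(comp)[comp == comp[child]]
    for (cl in cols) {
      cur <- seqs[child, cl]
      seqs[below, cl] <<- sample(setdiff(c("A", "C", "G", "T"), cur), 1)
    }
    if (carries_indel) seqs[below, block] <<- "-"
  }
  visited <- root
  queue <- root
  while (length(queue)) {
    parent <- queue[1]; queue <- queue[-1]
    kids <- spec$branches[spec$branches$from == parent | spec$branches$to == parent, ]
    for (r in seq_len(nrow(kids))) {
      child <- if (kids$from[r] == parent) kids$to[r] else kids$from[r]
      if (child %in% visited) next
      carries <- has_indel &&
        setequal(c(kids$from[r], kids$to[r]), spec$indel$branch)
      apply_branch(parent, child, kids$steps[r], carries)
      visited <- c(visited, child)
      queue <- c(queue, child)
    }
  }
  ids <- character(0); rows <- integer(0)
  for (h in seq_along(spec$labels)) {
    lab <- spec$labels[h]
    cnt <- spec$counts[[lab]] %||% 1L
    ids <- c(ids, sprintf("ind%02d_%02d", h, seq_len(cnt)))
    rows <- c(rows, rep(h, cnt))
  }
  new_alignment(ids, seqs[rows, , drop = FALSE])
}

#' Generate a multi-site haplotype count dataset
#'
#' Emulates near-fixed two-region structure: per-site counts are
#' multinomial draws from region-specific haplotype frequencies, and
#' coordinates scatter around two cluster centers. Ground-truth group
#' labels are kept in the `group` column.
#'
#' @param n_sites total number of sites (split evenly between regions).
#' @param region_freqs named list of two numeric frequency vectors
#'   (named by haplotype, each summing to 1).
#' @param n_per_site individuals per site.
#' @param centers two-row matrix of cluster centers (lon, lat).
#' @param spread standard deviation of coordinate scatter (degrees).
#' @param seed integer seed.
#' @return an `hg_dataset` with ground-truth `group` labels.
#' @export
generate_sites <- function(n_sites = 20,
                           region_freqs = list(
                             west = c(H1 = 0.95, H2 = 0.04, H4 = 0.01),
                             east = c(H3 = 0.93, H5 = 0.07)),
                           n_per_site = 10,
                           centers = rbind(c(105, 30), c(120, 35)),
                           spread = 1.5, seed = 1) {
  stopifnot(length(region_freqs) == 2)
  for (f in region_freqs)
    if (abs(sum(f) - 1) > 1e-8) hg_stop("region frequencies must sum to 1")
  set.seed(seed)
  haps <- sort(unique(unlist(lapply(region_freqs, names))))
  regions <- names(region_freqs)
  n1 <- ceiling(n_sites / 2)
  reg_of <- c(rep(regions[1], n1), rep(regions[2], n_sites - n1))
  m <- matrix(0, n_sites, length(haps),
              dimnames = list(NULL, haps))
  lon <- lat <- numeric(n_sites)
  for (i in seq_len(n_sites)) {
    f <- region_freqs[[reg_of[i]]]
    draw <- stats::rmultinom(1, n_per_site, f[names(f)])
    m[i, names(f)] <- draw
    ctr <- centers[match(reg_of[i], regions), ]
    lon[i] <- ctr[1] + stats::rnorm(1, 0, spread)
    lat[i] <- ctr[2] + stats::rnorm(1, 0, spread)
  }
  codes <- sprintf("S%02d", seq_len(n_sites))
  sites <- data.frame(code = codes,
                      locality = paste0("Synthetic, ", reg_of, ", Simland"),
                      lon = lon, lat = lat, elev_m = 0,
                      country = "Simland", group = reg_of,
                      row.names = codes)
  new_dataset(sites, m, m * 0, "synthetic")
}

#' Generate smooth environmental raster layers
#'
#' Planar gradients (rotating direction per layer) plus seeded Gaussian
#' noise; reproducible for a given seed.
#'
#' @param extent `c(xmin, xmax, ymin, ymax)` in degrees.
#' @param cellsize cell size (degrees).
#' @param n_layers number of layers.
#' @param noise_sd noise standard deviation (gradient spans ~1 unit).
#' @param seed integer seed.
#' @return list of `hg_raster` layers.
#' @export
generate_landscape <- function(extent = c(100, 110, 25, 35), cellsize = 0.25,
                               n_layers = 2, noise_sd = 0.05, seed = 1) {
  set.seed(seed)
  nc <- round((extent[2] - extent[1]) / cellsize)
  nr <- round((extent[4] - extent[3]) / cellsize)
  stopifnot(nc > 0, nr > 0)
  x <- (seq_len(nc) - 0.5) / nc
  y <- (nr - seq_len(nr) + 0.5) / nr
  lapply(seq_len(n_layers), function(l) {
    theta <- pi * (l - 1) / n_layers
    base <- outer(y * sin(theta), x * cos(theta), `+`)
    if (abs(cos(theta)) < 1e-9) base <- matrix(y, nr, nc)
    if (abs(sin(theta)) < 1e-9) base <- matrix(x, nr, nc, byrow = TRUE)
    vals <- base + matrix(stats::rnorm(nr * nc, 0, noise_sd), nr, nc)
    new_raster(vals, extent[1], extent[3], cellsize)
  })
}

#' Sample occurrence points proportional to suitability
#'
#' Cells are drawn with probability proportional to suitability and
#' points placed uniformly within each drawn cell. In `"divergent-pair"`
#' mode the suitability is multiplied by two horizontally displaced
#' Gaussian windows, planting a westerly and an easterly niche.
#'
#' @param suit suitability raster.
#' @param n points per set.
#' @param mode `"single"` or `"divergent-pair"`.
#' @param seed integer seed.
#' @return an `hg_occurrences`, or a list `a`/`b` of them in
#'   divergent-pair mode.
#' @export
sample_occurrences <- function(suit, n = 50, mode = c("single", "divergent-pair"),
                               seed = 1) {
  mode <- match.arg(mode)
  set.seed(seed)
  ax <- raster_axes(suit)
  draw <- function(weights) {
    w <- weights
    w[is.na(w) | w < 0] <- 0
    if (sum(w) <= 0) hg_stop("all-zero suitability: cannot sample occurrences")
    cells <- sample.int(length(w), n, replace = TRUE, prob = as.vector(w))
    rc <- arrayInd(cells, dim(w))
    occurrences(ax$x[rc[, 2]] + stats::runif(n, -0.5, 0.5) * suit$cellsize,
                ax$y[rc[, 1]] + stats::runif(n, -0.5, 0.5) * suit$cellsize)
  }
  if (mode == "single") return(draw(suit$values))
  xs <- matrix((seq_len(suit$ncols) - 0.5) / suit$ncols, suit$nrows,
               suit$ncols, byrow = TRUE)
  wa <- suit$values * exp(-((xs - 0.25) / 0.15)^2)
  wb <- suit$values * exp(-((xs - 0.75) / 0.15)^2)
  list(a = draw(wa), b = draw(wb))
}
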