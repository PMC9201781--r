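# PCoA, Mantel isolation-by-distance test, strict-clock divergence.

#' Principal coordinate analysis of a distance matrix
#'
#' Gower double-centering of -0.5 D^2 and eigendecomposition (via
#' [stats::cmdscale()]); percent variance is computed from the positive
#' eigenvalues only.
#'
#' @param d symmetric distance matrix with zero diagonal.
#' @param k number of axes to return.
#' @return list with `coordinates` (sites x axes), `eig` and
#'   `percent` (per returned axis).
#' @export
pcoa <- function(d, k = 2) {
  d <- as.matrix(d)
  if (!isSymmetric(unname(d), tol = 1e-8)) hg_stop("distance matrix not symmetric")
  if (all(d == 0)) hg_stop("all-zero distance matrix: variance undefined")
  k <- min(k, nrow(d) - 1)
  fit <- stats::cmdscale(d, k = k, eig = TRUE)
  pos <- fit$eig[fit$eig > max(fit$eig) * 1e-10]
  pct <- 100 * fit$eig[seq_len(k)] / sum(pos)
  list(coordinates = fit$points, eig = fit$eig, percent = pct)
}

#' Mantel test of isolation by distance
#'
#' Pearson correlation between the lower triangles of a genetic distance
#' matrix and (by default) log-transformed geographic distances, with
#' significance from permutations of the site labels of one matrix.
#' One-tailed for positive association (the isolation-by-distance
#' alternative), `(1 + hits)/(1 + n_perm)` convention.
#'
#' @param d_gen genetic distance matrix (e.g. pairwise PhiST).
#' @param d_geo_km geographic distances in km (same site order).
#' @param n_perm number of permutations.
#' @param seed integer seed.
#' @param transform `"log"` (natural log of km; distances must be
#'   positive) or `"none"`.
#' @return list with `r`, `p`, `n_perm`, `seed`.
#' @export
mantel_test <- function(d_gen, d_geo_km, n_perm = 9999, seed = 1,
                        transform = c("log", "none")) {
  transform <- match.arg(transform)
  d_gen <- as.matrix(d_gen); d_geo <- as.matrix(d_geo_km)
  if (!all(dim(d_gen) == dim(d_geo))) hg_stop("matrix dimensions differ")
  lt <- lower.tri(d_geo)
  if (transform == "log") {
    if (any(d_geo[lt] <= 0))
      hg_stop("nonpositive geographic distance: log transform undefined (duplicate sites?)")
    d_geo <- log(d_geo)
    diag(d_geo) <- 0
  }
  a <- d_gen[lt]
  if (stats::sd(a) == 0 || stats::sd(d_geo[lt]) == 0)
    hg_stop("constant distance matrix: correlation undefined")
  r_obs <- stats::cor(a, d_geo[lt])
  set.seed(seed)
  n <- nrow(d_gen)
  hits <- 0L
  for (b in seq_len(n_perm)) {
    p <- sample.int(n)
    r_p <- stats::cor(a, d_geo[p, p][lt])
    if (r_p >= r_obs - 1e-12) hits <- hits + 1L
  }
  list(r = r_obs, p = (1 + hits) / (1 + n_perm), n_perm = n_perm, seed = seed)
}

#' Strict-clock net divergence between two clades
#'
#' Net between-clade distance per site
#' `d_net = d_xy - (pi_x + pi_y)/2`, with frequency-weighted mean
#' distances computed from pooled haplotype counts, converted to a
#' divergence time `T = d_net / (2 mu)` under a strict molecular clock.
#' Intended as a first-order alternative to full Bayesian dating.
#'
#' @param ds dataset or count matrix.
#' @param grouping named vector (site code -> clade), exactly two clades.
#' @param dm labelled step-distance matrix.
#' @param L alignment length (bp).
#' @param mu substitution rate per site per year (default 2.0e-9, the
#'   angiosperm cpDNA average).
#' @return list with `d_xy`, `pi_x`, `pi_y`, `d_net`, `mu`, `T_years`.
#' @export
clock_divergence <- function(ds, grouping, dm, L, mu = 2.0e-9) {
  m <- if (inherits(ds, "hg_dataset")) site_counts(ds) else as.matrix(ds)
  m <- m[rowSums(m) > 0, , drop = FALSE]
  grp <- grouping[rownames(m)]
  lev <- unique(grp[!is.na(grp)])
  if (length(lev) != 2) hg_stop("grouping must define exactly two clades")
  d <- dm[colnames(m), colnames(m)]
  cx <- colSums(m[grp == lev[1], , drop = FALSE])
  cy <- colSums(m[grp == lev[2], , drop = FALSE])
  if (sum(cx) == 0 || sum(cy) == 0) hg_stop("empty clade")
  d_xy <- as.numeric(cx %*% d %*% cy) / (sum(cx) * sum(cy)) / L
  # frequency-based within-clade diversity (so identical clades give
  # exactly zero net divergence)
  within <- function(cc) {
    n <- sum(cc)
    as.numeric(cc %*% d %*% cc) / n^2 / L
  }
  pi_x <- within(cx); pi_y <- within(cy)
  d_net <- d_xy - (pi_x + pi_y) / 2
  T_years <- if (d_net < 0) {
    warning("negative net divergence; reporting T = 0")
    0
  } else d_net / (2 * mu)
  list(d_xy = d_xy, pi_x = pi_x, pi_y = pi_y, d_net = d_net, mu = mu,
       T_years = T_years)
}
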