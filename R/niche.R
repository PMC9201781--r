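# Niche overlap statistics and the randomization identity test.

joint_probs <- function(a, b) {
  if (!same_grid(a, b)) hg_stop("rasters are not on the same grid")
  ok <- !is.na(a$values) & !is.na(b$values)
  if (!any(ok)) hg_stop("no jointly valid cells")
  pa <- a$values[ok]; pb <- b$values[ok]
  if (sum(pa) <= 0 || sum(pb) <= 0) hg_stop("raster sums must be positive")
  list(pa = pa / sum(pa), pb = pb / sum(pb))
}

#' Schoener's D niche overlap
#'
#' `D = 1 - 0.5 * sum |p_a - p_b|` over cells jointly valid in both
#' rasters, each raster normalized to sum 1 over that joint support.
#' Ranges from 0 (fully discordant niches) to 1 (identical).
#'
#' @param a,b suitability rasters on the same grid.
#' @return D in `[0, 1]`.
#' @export
schoener_d <- function(a, b) {
  p <- joint_probs(a, b)
  1 - 0.5 * sum(abs(p$pa - p$pb))
}

#' Warren's I niche overlap
#'
#' `I = 1 - 0.5 * sum (sqrt(p_a) - sqrt(p_b))^2` (one minus the squared
#' Hellinger distance), same support and normalization as [schoener_d()].
#'
#' @inheritParams schoener_d
#' @return I in `[0, 1]`.
#' @export
warren_i <- function(a, b) {
  p <- joint_probs(a, b)
  1 - 0.5 * sum((sqrt(p$pa) - sqrt(p$pb))^2)
}

#' Drop highly correlated environmental layers
#'
#' Greedy retention in input order: a layer is dropped when its absolute
#' Pearson correlation with any already-retained layer reaches `r_max`
#' (computed over the cells valid in all layers).
#'
#' @param env list of rasters on a common grid.
#' @param r_max correlation threshold.
#' @return indices of retained layers.
#' @export
prune_correlated <- function(env, r_max = 0.8) {
  stopifnot(length(env) >= 1)
  ok <- Reduce(`&`, lapply(env, function(r) !is.na(r$values)))
  vals <- lapply(env, function(r) r$values[ok])
  retained <- 1L
  for (i in seq_along(env)[-1]) {
    r_with <- vapply(retained, function(j) abs(stats::cor(vals[[i]], vals[[j]])),
                     numeric(1))
    if (all(r_with < r_max, na.rm = TRUE)) retained <- c(retained, i)
  }
  retained
}

#' Maximum test sensitivity plus specificity threshold
#'
#' The presence-suitability value that maximizes sensitivity +
#' specificity, evaluated at the observed presence values as candidate
#' thresholds (cells at or above the threshold count as predicted
#' presence); ties resolve to the lowest threshold.
#'
#' @param suit suitability raster.
#' @param presences,background `hg_occurrences` or two-column (lon, lat)
#'   matrices.
#' @return list with `threshold`, `sensitivity`, `specificity`.
#' @export
max_sss_threshold <- function(suit, presences, background) {
  pv <- raster_extract(suit, occ_lon(presences), occ_lat(presences))
  bv <- raster_extract(suit, occ_lon(background), occ_lat(background))
  pv <- pv[!is.na(pv)]; bv <- bv[!is.na(bv)]
  if (!length(pv) || !length(bv))
    hg_stop("need at least one presence and one background point on valid cells")
  cand <- sort(unique(pv))
  score <- vapply(cand, function(t) mean(pv >= t) + mean(bv < t), numeric(1))
  best <- cand[which(score >= max(score) - 1e-12)][1]
  list(threshold = best, sensitivity = mean(pv >= best),
       specificity = mean(bv < best))
}

#' Occurrence point set
#'
#' @param lon,lat point coordinates.
#' @param label optional set label.
#' @return an `hg_occurrences` data.frame with attributes.
#' @export
occurrences <- function(lon, lat, label = "") {
  structure(data.frame(lon = lon, lat = lat),
            label = label, class = c("hg_occurrences", "data.frame"))
}

occ_lon <- function(o) if (is.matrix(o)) o[, 1] else o$lon
occ_lat <- function(o) if (is.matrix(o)) o[, 2] else o$lat

#' Read occurrences from CSV
#' @param path CSV with columns `lon`, `lat` (and optionally `label`).
#' @return an `hg_occurrences` (or a named list of them when a `label`
#'   column with several values is present).
#' @export
read_occurrences <- function(path) {
  tab <- utils::read.csv(path)
  if (!all(c("lon", "lat") %in% names(tab)))
    hg_stop("occurrence CSV needs lon and lat columns")
  if ("label" %in% names(tab) && length(unique(tab$label)) > 1) {
    sp <- split(tab, tab$label)
    return(lapply(sp, function(x) occurrences(x$lon, x$lat, x$label[1])))
  }
  occurrences(tab$lon, tab$lat, if ("label" %in% names(tab)) tab$label[1] else "")
}

#' Gaussian envelope suitability model
#'
#' A simple pluggable stand-in for a full species distribution model:
#' per-layer means and standard deviations at the occurrence cells define
#' a Gaussian envelope, and suitability is
#' `exp(-0.5 * mean(z^2))` rescaled to `[0, 1]`. Layers with zero
#' variance contribute z = 0 (with a message).
#'
#' @param occ occurrence points (>= 3).
#' @param env list of environmental rasters on a common grid.
#' @return a suitability `hg_raster` in `[0, 1]`.
#' @export
envelope_suitability <- function(occ, env) {
  if (nrow(as.data.frame(occ)) < 3) hg_stop("need at least 3 occurrences")
  z2 <- 0
  ok <- Reduce(`&`, lapply(env, function(r) !is.na(r$values)))
  for (r in env) {
    v <- raster_extract(r, occ_lon(occ), occ_lat(occ))
    v <- v[!is.na(v)]
    mu <- mean(v); sd <- stats::sd(v)
    if (!is.finite(sd) || sd == 0) {
      message("zero-variance layer in envelope model; z term set to 0")
      next
    }
    z2 <- z2 + ((r$values - mu) / sd)^2
  }
  s <- exp(-0.5 * z2 / length(env))
  s[!ok] <- NA
  mx <- max(s, na.rm = TRUE)
  if (mx > 0) s <- s / mx
  new_raster(s, env[[1]]$xllcorner, env[[1]]$yllcorner, env[[1]]$cellsize,
             env[[1]]$nodata)
}

#' Niche identity (equivalency) test
#'
#' Fits the suitability model to each occurrence set and measures
#' Schoener's D and Warren's I between the two predictions; the null
#' distribution re-partitions the pooled occurrence points (without
#' replacement) into two pseudoreplicate sets of the original sizes and
#' refits. One-tailed for niche divergence: the p-value is the
#' `(1 + #\{null <= observed\})/(1 + n_reps)` fraction of pseudoreplicate
#' overlaps at or below the observed overlap.
#'
#' @param occ_a,occ_b occurrence sets.
#' @param env list of environmental rasters.
#' @param model function `(occ, env) -> hg_raster` (default the built-in
#'   Gaussian envelope).
#' @param n_reps number of pseudoreplicates.
#' @param seed integer seed.
#' @return an `hg_nicheoverlap` list: `D`, `I`, `null_D`, `null_I`,
#'   `p_D`, `p_I`, `n_reps`, `seed`.
#' @export
identity_test <- function(occ_a, occ_b, env, model = envelope_suitability,
                          n_reps = 100, seed = 1) {
  if (n_reps < 1) hg_stop("n_reps must be >= 1")
  na <- nrow(as.data.frame(occ_a)); nb <- nrow(as.data.frame(occ_b))
  if (na < 3 || nb < 3) hg_stop("each occurrence set needs >= 3 points")
  sa <- model(occ_a, env); sb <- model(occ_b, env)
  D_obs <- schoener_d(sa, sb); I_obs <- warren_i(sa, sb)
  pool <- rbind(data.frame(lon = occ_lon(occ_a), lat = occ_lat(occ_a)),
                data.frame(lon = occ_lon(occ_b), lat = occ_lat(occ_b)))
  set.seed(seed)
  null_D <- null_I <- numeric(n_reps)
  for (b in seq_len(n_reps)) {
    idx <- sample.int(na + nb)
    pa <- pool[idx[seq_len(na)], ]
    pb <- pool[idx[na + seq_len(nb)], ]
    ra <- model(occurrences(pa$lon, pa$lat), env)
    rb <- model(occurrences(pb$lon, pb$lat), env)
    null_D[b] <- schoener_d(ra, rb)
    null_I[b] <- warren_i(ra, rb)
  }
  structure(list(D = D_obs, I = I_obs, null_D = null_D, null_I = null_I,
                 p_D = (1 + sum(null_D <= D_obs + 1e-12)) / (1 + n_reps),
                 p_I = (1 + sum(null_I <= I_obs + 1e-12)) / (1 + n_reps),
                 n_reps = n_reps, seed = seed),
            class = "hg_nicheoverlap")
}

#' @export
print.hg_nicheoverlap <- function(x, ...) {
  cat(sprintf("Schoener's D = %.3f (p = %.3f)  Warren's I = %.3f (p = %.3f)  [%d pseudoreplicates]\n",
              x$D, x$p_D, x$I, x$p_I, x$n_reps))
  invisible(x)
}
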