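# Per-site diversity and Pons & Petit (1996) differentiation statistics.

#' Nei's unbiased haplotype (gene) diversity
#'
#' `Hd = n (1 - sum p_i^2) / (n - 1)`.
#'
#' @param counts named or unnamed vector of haplotype counts at one site.
#' @return Hd in `[0, 1]`, or `NA` when fewer than two individuals.
#' @export
haplotype_diversity <- function(counts) {
  counts <- counts[counts > 0]
  n <- sum(counts)
  if (n < 2) return(NA_real_)
  p <- counts / n
  n * (1 - sum(p^2)) / (n - 1)
}

#' Per-site nucleotide diversity from haplotype counts
#'
#' Average number of differences per site over all pairs of individuals:
#' `pi = sum_{i<j} d(hap_i, hap_j) / (C(n,2) * L)`.
#'
#' @param counts named vector of haplotype counts.
#' @param dm labelled mutational-step distance matrix.
#' @param L alignment length in bp.
#' @return pi (per site), or `NA` when fewer than two individuals.
#' @export
nucleotide_diversity <- function(counts, dm, L) {
  counts <- counts[counts > 0]
  if (is.null(names(counts)) || !all(names(counts) %in% rownames(dm)))
    hg_stop("counts must be named with haplotypes present in the distance matrix")
  n <- sum(counts)
  if (n < 2) return(NA_real_)
  d <- dm[names(counts), names(counts), drop = FALSE]
  pairsum <- as.numeric(counts %*% d %*% counts) / 2
  pairsum / (choose(n, 2) * L)
}

#' Per-site diversity table
#'
#' @param ds an `hg_dataset`.
#' @param dm step-distance matrix (default: packaged network distances).
#' @param L alignment length in bp.
#' @param which which counts to use, see [site_counts()].
#' @return data.frame with `code`, `n`, `k`, `haplotypes`, `Hd`, `pi`.
#' @export
site_diversity <- function(ds, dm = fixture_distances(ds),
                           L = fixture_alignment_length(ds), which = "all") {
  m <- site_counts(ds, which)
  out <- data.frame(code = ds$sites$code, n = rowSums(m),
                    k = rowSums(m > 0))
  out$haplotypes <- apply(m, 1, function(x) {
    x <- x[x > 0]
    paste0(names(x), "(", x, ")", collapse = ", ")
  })
  out$Hd <- apply(m, 1, haplotype_diversity)
  out$pi <- apply(m, 1, function(x) {
    x <- x[x > 0]
    if (sum(x) < 2) NA_real_ else nucleotide_diversity(x, dm, L)
  })
  rownames(out) <- NULL
  out
}

# core Pons & Petit estimators from a sites x haplotypes count matrix.
# hT uses the among-site variance form: hT = 1 - sum(xbar^2) + mean of the
# per-haplotype between-site frequency variances; the within-site sampling
# corrections cancel exactly against the variance decomposition, so no
# harmonic-mean term appears. The ordered analogue replaces products by
# distance-weighted products.
pp_core <- function(m, dm = NULL) {
  K <- nrow(m)
  n <- rowSums(m)
  x <- m / n
  hk <- n / (n - 1) * (1 - rowSums(x^2))
  hS <- mean(hk)
  xbar <- colMeans(x)
  S <- stats::cov(x)
  hT <- 1 - sum(xbar^2) + sum(diag(S)) / K
  out <- list(K = K, n = sum(n), hS = hS, hT = hT,
              GST = if (is.finite(hT) && hT > 0) 1 - hS / hT else NA_real_)
  if (!is.null(dm)) {
    d <- dm[colnames(m), colnames(m)]
    vk <- n / (n - 1) * vapply(seq_len(K),
                               function(i) as.numeric(x[i, ] %*% d %*% x[i, ]),
                               numeric(1))
    vS <- mean(vk)
    vT <- as.numeric(xbar %*% d %*% xbar) - sum(d * S) / K
    out$vS <- vS
    out$vT <- vT
    out$NST <- if (is.finite(vT) && vT > 0) 1 - vS / vT else NA_real_
  }
  out
}

#' Pons & Petit differentiation statistics
#'
#' Unbiased estimators of average within-site gene diversity (hS), total
#' gene diversity (hT) and their ordered analogues (vS, vT) in which
#' haplotype pairs are weighted by genetic distance, with the
#' differentiation coefficients `GST = 1 - hS/hT` (unordered) and
#' `NST = 1 - vS/vT` (ordered). Sites contribute unweighted by sample
#' size (each of the K sites counts once). NST exceeding GST indicates
#' phylogeographic structure: closely related haplotypes co-occur within
#' sites more than unrelated ones. Standard errors are delete-one-site
#' jackknife estimates.
#'
#' @param ds an `hg_dataset`, or a plain sites x haplotypes count matrix.
#' @param dm labelled step-distance matrix, or `NULL` for unordered
#'   statistics only.
#' @return an `hg_differentiation` list: `K`, `n`, `hS`, `hT`, `GST`,
#'   `vS`, `vT`, `NST` and jackknife `se_*` fields.
#' @export
pons_petit <- function(ds, dm = NULL) {
  m <- if (inherits(ds, "hg_dataset")) site_counts(ds) else as.matrix(ds)
  m <- m[rowSums(m) > 0, colSums(m) > 0, drop = FALSE]
  if (nrow(m) < 2) hg_stop("need at least two sites")
  if (any(rowSums(m) < 2))
    hg_stop("every site needs at least two individuals; filter upstream (min n = 3 in the published protocol)")
  est <- pp_core(m, dm)
  if (est$hT <= 0)
    hg_stop("total gene diversity is zero: all sites fixed for one haplotype, differentiation undefined")
  K <- nrow(m)
  se <- rep(NA_real_, 6)
  if (K >= 3) {
    jack <- vapply(seq_len(K), function(i) {
      e <- pp_core(m[-i, , drop = FALSE], dm)
      c(e$hS, e$hT, e$GST %||% NA_real_, e$vS %||% NA_real_,
        e$vT %||% NA_real_, e$NST %||% NA_real_)
    }, numeric(6))
    se <- sqrt((K - 1) / K * rowSums((jack - rowMeans(jack))^2))
  }
  est$se_hS <- se[1]; est$se_hT <- se[2]; est$se_GST <- se[3]
  if (!is.null(dm)) {
    est$se_vS <- se[4]; est$se_vT <- se[5]; est$se_NST <- se[6]
  }
  structure(est, class = "hg_differentiation")
}

#' @export
print.hg_differentiation <- function(x, ...) {
  cat(sprintf("K = %d sites, n = %d individuals\n", x$K, x$n))
  cat(sprintf("hS = %.3f (%.3f)   hT = %.3f (%.3f)   GST = %.3f (%.3f)\n",
              x$hS, x$se_hS, x$hT, x$se_hT, x$GST, x$se_GST))
  if (!is.null(x$NST))
    cat(sprintf("vS = %.3f          vT = %.3f          NST = %.3f (%.3f)\n",
                x$vS, x$vT, x$NST, x$se_NST))
  invisible(x)
}

#' Permutation test of NST against GST
#'
#' Tests whether the distance-weighted differentiation NST significantly
#' exceeds the unordered GST (the signature of phylogeographic
#' structure), by breaking the association between haplotype relatedness
#' and haplotype distribution and recomputing NST; GST is invariant. Two
#' null schemes are available: `"distances"` (default) shuffles the
#' off-diagonal distance values among haplotype pairs; `"labels"`
#' relabels which haplotype carries which distance row/column. For three
#' haplotypes the two schemes generate the same null set. The one-tailed
#' p-value for NST > GST uses the `(1 + hits) / (1 + n_perm)`
#' convention. With `exact = TRUE` the full null set is enumerated and
#' the exact fraction returned.
#'
#' @param ds dataset or count matrix (as in [pons_petit()]).
#' @param dm labelled step-distance matrix.
#' @param n_perm number of random permutations.
#' @param seed integer seed.
#' @param scheme `"distances"` or `"labels"`.
#' @param exact enumerate the full null set (small k only).
#' @return list with `p_perm`, `nst_obs`, `gst_obs`, `null` (permuted NST
#'   values), `n_perm`, `seed`.
#' @export
nst_gst_permutation_test <- function(ds, dm, n_perm = 10000, seed = 1,
                                     scheme = c("distances", "labels"),
                                     exact = FALSE) {
  scheme <- match.arg(scheme)
  m <- if (inherits(ds, "hg_dataset")) site_counts(ds) else as.matrix(ds)
  m <- m[rowSums(m) > 0, colSums(m) > 0, drop = FALSE]
  k <- ncol(m)
  if (k < 3) {
    warning("fewer than three distinct haplotypes: permutation test degenerate")
    return(list(p_perm = NA_real_, nst_obs = NA_real_, gst_obs = NA_real_,
                null = numeric(0), n_perm = 0L, seed = seed))
  }
  est <- pp_core(m, dm)
  d <- dm[colnames(m), colnames(m)]
  K <- nrow(m)
  n <- rowSums(m)
  x <- m / n
  xbar <- colMeans(x)
  S <- stats::cov(x)
  MT <- outer(xbar, xbar) - S / K
  w <- n / (n - 1) / K
  MS <- Reduce(`+`, lapply(seq_len(K), function(i) w[i] * outer(x[i, ], x[i, ])))
  nst_for_matrix <- function(dp) {
    vS <- sum(dp * MS)
    vT <- sum(dp * MT)
    if (vT <= 0) return(NA_real_)
    1 - vS / vT
  }
  up <- upper.tri(d)
  vals <- d[up]
  from_pairs <- function(v) {
    dp <- matrix(0, k, k)
    dp[up] <- v
    dp + t(dp)
  }
  nst_for <- function(perm) {
    if (scheme == "labels") nst_for_matrix(d[perm, perm])
    else nst_for_matrix(from_pairs(vals[perm]))
  }
  n_items <- if (scheme == "labels") k else length(vals)
  if (exact) {
    if (n_items > 8) hg_stop("exact enumeration limited to 8 items")
    perms <- perm_enumerate(n_items)
    null <- vapply(perms, nst_for, numeric(1))
    p <- mean(null >= est$NST - 1e-12, na.rm = TRUE)
    return(list(p_perm = p, nst_obs = est$NST, gst_obs = est$GST,
                null = null, n_perm = length(perms), seed = NA_integer_))
  }
  set.seed(seed)
  null <- vapply(seq_len(n_perm), function(i) nst_for(sample.int(n_items)),
                 numeric(1))
  hits <- sum(null >= est$NST - 1e-12, na.rm = TRUE)
  list(p_perm = (1 + hits) / (1 + n_perm), nst_obs = est$NST,
       gst_obs = est$GST, null = null, n_perm = n_perm, seed = seed)
}

perm_enumerate <- function(k) {
  if (k == 1) return(list(1L))
  sub <- perm_enumerate(k - 1L)
  out <- list()
  for (p in sub) for (pos in 0:(k - 1L)) {
    out[[length(out) + 1L]] <- append(p, k, after = pos)
  }
  out
}

#' Write a differentiation summary table
#'
#' @param results named list of `hg_differentiation` objects (one row each).
#' @param pvals optional named numeric vector of permutation p-values.
#' @param path output TSV path.
#' @return `path`, invisibly.
#' @export
write_differentiation <- function(results, path, pvals = NULL) {
  rows <- lapply(names(results), function(nm) {
    x <- results[[nm]]
    data.frame(dataset = nm, K = x$K, n = x$n,
               hT = x$hT, se_hT = x$se_hT, hS = x$hS, se_hS = x$se_hS,
               GST = x$GST, se_GST = x$se_GST,
               NST = x$NST %||% NA_real_, se_NST = x$se_NST %||% NA_real_,
               p_perm = if (!is.null(pvals)) pvals[nm] else NA_real_)
  })
  utils::write.table(do.call(rbind, rows), path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}
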