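# Distance-based hierarchical AMOVA and pairwise PhiST.

# sum of squared inter-individual distances within a pool, divided by pool
# size, from a haplotype count vector: (c' D c / 2) / n
pool_ss <- function(counts, d) {
  as.numeric(counts %*% d %*% counts) / 2 / sum(counts)
}

# variance components of a 3-level design from site counts + grouping
amova_components <- function(m, grp, d) {
  S <- nrow(m)
  n_s <- rowSums(m)
  N <- sum(n_s)
  groups <- sort(unique(grp))
  G <- length(groups)
  cg <- rowsum(m, grp)
  n_g <- rowSums(cg)
  ss_total <- pool_ss(colSums(m), d)
  ss_within <- sum(vapply(seq_len(S), function(i) pool_ss(m[i, ], d), numeric(1)))
  ss_group_pools <- sum(vapply(seq_len(G),
                               function(g) pool_ss(cg[g, ], d), numeric(1)))
  ss_ag <- ss_total - ss_group_pools
  ss_aw <- ss_group_pools - ss_within
  df <- c(G - 1, S - G, N - S)
  ms_w <- ss_within / df[3]
  # unequal-n coefficients (Excoffier et al. 1992)
  sum_ns2_ng <- sum(n_s^2 / n_g[match(grp, groups)])
  n_c <- (N - sum_ns2_ng) / (S - G)
  n_b <- (sum_ns2_ng - sum(n_s^2) / N) / (G - 1)
  n_a <- (N - sum(n_g^2) / N) / (G - 1)
  s2_c <- ms_w
  s2_b <- (ss_aw / df[2] - s2_c) / n_c
  s2_a <- (ss_ag / df[1] - s2_c - n_b * s2_b) / n_a
  tot <- s2_a + s2_b + s2_c
  list(df = df, SS = c(ss_ag, ss_aw, ss_within),
       sigma2 = c(a = s2_a, b = s2_b, c = s2_c),
       pct = 100 * c(s2_a, s2_b, s2_c) / tot,
       FCT = s2_a / tot,
       FSC = s2_b / (s2_b + s2_c),
       FST = (s2_a + s2_b) / tot)
}

amova_components_2level <- function(m, d) {
  S <- nrow(m)
  n_s <- rowSums(m)
  N <- sum(n_s)
  ss_total <- pool_ss(colSums(m), d)
  ss_within <- sum(vapply(seq_len(S), function(i) pool_ss(m[i, ], d), numeric(1)))
  ss_among <- ss_total - ss_within
  df <- c(S - 1, N - S)
  s2_c <- if (df[2] > 0) ss_within / df[2] else 0
  n_c <- (N - sum(n_s^2) / N) / (S - 1)
  s2_a <- (ss_among / df[1] - s2_c) / n_c
  tot <- s2_a + s2_c
  list(df = df, SS = c(ss_among, ss_within),
       sigma2 = c(a = s2_a, c = s2_c),
       pct = if (tot > 0) 100 * c(s2_a, s2_c) / tot else c(NA_real_, NA_real_),
       FST = if (tot > 0) s2_a / tot else NA_real_)
}

#' Hierarchical analysis of molecular variance (AMOVA)
#'
#' Excoffier-style AMOVA in which the squared distance between two
#' individuals is the mutational-step count between their haplotypes
#' (the pairwise-difference convention). Sums of squares follow the
#' sum(d^2)/n decomposition; variance components use the standard
#' unequal-sample-size coefficients. Significance by permutation:
#' `FST` permutes individuals among sites, `FSC` individuals among sites
#' within groups, `FCT` whole sites among groups; p-values use the
#' `(1 + hits)/(1 + n_perm)` convention.
#'
#' @param ds an `hg_dataset` or sites x haplotypes count matrix.
#' @param grouping named character vector (site code -> group); defaults
#'   to the dataset's `group` column. A single group yields a two-level
#'   AMOVA with the among-group fields absent.
#' @param dm labelled step-distance matrix.
#' @param n_perm permutations for p-values (0 to skip).
#' @param seed integer seed.
#' @return an `hg_amova`: `df`, `SS`, `sigma2`, `pct`, `FCT`, `FSC`,
#'   `FST`, `p` (named), `n_perm`, `seed`.
#' @export
amova <- function(ds, grouping = NULL, dm, n_perm = 10000, seed = 1) {
  m <- if (inherits(ds, "hg_dataset")) site_counts(ds) else as.matrix(ds)
  m <- m[rowSums(m) > 0, , drop = FALSE]
  if (is.null(grouping) && inherits(ds, "hg_dataset"))
    grouping <- stats::setNames(ds$sites$group, ds$sites$code)
  if (is.null(grouping)) grouping <- stats::setNames(rep("all", nrow(m)), rownames(m))
  grp <- grouping[rownames(m)]
  if (anyNA(grp)) hg_stop("every site needs a group assignment")
  d <- dm[colnames(m), colnames(m)]
  if (length(unique(grp)) < 2) {
    comp <- amova_components_2level(m, d)
    res <- structure(c(comp, list(FCT = NA_real_, FSC = NA_real_,
                                  p = c(FST = NA_real_),
                                  n_perm = 0L, seed = seed, levels = 2L)),
                     class = "hg_amova")
    return(res)
  }
  comp <- amova_components(m, grp, d)
  p <- c(FCT = NA_real_, FSC = NA_real_, FST = NA_real_)
  if (n_perm > 0) {
    set.seed(seed)
    S <- nrow(m); k <- ncol(m)
    site_of <- rep(seq_len(S), times = rowSums(m))
    hap_of <- unlist(lapply(seq_len(S), function(i) rep(seq_len(k), m[i, ])))
    rebuild <- function(site, hap) {
      matrix(tabulate(site + S * (hap - 1L), nbins = S * k), S, k,
             dimnames = dimnames(m))
    }
    grp_levels <- grp
    hits <- c(FCT = 0, FSC = 0, FST = 0)
    for (b in seq_len(n_perm)) {
      # FST: individuals among all sites
      st <- amova_components(rebuild(site_of, sample(hap_of)), grp, d)$FST
      if (!is.na(st) && st >= comp$FST - 1e-12) hits["FST"] <- hits["FST"] + 1
      # FSC: individuals among sites within groups
      hap2 <- hap_of
      for (g in unique(grp_levels)) {
        idx <- which(grp_levels[site_of] == g)
        hap2[idx] <- hap2[idx][sample.int(length(idx))]
      }
      sc <- amova_components(rebuild(site_of, hap2), grp, d)$FSC
      if (!is.na(sc) && sc >= comp$FSC - 1e-12) hits["FSC"] <- hits["FSC"] + 1
      # FCT: whole sites among groups
      ct <- amova_components(m, sample(grp_levels), d)$FCT
      if (!is.na(ct) && ct >= comp$FCT - 1e-12) hits["FCT"] <- hits["FCT"] + 1
    }
    p <- (1 + hits) / (1 + n_perm)
  }
  structure(c(comp, list(p = p, n_perm = n_perm, seed = seed, levels = 3L)),
            class = "hg_amova")
}

#' @export
print.hg_amova <- function(x, ...) {
  if (x$levels == 3L) {
    tab <- data.frame(
      source = c("Among groups", "Among sites within groups", "Within sites"),
      df = x$df, SS = round(x$SS, 2), VC = round(x$sigma2, 4),
      pct = round(x$pct, 2))
    print(tab, row.names = FALSE)
    cat(sprintf("F_CT = %.3f  F_SC = %.3f  F_ST = %.3f\n", x$FCT, x$FSC, x$FST))
  } else {
    tab <- data.frame(source = c("Among sites", "Within sites"),
                      df = x$df, SS = round(x$SS, 2), VC = round(x$sigma2, 4),
                      pct = round(x$pct, 2))
    print(tab, row.names = FALSE)
    cat(sprintf("F_ST = %.3f\n", x$FST))
  }
  if (!all(is.na(x$p)))
    cat("permutation p:", paste(names(x$p), signif(x$p, 3), collapse = "  "), "\n")
  invisible(x)
}

#' Write an AMOVA table as TSV
#'
#' @param x an `hg_amova`.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_amova <- function(x, path) {
  src <- if (x$levels == 3L)
    c("Among groups", "Among sites within groups", "Within sites")
  else c("Among sites", "Within sites")
  fix <- if (x$levels == 3L) c(x$FCT, x$FSC, x$FST) else c(x$FST, NA)
  utils::write.table(data.frame(source = src, df = x$df, SS = x$SS,
                                VC = x$sigma2, percent = x$pct,
                                fixation = fix),
                     path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

phist_pair <- function(c1, c2, d) {
  n1 <- sum(c1); n2 <- sum(c2); n <- n1 + n2
  ss_t <- pool_ss(c1 + c2, d)
  ss_w <- pool_ss(c1, d) + pool_ss(c2, d)
  ss_a <- ss_t - ss_w
  ms_w <- if (n > 2) ss_w / (n - 2) else 0
  n_c <- n - (n1^2 + n2^2) / n
  s2_a <- (ss_a - ms_w) / n_c
  tot <- s2_a + ms_w
  if (tot <= 0) return(0)
  s2_a / tot
}

#' Pairwise PhiST matrix between sampling sites
#'
#' Two-site AMOVA fixation index for every site pair. `convention`
#' selects the inter-haplotype squared distance: `"binary"` (0/1,
#' frequency-based, GenAlEx-like; the default used for PCoA and Mantel
#' inputs) or `"steps"` (mutational step counts, as in the hierarchical
#' AMOVA). Negative estimates are clamped to zero; identical monomorphic
#' pairs give 0.
#'
#' @param ds dataset or count matrix.
#' @param dm labelled step-distance matrix.
#' @param convention `"binary"` or `"steps"`.
#' @param clamp clamp negative estimates to 0 (needed for PCoA input).
#' @return labelled site x site matrix.
#' @export
pairwise_phist <- function(ds, dm, convention = c("binary", "steps"),
                           clamp = TRUE) {
  convention <- match.arg(convention)
  m <- if (inherits(ds, "hg_dataset")) site_counts(ds) else as.matrix(ds)
  m <- m[rowSums(m) > 0, , drop = FALSE]
  if (nrow(m) < 2) hg_stop("need at least two sites")
  d <- dm[colnames(m), colnames(m)]
  if (convention == "binary") d <- (d > 0) + 0
  S <- nrow(m)
  out <- matrix(0, S, S, dimnames = list(rownames(m), rownames(m)))
  for (i in 1:(S - 1)) for (j in (i + 1):S) {
    v <- phist_pair(m[i, ], m[j, ], d)
    out[i, j] <- out[j, i] <- if (clamp) max(0, v) else v
  }
  out
}
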