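# Shared fixtures and independent brute-force oracles used across tests.

write_tmp_fasta <- function(records) {
  path <- tempfile(fileext = ".fasta")
  con <- file(path, "w")
  for (nm in names(records)) writeLines(c(paste0(">", nm), records[[nm]]), con)
  close(con)
  path
}

# expand a sites x haplotypes count matrix into individual-level vectors
expand_individuals <- function(m) {
  site <- rep(seq_len(nrow(m)), rowSums(m))
  hap <- unlist(lapply(seq_len(nrow(m)), function(i)
    rep(colnames(m), m[i, ])))
  list(site = site, hap = hap)
}

# brute-force AMOVA sums of squares from explicit individual pairs
brute_amova_ss <- function(m, grp, d) {
  ind <- expand_individuals(m)
  N <- length(ind$site)
  delta <- outer(ind$hap, ind$hap, function(a, b) d[cbind(a, b)])
  ss_pool <- function(keep) {
    idx <- which(keep)
    if (length(idx) < 2) return(0)
    s <- 0
    for (i in idx) for (j in idx) if (i < j) s <- s + delta[i, j]
    s / length(idx)
  }
  ss_total <- ss_pool(rep(TRUE, N))
  ss_within <- sum(vapply(seq_len(nrow(m)), function(s)
    ss_pool(ind$site == s), numeric(1)))
  grp_of_ind <- grp[ind$site]
  ss_groups <- sum(vapply(unique(grp), function(g)
    ss_pool(grp_of_ind == g), numeric(1)))
  c(among_groups = ss_total - ss_groups,
    among_sites = ss_groups - ss_within,
    within = ss_within)
}

# brute-force minimum path cost on a small friction grid: enumerate all
# simple paths over the 8-connected lattice
brute_min_cost <- function(f, from_rc, to_rc) {
  nr <- nrow(f); nc <- ncol(f)
  best <- Inf
  visit <- function(r, c, cost, seen) {
    if (cost >= best) return()
    if (r == to_rc[1] && c == to_rc[2]) {
      best <<- min(best, cost)
      return()
    }
    for (dr in -1:1) for (dc in -1:1) {
      if (dr == 0 && dc == 0) next
      r2 <- r + dr; c2 <- c + dc
      if (r2 < 1 || r2 > nr || c2 < 1 || c2 > nc) next
      if (seen[r2, c2] || is.na(f[r2, c2])) next
      len <- if (dr != 0 && dc != 0) sqrt(2) else 1
      seen[r2, c2] <- TRUE
      visit(r2, c2, cost + (f[r, c] + f[r2, c2]) / 2 * len, seen)
      seen[r2, c2] <- FALSE
    }
  }
  seen <- matrix(FALSE, nr, nc)
  seen[from_rc[1], from_rc[2]] <- TRUE
  visit(from_rc[1], from_rc[2], 0, seen)
  best
}

# a random tree-shaped network spec for round-trip properties
random_network_spec <- function(k, L = 200, seed = 1, indel = FALSE) {
  set.seed(seed)
  labels <- paste0("H", seq_len(k))
  branches <- data.frame(from = character(0), to = character(0),
                         steps = integer(0))
  for (i in 2:k) {
    branches <- rbind(branches,
                      data.frame(from = labels[sample.int(i - 1, 1)],
                                 to = labels[i],
                                 steps = sample(1:4, 1)))
  }
  new_network_spec(labels, branches, L,
                   indel = if (indel) list(branch = c(branches$from[1],
                                                      branches$to[1]),
                                           length = 12L) else NULL,
                   counts = stats::setNames(sample(1:3, k, replace = TRUE),
                                            labels))
}

toy_raster <- function(values, cellsize = 1, xll = 0, yll = 0) {
  new_raster(values, xll, yll, cellsize)
}
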