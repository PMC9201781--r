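# Spatial analysis of molecular variance by simulated annealing.

#' Delaunay neighbourhood of sampling sites
#'
#' Direct circumcircle test: an edge joins two sites if some triangle
#' through them has an empty circumcircle. Intended for the modest site
#' counts of phylogeographic surveys (<= a few hundred). If the result is
#' disconnected (possible after numerical degeneracies) it is augmented by
#' nearest-neighbour links.
#'
#' @param lon,lat site coordinates (decimal degrees, treated as planar).
#' @return two-column integer matrix of edges (site indices).
#' @export
delaunay_edges <- function(lon, lat) {
  n <- length(lon)
  if (n < 2) return(matrix(integer(0), 0, 2))
  if (n == 2) return(matrix(c(1L, 2L), 1, 2))
  x <- lon; y <- lat
  adj <- matrix(FALSE, n, n)
  for (i in 1:(n - 2)) for (j in (i + 1):(n - 1)) for (k in (j + 1):n) {
    ax <- x[i]; ay <- y[i]; bx <- x[j]; by <- y[j]; cx <- x[k]; cy <- y[k]
    ddet <- 2 * (ax * (by - cy) + bx * (cy - ay) + cx * (ay - by))
    if (abs(ddet) < 1e-12) next
    ux <- ((ax^2 + ay^2) * (by - cy) + (bx^2 + by^2) * (cy - ay) +
             (cx^2 + cy^2) * (ay - by)) / ddet
    uy <- ((ax^2 + ay^2) * (cx - bx) + (bx^2 + by^2) * (ax - cx) +
             (cx^2 + cy^2) * (bx - ax)) / ddet
    r2 <- (ax - ux)^2 + (ay - uy)^2
    inside <- (x - ux)^2 + (y - uy)^2 < r2 - 1e-9
    inside[c(i, j, k)] <- FALSE
    if (!any(inside)) {
      adj[i, j] <- adj[j, i] <- TRUE
      adj[i, k] <- adj[k, i] <- TRUE
      adj[j, k] <- adj[k, j] <- TRUE
    }
  }
  # connectivity augmentation
  comp <- components_from_adj(adj)
  while (length(unique(comp)) > 1) {
    best <- NULL
    for (a in which(comp == comp[1])) for (b in which(comp != comp[1])) {
      d2 <- (x[a] - x[b])^2 + (y[a] - y[b])^2
      if (is.null(best) || d2 < best$d2) best <- list(a = a, b = b, d2 = d2)
    }
    adj[best$a, best$b] <- adj[best$b, best$a] <- TRUE
    comp <- components_from_adj(adj)
  }
  which(adj & upper.tri(adj), arr.ind = TRUE)
}

components_from_adj <- function(adj) {
  n <- nrow(adj)
  comp <- rep(0L, n)
  cur <- 0L
  for (s in seq_len(n)) {
    if (comp[s] > 0) next
    cur <- cur + 1L
    stack <- s
    while (length(stack)) {
      v <- stack[length(stack)]
      stack <- stack[-length(stack)]
      if (comp[v] > 0) next
      comp[v] <- cur
      stack <- c(stack, which(adj[v, ] & comp == 0L))
    }
  }
  comp
}

# precomputed FCT evaluator for the annealing objective; algebraically the
# same quantity as amova_components()$FCT (asserted in tests)
make_fct_evaluator <- function(m, d) {
  S <- nrow(m)
  n_s <- rowSums(m)
  N <- sum(n_s)
  W_s <- vapply(seq_len(S), function(i)
    as.numeric(m[i, ] %*% d %*% m[i, ]) / 2, numeric(1))
  ss_within <- sum(W_s / n_s)
  ctot <- colSums(m)
  ss_total <- as.numeric(ctot %*% d %*% ctot) / 2 / N
  sum_ns2 <- sum(n_s^2)
  function(grp) {
    G <- length(unique(grp))
    if (G < 2) return(-Inf)
    cg <- rowsum(m, grp)
    n_g <- rowSums(cg)
    P_g <- rowSums((cg %*% d) * cg) / 2
    ss_group_pools <- sum(P_g / n_g)
    ss_ag <- ss_total - ss_group_pools
    ss_aw <- ss_group_pools - ss_within
    ms_w <- ss_within / (N - S)
    n_g_of_site <- n_g[match(grp, rownames(cg))]
    sum_ns2_ng <- sum(n_s^2 / n_g_of_site)
    n_c <- (N - sum_ns2_ng) / (S - G)
    n_b <- (sum_ns2_ng - sum_ns2 / N) / (G - 1)
    n_a <- (N - sum(n_g^2) / N) / (G - 1)
    s2_c <- ms_w
    s2_b <- (ss_aw / (S - G) - s2_c) / n_c
    s2_a <- (ss_ag / (G - 1) - s2_c - n_b * s2_b) / n_a
    s2_a / (s2_a + s2_b + s2_c)
  }
}

# random contiguous K-partition by seeded region growing
grow_partition <- function(nbrs, K) {
  n <- length(nbrs)
  grp <- rep(NA_integer_, n)
  seeds <- sample.int(n, K)
  grp[seeds] <- seq_len(K)
  frontier <- seeds
  while (anyNA(grp)) {
    cand <- which(!is.na(grp) &
                    vapply(seq_len(n), function(v)
                      !is.na(grp[v]) && any(is.na(grp[nbrs[[v]]])), logical(1)))
    if (!length(cand)) {
      grp[is.na(grp)] <- sample.int(K, sum(is.na(grp)), replace = TRUE)
      break
    }
    v <- cand[sample.int(length(cand), 1)]
    u <- nbrs[[v]][is.na(grp[nbrs[[v]]])]
    u <- u[sample.int(length(u), 1)]
    grp[u] <- grp[v]
  }
  grp
}

#' Spatially constrained AMOVA (SAMOVA)
#'
#' Searches for the K-group partition of sampling sites that maximizes
#' the among-group fixation index F_CT, under geographic contiguity
#' defined by the Delaunay triangulation of site coordinates. Each run
#' starts from a random contiguous partition (seeded region growing) and
#' anneals by moving boundary sites into adjacent groups, accepting
#' worsening moves with Metropolis probability under a geometric cooling
#' schedule; the best partition over all runs is returned.
#'
#' @param ds an `hg_dataset` or count matrix.
#' @param dm labelled step-distance matrix.
#' @param K number of groups (2 <= K <= number of sites).
#' @param coords optional two-column matrix (lon, lat); defaults to the
#'   dataset's site coordinates.
#' @param n_runs independent annealing runs.
#' @param seed integer seed.
#' @param moves_per_site annealing moves per site per run.
#' @param cooling geometric temperature decay per sweep.
#' @return an `hg_samova`: `K`, `assignment` (named by site, groups
#'   relabelled 1..K), `FCT`, `trace` (best F_CT per run), `n_runs`,
#'   `seed`.
#' @export
samova <- function(ds, dm, K, coords = NULL, n_runs = 100, seed = 1,
                   moves_per_site = 100, cooling = 0.9) {
  m <- if (inherits(ds, "hg_dataset")) site_counts(ds) else as.matrix(ds)
  m <- m[rowSums(m) > 0, , drop = FALSE]
  S <- nrow(m)
  if (K > S) hg_stop("K exceeds the number of sites")
  if (K < 2) hg_stop("K must be at least 2")
  if (is.null(coords) && inherits(ds, "hg_dataset"))
    coords <- as.matrix(ds$sites[match(rownames(m), ds$sites$code),
                                 c("lon", "lat")])
  d <- dm[colnames(m), colnames(m)]
  ed <- delaunay_edges(coords[, 1], coords[, 2])
  nbrs <- lapply(seq_len(S), function(v)
    sort(unique(c(ed[ed[, 1] == v, 2], ed[ed[, 2] == v, 1]))))
  set.seed(seed)
  fct_eval <- make_fct_evaluator(m, d)
  best <- NULL
  trace <- numeric(n_runs)
  for (run in seq_len(n_runs)) {
    grp <- grow_partition(nbrs, K)
    f <- fct_eval(grp)
    # temperature calibration on a prefix of random candidate moves
    deltas <- c()
    for (t in 1:50) {
      mv <- propose_move(grp, nbrs, K)
      if (is.null(mv)) next
      g2 <- grp; g2[mv$site] <- mv$to
      df <- fct_eval(g2) - f
      if (df < 0) deltas <- c(deltas, -df)
    }
    temp <- if (length(deltas)) stats::median(deltas) / log(2) else 0.01
    run_best <- list(grp = grp, f = f)
    for (sweep in seq_len(moves_per_site)) {
      for (step in seq_len(S)) {
        mv <- propose_move(grp, nbrs, K)
        if (is.null(mv)) next
        g2 <- grp; g2[mv$site] <- mv$to
        f2 <- fct_eval(g2)
        if (f2 >= f || stats::runif(1) < exp((f2 - f) / max(temp, 1e-12))) {
          grp <- g2; f <- f2
          if (f > run_best$f) run_best <- list(grp = grp, f = f)
        }
      }
      temp <- temp * cooling
    }
    trace[run] <- run_best$f
    if (is.null(best) || run_best$f > best$f) best <- run_best
  }
  # relabel groups 1..K in order of first site
  lev <- unique(best$grp)
  assignment <- stats::setNames(match(best$grp, lev), rownames(m))
  structure(list(K = K, assignment = assignment, FCT = best$f,
                 trace = trace, n_runs = n_runs, seed = seed,
                 edges = ed),
            class = "hg_samova")
}

propose_move <- function(grp, nbrs, K) {
  n <- length(grp)
  boundary <- which(vapply(seq_len(n),
                           function(v) any(grp[nbrs[[v]]] != grp[v]),
                           logical(1)))
  # moves that would empty a group are not allowed
  sizes <- tabulate(grp, nbins = max(grp))
  boundary <- boundary[sizes[grp[boundary]] > 1]
  if (!length(boundary)) return(NULL)
  v <- boundary[sample.int(length(boundary), 1)]
  targets <- unique(grp[nbrs[[v]]])
  targets <- targets[targets != grp[v]]
  list(site = v, to = targets[sample.int(length(targets), 1)])
}

#' @export
print.hg_samova <- function(x, ...) {
  cat(sprintf("SAMOVA: K = %d, best F_CT = %.4f over %d runs\n",
              x$K, x$FCT, x$n_runs))
  print(table(x$assignment))
  invisible(x)
}

#' Write a SAMOVA partition and run trace
#'
#' @param x an `hg_samova`.
#' @param path_tsv partition TSV (site, group).
#' @param path_json optional JSON with the per-run F_CT trace.
#' @return `path_tsv`, invisibly.
#' @export
write_samova <- function(x, path_tsv, path_json = NULL) {
  utils::write.table(data.frame(site = names(x$assignment),
                                group = unname(x$assignment)),
                     path_tsv, sep = "\t", quote = FALSE, row.names = FALSE)
  if (!is.null(path_json))
    jsonlite::write_json(list(K = x$K, FCT = x$FCT, trace = x$trace,
                              n_runs = x$n_runs, seed = x$seed),
                         path_json, auto_unbox = TRUE, digits = NA)
  invisible(path_tsv)
}
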