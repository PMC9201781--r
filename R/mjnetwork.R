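# Median-joining haplotype network (Bandelt, Forster & Roehl 1999 style).

# minimum spanning network over a distance matrix: links are added level by
# level; at each round all cross-component pairs within epsilon of the
# cheapest cross-component link are added simultaneously, so equal-cost
# alternatives are retained as reticulations.
msn_edges <- function(d, epsilon = 0) {
  n <- nrow(d)
  comp <- seq_len(n)
  edges <- matrix(integer(0), 0, 2)
  while (length(unique(comp)) > 1L) {
    cross <- which(outer(comp, comp, "!=") & upper.tri(d), arr.ind = TRUE)
    lambda <- min(d[cross])
    sel <- cross[d[cross] <= lambda + epsilon, , drop = FALSE]
    ord <- order(d[sel], rownames(d)[sel[, 1]], rownames(d)[sel[, 2]])
    sel <- sel[ord, , drop = FALSE]
    edges <- rbind(edges, sel)
    for (r in seq_len(nrow(sel))) {
      a <- comp[sel[r, 1]]; b <- comp[sel[r, 2]]
      comp[comp == b] <- a
    }
  }
  edges
}

mst_length <- function(d) {
  n <- nrow(d)
  if (n < 2) return(0)
  g <- igraph::graph_from_adjacency_matrix(d, mode = "undirected",
                                           weighted = TRUE, diag = FALSE)
  sum(igraph::E(igraph::mst(g))$weight)
}

# column-majority consensus of three sequences; three-way ties keep the
# first sequence's state (coded cpDNA columns are effectively binary)
triplet_median <- function(a, b, c) {
  out <- a
  bc <- b == c
  out[bc] <- b[bc]
  out
}

#' Median-joining network of haplotypes
#'
#' Builds a median-joining network: a minimum spanning network is
#' constructed over the haplotype step distances, consensus (median)
#' vectors of linked triplets are added greedily while they shorten the
#' spanning length, and median vectors that end up on a single path
#' (degree at most two) are pruned. Edge weights are mutational step
#' counts. With `epsilon = 0` (the default, as in PopART) only
#' minimum-cost links are retained; ties are kept as reticulations and
#' broken deterministically by (weight, endpoint label) order.
#'
#' @param hapset an `hg_haplotypes` object from [collapse_haplotypes()].
#' @param epsilon non-negative integer tolerance for feasible links.
#' @return an `hg_mjnetwork`: list with `nodes` (data.frame: `label`,
#'   `type` = observed/median, `freq` sample counts) and `edges`
#'   (data.frame: `from`, `to`, `steps`).
#' @export
median_joining_network <- function(hapset, epsilon = 0) {
  stopifnot(epsilon >= 0)
  seqs <- hapset$rep_cmp
  labels <- rownames(seqs)
  observed <- rep(TRUE, nrow(seqs))
  n_median <- 0L
  repeat {
    d <- hamming_matrix(seqs)
    if (nrow(seqs) < 3) break
    ed <- msn_edges(d, epsilon)
    adj <- matrix(FALSE, nrow(seqs), nrow(seqs))
    adj[ed] <- TRUE; adj <- adj | t(adj)
    base_len <- mst_length(d)
    best <- NULL
    for (i in seq_len(nrow(seqs))) {
      nb <- which(adj[i, ])
      if (length(nb) < 2) next
      prs <- utils::combn(nb, 2)
      for (p in seq_len(ncol(prs))) {
        m <- triplet_median(seqs[i, ], seqs[prs[1, p], ], seqs[prs[2, p], ])
        key <- paste(m, collapse = "")
        if (key %in% apply(seqs, 1, paste, collapse = "")) next
        d2 <- hamming_matrix(rbind(seqs, m))
        len <- mst_length(d2)
        if (len < base_len - 1e-9 &&
            (is.null(best) || len < best$len ||
             (len == best$len && key < best$key)))
          best <- list(m = m, len = len, key = key)
      }
    }
    if (is.null(best)) break
    n_median <- n_median + 1L
    seqs <- rbind(seqs, best$m)
    labels <- c(labels, paste0("mv", n_median))
    rownames(seqs) <- labels
    observed <- c(observed, FALSE)
    if (n_median > 50L) break
  }
  # prune median vectors that sit on a simple path (degree <= 2)
  repeat {
    d <- hamming_matrix(seqs)
    ed <- msn_edges(d, epsilon)
    deg <- tabulate(c(ed), nbins = nrow(seqs))
    drop <- which(!observed & deg <= 2)
    if (!length(drop)) break
    seqs <- seqs[-drop[1], , drop = FALSE]
    labels <- labels[-drop[1]]
    observed <- observed[-drop[1]]
  }
  d <- hamming_matrix(seqs)
  ed <- if (nrow(seqs) > 1) msn_edges(d, epsilon) else matrix(integer(0), 0, 2)
  freq <- rep(0L, length(labels))
  freq[observed] <- as.integer(hapset$counts[labels[observed]])
  edges <- data.frame(from = labels[ed[, 1]], to = labels[ed[, 2]],
                      steps = d[ed])
  if (nrow(edges)) {
    swap <- edges$from > edges$to
    tmp <- edges$from[swap]; edges$from[swap] <- edges$to[swap]; edges$to[swap] <- tmp
    edges <- edges[order(edges$steps, edges$from, edges$to), , drop = FALSE]
    rownames(edges) <- NULL
  }
  structure(list(nodes = data.frame(label = labels,
                                    type = ifelse(observed, "observed", "median"),
                                    freq = freq),
                 edges = edges,
                 sequences = seqs),
            class = "hg_mjnetwork")
}

#' @export
print.hg_mjnetwork <- function(x, ...) {
  cat("median-joining network:", sum(x$nodes$type == "observed"),
      "observed haplotypes,", sum(x$nodes$type == "median"),
      "median vectors,", nrow(x$edges), "edges\n")
  print(x$edges)
  invisible(x)
}

#' Write a network as edge-list TSV and GraphML
#'
#' @param net an `hg_mjnetwork`.
#' @param path_tsv edge-list TSV path (node_a, node_b, steps, node types).
#' @param path_graphml optional GraphML path.
#' @return `path_tsv`, invisibly.
#' @export
write_network <- function(net, path_tsv, path_graphml = NULL) {
  typ <- stats::setNames(net$nodes$type, net$nodes$label)
  out <- data.frame(node_a = net$edges$from, node_b = net$edges$to,
                    steps = net$edges$steps,
                    type_a = typ[net$edges$from], type_b = typ[net$edges$to])
  utils::write.table(out, path_tsv, sep = "\t", quote = FALSE, row.names = FALSE)
  if (!is.null(path_graphml)) {
    g <- igraph::graph_from_data_frame(net$edges, directed = FALSE,
                                       vertices = net$nodes)
    igraph::write_graph(g, path_graphml, format = "graphml")
  }
  invisible(path_tsv)
}

#' Path-sum distances between observed haplotypes in a tree-like network
#'
#' @param net an `hg_mjnetwork`.
#' @return labelled matrix of summed step counts along shortest paths.
#' @export
network_path_distances <- function(net) {
  g <- igraph::graph_from_data_frame(net$edges, directed = FALSE,
                                     vertices = net$nodes)
  obs <- net$nodes$label[net$nodes$type == "observed"]
  igraph::distances(g, v = obs, to = obs, weights = igraph::E(g)$steps)
}
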