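# End-to-end orchestration of the three analysis tracks. These functions
# are the programmatic equivalent of the command-line entry point shipped
# at inst/exec/haplogeo.

write_manifest <- function(out_dir, step, params) {
  path <- file.path(out_dir, "manifest.json")
  manifest <- if (file.exists(path)) jsonlite::fromJSON(path, simplifyVector = FALSE) else list()
  manifest[[step]] <- c(list(timestamp = format(Sys.time(), "%Y-%m-%dT%H:%M:%S"),
                             package_version = as.character(utils::packageVersion("haplogeo"))),
                        params)
  jsonlite::write_json(manifest, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(path)
}

#' Haplotype track: alignment to network files
#'
#' Reads a FASTA alignment, codes indels, collapses haplotypes and builds
#' the median-joining network, writing the assignment table, distance
#' matrix, edge list and GraphML under `out_dir`.
#'
#' @param fasta input alignment path.
#' @param out_dir output directory (created if needed).
#' @param epsilon median-joining tolerance.
#' @return invisibly, the list from [collapse_haplotypes()] plus `network`.
#' @export
run_haplotypes <- function(fasta, out_dir, epsilon = 0) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  aln <- read_fasta(fasta)
  coded <- code_indels(aln)
  hap <- collapse_haplotypes(coded)
  net <- median_joining_network(hap$haplotypes, epsilon = epsilon)
  write_haplotype_assignment(hap$haplotypes,
                             file.path(out_dir, "haplotype_assignment.tsv"))
  write_distance_matrix(hap$distances,
                        file.path(out_dir, "haplotype_distances.tsv"))
  write_network(net, file.path(out_dir, "network_edges.tsv"),
                file.path(out_dir, "network.graphml"))
  write_manifest(out_dir, "haplotypes",
                 list(fasta = fasta, epsilon = epsilon,
                      records = length(aln$ids), L_raw = aln$L,
                      L_coded = hap$haplotypes$L,
                      k = length(hap$haplotypes$labels),
                      S = hap$haplotypes$S))
  invisible(c(hap, list(network = net)))
}

#' Population-genetic track: diversity, differentiation, AMOVA, SAMOVA,
#' PCoA and Mantel
#'
#' Runs the full statistics chain on a site table (default: the packaged
#' dataset) and writes per-site diversity, differentiation, AMOVA,
#' SAMOVA, PCoA and Mantel outputs under `out_dir`.
#'
#' @param site_table path to a long-format site TSV, or `NULL` for the
#'   packaged dataset.
#' @param out_dir output directory.
#' @param seed integer seed for all stochastic stages.
#' @param n_perm permutations for the NST/GST and Mantel tests.
#' @param samova_runs independent SAMOVA runs (0 skips SAMOVA).
#' @param amova_perm permutations for AMOVA p-values.
#' @return invisibly, a list of all result objects.
#' @export
run_popgen <- function(site_table = NULL, out_dir, seed = 1, n_perm = 1000,
                       samova_runs = 25, amova_perm = 0) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  ds <- if (is.null(site_table)) load_fixture() else load_sites(site_table)
  dm <- fixture_distances(ds)
  L <- fixture_alignment_length(ds)
  div <- site_diversity(dataset_preset(ds, "table1_as_printed"), dm, L,
                        which = "wild")
  utils::write.table(div, file.path(out_dir, "site_diversity.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  permut_all <- dataset_preset(ds, "paper_permut_sites")
  permut_cn <- dataset_preset(ds, "paper_permut_china")
  res <- list(range_wide = pons_petit(permut_all, dm),
              mainland_china = pons_petit(permut_cn, dm))
  pv <- c(range_wide = nst_gst_permutation_test(permut_all, dm, n_perm,
                                                derive_seed(seed, 1))$p_perm,
          mainland_china = nst_gst_permutation_test(permut_cn, dm, n_perm,
                                                    derive_seed(seed, 2))$p_perm)
  write_differentiation(res, file.path(out_dir, "differentiation.tsv"), pv)
  am_ds <- dataset_preset(ds, "paper_amova_sites")
  am <- amova(am_ds, dm = dm, n_perm = amova_perm, seed = derive_seed(seed, 3))
  write_amova(am, file.path(out_dir, "amova.tsv"))
  sam <- NULL
  if (samova_runs > 0) {
    sam <- samova(am_ds, dm, K = 2, n_runs = samova_runs,
                  seed = derive_seed(seed, 4))
    write_samova(sam, file.path(out_dir, "samova_partition.tsv"),
                 file.path(out_dir, "samova_trace.json"))
  }
  phi <- pairwise_phist(am_ds, dm)
  write_distance_matrix(round(phi, 6), file.path(out_dir, "pairwise_phist.tsv"))
  pc <- pcoa(phi)
  utils::write.table(data.frame(site = rownames(pc$coordinates),
                                pc$coordinates),
                     file.path(out_dir, "pcoa_coordinates.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  coords <- as.matrix(am_ds$sites[match(rownames(phi), am_ds$sites$code),
                                  c("lon", "lat")])
  S <- nrow(coords)
  geo <- matrix(0, S, S)
  for (i in seq_len(S - 1)) for (j in (i + 1):S)
    geo[i, j] <- geo[j, i] <- great_circle_km(coords[i, ], coords[j, ])
  mt <- mantel_test(phi, geo, n_perm = n_perm, seed = derive_seed(seed, 5))
  jsonlite::write_json(list(mantel_r = mt$r, mantel_p = mt$p,
                            pcoa_axis1_percent = pc$percent[1],
                            samova_FCT = if (!is.null(sam)) sam$FCT else NULL),
                       file.path(out_dir, "structure_summary.json"),
                       auto_unbox = TRUE, digits = NA)
  write_manifest(out_dir, "popgen",
                 list(site_table = site_table %||% "packaged fixture",
                      seed = seed, n_perm = n_perm,
                      samova_runs = samova_runs, amova_perm = amova_perm,
                      dropped = am_ds$provenance))
  invisible(list(diversity = div, differentiation = res, p_perm = pv,
                 amova = am, samova = sam, phist = phi, pcoa = pc,
                 mantel = mt))
}

#' Landscape track: niche overlap, migration vectors and corridors
#'
#' Demonstration orchestration over synthetic inputs (or caller-supplied
#' rasters/occurrences): fits envelope suitability models for two
#' occurrence sets, runs the niche identity test, thresholds the pooled
#' model, derives block centroids and migration vectors between two
#' suitability periods, and sums least-cost corridors over
#' shared-haplotype site pairs.
#'
#' @param env list of environmental rasters (default: synthetic).
#' @param occ list with occurrence sets `a` and `b` (default: sampled
#'   from a synthetic landscape, divergent pair).
#' @param ds site dataset for the corridor network (default: synthetic).
#' @param out_dir output directory.
#' @param seed integer seed.
#' @param n_reps identity-test pseudoreplicates.
#' @return invisibly, a list of result objects.
#' @export
run_landscape <- function(env = NULL, occ = NULL, ds = NULL, out_dir,
                          seed = 1, n_reps = 100) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  if (is.null(env)) env <- generate_landscape(seed = derive_seed(seed, 10))
  if (is.null(occ)) {
    base <- new_raster(matrix(1, env[[1]]$nrows, env[[1]]$ncols),
                       env[[1]]$xllcorner, env[[1]]$yllcorner,
                       env[[1]]$cellsize)
    occ <- sample_occurrences(base, n = 40, mode = "divergent-pair",
                              seed = derive_seed(seed, 11))
  }
  keep <- prune_correlated(env)
  env <- env[keep]
  it <- identity_test(occ$a, occ$b, env, n_reps = n_reps,
                      seed = derive_seed(seed, 12))
  jsonlite::write_json(list(D = it$D, I = it$I, p_D = it$p_D, p_I = it$p_I,
                            null_D = it$null_D, null_I = it$null_I,
                            n_reps = it$n_reps, seed = it$seed),
                       file.path(out_dir, "niche_identity.json"),
                       auto_unbox = TRUE, digits = NA)
  pooled <- occurrences(c(occ$a$lon, occ$b$lon), c(occ$a$lat, occ$b$lat))
  suit <- envelope_suitability(pooled, env)
  write_asc(suit, file.path(out_dir, "suitability.asc"))
  bg <- sample_occurrences(new_raster(matrix(1, suit$nrows, suit$ncols),
                                      suit$xllcorner, suit$yllcorner,
                                      suit$cellsize),
                           n = 200, seed = derive_seed(seed, 13))
  thr <- max_sss_threshold(suit, pooled, bg)
  pa <- presence_absence(suit, thr$threshold)
  write_asc(pa, file.path(out_dir, "presence.asc"))
  suit_a <- envelope_suitability(occ$a, env)
  c1 <- block_centroids(presence_absence(suit_a, thr$threshold),
                        block_deg = suit$cellsize * 5)
  c2 <- block_centroids(pa, block_deg = suit$cellsize * 5)
  vec <- if (nrow(c1) && nrow(c2)) migration_vectors(c1, c2) else NULL
  if (!is.null(vec))
    utils::write.csv(vec, file.path(out_dir, "migration_vectors.csv"),
                     row.names = FALSE)
  if (is.null(ds)) ds <- generate_sites(n_sites = 6, n_per_site = 5,
                                        centers = rbind(
                                          c(suit$xllcorner + 2, suit$yllcorner + 2),
                                          c(suit$xllcorner + 7, suit$yllcorner + 7)),
                                        spread = 0.8,
                                        seed = derive_seed(seed, 14))
  ds <- thin_one_per_grid(ds, grid_deg = suit$cellsize * 5)
  net <- corridor_network(ds, suit)
  write_asc(net$surface, file.path(out_dir, "corridor_network.asc"))
  jsonlite::write_json(net$pair_costs, file.path(out_dir, "corridor_costs.json"),
                       digits = NA)
  write_manifest(out_dir, "landscape",
                 list(seed = seed, n_reps = n_reps,
                      threshold = thr$threshold,
                      corridor_classes = net$classes,
                      corridor_weights = net$weights,
                      layers_retained = keep))
  invisible(list(identity = it, threshold = thr, presence = pa,
                 vectors = vec, corridors = net))
}
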