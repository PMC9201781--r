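# Site-level dataset: loading, inclusion/aggregation rules, geography.

new_dataset <- function(sites, wild, cultivated, provenance = character()) {
  stopifnot(nrow(sites) >= 1, !anyDuplicated(sites$code))
  rownames(wild) <- rownames(cultivated) <- sites$code
  structure(list(sites = sites, wild = wild, cultivated = cultivated,
                 provenance = provenance),
            class = "hg_dataset")
}

#' @export
print.hg_dataset <- function(x, ...) {
  cat("sampling-site dataset:", nrow(x$sites), "sites,",
      sum(x$wild), "wild +", sum(x$cultivated), "cultivated individuals\n")
  if (length(x$provenance))
    cat("filters applied:\n", paste(" -", x$provenance, collapse = "\n"), "\n")
  invisible(x)
}

#' Load a long-format site table
#'
#' The table has one row per (site, status, haplotype) with columns
#' `code, locality, lon, lat, elev_m, status, haplotype, count`.
#'
#' @param path TSV path.
#' @param meta_path optional JSON sidecar with `groups` (west/east site
#'   codes) and other presets.
#' @return an `hg_dataset`.
#' @export
load_sites <- function(path, meta_path = NULL) {
  tab <- utils::read.delim(path, stringsAsFactors = FALSE)
  need <- c("code", "locality", "lon", "lat", "elev_m", "status",
            "haplotype", "count")
  if (!all(need %in% names(tab)))
    hg_stop("site table must have columns: ", paste(need, collapse = ", "))
  if (any(tab$count < 0)) hg_stop("negative counts in site table")
  if (any(abs(tab$lon) > 180) || any(abs(tab$lat) > 90))
    hg_stop("coordinates out of range")
  codes <- unique(tab$code)
  haps <- sort(unique(tab$haplotype))
  sites <- tab[!duplicated(tab$code),
               c("code", "locality", "lon", "lat", "elev_m")]
  rownames(sites) <- sites$code
  sites <- sites[codes, ]
  sites$country <- site_country(sites$locality)
  sites$group <- "none"
  meta <- NULL
  if (!is.null(meta_path)) {
    meta <- jsonlite::fromJSON(meta_path)
    sites$group[sites$code %in% meta$groups$west] <- "west"
    sites$group[sites$code %in% meta$groups$east] <- "east"
    haps <- meta$haplotype_order %||% haps
  }
  mk <- function(status) {
    m <- matrix(0, length(codes), length(haps), dimnames = list(codes, haps))
    sub <- tab[tab$status == status, ]
    for (i in seq_len(nrow(sub)))
      m[sub$code[i], sub$haplotype[i]] <- m[sub$code[i], sub$haplotype[i]] + sub$count[i]
    m
  }
  ds <- new_dataset(sites, mk("wild"), mk("cultivated"))
  attr(ds, "meta") <- meta
  ds
}

#' Load the packaged lacquer-tree sampling-site dataset
#'
#' The full published site table: 79 sampling sites across China, South
#' Korea and Japan with per-haplotype wild and cultivated counts,
#' coordinates, elevations and west/east group labels, plus the
#' step-distance matrix implied by the published haplotype network.
#'
#' @return an `hg_dataset` with a `meta` attribute carrying the distance
#'   matrix, alignment length and dataset presets.
#' @export
load_fixture <- function() {
  load_sites(system.file("extdata", "toxicodendron_sites.tsv",
                         package = "haplogeo"),
             system.file("extdata", "toxicodendron_sites_meta.json",
                         package = "haplogeo"))
}

#' Haplotype step-distance matrix of the packaged dataset
#'
#' @param ds a dataset from [load_fixture()] (or any with a meta attribute).
#' @return labelled integer matrix of pairwise mutational steps.
#' @export
fixture_distances <- function(ds = load_fixture()) {
  meta <- attr(ds, "meta")
  if (is.null(meta)) hg_stop("dataset carries no step-distance metadata")
  sd <- meta$step_distances
  m <- sd$matrix
  if (is.list(m)) m <- do.call(rbind, m)
  dimnames(m) <- list(sd$labels, sd$labels)
  m
}

#' Alignment length (bp) of the packaged dataset
#' @param ds dataset with meta attribute.
#' @return integer number of base pairs.
#' @export
fixture_alignment_length <- function(ds = load_fixture()) {
  as.integer(attr(ds, "meta")$alignment_length_bp)
}

#' Per-site analysis counts
#'
#' @param ds an `hg_dataset`.
#' @param which `"all"` (wild + cultivated remaining in the dataset),
#'   `"wild"`, or `"cultivated"`.
#' @return sites x haplotypes count matrix.
#' @export
site_counts <- function(ds, which = c("all", "wild", "cultivated")) {
  which <- match.arg(which)
  switch(which,
         all = ds$wild + ds$cultivated,
         wild = ds$wild,
         cultivated = ds$cultivated)
}

drop_empty_sites <- function(ds, reason) {
  n <- rowSums(ds$wild + ds$cultivated)
  drop <- which(n == 0)
  if (length(drop)) {
    ds$provenance <- c(ds$provenance,
                       paste0("dropped (", reason, "): ",
                              paste(ds$sites$code[drop], collapse = ", ")))
    ds$sites <- ds$sites[-drop, , drop = FALSE]
    ds$wild <- ds$wild[-drop, , drop = FALSE]
    ds$cultivated <- ds$cultivated[-drop, , drop = FALSE]
  }
  ds
}

#' Remove cultivated trees sampled in China
#'
#' Cultivated counts of Chinese sites are zeroed (they reflect historical
#' transplanting rather than natural range); cultivated trees outside
#' China are kept because they represent the species' distribution there.
#' Sites left with zero individuals are removed.
#'
#' @param ds an `hg_dataset`.
#' @return filtered `hg_dataset`.
#' @export
exclude_china_cultivated <- function(ds) {
  cn <- is_china(ds$sites$locality)
  ds$cultivated[cn, ] <- 0
  ds$provenance <- c(ds$provenance, "Chinese cultivated trees excluded")
  drop_empty_sites(ds, "no individuals after excluding Chinese cultivated trees")
}

grid_cell <- function(lon, lat, grid_deg) {
  paste(floor(lon / grid_deg), floor(lat / grid_deg))
}

#' Merge or drop small sampling sites on a geographic grid
#'
#' Sites with fewer than `min_n` individuals are merged into the largest
#' site sharing their grid cell (counts summed, the larger site's
#' coordinates and code kept); sites still below `min_n` afterwards are
#' dropped. Grid cells are half-open intervals anchored at 0 degrees.
#'
#' @param ds an `hg_dataset` (typically wild-only after
#'   [exclude_china_cultivated()]).
#' @param grid_deg grid cell size in decimal degrees.
#' @param min_n minimum individuals per retained site.
#' @return aggregated `hg_dataset`; merges and drops are recorded in the
#'   provenance notes.
#' @export
aggregate_small_sites <- function(ds, grid_deg = 0.625, min_n = 3) {
  repeat {
    n <- rowSums(ds$wild + ds$cultivated)
    cells <- grid_cell(ds$sites$lon, ds$sites$lat, grid_deg)
    small <- which(n < min_n & n > 0)
    if (!length(small)) break
    small <- small[order(n[small], ds$sites$code[small])]
    merged <- FALSE
    for (i in small) {
      mates <- setdiff(which(cells == cells[i]), i)
      if (!length(mates)) next
      j <- mates[order(-n[mates], ds$sites$code[mates])][1]
      keep <- if (n[j] >= n[i]) j else i
      gone <- if (keep == j) i else j
      ds$wild[keep, ] <- ds$wild[keep, ] + ds$wild[gone, ]
      ds$cultivated[keep, ] <- ds$cultivated[keep, ] + ds$cultivated[gone, ]
      ds$provenance <- c(ds$provenance,
                         paste0("merged ", ds$sites$code[gone], " into ",
                                ds$sites$code[keep], " (shared ", grid_deg,
                                " degree grid cell)"))
      ds$sites <- ds$sites[-gone, , drop = FALSE]
      ds$wild <- ds$wild[-gone, , drop = FALSE]
      ds$cultivated <- ds$cultivated[-gone, , drop = FALSE]
      merged <- TRUE
      break
    }
    if (!merged) break
  }
  n <- rowSums(ds$wild + ds$cultivated)
  drop <- which(n < min_n)
  if (length(drop)) {
    ds$provenance <- c(ds$provenance,
                       paste0("dropped (n < ", min_n, "): ",
                              paste(ds$sites$code[drop], collapse = ", ")))
    ds$sites <- ds$sites[-drop, , drop = FALSE]
    ds$wild <- ds$wild[-drop, , drop = FALSE]
    ds$cultivated <- ds$cultivated[-drop, , drop = FALSE]
  }
  ds
}

#' Keep one site per grid cell
#'
#' Retains the largest site (ties broken by lexicographic code) within
#' each occupied grid cell, to reduce spatial sampling bias before
#' corridor analyses.
#'
#' @inheritParams aggregate_small_sites
#' @return thinned `hg_dataset`.
#' @export
thin_one_per_grid <- function(ds, grid_deg = 0.625) {
  n <- rowSums(ds$wild + ds$cultivated)
  cells <- grid_cell(ds$sites$lon, ds$sites$lat, grid_deg)
  ord <- order(cells, -n, ds$sites$code)
  keep <- ord[!duplicated(cells[ord])]
  keep <- sort(keep)
  dropped <- ds$sites$code[-keep]
  if (length(dropped))
    ds$provenance <- c(ds$provenance,
                       paste0("thinned to one site per ", grid_deg,
                              " degree cell; dropped: ",
                              paste(dropped, collapse = ", ")))
  ds$sites <- ds$sites[keep, , drop = FALSE]
  ds$wild <- ds$wild[keep, , drop = FALSE]
  ds$cultivated <- ds$cultivated[keep, , drop = FALSE]
  ds
}

#' Great-circle distance in kilometres
#'
#' Haversine distance with Earth radius 6371.0 km.
#'
#' @param a,b points as `c(lon, lat)` or two-column matrices.
#' @return distance(s) in km.
#' @export
great_circle_km <- function(a, b) {
  geosphere::distHaversine(a, b, r = 6371000) / 1000
}

#' Site pairs sharing at least one haplotype
#'
#' @param ds an `hg_dataset`.
#' @return data.frame with columns `a`, `b` (site codes, a < b).
#' @export
shared_haplotype_pairs <- function(ds) {
  m <- site_counts(ds) > 0
  codes <- ds$sites$code
  out <- list()
  if (nrow(m) > 1) for (i in 1:(nrow(m) - 1)) for (j in (i + 1):nrow(m)) {
    if (any(m[i, ] & m[j, ]))
      out[[length(out) + 1L]] <- data.frame(a = codes[i], b = codes[j])
  }
  if (!length(out)) return(data.frame(a = character(), b = character()))
  do.call(rbind, out)
}

#' Published dataset presets
#'
#' Reconstructs the analysis datasets used in the source study:
#' * `"paper_amova_sites"` - 75 sites / 385 trees: Chinese cultivated
#'   trees excluded (derived by rule).
#' * `"paper_permut_sites"` - 47 sites / 353 trees: additionally drops the
#'   published list of Chinese sites with fewer than three wild trees and
#'   applies the published Japanese within-grid combinations (membership
#'   hard-coded from the publication; all Japanese and Korean sites are
#'   fixed for one haplotype, so differentiation statistics do not depend
#'   on the particular pairing).
#' * `"paper_permut_china"` - the 39-site / 327-tree mainland-China subset
#'   of the above.
#' * `"table1_as_printed"` - the full table with site ZAO's cultivated
#'   trees folded into its analysis counts, matching the printed per-site
#'   diversity cells.
#'
#' @param ds the packaged dataset ([load_fixture()]).
#' @param name preset name.
#' @return an `hg_dataset`.
#' @export
dataset_preset <- function(ds = load_fixture(),
                           name = c("paper_amova_sites", "paper_permut_sites",
                                    "paper_permut_china", "table1_as_printed")) {
  name <- match.arg(name)
  meta <- attr(ds, "meta")
  if (is.null(meta)) hg_stop("presets require the packaged dataset metadata")
  if (name == "paper_amova_sites") {
    out <- exclude_china_cultivated(ds)
    attr(out, "meta") <- meta
    return(out)
  }
  if (name == "table1_as_printed") {
    p <- meta$presets$table1_as_printed
    for (code in p$sites_with_cultivated_included) {
      ds$wild[code, ] <- ds$wild[code, ] + ds$cultivated[code, ]
      ds$cultivated[code, ] <- 0
    }
    cn <- is_china(ds$sites$locality)
    ds$cultivated[cn, ] <- 0
    ds$provenance <- c(ds$provenance,
                       "per-site diversity preset: Chinese cultivated excluded except as printed")
    attr(ds, "meta") <- meta
    return(ds)
  }
  p <- meta$presets$paper_permut_sites
  base <- exclude_china_cultivated(ds)
  cn <- is_china(base$sites$locality)
  keep_cn <- base$sites$code[cn & !(base$sites$code %in% p$china_excluded)]
  sel <- base$sites$code %in% keep_cn
  sites <- base$sites[sel, , drop = FALSE]
  wild <- base$wild[sel, , drop = FALSE]
  cult <- base$cultivated[sel, , drop = FALSE]
  prov <- c(base$provenance,
            paste0("Permut preset: dropped Chinese sites ",
                   paste(p$china_excluded, collapse = ", ")))
  if (name == "paper_permut_sites") {
    add_site <- function(code, members) {
      idx <- match(members, base$sites$code)
      n <- rowSums(base$wild + base$cultivated)[idx]
      lead <- idx[order(-n, base$sites$code[idx])][1]
      s <- base$sites[lead, , drop = FALSE]
      s$code <- code
      rownames(s) <- code
      sites <<- rbind(sites, s)
      wild <<- rbind(wild, colSums(base$wild[idx, , drop = FALSE]))
      cult <<- rbind(cult, colSums(base$cultivated[idx, , drop = FALSE]))
    }
    for (nm in names(p$japan_combined)) add_site(nm, p$japan_combined[[nm]])
    for (nm in c(p$japan_kept_single, p$korea_kept)) add_site(nm, nm)
    prov <- c(prov, "Permut preset: published Japanese grid combinations applied")
  }
  out <- new_dataset(sites, wild, cult, prov)
  attr(out, "meta") <- meta
  out
}

#' Write a site table in long format
#'
#' @param ds an `hg_dataset`.
#' @param path output TSV path.
#' @return `path`, invisibly.
#' @export
write_sites <- function(ds, path) {
  rows <- list()
  for (status in c("wild", "cultivated")) {
    m <- if (status == "wild") ds$wild else ds$cultivated
    idx <- which(m > 0, arr.ind = TRUE)
    if (nrow(idx)) {
      s <- ds$sites[idx[, 1], ]
      rows[[status]] <- data.frame(code = s$code, locality = s$locality,
                                   lon = s$lon, lat = s$lat, elev_m = s$elev_m,
                                   status = status,
                                   haplotype = colnames(m)[idx[, 2]],
                                   count = m[idx])
    }
  }
  out <- do.call(rbind, rows)
  out <- out[order(match(out$code, ds$sites$code), out$status, out$haplotype), ]
  utils::write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
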