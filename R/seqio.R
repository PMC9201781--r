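# Alignment input and haplotype collapsing for cpDNA spacer data.

#' Read an aligned FASTA file
#'
#' Reads a multiple sequence alignment in FASTA format (wrapped or
#' single-line). Sequences are upper-cased and RNA 'U' is mapped to 'T'.
#' All records must have equal length; a ragged file is an error naming
#' the offending record.
#'
#' @param path path to a FASTA file.
#' @return an object of class `hg_alignment`: a list with `ids` (record
#'   identifiers, in file order) and `seq` (character matrix, one row per
#'   record, one column per alignment position, alphabet A/C/G/T/-/N).
#' @export
read_fasta <- function(path) {
  if (!file.exists(path)) hg_stop("file not found: ", path)
  lines <- readLines(path)
  if (!length(lines) || !any(startsWith(lines, ">")))
    hg_stop("empty FASTA file: ", path)
  # RNA 'U' is outside the DNA alphabet of the parser; map it up front
  isseq <- !startsWith(lines, ">")
  lines[isseq] <- chartr("uU", "tT", lines[isseq])
  tmp <- tempfile(fileext = ".fasta")
  on.exit(unlink(tmp))
  writeLines(lines, tmp)
  raw <- ape::read.FASTA(tmp)
  if (length(raw) == 0) hg_stop("empty FASTA file: ", path)
  chars <- lapply(as.character(raw), toupper)
  lens <- lengths(chars)
  if (length(unique(lens)) > 1L) {
    bad <- names(chars)[lens != lens[1L]]
    hg_stop("ragged alignment: record(s) ", paste(bad, collapse = ", "),
            " differ in length from record ", names(chars)[1L])
  }
  if (lens[1L] == 0L) hg_stop("zero-length sequences in ", path)
  m <- do.call(rbind, chars)
  rownames(m) <- names(chars)
  new_alignment(names(chars), m)
}

new_alignment <- function(ids, seq) {
  if (anyDuplicated(ids)) hg_stop("duplicate record ids in alignment")
  structure(list(ids = ids, seq = seq, L = ncol(seq)),
            class = "hg_alignment")
}

#' @export
print.hg_alignment <- function(x, ...) {
  cat("cpDNA alignment:", length(x$ids), "records x", x$L, "positions\n")
  invisible(x)
}

#' Write an alignment to FASTA
#'
#' @param aln an `hg_alignment`.
#' @param path output file path.
#' @param width line wrap width.
#' @return `path`, invisibly.
#' @export
write_fasta <- function(aln, path, width = 70) {
  con <- file(path, "w")
  on.exit(close(con))
  for (i in seq_along(aln$ids)) {
    writeLines(paste0(">", aln$ids[i]), con)
    s <- paste(aln$seq[i, ], collapse = "")
    starts <- seq(1, nchar(s), by = width)
    writeLines(substring(s, starts, pmin(starts + width - 1, nchar(s))), con)
  }
  invisible(path)
}

# maximal gap runs per sequence, as (start, end, record) rows
gap_intervals <- function(seq) {
  out <- list()
  for (i in seq_len(nrow(seq))) {
    r <- rle(seq[i, ] == "-")
    ends <- cumsum(r$lengths)
    starts <- ends - r$lengths + 1L
    g <- which(r$values)
    if (length(g))
      out[[length(out) + 1L]] <- data.frame(start = starts[g], end = ends[g],
                                            record = i)
  }
  if (!length(out)) return(NULL)
  do.call(rbind, out)
}

#' Code indels as single binary characters
#'
#' Each maximal gap run whose column extent is identical across all
#' gap-bearing sequences is treated as a single mutation event: the run is
#' replaced by one binary column in which gap-bearing sequences carry 'T'
#' and all others 'A' (the convention used for the 96-bp *trnL-F* indel of
#' the packaged study data). Gap runs that overlap between sequences with
#' different extents are ambiguous and raise an error rather than guess a
#' coding. The rule applies to any shared gap run, minimum length 1.
#'
#' @param aln an `hg_alignment` (gap character `-`).
#' @return an `hg_alignment` with each coded run collapsed to one column;
#'   the alignment length decreases by (run length - 1) per coded run.
#' @export
code_indels <- function(aln) {
  iv <- gap_intervals(aln$seq)
  if (is.null(iv)) return(aln)
  key <- paste(iv$start, iv$end)
  events <- unique(iv[, c("start", "end")])
  events <- events[order(events$start), , drop = FALSE]
  # identical-extent runs are fine; overlapping different extents are not
  if (nrow(events) > 1L) {
    for (i in seq_len(nrow(events) - 1L)) {
      if (events$end[i] >= events$start[i + 1L]) {
        cols <- seq(events$start[i + 1L], min(events$end[i], events$end[i + 1L]))
        hg_stop("inconsistent gap run boundaries at column(s) ",
                paste(cols, collapse = ", "),
                ": overlapping gap runs with different extents")
      }
    }
  }
  seq <- aln$seq
  for (i in rev(seq_len(nrow(events)))) {
    s <- events$start[i]; e <- events$end[i]
    members <- unique(iv$record[iv$start == s & iv$end == e])
    coded <- rep("A", nrow(seq))
    coded[members] <- "T"
    left <- if (s > 1) seq[, 1:(s - 1), drop = FALSE] else NULL
    right <- if (e < ncol(seq)) seq[, (e + 1):ncol(seq), drop = FALSE] else NULL
    seq <- cbind(left, coded, right)
  }
  dimnames(seq) <- list(aln$ids, NULL)
  new_alignment(aln$ids, seq)
}

#' Collapse aligned sequences into haplotypes
#'
#' Identical sequences share a haplotype; labels H1, H2, ... are assigned
#' in order of first appearance in the alignment. Columns containing 'N'
#' in any record are masked from both the comparison and the
#' segregating-character count. Pairwise distances between haplotype
#' representatives are counts of differing (unmasked) columns, i.e.
#' mutational steps on an indel-coded alignment.
#'
#' @param aln an `hg_alignment` (typically after [code_indels()]).
#' @return a list with components `haplotypes` (class `hg_haplotypes`:
#'   `labels`, `representatives` character matrix, `assignment` named by
#'   record id, `counts`, `S` segregating characters, `L`, `masked`
#'   column indices) and `distances` (labelled integer step matrix).
#' @export
collapse_haplotypes <- function(aln) {
  if (length(aln$ids) == 0L) hg_stop("alignment has zero records")
  masked <- which(apply(aln$seq == "N", 2, any))
  use <- setdiff(seq_len(ncol(aln$seq)), masked)
  if (!length(use)) hg_stop("all columns masked by N characters")
  cmp <- aln$seq[, use, drop = FALSE]
  key <- apply(cmp, 1, paste, collapse = "")
  first <- !duplicated(key)
  k <- sum(first)
  labels <- paste0("H", seq_len(k))
  names(labels) <- key[first]
  assignment <- unname(labels[key])
  names(assignment) <- aln$ids
  reps <- aln$seq[first, , drop = FALSE]
  rownames(reps) <- unname(labels)
  rep_cmp <- cmp[first, , drop = FALSE]
  rownames(rep_cmp) <- unname(labels)
  d <- hamming_matrix(rep_cmp)
  S <- sum(apply(rep_cmp, 2, function(col) length(unique(col)) > 1L))
  hs <- structure(list(labels = unname(labels),
                       representatives = reps,
                       rep_cmp = rep_cmp,
                       assignment = assignment,
                       counts = table(factor(assignment, levels = labels)),
                       S = S, L = ncol(aln$seq), masked = masked),
                  class = "hg_haplotypes")
  list(haplotypes = hs, distances = d)
}

#' @export
print.hg_haplotypes <- function(x, ...) {
  cat("haplotype set:", length(x$labels), "haplotypes,",
      x$S, "segregating characters, L =", x$L, "\n")
  print(x$counts)
  invisible(x)
}

hamming_matrix <- function(m) {
  n <- nrow(m)
  d <- matrix(0L, n, n, dimnames = list(rownames(m), rownames(m)))
  if (n > 1) for (i in 1:(n - 1)) for (j in (i + 1):n)
    d[i, j] <- d[j, i] <- sum(m[i, ] != m[j, ])
  d
}

#' Write a haplotype assignment table
#'
#' @param hapset an `hg_haplotypes` object.
#' @param path output TSV path.
#' @return `path`, invisibly.
#' @export
write_haplotype_assignment <- function(hapset, path) {
  utils::write.table(data.frame(id = names(hapset$assignment),
                                haplotype = unname(hapset$assignment)),
                     path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Write a labelled distance matrix as TSV
#'
#' @param d square labelled matrix.
#' @param path output TSV path.
#' @return `path`, invisibly.
#' @export
write_distance_matrix <- function(d, path) {
  utils::write.table(cbind(haplotype = rownames(d), as.data.frame(d)),
                     path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
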