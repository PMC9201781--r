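#' @keywords internal
"_PACKAGE"

`%||%` <- function(a, b) if (is.null(a)) b else a

hg_stop <- function(...) stop(..., call. = FALSE)

#' Country of a sampling site
#'
#' Parsed as the last comma-separated token of the locality string
#' (the convention of the packaged site table).
#'
#' @param locality character vector of locality strings.
#' @return character vector of country names.
#' @export
site_country <- function(locality) {
  vapply(strsplit(as.character(locality), ","),
         function(x) trimws(x[length(x)]), character(1))
}

is_china <- function(locality) site_country(locality) == "China"

# deterministic per-purpose sub-seeds derived from one user seed
derive_seed <- function(seed, offset) {
  (as.integer(seed) + as.integer(offset) * 10007L) %% 2147483647L
}
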