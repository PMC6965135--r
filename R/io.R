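## Plain-text interchange: variant tables, SEG-like segment tables, presence
## matrices, spectra and catalogs are all tab-separated with documented
## column names; coordinates are 1-based inclusive.

#' Write / read a multi-sample variant table
#'
#' @param sites site table.
#' @param path TSV path.
#' @return `path` (write) or the site table (read).
#' @export
write_sites_tsv <- function(sites, path) {
  utils::write.table(sites, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' @rdname write_sites_tsv
#' @export
read_sites_tsv <- function(path) {
  utils::read.delim(path, stringsAsFactors = FALSE,
                    colClasses = c(chrom = "character"))
}

#' Write / read a SEG-like segment table
#'
#' Columns: `chrom`, `start`, `end` (1-based inclusive), `cn_total`,
#' `cn_major`, `cn_minor`; the region id and purity travel in a header
#' comment line `#region=<id> purity=<p>`.
#'
#' @param profile an [segment_profile()].
#' @param path TSV path.
#' @export
write_segments_tsv <- function(profile, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(sprintf("#region=%s purity=%.6f", profile$region_id,
                     profile$purity), con)
  utils::write.table(profile$segments, con, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' @rdname write_segments_tsv
#' @export
read_segments_tsv <- function(path) {
  header <- readLines(path, n = 1L)
  m <- regmatches(header, regexec("#region=(\\S+) purity=([0-9.eE+-]+)",
                                  header))[[1]]
  if (length(m) != 3L) stop_mseq("missing #region/purity header in %s", path)
  seg <- utils::read.delim(path, skip = 1L, stringsAsFactors = FALSE,
                           colClasses = c(chrom = "character"))
  segment_profile(m[2], as.numeric(m[3]), seg)
}

#' Write a presence matrix as 0/1 TSV
#'
#' @param presence an `mseq_presence`.
#' @param path TSV path.
#' @export
write_presence_tsv <- function(presence, path) {
  df <- data.frame(mutation_id = rownames(presence$presence),
                   presence$presence * 1L,
                   category = presence$category,
                   check.names = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Write a 96-context spectrum (or catalog) as TSV
#'
#' Rows follow the canonical context order `A[C>A]A ... T[T>G]T`.
#'
#' @param x named 96-vector or a 96-row matrix.
#' @param path TSV path.
#' @export
write_spectrum_tsv <- function(x, path) {
  if (is.matrix(x)) {
    df <- data.frame(context = rownames(x), x, check.names = FALSE)
  } else {
    df <- data.frame(context = names(x), count = as.numeric(x))
  }
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a signature catalog TSV (96 rows x S signature columns)
#'
#' @param path TSV with a `context` column and one column per signature.
#' @return numeric matrix with context rownames.
#' @export
read_catalog_tsv <- function(path) {
  df <- utils::read.delim(path, stringsAsFactors = FALSE, check.names = FALSE)
  mat <- as.matrix(df[setdiff(names(df), "context")])
  rownames(mat) <- df$context
  mat
}
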