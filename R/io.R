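# TSV dialects: canonical column sets for every table the pipeline reads
# or writes. Reader is tolerant (extra columns kept with a warning),
# writer is strict.
.dialects <- list(
  densitometry = c("sample_id", "tissue", "timepoint", "gene", "exon",
                   "band", "intensity", "ef1a", "replicate"),
  calibration  = c("gene", "exon", "epsilon"),
  profile      = c("sample_id", "tissue", "timepoint", "replicate",
                   "gene", "exon", "cterm", "proportion"),
  tracks       = c("track_id", "t", "x", "y"),
  track_metrics = c("track_id", "S", "V", "W", "undefined_wander"),
  nuclei       = c("x", "y", "mef2", "s46", "marker"),
  bands        = c("variant", "amplified", "amplicon_nt", "fragments",
                   "is_cut"),
  trace        = c("t", "diameter"),
  series       = c("template", "intensity"))

#' Read a typed pipeline table
#'
#' Tab-separated reader for the pipeline's table dialects. The expected
#' columns must all be present; unknown extra columns are kept with a
#' warning (tolerant reader), so hand-annotated lab tables survive a
#' round trip.
#'
#' @param path File path.
#' @param dialect One of `"densitometry"`, `"calibration"`, `"profile"`,
#'   `"tracks"`, `"track_metrics"`, `"nuclei"`, `"bands"`, `"trace"`,
#'   `"series"`.
#' @return data.frame with the dialect's columns first.
#' @export
read_table <- function(path, dialect) {
  cols <- .dialects[[match.arg(dialect, names(.dialects))]]
  if (!file.exists(path)) .stop_cls("file_error", "no such file: %s", path)
  tab <- read.delim(path, stringsAsFactors = FALSE, check.names = FALSE)
  missing <- setdiff(cols, names(tab))
  if (length(missing))
    .stop_cls("dialect_error",
              "%s table %s: expected columns [%s], found [%s]",
              dialect, path, paste(cols, collapse = ", "),
              paste(names(tab), collapse = ", "))
  extra <- setdiff(names(tab), cols)
  if (length(extra))
    warning(sprintf("extra column(s) preserved in %s: %s", path,
                    paste(extra, collapse = ", ")))
  tab[, c(cols, extra), drop = FALSE]
}

#' Write a typed pipeline table
#'
#' Strict writer for the dialects accepted by [read_table()]: all dialect
#' columns must be present and are written first, in canonical order.
#'
#' @param x data.frame to write.
#' @param path Output path.
#' @param dialect Dialect name; see [read_table()].
#' @return `path`, invisibly.
#' @export
write_table <- function(x, path, dialect) {
  cols <- .dialects[[match.arg(dialect, names(.dialects))]]
  missing <- setdiff(cols, names(x))
  if (length(missing))
    .stop_cls("dialect_error", "cannot write %s table: missing [%s]",
              dialect, paste(missing, collapse = ", "))
  extra <- setdiff(names(x), cols)
  write.table(x[, c(cols, extra), drop = FALSE], path, sep = "\t",
              quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Write transcript variants as FASTA
#'
#' Record ids encode the variant key as `gene|exon|cterm`.
#'
#' @param seqs Named list/vector of nucleotide (or peptide) strings.
#' @param path Output path.
#' @param type `"dna"` or `"aa"`.
#' @return `path`, invisibly.
#' @export
write_fasta <- function(seqs, path, type = c("dna", "aa")) {
  type <- match.arg(type)
  set <- if (type == "dna")
    Biostrings::DNAStringSet(unlist(seqs)) else
    Biostrings::AAStringSet(unlist(seqs))
  Biostrings::writeXStringSet(set, path)
  invisible(path)
}

#' Read a FASTA file into a named character vector
#'
#' @param path FASTA path.
#' @param type `"dna"` or `"aa"`.
#' @return Named character vector of sequences.
#' @export
read_fasta <- function(path, type = c("dna", "aa")) {
  type <- match.arg(type)
  set <- if (type == "dna") Biostrings::readDNAStringSet(path) else
    Biostrings::readAAStringSet(path)
  setNames(as.character(set), names(set))
}

#' Read a binary mask from a plain-text 0/1 matrix or TIFF
#'
#' Plain-text masks are whitespace-separated 0/1 rows; `.tif`/`.tiff`
#' files are read with the tiff package when available.
#'
#' @param path Mask path.
#' @return Logical matrix.
#' @export
read_mask <- function(path) {
  if (grepl("\\.tiff?$", path, ignore.case = TRUE)) {
    if (!requireNamespace("tiff", quietly = TRUE))
      .stop_cls("file_error", "tiff package required for TIFF masks")
    m <- tiff::readTIFF(path)
    if (length(dim(m)) > 2) m <- m[, , 1]
    return(m > 0.5)
  }
  m <- as.matrix(read.table(path))
  if (!all(m %in% c(0, 1)))
    .stop_cls("invalid_mask", "mask file %s is not binary", path)
  m <- m > 0
  dimnames(m) <- NULL
  m
}
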