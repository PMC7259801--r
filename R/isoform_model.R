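#' Translate a coding sequence
#'
#' Standard-code translation of a nucleotide string from a given frame,
#' truncated at the first stop codon. Truncation is reported, not an error,
#' so that premature-stop mutant sequences translate cleanly.
#'
#' @param cds Nucleotide string containing only A/C/G/T.
#' @param frame Integer 0, 1 or 2: number of nucleotides skipped before the
#'   first codon.
#' @return A list with `peptide` (amino-acid string, stop excluded) and
#'   `stopped` (`TRUE` iff a stop codon was reached).
#' @export
#' @examples
#' translate_cds("ATGAAA")          # MK, no stop seen
#' translate_cds("ATGTAA")$stopped  # TRUE
translate_cds <- function(cds, frame = 0) {
  stopifnot(is.character(cds), length(cds) == 1)
  if (!frame %in% 0:2) .stop_cls("invalid_frame", "frame must be 0, 1 or 2")
  cds <- toupper(cds)
  if (grepl("[^ACGT]", cds))
    .stop_cls("invalid_sequence", "cds contains non-ACGT characters")
  if (nchar(cds) - frame < 3)
    .stop_cls("length_error", "cds too short to translate from frame %d", frame)
  body <- substring(cds, frame + 1)
  n_codon <- nchar(body) %/% 3
  codons <- substring(body, 3 * seq_len(n_codon) - 2, 3 * seq_len(n_codon))
  aa <- unname(Biostrings::GENETIC_CODE[codons])
  stop_at <- match("*", aa)
  if (!is.na(stop_at)) {
    list(peptide = paste(aa[seq_len(stop_at - 1)], collapse = ""),
         stopped = TRUE)
  } else {
    list(peptide = paste(aa, collapse = ""), stopped = FALSE)
  }
}

#' Construct a primer/enzyme assay description
#'
#' One reaction of the splicing assay: a forward primer specific for one
#' gene and alternative exon, a common reverse primer (given 5'->3', i.e. as
#' the reverse complement of its template binding site), and the diagnostic
#' restriction enzyme used to split the C-terminal classes (StyI `CC^WWGG`
#' for jnk1a, NheI `G^CTAGC` for jnk1b by default).
#'
#' @param gene `"jnk1a"` or `"jnk1b"`.
#' @param exon_target `"Ex7"` or `"Ex8"`.
#' @param fwd,rev Primer sequences, 5'->3'.
#' @param enzyme_site IUPAC pattern of the recognition site.
#' @param cut_offset 0-based number of nucleotides 5' of the cut within the
#'   site on the top strand.
#' @return An object of class `primer_assay`.
#' @export
primer_assay <- function(gene, exon_target, fwd, rev,
                         enzyme_site, cut_offset) {
  gene <- match.arg(gene, .genes)
  exon_target <- match.arg(exon_target, .exons)
  stopifnot(nzchar(fwd), nzchar(rev))
  if (grepl("[^ACGTRYSWKMBDHVN]", toupper(enzyme_site)))
    .stop_cls("invalid_pattern", "enzyme_site contains non-IUPAC characters")
  if (cut_offset < 0 || cut_offset > nchar(enzyme_site))
    .stop_cls("invalid_offset", "cut_offset outside enzyme site")
  structure(list(gene = gene, exon_target = exon_target,
                 fwd = toupper(fwd), rev = toupper(rev),
                 enzyme_site = toupper(enzyme_site),
                 cut_offset = as.integer(cut_offset)),
            class = "primer_assay")
}

#' In-silico PCR with exact primer matching
#'
#' Locates the forward primer and the reverse complement of the reverse
#' primer on the template and returns the inclusive amplicon (both primer
#' footprints included). Matching is exact; zero or multiple sites for
#' either primer are errors.
#'
#' @param template Nucleotide string.
#' @param assay A [primer_assay()] (only `fwd` and `rev` are used).
#' @return The amplicon as a character string.
#' @export
in_silico_pcr <- function(template, assay) {
  stopifnot(inherits(assay, "primer_assay"))
  if (nchar(assay$fwd) < 15 || nchar(assay$rev) < 15)
    .stop_cls("primer_too_short", "primers must be at least 15 nt")
  tmpl <- Biostrings::DNAString(toupper(template))
  fhits <- Biostrings::matchPattern(assay$fwd, tmpl)
  rsite <- as.character(
    Biostrings::reverseComplement(Biostrings::DNAString(assay$rev)))
  rhits <- Biostrings::matchPattern(rsite, tmpl)
  if (length(fhits) == 0 || length(rhits) == 0)
    .stop_cls("no_amplicon", "no %s primer site on template",
              if (length(fhits) == 0) "forward" else "reverse")
  if (length(fhits) > 1 || length(rhits) > 1)
    .stop_cls("ambiguous_template", "multiple primer sites on template")
  from <- BiocGenerics::start(fhits)[1]
  to <- BiocGenerics::end(rhits)[1]
  if (to <= from)
    .stop_cls("no_amplicon", "reverse site lies upstream of forward site")
  as.character(Biostrings::subseq(tmpl, from, to))
}

#' Restriction digest with an IUPAC degenerate site
#'
#' Scans the sequence left to right for every (possibly overlapping) match
#' of the recognition pattern and applies a cut at each match start plus
#' `cut_offset`, modelling complete digestion. Fragment lengths always sum
#' to the input length; a sequence with no site returns one full-length
#' fragment.
#'
#' @param seq Nucleotide string.
#' @param site IUPAC recognition pattern.
#' @param cut_offset 0-based cut position within the site (nucleotides 5' of
#'   the cut on the top strand).
#' @return Integer vector of fragment lengths, 5' to 3'.
#' @export
#' @examples
#' in_silico_digest("AAAGCTAGCAAA", "GCTAGC", 1)  # NheI-style: 4, 8
in_silico_digest <- function(seq, site, cut_offset) {
  seq <- toupper(seq)
  site <- toupper(site)
  if (!nzchar(seq)) .stop_cls("empty_input", "empty sequence")
  if (grepl("[^ACGTRYSWKMBDHVN]", site))
    .stop_cls("invalid_pattern", "site contains non-IUPAC characters")
  if (cut_offset < 0 || cut_offset > nchar(site))
    .stop_cls("invalid_offset", "cut_offset outside site")
  n <- nchar(seq)
  hits <- Biostrings::matchPattern(site, Biostrings::DNAString(seq),
                                   fixed = FALSE)
  cuts <- BiocGenerics::start(hits) - 1L + as.integer(cut_offset)
  cuts <- sort(unique(cuts[cuts > 0 & cuts < n]))
  diff(c(0L, cuts, n))
}

#' Predict assay bands for a set of transcript variants
#'
#' For each variant, runs the assay matching its gene and exon choice:
#' in-silico PCR followed by digestion with the assay's enzyme. Variants
#' whose exon is not an assay target, or whose template no longer carries a
#' primer site, are reported as not amplified rather than failing the batch.
#'
#' @param variants Named list of nucleotide strings; names are variant ids
#'   `gene|exon|cterm` (as written by [gen_transcript_set()]).
#' @param assays List of [primer_assay()] objects covering the exon targets.
#' @return A data.frame with one row per variant: `variant`, `amplified`,
#'   `amplicon_nt`, `fragments` (semicolon-joined lengths), `is_cut`.
#' @export
predict_assay_bands <- function(variants, assays) {
  stopifnot(is.list(variants), !is.null(names(variants)))
  key <- function(a) paste(a$gene, a$exon_target, sep = "|")
  assay_map <- setNames(assays, vapply(assays, key, character(1)))
  rows <- lapply(names(variants), function(id) {
    parts <- strsplit(id, "|", fixed = TRUE)[[1]]
    out <- data.frame(variant = id, amplified = FALSE,
                      amplicon_nt = NA_integer_, fragments = "",
                      is_cut = NA, stringsAsFactors = FALSE)
    assay <- assay_map[[paste(parts[1], parts[2], sep = "|")]]
    if (is.null(assay)) return(out)
    amp <- tryCatch(in_silico_pcr(variants[[id]], assay),
                    no_amplicon = function(e) NULL,
                    ambiguous_template = function(e) NULL)
    if (is.null(amp)) return(out)
    frags <- in_silico_digest(amp, assay$enzyme_site, assay$cut_offset)
    out$amplified <- TRUE
    out$amplicon_nt <- nchar(amp)
    out$fragments <- paste(frags, collapse = ";")
    out$is_cut <- length(frags) > 1
    out
  })
  do.call(rbind, rows)
}

#' Classify peptide divergence between two sequences
#'
#' Global (Needleman-Wunsch) alignment of two peptides followed by
#' per-column classification: `identical` for equal residues, `favourable`
#' for substitutions with positive substitution-matrix score, `divergent`
#' for score <= 0, and `insertion`/`deletion` for gap columns (gap in the
#' reference `b` / gap in `a`). This mirrors the black/green/red colouring
#' conventionally used to annotate alternatively spliced exon peptides.
#'
#' @param a,b Amino-acid strings (20 standard residues).
#' @param matrix Substitution matrix; default BLOSUM62 from Biostrings.
#' @param gap_open,gap_extend Gap scores (negative by convention; absolute
#'   values are used as penalties).
#' @return A list of class `peptide_comparison`: `columns` data.frame
#'   (`pos`, `residue_a`, `residue_b`, `class`) and counts `n_identical`,
#'   `n_favourable`, `n_divergent`, `n_indel`.
#' @export
#' @examples
#' cmp <- compare_peptides("ACDE", "ACEE")
#' cmp$n_favourable  # D<->E scores +2 in BLOSUM62
compare_peptides <- function(a, b, matrix = NULL,
                             gap_open = -11, gap_extend = -1) {
  stopifnot(nzchar(a), nzchar(b))
  a <- toupper(a); b <- toupper(b)
  if (is.null(matrix)) {
    e <- new.env()
    utils::data("BLOSUM62", package = "Biostrings", envir = e)
    matrix <- e$BLOSUM62
  }
  std <- strsplit("ACDEFGHIKLMNPQRSTVWY", "")[[1]]
  if (!all(std %in% rownames(matrix)))
    .stop_cls("invalid_matrix", "matrix must cover the 20 standard residues")
  bad <- setdiff(unique(strsplit(paste0(a, b), "")[[1]]), rownames(matrix))
  if (length(bad))
    .stop_cls("invalid_residue", "unknown residue(s): %s",
              paste(bad, collapse = ", "))
  aln <- Biostrings::pairwiseAlignment(
    Biostrings::AAString(a), Biostrings::AAString(b),
    substitutionMatrix = matrix,
    gapOpening = abs(gap_open), gapExtension = abs(gap_extend),
    type = "global")
  ra <- strsplit(as.character(Biostrings::pattern(aln)), "")[[1]]
  rb <- strsplit(as.character(Biostrings::subject(aln)), "")[[1]]
  cls <- character(length(ra))
  for (i in seq_along(ra)) {
    if (ra[i] == "-") cls[i] <- "deletion"
    else if (rb[i] == "-") cls[i] <- "insertion"
    else if (ra[i] == rb[i]) cls[i] <- "identical"
    else if (matrix[ra[i], rb[i]] > 0) cls[i] <- "favourable"
    else cls[i] <- "divergent"
  }
  cols <- data.frame(pos = seq_along(ra), residue_a = ra, residue_b = rb,
                     class = cls, stringsAsFactors = FALSE)
  structure(list(columns = cols,
                 n_identical = sum(cls == "identical"),
                 n_favourable = sum(cls == "favourable"),
                 n_divergent = sum(cls == "divergent"),
                 n_indel = sum(cls %in% c("insertion", "deletion"))),
            class = "peptide_comparison")
}

#' @export
print.peptide_comparison <- function(x, ...) {
  cat(sprintf(
    "peptide comparison: %d columns (%d identical, %d favourable, %d divergent, %d indel)\n",
    nrow(x$columns), x$n_identical, x$n_favourable, x$n_divergent, x$n_indel))
  invisible(x)
}

#' Synthetic C-terminal extension fixture pair
#'
#' Returns a synthetic reconstruction of the long C-terminal extension
#' comparison between the divergent fish paralog (jnk1b Lg) and the
#' canonical human JNK1 p54 extension. The pair is engineered to the
#' published divergence structure -- 9 divergent substitutions across the 39
#' aligned extension residues plus a single inserted threonine -- because
#' the original peptide sequences are published only as supplementary
#' figures. It is a labelled stand-in, not the real sequence.
#'
#' @return Named character vector with elements `human_p54_extension` and
#'   `jnk1b_lg_extension`.
#' @export
cterm_extension_fixture <- function() {
  path <- system.file("extdata", "synthetic_cterm_extensions.fasta",
                      package = "splicecard", mustWork = TRUE)
  seqs <- Biostrings::readAAStringSet(path)
  setNames(as.character(seqs), sub(" .*", "", names(seqs)))
}
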