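test_that("translation follows the standard code and truncates at stops", {
  expect_equal(translate_cds("ATGAAA"), list(peptide = "MK", stopped = FALSE))
  expect_equal(translate_cds("ATGTAA"), list(peptide = "M", stopped = TRUE))
  # frame shift
  expect_equal(translate_cds("CATGAAA", frame = 1)$peptide, "MK")
  # trailing partial codon ignored
  expect_equal(translate_cds("ATGAAAC")$peptide, "MK")
  expect_error(translate_cds("ATGXAA"), class = "invalid_sequence")
  expect_error(translate_cds("AT"), class = "length_error")
})

test_that("generated variant peptides match stored translations, with the
           Ex8 serine/threonine paralog difference", {
  ts <- gen_transcript_set()
  for (id in names(ts$variants))
    expect_equal(translate_cds(ts$variants[[id]])$peptide,
                 ts$peptides[[id]], info = id)
  pa8 <- strsplit(ts$peptides[["jnk1a|Ex8|Sh"]], "")[[1]]
  pb8 <- strsplit(ts$peptides[["jnk1b|Ex8|Sh"]], "")[[1]]
  d <- which(pa8 != pb8)
  # the paralogs' Ex8 blocks differ at exactly the diagnostic residue:
  # serine in jnk1a where jnk1b carries threonine
  diag <- d[pa8[d] == "S" & pb8[d] == "T"]
  expect_length(diag, 1)
})

test_that("in-silico PCR slices the template between exact primer sites", {
  assay <- primer_assay("jnk1a", "Ex7",
                        fwd = "GAAGCAGAAGCAGAAGCA",
                        rev = "TACTTCTACTTCTACTTC",
                        enzyme_site = "CCWWGG", cut_offset = 2)
  rsite <- "GAAGTAGAAGTAGAAGTA"  # revcomp of rev
  tmpl <- paste0(strrep("ACT", 10), assay$fwd, strrep("CAT", 20), rsite,
                 strrep("TTC", 5))
  amp <- in_silico_pcr(tmpl, assay)
  # matches an independent substring-scan oracle
  f <- oracle_substring_starts(tmpl, assay$fwd)
  r <- oracle_substring_starts(tmpl, rsite)
  expect_equal(amp, substr(tmpl, f, r + nchar(rsite) - 1))
  expect_equal(nchar(amp), 18 + 60 + 18)
  # missing or duplicated sites are errors
  expect_error(in_silico_pcr(strrep("ACT", 40), assay),
               class = "no_amplicon")
  expect_error(in_silico_pcr(paste0(tmpl, tmpl), assay),
               class = "ambiguous_template")
})

test_that("digest cuts every IUPAC site and conserves total length", {
  expect_equal(in_silico_digest("AAAAAA", "GCTAGC", 1), 6L)
  expect_equal(in_silico_digest("AAAGCTAGCAAA", "GCTAGC", 1), c(4L, 8L))
  expect_equal(in_silico_digest("CCATGGCCTTGG", "CCWWGG", 2),
               c(2L, 6L, 4L))
  expect_error(in_silico_digest("", "GCTAGC", 1), class = "empty_input")
  expect_error(in_silico_digest("ACGT", "GCTAXC", 1),
               class = "invalid_pattern")
})

test_that("digest agrees with the brute-force IUPAC scan oracle", {
  set.seed(42)
  sites <- c("GCTAGC", "CCWWGG", "GGNNCC", "RAATTY")
  for (i in 1:60) {
    s <- random_dna(sample(50:2000, 1))
    site <- sample(sites, 1)
    off <- sample(0:nchar(site), 1)
    frags <- in_silico_digest(s, site, off)
    expect_equal(frags, oracle_digest(s, site, off),
                 info = sprintf("iter %d site %s off %d", i, site, off))
    expect_equal(sum(frags), nchar(s))
  }
  # a long sequence as well
  s <- random_dna(10000)
  expect_equal(in_silico_digest(s, "CCWWGG", 2), oracle_digest(s, "CCWWGG", 2))
})

test_that("digest round-trips: rejoining fragments with a site-free joiner
           preserves the fragment count", {
  set.seed(7)
  s <- random_dna(800)
  frags <- in_silico_digest(s, "GCTAGC", 1)
  lens <- c(0, cumsum(frags))
  pieces <- substring(s, lens[-length(lens)] + 1, lens[-1])
  # AAAA cannot complete a GCTAGC site across junctions
  rejoined <- paste(pieces, collapse = "AAAA")
  refrag <- in_silico_digest(rejoined, "GCTAGC", 1)
  expect_equal(length(refrag), length(frags))
})

test_that("band prediction cuts all Lg variants, none of the Sh, and
           conserves amplicon length", {
  ts <- gen_transcript_set()
  bands <- predict_assay_bands(ts$variants, ts$assays)
  expect_true(all(bands$amplified))
  lg <- grepl("\\|Lg$", bands$variant)
  expect_true(all(bands$is_cut[lg]))
  expect_true(all(!bands$is_cut[!lg]))
  expect_true(all(vapply(strsplit(bands$fragments[lg], ";"),
                         function(f) length(f) == 2, logical(1))))
  frag_sums <- vapply(strsplit(bands$fragments, ";"),
                      function(f) sum(as.integer(f)), numeric(1))
  expect_equal(frag_sums, bands$amplicon_nt)
  # independent oracle on the generated sequences
  for (i in which(lg)) {
    parts <- strsplit(bands$variant[i], "|", fixed = TRUE)[[1]]
    assay <- Filter(function(a) a$gene == parts[1] &&
                      a$exon_target == parts[2], ts$assays)[[1]]
    amp_oracle <- {
      v <- ts$variants[[bands$variant[i]]]
      f <- oracle_substring_starts(v, assay$fwd)
      rsite <- as.character(Biostrings::reverseComplement(
        Biostrings::DNAString(assay$rev)))
      r <- oracle_substring_starts(v, rsite)
      substr(v, f, r + nchar(rsite) - 1)
    }
    expect_equal(
      as.integer(strsplit(bands$fragments[i], ";")[[1]]),
      oracle_digest(amp_oracle, assay$enzyme_site, assay$cut_offset))
  }
})

test_that("a variant with a deleted primer site is reported, not fatal", {
  ts <- gen_transcript_set()
  broken <- ts$variants
  a7 <- Filter(function(a) a$gene == "jnk1a" && a$exon_target == "Ex7",
               ts$assays)[[1]]
  broken[["jnk1a|Ex7|Sh"]] <- sub(a7$fwd, "", broken[["jnk1a|Ex7|Sh"]],
                                  fixed = TRUE)
  bands <- predict_assay_bands(broken, ts$assays)
  expect_false(bands$amplified[bands$variant == "jnk1a|Ex7|Sh"])
  expect_true(all(bands$amplified[bands$variant != "jnk1a|Ex7|Sh"]))
})

test_that("peptide comparison classifies columns against BLOSUM62", {
  id4 <- compare_peptides("ACDE", "ACDE")
  expect_equal(id4$n_identical, 4)
  expect_equal(id4$n_favourable + id4$n_divergent + id4$n_indel, 0)
  cmp <- compare_peptides("ACDE", "ACEE")
  expect_equal(cmp$n_identical, 3)
  expect_equal(cmp$n_favourable, 1)  # D<->E scores +2
  expect_equal(cmp$n_divergent, 0)
  expect_error(compare_peptides("ACDE", "ACOE"), class = "invalid_residue")
  # self comparison is all-identical for arbitrary peptides
  set.seed(11)
  for (i in 1:10) {
    p <- paste(sample(strsplit("ACDEFGHIKLMNPQRSTVWY", "")[[1]],
                      sample(5:40, 1), replace = TRUE), collapse = "")
    self <- compare_peptides(p, p)
    expect_equal(self$n_identical, nchar(p))
    expect_equal(self$n_favourable + self$n_divergent + self$n_indel, 0)
  }
  # counts always sum to the number of aligned columns
  expect_equal(cmp$n_identical + cmp$n_favourable + cmp$n_divergent +
                 cmp$n_indel, nrow(cmp$columns))
})
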