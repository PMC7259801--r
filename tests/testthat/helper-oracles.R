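# Independent brute-force oracles, deliberately naive and free of
# Biostrings, used to cross-check the sequence operations.

iupac_map <- list(
  A = "A", C = "C", G = "G", T = "T",
  R = c("A", "G"), Y = c("C", "T"), S = c("C", "G"), W = c("A", "T"),
  K = c("G", "T"), M = c("A", "C"),
  B = c("C", "G", "T"), D = c("A", "G", "T"), H = c("A", "C", "T"),
  V = c("A", "C", "G"), N = c("A", "C", "G", "T"))

# O(n * m) windowed scan for IUPAC pattern match starts (1-based)
oracle_iupac_starts <- function(seq, pattern) {
  s <- strsplit(seq, "")[[1]]
  p <- strsplit(pattern, "")[[1]]
  n <- length(s); m <- length(p)
  if (m > n) return(integer(0))
  starts <- integer(0)
  for (i in seq_len(n - m + 1)) {
    ok <- TRUE
    for (j in seq_len(m)) {
      if (!s[i + j - 1] %in% iupac_map[[p[j]]]) { ok <- FALSE; break }
    }
    if (ok) starts <- c(starts, i)
  }
  starts
}

oracle_digest <- function(seq, site, cut_offset) {
  n <- nchar(seq)
  cuts <- oracle_iupac_starts(seq, site) - 1L + as.integer(cut_offset)
  cuts <- sort(unique(cuts[cuts > 0 & cuts < n]))
  diff(c(0L, cuts, n))
}

# plain substring scan for exact primer sites
oracle_substring_starts <- function(seq, sub) {
  n <- nchar(seq); m <- nchar(sub)
  which(vapply(seq_len(n - m + 1),
               function(i) substr(seq, i, i + m - 1) == sub, logical(1)))
}

random_dna <- function(n) paste(sample(c("A", "C", "G", "T"), n,
                                       replace = TRUE), collapse = "")

default_calibration <- function() {
  data.frame(gene = rep(c("jnk1a", "jnk1b"), each = 2),
             exon = rep(c("Ex7", "Ex8"), 2), epsilon = 1,
             stringsAsFactors = FALSE)
}

# mean per-gene share over replicates from a profile data.frame
gene_share_mean <- function(profiles, gene) {
  per <- vapply(split(profiles, profiles$sample_id), function(s)
    sum(s$proportion[s$gene == gene]), numeric(1))
  mean(per)
}
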