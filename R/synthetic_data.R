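#' Simulation configuration
#'
#' Collects every parameter of the synthetic-data generators with defaults
#' matching the study conditions the pipeline is designed around: n = 8
#' replicate clutches with lognormal densitometry noise sigma = 0.15;
#' tracks sampled every 6 minutes over a 2-hour mid-somitogenesis window;
#' chamber means of 100 ventricular and 30 atrial cardiomyocytes with a
#' 26% ventricular deficit in mutant mode; a 100/60 micrometre
#' diastole/systole diameter trace at 2.5 beats per second filmed at 127
#' frames per second.
#'
#' @param seed Integer seed; every generator derives its randomness from
#'   it deterministically.
#' @param truth_profile Named numeric vector of 8 transcript proportions
#'   (names `gene|exon|cterm`) summing to 1.
#' @param epsilons Named per-reaction efficiency factors (`gene|exon`).
#' @param noise_sigma Lognormal sigma of band intensity noise.
#' @param n_replicates Biological replicates (clutches).
#' @param n_tracks Tracks per group.
#' @param drift Directed migration speed towards the target (um/min).
#' @param sigma Random-walk scale (um per sqrt(min)).
#' @param duration Track duration (min).
#' @param frame_interval Sampling interval (min).
#' @param mutant_speed_factor Multiplier on drift in mutant mode, in (0, 1].
#' @param lambda_vent,lambda_atr Poisson means of chamber counts.
#' @param ventricular_reduction Relative ventricular deficit in mutants.
#' @param n_fields Nuclei fields per group.
#' @param dd,ds Diastolic and systolic diameters (um), `dd > ds > 0`.
#' @param rate Beat rate (Hz).
#' @param trace_duration Trace duration (s).
#' @param frame_rate Sampling rate (frames/s).
#' @param trace_noise Additive Gaussian diameter noise SD (um).
#' @return A list of class `sim_config`.
#' @export
sim_config <- function(seed = 1,
                       truth_profile = truth_profiles()$pre_gastrulation,
                       epsilons = setNames(rep(1, 4),
                                           paste(rep(.genes, each = 2),
                                                 .exons, sep = "|")),
                       noise_sigma = 0.15,
                       n_replicates = 8,
                       n_tracks = 50,
                       drift = 0.5,
                       sigma = 0.8,
                       duration = 120,
                       frame_interval = 6,
                       mutant_speed_factor = 0.6,
                       lambda_vent = 100,
                       lambda_atr = 30,
                       ventricular_reduction = 0.26,
                       n_fields = 20,
                       dd = 100, ds = 60,
                       rate = 2.5,
                       trace_duration = 6,
                       frame_rate = 127,
                       trace_noise = 0) {
  stopifnot(abs(sum(truth_profile) - 1) < 1e-9, all(truth_profile >= 0),
            all(epsilons > 0), noise_sigma >= 0, n_replicates >= 1,
            drift > 0, sigma >= 0, duration > 0, frame_interval > 0,
            mutant_speed_factor > 0, mutant_speed_factor <= 1,
            lambda_vent > 0, lambda_atr > 0,
            ventricular_reduction >= 0, ventricular_reduction < 1)
  if (dd <= ds || ds <= 0)
    .stop_cls("parameter_error", "need dd > ds > 0")
  if (rate <= 0) .stop_cls("parameter_error", "rate must be positive")
  structure(as.list(environment()), class = "sim_config")
}

# deterministic substream: each generator perturbs the master seed by a
# fixed offset so generators can be called in any order
.set_substream <- function(seed, offset) {
  set.seed((as.integer(seed) + offset) %% .Machine$integer.max)
}

#' Bundled ground-truth transcript proportion profiles
#'
#' Named reconstructions of the two whole-embryo compositions the assay is
#' benchmarked against: `pre_gastrulation` (80% of jnk1 transcripts from
#' jnk1a, roughly even exon 7/8 usage in jnk1a, jnk1b mostly Ex8 Sh) and
#' `larval_120hpf` (80% from jnk1b, with the late shift towards jnk1b
#' Ex7). These are reconstructions of reported proportions, not measured
#' data; only the gene-level shares are anchored to reported values, the
#' within-gene splits follow the described qualitative pattern.
#'
#' @return Named list of two named numeric vectors (names
#'   `gene|exon|cterm`), each summing to 1.
#' @export
truth_profiles <- function() {
  path <- system.file("extdata", "truth_profiles.tsv",
                      package = "splicecard", mustWork = TRUE)
  tab <- read.delim(path, stringsAsFactors = FALSE)
  out <- lapply(split(tab, tab$profile), function(d)
    setNames(d$proportion, .variant_id(d$gene, d$exon, d$cterm)))
  out
}

# codons free of G and of stop codons; used for neutral filler so that the
# G-containing primer and enzyme motifs can only occur where inserted
.filler <- function(n_codons, phase = 0) {
  pool <- c("ACT", "CAT", "TAC", "CTC", "ACC", "TTC", "ATC", "CCT",
            "AAC", "CTT", "TCA", "CAC", "ATT", "ACA", "TCC", "CCA")
  idx <- ((seq_len(n_codons) - 1 + phase) %% length(pool)) + 1
  paste(pool[idx], collapse = "")
}

#' Generate the eight-variant transcript set and its four assays
#'
#' Builds synthetic coding sequences sharing a common core, with
#' gene-specific alternative exon blocks carrying unique forward-primer
#' sites, a gene-specific common reverse-primer site, and a diagnostic
#' enzyme site present only in the long (Lg) C-terminal tails: a
#' StyI-type site (`CC^WWGG`) for jnk1a and an NheI-type site (`G^CTAGC`)
#' for jnk1b. Filler sequence is G-free, so the G-rich primer and enzyme
#' motifs cannot occur anywhere except where deliberately placed; the
#' constructor re-scans every sequence and fails if a spurious site is
#' found. The jnk1a Ex8 block encodes a serine at the position where the
#' jnk1b Ex8 block encodes a threonine, mirroring the single diagnostic
#' residue difference between the paralogs' Ex8 peptides.
#'
#' @param config A [sim_config()] (only `seed` is used, for provenance;
#'   the construction itself is deterministic).
#' @return List with `variants` (named list of 8 CDS strings, names
#'   `gene|exon|cterm`), `peptides` (their translations), and `assays`
#'   (list of 4 [primer_assay()]).
#' @export
gen_transcript_set <- function(config = sim_config()) {
  fwd <- list(
    "jnk1a|Ex7" = "GAAGCAGAAGCAGAAGCA",
    "jnk1a|Ex8" = "GGAGCAGGAGCAGGAGCA",
    "jnk1b|Ex7" = "GAGGCAGAGGCAGAGGCA",
    "jnk1b|Ex8" = "GGTGCAGGTGCAGGTGCA")
  rev_site <- list(jnk1a = "GAAGTAGAAGTAGAAGTA",  # rev primer binding site
                   jnk1b = "GACGTAGACGTAGACGTA")
  enzyme <- list(jnk1a = list(site = "CCWWGG", insert = "CCATGG", offset = 2L),
                 jnk1b = list(site = "GCTAGC", insert = "GCTAGC", offset = 1L))
  # Ex8 diagnostic residue: serine codon in jnk1a, threonine codon in jnk1b
  diag_codon <- list(jnk1a = "TCA", jnk1b = "ACA")
  core5 <- paste0("ATG", .filler(15, phase = 0))
  mid <- .filler(10, phase = 3)
  sh_tail <- .filler(5, phase = 6)
  variants <- list()
  assays <- list()
  for (g in .genes) {
    for (x in .exons) {
      exon_block <- paste0(
        .filler(2, phase = if (x == "Ex7") 1 else 2),
        fwd[[paste(g, x, sep = "|")]],
        if (x == "Ex8") diag_codon[[g]] else .filler(1, phase = 9),
        .filler(2, phase = 5))
      for (ct in .cterms) {
        tail_seq <- if (ct == "Sh") sh_tail else
          paste0(.filler(6, phase = 7), enzyme[[g]]$insert,
                 .filler(6, phase = 8))
        cds <- paste0(core5, exon_block, mid, tail_seq,
                      rev_site[[g]], .filler(2, phase = 4), "TAA")
        variants[[.variant_id(g, x, ct)]] <- cds
      }
      assays[[paste(g, x, sep = "|")]] <- primer_assay(
        gene = g, exon_target = x,
        fwd = fwd[[paste(g, x, sep = "|")]],
        rev = as.character(Biostrings::reverseComplement(
          Biostrings::DNAString(rev_site[[g]]))),
        enzyme_site = enzyme[[g]]$site,
        cut_offset = enzyme[[g]]$offset)
    }
  }
  .verify_transcript_set(variants, assays, enzyme)
  peptides <- lapply(variants, function(s) translate_cds(s)$peptide)
  list(variants = variants, peptides = peptides, assays = unname(assays),
       seed = config$seed)
}

# spurious-site scan: every primer occurs exactly once in its own
# transcripts and never elsewhere; each enzyme site occurs exactly once in
# Lg tails of its own gene and nowhere else; translations carry no
# premature stop
.verify_transcript_set <- function(variants, assays, enzyme) {
  count_hits <- function(pat, s, fixed = TRUE)
    length(Biostrings::matchPattern(pat, Biostrings::DNAString(s),
                                    fixed = fixed))
  for (id in names(variants)) {
    parts <- strsplit(id, "|", fixed = TRUE)[[1]]
    s <- variants[[id]]
    for (ak in names(assays)) {
      a <- assays[[ak]]
      expected <- as.integer(a$gene == parts[1] &&
                             a$exon_target == parts[2])
      if (count_hits(a$fwd, s) != expected)
        .stop_cls("construction_error",
                  "spurious/missing fwd site for %s in %s", ak, id)
      rsite <- as.character(Biostrings::reverseComplement(
        Biostrings::DNAString(a$rev)))
      if (count_hits(rsite, s) != as.integer(a$gene == parts[1]))
        .stop_cls("construction_error",
                  "spurious/missing rev site for %s in %s", ak, id)
    }
    for (g in names(enzyme)) {
      expected <- as.integer(g == parts[1] && parts[3] == "Lg")
      if (count_hits(enzyme[[g]]$site, s, fixed = FALSE) != expected)
        .stop_cls("construction_error",
                  "spurious/missing %s enzyme site in %s", g, id)
    }
    tr <- translate_cds(s)
    if (!tr$stopped || nchar(tr$peptide) * 3 + 3 != nchar(s))
      .stop_cls("construction_error", "premature stop codon in %s", id)
  }
  invisible(TRUE)
}

#' Simulate a densitometry table from a known transcript composition
#'
#' Inverse of [quantify_profile()]: per replicate and per (gene, exon)
#' reaction, the Sh and Lg components of the transcript pair are rendered
#' as band intensities proportional to `epsilon * proportion * ef1a`, each
#' multiplied by independent lognormal noise `exp(N(0, sigma^2))`. The
#' cut C-terminal class is split over two cut-fragment bands (fixed 60/40
#' upper/lower split); the uncut class forms the uncut band. With
#' `noise_sigma = 0` the quantification stage recovers the truth exactly.
#'
#' @param truth Named 8-vector of transcript proportions summing to 1
#'   (names `gene|exon|cterm`).
#' @param config A [sim_config()]; `epsilons`, `noise_sigma`,
#'   `n_replicates` and `seed` are used.
#' @param cut_class C-terminal class the enzyme cuts (default `"Lg"`).
#' @param tissue,timepoint Metadata stamped on every row.
#' @return Densitometry data.frame in the dialect [quantify_profile()]
#'   reads.
#' @export
gen_gel_dataset <- function(truth = NULL, config = sim_config(),
                            cut_class = "Lg",
                            tissue = "whole_embryo", timepoint = "6hpf") {
  if (is.null(truth)) truth <- config$truth_profile
  if (abs(sum(truth) - 1) > 1e-9 || any(truth < 0))
    .stop_cls("profile_error", "truth must be 8 proportions summing to 1")
  keys <- variant_keys()
  ids <- .variant_id(keys$gene, keys$exon, keys$cterm)
  if (!setequal(names(truth), ids))
    .stop_cls("profile_error", "truth names must be the 8 variant ids")
  other_class <- setdiff(.cterms, cut_class)
  .set_substream(config$seed, 101L)
  ef1a <- 1000
  rows <- list()
  for (r in seq_len(config$n_replicates)) {
    sample_id <- sprintf("%s_%s_rep%02d", tissue, timepoint, r)
    for (g in .genes) for (x in .exons) {
      eps <- config$epsilons[[paste(g, x, sep = "|")]]
      p_cut <- truth[[.variant_id(g, x, cut_class)]]
      p_uncut <- truth[[.variant_id(g, x, other_class)]]
      noise <- exp(rnorm(3, 0, config$noise_sigma))
      base <- eps * ef1a
      band <- c("uncut", "cut_upper", "cut_lower")
      inten <- c(base * p_uncut * noise[1],
                 base * p_cut * 0.6 * noise[2],
                 base * p_cut * 0.4 * noise[3])
      rows[[length(rows) + 1]] <- data.frame(
        sample_id = sample_id, tissue = tissue, timepoint = timepoint,
        gene = g, exon = x, band = band, intensity = inten,
        ef1a = ef1a, replicate = r, stringsAsFactors = FALSE)
    }
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Simulate cardiomyocyte migration tracks
#'
#' Biased random walk towards a fixed target: per frame of length
#' `frame_interval`, the step is
#' `speed_factor * (drift * dt * unit(target - pos) + N(0, sigma^2 * dt))`
#' on each axis, with `speed_factor = 1` for the control group and
#' `mutant_speed_factor` for mutants. The factor scales the whole step --
#' directed and random components alike -- so mutant cells are slower but
#' exactly as directional as controls (the wandering index distribution
#' is unchanged), the pattern reported for jnk1-deficient cardiomyocytes.
#'
#' @param config A [sim_config()].
#' @param group `"control"` or `"mutant"`.
#' @return data.frame `track_id`, `t`, `x`, `y` (minutes / micrometres).
#' @export
gen_tracks <- function(config = sim_config(),
                       group = c("control", "mutant")) {
  group <- match.arg(group)
  factor <- if (group == "mutant") config$mutant_speed_factor else 1
  .set_substream(config$seed, if (group == "control") 211L else 223L)
  dt <- config$frame_interval
  n_steps <- floor(config$duration / dt)
  target <- c(0, 0)
  rows <- lapply(seq_len(config$n_tracks), function(k) {
    # start positions on a ring 150-250 um from the target
    ang <- stats::runif(1, 0, 2 * pi)
    rad <- stats::runif(1, 150, 250)
    pos <- matrix(NA_real_, n_steps + 1, 2)
    pos[1, ] <- rad * c(cos(ang), sin(ang))
    for (i in seq_len(n_steps)) {
      d <- target - pos[i, ]
      nd <- sqrt(sum(d^2))
      u <- if (nd > 0) d / nd else c(0, 0)
      pos[i + 1, ] <- pos[i, ] +
        factor * (config$drift * dt * u + rnorm(2, 0, config$sigma * sqrt(dt)))
    }
    data.frame(track_id = sprintf("%s_%03d", group, k),
               t = dt * (0:n_steps), x = pos[, 1], y = pos[, 2],
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Simulate marker-labelled nuclei fields
#'
#' Ventricular cardiomyocyte nuclei (Mef2+, S46-) are drawn from
#' `Poisson(lambda_vent)`, reduced by `ventricular_reduction` in the
#' mutant group; atrial nuclei (Mef2+, S46+) from `Poisson(lambda_atr)`
#' in both groups (atrial numbers are unaffected by the mutation). Points
#' are placed in disjoint half-planes (ventricle x < 0, atrium x > 0).
#'
#' @param config A [sim_config()].
#' @param group `"control"` or `"mutant"`.
#' @param n_fields Number of fields (default `config$n_fields`).
#' @return List of data.frames, one per field, columns `x`, `y`, `mef2`,
#'   `s46`, `marker`.
#' @export
gen_nuclei_fields <- function(config = sim_config(),
                              group = c("control", "mutant"),
                              n_fields = config$n_fields) {
  group <- match.arg(group)
  lam_v <- config$lambda_vent *
    (1 - if (group == "mutant") config$ventricular_reduction else 0)
  .set_substream(config$seed, if (group == "control") 307L else 311L)
  lapply(seq_len(n_fields), function(k) {
    nv <- rpois(1, lam_v)
    na_ <- rpois(1, config$lambda_atr)
    data.frame(
      x = c(stats::runif(nv, -100, -5), stats::runif(na_, 5, 100)),
      y = stats::runif(nv + na_, -50, 50),
      mef2 = TRUE,
      s46 = c(rep(FALSE, nv), rep(TRUE, na_)),
      marker = FALSE,
      stringsAsFactors = FALSE)
  })
}

#' Simulate a ventricular diameter trace (and optional disc stack)
#'
#' `diameter(t) = ds + (dd - ds) * (1 + cos(2 * pi * rate * t)) / 2`
#' plus optional Gaussian noise, sampled at `frame_rate`. With
#' `as_stack = TRUE` a movie is rendered as well: each frame is a filled
#' disc of the corresponding diameter centred in a square image, the
#' input expected by [reslice_mmode()].
#'
#' @param config A [sim_config()].
#' @param as_stack Also render the disc movie.
#' @param img_size Square image edge (pixels) for the rendered stack.
#' @return List with `t` (seconds), `diameter` (micrometres),
#'   `frame_rate`, and (if requested) `stack` `[frame, row, col]`.
#' @export
gen_contraction_trace <- function(config = sim_config(), as_stack = FALSE,
                                  img_size = 128) {
  .set_substream(config$seed, 401L)
  t <- seq(0, config$trace_duration, by = 1 / config$frame_rate)
  d <- config$ds + (config$dd - config$ds) *
    (1 + cos(2 * pi * config$rate * t)) / 2
  if (config$trace_noise > 0)
    d <- pmax(d + rnorm(length(d), 0, config$trace_noise), 1e-6)
  out <- list(t = t, diameter = d, frame_rate = config$frame_rate)
  if (as_stack) {
    ctr <- (img_size + 1) / 2
    gx <- matrix(rep(seq_len(img_size), each = img_size), img_size)
    gy <- t(gx)
    dist2 <- (gx - ctr)^2 + (gy - ctr)^2
    stack <- array(0, dim = c(length(t), img_size, img_size))
    for (f in seq_along(t)) {
      # scale diameters into the image so the largest disc fits
      r_px <- d[f] / config$dd * (img_size * 0.45)
      stack[f, , ] <- as.numeric(dist2 <= r_px^2)
    }
    out$stack <- stack
  }
  out
}
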