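#' Saturating exponential PCR amplification
#'
#' Product amount after `c` cycles of amplification with per-cycle gain `e`
#' from initial template `n0`, capped at plateau `P`:
#' `min(n0 * (1 + e)^c, P)`. Below the plateau the product is exactly
#' linear in the starting template, which is the regime the
#' semi-quantitative gel assay relies on.
#'
#' @param n0 Initial template amount (arbitrary units, >= 0).
#' @param efficiency Per-cycle gain in `[0, 1]`.
#' @param cycles Integer number of cycles.
#' @param plateau Saturation cap (default `Inf`).
#' @return Product amount (arbitrary units).
#' @export
#' @examples
#' simulate_amplification(1, 1, 10)         # 2^10 = 1024
#' simulate_amplification(1, 1, 10, 100)    # capped at plateau
simulate_amplification <- function(n0, efficiency, cycles, plateau = Inf) {
  stopifnot(n0 >= 0, efficiency >= 0, efficiency <= 1,
            cycles >= 0, plateau > 0)
  pmin(n0 * (1 + efficiency)^cycles, plateau)
}

#' Check that a dilution series sits in the linear phase
#'
#' Least-squares fit of `log(intensity)` on `log(template)` over a template
#' dilution series. The assay is judged to be in the linear phase when the
#' fit is tight and the slope is close to one (product proportional to
#' starting template).
#'
#' @param template Relative template amounts (strictly positive, distinct).
#' @param intensity Measured band intensities (strictly positive).
#' @param r2_min Minimum r-squared (default 0.98).
#' @param slope_tol Maximum `|slope - 1|` (default 0.15).
#' @return List with `slope`, `r2`, `pass`.
#' @export
#' @examples
#' check_linear_phase(c(1, 2, 4), c(10, 20, 40))  # slope 1, pass
check_linear_phase <- function(template, intensity,
                               r2_min = 0.98, slope_tol = 0.15) {
  if (length(template) < 3)
    .stop_cls("insufficient_data", "need at least 3 dilution points")
  stopifnot(length(template) == length(intensity),
            all(template > 0), all(intensity > 0),
            !anyDuplicated(template))
  fit <- lm(log(intensity) ~ log(template))
  slope <- unname(coef(fit)[2])
  # summary.lm warns on the degenerate zero-residual (saturated) case,
  # which is handled explicitly below
  r2 <- suppressWarnings(summary(fit)$r.squared)
  # a perfectly flat series fits perfectly with slope 0; r2 is NaN then
  if (is.nan(r2)) r2 <- 1
  if (is.na(slope)) slope <- 0
  list(slope = slope, r2 = r2,
       pass = r2 >= r2_min && abs(slope - 1) <= slope_tol)
}

#' Relative PCR efficiency from equimolar plasmid standards
#'
#' Yields measured on equimolar full-length plasmid templates are converted
#' to dimensionless per-reaction factors relative to a designated reference
#' reaction (which gets epsilon = 1).
#'
#' @param yields Named numeric vector of reaction yields, names
#'   `gene|exon`.
#' @param reference Name of the reference reaction (default: first).
#' @return A data.frame `gene`, `exon`, `epsilon`.
#' @export
calibrate_efficiency <- function(yields, reference = names(yields)[1]) {
  stopifnot(is.numeric(yields), !is.null(names(yields)), all(yields > 0),
            reference %in% names(yields))
  eps <- yields / yields[[reference]]
  parts <- do.call(rbind, strsplit(names(yields), "|", fixed = TRUE))
  data.frame(gene = parts[, 1], exon = parts[, 2],
             epsilon = unname(eps), stringsAsFactors = FALSE)
}

.calib_lookup <- function(calib) {
  stopifnot(all(c("gene", "exon", "epsilon") %in% names(calib)),
            all(calib$epsilon > 0))
  setNames(calib$epsilon, paste(calib$gene, calib$exon, sep = "|"))
}

#' Estimate the eight-way transcript proportion profile
#'
#' Turns a densitometry table into per-sample transcript proportions. Per
#' (sample, gene, exon) reaction lane the digested-aliquot band intensities
#' give a lane total and a cut fraction; the lane abundance is
#' `A = (lane_total / ef1a) / epsilon` (housekeeping normalisation then
#' efficiency correction), the C-terminal class cut by the enzyme receives
#' `f_cut * A` and the other class `(1 - f_cut) * A`; the eight abundances
#' are finally renormalised to sum to one per sample.
#'
#' @param dens Densitometry data.frame with columns `sample_id`, `tissue`,
#'   `timepoint`, `gene`, `exon`, `band` (`uncut`, `cut_upper`,
#'   `cut_lower`), `intensity`, `ef1a`, `replicate`.
#' @param calib Calibration data.frame `gene`, `exon`, `epsilon` covering
#'   all four reactions.
#' @param cut_class Which C-terminal class the diagnostic enzyme cuts
#'   (`"Lg"` default, or `"Sh"`).
#' @return A data.frame, one row per sample x transcript: `sample_id`,
#'   `tissue`, `timepoint`, `replicate`, `gene`, `exon`, `cterm`,
#'   `proportion`. Proportions sum to 1 within each sample.
#' @export
quantify_profile <- function(dens, calib, cut_class = c("Lg", "Sh")) {
  cut_class <- match.arg(cut_class)
  other_class <- setdiff(.cterms, cut_class)
  req <- c("sample_id", "tissue", "timepoint", "gene", "exon", "band",
           "intensity", "ef1a", "replicate")
  if (!all(req %in% names(dens)))
    .stop_cls("dialect_error", "densitometry table missing columns: %s",
              paste(setdiff(req, names(dens)), collapse = ", "))
  if (any(dens$intensity < 0)) .stop_cls("invalid_intensity",
                                         "negative intensity")
  if (any(dens$ef1a <= 0)) .stop_cls("invalid_intensity",
                                     "ef1a intensity must be positive")
  eps <- .calib_lookup(calib)
  reactions <- paste(rep(.genes, each = 2), .exons, sep = "|")
  if (!all(reactions %in% names(eps)))
    .stop_cls("incomplete_calibration", "calibration missing reactions: %s",
              paste(setdiff(reactions, names(eps)), collapse = ", "))
  out <- lapply(split(dens, dens$sample_id), function(d) {
    abund <- numeric(0)
    for (g in .genes) for (x in .exons) {
      lane <- d[d$gene == g & d$exon == x, ]
      if (nrow(lane) == 0 || !"uncut" %in% lane$band)
        .stop_cls("incomplete_sample",
                  "sample %s lacks reaction %s %s", d$sample_id[1], g, x)
      total <- sum(lane$intensity)
      if (total <= 0)
        .stop_cls("degenerate_sample",
                  "sample %s reaction %s %s has zero total intensity",
                  d$sample_id[1], g, x)
      f_cut <- sum(lane$intensity[lane$band != "uncut"]) / total
      A <- (total / lane$ef1a[1]) / eps[[paste(g, x, sep = "|")]]
      abund[.variant_id(g, x, cut_class)] <- f_cut * A
      abund[.variant_id(g, x, other_class)] <- (1 - f_cut) * A
    }
    keys <- variant_keys()
    p <- abund[.variant_id(keys$gene, keys$exon, keys$cterm)]
    data.frame(sample_id = d$sample_id[1], tissue = d$tissue[1],
               timepoint = d$timepoint[1], replicate = d$replicate[1],
               keys, proportion = unname(p / sum(p)),
               stringsAsFactors = FALSE, row.names = NULL)
  })
  out <- do.call(rbind, out)
  rownames(out) <- NULL
  out
}

.sem <- function(x) if (length(x) > 1) sd(x) / sqrt(length(x)) else NA_real_

#' Summarise transcript proportion profiles across replicates
#'
#' Aggregates per-sample profiles within each (tissue, timepoint) group:
#' per-gene shares (summed over exon and C-terminal class), the Lg share
#' within each gene, and per-transcript means, each computed per replicate
#' and then averaged (mean and SEM across replicates).
#'
#' @param profiles Output of [quantify_profile()], possibly several
#'   timepoints/tissues row-bound together.
#' @return A list of data.frames: `gene_share` (`tissue`, `timepoint`,
#'   `gene`, `mean`, `sem`, `n`), `lg_share` (same keys; share of Lg within
#'   each gene's transcripts), `transcripts` (per transcript mean and SEM).
#' @export
summarize_profile <- function(profiles) {
  if (is.null(profiles) || nrow(profiles) == 0)
    .stop_cls("empty_input", "no profiles to summarise")
  grp <- interaction(profiles$tissue, profiles$timepoint, drop = TRUE)
  agg <- function(per_sample_fun) {
    do.call(rbind, lapply(split(profiles, grp), per_sample_fun))
  }
  gene_share <- agg(function(g) {
    per <- lapply(split(g, g$sample_id), function(s)
      vapply(split(s$proportion, s$gene), sum, numeric(1)))
    m <- do.call(rbind, per)
    data.frame(tissue = g$tissue[1], timepoint = g$timepoint[1],
               gene = colnames(m), mean = colMeans(m),
               sem = apply(m, 2, .sem), n = nrow(m),
               stringsAsFactors = FALSE, row.names = NULL)
  })
  lg_share <- agg(function(g) {
    per <- lapply(split(g, g$sample_id), function(s) {
      vapply(split(s, s$gene), function(sg)
        sum(sg$proportion[sg$cterm == "Lg"]) / sum(sg$proportion),
        numeric(1))
    })
    m <- do.call(rbind, per)
    data.frame(tissue = g$tissue[1], timepoint = g$timepoint[1],
               gene = colnames(m), mean = colMeans(m),
               sem = apply(m, 2, .sem), n = nrow(m),
               stringsAsFactors = FALSE, row.names = NULL)
  })
  transcripts <- agg(function(g) {
    per <- do.call(rbind, lapply(split(g, g$sample_id), function(s)
      setNames(s$proportion, .variant_id(s$gene, s$exon, s$cterm))))
    keys <- variant_keys()
    ord <- .variant_id(keys$gene, keys$exon, keys$cterm)
    data.frame(tissue = g$tissue[1], timepoint = g$timepoint[1], keys,
               mean = colMeans(per[, ord, drop = FALSE]),
               sem = apply(per[, ord, drop = FALSE], 2, .sem),
               n = nrow(per), stringsAsFactors = FALSE, row.names = NULL)
  })
  rownames(gene_share) <- rownames(lg_share) <- rownames(transcripts) <- NULL
  list(gene_share = gene_share, lg_share = lg_share,
       transcripts = transcripts)
}
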