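---
title: "Methods: the splicing assay model and cardiac phenotyping metrics"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: the splicing assay model and cardiac phenotyping metrics}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(splicecard)
```

# Background

Zebrafish carry two paralogs of the single human *JNK1* gene, *jnk1a* and
*jnk1b*. Each produces four transcripts by mutually exclusive use of the
central exons 7 and 8 (human 6a/6b) combined with a short (Sh) or long (Lg)
C-terminal extension (human p46/p54), giving an eight-way transcript space.
The relative abundance of these transcripts shifts during development and
differs between the whole embryo and the heart, and specific variants are
required for formation of the first-heart-field-derived part of the
ventricle. splicecard implements the quantitative machinery around those
observations: the molecular readout of the semi-quantitative RT-PCR
splicing assay, the densitometry arithmetic that converts gel bands into
transcript proportions, and the metrics used to phenotype the embryonic
heart (cardiomyocyte migration tracks, chamber-resolved nuclei counts,
M-mode contraction traces, expression-field areas).

Because no machine-readable data accompany the original observations,
every pipeline input can be simulated by a seeded generator with the
statistical structure the analysis assumes. The generators are first-class,
tested code: each one is exactly inverted by its paired analysis stage when
its noise is switched off, which is the backbone of the test suite.

# The splicing assay

## Molecular model

Each assay reaction is a forward primer specific for one gene and one
alternative exon, a gene-specific common reverse primer, and a diagnostic
restriction enzyme that cuts only amplicons carrying the long C-terminal
extension (StyI, `CC^WWGG`, for *jnk1a*; NheI, `G^CTAGC`, for *jnk1b*).
`in_silico_pcr()` uses exact primer matching only — no mismatch or
thermodynamic model — because the assay's primers are designed for perfect
specificity and exactness keeps the prediction deterministic. Coordinates
are 0-based half-open internally and the amplicon includes both primer
footprints.

`in_silico_digest()` scans for every, possibly overlapping, IUPAC match of
the recognition site and applies a cut at each match start plus the
enzyme's cut offset. This models complete digestion: all sites present in
the intact molecule are cut, and fragment lengths always sum to the input
length. Cut positions falling on a sequence boundary are no-ops rather
than empty fragments.

Which C-terminal class carries the diagnostic site is a parameter
(`cut_class`), not an assumption: the assay design only requires that the
digest separates the two classes. The synthetic transcript set places the
site in the Lg tails, and `quantify_profile(cut_class = "Lg")` mirrors
that; nothing in the package asserts the polarity of the real assay.

`compare_peptides()` classifies aligned residue columns as identical,
favourable (substitution-matrix score > 0) or divergent (score <= 0),
with BLOSUM62 as the default matrix. A positive-score criterion is the
conventional reading of "favourable substitution"; the matrix and gap
scores (-11/-1) are configurable. The bundled C-terminal extension pair in
`cterm_extension_fixture()` is a synthetic reconstruction engineered to
the documented divergence structure (9 divergent substitutions over 39
aligned residues plus one inserted threonine); the real peptide sequences
are published only as supplementary figures.

## Quantification model

The assay is semi-quantitative: products are measured inside the linear
phase of PCR, where the product is proportional to the starting template.
`simulate_amplification()` is the saturating exponential
`min(n0 (1+e)^c, P)`, and `check_linear_phase()` validates a dilution
series by regressing log intensity on log template; the defaults
(r² >= 0.98, |slope − 1| <= 0.15) are configurable because no numeric
criterion is standard.

No published equation exists for the normalisation, so the package adopts
the simplest model consistent with "normalise to the housekeeping ef1α
band and correct for reaction efficiency":

* lane abundance `A = (lane_total / ef1a) / epsilon`, with `epsilon` a
  single multiplicative yield factor per reaction measured from equimolar
  plasmid standards (`calibrate_efficiency()`, reference reaction = 1);
* cut fraction `f_cut` = cut-band intensity over lane total, so the cut
  class receives `f_cut * A` and the uncut class `(1 − f_cut) * A`;
* the eight abundances are renormalised to sum to one per sample.

Two consequences are load-bearing and tested: profiles are invariant to
any common rescaling of a sample's intensities and its ef1α value, and
doubling one reaction's `epsilon` halves that reaction's
pre-renormalisation abundance.

Replicate aggregation in `summarize_profile()` is per-replicate-then-
average (mean ± SEM across biological replicate clutches, n = 6–8 in the
study design), not pooled-intensity: each clutch is an independent
biological unit and pooling would weight clutches by their arbitrary
loading. ef1α is treated as per-sample, not per-run.

## Densitometry noise model

`gen_gel_dataset()` renders a known truth profile into band intensities
with independent lognormal noise `exp(N(0, sigma^2))` per band, default
`sigma = 0.15`. Band intensities are positive and error sources
(pipetting, staining, exposure) act multiplicatively, which makes the
lognormal the natural first choice. The bundled truth profiles
(`truth_profiles()`) encode the two benchmark compositions — 80% of jnk1
transcripts from *jnk1a* before gastrulation, 80% from *jnk1b* at 120
hpf — with within-gene splits following the described qualitative pattern
(roughly even exon 7/8 use in *jnk1a*; *jnk1b* dominated by Ex8 early and
shifting to Ex7 late). They are labelled reconstructions, not data.

What the generator does **not** emulate: gel image formation (lane
segmentation happens upstream, in Fiji, in the real workflow), partial
digestion, primer cross-reactivity, and heteroduplex artefacts. Passing
tests therefore demonstrate that the quantification arithmetic is correct
and well-conditioned under realistic multiplicative noise — not that the
wet-lab assay is free of those artefacts.

# Cardiac phenotyping metrics

## Track statistics

For a track sampled at times `t_1 < ... < t_n`:

* mean speed `S` = total path length / `(t_n − t_1)`,
* mean velocity `V` = net displacement / `(t_n − t_1)`,
* wandering index `W = S / V`.

Two deliberate literalisms: the denominator is elapsed time, not the
number of steps, and `W` is speed over velocity — so `W >= 1`, with 1 a
perfectly straight path — even though the meandering index common in the
migration literature is the reciprocal. Both follow the protocol the
metrics reproduce; the reciprocal is `1 / W` if needed. A closed track has
`V = 0` and an undefined `W`, reported as a flag with `S` still returned.
Units are micrometres and minutes, with a 6-minute frame interval over the
two-hour mid-somitogenesis imaging window as the generator default.

The track generator is a biased random walk towards a fixed target. The
mutant condition multiplies the *entire* step — directed and diffusive
components alike — by `mutant_speed_factor` (default 0.6). Scaling only
the drift would slow mutants but also make their paths relatively more
tortuous, raising `W`; scaling the whole step reproduces the reported
phenotype exactly: slower migration with unchanged directionality, i.e.
the `W` distribution is identical between groups by construction.

## Chamber counts and labelled fractions

Mef2 labels all cardiomyocyte nuclei; S46 co-labelling marks atrial
cardiomyocytes. `count_chambers()` therefore counts Mef2+S46− as
ventricular and Mef2+S46+ as atrial — a co-labelled nucleus is atrial,
never ventricular — and ignores S46-only points. `labeled_fraction()`
generalises to BrdU/TUNEL indices as `count(mef2 & marker)/count(mef2)`.
The nuclei generator draws ventricular counts from
`Poisson(lambda_vent)` (default 100), reduced by 26% in mutant mode, and
atrial counts from `Poisson(lambda_atr)` (default 30) in both groups.

## M-mode and contraction metrics

`reslice_mmode()` resamples each movie frame along a fixed line at unit
spacing with bilinear interpolation, producing the kymograph
(`floor(length)+1` positions × frames). `contraction_metrics()` reduces a
ventricular diameter trace to fractional shortening
`FS = (Dd − Ds)/Dd`, with `Dd` the mean of diastolic peaks and `Ds` the
mean of the intervening systolic minima, and heart rate =
(peak count − 1) / time between first and last peak. Peak detection uses
local maxima filtered by topographic prominence (default 10% of the trace
range) and a minimum separation (default 25% of the median beat period);
the original analysis was manual, so these are the package's own
defaults, chosen to be robust for traces with mild noise, and both are
configurable. The trace generator uses a 100/60 µm diastole/systole
envelope at 2.5 Hz sampled at 127 frames/s — values in the normal range
for a 72-hpf zebrafish ventricle and the camera used in the study design.

## Expression area

`expression_area()` is pixel counting on a strictly binary mask times the
squared pixel size; masks enter as plain-text 0/1 matrices or TIFFs. Area
is reported in µm² when a pixel size is given, else in pixels².

# Numerical and design notes

* **Determinism.** Every generator is a pure function of its
  configuration and a single integer seed; per-generator substreams are
  derived from the seed by fixed offsets so generators may be called in
  any order. Same seed, byte-identical outputs.
* **Synthetic transcript construction.** Filler sequence uses only
  G-free, stop-free codons, so the G-rich primer and enzyme motifs cannot
  arise anywhere except where deliberately inserted; the constructor
  re-scans all eight sequences for spurious sites and premature stops and
  refuses to return if any is found. The jnk1a Ex8 block encodes a serine
  where jnk1b Ex8 encodes a threonine, mirroring the paralogs' single
  diagnostic Ex8 residue difference.
* **Degenerate inputs.** Flat dilution series fail the linear check with
  slope 0 rather than erroring; constant contraction traces and traces
  with fewer than two detected beats raise `insufficient_cycles`;
  zero-Mef2 fields raise `undefined_denominator`; an all-zero reaction
  lane raises `degenerate_sample`.
* **Problem sizes.** The test-suite simulations use the study-scale
  designs: 8 replicate gels, 20 nuclei fields per group, 50 tracks per
  group, 6-second traces; the digest implementation is cross-checked
  against a brute-force IUPAC scan oracle on 1,000 random sequences (up
  to 10 kb in the unit tests).
* **Tolerant reader, strict writer.** `read_table()` accepts and
  preserves unknown extra columns with a warning (hand-edited lab tables
  survive); `write_table()` refuses to write a table missing dialect
  columns. Pipeline runs write a manifest with md5 digests of every input
  and output and never overwrite without `force`.

# Limitations

The simulators establish correctness of the analysis arithmetic, not of
wet-lab steps: no gel image processing, no tracking from raw movies
(tracks enter as coordinates, as they leave manual Fiji tracking), no
image segmentation for expression masks, and no inferential statistics
beyond means, SEMs and the standard tests R already provides. The bundled
truth profiles and the C-terminal extension pair are reconstructions for
benchmarking the pipeline, clearly labelled as such, and should not be
mistaken for measured sequence or expression data.

# A worked end-to-end run

```{r pipeline, eval = FALSE}
cfg <- list(seed = 1, stages = c("transcripts", "gel", "nuclei", "trace"),
            sim = list(n_replicates = 8, noise_sigma = 0.15))
manifest <- run_pipeline(cfg, "splicecard_demo")
names(manifest$outputs)
```

The same pipeline is exposed as a thin command-line wrapper
(`system.file("cli", "splicecard.R", package = "splicecard")`) with
subcommands `run`, `digest`, `bands`, `quantify`, `linear-check`,
`tracks`, `count`, `contraction` and `area`.
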