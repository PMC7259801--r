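#' Validate a pipeline configuration
#'
#' Checks the configuration list (usually parsed from YAML) against the
#' pipeline schema. Errors name the offending field path.
#'
#' @param config Named list with at least `seed` (integer) and `stages`
#'   (character vector drawn from `"transcripts"`, `"gel"`, `"tracks"`,
#'   `"nuclei"`, `"trace"`). A `gel` stage quantifying an external
#'   densitometry file additionally needs `densitometry` and
#'   `calibration` file paths; a simulated gel stage needs neither.
#'   Generator parameters may be overridden under `sim`.
#' @return The validated config, invisibly.
#' @export
validate_config <- function(config) {
  known_stages <- c("transcripts", "gel", "tracks", "nuclei", "trace")
  if (is.null(config$seed) || !is.numeric(config$seed))
    .stop_cls("config_error", "config field `seed` must be an integer")
  if (is.null(config$stages) || !length(config$stages))
    .stop_cls("config_error", "config field `stages` must list stages")
  bad <- setdiff(config$stages, known_stages)
  if (length(bad))
    .stop_cls("config_error", "config field `stages`: unknown stage(s) %s",
              paste(bad, collapse = ", "))
  if ("gel" %in% config$stages && !is.null(config$densitometry)) {
    if (is.null(config$calibration))
      .stop_cls("config_error",
                "config field `calibration` is required when `densitometry` is given")
    for (f in c("densitometry", "calibration"))
      if (!file.exists(config[[f]]))
        .stop_cls("config_error", "config field `%s`: no such file %s",
                  f, config[[f]])
  }
  if (!is.null(config$sim) && !is.list(config$sim))
    .stop_cls("config_error", "config field `sim` must be a mapping")
  invisible(config)
}

.digest_file <- function(path) unname(tools::md5sum(path))

#' Run the configured pipeline stages
#'
#' Executes the configured simulate/quantify/phenotype stages and writes
#' every output plus a run manifest (`manifest.json`) recording the config
#' snapshot, seed, package version, and an md5 digest of every input and
#' output file. Outputs are only overwritten with `force = TRUE`.
#'
#' @param config Config list or path to a YAML file; see
#'   [validate_config()].
#' @param out_dir Output directory (created if needed).
#' @param force Overwrite existing outputs.
#' @return The manifest, invisibly.
#' @export
run_pipeline <- function(config, out_dir, force = FALSE) {
  if (is.character(config) && length(config) == 1)
    config <- yaml::read_yaml(config)
  validate_config(config)
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  sc <- do.call(sim_config,
                c(list(seed = config$seed),
                  config$sim[intersect(names(config$sim),
                                       names(formals(sim_config)))]))
  manifest <- list(tool = "splicecard",
                   version = as.character(utils::packageVersion("splicecard")),
                   seed = config$seed, config = config,
                   inputs = list(), outputs = list(), stages = list())
  emit <- function(writer, name) {
    path <- file.path(out_dir, name)
    if (file.exists(path) && !force)
      .stop_cls("overwrite_error",
                "output %s exists; use force = TRUE to overwrite", path)
    writer(path)
    manifest$outputs[[name]] <<- .digest_file(path)
    path
  }
  for (stage in config$stages) {
    switch(stage,
      transcripts = {
        ts <- gen_transcript_set(sc)
        emit(function(p) write_fasta(ts$variants, p, "dna"),
             "transcripts.fasta")
        emit(function(p) write_table(predict_assay_bands(ts$variants,
                                                         ts$assays),
                                     p, "bands"), "bands.tsv")
      },
      gel = {
        if (!is.null(config$densitometry)) {
          dens <- read_table(config$densitometry, "densitometry")
          calib <- read_table(config$calibration, "calibration")
          manifest$inputs[[config$densitometry]] <-
            .digest_file(config$densitometry)
          manifest$inputs[[config$calibration]] <-
            .digest_file(config$calibration)
        } else {
          dens <- gen_gel_dataset(config = sc)
          calib <- data.frame(gene = rep(.genes, each = 2),
                              exon = rep(.exons, 2),
                              epsilon = unname(sc$epsilons),
                              stringsAsFactors = FALSE)
          emit(function(p) write_table(dens, p, "densitometry"),
               "densitometry.tsv")
        }
        prof <- quantify_profile(dens, calib)
        emit(function(p) write_table(prof, p, "profile"), "profile.tsv")
        summ <- summarize_profile(prof)
        emit(function(p) write.table(summ$gene_share, p, sep = "\t",
                                     quote = FALSE, row.names = FALSE),
             "gene_share.tsv")
      },
      tracks = {
        for (grp in c("control", "mutant")) {
          tr <- gen_tracks(sc, grp)
          emit(function(p) write_table(tr, p, "tracks"),
               sprintf("tracks_%s.tsv", grp))
          emit(function(p) write_table(track_metrics_table(tr), p,
                                       "track_metrics"),
               sprintf("track_metrics_%s.tsv", grp))
        }
      },
      nuclei = {
        counts <- lapply(c(control = "control", mutant = "mutant"),
          function(grp) {
            fields <- gen_nuclei_fields(sc, grp)
            do.call(rbind, lapply(seq_along(fields), function(i) {
              cc <- count_chambers(fields[[i]])
              data.frame(group = grp, field = i,
                         ventricular = cc$ventricular, atrial = cc$atrial,
                         total = cc$total, stringsAsFactors = FALSE)
            }))
          })
        counts <- do.call(rbind, counts)
        emit(function(p) write.table(counts, p, sep = "\t", quote = FALSE,
                                     row.names = FALSE), "chamber_counts.tsv")
      },
      trace = {
        tr <- gen_contraction_trace(sc)
        cm <- contraction_metrics(tr$t, tr$diameter)
        emit(function(p) write_table(
          data.frame(t = tr$t, diameter = tr$diameter), p, "trace"),
          "trace.tsv")
        emit(function(p) write.table(
          data.frame(fractional_shortening = cm$fractional_shortening,
                     heart_rate_bpm = cm$heart_rate_bpm,
                     n_beats = cm$n_beats),
          p, sep = "\t", quote = FALSE, row.names = FALSE),
          "contraction_metrics.tsv")
      })
    manifest$stages[[stage]] <- "ok"
  }
  manifest_path <- file.path(out_dir, "manifest.json")
  jsonlite::write_json(manifest, manifest_path, auto_unbox = TRUE,
                       pretty = TRUE, digits = NA)
  invisible(manifest)
}
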