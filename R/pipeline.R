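#' Assemble a pipeline configuration
#'
#' A plain list validated for the end-to-end run: either a `simulate` block
#' (arguments for [generate_study()]) or an `inputs` block naming TSV files
#' on disk, plus analysis thresholds and an output directory.
#'
#' @param simulate named list of [generate_study()] arguments (optional).
#' @param inputs named list of file paths produced by [write_study()]
#'   (optional; ignored when `simulate` is given).
#' @param fc_threshold linear fold-change cutoff for responsiveness
#'   (default 1.75).
#' @param rsq_threshold goodness-of-fit cutoff for decay fits (default 0.9).
#' @param hl_threshold linear stability-change cutoff (default 1.5).
#' @param k number of clusters (default 3).
#' @param reference one of `"shared"` (normalize every decay course to the
#'   single wild-type reference profile, the study's own procedure),
#'   `"matched"` (each course to its own genome-mean truth profile;
#'   simulation only) or a path to a two-column TSV profile.
#' @param seed integer seed (overrides `simulate$seed`).
#' @param out_dir output directory (`NULL` = return results only).
#' @return A validated list of class `pipeline_config`.
#' @export
pipeline_config <- function(simulate = list(), inputs = NULL,
                            fc_threshold = 1.75, rsq_threshold = 0.9,
                            hl_threshold = 1.5, k = 3,
                            reference = "shared", seed = 1,
                            out_dir = NULL) {
  stopifnot(fc_threshold > 0, rsq_threshold >= 0, hl_threshold > 0, k >= 1)
  if (is.null(simulate) && is.null(inputs))
    stop("either a simulate block or an inputs block is required")
  if (!is.null(inputs)) {
    missing <- unlist(inputs)[!file.exists(unlist(inputs))]
    if (length(missing))
      stop("missing input file(s): ", paste(missing, collapse = ", "))
  }
  structure(list(simulate = simulate, inputs = inputs,
                 fc_threshold = fc_threshold,
                 rsq_threshold = rsq_threshold,
                 hl_threshold = hl_threshold, k = k,
                 reference = reference, seed = seed, out_dir = out_dir),
            class = "pipeline_config")
}

#' Read a pipeline configuration from a YAML file
#' @param path YAML file with keys mirroring [pipeline_config()].
#' @return A `pipeline_config`.
#' @export
read_pipeline_config <- function(path) {
  do.call(pipeline_config, yaml::read_yaml(path))
}

#' Run the full analysis pipeline
#'
#' Executes simulate (or ingest) -> normalize -> half-life fitting ->
#' response profiling -> coupling statistics -> clustering, and writes all
#' tables plus a JSON manifest when `out_dir` is set. Rerunning with an
#' identical configuration and seed reproduces every number exactly.
#'
#' @param config a [pipeline_config()] (or a YAML path understood by
#'   [read_pipeline_config()]).
#' @return A list of class `pipeline_result` with elements `study`,
#'   `halflives`, `stability`, `responses`, `coupling`, `enrichment`,
#'   `basal`, `clusters`, `cluster_slopes` and `manifest`.
#' @export
run_all <- function(config = pipeline_config()) {
  if (is.character(config)) config <- read_pipeline_config(config)
  stopifnot(inherits(config, "pipeline_config"))
  stage <- "simulate"
  res <- tryCatch({
    study <- if (!is.null(config$simulate) && is.null(config$inputs)) {
      args <- config$simulate
      args$seed <- config$seed
      do.call(generate_study, args)
    } else read_study(config$inputs)

    stage <- "normalize"
    decay_keys <- grep("decay", names(study$observed), value = TRUE)
    normalized <- lapply(decay_keys, function(key) {
      ref <- switch(config$reference,
                    shared = study$reference_profile,
                    matched = study$matched_profiles[[key]],
                    read_reference_profile(config$reference))
      zero_transform(reference_scale(study$observed[[key]], ref))
    })
    names(normalized) <- decay_keys

    stage <- "fit-halflives"
    halflives <- lapply(normalized, fit_halflives,
                        threshold = config$rsq_threshold)
    stability <- list(
      wild_type = stability_change(
        filter_fits(halflives[["wild_type.reference_decay"]],
                    config$rsq_threshold),
        filter_fits(halflives[["wild_type.stress_decay"]],
                    config$rsq_threshold)),
      mutant = stability_change(
        filter_fits(halflives[["mutant.reference_decay"]],
                    config$rsq_threshold),
        filter_fits(halflives[["mutant.stress_decay"]],
                    config$rsq_threshold)))

    stage <- "respond"
    ab <- list(wild_type = zero_transform(
                 study$observed[["wild_type.stress_abundance"]]),
               mutant = zero_transform(
                 study$observed[["mutant.stress_abundance"]]))
    responses <- lapply(ab, profile_responses,
                        fc_threshold = config$fc_threshold)

    stage <- "couple"
    coupling <- list(); enrichment <- list()
    for (st in c("wild_type", "mutant")) {
      merged <- merge(stability[[st]], responses[[st]],
                      by = "gene_id")
      coupling[[st]] <- coupling_fit(merged$delta, merged$max_fc)
      labels <- classify_changes(merged$max_fc, merged$delta,
                                 config$fc_threshold, config$hl_threshold)
      enrichment[[st]] <- fold_enrichment(labels)
    }
    basal <- basal_comparison(
      spike_in_t0(study, "wild_type"), spike_in_t0(study, "mutant"),
      filter_fits(halflives[["wild_type.reference_decay"]],
                  config$rsq_threshold),
      filter_fits(halflives[["mutant.reference_decay"]],
                  config$rsq_threshold),
      gene_ids = rownames(study$observed[["wild_type.reference_decay"]]))

    stage <- "cluster"
    responsive <- responses$wild_type$gene_id[responses$wild_type$responsive]
    clusters <- cluster_profiles(ab$wild_type, ab$mutant,
                                 responsive = responsive, k = config$k)
    slopes <- cluster_stability_slopes(clusters, stability$wild_type,
                                       stability$mutant)

    list(study = study, normalized = normalized, halflives = halflives,
         stability = stability, responses = responses, coupling = coupling,
         enrichment = enrichment, basal = basal, clusters = clusters,
         cluster_slopes = slopes)
  }, error = function(e)
    stop(sprintf("pipeline stage '%s' failed: %s", stage,
                 conditionMessage(e)), call. = FALSE))

  res$manifest <- list(seed = config$seed,
                       thresholds = config[c("fc_threshold", "rsq_threshold",
                                             "hl_threshold", "k")],
                       reference = config$reference,
                       config_hash = config_hash(config))
  class(res) <- "pipeline_result"
  if (!is.null(config$out_dir)) write_pipeline_result(res, config$out_dir)
  res
}

# spike-in-normalized time-zero intensities of a strain's reference decay
spike_in_t0 <- function(study, strain) {
  key <- paste0(strain, ".reference_decay")
  t0 <- unclass(study$observed[[key]])[, 1]
  spike <- study$spike_ins[[key]]
  ref_level <- study$obs_params$spike_in_level
  if (is.null(ref_level)) ref_level <- spike[1]
  drop(spike_in_normalize(t0, spike[1], reference_level = ref_level))
}

config_hash <- function(config) {
  tmp <- tempfile()
  on.exit(unlink(tmp))
  saveRDS(config[setdiff(names(config), "out_dir")], tmp)
  unname(tools::md5sum(tmp))
}

# read a study bundle back from an inputs block (paths as in write_study)
read_study <- function(inputs) {
  manifest <- jsonlite::read_json(inputs$manifest)
  dir <- dirname(inputs$manifest)
  observed <- list(); truth_matrices <- list()
  for (fn in names(manifest$files)) {
    info <- manifest$files[[fn]]
    if (!info$kind %in% c("observed", "truth")) next
    em <- read_expression_tsv(file.path(dir, fn))
    key <- sub("\\.tsv$", "", sub("^(observed|truth)\\.", "", fn))
    if (info$kind == "observed") observed[[key]] <- em
    else truth_matrices[[key]] <- em
  }
  spikes <- utils::read.delim(file.path(dir, "spike_ins.tsv"))
  spike_ins <- split(spikes$value, spikes$experiment)
  truth <- utils::read.delim(file.path(dir, "truth_halflives.tsv"))
  matched <- lapply(truth_matrices[grep("decay", names(truth_matrices))],
                    function(em) reference_profile(em_times(em), colMeans(em)))
  list(observed = observed, truth_matrices = truth_matrices,
       spike_ins = spike_ins, truth = truth,
       reference_profile = read_reference_profile(
         file.path(dir, "reference_profile.tsv")),
       matched_profiles = matched,
       obs_params = NULL, seed = manifest$seed)
}

#' Write a pipeline result bundle to disk
#' @param res a `pipeline_result`.
#' @param dir output directory.
#' @return The manifest path, invisibly.
#' @export
write_pipeline_result <- function(res, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  wt <- function(df, fn) utils::write.table(
    df, file.path(dir, fn), sep = "\t", quote = FALSE, row.names = FALSE)
  for (key in names(res$halflives))
    wt(res$halflives[[key]], paste0("halflives.", key, ".tsv"))
  for (st in names(res$stability))
    wt(res$stability[[st]], paste0("stability.", st, ".tsv"))
  for (st in names(res$responses))
    wt(res$responses[[st]], paste0("responses.", st, ".tsv"))
  for (st in names(res$enrichment))
    wt(res$enrichment[[st]], paste0("enrichment.", st, ".tsv"))
  wt(res$basal$table, "basal_comparison.tsv")
  wt(data.frame(gene_id = res$clusters$gene_ids,
                cluster = unname(res$clusters$assignments)),
     "clusters.tsv")
  wt(res$cluster_slopes, "cluster_slopes.tsv")
  write_dendrogram_newick(res$clusters, file.path(dir, "dendrogram.nwk"))
  summary <- list(manifest = res$manifest,
                  coupling = lapply(res$coupling, unclass),
                  basal_median_x = res$basal$median_x,
                  basal_fit = if (!is.null(res$basal$fit))
                    unclass(res$basal$fit))
  path <- file.path(dir, "summary.json")
  jsonlite::write_json(summary, path, auto_unbox = TRUE, pretty = TRUE,
                       digits = NA)
  invisible(path)
}
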