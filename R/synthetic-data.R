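#' Sample a synthetic genome of kinetic gene parameters
#'
#' Draws per-gene kinetic parameters for a genome with the given mix of
#' stress-induced, stress-neutral and stress-repressed genes. Basal
#' transcription rates are log-normal; induced/repressed stress amplitudes
#' scatter (on the log2 scale) around peak multipliers of 8 and 1/8; onset and
#' relaxation time constants vary gene to gene; imprinting affinities are
#' uniform on `[0.6, 1]`. Uses the current RNG state — call `set.seed()`
#' first for reproducibility.
#'
#' @param n_induced,n_neutral,n_repressed gene counts per stress class.
#' @param strain_recruitment Rpb4/7 recruitment efficiency `rho` (1 = wild
#'   type).
#' @param production_attenuation global multiplier on basal transcription
#'   (models the mutant's reduced synthesis; 1 = wild type).
#' @param phi_shape `"pulse"` (transient, oxidative-like stress program) or
#'   `"step"` (sustained, MMS-like).
#' @return A [gene_params()] table.
#' @export
sample_genome <- function(n_induced = 300, n_neutral = 400, n_repressed = 300,
                          strain_recruitment = 1, production_attenuation = 1,
                          phi_shape = "pulse") {
  n <- n_induced + n_neutral + n_repressed
  cls <- rep(c("induced", "neutral", "repressed"),
             c(n_induced, n_neutral, n_repressed))
  amp <- rep(1, n)
  amp[cls == "induced"] <- 8 * 2 ^ stats::rnorm(n_induced, 0, 0.5)
  amp[cls == "repressed"] <- 0.125 * 2 ^ stats::rnorm(n_repressed, 0, 0.5)
  gene_params(gene_id = sprintf("g%04d", seq_len(n)),
              beta_basal = production_attenuation *
                stats::rlnorm(n, meanlog = log(2), sdlog = 0.4),
              stress_class = cls,
              phi_amplitude = amp,
              phi_shape = phi_shape,
              phi_tau_on = stats::runif(n, 2, 4),
              phi_tau_off = stats::runif(n, 14, 24),
              affinity = stats::runif(n, 0.6, 1),
              strain_recruitment = strain_recruitment)
}

#' Observation-layer parameters
#'
#' @param noise_sd standard deviation of multiplicative log-normal
#'   measurement noise, in log2 units (default 0.15).
#' @param array_scale_factors per-time-point global multiplicative
#'   distortions; `NULL` draws them as `2^Normal(0, scale_sd^2)` per array.
#' @param scale_sd log2 spread of drawn scale factors (default 0.25).
#' @param spike_in_level true intensity of the spiked-in internal standard.
#' @param spike_in_probes number of control probes measuring the spike-in on
#'   each array; the reported spike-in value is their log-scale average, so
#'   its effective noise is `noise_sd / sqrt(spike_in_probes)` (default 96,
#'   the order of control probes on a yeast expression array).
#' @param seed random seed applied inside [observe()] (`NULL` = use the
#'   current RNG state).
#' @return A list of class `observation_params`.
#' @export
observation_params <- function(noise_sd = 0.15, array_scale_factors = NULL,
                               scale_sd = 0.25, spike_in_level = 1000,
                               spike_in_probes = 96, seed = NULL) {
  stopifnot(noise_sd >= 0, scale_sd >= 0, spike_in_level > 0,
            spike_in_probes >= 1,
            is.null(array_scale_factors) || all(array_scale_factors > 0))
  structure(list(noise_sd = noise_sd,
                 array_scale_factors = array_scale_factors,
                 scale_sd = scale_sd, spike_in_level = spike_in_level,
                 spike_in_probes = spike_in_probes,
                 seed = seed),
            class = "observation_params")
}

#' Turn true copy numbers into microarray-like intensities
#'
#' Applies, per array (time point), a global multiplicative scale distortion
#' and per-measurement multiplicative log-normal noise:
#' `value(g, t) = truth(g, t) * scale(t) * 2^eps`, `eps ~ N(0, noise_sd^2)`.
#' A spiked-in internal standard of constant true intensity is measured
#' through the same distortions.
#'
#' @param truth an `expression_matrix` of true copy numbers
#'   (`linear_intensity` scale).
#' @param params an [observation_params()] object.
#' @return A list with `matrix` (the observed `expression_matrix`),
#'   `spike_in` (one observed spike-in intensity per array) and
#'   `scale_factors` (the distortions actually applied).
#' @export
observe <- function(truth, params = observation_params()) {
  stopifnot(inherits(truth, "expression_matrix"),
            attr(truth, "scale") == "linear_intensity")
  if (!is.null(params$seed)) {
    old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
    on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
    set.seed(params$seed)
  }
  nt <- ncol(truth)
  sf <- params$array_scale_factors
  if (is.null(sf)) sf <- 2 ^ stats::rnorm(nt, 0, params$scale_sd)
  if (length(sf) != nt)
    stop("array_scale_factors length must match the number of time points")
  eps <- matrix(stats::rnorm(length(truth), 0, params$noise_sd), nrow(truth))
  values <- unclass(truth) * rep(sf, each = nrow(truth)) * 2 ^ eps
  spike <- params$spike_in_level * sf *
    2 ^ stats::rnorm(nt, 0, params$noise_sd / sqrt(params$spike_in_probes))
  list(matrix = em_update(truth, values), spike_in = spike,
       scale_factors = sf)
}

# run one scenario for one strain and wrap truth in an expression_matrix
scenario_truth_em <- function(genes, params, scenario, strain, condition,
                              arrest_delay = 7) {
  sc <- run_scenario(genes, params, scenario, arrest_delay = arrest_delay)
  em <- expression_matrix(sc$total, sc$sample_times,
                          gene_ids = genes$gene_id, strain = strain,
                          condition = condition,
                          experiment = if (scenario == "stress_abundance")
                            "abundance" else "decay",
                          scale = "linear_intensity")
  list(em = em, truth = sc$truth)
}

#' Generate the full two-strain, three-experiment study fixture
#'
#' One call produces the whole study design: for each strain (wild type and a
#' reduced-recruitment mutant) a reference decay course, a stress decay
#' course (arrest 7 min after stress) and a stress abundance course, each as
#' both noiseless truth and an observed microarray-like matrix with spike-in
#' measurements; plus ground-truth half-life tables and genome-mean reference
#' decay profiles. Decay arrays receive global scale distortions (these are
#' what reference-profile normalization must undo); abundance arrays are
#' taken as already globally normalized upstream, so only measurement noise
#' is applied there.
#'
#' @param n_induced,n_neutral,n_repressed genome composition (default
#'   300/400/300).
#' @param model_params an [imprinting_params()] object (wild-type constants;
#'   `p_basal`/`p_stress` default 0.3/0.8).
#' @param rho_mutant mutant Rpb4/7 recruitment efficiency (default 0.4).
#' @param production_attenuation mutant global transcription multiplier
#'   (default 0.7).
#' @param obs_params an [observation_params()] object.
#' @param include_mms also simulate a sustained MMS-like abundance course per
#'   strain.
#' @param seed integer seed controlling genome sampling and observation
#'   noise.
#' @param dir if non-`NULL`, write all matrices, truth tables, reference
#'   profiles and a JSON manifest to this directory as TSV/JSON.
#' @return A list of class `study_bundle`: `genes` (per-strain parameter
#'   tables), `truth` (per-gene table with stress class and true half-lives
#'   per strain/condition), `truth_matrices` and `observed` (named lists of
#'   `expression_matrix` objects), `spike_ins`, `reference_profile` (wild-type
#'   genome-mean reference-decay profile), `matched_profiles` (genome-mean
#'   profile of each decay matrix), and the parameters used.
#' @export
generate_study <- function(n_induced = 300, n_neutral = 400,
                           n_repressed = 300,
                           model_params = imprinting_params(),
                           rho_mutant = 0.4, production_attenuation = 0.7,
                           obs_params = observation_params(),
                           include_mms = FALSE, seed = 1, dir = NULL) {
  set.seed(seed)
  genes_wt <- sample_genome(n_induced, n_neutral, n_repressed)
  genes_mut <- genes_wt
  genes_mut$strain_recruitment <- rho_mutant
  # the transcription defect is strongest for the strongest Rpb4/7 clients:
  # per-gene attenuation scales with imprinting affinity, genome mean equal
  # to production_attenuation
  att <- 1 - (1 - production_attenuation) *
    genes_wt$affinity / mean(genes_wt$affinity)
  genes_mut$beta_basal <- genes_wt$beta_basal * pmax(att, 0.05)

  strains <- list(wild_type = genes_wt, mutant = genes_mut)
  scen <- c(reference_decay = "reference_decay",
            stress_decay = "stress_decay",
            stress_abundance = "stress_abundance")
  truth_matrices <- list(); observed <- list(); spike_ins <- list()
  truth <- NULL
  for (st in names(strains)) {
    for (sn in names(scen)) {
      condition <- if (sn == "reference_decay") "reference" else "oxidative"
      res <- scenario_truth_em(strains[[st]], model_params, scen[[sn]],
                               strain = st, condition = condition)
      key <- paste(st, sn, sep = ".")
      truth_matrices[[key]] <- res$em
      ob <- observe(res$em, obs_params_for(obs_params, sn))
      observed[[key]] <- ob$matrix
      spike_ins[[key]] <- ob$spike_in
      if (!is.null(res$truth$true_halflife)) {
        col <- paste0("true_halflife_",
                      if (sn == "reference_decay") "ref" else "stress",
                      "_", if (st == "wild_type") "wt" else "mut")
        if (is.null(truth))
          truth <- res$truth[c("gene_id", "stress_class")]
        truth[[col]] <- res$truth$true_halflife
      }
    }
    if (include_mms) {
      g <- strains[[st]]
      g$phi_shape <- "step"
      res <- scenario_truth_em(g, model_params, "stress_abundance",
                               strain = st, condition = "mms_like")
      key <- paste(st, "mms_abundance", sep = ".")
      truth_matrices[[key]] <- res$em
      ob <- observe(res$em, obs_params_for(obs_params, "stress_abundance"))
      observed[[key]] <- ob$matrix
      spike_ins[[key]] <- ob$spike_in
    }
  }
  matched <- lapply(truth_matrices[grep("decay", names(truth_matrices))],
                    function(em) reference_profile(em_times(em), colMeans(em)))
  bundle <- structure(list(
    genes = strains, truth = truth, truth_matrices = truth_matrices,
    observed = observed, spike_ins = spike_ins,
    reference_profile = matched[["wild_type.reference_decay"]],
    matched_profiles = matched,
    model_params = model_params, obs_params = obs_params,
    rho_mutant = rho_mutant,
    production_attenuation = production_attenuation, seed = seed),
    class = "study_bundle")
  if (!is.null(dir)) write_study(bundle, dir)
  bundle
}

# decay arrays get global scale distortions; abundance arrays are assumed
# globally normalized upstream (unit factors), noise only
obs_params_for <- function(obs, scenario) {
  if (scenario == "stress_abundance" && is.null(obs$array_scale_factors)) {
    obs$array_scale_factors <- rep(1, 7)
  }
  obs
}

#' Write a study bundle to disk
#'
#' Writes every observed and truth matrix as TSV, spike-in vectors,
#' truth table and reference profiles, plus a JSON manifest naming each file
#' with its strain/condition/experiment tags and the generation seed.
#'
#' @param bundle a `study_bundle` from [generate_study()].
#' @param dir output directory (created if needed).
#' @return The manifest path, invisibly.
#' @export
write_study <- function(bundle, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  files <- list()
  for (key in names(bundle$observed)) {
    fn <- file.path(dir, paste0("observed.", key, ".tsv"))
    write_expression_tsv(bundle$observed[[key]], fn)
    em <- bundle$observed[[key]]
    files[[basename(fn)]] <- list(kind = "observed",
                                  strain = attr(em, "strain"),
                                  condition = attr(em, "condition"),
                                  experiment = attr(em, "experiment"))
    fn2 <- file.path(dir, paste0("truth.", key, ".tsv"))
    write_expression_tsv(bundle$truth_matrices[[key]], fn2)
    files[[basename(fn2)]] <- list(kind = "truth",
                                   strain = attr(em, "strain"),
                                   condition = attr(em, "condition"),
                                   experiment = attr(em, "experiment"))
  }
  spikes <- data.frame(experiment = rep(names(bundle$spike_ins),
                                        lengths(bundle$spike_ins)),
                       value = unlist(bundle$spike_ins, use.names = FALSE))
  utils::write.table(spikes, file.path(dir, "spike_ins.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  files[["spike_ins.tsv"]] <- list(kind = "spike_ins")
  utils::write.table(bundle$truth, file.path(dir, "truth_halflives.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  files[["truth_halflives.tsv"]] <- list(kind = "truth_table")
  write_reference_profile(bundle$reference_profile,
                          file.path(dir, "reference_profile.tsv"))
  files[["reference_profile.tsv"]] <- list(kind = "reference_profile")
  manifest <- list(seed = bundle$seed,
                   rho_mutant = bundle$rho_mutant,
                   production_attenuation = bundle$production_attenuation,
                   files = files)
  path <- file.path(dir, "manifest.json")
  jsonlite::write_json(manifest, path, auto_unbox = TRUE, pretty = TRUE)
  invisible(path)
}
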