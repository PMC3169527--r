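# fixtures shared across test files; heavyweight bundles are generated once
# per test run and cached
.fixtures <- new.env(parent = emptyenv())

# the default two-strain study (1000 genes, seed 1)
default_study <- function() {
  if (is.null(.fixtures$study))
    .fixtures$study <- generate_study(seed = 1)
  .fixtures$study
}

# same study without measurement noise or array distortions
noiseless_study <- function() {
  if (is.null(.fixtures$study0))
    .fixtures$study0 <- generate_study(
      seed = 1, obs_params = observation_params(noise_sd = 0, scale_sd = 0))
  .fixtures$study0
}

# estimation chain: observed decay matrix -> normalized -> half-life records,
# each matrix normalized to its own genome-mean truth profile
est_halflives <- function(study, key, threshold = 0.9) {
  fit_halflives(zero_transform(reference_scale(
    study$observed[[key]], study$matched_profiles[[key]])),
    threshold = threshold)
}

est_stability <- function(study, strain, threshold = 0.9) {
  stability_change(
    filter_fits(est_halflives(study, paste0(strain, ".reference_decay")),
                threshold),
    filter_fits(est_halflives(study, paste0(strain, ".stress_decay")),
                threshold))
}

true_stability <- function(study, strain) {
  suf <- if (strain == "wild_type") "wt" else "mut"
  log2(study$truth[[paste0("true_halflife_stress_", suf)]] /
         study$truth[[paste0("true_halflife_ref_", suf)]])
}

# a small deterministic genome for simulator unit tests
tiny_genes <- function(n = 3, beta = 2, class = "neutral", affinity = 1,
                       rho = 1) {
  gene_params(gene_id = paste0("g", seq_len(n)), beta_basal = rep(beta, n),
              stress_class = rep(class, n), affinity = rep(affinity, n),
              strain_recruitment = rep(rho, n))
}
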