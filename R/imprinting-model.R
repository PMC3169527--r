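#' Global constants of the co-transcriptional imprinting model
#'
#' The model tracks, per gene, two cytoplasmic mRNA pools: copies imprinted
#' with the Rpb4/7 mark (`I`) and unmarked copies (`U`). A newly made
#' transcript is exported imprinted with probability
#' `q_i(t) = clip(p(t) * affinity_i * rho_i, 0, 1)` where `p(t)` jumps from
#' `p_basal` to `p_stress` at stress onset. A limited cytoplasmic decay
#' machinery of total capacity `D` (molecules/min) is recruited by imprinted
#' copies, so it distributes across genes in proportion to each gene's share
#' of the cell's imprinted transcripts, `s_i = I_i / sum(I)`; the
#' machinery-mediated decay flux of gene *i* is
#' `min(D * s_i, lambda_max * I_i)`, acting on imprinted copies only
#' (equivalently, every imprinted molecule decays at the extra rate
#' `min(D / sum(I), lambda_max)`). Both pools additionally turn over at the
#' basal first-order rate `k_U`.
#'
#' @param p_basal imprinting probability before stress (default 0.3).
#' @param p_stress imprinting probability after stress onset (default 0.8).
#' @param D total decay-machinery capacity, molecules/min.
#' @param k_U basal first-order decay rate of any molecule, 1/min.
#' @param lambda_max per-molecule cap on machinery-mediated decay, 1/min.
#' @param stress_onset time of stress onset, min (`Inf` for no stress).
#' @param dt Euler integration step, min.
#' @param t_end integration horizon, min.
#' @return A list of class `imprinting_params`.
#' @export
imprinting_params <- function(p_basal = 0.3, p_stress = 0.8,
                              D = 2000, k_U = 0.035, lambda_max = 0.008,
                              stress_onset = 0, dt = 0.05, t_end = 120) {
  stopifnot(p_basal >= 0, p_basal <= 1, p_stress >= 0, p_stress <= 1,
            D >= 0, k_U > 0, lambda_max >= 0, dt > 0, t_end > 0)
  structure(list(p_basal = p_basal, p_stress = p_stress, D = D, k_U = k_U,
                 lambda_max = lambda_max, stress_onset = stress_onset,
                 dt = dt, t_end = t_end),
            class = "imprinting_params")
}

#' Per-gene kinetic parameter table
#'
#' @param gene_id character identifiers.
#' @param beta_basal basal transcription rate, molecules/min.
#' @param stress_class `"induced"`, `"neutral"` or `"repressed"`.
#' @param phi_amplitude peak transcription multiplier under stress (8 for a
#'   typical induced gene, 0.125 for a repressed one, 1 for neutral).
#' @param phi_shape `"pulse"` (transient, oxidative-like) or `"step"`
#'   (sustained, MMS-like).
#' @param phi_tau_on onset time constant of the stress program, min.
#' @param phi_tau_off relaxation time constant (pulse shape only), min.
#' @param affinity per-gene imprinting affinity in `[0, 1]`.
#' @param strain_recruitment Rpb4/7 recruitment efficiency `rho` in `[0, 1]`
#'   (1 for wild type, < 1 for an rpb6-like mutant). The same molecular
#'   defect acts twice: `rho` scales both the probability that a transcript
#'   leaves the nucleus imprinted and the imprint's effectiveness at
#'   recruiting decay machinery (the per-imprinted-molecule rate cap becomes
#'   `lambda_max * rho`).
#' @return A `data.frame` with one row per gene.
#' @export
gene_params <- function(gene_id, beta_basal, stress_class = "neutral",
                        phi_amplitude = 1, phi_shape = "pulse",
                        phi_tau_on = 3, phi_tau_off = 18,
                        affinity = 1, strain_recruitment = 1) {
  df <- data.frame(gene_id = as.character(gene_id),
                   beta_basal = beta_basal,
                   stress_class = stress_class,
                   phi_amplitude = phi_amplitude,
                   phi_shape = phi_shape,
                   phi_tau_on = phi_tau_on,
                   phi_tau_off = phi_tau_off,
                   affinity = affinity,
                   strain_recruitment = strain_recruitment,
                   stringsAsFactors = FALSE)
  stopifnot(all(df$beta_basal >= 0),
            all(df$affinity >= 0 & df$affinity <= 1),
            all(df$strain_recruitment >= 0 & df$strain_recruitment <= 1),
            all(df$stress_class %in% c("induced", "neutral", "repressed")),
            all(df$phi_shape %in% c("pulse", "step")))
  df
}

#' Stress transcription multiplier profile
#'
#' Evaluates each gene's transcription multiplier `phi_i(t)` at time `t`
#' measured from stress onset (`t < 0` gives 1 for every gene). The multiplier
#' moves on the log scale from 1 toward `phi_amplitude` along a unit-peak
#' shape: a double-exponential pulse (`(exp(-t/tau_off) - exp(-t/tau_on))`,
#' rescaled to peak at 1) or a saturating step (`1 - exp(-t/tau_on)`).
#'
#' @param genes a [gene_params()] table.
#' @param t time since stress onset, min (scalar).
#' @return Numeric vector of multipliers, one per gene.
#' @export
phi_profile <- function(genes, t) {
  if (t <= 0) return(rep(1, nrow(genes)))
  g <- numeric(nrow(genes))
  pulse <- genes$phi_shape == "pulse"
  if (any(pulse)) {
    on <- genes$phi_tau_on[pulse]; off <- genes$phi_tau_off[pulse]
    tpk <- log(off / on) / (1 / on - 1 / off)
    peak <- exp(-tpk / off) - exp(-tpk / on)
    g[pulse] <- (exp(-t / off) - exp(-t / on)) / peak
  }
  if (any(!pulse))
    g[!pulse] <- 1 - exp(-t / genes$phi_tau_on[!pulse])
  genes$phi_amplitude ^ g
}

#' Model state constructor
#' @param t time, min.
#' @param I per-gene imprinted copy counts (continuous).
#' @param U per-gene non-imprinted copy counts.
#' @return A list of class `model_state`.
#' @export
model_state <- function(t, I, U) {
  stopifnot(length(I) == length(U), all(I >= 0), all(U >= 0))
  structure(list(t = t, I = I, U = U), class = "model_state")
}

#' Machinery shares across genes
#'
#' The limited decay machinery is recruited per imprinted transcript, so
#' gene *i*'s share of the pool is its fraction of all imprinted copies in
#' the cell: `s_i = I_i / sum(I)`. Genes with equal imprinted percentages and
#' equal expression receive equal ("uniform") shares; a gene whose imprinted
#' copies accumulate gains share at the others' expense. When every pool is
#' empty all shares are 0; otherwise they sum to 1. Combined with the
#' per-molecule cap, the machinery-mediated decay rate per imprinted molecule
#' is the genome-wide quantity `min(D / sum(I), lambda_max)`.
#'
#' @param state a [model_state()].
#' @return Numeric share vector, one per gene.
#' @export
machinery_shares <- function(state) {
  S <- sum(state$I)
  if (S > 0) state$I / S else state$I * 0
}

# effective imprinting probability per gene at probability p
imprint_prob <- function(genes, p) {
  pmin(pmax(p * genes$affinity * genes$strain_recruitment, 0), 1)
}

#' Advance the model by one Euler step
#'
#' Integrates `dI/dt = q beta - k_U I - min(D s, lambda_max I)` and
#' `dU/dt = (1 - q) beta - k_U U` over one step `dt`. Pools that would go
#' negative are clipped to zero with a warning (a sign that `dt` is too
#' coarse).
#'
#' @param state a [model_state()].
#' @param genes a [gene_params()] table.
#' @param params an [imprinting_params()] object.
#' @param beta per-gene transcription rates at the current time
#'   (defaults to basal rates); pass 0 to model transcription arrest.
#' @param p imprinting probability now (defaults from `params` and `state$t`).
#' @return The advanced `model_state`.
#' @export
model_step <- function(state, genes, params,
                       beta = genes$beta_basal,
                       p = if (state$t < params$stress_onset) params$p_basal
                           else params$p_stress) {
  q <- imprint_prob(genes, p)
  s <- machinery_shares(state)
  flux <- pmin(params$D * s,
               params$lambda_max * genes$strain_recruitment * state$I)
  I2 <- state$I + params$dt * (q * beta - params$k_U * state$I - flux)
  U2 <- state$U + params$dt * ((1 - q) * beta - params$k_U * state$U)
  if (any(I2 < 0) || any(U2 < 0)) {
    warning("pool clipped at zero; consider a smaller dt", call. = FALSE)
    I2 <- pmax(I2, 0); U2 <- pmax(U2, 0)
  }
  model_state(state$t + params$dt, I2, U2)
}

#' Pre-stress steady state of the imprinting model
#'
#' Solves the stationarity conditions at fixed imprinting probability `p` and
#' basal transcription. With per-copy machinery shares the machinery rate per
#' imprinted molecule is the single genome-wide number
#' `mu = min(D / sum(I), lambda_max)`, so the gene equations decouple given
#' `mu`: `U* = (1-q) beta / k_U`, `I*(mu) = q beta / (k_U + mu)`. The scalar
#' self-consistency `mu = min(D / sum(I*(mu)), lambda_max)` is solved by
#' damped fixed-point iteration.
#'
#' @inheritParams model_step
#' @param p imprinting probability (defaults to `p_basal`).
#' @param tol relative convergence tolerance.
#' @param max_iter iteration cap.
#' @return A `model_state` at `t = 0`.
#' @export
steady_state <- function(genes, params, p = params$p_basal,
                         tol = 1e-13, max_iter = 10000L) {
  q <- imprint_prob(genes, p)
  beta <- genes$beta_basal
  lmax <- params$lambda_max * genes$strain_recruitment
  U <- (1 - q) * beta / params$k_U
  if (all(q * beta == 0))
    return(model_state(0, q * beta, U))
  # scalar machinery load: mu0 = D / sum(I); per-gene rate min(mu0, lmax_i)
  mu0 <- max(lmax) / 2
  for (iter in seq_len(max_iter)) {
    S <- sum(q * beta / (params$k_U + pmin(mu0, lmax)))
    mu_new <- if (S > 0) params$D / S else Inf
    if (abs(mu_new - mu0) <= tol * max(mu0, 1e-12)) { mu0 <- mu_new; break }
    mu0 <- 0.5 * mu0 + 0.5 * mu_new
  }
  model_state(0, q * beta / (params$k_U + pmin(mu0, lmax)), U)
}

# integrate from state over [state$t, t_stop], recording I+U at sample times;
# beta_fun(t) and p_fun(t) give the instantaneous inputs
integrate_model <- function(state, genes, params, t_stop, sample_times,
                            beta_fun, p_fun) {
  dt <- params$dt
  n_steps <- as.integer(round((t_stop - state$t) / dt))
  sample_idx <- as.integer(round((sample_times - state$t) / dt))
  stopifnot(all(abs(sample_times - (state$t + sample_idx * dt)) < 1e-8))
  out <- matrix(NA_real_, nrow(genes), length(sample_times))
  I_out <- matrix(NA_real_, nrow(genes), length(sample_times))
  hit <- match(0L, sample_idx)
  if (!is.na(hit)) { out[, hit] <- state$I + state$U; I_out[, hit] <- state$I }
  clipped <- FALSE
  I <- state$I; U <- state$U; t0 <- state$t
  k_U <- params$k_U; D <- params$D
  lmax <- params$lambda_max * genes$strain_recruitment
  aff <- genes$affinity * genes$strain_recruitment
  for (step in seq_len(n_steps)) {
    t <- t0 + (step - 1L) * dt
    beta <- beta_fun(t)
    q <- pmin(pmax(p_fun(t) * aff, 0), 1)
    S <- sum(I)
    s <- if (S > 0) I / S else I * 0
    flux <- pmin(D * s, lmax * I)
    I <- I + dt * (q * beta - k_U * I - flux)
    U <- U + dt * ((1 - q) * beta - k_U * U)
    if (any(I < 0) || any(U < 0)) {
      clipped <- TRUE
      I <- pmax(I, 0); U <- pmax(U, 0)
    }
    hit <- match(step, sample_idx)
    if (!is.na(hit)) { out[, hit] <- I + U; I_out[, hit] <- I }
  }
  if (clipped)
    warning("pool clipped at zero during integration; consider a smaller dt",
            call. = FALSE)
  list(total = out, imprinted = I_out,
       state = model_state(t0 + n_steps * dt, I, U))
}

# ln-linear effective half-life of a noiseless trajectory over the sampled
# decay window: ln 2 / (-OLS slope of ln copies vs time)
effective_halflife <- function(total, sample_times) {
  apply(total, 1L, function(y) {
    ok <- y > 0
    if (sum(ok) < 2L) return(NA_real_)
    slope <- stats::cov(sample_times[ok], log(y[ok])) / stats::var(sample_times[ok])
    if (slope >= 0) Inf else log(2) / (-slope)
  })
}

#' Run one experiment scenario of the study design
#'
#' Three scenarios mirror the study's per-strain design: a reference decay
#' experiment (transcription arrested at time 0, no stress), a stress decay
#' experiment (stress at time 0, arrest `arrest_delay` minutes later, with the
#' sampling clock restarting at arrest) and a stress abundance experiment
#' (stress only). The system is first relaxed to its pre-stress steady state.
#'
#' @inheritParams model_step
#' @param scenario `"reference_decay"`, `"stress_decay"` or
#'   `"stress_abundance"`.
#' @param sample_times sampling times, min (decay scenarios: minutes after
#'   arrest; abundance: minutes after stress onset).
#' @param arrest_delay minutes between stress onset and transcription arrest
#'   in the stress decay scenario (default 7).
#' @return A list with `total` (genes x sample-times true copy-number matrix),
#'   `truth` (a `data.frame` with `gene_id`, `stress_class` and, for decay
#'   scenarios, `true_halflife` from a ln-linear fit to the noiseless
#'   trajectory) and `sample_times`.
#' @export
run_scenario <- function(genes, params,
                         scenario = c("reference_decay", "stress_decay",
                                      "stress_abundance"),
                         sample_times = NULL, arrest_delay = 7) {
  scenario <- match.arg(scenario)
  if (is.null(sample_times))
    sample_times <- if (scenario == "stress_abundance")
      c(0, 5, 10, 15, 25, 35, 45) else c(0, 5, 10, 20, 30, 40, 50)
  t_span <- max(sample_times) +
    if (scenario == "stress_decay") arrest_delay else 0
  if (t_span > params$t_end)
    stop("sample times extend beyond params$t_end")
  state <- steady_state(genes, params, p = params$p_basal)
  beta0 <- genes$beta_basal
  p_b <- params$p_basal; p_s <- params$p_stress
  if (scenario == "reference_decay") {
    res <- integrate_model(state, genes, params, max(sample_times),
                           sample_times,
                           beta_fun = function(t) 0,
                           p_fun = function(t) p_b)
  } else if (scenario == "stress_abundance") {
    res <- integrate_model(state, genes, params, max(sample_times),
                           sample_times,
                           beta_fun = function(t) beta0 * phi_profile(genes, t),
                           p_fun = function(t) p_s)
  } else {
    res <- integrate_model(state, genes, params,
                           arrest_delay + max(sample_times),
                           arrest_delay + sample_times,
                           beta_fun = function(t)
                             if (t < arrest_delay) beta0 * phi_profile(genes, t)
                             else 0 * beta0,
                           p_fun = function(t) p_s)
  }
  truth <- data.frame(gene_id = genes$gene_id,
                      stress_class = genes$stress_class,
                      stringsAsFactors = FALSE)
  if (scenario != "stress_abundance")
    truth$true_halflife <- effective_halflife(res$total, sample_times)
  rownames(res$total) <- genes$gene_id
  colnames(res$total) <- format(sample_times, trim = TRUE)
  list(total = res$total, truth = truth, sample_times = sample_times)
}
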