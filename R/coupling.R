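#' Association between stability change and abundance fold change
#'
#' The headline coupling statistic: ordinary least squares of per-gene
#' stability change (`delta`, y) on maximal abundance fold change
#' (`max_fc`, x), with Pearson correlation, a two-sided test reported as
#' `-log10(p)`, and 95% parameter confidence intervals from the t
#' distribution. A negative slope is the counter-action regime (induced
#' genes destabilized, repressed genes stabilized).
#'
#' @param delta per-gene stability changes (log2 stress/reference
#'   half-life).
#' @param max_fc per-gene maximal log2 abundance fold changes, same order.
#' @param subset optional logical mask restricting the fit (e.g. responsive
#'   genes).
#' @return A list of class `coupling_summary`: `n_genes`, `pearson_r`,
#'   `neg_log10_p`, `slope`, `intercept`, `slope_ci95`, `intercept_ci95`.
#' @export
coupling_fit <- function(delta, max_fc, subset = NULL) {
  if (!is.null(subset)) { delta <- delta[subset]; max_fc <- max_fc[subset] }
  ok <- is.finite(delta) & is.finite(max_fc)
  delta <- delta[ok]; max_fc <- max_fc[ok]
  n <- length(delta)
  if (n < 3L) stop("at least 3 finite pairs are required")
  fit <- stats::lm(delta ~ max_fc)
  cf <- stats::coef(fit)
  ci <- suppressWarnings(stats::confint(fit, level = 0.95))
  ci[is.nan(ci)] <- rep(cf, 2)[is.nan(ci)]
  r <- stats::cor(max_fc, delta)
  p <- if (abs(r) >= 1) 0 else {
    tval <- r * sqrt((n - 2) / (1 - r ^ 2))
    2 * stats::pt(-abs(tval), df = n - 2)
  }
  structure(list(n_genes = n, pearson_r = r,
                 neg_log10_p = -log10(max(p, .Machine$double.xmin)),
                 slope = unname(cf[2]), intercept = unname(cf[1]),
                 slope_ci95 = unname(ci[2, ]),
                 intercept_ci95 = unname(ci[1, ])),
            class = "coupling_summary")
}

#' @export
print.coupling_summary <- function(x, ...) {
  cat(sprintf("coupling fit over %d genes\n", x$n_genes))
  cat(sprintf("  Pearson r = %.3f, -log10(p) = %.2f\n",
              x$pearson_r, x$neg_log10_p))
  cat(sprintf("  y = %.4fx%+.4f; slope CI95 (%.4f, %.4f); intercept CI95 (%.4f, %.4f)\n",
              x$slope, x$intercept, x$slope_ci95[1], x$slope_ci95[2],
              x$intercept_ci95[1], x$intercept_ci95[2]))
  invisible(x)
}

#' Classify genes by abundance and stability change
#'
#' Thresholds are linear fold changes applied on the log2 scale:
#' induced/repressed when `|max_fc| > log2(fc_threshold)`,
#' stabilized/destabilized when `|delta| > log2(hl_threshold)`.
#'
#' @param max_fc per-gene maximal log2 abundance fold changes.
#' @param delta per-gene log2 stability changes, same order.
#' @param fc_threshold linear abundance threshold (default 1.75).
#' @param hl_threshold linear stability threshold (default 1.5).
#' @return A `data.frame` with factors `abundance`
#'   (`induced`/`neutral`/`repressed`) and `stability`
#'   (`stabilized`/`unchanged`/`destabilized`).
#' @export
classify_changes <- function(max_fc, delta, fc_threshold = 1.75,
                             hl_threshold = 1.5) {
  stopifnot(length(max_fc) == length(delta),
            fc_threshold > 0, hl_threshold > 0)
  ab <- ifelse(max_fc > log2(fc_threshold), "induced",
               ifelse(max_fc < -log2(fc_threshold), "repressed", "neutral"))
  st <- ifelse(delta > log2(hl_threshold), "stabilized",
               ifelse(delta < -log2(hl_threshold), "destabilized",
                      "unchanged"))
  data.frame(abundance = factor(ab, c("induced", "neutral", "repressed")),
             stability = factor(st, c("stabilized", "unchanged",
                                      "destabilized")))
}

#' Fold enrichment of stability changes within abundance classes
#'
#' For each of the four cells {induced, repressed} x {stabilized,
#' destabilized}, the observed count is compared with the count expected
#' under independence: the genome-wide fraction of stabilized (or
#' destabilized) genes times the induced (or repressed) group size.
#' Enrichment is observed/expected; a hypergeometric upper-tail p-value per
#' cell is reported as auxiliary output.
#'
#' @param labels a classification table from [classify_changes()] over the
#'   full gene set.
#' @return A `data.frame` of class `fold_enrichment_table` with one row per
#'   cell: `abundance`, `stability`, `observed`, `expected`, `enrichment`,
#'   `p_hyper` (`NA` enrichment for an empty group).
#' @export
fold_enrichment <- function(labels) {
  n <- nrow(labels)
  cells <- expand.grid(abundance = c("induced", "repressed"),
                       stability = c("stabilized", "destabilized"),
                       stringsAsFactors = FALSE)
  out <- lapply(seq_len(nrow(cells)), function(i) {
    ab <- cells$abundance[i]; st <- cells$stability[i]
    grp <- labels$abundance == ab
    hit <- labels$stability == st
    obs <- sum(grp & hit)
    expd <- mean(hit) * sum(grp)
    data.frame(abundance = ab, stability = st, observed = obs,
               expected = expd,
               enrichment = if (expd > 0) obs / expd else NA_real_,
               p_hyper = stats::phyper(obs - 1, sum(hit), n - sum(hit),
                                       sum(grp), lower.tail = FALSE),
               stringsAsFactors = FALSE)
  })
  structure(do.call(rbind, out),
            class = c("fold_enrichment_table", "data.frame"))
}

#' Basal (unstressed) comparison of two strains
#'
#' Emulates the study's steady-state contrast: spike-in-normalized time-zero
#' intensities give per-gene basal abundance differences
#' `x = log2(mut / wt)`, plotted against basal stability differences
#' `y = log2(halflife_mut / halflife_wt)` from the two strains' reference
#' decay fits. Reports the genome-wide abundance shift (median x) and an OLS
#' fit of y on x.
#'
#' @param wt_t0,mut_t0 time-zero intensity vectors (same genes, same order),
#'   already spike-in normalized — see [spike_in_normalize()].
#' @param wt_hl,mut_hl reference-condition half-life record tables per
#'   strain.
#' @param gene_ids gene identifiers aligned with the intensity vectors.
#' @return A list: `table` (per-gene `x`, `y`), `median_x`, and `fit`
#'   (a `coupling_summary` of y on x).
#' @export
basal_comparison <- function(wt_t0, mut_t0, wt_hl, mut_hl,
                             gene_ids = names(wt_t0)) {
  stopifnot(length(wt_t0) == length(mut_t0))
  ok_hl <- intersect(wt_hl$gene_id[wt_hl$passed],
                     mut_hl$gene_id[mut_hl$passed])
  keep <- gene_ids %in% ok_hl & wt_t0 > 0 & mut_t0 > 0
  g <- gene_ids[keep]
  x <- log2(mut_t0[keep] / wt_t0[keep])
  y <- log2(mut_hl$halflife[match(g, mut_hl$gene_id)] /
              wt_hl$halflife[match(g, wt_hl$gene_id)])
  tab <- data.frame(gene_id = g, x = x, y = y, stringsAsFactors = FALSE)
  fit <- if (stats::var(x) > 0) coupling_fit(y, x) else NULL
  list(table = tab, median_x = stats::median(x), fit = fit)
}
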