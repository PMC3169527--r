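#' Fit a first-order decay model to one zero-transformed profile
#'
#' Fits `m(t) = m0 * exp(-k t)` by ordinary least squares on the log2 scale:
#' the log2 profile is regressed on time with a free intercept, and the decay
#' constant recovered as `k = -slope * ln 2`. Goodness of fit is the usual
#' `R^2 = 1 - SS_res / SS_tot` of the log-linear fit. A non-positive `k`
#' yields an infinite half-life and fails the filter.
#'
#' @param profile numeric vector of log2-to-t0 values.
#' @param times sampling times, min.
#' @param gene_id identifier carried into the record.
#' @param threshold goodness-of-fit cutoff defining `passed`
#'   (`r_squared > threshold`, strict; default 0.9).
#' @param strain,condition metadata carried into the record.
#' @return A one-row `data.frame`: `gene_id`, `k` (1/min), `halflife` (min),
#'   `r_squared`, `passed`, `strain`, `condition`.
#' @export
fit_decay <- function(profile, times, gene_id = NA_character_,
                      threshold = 0.9, strain = NA_character_,
                      condition = NA_character_) {
  ok <- is.finite(profile) & is.finite(times)
  if (sum(ok) < 3L) stop("at least 3 finite time points are required")
  y <- profile[ok]; x <- times[ok]
  xc <- x - mean(x); yc <- y - mean(y)
  slope <- sum(xc * yc) / sum(xc * xc)
  ss_tot <- sum(yc ^ 2)
  if (ss_tot == 0) {
    r2 <- NA_real_
  } else {
    ss_res <- sum((yc - slope * xc) ^ 2)
    r2 <- 1 - ss_res / ss_tot
  }
  k <- -slope * log(2)
  hl <- if (k > 0) log(2) / k else Inf
  data.frame(gene_id = gene_id, k = k, halflife = hl, r_squared = r2,
             passed = !is.na(r2) && r2 > threshold && k > 0,
             strain = strain, condition = condition,
             stringsAsFactors = FALSE)
}

#' Fit half-lives for every gene of a decay matrix
#'
#' Applies [fit_decay()] row-wise to a zero-transformed decay course
#' (a `linear_intensity` matrix is zero-transformed first).
#'
#' @param matrix an `expression_matrix` (decay experiment).
#' @param threshold goodness-of-fit cutoff (default 0.9).
#' @return A `data.frame` of half-life records, one row per gene.
#' @export
fit_halflives <- function(matrix, threshold = 0.9) {
  stopifnot(inherits(matrix, "expression_matrix"))
  if (attr(matrix, "scale") == "linear_intensity")
    matrix <- zero_transform(matrix)
  times <- em_times(matrix)
  recs <- lapply(seq_len(nrow(matrix)), function(i)
    fit_decay(unclass(matrix)[i, ], times, gene_id = rownames(matrix)[i],
              threshold = threshold, strain = attr(matrix, "strain"),
              condition = attr(matrix, "condition")))
  do.call(rbind, recs)
}

#' Filter half-life records on goodness of fit
#'
#' Keeps genes whose log-linear decay fit achieves `r_squared > threshold`
#' (strict inequality) and a positive decay constant.
#'
#' @param records a half-life record table from [fit_halflives()].
#' @param threshold goodness-of-fit cutoff (default 0.9).
#' @return The passing subset, with a `report` attribute listing the number
#'   fitted, number passing and pass fraction.
#' @export
filter_fits <- function(records, threshold = 0.9) {
  pass <- !is.na(records$r_squared) & records$r_squared > threshold &
    records$k > 0
  out <- records[pass, , drop = FALSE]
  attr(out, "report") <- list(n = nrow(records), n_passed = sum(pass),
                              pass_fraction = mean(pass),
                              threshold = threshold)
  out
}

#' Stability change between stress and reference conditions
#'
#' For each gene passing the fit filter in both conditions, the stability
#' change is `delta = log2(halflife_stress / halflife_ref)`; negative values
#' mean destabilization under stress.
#'
#' @param ref_records,stress_records half-life record tables for the
#'   reference and stress conditions of one strain.
#' @return A `data.frame` (`gene_id`, `delta`), with dropped-gene counts in
#'   `attr(, "report")`.
#' @export
stability_change <- function(ref_records, stress_records) {
  ref <- ref_records[ref_records$passed, ]
  str <- stress_records[stress_records$passed, ]
  common <- intersect(ref$gene_id, str$gene_id)
  hl_ref <- ref$halflife[match(common, ref$gene_id)]
  hl_str <- str$halflife[match(common, str$gene_id)]
  out <- data.frame(gene_id = common,
                    delta = log2(hl_str / hl_ref),
                    stringsAsFactors = FALSE)
  attr(out, "report") <- list(
    n_ref_failed = sum(!ref_records$passed),
    n_stress_failed = sum(!stress_records$passed),
    n_used = length(common))
  out
}
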