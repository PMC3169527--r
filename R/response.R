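#' Call stress-responsive genes from an abundance time course
#'
#' A gene is responsive when its abundance changes by more than a linear
#' fold-change threshold, in either direction, at one or more time points:
#' `max_t max(ratio, 1/ratio) > threshold`, i.e.
#' `|log2fc(t)| > log2(threshold)` (strict).
#'
#' @param matrix an `expression_matrix` on the `log2_to_t0` scale.
#' @param threshold linear fold-change cutoff (default 1.75).
#' @return Named logical vector, one entry per gene.
#' @export
call_responsive <- function(matrix, threshold = 1.75) {
  stopifnot(inherits(matrix, "expression_matrix"),
            attr(matrix, "scale") == "log2_to_t0")
  apply(abs(unclass(matrix)) > log2(threshold), 1L, any)
}

#' Maximal fold change of a response profile by cubic-spline interpolation
#'
#' Interpolates the log2 response profile with a natural cubic spline and
#' takes the extreme point where the spline derivative vanishes and the
#' fitted value attains its maximal absolute value; both endpoints are also
#' candidates (a monotone response peaks at the boundary, where the
#' derivative need not vanish). Ties in absolute value are broken by the
#' earliest time.
#'
#' @param profile numeric vector of log2-to-t0 values.
#' @param times sampling times, min (>= 4 points for the spline).
#' @return A list: `max_fc` (signed log2 maximal change) and `t_max` (min).
#' @export
max_fold_change <- function(profile, times) {
  ok <- is.finite(profile) & is.finite(times)
  profile <- profile[ok]; times <- times[ok]
  o <- order(times); times <- times[o]; profile <- profile[o]
  if (length(times) < 4L) {
    i <- which.max(abs(profile))
    return(list(max_fc = profile[i], t_max = times[i]))
  }
  sp <- tryCatch(stats::splinefun(times, profile, method = "natural"),
                 error = function(e) NULL)
  if (is.null(sp)) {
    warning("spline interpolation failed; using discrete extremum",
            call. = FALSE)
    i <- which.max(abs(profile))
    return(list(max_fc = profile[i], t_max = times[i]))
  }
  dsp <- function(x) sp(x, deriv = 1)
  grid <- seq(min(times), max(times), length.out = 64L * length(times))
  dv <- dsp(grid)
  cand <- c(min(times), max(times))
  sgn <- sign(dv)
  flip <- which(sgn[-1] * sgn[-length(sgn)] < 0)
  for (i in flip) {
    root <- stats::uniroot(dsp, c(grid[i], grid[i + 1]), tol = 1e-12)$root
    cand <- c(cand, root)
  }
  cand <- c(cand, grid[dv == 0])
  vals <- sp(cand)
  best <- max(abs(vals))
  hit <- which(abs(vals) >= best - 1e-12)
  i <- hit[which.min(cand[hit])]
  list(max_fc = vals[i], t_max = cand[i])
}

#' Transience index of a response profile
#'
#' Quantifies how much of the maximal response has relaxed by the end of the
#' course: `1 - |log2fc(t_end)| / |max_fc|`, clipped to `[0, 1]`. 1 means the
#' profile returned to baseline (spiked, fast-relaxing kinetics); 0 means the
#' response is fully sustained at the endpoint.
#'
#' @param profile numeric vector of log2-to-t0 values.
#' @param times sampling times, min.
#' @param max_fc optional precomputed signed maximal change
#'   (from [max_fold_change()]).
#' @return Scalar in `[0, 1]`, or `NA` when `max_fc` is 0.
#' @export
transience_index <- function(profile, times, max_fc = NULL) {
  if (is.null(max_fc)) max_fc <- max_fold_change(profile, times)$max_fc
  if (!is.finite(max_fc) || max_fc == 0) return(NA_real_)
  end <- profile[which.max(times)]
  min(max(1 - abs(end) / abs(max_fc), 0), 1)
}

#' Response summary for every gene of an abundance course
#'
#' Combines [call_responsive()], [max_fold_change()] and
#' [transience_index()] into one table.
#'
#' @param matrix an `expression_matrix` (`log2_to_t0`; a `linear_intensity`
#'   matrix is zero-transformed first).
#' @param fc_threshold linear fold-change cutoff for responsiveness
#'   (default 1.75).
#' @return A `data.frame`: `gene_id`, `responsive`, `max_fc`, `t_max`,
#'   `transience` (`NA` for non-responsive genes).
#' @export
profile_responses <- function(matrix, fc_threshold = 1.75) {
  stopifnot(inherits(matrix, "expression_matrix"))
  if (attr(matrix, "scale") == "linear_intensity")
    matrix <- zero_transform(matrix)
  times <- em_times(matrix)
  resp <- call_responsive(matrix, fc_threshold)
  rows <- lapply(seq_len(nrow(matrix)), function(i) {
    mf <- max_fold_change(unclass(matrix)[i, ], times)
    data.frame(gene_id = rownames(matrix)[i], responsive = resp[i],
               max_fc = mf$max_fc, t_max = mf$t_max,
               transience = if (resp[i])
                 transience_index(unclass(matrix)[i, ], times, mf$max_fc)
               else NA_real_,
               stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}
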