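#' Reference genome-mean decay profile
#'
#' The transcription-arrest drug used in these decay courses inhibits all
#' three RNA polymerases, so spike-in normalization is invalid there.
#' Instead, each array of a decay course is rescaled so that the genome-mean
#' intensity follows a prescribed reference decay profile.
#'
#' @param times sampling times, min.
#' @param mean_intensity expected genome-mean intensity at each time
#'   (arbitrary units; the first value sets the scale). Must be positive and
#'   non-increasing.
#' @return A `data.frame` of class `reference_decay_profile`.
#' @export
reference_profile <- function(times, mean_intensity) {
  stopifnot(length(times) == length(mean_intensity),
            all(mean_intensity > 0),
            !is.unsorted(times, strictly = TRUE))
  if (any(diff(mean_intensity) > 1e-9 * mean_intensity[1]))
    stop("reference profile must be non-increasing")
  structure(data.frame(time = as.numeric(times),
                       mean_intensity = as.numeric(mean_intensity)),
            class = c("reference_decay_profile", "data.frame"))
}

#' Default exponential reference profile
#'
#' A genome-mean profile decaying exponentially with the given half-life,
#' standing in for reference measurements when none are supplied.
#'
#' @param times sampling times, min.
#' @param halflife genome-mean half-life, min (default 20).
#' @param scale intensity at time 0.
#' @return A [reference_profile()].
#' @export
default_reference_profile <- function(times = c(0, 5, 10, 20, 30, 40, 50),
                                      halflife = 20, scale = 1000) {
  reference_profile(times, scale * 2 ^ (-times / halflife))
}

#' Write / read a reference profile as two-column TSV
#' @param profile a [reference_profile()].
#' @param path file path.
#' @return `path` (write) or the profile (read).
#' @export
write_reference_profile <- function(profile, path) {
  utils::write.table(as.data.frame(profile), path, sep = "\t",
                     quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_reference_profile
#' @export
read_reference_profile <- function(path) {
  df <- utils::read.delim(path)
  reference_profile(df$time, df$mean_intensity)
}

# reference values at the matrix's times, linearly interpolated if needed
ref_at <- function(profile, times) {
  if (min(times) < min(profile$time) || max(times) > max(profile$time))
    stop("matrix times outside the reference profile's range")
  stats::approx(profile$time, profile$mean_intensity, xout = times)$y
}

#' Reference-profile scaling of a decay course
#'
#' Rescales each array (column) of a linear-intensity decay matrix so that
#' the genome-mean intensity follows the reference profile, anchored at the
#' matrix's own time-zero mean: column `t` is multiplied by
#' `c_t = ref(t) * (mean(col_0) / ref(0)) / mean(col_t)`. The scaling is
#' per-column and monotone, so within-array gene rankings are untouched, and
#' it is idempotent.
#'
#' @param matrix an `expression_matrix` (`linear_intensity`, decay).
#' @param ref a [reference_decay_profile][reference_profile()]
#'   (default: exponential, 20-min genome-mean half-life).
#' @return The rescaled `expression_matrix`, with the applied per-column
#'   factors in `attr(, "scale_applied")`.
#' @export
reference_scale <- function(matrix, ref = default_reference_profile()) {
  stopifnot(inherits(matrix, "expression_matrix"),
            attr(matrix, "scale") == "linear_intensity")
  times <- em_times(matrix)
  rv <- ref_at(ref, times)
  cm <- colMeans(matrix)
  if (any(cm <= 0)) stop("zero or negative column mean; cannot rescale")
  cf <- rv * (cm[1] / rv[1]) / cm
  out <- em_update(matrix, sweep(unclass(matrix), 2L, cf, `*`))
  attr(out, "scale_applied") <- unname(cf)
  out
}

#' Zero transform: log2 ratio to the first time point
#'
#' Converts a linear-intensity course to `log2(value(t) / value(0))` per
#' gene. Genes with any non-positive intensity cannot be log-transformed;
#' they are dropped with a warning and listed in `attr(, "excluded")`.
#'
#' @param matrix an `expression_matrix` on the `linear_intensity` scale.
#' @return An `expression_matrix` on the `log2_to_t0` scale (first column all
#'   zeros).
#' @export
zero_transform <- function(matrix) {
  stopifnot(inherits(matrix, "expression_matrix"),
            attr(matrix, "scale") == "linear_intensity")
  bad <- apply(unclass(matrix) <= 0, 1L, any)
  if (any(bad))
    warning(sprintf("%d gene(s) with non-positive intensities excluded",
                    sum(bad)), call. = FALSE)
  v <- unclass(matrix)[!bad, , drop = FALSE]
  lv <- log2(v / v[, 1])
  lv[, 1] <- 0
  out <- em_update(matrix, lv, gene_ids = rownames(v), scale = "log2_to_t0")
  attr(out, "excluded") <- rownames(matrix)[bad]
  out
}

#' Spike-in normalization of array intensities
#'
#' Scales each array by the ratio of a reference spike-in level to that
#' array's measured spike-in intensity. Unlike rank-preserving global
#' normalizations, this preserves true genome-wide differences in mean mRNA
#' level between samples (e.g. between strains), because the internal
#' standard is independent of the cellular mRNA pool.
#'
#' @param values numeric matrix (or vector) of intensities, one column per
#'   array.
#' @param spike_in measured spike-in intensity per array.
#' @param reference_level spike-in level to scale to (default: the first
#'   array's measured value).
#' @return The rescaled values.
#' @export
spike_in_normalize <- function(values, spike_in,
                               reference_level = spike_in[1]) {
  values <- as.matrix(values)
  if (length(spike_in) != ncol(values))
    stop("one spike-in value per array is required")
  if (any(spike_in <= 0)) stop("spike-in values must be positive")
  sweep(values, 2L, reference_level / spike_in, `*`)
}
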