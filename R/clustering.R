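#' Cluster concatenated wild-type and mutant response profiles
#'
#' Each responsive gene is represented by the concatenation of its wild-type
#' and mutant log2 response profiles; pairwise distance is
#' `1 - Spearman rank correlation` between these feature vectors, followed
#' by average-linkage agglomerative clustering and a cut into `k` clusters.
#' Genes with a constant feature vector (undefined rank correlation) are
#' excluded with a warning. Gene input order does not affect the partition:
#' genes are ordered by identifier internally and cluster labels are
#' renumbered by first appearance in that order.
#'
#' @param wt,mut `expression_matrix` objects on the `log2_to_t0` scale with
#'   the same genes.
#' @param responsive logical mask (or character vector of gene ids) selecting
#'   the genes to cluster.
#' @param k number of clusters (default 3).
#' @return A list of class `cluster_result`: `gene_ids`, `assignments`
#'   (labels in `1..k`), `k`, `hclust` (the dendrogram), `profile_means`
#'   (per-cluster mean profile per strain).
#' @export
cluster_profiles <- function(wt, mut, responsive = NULL, k = 3) {
  stopifnot(inherits(wt, "expression_matrix"),
            inherits(mut, "expression_matrix"),
            attr(wt, "scale") == "log2_to_t0",
            attr(mut, "scale") == "log2_to_t0")
  common <- intersect(rownames(wt), rownames(mut))
  if (is.character(responsive)) common <- intersect(common, responsive)
  else if (is.logical(responsive))
    common <- intersect(common, rownames(wt)[responsive])
  common <- sort(common)
  if (length(common) < k) stop("need at least k genes to cluster")
  feat <- cbind(unclass(wt)[common, , drop = FALSE],
                unclass(mut)[common, , drop = FALSE])
  const <- apply(feat, 1L, function(v) stats::sd(v) == 0)
  if (any(const)) {
    warning(sprintf("%d gene(s) with constant profiles excluded",
                    sum(const)), call. = FALSE)
    feat <- feat[!const, , drop = FALSE]
  }
  rho <- stats::cor(t(feat), method = "spearman")
  d <- stats::as.dist(1 - rho)
  hc <- stats::hclust(d, method = "average")
  raw <- stats::cutree(hc, k = k)
  assignments <- match(raw, unique(raw))
  names(assignments) <- rownames(feat)
  nt <- ncol(wt)
  means <- lapply(seq_len(k), function(cl) {
    m <- feat[assignments == cl, , drop = FALSE]
    list(wild_type = colMeans(m[, seq_len(nt), drop = FALSE]),
         mutant = colMeans(m[, nt + seq_len(nt), drop = FALSE]),
         n = nrow(m))
  })
  structure(list(gene_ids = rownames(feat), assignments = assignments,
                 k = k, hclust = hc, profile_means = means),
            class = "cluster_result")
}

#' Per-cluster wild-type vs mutant stability-change slopes
#'
#' Within each cluster, the mutant's stability change is regressed on the
#' wild type's (y = mutant, x = wild type). A slope below one means the
#' mutant modulates stability less than the wild type for those genes;
#' a cluster is flagged `impaired` when the entire 95% confidence interval
#' of the slope lies below 1.
#'
#' @param clusters a `cluster_result` from [cluster_profiles()].
#' @param wt_delta,mut_delta stability-change tables
#'   (see [stability_change()]) for each strain.
#' @return A `data.frame` with one row per cluster: `cluster`, `n`, `slope`,
#'   `intercept`, `slope_lo`, `slope_hi`, `impaired` (`NA` fits are reported
#'   for clusters with < 3 usable genes). The regression orientation is
#'   recorded in `attr(, "orientation")`.
#' @export
cluster_stability_slopes <- function(clusters, wt_delta, mut_delta) {
  rows <- lapply(seq_len(clusters$k), function(cl) {
    g <- clusters$gene_ids[clusters$assignments == cl]
    g <- Reduce(intersect, list(g, wt_delta$gene_id, mut_delta$gene_id))
    x <- wt_delta$delta[match(g, wt_delta$gene_id)]
    y <- mut_delta$delta[match(g, mut_delta$gene_id)]
    if (length(g) < 3L || stats::var(x) == 0)
      return(data.frame(cluster = cl, n = length(g), slope = NA_real_,
                        intercept = NA_real_, slope_lo = NA_real_,
                        slope_hi = NA_real_, impaired = NA))
    fit <- stats::lm(y ~ x)
    ci <- suppressWarnings(stats::confint(fit))[2, ]
    data.frame(cluster = cl, n = length(g),
               slope = unname(stats::coef(fit)[2]),
               intercept = unname(stats::coef(fit)[1]),
               slope_lo = unname(ci[1]), slope_hi = unname(ci[2]),
               impaired = unname(ci[2] < 1))
  })
  out <- do.call(rbind, rows)
  attr(out, "orientation") <- "y = mutant delta, x = wild-type delta"
  out
}

#' Export a cluster dendrogram in Newick format
#'
#' @param clusters a `cluster_result`.
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_dendrogram_newick <- function(clusters, path) {
  phy <- ape::as.phylo(clusters$hclust)
  ape::write.tree(phy, file = path)
  invisible(path)
}
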