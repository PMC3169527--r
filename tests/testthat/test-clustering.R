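ab_times <- c(0, 5, 10, 15, 25, 35, 45)

# planted-archetype profiles: transient-up, sustained-up, down
archetype_matrices <- function(n_per = 50, noise = 0.15, seed = 71) {
  set.seed(seed)
  shapes <- list(
    transient = c(0, 1.6, 2.2, 1.8, 0.9, 0.4, 0.1),
    sustained = c(0, 0.5, 1.1, 1.6, 2.0, 2.2, 2.3),
    down = c(0, -0.8, -1.5, -1.9, -2.1, -2.2, -2.2))
  ids <- paste0("g", seq_len(3 * n_per))
  truth <- rep(names(shapes), each = n_per)
  mk <- function() {
    v <- t(sapply(seq_along(truth), function(i)
      shapes[[truth[i]]] + c(0, rnorm(6, 0, noise))))
    expression_matrix(v, ab_times, gene_ids = ids,
                      experiment = "abundance", scale = "log2_to_t0")
  }
  list(wt = mk(), mut = mk(), truth = truth, ids = ids)
}

test_that("planted archetypes are recovered by rank-correlation clustering", {
  skip_if_not_installed("mclust")
  arch <- archetype_matrices()
  cl <- cluster_profiles(arch$wt, arch$mut, k = 3)
  truth <- arch$truth[match(cl$gene_ids, arch$ids)]
  ari <- mclust::adjustedRandIndex(cl$assignments, truth)
  expect_gte(ari, 0.9)
  expect_equal(cl$k, 3)
  expect_setequal(unique(cl$assignments), 1:3)
})

test_that("the rank-correlation distance is a valid dissimilarity", {
  arch <- archetype_matrices(n_per = 8)
  feat <- cbind(unclass(arch$wt), unclass(arch$mut))
  rho <- cor(t(feat), method = "spearman")
  d <- 1 - rho
  expect_equal(d, t(d))
  expect_equal(diag(d), rep(0, nrow(d)), ignore_attr = TRUE)
  expect_true(all(d >= -1e-12 & d <= 2 + 1e-12))
})

test_that("duplicated profiles merge first at zero height", {
  arch <- archetype_matrices(n_per = 5)
  wt <- rbind(unclass(arch$wt), dup = unclass(arch$wt)[1, ])
  mut <- rbind(unclass(arch$mut), dup = unclass(arch$mut)[1, ])
  ids <- c(arch$ids, "g0dup")
  em <- function(v) expression_matrix(v, ab_times, gene_ids = ids,
                                      experiment = "abundance",
                                      scale = "log2_to_t0")
  cl <- cluster_profiles(em(wt), em(mut), k = 3)
  expect_equal(min(cl$hclust$height), 0)
  expect_equal(unname(cl$assignments["g0dup"]),
               unname(cl$assignments[arch$ids[1]]))
})

test_that("k = 1 collapses everything into one cluster", {
  arch <- archetype_matrices(n_per = 5)
  cl <- cluster_profiles(arch$wt, arch$mut, k = 1)
  expect_true(all(cl$assignments == 1))
})

test_that("the partition is invariant to gene input order", {
  arch <- archetype_matrices(n_per = 10)
  cl1 <- cluster_profiles(arch$wt, arch$mut, k = 3)
  o <- sample(nrow(arch$wt))
  shuf <- function(m) expression_matrix(unclass(m)[o, ], ab_times,
                                        gene_ids = rownames(m)[o],
                                        experiment = "abundance",
                                        scale = "log2_to_t0")
  cl2 <- cluster_profiles(shuf(arch$wt), shuf(arch$mut), k = 3)
  expect_identical(cl1$assignments[cl1$gene_ids],
                   cl2$assignments[cl1$gene_ids])
})

test_that("cutting at k and k - 1 is a strict coarsening", {
  arch <- archetype_matrices(n_per = 10)
  cl4 <- cluster_profiles(arch$wt, arch$mut, k = 4)
  cl3 <- cluster_profiles(arch$wt, arch$mut, k = 3)
  # genes sharing a cluster at k = 4 still share one at k = 3
  for (c4 in unique(cl4$assignments)) {
    members <- names(cl4$assignments)[cl4$assignments == c4]
    expect_length(unique(cl3$assignments[members]), 1)
  }
})

test_that("constant profiles are excluded with a warning", {
  arch <- archetype_matrices(n_per = 5)
  wt <- unclass(arch$wt); wt[1, ] <- 0
  mut <- unclass(arch$mut); mut[1, ] <- 0
  em <- function(v) expression_matrix(v, ab_times, gene_ids = arch$ids,
                                      experiment = "abundance",
                                      scale = "log2_to_t0")
  expect_warning(cl <- cluster_profiles(em(wt), em(mut), k = 3),
                 "constant")
  expect_false(arch$ids[1] %in% cl$gene_ids)
})

test_that("per-cluster slopes flag impaired stability modulation", {
  set.seed(72)
  ids <- paste0("g", 1:60)
  wt <- data.frame(gene_id = ids, delta = rnorm(60, -0.5, 0.6))
  # mutant modulates identically in cluster 1, at 40% in cluster 2
  mut <- data.frame(gene_id = ids,
                    delta = c(wt$delta[1:30],
                              0.4 * wt$delta[31:60] + rnorm(30, 0, 0.05)))
  fake <- list(gene_ids = ids, assignments = stats::setNames(
    rep(1:2, each = 30), ids), k = 2)
  out <- cluster_stability_slopes(fake, wt, mut)
  expect_equal(out$slope[1], 1, tolerance = 0.05)
  expect_false(out$impaired[1])
  expect_equal(out$slope[2], 0.4, tolerance = 0.1)
  expect_true(out$impaired[2])
  # too-small clusters are reported, not fitted
  fake$assignments[1:58] <- 1; fake$k <- 2
  out2 <- cluster_stability_slopes(fake, wt, mut)
  expect_true(is.na(out2$slope[2]))
})

test_that("dendrograms export as parseable Newick trees", {
  arch <- archetype_matrices(n_per = 4)
  cl <- cluster_profiles(arch$wt, arch$mut, k = 2)
  path <- withr::local_tempfile(fileext = ".nwk")
  write_dendrogram_newick(cl, path)
  tree <- ape::read.tree(path)
  expect_setequal(tree$tip.label, cl$gene_ids)
})
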