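test_that("a perfect anti-correlation is fitted exactly", {
  x <- seq(-2, 2, length.out = 20)
  fit <- coupling_fit(-x, x)
  expect_equal(fit$slope, -1)
  expect_equal(fit$pearson_r, -1)
  expect_equal(fit$slope_ci95, c(-1, -1), tolerance = 1e-9)
  expect_gt(fit$neg_log10_p, 50)
  expect_error(coupling_fit(1:2, 1:2), "3 finite")
})

test_that("coupling_fit matches the closed-form normal equations", {
  set.seed(61)
  for (i in 1:5) {
    x <- rnorm(50); y <- -0.5 * x + rnorm(50, 0, 0.3)
    fit <- coupling_fit(y, x)
    slope <- (mean(x * y) - mean(x) * mean(y)) /
      (mean(x ^ 2) - mean(x) ^ 2)
    expect_equal(fit$slope, slope, tolerance = 1e-10)
    expect_equal(fit$intercept, mean(y) - slope * mean(x),
                 tolerance = 1e-10)
  }
})

test_that("independent variables show no coupling", {
  set.seed(62)
  x <- rnorm(1000); y <- rnorm(1000)
  fit <- coupling_fit(y, x)
  expect_lt(abs(fit$pearson_r), 0.1)
  expect_true(fit$slope_ci95[1] < 0 && fit$slope_ci95[2] > 0)
})

test_that("genes classify by symmetric linear thresholds", {
  lab <- classify_changes(max_fc = c(1.5, 0, -1.2, 0.5),
                          delta = c(-1, 0, 0.9, 0.3),
                          fc_threshold = 1.75, hl_threshold = 1.5)
  expect_equal(as.character(lab$abundance),
               c("induced", "neutral", "repressed", "neutral"))
  expect_equal(as.character(lab$stability),
               c("destabilized", "unchanged", "stabilized", "unchanged"))
})

test_that("fold enrichment follows the observed-over-expected formula", {
  lab <- data.frame(
    abundance = factor(rep(c("induced", "neutral"), c(20, 80)),
                       c("induced", "neutral", "repressed")),
    stability = factor(c(rep("destabilized", 12), rep("unchanged", 8),
                         rep("destabilized", 18), rep("unchanged", 62)),
                       c("stabilized", "unchanged", "destabilized")))
  fe <- fold_enrichment(lab)
  cell <- fe[fe$abundance == "induced" & fe$stability == "destabilized", ]
  expect_equal(cell$observed, 12)
  expect_equal(cell$expected, 6)   # 30% destabilized genome-wide x 20 genes
  expect_equal(cell$enrichment, 2)
  # empty group reported as missing
  rep_cell <- fe[fe$abundance == "repressed", ]
  expect_true(all(is.na(rep_cell$enrichment)))
  # saturated cell: enrichment is the reciprocal of the genome fraction
  lab2 <- data.frame(
    abundance = factor(rep(c("induced", "neutral"), c(10, 90)),
                       c("induced", "neutral", "repressed")),
    stability = factor(rep(c("destabilized", "unchanged"), c(30, 70))[
      c(1:10, 11:100)], c("stabilized", "unchanged", "destabilized")))
  fe2 <- fold_enrichment(lab2)
  cell2 <- fe2[fe2$abundance == "induced" & fe2$stability == "destabilized", ]
  expect_equal(cell2$enrichment, 1 / 0.3)
})

test_that("fold enrichment agrees with brute-force contingency counting", {
  set.seed(63)
  for (i in 1:10) {
    n <- sample(20:50, 1)
    lab <- data.frame(
      abundance = factor(sample(c("induced", "neutral", "repressed"), n,
                                replace = TRUE),
                         c("induced", "neutral", "repressed")),
      stability = factor(sample(c("stabilized", "unchanged", "destabilized"),
                                n, replace = TRUE),
                         c("stabilized", "unchanged", "destabilized")))
    fe <- fold_enrichment(lab)
    for (r in seq_len(nrow(fe))) {
      obs <- 0; grp <- 0; hit <- 0
      for (g in seq_len(n)) {         # explicit enumeration
        in_grp <- lab$abundance[g] == fe$abundance[r]
        is_hit <- lab$stability[g] == fe$stability[r]
        grp <- grp + in_grp; hit <- hit + is_hit
        obs <- obs + (in_grp && is_hit)
      }
      expect_equal(fe$observed[r], obs)
      expect_equal(fe$expected[r], hit / n * grp)
      if (grp > 0 && hit > 0) {
        # hypergeometric tail against the Fisher oracle
        ft <- fisher.test(matrix(c(obs, grp - obs, hit - obs,
                                   n - grp - hit + obs), 2),
                          alternative = "greater")
        expect_equal(fe$p_hyper[r], ft$p.value, tolerance = 1e-9)
      }
    }
  }
})

test_that("label permutation gives near-null enrichments", {
  set.seed(64)
  n <- 600
  lab <- data.frame(
    abundance = factor(sample(rep(c("induced", "neutral", "repressed"),
                                  c(200, 200, 200))),
                       c("induced", "neutral", "repressed")),
    stability = factor(sample(rep(c("stabilized", "unchanged",
                                    "destabilized"), c(150, 300, 150))),
                       c("stabilized", "unchanged", "destabilized")))
  fe <- fold_enrichment(lab)
  expect_true(all(fe$enrichment > 0.7 & fe$enrichment < 1.4))
  expect_true(all(fe$p_hyper > 0.01))
})

test_that("identical strains give a degenerate basal comparison", {
  times <- c(0, 5, 10, 20, 30, 40, 50)
  hl <- do.call(rbind, lapply(1:6, function(i)
    fit_decay(-times / (8 + i), times, gene_id = paste0("g", i))))
  t0 <- stats::setNames(runif(6, 10, 100), hl$gene_id)
  out <- basal_comparison(t0, t0, hl, hl, gene_ids = hl$gene_id)
  expect_equal(out$table$x, rep(0, 6))
  expect_equal(out$table$y, rep(0, 6))
  expect_equal(out$median_x, 0)
  expect_null(out$fit)
})

test_that("permuting genes between axes removes the basal association", {
  st <- default_study()
  hw <- filter_fits(est_halflives(st, "wild_type.reference_decay"))
  hm <- filter_fits(est_halflives(st, "mutant.reference_decay"))
  t0 <- function(strain) {
    key <- paste0(strain, ".reference_decay")
    drop(spike_in_normalize(unclass(st$observed[[key]])[, 1],
                            st$spike_ins[[key]][1],
                            reference_level = 1000))
  }
  wt0 <- t0("wild_type"); mut0 <- t0("mutant")
  out <- basal_comparison(wt0, mut0, hw, hm, gene_ids = names(wt0))
  expect_lt(out$fit$slope, 0)
  set.seed(65)
  perm <- out$table
  perm$y <- sample(perm$y)
  null_fit <- coupling_fit(perm$y, perm$x)
  expect_true(null_fit$slope_ci95[1] < 0 && null_fit$slope_ci95[2] > 0)
})
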