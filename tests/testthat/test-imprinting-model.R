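test_that("machinery shares follow imprinted copies and sum to one", {
  # equal imprinted fractions at equal abundance: uniform allocation
  s <- machinery_shares(model_state(0, I = c(30, 30), U = c(70, 70)))
  expect_equal(s, c(0.5, 0.5))
  # unequal fractions at equal totals: shares proportional to the fractions
  s <- machinery_shares(model_state(0, I = c(80, 20), U = c(20, 80)))
  expect_equal(s, c(0.8, 0.2))
  # empty genome / empty pools
  expect_equal(machinery_shares(model_state(0, c(0, 0), c(0, 0))), c(0, 0))
  expect_length(machinery_shares(model_state(0, numeric(0), numeric(0))), 0)
  # shares sum to 1 whenever any pool is non-empty
  set.seed(7)
  for (i in 1:20) {
    st <- model_state(0, runif(10) * rbinom(10, 1, 0.7), runif(10))
    s <- machinery_shares(st)
    expect_true(sum(s) %in% c(0, 1) || abs(sum(s) - 1) < 1e-12)
  }
})

test_that("machinery flux never exceeds the pool capacity", {
  genes <- tiny_genes(5, beta = 3)
  params <- imprinting_params(D = 1.5, k_U = 0.05, lambda_max = 0.5)
  state <- steady_state(genes, params)
  for (i in 1:50) {
    s <- machinery_shares(state)
    flux <- sum(pmin(params$D * s, params$lambda_max * state$I))
    expect_lte(flux, params$D + 1e-9)
    state <- model_step(state, genes, params)
  }
})

test_that("an isolated pool with no machinery decays exponentially", {
  genes <- tiny_genes(1, beta = 0)
  params <- imprinting_params(D = 0, k_U = 0.1, lambda_max = 0, dt = 0.05)
  state <- model_state(0, I = 100, U = 0)
  for (i in seq_len(200)) state <- model_step(state, genes, params)
  expect_equal(state$t, 10)
  # explicit Euler at dt = 0.05 tracks the closed form to ~0.3%
  expect_equal(state$I, 100 * exp(-0.1 * 10), tolerance = 5e-3)
  expect_equal(state$U, 0)
})

test_that("the fixed-point steady state is stationary under stepping", {
  genes <- gene_params(gene_id = c("a", "b", "c"),
                      beta_basal = c(1, 2.5, 4), affinity = c(0.6, 0.8, 1))
  params <- imprinting_params(D = 5, k_U = 0.03, lambda_max = 0.05)
  st0 <- steady_state(genes, params)
  st1 <- model_step(st0, genes, params, p = params$p_basal)
  # drift per step is O(dt^2)
  expect_lt(max(abs(st1$I - st0$I)), 1e-6 * max(st0$I))
  expect_lt(max(abs(st1$U - st0$U)), 1e-6 * max(st0$U))
  # matches analytic single-gene solution when machinery is molecule-limited
  g1 <- tiny_genes(1, beta = 2)
  p1 <- imprinting_params(D = 100, k_U = 0.03, lambda_max = 0.02)
  s1 <- steady_state(g1, p1)
  q <- 0.3
  expect_equal(s1$U, (1 - q) * 2 / 0.03, tolerance = 1e-10)
  expect_equal(s1$I, q * 2 / (0.03 + 0.02), tolerance = 1e-8)
})

test_that("identical genes follow identical trajectories", {
  genes <- tiny_genes(2, beta = 2, class = "induced")
  genes$phi_amplitude <- 8
  params <- imprinting_params(D = 3, k_U = 0.03, lambda_max = 0.05)
  sc <- run_scenario(genes, params, "stress_decay")
  expect_equal(sc$total[1, ], sc$total[2, ])
})

test_that("machinery off yields a uniform first-order half-life", {
  genes <- tiny_genes(4, beta = 2)
  params <- imprinting_params(D = 0, k_U = 0.0693, lambda_max = 0)
  for (scen in c("reference_decay", "stress_decay")) {
    sc <- run_scenario(genes, params, scen)
    # explicit Euler at dt = 0.05 carries an O(k dt / 2) rate bias
    expect_equal(unname(sc$truth$true_halflife),
                 rep(log(2) / 0.0693, 4), tolerance = 3e-3)
  }
})

test_that("scenario sampling grids match the assay design", {
  genes <- tiny_genes(2)
  params <- imprinting_params()
  expect_equal(run_scenario(genes, params, "reference_decay")$sample_times,
               c(0, 5, 10, 20, 30, 40, 50))
  expect_equal(run_scenario(genes, params, "stress_abundance")$sample_times,
               c(0, 5, 10, 15, 25, 35, 45))
  expect_error(run_scenario(genes, params, "stress_decay",
                            sample_times = c(0, 500)), "t_end")
})

test_that("imprinted fraction rises for induced genes and falls without synthesis", {
  genes <- gene_params(gene_id = c("ind", "off"),
                      beta_basal = c(2, 2),
                      stress_class = c("induced", "repressed"),
                      phi_amplitude = c(8, 1e-9), phi_shape = "step")
  params <- imprinting_params(D = 1e6, k_U = 0.035, lambda_max = 0.008)
  state <- steady_state(genes, params)
  f_prev <- state$I / (state$I + state$U)
  ok_up <- TRUE; ok_down <- TRUE
  for (i in seq_len(600)) {
    beta <- genes$beta_basal * phi_profile(genes, state$t)
    beta[2] <- 0                       # fully repressed: no synthesis at all
    state <- model_step(state, genes, params, beta = beta,
                        p = params$p_stress)
    f <- state$I / (state$I + state$U)
    if (f[1] < f_prev[1] - 1e-12) ok_up <- FALSE
    if (f[2] > f_prev[2] + 1e-12) ok_down <- FALSE
    f_prev <- f
  }
  expect_true(ok_up)
  expect_true(ok_down)
})

test_that("trajectories are converged in the integration step", {
  genes <- tiny_genes(3, beta = 2, class = "induced")
  genes$phi_amplitude <- c(8, 4, 2)
  p1 <- imprinting_params(D = 6, k_U = 0.035, lambda_max = 0.02, dt = 0.05)
  p2 <- imprinting_params(D = 6, k_U = 0.035, lambda_max = 0.02, dt = 0.005)
  s1 <- run_scenario(genes, p1, "stress_decay")
  s2 <- run_scenario(genes, p2, "stress_decay")
  expect_lt(max(abs(s1$total - s2$total) / s2$total), 0.005)
})

test_that("stress multiplier profiles start at 1 and approach their targets", {
  genes <- gene_params(gene_id = c("p", "s"), beta_basal = 1,
                      phi_amplitude = c(8, 8), phi_shape = c("pulse", "step"))
  expect_equal(phi_profile(genes, 0), c(1, 1))
  expect_equal(phi_profile(genes, -5), c(1, 1))
  # step saturates at the amplitude; pulse peaks at it then relaxes
  expect_equal(phi_profile(genes, 500)[2], 8, tolerance = 1e-6)
  peak <- max(sapply(seq(0, 60, 0.25), function(t) phi_profile(genes, t)[1]))
  expect_equal(peak, 8, tolerance = 1e-3)
  expect_lt(phi_profile(genes, 120)[1], 1.1)
})
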