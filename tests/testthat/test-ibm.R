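test_that("compiled and reference single steps are bit-identical", {
  cfg <- ibm_config("mss", r = 5, K = 100, d = 0.05, m = 0.5, sigma = 0.1)
  set.seed(321)
  b0 <- runif(150, 0.17, 15)
  set.seed(99)
  ref <- ibm_step(b0, cfg)
  set.seed(99)
  rec <- run_ibm(b0, cfg, generations = 1, hist_at = 1)
  expect_identical(ref, rec$histograms[[1]])
  # and with the trade-off modification active
  cfgm <- ibm_config("mss", r = 5, K = 100, d = 0.05, m = 0.5,
                     mod = tradeoff_mod())
  set.seed(7); refm <- ibm_step(b0, cfgm)
  set.seed(7); recm <- run_ibm(b0, cfgm, generations = 1, hist_at = 1)
  expect_identical(refm, recm$histograms[[1]])
})

test_that("identical seeds reproduce identical trajectories", {
  cfg <- ibm_config("mss", r = 5, K = 200, d = 0.05, m = 0.3, seed = 42)
  r1 <- run_ibm(NULL, cfg, 400, record_every = 50)
  r2 <- run_ibm(NULL, cfg, 400, record_every = 50)
  expect_identical(r1$record, r2$record)
  expect_identical(r1$final_b, r2$final_b)
})

test_that("without mutation the strategy set is closed under inheritance", {
  cfg <- ibm_config("mss", r = 5, K = 300, d = 0.05, m = 0, seed = 5)
  init <- rep(c(1, 2.5, 4), each = 100)
  rec <- run_ibm(init, cfg, 300)
  expect_true(all(rec$final_b %in% c(1, 2.5, 4)))
  # monomorphic stays monomorphic
  rec1 <- run_ibm(rep(2, 300), cfg, 200)
  expect_true(all(rec1$final_b == 2))
})

test_that("the empty population is absorbing", {
  cfg <- ibm_config("mss", r = 5, K = 100, d = 0.05)
  expect_identical(ibm_step(numeric(0), cfg), numeric(0))
  # a non-viable configuration dies and the record keeps later checkpoints
  cfg_dead <- ibm_config("mss", r = 5, K = 100, d = 0.75, seed = 9)
  rec <- run_ibm(rep(1, 5), cfg_dead, 200, record_every = 50)
  expect_identical(tail(rec$record$N, 1), 0)
  expect_identical(max(rec$record$generation), 200L)
  expect_length(rec$final_b, 0)
})

test_that("checkpoint generations are strictly increasing and quantiles
           are ordered", {
  cfg <- ibm_config("mss", r = 5, K = 500, d = 0.05, m = 0.3, seed = 11)
  rec <- run_ibm(NULL, cfg, 500, record_every = 100, hist_at = c(250, 500))
  g <- rec$record$generation
  expect_true(all(diff(g) > 0))
  alive <- rec$record$N > 0
  expect_true(all(rec$record$q05[alive] <= rec$record$median_b[alive]))
  expect_true(all(rec$record$median_b[alive] <= rec$record$q95[alive]))
  expect_named(rec$histograms, c("250", "500"))
})

test_that("replicate-mean of the monomorphic IBM tracks the deterministic
           map", {
  cfg <- ibm_config("mss", r = 5, K = 1000, d = 0.05, m = 0)
  p <- growth_params("mss", r = 5, K = 1000, b = 2, d = 0.05)
  det <- iterate_map(p, 200, 60)$sizes
  set.seed(14)
  n_rep <- 60
  mat <- matrix(NA_real_, n_rep, 61)
  for (i in seq_len(n_rep))
    mat[i, ] <- run_ibm(rep(2, 200), cfg, 60, record_every = 1)$record$N
  mm <- colMeans(mat)
  se <- apply(mat, 2, sd) / sqrt(n_rep)
  z <- (mm[-1] - det[-1]) / se[-1]
  expect_lt(max(abs(z)), 4)
})

test_that("invasion estimates carry coherent probability scaffolding", {
  cfg <- ibm_config("mss", r = 5, K = 200, d = 0.05, seed = 3)
  est <- invasion_probability(1, 3, cfg, n_reps = 120)
  expect_s3_class(est, "invasion_estimate")
  expect_true(est$p >= 0 && est$p <= 1)
  expect_equal(est$q, 1 - est$p)
  expect_equal(est$q, est$q_ext^(1 / 3))
  expect_gt(est$se_p, 0)
  # a hopeless invader: strong overcompensation is not viable at K = 200
  est12 <- invasion_probability(1, 12, cfg, n_reps = 60)
  expect_lt(est12$p, 0.05)
  # mutual invasibility around (1, 4)
  e_ab <- invasion_probability(1, 4, cfg, n_reps = 150)
  e_ba <- invasion_probability(4, 1, cfg, n_reps = 150)
  expect_gt(e_ab$p, 0.05)
  expect_gt(e_ba$p, 0.05)
  # a non-viable resident is rejected up front
  expect_error(invasion_probability(1, 2,
    ibm_config("mss", r = 5, K = 200, d = 0.85)), "not viable")
})

test_that("neutral pairs drift to exclusion with exchangeable winners", {
  cfg <- ibm_config("mss", r = 5, K = 200, d = 0.05, seed = 21)
  cs <- coexistence_time(1.3, 1.3, cfg, max_gen = 1e5, n_reps = 40)
  expect_identical(cs$censored_fraction, 0)
  w1 <- mean(cs$winners == 1)
  expect_gt(w1, 0.2)  # 4 sigma around 1/2 at 40 replicates
  expect_lt(w1, 0.8)
  # censoring is reported, not fabricated
  cs2 <- coexistence_time(0.9, 5.4, cfg, max_gen = 50, n_reps = 4)
  expect_identical(cs2$censored_fraction, 1)
  expect_true(all(cs2$times == 50))
})

test_that("unequal pairs far from the coexistence curve are excluded
           faster than neutral ones, with a deterministic winner", {
  cfg <- ibm_config("mss", r = 5, K = 200, d = 0.05, seed = 31)
  neu <- coexistence_time(1.5, 1.5, cfg, max_gen = 1e5, n_reps = 30)
  far <- coexistence_time(1, 2, cfg, max_gen = 1e5, n_reps = 30)
  expect_lt(far$mean_time, neu$mean_time)
  expect_identical(far$typical_winner, "b2")
  expect_gt(mean(far$winners == 2), 0.9)
})

test_that("branch detection clusters strategy histograms by gaps", {
  # monomorphic: one cluster at that strategy
  br <- detect_branches(rep(2.2, 500), sigma = 0.1)
  expect_identical(br$n_branches, 1L)
  expect_equal(br$means, 2.2)
  # clean bimodal: two clusters with the right means
  set.seed(17)
  b <- c(rnorm(400, 1, 0.05), rnorm(600, 5, 0.05))
  br2 <- detect_branches(b, sigma = 0.1)
  expect_identical(br2$n_branches, 2L)
  expect_equal(br2$means, c(1, 5), tolerance = 0.05)
  expect_equal(br2$masses, c(0.4, 0.6), tolerance = 0.01)
  # a sub-threshold satellite cluster is dropped as mutational fringe
  b3 <- c(rnorm(950, 1, 0.05), rnorm(50, 5, 0.05))
  br3 <- detect_branches(b3, sigma = 0.1)
  expect_identical(br3$n_branches, 1L)
  # empty population: zero clusters
  expect_identical(detect_branches(numeric(0))$n_branches, 0L)
})

test_that("evolution runs are reproducible and expose convergence
           diagnostics", {
  cfg <- ibm_config("mss", r = 5, K = 300, d = 0.05, m = 0.3, seed = 8)
  rec <- evolve_to_equilibrium(cfg, generations = 4000, record_every = 100)
  expect_false(rec$extinct)
  expect_true(is.finite(rec$evolved_mean_b))
  rec2 <- evolve_to_equilibrium(cfg, generations = 4000, record_every = 100)
  expect_identical(rec$record, rec2$record)
})
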