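test_that("reproduction ratio pivots at the carrying capacity", {
  # f(K) = 1 - d exactly, for every model and strategy: the trade-off pivot
  for (m in names(model_presets)) {
    for (b in c(0.17, 0.5, 1, 2.5, 6, 15)) {
      for (d in c(0, 0.05, 0.3)) {
        p <- growth_params(model_presets[[m]]$model,
                           r = model_presets[[m]]$r, K = 100, b = b, d = d)
        expect_equal(reproduction_ratio(p, 100), 1 - d, tolerance = 1e-12)
      }
    }
  }
  # limits of the MSS form
  p <- growth_params("mss", r = 5, K = 100, b = 2, d = 0.05)
  expect_equal(reproduction_ratio(p, 0), 4.75)
  p0 <- growth_params("mss", r = 5, K = 100, b = 2, d = 0)
  expect_identical(reproduction_ratio(p0, 100), 1)
})

test_that("growth trade-off: b raises growth below K and lowers it above", {
  Nlo <- c(5, 20, 50, 80, 95)
  Nhi <- c(105, 120, 150, 200)
  bs <- c(0.3, 0.8, 1.5, 3, 6, 12)
  for (m in names(model_presets)) {
    f_of_b <- function(N) vapply(bs, function(b) {
      p <- growth_params(model_presets[[m]]$model,
                         r = model_presets[[m]]$r, K = 100, b = b, d = 0.05)
      reproduction_ratio(p, N)
    }, numeric(1))
    for (N in Nlo) expect_true(all(diff(f_of_b(N)) > 0), label = paste(m, N))
    for (N in Nhi) expect_true(all(diff(f_of_b(N)) < 0), label = paste(m, N))
    # and f strictly decreasing in N for fixed b
    for (b in bs) {
      p <- growth_params(model_presets[[m]]$model,
                         r = model_presets[[m]]$r, K = 100, b = b, d = 0.05)
      expect_true(all(diff(reproduction_ratio(p, c(Nlo, 100, Nhi))) < 0))
    }
  }
})

test_that("parameter validation rejects out-of-domain input", {
  expect_error(growth_params("mss", r = 0.9, K = 100, b = 1), "exceed 1")
  expect_error(growth_params("mss", r = 5, K = 100, b = 1, d = 1), "0, 1")
  expect_error(growth_params("mss", r = 5, K = -1, b = 1))
  p <- growth_params("mss", r = 5, K = 100, b = 1, d = 0.05)
  expect_error(reproduction_ratio(p, -1), "nonnegative")
})

test_that("equilibrium density solves f(N) = 1", {
  # d = 0: equilibrium exactly at K for every model
  for (m in names(model_presets)) {
    p <- growth_params(model_presets[[m]]$model, r = model_presets[[m]]$r,
                       K = 250, b = 2, d = 0)
    expect_identical(equilibrium_density(p), 250)
  }
  # d > 0: root search agrees with the closed-form inversion, and sits
  # slightly below K
  for (b in c(0.5, 1, 2, 4)) {
    p <- growth_params("mss", r = 5, K = 100, b = b, d = 0.05)
    Nhat <- equilibrium_density(p)
    expect_lt(Nhat, 100)
    expect_equal(Nhat, mss_nhat_closed(5, 100, b, 0.05), tolerance = 1e-10)
    expect_lt(abs(reproduction_ratio(p, Nhat) - 1), 1e-10)
  }
  # non-viable: (1-d) r <= 1
  p_bad <- growth_params("mss", r = 5, K = 100, b = 1, d = 0.85)
  expect_error(equilibrium_density(p_bad), "no positive equilibrium")
})

test_that("complexity matches linearization and finite differences", {
  # d = 0 closed form for MSS: c = 1 - b (r-1)/r
  for (b in c(0.5, 1, 2.5, 4)) {
    p <- growth_params("mss", r = 5, K = 100, b = b, d = 0)
    expect_equal(complexity(p), 1 - b * 4 / 5, tolerance = 1e-12)
  }
  # the marginal case: b = 2.5 at r = 5, d = 0 gives exactly c = -1
  p <- growth_params("mss", r = 5, K = 100, b = 2.5, d = 0)
  expect_equal(complexity(p), -1, tolerance = 1e-12)
  # analytic and finite-difference paths agree across models and mortality
  for (m in names(model_presets)) {
    for (b in c(0.6, 1.7, 3.2)) {
      p <- growth_params(model_presets[[m]]$model, r = model_presets[[m]]$r,
                         K = 100, b = b, d = 0.05)
      expect_equal(complexity(p, method = "analytic"), fd_complexity(p),
                   tolerance = 1e-6)
    }
  }
  # b -> 0: density-independent limit has unit slope
  p <- growth_params("mss", r = 5, K = 100, b = 1e-8, d = 0)
  expect_equal(complexity(p), 1, tolerance = 1e-6)
})

test_that("critical strategy solves c = -1", {
  expect_equal(critical_b("mss", 5, 0), 2.5, tolerance = 1e-8)
  expect_equal(critical_b("mss", 10, 0), 20 / 9, tolerance = 1e-8)
  expect_equal(critical_b("mss", 5, 0.05), mss_bcri_closed(5, 0.05),
               tolerance = 1e-8)
  expect_equal(critical_b("ricker", 0.5, 0.05), ricker_bcri_closed(0.5, 0.05),
               tolerance = 1e-8)
  # b_cri decreases with growth rate (MSS, d = 0)
  expect_lt(critical_b("mss", 10, 0), critical_b("mss", 5, 0))
  # residual of the defining equation
  for (m in names(model_presets)) {
    bc <- critical_b(model_presets[[m]]$model, model_presets[[m]]$r, 0.05)
    p <- growth_params(model_presets[[m]]$model, r = model_presets[[m]]$r,
                       K = 1, b = bc, d = 0.05)
    expect_lt(abs(complexity(p) + 1), 1e-7)
  }
})

test_that("map iteration: fixed points hold and overcompensation cycles", {
  p <- growth_params("mss", r = 5, K = 100, b = 1, d = 0.05)
  Nhat <- equilibrium_density(p)
  tr <- iterate_map(p, Nhat, 50)
  expect_equal(tr$sizes, rep(Nhat, 51), tolerance = 1e-12)
  # subcritical: converges to the equilibrium
  tr <- iterate_map(p, 10, 500)
  expect_equal(tail(tr$sizes, 1), Nhat, tolerance = 1e-8)
  # strongly overcompensating: no convergence, many distinct values
  p6 <- growth_params("mss", r = 5, K = 100, b = 6, d = 0.05)
  tr6 <- iterate_map(p6, 50, 1500)
  att <- round(tail(tr6$sizes, 200), 6)
  expect_gt(length(unique(att)), 2)
})

test_that("bifurcation scan period-doubles at the critical strategy", {
  bc <- critical_b("mss", 5, 0.05)
  b_grid <- seq(1, 4, by = 0.05)
  scan <- bifurcation_scan("mss", r = 5, d = 0.05, b_grid = b_grid, K = 1,
                           burn_in = 2000, sample = 60)
  card <- attractor_cardinality(scan)
  expect_true(all(card$n_attractor[card$b < bc - 0.05] == 1))
  expect_true(all(card$n_attractor[card$b > bc + 0.05 & card$b < 3.3] == 2))
  first_super <- min(card$b[card$n_attractor > 1])
  expect_lt(abs(first_super - bc), 0.05 + 1e-9)
})

test_that("trade-off modification maps strategies as documented", {
  mod <- tradeoff_mod(b_low = 0.8, b_up = 5, scaling = 2)
  # midpoint below K: b_m = b_low + 0.25 (b_up - b_low)
  expect_equal(modified_b(2.9, 50, 100, mod), 0.8 + 0.25 * 4.2)
  # at/above K the exponent inverts
  expect_equal(modified_b(2.9, 150, 100, mod), 0.8 + sqrt(0.5) * 4.2)
  # neutral scaling is the identity
  mod1 <- tradeoff_mod(scaling = 1)
  expect_equal(modified_b(c(1, 2, 4.9), 50, 100, mod1), c(1, 2, 4.9))
  # outside the band, disabled, or NULL: identity
  expect_equal(modified_b(c(0.5, 5, 7), 50, 100, mod), c(0.5, 5, 7))
  expect_equal(modified_b(2, 50, 100, tradeoff_mod(enabled = FALSE)), 2)
  expect_equal(modified_b(2, 50, 100, NULL), 2)
  # continuity at the pivots and containment in [b_low, b_up]
  eps <- 1e-9
  expect_equal(modified_b(0.8 + eps, 30, 100, mod), 0.8, tolerance = 1e-6)
  expect_equal(modified_b(5 - eps, 30, 100, mod), 5, tolerance = 1e-4)
  bs <- seq(0.81, 4.99, length.out = 50)
  bm <- modified_b(bs, 10, 100, mod)
  expect_true(all(bm >= 0.8 & bm <= 5))
  # f stays continuous in N at N = K because f(K) is b-independent
  p <- growth_params("mss", r = 5, K = 100, b = 2.5, d = 0.05)
  expect_equal(reproduction_ratio(p, 100 - 1e-9, mod),
               reproduction_ratio(p, 100 + 1e-9, mod), tolerance = 1e-6)
  # pluggable mapping is honored
  modc <- tradeoff_mod(map = function(b, N, K, b_low, b_up, s) b * 0 + 1.23)
  expect_equal(modified_b(2, 50, 100, modc), 1.23)
})

test_that("parameter sets round-trip through the flat config mapping", {
  p <- growth_params("hassell", r = 40, K = 500, b = 3.3, d = 0.1)
  mod <- tradeoff_mod(b_low = 0.7, b_up = 6, scaling = 4)
  back <- config_to_params(params_to_config(p, mod))
  expect_equal(back$params, p)
  expect_equal(back$mod[c("b_low", "b_up", "scaling", "enabled")],
               mod[c("b_low", "b_up", "scaling", "enabled")])
  plain <- config_to_params(params_to_config(p))
  expect_null(plain$mod)
})
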