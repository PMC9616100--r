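test_that("binding_params validates and derives constants", {
  expect_error(binding_params(1, 1, 1e6, 1, k_if = 2), "together")
  expect_error(binding_params(0, 1, 1e6, 1), "> 0")
  p <- binding_params(6e-4, 2e-4, 1e6, 276)
  cn <- binding_constants(p)
  expect_equal(cn$K1, 1 / 3)
  expect_equal(cn$K2, 276e-6)
  expect_equal(cn$p_active, 0.75)
  expect_null(cn$K3)
})

test_that("simulate_binding reduces to pseudo-first-order 1:1 binding", {
  # conformational step much faster than binding, K1 -> 0
  p <- binding_params(k_ia = 1e4, k_ai = 1e-4, k_on = 1e6, k_off = 10)
  L <- 1e-4; E0 <- 1e-6                      # L = 100 E0
  kobs <- p$k_on * L + p$k_off
  tt <- seq(1e-4, 6 / kobs, length.out = 100)
  tr <- simulate_binding(p, L, E0, tt)
  AL_inf <- E0 * L / (L + p$k_off / p$k_on)
  oracle <- AL_inf * (1 - exp(-kobs * tt))
  expect_lt(max(abs(tr$AL - oracle)) / AL_inf, 5e-3)
})

test_that("zero ligand gives pure two-state relaxation", {
  p <- variant_preset("HG3")$binding
  tt <- seq(1, 10000, length.out = 80)
  sc <- binding_scheme(p)
  # micromolar concentrations: tighten atol so it does not dominate rtol
  tr <- integrate_scheme(sc, c(I = 1e-6, A = 0, L = 0, AL = 0), tt,
                         rtol = 1e-9, atol = 1e-18)
  oracle <- 0.75 * (1 - exp(-(p$k_ia + p$k_ai) * tt)) * 1e-6
  expect_lt(max(abs(tr$A - oracle)) / 1e-6, 1e-5)
  expect_true(all(tr$AL == 0))
})

test_that("detailed balance holds at long times", {
  p <- variant_preset("HG3.17")$binding
  tr <- simulate_binding(p, 2e-5, 1e-6, c(1e5, 2e5))
  fin <- tr[2, ]
  cn <- binding_constants(p)
  expect_rel_equal(fin$I / fin$A, cn$K1, 1e-3)
  expect_rel_equal(fin$A * fin$L / fin$AL, cn$K2, 1e-3)
  expect_rel_equal(fin$AL / fin$ALs, cn$K3, 1e-3)
})

test_that("fit_exponential_phases recovers rates and flags degeneracy", {
  tt <- seq(0.001, 1.5, length.out = 120)
  set.seed(5)
  y <- 1 + 0.5 * exp(-5 * tt) + stats::rnorm(120, 0, 0.005)
  f <- fit_exponential_phases(kk_timeseries(tt, y), 1L)
  expect_lt(abs(f$rates[1] - 5), 0.1)

  flat <- kk_timeseries(tt, rep(1, 120) + stats::rnorm(120, 0, 1e-4))
  ff <- fit_exponential_phases(flat, 1L)
  expect_true("degenerate" %in% ff$flags)

  # widely separated phases both recovered within 5%
  tl <- exp(seq(log(1e-4), log(8000), length.out = 220))
  y2 <- 1 + 0.4 * exp(-100 * tl) + 0.3 * exp(-1e-3 * tl)
  f2 <- fit_exponential_phases(kk_timeseries(tl, y2), 2L)
  expect_rel_equal(f2$rates[1], 100, 0.05)
  expect_rel_equal(f2$rates[2], 1e-3, 0.05)

  # close rates are flagged unresolved
  y3 <- 1 + 0.4 * exp(-2 * tt) + 0.3 * exp(-4 * tt)
  f3 <- fit_exponential_phases(kk_timeseries(tt, y3), 2L, seed = 2)
  expect_true("unresolved" %in% f3$flags)

  expect_error(fit_exponential_phases(kk_timeseries(1:5, 1:5), 1L), "10 points")
})

test_that("BIC phase selection picks the generating phase count", {
  tl <- exp(seq(log(1e-3), log(5000), length.out = 200))
  y <- 1 + 0.4 * exp(-50 * tl) + 0.3 * exp(-5e-3 * tl)
  set.seed(8)
  yn <- y + stats::rnorm(200, 0, 0.003)
  f <- fit_exponential_phases(kk_timeseries(tl, yn), "auto")
  expect_equal(f$n_phases, 2L)
})

test_that("closed-form kobs has the right limits and matches the ODE", {
  p <- binding_params(k_ia = 5e-4, k_ai = 5e-4, k_on = 1e6, k_off = 50)
  K2 <- 5e-5
  ks <- predict_kobs_curve(p, c(0, 1e30), "CS")
  expect_equal(ks$kobs[1], 1e-3)             # L = 0: sum of rates
  expect_rel_equal(ks$kobs[2], 5e-4, 1e-6)   # L -> Inf: k_ia

  pif <- binding_params(1e-3, 1e-3, 1e6, 50, k_if = 3, k_ir = 1)
  ki <- predict_kobs_curve(pif, c(0, 1e30), "IF")
  expect_equal(ki$kobs[1], 1)                # L = 0: k_ir
  expect_rel_equal(ki$kobs[2], 4, 1e-6)      # L -> Inf: k_ir + k_if

  # ODE + phase fitting agrees with the closed form within 5% when the
  # binding step is >= 100x faster than the conformational step
  for (L in K2 * c(0.5, 2, 8)) {
    ds <- gen_stopped_flow(p, L, 1e-7, dead_time = 1e-4, n_points = 220,
                           t_end = 2e4, noise = noise_model(0))
    f <- fit_exponential_phases(ds$traces[[1]], 2L)
    expect_rel_equal(f$rates[2], predict_kobs_curve(p, L, "CS")$kobs, 0.05)
  }
})

test_that("mechanism classification separates CS, IF and noise", {
  p <- binding_params(5e-4, 5e-4, 1e6, 50)
  L <- 5e-5 * c(0.3, 1, 3, 10, 30)
  expect_equal(classify_mechanism(predict_kobs_curve(p, L, "CS")),
               "conformational-selection")
  pif <- binding_params(1e-3, 1e-3, 1e6, 50, k_if = 3, k_ir = 1)
  expect_equal(classify_mechanism(predict_kobs_curve(pif, L, "IF")),
               "induced-fit")
  set.seed(3)
  flat <- list(ligand_concs = L, kobs = 1e-3 * (1 + stats::rnorm(5, 0, 0.3)))
  expect_equal(classify_mechanism(flat), "ambiguous")
  expect_error(classify_mechanism(list(ligand_concs = L[1:3], kobs = 1:3)),
               ">= 4")
})

test_that("macroscopic K_D formula matches limits and titration oracle", {
  # K1 = 0 limit: K_D = K2
  p0 <- binding_params(k_ia = 1, k_ai = 1e-9, k_on = 1e6, k_off = 10)
  expect_rel_equal(macroscopic_kd(p0), 1e-5, 1e-6)
  # K1 = 1: K_D = 2 K2
  p1 <- binding_params(k_ia = 1e-3, k_ai = 1e-3, k_on = 1e6, k_off = 10)
  expect_rel_equal(macroscopic_kd(p1), 2e-5, 1e-6)
  # arbitrary draws against the brute-force equilibrium titration
  set.seed(14)
  for (i in 1:4) {
    has_if <- i > 2
    pars <- binding_params(k_ia = 10^stats::runif(1, -4, -1),
                           k_ai = 10^stats::runif(1, -4, -1),
                           k_on = 10^stats::runif(1, 5, 7),
                           k_off = 10^stats::runif(1, -1, 3),
                           k_if = if (has_if) 10^stats::runif(1, -2, 2),
                           k_ir = if (has_if) 10^stats::runif(1, -2, 2))
    expect_rel_equal(titration_midpoint_kd(pars), macroscopic_kd(pars), 5e-3)
  }
})

test_that("global binding fit recovers a noiseless CS dataset to 0.1%", {
  p <- variant_preset("HG3.7")$binding
  L <- binding_constants(p)$K2 * c(0.5, 1, 2, 4, 8)
  ds <- gen_stopped_flow(p, L, 5e-7, n_points = 90, noise = noise_model(0))
  fit <- global_fit_binding(ds, scheme = "cs",
                            fixed = c(k_ia = p$k_ia, k_ai = p$k_ai),
                            n_starts = 8L, seed = 2)
  expect_rel_equal(fit$params$k_on, p$k_on, 1e-3)
  expect_rel_equal(fit$params$k_off, p$k_off, 1e-3)
  expect_rel_equal(fit$constants$KD_macro, macroscopic_kd(p), 1e-3)
})

test_that("wrong fixed interconversion rates degrade the fit residuals", {
  p <- variant_preset("HG3")$binding
  L <- binding_constants(p)$K2 * c(0.5, 1, 2, 4)
  ds <- gen_stopped_flow(p, L, 5e-7, n_points = 70,
                         noise = noise_model(0.002, 9))
  good <- global_fit_binding(ds, "cs", fixed = c(k_ia = p$k_ia, k_ai = p$k_ai),
                             n_starts = 6L, seed = 2)
  bad <- global_fit_binding(ds, "cs",
                            fixed = c(k_ia = p$k_ia * 10, k_ai = p$k_ai / 10),
                            n_starts = 6L, seed = 2)
  expect_gt(bad$rss / good$rss, 2)
})

test_that("unidentifiable parameters are flagged, not silently reported", {
  # an induced-fit step fitted to data generated without one
  p <- variant_preset("HG3")$binding
  L <- binding_constants(p)$K2 * c(0.5, 1, 2, 4)
  ds <- gen_stopped_flow(p, L, 5e-7, n_points = 60,
                         noise = noise_model(0.002, 4))
  fit <- global_fit_binding(ds, "cs-if",
                            fixed = c(k_ia = p$k_ia, k_ai = p$k_ai),
                            n_starts = 6L, seed = 3)
  expect_true(any(grepl("unidentifiable", fit$flags)))
})
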