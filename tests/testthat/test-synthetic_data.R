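hg3 <- variant_preset("HG3")

test_that("generators are deterministic under a fixed seed", {
  ds1 <- gen_stopped_flow(hg3$binding, c(1e-4, 5e-4), 5e-7, n_points = 40,
                          noise = noise_model(0.01, seed = 7))
  ds2 <- gen_stopped_flow(hg3$binding, c(1e-4, 5e-4), 5e-7, n_points = 40,
                          noise = noise_model(0.01, seed = 7))
  f1 <- tempfile(); f2 <- tempfile()
  write_timeseries_csv(ds1$traces[[2]], f1)
  write_timeseries_csv(ds2$traces[[2]], f2)
  expect_identical(readLines(f1), readLines(f2))
  # different traces get independent noise streams
  expect_false(identical(ds1$traces[[1]]$values - ds2$traces[[1]]$values * 0,
                         ds1$traces[[2]]$values))
})

test_that("equal fluorescence coefficients give flat traces", {
  ds <- gen_stopped_flow(hg3$binding, 2e-4, 1e-6, n_points = 50,
                         fluor_coeffs = c(I = 2, A = 2, AL = 2, ALs = 2),
                         noise = noise_model(0))
  v <- ds$traces[[1]]$values
  expect_lt(diff(range(v)) / abs(mean(v)), 1e-6)
})

test_that("CS slow-phase amplitude fraction equals the initial inactive fraction", {
  # K2 = 10 uM; L = 50 K2 so nearly all enzyme ends bound; dead time kept
  # small so the fast binding phase is observed
  p <- binding_params(k_ia = 7.5e-4, k_ai = 2.5e-4, k_on = 1e6, k_off = 10)
  ds <- gen_stopped_flow(p, 50 * 1e-5, 1e-6, n_points = 250,
                         dead_time = 1e-5, noise = noise_model(0))
  f <- fit_exponential_phases(ds$traces[[1]], 2L)
  slow_frac <- abs(f$amplitudes[2]) / sum(abs(f$amplitudes))
  expect_equal(slow_frac, 0.25, tolerance = 0.05)
  # and the slow rate approaches k_ia
  expect_rel_equal(f$rates[2], 7.5e-4, 0.05)
})

test_that("stopped-flow generator validates concentrations and dead time", {
  expect_error(gen_stopped_flow(hg3$binding, c(-1e-5), 1e-6), "positive")
  expect_error(gen_stopped_flow(hg3$binding, 5e-6, 1e-6,
                                pseudo_first_order = TRUE), "10")
  ds <- gen_stopped_flow(hg3$binding, 1e-4, 1e-6, n_points = 30,
                         dead_time = 2e-3, noise = noise_model(0))
  expect_gte(min(ds$traces[[1]]$times), 2e-3)
})

test_that("progress generator honours limits and first-order oracle", {
  mm <- variant_preset("HG3")$mm
  expect_error(gen_progress_curves(mm, 2e-3, 1e-6, 100), "solubility")

  # k_cat = 0: flat baseline
  mm0 <- mm_extended_params(k_ia = 1, k_ai = 1e-9, k1 = 1e6, k_minus1 = 100,
                            k_cat = 0, kp_on = 1e6, kp_off = 100,
                            eps_path = 4000, baseline = 0.1)
  suppressWarnings(
    ds0 <- gen_progress_curves(mm0, 1e-4, 1e-6, 100, n_points = 30,
                               noise = noise_model(0)))
  expect_lt(diff(range(ds0$traces[[1]]$values)), 1e-9)

  # no product inhibition, fully active, S0 << K_S: initial slope =
  # (k_cat/K_S) E0 S0 eps within 1%
  mm1 <- mm_extended_params(k_ia = 1, k_ai = 1e-9, k1 = 1e6, k_minus1 = 1000,
                            k_cat = 1, kp_on = 1e6, kp_off = 1e6,
                            eps_path = 4000, baseline = 0)
  S0 <- 1e-6; E0 <- 1e-6    # S0 = K_S/1000
  suppressWarnings(
    ds1 <- gen_progress_curves(mm1, S0, E0, 50, n_points = 400,
                               noise = noise_model(0)))
  tr <- ds1$traces[[1]]
  slope <- (tr$values[3] - tr$values[2]) / (tr$times[3] - tr$times[2])
  expect_rel_equal(slope, (1 / 1e-3) * E0 * S0 * 4000, 0.01)
})

test_that("doubling E0 halves the time to 50% conversion (first-order regime)", {
  mm1 <- mm_extended_params(k_ia = 1, k_ai = 1e-9, k1 = 1e6, k_minus1 = 1000,
                            k_cat = 1, kp_on = 1e6, kp_off = 1e6,
                            eps_path = 4000, baseline = 0)
  t50 <- function(E0) {
    ts <- simulate_progress(mm1, 1e-5, E0, seq(0, 20000, length.out = 4000))
    conv <- ts$values / (4000 * 1e-5)
    sel <- conv < 0.95      # strictly monotone segment, no interpolation ties
    stats::approx(conv[sel], ts$times[sel], xout = 0.5)$y
  }
  expect_rel_equal(t50(1e-6) / t50(2e-6), 2, 0.01)
})

test_that("NMR peak generator obeys its closed-form structure", {
  # p = 0: no area in the minor region
  sp0 <- gen_nmr_peaks(0, c(8.3, 8.8), noise = noise_model(0))
  expect_lt(abs(integrate_peak(sp0, c(8.7, 8.9), baseline = "none")), 5e-3)

  # p = 0.5, equal widths: equal heights
  sp5 <- gen_nmr_peaks(0.5, c(8.3, 8.8), widths_hz = 20, noise = noise_model(0))
  h1 <- max(sp5$values[abs(sp5$times - 8.3) < 0.1])
  h2 <- max(sp5$values[abs(sp5$times - 8.8) < 0.1])
  expect_rel_equal(h1, h2, 1e-3)

  # quadrature on the noiseless spectrum recovers p to < 0.1% of total;
  # needs well-separated narrow lines (Lorentzian cross-talk between the
  # half-spectrum windows scales as width / separation)
  p_true <- 0.37
  sp <- gen_nmr_peaks(p_true, c(7.8, 9.8), widths_hz = 6, pad = 40,
                      noise = noise_model(0))
  vA <- integrate_peak(sp, c(6.8, 8.8), baseline = "none")
  vI <- integrate_peak(sp, c(8.8, 10.8), baseline = "none")
  expect_lt(abs(vI / (vA + vI) - p_true), 1e-3)

  expect_error(gen_nmr_peaks(0.5, c(8.3, 8.31), widths_hz = 20), "separation")
  expect_error(gen_nmr_peaks(1.2, c(8, 9)), "p_inactive")
})

test_that("pH-jump generator relaxes to equilibrium with rate k_ia + k_ai", {
  # start at equilibrium: flat
  ts_eq <- gen_ph_jump(7.5e-4, 2.5e-4, p_start = 0.75, noise = noise_model(0))
  expect_lt(diff(range(ts_eq$values)), 1e-12)

  ts <- gen_ph_jump(7.5e-4, 2.5e-4, p_start = 0.2, noise = noise_model(0))
  f <- fit_relaxation(ts)
  expect_rel_equal(f$k_obs, 1e-3, 1e-3)
  expect_equal(f$endpoint, 0.75, tolerance = 1e-3)

  # activity observable is linear in p_active: identical to peak-area
  ts2 <- gen_ph_jump(7.5e-4, 2.5e-4, p_start = 0.2, observable = "activity",
                     noise = noise_model(0))
  expect_equal(ts$values, ts2$values)
  expect_error(gen_ph_jump(1e-3, 1e-3, 0.2, t_end = 100), "3 relaxation")
})

test_that("noisy residuals about the truth model match the declared sigma", {
  sigma <- 0.02
  ts <- gen_ph_jump(7.5e-4, 2.5e-4, p_start = 0.2, n_points = 600,
                    noise = noise_model(sigma, seed = 21))
  truth <- 0.75 + (0.2 - 0.75) * exp(-1e-3 * ts$times)
  r <- ts$values - truth
  expect_lt(abs(mean(r)), 3 * sigma / sqrt(600))
  expect_lt(abs(stats::sd(r) / sigma - 1), 0.10)
})

test_that("datasets carry truth and provenance separately from the data", {
  ds <- gen_stopped_flow(hg3$binding, 1e-4, 1e-6, n_points = 20,
                         noise = noise_model(0.01, 3))
  expect_s3_class(ds, "kk_dataset")
  expect_identical(ds$provenance$generator, "gen_stopped_flow")
  expect_identical(ds$provenance$seed, 3L)
  expect_identical(ds$truth$params, hg3$binding)
})
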