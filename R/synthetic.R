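#' Additive-Gaussian noise model
#' @param sigma noise standard deviation in signal units (>= 0).
#' @param seed integer seed; identical seed implies identical datasets.
#' @export
noise_model <- function(sigma = 0, seed = 1L) {
  if (sigma < 0) stop("sigma must be >= 0")
  structure(list(kind = "additive-gaussian", sigma = sigma,
                 seed = as.integer(seed)), class = "noise_model")
}

add_noise <- function(values, noise, stream = 0L) {
  if (noise$sigma == 0) return(values)
  # independent, reproducible stream per trace
  rng <- local({
    set.seed(noise$seed + 1000L * stream)
    stats::rnorm(length(values), 0, noise$sigma)
  })
  values + rng
}

new_dataset <- function(traces, truth, generator, seed, extra = list()) {
  structure(list(traces = traces, truth = truth,
                 provenance = c(list(generator = generator,
                                     version = as.character(utils::packageVersion("confmodel")),
                                     seed = seed), extra)),
            class = "kk_dataset")
}

#' @export
print.kk_dataset <- function(x, ...) {
  cat(sprintf("<kk_dataset: %d traces from %s (seed %s)>\n",
              length(x$traces), x$provenance$generator, x$provenance$seed))
  invisible(x)
}

#' Named variant presets
#'
#' Generating parameter sets for the three characterised Kemp eliminase
#' variants.  Anchored quantities: TSA dissociation constants of the
#' physical binding step K2 = 276, 16.5 and 4.4 uM for HG3, HG3.7 and
#' HG3.17; inactive populations 25%/25%/5% at 25 C (42% for HG3.17 and 58%
#' for HG3.7 at 40 C); interconversion in the 1e-4..1e-3 s^-1 band; an
#' induced-fit step for HG3.17 only.  Association rates, induced-fit rates
#' and all steady-state turnover parameters are not printed in the source
#' text: the values here are physically plausible synthetic choices,
#' recorded in the generator provenance.
#'
#' @param variant `"HG3"`, `"HG3.7"` or `"HG3.17"`.
#' @return list with `binding` ([binding_params()]), `mm`
#'   ([mm_extended_params()]), `p_inactive_25C`, `p_inactive_40C` (may be
#'   NA), `k_obs`, `induced_fit`.
#' @export
variant_preset <- function(variant = c("HG3", "HG3.7", "HG3.17")) {
  variant <- match.arg(variant)
  presets <- list(
    "HG3" = list(
      k_ia = 6e-4, k_ai = 2e-4,              # p_I = 0.25, k_obs = 8e-4
      K2 = 276e-6, k_on = 1e6, induced_fit = FALSE,
      p_inactive_25C = 0.25, p_inactive_40C = NA_real_,
      k_cat = 0.6, K_S = 1.0e-3, K_P = 5e-5),
    "HG3.7" = list(
      k_ia = 3.75e-4, k_ai = 1.25e-4,        # p_I = 0.25, k_obs = 5e-4
      K2 = 16.5e-6, k_on = 1e6, induced_fit = FALSE,
      p_inactive_25C = 0.25, p_inactive_40C = 0.58,
      k_cat = 18, K_S = 4.5e-4, K_P = 2e-4),
    "HG3.17" = list(
      k_ia = 3.8e-4, k_ai = 2e-5,            # p_I = 0.05, k_obs = 4e-4
      K2 = 4.4e-6, k_on = 1e6, induced_fit = TRUE,
      k_if = 2, k_ir = 1,                    # K3 = 0.5
      p_inactive_25C = 0.05, p_inactive_40C = 0.42,
      k_cat = 40, K_S = 3.0e-4, K_P = 1e-3))
  p <- presets[[variant]]
  bind <- binding_params(k_ia = p$k_ia, k_ai = p$k_ai, k_on = p$k_on,
                         k_off = p$K2 * p$k_on,
                         k_if = if (p$induced_fit) p$k_if else NULL,
                         k_ir = if (p$induced_fit) p$k_ir else NULL)
  # eps_path: product extinction (~1.6e4 /M/cm) times a short plate-reader
  # path (~0.25 cm) keeps absorbance in the detector's linear range
  mm <- mm_extended_params(k_ia = p$k_ia, k_ai = p$k_ai,
                           k1 = 1e6, k_minus1 = p$K_S * 1e6,
                           k_cat = p$k_cat, kp_on = 1e6,
                           kp_off = p$K_P * 1e6,
                           eps_path = 4000, baseline = 0.05)
  list(variant = variant, binding = bind, mm = mm,
       p_inactive_25C = p$p_inactive_25C, p_inactive_40C = p$p_inactive_40C,
       k_obs = p$k_ia + p$k_ai, induced_fit = p$induced_fit)
}

#' Synthetic stopped-flow binding traces
#'
#' Simulates the fluorescence response of mixing pre-equilibrated enzyme
#' with a ladder of TSA concentrations under the conformational-selection
#' (+ induced-fit) scheme.  The signal is linear in the state populations;
#' an instrument dead time (default 1.5 ms) is removed from the front of
#' each trace by starting the reported grid there.
#'
#' @param params a [binding_params()].
#' @param ligand_concs ligand concentrations (M), one trace each.
#' @param E0 total enzyme (M).
#' @param t_end trace end (s); default covers five slow relaxation times.
#' @param n_points points per trace (log-spaced).
#' @param fluor_coeffs named fluorescence coefficient per species
#'   (I, A, AL and, with induced fit, ALs), in signal units per M.  The
#'   default normalises by `E0` so the pre-mix signal is ~1 and binding
#'   quenches it (Trp fluorescence-style).
#' @param noise a [noise_model()].
#' @param dead_time instrument dead time (s) truncated from the front.
#' @param pseudo_first_order if TRUE, require `ligand_concs >= 10 * E0`.
#' @return `kk_dataset`; each trace carries `meta$L`, `meta$E0`.
#' @export
gen_stopped_flow <- function(params, ligand_concs, E0,
                             t_end = NULL, n_points = 150L,
                             fluor_coeffs = NULL,
                             noise = noise_model(0), dead_time = 1.5e-3,
                             pseudo_first_order = FALSE) {
  if (any(ligand_concs <= 0) || E0 <= 0)
    stop("concentrations must be positive")
  if (pseudo_first_order && any(ligand_concs < 10 * E0))
    stop("pseudo-first-order flag requires ligand_concs >= 10 * E0")
  if (is.null(fluor_coeffs))
    fluor_coeffs <- c(I = 1, A = 1, AL = 0.6, ALs = 0.45) / E0
  if (is.null(t_end)) t_end <- 5 / params$k_ia
  times <- exp(seq(log(dead_time), log(t_end), length.out = n_points))
  species <- c("I", "A", "AL", if (!is.null(params$k_if)) "ALs")
  traces <- vector("list", length(ligand_concs))
  for (i in seq_along(ligand_concs)) {
    traj <- simulate_binding(params, ligand_concs[i], E0, times)
    sig <- rep(0, n_points)
    for (s in species) sig <- sig + fluor_coeffs[[s]] * traj[[s]]
    traces[[i]] <- kk_timeseries(times, add_noise(sig, noise, stream = i),
                                 sigma = if (noise$sigma > 0) noise$sigma,
                                 meta = list(L = ligand_concs[i], E0 = E0,
                                             kind = "stopped-flow"))
  }
  new_dataset(traces, truth = list(params = params,
                                   fluor_coeffs = fluor_coeffs),
              generator = "gen_stopped_flow", seed = noise$seed,
              extra = list(dead_time = dead_time, noise_sigma = noise$sigma))
}

#' Synthetic absorbance progress curves
#'
#' Full substrate-depletion curves of 5-nitrobenzisoxazole conversion under
#' the extended Michaelis-Menten scheme, reported as absorbance
#' `eps_path * [P] + baseline` on a linear time grid.
#'
#' @param params a [mm_extended_params()].
#' @param S0_list initial substrate concentrations (M), one curve each.
#' @param E0 total enzyme (M).
#' @param t_end end time (s).
#' @param n_points points per curve.
#' @param noise a [noise_model()].
#' @param solubility_ceiling maximum admissible S0 (default 1 mM, mirroring
#'   the substrate's limited solubility).
#' @return `kk_dataset`; provenance records a warning when `t_end` is too
#'   short for 99% conversion.
#' @export
gen_progress_curves <- function(params, S0_list, E0, t_end, n_points = 200L,
                                noise = noise_model(0),
                                solubility_ceiling = 1e-3) {
  if (any(S0_list <= 0) || E0 < 0) stop("concentrations must be positive")
  if (any(S0_list > solubility_ceiling))
    stop(sprintf("S0 exceeds the solubility ceiling (%g M)", solubility_ceiling))
  times <- seq(0, t_end, length.out = n_points)
  traces <- vector("list", length(S0_list))
  warn <- character(0)
  for (i in seq_along(S0_list)) {
    ts <- simulate_progress(params, S0_list[i], E0, times)
    conv_end <- (ts$values[n_points] - params$baseline) / (params$eps_path * S0_list[i])
    if (conv_end < 0.99)
      warn <- c(warn, sprintf("curve %d reaches only %.1f%% conversion at t_end",
                              i, 100 * conv_end))
    traces[[i]] <- kk_timeseries(times, add_noise(ts$values, noise, stream = i),
                                 sigma = if (noise$sigma > 0) noise$sigma,
                                 meta = list(S0 = S0_list[i], E0 = E0,
                                             kind = "progress"))
  }
  new_dataset(traces, truth = list(params = params),
              generator = "gen_progress_curves", seed = noise$seed,
              extra = list(noise_sigma = noise$sigma, warnings = warn))
}

#' Synthetic slow-exchange NMR peak pair (1D trace)
#'
#' Two Lorentzians with areas `(1 - p_inactive)` and `p_inactive` times
#' `total_area`, centred at `centers` (ppm) with full widths at half
#' maximum given in Hz (converted to ppm via the spectrometer frequency).
#' The slow-exchange regime requires the peak separation to exceed three
#' times the widest line.
#'
#' @param p_inactive inactive fraction in \[0, 1\].
#' @param centers length-2 ppm positions, `c(active, inactive)`.
#' @param widths_hz FWHM in Hz (recycled to length 2).
#' @param total_area total integrated area (signal x ppm units).
#' @param noise a [noise_model()].
#' @param sfreq spectrometer frequency (MHz) for the Hz -> ppm conversion.
#' @param n_points points across the spectrum.
#' @param pad half-width multiples of padding beyond the outer peaks.
#' @return [kk_timeseries()] whose axis is ppm (increasing).
#' @export
gen_nmr_peaks <- function(p_inactive, centers, widths_hz = 20,
                          total_area = 1, noise = noise_model(0),
                          sfreq = 600, n_points = 4096L, pad = 25) {
  if (p_inactive < 0 || p_inactive > 1) stop("p_inactive must be in [0, 1]")
  stopifnot(length(centers) == 2L)
  widths_hz <- rep_len(widths_hz, 2L)
  w_ppm <- widths_hz / sfreq                       # FWHM in ppm
  sep <- abs(diff(centers))
  if (sep < 3 * max(w_ppm))
    stop("peak separation must be >= 3x the maximum linewidth (slow exchange)")
  lo <- min(centers) - pad * max(w_ppm)
  hi <- max(centers) + pad * max(w_ppm)
  x <- seq(lo, hi, length.out = n_points)
  lorentz <- function(x0, fwhm, area) {
    g <- fwhm / 2
    area / pi * g / ((x - x0)^2 + g^2)
  }
  y <- lorentz(centers[1], w_ppm[1], (1 - p_inactive) * total_area) +
       lorentz(centers[2], w_ppm[2], p_inactive * total_area)
  kk_timeseries(x, add_noise(y, noise, stream = 1L),
                sigma = if (noise$sigma > 0) noise$sigma,
                meta = list(kind = "nmr-spectrum", centers = centers,
                            widths_hz = widths_hz, p_inactive = p_inactive,
                            sfreq = sfreq))
}

#' Synthetic pH-jump relaxation series
#'
#' Two-state repopulation after a rapid pH change: the active fraction
#' relaxes from `p_start` to its equilibrium value `k_ia/(k_ia + k_ai)`
#' with rate `k_obs = k_ia + k_ai`.  The reported signal is linear in the
#' active fraction; coefficients depend on the observable.
#'
#' @param k_ia,k_ai interconversion rates (s^-1).
#' @param p_start active fraction at t = 0 (e.g. the high-pH equilibrium).
#' @param t_end series end (s); must cover >= 3 relaxation times.
#' @param n_points number of samples.
#' @param observable `"peak-area"` (signal = p_active), `"activity"`
#'   (signal = p_active) or `"fluorescence"` (signal = 1 - 0.3 p_active).
#' @param noise a [noise_model()].
#' @return [kk_timeseries()] with the truth in `meta`.
#' @export
gen_ph_jump <- function(k_ia, k_ai, p_start, t_end = NULL, n_points = 60L,
                        observable = c("peak-area", "activity", "fluorescence"),
                        noise = noise_model(0)) {
  observable <- match.arg(observable)
  k_obs <- k_ia + k_ai
  if (is.null(t_end)) t_end <- 5 / k_obs
  if (t_end < 3 / k_obs) stop("t_end must cover >= 3 relaxation times")
  times <- seq(0, t_end, length.out = n_points)
  p_eq <- k_ia / k_obs
  p_act <- p_eq + (p_start - p_eq) * exp(-k_obs * times)
  sig <- switch(observable,
                "peak-area" = p_act,
                "activity" = p_act,
                "fluorescence" = 1 - 0.3 * p_act)
  kk_timeseries(times, add_noise(sig, noise, stream = 1L),
                sigma = if (noise$sigma > 0) noise$sigma,
                meta = list(kind = "relaxation", k_obs = k_obs,
                            p_eq = p_eq, observable = observable))
}

#' Ladder of ligand concentrations for a binding preset
#' @param preset output of [variant_preset()].
#' @param n number of concentrations.
#' @keywords internal
preset_ligand_ladder <- function(preset, n = 6L) {
  K2 <- binding_constants(preset$binding)$K2
  K2 * 2^seq(-2, -2 + n - 1)
}
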