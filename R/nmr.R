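#' Inactive-state population from duplicated cross-peak volumes
#'
#' In slow exchange each conformer gives its own resonance and peak volumes
#' are proportional to populations (equal per-molecule intensity is assumed
#' for the two forms of the same residue and flagged as an assumption in
#' reports).  For a single peak pair `p_I = v_inactive / (v_active +
#' v_inactive)`; several residues are aggregated by inverse-variance
#' weighting, with residues deviating > 3 sd from the pooled estimate
#' flagged as outliers.
#'
#' @param volumes data.frame with columns `v_active`, `v_inactive` and
#'   optionally `residue`, `sd_active`, `sd_inactive`; or two scalars via
#'   `v_active=`, `v_inactive=`.
#' @param v_active,v_inactive scalar shortcut for a single pair.
#' @return list `p_inactive`, `sd`, `per_residue` (data.frame), `outliers`.
#' @export
population_from_volumes <- function(volumes = NULL, v_active = NULL,
                                    v_inactive = NULL) {
  if (is.null(volumes)) {
    volumes <- data.frame(v_active = v_active, v_inactive = v_inactive)
  }
  stopifnot(all(c("v_active", "v_inactive") %in% names(volumes)))
  va <- volumes$v_active; vi <- volumes$v_inactive
  if (any(va < 0 | vi < 0)) stop("volumes must be >= 0")
  tot <- va + vi
  if (any(tot <= 0)) stop("v_active + v_inactive must be > 0")
  p <- vi / tot
  # per-pair sd: propagated from volume sds when given
  if (all(c("sd_active", "sd_inactive") %in% names(volumes))) {
    sa <- volumes$sd_active; si <- volumes$sd_inactive
    sd_p <- sqrt((va * si)^2 + (vi * sa)^2) / tot^2
  } else sd_p <- rep(NA_real_, length(p))
  if (length(p) == 1L) {
    return(list(p_inactive = p, sd = sd_p, per_residue = NULL,
                outliers = character(0)))
  }
  # outliers flagged on a robust (median/MAD) scale, then excluded from the
  # pooled estimate; a plain sd would be inflated by the outlier itself
  med <- stats::median(p)
  scale_rob <- max(stats::mad(p), 1e-12)
  out_idx <- which(abs(p - med) > 3 * scale_rob)
  keep <- setdiff(seq_along(p), out_idx)
  if (!length(keep)) keep <- seq_along(p)
  w <- if (all(is.finite(sd_p)) && all(sd_p > 0)) 1 / sd_p^2 else rep(1, length(p))
  pbar <- sum(w[keep] * p[keep]) / sum(w[keep])
  scatter_sd <- stats::sd(p[keep]) / sqrt(length(keep))
  pooled_sd <- if (all(is.finite(sd_p))) max(sqrt(1 / sum(w[keep])), scatter_sd,
                                             na.rm = TRUE) else scatter_sd
  pbar <- min(max(pbar, min(p)), max(p))  # stay in the convex hull
  outliers <- if ("residue" %in% names(volumes)) as.character(volumes$residue[out_idx])
              else as.character(out_idx)
  list(p_inactive = pbar, sd = pooled_sd,
       per_residue = data.frame(
         residue = if ("residue" %in% names(volumes)) volumes$residue else seq_along(p),
         p_inactive = p, sd = sd_p),
       outliers = outliers)
}

#' Baseline-corrected numerical integral of a spectral window
#'
#' Trapezoidal integration of a 1D trace over `window`, after subtracting a
#' constant baseline estimated from the edge points of the window (median of
#' the outermost `edge_n` samples on each side), or a user-supplied value.
#'
#' @param spectrum [kk_timeseries()] whose "times" hold the frequency axis.
#' @param window numeric length-2, integration bounds on the frequency axis.
#' @param baseline `"edges"` (default), `"none"`, or a number.
#' @param edge_n samples per side used for the edge baseline.
#' @return numeric volume (signal units x axis units).
#' @export
integrate_peak <- function(spectrum, window, baseline = "edges", edge_n = 5L) {
  x <- spectrum$times; y <- spectrum$values
  sel <- x >= min(window) & x <= max(window)
  if (sum(sel) < 4L) stop("window contains too few points")
  xs <- x[sel]; ys <- y[sel]
  b <- if (identical(baseline, "edges")) {
    stats::median(c(utils::head(ys, edge_n), utils::tail(ys, edge_n)))
  } else if (identical(baseline, "none")) 0 else as.numeric(baseline)
  ys <- ys - b
  sum(diff(xs) * (utils::head(ys, -1) + utils::tail(ys, -1)) / 2)
}

#' Single-exponential relaxation fit
#'
#' Fits `S(t) = S_inf + (S_0 - S_inf) exp(-k_obs t)` for pH-jump style
#' series (peak areas, activity, fluorescence).  For a two-state
#' interconversion `k_obs = k_ia + k_ai`.  A Wald confidence interval on
#' `k_obs` and a residual runs test are reported; series in which the rate
#' or the amplitude is indistinguishable from zero return
#' `detected = FALSE` ("no relaxation detected").
#'
#' @param series [kk_timeseries()] (>= 6 points spanning >= 2 relaxation
#'   times for a trustworthy rate).
#' @param seed multistart seed.
#' @return list `k_obs`, `k_obs_ci`, `endpoint` (S_inf), `amplitude`
#'   (S_0 - S_inf), `detected`, `runs_p`, `fit` (`kk_fit`).
#' @export
fit_relaxation <- function(series, seed = 1L) {
  stopifnot(inherits(series, "kk_timeseries"))
  t <- series$times; yv <- series$values
  if (length(t) < 6L) stop("need >= 6 points")
  # degenerate flat series: compare scatter about mean vs best exponential
  f <- tryCatch(fit_exponential_phases(series, 1L, seed = seed),
                error = function(e) NULL)
  if (is.null(f))
    return(list(k_obs = NA_real_, k_obs_ci = c(NA_real_, NA_real_),
                endpoint = mean(yv), amplitude = 0, detected = FALSE,
                runs_p = NA_real_, fit = NULL))
  k <- f$rates[1]; amp <- f$amplitudes[1]
  # se on log k from the fit; rate "includes 0" when CI lower bound has
  # e^(log k - 1.96 se) indistinguishable from 0 relative to the time window
  se_logk <- f$se[1]
  ci <- exp(log(k) + c(-1.96, 1.96) * se_logk)
  resid <- f$resid
  runs_p <- runs_test_p(resid)
  degenerate <- "degenerate" %in% f$flags
  span <- diff(range(t))
  detected <- !degenerate && is.finite(se_logk) && se_logk < 1 &&
    k * span > 0.5  # at least half a relaxation time observed
  list(k_obs = if (detected) k else NA_real_,
       k_obs_ci = if (detected) ci else c(NA_real_, NA_real_),
       endpoint = f$offset, amplitude = amp,
       detected = detected, runs_p = runs_p, fit = f)
}

# two-sided runs test on residual signs (normal approximation)
runs_test_p <- function(r) {
  s <- sign(r); s <- s[s != 0]
  n1 <- sum(s > 0); n2 <- sum(s < 0)
  if (n1 == 0 || n2 == 0) return(NA_real_)
  runs <- 1 + sum(diff(s) != 0)
  mu <- 2 * n1 * n2 / (n1 + n2) + 1
  v <- 2 * n1 * n2 * (2 * n1 * n2 - n1 - n2) /
    ((n1 + n2)^2 * (n1 + n2 - 1))
  if (v <= 0) return(NA_real_)
  2 * stats::pnorm(-abs((runs - mu) / sqrt(v)))
}

#' Microscopic interconversion rates from k_obs and the active population
#'
#' For a two-state system the relaxation rate is the sum of the forward and
#' reverse rate constants; combining it with the equilibrium populations
#' splits it: `k_ina->act = p_active * k_obs`, `k_act->ina = (1 - p_active)
#' * k_obs` (the two always sum to `k_obs` exactly).
#'
#' @param k_obs observed relaxation rate (s^-1).
#' @param p_active active-state fraction, strictly inside (0, 1).
#' @param sd_kobs,sd_p optional standard errors, propagated in quadrature.
#' @return list `k_ina_act`, `k_act_ina` (each `value`/`sd`).
#' @export
activation_rate <- function(k_obs, p_active, sd_kobs = NULL, sd_p = NULL) {
  if (p_active <= 0 || p_active >= 1) stop("p_active must be in (0, 1)")
  kia <- p_active * k_obs
  kai <- (1 - p_active) * k_obs
  prop <- function(val, frac, sd_frac) {
    if (is.null(sd_kobs) && is.null(sd_p)) return(NA_real_)
    cv2 <- 0
    if (!is.null(sd_kobs)) cv2 <- cv2 + (sd_kobs / k_obs)^2
    if (!is.null(sd_p)) cv2 <- cv2 + (sd_p / frac)^2
    val * sqrt(cv2)
  }
  list(k_ina_act = list(value = kia, sd = prop(kia, p_active, sd_p)),
       k_act_ina = list(value = kai, sd = prop(kai, 1 - p_active, sd_p)))
}

#' Van't Hoff analysis of the active/inactive equilibrium
#'
#' Treats `K_eq = p_I / (1 - p_I) = [I]/[A]` and regresses `ln K_eq` on
#' `1/T`: slope `= -dH/R`, intercept `= dS/R`.  With exactly two
#' temperatures this reduces to the two-point formula.  Intended only for
#' interpolating populations between the measured temperatures.
#'
#' @param p_inactive inactive fractions strictly inside (0, 1).
#' @param temps_K matching temperatures in Kelvin (>= 2 distinct).
#' @return list `dH` (J/mol), `dS` (J/mol/K), `interpolate` =
#'   function(T_K) -> p_inactive.
#' @export
vant_hoff_shift <- function(p_inactive, temps_K) {
  if (length(p_inactive) != length(temps_K) || length(temps_K) < 2L)
    stop("need populations at >= 2 temperatures")
  if (any(p_inactive <= 0 | p_inactive >= 1))
    stop("populations must be strictly inside (0, 1)")
  if (length(unique(temps_K)) < 2L) stop("temperatures must differ")
  R <- 8.31446261815324
  lnK <- log(p_inactive / (1 - p_inactive))
  fit <- stats::lm(lnK ~ I(1 / temps_K))
  dH <- -unname(stats::coef(fit)[2]) * R
  dS <- unname(stats::coef(fit)[1]) * R
  list(dH = dH, dS = dS,
       interpolate = function(T_K) {
         K <- exp((dS - dH / T_K) / R)
         K / (1 + K)
       })
}
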