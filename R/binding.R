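#' Microscopic parameters of the TSA-binding schemes
#'
#' The minimal binding mechanism is conformational selection (a slow
#' inactive/active exchange of the free enzyme, I <-> A) followed by the
#' physical binding step (A + L <-> AL); the most evolved variant carries an
#' additional induced-fit step (AL <-> AL*).  Equilibrium constants are
#' derived, never stored:
#' \itemize{
#'   \item `K1 = k_ai / k_ia = [I]/[A]` (dimensionless; larger = more
#'     inactive),
#'   \item `K2 = k_off / k_on` (M; dissociation constant of the physical
#'     step),
#'   \item `K3 = k_ir / k_if = [AL]/[AL*]` (dimensionless).
#' }
#'
#' @param k_ia inactive -> active rate (s^-1).
#' @param k_ai active -> inactive rate (s^-1).
#' @param k_on bimolecular association rate (M^-1 s^-1).
#' @param k_off dissociation rate (s^-1).
#' @param k_if,k_ir optional induced-fit forward/reverse rates (s^-1);
#'   present together or absent together.
#' @return object of class `binding_params`.
#' @export
binding_params <- function(k_ia, k_ai, k_on, k_off, k_if = NULL, k_ir = NULL) {
  if (xor(is.null(k_if), is.null(k_ir)))
    stop("induced-fit rates k_if and k_ir must be given together")
  rates <- c(k_ia = k_ia, k_ai = k_ai, k_on = k_on, k_off = k_off)
  if (!is.null(k_if)) rates <- c(rates, k_if = k_if, k_ir = k_ir)
  if (any(rates <= 0)) stop("all rate constants must be > 0")
  structure(as.list(rates), class = "binding_params")
}

#' Derived equilibrium constants of a binding parameter set
#' @param params a [binding_params()].
#' @return list with K1, K2 (M), K3 (or NULL), p_active, and KD_macro (M).
#' @export
binding_constants <- function(params) {
  K1 <- params$k_ai / params$k_ia
  K2 <- params$k_off / params$k_on
  K3 <- if (!is.null(params$k_if)) params$k_ir / params$k_if else NULL
  list(K1 = K1, K2 = K2, K3 = K3,
       p_active = 1 / (1 + K1),
       KD_macro = macroscopic_kd(params))
}

#' @export
print.binding_params <- function(x, ...) {
  cn <- binding_constants(x)
  cat("<binding_params>\n")
  cat(sprintf("  k_ia = %.4g /s, k_ai = %.4g /s  (K1 = [I]/[A] = %.4g)\n",
              x$k_ia, x$k_ai, cn$K1))
  cat(sprintf("  k_on = %.4g /M/s, k_off = %.4g /s  (K2 = %.4g M)\n",
              x$k_on, x$k_off, cn$K2))
  if (!is.null(x$k_if))
    cat(sprintf("  k_if = %.4g /s, k_ir = %.4g /s  (K3 = [AL]/[AL*] = %.4g)\n",
                x$k_if, x$k_ir, cn$K3))
  cat(sprintf("  macroscopic K_D = %.4g M\n", cn$KD_macro))
  invisible(x)
}

#' Kinetic scheme for TSA binding
#'
#' Species `I`, `A`, `L`, `AL` (and `ALs` when induced fit is present).
#' @param params a [binding_params()].
#' @export
binding_scheme <- function(params) {
  has_if <- !is.null(params$k_if)
  species <- c("I", "A", "L", "AL", if (has_if) "ALs")
  reactions <- c("I -> A : k_ia", "A -> I : k_ai",
                 "A + L -> AL : k_on", "AL -> A + L : k_off",
                 if (has_if) c("AL -> ALs : k_if", "ALs -> AL : k_ir"))
  kinetic_scheme(species, as.list(reactions),
                 unlist(params),
                 name = if (has_if) "cs_if_binding" else "cs_binding")
}

#' Simulate a TSA-binding time course
#'
#' The free enzyme is pre-equilibrated between inactive and active states
#' (as in a stopped-flow experiment where enzyme is mixed with ligand), then
#' binding proceeds under mass action.
#'
#' @param params a [binding_params()].
#' @param L total ligand concentration (M).
#' @param E0 total enzyme concentration (M).
#' @param times output time grid (s).
#' @param rtol,atol integrator tolerances.
#' @return trajectory data.frame from [integrate_scheme()].
#' @export
simulate_binding <- function(params, L, E0, times, rtol = 1e-8, atol = 1e-12) {
  sc <- binding_scheme(params)
  p_act <- 1 / (1 + params$k_ai / params$k_ia)
  init <- c(I = E0 * (1 - p_act), A = E0 * p_act, L = L, AL = 0)
  if (!is.null(params$k_if)) init <- c(init, ALs = 0)
  integrate_scheme(sc, init, times, rtol = rtol, atol = atol)
}

#' Macroscopic dissociation constant implied by microscopic rates
#'
#' For conformational selection only, `K_D = K2 (1 + K1)`; with the
#' induced-fit extension, `K_D = K2 (1 + K1) / (1 + 1/K3)`.  Equals the free
#' ligand concentration at half-saturation of all bound forms.
#'
#' @param params a [binding_params()].
#' @return K_D in M.
#' @export
macroscopic_kd <- function(params) {
  cn <- list(K1 = params$k_ai / params$k_ia, K2 = params$k_off / params$k_on)
  kd <- cn$K2 * (1 + cn$K1)
  if (!is.null(params$k_if)) kd <- kd / (1 + params$k_if / params$k_ir)
  kd
}

#' Multi-exponential fit of a single trace
#'
#' Fits `S(t) = C + sum_i A_i exp(-k_i t)` by variable projection: the decay
#' rates are optimised by Levenberg-Marquardt in log space while amplitudes
#' and offset are profiled out linearly.  Rates closer than a factor 3 are
#' flagged `"unresolved"`; fits whose total amplitude is indistinguishable
#' from noise are flagged `"degenerate"`.
#'
#' @param trace a [kk_timeseries()].
#' @param n_phases number of exponential phases (1-3), or `"auto"` to select
#'   by BIC.
#' @param seed RNG seed for the multistart.
#' @return `kk_fit` with elements `rates` (fast -> slow), `amplitudes`,
#'   `offset`, `bic`, `n_phases`.
#' @export
fit_exponential_phases <- function(trace, n_phases = 1L, seed = 1L) {
  stopifnot(inherits(trace, "kk_timeseries"))
  if (identical(n_phases, "auto")) {
    fits <- lapply(1:3, function(np)
      tryCatch(fit_exponential_phases(trace, np, seed), error = function(e) NULL))
    fits <- Filter(Negate(is.null), fits)
    if (!length(fits)) stop("exponential fitting failed for 1-3 phases")
    return(fits[[which.min(vapply(fits, `[[`, numeric(1), "bic"))]])
  }
  n_phases <- as.integer(n_phases)
  stopifnot(n_phases >= 1L, n_phases <= 3L)
  t <- trace$times; yv <- trace$values
  if (length(t) < 10L * n_phases)
    stop("need >= 10 points per expected phase")
  w <- if (!is.null(trace$sigma)) 1 / rep_len(trace$sigma, length(t)) else rep(1, length(t))

  lin_solve <- function(logk) {
    X <- cbind(1, vapply(exp(logk), function(k) exp(-k * t), numeric(length(t))))
    fitc <- tryCatch(qr.coef(qr(X * w), yv * w), error = function(e) NULL)
    if (is.null(fitc) || any(!is.finite(fitc))) return(NULL)
    list(coef = fitc, model = drop(X %*% fitc))
  }
  resid_fn <- function(logk) {
    ls <- lin_solve(logk)
    if (is.null(ls)) stop("linear stage failed")
    (ls$model - yv) * w
  }
  span <- range(t[t > 0])
  center <- log(10^(seq(log10(1 / span[2]), log10(1 / max(span[1], 1e-12)),
                        length.out = n_phases + 2)[2:(n_phases + 1)]))
  fit <- multistart_fit(resid_fn, center, spread = log(30),
                        n_starts = 12L, seed = seed)
  ls <- lin_solve(fit$par)
  k <- exp(fit$par); ord <- order(-k)
  rates <- k[ord]
  amps <- ls$coef[-1][ord]
  res <- make_fit_result(fit, length(t))
  res$rates <- unname(rates)
  res$amplitudes <- unname(amps)
  res$offset <- unname(ls$coef[1])
  rss <- fit$rss
  res$bic <- length(t) * log(rss / length(t)) + (2 * n_phases + 1) * log(length(t))
  res$n_phases <- n_phases
  amp_scale <- sum(abs(amps))
  sd_resid <- stats::sd(ls$model - yv)
  if (!is.finite(amp_scale) || amp_scale < 5 * sd_resid ||
      amp_scale < 1e-12 * max(abs(yv), 1))
    res$flags <- c(res$flags, "degenerate")
  if (n_phases > 1L && any(rates[-n_phases] / rates[-1] < 3))
    res$flags <- c(res$flags, "unresolved")
  res
}

#' Closed-form slow-phase k_obs under rapid-equilibrium assumptions
#'
#' Conformational selection (binding fast relative to the conformational
#' step): `kobs = k_ia + k_ai / (1 + L/K2)`, decreasing in L.  Induced fit
#' (binding fast relative to the isomerisation): `kobs = k_ir +
#' k_if L / (L + K2)`, increasing in L.
#'
#' @param params a [binding_params()] (induced-fit rates required for
#'   `mechanism = "IF"`).
#' @param L_grid ligand concentrations (M).
#' @param mechanism `"CS"` or `"IF"`.
#' @return list of class `kobs_series`: `ligand_concs`, `kobs` (slow phase),
#'   `mechanism`.
#' @export
predict_kobs_curve <- function(params, L_grid, mechanism = c("CS", "IF")) {
  mechanism <- match.arg(mechanism)
  K2 <- params$k_off / params$k_on
  kobs <- if (mechanism == "CS") {
    params$k_ia + params$k_ai / (1 + L_grid / K2)
  } else {
    if (is.null(params$k_if)) stop("IF mechanism requires induced-fit rates")
    params$k_ir + params$k_if * L_grid / (L_grid + K2)
  }
  structure(list(ligand_concs = L_grid, kobs = kobs, mechanism = mechanism),
            class = "kobs_series")
}

#' Classify the binding mechanism from a slow-phase kobs series
#'
#' A slow-phase observed rate that decreases with ligand concentration is
#' the signature of conformational selection; an increasing one indicates
#' induced fit; anything flat or non-monotone within confidence is reported
#' ambiguous.
#'
#' @param kobs list/`kobs_series` with `ligand_concs` and `kobs` (and
#'   optionally `kobs_se`).
#' @param conf confidence level for the trend test.
#' @details The trend is tested by regressing kobs on log ligand
#'   concentration (both mechanisms are monotone in L, and the log axis
#'   spreads the leverage of a geometric concentration ladder evenly).
#' @return one of `"conformational-selection"`, `"induced-fit"`,
#'   `"ambiguous"`.
#' @export
classify_mechanism <- function(kobs, conf = 0.95) {
  L <- kobs$ligand_concs; y <- kobs$kobs
  if (length(L) < 4L) stop("need >= 4 ligand concentrations")
  if (max(L) / min(L) < 10) stop("ligand concentrations must span >= 10-fold")
  lL <- log(L)
  fit <- stats::lm(y ~ lL)
  ci <- stats::confint(fit, "lL", level = conf)
  if (ci[2] < 0) "conformational-selection"
  else if (ci[1] > 0) "induced-fit"
  else "ambiguous"
}

#' Global fit of stopped-flow binding traces
#'
#' Fits one microscopic parameter set simultaneously to traces recorded at a
#' ladder of ligand concentrations.  Fluorescence coefficients (one per
#' species, shared across traces) are profiled out linearly at every
#' residual evaluation (variable projection), so only the rate constants are
#' optimised nonlinearly, in log space, with a seeded multistart.
#'
#' By default `k_ia`/`k_ai` are fixed to values determined independently by
#' the NMR interconversion analysis, mirroring the combined experimental
#' strategy; pass them in `free` to co-fit.
#'
#' @param dataset a `kk_dataset` from [gen_stopped_flow()] or a list of
#'   [kk_timeseries()] each carrying `meta$L` and `meta$E0`.
#' @param scheme `"cs"` (conformational selection + binding) or `"cs-if"`
#'   (additional induced-fit step).
#' @param fixed named numeric of fixed rates; must contain `k_ia`, `k_ai`
#'   unless those names appear in `free`.
#' @param free character vector of rates to optimise (default: binding and,
#'   for `"cs-if"`, induced-fit rates).
#' @param n_starts,seed multistart control.
#' @param rtol integrator tolerance used inside the fit.
#' @return `kk_fit` with `params` ([binding_params()]), `constants`
#'   (K1/K2/K3/KD_macro), `coefficients` (profiled fluorescence
#'   coefficients).
#' @export
global_fit_binding <- function(dataset, scheme = c("cs", "cs-if"),
                               fixed = NULL, free = NULL,
                               n_starts = 16L, seed = 1L, rtol = 1e-7) {
  scheme <- match.arg(scheme)
  traces <- if (inherits(dataset, "kk_dataset")) dataset$traces else dataset
  if (length(traces) < 4L) stop("need traces at >= 4 ligand concentrations")
  all_rates <- c("k_ia", "k_ai", "k_on", "k_off",
                 if (scheme == "cs-if") c("k_if", "k_ir"))
  if (is.null(free))
    free <- setdiff(all_rates, c("k_ia", "k_ai"))
  fixed <- unlist(fixed)
  missing_fixed <- setdiff(setdiff(all_rates, free), names(fixed))
  if (length(missing_fixed))
    stop("fix or free these rates: ", paste(missing_fixed, collapse = ", "),
         " (k_ia/k_ai are typically fixed from the NMR relaxation analysis)")

  Ls <- vapply(traces, function(tr) tr$meta$L, numeric(1))
  E0s <- vapply(traces, function(tr) tr$meta$E0, numeric(1))
  ws <- lapply(traces, function(tr)
    if (!is.null(tr$sigma)) 1 / rep_len(tr$sigma, length(tr$times)) else
      rep(1, length(tr$times)))
  yall <- unlist(lapply(traces, `[[`, "values"))
  wall <- unlist(ws)
  species <- c("I", "A", "AL", if (scheme == "cs-if") "ALs")

  make_params <- function(logpar) {
    names(logpar) <- free
    rates <- c(exp(logpar), fixed)[all_rates]
    names(rates) <- all_rates
    do.call(binding_params, as.list(rates))
  }
  design <- function(logpar) {
    pars <- make_params(logpar)
    X <- vector("list", length(traces))
    for (i in seq_along(traces)) {
      traj <- simulate_binding(pars, Ls[i], E0s[i], traces[[i]]$times,
                               rtol = rtol, atol = 1e-13)
      X[[i]] <- as.matrix(traj[, species, drop = FALSE])
    }
    do.call(rbind, X)
  }
  resid_fn <- function(logpar) {
    X <- design(logpar)
    cf <- qr.coef(qr(X * wall), yall * wall)
    cf[is.na(cf)] <- 0
    drop(X %*% cf - yall) * wall
  }

  # heuristic seed for k_on/k_off from two-phase reductions of the extreme traces
  seed_rates <- heuristic_binding_seed(traces, Ls)
  center0 <- c(k_on = seed_rates$k_on, k_off = seed_rates$k_off,
               k_if = 1, k_ir = 1)
  if (!is.null(fixed)) center0[names(fixed)] <- fixed
  center <- log(center0[free])
  fit <- multistart_fit(resid_fn, center, spread = log(100),
                        n_starts = n_starts, seed = seed)
  names(fit$par) <- free
  pars <- make_params(fit$par)
  X <- design(fit$par)
  cf <- qr.coef(qr(X * wall), yall * wall)
  cf[is.na(cf)] <- 0
  names(cf) <- species
  res <- make_fit_result(fit, length(yall))
  res$params <- pars
  res$constants <- binding_constants(pars)
  res$coefficients <- cf
  res$fixed <- fixed
  res
}

heuristic_binding_seed <- function(traces, Ls) {
  ord <- order(Ls)
  pick <- unique(c(ord[length(ord)], ord[1]))
  kfast <- rep(NA_real_, length(pick))
  for (i in seq_along(pick)) {
    f <- tryCatch(fit_exponential_phases(traces[[pick[i]]], 2L), error = function(e) NULL)
    if (!is.null(f)) kfast[i] <- f$rates[1]
  }
  if (all(is.finite(kfast)) && length(pick) == 2L && diff(Ls[pick]) != 0) {
    k_on <- abs(diff(kfast) / diff(Ls[pick]))
    k_off <- max(kfast[2] - k_on * Ls[pick[2]], 0.05 * kfast[2])
    if (is.finite(k_on) && k_on > 0 && k_off > 0)
      return(list(k_on = k_on, k_off = k_off))
  }
  list(k_on = 1e6, k_off = 10)
}
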