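#' Levenberg-Marquardt nonlinear least squares
#'
#' Compact damped Gauss-Newton / Levenberg-Marquardt minimiser of
#' `sum(resid_fn(par)^2)` with forward-difference Jacobian and optional box
#' constraints.  Callers in this package typically optimise in log-parameter
#' space so that rate constants stay positive and scale-free.
#'
#' @param resid_fn function(par) -> numeric residual vector (already
#'   weighted by 1/sigma where applicable).
#' @param par numeric start vector (named names are preserved).
#' @param lower,upper optional box bounds (recycled).
#' @param maxit iteration cap.
#' @param ftol,ptol relative convergence tolerances on the objective and on
#'   the step.
#' @return list with `par`, `rss`, `resid`, `jacobian`, `converged`,
#'   `iterations`, `message`.
#' @export
lm_least_squares <- function(resid_fn, par, lower = -Inf, upper = Inf,
                             maxit = 100L, ftol = 1e-12, ptol = 1e-10) {
  par <- as.numeric(par0 <- par)
  nm <- names(par0)
  p <- length(par)
  lower <- rep_len(lower, p); upper <- rep_len(upper, p)
  par <- pmin(pmax(par, lower), upper)
  safe_res <- function(x) {
    r <- tryCatch(resid_fn(x), error = function(e) NULL)
    if (is.null(r) || any(!is.finite(r))) return(NULL)
    r
  }
  r <- safe_res(par)
  if (is.null(r)) stop("residual function failed at the starting point")
  rss <- sum(r^2)
  lambda <- 1e-3
  converged <- FALSE
  it <- 0L
  J <- NULL
  numjac <- function(x, r0) {
    J <- matrix(NA_real_, length(r0), p)
    for (j in seq_len(p)) {
      # step large enough to clear integrator noise in the residuals
      h <- max(1e-4, 1e-4 * abs(x[j]))
      xj <- x; xj[j] <- min(x[j] + h, upper[j])
      if (xj[j] == x[j]) { xj[j] <- x[j] - h }
      rj <- safe_res(xj)
      if (is.null(rj)) rj <- r0
      J[, j] <- (rj - r0) / (xj[j] - x[j])
    }
    J
  }
  while (it < maxit) {
    it <- it + 1L
    J <- numjac(par, r)
    g <- crossprod(J, r)
    H <- crossprod(J)
    step_ok <- FALSE
    for (tries in 1:25) {
      Hd <- H + lambda * diag(pmax(diag(H), 1e-12), p)
      delta <- tryCatch(drop(solve(Hd, -g)), error = function(e) NULL)
      if (!is.null(delta)) {
        new_par <- pmin(pmax(par + delta, lower), upper)
        rn <- safe_res(new_par)
        if (!is.null(rn) && sum(rn^2) < rss) {
          rel_f <- (rss - sum(rn^2)) / max(rss, 1e-300)
          rel_p <- max(abs(new_par - par) / pmax(abs(par), 1e-10))
          par <- new_par; r <- rn; rss <- sum(rn^2)
          lambda <- max(lambda / 5, 1e-12)
          step_ok <- TRUE
          if (rel_f < ftol || rel_p < ptol) converged <- TRUE
          break
        }
      }
      lambda <- lambda * 6
    }
    if (!step_ok) { converged <- TRUE; break }  # stalled at (local) optimum
    if (converged) break
  }
  names(par) <- nm
  list(par = par, rss = rss, resid = r, jacobian = J,
       converged = converged, iterations = it,
       message = if (converged) "converged" else "iteration limit reached")
}

#' Multistart wrapper around [lm_least_squares()]
#'
#' Draws `n_starts` seeded starting points log-uniform in a multiplicative
#' band around a heuristic seed, triages them by a short refinement, and
#' polishes the best candidate.  This is the standard guard against local
#' minima in global kinetic fits.
#'
#' @param resid_fn residual function over the *transformed* (log) parameters.
#' @param center start vector in transformed space.
#' @param spread half-width of the uniform perturbation band applied to each
#'   transformed coordinate (default `log(100)`: factors of 1e-2..1e2).
#' @param n_starts number of starting points (>= 1); the first one is
#'   `center` itself.
#' @param seed integer RNG seed for reproducible starts.
#' @param n_refine how many triaged candidates get a medium-length run.
#' @param ... passed to [lm_least_squares()].
#' @return best fit, augmented with `multistart` provenance.
#' @export
multistart_fit <- function(resid_fn, center, spread = log(100),
                           n_starts = 16L, seed = 1L, n_refine = 4L, ...) {
  p <- length(center)
  starts <- matrix(rep(center, each = n_starts), n_starts, p)
  if (n_starts > 1L) {
    rng <- local({
      set.seed(seed)
      matrix(stats::runif((n_starts - 1L) * p, -spread, spread),
             n_starts - 1L, p)
    })
    starts[-1L, ] <- starts[-1L, , drop = FALSE] + rng
  }
  score <- rep(Inf, n_starts)
  for (i in seq_len(n_starts)) {
    r <- tryCatch(resid_fn(starts[i, ]), error = function(e) NULL)
    if (!is.null(r) && all(is.finite(r))) score[i] <- sum(r^2)
  }
  ord <- order(score)[seq_len(min(n_refine, sum(is.finite(score))))]
  if (!length(ord)) stop("all multistart points failed to evaluate")
  cands <- lapply(ord, function(i)
    tryCatch(lm_least_squares(resid_fn, starts[i, ], maxit = 25L, ...),
             error = function(e) NULL))
  cands <- Filter(Negate(is.null), cands)
  if (!length(cands)) stop("multistart fit failed to converge from any start")
  # polish the two best refined candidates fully: cheap insurance against
  # the flat-ridge local optima typical of kinetic global fits
  ord2 <- order(vapply(cands, `[[`, numeric(1), "rss"))
  finals <- lapply(cands[ord2[seq_len(min(2L, length(cands)))]], function(cd)
    lm_least_squares(resid_fn, cd$par, maxit = 60L, ...))
  fit <- finals[[which.min(vapply(finals, `[[`, numeric(1), "rss"))]]
  fit$multistart <- list(n_starts = n_starts, seed = seed,
                         start_rss = unname(score),
                         refined = length(cands), best_rss = fit$rss)
  fit
}

#' Assemble a fit-result object with Wald uncertainties
#'
#' @param fit output of [lm_least_squares()] / [multistart_fit()].
#' @param n_obs number of observations behind the residual vector.
#' @param log_scale logical vector: which parameters were fitted as natural
#'   logs (their SEs are multiplicative).
#' @param flags character vector of diagnostic flags.
#' @keywords internal
make_fit_result <- function(fit, n_obs, log_scale = NULL, flags = character(0)) {
  p <- length(fit$par)
  dof <- max(n_obs - p, 1L)
  s2 <- fit$rss / dof
  cov <- tryCatch(s2 * solve(crossprod(fit$jacobian)), error = function(e) NULL)
  se <- if (is.null(cov)) rep(NA_real_, p) else sqrt(pmax(diag(cov), 0))
  if (is.null(log_scale)) log_scale <- rep(TRUE, p)
  ci_lo <- fit$par - 1.96 * se
  ci_hi <- fit$par + 1.96 * se
  # unidentifiability: CI spanning more than a factor 100 on a log-fitted par
  wide <- log_scale & is.finite(se) & (ci_hi - ci_lo > log(100))
  if (any(wide))
    flags <- c(flags, paste0("unidentifiable:",
                             paste(names(fit$par)[wide], collapse = ",")))
  structure(list(par = fit$par, se = se, ci_lower = ci_lo, ci_upper = ci_hi,
                 log_scale = log_scale, rss = fit$rss, n_obs = n_obs,
                 sigma_hat = sqrt(s2), resid = fit$resid,
                 converged = fit$converged, iterations = fit$iterations,
                 multistart = fit$multistart, flags = flags),
            class = "kk_fit")
}

#' @export
print.kk_fit <- function(x, ...) {
  cat(sprintf("<kk_fit: rss = %.6g over %d observations, %s>\n",
              x$rss, x$n_obs, if (x$converged) "converged" else "NOT converged"))
  tab <- data.frame(estimate = x$par, se = x$se,
                    ci_lower = x$ci_lower, ci_upper = x$ci_upper)
  print(tab)
  if (length(x$flags)) cat("flags:", paste(x$flags, collapse = "; "), "\n")
  invisible(x)
}
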