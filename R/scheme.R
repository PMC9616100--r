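#' Declarative mass-action kinetic schemes
#'
#' A `kinetic_scheme` is the central container of the package: an ordered set
#' of species, a list of (at most bimolecular) reactions referencing named
#' rate constants, and optional linear observables.  All concentrations are
#' molar and all times are seconds; unimolecular rate constants are s^-1 and
#' bimolecular ones M^-1 s^-1.
#'
#' @param species character vector of species names (unique, non-empty).
#' @param reactions list of reaction steps, each created by [reaction_step()]
#'   or given as a string like `"A + L -> AL : k_on"` (use `"<->"` with two
#'   rate names, `"A + L <-> AL : k_on, k_off"`, for a reversible pair).
#' @param rate_constants named numeric vector mapping every referenced rate
#'   constant name to a non-negative value.
#' @param observables optional named list; each element is
#'   `list(coeff = <named numeric per species>, baseline = <number>)`
#'   describing a signal linear in the state populations.
#' @param name optional scheme label used in error messages and reports.
#' @return object of class `kinetic_scheme`.
#' @examples
#' sc <- kinetic_scheme(
#'   species = c("I", "A"),
#'   reactions = list("I -> A : k_ia", "A -> I : k_ai"),
#'   rate_constants = c(k_ia = 7.5e-4, k_ai = 2.5e-4))
#' @export
kinetic_scheme <- function(species, reactions, rate_constants,
                           observables = list(), name = "scheme") {
  stopifnot(is.character(species), length(species) >= 1L)
  if (anyDuplicated(species)) stop("duplicated species names")
  steps <- lapply(reactions, function(r) {
    if (is.character(r)) parse_reaction_string(r) else list(r)
  })
  steps <- unlist(steps, recursive = FALSE)
  for (st in steps) {
    bad <- setdiff(c(st$reactants, st$products), species)
    if (length(bad))
      stop(sprintf("reaction '%s' references undeclared species: %s",
                   format_step(st), paste(bad, collapse = ", ")))
    if (length(st$reactants) > 2L || length(st$products) > 2L)
      stop(sprintf("reaction '%s' exceeds bimolecular order", format_step(st)))
    if (!st$rate %in% names(rate_constants))
      stop(sprintf("reaction '%s' references undeclared rate constant '%s'",
                   format_step(st), st$rate))
  }
  if (any(rate_constants < 0)) stop("rate constants must be >= 0")
  for (nm in names(observables)) {
    ob <- observables[[nm]]
    if (is.null(ob$baseline)) observables[[nm]]$baseline <- 0
    bad <- setdiff(names(ob$coeff), species)
    if (length(bad))
      stop(sprintf("observable '%s' references undeclared species: %s",
                   nm, paste(bad, collapse = ", ")))
  }
  structure(list(species = species, reactions = steps,
                 rate_constants = rate_constants,
                 observables = observables, name = name),
            class = "kinetic_scheme")
}

#' Create a single irreversible reaction step
#'
#' @param reactants,products character vectors of species (0-2 each).
#' @param rate name of the rate constant governing the step.
#' @export
reaction_step <- function(reactants, products, rate) {
  list(reactants = as.character(reactants),
       products = as.character(products), rate = as.character(rate))
}

format_step <- function(st) {
  sprintf("%s -> %s : %s",
          if (length(st$reactants)) paste(st$reactants, collapse = " + ") else "0",
          if (length(st$products)) paste(st$products, collapse = " + ") else "0",
          st$rate)
}

# "A + L -> AL : k_on"  or  "A + L <-> AL : k_on, k_off"
parse_reaction_string <- function(x) {
  x <- trimws(x)
  rev_step <- grepl("<->", x, fixed = TRUE)
  arrow <- if (rev_step) "<->" else "->"
  main <- strsplit(x, ":", fixed = TRUE)[[1]]
  if (length(main) != 2L) stop(sprintf("malformed reaction string '%s'", x))
  rates <- trimws(strsplit(main[2], ",", fixed = TRUE)[[1]])
  sides <- strsplit(main[1], arrow, fixed = TRUE)[[1]]
  if (length(sides) != 2L) stop(sprintf("malformed reaction string '%s'", x))
  split_side <- function(s) {
    s <- trimws(strsplit(s, "+", fixed = TRUE)[[1]])
    s[nzchar(s) & s != "0"]
  }
  lhs <- split_side(sides[1]); rhs <- split_side(sides[2])
  if (rev_step) {
    if (length(rates) != 2L)
      stop(sprintf("reversible reaction '%s' needs two rate names", x))
    list(reaction_step(lhs, rhs, rates[1]), reaction_step(rhs, lhs, rates[2]))
  } else {
    if (length(rates) != 1L)
      stop(sprintf("irreversible reaction '%s' needs one rate name", x))
    list(reaction_step(lhs, rhs, rates[1]))
  }
}

#' @export
print.kinetic_scheme <- function(x, ...) {
  cat(sprintf("<kinetic_scheme '%s': %d species, %d irreversible steps>\n",
              x$name, length(x$species), length(x$reactions)))
  cat("species:", paste(x$species, collapse = ", "), "\n")
  for (st in x$reactions)
    cat(" ", format_step(st), sprintf("= %g", x$rate_constants[[st$rate]]), "\n")
  invisible(x)
}

# internal encoding for the C++ core: 0-based indices, -1 = empty slot
scheme_encoding <- function(scheme) {
  m <- length(scheme$reactions)
  re <- matrix(-1L, m, 2); pr <- matrix(-1L, m, 2)
  k <- numeric(m)
  for (j in seq_len(m)) {
    st <- scheme$reactions[[j]]
    ir <- match(st$reactants, scheme$species) - 1L
    ip <- match(st$products, scheme$species) - 1L
    if (length(ir)) re[j, seq_along(ir)] <- ir
    if (length(ip)) pr[j, seq_along(ip)] <- ip
    k[j] <- scheme$rate_constants[[st$rate]]
  }
  list(re = re, pr = pr, k = k)
}

#' Net stoichiometric matrix (species x reactions)
#' @param scheme a [kinetic_scheme()].
#' @export
stoich_matrix <- function(scheme) {
  n <- length(scheme$species); m <- length(scheme$reactions)
  N <- matrix(0, n, m, dimnames = list(scheme$species, NULL))
  for (j in seq_len(m)) {
    st <- scheme$reactions[[j]]
    for (s in st$reactants) N[s, j] <- N[s, j] - 1
    for (s in st$products) N[s, j] <- N[s, j] + 1
  }
  N
}

#' Conserved moieties of a scheme
#'
#' Returns a basis of the left null space of the stoichiometric matrix as a
#' (moieties x species) matrix: every row `b` satisfies `b . c(t)` constant
#' along any trajectory.  The basis is reduced to row-echelon form so that
#' for typical enzyme schemes the rows come out as 0/1 indicator vectors
#' (total enzyme, total ligand, ...).
#' @param scheme a [kinetic_scheme()].
#' @export
conserved_moieties <- function(scheme) {
  N <- stoich_matrix(scheme)
  sv <- svd(t(N), nu = nrow(t(N)), nv = ncol(t(N)))
  tolr <- max(dim(N)) * max(sv$d, 0) * .Machine$double.eps
  rank <- sum(sv$d > tolr)
  if (rank == ncol(t(N))) {
    return(matrix(0, 0, length(scheme$species),
                  dimnames = list(NULL, scheme$species)))
  }
  B <- t(sv$v[, (rank + 1):ncol(t(N)), drop = FALSE])
  B <- rref(B)
  B[abs(B) < 1e-10] <- 0
  # scale each row so its smallest non-zero |entry| is 1
  for (i in seq_len(nrow(B))) {
    nz <- abs(B[i, ])[abs(B[i, ]) > 0]
    if (length(nz)) B[i, ] <- B[i, ] / min(nz)
    if (sum(B[i, ]) < 0) B[i, ] <- -B[i, ]
  }
  dimnames(B) <- list(NULL, scheme$species)
  round(B, 10)
}

# reduced row echelon form, partial pivoting
rref <- function(A, tol = 1e-10) {
  A <- as.matrix(A)
  lead <- 1L
  for (r in seq_len(nrow(A))) {
    if (lead > ncol(A)) break
    piv <- which.max(abs(A[r:nrow(A), lead])) + r - 1L
    while (abs(A[piv, lead]) < tol) {
      lead <- lead + 1L
      if (lead > ncol(A)) return(A)
      piv <- which.max(abs(A[r:nrow(A), lead])) + r - 1L
    }
    A[c(r, piv), ] <- A[c(piv, r), ]
    A[r, ] <- A[r, ] / A[r, lead]
    for (i in seq_len(nrow(A))) {
      if (i != r) A[i, ] <- A[i, ] - A[i, lead] * A[r, ]
    }
    lead <- lead + 1L
  }
  A
}

#' Build the mass-action derivative function of a scheme
#'
#' Returns a plain R closure mapping a named (or ordered) concentration
#' vector to the vector of time derivatives d\[species\]/dt under the law of
#' mass action.  The closure is independent of the compiled integrator and
#' is used both for oracle cross-checks and for the equilibrium solver.
#'
#' @param scheme a [kinetic_scheme()].
#' @return function(conc) -> named numeric vector of derivatives (M/s).
#' @export
build_rhs <- function(scheme) {
  enc <- scheme_encoding(scheme)
  species <- scheme$species
  function(conc) {
    conc <- as_state(conc, species)
    dy <- numeric(length(species))
    for (j in seq_along(enc$k)) {
      f <- enc$k[j]
      for (s in enc$re[j, ]) if (s >= 0) f <- f * conc[s + 1L]
      for (s in enc$re[j, ]) if (s >= 0) dy[s + 1L] <- dy[s + 1L] - f
      for (s in enc$pr[j, ]) if (s >= 0) dy[s + 1L] <- dy[s + 1L] + f
    }
    names(dy) <- species
    dy
  }
}

as_state <- function(conc, species) {
  if (!is.null(names(conc))) {
    bad <- setdiff(species, names(conc))
    if (length(bad))
      stop("missing concentrations for species: ", paste(bad, collapse = ", "))
    conc <- conc[species]
  } else if (length(conc) != length(species)) {
    stop("concentration vector length does not match species count")
  }
  if (any(!is.finite(conc))) stop("non-finite concentrations")
  unname(conc)
}

#' Integrate a kinetic scheme
#'
#' Stiff-capable numerical integration of the mass-action ODE system using a
#' linearly implicit Rosenbrock pair with analytic Jacobian.  Defaults
#' (`rtol = 1e-8`, `atol = 1e-12` M) are chosen for schemes whose rate
#' constants span many orders of magnitude (1e-4 s^-1 conformational
#' exchange next to ~1e6 M^-1 s^-1 binding).
#'
#' @param scheme a [kinetic_scheme()].
#' @param init named or ordered non-negative initial concentrations (M).
#' @param times strictly increasing output times (s), starting at >= 0.
#' @param rtol,atol relative / absolute integration tolerances.
#' @return data.frame with column `time_s` followed by one column per
#'   species; attribute `"moiety_drift"` records the maximum relative drift
#'   of each conserved moiety over the trajectory.
#' @export
integrate_scheme <- function(scheme, init, times, rtol = 1e-8, atol = 1e-12) {
  y0 <- as_state(init, scheme$species)
  if (any(y0 < 0)) stop("initial concentrations must be non-negative")
  times <- as.numeric(times)
  if (length(times) < 1L || any(diff(times) <= 0) || times[1] < 0)
    stop("times must be strictly increasing and start at >= 0")
  enc <- scheme_encoding(scheme)
  Y <- tryCatch(
    ode23s_cpp(y0, enc$re, enc$pr, enc$k, times, rtol, atol),
    error = function(e) stop(sprintf("integration of scheme '%s' failed: %s",
                                     scheme$name, conditionMessage(e)), call. = FALSE))
  colnames(Y) <- scheme$species
  out <- data.frame(time_s = times, Y, check.names = FALSE)
  B <- conserved_moieties(scheme)
  if (nrow(B) > 0) {
    tot0 <- drop(B %*% y0)
    tot <- Y %*% t(B)
    scale <- pmax(abs(tot0), atol)
    drift <- apply(abs(sweep(tot, 2, tot0, "-")), 2, max) / scale
    attr(out, "moiety_drift") <- drift
  } else attr(out, "moiety_drift") <- numeric(0)
  out
}

#' Evaluate a linear observable along a trajectory
#' @param scheme a [kinetic_scheme()].
#' @param traj data.frame from [integrate_scheme()].
#' @param observable name of an observable declared in the scheme, or a
#'   `list(coeff=, baseline=)` given directly.
#' @export
observe_trajectory <- function(scheme, traj, observable) {
  ob <- if (is.character(observable)) scheme$observables[[observable]] else observable
  if (is.null(ob)) stop("unknown observable")
  sig <- rep(ob$baseline %||% 0, nrow(traj))
  for (s in names(ob$coeff)) sig <- sig + ob$coeff[[s]] * traj[[s]]
  sig
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Equilibrium state of a kinetic scheme
#'
#' Solves for the steady state compatible with the conserved-moiety totals by
#' damped Gauss-Newton iteration on log-concentrations (positivity
#' preserving), falling back to long-time integration when Newton stalls.
#'
#' @param scheme a [kinetic_scheme()].
#' @param init initial concentrations; the moiety totals are computed from
#'   these and the returned equilibrium satisfies the same totals.
#' @param totals alternatively, named or ordered totals per conserved moiety
#'   (rows of [conserved_moieties()]); when given, `init` is built from a
#'   least-squares preimage.
#' @param tol convergence tolerance on the scaled net fluxes.
#' @return named concentration vector at equilibrium.
#' @export
equilibrium_state <- function(scheme, init = NULL, totals = NULL, tol = 1e-12) {
  B <- conserved_moieties(scheme)
  if (is.null(init)) {
    if (is.null(totals)) stop("supply either init or totals")
    if (nrow(B) != length(totals))
      stop(sprintf("expected %d moiety totals", nrow(B)))
    init <- drop(crossprod(B, solve(B %*% t(B), as.numeric(totals))))
    init <- pmax(init, 0)
  }
  y0 <- as_state(init, scheme$species)
  tot <- if (nrow(B)) drop(B %*% y0) else numeric(0)

  # zero-total moieties force their species to zero: drop them
  keep <- rep(TRUE, length(y0))
  if (nrow(B)) {
    for (i in seq_len(nrow(B)))
      if (tot[i] <= 0) keep[B[i, ] != 0] <- FALSE
  }
  y <- y0
  y[!keep] <- 0

  rhs <- build_rhs(scheme)
  cscale <- max(y, 1e-12)
  flux0 <- characteristic_flux(scheme, pmax(y, cscale * 1e-3))

  res <- equilibrium_newton(scheme, y, keep, B, tot, flux0, tol)
  if (!res$ok) {
    # integration fallback to near-steady-state, then re-polish
    lam <- characteristic_rate(scheme, pmax(y, cscale * 1e-3))
    t_long <- 100 / max(lam[lam > 0][which.min(lam[lam > 0])], 1e-12)
    t_long <- 100 / min(lam[lam > 0])
    traj <- integrate_scheme(scheme, y, times = c(t_long * 0.5, t_long))
    y1 <- as.numeric(traj[nrow(traj), -1])
    res <- equilibrium_newton(scheme, y1, keep, B, tot, flux0, tol)
    if (!res$ok)
      stop("equilibrium solve did not converge; consider integrating to steady state explicitly")
  }
  out <- res$y
  names(out) <- scheme$species
  out
}

# per-reaction first-order-equivalent rates at a reference state
characteristic_rate <- function(scheme, y) {
  names(y) <- scheme$species
  vapply(scheme$reactions, function(st) {
    k <- scheme$rate_constants[[st$rate]]
    if (length(st$reactants) == 2L) k * max(y[st$reactants[2]], y[st$reactants[1]]) else k
  }, numeric(1))
}

characteristic_flux <- function(scheme, y) {
  names(y) <- scheme$species
  f <- vapply(scheme$reactions, function(st) {
    k <- scheme$rate_constants[[st$rate]]
    for (s in st$reactants) k <- k * y[[s]]
    k
  }, numeric(1))
  max(f, 1e-300)
}

equilibrium_newton <- function(scheme, y, keep, B, tot, flux0, tol,
                               maxit = 200L) {
  rhs <- build_rhs(scheme)
  n <- length(y)
  idx <- which(keep)
  floor_c <- max(max(y), 1e-12) * 1e-25
  y[idx] <- pmax(y[idx], floor_c)
  # scaled residual: net production rates / flux0 and conservation gaps
  resid <- function(yfull) {
    r1 <- rhs(yfull) / flux0
    r2 <- if (nrow(B)) (drop(B %*% yfull) - tot) / pmax(abs(tot), 1e-15) else numeric(0)
    c(r1, r2)
  }
  jac_full <- function(yfull) {
    # analytic: d rhs / d y
    J <- matrix(0, n, n)
    for (st in scheme$reactions) {
      k <- scheme$rate_constants[[st$rate]]
      ri <- match(st$reactants, scheme$species)
      pi <- match(st$products, scheme$species)
      for (w in seq_along(ri)) {
        d <- k
        other <- ri[-w]
        if (length(other)) d <- d * yfull[other]
        for (s in ri) J[s, ri[w]] <- J[s, ri[w]] - d
        for (s in pi) J[s, ri[w]] <- J[s, ri[w]] + d
      }
    }
    J
  }
  x <- log(y[idx])
  r <- resid(y)
  fn <- max(abs(r))
  for (it in seq_len(maxit)) {
    if (fn < tol) break
    J <- jac_full(y) / flux0
    Jc <- rbind(J, if (nrow(B)) B / pmax(abs(tot), 1e-15) else NULL)
    # chain rule to log space, restricted to free species
    Jx <- Jc[, idx, drop = FALSE] %*% diag(y[idx], nrow = length(idx))
    dx <- tryCatch(qr.solve(qr(Jx, LAPACK = TRUE), -r),
                   error = function(e) NULL)
    if (is.null(dx) || any(!is.finite(dx))) return(list(ok = FALSE, y = y))
    dx <- pmin(pmax(dx, -5), 5)  # trust region in log space
    step <- 1
    improved <- FALSE
    for (half in 1:30) {
      xn <- x + step * dx
      yn <- y; yn[idx] <- exp(xn)
      rn <- resid(yn)
      if (max(abs(rn)) < fn || max(abs(rn)) < tol) {
        x <- xn; y <- yn; r <- rn; fn <- max(abs(rn)); improved <- TRUE
        break
      }
      step <- step / 2
    }
    if (!improved) return(list(ok = fn < tol * 100, y = y))
  }
  list(ok = fn < tol * 100, y = y)
}
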