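#' Per-variant kinetic and thermodynamic summary row
#'
#' Collects the steady-state and binding constants of one variant into the
#' row type behind the cross-variant tables: turnover number, substrate
#' constants, product and TSA dissociation constants, active fraction and
#' the derived ideal-TSA dissociation constant
#' `K_TX = (K_S / k_cat) * k_uncat` (always recomputed, never stored).
#'
#' @param variant name.
#' @param k_cat s^-1. @param K_M,K_S,K_P,K_2 molar. @param p_active_25C
#'   fraction. @param k_uncat uncatalysed reference rate (s^-1), a
#'   user-supplied literature constant — never defaulted.
#' @param cv optional relative uncertainty applied to ratio propagation.
#' @return one-row data.frame with derived `K_TX`.
#' @export
variant_summary <- function(variant, k_cat, K_M, K_S, K_P, K_2,
                            p_active_25C, k_uncat, cv = NA_real_) {
  vals <- c(k_cat = k_cat, K_M = K_M, K_S = K_S, K_P = K_P, K_2 = K_2,
            k_uncat = k_uncat)
  if (any(vals <= 0)) stop("all kinetic quantities must be positive")
  if (p_active_25C <= 0 || p_active_25C > 1) stop("p_active must be in (0,1]")
  data.frame(variant = variant, k_cat = k_cat, K_M = K_M, K_S = K_S,
             K_P = K_P, K_2 = K_2, p_active_25C = p_active_25C,
             k_uncat = k_uncat,
             K_TX = transition_state_affinity(K_S, k_cat, k_uncat),
             cv = cv, stringsAsFactors = FALSE)
}

#' Ideal transition-state-analogue dissociation constant
#'
#' From transition-state theory, an enzyme's affinity for an ideal TSA is
#' proportional to the rate enhancement of the chemical step:
#' `K_TX = K_S * k_uncat / k_cat` (M).
#'
#' @param K_S substrate dissociation constant (M).
#' @param k_cat chemical step rate (s^-1).
#' @param k_uncat uncatalysed reference rate (s^-1).
#' @export
transition_state_affinity <- function(K_S, k_cat, k_uncat) {
  if (any(c(K_S, k_cat, k_uncat) <= 0)) stop("inputs must be positive")
  K_S * k_uncat / k_cat
}

#' Correlation between catalytic proficiency and TSA affinity
#'
#' Ordinary least squares of `log10(K_TX)` on `log10(K_2)` across variants.
#' For an ideal transition-state analogue the slope is ~1.  Requires at
#' least three variants (two points make the regression degenerate).
#'
#' @param summaries data.frame with columns `K_TX` and `K_2` (e.g. rows
#'   from [variant_summary()]).
#' @return list `slope`, `intercept`, `r` (Pearson on log10 scale),
#'   `n`.
#' @export
correlate_proficiency <- function(summaries) {
  if (nrow(summaries) < 3L)
    stop("need >= 3 variants; regression is degenerate otherwise")
  x <- log10(summaries$K_2); y <- log10(summaries$K_TX)
  fit <- stats::lm(y ~ x)
  list(slope = unname(stats::coef(fit)[2]),
       intercept = unname(stats::coef(fit)[1]),
       r = stats::cor(x, y), n = nrow(summaries))
}

#' Fold-change table relative to a reference variant
#'
#' Pairwise ratios of `k_cat`, `k_cat/K_M`, `K_2` and `K_P` of the
#' reference over/under each variant, with uncertainties propagated in
#' quadrature on the relative scale when per-variant `cv` values are
#' present.
#'
#' @param summaries data.frame of [variant_summary()] rows.
#' @param ref reference variant name (must be present).
#' @return data.frame of ratios `<quantity>_ratio` (variant / reference for
#'   `k_cat` and efficiency; reference / variant for the dissociation
#'   constants so that "improvement" is > 1) plus `ratio_cv`.
#' @export
fold_change_table <- function(summaries, ref) {
  i0 <- match(ref, summaries$variant)
  if (is.na(i0)) stop("reference variant not present: ", ref)
  r0 <- summaries[i0, ]
  eff <- summaries$k_cat / summaries$K_M
  cv <- summaries$cv %||% rep(NA_real_, nrow(summaries))
  ratio_cv <- sqrt(ifelse(is.na(cv), 0, cv^2) +
                   ifelse(is.na(cv[i0]), 0, cv[i0]^2))
  ratio_cv[is.na(cv) & is.na(cv[i0])] <- NA_real_
  data.frame(variant = summaries$variant,
             k_cat_ratio = summaries$k_cat / r0$k_cat,
             efficiency_ratio = eff / (r0$k_cat / r0$K_M),
             K_2_ratio = r0$K_2 / summaries$K_2,
             K_P_ratio = r0$K_P / summaries$K_P,
             ratio_cv = ratio_cv,
             stringsAsFactors = FALSE)
}
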