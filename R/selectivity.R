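# I/V regression, reversal potentials, and Goldman-Hodgkin-Katz
# ion-selectivity inference for a K+/Cl- salt gradient.

#' Construct a salt condition
#'
#' @param cis_KCl cis-side KCl concentration in mM.
#' @param trans_KCl trans-side KCl concentration in mM.
#' @param temperature_K temperature in kelvin (default 298.15).
#' @return list of class `salt_condition`.
#' @export
salt_condition <- function(cis_KCl = 150, trans_KCl = 730,
                           temperature_K = 298.15) {
  if (cis_KCl <= 0 || trans_KCl <= 0) stop("concentrations must be positive")
  if (temperature_K <= 0) stop("temperature must be positive")
  structure(list(cis_KCl = cis_KCl, trans_KCl = trans_KCl,
                 temperature_K = temperature_K),
            class = "salt_condition")
}

#' Fit a linear I/V relation
#'
#' Ordinary least squares of current on voltage. The slope is the level's
#' conductance (pA/mV = nS) and the reversal potential is the voltage-axis
#' intercept, i.e. the voltage at which the fitted current is zero:
#' psi_rev = -(current intercept) / slope.
#'
#' @param points data frame with columns `voltage_mV` and `current_pA`
#'   (extra columns such as `level` are ignored).
#' @param level label carried through to the result.
#' @return object of class `iv_fit`: list with `conductance_nS`,
#'   `reversal_mV`, `reversal_defined`, `r_squared`, `residual_sd`, `level`.
#' @export
fit_iv <- function(points, level = NA_character_) {
  stopifnot(is.data.frame(points),
            all(c("voltage_mV", "current_pA") %in% names(points)))
  v <- points$voltage_mV; i <- points$current_pA
  if (length(unique(v)) < 2L) stop("need at least two distinct voltages")
  fit <- stats::lm(i ~ v)
  b <- unname(stats::coef(fit))
  slope <- b[2]; icpt <- b[1]
  rev_defined <- slope != 0
  # summary.lm warns on noiseless (exactly collinear) input; that input is
  # legitimate here
  s <- suppressWarnings(summary(fit))
  structure(
    list(conductance_nS = slope,
         reversal_mV = if (rev_defined) -icpt / slope else NA_real_,
         reversal_defined = rev_defined,
         r_squared = s$r.squared,
         residual_sd = s$sigma,
         level = level),
    class = "iv_fit"
  )
}

#' @export
print.iv_fit <- function(x, ...) {
  cat(sprintf("<iv_fit>%s G = %.3f nS, psi_rev = %s mV (r2 = %.4f)\n",
              if (is.na(x$level)) "" else paste0(" [", x$level, "]"),
              x$conductance_nS,
              if (x$reversal_defined) sprintf("%.3f", x$reversal_mV) else "undefined",
              x$r_squared))
  invisible(x)
}

#' Fit all conductance levels of an I/V point set
#'
#' @param points data frame with columns `voltage_mV`, `current_pA`, `level`.
#' @return list of [fit_iv()] results, one per level.
#' @export
fit_iv_levels <- function(points) {
  stopifnot("level" %in% names(points))
  lapply(split(points, points$level), function(d) fit_iv(d, level = d$level[1]))
}

#' GHK reversal potential for a KCl gradient
#'
#' Bi-ionic Goldman-Hodgkin-Katz voltage equation for K+ and Cl-:
#' psi_rev = (RT/F) ln[(P_K [K]_trans + P_Cl [Cl]_cis) /
#'                     (P_K [K]_cis + P_Cl [Cl]_trans)],
#' reported as the potential of the cis side relative to trans. For a 1:1
#' salt, P_K/P_Cl = 1 gives 0 mV for any gradient; the limits
#' P_K/P_Cl -> Inf and -> 0 give the K+ and Cl- Nernst potentials.
#'
#' @param p_ratio permeability ratio P_K/P_Cl (> 0; `Inf` allowed for the
#'   pure-cation limit).
#' @param salt a [salt_condition()].
#' @return reversal potential in mV.
#' @export
ghk_reversal <- function(p_ratio, salt = salt_condition()) {
  stopifnot(inherits(salt, "salt_condition"))
  if (p_ratio < 0) stop("p_ratio must be positive")
  vt <- rt_over_f_mV(salt$temperature_K)
  cis <- salt$cis_KCl; trans <- salt$trans_KCl
  if (is.infinite(p_ratio)) return(vt * log(trans / cis))
  if (p_ratio == 0) return(vt * log(cis / trans))
  # KCl is 1:1 so [K]_side = [Cl]_side = the side's concentration
  vt * log((p_ratio * trans + cis) / (p_ratio * cis + trans))
}

#' Nernst potential limits for a salt condition
#'
#' @param salt a [salt_condition()].
#' @return named vector `c(K = ..., Cl = ...)` in mV: the reversal potentials
#'   of an ideally K+-selective and Cl--selective pore.
#' @export
nernst_limits <- function(salt = salt_condition()) {
  vt <- rt_over_f_mV(salt$temperature_K)
  c(K = vt * log(salt$trans_KCl / salt$cis_KCl),
    Cl = -vt * log(salt$trans_KCl / salt$cis_KCl))
}

#' Permeability ratio and selectivity classification from a reversal potential
#'
#' Exact algebraic inversion of [ghk_reversal()]. Writing
#' x = exp(psi_rev F / RT), the ratio is
#' P_K/P_Cl = (x [Cl]_trans - [Cl]_cis) / ([K]_trans - x [K]_cis).
#' The pore is classified non-selective when |psi_rev| is within `tolerance`
#' of zero, otherwise cation- or anion-selective by the sign of psi_rev
#' (positive means cation-selective under a cis < trans gradient).
#'
#' @param reversal_mV measured reversal potential in mV; must lie strictly
#'   between the two Nernst limits.
#' @param salt a [salt_condition()].
#' @param tolerance_mV classification tolerance in mV (default 2).
#' @return object of class `selectivity_result`: list with `p_ratio`,
#'   `classification`, `reversal_mV`, `tolerance_mV`, `nernst_limits_mV`.
#' @export
permeability_ratio_from_reversal <- function(reversal_mV,
                                             salt = salt_condition(),
                                             tolerance_mV = 2) {
  stopifnot(inherits(salt, "salt_condition"))
  lim <- nernst_limits(salt)
  hi <- max(lim); lo <- min(lim)
  if (reversal_mV >= hi || reversal_mV <= lo) {
    stop(sprintf(
      "reversal potential %.3f mV lies at/outside the Nernst limits [%.3f, %.3f] mV; permeability ratio is unbounded",
      reversal_mV, lo, hi))
  }
  vt <- rt_over_f_mV(salt$temperature_K)
  x <- exp(reversal_mV / vt)
  cis <- salt$cis_KCl; trans <- salt$trans_KCl
  ratio <- (x * trans - cis) / (trans - x * cis)
  sign_for_gradient <- sign(log(trans / cis))
  cls <- if (abs(reversal_mV) <= tolerance_mV) "non-selective"
  else if (sign(reversal_mV) == sign_for_gradient) "cation-selective"
  else "anion-selective"
  structure(
    list(p_ratio = ratio, classification = cls,
         reversal_mV = reversal_mV, tolerance_mV = tolerance_mV,
         nernst_limits_mV = lim),
    class = "selectivity_result"
  )
}

#' @export
print.selectivity_result <- function(x, ...) {
  cat(sprintf("<selectivity_result> P_K/P_Cl = %.4f (%s; psi_rev = %.3f mV, tol %.1f mV)\n",
              x$p_ratio, x$classification, x$reversal_mV, x$tolerance_mV))
  invisible(x)
}
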