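#' Concentration unit conversions
#'
#' Converts mass concentration in ppm (taken as mg/L, the convention for
#' exposure media) to molarity in micromolar and back:
#' `uM = ppm / MW * 1000`.
#'
#' @param conc_ppm Concentration(s) in ppm (mg/L), `>= 0`.
#' @param mw_g_per_mol Molecular weight in g/mol, `> 0`.
#' @return Concentration(s) in µM.
#' @export
#' @examples
#' ppm_to_micromolar(375, 414)     # 905.8 uM
#' ppm_to_micromolar(17.5, 438.20) # 39.9 uM
ppm_to_micromolar <- function(conc_ppm, mw_g_per_mol) {
  if (any(mw_g_per_mol <= 0)) {
    stop("molecular weight must be positive", call. = FALSE)
  }
  if (any(conc_ppm < 0)) stop("concentration must be >= 0", call. = FALSE)
  conc_ppm / mw_g_per_mol * 1000
}

#' @rdname ppm_to_micromolar
#' @param conc_uM Concentration(s) in µM.
#' @export
micromolar_to_ppm <- function(conc_uM, mw_g_per_mol) {
  if (any(mw_g_per_mol <= 0)) {
    stop("molecular weight must be positive", call. = FALSE)
  }
  conc_uM * mw_g_per_mol / 1000
}

#' Percent recovery of a measured concentration
#'
#' `measured / nominal * 100`, conventionally reported to one decimal.
#'
#' @param measured_ppm Measured concentration.
#' @param nominal_ppm Nominal (intended) concentration, `> 0`.
#' @return Percent recovery (unrounded).
#' @export
#' @examples
#' percent_recovery(188, 200)  # 94.0
#' percent_recovery(2.42, 2)   # 121.0
percent_recovery <- function(measured_ppm, nominal_ppm) {
  if (any(nominal_ppm <= 0)) {
    stop("nominal concentration must be positive", call. = FALSE)
  }
  measured_ppm / nominal_ppm * 100
}

#' Mean signed deviation from nominal concentration
#'
#' Mean of the recovery percentages minus 100: negative values mean the
#' measured media concentrations ran below nominal, positive above.
#'
#' @param recovery_pcts Vector of percent recoveries (at least one).
#' @return Signed mean percent deviation.
#' @export
#' @examples
#' mean_nominal_deviation(c(94.0, 96.8, 84.3, 84.0, 100.0)) # -8.2
mean_nominal_deviation <- function(recovery_pcts) {
  if (length(recovery_pcts) == 0L) {
    stop("need at least one recovery value", call. = FALSE)
  }
  mean(recovery_pcts) - 100
}

#' Probit lethal-concentration estimation
#'
#' Maximum-likelihood probit regression of mortality on log10 dose:
#' `Phi^-1(p_death) = intercept + slope * log10(dose)`. The lethal
#' concentration for fraction `p` is
#' `LCp = 10^((Phi^-1(p) - intercept) / slope)`, with delta-method
#' confidence intervals computed on the log10 scale. Control rows
#' (dose 0) are excluded from the likelihood, and no natural-mortality
#' (Abbott) correction is applied unless requested. The fit is flagged
#' `extrapolated` when the LC50 falls outside the tested dose range --
#' the situation where the estimate rests on the assumed probit shape
#' rather than on observed mortality crossings.
#'
#' @param table Mortality table: data frame with `dose_ppm`,
#'   `n_exposed`, `n_dead` (a `timepoint_hpf` column is carried but not
#'   used).
#' @param conf_level Confidence level for the LC intervals (default
#'   0.95).
#' @param abbott Apply Abbott's correction using the dose-0 control row
#'   (default FALSE).
#' @return An `lc_fit`: list with `lc10`, `lc50`, `lc10_ci`, `lc50_ci`,
#'   `intercept`, `slope` (log10-dose probit scale), `converged`,
#'   `extrapolated`, and the underlying `glm` fit.
#' @export
fit_probit <- function(table, conf_level = 0.95, abbott = FALSE) {
  stopifnot(all(c("dose_ppm", "n_exposed", "n_dead") %in% names(table)))
  if (any(table$n_dead < 0 | table$n_dead > table$n_exposed)) {
    stop("need 0 <= n_dead <= n_exposed", call. = FALSE)
  }
  ctl <- table[table$dose_ppm == 0, , drop = FALSE]
  tab <- table[table$dose_ppm > 0, , drop = FALSE]
  if (nrow(tab) < 2L) {
    stop("need at least two nonzero dose levels", call. = FALSE)
  }
  dead <- tab$n_dead
  alive <- tab$n_exposed - tab$n_dead
  if (abbott && nrow(ctl) > 0) {
    c0 <- sum(ctl$n_dead) / sum(ctl$n_exposed)
    p <- pmax((dead / tab$n_exposed - c0) / (1 - c0), 0)
    dead <- round(p * tab$n_exposed)
    alive <- tab$n_exposed - dead
  }
  if (sum(dead) == 0 || sum(alive) == 0) {
    stop("degenerate response: all subjects dead or all alive",
         call. = FALSE)
  }
  ld <- log10(tab$dose_ppm)
  fit <- suppressWarnings(
    stats::glm(cbind(dead, alive) ~ ld, family = stats::binomial("probit"))
  )
  cf <- stats::coef(fit)
  if (!fit$converged || !all(is.finite(cf)) || cf[2] <= 0) {
    stop("probit fit did not converge to a positive slope ",
         "(separated or inverted dose-response)", call. = FALSE)
  }
  V <- stats::vcov(fit)
  z <- stats::qnorm(1 - (1 - conf_level) / 2)
  lcp <- function(p) {
    theta <- (stats::qnorm(p) - cf[1]) / cf[2] # log10 LCp
    grad <- c(-1 / cf[2], -(stats::qnorm(p) - cf[1]) / cf[2]^2)
    se <- sqrt(drop(t(grad) %*% V %*% grad))
    list(est = 10^theta, ci = 10^(theta + c(-1, 1) * z * se))
  }
  l10 <- lcp(0.10)
  l50 <- lcp(0.50)
  structure(list(
    lc10 = unname(l10$est), lc50 = unname(l50$est),
    lc10_ci = unname(l10$ci), lc50_ci = unname(l50$ci),
    intercept = unname(cf[1]), slope = unname(cf[2]),
    converged = fit$converged,
    extrapolated = l50$est < min(tab$dose_ppm) | l50$est > max(tab$dose_ppm),
    conf_level = conf_level,
    glm = fit
  ), class = "lc_fit")
}

#' @export
print.lc_fit <- function(x, ...) {
  cat(sprintf("<lc_fit> probit on log10 dose: intercept %.3f, slope %.3f\n",
              x$intercept, x$slope))
  cat(sprintf("  LC10 = %.4g  [%.4g, %.4g]\n", x$lc10, x$lc10_ci[1],
              x$lc10_ci[2]))
  cat(sprintf("  LC50 = %.4g  [%.4g, %.4g]%s\n", x$lc50, x$lc50_ci[1],
              x$lc50_ci[2],
              if (x$extrapolated) "  (extrapolated beyond tested doses)" else ""))
  invisible(x)
}

#' Tissue-to-media lethality ratio
#'
#' Ratio of a tissue-based lethal concentration to the media-based one;
#' values far above 1 indicate bioaccumulation-driven potency hidden by
#' media-only reporting. `format_lc_ratio()` applies the conventional
#' reporting rounding: one decimal below 100, whole numbers above.
#'
#' @param lc_tissue,lc_media Positive lethal concentrations.
#' @return `lc_ratio()` the raw ratio; `format_lc_ratio()` the rounded
#'   ratio.
#' @export
#' @examples
#' format_lc_ratio(lc_ratio(850, 2.14))    # 397
#' format_lc_ratio(lc_ratio(2030, 528.6))  # 3.8
lc_ratio <- function(lc_tissue, lc_media) {
  if (any(lc_tissue <= 0) || any(lc_media <= 0)) {
    stop("lethal concentrations must be positive", call. = FALSE)
  }
  lc_tissue / lc_media
}

#' @rdname lc_ratio
#' @param ratio A ratio from `lc_ratio()`.
#' @export
format_lc_ratio <- function(ratio) {
  ifelse(ratio >= 100, round(ratio), round(ratio, 1))
}

#' Published PFAS exposure concentrations
#'
#' The nominal and measured media concentrations of the three PFAS
#' exposures (PFOA, PFHxS, PFOS) with molecular weights, as printed in
#' the source study's media-chemistry table. Useful as worked-example
#' input for [percent_recovery()], [mean_nominal_deviation()] and
#' [ppm_to_micromolar()].
#'
#' @return Tibble with columns `chemical`, `nominal_ppm`,
#'   `measured_ppm`, `mw_g_per_mol`.
#' @export
pfas_concentrations <- function() {
  tibble::tibble(
    chemical = rep(c("PFOA", "PFHxS", "PFOS"), each = 5),
    nominal_ppm = c(200, 250, 300, 350, 375,
                    7.5, 10, 12.5, 15, 17.5,
                    1, 1.25, 1.5, 1.75, 2),
    measured_ppm = c(188, 242, 253, 294, 375,
                     6.35, 8.70, 10.15, 11.50, 14.35,
                     1.21, 1.40, 1.86, 2.03, 2.42),
    mw_g_per_mol = rep(c(414, 438.20, 538.22), each = 5)
  )
}

#' Published lethal-concentration estimates
#'
#' Media-based LC10/LC50 and tissue-based LCt50 point estimates for the
#' three PFAS exposures at 120 hpf, as printed in the source study.
#' Input for [lc_ratio()].
#'
#' @return Tibble with columns `chemical`, `lc10_media_ppm`,
#'   `lc50_media_ppm`, `lct50_tissue_ppm`.
#' @export
pfas_lc_published <- function() {
  tibble::tibble(
    chemical = c("PFOA", "PFHxS", "PFOS"),
    lc10_media_ppm = c(318.1, 8.6, 1.41),
    lc50_media_ppm = c(528.6, 14.28, 2.14),
    lct50_tissue_ppm = c(2030, 124, 850)
  )
}
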