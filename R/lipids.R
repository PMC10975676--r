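#' Quality-control CV filter for lipid analytes
#'
#' An analyte is eliminated when its coefficient of variation
#' (standard deviation / mean) across the quality-control replicates
#' exceeds the threshold. The rule is strict: a CV of exactly the
#' threshold is kept. Analytes whose QC mean is zero cannot be assessed
#' and are dropped with a divide-by-zero caveat.
#'
#' @param qc Data frame or matrix of QC replicate values: rows are QC
#'   runs, columns are analytes (at least 2 rows).
#' @param threshold CV above which an analyte is dropped (default 0.3,
#'   strict `>`).
#' @return Tibble with one row per analyte: `analyte`, `mean`, `sd`,
#'   `cv`, `keep`, `note`.
#' @export
#' @examples
#' qc <- data.frame(a = c(1, 1.05, 0.95), b = c(1, 2.5, 0.2))
#' qc_filter(qc)
qc_filter <- function(qc, threshold = 0.3) {
  qc <- as.matrix(qc)
  if (nrow(qc) < 2L) {
    stop("need >= 2 QC replicate values per analyte", call. = FALSE)
  }
  m <- colMeans(qc)
  s <- apply(qc, 2, stats::sd)
  cv <- ifelse(m == 0, NA_real_, s / m)
  keep <- !is.na(cv) & cv <= threshold
  tibble::tibble(
    analyte = colnames(qc) %||% as.character(seq_along(m)),
    mean = unname(m), sd = unname(s), cv = unname(cv),
    keep = unname(keep),
    note = ifelse(is.na(cv), "zero QC mean",
                  ifelse(keep, "", sprintf("CV > %g", threshold)))
  )
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Normalize lipid amounts to pooled wet weight
#'
#' @param amount_nmol Raw amounts (vector or matrix, nmol).
#' @param wet_weight_mg Pool wet weight(s) in mg, `> 0`.
#' @return nmol per mg wet weight.
#' @export
normalize_to_wet_weight <- function(amount_nmol, wet_weight_mg) {
  if (any(wet_weight_mg <= 0)) {
    stop("wet weight must be positive", call. = FALSE)
  }
  amount_nmol / wet_weight_mg
}

#' Parse lipid species names
#'
#' Accepts the `CLASS(C:D)` nomenclature with class prefixes such as
#' ether (`ePC`, `ePE`), lyso (`LPE`), and dihydro (`DSM`), plus
#' per-class totals written `Total X` / `Total_X`.
#'
#' @param species Character vector of species names.
#' @return Tibble with `species`, `class`, `carbons`, `double_bonds`,
#'   `is_total`. Carbon fields are `NA` for totals; unparseable names
#'   yield `NA` class.
#' @export
#' @examples
#' parse_lipid_species(c("PS(40:5)", "ePC(34:1)", "Total ePC"))
parse_lipid_species <- function(species) {
  tot <- grepl("^Total[ _]", species)
  cls <- rep(NA_character_, length(species))
  carbons <- rep(NA_integer_, length(species))
  dbl <- rep(NA_integer_, length(species))
  cls[tot] <- sub("^Total[ _]+", "", species[tot])
  m <- regmatches(species, regexec("^([A-Za-z]+)\\((\\d+):(\\d+)\\)$", species))
  ok <- !tot & vapply(m, length, integer(1)) == 4L
  cls[ok] <- vapply(m[ok], `[`, character(1), 2)
  carbons[ok] <- as.integer(vapply(m[ok], `[`, character(1), 3))
  dbl[ok] <- as.integer(vapply(m[ok], `[`, character(1), 4))
  tibble::tibble(species = species, class = cls, carbons = carbons,
                 double_bonds = dbl, is_total = tot)
}

#' Fold-change band for a significant lipid trend
#'
#' Fold change is defined symmetrically as
#' `max(mean_a, mean_b) / min(mean_a, mean_b)` (always `>= 1`), with the
#' direction of change carried separately, so a halving and a doubling
#' band identically. Bands are half-open: `"1-2"` for fold changes in
#' `[1, 2)` and `">2"` for `[2, Inf)`; the `"0-1"` label is reserved for
#' sub-threshold changes (fold change indistinguishable from 1) and
#' does not arise for significant cells under this definition.
#'
#' @param mean_control,mean_treated Group means, `> 0`.
#' @return List with `fold_change` and `band`.
#' @export
#' @examples
#' fold_change_band(1, 0.4) # fold change 2.5, band ">2"
fold_change_band <- function(mean_control, mean_treated) {
  if (any(c(mean_control, mean_treated) <= 0)) {
    stop("group means must be positive for fold-change banding",
         call. = FALSE)
  }
  fc <- max(mean_control, mean_treated) / min(mean_control, mean_treated)
  band <- if (fc >= 2) ">2" else "1-2"
  list(fold_change = fc, band = band)
}

#' Per-species permutation tests and trend-table construction
#'
#' For every lipid species column: an omnibus [perm_anova()] across
#' treatments, followed (when the omnibus p-value is below `alpha`) by
#' [tukey_hsd()] against the control. Each significant control-vs-dose
#' pair yields a trend cell: direction (`Increase`/`Decrease` of the
#' treated mean relative to control), significance tier (`p<0.05` or
#' `p<0.01` from the Tukey-adjusted p), and fold-change band (see
#' [fold_change_band()]). Cells from treatments with fewer pools than
#' `min_pools` carry a low-sample caveat flag.
#'
#' @param table Lipid tibble as from [simulate_lipids()]: metadata
#'   columns plus one numeric column per species.
#' @param control Control treatment label.
#' @param cfg A [perm_config()] for the omnibus tests.
#' @param alpha Significance level (default 0.05).
#' @param min_pools Low-sample caveat floor (default 3 pools).
#' @param species_cols Species columns (default: all numeric columns
#'   that are not pool metadata).
#' @return Trend tibble: one row per (species, treatment) with
#'   `species`, `treatment`, `direction` (`"Increase"`, `"Decrease"` or
#'   `"none"`), `tier`, `fold_change`, `band`, `low_sample`, plus the
#'   omnibus `anova_p` per species.
#' @export
species_tests <- function(table, control, cfg = perm_config(max_iter = 2000),
                          alpha = 0.05, min_pools = 3, species_cols = NULL) {
  meta <- c("pool_id", "treatment", "dose_ppm", "wet_weight_mg", "n_embryos",
            "quality_flag")
  if (!"treatment" %in% names(table)) {
    stop("lipid table needs a 'treatment' column", call. = FALSE)
  }
  if (is.null(species_cols)) {
    species_cols <- setdiff(names(table)[vapply(table, is.numeric,
                                                logical(1))], meta)
  }
  trt <- factor(table$treatment)
  if (!control %in% levels(trt)) {
    stop("control label not found among treatments", call. = FALSE)
  }
  sizes <- table(trt)
  if (any(sizes < 2)) {
    stop("every treatment entering the test needs >= 2 pools", call. = FALSE)
  }
  doses <- setdiff(levels(trt), control)
  rows <- list()
  for (sp in species_cols) {
    v <- table[[sp]]
    if (all(is.na(v))) {
      message("species ", sp, " missing after QC; skipped")
      next
    }
    om <- perm_anova(v, trt, cfg)
    cells <- tibble::tibble(
      species = sp, treatment = doses, direction = "none",
      tier = NA_character_, fold_change = NA_real_, band = NA_character_,
      low_sample = as.vector(sizes[doses] < min_pools |
                               sizes[[control]] < min_pools),
      anova_p = om$p_hat
    )
    if (om$p_hat < alpha) {
      tk <- tukey_hsd(v, trt, alpha = alpha, control = control)
      ctl_pairs <- tk[(tk$group_a == control | tk$group_b == control) &
                        tk$significant, , drop = FALSE]
      means <- tapply(v, trt, mean)
      for (r in seq_len(nrow(ctl_pairs))) {
        treated <- if (ctl_pairs$group_a[r] == control) {
          ctl_pairs$group_b[r]
        } else {
          ctl_pairs$group_a[r]
        }
        i <- match(treated, cells$treatment)
        fb <- fold_change_band(means[[control]], means[[treated]])
        cells$direction[i] <- ctl_pairs$direction[r]
        cells$tier[i] <- if (ctl_pairs$p_adj[r] < 0.01) "p<0.01" else "p<0.05"
        cells$fold_change[i] <- fb$fold_change
        cells$band[i] <- fb$band
      }
    }
    rows[[length(rows) + 1L]] <- cells
  }
  do.call(rbind, rows)
}
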