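#' Assemble the analysis dataset from a raw cohort table
#'
#' Applies the assembly rules of the harmonised multi-study design:
#' individuals must be at least 50 years old at the first grid year and must
#' have participated at their study's first configured wave (at least one
#' substantive variable observed there); structurally missing waves/variables
#' are blanked; for a study observed at baseline plus a single follow-up, each
#' participant's follow-up is assigned to one of the two final waves by an
#' independent fair coin. The coin is a deterministic function of `(seed, id)`
#' so assembly is idempotent and stable under row reordering.
#'
#' @param raw a cohort table on the configured wave grid.
#' @param config a [cohort_config()] carrying the assembly rules
#'   (`missingness$structural`, `baseline_wave`, `single_followup`).
#' @param seed RNG seed for the follow-up coin; defaults to `config$seed`.
#' @return the eligible subset, class `analysis_dataset`.
#' @export
assemble_dataset <- function(raw, config, seed = config$seed) {
  validate_cohort_config(config)
  wy <- config$wave_years
  need <- wave_col("age", wy)
  if (!all(need %in% names(raw)))
    stopf("raw table lacks the configured wave grid (missing %s)",
          paste(setdiff(need, names(raw)), collapse = ", "))
  tab <- raw[, !grepl("^latent_", names(raw)), drop = FALSE]

  # age restriction at the first grid year
  keep <- tab[[wave_col("age", wy[1])]] >= 50
  # participation at the study's first configured wave
  base_year <- config$baseline_wave[tab$study]
  participated <- rep(FALSE, nrow(tab))
  for (year in unique(base_year)) {
    rows <- which(base_year == year)
    sub <- tab[rows, wave_col(.substantive_vars, year), drop = FALSE]
    participated[rows] <- rowSums(!is.na(sub)) > 0
  }
  tab <- tab[keep & participated, , drop = FALSE]

  tab <- apply_structural_rules(tab, config)

  sf <- config$single_followup
  if (!is.null(sf)) {
    rows <- which(tab$study == sf$study)
    if (length(rows)) {
      assigned <- sf$years[1L + id_coin(tab$id[rows], seed)]
      for (yr in sf$years) {
        b <- rows[assigned != yr]
        if (length(b))
          for (v in .substantive_vars) tab[b, wave_col(v, yr)] <- NA
      }
      attr(tab, "followup_assignment") <-
        data.frame(id = tab$id[rows], year = assigned)
    }
  }
  rownames(tab) <- NULL
  class(tab) <- c("analysis_dataset", "cohort_table", "data.frame")
  tab
}

#' Derive a disability sum score from six binary items
#'
#' The ADL and IADL scores are the sum of six items coded 1 = no difficulty,
#' 0 = difficulty, so the score runs 0 (severe disability) to 6 (no
#' difficulty on any item). Scores are only ever derived on complete,
#' post-imputation items; a missing item is a contract violation.
#'
#' @param items numeric vector of six values in `{0, 1}`.
#' @return integer score in `{0, ..., 6}`.
#' @export
derive_score <- function(items) {
  if (length(items) != 6) stopf("expected six items, got %d", length(items))
  if (anyNA(items))
    stopf("cannot derive a score from incomplete items (missing at position %s)",
          paste(which(is.na(items)), collapse = ", "))
  if (!all(items %in% c(0, 1))) stopf("items must be binary 0/1")
  as.integer(sum(items))
}

#' Replace ADL/IADL items by their sum scores
#'
#' Computes `adl_score_<year>` and `iadl_score_<year>` at every wave and
#' removes the individual item columns, so that downstream imputation and
#' projection models see only the scores. Items must be complete at every
#' wave where the individual is alive (i.e. the table has been imputed);
#' scores at waves where the individual is dead are missing.
#'
#' @param imputed a cohort table with no missing items at alive waves.
#' @return an `analysis_dataset` with score columns in place of items.
#' @export
attach_scores <- function(imputed) {
  years <- sort(unique(parse_col(names(imputed))$year))
  years <- years[!is.na(years)]
  for (year in years) {
    alive <- imputed[[wave_col("alive", year)]]
    if (anyNA(alive))
      stopf("vital status missing at alive_%d (rows %s): impute before scoring",
            year, paste(utils::head(which(is.na(alive)), 3), collapse = ", "))
    for (grp in list(c("adl_score", .adl_items), c("iadl_score", .iadl_items))) {
      cols <- wave_col(grp[-1], year)
      if (!all(cols %in% names(imputed)))
        stopf("item columns absent at year %d; scores may already be attached", year)
      m <- as.matrix(imputed[, cols])
      bad <- which(alive == 1 & rowSums(is.na(m)) > 0)
      if (length(bad)) {
        miss_col <- cols[which(is.na(m[bad[1], ]))[1]]
        stopf("residual missingness in %s at row %d: impute before scoring",
              miss_col, bad[1])
      }
      sc <- rep(NA_integer_, nrow(imputed))
      sc[alive == 1] <- as.integer(rowSums(m[alive == 1, , drop = FALSE]))
      imputed[[wave_col(grp[1], year)]] <- sc
    }
  }
  drop <- wave_col(rep(.item_vars, each = length(years)), years)
  imputed <- imputed[, setdiff(names(imputed), drop), drop = FALSE]
  class(imputed) <- c("analysis_dataset", "cohort_table", "data.frame")
  imputed
}
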