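#' Intervention scenario specification
#'
#' The three scenarios of the projection method: no intervention (0), a
#' physical-activity intervention shifting the IADL score (1), and the same
#' intervention shifting both IADL and ADL scores (2). The shift is applied
#' once, at the first projected wave, to individuals with no vigorous
#' physical activity: each eligible score is replaced by a draw from
#' `Normal(score + smd * SD, SD)` truncated to `[0, 6]`, where `SD` is the
#' study-specific standard deviation of the score at the anchor wave
#' (baseline). A zero effect size is a null intervention and applies no
#' shift.
#'
#' @param id scenario identity: 0, 1 or 2.
#' @param smd effect size on the standardised score scale; the default is
#'   the meta-analytic standardised mean difference of 1.12 for
#'   physical-activity interventions on self-reported ADL/IADL measures.
#' @param targets score columns shifted; defaults by scenario id
#'   (`character(0)`, `"iadl_score"`, or `c("iadl_score", "adl_score")`).
#' @param eligibility variable (at the intervention wave) whose value 0
#'   marks eligible individuals; default `"vpa"`, no vigorous physical
#'   activity.
#' @param eligibility_wave `"intervention"` (the first projected wave,
#'   default) or `"observed"` (the last observed wave).
#' @param sd_source `"matched"` (each score scaled by its own baseline SD,
#'   default) or `"iadl"` (both scores scaled by the IADL SD).
#' @param anchor_year calendar year of the SD anchor wave.
#' @return an object of class `scenario_spec`.
#' @export
scenario_spec <- function(id, smd = 1.12, targets = NULL,
                          eligibility = "vpa",
                          eligibility_wave = c("intervention", "observed"),
                          sd_source = c("matched", "iadl"),
                          anchor_year = 2000) {
  if (!id %in% 0:2) stopf("scenario id must be 0, 1 or 2")
  if (!is.finite(smd)) stopf("smd must be finite")
  if (is.null(targets))
    targets <- switch(as.character(id),
                      "0" = character(0),
                      "1" = "iadl_score",
                      "2" = c("iadl_score", "adl_score"))
  if ((id == 0) != (length(targets) == 0))
    stopf("scenario 0 has no targets; scenarios 1 and 2 must have targets")
  structure(list(id = as.integer(id), smd = smd, targets = targets,
                 eligibility = eligibility,
                 eligibility_wave = match.arg(eligibility_wave),
                 sd_source = match.arg(sd_source),
                 anchor_year = as.integer(anchor_year)),
            class = "scenario_spec")
}

#' @export
print.scenario_spec <- function(x, ...) {
  cat(sprintf("<scenario_spec> id %d: %s\n", x$id,
              if (x$id == 0) "no intervention" else
                sprintf("SMD %.2f shift on %s for %s == 0 at the %s wave",
                        x$smd, paste(x$targets, collapse = " + "),
                        x$eligibility, x$eligibility_wave)))
  invisible(x)
}

#' Study-specific anchor standard deviation of a score
#'
#' The intervention effect size is transformed to the absolute score scale
#' by multiplying it with the study-specific standard deviation of the score
#' at the anchor (baseline) wave, computed with denominator `n - 1` on the
#' completed (post-imputation) data.
#'
#' @param dataset a completed `analysis_dataset` with score columns.
#' @param study study label.
#' @param score `"iadl"` or `"adl"` (or the full column prefix
#'   `"iadl_score"` / `"adl_score"`).
#' @param year anchor wave calendar year.
#' @return the sample standard deviation.
#' @export
anchor_sd <- function(dataset, study, score = c("iadl", "adl"), year = 2000) {
  score <- sub("_score$", "", score[1])
  score <- match.arg(score, c("iadl", "adl"))
  cl <- wave_col(paste0(score, "_score"), year)
  if (!cl %in% names(dataset)) stopf("no column '%s' in dataset", cl)
  x <- dataset[[cl]][dataset$study == study]
  x <- x[!is.na(x)]
  if (length(x) < 2)
    stopf("fewer than 2 baseline %s scores in study '%s'", toupper(score), study)
  stats::sd(x)
}

#' Apply the intervention shift to score values
#'
#' Replaces each eligible score by a draw from
#' `Normal(score + smd * sd, sd)`; draws below 0 are set to 0 and above 6 to
#' 6 (scores remain on a continuous scale within `[0, 6]`). Ineligible
#' values are returned unchanged. With `sd = 0` the normal is degenerate at
#' the original score and the operator is the identity.
#'
#' @param scores numeric score values at the intervention wave.
#' @param eligible logical mask, same length.
#' @param smd standardised effect size.
#' @param sd anchor standard deviation (non-negative).
#' @param truncate clamp to `[0, 6]` (default); disable to study the
#'   pre-truncation operator.
#' @param seed optional seed; `NULL` uses the current RNG stream.
#' @return the shifted score vector.
#' @export
apply_shift <- function(scores, eligible, smd, sd, truncate = TRUE,
                        seed = NULL) {
  if (sd < 0) stopf("anchor sd must be non-negative")
  if (!is.null(seed)) set.seed(derive_seed(seed, "shift"))
  stopifnot(length(eligible) == length(scores))
  idx <- which(eligible)
  if (!length(idx)) return(scores)
  if (anyNA(scores[idx])) stopf("eligible scores must be complete before the shift")
  shifted <- stats::rnorm(length(idx), mean = scores[idx] + smd * sd, sd = sd)
  if (truncate) shifted <- pmin(pmax(shifted, 0), 6)
  scores[idx] <- shifted
  scores
}

# Impute the projected wave of a frame in two phases: all variables except
# the mobility outcomes and vital status first, then (after an optional
# score modification) outcomes and vital status, so that a scenario's score
# shift precedes - and can influence - the imputation of outcomes and death.
impute_projection_wave <- function(frame, specs, params, seed,
                                   shift_fun = NULL) {
  py <- frame$pos_years
  W <- frame$W
  last <- py[W]
  phase1 <- wave_col(c(.risk_vars, .score_vars), last)
  phase2 <- wave_col(c(.outcome_vars, "alive"), last)
  prov <- character(0)

  frame$df <- chained_impute(frame$df, specs, params,
                             seed = derive_seed(seed, "phase1"),
                             visit = phase1)
  prov <- c(prov, paste0("imputed:", phase1))
  if (!is.null(shift_fun)) {
    frame$df <- shift_fun(frame$df)
    prov <- c(prov, "shifted:scores")
  }
  frame$df <- chained_impute(frame$df, specs, params,
                             seed = derive_seed(seed, "phase2"),
                             visit = phase2)
  prov <- c(prov, paste0("imputed:", phase2))

  # death masking: substantive values at the projected wave are missing for
  # rows imputed dead there
  dead <- frame$df$block == "project" &
    frame$df[[wave_col("alive", last)]] == 0
  if (any(dead))
    for (v in setdiff(.frame_vars, c("age", "alive")))
      frame$df[[wave_col(v, last)]][dead] <- NA
  attr(frame, "provenance") <- prov
  frame
}

#' Complete the first projection frame under a scenario
#'
#' Scenario 0 imputes the projected wave with no score modification.
#' Scenarios 1 and 2 impute in two phases: first all projected-wave
#' variables except the mobility outcomes and vital status; then the shift
#' of [apply_shift()] is applied to the target score(s) of rows whose
#' (possibly just-imputed) eligibility variable at the intervention wave is
#' 0, study by study with the study's anchor SD; finally outcomes and vital
#' status are imputed, seeing the modified scores as predictors. All
#' scenarios share the same imputation visit order and per-phase RNG
#' streams, so scenario copies run under the same seed differ only through
#' the intervention itself.
#'
#' @param frame the step-1 `projection_frame`.
#' @param spec a [scenario_spec()].
#' @param specs named list of [imputation_spec()] for the projected-wave
#'   variables.
#' @param params a [cart_params()].
#' @param anchor_sds named list: `anchor_sds[[study]][[score_column]]` giving
#'   the study-specific anchor SD (from [anchor_sd()]); required for
#'   scenarios 1 and 2.
#' @param seed seed for the step's RNG streams.
#' @return the completed frame, with a `provenance` attribute recording the
#'   order of imputation and modification.
#' @export
scenario_step <- function(frame, spec, specs, params = cart_params(),
                          anchor_sds = NULL, seed = 1L) {
  if (frame$step != 1L)
    stopf("scenario incorporation applies to the step-1 frame (got step %d)",
          frame$step)
  shift_fun <- NULL
  if (spec$id != 0 && spec$smd != 0) {
    if (is.null(anchor_sds)) stopf("anchor_sds required for scenario %d", spec$id)
    last <- frame$pos_years[frame$W]
    elig_col <- wave_col(spec$eligibility, last)
    if (identical(spec$eligibility_wave, "observed"))
      elig_col <- wave_col(spec$eligibility, frame$pos_years[frame$W - 1])
    shift_fun <- function(df) {
      set.seed(derive_seed(seed, "shift"))
      lower <- df$block == "project"
      eligible <- lower & !is.na(df[[elig_col]]) & df[[elig_col]] == 0
      for (tg in spec$targets) {
        sc_col <- wave_col(tg, last)
        sd_key <- if (spec$sd_source == "iadl") "iadl_score" else tg
        for (st in unique(df$study[eligible])) {
          rows <- eligible & df$study == st
          sdv <- anchor_sds[[st]][[sd_key]]
          if (is.null(sdv)) stopf("no anchor SD for study '%s', score '%s'", st, sd_key)
          df[[sc_col]] <- apply_shift(df[[sc_col]], rows, spec$smd, sdv)
        }
      }
      df
    }
  }
  impute_projection_wave(frame, specs, params, seed, shift_fun)
}
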