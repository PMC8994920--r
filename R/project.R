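#' Rao-Wu rescaled bootstrap resample
#'
#' Draws, independently within each study stratum of size `n`, `n - 1`
#' individuals with replacement (the rescaling choice that makes the naive
#' with-replacement bootstrap variance consistent under equal-weight simple
#' random sampling). Resampled individuals receive fresh ids; the original
#' id is kept in `orig_id`.
#'
#' @param dataset an `analysis_dataset`.
#' @param replicate bootstrap replicate index (its own reproducible stream).
#' @param seed master seed.
#' @return the resampled dataset.
#' @export
rao_wu_resample <- function(dataset, replicate = 1L, seed = 1L) {
  set.seed(derive_seed(seed, "bootstrap", replicate))
  studies <- unique(dataset$study)
  parts <- vector("list", length(studies))
  for (i in seq_along(studies)) {
    rows <- which(dataset$study == studies[i])
    n <- length(rows)
    if (n < 2) stopf("study stratum '%s' has fewer than 2 individuals", studies[i])
    parts[[i]] <- dataset[rows[sample.int(n, n - 1L, replace = TRUE)], ,
                          drop = FALSE]
  }
  out <- do.call(rbind, parts)
  out$orig_id <- out$id
  out$id <- seq_len(nrow(out))
  rownames(out) <- NULL
  class(out) <- class(dataset)
  out
}

# wave grid of a wide table: the years carrying an age column
infer_wave_years <- function(data) {
  p <- parse_col(names(data))
  sort(unique(p$year[p$var == "age" & !is.na(p$year)]))
}

# Predictor-selection specs for the observed-data chained imputation: for
# each incomplete variable one selection tree over a pragmatic candidate set
# (the same variable at the other waves, all substantive variables of the
# same wave, and study), with age at the anchor wave, sex and education
# forced everywhere.
build_observed_specs <- function(data, params, wave_years, anchor_year) {
  forced <- c(wave_col("age", anchor_year), "sex", "education")
  p <- parse_col(names(data))
  specs <- list()
  for (j in seq_len(nrow(p))) {
    cl <- p$col[j]
    if (cl %in% .id_vars || is.na(p$year[j])) next
    if (!anyNA(data[[cl]])) next
    var <- p$var[j]
    if (var == "age") next
    cands <- c(wave_col(var, setdiff(wave_years, p$year[j])),
               wave_col(setdiff(c(.substantive_vars, "alive"),
                                c(var, "alive"[var == "alive"])), p$year[j]),
               "study")
    cands <- intersect(cands, names(data))
    specs[[cl]] <- select_predictors(data, cl, cands, forced, params)
  }
  specs
}

# Predictor-selection specs for the projected wave, fitted on the completed
# observed panel mapped to window positions: for each last-position variable
# one selection tree over all window variables (excluding ages other than
# the forced one) plus study.
build_projection_specs <- function(panel, params, wave_years) {
  W <- length(wave_years)
  py <- pos_years(W)
  ppanel <- panel_to_positions(panel, stats::setNames(py, wave_years))
  last <- py[W]
  forced <- c(wave_col("age", last), "sex", "education")
  targets <- wave_col(c(.outcome_vars, .score_vars, .risk_vars, "alive"), last)
  all_vars <- unlist(lapply(py, function(y)
    wave_col(c(.outcome_vars, .score_vars, .risk_vars, "alive"), y)))
  specs <- list()
  for (tg in targets) {
    cands <- c(setdiff(all_vars, tg), "study")
    cands <- intersect(cands, names(ppanel))
    specs[[tg]] <- select_predictors(ppanel, tg, cands, forced, params)
  }
  specs
}

# Phase (a) of a replicate: chained-impute the observed data, attach scores,
# compute anchor SDs and projection specs.
prepare_replicate <- function(sample, params, wave_years, anchor_year, seed) {
  specs_obs <- build_observed_specs(sample, params, wave_years,
                                    anchor_year = wave_years[length(wave_years)])
  panel <- chained_impute(sample, specs_obs, params,
                          seed = derive_seed(seed, "observed"))
  panel <- attach_scores(panel)
  specs_proj <- build_projection_specs(panel, params, wave_years)
  anchor_sds <- list()
  for (st in unique(panel$study))
    anchor_sds[[st]] <- list(
      iadl_score = anchor_sd(panel, st, "iadl", anchor_year),
      adl_score  = anchor_sd(panel, st, "adl", anchor_year))
  list(panel = panel, specs = specs_proj, anchor_sds = anchor_sds)
}

project_one_scenario <- function(panel, specs, scen, params, anchor_sds,
                                 wave_years, horizon_year, seed) {
  slices <- list()
  if (horizon_year <= wave_years[length(wave_years)]) return(slices)
  frame <- build_projection_frame(panel, wave_years)
  s <- 1L
  repeat {
    step_seed <- derive_seed(seed, "step", s) # shared across scenarios
    frame <- if (s == 1L)
      scenario_step(frame, scen, specs, params, anchor_sds, seed = step_seed)
    else
      impute_projection_wave(frame, specs, params, seed = step_seed)
    slices[[as.character(frame$proj_year)]] <- extract_projected_wave(frame)
    if (frame$proj_year + 2L > horizon_year) break
    frame <- advance_frame(frame)
    s <- s + 1L
  }
  slices
}

#' Project one bootstrap sample under one scenario
#'
#' Runs the full single-replicate pipeline: chained-equations imputation of
#' the observed data, score derivation, predictor selection for the
#' projected wave, and the sequential wave-advancing projection to the
#' horizon, applying the scenario at the first projected wave. The
#' observed-data phase and the per-step RNG streams do not depend on the
#' scenario, so calls under different scenarios with the same seed share
#' their observed-data imputation and differ only through the intervention.
#'
#' @param sample an (possibly resampled) `analysis_dataset`.
#' @param scenario a [scenario_spec()].
#' @param horizon_year final projected calendar year; must be reachable from
#'   the last observed wave in biennial steps.
#' @param params a [cart_params()].
#' @param seed replicate seed.
#' @param anchor_year calendar year anchoring the scenario SD.
#' @return a list with the completed observed `panel`, the projected-wave
#'   `slices` (one per projected year), the projection `specs` and the
#'   `anchor_sds`.
#' @export
project_replicate <- function(sample, scenario, horizon_year,
                              params = cart_params(), seed = 1L,
                              anchor_year = NULL) {
  wave_years <- infer_wave_years(sample)
  if (length(wave_years) < 2) stopf("sample has no recognisable wave grid")
  last <- wave_years[length(wave_years)]
  if (horizon_year < last || (horizon_year - last) %% 2 != 0)
    stopf("horizon year %d is not reachable from %d by biennial steps",
          horizon_year, last)
  anchor_year <- anchor_year %||% wave_years[1]
  prep <- prepare_replicate(sample, params, wave_years, anchor_year, seed)
  slices <- project_one_scenario(prep$panel, prep$specs, scenario, params,
                                 prep$anchor_sds, wave_years, horizon_year,
                                 seed)
  list(panel = prep$panel, slices = slices, specs = prep$specs,
       anchor_sds = prep$anchor_sds, scenario = scenario)
}

#' Project mobility limitation prevalence under intervention scenarios
#'
#' The main fitting function. For each of `n_bootstrap` Rao-Wu bootstrap
#' replicates it imputes the missing values of the resampled observed data
#' with CART chained equations, derives the ADL/IADL scores, selects
#' predictors for the projected-wave imputation models, and advances a
#' sliding multi-wave window two calendar years at a time to the horizon,
#' imputing each new wave from the trailing waves; the intervention
#' scenarios modify the first projected wave's scores. All scenarios within
#' a replicate share the replicate's observed-data imputation and per-step
#' RNG streams. Per-replicate prevalences of the two mobility limitation
#' outcomes (among survivors aged at least `min_age`) are retained per
#' study and pooled, forming the Monte-Carlo ensemble that
#' [summarize_prevalence()], [contrast()] and [selection_table()] combine.
#'
#' @param dataset an `analysis_dataset` (items present, pre-imputation).
#' @param scenarios list of [scenario_spec()]s.
#' @param n_bootstrap number of bootstrap replicates.
#' @param horizon_year final projected calendar year.
#' @param params a [cart_params()].
#' @param min_age results are restricted to individuals at least this old.
#' @param anchor_year calendar year anchoring the scenario SD; defaults to
#'   the first wave.
#' @param seed master seed; every stream of the run derives from it.
#' @param keep_trajectories retain per-individual projected slices (memory
#'   grows with `n_bootstrap`; default off).
#' @return an object of class `mobility_projection`.
#' @export
project_mobility <- function(dataset,
                             scenarios = list(scenario_spec(0),
                                              scenario_spec(1),
                                              scenario_spec(2)),
                             n_bootstrap = 120L, horizon_year = 2026L,
                             params = cart_params(), min_age = 76L,
                             anchor_year = NULL, seed = 1L,
                             keep_trajectories = FALSE) {
  wave_years <- infer_wave_years(dataset)
  if (length(wave_years) < 2) stopf("dataset has no recognisable wave grid")
  last <- wave_years[length(wave_years)]
  if (horizon_year < last || (horizon_year - last) %% 2 != 0)
    stopf("horizon year %d is not reachable from %d by biennial steps",
          horizon_year, last)
  if (n_bootstrap < 1) stopf("n_bootstrap must be positive")
  anchor_year <- anchor_year %||% wave_years[1]
  proj_years <- if (horizon_year > last) seq(last + 2L, horizon_year, by = 2L)
                else integer(0)
  years <- c(wave_years, proj_years)
  studies <- sort(unique(dataset$study))
  scen_names <- vapply(scenarios, function(s) paste0("scenario", s$id), "")
  if (anyDuplicated(scen_names)) stopf("duplicate scenario ids")
  dn <- list(replicate = seq_len(n_bootstrap), scenario = scen_names,
             year = years, study = c(studies, "ALL"), outcome = .outcome_vars)
  prev <- array(NA_real_, dim = lengths(dn), dimnames = dn)
  denom <- array(NA_real_, dim = lengths(dn), dimnames = dn)
  spec_store <- vector("list", n_bootstrap)
  traj <- if (keep_trajectories) vector("list", n_bootstrap) else NULL

  for (r in seq_len(n_bootstrap)) {
    boot <- rao_wu_resample(dataset, r, seed)
    rep_seed <- derive_seed(seed, "replicate", r)
    prep <- tryCatch(
      prepare_replicate(boot, params, wave_years, anchor_year, rep_seed),
      error = function(e) stopf("replicate %d failed: %s", r, conditionMessage(e)))
    spec_store[[r]] <- prep$specs
    obs_cells <- prevalence_cells(prep$panel, wave_years, studies, min_age)
    for (sc in scen_names) {
      prev[r, sc, as.character(wave_years), , ] <- obs_cells$prev
      denom[r, sc, as.character(wave_years), , ] <- obs_cells$denom
    }
    if (keep_trajectories) traj[[r]] <- list()
    for (i in seq_along(scenarios)) {
      slices <- tryCatch(
        project_one_scenario(prep$panel, prep$specs, scenarios[[i]], params,
                             prep$anchor_sds, wave_years, horizon_year,
                             rep_seed),
        error = function(e) stopf("replicate %d (%s) failed: %s", r,
                                  scen_names[i], conditionMessage(e)))
      for (ys in names(slices)) {
        cells <- slice_prevalence(slices[[ys]], studies, min_age)
        prev[r, scen_names[i], ys, , ] <- cells$prev
        denom[r, scen_names[i], ys, , ] <- cells$denom
      }
      if (keep_trajectories) traj[[r]][[scen_names[i]]] <- slices
    }
  }
  structure(list(prevalence = prev, denominators = denom, specs = spec_store,
                 scenarios = scenarios, wave_years = wave_years,
                 proj_years = proj_years, min_age = min_age,
                 n_bootstrap = n_bootstrap, params = params, seed = seed,
                 studies = studies, trajectories = traj,
                 call = match.call()),
            class = "mobility_projection")
}

# prevalence of both outcomes at every observed wave, by study and pooled
prevalence_cells <- function(panel, wave_years, studies, min_age) {
  dn <- list(year = wave_years, study = c(studies, "ALL"),
             outcome = .outcome_vars)
  pr <- array(NA_real_, lengths(dn), dn)
  de <- array(NA_real_, lengths(dn), dn)
  for (y in wave_years) {
    alive <- panel[[wave_col("alive", y)]]
    age <- panel[[wave_col("age", y)]]
    in_denom <- !is.na(alive) & alive == 1 & age >= min_age
    for (o in .outcome_vars) {
      v <- panel[[wave_col(o, y)]]
      for (st in c(studies, "ALL")) {
        rows <- in_denom & (st == "ALL" | panel$study == st)
        de[as.character(y), st, o] <- sum(rows)
        pr[as.character(y), st, o] <-
          if (sum(rows) > 0) mean(v[rows], na.rm = TRUE) else NA_real_
      }
    }
  }
  list(prev = pr, denom = de)
}

slice_prevalence <- function(slice, studies, min_age) {
  dn <- list(study = c(studies, "ALL"), outcome = .outcome_vars)
  pr <- array(NA_real_, lengths(dn), dn)
  de <- array(NA_real_, lengths(dn), dn)
  in_denom <- !is.na(slice$alive) & slice$alive == 1 & slice$age >= min_age
  for (o in .outcome_vars) for (st in c(studies, "ALL")) {
    rows <- in_denom & (st == "ALL" | slice$study == st)
    de[st, o] <- sum(rows)
    pr[st, o] <- if (sum(rows) > 0) mean(slice[[o]][rows], na.rm = TRUE) else NA_real_
  }
  list(prev = pr, denom = de)
}
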