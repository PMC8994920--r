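#' Prevalence of a mobility limitation in a completed panel
#'
#' The proportion with the limitation among individuals alive at the given
#' year's wave and aged at least `min_age` (default 76: with a baseline
#' minimum age of 50 in 2000, 76 is the minimum age at the 2026 horizon, so
#' this restriction keeps the reported population comparable across years).
#'
#' @param panel either a wide completed panel (columns `<var>_<year>`) or a
#'   projected-wave slice (columns `year, age, alive, climb, walk, study`).
#' @param year calendar year.
#' @param outcome `"climb"` or `"walk"`.
#' @param study a study label, or `"ALL"` for the pooled estimate.
#' @param min_age minimum age of the reported population.
#' @return the prevalence (a proportion).
#' @export
prevalence <- function(panel, year, outcome, study = "ALL", min_age = 76) {
  if (!outcome %in% .outcome_vars)
    stopf("unknown outcome '%s'", outcome)
  if ("year" %in% names(panel) && outcome %in% names(panel)) {
    sl <- panel[panel$year == year, , drop = FALSE]
    alive <- sl$alive; age <- sl$age; v <- sl[[outcome]]; stcol <- sl$study
  } else {
    cols <- wave_col(c("alive", "age", outcome), year)
    if (!all(cols %in% names(panel)))
      stopf("panel has no wave at year %d", year)
    alive <- panel[[cols[1]]]; age <- panel[[cols[2]]]
    v <- panel[[cols[3]]]; stcol <- panel$study
  }
  rows <- !is.na(alive) & alive == 1 & age >= min_age &
    (study == "ALL" | stcol == study)
  if (!sum(rows))
    stopf("empty denominator: no one alive and aged >= %s at %d%s", min_age,
          year, if (study == "ALL") "" else paste0(" in ", study))
  if (anyNA(v[rows]))
    stopf("outcome '%s' has missing values in the denominator at %d", outcome, year)
  mean(v[rows])
}

replicate_values <- function(fit, scenario, year, study, outcome) {
  sc <- if (is.numeric(scenario)) paste0("scenario", scenario) else scenario
  dn <- dimnames(fit$prevalence)
  if (!sc %in% dn$scenario) stopf("no scenario '%s' in this run", sc)
  if (!as.character(year) %in% dn$year) stopf("no year %s in this run", year)
  if (!study %in% dn$study) stopf("no study '%s' in this run", study)
  if (!outcome %in% dn$outcome) stopf("no outcome '%s'", outcome)
  fit$prevalence[, sc, as.character(year), study, outcome]
}

summary_row <- function(vals, method) {
  vals <- vals[!is.na(vals)]
  if (length(vals) < 2) stopf("need at least 2 replicates to summarise")
  m <- mean(vals); v <- stats::var(vals)
  if (method == "normal") {
    lo <- m - 1.96 * stats::sd(vals); hi <- m + 1.96 * stats::sd(vals)
  } else {
    q <- stats::quantile(vals, c(0.025, 0.975), names = FALSE)
    lo <- q[1]; hi <- q[2]
  }
  c(mean = m, variance = v, cri_low = lo, cri_high = hi)
}

#' Monte-Carlo summary of a projected prevalence
#'
#' The expected value and predictive variance of a (scenario, year, study,
#' outcome) prevalence are the mean and variance of its bootstrap-replicate
#' values; the 95% credible interval is by default the 2.5th/97.5th
#' percentile of the replicate distribution (a normal approximation,
#' mean +/- 1.96 SD, is available by flag).
#'
#' @param fit a `mobility_projection`.
#' @param scenario scenario id (0/1/2) or name (`"scenario1"`).
#' @param year calendar year.
#' @param study study label or `"ALL"`.
#' @param outcome `"climb"` or `"walk"`.
#' @param method `"percentile"` (default) or `"normal"`.
#' @return a one-row data.frame: mean, variance, cri_low, cri_high,
#'   n_replicates.
#' @export
summarize_prevalence <- function(fit, scenario, year, study = "ALL", outcome,
                                 method = c("percentile", "normal")) {
  method <- match.arg(method)
  vals <- replicate_values(fit, scenario, year, study, outcome)
  s <- summary_row(vals, method)
  data.frame(scenario = if (is.numeric(scenario)) paste0("scenario", scenario)
             else scenario,
             year = year, study = study, outcome = outcome,
             mean = s[["mean"]], variance = s[["variance"]],
             cri_low = s[["cri_low"]], cri_high = s[["cri_high"]],
             n_replicates = sum(!is.na(vals)))
}

#' Scenario contrast of projected prevalences
#'
#' Per-replicate paired difference (first minus second scenario) of the two
#' cells, summarised like [summarize_prevalence()]. Pairing within replicate
#' preserves the shared-history correlation of scenario copies, which is
#' what makes the contrast of a null intervention exactly zero.
#'
#' @param fit a `mobility_projection`.
#' @param scenarios length-2 vector of scenario ids/names: difference is
#'   `scenarios[1] - scenarios[2]`.
#' @param year calendar year (a length-2 vector contrasts
#'   `year[1] - year[2]` within `scenarios[1]`, e.g. 2026 vs 2012).
#' @param study study label or `"ALL"`.
#' @param outcome `"climb"` or `"walk"`.
#' @param method `"percentile"` or `"normal"`.
#' @return a one-row data.frame as in [summarize_prevalence()].
#' @export
contrast <- function(fit, scenarios, year, study = "ALL", outcome,
                     method = c("percentile", "normal")) {
  method <- match.arg(method)
  if (length(year) == 2) {
    a <- replicate_values(fit, scenarios[1], year[1], study, outcome)
    b <- replicate_values(fit, scenarios[1], year[2], study, outcome)
    label <- sprintf("%s: %d - %d", scenarios[1], year[1], year[2])
  } else {
    stopifnot(length(scenarios) == 2)
    a <- replicate_values(fit, scenarios[1], year, study, outcome)
    b <- replicate_values(fit, scenarios[2], year, study, outcome)
    label <- sprintf("%s - %s at %d",
                     if (is.numeric(scenarios[1])) paste0("scenario", scenarios[1]) else scenarios[1],
                     if (is.numeric(scenarios[2])) paste0("scenario", scenarios[2]) else scenarios[2],
                     year)
  }
  d <- a - b
  s <- summary_row(d, method)
  data.frame(contrast = label, study = study, outcome = outcome,
             mean = s[["mean"]], variance = s[["variance"]],
             cri_low = s[["cri_low"]], cri_high = s[["cri_high"]],
             n_replicates = sum(!is.na(d)))
}

#' Predictor selection proportions across bootstrap replicates
#'
#' For each projected-wave imputation target, the proportion of bootstrap
#' replicates in which each candidate predictor was selected by the
#' selection tree. Rows below the reporting threshold (default 10%) are
#' suppressed; forced predictors (in every model by construction) are
#' listed separately with `forced = TRUE`.
#'
#' @param fit a `mobility_projection`.
#' @param threshold minimum selection proportion reported.
#' @param targets restrict to these targets (default: the two mobility
#'   limitation outcomes at the projected wave).
#' @return a data.frame (target, predictor, proportion, forced), sorted by
#'   target then decreasing proportion.
#' @export
selection_table <- function(fit, threshold = 0.10, targets = NULL) {
  specs <- fit$specs
  all_targets <- names(specs[[1]])
  if (is.null(targets)) {
    last <- pos_years(length(fit$wave_years))[length(fit$wave_years)]
    targets <- intersect(wave_col(.outcome_vars, last), all_targets)
    if (!length(targets)) targets <- all_targets
  }
  R <- length(specs)
  rows <- list()
  for (tg in targets) {
    counts <- table(unlist(lapply(specs, function(s) unique(s[[tg]]$selected))))
    props <- as.numeric(counts) / R
    keep <- props >= threshold
    if (any(keep))
      rows[[tg]] <- data.frame(target = tg, predictor = names(counts)[keep],
                               proportion = props[keep], forced = FALSE)
    forced <- specs[[1]][[tg]]$forced
    if (length(forced))
      rows[[paste0(tg, ".forced")]] <-
        data.frame(target = tg, predictor = forced, proportion = 1, forced = TRUE)
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out[order(out$target, out$forced, -out$proportion), , drop = FALSE]
}

#' @export
print.mobility_projection <- function(x, ...) {
  cat("Mobility limitation projection\n")
  cat(sprintf("  %d bootstrap replicates, %d scenario(s), seed %d\n",
              x$n_bootstrap, length(x$scenarios), x$seed))
  cat(sprintf("  observed waves %d-%d, projected to %d, ages >= %d\n",
              x$wave_years[1], x$wave_years[length(x$wave_years)],
              if (length(x$proj_years)) x$proj_years[length(x$proj_years)]
              else x$wave_years[length(x$wave_years)], x$min_age))
  last_year <- if (length(x$proj_years)) x$proj_years[length(x$proj_years)]
               else x$wave_years[length(x$wave_years)]
  if (x$n_bootstrap >= 2) {
    cat(sprintf("  pooled prevalence at %d (%% , 95%% CrI):\n", last_year))
    for (sc in dimnames(x$prevalence)$scenario) for (o in .outcome_vars) {
      s <- summarize_prevalence(x, sc, last_year, "ALL", o)
      cat(sprintf("    %-10s %-6s %5.1f (%.1f, %.1f)\n", sc, o,
                  100 * s$mean, 100 * s$cri_low, 100 * s$cri_high))
    }
  }
  invisible(x)
}

#' Summarise a projection run
#'
#' Builds the full table of Monte-Carlo summaries: one row per (scenario,
#' year, study, outcome) with the replicate mean, predictive variance and
#' 95% credible interval.
#'
#' @param object a `mobility_projection`.
#' @param method `"percentile"` or `"normal"` credible intervals.
#' @param ... unused.
#' @return a data.frame of class `mobility_projection_summary`.
#' @export
summary.mobility_projection <- function(object,
                                        method = c("percentile", "normal"),
                                        ...) {
  method <- match.arg(method)
  dn <- dimnames(object$prevalence)
  rows <- list()
  for (sc in dn$scenario) for (y in dn$year) for (st in dn$study)
    for (o in dn$outcome) {
      vals <- object$prevalence[, sc, y, st, o]
      if (all(is.na(vals))) next
      s <- summary_row(vals, method)
      rows[[length(rows) + 1]] <-
        data.frame(scenario = sc, year = as.integer(y), study = st,
                   outcome = o, mean = s[["mean"]], variance = s[["variance"]],
                   cri_low = s[["cri_low"]], cri_high = s[["cri_high"]])
    }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  class(out) <- c("mobility_projection_summary", "data.frame")
  out
}

#' @export
print.mobility_projection_summary <- function(x, digits = 1, ...) {
  y <- as.data.frame(x)
  for (cl in c("mean", "cri_low", "cri_high"))
    y[[cl]] <- round(100 * y[[cl]], digits)
  y$variance <- signif(y$variance, 3)
  names(y)[names(y) == "mean"] <- "mean_pct"
  print(y, row.names = FALSE)
  invisible(x)
}

#' Plot projected prevalence series
#'
#' One line per scenario of the Monte-Carlo mean prevalence over calendar
#' years for a given outcome and study, with dashed 95% credible bounds;
#' the vertical line separates observed waves from projections.
#'
#' @param x a `mobility_projection`.
#' @param outcome `"climb"` or `"walk"`.
#' @param study study label or `"ALL"`.
#' @param ... further arguments passed to [graphics::matplot()].
#' @export
plot.mobility_projection <- function(x, outcome = "climb", study = "ALL", ...) {
  dn <- dimnames(x$prevalence)
  years <- as.integer(dn$year)
  scs <- dn$scenario
  m <- sapply(scs, function(sc) vapply(dn$year, function(y)
    mean(x$prevalence[, sc, y, study, outcome], na.rm = TRUE), 0))
  lo <- sapply(scs, function(sc) vapply(dn$year, function(y)
    stats::quantile(x$prevalence[, sc, y, study, outcome], 0.025, na.rm = TRUE), 0))
  hi <- sapply(scs, function(sc) vapply(dn$year, function(y)
    stats::quantile(x$prevalence[, sc, y, study, outcome], 0.975, na.rm = TRUE), 0))
  graphics::matplot(years, 100 * m, type = "b", pch = 19, lty = 1,
                    xlab = "year", ylab = sprintf("%s limitation prevalence (%%)", outcome),
                    main = sprintf("%s, ages >= %d", study, x$min_age), ...)
  graphics::matlines(years, 100 * lo, lty = 2)
  graphics::matlines(years, 100 * hi, lty = 2)
  if (length(x$proj_years))
    graphics::abline(v = x$wave_years[length(x$wave_years)] + 1, col = "grey")
  graphics::legend("topleft", legend = scs, col = seq_along(scs), lty = 1,
                   bty = "n")
  invisible(x)
}

#' Export run results to CSV and a manifest
#'
#' Writes the prevalence summary series (one row per scenario, year, study,
#' outcome), the selection-proportion table and a JSON manifest (seed,
#' parameters, wave grid) to a directory; if the run kept per-individual
#' trajectories, one CSV per (replicate, scenario, year) slice is written
#' under `trajectories/`.
#'
#' @param fit a `mobility_projection`.
#' @param dir output directory (created if needed).
#' @param method credible-interval method passed to
#'   [summary.mobility_projection()].
#' @return `dir`, invisibly.
#' @export
export_results <- function(fit, dir, method = c("percentile", "normal")) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  utils::write.csv(as.data.frame(summary(fit, method = match.arg(method))),
                   file.path(dir, "prevalence.csv"), row.names = FALSE)
  utils::write.csv(selection_table(fit),
                   file.path(dir, "selection-proportions.csv"),
                   row.names = FALSE)
  manifest <- list(
    seed = fit$seed, n_bootstrap = fit$n_bootstrap,
    wave_years = fit$wave_years, proj_years = fit$proj_years,
    min_age = fit$min_age,
    scenarios = vapply(fit$scenarios, function(s) s$id, 0L),
    params = unclass(fit$params))
  jsonlite::write_json(manifest, file.path(dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA)
  if (!is.null(fit$trajectories)) {
    tdir <- file.path(dir, "trajectories")
    dir.create(tdir, showWarnings = FALSE)
    for (r in seq_along(fit$trajectories))
      for (sc in names(fit$trajectories[[r]])) {
        slices <- fit$trajectories[[r]][[sc]]
        if (!length(slices)) next
        utils::write.csv(do.call(rbind, slices),
                         file.path(tdir, sprintf("rep%03d-%s.csv", r, sc)),
                         row.names = FALSE)
      }
  }
  invisible(dir)
}
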