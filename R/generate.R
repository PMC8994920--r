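#' Generate a complete synthetic cohort
#'
#' Simulates the pre-missingness individual-level panel: one row per
#' individual, per-wave columns `<var>_<year>`. Disability evolves as a
#' first-order latent Markov chain over `config$latent$states`; the six ADL
#' items, six IADL items (coded 1 = no difficulty, 0 = difficulty) and the two
#' mobility limitation outcomes (coded 1 = has limitation) are drawn
#' conditionally on the current latent state (outcomes additionally on age
#' band); the five binary risk factors follow first-order transitions; death
#' is drawn per wave from a logistic model in age and latent state and is
#' absorbing. Ages increment deterministically by 2 between waves.
#'
#' The returned table carries the latent state in columns `latent_<year>`
#' (used by test oracles); [inject_missingness()] and [assemble_dataset()]
#' drop them.
#'
#' @param config a [cohort_config()].
#' @param seed RNG seed; defaults to `config$seed`.
#' @return a `data.frame` (class `cohort_table`) with columns
#'   `id, study, sex, education` and per-wave variables.
#' @export
generate_cohort <- function(config, seed = config$seed) {
  validate_cohort_config(config)
  set.seed(derive_seed(seed, "generate"))
  wy <- config$wave_years
  W <- length(wy)
  n <- sum(config$n_per_study)
  k <- length(config$latent$states)
  band <- function(age) findInterval(age, config$age_bands) + 1L

  tab <- data.frame(
    id = seq_len(n),
    study = rep(config$study_labels, config$n_per_study),
    sex = rbinom(n, 1, config$sex_p_male),
    education = sample(names(config$education_probs), n, replace = TRUE,
                       prob = config$education_probs),
    stringsAsFactors = FALSE
  )
  age_pool <- seq(config$baseline_age_range[1], config$baseline_age_range[2])
  age0 <- age_pool[sample.int(length(age_pool), n, replace = TRUE)]

  rf <- config$risk_factor_probs
  mc <- config$mortality_coefs
  latent <- matrix(NA_integer_, n, W)
  alive  <- matrix(NA_integer_, n, W)
  latent[, 1] <- sample.int(k, n, replace = TRUE, prob = config$latent$init)
  alive[, 1] <- 1L
  rf_prev <- list()

  for (w in seq_len(W)) {
    year <- wy[w]
    age_w <- age0 + 2L * (w - 1L)
    if (w > 1) {
      # death between waves w-1 and w, from age and state at w-1
      was_alive <- which(alive[, w - 1] == 1L)
      eta <- mc$intercept + mc$age * (age0[was_alive] + 2 * (w - 2) - 70) +
        mc$state[latent[was_alive, w - 1]]
      die <- rbinom(length(was_alive), 1, plogis(eta))
      alive[, w] <- 0L
      alive[was_alive[die == 0L], w] <- 1L
      # latent transition for survivors
      nxt <- rep(NA_integer_, n)
      idx <- which(alive[, w] == 1L)
      if (length(idx)) {
        u <- runif(length(idx))
        cum <- t(apply(config$latent$trans, 1, cumsum))
        nxt[idx] <- max.col(u <= cum[latent[idx, w - 1], , drop = FALSE],
                            ties.method = "first")
      }
      latent[, w] <- nxt
    }
    a_idx <- which(alive[, w] == 1L)
    st <- latent[a_idx, w]

    tab[[wave_col("age", year)]] <- age_w
    tab[[wave_col("alive", year)]] <- alive[, w]
    for (o in .outcome_vars) {
      v <- rep(NA_integer_, n)
      p <- config$outcome_probs[[o]][cbind(st, band(age_w[a_idx]))]
      v[a_idx] <- rbinom(length(a_idx), 1, p)
      tab[[wave_col(o, year)]] <- v
    }
    for (j in seq_along(.item_vars)) {
      v <- rep(NA_integer_, n)
      v[a_idx] <- rbinom(length(a_idx), 1, config$item_probs[st, j])
      tab[[wave_col(.item_vars[j], year)]] <- v
    }
    for (r in .risk_vars) {
      v <- rep(NA_integer_, n)
      if (w == 1) {
        v[a_idx] <- rbinom(length(a_idx), 1, rf[r, "p0"])
      } else {
        prev <- rf_prev[[r]]
        p <- ifelse(prev[a_idx] == 1L, rf[r, "p11"], rf[r, "p01"])
        v[a_idx] <- rbinom(length(a_idx), 1, p)
      }
      rf_prev[[r]] <- v
      tab[[wave_col(r, year)]] <- v
    }
    tab[[wave_col("latent", year)]] <- latent[, w]
  }
  if (config$age_topcode) tab <- topcode_ages(tab)
  class(tab) <- c("cohort_table", "data.frame")
  tab
}

#' Top-code ages (disclosure-control emulation)
#'
#' Recodes all age values above `over` to `code`, emulating the
#' disclosure-control recoding some source studies apply. Off by default in
#' the generator because it deliberately breaks the deterministic
#' age-increment structure.
#'
#' @param table a cohort table.
#' @param over ages strictly above this are recoded.
#' @param code replacement value.
#' @export
topcode_ages <- function(table, over = 90, code = 99) {
  for (cl in grep("^age_[0-9]{4}$", names(table), value = TRUE))
    table[[cl]][table[[cl]] > over] <- code
  table
}

#' Inject missingness into a complete cohort table
#'
#' Applies, in order: structural missingness rules (blanked with certainty),
#' wave non-response (a skipped non-baseline wave blanks all substantive
#' variables but not age, sex or vital status), and independent cell-level
#' missingness on substantive variables. Cells at waves where the individual
#' is dead are already missing by construction. Latent-state columns are
#' dropped.
#'
#' @param table a complete cohort table from [generate_cohort()].
#' @param config the [cohort_config()] that produced it.
#' @param seed RNG seed; defaults to `config$seed`.
#' @return the table with missingness injected.
#' @export
inject_missingness <- function(table, config, seed = config$seed) {
  set.seed(derive_seed(seed, "missingness"))
  table <- table[, !grepl("^latent_", names(table)), drop = FALSE]
  table <- apply_structural_rules(table, config)
  mis <- config$missingness
  wy <- config$wave_years
  n <- nrow(table)
  # wave non-response (not at the study's baseline wave)
  if (mis$wave_nonresponse > 0) {
    for (year in wy) {
      skip <- rbinom(n, 1, mis$wave_nonresponse) == 1L
      skip[config$baseline_wave[table$study] == year] <- FALSE
      if (any(skip))
        for (v in .substantive_vars)
          table[[wave_col(v, year)]][skip] <- NA
    }
  }
  # independent cell-level missingness
  if (mis$item > 0) {
    for (year in wy) for (v in .substantive_vars) {
      cl <- wave_col(v, year)
      hit <- rbinom(n, 1, mis$item) == 1L
      table[[cl]][hit] <- NA
    }
  }
  class(table) <- c("cohort_table", "data.frame")
  table
}

apply_structural_rules <- function(table, config) {
  for (rule in config$missingness$structural %||% list()) {
    rows <- table$study == rule$study
    years <- if (identical(rule$years, "all")) config$wave_years else rule$years
    vars <- if (identical(rule$vars, "all")) .substantive_vars else rule$vars
    for (year in years) for (v in vars) {
      cl <- wave_col(v, year)
      if (cl %in% names(table)) table[[cl]][rows] <- NA
    }
  }
  table
}

#' Exact marginal prevalence under the generator's model
#'
#' Computes, by forward recursion over (latent state, survival) jointly with
#' the deterministic age process, the exact probability of a mobility
#' limitation outcome at a given wave among survivors. Serves as the analytic
#' recovery target for the projection engine: on synthetic data the
#' scenario-0 projection must track this quantity.
#'
#' The wave index may exceed the observed grid, in which case the recursion
#' is simply continued (the generator's chain is time-homogeneous).
#'
#' @param config a [cohort_config()].
#' @param wave 1-based wave index (1 = baseline).
#' @param outcome `"climb"` or `"walk"`.
#' @return the prevalence among survivors at that wave.
#' @export
analytic_prevalence <- function(config, wave, outcome) {
  validate_cohort_config(config)
  if (!outcome %in% .outcome_vars)
    stopf("unknown outcome '%s' (expected one of: %s)", outcome,
          paste(.outcome_vars, collapse = ", "))
  stopifnot(wave >= 1)
  band <- function(age) findInterval(age, config$age_bands) + 1L
  ages <- seq(config$baseline_age_range[1], config$baseline_age_range[2])
  mc <- config$mortality_coefs
  Tm <- config$latent$trans
  pout <- config$outcome_probs[[outcome]]
  num <- 0; den <- 0
  for (a in ages) {
    f <- config$latent$init # joint P(state, alive) at wave 1
    if (wave > 1) for (w in 2:wave) {
      surv <- 1 - plogis(mc$intercept + mc$age * (a + 2 * (w - 2) - 70) + mc$state)
      f <- as.numeric((f * surv) %*% Tm)
    }
    num <- num + sum(f * pout[, band(a + 2 * (wave - 1))])
    den <- den + sum(f)
  }
  num / den
}

#' Write / read a cohort table as CSV
#'
#' One row per individual, columns `id, study, sex, education` then
#' `<var>_<year>`; missing cells empty.
#'
#' @param table a cohort table or analysis dataset.
#' @param path file path.
#' @export
write_cohort_csv <- function(table, path) {
  utils::write.csv(table, path, row.names = FALSE, na = "")
  invisible(path)
}

#' @rdname write_cohort_csv
#' @export
read_cohort_csv <- function(path) {
  tab <- utils::read.csv(path, stringsAsFactors = FALSE,
                         na.strings = c("NA", ""))
  class(tab) <- c("cohort_table", "data.frame")
  tab
}
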