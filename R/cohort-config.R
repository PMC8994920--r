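#' Configuration of the synthetic cohort generator
#'
#' Builds a validated configuration for [generate_cohort()]. The generator
#' emulates the statistical structure the projection method assumes: three
#' longitudinal studies observed on a common biennial wave grid, individual
#' disability evolving as a first-order latent Markov chain, ADL/IADL items
#' and mobility outcomes drawn conditionally on the latent state, binary risk
#' factors with first-order transitions, mortality increasing with age and
#' disability, and the studies' characteristic structural missingness
#' (a study without its first wave, a study observed only at baseline and at
#' a single follow-up randomly placed on one of the last two waves).
#'
#' @param n_per_study named integer vector, individuals per study.
#' @param wave_years  strictly increasing even-spaced years (spacing 2).
#' @param baseline_age_range integer range of ages at the first wave
#'   (minimum 50); baseline ages are uniform on this range.
#' @param latent list with `states` (labels), `init` (baseline distribution)
#'   and `trans` (per-wave transition matrix, rows sum to 1).
#' @param item_probs matrix `length(states) x 12`: probability of *no
#'   difficulty* (coded 1) for each of the six ADL then six IADL items,
#'   given the latent state.
#' @param outcome_probs named list `climb`, `walk`; each a matrix
#'   `length(states) x length(age_bands)+1` of limitation probabilities by
#'   latent state and age band.
#' @param age_bands increasing interior cut points for age bands (an age `a`
#'   falls in band `1 + sum(a >= age_bands)`).
#' @param risk_factor_probs data.frame with rownames the five risk factors
#'   and columns `p0` (baseline prevalence), `p01`, `p11` (per-wave
#'   transition probabilities into state 1).
#' @param mortality_coefs list with `intercept`, `age` (per year, centred at
#'   70) and `state` (one log-odds offset per latent state) for the per-wave
#'   probability of dying before the next wave.
#' @param missingness list with `wave_nonresponse` (probability a non-baseline
#'   wave is skipped; skipping blanks substantive variables, not age, sex or
#'   vital status), `item` (independent cell-level missingness probability on
#'   substantive variables), and `structural`, a list of rules
#'   `list(study=, years=, vars=)` where `years`/`vars` may be `"all"`.
#' @param baseline_wave named vector: each study's first participating wave.
#' @param single_followup `NULL`, or `list(study=, years=c(y1, y2))`: the
#'   study observed at baseline plus one follow-up to be randomly assigned to
#'   one of two final waves during assembly.
#' @param sex_p_male probability of male sex.
#' @param education_probs probabilities of low/medium/high education.
#' @param age_topcode if `TRUE`, ages over 90 are recoded to 99 on output
#'   (a disclosure-control artefact of one source study; default off).
#' @param seed default RNG seed used when `generate_cohort()` is called
#'   without one.
#' @return an object of class `cohort_config`.
#' @seealso [generate_cohort()], [inject_missingness()], [analytic_prevalence()]
#' @export
cohort_config <- function(n_per_study = c(HRS = 9765, ELSA = 10815, H2000 = 4402),
                          wave_years = seq(2000, 2012, by = 2),
                          baseline_age_range = c(50, 85),
                          latent = list(
                            states = c("good", "limited", "severe"),
                            init   = c(0.70, 0.24, 0.06),
                            trans  = matrix(c(0.86, 0.11, 0.03,
                                              0.18, 0.68, 0.14,
                                              0.03, 0.17, 0.80),
                                            nrow = 3, byrow = TRUE)
                          ),
                          item_probs = default_item_probs(length(latent$states)),
                          outcome_probs = default_outcome_probs(length(latent$states)),
                          age_bands = c(65, 76),
                          risk_factor_probs = default_risk_factor_probs(),
                          mortality_coefs = list(intercept = -4.8, age = 0.09,
                                                 state = c(0, 0.8, 1.8)),
                          missingness = list(
                            wave_nonresponse = 0.12,
                            item = 0.02,
                            structural = list(
                              list(study = "ELSA",  years = 2000,
                                   vars = "all"),
                              list(study = "H2000", years = c(2002, 2004, 2006, 2008),
                                   vars = "all"),
                              list(study = "HRS",   years = "all", vars = "adl2"),
                              list(study = "H2000", years = "all", vars = "iadl6")
                            )
                          ),
                          baseline_wave = c(HRS = 2000, ELSA = 2002, H2000 = 2000),
                          single_followup = list(study = "H2000",
                                                 years = c(2010, 2012)),
                          sex_p_male = 0.45,
                          education_probs = c(low = 0.4, medium = 0.35, high = 0.25),
                          age_topcode = FALSE,
                          seed = 1L) {
  cfg <- structure(list(
    n_per_study = n_per_study, study_labels = names(n_per_study),
    wave_years = as.integer(wave_years),
    baseline_age_range = as.integer(baseline_age_range),
    latent = latent, item_probs = item_probs, outcome_probs = outcome_probs,
    age_bands = age_bands, risk_factor_probs = risk_factor_probs,
    mortality_coefs = mortality_coefs, missingness = missingness,
    baseline_wave = baseline_wave, single_followup = single_followup,
    sex_p_male = sex_p_male, education_probs = education_probs,
    age_topcode = isTRUE(age_topcode), seed = as.integer(seed)
  ), class = "cohort_config")
  validate_cohort_config(cfg)
  cfg
}

#' @rdname cohort_config
#' @param n_states number of latent states.
#' @export
default_item_probs <- function(n_states = 3) {
  base <- c(good = 0.97, limited = 0.80, severe = 0.35)[seq_len(n_states)]
  # per-item offsets keep items distinguishable (housework and shopping are
  # the most demanding IADL items, eating the least demanding ADL item)
  off <- c(0.00, -0.01, 0.01, 0.00, -0.02, 0.02,   # adl1..adl6
           0.02, -0.04, -0.02, -0.08, 0.02, 0.01)  # iadl1..iadl6
  m <- outer(unname(base), rep(1, 12)) + outer(rep(1, n_states), off)
  m <- pmin(pmax(m, 0), 1)
  dimnames(m) <- list(NULL, .item_vars)
  m
}

#' @rdname cohort_config
#' @export
default_outcome_probs <- function(n_states = 3) {
  climb <- rbind(c(0.06, 0.10, 0.16),
                 c(0.30, 0.40, 0.50),
                 c(0.70, 0.80, 0.88))[seq_len(n_states), , drop = FALSE]
  walk  <- rbind(c(0.01, 0.02, 0.05),
                 c(0.08, 0.12, 0.20),
                 c(0.40, 0.50, 0.65))[seq_len(n_states), , drop = FALSE]
  list(climb = climb, walk = walk)
}

#' @rdname cohort_config
#' @export
default_risk_factor_probs <- function() {
  data.frame(
    p0  = c(smoker = 0.18, obese = 0.28, alcohol = 0.60,
            hypertension = 0.45, vpa = 0.45),
    p01 = c(0.02, 0.05, 0.15, 0.12, 0.18),
    p11 = c(0.90, 0.92, 0.90, 0.95, 0.72)
  )
}

validate_cohort_config <- function(cfg) {
  fail <- function(field, msg) stopf("invalid cohort_config: field '%s' %s", field, msg)
  if (is.null(names(cfg$n_per_study)) || any(!nzchar(names(cfg$n_per_study))))
    fail("n_per_study", "must be a named vector of study sizes")
  if (any(cfg$n_per_study < 1)) fail("n_per_study", "must be positive")
  wy <- cfg$wave_years
  if (length(wy) < 2 || any(diff(wy) != 2))
    fail("wave_years", "must be strictly increasing with spacing 2")
  if (cfg$baseline_age_range[1] < 50)
    fail("baseline_age_range", "minimum baseline age is 50")
  if (diff(cfg$baseline_age_range) < 0) fail("baseline_age_range", "must be a range")
  k <- length(cfg$latent$states)
  if (length(cfg$latent$init) != k || abs(sum(cfg$latent$init) - 1) > 1e-8 ||
      any(cfg$latent$init < 0))
    fail("latent$init", "must be a probability distribution over the states")
  tr <- cfg$latent$trans
  if (!is.matrix(tr) || any(dim(tr) != k) || any(tr < 0) || any(tr > 1) ||
      any(abs(rowSums(tr) - 1) > 1e-8))
    fail("latent$trans", "rows must be probability distributions")
  if (!is.matrix(cfg$item_probs) || nrow(cfg$item_probs) != k ||
      ncol(cfg$item_probs) != 12 ||
      any(cfg$item_probs < 0) || any(cfg$item_probs > 1))
    fail("item_probs", "must be a states x 12 matrix of probabilities")
  nb <- length(cfg$age_bands) + 1
  for (o in .outcome_vars) {
    m <- cfg$outcome_probs[[o]]
    if (is.null(m) || !is.matrix(m) || nrow(m) != k || ncol(m) != nb ||
        any(m < 0) || any(m > 1))
      fail(paste0("outcome_probs$", o),
           sprintf("must be a states x %d matrix of probabilities", nb))
  }
  rf <- cfg$risk_factor_probs
  if (!all(.risk_vars %in% rownames(rf)))
    fail("risk_factor_probs", "must have rows smoker/obese/alcohol/hypertension/vpa")
  if (any(unlist(rf[, c("p0", "p01", "p11")]) < 0) ||
      any(unlist(rf[, c("p0", "p01", "p11")]) > 1))
    fail("risk_factor_probs", "probabilities must lie in [0, 1]")
  if (length(cfg$mortality_coefs$state) != k)
    fail("mortality_coefs$state", "needs one offset per latent state")
  mis <- cfg$missingness
  if (mis$wave_nonresponse < 0 || mis$wave_nonresponse > 1)
    fail("missingness$wave_nonresponse", "must lie in [0, 1]")
  if (mis$item < 0 || mis$item > 1) fail("missingness$item", "must lie in [0, 1]")
  for (rule in mis$structural %||% list()) {
    if (!rule$study %in% cfg$study_labels)
      fail("missingness$structural", sprintf("references unknown study '%s'", rule$study))
    if (!identical(rule$years, "all") && !all(rule$years %in% wy))
      fail("missingness$structural",
           sprintf("references years outside the wave grid (study '%s')", rule$study))
    if (!identical(rule$vars, "all") && !all(rule$vars %in% .substantive_vars))
      fail("missingness$structural",
           sprintf("references unknown variables (study '%s')", rule$study))
  }
  if (!all(names(cfg$baseline_wave) %in% cfg$study_labels) ||
      !all(cfg$study_labels %in% names(cfg$baseline_wave)))
    fail("baseline_wave", "must name every study")
  if (!all(cfg$baseline_wave %in% wy)) fail("baseline_wave", "must lie on the wave grid")
  sf <- cfg$single_followup
  if (!is.null(sf)) {
    if (!sf$study %in% cfg$study_labels)
      fail("single_followup", sprintf("references unknown study '%s'", sf$study))
    if (length(sf$years) != 2 || !all(sf$years %in% wy))
      fail("single_followup", "years must be two waves on the grid")
  }
  invisible(cfg)
}

#' @export
print.cohort_config <- function(x, ...) {
  cat("<cohort_config>\n")
  cat("  studies: ", paste(sprintf("%s (n=%d)", x$study_labels, x$n_per_study),
                           collapse = ", "), "\n", sep = "")
  cat("  waves:   ", paste(range(x$wave_years), collapse = "-"),
      " biennial (", length(x$wave_years), " waves)\n", sep = "")
  cat("  latent states: ", paste(x$latent$states, collapse = ", "), "\n", sep = "")
  cat("  missingness: wave non-response ", x$missingness$wave_nonresponse,
      ", item ", x$missingness$item, ", ",
      length(x$missingness$structural %||% list()), " structural rule(s)\n", sep = "")
  invisible(x)
}

#' Read a cohort configuration from YAML
#'
#' Reads a YAML file whose keys mirror the arguments of [cohort_config()];
#' absent keys fall back to the defaults. Matrices are given as lists of rows.
#'
#' @param path path to a YAML file.
#' @return a `cohort_config`.
#' @export
read_cohort_config <- function(path) {
  y <- yaml::read_yaml(path)
  args <- list()
  if (!is.null(y$n_per_study)) args$n_per_study <- unlist(y$n_per_study)
  if (!is.null(y$wave_years)) args$wave_years <- as.integer(y$wave_years)
  if (!is.null(y$baseline_age_range)) args$baseline_age_range <- as.integer(y$baseline_age_range)
  if (!is.null(y$latent)) {
    args$latent <- list(states = y$latent$states,
                        init = as.numeric(y$latent$init),
                        trans = do.call(rbind, lapply(y$latent$trans, as.numeric)))
  }
  if (!is.null(y$item_probs)) {
    m <- do.call(rbind, lapply(y$item_probs, as.numeric)); colnames(m) <- .item_vars
    args$item_probs <- m
  }
  if (!is.null(y$outcome_probs))
    args$outcome_probs <- lapply(y$outcome_probs,
                                 function(o) do.call(rbind, lapply(o, as.numeric)))
  if (!is.null(y$age_bands)) args$age_bands <- as.numeric(y$age_bands)
  if (!is.null(y$risk_factor_probs)) {
    rf <- as.data.frame(do.call(rbind, lapply(y$risk_factor_probs, unlist)))
    args$risk_factor_probs <- rf
  }
  if (!is.null(y$mortality_coefs)) args$mortality_coefs <- y$mortality_coefs
  if (!is.null(y$missingness)) args$missingness <- y$missingness
  if (!is.null(y$baseline_wave)) args$baseline_wave <- unlist(y$baseline_wave)
  if (!is.null(y$studies) && !is.null(y$studies$single_followup))
    args$single_followup <- y$studies$single_followup
  else if (!is.null(y$single_followup)) args$single_followup <- y$single_followup
  for (nm in c("sex_p_male", "age_topcode", "seed"))
    if (!is.null(y[[nm]])) args[[nm]] <- y[[nm]]
  if (!is.null(y$education_probs)) args$education_probs <- unlist(y$education_probs)
  do.call(cohort_config, args)
}
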