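# Shared fixtures: small cohort configurations exercising particular
# structural features, built in code at test time.

# default structure at reduced size
small_cfg <- function(n = c(HRS = 300, ELSA = 300, H2000 = 200), seed = 42, ...) {
  cohort_config(n_per_study = n, seed = seed, ...)
}

# single-study configuration with no missingness and no structural rules:
# isolates the generative model from the missingness machinery
clean_cfg <- function(n = 1000, seed = 42, ...) {
  cohort_config(
    n_per_study = c(S1 = n),
    missingness = list(wave_nonresponse = 0, item = 0, structural = list()),
    baseline_wave = c(S1 = 2000),
    single_followup = NULL,
    seed = seed, ...)
}

# two-state chain with a deterministic stair-climbing outcome, constant
# items, independent risk factors and no mortality: the observable outcome
# is itself a first-order Markov chain whose marginal the projection engine
# must recover
markov_cfg <- function(n = 5000, seed = 42,
                       trans = matrix(c(0.85, 0.15,
                                        0.25, 0.75), 2, byrow = TRUE),
                       init = c(0.8, 0.2)) {
  k <- 2
  item_probs <- matrix(1, k, 12, dimnames = list(NULL, paste0(
    rep(c("adl", "iadl"), each = 6), 1:6)))
  outcome_probs <- list(
    climb = matrix(rep(c(0, 1), 3), k, 3),          # deterministic in state
    walk  = matrix(rep(c(0.05, 0.30), 3), k, 3))    # noisy companion
  cohort_config(
    n_per_study = c(S1 = n),
    latent = list(states = c("good", "limited"), init = init, trans = trans),
    item_probs = item_probs, outcome_probs = outcome_probs,
    mortality_coefs = list(intercept = -30, age = 0, state = c(0, 0)),
    missingness = list(wave_nonresponse = 0, item = 0, structural = list()),
    baseline_wave = c(S1 = 2000),
    single_followup = NULL,
    seed = seed)
}

# three-state configuration with a steep monotone state -> outcome link and
# tight item-state coupling, so the IADL score is a strong outcome
# predictor; no missingness, modest mortality
planted_cfg <- function(n = 3000, seed = 42) {
  item_probs <- rbind(rep(0.98, 12), rep(0.55, 12), rep(0.08, 12))
  colnames(item_probs) <- paste0(rep(c("adl", "iadl"), each = 6), 1:6)
  outcome_probs <- list(
    climb = rbind(c(0.04, 0.06, 0.08), c(0.45, 0.50, 0.55), c(0.90, 0.92, 0.94)),
    walk  = rbind(c(0.01, 0.02, 0.03), c(0.15, 0.20, 0.25), c(0.55, 0.60, 0.70)))
  rf <- default_risk_factor_probs()
  rf["vpa", ] <- c(0.5, 0.25, 0.70)
  cohort_config(
    n_per_study = c(S1 = n),
    latent = list(states = c("good", "limited", "severe"),
                  init = c(0.65, 0.27, 0.08),
                  trans = matrix(c(0.85, 0.12, 0.03,
                                   0.20, 0.65, 0.15,
                                   0.04, 0.16, 0.80), 3, byrow = TRUE)),
    item_probs = item_probs, outcome_probs = outcome_probs,
    risk_factor_probs = rf,
    mortality_coefs = list(intercept = -5.2, age = 0.07, state = c(0, 0.6, 1.4)),
    missingness = list(wave_nonresponse = 0, item = 0, structural = list()),
    baseline_wave = c(S1 = 2000),
    single_followup = NULL,
    seed = seed)
}

assembled_small <- function(seed = 42, n = c(HRS = 300, ELSA = 300, H2000 = 200)) {
  cfg <- small_cfg(n = n, seed = seed)
  assemble_dataset(inject_missingness(generate_cohort(cfg), cfg), cfg)
}

# a complete panel with scores attached, for frame/scenario tests
clean_panel <- function(n = 400, seed = 42) {
  cfg <- clean_cfg(n = n, seed = seed)
  tab <- generate_cohort(cfg)
  attach_scores(tab[, !grepl("^latent_", names(tab))])
}
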