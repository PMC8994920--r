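test_that("configuration validation names the offending field", {
  expect_error(cohort_config(baseline_age_range = c(40, 85)),
               "baseline_age_range")
  expect_error(cohort_config(wave_years = c(2000, 2003, 2006)), "wave_years")
  bad <- list(states = c("a", "b"), init = c(0.5, 0.5),
              trans = matrix(c(0.9, 0.2, 0.2, 0.8), 2))
  expect_error(cohort_config(latent = bad), "trans")
  expect_error(
    cohort_config(missingness = list(wave_nonresponse = 0, item = 0,
                                     structural = list(list(study = "NOPE",
                                                            years = 2000,
                                                            vars = "all")))),
    "unknown study")
})

test_that("zero hazard keeps everyone alive; saturated items give score 6", {
  cfg <- clean_cfg(n = 200, seed = 3)
  cfg$mortality_coefs$intercept <- -1e6
  tab <- generate_cohort(cfg)
  for (y in cfg$wave_years)
    expect_true(all(tab[[paste0("alive_", y)]] == 1))

  cfg2 <- clean_cfg(n = 150, seed = 4, item_probs = matrix(1, 3, 12))
  tab2 <- generate_cohort(cfg2)
  pan <- attach_scores(tab2[, !grepl("^latent_", names(tab2))])
  for (y in cfg2$wave_years) {
    alive <- pan[[paste0("alive_", y)]] == 1
    expect_true(all(pan[[paste0("adl_score_", y)]][alive] == 6))
    expect_true(all(pan[[paste0("iadl_score_", y)]][alive] == 6))
  }
})

test_that("death is absorbing and ages increment by exactly 2", {
  cfg <- small_cfg(n = c(HRS = 400, ELSA = 300, H2000 = 300), seed = 9)
  tab <- generate_cohort(cfg)
  wy <- cfg$wave_years
  al <- as.matrix(tab[, paste0("alive_", wy)])
  expect_true(all(apply(al, 1, function(a) all(diff(a) <= 0))))
  ag <- as.matrix(tab[, paste0("age_", wy)])
  expect_true(all(apply(ag, 1, diff) == 2))
  # substantive variables are missing wherever dead
  for (y in wy) {
    dead <- tab[[paste0("alive_", y)]] == 0
    if (!any(dead)) next
    expect_true(all(is.na(tab[dead, paste0("climb_", y)])))
    expect_true(all(is.na(tab[dead, paste0("iadl3_", y)])))
  }
})

test_that("latent chain marginals match the matrix-power oracle at large n", {
  trans <- matrix(c(0.85, 0.15, 0.25, 0.75), 2, byrow = TRUE)
  init <- c(0.8, 0.2)
  cfg <- markov_cfg(n = 50000, seed = 11, trans = trans, init = init)
  tab <- generate_cohort(cfg)
  # no mortality: wave-7 latent marginal = init %*% trans^6
  marg <- init
  for (i in 1:6) marg <- as.numeric(marg %*% trans)
  emp <- mean(tab$latent_2012 == 2)
  se <- sqrt(marg[2] * (1 - marg[2]) / 50000)
  expect_lt(abs(emp - marg[2]), 3 * se)
  # pooled empirical transition frequencies recover the configured matrix
  from <- unlist(tab[, paste0("latent_", seq(2000, 2010, 2))])
  to <- unlist(tab[, paste0("latent_", seq(2002, 2012, 2))])
  ok <- !is.na(from) & !is.na(to)
  p12 <- mean(to[ok & from == 1] == 2)
  se12 <- sqrt(trans[1, 2] * (1 - trans[1, 2]) / sum(ok & from == 1))
  expect_lt(abs(p12 - trans[1, 2]), 4 * se12)
})

test_that("analytic_prevalence matches degenerate, stationary and enumerated cases", {
  # all mass on one state: prevalence is that state's outcome probability
  cfg <- clean_cfg(n = 10)
  cfg$latent$init <- c(1, 0, 0)
  cfg$outcome_probs$climb[1, ] <- 0.1
  expect_equal(analytic_prevalence(cfg, 1, "climb"), 0.1)
  expect_error(analytic_prevalence(cfg, 1, "stairs"), "unknown outcome")

  # identity transitions + state-independent mortality: constant prevalence
  # across waves when outcome probabilities do not depend on age band
  cfg2 <- clean_cfg(n = 10)
  cfg2$latent$trans <- diag(3)
  cfg2$mortality_coefs <- list(intercept = -3, age = 0, state = c(0, 0, 0))
  for (o in c("climb", "walk"))
    cfg2$outcome_probs[[o]] <- matrix(rep(c(0.1, 0.4, 0.8), 3), 3)
  p1 <- analytic_prevalence(cfg2, 1, "climb")
  for (w in 2:7) expect_equal(analytic_prevalence(cfg2, w, "climb"), p1)

  # brute-force path enumeration over a 3-wave, 3-state chain
  cfg3 <- clean_cfg(n = 10)
  cfg3$baseline_age_range <- c(60, 60) # single age, pure chain computation
  enum <- function(cfg, wave, outcome) {
    k <- 3; mc <- cfg$mortality_coefs
    paths <- expand.grid(rep(list(1:k), wave))
    num <- 0; den <- 0
    for (i in seq_len(nrow(paths))) {
      pr <- cfg$latent$init[paths[i, 1]]
      if (wave > 1) for (w in 2:wave) {
        surv <- 1 - plogis(mc$intercept + mc$age * (60 + 2 * (w - 2) - 70) +
                             mc$state[paths[i, w - 1]])
        pr <- pr * surv * cfg$latent$trans[paths[i, w - 1], paths[i, w]]
      }
      band <- findInterval(60 + 2 * (wave - 1), cfg$age_bands) + 1
      num <- num + pr * cfg$outcome_probs[[outcome]][paths[i, wave], band]
      den <- den + pr
    }
    num / den
  }
  expect_equal(analytic_prevalence(cfg3, 3, "climb"), enum(cfg3, 3, "climb"),
               tolerance = 1e-12)
  expect_equal(analytic_prevalence(cfg3, 3, "walk"), enum(cfg3, 3, "walk"),
               tolerance = 1e-12)
})

test_that("analytic and empirical prevalence agree at large n", {
  cfg <- clean_cfg(n = 50000, seed = 13)
  tab <- generate_cohort(cfg)
  for (w in c(1, 4, 7)) {
    y <- cfg$wave_years[w]
    alive <- tab[[paste0("alive_", y)]] == 1
    emp <- mean(tab[[paste0("climb_", y)]][alive])
    th <- analytic_prevalence(cfg, w, "climb")
    se <- sqrt(th * (1 - th) / sum(alive))
    expect_lt(abs(emp - th), 4 * se)
  }
})

test_that("missingness injection honours rules, rates and reproducibility", {
  cfg <- clean_cfg(n = 300, seed = 5)
  tab <- generate_cohort(cfg)
  nolat <- tab[, !grepl("^latent_", names(tab))]
  # all probabilities zero, no structural rules: identity
  expect_identical(inject_missingness(tab, cfg),
                   structure(nolat, class = c("cohort_table", "data.frame")))

  # structural rule blanks a whole wave for one study
  cfg2 <- small_cfg(n = c(HRS = 100, ELSA = 100, H2000 = 100), seed = 6)
  cfg2$missingness$wave_nonresponse <- 0; cfg2$missingness$item <- 0
  cfg2$missingness$structural <- list(list(study = "ELSA", years = 2000,
                                           vars = "all"))
  out <- inject_missingness(generate_cohort(cfg2), cfg2)
  elsa <- out$study == "ELSA"
  expect_true(all(is.na(out[elsa, paste0(c("climb", "adl1", "vpa"), "_2000")])))
  expect_true(all(!is.na(out$age_2000[elsa])))
  expect_true(all(!is.na(out$alive_2000[elsa])))
  expect_false(all(is.na(out$climb_2000[!elsa])))

  # cell-level missingness rate within a 4-SE binomial band
  cfg3 <- clean_cfg(n = 10000, seed = 7)
  cfg3$mortality_coefs$intercept <- -1e6 # keep all cells at risk
  cfg3$missingness$item <- 0.1
  out3 <- inject_missingness(generate_cohort(cfg3), cfg3)
  cells <- unlist(out3[, paste0("iadl", rep(1:6, 7), "_",
                                rep(cfg3$wave_years, each = 6))])
  frac <- mean(is.na(cells))
  expect_gt(frac, 0.09); expect_lt(frac, 0.11)
  # reproducible under a fixed seed
  out3b <- inject_missingness(generate_cohort(cfg3), cfg3)
  expect_identical(out3, out3b)
})
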