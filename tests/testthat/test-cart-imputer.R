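test_that("cart_params enforces donor and sweep minima", {
  expect_error(cart_params(min_leaf = 1), "min_leaf")
  expect_error(cart_params(n_chained_iters = 0), "n_chained_iters")
  expect_s3_class(cart_params(), "cart_params")
})

test_that("selection finds perfect predictors and drops null ones", {
  set.seed(1)
  n <- 400
  d <- data.frame(X = rbinom(n, 1, 0.5), N1 = rnorm(n), N2 = rbinom(n, 1, 0.5))
  d$y <- d$X
  sp <- select_predictors(d, "y", c("X", "N1", "N2"), forced = character())
  expect_identical(sp$selected, "X")

  # independent target with a high complexity threshold: nothing selected,
  # final design is the forced set alone
  d$z <- rbinom(n, 1, 0.5)
  sp2 <- select_predictors(d, "z", c("X", "N1", "N2"), forced = c("X"),
                           params = cart_params(complexity = 0.05))
  expect_identical(sp2$selected, character(0))
  expect_identical(sp2$forced, "X")

  expect_error(select_predictors(d, "nope", "X"), "unknown target")
  d$allmiss <- NA_real_
  expect_error(select_predictors(d, "allmiss", "X"), "fully missing")
  # zero candidates: spec with only forced predictors
  sp3 <- select_predictors(d, "y", character(0), forced = c("N1"))
  expect_identical(sp3$selected, character(0))
  expect_identical(sp3$forced, "N1")
})

test_that("selection recovers planted lag-1 and score structure", {
  # outcome at wave 2 driven by its lag and the concurrent IADL-like score
  hits <- 0
  for (r in 1:100) {
    set.seed(1000 + r)
    n <- 500
    d <- data.frame(out_lag = rbinom(n, 1, 0.3),
                    score = sample(0:6, n, replace = TRUE),
                    noise1 = rnorm(n), noise2 = rbinom(n, 1, 0.5))
    p <- plogis(-2.5 + 2.2 * d$out_lag + 0.45 * (6 - d$score))
    d$out <- rbinom(n, 1, p)
    sp <- select_predictors(d, "out", c("out_lag", "score", "noise1", "noise2"))
    if (all(c("out_lag", "score") %in% sp$selected)) hits <- hits + 1
  }
  expect_gte(hits, 90)
})

test_that("donor draws come from the routed node's observed donors", {
  # constant observed target: every imputation is that constant
  d <- data.frame(y = c(rep(1, 50), rep(NA, 20)), x = rnorm(70))
  sp <- imputation_spec("y", "x", selected = "x")
  out <- impute_variable(d, sp, seed = 1)
  expect_true(all(out$y == 1))

  # rows identical (in predictors) to a single observed stratum with donor
  # values {0, 0, 1}: each imputation is a uniform donor draw, P(1) ~ 1/3
  set.seed(99)
  base <- data.frame(g = rep(c(0, 1), c(3, 30)),
                     y = c(0, 0, 1, rbinom(30, 1, 0.9)))
  d2 <- rbind(base, data.frame(g = 0, y = rep(NA, 10000)))
  out2 <- impute_variable(d2, imputation_spec("y", "g", selected = "g"),
                          params = cart_params(min_leaf = 3))
  draws <- out2$y[-seq_len(nrow(base))]
  expect_true(all(draws %in% c(0, 1)))
  se <- sqrt((1 / 3) * (2 / 3) / 10000)
  expect_lt(abs(mean(draws) - 1 / 3), 4 * se)

  # donor closure for a continuous target
  set.seed(7)
  d3 <- data.frame(x = rnorm(300), z = rbinom(300, 1, 0.5))
  d3$y <- round(d3$x + rnorm(300), 3)
  d3$y[sample(300, 60)] <- NA
  obs_vals <- d3$y[!is.na(d3$y)]
  out3 <- impute_variable(d3, imputation_spec("y", c("x", "z"),
                                              selected = c("x", "z")), seed = 2)
  expect_true(all(out3$y[is.na(d3$y)] %in% obs_vals))
})

test_that("chained imputation is an identity on complete data and preserves marginals under MCAR", {
  pan <- clean_panel(n = 200, seed = 5)
  out <- chained_impute(pan, specs = list(), seed = 1)
  expect_identical(out, pan)

  # MCAR 20% on a binary variable, n = 5000: marginal preserved within 4 SE
  set.seed(21)
  n <- 5000
  p_true <- 0.3
  d <- data.frame(x1 = rbinom(n, 1, 0.5), x2 = rnorm(n))
  d$y <- rbinom(n, 1, p_true)
  miss <- rbinom(n, 1, 0.2) == 1
  d$y[miss] <- NA
  specs <- list(y = imputation_spec("y", c("x1", "x2"), selected = c("x1", "x2")))
  out2 <- chained_impute(d, specs, seed = 3)
  expect_false(anyNA(out2$y))
  se <- sqrt(p_true * (1 - p_true) / n)
  expect_lt(abs(mean(out2$y) - p_true), 4 * se)

  # a forced-only spec reproduces the observed marginal within each stratum
  set.seed(22)
  d3 <- data.frame(g = rep(0:1, each = 2500))
  d3$y <- rbinom(5000, 1, ifelse(d3$g == 1, 0.7, 0.2))
  ymiss <- rbinom(5000, 1, 0.25) == 1
  truth <- d3$y
  d3$y[ymiss] <- NA
  out3 <- chained_impute(d3, list(y = imputation_spec("y", "g", forced = "g")),
                         seed = 4)
  for (g in 0:1) {
    obs_marg <- mean(d3$y[d3$g == g], na.rm = TRUE)
    imp_marg <- mean(out3$y[ymiss & d3$g == g])
    n_imp <- sum(ymiss & d3$g == g)
    expect_lt(abs(imp_marg - obs_marg),
              4 * sqrt(obs_marg * (1 - obs_marg) / n_imp))
  }
})

test_that("chained imputation fails loudly on an unspecified incomplete variable", {
  d <- data.frame(x = 1:10, y = c(1:8, NA, NA))
  expect_error(chained_impute(d, specs = list()), "'y'")
})

test_that("chained imputation is deterministic and donor-closed on cohort data", {
  ds <- assembled_small(seed = 17, n = c(HRS = 150, ELSA = 150, H2000 = 100))
  params <- cart_params(n_chained_iters = 2)
  specs <- mobproj:::build_observed_specs(ds, params,
                                          seq(2000, 2012, 2), 2012)
  a <- chained_impute(ds, specs, params, seed = 10)
  b <- chained_impute(ds, specs, params, seed = 10)
  expect_identical(a, b)
  # donor closure: imputed values occur among the variable's observed values
  for (cl in c("climb_2006", "iadl4_2002", "vpa_2010")) {
    was_na <- is.na(ds[[cl]])
    filled <- !is.na(a[[cl]]) & was_na
    expect_true(all(a[[cl]][filled] %in% ds[[cl]][!was_na]))
  }
  # death masking: no substantive values at dead waves
  dead12 <- a$alive_2012 == 0
  expect_true(all(is.na(a$climb_2012[dead12])))
  # forced-predictor law: every spec's design includes the anchor demographics
  for (sp in specs)
    expect_true(all(c("age_2012", "sex", "education") %in%
                      union(sp$forced, sp$selected)))
})
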