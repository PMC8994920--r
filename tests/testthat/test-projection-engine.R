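test_that("Rao-Wu resampling draws n-1 per stratum with the right multiplicities", {
  ds <- assembled_small(seed = 23, n = c(HRS = 40, ELSA = 30, H2000 = 10))
  boot <- rao_wu_resample(ds, replicate = 1, seed = 5)
  for (st in unique(ds$study))
    expect_equal(sum(boot$study == st), sum(ds$study == st) - 1)
  expect_false(anyDuplicated(boot$id) > 0) # fresh ids
  expect_true(all(boot$orig_id %in% ds$id))

  # smallest stratum: size 2 -> one of the two originals
  tiny <- ds[ds$study == "H2000", ][1:2, ]
  b2 <- rao_wu_resample(tiny, 1, seed = 1)
  expect_equal(nrow(b2), 1)
  expect_true(b2$orig_id %in% tiny$id)
  expect_error(rao_wu_resample(tiny[1, , drop = FALSE], 1, 1), "fewer than 2")

  # expected inclusion count of any individual is (n-1)/n
  n <- 10
  toy <- data.frame(id = 1:n, study = "A")
  counts <- numeric(10000)
  for (r in 1:10000)
    counts[r] <- sum(rao_wu_resample(toy, r, seed = 77)$orig_id == 1)
  se <- sqrt(((n - 1) / n) / 10000) # Poisson-binomial scale bound
  expect_lt(abs(mean(counts) - (n - 1) / n), 4 * se)
})

test_that("Rao-Wu bootstrap variance of a stratum mean matches s^2/n", {
  # equal-weight SRS toy: variance over replicates of the resampled mean
  # approximates s^2/n (the m = n-1 rescaling makes this consistent)
  set.seed(13)
  n <- 25
  x <- rnorm(n, sd = 2)
  toy <- data.frame(id = 1:n, study = "A", x = x)
  means <- vapply(1:20000, function(r)
    mean(rao_wu_resample(toy, r, seed = 3)$x), 0)
  expect_lt(abs(var(means) / (var(x) / n) - 1), 0.05)
})

test_that("projection frames have the fixed window shape and survivor chain", {
  pan <- clean_panel(n = 250, seed = 41)
  wy <- seq(2000, 2012, 2)
  fr <- build_projection_frame(pan, wy)
  expect_equal(fr$W, 7)
  expect_equal(fr$proj_year, 2014)
  # upper block = whole panel; lower block = survivors at 2012
  expect_equal(sum(fr$df$block == "history"), nrow(pan))
  expect_equal(sum(fr$df$block == "project"), sum(pan$alive_2012 == 1))
  lower <- fr$df[fr$df$block == "project", ]
  # at the new wave only age and sex are non-missing, age incremented by 2
  expect_true(all(is.na(lower$climb_9014)))
  expect_true(all(is.na(lower$alive_9014)))
  expect_false(anyNA(lower$age_9014))
  expect_false(anyNA(lower$sex))
  m <- match(lower$id, pan$id)
  expect_equal(lower$age_9014, pan$age_2012[m] + 2L)
  # window positions hold the shifted waves
  expect_equal(lower$climb_9002, pan$climb_2002[m])
  expect_equal(lower$climb_9012, pan$climb_2012[m])

  # complete the wave by hand, advance, and check the survivor subset and ages
  py <- fr$pos_years
  proj <- fr$df$block == "project"
  fr$df$alive_9014[proj] <- rep_len(c(1L, 1L, 0L), sum(proj))
  for (v in c("climb", "walk", "smoker", "obese", "alcohol", "hypertension",
              "vpa")) fr$df[[paste0(v, "_9014")]][proj] <- 0L
  fr$df$adl_score_9014[proj] <- 6L; fr$df$iadl_score_9014[proj] <- 6L
  fr2 <- advance_frame(fr)
  expect_equal(fr2$step, 2L)
  expect_equal(fr2$proj_year, 2016)
  expect_equal(sum(fr2$df$block == "history"), sum(proj))
  # survivor chain: next step's rows are the subset imputed alive
  alive_ids <- fr$df$id[proj][fr$df$alive_9014[proj] == 1]
  expect_setequal(fr2$df$id[fr2$df$block == "project"], alive_ids)
  lower2 <- fr2$df[fr2$df$block == "project", ]
  m2 <- match(lower2$id, pan$id)
  expect_equal(lower2$age_9014, pan$age_2012[m2] + 4L)
  expect_true(all(is.na(lower2$climb_9014)))
})

test_that("a 50-year-old at baseline is 76 at the 2026 projection wave", {
  # 13 biennial increments from 2000 to 2026
  cfg <- clean_cfg(n = 60, seed = 55)
  cfg$baseline_age_range <- c(50, 50)
  cfg$mortality_coefs$intercept <- -1e6
  tab <- generate_cohort(cfg)
  pan <- attach_scores(tab[, !grepl("^latent_", names(tab))])
  fr <- build_projection_frame(pan, cfg$wave_years)
  fill <- function(fr) {
    proj <- fr$df$block == "project"
    fr$df$alive_9014[proj] <- 1L
    for (v in c("climb", "walk", "smoker", "obese", "alcohol",
                "hypertension", "vpa")) fr$df[[paste0(v, "_9014")]][proj] <- 0L
    fr$df$adl_score_9014[proj] <- 6L; fr$df$iadl_score_9014[proj] <- 6L
    fr
  }
  repeat {
    fr <- fill(fr)
    if (fr$proj_year == 2026) break
    fr <- advance_frame(fr)
  }
  lower <- fr$df[fr$df$block == "project", ]
  expect_true(all(lower$age_9014 == 76L))
  expect_equal(fr$proj_year, 2026)
  expect_equal(2026 - 2000, 13 * 2)
})

test_that("zero-step projection returns the imputed panel only and respects death", {
  ds <- assembled_small(seed = 29, n = c(HRS = 120, ELSA = 120, H2000 = 80))
  params <- cart_params(n_chained_iters = 2)
  rep0 <- project_replicate(ds, scenario_spec(0), horizon_year = 2012,
                            params = params, seed = 2)
  expect_length(rep0$slices, 0)
  expect_false(anyNA(rep0$panel$climb_2012[rep0$panel$alive_2012 == 1]))
  expect_error(project_replicate(ds, scenario_spec(0), 2015, params, 2),
               "biennial")

  # individuals dead at the last observed wave never enter a frame
  rep1 <- project_replicate(ds, scenario_spec(0), 2014, params, seed = 2)
  dead_ids <- rep1$panel$id[rep1$panel$alive_2012 == 0]
  expect_false(any(dead_ids %in% rep1$slices[["2014"]]$id))
})

test_that("scenario copies share history and the run is deterministic", {
  ds <- assembled_small(seed = 37, n = c(HRS = 120, ELSA = 120, H2000 = 80))
  params <- cart_params(n_chained_iters = 2)
  fit <- project_mobility(ds, list(scenario_spec(0), scenario_spec(1)),
                          n_bootstrap = 2, horizon_year = 2014,
                          params = params, seed = 9, min_age = 60)
  # observed-wave prevalences are identical across scenarios within replicate
  expect_identical(fit$prevalence[, "scenario0", "2012", , ],
                   fit$prevalence[, "scenario1", "2012", , ])
  fit2 <- project_mobility(ds, list(scenario_spec(0), scenario_spec(1)),
                           n_bootstrap = 2, horizon_year = 2014,
                           params = params, seed = 9, min_age = 60)
  expect_identical(fit$prevalence, fit2$prevalence)
  expect_identical(fit$specs, fit2$specs)
})
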