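test_that("relative growth scales to the site maximum", {
  ev <- data.frame(year = 2001, doy = c(100, 200, 300),
                   cum_fg_obs = c(4559.5, 9119, 2000),
                   treatment = "a", replicate = "r1")
  out <- relative_growth(ev)
  expect_equal(out$rel_fg_obs[2], 100)        # site maximum maps to 100
  expect_equal(out$rel_fg_obs[1], 50)
  expect_equal(relative_growth(ev[1, ])$rel_fg_obs, 100)  # single event
  expect_equal(relative_growth(ev, reference_max = 18238)$rel_fg_obs[2], 50)
  expect_error(relative_growth(ev, reference_max = -1), "positive")
})

test_that("pairing attaches cum_rgr_env and never drops events silently", {
  wx <- generate_weather(climate_spec(seed = 8), years = 1)
  st <- simulate_growth(wx, site_config(39.6, asw_max = 127))
  ev <- data.frame(year = 2001, doy = c(150, 250), cum_fg_obs = c(1, 2),
                   treatment = "a", replicate = "r1")
  paired <- pair_with_model(ev, st)
  expect_equal(paired$cum_rgr_env, st$cum_rgr_env[c(150, 250)])
  # invariant to event ordering
  flipped <- pair_with_model(ev[2:1, ], st)
  expect_equal(sort(flipped$cum_rgr_env), sort(paired$cum_rgr_env))
  ev$year[2] <- 1990
  expect_error(pair_with_model(ev, st), "year 1990, doy 250")
})

test_that("a noiseless line is recovered exactly", {
  d <- data.frame(cum_rgr_env = seq(10, 150, by = 10))
  d$rel_fg_obs <- 5 + 2 * d$cum_rgr_env
  fit <- suppressWarnings(fit_observed_vs_modelled(d))  # lm warns on exact fits
  expect_equal(fit$slope, 2, tolerance = 1e-10)
  expect_equal(fit$intercept, 5, tolerance = 1e-9)
  expect_equal(fit$r2, 1, tolerance = 1e-12)
  expect_equal(fit$sd_reg, 0, tolerance = 1e-9)
  expect_equal(fit$aape, 0, tolerance = 1e-10)
})

test_that("coefficients and criteria match closed-form OLS on a small fit", {
  x <- c(2, 5, 9, 14, 20)
  y <- c(3.1, 7.9, 11.2, 19.4, 24.8)
  fit <- fit_observed_vs_modelled(data.frame(cum_rgr_env = x, rel_fg_obs = y))
  oracle <- closed_form_ols(x, y)
  expect_equal(fit$slope, oracle$slope, tolerance = 1e-10)
  expect_equal(fit$intercept, oracle$intercept, tolerance = 1e-10)
  expect_equal(fit$r2, oracle$r2, tolerance = 1e-10)
  expect_equal(fit$sd_reg, oracle$sd_reg, tolerance = 1e-10)
  expect_equal(fit$aape, oracle$aape, tolerance = 1e-10)
  # brute-force residual loops agree to 10 decimals
  res <- y - (oracle$intercept + oracle$slope * x)
  sse <- 0; ape <- 0
  for (i in seq_along(y)) {
    sse <- sse + res[i]^2
    ape <- ape + abs(res[i]) / y[i]
  }
  expect_equal(fit$sd_reg, sqrt(sse / (length(y) - 2)), tolerance = 1e-10)
  expect_equal(fit$aape, 100 * ape / length(y), tolerance = 1e-10)
})

test_that("average absolute percent error matches a hand-worked example", {
  # two observations 100 and 200 with fitted values 90 and 220:
  # (10/100 + 20/200)/2 * 100 = 10%. Build data whose OLS fit passes through
  # exactly those fitted values: with two x levels duplicated, fitted values
  # are the group means.
  d <- data.frame(cum_rgr_env = c(1, 1, 2, 2),
                  rel_fg_obs = c(80, 100, 200, 240))
  fit <- fit_observed_vs_modelled(d)
  expect_equal(stats::fitted(fit$model), c(90, 90, 220, 220),
               ignore_attr = TRUE)
  expect_equal(fit$aape,
               100 / 4 * (10 / 80 + 10 / 100 + 20 / 200 + 20 / 240))
})

test_that("adding a constant shifts only the intercept", {
  set.seed(31)
  d <- data.frame(cum_rgr_env = runif(30, 0, 150))
  d$rel_fg_obs <- 4 + 0.5 * d$cum_rgr_env + rnorm(30, 0, 3)
  f1 <- fit_observed_vs_modelled(d)
  d2 <- d
  d2$rel_fg_obs <- d$rel_fg_obs + 25
  f2 <- fit_observed_vs_modelled(d2)
  expect_equal(f2$intercept, f1$intercept + 25, tolerance = 1e-9)
  expect_equal(f2$slope, f1$slope, tolerance = 1e-12)
  expect_equal(f2$r2, f1$r2, tolerance = 1e-9)
})

test_that("the intercept-zero flag agrees with an explicit t test", {
  set.seed(13)
  for (true_a in c(0, 40)) {
    d <- data.frame(cum_rgr_env = runif(25, 0, 100))
    d$rel_fg_obs <- true_a + 0.5 * d$cum_rgr_env + rnorm(25, 0, 8)
    fit <- fit_observed_vs_modelled(d)
    tstat <- fit$intercept / fit$intercept_se
    manual <- abs(tstat) < stats::qt(0.975, fit$n - 2)
    expect_identical(fit$intercept_zero_flag, manual)
  }
})

test_that("year dummies use reference coding and recover planted offsets", {
  set.seed(21)
  d <- expand.grid(cum_rgr_env = seq(20, 160, by = 20),
                   year = c(1997, 1998, 1999))
  offs <- c(`1997` = 0, `1998` = 9, `1999` = 14)
  d$rel_fg_obs <- -9 + 0.44 * d$cum_rgr_env + offs[as.character(d$year)] +
    rnorm(nrow(d), 0, 1)
  fit <- fit_observed_vs_modelled(d, dummies = "year")
  expect_named(fit$dummy_effects, c("year1998", "year1999"))  # 1997 = reference
  expect_equal(unname(fit$dummy_effects["year1998"]), 9, tolerance = 0.5)
  expect_equal(unname(fit$dummy_effects["year1999"]), 14, tolerance = 0.5)
  expect_equal(fit$slope, 0.44, tolerance = 0.05)
})

test_that("degenerate designs and undefined AAPE are errors", {
  d <- data.frame(cum_rgr_env = 1:6, rel_fg_obs = 2 * (1:6), year = 2001,
                  treatment = "a")
  expect_error(fit_observed_vs_modelled(d, dummies = "year"), "only one year")
  expect_error(fit_observed_vs_modelled(d, dummies = "year+treatment"))
  d0 <- data.frame(cum_rgr_env = 0:5, rel_fg_obs = c(0, 2, 4, 6, 8, 10))
  expect_error(suppressWarnings(fit_observed_vs_modelled(d0)),
               "AAPE undefined")
  expect_error(fit_observed_vs_modelled(d[1:3, ]), "too few")
})

test_that("drought impact ratios reproduce the worked drought comparison", {
  expect_equal(drought_impact_ratio(3323, 5736), 0.58)
  expect_equal(drought_impact_ratio(92, 174), 0.53)
  expect_equal(drought_impact_ratio(100, 100), 1)
  expect_equal(drought_impact_ratio(1, 3, digits = NULL), 1 / 3)
  expect_error(drought_impact_ratio(1, 0), "zero")
})

test_that("fit results serialise to JSON with all reported fields", {
  d <- data.frame(cum_rgr_env = 1:10, rel_fg_obs = 5 + 2 * (1:10))
  js <- fit_result_json(suppressWarnings(fit_observed_vs_modelled(d)))
  parsed <- jsonlite::fromJSON(js)
  expect_setequal(names(parsed),
                  c("intercept", "intercept_se", "slope", "slope_se",
                    "dummy_effects", "r2", "sd_reg", "aape", "n",
                    "intercept_zero_flag"))
  expect_equal(parsed$n, 10)
})
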