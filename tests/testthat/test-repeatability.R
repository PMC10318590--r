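test_that("REML equals the closed-form ANOVA estimator on balanced data", {
  for (seed in c(1, 2, 3)) {
    d <- sim_vc_data(60, 2, s2H = 2, s2E = 1, seed = seed)
    reml <- fit_variance_components(d, method = "reml")
    cf <- fit_variance_components(d, method = "anova_closed_form")
    expect_equal(reml$sigma2_H, cf$sigma2_H, tolerance = 1e-6)
    expect_equal(reml$sigma2_E, cf$sigma2_E, tolerance = 1e-6)
  }
})

test_that("REML agrees with an independent mixed-model fit (lme4)", {
  skip_if_not_installed("lme4")
  d <- sim_vc_data(80, 3, s2H = 1.5, s2E = 0.8, seed = 7)
  d_unbal <- d[-c(3, 41, 100), ] # missing plots allowed
  for (dat in list(d, d_unbal)) {
    ours <- fit_variance_components(dat)
    m <- lme4::lmer(value ~ factor(rep) + (1 | hybrid), data = dat,
                    REML = TRUE)
    vc <- as.data.frame(lme4::VarCorr(m))$vcov
    expect_equal(ours$sigma2_H, vc[1], tolerance = 1e-5)
    expect_equal(ours$sigma2_E, vc[2], tolerance = 1e-5)
  }
})

test_that("a zero-signal dataset hits the boundary estimate sigma2_H = 0", {
  set.seed(5)
  d <- expand.grid(hybrid = sprintf("H%02d", 1:40), rep = 1:2)
  d$value <- rnorm(nrow(d)) # no hybrid structure at all
  # enough noise realizations put MS_hybrid below MS_error; find one
  fits <- replicate(10, {
    d$value <- rnorm(nrow(d))
    fit_variance_components(d)$sigma2_H
  })
  expect_true(any(fits == 0))
  expect_true(all(fits >= 0))
})

test_that("variance estimation fails informatively on degenerate input", {
  d <- data.frame(hybrid = c("A", "A"), rep = 1:2, value = c(1, 2))
  expect_error(fit_variance_components(d), ">= 2 hybrids")
  d2 <- data.frame(hybrid = rep(c("A", "B"), 2), rep = rep(1:2, each = 2),
                   value = rep(1, 4))
  expect_error(fit_variance_components(d2), "identical")
})

test_that("repeatability implements the entry-mean formula", {
  expect_equal(repeatability(list(sigma2_H = 1, sigma2_E = 1), rep = 2), 2 / 3)
  expect_equal(repeatability(list(sigma2_H = 0, sigma2_E = 1), rep = 2), 0)
  expect_equal(repeatability(list(sigma2_H = 1, sigma2_E = 3), rep = 3), 0.5)
  expect_true(is.na(repeatability(list(sigma2_H = 0, sigma2_E = 0), rep = 2)))
  # monotone in rep and in sigma2_H
  h_rep <- vapply(1:6, function(r)
    repeatability(list(sigma2_H = 1, sigma2_E = 2), r), numeric(1))
  expect_true(all(diff(h_rep) > 0))
  h_sig <- vapply(seq(0, 3, by = 0.5), function(s)
    repeatability(list(sigma2_H = s, sigma2_E = 1), 2), numeric(1))
  expect_true(all(diff(h_sig) > 0))
})

test_that("H2 equals the intraclass correlation from brute-force mean squares", {
  d <- sim_vc_data(50, 2, s2H = 1.2, s2E = 0.9, seed = 11)
  fit <- fit_variance_components(d)
  h2 <- repeatability(fit, 2)
  a <- anova(lm(value ~ factor(rep) + factor(hybrid), data = d))
  msH <- a["factor(hybrid)", "Mean Sq"]; msE <- a["Residuals", "Mean Sq"]
  s2H <- max(0, (msH - msE) / 2)
  expect_equal(h2, s2H / (s2H + msE / 2), tolerance = 1e-6)
})

test_that("parameter recovery at trial scale is unbiased within tolerance", {
  h2 <- vapply(1:30, function(i) {
    d <- sim_vc_data(200, 2, s2H = 2, s2E = 1, seed = 1000 + i)
    repeatability(fit_variance_components(d), 2)
  }, numeric(1))
  expect_equal(mean(h2), 0.8, tolerance = 0.03 / 0.8)
})

test_that("the sweep produces one record per factor cell", {
  tr <- tiny_trial(seed = 41)
  obs <- simulate_trait_observations(
    tr, flight_gdds = c(400, 800, 1000),
    selections = names(row_selections()),
    traits = c("CC", "CC10", "Height95", "PlotVolume", "NDVI"))
  sw <- repeatability_sweep(obs)
  expect_equal(nrow(sw), 5 * 3 * 7 * 2) # 210 cells
  expect_true(all(sw$H2 >= 0 & sw$H2 <= 1, na.rm = TRUE))
  expect_identical(sw, repeatability_sweep(obs))
  # the entry-mean identity holds record-wise
  ok <- is.finite(sw$H2)
  expect_equal(sw$H2[ok],
               sw$sigma2_H[ok] / (sw$sigma2_H[ok] + sw$sigma2_E[ok] / sw$rep[ok]))
})

test_that("border noise depresses single-outer-row repeatability", {
  set.seed(42)
  diffs <- replicate(8, {
    tr <- simulate_trial(trial_config(n_genotypes = 50, n_reps = 2,
                                      rng_seed = sample.int(1e6, 1)))
    obs <- simulate_trait_observations(tr, c(800, 1000),
                                       selections = c("RS23", "RS1"),
                                       trims = FALSE, traits = "Height95")
    sw <- repeatability_sweep(obs)
    mean(sw$H2[sw$selection == "RS23"]) - mean(sw$H2[sw$selection == "RS1"])
  })
  expect_gt(mean(diffs), 0)
  expect_gt(mean(diffs > 0), 0.8)
})
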