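test_that("config validation names the offending field", {
  expect_error(trial_config(n_genotypes = 0), "n_genotypes")
  expect_error(trial_config(row_length_m = -1), "row_length_m")
  expect_error(trial_config(genetic_variance = -0.1), "genetic_variance")
})

test_that("zero-variance configuration gives identical latents within a replicate", {
  tr <- simulate_trial(trial_config(
    n_genotypes = 8, n_reps = 2, genetic_variance = 0, residual_variance = 0,
    border_effect_mean_shift = 0, border_extra_sd = 0, rng_seed = 4))
  for (j in 1:2) {
    lat <- tr$truth$latent[tr$truth$rep == j]
    expect_equal(max(lat) - min(lat), 0, tolerance = 1e-12)
  }
})

test_that("RCBD structure: each genotype once per replicate block", {
  tr <- simulate_trial(trial_config(n_genotypes = 10, n_reps = 3, rng_seed = 2))
  expect_equal(nrow(tr$plots), 30)
  tab <- table(tr$plots$genotype, tr$plots$rep)
  expect_true(all(tab == 1))
  expect_equal(nrow(tr$truth), 30 * 4) # rows_per_plot entries per plot
})

test_that("identical seed reproduces the trial byte for byte", {
  cfg <- trial_config(n_genotypes = 7, n_reps = 2, rng_seed = 7)
  expect_identical(simulate_trial(cfg), simulate_trial(cfg))
  # and rendering is a pure function of (trial, gdd, seed)
  tr <- simulate_trial(cfg)
  expect_identical(render_point_cloud(tr, 500), render_point_cloud(tr, 500))
  expect_identical(render_rasters(tr, 500, extent = c(xmin = 0, xmax = 2, ymin = 0, ymax = 2)),
                   render_rasters(tr, 500, extent = c(xmin = 0, xmax = 2, ymin = 0, ymax = 2)))
})

test_that("empirical genotype-effect variance converges to genetic_variance", {
  tr <- simulate_trial(trial_config(n_genotypes = 500, n_reps = 2,
                                    plants_per_row = 2, rng_seed = 31))
  expect_equal(var(tr$genotypes$effect), 0.04, tolerance = 0.15)
  # entry means of the inner-row latents carry genetic + residual/4 variance
  inner <- tr$truth[tr$truth$row_index %in% 2:3, ]
  em <- tapply(inner$latent, inner$genotype, mean)
  expect_equal(var(as.numeric(em)), 0.04 + 0.01 / 4, tolerance = 0.2)
})

test_that("border mean shift appears in rendered canopy heights", {
  tr <- simulate_trial(trial_config(n_genotypes = 40, n_reps = 2,
                                    border_effect_mean_shift = 0.3,
                                    border_extra_sd = 0, rng_seed = 5))
  cl <- render_point_cloud(tr, 900, points_per_plant = 10)
  cn <- cl[cl$label == "canopy", ]
  z1 <- mean(cn$z[cn$row_index == 1])
  z2 <- mean(cn$z[cn$row_index == 2])
  expect_gt(z1, z2)
  # the relative inflation tracks the configured shift on the vigor scale
  expect_equal(z1 / z2, (1 + 0.3), tolerance = 0.1)
})

test_that("pre-emergence flight has ground points only, later flights add canopy", {
  tr <- tiny_trial()
  cl0 <- render_point_cloud(tr, 0)
  expect_true(all(cl0$label == "ground"))
  expect_true(all(abs(cl0$z) < 0.05))
  cl <- render_point_cloud(tr, 700)
  expect_gt(sum(cl$label == "canopy"), 0)
})

test_that("vegetation fraction of a row strip grows with thermal time", {
  tr <- tiny_trial(seed = 8)
  ext <- c(xmin = 0, xmax = 3.1, ymin = 0, ymax = 3.1)
  boxes <- build_grid(tr$plants)
  b <- select_rows(boxes, tr$plots$plot_id[1], "RS1234")
  frac <- vapply(c(300, 900), function(gdd) {
    ras <- render_rasters(tr, gdd, extent = ext)
    canopy_cover_rgb(ras$rgb, b)
  }, numeric(1))
  expect_gt(frac[2], frac[1])
})

test_that("soil pixels sit below the NDVI vegetation threshold", {
  tr <- tiny_trial(seed = 3)
  ras <- render_rasters(tr, 0, extent = c(xmin = 0, xmax = 1, ymin = 0, ymax = 1))
  mask <- mask_ground_hyperspectral(ras$hyperspectral)
  expect_false(any(mask)) # bare field: no vegetation anywhere
})

test_that("default raster resolutions are ~1 cm (RGB) and ~4 cm (hyperspectral)", {
  tr <- tiny_trial(seed = 3)
  ras <- render_rasters(tr, 500, extent = c(xmin = 0, xmax = 1, ymin = 0, ymax = 1))
  expect_equal(ras$rgb$res, 0.01)
  expect_equal(ras$hyperspectral$res, 0.04)
})

test_that("with null border parameters, row position is exchangeable", {
  # no test on row index should reject beyond the nominal type-I rate
  set.seed(99)
  p <- replicate(40, {
    tr <- simulate_trial(trial_config(
      n_genotypes = 30, n_reps = 2, border_effect_mean_shift = 0,
      border_extra_sd = 0, alley_end_shift = 0,
      rng_seed = sample.int(1e6, 1)))
    outer <- tr$truth$latent[tr$truth$row_index %in% c(1, 4)]
    inner <- tr$truth$latent[tr$truth$row_index %in% c(2, 3)]
    t.test(outer, inner)$p.value
  })
  expect_lt(mean(p < 0.05), 0.25)
})

test_that("weather simulation is well formed and seeded", {
  w <- simulate_weather("2020-05-01", 60, seed = 2)
  expect_true(all(w$tmax_c >= w$tmin_c))
  expect_identical(w, simulate_weather("2020-05-01", 60, seed = 2))
})

test_that("trait observations pool plants over selections and respect trimming", {
  tr <- tiny_trial(seed = 12)
  obs <- simulate_trait_observations(tr, flight_gdds = 800,
                                     selections = c("RS1234", "RS23", "RS1"),
                                     traits = "Height95")
  expect_setequal(unique(obs$selection), c("RS1234", "RS23", "RS1"))
  expect_setequal(unique(obs$trimmed), c(TRUE, FALSE))
  expect_equal(nrow(obs), nrow(tr$plots) * 3 * 2)
  expect_true(all(obs$value >= 0))
})
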