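test_that("RGB canopy cover recovers a painted vegetation fraction", {
  # paint a known fraction of a 100x100 patch green, the rest soil brown
  n <- 100
  veg_px <- 3700 # fraction 0.37
  arr <- array(0, c(n, n, 3))
  soil <- c(0.45, 0.36, 0.25); veg <- c(0.15, 0.45, 0.12)
  idx <- seq_len(n * n) <= veg_px
  for (b in 1:3) arr[, , b] <- ifelse(idx, veg[b], soil[b])
  r <- field_raster(arr, 0.01, 0, 0, c("R", "G", "B"))
  expect_equal(canopy_cover_rgb(r, full_box(r)), 0.37, tolerance = 1e-4)
  # all-vegetation and all-soil degenerate patches
  for (b in 1:3) arr[, , b] <- veg[b]
  expect_equal(canopy_cover_rgb(field_raster(arr, 0.01, 0, 0, c("R", "G", "B")),
                                full_box(r)), 1.0)
  for (b in 1:3) arr[, , b] <- soil[b]
  expect_equal(canopy_cover_rgb(field_raster(arr, 0.01, 0, 0, c("R", "G", "B")),
                                full_box(r)), 0.0)
  # a box with no pixels is an error
  empty <- full_box(r); empty$x_min <- 50; empty$x_max <- 51
  expect_error(canopy_cover_rgb(r, empty), "no pixels")
})

test_that("ground classification recovers truth labels on tall canopies", {
  tr <- simulate_trial(trial_config(n_genotypes = 4, n_reps = 2,
                                    plants_per_row = 6, plots_per_range = 4,
                                    rng_seed = 6))
  cl <- render_point_cloud(tr, 900, points_per_plant = 20)
  # drop low canopy points so plants are >= 0.3 m, as the contract assumes
  cl <- cl[cl$label == "ground" | cl$z >= 0.3, ]
  lab <- classify_ground(cl, h0 = 0.10)
  acc <- mean((lab == "ground") == (cl$label == "ground"))
  expect_gte(acc, 0.99)
  # a flat cloud is all ground
  flat <- data.frame(x = runif(50), y = runif(50), z = 0)
  expect_true(all(classify_ground(flat) == "ground"))
})

test_that("CC10 matches the brute-force percentile-and-count oracle", {
  box <- data.frame(plot_id = "P1", row_index = 1L, x_min = 0, x_max = 1,
                    y_min = 0, y_max = 1, trimmed = FALSE, missing = FALSE)
  pts <- data.frame(
    x = rep(0.5, 20), y = rep(0.5, 20),
    z = c(rep(0, 10), seq(1.0, 1.9, by = 0.1)),
    label = rep(c("ground", "canopy"), each = 10)
  )
  # oracle: z* = 1.09 (10th pctl of the ten canopy heights), 9 of 20 above
  expect_equal(oracle_pctl(seq(1.0, 1.9, by = 0.1), 0.10), 1.09)
  expect_equal(canopy_cover_lidar(pts, box), 9 / 20)
  # all nonground with distinct heights: definitionally 90% above own 10th pct
  pts2 <- data.frame(x = 0.5, y = 0.5, z = seq(0.1, 1, by = 0.1),
                     label = "canopy")
  expect_equal(canopy_cover_lidar(pts2, box), 0.9)
  expect_lte(canopy_cover_lidar(pts, box), 1)
  # no nonground points: flagged missing
  ground_only <- data.frame(x = 0.5, y = 0.5, z = 0, label = "ground")
  expect_true(is.na(canopy_cover_lidar(ground_only, box)))
})

test_that("height percentile uses nonground points with linear interpolation", {
  box <- data.frame(plot_id = "P1", row_index = 1L, x_min = 0, x_max = 1,
                    y_min = 0, y_max = 1, trimmed = FALSE, missing = FALSE)
  pts <- data.frame(x = c(0.2, 0.8), y = 0.5, z = c(1, 2), label = "canopy")
  expect_equal(height_p95(pts, box), 1.95)
  # constant height is returned exactly
  pts_c <- data.frame(x = 0.5, y = 0.5, z = rep(1.3, 5), label = "canopy")
  expect_equal(height_p95(pts_c, box), 1.3)
  # adding ground points changes nothing
  with_ground <- rbind(pts, data.frame(x = 0.5, y = 0.5, z = 0, label = "ground"))
  expect_equal(height_p95(with_ground, box), 1.95)
})

test_that("plot volume matches hand and brute-force oracles", {
  # one full 8 cm cell with two nonground points
  box <- data.frame(plot_id = "P1", row_index = 1L, x_min = 0, x_max = 0.08,
                    y_min = 0, y_max = 0.08, trimmed = FALSE, missing = FALSE)
  pts <- data.frame(x = c(0.02, 0.06), y = 0.04, z = c(0.5, 1.5),
                    label = "canopy")
  expect_equal(plot_volume(pts, box), (1.45 + 0.5) / 2 * 0.0064)
  # empty boxes contribute zero
  expect_equal(plot_volume(pts[0, ], box), 0)
  # doubling every height doubles the volume
  pts2 <- pts; pts2$z <- 2 * pts2$z
  expect_equal(plot_volume(pts2, box), 2 * plot_volume(pts, box))
  # full brute-force re-binning oracle on a generated fixture
  fx <- make_fixtures("tiny_cloud", seed = 2)
  expect_equal(plot_volume(fx$cloud, fx$boxes), fx$truth$volume,
               tolerance = 1e-9)
  expect_equal(height_p95(fx$cloud, fx$boxes), fx$truth$height_p95,
               tolerance = 1e-9)
  expect_equal(canopy_cover_lidar(fx$cloud, fx$boxes), fx$truth$cc10,
               tolerance = 1e-9)
})

test_that("vegetation indices reproduce their closed forms on uniform rasters", {
  r <- uniform_raster(list(`420` = 0.1, `445` = 0.05, `500` = 0.05,
                           `531` = 0.3, `550` = 0.2, `570` = 0.2,
                           `670` = 0.1, `680` = 0.1, `695` = 0.2,
                           `700` = 0.2, `705` = 0.2, `720` = 0.3,
                           `740` = 0.45, `750` = 0.6, `800` = 0.5))
  b <- full_box(r)
  mask <- matrix(TRUE, 10, 10)
  expect_equal(vegetation_index(r, b, "NDVI", mask), (0.6 - 0.2) / (0.6 + 0.2))
  expect_equal(vegetation_index(r, b, "PSRI", mask), (0.1 - 0.05) / 0.6)
  expect_equal(vegetation_index(r, b, "SR800680", mask), 0.5 / 0.1)
  expect_equal(vegetation_index(r, b, "VOG1", mask), 0.45 / 0.3)
  expect_equal(vegetation_index(r, b, "Carte1", mask), 0.2 / 0.1)
  expect_equal(vegetation_index(r, b, "PRI", mask), (0.3 - 0.2) / (0.3 + 0.2))
  expect_equal(vegetation_index(r, b, "mRENDVI", mask),
               (0.6 - 0.2) / (0.6 + 0.2 - 2 * 0.05))
  # OSAVI with equal red and NIR reflectance is exactly zero
  r0 <- uniform_raster(list(`670` = 0.3, `800` = 0.3))
  expect_equal(vegetation_index(r0, full_box(r0), "OSAVI",
                                matrix(TRUE, 10, 10)), 0)
  expect_error(vegetation_index(r0, full_box(r0), "NDVI",
                                matrix(TRUE, 10, 10)), "750")
})

test_that("hyperspectral masking separates soil from vegetation", {
  fx <- make_fixtures("tiny_rasters", seed = 4)
  hyp <- fx$hyperspectral
  mask <- mask_ground_hyperspectral(hyp)
  # with threshold -1 every pixel passes (NDVI >= -1 by construction)
  expect_true(all(mask_ground_hyperspectral(hyp, threshold = -1)))
  # soil pixels (outside the canopy mask) have NDVI below 0.5
  expect_true(any(mask))
  expect_true(any(!mask))
  # an empty vegetation mask flags the trait missing
  b <- full_box(hyp)
  expect_true(is.na(vegetation_index(hyp, b, "NDVI",
                                     mask = matrix(FALSE, nrow(mask), ncol(mask)))))
})

test_that("traits are invariant to point order and field translation", {
  fx <- make_fixtures("tiny_cloud", seed = 9)
  set.seed(1)
  perm <- sample(nrow(fx$cloud))
  shuffled <- fx$cloud[perm, ]
  expect_equal(height_p95(shuffled, fx$boxes), height_p95(fx$cloud, fx$boxes))
  expect_equal(plot_volume(shuffled, fx$boxes), plot_volume(fx$cloud, fx$boxes))
  moved <- fx$cloud; moved$x <- moved$x + 100; moved$y <- moved$y - 50
  mboxes <- fx$boxes
  mboxes$x_min <- mboxes$x_min + 100; mboxes$x_max <- mboxes$x_max + 100
  mboxes$y_min <- mboxes$y_min - 50; mboxes$y_max <- mboxes$y_max - 50
  expect_equal(plot_volume(moved, mboxes), plot_volume(fx$cloud, fx$boxes),
               tolerance = 1e-9)
})

test_that("pooled RS1234 equals the weighted combination of single rows", {
  tr <- tiny_trial(seed = 31)
  boxes <- build_grid(tr$plants)
  cl <- render_point_cloud(tr, 800, points_per_plant = 15)
  p <- tr$plots$plot_id[1]
  # volume is additive over disjoint boxes
  singles_vol <- sum(vapply(c("RS1", "RS2", "RS3", "RS4"), function(s) {
    plot_volume(cl, select_rows(boxes, p, s))
  }, numeric(1)))
  expect_equal(plot_volume(cl, select_rows(boxes, p, "RS1234")), singles_vol,
               tolerance = 1e-9)
  # RGB canopy cover pools pixels: pixel-count weighted mean of single rows
  ext <- with(tr$plots[tr$plots$plot_id == p, ],
              c(xmin = x0 - 0.2, xmax = x0 + 3.3, ymin = y0 - 0.2,
                ymax = y0 + 3.3))
  ras <- render_rasters(tr, 800, extent = ext)
  cc <- vapply(c("RS1", "RS2", "RS3", "RS4"), function(s) {
    b <- select_rows(boxes, p, s)
    n_px <- sum(rowseg:::pixels_in_boxes(ras$rgb, b))
    c(canopy_cover_rgb(ras$rgb, b), n_px)
  }, numeric(2))
  pooled <- canopy_cover_rgb(ras$rgb, select_rows(boxes, p, "RS1234"))
  expect_equal(pooled, sum(cc[1, ] * cc[2, ]) / sum(cc[2, ]), tolerance = 1e-9)
})

test_that("border mean shift is recovered as a Height95 contrast", {
  set.seed(7)
  shifts <- replicate(6, {
    tr <- simulate_trial(trial_config(n_genotypes = 25, n_reps = 2,
                                      border_effect_mean_shift = 0.2,
                                      border_extra_sd = 0,
                                      rng_seed = sample.int(1e6, 1)))
    obs <- simulate_trait_observations(tr, 900, selections = c("RS14", "RS23"),
                                       trims = FALSE, traits = "Height95")
    h14 <- mean(obs$value[obs$selection == "RS14"])
    h23 <- mean(obs$value[obs$selection == "RS23"])
    (h14 - h23) / 2.0 / growth_fraction(900) # back to the vigor scale
  })
  expect_equal(mean(shifts), 0.2, tolerance = 0.05)
})
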