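# Shared small fixtures, built in code. Kept cheap: helpers run once per
# test session.

tiny_trial <- function(seed = 1L, ...) {
  simulate_trial(trial_config(n_genotypes = 6, n_reps = 2,
                              plants_per_row = 6, plots_per_range = 4,
                              rng_seed = seed, ...))
}

# a single-band "hyperspectral" style raster with uniform reflectance per band
uniform_raster <- function(values_by_band, n = 10, res = 0.04) {
  arr <- array(0, c(n, n, length(values_by_band)))
  for (b in seq_along(values_by_band)) arr[, , b] <- values_by_band[[b]]
  field_raster(arr, res, 0, 0, as.numeric(names(values_by_band)))
}

# one box covering an entire raster
full_box <- function(raster) {
  d <- dim(raster$values)
  data.frame(plot_id = "P1", row_index = 1L,
             x_min = raster$xmin, x_max = raster$xmin + d[2] * raster$res,
             y_min = raster$ymin, y_max = raster$ymin + d[1] * raster$res,
             trimmed = FALSE, missing = FALSE, stringsAsFactors = FALSE)
}

# independent linear-interpolation percentile (order-statistic oracle)
oracle_pctl <- function(z, p) {
  z <- sort(z)
  h <- (length(z) - 1) * p
  lo <- floor(h)
  z[lo + 1] + (h - lo) * (z[min(lo + 2, length(z))] - z[lo + 1])
}

# balanced RCBD-style response table for variance-component tests
sim_vc_data <- function(n_geno, n_rep, s2H, s2E, seed, mu = 10) {
  set.seed(seed)
  g <- rnorm(n_geno, 0, sqrt(s2H))
  d <- expand.grid(hybrid = sprintf("H%03d", seq_len(n_geno)),
                   rep = seq_len(n_rep), KEEP.OUT.ATTRS = FALSE,
                   stringsAsFactors = FALSE)
  d$value <- mu + 0.3 * (d$rep - 1) + g[match(d$hybrid, sprintf("H%03d", seq_len(n_geno)))] +
    rnorm(nrow(d), 0, sqrt(s2E))
  d
}
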