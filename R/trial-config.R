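#' Configuration for a synthetic multi-row field trial
#'
#' Defines the layout and the ground-truth effect sizes of a simulated
#' randomized complete block trial of four-row plots. Layout defaults follow
#' the common breeding-trial geometry this package targets: 3.05 m rows on
#' 76 cm spacing with 76 cm alleys between ranges.
#'
#' The latent "vigor" of plot \eqn{i}, row \eqn{r} in replicate \eqn{j} is
#' \deqn{v_{ir} = \mu + G_i + R_j + b\,1[r \in \{1, n\}] + e_{ir},}
#' with \eqn{G_i \sim N(0, \sigma^2_G)}, fixed replicate offsets \eqn{R_j},
#' and \eqn{e_{ir} \sim N(0, \sigma^2_e + s_b^2\,1[r \in \{1, n\}])}; border
#' rows (the first and last row of a plot) receive both a mean inflation
#' \eqn{b} (`border_effect_mean_shift`) and extra noise \eqn{s_b}
#' (`border_extra_sd`). Plants within `end_zone_m` of a row end receive an
#' additional `alley_end_shift`. Yield is a linear function of the plot's
#' inner-row latent means plus Gaussian noise, mirroring trials where only
#' the inner rows are harvested.
#'
#' @param n_genotypes number of genotypes (entries).
#' @param n_reps number of replicate blocks (commonly 2 or 3).
#' @param rows_per_plot rows in each plot (default 4).
#' @param row_spacing_m distance between row centers, meters.
#' @param row_length_m nominal planted row length, meters.
#' @param alley_m alley length between ranges, meters.
#' @param plants_per_row plants emerged per row.
#' @param plots_per_range plots laid side by side across a range.
#' @param trait_mean grand mean \eqn{\mu} of the latent vigor (unitless).
#' @param genetic_variance \eqn{\sigma^2_G}, variance of genotype effects.
#' @param residual_variance \eqn{\sigma^2_e}, plot-row residual variance.
#' @param rep_effect_step fixed replicate offset between consecutive blocks.
#' @param border_effect_mean_shift vigor added to rows 1 and `rows_per_plot`.
#' @param border_extra_sd extra residual sd on rows 1 and `rows_per_plot`.
#' @param alley_end_shift vigor added to plants inside the alley end zone.
#' @param end_zone_m length of the end zone at each row end, meters.
#' @param plant_sd plant-to-plant vigor sd within a row.
#' @param meas_sd per-plant, per-flight measurement noise sd (vigor units).
#' @param row_meas_sd per-row, per-flight measurement noise sd (vigor units):
#'   scene-level sensor/illumination error shared by every plant of a row in
#'   one overpass, and hence by the trimmed and untrimmed views of that row.
#' @param canopy_max_height_m mature canopy height of a vigor-1 plant.
#' @param yield_base,yield_scale yield (g m\eqn{^{-2}}) intercept and slope on
#'   the mean inner-row vigor.
#' @param yield_noise_sd yield noise sd, g m\eqn{^{-2}}.
#' @param n_subpops number of germplasm subpopulations to label (temperate /
#'   tropical style grouping used to balance cross-validation folds).
#' @param rng_seed integer seed; identical seeds give identical trials.
#' @return A list of class `trial_config`.
#' @seealso [simulate_trial()]
#' @export
#' @examples
#' cfg <- trial_config(n_genotypes = 10, n_reps = 2)
#' cfg$row_length_m
trial_config <- function(n_genotypes = 100,
                         n_reps = 2,
                         rows_per_plot = 4,
                         row_spacing_m = 0.76,
                         row_length_m = 3.05,
                         alley_m = 0.76,
                         plants_per_row = 20,
                         plots_per_range = 10,
                         trait_mean = 1,
                         genetic_variance = 0.04,
                         residual_variance = 0.01,
                         rep_effect_step = 0.05,
                         border_effect_mean_shift = 0.15,
                         border_extra_sd = 0.10,
                         alley_end_shift = 0.10,
                         end_zone_m = 0.40,
                         plant_sd = 0.05,
                         meas_sd = 0.05,
                         row_meas_sd = 0.05,
                         canopy_max_height_m = 2.0,
                         yield_base = 500,
                         yield_scale = 1200,
                         yield_noise_sd = 150,
                         n_subpops = 2,
                         rng_seed = 1L) {
  cfg <- list(
    n_genotypes = n_genotypes, n_reps = n_reps, rows_per_plot = rows_per_plot,
    row_spacing_m = row_spacing_m, row_length_m = row_length_m,
    alley_m = alley_m, plants_per_row = plants_per_row,
    plots_per_range = plots_per_range, trait_mean = trait_mean,
    genetic_variance = genetic_variance,
    residual_variance = residual_variance,
    rep_effect_step = rep_effect_step,
    border_effect_mean_shift = border_effect_mean_shift,
    border_extra_sd = border_extra_sd, alley_end_shift = alley_end_shift,
    end_zone_m = end_zone_m, plant_sd = plant_sd, meas_sd = meas_sd,
    row_meas_sd = row_meas_sd,
    canopy_max_height_m = canopy_max_height_m, yield_base = yield_base,
    yield_scale = yield_scale, yield_noise_sd = yield_noise_sd,
    n_subpops = n_subpops, rng_seed = as.integer(rng_seed)
  )
  validate_trial_config(cfg)
  structure(cfg, class = "trial_config")
}

validate_trial_config <- function(cfg) {
  counts <- c("n_genotypes", "n_reps", "rows_per_plot", "plants_per_row",
              "plots_per_range", "n_subpops")
  for (f in counts) {
    v <- cfg[[f]]
    if (!is.numeric(v) || length(v) != 1 || is.na(v) || v < 1 || v != round(v)) {
      stop_config(f, "must be a whole number >= 1")
    }
  }
  lengths <- c("row_spacing_m", "row_length_m", "alley_m", "end_zone_m",
               "canopy_max_height_m")
  for (f in lengths) {
    v <- cfg[[f]]
    if (!is.numeric(v) || length(v) != 1 || is.na(v) || v <= 0) {
      stop_config(f, "must be a positive length in meters")
    }
  }
  vars <- c("genetic_variance", "residual_variance", "border_extra_sd",
            "plant_sd", "meas_sd", "row_meas_sd", "yield_noise_sd")
  for (f in vars) {
    v <- cfg[[f]]
    if (!is.numeric(v) || length(v) != 1 || is.na(v) || v < 0) {
      stop_config(f, "must be a nonnegative number")
    }
  }
  if (!is.numeric(cfg$rng_seed) || length(cfg$rng_seed) != 1 || is.na(cfg$rng_seed)) {
    stop_config("rng_seed", "must be a single integer")
  }
  invisible(cfg)
}
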