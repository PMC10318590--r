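#' Simulate a randomized complete block field trial with known ground truth
#'
#' Draws genotype effects, assigns genotypes to plots in a randomized
#' complete block design (each genotype once per replicate block), lays the
#' plots out on a field grid of ranges and plot columns, places plants along
#' each row, and generates latent row vigor and end-season yield. The latent
#' model is described in [trial_config()]. All randomness is driven by
#' `config$rng_seed`; the same configuration always yields a byte-identical
#' trial.
#'
#' Field coordinates are local meters with `x` running along the rows
#' (ranges stacked in `x`, separated by alleys) and `y` across rows.
#'
#' @param config a [trial_config()].
#' @return An object of class `field_trial`: a list with elements
#'   \describe{
#'     \item{config}{the input configuration.}
#'     \item{genotypes}{data frame of genotype id, effect, subpopulation.}
#'     \item{plots}{one row per plot: `plot_id`, `genotype`, `rep`,
#'       `subpop`, field `range`/`col` indices, and the plot origin
#'       `x0`, `y0` (start of the rows).}
#'     \item{truth}{per (plot, row) latent vigor means and their border
#'       status.}
#'     \item{plants}{per-plant positions (field meters) and latent vigor,
#'       including alley end-zone shifts.}
#'     \item{yield}{per-plot yield (g m^-2) generated from the inner-row
#'       latent means.}
#'   }
#' @export
#' @examples
#' tr <- simulate_trial(trial_config(n_genotypes = 10, n_reps = 3, rng_seed = 7))
#' nrow(tr$plots) # 30 plots: 10 genotypes x 3 blocks
simulate_trial <- function(config) {
  validate_trial_config(config)
  cfg <- config
  with_seed(derive_seed(cfg$rng_seed, "trial"), {
    gid <- sprintf("G%03d", seq_len(cfg$n_genotypes))
    genotypes <- data.frame(
      genotype = gid,
      effect = stats::rnorm(cfg$n_genotypes, 0, sqrt(cfg$genetic_variance)),
      subpop = paste0("SP", (seq_len(cfg$n_genotypes) - 1L) %% cfg$n_subpops + 1L),
      stringsAsFactors = FALSE
    )

    # RCBD: a fresh randomization of all genotypes within each block
    plot_geno <- unlist(lapply(seq_len(cfg$n_reps), function(j) sample(gid)))
    n_plots <- cfg$n_genotypes * cfg$n_reps
    idx <- seq_len(n_plots) - 1L
    rng <- idx %/% cfg$plots_per_range + 1L
    col <- idx %% cfg$plots_per_range + 1L
    plot_w <- cfg$rows_per_plot * cfg$row_spacing_m
    plots <- data.frame(
      plot_id = sprintf("P%04d", seq_len(n_plots)),
      genotype = plot_geno,
      rep = rep(seq_len(cfg$n_reps), each = cfg$n_genotypes),
      subpop = genotypes$subpop[match(plot_geno, genotypes$genotype)],
      range = rng,
      col = col,
      x0 = (rng - 1L) * (cfg$row_length_m + cfg$alley_m),
      y0 = (col - 1L) * plot_w,
      stringsAsFactors = FALSE
    )

    # latent vigor per (plot, row)
    nr <- cfg$rows_per_plot
    border <- rep(seq_len(nr) %in% c(1L, nr), times = n_plots)
    truth <- data.frame(
      plot_id = rep(plots$plot_id, each = nr),
      genotype = rep(plots$genotype, each = nr),
      rep = rep(plots$rep, each = nr),
      row_index = rep(seq_len(nr), times = n_plots),
      border = border,
      stringsAsFactors = FALSE
    )
    g_eff <- genotypes$effect[match(truth$genotype, genotypes$genotype)]
    r_eff <- cfg$rep_effect_step * (truth$rep - 1L)
    e_sd <- sqrt(cfg$residual_variance + cfg$border_extra_sd^2 * border)
    truth$latent <- cfg$trait_mean + g_eff + r_eff +
      cfg$border_effect_mean_shift * border +
      stats::rnorm(nrow(truth), 0, e_sd)

    # plants: regular spacing with 2 cm longitudinal jitter, 1 cm lateral
    np <- cfg$plants_per_row
    margin <- min(0.05, cfg$row_length_m / (2 * np))
    base_x <- seq(margin, cfg$row_length_m - margin, length.out = np)
    n_plants <- nrow(truth) * np
    plants <- data.frame(
      plot_id = rep(truth$plot_id, each = np),
      row_index = rep(truth$row_index, each = np),
      stringsAsFactors = FALSE
    )
    x_local <- rep(base_x, times = nrow(truth)) + stats::rnorm(n_plants, 0, 0.02)
    x_local <- pmin(pmax(x_local, 0), cfg$row_length_m)
    pidx <- match(plants$plot_id, plots$plot_id)
    row_y <- plots$y0[pidx] + (plants$row_index - 0.5) * cfg$row_spacing_m
    plants$x <- plots$x0[pidx] + x_local
    plants$y <- row_y + stats::rnorm(n_plants, 0, 0.01)
    end_zone <- x_local < cfg$end_zone_m | x_local > cfg$row_length_m - cfg$end_zone_m
    plants$end_zone <- end_zone
    plants$vigor <- rep(truth$latent, each = np) +
      stats::rnorm(n_plants, 0, cfg$plant_sd) +
      cfg$alley_end_shift * end_zone

    # yield from the inner rows only (the harvested rows)
    inner <- if (nr >= 3) 2:(nr - 1) else seq_len(nr)
    inner_mean <- vapply(plots$plot_id, function(p) {
      mean(truth$latent[truth$plot_id == p & truth$row_index %in% inner])
    }, numeric(1))
    yield <- data.frame(
      plot_id = plots$plot_id,
      yield = cfg$yield_base + cfg$yield_scale * inner_mean +
        stats::rnorm(n_plots, 0, cfg$yield_noise_sd),
      stringsAsFactors = FALSE
    )
    rownames(yield) <- NULL

    structure(
      list(config = cfg, genotypes = genotypes, plots = plots,
           truth = truth, plants = plants, yield = yield),
      class = "field_trial"
    )
  })
}

#' @export
print.field_trial <- function(x, ...) {
  cat(sprintf(
    "<field_trial> %d genotypes x %d reps = %d plots (%d rows/plot, seed %d)\n",
    x$config$n_genotypes, x$config$n_reps, nrow(x$plots),
    x$config$rows_per_plot, x$config$rng_seed
  ))
  invisible(x)
}

#' Canopy growth fraction at a thermal time
#'
#' Smooth logistic development curve rescaled so that growth is exactly zero
#' at 0 growing degree days (pre-emergence) and approaches one late in the
#' season. Used by the renderers and the trait-observation generator to make
#' canopy size, point density and vegetation fraction increase with GDD.
#'
#' @param gdd cumulative growing degree days (base 10, capped), `>= 0`.
#' @return Growth fraction in `[0, 1)`, monotone in `gdd`.
#' @export
growth_fraction <- function(gdd) {
  if (any(gdd < 0)) stop("gdd must be >= 0", call. = FALSE)
  f0 <- stats::plogis(-500 / 180)
  pmax(0, (stats::plogis((gdd - 500) / 180) - f0) / (1 - f0))
}

#' Simulate a daily weather table
#'
#' Seasonal sinusoidal temperature course with Gaussian day-to-day noise,
#' suitable input for [cumulative_gdd()]. Maximum temperature is always at
#' least the minimum.
#'
#' @param start_date first day (planting date), `Date` or string.
#' @param n_days number of days.
#' @param seed integer seed.
#' @return Data frame with columns `date`, `tmax_c`, `tmin_c`.
#' @export
simulate_weather <- function(start_date = "2020-05-01", n_days = 150, seed = 1L) {
  start_date <- as.Date(start_date)
  with_seed(derive_seed(seed, "weather"), {
    day <- seq_len(n_days)
    season <- 21 + 6 * sin(pi * day / n_days)
    tmax <- season + stats::rnorm(n_days, 0, 3)
    spread <- pmax(2, 10 + stats::rnorm(n_days, 0, 2))
    data.frame(
      date = start_date + day - 1L,
      tmax_c = tmax,
      tmin_c = tmax - spread
    )
  })
}

#' Simulate per-flight trait observations directly from trial ground truth
#'
#' Generates the long trait table the repeatability and prediction stages
#' consume without rendering point clouds or rasters: for each flight, every
#' row receives a scene-level measurement error (`row_meas_sd`, one draw per
#' row and overpass) and every plant an independent per-plant error
#' (`meas_sd`); plants are pooled over the member rows of each row selection
#' (optionally excluding a 40 cm trimmed zone at both row ends), and the
#' pooled vigor is mapped to each trait's scale by a trait-specific monotone
#' map multiplied by the [growth_fraction()] at the flight's GDD. This is the
#' fast, statistically faithful counterpart of rendering followed by
#' [extract_traits()]: the trimmed and untrimmed views of a row share the
#' same overpass, plants and noise except in the end zones, so trimming
#' carries no systematic effect, while border rows carry the configured mean
#' shift and extra noise.
#'
#' @param trial a [simulate_trial()] result.
#' @param flight_gdds numeric vector of flight thermal times.
#' @param selections character vector of row-selection names
#'   (see [row_selections()]).
#' @param trims logical vector of trimming variants to produce.
#' @param traits character vector of trait names among `CC`, `CC10`,
#'   `Height95`, `PlotVolume`, `NDVI`.
#' @param trim_m trimmed length at each row end, meters.
#' @param seed integer seed for the measurement noise.
#' @return Long data frame with columns `plot_id`, `genotype`, `rep`,
#'   `subpop`, `selection`, `trimmed`, `flight_id`, `gdd`, `trait`, `value`.
#' @export
simulate_trait_observations <- function(trial,
                                        flight_gdds,
                                        selections = names(row_selections()),
                                        trims = c(FALSE, TRUE),
                                        traits = c("CC", "CC10", "Height95",
                                                   "PlotVolume", "NDVI"),
                                        trim_m = 0.40,
                                        seed = trial$config$rng_seed) {
  stopifnot(inherits(trial, "field_trial"))
  cfg <- trial$config
  plants <- trial$plants
  sel_rows <- row_selections()[selections]
  if (any(vapply(sel_rows, is.null, logical(1)))) {
    stop("unknown row selection name", call. = FALSE)
  }
  # plant x position within its plot (rows start at the plot origin x0)
  x0 <- trial$plots$x0[match(plants$plot_id, trial$plots$plot_id)]
  x_local <- plants$x - x0
  keep_trimmed <- x_local >= trim_m & x_local < cfg$row_length_m - trim_m

  out <- vector("list", length(flight_gdds))
  for (f in seq_along(flight_gdds)) {
    gdd <- flight_gdds[[f]]
    g <- growth_fraction(gdd)
    obs_vigor <- with_seed(derive_seed(seed, paste0("traitobs:", f)), {
      row_key <- factor(paste(plants$plot_id, plants$row_index))
      eta <- stats::rnorm(nlevels(row_key), 0, cfg$row_meas_sd)
      plants$vigor + eta[as.integer(row_key)] +
        stats::rnorm(nrow(plants), 0, cfg$meas_sd)
    })
    cells <- list()
    for (sel in names(sel_rows)) {
      in_sel <- plants$row_index %in% sel_rows[[sel]]
      for (tm in trims) {
        keep <- in_sel & (!tm | keep_trimmed)
        pooled <- rowsum(obs_vigor[keep], plants$plot_id[keep])
        n_in <- rowsum(rep(1, sum(keep)), plants$plot_id[keep])
        v <- drop(pooled / n_in)
        cells[[length(cells) + 1L]] <- data.frame(
          plot_id = rownames(pooled),
          selection = sel,
          trimmed = tm,
          vigor = v,
          stringsAsFactors = FALSE
        )
      }
    }
    cells <- do.call(rbind, cells)
    per_trait <- lapply(traits, function(tr) {
      val <- switch(tr,
        CC         = pmin(1, pmax(0, 0.45 * g * cells$vigor)),
        CC10       = pmin(1, pmax(0, 0.30 + 0.35 * g * cells$vigor)),
        Height95   = pmax(0, cfg$canopy_max_height_m * g * cells$vigor),
        PlotVolume = pmax(0, 1.5 * g * cells$vigor),
        NDVI       = pmin(1, pmax(-1, 0.20 + 0.55 * g * cells$vigor)),
        stop(sprintf("unknown trait '%s'", tr), call. = FALSE)
      )
      data.frame(cells[c("plot_id", "selection", "trimmed")],
                 flight_id = sprintf("F%02d", f), gdd = gdd,
                 trait = tr, value = val, stringsAsFactors = FALSE)
    })
    out[[f]] <- do.call(rbind, per_trait)
  }
  out <- do.call(rbind, out)
  pidx <- match(out$plot_id, trial$plots$plot_id)
  out <- data.frame(
    plot_id = out$plot_id,
    genotype = trial$plots$genotype[pidx],
    rep = trial$plots$rep[pidx],
    subpop = trial$plots$subpop[pidx],
    out[c("selection", "trimmed", "flight_id", "gdd", "trait", "value")],
    stringsAsFactors = FALSE
  )
  rownames(out) <- NULL
  out
}
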