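#' Configuration of a full pipeline run
#'
#' Bundles every stage's settings: the synthetic trial, the flight calendar,
#' which row selections and trim variants to evaluate, the SVR
#' cross-validation design, and the ANOVA/LSD settings. A single master
#' `seed` fans out to stage-specific substreams
#' (see [derive_seed()]), so rerunning with the same configuration
#' reproduces every output.
#'
#' @param trial a [trial_config()].
#' @param years number of simulated years (each year is an independent trial
#'   of the same design).
#' @param year_shift additive vigor shift per successive year (a year main
#'   effect).
#' @param planting_date planting date of year 1; later years shift by one
#'   year.
#' @param flight_days days after planting of each flight.
#' @param mode `"direct"` generates trait observations from ground truth
#'   ([simulate_trait_observations()]); `"render"` renders point clouds and
#'   rasters and extracts traits from them ([extract_traits()]), range by
#'   range.
#' @param selections row-selection names to evaluate.
#' @param trims trim variants.
#' @param trim_m trim length per row end, meters.
#' @param traits traits for the direct path (`mode = "direct"`).
#' @param svr list of SVR settings: `k`, `repeats`, `sigma_grid`,
#'   `cost_grid`, `inner_k`, `epsilon`, `selections` (selections to run
#'   prediction for; default all configured).
#' @param alpha ANOVA/LSD significance level.
#' @param seed master seed.
#' @return List of class `run_config`.
#' @export
run_config <- function(trial = trial_config(),
                       years = 2,
                       year_shift = 0.05,
                       planting_date = "2020-05-01",
                       flight_days = c(30, 50, 65, 80, 95, 110),
                       mode = c("direct", "render"),
                       selections = names(row_selections()),
                       trims = c(FALSE, TRUE),
                       trim_m = 0.40,
                       traits = c("CC", "CC10", "Height95", "PlotVolume",
                                  "NDVI"),
                       svr = list(),
                       alpha = 0.05,
                       seed = 1L) {
  mode <- match.arg(mode)
  if (!inherits(trial, "trial_config")) trial <- do.call(trial_config, trial)
  svr_defaults <- list(k = 5, repeats = 3,
                       sigma_grid = c(1e-4, 1e-3, 1e-2, 0.1),
                       cost_grid = list(10, 100, "n"),
                       inner_k = 5, epsilon = 0.1,
                       selections = selections)
  svr <- utils::modifyList(svr_defaults, svr)
  structure(
    list(trial = trial, years = years, year_shift = year_shift,
         planting_date = as.character(planting_date),
         flight_days = flight_days, mode = mode, selections = selections,
         trims = trims, trim_m = trim_m, traits = traits, svr = svr,
         alpha = alpha, seed = as.integer(seed)),
    class = "run_config"
  )
}

log_line <- function(con, fmt, ...) {
  msg <- sprintf(fmt, ...)
  writeLines(paste(format(Sys.time(), "%H:%M:%S"), msg), con)
  message(msg)
}

simulate_year <- function(config, year) {
  tc <- config$trial
  tc$trait_mean <- tc$trait_mean + config$year_shift * (year - 1)
  tc$rng_seed <- derive_seed(config$seed, paste0("year:", year))
  simulate_trial(tc)
}

year_flights <- function(config, year) {
  planting <- seq(as.Date(config$planting_date), by = "year",
                  length.out = config$years)[year]
  weather <- simulate_weather(planting,
                              n_days = max(config$flight_days) + 10,
                              seed = derive_seed(config$seed,
                                                 paste0("weather:", year)))
  dates <- planting + config$flight_days
  gdd <- vapply(dates, function(d) cumulative_gdd(weather, planting, d),
                numeric(1))
  data.frame(flight_id = sprintf("F%02d", seq_along(dates)),
             date = dates, gdd = gdd, stage = assign_stage(gdd),
             stringsAsFactors = FALSE)
}

render_and_extract <- function(trial, flights, config) {
  boxes <- build_grid(trial$plants, trial$config$row_spacing_m)
  out <- list()
  for (f in seq_len(nrow(flights))) {
    gdd <- flights$gdd[f]
    for (rng in sort(unique(trial$plots$range))) {
      in_rng <- trial$plots$range == rng
      x0 <- min(trial$plots$x0[in_rng])
      ext <- c(xmin = x0 - 0.3, xmax = x0 + trial$config$row_length_m + 0.3,
               ymin = -0.3,
               ymax = max(trial$plots$y0[in_rng]) +
                 trial$config$rows_per_plot * trial$config$row_spacing_m + 0.3)
      cloud <- render_point_cloud(trial, gdd, extent = ext)
      ras <- render_rasters(trial, gdd, extent = ext)
      bx <- boxes[boxes$plot_id %in% trial$plots$plot_id[in_rng], ,
                  drop = FALSE]
      out[[length(out) + 1L]] <- extract_traits(
        bx, cloud = cloud, rgb = ras$rgb, hyperspectral = ras$hyperspectral,
        flight_id = flights$flight_id[f], gdd = gdd,
        selections = config$selections, trims = config$trims,
        trim_m = config$trim_m)
    }
  }
  traits <- do.call(rbind, out)
  pidx <- match(traits$plot_id, trial$plots$plot_id)
  traits$genotype <- trial$plots$genotype[pidx]
  traits$rep <- trial$plots$rep[pidx]
  traits$subpop <- trial$plots$subpop[pidx]
  traits
}

#' Run the full analysis pipeline on a synthetic trial
#'
#' Executes simulate, segment, extract, phenology, repeatability, prediction
#' and factor-analysis stages for every simulated year and writes all
#' intermediate and final tables to `out_dir`: `traits.csv`,
#' `repeatability.csv`, ANOVA and LSD tables per trait and growth stage
#' (`anova.csv`, `lsd_selection.csv`), a prediction summary
#' (`prediction.csv`), the resolved configuration (`config.yaml`), and a run
#' log (`run.log`). Rerunning with the same configuration reproduces every
#' numeric output.
#'
#' @param config a [run_config()].
#' @param out_dir output directory (created if needed).
#' @return Invisibly, a list with the in-memory tables (`flights`, `traits`,
#'   `repeatability`, `anova`, `lsd`, `prediction`) and `out_dir`.
#' @export
run_pipeline <- function(config = run_config(), out_dir = tempfile("rowseg_run")) {
  stopifnot(inherits(config, "run_config"))
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  log <- file(file.path(out_dir, "run.log"), open = "wt")
  on.exit(close(log))
  write_run_config(config, file.path(out_dir, "config.yaml"))

  all_traits <- list()
  all_flights <- list()
  yields <- list()
  stage <- "simulate"
  result <- tryCatch({
    for (year in seq_len(config$years)) {
      stage <- sprintf("simulate (year %d)", year)
      trial <- simulate_year(config, year)
      log_line(log, "year %d: simulated %d plots", year, nrow(trial$plots))

      stage <- sprintf("phenology (year %d)", year)
      flights <- year_flights(config, year)
      flights$year <- year
      all_flights[[year]] <- flights

      stage <- sprintf("extract (year %d)", year)
      traits <- if (config$mode == "render") {
        render_and_extract(trial, flights, config)
      } else {
        tr <- simulate_trait_observations(
          trial, flights$gdd, selections = config$selections,
          trims = config$trims, traits = config$traits,
          trim_m = config$trim_m,
          seed = derive_seed(config$seed, paste0("traitobs:", year)))
        tr$flight_id <- flights$flight_id[match(tr$gdd, flights$gdd)]
        tr
      }
      traits$year <- year
      traits$plot_id <- paste0("Y", year, "_", traits$plot_id)
      all_traits[[year]] <- traits
      yld <- trial$yield
      yld$plot_id <- paste0("Y", year, "_", yld$plot_id)
      yld$year <- year
      yields[[year]] <- yld
      log_line(log, "year %d: %d trait observations", year, nrow(traits))
    }
    traits <- do.call(rbind, all_traits)
    flights <- do.call(rbind, all_flights)
    yields <- do.call(rbind, yields)
    utils::write.csv(traits, file.path(out_dir, "traits.csv"),
                     row.names = FALSE)
    utils::write.csv(flights, file.path(out_dir, "flights.csv"),
                     row.names = FALSE)

    stage <- "repeatability"
    h2 <- repeatability_sweep(traits)
    h2$stage <- assign_stage(h2$gdd)
    utils::write.csv(h2, file.path(out_dir, "repeatability.csv"),
                     row.names = FALSE)
    log_line(log, "repeatability: %d records", nrow(h2))

    stage <- "factor analysis"
    anova_rows <- list(); lsd_rows <- list()
    for (tr in unique(h2$trait)) {
      for (st in levels(h2$stage)) {
        sub <- h2[h2$trait == tr & h2$stage == st & is.finite(h2$H2), ,
                  drop = FALSE]
        if (length(unique(sub$flight_id)) < 2) next
        an <- anova_factorial(sub, response = "H2")
        tab <- an$table
        tab$trait <- tr; tab$growth_stage <- st
        anova_rows[[length(anova_rows) + 1L]] <- tab
        ls <- lsd_test(sub, "selection", anova = an, alpha = config$alpha)
        lm_ <- ls$means
        lm_$trait <- tr; lm_$growth_stage <- st; lm_$lsd <- ls$lsd
        lsd_rows[[length(lsd_rows) + 1L]] <- lm_
      }
    }
    anova_tab <- do.call(rbind, anova_rows)
    lsd_tab <- do.call(rbind, lsd_rows)
    utils::write.csv(anova_tab, file.path(out_dir, "anova.csv"),
                     row.names = FALSE)
    utils::write.csv(lsd_tab, file.path(out_dir, "lsd_selection.csv"),
                     row.names = FALSE)
    log_line(log, "factor analysis: %d ANOVA tables",
             length(anova_rows))

    stage <- "prediction"
    pred_rows <- list()
    for (year in seq_len(config$years)) {
      ytr <- traits[traits$year == year, , drop = FALSE]
      yyl <- yields[yields$year == year, , drop = FALSE]
      for (sel in config$svr$selections) {
        fm <- feature_matrix(ytr, yyl, sel, trimmed = FALSE)
        run <- grid_search_cv(
          fm$x, fm$y, k = config$svr$k, repeats = config$svr$repeats,
          sigma_grid = config$svr$sigma_grid,
          cost_grid = config$svr$cost_grid, groups = fm$groups,
          inner_k = config$svr$inner_k, epsilon = config$svr$epsilon,
          seed = derive_seed(config$seed, sprintf("svr:%d:%s", year, sel)))
        pred_rows[[length(pred_rows) + 1L]] <- data.frame(
          year = year, selection = sel, mean_r = run$mean_r,
          sd_r = run$sd_r, n_folds = nrow(run$fold_r))
        log_line(log, "prediction year %d %s: mean r = %.3f", year, sel,
                 run$mean_r)
      }
    }
    prediction <- do.call(rbind, pred_rows)
    utils::write.csv(prediction, file.path(out_dir, "prediction.csv"),
                     row.names = FALSE)

    list(flights = flights, traits = traits, repeatability = h2,
         anova = anova_tab, lsd = lsd_tab, prediction = prediction,
         out_dir = out_dir)
  }, error = function(e) {
    stop(sprintf("pipeline stage '%s' failed: %s", stage,
                 conditionMessage(e)), call. = FALSE)
  })
  log_line(log, "done")
  invisible(result)
}

#' Generate small hand-checkable test datasets
#'
#' Fixtures used by the unit tests; all regenerate identically from `seed`.
#' `tiny_trial` is a 10-genotype, 2-replicate trial. `tiny_cloud` is a point
#' cloud of at most 1000 points over a 2-plot trial together with a truth
#' list holding brute-force (independent, loop-based) values of the
#' 95th-percentile height, CC10 and plot volume over the untrimmed RS1234
#' boxes. `tiny_rasters` are RGB and hyperspectral rasters of at most
#' 100 x 100 pixels with their painted vegetation fraction.
#'
#' @param kind one of `"tiny_trial"`, `"tiny_cloud"`, `"tiny_rasters"`.
#' @param seed integer seed.
#' @return A list; contents depend on `kind` (always includes the generating
#'   objects plus, where applicable, a `truth` list).
#' @export
make_fixtures <- function(kind = c("tiny_trial", "tiny_cloud", "tiny_rasters"),
                          seed = 1L) {
  kind <- match.arg(kind)
  if (kind == "tiny_trial") {
    trial <- simulate_trial(trial_config(n_genotypes = 10, n_reps = 2,
                                         plants_per_row = 8,
                                         plots_per_range = 5,
                                         rng_seed = seed))
    return(list(trial = trial))
  }
  small <- trial_config(n_genotypes = 2, n_reps = 1, plants_per_row = 4,
                        plots_per_range = 2, rng_seed = seed)
  trial <- simulate_trial(small)
  if (kind == "tiny_cloud") {
    cloud <- render_point_cloud(trial, flight_gdd = 800,
                                points_per_plant = 12,
                                ground_spacing_m = 0.4, seed = seed)
    stopifnot(nrow(cloud) <= 1000)
    boxes <- build_grid(trial$plants, small$row_spacing_m)
    # brute-force truth, computed with plain loops independent of the
    # extraction code
    keep <- rep(FALSE, nrow(cloud))
    for (i in seq_len(nrow(boxes))) {
      b <- boxes[i, ]
      keep <- keep | (cloud$x >= b$x_min & cloud$x < b$x_max &
                        cloud$y >= b$y_min & cloud$y < b$y_max)
    }
    pts <- cloud[keep, ]
    ng <- pts$label != "ground"
    zs <- sort(pts$z[ng])
    q <- function(z, p) { # linear interpolation percentile
      h <- (length(z) - 1) * p
      lo <- floor(h)
      z[lo + 1] + (h - lo) * (z[min(lo + 2, length(z))] - z[lo + 1])
    }
    p95 <- q(zs, 0.95)
    z10 <- q(zs, 0.10)
    cc10 <- sum(pts$z > z10) / nrow(pts)
    vol <- 0
    cell_m <- 0.08
    for (i in seq_len(nrow(boxes))) {
      b <- boxes[i, ]
      inb <- cloud$x >= b$x_min & cloud$x < b$x_max &
        cloud$y >= b$y_min & cloud$y < b$y_max & cloud$label != "ground"
      if (!any(inb)) next
      sub <- cloud[inb, ]
      nx <- ceiling((b$x_max - b$x_min) / cell_m - 1e-9)
      ny <- ceiling((b$y_max - b$y_min) / cell_m - 1e-9)
      for (ix in 0:(nx - 1)) {
        for (iy in 0:(ny - 1)) {
          lo_x <- b$x_min + ix * cell_m
          hi_x <- min(lo_x + cell_m, b$x_max)
          lo_y <- b$y_min + iy * cell_m
          hi_y <- min(lo_y + cell_m, b$y_max)
          inc <- sub$x >= lo_x & sub$x < hi_x & sub$y >= lo_y & sub$y < hi_y
          if (!any(inc)) next
          z <- sort(sub$z[inc])
          vol <- vol + (q(z, 0.95) + z[1]) / 2 * (hi_x - lo_x) * (hi_y - lo_y)
        }
      }
    }
    return(list(trial = trial, cloud = cloud, boxes = boxes,
                truth = list(height_p95 = p95, cc10 = cc10, volume = vol)))
  }
  # tiny_rasters
  ext <- c(xmin = 0, xmax = 1, ymin = 0, ymax = 1)
  ras <- render_rasters(trial, flight_gdd = 800, extent = ext, seed = seed)
  stopifnot(all(dim(ras$rgb$values)[1:2] <= 100))
  list(trial = trial, rgb = ras$rgb, hyperspectral = ras$hyperspectral)
}
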