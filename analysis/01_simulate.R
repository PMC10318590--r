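#!/usr/bin/env Rscript
# Stage 1: simulate the two-year field trial that the rest of the analysis
# consumes — layout, ground-truth effects, yield, weather and the flight
# calendar — and persist everything under results/analysis/.

library(rowseg)

out <- "results/analysis"
dir.create(out, recursive = TRUE, showWarnings = FALSE)

MASTER_SEED <- 2026L
YEARS <- 2
FLIGHT_DAYS <- c(35, 55, 70, 85, 100, 115)

base <- trial_config(n_genotypes = 60, n_reps = 2)

for (year in seq_len(YEARS)) {
  cfg <- base
  cfg$trait_mean <- cfg$trait_mean + 0.05 * (year - 1) # year main effect
  cfg$rng_seed <- derive_seed(MASTER_SEED, paste0("year:", year))
  trial <- simulate_trial(cfg)

  planting <- as.Date("2020-05-01") + 365 * (year - 1)
  weather <- simulate_weather(planting, max(FLIGHT_DAYS) + 10,
                              seed = derive_seed(MASTER_SEED,
                                                 paste0("weather:", year)))
  flights <- data.frame(
    year = year,
    flight_id = sprintf("F%02d", seq_along(FLIGHT_DAYS)),
    date = planting + FLIGHT_DAYS
  )
  flights$gdd <- vapply(flights$date, function(d)
    cumulative_gdd(weather, planting, d), numeric(1))
  flights$stage <- assign_stage(flights$gdd)

  boxes <- build_grid(trial$plants, cfg$row_spacing_m)
  boxes_to_geojson(boxes, file.path(out, sprintf("boxes_y%d.geojson", year)))

  for (tab in c("plots", "truth", "yield")) {
    df <- trial[[tab]]
    df$year <- year
    write.csv(df, file.path(out, sprintf("%s_y%d.csv", tab, year)),
              row.names = FALSE)
  }
  write.csv(weather, file.path(out, sprintf("weather_y%d.csv", year)),
            row.names = FALSE)
  write.csv(flights, file.path(out, sprintf("flights_y%d.csv", year)),
            row.names = FALSE)

  cat(sprintf(
    "year %d: %d plots (%d genotypes x %d reps), yield %.0f g/m2 (range %.0f-%.0f)\n",
    year, nrow(trial$plots), cfg$n_genotypes, cfg$n_reps,
    mean(trial$yield$yield), min(trial$yield$yield), max(trial$yield$yield)))
  cat(sprintf("  flights at %s GDD -> stages %s\n",
              paste(round(flights$gdd), collapse = ", "),
              paste(as.character(flights$stage), collapse = ", ")))
}

cat("done: trial tables, boxes, weather and flight calendars written to",
    out, "\n")
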