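#!/usr/bin/env Rscript
# Stage 4: predict end-season yield from the season-long trait features with
# epsilon-SVR under repeated, subpopulation-balanced 5-fold cross-validation,
# separately per year and row selection, and letter-group the selections on
# their repeat-level accuracies.

library(rowseg)

out <- "results/analysis"
MASTER_SEED <- 2026L
REPEATS <- 5

traits <- read.csv(file.path(out, "traits.csv"))
years <- sort(unique(traits$year))
selections <- names(row_selections())

summary_rows <- list()
repeat_rows <- list()
for (year in years) {
  ytr <- traits[traits$year == year, ]
  yld <- read.csv(file.path(out, sprintf("yield_y%d.csv", year)))
  yld$plot_id <- paste0("Y", year, "_", yld$plot_id)
  for (sel in selections) {
    fm <- feature_matrix(ytr, yld, sel, trimmed = FALSE)
    run <- grid_search_cv(
      fm$x, fm$y, k = 5, repeats = REPEATS,
      sigma_grid = c(1e-3, 1e-2, 0.1), cost_grid = list(10, 100, "n"),
      groups = fm$groups,
      seed = derive_seed(MASTER_SEED, sprintf("svr:%d:%s", year, sel)))
    summary_rows[[length(summary_rows) + 1L]] <- data.frame(
      year = year, selection = sel, mean_r = run$mean_r, sd_r = run$sd_r)
    rep_mean <- aggregate(r ~ repeat_id, run$fold_r, mean)
    repeat_rows[[length(repeat_rows) + 1L]] <- data.frame(
      year = year, selection = sel, repeat_id = rep_mean$repeat_id,
      r = rep_mean$r)
    cat(sprintf("year %d %-7s mean r = %.3f (sd %.3f)\n", year, sel,
                run$mean_r, run$sd_r))
  }
}
summary <- do.call(rbind, summary_rows)
repeats <- do.call(rbind, repeat_rows)
write.csv(summary, file.path(out, "prediction.csv"), row.names = FALSE)
write.csv(repeats, file.path(out, "prediction_repeats.csv"),
          row.names = FALSE)

# letter groupings of selections per year, on repeat-level mean accuracies
cat("\nLSD letter groups per year (repeat-level accuracies):\n")
for (year in years) {
  d <- repeats[repeats$year == year, ]
  d$trimmed <- FALSE
  an <- anova_factorial(d, response = "r")
  g <- lsd_test(d, "selection", anova = an, response = "r")
  cat(sprintf("year %d (LSD = %.3f):\n", year, g$lsd))
  print(g$means, row.names = FALSE, digits = 3)
}
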