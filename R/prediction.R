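# End-season yield prediction with epsilon-SVR under repeated,
# subpopulation-balanced k-fold cross-validation.

#' Standardize features with training-set parameters only
#'
#' Centers and scales every column of `train` to mean 0 and sd 1 (sample sd,
#' n-1 denominator) and applies the *training* center/scale to `test`.
#' Zero-variance columns are dropped with a message; an all-constant feature
#' set is an error.
#'
#' @param train numeric matrix of training features.
#' @param test optional matrix to transform with the training parameters.
#' @return List with `train`, `test` (or `NULL`), `center`, `scale`,
#'   `dropped` (names/indices of dropped columns).
#' @export
standardize_features <- function(train, test = NULL) {
  train <- as.matrix(train)
  if (nrow(train) < 2) stop("train must have >= 2 rows", call. = FALSE)
  ctr <- colMeans(train)
  scl <- apply(train, 2, stats::sd)
  keep <- scl > 0
  if (!any(keep)) stop("all features are constant on the training set",
                       call. = FALSE)
  if (!all(keep)) {
    message(sprintf("dropped %d zero-variance feature(s)", sum(!keep)))
  }
  tr <- scale(train[, keep, drop = FALSE], center = ctr[keep],
              scale = scl[keep])
  te <- if (!is.null(test)) {
    scale(as.matrix(test)[, keep, drop = FALSE], center = ctr[keep],
          scale = scl[keep])
  }
  list(train = tr, test = te, center = ctr[keep], scale = scl[keep],
       dropped = which(!keep))
}

#' Fit epsilon-SVR with a Gaussian kernel and predict
#'
#' Thin wrapper around [kernlab::ksvm()] with the radial-basis kernel
#' \eqn{k(u, v) = \exp(-\sigma \lVert u - v \rVert^2)}; deterministic given
#' its inputs. Features are expected pre-standardized
#' ([standardize_features()]); no internal scaling is applied.
#'
#' @param train_x,train_y training features (matrix) and response.
#' @param test_x features to predict.
#' @param sigma kernel bandwidth, `> 0`.
#' @param cost SVR cost parameter `C`, `> 0`.
#' @param epsilon epsilon-insensitive loss width (default 0.1).
#' @return Numeric predictions, one per row of `test_x`.
#' @export
svr_fit_predict <- function(train_x, train_y, test_x, sigma, cost,
                            epsilon = 0.1) {
  if (sigma <= 0 || cost <= 0) stop("sigma and cost must be > 0", call. = FALSE)
  fit <- tryCatch(
    kernlab::ksvm(as.matrix(train_x), as.numeric(train_y), type = "eps-svr",
                  kernel = "rbfdot", kpar = list(sigma = sigma), C = cost,
                  epsilon = epsilon, scaled = FALSE),
    error = function(e) stop(sprintf("SVR fit failed: %s",
                                     conditionMessage(e)), call. = FALSE))
  as.numeric(kernlab::predict(fit, as.matrix(test_x)))
}

# Deal entries into k folds, round-robin within each group after shuffling,
# so every fold's composition per group differs by at most one entry.
# Uses the current RNG state.
make_folds <- function(n, k, groups = NULL) {
  if (k < 2 || k > n) stop("k must be in [2, n]", call. = FALSE)
  fold <- integer(n)
  if (is.null(groups)) groups <- rep(1L, n)
  groups <- as.factor(groups)
  if (min(table(groups)) < k) {
    stop("group sizes incompatible with balancing: smallest group < k",
         call. = FALSE)
  }
  start <- 0L
  for (g in levels(groups)) {
    idx <- sample(which(groups == g))
    fold[idx] <- (start + seq_along(idx) - 1L) %% k + 1L
    start <- start + length(idx)
  }
  fold
}

resolve_cost_grid <- function(cost_grid, n_features) {
  vapply(cost_grid, function(cg) {
    if (identical(cg, "n")) as.numeric(n_features) else as.numeric(cg)
  }, numeric(1))
}

cv_mean_r <- function(x, y, fold, sigma, cost, epsilon) {
  rs <- vapply(sort(unique(fold)), function(f) {
    te <- fold == f
    std <- standardize_features(x[!te, , drop = FALSE], x[te, , drop = FALSE])
    pred <- svr_fit_predict(std$train, y[!te], std$test, sigma, cost, epsilon)
    if (stats::sd(pred) == 0 || stats::sd(y[te]) == 0) return(NA_real_)
    stats::cor(pred, y[te])
  }, numeric(1))
  mean(rs, na.rm = TRUE)
}

#' Repeated k-fold cross-validated SVR with a hyperparameter grid search
#'
#' For each repeat, entries are shuffled into `k` folds (balanced by
#' `groups` when supplied, so each fold holds an equal share of every
#' subpopulation); one grid search per repeat selects the `(sigma, cost)`
#' pair maximizing the mean correlation of an inner `inner_k`-fold
#' cross-validation run on the first outer fold's training portion; every
#' outer fold is then fit at the chosen pair, and the correlation between
#' predicted and observed yield on the held-out fold is recorded.
#' Standardization parameters always come from the training portion only.
#' Replicates of a genotype are treated as unique entries and may co-occur
#' across train and test folds. Fully reproducible from `seed`.
#'
#' The default grids are sigma in \{1e-4, 1e-3, 1e-2, 0.1\} and cost in
#' \{10, 50, 100, 150, 200, n\}, where the token `"n"` stands for the number
#' of features and is resolved at run time.
#'
#' @param features numeric matrix, rows = plot entries, columns = trait x
#'   flight features.
#' @param target numeric yield vector.
#' @param k outer folds.
#' @param repeats number of repeated fold randomizations.
#' @param sigma_grid numeric vector of kernel bandwidths.
#' @param cost_grid numeric vector of costs; may contain the string `"n"`.
#' @param groups optional subpopulation labels for balanced folds.
#' @param inner_k folds of the inner selection cross-validation.
#' @param epsilon SVR epsilon (default 0.1).
#' @param seed integer seed.
#' @return Object of class `prediction_run`: list with `fold_r` (data frame
#'   `repeat_id`, `fold`, `r`), `params` (chosen `sigma`, `cost` per repeat),
#'   `mean_r`, `sd_r`, `k`, `repeats`, `seed`.
#' @export
grid_search_cv <- function(features, target, k = 10, repeats = 100,
                           sigma_grid = c(1e-4, 1e-3, 1e-2, 0.1),
                           cost_grid = list(10, 50, 100, 150, 200, "n"),
                           groups = NULL, inner_k = 5, epsilon = 0.1,
                           seed = 1L) {
  features <- as.matrix(features)
  n <- nrow(features)
  stopifnot(length(target) == n)
  if (!length(sigma_grid) || !length(cost_grid)) {
    stop("hyperparameter grids must be nonempty", call. = FALSE)
  }
  costs <- resolve_cost_grid(cost_grid, ncol(features))
  grid <- expand.grid(sigma = sigma_grid, cost = costs,
                      KEEP.OUT.ATTRS = FALSE)

  fold_r <- vector("list", repeats)
  params <- vector("list", repeats)
  for (rep_i in seq_len(repeats)) {
    res <- with_seed(derive_seed(seed, paste0("cv:", rep_i)), {
      fold <- make_folds(n, k, groups)
      # hyperparameter selection on the training portion of the first fold
      tr <- fold != 1L
      x_tr <- features[tr, , drop = FALSE]
      y_tr <- target[tr]
      g_tr <- if (!is.null(groups)) groups[tr]
      inner_fold <- make_folds(sum(tr), inner_k, g_tr)
      score <- vapply(seq_len(nrow(grid)), function(i) {
        cv_mean_r(x_tr, y_tr, inner_fold, grid$sigma[i], grid$cost[i], epsilon)
      }, numeric(1))
      best <- grid[which.max(score), ]
      rs <- vapply(seq_len(k), function(f) {
        te <- fold == f
        std <- standardize_features(features[!te, , drop = FALSE],
                                    features[te, , drop = FALSE])
        pred <- svr_fit_predict(std$train, target[!te], std$test,
                                best$sigma, best$cost, epsilon)
        if (stats::sd(pred) == 0 || stats::sd(target[te]) == 0) {
          return(NA_real_)
        }
        stats::cor(pred, target[te])
      }, numeric(1))
      list(rs = rs, best = best)
    })
    fold_r[[rep_i]] <- data.frame(repeat_id = rep_i, fold = seq_len(k),
                                  r = res$rs)
    params[[rep_i]] <- data.frame(repeat_id = rep_i, sigma = res$best$sigma,
                                  cost = res$best$cost)
  }
  fold_r <- do.call(rbind, fold_r)
  params <- do.call(rbind, params)
  structure(
    list(fold_r = fold_r, params = params,
         mean_r = mean(fold_r$r, na.rm = TRUE),
         sd_r = stats::sd(fold_r$r, na.rm = TRUE),
         k = k, repeats = repeats, seed = seed),
    class = "prediction_run"
  )
}

#' @export
print.prediction_run <- function(x, ...) {
  cat(sprintf(
    "<prediction_run> %d-fold CV x %d repeats: mean r = %.3f (sd %.3f)\n",
    x$k, x$repeats, x$mean_r, x$sd_r))
  invisible(x)
}

#' Build a plot-entry feature matrix from a long trait table
#'
#' Spreads one (selection, trim) slice of a trait table into a wide matrix
#' with one row per plot entry and one `trait x flight` column, aligned with
#' a yield table.
#'
#' @param traits long trait table (as from [simulate_trait_observations()] or
#'   [extract_traits()]).
#' @param yield data frame `plot_id`, `yield`.
#' @param selection,trimmed the slice to use.
#' @return List with `x` (matrix), `y` (yield), `plot_id`, `groups`
#'   (subpopulation labels when present, else `NULL`).
#' @export
feature_matrix <- function(traits, yield, selection, trimmed = FALSE) {
  sub <- traits[traits$selection == selection & traits$trimmed == trimmed, ,
                drop = FALSE]
  if (!nrow(sub)) stop("no trait rows for the requested slice", call. = FALSE)
  sub$feature <- paste(sub$trait, sub$flight_id, sep = "_")
  wide <- stats::reshape(
    sub[c("plot_id", "feature", "value")],
    idvar = "plot_id", timevar = "feature", direction = "wide")
  names(wide) <- sub("^value\\.", "", names(wide))
  m <- match(wide$plot_id, yield$plot_id)
  if (anyNA(m)) stop("yield table missing plots present in traits",
                     call. = FALSE)
  x <- as.matrix(wide[, -1, drop = FALSE])
  rownames(x) <- wide$plot_id
  groups <- if ("subpop" %in% names(sub)) {
    sub$subpop[match(wide$plot_id, sub$plot_id)]
  }
  list(x = x, y = yield$yield[m], plot_id = wide$plot_id, groups = groups)
}
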