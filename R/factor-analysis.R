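# Factorial ANOVA over trimming, year and row selection, with LSD letter
# groupings for significant factors.

p_stars <- function(p) {
  ifelse(is.na(p), "", ifelse(p < 0.001, "***",
                              ifelse(p < 0.01, "**",
                                     ifelse(p < 0.05, "*", "NS"))))
}

#' Factorial ANOVA of repeatability or prediction-accuracy observations
#'
#' Fixed-effects linear model with type-I (sequential) sums of squares on the
#' term order `trim + year + selection + selection:year`. With the balanced
#' designs produced by the synthetic generator the order is immaterial.
#' Main-effect interactions with trimming are not modeled. An empty cell for
#' any tested term is an error naming the cell. A constant response yields
#' zero sums of squares everywhere; such terms are reported with `F = 0` and
#' `p = 1`.
#'
#' @param observations data frame with a numeric response column and factor
#'   columns `trimmed`, `year`, `selection` (plus anything else, ignored).
#' @param response name of the response column (default `"H2"`).
#' @return List of class `anova_table`: `table` (term, df, SS, MS, F, p,
#'   stars), `mse`, `df_error`, `model` (the fitted `lm`).
#' @export
anova_factorial <- function(observations, response = "H2") {
  req <- c(response, "trimmed", "year", "selection")
  if (!all(req %in% names(observations))) {
    stop(sprintf("observations must have columns %s",
                 paste(req, collapse = ", ")), call. = FALSE)
  }
  d <- data.frame(
    y = as.numeric(observations[[response]]),
    trim = factor(observations$trimmed),
    year = factor(observations$year),
    selection = factor(observations$selection)
  )
  d <- d[is.finite(d$y), , drop = FALSE]
  for (term in list("trim", "year", "selection", c("selection", "year"))) {
    counts <- table(d[term])
    if (any(counts == 0)) {
      empty <- which(counts == 0, arr.ind = TRUE)[1, , drop = TRUE]
      lab <- paste(mapply(function(dim, i) dimnames(counts)[[dim]][i],
                          seq_along(empty), empty), collapse = " x ")
      stop(sprintf("empty cell for term %s: %s",
                   paste(term, collapse = ":"), lab), call. = FALSE)
    }
  }
  # terms whose factor has a single level carry no information and are
  # dropped from the model (e.g. a one-year dataset)
  terms <- c(
    if (nlevels(droplevels(d$trim)) > 1) "trim",
    if (nlevels(droplevels(d$year)) > 1) "year",
    if (nlevels(droplevels(d$selection)) > 1) "selection",
    if (nlevels(droplevels(d$year)) > 1 &&
          nlevels(droplevels(d$selection)) > 1) "selection:year"
  )
  if (!length(terms)) {
    stop("no factor with >= 2 levels to test", call. = FALSE)
  }
  fit <- stats::lm(stats::reformulate(terms, response = "y"), data = d)
  a <- suppressWarnings(stats::anova(fit)) # silence the perfect-fit warning
  tab <- data.frame(
    term = rownames(a),
    df = a$Df,
    SS = a$`Sum Sq`,
    MS = a$`Mean Sq`,
    F = a$`F value`,
    p = a$`Pr(>F)`,
    stringsAsFactors = FALSE
  )
  # degenerate constant response: total variation at rounding-error level
  tot <- sum(tab$SS)
  scale <- max(1, mean(abs(d$y)))^2
  if (tot <= nrow(d) * scale * 1e-16) {
    terms_only <- tab$term != "Residuals"
    tab$F[terms_only] <- 0
    tab$p[terms_only] <- 1
  }
  tab$stars <- p_stars(tab$p)
  rownames(tab) <- NULL
  structure(
    list(table = tab,
         mse = tab$MS[tab$term == "Residuals"],
         df_error = tab$df[tab$term == "Residuals"],
         model = fit),
    class = "anova_table"
  )
}

#' @export
print.anova_table <- function(x, ...) {
  print(x$table, digits = 4)
  invisible(x)
}

#' Least significant difference test with letter groupings
#'
#' Compares the level means of one factor using the ANOVA error mean square:
#' \deqn{LSD = t_{1-\alpha/2,\,df_e} \sqrt{2\,MSE/n},}
#' with `n` the per-level replication (the harmonic mean of the level sizes,
#' noted with a message, when unbalanced). Letters are assigned to the means
#' sorted in descending order: every maximal run of levels whose extremes
#' differ by at most the LSD shares a letter, so two levels share a letter
#' exactly when their difference is within the LSD.
#'
#' @param observations data frame with the response and factor columns.
#' @param factor_name the factor whose levels are compared (e.g.
#'   `"selection"`).
#' @param anova an [anova_factorial()] result supplying `mse` and
#'   `df_error`; alternatively pass `mse` and `df_error` directly.
#' @param response response column name.
#' @param mse,df_error error mean square and degrees of freedom (override).
#' @param alpha significance level (default 0.05).
#' @return List of class `lsd_grouping`: `means` (level, mean, n, letters,
#'   sorted by descending mean), `lsd`, `alpha`, `mse`, `df_error`.
#' @export
lsd_test <- function(observations, factor_name, anova = NULL,
                     response = "H2", mse = NULL, df_error = NULL,
                     alpha = 0.05) {
  if (!is.null(anova)) {
    mse <- mse %||% anova$mse
    df_error <- df_error %||% anova$df_error
  }
  if (is.null(mse) || is.null(df_error)) {
    stop("supply an anova_factorial result or mse and df_error", call. = FALSE)
  }
  if (df_error < 1) stop("df_error must be >= 1", call. = FALSE)
  y <- as.numeric(observations[[response]])
  f <- factor(observations[[factor_name]])
  ok <- is.finite(y)
  y <- y[ok]; f <- droplevels(f[ok])
  n_lev <- tapply(y, f, length)
  n <- if (length(unique(n_lev)) > 1) {
    message("unbalanced level sizes: using the harmonic mean n")
    length(n_lev) / sum(1 / n_lev)
  } else {
    unname(n_lev[1])
  }
  lsd <- stats::qt(1 - alpha / 2, df_error) * sqrt(2 * mse / n)
  means <- sort(tapply(y, f, mean), decreasing = TRUE)
  L <- length(means)
  letters_out <- character(L)
  lab <- 0L
  prev_end <- 0L
  for (i in seq_len(L)) {
    j <- i
    while (j < L && means[i] - means[j + 1] <= lsd) j <- j + 1L
    if (j > prev_end || i == 1L) {
      lab <- lab + 1L
      ltr <- make_letter(lab)
      for (m in i:j) letters_out[m] <- paste0(letters_out[m], ltr)
      prev_end <- j
    }
  }
  out <- data.frame(
    level = names(means),
    mean = as.numeric(means),
    n = as.numeric(n_lev[names(means)]),
    letters = letters_out,
    stringsAsFactors = FALSE
  )
  structure(list(means = out, lsd = unname(lsd), alpha = alpha,
                 mse = mse, df_error = df_error),
            class = "lsd_grouping")
}

# a, b, ..., z, aa, ab, ... for pathological numbers of groups
make_letter <- function(i) {
  out <- ""
  i <- i - 1L
  repeat {
    out <- paste0(letters[i %% 26L + 1L], out)
    i <- i %/% 26L - 1L
    if (i < 0L) break
  }
  out
}

#' @export
print.lsd_grouping <- function(x, ...) {
  cat(sprintf("LSD = %.4g at alpha = %g (MSE %.4g, df %d)\n",
              x$lsd, x$alpha, x$mse, x$df_error))
  print(x$means, digits = 4)
  invisible(x)
}
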