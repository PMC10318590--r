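#' Variance components of the entry-mean repeatability model
#'
#' Fits the one-trait mixed model
#' \deqn{y_{ij} = \mu + H_i + R_j + \varepsilon_{ij},}
#' with hybrid \eqn{H_i \sim N(0, \sigma^2_H)} random, replicate \eqn{R_j}
#' fixed, and residual \eqn{\varepsilon_{ij} \sim N(0, \sigma^2_\varepsilon)}.
#'
#' `method = "reml"` (default) maximizes the restricted log-likelihood by a
#' deterministic Brent search over the profiled variance ratio
#' \eqn{\lambda = \sigma^2_H / \sigma^2_\varepsilon \ge 0} (the grouped
#' structure makes each evaluation closed-form, so unbalanced designs with
#' missing plots are handled exactly). A negative genetic variance is
#' truncated at the \eqn{\lambda = 0} boundary. `method =
#' "anova_closed_form"` instead uses the balanced two-way ANOVA estimators
#' \eqn{\hat\sigma^2_H = \max(0, (MS_H - MS_E)/r)},
#' \eqn{\hat\sigma^2_\varepsilon = MS_E}; on balanced complete data the two
#' methods agree.
#'
#' @param values data frame with columns `hybrid`, `rep`, `value` (one row
#'   per plot observation; missing plots simply absent).
#' @param method `"reml"` or `"anova_closed_form"`.
#' @return List of class `variance_components`: `sigma2_H`, `sigma2_E`,
#'   `grand_mean`, `rep_effects` (deviations from the grand mean),
#'   `method`, `n_hybrids`, `n_obs`, `reps`.
#' @export
#' @examples
#' d <- expand.grid(hybrid = paste0("H", 1:20), rep = 1:2)
#' d$value <- rnorm(40) + rnorm(20)[as.integer(d$hybrid)]
#' fit_variance_components(d)
fit_variance_components <- function(values,
                                    method = c("reml", "anova_closed_form")) {
  method <- match.arg(method)
  req <- c("hybrid", "rep", "value")
  if (!all(req %in% names(values))) {
    stop("values must have columns hybrid, rep, value", call. = FALSE)
  }
  values <- values[is.finite(values$value), , drop = FALSE]
  hyb <- factor(values$hybrid)
  rp <- factor(values$rep)
  y <- as.numeric(values$value)
  if (nlevels(hyb) < 2) {
    stop("variance not estimable: need >= 2 hybrids", call. = FALSE)
  }
  if (nlevels(rp) < 2) {
    stop("variance not estimable: need >= 2 replicates", call. = FALSE)
  }
  if (stats::var(y) == 0) {
    stop("variance not estimable: all values identical", call. = FALSE)
  }

  if (method == "anova_closed_form") {
    tab <- table(hyb, rp)
    if (any(tab != 1)) {
      stop("anova_closed_form requires a balanced complete design",
           call. = FALSE)
    }
    r <- nlevels(rp)
    a <- stats::anova(stats::lm(y ~ rp + hyb))
    ms_h <- a["hyb", "Mean Sq"]
    ms_e <- a["Residuals", "Mean Sq"]
    s2H <- max(0, (ms_h - ms_e) / r)
    s2E <- ms_e
    fit <- stats::lm(y ~ rp)
    mu_rep <- stats::coef(fit)[1] + c(0, stats::coef(fit)[-1])
  } else {
    res <- profile_reml(y, hyb, rp)
    s2H <- res$s2H
    s2E <- res$s2E
    mu_rep <- res$mu_rep
  }
  grand_mean <- mean(mu_rep)
  structure(
    list(sigma2_H = unname(s2H), sigma2_E = unname(s2E),
         grand_mean = unname(grand_mean),
         rep_effects = stats::setNames(unname(mu_rep - grand_mean), levels(rp)),
         method = method, n_hybrids = nlevels(hyb), n_obs = length(y),
         reps = nlevels(rp)),
    class = "variance_components"
  )
}

# Profiled REML for the two-variance-component grouped model. The marginal
# covariance is sigma2_E * (I + lambda Z Z') with Z the hybrid incidence;
# blocks per hybrid give (I + lambda J)^-1 = I - lambda/(1+lambda r) J, so the
# restricted likelihood is evaluated in O(n) per lambda.
profile_reml <- function(y, hyb, rp) {
  n <- length(y)
  X <- stats::model.matrix(~rp)
  p <- ncol(X)
  r_i <- as.vector(table(hyb))
  Zt_X <- rowsum(X, hyb)
  Zt_y <- as.vector(rowsum(y, hyb))
  XtX <- crossprod(X)
  Xty <- crossprod(X, y)
  yty <- sum(y * y)

  pieces <- function(lam) {
    w <- lam / (1 + lam * r_i)
    XtWiX <- XtX - crossprod(Zt_X, Zt_X * w)
    XtWiy <- Xty - crossprod(Zt_X, Zt_y * w)
    ytWiy <- yty - sum(w * Zt_y^2)
    ch <- chol(XtWiX)
    beta <- backsolve(ch, forwardsolve(t(ch), XtWiy))
    rss <- max(drop(ytWiy - 2 * sum(beta * XtWiy) +
                      crossprod(beta, XtWiX %*% beta)), 1e-300)
    list(beta = drop(beta), rss = rss, ch = ch,
         ldW = sum(log1p(lam * r_i)))
  }
  crit <- function(lam) {
    pc <- pieces(lam)
    (n - p) * log(pc$rss / (n - p)) + pc$ldW + 2 * sum(log(diag(pc$ch)))
  }
  opt <- stats::optimize(function(u) crit(expm1(u)), c(0, 25), tol = 1e-12)
  lam <- if (crit(0) <= opt$objective + 1e-10) 0 else expm1(opt$minimum)
  pc <- pieces(lam)
  s2E <- pc$rss / (n - p)
  mu_rep <- pc$beta[1] + c(0, pc$beta[-1])
  list(s2H = lam * s2E, s2E = s2E, mu_rep = mu_rep, lambda = lam)
}

#' Entry-mean repeatability (broad-sense heritability)
#'
#' \deqn{H^2 = \sigma^2_H / (\sigma^2_H + \sigma^2_\varepsilon / rep)}
#'
#' @param vc a [fit_variance_components()] result, or a list with
#'   `sigma2_H` and `sigma2_E`.
#' @param rep number of replications entering the entry means.
#' @return Repeatability in `[0, 1]`; `NA` when both variances are zero.
#' @export
#' @examples
#' repeatability(list(sigma2_H = 1, sigma2_E = 1), rep = 2) # 2/3
repeatability <- function(vc, rep) {
  if (rep < 1) stop("rep must be >= 1", call. = FALSE)
  s2H <- vc$sigma2_H
  s2E <- vc$sigma2_E
  if (s2H < 0 || s2E < 0) stop("variances must be >= 0", call. = FALSE)
  denom <- s2H + s2E / rep
  if (denom == 0) return(NA_real_)
  s2H / denom
}

#' Repeatability for every (trait, flight, year, selection, trim) cell
#'
#' Splits a long trait table into cells and fits [fit_variance_components()]
#' plus [repeatability()] in each. Cells that are empty or not estimable are
#' returned flagged missing (`H2 = NA`) with a message rather than an error.
#'
#' @param traits long data frame with columns `genotype`, `rep`, `selection`,
#'   `trimmed`, `flight_id`, `trait`, `value`, and optionally `year` and
#'   `gdd` (carried through).
#' @param rep number of replications for the Eq.-style entry-mean formula
#'   (defaults to the number of distinct `rep` levels).
#' @param method passed to [fit_variance_components()].
#' @return Data frame with one row per cell: the factors plus `sigma2_H`,
#'   `sigma2_E`, `H2`, `rep`, `n_obs`.
#' @export
repeatability_sweep <- function(traits, rep = NULL,
                                method = c("reml", "anova_closed_form")) {
  method <- match.arg(method)
  req <- c("genotype", "rep", "selection", "trimmed", "flight_id", "trait",
           "value")
  if (!all(req %in% names(traits))) {
    stop(sprintf("traits table must have columns %s",
                 paste(req, collapse = ", ")), call. = FALSE)
  }
  if (!"year" %in% names(traits)) traits$year <- 1L
  n_rep <- rep %||% length(unique(traits$rep))
  cells <- unique(traits[c("trait", "flight_id", "year", "selection", "trimmed")])
  cells <- cells[order(cells$trait, cells$year, cells$flight_id,
                       cells$selection, cells$trimmed), , drop = FALSE]
  key_all <- paste(traits$trait, traits$flight_id, traits$year,
                   traits$selection, traits$trimmed)
  key_cell <- paste(cells$trait, cells$flight_id, cells$year,
                    cells$selection, cells$trimmed)
  out <- lapply(seq_len(nrow(cells)), function(i) {
    sub <- traits[key_all == key_cell[i], , drop = FALSE]
    rec <- cells[i, , drop = FALSE]
    rec$rep <- n_rep
    rec$gdd <- if ("gdd" %in% names(sub) && nrow(sub)) sub$gdd[1] else NA_real_
    fit <- tryCatch(
      fit_variance_components(
        data.frame(hybrid = sub$genotype, rep = sub$rep, value = sub$value),
        method = method),
      error = function(e) {
        message(sprintf("cell (%s, %s, %s, %s, trimmed=%s) flagged missing: %s",
                        rec$trait, rec$flight_id, rec$year, rec$selection,
                        rec$trimmed, conditionMessage(e)))
        NULL
      })
    if (is.null(fit)) {
      rec$sigma2_H <- NA_real_; rec$sigma2_E <- NA_real_
      rec$H2 <- NA_real_; rec$n_obs <- nrow(sub)
    } else {
      rec$sigma2_H <- fit$sigma2_H
      rec$sigma2_E <- fit$sigma2_E
      rec$H2 <- repeatability(fit, n_rep)
      rec$n_obs <- fit$n_obs
    }
    rec
  })
  out <- do.call(rbind, out)
  rownames(out) <- NULL
  out
}
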