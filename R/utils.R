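# Internal helpers shared across modules.

#' Derive a reproducible substream seed from a master seed and a label
#'
#' Every stochastic stage of the pipeline draws its seed from the master seed
#' and a stage label, so adding a stage never perturbs the random stream of
#' another.
#'
#' @param master integer master seed.
#' @param label character stage label (e.g. `"trial"`, `"flight:300"`).
#' @return An integer seed in `[0, 2^31 - 2]`.
#' @export
#' @examples
#' derive_seed(1, "trial")
derive_seed <- function(master, label) {
  m <- 2147483647 # 2^31 - 1, Mersenne prime
  h <- as.double(master %% m)
  for (code in utf8ToInt(label)) {
    h <- (h * 31 + code) %% m
  }
  as.integer(h)
}

# Evaluate `expr` under a fixed seed without disturbing the caller's RNG state.
with_seed <- function(seed, expr) {
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    get(".Random.seed", envir = globalenv())
  } else {
    NULL
  }
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
        rm(".Random.seed", envir = globalenv())
      }
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  })
  set.seed(seed)
  expr
}

# Percentile with linear interpolation between order statistics.
pctl <- function(x, p) {
  unname(stats::quantile(x, probs = p, type = 7, names = FALSE))
}

stop_config <- function(field, why) {
  stop(sprintf("invalid TrialConfig field '%s': %s", field, why), call. = FALSE)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
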