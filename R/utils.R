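# Internal helpers shared across modules.

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Evaluate an expression with a temporary RNG seed
#'
#' Runs `expr` with the global random number generator seeded to `seed`,
#' restoring the caller's RNG state afterwards so seeded operations never
#' perturb the surrounding session.
#'
#' @param seed Integer seed.
#' @param expr Expression to evaluate.
#' @return The value of `expr`.
#' @keywords internal
with_seed <- function(seed, expr) {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(suppressWarnings(rm(".Random.seed", envir = globalenv())),
            add = TRUE)
  }
  set.seed(as.integer(seed))
  expr
}

# Deterministically derive a per-stage seed from a global seed and a label,
# kept below 2^31 so it is always a valid R integer seed.
derive_seed <- function(seed, label) {
  h <- 0
  for (ch in utf8ToInt(label)) h <- (h * 31 + ch) %% 2147483647
  as.integer((as.numeric(seed) * 48271 + h) %% 2147483647)
}

stopifnot_scalar_number <- function(x, name) {
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x))
    stop(sprintf("'%s' must be a single finite number", name), call. = FALSE)
}

# Column-wise z-scoring; zero-sd columns become all-zero (optionally warning).
zscore_columns <- function(m, warn = TRUE) {
  mu <- colMeans(m)
  sd <- apply(m, 2, stats::sd)
  degenerate <- sd == 0 | !is.finite(sd)
  if (any(degenerate) && warn)
    warning(sprintf("%d zero-variance column(s) set to z-score 0",
                    sum(degenerate)), call. = FALSE)
  sd[degenerate] <- 1
  z <- sweep(sweep(m, 2, mu, "-"), 2, sd, "/")
  z[, degenerate] <- 0
  z
}
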