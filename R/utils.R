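# Internal helpers: argument validation and per-operation seed streams.

# Stop with the offending argument named, in the style of base R checks.
check_number <- function(x, name, lower = -Inf, upper = Inf,
                         allow_na = FALSE) {
  if (length(x) != 1L || !is.numeric(x) ||
      (!allow_na && (is.na(x) || !is.finite(x)))) {
    stop(sprintf("`%s` must be a single finite number", name), call. = FALSE)
  }
  if (x < lower) {
    stop(sprintf("`%s` must be >= %g (got %g)", name, lower, x),
         call. = FALSE)
  }
  if (x > upper) {
    stop(sprintf("`%s` must be <= %g (got %g)", name, upper, x),
         call. = FALSE)
  }
  invisible(x)
}

check_columns <- function(df, cols, what = "input table") {
  missing <- setdiff(cols, names(df))
  if (length(missing)) {
    stop(sprintf("%s is missing required column(s): %s", what,
                 paste(missing, collapse = ", ")), call. = FALSE)
  }
  invisible(df)
}

#' Derive a reproducible per-operation seed from a master seed
#'
#' Each stochastic operation in the package draws from its own stream so
#' that re-running one stage of a pipeline does not perturb the random
#' numbers used by another. Streams are derived deterministically from a
#' single master seed and a short operation label.
#'
#' @param master integer master seed.
#' @param op character scalar naming the operation (e.g. `"binding"`).
#' @return An integer seed in `[0, 2^31 - 2]`.
#' @examples
#' derive_seed(1, "binding")
#' derive_seed(1, "gradient")
#' @export
derive_seed <- function(master, op) {
  check_number(master, "master")
  stopifnot(is.character(op), length(op) == 1L)
  h <- 0
  for (k in utf8ToInt(op)) h <- (h * 131 + k) %% 2147483647
  as.integer((abs(master) * 48271 + h) %% 2147483646) + 1L
}

# Run `expr` under a temporary RNG state seeded with `seed`; restores the
# caller's RNG afterwards so simulators do not interfere with user code.
with_seed <- function(seed, expr) {
  if (!is.null(seed)) {
    if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      old <- get(".Random.seed", envir = globalenv())
      on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
    } else {
      on.exit(rm(".Random.seed", envir = globalenv()), add = TRUE)
    }
    set.seed(as.integer(seed %% 2147483647))
  }
  expr
}
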