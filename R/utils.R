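# Internal helpers: seeded evaluation, sub-stream derivation, interval folding.

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Evaluate an expression under a fixed RNG seed, leaving the caller's RNG
#' state untouched.
#' @noRd
local_seed <- function(seed, code) {
  genv <- globalenv()
  if (exists(".Random.seed", envir = genv, inherits = FALSE)) {
    old <- get(".Random.seed", envir = genv, inherits = FALSE)
    on.exit(assign(".Random.seed", old, envir = genv), add = TRUE)
  } else {
    on.exit(
      if (exists(".Random.seed", envir = genv, inherits = FALSE)) {
        rm(".Random.seed", envir = genv)
      },
      add = TRUE
    )
  }
  set.seed(seed)
  code
}

#' Derive a deterministic sub-stream seed from a base seed and a label, so
#' each simulation stage draws from its own stream and adding a stage never
#' shifts another stage's draws. Result is a positive 32-bit integer.
#' @noRd
derive_seed <- function(seed, salt) {
  stopifnot(is.numeric(seed), length(seed) == 1L, is.character(salt))
  codes <- utf8ToInt(salt)
  h <- sum(codes * seq_along(codes)) %% 2147483563
  v <- ((abs(seed) %% 2147483563) * 7919 + h * 104729) %% 2147483562
  as.integer(v) + 1L
}

#' Fold a coordinate into [lo, hi] by repeated reflection at the borders.
#' Vectorised; exact for values already inside.
#' @noRd
reflect_into <- function(x, lo, hi) {
  stopifnot(hi > lo)
  span <- hi - lo
  y <- (x - lo) %% (2 * span)
  y <- ifelse(y > span, 2 * span - y, y)
  lo + y
}

#' round() half away from zero, matching how the printed tables round.
#' @noRd
round_half_up <- function(x, digits = 2) {
  p <- 10^digits
  sign(x) * floor(abs(x) * p + 0.5) / p
}

assert_scalar_number <- function(x, name, lower = -Inf, upper = Inf) {
  if (!is.numeric(x) || length(x) != 1L || is.na(x)) {
    stop(sprintf("`%s` must be a single non-missing number", name),
         call. = FALSE)
  }
  if (x < lower || x > upper) {
    stop(sprintf("`%s` must be in [%s, %s], got %s", name,
                 format(lower), format(upper), format(x)), call. = FALSE)
  }
  invisible(x)
}
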