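# Internal helpers shared across modules.

#' Evaluate an expression under a temporary RNG state
#'
#' Runs `expr` after `set.seed(seed)` and restores the caller's
#' `.Random.seed` afterwards, so simulators are reproducible without
#' clobbering the session RNG.
#' @noRd
with_seed <- function(seed, expr) {
  env <- globalenv()
  had <- exists(".Random.seed", envir = env, inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = env)
  on.exit({
    if (had) assign(".Random.seed", old, envir = env)
    else if (exists(".Random.seed", envir = env, inherits = FALSE))
      rm(".Random.seed", envir = env)
  })
  set.seed(as.integer(seed))
  expr
}

#' @noRd
geometric_mean <- function(x) exp(mean(log(x)))

# log(sum(exp(x))) without overflow
#' @noRd
logsumexp <- function(x) {
  m <- max(x)
  if (!is.finite(m)) return(m)
  m + log(sum(exp(x - m)))
}

#' @noRd
is_count <- function(x) {
  is.numeric(x) && length(x) == 1L && is.finite(x) && x >= 0 && x == round(x)
}

# Edge-to-edge gap between half-open intervals [s1,e1) and [s2,e2);
# 0 when they intersect or touch.
#' @noRd
interval_gap <- function(s1, e1, s2, e2) {
  pmax(0, pmax(s2 - e1, s1 - e2))
}

#' @noRd
stop_medip <- function(...) stop(..., call. = FALSE)
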