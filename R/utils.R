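# internal helpers shared across modules

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Signal a classed ethokinetics error
#'
#' @param msg message string
#' @param class condition subclass, e.g. "ek_invalid_input"
#' @param data optional list attached to the condition
#' @noRd
ek_stop <- function(msg, class, data = NULL) {
  cond <- structure(
    class = c(class, "ethokinetics_error", "error", "condition"),
    c(list(message = msg, call = sys.call(-1)), data)
  )
  stop(cond)
}

assert_scalar_num <- function(x, name, lower = -Inf, upper = Inf,
                              strict_lower = FALSE) {
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x) ||
      x < lower || x > upper || (strict_lower && x <= lower)) {
    ek_stop(sprintf("`%s` must be a finite scalar in [%s, %s]%s, got: %s",
                    name, lower, upper,
                    if (strict_lower) sprintf(" (strictly > %s)", lower) else "",
                    paste(format(x), collapse = ", ")),
            "ek_invalid_input")
  }
  invisible(x)
}

#' Run code with a temporary RNG state
#'
#' Restores (or removes) .Random.seed afterwards so seeded simulator calls do
#' not perturb the caller's RNG stream.
#' @noRd
with_seed_local <- function(seed, code) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  }, add = TRUE)
  set.seed(seed)
  force(code)
}

#' Maximal runs of TRUE in a logical vector
#'
#' @return data.frame(start, end, length), 1-based inclusive step indices
#' @noRd
true_runs <- function(x) {
  if (length(x) == 0L || !any(x)) {
    return(data.frame(start = integer(0), end = integer(0),
                      length = integer(0)))
  }
  r <- rle(as.logical(x))
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  keep <- r$values
  data.frame(start = starts[keep], end = ends[keep],
             length = r$lengths[keep])
}

# Euclidean step lengths between consecutive points
step_lengths <- function(x, y) {
  if (length(x) < 2L) return(numeric(0))
  sqrt(diff(x)^2 + diff(y)^2)
}
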