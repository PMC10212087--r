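#' @keywords internal
"_PACKAGE"

# Validation helper: abort with a clean message (no call).
abort_if <- function(cond, ...) {
  if (isTRUE(cond)) stop(paste0(...), call. = FALSE)
}

assert_number <- function(x, name, positive = FALSE, nonneg = FALSE) {
  abort_if(!is.numeric(x) || length(x) != 1L || !is.finite(x),
           sprintf("'%s' must be a single finite number", name))
  if (positive) abort_if(x <= 0, sprintf("'%s' must be > 0 (got %g)", name, x))
  if (nonneg)  abort_if(x < 0,  sprintf("'%s' must be >= 0 (got %g)", name, x))
  invisible(x)
}

#' Evaluate code with a temporary RNG seed
#'
#' Runs `code` with the RNG seeded to `seed`, restoring the caller's RNG
#' state afterwards. All randomness in the package flows through explicit
#' seeds passed by the caller; nothing touches the global stream.
#'
#' @param seed Integer seed.
#' @param code Expression to evaluate.
#' @return The value of `code`.
#' @keywords internal
with_seed <- function(seed, code) {
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(as.integer(seed))
  force(code)
}

# Stage-tagged logging to stderr. Suppressed below "warn" when quiet.
log_msg <- function(stage, ..., quiet = getOption("spheromech.quiet", FALSE),
                    level = "info") {
  if (isTRUE(quiet) && level == "info") return(invisible(NULL))
  message(sprintf("[%s] %s", stage, paste0(...)))
}
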