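#' @keywords internal
#' @noRd
local_seed <- function(seed, code) {
  if (is.null(seed)) return(force(code))
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  force(code)
}

# scalar validators; stop() with the caller-facing argument name
check_number <- function(x, name, lower = -Inf, upper = Inf,
                         strict_lower = FALSE, strict_upper = FALSE) {
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x))
    stop(sprintf("`%s` must be a single finite number", name), call. = FALSE)
  if (strict_lower && x <= lower)
    stop(sprintf("`%s` must be > %g", name, lower), call. = FALSE)
  if (!strict_lower && x < lower)
    stop(sprintf("`%s` must be >= %g", name, lower), call. = FALSE)
  if (strict_upper && x >= upper)
    stop(sprintf("`%s` must be < %g", name, upper), call. = FALSE)
  if (!strict_upper && x > upper)
    stop(sprintf("`%s` must be <= %g", name, upper), call. = FALSE)
  invisible(x)
}

check_finite <- function(x, name) {
  if (!is.numeric(x) || anyNA(x) || any(!is.finite(x)))
    stop(sprintf("`%s` must be finite and non-missing", name), call. = FALSE)
  invisible(x)
}
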