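#' @keywords internal
"_PACKAGE"

#' Round half away from zero
#'
#' Reporting convention for megabase spans: `round()` in R rounds half to
#' even, which would print 12.705 as 12.70; published span tables round half
#' up instead.
#'
#' @param x numeric vector
#' @param digits number of decimal places
#' @return rounded numeric vector
#' @export
round_half_up <- function(x, digits = 0) {
  m <- 10^digits
  sign(x) * floor(abs(x) * m + 0.5) / m
}

#' Evaluate an expression under a fixed RNG seed
#'
#' Saves and restores `.Random.seed` so that seeded generators behave as pure
#' functions of (config, seed) without disturbing the caller's RNG stream.
#'
#' @param seed integer seed
#' @param expr expression to evaluate
#' @return value of `expr`
#' @export
with_seed <- function(seed, expr) {
  has_seed <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has_seed) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (has_seed) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  expr
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Merge user parameters into a default list
#' @noRd
merge_params <- function(defaults, user) {
  if (is.null(user)) return(defaults)
  stopifnot(is.list(user))
  bad <- setdiff(names(user), names(defaults))
  if (length(bad)) stop("unknown parameter(s): ", paste(bad, collapse = ", "))
  defaults[names(user)] <- user
  defaults
}
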