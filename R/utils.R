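# Internal argument checks shared across the package.

check_positive <- function(x, name) {
  if (!is.numeric(x) || length(x) < 1 || anyNA(x) || any(x <= 0)) {
    rlang::abort(sprintf("`%s` must be numeric and > 0.", name),
      class = "cryosect_invalid_argument"
    )
  }
  invisible(x)
}

check_non_negative <- function(x, name) {
  if (!is.numeric(x) || length(x) < 1 || anyNA(x) || any(x < 0)) {
    rlang::abort(sprintf("`%s` must be numeric and >= 0.", name),
      class = "cryosect_invalid_argument"
    )
  }
  invisible(x)
}

check_scalar_count <- function(x, name, min = 1) {
  if (!is.numeric(x) || length(x) != 1 || is.na(x) || x < min || x != floor(x)) {
    rlang::abort(sprintf("`%s` must be a single integer >= %d.", name, min),
      class = "cryosect_invalid_argument"
    )
  }
  invisible(as.integer(x))
}

# Seeds are applied locally so simulations never disturb the caller's RNG
# stream; NULL leaves the current stream untouched.
with_seed <- function(seed, code) {
  if (is.null(seed)) {
    return(force(code))
  }
  had_seed <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had_seed) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (had_seed) {
      assign(".Random.seed", old, envir = globalenv())
    } else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  })
  set.seed(seed)
  force(code)
}
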