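#' Evaluate code with a temporary RNG state
#'
#' Runs `code` after `set.seed(seed)` and restores the caller's RNG state on
#' exit, so seeded helpers do not perturb the global random stream. With
#' `seed = NULL` the code runs on the current stream.
#'
#' @param seed integer seed or `NULL`.
#' @param code expression to evaluate.
#' @return the value of `code`.
#' @keywords internal
with_seed <- function(seed, code) {
  if (is.null(seed)) return(force(code))
  genv <- globalenv()
  had <- exists(".Random.seed", envir = genv, inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = genv, inherits = FALSE)
  on.exit({
    if (had) assign(".Random.seed", old, envir = genv)
    else suppressWarnings(rm(".Random.seed", envir = genv))
  })
  set.seed(as.integer(seed))
  force(code)
}

stop_field <- function(field, msg) {
  stop(sprintf("invalid configuration: field '%s' %s", field, msg), call. = FALSE)
}

check_scalar_num <- function(x, field, lower = -Inf, upper = Inf,
                             strict_lower = FALSE, strict_upper = FALSE) {
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x))
    stop_field(field, "must be a finite numeric scalar")
  if (strict_lower && x <= lower) stop_field(field, sprintf("must be > %g", lower))
  if (!strict_lower && x < lower) stop_field(field, sprintf("must be >= %g", lower))
  if (strict_upper && x >= upper) stop_field(field, sprintf("must be < %g", upper))
  if (!strict_upper && x > upper) stop_field(field, sprintf("must be <= %g", upper))
  invisible(x)
}

check_interval <- function(x, field, allow_degenerate = TRUE) {
  if (!is.numeric(x) || length(x) != 2L || any(!is.finite(x)))
    stop_field(field, "must be a numeric interval c(lower, upper)")
  if (allow_degenerate) {
    if (x[1] > x[2]) stop_field(field, "must satisfy lower <= upper")
  } else if (x[1] >= x[2]) stop_field(field, "must satisfy lower < upper")
  invisible(x)
}

# Near-equal fold sizes: n observations into k folds, sizes differing by at
# most one, assigned to a permutation drawn from the current RNG stream.
fold_assignment <- function(n, k) {
  if (k < 1L || k > n) stop("number of folds must be in 1..n", call. = FALSE)
  sizes <- rep(n %/% k, k) + c(rep(1L, n %% k), rep(0L, k - n %% k))
  fold <- integer(n)
  fold[sample.int(n)] <- rep.int(seq_len(k), sizes)
  fold
}
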