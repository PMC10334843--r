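#' @keywords internal
"_PACKAGE"

# Run `expr` under a local RNG state seeded with `seed`; the caller's
# .Random.seed is restored afterwards. `seed = NULL` leaves the current
# stream untouched (still reproducible if the caller seeded it).
with_local_seed <- function(seed, expr) {
  if (is.null(seed)) return(expr)
  stopifnot(is.numeric(seed), length(seed) == 1L, is.finite(seed))
  has_seed <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has_seed) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (has_seed) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  }, add = TRUE)
  set.seed(as.integer(seed))
  expr
}

#' Derive an independent substream seed from a master seed
#'
#' Fixed offsets give child operations independent substreams from one
#' top-level seed. The (seed, offset) pair is scrambled through two
#' Lehmer-LCG rounds before use: nearby raw integers fed to [set.seed()]
#' can yield noticeably correlated streams, which would leak systematic
#' differences between simulated groups.
#'
#' @param seed Master integer seed (`NULL` passes through).
#' @param offset Integer offset identifying the child operation.
#' @return An integer seed, or `NULL`.
#' @export
child_seed <- function(seed, offset) {
  if (is.null(seed)) return(NULL)
  m <- 2147483647
  x <- (as.numeric(seed) %% m) + 1
  x <- (x * 48271) %% m
  x <- ((x + as.numeric(offset)) %% m + 1)
  x <- (x * 48271) %% m
  x <- (x * 16807) %% m
  as.integer(x)
}

stop_if_not_scalar_number <- function(x, name) {
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x))
    stop(sprintf("'%s' must be a single finite number", name), call. = FALSE)
  invisible(x)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
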