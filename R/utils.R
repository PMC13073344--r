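#' Evaluate an expression under a fixed RNG seed
#'
#' Runs `expr` with the RNG seeded to `seed` and restores the caller's RNG
#' state afterwards, so seeded generators do not perturb the global stream.
#'
#' @param seed Integer seed, or `NULL` to use the current RNG state.
#' @param expr Expression to evaluate.
#' @return The value of `expr`.
#' @examples
#' with_seed(1, rnorm(2))
#' @export
with_seed <- function(seed, expr) {
  if (is.null(seed)) return(expr)
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  expr
}

# clip to [lo, hi], preserving dim and other attributes of x
clip <- function(x, lo, hi) {
  x[x < lo] <- lo
  x[x > hi] <- hi
  x
}

stop_if_not_image <- function(image) {
  if (!is.matrix(image) || !is.numeric(image))
    stop("`image` must be a single-channel numeric matrix", call. = FALSE)
  if (length(image) == 0L) stop("`image` is empty", call. = FALSE)
  rng <- range(image)
  if (is.na(rng[1]) || rng[1] < 0 || rng[2] > 255)
    stop("`image` must hold grayscale values in [0, 255]", call. = FALSE)
  invisible(image)
}

check_scalar <- function(x, name, lo = -Inf, hi = Inf,
                         strict_lo = FALSE, strict_hi = FALSE,
                         integer = FALSE) {
  if (!is.numeric(x) || length(x) != 1L || is.na(x))
    stop(sprintf("`%s` must be a single non-missing number", name), call. = FALSE)
  ok <- if (strict_lo) x > lo else x >= lo
  ok <- ok && if (strict_hi) x < hi else x <= hi
  if (!ok)
    stop(sprintf("`%s` = %s is outside its admissible range %s%s, %s%s",
                 name, format(x), if (strict_lo) "(" else "[", format(lo),
                 format(hi), if (strict_hi) ")" else "]"), call. = FALSE)
  if (integer && x != round(x))
    stop(sprintf("`%s` must be an integer", name), call. = FALSE)
  invisible(x)
}

# shoelace area of a polygon given as a 2-column matrix of vertices
polygon_area <- function(p) {
  if (nrow(p) < 3L) return(0)
  x <- p[, 1]; y <- p[, 2]
  abs(sum(x * c(y[-1], y[1]) - c(x[-1], x[1]) * y)) / 2
}

polygon_perimeter <- function(p) {
  if (nrow(p) < 2L) return(0)
  q <- p[c(2:nrow(p), 1L), , drop = FALSE]
  sum(sqrt(rowSums((q - p)^2)))
}
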