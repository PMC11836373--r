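# Internal helpers shared across modules.

#' @keywords internal
clip01 <- function(x) {
  x[x < 0] <- 0
  x[x > 1] <- 1
  x
}

# Evaluate `expr` under a temporary RNG state seeded with `seed`; the caller's
# RNG state is restored afterwards. `seed = NULL` uses the current stream.
with_seed <- function(seed, expr) {
  if (is.null(seed)) return(expr)
  has_old <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (has_old) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (has_old) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  expr
}

stopf <- function(fmt, ...) stop(sprintf(fmt, ...), call. = FALSE)

# reflect (mirror, no edge repeat beyond one sample) index into 1..n
reflect_index <- function(i, n) {
  if (n == 1L) return(rep(1L, length(i)))
  period <- 2L * (n - 1L)
  j <- (i - 1L) %% period
  j <- ifelse(j < 0L, j + period, j)
  as.integer(ifelse(j >= n, period - j, j) + 1L)
}

is_scalar_number <- function(x) is.numeric(x) && length(x) == 1L && is.finite(x)

#' Validate a grayscale image matrix
#'
#' Images throughout the package are plain numeric matrices with values in
#' `[0, 1]` (rows = image rows, columns = image columns).
#'
#' @param img numeric matrix.
#' @return the matrix, invisibly, after validation.
#' @keywords internal
check_image <- function(img) {
  if (!is.matrix(img) || !is.numeric(img))
    stopf("image must be a numeric matrix")
  if (any(!is.finite(img)))
    stopf("image contains non-finite values")
  if (min(img) < -1e-9 || max(img) > 1 + 1e-9)
    stopf("image values must lie in [0, 1]")
  invisible(img)
}
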