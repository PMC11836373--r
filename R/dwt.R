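# Multilevel 2-D discrete wavelet transform with significance-based
# coefficient retention, used to denoise/simplify OCT B-scans before
# embedding.
#
# Orthonormal filters with periodized (circular) boundary handling: the
# one-level analysis operator is then an exactly orthogonal matrix, so
# reconstruction is exact to floating point and coefficient energy equals
# pixel energy (Parseval).

# Daubechies scaling (low-pass decomposition) filters, orthonormal.
.dwt_filters <- list(
  haar = c(1, 1) / sqrt(2),
  db2  = c(1 + sqrt(3), 3 + sqrt(3), 3 - sqrt(3), 1 - sqrt(3)) / (4 * sqrt(2)),
  db4  = c(0.23037781330885523, 0.71484657055254153, 0.63088076792959036,
           -0.02798376941698385, -0.18703481171888114, 0.03084138183598697,
           0.03288301166698295, -0.01059740178499728)
)

#' Available orthogonal wavelet names
#' @return character vector of supported wavelet identifiers.
#' @export
dwt_wavelets <- function() names(.dwt_filters)

dwt_filter <- function(wavelet) {
  h <- .dwt_filters[[wavelet]]
  if (is.null(h))
    stopf("unknown wavelet '%s'; available: %s", wavelet,
          paste(names(.dwt_filters), collapse = ", "))
  h
}

# quadrature-mirror high-pass from the scaling filter
dwt_highpass <- function(h) {
  L <- length(h)
  rev(h) * (-1)^(seq_len(L) - 1)
}

# One-level periodized analysis matrix for signals of even length n.
# Rows 1..n/2 are circular even shifts of the low-pass filter, rows
# n/2+1..n of the high-pass filter; orthogonal for orthonormal filters.
.dwt_mat_cache <- new.env(parent = emptyenv())

dwt_analysis_matrix <- function(n, wavelet) {
  key <- paste0(wavelet, "_", n)
  cached <- .dwt_mat_cache[[key]]
  if (!is.null(cached)) return(cached)
  h <- dwt_filter(wavelet)
  g <- dwt_highpass(h)
  L <- length(h)
  if (n %% 2L != 0L || n < L)
    stopf("signal length %d unsupported for wavelet '%s' (need even length >= %d)",
          n, wavelet, L)
  A <- matrix(0, n, n)
  half <- n %/% 2L
  for (k in seq_len(half)) {
    cols <- ((2L * (k - 1L) + seq_len(L) - 1L) %% n) + 1L
    for (i in seq_len(L)) {
      A[k, cols[i]] <- A[k, cols[i]] + h[i]
      A[half + k, cols[i]] <- A[half + k, cols[i]] + g[i]
    }
  }
  .dwt_mat_cache[[key]] <- A
  A
}

# Number of feasible decomposition levels for one dimension.
.max_levels_1d <- function(n, filter_len) {
  j <- 0L
  while (n %% 2L == 0L && n >= filter_len) {
    j <- j + 1L
    n <- n %/% 2L
  }
  j
}

#' Maximum feasible decomposition depth for an image
#'
#' @param height,width image extents in pixels.
#' @param wavelet wavelet name (see [dwt_wavelets()]).
#' @return integer, the largest usable number of levels.
#' @export
dwt_max_levels <- function(height, width, wavelet = "haar") {
  L <- length(dwt_filter(wavelet))
  min(.max_levels_1d(as.integer(height), L), .max_levels_1d(as.integer(width), L))
}

#' Multilevel 2-D discrete wavelet decomposition
#'
#' Decomposes a grayscale image (numeric matrix in `[0,1]`) into a coarsest
#' approximation subband and, per level, three orientation detail subbands.
#' Level 1 holds the finest details. Orientation naming: `h` is low-pass
#' along rows / high-pass along columns, `v` the converse, `d` high-pass in
#' both directions.
#'
#' @param image numeric matrix with values in `[0, 1]`.
#' @param wavelet orthogonal wavelet name, one of [dwt_wavelets()].
#' @param levels number of decomposition levels `J >= 1`.
#' @return an object of class `wavelet_decomposition` with fields
#'   `wavelet`, `levels`, `approx` (matrix), `details` (list of per-level
#'   lists with matrices `h`, `v`, `d`) and `original_shape`.
#' @examples
#' img <- matrix(runif(64 * 64), 64, 64)
#' d <- dwt_decompose(img, "haar", 2)
#' max(abs(dwt_reconstruct(d) - img)) < 1e-8
#' @export
dwt_decompose <- function(image, wavelet = "haar", levels = 2L) {
  check_image(image)
  levels <- as.integer(levels)
  if (levels < 1L) stopf("levels must be >= 1")
  maxJ <- dwt_max_levels(nrow(image), ncol(image), wavelet)
  if (levels > maxJ)
    stopf("levels = %d too deep for a %dx%d image with wavelet '%s' (maximum feasible: %d)",
          levels, nrow(image), ncol(image), wavelet, maxJ)
  approx <- image
  details <- vector("list", levels)
  for (j in seq_len(levels)) {
    Ar <- dwt_analysis_matrix(nrow(approx), wavelet)
    Ac <- dwt_analysis_matrix(ncol(approx), wavelet)
    Z <- Ar %*% approx %*% t(Ac)
    hr <- nrow(approx) %/% 2L
    hc <- ncol(approx) %/% 2L
    details[[j]] <- list(
      h = Z[seq_len(hr), hc + seq_len(hc), drop = FALSE],
      v = Z[hr + seq_len(hr), seq_len(hc), drop = FALSE],
      d = Z[hr + seq_len(hr), hc + seq_len(hc), drop = FALSE]
    )
    approx <- Z[seq_len(hr), seq_len(hc), drop = FALSE]
  }
  structure(
    list(wavelet = wavelet, levels = levels, approx = approx,
         details = details, original_shape = dim(image)),
    class = "wavelet_decomposition"
  )
}

#' Inverse multilevel 2-D wavelet transform
#'
#' Reconstructs the image from a [dwt_decompose()] result and clips the
#' result to `[0, 1]`.
#'
#' @param decomp a `wavelet_decomposition`.
#' @return numeric matrix of the decomposition's `original_shape`.
#' @export
dwt_reconstruct <- function(decomp) {
  if (!inherits(decomp, "wavelet_decomposition"))
    stopf("decomp must be a wavelet_decomposition")
  approx <- decomp$approx
  for (j in rev(seq_len(decomp$levels))) {
    det <- decomp$details[[j]]
    hr <- nrow(approx)
    hc <- ncol(approx)
    if (!all(dim(det$h) == c(hr, hc)) || !all(dim(det$v) == c(hr, hc)) ||
        !all(dim(det$d) == c(hr, hc)))
      stopf("detail subband shapes at level %d are inconsistent with the approximation", j)
    Z <- rbind(cbind(approx, det$h), cbind(det$v, det$d))
    Ar <- dwt_analysis_matrix(nrow(Z), decomp$wavelet)
    Ac <- dwt_analysis_matrix(ncol(Z), decomp$wavelet)
    approx <- t(Ar) %*% Z %*% Ac
  }
  if (!all(dim(approx) == decomp$original_shape))
    stopf("reconstructed shape disagrees with original_shape")
  clip01(approx)
}

# top-k magnitude mask in row-major order; ties at the cutoff keep the
# lower row-major index
.retain_subband <- function(S, fraction) {
  vec <- as.vector(t(S))
  n <- length(vec)
  k <- ceiling(fraction * n)
  out <- numeric(n)
  if (k > 0L) {
    ord <- order(-abs(vec), seq_len(n), method = "radix")
    keep <- ord[seq_len(k)]
    out[keep] <- vec[keep]
  }
  matrix(out, nrow(S), ncol(S), byrow = TRUE)
}

#' Retain the most significant wavelet coefficients
#'
#' Within each detail subband independently, keeps the `ceiling(p * n)`
#' largest-magnitude coefficients and zeroes the rest; the approximation
#' subband is always kept intact. Ties at the cutoff are resolved in favour
#' of the lower row-major index.
#'
#' @param decomp a `wavelet_decomposition`.
#' @param fraction retention fraction `p` in `[0, 1]`.
#' @return a `wavelet_decomposition` with thresholded detail subbands.
#' @export
dwt_retain <- function(decomp, fraction) {
  if (!inherits(decomp, "wavelet_decomposition"))
    stopf("decomp must be a wavelet_decomposition")
  if (!is_scalar_number(fraction) || fraction < 0 || fraction > 1)
    stopf("fraction must be a number in [0, 1]")
  decomp$details <- lapply(decomp$details, function(det)
    lapply(det, .retain_subband, fraction = fraction))
  decomp
}

#' Total coefficient energy of a decomposition
#' @param decomp a `wavelet_decomposition`.
#' @return sum of squared coefficients over all subbands.
#' @export
dwt_energy <- function(decomp) {
  e <- sum(decomp$approx^2)
  for (det in decomp$details) e <- e + sum(det$h^2) + sum(det$v^2) + sum(det$d^2)
  e
}

#' Wavelet preprocessing of an image batch
#'
#' Per image: decompose, retain the top `fraction` of detail coefficients,
#' reconstruct. Order-preserving and deterministic.
#'
#' @param images list of numeric matrices in `[0, 1]`.
#' @inheritParams dwt_decompose
#' @param fraction retention fraction in `[0, 1]` (default 0.5).
#' @return list of preprocessed images.
#' @export
dwt_preprocess_batch <- function(images, wavelet = "haar", levels = 2L,
                                 fraction = 0.5) {
  if (length(images) == 0L) return(images)
  out <- vector("list", length(images))
  for (i in seq_along(images)) {
    out[[i]] <- tryCatch(
      dwt_reconstruct(dwt_retain(dwt_decompose(images[[i]], wavelet, levels), fraction)),
      error = function(e) stopf("image %d: %s", i, conditionMessage(e))
    )
  }
  out
}
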