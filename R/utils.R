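#' @keywords internal
"_PACKAGE"

`%||%` <- function(a, b) if (is.null(a)) b else a

vox_stop <- function(...) stop(..., call. = FALSE)

#' Apply a square matrix along one axis of an array
#'
#' Multiplies `mat` (n x n) along dimension `axis` of `x`, keeping all other
#' dimensions intact. Used for separable convolutions (Gaussian, box sums).
#' @noRd
apply_along_axis <- function(x, mat, axis) {
  d <- dim(x)
  stopifnot(nrow(mat) == d[axis], ncol(mat) == d[axis])
  perm <- c(axis, seq_along(d)[-axis])
  xp <- aperm(x, perm)
  m <- matrix(xp, nrow = d[axis])
  out <- mat %*% m
  dim(out) <- d[perm]
  aperm(out, order(perm))
}

#' Reflection-padded Gaussian convolution matrix for one axis
#' @noRd
gaussian_band_matrix <- function(n, sigma_vox) {
  if (sigma_vox <= 0) return(diag(n))
  r <- max(1L, as.integer(ceiling(4 * sigma_vox)))
  off <- -r:r
  w <- exp(-off^2 / (2 * sigma_vox^2))
  w <- w / sum(w)
  K <- matrix(0, n, n)
  for (i in seq_len(n)) {
    j <- i + off
    # mirror without edge repetition is ambiguous for tiny n; use symmetric
    # (half-sample) reflection: ... c b a | a b c ... which conserves mass
    j <- ifelse(j < 1L, 1L - j, j)
    j <- ifelse(j > n, 2L * n + 1L - j, j)
    # repeated reflection for very small n
    while (any(j < 1L | j > n)) {
      j <- ifelse(j < 1L, 1L - j, j)
      j <- ifelse(j > n, 2L * n + 1L - j, j)
    }
    for (t in seq_along(j)) K[j[t], i] <- K[j[t], i] + w[t]
  }
  t(K)
}

#' Windowed (box) sum matrix along one axis, truncated at the borders
#' @noRd
box_band_matrix <- function(n, r) {
  K <- matrix(0, n, n)
  for (i in seq_len(n)) {
    j <- max(1L, i - r):min(n, i + r)
    K[i, j] <- 1
  }
  K
}

# format a tag key for error messages
format_key <- function(subject, timepoint, sequence, type) {
  sprintf("(%s, %s, %s, %s)", subject, timepoint, sequence, type)
}

is_scalar_character <- function(x) is.character(x) && length(x) == 1L && !is.na(x)

#' Read a (possibly gzipped) file as a raw vector of its decompressed content
#'
#' gzip headers embed a modification time, so two logically identical
#' `.nii.gz` files can differ byte-wise; comparisons of pipeline outputs are
#' therefore made on the decompressed stream.
#' @param path file path
#' @return raw vector
#' @export
read_decompressed_bytes <- function(path) {
  con <- gzfile(path, "rb")
  on.exit(close(con))
  chunks <- list()
  repeat {
    b <- readBin(con, "raw", n = 1048576L)
    if (length(b) == 0L) break
    chunks[[length(chunks) + 1L]] <- b
  }
  do.call(c, chunks) %||% raw(0)
}

#' Compare two image files on decompressed content
#' @param a,b file paths
#' @return TRUE if the decompressed byte streams are identical
#' @export
same_image_bytes <- function(a, b) {
  identical(read_decompressed_bytes(a), read_decompressed_bytes(b))
}
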