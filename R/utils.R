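# Internal helpers shared across modules.

# Evaluate `expr` under a fixed RNG seed, restoring the caller's RNG state.
with_seed <- function(seed, expr) {
  if (!is.null(seed)) {
    old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      get(".Random.seed", envir = globalenv()) else NULL
    on.exit({
      if (is.null(old)) {
        if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
          rm(".Random.seed", envir = globalenv())
      } else assign(".Random.seed", old, envir = globalenv())
    })
    set.seed(as.integer(seed))
  }
  force(expr)
}

stopf <- function(...) stop(sprintf(...), call. = FALSE)
warnf <- function(...) warning(sprintf(...), call. = FALSE)

# Replicate-pad a matrix by `n` pixels on every side.
pad_replicate <- function(m, n = 1L) {
  nr <- nrow(m); nc <- ncol(m)
  ri <- c(rep(1L, n), seq_len(nr), rep(nr, n))
  ci <- c(rep(1L, n), seq_len(nc), rep(nc, n))
  m[ri, ci, drop = FALSE]
}

# Integer translation of a matrix: content moves by (+dx right, +dy down);
# exposed pixels are filled with `fill`.
translate_matrix <- function(m, dx, dy, fill) {
  nr <- nrow(m); nc <- ncol(m)
  out <- matrix(fill, nr, nc)
  ys <- seq_len(nr); xs <- seq_len(nc)
  ys_src <- ys - dy; xs_src <- xs - dx
  keep_y <- ys_src >= 1 & ys_src <= nr
  keep_x <- xs_src >= 1 & xs_src <= nc
  if (any(keep_y) && any(keep_x))
    out[ys[keep_y], xs[keep_x]] <- m[ys_src[keep_y], xs_src[keep_x]]
  out
}

# Bilinear translation by fractional (dx, dy), replicate boundary then fill.
translate_matrix_subpix <- function(m, dx, dy, fill) {
  i <- floor(dy); fy <- dy - i
  j <- floor(dx); fx <- dx - j
  if (fy == 0 && fx == 0) return(translate_matrix(m, j, i, fill))
  a <- translate_matrix(m, j,     i,     fill)
  b <- translate_matrix(m, j + 1, i,     fill)
  c <- translate_matrix(m, j,     i + 1, fill)
  d <- translate_matrix(m, j + 1, i + 1, fill)
  (1 - fy) * ((1 - fx) * a + fx * b) + fy * ((1 - fx) * c + fx * d)
}

# Separable Gaussian smoothing with replicate padding.
gaussian_blur <- function(m, sigma) {
  stopifnot(sigma > 0)
  r <- max(1L, as.integer(ceiling(3 * sigma)))
  k <- exp(-((-r:r)^2) / (2 * sigma^2))
  k <- k / sum(k)
  p <- pad_replicate(m, r)
  # convolve along rows (y), then columns (x)
  conv1 <- function(mat, along) {
    n <- if (along == 1) nrow(mat) else ncol(mat)
    acc <- NULL
    for (o in -r:r) {
      w <- k[o + r + 1]
      piece <- if (along == 1) mat[seq(1 + r + o, n - r + o), , drop = FALSE]
               else mat[, seq(1 + r + o, n - r + o), drop = FALSE]
      acc <- if (is.null(acc)) w * piece else acc + w * piece
    }
    acc
  }
  out <- conv1(p, 1)
  conv1(out, 2)
}

# Block-average downsampling by an integer factor (trailing rows/cols that
# do not fill a block are truncated).
block_downsample <- function(m, factor) {
  factor <- as.integer(factor)
  nr <- (nrow(m) %/% factor) * factor
  nc <- (ncol(m) %/% factor) * factor
  m <- m[seq_len(nr), seq_len(nc), drop = FALSE]
  # average over factor x factor blocks
  rowg <- rep(seq_len(nr %/% factor), each = factor)
  colg <- rep(seq_len(nc %/% factor), each = factor)
  t(rowsum(t(rowsum(m, rowg)), colg)) / factor^2
}

normalize01 <- function(m) {
  rng <- range(m, finite = TRUE)
  if (diff(rng) == 0) return(matrix(0, nrow(m), ncol(m)))
  (m - rng[1]) / diff(rng)
}

is_scalar_num <- function(x) is.numeric(x) && length(x) == 1L && is.finite(x)
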