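# Internal numerics shared across modules. Images are plain numeric matrices
# indexed [row, col] with values in [0, 1]; x = column, y = row, 1-based,
# continuous coordinates, pixel centers at integers.

.clamp01 <- function(x) pmin(pmax(x, 0), 1)

# Validate an image matrix; returns it invisibly.
.checkGray <- function(img, what = "image") {
  if (!is.matrix(img) || !is.numeric(img))
    stop(what, " must be a numeric matrix", call. = FALSE)
  if (anyNA(img) || any(!is.finite(img)))
    stop(what, " must contain only finite values", call. = FALSE)
  if (min(img) < 0 || max(img) > 1)
    stop(what, " values must lie in [0, 1]", call. = FALSE)
  invisible(img)
}

# Bilinear interpolation at continuous (x, y). Returns list(values, valid);
# values are NA where a point falls outside [1, W] x [1, H].
.bilinear <- function(img, x, y) {
  x <- as.numeric(x); y <- as.numeric(y)
  h <- nrow(img); w <- ncol(img)
  valid <- x >= 1 & x <= w & y >= 1 & y <= h
  valid[is.na(valid)] <- FALSE
  bad <- !valid
  x0 <- floor(x); y0 <- floor(y)
  x0[bad] <- 1; y0[bad] <- 1
  x0[x0 > w - 1] <- w - 1; y0[y0 > h - 1] <- h - 1
  fx <- x - x0; fy <- y - y0
  fx[bad] <- 0; fy[bad] <- 0
  base <- (x0 - 1) * h + y0        # column-major linear index of (y0, x0)
  i00 <- img[base]; i10 <- img[base + 1]
  i01 <- img[base + h]; i11 <- img[base + h + 1]
  v <- (1 - fy) * ((1 - fx) * i00 + fx * i01) + fy * ((1 - fx) * i10 + fx * i11)
  v[bad] <- NA_real_
  list(values = v, valid = valid)
}

# Run expr with a local RNG state seeded by `seed`; global RNG untouched.
.withSeed <- function(seed, expr) {
  has <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (has) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(as.integer(seed))
  expr
}

# 1-D Gaussian kernel, sigma in samples, truncated at 3 sigma, normalized.
.gaussKernel <- function(sigma) {
  if (sigma <= 0) return(1)
  rad <- max(1L, ceiling(3 * sigma))
  k <- exp(-((-rad:rad)^2) / (2 * sigma^2))
  k / sum(k)
}

# Convolve a vector with a symmetric kernel using reflect padding.
.convReflect <- function(v, k) {
  m <- length(k)
  if (m == 1L) return(v)
  rad <- (m - 1L) %/% 2L
  n <- length(v)
  idx <- c(rev(seq_len(min(rad, n))), seq_len(n),
           n + 1L - rev(seq_len(min(rad, n))))
  # if the vector is shorter than the pad, recycle reflections
  while (length(idx) < n + 2L * rad)
    idx <- c(idx[1L], idx, idx[length(idx)])
  padded <- v[idx]
  out <- stats::filter(padded, k, sides = 2)
  as.numeric(out[(rad + 1L):(rad + n)])
}

# Separable Gaussian blur of an image matrix, reflect padding.
.gaussBlur <- function(img, sigma) {
  if (sigma <= 0) return(img)
  k <- .gaussKernel(sigma)
  img <- apply(img, 2L, .convReflect, k = k)
  t(apply(img, 1L, .convReflect, k = k))
}

# Deep-merge two named lists (b overrides a).
.mergeLists <- function(a, b) {
  if (is.null(b)) return(a)
  for (nm in names(b)) {
    if (is.list(a[[nm]]) && is.list(b[[nm]])) a[[nm]] <- .mergeLists(a[[nm]], b[[nm]])
    else a[[nm]] <- b[[nm]]
  }
  a
}
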