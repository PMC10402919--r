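# Internal image-processing helpers shared across modules. Matrices are
# indexed (row, col); every kernel used here is passed explicitly so the
# EBImage x/y convention is irrelevant for symmetric operations.

# Reflect-pad a matrix by k pixels on every side (symmetric, edge included).
reflect_pad <- function(m, k) {
  nr <- nrow(m); nc <- ncol(m)
  if (k >= nr || k >= nc) {
    stop("padding width ", k, " too large for a ", nr, "x", nc, " image")
  }
  ri <- c(k:1, 1:nr, nr:(nr - k + 1))
  ci <- c(k:1, 1:nc, nc:(nc - k + 1))
  m[ri, ci, drop = FALSE]
}

# 2D convolution with reflective boundary handling via explicit padding.
conv2_reflect <- function(m, kern) {
  k <- max(dim(kern)) %/% 2
  if (k == 0) return(m * kern[1, 1])
  p <- reflect_pad(m, k)
  out <- EBImage::filter2(p, kern, boundary = "circular")
  out[(k + 1):(k + nrow(m)), (k + 1):(k + ncol(m)), drop = FALSE]
}

gaussian_kernel <- function(sigma) {
  h <- max(1L, as.integer(ceiling(3 * sigma)))
  x <- (-h):h
  g <- exp(-x^2 / (2 * sigma^2))
  g <- g / sum(g)
  outer(g, g)
}

gaussian_blur <- function(m, sigma) conv2_reflect(m, gaussian_kernel(sigma))

LAPLACIAN_KERNEL <- matrix(c(0, 1, 0, 1, -4, 1, 0, 1, 0), 3, 3)

# Central-difference gradients along rows and columns.
grad_row <- function(m) conv2_reflect(m, matrix(c(-0.5, 0, 0.5), 3, 1))
grad_col <- function(m) conv2_reflect(m, matrix(c(-0.5, 0, 0.5), 1, 3))

# 4-connected components of a logical matrix; 0 = background.
label_components <- function(mask) {
  storage.mode(mask) <- "double"
  EBImage::bwlabel(mask)
}

disc_brush <- function(r) EBImage::makeBrush(2L * as.integer(r) + 1L, shape = "disc")

# Drop connected components smaller than min_area pixels from a logical mask.
remove_small_objects <- function(mask, min_area) {
  if (!any(mask) || min_area <= 1) return(mask)
  lab <- label_components(mask)
  sizes <- tabulate(lab[lab > 0])
  keep <- which(sizes >= min_area)
  matrix(lab %in% keep, nrow(mask), ncol(mask))
}

# Otsu threshold: exhaustive maximisation of between-class variance over a
# histogram of the (integer-valued or continuous) intensities.
otsu_threshold <- function(values, n_bins = 256L) {
  v <- as.numeric(values)
  v <- v[is.finite(v)]
  rng <- range(v)
  if (diff(rng) == 0) return(rng[1])
  breaks <- seq(rng[1], rng[2], length.out = n_bins + 1L)
  h <- hist(v, breaks = breaks, plot = FALSE)
  p <- h$counts / sum(h$counts)
  mids <- h$mids
  omega <- cumsum(p)
  mu <- cumsum(p * mids)
  mu_t <- mu[length(mu)]
  # between-class variance for a cut after bin k
  bcv <- (mu_t * omega - mu)^2 / (omega * (1 - omega))
  bcv[!is.finite(bcv)] <- -Inf
  k <- which.max(bcv[-length(bcv)])
  # threshold between bin k and k+1
  breaks[k + 1L]
}

# Strict 8-neighbour local maxima of a matrix (border pixels excluded).
local_maxima <- function(m) {
  nr <- nrow(m); nc <- ncol(m)
  if (nr < 3 || nc < 3) return(matrix(FALSE, nr, nc))
  p <- matrix(-Inf, nr + 2, nc + 2)
  p[2:(nr + 1), 2:(nc + 1)] <- m
  ctr <- p[2:(nr + 1), 2:(nc + 1)]
  ok <- matrix(TRUE, nr, nc)
  for (dr in -1:1) for (dc in -1:1) {
    if (dr == 0 && dc == 0) next
    ok <- ok & (ctr > p[(2 + dr):(nr + 1 + dr), (2 + dc):(nc + 1 + dc)])
  }
  ok
}

# Distance from each pixel centre (1-based row/col) to a point.
pixel_distance <- function(shape, center) {
  rr <- matrix(seq_len(shape[1]), shape[1], shape[2])
  cc <- matrix(seq_len(shape[2]), shape[1], shape[2], byrow = TRUE)
  sqrt((rr - center[1])^2 + (cc - center[2])^2)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

qc_add <- function(flags, flag) unique(c(flags, flag))
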