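# Internal helpers shared across the pipeline.

`%||%` <- function(a, b) if (is.null(a)) b else a

stopifnot_scalar_num <- function(x, name, positive = FALSE) {
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x))
    stop(sprintf("'%s' must be a single finite number", name), call. = FALSE)
  if (positive && x <= 0)
    stop(sprintf("'%s' must be > 0", name), call. = FALSE)
  invisible(x)
}

# Fold an index vector into 1..n by mirror reflection about the edges
# (1 -> 1, 0 -> 2, -1 -> 3, n+1 -> n-1, ...). Handles kernels wider than
# the image by repeated folding.
reflect_index <- function(i, n) {
  if (n == 1L) return(rep(1L, length(i)))
  period <- 2L * (n - 1L)
  j <- (i - 1L) %% period
  j <- ifelse(j >= n, period - j, j)
  as.integer(j + 1L)
}

# Row/column blur operator with reflective padding, as a dense n x n matrix.
blur_operator <- function(n, sigma) {
  r <- max(1L, as.integer(ceiling(3.5 * sigma)))
  k <- stats::dnorm(seq.int(-r, r), sd = sigma)
  k <- k / sum(k)
  W <- matrix(0, n, n)
  for (i in seq_len(n)) {
    src <- reflect_index(i + seq.int(-r, r), n)
    for (m in seq_along(src)) W[i, src[m]] <- W[i, src[m]] + k[m]
  }
  W
}

# Separable Gaussian blur with reflective boundary handling.
gaussian_blur <- function(x, sigma) {
  stopifnot_scalar_num(sigma, "sigma", positive = TRUE)
  if (!is.matrix(x)) stop("'x' must be a matrix")
  Wr <- blur_operator(nrow(x), sigma)
  Wc <- if (ncol(x) == nrow(x)) Wr else blur_operator(ncol(x), sigma)
  Wr %*% x %*% t(Wc)
}

# 8-connected labeling of foreground pixels of a logical matrix.
# Returns an integer matrix of labels (0 = background), labels assigned in
# raster order. EBImage::bwlabel is 4-connected, hence this implementation.
label_components8 <- function(mask) {
  nr <- nrow(mask); nc <- ncol(mask)
  idx <- which(mask)
  lab <- matrix(0L, nr, nc)
  if (length(idx) == 0L) return(lab)
  # union-find over foreground pixels, keyed by linear index
  pos <- integer(nr * nc)          # linear index -> rank in idx (0 = bg)
  pos[idx] <- seq_along(idx)
  parent <- seq_along(idx)
  find <- function(i) {
    while (parent[i] != i) {
      parent[i] <<- parent[parent[i]]
      i <- parent[i]
    }
    i
  }
  row_i <- ((idx - 1L) %% nr) + 1L
  col_i <- ((idx - 1L) %/% nr) + 1L
  # neighbors already scanned in column-major order: up, and the three in
  # the previous column (covers all 8 neighbors symmetrically)
  offs <- list(c(-1L, 0L), c(-1L, -1L), c(0L, -1L), c(1L, -1L))
  for (k in seq_along(idx)) {
    r <- row_i[k]; cc <- col_i[k]
    for (o in offs) {
      rr <- r + o[1L]; c2 <- cc + o[2L]
      if (rr < 1L || rr > nr || c2 < 1L) next
      nb <- pos[(c2 - 1L) * nr + rr]
      if (nb > 0L) {
        a <- find(k); b <- find(nb)
        if (a != b) parent[max(a, b)] <- min(a, b)
      }
    }
  }
  roots <- vapply(seq_along(idx), find, integer(1))
  # labels in column-major order of first appearance (idx is sorted)
  lab[idx] <- match(roots, unique(roots))
  lab
}

# 3x3 square (box) morphological dilation of a logical matrix.
dilate3x3 <- function(mask) {
  m <- EBImage::dilate(mask * 1L, EBImage::makeBrush(3L, shape = "box"))
  matrix(as.vector(m) > 0, nrow(mask), ncol(mask))
}

# Euclidean distance of each pixel to the nearest background (FALSE) pixel.
# Background pixels get 0; a foreground pixel adjacent to background gets 1.
distance_to_background <- function(mask) {
  d <- EBImage::distmap(mask * 1L, metric = "euclidean")
  matrix(as.vector(d), nrow(mask), ncol(mask))
}

# ceiling() with protection against floating-point fuzz (3.15/0.09 -> 35).
ceiling_safe <- function(x) as.integer(ceiling(x - 1e-9))

# Save/restore the global RNG state around seeded generation.
with_seed <- function(seed, code) {
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(seed)
  force(code)
}
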