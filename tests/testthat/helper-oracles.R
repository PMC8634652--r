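# Independent oracles used across the suite. These deliberately use naive,
# direct formulations (explicit loops, flood fill, exhaustive search) so they
# share no code path with the implementation they check.

# Entropy-sum threshold by explicit per-cut evaluation. `entropy` computes the
# class entropy from the raw class counts; returns the first foreground bin.
entropy_cut_oracle <- function(counts, entropy) {
  n <- length(counts)
  best_t <- NA_integer_
  best_val <- -Inf
  for (t in 2:n) {
    bg <- counts[1:(t - 1)]
    fg <- counts[t:n]
    if (sum(bg) == 0 || sum(fg) == 0) next
    val <- entropy(bg) + entropy(fg)
    if (val > best_val + 1e-12) {
      best_val <- val
      best_t <- t
    }
  }
  best_t
}

renyi_oracle <- function(counts, alpha) {
  entropy_cut_oracle(counts, function(cls) {
    p <- cls[cls > 0] / sum(cls)
    log(sum(p^alpha)) / (1 - alpha)
  })
}

# Shannon (Kapur) maximum-entropy threshold
kapur_oracle <- function(counts) {
  entropy_cut_oracle(counts, function(cls) {
    p <- cls[cls > 0] / sum(cls)
    -sum(p * log(p))
  })
}

# Direct-convolution Gaussian blur with mirror padding (small images only)
blur_oracle <- function(x, sigma) {
  r <- max(1L, as.integer(ceiling(3.5 * sigma)))
  k <- dnorm(-r:r, sd = sigma)
  k <- k / sum(k)
  reflect1 <- function(i, n) {
    period <- 2 * (n - 1)
    j <- (i - 1) %% period
    ifelse(j >= n, period - j, j) + 1
  }
  nr <- nrow(x); nc <- ncol(x)
  out <- matrix(0, nr, nc)
  for (i in seq_len(nr)) for (j in seq_len(nc)) {
    acc <- 0
    for (a in -r:r) for (b in -r:r) {
      acc <- acc + k[a + r + 1] * k[b + r + 1] *
        x[reflect1(i + a, nr), reflect1(j + b, nc)]
    }
    out[i, j] <- acc
  }
  out
}

# Flood-fill 8-connected labeling (queue-based)
flood_fill_label <- function(mask) {
  nr <- nrow(mask); nc <- ncol(mask)
  lab <- matrix(0L, nr, nc)
  cur <- 0L
  for (j in seq_len(nc)) for (i in seq_len(nr)) {
    if (!mask[i, j] || lab[i, j] > 0L) next
    cur <- cur + 1L
    queue <- list(c(i, j))
    lab[i, j] <- cur
    while (length(queue)) {
      p <- queue[[1]]; queue <- queue[-1]
      for (di in -1:1) for (dj in -1:1) {
        a <- p[1] + di; b <- p[2] + dj
        if (a < 1 || a > nr || b < 1 || b > nc) next
        if (mask[a, b] && lab[a, b] == 0L) {
          lab[a, b] <- cur
          queue[[length(queue) + 1L]] <- c(a, b)
        }
      }
    }
  }
  lab
}

# Exhaustive minimum box cover for small pixel sets. Boxes are canonical
# (top/left edge on a pixel, clamped); depth-limited branch and bound.
min_cover_oracle <- function(pixels, fov, nx, ny, max_boxes = nrow(pixels)) {
  px <- pixels[, 1]; py <- pixels[, 2]
  n <- nrow(pixels)
  cand_x <- sort(unique(pmin(pmax(px, 0), nx - fov)))
  cand_y <- sort(unique(pmin(pmax(py, 0), ny - fov)))
  cand <- expand.grid(x0 = cand_x, y0 = cand_y)
  cover_sets <- lapply(seq_len(nrow(cand)), function(i) {
    which(px >= cand$x0[i] & px < cand$x0[i] + fov &
          py >= cand$y0[i] & py < cand$y0[i] + fov)
  })
  # dedupe identical coverage patterns
  keys <- vapply(cover_sets, function(s) paste(s, collapse = ","),
                 character(1))
  keep <- !duplicated(keys) & vapply(cover_sets, length, integer(1)) > 0
  cover_sets <- cover_sets[keep]
  search <- function(uncovered, depth) {
    if (length(uncovered) == 0L) return(0L)
    if (depth == 0L) return(NA_integer_)
    target <- uncovered[1]
    best <- NA_integer_
    for (s in cover_sets) {
      if (!(target %in% s)) next
      rest <- setdiff(uncovered, s)
      sub <- search(rest, depth - 1L)
      if (!is.na(sub) && (is.na(best) || sub + 1L < best)) best <- sub + 1L
    }
    best
  }
  for (k in seq_len(max_boxes)) {
    res <- search(seq_len(n), k)
    if (!is.na(res)) return(res)
  }
  stop("oracle failed to find a cover")  # one box per pixel always works
}

box_cover_complete <- function(boxes, pixels) {
  all(vapply(seq_len(nrow(pixels)), function(j) {
    any(pixels[j, 1] >= boxes$x0 & pixels[j, 1] < boxes$x1 &
        pixels[j, 2] >= boxes$y0 & pixels[j, 2] < boxes$y1)
  }, logical(1)))
}
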