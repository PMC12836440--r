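# Independent brute-force oracles: deliberately naive nested-loop
# definitions against which the vectorized implementations are checked.

# Direct 2-D Gaussian convolution with edge replication (no separability).
oracle_gaussian_blur <- function(img, sigma) {
  r <- max(1L, as.integer(ceiling(3 * sigma)))
  k1 <- exp(-(seq(-r, r))^2 / (2 * sigma^2))
  kern <- outer(k1, k1); kern <- kern / sum(kern)
  n <- nrow(img); m <- ncol(img)
  out <- matrix(0, n, m)
  for (i in seq_len(n)) for (j in seq_len(m)) {
    acc <- 0
    for (di in -r:r) for (dj in -r:r) {
      ii <- min(max(i + di, 1L), n); jj <- min(max(j + dj, 1L), m)
      acc <- acc + kern[di + r + 1L, dj + r + 1L] * img[ii, jj]
    }
    out[i, j] <- acc
  }
  matrix(as.integer(pmin(pmax(round(out), 0), 255)), n, m)
}

# Set-definition erosion: pixel kept iff the whole neighborhood (padded
# with `pad`) is foreground.
oracle_erode <- function(bin, radius, pad = FALSE) {
  n <- nrow(bin); m <- ncol(bin)
  out <- matrix(FALSE, n, m)
  for (i in seq_len(n)) for (j in seq_len(m)) {
    keep <- TRUE
    for (di in -radius:radius) for (dj in -radius:radius) {
      ii <- i + di; jj <- j + dj
      v <- if (ii < 1L || ii > n || jj < 1L || jj > m) pad else bin[ii, jj]
      if (!v) { keep <- FALSE; break }
    }
    out[i, j] <- keep
  }
  out
}

# Set-union dilation.
oracle_dilate <- function(bin, radius, pad = FALSE) {
  n <- nrow(bin); m <- ncol(bin)
  out <- matrix(FALSE, n, m)
  for (i in seq_len(n)) for (j in seq_len(m)) {
    hit <- FALSE
    for (di in -radius:radius) for (dj in -radius:radius) {
      ii <- i + di; jj <- j + dj
      v <- if (ii < 1L || ii > n || jj < 1L || jj > m) pad else bin[ii, jj]
      if (v) { hit <- TRUE; break }
    }
    out[i, j] <- hit
  }
  out
}

# Exhaustive cell scan for box counting.
oracle_count_boxes <- function(bin, size) {
  n <- nrow(bin); m <- ncol(bin)
  count <- 0L
  for (r0 in seq(1L, n, by = size)) for (c0 in seq(1L, m, by = size)) {
    cell <- bin[r0:min(r0 + size - 1L, n), c0:min(c0 + size - 1L, m),
                drop = FALSE]
    if (any(cell)) count <- count + 1L
  }
  count
}

# 8-connected foreground component count via flood fill.
oracle_components <- function(bin) {
  n <- nrow(bin); m <- ncol(bin)
  seen <- matrix(FALSE, n, m)
  comps <- 0L
  for (i in seq_len(n)) for (j in seq_len(m)) {
    if (!bin[i, j] || seen[i, j]) next
    comps <- comps + 1L
    stack <- list(c(i, j)); seen[i, j] <- TRUE
    while (length(stack) > 0L) {
      p <- stack[[length(stack)]]; stack[[length(stack)]] <- NULL
      for (di in -1:1) for (dj in -1:1) {
        ii <- p[1L] + di; jj <- p[2L] + dj
        if (ii >= 1L && ii <= n && jj >= 1L && jj <= m &&
            bin[ii, jj] && !seen[ii, jj]) {
          seen[ii, jj] <- TRUE
          stack[[length(stack) + 1L]] <- c(ii, jj)
        }
      }
    }
  }
  comps
}

random_binary <- function(n, m, p = 0.5) {
  matrix(stats::runif(n * m) < p, n, m)
}

random_gray <- function(n, m) {
  matrix(sample(0:255, n * m, replace = TRUE), n, m)
}
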