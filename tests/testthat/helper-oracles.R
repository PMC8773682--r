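# Independent oracles used to cross-check the implementation.

# 8-connected component labeling by breadth-first flood fill.
flood_fill_label <- function(binary) {
  nr <- nrow(binary); nc <- ncol(binary)
  labels <- matrix(0L, nr, nc)
  nxt <- 0L
  offs <- cbind(
    dr = c(-1L, -1L, -1L, 0L, 0L, 1L, 1L, 1L),
    dc = c(-1L, 0L, 1L, -1L, 1L, -1L, 0L, 1L)
  )
  for (start in which(binary)) {
    if (labels[start] > 0L) next
    nxt <- nxt + 1L
    queue <- start
    labels[start] <- nxt
    while (length(queue)) {
      p <- queue[1]; queue <- queue[-1]
      pr <- ((p - 1L) %% nr) + 1L
      pc <- ((p - 1L) %/% nr) + 1L
      for (k in 1:8) {
        r2 <- pr + offs[k, 1]; c2 <- pc + offs[k, 2]
        if (r2 < 1L || r2 > nr || c2 < 1L || c2 > nc) next
        q <- (c2 - 1L) * nr + r2
        if (binary[q] && labels[q] == 0L) {
          labels[q] <- nxt
          queue <- c(queue, q)
        }
      }
    }
  }
  labels
}

# Are two label matrices the same partition of the foreground (up to a
# permutation of label ids)?
same_partition <- function(a, b) {
  if (!all((a > 0) == (b > 0))) return(FALSE)
  fg <- a > 0
  key <- paste(a[fg], b[fg])
  pairs <- unique(key)
  # bijection: every a-label maps to exactly one b-label and vice versa
  av <- vapply(strsplit(pairs, " "), `[`, character(1), 1)
  bv <- vapply(strsplit(pairs, " "), `[`, character(1), 2)
  !anyDuplicated(av) && !anyDuplicated(bv)
}

# Brute-force Otsu over 256 candidate thresholds spanning [0, maxv]:
# maximize between-class variance of the two sides.
brute_otsu <- function(pixels, maxv) {
  breaks <- seq(0, maxv, length.out = 257)
  h <- hist(pixels, breaks = breaks, plot = FALSE)
  counts <- h$counts
  mids <- h$mids
  best_t <- NA; best_v <- -Inf
  for (k in 1:255) {
    w0 <- sum(counts[1:k]); w1 <- sum(counts) - w0
    if (w0 == 0 || w1 == 0) next
    m0 <- sum(counts[1:k] * mids[1:k]) / w0
    m1 <- sum(counts[(k + 1):256] * mids[(k + 1):256]) / w1
    v <- w0 * w1 * (m0 - m1)^2
    if (v > best_v) { best_v <- v; best_t <- breaks[k + 1] }
  }
  best_t
}

# Brute-force 1-D between-class-variance split over a numeric sample:
# try every split of the sorted values with explicit loops.
brute_split_1d <- function(x) {
  x <- sort(x)
  n <- length(x)
  best_v <- -Inf; best_t <- NA
  for (k in 1:(n - 1)) {
    g0 <- x[1:k]; g1 <- x[(k + 1):n]
    v <- k * (n - k) * (mean(g0) - mean(g1))^2
    if (v > best_v) { best_v <- v; best_t <- (x[k] + x[k + 1]) / 2 }
  }
  best_t
}

# Brute-force grayscale morphological opening (erode then dilate) with a
# disc, looping over pixels; for small fixtures only.
brute_opening <- function(m, radius) {
  nr <- nrow(m); nc <- ncol(m)
  offs <- expand.grid(dr = -radius:radius, dc = -radius:radius)
  offs <- offs[offs$dr^2 + offs$dc^2 <= radius^2, ]
  ero <- matrix(0, nr, nc)
  for (r in 1:nr) for (c in 1:nc) {
    rr <- r + offs$dr; cc <- c + offs$dc
    ok <- rr >= 1 & rr <= nr & cc >= 1 & cc <= nc
    ero[r, c] <- min(m[cbind(rr[ok], cc[ok])])
  }
  dil <- matrix(0, nr, nc)
  for (r in 1:nr) for (c in 1:nc) {
    rr <- r + offs$dr; cc <- c + offs$dc
    ok <- rr >= 1 & rr <= nr & cc >= 1 & cc <= nc
    dil[r, c] <- max(ero[cbind(rr[ok], cc[ok])])
  }
  dil
}

# Brute-force optimal one-to-one frame assignment minimizing total
# distance (enumerates all detection permutations; tiny inputs only).
brute_assignment <- function(d, max_dist) {
  nt <- nrow(d); nd <- ncol(d)
  perms <- function(v) {
    if (length(v) <= 1) return(list(v))
    out <- list()
    for (i in seq_along(v)) {
      for (p in perms(v[-i])) out[[length(out) + 1]] <- c(v[i], p)
    }
    out
  }
  k <- min(nt, nd)
  best <- NULL; best_cost <- Inf
  for (rows in utils::combn(nt, k, simplify = FALSE)) {
    for (cols in perms(seq_len(nd))) {
      cols <- cols[seq_len(k)]
      dd <- d[cbind(rows, cols)]
      if (any(dd > max_dist)) next
      cost <- sum(dd)
      if (cost < best_cost) { best_cost <- cost; best <- cbind(rows, cols) }
    }
  }
  best
}
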