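# Fixtures are built in code; nothing is read from disk.

# Minimal valid packet log: constant counts per channel.
tiny_packet_log <- function(n = 3L, level = 512L, node = 2L) {
  packet_log(node, seq = 0:(n - 1L), t = (0:(n - 1L)) / 8,
             counts = matrix(level, n, 6L * 128L))
}

# Hand-set 2-2-2 miniature network (sizes are configurable for tests).
mini_net <- function() {
  m <- new_bpnn(n = 2L, l = 2L, m = 2L, seed = 1L)
  m$W1 <- matrix(c(0.1, 0.3, 0.2, -0.4), 2, 2)  # column-major
  m$b1 <- c(0.05, -0.05)
  m$W2 <- matrix(c(1, 0.5, -1, 0.25), 2, 2)
  m$b2 <- c(0, 0.1)
  m$scaling <- NULL
  m
}

# Bare spectrum_histogram from explicit bins.
raw_spectrum <- function(mag, rate = 8, n = NULL) {
  if (is.null(n)) n <- 2L * (length(mag) - 1L)
  sp <- data.frame(freq = (seq_along(mag) - 1L) * rate / n, mag = mag)
  attr(sp, "rate") <- rate
  attr(sp, "n") <- n
  class(sp) <- c("spectrum_histogram", "data.frame")
  sp
}

# Decreasing staircase whose steps sit exactly on the 0.115 + 0.1k grid;
# the aligned envelope hugs it (dE ~ 0), misaligned grids bridge the steps.
staircase_spectrum <- function(n, rate = 8) {
  u <- (0:(floor(n / 2))) * rate / n / (rate / 2)
  step <- pmax(ceiling((u - 0.115) / 0.1), 0)
  raw_spectrum(pmax(2 - 0.18 * step, 0.2), rate = rate, n = n)
}

# Synthetic sample stream with prescribed acceleration columns.
samples_from_acc <- function(acc, rate = 8) {
  n <- nrow(acc)
  out <- data.frame(t = (0:(n - 1L)) / rate,
                    ax = acc[, 1], ay = acc[, 2], az = acc[, 3],
                    wx = 0, wy = 0, wz = 0, node_id = 2L)
  class(out) <- c("calibrated_samples", "data.frame")
  out
}

# Independent proper-crossing predicate via orientation signs (strict).
oracle_segments_cross <- function(p1, p2, p3, p4) {
  ccw <- function(a, b, c)
    sign((b[1] - a[1]) * (c[2] - a[2]) - (b[2] - a[2]) * (c[1] - a[1]))
  d1 <- ccw(p3, p4, p1); d2 <- ccw(p3, p4, p2)
  d3 <- ccw(p1, p2, p3); d4 <- ccw(p1, p2, p4)
  d1 != 0 && d2 != 0 && d3 != 0 && d4 != 0 && d1 != d2 && d3 != d4
}

# Vectorized strict point-in-triangle membership (barycentric signs).
oracle_in_triangle <- function(px, py, tri) {
  s <- function(ax, ay, bx, by) (bx - ax) * (py - ay) - (by - ay) * (px - ax)
  d1 <- s(tri[1, 1], tri[1, 2], tri[2, 1], tri[2, 2])
  d2 <- s(tri[2, 1], tri[2, 2], tri[3, 1], tri[3, 2])
  d3 <- s(tri[3, 1], tri[3, 2], tri[1, 1], tri[1, 2])
  (d1 > 0 & d2 > 0 & d3 > 0) | (d1 < 0 & d2 < 0 & d3 < 0)
}

# Monte-Carlo overlap oracle: do any sampled points lie strictly inside
# both triangles?
oracle_triangles_overlap <- function(a, b, n_grid = 150L) {
  lo <- pmax(apply(a, 2, min), apply(b, 2, min))
  hi <- pmin(apply(a, 2, max), apply(b, 2, max))
  if (any(lo >= hi)) return(FALSE)           # bounding boxes disjoint
  gx <- seq(lo[1], hi[1], length.out = n_grid)
  gy <- seq(lo[2], hi[2], length.out = n_grid)
  px <- rep(gx, times = n_grid); py <- rep(gy, each = n_grid)
  any(oracle_in_triangle(px, py, a) & oracle_in_triangle(px, py, b))
}

random_triangle <- function(min_area = 0.05) {
  repeat {
    v <- matrix(runif(6, 0, 4), 3, 2)
    area <- abs((v[2, 1] - v[1, 1]) * (v[3, 2] - v[1, 2]) -
                  (v[3, 1] - v[1, 1]) * (v[2, 2] - v[1, 2])) / 2
    if (area > min_area) return(v)
  }
}
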