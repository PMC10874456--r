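# Independent brute-force oracles for the fractal and thresholding code.
# These deliberately use naive double loops / direct definitions so they
# share no code path with the implementations they check.

# Count occupied eps x eps boxes by scanning every box of the lattice
# anchored at (-dx, -dy) and testing its pixel sub-block directly.
brute_box_count <- function(p, eps, origin = c(0, 0)) {
  h <- nrow(p); w <- ncol(p)
  dx <- origin[1]; dy <- origin[2]
  n <- 0L
  for (bx in 0:((w - 1 + dx) %/% eps)) {
    for (by in 0:((h - 1 + dy) %/% eps)) {
      # pixel x-range (0-based) of box bx on the shifted lattice
      xs <- (bx * eps - dx):((bx + 1) * eps - 1 - dx)
      ys <- (by * eps - dy):((by + 1) * eps - 1 - dy)
      xs <- xs[xs >= 0 & xs < w]
      ys <- ys[ys >= 0 & ys < h]
      if (length(xs) && length(ys) && any(p[ys + 1, xs + 1])) n <- n + 1L
    }
  }
  n
}

# Foreground mass of every fully-inside eps x eps window at the stride,
# by direct submatrix sums.
brute_window_masses <- function(p, eps, stride = 1) {
  h <- nrow(p); w <- ncol(p)
  out <- numeric(0)
  for (i in seq(1, h - eps + 1, by = stride)) {
    for (j in seq(1, w - eps + 1, by = stride)) {
      out <- c(out, sum(p[i:(i + eps - 1), j:(j + eps - 1)]))
    }
  }
  out
}

# Moment-preserving threshold by exhaustive search: solve the moment
# equations for the background fraction p0 via the quadratic's roots
# (found numerically with polyroot), then scan all 255 candidate cuts for
# the one whose cumulative fraction is closest to p0.
brute_moments_threshold <- function(img) {
  v <- floor(as.vector(img) + 0.5)
  h <- tabulate(v + 1L, nbins = 256L) / length(v)
  z <- 0:255
  m1 <- sum(h * z); m2 <- sum(h * z^2); m3 <- sum(h * z^3)
  cd <- m2 - m1^2
  roots <- sort(Re(polyroot(c((-m2^2 + m1 * m3) / cd, (m1 * m2 - m3) / cd, 1))))
  p0 <- (roots[2] - m1) / (roots[2] - roots[1])
  p0 <- min(max(p0, 0), 1)
  cum <- cumsum(h)
  best_t <- 0L; best_gap <- Inf
  for (t in 0:254) {
    gap <- abs(cum[t + 1] - p0)
    if (gap < best_gap) { best_gap <- gap; best_t <- t }
  }
  best_t
}

jaccard <- function(a, b) sum(a & b) / sum(a | b)

random_pattern <- function(h, w, density) matrix(runif(h * w) < density, h, w)
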