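#' Analytic binary fixtures
#'
#' Patterns with known box-counting behavior, used as oracles for the
#' fractal estimators: a filled square (dimension 2), a one-pixel straight
#' line (dimension 1) and the Sierpinski carpet (dimension
#' `log(8)/log(3) ~ 1.8928`, with exact integer box counts `8^(order - j)`
#' at sizes `3^j` on the origin-anchored lattice).
#'
#' @param size Side length in pixels.
#' @return Logical matrix.
#' @export
filled_square <- function(size) {
  matrix(TRUE, size, size)
}

#' @rdname filled_square
#' @param length Line length in pixels (default `size`).
#' @export
straight_line <- function(size, length = size) {
  p <- matrix(FALSE, size, size)
  row <- max(1L, size %/% 2L)
  p[row, seq_len(min(length, size))] <- TRUE
  p
}

#' @rdname filled_square
#' @param order Carpet recursion depth; the side is `3^order`.
#' @export
sierpinski_carpet <- function(order) {
  stopifnot(order >= 0)
  p <- matrix(TRUE, 1, 1)
  for (k in seq_len(order)) {
    s <- nrow(p)
    q <- matrix(FALSE, 3 * s, 3 * s)
    for (bi in 0:2) for (bj in 0:2) {
      if (bi == 1 && bj == 1) next
      q[bi * s + seq_len(s), bj * s + seq_len(s)] <- p
    }
    p <- q
  }
  p
}

# von Mises sampler (Best & Fisher rejection algorithm); used for fiber
# orientations. kappa = 0 falls back to the uniform circle.
rvonmises <- function(n, mu, kappa) {
  if (kappa < 1e-8) return((runif(n, -pi, pi) + mu))
  a <- 1 + sqrt(1 + 4 * kappa^2)
  b <- (a - sqrt(2 * a)) / (2 * kappa)
  r <- (1 + b^2) / (2 * b)
  out <- numeric(n)
  i <- 1L
  while (i <= n) {
    u <- runif(3)
    z <- cos(pi * u[1])
    f <- (1 + r * z) / (r + z)
    cc <- kappa * (r - f)
    if (u[2] < cc * (2 - cc) || log(cc) - log(u[2]) + 1 - cc >= 0) {
      out[i] <- mu + sign(u[3] - 0.5) * acos(f)
      i <- i + 1L
    }
  }
  out
}

#' Synthetic fiber-network pattern
#'
#' Rasterizes straight fiber segments at a given thickness, adding fibers
#' until the foreground fraction first reaches the target. Orientations
#' are axial: the doubled angle follows a von Mises distribution with
#' concentration `kappa`, so `kappa = 0` gives an isotropic meshwork and
#' large `kappa` gives parallel bundles around `mean_angle` — the two ends
#' of the fiber-alignment spectrum seen in fibrotic remodeling.
#' Deterministic per seed.
#'
#' @param size Image side in pixels.
#' @param target_fraction Foreground fraction at which fiber addition
#'   stops, in `(0, 1)`.
#' @param thickness Fiber thickness in pixels.
#' @param kappa Alignment concentration of the doubled angle, `>= 0`.
#' @param mean_angle Mean fiber orientation in radians.
#' @param length_range Fiber length range as fractions of `size`.
#' @param max_fibers Attempt budget; exceeded means the target is
#'   unreachable and is an error.
#' @param seed Integer seed.
#' @return Logical matrix with attributes `orientations` (radians, one per
#'   fiber) and `realized_fraction`.
#' @export
fiber_network <- function(size, target_fraction = 0.3, thickness = 3,
                          kappa = 0, mean_angle = 0,
                          length_range = c(0.2, 0.5),
                          max_fibers = 20000, seed = 1) {
  stopifnot(size >= 16, target_fraction > 0, target_fraction < 1,
            thickness >= 1, kappa >= 0)
  if (thickness > size / 2) {
    stop("fiber_network(): fiber thickness too large for the image size",
         call. = FALSE)
  }
  with_seed(seed, {
    p <- matrix(FALSE, size, size)
    n_px <- size * size
    orientations <- numeric(0)
    half_t <- thickness / 2
    n <- 0L
    while (sum(p) / n_px < target_fraction) {
      n <- n + 1L
      if (n > max_fibers) {
        stop(sprintf(
          "fiber_network(): target fraction %.2f unreachable within %d fibers",
          target_fraction, max_fibers), call. = FALSE)
      }
      theta <- rvonmises(1, 2 * mean_angle, kappa) / 2
      len <- runif(1, length_range[1], length_range[2]) * size
      cx <- runif(1, 1, size)
      cy <- runif(1, 1, size)
      dx <- cos(theta); dy <- sin(theta)
      x1 <- cx - dx * len / 2; x2 <- cx + dx * len / 2
      y1 <- cy - dy * len / 2; y2 <- cy + dy * len / 2
      pad <- half_t + 1
      jr <- max(1, floor(min(x1, x2) - pad)):min(size, ceiling(max(x1, x2) + pad))
      ir <- max(1, floor(min(y1, y2) - pad)):min(size, ceiling(max(y1, y2) + pad))
      if (!length(ir) || !length(jr)) next
      # distance from each candidate pixel center to the segment
      px <- matrix(jr, length(ir), length(jr), byrow = TRUE)
      py <- matrix(ir, length(ir), length(jr))
      vx <- x2 - x1; vy <- y2 - y1
      tt <- pmin(pmax(((px - x1) * vx + (py - y1) * vy) / (len^2), 0), 1)
      d2 <- (px - (x1 + tt * vx))^2 + (py - (y1 + tt * vy))^2
      hit <- d2 <= half_t^2
      if (any(hit)) p[ir, jr] <- p[ir, jr] | hit
      orientations <- c(orientations, theta)
    }
    attr(p, "orientations") <- orientations
    attr(p, "realized_fraction") <- sum(p) / n_px
    p
  })
}

#' Render a binary ECM pattern as a trichrome-like RGB image
#'
#' Emulates the appearance of a Masson-trichrome section: pattern
#' foreground becomes aniline-blue ECM, the remaining tissue region
#' becomes the red-pink counterstain, and everything outside the tissue
#' region becomes near-white slide background. Optional i.i.d. Gaussian
#' noise is added per channel and clamped. The tissue region is the left
#' `tissue_fraction` of the image columns; pattern pixels outside it are
#' dropped.
#'
#' @param pattern Logical matrix.
#' @param noise_sd Gaussian noise standard deviation in intensity units
#'   (default 0).
#' @param tissue_fraction Fraction of columns covered by tissue
#'   (default 1).
#' @param ecm_rgb,tissue_rgb,background_rgb Render colours.
#' @param seed Seed for the noise draw.
#' @return `H x W x 3` array in `[0, 255]` with attribute `truth`: a list
#'   holding the rendered `ecm` and `tissue` masks and the ground-truth
#'   `ecm_fraction`.
#' @export
render_trichrome <- function(pattern, noise_sd = 0, tissue_fraction = 1,
                             ecm_rgb = c(60, 80, 180),
                             tissue_rgb = c(200, 90, 110),
                             background_rgb = c(245, 245, 245),
                             seed = 1) {
  assert_pattern(pattern, "render_trichrome")
  h <- nrow(pattern); w <- ncol(pattern)
  n_tissue_cols <- round_half_up(tissue_fraction * w)
  tissue <- matrix(FALSE, h, w)
  if (n_tissue_cols > 0) tissue[, seq_len(n_tissue_cols)] <- TRUE
  ecm <- pattern & tissue
  img <- array(0, c(h, w, 3))
  for (ch in 1:3) {
    plane <- matrix(background_rgb[ch], h, w)
    plane[tissue] <- tissue_rgb[ch]
    plane[ecm] <- ecm_rgb[ch]
    img[, , ch] <- plane
  }
  if (noise_sd > 0) {
    img <- with_seed(seed,
      img + array(rnorm(length(img), 0, noise_sd), dim(img)))
  }
  img <- round_half_up(clamp8(img))
  attr(img, "truth") <- list(
    ecm = ecm, tissue = tissue,
    ecm_fraction = if (any(tissue)) sum(ecm) / sum(tissue) else NA_real_)
  img
}

#' Default parameters of the cohort simulator
#'
#' Distributional anchors for simulated patient cohorts. Per-grade fractal
#' dimension means/SDs are the study values for grades 0-4
#' (1.71/0.035, 1.67/0.038, 1.74/0.032, 1.76/0.030, 1.79/0.027) —
#' including the characteristic dip at grade 1, interpreted as matrix
#' expansion in early fibrosis. Lacunarity is anchored at grade 1
#' (1.17/0.36) and grade 4 (0.75/0.15) with the other grades linearly
#' interpolated/extrapolated, since only those two grades have printed
#' values. Expression means are the margin/focus values for COL1A1
#' (0.09/0.45) and COL3A1 (0.37/0.91). Fractal dimension and lacunarity
#' draws are negatively coupled (latent correlation -0.70). Margin and
#' focus records of one patient share a patient-level latent with
#' intra-class correlation `icc`; the strong default reflects that the
#' structural measures discriminate focus from margin within essentially
#' every patient.
#'
#' @param fd_mean,fd_sd Per-grade fractal-dimension means and SDs
#'   (grades 0-4).
#' @param lac_mean,lac_sd Per-grade lacunarity means and SDs.
#' @param ecm_base,ecm_slope,ecm_sd ECM-fraction mean at grade 0, increase
#'   per grade, and residual SD.
#' @param expr_mean List with per-location mean relative expression for
#'   `col1a1` and `col3a1`.
#' @param expr_sdlog Log-scale SD of the multiplicative expression noise.
#' @param margin_grade_probs,focus_grade_probs Grade mixture weights for
#'   margin (grades 0-1) and focus (grades 3-4) samples.
#' @param fd_lac_cor Latent correlation between FD and lacunarity draws.
#' @param icc Within-patient intra-class correlation of the structural
#'   measures.
#' @return A list of class `cohort_sim_params`.
#' @export
cohort_sim_params <- function(
    fd_mean = c(1.71, 1.67, 1.74, 1.76, 1.79),
    fd_sd = c(0.035, 0.038, 0.032, 0.030, 0.027),
    lac_mean = c(1.31, 1.17, 1.03, 0.89, 0.75),
    lac_sd = c(0.43, 0.36, 0.29, 0.22, 0.15),
    ecm_base = 0.15, ecm_slope = 0.07, ecm_sd = 0.10,
    expr_mean = list(col1a1 = c(margin = 0.09, focus = 0.45),
                     col3a1 = c(margin = 0.37, focus = 0.91)),
    expr_sdlog = 0.4,
    margin_grade_probs = c(0.5, 0.5),
    focus_grade_probs = c(0.5, 0.5),
    fd_lac_cor = -0.70,
    icc = 0.9) {
  stopifnot(length(fd_mean) == 5, length(fd_sd) == 5,
            length(lac_mean) == 5, length(lac_sd) == 5,
            all(fd_sd > 0), all(lac_sd > 0),
            abs(fd_lac_cor) <= 1, icc >= 0, icc <= 1)
  structure(as.list(environment()), class = "cohort_sim_params")
}

#' Simulate a paired margin/focus cohort
#'
#' Draws one resection-margin and one fibrotic-focus record per patient.
#' Margin fibrosis grades concentrate on 0-1 and focus grades on 3-4; per
#' record, fractal dimension and lacunarity are drawn from the grade's
#' normal (lacunarity truncated at 0) with a shared within-patient latent
#' and a negative FD-lacunarity coupling; the ECM fraction has a
#' grade-increasing mean; expression values are lognormal around the
#' location means. Fully reproducible per seed.
#'
#' @param n_patients Number of patients (default 28).
#' @param params A [cohort_sim_params()].
#' @param seed Integer seed.
#' @return Cohort `data.frame` with `2 * n_patients` rows and columns
#'   `patient_id`, `location`, `fibrosis_score`, `fractal_dimension`,
#'   `lacunarity`, `ecm_fraction`, `col1a1_expr`, `col3a1_expr`.
#' @export
simulate_cohort <- function(n_patients = 28, params = cohort_sim_params(),
                            seed = 1) {
  stopifnot(n_patients >= 1)
  p <- params
  rho <- p$fd_lac_cor
  with_seed(seed, {
    rows <- vector("list", 2 * n_patients)
    for (i in seq_len(n_patients)) {
      # patient-level latents, coupled across the two measures
      u1 <- rnorm(1)
      u2 <- rho * u1 + sqrt(1 - rho^2) * rnorm(1)
      g_margin <- sample(0:1, 1, prob = p$margin_grade_probs)
      g_focus <- sample(3:4, 1, prob = p$focus_grade_probs)
      for (loc in c("margin", "focus")) {
        g <- if (loc == "margin") g_margin else g_focus
        e1 <- rnorm(1)
        e2 <- rho * e1 + sqrt(1 - rho^2) * rnorm(1)
        z_fd <- sqrt(p$icc) * u1 + sqrt(1 - p$icc) * e1
        z_lac <- sqrt(p$icc) * u2 + sqrt(1 - p$icc) * e2
        fd <- p$fd_mean[g + 1] + p$fd_sd[g + 1] * z_fd
        lac <- max(0, p$lac_mean[g + 1] + p$lac_sd[g + 1] * z_lac)
        ecm <- min(max(p$ecm_base + p$ecm_slope * g + rnorm(1, 0, p$ecm_sd),
                       0.01), 0.99)
        c1 <- p$expr_mean$col1a1[[loc]] *
          exp(rnorm(1, -p$expr_sdlog^2 / 2, p$expr_sdlog))
        c3 <- p$expr_mean$col3a1[[loc]] *
          exp(rnorm(1, -p$expr_sdlog^2 / 2, p$expr_sdlog))
        rows[[2 * (i - 1) + (loc == "focus") + 1]] <- data.frame(
          patient_id = sprintf("P%02d", i), location = loc,
          fibrosis_score = g, fractal_dimension = fd, lacunarity = lac,
          ecm_fraction = ecm, col1a1_expr = c1, col3a1_expr = c3)
      }
    }
    validate_cohort(do.call(rbind, rows))
  })
}
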