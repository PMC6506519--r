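# Shared fixtures, all generated in code.

# Smooth random field: Gaussian white noise low-passed and normalized to
# [0, 1]. Used wherever a generic "smooth image" is needed.
smooth_field <- function(h, w, sigma = 6) {
  m <- matrix(stats::rnorm(h * w), h, w)
  m <- EBImage::gblur(m, sigma, boundary = "replicate")
  (m - min(m)) / (max(m) - min(m))
}

# Binary disc image (optionally softened), the analytic test object for the
# contrast energy.
binary_disc_image <- function(n, cx, cy, a, soften = 0) {
  img <- matrix(0, n, n)
  img[circle_mask(circle(cx, cy, a), n, n) == 1] <- 1
  if (soften > 0) img <- EBImage::gblur(img, soften, boundary = "replicate")
  img
}

# The three severity strata used for end-to-end cohort checks: cup geometry
# chosen so each stratum is unambiguously normal / moderate / severe by the
# DDLS rules applied to the true circles.
severity_strata_specs <- function() {
  list(
    normal = synthetic_spec(cup_radius_fraction_range = c(0.35, 0.55),
                            cup_offset_fraction_range = c(0, 0.10)),
    moderate = synthetic_spec(cup_radius_fraction_range = c(0.85, 0.95),
                              cup_offset_fraction_range = c(0, 0.02)),
    severe = synthetic_spec(cup_radius_fraction_range = c(0.95, 1.05),
                            cup_offset_fraction_range = c(0.35, 0.45),
                            allow_rim_absence = TRUE)
  )
}

# Random valid disc/cup circle pair (cup center inside the disc).
random_circle_pair <- function(allow_overshoot = TRUE) {
  Rd <- stats::runif(1, 20, 120)
  cx <- stats::runif(1, -50, 50); cy <- stats::runif(1, -50, 50)
  d <- stats::runif(1, 0, 0.95) * Rd
  ang <- stats::runif(1, 0, 2 * pi)
  rc_max <- if (allow_overshoot) 1.1 * Rd else Rd - d
  Rc <- stats::runif(1, 0.05 * Rd, max(0.06 * Rd, rc_max))
  list(disc = circle(cx, cy, Rd),
       cup = circle(cx + d * cos(ang), cy + d * sin(ang), Rc))
}

# Brute-force narrowest rim: minimum over dense boundary directions of the
# rim width measured along each ray from the disc center (vectorized
# re-derivation of the ray-circle geometry, independent of narrowest_rim).
narrowest_rim_sampled <- function(disc, cup, n = 36000) {
  th <- seq(0, 2 * pi, length.out = n + 1)[-(n + 1)]
  dx <- cup$cx - disc$cx; dy <- cup$cy - disc$cy
  d <- sqrt(dx^2 + dy^2)
  phi <- atan2(dy, dx)
  a <- th - phi
  disc2 <- cup$r^2 - d^2 * sin(a)^2
  g <- ifelse(disc2 >= 0, d * cos(a) + sqrt(pmax(disc2, 0)), -Inf)
  w <- ifelse(g >= 0, pmax(0, disc$r - g), NA_real_)
  miss <- is.na(w)
  if (any(miss)) {
    px <- disc$cx + disc$r * cos(th[miss])
    py <- disc$cy + disc$r * sin(th[miss])
    w[miss] <- pmax(0, sqrt((px - cup$cx)^2 + (py - cup$cy)^2) - cup$r)
  }
  list(l = min(w), meridian = th[which.min(w)] * 180 / pi)
}

# Sampling oracle for the rim-absence extent: fraction of disc-boundary
# directions whose ray meets the cup at or beyond the disc boundary.
rim_absence_sampled <- function(disc, cup, n = 14400) {
  th <- seq(0, 2 * pi, length.out = n + 1)[-(n + 1)]
  dx <- cup$cx - disc$cx; dy <- cup$cy - disc$cy
  d <- sqrt(dx^2 + dy^2)
  phi <- atan2(dy, dx)
  a <- th - phi
  disc2 <- cup$r^2 - d^2 * sin(a)^2
  g <- ifelse(disc2 >= 0, d * cos(a) + sqrt(pmax(disc2, 0)), -Inf)
  360 * mean(g >= disc$r)
}

# Exhaustive multilevel-Otsu search over all threshold placements, summing
# class costs in the same left-to-right order as the DP so floating-point
# values coincide.
otsu_exhaustive <- function(counts, k) {
  nb <- length(counts)
  cost <- activedisc:::otsu_class_cost(counts)
  best <- -Inf; best_cuts <- NULL
  if (k == 2) {
    for (c1 in 1:(nb - 1)) {
      obj <- cost(1, c1) + cost(c1 + 1, nb)
      if (obj > best) { best <- obj; best_cuts <- c1 }
    }
  } else if (k == 3) {
    for (c1 in 1:(nb - 2)) {
      base1 <- cost(1, c1)
      for (c2 in (c1 + 1):(nb - 1)) {
        obj <- (base1 + cost(c1 + 1, c2)) + cost(c2 + 1, nb)
        if (obj > best) { best <- obj; best_cuts <- c(c1, c2) }
      }
    }
  } else if (k == 4) {
    for (c1 in 1:(nb - 3)) {
      base1 <- cost(1, c1)
      for (c2 in (c1 + 1):(nb - 2)) {
        base2 <- base1 + cost(c1 + 1, c2)
        c3 <- (c2 + 1):(nb - 1)
        obj <- (base2 + cost(c2 + 1, c3)) + cost(c3 + 1, nb)
        i <- which.max(obj)
        if (obj[i] > best) { best <- obj[i]; best_cuts <- c(c1, c2, c3[i]) }
      }
    }
  } else {
    stop("unsupported k")
  }
  list(cuts = best_cuts - 1L, objective = best)
}
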