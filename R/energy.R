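#' Active-disc template parameters
#'
#' The active disc is a pair of concentric circles with template radii 1
#' (outer) and 1/sqrt(2) (inner), subjected to isotropic scaling `R` and
#' translation `(xc, yc)` - three degrees of freedom in total. The inner
#' radius is fixed at `R / sqrt(2)` so that the inner disc covers exactly
#' half the area of the outer one, which makes the contrast energy of a
#' uniform image identically zero.
#'
#' @param R Outer scale (pixels), positive.
#' @param xc,yc Template center (0-based pixel coordinates).
#' @return Object of class `"active_disc_params"`.
#' @export
active_disc_params <- function(R, xc, yc) {
  if (!is.finite(R) || R <= 0) stop_invalid("R must be positive")
  structure(list(R = as.numeric(R), xc = as.numeric(xc), yc = as.numeric(yc)),
            class = "active_disc_params")
}

#' @export
print.active_disc_params <- function(x, ...) {
  cat(sprintf("active disc: R = %.3f (inner %.3f), center (%.3f, %.3f)\n",
              x$R, x$R / sqrt(2), x$xc, x$yc))
  invisible(x)
}

inner_radius <- function(params) params$R / sqrt(2)

#' Sample points on an active-disc boundary
#'
#' Returns `n` points on the outer or inner circle at angles
#' `t = 2*pi*k/n`, `k = 1..n`, mapped by the scale (R for the outer circle,
#' R/sqrt(2) for the inner) and translated by the template center.
#'
#' @param params [active_disc_params()].
#' @param which `"outer"` or `"inner"`.
#' @param n Number of samples (>= 3).
#' @return `n x 2` matrix with columns `x`, `y`.
#' @export
boundary_samples <- function(params, which = c("outer", "inner"), n = 64L) {
  which <- match.arg(which)
  if (n < 3) stop_invalid("need at least 3 boundary samples")
  rho <- if (which == "outer") params$R else inner_radius(params)
  t <- 2 * pi * seq_len(n) / n
  cbind(x = params$xc + rho * cos(t), y = params$yc + rho * sin(t))
}

default_boundary_n <- function(R) max(64L, ceiling(2 * pi * R))

#' Active-disc contrast energy by direct pixel summation
#'
#' The normalized contrast energy is `E = (E1 - 2*E2) / R^2`, where `E1` and
#' `E2` are the sums of the image over the outer and inner discs
#' respectively (pixel-center membership, image taken as zero outside its
#' support). Since the inner disc has half the outer's area, the energy of a
#' constant image vanishes and minimizing E drives the inner disc onto a
#' bright object surrounded by a darker annulus. This direct evaluation is
#' the brute-force reference for the Green's-theorem evaluation
#' ([disc_energy_green()]).
#'
#' @param channel Numeric matrix.
#' @param params [active_disc_params()]; `R` must be at least 1 pixel.
#' @return Scalar energy.
#' @export
disc_energy_direct <- function(channel, params) {
  if (params$R < 1) {
    stop(errorCondition("degenerate active disc: R < 1 px",
                        class = c("activedisc_degenerate_template", "activedisc_error")))
  }
  h <- nrow(channel); w <- ncol(channel)
  sum_in_circle <- function(rho) {
    jlo <- max(0, floor(params$xc - rho)); jhi <- min(w - 1, ceiling(params$xc + rho))
    ilo <- max(0, floor(params$yc - rho)); ihi <- min(h - 1, ceiling(params$yc + rho))
    if (jlo > jhi || ilo > ihi) return(0)
    jj <- jlo:jhi; ii <- ilo:ihi
    d2 <- outer((ii - params$yc)^2, (jj - params$xc)^2, "+")
    sub <- channel[ii + 1, jj + 1, drop = FALSE]
    sum(sub[d2 <= rho^2])
  }
  E1 <- sum_in_circle(params$R)
  E2 <- sum_in_circle(inner_radius(params))
  (E1 - 2 * E2) / params$R^2
}

#' Row-wise running sum of an image channel
#'
#' `F[i, j] = sum(channel[i, 1:j])`, the discrete antiderivative along x
#' used by the Green's-theorem energy evaluation.
#'
#' @param channel Numeric matrix.
#' @return Matrix of the same dimensions.
#' @export
row_cumulative <- function(channel) {
  t(apply(channel, 1, cumsum))
}

# Interpolate the continuous antiderivative F(x, y) = integral of f from the
# left image edge to x, together with its exact spatial gradient, from the
# row-cumulative raster. The running sum at 0-based column j covers the
# channel up to x = j + 0.5, so F is the cumulative raster interpolated at
# column coordinate x - 0.5. Interpolation is C1 cubic convolution (Keys,
# a = -1/2): a continuously differentiable surface is required for the
# analytic gradient of the energy to agree with finite differences of the
# energy across pixel-grid knots. Columns are replicated on the right (F is
# constant past the image, so dF/dx = 0 there); everywhere else the image
# is zero outside its support.
cubic_w <- function(t) {
  # Keys kernel weights for the 4 taps at offsets -1, 0, 1, 2, and their
  # derivatives with respect to t in [0, 1)
  list(
    w = cbind(((-0.5 * t + 1) * t - 0.5) * t,
              (1.5 * t - 2.5) * t * t + 1,
              ((-1.5 * t + 2) * t + 0.5) * t,
              (0.5 * t - 0.5) * t * t),
    dw = cbind((-1.5 * t + 2) * t - 0.5,
               (4.5 * t - 5) * t,
               (-4.5 * t + 4) * t + 0.5,
               (1.5 * t - 1) * t)
  )
}

antideriv_interp <- function(Fc, x, y) {
  h <- nrow(Fc); w <- ncol(Fc)
  xs <- x - 0.5
  clamped <- xs >= w - 1
  xs[clamped] <- w - 1 - 1e-9
  jb <- floor(xs); ib <- floor(y)
  kx <- cubic_w(xs - jb)
  ky <- cubic_w(y - ib)

  val_at <- function(i, j) {
    # zero above/below and left of the support; replicate to the right
    j2 <- pmin(j, w - 1)
    ok <- i >= 0 & i <= h - 1 & j2 >= 0
    out <- numeric(length(i))
    if (any(ok)) out[ok] <- Fc[cbind(i[ok] + 1L, j2[ok] + 1L)]
    out
  }

  v <- gx <- gy <- numeric(length(xs))
  for (r in 1:4) {
    rowv <- rowdx <- numeric(length(xs))
    i <- ib + (r - 2L)
    for (c in 1:4) {
      vc <- val_at(i, jb + (c - 2L))
      rowv <- rowv + kx$w[, c] * vc
      rowdx <- rowdx + kx$dw[, c] * vc
    }
    v <- v + ky$w[, r] * rowv
    gx <- gx + ky$w[, r] * rowdx
    gy <- gy + ky$dw[, r] * rowv
  }
  gx[clamped] <- 0
  list(v = v, gx = gx, gy = gy)
}

#' Active-disc contrast energy via Green's theorem
#'
#' Evaluates the same energy as [disc_energy_direct()] but as boundary line
#' integrals: each area integral over a disc becomes the closed line
#' integral of the row antiderivative F against dy, discretized by the
#' trapezoid rule over `n` boundary samples with bilinear interpolation of
#' F. Cost is O(n) per evaluation instead of O(R^2), which is what makes
#' gradient-descent fitting cheap.
#'
#' @param row_cum Row-cumulative raster from [row_cumulative()].
#' @param params [active_disc_params()].
#' @param n Boundary samples per circle; default `max(64, ceiling(2*pi*R))`.
#' @return Scalar energy. Exactly 0 when the outer circle lies entirely
#'   outside the image support.
#' @export
disc_energy_green <- function(row_cum, params, n = NULL) {
  if (!is.matrix(row_cum)) stop_invalid("row_cum must be a matrix (see row_cumulative)")
  if (params$R < 1) {
    stop(errorCondition("degenerate active disc: R < 1 px",
                        class = c("activedisc_degenerate_template", "activedisc_error")))
  }
  h <- nrow(row_cum); w <- ncol(row_cum)
  # outer circle disjoint from the image support => both integrals vanish
  if (params$xc + params$R < -0.5 || params$xc - params$R > w - 0.5 ||
      params$yc + params$R < -0.5 || params$yc - params$R > h - 0.5) {
    return(0)
  }
  if (is.null(n)) n <- default_boundary_n(params$R)

  area_integral <- function(which) {
    p <- boundary_samples(params, which, n)
    Fv <- antideriv_interp(row_cum, p[, 1], p[, 2])$v
    ynext <- c(p[-1, 2], p[1, 2])
    Fnext <- c(Fv[-1], Fv[1])
    sum((Fv + Fnext) / 2 * (ynext - p[, 2]))
  }
  (area_integral("outer") - 2 * area_integral("inner")) / params$R^2
}

#' Analytic gradient of the active-disc energy
#'
#' Differentiates `E = (E1 - 2*E2)/R^2` with respect to the three template
#' parameters. Each area term is the Green's-theorem line integral of the
#' row antiderivative F against dy over the moving circular boundary; the
#' gradient differentiates that (discretized) functional exactly, using the
#' exact spatial gradient of the bilinear interpolant of F. In the
#' continuum limit these sums reduce to the transport-theorem boundary
#' integrals `dA/dxc = closed integral of f nx ds`, `dA/dyc = closed
#' integral of f ny ds`, `dA/drho = closed integral of f ds` (with
#' `drho/dR = 1` for the outer circle and `1/sqrt(2)` for the inner), and
#' the quotient rule contributes the `-(2/R) E` term to the scale
#' derivative.
#'
#' @param channel Numeric matrix. Ignored when `row_cum` is supplied.
#' @param params [active_disc_params()].
#' @param n Boundary samples per circle; default `max(64, ceiling(2*pi*R))`.
#' @param row_cum Optional precomputed [row_cumulative()] raster (recomputed
#'   if omitted); passed in by the fitting loop to avoid redundant work.
#' @return Named numeric vector `c(dR, dxc, dyc)`.
#' @export
energy_gradient <- function(channel, params, n = NULL, row_cum = NULL) {
  if (params$R < 1) {
    stop(errorCondition("degenerate active disc: R < 1 px",
                        class = c("activedisc_degenerate_template", "activedisc_error")))
  }
  if (is.null(n)) n <- default_boundary_n(params$R)
  if (is.null(row_cum)) row_cum <- row_cumulative(channel)
  t <- 2 * pi * seq_len(n) / n
  ct <- cos(t); st <- sin(t)

  # dA/d(xc, yc, rho) of the trapezoid line integral sum((F_k + F_{k+1})/2 *
  # (y_{k+1} - y_k)) for a circle of radius rho; F is sampled at column
  # coordinate x - 0.5 (clamped right, where F is constant so dF/dx = 0).
  circle_terms <- function(rho) {
    x <- params$xc + rho * ct
    y <- params$yc + rho * st
    gi <- antideriv_interp(row_cum, x, y)
    Fv <- gi$v
    Fx <- gi$gx
    Fy <- gi$gy

    nxt <- c(2:n, 1L)
    dy <- y[nxt] - y
    pair <- function(a) (a + a[nxt]) / 2
    dF_drho <- Fx * ct + Fy * st  # boundary point moves radially
    list(
      A = sum(pair(Fv) * dy),
      dxc = sum(pair(Fx) * dy),
      dyc = sum(pair(Fy) * dy),
      drho = sum(pair(dF_drho) * dy) + sum(pair(Fv) * (st[nxt] - st))
    )
  }

  g1 <- circle_terms(params$R)
  g2 <- circle_terms(inner_radius(params))
  R <- params$R
  E <- (g1$A - 2 * g2$A) / R^2
  dR <- (g1$drho - 2 * g2$drho / sqrt(2)) / R^2 - 2 * E / R
  c(dR = dR,
    dxc = (g1$dxc - 2 * g2$dxc) / R^2,
    dyc = (g1$dyc - 2 * g2$dyc) / R^2)
}
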