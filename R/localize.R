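#' Build a low-pass image pyramid
#'
#' Constructs an n-level pyramid by repeatedly Gaussian-filtering and
#' decimating by 2. Level 1 is the full-resolution image ("top"); the last
#' level is the coarsest. Level k+1 has dimensions `ceiling(dim(level k)/2)`
#' (decimation keeps every other pixel starting from the first, so a 0-based
#' coarse coordinate maps to `2^(k-1)` times itself at full resolution).
#'
#' @param channel Numeric matrix (a single image channel).
#' @param n_levels Number of levels (default 3).
#' @param sigma Anti-aliasing Gaussian sigma applied before each decimation.
#' @return Object of class `"pyramid"`: list with `levels` (list of
#'   matrices) and `scale_factor` (2).
#' @export
build_pyramid <- function(channel, n_levels = 3L, sigma = 1.0) {
  if (!is.matrix(channel)) stop_invalid("channel must be a matrix")
  if (n_levels < 1) stop_invalid("n_levels must be >= 1")
  if (min(dim(channel)) < 2^(n_levels - 1)) {
    stop_invalid("image too small for ", n_levels, " pyramid levels")
  }
  levels <- vector("list", n_levels)
  levels[[1]] <- channel
  for (k in seq_len(n_levels - 1L)) {
    prev <- levels[[k]]
    sm <- if (sigma > 0) {
      EBImage::gblur(prev, sigma = sigma, boundary = "replicate")
    } else {
      prev
    }
    levels[[k + 1]] <- sm[seq(1, nrow(sm), by = 2), seq(1, ncol(sm), by = 2),
                          drop = FALSE]
  }
  structure(list(levels = levels, scale_factor = 2L), class = "pyramid")
}

#' Gaussian bright-blob matched-filter template
#'
#' The default optic-disc template for localization: an isotropic 2-D
#' Gaussian bright blob. Normalized cross-correlation is invariant to the
#' template's gain and offset, so only its shape matters; a Gaussian of
#' sigma `radius / 2` peaks sharply when centered on a bright disc of
#' comparable radius.
#'
#' @param radius Nominal disc radius in pixels at the scale the template is
#'   used.
#' @return Numeric matrix of side `2*ceiling(2*radius) + 1`.
#' @export
disc_template <- function(radius) {
  if (radius <= 0) stop_invalid("template radius must be positive")
  half <- ceiling(2 * radius)
  ax <- seq(-half, half)
  sig <- radius / 2
  g <- exp(-outer(ax^2, ax^2, "+") / (2 * sig^2))
  g
}

#' Normalized cross-correlation map
#'
#' Slides the template over the image and computes, at every position where
#' the template fits entirely inside the image, the zero-mean, unit-norm
#' correlation between the template and the co-located window. Values lie in
#' [-1, 1]; positions where the window or template has zero variance, and
#' border positions where the template does not fit, are defined as 0.
#' Computed with FFT convolution plus running-sum window statistics.
#'
#' @param channel Numeric matrix.
#' @param template Numeric matrix, strictly smaller than `channel`.
#' @return Numeric matrix of the same size as `channel`; entry (i, j) is the
#'   correlation with the window centered at pixel (i, j).
#' @export
normalized_cross_correlation <- function(channel, template) {
  h <- nrow(channel); w <- ncol(channel)
  th <- nrow(template); tw <- ncol(template)
  if (th >= h || tw >= w) stop_invalid("template must be smaller than the image")
  t0 <- template - mean(template)
  tnorm2 <- sum(t0^2)

  # cross-correlation of channel with t0 via zero-padded FFT
  ph <- h + th - 1L
  pw <- w + tw - 1L
  A <- matrix(0, ph, pw); A[1:h, 1:w] <- channel
  B <- matrix(0, ph, pw); B[1:th, 1:tw] <- t0[th:1, tw:1]  # flip => correlation
  num_full <- Re(stats::fft(stats::fft(A) * stats::fft(B), inverse = TRUE)) / (ph * pw)
  # valid part: window with top-left at (i, j) has its correlation at
  # num_full[i + th - 1, j + tw - 1]
  nvr <- h - th + 1L; nvc <- w - tw + 1L
  num <- num_full[th:(th + nvr - 1L), tw:(tw + nvc - 1L), drop = FALSE]

  # window sums and sums of squares via 2-D running sums (integral images)
  win_sum <- function(m) {
    S <- apply(apply(m, 2, cumsum), 1, cumsum)  # transposed cumulative sums
    S <- t(S)
    P <- matrix(0, h + 1L, w + 1L)
    P[2:(h + 1L), 2:(w + 1L)] <- S
    P[(th + 1L):(h + 1L), (tw + 1L):(w + 1L)] -
      P[1:nvr, (tw + 1L):(w + 1L)] -
      P[(th + 1L):(h + 1L), 1:nvc] +
      P[1:nvr, 1:nvc]
  }
  npix <- th * tw
  s1 <- win_sum(channel)
  s2 <- win_sum(channel^2)
  winvar <- s2 - s1^2 / npix  # = npix * variance of the window
  winvar[winvar < 0] <- 0

  denom <- sqrt(winvar * tnorm2)
  corr <- matrix(0, nvr, nvc)
  # a window is flat when its variance is lost to cancellation noise
  # relative to its energy; such positions are defined as 0
  ok <- winvar > 1e-9 * pmax(s2, .Machine$double.xmin) & tnorm2 > 0
  corr[ok] <- num[ok] / denom[ok]
  corr <- clamp(corr, -1, 1)

  # embed at window-center positions; borders stay 0
  out <- matrix(0, h, w)
  r0 <- (th - 1L) %/% 2L
  c0 <- (tw - 1L) %/% 2L
  out[(r0 + 1L):(r0 + nvr), (c0 + 1L):(c0 + nvc)] <- corr
  out
}

#' Localize the optic disc by multiscale matched filtering
#'
#' Builds a pyramid of the red channel (the disc is brightest in red),
#' computes the normalized cross-correlation with a disc template at the
#' coarsest level, and maps the correlation peak back to full resolution.
#' Ties in the argmax are broken by smallest row, then smallest column; a
#' flat correlation map (e.g. a uniform image) raises an
#' ambiguous-localization error listing the tied positions.
#'
#' @param img H x W x 3 array in [0, 1] (or a single-channel matrix).
#' @param template Optional template matrix at the coarsest scale; default
#'   [disc_template()] with `template_radius`.
#' @param n_levels Pyramid depth (default 3).
#' @param template_radius Template radius at the coarsest scale; default
#'   `0.13 * min(W, H) / 2^(n_levels - 1)` (a typical disc-to-field
#'   proportion).
#' @return Object of class `"localization"`: list with `peak = c(x, y)`
#'   (full-resolution 0-based pixel coordinates), `peak_score`, and
#'   `roi_box = c(x0, y0, x1, y1)` (a square of side 4 x the full-resolution
#'   template radius, clipped to the image).
#' @export
localize_disc <- function(img, template = NULL, n_levels = 3L,
                          template_radius = NULL) {
  red <- get_channel(img, 1L)
  h <- nrow(red); w <- ncol(red)
  down <- 2^(n_levels - 1L)
  if (is.null(template_radius)) {
    template_radius <- 0.13 * min(w, h) / down
  }
  if (is.null(template)) {
    template <- disc_template(template_radius)
  }
  pyr <- build_pyramid(red, n_levels)
  coarse <- pyr$levels[[n_levels]]

  # replicate-pad by the template half-width so discs near the image border
  # still receive a valid (fully supported) correlation window
  pr <- (nrow(template) - 1L) %/% 2L
  pc <- (ncol(template) - 1L) %/% 2L
  padded <- coarse[
    pmin(pmax(seq_len(nrow(coarse) + 2L * pr) - pr, 1L), nrow(coarse)),
    pmin(pmax(seq_len(ncol(coarse) + 2L * pc) - pc, 1L), ncol(coarse)),
    drop = FALSE]
  cmap <- normalized_cross_correlation(padded, template)
  cmap <- cmap[(pr + 1L):(pr + nrow(coarse)), (pc + 1L):(pc + ncol(coarse)),
               drop = FALSE]

  mx <- max(cmap)
  ties <- which(cmap >= mx - 1e-12, arr.ind = TRUE)
  if (nrow(ties) > 1L && (mx - min(cmap)) < 1e-9) {
    stop(errorCondition(
      sprintf("ambiguous localization: %d tied correlation peaks", nrow(ties)),
      tied_positions = ties,
      class = c("activedisc_ambiguous_localization", "activedisc_error")
    ))
  }
  # deterministic tie-break: smallest row, then smallest column
  ties <- ties[order(ties[, 1], ties[, 2]), , drop = FALSE]
  pk <- ties[1, ]
  x_p <- (pk[["col"]] - 1L) * down
  y_p <- (pk[["row"]] - 1L) * down
  x_p <- min(max(x_p, 0L), w - 1L)
  y_p <- min(max(y_p, 0L), h - 1L)

  r_full <- template_radius * down
  half <- 2 * r_full
  roi <- c(
    x0 = max(0, floor(x_p - half)), y0 = max(0, floor(y_p - half)),
    x1 = min(w - 1, ceiling(x_p + half)), y1 = min(h - 1, ceiling(y_p + half))
  )
  structure(list(peak = c(x = as.numeric(x_p), y = as.numeric(y_p)),
                 peak_score = mx, roi_box = roi,
                 template_radius_full = r_full, n_levels = n_levels),
            class = "localization")
}

#' @export
print.localization <- function(x, ...) {
  cat(sprintf("disc localization: peak (%g, %g), score %.4f, roi [%g, %g] x [%g, %g]\n",
              x$peak[1], x$peak[2], x$peak_score,
              x$roi_box[1], x$roi_box[3], x$roi_box[2], x$roi_box[4]))
  invisible(x)
}
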