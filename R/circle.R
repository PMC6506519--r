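#' Circle in pixel coordinates
#'
#' Constructs a circle object, the common currency for disc and cup
#' outlines. Coordinates are 0-based continuous pixel coordinates
#' (x = column, y = row, both increasing right/down); pixel (i, j) of a
#' matrix has its center at (j - 1, i - 1).
#'
#' @param cx,cy Center coordinates in pixels.
#' @param r Radius in pixels; must be positive.
#' @return An object of class `"circle"`: a list with elements `cx`, `cy`, `r`.
#' @examples
#' circle(50, 60, 20)
#' @export
circle <- function(cx, cy, r) {
  if (!is.numeric(cx) || !is.numeric(cy) || !is.numeric(r) ||
      length(cx) != 1L || length(cy) != 1L || length(r) != 1L) {
    stop_invalid("cx, cy, r must be numeric scalars")
  }
  if (!is.finite(r) || r <= 0) {
    stop_invalid("circle radius must be positive, got ", r)
  }
  structure(list(cx = as.numeric(cx), cy = as.numeric(cy), r = as.numeric(r)),
            class = "circle")
}

#' @export
print.circle <- function(x, ...) {
  cat(sprintf("circle: center (%.3f, %.3f), radius %.3f px\n", x$cx, x$cy, x$r))
  invisible(x)
}

#' Rasterize a circle to a binary mask
#'
#' Pixel (i, j) is set iff its center lies at distance <= r from the circle
#' center. This pixel-center membership rule is the single rasterization
#' convention shared by the synthetic generator, the direct energy oracle,
#' and the evaluation metrics.
#'
#' @param circ A [circle()].
#' @param height,width Output mask dimensions in pixels.
#' @return An integer matrix of 0/1 values, `height` x `width`.
#' @examples
#' m <- circle_mask(circle(5, 5, 3), 11, 11)
#' sum(m)
#' @export
circle_mask <- function(circ, height, width) {
  stopifnot(inherits(circ, "circle"))
  if (height < 1 || width < 1) {
    stop_invalid("mask dimensions must be positive")
  }
  dy2 <- (seq_len(height) - 1 - circ$cy)^2
  dx2 <- (seq_len(width) - 1 - circ$cx)^2
  mask <- outer(dy2, dx2, "+") <= circ$r^2
  storage.mode(mask) <- "integer"
  mask
}
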