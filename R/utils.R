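# Internal helpers shared across modules.
#
# Coordinate convention used throughout the package: images are numeric
# matrices (or H x W x 3 arrays) indexed [row, col] in the usual R way, but
# all *continuous* coordinates are 0-based with x = column index increasing
# rightward and y = row index increasing downward; pixel (i, j) (1-based
# matrix indices) has its center at (x, y) = (j - 1, i - 1).

# Run `expr` under a temporary RNG state seeded with `seed`, restoring the
# caller's RNG afterwards so library code never perturbs user simulations.
with_seed <- function(seed, expr) {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
        rm(".Random.seed", envir = globalenv())
      },
      add = TRUE
    )
  }
  set.seed(seed)
  expr
}

clamp <- function(x, lo, hi) pmin(pmax(x, lo), hi)

stop_invalid <- function(...) {
  stop(errorCondition(paste0(...), class = c("activedisc_invalid_argument", "activedisc_error")))
}

#' Bilinear interpolation of a raster at continuous coordinates
#'
#' Samples a numeric matrix at arbitrary (x, y) positions using bilinear
#' interpolation of the four surrounding pixel centers. The image is treated
#' as zero outside its support, so samples fade linearly to zero across the
#' last pixel at each border.
#'
#' @param mat Numeric matrix (rows = y, columns = x).
#' @param x,y Numeric vectors of 0-based continuous coordinates
#'   (pixel centers at integers).
#' @return Numeric vector of interpolated values.
#' @keywords internal
bilinear_interp <- function(mat, x, y) {
  h <- nrow(mat)
  w <- ncol(mat)
  j0 <- floor(x)
  i0 <- floor(y)
  fx <- x - j0
  fy <- y - i0

  # value at 0-based (row, col), 0 outside support
  val_at <- function(i, j) {
    ok <- i >= 0 & i <= h - 1 & j >= 0 & j <= w - 1
    out <- numeric(length(i))
    if (any(ok)) {
      out[ok] <- mat[cbind(i[ok] + 1L, j[ok] + 1L)]
    }
    out
  }

  v00 <- val_at(i0, j0)
  v01 <- val_at(i0, j0 + 1)
  v10 <- val_at(i0 + 1, j0)
  v11 <- val_at(i0 + 1, j0 + 1)

  (1 - fy) * ((1 - fx) * v00 + fx * v01) + fy * ((1 - fx) * v10 + fx * v11)
}
# Extract one channel (1 = red, 2 = green, 3 = blue) from an H x W x 3 array,
# passing plain matrices through untouched.
get_channel <- function(img, channel) {
  if (is.matrix(img)) {
    return(img)
  }
  if (length(dim(img)) == 3L) {
    return(img[, , channel])
  }
  stop_invalid("expected a matrix or an H x W x 3 array")
}

package_version_string <- function() {
  as.character(utils::packageVersion("activedisc"))
}
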