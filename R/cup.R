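#' Multilevel Otsu thresholding
#'
#' Finds the `k - 1` thresholds that partition a 256-bin intensity histogram
#' into `k` classes maximizing the between-class variance, by exact dynamic
#' programming over all cut positions (equivalent to exhaustive search; the
#' DP is O(k * 256^2)). Ties are resolved toward the lexicographically
#' smallest cut-bin indices. Threshold values are reported as the midpoint
#' between the last bin of one class and the first bin of the next, in the
#' intensity units of the input.
#'
#' @param x Either a numeric raster with values in [0, 1] (binned into 256
#'   levels) or a length-256 vector of histogram counts (taken to span
#'   [0, 1]).
#' @param k Number of classes (>= 2); the clinically validated default for
#'   cup clustering is 4.
#' @return Object of class `"threshold_set"`: list with `thresholds`
#'   (increasing numeric vector of length k - 1), `k`, `cut_bins` (0-based
#'   last-bin index of each class but the final one), and
#'   `between_class_variance`.
#' @export
otsu_multilevel <- function(x, k = 4L) {
  if (k < 2) stop_invalid("k must be >= 2")
  if (is.matrix(x) || (is.numeric(x) && length(x) != 256L)) {
    v <- as.numeric(x)
    if (any(!is.finite(v))) stop_invalid("raster contains non-finite values")
    if (min(v) < 0 || max(v) > 1) stop_invalid("raster values must lie in [0, 1]")
    counts <- tabulate(pmin(floor(v * 256), 255) + 1L, nbins = 256L)
  } else {
    counts <- as.numeric(x)
    if (any(counts < 0)) stop_invalid("histogram counts must be non-negative")
  }
  nz <- which(counts > 0)
  if (length(nz) < k) {
    stop(errorCondition(
      sprintf("degenerate histogram: %d distinct levels but k = %d", length(nz), k),
      class = c("activedisc_degenerate_histogram", "activedisc_error")))
  }

  sol <- otsu_search_dp(counts, k)
  mids <- (seq_len(256L) - 0.5) / 256  # bin-center intensities on [0, 1]
  thr <- (mids[sol$cuts + 1L] + mids[sol$cuts + 2L]) / 2
  structure(list(thresholds = thr, k = as.integer(k),
                 cut_bins = sol$cuts, between_class_variance = sol$objective),
            class = "threshold_set")
}

# Shared class-statistic helper: contribution w * mu^2 of the class spanning
# 1-based bins a..b. Used identically by the DP and by the exhaustive test
# oracle so that floating-point values coincide bit for bit.
otsu_class_cost <- function(counts) {
  P <- c(0, cumsum(counts / sum(counts)))
  mids <- (seq_along(counts) - 0.5) / length(counts)
  S <- c(0, cumsum(counts / sum(counts) * mids))
  function(a, b) {
    wgt <- P[b + 1L] - P[a]
    mu_sum <- S[b + 1L] - S[a]
    ifelse(wgt > 0, mu_sum^2 / wgt, 0)
  }
}

otsu_search_dp <- function(counts, k) {
  nb <- length(counts)
  cost <- otsu_class_cost(counts)
  # best[c, j]: max objective for the first c classes covering bins 1..j
  best <- matrix(-Inf, k, nb)
  argc <- matrix(NA_integer_, k, nb)
  best[1, ] <- cost(1L, seq_len(nb))
  for (cl in 2:k) {
    for (j in cl:nb) {
      prev <- best[cl - 1L, (cl - 1L):(j - 1L)]
      cand <- prev + cost(cl:j, j)
      # strict '>' keeps the first (lexicographically smallest) maximizer
      i_rel <- which.max(cand)
      best[cl, j] <- cand[i_rel]
      argc[cl, j] <- (cl - 1L) + i_rel - 1L  # last bin of class cl-1
    }
  }
  cuts <- integer(k - 1L)
  j <- nb
  for (cl in k:2) {
    cuts[cl - 1L] <- argc[cl, j]
    j <- argc[cl, j]
  }
  list(cuts = cuts - 1L, objective = best[k, nb])  # cuts as 0-based bin indices
}

#' @export
print.threshold_set <- function(x, ...) {
  cat(sprintf("%d-class Otsu thresholds: %s\n", x$k,
              paste(sprintf("%.4f", x$thresholds), collapse = ", ")))
  invisible(x)
}

#' Coarse optic-cup mask by multilevel Otsu inside the disc
#'
#' Restricts the green-channel histogram to the disc interior (so the cup is
#' the locally brightest class), thresholds it into `k` classes, and keeps
#' every class above the rim/cup separator - the threshold with the largest
#' gap between adjacent class means. (With a dominant bright cup, Otsu
#' spends classes subdividing the cup's own intensity mode; taking only the
#' single top class would then halve the cup, while the largest mean gap
#' reliably marks the rim-to-cup transition.) The retained pixels are
#' intersected with the disc, morphologically closed to bridge vessel
#' crossings, and reduced to the largest connected component (ties broken
#' by smallest centroid row, then column). The component's centroid and
#' equivalent radius `sqrt(area/pi)` give the initialization circle for the
#' active-disc refinement.
#'
#' @param green Numeric matrix (green channel, values in [0, 1]).
#' @param disc [circle()] of the segmented disc.
#' @param k Number of Otsu classes (default 4).
#' @param close_radius Radius (pixels) of the disc brush used to
#'   morphologically close the top-class mask before component analysis;
#'   bridges the gaps cut by vessels crossing the cup. 0 disables closing.
#' @return List with `mask` (0/1 matrix) and `init` ([circle()]).
#' @export
coarse_cup_mask <- function(green, disc, k = 4L, close_radius = 3) {
  h <- nrow(green); w <- ncol(green)
  dmask <- circle_mask(disc, h, w) == 1L
  if (!any(dmask)) stop_invalid("disc circle does not overlap the image")
  ts <- otsu_multilevel(green[dmask], k)
  # class means inside the disc; the rim/cup separator is the threshold
  # with the widest gap between adjacent class means
  edges <- c(-Inf, ts$thresholds, Inf)
  cls <- findInterval(green[dmask], edges[-c(1, length(edges))]) + 1L
  mus <- vapply(seq_len(k), function(c) {
    v <- green[dmask][cls == c]
    if (length(v)) mean(v) else NA_real_
  }, numeric(1))
  gaps <- diff(mus)
  sep <- if (all(is.na(gaps))) k - 1L else which.max(gaps)
  top <- green > ts$thresholds[sep] & dmask
  if (close_radius > 0 && any(top)) {
    brush <- EBImage::makeBrush(2L * ceiling(close_radius) + 1L, "disc")
    top <- EBImage::closing(top * 1, brush) > 0 & dmask
  }

  if (!any(top)) {
    stop(errorCondition("no cup candidate pixels in the top intensity class",
                        class = c("activedisc_no_cup_found", "activedisc_error")))
  }
  lab <- EBImage::bwlabel(top * 1)
  sizes <- tabulate(lab[lab > 0])
  biggest <- which(sizes == max(sizes))
  if (length(biggest) > 1L) {
    # tie-break: smallest centroid row, then column
    cents <- t(vapply(biggest, function(b) {
      idx <- which(lab == b, arr.ind = TRUE)
      colMeans(idx)
    }, numeric(2)))
    biggest <- biggest[order(cents[, 1], cents[, 2])][1]
  }
  comp <- lab == biggest
  idx <- which(comp, arr.ind = TRUE)
  area <- nrow(idx)
  cy <- mean(idx[, 1]) - 1
  cx <- mean(idx[, 2]) - 1
  r_eq <- sqrt(area / pi)
  if (r_eq < 1) {
    stop(errorCondition("cup candidate component is degenerately small",
                        class = c("activedisc_no_cup_found", "activedisc_error")))
  }
  mask <- matrix(0L, h, w)
  mask[comp] <- 1L
  list(mask = mask, init = circle(cx, cy, r_eq))
}

#' Segment the optic cup with a constrained active-disc fit
#'
#' Refines the coarse Otsu cup estimate by fitting the active disc on the
#' green channel (where the cup has its highest contrast against the disc),
#' under anatomical constraints projected after every optimizer step: the
#' cup center stays inside the disc circle and the cup radius never exceeds
#' the disc radius. The cup boundary may still extend beyond the disc
#' boundary (center offset + radius > disc radius), which is exactly the
#' zero-rim configuration the advanced DDLS stages require.
#'
#' The normalized energy is scale-free, so fits started from different
#' initializations are directly comparable: the optimizer runs from a small
#' ladder of starts (the coarse-mask circle, and object radii 0.55 x and
#' 0.9 x the disc radius, centered on the coarse centroid) and the
#' lowest-energy fit is kept. The larger starts rescue advanced cupping,
#' where the bright region nearly fills the disc and a small initialization
#' stalls on the flat energy plateau in its interior; the smaller ones
#' protect small cups from capture by the disc boundary.
#'
#' @param img H x W x 3 array in [0, 1].
#' @param disc [circle()] of the segmented disc (object circle).
#' @param opts [fit_options()]; the cup fit runs at full resolution only.
#' @param k Otsu classes for the coarse stage.
#' @return `"active_disc_fit"` for the cup, with the coarse mask attached as
#'   `coarse` (list with `mask`, `init`).
#' @export
segment_optic_cup <- function(img, disc, opts = fit_options(), k = 4L) {
  stopifnot(inherits(disc, "circle"))
  green <- get_channel(img, 2L)
  coarse <- coarse_cup_mask(green, disc, k)

  project <- function(p) {
    # clamp center into the disc, cap the object (inner) radius at the disc's
    dx <- p$xc - disc$cx; dy <- p$yc - disc$cy
    d <- sqrt(dx^2 + dy^2)
    if (d > 0.95 * disc$r) {
      s <- 0.95 * disc$r / d
      p <- active_disc_params(p$R, disc$cx + dx * s, disc$cy + dy * s)
    }
    if (p$R > sqrt(2) * disc$r) {
      p <- active_disc_params(sqrt(2) * disc$r, p$xc, p$yc)
    }
    p
  }
  inits <- lapply(c(coarse$init$r * 1.1, 0.55 * disc$r, 0.9 * disc$r),
                  function(r0) {
                    active_disc_params(sqrt(2) * r0,
                                       coarse$init$cx, coarse$init$cy)
                  })
  fits <- lapply(inits, function(ini) {
    fit_active_disc(green, project(ini), opts, project = project)
  })
  # evidence-consistency gate: a candidate whose area is more than 3x the
  # coarse Otsu candidate's contradicts the thresholding evidence (the
  # classic failure is a fit locked onto the disc outline); it is dropped
  # unless nothing else survives
  ok <- vapply(fits, function(f) {
    f$object_circle$r <= sqrt(3) * coarse$init$r
  }, logical(1))
  if (!any(ok)) ok <- rep(TRUE, length(fits))
  fits <- fits[ok]
  fit <- fits[[which.min(vapply(fits, `[[`, numeric(1), "energy"))]]
  fit$coarse <- coarse
  fit
}
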