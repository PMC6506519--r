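# Clinical geometry on the fitted disc and cup circles.
#
# All angles are in degrees, measured from the +x image axis with the y
# axis pointing down (image rows); "superior" is the decreasing-row
# direction (270 deg), "inferior" 90 deg.

check_cup_in_disc <- function(disc, cup) {
  d <- sqrt((cup$cx - disc$cx)^2 + (cup$cy - disc$cy)^2)
  if (d > disc$r) {
    stop(errorCondition("cup center lies outside the disc circle",
                        class = c("activedisc_invalid_geometry", "activedisc_error")))
  }
  d
}

#' Narrowest neuroretinal rim width
#'
#' For two circles, the narrowest rim lies along the line joining the
#' centers, extended through the cup center to the disc periphery:
#' `l = max(0, R_d - (d + R_c))` where `d` is the center separation. The
#' meridian is the direction from the disc center through the cup center
#' (degrees, from +x, y down); for concentric circles it is reported as 0
#' by convention.
#'
#' @param disc,cup [circle()]s; the cup center must lie inside the disc.
#' @return List with `l` (pixels) and `meridian` (degrees in [0, 360)).
#' @export
narrowest_rim <- function(disc, cup) {
  d <- check_cup_in_disc(disc, cup)
  l <- max(0, disc$r - (d + cup$r))
  meridian <- if (d < 1e-12) 0 else {
    (atan2(cup$cy - disc$cy, cup$cx - disc$cx) * 180 / pi) %% 360
  }
  list(l = l, meridian = meridian)
}

#' Vertical cup-to-disc ratio
#'
#' The ratio of the vertical cup diameter to the vertical disc diameter.
#' For circular outlines the diameter is orientation-independent, so this
#' reduces exactly to `R_c / R_d`.
#'
#' @param disc,cup [circle()]s.
#' @return Ratio in (0, Inf); values above 1 can only arise from a cup
#'   fitted larger than the disc.
#' @export
vertical_cdr <- function(disc, cup) {
  cup$r / disc$r
}

#' Rim-to-disc ratio
#'
#' The narrowest rim width normalized by the disc *diameter* along that
#' meridian (constant `2 R_d` for a circle): `rdr = l / (2 R_d)`. This is
#' the normalization whose attainable range, (0, 0.5), matches the DDLS
#' normal-range ceiling of 0.50.
#'
#' @param disc,cup [circle()]s.
#' @return Ratio in [0, 0.5).
#' @export
rdr <- function(disc, cup) {
  nr <- narrowest_rim(disc, cup)
  nr$l / (2 * disc$r)
}

#' Rim width along a given meridian
#'
#' Casts a ray from the disc center at `angle` and measures the rim as the
#' distance from the far cup intersection to the disc boundary:
#' `width = R_d - g`, with `g = d cos(a) + sqrt(R_c^2 - d^2 sin^2(a))`
#' where `a` is the angle between the ray and the center line. If the ray
#' misses the cup entirely, the width is the distance from the disc
#' boundary point to the nearest point of the cup circle. Clamped at >= 0.
#'
#' @param disc,cup [circle()]s; cup center inside disc.
#' @param angle Degrees from +x, y down.
#' @return Width in pixels.
#' @export
rim_width_along <- function(disc, cup, angle) {
  d <- check_cup_in_disc(disc, cup)
  th <- angle * pi / 180
  if (d < 1e-12) {
    return(max(0, disc$r - cup$r))
  }
  phi <- atan2(cup$cy - disc$cy, cup$cx - disc$cx)
  a <- th - phi
  disc2 <- cup$r^2 - d^2 * sin(a)^2
  if (disc2 >= 0) {
    g <- d * cos(a) + sqrt(disc2)
    if (g >= 0) {
      return(max(0, disc$r - g))
    }
  }
  # ray misses the cup: distance from the disc boundary point to the cup
  px <- disc$cx + disc$r * cos(th)
  py <- disc$cy + disc$r * sin(th)
  max(0, sqrt((px - cup$cx)^2 + (py - cup$cy)^2) - cup$r)
}

#' Directional (ISNT) rim widths
#'
#' Rim widths along the four clinical meridians. Superior is the upward
#' image direction (decreasing row), inferior downward. Temporal/nasal are
#' horizontal and depend on laterality: for a right eye (OD) the temporal
#' side is image-left; for a left eye (OS) it is image-right. The
#' convention is overridable by flipping `laterality`.
#'
#' @param disc,cup [circle()]s.
#' @param laterality `"right"` (OD) or `"left"` (OS).
#' @return Object of class `"isnt_widths"`: list with `inferior`,
#'   `superior`, `nasal`, `temporal` (pixels) and `laterality`.
#' @export
isnt_widths <- function(disc, cup, laterality = c("right", "left")) {
  laterality <- match.arg(laterality)
  left_w <- rim_width_along(disc, cup, 180)
  right_w <- rim_width_along(disc, cup, 0)
  temporal <- if (laterality == "right") left_w else right_w
  nasal <- if (laterality == "right") right_w else left_w
  structure(list(
    inferior = rim_width_along(disc, cup, 90),
    superior = rim_width_along(disc, cup, 270),
    nasal = nasal,
    temporal = temporal,
    laterality = laterality
  ), class = "isnt_widths")
}

#' ISNT rule check
#'
#' A healthy neuroretinal rim typically satisfies
#' Inferior >= Superior >= Nasal >= Temporal; violation of this ordering is
#' a glaucoma indicator. Inequalities are non-strict.
#'
#' @param w An `"isnt_widths"` object.
#' @return Logical flag.
#' @export
isnt_satisfied <- function(w) {
  stopifnot(inherits(w, "isnt_widths"))
  w$inferior >= w$superior && w$superior >= w$nasal && w$nasal >= w$temporal
}

#' Angular extent of rim absence
#'
#' When the cup reaches or passes the disc boundary (`d + R_c > R_d`), the
#' rim is absent over an arc of the disc boundary. Seen from the disc
#' center, that arc subtends `2 * acos((R_d^2 + d^2 - R_c^2)/(2 d R_d))`
#' degrees (the chord geometry of the two intersecting circles); it is 0
#' when the cup stays inside (including internal tangency) and 360 when
#' the cup covers the entire disc boundary.
#'
#' @param disc,cup [circle()]s; cup center inside disc.
#' @return Degrees in [0, 360].
#' @export
rim_absence_extent <- function(disc, cup) {
  d <- check_cup_in_disc(disc, cup)
  if (d + cup$r <= disc$r) return(0)
  if (d < 1e-12) return(if (cup$r >= disc$r) 360 else 0)
  arg <- (disc$r^2 + d^2 - cup$r^2) / (2 * d * disc$r)
  arg <- clamp(arg, -1, 1)
  2 * acos(arg) * 180 / pi
}

#' All clinically relevant parameters from the fitted circles
#'
#' Bundles vertical CDR, RDR, the narrowest rim width and its meridian,
#' the four ISNT widths, and the rim-absence extent.
#'
#' @param disc,cup [circle()]s.
#' @param laterality `"right"` or `"left"`.
#' @return Object of class `"clinical_params"`.
#' @export
clinical_params <- function(disc, cup, laterality = c("right", "left")) {
  laterality <- match.arg(laterality)
  nr <- narrowest_rim(disc, cup)
  structure(list(
    cdr = vertical_cdr(disc, cup),
    rdr = rdr(disc, cup),
    narrowest_rim_width = nr$l,
    narrowest_meridian = nr$meridian,
    isnt = isnt_widths(disc, cup, laterality),
    rim_absence_extent = rim_absence_extent(disc, cup)
  ), class = "clinical_params")
}

#' @export
print.clinical_params <- function(x, ...) {
  cat(sprintf("CDR %.3f | RDR %.3f | narrowest rim %.2f px @ %.1f deg | no-rim extent %.1f deg\n",
              x$cdr, x$rdr, x$narrowest_rim_width, x$narrowest_meridian,
              x$rim_absence_extent))
  cat(sprintf("ISNT (%s eye): I %.2f, S %.2f, N %.2f, T %.2f -> %s\n",
              x$isnt$laterality, x$isnt$inferior, x$isnt$superior,
              x$isnt$nasal, x$isnt$temporal,
              if (isnt_satisfied(x$isnt)) "satisfied" else "violated"))
  invisible(x)
}
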