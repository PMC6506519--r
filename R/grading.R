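# DDLS and ICD-9 severity grading, and the image-to-report pipeline.

DDLS_BANDS <- c("S1_2", "S3", "S4", "S5", "S6", "S7", "S8", "S9_10")
SEVERITY_LEVELS <- c("normal", "moderate", "severe")

#' DDLS stage from clinical parameters
#'
#' Implements the revised 10-stage disc damage likelihood scale, driven by
#' RDR while any rim remains and by the angular extent of rim absence
#' otherwise. The published interval endpoints are rounded to two decimals
#' and leave small gaps; stages are implemented as contiguous half-open
#' intervals with boundaries at 0.10, 0.20 and 0.30 (each owned by the
#' lower stage) so that the classifier is total. Stages 1/2 and 9/10 are
#' reported merged, as the scale prints them.
#'
#' @param params A `"clinical_params"` object, or a numeric RDR (in which
#'   case `extent` supplies the rim-absence extent in degrees).
#' @param extent Rim-absence extent in degrees (ignored when `params` is a
#'   `"clinical_params"`).
#' @return One of `"S1_2", "S3", "S4", "S5", "S6", "S7", "S8", "S9_10"`.
#' @export
ddls_stage <- function(params, extent = 0) {
  if (inherits(params, "clinical_params")) {
    rdr_val <- params$rdr
    extent <- params$rim_absence_extent
  } else {
    rdr_val <- params
  }
  if (rdr_val < 0 || extent < 0 || extent > 360) {
    stop_invalid("invalid rdr/extent for DDLS staging")
  }
  if (rdr_val > 0 && extent == 0) {
    if (rdr_val >= 0.30) return("S1_2")
    if (rdr_val >= 0.20) return("S3")
    if (rdr_val >= 0.10) return("S4")
    return("S5")
  }
  # rim absent (or tangent): grade by angular extent
  if (extent < 45) return("S6")
  if (extent < 90) return("S7")
  if (extent <= 180) return("S8")
  "S9_10"
}

#' Three-stage severity from a DDLS stage
#'
#' Groups the DDLS stages into the internationally used three-stage scheme:
#' not definitely damaged (normal), asymptomatic glaucoma damage
#' (moderate), and glaucomatous disease/disability (severe). The default
#' span reads the scale's merged condition labels as starting at the row
#' they are printed on (normal = stages 1-4, moderate = 5-7, severe =
#' 8-10); `span = "narrow"` keeps only stages 1-2 normal.
#'
#' @param stage A DDLS band string from [ddls_stage()].
#' @param span `"printed"` (default) or `"narrow"`.
#' @return `"normal"`, `"moderate"`, or `"severe"`.
#' @export
ddls_three_stage <- function(stage, span = c("printed", "narrow")) {
  span <- match.arg(span)
  stage <- match.arg(stage, DDLS_BANDS)
  normal <- if (span == "printed") c("S1_2", "S3", "S4") else "S1_2"
  moderate <- if (span == "printed") c("S5", "S6", "S7") else c("S3", "S4", "S5", "S6", "S7")
  if (stage %in% normal) "normal" else if (stage %in% moderate) "moderate" else "severe"
}

#' Three-stage severity from the ICD-9 cup-to-disc rule
#'
#' CDR thresholds 0.5 and 0.8; the published ranges share their endpoints,
#' resolved here as half-open intervals `[0, 0.5]`, `(0.5, 0.8]`,
#' `(0.8, 1]`.
#'
#' @param cdr Cup-to-disc ratio in [0, 1].
#' @return `"normal"`, `"moderate"`, or `"severe"`.
#' @export
icd9_three_stage <- function(cdr) {
  if (!is.finite(cdr) || cdr < 0 || cdr > 1) {
    stop_invalid("CDR must lie in [0, 1], got ", cdr)
  }
  if (cdr <= 0.5) "normal" else if (cdr <= 0.8) "moderate" else "severe"
}

#' Collapse a three-stage severity to two stages
#'
#' @param severity `"normal"`, `"moderate"`, or `"severe"`.
#' @return `"normal"` or `"glaucomatous"`.
#' @export
two_stage <- function(severity) {
  severity <- match.arg(severity, SEVERITY_LEVELS)
  if (severity == "normal") "normal" else "glaucomatous"
}

#' Grade a fundus image end to end
#'
#' Runs the full prescreening pipeline: matched-filter localization,
#' multiscale active-disc segmentation of the optic disc (red channel),
#' Otsu-initialized active-disc segmentation of the cup (green channel),
#' clinical geometry, and severity grading by DDLS (RDR), ICD-9 (CDR) and
#' the ISNT rule. Any stage failure is re-signalled with the stage name and
#' the partial report attached to the condition.
#'
#' @param img H x W x 3 array in [0, 1] (see [read_fundus_image()]).
#' @param opts [fit_options()].
#' @param laterality `"right"` or `"left"`.
#' @param span DDLS three-stage span reading (see [ddls_three_stage()]).
#' @param provenance Optional list (e.g. input path, seed) copied into the
#'   report.
#' @return Object of class `"grading_report"`: disc and cup [circle()]s,
#'   `params` (clinical parameters), `ddls` stage band, `ddls_severity`,
#'   `icd9_severity`, `two_stage`, `isnt_two_stage`, the underlying fits,
#'   and provenance metadata.
#' @export
grade_image <- function(img, opts = fit_options(),
                        laterality = c("right", "left"),
                        span = c("printed", "narrow"),
                        provenance = list()) {
  laterality <- match.arg(laterality)
  span <- match.arg(span)
  partial <- list()
  run_stage <- function(stage, expr) {
    tryCatch(expr, error = function(e) {
      stop(errorCondition(
        sprintf("pipeline failed at stage '%s': %s", stage, conditionMessage(e)),
        stage = stage, partial_report = partial, parent = e,
        class = c("activedisc_stage_failure", "activedisc_error")))
    })
  }

  loc <- run_stage("localization", localize_disc(img, n_levels = opts$n_pyramid_levels))
  partial$localization <- loc
  disc_fit <- run_stage("disc_segmentation", segment_optic_disc(img, loc, opts))
  partial$disc_fit <- disc_fit
  disc <- disc_fit$object_circle
  cup_fit <- run_stage("cup_segmentation", segment_optic_cup(img, disc, opts))
  partial$cup_fit <- cup_fit
  cup <- cup_fit$object_circle
  params <- run_stage("clinical_geometry", clinical_params(disc, cup, laterality))
  stage_band <- run_stage("grading", ddls_stage(params))
  ddls_sev <- ddls_three_stage(stage_band, span)
  icd9_sev <- icd9_three_stage(min(params$cdr, 1))

  structure(list(
    disc = disc, cup = cup, params = params,
    ddls = stage_band,
    ddls_severity = ddls_sev,
    icd9_severity = icd9_sev,
    two_stage = two_stage(ddls_sev),
    isnt_two_stage = if (isnt_satisfied(params$isnt)) "normal" else "glaucomatous",
    localization = loc, disc_fit = disc_fit, cup_fit = cup_fit,
    provenance = c(provenance, list(version = package_version_string()))
  ), class = "grading_report")
}

#' @export
print.grading_report <- function(x, ...) {
  cat("glaucoma prescreening report\n")
  cat("  disc: "); print(x$disc)
  cat("  cup:  "); print(x$cup)
  cat("  "); print(x$params)
  cat(sprintf("  DDLS stage %s -> %s | ICD-9 (CDR): %s | two-stage: %s | ISNT: %s\n",
              x$ddls, x$ddls_severity, x$icd9_severity, x$two_stage,
              x$isnt_two_stage))
  invisible(x)
}

#' @export
summary.grading_report <- function(object, ...) {
  data.frame(
    disc_cx = object$disc$cx, disc_cy = object$disc$cy, disc_r = object$disc$r,
    cup_cx = object$cup$cx, cup_cy = object$cup$cy, cup_r = object$cup$r,
    cdr = object$params$cdr, rdr = object$params$rdr,
    rim_width_px = object$params$narrowest_rim_width,
    meridian_deg = object$params$narrowest_meridian,
    absence_deg = object$params$rim_absence_extent,
    ddls = object$ddls,
    ddls_severity = object$ddls_severity,
    icd9_severity = object$icd9_severity,
    two_stage = object$two_stage,
    isnt_two_stage = object$isnt_two_stage,
    stringsAsFactors = FALSE
  )
}
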