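# Readers, writers, run configuration and the batch driver.

#' Read a color fundus image
#'
#' Reads a PNG/TIFF/JPEG image into an H x W x 3 array of intensities in
#' [0, 1] (8- and 16-bit inputs are scaled by their bit depth; an alpha
#' channel, if present, is dropped). Grayscale inputs are rejected: disc
#' segmentation needs the red channel and cup segmentation the green one.
#'
#' @param path Path to the image file.
#' @return `height x width x 3` numeric array.
#' @export
read_fundus_image <- function(path) {
  if (!file.exists(path)) {
    stop_invalid("cannot read image: no such file: ", path)
  }
  img <- tryCatch(EBImage::readImage(path), error = function(e) {
    stop(errorCondition(
      sprintf("cannot decode '%s' as PNG/TIFF/JPEG: %s", path, conditionMessage(e)),
      class = c("activedisc_io_error", "activedisc_error")))
  })
  dat <- EBImage::imageData(img)  # EBImage stores x (col) first
  if (length(dim(dat)) == 2L) {
    stop(errorCondition(
      sprintf("'%s' is single-channel; a 3-channel color image is required", path),
      class = c("activedisc_channel_missing", "activedisc_error")))
  }
  if (dim(dat)[3] > 3L) dat <- dat[, , 1:3]
  if (dim(dat)[3] < 3L) {
    stop(errorCondition(
      sprintf("'%s' has %d channels; 3 are required", path, dim(dat)[3]),
      class = c("activedisc_channel_missing", "activedisc_error")))
  }
  clamp(aperm(dat, c(2, 1, 3)), 0, 1)
}

#' Write an RGB array (or mask) as an image file
#'
#' @param img H x W x 3 array in [0, 1], or an 0/1 matrix (written as 0/255
#'   grayscale).
#' @param path Output path; format from the extension (png/tiff/jpeg).
#' @export
write_fundus_image <- function(img, path) {
  dat <- if (is.matrix(img)) t(img * 1) else aperm(img, c(2, 1, 3))
  EBImage::writeImage(EBImage::Image(dat,
    colormode = if (is.matrix(img)) "Grayscale" else "Color"), path)
  invisible(path)
}

#' Serialize / read a circle as JSON
#'
#' Decimal-preserving round trip of `{cx, cy, r}` (plus any extra fields
#' supplied), used for fitted outlines and synthetic ground truth.
#'
#' @param circ A [circle()].
#' @param path Output path.
#' @param extra Named list of additional scalar fields.
#' @export
write_circle_json <- function(circ, path, extra = list()) {
  stopifnot(inherits(circ, "circle"))
  jsonlite::write_json(c(list(cx = circ$cx, cy = circ$cy, r = circ$r), extra),
                       path, auto_unbox = TRUE, digits = I(17))
  invisible(path)
}

#' @rdname write_circle_json
#' @export
read_circle_json <- function(path) {
  obj <- jsonlite::read_json(path)
  circle(obj$cx, obj$cy, obj$r)
}

#' Write synthetic ground truth to disk
#'
#' Writes the geometry as JSON (`{disc:{cx,cy,r}, cup:{cx,cy,r},
#' laterality}`) and the masks as 8-bit PNGs with values {0, 255}.
#'
#' @param truth The `truth` element of a [generate_fundus_image()] result.
#' @param stem Output path stem; writes `<stem>.json`,
#'   `<stem>_disc_mask.png`, `<stem>_cup_mask.png`.
#' @export
write_ground_truth <- function(truth, stem) {
  jsonlite::write_json(list(
    disc = list(cx = truth$disc$cx, cy = truth$disc$cy, r = truth$disc$r),
    cup = list(cx = truth$cup$cx, cy = truth$cup$cy, r = truth$cup$r),
    laterality = truth$laterality
  ), paste0(stem, ".json"), auto_unbox = TRUE, digits = I(17))
  write_fundus_image(truth$disc_mask, paste0(stem, "_disc_mask.png"))
  write_fundus_image(truth$cup_mask, paste0(stem, "_cup_mask.png"))
  invisible(stem)
}

#' Run configuration for the batch driver
#'
#' Reads a YAML key-value file and merges it over the defaults. Recognized
#' keys: `inputs` (path vector or glob), `output_dir`, `laterality`,
#' `seed`, `span`, plus any [fit_options()] field.
#'
#' @param path YAML file, or `NULL` for defaults.
#' @param overrides Named list applied after the file (CLI flags).
#' @return List of class `"run_config"`.
#' @export
read_run_config <- function(path = NULL, overrides = list()) {
  cfg <- list(inputs = character(), output_dir = ".", laterality = "right",
              span = "printed", seed = 1L)
  if (!is.null(path)) {
    if (!file.exists(path)) stop_invalid("config file not found: ", path)
    cfg <- utils::modifyList(cfg, yaml::read_yaml(path))
  }
  cfg <- utils::modifyList(cfg, overrides)
  opt_names <- names(formals(fit_options))
  cfg$fit_options <- do.call(fit_options, cfg[intersect(names(cfg), opt_names)])
  structure(cfg, class = "run_config")
}

#' Grade a batch of fundus images
#'
#' Processes images in sorted path order, writing one grading-report JSON
#' per image and a consolidated CSV. Failures are logged to stderr and
#' skipped; the summary records them so a CLI wrapper can exit non-zero.
#'
#' @param config A `"run_config"` from [read_run_config()], or a character
#'   vector of input paths.
#' @param output_dir Output directory (overrides the config's).
#' @return List with `table` (the consolidated data frame), `csv` (path),
#'   `n_failed`, and `failures` (named list of error messages).
#' @export
run_batch <- function(config, output_dir = NULL) {
  if (is.character(config)) {
    config <- read_run_config(overrides = list(inputs = config))
  }
  paths <- sort(unlist(lapply(config$inputs, function(p) {
    if (file.exists(p)) p else Sys.glob(p)
  })))
  if (length(paths) == 0L) stop_invalid("no input images")
  out_dir <- if (is.null(output_dir)) config$output_dir else output_dir
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)

  rows <- list()
  failures <- list()
  for (p in paths) {
    rep <- tryCatch({
      img <- read_fundus_image(p)
      grade_image(img, config$fit_options,
                  laterality = config$laterality, span = config$span,
                  provenance = list(path = p, seed = config$seed))
    }, error = function(e) e)
    if (inherits(rep, "error")) {
      message(sprintf("[activedisc] FAILED %s: %s", p, conditionMessage(rep)))
      failures[[p]] <- conditionMessage(rep)
      next
    }
    row <- cbind(data.frame(path = p, stringsAsFactors = FALSE), summary(rep))
    rows[[p]] <- row
    stem <- file.path(out_dir, sub("\\.[^.]+$", "", basename(p)))
    jsonlite::write_json(c(list(path = p), as.list(summary(rep))),
                         paste0(stem, "_report.json"),
                         auto_unbox = TRUE, digits = I(17))
  }
  tab <- if (length(rows)) do.call(rbind, c(rows, make.row.names = FALSE)) else
    data.frame()
  csv <- file.path(out_dir, "grading_reports.csv")
  utils::write.csv(tab, csv, row.names = FALSE)
  list(table = tab, csv = csv, n_failed = length(failures), failures = failures)
}
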