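#' Options for active-disc fitting
#'
#' @param max_iterations Iteration cap per pyramid level.
#' @param step_sizes Named per-parameter learning rates `c(R=, xc=, yc=)`.
#'   Effective steps are multiplied by the current scale R, which balances
#'   the units of the three gradients (the translational gradient scales
#'   like contrast/R).
#' @param momentum Classical momentum coefficient in [0, 1); 0 disables
#'   acceleration and enables a monotone backtracking safeguard.
#' @param nesterov Use the Nesterov look-ahead variant of acceleration.
#' @param tolerance Relative energy-change convergence threshold: the fit
#'   stops when `|dE| < tolerance * max(|E|, 1e-8)`.
#' @param n_boundary_samples Boundary samples per circle, or `NULL` for the
#'   scale-adaptive default `max(64, ceiling(2*pi*R))`.
#' @param n_pyramid_levels Pyramid depth used by the multiscale wrappers.
#' @param init_scale_frac Initial outer scale at full resolution as a
#'   fraction of `min(width, height)`. The default 0.25 starts the template
#'   strictly larger than a typical optic disc: the contrast energy is flat
#'   when both circles sit wholly inside a bright object, so descending from
#'   above is the reliable direction.
#' @return Object of class `"fit_options"`.
#' @export
fit_options <- function(max_iterations = 500L,
                        step_sizes = c(R = 2, xc = 2, yc = 2),
                        momentum = 0.9,
                        nesterov = FALSE,
                        tolerance = 1e-6,
                        n_boundary_samples = NULL,
                        n_pyramid_levels = 3L,
                        init_scale_frac = 0.25) {
  if (max_iterations < 1) stop_invalid("max_iterations must be >= 1")
  if (any(step_sizes <= 0)) stop_invalid("step sizes must be positive")
  if (momentum < 0 || momentum >= 1) stop_invalid("momentum must be in [0, 1)")
  if (tolerance <= 0) stop_invalid("tolerance must be positive")
  structure(list(max_iterations = as.integer(max_iterations),
                 step_sizes = step_sizes, momentum = momentum,
                 nesterov = isTRUE(nesterov), tolerance = tolerance,
                 n_boundary_samples = n_boundary_samples,
                 n_pyramid_levels = as.integer(n_pyramid_levels),
                 init_scale_frac = init_scale_frac),
            class = "fit_options")
}

#' Fit an active disc to an image channel by accelerated gradient descent
#'
#' Minimizes the normalized contrast energy `E = (E1 - 2*E2)/R^2` over the
#' three template parameters (scale R and center) by momentum gradient
#' descent, evaluating the energy with Green's-theorem boundary integrals
#' and the analytic boundary-integral gradient. At a minimum the *inner*
#' circle (radius `R/sqrt(2)`) coincides with the boundary of a bright
#' object on a darker surround, so the reported `object_circle` is the inner
#' circle.
#'
#' @param channel Numeric matrix (e.g. the red channel for the optic disc).
#' @param init [active_disc_params()] initialization; the center must lie
#'   inside the image.
#' @param opts [fit_options()].
#' @param project Optional function `params -> params` applied after every
#'   update (used to impose anatomical constraints, e.g. cup-in-disc).
#' @return Object of class `"active_disc_fit"` with elements `params`,
#'   `object_circle` ([circle()] of radius `R/sqrt(2)`), `energy`,
#'   `n_iterations`, `converged`, `status` (one of `"converged"`,
#'   `"max_iterations"`, `"no_progress"`, `"diverged"`), and `energy_trace`.
#' @examples
#' img <- matrix(0, 96, 96)
#' img[circle_mask(circle(48, 48, 20), 96, 96) == 1] <- 1
#' fit <- fit_active_disc(img, active_disc_params(40, 44, 44),
#'                        fit_options(momentum = 0))
#' fit$object_circle
#' @export
fit_active_disc <- function(channel, init, opts = fit_options(), project = NULL) {
  stopifnot(inherits(init, "active_disc_params"), inherits(opts, "fit_options"))
  h <- nrow(channel); w <- ncol(channel)
  if (init$xc < 0 || init$xc > w - 1 || init$yc < 0 || init$yc > h - 1) {
    stop_invalid("initialization center must lie inside the image")
  }
  row_cum <- row_cumulative(channel)
  nb <- function(p) {
    if (is.null(opts$n_boundary_samples)) default_boundary_n(p$R)
    else opts$n_boundary_samples
  }

  params <- init
  if (!is.null(project)) params <- project(params)
  E <- disc_energy_green(row_cum, params, nb(params))
  trace <- E
  v <- c(R = 0, xc = 0, yc = 0)
  step_scale <- 1        # adaptive global step multiplier
  status <- "max_iterations"
  converged <- FALSE
  it <- 0L

  for (it in seq_len(opts$max_iterations)) {
    eval_at <- params
    if (opts$nesterov && opts$momentum > 0) {
      eval_at <- active_disc_params(
        max(params$R + opts$momentum * v["R"], 1.01),
        params$xc + opts$momentum * v["xc"],
        params$yc + opts$momentum * v["yc"]
      )
    }
    g <- energy_gradient(channel, eval_at, nb(eval_at), row_cum = row_cum)

    if (it == 1L && max(abs(g)) < 1e-12 && abs(E) < 1e-10) {
      status <- "no_progress"
      break
    }

    # momentum step with adaptive restart: an energy increase (or an
    # invalid candidate) zeroes the velocity and halves the step scale, so
    # the accepted trace is non-increasing
    scale <- opts$step_sizes * params$R
    accepted <- FALSE
    for (bt in seq_len(40L)) {
      v_new <- opts$momentum * v - step_scale * scale *
        c(g[["dR"]], g[["dxc"]], g[["dyc"]])
      names(v_new) <- c("R", "xc", "yc")
      cand <- list(R = params$R + v_new[["R"]],
                   xc = params$xc + v_new[["xc"]],
                   yc = params$yc + v_new[["yc"]])
      valid <- is.finite(cand$R) && cand$R >= 2 &&
        cand$xc >= 0 && cand$xc <= w - 1 && cand$yc >= 0 && cand$yc <= h - 1
      if (valid) {
        cand <- active_disc_params(cand$R, cand$xc, cand$yc)
        if (!is.null(project)) cand <- project(cand)
        E_new <- disc_energy_green(row_cum, cand, nb(cand))
        if (E_new <= E + 1e-12) {
          accepted <- TRUE
          break
        }
      }
      v <- c(R = 0, xc = 0, yc = 0)  # restart acceleration
      step_scale <- step_scale / 2
      if (step_scale < 1e-8) break
    }
    if (!accepted) {
      if (max(abs(v)) == 0 && step_scale < 1e-8) {
        # no descent direction at any step size: at a (local) optimum
        status <- "converged"
        converged <- TRUE
      } else {
        status <- "diverged"
      }
      break
    }

    params <- cand
    v <- v_new
    step_scale <- min(1, step_scale * 1.5)
    dE <- E_new - E
    E <- E_new
    trace <- c(trace, E)
    if (abs(dE) < opts$tolerance * max(abs(E), 1e-8)) {
      status <- "converged"
      converged <- TRUE
      break
    }
  }

  structure(list(
    params = params,
    object_circle = circle(params$xc, params$yc, inner_radius(params)),
    energy = E,
    n_iterations = it,
    converged = converged,
    status = status,
    energy_trace = trace
  ), class = "active_disc_fit")
}

#' @export
print.active_disc_fit <- function(x, ...) {
  cat(sprintf("active-disc fit (%s, %d iterations)\n", x$status, x$n_iterations))
  cat("  "); print(x$params)
  cat(sprintf("  object circle: (%.2f, %.2f) r = %.2f; energy = %.5f\n",
              x$object_circle$cx, x$object_circle$cy, x$object_circle$r, x$energy))
  invisible(x)
}

#' @export
coef.active_disc_fit <- function(object, ...) {
  c(R = object$params$R, xc = object$params$xc, yc = object$params$yc)
}

#' Plot an active-disc fit over an image
#'
#' @param x An `"active_disc_fit"`.
#' @param image Optional matrix or H x W x 3 array to draw under the outline.
#' @param ... Passed to [graphics::lines()].
#' @export
plot.active_disc_fit <- function(x, image = NULL, ...) {
  if (!is.null(image)) {
    if (is.matrix(image)) image <- array(rep(image, 3), c(dim(image), 3))
    h <- dim(image)[1]; w <- dim(image)[2]
    graphics::plot(NA, xlim = c(0, w - 1), ylim = c(h - 1, 0), asp = 1,
                   xlab = "x (px)", ylab = "y (px)")
    graphics::rasterImage(grDevices::as.raster(image), -0.5, h - 0.5, w - 0.5, -0.5)
  }
  t <- seq(0, 2 * pi, length.out = 256)
  oc <- x$object_circle
  graphics::lines(oc$cx + oc$r * cos(t), oc$cy + oc$r * sin(t), col = "green", ...)
  graphics::lines(x$params$xc + x$params$R * cos(t),
                  x$params$yc + x$params$R * sin(t), col = "yellow", lty = 2, ...)
  invisible(x)
}

#' Segment the optic disc with a multiscale active-disc fit
#'
#' Fits the active disc to the red channel coarse-to-fine: the fit runs at
#' the coarsest pyramid level starting from the matched-filter peak, and the
#' converged parameters (doubled) initialize each finer level up to full
#' resolution. The red channel is used because the optic disc is brightest
#' there and vessels are de-emphasized.
#'
#' @param img H x W x 3 array in [0, 1].
#' @param loc A `"localization"` from [localize_disc()], or `NULL` to run
#'   localization with defaults.
#' @param opts [fit_options()].
#' @return The full-resolution `"active_disc_fit"`, with an extra
#'   `level_fits` element (coarse-to-fine list) and `total_iterations`.
#' @export
segment_optic_disc <- function(img, loc = NULL, opts = fit_options()) {
  red <- get_channel(img, 1L)
  if (is.null(loc)) loc <- localize_disc(img, n_levels = opts$n_pyramid_levels)
  L <- opts$n_pyramid_levels
  pyr <- build_pyramid(red, L)
  down <- 2^(L - 1L)

  R0 <- opts$init_scale_frac * min(dim(red)) / down
  params <- active_disc_params(R0, loc$peak[["x"]] / down, loc$peak[["y"]] / down)

  level_fits <- vector("list", L)
  total_it <- 0L
  fit <- NULL
  for (k in L:1) {
    fit <- fit_active_disc(pyr$levels[[k]], params, opts)
    level_fits[[k]] <- fit
    total_it <- total_it + fit$n_iterations
    if (fit$status == "diverged") break
    if (k > 1) {
      params <- active_disc_params(fit$params$R * 2,
                                   fit$params$xc * 2, fit$params$yc * 2)
    }
  }
  fit$level_fits <- level_fits
  fit$total_iterations <- total_it
  fit
}
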