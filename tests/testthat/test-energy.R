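test_that("boundary samples follow the two-circle template parameterization", {
  p <- active_disc_params(1, 0, 0)
  pts <- boundary_samples(p, "outer", 4)
  # t = pi/2, pi, 3pi/2, 2pi
  expect_equal(unname(pts),
               cbind(c(0, -1, 0, 1), c(1, 0, -1, 0)), tolerance = 1e-12)

  p2 <- active_disc_params(2, 5, 5)
  pts2 <- boundary_samples(p2, "inner", 1000)
  d <- sqrt((pts2[, 1] - 5)^2 + (pts2[, 2] - 5)^2)
  expect_true(all(abs(d - sqrt(2)) < 1e-12))

  expect_error(boundary_samples(p, "outer", 2),
               class = "activedisc_invalid_argument")
})

test_that("outer boundary polygon area converges to pi R^2 (shoelace)", {
  p <- active_disc_params(17.3, 4.2, -6.1)
  pts <- boundary_samples(p, "outer", 1e4)
  x <- pts[, 1]; y <- pts[, 2]
  nxt <- c(2:nrow(pts), 1L)
  area <- abs(sum(x * y[nxt] - x[nxt] * y)) / 2
  expect_lt(abs(area - pi * 17.3^2) / (pi * 17.3^2), 1e-3)
})

test_that("energy of a uniform image is zero (inner disc has half the area)", {
  img <- matrix(0.7, 101, 101)
  p <- active_disc_params(30, 50, 50)
  expect_lt(abs(disc_energy_direct(img, p)), 0.7 * 1e-2)
  expect_lt(abs(disc_energy_green(row_cumulative(img), p)), 0.7 * 1e-2)
})

test_that("aligned binary disc and annulus reach the closed-form energies", {
  for (a in c(30, 50)) {
    n <- 4 * a + 41
    cc <- (n - 1) / 2
    img <- binary_disc_image(n, cc, cc, a)
    p <- active_disc_params(sqrt(2) * a, cc, cc)
    # inner circle on the object: E -> -pi/2
    expect_lt(abs(disc_energy_direct(img, p) - (-pi / 2)) / (pi / 2), 0.02)
    # bright annulus between the two template circles: E -> +pi/2
    ann <- binary_disc_image(n, cc, cc, sqrt(2) * a) - img
    expect_lt(abs(disc_energy_direct(ann, p) - pi / 2) / (pi / 2), 0.02)
  }
})

test_that("Green's-theorem energy matches the direct oracle on smooth images", {
  set.seed(101)
  for (i in 1:25) {
    img <- smooth_field(200, 200)
    Fc <- row_cumulative(img)
    R <- runif(1, 35, 55)
    p <- active_disc_params(R, runif(1, 70, 130), runif(1, 70, 130))
    Ed <- disc_energy_direct(img, p)
    Eg <- disc_energy_green(Fc, p)
    expect_lt(abs(Eg - Ed), max(1e-3 * abs(Ed), 1e-2 * max(abs(img))))
  }
})

test_that("energy is exactly zero when the disc lies outside the image", {
  set.seed(3)
  img <- matrix(runif(64 * 64), 64, 64)
  Fc <- row_cumulative(img)
  expect_identical(disc_energy_green(Fc, active_disc_params(10, -40, 30)), 0)
  expect_identical(disc_energy_green(Fc, active_disc_params(10, 30, 200)), 0)
})

test_that("degenerate templates and bad inputs are rejected", {
  img <- matrix(0.5, 32, 32)
  expect_error(disc_energy_direct(img, active_disc_params(0.5, 16, 16)),
               class = "activedisc_degenerate_template")
  expect_error(disc_energy_green(1:10, active_disc_params(5, 16, 16)),
               class = "activedisc_invalid_argument")
})

test_that("analytic gradient matches central finite differences", {
  set.seed(202)
  h <- 0.1
  for (i in 1:15) {
    img <- smooth_field(200, 200)
    Fc <- row_cumulative(img)
    R <- runif(1, 35, 55)
    p <- active_disc_params(R, runif(1, 70, 130), runif(1, 70, 130))
    n <- max(64, ceiling(2 * pi * R))
    g <- energy_gradient(img, p, n, row_cum = Fc)
    fd <- c(
      (disc_energy_green(Fc, active_disc_params(R + h, p$xc, p$yc), n) -
       disc_energy_green(Fc, active_disc_params(R - h, p$xc, p$yc), n)) / (2 * h),
      (disc_energy_green(Fc, active_disc_params(R, p$xc + h, p$yc), n) -
       disc_energy_green(Fc, active_disc_params(R, p$xc - h, p$yc), n)) / (2 * h),
      (disc_energy_green(Fc, active_disc_params(R, p$xc, p$yc + h), n) -
       disc_energy_green(Fc, active_disc_params(R, p$xc, p$yc - h), n)) / (2 * h))
    expect_lt(max(abs(g - fd) / pmax(abs(fd), 0.05 * max(abs(fd)))), 0.05)
  }
})

test_that("gradient vanishes on uniform images and at the symmetric optimum", {
  img <- matrix(0.6, 101, 101)
  p <- active_disc_params(25, 50, 50)
  g <- energy_gradient(img, p)
  expect_lt(max(abs(g)), 1e-6 * 0.6 * 25)

  a <- 30; n <- 161; cc <- 80
  img2 <- binary_disc_image(n, cc, cc, a)
  g2 <- energy_gradient(img2, active_disc_params(sqrt(2) * a, cc, cc))
  expect_lt(abs(g2[["dxc"]]), 5e-3)
  expect_lt(abs(g2[["dyc"]]), 5e-3)
})
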