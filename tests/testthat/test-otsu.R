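test_that("four equal spikes are separated one level per class", {
  v <- rep(c(0, 85, 170, 255) / 255, each = 40)
  ts <- otsu_multilevel(v, 4)
  expect_length(ts$thresholds, 3L)
  expect_true(ts$thresholds[1] > 0 && ts$thresholds[1] < 85 / 255)
  expect_true(ts$thresholds[2] > 85 / 255 && ts$thresholds[2] < 170 / 255)
  expect_true(ts$thresholds[3] > 170 / 255 && ts$thresholds[3] < 1)
  # and the DP matches the exhaustive search on this histogram's classes
  counts <- tabulate(pmin(floor(v * 256), 255) + 1L, nbins = 256L)
  ex <- otsu_exhaustive(counts, 4)
  expect_equal(ts$between_class_variance, ex$objective)
})

test_that("binary Otsu separates a two-level image", {
  v <- c(rep(0.2, 60), rep(0.8, 40))
  ts <- otsu_multilevel(v, 2)
  expect_true(ts$thresholds > 0.2 && ts$thresholds < 0.8)
  expect_error(otsu_multilevel(rep(0.5, 100), 2),
               class = "activedisc_degenerate_histogram")
})

test_that("the DP equals exhaustive search on random 256-bin histograms", {
  set.seed(13)
  for (i in 1:4) {
    counts <- runif(256)
    for (k in 2:4) {
      dp <- otsu_multilevel(counts, k)
      ex <- otsu_exhaustive(counts, k)
      expect_identical(dp$cut_bins, ex$cuts)
      expect_identical(dp$between_class_variance, ex$objective)
    }
  }
})

test_that("returned thresholds beat random threshold placements", {
  set.seed(14)
  counts <- runif(256) * rexp(256)
  dp <- otsu_multilevel(counts, 4)
  cost <- activedisc:::otsu_class_cost(counts)
  for (i in 1:1000) {
    cuts <- sort(sample(1:255, 3))
    obj <- ((cost(1, cuts[1]) + cost(cuts[1] + 1, cuts[2])) +
              cost(cuts[2] + 1, cuts[3])) + cost(cuts[3] + 1, 256)
    expect_lte(obj, dp$between_class_variance + 1e-12)
  }
})

test_that("coarse cup extraction finds the cup on a clean image", {
  spec <- synthetic_spec(noise_sigma = 0, n_vessels = 0, seed = 6)
  sf <- generate_fundus_image(spec)
  cc <- coarse_cup_mask(sf$image[, , 2], sf$truth$disc)
  expect_gte(dice_coefficient(cc$mask, sf$truth$cup_mask), 0.9)
  tc <- sf$truth$cup
  expect_lt(sqrt((cc$init$cx - tc$cx)^2 + (cc$init$cy - tc$cy)^2), 3)
})

test_that("a cup indistinguishable from the disc is flagged degenerate", {
  ints <- list(background = c(0.45, 0.30, 0.15),
               disc = c(0.85, 0.45, 0.20),
               cup = c(0.85, 0.45, 0.20))  # cup == disc in every channel
  spec <- synthetic_spec(channel_intensities = ints, noise_sigma = 0,
                         n_vessels = 0, seed = 2)
  sf <- generate_fundus_image(spec)
  # with no internal contrast the top class is the whole disc plateau: the
  # candidate spans the disc itself, the detectable cup-absent signature
  # (downstream CDR ~ 1)
  cc <- coarse_cup_mask(sf$image[, , 2], sf$truth$disc)
  expect_gt(cc$init$r, 0.8 * sf$truth$disc$r)
  expect_lt(sqrt((cc$init$cx - sf$truth$disc$cx)^2 +
                 (cc$init$cy - sf$truth$disc$cy)^2), 3)
})

test_that("of two bright blobs inside the disc the larger is selected", {
  green <- matrix(0.4, 128, 128)
  disc <- circle(64, 64, 40)
  green[circle_mask(disc, 128, 128) == 1] <- 0.45
  green[circle_mask(circle(50, 60, 10), 128, 128) == 1] <- 0.8  # larger
  green[circle_mask(circle(85, 70, 5), 128, 128) == 1] <- 0.8   # smaller
  cc <- coarse_cup_mask(green, disc, 2, close_radius = 0)
  expect_lt(sqrt((cc$init$cx - 50)^2 + (cc$init$cy - 60)^2), 1)
  expect_lt(abs(cc$init$r - 10) / 10, 0.1)
})

test_that("cup segmentation recovers the truth and respects containment", {
  sf <- generate_fundus_image(synthetic_spec(seed = 11))
  disc_fit <- segment_optic_disc(sf$image)
  cup <- segment_optic_cup(sf$image, disc_fit$object_circle)
  h <- dim(sf$image)[1]; w <- dim(sf$image)[2]
  expect_gte(dice_coefficient(circle_mask(cup$object_circle, h, w),
                              sf$truth$cup_mask), 0.85)
  d <- sqrt((cup$object_circle$cx - disc_fit$object_circle$cx)^2 +
            (cup$object_circle$cy - disc_fit$object_circle$cy)^2)
  expect_lte(d, disc_fit$object_circle$r)
})

test_that("a concentric cup is recovered concentric", {
  spec <- synthetic_spec(cup_offset_fraction_range = c(0, 0),
                         cup_radius_fraction_range = c(0.5, 0.5), seed = 9)
  sf <- generate_fundus_image(spec)
  cup <- segment_optic_cup(sf$image, sf$truth$disc)
  expect_lt(sqrt((cup$object_circle$cx - sf$truth$disc$cx)^2 +
                 (cup$object_circle$cy - sf$truth$disc$cy)^2), 2)
})

test_that("cup recovery survives a corrupted initialization (basin test)", {
  sf <- generate_fundus_image(synthetic_spec(seed = 15))
  tc <- sf$truth$cup
  green <- sf$image[, , 2]
  init <- active_disc_params(sqrt(2) * tc$r, tc$cx + 5 / sqrt(2), tc$cy + 5 / sqrt(2))
  fit <- fit_active_disc(green, init)
  expect_lt(sqrt((fit$object_circle$cx - tc$cx)^2 +
                 (fit$object_circle$cy - tc$cy)^2), 2)
})
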