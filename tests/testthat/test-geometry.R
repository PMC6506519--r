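test_that("narrowest rim follows the center-line geometry", {
  # concentric template ratio
  nr <- narrowest_rim(circle(0, 0, 1), circle(0, 0, 1 / sqrt(2)))
  expect_equal(nr$l, 1 - 1 / sqrt(2), tolerance = 1e-12)
  expect_equal(nr$meridian, 0)  # undefined -> 0 by convention

  nr2 <- narrowest_rim(circle(0, 0, 100), circle(20, 0, 40))
  expect_equal(nr2$l, 40, tolerance = 1e-12)
  expect_equal(nr2$meridian, 0, tolerance = 1e-12)

  # rim fully absent along the meridian
  expect_equal(narrowest_rim(circle(0, 0, 100), circle(40, 0, 70))$l, 0)

  expect_error(narrowest_rim(circle(0, 0, 10), circle(20, 0, 5)),
               class = "activedisc_invalid_geometry")
})

test_that("narrowest rim equals the dense direction-sampling minimum", {
  set.seed(55)
  for (i in 1:200) {
    pr <- random_circle_pair()
    nr <- narrowest_rim(pr$disc, pr$cup)
    bf <- narrowest_rim_sampled(pr$disc, pr$cup)
    expect_lt(abs(nr$l - bf$l), 1e-6 * max(1, pr$disc$r))
  }
})

test_that("vertical CDR reduces to the radius ratio", {
  expect_equal(vertical_cdr(circle(0, 0, 100), circle(10, 5, 40)), 0.4)
  expect_equal(vertical_cdr(circle(0, 0, 7), circle(0, 0, 7)), 1.0)
  expect_equal(vertical_cdr(circle(0, 0, 1), circle(0, 0, 1 / sqrt(2))),
               1 / sqrt(2), tolerance = 1e-12)
})

test_that("RDR normalizes the narrowest rim by the disc diameter", {
  expect_equal(rdr(circle(0, 0, 100), circle(20, 0, 40)), 0.2, tolerance = 1e-12)
  # point cup, concentric: rdr tends to its supremum 0.5
  expect_equal(rdr(circle(0, 0, 100), circle(0, 0, 1e-9)), 0.5,
               tolerance = 1e-6)
  expect_equal(rdr(circle(0, 0, 100), circle(40, 0, 70)), 0)
  # bounded in [0, 0.5) for random valid pairs; exact concentric identity
  set.seed(66)
  for (i in 1:200) {
    pr <- random_circle_pair()
    r <- rdr(pr$disc, pr$cup)
    expect_gte(r, 0); expect_lt(r, 0.5)
  }
  expect_equal(rdr(circle(3, 4, 80), circle(3, 4, 20)), (1 - 20 / 80) / 2)
})

test_that("directional rim widths are consistent with the narrowest rim", {
  d <- circle(0, 0, 100); cp <- circle(20, 0, 40)
  # concentric: constant width at every angle
  for (a in c(0, 33, 90, 200)) {
    expect_equal(rim_width_along(circle(0, 0, 100), circle(0, 0, 40), a), 60)
  }
  expect_equal(rim_width_along(d, cp, 0), 40, tolerance = 1e-12)   # meridian
  expect_equal(rim_width_along(d, cp, 180), 80, tolerance = 1e-12) # opposite
  # minimum of rim_width_along over a direction grid equals the narrowest
  # rim, up to the quadratic sampling bound of the grid
  set.seed(77)
  for (i in 1:50) {
    pr <- random_circle_pair()
    th <- seq(0, 360, length.out = 721)[-721]
    widths <- vapply(th, function(a) rim_width_along(pr$disc, pr$cup, a),
                     numeric(1))
    l <- narrowest_rim(pr$disc, pr$cup)$l
    dd <- sqrt((pr$cup$cx - pr$disc$cx)^2 + (pr$cup$cy - pr$disc$cy)^2)
    bound <- 0.5 * dd * (1 + dd / pr$cup$r) * (pi / 720)^2 + 1e-9
    expect_gte(min(widths), l - 1e-9)
    expect_lt(min(widths) - l, bound)
  }
})

test_that("ISNT widths map laterality onto the horizontal directions", {
  d <- circle(0, 0, 100)
  cp <- circle(0, 0, 40)
  w <- isnt_widths(d, cp, "right")
  expect_equal(unlist(w[c("inferior", "superior", "nasal", "temporal")]),
               c(inferior = 60, superior = 60, nasal = 60, temporal = 60))
  expect_true(isnt_satisfied(w))

  # cup shifted toward image-left: for a right eye that is the temporal side
  cp2 <- circle(-20, 0, 40)
  wr <- isnt_widths(d, cp2, "right")
  expect_lt(wr$temporal, wr$nasal)
  wl <- isnt_widths(d, cp2, "left")
  expect_equal(wr$temporal, wl$nasal)
  expect_equal(wr$nasal, wl$temporal)
  expect_equal(wr$superior, wl$superior)
})

test_that("the ISNT rule uses non-strict ordering", {
  mk <- function(i, s, n, t) structure(
    list(inferior = i, superior = s, nasal = n, temporal = t,
         laterality = "right"), class = "isnt_widths")
  expect_true(isnt_satisfied(mk(4, 3, 2, 1)))
  expect_false(isnt_satisfied(mk(1, 2, 3, 4)))
  expect_true(isnt_satisfied(mk(2, 2, 2, 2)))
})

test_that("rim-absence extent matches the chord formula and the sampler", {
  expect_equal(rim_absence_extent(circle(0, 0, 100), circle(30, 0, 40)), 0)
  expect_equal(rim_absence_extent(circle(0, 0, 100), circle(30, 0, 70)), 0)
  ext <- rim_absence_extent(circle(0, 0, 100), circle(40, 0, 70))
  expect_equal(ext, 2 * acos(0.8375) * 180 / pi, tolerance = 1e-10)
  expect_equal(round(ext, 2), 66.25)  # frozen from the dense sampling oracle

  set.seed(88)
  for (i in 1:150) {
    pr <- random_circle_pair()
    ext <- rim_absence_extent(pr$disc, pr$cup)
    expect_lt(abs(ext - rim_absence_sampled(pr$disc, pr$cup)), 0.5)
  }
})

test_that("clinical parameters compose the individual measures coherently", {
  d <- circle(0, 0, 100); cp <- circle(20, 0, 40)
  par <- clinical_params(d, cp, "right")
  expect_equal(par$cdr, 0.4)
  expect_equal(par$rdr, 0.2, tolerance = 1e-12)
  expect_equal(par$narrowest_rim_width, 40, tolerance = 1e-12)
  expect_equal(par$rim_absence_extent, 0)
  # invariant: positive absence extent forces a zero narrowest rim
  par2 <- clinical_params(circle(0, 0, 100), circle(40, 0, 70), "left")
  expect_gt(par2$rim_absence_extent, 0)
  expect_equal(par2$narrowest_rim_width, 0)
})
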