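phantom_fixture <- function(case = "stomach", seed = 5L) {
  ph <- generate_slice(phantom_spec(case, seed = seed))
  img <- rescale_intensities(ph$image)
  hs <- smooth_histogram(compute_histogram(img), 12L)
  v <- find_thresholds(slope_difference(hs, 20L))
  roles <- assign_threshold_roles(v, hs)
  list(ph = ph, img = img, roles = roles)
}

test_that("bone blobs split into flank ribs and a central spine", {
  fx <- phantom_fixture()
  bones <- segment_bones(fx$img, fx$roles$T1)
  cls <- classify_bone_blobs(bones, ncol(bones) / 2)
  expect_equal(nrow(cls$ribs), 5L)            # phantom draws 5 ribs
  expect_equal(nrow(cls$spine), 1L)
  # spine is the posterior central blob
  expect_gt(cls$spine$centroid_row, nrow(bones) * 0.7)
  expect_lt(max(cls$ribs$centroid_col), ncol(bones) / 2)
  # rib and spine masks are disjoint subsets of the bone mask
  expect_true(all(cls$rib_mask + cls$spine_mask <= bones))
  expect_equal(sum(cls$rib_mask * cls$spine_mask), 0L)

  two <- matrix(0L, 20, 40)
  two[8:12, 3:6] <- 1L; two[8:12, 25:30] <- 1L
  cls2 <- classify_bone_blobs(two, 20)
  expect_equal(nrow(cls2$ribs), 1L)
  expect_equal(cls2$spine$area, 30)

  left_only <- matrix(0L, 20, 40)
  left_only[3:5, 2:4] <- 1L; left_only[10:12, 2:4] <- 1L
  expect_error(classify_bone_blobs(left_only, 35), "no spine candidate")
  expect_error(classify_bone_blobs(matrix(0L, 5, 5), 2), "insufficient bone blobs")
})

test_that("rib curve fit recovers exact, collinear and noisy quadratics", {
  rows <- c(50, 120, 200)
  cols <- 0.01 * rows^2 - 2 * rows + 300
  cv <- fit_rib_curve(cbind(rows, cols))
  expect_equal(unname(cv[["c2"]]), 0.01, tolerance = 1e-9)
  expect_equal(unname(cv[["c1"]]), -2, tolerance = 1e-9)
  expect_equal(unname(cv[["c0"]]), 300, tolerance = 1e-9)

  lin <- fit_rib_curve(cbind(c(10, 60, 110, 160), 5 + 0.3 * c(10, 60, 110, 160)))
  expect_equal(unname(lin[["c2"]]), 0, tolerance = 1e-9)
  expect_equal(unname(lin[["c1"]]), 0.3, tolerance = 1e-9)

  set.seed(71)
  r8 <- seq(20, 190, length.out = 8)
  c8 <- 0.002 * r8^2 - 0.5 * r8 + 80 + rnorm(8, 0, 2)
  got <- fit_rib_curve(cbind(r8, c8))
  B <- cbind(r8^2, r8, 1)
  oracle <- solve(t(B) %*% B, t(B) %*% c8)
  expect_equal(unname(unclass(got)), as.vector(oracle), tolerance = 1e-9)

  expect_error(fit_rib_curve(cbind(c(1, 1, 1), c(2, 3, 4))), "distinct rows")
})

test_that("curve exclusion marks the half-region away from the interior point", {
  vert <- structure(c(c2 = 0, c1 = 0, c0 = 30.5), class = "rib_curve")
  m <- curve_exclusion_mask(vert, c(20, 60), interior_point = c(10, 50))
  expect_true(all(m[, 1:30] == 1L))
  expect_true(all(m[, 31:60] == 0L))
  # the two sides partition the frame
  m2 <- curve_exclusion_mask(vert, c(20, 60), interior_point = c(10, 5))
  expect_equal(m + m2, matrix(1L, 20, 60))

  off <- structure(c(c2 = 0, c1 = 0, c0 = -50), class = "rib_curve")
  expect_equal(sum(curve_exclusion_mask(off, c(20, 60), c(10, 30))), 0L)

  fx <- phantom_fixture()
  cn <- build_constraints(fx$img, fx$roles)
  lt <- fx$ph$masks$liver
  expect_gte(sum(lt * (1L - cn$curve_excluded)) / sum(lt), 0.95)
})

test_that("body segmentation reaches near-perfect overlap on the phantom", {
  fx <- phantom_fixture()
  body <- segment_body(fx$img, fx$roles$T2)
  expect_gte(dice_coefficient(body, fx$ph$masks$body), 0.98)
})

test_that("rib width is twice the maximal inscribed diamond radius", {
  rect <- matrix(0L, 20, 44); rect[8:13, 6:35] <- 1L   # 6 x 30 rib
  expect_equal(estimate_rib_width(rect), 6L)

  two <- matrix(0L, 40, 50)
  two[5:10, 5:40] <- 1L                       # width 6
  two[25:34, 5:40] <- 1L                      # width 10
  expect_equal(estimate_rib_width(two), 8L)

  fx <- phantom_fixture()
  bones <- segment_bones(fx$img, fx$roles$T1)
  cls <- classify_bone_blobs(bones, ncol(bones) / 2)
  w <- fx$ph$spec$rib_width
  expect_gte(estimate_rib_width(cls$rib_mask), w - 1L)
  expect_lte(estimate_rib_width(cls$rib_mask), w + 1L)
})

test_that("ring constraint equals body minus its n_c-fold erosion", {
  body <- matrix(0L, 50, 50)
  body[(row(body) - 25)^2 + (col(body) - 25)^2 <= 20^2] <- 1L

  expect_equal(sum(ring_constraint(body, 0L)), 0L)
  expect_equal(sum(ring_constraint(matrix(0L, 10, 10), 5L)), 0L)

  ring <- ring_constraint(body, 5L)
  er <- body
  for (i in 1:5) er <- oracle_erode_shift(er, se_diamond(1L))
  expect_equal(ring, body * (1L - er))
  expect_true(all(ring <= body))
})

test_that("organ pipeline merges the split stomach and stays right of the spine", {
  fx <- phantom_fixture("stomach")
  cn <- build_constraints(fx$img, fx$roles)
  stm <- cn$stomach
  expect_equal(max(label_components(stm)), 1L)          # two lobes merged
  expect_gte(dice_coefficient(stm, fx$ph$masks$organ), 0.85)
  st <- component_stats(label_components(stm))
  expect_gt(st$centroid_col, cn$bone_classes$spine$centroid_col)

  # nothing at or above T3 -> empty mask
  img_low <- matrix(50L, 40, 40)
  empty <- segment_stomach(img_low, 200, matrix(0L, 40, 40), 20)
  expect_equal(sum(empty), 0L)

  # organ at liver intensity (heart case): organ threshold falls back to T1,
  # so the organ constraint is empty or negligible
  fxh <- phantom_fixture("heart")
  cnh <- build_constraints(fxh$img, fxh$roles)
  expect_lte(sum(cnh$stomach), 0.01 * sum(cnh$body))
})

test_that("constraint masks are bit-reproducible", {
  fx <- phantom_fixture()
  c1 <- build_constraints(fx$img, fx$roles)
  c2 <- build_constraints(fx$img, fx$roles)
  expect_identical(c1$curve_excluded, c2$curve_excluded)
  expect_identical(c1$ring, c2$ring)
  expect_identical(c1$stomach, c2$stomach)
})
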