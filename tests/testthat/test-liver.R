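test_that("constrained liver segmentation is the per-pixel conjunction", {
  set.seed(81)
  img <- matrix(sample.int(255, 1600, replace = TRUE), 40, 40)
  zeros <- matrix(0L, 40, 40)
  none <- list(curve_excluded = zeros, ring = zeros, stomach = zeros)
  expect_equal(segment_liver(img, 120, none), binarize(img, 120))

  all_ring <- list(curve_excluded = zeros, ring = matrix(1L, 40, 40),
                   stomach = zeros)
  expect_equal(sum(segment_liver(img, 120, all_ring)), 0L)

  cons <- list(curve_excluded = matrix(rbinom(1600, 1, 0.2), 40, 40),
               ring = matrix(rbinom(1600, 1, 0.2), 40, 40),
               stomach = matrix(rbinom(1600, 1, 0.2), 40, 40))
  got <- segment_liver(img, 120, cons)
  oracle <- matrix(0L, 40, 40)
  for (i in 1:40) for (j in 1:40) {
    oracle[i, j] <- as.integer(img[i, j] >= 120 &&
                                 cons$curve_excluded[i, j] < 1L &&
                                 cons$ring[i, j] < 1L &&
                                 cons$stomach[i, j] < 1L)
  }
  expect_equal(got, oracle)
  expect_true(all(got <= binarize(img, 120)))
})

test_that("liver cleaning keeps one blob and rejects empty masks", {
  blob <- matrix(0L, 60, 60)
  blob[(row(blob) - 30)^2 + (col(blob) - 30)^2 <= 18^2] <- 1L
  speckles <- blob
  set.seed(82)
  pts <- cbind(sample(60, 20, replace = TRUE), sample(60, 20, replace = TRUE))
  pts <- pts[speckles[pts] == 0L, , drop = FALSE]
  speckles[pts] <- 1L
  cleaned <- clean_liver(speckles)
  expect_equal(max(label_components(cleaned)), 1L)
  # the opening rounds the disk boundary at most by its radius-8 band
  expect_gte(sum(cleaned * blob) / sum(blob), 0.95)
  expect_true(all(cleaned <= morphological_merge(blob, 1L)))

  expect_error(clean_liver(matrix(0L, 30, 30)), "no liver found")
})

test_that("boundary tracing yields an ordered closed pixel contour", {
  sq <- matrix(0L, 14, 14); sq[3:12, 3:12] <- 1L
  b <- extract_boundary(sq)
  expect_equal(nrow(b), 36L)                  # 4 * 10 - 4 perimeter pixels
  expect_true(all(sq[unclass(b)] == 1L))
  steps <- sqrt(rowSums((unclass(b) - unclass(b)[c(2:36, 1), ])^2))
  expect_true(all(steps <= sqrt(2) + 1e-9))   # 8-connected closed walk

  px <- matrix(0L, 5, 5); px[2, 4] <- 1L
  expect_equal(as.vector(extract_boundary(px)), c(2, 4))

  two <- matrix(0L, 10, 10); two[2, 2] <- 1L; two[8, 8] <- 1L
  expect_error(extract_boundary(two), "single component")
  expect_error(extract_boundary(matrix(0L, 4, 4)), "empty")
})

test_that("boundary pixels agree with an independent contour tracer", {
  ph <- generate_slice(phantom_spec("stomach", seed = 3))
  liver <- ph$masks$liver
  b <- extract_boundary(liver)
  oc <- EBImage::ocontour(liver)[[1]] + 1L    # oracle; 0-based coordinates
  expect_setequal(paste(b[, 1], b[, 2]), paste(oc[, 1], oc[, 2]))
})

test_that("re-rasterizing the traced contour recovers the mask", {
  ph <- generate_slice(phantom_spec("kidney", seed = 9))
  liver <- ph$masks$liver
  b <- unclass(extract_boundary(liver))
  canvas <- matrix(0L, nrow(liver), ncol(liver))
  canvas[b] <- 1L
  filled <- as.matrix(EBImage::fillHull(canvas))
  agreement <- sum(filled == liver) / length(liver)
  expect_gte(agreement, 0.99)
})

test_that("contour spline smoothing honours its limits", {
  circ <- resample_contour(circle_contour(40), 200L)
  expect_identical(unclass(smooth_contour(circ, 0)), unclass(circ))

  sm <- smooth_contour(circ, 0.5)
  expect_lt(max(abs(unclass(sm) - unclass(circ))), 0.5)

  seg <- cbind(seq(0, 30, length.out = 12), seq(0, 60, length.out = 12))
  for (a in c(0.3, 0.9)) {
    out <- smooth_contour(seg, a, closed = FALSE)
    expect_equal(as.vector(unclass(out)), as.vector(seg), tolerance = 1e-8)
  }
  expect_error(smooth_contour(circ, 1), "alpha")
  expect_error(smooth_contour(circ[1:3, ], 0.5), ">= 4 vertices")
})

test_that("full slice processing recovers the phantom liver in every case", {
  for (case in c("stomach", "kidney")) {
    ph <- generate_slice(phantom_spec(case, seed = 13))
    res <- process_slice(ph$image)
    expect_false(res$empty)
    expect_gte(dice_coefficient(res$liver, ph$masks$liver), 0.90)
    # the constrained (uncleaned) result is inside the plain threshold mask
    img <- rescale_intensities(ph$image)
    raw <- segment_liver(img, res$thresholds$T4, res$constraints)
    expect_true(all(raw <= binarize(img, res$thresholds$T4)))
    # smoothing must not inflate the boundary of a convex-ish liver
    per <- function(cc) {
      p <- unclass(cc)
      sum(sqrt(rowSums((p - p[c(2:nrow(p), 1), ])^2)))
    }
    expect_lte(per(res$boundary_smoothed), 1.05 * per(res$boundary))
  }
})

test_that("slice processing is deterministic and safe on blank slices", {
  ph <- generate_slice(phantom_spec("heart", seed = 17))
  r1 <- process_slice(ph$image)
  r2 <- process_slice(ph$image)
  expect_identical(r1$liver, r2$liver)
  expect_identical(unclass(r1$boundary), unclass(r2$boundary))

  blank <- process_slice(matrix(7, 32, 32))
  expect_true(blank$empty)
  expect_match(blank$flags, "degenerate")

  noisy_flat <- process_slice(matrix(stats::runif(1024, 0, 4096), 32, 32))
  expect_s3_class(noisy_flat, "slice_result")  # no exception escapes
})
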