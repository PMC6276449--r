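test_that("intensity rescaling maps the observed range onto 1..255", {
  expect_equal(as.vector(rescale_intensities(matrix(c(0, 1000), 1))), c(1L, 255L))

  const <- rescale_intensities(matrix(42, 4, 4))
  expect_true(all(const == 255L))
  expect_true(isTRUE(attr(const, "degenerate")))

  set.seed(101)
  raw <- matrix(sample.int(4096, 64 * 64, replace = TRUE) - 1L, 64, 64)
  got <- rescale_intensities(raw)
  oracle <- round(1 + 254 * (raw - min(raw)) / (max(raw) - min(raw)))
  expect_equal(as.vector(got), as.vector(oracle))
  expect_equal(got[which.min(raw)], 1L)
  expect_equal(got[which.max(raw)], 255L)
  ord <- order(raw)
  expect_true(all(diff(got[ord]) >= 0))       # monotone order preserved

  expect_error(rescale_intensities(matrix(numeric(0), 0, 0)), "empty")
})

test_that("histogram is max-normalized per intensity level", {
  img <- matrix(1:255, 255, 1)
  expect_equal(compute_histogram(img), rep(1, 255))

  img2 <- matrix(c(rep(100L, 10), rep(200L, 5)), ncol = 1)
  h <- compute_histogram(img2)
  expect_equal(h[100], 1)
  expect_equal(h[200], 0.5)
  expect_equal(sum(h != 0), 2)

  set.seed(7)
  img3 <- matrix(sample.int(255, 64 * 64, replace = TRUE), 64, 64)
  counts <- vapply(1:255, function(v) sum(img3 == v), numeric(1))
  expect_equal(compute_histogram(img3), counts / max(counts))
})

test_that("DFT band-limiting matches a direct-summation transform oracle", {
  spike <- rep(0, 255); spike[100] <- 1
  expect_equal(smooth_histogram(spike, 10), oracle_dft_smooth(spike, 10),
               tolerance = 1e-12)

  set.seed(11)
  h <- runif(255)
  expect_equal(smooth_histogram(h, 25), oracle_dft_smooth(h, 25),
               tolerance = 1e-12)
})

test_that("band-limit filter keeps DC, is idempotent and full-band is identity", {
  set.seed(12)
  h <- runif(255)
  expect_equal(smooth_histogram(h, 127), h, tolerance = 1e-9)
  expect_equal(smooth_histogram(rep(0.4, 255), 33), rep(0.4, 255), tolerance = 1e-12)
  for (W in c(3L, 12L, 60L)) {
    hs <- smooth_histogram(h, W)
    expect_equal(mean(hs), mean(h), tolerance = 1e-12)
    expect_equal(smooth_histogram(hs, W), hs, tolerance = 1e-9)
  }
  expect_error(smooth_histogram(h, 0), "1..127")
  expect_error(smooth_histogram(h, 128), "1..127")
})

test_that("line fit reproduces exact and noisy least-squares solutions", {
  x <- 1:10
  expect_equal(fit_line(x, 3 * x + 1), c(slope = 3, intercept = 1))
  expect_equal(unname(fit_line(c(2, 6), c(5, 13))), c(2, 1))

  set.seed(21)
  xn <- sort(runif(20, 0, 50)); yn <- 1.7 * xn - 4 + rnorm(20)
  expect_equal(fit_line(xn, yn), oracle_ols(xn, yn), tolerance = 1e-9)

  expect_error(fit_line(1, 2), ">= 2")
  expect_error(fit_line(c(3, 3), c(1, 2)), "distinct")
})

test_that("slope difference is zero for affine histograms and matches two-fit oracle", {
  h_lin <- (1:255) / 300
  s <- slope_difference(h_lin, 15)
  expect_equal(s$index, 16:240)
  expect_true(all(abs(s$values) < 1e-12))

  # V-shaped histogram: arms -m then +m meeting at the vertex; with the
  # boundary-as-valley sign convention s(vertex) = -2m (magnitude 2m)
  m <- 0.004; c0 <- 128
  hv <- ifelse(1:255 <= c0, m * (c0 - 1:255), m * (1:255 - c0))
  sv <- slope_difference(hv, 10)
  expect_equal(sv$values[sv$index == c0], -2 * m, tolerance = 1e-12)
  expect_equal(find_thresholds(sv)[1], c0)

  set.seed(31)
  hr <- smooth_histogram(runif(255), 20)
  sr <- slope_difference(hr, 15)
  N <- 15L
  for (i in sample(sr$index, 25)) {
    al <- oracle_ols(seq_len(N), hr[(i - N + 1L):i])[["slope"]]
    ar <- oracle_ols(seq_len(N), hr[i:(i + N - 1L)])[["slope"]]
    expect_equal(sr$values[sr$index == i], al - ar, tolerance = 1e-9)
  }
  expect_error(slope_difference(hr, 1), "2..100")
})

test_that("valley detection matches an exhaustive scan and handles plateaus", {
  fake_sdd <- function(vals, N = 20L) {
    structure(list(values = vals, index = seq_along(vals) + N, window_N = N),
              class = "slope_difference")
  }

  expect_length(find_thresholds(fake_sdd(seq(-1, 1, length.out = 100))), 0)

  idx <- 21:235
  vals <- cos(2 * pi * idx / 64)
  v <- find_thresholds(fake_sdd(vals), merge_distance = 0L)
  # exhaustive scan oracle: strict interior minima with negative value
  oracle <- idx[which(vals < 0 &
                        vals <= c(Inf, head(vals, -1)) &
                        vals <= c(tail(vals, -1), Inf))]
  oracle <- oracle[oracle > min(idx) & oracle < max(idx)]
  expect_equal(as.integer(v), oracle)

  # plateau: central index, floor of midpoint
  vp <- rep(0, 60); vp[25:28] <- -1
  expect_equal(as.integer(find_thresholds(fake_sdd(vp))), 26L + 20L)

  # merge rule keeps the deeper of two close valleys
  vm <- rep(0, 60)
  vm[20] <- -0.5; vm[25] <- -0.9
  expect_equal(as.integer(find_thresholds(fake_sdd(vm), merge_distance = 8L)),
               45L)
  expect_equal(sort(as.integer(find_thresholds(fake_sdd(vm), merge_distance = 2L))),
               c(40L, 45L))
})

test_that("threshold roles follow rank order with liver as most populated class", {
  hs <- rep(0.001, 255)
  hs[60:100] <- 0.2     # body class
  hs[115:145] <- 0.8    # liver class (most populated between 110 and 150)
  hs[155:200] <- 0.3    # organ class
  roles <- assign_threshold_roles(c(40L, 110L, 150L, 210L), hs)
  expect_equal(roles$T2, 40L)
  expect_equal(roles$T4, 110L)
  expect_equal(roles$T3, 150L)
  expect_equal(roles$T1, 210L)

  r2 <- assign_threshold_roles(c(40L, 180L), hs)
  expect_equal(r2$T1, 180L)
  expect_equal(r2$T2, 40L)
  expect_equal(r2$T3, 40L)
  expect_equal(r2$T4, 40L)

  r3 <- assign_threshold_roles(c(40L, 110L, 210L), hs)
  expect_equal(r3$T4, 110L)
  expect_equal(r3$T3, 210L)   # upper neighbour absent -> T1

  expect_error(assign_threshold_roles(100L, hs), "insufficient pixel classes")
})

test_that("binarization matches the per-pixel rule and is monotone in T", {
  img <- matrix(rep(1:255, length.out = 900), 30, 30)
  expect_true(all(binarize(img, 1) == 1L))
  sat <- binarize(img, 255)
  expect_equal(which(sat == 1L), which(img == 255L))

  set.seed(41)
  img2 <- matrix(sample.int(255, 400, replace = TRUE), 20, 20)
  expect_equal(binarize(img2, 128), matrix((img2 >= 128) * 1L, 20, 20))
  counts <- vapply(c(1, 50, 128, 200, 255), function(T) sum(binarize(img2, T)),
                   numeric(1))
  expect_true(all(diff(counts) <= 0))
  expect_error(binarize(img2, 0), "1..255")
  expect_error(binarize(img2, 256), "1..255")
})

test_that("grid-search calibration returns the exhaustive-search optimum", {
  ph <- generate_slice(phantom_spec("stomach", seed = 5))
  one <- calibrate_sdd(list(ph$image), list(ph$masks$liver),
                       W_grid = 12L, N_grid = 20L)
  expect_equal(one$bandwidth_W, 12L)
  expect_equal(one$window_N, 20L)

  W_grid <- c(4L, 12L); N_grid <- c(20L, 60L)
  cal <- calibrate_sdd(list(ph$image), list(ph$masks$liver), W_grid, N_grid)
  # exhaustive oracle: independently score every cell
  scores <- sapply(W_grid, function(W) sapply(N_grid, function(N) {
    cfg <- default_config()
    cfg[["sdd.bandwidth_W"]] <- W; cfg[["sdd.window_N"]] <- N
    res <- process_slice(ph$image, cfg)
    if (res$empty) 0 else dice_coefficient(res$liver, ph$masks$liver)
  }))
  best <- which(scores == max(scores), arr.ind = TRUE)[1L, ]
  expect_equal(cal$window_N, N_grid[best[1L]])
  expect_equal(cal$bandwidth_W, W_grid[best[2L]])
  expect_equal(cal$mean_dice, max(scores), tolerance = 1e-12)

  expect_error(calibrate_sdd(list(), list()), "non-empty")
})
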