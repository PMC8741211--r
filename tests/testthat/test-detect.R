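test_that("min_image matches constants and the brute-force oracle", {
  m <- MovieStack(array(7, c(6, 5, 1, 9)), 1, 9)
  expect_equal(min_image(m), array(7, c(6, 5, 1)))
  set.seed(2)
  m2 <- MovieStack(array(runif(10 * 8 * 2 * 12, 10, 50), c(10, 8, 2, 12)), 1, 9)
  expect_identical(min_image(m2), oracle_min_image(m2))
})

test_that("minimum image recovers the baseline of a noiseless movie exactly", {
  cfg <- noiseless(tiny_config(seed = 4))
  sim <- simulate_calyx_movie(cfg, fixed_layer(60))
  expect_equal(min_image(sim$movie)[, , 1], sim$ground_truth$baseline_img,
               tolerance = 0)
})

test_that("normalize_to_min follows its definition", {
  m <- MovieStack(array(100, c(4, 4, 1, 6)), 1, 9)
  n <- normalize_to_min(m)
  expect_true(all(n == 0))
  dat <- array(100, c(4, 4, 1, 6)); dat[2, 2, 1, 4] <- 150
  m2 <- MovieStack(dat, 1, 9)
  n2 <- normalize_to_min(m2, eps = 1e-9)
  expect_equal(max(n2), 0.5, tolerance = 1e-7)
  set.seed(2)
  m3 <- MovieStack(array(runif(9 * 7 * 2 * 8, 5, 20), c(9, 7, 2, 8)), 1, 9)
  mi <- min_image(m3)
  expect_equal(normalize_to_min(m3, mi, eps = 1e-4),
               oracle_normalize(m3, mi, 1e-4))
})

test_that("otsu_threshold separates classes and matches exhaustive search", {
  x <- c(rep(0, 40), rep(1, 60))
  thr <- otsu_threshold(x)
  expect_gt(thr, 0); expect_lt(thr, 1)
  set.seed(5)
  bim <- c(rnorm(300, 20, 5), rnorm(200, 200, 5))
  thr2 <- otsu_threshold(bim)
  expect_gt(thr2, 50); expect_lt(thr2, 170)
  expect_error(otsu_threshold(rep(3, 10)), "degenerate")
  for (s in 1:5) {
    set.seed(s)
    img <- matrix(rexp(64 * 64, 1 / 30) + rnorm(64 * 64, 50, 10), 64, 64)
    expect_equal(otsu_threshold(img), oracle_otsu(img))
  }
})

test_that("label_components uses 8-connectivity with contiguous labels", {
  m <- matrix(FALSE, 5, 5)
  m[1, 1] <- TRUE; m[2, 2] <- TRUE   # diagonal touch: one component
  m[5, 5] <- TRUE                    # far corner: second component
  lab <- label_components(m)
  expect_equal(lab[1, 1], lab[2, 2])
  expect_equal(sort(unique(as.vector(lab))), c(0L, 1L, 2L))
  ## column wrap guard: last row of col 1 and first row of col 2 not joined
  m2 <- matrix(FALSE, 4, 3)
  m2[4, 1] <- TRUE; m2[1, 2] <- TRUE
  expect_equal(max(label_components(m2)), 2L)
  ## blob areas preserved
  m3 <- matrix(FALSE, 10, 10); m3[3:5, 3:5] <- TRUE; m3[8:9, 8] <- TRUE
  lab3 <- label_components(m3)
  expect_equal(sort(tabulate(lab3[lab3 > 0])), c(2L, 9L))
})

test_that("null movies yield zero active ROIs", {
  cfg <- tiny_config(seed = 8, n_mg = 5L)
  sim <- simulate_calyx_movie(cfg, fixed_layer(50, active = 0))
  expect_equal(sum(sim$ground_truth$mg$active_Mch), 0)
  res <- analyze_movie(sim$movie, sim$protocol, register = FALSE)
  expect_true(all(res$summaries$active_roi_count == 0))
})

test_that("the size gate rejects specks but keeps MG-sized components", {
  ## hand-built: flat baseline, one MG-sized blob plus one hot pixel
  ny <- 40; nx <- 40; nt <- 30
  dat <- array(100, c(ny, nx, 1, nt))
  yy <- matrix(1:ny, ny, nx); xx <- matrix(1:nx, ny, nx, byrow = TRUE)
  g <- exp(-log(20) * (((yy - 15)^2 + (xx - 15)^2) / 3.5^2)^2)
  for (t in 16:22) dat[, , 1, t] <- 100 * (1 + 0.5 * g)
  dat[30, 30, 1, 16:22] <- 100 * (1 + 3)      # 1-px speck at 300%
  m <- MovieStack(dat, pixel_size_um = 0.85, frame_rate_hz = 9)
  tr <- data.frame(odour = "A", puff = 1L, onset = 15L, offset = 22L,
                   window_end = 30L)
  prot <- StimulusProtocol(tr, 10L, 9, n_frames = nt)
  rs <- detect_active_rois(m, prot, 1, region_mask = array(TRUE, c(ny, nx, 1)),
                           mask_erosion_px = 0L)
  expect_equal(nrow(rs$rois), 1L)
  expect_equal(rs$rois$centroid_y, 15, tolerance = 0.5)
  expect_equal(rs$rois$centroid_x, 15, tolerance = 0.5)
  expect_gte(rs$dropped["below"], 1)
})

test_that("detection is invariant to a global intensity scale", {
  cfg <- tiny_config(seed = 12, n_mg = 6L, field_px = c(40L, 40L))
  sim <- simulate_calyx_movie(cfg, fixed_layer(60))
  r1 <- analyze_movie(sim$movie, sim$protocol, register = FALSE)
  m2 <- MovieStack(sim$movie$data * 3.7, sim$movie$pixel_size_um,
                   sim$movie$frame_rate_hz)
  r2 <- analyze_movie(m2, sim$protocol, register = FALSE)
  expect_equal(r1$summaries$active_roi_count, r2$summaries$active_roi_count)
  expect_equal(r1$summaries$mean_peak, r2$summaries$mean_peak, tolerance = 1e-6)
})

test_that("raising amplitudes never loses true positives (noiseless)", {
  cfg <- noiseless(tiny_config(seed = 21, n_mg = 6L, field_px = c(48L, 48L)))
  detected_ids <- function(amp) {
    sim <- simulate_calyx_movie(cfg, fixed_layer(amp))
    res <- analyze_movie(sim$movie, sim$protocol, register = FALSE,
                         keep_roisets = TRUE)
    sc <- score_detection(res$roisets[[1]], sim$ground_truth)
    sc$sensitivity
  }
  s_low <- detected_ids(30)
  s_high <- detected_ids(90)
  expect_gte(s_high, s_low)
})
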