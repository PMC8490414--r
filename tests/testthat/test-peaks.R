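test_that("constant maps have no strict maxima and no detections", {
  g <- matrix(0.5, 8, 8)
  expect_equal(nrow(find_local_maxima(g)), 0)
  expect_equal(nrow(extract_detections(confidence_map(g),
                                       peak_params(tau = 0.1))), 0)
})

test_that("an isolated peak is found, plateau ties are not maxima", {
  g <- matrix(0, 5, 5)
  g[3, 3] <- 0.9  # cell (x=2, y=2), 0-based
  m <- find_local_maxima(g)
  expect_equal(m, data.frame(cell_x = 2L, cell_y = 2L, value = 0.9))
  g[3, 4] <- 0.9  # two-cell plateau: strict inequality fails for both
  expect_equal(nrow(find_local_maxima(g)), 0)
})

test_that("maxima agree with the exhaustive 4-neighbour scan", {
  set.seed(17)
  for (i in 1:10) {
    g <- matrix(runif(16 * 16), 16, 16)
    got <- find_local_maxima(g)
    want <- oracle_local_maxima(g)
    want <- want[order(want$cell_y, want$cell_x), ]
    rownames(want) <- NULL
    expect_equal(got, want)
  }
})

test_that("delta suppression keeps the stronger of two close peaks", {
  g <- matrix(0, 9, 9)
  g[5, 5] <- 0.9
  g[5, 7] <- 0.8  # 2 cells away; delta = 2 suppresses it (inclusive)
  det <- extract_detections(confidence_map(g), peak_params(0.35, 2))
  expect_equal(nrow(det), 1)
  expect_equal(det$score, 0.9)
  g2 <- matrix(0, 9, 9)
  g2[3, 2] <- 0.9
  g2[3, 7] <- 0.8  # 5 cells apart; both survive at delta = 2
  det2 <- extract_detections(confidence_map(g2), peak_params(0.35, 2))
  expect_equal(sort(det2$score), c(0.8, 0.9))
})

test_that("extraction matches the brute-force pipeline on random maps", {
  set.seed(23)
  for (i in 1:10) {
    n <- sample(8:32, 1)
    g <- matrix(runif(n * n), n, n)
    tau <- runif(1, 0.3, 0.8)
    delta <- sample(0:4, 1)
    got <- extract_detections(confidence_map(g), peak_params(tau, delta))
    want <- oracle_suppress(oracle_local_maxima(g), tau, delta)
    expect_equal(nrow(got), nrow(want))
    expect_equal(got$score, want$value)
    expect_equal(got$x, want$cell_x + 0.5)  # scale-1 cell-centre convention
    expect_equal(got$y, want$cell_y + 0.5)
    # suppression sanity: accepted peaks are pairwise farther than delta
    if (nrow(got) > 1) {
      d <- as.matrix(dist(cbind(got$x, got$y)))
      expect_true(all(d[upper.tri(d)] > delta))
    }
  }
})

test_that("raising tau never increases the number of detections", {
  set.seed(29)
  g <- matrix(runif(400), 20, 20)
  taus <- seq(0.05, 0.95, by = 0.1)
  counts <- vapply(taus, function(t)
    nrow(extract_detections(confidence_map(g), peak_params(t, 1))), 0L)
  expect_true(all(diff(counts) <= 0))
})

test_that("detections map to input pixels with the cell-centre convention", {
  g <- matrix(0, 8, 8)
  g[4, 3] <- 0.9  # cell (x=2, y=3) at scale 4
  det <- extract_detections(confidence_map(g, scale = 4), peak_params(0.5, 1))
  expect_equal(det$x, 2 * 4 + 2)
  expect_equal(det$y, 3 * 4 + 2)
})

test_that("noiseless target maps are recovered exactly", {
  # trees >= 3 sigma apart on the sigma_min kernel: detections must equal
  # the annotation set in count, each within 1 map cell
  set.seed(41)
  sigma <- 1.5
  for (scale in c(1L, 4L)) {
    ann <- data.frame(x = c(20, 60, 100, 40) * scale / 2,
                      y = c(24, 30, 80, 100) * scale / 2)
    shape <- c(64L, 64L)
    m <- render_confidence_map(ann, shape, sigma, scale = scale)
    det <- extract_detections(m, peak_params(0.35, 1))
    expect_equal(nrow(det), nrow(ann))
    mres <- match_points(det, ann, max_match_distance = 1.5 * scale)
    expect_equal(mres$n_tp, nrow(ann))
    # exact cell-level recovery: detected cell == annotation's nearest cell
    expect_equal((det$x[mres$pairs$detection] - scale / 2) / scale,
                 round(ann$x[mres$pairs$annotation] / scale))
    expect_equal((det$y[mres$pairs$detection] - scale / 2) / scale,
                 round(ann$y[mres$pairs$annotation] / scale))
  }
})

test_that("patch-to-mosaic translation composes and inverts", {
  det <- data.frame(x = 10, y = 10, score = 0.9)
  expect_equal(patch_to_mosaic_coords(det, c(0, 0)), det)
  tr <- patch_to_mosaic_coords(det, c(256, 512))
  expect_equal(tr$x, 522)
  expect_equal(tr$y, 266)
  back <- patch_to_mosaic_coords(tr, c(-256, -512) * 0)  # identity check
  expect_equal(back, tr)
  tr$x <- tr$x - 512; tr$y <- tr$y - 256
  expect_equal(tr, det)
})

test_that("geolocation applies the affine transform and inverts", {
  det <- data.frame(x = 100, y = 100, score = 0.8)
  idt <- c(0, 1, 0, 0, 0, 1)
  g <- pixel_to_geo(det, idt)
  expect_equal(g$geo_x, det$x)
  expect_equal(g$geo_y, det$y)
  # 10 cm GSD, origin (1000, 2000): pixel (100, 100) is 10 m from origin
  gt <- c(1000, 0.1, 0, 2000, 0, 0.1)
  g <- pixel_to_geo(det, gt)
  expect_equal(g$geo_x, 1010)
  expect_equal(g$geo_y, 2010)
  back <- geo_to_pixel(g, gt)
  expect_lt(abs(back$x - det$x), 1e-6)
  expect_lt(abs(back$y - det$y), 1e-6)
  expect_error(pixel_to_geo(det, c(0, 0, 0, 0, 0, 0)), "invertible")
})

test_that("detections export to CSV and GeoJSON", {
  det <- data.frame(x = c(1.5, 3), y = c(2.5, 4), score = c(0.9, 0.6))
  csv <- tempfile(fileext = ".csv")
  write_detections_csv(det, csv, image_id = "p1")
  got <- read.csv(csv)
  expect_equal(names(got), c("image_id", "x", "y", "score"))
  expect_equal(got$score, det$score)
  geo <- pixel_to_geo(det, c(100, 0.1, 0, 200, 0, -0.1))
  gj <- tempfile(fileext = ".geojson")
  write_detections_geojson(geo, gj)
  parsed <- jsonlite::read_json(gj)
  expect_equal(parsed$type, "FeatureCollection")
  expect_length(parsed$features, 2)
  expect_equal(parsed$features[[1]]$properties$score, 0.9)
  unlink(c(csv, gj))
})
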