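# spot detection, sub-pixel localization, backbone segmentation,
# registration and spot-molecule association

test_that("detect_spots finds isolated spots and nothing in blanks", {
  sig <- 0.98
  expect_equal(nrow(detect_spots(matrix(0, 40, 40), sig)), 0)
  set.seed(30)
  img <- matrix(rpois(1600, 10), 40, 40)
  img <- img + slitmap:::add_spot(matrix(0, 40, 40), 20.3, 14.7, sig, 1600)
  cand <- detect_spots(img, sig)
  expect_equal(nrow(cand), 1)
  expect_lt(abs(cand$x_px - 20.3), 1)
  expect_lt(abs(cand$y_px - 14.7), 1)
  # two spots 10 FWHM apart
  img2 <- slitmap:::add_spot(matrix(rpois(1600, 10), 40, 40),
                             10, 20, sig, 1600)
  img2 <- slitmap:::add_spot(img2, 10 + 10 * 2.3548 * sig, 20, sig, 1600)
  expect_equal(nrow(detect_spots(img2, sig)), 2)
})

test_that("centroid equals the brute-force oracle on identical patches", {
  sig <- 0.98
  for (off in list(c(0, 0), c(0.30, -0.20), c(-0.43, 0.11))) {
    win <- render_spot(8 + off[1], 8 + off[2], sig, 1600, poisson = FALSE)
    l <- localize_centroid(win, 8, 8, sig, 100, halfwidth_px = 7)
    o <- oracle_centroid(win, 1:15, 1:15, sig)
    expect_lt(abs(l$x_px - o[1]), 1e-6)
    expect_lt(abs(l$y_px - o[2]), 1e-6)
  }
})

test_that("noiseless centroid recovers sub-pixel offsets", {
  sig <- 0.98
  win <- render_spot(8, 8, sig, 1600, poisson = FALSE)
  l <- localize_centroid(win, 8, 8, sig, 100)
  expect_lt(abs(l$x_px - 8), 1e-6)
  expect_lt(abs(l$y_px - 8), 1e-6)
  win <- render_spot(8.30, 7.80, sig, 1600, poisson = FALSE)
  l <- localize_centroid(win, 8, 8, sig, 100)
  expect_lt(abs(l$x_px - 8.30), 0.02)
  expect_lt(abs(l$y_px - 7.80), 0.02)
  expect_error(localize_centroid(matrix(0, 15, 15), 8, 8, sig),
               "degenerate spot")
})

test_that("localization error scales as 1/sqrt(photons)", {
  sig <- 0.98
  photons <- c(400, 1600, 6400)  # 16x range
  set.seed(77)
  sds <- vapply(photons, function(N) {
    err <- replicate(150, {
      cx <- 8 + runif(1) - 0.5
      win <- render_spot(cx, 8, sig, N)
      localize_centroid(win, 8, 8, sig, 100)$x_px - cx
    })
    sd(err)
  }, numeric(1))
  slope <- coef(lm(log(sds) ~ log(photons)))[2]
  expect_lt(abs(slope + 0.5), 0.05)
})

test_that("gaussian-fit cross-check localizer agrees with the centroid", {
  sig <- 0.98
  set.seed(41)
  win <- render_spot(8.25, 7.6, sig, 3000)
  lc <- localize_centroid(win, 8, 8, sig, 100)
  lg <- localize_gaussian_fit(win, 8, 8, sig, 100)
  expect_lt(abs(lc$x_px - lg$x_px), 0.05)
  expect_lt(abs(lc$y_px - lg$y_px), 0.05)
})

make_backbone_image <- function(lanes_y, ext_px, junction = 16, nx = 256,
                                ny = 100, sigma = 0.8, photons = 150,
                                bg = 10) {
  img <- matrix(0, ny, nx)
  for (i in seq_along(lanes_y))
    img <- slitmap:::add_line(img, junction, junction + ext_px[i],
                              lanes_y[i], sigma, photons)
  matrix(rpois(length(img), img + bg), ny)
}

test_that("backbone segmentation measures extension and separates lanes", {
  set.seed(50)
  # 6 px lane separation: the closest spacing whose inter-lane gap stays
  # below threshold given the PSF tails (at 5 px the tails bridge the
  # single gap row and the pair merges into one ambiguous component)
  img <- make_backbone_image(c(30, 36), c(191.4, 120))
  bb <- segment_backbones(img, 16, 0.8, 100)
  expect_equal(nrow(bb), 2)
  expect_lt(abs(bb$extension_um[1] - 19.14), 0.2)
  expect_lt(abs(bb$extension_um[2] - 12.0), 0.2)
  expect_equal(nrow(segment_backbones(matrix(0, 50, 50), 16, 0.8, 100)), 0)
})

test_that("overlapping molecules merge into one flagged-ambiguous component", {
  set.seed(52)
  img <- make_backbone_image(c(30, 33), c(191.4, 120))
  bb <- segment_backbones(img, 16, 0.8, 100)
  expect_equal(nrow(bb), 1)
  expect_true(bb$ambiguous)
})

test_that("measured extension is invariant to lane position", {
  set.seed(51)
  exts <- vapply(c(25, 50, 75), function(y) {
    img <- make_backbone_image(y, 191.4)
    segment_backbones(img, 16, 0.8, 100)$extension_um[1]
  }, numeric(1))
  expect_lt(diff(range(exts)), 0.15)
})

test_that("channel registration subtracts the offset exactly", {
  spots <- data.frame(x_px = c(10, 20), y_px = c(5, 6),
                      photons = c(1e4, 1e4), precision_nm = 3)
  expect_equal(register_channels(spots, c(0, 0)), spots)
  reg <- register_channels(spots, c(2.5, -1.0))
  expect_equal(reg$x_px, spots$x_px - 2.5)
  expect_equal(reg$y_px, spots$y_px + 1.0)
})

test_that("channel offset is recoverable from fluosphere fiducials", {
  set.seed(60)
  truth <- simulate_truth(scenario_config(n_molecules = 12, seed = 31,
                                          end_label_efficiency = 1),
                          optics = optical_config(
                            channel_offset_px = c(3.2, 0.4)))
  frames <- render_frame_pair(truth, 1)
  opt <- truth$optics
  bb <- segment_backbones(frames$on_green, truth$geometry$junction_x_px,
                          0.8, 100)
  spots <- localize_spots(frames$on_red, 0.98, 100)
  est <- estimate_channel_offset(spots, bb, truth$geometry$junction_x_px)
  expect_lt(abs(est[1] - 3.2), 0.1)
  expect_lt(abs(est[2] - 0.4), 0.1)
  expect_error(estimate_channel_offset(spots[0, ], bb, 16), "fiducials")
})

test_that("spots are assigned to molecules, orphans retained", {
  bb <- data.frame(backbone_id = 1:2, root_y_px = c(20, 40),
                   extension_um = c(19, 18), n_pixels = 500,
                   ambiguous = FALSE)
  spots <- data.frame(
    x_px = c(16.1, 100, 120, 100), y_px = c(20.2, 20.5, 39.8, 30),
    photons = c(2e4, 1600, 1600, 1600), precision_nm = 3)
  m <- match_spots_to_molecules(spots, bb, 16, 0.98, 100)
  expect_true(m$molecules$has_anchor[1])
  expect_false(m$molecules$has_anchor[2])
  expect_equal(nrow(m$qds), 2)           # one per molecule
  expect_equal(nrow(m$orphans), 1)       # equidistant-ish far spot at y=30
  expect_equal(m$qds$molecule_id, c(1, 2))
  # distance measured from the fluosphere anchor along the stretch axis
  expect_equal(m$qds$distance_um[1], (100 - 16.1) * 0.1, tolerance = 1e-9)
})
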