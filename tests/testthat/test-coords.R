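# lambda coordinate model and confinement physics

test_that("locus -> distance reproduces the promoter geometry", {
  g <- genome_model()
  # anchor is the 3' end
  expect_equal(locus_to_distance(48502, g, "unstained"), 0)
  # frozen closed-form values: (48502 - locus) * 0.34 nm
  expect_equal(locus_to_distance(38000, g, "unstained"), 3.57068,
               tolerance = 1e-9)
  expect_equal(locus_to_distance(35600, g, "unstained"), 4.38668,
               tolerance = 1e-9)
  # consistent with the expected promoter distances from the anchor
  expect_lt(abs(locus_to_distance(38000, g, "unstained") - 3.55), 0.05)
  expect_lt(abs(locus_to_distance(35600, g, "unstained") - 4.40), 0.05)
  # full unstained contour
  expect_lt(abs(locus_to_distance(1, g, "unstained") - 16.5), 0.05)
  expect_error(locus_to_distance(0, g), "out of range")
  expect_error(locus_to_distance(48503, g), "out of range")
})

test_that("distance -> locus inverts the map", {
  g <- genome_model()
  expect_equal(distance_to_locus(0, g, extension_um = 19.14), 48502L)
  expect_equal(distance_to_locus(19.14, g, extension_um = 19.14), 1L)
  # per-molecule normalization: 48502 * (1 - 4.14/19.14)
  expect_lt(abs(distance_to_locus(4.14, g, extension_um = 19.14) - 38012), 2)
  expect_error(distance_to_locus(-0.1, g), "non-negative")
  expect_error(distance_to_locus(20, g, extension_um = 19.14), "exceeds")
})

test_that("round trip locus -> distance -> locus is identity to 1 bp", {
  g <- genome_model()
  set.seed(11)
  loci <- c(1L, 48502L, sample.int(48502, 200))
  for (mode in c("unstained", "stained")) {
    d <- locus_to_distance(loci, g, mode)
    back <- distance_to_locus(d, g, mode = mode)
    expect_lte(max(abs(back - loci)), 1)
  }
  # and through the per-molecule normalization used by the pipeline
  ext <- 0.87 * g$stained_contour_um
  d <- locus_to_distance(loci, g, "stained") * (ext / g$stained_contour_um)
  expect_lte(max(abs(distance_to_locus(d, g, extension_um = ext) - loci)), 1)
})

test_that("contour span matches the rise for both modes", {
  g <- genome_model()
  for (mode in c("unstained", "stained")) {
    span <- locus_to_distance(1, g, mode) - locus_to_distance(48502, g, mode)
    rise_um <- if (mode == "unstained") 0.34e-3 else 22 / 48502
    expect_equal(span, (48502 - 1) * rise_um, tolerance = 1e-9)
  }
})

test_that("loop bending energy follows pi * Lp / (2R)", {
  expect_equal(loop_bending_energy(confinement_model(60, 60)), pi,
               tolerance = 1e-12)
  expect_equal(loop_bending_energy(confinement_model(50, 60)), 2.61799,
               tolerance = 1e-5)
  expect_equal(loop_bending_energy(confinement_model(50, 500)), 0.31416,
               tolerance = 1e-5)
  expect_error(confinement_model(-50, 60))
})

test_that("bending energy scales linearly in Lp and inversely in depth", {
  for (lp in c(20, 50, 80)) for (depth in c(40, 60, 200)) {
    u <- loop_bending_energy(confinement_model(lp, depth))
    expect_equal(u / loop_bending_energy(confinement_model(1, depth)), lp,
                 tolerance = 1e-9)
    expect_equal(u * depth, pi * lp, tolerance = 1e-9)
  }
})

test_that("confinement check is strict at the 1 kBT boundary", {
  expect_true(loops_suppressed(confinement_model(50, 60)))
  expect_false(loops_suppressed(confinement_model(50, 500)))
  # U = kBT exactly when depth = pi * Lp: reported as not suppressed
  expect_false(loops_suppressed(confinement_model(50, pi * 50)))
  expect_true(loops_suppressed(confinement_model(50, pi * 50 - 1e-6)))
})

test_that("known sites export as width-1 BED intervals on 'lambda'", {
  g <- genome_model()
  bed <- tempfile(fileext = ".bed")
  export_known_sites_bed(g, bed)
  back <- rtracklayer::import(bed, format = "BED")
  expect_equal(length(back), 5L)
  expect_equal(as.character(GenomicRanges::seqnames(back)),
               rep("lambda", 5))
  expect_setequal(GenomicRanges::start(back), g$known_sites$locus_bp)
  expect_true(all(GenomicRanges::width(back) == 1L))
})

test_that("genome model validates its invariants", {
  expect_error(genome_model(stained_contour_um = 10), "stained contour")
  ks <- lambda_known_sites(); ks$name[2] <- ks$name[1]
  expect_error(genome_model(known_sites = ks), "unique")
  ks <- lambda_known_sites(); ks$locus_bp[1] <- 50000L
  expect_error(genome_model(known_sites = ks), "loci")
})
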