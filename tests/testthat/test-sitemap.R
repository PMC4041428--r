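# event assignment, histogramming, multi-peak Gaussian fitting, site calls

test_that("assign_loci maps anchor-referenced distances to bp", {
  g <- genome_model()
  mol <- data.frame(molecule_id = "m1", extension_um = 19.14,
                    qualified = TRUE)
  qd <- function(d) data.frame(molecule_id = "m1", distance_um = d,
                               precision_nm = 2.5)
  expect_equal(assign_loci(qd(0), mol, g)$locus_bp, 48502L)
  # P_R geometry: 21.65% of the extension
  ev <- assign_loci(qd(0.2165 * 19.14), mol, g)
  expect_lt(abs(ev$locus_bp - 38001), 2)
  expect_gt(ev$locus_sd_bp, 0)
  # events beyond the extension are discarded with a warning
  expect_warning(out <- assign_loci(qd(25), mol, g), "discarded")
  expect_equal(nrow(out), 0)
})

test_that("assigned loci track the generator's event noise", {
  g <- genome_model()
  set.seed(70)
  n <- 1000
  truth_locus <- 38003
  noise <- rnorm(n, 0, 600)
  d <- locus_to_distance(pmin(pmax(round(truth_locus + noise), 1), 48502),
                         g, "stained") * 0.87
  mol <- data.frame(molecule_id = as.character(1:n), extension_um = 19.14,
                    qualified = TRUE)
  ev <- assign_loci(data.frame(molecule_id = as.character(1:n),
                               distance_um = d, precision_nm = 2.5),
                    mol, g)
  # KS test against the configured N(truth, 600)
  ks <- suppressWarnings(ks.test(ev$locus_bp, "pnorm", truth_locus, 600))
  expect_gt(ks$p.value, 0.01)
})

test_that("histogram conserves counts for any spec", {
  set.seed(71)
  for (bw in c(250, 500, 1000)) {
    ev <- data.frame(molecule_id = "m",
                     locus_bp = sample.int(48502, 377, TRUE))
    h <- build_histogram(ev, histogram_spec(bin_width_bp = bw))
    expect_equal(sum(h$count), 377)
  }
  expect_equal(sum(build_histogram(
    data.frame(molecule_id = character(0), locus_bp = integer(0)),
    histogram_spec())$count), 0)
})

test_that("histogram of noisy single-site events has the event SD", {
  set.seed(72)
  ev <- data.frame(molecule_id = "m",
                   locus_bp = round(rnorm(1000, 25000, 600)))
  h <- build_histogram(ev, histogram_spec())
  m <- sum(h$bin_mid_bp * h$count) / sum(h$count)
  s <- sqrt(sum(h$count * (h$bin_mid_bp - m)^2) / sum(h$count))
  expect_lt(abs(s - 600), 60)
})

test_that("peak detection handles flat, well-separated and merged cases", {
  flat <- build_histogram(data.frame(molecule_id = character(0),
                                     locus_bp = integer(0)))
  expect_equal(nrow(detect_peaks(flat)), 0)
  set.seed(73)
  centers <- c(5000, 15000, 25000, 35000, 45000)
  ev <- data.frame(molecule_id = "m",
                   locus_bp = round(rnorm(1500, sample(centers, 1500,
                                                       TRUE), 600)))
  pk <- detect_peaks(build_histogram(ev))
  expect_equal(nrow(pk), 5)
  expect_lt(max(abs(sort(pk$bin_mid_bp) - centers)), 500)
  # two bumps closer than the separation floor merge into one
  ev2 <- data.frame(molecule_id = "m",
                    locus_bp = round(rnorm(1000, sample(c(25000, 26000),
                                                        1000, TRUE), 500)))
  expect_equal(nrow(detect_peaks(build_histogram(ev2))), 1)
})

test_that("fit recovers a noise-free Gaussian to < 1%", {
  spec <- histogram_spec()
  x <- seq(1, 48502, by = 500) + 250
  y <- 20 * exp(-(x - 25120)^2 / (2 * 700^2))
  h <- data.frame(bin_start_bp = x - 250, bin_mid_bp = x, count = y)
  fit <- fit_multi_gaussian(h, detect_peaks(h))
  expect_true(fit$converged)
  expect_lt(abs(fit$peaks$mean_bp - 25120) / 25120, 0.01)
  expect_lt(abs(fit$peaks$sd_bp - 700) / 700, 0.01)
  expect_lt(abs(fit$peaks$amplitude - 20) / 20, 0.01)
})

test_that("fit self-consistency: refitting its own expectation", {
  set.seed(74)
  ev <- data.frame(molecule_id = "m",
                   locus_bp = round(c(rnorm(400, 25000, 600),
                                      rnorm(300, 35000, 700))))
  h <- build_histogram(ev)
  fit <- fit_multi_gaussian(h, detect_peaks(h))
  h2 <- h
  h2$count <- slitmap:::predict_multi_gaussian(fit, h$bin_mid_bp)
  refit <- fit_multi_gaussian(h2, detect_peaks(h2), refine = FALSE)
  expect_true(refit$converged)
  expect_lt(max(abs(refit$peaks$mean_bp - fit$peaks$mean_bp) /
                  fit$peaks$mean_bp), 0.001)
  expect_lt(max(abs(refit$peaks$sd_bp - fit$peaks$sd_bp) /
                  fit$peaks$sd_bp), 0.001)
})

test_that("two components 10 kb apart are recovered within 50 bp", {
  spec <- histogram_spec()
  x <- seq(1, 48502, by = 500) + 250
  y <- 18 * exp(-(x - 20000)^2 / (2 * 600^2)) +
       14 * exp(-(x - 30000)^2 / (2 * 600^2))
  h <- data.frame(bin_start_bp = x - 250, bin_mid_bp = x, count = y)
  fit <- fit_multi_gaussian(h, detect_peaks(h))
  expect_true(fit$converged)
  expect_equal(nrow(fit$peaks), 2)
  expect_lt(abs(fit$peaks$mean_bp[1] - 20000), 50)
  expect_lt(abs(fit$peaks$mean_bp[2] - 30000), 50)
})

test_that("site calls report nearest-peak frequencies per molecule", {
  g <- genome_model()
  fit <- list(peaks = data.frame(mean_bp = c(38266, 10000),
                                 sd_bp = c(600, 600),
                                 amplitude = c(10, 5)),
              baseline = 0, converged = TRUE, residual_rms = 0)
  ev <- data.frame(molecule_id = c("a", "a", "b", "c"),
                   locus_bp = c(38100, 38200, 38300, 10200))
  sites <- call_sites(fit, ev, n_qualified = 4, g)
  # duplicate events on one molecule count once
  expect_equal(sites$n_molecules[sites$mean_bp == 38266], 2L)
  expect_equal(sites$frequency[sites$mean_bp == 38266], 0.5)
  # matching and error against the known locus: |38266 - 38003| = 263
  expect_equal(sites$matched_known_site[sites$mean_bp == 38266], "PR")
  expect_equal(sites$error_bp[sites$mean_bp == 38266], 263)
  # peak 3,000 bp from every known site stays unmatched
  expect_true(is.na(sites$matched_known_site[sites$mean_bp == 10000]))
  expect_error(call_sites(fit, ev, 0, g), "qualified")
})

test_that("events in overlapping windows are never double-counted", {
  g <- genome_model()
  fit <- list(peaks = data.frame(mean_bp = c(23619, 25620),
                                 sd_bp = c(600, 600), amplitude = c(5, 5)),
              baseline = 0, converged = TRUE, residual_rms = 0)
  # event in the window overlap: nearest peak is 25620
  ev <- data.frame(molecule_id = "a", locus_bp = 24700)
  sites <- call_sites(fit, ev, 10, g)
  expect_equal(sites$n_molecules, c(0L, 1L))
})

test_that("comparison table summarizes known-site recovery", {
  g <- genome_model()
  calls <- data.frame(mean_bp = g$known_sites$locus_bp,
                      sd_bp = 600, amplitude = 10, n_molecules = 5L,
                      frequency = 0.4,
                      matched_known_site = g$known_sites$name,
                      matched_class = g$known_sites$class,
                      error_bp = 0, converged = TRUE)
  cmp <- compare_to_known(calls, g)
  expect_true(all(cmp$table$called))
  expect_equal(cmp$max_promoter_error_bp, 0)
  expect_equal(cmp$max_sd_bp, 600)
  empty <- compare_to_known(calls[0, ], g)
  expect_false(any(empty$table$called))
  expect_true(is.na(empty$max_promoter_error_bp))
})

test_that("site calls export as BED intervals", {
  g <- genome_model()
  sites <- data.frame(mean_bp = c(38003, 25620), sd_bp = c(600, 700),
                      amplitude = 10, n_molecules = 5L, frequency = 0.45,
                      matched_known_site = c("PR", "pseudo_25620"),
                      matched_class = c("promoter", "pseudo_promoter"),
                      error_bp = 0, converged = TRUE)
  bed <- tempfile(fileext = ".bed")
  export_sites_bed(sites, g, bed)
  back <- rtracklayer::import(bed, format = "BED")
  expect_length(back, 2)
  expect_equal(GenomicRanges::start(back), round(sites$mean_bp - sites$sd_bp))
})
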