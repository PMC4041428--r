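# synthetic-data generator: truth sampling and frame rendering

test_that("degenerate probabilities give the exact promoter loci", {
  g <- genome_model()
  sc <- scenario_config(promoter_bind_prob = 1, pseudo_bind_prob = 0,
                        event_noise_sd_bp = 0)
  set.seed(1)
  m <- sample_molecule_truth(sc, g)
  expect_setequal(m$bound$locus_bp, c(38003L, 35602L))
  expect_setequal(m$bound$class, "promoter")
})

test_that("binding frequencies converge to configured probabilities", {
  g <- genome_model()
  sc <- scenario_config()
  set.seed(101)
  n <- 10000
  pr <- logical(n); ps <- logical(n)
  for (i in seq_len(n)) {
    m <- sample_molecule_truth(sc, g)
    pr[i] <- "PR" %in% m$bound$site_name
    ps[i] <- "pseudo_25620" %in% m$bound$site_name
  }
  # 3 binomial SDs at n = 10,000
  expect_lt(abs(mean(pr) - 0.45), 3 * sqrt(0.45 * 0.55 / n))
  expect_lt(abs(mean(ps) - 0.30), 3 * sqrt(0.30 * 0.70 / n))
})

test_that("deterministic stretch gives the exact extension", {
  g <- genome_model()
  sc <- scenario_config(stretch_mean = 0.87, stretch_sd = 0)
  set.seed(5)
  m <- sample_molecule_truth(sc, g)
  expect_equal(m$extension_um, 0.87 * 22)
})

test_that("end-labeling efficiency shows up in the truth table", {
  truth <- simulate_truth(scenario_config(n_molecules = 200, seed = 42))
  n_fluo <- sum(truth$molecules$has_fluosphere)
  expect_lt(abs(n_fluo - 140), 3 * sqrt(200 * 0.7 * 0.3))
})

test_that("truth generation is deterministic and render-independent", {
  sc <- scenario_config(n_molecules = 12, seed = 99)
  t1 <- simulate_truth(sc)
  t2 <- simulate_truth(sc)
  expect_identical(t1$molecules, t2$molecules)
})

test_that("renderer places a QD at the fractional-locus position", {
  g <- genome_model()
  sc <- scenario_config(n_molecules = 1, promoter_bind_prob = 1,
                        pseudo_bind_prob = 0, event_noise_sd_bp = 0,
                        stretch_sd = 0, end_label_efficiency = 0,
                        stuck_qd_rate = 0, seed = 3,
                        true_sites = data.frame(
                          name = "PR", locus_bp = 38003L,
                          class = "promoter"))
  opt <- optical_config(background_photons_per_pixel = 0,
                        channel_offset_px = c(0, 0))
  truth <- simulate_truth(sc, g, opt)
  set.seed(4)
  frames <- render_frame_pair(truth, 1)
  red <- frames$on_red
  peak <- which(red == max(red), arr.ind = TRUE)[1, ]
  mol <- truth$molecules[1, ]
  d_px <- (48502 - 38003) / 48502 * mol$extension_um * 10  # 100 nm px
  expect_lt(abs(peak["col"] - (mol$anchor_x_px + d_px)), 1.5)
  expect_lt(abs(peak["row"] - mol$anchor_y_px), 1.5)
})

test_that("stuck QDs sit at identical coordinates in both frames", {
  sc <- scenario_config(n_molecules = 4, stuck_qd_rate = 2, seed = 21,
                        promoter_bind_prob = 0, pseudo_bind_prob = 0,
                        end_label_efficiency = 0)
  opt <- optical_config(background_photons_per_pixel = 0,
                        backbone_photons_per_pixel = 0,
                        channel_offset_px = c(0, 0))
  truth <- simulate_truth(sc, genome_model(), opt)
  stuck <- do.call(rbind, lapply(truth$molecules$stuck_qds,
                                 slitmap:::unpack_stuck))
  expect_gt(nrow(stuck), 0)  # seed 21 draws 7 contaminants
  set.seed(8)
  frames <- render_frame_pair(truth, 1)
  for (i in seq_len(nrow(stuck))) {
    for (page in c("on_red", "off_red")) {
      img <- frames[[page]]
      r <- round(stuck$y_px[i]); c <- round(stuck$x_px[i])
      # photons concentrated at the same absolute pixel in both frames
      expect_gt(sum(img[(r - 2):(r + 2), (c - 2):(c + 2)]), 800)
    }
  }
})

test_that("rendered spot photon sums match the configured budget", {
  set.seed(10)
  sums <- replicate(50, sum(render_spot(8, 8, 0.98, 1600)))
  expect_lt(abs(mean(sums) - 1600), 3 * sqrt(1600 / 50))
})

test_that("field-off distances shrink by the recoil ratio", {
  g <- genome_model()
  sc <- scenario_config(n_molecules = 1, promoter_bind_prob = 1,
                        pseudo_bind_prob = 0, event_noise_sd_bp = 0,
                        stretch_sd = 0, stuck_qd_rate = 0, seed = 13,
                        end_label_efficiency = 0,
                        true_sites = data.frame(
                          name = "PR", locus_bp = 38003L,
                          class = "promoter"))
  opt <- optical_config(background_photons_per_pixel = 0,
                        channel_offset_px = c(0, 0))
  truth <- simulate_truth(sc, g, opt)
  set.seed(14)
  frames <- render_frame_pair(truth, 1)
  mol <- truth$molecules[1, ]
  frac <- (48502 - 38003) / 48502
  for (ph in c("on", "off")) {
    ext <- if (ph == "on") mol$extension_um else mol$recoiled_extension_um
    img <- frames[[paste0(ph, "_red")]]
    peak <- which(img == max(img), arr.ind = TRUE)[1, ]
    expect_lt(abs(peak["col"] - (mol$anchor_x_px + frac * ext * 10)), 1.5)
  }
})

test_that("generate_experiment writes a complete, reproducible dataset", {
  cfg <- scenario_config(n_molecules = 6, seed = 17)
  d1 <- file.path(tempdir(), "gen1"); d2 <- file.path(tempdir(), "gen2")
  quiet(generate_experiment(cfg, d1))
  quiet(generate_experiment(cfg, d2))
  expect_identical(unname(tools::md5sum(file.path(d1, "truth.csv"))),
                   unname(tools::md5sum(file.path(d2, "truth.csv"))))
  expect_true(file.exists(file.path(d1, "fov_001.tif")))
  expect_true(file.exists(file.path(d1, "scenario.yaml")))
  man <- jsonlite::read_json(file.path(d1, "manifest.json"))
  expect_gte(length(man$files), 3)
  # zero molecules: empty truth, no frames
  d0 <- file.path(tempdir(), "gen0")
  quiet(generate_experiment(scenario_config(n_molecules = 0), d0))
  expect_equal(nrow(slitmap:::read_truth_csv(file.path(d0, "truth.csv"))), 0)
  expect_length(list.files(d0, pattern = "\\.tif$"), 0)
})
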