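# Frame rendering: expected-photon images composed from pixel-integrated
# Gaussians, then Poisson-sampled. Coordinate convention: pixel (row r,
# col c) is centered at (x = c, y = r) and covers [c - 0.5, c + 0.5] x
# [r - 0.5, r + 0.5] in pixel units.

# pixel-integrated 1-D Gaussian profile over pixel centers `idx`
pix_gauss <- function(idx, center, sigma) {
  stats::pnorm(idx + 0.5, center, sigma) - stats::pnorm(idx - 0.5, center, sigma)
}

add_spot <- function(img, cx, cy, sigma, photons) {
  if (photons <= 0) return(img)
  hw <- ceiling(4 * sigma) + 1
  cols <- max(1, floor(cx - hw)):min(ncol(img), ceiling(cx + hw))
  rows <- max(1, floor(cy - hw)):min(nrow(img), ceiling(cy + hw))
  if (!length(cols) || !length(rows)) return(img)
  img[rows, cols] <- img[rows, cols] +
    photons * outer(pix_gauss(rows, cy, sigma), pix_gauss(cols, cx, sigma))
  img
}

# uniform line source from x0 to x1 at row y, linear density
# `photons_per_px`, convolved with an isotropic Gaussian PSF
add_line <- function(img, x0, x1, y, sigma, photons_per_px) {
  if (photons_per_px <= 0 || x1 <= x0) return(img)
  cols <- max(1, floor(x0 - 4 * sigma)):min(ncol(img), ceiling(x1 + 4 * sigma))
  rows <- max(1, floor(y - 4 * sigma - 1)):min(nrow(img), ceiling(y + 4 * sigma + 1))
  if (!length(cols) || !length(rows)) return(img)
  fx <- photons_per_px *
    (stats::pnorm(cols, x0, sigma) - stats::pnorm(cols, x1, sigma))
  fy <- pix_gauss(rows, y, sigma)
  img[rows, cols] <- img[rows, cols] + outer(fy, fx)
  img
}

#' Render one field of view as a field-on / field-off frame pair
#'
#' Green channel: each molecule's stained backbone drawn as a line of its
#' (field-on) stretched or (field-off) recoiled extension from the anchor
#' at the junction line. Red channel: the fluosphere at the anchor (when
#' present), one QD per bound locus riding with the DNA (field-off
#' positions rescale with the recoiled extension), and surface-stuck
#' contaminant QDs at fixed absolute positions in both frames. The red
#' channel is shifted by the split-view `channel_offset_px`; all
#' intensities are Poisson-sampled on top of a uniform background.
#'
#' Uses the current RNG state; [generate_experiment()] seeds a dedicated
#' rendering substream so truth tables are invariant to renderer changes.
#'
#' @param truth An `experiment_truth` from [simulate_truth()].
#' @param fov Field-of-view index to render.
#' @return List of four matrices: `on_green`, `on_red`, `off_green`,
#'   `off_red` (expected photons, Poisson-sampled, clamped to 16 bits).
#' @export
render_frame_pair <- function(truth, fov = 1L) {
  geom <- truth$geometry
  optics <- truth$optics
  genome <- truth$genome
  pix_um <- optics$pixel_size_nm / 1000
  mol <- truth$molecules[truth$molecules$fov == fov, , drop = FALSE]
  if (max(mol$extension_um, 0) / pix_um + geom$junction_x_px > geom$nx)
    stop("geometry error: molecule longer than the rendered strip")
  blank <- function() matrix(0, nrow = geom$ny, ncol = geom$nx)
  imgs <- list(on_green = blank(), on_red = blank(),
               off_green = blank(), off_red = blank())
  off <- optics$channel_offset_px
  sig_g <- optics$psf_sigma_green_nm / optics$pixel_size_nm
  sig_r <- optics$psf_sigma_red_nm / optics$pixel_size_nm
  sig_fluo <- sig_r * optics$fluosphere_sigma_factor
  for (i in seq_len(nrow(mol))) {
    x0 <- mol$anchor_x_px[i]; y0 <- mol$anchor_y_px[i]
    for (phase in c("on", "off")) {
      ext <- if (phase == "on") mol$extension_um[i] else mol$recoiled_extension_um[i]
      gkey <- paste0(phase, "_green"); rkey <- paste0(phase, "_red")
      imgs[[gkey]] <- add_line(imgs[[gkey]], x0, x0 + ext / pix_um, y0,
                               sig_g, optics$backbone_photons_per_pixel)
      if (mol$has_fluosphere[i])
        imgs[[rkey]] <- add_spot(imgs[[rkey]], x0 + off[1], y0 + off[2],
                                 sig_fluo, optics$photons_fluosphere)
      bound <- truth_events(mol[i, , drop = FALSE])
      if (nrow(bound) > 0) {
        d_um <- locus_to_distance(bound$locus_bp, genome, "stained") *
          (ext / genome$stained_contour_um)
        for (k in seq_along(d_um)) {
          jitter_y <- stats::rnorm(1, 0, 0.3)
          imgs[[rkey]] <- add_spot(imgs[[rkey]],
                                   x0 + d_um[k] / pix_um + off[1],
                                   y0 + jitter_y + off[2],
                                   sig_r, optics$photons_qd)
        }
      }
      stuck <- unpack_stuck(mol$stuck_qds[i])
      for (k in seq_len(nrow(stuck)))
        imgs[[rkey]] <- add_spot(imgs[[rkey]], stuck$x_px[k] + off[1],
                                 stuck$y_px[k] + off[2], sig_r,
                                 optics$photons_qd)
    }
  }
  lapply(imgs, function(im) {
    im <- im + optics$background_photons_per_pixel
    matrix(pmin(stats::rpois(length(im), as.numeric(im)), 65535),
           nrow = nrow(im))
  })
}

#' Generate a full synthetic experiment on disk
#'
#' Writes, under `out_dir`: one multi-page TIFF per field of view (page
#' order: field-on green, field-on red, field-off green, field-off red;
#' 16-bit), the ground-truth table `truth.csv`, the scenario + optics
#' metadata `scenario.yaml`, and `manifest.json` with MD5 checksums.
#' Reruns with the same scenario seed produce byte-identical truth tables.
#'
#' @param scenario A [scenario_config()].
#' @param out_dir Output directory (created if needed).
#' @param genome A [genome_model()].
#' @param optics An [optical_config()].
#' @return Invisibly, the `experiment_truth` with `$paths` attached.
#' @export
generate_experiment <- function(scenario, out_dir,
                                genome = genome_model(),
                                optics = optical_config()) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  if (!dir.exists(out_dir)) stop("cannot create output directory: ", out_dir)
  truth <- simulate_truth(scenario, genome, optics)
  fovs <- unique(truth$molecules$fov)
  tiff_paths <- character(0)
  render_seed <- substream_seed(scenario$seed, "render")
  for (fov in fovs) {
    set.seed((render_seed + fov) %% 2147483629)
    frames <- render_frame_pair(truth, fov)
    p <- file.path(out_dir, sprintf("fov_%03d.tif", fov))
    write_tiff(frames, p)
    tiff_paths <- c(tiff_paths, p)
  }
  truth_path <- file.path(out_dir, "truth.csv")
  write_truth_csv(truth, truth_path)
  meta_path <- file.path(out_dir, "scenario.yaml")
  write_experiment_meta(truth, meta_path)
  files <- c(tiff_paths, truth_path, meta_path)
  manifest <- list(files = lapply(files, function(f)
    list(path = basename(f), md5 = unname(tools::md5sum(f)))))
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE)
  truth$paths <- list(dir = out_dir, tiffs = tiff_paths, truth = truth_path,
                      meta = meta_path,
                      manifest = file.path(out_dir, "manifest.json"))
  invisible(truth)
}

write_truth_csv <- function(truth, path) {
  mol <- truth$molecules
  num <- c("anchor_y_px", "stretch_fraction", "extension_um",
           "recoiled_extension_um")
  for (cn in num) mol[[cn]] <- sprintf("%.4f", as.numeric(mol[[cn]]))
  utils::write.csv(mol, path, row.names = FALSE, quote = TRUE)
  invisible(path)
}

read_truth_csv <- function(path) {
  utils::read.csv(path, stringsAsFactors = FALSE,
                  colClasses = c(bound_sites = "character",
                                 stuck_qds = "character"))
}

write_experiment_meta <- function(truth, path) {
  sc <- truth$scenario
  meta <- list(
    scenario = c(sc[setdiff(names(sc), "true_sites")],
                 list(true_sites = as.list(as.data.frame(sc$true_sites)))),
    genome = list(length_bp = truth$genome$length_bp,
                  rise_unstained_nm_per_bp = truth$genome$rise_unstained_nm_per_bp,
                  stained_contour_um = truth$genome$stained_contour_um,
                  labeled_end = truth$genome$labeled_end),
    optics = unclass(truth$optics),
    geometry = truth$geometry,
    pages = c("on_green", "on_red", "off_green", "off_red"))
  yaml::write_yaml(meta, path)
  invisible(path)
}

read_experiment_meta <- function(path) {
  meta <- yaml::read_yaml(path)
  meta$optics <- do.call(optical_config, meta$optics)
  meta$genome <- do.call(genome_model, meta$genome)
  if (!is.null(meta$scenario)) {
    sc <- meta$scenario
    sc$true_sites <- as.data.frame(sc$true_sites, stringsAsFactors = FALSE)
    sc$recoil_range <- as.numeric(unlist(sc$recoil_range))
    meta$scenario <- do.call(scenario_config, sc)
  }
  meta$geometry <- lapply(meta$geometry, function(v)
    if (is.numeric(v)) as.integer(v) else v)
  meta
}
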