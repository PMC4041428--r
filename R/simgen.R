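# Synthetic-microscopy generator: samples ground-truth molecules with the
# experiment's statistical structure (promoter/pseudo-promoter binding
# probabilities, stretch-fraction variability, end-labeling efficiency,
# surface-stuck contaminants) and renders two-channel field-on/field-off
# frame pairs with Poisson photon noise.

#' Simulation scenario configuration
#'
#' Defaults reproduce the experiment's stated conditions: ~200 analyzed
#' molecules, promoter binding probability 0.45 and pseudo-promoter 0.30,
#' stretch fraction 0.87 +/- 0.03 of the 22 um stained contour, 3' end
#' labeling efficiency 0.70, and a low rate of surface-stuck contaminant
#' quantum dots exercising the field-reversal false-positive filter.
#'
#' @param n_molecules Number of molecules to simulate.
#' @param promoter_bind_prob Per-site binding probability for promoters.
#' @param pseudo_bind_prob Per-site binding probability for pseudo-promoters.
#' @param true_sites data.frame (`name`, `locus_bp`, `class`) of sites the
#'   generator binds; defaults to [lambda_known_sites()].
#' @param stretch_mean,stretch_sd Stretch fraction distribution (of the
#'   stained contour), truncated to (0, 1].
#' @param end_label_efficiency Probability a molecule carries the
#'   fluosphere anchor.
#' @param stuck_qd_rate Expected surface-stuck contaminant QDs per
#'   molecule strip (Poisson).
#' @param event_noise_sd_bp SD of the per-event positional noise (bp),
#'   lumping binding-position and measurement jitter.
#' @param recoil_range Range (fractions of stained contour) of the
#'   field-off recoiled extension, drawn uniformly.
#' @param molecules_per_fov Molecules laid out per field of view.
#' @param seed Integer master seed; all generator randomness derives from it.
#' @return An object of class `scenario_config`.
#' @export
scenario_config <- function(n_molecules = 200L,
                            promoter_bind_prob = 0.45,
                            pseudo_bind_prob = 0.30,
                            true_sites = lambda_known_sites(),
                            stretch_mean = 0.87,
                            stretch_sd = 0.03,
                            end_label_efficiency = 0.70,
                            stuck_qd_rate = 0.2,
                            event_noise_sd_bp = 600,
                            recoil_range = c(0.1, 0.3),
                            molecules_per_fov = 24L,
                            seed = 42L) {
  stopifnot(n_molecules >= 0,
            promoter_bind_prob >= 0, promoter_bind_prob <= 1,
            pseudo_bind_prob >= 0, pseudo_bind_prob <= 1,
            stretch_mean > 0, stretch_mean <= 1, stretch_sd >= 0,
            end_label_efficiency >= 0, end_label_efficiency <= 1,
            stuck_qd_rate >= 0, event_noise_sd_bp >= 0,
            length(recoil_range) == 2, recoil_range[1] > 0,
            recoil_range[2] < 1, molecules_per_fov >= 1)
  structure(list(n_molecules = as.integer(n_molecules),
                 promoter_bind_prob = promoter_bind_prob,
                 pseudo_bind_prob = pseudo_bind_prob,
                 true_sites = true_sites,
                 stretch_mean = stretch_mean, stretch_sd = stretch_sd,
                 end_label_efficiency = end_label_efficiency,
                 stuck_qd_rate = stuck_qd_rate,
                 event_noise_sd_bp = event_noise_sd_bp,
                 recoil_range = recoil_range,
                 molecules_per_fov = as.integer(molecules_per_fov),
                 seed = as.integer(seed)),
            class = "scenario_config")
}

#' Optical model configuration
#'
#' Defaults derive from the stated imaging hardware: a 100x/NA 1.4 oil
#' objective with a 1.6x magnifier onto a 16 um-pixel EMCCD gives
#' 100 nm/px; PSF sigma 0.21*lambda/NA is ~98 nm for the 655 nm QD
#' channel and ~80 nm for the DNA-stain channel. Photon budgets are free
#' parameters of the simulation (shot-noise-only model; EMCCD excess
#' noise omitted).
#'
#' @param pixel_size_nm Camera pixel size in sample space (nm).
#' @param psf_sigma_green_nm,psf_sigma_red_nm Gaussian PSF sigma per channel.
#' @param photons_qd Mean detected photons per quantum-dot spot.
#' @param photons_fluosphere Mean detected photons per fluosphere.
#' @param fluosphere_sigma_factor Fluosphere apparent width relative to the
#'   red PSF (the bead is slightly larger than the slit depth).
#' @param backbone_photons_per_pixel Stained-DNA line intensity (photons per
#'   pixel of backbone length).
#' @param background_photons_per_pixel Mean background level, both channels.
#' @param channel_offset_px Split-view offset (dx, dy) of the red channel
#'   relative to the green, pixels.
#' @return An object of class `optical_config`.
#' @export
optical_config <- function(pixel_size_nm = 100,
                           psf_sigma_green_nm = 80,
                           psf_sigma_red_nm = 98,
                           photons_qd = 1600,
                           photons_fluosphere = 20000,
                           fluosphere_sigma_factor = 1.3,
                           backbone_photons_per_pixel = 150,
                           background_photons_per_pixel = 10,
                           channel_offset_px = c(3.2, 0.4)) {
  stopifnot(pixel_size_nm > 0, psf_sigma_green_nm > 0, psf_sigma_red_nm > 0,
            photons_qd >= 0, photons_fluosphere >= 0,
            fluosphere_sigma_factor > 0, backbone_photons_per_pixel >= 0,
            background_photons_per_pixel >= 0,
            length(channel_offset_px) == 2, all(is.finite(channel_offset_px)))
  structure(list(pixel_size_nm = pixel_size_nm,
                 psf_sigma_green_nm = psf_sigma_green_nm,
                 psf_sigma_red_nm = psf_sigma_red_nm,
                 photons_qd = photons_qd,
                 photons_fluosphere = photons_fluosphere,
                 fluosphere_sigma_factor = fluosphere_sigma_factor,
                 backbone_photons_per_pixel = backbone_photons_per_pixel,
                 background_photons_per_pixel = background_photons_per_pixel,
                 channel_offset_px = as.numeric(channel_offset_px)),
            class = "optical_config")
}

# Strip layout: molecules lie on parallel lanes sharing one vertical
# junction line (the micro-nano boundary); the field stretches them along
# +x. Dimensions in pixels.
fov_geometry <- function(scenario, genome, optics) {
  pix_um <- optics$pixel_size_nm / 1000
  contour_px <- ceiling(genome$stained_contour_um / pix_um)
  n_lanes <- scenario$molecules_per_fov
  list(junction_x_px = 16L,
       lane_spacing_px = 10L,
       lane_start_px = 10L,
       nx = as.integer(16L + contour_px + 20L),
       ny = as.integer(10L + n_lanes * 10L))
}

# Deterministic substream seeds so truth tables are stable under
# renderer changes (all randomness flows from scenario$seed).
substream_seed <- function(seed, name) {
  h <- sum(utf8ToInt(name) * seq_along(utf8ToInt(name)))
  as.integer((as.numeric(seed) * 48271 + h * 9973) %% 2147483629)
}

rtruncnorm01 <- function(n, mean, sd) {
  if (sd == 0) return(rep(mean, n))
  x <- stats::rnorm(n, mean, sd)
  bad <- which(x <= 0 | x > 1)
  while (length(bad)) {
    x[bad] <- stats::rnorm(length(bad), mean, sd)
    bad <- which(x <= 0 | x > 1)
  }
  x
}

#' Sample one molecule's ground truth
#'
#' Uses the current RNG state (callers seed a substream). Each
#' promoter-class site binds independently with `promoter_bind_prob`,
#' pseudo-promoter sites with `pseudo_bind_prob`; bound loci get zero-mean
#' Gaussian positional noise (SD `event_noise_sd_bp`, clipped to the
#' genome); the stretch fraction is Normal(`stretch_mean`, `stretch_sd`)
#' truncated to (0, 1]; the fluosphere is present with probability
#' `end_label_efficiency`; the recoiled (field-off) extension is uniform
#' in `recoil_range` times the stained contour.
#'
#' @param scenario A [scenario_config()].
#' @param genome A [genome_model()].
#' @return A list with fields `has_fluosphere`, `stretch_fraction`,
#'   `extension_um`, `recoiled_extension_um`, and `bound` (data.frame
#'   `site_name`, `class`, `site_locus_bp`, `locus_bp`).
#' @export
sample_molecule_truth <- function(scenario, genome) {
  sites <- scenario$true_sites
  has_fluo <- stats::runif(1) < scenario$end_label_efficiency
  stretch <- rtruncnorm01(1, scenario$stretch_mean, scenario$stretch_sd)
  p <- ifelse(sites$class == "promoter",
              scenario$promoter_bind_prob, scenario$pseudo_bind_prob)
  bound_idx <- which(stats::runif(nrow(sites)) < p)
  noise <- stats::rnorm(length(bound_idx), 0, scenario$event_noise_sd_bp)
  loci <- round(sites$locus_bp[bound_idx] + noise)
  loci <- pmin(pmax(loci, 1), genome$length_bp)
  recoil_frac <- stats::runif(1, scenario$recoil_range[1],
                              scenario$recoil_range[2])
  list(has_fluosphere = has_fluo,
       stretch_fraction = stretch,
       extension_um = stretch * genome$stained_contour_um,
       recoiled_extension_um = recoil_frac * genome$stained_contour_um,
       bound = data.frame(site_name = sites$name[bound_idx],
                          class = sites$class[bound_idx],
                          site_locus_bp = sites$locus_bp[bound_idx],
                          locus_bp = as.integer(loci),
                          stringsAsFactors = FALSE))
}

#' Sample ground truth for a whole experiment
#'
#' Lays molecules out on parallel lanes across fields of view (a common
#' junction line per FOV), samples each molecule's truth, and adds
#' Poisson-distributed surface-stuck contaminant QDs at fixed absolute
#' positions in each lane's strip.
#'
#' @param scenario A [scenario_config()].
#' @param genome A [genome_model()].
#' @param optics An [optical_config()].
#' @return An `experiment_truth` list: `scenario`, `genome`, `optics`,
#'   `geometry`, `molecules` (data.frame, one row per molecule with
#'   `bound_sites` and `stuck_qds` packed as `;`-delimited strings).
#' @export
simulate_truth <- function(scenario, genome = genome_model(),
                           optics = optical_config()) {
  geom <- fov_geometry(scenario, genome, optics)
  set.seed(substream_seed(scenario$seed, "truth"))
  n <- scenario$n_molecules
  rows <- vector("list", n)
  pix_um <- optics$pixel_size_nm / 1000
  for (i in seq_len(n)) {
    m <- sample_molecule_truth(scenario, genome)
    fov <- ((i - 1L) %/% scenario$molecules_per_fov) + 1L
    lane <- ((i - 1L) %% scenario$molecules_per_fov) + 1L
    anchor_y <- geom$lane_start_px + (lane - 1L) * geom$lane_spacing_px +
      stats::runif(1, -1, 1)
    n_stuck <- stats::rpois(1, scenario$stuck_qd_rate)
    stuck <- if (n_stuck > 0) {
      data.frame(
        x_px = stats::runif(n_stuck, geom$junction_x_px + 2,
                            geom$junction_x_px +
                              genome$stained_contour_um / pix_um - 2),
        y_px = anchor_y + stats::runif(n_stuck, -3, 3))
    } else data.frame(x_px = numeric(0), y_px = numeric(0))
    rows[[i]] <- list(
      molecule_id = sprintf("mol_%04d", i), fov = fov, lane = lane,
      anchor_x_px = geom$junction_x_px, anchor_y_px = anchor_y,
      has_fluosphere = m$has_fluosphere,
      stretch_fraction = m$stretch_fraction,
      extension_um = m$extension_um,
      recoiled_extension_um = m$recoiled_extension_um,
      bound_sites = pack_bound(m$bound),
      stuck_qds = pack_stuck(stuck))
  }
  molecules <- if (n > 0) {
    do.call(rbind, lapply(rows, function(r) as.data.frame(r, stringsAsFactors = FALSE)))
  } else empty_truth_df()
  structure(list(scenario = scenario, genome = genome, optics = optics,
                 geometry = geom, molecules = molecules),
            class = "experiment_truth")
}

empty_truth_df <- function() {
  data.frame(molecule_id = character(0), fov = integer(0), lane = integer(0),
             anchor_x_px = numeric(0), anchor_y_px = numeric(0),
             has_fluosphere = logical(0), stretch_fraction = numeric(0),
             extension_um = numeric(0), recoiled_extension_um = numeric(0),
             bound_sites = character(0), stuck_qds = character(0),
             stringsAsFactors = FALSE)
}

pack_bound <- function(bound) {
  if (nrow(bound) == 0) return("")
  paste(sprintf("%s:%s:%d", bound$site_name, bound$class, bound$locus_bp),
        collapse = ";")
}

pack_stuck <- function(stuck) {
  if (nrow(stuck) == 0) return("")
  paste(sprintf("%.2f:%.2f", stuck$x_px, stuck$y_px), collapse = ";")
}

#' Unpack truth bound-site strings into a long event table
#'
#' @param truth An `experiment_truth`, or its `molecules` data.frame.
#' @return data.frame `molecule_id`, `site_name`, `class`,
#'   `site_locus_bp`, `locus_bp` (one row per true binding event).
#' @export
truth_events <- function(truth) {
  mol <- if (inherits(truth, "experiment_truth")) truth$molecules else truth
  out <- lapply(seq_len(nrow(mol)), function(i) {
    s <- mol$bound_sites[i]
    if (is.na(s) || s == "") return(NULL)
    parts <- strsplit(strsplit(s, ";", fixed = TRUE)[[1]], ":", fixed = TRUE)
    data.frame(molecule_id = mol$molecule_id[i],
               site_name = vapply(parts, `[`, "", 1),
               class = vapply(parts, `[`, "", 2),
               locus_bp = as.integer(vapply(parts, `[`, "", 3)),
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, out)
  if (is.null(out))
    out <- data.frame(molecule_id = character(0), site_name = character(0),
                      class = character(0), locus_bp = integer(0))
  ks <- if (inherits(truth, "experiment_truth"))
    truth$scenario$true_sites else lambda_known_sites()
  out$site_locus_bp <- ks$locus_bp[match(out$site_name, ks$name)]
  out
}

unpack_stuck <- function(s) {
  if (is.na(s) || s == "")
    return(data.frame(x_px = numeric(0), y_px = numeric(0)))
  parts <- strsplit(strsplit(s, ";", fixed = TRUE)[[1]], ":", fixed = TRUE)
  data.frame(x_px = as.numeric(vapply(parts, `[`, "", 1)),
             y_px = as.numeric(vapply(parts, `[`, "", 2)))
}
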