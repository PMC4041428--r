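# End-to-end orchestration: simulate / analyze / evaluate, with a single
# YAML config and stderr logging. The analyze half only consumes TIFFs +
# metadata, so it runs unchanged on any real dataset laid out the same way.

#' Default pipeline configuration
#'
#' A nested list mirroring the YAML config accepted by the command-line
#' interface; every tunable default of the pipeline is overridable here.
#'
#' @param seed Master seed.
#' @return Nested configuration list.
#' @export
default_pipeline_config <- function(seed = 42L) {
  list(seed = as.integer(seed),
       scenario = unclass(scenario_config(seed = seed)),
       genome = list(length_bp = 48502L, rise_unstained_nm_per_bp = 0.34,
                     stained_contour_um = 22, labeled_end = "three_prime"),
       optics = unclass(optical_config()),
       rules = unclass(qualification_rules()),
       histogram = unclass(histogram_spec()),
       analysis = list(detect_k_red = 5, segment_k_green = 3,
                       fluo_photon_min = 5000, extension_sd_um = 0.1,
                       window_bp = 1500, match_radius_bp = 2000,
                       reestimate_offset = FALSE, plot = TRUE))
}

#' Load a pipeline configuration from YAML
#'
#' Values present in the file override the defaults; everything else
#' keeps its default.
#'
#' @param path YAML file path, or `NULL` for pure defaults.
#' @param seed Seed used when the file does not set one.
#' @return Configuration list (see [default_pipeline_config()]).
#' @export
load_pipeline_config <- function(path = NULL, seed = 42L) {
  cfg <- default_pipeline_config(seed)
  if (is.null(path)) return(cfg)
  if (!file.exists(path)) stop("config file not found: ", path)
  user <- yaml::read_yaml(path)
  if (!is.null(user$seed)) {
    cfg <- default_pipeline_config(as.integer(user$seed))
  }
  modifyList(cfg, user)
}

config_objects <- function(cfg) {
  sc <- cfg$scenario
  sc$true_sites <- as.data.frame(sc$true_sites, stringsAsFactors = FALSE)
  sc$recoil_range <- as.numeric(unlist(sc$recoil_range))
  sc$seed <- cfg$seed
  opt <- cfg$optics
  opt$channel_offset_px <- as.numeric(unlist(opt$channel_offset_px))
  hs <- cfg$histogram
  hs$range_bp <- as.numeric(unlist(hs$range_bp))
  list(scenario = do.call(scenario_config, sc),
       genome = do.call(genome_model, cfg$genome),
       optics = do.call(optical_config, opt),
       rules = do.call(qualification_rules, cfg$rules),
       histogram = do.call(histogram_spec, hs),
       analysis = cfg$analysis)
}

log_msg <- function(...) message("[slitmap] ", sprintf(...))

#' Simulate a synthetic dataset to disk
#'
#' @param config Configuration list ([default_pipeline_config()]) or a
#'   YAML path.
#' @param out_dir Output directory.
#' @return Invisibly, the `experiment_truth` (with `$paths`).
#' @export
run_simulate <- function(config = default_pipeline_config(), out_dir) {
  if (is.character(config)) config <- load_pipeline_config(config)
  obj <- config_objects(config)
  log_msg("simulating %d molecules (seed %d) -> %s",
          obj$scenario$n_molecules, obj$scenario$seed, out_dir)
  truth <- generate_experiment(obj$scenario, out_dir, obj$genome, obj$optics)
  log_msg("wrote %d FOV frame pairs, truth table, manifest",
          length(truth$paths$tiffs))
  invisible(truth)
}

analyze_fov <- function(pages, obj, fov_label) {
  optics <- obj$optics
  geom <- obj$geometry
  sig_g <- optics$psf_sigma_green_nm / optics$pixel_size_nm
  sig_r <- optics$psf_sigma_red_nm / optics$pixel_size_nm
  an <- obj$analysis
  has_off <- length(pages) >= 4
  obs <- list()
  for (phase in if (has_off) c("on", "off") else "on") {
    green <- pages[[if (phase == "on") 1 else 3]]
    red <- pages[[if (phase == "on") 2 else 4]]
    bb <- segment_backbones(green, geom$junction_x_px, sig_g,
                            optics$pixel_size_nm, k = an$segment_k_green)
    spots <- localize_spots(red, sig_r, optics$pixel_size_nm,
                            k = an$detect_k_red)
    offset <- optics$channel_offset_px
    if (isTRUE(an$reestimate_offset) && nrow(spots) > 0)
      offset <- tryCatch(
        estimate_channel_offset(spots, bb, geom$junction_x_px,
                                an$fluo_photon_min),
        error = function(e) optics$channel_offset_px)
    spots <- register_channels(spots, offset)
    obs[[phase]] <- match_spots_to_molecules(
      spots, bb, geom$junction_x_px, sig_r, optics$pixel_size_nm,
      an$fluo_photon_min)
    obs[[phase]]$n_spots <- nrow(spots)
  }
  qc <- qc_fov(obs$on, if (has_off) obs$off else NULL, obj$rules)
  # globally unique molecule ids
  relabel <- function(df) {
    df$molecule_id <- sprintf("%s_m%02d", fov_label, df$molecule_id)
    df
  }
  qc$molecules <- relabel(qc$molecules)
  qc$molecules$fov_label <- rep(fov_label, nrow(qc$molecules))
  qc$qds <- relabel(qc$qds)
  qc$n_spots_on <- obs$on$n_spots
  qc$verified <- has_off
  qc
}

#' Analyze a dataset of frame pairs into site calls
#'
#' Runs localization, molecule qualification + recoil filtering, event
#' assignment, histogramming, the multi-peak Gaussian fit, and site
#' calling. All intermediates are persisted as CSV under `out_dir`
#' (localization/molecule/QC/event tables, histogram, site calls,
#' known-site comparison, BED) and stage counts are logged to stderr.
#'
#' @param in_dir Dataset directory (TIFFs + `scenario.yaml` metadata).
#' @param out_dir Results directory.
#' @param config Configuration list or YAML path (analysis knobs; optics
#'   and geometry come from the dataset metadata).
#' @return Invisibly, a list with `molecules`, `qds`, `events`, `hist`,
#'   `fit`, `sites`, `comparison`, `n_qualified`.
#' @export
run_analyze <- function(in_dir, out_dir,
                        config = default_pipeline_config()) {
  if (is.character(config)) config <- load_pipeline_config(config)
  meta_path <- file.path(in_dir, "scenario.yaml")
  if (!file.exists(meta_path))
    stop("format error: missing metadata file ", meta_path,
         " (expected scenario.yaml with optics + geometry)")
  meta <- read_experiment_meta(meta_path)
  obj <- list(genome = meta$genome, optics = meta$optics,
              geometry = meta$geometry,
              rules = do.call(qualification_rules, config$rules),
              histogram = do.call(histogram_spec, {
                h <- config$histogram
                h$range_bp <- as.numeric(unlist(h$range_bp)); h
              }),
              analysis = config$analysis)
  tiffs <- sort(list.files(in_dir, pattern = "^fov_\\d+\\.tif$",
                           full.names = TRUE))
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  mols <- list(); qds <- list(); n_spots <- 0L
  for (p in tiffs) {
    pages <- read_tiff(p)
    if (!length(pages) %in% c(2L, 4L))
      stop("format error: ", p, " has ", length(pages),
           " pages; expected 4 (on-green, on-red, off-green, off-red)",
           " or 2 (field-on only)")
    fov_label <- sub("\\.tif$", "", basename(p))
    res <- analyze_fov(pages, obj, fov_label)
    mols[[fov_label]] <- res$molecules
    qds[[fov_label]] <- res$qds
    n_spots <- n_spots + res$n_spots_on
  }
  molecules <- if (length(mols)) do.call(rbind, mols) else
    data.frame(molecule_id = character(0), root_y_px = numeric(0),
               anchor_x_px = numeric(0), has_anchor = logical(0),
               extension_um = numeric(0), ambiguous = logical(0),
               n_qd = integer(0), qualified = logical(0),
               reason = character(0), in_denominator = logical(0),
               fov_label = character(0))
  qd_df <- if (length(qds)) do.call(rbind, qds) else
    data.frame(molecule_id = character(0), distance_um = numeric(0),
               x_px = numeric(0), y_px = numeric(0), photons = numeric(0),
               precision_nm = numeric(0), keep = logical(0),
               label = character(0))
  rownames(molecules) <- rownames(qd_df) <- NULL
  n_qualified <- sum(molecules$qualified)
  n_denominator <- if (nrow(molecules)) sum(molecules$in_denominator) else 0L
  log_msg("detected %d field-on red spots across %d FOVs", n_spots,
          length(tiffs))
  log_msg("segmented %d molecules, %d qualified (%d in frequency denominator)",
          nrow(molecules), n_qualified, n_denominator)
  events <- assign_loci(qd_df, molecules, obj$genome,
                        extension_sd_um = obj$analysis$extension_sd_um)
  log_msg("accepted %d binding events on qualified molecules", nrow(events))
  hist <- build_histogram(events, obj$histogram)
  peaks <- detect_peaks(hist)
  sites <- data.frame()
  fit <- NULL
  comparison <- compare_to_known(
    data.frame(mean_bp = numeric(0), sd_bp = numeric(0),
               amplitude = numeric(0), n_molecules = integer(0),
               frequency = numeric(0), matched_known_site = character(0),
               matched_class = character(0), error_bp = numeric(0),
               converged = logical(0)), obj$genome)
  if (nrow(peaks) > 0 && n_denominator > 0) {
    fit <- fit_multi_gaussian(hist, peaks)
    sites <- call_sites(fit, events, n_denominator, obj$genome,
                        window_bp = obj$analysis$window_bp,
                        match_radius_bp = obj$analysis$match_radius_bp)
    comparison <- compare_to_known(sites, obj$genome)
  }
  log_msg("called %d sites (%d matched to known loci)", nrow(sites),
          if (nrow(sites)) sum(!is.na(sites$matched_known_site)) else 0L)
  # persist intermediates
  w <- function(df, name) utils::write.csv(df, file.path(out_dir, name),
                                           row.names = FALSE)
  qd_out <- qd_df
  qd_out$distance_um <- round(qd_out$distance_um, 4)
  qd_out$x_px <- round(qd_out$x_px, 2); qd_out$y_px <- round(qd_out$y_px, 2)
  w(round_df(molecules), "molecules.csv")
  w(qd_out, "qc_qds.csv")
  w(events, "events.csv")
  w(hist, "histogram.csv")
  w(round_df(sites), "sites.csv")
  w(round_df(comparison$table), "comparison.csv")
  if (nrow(sites) > 0)
    export_sites_bed(sites, obj$genome, file.path(out_dir, "sites.bed"))
  if (isTRUE(obj$analysis$plot)) {
    grDevices::png(file.path(out_dir, "site_histogram.png"),
                   width = 900, height = 450)
    plot_site_histogram(hist, fit, obj$genome)
    grDevices::dev.off()
  }
  summary <- list(n_fovs = length(tiffs), n_spots_on = n_spots,
                  n_molecules = nrow(molecules), n_qualified = n_qualified,
                  n_frequency_denominator = n_denominator,
                  n_events = nrow(events), n_sites = nrow(sites),
                  max_promoter_error_bp = comparison$max_promoter_error_bp,
                  max_sd_bp = comparison$max_sd_bp,
                  fit_converged = if (is.null(fit)) NA else fit$converged)
  jsonlite::write_json(summary, file.path(out_dir, "analysis_summary.json"),
                       auto_unbox = TRUE, pretty = TRUE, digits = NA)
  invisible(list(molecules = molecules, qds = qd_df, events = events,
                 hist = hist, fit = fit, sites = sites,
                 comparison = comparison, n_qualified = n_qualified,
                 summary = summary))
}

round_df <- function(df, digits = 4) {
  for (cn in names(df)) if (is.numeric(df[[cn]]))
    df[[cn]] <- round(df[[cn]], digits)
  df
}

empty_spots_loc <- function() {
  data.frame(x_px = numeric(0), y_px = numeric(0), photons = numeric(0),
             precision_nm = numeric(0))
}

#' Evaluate analysis results against simulation ground truth
#'
#' Matches analyzed molecules to truth molecules by FOV and lane
#' position, then reports per-site recovery error and fitted SDs,
#' frequency estimates against the configured binding probabilities, QD
#' assignment sensitivity, and the stuck-contaminant rejection rate.
#' Written as `evaluation.json` plus a human-readable summary.
#'
#' @param results_dir Directory produced by [run_analyze()].
#' @param truth Dataset directory or `truth.csv` path from
#'   [run_simulate()].
#' @param out_dir Where to write the report (default `results_dir`).
#' @param match_window_bp Truth-event matching window (bp).
#' @return Invisibly, the metrics list.
#' @export
run_evaluate <- function(results_dir, truth, out_dir = results_dir,
                         match_window_bp = 1500) {
  truth_csv <- if (dir.exists(truth)) file.path(truth, "truth.csv") else truth
  if (!file.exists(truth_csv)) stop("truth table not found: ", truth_csv)
  meta_path <- file.path(dirname(truth_csv), "scenario.yaml")
  meta <- if (file.exists(meta_path)) read_experiment_meta(meta_path) else NULL
  tmol <- read_truth_csv(truth_csv)
  molecules <- utils::read.csv(file.path(results_dir, "molecules.csv"),
                               stringsAsFactors = FALSE)
  events <- utils::read.csv(file.path(results_dir, "events.csv"),
                            stringsAsFactors = FALSE)
  sites <- tryCatch(utils::read.csv(file.path(results_dir, "sites.csv"),
                                    stringsAsFactors = FALSE),
                    error = function(e) data.frame())
  if (nrow(molecules) > 0 && nrow(tmol) > 0) {
    tmol$fov_label <- sprintf("fov_%03d", tmol$fov)
    molecules$truth_id <- NA_character_
    for (i in seq_len(nrow(molecules))) {
      cand <- tmol[tmol$fov_label == molecules$fov_label[i], , drop = FALSE]
      if (!nrow(cand)) next
      d <- abs(cand$anchor_y_px - molecules$root_y_px[i])
      j <- which.min(d)
      if (d[j] <= 3) molecules$truth_id[i] <- cand$molecule_id[j]
    }
  } else molecules$truth_id <- character(0)
  if (anyDuplicated(stats::na.omit(molecules$truth_id)))
    stop("pairing error: two analyzed molecules map to one truth molecule")
  # per-known-site recovery
  truth_sites <- if (!is.null(meta)) meta$scenario$true_sites else
    lambda_known_sites()
  site_rows <- lapply(seq_len(nrow(truth_sites)), function(i) {
    nm <- truth_sites$name[i]
    m <- sites[!is.na(sites$matched_known_site) &
                 sites$matched_known_site == nm, , drop = FALSE]
    data.frame(name = nm, class = truth_sites$class[i],
               locus_bp = truth_sites$locus_bp[i],
               called = nrow(m) > 0,
               error_bp = if (nrow(m)) min(abs(m$mean_bp - truth_sites$locus_bp[i])) else NA_real_,
               sd_bp = if (nrow(m)) m$sd_bp[which.min(m$error_bp)] else NA_real_,
               frequency = if (nrow(m)) m$frequency[which.min(m$error_bp)] else NA_real_)
  })
  site_tab <- do.call(rbind, site_rows)
  # truth-event recovery on qualified, truth-matched molecules
  tev <- truth_events(tmol)
  qual <- molecules[molecules$qualified & !is.na(molecules$truth_id), ,
                    drop = FALSE]
  tev_q <- tev[tev$molecule_id %in% qual$truth_id, , drop = FALSE]
  hit <- 0L
  for (i in seq_len(nrow(tev_q))) {
    aid <- qual$molecule_id[qual$truth_id == tev_q$molecule_id[i]]
    ev <- events[events$molecule_id == aid, , drop = FALSE]
    if (any(abs(ev$locus_bp - tev_q$locus_bp[i]) <= match_window_bp))
      hit <- hit + 1L
  }
  sensitivity <- if (nrow(tev_q)) hit / nrow(tev_q) else NA_real_
  # stuck-QD rejection: a stuck contaminant is "accepted" if any accepted
  # event sits at its would-be locus on the analyzed molecule
  stuck_total <- 0L; stuck_accepted <- 0L
  if (!is.null(meta)) {
    pix_um <- meta$optics$pixel_size_nm / 1000
    for (i in seq_len(nrow(qual))) {
      tr <- tmol[tmol$molecule_id == qual$truth_id[i], , drop = FALSE]
      st <- unpack_stuck(tr$stuck_qds[1])
      if (!nrow(st)) next
      d_um <- (st$x_px - tr$anchor_x_px[1]) * pix_um
      keepable <- d_um >= 0 & d_um <= qual$extension_um[i]
      st_loci <- distance_to_locus(pmin(pmax(d_um, 0), qual$extension_um[i]),
                                   meta$genome,
                                   extension_um = qual$extension_um[i])
      ev <- events[events$molecule_id == qual$molecule_id[i], , drop = FALSE]
      for (k in seq_len(nrow(st))) {
        stuck_total <- stuck_total + 1L
        if (keepable[k] &&
            any(abs(ev$locus_bp - st_loci[k]) <= 600))
          stuck_accepted <- stuck_accepted + 1L
      }
    }
  }
  stuck_rejection <- if (stuck_total) 1 - stuck_accepted / stuck_total else NA_real_
  freq_cfg <- if (!is.null(meta))
    c(promoter = meta$scenario$promoter_bind_prob,
      pseudo_promoter = meta$scenario$pseudo_bind_prob) else
        c(promoter = NA_real_, pseudo_promoter = NA_real_)
  prom <- site_tab[site_tab$class == "promoter" & site_tab$called, ]
  pseu <- site_tab[site_tab$class == "pseudo_promoter" & site_tab$called, ]
  metrics <- list(
    n_truth_molecules = nrow(tmol),
    n_analyzed = nrow(molecules),
    n_qualified = sum(molecules$qualified),
    per_site = site_tab,
    max_promoter_error_bp = if (nrow(prom)) max(prom$error_bp) else NA_real_,
    max_sd_bp = if (any(site_tab$called)) max(site_tab$sd_bp, na.rm = TRUE) else NA_real_,
    mean_promoter_frequency = if (nrow(prom)) mean(prom$frequency) else NA_real_,
    mean_pseudo_frequency = if (nrow(pseu)) mean(pseu$frequency) else NA_real_,
    configured_promoter_prob = unname(freq_cfg["promoter"]),
    configured_pseudo_prob = unname(freq_cfg["pseudo_promoter"]),
    qd_assignment_sensitivity = sensitivity,
    stuck_qd_rejection_rate = stuck_rejection)
  out <- metrics
  out$per_site <- NULL
  out$per_site_table <- site_tab
  jsonlite::write_json(out, file.path(out_dir, "evaluation.json"),
                       auto_unbox = TRUE, pretty = TRUE, digits = NA,
                       dataframe = "rows", na = "null")
  lines <- c(
    sprintf("molecules: %d truth, %d analyzed, %d qualified",
            metrics$n_truth_molecules, metrics$n_analyzed,
            metrics$n_qualified),
    sprintf("max promoter error: %.0f bp; max fitted SD: %.0f bp",
            metrics$max_promoter_error_bp, metrics$max_sd_bp),
    sprintf("mean frequency: promoters %.3f (configured %.2f), pseudo %.3f (configured %.2f)",
            metrics$mean_promoter_frequency, metrics$configured_promoter_prob,
            metrics$mean_pseudo_frequency, metrics$configured_pseudo_prob),
    sprintf("QD assignment sensitivity: %.3f; stuck-QD rejection: %.3f",
            metrics$qd_assignment_sensitivity,
            metrics$stuck_qd_rejection_rate))
  writeLines(lines, file.path(out_dir, "evaluation.txt"))
  log_msg("%s", paste(lines, collapse = "\n[slitmap] "))
  invisible(metrics)
}
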