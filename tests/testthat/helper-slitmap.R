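# Shared fixtures and independent oracles. Everything is generated in
# code; heavyweight end-to-end runs are cached for the session.

quiet <- function(expr) suppressMessages(suppressWarnings(expr))

small_config <- function(n = 16, seed = 7, ...) {
  cfg <- default_pipeline_config(seed)
  cfg$scenario <- utils::modifyList(cfg$scenario,
                                    c(list(n_molecules = n), list(...)))
  cfg$analysis$plot <- FALSE
  cfg
}

# one isolated synthetic QD spot on a blank patch (pixel-integrated PSF,
# optionally Poisson-sampled); mirrors the acceptance precision setup
render_spot <- function(cx, cy, sigma_px, photons, size = 15,
                        poisson = TRUE) {
  img <- slitmap:::add_spot(matrix(0, size, size), cx, cy, sigma_px, photons)
  if (poisson) img <- matrix(stats::rpois(length(img), img), nrow = size)
  img
}

# independent brute-force oracle for the PSF-weighted centroid: same
# estimator definition, written directly (no shared code path)
oracle_centroid <- function(win, rows, cols, sigma_px, mask_factor = 3) {
  bord <- c(win[1, ], win[nrow(win), ], win[, 1], win[, ncol(win)])
  w0 <- win - median(bord)
  w0[w0 < 0] <- 0
  sm2 <- (mask_factor * sigma_px)^2
  k <- sm2 / (sm2 + sigma_px^2)
  cx <- cols[(length(cols) + 1) / 2]
  cy <- rows[(length(rows) + 1) / 2]
  for (it in 1:20) {
    sw <- 0; sx <- 0; sy <- 0
    for (r in seq_along(rows)) for (c in seq_along(cols)) {
      g <- exp(-((cols[c] - cx)^2 + (rows[r] - cy)^2) / (2 * sm2))
      sw <- sw + w0[r, c] * g
      sx <- sx + w0[r, c] * g * cols[c]
      sy <- sy + w0[r, c] * g * rows[r]
    }
    nx <- cx + (sx / sw - cx) / k
    ny <- cy + (sy / sw - cy) / k
    if (sqrt((nx - cx)^2 + (ny - cy)^2) < 0.01) { cx <- nx; cy <- ny; break }
    cx <- nx; cy <- ny
  }
  c(cx, cy)
}

# session cache for the expensive default-scenario end-to-end run
.slitmap_cache <- new.env(parent = emptyenv())

default_run <- function(seed = 42L) {
  key <- paste0("run_", seed)
  if (!is.null(.slitmap_cache[[key]])) return(.slitmap_cache[[key]])
  sim <- file.path(tempdir(), sprintf("slitmap_sim_%d", seed))
  res <- file.path(tempdir(), sprintf("slitmap_res_%d", seed))
  cfg <- default_pipeline_config(seed)
  cfg$analysis$plot <- FALSE
  quiet(run_simulate(cfg, sim))
  out <- quiet(run_analyze(sim, res, cfg))
  ev <- quiet(run_evaluate(res, sim))
  .slitmap_cache[[key]] <- list(sim = sim, res = res, analysis = out,
                                metrics = ev)
  .slitmap_cache[[key]]
}
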