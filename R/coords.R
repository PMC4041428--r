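# Lambda-DNA coordinate model and nanoslit confinement physics.
#
# The molecule is anchored by a fluosphere ligated to the 3' cos end
# (base 48,502 in the 1-based GenBank convention), so physical distance
# from the anchor increases toward base 1.

#' Known RNA-polymerase binding sites on the lambda genome
#'
#' The two strong promoters P_R and P_L plus three interior
#' pseudo-promoter loci that E. coli RNAP holoenzyme binds at lower
#' frequency. Loci are 1-based base-pair coordinates.
#'
#' @return A data.frame with columns `name`, `locus_bp`, `class`
#'   (`"promoter"` or `"pseudo_promoter"`).
#' @export
lambda_known_sites <- function() {
  data.frame(
    name = c("PR", "PL", "pseudo_27649", "pseudo_25620", "pseudo_23619"),
    locus_bp = c(38003L, 35602L, 27649L, 25620L, 23619L),
    class = c("promoter", "promoter",
              "pseudo_promoter", "pseudo_promoter", "pseudo_promoter"),
    stringsAsFactors = FALSE
  )
}

#' Lambda-DNA genome coordinate model
#'
#' Describes the coordinate system used throughout the pipeline: genome
#' length, helical rise of unstained B-DNA, contour length of the
#' intercalator-stained molecule (YOYO-1 lengthens DNA from 16.5 to about
#' 22 um), which end carries the fluosphere anchor, and the table of known
#' binding sites.
#'
#' @param length_bp Genome length in base pairs.
#' @param rise_unstained_nm_per_bp Rise per base pair of unstained DNA (nm).
#' @param stained_contour_um Contour length of the dye-stained molecule (um).
#' @param labeled_end Which end carries the fluosphere anchor.
#' @param known_sites data.frame of known sites (`name`, `locus_bp`, `class`).
#' @return An object of class `genome_model`.
#' @examples
#' g <- genome_model()
#' locus_to_distance(38000, g)  # ~3.57 um from the 3' anchor
#' @export
genome_model <- function(length_bp = 48502L,
                         rise_unstained_nm_per_bp = 0.34,
                         stained_contour_um = 22,
                         labeled_end = c("three_prime", "five_prime"),
                         known_sites = lambda_known_sites()) {
  labeled_end <- match.arg(labeled_end)
  length_bp <- as.integer(length_bp)
  stopifnot(length_bp > 0, rise_unstained_nm_per_bp > 0,
            stained_contour_um > 0)
  if (stained_contour_um * 1000 <= length_bp * rise_unstained_nm_per_bp)
    stop("stained contour must exceed the unstained contour (dye lengthens DNA)")
  if (!all(c("name", "locus_bp", "class") %in% names(known_sites)))
    stop("known_sites needs columns name, locus_bp, class")
  if (anyDuplicated(known_sites$name))
    stop("known site names must be unique")
  if (any(known_sites$locus_bp < 1 | known_sites$locus_bp > length_bp))
    stop("known site loci must lie in [1, length_bp]")
  if (!all(known_sites$class %in% c("promoter", "pseudo_promoter")))
    stop("site class must be promoter or pseudo_promoter")
  structure(
    list(length_bp = length_bp,
         rise_unstained_nm_per_bp = rise_unstained_nm_per_bp,
         stained_contour_um = stained_contour_um,
         labeled_end = labeled_end,
         known_sites = known_sites),
    class = "genome_model")
}

#' @export
print.genome_model <- function(x, ...) {
  cat(sprintf("genome_model: %d bp, rise %.3g nm/bp (unstained), stained contour %.3g um, %s anchor\n",
              x$length_bp, x$rise_unstained_nm_per_bp, x$stained_contour_um,
              sub("_", "-", x$labeled_end)))
  cat(sprintf("known sites: %s\n",
              paste0(x$known_sites$name, "@", x$known_sites$locus_bp,
                     collapse = ", ")))
  invisible(x)
}

rise_nm_per_bp <- function(genome, mode) {
  switch(mode,
         unstained = genome$rise_unstained_nm_per_bp,
         stained = genome$stained_contour_um * 1000 / genome$length_bp,
         stop("mode must be 'unstained' or 'stained'"))
}

#' Convert a base-pair locus to physical distance from the labeled end
#'
#' For the 3'-labeled lambda molecule the anchor sits at base
#' `length_bp`, so `distance = (length_bp - locus) * rise(mode)`. With the
#' default 0.34 nm/bp rise this reproduces the expected promoter
#' distances: P_R near base 38,000 lies ~3.55 um and P_L near base
#' 35,600 lies ~4.40 um from the fluosphere.
#'
#' @param locus Base-pair coordinate(s), 1-based; vectorized.
#' @param genome A [genome_model()].
#' @param mode `"unstained"` (B-DNA rise) or `"stained"` (stained contour
#'   divided by genome length).
#' @return Distance(s) from the labeled end, micrometers.
#' @export
locus_to_distance <- function(locus, genome,
                              mode = c("unstained", "stained")) {
  mode <- match.arg(mode)
  if (any(locus < 1 | locus > genome$length_bp))
    stop("locus out of range [1, ", genome$length_bp, "]")
  rise <- rise_nm_per_bp(genome, mode)
  bp_from_anchor <- if (genome$labeled_end == "three_prime")
    genome$length_bp - locus else locus - 1
  bp_from_anchor * rise / 1000
}

#' Convert a distance from the anchor to a base-pair locus
#'
#' Inverse of [locus_to_distance()]. When the per-molecule extension is
#' known, the map is normalized molecule by molecule:
#' `locus = length_bp * (1 - distance / extension)` (anchor at the 3'
#' end). Without an extension the stained rise scaled by a global stretch
#' factor is used.
#'
#' @param distance_um Distance(s) from the anchor, micrometers.
#' @param genome A [genome_model()].
#' @param extension_um Measured end-to-end extension of the molecule (um),
#'   or `NULL` to use `mode` + `stretch_fraction`.
#' @param mode Rise mode used when `extension_um` is absent.
#' @param stretch_fraction Global stretch factor applied to the rise when
#'   `extension_um` is absent.
#' @return Integer base-pair locus (rounded, clamped to `[1, length_bp]`).
#' @export
distance_to_locus <- function(distance_um, genome, extension_um = NULL,
                              mode = c("stained", "unstained"),
                              stretch_fraction = 1) {
  mode <- match.arg(mode)
  if (any(distance_um < 0))
    stop("distance must be non-negative")
  if (!is.null(extension_um)) {
    if (any(distance_um > extension_um + 1e-9))
      stop("distance exceeds molecule extension")
    frac <- distance_um / extension_um
  } else {
    rise <- rise_nm_per_bp(genome, mode) * stretch_fraction
    frac <- distance_um * 1000 / (rise * genome$length_bp)
    if (any(frac > 1 + 1e-9))
      stop("distance exceeds the genome contour at this stretch")
  }
  locus <- if (genome$labeled_end == "three_prime")
    genome$length_bp * (1 - frac) else genome$length_bp * frac + 1
  as.integer(pmin(pmax(round(locus), 1L), genome$length_bp))
}

#' Nanoslit confinement model
#'
#' Parameters of the loop-suppression criterion: DNA persistence length
#' L_p, slit depth (treated as the loop diameter 2R for a 180-degree
#' bend), and absolute temperature.
#'
#' @param persistence_length_nm DNA persistence length L_p (nm), ~50-60 nm
#'   for double-stranded DNA.
#' @param slit_depth_nm Nanoslit depth (nm); the device here is 60 nm deep.
#' @param temperature_K Absolute temperature (K).
#' @return An object of class `confinement_model`.
#' @export
confinement_model <- function(persistence_length_nm = 50,
                              slit_depth_nm = 60,
                              temperature_K = 298) {
  stopifnot(persistence_length_nm > 0, slit_depth_nm > 0, temperature_K > 0)
  structure(list(persistence_length_nm = persistence_length_nm,
                 slit_depth_nm = slit_depth_nm,
                 temperature_K = temperature_K),
            class = "confinement_model")
}

#' Bending energy of a hairpin loop in the slit, in units of k_B T
#'
#' `U = pi * k_B * T * L_p / (2R)` with the slit depth playing the role of
#' the loop diameter 2R. When U exceeds the thermal energy k_B T, loop
#' formation during field stretching is suppressed and the extension is
#' uniform.
#'
#' @param conf A [confinement_model()].
#' @return Loop bending energy in k_B T units.
#' @export
loop_bending_energy <- function(conf) {
  stopifnot(inherits(conf, "confinement_model"))
  pi * conf$persistence_length_nm / conf$slit_depth_nm
}

#' Are hairpin loops suppressed under this confinement?
#'
#' TRUE iff the loop bending energy strictly exceeds 1 k_B T. The
#' boundary case U = k_B T is reported as not suppressed (conservative).
#'
#' @param conf A [confinement_model()].
#' @return Logical.
#' @export
loops_suppressed <- function(conf) {
  loop_bending_energy(conf) > 1
}

#' Known sites as a GRanges / BED export
#'
#' Each site becomes a width-1 interval on chromosome `"lambda"`
#' (0-based half-open in the written BED, handled by rtracklayer).
#'
#' @param genome A [genome_model()].
#' @return A `GRanges` with site names and classes.
#' @export
known_sites_granges <- function(genome) {
  ks <- genome$known_sites
  gr <- GenomicRanges::GRanges(
    seqnames = "lambda",
    ranges = IRanges::IRanges(start = ks$locus_bp, width = 1L),
    name = ks$name, site_class = ks$class)
  GenomeInfoDb_safe_seqlengths(gr, genome$length_bp)
}

# rtracklayer emits cleaner BED when seqlengths are set; tolerate absence
# of GenomeInfoDb-level helpers.
GenomeInfoDb_safe_seqlengths <- function(gr, len) {
  try({
    GenomeInfoDb::seqlengths(gr) <- stats::setNames(as.integer(len), "lambda")
  }, silent = TRUE)
  gr
}

#' @rdname known_sites_granges
#' @param path Output BED path.
#' @export
export_known_sites_bed <- function(genome, path) {
  rtracklayer::export(known_sites_granges(genome), path, format = "BED")
  invisible(path)
}
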