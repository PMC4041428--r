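# Molecule qualification and false-positive exclusion by field-reversal
# (recoil) consistency: DNA-bound QDs ride with the relaxing chain when
# the field is released; surface-stuck contaminants do not move.

#' Molecule qualification rules
#'
#' Only molecules with the end-labeled fluosphere, at least one bound
#' QD, and a field-on extension of 9 um or longer (inclusive) enter the
#' binding statistics.
#'
#' @param min_extension_um Minimum field-on extension (um).
#' @param require_fluosphere Must the anchor fluosphere be present?
#' @param min_qd_count Minimum number of assigned QDs.
#' @param recoil_tolerance_um Matching tolerance of the recoil filter (um);
#'   ~3 px at 100 nm pixels.
#' @return An object of class `qualification_rules`.
#' @export
qualification_rules <- function(min_extension_um = 9.0,
                                require_fluosphere = TRUE,
                                min_qd_count = 1L,
                                recoil_tolerance_um = 0.3) {
  stopifnot(min_extension_um > 0, min_qd_count >= 0, recoil_tolerance_um > 0)
  structure(list(min_extension_um = min_extension_um,
                 require_fluosphere = isTRUE(require_fluosphere),
                 min_qd_count = as.integer(min_qd_count),
                 recoil_tolerance_um = recoil_tolerance_um),
            class = "qualification_rules")
}

#' Qualify field-on molecules for binding statistics
#'
#' Applies the rules in order and reports the first failing one:
#' `ambiguous` (merged backbones), `too_short`, `no_anchor`,
#' `too_few_qds`, else `ok`. `qualified` molecules contribute binding
#' events; `in_denominator` additionally marks molecules that count in
#' the binding-frequency denominator — those passing the anchor, length
#' and ambiguity rules regardless of QD count, since a labeled,
#' fully-stretched molecule with zero bound proteins is a valid
#' observation of "no binding".
#'
#' @param molecules Molecule table from [match_spots_to_molecules()]
#'   (field-on frame), with `extension_um`, `has_anchor`, `n_qd`,
#'   `ambiguous`.
#' @param rules A [qualification_rules()].
#' @return `molecules` with logical `qualified`, character `reason`, and
#'   logical `in_denominator`.
#' @export
qualify_molecules <- function(molecules, rules = qualification_rules()) {
  reason <- rep("ok", nrow(molecules))
  reason[molecules$n_qd < rules$min_qd_count] <- "too_few_qds"
  if (rules$require_fluosphere) reason[!molecules$has_anchor] <- "no_anchor"
  reason[molecules$extension_um < rules$min_extension_um] <- "too_short"
  if (!is.null(molecules$ambiguous)) reason[molecules$ambiguous] <- "ambiguous"
  molecules$qualified <- reason == "ok"
  molecules$reason <- reason
  molecules$in_denominator <- reason %in% c("ok", "too_few_qds")
  molecules
}

#' Recoil-consistency filter for one molecule's QDs
#'
#' A field-on QD at distance `d` from the anchor is kept when some
#' field-off QD lies within `recoil_tolerance_um` of the rescaled
#' position `d * off_extension / on_extension` (the label rides with the
#' chain). A QD whose absolute distance is unchanged between frames
#' (within tolerance) while the molecule recoiled by more than twice the
#' tolerance is labelled `stuck` and dropped. Without a field-off
#' observation every QD is kept with the label `unverified`.
#'
#' @param on_distances_um Field-on QD distances from the anchor (um).
#' @param off_distances_um Field-off QD distances, or `NULL` if no
#'   field-off frame exists.
#' @param on_extension_um,off_extension_um Molecule extensions in the two
#'   frames.
#' @param rules A [qualification_rules()].
#' @return data.frame `distance_um`, `keep`, `label` (one row per
#'   field-on QD; labels: `consistent`, `stuck`, `no_match`,
#'   `unverified`).
#' @export
recoil_filter <- function(on_distances_um, off_distances_um,
                          on_extension_um, off_extension_um,
                          rules = qualification_rules()) {
  n <- length(on_distances_um)
  if (is.null(off_distances_um) || is.na(off_extension_um)) {
    return(data.frame(distance_um = on_distances_um,
                      keep = rep(TRUE, n),
                      label = rep("unverified", n)))
  }
  tol <- rules$recoil_tolerance_um
  ratio <- off_extension_um / on_extension_um
  recoiled <- (on_extension_um - off_extension_um) > 2 * tol
  keep <- logical(n); label <- character(n)
  for (i in seq_len(n)) {
    d <- on_distances_um[i]
    stuck <- recoiled && any(abs(off_distances_um - d) <= tol)
    matched <- any(abs(off_distances_um - d * ratio) <= tol)
    if (stuck && !(matched && d * (1 - ratio) <= 2 * tol)) {
      # unchanged absolute position on a recoiling chain: contaminant
      keep[i] <- FALSE; label[i] <- "stuck"
    } else if (matched) {
      keep[i] <- TRUE; label[i] <- "consistent"
    } else {
      keep[i] <- FALSE; label[i] <- "no_match"
    }
  }
  data.frame(distance_um = on_distances_um, keep = keep, label = label)
}

#' Apply qualification and the recoil filter across an experiment
#'
#' @param on_obs,off_obs Lists from [match_spots_to_molecules()] for the
#'   field-on and (optionally `NULL`) field-off frames of one FOV; the
#'   two are paired by matching junction-root lane positions within
#'   `pair_tolerance_px`.
#' @param rules A [qualification_rules()].
#' @param pair_tolerance_px Maximum lane distance for cross-frame pairing.
#' @return List: `molecules` (qualified table), `qds` (field-on QDs with
#'   `keep`/`label`), `orphans`.
#' @export
qc_fov <- function(on_obs, off_obs = NULL, rules = qualification_rules(),
                   pair_tolerance_px = 3) {
  mol <- qualify_molecules(on_obs$molecules, rules)
  qds <- on_obs$qds
  qds$keep <- rep(TRUE, nrow(qds))
  qds$label <- rep("unverified", nrow(qds))
  for (j in seq_len(nrow(mol))) {
    id <- mol$molecule_id[j]
    sel <- which(qds$molecule_id == id)
    if (!length(sel)) next
    off_d <- NULL; off_ext <- NA_real_
    if (!is.null(off_obs) && nrow(off_obs$molecules) > 0) {
      dd <- abs(off_obs$molecules$root_y_px - mol$root_y_px[j])
      jj <- which.min(dd)
      if (dd[jj] <= pair_tolerance_px) {
        off_ext <- off_obs$molecules$extension_um[jj]
        off_d <- off_obs$qds$distance_um[
          off_obs$qds$molecule_id == off_obs$molecules$molecule_id[jj]]
      }
    }
    res <- recoil_filter(qds$distance_um[sel], off_d,
                         mol$extension_um[j], off_ext, rules)
    qds$keep[sel] <- res$keep
    qds$label[sel] <- res$label
  }
  # a qualified molecule must retain >= min_qd_count accepted QDs
  kept_counts <- vapply(mol$molecule_id, function(id)
    sum(qds$keep[qds$molecule_id == id]), integer(1))
  drop <- mol$qualified & kept_counts < rules$min_qd_count
  mol$qualified[drop] <- FALSE
  mol$reason[drop] <- "too_few_qds"
  list(molecules = mol, qds = qds, orphans = on_obs$orphans)
}
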