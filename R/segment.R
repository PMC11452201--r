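#' Configuration for the rules-based segmenter
#'
#' Transparent replacement for a learned segmenter: lumen by global
#' thresholding, vessels by a local-thickness criterion, lesions by the two
#' structural signals that distinguish fibrotic regions — locally sparser and
#' locally thicker sinusoids.
#'
#' @param polarity `"lumen_dark"` (vascular lumen darker than tissue, the
#'   package's rendering convention) or `"lumen_bright"`.
#' @param lumen_threshold_method `"otsu"` for a global Otsu threshold on the
#'   normalized intensities, or `"fixed"`.
#' @param fixed_threshold threshold in `[0, 1]`; required iff method is
#'   `"fixed"`.
#' @param vessel_min_radius_um lumen voxels with local thickness at or above
#'   this radius are classified as vessel rather than sinusoid.
#' @param min_object_voxels connected lumen components (26-connectivity)
#'   smaller than this are discarded as noise.
#' @param lesion_reach_um sinusoid reach: tissue farther than this from any
#'   normal-caliber sinusoid is considered lesion candidate. `NULL` (default)
#'   chooses the reach automatically as 2.5 times the median
#'   distance-to-sinusoid of the tissue, i.e. a multiple of the network's own
#'   spacing scale.
#' @param min_caliber_ratio minimum ratio between the mean thickness of the
#'   wide and narrow sinusoid caliber classes for the caliber split to be
#'   trusted; below it the network is treated as single-caliber.
#' @param opening_radius_um radius of the morphological opening that removes
#'   spurious small detections.
#' @param closing_radius_um radius of the morphological closing that smooths
#'   the final lesion mask.
#' @param min_lesion_diameter_um detected lesion components smaller in
#'   volume than a ball of this diameter are discarded.
#' @return An object of class `segmenter_config`.
#' @export
segmenter_config <- function(polarity = c("lumen_dark", "lumen_bright"),
                             lumen_threshold_method = c("otsu", "fixed"),
                             fixed_threshold = NULL,
                             vessel_min_radius_um = 15,
                             min_object_voxels = 27L,
                             lesion_reach_um = NULL,
                             min_caliber_ratio = 1.4,
                             opening_radius_um = 5,
                             closing_radius_um = 10,
                             min_lesion_diameter_um = 25) {
  polarity <- match.arg(polarity)
  lumen_threshold_method <- match.arg(lumen_threshold_method)
  if (lumen_threshold_method == "fixed" && is.null(fixed_threshold))
    stop("`fixed_threshold` is required when lumen_threshold_method='fixed'")
  if (lumen_threshold_method == "otsu" && !is.null(fixed_threshold))
    stop("`fixed_threshold` must be NULL unless lumen_threshold_method='fixed'")
  if (!is.null(lesion_reach_um) && lesion_reach_um <= 0)
    stop("`lesion_reach_um` must be positive (or NULL for automatic)")
  structure(list(polarity = polarity,
                 lumen_threshold_method = lumen_threshold_method,
                 fixed_threshold = fixed_threshold,
                 vessel_min_radius_um = vessel_min_radius_um,
                 min_object_voxels = as.integer(min_object_voxels),
                 lesion_reach_um = lesion_reach_um,
                 min_caliber_ratio = min_caliber_ratio,
                 opening_radius_um = opening_radius_um,
                 closing_radius_um = closing_radius_um,
                 min_lesion_diameter_um = min_lesion_diameter_um),
            class = "segmenter_config")
}

#' Segment the vascular lumen
#'
#' Global threshold (Otsu on the intensity histogram, or fixed) applied with
#' the configured polarity to a preprocessed, normalized volume, followed by
#' removal of connected components (26-connectivity) below the minimum object
#' size.
#'
#' @param vol a normalized [volume3d()] (intensities in `[0, 1]`).
#' @param cfg a [segmenter_config()].
#' @return 3D logical lumen mask.
#' @export
segment_lumen <- function(vol, cfg = segmenter_config()) {
  stopifnot(inherits(vol, "volume3d"), inherits(cfg, "segmenter_config"))
  x <- vol$data
  if (min(x) < 0 || max(x) > 1)
    stop("expected a normalized volume with intensities in [0, 1]")
  thr <- if (cfg$lumen_threshold_method == "fixed") cfg$fixed_threshold
  else if (diff(range(x)) == 0) NA_real_
  else EBImage::otsu(matrix(as.numeric(x), ncol = 1L), range = c(0, 1))
  if (is.na(thr)) {
    warning("constant volume: returning empty lumen mask")
    return(array(FALSE, dim(x)))
  }
  lumen <- if (cfg$polarity == "lumen_dark") x < thr else x > thr
  lumen <- drop_small_components(lumen, cfg$min_object_voxels, 26L)
  if (!any(lumen)) warning("lumen mask empty after size filtering")
  lumen
}

#' Split the lumen into sinusoids and vessels
#'
#' Computes the local thickness of the lumen mask and classifies voxels whose
#' largest inscribed sphere has radius at or above `vessel_min_radius_um` —
#' the thick cores of large vessels, which sphere painting extends over the
#' entire vessel body — as vessel; the remaining lumen is sinusoid. The two
#' outputs are disjoint by construction.
#'
#' @param lumen 3D logical lumen mask.
#' @param voxel_size_um voxel size in micrometres.
#' @param cfg a [segmenter_config()].
#' @return List with logical `sinusoid` and `vessel` masks.
#' @export
split_vessels <- function(lumen, voxel_size_um, cfg = segmenter_config()) {
  lumen <- as_mask(lumen)
  if (!any(lumen))
    return(list(sinusoid = lumen, vessel = lumen))
  # vessels continue beyond the field of view, so the split thickness treats
  # the volume border as object continuation rather than background
  tm <- local_thickness(lumen, voxel_size_um, border = "object")
  vessel <- !is.na(tm$values) & tm$values >= cfg$vessel_min_radius_um
  list(sinusoid = lumen & !vessel, vessel = vessel)
}

#' Segment lesion regions
#'
#' Fibrotic lesions are detected from the two structural signals that
#' distinguish them: the sinusoid network inside lesions is sparser and its
#' tubes are wider. Sinusoid voxels are first split into a narrow (normal)
#' and a wide caliber class by an Otsu cut on their local thickness (the
#' split is only trusted when the class mean thicknesses differ by at least
#' `min_caliber_ratio`, otherwise the whole network counts as normal).
#' Unaffected tissue is, by definition, tissue within sinusoid reach of a
#' normal-caliber sinusoid; the raw lesion mask is the tissue beyond
#' `lesion_reach_um` of any narrow tube. It is then cleaned by a
#' morphological opening, re-expanded by the reach (the raw detection is an
#' eroded core of the true region), closed, filtered for a minimum lesion
#' size, and stripped of vessel voxels.
#'
#' @param vol the [volume3d()] the masks belong to, or a voxel size in
#'   micrometres.
#' @param sinusoid,vessel 3D logical masks from [split_vessels()].
#' @param cfg a [segmenter_config()].
#' @return 3D logical lesion mask, disjoint from `vessel`.
#' @export
segment_lesions <- function(vol, sinusoid, vessel,
                            cfg = segmenter_config()) {
  sinusoid <- as_mask(sinusoid); vessel <- as_mask(vessel)
  check_same_shape(sinusoid, vessel)
  d <- dim(sinusoid)
  vs <- if (inherits(vol, "volume3d")) vol$voxel_size_um else rep(vol, 3L)
  if (length(vs) == 1L) vs <- rep(vs, 3L)
  dom <- !vessel
  if (!any(sinusoid)) return(array(FALSE, d))

  # caliber split on local thickness
  tm <- local_thickness(sinusoid, vs)
  tv <- tm$values[sinusoid]
  cut <- EBImage::otsu(matrix(tv / max(tv), ncol = 1L),
                       range = c(0, 1)) * max(tv)
  wide <- tv >= cut
  trusted <- any(wide) && any(!wide) &&
    mean(tv[wide]) / mean(tv[!wide]) >= cfg$min_caliber_ratio
  # a fibrotic lesion is vascularized by widened sinusoids; without caliber
  # contrast in the network there is no lesion signature to report
  if (!trusted) return(array(FALSE, d))
  narrow <- sinusoid
  narrow[sinusoid] <- !wide

  d2 <- dist_to_set_sq(narrow, vs)
  dthin <- sqrt(d2)
  reach <- cfg$lesion_reach_um
  if (is.null(reach)) {
    pos <- dthin[dom & dthin > 0]
    if (!length(pos)) return(array(FALSE, d))
    reach <- 2.5 * median(pos)
  }

  raw <- dom & dthin > reach
  op <- dilate_ball(erode_ball(raw, cfg$opening_radius_um, vs),
                    cfg$opening_radius_um, vs)
  lesion <- dilate_ball(op, reach, vs)
  lesion <- close_ball(lesion, cfg$closing_radius_um, vs) & dom
  min_vox <- ceiling(pi / 6 * cfg$min_lesion_diameter_um^3 / prod(vs))
  lesion <- drop_small_components(lesion, min_vox, 26L)
  lesion & dom
}

#' Run the full segmentation chain
#'
#' Lumen thresholding, vessel/sinusoid split, lesion detection; returns a
#' [region_masks()] with domain equal to the full volume.
#'
#' @param vol a normalized [volume3d()].
#' @param cfg a [segmenter_config()].
#' @return A [region_masks()] object.
#' @export
segment_volume <- function(vol, cfg = segmenter_config()) {
  lumen <- segment_lumen(vol, cfg)
  sv <- split_vessels(lumen, vol$voxel_size_um, cfg)
  lesion <- segment_lesions(vol, sv$sinusoid, sv$vessel, cfg)
  region_masks(sv$sinusoid, sv$vessel, lesion, array(TRUE, dim(vol$data)),
               voxel_size_um = vol$voxel_size_um)
}

#' Dice overlap coefficient
#'
#' `2|A n B| / (|A| + |B|)` for two binary masks of the same shape; defined
#' as 1 when both masks are empty.
#'
#' @param a,b 3D logical masks.
#' @return Dice coefficient in `[0, 1]`.
#' @export
dice <- function(a, b) {
  a <- as_mask(a); b <- as_mask(b)
  check_same_shape(a, b)
  sa <- sum(a); sb <- sum(b)
  if (sa + sb == 0) return(1.0)
  2 * sum(a & b) / (sa + sb)
}
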