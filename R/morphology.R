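# Low-level binary morphology built on the exact Euclidean distance
# transform: dilation/erosion by an open Euclidean ball of physical radius.

dist_to_set_sq <- function(set, spacing, border_in_set = FALSE) {
  set <- as_mask(set)
  d <- dim(set)
  out <- dist_to_set_sq_cpp(set, as.integer(d), as.numeric(spacing),
                            border_in_set)
  array(out, d)
}

dilate_ball <- function(mask, radius_um, spacing) {
  mask <- as_mask(mask)
  if (radius_um <= 0 || !any(mask)) return(mask)
  d2 <- dist_to_set_sq(mask, spacing, border_in_set = FALSE)
  mask | (d2 < radius_um^2)
}

erode_ball <- function(mask, radius_um, spacing) {
  mask <- as_mask(mask)
  if (radius_um <= 0 || !any(mask)) return(mask)
  # distance from mask voxels to the background; the field outside the volume
  # is not treated as background so closing does not erode at the faces
  d2 <- dist_to_set_sq(!mask, spacing, border_in_set = FALSE)
  mask & !(d2 < radius_um^2)
}

close_ball <- function(mask, radius_um, spacing) {
  erode_ball(dilate_ball(mask, radius_um, spacing), radius_um, spacing)
}

label_components <- function(mask, connectivity = 26L) {
  mask <- as_mask(mask)
  array(label3d_cpp(mask, as.integer(dim(mask)), as.integer(connectivity)),
        dim(mask))
}

drop_small_components <- function(mask, min_voxels, connectivity = 26L) {
  if (min_voxels <= 1L || !any(mask)) return(as_mask(mask))
  lab <- label_components(mask, connectivity)
  sizes <- tabulate(lab[lab > 0L])
  keep <- which(sizes >= min_voxels)
  array(lab %in% keep, dim(lab))
}

gaussian_smooth <- function(vol, sigma_vox) {
  d <- dim(vol)
  out <- as.numeric(vol)
  for (axis in 1:3) {
    s <- sigma_vox[min(axis, length(sigma_vox))]
    if (s <= 0) next
    r <- max(1L, ceiling(3 * s))
    k <- exp(-(seq(-r, r))^2 / (2 * s^2))
    k <- k / sum(k)
    out <- conv_axis_cpp(out, as.integer(d), k, axis)
  }
  array(out, d)
}
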