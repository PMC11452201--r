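#' 3D intensity volume with physical voxel size
#'
#' Container for a 3D scalar grid together with its voxel size in micrometres
#' and a provenance log of the operations applied to it. The array uses
#' `(z, y, x)` axis order throughout the package; voxel size may be a single
#' number (isotropic) or one value per axis in the same order.
#'
#' @param data 3D numeric array, axis order `(z, y, x)`.
#' @param voxel_size_um positive numeric, length 1 or 3 (z, y, x), in
#'   micrometres.
#' @param provenance list of previously applied operations; each entry is a
#'   list with at least an `op` name and its parameters.
#' @return An object of class `volume3d`.
#' @export
#' @examples
#' v <- volume3d(array(runif(8^3), c(8, 8, 8)), voxel_size_um = 1.6)
#' dim(v$data)
volume3d <- function(data, voxel_size_um, provenance = list()) {
  if (!is.array(data) || length(dim(data)) != 3L)
    stop("`data` must be a 3D array (z, y, x)")
  storage.mode(data) <- "double"
  voxel_size_um <- as.numeric(voxel_size_um)
  if (length(voxel_size_um) == 1L) voxel_size_um <- rep(voxel_size_um, 3L)
  if (length(voxel_size_um) != 3L || any(!is.finite(voxel_size_um)) ||
      any(voxel_size_um <= 0))
    stop("`voxel_size_um` must be 1 or 3 positive finite values")
  structure(list(data = data, voxel_size_um = voxel_size_um,
                 provenance = provenance),
            class = "volume3d")
}

#' @export
print.volume3d <- function(x, ...) {
  d <- dim(x$data)
  cat(sprintf("volume3d: %d x %d x %d voxels (z,y,x), voxel size %s um\n",
              d[1], d[2], d[3],
              paste(format(x$voxel_size_um, digits = 4), collapse = " x ")))
  if (length(x$provenance))
    cat("provenance:", paste(vapply(x$provenance, `[[`, "", "op"),
                             collapse = " -> "), "\n")
  invisible(x)
}

#' @export
dim.volume3d <- function(x) dim(x$data)

log_op <- function(vol, op, ...) {
  vol$provenance <- c(vol$provenance, list(c(list(op = op), list(...))))
  vol
}

as_mask <- function(x, name = deparse(substitute(x))) {
  if (inherits(x, "volume3d")) x <- x$data
  if (is.numeric(x)) x <- x != 0
  if (!is.logical(x) || length(dim(x)) != 3L)
    stop(sprintf("`%s` must be a 3D logical mask", name))
  x[is.na(x)] <- FALSE
  x
}

check_same_shape <- function(...) {
  dims <- lapply(list(...), dim)
  if (!all(vapply(dims, identical, TRUE, dims[[1]])))
    stop("masks/volumes must share the same shape")
  invisible(dims[[1]])
}

#' Aligned region masks for one volume
#'
#' Bundles the four binary region classes produced by segmentation (or by the
#' phantom generator as ground truth): the sinusoid lumen network, large
#' vessels, lesion regions, and the tissue-domain support. Sinusoids may lie
#' inside lesions; lesions are defined as the tissue region including its
#' sinusoid lumina. Vessels and lesions are disjoint by construction.
#'
#' @param sinusoid,vessel,lesion,domain 3D logical arrays of identical shape.
#' @param voxel_size_um voxel size in micrometres (length 1 or 3, z/y/x).
#' @return An object of class `region_masks`.
#' @export
region_masks <- function(sinusoid, vessel, lesion, domain,
                         voxel_size_um = 1) {
  sinusoid <- as_mask(sinusoid); vessel <- as_mask(vessel)
  lesion <- as_mask(lesion); domain <- as_mask(domain)
  check_same_shape(sinusoid, vessel, lesion, domain)
  if (any(vessel & lesion)) stop("vessel and lesion masks must be disjoint")
  if (any(vessel & sinusoid)) stop("vessel and sinusoid masks must be disjoint")
  if (any(lesion & !domain)) stop("lesion mask must lie within the domain")
  if (any(sinusoid & !domain)) stop("sinusoid mask must lie within the domain")
  voxel_size_um <- as.numeric(voxel_size_um)
  if (length(voxel_size_um) == 1L) voxel_size_um <- rep(voxel_size_um, 3L)
  structure(list(sinusoid = sinusoid, vessel = vessel, lesion = lesion,
                 domain = domain, voxel_size_um = voxel_size_um),
            class = "region_masks")
}

#' @export
print.region_masks <- function(x, ...) {
  d <- dim(x$domain)
  cat(sprintf("region_masks: %d x %d x %d voxels (z,y,x)\n", d[1], d[2], d[3]))
  for (cl in c("sinusoid", "vessel", "lesion", "domain"))
    cat(sprintf("  %-8s %d voxels\n", cl, sum(x[[cl]])))
  invisible(x)
}
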