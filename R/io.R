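#' Read a 3D volume from disk
#'
#' Reads a multi-page TIFF stack or a NIfTI-1 file into a [volume3d()].
#' NIfTI voxel sizes come from the header (`pixdim`); TIFF stacks require a
#' JSON sidecar (`<path>.json`) with at least a `voxel_size_um` entry, since
#' plain TIFF carries no reliable physical scale. Missing metadata is an
#' error, never a silent default.
#'
#' TIFF pages are z-slices; NIfTI `(x, y, z)` axes are transposed to the
#' package's `(z, y, x)` order on read. TIFF intensities are stored in
#' `[0, 1]` (32-bit float) and mapped back to the original range recorded in
#' the sidecar.
#'
#' @param path file path ending in `.tif`, `.tiff`, `.nii` or `.nii.gz`.
#' @return A [volume3d()].
#' @seealso [write_volume()]
#' @export
read_volume <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  if (grepl("\\.tiff?$", path, ignore.case = TRUE)) {
    sidecar <- paste0(path, ".json")
    if (!file.exists(sidecar))
      stop("TIFF volume requires a JSON sidecar with voxel_size_um: ",
           sidecar, " not found")
    meta <- jsonlite::read_json(sidecar, simplifyVector = TRUE)
    if (is.null(meta$voxel_size_um))
      stop("sidecar ", sidecar, " lacks voxel_size_um")
    pages <- tiff::readTIFF(path, all = TRUE)
    if (!is.list(pages)) pages <- list(pages)
    d <- dim(pages[[1]])
    if (length(d) != 2L) stop("expected single-channel grayscale TIFF pages")
    a <- array(0, c(length(pages), d[1], d[2]))
    for (z in seq_along(pages)) a[z, , ] <- pages[[z]]
    rng <- meta$intensity_range
    if (!is.null(rng) && length(rng) == 2L && rng[2] > rng[1])
      a <- a * (rng[2] - rng[1]) + rng[1]
    volume3d(a, meta$voxel_size_um)
  } else if (grepl("\\.nii(\\.gz)?$", path, ignore.case = TRUE)) {
    img <- RNifti::readNifti(path)
    a <- as.array(img)
    if (length(dim(a)) != 3L) stop("expected 3D NIfTI data in ", path)
    pd <- RNifti::pixdim(img)[seq_len(3)]
    if (any(!is.finite(pd)) || any(pd <= 0))
      stop("NIfTI header of ", path, " has invalid pixdim")
    volume3d(aperm(a, c(3, 2, 1)), voxel_size_um = rev(pd))
  } else {
    stop("unsupported volume format: ", path)
  }
}

#' Write a 3D volume to disk
#'
#' Writes a [volume3d()] as a multi-page 32-bit float TIFF (one page per
#' z-slice, intensities rescaled to `[0, 1]` with the original range stored in
#' a JSON sidecar alongside the voxel size) or as a double-precision NIfTI-1
#' file (bit-exact round trip, voxel size in the header).
#'
#' @param vol a [volume3d()].
#' @param path output path; format chosen by extension.
#' @return `path`, invisibly.
#' @export
write_volume <- function(vol, path) {
  stopifnot(inherits(vol, "volume3d"))
  a <- vol$data
  if (grepl("\\.tiff?$", path, ignore.case = TRUE)) {
    rng <- range(a)
    meta <- list(voxel_size_um = vol$voxel_size_um, format = "float32")
    if (rng[1] < 0 || rng[2] > 1) {
      if (rng[2] > rng[1]) a <- (a - rng[1]) / (rng[2] - rng[1])
      else a <- array(0, dim(a))
      meta$intensity_range <- rng
    }
    pages <- lapply(seq_len(dim(a)[1]), function(z) a[z, , ])
    tiff::writeTIFF(pages, path, bits.per.sample = 32L, reduce = FALSE)
    jsonlite::write_json(meta, paste0(path, ".json"),
                         auto_unbox = TRUE, digits = NA)
  } else if (grepl("\\.nii(\\.gz)?$", path, ignore.case = TRUE)) {
    arr <- aperm(a, c(3, 2, 1))
    attr(arr, "pixdim") <- rev(vol$voxel_size_um)
    img <- RNifti::asNifti(arr, datatype = "double")
    RNifti::writeNifti(img, path, datatype = "double")
  } else {
    stop("unsupported volume format: ", path)
  }
  invisible(path)
}

#' Read or write region masks
#'
#' Masks are stored one file per class (`sinusoid`, `vessel`, `lesion`,
#' `domain`) in a directory, as 8-bit 0/1 TIFF stacks or NIfTI volumes, with
#' a `masks.json` sidecar recording the voxel size.
#'
#' @param masks a [region_masks()] object.
#' @param dir directory to write into (created if missing).
#' @param format `"tiff"` or `"nifti"`.
#' @return `dir` (write) or a [region_masks()] (read).
#' @export
write_masks <- function(masks, dir, format = c("tiff", "nifti")) {
  format <- match.arg(format)
  stopifnot(inherits(masks, "region_masks"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  ext <- if (format == "tiff") ".tif" else ".nii"
  for (cl in c("sinusoid", "vessel", "lesion", "domain")) {
    a <- masks[[cl]] * 1
    path <- file.path(dir, paste0(cl, ext))
    if (format == "tiff") {
      pages <- lapply(seq_len(dim(a)[1]), function(z) a[z, , ])
      tiff::writeTIFF(pages, path, bits.per.sample = 8L, reduce = FALSE)
    } else {
      arr <- aperm(a, c(3, 2, 1))
      attr(arr, "pixdim") <- rev(masks$voxel_size_um)
      RNifti::writeNifti(RNifti::asNifti(arr, datatype = "uint8"), path,
                         datatype = "uint8")
    }
  }
  jsonlite::write_json(list(voxel_size_um = masks$voxel_size_um),
                       file.path(dir, "masks.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(dir)
}

#' @rdname write_masks
#' @export
read_masks <- function(dir) {
  meta_path <- file.path(dir, "masks.json")
  if (!file.exists(meta_path)) stop("masks.json sidecar not found in ", dir)
  meta <- jsonlite::read_json(meta_path, simplifyVector = TRUE)
  get1 <- function(cl) {
    for (ext in c(".tif", ".tiff", ".nii", ".nii.gz")) {
      p <- file.path(dir, paste0(cl, ext))
      if (file.exists(p)) {
        if (grepl("tif", ext)) {
          pages <- tiff::readTIFF(p, all = TRUE)
          if (!is.list(pages)) pages <- list(pages)
          a <- array(0, c(length(pages), dim(pages[[1]])))
          for (z in seq_along(pages)) a[z, , ] <- pages[[z]]
        } else {
          a <- aperm(as.array(RNifti::readNifti(p)), c(3, 2, 1))
        }
        return(a > 0.5)
      }
    }
    stop("mask file for class '", cl, "' not found in ", dir)
  }
  region_masks(get1("sinusoid"), get1("vessel"), get1("lesion"),
               get1("domain"), voxel_size_um = meta$voxel_size_um)
}
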