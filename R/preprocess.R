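#' Downscale a volume by block averaging
#'
#' Each output voxel is the arithmetic mean of a `factor^3` block, the usual
#' meaning of "2x binning" in tomography; the voxel size scales by the same
#' factor so physical dimensions are preserved. Dimensions that are not
#' divisible by the factor are cropped at the trailing end (never padded) and
#' the crop is recorded in the provenance log.
#'
#' @param vol a [volume3d()].
#' @param factor positive integer binning factor.
#' @return The binned [volume3d()].
#' @export
bin_volume <- function(vol, factor) {
  stopifnot(inherits(vol, "volume3d"))
  factor <- as.integer(factor)
  if (is.na(factor) || factor < 1L) stop("`factor` must be a positive integer")
  a <- vol$data
  d <- dim(a)
  nd <- d %/% factor
  if (any(nd < 1L)) stop("volume too small for binning factor ", factor)
  cropped <- any(nd * factor != d)
  if (cropped) a <- a[seq_len(nd[1] * factor), seq_len(nd[2] * factor),
                      seq_len(nd[3] * factor), drop = FALSE]
  if (factor > 1L) {
    dim(a) <- c(factor, nd[1], factor, nd[2], factor, nd[3])
    a <- aperm(a, c(1, 3, 5, 2, 4, 6))
    dim(a) <- c(factor^3, prod(nd))
    a <- array(colMeans(a), nd)
  }
  out <- volume3d(a, vol$voxel_size_um * factor, vol$provenance)
  log_op(out, "bin_volume", factor = factor, cropped = cropped,
         cropped_to = if (cropped) nd * factor else NULL)
}

resolve_mask <- function(mask, vol) {
  if (identical(mask, "all")) return(array(TRUE, dim(vol$data)))
  m <- as_mask(mask)
  check_same_shape(m, vol$data)
  m
}

#' Correct a multiplicative linear bias field
#'
#' Models the slow illumination/detector gain drift across a reconstruction
#' as a trilinear multiplicative field `I = c (1 + a z + b y + d x)`, fits it
#' by least squares over the voxels of `fit_mask`, and divides the volume by
#' the fitted field rescaled to unit mean over the mask. The in-mask mean
#' intensity is therefore preserved up to the fit residual (exactly, for an
#' input that follows the model).
#'
#' @param vol a [volume3d()]; must be strictly positive within `fit_mask`.
#' @param fit_mask 3D logical mask of voxels used for the fit, or `"all"`.
#' @return The corrected [volume3d()].
#' @export
correct_bias <- function(vol, fit_mask = "all") {
  stopifnot(inherits(vol, "volume3d"))
  m <- resolve_mask(fit_mask, vol)
  if (!any(m)) stop("`fit_mask` is empty")
  if (any(vol$data[m] <= 0))
    stop("volume must be strictly positive within `fit_mask` ",
         "(multiplicative bias model)")
  d <- dim(vol$data)
  z <- rep(seq_len(d[1]) - 1, times = d[2] * d[3])
  y <- rep(rep(seq_len(d[2]) - 1, each = d[1]), times = d[3])
  x <- rep(seq_len(d[3]) - 1, each = d[1] * d[2])
  sel <- which(m)
  X <- cbind(1, z[sel], y[sel], x[sel])
  qrX <- qr(X)
  if (qrX$rank < 4L)
    stop("degenerate bias fit: mask voxels do not span all three axes")
  beta <- qr.coef(qrX, vol$data[sel])
  field <- beta[1] + beta[2] * z + beta[3] * y + beta[4] * x
  field <- field / mean(field[sel])
  if (any(field <= 0))
    stop("fitted bias field is non-positive inside the volume; ",
         "linear model not applicable")
  out <- volume3d(array(vol$data / field, d), vol$voxel_size_um,
                  vol$provenance)
  log_op(out, "correct_bias", coefficients = as.numeric(beta))
}

#' Clamp sparse bright artifacts
#'
#' Bright spots (detector hits, dense debris) are suppressed by clamping all
#' in-mask intensities above the given in-mask percentile to that percentile's
#' value. Voxels outside the mask are untouched; output never exceeds input.
#'
#' @param vol a [volume3d()].
#' @param mask 3D logical mask or `"all"`.
#' @param percentile clamp threshold percentile, in `(50, 100)`.
#' @return The clamped [volume3d()].
#' @export
suppress_bright <- function(vol, mask = "all", percentile = 99.5) {
  stopifnot(inherits(vol, "volume3d"))
  if (!is.numeric(percentile) || percentile <= 50 || percentile >= 100)
    stop("`percentile` must lie in (50, 100)")
  m <- resolve_mask(mask, vol)
  if (!any(m)) stop("`mask` is empty")
  thr <- quantile(vol$data[m], percentile / 100, names = FALSE)
  a <- vol$data
  hot <- m & a > thr
  a[hot] <- thr
  out <- volume3d(a, vol$voxel_size_um, vol$provenance)
  log_op(out, "suppress_bright", percentile = percentile, threshold = thr,
         n_clamped = sum(hot))
}

#' Robust intensity normalization
#'
#' Affine rescale mapping the in-mask 1st and 99th intensity percentiles to 0
#' and 1, with values clipped to `[0, 1]`. Percentile anchoring keeps the
#' result insensitive to residual hot voxels, and the map is invariant to
#' affine transforms of the input (`a I + b`, `a > 0`).
#'
#' @param vol a [volume3d()].
#' @param mask 3D logical mask or `"all"`.
#' @return The normalized [volume3d()] with intensities in `[0, 1]`.
#' @export
normalize_intensity <- function(vol, mask = "all") {
  stopifnot(inherits(vol, "volume3d"))
  m <- resolve_mask(mask, vol)
  if (!any(m)) stop("`mask` is empty")
  # anchor on actual order statistics bracketing the 1%/99% positions so
  # that the percentiles recomputed on the clipped output are exactly 0/1
  v <- sort(vol$data[m])
  n <- length(v)
  p <- c(v[min(n, ceiling(1 + 0.01 * (n - 1)))],
         v[max(1, floor(1 + 0.99 * (n - 1)))])
  if (p[2] <= p[1]) stop("zero intensity spread within mask; cannot normalize")
  a <- pmin(pmax((vol$data - p[1]) / (p[2] - p[1]), 0), 1)
  out <- volume3d(array(a, dim(vol$data)), vol$voxel_size_um, vol$provenance)
  log_op(out, "normalize_intensity", p01 = p[1], p99 = p[2])
}

#' Standard preprocessing chain
#'
#' Applies, in order: block binning, linear bias-field correction, bright
#' artifact suppression, robust normalization. Each step is recorded in the
#' volume's provenance, so the chain is reproducible from the parameters
#' alone.
#'
#' @param vol a [volume3d()].
#' @param factor binning factor (1 skips binning).
#' @param percentile bright-artifact clamp percentile.
#' @param mask fit/statistics mask or `"all"`.
#' @return The preprocessed [volume3d()].
#' @export
preprocess_volume <- function(vol, factor = 1L, percentile = 99.5,
                              mask = "all") {
  if (factor > 1L) {
    vol <- bin_volume(vol, factor)
    if (!identical(mask, "all")) mask <- bin_mask(mask, factor)
  }
  # the multiplicative bias model needs positive intensities; noise tails
  # below zero are excluded from the fit but still corrected
  fit_mask <- vol$data > 0
  if (!identical(mask, "all")) fit_mask <- fit_mask & as_mask(mask)
  vol <- correct_bias(vol, fit_mask)
  vol <- suppress_bright(vol, mask, percentile)
  normalize_intensity(vol, mask)
}

bin_mask <- function(mask, factor) {
  m <- as_mask(mask)
  d <- dim(m); nd <- d %/% factor
  m <- m[seq_len(nd[1] * factor), seq_len(nd[2] * factor),
         seq_len(nd[3] * factor), drop = FALSE] * 1
  dim(m) <- c(factor, nd[1], factor, nd[2], factor, nd[3])
  m <- aperm(m, c(1, 3, 5, 2, 4, 6))
  dim(m) <- c(factor^3, prod(nd))
  array(colMeans(m) >= 0.5, nd)
}
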