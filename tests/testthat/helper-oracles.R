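# Independent brute-force oracles used to validate the production code.
# These deliberately avoid the package's algorithms: exhaustive searches and
# direct formula evaluation only.

# voxel coordinates (0-based, z/y/x) of linear indices
oracle_coords <- function(idx, d) {
  i0 <- idx - 1
  cbind(i0 %% d[1], (i0 %/% d[1]) %% d[2], i0 %/% (d[1] * d[2]))
}

# exhaustive maximal-inscribed-sphere local thickness: for every object
# voxel, candidate radius = distance to nearest background voxel center
# (space outside the volume counts as background), spheres are open balls,
# thickness(v) = max radius over candidate spheres containing v
oracle_thickness <- function(obj, spacing = c(1, 1, 1)) {
  d <- dim(obj)
  co <- which(obj)
  cb <- which(!obj)
  O <- oracle_coords(co, d)
  B <- if (length(cb)) oracle_coords(cb, d) else matrix(0, 0, 3)
  sp2 <- spacing^2
  r2 <- vapply(seq_len(nrow(O)), function(k) {
    p <- O[k, ]
    db <- if (nrow(B)) min((B[, 1] - p[1])^2 * sp2[1] +
                             (B[, 2] - p[2])^2 * sp2[2] +
                             (B[, 3] - p[3])^2 * sp2[3]) else Inf
    dborder <- min(((p + 1) * spacing)^2, ((d - p) * spacing)^2)
    min(db, dborder)
  }, 0.0)
  th <- numeric(nrow(O))
  for (k in seq_len(nrow(O))) {
    p <- O[k, ]
    dv <- (O[, 1] - p[1])^2 * sp2[1] + (O[, 2] - p[2])^2 * sp2[2] +
      (O[, 3] - p[3])^2 * sp2[3]
    th[k] <- max(r2[dv < r2])
  }
  out <- array(NA_real_, d)
  out[co] <- sqrt(th)
  out
}

# loop-based block-mean binning
oracle_bin <- function(a, f) {
  d <- dim(a) %/% f
  out <- array(0, d)
  for (i in seq_len(d[1])) for (j in seq_len(d[2])) for (k in seq_len(d[3]))
    out[i, j, k] <- mean(a[((i - 1) * f + 1):(i * f),
                           ((j - 1) * f + 1):(j * f),
                           ((k - 1) * f + 1):(k * f)])
  out
}

# exhaustive permutation p-value for the tie-corrected Kruskal-Wallis H,
# enumerating every distinct assignment of observations to the group sizes;
# H computed from the rank sum-of-squares decomposition (independent route)
oracle_kw_perm <- function(value, g) {
  g <- factor(g)
  r <- rank(value)
  N <- length(r)
  sizes <- as.integer(table(g))
  k <- length(sizes)
  h_of <- function(lab) {
    gm <- tapply(r, lab, mean)
    ssb <- sum(tabulate(lab, k) * (gm - mean(r))^2)
    sst <- sum((r - mean(r))^2)
    if (sst == 0) return(NA_real_)
    (N - 1) * ssb / sst
  }
  H_obs <- h_of(as.integer(g))
  hits <- 0L
  total <- 0L
  recurse <- function(avail, gi, lab) {
    if (gi == k) {
      lab[avail] <- k
      h <- h_of(lab)
      total <<- total + 1L
      if (h >= H_obs - 1e-10) hits <<- hits + 1L
      return(invisible(NULL))
    }
    cs <- utils::combn(avail, sizes[gi])
    for (ci in seq_len(ncol(cs))) {
      lab2 <- lab
      lab2[cs[, ci]] <- gi
      recurse(setdiff(avail, cs[, ci]), gi + 1L, lab2)
    }
  }
  recurse(seq_len(N), 1L, integer(N))
  hits / total
}

# random blobby binary mask (mixture of noise and smoothed balls)
random_mask <- function(d, p = 0.35, mode = c("noise", "balls")) {
  mode <- match.arg(mode)
  if (mode == "noise") return(array(runif(prod(d)) < p, d))
  m <- array(FALSE, d)
  for (i in seq_len(3)) {
    ctr <- runif(3) * (d - 1)
    r <- runif(1, 0.15, 0.35) * min(d)
    g <- expand.grid(z = 0:(d[1] - 1), y = 0:(d[2] - 1), x = 0:(d[3] - 1))
    m <- m | array((g$z - ctr[1])^2 + (g$y - ctr[2])^2 +
                     (g$x - ctr[3])^2 < r^2, d)
  }
  m
}

# small fast phantom spec for unit tests
tiny_spec <- function(...) {
  phantom_spec(shape = c(48L, 48L, 48L), n_vessels = 1L,
               vessel_radius_um = 12, ...)
}
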