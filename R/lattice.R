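#' Regular 3D voxel lattice
#'
#' Synthetic "brains" live on an explicit integer lattice so that voxel
#' adjacency (needed by the cluster-extent permutation test) and a simple
#' Gaussian lattice smoother are well defined. Voxels are enumerated
#' x-fastest with 0-based coordinates, matching the flattening used when
#' reading 4D volumes.
#'
#' @param dims integer vector of length 3 (nx, ny, nz).
#' @return a `"voxel_lattice"`: list with `dims`, an `n x 3` 0-based
#'   coordinate matrix `coords`, and `n` the voxel count.
#' @export
voxel_lattice <- function(dims) {
  dims <- as.integer(dims)
  if (length(dims) != 3L || any(dims < 1L)) stop("`dims` must be 3 positive integers")
  grid <- expand.grid(x = seq_len(dims[1]) - 1L,
                      y = seq_len(dims[2]) - 1L,
                      z = seq_len(dims[3]) - 1L)
  structure(list(dims = dims, coords = as.matrix(grid), n = prod(dims)),
            class = "voxel_lattice")
}

#' @export
print.voxel_lattice <- function(x, ...) {
  cat(sprintf("<voxel_lattice> %d x %d x %d (%d voxels)\n",
              x$dims[1], x$dims[2], x$dims[3], x$n))
  invisible(x)
}

#' Face-neighbour adjacency of a voxel lattice
#'
#' 6-connectivity: voxels are neighbours when they differ by one step along
#' exactly one axis. Returned as a list of integer neighbour indices per
#' voxel — the structure consumed by [cluster_permutation_test()].
#'
#' @param lattice a [voxel_lattice()].
#' @return list of length `n`; element `i` holds the neighbour indices of
#'   voxel `i` (possibly empty).
#' @export
lattice_adjacency <- function(lattice) {
  d <- lattice$dims
  co <- lattice$coords
  idx <- function(x, y, z) 1L + x + d[1] * (y + d[2] * z)
  lapply(seq_len(lattice$n), function(i) {
    x <- co[i, 1]; y <- co[i, 2]; z <- co[i, 3]
    nb <- integer(0)
    if (x > 0L)        nb <- c(nb, idx(x - 1L, y, z))
    if (x < d[1] - 1L) nb <- c(nb, idx(x + 1L, y, z))
    if (y > 0L)        nb <- c(nb, idx(x, y - 1L, z))
    if (y < d[2] - 1L) nb <- c(nb, idx(x, y + 1L, z))
    if (z > 0L)        nb <- c(nb, idx(x, y, z - 1L))
    if (z < d[3] - 1L) nb <- c(nb, idx(x, y, z + 1L))
    nb
  })
}

#' Partition lattice voxels into named networks
#'
#' Assigns voxels to `n_networks` contiguous slabs along the y axis (then
#' balanced by voxel index), emulating a resting-state-network labelling of
#' the synthetic brain. Every voxel is labelled and every network holds at
#' least 2 voxels.
#'
#' @param lattice a [voxel_lattice()] (or an integer voxel count, in which
#'   case voxels are split into consecutive runs).
#' @param names character vector of network names; its length sets the number
#'   of networks. Default: seven canonical RSN abbreviations.
#' @return a `"network_partition"`: list with integer `labels` (per voxel,
#'   1-based into `names`) and `names`.
#' @export
network_partition <- function(lattice,
                              names = c("DAN", "VAN", "SMN", "VIS",
                                        "FPC", "LAN", "DMN")) {
  m <- length(names)
  if (m < 1L) stop("need at least one network name")
  n <- if (inherits(lattice, "voxel_lattice")) lattice$n else as.integer(lattice)
  if (n < 2L * m)
    stop("partition needs at least 2 voxels per network (", n, " voxels, ",
         m, " networks)")
  if (inherits(lattice, "voxel_lattice")) {
    # slabs along y keep networks spatially contiguous on the lattice
    y <- lattice$coords[, 2]
    breaks <- seq(-0.5, max(y) + 0.5, length.out = m + 1L)
    labels <- as.integer(cut(y, breaks = breaks, labels = FALSE))
    # lattices shorter than m networks along y: fall back to index runs
    if (length(unique(labels)) < m || min(tabulate(labels, m)) < 2L)
      labels <- as.integer(cut(seq_len(n), breaks = m, labels = FALSE))
  } else {
    labels <- as.integer(cut(seq_len(n), breaks = m, labels = FALSE))
  }
  structure(list(labels = labels, names = names),
            class = "network_partition")
}

#' @export
print.network_partition <- function(x, ...) {
  tab <- table(factor(x$labels, levels = seq_along(x$names), labels = x$names))
  cat("<network_partition>", length(x$labels), "voxels,",
      length(x$names), "networks\n")
  print(tab)
  invisible(x)
}

#' Gaussian smoothing on the lattice
#'
#' Separable Gaussian blur of each frame over the 3D lattice, the synthetic
#' analogue of volumetric FWHM smoothing. Off by default in the pipeline.
#'
#' @param epoch a [ts_epoch()] whose voxels enumerate `lattice` x-fastest.
#' @param lattice the [voxel_lattice()].
#' @param fwhm_vox full width at half maximum in voxel units.
#' @return the smoothed epoch.
#' @export
lattice_smooth <- function(epoch, lattice, fwhm_vox = 2) {
  stopifnot_epoch(epoch)
  if (nrow(epoch$data) != lattice$n)
    stop("epoch voxel count does not match lattice")
  sigma <- fwhm_vox / (2 * sqrt(2 * log(2)))
  half <- max(1L, ceiling(3 * sigma))
  kern <- exp(-(seq(-half, half))^2 / (2 * sigma^2))
  kern <- kern / sum(kern)
  d <- lattice$dims
  arr <- array(epoch$data, dim = c(d, ncol(epoch$data)))
  smooth_axis <- function(a, axis) {
    # reflectively padded 1D convolution along `axis`
    n <- dim(a)[axis]
    out <- array(0, dim = dim(a))
    for (off in seq(-half, half)) {
      src <- pmin(pmax(seq_len(n) + off, 1L), n)
      idx_src <- switch(axis,
        `1` = a[src, , , , drop = FALSE],
        `2` = a[, src, , , drop = FALSE],
        `3` = a[, , src, , drop = FALSE])
      out <- out + kern[off + half + 1L] * idx_src
    }
    out
  }
  for (ax in 1:3) if (d[ax] > 1L) arr <- smooth_axis(arr, ax)
  epoch$data <- matrix(arr, nrow = lattice$n)
  epoch
}
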