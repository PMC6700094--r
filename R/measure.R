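#' Areal cell density by optical-section counting
#'
#' Counts the cells of a sample whose sphere intersects a focal plane
#' (`|z_centroid - plane_z| < radius`) inside a field of view, and divides
#' by the field area. Under isotropic linear expansion by \eqn{\lambda} this
#' plane-intersection count scales areal density exactly as
#' \eqn{\lambda^{-2}}, which is the geometric premise for square-rooting 2D
#' density ratios when normalising expansion to one dimension.
#'
#' @param sample a `tissue_sample`.
#' @param plane_z focal-plane depth in micrometres; default mid-block.
#' @param field_area field-of-view area in mm^2, realised as a centred
#'   square; `NULL` (default) uses the full block cross-section.
#' @param method `"intersection"` (default) counts plane-crossing spheres;
#'   `"slab"` counts centroids within a slab of `slab_depth` µm about the
#'   plane (an alternative that scales as \eqn{\lambda^{-3}} per unit area
#'   only when the slab is rescaled too).
#' @param slab_depth slab thickness, µm (used by `method = "slab"`).
#' @return Areal density, cells/mm^2 (a single number).
#' @export
count_cells_2d <- function(sample, plane_z = NULL, field_area = NULL,
                           method = c("intersection", "slab"),
                           slab_depth = 10) {
  stopifnot(inherits(sample, "tissue_sample"))
  method <- match.arg(method)
  bs <- sample$block_size
  if (is.null(plane_z)) plane_z <- bs[3] / 2
  if (plane_z < 0 || plane_z > bs[3]) {
    abort("`plane_z` lies outside the block.")
  }

  if (is.null(field_area)) {
    half_x <- bs[1] / 2; half_y <- bs[2] / 2
    area_mm2 <- bs[1] * bs[2] * 1e-6
  } else {
    check_number(field_area, "field_area", positive = TRUE)
    side <- sqrt(field_area) * 1000  # mm -> um
    if (side > bs[1] || side > bs[2]) {
      abort("requested field extends outside the block.")
    }
    half_x <- side / 2; half_y <- side / 2
    area_mm2 <- field_area
  }
  cx <- bs[1] / 2; cy <- bs[2] / 2
  cells <- sample$cells
  in_field <- abs(cells$x_um - cx) <= half_x & abs(cells$y_um - cy) <= half_y
  hit <- switch(method,
    intersection = abs(cells$z_um - plane_z) < cells$radius_um,
    slab = abs(cells$z_um - plane_z) <= slab_depth / 2
  )
  sum(in_field & hit) / area_mm2
}

#' Segment cells in a 3D stack and measure their volumes
#'
#' Thresholds the stack (fixed value, or an automatic bimodal threshold that
#' maximises between-class variance when `threshold = NULL`), labels
#' 26-connected foreground components, discards components below
#' `min_voxels`, and reports each component's volume as voxel count times
#' voxel volume.
#'
#' @param stack an `image_stack`.
#' @param threshold fixed intensity threshold, or `NULL` for the automatic
#'   between-class-variance split.
#' @param min_voxels smallest component kept, in voxels. Default 27 (a
#'   3x3x3 speck).
#' @return A tibble with one row per retained cell: `label`, `n_voxels`,
#'   `volume_um3`. Zero rows for an all-background stack.
#' @export
segment_cells_3d <- function(stack, threshold = NULL, min_voxels = 27) {
  stopifnot(inherits(stack, "image_stack"))
  v <- stack$voxels
  if (is.null(threshold)) threshold <- threshold_otsu(as.numeric(v))
  mask <- v > threshold
  if (!any(mask)) {
    return(tibble(label = integer(), n_voxels = integer(), volume_um3 = double()))
  }
  sizes <- component_sizes_3d(mask)
  sizes <- sizes[sizes >= min_voxels]
  voxel_vol <- prod(stack$voxel_size)
  tibble(
    label = seq_along(sizes),
    n_voxels = as.integer(sizes),
    volume_um3 = as.numeric(sizes) * voxel_vol
  )
}

# Otsu's between-class-variance-maximising threshold on a 256-bin histogram.
threshold_otsu <- function(x, n_bins = 256L) {
  rng <- range(x)
  if (diff(rng) == 0) return(rng[1])
  breaks <- seq(rng[1], rng[2], length.out = n_bins + 1L)
  h <- tabulate(findInterval(x, breaks, rightmost.closed = TRUE), n_bins)
  p <- h / sum(h)
  mids <- (breaks[-1] + breaks[-(n_bins + 1L)]) / 2
  w0 <- cumsum(p)
  mu_cum <- cumsum(p * mids)
  mu_tot <- mu_cum[n_bins]
  between <- (mu_tot * w0 - mu_cum)^2 / (w0 * (1 - w0))
  between[!is.finite(between)] <- -Inf
  mids[which.max(between)]
}

# Sizes of 26-connected foreground components of a logical 3D array,
# computed as graph components over the foreground-voxel adjacency.
component_sizes_3d <- function(mask) {
  d <- dim(mask)
  fg <- which(mask)
  n <- length(fg)
  idmap <- array(0L, dim = d)
  idmap[fg] <- seq_len(n)
  coord <- arrayInd(fg, d)

  offsets <- as.matrix(expand.grid(dz = -1:1, dy = -1:1, dx = -1:1))
  offsets <- offsets[seq_len(13L), , drop = FALSE]  # one of each +/- pair

  edge_list <- vector("list", nrow(offsets))
  for (k in seq_len(nrow(offsets))) {
    nb <- coord + matrix(offsets[k, ], n, 3, byrow = TRUE)
    ok <- nb[, 1] >= 1 & nb[, 1] <= d[1] &
          nb[, 2] >= 1 & nb[, 2] <= d[2] &
          nb[, 3] >= 1 & nb[, 3] <= d[3]
    if (!any(ok)) next
    lin <- nb[ok, 1] + (nb[ok, 2] - 1L) * d[1] + (nb[ok, 3] - 1L) * d[1] * d[2]
    nbr <- idmap[lin]
    hit <- nbr > 0L
    if (!any(hit)) next
    edge_list[[k]] <- cbind(seq_len(n)[ok][hit], nbr[hit])
  }
  edges <- do.call(rbind, edge_list)
  g <- igraph::make_empty_graph(n = n, directed = FALSE)
  if (!is.null(edges) && nrow(edges) > 0) {
    g <- igraph::add_edges(g, t(edges))
  }
  comp <- igraph::components(g)
  as.integer(comp$csize)
}

#' Cortical thickness as a straight-line length
#'
#' Mirrors the line-length procedure used on DAPI-stained sections: the
#' thickness is the Euclidean distance between two endpoints placed across
#' the cortex. When called on a `tissue_sample` without endpoints, returns
#' the sample's ground-truth cortical thickness.
#'
#' @param x a `tissue_sample`, or anything when `endpoints` is supplied.
#' @param endpoints a list or 2-row matrix of two distinct 3D points, µm.
#' @return Thickness in micrometres.
#' @export
measure_cortical_thickness <- function(x, endpoints = NULL) {
  if (is.null(endpoints)) {
    stopifnot(inherits(x, "tissue_sample"))
    if (is.na(x$cortical_thickness)) {
      abort("sample has no cortical thickness (non-cortical region).")
    }
    return(x$cortical_thickness)
  }
  if (is.list(endpoints)) endpoints <- do.call(rbind, endpoints)
  stopifnot(is.matrix(endpoints), nrow(endpoints) == 2L, ncol(endpoints) == 3L)
  delta <- endpoints[2, ] - endpoints[1, ]
  len <- sqrt(sum(delta^2))
  if (len == 0) abort("endpoints coincide; thickness undefined.")
  len
}

#' Antibody penetration depth from detected cell depths
#'
#' The staining depth is the distance into the tissue at which brightly
#' positive cells can still be seen: operationally, the maximum depth among
#' detected cells, guarded by a minimum detection count so that a single
#' stray detection cannot set the depth.
#'
#' @param cell_depths depths of detected brightly-positive cells from the
#'   incubated surface, micrometres.
#' @param min_cells minimum number of detections required. Default 3.
#' @return Penetration depth in millimetres, or `NA` (with a warning) when
#'   fewer than `min_cells` cells were detected.
#' @export
measure_penetration_depth <- function(cell_depths, min_cells = 3) {
  if (length(cell_depths) < min_cells) {
    warn(sprintf("fewer than %d cells detected; penetration depth is NA.",
                 as.integer(min_cells)))
    return(NA_real_)
  }
  max(cell_depths) / 1000
}
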