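#' Imaging parameters for the synthetic microscope
#'
#' @param voxel_size numeric 3-vector, micrometres per voxel along (x, y, z).
#' @param psf_sigma isotropic Gaussian point-spread sigma, micrometres.
#'   0 disables blurring.
#' @param background_level background intensity (arbitrary units).
#' @param cell_intensity intensity painted inside each cell.
#' @param noise one of `"none"`, `"gaussian"`, `"poisson"`.
#' @param noise_magnitude for `"gaussian"`, the additive noise SD in
#'   intensity units; for `"poisson"`, the detector gain g (counts drawn as
#'   `rpois(g * I) / g`).
#' @param seed integer seed for the noise draw.
#' @return An object of class `imaging_params`.
#' @export
imaging_params <- function(voxel_size = c(1, 1, 1),
                           psf_sigma = 0,
                           background_level = 100,
                           cell_intensity = 1000,
                           noise = c("none", "gaussian", "poisson"),
                           noise_magnitude = 1,
                           seed = 1L) {
  check_vec3(voxel_size, "voxel_size", positive = TRUE)
  check_number(psf_sigma, "psf_sigma", non_negative = TRUE)
  check_number(background_level, "background_level", non_negative = TRUE)
  check_number(cell_intensity, "cell_intensity", non_negative = TRUE)
  noise <- match.arg(noise)
  check_number(noise_magnitude, "noise_magnitude", positive = TRUE)
  structure(
    list(voxel_size = as.numeric(voxel_size), psf_sigma = psf_sigma,
         background_level = background_level, cell_intensity = cell_intensity,
         noise = noise, noise_magnitude = noise_magnitude,
         seed = as.integer(seed)),
    class = "imaging_params"
  )
}

#' Render a tissue sample to a 3D image stack
#'
#' Paints every cell as a solid sphere of `cell_intensity` on a background
#' of `background_level`, applies an isotropic Gaussian point-spread blur,
#' and corrupts the result with the configured noise model. Voxels are
#' 0-based with the value referring to the voxel centre: the centre of voxel
#' `i` along an axis sits at world coordinate `i * voxel_size` for that axis.
#' The voxel array is stored in depth-row-column order, i.e. `[z, y, x]`.
#'
#' @param sample a [simulate_tissue_sample()] result.
#' @param params an [imaging_params()].
#' @return An object of class `image_stack`: list with `voxels` (3D numeric
#'   array `[z, y, x]`) and `voxel_size` (µm per voxel, x/y/z order).
#' @export
render_image_stack <- function(sample, params) {
  stopifnot(inherits(sample, "tissue_sample"), inherits(params, "imaging_params"))
  vs <- params$voxel_size
  dims_xyz <- pmax(ceiling(sample$block_size / vs), 1L)
  nx <- dims_xyz[1]; ny <- dims_xyz[2]; nz <- dims_xyz[3]
  arr <- array(params$background_level, dim = c(nz, ny, nx))

  cells <- sample$cells
  tiny <- 0L
  for (i in seq_len(nrow(cells))) {
    cx <- cells$x_um[i]; cy <- cells$y_um[i]; cz <- cells$z_um[i]
    r <- cells$radius_um[i]
    # candidate voxel index ranges (1-based), centre of index j at (j-1)*vs
    ix <- seq(max(1L, floor((cx - r) / vs[1]) + 1L), min(nx, ceiling((cx + r) / vs[1]) + 1L))
    iy <- seq(max(1L, floor((cy - r) / vs[2]) + 1L), min(ny, ceiling((cy + r) / vs[2]) + 1L))
    iz <- seq(max(1L, floor((cz - r) / vs[3]) + 1L), min(nz, ceiling((cz + r) / vs[3]) + 1L))
    dx2 <- ((ix - 1) * vs[1] - cx)^2
    dy2 <- ((iy - 1) * vs[2] - cy)^2
    dz2 <- ((iz - 1) * vs[3] - cz)^2
    inside <- outer(outer(dz2, dy2, `+`), dx2, `+`) <= r^2  # [z, y, x]
    if (!any(inside)) {
      # sub-voxel cell: paint its nearest voxel so no cell vanishes
      tiny <- tiny + 1L
      jx <- min(nx, max(1L, round(cx / vs[1]) + 1L))
      jy <- min(ny, max(1L, round(cy / vs[2]) + 1L))
      jz <- min(nz, max(1L, round(cz / vs[3]) + 1L))
      arr[jz, jy, jx] <- params$cell_intensity
    } else {
      sub <- arr[iz, iy, ix, drop = FALSE]
      sub[inside] <- params$cell_intensity
      arr[iz, iy, ix] <- sub
    }
  }
  if (tiny > 0L) {
    warn(sprintf("%d cell(s) smaller than one voxel; painted on nearest voxel.", tiny))
  }

  if (params$psf_sigma > 0) {
    arr <- gaussian_blur_3d(arr, params$psf_sigma / vs[c(3, 2, 1)])
  }

  if (params$noise != "none") {
    arr <- with_seed(params$seed, {
      switch(params$noise,
        gaussian = arr + rnorm(length(arr), sd = params$noise_magnitude),
        poisson = {
          g <- params$noise_magnitude
          array(rpois(length(arr), g * pmax(arr, 0)) / g, dim = dim(arr))
        }
      )
    })
    arr[arr < 0] <- 0
  }

  structure(list(voxels = arr, voxel_size = vs), class = "image_stack")
}

# Separable Gaussian blur of a 3D array; sigma_vox gives the per-axis sigma
# in voxel units, in array (z, y, x) axis order. Truncated kernels are
# renormalised at the borders so flat regions stay flat.
gaussian_blur_3d <- function(arr, sigma_vox) {
  for (ax in 1:3) {
    s <- sigma_vox[ax]
    if (s <= 0) next
    n <- dim(arr)[ax]
    half <- ceiling(3 * s)
    kern <- dnorm(-half:half, sd = s)
    # banded convolution matrix with border renormalisation
    K <- matrix(0, n, n)
    for (j in seq_len(n)) {
      idx <- (j - half):(j + half)
      ok <- idx >= 1 & idx <= n
      w <- kern[ok] / sum(kern[ok])
      K[j, idx[ok]] <- w
    }
    perm <- switch(ax, `1` = c(1, 2, 3), `2` = c(2, 1, 3), `3` = c(3, 2, 1))
    a <- aperm(arr, perm)
    d <- dim(a)
    a <- array(K %*% matrix(a, d[1]), dim = d)
    arr <- aperm(a, order(perm))
  }
  arr
}

#' @export
print.image_stack <- function(x, ...) {
  d <- dim(x$voxels)
  cat(sprintf("<image_stack> %d x %d x %d voxels [z,y,x], voxel %s um\n",
              d[1], d[2], d[3], paste(fmt_num(x$voxel_size), collapse = " x ")))
  invisible(x)
}

#' Write / read an image stack as multi-page 16-bit TIFF + JSON sidecar
#'
#' Intensities are rounded and clamped to the unsigned 16-bit range; one
#' TIFF page per z-plane. The voxel size is recorded in a `.json` sidecar.
#'
#' @param stack an `image_stack`.
#' @param path TIFF file path; sidecar is `path` with `.json` appended.
#' @return `path`, invisibly (`write`); an `image_stack` (`read`).
#' @export
write_image_stack <- function(stack, path) {
  stopifnot(inherits(stack, "image_stack"))
  v <- pmin(pmax(round(stack$voxels), 0), 65535)
  pages <- lapply(seq_len(dim(v)[1]), function(z) v[z, , ] / 65535)
  tiff::writeTIFF(pages, path, bits.per.sample = 16L)
  jsonlite::write_json(list(voxel_size_um = stack$voxel_size),
                       paste0(path, ".json"), auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_image_stack
#' @export
read_image_stack <- function(path) {
  pages <- tiff::readTIFF(path, all = TRUE)
  if (!is.list(pages)) pages <- list(pages)
  d2 <- dim(pages[[1]])
  arr <- array(0, dim = c(length(pages), d2[1], d2[2]))
  for (z in seq_along(pages)) arr[z, , ] <- round(pages[[z]] * 65535)
  meta <- jsonlite::read_json(paste0(path, ".json"), simplifyVector = TRUE)
  structure(list(voxels = arr, voxel_size = as.numeric(meta$voxel_size_um)),
            class = "image_stack")
}
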