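#' Configuration of a synthetic tissue block
#'
#' Describes the *uncleared reference* state of a simulated block of tissue:
#' cell density, cell size, block dimensions and (for cortical regions) the
#' cortical thickness. Cleared samples are obtained by scaling this reference
#' by a linear expansion factor.
#'
#' @param density reference cell density, cells/mm^3.
#' @param mean_radius reference mean cell radius, micrometres.
#' @param radius_cv relative spread of cell radii (coefficient of variation
#'   of the multiplicative radius noise). Default 0.10.
#' @param block_size numeric 3-vector, block edge lengths in micrometres
#'   (x, y, z; z is the imaging depth axis).
#' @param region `"cortex"` or `"striatum"`. Cortical thickness is only
#'   defined for `"cortex"`.
#' @param marker marker label, e.g. `"CTIP2"` or `"parvalbumin"`.
#' @param thickness reference cortical thickness, micrometres (ignored for
#'   non-cortical regions).
#' @param thickness_noise relative noise on the realised thickness.
#'   Default 0.03.
#'
#' @return An object of class `sample_config` (a named list).
#' @examples
#' cfg <- sample_config(density = 1e5, mean_radius = 5)
#' smp <- simulate_tissue_sample(cfg, condition = "uncleared", seed = 1)
#' nrow(smp$cells)
#' @export
sample_config <- function(density,
                          mean_radius,
                          radius_cv = 0.10,
                          block_size = c(300, 300, 100),
                          region = c("cortex", "striatum"),
                          marker = "CTIP2",
                          thickness = 1200,
                          thickness_noise = 0.03) {
  check_number(density, "density", positive = TRUE)
  check_number(mean_radius, "mean_radius", positive = TRUE)
  check_number(radius_cv, "radius_cv", non_negative = TRUE)
  check_vec3(block_size, "block_size", positive = TRUE)
  region <- match.arg(region)
  if (region == "cortex") check_number(thickness, "thickness", positive = TRUE)
  check_number(thickness_noise, "thickness_noise", non_negative = TRUE)
  structure(
    list(
      density = density, mean_radius = mean_radius, radius_cv = radius_cv,
      block_size = as.numeric(block_size), region = region,
      marker = as.character(marker),
      thickness = if (region == "cortex") thickness else NA_real_,
      thickness_noise = thickness_noise
    ),
    class = "sample_config"
  )
}

#' Simulate a synthetic tissue sample
#'
#' Draws a homogeneous spatial Poisson field of spherical cells in the
#' reference (uncleared) block, then applies an isotropic (or optionally
#' per-axis) linear expansion factor to obtain the cleared state. The
#' centroid point process depends only on `seed`, not on the condition, so a
#' cleared and an uncleared sample generated with the same seed are the same
#' underlying cells before and after expansion; expansion is then the only
#' systematic difference between the two. Radius and thickness noise are
#' drawn from condition-specific streams (independent measurement noise).
#'
#' In the expanded block the realised cell density is `density / prod(lambda)`
#' per unit physical volume: expansion dilutes cells, it does not create or
#' destroy them.
#'
#' @param config a [sample_config()].
#' @param condition `"uncleared"` or `"cleared"`.
#' @param expansion linear expansion factor \eqn{\lambda > 0}; a scalar for
#'   isotropic expansion or a 3-vector (x, y, z) to simulate anisotropy.
#'   Must be 1 for uncleared samples.
#' @param seed integer seed; identical config + seed gives an identical
#'   sample.
#'
#' @return An object of class `tissue_sample`: a list with a `cells` tibble
#'   (`x_um`, `y_um`, `z_um`, `radius_um`), the realised `block_size`,
#'   `cortical_thickness` (µm, `NA` outside cortex), `condition`, `region`,
#'   `marker`, per-axis `expansion` and the `seed`.
#' @seealso [simulate_tissue_pair()] for matched cleared/uncleared pairs.
#' @export
simulate_tissue_sample <- function(config,
                                   condition = c("uncleared", "cleared"),
                                   expansion = 1,
                                   seed = 1L) {
  stopifnot(inherits(config, "sample_config"))
  condition <- match.arg(condition)
  lambda <- as_lambda3(expansion)
  if (any(!is.finite(lambda)) || any(lambda <= 0)) {
    abort("`expansion` must be > 0.")
  }
  if (condition == "uncleared" && any(lambda != 1)) {
    abort("uncleared samples have expansion 1 by definition.")
  }

  ref <- reference_field(config, seed)
  lambda_iso <- prod(lambda)^(1 / 3)
  noise_stream <- derive_seed(seed, if (condition == "cleared") 11L else 12L)

  cells <- with_seed(noise_stream, {
    n <- nrow(ref)
    radius_noise <- if (config$radius_cv > 0 && n > 0) {
      1 + config$radius_cv * rnorm(n)
    } else {
      rep(1, n)
    }
    radius_noise <- pmax(radius_noise, 0.05)  # guard against negative radii
    tibble(
      x_um = ref$x * lambda[1],
      y_um = ref$y * lambda[2],
      z_um = ref$z * lambda[3],
      radius_um = config$mean_radius * lambda_iso * radius_noise
    )
  })

  thickness <- NA_real_
  if (config$region == "cortex") {
    t_noise <- with_seed(derive_seed(seed, if (condition == "cleared") 21L else 22L), {
      if (config$thickness_noise > 0) 1 + config$thickness_noise * rnorm(1) else 1
    })
    # thickness is measured along the depth (z) axis of the block
    thickness <- config$thickness * lambda[3] * t_noise
  }

  structure(
    list(
      cells = cells,
      block_size = config$block_size * lambda,
      cortical_thickness = thickness,
      condition = condition,
      region = config$region,
      marker = config$marker,
      expansion = lambda,
      config = config,
      seed = as.integer(seed)
    ),
    class = "tissue_sample"
  )
}

# Reference (lambda = 1) Poisson cell field: count ~ Pois(rho * V), positions
# uniform. Depends on seed only, so paired conditions share it.
reference_field <- function(config, seed) {
  vol_mm3 <- prod(config$block_size) * 1e-9  # um^3 -> mm^3
  with_seed(derive_seed(seed, 1L), {
    n <- rpois(1, config$density * vol_mm3)
    tibble(
      x = runif(n, 0, config$block_size[1]),
      y = runif(n, 0, config$block_size[2]),
      z = runif(n, 0, config$block_size[3])
    )
  })
}

#' Simulate a matched cleared/uncleared sample pair
#'
#' The two samples of a comparison pair are generated from one shared
#' reference point process: the cleared member is that process scaled by the
#' expansion factor. Set `paired = FALSE` to draw two independent Poisson
#' fields instead (more realistic between-subject design, noisier ratios).
#'
#' @inheritParams simulate_tissue_sample
#' @param paired logical; share the reference point process (default) or
#'   draw the cleared field independently.
#' @return A list with elements `uncleared` and `cleared`, both
#'   `tissue_sample` objects.
#' @export
simulate_tissue_pair <- function(config, expansion = 1.2, seed = 1L,
                                 paired = TRUE) {
  cleared_seed <- if (paired) seed else derive_seed(seed, 31L)
  list(
    uncleared = simulate_tissue_sample(config, "uncleared", 1, seed),
    cleared = simulate_tissue_sample(config, "cleared", expansion, cleared_seed)
  )
}

#' @export
print.tissue_sample <- function(x, ...) {
  cat(sprintf(
    "<tissue_sample> %s %s (%s), %d cells, block %s um, expansion %s\n",
    x$region, x$marker, x$condition, nrow(x$cells),
    paste(fmt_num(x$block_size), collapse = " x "),
    paste(fmt_num(x$expansion), collapse = "/")
  ))
  if (!is.na(x$cortical_thickness)) {
    cat(sprintf("  cortical thickness: %s um\n", fmt_num(x$cortical_thickness)))
  }
  invisible(x)
}

#' Write / read a tissue sample as CSV + JSON sidecar
#'
#' The cell table goes to `path` as CSV (`x_um`, `y_um`, `z_um`,
#' `radius_um`); sample metadata (condition, region, marker, expansion,
#' block, thickness, seed) go to a `.json` sidecar next to it.
#'
#' @param sample a `tissue_sample`.
#' @param path CSV file path; the sidecar is `path` with `.json` appended.
#' @return `path`, invisibly (`write`); a `tissue_sample` (`read`).
#' @export
write_tissue_sample <- function(sample, path) {
  stopifnot(inherits(sample, "tissue_sample"))
  utils::write.csv(sample$cells, path, row.names = FALSE)
  meta <- list(
    condition = sample$condition, region = sample$region,
    marker = sample$marker, expansion = sample$expansion,
    block_size_um = sample$block_size,
    cortical_thickness_um = sample$cortical_thickness,
    seed = sample$seed
  )
  jsonlite::write_json(meta, paste0(path, ".json"),
                       auto_unbox = TRUE, digits = NA, null = "null")
  invisible(path)
}

#' @rdname write_tissue_sample
#' @export
read_tissue_sample <- function(path) {
  cells <- as_tibble(utils::read.csv(path))
  meta <- jsonlite::read_json(paste0(path, ".json"), simplifyVector = TRUE)
  structure(
    list(
      cells = cells,
      block_size = as.numeric(meta$block_size_um),
      cortical_thickness = meta$cortical_thickness_um %||% NA_real_,
      condition = meta$condition, region = meta$region, marker = meta$marker,
      expansion = as.numeric(meta$expansion), config = NULL,
      seed = as.integer(meta$seed)
    ),
    class = "tissue_sample"
  )
}
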