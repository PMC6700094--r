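test_that("plane-intersection counting handles the degenerate cases", {
  empty <- manual_sample(
    tibble::tibble(x_um = numeric(), y_um = numeric(), z_um = numeric(),
                   radius_um = numeric()),
    block_size = c(100, 100, 100))
  expect_identical(count_cells_2d(empty, plane_z = 50), 0)

  one <- manual_sample(
    tibble::tibble(x_um = 50, y_um = 50, z_um = 50, radius_um = 5),
    block_size = c(100, 100, 100))
  # centroid exactly on the focal plane: counted once
  expect_equal(count_cells_2d(one, plane_z = 50, field_area = 0.01), 1 / 0.01)
  # plane beyond the cell's reach: not counted
  expect_identical(count_cells_2d(one, plane_z = 60), 0)

  expect_error(count_cells_2d(one, plane_z = 200), "outside the block")
  expect_error(count_cells_2d(one, plane_z = 50, field_area = 1),
               "outside the block")
})

test_that("plane-intersection density recovers rho * 2r on average", {
  cfg <- sample_config(density = 1e5, mean_radius = 5, radius_cv = 0,
                       block_size = c(300, 300, 100))
  dens <- vapply(1:500, function(s) {
    smp <- simulate_tissue_sample(cfg, "uncleared", seed = s)
    count_cells_2d(smp, plane_z = 50)
  }, numeric(1))
  # expected areal density rho * 2r = 1e5 * 0.01 = 1000 cells/mm^2;
  # each field is 0.09 mm^2 so a count averages 90 cells
  se <- 1000 * sqrt(1 / (90 * 500))
  expect_lt(abs(mean(dens) - 1000), 3 * se)
})

test_that("segmentation returns nothing on an all-background stack", {
  smp <- manual_sample(
    tibble::tibble(x_um = numeric(), y_um = numeric(), z_um = numeric(),
                   radius_um = numeric()),
    block_size = c(30, 30, 30))
  stack <- render_image_stack(smp, imaging_params(background_level = 50))
  seg <- segment_cells_3d(stack, threshold = 100)
  expect_identical(nrow(seg), 0L)
})

test_that("two separated spheres segment into two components of known volume", {
  smp <- manual_sample(
    tibble::tibble(x_um = c(15, 45), y_um = c(30, 30), z_um = c(30, 30),
                   radius_um = c(5, 5)),
    block_size = c(60, 60, 60))
  p <- imaging_params(background_level = 0, cell_intensity = 1000)
  seg <- segment_cells_3d(render_image_stack(smp, p), threshold = 500)
  expect_identical(nrow(seg), 2L)
  v_true <- 4 / 3 * pi * 5^3
  expect_true(all(abs(seg$volume_um3 - v_true) / v_true < 0.05))
  # the operator must agree with the direct voxel-count oracle exactly
  expect_identical(sum(seg$n_voxels),
                   oracle_sphere_voxels(c(15, 30, 30), 5, c(60, 60, 60), c(1, 1, 1)) +
                   oracle_sphere_voxels(c(45, 30, 30), 5, c(60, 60, 60), c(1, 1, 1)))
})

test_that("automatic thresholding and speck removal work on noisy stacks", {
  smp <- manual_sample(
    tibble::tibble(x_um = 30, y_um = 30, z_um = 30, radius_um = 6),
    block_size = c(60, 60, 60))
  p <- imaging_params(background_level = 100, cell_intensity = 1000,
                      noise = "gaussian", noise_magnitude = 30, seed = 6L)
  seg <- segment_cells_3d(render_image_stack(smp, p))
  expect_identical(nrow(seg), 1L)
  v_true <- 4 / 3 * pi * 6^3
  expect_lt(abs(seg$volume_um3 - v_true) / v_true, 0.05)
})

test_that("segmented volumes obey the lambda-cubed scaling law", {
  lam <- 1.2
  mk <- function(r) manual_sample(
    tibble::tibble(x_um = 36, y_um = 36, z_um = 36, radius_um = r),
    block_size = c(72, 72, 72))
  p <- imaging_params(background_level = 0, cell_intensity = 1000)
  v_un <- segment_cells_3d(render_image_stack(mk(5), p), threshold = 500)$volume_um3
  v_cl <- segment_cells_3d(render_image_stack(mk(5 * lam), p), threshold = 500)$volume_um3
  expect_lt(abs(v_cl / v_un - lam^3) / lam^3, 0.05)
})

test_that("volume operator matches the oracle within 2% for r >= 4 voxels", {
  p <- imaging_params(background_level = 0, cell_intensity = 1000)
  for (r in c(4, 5.5, 7, 9)) {
    smp <- manual_sample(
      tibble::tibble(x_um = 30, y_um = 30, z_um = 30, radius_um = r),
      block_size = c(60, 60, 60))
    seg <- segment_cells_3d(render_image_stack(smp, p), threshold = 500)
    oracle <- oracle_sphere_voxels(c(30, 30, 30), r, c(60, 60, 60), c(1, 1, 1))
    expect_lt(abs(seg$n_voxels - oracle) / oracle, 0.02)
  }
})

test_that("cortical thickness is the endpoint distance or the ground truth", {
  expect_equal(measure_cortical_thickness(NULL, list(c(0, 0, 0), c(0, 0, 100))),
               100)
  expect_equal(measure_cortical_thickness(NULL, list(c(0, 3, 4), c(0, 0, 0))),
               5)
  expect_error(measure_cortical_thickness(NULL, list(c(1, 2, 3), c(1, 2, 3))),
               "coincide")

  cfg <- sample_config(density = 1e4, mean_radius = 5, thickness = 1200,
                       thickness_noise = 0)
  smp <- simulate_tissue_sample(cfg, "cleared", expansion = 1.14, seed = 1)
  expect_equal(measure_cortical_thickness(smp), 1368)
})

test_that("penetration depth is the guarded maximum detected cell depth", {
  expect_equal(measure_penetration_depth(c(10, 200, 450), min_cells = 1), 0.45)
  expect_warning(out <- measure_penetration_depth(numeric(0)), "fewer than")
  expect_true(is.na(out))
  expect_warning(measure_penetration_depth(c(100, 200), min_cells = 3),
                 "fewer than")
})

test_that("a simulated staining front is recovered to within one cell spacing", {
  # cells every 10 um up to a front at 544 um
  depths <- seq(10, 544, by = 10)
  expect_lt(abs(measure_penetration_depth(depths) - 0.544), 0.010 + 1e-12)
})
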