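# Independent oracles used across the suite. These deliberately avoid the
# package's own code paths.

# Two-pass sample CV.
oracle_cv <- function(x) {
  n <- length(x)
  m <- sum(x) / n
  sqrt(sum((x - m)^2) / (n - 1)) / m
}

# Welch t statistic and Welch-Satterthwaite degrees of freedom, by hand.
oracle_welch <- function(a, b) {
  va <- sum((a - mean(a))^2) / (length(a) - 1)
  vb <- sum((b - mean(b))^2) / (length(b) - 1)
  sa <- va / length(a)
  sb <- vb / length(b)
  t <- (mean(a) - mean(b)) / sqrt(sa + sb)
  dof <- (sa + sb)^2 / (sa^2 / (length(a) - 1) + sb^2 / (length(b) - 1))
  list(t = t, dof = dof)
}

# Direct voxel-centre-in-sphere count on the grid used by the renderer:
# voxel i (1-based) has its centre at (i - 1) * voxel_size.
oracle_sphere_voxels <- function(centre, radius, dims_xyz, voxel_size) {
  xs <- (seq_len(dims_xyz[1]) - 1) * voxel_size[1]
  ys <- (seq_len(dims_xyz[2]) - 1) * voxel_size[2]
  zs <- (seq_len(dims_xyz[3]) - 1) * voxel_size[3]
  d2 <- outer(outer((zs - centre[3])^2, (ys - centre[2])^2, `+`),
              (xs - centre[1])^2, `+`)
  sum(d2 <= radius^2)
}

# Hand-build a tissue sample with known cells (bypasses the generator).
manual_sample <- function(cells, block_size = c(100, 100, 100),
                          condition = "uncleared", expansion = 1,
                          thickness = NA_real_) {
  structure(
    list(cells = tibble::as_tibble(cells), block_size = block_size,
         cortical_thickness = thickness, condition = condition,
         region = "cortex", marker = "test",
         expansion = rep(expansion, 3), config = NULL, seed = 0L),
    class = "tissue_sample"
  )
}

# Long measurement table for two conditions of a set of measures.
make_measurements <- function(spec_list) {
  dplyr::bind_rows(lapply(spec_list, function(s) {
    m <- expansion_measure(s$id, s$kind, region = "cortex", marker = "test")
    dplyr::bind_rows(
      measurement_set(m, "uncleared", s$uncleared),
      measurement_set(m, "cleared", s$cleared)
    )
  }))
}
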