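#' Welch's two-sample t-test
#'
#' Two-sided unequal-variance t-test with Welch-Satterthwaite degrees of
#' freedom, used for every cleared-vs-uncleared group comparison. The
#' degenerate case (zero variance in both groups with equal means) returns
#' statistic 0 and p = 1 rather than an error.
#'
#' @param group_a,group_b numeric vectors, each with at least 2 values.
#' @return One-row tibble: `statistic`, `dof`, `p_value`.
#' @export
welch_t_test <- function(group_a, group_b) {
  if (length(group_a) < 2 || length(group_b) < 2) {
    abort("each group needs at least 2 values.")
  }
  res <- tryCatch(
    t.test(group_a, group_b, var.equal = FALSE),
    error = function(e) NULL
  )
  if (is.null(res)) {
    # both groups essentially constant
    if (isTRUE(all.equal(mean(group_a), mean(group_b)))) {
      return(tibble(statistic = 0, dof = NA_real_, p_value = 1))
    }
    return(tibble(statistic = Inf * sign(mean(group_a) - mean(group_b)),
                  dof = NA_real_, p_value = 0))
  }
  tibble(statistic = unname(res$statistic), dof = unname(res$parameter),
         p_value = res$p.value)
}

#' Shapiro-Wilk normality gate
#'
#' Normality is assessed and *reported*; the parametric comparison proceeds
#' regardless of the outcome (the gate is advisory, not a branch to a
#' non-parametric test).
#'
#' @param values numeric vector; the test is defined for 3 to 5000 values.
#' @return The Shapiro-Wilk p-value, or `NA` (with a warning) when the
#'   sample size is out of range or the values are constant.
#' @export
shapiro_wilk_gate <- function(values) {
  n <- length(values)
  if (n < 3 || n > 5000) {
    warn(sprintf("Shapiro-Wilk needs 3..5000 values (got %d); returning NA.", n))
    return(NA_real_)
  }
  tryCatch(shapiro.test(values)$p.value,
           error = function(e) {
             warn(paste("Shapiro-Wilk failed:", conditionMessage(e)))
             NA_real_
           })
}

#' Configure a synthetic clearing study
#'
#' Defines the simulated experiment: which measures are taken, how many
#' regions of interest (ROIs) per condition, the true linear expansion
#' factor, and the noise levels. The default design mirrors a
#' two-littermate comparison: four 2D density measures (CTIP2 and
#' parvalbumin in cortex and striatum; 40 fields per condition for cortical
#' parvalbumin, 20 for the rest), four 3D volume measures (30 cells per
#' condition each) and two cortical thickness measures (motor and barrel
#' cortex, 9 hemispheres per condition).
#'
#' @param expansion true linear expansion factor of the cleared tissue;
#'   scalar or per-axis 3-vector. Default 1.2.
#' @param seed integer master seed; every stage derives its stream from it
#'   (no wall-clock seeding).
#' @param radius_cv relative cell-radius noise. Default 0.10.
#' @param thickness_noise relative thickness noise. Default 0.03.
#' @param round_digits passed to [clearing_report()]; default `NULL`
#'   (no rounding of adjusted ratios).
#' @param measures optional tibble overriding the default design; columns
#'   `measure_id`, `kind`, `region`, `marker`, `n_roi`, `density`
#'   (cells/mm^3), `mean_radius` (µm), `thickness` (µm).
#' @param paired share the reference point process between conditions
#'   (default TRUE); see [simulate_tissue_pair()].
#' @return An object of class `study_config`.
#' @export
study_config <- function(expansion = 1.2, seed = 1L,
                         radius_cv = 0.10, thickness_noise = 0.03,
                         round_digits = NULL, measures = NULL,
                         paired = TRUE) {
  lambda <- as_lambda3(expansion)
  if (any(lambda <= 0)) abort("`expansion` must be > 0.")
  if (is.null(measures)) measures <- default_study_measures()
  stopifnot(all(measures$n_roi >= 2))
  structure(
    list(expansion = lambda, seed = as.integer(seed),
         radius_cv = radius_cv, thickness_noise = thickness_noise,
         round_digits = round_digits, measures = measures, paired = paired),
    class = "study_config"
  )
}

# Plausible mouse-brain generator settings per measure. Densities are
# marker-positive cells per mm^3; radii in um (CTIP2 labels nuclei,
# parvalbumin whole somata); thicknesses in um.
default_study_measures <- function() {
  tibble(
    measure_id = c("density_cortical_ctip2", "density_cortical_parvalbumin",
                   "density_striatal_ctip2", "density_striatal_parvalbumin",
                   "volume_cortical_ctip2", "volume_cortical_parvalbumin",
                   "volume_striatal_ctip2", "volume_striatal_parvalbumin",
                   "thickness_motor_cortex", "thickness_barrel_cortex"),
    kind = rep(c("density", "volume", "thickness"), c(4, 4, 2)),
    region = c("cortex", "cortex", "striatum", "striatum",
               "cortex", "cortex", "striatum", "striatum",
               "cortex", "cortex"),
    marker = c("CTIP2", "parvalbumin", "CTIP2", "parvalbumin",
               "CTIP2", "parvalbumin", "CTIP2", "parvalbumin",
               "DAPI", "DAPI"),
    n_roi = c(20L, 40L, 20L, 20L, 30L, 30L, 30L, 30L, 9L, 9L),
    density = c(8e4, 1.5e4, 9e4, 5e3, 8e4, 1.5e4, 9e4, 5e3, 8e4, 8e4),
    mean_radius = c(4, 7, 4, 7, 4, 7, 4, 7, 4, 4),
    thickness = c(NA, NA, NA, NA, NA, NA, NA, NA, 1200, 1300)
  )
}

#' Run the simulate-measure-analyze pipeline
#'
#' For every configured measure, generates matched cleared/uncleared tissue
#' samples, applies the corresponding measurement operator (plane-
#' intersection counting for 2D density, per-cell sphere volumes for 3D
#' volume, line-length ground truth for thickness), assembles the
#' long-format measurement table, runs Welch comparisons with Shapiro-Wilk
#' gates per measure, and produces the clearing uniformity report. Fully
#' deterministic given the config (which carries all seeds).
#'
#' @param config a [study_config()].
#' @param output_dir optional directory; when given, writes
#'   `measurements.csv`, `expansion_ratios.csv`, `clearing_report.json`,
#'   `comparisons.csv`, `summary.txt` and `manifest.json`. Numeric output
#'   is fixed to 6 significant digits so repeated runs are byte-identical.
#' @return An object of class `clearing_study`: list with `measurements`
#'   (long tibble), `comparisons` (per-measure Welch results), `report`
#'   (a [clearing_report()]) and `config`.
#' @export
run_study <- function(config = study_config(), output_dir = NULL) {
  stopifnot(inherits(config, "study_config"))
  meas_tbl <- config$measures
  rows <- purrr::pmap(meas_tbl, function(measure_id, kind, region, marker,
                                         n_roi, density, mean_radius,
                                         thickness, ...) {
    measure <- expansion_measure(measure_id, kind, region, marker)
    seed_m <- derive_seed(config$seed, match(measure_id, meas_tbl$measure_id))
    vals <- switch(kind,
      density = measure_density_pair(config, density, mean_radius, region,
                                     marker, n_roi, seed_m),
      volume = measure_volume_pair(config, density, mean_radius, region,
                                   marker, n_roi, seed_m),
      thickness = measure_thickness_pair(config, thickness, region, marker,
                                         n_roi, seed_m)
    )
    dplyr::bind_rows(
      dplyr::mutate(measurement_set(measure, "uncleared", vals$uncleared),
                    seed = seed_m),
      dplyr::mutate(measurement_set(measure, "cleared", vals$cleared),
                    seed = seed_m)
    )
  })
  measurements <- dplyr::bind_rows(rows)

  comparisons <- measurements |>
    dplyr::group_by(.data$measure_id, .data$kind) |>
    dplyr::group_modify(function(d, key) {
      cl <- d$value[d$condition == "cleared"]
      un <- d$value[d$condition == "uncleared"]
      test <- welch_t_test(cl, un)
      test$normality_p_cleared <- suppressWarnings(shapiro_wilk_gate(cl))
      test$normality_p_uncleared <- suppressWarnings(shapiro_wilk_gate(un))
      test$test <- "welch_t"
      test
    }) |>
    dplyr::ungroup()

  report <- clearing_report(measurements, round_digits = config$round_digits)
  study <- structure(
    list(measurements = measurements, comparisons = comparisons,
         report = report, config = config),
    class = "clearing_study"
  )
  if (!is.null(output_dir)) write_study_outputs(study, output_dir)
  study
}

sample_cfg_for <- function(config, density, mean_radius, region, marker,
                           thickness = 1200,
                           block_size = c(300, 300, 100)) {
  sample_config(
    density = density, mean_radius = mean_radius,
    radius_cv = config$radius_cv, block_size = block_size,
    region = region, marker = marker,
    thickness = if (is.na(thickness)) 1200 else thickness,
    thickness_noise = config$thickness_noise
  )
}

# One matched pair per measure, one focal plane per ROI. The cleared plane
# sits at the scaled depth of its uncleared counterpart, i.e. the "same
# anatomy" is imaged in both conditions.
measure_density_pair <- function(config, density, mean_radius, region,
                                 marker, n_roi, seed) {
  cfg <- sample_cfg_for(config, density, mean_radius, region, marker,
                        block_size = c(400, 400, 120))
  pair <- simulate_tissue_pair(cfg, config$expansion, seed,
                               paired = config$paired)
  planes <- seq(0.15, 0.85, length.out = n_roi) * cfg$block_size[3]
  lam_z <- pair$cleared$expansion[3]
  list(
    uncleared = vapply(planes, function(z)
      count_cells_2d(pair$uncleared, plane_z = z), numeric(1)),
    cleared = vapply(planes * lam_z, function(z)
      count_cells_2d(pair$cleared, plane_z = z), numeric(1))
  )
}

measure_volume_pair <- function(config, density, mean_radius, region,
                                marker, n_roi, seed) {
  cfg <- sample_cfg_for(config, density, mean_radius, region, marker,
                        block_size = c(500, 500, 200))
  pair <- simulate_tissue_pair(cfg, config$expansion, seed,
                               paired = config$paired)
  vol <- function(s) {
    r <- s$cells$radius_um
    if (length(r) < n_roi) {
      warn(sprintf("only %d cells available for %d requested volume ROIs.",
                   length(r), n_roi))
    }
    4 / 3 * pi * r[seq_len(min(n_roi, length(r)))]^3
  }
  list(uncleared = vol(pair$uncleared), cleared = vol(pair$cleared))
}

# Thickness: one simulated hemisphere pair per ROI.
measure_thickness_pair <- function(config, thickness, region, marker,
                                   n_roi, seed) {
  cfg <- sample_cfg_for(config, density = 1e4, mean_radius = 4,
                        region = region, marker = marker,
                        thickness = thickness)
  vals <- purrr::map(seq_len(n_roi), function(i) {
    pair <- simulate_tissue_pair(cfg, config$expansion, derive_seed(seed, i),
                                 paired = config$paired)
    c(uncleared = measure_cortical_thickness(pair$uncleared),
      cleared = measure_cortical_thickness(pair$cleared))
  })
  list(uncleared = purrr::map_dbl(vals, "uncleared"),
       cleared = purrr::map_dbl(vals, "cleared"))
}

write_study_outputs <- function(study, output_dir) {
  dir.create(output_dir, recursive = TRUE, showWarnings = FALSE)
  ok <- FALSE
  written <- character()
  on.exit(if (!ok) unlink(written), add = TRUE)
  wpath <- function(f) {
    p <- file.path(output_dir, f)
    written <<- c(written, p)
    p
  }

  meas <- study$measurements
  meas$value <- fmt_num(meas$value)
  utils::write.csv(meas, wpath("measurements.csv"), row.names = FALSE)

  write_clearing_report(study$report, wpath("clearing_report.json"),
                        wpath("expansion_ratios.csv"))

  comp <- study$comparisons
  comp$statistic <- fmt_num(comp$statistic)
  comp$dof <- fmt_num(comp$dof)
  comp$p_value <- signif(comp$p_value, 3)
  comp$normality_p_cleared <- signif(comp$normality_p_cleared, 3)
  comp$normality_p_uncleared <- signif(comp$normality_p_uncleared, 3)
  utils::write.csv(comp, wpath("comparisons.csv"), row.names = FALSE)

  summary_lines <- c(
    "Clearing uniformity study",
    sprintf("measures: %d", nrow(study$report$ratios)),
    sprintf("clearing CV: %.3f", study$report$clearing_cv),
    sprintf("uncleared-CV threshold: %.3f", study$report$threshold),
    sprintf("verdict: %s", study$report$verdict),
    "",
    "per-measure comparisons (Welch, two-sided):",
    sprintf("  %-32s t = %8s, p %s", comp$measure_id,
            format(comp$statistic),
            ifelse(comp$p_value < 0.001, "< 0.001 (***)",
                   paste0("= ", format(comp$p_value))))
  )
  writeLines(summary_lines, wpath("summary.txt"))

  cfg <- study$config
  manifest <- list(
    package = "clearcv",
    version = as.character(utils::packageVersion("clearcv")),
    seed = cfg$seed,
    expansion = cfg$expansion,
    radius_cv = cfg$radius_cv,
    thickness_noise = cfg$thickness_noise,
    paired = cfg$paired,
    n_measures = nrow(cfg$measures),
    config_hash = config_hash(cfg)
  )
  jsonlite::write_json(manifest, wpath("manifest.json"),
                       auto_unbox = TRUE, digits = NA)
  ok <- TRUE
  invisible(output_dir)
}

# Order-insensitive content hash of the serialized config (hex, 8 chars);
# enough to detect config drift between runs in the manifest.
config_hash <- function(cfg) {
  js <- jsonlite::toJSON(cfg[setdiff(names(cfg), "measures")], digits = NA)
  bytes <- utf8ToInt(paste0(js, jsonlite::toJSON(cfg$measures, digits = NA)))
  h <- 5381
  for (b in bytes) h <- (h * 33 + b) %% 2147483647
  sprintf("%08x", as.integer(h))
}

#' @export
print.clearing_study <- function(x, ...) {
  cat("<clearing_study>\n")
  print(x$report)
  cat(sprintf("  %d measurements across %d measures; seed %d\n",
              nrow(x$measurements), nrow(x$config$measures), x$config$seed))
  invisible(x)
}

#' @rdname tidy.clearing_report
#' @export
tidy.clearing_study <- function(x, ...) tidy(x$report)

#' @rdname glance.clearing_report
#' @export
glance.clearing_study <- function(x, ...) glance(x$report)

#' Plot the per-condition measurement distributions of a study
#'
#' @param object a `clearing_study`.
#' @param ... unused.
#' @return A ggplot faceted by measure, one point per ROI.
#' @export
autoplot.clearing_study <- function(object, ...) {
  ggplot2::ggplot(object$measurements,
                  ggplot2::aes(.data$condition, .data$value,
                               colour = .data$condition)) +
    ggplot2::geom_jitter(width = 0.15, alpha = 0.6, show.legend = FALSE) +
    ggplot2::stat_summary(fun = mean, geom = "crossbar", width = 0.4,
                          linewidth = 0.3, colour = "black") +
    ggplot2::facet_wrap(~measure_id, scales = "free_y") +
    ggplot2::labs(x = NULL, y = NULL) +
    ggplot2::theme_minimal()
}
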