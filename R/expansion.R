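#' Define an expansion measure
#'
#' A measure is one named quantity compared between cleared and uncleared
#' tissue — e.g. cortical CTIP2 cell density. Its kind fixes both its
#' spatial dimensionality (thickness 1, areal density 2, volume 3) and the
#' direction of the expansion ratio: volume and thickness grow with
#' expansion (ratio = cleared / uncleared) while areal density falls
#' (ratio = uncleared / cleared), so every ratio reads "> 1 means swelling".
#'
#' @param measure_id unique label for the measure.
#' @param kind `"density"`, `"volume"` or `"thickness"`.
#' @param region brain region label (e.g. `"cortex"`, `"striatum"`).
#' @param marker marker label (e.g. `"CTIP2"`, `"parvalbumin"`).
#' @return A one-row tibble with `measure_id`, `kind`, `dimensionality`,
#'   `units`, `region`, `marker`.
#' @export
expansion_measure <- function(measure_id, kind = c("density", "volume", "thickness"),
                              region = NA_character_, marker = NA_character_) {
  kind <- match.arg(kind)
  tibble(
    measure_id = as.character(measure_id),
    kind = kind,
    dimensionality = measure_dimensionality(kind),
    units = measure_units(kind),
    region = as.character(region),
    marker = as.character(marker)
  )
}

measure_dimensionality <- function(kind) {
  unname(c(density = 2L, volume = 3L, thickness = 1L)[kind])
}

measure_units <- function(kind) {
  unname(c(density = "cells/mm^2", volume = "um^3", thickness = "um")[kind])
}

#' Build a long-format measurement set
#'
#' One row per region of interest (ROI): the unit of observation for all
#' group comparisons. Units are fixed by the measure kind and carried on
#' every row so that mixed-unit comparisons can be rejected.
#'
#' @param measure a one-row tibble from [expansion_measure()].
#' @param condition `"cleared"` or `"uncleared"`.
#' @param values non-empty vector of non-negative per-ROI values.
#' @return A tibble with columns `measure_id`, `condition`, `region`,
#'   `marker`, `kind`, `dimensionality`, `value`, `units`, `roi_id`.
#' @export
measurement_set <- function(measure, condition = c("cleared", "uncleared"),
                            values) {
  condition <- match.arg(condition)
  stopifnot(is.data.frame(measure), nrow(measure) == 1L)
  if (length(values) == 0) abort("`values` must be non-empty.")
  if (any(!is.finite(values)) || any(values < 0)) {
    abort("`values` must be finite and non-negative.")
  }
  tibble(
    measure_id = measure$measure_id,
    condition = condition,
    region = measure$region,
    marker = measure$marker,
    kind = measure$kind,
    dimensionality = measure$dimensionality,
    value = as.numeric(values),
    units = measure$units,
    roi_id = seq_along(values)
  )
}

#' Relative expansion per measure
#'
#' The relative change in the mean of each measure between conditions,
#' oriented so that values above 1 indicate swelling: mean cleared over mean
#' uncleared for volume and thickness, and the inverse (mean uncleared over
#' mean cleared) for density, since expansion dilutes cells.
#'
#' @param data long-format measurement tibble (rows for both conditions of
#'   one or more measures), as produced by [measurement_set()] /
#'   [run_study()].
#' @return A tibble with one row per measure: `measure_id`, `kind`,
#'   `dimensionality`, `relative_expansion`.
#' @export
relative_expansion <- function(data) {
  check_measurements(data)
  out <- data |>
    dplyr::group_by(.data$measure_id, .data$kind, .data$dimensionality) |>
    dplyr::group_modify(function(d, key) {
      if (dplyr::n_distinct(d$units) > 1) {
        abort(sprintf("measure '%s' mixes units: %s", key$measure_id,
                      paste(unique(d$units), collapse = ", ")))
      }
      if (!any(d$condition == "cleared") || !any(d$condition == "uncleared")) {
        abort(sprintf("measure '%s' lacks one condition.", key$measure_id))
      }
      m_cl <- mean(d$value[d$condition == "cleared"])
      m_un <- mean(d$value[d$condition == "uncleared"])
      ratio <- if (key$kind == "density") m_un / m_cl else m_cl / m_un
      if (!is.finite(ratio)) {
        abort(sprintf("measure '%s': zero denominator in expansion ratio.",
                      key$measure_id))
      }
      tibble(relative_expansion = ratio)
    }) |>
    dplyr::ungroup()
  out[, c("measure_id", "kind", "dimensionality", "relative_expansion")]
}

#' Adjusted expansion ratio (dimension-normalised)
#'
#' Normalises each relative expansion to expansion in one spatial dimension
#' by taking its d-th root: square root for 2D areal densities, cube root
#' for 3D volumes, identity for 1D thickness. Under uniform isotropic
#' expansion by \eqn{\lambda} every adjusted ratio equals \eqn{\lambda}.
#'
#' @param ratios tibble with columns `relative_expansion` and
#'   `dimensionality` (as returned by [relative_expansion()]).
#' @return `ratios` with an `adjusted_expansion_ratio` column appended.
#' @examples
#' adjust_ratio(tibble::tibble(dimensionality = c(2, 3, 1),
#'                             relative_expansion = c(1.83, 1.68, 1.14)))
#' @export
adjust_ratio <- function(ratios) {
  stopifnot(is.data.frame(ratios),
            all(c("relative_expansion", "dimensionality") %in% names(ratios)))
  if (any(ratios$relative_expansion <= 0)) {
    abort("relative expansions must be > 0.")
  }
  if (!all(ratios$dimensionality %in% 1:3)) {
    abort("dimensionality must be 1, 2 or 3.")
  }
  dplyr::mutate(ratios,
    adjusted_expansion_ratio = .data$relative_expansion^(1 / .data$dimensionality))
}

#' Coefficient of variation
#'
#' Sample standard deviation (n - 1 denominator) divided by the mean.
#'
#' @param values numeric vector, at least 2 values, non-zero mean.
#' @return The CV (dimensionless).
#' @export
cv <- function(values) {
  if (length(values) < 2) abort("CV needs at least 2 values.")
  m <- mean(values)
  if (m == 0) abort("CV undefined for zero mean.")
  sd(values) / m
}

#' Clearing CV: how uniform is the expansion?
#'
#' The coefficient of variation of the adjusted expansion ratios across all
#' measures. A low clearing CV means clearing affected every measure — in
#' every region and at every spatial scale probed — to a similar degree,
#' i.e. the expansion can be regarded as uniform.
#'
#' @param adjusted a numeric vector of adjusted expansion ratios, or a
#'   tibble with an `adjusted_expansion_ratio` column.
#' @return The clearing CV (dimensionless).
#' @export
clearing_cv <- function(adjusted) {
  if (is.data.frame(adjusted)) adjusted <- adjusted$adjusted_expansion_ratio
  cv(adjusted)
}

#' Acceptability threshold from uncleared-tissue variability
#'
#' There is no rule of thumb for how low a CV is "low", so the yardstick is
#' the variability the field already accepts: the CV of each measure within
#' conventionally fixed (uncleared) tissue from a single subject. The
#' threshold is the arithmetic mean of those per-measure CVs.
#'
#' @param data long-format measurement tibble containing uncleared rows.
#' @param group grouping columns defining one CV each; default
#'   `"measure_id"` (one pooled CV per measure).
#' @return A list with `per_measure` (tibble of per-group CVs) and
#'   `threshold` (their mean).
#' @export
acceptability_threshold <- function(data, group = "measure_id") {
  check_measurements(data)
  unc <- dplyr::filter(data, .data$condition == "uncleared")
  if (nrow(unc) == 0) abort("no uncleared measurements supplied.")
  per <- unc |>
    dplyr::group_by(dplyr::across(dplyr::all_of(group))) |>
    dplyr::group_modify(function(d, key) {
      if (nrow(d) < 2) {
        abort(sprintf("set '%s' has fewer than 2 values; CV undefined.",
                      paste(unlist(key), collapse = "/")))
      }
      if (mean(d$value) == 0) {
        abort(sprintf("set '%s' has zero mean; CV undefined.",
                      paste(unlist(key), collapse = "/")))
      }
      tibble(cv = cv(d$value), n = nrow(d))
    }) |>
    dplyr::ungroup()
  list(per_measure = per, threshold = mean(per$cv))
}

#' Uniformity verdict
#'
#' Expansion is called uniform when the clearing CV does not exceed the
#' acceptability threshold; the boundary case counts as uniform, the
#' conservative reading of "of a similar magnitude".
#'
#' @param clearing_cv clearing CV (non-negative).
#' @param threshold acceptability threshold (non-negative).
#' @return A one-row tibble: `clearing_cv`, `threshold`, `verdict`.
#' @export
uniformity_verdict <- function(clearing_cv, threshold) {
  check_number(clearing_cv, "clearing_cv", non_negative = TRUE)
  check_number(threshold, "threshold", non_negative = TRUE)
  tibble(
    clearing_cv = clearing_cv,
    threshold = threshold,
    verdict = if (clearing_cv <= threshold) "uniform" else "non_uniform"
  )
}

#' Full clearing report from a measurement table
#'
#' Chains the whole uniformity analysis: relative expansions per measure,
#' dimension-normalised adjusted ratios, the clearing CV across measures,
#' the acceptability threshold from uncleared-tissue CVs, and the verdict.
#'
#' @param data long-format measurement tibble with both conditions.
#' @param round_digits round adjusted ratios to this many decimals before
#'   the clearing CV (as when working from a published 2-dp table);
#'   `NULL` (default) uses unrounded ratios.
#' @param cv_group grouping for the uncleared CVs; see
#'   [acceptability_threshold()].
#' @return An object of class `clearing_report`; see [tidy.clearing_report()]
#'   and [glance.clearing_report()].
#' @export
clearing_report <- function(data, round_digits = NULL, cv_group = "measure_id") {
  ratios <- adjust_ratio(relative_expansion(data))
  adj <- ratios$adjusted_expansion_ratio
  if (!is.null(round_digits)) adj <- round(adj, round_digits)
  thr <- acceptability_threshold(data, group = cv_group)
  ccv <- cv(adj)
  verdict <- uniformity_verdict(ccv, thr$threshold)
  structure(
    list(ratios = ratios, clearing_cv = ccv,
         uncleared_cvs = thr$per_measure, threshold = thr$threshold,
         verdict = verdict$verdict, round_digits = round_digits),
    class = "clearing_report"
  )
}

check_measurements <- function(data) {
  req <- c("measure_id", "condition", "kind", "dimensionality", "value", "units")
  if (!is.data.frame(data) || !all(req %in% names(data))) {
    abort(paste("expected a long-format measurement table with columns:",
                paste(req, collapse = ", ")))
  }
  invisible(data)
}

#' @export
print.clearing_report <- function(x, ...) {
  cat("<clearing_report>\n")
  cat(sprintf("  measures: %d; clearing CV %.3f vs threshold %.3f -> %s\n",
              nrow(x$ratios), x$clearing_cv, x$threshold, x$verdict))
  invisible(x)
}

#' Tidy a clearing report
#'
#' @param x a `clearing_report`.
#' @param ... unused.
#' @return The per-measure ratio table (measure, kind, dimensionality,
#'   relative and adjusted expansion ratios).
#' @export
tidy.clearing_report <- function(x, ...) x$ratios

#' One-row summary of a clearing report
#'
#' @param x a `clearing_report`.
#' @param ... unused.
#' @return Tibble with `n_measures`, `clearing_cv`, `threshold`, `verdict`.
#' @export
glance.clearing_report <- function(x, ...) {
  tibble(n_measures = nrow(x$ratios), clearing_cv = x$clearing_cv,
         threshold = x$threshold, verdict = x$verdict)
}

#' Plot adjusted expansion ratios with the uniformity yardstick
#'
#' @param object a `clearing_report`.
#' @param ... unused.
#' @return A ggplot: one bar per measure's adjusted ratio, annotated with
#'   the clearing CV and threshold.
#' @export
autoplot.clearing_report <- function(object, ...) {
  df <- object$ratios
  ggplot2::ggplot(df, ggplot2::aes(
    x = stats::reorder(.data$measure_id, .data$adjusted_expansion_ratio),
    y = .data$adjusted_expansion_ratio, fill = .data$kind)) +
    ggplot2::geom_col() +
    ggplot2::geom_hline(yintercept = mean(df$adjusted_expansion_ratio),
                        linetype = "dashed") +
    ggplot2::coord_flip() +
    ggplot2::labs(
      x = NULL, y = "adjusted expansion ratio",
      title = sprintf("clearing CV %.3f vs threshold %.3f (%s)",
                      object$clearing_cv, object$threshold, object$verdict)) +
    ggplot2::theme_minimal()
}

#' Write a clearing report as JSON plus a flat ratio CSV
#'
#' @param report a `clearing_report`.
#' @param json_path output JSON path (adjusted ratios, per-measure uncleared
#'   CVs, clearing CV, threshold, verdict).
#' @param csv_path optional CSV path for the ratio table
#'   (`measure_id`, `kind`, `relative_expansion`, `adjusted_expansion_ratio`).
#' @return `json_path`, invisibly.
#' @export
write_clearing_report <- function(report, json_path, csv_path = NULL) {
  stopifnot(inherits(report, "clearing_report"))
  payload <- list(
    adjusted_ratios = lapply(seq_len(nrow(report$ratios)), function(i) {
      r <- report$ratios[i, ]
      list(measure_id = r$measure_id, kind = r$kind,
           relative_expansion = fmt_num(r$relative_expansion),
           adjusted_expansion_ratio = fmt_num(r$adjusted_expansion_ratio))
    }),
    uncleared_cvs = lapply(seq_len(nrow(report$uncleared_cvs)), function(i) {
      r <- report$uncleared_cvs[i, ]
      c(as.list(r[setdiff(names(r), c("cv", "n"))]),
        list(cv = fmt_num(r$cv), n = r$n))
    }),
    clearing_cv = fmt_num(report$clearing_cv),
    threshold = fmt_num(report$threshold),
    verdict = report$verdict
  )
  jsonlite::write_json(payload, json_path, auto_unbox = TRUE, digits = NA)
  if (!is.null(csv_path)) {
    out <- report$ratios[, c("measure_id", "kind", "relative_expansion",
                             "adjusted_expansion_ratio")]
    out$relative_expansion <- fmt_num(out$relative_expansion)
    out$adjusted_expansion_ratio <- fmt_num(out$adjusted_expansion_ratio)
    utils::write.csv(out, csv_path, row.names = FALSE)
  }
  invisible(json_path)
}

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance
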