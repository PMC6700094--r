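#' Saturating-exponential antibody penetration model
#'
#' Antibody staining depth as a function of incubation time t (days) is
#' modelled as \eqn{D(t) = A (1 - e^{-k t})}: depth zero at t = 0 rising to
#' an asymptote A (mm) at rate k (per day). The curve is constrained
#' through the origin — no staining before incubation starts.
#'
#' @param A asymptotic penetration depth, mm (> 0).
#' @param k rate constant, per day (> 0).
#' @return An object of class `penetration_model`.
#' @examples
#' m <- penetration_model(A = 0.8, k = 0.38)
#' predict_depth(m, t = 3)
#' @export
penetration_model <- function(A, k) {
  check_number(A, "A", positive = TRUE)
  check_number(k, "k", positive = TRUE)
  structure(list(A = A, k = k), class = "penetration_model")
}

#' @export
print.penetration_model <- function(x, ...) {
  cat(sprintf("<penetration_model> D(t) = %s * (1 - exp(-%s t)) mm, t in days\n",
              fmt_num(x$A), fmt_num(x$k)))
  invisible(x)
}

#' Predicted staining depth at incubation time t
#'
#' @param model a [penetration_model()].
#' @param t incubation time(s) in days, non-negative.
#' @return Depth(s) in mm.
#' @export
predict_depth <- function(model, t) {
  stopifnot(inherits(model, "penetration_model"))
  if (any(t < 0)) abort("incubation time must be non-negative.")
  model$A * (1 - exp(-model$k * t))
}

#' @export
predict.penetration_model <- function(object, t, ...) predict_depth(object, t)

#' Simulate an antibody-penetration time series
#'
#' Depths follow the saturating exponential plus additive Gaussian noise,
#' clipped at zero (a staining front cannot be negative).
#'
#' @param model a [penetration_model()] (recorded as the ground truth).
#' @param times incubation times, days; non-negative, strictly increasing,
#'   non-empty.
#' @param noise_sd additive depth noise SD, mm.
#' @param seed integer seed.
#' @return A tibble (`time_days`, `depth_mm`) with attributes `truth`
#'   (the generating model) and `seed`.
#' @export
simulate_penetration_series <- function(model, times = c(1, 3, 7, 11),
                                        noise_sd = 0, seed = 1L) {
  stopifnot(inherits(model, "penetration_model"))
  if (length(times) == 0) abort("`times` must be non-empty.")
  if (any(times < 0) || is.unsorted(times, strictly = TRUE)) {
    abort("`times` must be non-negative and strictly increasing.")
  }
  check_number(noise_sd, "noise_sd", non_negative = TRUE)
  depths <- predict_depth(model, times)
  if (noise_sd > 0) {
    depths <- with_seed(seed, pmax(depths + rnorm(length(times), sd = noise_sd), 0))
  }
  out <- tibble(time_days = as.numeric(times), depth_mm = depths)
  attr(out, "truth") <- model
  attr(out, "seed") <- as.integer(seed)
  out
}

#' Fit the saturating-exponential penetration model
#'
#' Unweighted nonlinear least squares of depth on incubation time, with
#' analytic residual Jacobian and positivity bounds on both parameters.
#' Started from A = max depth, k = 1 / mean(t). Non-convergence is reported,
#' never silently swallowed; a rate pinned at its upper bound (the
#' non-identifiable flat-series case) triggers a warning.
#'
#' @param data a data frame with columns `time_days` and `depth_mm` (e.g.
#'   from [simulate_penetration_series()] or a CSV with those columns).
#' @param k_max upper bound on the rate, per day. Default 1e3.
#' @return An object of class `penetration_fit`: `model`
#'   ([penetration_model()]), `rss` (mm^2), `n`, `converged`, `data`.
#' @export
fit_penetration <- function(data, k_max = 1e3) {
  stopifnot(is.data.frame(data),
            all(c("time_days", "depth_mm") %in% names(data)))
  t <- data$time_days
  d <- data$depth_mm
  if (length(unique(t[t > 0])) < 3) {
    abort("need depths at >= 3 distinct positive times to fit A and k.")
  }
  flat <- sd(d) <= 1e-12 * max(abs(d), 1e-12)

  resid_fn <- function(p) d - p[1] * (1 - exp(-p[2] * t))
  jac_fn <- function(p) {
    e <- exp(-p[2] * t)
    cbind(-(1 - e), -p[1] * t * e)
  }
  start <- c(A = max(d, 1e-6), k = 1 / mean(t))
  fit <- minpack.lm::nls.lm(
    par = start, fn = resid_fn, jac = jac_fn,
    lower = c(1e-12, 1e-12), upper = c(Inf, k_max),
    control = minpack.lm::nls.lm.control(
      ptol = 1e-10, ftol = 1e-15, maxiter = 500)
  )
  converged <- fit$info %in% 1:4
  if (flat || fit$par[2] >= k_max * (1 - 1e-6)) {
    warn(paste("depths do not identify the rate (flat series or k at its",
               "upper bound); treating the fit as non-converged."))
    converged <- FALSE
  }
  structure(
    list(
      model = penetration_model(max(fit$par[1], 1e-12), max(fit$par[2], 1e-12)),
      rss = sum(resid_fn(fit$par)^2),
      n = length(t),
      converged = converged,
      data = as_tibble(data[, c("time_days", "depth_mm")])
    ),
    class = "penetration_fit"
  )
}

#' @export
print.penetration_fit <- function(x, ...) {
  cat(sprintf("<penetration_fit> A = %s mm, k = %s /day, RSS %s (n = %d%s)\n",
              fmt_num(x$model$A), fmt_num(x$model$k), fmt_num(x$rss), x$n,
              if (x$converged) "" else "; NOT converged"))
  invisible(x)
}

#' @export
predict.penetration_fit <- function(object, t, ...) predict_depth(object$model, t)

#' Tidy a penetration fit
#'
#' @param x a `penetration_fit`.
#' @param ... unused.
#' @return Tibble with one row per parameter (`term`, `estimate`).
#' @export
tidy.penetration_fit <- function(x, ...) {
  tibble(term = c("A_mm", "k_per_day"), estimate = c(x$model$A, x$model$k))
}

#' One-row summary of a penetration fit
#'
#' @param x a `penetration_fit`.
#' @param ... unused.
#' @return Tibble with `A_mm`, `k_per_day`, `rss`, `n`, `converged`.
#' @export
glance.penetration_fit <- function(x, ...) {
  tibble(A_mm = x$model$A, k_per_day = x$model$k, rss = x$rss,
         n = x$n, converged = x$converged)
}

#' Plot a penetration fit over its data
#'
#' @param object a `penetration_fit`.
#' @param ... unused.
#' @return A ggplot of observed depths and the fitted saturating curve.
#' @export
autoplot.penetration_fit <- function(object, ...) {
  grid <- tibble(time_days = seq(0, max(object$data$time_days) * 1.1,
                                 length.out = 200))
  grid$depth_mm <- predict_depth(object$model, grid$time_days)
  ggplot2::ggplot(object$data, ggplot2::aes(.data$time_days, .data$depth_mm)) +
    ggplot2::geom_line(data = grid, colour = "grey40") +
    ggplot2::geom_point() +
    ggplot2::labs(x = "incubation time (days)", y = "penetration depth (mm)",
                  title = sprintf("A = %.3f mm, k = %.3f /day",
                                  object$model$A, object$model$k)) +
    ggplot2::theme_minimal()
}

#' Read / write penetration series and fitted models
#'
#' CSV columns are `time_days`, `depth_mm`; the fitted model is emitted as
#' JSON with fields `A_mm`, `k_per_day`, `rss`, `converged`.
#'
#' @param data tibble with `time_days`, `depth_mm` (write) / `path` file
#'   path (read).
#' @param path file path.
#' @param fit a `penetration_fit`.
#' @return `path` invisibly (writers); a tibble (reader).
#' @export
write_penetration_series <- function(data, path) {
  utils::write.csv(data[, c("time_days", "depth_mm")], path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_penetration_series
#' @export
read_penetration_series <- function(path) {
  as_tibble(utils::read.csv(path))
}

#' @rdname write_penetration_series
#' @export
write_penetration_fit <- function(fit, path) {
  stopifnot(inherits(fit, "penetration_fit"))
  jsonlite::write_json(
    list(A_mm = fit$model$A, k_per_day = fit$model$k,
         rss = fit$rss, converged = fit$converged),
    path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}
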