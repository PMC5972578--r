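# Fixed-effects gradient statistics. Linear trends of calibrated protein
# concentration (and of log body size) against distance from the aleurone
# layer are fitted per treatment group by ordinary least squares, with a
# distance-squared term available as a lack-of-fit check. This is the
# fixed-effects analogue of a full nested mixed-model analysis: tables are
# exported so the nested random structure can be fitted externally, and the
# group comparison here is explicitly descriptive.

#' Fit a linear gradient of a response against distance
#'
#' Ordinary least squares of `response` on `distance`. The slope is in
#' response units per micrometre; a negative concentration slope means more
#' protein near the aleurone layer.
#'
#' @param records data.frame with columns `distance_um` and `response`
#'   (or a two-column numeric data.frame/matrix taken in that order).
#' @param group optional named list or character label identifying the
#'   treatment group.
#' @param response name of the response ("concentration" or
#'   "log_body_area", free-text otherwise).
#' @return object of class `gradient_fit` with `slope`, `intercept`,
#'   `slope_se`, `intercept_se`, `n`, `r2`, `quad_p` (NA until
#'   [quadratic_check()]), `group`, `response`, and the underlying `lm`
#'   fit.
#' @export
fit_gradient <- function(records, group = NULL, response = "response") {
  df <- as_gradient_records(records)
  if (nrow(df) < 3L) stop("need at least 3 observations", call. = FALSE)
  if (length(unique(df$distance_um)) < 2L)
    stop("degenerate design: all distances equal", call. = FALSE)
  fit <- stats::lm(response ~ distance_um, data = df)
  # exactly collinear observations are legitimate here (noise-free zones)
  sm <- suppressWarnings(summary(fit))
  co <- sm$coefficients
  r2 <- sm$r.squared
  structure(list(slope = co["distance_um", "Estimate"],
                 intercept = co["(Intercept)", "Estimate"],
                 slope_se = co["distance_um", "Std. Error"],
                 intercept_se = co["(Intercept)", "Std. Error"],
                 n = nrow(df),
                 r2 = if (is.finite(r2)) r2 else 1,
                 quad_p = NA_real_,
                 group = group,
                 response = response,
                 lm = fit,
                 records = df),
            class = "gradient_fit")
}

as_gradient_records <- function(records) {
  if (is.matrix(records)) records <- as.data.frame(records)
  if (!all(c("distance_um", "response") %in% names(records))) {
    stopifnot(ncol(records) >= 2L)
    names(records)[1:2] <- c("distance_um", "response")
  }
  records[, c("distance_um", "response")]
}

#' @export
print.gradient_fit <- function(x, ...) {
  lbl <- if (is.null(x$group)) "" else
    paste0(" [", paste(unlist(x$group), collapse = "/"), "]")
  cat(sprintf("gradient_fit%s: %s ~ distance\n", lbl, x$response))
  cat(sprintf("  slope     %12.6g  (se %.4g) per um\n", x$slope, x$slope_se))
  cat(sprintf("  intercept %12.6g  (se %.4g)\n", x$intercept, x$intercept_se))
  cat(sprintf("  n = %d, R^2 = %.4f", x$n, x$r2))
  if (!is.na(x$quad_p))
    cat(sprintf(", lack-of-fit (distance^2) p = %.4g", x$quad_p))
  cat("\n")
  invisible(x)
}

#' @export
summary.gradient_fit <- function(object, ...) {
  print(object)
  invisible(object)
}

#' @export
coef.gradient_fit <- function(object, ...) {
  c(intercept = object$intercept, slope = object$slope)
}

#' @export
predict.gradient_fit <- function(object, distance_um = NULL, ...) {
  if (is.null(distance_um)) distance_um <- object$records$distance_um
  object$intercept + object$slope * distance_um
}

#' @export
residuals.gradient_fit <- function(object, ...) {
  object$records$response - predict(object)
}

#' Log-transform protein body areas for gradient fitting
#'
#' Natural log of each body area, paired with the body's distance from the
#' outline. The log transform stabilises the strongly right-skewed size
#' variance; back-transform with `exp()` for reporting.
#'
#' @param bodies data.frame with `area_um2` and `distance_um`.
#' @return data.frame with columns `distance_um`, `response` (= log area).
#' @export
log_transform_areas <- function(bodies) {
  if (nrow(bodies) > 0L && any(bodies$area_um2 <= 0))
    stop("non-positive body area", call. = FALSE)
  data.frame(distance_um = bodies$distance_um,
             response = log(bodies$area_um2))
}

#' Lack-of-fit check: add a distance-squared term
#'
#' Nested-model F-test comparing the linear fit with linear + quadratic.
#' The p-value is reported on the fit; the linear model is never replaced
#' automatically. Exactly linear data (zero residual) give F = 0 and
#' p = 1.
#'
#' @param fit a [fit_gradient()] result.
#' @param records observations; defaults to those stored in the fit.
#' @return the `gradient_fit` with `quad_p` (and `quad_F`) filled in.
#' @export
quadratic_check <- function(fit, records = NULL) {
  stopifnot(inherits(fit, "gradient_fit"))
  df <- if (is.null(records)) fit$records else as_gradient_records(records)
  n <- nrow(df)
  if (n < 4L) stop("need at least 4 observations", call. = FALSE)
  lin <- stats::lm(response ~ distance_um, data = df)
  quad <- stats::lm(response ~ distance_um + I(distance_um^2), data = df)
  rss1 <- sum(stats::residuals(lin)^2)
  rss2 <- sum(stats::residuals(quad)^2)
  if (rss1 <= .Machine$double.eps * sum(df$response^2) || rss2 <= 0) {
    # perfectly linear (or saturated): no evidence of curvature
    Fstat <- 0
    p <- 1
  } else {
    Fstat <- ((rss1 - rss2) / 1) / (rss2 / (n - 3))
    p <- stats::pf(Fstat, 1, n - 3, lower.tail = FALSE)
  }
  fit$quad_F <- Fstat
  fit$quad_p <- p
  fit
}

#' Descriptive comparison of gradient slopes across treatment groups
#'
#' Pairwise slope differences with Welch-type z statistics computed from
#' the per-group OLS standard errors. Descriptive only: inference under the
#' full nested experimental structure belongs in an external mixed-model
#' analysis of the exported tables.
#'
#' @param fits list of `gradient_fit` objects (>= 2).
#' @return data.frame with one row per pair: group labels, slopes, slope
#'   difference, its standard error, z statistic and two-sided normal
#'   p-value.
#' @export
compare_groups <- function(fits) {
  if (length(fits) < 2L) stop(">= 2 groups required", call. = FALSE)
  stopifnot(all(vapply(fits, inherits, logical(1), "gradient_fit")))
  lbl <- vapply(seq_along(fits), function(i) {
    g <- fits[[i]]$group
    if (is.null(g)) paste0("group", i) else paste(unlist(g), collapse = "/")
  }, character(1))
  pairs <- utils::combn(length(fits), 2)
  out <- lapply(seq_len(ncol(pairs)), function(j) {
    a <- fits[[pairs[1, j]]]; b <- fits[[pairs[2, j]]]
    diff <- a$slope - b$slope
    se <- sqrt(a$slope_se^2 + b$slope_se^2)
    z <- if (se > 0) diff / se else 0
    data.frame(group_a = lbl[pairs[1, j]], group_b = lbl[pairs[2, j]],
               slope_a = a$slope, slope_b = b$slope,
               slope_diff = diff, diff_se = se, z = z,
               p = 2 * stats::pnorm(-abs(z)))
  })
  do.call(rbind, out)
}

#' Tabulate gradient fits for export
#' @param fits list of `gradient_fit` objects.
#' @return data.frame, one row per fit.
#' @export
gradient_table <- function(fits) {
  do.call(rbind, lapply(fits, function(f) {
    g <- f$group
    data.frame(group = if (is.null(g)) NA_character_ else
                 paste(unlist(g), collapse = "/"),
               response = f$response, slope = f$slope,
               slope_se = f$slope_se, intercept = f$intercept,
               intercept_se = f$intercept_se, n = f$n, r2 = f$r2,
               quad_p = f$quad_p)
  }))
}
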