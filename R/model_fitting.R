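## Model-building machinery: fixed-exponent power-law fits of shift-vs-
## distance scans and the linear calibrations mapping raw dimer-model
## sums onto cluster-level shifts.

#' Fit a fixed-exponent power law to a (distance, shift) scan
#'
#' Least-squares fit of `delta = slope / r^exponent` with the exponent
#' held fixed (4 for the water-water terms, 6 for DMSO and CH...O).  The
#' default through-origin constraint encodes the physical requirement
#' that the shift vanish at infinite separation; for through-origin fits
#' the R^2 is computed against the uncentered sum of squares.
#'
#' @param points data frame with columns `r` (A, positive, distinct) and
#'   `delta` (ppm).
#' @param exponent fixed positive integer exponent (4 or 6 in practice).
#' @param through_origin constrain the intercept to zero (default
#'   `TRUE`).
#' @return Object of class `power_law_fit`: `slope` (ppm A^exponent),
#'   `exponent`, `intercept` (0 when constrained), `r_squared`,
#'   `through_origin`, `n`.
#' @examples
#' r <- c(1.7, 1.8, 1.9, 2.0)
#' fit_power_law(data.frame(r = r, delta = 137.08 / r^4), exponent = 4)
#' @export
fit_power_law <- function(points, exponent, through_origin = TRUE) {
  stopifnot(is.data.frame(points), all(c("r", "delta") %in% names(points)),
            length(exponent) == 1, exponent > 0)
  if (any(points$r <= 0)) stop("distances must be positive")
  n_min <- if (through_origin) 1L else 2L
  if (nrow(points) < n_min)
    stop(sprintf("need at least %d point(s)", n_min))
  if (!through_origin && length(unique(points$r)) < 2)
    stop("need at least two distinct r values for a free-intercept fit")
  x <- points$r^(-exponent)
  y <- points$delta
  fit <- if (through_origin) stats::lm(y ~ 0 + x) else stats::lm(y ~ x)
  co <- stats::coef(fit)
  slope <- unname(co[["x"]])
  intercept <- if (through_origin) 0 else unname(co[["(Intercept)"]])
  rss <- sum(stats::residuals(fit)^2)
  tss <- if (through_origin) sum(y^2) else sum((y - mean(y))^2)
  r2 <- if (tss > 0) 1 - rss / tss else NA_real_
  structure(list(slope = slope, exponent = as.integer(exponent),
                 intercept = intercept, r_squared = r2,
                 through_origin = through_origin, n = nrow(points)),
            class = "power_law_fit")
}

#' @export
print.power_law_fit <- function(x, ...) {
  cat(sprintf(
    "power-law fit: delta = %.4f / r^%d%s  (n = %d, R^2 = %.4f%s)\n",
    x$slope, x$exponent,
    if (x$through_origin) "" else sprintf(" %+.4f", x$intercept),
    x$n, x$r_squared,
    if (x$through_origin) ", uncentered" else ""))
  invisible(x)
}

#' Ordinary least-squares line, optionally through the origin
#'
#' @param x,y equal-length numeric vectors (at least 2 points; `x` must
#'   not be constant).
#' @param with_intercept fit an intercept (default `TRUE`); `FALSE`
#'   constrains it to zero and reports the uncentered R^2.
#' @return Object of class `linear_calibration`: `slope`, `intercept`,
#'   `r_squared`, `n`.
#' @examples
#' fit_linear(1:5, 1.38 * (1:5) - 0.78)
#' @export
fit_linear <- function(x, y, with_intercept = TRUE) {
  stopifnot(is.numeric(x), is.numeric(y), length(x) == length(y))
  if (length(x) < 2) stop("need at least two points")
  if (max(x) - min(x) < 1e-12)
    stop("degenerate fit: all x values are equal")
  fit <- if (with_intercept) stats::lm(y ~ x) else stats::lm(y ~ 0 + x)
  co <- stats::coef(fit)
  rss <- sum(stats::residuals(fit)^2)
  tss <- if (with_intercept) sum((y - mean(y))^2) else sum(y^2)
  structure(list(slope = unname(co[["x"]]),
                 intercept = if (with_intercept)
                   unname(co[["(Intercept)"]]) else 0,
                 r_squared = if (tss > 0) 1 - rss / tss else NA_real_,
                 n = length(x)),
            class = "linear_calibration")
}

#' @export
print.linear_calibration <- function(x, ...) {
  cat(sprintf("linear calibration: y = %.4f x %+.4f  (n = %d, R^2 = %.4f)\n",
              x$slope, x$intercept, x$n, x$r_squared))
  invisible(x)
}

#' Fit the split dangling / no-dangling calibration
#'
#' Partitions (raw predicted, target) pairs by the dangling flag and fits
#' an independent linear calibration to each partition, reproducing the
#' workflow that produced the 1.38/−0.78 (no dangling) and 1.20/−0.64
#' (dangling) constants.
#'
#' @param predicted raw model sums, ppm.
#' @param target reference (e.g. ab initio cluster) shifts, ppm.
#' @param dangling logical flag per pair.
#' @param with_intercept fit intercepts (default `TRUE`).
#' @return List with `linear_calibration` elements `dangling` and
#'   `nodangling`.
#' @export
calibrate_predictor <- function(predicted, target, dangling,
                                with_intercept = TRUE) {
  stopifnot(length(predicted) == length(target),
            length(predicted) == length(dangling),
            is.logical(dangling))
  fits <- list()
  for (grp in c("dangling", "nodangling")) {
    sel <- if (grp == "dangling") dangling else !dangling
    if (sum(sel) < 2)
      stop(sprintf("partition '%s' has fewer than two pairs", grp))
    fits[[grp]] <- fit_linear(predicted[sel], target[sel], with_intercept)
  }
  fits
}
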