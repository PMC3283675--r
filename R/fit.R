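#' Least-squares proportional fit through the origin
#'
#' Both per-cell estimators reduce a sweep to the slope of a response that is
#' physically forced through the origin (a cell in zero field does not
#' migrate; a cell at zero drag speed is undeformed). The zero-intercept
#' least-squares slope is `sum(x * y) / sum(x^2)`; the Pearson correlation of
#' the raw pairs is kept as the fit diagnostic, following the convention of
#' reporting per-cell correlation coefficients.
#'
#' @param x,y Paired numeric vectors (>= 2 finite points, `x` not all zero).
#' @param intercept If `TRUE`, additionally fit a free-intercept line for
#'   diagnostics; the reported `slope` is still the through-origin slope, the
#'   free fit is stored in the `diagnostic` element.
#' @return An object of class `"prop_fit"`: a list with `slope`, `pearson_r`,
#'   `n`, `sigma` (residual RMS about the proportional fit) and, when
#'   requested, `diagnostic` (free-intercept slope and intercept).
#'   [generics::tidy()] and [generics::glance()] methods return tibbles.
#' @examples
#' fit <- fit_proportional(c(1, 2, 3), c(2.1, 3.9, 6.0))
#' fit$slope        # 29.9 / 14
#' generics::glance(fit)
#' @export
fit_proportional <- function(x, y, intercept = FALSE) {
  stopifnot(is.numeric(x), is.numeric(y), length(x) == length(y))
  keep <- is.finite(x) & is.finite(y)
  x <- x[keep]; y <- y[keep]
  if (length(x) < 2L)
    stop("insufficient data: need at least 2 finite paired points",
         call. = FALSE)
  sxx <- sum(x^2)
  if (sxx == 0)
    stop("degenerate fit: all x values are zero", call. = FALSE)
  slope <- sum(x * y) / sxx
  r <- if (stats::sd(x) > 0 && stats::sd(y) > 0) stats::cor(x, y) else NA_real_
  resid <- y - slope * x
  out <- list(slope = slope, pearson_r = r, n = length(x),
              sigma = sqrt(mean(resid^2)), sxx = sxx)
  if (intercept) {
    co <- stats::coef(stats::lm(y ~ x))
    out$diagnostic <- list(intercept = unname(co[1L]), slope = unname(co[2L]))
  }
  class(out) <- "prop_fit"
  out
}

#' @export
print.prop_fit <- function(x, ...) {
  cat("Proportional least-squares fit\n")
  cat(sprintf("  slope: %.6g   pearson r: %.4f   n: %d\n",
              x$slope, x$pearson_r, x$n))
  invisible(x)
}

#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' Tidy a proportional fit
#'
#' @param x A `"prop_fit"` object.
#' @param ... Unused.
#' @return One-row tibble with `term`, `estimate`, `std.error`.
#' @method tidy prop_fit
#' @export
tidy.prop_fit <- function(x, ...) {
  # through-origin model has n - 1 residual degrees of freedom
  s2 <- x$sigma^2 * x$n / max(x$n - 1L, 1L)
  tibble::tibble(term = "slope", estimate = x$slope,
                 std.error = sqrt(s2 / x$sxx))
}

#' Glance at a proportional fit
#'
#' @param x A `"prop_fit"` object.
#' @param ... Unused.
#' @return One-row tibble with `pearson_r`, `r.squared`, `sigma`, `nobs`.
#' @method glance prop_fit
#' @export
glance.prop_fit <- function(x, ...) {
  tibble::tibble(pearson_r = x$pearson_r, r.squared = x$pearson_r^2,
                 sigma = x$sigma, nobs = x$n)
}
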