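#' Preprocess a measured cell spectrum
#'
#' Standard conditioning before spectral decomposition: the pointwise mean of
#' the background spectra (imaging solution on the same coverslip) is
#' subtracted, the spectrum is cropped to the analysis window, smoothed with
#' a Savitzky-Golay filter, and negative excursions are clipped to zero
#' (emission is non-negative). Smoothing can be disabled for already-clean
#' synthetic input.
#'
#' @param cell a cell [spectrum]; its grid must cover `range_nm`.
#' @param backgrounds non-empty list of background [spectrum] objects.
#' @param range_nm analysis window in nm, default `c(400, 850)` — wide enough
#'   to encompass all four fluorophores' emission.
#' @param smooth apply the Savitzky-Golay smoother (window 11, order 3)?
#' @return A corrected [spectrum] with `meta$preprocessed = TRUE`.
#' @examples
#' wl <- seq(400, 850)
#' bg <- spectrum(wl, rep(0.05, length(wl)), role = "background")
#' cell <- spectrum(wl, 0.05 + exp(-(wl - 525)^2 / 3200))
#' cor <- preprocess(cell, list(bg))
#' @export
preprocess <- function(cell, backgrounds, range_nm = c(400, 850),
                       smooth = TRUE) {
  stopifnot(inherits(cell, "spectrum"))
  if (!length(backgrounds)) stop("at least one background spectrum is required")
  if (min(cell$wavelength_nm) > range_nm[1] + 1e-9 ||
      max(cell$wavelength_nm) < range_nm[2] - 1e-9)
    stop(sprintf("cell spectrum grid does not cover the %g-%g nm analysis range",
                 range_nm[1], range_nm[2]))
  keep <- cell$wavelength_nm >= range_nm[1] & cell$wavelength_nm <= range_nm[2]
  grid <- cell$wavelength_nm[keep]
  y <- cell$intensity[keep] - mean_background(backgrounds, grid)
  if (smooth) y <- smooth_signal(y)
  y <- pmax(y, 0)
  out <- cell
  out$wavelength_nm <- grid
  out$intensity <- y
  out$meta$preprocessed <- TRUE
  out
}

#' Decompose a corrected spectrum into library components
#'
#' Fits the linear unmixing model: the corrected per-cell emission spectrum
#' is modelled as a non-negative combination of the library's unit-peak
#' component shapes,
#' \deqn{I(\lambda) = \sum_k a_k S_k(\lambda) + \epsilon(\lambda), \quad a_k \ge 0,}
#' solved by non-negative least squares. The returned fit object carries, per
#' component, the abundance coefficient, the peak value of its fitted
#' contribution and the trapezoidal integral of that contribution over the
#' domain (the "sum of intensities under the peak"), together with the total
#' autofluorescence, the residual norm and an uncentered R-squared.
#'
#' @param corrected a preprocessed [spectrum] (see [preprocess()]); its grid
#'   must lie inside the library domain and hold at least as many points as
#'   there are components.
#' @param library a [spectral_library].
#' @param total how to compute total autofluorescence: `"spectrum"`
#'   (default) integrates the corrected spectrum itself, model-free;
#'   `"components"` sums the per-component integrals.
#' @return An object of class `"unmix_fit"` with elements `coefficients`
#'   (named, >= 0), `peak_value`, `integrated_intensity`,
#'   `total_autofluorescence`, `residual_l2`, `r_squared`, plus the grid,
#'   data and component matrix needed by the methods.
#' @seealso [coef.unmix_fit()], [fitted.unmix_fit()], [residuals.unmix_fit()],
#'   [summarize_cells()]
#' @examples
#' lib <- default_library()
#' wl <- seq(400, 850)
#' y <- 2 * predict(lib$components$FAD, wl)
#' fit <- unmix(spectrum(wl, y), lib)
#' coef(fit)
#' @export
unmix <- function(corrected, library, total = c("spectrum", "components")) {
  stopifnot(inherits(corrected, "spectrum"), inherits(library, "spectral_library"))
  total <- match.arg(total)
  grid <- corrected$wavelength_nm
  k <- length(library$components)
  if (length(grid) < k)
    stop("underdetermined: fewer grid points than library components")
  S <- library_matrix(library, grid)
  sol <- nnls_solve(S, corrected$intensity)
  a <- sol$x
  names(a) <- colnames(S)
  contrib <- sweep(S, 2L, a, "*")
  peak <- apply(contrib, 2L, max)
  integral <- apply(contrib, 2L, function(y) trapz(grid, y))
  total_af <- if (total == "spectrum") trapz(grid, corrected$intensity)
              else sum(integral)
  structure(list(
    coefficients = a,
    peak_value = peak,
    integrated_intensity = integral,
    total_autofluorescence = total_af,
    residual_l2 = sol$residual_l2,
    r_squared = r2_uncentered(corrected$intensity, as.numeric(S %*% a)),
    wavelength_nm = grid,
    intensity = corrected$intensity,
    component_matrix = S,
    meta = corrected$meta
  ), class = "unmix_fit")
}

#' @export
coef.unmix_fit <- function(object, ...) object$coefficients

#' @export
fitted.unmix_fit <- function(object, ...)
  as.numeric(object$component_matrix %*% object$coefficients)

#' @export
residuals.unmix_fit <- function(object, ...)
  object$intensity - fitted(object)

#' @export
print.unmix_fit <- function(x, ...) {
  cat("Non-negative spectral unmixing fit\n")
  cat(sprintf("  grid: %d points, %.0f-%.0f nm\n", length(x$wavelength_nm),
              min(x$wavelength_nm), max(x$wavelength_nm)))
  cat("  coefficients (a.u.):\n")
  print(round(x$coefficients, 6))
  cat(sprintf("  total autofluorescence: %.4g a.u.*nm   residual L2: %.3g   R2: %s\n",
              x$total_autofluorescence, x$residual_l2,
              ifelse(is.na(x$r_squared), "NA", sprintf("%.4f", x$r_squared))))
  invisible(x)
}

#' @export
summary.unmix_fit <- function(object, ...) {
  df <- data.frame(
    component = names(object$coefficients),
    coefficient = as.numeric(object$coefficients),
    peak_value = as.numeric(object$peak_value),
    integrated_intensity = as.numeric(object$integrated_intensity),
    row.names = NULL
  )
  out <- list(components = df,
              total_autofluorescence = object$total_autofluorescence,
              residual_l2 = object$residual_l2,
              r_squared = object$r_squared)
  class(out) <- "summary.unmix_fit"
  out
}

#' @export
print.summary.unmix_fit <- function(x, ...) {
  print(x$components)
  cat(sprintf("total autofluorescence %.4g a.u.*nm, residual L2 %.3g, R2 %s\n",
              x$total_autofluorescence, x$residual_l2,
              ifelse(is.na(x$r_squared), "NA", sprintf("%.4f", x$r_squared))))
  invisible(x)
}

#' @export
plot.unmix_fit <- function(x, ...) {
  graphics::plot(x$wavelength_nm, x$intensity, type = "l", col = "grey40",
                 xlab = "wavelength (nm)", ylab = "intensity (a.u.)", ...)
  graphics::lines(x$wavelength_nm, fitted(x), col = "black", lwd = 2)
  contrib <- sweep(x$component_matrix, 2L, x$coefficients, "*")
  for (j in seq_len(ncol(contrib)))
    graphics::lines(x$wavelength_nm, contrib[, j], col = j + 1, lty = 2)
  graphics::legend("topright", bty = "n", lty = c(1, 1, rep(2, ncol(contrib))),
                   col = c("grey40", "black", seq_len(ncol(contrib)) + 1),
                   legend = c("data", "fit", colnames(contrib)))
  invisible(x)
}

#' Summarise a per-cell metric over a set of unmixing fits
#'
#' Computes the sample mean, sample standard deviation (n - 1 denominator;
#' zero by convention for a single cell) and count of one per-cell metric —
#' the building block for the per-sample "total autofluorescence mean" and
#' "lipopigment autofluorescence mean" comparisons.
#'
#' @param results non-empty list of `unmix_fit` objects.
#' @param metric `"total_af"` for total autofluorescence, or
#'   `"integral"`, `"peak"`, `"coefficient"` for a per-component metric.
#' @param component component name, required for the per-component metrics.
#' @return A list with `mean`, `sd`, `n` and the raw per-cell `values`.
#' @export
summarize_cells <- function(results,
                            metric = c("total_af", "integral", "peak",
                                       "coefficient"),
                            component = NULL) {
  metric <- match.arg(metric)
  if (!length(results)) stop("no unmixing results to summarise")
  stopifnot(all(vapply(results, inherits, TRUE, "unmix_fit")))
  values <- vapply(results, function(r) {
    switch(metric,
      total_af = r$total_autofluorescence,
      integral = pick_component(r$integrated_intensity, component),
      peak = pick_component(r$peak_value, component),
      coefficient = pick_component(r$coefficients, component))
  }, 0)
  list(mean = mean(values),
       sd = if (length(values) > 1L) stats::sd(values) else 0,
       n = length(values),
       values = values)
}

pick_component <- function(v, component) {
  if (is.null(component))
    stop("a component name is required for per-component metrics")
  if (!component %in% names(v))
    stop(sprintf("unknown component '%s' (have: %s)", component,
                 paste(names(v), collapse = ", ")))
  as.numeric(v[[component]])
}
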