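#' @importFrom minpack.lm nlsLM nls.lm.control
NULL

# Savitzky-Golay smoother used throughout: window 11 grid points, order 3.
# Preserves peak height/width far better than a moving average at the grid
# resolution (1 nm) these spectra are recorded on.
smooth_signal <- function(y, window = 11L, order = 3L) {
  if (length(y) <= window) return(y)
  as.numeric(signal::sgolayfilt(y, p = order, n = window))
}

# mean background spectrum resampled onto a target grid
mean_background <- function(background_spectra, wavelength_nm) {
  stopifnot(length(background_spectra) >= 1L)
  mats <- vapply(background_spectra,
                 function(b) resample_spectrum(b, wavelength_nm)$intensity,
                 numeric(length(wavelength_nm)))
  rowMeans(as.matrix(mats))
}

# uncentered R^2: fraction of raw signal energy explained by the fit
r2_uncentered <- function(y, fit) {
  ss <- sum(y^2)
  if (ss == 0) return(NA_real_)
  1 - sum((y - fit)^2) / ss
}

# Least-squares fit of y(x) by a sum of <= max_terms Gaussians.
# Greedy initialisation: place each new term at the residual maximum with a
# half-maximum width estimate, then refine all terms jointly with
# Levenberg-Marquardt under amplitude >= 0, width > 0 bounds. Stops adding
# terms once the uncentered R^2 exceeds `stop_r2`.
fit_gaussian_sum <- function(x, y, max_terms = 3L, stop_r2 = 0.9999) {
  stopifnot(max_terms >= 1L)
  peak <- max(y)
  if (peak <= 0) stop("no signal: corrected spectrum is non-positive everywhere")
  terms <- NULL
  best <- NULL
  resid <- y
  for (k in seq_len(max_terms)) {
    i0 <- which.max(resid)
    amp0 <- max(resid[i0], peak * 1e-3)
    # half width at half maximum of the residual bump, converted to sd
    above <- resid >= amp0 / 2
    lo <- i0; while (lo > 1L && above[lo - 1L]) lo <- lo - 1L
    hi <- i0; while (hi < length(x) && above[hi + 1L]) hi <- hi + 1L
    hwhm <- max((x[hi] - x[lo]) / 2, 2 * (x[2] - x[1]))
    init <- rbind(terms, c(center_nm = x[i0], width_nm = hwhm / sqrt(2 * log(2)),
                           amplitude = amp0))
    fitk <- refine_gaussians(x, y, init)
    if (is.null(best) || fitk$r2 > best$r2) best <- fitk
    terms <- best$terms
    resid <- y - eval_gaussians(as.data.frame(terms), x)
    if (best$r2 >= stop_r2) break
  }
  list(gaussians = as.data.frame(best$terms), r_squared = best$r2)
}

refine_gaussians <- function(x, y, init) {
  k <- nrow(init)
  start <- as.list(as.numeric(t(init)))
  names(start) <- paste0(rep(c("c", "w", "a"), k), rep(seq_len(k), each = 3))
  form <- paste0("a", seq_len(k), " * exp(-(x - c", seq_len(k),
                 ")^2 / (2 * w", seq_len(k), "^2))")
  fml <- stats::as.formula(paste("y ~", paste(form, collapse = " + ")))
  dx <- x[2] - x[1]
  lower <- rep(c(min(x), dx / 2, 0), k)
  upper <- rep(c(max(x), (max(x) - min(x)), Inf), k)
  fit <- tryCatch(
    minpack.lm::nlsLM(fml, data = data.frame(x = x, y = y), start = start,
                      lower = lower, upper = upper,
                      control = minpack.lm::nls.lm.control(maxiter = 200)),
    error = function(e) NULL)
  if (is.null(fit)) {
    terms <- init
  } else {
    cf <- stats::coef(fit)
    terms <- cbind(center_nm = cf[paste0("c", seq_len(k))],
                   width_nm = cf[paste0("w", seq_len(k))],
                   amplitude = cf[paste0("a", seq_len(k))])
  }
  colnames(terms) <- c("center_nm", "width_nm", "amplitude")
  rownames(terms) <- NULL
  fitted <- eval_gaussians(as.data.frame(terms), x)
  list(terms = terms, r2 = r2_uncentered(y, fitted))
}

#' Train one spectral component from reference-solution spectra
#'
#' Implements the library-training step: replicate emission spectra of a
#' reference solution (pure NADH, NADH + lactate dehydrogenase, or FAD) are
#' background-corrected with the mean of the supplied background spectra,
#' averaged, smoothed, clipped at zero, and least-squares fitted by a sum of
#' at most `max_gaussians` Gaussian terms. The result is unit-peak normalized
#' and carries the fit R-squared in its provenance. The fitted shape is
#' invariant to uniform intensity scaling of the input spectra.
#'
#' @param reference_spectra list of [spectrum] objects (role `"reference"`).
#' @param background_spectra list of background [spectrum] objects; pass an
#'   all-zero spectrum if the references are already corrected.
#' @param name component name for the result.
#' @param max_gaussians maximum number of Gaussian terms (default 3).
#' @param domain wavelength domain for normalization, default `c(400, 850)`.
#' @return A [spectral_component].
#' @examples
#' wl <- seq(400, 850)
#' ref <- spectrum(wl, exp(-(wl - 525)^2 / (2 * 40^2)), role = "reference")
#' bg <- spectrum(wl, rep(0, length(wl)), role = "background")
#' comp <- fit_component(list(ref), list(bg), "FAD")
#' comp$gaussians
#' @export
fit_component <- function(reference_spectra, background_spectra, name,
                          max_gaussians = 3L, domain = c(400, 850)) {
  if (!length(reference_spectra)) stop("at least one reference spectrum required")
  grid <- common_grid(c(reference_spectra, background_spectra), domain)
  refs <- vapply(reference_spectra,
                 function(s) resample_spectrum(s, grid)$intensity,
                 numeric(length(grid)))
  corrected <- rowMeans(as.matrix(refs)) - mean_background(background_spectra, grid)
  corrected <- pmax(smooth_signal(corrected), 0)
  if (max(corrected) <= 0)
    stop("no signal: background-corrected reference is non-positive everywhere")
  fit <- fit_gaussian_sum(grid, corrected, max_terms = max_gaussians)
  spectral_component(
    name, fit$gaussians, domain = domain,
    provenance = sprintf(
      "fit_component: %d reference spectrum/a, %d background(s), R2=%.6f",
      length(reference_spectra), length(background_spectra), fit$r_squared))
}

# largest grid shared by all spectra, clipped to the library domain;
# the step is taken from the first spectrum
common_grid <- function(spectra, domain) {
  lo <- max(c(domain[1], vapply(spectra, function(s) min(s$wavelength_nm), 0)))
  hi <- min(c(domain[2], vapply(spectra, function(s) max(s$wavelength_nm), 0)))
  if (hi - lo < 10) stop("spectra grids do not overlap over the library domain")
  step <- min(diff(spectra[[1]]$wavelength_nm))
  seq(lo, hi, by = step)
}

#' Learn the lipopigment component from senescent-cell residuals
#'
#' The fourth library component cannot be trained from a reference solution;
#' it is estimated from cells that carry it. Each senescent-cell spectrum is
#' background-corrected and unmixed against the three solution-trained
#' components; the unexplained per-wavelength residuals are averaged, floored
#' at zero and smoothed into an initial shape estimate. A few alternating
#' refinement passes then re-unmix every spectrum against the three known
#' components plus the current estimate and re-solve the shape from the
#' coefficient-weighted residuals, which removes the bias the three-component
#' projection leaves in the one-shot residual. The final shape is fitted by
#' at most `max_gaussians` Gaussian terms and unit-peak normalized.
#'
#' @param senescent_spectra list of at least 5 cell [spectrum] objects from a
#'   senescent culture.
#' @param background_spectra list of background [spectrum] objects.
#' @param library3 a [spectral_library] holding exactly the three
#'   solution-trained components.
#' @param name name of the learned component (default `"lipopigment"`).
#' @param max_gaussians maximum Gaussian terms for the final parametric fit.
#' @param refine number of alternating refinement passes (default 10).
#' @param detect_tol minimum height of the mean residual, as a fraction of the
#'   mean corrected signal peak, below which no fourth component is declared
#'   detectable.
#' @return A [spectral_component] to append to the library.
#' @export
learn_residual_component <- function(senescent_spectra, background_spectra,
                                     library3, name = "lipopigment",
                                     max_gaussians = 3L, refine = 10L,
                                     detect_tol = 0.01) {
  stopifnot(inherits(library3, "spectral_library"))
  if (length(library3$components) != 3L)
    stop("library3 must hold exactly the three solution-trained components")
  if (length(senescent_spectra) < 5L)
    stop("at least 5 senescent spectra are required to learn a residual component")
  domain <- library3$domain
  grid <- common_grid(c(senescent_spectra, background_spectra), domain)
  bg <- mean_background(background_spectra, grid)
  corrected <- vapply(senescent_spectra, function(s) {
    pmax(smooth_signal(resample_spectrum(s, grid)$intensity - bg), 0)
  }, numeric(length(grid)))
  corrected <- as.matrix(corrected)
  S3mat <- library_matrix(library3, grid)

  coefs3 <- apply(corrected, 2L, function(y) nnls_solve(S3mat, y)$x)
  resid <- corrected - S3mat %*% coefs3
  shape <- pmax(smooth_signal(rowMeans(resid)), 0)
  signal_peak <- max(rowMeans(corrected))
  if (max(shape) <= detect_tol * signal_peak)
    stop("no residual component detectable: three components already explain ",
         "the senescent spectra")
  shape <- shape / max(shape)

  # Alternating refinement. The residual shape is only identified up to an
  # admixture of the known components (any s - S3*gamma with compensating
  # coefficient shifts fits equally well), so each pass (i) re-unmixes all
  # spectra against the three known shapes plus the current estimate,
  # (ii) re-solves the shape per wavelength by least squares given the
  # coefficients, and (iii) resolves the admixture by requiring the learned
  # component's abundance to be uncorrelated, across training cells, with
  # the apparent abundances of the known fluorophores: absorbed flank
  # signal manifests as exactly such a correlation. This needs genuine
  # cell-to-cell variation in lipopigment content, which senescent cultures
  # provide (lipofuscin accumulation is highly heterogeneous).
  for (it in seq_len(refine)) {
    A <- cbind(S3mat, shape)
    cf <- apply(corrected, 2L, function(y) nnls_solve(A, y)$x)
    w <- cf[4L, ]
    if (sum(w^2) == 0)
      stop("no residual component detectable: refinement assigned it zero weight")
    part3 <- S3mat %*% cf[seq_len(3L), , drop = FALSE]
    shape_raw <- as.numeric((corrected - part3) %*% w) / sum(w^2)
    if (stats::var(w) > 0) {
      gamma <- vapply(seq_len(3L), function(k)
        stats::cov(cf[k, ], w) / stats::var(w), 0)
      shape_raw <- shape_raw + as.numeric(S3mat %*% gamma)
    }
    shape <- pmax(shape_raw, 0)
    shape <- shape / max(shape)
  }

  fit <- fit_gaussian_sum(grid, shape, max_terms = max_gaussians)
  spectral_component(
    name, fit$gaussians, domain = domain,
    provenance = sprintf(
      "learn_residual_component: %d senescent spectra, %d refinement pass(es), R2=%.6f",
      ncol(corrected), refine, fit$r_squared))
}

#' Append a component to a library
#'
#' @param library a [spectral_library].
#' @param component a [spectral_component] whose name is not yet present.
#' @return The extended [spectral_library].
#' @export
add_component <- function(library, component) {
  stopifnot(inherits(library, "spectral_library"),
            inherits(component, "spectral_component"))
  spectral_library(c(unname(library$components), list(component)),
                   domain = library$domain, provenance = library$provenance)
}
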