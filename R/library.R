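#' Spectral components and component libraries
#'
#' A spectral component is the unit emission shape of one endogenous
#' fluorophore, parameterised as a sum of Gaussians in wavelength and
#' normalized to unit peak over the library domain. A spectral library is an
#' ordered set of uniquely named components over a common wavelength domain;
#' it is what gets trained from reference solutions, extended with the
#' lipopigment residual component, persisted to a library file, and applied
#' during unmixing.
#'
#' @param name component name, e.g. `"NADH_free"`, `"NADH_bound"`, `"FAD"`,
#'   `"lipopigment"`.
#' @param gaussians data frame (or coercible) with columns `center_nm`,
#'   `width_nm` (Gaussian sd, nm, > 0) and `amplitude` (>= 0).
#' @param domain numeric length-2, wavelength domain in nm over which the
#'   unit-peak normalization is taken. Default `c(400, 850)`.
#' @param provenance free-text description of where the shape came from.
#' @param normalize if `TRUE` (default) rescale amplitudes so the evaluated
#'   maximum over the domain equals 1.
#' @return `spectral_component()` returns a `"spectral_component"`;
#'   `spectral_library()` a `"spectral_library"`.
#' @examples
#' fad <- spectral_component("FAD", data.frame(center_nm = 525,
#'                                             width_nm = 40, amplitude = 1))
#' max(predict(fad, 400:850))
#' @export
spectral_component <- function(name, gaussians, domain = c(400, 850),
                               provenance = "", normalize = TRUE) {
  gaussians <- as.data.frame(gaussians)
  need <- c("center_nm", "width_nm", "amplitude")
  if (!all(need %in% names(gaussians)))
    stop("gaussians needs columns center_nm, width_nm, amplitude")
  gaussians <- gaussians[, need, drop = FALSE]
  if (nrow(gaussians) < 1L) stop("at least one Gaussian term required")
  if (any(gaussians$width_nm <= 0)) stop("Gaussian widths must be > 0")
  if (any(gaussians$amplitude < 0)) stop("Gaussian amplitudes must be >= 0")
  obj <- structure(list(name = as.character(name), gaussians = gaussians,
                        domain = as.numeric(domain), provenance = provenance),
                   class = "spectral_component")
  if (normalize) {
    grid <- seq(domain[1], domain[2], by = 1)
    peak <- max(eval_gaussians(gaussians, grid))
    if (peak <= 0) stop("component evaluates to zero everywhere on the domain")
    obj$gaussians$amplitude <- obj$gaussians$amplitude / peak
  }
  obj
}

eval_gaussians <- function(gaussians, wavelength_nm) {
  y <- numeric(length(wavelength_nm))
  for (i in seq_len(nrow(gaussians))) {
    y <- y + gaussians$amplitude[i] *
      exp(-(wavelength_nm - gaussians$center_nm[i])^2 /
            (2 * gaussians$width_nm[i]^2))
  }
  y
}

#' Evaluate a spectral component on a wavelength grid
#'
#' @param object a `spectral_component`.
#' @param wavelength_nm numeric grid in nm.
#' @param ... ignored.
#' @return Numeric vector of unit-peak intensities.
#' @export
predict.spectral_component <- function(object, wavelength_nm, ...) {
  eval_gaussians(object$gaussians, wavelength_nm)
}

#' @export
print.spectral_component <- function(x, ...) {
  cat(sprintf("<spectral component '%s': %d Gaussian term(s), peak %d nm>\n",
              x$name, nrow(x$gaussians), component_peak_nm(x)))
  invisible(x)
}

# wavelength (1 nm grid) where the unit-normalized shape peaks
component_peak_nm <- function(comp) {
  grid <- seq(comp$domain[1], comp$domain[2], by = 1)
  grid[which.max(eval_gaussians(comp$gaussians, grid))]
}

#' @rdname spectral_component
#' @param components list of `spectral_component` objects with unique names.
#' @export
spectral_library <- function(components, domain = c(400, 850),
                             provenance = "") {
  if (!length(components)) stop("library needs at least one component")
  stopifnot(all(vapply(components, inherits, TRUE, "spectral_component")))
  nms <- vapply(components, function(x) x$name, "")
  if (anyDuplicated(nms)) stop("component names must be unique")
  names(components) <- nms
  structure(list(components = components, domain = as.numeric(domain),
                 provenance = provenance,
                 created = format(Sys.time(), tz = "UTC"),
                 version = LIBRARY_FORMAT_VERSION),
            class = "spectral_library")
}

LIBRARY_FORMAT_VERSION <- "1.0"

#' @export
print.spectral_library <- function(x, ...) {
  cat(sprintf("<spectral library: %d components over [%g, %g] nm>\n",
              length(x$components), x$domain[1], x$domain[2]))
  for (comp in x$components)
    cat(sprintf("  %-12s %d Gaussian(s), peak %d nm\n", comp$name,
                nrow(comp$gaussians), component_peak_nm(comp)))
  invisible(x)
}

#' @export
plot.spectral_library <- function(x, wavelength_nm = NULL, ...) {
  if (is.null(wavelength_nm))
    wavelength_nm <- seq(x$domain[1], x$domain[2], by = 1)
  mat <- library_matrix(x, wavelength_nm)
  graphics::matplot(wavelength_nm, mat, type = "l", lty = 1,
                    xlab = "wavelength (nm)", ylab = "unit emission", ...)
  graphics::legend("topright", legend = colnames(mat), lty = 1,
                   col = seq_len(ncol(mat)), bty = "n")
  invisible(x)
}

# components evaluated column-wise on a grid
library_matrix <- function(library, wavelength_nm) {
  mat <- vapply(library$components,
                function(comp) eval_gaussians(comp$gaussians, wavelength_nm),
                numeric(length(wavelength_nm)))
  colnames(mat) <- names(library$components)
  mat
}

#' The built-in ground-truth fluorophore library
#'
#' Four unit-peak components on the 400-850 nm domain, used as the simulation
#' ground truth and as a sensible default for worked examples: free NADH
#' (broad, peaking near 470 nm), protein-bound NADH (blue-shifted to
#' ~430 nm and narrowed by binding), FAD (peak 525 nm), and a broad
#' two-Gaussian lipopigment band spanning roughly 450-700 nm with a red
#' tail. NADH centers are literature-typical emission maxima; FAD and the
#' lipopigment band limits follow the senescence autofluorescence
#' literature.
#'
#' @return A [spectral_library] with components `NADH_free`, `NADH_bound`,
#'   `FAD`, `lipopigment` in that order.
#' @examples
#' lib <- default_library()
#' names(lib$components)
#' @export
default_library <- function() {
  g <- function(...) data.frame(...)
  spectral_library(list(
    spectral_component("NADH_free",
      g(center_nm = 468, width_nm = 65, amplitude = 1),
      provenance = "simulation ground truth (free NADH: broad emission near 470 nm)"),
    spectral_component("NADH_bound",
      g(center_nm = 432, width_nm = 36, amplitude = 1),
      provenance = "simulation ground truth (bound NADH: blue-shifted, narrowed by protein binding)"),
    spectral_component("FAD",
      g(center_nm = 525, width_nm = 40, amplitude = 1),
      provenance = "simulation ground truth (FAD emission maximum 525 nm)"),
    spectral_component("lipopigment",
      g(center_nm = c(560, 640), width_nm = c(60, 70), amplitude = c(1, 0.5)),
      provenance = "simulation ground truth (broad lipofuscin-like band spanning 450-700 nm with red tail)")
  ), provenance = "built-in synthetic ground truth library")
}

#' Persist a spectral library to a versioned JSON file
#'
#' The library file holds the format version, the domain, and for each
#' component its name, Gaussian terms and provenance. Numbers are written at
#' full precision so a save/load round trip reproduces every parameter
#' exactly. `load_library()` validates the schema: a missing or unknown
#' version, duplicate component names, non-positive widths or negative
#' amplitudes are load errors.
#'
#' @param library a [spectral_library].
#' @param path JSON file path.
#' @return `save_library()` returns `path` invisibly; `load_library()` the
#'   reconstructed [spectral_library].
#' @export
save_library <- function(library, path) {
  stopifnot(inherits(library, "spectral_library"))
  doc <- list(
    version = library$version,
    domain = library$domain,
    created = library$created,
    provenance = library$provenance,
    components = unname(lapply(library$components, function(comp) list(
      name = comp$name,
      gaussians = as.list(comp$gaussians),
      provenance = comp$provenance
    )))
  )
  # I(17): 17 significant digits, so doubles survive the round trip exactly
  jsonlite::write_json(doc, path, auto_unbox = TRUE, digits = I(17),
                       pretty = TRUE)
  invisible(path)
}

#' @rdname save_library
#' @export
load_library <- function(path) {
  doc <- jsonlite::read_json(path)
  if (is.null(doc$version) || !identical(doc$version, LIBRARY_FORMAT_VERSION))
    stop(sprintf("unsupported library file version '%s' (expected '%s')",
                 if (is.null(doc$version)) "none" else doc$version,
                 LIBRARY_FORMAT_VERSION))
  if (is.null(doc$components) || !length(doc$components))
    stop("library file has no components")
  comps <- lapply(doc$components, function(c0) {
    if (is.null(c0$name) || is.null(c0$gaussians))
      stop("library file invalid: component without name or gaussians")
    g <- as.data.frame(lapply(c0$gaussians, function(col)
      as.numeric(unlist(col))))
    spectral_component(c0$name, g, domain = as.numeric(unlist(doc$domain)),
                       provenance = if (is.null(c0$provenance)) "" else c0$provenance,
                       normalize = FALSE)
  })
  nms <- vapply(comps, function(x) x$name, "")
  if (anyDuplicated(nms))
    stop("library file invalid: duplicate component names")
  lib <- spectral_library(comps, domain = as.numeric(unlist(doc$domain)),
                          provenance = if (is.null(doc$provenance)) "" else doc$provenance)
  lib$created <- doc$created
  lib
}
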