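#' Construct an emission spectrum
#'
#' A spectrum is one emission measurement: a strictly increasing wavelength
#' grid (nm) with matching intensities (arbitrary units) and a small metadata
#' record saying what was measured (a cell, a background of imaging solution,
#' or a reference solution used for library training).
#'
#' @param wavelength_nm numeric vector of wavelengths in nm, strictly
#'   increasing, length >= 2.
#' @param intensity numeric vector of intensities (a.u.), same length, finite.
#' @param role one of `"cell"`, `"background"`, `"reference"`.
#' @param sample_id,donor,passage optional identifiers; `passage` is `"E"`
#'   (early), `"S"` (senescent) or `NA`.
#' @param meta optional named list of further metadata entries.
#' @return An object of class `"spectrum"`.
#' @examples
#' sp <- spectrum(400:850, rep(1, 451), role = "background")
#' range(sp$wavelength_nm)
#' @export
spectrum <- function(wavelength_nm, intensity, role = "cell",
                     sample_id = NA_character_, donor = NA_character_,
                     passage = NA_character_, meta = list()) {
  wavelength_nm <- as.numeric(wavelength_nm)
  intensity <- as.numeric(intensity)
  if (length(wavelength_nm) < 2L)
    stop("a spectrum needs at least two wavelength points")
  if (length(wavelength_nm) != length(intensity))
    stop("wavelength and intensity vectors differ in length")
  if (any(diff(wavelength_nm) <= 0))
    stop("wavelengths must be strictly increasing")
  if (!all(is.finite(intensity)))
    stop("intensities must be finite")
  role <- match.arg(role, c("cell", "background", "reference"))
  if (!is.na(passage)) passage <- match.arg(passage, c("E", "S"))
  obj <- list(
    wavelength_nm = wavelength_nm,
    intensity = intensity,
    meta = c(list(sample_id = sample_id, donor = donor, passage = passage,
                  role = role), meta)
  )
  class(obj) <- "spectrum"
  obj
}

#' @export
print.spectrum <- function(x, ...) {
  cat(sprintf("<spectrum: %d points, %.0f-%.0f nm, role=%s%s>\n",
              length(x$wavelength_nm), min(x$wavelength_nm),
              max(x$wavelength_nm), x$meta$role,
              if (!is.na(x$meta$passage)) paste0(", passage=", x$meta$passage)
              else ""))
  invisible(x)
}

#' @export
plot.spectrum <- function(x, ...) {
  graphics::plot(x$wavelength_nm, x$intensity, type = "l",
                 xlab = "wavelength (nm)", ylab = "intensity (a.u.)", ...)
  invisible(x)
}

# trapezoidal integral over an ordered grid
trapz <- function(x, y) {
  n <- length(x)
  sum(diff(x) * (y[-1L] + y[-n]) / 2)
}

# cosine similarity of two equal-length vectors
cosine_similarity <- function(a, b) {
  na <- sqrt(sum(a^2)); nb <- sqrt(sum(b^2))
  if (na == 0 || nb == 0) return(NA_real_)
  sum(a * b) / (na * nb)
}

#' Resample a spectrum onto a new wavelength grid
#'
#' Linear interpolation; extrapolation outside the measured range is refused
#' because emission outside the recorded window is unknown, not zero.
#'
#' @param x a [spectrum].
#' @param wavelength_nm target grid (strictly increasing).
#' @return A resampled [spectrum] with the same metadata.
#' @export
resample_spectrum <- function(x, wavelength_nm) {
  stopifnot(inherits(x, "spectrum"))
  if (min(wavelength_nm) < min(x$wavelength_nm) - 1e-9 ||
      max(wavelength_nm) > max(x$wavelength_nm) + 1e-9)
    stop("target grid extends beyond the measured range; refusing to extrapolate")
  yi <- stats::approx(x$wavelength_nm, x$intensity, xout = wavelength_nm,
                      rule = 1)$y
  out <- x
  out$wavelength_nm <- as.numeric(wavelength_nm)
  out$intensity <- yi
  out
}

#' Read / write the spectra CSV dialect
#'
#' One file per measurement: optional leading `# key=value` comment lines for
#' metadata, then a `wavelength_nm,intensity` header and one row per grid
#' point.
#'
#' @param path file path.
#' @return `read_spectrum_csv()` returns a [spectrum];
#'   `write_spectrum_csv()` returns `path` invisibly.
#' @examples
#' f <- tempfile(fileext = ".csv")
#' write_spectrum_csv(spectrum(1:5, c(0, 1, 3, 1, 0)), f)
#' read_spectrum_csv(f)
#' @export
read_spectrum_csv <- function(path) {
  lines <- readLines(path)
  hdr <- grep("^#", lines)
  meta <- list()
  for (ln in lines[hdr]) {
    kv <- sub("^#\\s*", "", ln)
    eq <- regexpr("=", kv, fixed = TRUE)
    if (eq > 0)
      meta[[substr(kv, 1, eq - 1)]] <- substr(kv, eq + 1, nchar(kv))
  }
  body <- if (length(hdr)) lines[-hdr] else lines
  df <- utils::read.csv(text = paste(body, collapse = "\n"))
  if (!all(c("wavelength_nm", "intensity") %in% names(df)))
    stop("spectra CSV must have columns wavelength_nm,intensity")
  grab <- function(key, default) if (!is.null(meta[[key]])) meta[[key]] else default
  pass <- grab("passage", NA_character_)
  if (!is.na(pass) && pass == "n/a") pass <- NA_character_
  spectrum(df$wavelength_nm, df$intensity,
           role = grab("role", "cell"),
           sample_id = grab("sample_id", NA_character_),
           donor = grab("donor", NA_character_),
           passage = pass)
}

#' @rdname read_spectrum_csv
#' @param x a [spectrum] to write.
#' @export
write_spectrum_csv <- function(x, path) {
  stopifnot(inherits(x, "spectrum"))
  m <- x$meta
  hdr <- character(0)
  for (key in c("sample_id", "donor", "passage", "role")) {
    val <- m[[key]]
    if (!is.null(val) && !is.na(val)) hdr <- c(hdr, sprintf("# %s=%s", key, val))
  }
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(hdr, con)
  writeLines("wavelength_nm,intensity", con)
  # %.17g so the doubles survive the text round trip exactly
  writeLines(sprintf("%.17g,%.17g", x$wavelength_nm, x$intensity), con)
  invisible(path)
}
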