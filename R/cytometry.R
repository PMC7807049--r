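#' Flow-cytometry samples
#'
#' A flow sample is an event-level table with forward scatter (FSC, a
#' cell-size proxy) and FL1 (the channel carrying C12FDG fluorescence, the
#' fluorogenic readout of senescence-associated beta-galactosidase activity),
#' plus sample metadata and a record of any gate applied.
#'
#' @param fsc,fl1 numeric event vectors, finite and >= 0, equal length >= 1.
#' @param donor,passage,stain metadata; `stain` is `"C12FDG"` or
#'   `"unstained"`.
#' @param label optional per-event truth labels (used by the simulator).
#' @return An object of class `"flow_sample"`.
#' @export
flow_sample <- function(fsc, fl1, donor = NA_character_,
                        passage = NA_character_, stain = "C12FDG",
                        label = NULL) {
  fsc <- as.numeric(fsc); fl1 <- as.numeric(fl1)
  if (!length(fsc) || length(fsc) != length(fl1))
    stop("FSC and FL1 must be equal-length, non-empty event vectors")
  if (!all(is.finite(fsc)) || !all(is.finite(fl1)) ||
      any(fsc < 0) || any(fl1 < 0))
    stop("channel values must be finite and non-negative")
  stain <- match.arg(stain, c("C12FDG", "unstained"))
  if (!is.na(passage)) passage <- match.arg(passage, c("E", "S"))
  events <- data.frame(FSC = fsc, FL1 = fl1)
  if (!is.null(label)) events$label <- label
  structure(list(events = events,
                 meta = list(donor = donor, passage = passage, stain = stain),
                 gate = NULL),
            class = "flow_sample")
}

#' @export
print.flow_sample <- function(x, ...) {
  cat(sprintf("<flow sample: %d events, stain=%s%s%s>\n", nrow(x$events),
              x$meta$stain,
              if (!is.na(x$meta$passage)) paste0(", passage=", x$meta$passage) else "",
              if (!is.null(x$gate)) paste0(", gate: ", x$gate) else ""))
  invisible(x)
}

#' Exclude debris by a forward-scatter threshold gate
#'
#' Debris (cell fragments, precipitates) sits at low forward scatter; the
#' standard exclusion gate keeps events with FSC at or above a threshold.
#' The input sample is not modified; the returned copy records the gate in
#' its metadata. Gating is idempotent.
#'
#' @param sample a [flow_sample].
#' @param fsc_min threshold (a.u., >= 0); events with `FSC >= fsc_min` are
#'   kept.
#' @return The gated [flow_sample].
#' @examples
#' s <- flow_sample(c(10, 1000, 2000), c(1, 2, 3))
#' gate_debris(s, 500)
#' @export
gate_debris <- function(sample, fsc_min) {
  stopifnot(inherits(sample, "flow_sample"), fsc_min >= 0)
  keep <- sample$events$FSC >= fsc_min
  if (!any(keep)) stop("empty gate: no events with FSC >= ", fsc_min)
  out <- sample
  out$events <- sample$events[keep, , drop = FALSE]
  rownames(out$events) <- NULL
  out$gate <- sprintf("FSC >= %g", fsc_min)
  out
}

#' Channel summary of a flow sample
#'
#' Arithmetic mean (on the linear scale, matching how channel means are
#' reported), sample standard deviation and event count of one channel.
#'
#' @param sample a [flow_sample], normally after [gate_debris()].
#' @param channel `"FSC"` or `"FL1"`.
#' @return A list with `mean`, `sd`, `n`.
#' @export
channel_mean <- function(sample, channel = c("FSC", "FL1")) {
  stopifnot(inherits(sample, "flow_sample"))
  channel <- match.arg(channel)
  v <- sample$events[[channel]]
  if (!length(v)) stop("empty sample")
  list(mean = mean(v), sd = if (length(v) > 1L) stats::sd(v) else 0,
       n = length(v))
}

#' Read / write the flow-events CSV dialect
#'
#' One event per row under an `FSC,FL1` header. Exported instrument tables
#' with `FSC-A` / `FL1-A` area-channel names are remapped automatically; any
#' other naming can be supplied through `channel_map`.
#'
#' @param path file path.
#' @param channel_map named character vector mapping the canonical names
#'   (`FSC`, `FL1`) to column names in the file.
#' @param donor,passage,stain metadata for the constructed sample.
#' @return `read_flow_csv()` returns a [flow_sample]; `write_flow_csv()`
#'   returns `path` invisibly.
#' @export
read_flow_csv <- function(path, channel_map = NULL, donor = NA_character_,
                          passage = NA_character_, stain = "C12FDG") {
  df <- utils::read.csv(path, check.names = FALSE)
  find <- function(canonical) {
    cands <- c(channel_map[[canonical]], canonical,
               paste0(canonical, "-A"))
    hit <- cands[cands %in% names(df)]
    if (!length(hit))
      stop(sprintf("channel '%s' not found; available columns: %s",
                   canonical, paste(names(df), collapse = ", ")))
    hit[[1L]]
  }
  flow_sample(df[[find("FSC")]], df[[find("FL1")]],
              donor = donor, passage = passage, stain = stain,
              label = if ("label" %in% names(df)) df$label else NULL)
}

#' @rdname read_flow_csv
#' @param sample a [flow_sample] to write.
#' @export
write_flow_csv <- function(sample, path) {
  stopifnot(inherits(sample, "flow_sample"))
  ev <- sample$events
  has_label <- "label" %in% names(ev)
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(if (has_label) "FSC,FL1,label" else "FSC,FL1", con)
  body <- sprintf("%.17g,%.17g", ev$FSC, ev$FL1)  # exact double round trip
  if (has_label) body <- paste(body, ev$label, sep = ",")
  writeLines(body, con)
  invisible(path)
}
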