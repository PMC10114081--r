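# A Spectrum is a count or probability vector over one canonical channel
# axis, tagged with a sample identity and a kind.

#' Construct a spectrum
#'
#' @param axis_kind `"SBS96"`, `"DBS78"` or `"ID83"`.
#' @param counts numeric vector of length equal to the axis size; may be
#'   named by channel (order is then canonicalized) or unnamed in canonical
#'   order.
#' @param sample_id sample identifier.
#' @param kind one of `"raw_counts"`, `"control_subtracted"`, `"mean"`,
#'   `"probability"`.
#' @return object of class `spectrum`.
#' @export
spectrum <- function(axis_kind, counts, sample_id = "sample",
                     kind = c("raw_counts", "control_subtracted", "mean",
                              "probability")) {
  kind <- match.arg(kind)
  channels <- channel_axis(axis_kind)$channels
  if (!is.null(names(counts))) {
    if (!setequal(names(counts), channels))
      stop("named counts must cover the full ", axis_kind, " axis")
    counts <- counts[channels]
  } else {
    if (length(counts) != length(channels))
      stop("counts must have length ", length(channels), " for ", axis_kind)
    names(counts) <- channels
  }
  if (any(counts < 0)) stop("counts must be non-negative")
  if (kind == "raw_counts" && any(counts != round(counts)))
    stop("raw counts must be integers")
  structure(list(axis_kind = axis_kind, counts = counts,
                 sample_id = sample_id, kind = kind,
                 all_zero = sum(counts) == 0),
            class = "spectrum")
}

#' @export
print.spectrum <- function(x, ...) {
  cat("<spectrum>", x$axis_kind, x$kind, "for", x$sample_id,
      "- total", format(sum(x$counts)), "\n")
  top <- sort(x$counts, decreasing = TRUE)[1:3]
  cat("  top channels:",
      paste(names(top), format(unname(top), digits = 3), collapse = ", "), "\n")
  invisible(x)
}

stopifnot_same_axis <- function(a, b) {
  if (a$axis_kind != b$axis_kind)
    stop("axis mismatch: ", a$axis_kind, " vs ", b$axis_kind)
}

#' Count a spectrum from classified mutations
#'
#' @param classified a classified frame (from [classify_sbs()],
#'   [classify_dbs()] or [classify_indel()]); all rows must be classified on
#'   the given axis.
#' @param axis_kind the channel axis.
#' @param sample_id sample identifier for the spectrum.
#' @return a [spectrum()] of kind `raw_counts`; counts sum to `nrow(classified)`.
#' @export
count_spectrum <- function(classified, axis_kind, sample_id = "sample") {
  channels <- channel_axis(axis_kind)$channels
  if (nrow(classified) > 0) {
    if (!all(classified$axis == axis_kind))
      stop("classified mutations are not on axis ", axis_kind)
    if (!all(classified$status == "classified"))
      stop("count_spectrum expects classified mutations only")
  }
  counts <- table(factor(classified$channel, levels = channels))
  spectrum(axis_kind, as.numeric(counts), sample_id, "raw_counts")
}

#' Mean spectrum over replicates, with per-channel SD
#'
#' Elementwise mean and sample standard deviation (n - 1 denominator;
#' SD = 0 when n = 1) over biological replicates.
#'
#' @param spectra non-empty list of [spectrum()] objects on one axis.
#' @param sample_id identifier for the aggregated spectrum.
#' @return a [spectrum()] of kind `mean` with an extra element `sd`
#'   (named numeric vector).
#' @export
mean_spectrum <- function(spectra, sample_id = "mean") {
  if (length(spectra) == 0) stop("mean_spectrum needs >= 1 spectrum")
  ax <- spectra[[1]]$axis_kind
  for (s in spectra) stopifnot_same_axis(spectra[[1]], s)
  m <- vapply(spectra, function(s) s$counts, numeric(length(spectra[[1]]$counts)))
  mu <- rowMeans(m)
  sdv <- if (length(spectra) == 1) rep(0, nrow(m)) else apply(m, 1, stats::sd)
  out <- spectrum(ax, mu, sample_id, "mean")
  out$sd <- stats::setNames(sdv, names(out$counts))
  out
}

#' Subtract a control spectrum from a treatment spectrum
#'
#' Channel-wise `max(0, treatment - control)`: endogenous background
#' mutations measured in vehicle-control clones are removed from the
#' treatment spectrum. Negative differences clamp to zero (counts cannot be
#' negative); the number of clamped channels is recorded — heavy clamping
#' signals a treatment with no excess burden over background.
#'
#' @param treatment treatment [spectrum()].
#' @param control_mean control [spectrum()] (typically a mean over control
#'   clones), same axis.
#' @return a [spectrum()] of kind `control_subtracted` with element
#'   `clamped` (integer count of clamped channels).
#' @export
subtract_control <- function(treatment, control_mean) {
  stopifnot_same_axis(treatment, control_mean)
  diff <- treatment$counts - control_mean$counts
  clamped <- sum(diff < 0)
  diff[diff < 0] <- 0
  out <- spectrum(treatment$axis_kind, diff, treatment$sample_id,
                  "control_subtracted")
  out$clamped <- as.integer(clamped)
  out
}

#' Total mutation burden of a spectrum
#'
#' @param spec a [spectrum()].
#' @return sum of channel counts.
#' @export
total_burden <- function(spec) sum(spec$counts)

#' Normalize a spectrum to channel probabilities
#'
#' Divides by the total so channels sum to 1. An all-zero spectrum stays
#' all-zero with `all_zero = TRUE` (flagged, never NaN).
#'
#' @param spec a [spectrum()].
#' @return a [spectrum()] of kind `probability`.
#' @export
to_probability <- function(spec) {
  tot <- sum(spec$counts)
  if (tot == 0) {
    out <- spectrum(spec$axis_kind, spec$counts, spec$sample_id, "probability")
    out$all_zero <- TRUE
    return(out)
  }
  spectrum(spec$axis_kind, spec$counts / tot, spec$sample_id, "probability")
}

#' Per-compound signature from clone spectra
#'
#' The composition used for per-compound signatures: subtract the control
#' mean from each treatment clone's raw spectrum, average the subtracted
#' spectra over clones, and normalize to probabilities. The alternative
#' order (`"aggregate"`: average first, subtract once) is available; with
#' zero-clamping the two differ, and per-clone subtraction is the default.
#'
#' @param clone_spectra list of per-clone raw [spectrum()]s for one
#'   treatment.
#' @param control_mean control mean [spectrum()], same axis.
#' @param sample_id identifier for the signature.
#' @param order `"per-clone"` (default) or `"aggregate"`.
#' @return a probability [spectrum()]; attribute `burden` holds the mean
#'   control-subtracted total burden.
#' @export
compound_signature <- function(clone_spectra, control_mean,
                               sample_id = "signature",
                               order = c("per-clone", "aggregate")) {
  order <- match.arg(order)
  if (order == "per-clone") {
    subtracted <- lapply(clone_spectra, subtract_control, control_mean)
    m <- mean_spectrum(subtracted, sample_id)
  } else {
    m <- subtract_control(mean_spectrum(clone_spectra, sample_id), control_mean)
  }
  out <- to_probability(m)
  attr(out, "burden") <- sum(m$counts)
  attr(out, "burden_sd") <- if (!is.null(m$sd)) {
    bs <- vapply(clone_spectra, function(s)
      total_burden(subtract_control(s, control_mean)), numeric(1))
    if (length(bs) > 1) stats::sd(bs) else 0
  } else 0
  out
}

#' Assemble spectra into a channels-by-samples matrix
#'
#' @param spectra list of [spectrum()]s on one axis.
#' @return numeric matrix, rows = channels (canonical order), columns =
#'   sample ids.
#' @export
spectra_matrix <- function(spectra) {
  if (length(spectra) == 0) stop("no spectra")
  for (s in spectra) stopifnot_same_axis(spectra[[1]], s)
  m <- vapply(spectra, function(s) s$counts,
              numeric(length(spectra[[1]]$counts)))
  m <- matrix(m, ncol = length(spectra),
              dimnames = list(names(spectra[[1]]$counts),
                              vapply(spectra, function(s) s$sample_id,
                                     character(1))))
  m
}
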