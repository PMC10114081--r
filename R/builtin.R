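# Built-in SYNTHETIC signature shapes. These are illustrative fixtures for
# simulation and demos: qualitatively shaped like published descriptions of
# the compound spectra (BaP-like: C>A and C>T rich; MNNG-like: T>C preceded
# by a purine; NNK-acetate-like: balanced C>T/T>A/T>C/T>G with 5' A
# preference; norharmane-like: close to BaP-like but not identical), not
# values read off any real catalog.

sbs_shape <- function(class_weights, f5 = NULL, f3 = NULL) {
  channels <- sbs96_channel_names()
  sub <- substr(channels, 3, 5)
  p5 <- substr(channels, 1, 1)
  p3 <- substr(channels, 7, 7)
  flat <- stats::setNames(rep(0.25, 4), BASES)
  w <- unname(class_weights[sub])
  for (s in names(class_weights)) {
    i <- sub == s
    a5 <- if (!is.null(f5[[s]])) f5[[s]] else flat
    a3 <- if (!is.null(f3[[s]])) f3[[s]] else flat
    w[i] <- w[i] * unname(a5[p5[i]]) * unname(a3[p3[i]])
  }
  stats::setNames(w / sum(w), channels)
}

b4 <- function(a, c, g, t) stats::setNames(c(a, c, g, t), BASES)

.builtin_sbs <- function() {
  list(
    flat = stats::setNames(rep(1 / 96, 96), sbs96_channel_names()),
    oxidative_like = sbs_shape(
      c("C>A" = 0.60, "C>G" = 0.05, "C>T" = 0.20,
        "T>A" = 0.05, "T>C" = 0.05, "T>G" = 0.05)),
    bap_like = sbs_shape(
      c("C>A" = 0.50, "C>G" = 0.06, "C>T" = 0.30,
        "T>A" = 0.05, "T>C" = 0.05, "T>G" = 0.04),
      f5 = list("C>A" = b4(0.20, 0.35, 0.25, 0.20)),
      f3 = list("C>A" = b4(0.30, 0.30, 0.15, 0.25))),
    norharmane_like = sbs_shape(
      c("C>A" = 0.40, "C>G" = 0.06, "C>T" = 0.34,
        "T>A" = 0.07, "T>C" = 0.08, "T>G" = 0.05),
      f5 = list("C>A" = b4(0.30, 0.20, 0.20, 0.30),
                "C>T" = b4(0.20, 0.30, 0.30, 0.20))),
    mnng_like = sbs_shape(
      c("C>A" = 0.04, "C>G" = 0.03, "C>T" = 0.25,
        "T>A" = 0.05, "T>C" = 0.55, "T>G" = 0.08),
      f5 = list("T>C" = b4(0.42, 0.08, 0.42, 0.08))),
    nnk_acetate_like = sbs_shape(
      c("C>A" = 0.06, "C>G" = 0.06, "C>T" = 0.22,
        "T>A" = 0.22, "T>C" = 0.22, "T>G" = 0.22),
      f5 = list("C>T" = b4(0.55, 0.15, 0.15, 0.15),
                "T>A" = b4(0.55, 0.15, 0.15, 0.15),
                "T>C" = b4(0.55, 0.15, 0.15, 0.15),
                "T>G" = b4(0.55, 0.15, 0.15, 0.15)))
  )
}

.builtin_dbs <- function() {
  channels <- dbs78_channel_names()
  flat <- stats::setNames(rep(1 / 78, 78), channels)
  bap <- stats::setNames(rep(0, 78), channels)
  bap["CC>AA"] <- 0.65
  bap["CC>TA"] <- 0.30
  bap["CC>TT"] <- 0.05
  list(flat = flat, bap_dbs_like = bap)
}

.builtin_id <- function() {
  channels <- id83_channel_names()
  flat <- stats::setNames(rep(1 / 83, 83), channels)
  hp <- c(0.25, 0.30, 0.20, 0.12, 0.08, 0.05)  # weight over run-length bins
  bap <- stats::setNames(rep(0, 83), channels)
  bap[paste0("1:Del:C:", 0:5)] <- 0.45 * hp
  bap[paste0("1:Del:T:", 0:5)] <- 0.30 * hp
  bap[paste0("1:Ins:T:", 0:5)] <- 0.25 * hp
  # endogenous indels: replication slippage in homopolymers (1 bp events)
  bg <- stats::setNames(rep(0, 83), channels)
  bg[paste0("1:Del:T:", 0:5)] <- 0.40 * hp
  bg[paste0("1:Del:C:", 0:5)] <- 0.25 * hp
  bg[paste0("1:Ins:T:", 0:5)] <- 0.20 * hp
  bg[paste0("1:Ins:C:", 0:5)] <- 0.15 * hp
  list(flat = flat, bap_id_like = bap, background_id_like = bg)
}

#' Built-in synthetic signature catalog
#'
#' A small catalog of synthetic signatures shipped with the package: the
#' simulator's default compound and background shapes. They are
#' illustrative fixtures with documented qualitative structure, not
#' reference signatures from any public catalog; matching a recovered
#' signature against this catalog is how the simulator's ground truth is
#' checked end to end. The same tables are shipped as TSV under
#' `inst/extdata/signatures/` for command-line use.
#'
#' @param axis_kind `"SBS96"`, `"DBS78"` or `"ID83"`.
#' @return a [signature_catalog()].
#' @export
#' @examples
#' builtin_signatures("SBS96")
builtin_signatures <- function(axis_kind = c("SBS96", "DBS78", "ID83")) {
  axis_kind <- match.arg(axis_kind)
  sigs <- switch(axis_kind,
                 SBS96 = .builtin_sbs(),
                 DBS78 = .builtin_dbs(),
                 ID83  = .builtin_id())
  mat <- do.call(cbind, sigs)
  signature_catalog(axis_kind, mat)
}
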