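BASES <- c("A", "C", "G", "T")
PYRIMIDINES <- c("C", "T")

#' Reverse complement of DNA strings
#'
#' Vectorised reverse complement over the strict DNA alphabet; `N` is
#' preserved as `N`.
#'
#' @param x character vector of DNA strings (A/C/G/T/N).
#' @return character vector of the same length.
#' @export
#' @examples
#' revcomp(c("ACGT", "CC"))
revcomp <- function(x) {
  flipped <- chartr("ACGTN", "TGCAN", x)
  vapply(strsplit(flipped, "", fixed = TRUE),
         function(b) paste(rev(b), collapse = ""), character(1))
}

comp_base <- function(x) chartr("ACGTN", "TGCAN", x)

# ---- SBS96 ---------------------------------------------------------------

SBS_SUBSTITUTIONS <- c("C>A", "C>G", "C>T", "T>A", "T>C", "T>G")

sbs96_channel_names <- function() {
  out <- character(0)
  for (sub in SBS_SUBSTITUTIONS) {
    ref <- substr(sub, 1, 1)
    for (p5 in BASES) for (p3 in BASES) {
      out <- c(out, paste0(p5, "[", sub, "]", p3))
    }
  }
  out
}

# Lookup table keyed "<trinuc>><alt>" for all 192 strand-specific cases,
# collapsing purine-centered events onto the pyrimidine strand.
.sbs96_lookup <- local({
  tab <- NULL
  function() {
    if (is.null(tab)) {
      keys <- character(0); vals <- character(0)
      for (p5 in BASES) for (ref in BASES) for (p3 in BASES) {
        for (alt in setdiff(BASES, ref)) {
          ctx <- paste0(p5, ref, p3)
          if (ref %in% PYRIMIDINES) {
            ch <- paste0(p5, "[", ref, ">", alt, "]", p3)
          } else {
            ch <- paste0(comp_base(p3), "[", comp_base(ref), ">",
                         comp_base(alt), "]", comp_base(p5))
          }
          keys <- c(keys, paste0(ctx, ">", alt))
          vals <- c(vals, ch)
        }
      }
      tab <<- stats::setNames(vals, keys)
    }
    tab
  }
})

sbs96_channel <- function(trinuc, alt) {
  unname(.sbs96_lookup()[paste0(trinuc, ">", alt)])
}

# ---- DBS78 ---------------------------------------------------------------

# Canonical COSMIC/SigProfiler DBS78 row order. Frozen; the exhaustive
# 144-substitution enumeration test validates the reverse-complement
# involution against this list.
dbs78_channel_names <- function() {
  c(
    "AC>CA", "AC>CG", "AC>CT", "AC>GA", "AC>GG", "AC>GT", "AC>TA", "AC>TG", "AC>TT",
    "AT>CA", "AT>CC", "AT>CG", "AT>GA", "AT>GC", "AT>TA",
    "CC>AA", "CC>AG", "CC>AT", "CC>GA", "CC>GG", "CC>GT", "CC>TA", "CC>TG", "CC>TT",
    "CG>AT", "CG>GC", "CG>GT", "CG>TA", "CG>TC", "CG>TT",
    "CT>AA", "CT>AC", "CT>AG", "CT>GA", "CT>GC", "CT>GG", "CT>TA", "CT>TC", "CT>TG",
    "GC>AA", "GC>AG", "GC>AT", "GC>CA", "GC>CG", "GC>TA",
    "TA>AT", "TA>CG", "TA>CT", "TA>GC", "TA>GG", "TA>GT",
    "TC>AA", "TC>AG", "TC>AT", "TC>CA", "TC>CG", "TC>CT", "TC>GA", "TC>GG", "TC>GT",
    "TG>AA", "TG>AC", "TG>AT", "TG>CA", "TG>CC", "TG>CT", "TG>GA", "TG>GC", "TG>GT",
    "TT>AA", "TT>AC", "TT>AG", "TT>CA", "TT>CC", "TT>CG", "TT>GA", "TT>GC", "TT>GG"
  )
}

dbs78_channel <- function(ref, alt) {
  cand <- paste0(ref, ">", alt)
  canon <- dbs78_channel_names()
  rc <- paste0(revcomp(ref), ">", revcomp(alt))
  ifelse(cand %in% canon, cand,
         ifelse(rc %in% canon, rc, NA_character_))
}

# ---- ID83 ----------------------------------------------------------------

# COSMIC ID83 row order. Numeric field is 0-based for homopolymer and
# repeat bins: 1:Del:C:0 = deletion from a homopolymer of length 1,
# s:Del:R:k = k additional full copies of the deleted fragment remain.
id83_channel_names <- function() {
  out <- character(0)
  for (b in c("C", "T")) out <- c(out, paste0("1:Del:", b, ":", 0:5))
  for (b in c("C", "T")) out <- c(out, paste0("1:Ins:", b, ":", 0:5))
  for (s in 2:5) out <- c(out, paste0(s, ":Del:R:", 0:5))
  for (s in 2:5) out <- c(out, paste0(s, ":Ins:R:", 0:5))
  out <- c(out, "2:Del:M:1",
           paste0("3:Del:M:", 1:2),
           paste0("4:Del:M:", 1:3),
           paste0("5:Del:M:", 1:5))
  out
}

#' Canonical channel axes
#'
#' The three canonical COSMIC-style mutation classification axes: `SBS96`
#' (6 pyrimidine-centered substitution types in 16 trinucleotide contexts),
#' `DBS78` (reverse-complement-collapsed doublet substitutions) and `ID83`
#' (small indels binned by size, homopolymer run length, tandem-repeat copy
#' number and microhomology length). Channel names and their order are
#' frozen; they are also shipped as plain-text tables under
#' `inst/extdata/channels/`.
#'
#' @param axis_kind one of `"SBS96"`, `"DBS78"`, `"ID83"`.
#' @return object of class `channel_axis`: list with `axis_kind` and
#'   `channels` (ordered character vector of 96, 78 or 83 names).
#' @export
#' @examples
#' channel_axis("SBS96")$channels[1:4]
channel_axis <- function(axis_kind = c("SBS96", "DBS78", "ID83")) {
  axis_kind <- match.arg(axis_kind)
  channels <- switch(axis_kind,
    SBS96 = sbs96_channel_names(),
    DBS78 = dbs78_channel_names(),
    ID83  = id83_channel_names()
  )
  structure(list(axis_kind = axis_kind, channels = channels),
            class = "channel_axis")
}

axis_size <- function(axis_kind) {
  switch(axis_kind, SBS96 = 96L, DBS78 = 78L, ID83 = 83L,
         stop("unknown axis kind: ", axis_kind))
}

#' @export
print.channel_axis <- function(x, ...) {
  cat("<channel_axis>", x$axis_kind, "with", length(x$channels),
      "channels:", x$channels[1], "...",
      x$channels[length(x$channels)], "\n")
  invisible(x)
}
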