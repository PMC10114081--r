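# Coordinates are 1-based and inclusive throughout the package, matching
# VCF POS. All position arithmetic relies on this convention.

#' Construct a reference genome object
#'
#' @param seqs named character vector: contig id -> sequence over A/C/G/T/N.
#' @return object of class `ref_genome`.
#' @export
ref_genome <- function(seqs) {
  if (length(seqs) == 0) stop("genome must contain at least one contig")
  if (is.null(names(seqs)) || anyDuplicated(names(seqs)) || any(names(seqs) == ""))
    stop("contig ids must be unique and non-empty")
  seqs <- toupper(seqs)
  if (any(nchar(seqs) == 0)) stop("contig sequences must be non-empty")
  bad <- grepl("[^ACGTN]", seqs)
  if (any(bad))
    stop("contig(s) contain characters outside {A,C,G,T,N}: ",
         paste(names(seqs)[bad], collapse = ", "))
  structure(list(seqs = seqs, cache = new.env(parent = emptyenv())),
            class = "ref_genome")
}

#' @export
print.ref_genome <- function(x, ...) {
  cat("<ref_genome>", length(x$seqs), "contig(s),",
      sum(nchar(x$seqs)), "bp total\n")
  for (nm in utils::head(names(x$seqs), 10))
    cat("  ", nm, ": ", nchar(x$seqs[[nm]]), " bp\n", sep = "")
  invisible(x)
}

contig_seq <- function(genome, contig) {
  seq <- genome$seqs[contig]
  if (is.na(seq)) stop("unknown contig: ", contig)
  unname(seq)
}

contig_lengths <- function(genome) {
  stats::setNames(nchar(genome$seqs), names(genome$seqs))
}

#' Generate a random reference genome
#'
#' Bases are drawn i.i.d. with `P(G) + P(C) = gc_fraction`, split evenly
#' within the GC and AT pairs. Contig lengths partition `total_length` as
#' evenly as possible. The result is a pure function of the arguments: the
#' same seed always yields the identical genome.
#'
#' @param total_length total genome size in bp (`>= n_contigs`).
#' @param n_contigs number of contigs.
#' @param gc_fraction expected GC content, in `[0, 1]`.
#' @param seed integer seed.
#' @return a [ref_genome()] with contigs named `chr1`, `chr2`, ...
#' @export
#' @examples
#' g <- generate_reference(4000, 2, 0.5, seed = 1)
#' sum(nchar(g$seqs))
generate_reference <- function(total_length, n_contigs = 1L,
                               gc_fraction = 0.41, seed = 1L) {
  if (total_length < 1 || n_contigs < 1)
    stop("total_length and n_contigs must be positive")
  if (total_length < n_contigs)
    stop("total_length must be >= n_contigs")
  if (gc_fraction < 0 || gc_fraction > 1)
    stop("gc_fraction must be in [0, 1]")
  lens <- rep(total_length %/% n_contigs, n_contigs)
  extra <- total_length %% n_contigs
  if (extra > 0) lens[seq_len(extra)] <- lens[seq_len(extra)] + 1L
  p <- c(A = (1 - gc_fraction) / 2, C = gc_fraction / 2,
         G = gc_fraction / 2, T = (1 - gc_fraction) / 2)
  seqs <- withr::with_seed(seed, {
    vapply(lens, function(L) {
      paste(sample(names(p), L, replace = TRUE, prob = p), collapse = "")
    }, character(1))
  })
  names(seqs) <- paste0("chr", seq_len(n_contigs))
  ref_genome(seqs)
}

#' Local sequence context around a position
#'
#' Returns the `2 * flank + 1` reference bases centered on `pos`. Windows
#' that run past a contig end, or that contain `N`, are reported as
#' unavailable (`NA`) rather than guessed: downstream classification treats
#' such mutations as unclassifiable.
#'
#' @param genome a [ref_genome()].
#' @param contig contig id.
#' @param pos 1-based position within the contig.
#' @param flank number of bases on each side (`flank = 0` returns the base
#'   itself).
#' @return character scalar, or `NA_character_` when the window is
#'   unavailable.
#' @export
#' @examples
#' g <- ref_genome(c(chr1 = "ACGTA"))
#' get_context(g, "chr1", 3, 1)   # "CGT"
#' get_context(g, "chr1", 1, 1)   # NA: no 5' base
get_context <- function(genome, contig, pos, flank = 1L) {
  seq <- contig_seq(genome, contig)
  n <- nchar(seq)
  if (any(pos < 1 | pos > n)) stop("position out of range for contig ", contig)
  lo <- pos - flank
  hi <- pos + flank
  out <- substring(seq, pmax(lo, 1L), pmin(hi, n))
  out[lo < 1 | hi > n] <- NA_character_
  out[!is.na(out) & grepl("N", out, fixed = TRUE)] <- NA_character_
  out
}

genome_base <- function(genome, contig, pos) {
  substring(genome$seqs[[contig]], pos, pos)
}

#' Read / write FASTA
#'
#' Plain-text FASTA via Biostrings; sequences are uppercased on read and
#' wrapped at 70 columns on write. Duplicate contig ids are an error.
#'
#' @param path file path.
#' @return `read_fasta()` returns a [ref_genome()].
#' @export
read_fasta <- function(path) {
  ss <- Biostrings::readDNAStringSet(path)
  if (length(ss) == 0) stop("empty FASTA: ", path)
  seqs <- toupper(as.character(ss))
  names(seqs) <- sub("\\s.*$", "", names(ss))
  if (anyDuplicated(names(seqs)))
    stop("duplicate contig id in FASTA: ",
         names(seqs)[duplicated(names(seqs))][1])
  ref_genome(seqs)
}

#' @param genome a [ref_genome()].
#' @rdname read_fasta
#' @export
write_fasta <- function(genome, path) {
  ss <- Biostrings::DNAStringSet(genome$seqs)
  Biostrings::writeXStringSet(ss, path, width = 70L)
  invisible(path)
}

# ---- cached per-contig indexes for simulation ---------------------------

base_codes <- function(seq) {
  # A=0 C=1 G=2 T=3, N/other = NA
  v <- utf8ToInt(seq)
  code <- rep(NA_integer_, length(v))
  code[v == 65L] <- 0L; code[v == 67L] <- 1L
  code[v == 71L] <- 2L; code[v == 84L] <- 3L
  code
}

# positions i (2..n-1) indexed by trinucleotide code 16*b[i-1]+4*b[i]+b[i+1]
trinuc_index <- function(genome, contig) {
  key <- paste0("tri:", contig)
  idx <- genome$cache[[key]]
  if (!is.null(idx)) return(idx)
  b <- base_codes(genome$seqs[[contig]])
  n <- length(b)
  if (n < 3) {
    idx <- vector("list", 64)
  } else {
    i <- 2:(n - 1)
    code <- 16L * b[i - 1] + 4L * b[i] + b[i + 1]
    keep <- !is.na(code)
    idx <- split(i[keep], factor(code[keep], levels = 0:63))
  }
  genome$cache[[key]] <- idx
  idx
}

# positions i (1..n-1) of dinucleotide code 4*b[i]+b[i+1]
dinuc_index <- function(genome, contig) {
  key <- paste0("di:", contig)
  idx <- genome$cache[[key]]
  if (!is.null(idx)) return(idx)
  b <- base_codes(genome$seqs[[contig]])
  n <- length(b)
  i <- seq_len(n - 1)
  code <- 4L * b[i] + b[i + 1]
  keep <- !is.na(code)
  idx <- split(i[keep], factor(code[keep], levels = 0:15))
  genome$cache[[key]] <- idx
  idx
}

# homopolymer runs: data.frame(start, length, base_code)
run_index <- function(genome, contig) {
  key <- paste0("run:", contig)
  idx <- genome$cache[[key]]
  if (!is.null(idx)) return(idx)
  b <- base_codes(genome$seqs[[contig]])
  r <- rle(b)
  ends <- cumsum(r$lengths)
  idx <- data.frame(start = ends - r$lengths + 1L, length = r$lengths,
                    base = r$values)
  idx <- idx[!is.na(idx$base), , drop = FALSE]
  genome$cache[[key]] <- idx
  idx
}

invalidate_cache <- function(genome, contig) {
  for (pre in c("tri:", "di:", "run:")) {
    key <- paste0(pre, contig)
    if (!is.null(genome$cache[[key]])) rm(list = key, envir = genome$cache)
  }
  invisible(genome)
}
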