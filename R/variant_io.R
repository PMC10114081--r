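# A MutationRecord is one row of a base data.frame with columns
# contig, pos, ref, alt, clone_id (VCF anchored representation; ref != alt).
# The identity key used for all set logic is contig:pos:ref:alt.

#' Build a mutation record table
#'
#' @param contig,pos,ref,alt,clone_id vectors, recycled to a common length.
#' @return data.frame with columns `contig`, `pos`, `ref`, `alt`, `clone_id`.
#' @export
mutation_records <- function(contig = character(), pos = integer(),
                             ref = character(), alt = character(),
                             clone_id = character()) {
  df <- data.frame(contig = as.character(contig), pos = as.integer(pos),
                   ref = toupper(as.character(ref)),
                   alt = toupper(as.character(alt)),
                   clone_id = as.character(clone_id),
                   stringsAsFactors = FALSE)
  if (nrow(df) > 0) {
    if (any(df$ref == df$alt)) stop("ref must differ from alt")
    if (any(nchar(df$ref) == 0 | nchar(df$alt) == 0))
      stop("ref and alt must be non-empty")
    if (any(grepl("[^ACGT]", df$ref) | grepl("[^ACGT]", df$alt)))
      stop("ref/alt restricted to A,C,G,T")
  }
  df
}

#' Identity keys for mutation records
#'
#' @param records a mutation record data.frame.
#' @return character vector `contig:pos:ref:alt`.
#' @export
variant_key <- function(records) {
  if (nrow(records) == 0) return(character(0))
  paste(records$contig, records$pos, records$ref, records$alt, sep = ":")
}

#' Variant class of each record
#'
#' @param records mutation record data.frame.
#' @return character vector: `"SNV"`, `"MNV"` (equal lengths > 1),
#'   `"insertion"`, `"deletion"`, or `"complex"`.
#' @export
variant_class <- function(records) {
  nr <- nchar(records$ref); na <- nchar(records$alt)
  out <- rep("complex", nrow(records))
  out[nr == 1 & na == 1] <- "SNV"
  out[nr > 1 & nr == na] <- "MNV"
  ins <- nr == 1 & na > 1 &
    substr(records$alt, 1, 1) == records$ref
  del <- na == 1 & nr > 1 &
    substr(records$ref, 1, 1) == records$alt
  out[ins] <- "insertion"
  out[del] <- "deletion"
  out
}

#' Read per-clone variant calls from a VCF
#'
#' Consumes VCF v4.x via \pkg{vcfR}. Multi-allelic sites are split into one
#' record per ALT. Genotype and quality fields are ignored: a passing record
#' means the clone carries the mutation. Records with FILTER other than
#' `PASS` or `.`, symbolic/breakend alleles, or alleles outside A,C,G,T,N
#' are dropped, with reasons tallied in the `"dropped"` attribute.
#'
#' @param path VCF file path.
#' @param clone_id clone identifier stamped on every record.
#' @return mutation record data.frame; attribute `dropped` is a named
#'   integer vector of drop reasons.
#' @export
read_vcf <- function(path, clone_id) {
  v <- vcfR::read.vcfR(path, verbose = FALSE)
  fix <- vcfR::getFIX(v)
  if (is.null(dim(fix))) fix <- t(fix)   # single-record VCF drops dimensions
  fix <- as.data.frame(fix, stringsAsFactors = FALSE)
  dropped <- c(filter_failed = 0L, symbolic_allele = 0L, bad_allele = 0L)
  if (nrow(fix) == 0) {
    out <- mutation_records()
    attr(out, "dropped") <- dropped
    return(out)
  }
  filt <- fix$FILTER
  ok_filter <- is.na(filt) | filt %in% c("PASS", ".")
  dropped["filter_failed"] <- sum(!ok_filter)
  fix <- fix[ok_filter, , drop = FALSE]

  # split multi-allelic ALT
  alts <- strsplit(fix$ALT, ",", fixed = TRUE)
  n_alt <- lengths(alts)
  idx <- rep(seq_len(nrow(fix)), n_alt)
  contig <- fix$CHROM[idx]
  pos <- as.integer(fix$POS[idx])
  ref <- toupper(fix$REF[idx])
  alt <- toupper(unlist(alts, use.names = FALSE))

  sym <- grepl("<|>|\\[|\\]", alt) | alt == "*"
  dropped["symbolic_allele"] <- sum(sym)
  bad <- !sym & (grepl("[^ACGTN]", ref) | grepl("[^ACGTN]", alt) |
                   grepl("N", ref, fixed = TRUE) | grepl("N", alt, fixed = TRUE) |
                   ref == alt)
  dropped["bad_allele"] <- sum(bad)
  keep <- !sym & !bad
  out <- mutation_records(contig[keep], pos[keep], ref[keep], alt[keep],
                          rep(clone_id, sum(keep)))
  attr(out, "dropped") <- dropped
  out
}

#' Write mutation records as a minimal VCF v4.2
#'
#' Emits `##contig` headers and the fixed columns only; round-trips with
#' [read_vcf()] on the identity key. Records are sorted by contig order
#' (the order of `contig_lengths`) then position.
#'
#' @param records mutation record data.frame (single clone).
#' @param path output path.
#' @param contig_lengths named integer vector of contig lengths.
#' @export
write_vcf <- function(records, path, contig_lengths) {
  unknown <- setdiff(unique(records$contig), names(contig_lengths))
  if (length(unknown) > 0)
    stop("record(s) reference unknown contig(s): ",
         paste(unknown, collapse = ", "))
  hdr <- c("##fileformat=VCFv4.2",
           "##source=clonespect",
           paste0("##contig=<ID=", names(contig_lengths),
                  ",length=", as.integer(contig_lengths), ">"),
           paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL",
                   "FILTER", "INFO"), collapse = "\t"))
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(hdr, con)
  if (nrow(records) > 0) {
    ord <- order(match(records$contig, names(contig_lengths)), records$pos)
    r <- records[ord, , drop = FALSE]
    writeLines(paste(r$contig, r$pos, ".", r$ref, r$alt, ".", "PASS", ".",
                     sep = "\t"), con)
  }
  invisible(path)
}

#' Left-align anchored indels against the reference
#'
#' VCF does not guarantee left-alignment; the indel classification channels
#' depend on it. SNVs and non-indels pass through unchanged. For each
#' anchored insertion/deletion the allele pair is shifted to its leftmost
#' equivalent representation, then trimmed to the minimal anchored form.
#'
#' @param records mutation record data.frame.
#' @param genome a [ref_genome()].
#' @return records with normalized `pos`, `ref`, `alt`.
#' @export
left_align <- function(records, genome) {
  touch <- which(pmax(nchar(records$ref), nchar(records$alt)) > 1)
  for (i in touch) {
    contig <- records$contig[i]
    seq <- contig_seq(genome, contig)
    pos <- records$pos[i]; ref <- records$ref[i]; alt <- records$alt[i]
    # minimal representation: trim shared trailing, then shared leading bases
    while (nchar(ref) > 1 && nchar(alt) > 1 &&
           substr(ref, nchar(ref), nchar(ref)) ==
             substr(alt, nchar(alt), nchar(alt))) {
      ref <- substr(ref, 1, nchar(ref) - 1)
      alt <- substr(alt, 1, nchar(alt) - 1)
    }
    while (nchar(ref) > 1 && nchar(alt) > 1 &&
           substr(ref, 1, 1) == substr(alt, 1, 1)) {
      ref <- substr(ref, 2, nchar(ref))
      alt <- substr(alt, 2, nchar(alt))
      pos <- pos + 1L
    }
    # anchored indels: shift to the leftmost equivalent representation
    if (xor(nchar(ref) == 1, nchar(alt) == 1)) {
      while (pos > 1) {
        last_ref <- substr(ref, nchar(ref), nchar(ref))
        last_alt <- substr(alt, nchar(alt), nchar(alt))
        if (last_ref != last_alt) break
        prev <- substr(seq, pos - 1, pos - 1)
        if (!prev %in% BASES) break
        ref <- paste0(prev, substr(ref, 1, nchar(ref) - 1))
        alt <- paste0(prev, substr(alt, 1, nchar(alt) - 1))
        pos <- pos - 1L
      }
    }
    records$pos[i] <- pos; records$ref[i] <- ref; records$alt[i] <- alt
  }
  records
}

# ---- matrix / catalog TSV ------------------------------------------------

#' Write a channels-by-samples matrix as TSV
#'
#' First column `channel` holds channel names in canonical order; remaining
#' columns are samples or signatures. UTF-8, tab-delimited.
#'
#' @param mat numeric matrix with rownames = channel names.
#' @param path output path.
#' @export
write_matrix <- function(mat, path) {
  if (is.null(rownames(mat)) || is.null(colnames(mat)))
    stop("matrix must have channel rownames and sample colnames")
  if (anyDuplicated(colnames(mat)) || anyDuplicated(rownames(mat)))
    stop("duplicate row or column labels")
  df <- data.frame(channel = rownames(mat), mat, check.names = FALSE,
                   stringsAsFactors = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE,
                     fileEncoding = "UTF-8")
  invisible(path)
}

#' @rdname write_matrix
#' @param axis_kind expected channel axis; the full axis must be present and
#'   rows are reordered into canonical order.
#' @export
read_matrix <- function(path, axis_kind) {
  df <- utils::read.delim(path, check.names = FALSE, stringsAsFactors = FALSE)
  channels <- channel_axis(axis_kind)$channels
  got <- as.character(df[[1]])
  unknown <- setdiff(got, channels)
  if (length(unknown) > 0)
    stop("unknown channel name(s): ", paste(utils::head(unknown, 5), collapse = ", "))
  missing <- setdiff(channels, got)
  if (length(missing) > 0)
    stop("missing channel(s): ", paste(utils::head(missing, 5), collapse = ", "))
  mat <- as.matrix(df[, -1, drop = FALSE])
  rownames(mat) <- got
  storage.mode(mat) <- "double"
  mat[channels, , drop = FALSE]
}

#' Read a COSMIC-format signature catalog
#'
#' First column channel names, one signature per remaining column. Channels
#' are reordered into canonical order; each column must sum to 1 within
#' 1e-3 and is renormalized to sum exactly 1.
#'
#' @param path TSV path.
#' @param axis_kind channel axis of the catalog.
#' @return a [signature_catalog()].
#' @export
read_catalog <- function(path, axis_kind) {
  mat <- read_matrix(path, axis_kind)
  if (any(mat < 0)) stop("catalog contains negative entries")
  sums <- colSums(mat)
  off <- abs(sums - 1) > 1e-3
  if (any(off))
    stop("signature column(s) do not sum to 1: ",
         paste(colnames(mat)[off], collapse = ", "))
  mat <- sweep(mat, 2, sums, "/")
  signature_catalog(axis_kind, mat)
}
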