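# Channel classification. Every classifier returns the records augmented
# with columns `axis`, `channel`, `status` ("classified"/"unclassifiable")
# and `reason` (NA when classified). Purine-centered events are collapsed
# onto the pyrimidine strand by reverse complement; any context window that
# contains N or runs past a contig end makes the mutation unclassifiable —
# counted, never guessed.

classified_frame <- function(records, axis, channel, status, reason) {
  records$axis <- axis
  records$channel <- channel
  records$status <- status
  records$reason <- reason
  records
}

#' Classify single-base substitutions into SBS96 channels
#'
#' Looks up the trinucleotide context around each SNV; if the reference base
#' is a purine the context and the alternate allele are reverse-complemented
#' before naming, so channels are always pyrimidine-centered
#' (`"X[C>A]Y"` / `"X[T>A]Y"`). A mismatch between the record's REF and the
#' genome base is an error (it signals the wrong reference genome).
#'
#' @param records mutation record data.frame of SNVs.
#' @param genome a [ref_genome()].
#' @return records with `axis`, `channel`, `status`, `reason` columns.
#' @export
#' @examples
#' g <- ref_genome(c(chr1 = "AACAG"))
#' classify_sbs(mutation_records("chr1", 3, "C", "A", "cl1"), g)$channel
classify_sbs <- function(records, genome) {
  if (nrow(records) == 0)
    return(classified_frame(records, character(), character(),
                            character(), character()))
  if (!all(variant_class(records) == "SNV"))
    stop("classify_sbs expects SNV records only")
  channel <- rep(NA_character_, nrow(records))
  status <- rep("unclassifiable", nrow(records))
  reason <- rep(NA_character_, nrow(records))
  for (contig in unique(records$contig)) {
    i <- which(records$contig == contig)
    seq <- contig_seq(genome, contig)
    base <- substring(seq, records$pos[i], records$pos[i])
    mism <- base != records$ref[i] & base != "N"
    if (any(mism))
      stop("REF does not match reference genome at ", contig, ":",
           records$pos[i][mism][1], " (", records$ref[i][mism][1], " vs ",
           base[mism][1], ") - wrong reference?")
    ctx <- get_context(genome, contig, records$pos[i], flank = 1L)
    ok <- !is.na(ctx)
    channel[i][ok] <- sbs96_channel(ctx[ok], records$alt[i][ok])
    status[i][ok] <- "classified"
    reason[i][!ok] <- "context_unavailable"
  }
  classified_frame(records, "SBS96", channel, status, reason)
}

#' Merge adjacent SNVs of one clone into doublet substitutions
#'
#' Two SNVs of the same clone at consecutive positions on one contig become
#' a doublet (DBS) record. Runs of three or more consecutive mutated
#' positions are excluded entirely from both the SBS and DBS outputs
#' (the COSMIC convention, preventing double counting) and reported.
#'
#' @param records SNV records of a single clone.
#' @param genome a [ref_genome()] (unused for merging itself; retained so
#'   callers can verify doublet REF alleles downstream).
#' @return list with `doublets` (MNV records, ref/alt length 2), `snvs`
#'   (records in no adjacent run) and `excluded_runs` (data.frame contig,
#'   start, length of runs >= 3).
#' @export
merge_adjacent <- function(records, genome = NULL) {
  if (length(unique(records$clone_id)) > 1)
    stop("merge_adjacent expects records of a single clone")
  if (nrow(records) > 0 && !all(variant_class(records) == "SNV"))
    stop("merge_adjacent expects SNV records only")
  doublets <- mutation_records()
  excluded <- data.frame(contig = character(), start = integer(),
                         length = integer(), stringsAsFactors = FALSE)
  if (nrow(records) == 0)
    return(list(doublets = doublets, snvs = records, excluded_runs = excluded))
  ord <- order(records$contig, records$pos)
  r <- records[ord, , drop = FALSE]
  new_contig <- c(TRUE, r$contig[-1] != r$contig[-nrow(r)])
  gap <- c(TRUE, diff(r$pos) != 1L)
  run_id <- cumsum(new_contig | gap)
  run_len <- ave(run_id, run_id, FUN = length)
  keep_single <- run_len == 1
  pair_first <- run_len == 2 & !duplicated(run_id)
  if (any(pair_first)) {
    i <- which(pair_first)
    doublets <- mutation_records(
      r$contig[i], r$pos[i],
      paste0(r$ref[i], r$ref[i + 1]),
      paste0(r$alt[i], r$alt[i + 1]),
      r$clone_id[i])
  }
  long <- run_len >= 3 & !duplicated(run_id)
  if (any(long)) {
    i <- which(long)
    excluded <- data.frame(contig = r$contig[i], start = r$pos[i],
                           length = run_len[i], stringsAsFactors = FALSE)
  }
  snvs <- r[keep_single, , drop = FALSE]
  rownames(snvs) <- NULL
  list(doublets = doublets, snvs = snvs, excluded_runs = excluded)
}

#' Classify doublet substitutions into DBS78 channels
#'
#' Accepts length-2 MNV records whose alternate allele differs from the
#' reference at both positions; the pair is canonicalized by reverse
#' complement into the 78-channel set.
#'
#' @param records doublet MNV records.
#' @return records with `axis`, `channel`, `status`, `reason` columns.
#' @export
#' @examples
#' classify_dbs(mutation_records("chr1", 10, "GG", "TT", "cl1"))$channel  # "CC>AA"
classify_dbs <- function(records) {
  if (nrow(records) == 0)
    return(classified_frame(records, character(), character(),
                            character(), character()))
  if (any(nchar(records$ref) != 2 | nchar(records$alt) != 2))
    stop("classify_dbs expects length-2 ref and alt")
  same1 <- substr(records$ref, 1, 1) == substr(records$alt, 1, 1)
  same2 <- substr(records$ref, 2, 2) == substr(records$alt, 2, 2)
  if (any(same1 | same2))
    stop("doublet alt shares a base with ref at position ",
         which(same1 | same2)[1])
  channel <- dbs78_channel(records$ref, records$alt)
  classified_frame(records, "DBS78", channel, "classified", NA_character_)
}

# ---- ID83 ---------------------------------------------------------------

# longest run of `base` in seq starting exactly at position `from`
run_length_at <- function(seq, from, base) {
  n <- nchar(seq)
  k <- 0L
  while (from + k <= n && substr(seq, from + k, from + k) == base) k <- k + 1L
  k
}

# number of consecutive full copies of `frag` starting at `from`
count_copies <- function(seq, from, frag) {
  n <- nchar(seq); L <- nchar(frag); k <- 0L
  while (from + (k + 1L) * L - 1L <= n &&
         substr(seq, from + k * L, from + (k + 1L) * L - 1L) == frag)
    k <- k + 1L
  k
}

# longest common prefix length of frag with seq starting at `from`
prefix_match <- function(seq, from, frag) {
  n <- nchar(seq); L <- nchar(frag); k <- 0L
  while (k < L && from + k <= n &&
         substr(seq, from + k, from + k) == substr(frag, k + 1L, k + 1L))
    k <- k + 1L
  k
}

# longest common suffix length of frag with seq ending at `at`
suffix_match <- function(seq, at, frag) {
  L <- nchar(frag); k <- 0L
  while (k < L && at - k >= 1 &&
         substr(seq, at - k, at - k) == substr(frag, L - k, L - k))
    k <- k + 1L
  k
}

#' Classify small insertions and deletions into ID83 channels
#'
#' Events are anchored, left-aligned indels with fragment length 1-50 bp
#' (longer events are unclassifiable). 1 bp events are collapsed to a C or
#' T base (purines complemented); deletions are binned by the homopolymer
#' run length of the deleted base *including* the deleted base
#' (bins 1..6+, name fields 0..5), insertions by the count of identical
#' adjacent reference bases (bins 0..5+). Longer deletions are binned by
#' the number of additional full flanking copies of the deleted fragment
#' (tandem-repeat channels); deletions with no full extra copy but partial
#' flanking identity go to microhomology channels; insertions by flanking
#' copy count.
#'
#' @param records anchored indel records (see [variant_class()]).
#' @param genome a [ref_genome()].
#' @return records with `axis`, `channel`, `status`, `reason` columns.
#' @export
classify_indel <- function(records, genome) {
  if (nrow(records) == 0)
    return(classified_frame(records, character(), character(),
                            character(), character()))
  cls <- variant_class(records)
  if (!all(cls %in% c("insertion", "deletion")))
    stop("classify_indel expects anchored insertion/deletion records")
  channel <- rep(NA_character_, nrow(records))
  status <- rep("unclassifiable", nrow(records))
  reason <- rep(NA_character_, nrow(records))
  for (i in seq_len(nrow(records))) {
    contig <- records$contig[i]
    seq <- contig_seq(genome, contig)
    pos <- records$pos[i]; ref <- records$ref[i]; alt <- records$alt[i]
    is_del <- cls[i] == "deletion"
    frag <- if (is_del) substr(ref, 2, nchar(ref)) else substr(alt, 2, nchar(alt))
    L <- nchar(frag)
    if (L > 50) { reason[i] <- "too_long"; next }
    if (grepl("N", frag, fixed = TRUE)) { reason[i] <- "contains_N"; next }
    # REF must match the genome
    gref <- substring(seq, pos, pos + nchar(ref) - 1L)
    if (gref != ref)
      stop("REF does not match reference genome at ", contig, ":", pos,
           " (", ref, " vs ", gref, ") - wrong reference?")
    if (L == 1L) {
      b <- frag
      pyr <- if (b %in% c("A", "G")) comp_base(b) else b
      if (is_del) {
        # run of b containing the deleted base; left-aligned, so it starts
        # at pos + 1
        run <- run_length_at(seq, pos + 1L, b)
        field <- min(run - 1L, 5L)
        channel[i] <- paste0("1:Del:", pyr, ":", field)
      } else {
        run <- run_length_at(seq, pos + 1L, b)
        field <- min(run, 5L)
        channel[i] <- paste0("1:Ins:", pyr, ":", field)
      }
      status[i] <- "classified"
    } else {
      size <- min(L, 5L)
      if (is_del) {
        # copies of frag remaining to the right of the deleted copy
        copies <- count_copies(seq, pos + 1L + L, frag)
        if (copies >= 1L) {
          channel[i] <- paste0(size, ":Del:R:", min(copies, 5L))
        } else {
          mh <- max(prefix_match(seq, pos + 1L + L, frag),
                    suffix_match(seq, pos, frag))
          mh <- min(mh, L - 1L)
          if (mh >= 1L) {
            channel[i] <- paste0(size, ":Del:M:", min(mh, 5L))
          } else {
            channel[i] <- paste0(size, ":Del:R:0")
          }
        }
      } else {
        copies <- count_copies(seq, pos + 1L, frag)
        channel[i] <- paste0(size, ":Ins:R:", min(copies, 5L))
      }
      status[i] <- "classified"
    }
  }
  classified_frame(records, "ID83", channel, status, reason)
}

#' Classify a mixed set of mutation records
#'
#' Dispatches records of one clone: SNVs are merged into doublets where
#' adjacent ([merge_adjacent()]), then classified on SBS96; doublets
#' (merged or native length-2 MNVs) on DBS78; anchored indels on ID83.
#' Complex records are unclassifiable.
#'
#' @param records mutation record data.frame of a single clone.
#' @param genome a [ref_genome()].
#' @return list with elements `sbs`, `dbs`, `id` (classified frames),
#'   `unclassifiable` (records + reason), `excluded_runs`, and `ledger`
#'   (named integer counts: input, snv_singleton, merged_into_dbs,
#'   run_excluded, native_dbs, indel, complex).
#' @export
classify_mutations <- function(records, genome) {
  cls <- variant_class(records)
  snv <- records[cls == "SNV", , drop = FALSE]
  mnv <- records[cls == "MNV", , drop = FALSE]
  ind <- records[cls %in% c("insertion", "deletion"), , drop = FALSE]
  cplx <- records[cls == "complex" | (cls == "MNV" & nchar(records$ref) != 2),
                  , drop = FALSE]
  mnv2 <- mnv[nchar(mnv$ref) == 2, , drop = FALSE]
  # MNV with partially shared bases cannot be a true doublet
  if (nrow(mnv2) > 0) {
    shared <- substr(mnv2$ref, 1, 1) == substr(mnv2$alt, 1, 1) |
      substr(mnv2$ref, 2, 2) == substr(mnv2$alt, 2, 2)
    cplx <- rbind(cplx, mnv2[shared, , drop = FALSE])
    mnv2 <- mnv2[!shared, , drop = FALSE]
  }
  merged <- merge_adjacent(snv, genome)
  run_members <- sum(merged$excluded_runs$length)
  doublets <- rbind(merged$doublets, mnv2)
  sbs <- classify_sbs(merged$snvs, genome)
  dbs <- classify_dbs(doublets)
  idc <- classify_indel(ind, genome)
  unclass <- rbind(
    if (nrow(cplx) > 0)
      classified_frame(cplx, NA_character_, NA_character_,
                       "unclassifiable", "complex")
    else NULL,
    sbs[sbs$status == "unclassifiable", , drop = FALSE],
    dbs[dbs$status == "unclassifiable", , drop = FALSE],
    idc[idc$status == "unclassifiable", , drop = FALSE])
  ledger <- c(
    input = nrow(records),
    snv_singleton = nrow(merged$snvs),
    merged_into_dbs = 2L * nrow(merged$doublets),
    run_excluded = as.integer(run_members),
    native_dbs = nrow(mnv2),
    indel = nrow(ind),
    complex = nrow(records) - nrow(snv) - nrow(mnv2) - nrow(ind))
  list(sbs = sbs[sbs$status == "classified", , drop = FALSE],
       dbs = dbs[dbs$status == "classified", , drop = FALSE],
       id = idc[idc$status == "classified", , drop = FALSE],
       unclassifiable = unclass,
       excluded_runs = merged$excluded_runs,
       ledger = ledger)
}
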