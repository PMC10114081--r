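# Synthetic clonal-expansion experiments: a random reference genome,
# parental SNVs shared by every clone, per-clone background mutations and
# compound-specific mutations drawn from known channel distributions, with
# full per-mutation ground truth.
#
# Placement contract: classify(place(channel)) == channel. Each placement
# reserves its classification-relevant window in a global collision mask,
# so no two placed mutations (any clone) overlap or sit adjacent, and a
# synthesized context can never disturb an earlier placement.

new_mask <- function() new.env(parent = emptyenv(), hash = TRUE)

mask_free <- function(mask, contig, positions) {
  keys <- paste0(contig, ":", positions)
  for (k in keys) if (exists(k, envir = mask, inherits = FALSE)) return(FALSE)
  TRUE
}

mask_block <- function(mask, contig, positions) {
  keys <- paste0(contig, ":", positions)
  for (k in keys) assign(k, TRUE, envir = mask)
  invisible(mask)
}

trinuc_code <- function(s) {
  b <- base_codes(s)
  16L * b[1] + 4L * b[2] + b[3]
}

dinuc_code <- function(s) {
  b <- base_codes(s)
  4L * b[1] + b[2]
}

# pooled candidate sites (contig, pos, purine_strand) for a pyrimidine-
# centered trinucleotide context and its reverse complement
sbs_pool <- function(genome, ctx) {
  key <- paste0("pool:", ctx)
  pool <- genome$cache[[key]]
  if (!is.null(pool)) return(pool)
  code_p <- trinuc_code(ctx) + 1L
  code_r <- trinuc_code(revcomp(ctx)) + 1L
  contig <- character(0); pos <- integer(0); purine <- logical(0)
  for (cn in names(genome$seqs)) {
    idx <- trinuc_index(genome, cn)
    pp <- idx[[code_p]]; pr <- idx[[code_r]]
    contig <- c(contig, rep(cn, length(pp) + length(pr)))
    pos <- c(pos, pp, pr)
    purine <- c(purine, rep(FALSE, length(pp)), rep(TRUE, length(pr)))
  }
  pool <- list(contig = contig, pos = pos, purine = purine)
  genome$cache[[key]] <- pool
  pool
}

dbs_pool <- function(genome, ref2) {
  key <- paste0("dpool:", ref2)
  pool <- genome$cache[[key]]
  if (!is.null(pool)) return(pool)
  rc <- revcomp(ref2)
  code_p <- dinuc_code(ref2) + 1L
  code_r <- if (rc == ref2) NULL else dinuc_code(rc) + 1L
  contig <- character(0); pos <- integer(0); purine <- logical(0)
  for (cn in names(genome$seqs)) {
    idx <- dinuc_index(genome, cn)
    pp <- idx[[code_p]]
    pr <- if (is.null(code_r)) integer(0) else idx[[code_r]]
    contig <- c(contig, rep(cn, length(pp) + length(pr)))
    pos <- c(pos, pp, pr)
    purine <- c(purine, rep(FALSE, length(pp)), rep(TRUE, length(pr)))
  }
  pool <- list(contig = contig, pos = pos, purine = purine)
  genome$cache[[key]] <- pool
  pool
}

# homopolymer-run candidate sites for 1 bp indel channels
hp_pool <- function(genome, op, pyr, field) {
  key <- paste0("hp:", op, ":", pyr, ":", field)
  pool <- genome$cache[[key]]
  if (!is.null(pool)) return(pool)
  bases <- c(pyr, comp_base(pyr))
  codes <- vapply(bases, function(b) base_codes(b), integer(1))
  want_len <- if (op == "del") field + 1L else field
  min6 <- field == 5L
  contig <- character(0); start <- integer(0); len <- integer(0)
  base_out <- character(0)
  for (cn in names(genome$seqs)) {
    runs <- run_index(genome, cn)
    n <- nchar(genome$seqs[[cn]])
    for (bi in seq_along(bases)) {
      sel <- runs$base == codes[bi] & runs$start >= 2L &
        (if (min6) runs$length >= want_len else runs$length == want_len)
      # keep the run's right boundary inside the contig so the run length
      # is fully determined
      sel <- sel & (runs$start + runs$length - 1L) < n
      r <- runs[sel, , drop = FALSE]
      contig <- c(contig, rep(cn, nrow(r)))
      start <- c(start, r$start); len <- c(len, r$length)
      base_out <- c(base_out, rep(bases[bi], nrow(r)))
    }
  }
  pool <- list(contig = contig, start = start, len = len, base = base_out)
  genome$cache[[key]] <- pool
  pool
}

draw_free_sites <- function(pool_n, k, try_site, max_rounds = 60L) {
  # generic rejection sampler over a candidate pool; try_site(i) returns
  # TRUE when site i was accepted (and blocked)
  got <- integer(0)
  rounds <- 0L
  while (length(got) < k && rounds < max_rounds) {
    rounds <- rounds + 1L
    need <- k - length(got)
    m <- min(pool_n, max(2L * need + 10L, need))
    cand <- sample.int(pool_n, m)
    for (i in cand) {
      if (try_site(i)) {
        got <- c(got, i)
        if (length(got) == k) break
      }
    }
  }
  got
}

place_sbs_channel <- function(genome, channel, k, mask) {
  ctx <- paste0(substr(channel, 1, 1), substr(channel, 3, 3),
                substr(channel, 7, 7))
  altb <- substr(channel, 5, 5)
  pool <- sbs_pool(genome, ctx)
  n <- length(pool$pos)
  if (n == 0)
    stop("no genomic site compatible with SBS channel ", channel)
  out_contig <- character(0); out_pos <- integer(0)
  out_ref <- character(0); out_alt <- character(0)
  try_site <- function(i) {
    cn <- pool$contig[i]; p <- pool$pos[i]
    if (!mask_free(mask, cn, (p - 1L):(p + 1L))) return(FALSE)
    mask_block(mask, cn, (p - 1L):(p + 1L))
    if (pool$purine[i]) {
      out_ref <<- c(out_ref, comp_base(substr(channel, 3, 3)))
      out_alt <<- c(out_alt, comp_base(altb))
    } else {
      out_ref <<- c(out_ref, substr(channel, 3, 3))
      out_alt <<- c(out_alt, altb)
    }
    out_contig <<- c(out_contig, cn); out_pos <<- c(out_pos, p)
    TRUE
  }
  got <- draw_free_sites(n, k, try_site)
  if (length(got) < k)
    stop("collision exhaustion placing ", k, " x ", channel,
         " (", length(got), " placed)")
  data.frame(contig = out_contig, pos = out_pos, ref = out_ref,
             alt = out_alt, stringsAsFactors = FALSE)
}

place_dbs_channel <- function(genome, channel, k, mask) {
  ref2 <- substr(channel, 1, 2)
  alt2 <- substr(channel, 4, 5)
  pool <- dbs_pool(genome, ref2)
  n <- length(pool$pos)
  if (n == 0)
    stop("no genomic site compatible with DBS channel ", channel)
  out <- list(contig = character(0), pos = integer(0),
              ref = character(0), alt = character(0))
  try_site <- function(i) {
    cn <- pool$contig[i]; p <- pool$pos[i]
    if (!mask_free(mask, cn, (p - 1L):(p + 2L))) return(FALSE)
    mask_block(mask, cn, (p - 1L):(p + 2L))
    if (pool$purine[i]) {
      out$ref <<- c(out$ref, revcomp(ref2)); out$alt <<- c(out$alt, revcomp(alt2))
    } else {
      out$ref <<- c(out$ref, ref2); out$alt <<- c(out$alt, alt2)
    }
    out$contig <<- c(out$contig, cn); out$pos <<- c(out$pos, p)
    TRUE
  }
  got <- draw_free_sites(n, k, try_site)
  if (length(got) < k)
    stop("collision exhaustion placing ", k, " x ", channel)
  data.frame(contig = out$contig, pos = out$pos, ref = out$ref,
             alt = out$alt, stringsAsFactors = FALSE)
}

parse_id_channel <- function(channel) {
  parts <- strsplit(channel, ":", fixed = TRUE)[[1]]
  list(size = as.integer(parts[1]), op = tolower(parts[2]),
       sub = parts[3], field = as.integer(parts[4]))
}

frag_for_size <- function(size) {
  c(`2` = "AC", `3` = "ACG", `4` = "ACGT", `5` = "ACGGT")[[as.character(size)]]
}

other_base <- function(avoid) setdiff(BASES, avoid)[1]

# synthetic context window for an ID channel: list(window, anchor_off,
# ref, alt) with anchor_off the 1-based offset of the VCF anchor base
id_synth_plan <- function(channel) {
  p <- parse_id_channel(channel)
  if (p$sub %in% c("C", "T")) {
    b <- p$sub
    g <- other_base(b)
    if (p$op == "del") {
      runlen <- if (p$field < 5L) p$field + 1L else 6L
      list(window = paste0(g, strrep(b, runlen), g), anchor_off = 1L,
           ref = paste0(g, b), alt = g)
    } else {
      runlen <- if (p$field < 5L) p$field else 5L
      list(window = paste0(g, strrep(b, runlen), g), anchor_off = 1L,
           ref = g, alt = paste0(g, b))
    }
  } else if (p$sub == "R") {
    f <- frag_for_size(p$size)
    L <- nchar(f)
    lg <- other_base(substr(f, L, L))
    rg <- other_base(substr(f, 1, 1))
    if (p$op == "del") {
      copies <- p$field + 1L
      list(window = paste0(lg, strrep(f, copies), rg), anchor_off = 1L,
           ref = paste0(lg, f), alt = lg)
    } else {
      copies <- p$field
      list(window = paste0(lg, strrep(f, copies), rg), anchor_off = 1L,
           ref = lg, alt = paste0(lg, f))
    }
  } else {  # microhomology deletion
    m <- p$field
    L <- if (p$size == 5L && m == 5L) 6L else p$size
    f <- substr("ACGGTA", 1, L)
    lg <- other_base(substr(f, L, L))
    rg <- other_base(substr(f, m + 1L, m + 1L))
    list(window = paste0(lg, f, substr(f, 1, m), rg), anchor_off = 1L,
         ref = paste0(lg, f), alt = lg)
  }
}

# overwrite an unblocked region with `plan$window`; returns list(genome,
# record row). The whole window (plus 1 bp margin) is blocked afterwards.
synth_id_site <- function(genome, plan, mask, max_tries = 200L) {
  W <- nchar(plan$window)
  lens <- contig_lengths(genome)
  ok_contigs <- names(lens)[lens >= W + 4L]
  if (length(ok_contigs) == 0)
    stop("genome too small to synthesize a ", W, " bp context window")
  for (t in seq_len(max_tries)) {
    cn <- if (length(ok_contigs) == 1) ok_contigs else
      sample(ok_contigs, 1, prob = lens[ok_contigs])
    start <- sample.int(lens[[cn]] - W - 2L, 1) + 1L
    span <- (start - 1L):(start + W)
    if (!mask_free(mask, cn, span)) next
    seq <- genome$seqs[[cn]]
    if (grepl("N", substring(seq, start, start + W - 1L), fixed = TRUE)) next
    substr(seq, start, start + W - 1L) <- plan$window
    genome$seqs[[cn]] <- seq
    mask_block(mask, cn, span)
    pos <- start + plan$anchor_off - 1L
    return(list(genome = genome,
                record = data.frame(contig = cn, pos = pos, ref = plan$ref,
                                    alt = plan$alt, stringsAsFactors = FALSE),
                synthesized = TRUE))
  }
  stop("collision exhaustion: no free region to synthesize context")
}

# classification check used during rejection sampling of ID sites
id_channel_of <- function(genome, contig, pos, ref, alt) {
  rec <- mutation_records(contig, pos, ref, alt, "chk")
  cl <- classify_indel(rec, genome)
  if (cl$status[1] == "classified") cl$channel[1] else NA_character_
}

place_id_channel_one <- function(genome, channel, mask, n_tries = 400L) {
  p <- parse_id_channel(channel)
  synth <- FALSE
  rec <- NULL
  if (p$sub %in% c("C", "T")) {
    pool <- hp_pool(genome, p$op, p$sub, p$field)
    if (p$op == "ins" && p$field == 0L) {
      rec <- place_ins0_1bp(genome, p$sub, mask, n_tries)
    } else if (length(pool$start) > 0) {
      idx <- sample.int(length(pool$start), min(length(pool$start), 50L))
      for (i in idx) {
        cn <- pool$contig[i]; st <- pool$start[i]; ln <- pool$len[i]
        b <- pool$base[i]
        span <- (st - 1L):(st + ln)
        if (!mask_free(mask, cn, span)) next
        anchor <- st - 1L
        ab <- substring(genome$seqs[[cn]], anchor, anchor)
        if (!ab %in% BASES) next
        mask_block(mask, cn, span)
        if (p$op == "del") {
          rec <- data.frame(contig = cn, pos = anchor,
                            ref = paste0(ab, b), alt = ab,
                            stringsAsFactors = FALSE)
        } else {
          rec <- data.frame(contig = cn, pos = anchor,
                            ref = ab, alt = paste0(ab, b),
                            stringsAsFactors = FALSE)
        }
        break
      }
    }
  } else if (p$op == "del" && p$sub == "R" && p$field == 0L) {
    rec <- place_del_rejection(genome, channel, p$size, mask, n_tries)
  } else if (p$op == "del" && p$sub == "M") {
    rec <- place_del_rejection(genome, channel,
                               if (p$size == 5L && p$field == 5L) 6L else p$size,
                               mask, n_tries)
  } else if (p$op == "ins" && p$field == 0L) {
    rec <- place_insR0(genome, p$size, mask, n_tries)
  } else {
    rec <- place_repeat_natural(genome, p, mask)
  }
  if (is.null(rec)) {
    out <- synth_id_site(genome, id_synth_plan(channel), mask)
    genome <- out$genome
    rec <- out$record
    synth <- TRUE
  }
  list(genome = genome, record = rec, synthesized = synth)
}

random_site <- function(genome, margin) {
  lens <- contig_lengths(genome)
  ok <- names(lens)[lens > 2L * margin + 2L]
  cn <- if (length(ok) == 1) ok else sample(ok, 1, prob = lens[ok])
  pos <- sample.int(lens[[cn]] - 2L * margin, 1) + margin
  list(contig = cn, pos = pos)
}

place_ins0_1bp <- function(genome, b, mask, n_tries) {
  for (t in seq_len(n_tries)) {
    bb <- sample(c(b, comp_base(b)), 1)
    s <- random_site(genome, 3L)
    seq <- genome$seqs[[s$contig]]
    anchor <- s$pos
    if (substring(seq, anchor, anchor) %in% BASES &&
        substring(seq, anchor, anchor) != bb &&
        substring(seq, anchor + 1L, anchor + 1L) %in% BASES &&
        substring(seq, anchor + 1L, anchor + 1L) != bb &&
        mask_free(mask, s$contig, (anchor - 1L):(anchor + 2L))) {
      mask_block(mask, s$contig, (anchor - 1L):(anchor + 2L))
      return(data.frame(contig = s$contig, pos = anchor,
                        ref = substring(seq, anchor, anchor),
                        alt = paste0(substring(seq, anchor, anchor), bb),
                        stringsAsFactors = FALSE))
    }
  }
  NULL
}

place_del_rejection <- function(genome, channel, L, mask, n_tries) {
  margin <- 3L * L + 2L
  for (t in seq_len(n_tries)) {
    s <- random_site(genome, margin)
    seq <- genome$seqs[[s$contig]]
    anchor <- s$pos
    frag <- substring(seq, anchor + 1L, anchor + L)
    if (grepl("[^ACGT]", frag) ||
        !substring(seq, anchor, anchor) %in% BASES) next
    if (substring(seq, anchor, anchor) == substr(frag, L, L)) next  # not left-aligned
    span <- (anchor - L):(anchor + 3L * L + 1L)
    if (!mask_free(mask, s$contig, span)) next
    ch <- id_channel_of(genome, s$contig, anchor,
                        paste0(substring(seq, anchor, anchor), frag),
                        substring(seq, anchor, anchor))
    if (is.na(ch) || ch != channel) next
    mask_block(mask, s$contig, span)
    return(data.frame(contig = s$contig, pos = anchor,
                      ref = paste0(substring(seq, anchor, anchor), frag),
                      alt = substring(seq, anchor, anchor),
                      stringsAsFactors = FALSE))
  }
  NULL
}

place_insR0 <- function(genome, size, mask, n_tries) {
  for (t in seq_len(n_tries)) {
    s <- random_site(genome, 2L * size + 2L)
    seq <- genome$seqs[[s$contig]]
    anchor <- s$pos
    ab <- substring(seq, anchor, anchor)
    if (!ab %in% BASES) next
    frag <- paste(sample(BASES, size, replace = TRUE), collapse = "")
    if (ab == substr(frag, size, size)) next
    if (count_copies(seq, anchor + 1L, frag) != 0L) next
    span <- (anchor - 1L):(anchor + size + 1L)
    if (!mask_free(mask, s$contig, span)) next
    mask_block(mask, s$contig, span)
    return(data.frame(contig = s$contig, pos = anchor, ref = ab,
                      alt = paste0(ab, frag), stringsAsFactors = FALSE))
  }
  NULL
}

place_repeat_natural <- function(genome, p, mask, n_frags = 8L) {
  L <- p$size
  copies_needed <- if (p$op == "del") p$field + 1L else p$field
  for (t in seq_len(n_frags)) {
    f <- paste(sample(BASES, L, replace = TRUE), collapse = "")
    if (length(unique(strsplit(f, "")[[1]])) < 2) next
    pat <- strrep(f, copies_needed)
    for (cn in names(genome$seqs)) {
      seq <- genome$seqs[[cn]]
      hits <- gregexpr(pat, seq, fixed = TRUE)[[1]]
      if (hits[1] == -1) next
      hits <- as.integer(hits)
      hits <- hits[sample.int(length(hits))]
      for (q in utils::head(hits, 25L)) {
        anchor <- q - 1L
        if (anchor < 1L) next
        ab <- substring(seq, anchor, anchor)
        if (!ab %in% BASES || ab == substr(f, L, L)) next
        # exact copy count: no further full copy beyond the matched block
        after <- q + copies_needed * L
        if (p$field < 5L &&
            substring(seq, after, after + L - 1L) == f) next
        span <- (anchor - L):(q + (copies_needed + 1L) * L)
        if (!mask_free(mask, cn, span)) next
        if (p$op == "del") {
          ch <- id_channel_of(genome, cn, anchor, paste0(ab, f), ab)
          want <- paste0(p$size, ":Del:R:", p$field)
          if (is.na(ch) || ch != want) next
          mask_block(mask, cn, span)
          return(data.frame(contig = cn, pos = anchor, ref = paste0(ab, f),
                            alt = ab, stringsAsFactors = FALSE))
        } else {
          ch <- id_channel_of(genome, cn, anchor, ab, paste0(ab, f))
          want <- paste0(p$size, ":Ins:R:", p$field)
          if (is.na(ch) || ch != want) next
          mask_block(mask, cn, span)
          return(data.frame(contig = cn, pos = anchor, ref = ab,
                            alt = paste0(ab, f), stringsAsFactors = FALSE))
        }
      }
    }
  }
  NULL
}

#' Place a mutation whose classification round-trips to a channel
#'
#' Chooses a genomic site compatible with the channel's required context
#' (uniformly among indexed candidate sites for substitution channels) and
#' returns a record such that classifying it reproduces the channel. For
#' indel channels whose homopolymer / tandem-repeat / microhomology context
#' is absent from the genome, a compatible context window is synthesized
#' into an unused region (the returned record carries
#' `attr(, "synthesized") = TRUE` and the edited genome in
#' `attr(, "genome")`).
#'
#' @param genome a [ref_genome()].
#' @param channel channel name.
#' @param axis_kind the channel's axis.
#' @param clone_id clone id stamped on the record.
#' @param mask optional collision mask (internal); a fresh one is used when
#'   omitted.
#' @return one-row mutation record data.frame.
#' @export
#' @examples
#' g <- generate_reference(10000, 1, 0.5, seed = 4)
#' r <- place_mutation(g, "A[C>A]A", "SBS96")
#' classify_sbs(r, g)$channel
place_mutation <- function(genome, channel, axis_kind, clone_id = "sim",
                           mask = NULL) {
  if (is.null(mask)) mask <- new_mask()
  if (!channel %in% channel_axis(axis_kind)$channels)
    stop("channel ", channel, " is not on axis ", axis_kind)
  if (axis_kind == "SBS96") {
    rec <- place_sbs_channel(genome, channel, 1L, mask)
    synth <- FALSE
  } else if (axis_kind == "DBS78") {
    rec <- place_dbs_channel(genome, channel, 1L, mask)
    synth <- FALSE
  } else {
    out <- place_id_channel_one(genome, channel, mask)
    rec <- out$record
    synth <- out$synthesized
    if (synth) genome <- out$genome
  }
  rec$clone_id <- clone_id
  rec <- rec[, c("contig", "pos", "ref", "alt", "clone_id")]
  attr(rec, "synthesized") <- synth
  attr(rec, "genome") <- genome
  rec
}
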