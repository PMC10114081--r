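test_that("SBS classification is pyrimidine-centered and context-aware", {
  g <- ref_genome(c(chr1 = "AACAG"))   # context around pos 3 is ACA
  expect_equal(classify_sbs(mutation_records("chr1", 3, "C", "A", "c"), g)$channel,
               "A[C>A]A")
  # purine-centered event: TGT with G>T mirrors to A[C>A]A
  g2 <- ref_genome(c(chr1 = "ATGTA"))
  expect_equal(classify_sbs(mutation_records("chr1", 3, "G", "T", "c"), g2)$channel,
               "A[C>A]A")
  # REF/genome mismatch signals the wrong reference
  expect_error(classify_sbs(mutation_records("chr1", 3, "T", "A", "c"), g),
               "wrong reference")
  # context at contig edge or containing N is unclassifiable
  gn <- ref_genome(c(chr1 = "CNCAG"))
  out <- classify_sbs(mutation_records("chr1", c(1L, 3L), "C", "A", "c"), gn)
  expect_true(all(out$status == "unclassifiable"))
  expect_true(all(out$reason == "context_unavailable"))
})

test_that("exhaustive SBS enumeration reaches all 96 channels exactly twice", {
  combos <- expand.grid(p5 = c("A", "C", "G", "T"),
                        ref = c("A", "C", "G", "T"),
                        p3 = c("A", "C", "G", "T"),
                        stringsAsFactors = FALSE)
  channels <- character(0)
  for (i in seq_len(nrow(combos))) {
    tri <- paste0(combos$p5[i], combos$ref[i], combos$p3[i])
    g <- ref_genome(c(chr1 = paste0("A", tri, "A")))
    for (alt in setdiff(c("A", "C", "G", "T"), combos$ref[i])) {
      ch <- classify_sbs(mutation_records("chr1", 3, combos$ref[i], alt, "c"),
                         g)$channel
      channels <- c(channels, ch)
    }
  }
  tab <- table(channels)
  expect_length(tab, 96)
  expect_true(all(tab == 2))
  expect_setequal(names(tab), channel_axis("SBS96")$channels)
})

test_that("strand collapse is an involution: mirrored SNVs classify identically", {
  g <- random_genome(20000, seed = 8)
  seq <- g$seqs[[1]]
  n <- nchar(seq)
  mirror <- ref_genome(c(chr1 = revcomp(seq)))
  set.seed(21)
  pos <- sample(2:(n - 1), 2000)
  ref <- substring(seq, pos, pos)
  alt <- vapply(ref, function(b) sample(setdiff(c("A", "C", "G", "T"), b), 1),
                character(1))
  fwd <- classify_sbs(mutation_records("chr1", pos, ref, alt, "c"), g)
  rev <- classify_sbs(mutation_records("chr1", n - pos + 1,
                                       clonespect:::comp_base(ref),
                                       clonespect:::comp_base(alt), "c"),
                      mirror)
  expect_identical(fwd$channel, rev$channel)
})

test_that("adjacent SNVs merge into doublets and longer runs are excluded", {
  g <- tiny_genome()
  two <- mutation_records("chr1", c(5L, 6L), c("A", "C"), c("T", "A"), "c")
  m <- merge_adjacent(two, g)
  expect_equal(nrow(m$doublets), 1)
  expect_equal(m$doublets$ref, "AC")
  expect_equal(m$doublets$alt, "TA")
  expect_equal(nrow(m$snvs), 0)

  apart <- mutation_records("chr1", c(5L, 7L), c("A", "G"), c("T", "A"), "c")
  m2 <- merge_adjacent(apart, g)
  expect_equal(nrow(m2$doublets), 0)
  expect_equal(nrow(m2$snvs), 2)

  run3 <- mutation_records("chr1", c(5L, 6L, 7L), c("A", "C", "G"),
                           c("T", "A", "T"), "c")
  m3 <- merge_adjacent(run3, g)
  expect_equal(nrow(m3$doublets), 0)
  expect_equal(nrow(m3$snvs), 0)
  expect_equal(m3$excluded_runs$length, 3)
  expect_equal(m3$excluded_runs$start, 5)
})

test_that("DBS canonicalization covers exactly 78 channels over all 144 doublets", {
  expect_equal(classify_dbs(mutation_records("chr1", 1, "CC", "AA", "c"))$channel,
               "CC>AA")
  expect_equal(classify_dbs(mutation_records("chr1", 1, "GG", "TT", "c"))$channel,
               "CC>AA")
  expect_error(classify_dbs(mutation_records("chr1", 1, "CC", "CA", "c")),
               "shares a base")

  channels <- character(0)
  for (r1 in c("A", "C", "G", "T")) for (r2 in c("A", "C", "G", "T"))
    for (a1 in setdiff(c("A", "C", "G", "T"), r1))
      for (a2 in setdiff(c("A", "C", "G", "T"), r2)) {
        rec <- mutation_records("chr1", 1, paste0(r1, r2), paste0(a1, a2), "c")
        channels <- c(channels, classify_dbs(rec)$channel)
      }
  expect_length(channels, 144)
  expect_false(any(is.na(channels)))
  expect_setequal(unique(channels), channel_axis("DBS78")$channels)
  expect_length(unique(channels), 78)
})

test_that("1 bp indels bin by homopolymer run length with purine collapse", {
  # delete one T from the TTTT run in CTTTTG: run length 4 -> bin field 3
  g <- ref_genome(c(chr1 = "ACTTTTGA"))
  del <- classify_indel(mutation_records("chr1", 2, "CT", "C", "c"), g)
  expect_equal(del$channel, "1:Del:T:3")
  # deleting an A collapses to the T channel
  ga <- ref_genome(c(chr1 = "GCAAAGT"))
  dela <- classify_indel(mutation_records("chr1", 2, "CA", "C", "c"), ga)
  expect_equal(dela$channel, "1:Del:T:2")
  # T insertion with no adjacent T: repeat bin 0
  gi <- ref_genome(c(chr1 = "CCAGGA"))
  ins <- classify_indel(mutation_records("chr1", 3, "A", "AT", "c"), gi)
  expect_equal(ins$channel, "1:Ins:T:0")
  # T insertion next to TT: bin 2
  gi2 <- ref_genome(c(chr1 = "CCATTGA"))
  ins2 <- classify_indel(mutation_records("chr1", 3, "A", "AT", "c"), gi2)
  expect_equal(ins2$channel, "1:Ins:T:2")
})

test_that("longer deletions separate tandem-repeat from microhomology channels", {
  # delete CA from GCACACAT: two additional copies -> repeat bin 2
  g <- ref_genome(c(chr1 = "GGCACACATG"))
  del <- classify_indel(mutation_records("chr1", 2, "GCA", "G", "c"), g)
  expect_equal(del$channel, "2:Del:R:2")
  # delete TCTA whose right flank begins TC..: microhomology length 2
  g2 <- ref_genome(c(chr1 = "GGGTCTATCGGAAA"))
  del2 <- classify_indel(mutation_records("chr1", 3, "GTCTA", "G", "c"), g2)
  expect_equal(del2$channel, "4:Del:M:2")
  # no copy, no flanking identity: repeat bin 0
  g3 <- ref_genome(c(chr1 = "GGACGTGGGAA"))
  del3 <- classify_indel(mutation_records("chr1", 2, "GACGT", "G", "c"), g3)
  expect_equal(del3$channel, "4:Del:R:0")
  # insertion with one existing copy: repeat bin 1
  g4 <- ref_genome(c(chr1 = "GGACGTTTAA"))
  ins <- classify_indel(mutation_records("chr1", 2, "G", "GACG", "c"), g4)
  expect_equal(ins$channel, "3:Ins:R:1")
  # fragments over 50 bp are unclassifiable
  long_frag <- paste(rep("ACGGT", 11), collapse = "")
  g5 <- ref_genome(c(chr1 = paste0("GG", long_frag, "GG")))
  del5 <- classify_indel(
    mutation_records("chr1", 2, paste0("G", long_frag), "G", "c"), g5)
  expect_equal(del5$status, "unclassifiable")
  expect_equal(del5$reason, "too_long")
})

test_that("every ID83 channel is reachable by a constructed example", {
  for (ch in channel_axis("ID83")$channels) {
    plan <- clonespect:::id_synth_plan(ch)
    g <- ref_genome(c(chr1 = paste0("GT", plan$window, "TG")))
    rec <- mutation_records("chr1", 2L + plan$anchor_off, plan$ref, plan$alt, "c")
    out <- classify_indel(rec, g)
    expect_equal(out$channel, ch)
  }
})

test_that("repeat vs microhomology precedence holds on random deletions", {
  g <- random_genome(30000, seed = 31)
  seq <- g$seqs[[1]]
  set.seed(32)
  checked <- 0
  for (i in 1:300) {
    L <- sample(2:6, 1)
    pos <- sample(10:(30000 - 40), 1)
    frag <- substring(seq, pos + 1, pos + L)
    if (substring(seq, pos, pos) == substr(frag, L, L)) next  # not left-aligned
    rec <- mutation_records("chr1", pos, paste0(substring(seq, pos, pos), frag),
                            substring(seq, pos, pos), "c")
    out <- classify_indel(rec, g)
    expect_equal(out$status, "classified")
    copies <- clonespect:::count_copies(seq, pos + 1 + L, frag)
    mh <- max(clonespect:::prefix_match(seq, pos + 1 + L, frag),
              clonespect:::suffix_match(seq, pos, frag))
    if (grepl(":Del:R:", out$channel)) {
      field <- as.integer(sub(".*:", "", out$channel))
      if (field > 0) expect_gte(copies, 1)
      else expect_equal(copies + min(mh, 1), 0)
    } else if (grepl(":Del:M:", out$channel)) {
      expect_equal(copies, 0)
      expect_gte(mh, 1)
    }
    checked <- checked + 1
  }
  expect_gte(checked, 150)
})

test_that("mixed classification conserves every input record in the ledger", {
  g <- ref_genome(c(chr1 = paste0("ACGTACGTAC", "CTTTTG", "ACGTACGTACGT",
                                  "CCGGA", "ACGTT")))
  recs <- rbind(
    mutation_records("chr1", 3, "G", "T", "c"),          # SNV
    mutation_records("chr1", c(20L, 21L), c("T", "A"), c("C", "G"), "c"),  # doublet
    mutation_records("chr1", c(25L, 26L, 27L), c("A", "C", "G"),
                     c("T", "A", "T"), "c"),             # run of 3
    mutation_records("chr1", 11, "CT", "C", "c"),        # 1bp del
    mutation_records("chr1", 29, "CC", "TT", "c"))       # native MNV doublet
  out <- classify_mutations(recs, g)
  led <- out$ledger
  expect_equal(led[["input"]],
               led[["snv_singleton"]] + led[["merged_into_dbs"]] +
                 led[["run_excluded"]] + led[["native_dbs"]] +
                 led[["indel"]] + led[["complex"]])
  expect_equal(nrow(out$sbs), 1)
  expect_equal(nrow(out$dbs), 2)  # merged + native
  expect_equal(nrow(out$id), 1)
  expect_equal(out$excluded_runs$length, 3)
})
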