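make_records <- function(spec, contig = "chr1") {
  # spec: named list key -> character vector of carrier clones
  rows <- do.call(rbind, lapply(names(spec), function(k) {
    parts <- strsplit(k, ":")[[1]]
    data.frame(contig = contig, pos = as.integer(parts[1]),
               ref = parts[2], alt = parts[3],
               clone_id = spec[[k]], stringsAsFactors = FALSE)
  }))
  rownames(rows) <- NULL
  rows
}

test_that("parental removal removes exactly the parental keys from every clone", {
  recs <- make_records(list(`10:C:A` = c("c1", "c2"),
                            `20:G:T` = c("c1", "c2"),
                            `30:T:C` = c("c1", "c2"),
                            `40:A:G` = "c1", `50:C:G` = "c2",
                            `60:G:C` = "c1", `70:T:A` = "c2",
                            `80:A:C` = c("c1", "c2"),
                            `90:C:T` = "c1", `95:G:A` = "c2"))
  # empty parental set: identity
  expect_identical(remove_parental(recs, character())[, 1:5], recs)
  # all records parental: annihilation
  allgone <- remove_parental(recs, unique(variant_key(recs)))
  expect_equal(nrow(allgone), 0)
  # three shared parental keys removed from both clones
  par <- c("chr1:10:C:A", "chr1:20:G:T", "chr1:30:T:C")
  out <- remove_parental(recs, par)
  expect_equal(sum(out$clone_id == "c1"), sum(recs$clone_id == "c1") - 3)
  expect_equal(sum(out$clone_id == "c2"), sum(recs$clone_id == "c2") - 3)
  expect_equal(unname(attr(out, "removed")[c("c1", "c2")]), c(3L, 3L))
  expect_false(any(variant_key(out) %in% par))
})

test_that("colony-exclusive selection keeps keys with exactly one carrier", {
  grp <- clone_group("g", c(c1 = "A", c2 = "A", c3 = "control",
                            c4 = "control"))
  recs <- make_records(list(`10:C:A` = "c1",                    # exclusive
                            `20:G:T` = c("c1", "c2"),           # shared
                            `30:T:C` = c("c1", "c3", "c4")))    # shared w/ controls
  out <- select_exclusive(grp, recs)
  expect_equal(variant_key(out), "chr1:10:C:A")
  expect_equal(out$clone_id, "c1")
  # key in all clones retained for none
  all4 <- make_records(list(`10:C:A` = c("c1", "c2", "c3", "c4")))
  expect_equal(nrow(select_exclusive(grp, all4)), 0)
  # clone not in group is an error
  bad <- make_records(list(`10:C:A` = "cX"))
  expect_error(select_exclusive(grp, bad), "not in group")
})

test_that("same-treatment carrier scope ignores carriers under other labels", {
  grp <- clone_group("g", c(c1 = "A", c2 = "A", c3 = "control"))
  recs <- make_records(list(`10:C:A` = c("c1", "c3")))
  expect_equal(nrow(select_exclusive(grp, recs, "group")), 0)
  out <- select_exclusive(grp, recs, "same_treatment")
  expect_setequal(out$clone_id, c("c1", "c3"))
})

test_that("exclusive selection matches brute-force carrier counting on random instances", {
  grp6 <- clone_group("g", stats::setNames(
    c(rep("A", 3), rep("control", 3)), paste0("c", 1:6)))
  set.seed(99)
  for (i in 1:60) {
    n_keys <- sample(1:200, 1)
    n_clones <- sample(2:6, 1)
    clones <- paste0("c", 1:n_clones)
    rows <- do.call(rbind, lapply(seq_len(n_keys), function(k) {
      carriers <- sample(clones, sample(1:n_clones, 1))
      data.frame(contig = "chr1", pos = k, ref = "C", alt = "A",
                 clone_id = carriers, stringsAsFactors = FALSE)
    }))
    got <- select_exclusive(grp6, rows)
    want <- exclusive_oracle(rows)
    expect_setequal(paste(variant_key(got), got$clone_id),
                    paste(variant_key(want), want$clone_id))
  }
})

test_that("exclusive selection is idempotent and yields clone-disjoint keys", {
  grp <- clone_group("g", stats::setNames(
    c(rep("A", 2), rep("B", 2), rep("control", 2)), paste0("c", 1:6)))
  set.seed(5)
  rows <- do.call(rbind, lapply(1:150, function(k) {
    carriers <- sample(paste0("c", 1:6), sample(1:6, 1))
    data.frame(contig = "chr1", pos = k, ref = "G", alt = "T",
               clone_id = carriers, stringsAsFactors = FALSE)
  }))
  once <- select_exclusive(grp, rows)
  twice <- select_exclusive(grp, once)
  expect_identical(once[, 1:5], twice[, 1:5])
  expect_false(anyDuplicated(variant_key(once)) > 0)
})

test_that("manifests round-trip into clone groups", {
  path <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c("clone_id\tgroup_id\ttreatment",
               "c1\tg1\tMNNG", "c2\tg1\tMNNG", "c3\tg1\tcontrol",
               "c4\tg2\tBaP", "c5\tg2\tcontrol"), path)
  groups <- read_manifest(path)
  expect_named(groups, c("g1", "g2"))
  expect_equal(unname(groups$g1$members["c3"]), "control")
  expect_equal(clonespect:::control_clones(groups$g2), "c5")
  expect_equal(clonespect:::treatment_labels(groups$g1), "MNNG")

  dup <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c("clone_id\tgroup_id\ttreatment",
               "c1\tg1\tMNNG", "c1\tg2\tBaP"), dup)
  expect_error(read_manifest(dup), "more than once")
})
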