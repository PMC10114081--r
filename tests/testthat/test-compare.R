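test_that("cosine similarity satisfies its contracts", {
  expect_equal(cosine_similarity(c(1, 2, 3), c(1, 2, 3)), 1.0)
  expect_equal(cosine_similarity(c(1, 0), c(0, 1)), 0.0)
  expect_equal(cosine_similarity(c(3, 4), c(4, 3)), 0.96)
  # scale invariance: counts and probabilities score identically
  a <- c(2, 5, 1); b <- c(1, 4, 4)
  expect_equal(cosine_similarity(a * 1000, b), cosine_similarity(a, b))
  expect_equal(cosine_similarity(a / sum(a), b / sum(b)),
               cosine_similarity(a, b))
  # bounds on random non-negative vectors
  set.seed(12)
  for (i in 1:50) {
    x <- stats::runif(10); y <- stats::runif(10)
    s <- cosine_similarity(x, y)
    expect_gte(s, 0); expect_lte(s, 1)
  }
  expect_error(cosine_similarity(c(0, 0), c(1, 1)), "zero vector")
  expect_error(cosine_similarity(c(1, 2), c(1, 2, 3)), "length")
})

test_that("catalog matching ranks deterministically and flags the threshold", {
  channels <- channel_axis("SBS96")$channels
  mk <- function(idx) {
    v <- numeric(96); v[idx] <- 1; v / sum(v)
  }
  mat <- cbind(sigA = mk(1:10), sigB = mk(5:14), sigC = mk(50:60))
  rownames(mat) <- channels
  cat_ <- signature_catalog("SBS96", mat)
  q <- spectrum("SBS96", mk(1:10), "q", "probability")
  res <- match_catalog(q, cat_, threshold = 0.8)
  expect_equal(res$name[1], "sigA")
  expect_equal(res$similarity[1], 1.0)
  expect_true(res$above_threshold[1])
  # brute-force all-pairs oracle agrees with the ranking
  sims <- vapply(colnames(mat), function(n)
    cosine_similarity(mk(1:10), mat[, n]), numeric(1))
  expect_equal(res$name, names(sort(-sims)))
  # impossible threshold flags nothing beyond exact identity
  res2 <- match_catalog(spectrum("SBS96", mk(2:12), "q", "probability"),
                        cat_, threshold = 1.0)
  expect_false(any(res2$above_threshold))
  # ties keep catalog order
  mat2 <- cbind(first = mk(1:4), second = mk(1:4))
  rownames(mat2) <- channels
  res3 <- match_catalog(q, signature_catalog("SBS96", mat2))
  expect_equal(res3$name, c("first", "second"))
  expect_error(match_catalog(q, signature_catalog("SBS96", mat[, 0, drop = FALSE])),
               "empty catalog")
})

test_that("similarity matrices equal the elementwise oracle", {
  set.seed(9)
  channels <- channel_axis("DBS78")$channels
  qs <- lapply(1:4, function(i) {
    v <- stats::runif(78)
    spectrum("DBS78", v / sum(v), paste0("q", i), "probability")
  })
  cm <- vapply(1:5, function(i) { v <- stats::runif(78); v / sum(v) },
               numeric(78))
  dimnames(cm) <- list(channels, paste0("ref", 1:5))
  cat_ <- signature_catalog("DBS78", cm)
  m <- similarity_matrix(qs, cat_)
  expect_equal(dim(m), c(4, 5))
  for (i in 1:4) for (j in 1:5)
    expect_equal(m[i, j], cosine_similarity(qs[[i]]$counts, cm[, j]))
  # catalog against itself: unit diagonal
  self_q <- lapply(colnames(cm), function(n)
    spectrum("DBS78", cm[, n], n, "probability"))
  sm <- similarity_matrix(self_q, cat_)
  expect_equal(unname(diag(sm)), rep(1, 5), tolerance = 1e-12)
})

test_that("built-in synthetic signatures are valid and distinguishable", {
  for (ax in c("SBS96", "DBS78", "ID83")) {
    cat_ <- builtin_signatures(ax)
    expect_true(all(abs(colSums(cat_$mat) - 1) < 1e-9))
    expect_true(all(cat_$mat >= 0))
  }
  sbs <- builtin_signatures("SBS96")$mat
  compounds <- c("bap_like", "norharmane_like", "mnng_like", "nnk_acetate_like")
  for (i in seq_along(compounds)) for (j in seq_along(compounds)) {
    if (i < j) {
      s <- cosine_similarity(sbs[, compounds[i]], sbs[, compounds[j]])
      expect_lt(s, 0.97)
    }
  }
  # shipped TSV fixtures match the in-code definitions
  for (ax in c("SBS96", "DBS78", "ID83")) {
    path <- system.file("extdata", "signatures",
                        paste0("synthetic_signatures_", tolower(ax), ".tsv"),
                        package = "clonespect")
    expect_equal(read_catalog(path, ax)$mat, builtin_signatures(ax)$mat,
                 tolerance = 1e-9)
  }
  # shipped channel tables match the canonical axes
  for (ax in c("SBS96", "DBS78", "ID83")) {
    path <- system.file("extdata", "channels", paste0(tolower(ax), ".txt"),
                        package = "clonespect")
    expect_equal(readLines(path), channel_axis(ax)$channels)
  }
})
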