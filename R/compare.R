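# Cosine-similarity comparison of derived signatures against reference
# catalogs. Whole-signature comparison only; no refitting/attribution.

#' Construct a signature catalog
#'
#' Named probability vectors over one channel axis.
#'
#' @param axis_kind `"SBS96"`, `"DBS78"` or `"ID83"`.
#' @param mat numeric matrix, rows = channels in canonical order, one
#'   signature per column; columns must sum to 1 within 1e-9 and be
#'   non-negative.
#' @return object of class `signature_catalog`.
#' @export
signature_catalog <- function(axis_kind, mat) {
  channels <- channel_axis(axis_kind)$channels
  if (nrow(mat) != length(channels))
    stop("catalog must have ", length(channels), " rows for ", axis_kind)
  if (is.null(rownames(mat))) rownames(mat) <- channels
  if (!identical(rownames(mat), channels)) {
    if (!setequal(rownames(mat), channels))
      stop("catalog rownames do not match the ", axis_kind, " axis")
    mat <- mat[channels, , drop = FALSE]
  }
  if (ncol(mat) > 0 && (is.null(colnames(mat)) || anyDuplicated(colnames(mat))))
    stop("signatures must have unique names")
  if (any(mat < 0)) stop("catalog contains negative entries")
  if (any(abs(colSums(mat) - 1) > 1e-9))
    stop("signature column(s) must sum to 1")
  structure(list(axis_kind = axis_kind, mat = mat),
            class = "signature_catalog")
}

#' @export
print.signature_catalog <- function(x, ...) {
  cat("<signature_catalog>", x$axis_kind, "-", ncol(x$mat), "signatures:",
      paste(utils::head(colnames(x$mat), 6), collapse = ", "),
      if (ncol(x$mat) > 6) "..." else "", "\n")
  invisible(x)
}

#' Cosine similarity between two non-negative vectors
#'
#' `dot(a, b) / (|a| |b|)`, in `[0, 1]` for non-negative inputs; invariant
#' under positive scaling, so counts and probabilities give identical
#' scores. A zero vector is an error: an empty signature must be handled as
#' its flagged all-zero state upstream, not silently scored 0.
#'
#' @param a,b numeric vectors of equal length.
#' @return similarity in `[0, 1]`.
#' @export
#' @examples
#' cosine_similarity(c(3, 4), c(4, 3))  # 0.96
cosine_similarity <- function(a, b) {
  if (inherits(a, "spectrum")) a <- a$counts
  if (inherits(b, "spectrum")) b <- b$counts
  if (length(a) != length(b)) stop("vectors differ in length")
  na <- sqrt(sum(a^2)); nb <- sqrt(sum(b^2))
  if (na == 0 || nb == 0)
    stop("cosine similarity undefined for a zero vector (empty signature)")
  sum(a * b) / (na * nb)
}

#' Match a signature against a reference catalog
#'
#' Ranks catalog signatures by cosine similarity to the query, descending;
#' ties keep catalog order. Signatures at or above the threshold are
#' flagged as similar (default threshold 0.8).
#'
#' @param query a probability [spectrum()] (or bare vector on the catalog's
#'   axis).
#' @param catalog a [signature_catalog()].
#' @param threshold similarity threshold for flagging, in `[0, 1]`.
#' @return data.frame with columns `name`, `similarity`, `above_threshold`,
#'   sorted by decreasing similarity.
#' @export
match_catalog <- function(query, catalog, threshold = 0.8) {
  if (ncol(catalog$mat) == 0) stop("empty catalog")
  if (inherits(query, "spectrum")) {
    if (query$axis_kind != catalog$axis_kind)
      stop("axis mismatch: ", query$axis_kind, " vs ", catalog$axis_kind)
    if (isTRUE(query$all_zero))
      stop("query spectrum is flagged all-zero; no signature to match")
    q <- query$counts
  } else q <- query
  sims <- apply(catalog$mat, 2, cosine_similarity, b = q)
  ord <- order(-sims)   # stable: ties keep catalog order
  data.frame(name = colnames(catalog$mat)[ord],
             similarity = unname(sims[ord]),
             above_threshold = unname(sims[ord] >= threshold),
             stringsAsFactors = FALSE)
}

#' All-pairs similarity matrix between queries and a catalog
#'
#' @param queries list of probability [spectrum()]s (or a channels-by-query
#'   matrix) on the catalog's axis.
#' @param catalog a [signature_catalog()].
#' @return numeric matrix, entry `(i, j)` = cosine similarity of query `i`
#'   and catalog signature `j`.
#' @export
similarity_matrix <- function(queries, catalog) {
  if (is.list(queries)) {
    qm <- spectra_matrix(queries)
    if (queries[[1]]$axis_kind != catalog$axis_kind)
      stop("axis mismatch: ", queries[[1]]$axis_kind, " vs ", catalog$axis_kind)
  } else qm <- queries
  out <- matrix(NA_real_, ncol(qm), ncol(catalog$mat),
                dimnames = list(colnames(qm), colnames(catalog$mat)))
  for (i in seq_len(ncol(qm)))
    for (j in seq_len(ncol(catalog$mat)))
      out[i, j] <- cosine_similarity(qm[, i], catalog$mat[, j])
  out
}
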