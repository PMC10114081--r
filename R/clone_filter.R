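# Variant-selection logic: a mutation counts as compound-induced for a clone
# only if (a) it is not in the parental variant set and (b) within the
# clone's joint-calling group it was called exclusively for that clone.

#' Construct a joint-calling clone group
#'
#' @param group_id group identifier.
#' @param members named character vector: clone_id -> treatment label;
#'   control clones carry the label `"control"`.
#' @param parental_variants character vector of identity keys
#'   (`contig:pos:ref:alt`) of the parental clone's variants.
#' @return object of class `clone_group`.
#' @export
clone_group <- function(group_id, members, parental_variants = character()) {
  if (length(members) < 2) stop("a clone group needs >= 2 members")
  if (is.null(names(members)) || anyDuplicated(names(members)))
    stop("members must be named by unique clone ids")
  structure(list(group_id = as.character(group_id),
                 members = members,
                 parental_variants = unique(as.character(parental_variants))),
            class = "clone_group")
}

#' @export
print.clone_group <- function(x, ...) {
  cat("<clone_group>", x$group_id, "-", length(x$members), "clones (",
      sum(x$members == "control"), "controls ),",
      length(x$parental_variants), "parental keys\n")
  invisible(x)
}

control_clones <- function(group) names(group$members)[group$members == "control"]
treatment_labels <- function(group) setdiff(unique(group$members), "control")

#' Read a group manifest TSV
#'
#' Columns `clone_id`, `group_id`, `treatment` (controls labeled
#' `"control"`). Every clone belongs to exactly one group.
#'
#' @param path TSV path.
#' @param parental named list: group_id -> character vector of parental
#'   identity keys (optional).
#' @return named list of [clone_group()] objects.
#' @export
read_manifest <- function(path, parental = list()) {
  df <- utils::read.delim(path, stringsAsFactors = FALSE)
  need <- c("clone_id", "group_id", "treatment")
  if (!all(need %in% names(df)))
    stop("manifest must have columns: ", paste(need, collapse = ", "))
  if (anyDuplicated(df$clone_id))
    stop("clone(s) listed more than once: ",
         paste(unique(df$clone_id[duplicated(df$clone_id)]), collapse = ", "))
  groups <- split(df, df$group_id)
  out <- lapply(groups, function(g) {
    clone_group(g$group_id[1],
                stats::setNames(g$treatment, g$clone_id),
                parental[[g$group_id[1]]] %||% character())
  })
  out[unique(df$group_id)]
}

write_manifest <- function(groups, path) {
  rows <- do.call(rbind, lapply(groups, function(g) {
    data.frame(clone_id = names(g$members), group_id = g$group_id,
               treatment = unname(g$members), stringsAsFactors = FALSE)
  }))
  utils::write.table(rows, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Remove parental-clone variants
#'
#' Drops every record whose identity key is in the parental set, from every
#' clone. These are pre-existing variants of the parental clone, not
#' mutations caused by the exposure.
#'
#' @param records mutation record data.frame (any number of clones).
#' @param parental character vector of identity keys.
#' @return filtered records; attribute `removed` is a named integer vector
#'   of per-clone removal counts.
#' @export
remove_parental <- function(records, parental) {
  hit <- variant_key(records) %in% parental
  removed <- tapply(hit, records$clone_id, sum)
  out <- records[!hit, , drop = FALSE]
  rownames(out) <- NULL
  attr(out, "removed") <-
    stats::setNames(as.integer(removed), names(removed))
  out
}

#' Select colony-exclusive mutations
#'
#' A record is retained for clone `c` iff its identity key was called in `c`
#' and in no other clone of the group. By default all colonies of the
#' joint-calling group — controls and other treatments included — count as
#' carriers (the strictest reading, which best suppresses shared
#' artifacts); `carrier_scope = "same_treatment"` restricts the carrier
#' census to clones with the same treatment label.
#'
#' @param group a [clone_group()].
#' @param records mutation record data.frame; every clone_id must belong to
#'   the group.
#' @param carrier_scope `"group"` (default) or `"same_treatment"`.
#' @return records exclusive to one clone; attribute `non_exclusive` is a
#'   named integer vector of per-clone counts removed as shared.
#' @export
select_exclusive <- function(group, records,
                             carrier_scope = c("group", "same_treatment")) {
  carrier_scope <- match.arg(carrier_scope)
  clones <- unique(records$clone_id)
  unknown <- setdiff(clones, names(group$members))
  if (length(unknown) > 0)
    stop("clone(s) not in group ", group$group_id, ": ",
         paste(unknown, collapse = ", "))
  if (nrow(records) == 0) {
    attr(records, "non_exclusive") <- stats::setNames(integer(0), character(0))
    return(records)
  }
  keys <- variant_key(records)
  if (carrier_scope == "group") {
    # carriers = distinct clones per key across the whole group
    n_carriers <- rowsum(as.integer(!duplicated(paste(keys, records$clone_id))),
                         keys, reorder = FALSE)
    exclusive_keys <- rownames(n_carriers)[n_carriers[, 1] == 1L]
    keep <- keys %in% exclusive_keys & !duplicated(paste(keys, records$clone_id))
  } else {
    treat <- unname(group$members[records$clone_id])
    kt <- paste(keys, treat)
    n_carriers <- rowsum(as.integer(!duplicated(paste(kt, records$clone_id))),
                         kt, reorder = FALSE)
    excl <- rownames(n_carriers)[n_carriers[, 1] == 1L]
    keep <- kt %in% excl & !duplicated(paste(kt, records$clone_id))
  }
  shared <- tapply(!keep, records$clone_id, sum)
  out <- records[keep, , drop = FALSE]
  rownames(out) <- NULL
  attr(out, "non_exclusive") <-
    stats::setNames(as.integer(shared), names(shared))
  out
}
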