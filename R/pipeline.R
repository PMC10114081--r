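# Full dissection: per-clone VCFs + manifest + reference FASTA in; burden
# tables, per-compound signatures and catalog comparisons out. Every count
# is traceable through a per-clone conservation ledger:
#   input = parental_removed + non_exclusive + sbs_classified +
#           sbs_unclassifiable + merged_into_dbs + run_excluded +
#           native_dbs + id_classified + id_unclassifiable + complex

AXES <- c("SBS96", "DBS78", "ID83")

or_zero <- function(x) if (length(x) == 0 || is.na(x)) 0L else as.integer(x)

#' Dissect per-compound mutational signatures from clone VCFs
#'
#' Executes the full analysis: read per-clone variant calls, left-align
#' indels, remove parental variants, keep colony-exclusive mutations within
#' each joint-calling group, classify on SBS96/DBS78/ID83 (merging adjacent
#' SNVs into doublets), count per-clone spectra, subtract each group's
#' control mean from its treatment clones, average replicates, normalize to
#' signatures, and rank them against reference catalogs by cosine
#' similarity. Deterministic given its inputs.
#'
#' @param vcf_dir directory containing `<clone_id>.vcf` for every clone in
#'   the manifest (alternatively a named character vector of paths).
#' @param fasta reference genome FASTA.
#' @param manifest group manifest TSV (`clone_id`, `group_id`, `treatment`).
#' @param parental_vcf VCF of parental-clone variants to remove, or `NULL`.
#' @param catalogs named list of [signature_catalog()]s to compare against
#'   (any subset of the three axes); default: the built-in synthetic
#'   catalog on all axes.
#' @param threshold cosine-similarity threshold for flagging a catalog
#'   signature as similar.
#' @param out_dir directory for output TSVs, or `NULL` to skip writing.
#' @param subtract_order `"per-clone"` (subtract the control mean from each
#'   clone, then average) or `"aggregate"`.
#' @param carrier_scope passed to [select_exclusive()].
#' @return object of class `dissection_report`.
#' @export
run_dissection <- function(vcf_dir, fasta, manifest, parental_vcf = NULL,
                           catalogs = NULL, threshold = 0.8, out_dir = NULL,
                           subtract_order = c("per-clone", "aggregate"),
                           carrier_scope = c("group", "same_treatment")) {
  subtract_order <- match.arg(subtract_order)
  carrier_scope <- match.arg(carrier_scope)
  genome <- read_fasta(fasta)
  groups <- read_manifest(manifest)
  if (is.null(catalogs))
    catalogs <- list(SBS96 = builtin_signatures("SBS96"),
                     DBS78 = builtin_signatures("DBS78"),
                     ID83  = builtin_signatures("ID83"))
  parental_keys <- if (!is.null(parental_vcf))
    variant_key(left_align(read_vcf(parental_vcf, "parental"), genome))
  else character(0)

  all_clones <- unlist(lapply(groups, function(g) names(g$members)))
  vcf_paths <- if (length(vcf_dir) == 1 && dir.exists(vcf_dir)) {
    stats::setNames(file.path(vcf_dir, paste0(all_clones, ".vcf")), all_clones)
  } else vcf_dir
  missing <- all_clones[!file.exists(vcf_paths[all_clones])]
  if (length(missing) > 0)
    stop("missing VCF for clone(s): ", paste(missing, collapse = ", "))

  ledger_rows <- list()
  spectra <- list()     # [[axis]][[clone_id]]
  signatures <- list()  # [[axis]][[treatment]]
  burden_rows <- list()
  match_rows <- list()
  clamp_log <- list()

  for (gid in names(groups)) {
    grp <- groups[[gid]]
    grp$parental_variants <- union(grp$parental_variants, parental_keys)
    ctrl <- control_clones(grp)
    if (length(ctrl) == 0)
      stop("group ", gid, " has no control clones; control subtraction ",
           "is impossible")
    recs <- do.call(rbind, lapply(names(grp$members), function(cl)
      read_vcf(vcf_paths[[cl]], cl)))
    recs <- left_align(recs, genome)
    n_input <- table(factor(recs$clone_id, levels = names(grp$members)))
    recs <- remove_parental(recs, grp$parental_variants)
    n_par <- attr(recs, "removed")
    recs <- select_exclusive(grp, recs, carrier_scope)
    n_shared <- attr(recs, "non_exclusive")

    clone_class <- list()
    for (cl in names(grp$members)) {
      cr <- recs[recs$clone_id == cl, , drop = FALSE]
      cls <- classify_mutations(cr, genome)
      clone_class[[cl]] <- cls
      led <- cls$ledger
      ledger_rows[[cl]] <- data.frame(
        clone_id = cl, group_id = gid, treatment = grp$members[[cl]],
        input = as.integer(n_input[[cl]]),
        parental_removed = or_zero(n_par[cl]),
        non_exclusive = or_zero(n_shared[cl]),
        sbs_classified = nrow(cls$sbs),
        sbs_unclassifiable = led[["snv_singleton"]] - nrow(cls$sbs),
        merged_into_dbs = led[["merged_into_dbs"]],
        run_excluded = led[["run_excluded"]],
        native_dbs = led[["native_dbs"]],
        id_classified = nrow(cls$id),
        id_unclassifiable = led[["indel"]] - nrow(cls$id),
        complex = led[["complex"]],
        stringsAsFactors = FALSE)
      for (ax in AXES) {
        part <- switch(ax, SBS96 = cls$sbs, DBS78 = cls$dbs, ID83 = cls$id)
        spectra[[ax]][[cl]] <- count_spectrum(part, ax, cl)
      }
    }

    for (ax in AXES) {
      ctrl_mean <- mean_spectrum(spectra[[ax]][ctrl],
                                 paste0(gid, "_control_mean"))
      for (label in treatment_labels(grp)) {
        cls_ids <- names(grp$members)[grp$members == label]
        sig <- compound_signature(spectra[[ax]][cls_ids], ctrl_mean,
                                  sample_id = label, order = subtract_order)
        signatures[[ax]][[label]] <- sig
        burden_rows[[paste(label, ax)]] <- data.frame(
          treatment = label, group_id = gid, axis = ax,
          burden = attr(sig, "burden"), burden_sd = attr(sig, "burden_sd"),
          control_mean_total = total_burden(ctrl_mean),
          stringsAsFactors = FALSE)
        clamp_log[[paste(label, ax)]] <- data.frame(
          treatment = label, axis = ax,
          clamped = if (subtract_order == "per-clone")
            sum(vapply(lapply(spectra[[ax]][cls_ids], subtract_control,
                              ctrl_mean),
                       function(s) s$clamped, integer(1)))
          else NA_integer_,
          stringsAsFactors = FALSE)
        if (!isTRUE(sig$all_zero) && !is.null(catalogs[[ax]])) {
          mm <- match_catalog(sig, catalogs[[ax]], threshold)
          mm$treatment <- label; mm$axis <- ax
          match_rows[[paste(label, ax)]] <- mm
        }
      }
    }
  }

  ledger <- do.call(rbind, ledger_rows); rownames(ledger) <- NULL
  retained <- with(ledger, sbs_classified + sbs_unclassifiable +
                     merged_into_dbs + run_excluded + native_dbs +
                     id_classified + id_unclassifiable + complex)
  conservation_ok <- all(ledger$input ==
                           ledger$parental_removed + ledger$non_exclusive +
                           retained)
  burdens <- do.call(rbind, burden_rows); rownames(burdens) <- NULL
  matches <- if (length(match_rows) > 0) {
    m <- do.call(rbind, match_rows); rownames(m) <- NULL; m
  } else NULL

  report <- structure(list(
    ledger = ledger, conservation_ok = conservation_ok,
    spectra = spectra, signatures = signatures, burdens = burdens,
    matches = matches, clamped = do.call(rbind, clamp_log),
    threshold = threshold, subtract_order = subtract_order,
    carrier_scope = carrier_scope,
    version = as.character(utils::packageVersion("clonespect"))),
    class = "dissection_report")

  if (!is.null(out_dir)) {
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    utils::write.table(ledger, file.path(out_dir, "clone_ledger.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
    utils::write.table(burdens, file.path(out_dir, "burdens.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
    if (!is.null(matches))
      utils::write.table(matches, file.path(out_dir, "catalog_matches.tsv"),
                         sep = "\t", quote = FALSE, row.names = FALSE)
    for (ax in AXES) {
      if (length(spectra[[ax]]) > 0)
        write_matrix(spectra_matrix(spectra[[ax]]),
                     file.path(out_dir, paste0("spectra_", tolower(ax), ".tsv")))
      if (length(signatures[[ax]]) > 0)
        write_matrix(spectra_matrix(signatures[[ax]]),
                     file.path(out_dir,
                               paste0("signatures_", tolower(ax), ".tsv")))
    }
  }
  report
}

#' @export
print.dissection_report <- function(x, ...) {
  cat("<dissection_report> clonespect", x$version, "\n")
  cat("  clones:", nrow(x$ledger),
      "| count conservation:", if (x$conservation_ok) "exact" else "VIOLATED",
      "\n")
  b <- x$burdens[x$burdens$axis == "SBS96", , drop = FALSE]
  if (nrow(b) > 0) {
    cat("  SBS burden after control subtraction (mean over clones):\n")
    for (i in seq_len(nrow(b)))
      cat(sprintf("    %-18s %8.1f  (sd %.1f)\n",
                  b$treatment[i], b$burden[i], b$burden_sd[i]))
  }
  invisible(x)
}

#' @export
summary.dissection_report <- function(object, ...) {
  cat("Per-clone ledger:\n")
  print(object$ledger)
  cat("\nBurdens after control subtraction:\n")
  print(object$burdens)
  if (!is.null(object$matches)) {
    cat("\nCatalog matches at threshold", object$threshold, ":\n")
    print(object$matches[object$matches$above_threshold, , drop = FALSE])
  }
  invisible(object)
}
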