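# Whole-experiment simulation: the generative counterpart of the dissection
# pipeline. Defaults mirror the clonal-expansion study design: joint-calling
# groups each with their own vehicle controls, five clones per condition,
# shared parental SNVs, ~750 endogenous SBS per clone, and per-compound
# burdens spanning hundreds to tens of thousands.

#' Per-treatment exposure specification
#'
#' Bundles the expected mutation burden and signature mixture per mutation
#' class (SBS / DBS / indel) for one treatment or for the endogenous
#' background. Mixtures are named weight vectors over signatures of the
#' relevant catalog (see [builtin_signatures()]) and must sum to 1.
#'
#' @param sbs_burden,dbs_burden,id_burden expected mutations per clone.
#' @param sbs_mixture,dbs_mixture,id_mixture named mixture weights.
#' @return list keyed by axis, each with `burden` and `mixture`.
#' @export
#' @examples
#' exposure(sbs_burden = 700, sbs_mixture = c(mnng_like = 1))
exposure <- function(sbs_burden = 0, sbs_mixture = c(flat = 1),
                     dbs_burden = 0, dbs_mixture = c(flat = 1),
                     id_burden = 0, id_mixture = c(flat = 1)) {
  list(SBS96 = list(burden = sbs_burden, mixture = sbs_mixture),
       DBS78 = list(burden = dbs_burden, mixture = dbs_mixture),
       ID83  = list(burden = id_burden, mixture = id_mixture))
}

#' Simulation configuration
#'
#' @param genome list with `total_length`, `n_contigs`, `gc_fraction`.
#' @param groups named list; each group is a named list of treatments
#'   created with the `exposure()` fields (`sbs_burden`, `sbs_mixture`, ...);
#'   every group automatically receives its own control clones.
#' @param clones_per_condition clones per treatment and per control.
#' @param background an `exposure`-shaped list for the endogenous mutation
#'   load of every clone (default: 750 SBS from a flat signature, a small
#'   DBS and indel load).
#' @param n_parental_variants SNVs of the parental clone, shared by every
#'   clone of the experiment.
#' @param overdispersion `NULL` for Poisson burden noise (default), or a
#'   positive negative-binomial size parameter for over-dispersed counts.
#' @param seed integer seed; identical seeds give byte-identical outputs.
#' @return object of class `simulation_config`.
#' @export
simulation_config <- function(genome = list(total_length = 5e6, n_contigs = 2,
                                            gc_fraction = 0.41),
                              groups,
                              clones_per_condition = 5L,
                              background = exposure(sbs_burden = 750,
                                                    dbs_burden = 0.2,
                                                    id_burden = 50,
                                                    id_mixture =
                                                      c(background_id_like = 1)),
                              n_parental_variants = 1000L,
                              overdispersion = NULL,
                              seed = 1L) {
  for (g in groups) for (tr in g) for (ax in names(tr)) {
    w <- tr[[ax]]$mixture
    if (abs(sum(w) - 1) > 1e-9)
      stop("mixture weights must sum to 1")
    if (tr[[ax]]$burden < 0) stop("burdens must be non-negative")
  }
  structure(list(genome = genome, groups = groups,
                 clones_per_condition = as.integer(clones_per_condition),
                 background = background,
                 n_parental_variants = as.integer(n_parental_variants),
                 overdispersion = overdispersion,
                 seed = as.integer(seed)),
            class = "simulation_config")
}

#' Default study-design configuration
#'
#' Three joint-calling groups with their own controls; five clones per
#' condition; compound SBS burdens on the published scale (norharmane 200,
#' MNNG 700, NNK acetate 5500, BaP 25000 mean SBS per clone; harmane,
#' 1-naphthylamine and 3-aminobiphenyl non-mutagenic); BaP additionally
#' carries doublet and indel loads; every clone gets ~750 endogenous SBS
#' from a flat background signature.
#'
#' @param seed integer seed.
#' @param genome_length genome size in bp.
#' @return a [simulation_config()].
#' @export
default_simulation_config <- function(seed = 1L, genome_length = 5e6) {
  groups <- list(
    group1 = list(
      MNNG = exposure(sbs_burden = 700, sbs_mixture = c(mnng_like = 1)),
      NNK_acetate = exposure(sbs_burden = 5500,
                             sbs_mixture = c(nnk_acetate_like = 1))),
    group2 = list(
      harmane = exposure(),
      norharmane = exposure(sbs_burden = 200,
                            sbs_mixture = c(norharmane_like = 1)),
      naphthylamine_1 = exposure(),
      aminobiphenyl_3 = exposure()),
    group3 = list(
      BaP = exposure(sbs_burden = 25000, sbs_mixture = c(bap_like = 1),
                     dbs_burden = 0.7, dbs_mixture = c(bap_dbs_like = 1),
                     id_burden = 500, id_mixture = c(bap_id_like = 1)))
  )
  simulation_config(genome = list(total_length = genome_length, n_contigs = 2,
                                  gc_fraction = 0.41),
                    groups = groups, seed = seed)
}

#' @rdname simulation_config
#' @param path YAML file path.
#' @export
read_simulation_config <- function(path) {
  x <- yaml::read_yaml(path)
  groups <- lapply(x$groups, function(g) lapply(g, function(tr) {
    lapply(tr, function(ax) list(burden = ax$burden,
                                 mixture = unlist(ax$mixture)))
  }))
  simulation_config(genome = x$genome, groups = groups,
                    clones_per_condition = x$clones_per_condition,
                    background = lapply(x$background, function(ax)
                      list(burden = ax$burden, mixture = unlist(ax$mixture))),
                    n_parental_variants = x$n_parental_variants,
                    overdispersion = x$overdispersion,
                    seed = x$seed)
}

#' @rdname simulation_config
#' @param config a `simulation_config`.
#' @export
write_simulation_config <- function(config, path) {
  x <- unclass(config)
  x$groups <- lapply(x$groups, function(g) lapply(g, function(tr)
    lapply(tr, function(ax) list(burden = ax$burden,
                                 mixture = as.list(ax$mixture)))))
  x$background <- lapply(x$background, function(ax)
    list(burden = ax$burden, mixture = as.list(ax$mixture)))
  yaml::write_yaml(x, path)
  invisible(path)
}

mixture_vector <- function(axis_kind, mixture, bank) {
  cat_ <- bank[[axis_kind]]
  missing <- setdiff(names(mixture), colnames(cat_$mat))
  if (length(missing) > 0)
    stop("unknown signature(s) in mixture: ", paste(missing, collapse = ", "))
  v <- as.numeric(cat_$mat[, names(mixture), drop = FALSE] %*% mixture)
  stats::setNames(v, rownames(cat_$mat))
}

draw_burden <- function(expected, overdispersion) {
  if (expected == 0) return(0L)
  if (is.null(overdispersion)) stats::rpois(1, expected)
  else stats::rnbinom(1, mu = expected, size = overdispersion)
}

place_class_batch <- function(genome, axis_kind, n, mix, mask, clone_id,
                              source) {
  channels <- names(mix)
  recs <- list(); truth_channels <- character(0)
  n_synth <- 0L
  if (n > 0) {
    drawn <- sample(channels, n, replace = TRUE, prob = mix)
    tab <- table(drawn)
    for (ch in names(tab)) {
      k <- as.integer(tab[[ch]])
      if (axis_kind == "SBS96") {
        r <- place_sbs_channel(genome, ch, k, mask)
      } else if (axis_kind == "DBS78") {
        r <- place_dbs_channel(genome, ch, k, mask)
      } else {
        r <- NULL
        for (j in seq_len(k)) {
          one <- place_id_channel_one(genome, ch, mask)
          genome <- one$genome
          n_synth <- n_synth + one$synthesized
          r <- rbind(r, one$record)
        }
      }
      recs[[ch]] <- r
      truth_channels <- c(truth_channels, rep(ch, k))
    }
  }
  out <- if (length(recs) > 0) do.call(rbind, recs) else
    data.frame(contig = character(), pos = integer(), ref = character(),
               alt = character(), stringsAsFactors = FALSE)
  rownames(out) <- NULL
  out$clone_id <- rep(clone_id, nrow(out))
  out$source <- rep(source, nrow(out))
  out$class <- rep(axis_kind, nrow(out))
  out$true_channel <- truth_channels
  list(records = out, genome = genome, n_synth = n_synth)
}

#' Simulate a complete clonal-expansion experiment
#'
#' Generates a random reference genome, parental SNVs shared by every clone,
#' per-clone endogenous background mutations (counts Poisson around the
#' background burden, channels from the background mixture) and, for
#' treatment clones, compound-specific mutations from the treatment mixture.
#' All placements are collision-free (no two mutations within 1 bp of each
#' other, across all clones) and classification round-trips to the drawn
#' channel. Writes FASTA, one VCF per clone, the group manifest, the
#' parental VCF and ground-truth tables into `out_dir`.
#'
#' @param config a [simulation_config()].
#' @param out_dir output directory (created if missing).
#' @param signatures named list of [signature_catalog()]s per axis used to
#'   resolve mixture names; defaults to [builtin_signatures()].
#' @return object of class `clonal_simulation`: file paths, the (possibly
#'   context-augmented) genome, the clone groups, and `truth` (per-clone
#'   realized burdens, per-mutation source table, true mixture spectra).
#' @export
simulate_experiment <- function(config, out_dir, signatures = NULL) {
  stopifnot(inherits(config, "simulation_config"))
  if (is.null(signatures))
    signatures <- list(SBS96 = builtin_signatures("SBS96"),
                       DBS78 = builtin_signatures("DBS78"),
                       ID83  = builtin_signatures("ID83"))
  dir.create(file.path(out_dir, "vcfs"), recursive = TRUE, showWarnings = FALSE)
  withr::with_seed(config$seed, {
    genome <- generate_reference(config$genome$total_length,
                                 config$genome$n_contigs,
                                 config$genome$gc_fraction,
                                 seed = config$seed)
    mask <- new_mask()
    flat <- stats::setNames(rep(1 / 96, 96), sbs96_channel_names())

    # parental SNVs, shared by all clones
    par_counts <- stats::rmultinom(1, config$n_parental_variants, flat)[, 1]
    par_recs <- NULL
    for (ch in names(par_counts)[par_counts > 0])
      par_recs <- rbind(par_recs,
                        place_sbs_channel(genome, ch, par_counts[[ch]], mask))
    par_recs$clone_id <- "parental"
    parental_keys <- variant_key(par_recs)

    groups <- list()
    vcf_paths <- character(0)
    truth_mut <- list()
    burdens <- list()
    n_synth <- 0L
    lens <- contig_lengths(genome)

    for (gid in names(config$groups)) {
      g <- config$groups[[gid]]
      members <- character(0)
      conditions <- c(g, list(control = NULL))
      for (label in names(conditions)) {
        for (i in seq_len(config$clones_per_condition)) {
          clone_id <- sprintf("%s_%s_%d", gid, label, i)
          members[clone_id] <- label
          clone_recs <- par_recs
          clone_recs$clone_id <- clone_id
          clone_recs$source <- "parental"
          clone_recs$class <- "SBS96"
          clone_recs$true_channel <- NA_character_
          realized <- c(SBS96 = 0L, DBS78 = 0L, ID83 = 0L)
          loads <- list(background = config$background)
          if (label != "control") loads$compound <- conditions[[label]]
          for (src in names(loads)) {
            for (ax in c("SBS96", "DBS78", "ID83")) {
              spec_ax <- loads[[src]][[ax]]
              n <- draw_burden(spec_ax$burden, config$overdispersion)
              if (n == 0 && spec_ax$burden == 0) next
              mix <- mixture_vector(ax, spec_ax$mixture, signatures)
              pl <- place_class_batch(genome, ax, n, mix, mask, clone_id, src)
              genome <- pl$genome
              n_synth <- n_synth + pl$n_synth
              clone_recs <- rbind(clone_recs, pl$records)
              if (src == "compound") realized[ax] <- realized[ax] + n
            }
          }
          vcf <- file.path(out_dir, "vcfs", paste0(clone_id, ".vcf"))
          write_vcf(clone_recs[, c("contig", "pos", "ref", "alt", "clone_id")],
                    vcf, lens)
          vcf_paths[clone_id] <- vcf
          truth_mut[[clone_id]] <- clone_recs
          burdens[[clone_id]] <- data.frame(
            clone_id = clone_id, group_id = gid, treatment = label,
            sbs_placed = sum(clone_recs$source == "compound" &
                               clone_recs$class == "SBS96"),
            dbs_placed = sum(clone_recs$source == "compound" &
                               clone_recs$class == "DBS78"),
            id_placed = sum(clone_recs$source == "compound" &
                              clone_recs$class == "ID83"),
            background_sbs = sum(clone_recs$source == "background" &
                                   clone_recs$class == "SBS96"),
            stringsAsFactors = FALSE)
        }
      }
      groups[[gid]] <- clone_group(gid, members, parental_keys)
    }

    # files written after all placements: synthesis may have edited contigs
    fasta <- file.path(out_dir, "reference.fasta")
    write_fasta(genome, fasta)
    parental_vcf <- file.path(out_dir, "parental.vcf")
    write_vcf(par_recs, parental_vcf, lens)
    manifest <- file.path(out_dir, "manifest.tsv")
    write_manifest(groups, manifest)

    truth_df <- do.call(rbind, truth_mut)
    rownames(truth_df) <- NULL
    burdens_df <- do.call(rbind, burdens)
    rownames(burdens_df) <- NULL
    utils::write.table(burdens_df, file.path(out_dir, "truth_burdens.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
    utils::write.table(truth_df, file.path(out_dir, "truth_mutations.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)

    # true mixture spectra per axis for treatments with nonzero burden
    mixtures <- list()
    for (ax in c("SBS96", "DBS78", "ID83")) {
      cols <- list()
      for (gid in names(config$groups))
        for (label in names(config$groups[[gid]])) {
          tr <- config$groups[[gid]][[label]]
          if (tr[[ax]]$burden > 0)
            cols[[label]] <- mixture_vector(ax, tr[[ax]]$mixture, signatures)
        }
      if (length(cols) > 0) {
        m <- do.call(cbind, cols)
        mixtures[[ax]] <- m
        write_matrix(m, file.path(out_dir,
                                  paste0("truth_signature_",
                                         tolower(ax), ".tsv")))
      }
    }

    structure(list(dir = out_dir, fasta = fasta, vcfs = vcf_paths,
                   manifest = manifest, parental_vcf = parental_vcf,
                   groups = groups, genome = genome,
                   truth = list(burdens = burdens_df,
                                mutations = truth_df,
                                mixtures = mixtures),
                   n_synthesized_sites = n_synth,
                   config = config),
              class = "clonal_simulation")
  })
}

#' @export
print.clonal_simulation <- function(x, ...) {
  cat("<clonal_simulation>", length(x$vcfs), "clones in",
      length(x$groups), "groups;",
      nrow(x$truth$mutations), "mutations placed (",
      x$n_synthesized_sites, "synthesized context sites )\n")
  cat("  output:", x$dir, "\n")
  invisible(x)
}
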