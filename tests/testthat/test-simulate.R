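test_that("placed mutations reclassify to their requested channel on every axis", {
  g <- generate_reference(100000, 1, 0.41, seed = 2)
  mask <- clonespect:::new_mask()
  set.seed(1)
  n_synth <- 0
  for (ax in c("SBS96", "DBS78", "ID83")) {
    for (ch in channel_axis(ax)$channels) {
      r <- place_mutation(g, ch, ax, mask = mask)
      if (isTRUE(attr(r, "synthesized"))) {
        n_synth <- n_synth + 1
        g <- attr(r, "genome")
      }
      got <- switch(ax,
                    SBS96 = classify_sbs(r, g)$channel,
                    DBS78 = classify_dbs(r)$channel,
                    ID83  = classify_indel(r, g)$channel)
      expect_equal(got, ch)
    }
  }
  # rare repeat/microhomology contexts may be synthesized, never the
  # abundant substitution contexts
  expect_lt(n_synth, 40)
})

test_that("placement fails loudly on a degenerate genome lacking the context", {
  g <- ref_genome(c(chr1 = strrep("G", 500)))
  expect_error(place_mutation(g, "A[C>A]A", "SBS96"), "no genomic site")
})

test_that("simulation is deterministic and respects the experiment layout", {
  cfg <- simulation_config(
    genome = list(total_length = 60000, n_contigs = 2, gc_fraction = 0.41),
    groups = list(g1 = list(CMPD = exposure(
      sbs_burden = 60, sbs_mixture = c(mnng_like = 1)))),
    clones_per_condition = 2,
    background = exposure(sbs_burden = 30),
    n_parental_variants = 12, seed = 5)
  d1 <- withr::local_tempdir()
  d2 <- withr::local_tempdir()
  s1 <- simulate_experiment(cfg, d1)
  s2 <- simulate_experiment(cfg, d2)
  # identical seed: byte-identical FASTA and VCFs
  expect_identical(readLines(s1$fasta), readLines(s2$fasta))
  for (cl in names(s1$vcfs))
    expect_identical(readLines(s1$vcfs[[cl]]), readLines(s2$vcfs[[cl]]))

  # every clone carries every parental variant
  par_keys <- variant_key(read_vcf(s1$parental_vcf, "p"))
  expect_length(par_keys, 12)
  for (cl in names(s1$vcfs)) {
    keys <- variant_key(read_vcf(s1$vcfs[[cl]], cl))
    expect_true(all(par_keys %in% keys))
  }
  # truth labels partition every emitted record
  tm <- s1$truth$mutations
  expect_setequal(unique(tm$source), c("parental", "background", "compound"))
  for (cl in names(s1$vcfs))
    expect_equal(sum(tm$clone_id == cl),
                 nrow(read_vcf(s1$vcfs[[cl]], cl)))
  # control clones carry no compound mutations
  ctrl <- grep("control", names(s1$vcfs), value = TRUE)
  expect_length(ctrl, 2)
  expect_equal(sum(tm$source == "compound" & tm$clone_id %in% ctrl), 0)
})

test_that("zero burdens leave only parental variants in every clone", {
  cfg <- simulation_config(
    genome = list(total_length = 20000, n_contigs = 1, gc_fraction = 0.5),
    groups = list(g1 = list(NULLC = exposure())),
    clones_per_condition = 2,
    background = exposure(),
    n_parental_variants = 5, seed = 3)
  sim <- simulate_experiment(cfg, withr::local_tempdir())
  par_keys <- variant_key(read_vcf(sim$parental_vcf, "p"))
  for (cl in names(sim$vcfs)) {
    keys <- variant_key(read_vcf(sim$vcfs[[cl]], cl))
    expect_setequal(keys, par_keys)
  }
})

test_that("realized burdens follow the configured Poisson means", {
  cfg <- tiny_config(seed = 23, sbs_burden = 400)
  sim <- simulate_experiment(cfg, withr::local_tempdir())
  b <- sim$truth$burdens
  tr <- b[b$treatment == "CMPD", ]
  # within 4 SD of Poisson(400) per clone
  expect_true(all(abs(tr$sbs_placed - 400) < 4 * sqrt(400)))
  expect_true(all(abs(b$background_sbs - 100) < 4 * sqrt(100)))
  # single-channel treatment mixture: all compound mutations on one channel
  one <- simulation_config(
    genome = list(total_length = 50000, n_contigs = 1, gc_fraction = 0.41),
    groups = list(g1 = list(MONO = exposure(
      sbs_burden = 40,
      sbs_mixture = c(flat = 0, mnng_like = 0, bap_like = 0,
                      oxidative_like = 0, norharmane_like = 0,
                      nnk_acetate_like = 1)))),
    clones_per_condition = 1, background = exposure(),
    n_parental_variants = 0, seed = 4)
  expect_error(simulation_config(
    genome = list(total_length = 100, n_contigs = 1, gc_fraction = 0.5),
    groups = list(g = list(X = exposure(
      sbs_burden = 1, sbs_mixture = c(flat = 0.5)))), seed = 1),
    "sum to 1")
})

test_that("configs round-trip through YAML", {
  cfg <- default_simulation_config(seed = 77, genome_length = 123456)
  path <- withr::local_tempfile(fileext = ".yaml")
  write_simulation_config(cfg, path)
  back <- read_simulation_config(path)
  expect_equal(back$seed, cfg$seed)
  expect_equal(back$genome$total_length, cfg$genome$total_length)
  expect_equal(back$groups$group3$BaP$SBS96$burden,
               cfg$groups$group3$BaP$SBS96$burden)
  expect_equal(back$groups$group1$MNNG$SBS96$mixture,
               cfg$groups$group1$MNNG$SBS96$mixture)
})
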