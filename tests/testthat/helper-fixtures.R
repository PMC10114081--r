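# Shared fixtures, built in code at test time.

tiny_genome <- function(seqs = c(chr1 = "ACGTACGTACGTACGTACGT")) {
  ref_genome(seqs)
}

random_genome <- function(n = 10000, seed = 42, gc = 0.41, contigs = 1) {
  generate_reference(n, contigs, gc, seed = seed)
}

# brute-force carrier-counting oracle for colony exclusivity
exclusive_oracle <- function(records) {
  keys <- variant_key(records)
  keep <- logical(nrow(records))
  for (i in seq_len(nrow(records))) {
    carriers <- unique(records$clone_id[keys == keys[i]])
    keep[i] <- length(carriers) == 1
  }
  records[keep & !duplicated(paste(keys, records$clone_id)), , drop = FALSE]
}

# small two-clone experiment config for fast end-to-end tests
tiny_config <- function(seed = 11, sbs_burden = 400) {
  simulation_config(
    genome = list(total_length = 2e5, n_contigs = 1, gc_fraction = 0.41),
    groups = list(
      g1 = list(CMPD = exposure_fixture(sbs_burden))),
    clones_per_condition = 3,
    background = exposure(sbs_burden = 100),
    n_parental_variants = 40,
    seed = seed)
}

exposure_fixture <- function(sbs_burden) {
  exposure(sbs_burden = sbs_burden, sbs_mixture = c(mnng_like = 1))
}

expect_same_records <- function(a, b) {
  expect_setequal(variant_key(a), variant_key(b))
}
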