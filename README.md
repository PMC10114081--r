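# clonespect

Dissection of per-compound mutational signatures from clonally expanded
mutant genomes.

## The problem

In a clonal-expansion mutagenesis assay, single cells are exposed to a
candidate mutagen at a fixed dose (vehicle controls in parallel), grown into
colonies, and whole-genome sequenced — five independent clones per
condition. Each colony's *private* mutations record the mutational process
that acted in its founding cell. `clonespect` turns per-clone variant calls
into per-compound mutational signatures:

1. **Colony-exclusive selection** — remove parental-clone variants, then
   keep a mutation for a colony only if it was called exclusively in that
   colony within its joint-calling group (controls included in the carrier
   census).
2. **Classification** — map mutations onto the canonical COSMIC-style
   channel axes:
   * **SBS96**: the 6 pyrimidine-centered substitution types
     (C>A, C>G, C>T, T>A, T>C, T>G) × 16 flanking trinucleotide contexts,
     `X[C>A]Y`; purine-centered events are reverse-complement collapsed;
   * **DBS78**: doublet substitutions (adjacent SNV pairs merged; runs of
     3+ excluded), reverse-complement canonicalized, `CC>AA`;
   * **ID83**: small indels (1–50 bp) binned by size, homopolymer run
     length, tandem-repeat copy number and microhomology length,
     `1:Del:T:3`.
3. **Control subtraction and aggregation** — per treatment clone, subtract
   the mean spectrum of the group's vehicle-control clones channel-wise
   (clamped at zero), average over the biological replicates, and normalize:
   the compound's signature is
   `P = normalize( mean_clones( max(0, clone − control_mean) ) )`.
4. **Catalog comparison** — rank the signature against reference catalogs
   (COSMIC-format TSV) by cosine similarity
   `cos(a, b) = Σ aᵢbᵢ / (‖a‖‖b‖)`, flagging matches at ≥ 0.8.

A synthetic-experiment simulator (`simulate_experiment()`) generates
complete inputs — reference FASTA, per-clone VCFs, group manifest, parental
VCF — from known per-clone burdens and channel distributions, with full
ground truth, so the entire analysis validates end to end without any
sequencing data.

## Worked example

Simulate a one-group experiment (three treatment clones at 400 compound SBS
per clone over a 750→100-scaled background) and dissect it:

```r
library(clonespect)

cfg <- simulation_config(
  genome = list(total_length = 2e5, n_contigs = 1, gc_fraction = 0.41),
  groups = list(g1 = list(CMPD = exposure(
    sbs_burden = 400, sbs_mixture = c(mnng_like = 1)))),
  clones_per_condition = 3,
  background = exposure(sbs_burden = 100),
  n_parental_variants = 40, seed = 11)

sim <- simulate_experiment(cfg, "sim_demo")
rep <- run_dissection(file.path(sim$dir, "vcfs"), sim$fasta,
                      sim$manifest, sim$parental_vcf, out_dir = "out_demo")
rep
#> <dissection_report> clonespect 0.1.0
#>   clones: 6 | count conservation: exact
#>   SBS burden after control subtraction (mean over clones):
#>     CMPD                  400.9  (sd 16.6)

cosine_similarity(rep$signatures$SBS96$CMPD$counts,
                  sim$truth$mixtures$SBS96[, "CMPD"])
#> [1] 0.9830137
```

Reading the output: each clone carried its 40 parental variants plus ~100
endogenous background mutations plus ~400 compound mutations; after
parental removal, exclusivity filtering and control subtraction the
recovered mean burden is 400.9 (the configured 400 plus clamped subtraction
noise), and the recovered 96-channel signature matches the simulated
compound's true channel distribution at cosine 0.983. `rep$ledger` itemizes
every input record per clone (parental-removed, non-exclusive, classified
per axis, unclassifiable, excluded runs); the totals reconcile exactly.

For real data, point `run_dissection()` at a directory of `<clone_id>.vcf`
files, a manifest TSV (`clone_id`, `group_id`, `treatment` with controls
labeled `control`), the reference FASTA, optionally a parental VCF, and
reference catalogs read with `read_catalog()`.

A thin CLI over the same functions is installed at
`system.file("cli", "clonespect-cli.R", package = "clonespect")` with
subcommands `simulate`, `run` and `compare`.

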