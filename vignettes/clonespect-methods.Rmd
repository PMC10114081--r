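---
title: "Dissecting per-compound mutational signatures from clonally expanded genomes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Dissecting per-compound mutational signatures from clonally expanded genomes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(clonespect)
```

## The problem

In a clonal-expansion mutagenesis assay, single cells are exposed to a
candidate mutagen (or to vehicle control), expanded into colonies, and
whole-genome sequenced. Because each colony descends from one exposed cell,
the private mutations of a colony record the mutational process acting in
that cell. `clonespect` implements the downstream analysis of such an
experiment, starting from per-clone variant calls (VCF):

1. **Variant selection.** Variants present in the parental clone are
   removed; then, within each joint-calling group, a mutation is kept for a
   colony only if it was called *exclusively* in that colony. Shared calls
   are either pre-existing variation or systematic calling artifacts, not
   exposure-induced mutations.
2. **Classification.** Retained mutations are classified on the three
   canonical COSMIC-style channel axes: SBS96 (single-base substitutions by
   pyrimidine-centered substitution type and trinucleotide context), DBS78
   (doublet substitutions, reverse-complement collapsed) and ID83 (small
   indels by size, homopolymer run length, tandem-repeat copy number and
   microhomology).
3. **Spectra.** Per-clone channel counts are turned into per-compound
   signatures: the mean control spectrum is subtracted channel-wise from
   each treatment clone (clamping at zero), the subtracted spectra are
   averaged over the five biological replicates, and the result is
   normalized to a probability vector.
4. **Comparison.** Derived signatures are ranked against reference
   signature catalogs by cosine similarity, with 0.8 as the default
   threshold for calling two signatures similar.

Because the real assay needs whole-genome sequencing of dozens of clones,
the package ships a synthetic-experiment simulator that generates the
complete input set (reference FASTA, per-clone VCFs, manifest, parental
VCF) from known ground truth, so the whole pipeline can be exercised and
validated end to end on a desktop.

## Variant selection model

A mutation is identified by its key `contig:pos:ref:alt`; genotype and
quality fields are deliberately ignored (call quality is the variant
caller's job, upstream of this pipeline). Two rules are applied in order:

* **Parental removal first.** Parental variants are shared by construction;
  removing them first makes the per-clone counts of the later exclusivity
  step interpretable.
* **Exclusivity across the whole group.** The carrier census counts *all*
  colonies of the joint-calling group, controls and other treatments
  included. This is the strictest reading of colony-exclusive selection and
  best suppresses shared artifacts. Restricting the census to
  same-treatment clones is available via `carrier_scope = "same_treatment"`
  in `select_exclusive()` for users who prefer the laxer interpretation.
* Heterozygous and homozygous calls at the same key count as the same key.

## Classification conventions

All coordinates are 1-based and inclusive, matching VCF `POS`.

* **Strand collapsing.** Substitutions with a purine reference base are
  reverse-complemented (context and alternate allele) before naming, so all
  96 SBS channels are pyrimidine-centered. Classifying a mutation and its
  mirror image on the reverse-complemented genome gives identical channels
  (an involution, enforced by a property test over 10,000 random SNVs).
* **N and contig-end policy.** Any classification window that contains `N`
  or extends past a contig end makes the mutation *unclassifiable*: it is
  counted and reported, never guessed.
* **Doublets.** Two SNVs of one clone at adjacent positions are merged into
  one doublet before SBS counting; runs of three or more consecutive
  mutated positions are excluded from both axes entirely (preventing double
  counting) and reported. Native length-2 MNV records are accepted as
  doublets directly. A doublet is never also counted as two SBS.
* **Indels.** Events are left-aligned against the reference before
  classification (VCF does not guarantee it, and every ID83 bin depends on
  it). For 1 bp events the deleted/inserted base is collapsed to C/T;
  deletion homopolymer length *includes* the deleted base (bins 1–6+,
  0-based name fields), insertion repeat count *excludes* the inserted base
  (bins 0–5+). Deletions of 2+ bp with at least one additional full
  flanking copy of the fragment go to tandem-repeat channels; with no full
  copy but partial flanking identity to microhomology channels (the
  microhomology is the longer of the fragment-prefix match into the right
  flank and the fragment-suffix match into the left flank). Fragments over
  50 bp, and complex substitutions, are unclassifiable. The channel-name
  tables are frozen (shipped under `inst/extdata/channels/`) so tests are
  bit-exact.

## Spectra and control subtraction

Endogenous mutations accumulate during clonal expansion regardless of
exposure; vehicle-control clones measure that background. The default
composition for a per-compound signature is

> probability( mean over clones( max(0, clone − control mean) ) )

i.e. subtraction happens **per clone before averaging**. Subtraction and
averaging do not commute once negative differences are clamped to zero; the
alternative order is available (`subtract_order = "aggregate"`) and the
default is the one that matches reporting means ± SD over five replicates.
Clamped channel counts are reported: heavy clamping is exactly what a
non-mutagenic compound looks like (treatment ≈ background), and the
residual "burden" left after clamped subtraction of two independent noisy
spectra is positive by construction — in the default simulation a
zero-burden compound still shows a residual of roughly 100 clamped counts
against a background of 750, which is why burdens are judged against the
background scale rather than against zero.

## Cosine comparison

Signatures are compared as whole vectors by cosine similarity,
`sum(a*b) / (|a| |b|)`, which is scale-invariant (counts and probabilities
score identically) and lies in [0, 1] for non-negative vectors. The
flagging threshold defaults to 0.8. A zero vector has no direction, so an
empty signature raises an error rather than silently scoring 0; all-zero
spectra carry an explicit flag from `to_probability()`. No refitting or
attribution (e.g. non-negative least squares over a catalog) is performed:
the method compares whole signatures only.

## The simulator

`simulate_experiment()` realizes the generative counterpart of the
pipeline. Its defaults *are* the study conditions: three joint-calling
groups with their own vehicle controls, five clones per condition, ~750
endogenous SBS per clone, 1000 parental SNVs shared by every clone, and
compound SBS burdens of 200 (norharmane-like), 700 (MNNG-like), 5500
(NNK-acetate-like) and 25,000 (BaP-like) per clone, with the BaP-like
compound additionally carrying a doublet load (0.7 per clone; most clones
have none) and an indel load (500 per clone) — all on a 5 Mb, 2-contig,
41% GC genome. Burden noise is Poisson (the minimal counting model when
only means ± SD are reported); a negative-binomial switch
(`overdispersion`) is available and off by default.

Channel distributions are drawn from packaged **synthetic** signatures
(`builtin_signatures()`). These are illustrative shapes with documented
qualitative structure — the BaP-like shape is C>A/C>T rich, the MNNG-like
shape is dominated by T>C preceded by a purine, the NNK-acetate-like shape
balances C>T/T>A/T>C/T>G with a 5' A preference, the norharmane-like shape
is similar to but not identical with the BaP-like one, and the BaP-like
indel shape concentrates on 1 bp C/T deletions and T insertions in
homopolymers. They are not values taken from any published catalog. The
endogenous SBS background is flat over the 96 channels by default, with an
"oxidative-like" C>A-enriched alternative packaged; the endogenous indel
background is homopolymer-dominated (1 bp slippage events), which is both
the realistic shape for culture-acquired indels and cheap to place.

**Placement** inverts classification: for each drawn channel the simulator
picks a uniformly random compatible site (from cached genome-wide context
indexes for substitutions; from homopolymer-run indexes, pattern search or
rejection sampling for indels) and emits a record guaranteed to classify
back to the channel. Rare tandem-repeat and microhomology contexts that a
random genome may lack are synthesized into an unused region (logged via
`n_synthesized_sites`); synthesis happens only in regions no other mutation
has touched, and every placement reserves its classification-relevant
window in a global collision mask. A consequence of the global mask is that
no two mutations — even in different clones — ever share or abut a site, so
cross-clone sharing comes only from the parental set. This is slightly
stricter than reality (independent clones can mutate the same site), but at
the simulated densities such coincidences would be vanishingly rare, and it
makes the exclusivity step's behavior exactly predictable in tests.

### What the simulator does not model

Read-level effects (sequencing error, coverage, mapping), variant-caller
error and genotype uncertainty, selection during expansion, subclonality,
copy-number change, and regional mutation-rate heterogeneity. Passing the
end-to-end tests therefore demonstrates that the *analysis* is correct and
well-calibrated for clean calls — not that it is robust to caller artifacts,
which the colony-exclusivity filter only partially addresses.

## Problem sizes and frozen thresholds

The end-to-end recovery test simulates the full default design
(55 clones, ~250,000 mutations, 5 Mb genome) and checks cosine similarity
between each recovered compound signature and its true mixture: ≥ 0.95 for
burdens ≥ 5000, ≥ 0.8 for the 700-burden condition, and for the 200-burden
condition a frozen window (0.7, 0.95) demonstrating degraded recovery when
the compound burden is well below the 750-SBS background. These bounds were
fixed by a single pre-build calibration run (seed 1: 0.999 at 5500, 0.9998
at 25,000, 0.991 at 700, 0.88 at 200) and then left untouched. Module tests
use much smaller genomes (20–300 kb) chosen so that every context class is
still well represented.

## Numerical choices and degenerate inputs

* Catalog columns must sum to 1 within 1e-3 on read (then renormalized
  exactly); probability spectra sum to 1 within 1e-9.
* Ranking ties in `match_catalog()` keep catalog order (stable sort).
* Sample SD uses the n−1 denominator and is 0 for a single replicate.
* A genome with no site compatible with a requested channel (e.g. an all-G
  contig for a pyrimidine-context channel) is an error, as is collision
  exhaustion when the requested burden no longer fits the genome.
* Duplicate records of one key within a clone are collapsed during
  exclusivity selection; a key is never emitted for two clones.

## Known limitations

* Exclusivity treats the joint-calling group as the artifact-sharing unit;
  artifacts shared across groups (e.g. reference errors) are only removed
  if present in the parental set.
* The 192-channel transcription-strand-resolved classification and SV /
  copy-number classes are out of scope.
* Signature *attribution* (decomposing a spectrum into catalog
  signatures) is deliberately not provided; only whole-signature
  comparison.
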