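---
title: "zygopir: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{zygopir: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE, collapse = TRUE, comment = "#>")
```

This vignette is the package's own account of the science it implements:
the models, the assumptions behind the synthetic-data generators, the
tunable parameters, the numerical conventions, and the limits of what a
green test suite demonstrates.

## 1. Background and scope

In the P–M system of *Drosophila melanogaster*, paternally inherited
P-element transposons are mobilized in progeny of M-strain mothers,
producing gonadal dysgenesis (GD). Repression is driven by zygotically
produced P-element piRNAs — possible when paternal copies sit inside piRNA
clusters — and by repressor proteins from internally deleted variants,
most prominently KP. The package implements the computational chain from
raw junction-library and small-RNA reads to the statistical association of
molecular measurements with GD phenotypes, plus a synthetic-data module
that generates all inputs with recorded ground truth.

## 2. The element model

`make_element_model()` builds a seeded random 2907-bp consensus with
perfect 31-nt terminal inverted repeats (TIRs). Variants are named deletion
sets on consensus coordinates: FP has none; KP removes 808–2560 (1-based
inclusive), leaving 1154 bp. A deliberately synthetic consensus keeps the
package free of copyrighted reference data while preserving the
alignment-relevant geometry (length, TIRs, deletion junctions).

Two generator properties are assay-design choices rather than randomness:

* **Guaranteed restriction sites.** One recognition site per junction-assay
  enzyme is implanted at a fixed distance from each terminus (GCGC at
  320 bp, TCGA at 180 bp). The real protocol's enzymes were chosen because
  the element offers usable sites near its ends; a fully random 2907-mer
  sometimes does not, which would make entire simulated lines invisible to
  the assay for reasons that have nothing to do with the pipeline under
  test. Both distances lie outside the KP deletion and beyond the nested
  primer, so all variants remain assay substrates.
* **Perfect TIRs and their consequences.** Because the last 31 bases are
  the reverse complement of the first 31, any terminal element fragment of
  ≤ 31 bases is identical at both ends. The junction extractor therefore
  resolves element orientation from up to 60 junction-proximal element
  bases and discards (rare) reads whose element segment lies entirely
  within the TIR as orientation-ambiguous.

## 3. Variant typing and the qPCR layer

`classify_variant()` anchors unique exact 15-mers of the query on the
consensus, chains them greedily in increasing consensus order, and reports
consensus coverage gaps of ≥ 20 bp between adjacent anchors as deletion
intervals. FP ⇔ no deletions; KP ⇔ exactly one deletion matching the
808/2560 junctions within ±3 bp (absorbing junction microhomology); other
patterns are `other-deleted`; queries with no anchors are `unknown`. Both
query strands are tried. With unique k-mers and error-free queries the
recovered junctions are exact to the base, which the tests assert.

`amplicon_products()` maps a primer pair given as consensus coordinates
onto a template's deletions: a primer coordinate inside a deletion means no
product; otherwise the product shrinks by the deleted bases between the
primers. Primer coordinates are configuration, not constants, because
published product sizes cannot be reconstructed without the original primer
sequences; the default total-P pair spans positions 1–2526 so the
full-length template yields a 2526-bp product.

`relative_copy_number()` is the standard ΔΔCt with amplification
efficiency fixed at 2.0: per strain, ΔCt = mean Ct(target) − mean
Ct(single-copy reference gene); relative abundance
= 2^−(ΔCt − ΔCt(reference strain)). It is exactly invariant under a
constant Ct shift, and `kp_fraction()` = 100·KP/total, capped at 100 %.

## 4. The junction assay: simulator and caller

**Simulator.** For each planted insertion, each of `pool_size` (default 40)
individuals carries it independently with probability equal to its
occupancy — the Bernoulli-pool model of insertional polymorphism. For each
carried insertion and each enzyme (defaults GCGC and TCGA), both junctions
produce a restriction fragment running from the nearest internal element
site, across the junction, to the nearest flanking genomic site; fragments
outside the 300–600-bp size-selection window are discarded. The sequenced
template models the nested element-specific PCR: it begins at an element
primer `primer_offset` (default 100) bp from the terminus — a junction is
amplifiable only when its internal cut lies beyond the primer — and ends at
a fixed 30-mer adapter ligated at the genomic cut. Read 1 is the
element-anchored end (250 bp), read 2 the reverse complement of the other
end; reads truncate at short templates. Uniform substitution errors are
optional. Read-pair counts per fragment are Poisson with mean
carriers × `mean_depth_per_individual`.

The truth bundle records, per insertion: fragments passing size selection,
fragments whose template exposes enough flank to be mapped, carriers, and
emitted / recoverable / mappable pair counts. *Recoverable* means read 1
shows the junction plus ≥ 20 bp of flank with > 31 bp of element anchor;
*mappable* additionally requires ≥ 31 bp of flank (the mapper seed). These
are deterministic fragment properties, so truth-based comparisons are
exact.

**Caller.** `extract_junction_reads()` keeps pairs with a
≥ `min_element_match` (default 20) exact terminal element match on either
strand, orients them against the two 60-bp terminal contexts, trims element
and adapter bases, and returns flanks of ≥ 20 bp. `map_flanks()` looks up
the junction-proximal 31-mer exactly in the genome (both strands) and
extends across the full flank allowing ≤ 2 mismatches; several equally good
loci ⇒ unmapped (ambiguous multi-mappers are dropped, the conservative
choice). Positions are reported at the genome base adjacent to the element,
so the two junctions of one insertion map to the same coordinate.
`cluster_sites()` merges same-chromosome, same-orientation positions within
`merge_window` (default 10 bp; this also absorbs the unmodeled 8-bp target
site duplication) at the read-weighted modal position, ties toward the
smaller coordinate. `compute_occupancy()` divides each site's supporting
reads by the total element-supporting reads — "total reads" is interpreted
as element-supporting reads, which makes the fractions well defined — and
`assign_region_state()` labels sites active (track score > 0), silent
(score = 0) or unknown (uncovered position).

**What recall means here.** Recovery statistics (`compare_to_truth()`) are
computed against *assay-detectable* insertions: those whose truth records at
least one mappable pair. An insertion whose restriction fragments all fall
outside the size window, or expose almost no flank, is invisible to this
assay by construction — as it would be to the real protocol — and does not
belong in the denominator of a test of the *caller*.

## 5. piRNA clusters and membership

Cluster classification follows two fixed rules: dual-strand iff both strand
fractions are strictly > 20.0 % (threshold configurable), otherwise
unistrand with the majority strand as precursor; and activity = the top 15
clusters by cluster-unique piRNA count (stable sort, ties broken by
lexicographic cluster id so results are order-independent). Membership uses
point containment of the insertion position; overlapping clusters resolve
to the smallest interval. Orientation relative to the precursor is recorded
for unistrand clusters only — both strands of a dual-strand cluster are
transcribed, so sense/antisense is not meaningful there — and
`cluster_read_fraction()` is the in-cluster share of element-supporting
reads.

## 6. Small RNAs: simulator and quantification

**Simulator.** Only cluster-embedded insertions produce element piRNAs.
For a unistrand cluster, an element antisense to precursor transcription
yields antisense piRNAs at the cluster rate, plus cleavage-derived sense
piRNAs at `sense_fraction` (default 0.5) of that rate — a fixed-fraction
stand-in for sense piRNA production from cleaved element mRNA; a sense
element yields sense piRNAs. Dual-strand clusters produce both strands at
the full rate. Rates are `pirna_rate(rank)` (defaults 2000 reads for
active, 200 for low clusters, per unit occupancy), Poisson-sampled. piRNA
lengths are uniform on 24–35 nt; windows are drawn only from consensus
segments present in the variant and outside the TIRs, so every simulated
read has a unique, strand-unambiguous exact consensus match and mapped
counts conserve truth exactly (junction-spanning and TIR reads, a tiny
minority in reality, are not modeled). miRNA reads are drawn from a bundled
*synthetic* decoy set (40 sequences, 21–23 nt); random genomic degradation
fragments (18–50 nt) provide filterable background. Reads are emitted
adapter-trimmed at their RNA length (≤ 50 nt, the read length).

`embryo_mode` multiplies piRNA rates by `embryo_scale` (default 5e-4) and
the miRNA count by `embryo_mirna_factor` (default 5, on a 2×10⁵ default):
immediately after fertilization zygotic piRNA production has barely
started while the maternal miRNA pool is large, so the expected RPM drops
to single digits, against > 10³ in ovary mode.

**Quantification.** The canonical order is miRNA removal first (the
denominator counts every removed miRNA read regardless of length — the two
steps commute anyway whenever miRNA lengths lie outside 24–35 nt), then the
inclusive 24–35-nt size filter, then strand-aware mapping to the consensus
(exact by default, configurable to ≤ 3 mismatches). Hits are recorded at
the read's 5′-end consensus position (match start for sense, match end for
antisense); a multi-hit read is counted once at the lowest coordinate with
sense preferred on ties — a deterministic, recorded policy. RPM = element
reads × 10⁶ / miRNA reads, failing explicitly on a zero denominator.

## 7. Association statistics

* `pearson()`: sample correlation with the exact t-based two-sided p
  (n − 2 df), failing on zero variance or non-finite input.
* `multiple_regression()`: OLS via `stats::lm`. Because "standardized
  partial regression coefficient" is used in two senses in this
  literature, the result reports both `coef_zx` (response on z-scored
  predictors; recovers generative betas stated per predictor SD) and
  `std_coef` (response also z-scored; equals Pearson's R with a single
  predictor), along with the partial correlation r = t/√(t² + df).
  Small-n fits down to one residual degree of freedom are allowed — the
  motivating study design is five strains and two predictors — and rank
  deficiency fails explicitly.
* `hcluster()`: complete-linkage (furthest-neighbor) agglomeration on
  Euclidean distances over z-scored features, written in-package because
  the contract includes a deterministic tie-break (the candidate pair with
  the smallest member labels wins, heights compared with a 1e-12 slack),
  which makes the dendrogram invariant under permutation of the input rows
  — a property `stats::hclust` does not guarantee under ties.
  `stats::hclust` serves as the independent cross-check on tie-free random
  instances in the tests. Output is a standard `hclust` object; Newick
  export goes through `ape`.
* `t_test_groups()`: classical pooled-variance Student form by default
  (Welch by flag); the zero-variance degenerate cases return t = 0, p = 1
  (equal means) or |t| = ∞, p = 0.
* `label_phenotype()`: low iff GD strictly < 10.0 %, reported as
  inducibility for cross A and susceptibility for cross A*.
* No multiple-testing correction is applied anywhere, matching the
  analysis style this package reproduces.

## 8. The strain panel generator

`simulate_strain_panel()` draws piRNA RPM, P mRNA and KP mRNA from
lognormal distributions and generates
GD% = 100·logistic(β₀ + β_piRNA·z(piRNA) + β_KP·z(KP) + ε), ε ~ N(0,
`noise_sd`), clamped to [0, 100] (the link already guarantees it). Defaults
β = (−3, −1) and `noise_sd` = 0.5 were fixed at design time: both
predictors are suppressors, with effect-to-noise ratios of 6 and 2 — strong
but noisy enough that a five-strain fit occasionally misranks the weaker
predictor, which is what makes the 100-panel sign-recovery property a real
test. F2 scores use a dampened (×0.5) linear predictor; cross-A*
susceptibility depends on the maternal piRNA level only.

## 9. Tunables

| Parameter | Default | Units | Meaning |
|---|---|---|---|
| `enzymes` | GCGC, TCGA | — | junction-assay recognition sites (HhaI, TaqI) |
| `read_length` | 250 | bp | paired-end junction read length |
| `pool_size` | 40 | flies | pooled individuals per line |
| `size_range` | 300–600 | bp | restriction-fragment gel selection |
| `primer_offset` | 100 | bp | nested element primer to terminus |
| `min_element_match` | 20 | bp | terminal element anchor in a read |
| `map_k` | 31 | bp | flank mapping seed |
| `map_max_mismatch` | 2 | bases | flank extension tolerance |
| `merge_window` | 10 | bp | site consolidation window |
| `strandness_threshold` | 20.0 | % | minor-strand share for dual-strand calls |
| `n_active` | 15 | clusters | activity cutoff rank |
| `smallrna_min/max_len` | 24 / 35 | nt | piRNA size class (inclusive) |
| `smallrna_max_mismatch` | 0 | bases | consensus mapping tolerance |
| `sense_fraction` | 0.5 | — | cleavage-derived sense piRNA yield |
| `gd_criterion` | 10.0 | % GD | low/high phenotype threshold (strict <) |
| `beta_pirna`, `beta_kp`, `noise_sd` | −3, −1, 0.5 | per SD / logit | panel generative model |

All of these live in `pipeline_config()`, which round-trips losslessly
through YAML; a single seed drives every generator (each one restores the
session RNG state afterwards).

## 10. Problem sizes and numerical conventions

The test suite and `scripts/acceptance.R` run at sizes chosen to make the
properties sharp while keeping a full run in the order of a minute per
suite: a 5-Mb, 5-chromosome genome with 20 planted insertions at ≥ 50×
effective depth for site recovery; a 40-fly pool at occupancies 1.0 / 0.5 /
0.25 for occupancy recovery (3-standard-deviation binomial + Poisson
bands); ~10⁵ small-RNA reads for exact count conservation; 20 random
instances per statistic against longhand oracles at 1e-10; 100 five-strain
panels for sign recovery (≥ 95 expected negative). Coordinates are 1-based
inclusive in every user-facing table and 0-based only inside BED files;
ties are always broken deterministically (smallest coordinate, smallest
label, lexicographic id); degenerate inputs (zero reads, zero variance,
zero denominator, rank deficiency) fail with explicit messages rather than
propagating NaN, and the demo workflow captures per-stage failures and
reports them instead of aborting.

## 11. What the synthetic data does and does not show

The generators reproduce the *statistical structure* the pipeline must
handle: insertional polymorphism across a pooled line, restriction-fragment
size selection, element-anchored junction reads, cluster-dependent piRNA
production with strand logic, an miRNA normalization denominator, and a
logistic phenotype link with suppressor signs. They deliberately do not
reproduce: real chromosome sequence (so no repeat-induced multi-mapping
beyond planted duplications), PCR duplicates or amplification bias,
sequencing error models beyond uniform substitution, target-site
duplications, junction-spanning or TIR-derived small RNAs, ping-pong
signatures, or the unknown pool composition of real lines (the Bernoulli
pool is an assumption). A green suite therefore demonstrates correctness of
the *computational* chain under controlled conditions, not performance on
real libraries; on real data the conservative choices (ambiguous reads
dropped, exact matching defaults) trade sensitivity for precision.

## 12. Known limitations

* The variant typer assumes collinear queries (no inversions or
  duplications) and reports deletions only at ≥ 20 bp; indel-tolerant
  alignment is out of scope.
* Genome-wide TE discovery (split-read/discordant-pair scanning) is out of
  scope; the caller targets the element whose model it is given.
* `hcluster()` is quadratic-per-merge and intended for strain-panel sizes
  (tens of rows), not large matrices.
* The CLI is a thin wrapper for the demo workflow and single-stage runs;
  it is not a workflow engine.
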