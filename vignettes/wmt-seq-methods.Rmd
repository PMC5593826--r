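---
title: "Whole-mitochondrial-genome amplicon tracking: model and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Whole-mitochondrial-genome amplicon tracking: model and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(mttrack)
library(dplyr)
```

## Scope and model

`mttrack` implements the computational arm of a whole-mitochondrial-genome
(wmt-seq) amplicon workflow for tracking tumour clonality across multiple
lesions of the same patient. Mitochondrial DNA is a useful lineage marker:
it is small (16,569 bp), present in hundreds to thousands of copies per
cell, and somatic mtDNA mutations drift to high allele fractions, so they
are detectable at modest sequencing cost. If several tumour nodules share a
somatic mtDNA mutation, they almost certainly descend from one founding
clone; if each nodule carries only its own mutations, independent origin is
the parsimonious reading.

The package covers five stages:

1. **Panel design** on the circular genome: tiling amplicons with
   controlled insert length and neighbour overlap, plus PCR pool assignment
   so that overlapping amplicons never share a pool.
2. **Read simulation**: a synthetic FFPE-mtDNA cohort generator with a
   clonal-tree ground truth, used in place of deposited patient FASTQs.
3. **Ultra-deep variant calling** from primer-exact read assignment and a
   per-position pileup.
4. **False-variant heuristics** that flag (never delete) suspicious calls.
5. **Clonality analysis**: trunk/branch/private classification, clonal-tree
   reconstruction, and a monoclonal / independent / untrackable verdict.

## Coordinates and the circular genome

All user-facing coordinates are 1-based and inclusive. A region with
`start > end` wraps the origin of the circular map; the control region
(D-LOOP) spans 16024–576 and contains both position 16100 and position
300. At I/O boundaries (BED export) coordinates become 0-based half-open
and wrapping intervals split into two records with the same name. This
keeps the internal arithmetic uniform (`position_in_region()` is a single
branch on `start <= end`) while emitted files remain consumable by
standard genome-arithmetic tools.

The packaged reference is a deterministic synthetic stand-in with the rCRS
geometry (16,569 bp) and realistic base composition, including the two
hypermutable microsatellite stretches (16184–16193 poly-C with T at 16189,
and 303–315 with T at 310). It is generated by a pinned linear
congruential generator so the FASTA under `inst/extdata/` and
`synthetic_mt_reference()` agree byte for byte; no licensed sequence is
redistributed.

## Panel design and pooling

`design_panel()` places `n` amplicon inserts at starts
`floor((i-1)*L/n) + 1`, so the steps differ by at most 1 bp and the panel
closes the circle with the last insert wrapping the origin. The realised
neighbour overlap is `max(min_overlap, round(mean_length - L/n))`; with
the defaults (108 amplicons, mean 160 bp) that is 7 bp and inserts are
160–161 bp. Primers are the 22-bp reference flanks of each insert, the
reverse primer reverse-complemented.

`assign_pools()` greedily colours the amplicon overlap graph, always
assigning the least-filled admissible pool. A chain (cycle) of pairwise
overlapping neighbours is 2-colourable when even, so 4 pools with 108
amplicons yield a perfectly balanced 27/27/27/27 split; the round-robin
outcome is deterministic and verified against an all-pairs brute-force
overlap check in the tests. A single pool is correctly rejected as
unsatisfiable when any two amplicons overlap.

## The simulator as the study stand-in

`sim_config()` defaults encode the emulated study: multi-lesion FFPE
patients, a handful of homoplasmic germline polymorphisms drawn from the
packaged snapshot, heteroplasmic somatic variants with a Beta(0.8, 0.8)
VAF law truncated at 0.05 (bimodal toward the extremes, matching the
observation that mt-variants are mostly homoplasmic or strongly
heteroplasmic), 0.5% template deamination (the FFPE C>T/G>A artifact),
0.1% per-read sequencing error, 2.5% off-target pairs, and planted
sub-1%-VAF deamination artifact sites.

Realism choices that matter downstream:

* **Deamination is applied to the template fragment before mates are
  generated**, so both mates of a pair share the event and artifact
  support is strand-balanced — exactly why the strand-balance predicate
  alone cannot remove FFPE artifacts and a VAF floor is needed.
* **Planted alleles are fragment-level** (probability `true_vaf` per
  fragment, shared by both mates). The independent sampling unit of the
  observed VAF is therefore the fragment, not the read; both mates span
  the full insert, so pileup depth is exactly twice the pair count and
  the effective binomial sample size is `depth / 2`.
* **Primer bases are error-free**, which makes read-to-amplicon
  assignment by exact 22-bp primer prefix lossless. Real data would need
  tolerant matching; the package treats assignment fidelity as out of
  scope and counts unassignable pairs as off-target.
* Simulated clonal trees are random rooted binary-split trees over the
  patient's lesions; with only two lesions there is no internal edge and
  branch plants are re-allocated to trunk/private with a warning.

Limits: the generator does not model NUMT contamination (delegated to the
upstream aligner in the emulated study), PCR duplicates, indel sequencing
errors, quality-score structure, or length-variable microsatellite
stutter; planted sites avoid primer footprints, insert ends and
microsatellites so that ground truth is not confounded with the
position-based heuristics under test.

## Variant calling

`assign_and_pileup()` strips primers, orients reads, and builds a
per-position allele/strand count table. Reads whose length matches the
insert are counted directly; off-length reads (indel carriers) are
globally aligned to their amplicon insert with `Biostrings`
(gap opening 10, gap extension 4). For speed, identical fragments are
deduplicated before alignment and indel coordinates are taken from the
alignment's `indel()` ranges rather than from gapped-string extraction,
which is orders of magnitude more expensive per read.

Indels are canonicalised by **left alignment**: a deletion or insertion in
a repeat run is shifted to the leftmost equivalent position. The simulator
applies the same canonicalisation to planted truth, so labels
(`G3036A`, `66 del-G`, `12384^12385-ins C`) compare exactly.

A variant is called when, at its position, total depth ≥ 30
(insertion rows are not part of depth), alt fraction ≥ 5%, and it is
`PASS` when the minor-strand fraction of alt support is strictly greater
than 0.2 (otherwise `strand_imbalance`). The 5% VAF floor is what
suppresses the ≤1% deamination artifacts; at the emulated depths
(hundreds to thousands of fragments) the floor is far above the noise
band. The caller is tested for exact equality against a brute-force
oracle enumerating every (position, allele) pair.

Homoplasmy is declared at VAF ≥ 0.95 — a pragmatic convention
acknowledging that residual normal-tissue contamination in FFPE keeps
"true" homoplasmic variants slightly below 1.

## False-variant heuristics

Four heuristics annotate calls; none deletes a row:

* `recurrent_similar_vaf`: the same variant in ≥ 3 patients with a VAF
  spread ≤ 0.05 — a panel-level artifact signature. Known homoplasmic
  polymorphisms are exempt (they legitimately recur at VAF ≈ 1).
* `amplicon_end`: within 5 bp of an insert boundary in every covering
  amplicon; a position rescued by an overlapping neighbour's interior is
  exempt.
* `repetitive_region`: inside either microsatellite stretch.
* `noisy_region`: the position's background minor-allele fraction across
  non-carrier samples exceeds the cohort's 99th percentile (needs ≥ 3
  samples; the carrier's own signal never self-flags).

`apply_filters()` partitions calls into a `pass` table and a `review`
table carrying the flag provenance and a `needs_orthogonal_confirmation`
marker, reflecting the workflow in which flagged calls are verified by an
orthogonal assay rather than discarded.

## Polymorphism annotation

Annotation matches calls against a packaged, versioned snapshot of known
polymorphisms (MITOMAP/dbSNP/HAPMAP provenance, disease flags, including
the cancer-risk sites 10398 and 16189) by exact (position, ref, alt). No
live database is queried; the snapshot version travels as an attribute and
is echoed in the run log. Annotation is idempotent and never alters
filter or plasmy fields.

## Clonality

Germline polymorphisms are excluded from the somatic set by the heuristic
"annotated known polymorphism AND homoplasmic AND present in every lesion"
— no matched normal is assumed, mirroring the emulated study. Somatic
variants are classified by carrier count: `trunk` (all lesions),
`private` (one), `branch` (a proper subset of ≥ 2).

Carrier sets of a true clonal process are laminar (any two nested or
disjoint), which is equivalent to compatibility with a rooted tree.
`build_clonal_tree()` keeps a maximal laminar subfamily — greedily by
descending variant support, then larger set, then smaller minimum
position, so the outcome is deterministic — reports every crossing pair
as a conflict, and assembles the tree from the kept clades plus the full
lesion set and singletons.

Verdicts: `untrackable` (no somatic variants at all), `monoclonal` (≥ 1
trunk variant, proving a common cell of origin), otherwise `independent`.
A deliberate edge-case decision: a patient with branch but no trunk
variants is verdicted `independent` — a shared subset is evidence that
*some* lesions are related, but not that *all* lesions share one origin;
the branch counts remain in the evidence table so the nuance is visible.

`vaf_trend()` reports per-edge mean VAFs per carrier lesion; rising VAFs
down the tree (the packaged `preset_patient_05()` pattern, where TN2/TN3
share three branch mutations at VAFs growing from 0.30 to 0.45) are the
signature of accumulating mutations becoming dominant.

## Numerical and testing choices

* All randomness flows through R's RNG; `run_pipeline()` seeds once from
  the config and the full output tree (except `run.log`) is byte-identical
  between runs.
* Accuracy tests centre tolerances on the generator's *expected*
  read-level alt fraction (deamination gain/loss composed with the
  symmetric error channel) rather than the planted VAF, since a
  homoplasmic truth has zero binomial SE while any nonzero error rate
  shifts the observation; tolerance bands are exact binomial central
  99.73% intervals (the ±3 SE equivalent, correct in the skewed tail
  near homoplasmy) with the fragment count (`depth / 2`) as the sample
  size.
* Generator defaults are treated as study conditions: tests never tune
  simulation parameters or thresholds toward passing.

## Limitations

* The packaged reference is synthetic; results are method-level, not
  biological reproductions of the study's cohort numbers.
* Real-data ingestion is limited to FASTQ pairs with primer-exact
  assignment; aligned-BAM ingestion and NUMT handling are delegated
  upstream.
* The noise heuristic needs ≥ 3 samples and assumes comparable depth
  profiles across the cohort.
* Tree reconstruction resolves only clades witnessed by ≥ 1 somatic
  variant; edges without variant support are unrecoverable in principle.
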