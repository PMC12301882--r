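---
title: "Genotyping multiplex Cas12a knockouts: models and design choices"
author: "cas12mux"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Genotyping multiplex Cas12a knockouts: models and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(cas12mux)
```

# The problem

A single Cas12a construct carrying a tandem crRNA array can knock out many
genes in one transformation. In *Arabidopsis*, knocking out six clade A PP2C
phosphatases (HAI1, HAI2, HAI3, AHG1, AHG3, HAB2) — negative regulators of
ABA signalling — produces seeds that never germinate, so the germination
phenotype itself becomes a read-out of editing completeness. Scoring such an
experiment requires, per plant and per targeted gene, a zygosity call from
amplicon deep-sequencing reads; per plant, an aggregate multiplex genotype;
and per population, efficiency tallies stratified by germination behaviour.
`cas12mux` implements that full analysis plus the companion crRNA design
computations, with a synthetic-population generator in place of sequencing
data so that every stage is testable end to end.

# Zygosity model

For one plant at one gene, retained reads partition into a wild-type class
and mutant alleles (an allele = a canonical, ordered list of indel and
substitution events inside the calling window; two alleles are equal exactly
when their event lists are equal). With $f_1 \ge f_2 \ge \dots$ the mutant
allele read fractions and $f_{WT}$ the wild-type fraction
($\sum_i f_i + f_{WT} = 1$), the class is:

* **Ho** (homozygous): $f_1 \ge 0.95$
* **Bi** (biallelic): $\sum_i f_i \ge 0.95$ with at least two retained
  mutant alleles
* **WT**: no mutant allele retained
* **He** (heterozygous): $f_1 \ge 0.45$
* **Chi** (chimeric): everything else

The 95% and 45% read-share thresholds are the standard amplicon-HTS scoring
rule for T1 plants. Two interpretation points were genuinely open and are
resolved as follows:

* *Biallelic* means "at least 95% of reads are mutant, spread over two or
  more allele types". This matches diploid biology (two mutant chromosomes,
  PCR/sampling noise in the remainder) and makes He the natural complement
  (one mutant type plus a wild-type remainder).
* Wild-type reads are never counted as a "type of mutation", so the 45% He
  threshold applies to the top *mutant* allele only. A switch
  (`count_substitutions_as_mutant`) controls whether substitution-only reads
  count as mutant; the default treats them as wild type because the
  downstream loss-of-function logic is indel-driven and isolated
  substitutions are indistinguishable from sequencing error at these depths.

**Noise floor.** An allele is discarded — and its reads leave the
denominator — when it falls below both 5% of retained reads and 10 reads
(`allele_floor_fraction`, `allele_floor_reads`). Hi-throughput amplicon
counting pipelines apply comparable floors; the exact values are exposed as
parameters because no published values exist for this assay.

**No-call.** A pool with zero retained reads yields `no_call`, distinct
from WT; a plant with any no-call gene is excluded from sextuple tallies
rather than guessed.

# Read alignment and event extraction

Reads align to their amplicon semi-globally (read end-to-end, reference
end-gaps free) with match +2, mismatch −2, gap open −6, gap extend −1 — the
gap-heavy scoring appropriate for nuclease repair products. The dynamic
program is `Biostrings::pairwiseAlignment`; event extraction into 0-based
reference coordinates is this package's code, and each extracted event list
is required (and property-tested) to reconstruct the read exactly when
applied to the reference.

Numerical conventions:

* Equal-scoring indel placements are resolved to the **leftmost**
  equivalent position (the standard normalization), implemented as a
  post-alignment shift; without it, placements at the right edge of a
  repeat can fall outside the half-open calling window.
* Adjacent mismatches merge into one substitution run; a gap run is one
  event.
* Reads shorter than 30 nt, or with edited bases exceeding 20% of read
  length, are rejected with a reason code rather than silently dropped.
* The calling window is the spacer interval padded by 10 nt each side,
  clipped to the amplicon. Cas12a cleaves PAM-distal within the
  protospacer and repair outcomes spread around the cut; the pad absorbs
  both that spread and residual placement ambiguity. An event counts if
  any base lies inside the window.

For speed, pools are deduplicated before alignment (amplicon pools are
highly redundant), exact reference matches skip the aligner, and
same-length reads within Hamming distance 3 take a direct substitution
path — at these scores a substitution-only explanation is provably optimal
below four mismatches, since one insertion–deletion pair costs more than
three substitutions.

# Multiplex aggregation and germination

A plant is a **sextuple (no-WT) mutant** when all six targeted genes are Ho
or Bi, and **full loss-of-function** when additionally no retained allele
has a net indel length divisible by 3. In-frame (3×) alleles can retain
partial protein function, which is why sextuple mutants carrying one can
still germinate — late and often stunted. `predicted_type3 = is_full_lof`
is therefore a labeled genotype-based expectation, not a phenotype fact:
occasional plants germinate without any in-frame allele, plausibly because
some edits arose after germination commitment, and reports carry that
caveat.

Germination records classify as: Type-3, no germination within the
observation horizon (70 d); Type-2, germinated but stunted (long roots,
weak shoot); Type-0, germinated within 7 d; Type-1, delayed (day 14/21/28).

Heritability between generations is set logic on allele keys: a T2 gene
call is *heritable* when its allele set is a nonempty subset of the T1 set
(selfing can fix either allele of a biallelic plant), *novel-allele* when
T2 shows an allele T1 lacked, *inconsistent* when T2 is wild type where T1
had no wild-type allele to transmit.

# Efficiency tallies

Percentages print at one decimal with half-up rounding, which reproduces
the published ratios this package re-derives (45/61 → 73.8, 124/138 →
89.9). One transcription note: the source table prints 171/214 as 80.0%,
but 171/214 = 79.906…, which no half-up rounding produces; the package
prints the computed 79.9.

Two accounting rules deserve emphasis because the published totals are not
otherwise reproducible from their own per-type counts:

* Never-germinating (Type-3) seeds can be presumed sextuple mutants
  (`presume_type3_mutant`), justified when germinated siblings show
  near-complete editing and pooled HTS of stunted seedlings detects no
  wild-type reads.
* Seedlings that germinated but died before genotyping (`not_recovered`)
  are scored nonmutant within their germination type, but the overall
  estimate adds them to the mutant numerator under the same presumption —
  that is the arithmetic that yields 124/138 and 171/214 from per-type
  counts summing to 122/138 and 163/214.

Pooled samples (e.g. all stunted seedlings pooled into one library) are
scanned with the same clipping and floors; a pooled wild-type fraction at
or below `wt_noise_max` (0.5%) reads out as "all plants mutant-consistent",
explicitly labeled as pooled inference rather than per-plant genotype.

# The synthetic population generator

The generator emulates a T1 screen with known truth. Defaults define the
study conditions used throughout the tests:

| parameter | default | meaning |
|---|---|---|
| `n_plants` | 200 | T1 population size |
| genes | 6 synthetic 180-nt amplicons | spacer planted at a TTTV PAM |
| `class_probs` | WT .05, Ho .35, Bi .35, He .15, Chi .10 | per gene × plant |
| `depth` | 100 | reads per plant × gene |
| `substitution_error_rate` | 0.001 | per base, iid |
| indel sizes | deletions 1–30 nt (geometric, p=.15), insertions 1–10 nt (p=.3), deletions 70% | single indel per allele |
| `chimera_allele_count` | 4 | mutant alleles in a Chi plant |

The class mix reflects a highly efficient multiplex editor — mostly Ho/Bi
outcomes with minority He/Chi/WT — while still exercising every class.
Depth 100 is a typical per-target amplicon allocation in pooled HTS runs.

Archetypes are exact: Ho = one mutant allele at fraction 1; Bi = two
distinct mutant alleles at 0.5/0.5; He = mutant + WT at 0.5/0.5; Chi =
`chimera_allele_count` mutant alleles plus WT drawn from a flat simplex.
Read counts per allele are the largest-remainder quantization of
`fraction × depth` — truth stays analytically known and sampling jitter
enters only through the finite depth, not through multinomial resampling
(which would, at depth 100, scatter a true 50/50 heterozygote across the
45% threshold in a double-digit percentage of draws and make the truth
class meaningless).

Chi draws are rejection-sampled so that both the true fractions and their
depth-quantized counts keep every mutant allele below the He threshold, at
or above the caller's detection floor, and the mutant total below the Ho/Bi
threshold. A composition violating any of these at the configured depth has
no well-defined truth class — e.g. a top allele at 0.449 quantizes to 45/100
reads, exactly the He boundary — so such draws are excluded at generation
time instead of being scored as classification errors. At depths below 20
the floor is not representable and only the true-fraction constraints
apply. Mutant alleles within a plant are distinct by *sequence*, not just
by event list, since different event lists can collapse to one read
sequence in repeat context.

Indels are planted uniformly so as to overlap the protospacer; the ±10-nt
calling window pad is deliberately wider than the planting range so that
edge events and leftmost-normalized placements stay callable.

Germination simulation applies the genotype rule deterministically:
full-LOF sextuple → no germination; sextuple with an in-frame allele →
delayed day (14/21/28) or stunted, uniformly; everything else → day 7. An
`in_frame_rescue_prob` knob lets in-frame plants fail anyway; the two
published T1 exceptions (sextuple germinators without any in-frame allele,
attributed to late-stage editing) are noted in report footnotes but not
modeled — mutation timing is out of scope.

**What passing tests show, and what they do not.** The generator produces
clean archetypes, flat Q scores, iid substitution noise and single-indel
alleles. Real amplicon data add PCR chimeras and duplicates, quality-skewed
errors, somatic mosaicism over development, multi-event alleles and large
rearrangements escaping the amplicon. Recovery of ≥99% on synthetic
populations therefore validates the calling logic and its thresholds, not
performance on any particular sequencing chemistry.

# Design computations

* **PAM scanning**: every TTTV (IUPAC-configurable) occurrence with room
  for a spacer (default 23 nt, canonical LbCas12a) immediately 3′ on either
  strand; 0-based half-open plus-strand coordinates.
* **Dual targeting**: Cas12a tolerates PAM-distal spacer mismatches, so one
  crRNA can cut two homologs when it matches one gene perfectly and differs
  from the other only distally. Spacer positions count from the
  PAM-proximal base; the distal zone defaults to positions ≥ 19 of 23 (the
  final five nucleotides), covering the one to two terminal mismatches of
  validated homolog-pair designs, and is configurable because no exact zone
  boundary is established. At most 2 mismatches by default.
* **Off-targets**: Hamming-only window scan (no bulges) over both strands,
  defaulting to ≤ 3 mismatches with canonical-PAM gating; a flag relaxes
  the PAM requirement since reported off-target candidate sets do not
  always state it. Linear scan only — adequate for gene-sized subjects, not
  a genome-indexed search.
* **Arrays**: six crRNAs split three-and-three across U6-26 and U6-29
  promoters, each array rendered as tRNA(Gly) + (DR + spacer)×3 + HDV
  ribozyme. Spacer order within arrays is free (it has negligible effect on
  editing), so `split_six` simply preserves input order. All fixed parts
  (canonical LbCas12a direct repeat, tRNA(Gly), HDV, promoter names) live
  in an editable parts list, never hard-coded, because exact plasmid parts
  vary between vector systems.
* **Golden Gate oligos**: each insert renders as a top/bottom oligo pair
  with 4-nt 5′ overhangs; terminal overhangs come from configuration
  (defaults documented: the direct-repeat tail `AGAT` on the left), junction
  overhangs are cut from the insert sequence itself so ligation is
  seamless. A cut whose 4-mer collides with an existing overhang slides up
  to 8 nt into the core; designs with no unique placement are refused, as
  a one-pot reaction with duplicate overhangs has ambiguous order. The
  two-level route (BbsI spacer inserts into a cloning vector, BsaI units
  into the binary vector) mirrors standard practice; `ligate_oligos`
  simulates the one-pot reaction and is required to reconstruct the array
  core with zero edit distance.

# Problem sizes and tolerances

The validation suite runs, among others: exhaustive zygosity-rule
equivalence on the full 0.01-step fraction simplex with up to three mutant
alleles (~31,000 compositions); population recovery on 200 plants × 6
genes × depth 100 across ten seeds at error 10⁻³ (≥ 99% per-gene and
per-plant recovery; 100% at error 0); PAM-scan and off-target equivalence
against brute-force oracles on 100 random 2-kb sequences; and 50 random
six-spacer designs round-tripped through assembly, parsing and simulated
ligation. Allele fractions are required to sum to 1 within 10⁻⁹ after
collapsing; classification rejects inputs whose fractions miss 1 by more
than 10⁻⁶.

# Known limitations

* Zygosity classes are defined purely by read-share thresholds; true
  mosaicism gradients, contamination, or allele dropout can masquerade as
  any class.
* Allele identity is full event-list equality; a switch for merging alleles
  by net indel length alone is not provided (distinct repair events at the
  same site remain distinct alleles).
* The germination model is deterministic given genotype; it reproduces the
  published rule, not biological variance in germination timing.
* Off-target search ignores bulged alignments and is not indexed for
  genome-scale subjects.
* FASTQ qualities are read but unused; base-quality-aware calling is out of
  scope, as is paired-end merging and BAM ingestion.
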