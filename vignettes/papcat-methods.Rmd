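---
title: "Cataloguing C1 cysteine peptidases from transcriptome assemblies: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Cataloguing C1 cysteine peptidases from transcriptome assemblies: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(papcat)
```

## The problem

Tenebrionid beetle larvae (*Tenebrio molitor*, *Tribolium castaneum*) digest
dietary protein largely with C1 papain-family cysteine peptidases in the
acidic anterior midgut. Cataloguing this enzyme complement from gut
transcriptome data requires a chain of steps, none individually exotic but
each with field-specific rules: open-reading-frame discovery in assembled
contigs, retention of peptidase homologs, collapsing redundant and partial
contigs into unique genes, genome-free expression estimation in the presence
of multi-mapping reads between paralogs, classification on the papain
residue-numbering frame, orthology calling between species, and geometric
screening of docked enzyme-substrate poses. `papcat` implements that chain
as composable functions plus an orchestrating pipeline, with a synthetic
data generator so that every stage can be tested against ground truth.

## Classification model

All classification happens on a common coordinate frame: *papain numbering*
for the cathepsin L branch and cathepsin-B numbering for the B branch.

* **Catalytic tetrad.** Positions 19/25/159/175 (Gln, Cys, His, Asn — the
  string `QCHN`). Any substitution or deletion at these positions marks the
  sequence an inactive *homolog*; the call is deliberately strict because
  partial tetrads are not known to retain peptidase activity.
* **Occluding loop.** The B branch carries an insertion at cathepsin-B
  numbering 104–126 whose His110/His111 pair confers exopeptidase activity.
  We count the peptidase residues aligned within that region (insertions
  inside it included). Loops of ≥ 20 residues with both histidines are
  *typical*; loops of ≤ 18 residues, or lacking either histidine, are
  *short* — the B-like endopeptidase-only class. The thresholds sit between
  the two natural classes (about 25 vs about 15 residues) with margin on
  both sides and are configurable; the 19-residue-with-His-His gap case is
  reported as `ambiguous` rather than silently binned.
* **Subsite fingerprints.** S1 = positions 23 and 65; S2 = 67, 68, 133,
  157, 205; reported as 2- and 5-character strings with `-` for deletions.
* **Family.** Best-scoring reference in the packaged panel (global
  alignment, BLOSUM62); a family-B sequence with a short loop is reported
  as `B-like`. Family and activity are orthogonal: an L-branch gene with a
  broken tetrad is `L` + `homolog`.

Numbering maps come from a global alignment of the peptidase's mature
domain against the reference mature domain (BLOSUM62, gap open 10, gap
extension 2). The comparatively stiff gap extension keeps the single long
loop indel in one block instead of scattering it; with a cheap extension
penalty the alignment occasionally shifted a catalytic position into a gap
on sequences ~40% diverged from the reference. Maps with under 15% overlap
identity are refused outright (`status = "refused"`) — numbering a
non-homolog would produce confident-looking nonsense.

## Reference panel

The packaged panel (`inst/extdata/reference_panel_synthetic.fasta/.yaml`)
is a **constructed synthetic stand-in** for the classical reference set
(papain; human cathepsins L1, L2, B; F/O/K exemplars), labelled as such in
the filename. Each entry is a scaffold carrying the canonical residues at
the canonical positions — the L branch 212 residues in 1:1 papain
numbering, the B branch with a 23-residue occluding loop inserted after
core position 103 (so B numbering runs 104–126 across the loop, His at
110/111) — plus annotated mature-domain starts for the two precursor
entries. Sequence content away from the annotated positions is random
draws from natural amino-acid frequencies, with families separated by
20–35% scaffold divergence so that best-hit family assignment is
well-conditioned. Everything downstream (numbering, loop typing,
fingerprints, family calls, the generator) is exercised self-consistently
against this panel; conclusions about real sequences require swapping in
real references, which the panel's YAML annotation format supports.

## Redundancy clustering and consensus

Pairwise alignment uses the Wagner–Fischer dynamic programme under unit
match/mismatch/gap costs with a deterministic traceback (ties: match >
substitution > deletion > insertion; implemented in C++). Identity is
computed over *overlap columns* — columns where both sequences carry a
residue — so a 3'-truncated fragment of a gene aligns at ~100% identity to
its full-length sibling. ORFs at ≥ 95% identity over ≥ 10 overlapping
residues are merged by single-linkage transitive closure; single linkage
makes the partition independent of input order, and the transitive rule
lets partial fragments chain through shared overlaps.

Consensus building multiple-aligns cluster members progressively (longest
member first, anchoring coordinates) and applies a majority rule per
column: the most frequent residue wins only when it exceeds 50% of non-gap
observations; otherwise the column is written `X` and recorded as an
unresolved SNP. With two members every disagreement is a tie, so pipelines
feeding this rule should provide ≥ 3 redundant observations where SNP
resolution matters — the generator's default of three fragments per gene
reflects that.

The mature-enzyme start is mapped by homology: global alignment against
the mature human cathepsin L and B references (better score wins), taking
the consensus position aligned to the reference mature N-terminus. No
signal-peptide prediction is attempted (out of scope); the catalogue
reserves that as an external annotation.

## Expression estimators

Contigs are assigned to consensus mRNAs at ≥ 97% identity; full-length
alignments contribute weight 1, partial alignments contribute their
aligned fraction when it exceeds 50% of the contig length and nothing
otherwise. Two estimators are computed per peptidase:

* **Naive RPKM** counts each multiread as one full unit at *every* contig
  it maps to (configurable to `once_best`). This estimator deliberately
  inflates paralog expression — it is kept because it is the comparison
  baseline.
* **Rescue RPKM** counts unique reads first, computes per-contig densities
  (unique count / contig length), and splits each multiread across its
  contigs proportionally to those densities (equal split when all are
  zero). The allocation is single-pass by default; an iteration count is
  exposed but not iterated to convergence, since the one-pass form is the
  published method and further EM-style passes change little at catalogue
  scale.

Rescue conserves reads exactly (each multiread contributes 1.0 in total),
reduces to the naive count when no multireads exist, and on two-paralog
simulations with a shared 5' region recovers the true expression ratio
with smaller error than the naive estimator — all three properties are
asserted in the test suite. Relative expression is each peptidase's RPKM
over the summed RPKM of the whole peptidase set, ×100. Read mapping itself
is out of scope: the quantifier consumes read–contig alignment tables; a
built-in exact-substring mapper exists only to close the loop on synthetic
data.

## Phylogeny and orthology

Distances between aligned proteins are p-distances over shared non-gap
columns, optionally Dayhoff/PAM-corrected (`d = -ln(1 - p - 0.2 p²)`);
whether the original analysis used Dayhoff as a distance correction or
only as an alignment weight matrix is not stated, so both routes are
exposed via `correction`. Trees are neighbor-joining (via `ape`), rooted
on the cathepsin K outgroup; bootstrap support is computed by seeded
column resampling (default 1000 replicates, seed 111) with bipartition
counting on the full-data tree.

Orthology calls between the two species follow two rules in strict
precedence: first, every *cherry* with one leaf per species becomes an
ortholog pair; then, sweeping remaining clades smallest-first, each
minimal clade containing at least one unclaimed leaf of each species and
no already-called leaf becomes an ortholog group. The precedence resolves
the nested-mixed-clade ambiguity in favour of pairs ("could not be
separated into pairs" defines groups as the residual case). Reference
panel leaves are neutral: they neither form pairs nor block groups.

## Pose screening

Docking itself is out of scope; poses arrive as coordinates. Three
criteria, all parameters exposed:

1. **Catalytic distance** — scissile P1 carbonyl carbon to catalytic Cys
   SG ≤ 4.0 Å, boundary inclusive ("should not exceed"). The carbonyl
   carbon, not the arginine side-chain CZ, is measured because the
   criterion concerns hydrolysis of the P1–P1' bond; the atom name is
   configurable.
2. **Orientation** — the P2 side chain must be nearer (minimum heavy-atom
   distance) to the S2 residue set than to the S1' set, and the P1'
   residue the reverse, with both contact distances ≤ 6 Å.
3. **Terminal accessibility** — neither the free amino nor the carboxyl
   terminus may be buried: ≤ 12 enzyme heavy atoms within 5 Å of each
   (inclusive). The burial proxy quantifies a qualitative criterion; both
   knobs are configurable and the count is monotone in the radius.

Missing atoms or annotations give an `unevaluable` verdict, distinct from
failure, and a pose set with no evaluable member reports status
`no_evaluable` rather than "0 passed".

## Synthetic data generator

The generator emulates the statistical structure the analysis assumes:
clusters of tandem-duplicated paralogs descending from a family ancestor
(alternating L- and B-branch clusters); inactivating catalytic
substitutions (C25S, C25A, Q19E, H159T — those observed among natural
inactive homologs) injected with probability `homolog_fraction` *before*
the species split, so ortholog copies share them; occluding loops deleted
to ≤ 18 residues (His110/111 removed) with probability
`shortloop_fraction`; ortholog copies for the second species at half the
paralog divergence; per-gene TPM drawn log-uniformly over 10–10⁴; reads
sampled proportionally to TPM × length with per-base errors; and contigs
as redundant fragments carrying a second SNP haplotype.

Defaults are chosen once to mirror the study system: 4 clusters,
substitution rate 0.2/site between paralogs (orthologs ~0.1 each side, so
ortholog pairs are mutually closest and recoverable), `homolog_fraction`
0.15 and `shortloop_fraction` 0.7 (roughly the observed 10-of-13 short
B-branch fraction), `ortholog_fraction` 0.8, SNP rate 0.002/nt, 75-nt
reads at 0.1% error. Catalytic-tetrad positions and loop histidines are
protected from *random* substitution — purifying selection — so truth
labels stay well-defined; deliberate inactivating substitutions bypass the
protection and are logged. Fragmentation defaults to three 5'-anchored
fragments per gene (full length plus two 3'-truncations, the dominant
de novo assembly artefact), which guarantees clustered fragments share the
ORF start and gives the consensus three observations per column; a
`staggered` mode produces general tiling fragments for coverage-style
tests.

What the generator does **not** emulate: paired-end inserts, quality-score
distributions, assembler chimeras, indel polymorphism and sequencing
indels, codon-usage bias (back-translation draws synonymous codons
uniformly), and compositional heterogeneity across sites. Passing
recovery tests therefore demonstrates the pipeline's rules are implemented
correctly and are mutually consistent — not that they are robust to every
artefact of real assemblies.

## Problem sizes and numerical choices

The test suite and acceptance script run the end-to-end recovery at 4
clusters × 5 genes (≈ 36 gene copies over both species) across seeds 1–5,
two-paralog expression simulations with 3000 reads × 20 seeds, NJ recovery
on 100 random additive 5-taxon matrices against exhaustive topology
enumeration, and clustering oracle equivalence on 200 random ORFs — sizes
at which every oracle is exact and the whole suite completes in a few
minutes. The pipeline discards ORFs under 100 residues before homology
filtering: below the homology filter's own 100-residue alignment
requirement, the 50%-of-shorter fallback admits spurious short local
alignments (observed at 30–47% identity over 17–36 residues on
reverse-strand junk ORFs), and no genuine peptidase fragment that can be
classified is that short. Ties in consensus columns yield `X`, never an
arbitrary residue; clustering ids are assigned after sorting members so
the partition is permutation-invariant; NJ branch-length ties inherit
`ape`'s deterministic resolution; all stochastic steps take explicit
seeds.

## Known limitations

* The reference panel is synthetic; numbering against real papain/cathepsin
  references may differ at indel-rich regions even though the machinery is
  identical.
* Identity is overlap-based everywhere; two short non-overlapping fragments
  of one gene cannot be merged (they have no overlap columns) and will be
  catalogued separately — redundancy removal is only as good as fragment
  overlap.
* The rescue estimator's one-pass allocation inherits the bias of the
  unique-read density estimate when a paralog has almost no unique
  sequence.
* The expression percentages printed in the source tables are not exactly
  reproducible from the table columns themselves; tests assert rank order
  and internal consistency (sums to 100, conservation), not the printed
  percentage values.
* Orthology precision degrades when paralog divergence approaches ortholog
  divergence; the generator's defaults keep them separated by design, and
  the precision figure should be read under those conditions.
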