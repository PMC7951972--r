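---
title: "Structural profiling of antibody repertoires: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Structural profiling of antibody repertoires: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(repstruct)
```

## The problem

High-throughput Ig-seq snapshots of human B-cell receptor repertoires are
almost always unpaired collections of heavy (VH) and light (VL) variable
domain reads. Clonotyping — grouping reads by closest V gene, J gene and
CDRH3 sequence identity — finds almost no sharing between unrelated
individuals, yet antibodies only need a *similar binding-site geometry*
(and compatible paratope chemistry) to engage the same epitope. This
package estimates repertoire diversity and commonality in structure space
instead of sequence space: it predicts which reads are modellable by
template-based loop grafting, pairs chains combinatorially into Fvs,
summarises each predicted binding site by a small discrete-plus-geometric
descriptor, and greedily clusters those descriptors into **distinct
structures**. Structures realised by Fvs from every individual in a
comparison are **public**; a random-sampling null model calibrates how
much sharing chance alone would produce.

## The pipeline, stage by stage

### 1. Numbered reads and North CDRs

Inputs are IMGT-numbered amino-acid reads (OAS-style CSV, or FASTA with a
sidecar numbering table). Numbering itself is treated as an external,
solved problem: the package validates it (strictly increasing IMGT
positions, 20-letter alphabet, V-gene locus consistent with the chain
type) but never computes it. North CDR loops are sliced purely by
position: CDR1 at IMGT 24–40, CDR2 at 55–66 (heavy) or 55–69 (light),
CDR3 at 105–117, insertion codes included. A read missing a CDR window or
either flanking framework residue is flagged un-extractable and excluded.
Insertion codes order ascending after the base position, except at 112
where they descend and precede it (the CDR3 apex convention); this
dialect is exercised directly in the tests.

### 2. Modellability

Each CDR is matched against a library of loop templates of the same
region and length. A template is *admissible* when its
environment-specific substitution score (ESS) against the query sequence
reaches the admission threshold; among admissible candidates, the one
whose 10 anchor Cα (five residues on each side of the loop) superposes
onto the chain's assigned framework with the lowest RMSD is selected.
A chain survives only if all three of its CDRs receive a template.

The internal ESS formula is a position-wise sum over an
environment-conditioned substitution table. The default table has two
environment classes (buried/exposed) and scores 5 for an identical
residue, 4 for a same-physicochemical-group substitution and 0 otherwise,
so a self-match scores 5 per position and the published CDR3 admission
bands — length ≤ 8: ≥ 25; 9–10: ≥ 35; ≥ 11: ≥ 40 — are attainable by an
exact match at every length. Those bands are applied to both CDRH3 and
CDRL3; all other regions use the conventional default of 25. The table
and thresholds are data, not code: both are importable.

### 3. Sequence reduction and pairing

Surviving chains are clustered at 90% identity with a deterministic
greedy, longest-first pass over IMGT-aligned sequences (identity =
matching residues at shared occupied positions / longer sequence length).
This reproduces the contract of word-based tools — every member is at
least 90% identical to its centre — while remaining exactly testable
against a brute-force reference.

All VH centres are then paired with all VL centres. Each pair's
20-residue interface signature (residues at the library's 20 key VH–VL
interface positions; absent positions emit a gap that never matches) is
compared to every reference Fv. A pair is kept when its best reference
identity is at least 85% (17/20), and it inherits that reference's
orientation; ties go to the lexicographically first reference. The 20
positions are configuration, shipped with the library, because the
interface positions that matter empirically are themselves a data
artefact.

### 4. Distinct structures

A kept Fv is summarised by eight parameters: its orientation reference,
its six CDR template ids, and its CDR length vector. Clustering proceeds
in four steps:

1. identically-keyed Fvs collapse to one representative (chosen uniformly
   at random under the configured seed — the pipeline's only stochastic
   step; in overlap runs a representative that is already a centre of the
   seed set is always preferred and recorded as shared);
2. keys whose length vector is unique become distinct structures
   immediately, since RMSDs between loops of different lengths are not
   meaningful;
3. the remainder, partitioned by length vector, are scanned greedily in
   input order: an Fv founds a new centre when its orientation RMSD
   exceeds 1.5 Å to every existing centre, or when its combined CDR RMSD
   exceeds 1 Å to every existing centre;
4. otherwise it is stripped and recorded as a member of the first centre
   (in centre-creation order) within both gates.

The combined CDR measure is the length-weighted root-mean-square of the
per-region template RMSDs,

$$ D_{12} \;=\; \sqrt{ \frac{\sum_X L_X\, D_{X12}^2}{\sum_X L_X} },
   \qquad X \in \{H1,H2,H3,L1,L2,L3\}, $$

which is bounded between the smallest and largest per-region distance
and is thresholded in ångströms like any RMSD. A `sqrt_combined = FALSE`
switch exposes the no-root variant for sensitivity analysis. The
per-region distances come from precomputed symmetric matrices: each
template pair is superposed on its 10 anchor Cα (the graft frame — the
frame in which a grafted loop's deviation is what matters) and the RMSD
taken over loop Cα. Orientation dissimilarity is the plain coordinate
RMSD between orientation pseudo-atoms stored in a common heavy-chain
frame; users with their own orientation parameterisation can import a
precomputed matrix instead.

Two numerical choices deserve note. First, when an Fv is within the
orientation gate of one centre but within the CDR gate of only a
*different* centre, it is attached to the first centre within the CDR
gate; this configuration cannot arise under the synthetic generator's
enforced margins and is vanishingly rare in practice, but the rule is
fixed and documented rather than left to iteration order. Second, all
remaining ties (framework assignment, template selection, reference
inheritance) break lexicographically by identifier, making every stage
except dedup-representative choice fully deterministic.

### 5. Overlap, baselines and proximity

To measure sharing, repertoires are chained most-structurally-diverse
first: the first repertoire's distinct structures are listed as immovable
seed centres, the next repertoire's Fvs are clustered against them, and
so on. After step *k*, a centre whose member presence covers all *k*
repertoires is public. Presence is member-based: a repertoire counts as
containing a structure only if one of its Fvs was actually assigned
(including by identical key) to that centre. Seeded clustering never
merges or deletes seeds, so public counts are non-increasing along the
chain. The same machinery yields "pure after exposure" sets (Fvs that do
not fall into an individual's baseline centres) and proximity fractions
(share of one structure set within a CDR-RMSD radius of another, at
matching length vectors and within the orientation gate).

### 6. The null model

Random Repertoires answer: *how many distinct structures, and how much
sharing, would random sampling of modellable structure space produce at
this sampling depth?* Modellable Repertoire Structures (MRS) are random
keys assembled from five pools — orientation references, CDRH3 templates,
CDRL3 templates, and linked CDR1/CDR2 template pairs that must share a
source structure, mirroring their joint V-gene encoding. MRS draws are
with replacement (the published construction samples vastly more often
than its pools are large). Filtering the MRS to the CDR length vectors
observed in a genuine snapshot gives its Length-Accessible set (LARS);
sampling that *without replacement*, as many times as the snapshot's
predicted modellable Fvs, gives its Random Repertoire. RR distinct
structures are subsampled down to the genuine snapshot's distinct count
and chained exactly like genuine repertoires to give expected public
counts. One master seed fans out to per-stage sub-seeds so any stage can
be reproduced in isolation.

### 7. Clonotyping comparator

The sequence-space comparator groups VH reads by gene-level V and J call
(allele suffixes stripped) and CDRH3: either exact CDRH3 identity, or
80% identity under the same greedy-representative engine, with equal
CDRH3 length required in both modes (unaligned identity across lengths is
undefined; this is a documented divergence risk against alignment-based
implementations). Clonotype keys render in the field's
`V5-51+ARPYGSGSYSDY+J4` form. Germline proximity is the best identity
over shared occupied V-region positions (IMGT ≤ 104) against an
IMGT-aligned germline set.

## The synthetic data generator

Real template databases and deep Ig-seq snapshots are neither
redistributable nor desk-scale, so validation rests on a generator whose
ground truth is recoverable *by construction*:

* **Geometry with margins.** Loop templates form planted clusters per
  (region, length) bin: cluster bases are rejected until pairwise
  anchor-frame RMSDs exceed twice the 1 Å CDR gate (2.5 Å target
  separation), members jitter around bases to a within-cluster scale of
  0.3 Å, and the achieved matrix is verified (within < 0.5 Å, between
  > 2 Å) with bounded retries. Orientation references are planted the
  same way against the 1.5 Å gate (within < 0.75 Å, between > 3 Å).
  Because *within < gate/2 < 2·gate < between*, greedy order dependence
  cannot flip cluster identity, which is precisely the regime where
  exact recovery is guaranteed — and the documented limit of what
  passing tests prove about real data, where margins are not enforced.
* **Admission by construction.** Template loop sequences are random but
  mutually exclusive under the ESS thresholds (verified pairwise), so a
  synthetic read — whose CDRs copy one member template's sequence — is
  admitted by exactly its planted template. Decoy reads carry a
  4-residue CDR3: no such template exists and the lowest admission band
  (25) exceeds the maximal attainable self-score (20), so decoys are
  unmodellable twice over.
* **Cohort design.** By default 3 individuals share
  `ceiling(0.4 × 50) = 20` public structures; 30 private structures are
  distributed round-robin. Each structure contributes, per chain and
  individual, one read per template variant (2) plus one
  framework-mutant read that must merge with variant 1 at the 90%
  identity stage, and 4 decoy reads per chain. Per-structure interface
  signatures (pairwise ≤ 6/10 matches) make exactly the same-structure
  VH–VL pairs modellable at 20/20 while every cross pair stays at
  ≤ 16/20 < 85%; an 8-position framework barcode (standing in for
  FW1/junctional diversity) keeps cross-structure reads safely below
  the 90% identity threshold. Structures sharing a CDR3 length on a
  chain never share that chain's loop clusters, so same-length-vector
  structures differ in all six CDR clusters and separate cleanly under
  the combined-RMSD gate.
* **What it does not emulate.** V(D)J recombination, somatic
  hypermutation, realistic CDR length and gene-usage distributions,
  sequencing error, and real loop geometry are all out of scope; the
  generator probes the pipeline's correctness, not biology.

Generation is a pure function of (specification, seed); release dates
(a random ~15% of templates stamped recent) support the date-blinding
experiment, where filtering the library at a cutoff must flip
modellability for exactly the reads whose planted templates vanish.

## Problem sizes and runtime choices

The shipped validation runs use the default cohort (3 individuals,
50 structures, 94 VH + 94 VL reads per individual, ~350 templates),
20 seeds for the recovery and null-contrast properties, 50 random
instances of 30–150 Fvs for oracle equivalence against a line-by-line
transcription of the clustering steps, and 100-point random suites for
the geometric and formula oracles. These sizes were chosen so the whole
suite exercises every stage in a few minutes on one core while leaving
the margins of the planted design intact; all of them scale up by
changing `cohort_spec()` arguments.

## Known limitations

* Structural similarity across *different* CDR length combinations is
  undetectable by design: length vectors partition the space before any
  RMSD is computed.
* Alternative binding modes (different CDR subsets engaging the same
  epitope) are invisible to the 8-parameter key.
* The ESS table shipped as default is a declared, configurable stand-in
  with the published thresholds made meaningful by its self-match
  scaling; it is not a fit to structural data.
* Greedy clustering is order-dependent outside the margin regime;
  overlap runs fix cross-repertoire order (most diverse first), and
  within-repertoire order is input order.
* Combinatorial VH×VL pairing over-counts pairs relative to natively
  paired data; with single-cell inputs the pairing stage can simply be
  bypassed by constructing Fvs directly.
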