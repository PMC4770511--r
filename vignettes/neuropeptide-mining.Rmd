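---
title: "Mining neuropeptide precursors: models, rules and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Mining neuropeptide precursors: models, rules and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(NeuropeptideMiner)
```

## The biological model

Neuropeptides are made as prepropeptides: a secretory signal peptide,
followed by a propeptide in which one or more short bioactive peptides are
embedded between basic cleavage signals. Prohormone convertases cut at
these signals, carboxypeptidases trim the exposed basic residues, and a
C-terminal glycine left on a peptide is converted into an amide (written
here as a trailing `a`, e.g. `PFCNAFAGCa`); an N-terminal glutamine may
cyclize to pyroglutamate (`pQ`). A *paracopy* is one of several homologous
peptide copies encoded within a single precursor; *single-copy* families
(CCAP, corazonin, AKH, ...) encode exactly one bioactive peptide per
precursor.

The package models this chain explicitly: `predictSignalPeptide()` →
`predictCleavageSites()` → `excisePeptides()` → `assignFamily()`, wrapped
by `annotatePrecursor()` for one protein and `runAnnotate()`/`runReport()`
for whole datasets. Nucleotide input first passes `translateFrames()` and
`findOrfs()`. Comparative layers summarize paracopy counts per family and
taxon, group splice variants, classify *capa/pk* gene architectures, and
compute sequence-logo matrices.

## Signal-peptide heuristic

Signal peptides are predicted with a transparent scoring heuristic rather
than a neural network, so results are deterministic, auditable and
reproducible offline. Every candidate last-signal-residue position p in
10–45 is scored as the sum of

* the net positive charge of residues 1–5 (capped at 2) — the n-region;
* the mean Kyte–Doolittle hydropathy of the best 8-residue window ending
  3–7 residues upstream of p — the h-region, tethered to p so that a
  realistic c-region separates the hydrophobic core from the cleavage
  point (an untethered window makes the score monotone in p and drags the
  call toward the C-terminus);
* a graded bonus for small residues at p and p−2, the classical −1/−3
  positions of signal peptidase: 0.7/0.3 for A, G, S and 0.2/0.1 for the
  merely tolerated C, T, V. Weighting the −1 position more, and the
  smallest residues over C/T/V, resolves the ties that otherwise arise in
  runs of small residues (`...VASA`) and keeps a cysteine immediately after
  the cleavage point (as in inotocin, `CLITNCPRGa`) from capturing the
  call.

Ties that remain are broken toward the C-terminus. A precursor is called
signal-positive when the best score reaches a threshold (default 2, well
below the ~5–7 scored by bona fide signals and well above the negative
scores of hydrophilic N-termini). N-terminally incomplete records are never
scored; precomputed external predictions can be injected through a TSV.

## Cleavage rules

Cleavage-site assignment follows the classical criteria used when curating
insect prohormones, written out as an explicit rule table so that every
decision carries its reason:

* dibasic `KR` and `RR`: accepted; `KK`/`RK`: accepted at reduced
  confidence (config-disablable);
* monobasic R: accepted only with a basic residue at P4, P6 or P8 — and
  only a *lone* basic: a basic that is itself part of a dibasic cleavage
  signal does not license cleavage across a peptide boundary (without this
  restriction, the KR upstream of a peptide like `AGDNFMRFG` licenses a
  spurious cut inside the peptide);
* monobasic K: rejected;
* proline at P1′ blocks any site; a cysteine within two residues
  downstream blocks (disulfide protection);
* contiguous basic runs are one site (P1 = downstream-most basic, the run
  is consumed as signal); furin-like R-X-(K/R)-R additionally consumes the
  P4 arginine, unless P3 is a glycine — that glycine is an amide donor and
  belongs to the upstream peptide.

Excision partitions the precursor at accepted sites; by construction the
signal peptide, raw segments and consumed cleavage residues tile the input
exactly, and the suite asserts this partition identity on hundreds of
generated precursors. A segment ending in G before an accepted site is
amidated (the G is dropped in the processed display string); an N-terminal
Q is displayed as pQ. Glutamate is never auto-called as pyroglutamate.

## The family registry

The registry (`inst/extdata/family_registry.yaml`) defines 39
neuropeptide/protein-hormone families by anchored regular-expression
motifs matched against processed peptide strings, a copy-number class, an
amidation requirement, and a priority integer. Motifs encode consensus
C-/N-termini from the insect literature (e.g. `F.PRLa$` for pyrokinins,
`W[FY]GPRLa$` for tryptopyrokinins, `HVFLRFa$` for myosuppressin,
`[PT]FCNAF.GC.{0,2}a$` for CCAP including the collembolan extended
variants). Priorities resolve the genuine containments: myosuppressin
outranks the generic FMRFamide ending, natalisin outranks
tachykinin-related peptides. For the large cysteine-rich protein hormones
(bursicon subunits, EH, trissin, elevenin) a short regex cannot express
the real cysteine framework; their entries are clearly commented
approximations with synthetic exemplars, and EFLa and NPLP1 are marked
low-confidence because their short motifs carry little information —
assignments of these families in real data should lean on homology
evidence. Each entry carries an exemplar mature peptide used by the
synthetic generator; a test asserts that every exemplar classifies back to
its own family.

The *capa/pk* complex is special: the CAPA and PK/PBAN families share the
tryptopyrokinin and overlap on generic C-termini, so precursor-level
assignment is made on ligand types (`typeCapaLigand()`, priority
trypto-PK > PK > PVK): any precursor containing a periviscerokinin is a
CAPA precursor, a PVK-free pyrokinin precursor is PK/PBAN.

## capa/pk architectures

`classifyArchitecture()` implements a closed decision table over ligand
presence and gene/transcript structure: pattern A (one gene, PVK+PK, no
trypto-PK), B (one gene, all three ligands), B1 (B plus a splice
transcript restricted to PVK+trypto-PK), C1–C3 (two genes with
increasingly re-sorted ligands). Copy multiplicity is deliberately
irrelevant — only presence matters — except that A requires the absence of
trypto-PK anywhere. States outside the table (a lone PVK-only gene as in
the water flea, a lone PK-only gene, two PVK-free genes) return
`unresolved` with an explicit rationale rather than being forced into a
letter. Without genome data, two transcripts that do not share a splice
group are treated as two genes — the same inference a transcriptome-only
study has to make. The classifier is tested against an independently
written brute-force evaluation of the table over bounded ligand multisets.

## Paracopy statistics and logos

`summarizeParacopies()` reports, per family and taxon, the mean paracopy
count and the *uncorrected* standard deviation S_N = sqrt(mean((x −
mean(x))²)) over full-length precursors only; a single full-length
precursor yields a bare mean, and a cell with only partial precursors
reports `(≥k)`, the maximum observed count as a lower bound. The {3,4} →
0.5 witness distinguishes the N denominator from the sample SD (0.707...).
Display rounding is one decimal with a trailing `.0` dropped ("4 ± 0",
"3.5 ± 0.5"); full precision is kept underneath.

`buildLogo()` computes per-column residue frequencies, information content
log2(20) − H (bits) and letter heights freq × info, so heights sum to the
column information and are bounded by log2(20) ≈ 4.32. Gaps and the
no-residue marker X are excluded and frequencies renormalized under the
default `ignore_gaps` policy. The small-sample correction e_n =
(1/ln 2)(19/2n) is available but off by default: the published logos pool
modest numbers of sequences and do not state whether a correction was
applied, so the uncorrected formula is the safer default. Alignment is an
input — the tool only offers C-terminal padding, because neuropeptide
homology is anchored at the amidated C-terminus and curated alignments
should come from the analyst.

## The synthetic generator

`genPrecursor()` builds precursors from a grammar that mirrors the
biology: verified signal template (planted cleavage at 16–24), acidic
spacers, exemplar paracopies each ending in G+KR when amidated, and
padding propeptide segments up to 70 residues. The spacer alphabet
(D, E, N, Q, H) is disjoint from every motif's required residues and from
the small-residue classes of the signal heuristic, so spacers cannot
spawn chance motifs or shift the signal call — this is what keeps the
planted truth exact. Back-translation uses uniform synonymous codons (no
codon-usage model; translation testing does not need one) and ATG-free
UTRs with in-frame stops so the planted ORF is recovered unambiguously.
Mutations at `mutation_rate > 0` hit spacer positions only, emulating
neutral divergence outside diagnostic residues; lesions
(`corruptRecord()`) plant exactly one in-frame stop, single-nucleotide
frameshift, or 5′/3′ truncation at a recorded position.

`genTaxonPanel()` realizes per-taxon profiles whose copy-number means and
spreads, presence/absence switches (PDF absent from Protura and Diplura,
elevenin and CNMa absent where reported), splice-variant families
(ITP/ITPL, orcokinin) and capa/pk patterns (B in Protura, B1 in
Collembola, C1 in Diplura, B in Archaeognatha, C2 in Zygentoma) encode the
comparative structure of the study system. Copy numbers are rounded
Gaussians clipped to ≥ 1; `fixed_counts = TRUE` freezes them at rounded
means for exact-recovery tests. What the generator does *not* emulate:
assembly chimerism, allelic variation, expression levels, codon bias,
non-exemplar sequence diversity within a family, and cleavage-site
ambiguity beyond the rule table — so passing tests demonstrate the
pipeline's internal correctness and calibration, not its recall on real
transcriptomes, where doubtful signal peptides and unpredictable cleavage
sites remain a genuine limitation.

Problem sizes used by the tests and the acceptance script — panels of 2–9
species, 200–500 generated precursors per property check, 1000-sample
statistical oracles — were chosen as the smallest sizes at which every
family and decision branch is exercised repeatedly.

## Artifact flagging

Sequencing artifacts are flagged, never silently repaired: an
`in_frame_stop` flag is raised when a stop interrupts a region that
matches a family motif once the stop is masked (all 20 substitutions
tried), and a `frameshift_suspect` flag when a motif absent from the
candidate's frame is completed in a sibling frame within 60 nt of the
candidate. Motif cores spanning fewer than five positions are too
unspecific to scan and are excluded. The criterion for "sequencing error
more likely than a dead gene" is this package's own operationalization —
motif interruption — not a published rule; repairs happen only through the
explicit `repairFrameshift()`, which logs the edit.

## Interface decisions

Coordinates in all outputs are 1-based inclusive on the precursor protein
(GFF3 convention). Sidecar metadata TSVs override FASTA header metadata,
with a warning on conflict. `...`/terminal-X incompleteness markers are
stripped into completeness flags, and partial precursors contribute only
lower bounds to the statistics. The command-line entry points are thin
wrappers (`inst/scripts/npmine.R`) over exported functions; the functions
and this vignette are the primary interface. Splice grouping requires 30
identical N-terminal residues (longer than any signal peptide, shorter
than the divergence point of known variant pairs) and refuses plain
prefixes, which are more likely incomplete assemblies than splice
variants.
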