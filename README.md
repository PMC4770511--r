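# NeuropeptideMiner

Neuropeptides — the largest and most diverse class of messenger molecules
in animals — are encoded as precursor proteins: a signal peptide followed
by one or more short bioactive peptides flanked by basic
prohormone-convertase cleavage signals. Comparative studies of
"basal" (non-pterygote) hexapods and their arthropod relatives mine
transcriptome assemblies for these precursors, annotate the encoded mature
peptides, and compare families, paracopy numbers, splice variants and gene
architectures across taxa. Doing that by hand does not scale and is hard
to audit.

NeuropeptideMiner is a Bioconductor-style R package for that workflow,
aimed at comparative peptidomics and insect-neuroendocrinology groups. It
provides:

* six-frame translation and ORF extraction from transcripts, with
  advisory flags for likely sequencing artifacts (in-frame stops,
  frameshifts that displace a peptide motif into a sibling frame);
* deterministic signal-peptide prediction (n-region charge + tethered
  Kyte–Doolittle h-region window + the −3/−1 small-residue rule);
* cleavage-site assignment from an explicit rule table (dibasic KR/RR,
  reduced-confidence KK/RK, licensed monobasic R, proline and cysteine
  blocks, furin-like extended sites), every call carrying its reason;
* excision of mature peptides with amidation (`...Ga` → trailing `a`) and
  pyroglutamate (`pQ`) calls, with an exact partition guarantee;
* a curated, editable registry of 39 neuropeptide/protein-hormone
  families with anchored motifs, priorities and copy-number classes;
* paracopy statistics per family × taxon with the uncorrected standard
  deviation S_N = sqrt(mean((x − x̄)²)) (the `{3,4} → 0.5` convention),
  lower-bound `(≥k)` reporting for partial precursors, presence/absence
  matrices and sequence-logo matrices (information content in bits);
* splice-variant grouping and classification of *capa/pk* gene
  complements into architecture patterns A, B, B1, C1, C2, C3 from ligand
  types (PVK / trypto-PK / PK);
* a synthetic-precursor generator with planted ground truth that powers
  the whole test suite offline.

## Worked example

Annotate a single precursor (here a generated CCAP precursor; any
amino-acid string works):

```r
library(NeuropeptideMiner)
reg <- defaultRegistry()
g <- genPrecursor("CCAP", 1, seed = 7, registry = reg)
prot <- as.character(sequences(g$precursor))[[1]]
a <- annotatePrecursor(prot, reg, id = "ccap1",
                       species = "Lepidocampa weberi",
                       taxon_group = "Diplura")
a
#> AnnotatedPrecursor ccap1 (Lepidocampa weberi, Diplura)
#>   77 aa; signal 1-19 ; 5 mature peptides; family: CCAP (n=1)
maturePeptides(a)[1, c("start", "end", "processed", "amidated")]
#>   start end  processed amidated
#> 1    20  29 PFCNAFAGCa     TRUE
```

The signal peptide covers residues 1–19; the first excised segment is the
amidated mature CCAP (`PFCNAFAGCa` — the trailing `a` is the amide from
the encoded C-terminal glycine); the remaining segments are acidic
propeptide spacers that match no family motif. Whole-dataset runs and
comparative tables:

```r
pan <- genTaxonPanel(taxonProfile("Diplura"), 3, seed = 11, registry = reg)
ann <- annotatePrecursorSet(pan$precursors, reg)
s <- renderParacopyTable(summarizeParacopies(familyAssignments(ann)))
head(s[, c("family", "taxon", "n_full", "rendered")], 4)
#>   family   taxon n_full rendered
#> 1  AST-A Diplura      3   12 ± 0
#> 2    MIP Diplura      3   11 ± 0
#> 3  FMRFa Diplura      3    4 ± 0
#> 4   TKRP Diplura      3    4 ± 0
summarizePatterns(buildGeneComplements(ann))$histogram
#>           C1
#>   Diplura  3
```

`rendered` is the "mean ± S_N" display (uncorrected SD, one decimal,
trailing `.0` dropped); the pattern histogram shows all three synthetic
dipluran species carrying the two-gene C1 *capa/pk* architecture
(capa-like gene with PVKs + trypto-PK, pk-like gene with PKs only).

FASTA input with `id|species|taxon` headers (or a sidecar TSV) goes
through `runAnnotate()`/`runReport()`, which write annotation TSV/GFF3,
the paracopy table, the presence matrix and the pattern report into an
output directory. `inst/scripts/npmine.R` wraps these as `annotate`,
`report` and `synth` subcommands.

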