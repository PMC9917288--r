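---
title: "Curation, homeology and expression profiling of a polyploid serpin family"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Curation, homeology and expression profiling of a polyploid serpin family}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(serpinome)
```

## The analysis

Serpins (serine protease inhibitors) share a conserved ~400-residue scaffold
of eight to nine alpha-helices, three beta-sheets and an exposed reactive
centre loop (RCL).  Genome annotations of large polyploid genomes routinely
over-call such families: truncated fragments, mis-annotated gene models and
unrelated domain-containing proteins inflate the candidate list several-fold.
This package implements a desk-scale version of the complete analysis a
gene-family study runs after the initial homology scan:

1. **Structural curation** of candidate proteins against a reference serpin.
2. **Gene-model QC and pseudogene detection** from the genome and GFF3.
3. **Homeologue-triad construction** with A:B:D pattern classification,
   tandem-duplicate detection and Nei–Gojobori Ka/Ks.
4. **Phylogeny**: multiple alignment, Poisson-corrected distances,
   neighbour joining, bootstrap support, clade cutting.
5. **Expression profiling** of a TPM matrix with fixed thresholds.

Every stage is exercised end-to-end on a synthetic hexaploid family with
planted, machine-readable ground truth (`family_spec()`,
`make_hexaploid_family()`), so each claim the pipeline makes is testable
against what was planted.

## Curation model and assumptions

A candidate passes curation iff it can fold into a functional serpin
scaffold:

* **Length gate**: 330–600 residues (typical serpins are ~400).  Shorter
  polypeptides cannot complete the fold; the gate is inclusive at both ends.
* **Scaffold conservation**: the candidate is globally aligned to the
  reference (Needleman–Wunsch, BLOSUM62, affine gaps with opening 10 and
  extension 0.5, so a gap of length $L$ costs $10 + 0.5L$).  Six annotated
  core blocks of the reference stand in for the helices/sheets; a structural
  defect such as a missing helix manifests as an unaligned block.  Pass
  requires every block ≥ 50% covered and the core overall ≥ 80% covered
  (both configurable).
* **RCL annotation**: the reference P1 is mapped through the alignment onto
  the candidate; P17 is 16 residues N-terminal of P1 (15 when the P17 column
  is deleted — the rare 16-residue RCL, which is accepted and flagged).  The
  annotation fails when more than two P-sites align to gaps or the protein
  ends before P3′.
* **Hinge rule**: inhibitory serpins need Glu at P17 and a small-residue
  hinge; we require at least 4 of P15..P10 in {G, A, S, T, V}.  The P17
  requirement is absolute; the 4-of-6 rule is a configurable consensus
  choice, since the hinge composition beyond P17 is a literature consensus
  rather than a single fixed motif.
* **Classification**: RCL present + hinge intact → *inhibitory*; RCL present
  + hinge broken → *non-inhibitory* (retained — the Z9-type serpins are real
  genes); no RCL → structural failure.  The reactive centre is reported as
  the P2-P1-P1′ triplet; `is_LR` marks the Leu-Arg-[GAS] centre of the
  Zx/AtSerpin1 class.

The packaged reference (`reference_serpin()`) is a **constructed synthetic
stand-in** (`inst/extdata/reference_serpin_synthetic.json`): a real curated
AtSerpin1 record cannot be bundled, so the fixture plants the consensus
hinge `EEGTEAAAATAVKITLR` + `SAK` at a recorded position in an otherwise
arbitrary scaffold.  Any reference with the same JSON layout (protein,
0-based RCL coordinates, core blocks) can be supplied instead; all
coordinates in results are candidate-protein coordinates, so the choice of
reference only affects mapping quality.

The signal-peptide call is a deliberate heuristic (Met start + a ≥8-residue
hydrophobic run within residues 2–30), not a trained predictor: it is used
only to label secreted serpin groups, and its planted-truth recovery is part
of the test contract.

## Gene-model QC

`detect_pseudogene()` flags the three inactivation mechanisms the package
models, mirroring how annotation errors and pseudogenes present in real
polyploid data:

* **frameshift** — CDS length not divisible by 3 (e.g. an 8-bp insertion in
  exon 1, which typically also produces a premature stop);
* **premature stop** — an internal stop with translation < 80% of the
  reference protein length (the fraction is configurable; a stop in the last
  few codons is not treated as inactivating);
* **splice defect** — a short intron (< 20 bp by default; annotated 2-bp or
  4-bp "introns" are annotation errors) or a non-canonical site.  Canonical
  is GT..AG; a GC donor is reported as non-canonical but does not
  pseudogenise on its own, since GC..AG introns occur naturally.

The 20-bp intron floor is a conservative sanity threshold: real introns are
rarely shorter than ~60 bp, but the check is meant to catch annotation
artefacts, not to model splicing.

`compute_pI()` solves net charge = 0 by bisection over pH ∈ [0, 14] using
Henderson–Hasselbalch terms for the termini and the ionisable side chains
(D, E, C, Y, H, K, R) with the Lehninger free-amino-acid pKa set.  For a
single free residue the termini use that residue's own pKa1/pKa2, which
yields the textbook free-residue values (Arg 10.76, His 7.59) that explain
native-PAGE mobility differences between protein variants.  Bisection runs
to an interval of 1e-8 pH units rather than stopping on |Q| alone: the
charge curve of residues with no ionisable side chain is nearly flat around
the pI, and a charge-only stop can be off by ~0.1 pH.

## Ka/Ks

`kaks()` implements Nei–Gojobori (1986) from first principles: per-codon
synonymous site fractions exclude stop-creating substitutions from the
denominator, differences are averaged with equal weight over all orderings
of 1–3 changes per codon with stop-passing pathways excluded (with a
fallback to all pathways in the degenerate case where every ordering passes
through a stop), proportions are Jukes–Cantor corrected
($d = -\tfrac{3}{4}\ln(1 - \tfrac{4}{3}p)$), and Ka/Ks is undefined
(flagged, not an error) when Ks = 0.  Codons with gaps or ambiguity codes in
either sequence are dropped pairwise.  The implementation is checked against
an independent brute-force pathway-enumeration oracle to 1e-9 on random
pairs, and the estimator recovers planted ω ∈ {0.2, 0.5, 1.0} within ±0.1
at 300 codons and 10% divergence.  Raw proportions (pS, pN) are reported
alongside the corrected rates, since distance-method variants differ mainly
in the correction.

## Phylogeny

The desk-scale choice here is neighbour joining on Poisson-corrected
protein distances rather than a full maximum-likelihood search: NJ is
deterministic, exact on additive matrices, and sufficient to recover clade
structure on families of this size.  Multiple alignment is delegated to
MAFFT (the standard aligner, available on the PATH); with two sequences the
result coincides with the package's pairwise global alignment.  Gapped
columns are excluded pairwise from distances; negative NJ branch estimates
are clamped to zero and counted in an attribute.  Bootstrap support resamples
alignment columns (200 replicates by default, seeded and reproducible) and
scores each original bipartition.

`cut_clades()` partitions the leaves into *k* groups (default 3) by
iteratively removing the remaining edge with the largest length × support
score whose removal actually increases the number of leaf-containing
components.  Internal edges are preferred; pendant edges are only used when
no internal edge can split further, which makes the degenerate *k* = number
of leaves case well defined (cherry leaves can never be separated by
internal edges alone).  Ties break by edge index, so the cut is
deterministic.

## The synthetic family: what it emulates, and what it does not

`make_hexaploid_family()` builds a toy hexaploid genome in which every
downstream claim has a planted answer:

* three **clade ancestors** derive from the reference at 45% substitution
  divergence on mutable positions (everything outside the protected
  N-terminus and RCL); **triad ancestors** derive from their clade ancestor
  at 19%; **homeologues** evolve from the back-translated triad ancestor at
  the nucleotide level (10% pairwise divergence, planted dN/dS 0.2);
  **tandem duplicates** add 2% nucleotide divergence and sit within tens of
  kb of their parent copy.  These rates were chosen together so that the
  three separations the pipeline must make are all wide: within-triad
  protein identity stays near 90% (comfortably above the 80% homeologue
  threshold), cross-triad identity stays near 65% (comfortably below it),
  and the clade-stem edges of the NJ tree are decisively longer than any
  within-clade structure — including the long branches created by
  signal-peptide groups;
* **RCL variants** (LRS, LES, LMS, hinge-broken, missing) and
  **signal peptides** are installed at the triad level;
* **pseudogene lesions** copy the three observed mechanisms exactly: an
  8-bp exon-1 insertion (frameshift + premature stop), a GT→AT donor
  mutation, and a sense→stop change;
* gene loci have 2–4 exons with GT..AG introns on both strands, Traes-style
  identifiers consistent with their chromosome, and the emitted GFF3/FASTA
  are cross-consistent by construction (extracting the CDS from the genome
  through the gene model reproduces the CDS FASTA byte-for-byte);
* the **expression matrix** plants archetypes (ubiquitous 5–50 TPM,
  tissue-specific ≥ 8 TPM in the target tissue and < 0.5 elsewhere, silent
  < 0.5 everywhere), stress responses as TPM scaled by 2^(planted log2FC)
  on paired control/stress samples, and mean-preserving multiplicative
  lognormal noise at CV 0.2.

What it does **not** emulate: real intergenic composition and transposable
elements, alignment-fragmenting indel patterns, isoform complexity,
expression dispersion beyond lognormal noise, batch effects, or the
scale of a real wheat genome.  Passing the planted-truth tests therefore demonstrates
that the pipeline's logic is correct under its stated assumptions — not that
it would reproduce any specific real-genome census, which additionally
depends on the reference annotation and expression atlas used.

## Expression thresholds

All expression calls are pure thresholds (no dispersion modelling or
p-values):

* TPM < 0.5 → 0 (strictly-less rule: exactly 0.5 is kept); flooring is
  idempotent;
* log2(TPM) with zeros kept as an `NA` sentinel, never −∞;
* a gene is *expressed in tissue T* when the mean floored TPM over T's
  samples ≥ 0.5 (statistic configurable to max); *ubiquitous* = expressed in
  every tissue group, *not expressed* = in none;
* stress log2FC uses a pseudo-count equal to the floor:
  $\log_2(s + 0.5) - \log_2(c + 0.5)$, which keeps fold changes finite when
  one side is silent and is exactly antisymmetric under swapping the pair;
  direction requires |log2FC| > 0.5 strictly, and *highly up* requires
  log2FC > 2 strictly.

## Problem sizes and determinism

The default study conditions are 12 triads (38 genes, patterns 1:1:1 ×6,
1:2:1 ×2, 3:1:1, 0:2:1, 1:0:1, 0:1:1) with 200 bootstrap replicates; the
census-scale demonstration uses 43 homeologue sets (83 genes, subgenome
totals 24/32/27, 30 genes in 1:1:1 sets, 26 silent) with 100 replicates.
Every random step — generator, bootstrap, expression noise — derives from
one integer seed, and identical seeds give bit-identical outputs end to end.

## Known limitations

* Curation proxies "predicted structure examination" with alignment coverage
  of reference core blocks; a full-length candidate with a subtly broken
  fold would pass.
* Homeologue sets use identity + subgenome + clade co-membership;
  translocated copies are only handled through the clade map, and
  single-linkage can chain sets if a genuinely intermediate paralogue sits
  near the identity threshold.
* NJ clade boundaries can differ from a likelihood tree at weakly supported
  edges; clade recovery is validated on planted clusters and strongly
  supported splits only.
* The Ka/Ks pathway weighting is the classic equal-weight convention;
  codon-model (ML) dN/dS is out of scope.
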