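---
title: "orthoedit: methods and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{orthoedit: methods and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(orthoedit)
```

## Scope and model

`orthoedit` infers putative A-to-I RNA-editing events in a species for which
RNA-seq and genomic reads exist, and scores their conservation against a
second (reference) species with a catalogue of known edited residues. The
biological signal is simple — inosine is read as guanosine, so editing shows
up as A→G mismatches on the transcript strand — but in a highly polymorphic
genome the same signal is produced by ordinary heterozygous or
sample-specific SNPs. The pipeline therefore stacks three filters of
increasing biological specificity: a strand-aware coding-region SNV filter,
subtraction of SNPs confirmed by genomic reads, and an orthology filter that
asks whether the same residue is known to be edited in a distant species.

### SNV calling

Pileups are built from SAM alignments by an explicit CIGAR walk (`M`/`=`/`X`
count toward columns; `I`/`S` consume query only; `D`/`N` consume reference
only). RNA calls require depth ≥ `min_depth` (default 10), at least
`min_alt_reads` (default 2) supporting reads, and an alternative-allele
fraction of at least `min_alt_fraction` (default 0.1). The depth cut-off of
10 applies to RNA calls only; genomic SNPs are called with the cut-off
disabled, because any read support at all is enough to disqualify a
candidate as a polymorphism. The alt-read and alt-fraction thresholds are
this package's own, deliberately explicit, choices: upstream descriptions of
such pipelines typically delegate SNV calling to an external toolkit with
unstated settings, which makes results irreproducible; fixing modest,
configurable defaults trades fidelity to unknowable settings for
determinism. Base-quality filtering is available (`min_base_quality`) but
off by default, and duplicate reads are not detected.

An SNV is an editing candidate only if it is A→G and overlaps the CDS of a
forward-strand transcript, or T→C under a reverse-strand CDS; when
transcripts of both strands overlap the site, only strand-compatible
isoforms are kept. Subtraction matches position *and* allele: a genomic A→T
variant at the same position says nothing about an RNA A→G candidate, which
is a different variant. Consequences are annotated per isoform by
substituting G at the edited codon position of the spliced CDS; internal
stops are retained (`*`), so stop-loss (readthrough) edits remain
analyzable, and codons containing `N` are dropped from consequence calls.
For summary statistics an event counts as synonymous only when it is
synonymous in *every* isoform it hits — the conservative reading when a
single synonymous fraction must be reported; the per-isoform flags are kept
in the output for any other aggregation.

### Orthology windows and conservation classes

For every candidate-bearing isoform and every reference isoform of a paired
homologous gene, the two proteins are aligned once, globally, with affine
gaps (BLOSUM62, gap open 11, gap extend 1 — the familiar BLAST protein
defaults; all configurable). Global pairwise alignment of each
query-isoform/reference-isoform pair replaces a multiple aligner: it removes
an unpinned external dependency, and the window mechanism below absorbs the
small column shifts on which the two approaches differ. Two adjustments make
translated CDS alignable as-is: `*` (stop) participates as an ordinary
symbol at the matrix minimum, and `X` (untranslatable codon) scores 0
against everything.

The aligned distance between the query's edited residue and a known edited
residue of the reference is the absolute difference of their
alignment-column indices, gaps counted — the strictest deterministic
reading of "aligned distance"; a gap-free residue-coordinate alternative is
available (`distance_metric = "residue"`). A candidate/site pair is emitted
at every window `w ∈ {0, 1, 5, Inf}` with distance ≤ `w`, which makes the
per-window call sets nested by construction; per-window totals are therefore
non-decreasing, a property the tests assert. Classes follow the
pre/post-edit residue comparison: class 0 when the editing is synonymous in
both species, then 1/2/3/4 for both/post-only/pre-only/neither residues
conserved. Counting is per distinct event: an event hitting several isoforms
can contribute to several classes but counts once in each class and once in
the per-window total, so totals need not equal row sums.

Reference editing sites are consumed in isoform protein coordinates; lifting
a genomic catalogue to per-isoform residue positions is the caller's
responsibility and kept outside the package, because catalogues differ in
how (and against which transcript set) they report positions.

### dsRNA-context curation

ADAR requires double-stranded RNA, so a curated event should sit in a paired
region of its pre-mRNA (the genomic footprint of the CDS segments, introns
included — UTRs are not part of the annotation this pipeline consumes; a
configurable flank could be added at extraction). The package folds with a
maximum-base-pairing Nussinov dynamic program (Watson-Crick plus optional
G·U wobble, hairpin loops ≥ 3 nt, deterministic traceback) implemented in
C++ for its O(n³) cost, and accepts imported Vienna dot-bracket structures
so any thermodynamic folder can be plugged in; structure predictions are
known to vary across folders, which is exactly why the structure source is
recorded per event. A position passes if it is paired or is a
one-nucleotide nick flanked by paired bases; the verdict depends only on the
pairing pattern. Multi-isoform events pass if any isoform's structure
supports them.

Two numerical caveats are deliberate. First, pre-mRNAs longer than
`fold_window` (default 2,000 nt) are folded in a window centered on the
edited base: the DP is cubic, and long-range pairings predicted by a
max-pairing objective are not credible anyway. Second, maximum base pairing
systematically over-pairs relative to thermodynamic folding — in a long
random sequence nearly every base finds some partner — so *negative* dsRNA
verdicts are only meaningful over windows in which the local sequence
context is controlled; the synthetic fixtures therefore assert negative
verdicts over a 121-nt window in which they plant a pairing-free alphabet
(see below), and real-data users wanting stringent negatives should import
thermodynamic structures.

## The synthetic fixtures

`generate_fixture()` emulates the *shape* of the real inputs — multi-exon
genes on both strands, spliced RNA reads with `N` CIGAR operations across
introns, genomic reads, a reference proteome with known editing sites, and
tissue/stage sample labels — with planted, machine-checkable truth:

* **Editing events** are planted on transcript-strand adenosines in coding
  regions, as per-read Bernoulli draws at editing level 0.5, in 1–3 samples
  each, so the alt-fraction and alt-read thresholds are genuinely exercised.
* **SNPs** share the A→G signature but appear in *every* RNA and genomic
  read (homozygous), so they are indistinguishable from editing before the
  genomic subtraction and must be fully removed by it.
* **Conserved sites**: a fraction of edits (default 0.6) also receives a
  reference editing site planted by mutating the reference protein so the
  pair classifies as a chosen class at a chosen aligned distance
  (`plant_conserved_site()`); recovery of the exact class at the exact
  distance is asserted end to end.
* **Structure contexts**: some edits are embedded in a perfect 15-bp
  inverted repeat (dsRNA-positive truth) or in a ±60-nt window rewritten
  with an A/C-only alphabet, within which no Watson-Crick or wobble pair
  exists (dsRNA-negative truth under a ≤121-nt fold window).

The reference study conditions — the generator defaults used by the
acceptance script and the end-to-end tests — are 4 scaffolds × 12 kb, 20
genes of 2–3 exons, RNA depth 30×, genomic depth 15×, read length 60,
50 planted edits and 50 planted SNPs; `seq_error_rate` defaults to 0.001
and the end-to-end recovery checks set it to 0, where recovery is exactly
decidable. These sizes keep a full pipeline run in the tens of seconds
while leaving every gene with enough adenosine positions to plant into.
Plants are kept at least `10 × (read length / depth)` CDS bases away from
transcript ends so tiled reads cover every planted site at or above the
depth cut-off.

What the fixtures do *not* emulate: coverage biases, paired-end fragments,
indel or quality-model errors, alternative splicing beyond truncated
isoforms, heterozygous SNPs, allele-specific expression, and editing-level
gradients. Passing tests therefore demonstrate the correctness of the
pipeline's logic under its stated model, not robustness to every artifact of
real libraries — the genuinely hard cases on real data (marginal depth,
mapping artifacts, RNA/DNA sample mismatch) still require the manual
curation step the conservation classes are designed to prioritize.

## Numerical and interface choices

* **Coordinates** are 1-based inclusive everywhere, matching GFF3/VCF and
  R's own container semantics; event identifiers render as
  `scaffold|position`.
* **GFF3 phase** is honored (5'-most CDS segment, transcript orientation)
  and defaults to 0 when absent.
* **Determinism**: a single seed drives fixture generation; alignment,
  folding and traceback tie-breaks are fixed; two runs with the same config
  and seed produce byte-identical TSV outputs (asserted in the tests). The
  fixture's sample sheet stores SAM paths relative to itself so a bundle is
  relocatable and byte-stable across output directories.
* **Caching**: each pipeline stage is cached as an RDS under
  `out_dir/cache/` and reused with `resume = TRUE`.
* **Degenerate inputs**: empty event sets flow through every stage and the
  report bundle without error; `N` bases in the genome are skipped at
  calling and excluded from consequences; a reference site beyond its
  protein's length is ignored; a query residue aligned into a terminal
  overhang of the reference yields no call.

## Known limitations

* The Nussinov objective maximizes pair count, not free energy; use
  imported structures for thermodynamic realism.
* Many-to-many homolog pairs are all evaluated; no reconciliation to 1:1
  orthology is attempted.
* Editing *levels* (fraction of edited reads per site) are observed but not
  modeled or reported beyond the raw counts.
* Non-coding editing and C-to-U (APOBEC) editing are out of scope, as are
  indel calling and genotype-likelihood models.
* The in-memory pileup (one 4 × length integer matrix per scaffold) targets
  the scaffold sizes of the bundled fixtures and modest genomes; a
  streaming backend would be needed for chromosome-scale mammalian data.
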