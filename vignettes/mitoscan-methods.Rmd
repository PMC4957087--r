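---
title: "mitoscan: methods and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{mitoscan: methods and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(mitoscan)
```

# Scope

`mitoscan` re-implements, as a tested and reusable pipeline, the
annotation-level comparative analyses that are routinely reported for newly
assembled plant mitochondrial genomes: RNA-editing-site identification and
classification from genomic DNA / cDNA comparisons, relative synonymous
codon usage (RSCU) and third-codon-position composition, long direct and
inverted repeat screening, perfect-microsatellite (SSR) screening,
detection of chloroplast-derived fragments (mitochondrial plastid DNA,
MTPT) with cross-species homolog scoring, simplified collinear gene-cluster
detection, and the genome feature-summary statistics. Assembly, read
mapping and gene annotation are out of scope: a genome (FASTA) and a gene
annotation (GFF3 dialect) are inputs, not outputs.

The reference system for the default thresholds is the sacred-lotus
(*Nelumbo nucifera*) mitochondrial genome, a 524,797-bp circular-mapping
molecule with 48.16% GC; the package ships the printed chloroplast-insertion
table for that genome as a plain-text fixture (`lotusFragmentTable()`)
so that the published totals can be recomputed without downloading the
accession.

# Data model

Three S4 classes carry the data. `Genome` wraps a `Biostrings::DNAString`
(alphabet A/C/G/T/N, stored uppercase) with an identifier and a
`circular`/`linear` topology flag. `AnnotationSet` holds gene-level fields
(`gene_id`, `name`, `category` ∈ {protein, tRNA, rRNA, pseudogene, orf},
`origin` ∈ {native, plastid_derived}, `trans_spliced`) and a
`GenomicRanges::GRanges` of exon segments whose `coding_order` column gives
the splicing order. `PipelineConfig` collects every threshold. All
coordinates are 1-based and fully inclusive (GenBank convention), in one
documented place; origin-crossing features on circular genomes are stored
as two exon segments, never as `end < start`.

Naming conventions follow organelle practice: identical duplicated gene
copies are suffixed `-1`/`-2`, divergent copies `-a`/`-b`, and
plastid-derived genes `-cp` (or `(cp)`).

# RNA editing

Plant mitochondrial mRNAs are edited almost exclusively by C-to-U
deamination, observed in a DNA/cDNA alignment as a C (DNA) against T
(cDNA); the rare reverse U-to-C direction appears as T against C. The
caller aligns each gene's spliced CDS with its cDNA
(Needleman–Wunsch, match +1, mismatch −1, gap open −5, gap extend −2; a
gap of length $L$ costs $5 + 2L$) and emits an `EditingSite` for every
C↔T column. **Every other mismatch is quarantined as a non-edit
discrepancy** — sequencing noise must never inflate edit counts, and the
tests assert this precision property under 0.5% substitution noise.

Effects are classified by substituting the edited base into its codon and
translating both codons with the standard genetic code (plant mitochondria
use translation table 1); initiator codons are translated positionally
with no special-casing. A site is `synonymous` iff the amino acid is
unchanged; edits in the pseudogene, which has no reading frame, are
`unpartitioned`. The headline "nonsynonymous share" is reported under two
labelled denominators: all sites, and partitioned sites only. For the
published partition (612 nonsynonymous, 58 synonymous, 30 unpartitioned)
the all-sites share is 87%.

Editing frequency is $100 \cdot n_\text{edits} / L_\text{CDS}$ edits per
100 nt, rounded half-up to 3 decimals. Identical duplicated copies are
counted once (the copies' CDSs are compared; only exact duplicates
collapse). A cDNA flagged as pre-mRNA is compared against the unspliced
genomic span instead of the spliced CDS, mirroring amplicons derived
before intron removal.

Cross-species comparison aligns the two orthologous CDSs globally and
calls an edit *shared* when both species carry an edit in the same
alignment column. The operational matching rule for "shared" edits is not
standardized in the literature; the alignment-column rule used here is a
documented design choice, and an edit aligned to a gap is unique by
definition. The comparison is symmetric by construction.

Chromatogram peak heights, which bench workflows consult when calling
edits from Sanger traces, are not part of the data model; calling is
sequence-only, with a minimum-quality hook accepted and ignored so that a
quality-aware caller can be layered on later.

# Codon usage

RSCU for codon $c$ in synonymous family $F$ is
$\mathrm{RSCU}(c) = n_c / (\sum_{c' \in F} n_{c'} / |F|)$ — the observed
count over the family mean. Within every used family the values sum to
$|F|$ and average 1; unused families are reported as `NA` rather than 0
(0/0 is undefined). Stop codons form their own 3-member family. The
third-position A/T statistic counts stop codons in its denominator by
default (`include_stop = TRUE`), since published "percent of codons"
figures plausibly count all codons; the flag makes the other convention
available. Codons containing ambiguous bases are excluded from counts,
with a message.

# Repeats and SSRs

**Long repeats.** Detection is exact-seed and extend: all 31-mer anchor
matches (forward and reverse-complement) are clustered on diagonals,
merged within 100 bp, extended un-gapped under an X-drop rule (match +1,
mismatch −3, drop 12) and trimmed to the best-scoring span. A pair is
reported when the alignment length is **strictly greater than** the 500-bp
threshold (the conventional ">500 bp" criterion) at ≥ 99% identity. The
identity of every reported pair is re-verifiable by direct comparison of
the two loci, and an oracle test bounds misses against planted truth.
Self-hits are excluded, symmetric duplicates collapsed, and nested pairs
dropped in favour of maximal ones.

**SSRs.** A perfect SSR is a maximal run of a primitive 1–6-nt unit
meeting the per-unit-length minimum counts 10, 5, 4, 3, 3, 3 (mono- to
hexanucleotide). Runs are found as maximal stretches of `s[i] == s[i−k]`;
a run reportable at several unit lengths is reported at the smallest
(non-primitive units such as `ATAT` are suppressed). Motifs are reported
as observed plus a canonical (lexicographically least rotation) form.
Mononucleotide runs of N are never SSRs. Compound/interrupted
microsatellites are out of scope: only perfect repeats are reported. The
finder is checked against a brute-force enumeration oracle on short
genomes across 50 seeds.

**Circularity.** Both scanners append a `min(genome, 600)`-bp overhang to
circular genomes to catch origin-spanning features, then deduplicate by
modular coordinates; wrapping loci report `end` past the genome length
with a `wraps` flag. SSR calls are rotation-invariant on circular genomes
up to coordinate shift.

# Chloroplast-derived fragments (MTPT)

Protein, tRNA and rRNA gene exons are first masked with N so that
conserved housekeeping genes present in both organelle genomes cannot
produce hits — chloroplast-derived *tRNA genes themselves* are found
because they lie inside intergenic fragments of plastid origin, not
because the mask spares them. The masked genome is searched against the
chloroplast genome by an in-package local aligner: exact 12-mer seeds
(N never seeds), diagonal clustering, then exact Smith–Waterman refinement
of each candidate window (match +1, mismatch −2, gap open −5, gap extend
−2). Hits pass at ≥ 70% identity and e-value ≤ 1e−5, where
$E = K m n e^{-\lambda S}$ with fixed documented constants $K = 0.41$,
$\lambda = 1.28$ (un-gapped nucleotide approximations). The identity and
coverage floors, not the e-value, are the scientifically decisive filters,
so bit-exact BLAST statistics are deliberately not reproduced.

Hits within 30 bp on both genomes are merged into fragments — this
reproduces fragment-level granularity (one reported row per insertion
event) rather than HSP granularity; the 30-bp distance is a documented
choice, as published tables do not state their merging rule. Fragments are
numbered in decreasing length order. Each fragment lists the chloroplast
genes it overlaps; a gene is `intact` when the fragment fully contains its
span and, for protein genes, the mitochondrial copy retains an open
reading frame (tRNA folding checks are out of scope). ORFs are *not*
masked before the search, matching the conventional protein/tRNA/rRNA
mask list; a nuclear-insertion scan is the same masked search with a
different subject sequence, no special code path.

Cross-species homolog presence uses the best local hit of each fragment
against each genome: present iff identity ≥ 80% and coverage (alignment
length / fragment length) ≥ 90%.

# Collinear gene clusters

Gene orders are derived from the annotation by first-exon start position;
trans-spliced genes contribute one entry per genomically contiguous exon
group (`nad1_exon1`, `nad1_exon2,3`), since their pieces occupy
independent loci. Name-level matching replaces protein-similarity matching
deliberately: organelle gene nomenclature is standardized, and published
cluster definitions are name-level. Matching ignores the `-1`/`-2`,
`-a`/`-b` and `-cp`/`(cp)` suffixes. After projecting both orders onto the
shared gene set, a cluster is a maximal run of ≥ 2 genes consecutive in
order A and consecutive (within `max_gap` intervening shared genes,
default 0 — strict adjacency) in order B, in the same or exactly reversed
order; circular orders are scanned across the origin and clusters reported
once. Strand agreement is recorded as orientation but not required for
membership, since real conserved clusters include mixed-strand
arrangements. Consecutive clusters are disjoint (greedy left-to-right
scan), which the permutation-oracle test pins down as the package's
convention.

# The synthetic-data generator

The generator is first-class, tested code, not a fixture: it emits
miniature mitochondrial/chloroplast genome pairs whose planted ground
truth is re-derivable from the emitted FASTA/GFF3 alone by direct
substring inspection.

What it emulates, at reduced scale: a circular multi-kb genome with
forward- and reverse-strand genes; a two-exon cis-spliced gene; a
trans-spliced gene split across distant loci; an identical duplicated gene
pair (kept under 500 bp so the pair is not itself a long repeat); a
reading-frame-less pseudogene; rRNA and native/plastid-derived tRNA genes;
protein CDSs with ATG starts, single terminal stops and no internal stops
(gene lengths follow a catalog of realistic organelle values, e.g. 225 bp
for *atp9* and 621 bp for *ccmB*); planted C-to-U and rare U-to-C edits;
planted chloroplast fragments spanning the published length range (the
smallest real fragment is 54 bp); planted >500-bp direct and inverted
repeats; and SSR loci at each unit length's threshold. The background is
i.i.d. with GC weight 0.48, echoing the reference genome's 48.16% GC, so
composition-sensitive stages see realistic base frequencies. All
randomness flows from `PipelineConfig@rngSeed` through fixed per-stage
offsets; identical seeds give byte-identical bundles.

Truth unambiguity is engineered, not assumed. Planted features never
overlap genes or each other. Flanking bases at every planted boundary are
set so that no alignment or run can extend past the recorded locus (several
guarded bases per flank, because a local alignment can otherwise creep
through one mismatch on chance matches). Generated CDSs are screened
against SSR-threshold runs, and a sanitization pass mutates single bases
inside any chance background run so that the planted SSR set is the
complete truth. Substitution noise and fragment divergence are
substitution-only by default because the edit caller assumes colinear
DNA/cDNA; indel robustness is exercised separately through the aligner.

What it does **not** emulate — and therefore what passing tests do not
show about real data: sequencing error models and chromatogram artefacts,
partial editing (mixed peaks), recombination-mediated repeat families,
nested/interrupted repeats, genuine phylogenetic divergence patterns, and
real codon-usage bias. Exact-recovery results on bundles demonstrate
correctness of the implementations under clean conditions, not performance
on noisy traces.

# Numerical choices

* All printed statistics use **half-up rounding** (`roundHalfUp()`), not
  banker's rounding: percent-of-genome to 1 decimal, GC to 2, editing
  frequency and accuracy to 3. A 1e-9 epsilon absorbs binary
  floating-point representation error.
* GC% counts N positions in the denominator (length-based convention).
* Cis-intron length is computed from annotation geometry (gaps between
  consecutive exons of cis genes), not stored separately.
* Coverage depth and mean read length round to the nearest integer.
* Degenerate inputs error loudly: zero-length denominators, edits at
  non-editable bases, CDS lengths not divisible by 3, exons outside the
  genome, duplicate gene ids. A missing mitochondrial annotation in the
  fragment search proceeds unmasked with a loud warning rather than
  silently producing conserved-gene hits.
* DNA/cDNA pairs with a length ratio outside [0.8, 1.25] warn but still
  align.

# Problem sizes

The shipped tests and the acceptance script run on bundles of 8–12 genes
over 14–30 kb mitochondrial and 8–12 kb chloroplast genomes, 25–40 planted
edits, 3–5 fragments, 2–4 long repeats and 3–6 SSR loci, with 20-seed
recovery loops and 50-seed oracle comparisons — sizes chosen so the whole
suite exercises every code path in a couple of minutes on one core while
keeping every planted feature individually inspectable.

# Known limitations

* The aligner's e-value constants are documented approximations; e-values
  should be treated as a rank filter, not as calibrated significance.
* The seed-and-extend repeat finder can in principle miss a ≥ 99%-identity
  repeat whose mismatches are spaced closer than the 31-mer seed; the
  brute-force oracle tests bound this in practice at desk scale.
* The short-repeat (20–500 bp) class is exposed through `min_len` but has
  no canonical detection rule in the literature; no claims are made about
  reproducing published short-repeat counts.
* Gene-order clusters use name matching; genes annotated under
  non-standard names in one genome will not match.
* Editing extent (fraction of transcripts edited per site) is out of
  scope; the caller is binary per site.

# A worked micro-example

```{r example}
cfg <- PipelineConfig(rngSeed = 7)
b <- simulateBundle(cfg, n_genes = 8, mt_len = 14000, cp_len = 8000,
                    n_edits = 25,
                    fragment_lengths = c(600L, 250L, 54L),
                    repeat_spec = data.frame(kind = c("direct", "inverted"),
                                             length = c(550L, 520L)),
                    ssr_spec = data.frame(motif = c("A", "AT", "AGC"),
                                          n_units = c(11L, 6L, 5L)))
res <- runEditingAnalysis(b$mt, b$mt_ann, b$cdna)
nrow(res$sites)                         # edits recovered
head(res$profile)
findSsrs(b$mt)[, c("motif", "n_units", "start")]
findLongRepeats(b$mt)[, c("kind", "length", "identity")]
```
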