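---
title: "Methods: variant consequences, homology calls and burden summaries"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: variant consequences, homology calls and burden summaries}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

`straindiff` compares two closely related strains given a reference genome,
its gene models, and a variant set called against that reference. This
vignette is the package's account of the methods: the models and rules it
implements, the parameters that matter, the design choices made where the
design was genuinely open, and what its validation does and does not
establish.

## Data model and coordinate conventions

All coordinates are 1-based and closed, matching both GFF3 and VCF, so no
off-by-one translation happens at parse time. Genomes are
`Biostrings::DNAStringSet` objects restricted to A/C/G/T/N; gene models are a
tibble with one row per gene and list-columns of exon and CDS intervals
stored in genomic (ascending) order on both strands — splicing reorders them
for translation. When an annotation offers several transcripts per gene, the
one with the longest spliced CDS is kept (ties broken by smallest mRNA ID):
the analysis treats genes and models one-to-one, as typical fungal
annotations do.

VCF records are split per ALT allele and **left-normalized**: shared
trailing bases are trimmed (extending left through repeat context where an
allele would empty) and shared leading bases removed, yielding the unique
leftmost minimal representation. Normalization is idempotent and every
accepted record's REF allele is verified against the genome; a mismatch —
including any `N` in the reference at that position, which never matches an
allele — is a data error naming the contig and position rather than a silent
misclassification.

Variant classes follow allele lengths: SNP (`1/1`), insertion
(`|alt| > |ref|`), deletion (`|ref| > |alt|`), MNV (equal lengths > 1). For
composition summaries an MNV is decomposed into its per-base substitutions,
so SNP + indel counts partition the variant total; for consequence calling
it is kept whole.

## Consequence classification

Each variant's *affected interval* is: the substituted bases for SNPs/MNVs;
the deleted bases (excluding the anchor base) for deletions; the anchor base
for insertions. Region assignment per overlapping gene follows a fixed
precedence:

1. **splice site** — the affected interval touches the consensus
   dinucleotides, i.e. the first `w` and last `w` bases of any intron
   (`splice_window`, default `w = 2`: the GT donor and AG acceptor). The
   2+2 window is the minimal defensible reading of "consensus splice site"
   given canonical GT..AG introns; the width is a parameter because wider
   conventions (e.g. ±3 exonic bases) exist.
2. **CDS** — any overlap with a coding interval.
3. **UTR** — exonic but outside the CDS span; 5′ vs 3′ follows strand.
4. **intron**, else **intergenic**.

Coding effects are then computed on the spliced CDS through a bijective
genomic-position ↔ coding-offset map (minus-strand genes are
reverse-complemented; a nonzero phase on the first coding exon trims the
partial codon):

* substitutions compare reference and alternate codon translations under the
  standard genetic code: equal → `synonymous`; alternate codon a stop →
  `stop_gained`; reference stop lost → `stop_lost`; otherwise `AAC` with
  (ref-AA, protein position, alt-AA). MNVs are evaluated codon-wise over the
  substituted block and **each changed amino acid counts as one AAC**
  (`n_aa_changed`), consistent with per-gene AAC counts that can exceed the
  variant count.
* CDS indels are `frameshift` iff the net length change is not a multiple of
  3, else `inframe_insertion` / `inframe_deletion`.
* a variant straddling an exon/intron boundary is `VCSS` if it touches the
  consensus window (splice disruption dominates the downstream product);
  otherwise it is flagged `complex` and counted in region totals only.

A variant overlapping several genes yields one record per gene. For
genome-level tallies exactly one record per variant is flagged `primary`,
chosen by the severity order *frameshift > stop gained > stop lost > VCSS >
AAC > in-frame indel > synonymous > region-only* (ties broken by gene ID).
The ordering is a determinism device, not a biological claim: region counts
over primary records always sum to the variant total.

Stop gains/losses are deliberately **included in the AAC tally** of the
summary tables — the AAC category is the generic "amino acid change" — while
remaining distinguishable in the detailed table.

## Burden summaries

Per-gene summaries count AACs, CDS insertions/deletions, frameshifts and
VCSSs; genes whose only variants are intronic or UTR still appear with zero
effect counts so totals conserve. The *degree of affection* is
`100 · n_AAC / protein_length` (protein length excludes the stop codon). AAC
histograms use bins 1–10, 11–49, 50–99, ≥ 100 plus overlapping tail bins
≥ 50 and ≥ 100; degree-of-affection classes are `≤ 5%`, `(5, 10]%`, `> 10%`
— closures chosen so the three classes are exhaustive and disjoint, with
boundary membership (5 → lowest, 10 → middle) configurable in principle via
the cut points.

Two numerical conventions are fixed throughout:

* **percentages round half-up** (commercial rounding) to 2 decimals
  (1 decimal for genome identity), because half-even rounding disagrees on
  exact `.5` boundaries and the goal is bit-exact reproduction of printed
  tables from their numerator/denominator pairs;
* **denominators are explicit arguments, never inferred**: affected-gene
  percentages are taken against the reference annotation's gene total and
  family percentages against the family-list total supplied by the caller.
  Published tables of this kind sometimes mix denominators in ways that
  cannot be reconstructed; making the denominator an input keeps every
  reported percentage reproducible from its stated pair.

Family rollups join per-gene summaries onto the family table (a gene may
carry several family labels and contributes to each), report members with
each effect class and the size-normalized rate `total_variants / n_genes`,
and derive top-level class tallies (AA, GH, GT, CE, PL, CBM, EXP) from label
prefixes, grouping unknown prefixes under `other` with a warning.

`genome_identity(snps, size) = 100·(1 − snps/size)` and
`variant_density(total, size) = size/total` are the headline one-liners, each
with its rounding convention above.

## Homology: best hits, orthologs, presence/absence

Alignment is full Smith–Waterman local dynamic programming with affine gaps
(a gap of length L costs `gap_open + L·gap_extend`) — no heuristic seeding.
At desk scale exactness is affordable and enables brute-force oracle testing.
Defaults: nucleotide +1/−2 with gaps 5/2 (the package default mode, since
CDS-vs-CDS nucleotide search is the primary use), protein BLOSUM62 with gaps
11/1. Raw scores are scaled to e-values with the Karlin–Altschul form
`E = K·m·n·exp(−λS)` using fixed per-scheme parameters (nucleotide
λ = 1.28, K = 0.46; protein λ = 0.267, K = 0.041). The parameters are not
estimated from data: at this scale e-values rank hits and gate significance,
they are not publication statistics, and fixed constants keep runs
deterministic.

Per query, hits with `E ≤ 1e-5` (configurable; "significant" is otherwise
underdetermined) are ranked by higher score, then lower e-value, then higher
identity (percent identical columns over the optimal traceback), then
lexicographic target ID — mirroring best-hit selection "by e-value, score and
identity". Reciprocal best hits define ortholog pairs. Presence/absence
calling is two-stage: a gene missing from the partner's CDS set is
re-searched against the full assembly — on both strands, since genes sit on
either — and called `present_in_genome_only` on a hit, `absent` when both
stages fail.

## Overrepresentation tests

Group enrichment among a gene selection (typically genes with ≥ 50 AACs)
uses the one-sided hypergeometric upper tail `P(X ≥ x)` with population `N`,
group size `K`, selection size `n`, overlap `x`. Raw p-values are the
default — single raw bounds are the convention for this kind of screen — with
Benjamini–Hochberg available but off. The population size is an explicit
parameter: whether the universe is all predicted genes, all annotated genes,
or all genes with any AAC is a modelling choice the caller must make, so the
package refuses to guess (the pipeline defaults it to the reference
annotation's gene total).

## The synthetic strain pair

The simulator emulates the statistical structure of a real strain
comparison, not its sequence content. `generate`/`derive` produce:

* a multi-contig genome of intron-containing genes on both strands, each
  model complete (ATG start, single terminal stop, spliced CDS a whole
  number of codons) with canonical GT..AG introns and intergenic spacers
  ≥ 20 bp;
* a skewed family table (default five families over 16 of 50 genes,
  echoing a CAZome's concentration of a few hundred genes in a ~12,500-gene
  genome at toy scale) and functional-group table;
* a derived strain with SNPs at `0.96/60` and indels at `0.04/60` per bp —
  one variant per 60 bp at 96:4 SNP:indel, the realized density of the kind
  of monokaryon pair this emulates — plus explicitly placed splice-site SNPs
  and optional whole-gene deletions (gene span plus 10 bp flanks excised).

Design guarantees that make the truth labels trustworthy:

* injected sites are ≥ 10 bp apart and ≥ 10 bp from every region boundary,
  so each variant's consequence is independent and unambiguous;
* indel alleles are constructed already left-normalized (the last
  inserted/deleted base differs from the anchor base), so labels survive the
  reader's normalization pass;
* splice-site variants are a separate knob placed directly on the consensus
  dinucleotides — random placement almost never hits a 4-bp window at toy
  scale;
* one seeded Mersenne-Twister generator drives the whole run behind a
  save/restore shim, so outputs are byte-identical per seed and the global
  RNG state is untouched.

Truth labels are computed by machinery deliberately independent of the
classification engine: substitution effects by rebuilding the entire mutant
spliced CDS with plain string operations and diffing the full translations;
indel effects from net length change; splice labels from the injection site.
Derived coding sequences are extracted exactly via the cumulative coordinate
shift of all applied indels.

What the simulator does **not** emulate: realistic nucleotide composition,
repeats and low-complexity sequence, diploidy/heterozygosity, clustered or
region-biased variant placement (placement is uniform because the real
per-region distribution is unknown), overlapping variants, and sequencing
reads or their errors. Passing the truth-recovery suite therefore shows the
engine implements its stated rules exactly on clean, well-spaced variants —
it does not show robustness to overlapping calls, mis-left-aligned inputs
from other callers, or annotation errors, which real data can contain.

## Validation and problem sizes

The test suite validates each layer against an independent oracle at sizes
chosen to keep the whole suite fast while exercising every code path:

* consequence engine: 100% truth-label recovery on the default synthetic
  pair (1 contig × 100 kb, 50 genes, ≈ 1,600 variants), plus agreement with
  a rebuild-and-diff oracle and mirrored-strand symmetry on hand-built
  genes;
* alignment: score equality with a brute-force "last aligned pair"
  recursion over a fixed panel of sequences up to 12 residues, all pairs,
  both scoring modes;
* enrichment: equality with exhaustive enumeration of all draws for
  populations up to 25 (tolerance 1e-12);
* homology calls: identity pairing and input symmetry of reciprocal best
  hits; exact presence/absence recovery with 1 and 10 genes deleted on a
  20-gene pair.

## Limitations

One transcript per gene; no splicing-aware re-prediction downstream of a
VCSS; no compound effects of multiple variants on one codon (the simulator
spaces variants apart; real callers may not); no BLAST-compatible statistics
(e-values are internally consistent, not comparable across tools); no
phased/diploid genotypes (GT fields are ignored); plotting is quick-look,
not publication-grade.
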