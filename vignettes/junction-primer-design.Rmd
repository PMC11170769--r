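---
title: "Designing transcript-specific qPCR primers on exon-exon junctions"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Designing transcript-specific qPCR primers on exon-exon junctions}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(junctionprimer)
```

## The problem

Intercalating-dye RT-qPCR reports every double-stranded molecule a primer
pair amplifies. A well-designed assay therefore has to solve four problems at
once: the primers must hit the transcript isoforms the experiment is about
(and miss the ones it is not), they must not amplify contaminating genomic
DNA, they must avoid positions where common polymorphism would destabilise
annealing in some samples, and they must satisfy the usual thermodynamic
constraints (melting temperature, GC content, no dimers or hairpins).
`junctionprimer` treats these as one coupled design problem anchored on
exon-exon junctions: a junction is a cDNA position that does not exist as
contiguous sequence in the genome, so a primer crossing it (or an amplicon
bridging it) discriminates spliced RNA from gDNA, and the particular set of
junctions an isoform carries discriminates it from its siblings.

## The procedure

1. **Transcript models.** Exon features from a GTF/GFF are spliced against
   the genome FASTA into cDNA sequences; each transcript records the cDNA
   position of the last base of every upstream exon (its junctions). A
   junction is identified *genomically* by its (donor, acceptor, strand)
   triple, so the same splice event shared by isoforms with different 5'
   ends unifies. Custom transcripts can come from a FASTA whose header
   carries `junctions=<0-based offsets>` or from a GenBank record with exon
   features.

2. **Junction selection.** For a target set $S$ of transcripts, a junction
   $J$ with transcript incidence $T(J)$ is *perfect* when $T(J) = S$:
   present in every selected isoform, absent from every unselected one. When
   no perfect junction exists, all junctions are ranked by coverage
   ($|T(J) \cap S|$, descending), leakage ($|T(J) \setminus S|$, ascending),
   presence on the canonical transcript, then genomic coordinate, and the
   non-targeted/undetected transcripts of the top junction are reported as
   warnings. Ties at the top rank are all forwarded to primer design — the
   per-pair specificity screen, not an arbitrary choice, decides between
   them. Note that perfect sets for different target sets are disjoint
   (each junction is perfect precisely for its own incidence set), so the
   size of the perfect set is not monotone in $|S|$.

3. **Variant masking.** VCF records whose allele frequency reaches the
   threshold (default 1%, inclusive — the conservative reading for assay
   safety) mask their full REF footprint; masked genomic positions are
   projected through the exon structure and set to `N` in the design
   template. Masking is a hard exclusion: no primer window may contain `N`.

4. **Pair enumeration.** Around a junction at cDNA position $j$, every
   primer window is screened against the length, mask, $T_m$, GC, hairpin
   and homodimer constraints, then paired across the junction under
   amplicon-length, $T_m$-difference and heterodimer constraints. In `span`
   mode exactly one primer of a pair crosses the junction with at least the
   configured overhangs on its 3' and 5' sides; in `flank` mode the primers
   sit strictly on opposite sides (the amplicon crosses, the primers do
   not — acceptable only when gDNA contamination is not a concern).
   Enumeration is exhaustive and deterministic; each run reports a
   rejection-cause histogram.

5. **Two-round specificity screen.** Round 1 searches every pair against
   the spliced-transcript database — the nucleic-acid species that dominates
   an RT reaction — and classifies each predicted product as `on_target`,
   `non_target_isoform`, or `off_target_gene`. Pairs with off-target-gene
   products fail, unless *every* pair has one, in which case all are kept
   and flagged so the user can decide. The best survivors (default 10, by
   penalty then product count) advance to round 2, a genomic screen;
   genomic products down-rank a pair but never silently remove it, because
   transcript-side specificity is the primary concern in RT-qPCR and a
   flagged pair may still be the best available. Single-primer alignments
   that cannot form a product ("unproductive hits") are retained on every
   report.

## The models under the constraints

**Melting temperature** uses nearest-neighbor enthalpy/entropy summation
with the unified parameter set, duplex-initiation terms per terminal base
pair, the monovalent-salt entropy correction
$\Delta S_{salt} = 0.368\,(N-1)\ln[\mathrm{Na}^+]$, and
$T_m = \frac{1000\,\Delta H}{\Delta S + \Delta S_{salt} + R \ln C}\! - 273.15$
with $C = C_T/4$ for a non-self-complementary duplex ($C_T$ the total oligo
concentration, default 500 nM; 50 mM monovalent salt, no divalent
correction). The published table entries are stored as integers scaled by
ten, so the enthalpy/entropy sums are exact regardless of summation order:
the per-oligo path and the vectorised template-prefix-sum path used during
enumeration produce bit-identical temperatures, and
$T_m(s) = T_m(\mathrm{revcomp}(s))$ holds exactly.

**Dimer and hairpin scoring** is a deterministic ungapped complementarity
alignment (match $+1$, mismatch $-1$, best window over all antiparallel
offsets, floored at 0), with a 3'-anchored variant that only counts
alignments covering a primer's 3' terminus, and a hairpin variant requiring
a loop of at least 3 nt. Defaults reject a primer or pair when any score
reaches 8 or a 3'-anchored heterodimer score reaches 5. This is a testable
contract — every value is verifiable by brute-force enumeration — rather
than a thermodynamic duplex-folding model; users needing folding energies
should validate final candidates externally.

**Binding-site search** is an exhaustive Hamming scan over both strands of
every database sequence (delegated to `Biostrings::matchPattern`, which
guarantees the complete site set): a site qualifies with at most
`max_mismatch` (default 3) mismatches over the full primer length. A site
pair is *productive* — can yield a PCR product — when the sites converge on
one sequence, the product length is positive and within the cap (default
2000 nt on cDNA, 5000 nt on genome), and both sites have zero mismatches in
their 3'-terminal 5 nt. No heuristic seeding is involved, so no qualifying
site can be missed; an accelerated index would only be admissible if it
provably returned the identical set.

## Tunable parameters

| Parameter | Default | Meaning |
|---|---|---|
| `primer_len` | 18/20/25 nt | min / optimum / max primer length |
| `tm` | 59/60/62 °C | melting-temperature window and optimum |
| `gc` | 0.35–0.65 | GC-fraction window |
| `min_amplicon`, `max_amplicon` | 70, 200 nt | qPCR-sized products |
| `junction_overlap_3p`, `_5p` | 4, 4 nt | minimum bases past the junction on each side of a spanning primer |
| `max_pair_tm_diff` | 2 °C | forward/reverse $T_m$ mismatch |
| `dimer_any_limit`, `dimer_3p_limit` | 8, 5 | complementarity-score cutoffs |
| `monovalent_mM`, `oligo_nM` | 50, 500 | $T_m$ model conditions |
| `maf` threshold | 0.01 | variant-masking allele frequency (inclusive) |
| `max_mismatch` | 3 | binding-site search tolerance |
| `top_n` | 10 | round-1 survivors screened genomically |

The overlap minima and the thermodynamic settings are this package's own
declared defaults — published junction-design tools state that such minima
exist without giving values — and all are exposed as arguments and CLI
flags.

**A caveat worth knowing.** With the minimal 4-nt overhang, a spanning
primer's short tail is its only protection on the side where the tail
mismatches: at the corresponding genomic (or sibling-isoform) locus the
primer's other, long portion matches contiguously, its 3'-terminal window
can be clean, and three tolerated mismatches may not cover the tail. Such
pairs genuinely can prime gDNA — which is precisely why the genomic round
exists and reports them. Under exact-match semantics (mismatch tolerance 0)
a spanning primer has no genomic site at all, since its sequence does not
exist contiguously in the genome. If strict isoform or gDNA discrimination
matters, raise the overlap minima (8 nt on both sides is a comfortable
margin) and treat any pair flagged in round 2 as disqualified.

## Scoring and ranking

Each pair carries
$\mathrm{penalty} = |T_{m,f} - T_{opt}| + |T_{m,r} - T_{opt}| +
|T_{m,f} - T_{m,r}| + w_{len}\,\Sigma|L - L_{opt}| + w_{gc}\,\Sigma|gc - gc_{opt}|$
(with $w_{len} = 0.25$ °C/nt, $w_{gc} = 5$ °C per GC-fraction unit,
$gc_{opt}$ the window midpoint), and after screening
$\mathrm{score} = \mathrm{penalty} + 2\,n_{iso} + 5\,n_{gene} + 3\,n_{gen}
+ 0.1\,n_{unprod}$. Lower is better; a clean pair at the optimum scores 0.
The score is this package's own construction (reported tools display a
score without defining one) and is labelled as such in the output. Ties
break by amplicon length, then pair id, so ranking is a total order and
output is identical across runs and platforms. Reported temperatures and
scores are fixed at two decimals, which makes the CSV/TSV/JSON reports
round-trip losslessly.

## The synthetic-locus generator

`generate_locus()` builds a seeded single-chromosome locus with full ground
truth: a gene of `n_exons + 1` exon slots in which isoform $k$ skips slot
$2 + k$, so all isoforms share the first junction and each owns at least one
private exon-skipping junction; exon lengths 80–300 nt, introns 500–5000 nt,
background GC 0.5. Design feasibility is constructive, not hoped-for: each
exon's terminal 40 nt are drawn at 60% GC, and the leading window of every
exon is rejection-sampled (seeded, bounded tries) until every junction that
can end at it — from the consecutive and the one-exon-skip donor — admits at
least one spanning primer at default parameters; purely random GC-balanced
windows leave roughly a tenth of junctions with no candidate inside the
tight 3 °C window. Variants are written with allele frequencies straddling
the 1% threshold from both sides (including one at exactly 0.01, which must
mask, and one multi-base deletion exercising the REF-footprint rule), placed
at least 45 nt from exon boundaries so masking never destroys all
candidates. Optional plants: an intron-less copy of the canonical cDNA
elsewhere on the chromosome (a processed pseudogene), and a decoy
"other-gene" transcript containing the ±250 nt neighbourhood of the shared
junction verbatim — the flanking exons are then drawn ≥ 260 nt so the copied
window never crosses a private junction and contains every qPCR-sized
amplicon over the shared one, making it a universal off-target for that
junction by construction. The same seed reproduces every file byte for byte.

What the generator does *not* emulate: real splice-site motifs, sequence
repeats and low-complexity regions, paralogous gene families, expression
levels, or RefSeq/Ensembl annotation quirks. Green tests on these loci
demonstrate the algebra, the search and the bookkeeping are correct; they do
not certify wet-lab performance of any particular primer pair on a real
transcriptome, which still depends on validation qPCR.

## Numerical and edge-case choices

- Genomic coordinates are 1-based inclusive throughout (the Bioconductor
  convention); the custom-FASTA `junctions=` header keeps 0-based offsets
  and is converted at the parse boundary.
- Canonical transcript: the `Ensembl_canonical` tag when present, else the
  longest cDNA, ties broken by smallest transcript id — deterministic when
  the annotation lacks the tag.
- Ambiguity letters other than `N` are rejected at genome load; the
  thermodynamic tables are defined over A/C/G/T.
- Single-exon genes raise a structured error from junction selection:
  junction-anchored design is impossible and flanking design has nothing to
  flank.
- Dimer screening during enumeration walks candidate pairs in final ranking
  order and stops once `max_candidates` pairs are accepted; unevaluated
  pairs rank strictly below every accepted one, so the emitted set is
  unaffected while degenerate templates still produce a complete
  rejection histogram.
- The masking boundary is inclusive (frequency ≥ threshold masks), taking
  the conservative side of the two phrasings common in database
  documentation.

## Problem sizes used by the test suite

The automated checks run junction-selection oracle comparisons on 200
random gene models (≤ 6 isoforms, ≤ 12 exons, every non-empty target
subset), binding-site oracle comparisons on 50 random instances up to
100 kb, constraint validation across 100 seeded locus designs, planted
pseudogene/decoy recovery on 3 and 20 seeded loci respectively, and
duplex-symmetry checks on 1000 random oligos — sizes at which every
property is exercised many times over while the whole suite stays
comfortably interactive.

## Limitations

- No probe (hydrolysis) design, degenerate-base primers, or multiplex
  balancing.
- Dimer scores are alignment counts, not folding energies.
- Off-target ranking is count-based; no binding-energy weighting.
- Gapped (indel) primer-template alignments are not searched.
- Live annotation retrieval is out of scope: inputs are local files.
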