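---
title: "Methods and design notes for mitocomp"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods and design notes for mitocomp}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

This vignette documents the statistical and algorithmic choices behind
each analysis stage: the quantities computed, the assumptions they rest
on, the tunable parameters with their defaults and rationale, what the
synthetic-data generator does and does not emulate, and the numerical
corner cases. It states no empirical result that the test suite or
`scripts/acceptance.R` does not itself compute.

## Data model and coordinates

A genome is a circular (or partial) DNA string with typed features over a
closed set of 38 canonical labels: 13 protein-coding genes, 22 tRNAs
(with the leucine and serine isoacceptors disambiguated as `trnL1` =
Leu(CUN), `trnL2` = Leu(UUR), `trnS1` = Ser(AGY), `trnS2` = Ser(UCN)),
two rRNAs, and the A+T-rich control region `CR`. Internally all
coordinates are 0-based half-open on the plus strand of the input file;
GenBank's 1-based inclusive convention is converted exactly once, at the
I/O boundary, which keeps all interval arithmetic closed under rotation
and reverse complement. A feature crossing the origin keeps its start in
`[0, n)` and lets its end exceed `n`; `join(a..n,1..b)` locations are
merged into such a wrapping feature at parse time.

Free-text gene names are mapped by a case- and punctuation-insensitive
alias table plus a tRNA grammar (3-letter or 1-letter amino acid, codon
family where present). Mapping is a total function: unknown names yield
an `unmapped` sentinel and a collected warning, never an error, because
real records regularly carry idiosyncratic qualifiers.

Gene overlaps up to 10 bp are tolerated silently (mitochondrial genes
commonly overlap by ≤ 7 bp, e.g. *atp8*/*atp6*); larger overlaps warn.
Duplicated gene copies — as occur in real records with partial
duplications — are retained but flagged, and flagged copies are excluded
from gene-order extraction.

## Composition and strand asymmetry

AT skew = (A − T)/(A + T), GC skew = (G − C)/(G + C), A+T% =
100·(A+T)/(A+T+G+C). `N` and other ambiguity codes are excluded from both
numerators and denominators, because partial genomes are deposited with
gap-filling `N` runs; a skew whose denominator is empty is reported as
`NA`, never coerced to 0. Rounding (2 decimals, matching the field's
reporting convention) happens only at serialization.

The majority strand is *recomputed* as the strand encoding more genes
(control region excluded; ties broken toward the strand carrying *cox1*)
rather than trusted from the file, because heavily rearranged genomes can
have many minority-strand genes. The whole-genome profile measures the
majority strand of the full circular sequence. The all-PCG profile
concatenates the 13 protein-coding genes read in majority-strand
orientation by default; a `pcg_orientation = "sense"` switch reads each
gene on its own coding strand instead. Both conventions preserve the
ichneumonid-vs-braconid sign contrast, and the published table does not
state which was used, so the choice is exposed rather than hidden.

The asymmetry call uses a dead band of ε = 0.02 around zero: GC skew
above +ε is `reversed`, below −ε `normal`, otherwise `indeterminate`.
All published values for this clade sit at |skew| ≥ 0.05, so the call is
insensitive to ε an order of magnitude either way; the band only guards
against near-zero noise in short regions.

## Rearrangement classification

Gene orders are signed circular permutations, normalized deterministically:
rotate so *cox1* is first and, if *cox1* lies on the minus strand,
reflect (reverse the list, flip all signs) first. All reports are
therefore invariant under genome rotation and reverse complement.

Per-gene classification compares each gene's observed context with its
ancestral context. Neighbor checks are *side-aware* — the observed
predecessor is compared with the ancestral predecessor, the successor
with the successor — but *strand-blind* on the neighbors (a neighbor that
flipped strand still counts as present: "position" means location, not
orientation). Side-awareness is what makes a two-gene swap mark both
genes as shuffled while leaving their outer neighbors ancestral; a
side-blind test cannot express that case. A gene is *changed* iff its
sign differs from ancestral or neither flank is preserved; the status is
then:

* `local_inversion` — sign flipped, both flanks preserved;
* `shuffled` — sign preserved, flanks changed, displacement ≤ W;
* `translocation` — sign preserved, displacement > W;
* `remote_inversion` — sign flipped and flanks changed.

Displacement is measured against the gene's own ancestral neighbors'
observed positions (the minimum circular distance from the observed
position to the slot adjacent to either ancestral neighbor), not as a
difference of anchored ranks: anchored ranks shift by one when a move
crosses the anchor point, which would misclassify boundary cases. The
shuffle window defaults to W = 3 gene ranks; the literature describes
shuffling only by example (always within tRNA clusters spanning ≤ 3
positions), so W is a configurable convention, not an estimate. A
one-slot swap of two adjacent genes is inherently symmetric — both genes
are reported shuffled, which matches how such swaps are described in the
field.

Genes absent from partial genomes are dropped from both orders before
comparison, so the flanks of a sequencing gap bridge over it. A second
classification on the PCG+rRNA+CR projection (tRNAs removed first)
ensures tRNA-only movement never marks a protein-coding gene as changed;
both full-order and projected changed-counts are reported, the projected
one being the convention used for statements like "seven of 13
protein-coding genes rearranged". Maximal runs of adjacent genes sharing
one status merge into block events; mechanism attributions (recombination
vs tandem-duplication/random-loss narratives) are deliberately *not*
inferred — the block table has a free-text annotation column instead,
because mechanism arguments are interpretive, not computable from one
arrangement.

Breakpoint distance counts signed circular adjacencies of one order
missing from the other (each adjacency canonicalized over its two reading
directions). It is symmetric and zero exactly on equal normalized orders.
It is reported as a model-free oracle; minimum-event scenario
reconstruction (sorting by reversals, DCJ) is out of scope.

### Pseudogene remnants

Vacated loci are searched by Smith–Waterman local alignment (match +1,
mismatch −1, gap open 2, extend 1) of the query gene's sense sequence and
its reverse complement against every feature-free interval ≥ 20 bp. A hit
needs identity ≥ 0.6 over ≥ 65% of the gene length; the span floor
matters because 85% A+T sequences produce short high-identity local
alignments freely. When both strands of one interval pass (A+T-rich
sequences resemble their own reverse complement), only the better
alignment is kept. The reported strand states where the query's sense
sequence lies; for an in-place-inverted remnant of an ancestrally
minority-strand tRNA this is the plus strand, and the substantive claim —
the remnant runs opposite to the ancestral copy — is carried by the
generator's ground-truth log rather than by a sign convention.

## Control-region annotation

The region is the annotated CR feature, or the largest feature-free span
(≥ 100 bp) in a complete genome; partial genomes without either raise a
not-found error rather than guessing.

The canonical element layout, 5′→3′: polyT stretch, [TA(A)]ₙ stretch,
stem–loop flanked by TATA and G(A)ₙT motifs, G+A-rich tract. The source
literature describes these elements qualitatively; every numeric
threshold here is therefore a package choice, exposed as an argument:

| element | detector | default threshold |
|---|---|---|
| polyT | longest T run, ≤ 1 interruption | ≥ 12 (report), ≥ 14 (orientation) |
| [TA(A)]ₙ | maximal TA/TAA concatenation | ≥ 6 copies (report), ≥ 7 (orientation) |
| stem–loop | exhaustive hairpin scan | stem 10–25 bp, loop 3–30, ≤ 1 mismatch |
| TATA / G(A)ₙT | literal motifs near a hairpin | within 30 bp |
| G+A-rich | maximal purine-rich window | ≥ 20 bp at ≥ 0.7 purine |

Hairpin pairing is Watson–Crick DNA only (no G·U), as the elements are
genomic DNA signals, and the scan is exhaustive rather than
thermodynamic: free-energy folding is out of scope. The top three
non-overlapping hairpins are reported, each with its own flanking motifs
and downstream purine tract, because a chance hairpin can outscore the
functional one in A+T-rich sequence and would otherwise hijack the
flanking-motif search.

Tandem repeats are found by k-mer (k = 12) seed-and-extend: repeated
k-mers propose candidate unit lengths from occurrence distances, anchors
are walked to the leftmost copy and extended copy by copy while identity
to the first copy stays ≥ 0.85, fractional trailing copies are allowed,
and overlapping tracks are merged keeping the highest copies × identity.

### Orientation inference

Orientation is the argmax over strands of a layout score; ties (including
0–0) are `indeterminate`. The score is computed over the longest chain of
distinct element kinds in canonical order that starts with a 5′ anchor
(polyT or [TA(A)]ₙ), with one candidate chain per detected hairpin. Two
deliberate refinements over a bare kind count:

1. **Quality weighting.** Several detectors are strand-symmetric (a
   hairpin is its own reverse complement, TATA is palindromic) and the
   complement of a G+A tract resembles a polyT stretch — so on a genuinely
   inverted region, bare kind counts on the two strands are almost always
   tied. Each chained element therefore contributes its score relative to
   its detection threshold (capped at 2), which separates the real layout
   from its mirror image.
2. **Callability floor.** A chain of fewer than 5 kinds scores 0. With
   the orientation-level thresholds (polyT ≥ 14, ≥ 7 TAA copies), this
   floor was calibrated jointly against the generator and the A+T-matched
   random null model — the two reference distributions this package
   defines — giving 100% orientation accuracy on generated regions and
   ≈ 96% indeterminate calls on 575 bp, 85% A+T random strings (both
   recomputed by the acceptance script). On real divergent control
   regions an indeterminate call should be read as "no confident layout",
   not "no elements".

## Ka/Ks (Nei–Gojobori with Jukes–Cantor correction)

The classic unweighted-pathway Nei–Gojobori method under the invertebrate
mitochondrial code (table 5; `TGA` = Trp, `ATA` = Met, `AGA`/`AGG` =
Ser). Per codon, each position contributes the fraction of its possible
single-base changes that are synonymous, with stop-codon targets excluded
from the denominator; per codon pair, substitution counts are averaged
with equal weights over all orderings of the differing positions,
discarding orderings that pass through a stop codon (pairs with no valid
pathway are skipped with a warning). Codons containing gaps or ambiguity
in either sequence are excluded pairwise — not by complete-column
deletion — because five of the motivating genomes are partial. Site
totals are averaged over the two sequences; proportions pₛ = Sd/S and
pₙ = Nd/N are Jukes–Cantor corrected, d = −(3/4)·ln(1 − (4/3)p). The
64×64 pathway tables and per-codon site counts are computed once and
cached.

Guard rails: fewer than 30 comparable codons is an error (insufficient
data), pₛ or pₙ ≥ 3/4 is a saturation error naming the gene, and the
ratio is undefined (`NA`) when Ks = 0. Genome-level estimates strip
terminal (possibly truncated `TA`/`T`) stops, trim each shared gene pair
to a common codon count, report per-gene estimates, and pool the
comparable codons of all non-flagged genes into a concatenated estimate;
saturated or data-poor genes are flagged and excluded from the pool.
Maximum-likelihood codon models, transition/transversion-weighted
pathway variants, and bootstrap intervals are out of scope.

## Phylogenetic matrices

Per-gene codon alignments (read from FASTA or built by back-aligning
coding sequences onto an amino acid alignment, where each amino acid gap
expands to `---`) are concatenated following the ancestral gene order.
User-supplied column masks (0-based half-open intervals per gene) are
removed first and must leave a length divisible by 3 — the manual
exclusion of ambiguously aligned regions is accepted as explicit input,
never automated, since it is not reproducible otherwise. Four dataset
kinds: `aa` (table-5 translations), `Pos12`, `Pos123`, and `Pos12RY3`
(positions 1–2 as nucleotides, position 3 recoded A,G → R / C,T → Y;
recoding is idempotent and maps anything else to the missing symbol
`?`). Taxa missing a gene are padded with `?` and reported. `nad2` (or
any gene) can be excluded, mirroring its removal from subfamily-level
analyses where it failed to amplify in most taxa.

Partitions are per gene and codon position, represented as stride-3
column ranges and emitted as NEXUS charsets (`charset g_pos1 = 1-99\3;`);
the RY-coded third position is one charset per gene by default, as its
two-state model is what distinguishes it. The partition set provably
tiles every matrix (machine-checked in the tests). Writers (relaxed
PHYLIP, FASTA, NEXUS with a sets block) treat `?` as missing and `-` as
gap, bit-exactly. Running tree inference and model selection are out of
scope: the pipeline ends at publication-ready matrices.

## The synthetic-data generator

The generator is the package's test instrument, and its defaults are the
study conditions the analyses assume: a 37-gene + CR circular genome in
the ancestral hexapod arrangement, ≈ 15.4 kb, 85% A+T (the clade's
observed range is roughly 82–88%), AT skew −0.07, and majority-strand GC
skew −0.15 for the ancestral state (a positive value, e.g. +0.15, with an
inverted CR emulates the derived state). Composition is matched by
rejection sampling to ±1% (A+T) and ±0.02 (skews). Protein-coding genes
use typical insect mitochondrial lengths, start with `ATN`, end with
`TAA`, and contain no internal stops; tRNA/rRNA sequences are
composition-matched random strings — downstream analyses use only their
position, strand and composition, so no folding constraints are imposed.
The control region carries all five elements in a realistic forward
layout (polyT 20, 8 TA(A) copies, perfect 18 bp stem, 24 bp purine
tract, three 60 bp tandem-repeat copies), reverse-complemented wholesale
for the inverted state; homopolymer runs in its filler are capped at 6 bp
so that chance poly-A/T runs cannot fake an anchor on the wrong strand.

Event scripts (shuffle, local inversion, translocation, remote inversion,
block inversion, duplication) rewrite sequence and annotation
consistently: moved genes carry their sequence, inversions
reverse-complement it, and relocating events can leave a spacer (presets
23 and 52 bp, the observed intergenic remnant sizes) or a pseudogene
remnant mutated to a target identity; a remote inversion's remnant is the
reverse complement of the original locus, recording that inversion
preceded translocation. The random-script sampler keeps event loci ≥ 4
gene ranks apart and never targets *cox1* (the normalization anchor), so
scripted events do not interact; shuffles draw offsets of 2–3 ranks
(one-rank swaps are two-gene events by symmetry) and translocations
destinations 5–14 ranks away.

Codon divergence uses acceptance thinning rather than a rate-matrix
simulator, giving direct control of the realized ω: proposals pick a
codon, a position, and one of the position's non-stop alternatives
uniformly — mirroring the estimator's stop-excluded site normalization,
which is what makes the realized ω match the nominal one — and are
accepted with probability 1 (synonymous) or ω (nonsynonymous), until the
synonymous proportion against the original reaches the Jukes–Cantor
inverse of the target Ks. Non-coding positions then mutate at the
synonymous-equivalent per-site rate. Terminal stop codons are immutable.

What the generator does *not* emulate — and what passing tests therefore
do not show about real data: tRNA cloverleaf structure and rRNA secondary
structure; codon-usage bias beyond base composition; among-site rate
variation and indels within coding genes; phylogenetically correlated
multi-taxon divergence (pairs only); and control regions whose elements
have diverged beyond recognition, as real ones sometimes have.

## Problem sizes and determinism

The validation harness uses 200 single-event scripts, 100 multi-event
scripts of 2–5 events, 100 generated control regions plus 100 A+T-matched
nulls, exhaustive codon-pair checks against a brute-force pathway
enumerator, and ω recovery at ω ∈ {0.05, 0.1, 0.5, 1.0} on full-genome
divergence pairs (≈ 3 700 codons; 50 replicates in the test suite, 12 in
the acceptance script, medians compared at 15%) — sizes chosen to
exercise each claim with comfortable margins while keeping a full run in
the minutes range. All randomness flows from explicit integer seeds;
identical configurations produce byte-identical genomes and GenBank
output.

## Known limitations

- The ancestral arrangement is a fixed constant (the pancrustacean ground
  plan); taxa whose true ancestor differs need a custom baseline order.
- Classification is per-gene and greedy: it reports the most parsimonious
  *description* of each gene's context, not a minimum-event scenario, and
  a one-slot swap is attributed to both genes by symmetry.
- Element detection in the control region is calibrated on the package's
  own generator and null model; thresholds may need loosening for taxa
  with degenerate layouts.
- Ka/Ks assumes equal base frequencies and no transition/transversion
  bias (the classic Nei–Gojobori variant); at high divergence the
  Jukes–Cantor correction saturates and the package refuses rather than
  extrapolates.
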