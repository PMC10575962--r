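---
title: "resistamp: methods and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{resistamp: methods and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

resistamp implements the informatics for a dual inline-barcode amplicon
sequencing ("amp-seq") assay used to survey insecticide-resistance markers
and species identity in *Anopheles funestus*. This vignette records the
model behind each stage, the tunable parameters with their defaults and
rationale, what the synthetic cohort generator does and does not emulate,
and the design decisions taken where the methodology left choices open.

## The assay model

A panel is a set of PCR amplicons (~500 bp each; the packaged panel has 17
amplicons over nine genes: *vgsc* ×6, *rdl* ×2, *ace-1* ×3, *GSTe2*,
*CYP6P4*, *CYP6P9a*, *cox-1*, *mt-ND5*, *ITS2*). Each primer carries an
8-bp inline barcode at its 5′ end; a sample is identified by its
(forward, reverse) barcode combination, which lets many samples share one
sequencing pool. Reads are 2 × 250 bp: R1 reads barcode + forward primer +
the amplicon 5′ end, R2 reads barcode + reverse primer + the
reverse-complemented 3′ end.

The packaged manifest under `inst/extdata/drc_panel/` is *synthetic but
structurally faithful*: amplicon count, gene composition, lengths, primer
layout, CDS frames and every known marker codon (with the correct
wild-type amino acid planted) match the assay's structure, but the base
sequences are simulated placeholders — the real primer/reference sequences
live in the assay's supplementary material and are substituted by the
user. Everything downstream is data-driven from the manifest, so swapping
in a real panel changes no code.

Thresholds are stored beside the manifest (`thresholds.json`) and default
to the published pipeline's values: minimum allele depth 20 reads, base
Phred strictly greater than 30, heterozygote band 20–80%, consensus depth
≥ 20× with samples excluded above 90% uncalled bases.

## Demultiplexing

Each barcode is matched independently against the registry by Hamming
distance; a read is assigned to the barcode at minimal distance only when
that distance is ≤ `barcode_max_mismatch` *and* the minimum is unique.
The default tolerance is 1: the source pipeline does not state its
tolerance, and one mismatch balances recovery against collision for
barcode sets separated by ≥ 3–4 substitutions (the packaged set has
pairwise distance ≥ 4). Ties are never broken arbitrarily — the pair goes
to the unassigned bin, preserving the partition invariant
(assigned + unassigned = input). Whether the original assay used one
shared set of ten barcodes or distinct forward/reverse sets is not
recorded; both work here, and the packaged registry uses one shared set.

## Trimming

After the barcode and matched primer are stripped from each mate's 5′
end, a Trimmomatic-style sliding window (size 4, mean Phred ≥ 20) scans
from the 5′ end; the mate is truncated at the first failing window, then
the kept region is extended over immediately following bases that
individually pass (so a window straddling the good/bad boundary does not
eat passing bases — exactly the low-quality tail is removed). Pairs with
either mate under 50 bases are discarded, not errored. The window
parameters are conventional defaults; the original study names the tool
but not its settings.

## Amplicon assignment and alignment

Reads are assigned to amplicons by their primers (R1 vs forward primers,
R2 vs reverse primers, each within `primer_max_mismatch = 2`, unique
minimum required). Discordant mates are flagged chimeric and dropped;
this replaces a general-purpose mapper, which is unnecessary when every
read begins with a known anchor.

Alignment is *glocal*: global in the read, local in the reference, with
affine gaps (match +2, mismatch −3, gap open −5, gap extend −2; a gap of
length *k* costs `open + k·extend`, so a length-1 gap costs −7 — the
scoring examples in the tests pin only the match/mismatch part, and this
convention is stated here because tools differ). A read whose optimal
alignment would run past a reference end has the overhang soft-clipped at
zero cost, mirroring the published pipeline's read-clipping step. The DP
is banded around the primer-predicted diagonal (half-width 16 by
default — generous for the ≤ 5 bp indels the panel expects, including the
known 2-bp promoter insertion) and the band doubles automatically
whenever the optimal path touches its edge, up to the full matrix.
Indels are left-aligned by score-preserving rotation, so every read
reports the same normalised event. A gapless fast path handles reads
within 3 substitutions of their expected window; this is exact, not an
approximation, because one substitution costs 5 while the cheapest gap
pairing costs more. Equivalence of the banded aligner with full dynamic
programming is property-tested against an independent R implementation.

## Pileup, variant calling and filtering

A base contributes to the pileup only if its Phred exceeds 30 — strictly,
so Phred 30 is excluded and 31 counts, following the stated "> 30" rule.
Deletions carry no base quality and always count; insertions count when
every inserted base passes. Each non-reference allele (base, insertion or
deletion event) with allele depth ≥ 20 becomes a PASS call; sub-threshold
alleles are omitted unless filtered records are requested. Alternate
fraction is allele depth over total passing depth at the column (anchor
column for indels); indels are reported VCF-style with a one-base anchor
after left-normalisation. Multi-allelic columns yield one biallelic
record per allele.

The original pipeline ran two probabilistic callers and merged their
output (by an unstated rule). resistamp replaces both with one
deterministic pileup caller: at amplicon depths (hundreds-fold) the
operative filters are exactly the evidence rules above, and a
deterministic caller makes every downstream number reproducible.
Cross-caller concordance is out of scope. R1 and R2 both contribute to
the pileup where they overlap, without deduplication — amplicon reads are
clonal by design, so overlap de-duplication would be arbitrary; the
behaviour is documented rather than hidden.

## Genotyping

Genotypes come from the alternate-allele fraction alone: below 20%
homozygous reference (S/S), 20–80% inclusive heterozygous (R/S), above
80% homozygous alternate (R/R). Both band edges are heterozygous — the
stated rule writes the het band as a closed range and the homozygous
rules strictly. Sites with passing depth below the caller minimum (20)
are no-calls. The three classes partition [0, 1] for any valid
thresholds, which is property-tested. Dosages (0/1/2, NA for no-call)
feed the LD machinery.

## Consequence annotation and marker reporting

Coding substitutions are translated through the amplicon's CDS map
(strand and frame aware; codon numbers are native *An. funestus*
numbering, with cross-species aliases such as ace-1 643 → N485I carried
as labels only, never used for matching). Amino-acid changes involving a
stop are reported as missense with `Ter` rather than as separate classes —
a deliberate simplification for a marker panel where no known marker is a
stop. Coding indels are classed by length mod 3; variants outside a CDS
are non-coding, with the amplicon's region label (the CYP6P9a amplicon is
a promoter region, so its 2-bp insertion annotates as a promoter
non-coding indel with no amino-acid change). Annotation is oracle-tested:
every possible single-base change of a coding amplicon is compared
against full-sequence translation on both strands.

Marker prevalence reports percentages rounded to one decimal, half-up
(matching how such tables are usually printed); raw counts are always
retained so any rounding convention can be rechecked. Carriage is
%R/R + %R/S; the resistant-allele frequency is `(2·nRR + nRS)/(2·n)`,
exact.

## Consensus and population genetics

Consensus calling reports the majority base where passing depth is ≥ 20×,
`N` otherwise, with ties masked `N`; samples above 90% `N` are excluded.
Majority base rather than IUPAC ambiguity codes: the three phylogenetic
loci are mitochondrial/ribosomal, where within-sample heterozygosity is
not modelled (an IUPAC mode would be a straightforward extension and the
choice is isolated in one function). Primer-binding positions are never
covered after trimming and are always `N`; such all-`N` columns carry no
pairwise information and are dropped before haplotype collapsing by the
diversity wrapper.

* **Nucleotide diversity** is the mean over unordered pairs of the
  proportion of differing sites, comparing only positions where both
  sequences are non-`N` (pairwise deletion); pairs with no comparable
  sites are skipped with a warning.
* **Per-site diversity** is `2j(n−j)/(n(n−1))`, and equals the sequence
  version restricted to a single segregating site (tested identity).
* **Haplotype diversity** is `(n/(n−1))(1 − Σp²)` over equivalence
  classes of identical sequences; sequences still containing `N` are
  excluded from collapsing by default (a `drop_sites` alternative removes
  every N-containing column instead).
* **LD** is the squared Pearson correlation of dosage vectors over
  pairwise-complete cases; monomorphic vectors are undefined (NA), and
  the statistic is invariant to allele-label swaps.
* **Fst** uses the Weir & Cockerham (1984) two-population estimator in
  its allele-count (haploid) form, since the declared inputs are allele
  counts; the per-site value is `a/(a+b)` and the mean is the ratio of
  summed components. The estimator reaches exactly 1 for fixed
  differences and is *unbiased around* 0 rather than identically 0 when
  frequencies coincide — identical frequencies at equal sizes give
  `−1/(n̄−1)`. This is a property of the estimator, not a bug, and the
  tests assert the exact value.
* **Haplotype networks** are minimum spanning networks: Kruskal's MST
  over pairwise Hamming distances (ties broken by lexicographic node
  order, so output is deterministic) plus every non-tree edge whose
  distance equals the maximum edge weight on the tree path between its
  endpoints — the standard equal-cost "tie edge" rule; the exact variant
  used by the cited network tool is not published, so the conventional
  path-max rule is used and stated. Distances ignore indels (sequences
  must be aligned and equal length, which amplicon consensi are).
* **Species identification** replaces a BLAST query with a built-in
  percent-identity classifier: glocal alignment against each labelled
  reference, identity over aligned non-`N` columns, resolved when the
  best identity reaches 97% (below the ~97–99% identities reported for
  congeneric assignments, above within-species divergence at these loci),
  with the runner-up margin reported.

## The synthetic cohort generator

`simulate_cohort()` emits the world the assay states: fixed 250-bp mates
(barcode + primer + insert, R1 from the 5′ end, R2 reverse-complemented
from the 3′ end), a configurable per-amplicon depth (default 100 pairs
per sample-amplicon, comfortably above the ~290-read pool minimum the
assay budgets), constant Phred 35 (an optional two-level profile injects
sub-threshold tails to exercise the quality filter), and uniform i.i.d.
substitution errors (default 10⁻³, a typical post-filter short-read
rate; round-trip acceptance runs use 0 where the criterion states
error-free input). Heterozygous samples draw each read pair's haplotype
from Bernoulli(0.5), so alleles sharing a haplotype stay linked within
reads — which is what makes simulated LD behave like real amplicon LD.
Mitochondrial and ribosomal loci are constrained homozygous (haploid
biology), which also makes their expected consensus deterministic; truth
tables include expected consensus only where the outcome is deterministic
under deep error-free settings (no het or indel variant at that
sample-amplicon; primer shadows masked `N`).

What a green round-trip does *not* establish: the generator has no PCR
chimeras, no index hopping, no amplification bias, no platform error
spectra, no fragment-length jitter, and the packaged panel's sequences
are synthetic. Green tests certify the informatics — partitioning,
evidence arithmetic, threshold behaviour, coordinate bookkeeping,
estimator algebra — not robustness to artefacts the generator does not
model.

## Numerical and degenerate-input choices

Zero-depth pileup columns are skipped, not called. Consensus ties mask
`N`. Indel events unanchorable at the reference start (position 0) are
dropped. LD for monomorphic variants is NA, never 0. Fst sites with
`a + b = 0` are excluded from the mean. Diversity pairs with zero
comparable sites are skipped with a warning, and an error is raised only
when *no* pair is comparable. All report rounding is half-up to one
decimal and applied only at the reporting layer.

## Known limitations

Soft-clipping is limited to reference ends (no internal chimera
splitting); deletions are counted without a quality proxy; stop-gain
changes are folded into missense; the MSN tie rule is one conventional
choice among several; and within-sample heterozygosity is invisible in
consensus sequences. The packaged panel must be replaced with the real
manifest before the toolkit says anything about real mosquitoes.
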