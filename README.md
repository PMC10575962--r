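# resistamp

Targeted amplicon-sequencing informatics for insecticide-resistance
surveillance in *Anopheles funestus* mosquitoes.

Malaria vector control leans on insecticides, and resistance mutations —
*kdr* substitutions in the voltage-gated sodium channel (*vgsc*), ace-1
N643I (alias N485I) for carbamates, rdl A296S for dieldrin, GSTe2 L119F
for DDT, and the CYP6P9a promoter 2-bp insertion for pyrethroids — spread
fast. Multiplex amplicon sequencing ("amp-seq") screens dozens of such
loci in hundreds of field-caught mosquitoes per run: ~500 bp amplicons,
each primer carrying an 8-bp inline barcode so the (forward, reverse)
barcode combination identifies the sample within a pooled 2 × 250 bp
MiSeq run. resistamp is the complete analysis stack for such an assay,
for entomologists and genomic-surveillance groups: from pooled FASTQ to
genotypes, resistance-marker reports, consensus sequences and
population-genetic summaries — plus a simulator so the whole pipeline is
testable without sequencing anything.

## What it computes

* **Demultiplexing** by dual inline barcodes (Hamming matching,
  unique-minimum tie rule), **primer-based amplicon assignment** with
  chimera detection, **trimming** (barcode + primer strip, sliding-window
  quality rule), and **banded glocal affine-gap alignment** with
  left-aligned indels (Rcpp).
* **Variant calling** from base-quality-filtered pileups: a base counts
  only if Phred > 30, an allele is called only at allele depth ≥ 20; VCF
  4.2 output with per-sample GT/DP/AD.
* **Allele-fraction genotyping**: alt fraction < 20% → S/S, 20–80% → R/S,
  \> 80% → R/R; no-calls below 20× depth.
* **Codon-level annotation** against the panel CDS maps (strand/frame
  aware, native codon numbering with cross-species aliases such as
  N485I), known-marker matching, and prevalence reports — carriage
  (%R/R + %R/S) and resistant-allele frequency (2·nRR + nRS)/(2n).
* **Depth-masked consensus** (≥ 20× per position, N otherwise; samples
  \> 90% uncalled excluded) and **population genetics**: nucleotide
  diversity π (pairwise deletion), per-site π = 2j(n−j)/(n(n−1)),
  haplotype diversity H = n/(n−1)(1 − Σp²), LD r² from genotype dosages,
  Weir–Cockerham Fst, minimum-spanning haplotype networks
  (Kruskal + equal-cost tie edges), and percent-identity species
  assignment (e.g. *An. funestus* vs *An. gambiae* by *cox-1*).
* **A synthetic-cohort simulator** emitting barcoded paired reads plus
  truth tables (read map, genotypes, expected consensus) for end-to-end
  validation.

The packaged panel (`drc_panel_path()`) mirrors the real assay's
structure — 17 amplicons over 9 genes, 10 shared barcodes, an 80-sample
two-population sheet, 11 known markers — with synthetic placeholder
sequences users replace with their own manifest.

## Worked example

Simulate a 12-sample cohort over the packaged panel and run the full
pipeline:

```r
library(resistamp)
library(dplyr)

panel <- load_panel(drc_panel_path())
sheet <- load_sample_sheet(file.path(drc_panel_path(), "samples.tsv"), panel)

spec <- random_cohort_spec(panel, sheet, n_samples = 12, depth = 100,
                           error_rate = 0.001, seed = 99)
sim <- simulate_cohort(spec)
run <- run_pipeline(sim$pairs, sheet, panel)

glance(demultiplex(sim$pairs, sheet, panel))
#> # A tibble: 1 × 4
#>   n_pairs n_assigned n_unassigned n_samples
#>     <int>      <int>        <int>     <int>
#> 1   20400      20400            0        12
```

Every one of the 20,400 pairs (12 samples × 17 amplicons × 100 pairs)
found its sample. The cohort-union variant calls include the CYP6P9a
promoter insertion and the marker SNPs, with alternate fractions at the
values genotyping expects (≈0.5 for a cohort where some samples are het,
1.0 where all carriers are homozygous):

```r
run$variants %>% select(amplicon_id, pos, ref, alt, type, alt_fraction)
#> # A tibble: 20 × 6
#>   amplicon_id      pos ref   alt   type  alt_fraction
#>   <chr>          <dbl> <chr> <chr> <chr>        <dbl>
#> 1 CYP6P9A      8570149 G     GAT   ins           1
#> 2 ACE1I       19553117 G     A     snp           0.56
#> 3 ACE1III     19555131 A     T     snp           0.52
#> 4 RDL1        25420138 G     T     snp           1
#> 5 VGSCI       42338491 G     C     snp           0.57
#> # i 15 more rows
```

The marker report gives genotype-class counts, carriage and allele
frequency per marker (here three of the eleven):

```r
marker_summary(run$genotypes, run$marker_hits) %>%
  filter(population == "All",
         marker_id %in% c("ace1_N643I", "cyp6p9a_ins", "rdl_A296S")) %>%
  select(marker_id, n_genotyped, n_RR, n_RS, n_SS, carriage_pct,
         allele_freq_pct)
#> # A tibble: 3 × 7
#>   marker_id   n_genotyped  n_RR  n_RS  n_SS carriage_pct allele_freq_pct
#>   <chr>             <int> <int> <int> <int>        <dbl>           <dbl>
#> 1 ace1_N643I           12     0     3     9         25              12.5
#> 2 cyp6p9a_ins          12     2     3     7         41.7            29.2
#> 3 rdl_A296S            12     1     5     6         50              29.2
```

So 3 of 12 simulated samples carry at least one ace-1 N643I allele
(carriage 25%), and the CYP6P9a resistant-allele frequency is
(2·2 + 3)/24 = 29.2%. Diversity of the *cox-1* consensus sequences
across the cohort:

```r
cons <- run$consensus %>% filter(amplicon_id == "COX1", !excluded)
diversity_stats(cons$sequence)
#> # A tibble: 1 × 4
#>   n_seq n_hap hap_diversity nuc_diversity
#>   <int> <int>         <dbl>         <dbl>
#> 1    12     5         0.788       0.00353
```

Twelve sequences collapse to five haplotypes (H = 0.79) with π ≈ 0.0035 —
the "many low-frequency variants" signature typical of mitochondrial
amplicons. `min_spanning_network()` + `autoplot()` draws the haplotype
network; `ld_r2(dosage_matrix(run$genotypes))` gives the LD matrix;
`fst_wc()` compares the two collection-site populations;
`identify_species()` assigns consensus sequences to reference species by
percent identity.

A thin CLI wraps the same functions:
`Rscript inst/cli/resistamp.R <validate|simulate|run> --help`.

## Acceptance script

`scripts/acceptance.R` recomputes the toolkit's acceptance quantities
from scratch against the installed package: a full
simulate → demultiplex → align → call → genotype run on a 71-sample
cohort with two linked *vgsc* variants feeding the LD r² computation;
marker-prevalence arithmetic on printed genotype-class splits; pool
coverage arithmetic; and the packaged panel's composition. Run it from
the repository root:

```sh
Rscript scripts/acceptance.R --seed 1 --out results/acceptance.json
```

It writes one JSON object with a `value` and problem size `n` per target.
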