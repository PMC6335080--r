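# polycane

Dosage-aware population genomics for highly polyploid germplasm panels.

Highly polyploid crops — sugarcane is the canonical case, with even ploidies
from 4x to 12x in one collection — break most diploid population-genetics
tooling at the genotype: a biallelic SNP in an octoploid has nine possible
genotypes, and deep sequencing (~100x) is needed before the binomial
read-fraction classes

    f_d = (d/p)(1 - eps) + (1 - d/p) eps ,   d = 0, ..., p

become separable at all. `polycane` implements the analysis chain such
panels use, for researchers studying the ancestry, domestication and
environmental adaptation of polyploid crop germplasm:

* **Dosage genotyping** — per-genotype binomial maximum likelihood over
  dosage classes with a log-likelihood-ratio confidence, and the two-level
  (site, then genotype-confidence) filtering tiered SNP sets use;
  `min_depth_for_separation()` computes, by exact enumeration, the depth
  needed to distinguish single-dose from homozygous calls at a given ploidy
  and error rate (~110x for dodecaploids at conventional settings).
* **Species-diagnostic markers and genome composition** — loci fixed for
  alternate alleles between two progenitor panels, and the per-hybrid
  fraction of diagnostic loci classed to each progenitor species.
* **Population statistics** — dosage-weighted allele frequencies,
  small-sample-corrected nucleotide diversity, Nei Fst (ratio-of-sums,
  optionally bias-corrected), dosage-fraction distance matrices,
  neighbour-joining trees, ancestry-contributor ranking, codon-level effect
  annotation with Ti/Tv and N/S summaries.
* **LD decay** — dosage-correlation r-squared, distance-binned decay curves,
  and the interpolated distance at which LD drops to 0.2.
* **Scans** — a population-branch-statistic score over 20-SNP windows with
  top-1% selection and interval merging (externally computed scan scores can
  be ingested from TSV), per-gene pi-ratio scans with a top-5% cutoff,
  overlap/Venn reporting and hypergeometric enrichment with FDR control.
* **Environmental association** — PCA compression of a large environmental
  table, closed-form latent-factor association (an LFMM-style correction),
  multi-run z-score combination with genomic-control calibration, and
  Bonferroni hit selection with gene assignment.
* **A synthetic cohort generator** — Balding-Nichols progenitor divergence,
  mosaic (or designated-parent) hybrids, negative-binomial read depths,
  planted diagnostic markers, sweep genes and environmental clines — with
  the full ground truth returned, so every stage above is testable.

Standard formats throughout: VCF 4.2 with AD/DP in, GFF3/BED gene models,
TSV/BED/newick out.

## Worked example

Simulate a panel of 40 wild, 28 domesticated and 40 hybrid accessions at
~98x depth with 400 planted fixed differences, genotype it, and estimate
each hybrid's genome composition:

```r
library(polycane)

cfg <- sim_config(n_sites = 1500L, n_fixed_diff = 400L, seed = 42L)
co  <- simulate_cohort(cfg)
co
#> syn_cohort: 1500 sites x 108 accessions ( 40/40/28 ); seed 42

dm <- genotype_variants(co$variants, co$meta, error_rate = 0.005)
fl <- apply_filters(dm, co$variants)
fl$audit
#>                  rule removed
#> 1        multiallelic       0
#> 2     site-mean-depth       0
#> 3           call-rate       0
#> 4        genotype-llr   44072
#> 5 call-rate-post-mask     787
fl$level2
#> dosage_matrix: 713 sites x 108 accessions; mean call rate 0.955

pops <- split(co$meta$id, co$meta$group)
mk   <- find_diagnostic_snps(fl$level2, pops$speciesA, pops$speciesB)
nrow(mk)
#> [1] 400
comp <- genome_composition(fl$level2, mk, pops$hybrid)
head(comp[, 1:6], 3)
#>       id     fracA     fracB frac_both frac_neither n_loci
#> 1 acc069 0.4035990 0.5732648         0   0.02313625    389
#> 2 acc070 0.3789474 0.6026316         0   0.01842105    380
#> 3 acc071 0.3564103 0.6256410         0   0.01794872    390
mean(abs(comp$fracB - co$truth$composition$fracB))
#> [1] 0.01579568
```

Reading the output: the audit table shows the two-level filter at work —
no site fails the depth or call-rate floors at 98x, but 44,072 of the
162,000 genotype calls are below the confidence threshold (LLR 2) and are
masked, after which 787 sites drop below the 80% call-rate floor, leaving
713 confidently genotyped sites. All 400 planted fixed differences are
rediscovered as diagnostic markers. Each hybrid's composition (`fracB` =
fraction of diagnostic loci classed to the domesticated parent, drawn from
U(0.55, 0.80) in this simulation) is recovered with a mean absolute error
of 1.6 percentage points.

The whole chain — simulation, genotyping, statistics, composition, LD,
scans, association — also runs as one seeded, byte-reproducible pipeline:

```r
run_pipeline(list(out_dir = "run1", seed = 42,
                  sim = list(n_sites = 1500L, n_fixed_diff = 400L)))
```

A thin command-line wrapper over the same functions is included at
`inst/cli/polycane.R`:

```sh
Rscript inst/cli/polycane.R run-all --config config.yaml
```

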