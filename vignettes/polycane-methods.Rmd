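---
title: "Methods: dosage-aware population genomics for highly polyploid panels"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: dosage-aware population genomics for highly polyploid panels}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

# Scope

`polycane` implements the analysis chain used for deeply target-sequenced
germplasm panels of highly polyploid crops such as sugarcane: integer
allele-dosage genotyping from per-sample read depths, species-diagnostic
markers and hybrid genome composition, diversity and differentiation
statistics, linkage-disequilibrium (LD) decay, selective-sweep and
domestication scans, and latent-factor environmental association. A
synthetic cohort generator with injected ground truth makes every stage
testable end to end without any external data. This vignette records the
models, the tunable parameters, and the design decisions taken where the
analysis recipe left genuine freedom.

# Dosage genotyping

At a biallelic site an accession of ploidy $p$ carrying $d$ copies of the
alternate allele is expected to show an alternate-read fraction

$$f_d = \frac{d}{p}(1-\varepsilon) + \Big(1-\frac{d}{p}\Big)\varepsilon,$$

where $\varepsilon$ is the per-read miscall rate (default 0.005, the typical
hybrid-capture scale). `call_dosage()` maximises the binomial likelihood
$\mathrm{Bin}(a;\,r+a,\,f_d)$ over $d \in \{0,\dots,p\}$ with a flat prior —
pure per-genotype maximum likelihood, usable on a single sample, with no
population-informed updating. The confidence of a call is the natural-log
likelihood ratio (LLR) between the best and second-best dosage class. Ties
break toward the smaller dosage and carry LLR 0, so they are masked by the
confidence filter; zero depth is a missing call, never dosage 0.

Two-level filtering mirrors the tiered workflow of deep-capture SNP sets.
The exact thresholds behind published tier counts are generally not
recoverable, so they are explicit, configurable parameters with auditable
defaults:

* **level 1** (site level): biallelic, site mean depth $\ge 10$, call rate
  $\ge 0.5$;
* **level 2** (genotype level): calls with LLR $< 2$ masked, then sites with
  post-mask call rate $< 0.8$ dropped.

Every rule reports the count it removed. Binomial class overlap makes raw
argmax accuracy at $\sim$100x depth and ploidy 8 intrinsically limited for
mid-range dosages (the classes $f_3, f_4, f_5$ sit 0.125 apart while the
read-fraction standard error is $\sim$0.05); the pipeline therefore treats
the *confident* (level-2) calls as its genotype product, and accuracy is
assessed on those. `min_depth_for_separation()` exposes the other side of
the same fact: by exact enumeration it finds the smallest depth at which the
binomial likelihood-ratio classifier separates single-dose calls from
homozygous reference at given error probabilities; for dodecaploids at
$\varepsilon = 0.005$ and $\alpha = 0.01$ this lands near the
$\sim$110x depth often quoted as required for 12x genotyping.

Which dosage set feeds which statistic matters. Counting statistics (single-
dose fractions, diagnostic markers, composition, $\pi$, Fst, distances) use
level-2 calls: they need each genotype to be right. The association scan
instead uses level-1 calls: confidence masking removes mid-dosage genotypes
preferentially, which would gut the call rate of exactly the
intermediate-frequency SNPs an association scan needs, while regression is
robust to unbiased dosage noise. Note one consequence seen in the synthetic
runs: conditioning on high post-mask call rate enriches for near-fixed
sites, which deflates genome-wide Fst computed on the level-2 set relative
to the generating divergence — an ascertainment effect of confidence
filtering, not an estimator error (the estimator is unbiased on unfiltered
sites, as the calibration runs show).

# Population statistics

Allele frequencies are dosage-weighted allele-copy counts,
$\hat p = \sum_i d_i / \sum_i p_i$ over non-missing accessions, which makes
mixed-ploidy populations (4x-12x in one panel) directly comparable.

Per-site diversity is the small-sample-corrected expected heterozygosity
$\pi = \frac{n}{n-1}\, 2\hat p(1-\hat p)$ with $n$ allele copies. Regional
$\pi$ supports two denominators: per covered base pair (default — capture
data makes "per bp" meaningful only over targeted space, and the region
length stands in for it) and per variant site. Both are reported with the
genotyped-site count so either convention can be recomputed.

Nei's fixation index uses per-site $H_S$ (mean subpopulation heterozygosity)
and $H_T$ (pooled), with the genome-wide value as a ratio of sums
$\sum(H_T - H_S)/\sum H_T$ rather than a mean of ratios — the
variance-stabilised choice. By default the genome-wide estimate applies
unbiased moment corrections ($n/(n-1)$ on each subpopulation heterozygosity
and a sampling-variance term on $H_T$); without them the plain plug-in
estimator carries a small upward finite-sample bias that is visible in
calibration runs. The per-site table always uses the plain definition so
users can recompute alternatives.

Genetic distance is the mean absolute difference of dosage *fractions*
$|d_i/p_i - d_j/p_j|$ over shared sites — again so that a 4x and a 12x
accession can be compared — with pairs below a shared-site minimum reported
missing. Trees come from standard neighbour joining (via \pkg{ape});
negative branch estimates are clamped to zero and counted. NJ is a
deterministic, adequate stand-in here because group recovery, not topology
fidelity to any published figure, is what the tests assert. Ancestry
contributors are the rank-1 nearest progenitors per hybrid, aggregated with
support counts; the aggregation rule (rank-1 with support) is this package's
definition, since distance-based contributor reports rarely state one.

Coding effects are classed by codon substitution under the standard nuclear
code (minus-strand alleles complemented), against user-supplied gene models
and spliced CDS sequences; genes with broken phase chains are flagged and
their coding variants reported `coding_unresolved` rather than guessed.
Ti/Tv counts $A\!\leftrightarrow\!G$ and $C\!\leftrightarrow\!T$ as
transitions; N/S counts missense plus stop gain/loss over synonymous.

# Diagnostic markers and genome composition

A locus is diagnostic for a species when one allele is present (dosage
$\ge 1$) in at least a `purity` fraction of that species' genotyped panel
and absent from the other panel, with per-panel call-rate floors; the
default purity of 1.0 demands strict fixation, matching the absolute sense
in which species-specific markers are usually reported. Both alleles are
examined, so a fixed difference is recorded once as a dual-direction locus:
its alternate allele marks one species *and* its reference allele marks the
other. Panels below five accessions are refused — fixation in a tiny panel
is too easy.

Composition classes each genotyped diagnostic locus of a hybrid into one of
four mutually exclusive classes summing to one: at a dual locus, dosage $p$
shows only the first species' allele, dosage 0 only the second, and
intermediate dosages show both (`both`); at a single-direction locus,
presence classes the locus to its species and absence is uninformative
(`neither`). `fracA` and `fracB` therefore need not be complementary, which
reproduces the familiar situation where reported composition percentages do
not add to 100%. An alternative locus-classing rule that counts only
direction-positive evidence at every locus was considered and rejected: with
balanced dual-marker panels it estimates roughly half the true ancestry
fraction, so it cannot recover a known mixing proportion, whereas the rule
above recovers simulated compositions to within about one percentage point.

# LD

Pairwise LD is the squared Pearson correlation of dosage vectors over
pairwise-complete accessions — the standard genotype-level proxy when
haplotype phase is unavailable, and the deterministic replacement for
EM-based polyploid haplotype-frequency models. Sites are pre-filtered by MAF
and call rate and greedily thinned to a minimum spacing (leftmost site
wins; deterministic). Decay curves are bin means (default 50 kbp bins, 10
Mbp extent, $\ge 50$ pairs per bin, all recorded in the output); the "LD
drops to $r^2 = 0.2$" distance is the first downward crossing by linear
interpolation between populated bin midpoints. A curve that never crosses
returns `Inf` (censored at the curve extent); a curve already below the
threshold returns its first populated midpoint with a warning. The
binning-plus-interpolation rule is this package's definition and is logged,
since published "drops to 0.2" distances rarely state theirs.

# Sweep and domestication scans

The three-population sweep scan scores each window with a population branch
statistic: per site, the three pairwise Nei Fst values are transformed to
branch lengths $T = -\log(1 - F_{st})$ (capped before the singularity, with
capped sites counted) and the target branch is
$\mathrm{PBS} = (T_{ts} + T_{to} - T_{so})/2$. Windows are consecutive
non-overlapping runs of 20 SNPs, each reported at its central SNP with both
its SNP-index and physical span, since SNP-count windows have variable bp
extent. Composite-likelihood three-population scans are published external
methods; the windowing, the top-1% empirical-quantile selection with
inclusive ties, and the merging of adjacent or overlapping selected windows
into candidate intervals — the parts that *are* the stated procedure — are
implemented exactly, and the selector accepts externally computed window
scores from TSV so such methods can feed the same machinery.

The per-gene $\pi$-ratio scan flags genes whose ratio
$(\pi_1 + c)/(\pi_2 + c)$ reaches the top-5% quantile, ties inclusive. The
pseudocount $c$ — the smallest positive per-gene $\pi$ observed — keeps
zero-diversity genes rankable without letting them dominate; it is recorded
in the output because any zero-handling rule here is a choice. Gene-interval
overlap reports, pairwise/three-way intersections of candidate sets, curated-
ortholog bins (gene span $\pm$50 kbp), and hypergeometric term enrichment
with Benjamini-Hochberg control complete the reporting.

# Environmental association

The environment table is compressed by PCA after per-variable
standardisation (mean imputation for missing entries, constant variables
dropped); the top five components are the association targets, as is common
for large correlated bioclimatic panels.

The association model is a closed-form latent-factor regression standing in
for MCMC-based latent factor mixed models: the hidden structure factors are
the top-$K$ left singular vectors of the centred, scaled genotype matrix
($K = 6$ by default, mirroring the panel-structure choice such analyses
make), and each SNP is regressed on the environmental component plus the
factors; $z = \hat\beta/\mathrm{se}$. The multi-run workflow those programs
prescribe is kept: each of the (default 10) runs re-estimates the factors on
a seeded 90% jackknife of accessions and projects all accessions onto them,
the per-SNP combined statistic is the median $z$ across runs, the genomic
inflation factor $\lambda = \mathrm{median}(z^2)/0.456$ recalibrates
$z^2/\lambda$ against $\chi^2_1$, and hits are declared at Bonferroni
$\alpha = 0.01$ with containment-based gene assignment. Median combination
was chosen for robustness; the exact combination formula used by specific
external programs varies, so the rule is stated in the output. With $K = 0$
the test reduces exactly to simple linear regression, which is the
calibration anchor the tests exploit.

# The synthetic cohort generator

The generator emulates the statistical structure of a real polyploid
germplasm panel; truth is injected, never evolved — there is no coalescent,
recombination map, or selection dynamics.

* **Species divergence.** Ancestral frequencies are Beta(0.8, 0.8); each
  species' per-site frequency follows the Balding-Nichols construction.
  Because the analysis summarises divergence as pairwise Nei Fst, the
  generator parameter is calibrated so that the *expected pairwise Nei Fst
  between the two species equals* `divergence_fst`: plain Balding-Nichols
  with per-population parameter $F$ gives pairwise $G_{st}$ of
  $(F/2)/(1-F/2)$, so species are drawn with parameter $2F/(1+F)$. The
  default 0.084 is the genome-wide differentiation scale reported for
  wild-vs-domesticated sugarcane progenitors.
* **Panel layout.** Defaults: 40 wild, 28 domesticated, 40 hybrid
  accessions (the representative sub-population sizes used in such panels),
  ploidy 8 for both progenitor species, hybrids alternating 10x/12x, an
  optional outgroup for branch scans, mean capture depth 98x with
  negative-binomial overdispersion (size 8; `Inf` gives fixed depth), and
  $\sim$89% of sites inside gene spans, as target capture produces.
* **Hybrids.** Each hybrid is a two-state mosaic along every chromosome with
  exponentially distributed block lengths. Ancestry states strictly
  alternate with state-specific means $2Lc$ (domesticated parent) and
  $2L(1-c)$, so the expected domesticated-genome fraction equals the target
  composition $c \sim U(0.55, 0.80)$ and the mean block equals `L` (default
  2 Mbp). The block state applies to all homologous copies at a site —
  chromosome-segment-level inheritance, the regime in which hybrid
  sugarcane chromosomes descend from one progenitor or the other — which is
  what gives hybrids their long-range LD and makes diagnostic loci read out
  ancestry directly. Realised per-hybrid fractions are recorded as truth.
  Alternatively, hybrids can be bred from *designated parent accessions* by
  gamete subsampling (half the copies drawn hypergeometrically from each
  parent), which is the mode used to test ancestry-contributor recovery.
* **Planted signals.** Fixed allelic differences (diagnostic-marker truth),
  sweep genes whose domesticated-species minor-allele frequencies are
  multiplied by a diversity-reduction factor (pinning them toward
  fixation), and environmental-association SNPs whose per-accession
  frequency shifts by `effect` across the panel's latitudinal gradient.
  The gradient position is the ECDF rank of latitude in $[0,1]$, so "a 0.4
  frequency shift across the gradient" spans the panel robustly instead of
  hanging on the two most extreme origins. Baseline frequency for planted
  env-SNPs is 0.5; shifts are clamped to $[0.005, 0.995]$ and clamps
  counted.
* **Environment.** 104 variables generated from five latent factors with
  decreasing weights — the first two being standardised latitude and
  longitude — plus noise; climate tables are dominated by a few broad
  gradients, and this is what makes "top five PCs explain most variance"
  hold. Group-shifted origins with wide within-group dispersion (latitude
  s.d. 12 about group means $-5/12/5$) give a gradient that is genuinely
  confounded with population structure while leaving within-group signal
  for the corrected test to find — both properties the association tests
  need.
* **Reads.** Depth $\sim$ NB(mean, size), alternate reads
  $\sim \mathrm{Bin}(\mathrm{depth}, f_d)$; zero depth emits a
  missing-genotype record. All randomness derives from the config seed;
  identical configs are bit-identical.

What passing tests on this generator do **not** show: robustness to mapping
artefacts, paralogy and collapsed repeats, allele-specific capture bias,
aneuploidy within an accession, or frequency spectra shaped by real
demography. The generator's job is to make the *statistical contracts* of
each stage falsifiable, not to imitate sugarcane biology in full.

# Numerical choices and degenerate inputs

* Dosage ties break toward the smaller dosage with LLR 0 (deterministic,
  conservative: masked at level 2).
* $0\cdot\log 0 = 0$ in the likelihood so $\varepsilon = 0$ is exact.
* Quantile selections (top-1% windows, top-5% genes) include ties at the
  threshold; smaller fractions select subsets (monotone).
* Fst at sites with $H_T = 0$ is undefined and excluded from the ratio of
  sums; per-site branch transforms cap Fst at $1 - 10^{-4}$.
* Empty filter results, empty hit tables and empty BED files are valid
  outputs, produced with warnings rather than errors.
* Pipeline outputs carry provenance headers (stage, parameters, seed) and
  no timestamps, so reruns under one seed are byte-identical; the resolved
  config is written beside the outputs without the output path itself.

# Problem sizes used in the test suite

The shipped tests run cohorts of 200–6,000 sites and 12–180 accessions,
with 5–20 seeded replicates per property — sizes chosen so the full suite
and the acceptance script each complete on a laptop-class single core in a
few minutes while leaving the Monte-Carlo margins comfortably wider than
the assertion thresholds. All thresholds asserted by the tests (accuracy
$\ge 95\%$ / $\ge 99.9\%$, composition within $\pm 0.03$, recall
$\ge 0.8$, $\lambda \in [0.9, 1.1]$, and so on) were fixed before the
corresponding simulations were sized.

# Known limitations

* No haplotype phasing and no population-informed genotype updating; the
  caller is deliberately per-genotype.
* Composition is global (no local-ancestry painting along chromosomes).
* No haplotype-based LD ($D$, $D'$) or sweep statistics (iHS, nSL);
  composite-likelihood scan internals are out of scope by design, with TSV
  score ingestion as the bridge.
* Enrichment is a plain hypergeometric over user-supplied term maps, not a
  full GO stack.
* The environmental module neither retrieves climate rasters nor models
  kinship beyond the latent factors.
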