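---
title: "Estimating interspecies divergence from cross-species pileups"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Estimating interspecies divergence from cross-species pileups}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

## The problem

When a species has no finished reference genome of its own, its sequencing
reads can be aligned to the assembly of a close relative — for example,
donkey reads piled against a horse reference. Every aligned position then
carries two superimposed signals: *fixed interspecies differences* (sites
where the sequenced species is homozygous for an allele that differs from
the reference base in every individual) and *within-species polymorphism*
(sites that segregate among the sequenced individuals). Separating the two,
while suppressing sequencing error, yields a genome-wide nucleotide
divergence estimate, a SNP catalogue, and quality diagnostics such as the
transition/transversion ratio.

`equidiv` implements that comparative pipeline end to end, together with a
two-species genome simulator that carries a complete truth ledger, so every
estimator in the package can be validated by parameter recovery rather than
by eyeballing.

## The calling and filtering model

Evidence arrives per reference position as a pileup column: read bases with
base qualities and per-read mapping qualities for each sample. Parsing
discards indel evidence entirely (only nucleotide substitutions are
considered) and drops reads below a base-quality floor of 13, the
conventional default of pileup generators.

The genotype caller is a uniform-prior binomial maximum-likelihood model.
With assumed per-base error $e$ (default 0.01), a read $b$ has

$$P(b \mid GG) = \begin{cases}1-e & b = G\\ e/3 & b \ne G\end{cases}
\qquad
P(b \mid G_1G_2) = \tfrac12 P(b \mid G_1 G_1) + \tfrac12 P(b\mid G_2 G_2)$$

and the call maximizes the likelihood over $\{RR, RA, AA\}$ (haploid:
$\{R, A\}$), where $A$ is the modal non-reference base with alphabetical
tie-breaking. Exact likelihood ties resolve toward the reference — the
conservative direction for divergence estimation. Base qualities are
deliberately not folded into the likelihood: the model stays exactly
enumerable, which is what lets a brute-force oracle verify the caller over
thousands of random sites.

**Minimum alternative-allele support.** Pure maximum likelihood has a known
pathology at moderate depth: at depth seven and below, a *single*
dissenting read already makes the heterozygote the most likely genotype, so
at realistic error rates (about $10^{-3}$ per base) false heterozygote
calls would outnumber true SNPs severalfold and drag the SNP Ti/Tv ratio
toward the uniform-error value of 0.5. Real callers suppress this with a
genotype prior; `equidiv` achieves the same effect with an explicit,
auditable rule: any genotype containing the alternative allele needs at
least `min_alt_reads` (default 2) supporting reads, mirroring the support
threshold the pooled-sample caller uses. Setting `min_alt_reads = 1`
recovers the textbook ML caller.

Per-sample filters then mark sites `low_depth` (depth < 4) or `low_mq`
(site RMS mapping quality < 20; the RMS convention matches what
variant-calling toolchains report at site level). On flow-chemistry
platforms (`platform = "ion"`), sites inside or within 1 bp of a
homopolymer run of four or more identical bases are excluded wholesale —
this chemistry concentrates its errors at run boundaries. The slack is
configurable (`homopolymer_adjacency = 0` gives the strict inside-run
reading); the filter is skipped for `platform = "illumina"`.

Cross-sample classification distinguishes, per site:

* **fixed difference** — every callable sample homozygous for the same
  non-reference allele (a single callable sample suffices; cohorts with
  heterogeneous coverage would otherwise lose most of the genome);
* **SNP** — any callable heterozygote, or discordant genotypes;
* **invariant**, or **uncallable** (no passing sample, N reference,
  homopolymer-masked, or three or more alleles — the last demoted with a
  warning rather than modeled, since multiallelic sites are out of scope).

## Divergence, windows and summaries

Raw divergence is fixed differences over callable sites, reported overall
and per chromosome class. Because a fraction of apparent fixed differences
actually segregates in either species, the corrected estimate subtracts a
configured polymorphism term supplied as a (low, high) pair per species —
the query-side term can be estimated from the data, the reference-side term
cannot and must come from external knowledge. The subtraction is floored at
zero.

Window statistics tile each chromosome with 1-Mb windows (0-based half-open
internally; all file formats stay 1-based inclusive). Window sums equal
genome totals by construction — a conservation property the test suite
asserts on every run. Windows with fewer than `min_callable_fraction`
(default 0.2) callable sites are flagged `masked` for reporting, which
never changes totals. Per-chromosome box-plot summaries use type-7
(linear-interpolation) quantiles, whiskers at the range, and a notch
half-width of $1.58\,\mathrm{IQR}/\sqrt{n}$ — the standard surrogate for
the standard error of the median.

Ti/Tv (transitions A↔G, C↔T over everything else) is computed separately
for the SNP set and the fixed-difference set; the ratio is reported as
undefined, with counts, when no transversions exist.

## Y chromosome: error rate and paternal lineages

On a male's Y chromosome every true genotype is hemizygous, so read
disagreement at Y-specific scaffolds (assigned to Y and *not* also matching
X, to avoid mis-mapped X homologs) measures sequencing error directly. Two
statistics are deliberately distinguished:

* `per_base_mismatch_rate` — bases disagreeing with the called haploid
  allele over all bases at callable sites. This is a per-base quantity and
  recovers the simulator's configured error rate; it is the primary
  statistic.
* `het_call_rate` — the fraction of the same sites a diploid re-call labels
  heterozygous. This is a per-site quantity roughly depth times larger
  (and threshold-shaped), which is why "error rate" claims need their
  definition attached.

Lineage comparison calls haploid alleles at depth ≥ 3 (a deliberately
relaxed threshold for the sparse Y) and lists positions whose allele
differs from a supplied reference Y haplotype; shared variants intersect on
position and allele, invariant to sample order.

## The simulator and what it does (not) emulate

`simulate_dataset()` draws an i.i.d. uniform ancestor, mutates each site
independently with probability $\alpha \times$ a chromosome-class
multiplier (X default 0.5, Y default 1.5), assigns the divergence to the
query lineage (only the pairwise difference is observable, so placing all
of it on one branch is equivalent and keeps the truth ledger trivial),
plants polymorphism at rate $\pi$ with frequencies from a uniform (or
1/i neutral) spectrum and binomial genotypes, and emits pileups directly:
Poisson depth, fair-coin allele sampling at heterozygous sites, uniform
base-flip errors at rate $\varepsilon$ boosted 20-fold inside/adjacent to
reference homopolymer runs, and per-read mapping qualities drawn normal
(mean 45, sd 5, clipped to [0, 60]) and retained as site RMS. Substitutions
follow a $\kappa$-biased kernel — transition probability
$\kappa/(\kappa+2)$ — so the expected Ti/Tv is $\kappa/2$ (default
$\kappa = 4$, Ti/Tv 2, the mammalian genome-wide norm).

Defaults mirror the study conditions the package targets: autosomal
divergence 0.0067, polymorphism 0.001, error 0.001, three sequenced males
at 12X/12X/8X. The error-rate experiments use 0.00063 — the per-base scale
at which flow-chemistry instruments operate — on 3 Mb of Y at 7X; the
Ti/Tv experiment raises $\pi$ to 0.012 over 15 Mb in two 12X samples so
that comfortably more than $10^5$ SNP sites are called, which pins the
sampling error of the ratio near 0.01.

Deliberately *not* emulated: indels and structural variants (discarded by
the pipeline anyway), read-level artifacts and alignment ambiguity (pileups
are emitted directly, isolating the pipeline's own computation), reference-
side polymorphism (the reference is treated as a fixed haplotype), GC/CpG
rate covariates, and pooled-DNA contribution imbalance. Passing recovery
tests therefore demonstrates the estimators' correctness under the stated
generative model, not robustness to alignment artifacts.

Because the simulator's homopolymer-boost region coincides exactly with the
filter's exclusion region (run ≥ 4 plus 1 bp), the filtered site set is
error-homogeneous at the base rate $\varepsilon$ — which is what makes the
hemizygous estimator's unbiasedness testable against the configured value.

## Numerical and design choices

* **Determinism.** All randomness flows from one seed through named
  per-stage substreams; identical configurations produce byte-identical
  output bundles.
* **Tie-breaks.** Genotype ties resolve toward the reference; modal-allele
  ties resolve alphabetically. Both are asserted by oracle tests.
* **Recall convention.** Fixed-difference recall is measured over truth
  sites at callable positions. The homopolymer mask removes about 7% of a
  uniform random genome by design and divergence-neutrally; counting those
  sites as misses would measure the mask, not the caller.
* **Polymorphism estimator.** The SNP-site rate underestimates $\pi$
  because a planted site can be monomorphic in a finite sample; the
  recovery experiment divides by the closed-form segregation probability
  under the configured frequency spectrum
  ($1 - E_p[p^{2n} + (1-p)^{2n}]$).
* **Callable denominator.** Divergence uses callable sites (passing
  depth/MQ, outside masks) as the denominator, and the same denominator for
  SNP density, so numerator and denominator always refer to the same site
  universe.
* **Window masking** is report-only; genome totals never change.
* **Problem sizes.** The recovery experiments run at desk scale — 10 Mb
  genomes for divergence (three samples, ~320 M read observations), 3 Mb ×
  10 seeds per error level, 15 Mb for Ti/Tv — sizes at which binomial
  standard errors are a few percent of the measured quantities, chosen so
  the stated tolerances are meaningful rather than generous.
* **Consequence classes.** The annotator reports the seven classes named in
  comparative resequencing reports (intergenic, intronic, splice site — 2
  bp per intron end —, synonymous, missense, stop gained/lost) plus two
  explicit extension classes: `noncoding_exon` (exonic bases outside the
  CDS; UTR subtypes are not modeled) and `coding_incomplete` (codons
  truncated by non-zero phase or partial terminal codons). Start-codon loss
  is treated as missense. The standard genetic code only.

## Known limitations

The caller ignores base qualities by design; on data whose error profile
varies strongly per cycle this wastes information. Multiallelic sites are
demoted, not modeled. The reference-side polymorphism correction is an
input, not an estimate. Mapping quality is simulated per read but
summarized per site before filtering, so per-read MQ filtering (available
but off by default) has no simulated pathology to exercise. X-to-Y
read contamination is not simulated; on real data residual X homology
inflates the hemizygous error estimate, which is why Y-specific scaffold
selection excludes X-matching scaffolds.
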