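---
title: "Trio de novo mutation analysis: models and methods"
output: rmarkdown::html_vignette
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

`denovotrio` implements a pedigree-based (direct) estimate of the germline
mutation rate from deep whole-genome sequencing of a father-mother-offspring
trio, together with the supporting machinery that such an estimate needs:
high-confidence target-region construction, Mendelian inheritance error
(MIE) detection and classification, allelic-conversion clustering, read-pair
parental-origin phasing, validation bookkeeping, and a synthetic trio
simulator that makes every stage testable without sequencing data.

## The analysis model

### Mendelian inheritance errors

At a biallelic autosomal site with genotypes coded as alternate-allele
counts (0/1/2), the offspring's genotype must be producible by drawing one
allele from each parent's genotype. Exhaustive enumeration over the 27
genotype trios collapses to the closed rule used by
`mendelian_consistent()`:

$$(F{=}2) + (M{=}2) \;\le\; O \;\le\; (F{\ge}1) + (M{\ge}1).$$

Sites violating it are MIEs. Genotypes that are missing (no coverage) or
quality-filtered are skipped and counted, never imputed: an imputed
genotype would manufacture or hide MIEs.

### Four-way classification

An MIE can arise from a new point mutation, but also from copy-number
events and from interallelic gene conversion. The classifier uses the
offspring's allele provenance plus per-individual "half depth" flags
(one-copy state) from a depth window centred on the site, in fixed order:

1. **de novo SNV** — the offspring carries an allele absent from both
   parents, all three members copy-neutral;
2. **CNIV** (copy-number-neutral inherited variant) — all offspring alleles
   are parental, all members copy-neutral; the signature of allelic gene
   conversion (loss of heterozygosity without depth change);
3. **HDIV** (hemizygous-deletion inherited variant) — offspring and exactly
   one parent at half depth: the offspring inherited a one-copy deletion, so
   only the other parent's allele is observed;
4. **de novo CNV** — only the offspring at half depth (a new deletion).

Any other flag combination (e.g. both parents half but not the offspring)
is reported as `UNCLASSIFIED` rather than silently dropped. The de novo
allele test runs before the depth tests so that a genuine de novo SNV in a
copy-neutral region cannot be shadowed by a noisy depth ratio.

**Half-depth threshold.** The depth-comparison tooling used in the original
analyses of this kind does not publish an equality threshold, so the
package states one: a window's depth, normalised by the individual's
genome-wide mean, is "half" when it is at most 0.75 — the midpoint between
the one-copy (0.5) and two-copy (1.0) expectations. With the default 1 kb
window centred on the site, a site just inside a deletion boundary has at
worst half of its window outside the deletion, giving a normalised depth of
exactly 0.75; the inclusive threshold therefore keeps boundary sites on the
deletion side. Both window size (`window_bp`) and threshold
(`half_threshold`) are arguments throughout.

### Target regions

Rate denominators are only meaningful over regions where variant calls are
trustworthy in *all three* genomes. Five filters remove, from the whole
genome (the percentages are quoted against total genome length, with
overlaps counted per filter):

* **(i) depth** — each individual's acceptance window is mean ± 3σ of
  per-base depth, with the moments computed after clamping to a plausible
  pre-range (defaults: lower 15× for the parents, 18× for the offspring;
  upper 512×) so that pathological pileups do not distort them; a base
  fails if *any* member is outside its own window;
* **(ii) strand balance** — at least 10 forward and 10 reverse reads in
  every member (boundary inclusive);
* **(iii) indel proximity** — annotated indel positions ± 50 bp (indel
  calling itself is upstream of this package; positions are supplied as
  annotation);
* **(iv) allele/strand bias** — every heterozygous carrier needs ≥ 1 read
  in each of RF, RR, AF, AR (reference/alternate × forward/reverse); a
  homozygous-alternate carrier, which cannot show reference reads, needs
  AF ≥ 1 and AR ≥ 1 — the literal all-four rule would discard every
  hom-alt site; failing sites are removed ± 10 bp;
* **(v) read ends** — variant sites whose supporting reads lie near the
  read ends (mean distance to the nearer end ≤ 10 bp in any carrier),
  removed ± 10 bp. The "mean distance" reading of this criterion is a
  documented choice; the filter is parameterised so other readings can be
  configured.

"Adjacent N bp" is interpreted as symmetric padding of the site position.
The final target is the genome minus the union of removals minus the
repeat mask; all interval arithmetic is 0-based half-open (1-based only at
the VCF boundary) and is verified in the tests against a per-base bitmap
oracle. Target construction is idempotent, order-independent and monotone.

### Conversion clustering

Under uniform placement of $n$ CNIVs on a target of length $L$, adjacent
gaps have mean $L/n$ (for $n = 476$ on $L = 1.17$ Gb: $2.46 \times 10^6$
bp; $L/n$ rather than $L/(n+1)$ is used because it reproduces that printed
value). `bootstrap_distance_ci()` simulates many uniform placements, pools
the adjacent gaps, and returns symmetric percentiles — the most literal
reading of a "bootstrap resampling" interval; gaps are approximately
exponential, so the 99% interval brackets
$-\ln(0.995)\,L/n$ and $-\ln(0.005)\,L/n$. Published analyses of this
design quote a slightly higher lower bound ($1.75\times10^4$ bp for the
n = 476 case) than the exponential approximation gives ($\approx 1.2
\times 10^4$); since the exact resampling scheme behind that number is not
specified, the clustering threshold is a parameter (`--threshold`), with
the bootstrap lower bound as default. Clustering is single-linkage
chaining within chromosomes; it is threshold-monotone, never merges across
chromosomes, and every CNIV lands in exactly one event.

### Parental origin

A de novo allele is phased by read pairs that also cover a nearby
*informative* heterozygous site — one where the offspring's two alleles
are attributable to exactly one parent each. Fragments carrying the de
novo allele vote for the parent whose diagnostic allele they carry;
assignment requires a unanimous vote (any conflict → unassigned). The
conservative unanimity policy is the package's choice; published work of
this kind does not state how many supporting pairs were required. The
search radius defaults to the configured insert size (300/500 bp
paired-end libraries).

### Rates

With $n$ candidates, false-positive rate $f$ (from confirmation
genotyping of a testable subset), $s$ somatic calls (blood/hair
discordance), and target size $T$:

$$n_{germ} = n - \mathrm{round}(n f) - s, \qquad
\mu_g = \frac{n_{germ}}{2T}, \qquad \mu_y = \frac{\mu_g}{\bar a},$$

where $\bar a$ is the mean parental age at conception. The count range
treats untestable candidates as all-false (minimum) or all-true (maximum),
subtracting the observed false positives in both. The false-negative rate
defaults to zero (the regime deep trio sequencing is designed for) but is
exposed (`fn_rate`), dividing the rate by $1 - \mathrm{FN}$.

The phylogenetic comparator uses the neutral expectation for pairwise
divergence, $d = 2\mu_y t + 4 N_e g \mu_y$ — substitutions accumulated on
both lineages since the split plus the expected ancestral coalescent depth
— giving $\mu_y = d/(2t + 4 N_e g)$ and $\mu_g = \mu_y g$. It is
monotonically decreasing in $N_e$, $t$ and $g$, with the $N_e = 0$ limit
$d/(2t)$.

## The synthetic trio generator

`simulate_trio()` draws the study conditions the analysis assumes:

* parental SNV density 0.118% of sites, heterozygosity 0.076%, Ti/Tv 1.98
  (transitions drawn with probability $\kappa/(\kappa+1)$, transversion
  type uniform — a summary-level spectrum, not a context model);
* parents sample their variants from a shared population site pool (1.5×
  the per-individual density) so that co-variant sites agree on alleles —
  independent parental draws would place conflicting alternate alleles at
  the same position;
* Mendelian transmission of one haplotype per parent per chromosome;
  germline de novo SNVs Poisson per haploid transmission (`mu_denovo`),
  blood-only somatic SNVs, exponential-length allelic-conversion tracts
  (mean 170 bp, inside the 55–290 bp range reported for conversion
  tracts) that overwrite one offspring haplotype with its homolog,
  parent-carried hemizygous deletions on the transmitted haplotype, and
  offspring-only de novo microdeletions (default < 6 kb);
* per-base depth negative binomial around the configured coverage
  (size 20), halved by binomial thinning over one-copy intervals. Pure
  Poisson depth is available (`depth_dispersion = Inf`) and is what the
  distributional unit tests use, but the default is overdispersed on
  purpose: observed deep-sequencing depth histograms are wide enough that
  a ± 3σ depth filter retains half-depth regions, and that property is a
  precondition for detecting HDIVs and de novo CNVs at all — with Poisson
  depth at 150×, σ ≈ 12 and every hemizygous base would be filtered out;
* strand-resolved counts RF/RR/AF/AR multinomial in the individual's true
  allele dosage with per-read error `base_error` (miscalls flip to the
  other allele of the biallelic site), forward/reverse split evenly;
  RF+RR+AF+AR = DP holds by construction;
* genotype calls from a three-component binomial likelihood with
  phred-gap thresholds (< 200 for heterozygous, < 100 for homozygous calls
  → filtered), zero depth → missing;
* read-pair fragments as (span, haplotype) draws whose reads report
  haplotype alleles — sufficient for the phasing contract without
  sequence-level simulation.

Everything injected is recorded in a `truth` list (positions, tracts,
intervals, parental origins), and `true_mies()` derives the reference MIE
labelling the recovery tests compare against.

What the generator does **not** emulate: alignment and mapping artifacts,
mappability structure, GC bias, indels (positions are injected as
annotations only), recombination within chromosomes, multi-allelic sites,
and linked-error modes of real base callers. Passing recovery tests
therefore demonstrate the correctness of the pipeline's logic under its
stated statistical model, not robustness to real-data artifact classes.

## Numerical and design choices

* Coordinates 0-based half-open internally; 1-based only inside VCF
  records.
* `round(n f)` (not floor/ceiling) for the projected false-positive count.
* Rates are computed in full precision; rounding (3 significant figures)
  happens only at display.
* Seeds: one master seed per simulation; each stage derives a fixed child
  seed, so reruns are byte-identical and stages are individually
  reproducible.
* Degenerate inputs fail loudly: empty target regions, zero-coverage
  depth-ratio windows, confirmation rows for unknown sites, negative
  corrected counts, unplaceable event intervals (after 100 retries) are
  all hard errors; zero assigned origins make the paternal fraction an
  error rather than a silent `NaN`.
* The command-line wrapper (`inst/cli/denovotrio.R`) exposes the
  workflow-level entry points (`simulate`, `run`, `cluster`, `rate`,
  `phylo-rate`); the mid-pipeline stages (filtering, classification,
  phasing) are R functions composed by `run`, since their natural inputs
  (per-base depth, fragment evidence) are in-memory objects.

## Problem sizes used in the test suite

Unit tests run on 0.1–1 Mb genomes. The recovery properties use twenty
10 Mb simulations at 150× with all event types injected (de novo rate
10⁻⁶/site/transmission so each seed carries ~20 events; 200 conversion
tracts; two hemizygous deletions; one microdeletion): classification
recall and precision are pooled per category over ten seeds, and the
corrected germline count pooled over all twenty is checked against the
central 95% Poisson interval of its expectation. The coverage-titration
property thins a 120× dataset to 30× and checks that false-positive de
novo candidates do not increase with coverage. The bootstrap null is
exercised at the published scale (n = 476, L = 1.17 Gb, 10,000
replicates).

## Known limitations

* Recall/precision guarantees are with respect to the generator's model;
  see the non-emulated artifact classes above.
* The depth-based classifier needs deletions comparable to or larger than
  the window (default 1 kb); single-site CNV signals are invisible.
* Conversion events are only observable where the tract covers a
  heterozygous marker, so event counts are lower bounds — the package
  reports member counts and spans so users can apply their own
  span-based UPID heuristics.
* The simulator's confirmation assay is exact, so simulated FP rates are
  near zero; the rate machinery accepts externally measured FP/FN rates
  for real data.
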