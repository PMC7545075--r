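---
title: "Methods and design of popgenarray"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods and design of popgenarray}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(popgenarray)
```

popgenarray analyzes dense biallelic SNP-array genotypes from multiple
populations — the kind of data produced by livestock and wildlife
genotyping arrays — and estimates the population-genetic quantities that
summarize diversity, inbreeding, and demographic history: heterozygosity
and nucleotide diversity, Weir–Cockerham $F_{ST}$, linkage-disequilibrium
decay, runs of homozygosity and the genomic inbreeding coefficient
$F_{ROH}$, LD-based effective population size, and the effective sex
ratio inferred from the contrast between sex-linked and autosomal drift.
Every estimator is validated end to end against a bundled two-sex
Wright–Fisher forward simulator with recorded ground truth.

This vignette documents the statistical models, the tunable parameters
and their defaults, the numerical choices, and the known limitations.
It states no empirical result that the package's test suite or
acceptance script does not itself compute.

## Data model and quality control

Genotypes are stored as alternate-allele dosages (0/1/2, `NA` missing)
with 1-based coordinates sorted by chromosome and position. Hemizygous
sex-chromosome genotypes in the heterogametic sex are encoded as
homozygous-like 0/2 calls, the convention of array genotype callers;
all sex-aware code weights such calls by one chromosome.

`apply_qc()` implements the standard array filter: variants are kept
when minor allele frequency $\ge$ 0.05, call rate $\ge$ 0.90, and the
Hardy–Weinberg exact p-value $\ge 10^{-6}$ (all thresholds
configurable). Design choices the filter contract leaves open:

* **HWE test.** The conditional exact test on heterozygote counts
  (plain p, not mid-p), evaluated by the numerically stable recurrence
  started at the modal heterozygote count. The test suite checks it
  against a direct log-factorial enumeration for every genotype-count
  triple with total $\le 50$.
* **Pooled vs per-population.** MAF and HWE are evaluated once on the
  pooled data by default; a per-population mode (variant fails if it
  fails in any population) is available but non-default.
* **Sex-linked HWE exemption.** The heterogametic sex breaks the HWE
  sampling model, so sex-linked variants are exempt from the HWE filter
  unless explicitly included.
* **Removal-reason precedence.** For reporting, each removed variant is
  assigned one reason in the order MAF → call rate → HWE; the retained
  set itself is order-independent.

## Diversity and differentiation

Observed heterozygosity is per individual: heterozygous calls over
non-missing calls. Expected heterozygosity uses the unbiased per-variant
estimator $2\hat p(1-\hat p)\,m/(m-1)$ with $m$ the non-missing allele
count; averaging it over each individual's non-missing variants gives a
per-individual He with an across-individual spread comparable to Ho
(both spreads are reported and labelled, together with the
across-variant spread, since the two answer different questions).
Per-site nucleotide diversity is $\pi = n_{ref}\,n_{alt}/\binom{N}{2}$,
algebraically identical to the unbiased He at a complete-data site; the
reported mean is over ascertained SNP sites, not per base pair.

$F_{ST}$ is the full two-population Weir–Cockerham (1984) estimator with
all three variance components $a$ (among populations), $b$ (among
individuals within populations), and $c$ (within individuals), combined
multi-locus as $\sum a / \sum (a+b+c)$ over loci with a defined positive
denominator. Negative estimates are reported as computed — the
parameter, not the estimator, lives in $[0,1]$ — and loci monomorphic
across both populations drop out. The four-level classification uses
low $<0.05 \le$ medium $<0.15 \le$ high $\le 0.25 <$ extreme, with
negative estimates mapped to low; the interval endpoints are assigned
exactly as written because the conventional prose bands are ambiguous
there.

## Linkage disequilibrium

$r^2$ is computed from two-locus haplotype frequencies,
$r^2 = (p_{AB}p_{ab} - p_{Ab}p_{aB})^2 / (P_A P_a P_B P_b)$, which for
unphased genotypes requires estimating the haplotype frequencies.
`em_haplotype_freqs()` runs the standard EM over the phase of double
heterozygotes from the linkage-equilibrium start point, stopping when
the largest frequency change is below $10^{-10}$ or after 1,000
iterations. The all-double-heterozygote table has a likelihood symmetric
about $D=0$; the LE start is already stationary there and is returned
with a degenerate-case flag. On phase-unambiguous tables EM equals
direct haplotype counting exactly (a property the tests check on
thousands of random tables).

`ld_decay_curve()` bins all intra-chromosomal autosomal pairs closer
than 500 kb into half-open 5-kb distance bins (both configurable; bin
width 1 bp recovers single-distance evaluation points) and reports the
per-bin mean $r^2$ and pair count. Curves are computed on a seeded
random subsample of 7 individuals so that populations of very different
census size remain comparable; the subsample ids and seed are stored on
the result. Sex-linked SNPs are excluded (mixed ploidy in the
heterogametic sex).

## Effective population size

Two LD-based estimators, both downstream of the EM $r^2$:

* **Historical trajectory.** Under drift–recombination equilibrium
  $E[r^2_{adj}] = 1/(\alpha + 4N_ec)$ with $\alpha = 1$ by default
  ($\alpha = 2.2$ available for the mutation-adjusted variant). Pairs
  are mapped from physical distance to recombination fraction by a
  linear map (1 cM/Mb default, capped at $c = 0.5$), binned on $c$, and
  each bin inverts to $N_e = (1/4\bar c)(1/\overline{r^2_{adj}} - \alpha)$
  dated $t = 1/(2\bar c)$ generations ago. Bins with fewer than the
  minimum pair count are masked. The inversion is exact: feeding
  $r^2 = 1/(1+4Nc)$ back recovers $N$ to machine precision, a property
  the acceptance suite checks on an $(N, c)$ grid.
* **Contemporary point estimate.** On a seeded subsample of $S$
  individuals (default 40) and pairs of loci on different chromosomes,
  $\hat N_e = 1/\!\left(3(\overline{r^2} - 1/S)\right)$. The $1/S$
  sampling correction is the unphased form (phased data would use
  $1/2S$). A mean $r^2 \le 1/S$ is reported as undefined, consistent
  with infinite $N_e$. Numeric parity with existing LD-Ne tools' extra
  bias corrections is not claimed.

## Runs of homozygosity

`detect_roh()` reproduces the scanning-window semantics of the standard
array tooling: a 50-SNP window passes with at most 1 heterozygote and 5
missing calls; a SNP becomes a run candidate when at least 5% of the
windows overlapping it pass; maximal candidate runs are split at
inter-SNP gaps over 1,000 kb and kept when they span at least 100 kb,
contain at least 25 SNPs, and average at most 50 kb per SNP. The window
size, het/missing allowances, length, density and gap limits are the
usual published array settings; the 5% hit threshold and the 25-SNP
segment minimum are the scanning tool's documented defaults, exposed in
`roh_params()` because the 100 kb + density constraints alone would
admit implausible 2-SNP segments. Because the allowances act at the
window stage, a reported segment may contain isolated heterozygous or
missing calls — this matches the reference tool's behavior and is
deliberate. Segments are 1-based inclusive; BED export converts to
0-based half-open. The detector is verified against an independent
brute-force scanner on a thousand random instances.

$F_{ROH}$ divides the summed segment length by the autosomal map length:
the default 952,090 kb (the autosomal span of the chicken 600K array
map) or `l_auto_from_map()` for the span of the SNPs actually supplied.
ROH islands take the top 1% of per-SNP ROH incidence (empirical
quantile), require incidence $> 0$, and merge adjacent selected SNPs;
the all-equal-incidence tie collapses to one island per chromosome and
is flagged.

## Effective sex ratio

The effective sex ratio $\varepsilon$ — the proportion of females in the
effective population — is inferred by contrasting the drift accumulated
on sex-linked versus autosomal markers. Drift branch lengths are
measured on the diffusion time scale, $\tau = t/(2N_e)$ per marker
class, and converted by
$\varepsilon = 2 - \tfrac{9}{8}\,\tau_{X}/\tau_{A}$.
Composed with the classical sex-specific effective sizes
$N_e(A) = 4N_fN_m/(N_f+N_m)$ and $N_e(X) = 9N_fN_m/(4N_m+2N_f)$, the
formula returns exactly $N_f/(N_f+N_m)$ for all positive $N_f, N_m$ — a
closed-form identity the tests check on a grid. Balanced demography
gives $\tau_X/\tau_A = 4/3$ and $\varepsilon = 1/2$.

**Heterogamety.** The conversion algebra is written for an X chromosome
(heterogametic males). Chickens are ZW — males are the homogametic sex —
and under ZW the identical algebra yields the proportion of *males*.
The package computes the formula as printed and lets a
`heterogamety = {"XY", "ZW"}` flag control only the interpretation label
attached to the result; it does not silently remap the value. Module
tests verify both readings against simulations (ZW recovers
$N_m/(N_f+N_m)$; XY recovers $N_f/(N_f+N_m)$).

**Moment estimator.** For a SNP with ancestral frequency $\pi$ and
current sample frequency $\hat p$ from $m$ chromosomes, the drift
fraction $F = 1-(1-\tfrac{1}{2N_e})^t$ satisfies
$E\big[(\hat p-\pi)^2 - \hat p(1-\hat p)/(m-1)\big] = \pi(1-\pi)F$
exactly, so $F$ is estimated by averaging that ratio over SNPs and
$\tau$ by $-\log(1-\hat F)$, which is exact under pure drift up to
$O(1/N_e)$ rather than only in the small-$\tau$ linearization.
$m$ is sex-aware: $2n$ for autosomes, $2n_{homogametic} +
n_{heterogametic}$ for the sex chromosome. SNPs with $\pi \in \{0,1\}$
are excluded. When $\pi$ is estimated as the pooled mean of $K$
population frequencies rather than supplied externally, the estimator
is multiplied by $K/(K-1)$ to undo the shrinkage from estimating $\pi$
with the populations themselves (so a single population requires an
external $\pi$, e.g. the simulator's recorded ancestral frequencies,
which travel in the variant table and survive QC filtering). Two
caveats matter in practice. First, the pooled-mean correction assumes
comparable drift across the $K$ populations; when their $\tau$ differ
strongly, each population's drift leaks into the others' estimates
through the shared centroid, and the MCMC path — which estimates
$\pi_\ell$ jointly — is preferable. Second, drift-based $\tau$
estimation is sensitive to SNP ascertainment: pooled HWE filtering
across diverged populations preferentially removes differentiated
autosomal SNPs (the Wahlund effect; sex-linked SNPs are HWE-exempt)
and deflates $\tau_A$, while aggressive MAF filtering conditions on
segregation and deflates all $\tau$. When drift is strong relative to
the MAF threshold, estimate the ESR on call-rate-filtered but otherwise
unascertained SNPs.

**MCMC estimator.** `estimate_tau_mcmc()` fits the hierarchical
star-tree model $p_{k\ell} \sim \text{TruncNormal}(\pi_\ell,
\tau_k\,\pi_\ell(1-\pi_\ell))$ on $(0,1)$, with binomial sampling of the
observed counts, a uniform prior on each $\pi_\ell$, and a log-uniform
prior on each $\tau_k$. The truncated-normal drift kernel is the
standard diffusion approximation for moderate $\tau$; the full
time-dependent eigenfunction expansion of the drift transition density
is intentionally out of scope, and this approximation is the package's
key modeling simplification. Sampling is random-walk Metropolis with
reflection at the boundaries, vectorized across SNPs; pilot runs adapt
each block's step size toward an acceptance rate in (0.25, 0.45), and a
population whose pilot acceptance never reaches that window is flagged.
The default schedule (20 pilot runs of 500 iterations; 20,000
iterations thinned by 20 after a 10,000-iteration burn-in) matches
common practice for this model class; tests run reduced schedules and
check self-consistency on model-generated data, seed determinism, and
agreement with the moment estimator within two combined standard
errors.

**Pseudo-replication.** `pseudo_replicate_esr()` draws 50 replicates of
5,000 autosomal + 5,000 sex-linked SNPs by default (seeded per
replicate; with replacement when fewer are available, with a message),
estimates $\tau_A$ and $\tau_{sex}$ per replicate, and converts each to
$\varepsilon$. Out-of-range $\varepsilon$ values are reported and
flagged, never clamped, so the replicate distribution stays honest.
Note that pseudo-replicates resample SNPs from one dataset: they expose
SNP-sampling noise, not the genealogical noise discussed below.

## The Wright–Fisher simulator

`wf_simulate()` is a forward-in-time, two-sex, diploid simulator with
discrete non-overlapping generations — forward simulation because ROH,
pedigree inbreeding, and sex-specific transmission are exactly the
features a coalescent shortcut would lose. Defaults, chosen once to
emulate chicken-like array data at desk scale: 5 autosomes of 50 Mb at
3 cM/Mb (macrochromosome-like), one 80 Mb Z, 1,000 SNPs per chromosome
at uniformly random positions, ancestral frequencies
$\sim U(0.05, 0.95)$ (standing variation, as on an ascertained array),
mutation rate 0 so drift-only closed forms stay exact, and ZW
heterogamety. Populations descend independently from the shared
ancestral pool, founders in linkage equilibrium.

* **Transmission.** Autosomal gametes recombine with Poisson crossover
  counts on the linear map. The sex chromosome recombines only in the
  homogametic sex; the heterogametic parent passes its single copy,
  unchanged, to homogametic offspring only (under ZW: sires pass a
  recombinant Z to all offspring, dams pass their Z to sons). Offspring
  sex counts are fixed at the census sizes.
* **Mating schemes.** `random` draws a dam and a sire uniformly per
  offspring; `half_sib` uses a single sire per generation; `full_sib` a
  single sire and a single dam. The schemes are defined this way to
  span a wide, strictly ordered range of inbreeding intensity, which
  the tests verify both on the pedigree-F truth and on detected
  $F_{ROH}$.
* **Ground truth.** Census sizes, true $\varepsilon$, $N_e(A)$,
  $N_e(\text{sex})$, $\tau$ per class, the pure-drift $F_{ST}$
  expectation $1-(1-\tfrac{1}{2N_e})^t$, the ancestral frequencies of
  the emitted variants, and the mean pedigree inbreeding per generation
  from the exact kinship recursion.
* **Ascertainment.** Sites fixed in the final combined sample are
  dropped before emission, mimicking array polymorphism ascertainment;
  this slightly depresses drift-based estimates at large $\tau$ (it
  conditions on segregation) and is the main reason simulated He and
  $\pi$ sit above the unconditional expectation. Set
  `drop_fixed = FALSE` for closed-form drift checks.
* **Founder sampling.** Drawing founders from the infinite ancestral
  pool contributes approximately one extra generation of drift per
  marker class (the founder pool has the same copy number as one
  generation of transmission). The simulator's Z drift was verified
  against an exact allele-count Markov chain (implied $N_e(Z) = 75.4$
  versus the classical 75 for 50+50 breeders). At the validation scales
  used here the founder term inflates $\tau_A$ and $\tau_{sex}$ by the
  same $t \to t+1$ factor, which cancels in the $\tau$ ratio the ESR
  consumes.

### What the simulator does and does not emulate

It produces dense multi-population array-like genotypes with realistic
MAF spectra (standing variation), LD from recombination and drift, ROH
from inbreeding, sex-specific drift, and known truth. It does not model
selection, migration after divergence, overlapping generations,
genotyping error, or chicken-specific recombination heterogeneity
(micro- versus macrochromosomes). Passing tests therefore demonstrate
estimator correctness under the stated neutral demography — not
robustness to selection or to array genotyping artifacts.

## Validation design and problem sizes

The test suite favors independent oracles: brute-force loop
re-implementations for allele frequencies, $\pi$, IBS, GRM and ROH;
full enumeration for the HWE exact test; direct haplotype counting for
EM; hand-evaluated variance components for $F_{ST}$; closed-form
inversions for the Ne relations; and single-locus drift chains,
independent of the genotype simulator, for the $\tau$ moment estimator.
Simulation-recovery checks run at deliberately modest sizes (tens of
breeders, hundreds to thousands of SNPs, 10–50 generations) so the
whole suite completes in minutes on one core; the vignette-scale
defaults are larger.

One genuinely scale-bound quantity deserves a note: the ESR from a
single simulated history. A genome contributes essentially one Z
genealogy, so the across-history spread of the mean $\varepsilon$ is
large (standard deviation near 0.19 for a 50+50 population over 50
generations with an 80 Mb Z) even though the estimator is unbiased.
Validation of the balanced scenario therefore averages 12 independent
replicate simulations — the sampling unit is the evolutionary history,
not the SNP — bringing the Monte Carlo standard error near 0.055. The
same caveat applies to real single-species data: pseudo-replicating
SNPs cannot remove the shared-genealogy component of ESR uncertainty.

## Pipeline

`run_pipeline()` chains QC → diversity → $F_{ST}$ → LD decay → ROH →
islands → Ne → ESR → PCA/NJ with per-stage toggles, writing one
TSV/BED/newick file per result. Every output is stamped with the
package version, a hash of the analytic configuration (the output
directory is excluded so reruns elsewhere stay byte-identical), and a
per-stage seed derived from the global seed by a stable labeled hash —
so any stage can be rerun in isolation and the whole bundle is
deterministic given (input, config, seed). Structured progress lines go
to standard error, and every silent adjustment (subsampling with
replacement, masked Ne bins, out-of-range $\varepsilon$) is logged.
`validate_config()` fills defaults, rejects unknown keys, range-checks
values, and aggregates all errors into one message. A thin command-line
wrapper over these functions ships in `inst/cli/`.

## Known limitations

* The truncated-normal drift likelihood degrades for large $\tau$
  (strong drift) and near-fixed ancestral frequencies; the moment
  estimator's $-\log(1-F)$ inversion is similarly a pure-drift result.
* LD-based Ne assumes drift–recombination equilibrium; trajectories
  near the time horizon of the data (very small $c$) respond slowly and
  are best read over the recoverable window.
* $\pi$ is SNP-ascertained, not per-bp; comparisons across datasets
  require the same ascertainment.
* The ESR conversion interprets a two-sex demography only; under ZW
  data the printed formula estimates the male share (see above), and
  values outside $[0,1]$ signal estimator noise, small marker panels,
  or model misfit.
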