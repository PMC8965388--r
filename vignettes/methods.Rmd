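---
title: "Models and methods behind lampreyNb"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods behind lampreyNb}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

# The problem

Stream-dwelling larvae of a semelparous fish (the package was developed
around sea lamprey, *Petromyzon marinus*) accumulate over several spawning
years, and a single electrofishing or lampricide collection mixes age
classes. Managers want to know, per spawning year: how many adults bred
(`N_b`, the effective number of breeders), the minimum number of spawners
whose genotypes are required to explain the sampled offspring (`N_s`), and
an extrapolation of the total spawner number (`N_s`-hat). Because adults of
a semelparous species reproduce exactly once, full- and half-sibling
relationships can never span spawning years — this single biological fact
is what lets a reconstructed pedigree correct length-based ageing.

`lampreyNb` implements the full chain: SNP QC, sibship reconstruction of
unsampled parents, Bayesian Gaussian mixture ageing from body length,
pedigree-guided cohort reconciliation, and per-cohort estimators, plus a
seeded scenario simulator so every stage is testable against known truth.

# Genotype QC

Genotypes are diploid biallelic dosages. Filters run in a fixed order:

1. **Depth**: calls with fewer than 8 reads become missing (strictly
   `< 8`).
2. **Paralog screen**: a locus is dropped if observed heterozygosity
   exceeds 0.6, or the heterozygote read-ratio deviation exceeds 7 in
   absolute value. `D` pools reads over all heterozygous calls at a locus:
   with `x` reference-supporting reads out of `N`,
   `D = (x - N/2)/sqrt(N/4)`, the z-score against balanced 1:1 sampling.
   A true paralog merged into one assay shows excess heterozygosity and/or
   systematically unbalanced reads; the simulator can inject such
   pseudo-loci (`paralog_pairs`) by pooling the reads of two real loci.
3. **Individual missingness**: individuals missing strictly more than 80%
   of genotypes are removed.

An exact Hardy–Weinberg test is reported per locus but never auto-excludes:
the upstream study screened for HWE deviation without stating an action
threshold, so action is left to the analyst.

Two SNP panels are drawn from the QC survivors. The *pedigree panel* keeps,
per 1-Mb window along each chromosome, the locus with the (lexicographically)
highest minor allele frequency then call rate, among loci with MAF >= 0.05
and call rate >= 0.80, enforcing >= 1 Mb between successive picks (exactly
1 Mb apart is allowed; ties break uniformly at random under a seed). The
window scan is greedy left-to-right, which makes selection deterministic
and idempotent. The *LD panel* keeps the best-called SNP per capture-target
region and drops MAF < 0.05.

The depth filter is applied per genotype; the source protocol's phrase
("samples with <8X coverage") is ambiguous between per-genotype and
per-sample, so a per-sample mean-depth column is also reported.

# Sibship and parent reconstruction

The reference workflow runs a full-likelihood MCMC sibship program; this
package substitutes a transparent, desk-scale pipeline with the same
inputs and outputs:

1. **Pairwise screen.** For every pair, log-likelihoods under full-sib
   (identity coefficients 1/4, 1/2, 1/4 over 0/1/2 shared-parent paths),
   half-sib (1/2, 1/2, 0) and unrelated (1, 0, 0), using allele frequencies
   estimated from the offspring sample, with a one-parameter mistyping
   model: with probability `error_rate` (default 0.001, the published
   setting) an observed genotype is a fresh Hardy–Weinberg draw.
   Monomorphic loci are skipped; pairs with < 50 shared calls are
   unclassifiable.
2. **Full-sib partition.** Connected components of the graph whose edges
   are pairs with `logL(FS) - max(logL(HS), logL(U)) > 0`, refined by
   greedy single-offspring moves that must increase the summed joint family
   likelihood — each family's likelihood integrates, per locus, over the
   nine ordered parental genotype pairs under HWE priors. The joint
   criterion is considerably sharper than the pairwise one: FS/HS margins
   for a pair are only a few log units at 200 SNPs, but a misplaced member
   of a 6-offspring family is penalized through every sibling.
3. **Parent reconstruction.** Per family and locus, the posterior over the
   six unordered parental genotype-pair classes, proportional to the HWE
   pair prior times the product of member genotype probabilities.
4. **Half-sib linking.** Parents are "slots" (two per family; parents are
   unsexed, so slots are exchangeable). Slot clusters merge greedily by the
   gain in a composite likelihood: the joint likelihood of all involved
   families sharing one parent genotype (integrated per locus), each
   family's other parent integrated freely, versus independent parents.
   A merge is invalid if it would make one family's two parents coincide,
   or give two families a second shared parent (two families sharing both
   parents are one full-sib family). The acceptance threshold (default 10
   natural-log units) was calibrated on simulated nulls: gains between
   families with disjoint parents have a 99.9% quantile near 3.7 and an
   observed maximum near 5.2, while true shared parents score 6–24 and
   rising with family size; a pooled stream analysis tests thousands of
   family pairs and a single false link can chain cohorts together, so the
   threshold is set high at the cost of missing links between families
   with fewer than about three offspring (which inflates `N_s` slightly in
   heavily skewed scenarios).
5. **Family clusters.** Connected components of the offspring–parent
   graph. Cluster support is the fraction of locus-bootstrap replicates
   (resample loci with replacement, rerun partition + linking on the
   cluster's members) in which the cluster stays one component — an
   analogue, not a replica, of the reference program's "probability the
   cluster cannot be split". Singleton families have support 1 by
   definition.

# Length mixtures and the number of age classes

Lengths are modeled per stream and collection year as a univariate
Gaussian mixture, Gibbs-sampled with conjugate priors: component means
`Normal(sample mean, range^2)`, variances `InvGamma(2.5, 1.5 * sample
variance)` (prior mean equal to the sample variance), Dirichlet(1) weights,
10,000 iterations with 2,000 burn-in and thinning 5 by default (tests use
shorter chains — ample for well-separated test data — to stay inside time
budgets). Labels are switched to ascending-mean order per retained draw.

Two selectors for the number of components `K`:

* **Overfitted truncation**: fit `K = 10` deliberately overfitted
  components and, per retained draw, count components with weight >= 0.035
  (warning outside the conventional 0.01–0.05 band); the posterior for `K`
  is the distribution of that count. One deviation from a flat-prior setup:
  the overfitted fit uses a sparse Dirichlet concentration `1/K_max`.
  With concentration 1 the truncation rule is badly biased upward (mode
  `K = 7` on a single Gaussian of 300 points in our pilots) because a flat
  prior never empties surplus components; sparse weight priors are the
  standard fix, and asymptotic results require concentration below d/2 for
  surplus weights to vanish. Fixed-`K` fits keep concentration 1.
* **Birth–death MCMC**: `K` changes within the chain; between Gibbs
  sweeps a continuous-time birth–death process runs for one unit of
  virtual time, with births from the prior at rate 1 (Beta(1, k) weight)
  and per-component death rates equal to the likelihood ratio of the model
  without that component. The `K` posterior is the sojourn-time average.
  A chain that never changes dimension raises a diagnostic warning rather
  than failing silently.

The consensus rule: if the two posteriors' modes agree, that is `K`;
otherwise the mode with the larger posterior probability wins; an exact tie
resolves to the smaller `K` (parsimony; the reference analysis never hit a
tie). A final fixed-`K` fit assigns individuals by maximum responsibility.

# Reconciliation

Siblings cannot span spawning years, so a family cluster split across
mixture cohorts signals a problem with the length-based assignment. Two
situations are distinguished, because they require opposite actions:

* **Genuine oversplitting** — the minority side of the split has at least
  4 members and at least 25% of the cluster: the mixture has cut one true
  cohort in two (the reference study's largest cluster spanned all inferred
  cohort cutoffs in one collection), and the affected mixture cohorts are
  merged, transitively (union–find).
* **Stray members** — smaller minorities are indistinguishable from
  individual misassignment in the length-overlap zone (at a 4-standard-
  deviation mean separation about 2.3% of individuals fall past the
  component boundary); strays are reassigned to their cluster's majority
  cohort instead of triggering a merge. The 25%/4-member rule sits an
  order of magnitude above that noise rate.

A pure "merge whenever any cluster touches two cohorts" rule was rejected:
with realistic assignment noise nearly every sample contains at least one
stray, and whole-cohort merging would collapse genuinely distinct cohorts
almost always. After reconciliation every family cluster lies wholly inside
one final cohort, and the operation is idempotent. The same rule, applied
to collection-qualified labels, links cohorts across collection years when
families span them, and the per-cohort median length shift between
collections is reported as a growth proxy (reported, not modeled).

Spawn-year labels are then assigned from user-supplied length-at-age bands
(external benchmarks; the package ships none, because the underlying
length-at-age references give no transferable numbers) intersected with
constraint events: a lampricide treatment in year `y` makes spawn years
before `y` infeasible; barrier installations are recorded as context only,
since the reference systems demonstrate that barriers leak. Cohorts with
zero or multiple feasible years are labeled `infeasible` / `ambiguous`
with candidates listed, never silently forced.

# Per-cohort estimators

**Reproductive success.** `N_s` is the number of distinct inferred parents
of a cohort; `kbar = 2n/N_s` exactly; `V_k` is the sample variance of
per-parent offspring counts (denominator `N_s - 1`; the identity and the
estimator below are insensitive to this choice at the reported precision).

**Sibship-frequency Nb.** The demographic reproductive-variance form
`N_b = (kbar N_s - 2) / (kbar - 1 + V_k / kbar)`, which reproduces every
published sibship-frequency value from that table's own inputs after
nearest-integer rounding. Confidence intervals bootstrap offspring
(percentile, B = 1000, seeded).

**LD Nb.** Mean Burrows composite r-squared over cross-chromosome locus
pairs only (physical linkage excluded by design), at `pcrit = 0.05`. Two
conventions coexist in the literature: the raw composite correlation
(exactly 1 for perfectly correlated dosage vectors; independence mean
~ `1/S`) and the unbiased-products form with the `S/(S-1)` factor
(independence mean `1/S + 3.19/S^2`). The exported `burrows_r2()` defaults
to the raw form, whose toy oracles are exact; `nb_ld()` uses the
unbiased-products form internally because the published bias-correction
constants it subtracts (`E[r2|S] = 1/S + 3.19/S^2` for `S >= 30`, else
`0.0018 + 0.907/S + 4.44/S^2`) are calibrated for it — we verified by
simulation that the unbiased form's independence mean matches `1/S +
3.19/S^2` to four decimals at `S = 100`. The corrected `r2' = r2 - E[r2|S]`
converts to `N_b = (1/3 + sqrt(1/9 - 2.76 r2'))/(2 r2')` (small-`S`
constants 0.308/2.08 below `S = 30`); non-positive `r2'` reports `+Inf`,
never a negative size. Confidence intervals use a delete-one jackknife over
individuals converted to an effective chi-square degrees of freedom
(`df = 2 r2^2 / Var_jack`), the skew-respecting jackknife CI used with this
estimator in the literature; a normal-theory jackknife interval
under-covered in our calibrations.

**Calibration world for the LD method.** The estimator's bias correction
assumes a random-mating population at drift–recombination equilibrium. A
cohort founded by parents drawn fresh from Hardy–Weinberg carries only one
generation of drift LD — about `1/(4N)` for unlinked pairs instead of the
equilibrium `1/(3N)` — and the estimator then overshoots by roughly a
third regardless of mating design (monogamous pairing overshoots LD
instead, through excess full-sib mixture, and underestimates by ~30%).
`simulate_ld_cohort()` therefore breeds a constant-size Wright–Fisher
population forward for 20 generations (unlinked LD halves per generation,
so equilibrium is reached quickly) before producing the assayed cohort.
Under that idealized model, with 100 offspring and 200 SNPs, the median
estimate is within +9% of truth at `N in {25, 50}` and the 95% jackknife
CI covers truth in ~90% of replicates at `N = 50` — but only ~77% at
`N = 25`, short of the 80% design target. The misses are almost entirely
"lower bound above truth": the published estimator retains a ~+5–10% bias
when the sample size exceeds the true breeder number, and the CI is
centred on the biased point. We report this as a known limitation rather
than widening the interval ad hoc.
The one-generation founding world remains available through the main
simulator and is the honest analogue of a barrier-leak cohort whose parents
came from a large admixed lake population; LD-based `N_b` from such cohorts
should be read as upper-bound-leaning.

**Richness extrapolation.** Each offspring is an incidence "site" in which
its two parents occur. Chao2 with the `(m-1)/m` small-sample correction
(`S_obs + ((m-1)/m) q1^2 / (2 q2)`, bias-corrected `q1(q1-1)/(2(q2+1))`
form when `q2 = 0`) and the first-order jackknife
(`S_obs + q1 (m-1)/m`), with the standard incidence-based variances —
verified against the community-ecology reference implementation to 1e-12.
Parentage accumulation curves average cumulative distinct-parent counts
over random offspring orderings.

# What the simulator does and does not emulate

`sim_config()` states a world: disjoint parental pools per spawning year
(semelparity), polygamous mating with gamma-weighted skew solved
numerically to hit a target `V_k` (or monogamous random pairs), Mendelian
inheritance with HWE founders, mistyping, missingness, negative-binomial
read depth (mean 34x, matching typical on-target coverage), Gaussian
length-at-age with lethal multi-collection sampling, and optional paralog
injection. Defaults: 2 spawning years, 50 parents and 200 offspring per
year, `V_k` target 40 (strongly skewed, as the reference cohorts show),
200 SNPs on 20 chromosomes, error 0.001, 2% missingness. Length-at-age
defaults (45/75/95 mm at ages 0/1/2, sd 6-9 mm) are free parameters chosen
to resemble published larval length histograms, not published values.

Not emulated: read-level data, recombination maps (loci are unlinked, so
within-chromosome LD tests rely on the cross-chromosome rule rather than
genetic maps), selection, age-dependent survival, and ancestral
population structure (founders are unrelated). A green end-to-end test
therefore establishes correctness of the inference machinery under the
stated world, not robustness to linked loci or population structure.

# Numerical and degenerate-input choices

* All likelihood work is in logs with per-locus log-sum-exp; families of
  several hundred offspring stay in range.
* Mixture label switching: per-draw ascending-mean relabeling.
* Exact probability ties in the consensus rule: smaller `K`, with a
  message.
* Loci with zero heterozygous calls have undefined read-ratio `D` and are
  never flagged by the `|D|` rule; monomorphic loci are skipped in
  sibship and LD work.
* Empty QC survivors raise an explicit "no data survives QC" error.
* All stochastic steps consume seeds derived deterministically from one
  global seed, and identical configurations yield byte-identical outputs.

# Known limitations

* The sibship module is a surrogate for a full-likelihood MCMC program:
  accuracy targets are documented on simulations (>= 95% full-sib pair
  recovery, `N_s` within 10% at 200 SNPs with families of 5+), but exact
  cluster counts from the reference study are not reproducible targets.
* Half-sib links between one- and two-offspring families are usually below
  the evidence threshold; `N_s` is correspondingly conservative (biased
  up) under extreme reproductive skew.
* The published mixture posterior probabilities depend on the original
  length data and sampler; only the decision pattern of the consensus rule
  is reproduced, not the probabilities.
* LD-based `N_b` inherits the equilibrium assumption discussed above.
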