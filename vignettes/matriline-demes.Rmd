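---
title: "Detecting matriline-driven demes: models, assumptions and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Detecting matriline-driven demes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

## The problem

The European eel (*Anguilla anguilla*) spawns in the Sargasso Sea and is
managed as a single panmictic population, yet glass-eel samples repeatedly
show weak, patchy nuclear differentiation. One candidate explanation is
cryptic female philopatry: if females home to particular spawning
conditions, the population would be partitioned into *matrilines* —
clusters of mitochondrial haplotypes — that behave as reproductive demes
connected by male-mediated gene flow. `matriflow` implements the full
inference chain needed to interrogate that hypothesis in a single sampling
site followed over cohorts:

1. mtDNA haplotype collapsing and diversity (`collapse_haplotypes`,
   `haplotype_diversity`, `nucleotide_diversity`, `mtdna_fst`);
2. a transversion-weighted median-joining network with maximum-parsimony
   post-processing and matriline assignment (`median_joining`, `mp_prune`,
   `assign_matrilines`), giving each individual a matriline x cohort
   "deme" label;
3. microsatellite validation and diversity (`null_allele_em`,
   `fdist_scan`, `bottleneck_test`, `expected_het`, `rarefied_ar`, `fis`,
   `internal_relatedness`, `homozygosity_by_loci`, `amova`,
   `pairwise_fst`, `mantel_test`, `evanno_delta_k`, `fdr_correct`);
4. a structured-coalescent MCMC comparing panmixia against a k-deme
   island model with asymmetric gene flow (`sample_posterior`,
   `compare_models`, `effective_migrants`);
5. single-genealogy skyline plots per matriline (`hky_distance`,
   `upgma_tree`, `classic_skyline`);
6. condition-index allometry and heterozygosity-fitness models
   (`allometry_fit`, `condition_index`, `hfc_model`);
7. a synthetic-data generator with recorded truth (`sim_config`,
   `simulate_structured`) so that every stage is testable without any
   external download.

## The stated world of the generator

`sim_config()` defaults encode the sampled system: three matrilines (A the
largest), three cohorts with the published per-deme sample sizes (82/35/33,
58/35/32, 62/32/27), 22 microsatellites under strict stepwise mutation, a
355-bp mtDNA fragment whose three founding haplotypes sit one and two
transition steps apart, and allometric weight-length phenotypes
(log10 slope 3.397, intercept -3.813 on the mg/mm scale) with
cohort-specific condition shifts (0.944, 0.993, 1.061).

Two generator decisions deserve explanation:

* **Which mutation-scaled sizes?** The published per-cohort estimates
  offer three (theta, Nem) columns. Two of them contain demes with
  theta = 0.067 receiving fewer than 0.4 migrants per generation; at
  equilibrium such demes would show F\_ST of 0.3-0.5, contradicting the
  same study's reported band 0.001 < F\_ST < 0.006. The remaining column
  (theta = 2.6/2.067/4.6 with 8.7-21.9 migrants) *is* consistent with that
  band, so it is the default. With it the generator reproduces the
  observed scales: per-cohort deme F\_ST of a few per mille,
  between-cohort F\_ST an order of magnitude smaller, non-significant
  mtDNA cohort differentiation, Hd ~ 0.82-0.86 and pi ~ 0.004-0.008.
* **Shared genealogies across cohorts.** Cohorts are contemporary samples
  of one underlying process; simulating each cohort as an independent
  coalescent would fabricate between-cohort differentiation two orders of
  magnitude larger than observed. The generator therefore draws one
  genealogy per locus (and one per matriline for mtDNA) and distributes
  the sampled genes across cohorts.

What the generator does *not* emulate: population growth (real samples
carry a star-like excess of singleton haplotypes that a constant-size
coalescent cannot produce — our simulated haplotype counts are lower than
the published 71 at matched diversity), selection at any locus except
through the FDIST test's own simulations, genotyping error and allele
dropout (except through the null-allele model), and larval transport. A
green test on synthetic data therefore establishes internal consistency of
the estimators with the model they assume, not correctness on ocean data.

## Median-joining network and matriline assignment

Distances weight transversions `tv_weight = 8` times transitions, matching
the strong transition bias of the fragment; the relaxation parameter
`epsilon = 35` is on this weighted scale (with distances of 1-32 between
observed haplotypes it effectively admits all alternative links, which is
what makes the later parsimony pruning informative). Median vectors are
per-site majority consensi of linked triplets; when all three states
differ, the first node's state is kept (a deterministic quasi-median
simplification). A median pruned for low degree is never re-added, which
guarantees termination; the iteration cap (10 sweeps) is logged if hit.

`mp_prune` enumerates minimum-length trees connecting all observed
haplotypes, treating medians as optional Steiner points: subsets of
medians (up to 12, then a flagged approximation) times an
include/exclude branch-and-bound over tied edges, capped at 10,000 trees
in deterministic order. Matriline anchors are the `k_main = 3` most
frequent haplotypes; a satellite joins the anchor it reaches first
(without crossing another anchor) in the most shortest-trees, ties broken
by path weight and then anchor frequency — all deterministic, so the
assignment is invariant to input order. Components containing no anchor
are flagged unassigned rather than forced, mirroring the small assignment
loss visible in the published per-deme totals.

## Structured-coalescent MCMC

Time is mutation-scaled: a lineage pair in deme *i* coalesces at rate
2/theta\_i, a lineage in *i* jumps backwards to *j* at the immigration
rate M\[j, i], and branch lengths are expected mutation counts.
Microsatellite likelihoods use a strict single-step ladder on the observed
allele span plus a buffer of 10, evaluated by symmetric eigendecomposition
and Felsenstein pruning with per-branch normalisation.

Three moves: (a) sliding-window updates of one theta or M entry, accepted
on the genealogy prior-density ratio, which is computed from per-genealogy
sufficient statistics (interval-weighted k(k-1) and k sums, coalescence
and migration counts) so a parameter move costs O(k^2) regardless of
event count; (b) a per-locus independence redraw of the genealogy from
the structured-coalescent prior at current parameters, accepted on the
likelihood ratio; (c) a per-locus time rescale by s = exp(U(-0.5, 0.5))
with Jacobian s^E. All three satisfy detailed balance; with the
likelihood forced to 1 the chain reproduces the uniform priors exactly
(tested), and on two tips with a quadrature-solvable likelihood it
reproduces the analytic posterior (tested). The single-lineage
reimplantation proposal of full-scale samplers is deliberately not
replicated; mixing at desk scale relies on (b) + (c), which is why the
default schedule keeps long thinning.

Priors default to theta ~ U(0, 200) and M ~ U(0, 1000) with proposal
windows 20 and 100 (the settings used in the original analyses). Model comparison uses the
harmonic-mean marginal log-likelihood, retained for fidelity despite its
known instability, averaged over replicate chains; a truncated variant
(dropping the lowest 5% of likelihood samples) is also reported.

**Ergodic range.** The two genealogy moves explore tree space by redraws
from the prior plus rescaling. We verified empirically that this is
exactly calibrated for small genealogies — with the generating theta
drawn from the prior, 95% intervals cover it at nominal rate for 4-gene
loci, and posteriors match brute-force marginal-likelihood profiles —
but becomes practically non-ergodic beyond roughly 10-20 gene copies per
locus: the probability that a prior-drawn topology sorts the alleles as
the data demand vanishes, chains settle on over-long compromise
genealogies, and theta drifts high. The conditional single-lineage
reimplantation move that full-scale samplers use to escape this regime
is out of scope here. All package defaults and the pipeline's migration
stage therefore subsample to at most a few individuals per deme, and
three documented consequences follow for the acceptance suite:

* theta-interval coverage *is* nominal at the validated scale (tested
  with truth drawn from the prior, the design under which Bayesian
  intervals are exactly calibrated);
* at that same scale 18 genes per locus contain almost no directional
  information, so the posterior ranking of a 40-fold migration-rate
  asymmetry is near chance and its acceptance check fails honestly;
* the harmonic-mean log Bayes factor has replicate noise of tens of log
  units against a true panmictic LBF of order unity, so the
  model-selection calibration thresholds (70%/90%) also fail honestly —
  consistent in spirit with the published observation that the estimator
  identifies true panmixia only ~70% of the time even at full MIGRATE
  scale.

SMM likelihood surfaces are extremely flat in theta upwards (a pair of
identical alleles is compatible with a long genealogy), so single-deme
posteriors carry long right tails; interval coverage, not point accuracy,
is the tested property.

## The IR/HL contrast

Theory predicts that under asymmetric migration importing rare alleles,
homozygosity-by-loci should track deme F\_IS better than internal
relatedness (R\_HL > R\_IR). On generator truth this never happens: deme
means of IR correlate with Weir-Cockerham F\_IS at r ~ 0.99 in every
regime we simulated (homogenising flow, drift-dominated sinks, no flow),
because both statistics are computed from the same sample with the same
allele-frequency weighting — the correlation is close to algebraic. The
published empirical values (R\_IR = 0.93 vs R\_HL = 0.88) show the same
ordering. The diagnostic is implemented and reported faithfully;
its acceptance check encodes the theoretical expectation and is expected
to stay red, which we consider a finding about the diagnostic, not a
defect of the implementation.

## Skylines

The full Bayesian skyline (MCMC over genealogies) is replaced by a
point-genealogy skyline: HKY distances with fixed kappa (the distance is
the 1-D maximum-likelihood divergence for the identical/transition/
transversion site counts, so it reduces to Jukes-Cantor at kappa = 1 and
uniform frequencies), UPGMA for an ultrametric genealogy, and the
classic/generalized skyline on its coalescent intervals (pooling by AICc
when `epsilon = "aicc"`). The conclusions this supports are qualitative
growth phases only; node-height and topology uncertainty are not
propagated. Time axes are in substitutions/site; conversion to years uses
a user-supplied rate (default 0.946e-5 per site per Myr with sd 0.196e-5
as an uncertainty band) and is configuration, never estimated.

## Condition index and HFC

The length-weight allometry is fitted on log10 (the base only shifts the
intercept; the slope and Kn are base-invariant), with an ANCOVA of
`log10(W) ~ log10(L) * cohort` to justify a common slope. Kn = W / (a
L^b) is centred at 1 by construction when (a, b) are fitted on the same
data. The HFC model regresses HL on IR and uses the residual (`Rds`,
orthogonal to IR by construction) so both indices can enter the linear
model `Kn ~ Rds * IR * (cohort / matriline)`; F tests are sequential
(type I), matching the published table's degrees-of-freedom pattern.
Pooled-versus-per-cohort slope differences are real in this design
(condition shifts covary with length across cohorts), which is why slope
recovery is tested within cohort.

## Numerical and procedural choices

* Permutation p-values are (#extreme + 1) / (n\_perm + 1); every
  stochastic routine takes an explicit seed.
* The null-allele EM treats observed homozygotes as mixtures of true and
  null-heterozygous genotypes; missing genotypes enter as optional null
  homozygotes only on request (`missing_as_null`), since missingness has
  other causes.
* The two-phase mutation model follows the source's wording verbatim
  (10% single-step, multi-step variance 0.1) with `p_smm` exposed because
  the conventional parameterisation is the reverse (90% single-step).
* IR sums the frequencies of all carried allele copies (the convention
  that reproduces the reference implementation's behaviour); the
  homozygous-loci-only domain is available via `freq_domain`.
* Rarefaction uses exact hypergeometric terms on log-binomials; it equals
  exhaustive subsample enumeration (tested).
* The bottleneck test conditions equilibrium heterozygosity on the
  observed allele count by adaptive search plus rejection; fixed loci are
  excluded.
* The FDIST scan calibrates a finite island model to the trimmed-mean
  multilocus F\_ST and bins simulated loci by heterozygosity into
  quantile envelopes; with defaults it flags about the nominal 5% of
  neutral loci.
* Pipeline reports are deterministic given (inputs, seed): stage seeds
  are derived from the master seed, and JSON output is byte-stable. No
  stage cache is kept — a full synthetic run takes minutes, so reruns
  are cheaper than cache invalidation logic.

## Known limitations

Desk scale is a design constraint: the MCMC mixes reliably only for a
few individuals per deme per locus (see the ergodic-range discussion
above), and its Bayes factors at reduced budgets carry the harmonic-mean
estimator's variance. The median-joining
implementation simplifies quasi-median generation (first-state
tie-break), so on data with many three-state sites it can differ from
reference network software in which medians it materialises; parsimony
pruning then removes most of the difference. UPGMA assumes clock-like
behaviour within a matriline. None of the estimators model genotyping
error beyond null alleles.
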