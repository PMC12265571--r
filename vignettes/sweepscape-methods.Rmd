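---
title: "Detecting and classifying selective sweeps with sweepscape"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Detecting and classifying selective sweeps with sweepscape}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

## The problem

Recent positive selection leaves localized footprints in population
genomic data: a *hard* sweep — fixation of a single-origin *de novo*
beneficial mutation — erodes linked diversity around the selected site,
while a *soft* sweep — fixation of an allele that was already segregating
neutrally (standing variation) — leaves a subtler skew because the
beneficial allele goes to fixation on several haplotype backgrounds.
Windows *flanking* a sweep are also perturbed by hitchhiking and can
mimic soft sweeps (the "soft shoulder"), so a scan that only asks "sweep
or not?" at each window will misattribute signals. sweepscape implements
a five-class, simulation-trained classification pipeline for unphased
diploid genotype data: each genomic window is classified as hard, soft,
hard-linked, soft-linked or neutral from the spatial pattern of twelve
summary statistics across eleven adjacent subwindows.

The intended user is a population geneticist with a VCF of unphased
genotypes, an accessibility mask, a recombination map and an estimate of
the population size history, who wants window-level sweep calls with
false-discovery control and an estimate of how much of the adaptation
was soft.

## The model and its parts

### Training-data simulator

Labeled training data come from a forward-time Wright–Fisher simulator
(`simulate_replicate()`): discrete generations, 2N haplotypes over a
linear region, Poisson crossovers at rate r per bp per generation,
infinite-sites Poisson mutation at rate mu per bp, and additive selection
at a focal site (heterozygote fitness 1 + s/2, homozygote 1 + s).
Parameters are drawn per replicate (`draw_params()`) from priors chosen
for a large, highly diverse insect population:

| parameter | prior | default |
|---|---|---|
| mu (per bp per gen) | uniform | [8.82e-10, 8.82e-9], mean 4.85e-9 |
| r (per bp per gen) | exponential, truncated at 3x its mean | mean 4.85e-9 |
| s | log-uniform | [0.005, 0.05] |
| tau (fixation time before sampling, units of 4N0 gens) | uniform | [0, 0.001] |
| f0 (standing-variant frequency, soft classes) | uniform | [0, 0.05] |
| region | — | 2.75 Mb, 11 subwindows |

Hard sweeps introduce the beneficial allele as a single copy; soft
sweeps start selection on a standing neutral variant at frequency f0.
For soft sweeps the simulator prefers an *existing* segregating variant
in the focal subwindow whose carrier count is within 50% of
`round(f0 * 2N)` — such a variant carries genuine neutral ancestry, which
is the biologically meaningful part of the soft-sweep model — and only
injects a new variant on random backgrounds when none is available. The
class label is determined by where the sweep lands: the central
subwindow gives "hard"/"soft", any other subwindow gives the
corresponding "-linked" class, and neutral runs have no selected site.

Three design choices deserve emphasis:

* **Fixation conditioning.** Sweep runs are conditioned, by rejection
  (budget 1,000 attempts), on the beneficial allele fixing; sampling
  happens tau x 4N0 generations after fixation. The selection phase is
  *inserted* at that time point rather than carved out of the neutral
  timeline: neutral history runs to the fixation time, the sweep is run
  to completion from the saved state, and the remaining tau x 4N0
  neutral generations follow. This makes the conditioning exact at the
  cost of adding the (short) sweep duration to the total pedigree depth.
* **Rescaled populations.** Forward simulation of realistic population
  sizes is wasteful, so the simulator can run at a scaled-down diploid
  size `sim_n` with mu, r and s multiplied and epoch times divided by
  N0/sim_n, preserving theta = 4N mu L, rho = 4N r L and 2Ns. The
  burn-in is 10 x the ancestral size in generations, which leaves the
  expected number of segregating sites within about 1% of its
  equilibrium value (verified against Watterson's expectation in the
  test suite).
* **Time unit of tau.** The fixation-time prior is interpreted in units
  of 4N0 generations before sampling, the convention of coalescent sweep
  simulators; dominance is additive since nothing in the model motivates
  another choice.

Replicates can be masked with empirical-style accessibility profiles
(`apply_mask()`; one profile drawn per replicate from a user-supplied
library), serialized as gzipped text, and assembled into stratified
train/test sets (`build_class_sets()`); the reference design is 2,700
training and 300 test examples per class.

### Features

Twelve statistics are computed per subwindow (`subwindow_stats()`): pi,
Watterson's theta, Tajima's D, the number of distinct diplotypes, the
homozygosity statistics H1, H12 and H2/H1 on the diplotype frequency
spectrum, Kelly's Zns (mean pairwise r^2), the maximum of the omega
statistic over block splits, and the variance, skewness and kurtosis of
the pairwise-difference distribution. Because the input is unphased, all
"haplotype" quantities are computed on diplotypes — the multilocus
genotype string of each individual — and LD uses the squared dosage
correlation, the standard unphased r^2 estimator. Missing data are never
imputed: per-site frequencies use non-missing allele copies, pairwise
distances use jointly non-missing sites, and undefined site pairs are
excluded from LD averages.

Each 12 x 11 matrix is then normalized row-wise (`normalize_row()`): if
a statistic's minimum across the 11 subwindows is negative, its absolute
value is added to every entry (relevant for Tajima's D and the skewness);
the row is then divided by its sum. The shift is applied *before* the
division so outputs are guaranteed non-negative; an all-zero row stays
all zeros rather than becoming NaN, keeping classifier inputs finite.
The normalization makes the features capture the *spatial pattern* of
each statistic rather than its magnitude, which also cancels the count
units of pi and theta.

### Classifier

The five-class classifier (`train_classifier()`) is a small
fully-connected softmax network over the 132 normalized features (two
ReLU hidden layers, 64 and 32 units by default), trained with Adam on
categorical cross-entropy. Because the five class definitions are
invariant under reversing the subwindow axis (a central sweep stays
central, a linked window stays linked), each training example is also
presented mirrored, doubling the effective training set; validation
examples are never augmented. The architecture is a configuration
artifact, not a contract: anything passing the recovery suite is
acceptable. What
*is* contractual is the early-stopping rule: 10% of the training
examples are held out (class-stratified, seeded) as a validation set,
and training stops when 5 consecutive epochs each fail to lower the
validation loss by at least 0.001, restoring the weights of the best
validation epoch. Posteriors come from the final softmax
(`predict_posterior()`); they are used as-is, with no recalibration —
class-membership probabilities from softmax outputs are not guaranteed
to be well calibrated, and downstream error control comes from the
simulation-based q-values instead.

### Evaluation, calling, and the soft fraction

`confusion_at_threshold()` mirrors the calling rule: predicted class is
the argmax posterior, but an example whose argmax is hard or soft and
whose *combined sweep probability* (p_hard + p_soft) falls below the
threshold is "uncertain" and excluded from the accuracy denominators.
`roc_pr()` collapses the five classes to sweep (hard, soft) versus
unselected (linked, neutral), scores each window by its combined sweep
probability, and reports the trapezoid AUC and step-wise average
precision.

`call_sweeps()` calls a window at threshold t when its argmax is hard or
soft and p_hard + p_soft >= t (reference operating points 0.80, 0.90,
0.95, 0.99). `fdr_and_q()` assigns each call a q-value against a
neutral-simulation null: treating the call's own combined probability as
a threshold, the expected number of false positives is the fraction of
neutral simulations reaching that threshold times the number of windows
scanned — an all-neutral-genome null, deliberately conservative — and
the FDR is that expectation over the number of calls at or above the
threshold, capped at 1 and made monotone by a step-up pass.

`soft_fraction_corrected()` turns hard/soft call counts into a
deliberately conservative estimate of the fraction of sweeps that are
soft: all expected false discoveries (q x total calls) are assumed to be
soft calls and removed, and the estimated true-hard count
(n_hard / c_hh, using the confusion matrix at the same threshold) times
the hard-called-soft fraction c_hs is moved from the soft to the hard
side. Applying c_hs to the *estimated true* hard count rather than the
observed count keeps the bookkeeping internally consistent (expected
hard calls then match observed ones). Misclassification of soft sweeps
as hard is ignored on purpose; both corrections can only lower the soft
fraction, so the estimate is a lower bound.

Summary tables report the percentage of calls that are soft, rounded
half-up to one decimal through an intermediate two-decimal rounding —
the double-rounding convention of common spreadsheet formatting, chosen
so the package's tables match their reference layout cell for cell.

### Genome scan

`scan_genome()` reads a VCF (biallelic SNPs only; 1-based positions
converted to the package's 0-based half-open convention), slides an
11-subwindow context along each chromosome one focal subwindow at a
time (2.75 Mb context / 250 kb focal step at full scale), and drops
windows whose length-weighted mean recombination rate over the context
is zero — the spatial classifier is meaningless without recombination
distance — or whose masked fraction exceeds 0.85 (kept at exactly 0.85:
the filter is a strict inequality). Windows at chromosome edges require
a full context; truncated contexts are not classified. Kept windows are
masked, featurized and classified exactly like training replicates.

## Desk-scale study conditions

Full-scale training (2.75 Mb windows, thousands of replicates) is a
cluster job. The package's tests, demonstration and acceptance script
instead run a scaled-down version of the same design, chosen once as:

* priors passed through `rescale_region(alpha = 25)`: 110 kb regions in
  eleven 10 kb subwindows, s rescaled to [2e-4, 2e-3] — the same
  footprint-to-region geometry as the full-scale design, and the same
  device the full-scale design itself uses to keep simulations tractable;
* constant diploid N = 500,000, giving per-bp diversity 4 N mu of about
  0.01 (matching the high diversity of the large insect populations this
  method targets) and population-scaled selection 2Ns between roughly
  200 and 2,000 — strong sweeps, which are the method's stated quarry;
* forward runs at `sim_n = 100` (theta, rho and 2Ns preserved by
  rescaling) with a neutral burn-in of 8x the ancestral size (the
  standalone simulator default is 10x; both reproduce Watterson's
  expected segregating-site count within Monte Carlo error), 300
  replicates per class (250 train / 50 test), 20 sampled diploids, and
  a 12-tile planted-sweep synthetic genome for the scan stage.

On one CPU this takes roughly 10–15 minutes end to end. Two honest
caveats about what passing at this scale shows. First, with 50 test
examples per class the evaluation metrics carry non-trivial Monte Carlo
error. Second, the desk-scale regime is *harder* than the full-scale
one in a specific way: runtime caps the simulable diversity
(theta proportional to 2Ns under fixed priors), so the whole rescaled s
prior sits an order of magnitude below the population-scaled selection
strengths that realistic effective sizes imply at full scale, and its
weak tail produces faint footprints relative to window diversity. In
practice this caps desk-scale five-class accuracy well below what the
same pipeline achieves at full scale — hard and soft sweeps in
particular separate only partially, and windows linked to weak sweeps
are often indistinguishable from neutral ones — while the binary
sweep-versus-unselected discrimination remains strong (held-out AUC
above 0.9). Desk-scale metrics are therefore lower bounds on full-scale
behavior, not estimates of it.

## What the generator does and does not emulate

The simulator reproduces the features the classifier relies on —
diversity valleys with recombination-limited width, haplotype-structure
differences between single-origin and standing-variant fixation,
LD blocks flanking the selected site, and empirical-style missingness
when mask profiles are supplied. It deliberately does not model:
variable recombination along the region (the map is used for window
filtering, not simulation), gene conversion, dominance other than
additive, migration and population structure, recurrent-mutation soft
sweeps, or background selection. Real genomes contain all of these, so
simulated accuracy should be read as an upper bound on real-data
accuracy with respect to model misspecification — while being, as noted
above, a lower bound with respect to training scale.

## Numerical choices and degenerate inputs

* Statistics of empty subwindows: diversity and LD statistics are 0, the
  diplotype spectrum collapses to a single class (H1 = H12 = 1,
  H2/H1 = 0); the featurizer warns and continues.
* Tajima's D returns 0 when there are no segregating sites or the
  variance term vanishes; pairwise-difference skewness and kurtosis are
  0 when the distance variance is 0.
* omega_max requires at least 4 usable sites; splits with a zero
  between-block r^2 sum are skipped, and 0 is returned if every split is
  skipped. Undefined r^2 values (monomorphic pairwise-complete subsets)
  contribute 0 to omega's sums and are excluded from Zns entirely.
* Site positions from the continuous-coordinate simulator are floored to
  integers; collisions are nudged upward one bp so positions stay
  strictly increasing.
* The q-value step-up uses the running minimum from the least stringent
  call upward, so q is monotone non-increasing in the combined sweep
  probability; FDR is capped at 1.
* All randomness flows through R's RNG (including inside the compiled
  simulator), so a seed plus a configuration reproduces every artifact
  byte for byte; no global seed state is kept.

## Known limitations

* Soft sweeps whose standing variant is young look like hard sweeps —
  a property of the model, not a bug — so hard/soft confusion is
  intrinsically asymmetric; the conservative soft-fraction correction
  exists precisely because of this.
* The neutral-simulation null for q-values assumes an all-neutral
  genome, which overstates false discoveries when sweeps are common;
  q-values are conservative.
* The scan classifies each focal subwindow independently; adjacent calls
  are correlated because contexts overlap by 10 subwindows, and no
  clustering of calls is attempted.
* Posteriors are not calibrated probabilities; thresholds are operating
  points, not error rates.
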