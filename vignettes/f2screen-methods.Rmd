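---
title: "Models and methods behind f2screen"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods behind f2screen}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(f2screen)
```

# The screen and its genetics

An F2 screen makes rare recessive resistance alleles visible. Single
field-mated females found isofemale lines; each line therefore carries
exactly four gametic haplotypes from the field population. The F1 of a
line are sib-mated in one cage, and F2 neonates are screened on
toxin-expressing leaf tissue. If one founding parent was heterozygous for
a resistance allele R, half the F1 carry it, the within-line allele
frequency is 1/4, and random F1 mating yields 1/16 homozygous-resistant
F2 — enough to score the line as positive even when R is fully recessive.

Two assumptions do the heavy lifting throughout the package:

* **Panmixia.** The four founding haplotypes are independent draws at the
  population frequency $q$, so a line carries R with probability
  $1 - (1 - q)^4$ (`line_carrier_prob()`). No inbreeding coefficient is
  modelled; for a population believed to be one panmictic unit this is the
  natural first-order model, and a nonzero inbreeding coefficient would
  raise carrier probabilities slightly for the same $q$.
* **One locus, autosomal, recessive phenotype.** Multi-locus resistance,
  sex linkage and non-recessive scoring are out of scope.

`expected_rr_fraction_f2()` returns the exact Mendelian fractions (1/16
with a single heterozygous founder, 1/4 with two, 0 with none); the test
suite re-derives them by brute-force enumeration over all parental gamete
transmissions and F1 × F1 matings.

# Estimating the allele frequency

The screen's sufficient statistic is $(S, N)$: $S$ true-positive lines out
of $N$ screened. The default **beta convention** (`posterior_q(...,
method = "beta_approx")`) puts a uniform prior on the line-carrying
frequency $p$, giving $p \mid S, N \sim \mathrm{Beta}(S+1,\, N-S+1)$, and
maps to the allele scale through the rare-allele linearisation
$p \approx 4q$, i.e. $q = p/4$ on $[0, 1/4]$. The posterior mean is

$$E(q) = \frac{S + 1}{4\,(N + 2)},$$

and credibility intervals are scaled beta quantiles. For $S = 1$,
$N = 137$ this yields $E(q) = 0.0036$ with 95% interval
$(0.0004,\ 0.0099)$.

The **exact convention** (`method = "exact_numeric"`) places the uniform
prior directly on $q \in [0,1]$ and uses the exact carrier likelihood,
$\pi(q) \propto (1-(1-q)^4)^S (1-q)^{4(N-S)}$. Normalisation, means and
the CDF are computed with adaptive quadrature (`stats::integrate`,
relative tolerance $10^{-9}$–$10^{-10}$); quantiles invert the CDF by
`uniroot` at tolerance $10^{-12}$; sampling inverts a 4097-point CDF grid.
For rare-allele screens the two conventions agree to about two significant
figures — for $S=1, N=137$ the means are 0.00360 vs 0.00365 and the upper
95% bounds 0.0099 vs 0.0101 (≤ 2% apart) — and the beta convention is the
default because it is closed-form and is the convention in which the
screen literature reports its estimates. The linearisation degrades as
$q$ approaches $1/4$; the exact convention exists precisely for that
regime.

Intervals are **equal-tailed**, not highest-posterior-density: equal-tailed
intervals are the standard presentation in this literature and are
invariant under the monotone map between the $p$ and $q$ scales. Display
rounding is 4 decimal places; all serialised values keep full precision.

# Detection probability

A negative line is only informative if a present allele would actually
have been seen. The per-line miss probability models the screen forward
under a **mass-sib-mating story**: one founding parent heterozygous, each
F1 carrying R independently with probability 1/2, each F1 female's brood
sired by exactly one male drawn uniformly with replacement from the
line's $n_m$ males, and each of her $k_i$ screened neonates being a
*surviving* homozygous-resistant with probability
$\tfrac14 (1-\mu)$ when both parents carry. Conditioning on the number of
carrier males $m$:

$$P_{No} = \sum_{m=0}^{n_m} \binom{n_m}{m} 2^{-n_m} \prod_i
  \left[1 - \tfrac12 \tfrac{m}{n_m} \left(1 - \beta^{k_i}\right)\right],
  \qquad \beta = 1 - \tfrac{1-\mu}{4}.$$

The generative story is stated this precisely so that the closed form and
the forward Monte-Carlo oracle in the tests agree by construction; other
published variants (males mating multiply with fixed harem sizes,
conditioning on at least one carrier per sex) would change the formula
and are deliberately not assumed. Control mortality $\mu$ is applied as an
independent per-neonate Bernoulli failure, equally to RR neonates; no
day-5 versus day-8 mortality correction is attempted, which if anything
understates detection. A line "detects" when at least one surviving RR
neonate appears — the phenotypic scoring criterion collapsed into a single
event.

The experiment-wise detection probability is the arithmetic mean of
$1 - P_{No}$ over lines, and threshold tallies use strict inequalities
(fractions of lines with detection $> 0.95$, $< 0.80$), matching how such
results are reported. With the study-average line (27 females, 27 males,
11 neonates/female, $\mu = 0.132$), $1 - P_{No} \approx 0.975$.

# Comparing two campaigns

Two campaigns' posteriors are compared through their independent joint
density. The package defines the two-sided equality probability as

$$p = 2 \min\{P(q_a < q_b),\ P(q_a > q_b)\},$$

computed either by quadrature, $P(q_a < q_b) = \int F_a(x) f_b(x)\,dx$, or
by paired Monte-Carlo draws. This symmetric-tail definition is a
*reconstruction* — the source method for joint-pdf comparison is not
reproduced in print — so the raw half-plane masses are returned alongside
$p$, letting a user layer any alternative definition on top. Posteriors in
different conventions are integrated on the common $q$ scale.

The replication power simulation asks what a better-replicated pair of
campaigns would have concluded: per replicate, true line-carrying
frequencies are drawn from each posterior's beta distribution, screen
counts are re-simulated as $S^* \sim \mathrm{Binomial}(\text{round}(m
\cdot N), p_{true})$, posteriors are rebuilt and $p$ recomputed; the
power is the fraction of replicates with $p < \alpha$. Every stochastic
step flows from one seed and the full $p$-value vector is returned.
Campaign inputs are always user-supplied $(S, N)$ pairs — no historical
values are hard-coded.

# Forecasting resistance evolution

`step_generation()` is a standard one-locus two-allele recursion under
habitat-proportional soft selection: a fraction $\varphi_t$ (the year's Bt
adoption) of larvae develop on Bt plants, the rest in refuges, genotype
$G$ survives $W_G = \varphi_t w_G^{Bt} + (1-\varphi_t) w_G^{ref}$, and
survivors mate panmictically, so

$$q' = \frac{q^2 W_{RR} + q(1-q) W_{RS}}{\bar W}.$$

This recursion is the package's own documented stand-in for unpublished
model internals, so absolute forecasts (a specific number of years to
resistance) should be read as properties of *this* recursion and its
configuration, not as reproductions of any previously published figure.
All biology lives in configuration, never in code:

| parameter | default | rationale |
|---|---|---|
| `generations_per_year` | 2 | typical voltinism of a Mediterranean stem borer |
| `bt_survival` | ss 0.01, rs 0.02, rr 1 | high-dose event: heterozygotes nearly eliminated, resistance functionally recessive |
| `refuge_survival` | all 1 | refuge imposes no differential mortality |
| `threshold_q` | 0.5 | a common operational "resistance has arrived" point; exposed precisely because failure criteria differ between models |
| adoption schedule | CSV `year,proportion` | fractions, not percent; missing years carry the last value forward (the shipped example anchors 0.35 in 2005 and 0.74 in 2016) |

Deterministic mode (`years_to_resistance()`) iterates the recursion and
reports the first year with $q \ge$ threshold plus the full trajectory.
Stochastic mode (`run_stochastic()`) adds two sources of randomness: the
initial frequency drawn from a posterior (or pinned at its mean — the two
initialisation modes of a posterior-driven forecast), and optional
binomial allele resampling $q \leftarrow
\mathrm{Binomial}(2N_e, q)/2N_e$ per generation at an effective population
size. Absent `population_size`, only the initialisation is random.
Fixation at $q = 0$ and $q = 1$ is absorbing; mean fitness of zero is
reported as an explicit error rather than silently producing NaN.

# Egg counting from photographs

Fecundity per female is estimated from egg-mass photographs by a pure
threshold-plus-regression procedure: the blue channel of the split RGB
image is extracted and pixels with intensity in $[0, 98]$ (inclusive on
both ends; 0 = black, 255 = white) are counted as egg pixels, then an
ordinary least-squares line maps pixel counts to egg numbers
(`estimate = max(0, round(slope \cdot pixels + intercept))`). The window
is inclusive by choice — "between 0 and 98" is ambiguous and inclusivity
changes counts by at most the boundary bin. No background correction,
morphology or declumping is applied: anything beyond the threshold and
regression would be a different method. Grayscale input is rejected
rather than coerced, because the procedure is defined on the blue channel
of an RGB split. The original regression sample and coefficients are not
published, so only the procedure — not any particular coefficient — is
checkable; calibration is refit per dataset.

# The synthetic generator

`simulate_screen()` simulates the screen forward with exact Mendelian
bookkeeping: four parental haplotypes i.i.d. Bernoulli($q_{true}$); F1
genotypes by per-parent transmission probability $g/2$ (so both-het and
homozygous founders — rare but allowed — are handled exactly, letting
tests isolate the detection model's one-het-parent special case); mass
sib-mating and neonate survival exactly as in the detection model; a line
recorded positive iff at least one surviving RR neonate appears, twice in
independent generations when the F3-style rescreen toggle is on. The
generator has no false-positive mechanism — a susceptible line can never
score positive — so rescreening can only lose true carriers.

Family structure defaults are the study conditions: 27.4 F1 females and
27.2 males per cage and 11.4 screened neonates per female, with standard
deviations back-calculated from the reported standard errors over 137
lines (≈ 11.7, 11.7 and 7.0). Counts are drawn from negative-binomial
distributions matched to those means and sds (Poisson if at the floor),
truncated at one adult per sex and zero neonates; the distribution family
is a generator configuration choice, and any integer count model matching
the first two moments would serve.

What the generator deliberately does **not** emulate: diapause and
rearing physiology, density-dependent fecundity, region structure beyond
a label, assortative mating, inbreeding depression in the F2, and
scoring error (false positives). Passing tests therefore demonstrate
internal consistency of the statistical machinery under the stated
genetic model — not robustness of a real screen to those biological
complications.

`generate_egg_image()` renders non-overlapping elliptical egg blobs at a
fixed blue intensity (default 50, inside the threshold window) on a white
canvas, recording exact egg and pixel counts; placement is rejection
sampling, and an over-full canvas is an error rather than an overlap.

# Numerical and testing choices

* Probabilities near 0/1 are handled in log space (`log1p`) in the exact
  posterior kernel and the $P_{No}$ product.
* All seeded functions save and restore the caller's RNG state, so
  library calls never perturb a user's simulation stream.
* Monte-Carlo cross-checks in the tests use the 3-standard-error
  criterion; problem sizes were chosen as the smallest that make those
  checks sharp: $10^6$ replicates for the $P_{No}$ oracle on a randomised
  grid, $10^6$ posterior draws for quantile checks, 2,000 replicated
  137-line screens for generator/estimator consistency and interval
  coverage. At $q_{true} = 0.005$ the 95% interval covers the implied
  frequency in well over 90% of screens; exact nominal coverage is not
  expected, both because the beta convention is a linearisation and
  because imperfect detection (≈ 97%) slightly deflates observed
  positives — the same conservatism the detection module quantifies.
* The estimation and detection stages are kept separate: $E(q)$ is not
  corrected for imperfect detection. This mirrors the reporting
  convention of published screens; folding $1 - P_{No}$ into the
  likelihood is a possible extension but would change the meaning of the
  printed estimates.

# Known limitations

* The carrier model ignores inbreeding and population structure; $E(q)$
  is slightly anti-conservative if relatives are sampled.
* The comparison $p$ and the replication design are reconstructions (see
  above) and should be cited as this package's definitions.
* The evolution recursion is deterministic-panmictic with soft selection;
  spatially explicit refuges, density dependence and two-toxin pyramids
  are out of scope.
* Egg counting inherits every limitation of a global threshold:
  overlapping masses, stained backgrounds or non-white substrates require
  recalibration or a different method.
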