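---
title: "Interpreting mtDNA mixtures: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Interpreting mtDNA mixtures: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(mtmix)
```

## The problem

Mitochondrial DNA is inherited as a single non-recombining haplotype, so
a mixed stain — a cigarette butt shared by victim and suspect, a tumor
sample contaminated by exogenous DNA — cannot be decomposed marker by
marker the way autosomal STR mixtures can. The interpretive unit is the
*lineage*: every maternal relative carries the same haplotype, and the
data are (i) a list of positions where the stain differs from the rCRS
reference, with mixed base calls encoded as IUPAC ambiguity letters, and
optionally (ii) a scaled peak height per position quantifying how much
of the signal carries the variant base.

`mtmix` covers the three questions that arise in this setting:
which combinations of database haplotypes can explain the stain
(deconvolution), what fraction each contributor supplied (quantitative
estimation), and how strongly the evidence supports one hypothesis over
another (likelihood ratios).

## Data model

A *profile* is the set of variant positions over a declared range,
default 16024–16365 (HVS-I, the standard forensic typing window; any
range up to the full control region can be declared instead). Bare
positions denote transitions — by far the most common mtDNA
substitutions — so `16093` means T→C at 16093; explicit tokens such as
`C16232A` record transversions. Positions outside the declared range are
rejected rather than dropped, since silently truncating a profile would
change every downstream frequency and consistency computation.

Reference bases are looked up in a bundled curated table of commonly
reported control-region sites (`rcrs_sites()`). The table is used only
to resolve implied transition partners and to check IUPAC codes against
the reference (e.g. `16093R` decodes to A/G, which cannot include the
rCRS base T there, and draws a warning); all deconvolution and
likelihood arithmetic operates on variant *positions* and never on
bases, so a position absent from the table simply parses with bases
unresolved.

Databases are entry lists; identical profiles under different sample
ids collapse to one distinct profile with a count. Frequencies are plain
counting estimates, `count/total`. For a haplotype absent from the
database the `add_one` policy — the conventional, defendant-favorable
choice — adds the query profile once before estimating, so an unseen
haplotype in a database of 2575 gets frequency 1/2576. No coancestry
(theta) or confidence-interval adjustment is applied; that correction
layer is deliberately out of scope.

## Categorical deconvolution

Under the baseline assumption of no dropout and no drop-in, a
contributor set explains a stain iff at every position:

* `MIXED` — at least one contributor carries the variant *and* at least
  one carries the reference;
* `VARIANT_ONLY` — every contributor carries the variant;
* `REF_ONLY` — no contributor carries it.

`enumerate_contributors()` applies this predicate to every unordered
m-multiset of distinct database profiles. An identical pair can
therefore never explain a stain with a mixed position — the predicate
rules it out — but is a legitimate (unidentifiable) explanation of a
stain with none. The search is deliberately plain exhaustive
enumeration: worked casework sets are small, and correctness is easier
to argue for than for a pruned search. A guard refuses m > 4 or more
than 10,000 distinct profiles unless forced.

Two subtleties are worth stating. First, a unique two-person solution
does not bound the number of contributors: any haplotype agreeing with
the solution outside the mixed positions can be added without changing
the categorical data. `superset_solutions()` enumerates these enlarged
sets; in the packaged worked example the three-person supersets include
a genuinely distinct third haplotype (`16093 16293`), not just copies
of the base pair. Second, consistency is combinatorial only: candidate
sets should always be reviewed for phylogenetic plausibility, and the
report output says so. No plausibility filter is implemented because no
algorithmic criterion is defined for one; that review remains expert
work.

Known contributors (a typed victim) are handled by constraining the
search — they are fixed members of every candidate set — never by
subtracting their signal from the stain.

## The quantitative model

With scaled peak heights ($y_0 + y_1 = 1$ per site) and a candidate
pair with variant indicators $x_{1i}, x_{2i} \in \{0, 1\}$, the model is

$$y_i = \beta x_{1i} + (1 - \beta) x_{2i} + \varepsilon_i,$$

where $\beta$ is the fraction contributed by the first haplotype.
Rewriting gives the one-parameter no-intercept regression

$$y_i - x_{2i} = \beta (x_{1i} - x_{2i}) + \varepsilon_i,
\qquad
\hat\beta = \frac{\sum_i (y_i - x_{2i})(x_{1i} - x_{2i})}
                 {\sum_i (x_{1i} - x_{2i})^2},$$

with standard error and t-tests from ordinary least squares on
$n - 1$ degrees of freedom. $H_0$: "contributor 1 did not contribute"
is $\beta = 0$; the mirrored test for contributor 2 is $\beta = 1$.
Swapping the pair order maps $\hat\beta \mapsto 1 - \hat\beta$.

Numerical and design choices:

* **Sites with no information about $\beta$** (neither or both
  contributors carry the variant) are retained: they contribute to the
  residual variance estimate and keep the design aligned with tabulated
  11-row data that include such sites and a reference pseudo-row.
* **$\hat\beta$ is never clamped** to [0, 1]; out-of-range estimates are
  flagged. Clamping would visibly distort the simulation-study
  distributions that validate the method.
* **R² is the centered** $1 - SS_{res}/SS_{tot}$, clipped to [0, 1] with
  a flag when the fit is worse than the mean. Whether centered or
  uncentered R² is used does not change which of two candidate pairs
  ranks higher on the same response, which is the only use made of it;
  the centered form penalizes both candidates identically.
* **Ranking ties** (R² difference below 1e-9) are reported as
  unresolved, not broken arbitrarily — both orderings of one unordered
  pair, for example, fit identically.
* **Degenerate pairs** (identical at every modelled site) are an error:
  the fraction is unidentifiable, and reporting a number would be
  misleading.
* **Inference assumes homoscedastic errors.** The generator's truncated
  noise violates exact normality near the bounds; the point estimate is
  a projection and remains valid regardless, and the type-I error of
  the $\beta = 0$ test is verified by simulation (with truncation
  disabled) to sit at its nominal level.

The model is strictly two-contributor; no three-way quantitative
regression is offered.

## Likelihood ratios

`lr_known_contributor()` covers the usual casework pair — numerator:
the known lineage and the suspect's lineage formed the mixture;
denominator: the known lineage and an unknown one — which reduces to
LR = 1/p. The arithmetic runs on integer counts, so count 1 in an
add-one database of 2575 + 1 profiles yields exactly 2576.

`lr_two_unknown()` evaluates a specific unordered pair against two iid
draws from the database: denominator $2 p_1 p_2$ for distinct profiles
(both orderings of the draw produce the same unordered evidence),
$p^2$ for an identical pair. The factor-2 convention is switchable
(`ordered_factor = FALSE`) for comparison with conventions that treat
the pair as ordered.

`prob_informative()` gives the probability $1 - \sum_j p_j^m$ that m
iid contributors are not all identical — the precondition for a mixture
to be detectable at all — with a Monte-Carlo counterpart
(`prob_informative_mc()`) for stratified or resampled what-if analyses.

For the clinical question, `contamination_lr()` compares H2 "the
apparent instabilities are contamination by a known haplotype" against
H1 "the tumor added x mutations". With mutations striking independently
and uniformly over S candidate phylogenetic sites, the H1 likelihood is
$(1/S)^x$ (`mutation_likelihood()`); a `distinct_sites` variant,
$1/\binom{S}{x}$, conditions on the x sites being distinct and is
offered as the conservative alternative reading. The caller must supply
S explicitly — a conservative analysis assigns a deliberate lower
limit, and a hidden default would invite overstated LRs. When
deconvolution finds *no* consistent contaminating haplotype the
contamination hypothesis is dismissed outright (LR = 0) with no
calculation, and when several candidates remain their frequencies sum
in the numerator.

## The generator and its calibration

`simulate_peaks()` draws, per site, $y_i = t_i + \varepsilon_i$ around
the theoretical height $t_i = \beta x_{1i} + (1-\beta) x_{2i}$ with
$\varepsilon_i \sim N(0, \sigma)$ and the result confined to [0, 1].
Confinement is by **rejection** (redraw until inside), because a
truncated normal is a distribution and rejection sampling preserves it;
clipping, which piles mass on the bounds, and unbounded draws, useful
for t-test diagnostics, are available as options.

`simulate_with_dropout()` adds the two artifact processes of real
low-template work: each contributor's variant at each site is zeroed
independently with probability d before scaling (dropout — a real
allele failing to amplify; the total signal is deliberately *not*
renormalized afterwards), and with probability c a spurious height
appears at a site carried by neither contributor (drop-in), drawn by
default as |N(0, σ)|, since no drop-in magnitude convention exists.
With d = c = 0 the extended generator consumes the identical random
stream as the plain one, so zero-rate reductions are bit-exact.

**Noise calibration.** σ is a free parameter of the generator, in peak
height units on the [0, 1] scale. The package default is σ = 0.075,
fixed by calibrating the 1000-replicate validation study
(`scripts/calibrate_noise.R`) against its three reference summaries —
a ~99% correct-model rate, fraction estimates centered on 0.30, and a
central 95% interval of roughly [0.22, 0.37]. The calibration is also
analytic: over the 11-site worked design the estimator has
$SD(\hat\beta) = \sigma/2$ (four informative sites, all with
$|x_{1i} - x_{2i}| = 1$), so a 95% half-width of 0.075 pins
$\sigma \approx 2 \times 0.075 / 1.96 \approx 0.075$. A much smaller σ
(e.g. 0.02, the per-site deviation visible in the packaged quantitative
fixture, which is a single realization, not a variance estimate) would
give an interval of ±0.02 and a 100% identification rate — inconsistent
with all three summaries at once.

**What the generator does and does not emulate.** It reproduces
site-independent, homoscedastic measurement noise, binomial dropout and
sporadic drop-in on a fixed site panel. It does not model preferential
PCR amplification (which biases fractions along the electropherogram),
background noise structure, site-to-site error correlation, or
length-heteroplasmy regions (16182–16193 conventions are excluded from
the profile grammar altogether). Passing simulation-based tests
therefore demonstrates correctness of the estimator and search under
the stated error model — not robustness to every artifact of Sanger
chemistry.

## Study sizes and reproducibility

The validation harness (`run_study()`) uses 1000 replicates for the
main fraction-recovery/model-selection study and 500 per grid point for
the dropout sweep d ∈ {0.01, …, 0.04}; at these sizes the binomial
standard error of a ~99% rate is ~0.3 percentage points, small enough
to compare against the reference summaries, and a full run takes
seconds. One root seed drives each study; summaries record it, and
identical seeds give bit-identical results. The command-line interface
refuses stochastic subcommands without `--seed` for the same reason.

## Known limitations

* Two aggressors from the same matriline are indistinguishable in
  principle; no statistic can help.
* Heteroplasmy is empirically indistinguishable from a low-level
  mixture at a single site; the package treats every mixed call as
  mixture signal and leaves the heteroplasmy-vs-mixture judgement
  (rare, usually single-site, mutation-hotspot-biased) to the analyst.
* The categorical search treats a VARIANT_ONLY call strictly: a
  position shared by all contributors is never reinterpreted as a
  missed low-level mixed call. Dropout-aware interpretation is the
  generator's and the quantitative module's domain.
* Frequencies come from whatever database is supplied; population
  stratification, and the strong dependence of the informative-mixture
  probability on the population sampled, are the user's
  responsibility.
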