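# mtmix

Statistical interpretation of mitochondrial DNA (mtDNA) mixtures from
control-region haplotype data, for forensic geneticists working stains
where autosomal and Y markers fail (degraded samples, hair shafts, low
template) and for clinical geneticists weighing contamination against
genuine mtDNA instability in tumor studies.

Because mtDNA is a single non-recombining haplotype block, a mixed stain
cannot be interpreted marker by marker: the question is which *lineages*
(maternal haplotypes) jointly explain the observed pattern, and how
strongly the evidence supports one explanation over another. `mtmix`
implements that workflow end to end:

- **Profiles and stains.** Haplotypes are sets of variant positions
  relative to the rCRS over a typed range (default HVS-I, 16024–16365);
  mixed stains are IUPAC-coded position lists (`16126Y` = C and T both
  observed at 16126). Frequency databases are plain region / sample id /
  profile tables.
- **Categorical deconvolution.** `enumerate_contributors()` exhaustively
  finds every m-contributor combination of database haplotypes consistent
  with a stain (MIXED positions need both a carrier and a non-carrier,
  VARIANT_ONLY positions need all carriers, REF_ONLY positions need
  none). The outcome is NO_SOLUTION, UNIQUE or MULTIPLE.
- **Quantitative deconvolution.** When scaled peak heights are available
  (y0 + y1 = 1 per site), the expected variant height under a
  two-contributor model is

      E[y_i] = beta * x1_i + (1 - beta) * x2_i,

  with x_ji the 0/1 variant indicator of contributor j at site i and
  beta the fraction contributed by contributor 1. `fit_mixture()`
  estimates beta by least squares on the rewritten one-parameter model
  y_i − x2_i = beta (x1_i − x2_i) + eps_i, giving the closed form
  beta_hat = Σ(y_i − x2_i)(x1_i − x2_i) / Σ(x1_i − x2_i)², with standard
  error, t-tests of "contributor absent" (beta = 0 or 1) and R².
  Competing candidate pairs that categorical search cannot distinguish
  are ranked by R² (`rank_hypotheses()`).
- **Evidence weight.** Likelihood ratios LR = P(E|H_num)/P(E|H_den) for
  the standard hypothesis pairs: known contributor + suspect vs. unknown
  (`lr_known_contributor()`, LR = 1/p), a named pair vs. two random
  lineages (`lr_two_unknown()`), the probability that an m-person
  mixture is informative at all (`prob_informative()`, 1 − Σp_j^m), and
  the clinical contamination-vs-instability LR
  (`contamination_lr()`, p_c / (1/S)^x for x apparent mutations over S
  phylogenetic sites).
- **Simulation.** `simulate_peaks()` / `simulate_with_dropout()`
  generate peak heights with truncated-normal noise, per-contributor
  allele dropout and drop-in; `run_study()` wraps the
  simulate-fit-rank loop used to validate the method.

A thin command-line wrapper is installed as `exec/mtmix`
(subcommands `deconvolve`, `quantify`, `lr`, `informative`,
`contaminate`, `simulate`, `fixtures`).

## Worked example

The packaged fixture `table1_excerpt` is a nine-sample excerpt of an
Iberian HVS-I database (eight distinct haplotypes; `16093 16224 16311`
occurs twice). A stain shows the 16093 transition throughout plus mixed
calls at 16189 and 16293:

```r
library(mtmix)
db <- mtmix_fixture("table1_excerpt")
stain <- parse_mixture("16093 16189Y 16293R")
enumerate_contributors(db, stain, m = 2)
#> Deconvolution search (m = 2): UNIQUE
#>   [1] 16093  |  16093 16189 16293
#>   Note: candidate sets warrant phylogenetic review; larger mixtures
#>   may also be consistent (see superset_solutions).
```

Exactly one two-person combination explains the stain. If the
`16093`-lineage individual is a known contributor and the other
haplotype has estimated frequency 1/11, the evidence against a random
unknown donor is:

```r
lr_known_contributor(freq = 1 / 11)
#> Likelihood ratio
#>   H_num: known lineage + queried lineage contributed
#>   H_den: known lineage + unknown lineage contributed
#>   P(E|H_num) = 1, P(E|H_den) = 0.0909091
#>   LR = 11, log10(LR) = 1.04139
```

With peak heights (fixture `table2_quant`, a simulated
`16093 16189 16293` + `16093 16224 16311` mixture at fraction 0.3), the
contributor fraction is recovered from the quantitative model:

```r
tab2 <- mtmix_fixture("table2_quant")
pair <- db$profiles[c("16093 16189 16293", "16093 16224 16311")]
fit <- fit_mixture(tab2$y1,
                   two_contributor_model(pair, sites = tab2$sites,
                                         rcrs_row = TRUE))
summary(fit)
#> Two-contributor mixture fit (11 sites)
#>   contributor 1: 16093 16189 16293
#>   contributor 2: 16093 16224 16311
#>   beta_hat = 0.295 (se 0.006519), R^2 = 0.9987
#>   H0 'contributor 1 absent' (beta = 0): t = 45.25, p = 6.685e-13
#>   H0 'contributor 2 absent' (beta = 1): t = -108.1, p = 1.121e-16
#>   residual sd 0.01304 on 10 degrees of freedom
```

The first contributor is estimated at 29.5% of the template, close to
the generating fraction 0.3, and both "contributor absent" hypotheses
are firmly rejected. A 1000-replicate study of the same design
(`run_study()`, noise sd 0.075) identifies the correct pair over the
qualitatively indistinguishable alternative
`16093 16293` + `16093 16189 16224 16311` in ~99% of replicates, with
the fraction estimates centered on 0.30.

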