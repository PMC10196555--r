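---
title: "Refuge-based resistance management: models and methods in btrefuge"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Refuge-based resistance management: models and methods in btrefuge}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(btrefuge)
library(dplyr)
```

## The scientific problem

Transgenic cotton producing the Bacillus thuringiensis toxin Cry1Ac kills
cotton bollworm (*Helicoverpa armigera*) larvae, and resistance
management hinges on *refuges*: non-Bt host plants that sustain
susceptible insects which mate with resistant survivors from the Bt crop.
Classic theory says refuges work best when resistance is recessive. In
northern China resistance is conferred by a *dominant* point mutation
(T92C in the tetraspanin gene *HaTSPAN1*), which should spread fast — yet
field monitoring found its frequency stalling around 0.10. `btrefuge`
implements the full quantitative chain needed to interrogate this
situation: a deterministic selection model with habitat-weighted fitness,
an effective-refuge calculator, a pooled-amplicon estimation pipeline,
the surveillance statistics, and synthetic-data generators that make
every stage testable against known truth.

## The selection model

One autosomal locus, two alleles (`r` resistant, `s` susceptible), an
effectively infinite, randomly mating population, no mutation, migration
or drift. Each generation applies viability selection to Hardy–Weinberg
genotype frequencies:

$$p' = \frac{p\,(p\,w_{rr} + q\,w_{rs})}{p^2 w_{rr} + 2pq\,w_{rs} + q^2 w_{ss}},
\qquad q = 1 - p.$$

Because small plantings of Bt cotton and non-Bt hosts are interleaved and
moths disperse widely, the two habitats are not modelled as separate
demes; instead each genotype experiences the *marginal* fitness

$$w_g = R\,w_{g,\mathrm{refuge}} + (1 - R)\,w_{g,\mathrm{Bt}},$$

where $R$ is the year's effective refuge fraction. One refuge value
applies to all generations within a year (the data provide one value per
year), and the reported frequency for a year is the frequency *entering*
that year, so the first entry of every trajectory equals the initial
condition.

### Parameters

| parameter | meaning | default | units |
|---|---|---|---|
| `h` | dominance of resistance on Bt cotton | 0.79 | – |
| `cost` | recessive fitness cost on non-Bt hosts | 0.36 | – |
| `incomplete_resistance` | fitness of `rr` on Bt relative to non-Bt hosts | 0.49 | – |
| `w_ss_bt` | fitness of `ss` on Bt cotton | 0 | – |
| `p0` | initial allele frequency entering `start_year` | 0.001 | – |
| `generations_per_year` | selected generations per year | 3 | – |

All defaults are the empirical estimates for the T92C system: dominance
and incomplete resistance from fitness experiments with the resistant
strain, the observed 0.001 frequency in 2006, and three generations on
cotton per season in northern China. `w_ss_bt = 0` reflects complete
mortality of susceptibles at the diagnostic toxin dose; it is exposed as
a parameter for sensitivity analysis.

### Composing genotype fitness from (h, cost, I)

The underlying per-genotype fitness measurements on Bt and non-Bt cotton
are not published as a table; only the three summary parameters are. The
package therefore reconstructs the fitness table as

* refuge: $w_{ss} = w_{rs} = 1$, $w_{rr} = 1 - c$ (recessive cost);
* Bt cotton: $w_{rr} = I\,(1-c)$, $w_{rs} = w_{ss} + h\,(w_{rr} - w_{ss})$.

The `ratio` reading of incomplete resistance — `rr` fitness on Bt divided
by `rr` fitness on non-Bt hosts — follows its definition ("fitness of
the resistant strain was lower on Bt cotton than on non-Bt cotton"). An
`absolute` mode ($w_{rr,\mathrm{Bt}} = I$ outright) is available via
`fitness_table(mode = "absolute")` because the definition does not pin
down the normalisation.

This reconstruction matters, and it is the package's main known
limitation. With $w_{ss,\mathrm{Bt}} = 0$ the no-refuge recursion is
invariant to rescaling the Bt fitness column, so the explosive no-refuge
behaviour (frequency 0.795 entering 2007, past 0.75 in one season)
constrains only the *ratio* $w_{rs}/w_{rr} = h$ on Bt cotton. The
high-refuge trajectory, by contrast, depends on the *absolute* Bt
fitness: under the `ratio` reading the 2020 frequency under the
regression-derived refuge series is 0.070, under the `absolute` reading
0.187, while the originally published prediction from the unpublished
empirical fitness table is 0.13 — between the two. Reproducing 0.13
exactly would require $w_{rr,\mathrm{Bt}} \approx 0.40$, which no
composition of the three printed parameters yields. The package keeps the
definition-faithful `ratio` mode as the default and documents the spread;
both modes reproduce the qualitative conclusion (dominant resistance
halted at low frequency by large refuges) and the same equilibrium
structure.

### Overdominance and the halted trajectory

At high refuge fractions the marginal fitness becomes overdominant:
selection for resistance on Bt cotton is balanced by the recessive cost
and incomplete resistance, giving a stable internal equilibrium

$$p^{*} = \frac{w_{rs} - w_{ss}}{2\,w_{rs} - w_{ss} - w_{rr}}.$$

```{r}
ft <- fitness_table()
tibble(R = c(0.80, 0.85, 0.90),
       p_star = sapply(c(0.80, 0.85, 0.90),
                       function(R) overdominance_equilibrium(habitat_fitness(ft, R))))
```

`simulate_trajectory()` iterating at fixed $R$ converges to this closed
form (checked to 1e-6 in the test suite), which explains why a dominant
resistance allele can plateau near 0.1 instead of fixing.

## Effective refuge percentage

Hectares alone misstate refuge strength because host crops differ in how
many moths they produce. Each crop's non-Bt area is weighted by its
per-hectare production of *H. armigera* relative to non-Bt cotton
(weight 1):

$$\mathrm{ER\%} = 100 \cdot
\frac{\sum_i a_i (1-b_i) w_i}{\sum_i a_i (1-b_i) w_i + \sum_i a_i b_i}.$$

Bt-planted area enters the denominator hectare-for-hectare as pure
selection habitat (configurable via `bt_weight`); insecticide sprays are
deliberately *not* used to adjust the refuge, the conservative convention
of the source analysis. The yearly series can also be reconstructed from
the published regression of effective refuge percentage on year,
$y = 2.85x - 5667$ ($R^2 = 0.99$), clamped to $[0, 100]$ to guard the
extrapolated end years 2006 and 2020; this reconstruction reproduces the
published period means (66% for 2007–2015, 85% for 2016–2019) within one
percentage point and is the packaged default refuge series for the
"all non-Bt hosts" scenario, because the underlying yearly crop-area
table is supplementary-only.

## Pooled-amplicon frequency estimation

The assay pools one leg per moth per site and sequences a 216-bp
amplicon: a 204-bp genomic fragment containing the variant, flanked by
site-specific 6-bp tags on both primers. The pipeline:

1. **Demultiplex and merge** (`demultiplex_reads()`): each read pair is
   reconstructed into its amplicon (forward read plus
   reverse-complemented mate), requiring exact agreement over the
   overlap; both tags must exactly match one site's pair. Anything else
   is rejected, and assigned + rejected always equals the input count.
   Exact tag matching is the simplest faithful reading of sorting by
   barcode; no mismatch tolerance is applied. Full overlap-alignment
   merging of arbitrary library structures is out of scope — the merge
   assumes the amplicon length implied by the reference and tag lengths.
2. **Collapse and filter** (`count_alleles()`): identical sequences are
   collapsed; distinct sequences with frequency strictly below
   $1/(2n)$ — $n$ legs in the pool, so $1/(2n)$ is the smallest allele
   frequency the pool can truly contain — are removed as presumptive
   sequencing errors. The filter is idempotent, and the strictly-less-than
   rule keeps sequences sitting exactly at the threshold.
3. **Site frequency** (`site_frequency()`): resistant-base reads divided
   by *all* surviving reads; reads with a non-canonical base at the
   variant position stay in the denominator (configurable upstream).
4. **Annual mean** (`annual_mean_bootstrap()`): unweighted mean across
   sites with a percentile bootstrap interval over sites (1000
   repetitions). Weighting by the square root of pooled legs is
   available but off by default; the two give nearly identical series in
   practice.

The variant's offset within the fragment is not derivable from published
material, so for synthetic data it is placed mid-fragment (position 102
of 204) and recorded in the reference FASTA header, making generated
datasets self-describing.

## Monitoring statistics

* `wilson_ci_cc()`: Wilson score interval with Newcombe's continuity
  correction, bounds clipped to $[0,1]$, lower $= 0$ at zero successes
  and upper $= 1$ at $n$ of $n$ — the procedure used for allele
  frequencies from individually genotyped moths.
* `genotype_allele_frequency()`: $(2\,rr + rs) / (2\,\mathrm{total})$.
* `resistance_percentage()`: unweighted across-site mean of percent
  survival at the diagnostic dose (1 µg Cry1Ac/cm² diet), with a
  site-level bootstrap interval. The bioassay interval method is not
  stated in the source; the site-level bootstrap was chosen for
  consistency with the pooled-frequency procedure, and is documented as
  this package's choice rather than asserted as the original one.
* `log_linear_regression()` / `log_pearson_correlation()`: base-10 logs
  (base 10 reproduces the magnitude of published intercepts), two-sided
  p-values, $df = n - 2$.
* `two_sample_t_test()`: pooled-variance Student form with
  $df = n_a + n_b - 2$ — forced by the published $df = 11$ for group
  sizes 9 and 4 (Welch would give fractional df). All tests two-sided.

## Synthetic data: what it emulates and what it does not

`simulate_moth_pool()` draws Hardy–Weinberg genotypes;
`simulate_pooled_reads()` builds tagged read pairs from the pool's
allele copies (two per moth) with independent per-base substitution
errors applied to each read; `simulate_bioassay()` draws genotypes and
genotype-specific survival at the diagnostic dose;
`make_crop_table()` / `make_linear_refuge_crops()` build crop tables,
including landscapes whose refuge series follows a prescribed straight
line (used to verify that refitting recovers the slope 2.85).

Deliberate simplifications: constant read quality (no quality model), no
indels or chimeras, no PCR amplification bias, identical error rates
along the read, and known amplicon structure. Consequently, passing
recovery tests demonstrates correctness of the estimation logic — tag
sorting, merging, the $1/(2n)$ filter, frequency arithmetic, bootstrap —
under idealised noise, not robustness to real instrument artefacts.
Read allocation to alleles is multinomial by default; a deterministic
proportional mode exists so exactness tests (error rate 0, recovery
exact) are possible.

Every generator is reproducible under a fixed seed (via `withr`), and
each generated dataset carries its ground truth (the realised pool
allele fraction), which the recovery tests use: at pools of 100 legs,
depth 10,000 and error rate 0.001, estimated site frequencies fall
within three binomial standard errors of the pool truth for true
frequencies 0.01–0.5, and all injected singleton error variants fall
below the $1/(2 \cdot 100)$ threshold.

## Numerical and design notes

* Frequencies are clamped to $[0,1]$ after each generation only to absorb
  floating-point rounding; the recursion itself cannot leave the interval.
* Zero mean fitness (e.g. $p = 0$ with $w_{ss} = 0$) raises an explicit
  extinction error rather than returning NaN.
* `overdominance_equilibrium()` returns `NA` (not an error) when the
  fitness triple is not overdominant.
* Bootstrap intervals use `quantile()` type 7 on the resampled means;
  for four or fewer sites the bounds were validated against the
  exhaustive $n^n$ resampling distribution.
* The within-year order of operations applies the same habitat fitness
  to all three generations; reporting start-of-year frequencies matches
  yearly monitoring points, with a ±1-generation ambiguity inherent in
  comparing to published yearly values.
* Problem sizes in the shipped tests and default pipeline configuration
  (e.g. 2–4 sites, depths 300–10,000, 100–1000 bootstrap repetitions)
  were chosen as the smallest sizes at which the statistical assertions
  are stable; all generators scale to realistic depths.

## Limitations

Single locus and single toxin (no pyramids), deterministic (no drift, no
spatial structure), no migration between regions, fitness reconstruction
from three summary parameters as discussed above, and no processing of
real sequencer output (quality trimming, adapter clipping, mapping) —
the pipeline starts from structurally clean paired reads of the known
amplicon design.
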