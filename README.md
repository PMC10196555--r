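# btrefuge

Modelling and monitoring the evolution of insect resistance to transgenic
Bt crops under host-plant refuge strategies.

The motivating system is resistance of the cotton bollworm (*Helicoverpa
armigera*) to Cry1Ac cotton in northern China, where a single, *dominant*
point mutation (T92C in the tetraspanin gene *HaTSPAN1*) confers
resistance. Dominant resistance is expected to spread fast, yet large
plantings of conventional, non-Bt host crops (cotton, corn, peanut,
soybean) can act as refuges that sustain susceptible insects, dilute
selection, and — together with a fitness cost and incomplete resistance —
stall the mutation at low frequency. The package is aimed at resistance
researchers and modellers who want to reproduce, probe, or extend that
analysis chain: simulation, refuge accounting, pooled-sequencing
estimation, and monitoring statistics.

## What it implements

**Deterministic population-genetic simulator.** One locus, two alleles
(`s` susceptible, `r` resistant). Each generation applies the standard
Hardy–Weinberg viability-selection recursion

```
p' = p (p w_rr + q w_rs) / (p² w_rr + 2pq w_rs + q² w_ss),   q = 1 − p
```

with habitat-weighted marginal fitness `w_g = R w_g,refuge + (1 − R)
w_g,Bt` for effective refuge fraction `R`. Genotype fitness is composed
from the dominance of resistance on Bt cotton (`h`), a recessive fitness
cost on non-Bt hosts (`c`, so `w_rr,refuge = 1 − c`), and incomplete
resistance (`I`, the fitness of `rr` on Bt cotton relative to non-Bt
hosts). Empirical defaults: `h = 0.79`, `c = 0.36`, `I = 0.49`, complete
mortality of `ss` on Bt cotton, frequency 0.001 entering 2006, three
selected generations per year. A closed-form overdominance equilibrium
(`p* = (w_rs − w_ss)/(2 w_rs − w_ss − w_rr)`) supports analysis of the
balanced polymorphism that large refuges can create.

**Effective refuge calculator.** `100 · Σ aᵢ(1−bᵢ)wᵢ / (Σ aᵢ(1−bᵢ)wᵢ +
Σ aᵢbᵢ)` over crops with areas `aᵢ`, Bt fractions `bᵢ`, and per-hectare
pest production `wᵢ` relative to non-Bt cotton; plus reconstruction of
the yearly series from the published regression on year
(y = 2.85x − 5667).

**Pooled-amplicon frequency pipeline.** Demultiplexing of dual-tagged
216-bp paired-end amplicons by exact 6-bp tag match, pair merging with
overlap checking, collapse of identical sequences, removal of sequences
rarer than `1/(2n)` (n pooled legs — the smallest allele frequency the
pool can truly contain), allele classification at the variant position,
and annual means with site-level bootstrap confidence intervals (1000
repetitions).

**Monitoring statistics.** Continuity-corrected Wilson intervals,
genotype-tally allele frequencies, diagnostic-dose bioassay resistance
percentages, log10-scale linear regression and Pearson correlation, and
pooled-variance two-sample t-tests.

**Synthetic data with known truth.** Hardy–Weinberg moth pools, tagged
read-pair generators with per-base substitution errors, bioassay
outcomes, and crop tables — every pipeline stage is testable end to end
without external data.

## Worked example

```r
library(btrefuge)

ft <- fitness_table()           # h = 0.79, cost = 0.36, I = 0.49
ft
#> Genotype fitness table (h = 0.79, cost = 0.36, incomplete resistance = 0.49, ratio)
#> # A tibble: 2 × 4
#>   habitat    w_ss  w_rs  w_rr
#>   <chr>     <dbl> <dbl> <dbl>
#> 1 refuge        1 1     0.64
#> 2 bt_cotton     0 0.248 0.314

# hypothesis (i): refuges have no effect
no_refuge <- simulate_trajectory(scenario(refuge = 0, fitness = ft))
glance(no_refuge)
#> # A tibble: 1 × 5
#>   n_years p_start p_final threshold first_year_above
#>     <int>   <dbl>   <dbl>     <dbl>            <int>
#> 1      15   0.001   1.000      0.75             2007

# hypothesis (iii): non-Bt cotton and other non-Bt hosts act as refuge,
# with yearly fractions from the published regression line
series <- refuge_series_from_regression(2006:2019)
full <- simulate_trajectory(scenario(refuge = series, fitness = ft))
tail(full, 3)
#> # A tibble: 3 × 3
#>    year refuge      p
#>   <int>  <dbl>  <dbl>
#> 1  2018  0.843 0.0648
#> 2  2019  0.872 0.0685
#> 3  2020 NA     0.0704
```

Without refuges the dominant mutation rockets past 0.75 in the very first
simulated year (frequency 0.795 entering 2007) — resistance essentially
immediately. Under the observed effective-refuge series it climbs slowly
towards the overdominance equilibrium implied by the balance of selection
on Bt cotton against cost + incomplete resistance in the refuge
(`overdominance_equilibrium(habitat_fitness(ft, 0.87))` ≈ 0.096),
reaching 0.070 by 2020 — the same order as the ~0.10 frequency observed
in the field through 2020.

The pooled-sequencing side:

```r
ref <- synthetic_reference(seed = 1)
scheme <- make_tag_scheme("S01", n_legs = 100, year = 2016, seed = 2)
pool <- simulate_moth_pool(p = 0.10, n = 100, seed = 3)
reads <- simulate_pooled_reads(pool, "S01", scheme, ref,
                               depth = 10000, error_rate = 0.001, seed = 4)
demux <- demultiplex_reads(reads$r1, reads$r2, scheme)
counts <- count_alleles_by_site(demux$reads, scheme,
                                reference = ref$sequence,
                                variant_pos = ref$variant_pos)
site_frequency(counts)[, c("site", "n_reads_surviving", "frequency")]
#> # A tibble: 1 × 3
#>   site  n_reads_surviving frequency
#>   <chr>             <int>     <dbl>
#> 1 S01                7400    0.0846
```

(The realised pool of 100 moths carried allele fraction 0.08; the
pipeline recovers it within binomial noise after rejecting pairs with
overlap mismatches and filtering rare error sequences.)

A command-line wrapper with subcommands `simulate`, `refuge`, `freq`,
`stats`, `synth`, and `all` is installed at
`inst/scripts/btrefuge.R`; see its header for usage.

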