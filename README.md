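# amphidisp

Stage-biased dispersal inference for intertidal amphipod surveys.

## The problem

The mud-burrowing amphipod *Corophium volutator* dominates the intertidal
mudflats of the upper Bay of Fundy and swims at night around the new or full
moon. Swimmers caught in stationary plankton nets are a proxy for dispersing
individuals; sediment cores sample the resident population they leave
behind. Pairing the two reveals *which* life-history stages disperse and
*what* features of the resident population (density, biomass, sex and stage
structure) drive them — without mark-recapture, which is impractical for
small, numerous marine invertebrates.

`amphidisp` implements the complete inference chain for such paired surveys,
for ecologists analysing their own net/core data or simulating survey
designs:

1. **Normalization** — Folsom subsample expansion, swimmer density
   (ind·m⁻³ = count / fraction / filtered volume), resident density
   (ind·m⁻² = count / core area), biomass via a length–weight allometry
   *W* = *a·L^b*, and the `log10(x + 1)` variance-stabilizing transform.
2. **Where does the variation live?** A fully random three-factor ANOVA with
   Site (*S*), Round (*R*) and Night nested in Round (*N(R)*). All factors
   are random, so Round has no exact error term and is tested with a
   quasi-F, `(MS_R + MS_SN(R)) / (MS_N(R) + MS_RS)`, with Satterthwaite
   degrees of freedom. Variance components come from the expected-mean-square
   algebra, e.g. `σ²_S = (MS_S − MS_RS) / (bcn)` with *n* the harmonic mean
   of per-night replicate counts.
3. **Who disperses?** A bootstrap comparison of swimmer and resident size
   distributions on a 0.5-mm grid: 1000 resamples of *m* residents (with *m*
   the number of swimmers actually measured), trimming 25 values per tail per
   class for 95% limits; and likelihood-ratio G-tests,
   `G = 2·Σ O·ln(O/E)`, of the five adult stages (small/large males,
   small/large non-ovigerous females, ovigerous females) with the standard
   pooling rules when a stage is empty.
4. **Is dispersal density-dependent?** Reduced major axis (Model II)
   regression of log swimmer density on log resident density or biomass —
   slope = sign(r)·SD_y/SD_x — with Student's t for slope = 0, Clarke's T
   (non-integer df) for slope = 1, and the shape classification: a log-log
   slope below 1 means an ascending but decelerating response
   (proportionally less swimming as density rises).
5. **Propensity** — standardized swimming activity (stage swimmer density ÷
   same-stage resident density), Pearson-correlated against resident
   covariate stages, plus the variance/mean patchiness index.

A synthetic survey generator (`generate_survey()`) reproduces the field
design — 9 sites × 3 rounds × 3 nights × 2–3 nets plus 12 cores per
site × round, site-dominated hierarchical variance, 2:1 female-biased
adults, stage-specific swimming over-representation, sub-linear log-log
density dependence — so every stage of the pipeline is testable against
known truth.

## Worked example

```r
library(amphidisp)

sv <- generate_survey(survey_config(seed = 1))
d <- net_density(sv)               # per-net swimmer density, ind/m^3
d$y <- log10_plus1(d$density_m3)
varcomp_anova(d, "y")
```

```
Random-model ANOVA (Site x Round, Night nested in Round)
  a = 9 sites, b = 3 rounds, c = 3 nights, n = 2.656 (harmonic mean)
              Source  df    MS   F       p Component %Var
               Round   2 1.906 1.2  0.3483     0.004  0.9
                Site   8 5.855 7.3  0.0004     0.211 50.5
        Round x Site  16 0.802 5.0 6.4e-06     0.081 19.3
        Night(Round)   6 0.989 6.2 7.1e-05     0.035  8.3
 Night(Round) x Site  48 0.159 3.6 2.2e-09     0.043 10.3
               Error 145 0.045                 0.045 10.7
```

Most variation in swimming sits at the Site level (50% here): population-level
differences between mudflats, not night-to-night noise. Density dependence of
total swimming on the resident population:

```r
x <- cell_means(core_density(sv), "density_m2")   # site x round means, 12 cores
y <- cell_means(net_density(sv), "density_m3")    # site x round means, 7-9 nets
ok <- x$mean > 0 & y$mean > 0
rma_fit(log10_strict(x$mean[ok]), log10_strict(y$mean[ok]))
```

```
RMA fit (n = 26): slope = 0.770 +/- 0.095, intercept = -1.511, r = 0.795
  H0 slope=0: t[24] = 6.42, p = 1.23e-06
  H0 slope=1 (Clarke): T[19.4] = 2.11, p = 0.0477
  shape: ascending-decelerating
```

The slope is clearly positive (more residents, more swimmers) and
significantly below 1: a decreasing *proportion* of residents swims as
density rises. Single realizations vary — across surveys drawn from this
same configuration, fits range from undetectable to strongly decelerating;
nine sites give limited power, which is itself a useful design lesson from
the simulator.
`run_all()` executes the whole battery (ANOVA per stage, per-cell bootstrap
and G-tests with explicit skipped-below-threshold statuses, the RMA table,
propensity and patchiness) and writes a delimited-text report bundle with a
run manifest.

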