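# macaffil

Analysis pipeline for male-infant affiliative relationships in wild
multi-male, multi-female primate groups, built for the crested macaque
(*Macaca nigra*) study system: groups of 50-80 animals with 13-25
reproducing females, 4-11 adult males, high male turnover and strong male
reproductive skew, and infants followed through their first year by
focal-animal and scan sampling.

The package implements every quantitative stage of such a study:

* **Dominance** -- sequential Elo ratings from dated decided agonistic
  events. With ratings `r_w`, `r_l` and expected winner score
  `p = 1/(1 + 10^((r_l - r_w)/400))`, the winner gains `k(1 - p)` and the
  loser loses the same (entry rating 1000, `k = 100`); daily affine
  standardization to [0, 1] within each (group, sex, day) stratum.
* **Genotyping** -- multi-tube consensus calls from replicate
  microsatellite PCRs (heterozygote: both alleles confirmed twice in >= 4
  replicates; homozygote: one allele in >= 6 replicates with no second
  allele confirmed twice), allele frequencies, Ho, PIC, Monte Carlo exact
  Hardy-Weinberg test, null-allele index, and the probabilities of
  identity `PID = 2(sum p^2)^2 - sum p^4` and
  `PIDsib = 1/4 + (sum p^2)/2 + (sum p^2)^2/2 - (sum p^4)/4`.
* **Parentage** -- genetic maternity confirmation, Mendelian exclusion of
  candidate sires with strict/standard/relaxed categories and a
  conception-presence tie-break, LOD scores with a genotyping-error model,
  and a simulation-based assignment confidence.
* **Partner preference** -- event-level permutation tests on dyadic
  contingency tables (initiator labels shuffled, original data counted as
  one permutation, upper-tail chi-square p), with adjusted-residual
  preferred-partner flags.
* **Daily dyad models** -- assembly of dyad-day tables (binary affiliation
  response per direction, standardized ranks, mother presence,
  running mother-male affiliation, paternity, conception presence,
  controls, scan-count offset) and binomial (mixed) models with two
  Gaussian-kernel temporal-autocorrelation terms whose bandwidths are
  chosen by likelihood; full-vs-null LRT, hierarchical interaction
  pruning, VIF and stability diagnostics.
* **Synthetic data** -- a seeded generator that emulates the whole study
  (demography with gamma-tenure male migration, rank-skewed paternity,
  focal/scan sampling, dyad-day affiliation with planted effects and a
  per-dyad AR(1) latent term, Mendelian markers with allelic dropout), so
  every stage is validated against known truth.

## Worked example

One small synthetic study end to end:

```r
library(macaffil)
cfg <- sim_config(n_groups = 1, females_per_group = 10, males_per_group = 5,
                  study_days = 500, birth_rate = 4e-3,
                  male_mean_tenure_days = 400, male_tenure_sd_days = 250,
                  seed = 11)
res <- run_pipeline(cfg, out_dir = tempfile(), n_perm = 1000, fit = "glm")
res$descriptives
#> Male-infant interaction descriptives
#>   male-infant interactions: 782 (96.5% affiliative)
#>   affiliations initiated by infants: 538 of 755 (71.3%)
#>   scans near a male: mother absent 995 vs present 208 (ratio ~5)
#>   scans near the mother: male absent 2000 vs present 208 (ratio ~10)
#>   sires present at offspring's first birthday: 28.6%
```

Most male-infant interactions are affiliative and infants initiate about
two thirds of them; an infant is ~5 times more often near a male without
its mother than with her (the single-group setting inflates the second
ratio relative to the three-group default).

```r
subset(res$locus_stats, select = c(locus, n_alleles, Ho, PIC, PIDsib))[1:4, ]
#>   locus n_alleles        Ho       PIC    PIDsib
#> 1   L01         6 0.7500000 0.6684452 0.4315643
#> 2   L02         6 0.7142857 0.7692193 0.3682315
#> 3   L03         5 0.4444444 0.3591749 0.6536867
#> 4   L04         6 0.7142857 0.6675819 0.4274569

res$paternity[1:4, c("offspring", "sire", "category", "lod")]
#>   offspring   sire category       lod
#> 1     G1I01 G1M003   strict  7.944932
#> 2     G1I02 G1M010   strict 10.459356
#> 3     G1I03 G1M002   strict  6.827851
#> 4     G1I04 G1M003   strict  8.759462
```

Every sire here is assigned by strict exclusion (all other candidates
mismatch on >= 2 loci) with strongly positive LOD support; the assignments
match the generator's true sires.

```r
f <- res$fits$infant        # infant-initiated direction, with AC terms
round(f$sigma, 1)
#> infant   male
#>   52.8   43.5
subset(f$coefficients,
       term %in% c("male_rank", "mother_presence", "mother_male_affiliation"))
#>                      term    estimate        se
#> 2               male_rank  0.06800989 0.1134926
#> 4         mother_presence -0.13361538 0.1003705
#> 5 mother_male_affiliation  0.05320003 0.1218071
```

The optimized autocorrelation bandwidths are a few weeks, and the
recovered coefficients carry the generator's planted signs (+0.15, -0.2,
+0.1 at this small scale; estimates tighten at the default three-group
scale -- see `analysis/07_fit_models.R`).

## The analysis workflow

`analysis/01_simulate.R` through `analysis/08_report.R` run the default
two-year, three-group study stage by stage (simulation, Elo ratings,
genotyping, paternity, preference tests, model tables, AC-GLMM fits,
descriptive report), each printing what it found and writing its tables
under `results/`. Run them in order from the repository root:

```sh
Rscript analysis/01_simulate.R   # MACAFFIL_SEED=<int> to change the seed
Rscript analysis/02_dominance.R
# ...
Rscript analysis/08_report.R
```

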